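series_to_vector <- function(s, value_col = "value") {
  if (is.numeric(s) && !is.null(names(s))) return(s)
  if (is.data.frame(s) && all(c("sample_id", value_col) %in% names(s))) {
    return(stats::setNames(s[[value_col]], s$sample_id))
  }
  stop("a biomass series must be a named numeric vector or a data frame ",
       "with columns sample_id and ", value_col)
}

#' Fold difference between two paired biomass series
#'
#' Per shared sample, the >= 1-oriented ratio `max(a, b) / min(a, b)`;
#' reported are its mean and SD over pairs, the number of usable pairs, and
#' the fraction of pairs where series `a` exceeds `b` (the directional
#' count, e.g. "higher in 29 out of 30 samples"). Pairs with a zero or
#' missing value are dropped with a message.
#'
#' @param series_a,series_b Named numeric vectors (names = sample ids) or
#'   data frames with `sample_id` and `value` columns.
#' @return List `mean_fold`, `sd_fold`, `n`, `fraction_a_gt_b`.
#' @export
fold_difference <- function(series_a, series_b) {
  a <- series_to_vector(series_a)
  b <- series_to_vector(series_b)
  ids <- intersect(names(a), names(b))
  av <- a[ids]
  bv <- b[ids]
  ok <- is.finite(av) & is.finite(bv) & av > 0 & bv > 0
  dropped <- sum(!ok)
  if (dropped > 0L) {
    message("fold_difference: dropped ", dropped,
            " pair(s) with zero or missing values")
  }
  av <- av[ok]
  bv <- bv[ok]
  if (length(av) < 2L) stop("need at least 2 paired positive samples")
  fold <- pmax(av, bv) / pmin(av, bv)
  list(
    mean_fold = mean(fold),
    sd_fold = stats::sd(fold),
    n = length(fold),
    fraction_a_gt_b = mean(av > bv)
  )
}

#' Agreement of spatial dynamics between two measurement methods
#'
#' For each month with at least three locations, the Spearman correlation
#' (via [spearman_trend()]) between the two series across locations; months
#' with fewer locations are skipped.
#'
#' @param series_a,series_b Named numeric vectors or data frames as in
#'   [fold_difference()].
#' @param metadata Tibble with `sample_id`, `location`, `month`.
#' @return List: `per_month` tibble (`month`, `rs`, `p`, `n`) and
#'   `median_rs` across months.
#' @export
trend_agreement <- function(series_a, series_b, metadata) {
  a <- series_to_vector(series_a)
  b <- series_to_vector(series_b)
  meta <- metadata[metadata$sample_id %in% intersect(names(a), names(b)), ]
  meta <- meta[!is.na(meta$location), ]
  rows <- list()
  for (m in sort(unique(meta$month))) {
    mm <- meta[meta$month == m, ]
    if (length(unique(mm$location)) < 3L) next
    st <- spearman_trend(a[mm$sample_id], b[mm$sample_id])
    rows[[length(rows) + 1L]] <- tibble::tibble(
      month = m, rs = st$rs, p = st$p, n = st$n
    )
  }
  if (length(rows) == 0L) stop("no month has at least 3 locations")
  per_month <- dplyr::bind_rows(rows)
  list(per_month = per_month, median_rs = stats::median(per_month$rs))
}
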