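#' Per-location median copies over months
#'
#' For every OTU and location, the median of its copies/100 uL across the
#' sampled months. Missing samples are excluded, never imputed.
#'
#' @param long Long profile tibble with columns `otu_id`, `location`,
#'   `month`, `copies` (e.g. `quantify_dataset()$long`).
#' @return Tibble `otu_id`, `location`, `median_copies`, with `location` a
#'   factor in system order.
#' @export
location_medians <- function(long) {
  need <- c("otu_id", "location", "copies")
  if (!all(need %in% names(long))) {
    stop("`long` must contain columns: ", paste(need, collapse = ", "))
  }
  if (nrow(long) == 0L) stop("no samples: cannot compute location medians")
  levs <- sort(unique(long$location))
  long |>
    dplyr::mutate(location = factor(.data$location, levels = levs)) |>
    dplyr::group_by(.data$otu_id, .data$location) |>
    dplyr::summarise(median_copies = stats::median(.data$copies),
                     .groups = "drop")
}

#' Flag dominant OTUs (> 5\% median relative abundance per location)
#'
#' Relative abundance is each OTU's median copies divided by the summed
#' median copies at that location; the dominance comparison is strict
#' (an OTU at exactly the threshold is not dominant). An all-zero location
#' yields relative abundance 0 and no dominant flags.
#'
#' @param medians Output of [location_medians()].
#' @param threshold Dominance threshold on relative abundance (default 0.05).
#' @return `medians` plus `relative_abundance` and logical `dominant`.
#' @export
classify_dominant <- function(medians, threshold = 0.05) {
  if (threshold <= 0) stop("`threshold` must be > 0")
  medians |>
    dplyr::group_by(.data$location) |>
    dplyr::mutate(
      relative_abundance = if (sum(.data$median_copies) > 0) {
        .data$median_copies / sum(.data$median_copies)
      } else {
        rep(0, dplyr::n())
      },
      dominant = .data$relative_abundance > threshold
    ) |>
    dplyr::ungroup()
}

#' Fold changes between consecutive locations
#'
#' For each OTU and each consecutive location pair, the ratio of downstream
#' to upstream median copies after adding a shared pseudo-floor (so zero
#' medians give finite ratios), its binary logarithm, and a significance
#' flag: strictly more than `fold_threshold`-fold up or down.
#'
#' @param medians Output of [location_medians()].
#' @param pseudo Pseudo-floor added to both medians; in the pipeline this is
#'   half the smallest positive replicate LOD.
#' @param fold_threshold Significance threshold (default 2).
#' @return Tibble `otu_id`, `pair`, `upstream`, `downstream`, `ratio`,
#'   `log2_ratio`, `significant`.
#' @export
consecutive_fold_changes <- function(medians, pseudo = 0, fold_threshold = 2) {
  if (pseudo < 0) stop("`pseudo` must be >= 0")
  if (fold_threshold <= 1) stop("`fold_threshold` must be > 1")
  levs <- levels(factor(medians$location))
  if (length(levs) < 2L) stop("need at least two locations")
  wide <- tapply(medians$median_copies,
                 list(medians$otu_id, factor(medians$location, levels = levs)),
                 mean)
  wide[is.na(wide)] <- 0
  out <- list()
  for (i in seq_len(length(levs) - 1L)) {
    up <- wide[, i]
    down <- wide[, i + 1L]
    ratio <- (down + pseudo) / (up + pseudo)
    out[[i]] <- tibble::tibble(
      otu_id = rownames(wide),
      pair = paste0(levs[i], "->", levs[i + 1L]),
      upstream = unname(up), downstream = unname(down),
      ratio = unname(ratio), log2_ratio = unname(log2(ratio)),
      significant = unname(ratio > fold_threshold | ratio < 1 / fold_threshold)
    )
  }
  dplyr::bind_rows(out)
}

#' Spearman rank correlation with exact small-sample p-values
#'
#' Computes the Spearman coefficient as the Pearson correlation of
#' mid-ranks. The two-sided p-value is exact — enumeration of all `n!`
#' permutations of one margin — for `n <= exact_n` (default 9), and uses
#' the t approximation `t = rs * sqrt((n-2)/(1-rs^2))` with `n - 2` degrees
#' of freedom otherwise. A zero-variance margin leaves the coefficient
#' undefined (`NA`), never 0.
#'
#' @param x,y Numeric vectors of equal length (>= 3), no missing values.
#' @param exact_n Largest n for which the permutation-exact p is used.
#' @return List `rs`, `p`, `n`, `method` ("exact", "t-approximation", or
#'   "undefined").
#' @export
spearman_trend <- function(x, y, exact_n = 9L) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    return(list(rs = NA_real_, p = NA_real_, n = n, method = "undefined"))
  }
  rx <- midrank(x)
  ry <- midrank(y)
  cx <- rx - mean(rx)
  cy <- ry - mean(ry)
  denom <- sqrt(sum(cx^2) * sum(cy^2))
  rs <- sum(cx * cy) / denom
  if (n <= exact_n) {
    pm <- permutations(n)
    perm_cy <- matrix(cy[pm], nrow(pm))
    rs_all <- as.vector(perm_cy %*% cx) / denom
    p <- mean(abs(rs_all) >= abs(rs) - 1e-12)
    method <- "exact"
  } else {
    if (1 - rs^2 <= .Machine$double.eps) {
      p <- 0
    } else {
      tval <- rs * sqrt((n - 2) / (1 - rs^2))
      p <- 2 * stats::pt(-abs(tval), df = n - 2)
    }
    p <- min(1, p)
    method <- "t-approximation"
  }
  list(rs = rs, p = p, n = n, method = method)
}

#' Per-OTU abundance trends along the system
#'
#' Spearman correlation between each OTU's copies and the ordinal location
#' rank. By default all samples are pooled across months (location as the
#' rank variable, n = locations x months), which is the higher-power
#' configuration; `per_month = TRUE` computes one correlation per month
#' across locations instead.
#'
#' @param long Long profile tibble (`otu_id`, `location`, `month`, `copies`).
#' @param per_month Compute trends within each month separately?
#' @param exact_n Passed to [spearman_trend()].
#' @return Tibble `otu_id` (and `month` if per-month), `rs`, `p`, `n`.
#' @export
otu_trends <- function(long, per_month = FALSE, exact_n = 9L) {
  levs <- sort(unique(long$location))
  long <- dplyr::mutate(long, .loc_rank = match(.data$location, levs))
  one <- function(d) {
    st <- spearman_trend(d$copies, d$.loc_rank, exact_n = exact_n)
    tibble::tibble(rs = st$rs, p = st$p, n = st$n)
  }
  if (per_month) {
    long |>
      dplyr::group_by(.data$otu_id, .data$month) |>
      dplyr::group_modify(~ one(.x)) |>
      dplyr::ungroup()
  } else {
    long |>
      dplyr::group_by(.data$otu_id) |>
      dplyr::group_modify(~ one(.x)) |>
      dplyr::ungroup()
  }
}

#' Detect month-specific community-wide abundance anomalies
#'
#' For every month and consecutive location pair, counts the OTUs whose
#' within-month fold change (with pseudo-floor) reaches `fold_threshold`,
#' relative to the OTUs detected (nonzero) at either location of the pair in
#' that month. A (month, pair) is flagged anomalous when this fraction
#' reaches `fraction_threshold` while the pair's cross-month median fold is
#' below 1 — i.e. a direction reversal: a step of the system where biomass
#' typically drops suddenly carries widespread increases.
#'
#' @param long Long profile tibble (`otu_id`, `location`, `month`, `copies`).
#' @param fold_threshold Per-OTU fold counted as an increase (default 2;
#'   the comparison is `>=`).
#' @param fraction_threshold Fraction of detected OTUs that must increase
#'   (default 0.30; the comparison is `>=`).
#' @param pseudo Pseudo-floor for the fold ratios.
#' @return List: `table` (all month x pair statistics: `month`, `pair`,
#'   `n_increased`, `n_detected`, `fraction`, `cross_month_median_fold`,
#'   `anomaly`) and `anomalies` (flagged rows only).
#' @export
detect_anomalies <- function(long, fold_threshold = 2, fraction_threshold = 0.30,
                             pseudo = 0) {
  levs <- sort(unique(long$location))
  months <- sort(unique(long$month))
  if (length(levs) < 2L) stop("need at least two locations")
  rows <- list()
  per_month_median <- list()
  for (i in seq_len(length(levs) - 1L)) {
    pair <- paste0(levs[i], "->", levs[i + 1L])
    med_by_month <- numeric(0)
    for (m in months) {
      up <- long[long$location == levs[i] & long$month == m, ]
      down <- long[long$location == levs[i + 1L] & long$month == m, ]
      otus <- union(up$otu_id, down$otu_id)
      u <- stats::setNames(rep(0, length(otus)), otus)
      d <- u
      u[up$otu_id] <- up$copies
      d[down$otu_id] <- down$copies
      det <- u > 0 | d > 0
      fold <- (d + pseudo) / (u + pseudo)
      n_det <- sum(det)
      n_inc <- sum(det & fold >= fold_threshold)
      med <- if (n_det > 0) stats::median(fold[det]) else NA_real_
      med_by_month <- c(med_by_month, med)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        month = m, pair = pair, n_increased = n_inc, n_detected = n_det,
        fraction = if (n_det > 0) n_inc / n_det else 0,
        per_month_median_fold = med
      )
    }
    per_month_median[[pair]] <- stats::median(med_by_month, na.rm = TRUE)
  }
  tab <- dplyr::bind_rows(rows)
  tab$cross_month_median_fold <- unlist(per_month_median)[tab$pair]
  tab$anomaly <- tab$fraction >= fraction_threshold &
    !is.na(tab$cross_month_median_fold) & tab$cross_month_median_fold < 1
  list(table = tab, anomalies = tab[tab$anomaly, , drop = FALSE])
}

#' Long-format table of copies for heatmap display
#'
#' @param long Long profile tibble including `temperature`.
#' @param otu_subset Character vector of OTU ids to keep; all must exist.
#' @return Tibble `month`, `location`, `otu_id`, `copies`, `temperature`.
#' @export
heatmap_table <- function(long, otu_subset) {
  missing <- setdiff(otu_subset, unique(long$otu_id))
  if (length(missing) > 0L) {
    stop("unknown OTU id(s): ", paste(missing, collapse = ", "))
  }
  long |>
    dplyr::filter(.data$otu_id %in% otu_subset) |>
    dplyr::select("month", "location", "otu_id", "copies",
                  dplyr::any_of("temperature")) |>
    dplyr::arrange(.data$month, .data$location, .data$otu_id)
}
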