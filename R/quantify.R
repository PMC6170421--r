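#' Calibration settings for absolute quantification
#'
#' @param ic_copies 16S rRNA gene copies of internal-calibrator DNA spiked
#'   into each reaction. Copy units are gene copies, not genome equivalents:
#'   accounting for the calibrator organism's rRNA operon multiplicity is
#'   the responsibility of whoever quantifies the spike.
#' @param volume_scale Unitless factor converting per-reaction copies to
#'   copies per 100 uL of source water (from filtered volume, elution
#'   volume, and template fraction). Defaults to 1, i.e. per-reaction
#'   copies are reported on the /100 uL scale directly.
#' @param decontam_z z-threshold of the counting-noise censor applied during
#'   NEC subtraction (see [decontaminate()]); 0 disables censoring.
#' @param consensus Apply the replicate consensus rule (an OTU must be
#'   nonzero in >= 2 valid replicates to be retained)?
#' @param merge Replicate merging statistic, `"mean"` (default; preserves
#'   totals) or `"median"`.
#' @return A `calibration_config` list.
#' @export
calibration_config <- function(ic_copies = 1e4, volume_scale = 1,
                               decontam_z = 3, consensus = TRUE,
                               merge = c("mean", "median")) {
  if (ic_copies <= 0) stop("`ic_copies` must be > 0")
  if (volume_scale <= 0) stop("`volume_scale` must be > 0")
  if (decontam_z < 0) stop("`decontam_z` must be >= 0")
  structure(
    list(ic_copies = ic_copies, volume_scale = volume_scale,
         decontam_z = decontam_z, consensus = isTRUE(consensus),
         merge = match.arg(merge)),
    class = "calibration_config"
  )
}

#' Convert one replicate's read counts to absolute copies
#'
#' Each non-calibrator OTU's copies/100 uL are estimated as
#' `reads_otu / reads_IC * ic_copies * volume_scale`; the replicate's limit
#' of detection is the copies equivalent of a single read,
#' `ic_copies * volume_scale / reads_IC`. A replicate whose calibrator
#' received zero reads is flagged invalid — quantification is undefined
#' there and is never imputed.
#'
#' @param counts Named non-negative numeric vector of reads for one
#'   replicate, including the calibrator row.
#' @param config A [calibration_config()].
#' @param ic_otu_id Name of the calibrator row (default `"IC"`).
#' @return List with `valid` (logical), `copies` (named per-OTU copies/100
#'   uL, calibrator excluded; `NULL` if invalid), and `lod`.
#' @export
calibrate_replicate <- function(counts, config, ic_otu_id = "IC") {
  stopifnot(inherits(config, "calibration_config"))
  if (is.null(names(counts))) stop("`counts` must be a named vector")
  if (!ic_otu_id %in% names(counts)) {
    stop("calibrator row '", ic_otu_id, "' missing from counts")
  }
  if (any(counts < 0)) stop("read counts must be >= 0")
  ic_reads <- counts[[ic_otu_id]]
  if (ic_reads == 0) {
    return(list(valid = FALSE, copies = NULL, lod = NA_real_))
  }
  scale <- config$ic_copies * config$volume_scale / ic_reads
  copies <- counts[setdiff(names(counts), ic_otu_id)] * scale
  list(valid = TRUE, copies = copies, lod = scale)
}

#' Mean contamination profile from negative extraction controls
#'
#' Calibrates every valid NEC replicate and averages the resulting copy
#' vectors per OTU; OTUs absent from all NECs get contamination 0.
#'
#' @param nec_tables An `otu_count_table` or list of them (NEC samples).
#' @param config A [calibration_config()].
#' @param ic_otu_id Calibrator row name.
#' @return Named per-OTU mean contamination copies/100 uL.
#' @export
nec_profile <- function(nec_tables, config, ic_otu_id = "IC") {
  if (inherits(nec_tables, "otu_count_table")) nec_tables <- list(nec_tables)
  if (length(nec_tables) == 0L) stop("at least one NEC table is required")
  reps <- list()
  for (tbl in nec_tables) {
    for (j in seq_len(ncol(tbl$counts))) {
      cal <- calibrate_replicate(tbl$counts[, j], config,
                                 ic_otu_id = tbl$ic_otu_id)
      if (cal$valid) reps[[length(reps) + 1L]] <- cal$copies
    }
  }
  if (length(reps) == 0L) {
    stop("all NEC replicates are invalid (no calibrator reads); ",
         "contamination cannot be estimated")
  }
  otus <- unique(unlist(lapply(reps, names)))
  mat <- vapply(reps, function(v) {
    out <- stats::setNames(rep(0, length(otus)), otus)
    out[names(v)] <- v
    out
  }, numeric(length(otus)))
  rowMeans(matrix(mat, nrow = length(otus), dimnames = list(otus, NULL)))
}

#' Subtract NEC contamination from a calibrated copy vector
#'
#' The core rule is `max(0, sample - contamination)` per OTU. When a
#' replicate limit of detection is supplied, entries whose NEC
#' contamination is positive are additionally censored to exactly 0 unless
#' the post-subtraction excess clears a one-sided counting-noise threshold
#' `z * sqrt(contamination * lod + lod^2)` — the Poisson standard error of a
#' signal at the contamination level, expressed in copies. Without this
#' detection test, an OTU present only in the reagents retains a positive
#' residual in roughly half of all samples purely through counting noise.
#' OTUs with zero contamination are never censored.
#'
#' @param sample_copies Named per-OTU copies/100 uL of one replicate.
#' @param contamination Named per-OTU contamination copies/100 uL (missing
#'   OTUs are treated as 0).
#' @param lod The replicate's limit of detection in copies/100 uL; the
#'   default 0 disables censoring and gives the plain clipped subtraction.
#' @param z Censoring threshold in standard errors.
#' @return Named per-OTU decontaminated copies/100 uL.
#' @export
decontaminate <- function(sample_copies, contamination, lod = 0, z = 3) {
  cont <- stats::setNames(rep(0, length(sample_copies)), names(sample_copies))
  shared <- intersect(names(sample_copies), names(contamination))
  cont[shared] <- contamination[shared]
  excess <- sample_copies - cont
  out <- excess
  out[out < 0] <- 0
  if (lod > 0 && z > 0) {
    thr <- z * sqrt(cont * lod + lod^2)
    censor <- cont > 0 & excess <= thr
    out[censor] <- 0
  }
  out
}

#' Merge decontaminated replicates into one absolute profile
#'
#' Averages per-OTU copies over valid replicates (mean by default, median
#' optionally) and applies the triplicate consensus rule: an OTU is reset
#' to 0 unless it is nonzero in at least 2 valid replicates. The profile's
#' limit of detection is the largest replicate LOD.
#'
#' @param replicates List (length >= 2) of named per-OTU copy vectors, one
#'   per valid replicate.
#' @param lods Numeric vector of the replicates' LODs.
#' @param sample_id Identifier carried into the profile.
#' @param consensus Apply the >= 2-replicate detection rule?
#' @param merge `"mean"` or `"median"`.
#' @return An `absolute_profile`: `sample_id`, `copies` (named),
#'   `n_replicates_detected` (named integer), `lod`, `n_valid_replicates`.
#' @export
merge_replicates <- function(replicates, lods = NULL, sample_id = NA_character_,
                             consensus = TRUE, merge = c("mean", "median")) {
  merge <- match.arg(merge)
  if (length(replicates) < 2L) {
    stop("sample unquantifiable: fewer than 2 valid replicates")
  }
  otus <- unique(unlist(lapply(replicates, names)))
  mat <- vapply(replicates, function(v) {
    out <- stats::setNames(rep(0, length(otus)), otus)
    out[names(v)] <- v
    out
  }, numeric(length(otus)))
  mat <- matrix(mat, nrow = length(otus), dimnames = list(otus, NULL))
  detected <- as.integer(rowSums(mat > 0))
  names(detected) <- otus
  copies <- if (merge == "mean") rowMeans(mat) else apply(mat, 1, stats::median)
  if (isTRUE(consensus)) copies[detected < 2L] <- 0
  lod <- if (is.null(lods) || all(is.na(lods))) NA_real_ else max(lods, na.rm = TRUE)
  structure(
    list(sample_id = sample_id, copies = copies,
         n_replicates_detected = detected, lod = lod,
         n_valid_replicates = length(replicates)),
    class = "absolute_profile"
  )
}

#' Quantify one sample: calibrate, decontaminate, merge
#'
#' @param table An `otu_count_table` (see [otu_count_table()]).
#' @param contamination Named per-OTU contamination copies/100 uL from
#'   [nec_profile()], or `NULL` to skip subtraction.
#' @param config A [calibration_config()].
#' @return An `absolute_profile`.
#' @export
quantify_sample <- function(table, contamination = NULL, config = calibration_config()) {
  stopifnot(inherits(table, "otu_count_table"))
  reps <- list()
  lods <- numeric(0)
  for (j in seq_len(ncol(table$counts))) {
    cal <- calibrate_replicate(table$counts[, j], config,
                               ic_otu_id = table$ic_otu_id)
    if (!cal$valid) next
    copies <- cal$copies
    if (!is.null(contamination)) {
      copies <- decontaminate(copies, contamination, lod = cal$lod,
                              z = config$decontam_z)
    }
    reps[[length(reps) + 1L]] <- copies
    lods <- c(lods, cal$lod)
  }
  if (length(reps) < 2L) {
    stop("sample '", table$sample_id,
         "' unquantifiable: fewer than 2 replicates with calibrator reads")
  }
  merge_replicates(reps, lods = lods, sample_id = table$sample_id,
                   consensus = config$consensus, merge = config$merge)
}

#' Quantify a whole monitoring dataset
#'
#' Estimates a contamination profile from each month's NEC (one NEC set per
#' extraction batch, batch = month) and applies it to that month's samples.
#'
#' @param reads A `sim_reads` bundle or any list with `samples` (named list
#'   of `otu_count_table`), `necs` (list keyed by month), and `metadata`.
#' @param config A [calibration_config()].
#' @return A `quant_result`: `profiles` (named list of `absolute_profile`),
#'   `long` (tibble: sample_id, location, month, temperature, otu_id,
#'   copies, n_replicates_detected), `contamination` (per-month named
#'   vectors), `metadata`.
#' @export
quantify_dataset <- function(reads, config = calibration_config()) {
  meta <- reads$metadata
  smeta <- meta[meta$type == "sample", , drop = FALSE]
  months <- unique(smeta$month)
  contamination <- list()
  for (m in months) {
    nec <- reads$necs[[as.character(m)]]
    if (is.null(nec)) {
      stop("no negative extraction control for month ", m,
           ": contamination cannot be subtracted; supply an NEC for every ",
           "extraction batch or quantify samples individually with ",
           "`quantify_sample(..., contamination = NULL)`")
    }
    contamination[[as.character(m)]] <- nec_profile(nec, config)
  }
  profiles <- list()
  rows <- list()
  for (i in seq_len(nrow(smeta))) {
    sid <- smeta$sample_id[i]
    m <- as.character(smeta$month[i])
    prof <- quantify_sample(reads$samples[[sid]], contamination[[m]], config)
    profiles[[sid]] <- prof
    rows[[i]] <- tibble::tibble(
      sample_id = sid, location = smeta$location[i], month = smeta$month[i],
      temperature = smeta$temperature[i],
      otu_id = names(prof$copies), copies = unname(prof$copies),
      n_replicates_detected = unname(prof$n_replicates_detected)
    )
  }
  structure(
    list(profiles = profiles, long = dplyr::bind_rows(rows),
         contamination = contamination, metadata = meta),
    class = "quant_result"
  )
}

#' Total 16S rRNA gene copies of a profile (calibrator excluded)
#' @param profile An `absolute_profile`.
#' @return Copies/100 uL.
#' @export
total_biomass <- function(profile) {
  stopifnot(inherits(profile, "absolute_profile"))
  sum(profile$copies)
}

#' Observed richness: OTUs with nonzero copies after decontamination
#' @param profile An `absolute_profile`.
#' @return Integer count.
#' @export
observed_richness <- function(profile) {
  stopifnot(inherits(profile, "absolute_profile"))
  sum(profile$copies > 0)
}
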