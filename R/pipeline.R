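#' Run the full monitoring analysis on a synthetic campaign
#'
#' Orchestrates every stage: simulate ground truth, reads, and companion
#' biomass series; quantify all samples (calibration, NEC subtraction,
#' replicate merging); analyse spatial/temporal dynamics (location medians,
#' dominance, consecutive fold changes, per-OTU trends, anomaly scan); and
#' compare total-biomass series across methods. Fully deterministic given
#' the configuration seed.
#'
#' @param config A [sim_config()]; its `ic_copies` seeds the calibration
#'   config unless one is supplied.
#' @param cal A [calibration_config()] or `NULL` to derive from `config`.
#' @param dominance_threshold Relative-abundance threshold for dominance.
#' @param fold_threshold Fold-change significance threshold.
#' @param anomaly_fraction_threshold Fraction of detected OTUs that must
#'   increase for an anomaly flag.
#' @param per_month_trends Compute Spearman trends per month instead of
#'   pooled across months?
#' @param cell_fold_offset,qpcr_fold_offset,companion_noise_cv Passed to
#'   [simulate_companion_series()].
#' @return A `micmon_run` list: `truth`, `reads`, `series`, `quant`,
#'   `totals` (named per-sample pipeline totals), `medians`, `dominance`,
#'   `fold_changes`, `trends`, `anomalies`, `concordance`, `pseudo_floor`,
#'   `params`.
#' @export
run_pipeline <- function(config = sim_config(), cal = NULL,
                         dominance_threshold = 0.05, fold_threshold = 2,
                         anomaly_fraction_threshold = 0.30,
                         per_month_trends = FALSE,
                         cell_fold_offset = 4.9, qpcr_fold_offset = 1.3,
                         companion_noise_cv = 0.3) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(cal)) cal <- calibration_config(ic_copies = config$ic_copies)

  truth <- simulate_truth(config)
  reads <- simulate_reads(truth, config)
  series <- simulate_companion_series(
    truth, cell_fold_offset = cell_fold_offset,
    qpcr_fold_offset = qpcr_fold_offset, noise_cv = companion_noise_cv
  )

  quant <- quantify_dataset(reads, cal)

  lods <- vapply(quant$profiles, function(p) p$lod, numeric(1))
  lods <- lods[is.finite(lods) & lods > 0]
  pseudo <- if (length(lods) > 0) min(lods) / 2 else 0

  medians <- location_medians(quant$long)
  dominance <- classify_dominant(medians, threshold = dominance_threshold)
  fold_changes <- consecutive_fold_changes(medians, pseudo = pseudo,
                                           fold_threshold = fold_threshold)
  trends <- otu_trends(quant$long, per_month = per_month_trends)
  anomalies <- detect_anomalies(
    quant$long, fold_threshold = fold_threshold,
    fraction_threshold = anomaly_fraction_threshold, pseudo = pseudo
  )

  totals <- vapply(quant$profiles, total_biomass, numeric(1))
  fcm <- series[series$method == "fcm_intact", ]
  qpcr <- series[series$method == "qpcr_16s", ]
  concordance <- list(
    fcm = fold_difference(fcm, totals),
    qpcr = fold_difference(qpcr, totals),
    trend_agreement = trend_agreement(
      totals, stats::setNames(fcm$value, fcm$sample_id), quant$metadata
    )
  )

  structure(
    list(truth = truth, reads = reads, series = series, quant = quant,
         totals = totals, medians = medians, dominance = dominance,
         fold_changes = fold_changes, trends = trends, anomalies = anomalies,
         concordance = concordance, pseudo_floor = pseudo,
         params = list(dominance_threshold = dominance_threshold,
                       fold_threshold = fold_threshold,
                       anomaly_fraction_threshold = anomaly_fraction_threshold,
                       per_month_trends = per_month_trends,
                       cal = cal, config = config)),
    class = "micmon_run"
  )
}

#' @export
print.micmon_run <- function(x, ...) {
  cfg <- x$params$config
  cat("micmon pipeline run\n")
  cat("  design: ", cfg$n_locations, " locations x ", cfg$n_months,
      " months x ", cfg$n_replicates, " replicates\n", sep = "")
  cat("  samples quantified: ", length(x$quant$profiles), "\n", sep = "")
  rich <- vapply(x$quant$profiles, observed_richness, numeric(1))
  cat("  median observed richness: ", stats::median(rich), " OTUs/sample\n",
      sep = "")
  dom <- unique(x$dominance$otu_id[x$dominance$dominant])
  cat("  dominant OTUs (>", 100 * x$params$dominance_threshold,
      "% at some location): ", length(dom), "\n", sep = "")
  cat("  anomalies flagged: ", nrow(x$anomalies$anomalies), "\n", sep = "")
  cat("  FCM vs pipeline totals: mean fold ",
      round(x$concordance$fcm$mean_fold, 2), " (SD ",
      round(x$concordance$fcm$sd_fold, 2), ")\n", sep = "")
  cat("  qPCR vs pipeline totals: mean fold ",
      round(x$concordance$qpcr$mean_fold, 2), " (SD ",
      round(x$concordance$qpcr$sd_fold, 2), ")\n", sep = "")
  invisible(x)
}
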