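#' Configuration for a synthetic monitoring campaign
#'
#' Describes a drinking-water distribution system (DWDS) monitoring design:
#' consecutive sampling locations downstream of treatment, monthly sampling,
#' triplicate processing of every sample and of a monthly negative extraction
#' control (NEC), a spiked internal calibrator (IC), and the spatial dynamics
#' the simulator engineers into the community (disinfection kill-off between
#' the first two locations, regrowth towards the third, stability thereafter,
#' and an optional single-month anomaly).
#'
#' @param n_locations Number of consecutive locations, labelled `A`, `B`, ...
#' @param n_months Number of monthly sampling rounds (month 1 = July).
#' @param n_replicates Sequencing replicates per sample (and per NEC).
#' @param n_otus Community OTUs plus the calibrator; `n_otus = 145` means 144
#'   water-community OTUs and one IC row. Contamination-only OTUs are added
#'   on top of this count.
#' @param n_dominant_front,n_dominant_back Number of OTUs engineered to
#'   dominate (>5\% median relative abundance) at the start and at the end of
#'   the system, respectively.
#' @param total_copies_range Log-uniform bounds for the total 16S rRNA gene
#'   copies/100 uL at location A.
#' @param killoff_factor Multiplicative reduction of copies between locations
#'   A and B (disinfection residual), >= 1. Back-dominant OTUs are reduced by
#'   `killoff_factor^0.25` only, so that regrowth can carry them above their
#'   location-A level.
#' @param regrowth_factor Multiplicative increase B to C for back-dominant
#'   OTUs; background OTUs regrow by its square root.
#' @param seasonal_amplitude Relative amplitude of the cosine seasonal
#'   modulation of total biomass (0 = none).
#' @param month_cv Coefficient of variation of the lognormal per-(OTU, month)
#'   abundance effect shared across locations.
#' @param anomaly_month Month index receiving a location-B boost, or `NA` to
#'   disable the anomaly.
#' @param anomaly_fraction Fraction of community OTUs boosted >= 2-fold at
#'   location B in the anomaly month.
#' @param contamination_otus Number of reagent-contamination OTUs present in
#'   every DNA extract (samples and NECs) but absent from the water.
#' @param contamination_level Copies/100 uL contributed by each contamination
#'   OTU to every extract.
#' @param ic_copies 16S rRNA gene copies of calibrator DNA spiked per
#'   reaction.
#' @param read_depth Reads per sequencing replicate.
#' @param seed Integer seed fixing every simulator output.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_locations = 6L, n_months = 5L, n_replicates = 3L,
                       n_otus = 145L, n_dominant_front = 3L,
                       n_dominant_back = 3L,
                       total_copies_range = c(1e5, 1e6),
                       killoff_factor = 10, regrowth_factor = 8,
                       seasonal_amplitude = 0.3, month_cv = 0.3,
                       anomaly_month = 3L, anomaly_fraction = 0.30,
                       contamination_otus = 5L, contamination_level = 200,
                       ic_copies = 1e4, read_depth = 25000L, seed = 1L) {
  cfg <- list(
    n_locations = as.integer(n_locations), n_months = as.integer(n_months),
    n_replicates = as.integer(n_replicates), n_otus = as.integer(n_otus),
    n_dominant_front = as.integer(n_dominant_front),
    n_dominant_back = as.integer(n_dominant_back),
    total_copies_range = as.numeric(total_copies_range),
    killoff_factor = killoff_factor, regrowth_factor = regrowth_factor,
    seasonal_amplitude = seasonal_amplitude, month_cv = month_cv,
    anomaly_month = if (is.na(anomaly_month)) NA_integer_ else as.integer(anomaly_month),
    anomaly_fraction = anomaly_fraction,
    contamination_otus = as.integer(contamination_otus),
    contamination_level = contamination_level,
    ic_copies = ic_copies, read_depth = as.integer(read_depth),
    seed = as.integer(seed)
  )
  counts <- c("n_locations", "n_months", "n_replicates", "n_otus")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L) stop("`", f, "` must be a count >= 1")
  }
  if (cfg$n_dominant_front < 0L || cfg$n_dominant_back < 0L) {
    stop("dominant OTU counts must be >= 0")
  }
  if (cfg$killoff_factor < 1) stop("`killoff_factor` must be >= 1")
  if (cfg$regrowth_factor <= 0) stop("`regrowth_factor` must be > 0")
  if (cfg$seasonal_amplitude < 0 || cfg$seasonal_amplitude >= 1) {
    stop("`seasonal_amplitude` must be in [0, 1)")
  }
  if (cfg$month_cv < 0) stop("`month_cv` must be >= 0")
  if (cfg$anomaly_fraction < 0 || cfg$anomaly_fraction > 1) {
    stop("`anomaly_fraction` must be in [0, 1]")
  }
  if (length(cfg$total_copies_range) != 2L ||
      any(cfg$total_copies_range <= 0) ||
      diff(cfg$total_copies_range) < 0) {
    stop("`total_copies_range` must be increasing positive bounds")
  }
  if (cfg$contamination_otus < 0L) stop("`contamination_otus` must be >= 0")
  if (cfg$contamination_level < 0) stop("`contamination_level` must be >= 0")
  if (cfg$ic_copies < 0) stop("`ic_copies` must be >= 0")
  if (cfg$read_depth < 1L) stop("`read_depth` must be >= 1")
  structure(cfg, class = "sim_config")
}

# calendar month index (1 = July) -> average water temperature in degC,
# a cosine season peaking mid-summer
season_temperature <- function(month) {
  cal <- 7 + (month - 1)
  12 + 8 * cos(2 * pi * (cal - 7.5) / 12)
}

season_modulation <- function(month, amplitude) {
  cal <- 7 + (month - 1)
  1 + amplitude * cos(2 * pi * (cal - 7) / 12)
}

#' Simulate ground-truth absolute abundances for a DWDS campaign
#'
#' Draws per-OTU base abundances at the head of the system (three classes:
#' front-dominant, back-dominant, and a lognormal background), then applies a
#' deterministic spatial profile per class — kill-off A to B, regrowth
#' B to C for the back of the community, stability with gentle class-specific
#' drift from C onwards — modulated by a seasonal factor and a per-(OTU,
#' month) lognormal effect shared across locations. Spatial trends weaken
#' with falling water temperature. An optional anomaly multiplies a chosen
#' fraction of OTUs at location B in one month, including a single extreme
#' (138-fold) OTU.
#'
#' @param config A [sim_config()].
#' @return A `sim_truth` list: `copies` (OTU x location x month array of
#'   copies/100 uL, contamination-only OTUs all zero), `contamination`
#'   (named per-OTU copies/100 uL added to every extract), `temperature`
#'   (location x month matrix, degC), `otu_info` (tibble with OTU class and
#'   base weight), `config`, and `seed`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_comm <- config$n_otus - 1L
  nf <- config$n_dominant_front
  nb <- config$n_dominant_back
  if (nf + nb > n_comm) {
    stop("n_dominant_front + n_dominant_back exceeds the number of community OTUs")
  }
  L <- config$n_locations
  M <- config$n_months
  locs <- LETTERS[seq_len(L)]
  months <- seq_len(M)

  with_seed(config$seed, {
    n_bg <- n_comm - nf - nb
    otu_id <- sprintf("otu_%03d", seq_len(n_comm))
    cls <- rep("background", n_comm)
    if (nf > 0L) cls[seq_len(nf)] <- "front_dominant"
    if (nb > 0L) cls[nf + seq_len(nb)] <- "back_dominant"

    # base composition at location A: engineered dominant shares plus a
    # heavy-tailed background pool (fixed total share, individual cap keeps
    # any background OTU below the 5% dominance threshold at all locations)
    w <- numeric(n_comm)
    if (nf > 0L) w[cls == "front_dominant"] <- 0.23 * 0.55^(seq_len(nf) - 1)
    if (nb > 0L) w[cls == "back_dominant"] <- 0.028 * 0.55^(seq_len(nb) - 1)
    if (n_bg > 0L) {
      bg <- stats::rlnorm(n_bg, meanlog = log(6e-5), sdlog = 3.6)
      # water-filling: background pool keeps a fixed total share while no
      # single background OTU exceeds the per-OTU cap
      bg_total <- 0.14
      bg_cap <- 0.018
      target <- min(bg_total, n_bg * bg_cap)
      bg <- bg / sum(bg) * target
      for (it in 1:50) {
        over <- bg >= bg_cap
        if (!any(over) || all(over)) break
        bg[over] <- bg_cap
        rest <- target - sum(over) * bg_cap
        if (rest <= 0) {
          bg[!over] <- 0
          break
        }
        bg[!over] <- bg[!over] / sum(bg[!over]) * rest
        if (all(bg <= bg_cap + 1e-12)) break
      }
      w[cls == "background"] <- bg
    }
    total_a <- exp(stats::runif(1, log(config$total_copies_range[1]),
                                log(config$total_copies_range[2])))
    base <- w / sum(w) * total_a
    names(base) <- otu_id

    # log spatial profiles per class
    lk <- log(config$killoff_factor)
    lr <- log(config$regrowth_factor)
    prof <- list(
      front_dominant = {
        p <- c(0, rep(-lk, max(L - 1L, 0L)))
        if (L >= 3L) p[3:L] <- p[3:L] - 0.05 * lk * seq_len(L - 2L)
        p
      },
      back_dominant = {
        p <- c(0, rep(-lk / 4, max(L - 1L, 0L)))
        if (L >= 3L) p[3:L] <- p[3:L] + lr + 0.05 * lr * (seq_len(L - 2L) - 1L)
        p
      },
      background = {
        p <- c(0, rep(-lk, max(L - 1L, 0L)))
        if (L >= 3L) p[3:L] <- p[3:L] + lr / 2
        p
      }
    )
    temp <- season_temperature(months)
    weaken <- temp / temp[1]  # trends fade as the water cools
    smod <- season_modulation(months, config$seasonal_amplitude)

    sl <- sqrt(log(1 + config$month_cv^2))
    month_eff <- matrix(
      stats::rlnorm(n_comm * M, meanlog = -sl^2 / 2, sdlog = sl),
      n_comm, M
    )

    copies <- array(0, dim = c(n_comm, L, M),
                    dimnames = list(otu_id, locs, as.character(months)))
    pmat <- do.call(rbind, prof[cls])  # n_comm x L log profiles
    for (m in months) {
      copies[, , m] <- (base * smod[m] * month_eff[, m]) * exp(weaken[m] * pmat)
    }

    # anomaly: one extreme OTU plus the most abundant background OTUs get a
    # location-B boost relative to location A in the anomaly month
    am <- config$anomaly_month
    if (!is.na(am) && am >= 1L && am <= M && L >= 2L &&
        config$anomaly_fraction > 0) {
      n_boost <- round(config$anomaly_fraction * n_comm)
      if (n_boost >= 1L) {
        star <- if (nb > 0L) nf + 1L else integer(0)
        bg_idx <- which(cls == "background")
        bg_idx <- bg_idx[order(w[bg_idx], decreasing = TRUE)]
        pool <- unique(c(star, bg_idx, seq_len(n_comm)))
        boosted <- pool[seq_len(min(n_boost, n_comm))]
        folds <- exp(stats::runif(length(boosted), log(2.2), log(8)))
        if (length(star) == 1L) folds[1L] <- 138
        copies[boosted, 2L, am] <- copies[boosted, 1L, am] * folds
      }
    }

    # contamination-only OTUs: extra rows, zero in water, fixed extract load
    n_ct <- config$contamination_otus
    if (n_ct > 0L) {
      ct_id <- sprintf("contam_%02d", seq_len(n_ct))
      ct_rows <- array(0, dim = c(n_ct, L, M),
                       dimnames = list(ct_id, locs, as.character(months)))
      full <- array(0, dim = c(n_comm + n_ct, L, M),
                    dimnames = list(c(otu_id, ct_id), locs, as.character(months)))
      full[otu_id, , ] <- copies
      copies <- full
      contamination <- stats::setNames(
        c(rep(0, n_comm), rep(config$contamination_level, n_ct)),
        c(otu_id, ct_id)
      )
      otu_info <- tibble::tibble(
        otu_id = c(otu_id, ct_id),
        class = c(cls, rep("contaminant", n_ct)),
        base_weight = c(w / sum(w), rep(0, n_ct))
      )
    } else {
      contamination <- stats::setNames(rep(0, n_comm), otu_id)
      otu_info <- tibble::tibble(otu_id = otu_id, class = cls,
                                 base_weight = w / sum(w))
    }

    temperature <- matrix(rep(temp, each = L), L, M,
                          dimnames = list(locs, as.character(months)))

    structure(
      list(copies = copies, contamination = contamination,
           temperature = temperature, otu_info = otu_info,
           config = config, seed = config$seed),
      class = "sim_truth"
    )
  })
}

#' Simulate sequencing read counts for every sample and NEC
#'
#' For each replicate, reads are drawn multinomially over the template
#' molecules present in the reaction: each OTU's water copies plus the
#' shared reagent contamination, plus the spiked calibrator (`ic_copies`).
#' NEC replicates contain only contamination and calibrator templates.
#' Template-level multinomial sampling mirrors clonal (micelle) PCR, whose
#' premise is the absence of amplification competition, so no
#' per-OTU efficiency bias term is included.
#'
#' @param truth A [simulate_truth()] result consistent with `config`.
#' @param config The same [sim_config()].
#' @return A `sim_reads` list: `samples` (named list of `otu_count_table`),
#'   `necs` (list of `otu_count_table`, one per month), `metadata` (tibble:
#'   sample_id, location, month, type, temperature), `config`.
#' @export
simulate_reads <- function(truth, config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  if (config$ic_copies <= 0) {
    stop("`ic_copies` must be > 0: without a spiked calibrator, ",
         "absolute quantification is impossible")
  }
  dm <- dim(truth$copies)
  if (dm[2] != config$n_locations || dm[3] != config$n_months) {
    stop("`truth` is inconsistent with `config` (locations/months mismatch)")
  }
  locs <- colnames(truth$copies)
  months <- seq_len(config$n_months)
  otus <- rownames(truth$copies)

  with_seed(config$seed + 1L, {
    samples <- list()
    necs <- list()
    meta <- list()
    for (m in months) {
      for (l in locs) {
        sid <- paste0(l, "_m", m)
        tmpl <- c(truth$copies[, l, m] + truth$contamination,
                  IC = config$ic_copies)
        counts <- stats::rmultinom(config$n_replicates, config$read_depth, tmpl)
        rownames(counts) <- c(otus, "IC")
        colnames(counts) <- paste0("replicate_", seq_len(config$n_replicates))
        samples[[sid]] <- otu_count_table(
          sample_id = sid, counts = counts, ic_otu_id = "IC",
          sample_type = "sample", location = l, month = m
        )
        meta[[length(meta) + 1L]] <- tibble::tibble(
          sample_id = sid, location = l, month = m, type = "sample",
          temperature = truth$temperature[l, as.character(m)]
        )
      }
      nid <- paste0("NEC_m", m)
      tmpl <- c(truth$contamination, IC = config$ic_copies)
      counts <- stats::rmultinom(config$n_replicates, config$read_depth, tmpl)
      rownames(counts) <- c(otus, "IC")
      colnames(counts) <- paste0("replicate_", seq_len(config$n_replicates))
      necs[[as.character(m)]] <- otu_count_table(
        sample_id = nid, counts = counts, ic_otu_id = "IC",
        sample_type = "NEC", location = NA_character_, month = m
      )
      meta[[length(meta) + 1L]] <- tibble::tibble(
        sample_id = nid, location = NA_character_, month = m, type = "NEC",
        temperature = NA_real_
      )
    }
    structure(
      list(samples = samples, necs = necs,
           metadata = dplyr::bind_rows(meta), config = config),
      class = "sim_reads"
    )
  })
}

#' Simulate companion biomass series (flow cytometry and qPCR)
#'
#' Produces per-sample totals for external measurement methods as the true
#' total 16S copies (calibrator excluded) times a method-specific
#' multiplicative offset and lognormal noise with unit mean: flow-cytometry
#' intact cell counts sit a few-fold above the 16S copy totals, while qPCR
#' measures the same quantity up to a small offset.
#'
#' @param truth A [simulate_truth()] result.
#' @param cell_fold_offset Multiplicative offset of the FCM series (> 0).
#' @param qpcr_fold_offset Multiplicative offset of the qPCR series (> 0).
#' @param noise_cv Lognormal coefficient of variation (>= 0).
#' @param seed RNG seed; defaults to `truth$seed + 2`.
#' @return A tibble (`sample_id`, `method`, `value`) with methods
#'   `true_16s` (noiseless truth totals), `fcm_intact`, and `qpcr_16s`.
#' @export
simulate_companion_series <- function(truth, cell_fold_offset = 4.9,
                                      qpcr_fold_offset = 1.3,
                                      noise_cv = 0.3, seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  if (cell_fold_offset <= 0 || qpcr_fold_offset <= 0) stop("offsets must be > 0")
  if (noise_cv < 0) stop("`noise_cv` must be >= 0")
  if (is.null(seed)) seed <- truth$seed + 2L
  locs <- colnames(truth$copies)
  months <- dimnames(truth$copies)[[3]]
  totals <- apply(truth$copies, c(2, 3), sum)  # calibrator never in truth
  n <- length(totals)
  sl <- sqrt(log(1 + noise_cv^2))
  with_seed(seed, {
    noise_f <- stats::rlnorm(n, -sl^2 / 2, sl)
    noise_q <- stats::rlnorm(n, -sl^2 / 2, sl)
    sid <- as.vector(outer(locs, months, function(l, m) paste0(l, "_m", m)))
    v <- as.vector(totals)
    dplyr::bind_rows(
      tibble::tibble(sample_id = sid, method = "true_16s", value = v),
      tibble::tibble(sample_id = sid, method = "fcm_intact",
                     value = v * cell_fold_offset * noise_f),
      tibble::tibble(sample_id = sid, method = "qpcr_16s",
                     value = v * qpcr_fold_offset * noise_q)
    )
  })
}

#' One-call synthetic dataset (truth + reads + companion series)
#'
#' @param config A [sim_config()].
#' @param ... Passed on to [simulate_companion_series()].
#' @return List with elements `truth`, `reads`, `series`.
#' @export
simulate_dataset <- function(config = sim_config(), ...) {
  truth <- simulate_truth(config)
  reads <- simulate_reads(truth, config)
  series <- simulate_companion_series(truth, ...)
  list(truth = truth, reads = reads, series = series)
}
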