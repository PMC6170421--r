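# Independent oracles, deliberately written with plain loops and base R so
# they share no code path with the package implementation.

# Spearman via base rank() + cor(), the rank-then-Pearson route.
oracle_spearman_rs <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

# Brute-force calibrate -> subtract mean NEC -> consensus -> mean, one value
# at a time. `counts` and each element of `nec_counts` are OTU x replicate
# matrices that include the "IC" row. Plain clipped subtraction (no censor).
oracle_quantify <- function(counts, nec_counts, ic_copies, volume_scale = 1,
                            consensus = TRUE) {
  otus <- setdiff(rownames(counts), "IC")
  nec_cal <- list()
  for (nc in nec_counts) {
    for (j in seq_len(ncol(nc))) {
      ic <- nc["IC", j]
      if (ic == 0) next
      v <- numeric(length(otus))
      names(v) <- otus
      for (o in otus) v[o] <- nc[o, j] / ic * ic_copies * volume_scale
      nec_cal[[length(nec_cal) + 1]] <- v
    }
  }
  cont <- numeric(length(otus))
  names(cont) <- otus
  if (length(nec_cal) > 0) {
    for (o in otus) {
      s <- 0
      for (v in nec_cal) s <- s + v[o]
      cont[o] <- s / length(nec_cal)
    }
  }
  reps <- list()
  for (j in seq_len(ncol(counts))) {
    ic <- counts["IC", j]
    if (ic == 0) next
    v <- numeric(length(otus))
    names(v) <- otus
    for (o in otus) {
      raw <- counts[o, j] / ic * ic_copies * volume_scale
      v[o] <- max(0, raw - cont[o])
    }
    reps[[length(reps) + 1]] <- v
  }
  out <- numeric(length(otus))
  names(out) <- otus
  for (o in otus) {
    vals <- vapply(reps, function(v) v[[o]], numeric(1))
    m <- mean(vals)
    if (consensus && sum(vals > 0) < 2) m <- 0
    out[o] <- m
  }
  out
}

# tiny random count table with an IC row
random_count_table <- function(n_otus = 5, n_reps = 3, depth = 2000,
                               seed = 1) {
  set.seed(seed)
  p <- c(runif(n_otus, 0.01, 1), IC = 1)
  counts <- stats::rmultinom(n_reps, depth, p)
  rownames(counts) <- c(sprintf("otu_%d", seq_len(n_otus)), "IC")
  colnames(counts) <- paste0("replicate_", seq_len(n_reps))
  counts
}
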