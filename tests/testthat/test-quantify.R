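cc_unit <- calibration_config(ic_copies = 1e4, volume_scale = 1)

test_that("calibration arithmetic follows the read ratio to the calibrator", {
  counts <- c(otu_a = 500, otu_b = 0, IC = 1000)
  cal <- calibrate_replicate(counts, cc_unit)
  expect_true(cal$valid)
  expect_equal(unname(cal$copies["otu_a"]), 5000)
  expect_equal(unname(cal$copies["otu_b"]), 0)
  expect_equal(cal$lod, 10)
  # reads equal to the calibrator reads give ic_copies * volume_scale
  cc2 <- calibration_config(ic_copies = 1e4, volume_scale = 2.5)
  cal2 <- calibrate_replicate(c(x = 1000, IC = 1000), cc2)
  expect_equal(unname(cal2$copies["x"]), 1e4 * 2.5)
})

test_that("a replicate without calibrator reads is invalid, never imputed", {
  cal <- calibrate_replicate(c(a = 10, IC = 0), cc_unit)
  expect_false(cal$valid)
  expect_null(cal$copies)
  counts <- matrix(c(5, 0, 3, 0, 4, 0), nrow = 2,
                   dimnames = list(c("a", "IC"), NULL))
  tbl <- otu_count_table("s1", counts, ic_otu_id = "IC")
  expect_error(quantify_sample(tbl, NULL, cc_unit), "unquantifiable")
})

test_that("copy estimates are linear in ic_copies and invariant to depth scaling", {
  counts <- random_count_table(n_otus = 8, seed = 42)[, 1]
  for (c_mult in c(2, 10)) {
    a <- calibrate_replicate(counts, calibration_config(ic_copies = 1e3), "IC")
    b <- calibrate_replicate(counts, calibration_config(ic_copies = 1e3 * c_mult), "IC")
    expect_equal(b$copies, a$copies * c_mult, tolerance = 1e-12)
    expect_equal(b$lod, a$lod * c_mult, tolerance = 1e-12)
  }
  scaled <- calibrate_replicate(counts * 7L, cc_unit)
  base <- calibrate_replicate(counts, cc_unit)
  expect_equal(scaled$copies, base$copies, tolerance = 1e-12)
})

test_that("NEC profile is the mean of calibrated NEC replicates", {
  # three replicates calibrating one OTU to 30, 60, 90 copies
  counts <- rbind(contam_01 = c(3, 6, 9), IC = c(1000, 1000, 1000))
  nec <- otu_count_table("NEC_m1", counts, sample_type = "NEC")
  prof <- nec_profile(nec, cc_unit)
  expect_equal(unname(prof["contam_01"]), 60)
  # all-zero NEC -> zero contamination everywhere
  z <- rbind(a = c(0, 0, 0), IC = c(500, 500, 500))
  zprof <- nec_profile(otu_count_table("NEC_m2", z, sample_type = "NEC"), cc_unit)
  expect_true(all(zprof == 0))
  # every replicate invalid -> error
  bad <- rbind(a = c(1, 1, 1), IC = c(0, 0, 0))
  expect_error(
    nec_profile(otu_count_table("NEC_m3", bad, sample_type = "NEC"), cc_unit),
    "invalid"
  )
})

test_that("decontamination is clipped subtraction with optional censoring", {
  expect_equal(unname(decontaminate(c(a = 100), c(a = 30))), 70)
  expect_equal(unname(decontaminate(c(a = 20), c(a = 30))), 0)
  # weak idempotence property: 0 wherever contamination >= sample,
  # sample - contamination elsewhere (no censor)
  set.seed(1)
  for (i in 1:20) {
    s <- setNames(runif(10, 0, 100), letters[1:10])
    ct <- setNames(runif(10, 0, 100), letters[1:10])
    out <- decontaminate(s, ct)
    expect_equal(out, ifelse(ct >= s, 0, s - ct), tolerance = 1e-12,
                 ignore_attr = FALSE)
  }
  # censoring: residual within counting noise of the contamination level is
  # forced to exactly zero; strong genuine signal survives
  lod <- 10
  out <- decontaminate(c(weak = 220, strong = 5000), c(weak = 200, strong = 200),
                       lod = lod, z = 3)
  expect_identical(unname(out["weak"]), 0)
  expect_equal(unname(out["strong"]), 4800)
  # OTUs without contamination are never censored
  out2 <- decontaminate(c(tiny = 5), c(tiny = 0), lod = lod, z = 3)
  expect_equal(unname(out2["tiny"]), 5)
})

test_that("replicate merging applies the 2-of-3 consensus rule", {
  r1 <- c(a = 100, b = 100)
  r2 <- c(a = 110, b = 0)
  r3 <- c(a = 120, b = 0)
  p <- merge_replicates(list(r1, r2, r3), lods = c(1, 2, 3), sample_id = "s")
  expect_equal(unname(p$copies["a"]), 110)
  expect_identical(unname(p$n_replicates_detected["a"]), 3L)
  expect_equal(unname(p$copies["b"]), 0)  # detected in only 1 replicate
  expect_identical(unname(p$n_replicates_detected["b"]), 1L)
  expect_equal(p$lod, 3)
  # median merging and consensus off
  p2 <- merge_replicates(list(r1, r2, r3), consensus = FALSE, merge = "median")
  expect_equal(unname(p2$copies["a"]), 110)
  expect_equal(unname(p2$copies["b"]), 0)  # median of (100, 0, 0)
  p3 <- merge_replicates(list(r1, r2, r3), consensus = FALSE)
  expect_equal(unname(p3$copies["b"]), 100 / 3)
  expect_error(merge_replicates(list(r1)), "fewer than 2")
})

test_that("pipeline chain matches a brute-force oracle on tiny tables", {
  cc <- calibration_config(ic_copies = 5e3, volume_scale = 2,
                           decontam_z = 0)  # plain subtraction, as the oracle
  for (s in 1:20) {
    counts <- random_count_table(n_otus = 5, seed = s)
    nec1 <- random_count_table(n_otus = 5, depth = 200, seed = s + 1000)
    nec2 <- random_count_table(n_otus = 5, depth = 200, seed = s + 2000)
    tbl <- otu_count_table("s", counts)
    necs <- list(otu_count_table("n1", nec1, sample_type = "NEC"),
                 otu_count_table("n2", nec2, sample_type = "NEC"))
    cont <- nec_profile(necs, cc)
    got <- quantify_sample(tbl, cont, cc)
    want <- oracle_quantify(counts, list(nec1, nec2), ic_copies = 5e3,
                            volume_scale = 2)
    expect_equal(got$copies[names(want)], want, tolerance = 1e-12)
  }
})

test_that("consensus filtering reduces contamination false positives", {
  fp_on <- 0
  fp_off <- 0
  for (s in 1:15) {
    cfg <- sim_config(seed = 600 + s, n_months = 1L, n_locations = 2L,
                      n_otus = 30L)
    tr <- simulate_truth(cfg)
    rd <- simulate_reads(tr, cfg)
    ct <- grep("^contam_", rownames(tr$copies), value = TRUE)
    # plain subtraction isolates the effect of the consensus rule
    for (cons in c(TRUE, FALSE)) {
      cc <- calibration_config(ic_copies = cfg$ic_copies, decontam_z = 0,
                               consensus = cons)
      q <- quantify_dataset(rd, cc)
      fp <- sum(vapply(q$profiles, function(p) sum(p$copies[ct] > 0),
                       numeric(1)))
      if (cons) fp_on <- fp_on + fp else fp_off <- fp_off + fp
    }
  }
  expect_lt(fp_on, fp_off)
})

test_that("profile totals and richness summarise decontaminated copies", {
  p <- structure(list(sample_id = "s",
                      copies = c(a = 5000, b = 2500, c = 0),
                      n_replicates_detected = c(a = 3L, b = 3L, c = 0L),
                      lod = 1, n_valid_replicates = 3L),
                 class = "absolute_profile")
  expect_equal(total_biomass(p), 7500)
  expect_identical(observed_richness(p), 2L)
  empty <- structure(list(sample_id = "e", copies = numeric(0),
                          n_replicates_detected = integer(0), lod = 1,
                          n_valid_replicates = 3L),
                     class = "absolute_profile")
  expect_equal(total_biomass(empty), 0)
  expect_identical(observed_richness(empty), 0L)
})

test_that("copy estimates recover simulated truth at high depth", {
  errs <- c()
  for (s in 1:10) {
    cfg <- sim_config(seed = s, read_depth = 1e5, n_months = 1L)
    tr <- simulate_truth(cfg)
    q <- quantify_dataset(simulate_reads(tr, cfg),
                          calibration_config(ic_copies = cfg$ic_copies))
    for (sid in names(q$profiles)) {
      p <- q$profiles[[sid]]
      loc <- sub("_m.*", "", sid)
      tru <- tr$copies[names(p$copies), loc, 1]
      keep <- tru > 10 * p$lod
      errs <- c(errs, (p$copies[keep] - tru[keep]) / tru[keep])
    }
  }
  expect_lt(sqrt(mean(errs^2)), 0.10)
})

test_that("observed richness tracks the detectable ground truth", {
  ratios <- c()
  for (s in 1:20) {
    cfg <- sim_config(seed = 700 + s)
    tr <- simulate_truth(cfg)
    q <- quantify_dataset(simulate_reads(tr, cfg),
                          calibration_config(ic_copies = cfg$ic_copies))
    obs <- median(vapply(q$profiles, observed_richness, numeric(1)))
    # truth-side detectability: read rate at which the 2-of-3 consensus
    # detects an OTU with probability 1/2 (per-replicate rate log 2)
    det <- vapply(names(q$profiles), function(sid) {
      loc <- sub("_m.*", "", sid)
      m <- sub(".*_m", "", sid)
      tmpl <- tr$copies[, loc, m] + tr$contamination
      share <- tmpl / (sum(tmpl) + cfg$ic_copies)
      sum(share * cfg$read_depth >= log(2))
    }, numeric(1))
    ratios <- c(ratios, obs / median(det))
  }
  expect_lt(abs(mean(ratios) - 1), 0.10)
})
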