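make_long <- function(values) {
  # values: named list otu -> location -> vector of monthly copies
  rows <- list()
  for (o in names(values)) {
    for (l in names(values[[o]])) {
      v <- values[[o]][[l]]
      rows[[length(rows) + 1]] <- tibble::tibble(
        sample_id = paste0(l, "_m", seq_along(v)), location = l,
        month = seq_along(v), otu_id = o, copies = v
      )
    }
  }
  dplyr::bind_rows(rows)
}

test_that("location medians are medians across months, robust to outliers", {
  long <- make_long(list(x = list(A = c(10, 20, 1000), B = 7)))
  med <- location_medians(long)
  expect_equal(med$median_copies[med$location == "A"], 20)
  # single month: identity
  expect_equal(med$median_copies[med$location == "B"], 7)
  # brute-force sort-and-pick oracle on random tables
  set.seed(3)
  for (i in 1:10) {
    vals <- lapply(setNames(nm = c("u", "v", "w")), function(o)
      lapply(setNames(nm = c("A", "B")), function(l) runif(5, 0, 100)))
    med <- location_medians(make_long(vals))
    for (o in names(vals)) for (l in c("A", "B")) {
      srt <- sort(vals[[o]][[l]])
      expect_equal(med$median_copies[med$otu_id == o & med$location == l],
                   srt[3])
    }
  }
})

test_that("dominance requires strictly more than the threshold share", {
  med <- tibble::tibble(
    otu_id = c("a", "b", "c", "a", "b", "c"),
    location = rep(c("A", "B"), each = 3),
    median_copies = c(100, 0, 0,  # a is 100% at A
                      5, 95, 0)   # a exactly 5.0% at B: strictly not dominant
  )
  dom <- classify_dominant(med)
  expect_true(dom$dominant[dom$otu_id == "a" & dom$location == "A"])
  expect_false(dom$dominant[dom$otu_id == "a" & dom$location == "B"])
  # all-zero location: no flags
  med0 <- tibble::tibble(otu_id = c("a", "b"), location = "A",
                         median_copies = c(0, 0))
  dom0 <- classify_dominant(med0)
  expect_false(any(dom0$dominant))
  expect_true(all(dom0$relative_abundance == 0))
})

test_that("dominance is monotone in an OTU's own copies", {
  set.seed(8)
  for (i in 1:20) {
    m <- tibble::tibble(otu_id = letters[1:6], location = "A",
                        median_copies = runif(6, 0, 100))
    d1 <- classify_dominant(m)
    m2 <- m
    j <- sample(6, 1)
    m2$median_copies[j] <- m2$median_copies[j] * runif(1, 1, 10)
    d2 <- classify_dominant(m2)
    if (d1$dominant[j]) expect_true(d2$dominant[j])
  }
})

test_that("consecutive fold changes use the 2-fold rule strictly", {
  med <- tibble::tibble(
    otu_id = rep(c("x", "y"), each = 2),
    location = rep(c("A", "B"), 2),
    median_copies = c(200, 100, 100, 300)
  )
  fc <- consecutive_fold_changes(med, pseudo = 0)
  x <- fc[fc$otu_id == "x", ]
  expect_equal(x$ratio, 0.5)
  expect_false(x$significant)  # exactly 2-fold down is not significant
  y <- fc[fc$otu_id == "y", ]
  expect_equal(y$log2_ratio, log2(3), tolerance = 1e-12)
  expect_true(y$significant)
})

test_that("fold-change antisymmetry holds under a shared pseudo-floor", {
  set.seed(5)
  for (i in 1:20) {
    med <- tibble::tibble(
      otu_id = rep(letters[1:8], 2),
      location = rep(c("A", "B"), each = 8),
      median_copies = c(runif(8, 0, 50), sample(c(0, 10, 100), 8, TRUE))
    )
    rev_med <- med
    rev_med$location <- ifelse(med$location == "A", "B", "A")
    # relabelling reverses the pair direction; compare log ratios
    f <- consecutive_fold_changes(med, pseudo = 0.5)
    r <- consecutive_fold_changes(rev_med, pseudo = 0.5)
    f <- f[order(f$otu_id), ]
    r <- r[order(r$otu_id), ]
    expect_equal(f$log2_ratio, -r$log2_ratio, tolerance = 1e-12)
  }
})

test_that("spearman engine matches the rank-then-Pearson oracle", {
  set.seed(17)
  for (i in 1:300) {
    n <- sample(4:15, 1)
    x <- if (i %% 2 == 0) rnorm(n) else sample(5, n, replace = TRUE)  # ties
    y <- if (i %% 3 == 0) sample(4, n, replace = TRUE) else rnorm(n)
    if (length(unique(x)) == 1 || length(unique(y)) == 1) next
    st <- spearman_trend(x, y)
    expect_equal(st$rs, oracle_spearman_rs(x, y), tolerance = 1e-12)
  }
})

test_that("exact permutation p-value for a monotone series of six", {
  st <- spearman_trend(c(3, 9, 27, 81, 243, 729), 1:6)
  expect_equal(st$rs, 1)
  expect_equal(st$p, 2 / 720, tolerance = 1e-15)
  expect_identical(st$method, "exact")
  # monotone decreasing is the mirror image
  st2 <- spearman_trend(c(6, 5, 4, 3, 2, 1), 1:6)
  expect_equal(st2$rs, -1)
  expect_equal(st2$p, 2 / 720, tolerance = 1e-15)
})

test_that("large-sample p uses the t approximation, zero variance is NA", {
  set.seed(2)
  x <- rnorm(30)
  y <- rnorm(30)
  st <- spearman_trend(x, y)
  expect_identical(st$method, "t-approximation")
  rs <- oracle_spearman_rs(x, y)
  tval <- rs * sqrt(28 / (1 - rs^2))
  expect_equal(st$p, 2 * pt(-abs(tval), 28), tolerance = 1e-12)
  flat <- spearman_trend(rep(2, 10), 1:10)
  expect_true(is.na(flat$rs))
  expect_true(is.na(flat$p))
  expect_identical(flat$method, "undefined")
})

test_that("anomaly scan flags only widespread direction-reversing increases", {
  # a community that always halves A -> B: no anomaly
  set.seed(4)
  vals <- lapply(setNames(nm = sprintf("o%02d", 1:20)), function(o) {
    a <- runif(5, 50, 100)
    list(A = a, B = a / 2)
  })
  an <- detect_anomalies(make_long(vals), pseudo = 0.5)
  expect_identical(nrow(an$anomalies), 0L)
  # boosting a single OTU out of 20 in one month stays below the fraction rule
  vals_one <- vals
  vals_one[["o01"]]$B[3] <- vals_one[["o01"]]$A[3] * 10
  an1 <- detect_anomalies(make_long(vals_one), pseudo = 0.5)
  expect_identical(nrow(an1$anomalies), 0L)
  # boosting 8 of 20 OTUs >= 2-fold in month 3 flips the flag for that month
  vals_many <- vals
  for (o in sprintf("o%02d", 1:8)) {
    vals_many[[o]]$B[3] <- vals_many[[o]]$A[3] * 3
  }
  an2 <- detect_anomalies(make_long(vals_many), pseudo = 0.5)
  expect_identical(an2$anomalies$month, 3L)
  expect_identical(an2$anomalies$pair, "A->B")
  expect_gte(an2$anomalies$fraction, 0.30)
})

test_that("heatmap table is a lossless long-format extraction", {
  cfg <- sim_config(seed = 10L, n_otus = 12L)
  q <- quantify_dataset(simulate_reads(simulate_truth(cfg), cfg),
                        calibration_config(ic_copies = cfg$ic_copies))
  otus <- sprintf("otu_%03d", 1:6)
  ht <- heatmap_table(q$long, otus)
  expect_identical(nrow(ht), cfg$n_months * cfg$n_locations * 6L)
  for (i in sample(nrow(ht), 10)) {
    row <- ht[i, ]
    orig <- q$long[q$long$otu_id == row$otu_id &
                     q$long$location == row$location &
                     q$long$month == row$month, ]
    expect_equal(row$copies, orig$copies)
  }
  expect_error(heatmap_table(q$long, c("otu_001", "nope")), "unknown OTU")
})
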