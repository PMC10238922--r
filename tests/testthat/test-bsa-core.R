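test_that("JU1242 frequency rules follow the variant origin", {
  expect_equal(ju1242_frequency(12, 24, "JU1242"), 0.5)
  expect_equal(ju1242_frequency(18, 24, "CB4932"), 0.25)
  expect_equal(ju1242_frequency(0, 15, "JU1242"), 0)
  expect_equal(ju1242_frequency(c(10, 10), c(20, 40), c("JU1242", "CB4932")),
               c(0.5, 0.75))
  expect_error(ju1242_frequency(0, 0, "JU1242"), "positive")
  expect_error(ju1242_frequency(5, 4, "JU1242"), "read_var")
  expect_error(ju1242_frequency(1, 4, "N2"), "origin")
})

test_that("coverage filter is strict in both pools", {
  cnt <- pool_counts(tibble::tibble(
    chrom = "chr1", pos = c(100L, 200L, 300L), origin = "JU1242",
    var1 = c(5L, 6L, 2L), tot1 = c(10L, 11L, 5L),
    var2 = c(20L, 8L, 3L), tot2 = c(30L, 11L, 5L)))
  kept <- filter_by_coverage(cnt, 10)
  expect_identical(kept$pos, 200L)        # TOT=10 removed, TOT=11 retained
  expect_identical(nrow(filter_by_coverage(cnt, 100)), 0L)
  expect_error(bsa_scan(filter_by_coverage(cnt, 100)), "no data")
})

test_that("window smoothing equals the brute-force windowed mean", {
  # single SNP: every covering window reports its value
  one <- tibble::tibble(chrom = "c", pos = 1000L, freq = 0.7)
  sm <- smooth_frequencies(one, window_bp = 200, mode = "unique")
  expect_true(all(sm$freq == 0.7))
  expect_identical(sm$n_snps, 1L)

  # two SNPs sharing a window average
  two <- tibble::tibble(chrom = "c", pos = c(100L, 150L), freq = c(0.4, 0.6))
  sm2 <- smooth_frequencies(two, window_bp = 200, mode = "unique")
  expect_true(0.5 %in% sm2$freq)

  expect_error(smooth_frequencies(two[0, ]), "no data")

  # dense random track vs brute force, both modes
  set.seed(77)
  pos <- sort(sample(1:4000, 60))
  d <- tibble::tibble(chrom = "c", pos = pos, freq = runif(60))
  w <- 150L
  # exhaustive anchors spaced >= window: non-overlapping independent windows
  sme <- smooth_frequencies(d, window_bp = w, step_bp = 200L,
                            mode = "exhaustive")
  for (k in seq_len(nrow(sme))) {
    anchor <- sme$pos[k] - (w - 1L) %/% 2L
    bf <- brute_window_mean(pos, d$freq, anchor, w)
    expect_equal(sme$freq[k], bf$mean)
    expect_equal(sme$n_snps[k], bf$n)
  }
  # unique mode emits exactly the distinct step-1 window contents
  smu <- smooth_frequencies(d, window_bp = w, mode = "unique")
  contents <- list()
  for (anchor in 1:4000) {
    bf <- brute_window_mean(pos, d$freq, anchor, w)
    if (is.null(bf)) next
    key <- paste(bf$idx, collapse = ",")
    if (is.null(contents[[key]])) contents[[key]] <- bf$mean
  }
  expect_identical(nrow(smu), length(contents))
  expect_equal(sort(smu$freq), sort(unname(unlist(contents))))
  for (k in seq_len(nrow(smu))) {
    anchor <- smu$pos[k] - (w - 1L) %/% 2L
    bf <- brute_window_mean(pos, d$freq, anchor, w)
    expect_equal(smu$freq[k], bf$mean)
  }
})

test_that("log-odds ratio is zero at equality, antisymmetric and monotone", {
  for (f in c(0, 0.25, 0.5, 1)) expect_equal(log_odds_ratio(f, f), 0)

  set.seed(12)
  f1 <- runif(100); f2 <- runif(100)
  expect_equal(log_odds_ratio(f1, f2), -log_odds_ratio(f2, f1),
               tolerance = 1e-12)

  # strictly increasing in f1, decreasing in f2
  grid <- seq(0, 1, by = 0.05)
  expect_true(all(diff(log_odds_ratio(grid, 0.5)) > 0))
  expect_true(all(diff(log_odds_ratio(0.5, grid)) < 0))
})

test_that("null thresholds are symmetric, seeded and collapse as alpha grows", {
  p <- bsa_params(n_null_draws = 200000)
  thr <- simulate_threshold(p, seed = 4)
  expect_lt(abs(thr$threshold_low + thr$threshold_high), 0.2)
  expect_gt(thr$threshold_high, 0)

  thr2 <- simulate_threshold(p, seed = 4)
  expect_identical(thr[c("threshold_low", "threshold_high")],
                   thr2[c("threshold_low", "threshold_high")])

  wide <- simulate_threshold(bsa_params(alpha = 0.9, n_null_draws = 200000),
                             seed = 4)
  expect_lt(abs(wide$threshold_high), 0.35) # near the null median of 0
  expect_lt(abs(wide$threshold_low), 0.35)
})

test_that("interval calling finds runs, directions and fixation", {
  track <- tibble::tibble(
    chrom = "chrIV",
    pos = as.integer(seq(1000, 12000, by = 1000)),
    freq_pool1 = c(0.5, 0.5, 0.1, 0.05, 0.02, 0.1, 0.5, 0.5, 0.95, 0.99, 0.5, 0.5),
    freq_pool2 = c(0.5, 0.5, 0.9, 0.99, 0.99, 0.9, 0.5, 0.5, 0.1, 0.05, 0.5, 0.5))
  track$lor <- log_odds_ratio(track$freq_pool2, track$freq_pool1)

  none <- call_qtl_intervals(track, -100, 100)
  expect_identical(nrow(none), 0L)

  iv <- call_qtl_intervals(track, -3, 3, fixation_eps = 0.02)
  expect_identical(nrow(iv), 2L)
  up <- iv[iv$direction == "pool2", ]
  expect_identical(up$start, 3000L)
  expect_identical(up$end, 6000L)
  expect_true(up$fixed)
  expect_identical(up$fixed_start, 4000L) # freq_pool2 >= 0.98 run
  expect_identical(up$fixed_end, 5000L)
  dn <- iv[iv$direction == "pool1", ]
  expect_identical(c(dn$start, dn$end), c(9000L, 10000L))
})

test_that("swapping the pools negates the scan and mirrors the calls", {
  g <- default_genome(marker_spacing_bp = 500000)
  pop <- simulate_ril_population(g, qtl_model(), n_lines = 120, seed = 3)
  pools <- select_pools(pop, pool_spec(25, "lowest"), pool_spec(25, "highest"))
  cnt <- simulate_pool_counts(pop, pools, seed = 4)
  swapped <- pool_counts(tibble::tibble(
    chrom = cnt$chrom, pos = cnt$pos, origin = cnt$origin,
    var1 = cnt$var2, tot1 = cnt$tot2, var2 = cnt$var1, tot2 = cnt$tot1))

  p <- bsa_params(n_rils_per_pool = 25, n_null_draws = 50000)
  thr <- simulate_threshold(p, seed = 6)
  a <- bsa_scan(cnt, p, thresholds = thr)
  b <- bsa_scan(swapped, p, thresholds = thr)
  expect_equal(b$track$lor, -a$track$lor, tolerance = 1e-12)

  mirrored <- b$intervals
  expect_identical(nrow(mirrored), nrow(a$intervals))
  expect_identical(mirrored$start, a$intervals$start)
  expect_identical(mirrored$end, a$intervals$end)
  expect_identical(mirrored$direction,
                   ifelse(a$intervals$direction == "pool2", "pool1", "pool2"))
})
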