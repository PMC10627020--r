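test_that("variance screening keeps homogeneous channels and flags outliers", {
  set.seed(41)
  # equal variances: zero spread among the others, nothing rejected
  m <- matrix(rep(sin(seq_len(1000) / 7), 10), nrow = 10, byrow = TRUE)
  out <- reject_channels(make_rec(m))
  expect_length(out$rejected, 0)

  # nine channels with variance ~1, one with variance ~100
  m <- matrix(rnorm(10 * 2000), nrow = 10)
  m[4, ] <- m[4, ] * 10
  rec <- make_rec(m)
  out <- reject_channels(rec)
  expect_equal(out$rejected, "C04")
  # leave-one-out oracle for the outlier channel
  v <- apply(m, 1, var)
  expect_true(v[4] > mean(v[-4]) + 3 * sd(v[-4]))
  # the report reproduces the leave-one-out bounds for every channel
  for (ch in c(1, 4, 7)) {
    expect_equal(out$report$lower[ch], mean(v[-ch]) - 3 * sd(v[-ch]))
    expect_equal(out$report$upper[ch], mean(v[-ch]) + 3 * sd(v[-ch]))
  }
})

test_that("variance screening needs at least 4 channels", {
  m <- matrix(rnorm(3 * 100), nrow = 3)
  expect_error(reject_channels(make_rec(m)), "4 channels")
})

test_that("common-average referencing removes the shared mean exactly", {
  x <- sin(seq_len(500) / 5)
  # single channel: referencing leaves all zeros
  r1 <- common_average_reference(make_rec(matrix(x, nrow = 1)))
  expect_true(all(r1$samples == 0))
  expect_equal(r1$reference, "common_average")

  # antisymmetric pair: x and -x are unchanged
  r2 <- common_average_reference(make_rec(rbind(x, -x)))
  expect_equal(r2$samples[1, ], x)
  expect_equal(r2$samples[2, ], -x)

  # samplewise sum of the output is zero; a second pass changes nothing
  set.seed(5)
  m <- matrix(rnorm(6 * 400), nrow = 6)
  r3 <- common_average_reference(make_rec(m))
  expect_lt(max(abs(colSums(r3$samples))), 1e-9)
  r4 <- common_average_reference(r3)
  expect_equal(r4$samples, r3$samples, tolerance = 1e-12)

  expect_error(common_average_reference(make_rec(m), character(0)), "retained")
})

test_that("windows tile blocks without crossing boundaries", {
  fs <- 256
  d <- make_design(1, 1, 30)      # rest 0-30, movement 30-60
  rec <- make_rec(matrix(0, nrow = 1, ncol = 60 * fs))
  w <- segment_windows(rec, d, win_s = 2)
  expect_equal(sum(w$condition == "rest"), 15)
  expect_equal(sum(w$condition == "movement"), 15)
  # each window wholly inside one block
  ends <- w$onset + 2
  expect_true(all(ends[w$condition == "rest"] <= 30 + 1e-9))
  expect_true(all(w$onset[w$condition == "movement"] >= 30))

  d5 <- make_design(5, 5, 30)
  rec5 <- make_rec(matrix(0, nrow = 1, ncol = 300 * fs))
  w5 <- segment_windows(rec5, d5, win_s = 2)
  expect_equal(as.vector(table(w5$condition)), c(75, 75))

  # a block shorter than the window yields no windows
  dshort <- make_design(1, 1, 1)
  recs <- make_rec(matrix(0, nrow = 1, ncol = 2 * fs))
  expect_error(segment_windows(recs, dshort, win_s = 2), "no analysis windows")
})

test_that("band log power separates in-band from out-of-band sinusoids", {
  fs <- 512
  t <- (seq_len(2 * fs) - 1) / fs
  s80 <- sin(2 * pi * 80 * t)
  s10 <- sin(2 * pi * 10 * t)
  hfb80 <- band_log_power(s80, fs, 65, 95)
  hfb10 <- band_log_power(s10, fs, 65, 95)
  expect_gt(hfb80 - hfb10, 5)
  # doubling the amplitude raises log power by exactly log 4
  expect_equal(band_log_power(2 * s80, fs, 65, 95) - hfb80, log(4),
               tolerance = 1e-9)
})

test_that("the 65-95 Hz band covers 61 half-Hz bins, both edges included", {
  expect_length(ecogfmri:::.band_bins(1024, 512, 65, 95), 61)
  freqs <- (seq_len(513) - 1) * 0.5
  expect_equal(freqs[ecogfmri:::.band_bins(1024, 512, 65, 95)][1], 65)
  expect_equal(max(freqs[ecogfmri:::.band_bins(1024, 512, 65, 95)]), 95)
})

test_that("band log power validates its preconditions", {
  x <- rnorm(512)
  expect_error(band_log_power(x, 512, 65, 300), "Nyquist")
  expect_error(band_log_power(x, 512, 95, 65), "f_lo")
  # 1 s window at 512 Hz gives 1 Hz bins, too coarse
  expect_error(band_log_power(x, 512, 65, 95), "0.5 Hz")
  expect_warning(band_log_power(rep(0, 1024), 512, 65, 95), "floored")
})

test_that("pooled t and z match the hand-worked example", {
  res <- electrode_band_zscores(c(1, 2, 3), c(3, 4, 5))
  expect_equal(res$t_stat, -2.449, tolerance = 1e-3)
  expect_equal(res$p_value, 0.0705, tolerance = 1e-3)
  expect_equal(res$z_score, -1.81, tolerance = 5e-3)
  expect_false(res$significant)
})

test_that("pooled t agrees with the reference implementation on random samples", {
  set.seed(11)
  for (i in 1:100) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    a <- rnorm(n1, mean = runif(1, -1, 1)); b <- rnorm(n2)
    res <- electrode_band_zscores(a, b)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(res$t_stat, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-8)
    # z reproduces the two-sided p it was derived from
    expect_equal(2 * pnorm(-abs(res$z_score)), res$p_value, tolerance = 1e-8)
  }
})

test_that("welch flavor matches t.test(var.equal = FALSE)", {
  set.seed(12)
  a <- rnorm(8, sd = 3); b <- rnorm(15)
  res <- electrode_band_zscores(a, b, welch = TRUE)
  ref <- t.test(a, b)
  expect_equal(res$t_stat, unname(ref$statistic), tolerance = 1e-8)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-8)
})

test_that("z-score behaves as a signed monotone image of t", {
  # identical samples: t = 0, z = 0, not significant
  res0 <- electrode_band_zscores(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res0$t_stat, 0)
  expect_equal(res0$z_score, 0)
  expect_false(res0$significant)

  # swapping condition labels flips the sign exactly
  a <- c(0.3, 1.2, 0.8, 1.5); b <- c(2.2, 1.9, 2.8)
  fwd <- electrode_band_zscores(a, b)
  rev <- electrode_band_zscores(b, a)
  expect_equal(fwd$t_stat, -rev$t_stat)
  expect_equal(fwd$z_score, -rev$z_score)
  expect_equal(fwd$p_value, rev$p_value)

  # z strictly increasing in t at fixed window counts
  set.seed(3)
  base <- rnorm(10)
  shifts <- seq(-2, 2, by = 0.25)
  stats <- sapply(shifts, function(s)
    unlist(electrode_band_zscores(base + s, base + rnorm(10, sd = 1e-6))[c("t_stat", "z_score")]))
  ord <- order(stats["t_stat", ])
  expect_true(all(diff(stats["z_score", ord]) > 0))

  # an equal additive shift of both conditions leaves t unchanged
  res1 <- electrode_band_zscores(a, b)
  res2 <- electrode_band_zscores(a + 7.3, b + 7.3)
  expect_equal(res1$t_stat, res2$t_stat, tolerance = 1e-12)

  # degenerate zero-variance inputs
  expect_warning(res3 <- electrode_band_zscores(c(1, 1, 1), c(2, 2, 2)), "capped")
  expect_equal(res3$z_score, -38)
  expect_error(electrode_band_zscores(1, c(1, 2)), "2 windows")
})

test_that("electrode responses carry coordinates and respect band validity", {
  cfg <- tiny_config()
  sc <- make_scene(c(4, 4), margin_mm = 8, seed = 2)
  tr <- make_truth(sc, seed = 2)
  d <- make_design(2, 2, 20)
  rec <- simulate_ecog(sc, tr, d, fs = 256, seed = 2)
  resp <- ecog_band_responses(rec, d, sc$electrodes)
  expect_equal(nrow(resp), 16 * 3)
  expect_setequal(unique(resp$band), c("hfb", "alpha", "beta"))
  expect_true(all(is.finite(resp$z_score)))
  expect_equal(resp$significant, resp$p_value < 0.05)
  expect_equal(resp$x[resp$electrode == "E01"],
               rep(sc$electrodes$x[1], 3))
  lofi <- rec; lofi$fs <- 128
  expect_error(ecog_band_responses(lofi, d, sc$electrodes), "Nyquist")
})
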