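test_that("gaussian weights reproduce the closed-form two-voxel example", {
  # two GM voxels at 2 mm (z = 1) and 4 mm (z = 0) from the electrode
  mask <- array(FALSE, dim = c(3, 1, 1))
  mask[2:3, 1, 1] <- TRUE
  affine <- rbind(cbind(diag(c(2, 1, 1)), c(0, 0, 0)), c(0, 0, 0, 1))
  zvol <- array(NA_real_, dim = dim(mask)); zvol[2:3, 1, 1] <- c(1, 0)
  zmap <- structure(list(z = zvol, gm_mask = mask, affine = affine),
                    class = "zmap")
  gw <- gaussian_weights(c(0, 0, 0), zmap, sigma = 2)
  w_expect <- exp(-c(0.5, 2))
  expect_equal(gw$weights, w_expect / sum(w_expect), tolerance = 1e-12)
  wz <- weighted_zscores(zmap, data.frame(name = "e1", x = 0, y = 0, z = 0), 2)
  expect_equal(unname(wz), exp(-0.5) / (exp(-0.5) + exp(-2)), tolerance = 1e-12)
  expect_equal(unname(wz), 0.8176, tolerance = 1e-4)
})

test_that("weights are normalized, truncated, and error when nothing is in range", {
  sc <- tiny_scene()
  zmap <- zmap_from_scene(sc, rnorm(sum(sc$gm_mask)))
  e <- as.numeric(sc$electrodes[5, c("x", "y", "z")])
  for (sig in c(1, 3, 10)) {
    gw <- gaussian_weights(e, zmap, sig)
    expect_equal(sum(gw$weights), 1, tolerance = 1e-9)
    expect_true(all(gw$weights >= 0))
  }
  far <- c(1e4, 1e4, 1e4)
  expect_error(gaussian_weights(far, zmap, 2, label = "E99"), "E99")
})

test_that("weighted z respects the single-voxel, uniform and limit contracts", {
  sc <- tiny_scene()
  n_gm <- sum(sc$gm_mask)
  zval <- rnorm(n_gm)
  zmap <- zmap_from_scene(sc, zval)
  el <- sc$electrodes[c(1, 6, 11), ]

  # uniform map: weighted z equals the constant for any sigma
  zuni <- zmap_from_scene(sc, rep(2.5, n_gm))
  for (sig in c(1, 5, 15))
    expect_equal(unname(weighted_zscores(zuni, el, sig)), rep(2.5, 3),
                 tolerance = 1e-12)

  # huge sigma: plain GM mean (deviation is O(extent^2 / sigma^2))
  wz <- weighted_zscores(zmap, el, 1e3)
  expect_equal(unname(wz), rep(mean(zval), 3), tolerance = 1e-3)
  wz6 <- weighted_zscores(zmap, el, 1e6)
  expect_equal(unname(wz6), rep(mean(zval), 3), tolerance = 1e-9)

  # tiny sigma at a voxel center: that voxel's z
  gm_xyz <- ecogfmri:::voxel_to_world(which(sc$gm_mask, arr.ind = TRUE), sc$affine)
  probe <- data.frame(name = "p", x = gm_xyz[10, 1], y = gm_xyz[10, 2],
                      z = gm_xyz[10, 3])
  expect_equal(unname(weighted_zscores(zmap, probe, 0.04)), zval[10],
               tolerance = 1e-9)

  # translation equivariance: shifting electrodes and affine together
  sc2 <- sc
  sc2$affine[1:3, 4] <- sc2$affine[1:3, 4] + c(10, -20, 5)
  zmap2 <- zmap_from_scene(sc2, zval)
  el2 <- el
  el2$x <- el2$x + 10; el2$y <- el2$y - 20; el2$z <- el2$z + 5
  expect_equal(weighted_zscores(zmap2, el2, 3), weighted_zscores(zmap, el, 3),
               tolerance = 1e-9)
})

test_that("truncated weighting matches untruncated brute force", {
  set.seed(31)
  for (rep in 1:5) {
    sc <- tiny_scene(seed = rep)
    zval <- rnorm(sum(sc$gm_mask))
    zmap <- zmap_from_scene(sc, zval)
    gm_xyz <- ecogfmri:::voxel_to_world(which(sc$gm_mask, arr.ind = TRUE),
                                        sc$affine)
    for (sig in runif(4, 1, 15)) {
      el <- sc$electrodes[sample(nrow(sc$electrodes), 1), ]
      wz <- weighted_zscores(zmap, el, sig)
      d2 <- rowSums(sweep(gm_xyz, 2, as.numeric(el[, c("x", "y", "z")]))^2)
      w <- exp(-d2 / (2 * sig^2))
      expect_lt(abs(unname(wz) - sum(w * zval) / sum(w)), 1e-6)
    }
  }
})

test_that("across-electrode variance of weighted z never grows with sigma", {
  set.seed(32)
  for (rep in 1:3) {
    sc <- tiny_scene(seed = 10 + rep)
    zmap <- zmap_from_scene(sc, rnorm(sum(sc$gm_mask)))
    v <- sapply(seq(1, 20, by = 1), function(sig)
      var(weighted_zscores(zmap, sc$electrodes, sig)))
    expect_true(all(diff(v) <= 1e-9))
  }
})

test_that("correlation at one kernel width matches exact and hand-worked cases", {
  ez <- c(-1, 0, 1, 2)
  expect_equal(correlation_at_sigma(ez, 2 * ez + 1),
               list(r = 1, r2 = 1, slope = 2, n = 4))
  expect_equal(correlation_at_sigma(ez, -ez),
               list(r = -1, r2 = 1, slope = -1, n = 4))
  # hand-evaluated Pearson formula for an outlier-heavy pair
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 100)
  num <- sum((x - mean(x)) * (y - mean(y)))
  r_hand <- num / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  cs <- correlation_at_sigma(x, y)
  expect_equal(cs$r, r_hand, tolerance = 1e-12)
  expect_equal(cs$r2, r_hand^2, tolerance = 1e-12)
  expect_equal(cs$slope, num / sum((x - mean(x))^2), tolerance = 1e-12)

  expect_error(correlation_at_sigma(c(1, 2), c(1, 2)), "3 electrodes")
  expect_error(correlation_at_sigma(c(1, 1, 1), c(1, 2, 3)), "variance")
})

test_that("r2 is invariant to affine rescaling of either z vector", {
  set.seed(33)
  x <- rnorm(10); y <- 0.4 * x + rnorm(10, sd = 0.5)
  base <- correlation_at_sigma(x, y)
  resc <- correlation_at_sigma(2 * x + 3, y)
  expect_equal(resc$r2, base$r2, tolerance = 1e-12)
  expect_equal(resc$slope, base$slope / 2, tolerance = 1e-12)
  resc2 <- correlation_at_sigma(x, -5 * y + 1)
  expect_equal(resc2$r2, base$r2, tolerance = 1e-12)
})

test_that("a sigma-independent map yields a flat curve, boundary peak and no concavity", {
  set.seed(34)
  zmap <- isolated_zmap(n = 6, z = rnorm(6))
  gm_xyz <- ecogfmri:::voxel_to_world(which(zmap$gm_mask, arr.ind = TRUE),
                                      zmap$affine)
  el <- data.frame(electrode = sprintf("e%d", 1:6), band = "hfb",
                   z_score = rnorm(6), significant = TRUE,
                   x = gm_xyz[, 1] + 0.5, y = gm_xyz[, 2], z = gm_xyz[, 3])
  kc <- fit_kernel_curve(zmap, el)
  expect_lt(diff(range(kc$r2)), 1e-12)
  expect_equal(kc$peak_sigma, 1)               # tie resolves to smallest
  expect_true(kc$peak_on_boundary)
  expect_equal(kc$concavity_flag, "no_concavity")
  expect_true(is.na(kc$concavity_sigma))
})

test_that("curve peak is the argmax of r2 with first-maximum tie-breaking", {
  sc <- tiny_scene(seed = 20)
  set.seed(35)
  zmap <- zmap_from_scene(sc, rnorm(sum(sc$gm_mask)))
  el <- data.frame(electrode = sc$electrodes$name, band = "hfb",
                   z_score = rnorm(nrow(sc$electrodes)), significant = TRUE,
                   x = sc$electrodes$x, y = sc$electrodes$y,
                   z = sc$electrodes$z)
  kc <- fit_kernel_curve(zmap, el)
  expect_equal(kc$peak_sigma, kc$sigma[which.max(kc$r2)])
  expect_equal(kc$peak_r2, max(kc$r2))
  expect_true(all(kc$r2 >= 0 & kc$r2 <= 1))
  expect_equal(kc$r2, kc$r^2, tolerance = 1e-12)
  expect_true(kc$concavity_flag %in% c("ok", "no_concavity"))
  expect_s3_class(summary(kc), "summary.kernel_curve")
  co <- coef(kc)
  expect_named(co, c("peak_sigma", "peak_r2", "peak_slope",
                     "concavity_sigma", "concavity_r2"))
})

test_that("significant-electrode filtering is applied and fixed across the sweep", {
  sc <- tiny_scene(seed = 21)
  set.seed(36)
  zmap <- zmap_from_scene(sc, rnorm(sum(sc$gm_mask)))
  el <- data.frame(electrode = sc$electrodes$name, band = "hfb",
                   z_score = rnorm(16), significant = rep(c(TRUE, FALSE), 8),
                   x = sc$electrodes$x, y = sc$electrodes$y,
                   z = sc$electrodes$z)
  kc <- fit_kernel_curve(zmap, el)
  expect_equal(kc$n_electrodes, 8)
  expect_setequal(kc$electrodes, el$electrode[el$significant])
  el$significant[] <- FALSE
  el$significant[1:2] <- TRUE
  expect_error(fit_kernel_curve(zmap, el), "at least 3")
})

test_that("concavity operator matches the analytic oracle on a known curve", {
  # r2(s) = 1 - exp(-s/3): second derivative -(1/9) exp(-s/3), most
  # negative at the left end, so the first interior grid point wins
  g1 <- seq(1, 20, by = 1)
  cc1 <- concavity_sigma(list(sigma = g1, r2 = 1 - exp(-g1 / 3)))
  expect_equal(cc1$sigma, 2)
  expect_equal(cc1$flag, "ok")
  g2 <- seq(1, 20, by = 0.25)
  cc2 <- concavity_sigma(list(sigma = g2, r2 = 1 - exp(-g2 / 3)))
  expect_equal(cc2$sigma, 1.25)
  # discrete central difference approximates the analytic value
  expect_equal(unname(cc2$d2["5"]), -exp(-5 / 3) / 9, tolerance = 1e-3)
})

test_that("concavity flags linear curves and breaks constant-curvature ties", {
  g <- seq(1, 20, by = 0.25)
  lin <- concavity_sigma(list(sigma = g, r2 = 0.01 + 0.002 * g))
  expect_true(is.na(lin$sigma))
  expect_equal(lin$flag, "no_concavity")
  # pure quadratic: constant negative curvature everywhere, smallest sigma wins
  quad <- concavity_sigma(list(sigma = g, r2 = 1 - ((g - 10) / 15)^2))
  expect_equal(quad$sigma, 1.25)
  expect_equal(quad$flag, "ok")
  # upward-curved (convex) r2: no downwards concavity
  conv <- concavity_sigma(list(sigma = g, r2 = 0.001 * (g - 1)^2))
  expect_equal(conv$flag, "no_concavity")
  expect_error(concavity_sigma(list(sigma = c(1, 2, 4, 8, 16),
                                    r2 = rep(0.1, 5))), "uniform")
  expect_error(concavity_sigma(list(sigma = 1:4, r2 = rep(0.1, 4))), "5 grid")
})
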