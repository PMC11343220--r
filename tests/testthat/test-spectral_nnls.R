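b9 <- default_bvalues()

test_that("dictionary has the documented structure", {
  cfg <- spectral_config()
  dict <- build_dictionary(b9, cfg)
  expect_equal(dim(dict$A), c(9, 300))
  expect_equal(dict$A[1, ], rep(1, 300))        # b = 0 row
  expect_true(all(diff(dict$D_grid) > 0))
  expect_equal(dict$D_grid[1], 1e-4)
  expect_equal(dict$D_grid[300], 1)
  # column at the slowest grid point is close to all-ones
  expect_true(all(dict$A[, 1] > 0.9))
  expect_equal(dim(dict$A_aug), c(9 + 298, 300))
})

test_that("unregularized spectrum of an on-grid exponential is a single spike", {
  cfg <- spectral_config(M = 60, D_min = 1e-3, D_max = 0.1, lambda = 0)
  dict <- build_dictionary(b9, cfg)
  k <- 25
  curve <- decay_curve(b9, 0.8 * exp(-b9 * dict$D_grid[k]))
  spec <- fit_spectrum(curve, cfg, dict)
  expect_equal(which(spec$amplitudes > 1e-8), k)
  expect_equal(spec$amplitudes[k], 0.8, tolerance = 1e-8)
})

test_that("augmented NNLS matches independent QP solvers on small instances", {
  set.seed(11)
  cfg <- spectral_config(M = 20, D_min = 1e-4, D_max = 1, lambda = 0.1)
  dict <- build_dictionary(b9, cfg)
  for (i in 1:5) {
    truth <- table1_means()
    curve <- gaussian_signal(truth$f, truth$D, b9)
    curve$signal <- curve$signal + rnorm(9, 0, 0.02)
    y_aug <- c(curve$signal, numeric(cfg$M - 2))
    mine <- fit_spectrum(curve, cfg, dict)$amplitudes
    oracle <- pg_nnls(dict$A_aug, y_aug)
    expect_lt(max(abs(mine - oracle)), 1e-6)
    lh <- pracma::lsqnonneg(dict$A_aug, y_aug)$x
    expect_lt(max(abs(mine - lh)), 1e-6)
  }
})

test_that("noiseless three-component curve is recovered within grid tolerance", {
  truth <- table1_means()
  curve <- gaussian_signal(truth$f, truth$D, b9)
  fit <- spectral_fit_voxel(curve)
  expect_equal(fit$n_peaks, 3L)
  expect_true(all(fit$f > 0))
  expect_lt(max(abs(fit$f - truth$f) / truth$f), 0.05)
  expect_lt(max(abs(fit$D - truth$D) / truth$D), 0.10)
  expect_gt(fit$r2, 0.999)
})

test_that("amplitudes are non-negative and peak count is monotone in lambda", {
  truth <- table1_means()
  curve <- gaussian_signal(truth$f, truth$D, b9)
  lams <- c(0, 0.01, 0.1, 1, 10, 100)
  counts <- vapply(lams, function(l) {
    spec <- fit_spectrum(curve, spectral_config(lambda = l))
    expect_true(all(spec$amplitudes >= 0))
    nrow(segment_peaks(spec))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("peak segmentation computes area fractions and weighted means", {
  cfg <- spectral_config(M = 100, D_min = 1e-3, D_max = 0.1)
  dict <- build_dictionary(b9, cfg)
  spec <- structure(list(D_grid = dict$D_grid,
                         amplitudes = numeric(100), config = cfg),
                    class = "diffusion_spectrum")
  # two disjoint symmetric lobes of equal area
  spec$amplitudes[20:22] <- c(1, 2, 1)
  spec$amplitudes[70:72] <- c(1, 2, 1)
  pk <- segment_peaks(spec)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$f, c(0.5, 0.5))
  expect_equal(sum(pk$f), 1)
  # weighted-mean D of a symmetric lobe sits at its center coefficient
  expect_equal(pk$D[1], dict$D_grid[21], tolerance = 1e-3)
  # single lobe has f = 1; empty spectrum has no peaks
  spec$amplitudes[] <- 0; spec$amplitudes[40:45] <- 1
  expect_equal(segment_peaks(spec)$f, 1)
  spec$amplitudes[] <- 0
  expect_equal(nrow(segment_peaks(spec)), 0)
})

test_that("regime assignment bins, excludes and renormalizes as specified", {
  pk <- function(D, area) data.frame(idx_lo = 1, idx_hi = 2,
                                     area = area, f = area / sum(area), D = D)
  # tissue + vascular present, tubule absent
  fit <- assign_components(pk(c(1.8e-3, 70e-3), c(0.8, 0.2)))
  expect_equal(unname(fit$f), c(0.8, 0, 0.2))
  expect_equal(unname(fit$D), c(1.8e-3, 0, 70e-3))
  # single too-slow peak excluded entirely
  fit <- assign_components(pk(0.5e-3, 1))
  expect_equal(unname(fit$f), c(0, 0, 0))
  expect_equal(fit$flag, "no_peaks")
  # direct binning of three in-regime peaks
  fit <- assign_components(pk(c(1.5e-3, 10e-3, 80e-3), c(0.7, 0.2, 0.1)))
  expect_equal(unname(fit$f), c(0.7, 0.2, 0.1))
  # excluded slow peak forces renormalization of the remainder
  fit <- assign_components(pk(c(0.2e-3, 1.5e-3, 10e-3), c(0.5, 0.3, 0.2)))
  expect_equal(unname(fit$f), c(0.6, 0.4, 0))
  expect_equal(sum(fit$f), 1)
  # two peaks within one regime merge area-weighted
  fit <- assign_components(pk(c(1.2e-3, 2.4e-3), c(0.25, 0.75)))
  expect_equal(unname(fit$f["tissue"]), 1)
  expect_equal(unname(fit$D["tissue"]), 0.25 * 1.2e-3 + 0.75 * 2.4e-3)
})

test_that("spectral voxel fit handles flexible component counts", {
  # two-component curve: tubule regime stays empty
  curve <- gaussian_signal(c(0.85, 0.15), c(0.0015, 0.070), b9)
  fit <- spectral_fit_voxel(curve)
  expect_equal(unname(fit$f["tubule"]), 0)
  expect_gt(fit$f["tissue"], 0.75)
  expect_gt(fit$f["vascular"], 0.08)
  expect_gt(fit$r2, 0.999)
  expect_equal(sum(fit$f), 1)
  # fD is consistently f * D
  expect_equal(fit$fD, fit$f * fit$D)
})
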