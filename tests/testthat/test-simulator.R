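test_that("FA-targeted tensors hit the requested mean diffusivity exactly", {
  set.seed(4)
  for (i in 1:20) {
    D <- 10^runif(1, -3.5, -1.5)
    fa <- runif(1, 0, 0.5)
    tensor <- make_tensor(D, fa)
    expect_equal(mean(diag(tensor)), D, tolerance = 1e-14)
  }
  expect_error(make_tensor(-1, 0.1), "> 0")
  expect_error(make_tensor(0.001, 1), "FA_target")
})

test_that("candidate selection reaches the target FA reliably", {
  set.seed(8)
  fa <- replicate(200, attr(make_tensor(0.0015, 0.18), "FA_achieved"))
  expect_gte(mean(abs(fa - 0.18) <= 0.02), 0.99)
})

test_that("random rotations are proper and leave eigenvalues untouched", {
  set.seed(9)
  tensor <- make_tensor(0.0015, 0.18)
  ev0 <- sort(eigen(tensor, symmetric = TRUE, only.values = TRUE)$values)
  for (i in 1:15) {
    R <- random_rotation()
    expect_equal(crossprod(R), diag(3), tolerance = 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
    rot <- R %*% tensor %*% t(R)
    expect_equal(sort(eigen(rot, symmetric = TRUE, only.values = TRUE)$values),
                 ev0, tolerance = 1e-12)
    expect_equal(measure_three_directions(rot), mean(diag(tensor)),
                 tolerance = 1e-14)
  }
})

test_that("rotated principal axes distribute uniformly on the sphere", {
  set.seed(10)
  u <- t(vapply(1:2000, function(i) drop(random_rotation() %*% c(1, 0, 0)),
                numeric(3)))
  rayleigh <- 3 * nrow(u) * sum(colMeans(u)^2)
  expect_gt(stats::pchisq(rayleigh, df = 3, lower.tail = FALSE), 0.01)
})

test_that("three-direction measurement averages the diagonal", {
  expect_equal(measure_three_directions(diag(c(0.001, 0.002, 0.003))), 0.002)
  expect_equal(measure_three_directions(diag(3) * 0.010), 0.010)
})

test_that("Rician noise has the stated mean shift and spread", {
  cu <- gaussian_signal(1, 0.0015, default_bvalues())
  expect_identical(add_rician_noise(cu, 0), cu)
  set.seed(12)
  sigma <- 0.02
  # at zero signal the draws center on the Rician floor, sd sigma
  zero <- structure(list(bvalues = 0, signal = 0), class = "decay_curve")
  draws <- replicate(1e5, add_rician_noise(zero, sigma)$signal)
  expect_lt(abs(mean(draws) - sigma), 3e-4)
  expect_lt(abs(sd(draws) - sigma), 0.05 * sigma)
  # at finite signal the mean is sqrt(I^2 + sigma^2)
  one <- structure(list(bvalues = 0, signal = 0.5), class = "decay_curve")
  draws <- replicate(1e5, add_rician_noise(one, sigma)$signal)
  expect_lt(abs(mean(draws) - sqrt(0.25 + sigma^2)), 3e-4)
})

test_that("cohort simulation respects its configuration contract", {
  cfg <- cohort_config(n_sets = 25, master_seed = 77)
  sim <- simulate_cohort(cfg)
  sim2 <- simulate_cohort(cfg)
  # determinism under the same master seed
  expect_identical(sim$truth, sim2$truth)
  expect_identical(sim$curves, sim2$curves)
  # fractions sum to exactly 1 per set
  sums <- tapply(sim$truth$f, sim$truth$set_id, sum)
  expect_equal(as.numeric(sums), rep(1, 25))
  # trace invariance: D_approx equals the drawn mean diffusivity always
  expect_lt(max(abs(sim$truth$D_approx - sim$truth$D_mean)), 1e-12)
  # fD truth is the product
  expect_equal(sim$truth$fD_truth, sim$truth$f * sim$truth$D_approx)
  # default acquisition: SNR 50 at b = 0
  expect_equal(1 / cfg$noise_sigma, 50)
  expect_equal(cfg$bvalues, c(0, 10, 30, 50, 80, 120, 200, 400, 800))
})

test_that("two-component cohorts carry a structurally absent tubule", {
  sim <- simulate_cohort(cohort_config(n_sets = 12, n_components = 2,
                                       master_seed = 5))
  tub <- sim$truth[sim$truth$component == "tubule", ]
  expect_true(all(tub$f == 0 & tub$D_approx == 0 & tub$fD_truth == 0))
  act <- sim$truth[sim$truth$component != "tubule", ]
  expect_true(all(act$f > 0 & act$D_approx > 0))
})

test_that("noiseless cohorts start at unit signal and draws stay in range", {
  sim <- simulate_cohort(cohort_config(n_sets = 40, master_seed = 3,
                                       noise_sigma = 0))
  s0 <- vapply(sim$curves, function(cu) cu$signal[1], numeric(1))
  expect_equal(s0, rep(1, 40))
  expect_true(all(sim$truth$f >= 0 & sim$truth$f <= 1))
  expect_true(all(is.na(sim$truth$gamma) | sim$truth$gamma > 0))
  fa <- sim$truth$FA_target
  expect_true(all(is.na(fa) | (fa >= 0 & fa < 1)))
  # component means track the configured distributions (40 sets, loose band)
  tis <- sim$truth[sim$truth$component == "tissue", ]
  expect_equal(mean(tis$f), 0.6, tolerance = 0.1)
  expect_equal(mean(tis$D_mean), 0.0015, tolerance = 0.3)
})
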