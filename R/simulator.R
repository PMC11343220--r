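#' Literature parameter distributions of the simulated kidney cortex
#'
#' Means and standard deviations of the normal distributions the
#' per-component simulation inputs are drawn from: signal fraction f,
#' mean diffusivity D (mm^2/s), fractional anisotropy FA, and anomalous
#' exponent gamma, for the tissue-parenchyma, tubular and vascular
#' components of a cortical voxel.
#'
#' @return data.frame with one row per component.
#' @export
cortex_distributions <- function() {
  data.frame(
    component = .components,
    f_mean = c(0.60, 0.30, 0.10),      f_sd = c(0.10, 0.015, 0.05),
    D_mean = c(0.0015, 0.010, 0.070),  D_sd = c(0.00075, 0.0025, 0.009),
    FA_mean = c(0.18, 0.12, 0.09),     FA_sd = c(0.02, 0.03, 0.04),
    gamma_mean = c(0.85, 1.0, 1.75),   gamma_sd = c(0.051, 0.10, 0.2),
    stringsAsFactors = FALSE)
}

#' Simulated cohort configuration
#'
#' @param n_sets number of simulated voxels (parameter sets), >= 1.
#' @param n_components 3 (tissue + tubule + vascular) or 2 (tubular
#'   component removed, mimicking conventional two-compartment IVIM).
#' @param distributions per-component normal distributions, as returned by
#'   [cortex_distributions()].
#' @param bvalues acquisition b-values (s/mm^2).
#' @param noise_sigma Rician noise scale on the unit b=0 signal; the
#'   default 0.02 corresponds to SNR 50.
#' @param master_seed integer seed; per-set substreams are derived from it
#'   so cohorts are reproducible.
#' @param n_candidates candidate eigenvalue sets per tensor when targeting
#'   FA, default 500.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_sets = 1000, n_components = 3,
                          distributions = cortex_distributions(),
                          bvalues = default_bvalues(), noise_sigma = 0.02,
                          master_seed = 1, n_candidates = 500) {
  if (n_sets < 1) stop("n_sets must be >= 1")
  if (!n_components %in% c(2, 3)) stop("n_components must be 2 or 3")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(n_sets = as.integer(n_sets),
                 n_components = as.integer(n_components),
                 distributions = distributions, bvalues = bvalues,
                 noise_sigma = noise_sigma,
                 master_seed = as.integer(master_seed),
                 n_candidates = as.integer(n_candidates)),
            class = "cohort_config")
}

.fa_of_eigenvalues <- function(ev) {
  if (all(ev == 0)) return(0)
  sqrt(1.5 * sum((ev - mean(ev))^2) / sum(ev^2))
}

#' Build an anisotropic diffusion tensor with target FA and mean diffusivity
#'
#' Since FA does not determine the eigenvalues uniquely, `n_candidates`
#' eigenvalue triples are drawn i.i.d. uniform on (0, 1], the triple whose
#' FA is closest to the target is kept, and its eigenvalues are rescaled
#' multiplicatively (FA-preserving) so their mean equals `D_mean` exactly.
#' The tensor is returned in its principal frame (diagonal); combine with
#' [random_rotation()] for a randomly oriented tensor.
#'
#' @param D_mean target mean diffusivity (mm^2/s), > 0.
#' @param FA_target target fractional anisotropy in \[0, 1).
#' @param n_candidates number of candidate draws, >= 1.
#' @return 3 x 3 diagonal tensor with attribute `FA_achieved`.
#' @export
make_tensor <- function(D_mean, FA_target, n_candidates = 500) {
  if (D_mean <= 0) stop("D_mean must be > 0")
  if (FA_target < 0 || FA_target >= 1) stop("FA_target must be in [0, 1)")
  if (n_candidates < 1) stop("n_candidates must be >= 1")
  cand <- matrix(stats::runif(3 * n_candidates), ncol = 3)
  fa <- sqrt(1.5 * rowSums((cand - rowMeans(cand))^2) / rowSums(cand^2))
  ev <- cand[which.min(abs(fa - FA_target)), ]
  ev <- ev * D_mean / mean(ev)
  tensor <- diag(ev)
  attr(tensor, "FA_achieved") <- .fa_of_eigenvalues(ev)
  tensor
}

#' Uniform random 3-D rotation
#'
#' Rotation matrix drawn uniformly from SO(3) via a normalized random
#' Gaussian quaternion.
#'
#' @return 3 x 3 rotation matrix.
#' @export
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Apparent diffusivity from three orthogonal measurements
#'
#' Apparent D measured along the global x, y and z axes of a (rotated)
#' tensor, averaged: the mean of the diagonal entries. By trace
#' invariance this equals the tensor's mean diffusivity for any rotation.
#'
#' @param tensor symmetric positive-definite 3 x 3 diffusion tensor.
#' @return D_approx (mm^2/s).
#' @export
measure_three_directions <- function(tensor) {
  if (!isTRUE(all.equal(tensor, t(tensor), tolerance = 1e-8)))
    stop("tensor must be symmetric")
  mean(diag(tensor))
}

#' Add Rician noise to a decay curve
#'
#' Magnitude-image noise approximated as a non-zero-mean Gaussian: each
#' sample is drawn from Normal(mean = sqrt(I(b)^2 + sigma^2), sd = sigma).
#' The same sigma applies at every b-value, so SNR falls as the signal
#' decays while the Rician floor (about sigma where I ~ 0) persists.
#'
#' @param curve a [decay_curve()].
#' @param sigma noise scale, >= 0 (0 returns the curve unchanged).
#' @return A noisy [decay_curve()].
#' @export
add_rician_noise <- function(curve, sigma) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(curve)
  s <- stats::rnorm(length(curve$signal),
                    mean = sqrt(curve$signal^2 + sigma^2), sd = sigma)
  decay_curve(curve$bvalues, s)
}

# rejection sampling from a normal restricted to an open-ended range
.draw_trunc <- function(mean, sd, lower = -Inf, upper = Inf) {
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x > lower && x < upper) return(x)
  }
}

#' Simulate a cohort of anisotropic anomalous cortical voxels
#'
#' For each set, per-component (f, D, FA, gamma) are drawn from the
#' configured normal distributions (draws outside the valid range are
#' rejected and redrawn); fractions are normalized to sum to one;
#' anisotropic tensors are built with [make_tensor()], randomly rotated,
#' and measured along three orthogonal directions for a per-component
#' D_approx; the noiseless curve is the stretched-exponential sum
#' [anomalous_signal()] evaluated at D_approx; Rician noise is added at
#' `noise_sigma`. With `n_components = 2` the tubular component is absent:
#' its ground-truth f, D and fD are zero and it contributes no signal.
#'
#' @param config a [cohort_config()].
#' @return Object of class `dwi_cohort`: list with `truth` (data.frame,
#'   one row per set x component: `set_id`, `component`, `f`, `D_mean`,
#'   `FA_target`, `FA_achieved`, `gamma`, `D_approx`, `fD_truth`),
#'   `curves` (list of noisy [decay_curve()]s), and `config`.
#' @examples
#' sim <- simulate_cohort(cohort_config(n_sets = 5, master_seed = 7))
#' head(sim$truth)
#' @export
simulate_cohort <- function(config = cohort_config()) {
  dist <- config$distributions
  active <- if (config$n_components == 3) .components else
    c("tissue", "vascular")
  set.seed(config$master_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, config$n_sets)
  truth <- vector("list", config$n_sets)
  curves <- vector("list", config$n_sets)
  for (i in seq_len(config$n_sets)) {
    set.seed(seeds[i])
    rows <- data.frame(set_id = i, component = .components,
                       f = 0, D_mean = 0, FA_target = NA_real_,
                       FA_achieved = NA_real_, gamma = NA_real_,
                       D_approx = 0, fD_truth = 0,
                       stringsAsFactors = FALSE)
    for (cmp in active) {
      k <- match(cmp, dist$component)
      j <- match(cmp, rows$component)
      rows$f[j] <- .draw_trunc(dist$f_mean[k], dist$f_sd[k], 0, 1)
      rows$D_mean[j] <- .draw_trunc(dist$D_mean[k], dist$D_sd[k], 0)
      rows$FA_target[j] <- .draw_trunc(dist$FA_mean[k], dist$FA_sd[k], 0, 1)
      rows$gamma[j] <- .draw_trunc(dist$gamma_mean[k], dist$gamma_sd[k], 0)
    }
    on <- rows$component %in% active
    rows$f[on] <- rows$f[on] / sum(rows$f[on])
    for (j in which(on)) {
      tensor <- make_tensor(rows$D_mean[j], rows$FA_target[j],
                            config$n_candidates)
      rows$FA_achieved[j] <- attr(tensor, "FA_achieved")
      R <- random_rotation()
      rotated <- R %*% tensor %*% t(R)
      rows$D_approx[j] <- measure_three_directions(rotated)
    }
    rows$fD_truth <- rows$f * rows$D_approx
    curve <- anomalous_signal(rows$f[on], rows$D_approx[on], rows$gamma[on],
                              config$bvalues)
    curves[[i]] <- add_rician_noise(curve, config$noise_sigma)
    truth[[i]] <- rows
  }
  structure(list(truth = do.call(rbind, truth), curves = curves,
                 config = config),
            class = "dwi_cohort")
}

#' @export
print.dwi_cohort <- function(x, ...) {
  cat("<dwi_cohort>", x$config$n_sets, "sets,", x$config$n_components,
      "components,", length(x$config$bvalues), "b-values, sigma =",
      x$config$noise_sigma, "\n")
  invisible(x)
}

#' Fit every curve of a simulated cohort
#'
#' Applies one of the three fitting methods voxel-wise over a cohort,
#' reusing the method's precomputable structures (exponential dictionary
#' or posterior grid) across curves.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param method `"spectral"`, `"biexp"` or `"triexp"`.
#' @param config [spectral_config()] used when `method = "spectral"`.
#' @param priors [biexp_priors()] used when `method = "biexp"`.
#' @param starts [triexp_start()] used when `method = "triexp"`.
#' @return data.frame with one row per set: `set_id` plus the
#'   [component_fit()] columns.
#' @export
fit_cohort <- function(cohort, method = c("spectral", "biexp", "triexp"),
                       config = spectral_config(), priors = biexp_priors(),
                       starts = triexp_start()) {
  method <- match.arg(method)
  bvals <- cohort$config$bvalues
  pre <- switch(method,
    spectral = build_dictionary(bvals, config),
    biexp = biexp_grid(bvals, priors),
    triexp = NULL)
  rows <- lapply(seq_along(cohort$curves), function(i) {
    curve <- cohort$curves[[i]]
    fit <- switch(method,
      spectral = spectral_fit_voxel(curve, config, dictionary = pre),
      biexp = fit_biexponential_bayesian(curve, priors, grid = pre),
      triexp = fit_triexponential_ls(curve, starts))
    cbind(set_id = i, as.data.frame(fit))
  })
  do.call(rbind, rows)
}
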