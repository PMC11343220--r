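#' Multi-b-value decay curve
#'
#' Container for one voxel's normalized diffusion-weighted signal decay,
#' \eqn{S(b)/S_0}, sampled at an ordered set of b-values.
#'
#' @param bvalues numeric vector of diffusion weightings (s/mm^2),
#'   non-negative and strictly increasing.
#' @param signal numeric vector of normalized signal values, same length.
#' @return An object of class `decay_curve`: a list with elements
#'   `bvalues` and `signal`.
#' @examples
#' decay_curve(c(0, 100, 800), c(1, 0.8, 0.4))
#' @export
decay_curve <- function(bvalues, signal) {
  bvalues <- as.numeric(bvalues)
  signal <- as.numeric(signal)
  if (length(bvalues) != length(signal))
    stop("bvalues and signal must have the same length")
  if (anyNA(bvalues) || any(bvalues < 0))
    stop("b-values must be non-negative")
  if (is.unsorted(bvalues, strictly = TRUE))
    stop("b-values must be strictly increasing")
  structure(list(bvalues = bvalues, signal = signal), class = "decay_curve")
}

#' @export
print.decay_curve <- function(x, ...) {
  cat("<decay_curve> ", length(x$bvalues), " b-values, b = [",
      min(x$bvalues), ", ", max(x$bvalues), "] s/mm^2\n", sep = "")
  invisible(x)
}

#' The 9 b-value acquisition protocol
#'
#' b-values (s/mm^2) of the clinical multi-b-value kidney IVIM-DWI protocol
#' that all defaults in this package assume.
#'
#' @return Numeric vector `c(0, 10, 30, 50, 80, 120, 200, 400, 800)`.
#' @export
default_bvalues <- function() c(0, 10, 30, 50, 80, 120, 200, 400, 800)

.check_components <- function(f, D, gamma = NULL) {
  if (length(f) != length(D)) stop("f and D must have the same length")
  if (anyNA(f) || any(f < 0 | f > 1)) stop("fractions must lie in [0, 1]")
  if (anyNA(D) || any(D < 0)) stop("diffusion coefficients must be >= 0")
  if (!is.null(gamma)) {
    if (length(gamma) != length(f)) stop("gamma must match f in length")
    if (anyNA(gamma) || any(gamma <= 0)) stop("gamma must be > 0")
  }
  invisible(TRUE)
}

#' Multi-component Gaussian diffusion signal
#'
#' Evaluates the multi-exponential (multi-Gaussian) decay
#' \eqn{S(b)/S_0 = \sum_i f_i e^{-b D_i}}.
#'
#' Fractions are validated, not normalized: callers (the simulator and the
#' fitters) perform any normalization explicitly.
#'
#' @param f signal fractions, each in \[0, 1\].
#' @param D diffusion coefficients (mm^2/s), same length as `f`.
#' @param bvalues b-values (s/mm^2).
#' @return A [decay_curve].
#' @examples
#' gaussian_signal(c(0.6, 0.3, 0.1), c(0.0015, 0.010, 0.070), default_bvalues())
#' @seealso [anomalous_signal()] for the stretched-exponential counterpart.
#' @export
gaussian_signal <- function(f, D, bvalues) {
  .check_components(f, D)
  if (any(bvalues < 0)) stop("b-values must be non-negative")
  s <- rowSums(matrix(vapply(seq_along(f), function(i) {
    f[i] * exp(-(bvalues * D[i]))
  }, numeric(length(bvalues))), nrow = length(bvalues)))
  decay_curve(bvalues, s)
}

#' Multi-component anomalous (stretched-exponential) diffusion signal
#'
#' Evaluates \eqn{S(b)/S_0 = \sum_i f_i e^{-(b D_i)^{\gamma_i}}}: the
#' stretch exponent applies to the dimensionless product \eqn{bD}.
#' \eqn{\gamma < 1} is sub-diffusion, \eqn{\gamma = 1} Brownian diffusion
#' (identical to [gaussian_signal()]), \eqn{\gamma > 1} super-diffusion
#' (ballistic at 2).
#'
#' @inheritParams gaussian_signal
#' @param gamma anomalous exponents, all > 0, same length as `f`.
#' @return A [decay_curve].
#' @examples
#' anomalous_signal(1, 0.070, 2, c(0, 10))  # exp(-0.49) at b = 10
#' @export
anomalous_signal <- function(f, D, gamma, bvalues) {
  .check_components(f, D, gamma)
  if (any(bvalues < 0)) stop("b-values must be non-negative")
  s <- rowSums(matrix(vapply(seq_along(f), function(i) {
    f[i] * exp(-(bvalues * D[i])^gamma[i])
  }, numeric(length(bvalues))), nrow = length(bvalues)))
  decay_curve(bvalues, s)
}

#' Gaussian-equivalent fD of an anomalous component
#'
#' The anomalous flow product \eqn{f_A D_A^\gamma b^{\gamma-1}} evaluated at
#' a reference b-value near the center of the component's diffusion regime.
#' For \eqn{\gamma = 1} this reduces to \eqn{fD} exactly; for relevant
#' b-values it approximates the Gaussian product \eqn{f_i D_i}. The
#' regime-center defaults used in the worked example are b = 500 (tissue),
#' 100 (tubule) and 10 (vascular) s/mm^2.
#'
#' @param f signal fraction.
#' @param D anomalous diffusion coefficient (mm^2/s).
#' @param gamma anomalous exponent, > 0.
#' @param b_ref reference b-value (s/mm^2), > 0 (b_ref = 0 is singular when
#'   gamma < 1).
#' @return `f * D^gamma * b_ref^(gamma - 1)` (mm^2/s, scaled by f).
#' @export
effective_gaussian_fD <- function(f, D, gamma, b_ref) {
  .check_components(f, D, gamma)
  if (any(b_ref < 0)) stop("b_ref must be non-negative")
  if (any(b_ref == 0 & gamma < 1)) stop("b_ref = 0 is singular for gamma < 1")
  f * D^gamma * b_ref^(gamma - 1)
}
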