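#' Probability that a Gaussian walker has left a sphere
#'
#' Closed-form radial CDF complement for isotropic 3-D Gaussian displacement
#' with spread `sigma`: the probability that a molecule starting at the
#' center has moved beyond radius `radius` is
#' \eqn{1 - [\mathrm{erf}(u/\sqrt 2) - \sqrt{2/\pi}\, u\, e^{-u^2/2}]} with
#' \eqn{u = R/\sigma}. This function returns the escape probability (the
#' complement of the mass remaining inside the sphere... equivalently, the
#' sphere-integral of the Gaussian equals `1 - escape_probability`).
#'
#' @param sigma Gaussian spread (mm).
#' @param radius sphere radius (mm), default 0.5 (a 1 mm diameter sphere).
#' @return Probability in \[0, 1\] that displacement exceeds `radius`.
#' @export
escape_probability <- function(sigma, radius = 0.5) {
  if (any(sigma <= 0) || any(radius <= 0)) stop("sigma and radius must be > 0")
  u <- radius / sigma
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  inside <- erf(u / sqrt(2)) - sqrt(2 / pi) * u * exp(-u^2 / 2)
  1 - inside
}

#' Solve the sphere-escape equation for the Gaussian spread
#'
#' Finds the spread at which the probability mass remaining inside a sphere
#' of the given radius equals `target_prob`, i.e. solves
#' \eqn{\mathrm{erf}(u/\sqrt 2) - \sqrt{2/\pi}\, u\, e^{-u^2/2} = p} for
#' \eqn{u = R/\sigma} by Brent root-finding, and returns \eqn{2\sigma^2}.
#' At the defaults (R = 0.5 mm, p = 0.50) this gives
#' \eqn{2\sigma^2 \approx 0.21} mm^2, i.e. \eqn{\sigma \approx 0.32} mm.
#'
#' @param radius sphere radius (mm).
#' @param target_prob probability remaining inside the sphere, in (0, 1).
#' @return `2 * sigma^2` in mm^2.
#' @export
solve_sigma_sq <- function(radius = 0.5, target_prob = 0.50) {
  if (radius <= 0) stop("radius must be > 0")
  if (target_prob <= 0 || target_prob >= 1) stop("target_prob must be in (0, 1)")
  g <- function(u) (1 - escape_probability(radius / u, radius)) - target_prob
  # inside-mass is increasing in u = R/sigma; bracket generously
  root <- stats::uniroot(g, interval = c(1e-6, 50), tol = 1e-12)$root
  sigma <- radius / root
  2 * sigma^2
}

#' Flow-proxy constants
#'
#' Bundles the solved Gaussian spread of the sphere-escape problem with the
#' tissue constants of the volume-flow conversion: water content fraction
#' `fw` and density `rho` (kidney tissue density is taken as unity).
#'
#' @param radius escape-sphere radius (mm).
#' @param target_prob probability remaining inside the sphere.
#' @param fw water content fraction of the voxel volume.
#' @param rho tissue density (g/ml).
#' @param sigma optional explicit spread (mm); when supplied it overrides
#'   the numerical solve (e.g. `sigma = 0.32` reproduces the rounded
#'   textbook value).
#' @return Object of class `flow_constants` with elements `radius`,
#'   `target_prob`, `two_sigma_sq` (mm^2), `sigma` (mm), `fw`, `rho`.
#' @examples
#' fc <- flow_constants()
#' round(fc$two_sigma_sq, 2)  # 0.21
#' @export
flow_constants <- function(radius = 0.5, target_prob = 0.50, fw = 1, rho = 1,
                           sigma = NULL) {
  if (fw <= 0 || fw > 1) stop("fw must be in (0, 1]")
  if (rho <= 0) stop("rho must be > 0")
  if (is.null(sigma)) {
    tss <- solve_sigma_sq(radius, target_prob)
    sigma <- sqrt(tss / 2)
  } else {
    if (sigma <= 0) stop("sigma must be > 0")
    tss <- 2 * sigma^2
  }
  structure(list(radius = radius, target_prob = target_prob,
                 two_sigma_sq = tss, sigma = sigma, fw = fw, rho = rho),
            class = "flow_constants")
}

#' Half-residence time of a diffusing component
#'
#' Time for half of the molecules with diffusion coefficient `D` to leave
#' the escape sphere: \eqn{t = \sigma^2 / (2D)} with the solved spread.
#'
#' @param D diffusion coefficient (mm^2/s), > 0.
#' @param constants a [flow_constants()] object.
#' @return Time in seconds (vectorized over `D`).
#' @examples
#' half_residence_time(0.0015, flow_constants(sigma = 0.32))  # ~34.1 s
#' @export
half_residence_time <- function(D, constants = flow_constants()) {
  if (any(D <= 0)) stop("D must be > 0")
  constants$sigma^2 / (2 * D)
}

#' fD flow proxy and absolute volume flow
#'
#' The flow proxy of an isotropic Gaussian diffusion component is the
#' product of its signal fraction and diffusion coefficient,
#' \eqn{fD}; the corresponding absolute volume flow per tissue mass is
#' \eqn{f f_w / (\rho\, t(D))} in ml/(g s), with \eqn{t(D)} the
#' half-residence time. The two are strictly proportional:
#' `flow / fD = 2 fw / (rho * sigma^2)`.
#'
#' @param f signal fraction(s) in \[0, 1\].
#' @param D diffusion coefficient(s) (mm^2/s), >= 0.
#' @param constants a [flow_constants()] object.
#' @return List with `fD` (mm^2/s) and `flow` (ml/(g s)).
#' @export
flow_proxy <- function(f, D, constants = flow_constants()) {
  if (any(f < 0 | f > 1)) stop("f must be in [0, 1]")
  if (any(D < 0)) stop("D must be >= 0")
  fD <- f * D
  flow <- f * constants$fw * 2 * D / (constants$rho * constants$sigma^2)
  list(fD = fD, flow = flow)
}
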