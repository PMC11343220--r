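# Independent oracles used across test files.

# Brute-force projected-gradient solution of the non-negative quadratic
# program min ||A x - b||^2 s.t. x >= 0 (small instances only).
pg_nnls <- function(A, b, max_iter = 3e5, tol = 1e-13) {
  AtA <- crossprod(A)
  Atb <- crossprod(A, b)
  L <- max(eigen(AtA, symmetric = TRUE, only.values = TRUE)$values)
  x <- numeric(ncol(A))
  for (i in seq_len(max_iter)) {
    x_new <- pmax(0, x - (AtA %*% x - Atb) / L)
    if (max(abs(x_new - x)) < tol) { x <- x_new; break }
    x <- x_new
  }
  as.numeric(x)
}

# 3-D quadrature of the isotropic Gaussian over a sphere of radius R:
# probability mass remaining inside the sphere.
gaussian_sphere_mass <- function(sigma, radius = 0.5) {
  stats::integrate(function(r) {
    4 * pi * r^2 * exp(-r^2 / (2 * sigma^2)) / (2 * pi * sigma^2)^(3 / 2)
  }, 0, radius, rel.tol = 1e-12)$value
}

# Table-1 mean parameter sets used repeatedly.
table1_means <- function() {
  list(f = c(0.6, 0.3, 0.1), D = c(0.0015, 0.010, 0.070),
       gamma = c(0.85, 1.0, 1.75))
}

# fits data.frame that echoes a cohort's truth back (perfect fitter)
identity_fits <- function(cohort) {
  tr <- cohort$truth
  out <- data.frame(set_id = unique(tr$set_id), method = "spectral",
                    r2 = 1, n_peaks = 3L, flag = "ok")
  for (cmp in c("tissue", "tubule", "vascular")) {
    rows <- tr[tr$component == cmp, ]
    out[[paste0("f_", cmp)]] <- rows$f
    out[[paste0("D_", cmp)]] <- rows$D_approx
    out[[paste0("fD_", cmp)]] <- rows$fD_truth
  }
  out
}
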