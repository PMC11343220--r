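#' Symmetrized percent difference
#'
#' \eqn{\Delta\% = 200 |x_{in} - x_{out}| / (x_{in} + x_{out})}, the
#' symmetric alternative to mean percent error that avoids exploding when
#' the input alone is small. For non-negative arguments it is bounded by
#' 200 percent (attained when one of the pair is zero); a pair that is
#' zero on both sides scores 0 (an absent component correctly reported
#' absent).
#'
#' @param x_in,x_out non-negative input (truth) and output (fit) values,
#'   vectorized.
#' @return Percent differences in \[0, 200\].
#' @export
percent_difference <- function(x_in, x_out) {
  if (any(x_in < 0) || any(x_out < 0)) stop("inputs must be non-negative")
  out <- numeric(length(x_in))
  nz <- (x_in + x_out) > 0
  out[nz] <- 200 * abs(x_in[nz] - x_out[nz]) / (x_in[nz] + x_out[nz])
  out
}

#' Bland-Altman agreement
#'
#' Mean difference `y - x` and its 95 percent limits
#' (mean +/- 1.96 sd of the differences).
#'
#' @param x,y equal-length paired samples, n >= 2.
#' @return Named numeric vector `c(mean_diff, lo, hi)`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 2) stop("need n >= 2")
  d <- y - x
  m <- mean(d); s <- stats::sd(d)
  c(mean_diff = m, lo = m - 1.96 * s, hi = m + 1.96 * s)
}

#' Ordinary least-squares regression summary
#'
#' Slope, intercept and coefficient of determination (squared Pearson
#' correlation) of `y` on `x`, via [stats::lm()].
#'
#' @param x,y numeric vectors, n >= 3, `var(x) > 0`.
#' @return List with `slope`, `intercept`, `r2`, `n`.
#' @export
linear_regress <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 3) stop("need n >= 3")
  if (stats::var(x) == 0) stop("x has zero variance")
  fit <- stats::lm(y ~ x)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = summary(fit)$r.squared, n = length(x))
}

#' Coefficient of determination of a fitted curve
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} of fitted values against data; used
#' for the voxel-exclusion rule (voxels with R^2 below 0.70 are excluded
#' from map analysis, 0.70 itself retained).
#'
#' @param y observed signal.
#' @param y_fit fitted signal, same length.
#' @return R^2, or `NA` (with a warning) for constant data.
#' @export
goodness_of_fit <- function(y, y_fit) {
  if (length(y) != length(y_fit)) stop("lengths differ")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    warning("constant signal: R^2 undefined")
    return(NA_real_)
  }
  1 - sum((y - y_fit)^2) / ss_tot
}

#' Two-sample Mann-Whitney U test (normal approximation)
#'
#' Tie-corrected normal approximation via [stats::wilcox.test()]; the
#' reported `z` carries the sign of `U - n1 n2 / 2`.
#'
#' @param x,y the two samples.
#' @return List with `U`, `z`, `p`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("empty group")
  wt <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  U <- unname(wt$statistic)
  mu <- length(x) * length(y) / 2
  z <- if (U == mu) 0 else
    sign(U - mu) * stats::qnorm(wt$p.value / 2, lower.tail = FALSE)
  list(U = U, z = z, p = wt$p.value)
}

#' Group comparison tests
#'
#' One-way ANOVA F test across the groups defined by `labels` (via
#' [stats::aov()]), plus the Mann-Whitney U test when there are exactly
#' two groups. The conventional significance threshold is 0.05.
#'
#' @param values numeric outcomes.
#' @param labels group labels, same length.
#' @return List with `anova` (`F`, `df`, `p`) and, for two groups,
#'   `mann_whitney` (see [mann_whitney()]).
#' @export
group_tests <- function(values, labels) {
  labels <- factor(labels)
  if (length(values) != length(labels)) stop("lengths differ")
  if (nlevels(labels) < 2) stop("need at least 2 groups")
  if (any(table(labels) == 0)) stop("empty group")
  s <- summary(stats::aov(values ~ labels))[[1]]
  out <- list(anova = list(F = s$`F value`[1],
                           df = c(s$Df[1], s$Df[2]),
                           p = s$`Pr(>F)`[1]))
  if (nlevels(labels) == 2) {
    sp <- split(values, labels)
    out$mann_whitney <- mann_whitney(sp[[1]], sp[[2]])
  }
  out
}

#' Spearman rank correlation
#'
#' @param x,y paired samples, n >= 3.
#' @return List with `rho` and `p` (asymptotic).
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) < 3) stop("need n >= 3")
  ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  list(rho = unname(ct$estimate), p = ct$p.value)
}

# long view of a fit_cohort() data.frame: one row per set x component
.fits_long <- function(fits) {
  out <- lapply(.components, function(cmp) {
    data.frame(set_id = fits$set_id, component = cmp,
               f_out = fits[[paste0("f_", cmp)]],
               D_out = fits[[paste0("D_", cmp)]],
               fD_out = fits[[paste0("fD_", cmp)]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Agreement of fitted parameters with simulation truth
#'
#' Reproduces the simulation-study agreement analysis for one fitting
#' method: for each of f, D and fD, the pooled linear regression of
#' output against input across all components and sets, the Bland-Altman
#' mean difference with 95 percent limits, and the per-component median
#' percent difference. Input truth is the drawn fraction, the
#' three-direction D_approx, and their product. D and fD are analyzed in
#' 1e-3 mm^2/s. Pairs where a component is absent in both truth and fit
#' (both zero) score a percent difference of 0 and are excluded from the
#' regression and Bland-Altman pools; truth-nonzero/output-zero
#' mismatches (e.g. the biexponential's structurally missing tubule)
#' enter both.
#'
#' @param cohort a [simulate_cohort()] result (supplies the truth table).
#' @param fits the matching [fit_cohort()] data.frame.
#' @return Object of class `agreement_report`: list with elements `f`,
#'   `D`, `fD`, each containing `slope`, `intercept`, `r2`, `ba`,
#'   `delta_pct` (named per component), `per_component` regressions, and
#'   `n`; plus `method` and `mean_r2` (mean fit R^2 over sets).
#' @export
evaluate_cohort <- function(cohort, fits) {
  truth <- cohort$truth
  long <- .fits_long(fits)
  merged <- merge(truth, long, by = c("set_id", "component"))
  merged <- merged[order(merged$set_id, merged$component), ]
  input <- list(f = merged$f, D = merged$D_approx * 1e3,
                fD = merged$fD_truth * 1e3)
  output <- list(f = merged$f_out, D = merged$D_out * 1e3,
                 fD = merged$fD_out * 1e3)
  report <- lapply(names(input), function(q) {
    x <- input[[q]]; y <- output[[q]]
    dp <- percent_difference(x, y)
    delta <- vapply(.components, function(cmp) {
      stats::median(dp[merged$component == cmp])
    }, numeric(1))
    keep <- !(x == 0 & y == 0)
    per_cmp <- lapply(stats::setNames(.components, .components),
                      function(cmp) {
      idx <- keep & merged$component == cmp
      if (sum(idx) >= 3 && stats::var(x[idx]) > 0)
        linear_regress(x[idx], y[idx]) else NULL
    })
    c(linear_regress(x[keep], y[keep]),
      list(ba = bland_altman(x[keep], y[keep]), delta_pct = delta,
           per_component = per_cmp))
  })
  names(report) <- names(input)
  report$method <- fits$method[1]
  report$mean_r2 <- mean(fits$r2, na.rm = TRUE)
  class(report) <- "agreement_report"
  report
}

#' @export
print.agreement_report <- function(x, digits = 3, ...) {
  cat("<agreement_report> method =", x$method,
      " mean fit R2 =", round(x$mean_r2, digits), "\n")
  for (q in c("f", "D", "fD")) {
    r <- x[[q]]
    unit <- if (q == "f") "" else " (1e-3 mm2/s)"
    cat(sprintf("  %-3s y = %.2fx %+0.2f, R2 = %.2f; BA = %.2f (%.1f, %.1f)%s\n",
                q, r$slope, r$intercept, r$r2, r$ba["mean_diff"],
                r$ba["lo"], r$ba["hi"], unit))
    cat(sprintf("      median delta%%: vascular %.1f, tubule %.1f, tissue %.1f\n",
                r$delta_pct["vascular"], r$delta_pct["tubule"],
                r$delta_pct["tissue"]))
  }
  invisible(x)
}
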