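#' In-memory 4-D DWI volume
#'
#' @param data 4-D array (x, y, z, b) of trace-weighted signal.
#' @param bvalues b-values matching the 4th axis, strictly increasing and
#'   starting at 0.
#' @param reference optional `RNifti` image supplying geometry (affine)
#'   for map output.
#' @param normalize divide every voxel's curve by its b=0 value (the
#'   stored `data` of a `dwi_volume` is always normalized; `S0` keeps the
#'   raw b=0 volume).
#' @return Object of class `dwi_volume`.
#' @export
dwi_volume <- function(data, bvalues, reference = NULL, normalize = TRUE) {
  if (length(dim(data)) != 4) stop("data must be a 4-D array")
  if (dim(data)[4] != length(bvalues))
    stop("4th axis length must equal the number of b-values")
  if (is.unsorted(bvalues, strictly = TRUE) || bvalues[1] != 0)
    stop("b-values must be strictly increasing and start at 0")
  S0 <- data[, , , 1, drop = FALSE]
  dim(S0) <- dim(data)[1:3]
  if (normalize) {
    ok <- S0 > 0
    for (k in seq_along(bvalues)) {
      slab <- data[, , , k]
      slab[ok] <- slab[ok] / S0[ok]
      slab[!ok] <- NA_real_
      data[, , , k] <- slab
    }
  }
  structure(list(data = data, bvalues = bvalues, S0 = S0,
                 reference = reference),
            class = "dwi_volume")
}

#' Read a 4-D DWI NIfTI volume with its b-value file
#'
#' @param path NIfTI file (4th dimension = b-values).
#' @param bval_path plain-text b-value file, one value per line (or
#'   whitespace separated).
#' @return A [dwi_volume()] (per-voxel b=0 normalized).
#' @export
read_dwi <- function(path, bval_path) {
  img <- RNifti::readNifti(path)
  bvalues <- scan(bval_path, quiet = TRUE)
  dwi_volume(unclass(img)[, , , , drop = FALSE], bvalues, reference = img)
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$data)
  cat("<dwi_volume>", paste(d[1:3], collapse = " x "), "voxels,",
      d[4], "b-values [", min(x$bvalues), "-", max(x$bvalues), "s/mm^2 ]\n")
  invisible(x)
}

.map_names <- function() {
  c(outer(c("f", "D", "fD"), .components, paste, sep = "_"))
}

#' Voxel-wise multi-component fitting of a DWI volume
#'
#' Applies one fitting method to every in-mask voxel curve and assembles
#' parameter maps: f, D and fD per regime (D and fD in 1e-3 mm^2/s) plus
#' an R^2 map and an exclusion map. Voxels whose fit R^2 falls below
#' `r2_threshold` (default 0.70; the threshold itself is retained) are
#' excluded, as are voxels where spectral analysis retains no peak or an
#' optimizer fails; excluded voxels carry `NA` in the parameter maps and
#' a nonzero code in `exclusion` (1 = low R^2, 2 = no component/failed).
#'
#' @param vol a [dwi_volume()].
#' @param mask logical/0-1 3-D array aligned to `vol` (default: all
#'   voxels with finite curves).
#' @param method `"spectral"`, `"biexp"` or `"triexp"`.
#' @param config,priors,starts method settings as in [fit_cohort()].
#' @param r2_threshold exclusion threshold on fit R^2.
#' @return Object of class `map_set`: list with `maps` (named list of 3-D
#'   arrays), `r2`, `exclusion`, `mask`, `method`, `bvalues`, `reference`.
#' @export
fit_volume <- function(vol, mask = NULL,
                       method = c("spectral", "biexp", "triexp"),
                       config = spectral_config(), priors = biexp_priors(),
                       starts = triexp_start(), r2_threshold = 0.70) {
  method <- match.arg(method)
  d <- dim(vol$data)[1:3]
  if (is.null(mask)) mask <- array(TRUE, d)
  if (!all(dim(mask) == d)) stop("mask is not aligned to the volume")
  mask <- array(as.logical(mask), d)
  maps <- stats::setNames(
    lapply(.map_names(), function(n) array(NA_real_, d)), .map_names())
  r2map <- array(NA_real_, d)
  excl <- array(0L, d)
  idx <- which(mask)
  if (length(idx) == 0) {
    warning("mask contains no voxels")
  }
  pre <- switch(method,
    spectral = build_dictionary(vol$bvalues, config),
    biexp = biexp_grid(vol$bvalues, priors),
    triexp = NULL)
  nvox <- prod(d)
  for (v in idx) {
    sig <- vol$data[v + nvox * (seq_along(vol$bvalues) - 1L)]
    if (anyNA(sig)) { excl[v] <- 2L; next }
    curve <- decay_curve(vol$bvalues, sig)
    fit <- tryCatch(switch(method,
      spectral = spectral_fit_voxel(curve, config, dictionary = pre),
      biexp = fit_biexponential_bayesian(curve, priors, grid = pre),
      triexp = fit_triexponential_ls(curve, starts)),
      error = function(e) NULL)
    if (is.null(fit) || fit$flag != "ok") { excl[v] <- 2L; next }
    r2map[v] <- fit$r2
    if (!is.na(fit$r2) && fit$r2 < r2_threshold) { excl[v] <- 1L; next }
    for (cmp in .components) {
      maps[[paste0("f_", cmp)]][v] <- fit$f[cmp]
      maps[[paste0("D_", cmp)]][v] <- fit$D[cmp] * 1e3
      maps[[paste0("fD_", cmp)]][v] <- fit$fD[cmp] * 1e3
    }
  }
  structure(list(maps = maps, r2 = r2map, exclusion = excl, mask = mask,
                 method = method, bvalues = vol$bvalues,
                 reference = vol$reference),
            class = "map_set")
}

#' @export
print.map_set <- function(x, ...) {
  cat("<map_set> method =", x$method, " grid =",
      paste(dim(x$r2), collapse = " x "), "\n")
  cat("  in-mask:", sum(x$mask), " excluded:",
      sum(x$exclusion > 0 & x$mask), "\n")
  invisible(x)
}

#' ROI summaries of a map set
#'
#' Per-ROI and pooled means of every parameter map over retained
#' (non-excluded) voxels. Pooling is voxel-weighted: the pooled row
#' averages all retained voxels across the ROIs, not the ROI means.
#'
#' @param maps a [fit_volume()] map set.
#' @param roi_masks named list of logical/0-1 3-D masks aligned to the
#'   maps.
#' @return data.frame: one row per ROI plus a `pooled` row; columns
#'   `roi`, `n_voxels`, `n_excluded`, and the mean of each map
#'   (`NA`-flagged when every voxel of the ROI is excluded).
#' @export
roi_summary <- function(maps, roi_masks) {
  if (is.null(names(roi_masks)) || any(names(roi_masks) == ""))
    stop("roi_masks must be a named list")
  d <- dim(maps$r2)
  rows <- lapply(names(roi_masks), function(nm) {
    m <- array(as.logical(roi_masks[[nm]]), d)
    if (!all(dim(roi_masks[[nm]]) == d)) stop("ROI mask not aligned")
    keep <- m & maps$exclusion == 0 & maps$mask
    out <- data.frame(roi = nm, n_voxels = sum(m),
                      n_excluded = sum(m & maps$mask & maps$exclusion > 0),
                      stringsAsFactors = FALSE)
    for (p in names(maps$maps))
      out[[p]] <- if (any(keep)) mean(maps$maps[[p]][keep]) else NA_real_
    out$r2 <- if (any(keep)) mean(maps$r2[keep]) else NA_real_
    out
  })
  pooled <- Reduce(`|`, lapply(roi_masks, function(m) array(as.logical(m), d)))
  rows <- c(rows, list({
    keep <- pooled & maps$exclusion == 0 & maps$mask
    out <- data.frame(roi = "pooled", n_voxels = sum(pooled),
                      n_excluded = sum(pooled & maps$mask & maps$exclusion > 0),
                      stringsAsFactors = FALSE)
    for (p in names(maps$maps))
      out[[p]] <- if (any(keep)) mean(maps$maps[[p]][keep]) else NA_real_
    out$r2 <- if (any(keep)) mean(maps$r2[keep]) else NA_real_
    out
  }))
  do.call(rbind, rows)
}

#' Write a map set as NIfTI files
#'
#' One file per parameter map plus the R^2 and exclusion maps, inheriting
#' geometry from the source volume when available.
#'
#' @param maps a [fit_volume()] map set.
#' @param dir output directory (created if absent).
#' @return Invisibly, the written file paths.
#' @export
write_map_set <- function(maps, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  all_maps <- c(maps$maps, list(r2 = maps$r2,
                                exclusion = maps$exclusion + 0))
  paths <- vapply(names(all_maps), function(nm) {
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    img <- all_maps[[nm]]
    if (!is.null(maps$reference))
      img <- RNifti::asNifti(img, reference = maps$reference)
    RNifti::writeNifti(img, p)
    p
  }, character(1))
  invisible(paths)
}

#' Default two-region phantom layout
#'
#' A small synthetic stand-in for a cortical slab: a "cortex" region with
#' the three literature-mean components and a "vessel" region with only
#' tissue and vascular components (no tubular flow), mirroring the
#' simulation's two-component condition.
#'
#' @param dim 3-D grid size.
#' @return List of region specifications consumed by [generate_phantom()].
#' @export
default_phantom_layout <- function(dim = c(12, 12, 2)) {
  half <- seq_len(floor(dim[1] / 2))
  cortex <- array(FALSE, dim); cortex[half, , ] <- TRUE
  vessel <- array(FALSE, dim); vessel[setdiff(seq_len(dim[1]), half), , ] <- TRUE
  means <- cortex_distributions()
  list(
    cortex = list(mask = cortex, f = means$f_mean, D = means$D_mean,
                  gamma = means$gamma_mean),
    vessel = list(mask = vessel,
                  f = means$f_mean[c(1, 3)] / sum(means$f_mean[c(1, 3)]),
                  D = means$D_mean[c(1, 3)],
                  gamma = means$gamma_mean[c(1, 3)]))
}

#' Generate a synthetic DWI phantom volume with ground truth
#'
#' Builds a 4-D volume by evaluating [anomalous_signal()] region-wise
#' (fractions are normalized within each region) and adding Rician noise,
#' together with ground-truth f/D/fD maps on the regime grid (regions'
#' components are assigned to regimes by their D).
#'
#' @param layout named list of regions, each a list with `mask` (3-D
#'   logical array), `f`, `D` (mm^2/s) and `gamma` vectors; see
#'   [default_phantom_layout()].
#' @param bvalues acquisition b-values.
#' @param noise_sigma Rician noise scale (0.02 default, SNR 50; 0 for a
#'   noiseless phantom).
#' @return List with `volume` (a [dwi_volume()]) and `truth` (named list
#'   of 3-D arrays: f/D/fD per regime, D and fD in 1e-3 mm^2/s).
#' @export
generate_phantom <- function(layout = default_phantom_layout(),
                             bvalues = default_bvalues(),
                             noise_sigma = 0.02) {
  d <- dim(layout[[1]]$mask)
  nb <- length(bvalues)
  data <- array(0, c(d, nb))
  truth <- stats::setNames(
    lapply(.map_names(), function(n) array(0, d)), .map_names())
  nvox <- prod(d)
  for (rg in layout) {
    f <- rg$f / sum(rg$f)
    clean <- anomalous_signal(f, rg$D, rg$gamma, bvalues)$signal
    regime <- cut(rg$D, breaks = c(-Inf, .regime_bounds[["tubule_lo"]],
                                   .regime_bounds[["vascular_lo"]], Inf),
                  labels = .components)
    idx <- which(rg$mask)
    for (k in seq_len(nb)) {
      sig <- if (noise_sigma > 0)
        stats::rnorm(length(idx), sqrt(clean[k]^2 + noise_sigma^2),
                     noise_sigma)
      else rep(clean[k], length(idx))
      data[idx + nvox * (k - 1L)] <- sig
    }
    for (i in seq_along(f)) {
      cmp <- as.character(regime[i])
      truth[[paste0("f_", cmp)]][idx] <-
        truth[[paste0("f_", cmp)]][idx] + f[i]
      truth[[paste0("D_", cmp)]][idx] <- rg$D[i] * 1e3
      truth[[paste0("fD_", cmp)]][idx] <-
        truth[[paste0("fD_", cmp)]][idx] + f[i] * rg$D[i] * 1e3
    }
  }
  list(volume = dwi_volume(data, bvalues, normalize = FALSE), truth = truth)
}
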