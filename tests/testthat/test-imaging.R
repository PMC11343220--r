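small_layout <- function() default_phantom_layout(dim = c(6, 4, 1))

test_that("volume container validates geometry and normalizes by b = 0", {
  b <- default_bvalues()
  arr <- array(0, c(2, 2, 1, 9))
  for (k in 1:9) arr[, , , k] <- 100 * exp(-b[k] * 0.002)
  vol <- dwi_volume(arr, b)
  expect_equal(vol$data[1, 1, 1, 1], 1)
  expect_equal(vol$S0[2, 2, 1], 100)
  expect_equal(vol$data[1, 1, 1, 9], exp(-800 * 0.002))
  expect_error(dwi_volume(arr, b[-1]), "b-values")
  expect_error(dwi_volume(arr, b + 5), "start at 0")
  expect_error(dwi_volume(array(0, c(2, 2, 9)), b), "4-D")
})

test_that("NIfTI round trip preserves the volume and b-values", {
  b <- default_bvalues()
  set.seed(31)
  ph <- generate_phantom(small_layout(), noise_sigma = 0)
  raw <- ph$volume$data * 250  # un-normalized intensities
  dir <- withr::local_tempdir()
  nii <- file.path(dir, "dwi.nii.gz")
  bval <- file.path(dir, "dwi.bval")
  RNifti::writeNifti(RNifti::asNifti(raw), nii)
  writeLines(as.character(b), bval)
  vol <- read_dwi(nii, bval)
  expect_equal(vol$bvalues, b)
  expect_equal(dim(vol$data), dim(raw))
  # b = 0 normalization restores the unit-signal phantom
  expect_equal(vol$data[3, 2, 1, ], ph$volume$data[3, 2, 1, ],
               tolerance = 1e-6)
  expect_error(read_dwi(nii, {
    writeLines(as.character(b[-1]), bval); bval
  }), "b-values")
})

test_that("phantom generation is seeded and regionally faithful", {
  set.seed(32)
  a <- generate_phantom(small_layout())
  set.seed(32)
  b <- generate_phantom(small_layout())
  expect_identical(a$volume$data, b$volume$data)
  # noiseless phantom signal matches the generating model exactly
  ph <- generate_phantom(small_layout(), noise_sigma = 0)
  m <- table1_means()
  expect_equal(ph$volume$data[1, 1, 1, ],
               anomalous_signal(m$f, m$D, m$gamma, default_bvalues())$signal)
  # truth maps: cortex half has three components, vessel half no tubule
  expect_equal(ph$truth$f_tubule[1, 1, 1], 0.3)
  expect_equal(ph$truth$f_tubule[6, 1, 1], 0)
  expect_equal(ph$truth$fD_vascular[6, 1, 1],
               (0.1 / 0.7) * 70, tolerance = 1e-6)
})

test_that("voxel-wise fitting matches the per-curve fitter and flags exclusions", {
  ph <- generate_phantom(small_layout(), noise_sigma = 0)
  maps <- fit_volume(ph$volume, method = "spectral")
  expect_equal(sum(maps$exclusion), 0)
  # pipeline result identical to fitting the voxel curve directly
  curve <- decay_curve(default_bvalues(), ph$volume$data[2, 3, 1, ])
  direct <- spectral_fit_voxel(curve)
  expect_equal(maps$maps$f_tissue[2, 3, 1], unname(direct$f["tissue"]))
  expect_equal(maps$maps$fD_vascular[2, 3, 1],
               unname(direct$fD["vascular"]) * 1e3)
  # noiseless phantom recovered near truth; vessel region has no tubule
  expect_equal(maps$maps$f_tubule[6, 2, 1], 0)
  expect_lt(abs(maps$maps$f_tissue[1, 1, 1] - 0.6), 0.15)
  # fraction maps live in [0, 1] and sum to 1 at retained voxels
  fsum <- maps$maps$f_tissue + maps$maps$f_tubule + maps$maps$f_vascular
  expect_equal(range(fsum), c(1, 1), tolerance = 1e-9)
  # a strongly non-monotone voxel cannot be explained by decaying
  # exponentials and is excluded by the R^2 rule
  noisy <- ph$volume
  noisy$data[1, 4, 1, ] <- c(1, 0.2, 0.9, 0.1, 0.8, 0.05, 0.7, 0.3, 0.6)
  maps2 <- fit_volume(noisy, method = "spectral")
  expect_true(maps2$exclusion[1, 4, 1] > 0)
  expect_true(is.na(maps2$maps$f_tissue[1, 4, 1]))
})

test_that("empty masks warn and ROI summaries pool voxel-weighted", {
  ph <- generate_phantom(small_layout(), noise_sigma = 0)
  expect_warning(fit_volume(ph$volume, mask = array(FALSE, c(6, 4, 1)),
                            method = "spectral"), "no voxels")
  maps <- fit_volume(ph$volume, method = "spectral")
  cortex <- array(FALSE, c(6, 4, 1)); cortex[1:3, , ] <- TRUE
  vessel <- array(FALSE, c(6, 4, 1)); vessel[4:6, , ] <- TRUE
  tab <- roi_summary(maps, list(cortex = cortex, vessel = vessel))
  expect_equal(tab$roi, c("cortex", "vessel", "pooled"))
  # uniform region: ROI mean equals the voxel value
  expect_equal(tab$f_tubule[tab$roi == "cortex"],
               maps$maps$f_tubule[1, 1, 1])
  # pooled row is voxel-weighted over both ROIs
  expect_equal(tab$n_voxels[3], 24)
  expect_equal(tab$f_tubule[3],
               mean(c(maps$maps$f_tubule[1:3, , 1],
                      maps$maps$f_tubule[4:6, , 1])))
})

test_that("map sets serialize to NIfTI", {
  ph <- generate_phantom(small_layout(), noise_sigma = 0)
  maps <- fit_volume(ph$volume, method = "triexp")
  dir <- withr::local_tempdir()
  paths <- write_map_set(maps, dir)
  expect_true(all(file.exists(paths)))
  back <- RNifti::readNifti(paths[["fD_tissue"]])
  expect_equal(dim(back)[1:2], c(6, 4))  # trailing singleton may be dropped
})
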