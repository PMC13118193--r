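const_volume <- function(S0 = 100, Dapp = 1.1, K = 1.0, shape = c(3, 3, 2)) {
  sch <- paper_scheme()
  sig <- dki_signal(sch$bvalues, S0, Dapp, K)
  volume_set(array(rep(sig, each = prod(shape)), c(shape, length(sch$bvalues))), sch)
}

test_that("maps from a constant noiseless field are constant at ground truth", {
  vol <- const_volume(S0 = 100, Dapp = 1.1, K = 1.0)
  maps <- fit_maps(vol)
  expect_true(all(maps$Dapp$valid) && all(maps$ADC$valid))
  expect_equal(range(maps$Dapp$data), c(1.1, 1.1), tolerance = 1e-9)
  expect_equal(range(maps$K$data), c(1, 1), tolerance = 1e-8)
  expect_equal(range(maps$S0$data), c(100, 100), tolerance = 1e-7)
  expect_true(all(maps$ADC$data < 1.1))  # K > 0 pulls the ME fit down
  expect_true(all(maps$n_dropped == 0))
})

test_that("an all-zero volume yields only invalid voxels", {
  sch <- paper_scheme()
  vol <- volume_set(array(0, c(2, 2, 2, 6)), sch)
  maps <- fit_maps(vol)
  expect_false(any(maps$Dapp$valid))
  expect_false(any(maps$ADC$valid))
  expect_true(all(is.na(maps$K$data)))
  expect_true(all(maps$n_dropped == 6))
})

test_that("voxelwise failures are isolated and mixed voxels use the fallback path", {
  vol <- const_volume()
  vol$data[1, 1, 1, ] <- 0                 # dead voxel
  vol$data[2, 1, 1, 3] <- -1               # one corrupt measurement
  maps <- fit_maps(vol)
  expect_false(maps$Dapp$valid[1, 1, 1])
  expect_true(maps$Dapp$valid[2, 1, 1])
  expect_equal(maps$Dapp$data[2, 1, 1], 1.1, tolerance = 1e-8)
  expect_equal(maps$n_dropped[2, 1, 1], 1)
  expect_true(all(maps$Dapp$valid[3, , ]))
})

test_that("rescaling the volume changes only the S0 map", {
  vol <- const_volume(S0 = 50, Dapp = 0.9, K = 0.8)
  a <- fit_maps(vol)
  vol2 <- vol; vol2$data <- vol2$data * 3.5
  b <- fit_maps(vol2)
  expect_equal(b$Dapp$data, a$Dapp$data, tolerance = 1e-10)
  expect_equal(b$K$data, a$K$data, tolerance = 1e-9)
  expect_equal(b$ADC$data, a$ADC$data, tolerance = 1e-10)
  expect_equal(b$S0$data, 3.5 * a$S0$data, tolerance = 1e-9)
})

test_that("ROI statistics average valid voxels only", {
  m <- parameter_map <- structure(list(
    name = "K", data = array(0.8, c(4, 4, 2)), valid = array(TRUE, c(4, 4, 2))),
    class = "parameter_map")
  roi <- roi_mask(rbind(c(1, 1, 1), c(2, 1, 1)))
  expect_equal(extract_roi_stats(m, roi)$mean, 0.8)
  m$data[2, 1, 1] <- 1.0
  expect_equal(extract_roi_stats(m, roi)$mean, 0.9)
  m$valid[2, 1, 1] <- FALSE               # invalid voxel drops out, n shrinks
  st <- extract_roi_stats(m, roi)
  expect_equal(st$mean, 0.8)
  expect_equal(st$n, 1)
  expect_equal(st$n_total, 2)
  m$valid[, , ] <- FALSE
  expect_error(extract_roi_stats(m, roi), "no valid voxels")
  expect_error(extract_roi_stats(m, roi_mask(rbind(c(9, 1, 1)))), "outside")
})

test_that("ROI tables use one common voxel set across all maps", {
  vol <- const_volume(shape = c(4, 4, 2))
  maps <- fit_maps(vol)
  maps$ADC$valid[1, 1, 1] <- FALSE        # valid for DKI but not for ADC
  roi <- roi_mask(rbind(c(1, 1, 1), c(2, 1, 1), c(3, 1, 1)))
  tab <- roi_stats_table(maps, roi)
  expect_setequal(tab$parameter, c("ADC", "Dapp", "K"))
  expect_true(all(tab$n_voxels == 2))     # the invalid voxel is excluded everywhere
})

test_that("DWI volumes, maps and ROI labels round-trip through NIfTI", {
  dir <- withr::local_tempdir()
  vol <- const_volume(shape = c(4, 3, 2))
  nii <- file.path(dir, "dwi.nii.gz"); bval <- file.path(dir, "dwi.bval")
  write_dwi(vol, nii, bval)
  back <- read_dwi(nii, bval, n_averages = 5)
  expect_equal(back$data, unname(vol$data), tolerance = 1e-6)
  expect_equal(back$scheme$bvalues, vol$scheme$bvalues)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-5)

  files <- write_maps(fit_maps(vol), file.path(dir, "maps"))
  expect_true(all(file.exists(file.path(dir, "maps",
    c("adc.nii.gz", "dapp.nii.gz", "k.nii.gz", "s0.nii.gz", "valid.nii.gz")))))

  labels <- array(0L, c(4, 3, 2)); labels[1:2, 1, 1] <- 1L; labels[4, 3, 2] <- 2L
  lf <- file.path(dir, "roi.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(labels), lf)
  rois <- read_roi_masks(lf)
  expect_length(rois, 2)
  expect_equal(nrow(rois$lesion_1$voxels), 2)
  expect_equal(unname(rois$lesion_2$voxels[1, ]), c(4, 3, 2))
})
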