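# Hand-made volumes on a known voxel grid.
toy_volume <- function(values, nx = 8, ny = 8, nz = 1, voxel = 1) {
  vg <- voxel_grid(nx, ny, nz, voxel)
  structure(array(values, dim = c(nx, ny, nz)), voxel_grid = vg,
            class = c("blob_volume", "array"))
}

test_that("cv follows the sample-standard-deviation definition", {
  vol <- toy_volume(5)
  roi <- roi_spec(c(0, 0, 0), c(4, 4, 1))
  expect_equal(cv(vol, roi), 0)            # constant ROI
  # ROI holding exactly the values {2, 4}: cv = sqrt(2)/3
  vol2 <- toy_volume(0)
  vol2[4, 4, 1] <- 2; vol2[5, 4, 1] <- 4
  roi2 <- roi_spec(c(0, -0.5, 0), c(2, 1, 1))
  expect_equal(sort(blobpet:::roi_values(vol2, roi2)), c(2, 4))
  expect_equal(cv(vol2, roi2), sqrt(2) / 3, tolerance = 1e-12)
  # scale invariance under positive rescaling
  vol3 <- toy_volume(runif(64, 1, 2))
  expect_equal(cv(vol3, roi), cv(toy_volume(as.numeric(vol3) * 7.3), roi),
               tolerance = 1e-12)
  expect_error(cv(toy_volume(0), roi), "zero-mean")
})

test_that("cnr matches its two-ROI definition and is antisymmetric", {
  vol <- toy_volume(0)
  vol[3, 3:5, 1] <- c(2, 3, 4)    # mean 3, sd 1
  vol[6, 3:5, 1] <- c(0, 1, 2)    # mean 1, sd 1
  roi_s <- roi_spec(c(-1.5, 0, 0), c(1, 3, 1), "signal")
  roi_b <- roi_spec(c(1.5, 0, 0), c(1, 3, 1), "background")
  expect_equal(sort(blobpet:::roi_values(vol, roi_s)), c(2, 3, 4))
  expect_equal(cnr(vol, roi_s, roi_b), 2, tolerance = 1e-12)
  expect_equal(cnr(vol, roi_b, roi_s), -2, tolerance = 1e-12)
  expect_equal(cnr(vol, roi_s, roi_s), 0)
  expect_error(cnr(toy_volume(1), roi_s, roi_b), "constant")
})

test_that("cc is a Pearson correlation over whole volumes", {
  set.seed(19)
  a <- toy_volume(runif(64))
  expect_equal(cc(a, a), 1, tolerance = 1e-12)
  inv <- toy_volume(2 * mean(a) - as.numeric(a))
  expect_equal(cc(a, inv), -1, tolerance = 1e-12)
  # positive affine maps leave cc unchanged
  expect_equal(cc(a, toy_volume(3 + 2 * as.numeric(a))), 1, tolerance = 1e-12)
  # two independent pseudo-random volumes decorrelate as 1/sqrt(n)
  set.seed(101); u <- array(runif(1e5), dim = c(100, 100, 10))
  set.seed(202); v <- array(runif(1e5), dim = c(100, 100, 10))
  expect_lt(abs(cc(u, v)), 0.02)
  expect_error(cc(a, toy_volume(1)), "constant")
  expect_error(cc(a, array(1, dim = c(2, 2, 2))), "shape")
})

test_that("metrics are invariant under joint spatial translation", {
  set.seed(23)
  base <- array(runif(6 * 6), dim = c(6, 6, 1))
  vol <- toy_volume(0, nx = 10, ny = 10)
  vol[1:6, 1:6, 1] <- base
  shifted <- toy_volume(0, nx = 10, ny = 10)
  shifted[4:9, 4:9, 1] <- base
  roi_a <- roi_spec(c(-3, -3, 0), c(3, 3, 1))
  roi_b <- roi_spec(c(-1, -1, 0), c(3, 3, 1))
  d <- c(3, 3, 0)
  expect_equal(cv(vol, roi_a),
               cv(shifted, roi_spec(roi_a$centre + d, roi_a$dim)), tolerance = 1e-12)
  expect_equal(cnr(vol, roi_a, roi_b),
               cnr(shifted, roi_spec(roi_a$centre + d, roi_a$dim),
                   roi_spec(roi_b$centre + d, roi_b$dim)), tolerance = 1e-12)
  expect_equal(cc(vol, vol^2), cc(shifted, shifted^2), tolerance = 1e-12)
})

test_that("profiles interpolate trilinearly through the volume", {
  vol <- toy_volume(2, nx = 10, ny = 10, nz = 1)
  pr <- extract_profile(vol, c(-4, 0, 0), c(4, 0, 0), n = 33)
  expect_true(all(pr$value == 2))
  expect_equal(attr(pr, "spacing"), 8 / 32)
  # a profile along a voxel row reproduces the voxel values at centres
  vol2 <- toy_volume(seq_len(100), nx = 10, ny = 10)
  ax <- blobpet:::voxel_axes(attr(vol2, "voxel_grid"))
  pr2 <- extract_profile(vol2, c(ax$x[2], ax$y[4], 0), c(ax$x[9], ax$y[4], 0), n = 8)
  expect_equal(pr2$value, vol2[2:9, 4, 1], tolerance = 1e-12)
  # a linear ramp is reproduced exactly between arbitrary points
  ramp <- toy_volume(rep(seq_len(10), times = 10), nx = 10, ny = 10)
  pr3 <- extract_profile(ramp, c(-3.7, -2.1, 0), c(3.2, 1.4, 0), n = 57)
  fitted <- lm(value ~ position, data = pr3)
  expect_lt(max(abs(residuals(fitted))), 1e-9)
  expect_error(extract_profile(vol, c(-20, 0, 0), c(4, 0, 0)), "interior")
})

test_that("fwhm recovers analytic widths to within a sample spacing", {
  gauss_profile <- function(sigma, spacing, baseline = 0, half_range = 6) {
    x <- seq(-half_range, half_range, by = spacing)
    tibble::tibble(position = x, value = baseline + exp(-x^2 / (2 * sigma^2)))
  }
  expect_equal(fwhm(gauss_profile(1, 0.05)), 2.3548, tolerance = 0.01)
  # triangle of base 2w has FWHM w
  x <- seq(-2, 2, by = 0.01)
  tri <- tibble::tibble(position = x, value = pmax(0, 1 - abs(x) / 1.5))
  expect_equal(fwhm(tri), 1.5, tolerance = 1e-9)
  # a constant pedestal is removed by the min baseline
  expect_equal(fwhm(gauss_profile(1, 0.05, baseline = 0.5)),
               fwhm(gauss_profile(1, 0.05)), tolerance = 0.01)
  # accuracy within one sample spacing across widths and spacings
  for (sigma in c(0.5, 1, 2)) {
    for (spacing in c(0.02, 0.1, 0.3)) {
      est <- fwhm(gauss_profile(sigma, spacing, half_range = 8 * sigma))
      expect_lt(abs(est - 2 * sqrt(2 * log(2)) * sigma), spacing)
    }
  }
  mono <- tibble::tibble(position = 0:10, value = 0:10)
  expect_error(fwhm(mono), "monotone|interior")
  flat <- tibble::tibble(position = 0:10, value = c(0, rep(1, 10)))
  expect_error(fwhm(flat), "peak|flank|monotone")
})

test_that("fom_report aggregates ROI stats, CNR pairs and CC", {
  set.seed(31)
  vol <- toy_volume(runif(64, 1, 2))
  rois <- list(roi_spec(c(-1.5, 0, 0), c(3, 6, 1), "left"),
               roi_spec(c(1.5, 0, 0), c(3, 6, 1), "right"))
  rep <- fom_report(vol, rois, reference = vol)
  expect_equal(rep$roi$label, c("left", "right"))
  expect_equal(nrow(rep$cnr), 1L)
  expect_equal(rep$cc, 1, tolerance = 1e-12)
  expect_s3_class(autoplot(extract_profile(vol, c(-3, 0, 0), c(3, 0, 0))), "ggplot")
})
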