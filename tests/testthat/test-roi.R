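test_that("insert ROI mask area matches the brute-force pixel count", {
  # 28.5 mm insert, roi_fraction 0.7, 1 mm pixels
  spec <- phantom_spec(c(100, 100),
                       list(insert_spec(c(0, 0), 28.5, 5),
                            insert_spec(c(60, 0), 28.5, 10)))
  vol <- simulate_phantom_image(spec, test_acq(), flat_contrast(10), NULL,
                                grid = default_grid(spec, 1, n_slices = 1L))
  rois <- locate_rois(vol, spec, roi_fraction = 0.7)
  area <- sum(rois$insert_masks[[1]])
  r <- 0.7 * 28.5 / 2
  # independent brute force: count pixel centres inside the disk
  d <- dim(vol$voxels)
  xs <- (seq_len(d[2]) - (d[2] + 1) / 2) * 1
  ys <- (seq_len(d[1]) - (d[1] + 1) / 2) * 1
  brute <- sum(outer(ys^2, xs^2, `+`) <= r^2)
  expect_identical(area, brute)
  # and within one pixel ring of the continuous area
  expect_lt(abs(area - pi * r^2), 2 * pi * r + 1)
})

test_that("auto detection agrees with geometry mode within one pixel", {
  spec <- test_phantom(concs = c(2, 5, 10, 15), radius_mm = 80, ring_r_mm = 50,
                       insert_d_mm = 20)
  vol <- simulate_phantom_image(spec, test_acq(), flat_contrast(25), NULL)
  g <- locate_rois(vol, spec, mode = "geometry")
  a <- locate_rois(vol, spec, mode = "auto")
  expect_lt(max(abs(g$centers - a$centers)), vol$pixel_spacing_mm)
  # and still within a pixel in the presence of noise
  voln <- simulate_phantom_image(spec, test_acq(), flat_contrast(25),
                                 flat_noise(8), seed = 3)
  an <- locate_rois(voln, spec, mode = "auto")
  expect_lt(max(abs(g$centers - an$centers)), 1.5 * voln$pixel_spacing_mm)
})

test_that("auto detection reports missing inserts by name", {
  # a zero-concentration insert produces no high-HU component
  spec <- test_phantom(concs = c(0, 10), radius_mm = 70)
  vol <- simulate_phantom_image(spec, test_acq(), flat_contrast(20), NULL)
  expect_error(locate_rois(vol, spec, mode = "auto"), "0mgml|component")
})

test_that("background ROI placement collisions are configuration errors", {
  spec <- test_phantom(concs = c(2, 5, 10, 15), radius_mm = 80, ring_r_mm = 50)
  vol <- simulate_phantom_image(spec, test_acq(), flat_contrast(10), NULL)
  # background angle aimed straight at an insert
  expect_error(locate_rois(vol, spec, bg_angles_deg = c(0, 90, 180, 270)),
               "overlaps insert")
  # background radius outside the body
  expect_error(locate_rois(vol, spec, bg_radius_mm = 79), "outside the phantom")
  expect_error(locate_rois(vol, spec, roi_fraction = 0.95), "roi_fraction")
})

test_that("roi_stats reproduces hand-computed mean and sample SD", {
  vox <- array(50, dim = c(4, 4, 3))
  vol <- ct_volume(vox, 1, 1)
  mask <- matrix(TRUE, 4, 4)
  st <- roi_stats(vol, mask, 1)
  expect_equal(st$mean_hu, 50)
  expect_equal(st$sd_hu, 0)
  expect_equal(st$n_voxels, 48L)

  vox2 <- array(0, dim = c(2, 2, 1))
  vox2[, , 1] <- c(10, 10, 20, 20)
  vol2 <- ct_volume(vox2, 1, 1)
  st2 <- roi_stats(vol2, matrix(TRUE, 2, 2), 1)
  expect_equal(st2$mean_hu, 15)
  expect_equal(st2$sd_hu, 5.7735026918962573, tolerance = 1e-12)

  expect_error(roi_stats(vol, mask, 0), "0 slices")
  expect_error(roi_stats(vol, matrix(FALSE, 4, 4), 1), "empty")
})

test_that("central-fraction slice policy pools the middle slices", {
  vox <- array(0, dim = c(2, 2, 5))
  for (k in 1:5) vox[, , k] <- k
  vol <- ct_volume(vox, 1, 1)
  st <- roi_stats(vol, matrix(TRUE, 2, 2), 0.6)  # slices 2..4
  expect_equal(st$mean_hu, 3)
  expect_equal(st$n_voxels, 12L)
})

test_that("CNR follows its definition, sign convention and error paths", {
  mk <- function(mean, sd, n = 100) structure(
    list(mean_hu = mean, sd_hu = sd, n_voxels = n, label = "x"),
    class = "roi_stats")
  expect_equal(compute_cnr(mk(100, 5), mk(100, 10)), 0)
  expect_equal(compute_cnr(mk(100, 5), mk(50, 10)), 5)
  # signed: negative-contrast insert yields negative CNR
  expect_equal(compute_cnr(mk(40, 5), mk(50, 10)), -1)
  expect_error(compute_cnr(mk(100, 5), mk(50, 0)), "degenerate")
})

test_that("measured CNR matches its expectation kappa*c/sigma", {
  # kappa = 26, c = 10, sigma = 13 -> expected CNR 20
  spec <- test_phantom(concs = c(2, 10), radius_mm = 80, ring_r_mm = 50,
                       insert_d_mm = 24)
  vol <- simulate_phantom_image(spec, test_acq(), flat_contrast(26),
                                flat_noise(13), seed = 17)
  m <- measure_phantom_cnr(vol, spec, test_acq())
  row <- m[m$concentration == 10, ]
  # SE of measured CNR: insert-mean noise plus background-SD estimation noise
  se <- sqrt(1 / row$insert_n + 20^2 / (2 * (row$bg_n - 1)))
  expect_lt(abs(row$cnr - 20), 3 * se)
})

test_that("CNR is invariant under a constant HU offset", {
  spec <- test_phantom(concs = c(2, 5, 10), radius_mm = 80, ring_r_mm = 50)
  vol <- simulate_phantom_image(spec, test_acq(), flat_contrast(20),
                                flat_noise(10), seed = 23)
  m1 <- measure_phantom_cnr(vol, spec, test_acq())
  vol2 <- vol
  vol2$voxels <- vol$voxels + 100
  m2 <- measure_phantom_cnr(vol2, spec, test_acq())
  expect_equal(m2$cnr, m1$cnr, tolerance = 1e-12)
})

test_that("CNR scales as 1/s when the noise SD is scaled by s", {
  spec <- test_phantom(concs = c(2, 5, 10), radius_mm = 80, ring_r_mm = 50)
  cnr_at <- function(sigma) {
    # same seed: the underlying Gaussian field scales exactly with sigma
    vol <- simulate_phantom_image(spec, test_acq(), flat_contrast(20),
                                  flat_noise(sigma), seed = 29)
    mean(measure_phantom_cnr(vol, spec, test_acq())$cnr)
  }
  ratio <- cnr_at(5) / cnr_at(10)
  expect_equal(ratio, 2, tolerance = 0.05)
})

test_that("noise-free CNR with injected nominal sigma is exactly kappa*c/sigma", {
  spec <- test_phantom(concs = c(2, 5, 10, 15), radius_mm = 80, ring_r_mm = 50)
  vol <- simulate_phantom_image(spec, test_acq(), flat_contrast(30), NULL)
  rois <- locate_rois(vol, spec)
  bg <- roi_stats(vol, rois$background_mask, 0.6)
  sigma_nominal <- 12
  for (ins in spec$inserts) {
    st <- roi_stats(vol, rois$insert_masks[[ins$label]], 0.6)
    cnr <- (st$mean_hu - bg$mean_hu) / sigma_nominal
    expect_equal(cnr, 30 * ins$concentration / sigma_nominal, tolerance = 1e-12)
  }
})
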