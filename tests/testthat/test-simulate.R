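test_that("noise-free generation is exact: air, background and inserts", {
  spec <- test_phantom(concs = c(2, 5), background_hu = 0)
  vol <- simulate_phantom_image(spec, test_acq(60), flat_contrast(10),
                                noise = NULL, seed = 1)
  d <- dim(vol$voxels)
  # every insert-ROI voxel is exactly kappa * c
  rois <- locate_rois(vol, spec)
  v2 <- vol$voxels[, , 1]
  expect_true(all(v2[rois$insert_masks[["2mgml"]]] == 20))
  expect_true(all(v2[rois$insert_masks[["5mgml"]]] == 50))
  # air corners
  expect_equal(vol$voxels[1, 1, 1], -1000)
  # background ROI voxels exactly 0
  expect_true(all(v2[rois$background_mask] == 0))
})

test_that("generator is linear in concentration with noise off", {
  concs <- c(2, 5, 10, 15, 20)
  spec <- test_phantom(concs = concs, radius_mm = 80, ring_r_mm = 50)
  kap <- kappa_hu_per_mgml(contrast_model(), "DECT-VMI", 55)
  vol <- simulate_phantom_image(spec, test_acq(55), contrast_model(),
                                noise = NULL, seed = 1)
  rois <- locate_rois(vol, spec)
  bg <- roi_stats(vol, rois$background_mask, 1)
  for (ins in spec$inserts) {
    st <- roi_stats(vol, rois$insert_masks[[ins$label]], 1)
    expect_equal(st$mean_hu - bg$mean_hu, kap * ins$concentration,
                 tolerance = 1e-12)
  }
})

test_that("volumes are bit-identical under the same seed and differ otherwise", {
  spec <- test_phantom()
  a <- simulate_phantom_image(spec, test_acq(), flat_contrast(10),
                              flat_noise(12), seed = 42)
  b <- simulate_phantom_image(spec, test_acq(), flat_contrast(10),
                              flat_noise(12), seed = 42)
  c <- simulate_phantom_image(spec, test_acq(), flat_contrast(10),
                              flat_noise(12), seed = 43)
  expect_identical(a$voxels, b$voxels)
  expect_false(identical(a$voxels, c$voxels))
})

test_that("a zero-concentration insert is indistinguishable from background", {
  spec <- test_phantom(concs = c(0, 10), radius_mm = 70)
  vol <- simulate_phantom_image(spec, test_acq(), flat_contrast(20),
                                flat_noise(10), seed = 5)
  rois <- locate_rois(vol, spec)
  st <- roi_stats(vol, rois$insert_masks[["0mgml"]], 1)
  bg <- roi_stats(vol, rois$background_mask, 1)
  se <- sqrt(st$sd_hu^2 / st$n_voxels + bg$sd_hu^2 / bg$n_voxels)
  expect_lt(abs(st$mean_hu - bg$mean_hu), 3 * se)
})

test_that("realized noise SD matches the nominal SD within 5% at 1e4 voxels", {
  spec <- test_phantom(concs = c(2, 5), radius_mm = 120, ring_r_mm = 100,
                       insert_d_mm = 16)
  grid <- default_grid(spec, pixel_spacing_mm = 2, n_slices = 2L)
  vol <- simulate_phantom_image(spec, test_acq(), flat_contrast(10),
                                flat_noise(12), grid = grid, seed = 9)
  # background region away from inserts: central disk well inside the body
  d <- dim(vol$voxels)
  x <- (seq_len(d[2]) - (d[2] + 1) / 2) * vol$pixel_spacing_mm
  y <- (seq_len(d[1]) - (d[1] + 1) / 2) * vol$pixel_spacing_mm
  X <- matrix(x, d[1], d[2], byrow = TRUE); Y <- matrix(y, d[1], d[2])
  mask <- X^2 + Y^2 <= 80^2
  st <- roi_stats(vol, mask, 1)
  expect_gte(st$n_voxels, 1e4)
  expect_lt(abs(st$sd_hu - 12) / 12, 0.05)
})

test_that("doubling the dose shrinks noise by sqrt(2) within 3% at 1e4 voxels", {
  spec <- test_phantom(concs = c(2, 5), radius_mm = 120, ring_r_mm = 100)
  nm <- noise_model(sigma_ref = 12, d_ref_cm = 24, ctdi_ref = 10,
                    size_coeff = 0, recon_factor = c(none = 1))
  grid <- default_grid(spec, pixel_spacing_mm = 2, n_slices = 2L)
  sd_at <- function(ctdi, seed) {
    vol <- simulate_phantom_image(spec, test_acq(ctdi = ctdi), flat_contrast(10),
                                  nm, grid = grid, seed = seed)
    d <- dim(vol$voxels)
    x <- (seq_len(d[2]) - (d[2] + 1) / 2) * vol$pixel_spacing_mm
    y <- (seq_len(d[1]) - (d[1] + 1) / 2) * vol$pixel_spacing_mm
    X <- matrix(x, d[1], d[2], byrow = TRUE); Y <- matrix(y, d[1], d[2])
    st <- roi_stats(vol, X^2 + Y^2 <= 80^2, 1)
    expect_gte(st$n_voxels, 1e4)
    st$sd_hu
  }
  ratio <- sd_at(10, 21) / sd_at(20, 22)
  expect_lt(abs(ratio - sqrt(2)) / sqrt(2), 0.03)
})

test_that("realized noise increases strictly with phantom size at fixed dose", {
  nm <- noise_model(sigma_ref = 10, d_ref_cm = 20, ctdi_ref = 10,
                    size_coeff = 0.05, recon_factor = c(IR = 1))
  sds <- vapply(dect_phantom_set(), function(spec) {
    acq <- acquisition_setting("DECT-VMI", 60, recon_label = "IR",
                               size_label = spec$size_label, ctdi_vol = 10)
    vol <- simulate_phantom_image(spec, acq, contrast_model(), nm,
                                  default_grid(spec, 2, n_slices = 2L),
                                  seed = 11)
    rois <- locate_rois(vol, spec)
    roi_stats(vol, rois$background_mask, 1)$sd_hu
  }, 0)
  expect_true(all(diff(sds) > 0))
})

test_that("simulator rejects invalid grids", {
  spec <- test_phantom()
  expect_error(simulate_phantom_image(spec, test_acq(), flat_contrast(10),
                                      NULL, grid = list(pixel_spacing_mm = -1,
                                                        slice_thickness_mm = 5)),
               "spacing")
  expect_error(simulate_phantom_image(spec, test_acq(), flat_contrast(10), NULL,
                                      grid = list(pixel_spacing_mm = 2,
                                                  slice_thickness_mm = 5,
                                                  n_slices = 2L,
                                                  shape = c(10, 10))),
               "too small")
})

test_that("child seeds are stable, label-sensitive and within integer range", {
  s1 <- child_seed(7, "A", "SECT", 120)
  expect_identical(s1, child_seed(7, "A", "SECT", 120))
  expect_false(s1 == child_seed(7, "A", "SECT", 100))
  expect_false(s1 == child_seed(8, "A", "SECT", 120))
  expect_true(s1 >= 0 && s1 < 2^31)
})

test_that("fixture suite manifest matches the volumes and concentration sets", {
  suite <- build_fixture_suite(seed = 1, sect_kv = c(100, 120),
                               vmi_kev = c(50, 70), sect_recons = "SBIR",
                               sect_sizes = "newborn",
                               dect_sizes = "Small Adult",
                               grid_spacing_mm = 4, n_slices = 2L)
  # bookkeeping identity: one manifest row per generated volume
  expect_equal(nrow(suite$manifest), length(suite$volumes))
  expect_setequal(suite$manifest$key, names(suite$volumes))
  # SECT set carries 2,5,10,15,20 mg/mL; DECT set carries 2,5,10,15
  sect_rows <- suite$manifest$scanner_label == "SECT-A"
  expect_true(all(suite$manifest$concentrations[sect_rows] == "2;5;10;15;20"))
  expect_true(all(suite$manifest$concentrations[!sect_rows] %in%
                    c("2;5;10;15")))
  # 1 SECT size x 2 kV x 1 recon + 1 DECT size x (2 SECT kV + 2 VMI)
  expect_equal(nrow(suite$manifest), 2 + 4)
  # adding strata never perturbs existing volumes: child seeds depend only
  # on the stratum labels
  bigger <- build_fixture_suite(seed = 1, sect_kv = c(100, 120, 140),
                                vmi_kev = c(50, 70), sect_recons = "SBIR",
                                sect_sizes = "newborn",
                                dect_sizes = "Small Adult",
                                grid_spacing_mm = 4, n_slices = 2L)
  shared <- intersect(suite$manifest$key, bigger$manifest$key)
  for (k in shared)
    expect_identical(suite$volumes[[k]]$voxels, bigger$volumes[[k]]$voxels)
})
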