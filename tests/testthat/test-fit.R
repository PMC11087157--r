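test_that("exact proportional data recover the slope with R2 = 1", {
  f <- fit_slope(data.frame(concentration = c(1, 2), cnr = c(2, 4)))
  expect_equal(f$alpha, 2, tolerance = 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  expect_equal(f$n_points, 2L)
  # r2 = 1 whenever measurements are exactly proportional
  f2 <- fit_slope(data.frame(concentration = c(2, 5, 10, 15),
                             cnr = 3.7 * c(2, 5, 10, 15)))
  expect_equal(f2$r2, 1, tolerance = 1e-12)
})

test_that("all-zero CNR gives a zero slope", {
  f <- fit_slope(data.frame(concentration = c(2, 5, 10), cnr = c(0, 0, 0)))
  expect_equal(f$alpha, 0)
})

test_that("the lm-based slope equals the closed-form least-squares oracle", {
  set.seed(101)
  for (rep in 1:5) {
    c_all <- rep(c(2, 5, 10, 15, 20), 10)
    y <- 1.5 * c_all + rnorm(length(c_all), 0, 0.1)
    f <- fit_slope(data.frame(concentration = c_all, cnr = y))
    oracle <- sum(c_all * y) / sum(c_all^2)
    expect_equal(f$alpha, oracle, tolerance = 1e-12)
    expect_lt(abs(f$alpha - 1.5), 3 * f$alpha_se)
    # uncentered R2 oracle
    expect_equal(f$r2, 1 - sum((y - oracle * c_all)^2) / sum(y^2),
                 tolerance = 1e-12)
  }
})

test_that("degenerate designs and mixed strata are rejected", {
  expect_error(fit_slope(data.frame(concentration = c(5, 5, 5),
                                    cnr = c(1, 2, 3))),
               "insufficient design")
  mixed <- data.frame(energy = c(40, 50), mode = "DECT-VMI",
                      concentration = c(2, 5), cnr = c(1, 2))
  expect_error(fit_slope(mixed), "strata")
  expect_error(fit_slope(data.frame(concentration = c(2, 5),
                                    cnr = c(1, NA))), "non-finite|missing")
})

test_that("alpha is scale-equivariant in CNR", {
  d <- data.frame(concentration = c(2, 5, 10, 15),
                  cnr = c(3.1, 8.2, 15.9, 24.4))
  f1 <- fit_slope(d)
  d$cnr <- d$cnr * 7
  f7 <- fit_slope(d)
  expect_equal(f7$alpha, 7 * f1$alpha, tolerance = 1e-12)
})

test_that("cnr_calibration fits every stratum and reports failures", {
  tab <- exact_measurements(c("40" = 3, "60" = 1.5))
  # add a stratum with a single concentration -> must land in failures
  bad <- data.frame(scanner_label = "sim", mode = "DECT-VMI", energy = 80,
                    size_label = "test", recon_label = "none",
                    concentration = 5, cnr = 4)
  fit <- cnr_calibration(rbind(tab, bad))
  expect_length(fit$fits, 2L)
  expect_equal(nrow(fit$failures), 1L)
  expect_match(fit$failures$reason, "insufficient design")
  expect_equal(sort(unname(coef(fit))), c(1.5, 3), tolerance = 1e-12)
  expect_error(cnr_calibration(tab[0, ]), "empty")
})

test_that("noise-free simulated suite recovers alpha = kappa/sigma exactly", {
  # CNR computed with an injected nominal sigma on noise-free volumes
  spec <- test_phantom(concs = c(2, 5, 10, 15), radius_mm = 80, ring_r_mm = 50)
  sigma_nominal <- 10
  rows <- lapply(c(45, 60, 80), function(kev) {
    acq <- test_acq(kev)
    vol <- simulate_phantom_image(spec, acq, contrast_model(), NULL)
    rois <- locate_rois(vol, spec)
    bg <- roi_stats(vol, rois$background_mask, 0.6)
    do.call(rbind, lapply(spec$inserts, function(ins) {
      st <- roi_stats(vol, rois$insert_masks[[ins$label]], 0.6)
      data.frame(mode = "DECT-VMI", energy = kev,
                 concentration = ins$concentration,
                 cnr = (st$mean_hu - bg$mean_hu) / sigma_nominal)
    }))
  })
  fit <- cnr_calibration(do.call(rbind, rows), strata = c("mode", "energy"))
  for (kev in c(45, 60, 80)) {
    expected <- iodine_contrast_coefficient(kev) / sigma_nominal
    expect_equal(unname(coef(fit)[paste0("DECT-VMI|", kev)]), expected,
                 tolerance = 1e-12)
  }
})

test_that("model methods: predict, residuals, simulate, plot are coherent", {
  tab <- exact_measurements(c("40" = 3, "60" = 1.5))
  fit <- cnr_calibration(tab)
  expect_equal(predict(fit), tab$cnr, tolerance = 1e-12)
  expect_equal(residuals(fit), rep(0, nrow(tab)), tolerance = 1e-12)
  nd <- data.frame(scanner_label = "sim", mode = "DECT-VMI", energy = 40,
                   size_label = "test", recon_label = "none",
                   concentration = 7)
  expect_equal(predict(fit, nd), 21, tolerance = 1e-12)
  expect_error(predict(fit, transform(nd, energy = 99)), "no fitted stratum")
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(nrow(tab), 3L))
  # exact fit -> zero residual SD -> simulations reproduce the fit
  expect_equal(sims$sim_1, tab$cnr, tolerance = 1e-9)
  pdf(NULL)
  expect_invisible(plot(fit))
  dev.off()
})

test_that("cluster-robust alpha_se widens with correlated replicate errors", {
  set.seed(7)
  concs <- c(2, 5, 10, 15, 20); nrep <- 10
  img <- rep(seq_len(nrep), each = length(concs))
  c_all <- rep(concs, nrep)
  # shared multiplicative error per replicate image (shared background SD)
  shared <- rnorm(nrep, 0, 0.03)
  y <- 2 * c_all * (1 + shared[img]) + rnorm(length(c_all), 0, 0.05)
  d <- data.frame(concentration = c_all, cnr = y, replicate = img)
  f_cl <- fit_slope(d)           # auto -> cluster (replicate column present)
  f_ols <- fit_slope(d, se = "ols")
  expect_identical(f_cl$se_type, "cluster")
  expect_equal(f_cl$alpha, f_ols$alpha, tolerance = 1e-12)
  expect_gt(f_cl$alpha_se, f_ols$alpha_se)
})
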