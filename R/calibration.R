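#' Zero-intercept CNR-concentration slope for one stratum
#'
#' Fits CNR = alpha * concentration by least squares through the origin for
#' the measurements of a single acquisition stratum. The model has no
#' intercept by construction: zero iodine gives zero contrast, so the
#' calibration line is forced through the origin and alpha alone carries the
#' technique's contrast efficiency. Replicate measurements at the same
#' concentration all enter individually. A diagnostic fit with a free
#' intercept is also run; its intercept is flagged when it differs from zero
#' by more than two standard errors (but is never used downstream).
#'
#' @param measurements data frame with columns `concentration` and `cnr`
#'   (plus optional stratum columns, which must be constant, and an optional
#'   `replicate` column identifying the source image of each measurement).
#' @param stratum optional named list/vector of stratum labels stored with
#'   the fit; inferred from stratum columns when present.
#' @param se standard-error estimator for alpha. `"ols"` is the classical
#'   zero-intercept least-squares SE; it assumes independent homoscedastic
#'   errors, which CNR measurements violate twice over (all CNRs of one
#'   image share the measured background mean and SD, and the background-SD
#'   estimation error scales with CNR itself). `"cluster"` is robust to the
#'   within-image correlation and requires a `replicate` column. `"model"`
#'   propagates the ROI sampling error model analytically — insert-mean
#'   noise (1/n_insert), shared background-mean noise (1/n_background) and
#'   shared background-SD estimation error (inverse-chi moments on
#'   n_background - 1 df) — and requires `insert_n` and `bg_n` columns (as
#'   written by [measure_phantom_cnr()]); unlike the empirical estimators it
#'   has no sampling noise of its own, so +/- 3 SE intervals keep close to
#'   nominal coverage even with few replicate images. `"auto"` (default)
#'   picks `"model"` when the ROI count columns are present, else
#'   `"cluster"` when a `replicate` column with at least two levels is
#'   present, else `"ols"`.
#' @return An object of class `slope_fit`: `alpha` (CNR per mg/mL),
#'   `alpha_se`, `r2` (coefficient of determination about the zero-intercept
#'   model, i.e. 1 - RSS / sum(CNR^2)), `n_points`, `stratum`, and the
#'   diagnostic `intercept`, `intercept_se`, `intercept_flagged`.
#' @export
fit_slope <- function(measurements, stratum = NULL,
                      se = c("auto", "ols", "cluster", "model")) {
  se <- match.arg(se)
  stopifnot(is.data.frame(measurements),
            all(c("concentration", "cnr") %in% names(measurements)))
  m <- measurements
  if (se == "auto") {
    se <- if (all(c("insert_n", "bg_n") %in% names(m))) "model"
    else if ("replicate" %in% names(m) &&
             length(unique(m$replicate)) >= 2L) "cluster" else "ols"
  }
  strat_cols <- intersect(stratum_columns(), names(m))
  if (length(strat_cols)) {
    u <- unique(m[strat_cols])
    if (nrow(u) > 1)
      stop("measurements span ", nrow(u), " strata; fit_slope needs exactly one")
    if (is.null(stratum)) stratum <- as.list(u[1, , drop = FALSE])
  }
  if (any(m$concentration < 0)) stop("concentrations must be >= 0")
  if (length(unique(m$concentration[m$concentration > 0])) < 2)
    stop("insufficient design: need >= 2 distinct positive concentrations")
  if (any(!is.finite(m$cnr))) stop("non-finite CNR values")

  fit0 <- stats::lm(cnr ~ concentration - 1, data = m)
  # summary.lm warns on numerically perfect fits; exact proportional data are
  # a legitimate input here (noise-free fixtures)
  sm0 <- suppressWarnings(summary(fit0))
  tss <- sum(m$cnr^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit0)^2) / tss else NA_real_
  alpha_se <- unname(sm0$coefficients["concentration", "Std. Error"])
  if (se == "cluster") {
    if (!"replicate" %in% names(m))
      stop("cluster SE requested but no 'replicate' column present")
    r <- stats::residuals(fit0)
    u <- tapply(m$concentration * r, m$replicate, sum)
    g <- length(u)
    if (g < 2L) stop("cluster SE needs >= 2 replicate images")
    alpha_se <- sqrt(g / (g - 1) * sum(u^2)) / sum(m$concentration^2)
  } else if (se == "model") {
    if (!all(c("insert_n", "bg_n") %in% names(m)))
      stop("model SE requested but 'insert_n'/'bg_n' columns are absent")
    alpha_se <- model_alpha_se(m, unname(stats::coef(fit0)[["concentration"]]))
  }
  fit1 <- stats::lm(cnr ~ concentration, data = m)
  co1 <- suppressWarnings(summary(fit1))$coefficients
  intercept <- co1["(Intercept)", "Estimate"]
  intercept_se <- co1["(Intercept)", "Std. Error"]

  structure(list(
    stratum = stratum,
    alpha = unname(stats::coef(fit0)[["concentration"]]),
    alpha_se = alpha_se,
    se_type = se,
    r2 = r2,
    n_points = nrow(m),
    sigma_resid = sm0$sigma,
    intercept = intercept, intercept_se = intercept_se,
    intercept_flagged = is.finite(intercept_se) && intercept_se > 0 &&
      abs(intercept) > 2 * intercept_se,
    data = m[c(strat_cols, intersect("replicate", names(m)),
               "concentration", "cnr")]),
    class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  lab <- if (is.null(x$stratum)) "" else
    paste0(" [", paste(unlist(x$stratum), collapse = " / "), "]")
  cat(sprintf("slope_fit%s: alpha = %.4g (SE %.3g) CNR/(mg/mL), R2 = %.4f, n = %d\n",
              lab, x$alpha, x$alpha_se, x$r2, x$n_points))
  if (isTRUE(x$intercept_flagged))
    cat(sprintf("  note: diagnostic intercept %.3g differs from 0 by > 2 SE\n",
                x$intercept))
  invisible(x)
}

# Analytic first-order SE of the zero-intercept slope under the ROI error
# model. With CNR_i = (m_i - bbar) / S inside image g:
#   Var(m_i)/sigma^2 = 1/n_ins (independent),
#   Var(bbar)/sigma^2 = 1/n_bg (shared within g),
#   background SD: sigma/S = sqrt(nu/X), X ~ chisq(nu), nu = n_bg - 1,
#     giving a shared multiplicative error on all CNRs of the image with
#     Var(sigma/S) = nu/(nu-2) - E[sigma/S]^2, E[sigma/S] ~ 1 + 3/(4 nu).
# Images are identified by the replicate column when present; otherwise all
# rows are treated as one image (a single-acquisition measurement table).
model_alpha_se <- function(m, alpha) {
  grp <- if ("replicate" %in% names(m)) m$replicate else rep(1L, nrow(m))
  v <- 0
  for (g in split(m, grp)) {
    c_g <- g$concentration
    nu <- g$bg_n[1] - 1
    s_var <- if (nu > 4) {
      e_inv <- 1 + 3 / (4 * nu)
      nu / (nu - 2) - e_inv^2
    } else 1 / (2 * max(nu, 1))
    v <- v + sum(c_g^2 / g$insert_n) + sum(c_g)^2 / g$bg_n[1] +
      alpha^2 * sum(c_g^2)^2 * s_var
  }
  sqrt(v) / sum(m$concentration^2)
}

stratum_columns <- function()
  c("scanner_label", "mode", "energy", "size_label", "recon_label")

#' Fit CNR calibration lines across all acquisition strata
#'
#' The central estimator: splits a tidy CNR measurement table by stratum
#' (scanner, mode, energy, phantom size, reconstruction) and fits the
#' zero-intercept line CNR = alpha * concentration in each, returning a
#' `cnr_calibration` model object. Ratios of the fitted slopes between
#' techniques give CNR-matched concentration equivalence — the input to
#' [reduction_matrix()].
#'
#' Strata that fail the design preconditions (e.g. a single concentration)
#' are collected under `failures` with the reason, never silently dropped.
#'
#' @param data data frame with columns `concentration`, `cnr` and the
#'   stratum columns present in the data.
#' @param strata character vector of stratum column names; defaults to those
#'   of `scanner_label`, `mode`, `energy`, `size_label`, `recon_label`
#'   present in `data`.
#' @param se alpha standard-error estimator, passed to [fit_slope()].
#' @return An object of class `cnr_calibration` with elements `fits` (list
#'   of [fit_slope()] results keyed by stratum), `table` (one summary row
#'   per stratum), `failures` (data frame of stratum + reason), `strata`,
#'   `data`, `call`.
#' @seealso [coef.cnr_calibration()], [predict.cnr_calibration()],
#'   [reduction_matrix()]
#' @examples
#' d <- expand.grid(energy = c(60, 120), concentration = c(2, 5, 10, 15))
#' d$mode <- "DECT-VMI"
#' d$cnr <- ifelse(d$energy == 60, 2.0, 0.9) * d$concentration
#' fit <- cnr_calibration(d)
#' coef(fit)
#' @export
cnr_calibration <- function(data, strata = NULL, se = c("auto", "ols", "cluster")) {
  se <- match.arg(se)
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0) stop("empty measurement table")
  if (!all(c("concentration", "cnr") %in% names(data)))
    stop("data must have 'concentration' and 'cnr' columns")
  if (is.null(strata)) strata <- intersect(stratum_columns(), names(data))
  if (!length(strata)) stop("no stratum columns found in data")
  if (!all(strata %in% names(data)))
    stop("stratum columns missing from data: ",
         paste(setdiff(strata, names(data)), collapse = ", "))

  key <- interaction(data[strata], drop = TRUE, sep = "|", lex.order = TRUE)
  fits <- list(); fail <- list(); rows <- list()
  for (k in levels(key)) {
    sub <- data[key == k, , drop = FALSE]
    stratum <- as.list(sub[1, strata, drop = FALSE])
    f <- tryCatch(fit_slope(sub, stratum = stratum, se = se),
                  error = function(e) e)
    if (inherits(f, "error")) {
      fail[[length(fail) + 1L]] <- data.frame(
        stratum_key = k, reason = conditionMessage(f), stringsAsFactors = FALSE)
      next
    }
    fits[[k]] <- f
    rows[[length(rows) + 1L]] <- cbind(
      as.data.frame(stratum, stringsAsFactors = FALSE),
      data.frame(alpha = f$alpha, alpha_se = f$alpha_se, r2 = f$r2,
                 n_points = f$n_points,
                 intercept_flagged = f$intercept_flagged))
  }
  structure(list(
    fits = fits,
    table = if (length(rows)) do.call(rbind, rows) else NULL,
    failures = if (length(fail)) do.call(rbind, fail) else
      data.frame(stratum_key = character(), reason = character()),
    strata = strata, data = data, call = match.call()),
    class = "cnr_calibration")
}

#' @export
print.cnr_calibration <- function(x, ...) {
  cat("CNR calibration: zero-intercept fits CNR = alpha * concentration\n")
  cat(sprintf("  %d strata fitted over %s\n", length(x$fits),
              paste(x$strata, collapse = ", ")))
  if (nrow(x$failures))
    cat(sprintf("  %d strata failed preconditions (see $failures)\n",
                nrow(x$failures)))
  if (!is.null(x$table)) {
    tb <- x$table
    tb$alpha <- signif(tb$alpha, 4); tb$alpha_se <- signif(tb$alpha_se, 3)
    tb$r2 <- round(tb$r2, 4)
    print(utils::head(tb, 12), row.names = FALSE)
    if (nrow(tb) > 12) cat("  ...", nrow(tb) - 12, "more strata\n")
  }
  invisible(x)
}

#' @export
summary.cnr_calibration <- function(object, ...) {
  structure(list(table = object$table, failures = object$failures,
                 n_obs = nrow(object$data), strata = object$strata),
            class = "summary.cnr_calibration")
}

#' @export
print.summary.cnr_calibration <- function(x, ...) {
  cat("CNR calibration summary\n")
  cat(sprintf("  observations: %d; strata fitted: %d; failed: %d\n",
              x$n_obs, if (is.null(x$table)) 0L else nrow(x$table),
              nrow(x$failures)))
  cat("  R2 is computed about the zero-intercept model (uncentered):\n")
  cat("  R2 = 1 - sum(resid^2) / sum(CNR^2)\n\n")
  if (!is.null(x$table)) print(x$table, row.names = FALSE)
  if (nrow(x$failures)) {
    cat("\nFailed strata:\n"); print(x$failures, row.names = FALSE)
  }
  invisible(x)
}

#' Extract fitted slopes
#'
#' @param object a [cnr_calibration()] fit.
#' @param ... unused.
#' @return Named numeric vector of alpha values, one per stratum key.
#' @export
coef.cnr_calibration <- function(object, ...) {
  vapply(object$fits, `[[`, 0, "alpha")
}

#' Predict CNR at given concentrations
#'
#' @param object a [cnr_calibration()] fit.
#' @param newdata data frame with the fit's stratum columns and a
#'   `concentration` column; defaults to the training data.
#' @param ... unused.
#' @return Numeric vector of predicted CNR values (alpha * concentration).
#' @export
predict.cnr_calibration <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  key <- interaction(newdata[object$strata], drop = FALSE, sep = "|",
                     lex.order = TRUE)
  alpha <- coef(object)[as.character(key)]
  if (any(is.na(alpha)))
    stop("no fitted stratum for: ",
         paste(unique(as.character(key)[is.na(alpha)]), collapse = "; "))
  unname(alpha * newdata$concentration)
}

#' @export
residuals.cnr_calibration <- function(object, ...) {
  object$data$cnr - predict(object)
}

#' @export
fitted.cnr_calibration <- function(object, ...) predict(object)

#' Plot calibration lines
#'
#' CNR against iodine concentration, one colour per stratum, with the fitted
#' zero-intercept lines.
#'
#' @param x a [cnr_calibration()] fit.
#' @param strata_keys optional subset of stratum keys to show.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cnr_calibration <- function(x, strata_keys = NULL, ...) {
  keys <- strata_keys %||% names(x$fits)
  keys <- intersect(keys, names(x$fits))
  if (!length(keys)) stop("no fitted strata to plot")
  dat <- do.call(rbind, lapply(keys, function(k) x$fits[[k]]$data))
  cols <- grDevices::hcl.colors(length(keys), "Dark 3")
  graphics::plot(dat$concentration, dat$cnr, type = "n",
                 xlab = "iodine concentration (mg/mL)", ylab = "CNR", ...)
  for (i in seq_along(keys)) {
    f <- x$fits[[keys[i]]]
    graphics::points(f$data$concentration, f$data$cnr, col = cols[i], pch = 16)
    graphics::abline(0, f$alpha, col = cols[i])
  }
  graphics::legend("topleft", legend = keys, col = cols, lty = 1, cex = 0.7,
                   bty = "n")
  invisible(x)
}

#' Simulate CNR measurements from a fitted calibration
#'
#' Draws new CNR values at the training concentrations as
#' alpha * concentration + Gaussian residual noise with each stratum's
#' residual SD.
#'
#' @param object a [cnr_calibration()] fit.
#' @param nsim number of simulated replicate tables.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return A data frame of `nsim` columns (`sim_1`, ...) matching the rows
#'   of `object$data`.
#' @export
simulate.cnr_calibration <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object)
  key <- interaction(object$data[object$strata], drop = FALSE, sep = "|",
                     lex.order = TRUE)
  sig <- vapply(object$fits, `[[`, 0, "sigma_resid")[as.character(key)]
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), 0, sig)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
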