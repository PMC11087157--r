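#' CNR-matched equivalent concentration
#'
#' The target-technique iodine concentration that yields the same CNR as
#' `conc_baseline` under the baseline technique. With zero-intercept
#' calibrations CNR = alpha * conc, matching CNR gives
#' conc_target = (alpha_baseline / alpha_target) * conc_baseline.
#'
#' @param conc_baseline baseline concentration in mg/mL.
#' @param fit_baseline,fit_target [fit_slope()] objects (or bare positive
#'   slopes) for the baseline and target techniques.
#' @param allow_cross_size compare fits with different `size_label` strata?
#'   Refused by default: concentration equivalence is only meaningful within
#'   one phantom size.
#' @return Equivalent concentration in mg/mL.
#' @export
equivalent_concentration <- function(conc_baseline, fit_baseline, fit_target,
                                     allow_cross_size = FALSE) {
  ab <- slope_of(fit_baseline); at <- slope_of(fit_target)
  check_size_match(fit_baseline, fit_target, allow_cross_size)
  if (!is.finite(at) || at <= 0) stop("degenerate slope: target alpha must be > 0")
  if (!is.finite(ab) || ab <= 0) stop("degenerate slope: baseline alpha must be > 0")
  stopifnot(conc_baseline >= 0)
  (ab / at) * conc_baseline
}

slope_of <- function(x) {
  if (inherits(x, "slope_fit")) x$alpha
  else if (is.numeric(x) && length(x) == 1L) x
  else stop("expected a slope_fit or a single numeric slope")
}

se_of <- function(x) if (inherits(x, "slope_fit")) x$alpha_se else NA_real_

size_of <- function(x) {
  if (inherits(x, "slope_fit") && !is.null(x$stratum$size_label))
    as.character(x$stratum$size_label) else NA_character_
}

check_size_match <- function(b, t, allow_cross_size) {
  sb <- size_of(b); st <- size_of(t)
  if (!is.na(sb) && !is.na(st) && sb != st) {
    if (!allow_cross_size)
      stop("baseline and target fits are for different phantom sizes (",
           sb, " vs ", st, "); cross-size comparisons are refused ",
           "unless allow_cross_size = TRUE")
    warning("comparing slopes across phantom sizes (", sb, " vs ", st, ")")
  }
}

#' Iodine reduction between two techniques at matched CNR
#'
#' Percent reduction in iodinated contrast achievable by switching from the
#' baseline technique to the target while preserving CNR:
#' reduction = 100 * (1 - alpha_baseline / alpha_target).
#' Positive when the target technique has the larger slope (more contrast per
#' mg/mL); a negative value means the target needs an ICM *increase* of
#' 100 * (alpha_baseline / alpha_target - 1) percent. The uncertainty is
#' first-order propagation from the slope standard errors, slopes treated as
#' independent.
#'
#' @inheritParams equivalent_concentration
#' @return An object of class `reduction_plan`: a one-row data frame with
#'   `conc_ratio` (target/baseline concentration at matched CNR),
#'   `reduction_pct`, `reduction_se`, plus baseline/target stratum columns
#'   when available.
#' @export
iodine_reduction <- function(fit_baseline, fit_target,
                             allow_cross_size = FALSE) {
  ab <- slope_of(fit_baseline); at <- slope_of(fit_target)
  check_size_match(fit_baseline, fit_target, allow_cross_size)
  if (!is.finite(at) || at <= 0) stop("degenerate slope: target alpha must be > 0")
  if (!is.finite(ab) || ab <= 0) stop("degenerate slope: baseline alpha must be > 0")
  ratio <- ab / at
  seb <- se_of(fit_baseline); set <- se_of(fit_target)
  var_ratio <- if (is.finite(seb) && is.finite(set))
    ratio^2 * ((seb / ab)^2 + (set / at)^2) else NA_real_
  out <- data.frame(conc_ratio = ratio,
                    reduction_pct = 100 * (1 - ratio),
                    reduction_se = 100 * sqrt(var_ratio))
  bs <- stratum_prefix(fit_baseline, "baseline_")
  ts <- stratum_prefix(fit_target, "target_")
  if (!is.null(bs)) out <- cbind(bs, out)
  if (!is.null(ts)) out <- cbind(ts, out)
  class(out) <- c("reduction_plan", "data.frame")
  out
}

stratum_prefix <- function(x, prefix) {
  if (!inherits(x, "slope_fit") || is.null(x$stratum)) return(NULL)
  s <- as.data.frame(x$stratum, stringsAsFactors = FALSE)
  names(s) <- paste0(prefix, names(s))
  s
}

#' @export
print.reduction_plan <- function(x, ...) {
  y <- as.data.frame(x)
  y$conc_ratio <- round(y$conc_ratio, 4)
  y$reduction_pct <- round(y$reduction_pct, 1)
  y$reduction_se <- signif(y$reduction_se, 3)
  print(y, row.names = FALSE)
  neg <- y$reduction_pct < 0
  if (any(neg, na.rm = TRUE))
    cat("note: negative reductions are required ICM increases of ",
        paste(round(-y$reduction_pct[neg], 1), collapse = ", "),
        " percent\n", sep = "")
  invisible(x)
}

#' Reduction matrix across energies and phantom sizes
#'
#' For every phantom size, takes the baseline stratum (e.g. SECT 120 kV) and
#' computes the CNR-matched iodine reduction for each target stratum of the
#' requested mode, producing the size-by-energy reduction table normalised
#' to the baseline, plus per-energy averages across sizes (computed over
#' unrounded values). Sizes without a baseline fit are reported under
#' `unavailable`, never fabricated.
#'
#' @param object a [cnr_calibration()] fit.
#' @param baseline_energy baseline energy (kV for SECT), default 120.
#' @param baseline_mode mode of the baseline stratum, default "SECT".
#' @param target_mode mode of target strata ("DECT-VMI", "SECT", or NULL for
#'   all); target strata matching the baseline (same mode and energy) are
#'   skipped.
#' @param scanner_label optional scanner filter applied to both sides.
#' @return An object of class `reduction_matrix`: a data frame with one row
#'   per (size, target energy, recon) carrying `reduction_pct` and
#'   `reduction_se`, with attributes `averages` (per target energy across
#'   sizes) and `unavailable` (sizes lacking a baseline).
#' @export
reduction_matrix <- function(object, baseline_energy = 120,
                             baseline_mode = "SECT", target_mode = NULL,
                             scanner_label = NULL) {
  stopifnot(inherits(object, "cnr_calibration"))
  tb <- object$table
  if (is.null(tb) || !nrow(tb)) stop("calibration contains no fitted strata")
  need <- c("energy", "size_label", "mode")
  if (!all(need %in% names(tb)))
    stop("reduction_matrix needs strata over mode, energy and size_label")
  if (!is.null(scanner_label) && "scanner_label" %in% names(tb))
    tb <- tb[tb$scanner_label == scanner_label, , drop = FALSE]

  sizes <- unique(tb$size_label)
  rows <- list(); unavailable <- list()
  for (sz in sizes) {
    sub <- tb[tb$size_label == sz, , drop = FALSE]
    base_idx <- which(sub$mode == baseline_mode & sub$energy == baseline_energy)
    if (!length(base_idx)) {
      unavailable[[length(unavailable) + 1L]] <- data.frame(
        size_label = sz,
        reason = paste0("no ", baseline_mode, " ", baseline_energy,
                        " baseline fitted for this size"))
      next
    }
    targ <- sub
    if (!is.null(target_mode)) targ <- targ[targ$mode == target_mode, , drop = FALSE]
    targ <- targ[!(targ$mode == baseline_mode & targ$energy == baseline_energy), ,
                 drop = FALSE]
    for (bi in base_idx) {
      bkey <- row_key(sub[bi, ], object$strata)
      bfit <- object$fits[[bkey]]
      for (ti in seq_len(nrow(targ))) {
        # pair within matching recon when both sides share the label set
        if ("recon_label" %in% names(targ) &&
            targ$recon_label[ti] != sub$recon_label[bi]) next
        tkey <- row_key(targ[ti, ], object$strata)
        plan <- iodine_reduction(bfit, object$fits[[tkey]])
        rows[[length(rows) + 1L]] <- data.frame(
          size_label = sz, target_mode = targ$mode[ti],
          target_energy = targ$energy[ti],
          recon_label = if ("recon_label" %in% names(targ))
            targ$recon_label[ti] else NA_character_,
          baseline_mode = baseline_mode, baseline_energy = baseline_energy,
          conc_ratio = plan$conc_ratio,
          reduction_pct = plan$reduction_pct,
          reduction_se = plan$reduction_se, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    stop("no (baseline, target) stratum pairs found")
  out <- do.call(rbind, rows)
  agg <- stats::aggregate(reduction_pct ~ target_mode + target_energy + recon_label,
                          data = transform(out, recon_label =
                                             ifelse(is.na(recon_label), "", recon_label)),
                          FUN = mean)
  names(agg)[names(agg) == "reduction_pct"] <- "mean_reduction_pct"
  agg$n_sizes <- stats::aggregate(reduction_pct ~ target_mode + target_energy +
                                    recon_label,
                                  data = transform(out, recon_label =
                                                     ifelse(is.na(recon_label), "", recon_label)),
                                  FUN = length)$reduction_pct
  structure(out,
            averages = agg,
            unavailable = if (length(unavailable)) do.call(rbind, unavailable)
            else data.frame(size_label = character(), reason = character()),
            class = c("reduction_matrix", "data.frame"))
}

row_key <- function(row, strata)
  paste(vapply(strata, function(cn) as.character(row[[cn]]), ""), collapse = "|")

#' @export
print.reduction_matrix <- function(x, ...) {
  cat("ICM reduction matrix (percent, normalised to baseline ",
      x$baseline_mode[1], " ", x$baseline_energy[1], "; ",
      "negative = required increase)\n", sep = "")
  y <- as.data.frame(x)
  y$reduction_pct <- round(y$reduction_pct, 1)
  y$reduction_se <- signif(y$reduction_se, 2)
  y$conc_ratio <- round(y$conc_ratio, 3)
  print(y, row.names = FALSE)
  avg <- attr(x, "averages")
  if (!is.null(avg) && nrow(avg)) {
    cat("\nAverage reduction across sizes, per target energy:\n")
    avg$mean_reduction_pct <- round(avg$mean_reduction_pct, 1)
    print(avg, row.names = FALSE)
  }
  unav <- attr(x, "unavailable")
  if (!is.null(unav) && nrow(unav)) {
    cat("\nUnavailable sizes:\n"); print(unav, row.names = FALSE)
  }
  invisible(x)
}
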