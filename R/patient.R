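#' Patient ROI case measurement
#'
#' One aorta ROI summary from a patient scan: the scan label (dose level +
#' VMI energy), mean and SD in HU, and optionally background (e.g. psoas
#' muscle) mean/SD for CNR.
#'
#' @param label scan identifier, e.g. "full_70keV".
#' @param mean_hu,sd_hu ROI mean and SD in HU (sd_hu >= 0).
#' @param background_mean_hu,background_sd_hu optional background ROI stats.
#' @return An object of class `case_measurement`.
#' @export
case_measurement <- function(label, mean_hu, sd_hu,
                             background_mean_hu = NA_real_,
                             background_sd_hu = NA_real_) {
  stopifnot(is.numeric(mean_hu), is.numeric(sd_hu), sd_hu >= 0)
  structure(list(label = as.character(label), mean_hu = as.numeric(mean_hu),
                 sd_hu = as.numeric(sd_hu),
                 background_mean_hu = as.numeric(background_mean_hu),
                 background_sd_hu = as.numeric(background_sd_hu)),
            class = "case_measurement")
}

#' Percent HU difference between two measurements
#'
#' 100 * |other - reference| / reference, on the ROI means. Reporting
#' convention: the reduced-dose, CNR-matched low-keV measurement is the
#' reference (denominator) — the comparison asks how far the full-dose scan
#' sits from the dose-reduced surrogate. The quantity is symmetric up to
#' this choice; reports state which ordering was used.
#'
#' @param reference,other [case_measurement()] objects (reference is the
#'   denominator).
#' @return Percent difference (unrounded; reports round to 1 d.p.).
#' @export
percent_difference <- function(reference, other) {
  stopifnot(inherits(reference, "case_measurement"),
            inherits(other, "case_measurement"))
  if (reference$mean_hu == 0) stop("reference mean HU is zero")
  100 * abs(other$mean_hu - reference$mean_hu) / reference$mean_hu
}

#' Percent HU drop from baseline to follow-up
#'
#' 100 * (baseline - followup) / baseline on the ROI means, with the
#' full-dose baseline as denominator. Reports round to the nearest integer.
#'
#' @param baseline,followup [case_measurement()] objects.
#' @return Percent drop (unrounded).
#' @export
percent_drop <- function(baseline, followup) {
  stopifnot(inherits(baseline, "case_measurement"),
            inherits(followup, "case_measurement"))
  if (baseline$mean_hu <= 0) stop("baseline mean HU must be > 0")
  100 * (baseline$mean_hu - followup$mean_hu) / baseline$mean_hu
}

#' CNR of a patient case measurement
#'
#' (mean - background mean) / background SD — the same definition as
#' [compute_cnr()], applied to printed ROI summary statistics.
#'
#' @param m a [case_measurement()] with background fields present.
#' @return Signed CNR.
#' @export
case_cnr <- function(m) {
  stopifnot(inherits(m, "case_measurement"))
  if (!is.finite(m$background_mean_hu))
    stop("missing field: background_mean_hu")
  if (!is.finite(m$background_sd_hu))
    stop("missing field: background_sd_hu")
  if (m$background_sd_hu <= 0) stop("background_sd_hu must be > 0")
  (m$mean_hu - m$background_mean_hu) / m$background_sd_hu
}

#' Percent reduction in administered contrast volume
#'
#' @param full_ml,reduced_ml injected ICM volumes in mL.
#' @return Percent reduction (unrounded; e.g. 150 -> 100 mL gives 33.33...,
#'   printed as 33% or 33.3%).
#' @export
volume_reduction_pct <- function(full_ml, reduced_ml) {
  stopifnot(full_ml > 0, reduced_ml >= 0)
  100 * (full_ml - reduced_ml) / full_ml
}

#' Example patient ROI measurements
#'
#' The two urogram cases shipped with the package: for each patient, the
#' descending-aorta ROI mean +/- SD at full contrast dose (70 keV VMI) and at
#' reduced dose (70 keV and a CNR-matched lower keV). `reported_cnr` values
#' were computed against psoas-muscle background ROIs whose statistics are
#' not part of the record; they are display-only context and cannot be
#' recomputed from these inputs.
#'
#' @return Data frame, one row per (patient, scan).
#' @export
example_patient_cases <- function() {
  path <- system.file("extdata", "patient_cases.csv", package = "icmreduce",
                      mustWork = TRUE)
  utils::read.csv(path, comment.char = "#")
}

#' Patient worked-example report
#'
#' For each patient in a case table, computes the percent HU difference
#' between the full-dose scan and the reduced-dose CNR-matched low-keV scan
#' (reference = the reduced-dose low-keV measurement, rounded to 1 d.p.), the
#' percent HU drop from full dose to reduced dose at 70 keV (rounded to
#' integer), and CNR where background statistics are present.
#'
#' @param cases data frame like [example_patient_cases()]: columns `patient`,
#'   `role` (one of "full", "reduced_70", "reduced_low"), `mean_hu`, `sd_hu`,
#'   optional `background_mean_hu`, `background_sd_hu`.
#' @param full_volume_ml,reduced_volume_ml injected ICM volumes (mL) for the
#'   contrast bookkeeping row.
#' @return Data frame, one row per patient, with columns
#'   `pct_difference_1dp`, `pct_drop_int`, `volume_reduction_pct_1dp` and the
#'   reference convention used.
#' @export
patient_report <- function(cases, full_volume_ml = 150, reduced_volume_ml = 100) {
  stopifnot(is.data.frame(cases),
            all(c("patient", "role", "mean_hu", "sd_hu") %in% names(cases)))
  as_case <- function(row) case_measurement(
    label = paste(row$patient, row$role), mean_hu = row$mean_hu,
    sd_hu = row$sd_hu,
    background_mean_hu = row$background_mean_hu %||% NA_real_,
    background_sd_hu = row$background_sd_hu %||% NA_real_)
  out <- lapply(split(cases, cases$patient), function(p) {
    pick <- function(role) {
      i <- which(p$role == role)
      if (length(i) != 1L) stop("patient ", p$patient[1],
                                ": need exactly one '", role, "' row")
      as_case(as.list(p[i, , drop = FALSE]))
    }
    full <- pick("full"); red70 <- pick("reduced_70"); low <- pick("reduced_low")
    data.frame(
      patient = p$patient[1],
      pct_difference_1dp = round(percent_difference(low, full), 1),
      pct_drop_int = round(percent_drop(full, red70)),
      volume_reduction_pct_1dp = round(
        volume_reduction_pct(full_volume_ml, reduced_volume_ml), 1),
      reference = "reduced-dose low-keV measurement",
      stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
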