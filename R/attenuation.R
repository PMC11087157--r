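#' Bundled mass-attenuation table for iodine and water
#'
#' Returns the mass-attenuation table shipped with the package: one row per
#' photon energy (keV) with mass-attenuation coefficients (cm^2/g) for liquid
#' water and elemental iodine, covering 35--160 keV (above the iodine K-edge
#' at 33.2 keV, so log-log interpolation is smooth over the supported range).
#' The values are approximate, published-magnitude stand-ins adequate for
#' simulation; they are not a dosimetry reference.
#'
#' @return A data frame with columns `energy_kev`, `water`, `iodine`.
#' @export
attenuation_table <- function() {
  path <- system.file("extdata", "attenuation_iodine_water.csv",
                      package = "icmreduce", mustWork = TRUE)
  utils::read.csv(path)
}

#' Iodine contrast coefficient at a monochromatic energy
#'
#' Computes kappa(E), the Hounsfield-unit enhancement per mg/mL of iodine in
#' water at photon energy E (keV):
#' kappa(E) = 1000 * (mu/rho_iodine - mu/rho_water) / (mu/rho_water * rho_water) * 1e-3,
#' i.e. the HU shift produced by dissolving 1 mg of iodine per mL of water,
#' neglecting the volume displaced. Mass-attenuation coefficients are log-log
#' interpolated between tabulated energies, so kappa is strictly decreasing
#' over the supported range (iodine attenuation falls faster with energy than
#' water's above the K-edge).
#'
#' @param energy_kev photon energy in keV; must lie within the table range.
#' @param table attenuation table as from [attenuation_table()]: columns
#'   `energy_kev`, `water`, `iodine`.
#' @return HU per (mg/mL), a positive scalar (vectorised over `energy_kev`).
#' @examples
#' iodine_contrast_coefficient(70)
#' @export
iodine_contrast_coefficient <- function(energy_kev, table = attenuation_table()) {
  stopifnot(is.numeric(energy_kev), all(is.finite(energy_kev)))
  req <- c("energy_kev", "water", "iodine")
  if (!all(req %in% names(table)))
    stop("attenuation table must have columns: ", paste(req, collapse = ", "))
  if (any(energy_kev < min(table$energy_kev) | energy_kev > max(table$energy_kev)))
    stop("energy ", paste(energy_kev[energy_kev < min(table$energy_kev) |
                                       energy_kev > max(table$energy_kev)], collapse = ", "),
         " keV outside attenuation table range [",
         min(table$energy_kev), ", ", max(table$energy_kev), "]")
  mu_w <- loglog_interp(energy_kev, table$energy_kev, table$water)
  mu_i <- loglog_interp(energy_kev, table$energy_kev, table$iodine)
  rho_water <- 1.0 # g/mL
  1000 * (mu_i - mu_w) / (mu_w * rho_water) * 1e-3
}

# Piecewise-linear interpolation in log-log space; exact at the nodes.
loglog_interp <- function(x, xs, ys) {
  stopifnot(all(xs > 0), all(ys > 0))
  exp(stats::approx(log(xs), log(ys), xout = log(x), rule = 1)$y)
}
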