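#' Iodine contrast model
#'
#' Maps an acquisition setting to kappa, the HU enhancement per mg/mL iodine.
#' DECT virtual monochromatic images use the monochromatic coefficient at
#' their keV directly; SECT tube potentials are mapped to a configured
#' effective monochromatic energy (the polychromatic spectrum is not
#' modelled — the framework only needs a monotone contrast-energy response).
#'
#' @param attenuation attenuation table, as from [attenuation_table()].
#' @param kv_effective_kev named numeric vector mapping SECT kV stations to
#'   effective keV. Default: 70->45, 80->52, 100->58, 120->65, 135->70,
#'   140->72.
#' @return An object of class `contrast_model`.
#' @export
contrast_model <- function(attenuation = attenuation_table(),
                           kv_effective_kev = c("70" = 45, "80" = 52,
                                                "100" = 58, "120" = 65,
                                                "135" = 70, "140" = 72)) {
  stopifnot(is.numeric(kv_effective_kev), !is.null(names(kv_effective_kev)))
  structure(list(attenuation = attenuation,
                 kv_effective_kev = kv_effective_kev),
            class = "contrast_model")
}

#' Evaluate a contrast model
#'
#' @param model a [contrast_model()].
#' @param mode "SECT" or "DECT-VMI".
#' @param energy kV (SECT) or keV (DECT-VMI).
#' @return kappa in HU per (mg/mL).
#' @export
kappa_hu_per_mgml <- function(model, mode, energy) {
  stopifnot(inherits(model, "contrast_model"))
  kev <- if (identical(mode, "SECT")) {
    key <- as.character(energy)
    if (!key %in% names(model$kv_effective_kev))
      stop("no effective keV configured for SECT ", energy, " kV")
    model$kv_effective_kev[[key]]
  } else energy
  iodine_contrast_coefficient(kev, model$attenuation)
}

#' Image noise model
#'
#' Gaussian noise standard deviation as a function of phantom size, dose and
#' reconstruction:
#' sigma(d, ctdi, recon) = sigma_ref * exp(size_coeff * (d - d_ref)) *
#' sqrt(ctdi_ref / ctdi) * recon_factor[recon].
#' Exponential growth with effective diameter and inverse-square-root dose
#' dependence are the simplest forms reproducing the qualitative size and
#' dose behaviour of abdominal CT noise; all constants are configuration,
#' not measured truth.
#'
#' @param sigma_ref noise SD in HU at the reference diameter and dose.
#' @param d_ref_cm reference effective diameter in cm.
#' @param ctdi_ref reference CTDIvol in mGy.
#' @param size_coeff per-cm exponential growth rate of noise with diameter.
#' @param recon_factor named numeric vector of multiplicative noise factors
#'   per reconstruction label; unlisted labels default to 1.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma_ref = 10, d_ref_cm = 20, ctdi_ref = 10,
                        size_coeff = 0.05,
                        recon_factor = c(SBIR = 1.0, DLR = 0.7)) {
  stopifnot(sigma_ref > 0, d_ref_cm > 0, ctdi_ref > 0)
  structure(list(sigma_ref = sigma_ref, d_ref_cm = d_ref_cm,
                 ctdi_ref = ctdi_ref, size_coeff = size_coeff,
                 recon_factor = recon_factor),
            class = "noise_model")
}

#' Evaluate a noise model
#'
#' @param model a [noise_model()].
#' @param effective_diameter_cm phantom effective diameter in cm.
#' @param ctdi_vol CTDIvol in mGy.
#' @param recon_label reconstruction label; factors default to 1 if unlisted.
#' @return Noise SD in HU (> 0).
#' @export
noise_sd_hu <- function(model, effective_diameter_cm, ctdi_vol,
                        recon_label = "SBIR") {
  stopifnot(inherits(model, "noise_model"), ctdi_vol > 0)
  f <- if (recon_label %in% names(model$recon_factor))
    model$recon_factor[[recon_label]] else 1
  sd <- model$sigma_ref *
    exp(model$size_coeff * (effective_diameter_cm - model$d_ref_cm)) *
    sqrt(model$ctdi_ref / ctdi_vol) * f
  stopifnot(sd > 0)
  sd
}
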