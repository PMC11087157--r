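# Shared fixtures: small synthetic phantoms and simple forward models used
# across the test files. Everything is generated in code; no binary data.

# Contrast model with a flat kappa (HU per mg/mL) at every energy, for tests
# that need exact arithmetic. Built from a two-row attenuation table whose
# iodine/water ratio gives the requested kappa at all energies.
flat_contrast <- function(kappa) {
  contrast_model(
    attenuation = data.frame(energy_kev = c(35, 160), water = 0.2,
                             iodine = 0.2 * (1 + kappa)),
    kv_effective_kev = c("70" = 45, "80" = 52, "100" = 58, "120" = 65,
                         "135" = 70, "140" = 72))
}

# Noise model with a constant SD regardless of size, dose and recon.
flat_noise <- function(sigma) {
  noise_model(sigma_ref = sigma, d_ref_cm = 20, ctdi_ref = 10, size_coeff = 0,
              recon_factor = c(none = 1))
}

# A compact circular test phantom: inserts on a ring (plus optionally one at
# the centre), one insert per concentration.
test_phantom <- function(concs = c(2, 5, 10), radius_mm = 70,
                         insert_d_mm = 16, ring_r_mm = 45, background_hu = 0,
                         center_insert = FALSE, size_label = "test") {
  n <- length(concs) - center_insert
  ang <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
  inserts <- lapply(seq_len(n), function(k)
    insert_spec(ring_r_mm * c(cos(ang[k]), sin(ang[k])), insert_d_mm, concs[k]))
  if (center_insert)
    inserts <- c(inserts, list(insert_spec(c(0, 0), insert_d_mm,
                                           concs[length(concs)])))
  phantom_spec(rep(radius_mm, 2), inserts, background_hu = background_hu,
               size_label = size_label)
}

test_acq <- function(energy = 60, mode = "DECT-VMI", size_label = "test",
                     ctdi = 10, recon = "none")
  acquisition_setting(mode, energy, scanner_label = "sim", recon_label = recon,
                      size_label = size_label, ctdi_vol = ctdi)

# Measurement table with exact CNR = alpha * concentration for constructed
# strata; `alphas` is a named vector keyed by energy.
exact_measurements <- function(alphas, concs = c(2, 5, 10, 15),
                               size_label = "test", mode = "DECT-VMI") {
  do.call(rbind, lapply(names(alphas), function(e) {
    data.frame(scanner_label = "sim", mode = mode, energy = as.numeric(e),
               size_label = size_label, recon_label = "none",
               concentration = concs, cnr = alphas[[e]] * concs)
  }))
}
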