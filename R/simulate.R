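#' Simulate a phantom CT image volume
#'
#' Renders a phantom as a noisy HU volume with the statistical structure the
#' CNR analysis assumes: air (-1000 HU) outside the body, the body background
#' HU inside it, background + kappa(E) * concentration inside each insert,
#' plus i.i.d. Gaussian noise of the model SD inside the body. Voxels are
#' classified by their centre point (no partial-volume area weighting; the
#' downstream ROIs erode insert edges anyway). Deterministic given `seed`.
#'
#' @param spec a [phantom_spec()].
#' @param acq an [acquisition_setting()].
#' @param contrast a [contrast_model()].
#' @param noise a [noise_model()], or `NULL` for a noise-free volume.
#' @param grid list with `pixel_spacing_mm`, `slice_thickness_mm`, `n_slices`
#'   and optionally `shape` (rows, cols); when `shape` is absent the grid is
#'   sized to the body plus a margin. See [default_grid()].
#' @param seed integer RNG seed for the noise field.
#' @return A [ct_volume()] with attribute `"nominal"`: the noise-free insert
#'   HU, kappa and noise SD used (for diagnostics and tests).
#' @export
simulate_phantom_image <- function(spec, acq, contrast = contrast_model(),
                                   noise = noise_model(),
                                   grid = default_grid(spec), seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(acq, "acquisition_setting"),
            inherits(contrast, "contrast_model"))
  sp <- grid$pixel_spacing_mm
  if (is.null(sp) || sp <= 0) stop("grid pixel_spacing_mm must be > 0")
  if (is.null(grid$slice_thickness_mm) || grid$slice_thickness_mm <= 0)
    stop("grid slice_thickness_mm must be > 0")
  n_slices <- grid$n_slices %||% 5L
  shape <- grid$shape %||% fitted_shape(spec, sp)
  if (2 * spec$semi_axes_mm[2] > shape[1] * sp || 2 * spec$semi_axes_mm[1] > shape[2] * sp)
    stop("grid too small to contain the phantom body")

  x <- axis_coords(shape[2], sp)  # columns
  y <- axis_coords(shape[1], sp)  # rows
  a <- spec$semi_axes_mm[1]; b <- spec$semi_axes_mm[2]
  X <- matrix(x, nrow = shape[1], ncol = shape[2], byrow = TRUE)
  Y <- matrix(y, nrow = shape[1], ncol = shape[2])
  body <- (X / a)^2 + (Y / b)^2 <= 1

  kap <- kappa_hu_per_mgml(contrast, acq$mode, acq$energy)
  slice <- matrix(-1000, nrow = shape[1], ncol = shape[2])
  slice[body] <- spec$background_hu
  for (ins in spec$inserts) {
    disk <- (X - ins$center_xy[1])^2 + (Y - ins$center_xy[2])^2 <=
      (ins$diameter_mm / 2)^2
    slice[disk] <- spec$background_hu + kap * ins$concentration
  }

  vox <- array(slice, dim = c(shape[1], shape[2], n_slices))
  sigma <- 0
  if (!is.null(noise)) {
    sigma <- noise_sd_hu(noise, spec$effective_diameter_cm, acq$ctdi_vol,
                         acq$recon_label)
    nbody <- sum(body)
    set.seed(as.integer(seed))
    eps <- matrix(stats::rnorm(nbody * n_slices, 0, sigma), nrow = nbody)
    for (k in seq_len(n_slices)) {
      sl <- vox[, , k]
      sl[body] <- sl[body] + eps[, k]
      vox[, , k] <- sl
    }
  }
  out <- ct_volume(vox, sp, grid$slice_thickness_mm)
  attr(out, "nominal") <- list(kappa = kap, sigma = sigma,
                               insert_hu = vapply(spec$inserts, function(i)
                                 spec$background_hu + kap * i$concentration, 0))
  out
}

#' Default simulation grid for a phantom
#'
#' @param spec a [phantom_spec()].
#' @param pixel_spacing_mm in-plane spacing, default 2 mm.
#' @param slice_thickness_mm slice thickness, default 5 mm.
#' @param n_slices number of slices, default 5.
#' @param margin_mm air margin around the body, default 10 mm.
#' @return A grid list for [simulate_phantom_image()].
#' @export
default_grid <- function(spec, pixel_spacing_mm = 2, slice_thickness_mm = 5,
                         n_slices = 5L, margin_mm = 10) {
  list(pixel_spacing_mm = pixel_spacing_mm,
       slice_thickness_mm = slice_thickness_mm,
       n_slices = as.integer(n_slices),
       shape = fitted_shape(spec, pixel_spacing_mm, margin_mm))
}

fitted_shape <- function(spec, spacing, margin_mm = 10) {
  c(rows = ceiling((2 * spec$semi_axes_mm[2] + 2 * margin_mm) / spacing),
    cols = ceiling((2 * spec$semi_axes_mm[1] + 2 * margin_mm) / spacing))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable 31-bit string hash for deriving per-volume child seeds; independent
# of R's RNG so adding a volume never perturbs the others.
stable_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

#' Derive a per-stratum child seed
#'
#' @param seed top-level integer seed.
#' @param ... label components identifying the volume (coerced to character).
#' @return An integer seed in [0, 2^31), a stable function of its inputs.
#' @export
child_seed <- function(seed, ...) {
  lab <- paste(vapply(list(...), as.character, ""), collapse = "|")
  as.integer((as.numeric(seed) * 48271 + stable_hash(lab)) %% 2147483647)
}

#' Build the full synthetic phantom fixture suite
#'
#' Generates the study's eight phantom sizes with their concentration sets:
#' the four pediatric/adult SECT phantoms (2-20 mg/mL inserts) at tube
#' potentials 70/80/100/120/140 kV under SBIR and DLR reconstruction labels,
#' and the four adult DECT phantoms (2-15 mg/mL inserts) at VMI energies
#' 40-80 keV plus SECT 100 and 120 kV baselines. Each volume gets a child
#' seed hashed from its stratum labels. A manifest records every volume with
#' its stratum metadata.
#'
#' @param seed top-level integer seed.
#' @param out_dir when non-NULL, volumes are written there as ".nii.gz" +
#'   JSON sidecars and `manifest.csv`; otherwise volumes stay in memory.
#' @param sect_kv,vmi_kev,sect_recons energy and reconstruction subsets, for
#'   smaller suites.
#' @param sect_sizes,dect_sizes size-label subsets of the standard sets.
#' @param contrast,noise forward models for the simulation.
#' @param grid_spacing_mm in-plane pixel spacing for all volumes.
#' @param n_slices slices per volume.
#' @return List with `manifest` (data frame, one row per volume) and
#'   `volumes` (named list of [ct_volume()], `NULL` entries when written to
#'   disk) and `specs`/`acqs` (parallel named lists).
#' @export
build_fixture_suite <- function(seed = 1L, out_dir = NULL,
                                sect_kv = c(70, 80, 100, 120, 140),
                                vmi_kev = c(40, 50, 60, 70, 80),
                                sect_recons = c("SBIR", "DLR"),
                                sect_sizes = NULL, dect_sizes = NULL,
                                contrast = contrast_model(),
                                noise = noise_model(),
                                grid_spacing_mm = 2, n_slices = 5L) {
  sect <- sect_phantom_set()
  dect <- dect_phantom_set()
  if (!is.null(sect_sizes)) sect <- sect[sect_sizes]
  if (!is.null(dect_sizes)) dect <- dect[dect_sizes]
  # CTDIvol matched across systems per size; values rise with size
  ctdi_sect <- c(newborn = 3, "5YO" = 5, "15YO" = 8, "medium adult" = 12)
  ctdi_dect <- c("Small Adult" = 10, "Medium Adult" = 15,
                 "Large Adult" = 20, "Extra Large Adult" = 25)

  rows <- list(); volumes <- list(); specs <- list(); acqs <- list()
  add <- function(spec, acq) {
    key <- paste(acq$scanner_label, acq$mode, acq$energy, acq$size_label,
                 acq$recon_label, sep = "|")
    cs <- child_seed(seed, key)
    grid <- default_grid(spec, pixel_spacing_mm = grid_spacing_mm,
                         n_slices = n_slices)
    vol <- simulate_phantom_image(spec, acq, contrast, noise, grid, seed = cs)
    file <- NA_character_
    if (!is.null(out_dir)) {
      file <- file.path(out_dir, paste0(gsub("[^A-Za-z0-9]+", "_", key), ".nii.gz"))
      write_ct_volume(vol, file, spec = spec, acq = acq)
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      key = key, file = file, scanner_label = acq$scanner_label,
      mode = acq$mode, energy = acq$energy, size_label = acq$size_label,
      recon_label = acq$recon_label, ctdi_vol = acq$ctdi_vol,
      effective_diameter_cm = spec$effective_diameter_cm,
      concentrations = paste(vapply(spec$inserts, `[[`, 0, "concentration"),
                             collapse = ";"),
      child_seed = cs, stringsAsFactors = FALSE)
    volumes[[key]] <<- if (is.null(out_dir)) vol else NULL
    specs[[key]] <<- spec; acqs[[key]] <<- acq
  }

  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (spec in sect) for (kv in sect_kv) for (rc in sect_recons)
    add(spec, acquisition_setting("SECT", kv, scanner_label = "SECT-A",
                                  recon_label = rc, size_label = spec$size_label,
                                  ctdi_vol = ctdi_sect[[spec$size_label]]))
  for (spec in dect) {
    for (kv in c(100, 120))
      add(spec, acquisition_setting("SECT", kv, scanner_label = "DECT-1",
                                    recon_label = "IR", size_label = spec$size_label,
                                    ctdi_vol = ctdi_dect[[spec$size_label]]))
    for (kev in vmi_kev)
      add(spec, acquisition_setting("DECT-VMI", kev, scanner_label = "DECT-1",
                                    recon_label = "IR", size_label = spec$size_label,
                                    ctdi_vol = ctdi_dect[[spec$size_label]]))
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  list(manifest = manifest, volumes = volumes, specs = specs, acqs = acqs)
}
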