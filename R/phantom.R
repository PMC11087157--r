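#' Iodine insert specification
#'
#' One cylindrical iodine insert within a phantom: its in-plane centre,
#' diameter, and iodine concentration. Coordinates are physical millimetres
#' with the origin at the phantom centre.
#'
#' @param center_xy numeric length-2, (x, y) centre in mm.
#' @param diameter_mm insert diameter in mm, > 0.
#' @param concentration iodine concentration in mg/mL, >= 0.
#' @param label optional insert label; defaults to the concentration.
#' @return An object of class `insert_spec`.
#' @export
insert_spec <- function(center_xy, diameter_mm, concentration, label = NULL) {
  stopifnot(is.numeric(center_xy), length(center_xy) == 2L, all(is.finite(center_xy)))
  if (!is.numeric(diameter_mm) || diameter_mm <= 0)
    stop("insert diameter must be > 0 mm")
  if (!is.numeric(concentration) || concentration < 0)
    stop("insert concentration must be >= 0 mg/mL")
  if (is.null(label)) label <- paste0(format(concentration), "mgml")
  structure(list(center_xy = as.numeric(center_xy),
                 diameter_mm = as.numeric(diameter_mm),
                 concentration = as.numeric(concentration),
                 label = as.character(label)),
            class = "insert_spec")
}

#' Phantom specification
#'
#' Geometry of a water-equivalent abdomen phantom: a circular or elliptical
#' body with cylindrical iodine inserts. The effective diameter is the
#' equivalent circular diameter, 2*sqrt(semi_a*semi_b)/10 in cm.
#'
#' @param semi_axes_mm numeric length-2, in-plane semi-axes (a, b) in mm; a
#'   circle has equal entries.
#' @param inserts list of [insert_spec()] objects; pairwise disjoint and fully
#'   inside the body.
#' @param background_hu HU of the body material (0 for solid water).
#' @param z_length_mm phantom length along z in mm.
#' @param size_label free-text size label (e.g. "newborn", "Medium Adult").
#' @return An object of class `phantom_spec` with an `effective_diameter_cm`
#'   field derived from the semi-axes.
#' @export
phantom_spec <- function(semi_axes_mm, inserts = list(), background_hu = 0,
                         z_length_mm = 150, size_label = "phantom") {
  stopifnot(is.numeric(semi_axes_mm), length(semi_axes_mm) == 2L,
            all(semi_axes_mm > 0), is.list(inserts))
  eff_cm <- 2 * sqrt(prod(semi_axes_mm)) / 10
  a <- semi_axes_mm[1]; b <- semi_axes_mm[2]
  for (ins in inserts) {
    if (!inherits(ins, "insert_spec")) stop("inserts must be insert_spec objects")
    # insert disk entirely inside the elliptical body: conservative check on
    # the scaled radial coordinate at the insert boundary
    r <- ins$diameter_mm / 2
    cx <- ins$center_xy[1]; cy <- ins$center_xy[2]
    s <- sqrt((cx / a)^2 + (cy / b)^2)
    margin <- r / min(a, b)
    if (s + margin > 1)
      stop("insert '", ins$label, "' extends outside the phantom body")
  }
  if (length(inserts) >= 2L) {
    for (i in seq_len(length(inserts) - 1L)) for (j in seq(i + 1L, length(inserts))) {
      d <- sqrt(sum((inserts[[i]]$center_xy - inserts[[j]]$center_xy)^2))
      if (d < (inserts[[i]]$diameter_mm + inserts[[j]]$diameter_mm) / 2)
        stop("inserts '", inserts[[i]]$label, "' and '", inserts[[j]]$label,
             "' overlap")
    }
  }
  structure(list(semi_axes_mm = as.numeric(semi_axes_mm),
                 effective_diameter_cm = eff_cm,
                 background_hu = as.numeric(background_hu),
                 inserts = inserts,
                 z_length_mm = as.numeric(z_length_mm),
                 size_label = as.character(size_label)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("phantom_spec:", x$size_label,
      sprintf("(effective diameter %.1f cm, background %g HU, %d inserts)\n",
              x$effective_diameter_cm, x$background_hu, length(x$inserts)))
  invisible(x)
}

#' Acquisition setting
#'
#' The stratum metadata of one acquisition: single-energy CT (SECT, energy in
#' kV) or a dual-energy virtual monochromatic image (DECT-VMI, energy in keV),
#' plus scanner / reconstruction / size labels and the CTDIvol.
#'
#' @param mode "SECT" or "DECT-VMI".
#' @param energy tube potential in kV (SECT) or VMI energy in keV (DECT-VMI).
#' @param scanner_label,recon_label,size_label free-text stratum labels.
#' @param ctdi_vol volume CT dose index in mGy, > 0.
#' @return An object of class `acquisition_setting`.
#' @export
acquisition_setting <- function(mode = c("SECT", "DECT-VMI"), energy,
                                scanner_label = "scanner",
                                recon_label = "SBIR",
                                size_label = "phantom",
                                ctdi_vol = 10) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(energy), length(energy) == 1L)
  if (mode == "SECT" && !(energy %in% c(70, 80, 100, 110, 120, 135, 140)))
    stop("SECT energy must be a tube potential in {70, 80, 100, 110, 120, 135, 140} kV")
  if (mode == "DECT-VMI" && (energy < 40 || energy > 140))
    stop("VMI energy must lie in [40, 140] keV")
  if (!is.numeric(ctdi_vol) || ctdi_vol <= 0) stop("ctdi_vol must be > 0 mGy")
  structure(list(mode = mode, energy = as.numeric(energy),
                 scanner_label = as.character(scanner_label),
                 recon_label = as.character(recon_label),
                 size_label = as.character(size_label),
                 ctdi_vol = as.numeric(ctdi_vol)),
            class = "acquisition_setting")
}

#' Standard pediatric/adult SECT phantom set
#'
#' Builds the four tissue-equivalent abdomen phantoms used for the low-kV
#' single-energy study: circular bodies of effective diameter 9.7 (newborn),
#' 15.9 (5 year-old), 21.1 (15 year-old) and 28.5 cm (medium adult), each with
#' five 13.1 mm contrast rods (four peripheral, one central) at 2, 5, 10, 15
#' and 20 mg/mL iodine. The physical rods stack the five concentrations in
#' ~2 cm z-sections; the simulated phantoms place one single-concentration rod
#' per hole instead so every concentration is present on every slice.
#'
#' @param background_hu body HU; default 30 (soft-tissue-equivalent).
#' @return Named list of [phantom_spec()] objects.
#' @export
sect_phantom_set <- function(background_hu = 30) {
  sizes <- c(newborn = 9.7, "5YO" = 15.9, "15YO" = 21.1, "medium adult" = 28.5)
  concs <- c(2, 5, 10, 15, 20)
  out <- lapply(seq_along(sizes), function(i) {
    radius_mm <- sizes[i] * 10 / 2
    ring_r <- 0.62 * radius_mm       # peripheral holes
    ang <- c(0, 90, 180, 270) * pi / 180
    centers <- rbind(cbind(ring_r * cos(ang), ring_r * sin(ang)), c(0, 0))
    inserts <- lapply(seq_len(5L), function(k)
      insert_spec(centers[k, ], diameter_mm = 13.1, concentration = concs[k]))
    phantom_spec(rep(radius_mm, 2), inserts, background_hu = background_hu,
                 z_length_mm = 150, size_label = names(sizes)[i])
  })
  names(out) <- names(sizes)
  out
}

#' Standard adult DECT phantom set
#'
#' Builds the four adult multi-energy phantoms: a 20 cm solid-water cylinder
#' holding four 28.5 mm iodine inserts at 2, 5, 10 and 15 mg/mL, enclosed by
#' elliptical annular rings to reach effective diameters 20 (Small Adult),
#' 29.5 (Medium Adult), 34.6 (Large Adult) and 39.7 cm (Extra Large Adult).
#' The simulated bodies are solid-water ellipses of matching effective
#' diameter (rings are not modelled as separate materials).
#'
#' @param background_hu body HU; default 0 (solid water).
#' @return Named list of [phantom_spec()] objects.
#' @export
dect_phantom_set <- function(background_hu = 0) {
  sizes <- c("Small Adult" = 20, "Medium Adult" = 29.5,
             "Large Adult" = 34.6, "Extra Large Adult" = 39.7)
  concs <- c(2, 5, 10, 15)
  aspect <- c(1, 0.75, 0.75, 0.75)   # rings are elliptical, core is circular
  out <- lapply(seq_along(sizes), function(i) {
    # semi-axes with sqrt(a*b) = eff_d*10/2 and b/a = aspect
    g <- sizes[i] * 10 / 2
    a <- g / sqrt(aspect[i]); b <- g * sqrt(aspect[i])
    ring_r <- 60
    ang <- c(45, 135, 225, 315) * pi / 180
    inserts <- lapply(seq_len(4L), function(k)
      insert_spec(ring_r * c(cos(ang[k]), sin(ang[k])),
                  diameter_mm = 28.5, concentration = concs[k]))
    phantom_spec(c(a, b), inserts, background_hu = background_hu,
                 z_length_mm = 165, size_label = names(sizes)[i])
  })
  names(out) <- names(sizes)
  out
}
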