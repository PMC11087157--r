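#' Locate insert and background ROIs in a phantom image
#'
#' Builds one circular in-plane mask per insert plus four pooled background
#' masks. In `"geometry"` mode insert masks are centred on the specified
#' insert centres with diameter `roi_fraction` times the insert diameter
#' (eroding edge partial-volume pixels). In `"auto"` mode high-HU disks are
#' detected by thresholding the slice-averaged image and labelling connected
#' components; detected centroids are matched to the specified inserts by
#' nearest centre. Background ROIs have the same area as the insert ROIs and
#' sit at the peripheral insert radius, rotated midway between inserts, in
#' insert-free body regions.
#'
#' @param image a [ct_volume()].
#' @param spec the [phantom_spec()] imaged.
#' @param roi_fraction insert-ROI diameter as a fraction of the insert inner
#'   diameter, in (0, 0.9]; default 0.7.
#' @param mode "geometry" or "auto".
#' @param bg_radius_mm,bg_angles_deg optional overrides for background ROI
#'   placement.
#' @return List with `insert_masks` (named list of logical row x col masks),
#'   `background_masks` (list of 4), `background_mask` (their union),
#'   `centers` (matrix of insert centres used, mm).
#' @export
locate_rois <- function(image, spec, roi_fraction = 0.7,
                        mode = c("geometry", "auto"),
                        bg_radius_mm = NULL, bg_angles_deg = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(image, "ct_volume"), inherits(spec, "phantom_spec"))
  if (roi_fraction <= 0 || roi_fraction > 0.9)
    stop("roi_fraction must lie in (0, 0.9]")
  d <- dim(image$voxels); sp <- image$pixel_spacing_mm
  x <- axis_coords(d[2], sp); y <- axis_coords(d[1], sp)
  X <- matrix(x, nrow = d[1], ncol = d[2], byrow = TRUE)
  Y <- matrix(y, nrow = d[1], ncol = d[2])

  centers <- t(vapply(spec$inserts, `[[`, c(0, 0), "center_xy"))
  half_fov <- c(max(abs(x)) + sp / 2, max(abs(y)) + sp / 2)
  if (any(abs(centers[, 1]) > half_fov[1]) || any(abs(centers[, 2]) > half_fov[2]))
    stop("insert outside the field of view")

  if (mode == "auto") centers <- detect_insert_centers(image, spec, X, Y)

  disk <- function(cx, cy, r) (X - cx)^2 + (Y - cy)^2 <= r^2
  insert_masks <- list()
  for (i in seq_along(spec$inserts)) {
    ins <- spec$inserts[[i]]
    insert_masks[[ins$label]] <-
      disk(centers[i, 1], centers[i, 2], roi_fraction * ins$diameter_mm / 2)
  }

  # background ROI geometry: same area as the (mean) insert ROI, placed at
  # the peripheral insert radius rotated midway between inserts
  roi_r <- roi_fraction * mean(vapply(spec$inserts, `[[`, 0, "diameter_mm")) / 2
  spec_centers <- t(vapply(spec$inserts, `[[`, c(0, 0), "center_xy"))
  rad <- sqrt(rowSums(spec_centers^2))
  periph <- rad > roi_r
  if (!any(periph)) stop("no peripheral inserts to anchor background ROIs")
  if (is.null(bg_radius_mm)) bg_radius_mm <- mean(rad[periph])
  if (is.null(bg_angles_deg)) {
    ang <- sort(atan2(spec_centers[periph, 2], spec_centers[periph, 1]) * 180 / pi)
    gaps <- diff(c(ang, ang[1] + 360))
    mids <- (ang + gaps / 2) %% 360
    # four background ROIs for the standard 4+ insert layouts; fewer inserts
    # yield fewer insert-free gaps, so use what the geometry offers
    bg_angles_deg <- if (length(mids) >= 4) mids[1:4] else mids
  }
  a <- spec$semi_axes_mm[1]; b <- spec$semi_axes_mm[2]
  background_masks <- list()
  for (th in bg_angles_deg * pi / 180) {
    cx <- bg_radius_mm * cos(th); cy <- bg_radius_mm * sin(th)
    if (sqrt((cx / a)^2 + (cy / b)^2) + roi_r / min(a, b) > 1)
      stop("background ROI at angle ", round(th * 180 / pi),
           " deg falls outside the phantom body; adjust bg_radius_mm")
    for (i in seq_along(spec$inserts)) {
      ins <- spec$inserts[[i]]
      if (sqrt((cx - centers[i, 1])^2 + (cy - centers[i, 2])^2) <
          roi_r + ins$diameter_mm / 2)
        stop("background ROI at angle ", round(th * 180 / pi),
             " deg overlaps insert '", ins$label, "'")
    }
    background_masks[[length(background_masks) + 1L]] <- disk(cx, cy, roi_r)
  }
  background_mask <- Reduce(`|`, background_masks)
  list(insert_masks = insert_masks, background_masks = background_masks,
       background_mask = background_mask, centers = centers)
}

# Threshold the slice-averaged image and label connected high-HU components;
# returns one detected centre (mm) per spec insert, matched by nearest
# centroid. Detection must agree with the specified centres within one pixel
# on noise-free images.
detect_insert_centers <- function(image, spec, X, Y) {
  d <- dim(image$voxels)
  avg <- apply(image$voxels, c(1, 2), mean)
  body <- avg > -500
  med <- stats::median(avg[body])
  noise <- stats::mad(avg[body])
  bin <- body & (avg > med + max(5 * noise, 5))
  lab <- EBImage::bwlabel(bin)
  labels <- setdiff(unique(as.vector(lab)), 0)
  min_area <- 0.25 * min(vapply(spec$inserts, function(i)
    pi * (i$diameter_mm / 2)^2, 0)) / image$pixel_spacing_mm^2
  cents <- list()
  for (l in labels) {
    m <- lab == l
    if (sum(m) < min_area) next
    cents[[length(cents) + 1L]] <- c(mean(X[m]), mean(Y[m]))
  }
  if (length(cents) < length(spec$inserts))
    stop("auto ROI detection found ", length(cents), " component(s) for ",
         length(spec$inserts), " inserts")
  cmat <- do.call(rbind, cents)
  out <- matrix(NA_real_, nrow = length(spec$inserts), ncol = 2)
  for (i in seq_along(spec$inserts)) {
    ins <- spec$inserts[[i]]
    dist <- sqrt((cmat[, 1] - ins$center_xy[1])^2 + (cmat[, 2] - ins$center_xy[2])^2)
    j <- which.min(dist)
    if (dist[j] > ins$diameter_mm / 2)
      stop("auto ROI detection: no component matches insert '", ins$label, "'")
    out[i, ] <- cmat[j, ]
  }
  out
}

#' ROI summary statistics
#'
#' Mean and sample SD of the voxels under an in-plane mask, pooled across the
#' central fraction of slices.
#'
#' @param image a [ct_volume()].
#' @param mask logical row x col matrix.
#' @param central_fraction fraction of central slices to pool, in (0, 1];
#'   default 0.6 (end slices of physical rods risk edge effects).
#' @param label optional ROI label.
#' @return An object of class `roi_stats`: `mean_hu`, `sd_hu` (sample, n-1),
#'   `n_voxels`, `label`.
#' @export
roi_stats <- function(image, mask, central_fraction = 0.6, label = "roi") {
  stopifnot(inherits(image, "ct_volume"), is.logical(mask))
  d <- dim(image$voxels)
  stopifnot(all(dim(mask) == d[1:2]))
  k <- if (central_fraction > 0) max(1L, round(d[3] * central_fraction)) else 0L
  if (k < 1) stop("slice policy selects 0 slices")
  start <- floor((d[3] - k) / 2) + 1L
  slices <- seq(start, length.out = k)
  if (!any(mask)) stop("empty ROI mask")
  vals <- as.vector(image$voxels[, , slices, drop = FALSE][rep(mask, k)])
  structure(list(mean_hu = mean(vals),
                 sd_hu = if (length(vals) > 1) stats::sd(vals) else 0,
                 n_voxels = length(vals), label = label),
            class = "roi_stats")
}

#' Contrast-to-noise ratio from ROI statistics
#'
#' CNR = (insert mean - background mean) / background SD. The background SD
#' (not the insert SD) is the noise estimate, so insert texture does not
#' conflate contrast with noise; the sign is preserved so a negative-contrast
#' insert is visible in QA output.
#'
#' @param insert,background [roi_stats()] objects.
#' @return Signed CNR, a finite scalar.
#' @export
compute_cnr <- function(insert, background) {
  stopifnot(inherits(insert, "roi_stats"), inherits(background, "roi_stats"))
  if (background$sd_hu <= 0)
    stop("degenerate background: SD must be > 0 to define CNR")
  (insert$mean_hu - background$mean_hu) / background$sd_hu
}

#' Measure per-insert CNR in a phantom image
#'
#' Runs ROI placement and statistics and returns one row per insert with the
#' full stratum key, concentration, CNR and the underlying ROI statistics —
#' the tidy measurement table consumed by [cnr_calibration()].
#'
#' @inheritParams locate_rois
#' @param acq the [acquisition_setting()] of the image (stratum metadata).
#' @param central_fraction slice-pooling policy, see [roi_stats()].
#' @param replicate optional replicate-image identifier added as a
#'   `replicate` column, so fits over replicated acquisitions can use
#'   cluster-robust slope standard errors (see [fit_slope()]).
#' @return A data frame with columns scanner_label, mode, energy, size_label,
#'   recon_label, concentration, cnr, insert_mean_hu, insert_sd_hu,
#'   insert_n, bg_mean_hu, bg_sd_hu, bg_n.
#' @export
measure_phantom_cnr <- function(image, spec, acq, roi_fraction = 0.7,
                                mode = "geometry", central_fraction = 0.6,
                                replicate = NULL) {
  stopifnot(inherits(acq, "acquisition_setting"))
  rois <- locate_rois(image, spec, roi_fraction = roi_fraction, mode = mode)
  bg <- roi_stats(image, rois$background_mask, central_fraction, "background")
  rows <- lapply(seq_along(spec$inserts), function(i) {
    ins <- spec$inserts[[i]]
    st <- roi_stats(image, rois$insert_masks[[ins$label]], central_fraction,
                    ins$label)
    data.frame(scanner_label = acq$scanner_label, mode = acq$mode,
               energy = acq$energy, size_label = acq$size_label,
               recon_label = acq$recon_label,
               concentration = ins$concentration,
               cnr = compute_cnr(st, bg),
               insert_mean_hu = st$mean_hu, insert_sd_hu = st$sd_hu,
               insert_n = st$n_voxels, bg_mean_hu = bg$mean_hu,
               bg_sd_hu = bg$sd_hu, bg_n = bg$n_voxels,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(replicate)) out$replicate <- replicate
  out
}
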