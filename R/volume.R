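#' CT image volume
#'
#' A 3-D array of Hounsfield units with physical spacing. The array is
#' indexed `[row, col, slice]`; in-plane rows map to y and columns to x. The
#' phantom-centre origin sits at the image centre: the physical coordinate of
#' pixel centre i (1-based) along an axis of length n with spacing s is
#' `(i - (n + 1) / 2) * s` mm.
#'
#' @param voxels numeric 3-D array of HU values (rows x cols x slices).
#' @param pixel_spacing_mm in-plane pixel spacing in mm (isotropic).
#' @param slice_thickness_mm slice thickness / spacing in mm.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, pixel_spacing_mm, slice_thickness_mm) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L,
            all(is.finite(voxels)),
            pixel_spacing_mm > 0, slice_thickness_mm > 0)
  structure(list(voxels = voxels,
                 pixel_spacing_mm = as.numeric(pixel_spacing_mm),
                 slice_thickness_mm = as.numeric(slice_thickness_mm)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("ct_volume: %d x %d x %d voxels, %.3g mm pixels, %.3g mm slices, HU range [%.1f, %.1f]\n",
              d[1], d[2], d[3], x$pixel_spacing_mm, x$slice_thickness_mm,
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

# Physical pixel-centre coordinates (mm, image centre = origin) along an axis.
axis_coords <- function(n, spacing) (seq_len(n) - (n + 1) / 2) * spacing

#' Write a CT volume with JSON sidecar
#'
#' Stores the volume as a compressed NIfTI array (HU values, pixel dimensions
#' carried in the header) with a JSON sidecar describing the phantom and
#' acquisition so a volume on disk is self-describing.
#'
#' @param volume a [ct_volume()].
#' @param path output path; ".nii.gz" is appended if absent. The sidecar is
#'   written next to it with extension ".json".
#' @param spec,acq optional [phantom_spec()] / [acquisition_setting()] stored
#'   in the sidecar.
#' @return The NIfTI path, invisibly.
#' @export
write_ct_volume <- function(volume, path, spec = NULL, acq = NULL) {
  stopifnot(inherits(volume, "ct_volume"))
  if (!grepl("\\.nii(\\.gz)?$", path)) path <- paste0(path, ".nii.gz")
  img <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(img) <- c(volume$pixel_spacing_mm, volume$pixel_spacing_mm,
                           volume$slice_thickness_mm)
  RNifti::writeNifti(img, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- list(pixel_spacing_mm = volume$pixel_spacing_mm,
               slice_thickness_mm = volume$slice_thickness_mm,
               phantom = if (!is.null(spec)) unclass_deep(spec),
               acquisition = if (!is.null(acq)) unclass(acq))
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a CT volume written by [write_ct_volume()]
#'
#' @param path path to the ".nii.gz" file.
#' @return A [ct_volume()]; the parsed sidecar (if present) is attached as
#'   attribute `"sidecar"`.
#' @export
read_ct_volume <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  vol <- ct_volume(array(as.numeric(img), dim = dim(img)),
                   pixel_spacing_mm = pd[1], slice_thickness_mm = pd[3])
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (file.exists(sidecar))
    attr(vol, "sidecar") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  vol
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}
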