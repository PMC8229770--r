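#' Read a 3D volume from NIfTI or NRRD
#'
#' Supported formats are NIfTI-1 (`.nii`, `.nii.gz`) and NRRD (`.nrrd`), scalar
#' images only.  The file's `(x, y, z)` storage order is mapped onto the
#' package's canonical `(slice, row, col)` axis order with `slice = z`,
#' `row = y`, `col = x`; spacing is taken from the header and intensities are
#' returned unchanged.  No resampling or reorientation beyond this fixed axis
#' mapping is performed.
#'
#' @param path path to a `.nii`, `.nii.gz` or `.nrrd` file.
#' @return A [volume_grid()].
#' @seealso [write_volume()], [read_mask()]
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop(sprintf("format error: file not found: %s", path), call. = FALSE)
  fmt <- volume_format(path)
  if (fmt == "nifti") read_nifti_volume(path) else read_nrrd_volume(path)
}

#' Write a volume or mask to NIfTI or NRRD
#'
#' The file extension selects the format.  Masks are stored as 8-bit integers
#' in NRRD (bit-exact round trip); volumes as doubles.
#'
#' @param grid a [volume_grid()] or [binary_mask()].
#' @param path output path ending in `.nii`, `.nii.gz` or `.nrrd`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path) {
  stopifnot(inherits(grid, "volume_grid") || inherits(grid, "binary_mask"))
  fmt <- volume_format(path)
  a <- grid_data(grid)
  if (fmt == "nifti") {
    xyz <- aperm(a, c(3, 2, 1))                # x = col fastest on disk
    img <- RNifti::asNifti(xyz)
    RNifti::pixdim(img) <- rev(grid$spacing)
    RNifti::writeNifti(img, path)
  } else {
    write_nrrd(a, grid$spacing, path, integer_type = inherits(grid, "binary_mask"))
  }
  invisible(path)
}

#' Read a binary mask paired with a reference volume
#'
#' Reads a stored label image, binarizes it (any value `> 0` becomes 1) and
#' checks that it lives on the same grid as `reference`; shape or spacing
#' disagreement (beyond 1e-4 mm) is an error, never silently resampled.
#'
#' @param path label image file (`.nii`, `.nii.gz`, `.nrrd`).
#' @param reference the [volume_grid()] the mask must be congruent with.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path, reference) {
  stopifnot(inherits(reference, "volume_grid"))
  v <- read_volume(path)
  check_congruent(v, reference)
  binary_mask(array(as.numeric(v$intensities > 0), dim(v$intensities)),
              spacing = reference$spacing, origin_mm = reference$origin_mm)
}

volume_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) return("nrrd")
  stop(sprintf("format error: unsupported extension on '%s' (use .nii, .nii.gz or .nrrd)",
               path), call. = FALSE)
}

read_nifti_volume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf("format error: cannot read '%s': %s",
                                                   path, conditionMessage(e)), call. = FALSE))
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop(sprintf("unsupported image: expected a 3D scalar image, got %dD",
                 length(dim(arr))), call. = FALSE)
  sp_xyz <- RNifti::pixdim(img)[1:3]
  origin <- tryCatch(rev(RNifti::xform(img)[1:3, 4]), error = function(e) c(0, 0, 0))
  volume_grid(aperm(arr, c(3, 2, 1)), spacing = rev(abs(sp_xyz)), origin_mm = origin)
}

read_nrrd_volume <- function(path) {
  nr <- read_nrrd(path)
  if (length(dim(nr$data)) != 3L)
    stop(sprintf("unsupported image: expected a 3D scalar image, got %dD",
                 length(dim(nr$data))), call. = FALSE)
  volume_grid(aperm(nr$data, c(3, 2, 1)), spacing = rev(nr$spacings))
}
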