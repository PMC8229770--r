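#' Volume and mask containers
#'
#' `volume_grid()` wraps a 3D intensity array together with its physical voxel
#' spacing; `binary_mask()` does the same for a \{0, 1\} label array.  The axis
#' convention everywhere in this package is `(slice, row, col)`: index 1 runs
#' along the scan (z) direction and the slice recurrence proceeds in increasing
#' slice index.  Physical coordinates are voxel-centred: voxel `(i, j, k)`
#' (1-based) sits at `origin_mm + (c(i, j, k) - 1) * spacing` mm.
#'
#' @param intensities 3D numeric array, indexed `(slice, row, col)`; all values
#'   must be finite.
#' @param spacing positive numeric triple `(slice_mm, row_mm, col_mm)`.
#' @param origin_mm numeric triple, informational only (defaults to zeros).
#' @return An object of class `volume_grid` (resp. `binary_mask`): a list with
#'   elements `intensities` (resp. `labels`), `spacing` and `origin_mm`.
#' @examples
#' v <- volume_grid(array(0, c(4, 8, 8)), spacing = c(1.25, 1, 1))
#' dim(v$intensities)
#' @export
volume_grid <- function(intensities, spacing = c(1, 1, 1), origin_mm = c(0, 0, 0)) {
  intensities <- check_grid_array(intensities, "intensities")
  spacing <- check_spacing(spacing)
  if (!all(is.finite(intensities)))
    stop("volume_grid: all intensities must be finite", call. = FALSE)
  structure(list(intensities = intensities, spacing = spacing,
                 origin_mm = as.numeric(origin_mm)),
            class = "volume_grid")
}

#' @param labels 3D array with values exactly 0 or 1.
#' @rdname volume_grid
#' @export
binary_mask <- function(labels, spacing = c(1, 1, 1), origin_mm = c(0, 0, 0)) {
  labels <- check_grid_array(labels, "labels")
  spacing <- check_spacing(spacing)
  if (!all(labels %in% c(0, 1)))
    stop("binary_mask: labels must be exactly 0 or 1", call. = FALSE)
  storage.mode(labels) <- "double"
  structure(list(labels = labels, spacing = spacing,
                 origin_mm = as.numeric(origin_mm)),
            class = "binary_mask")
}

check_grid_array <- function(a, what) {
  if (is.matrix(a)) a <- array(a, c(dim(a), 1L))
  if (!is.array(a) || length(dim(a)) != 3L)
    stop(sprintf("%s must be a 3D array, got %s dims", what,
                 paste(dim(a), collapse = "x")), call. = FALSE)
  if (any(dim(a) < 1L)) stop(sprintf("%s has a zero-length dimension", what),
                             call. = FALSE)
  storage.mode(a) <- "double"
  a
}

check_spacing <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite numbers (slice_mm, row_mm, col_mm)",
         call. = FALSE)
  spacing
}

grid_shape <- function(x) dim(if (inherits(x, "binary_mask")) x$labels else x$intensities)

grid_data <- function(x) if (inherits(x, "binary_mask")) x$labels else x$intensities

## Shape + spacing congruence; spacing tolerated to 1e-4 mm (header rounding).
check_congruent <- function(a, b, tol = 1e-4) {
  if (!identical(grid_shape(a), grid_shape(b)))
    stop(sprintf("grid mismatch: shapes %s vs %s",
                 paste(grid_shape(a), collapse = "x"),
                 paste(grid_shape(b), collapse = "x")), call. = FALSE)
  if (any(abs(a$spacing - b$spacing) > tol))
    stop(sprintf("grid mismatch: spacings (%s) vs (%s) differ by more than %g mm",
                 paste(a$spacing, collapse = ", "),
                 paste(b$spacing, collapse = ", "), tol), call. = FALSE)
  invisible(TRUE)
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<volume_grid> %d x %d x %d (slice x row x col), spacing %.4g/%.4g/%.4g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<binary_mask> %d x %d x %d, spacing %.4g/%.4g/%.4g mm, %d foreground voxels\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              sum(x$labels)))
  invisible(x)
}

#' Normalize volume intensities to the unit interval
#'
#' CT-like intensities are clipped to a window and rescaled to `[0, 1]`.  With
#' `window = NULL` the behaviour is adaptive: data already inside `[0, 1]` are
#' passed through unchanged (the phantom regime), anything else is min-max
#' scaled per volume.  A fixed window (e.g. `c(-500, 2000)`, a bone-inclusive
#' CT window in Hounsfield units) makes the mapping scan-independent.
#'
#' @param x numeric array of intensities.
#' @param window `NULL` or a length-2 numeric `c(lo, hi)` clipping window.
#' @return Array of the same shape with values in `[0, 1]`.
#' @export
normalize_intensities <- function(x, window = NULL) {
  if (!is.null(window)) {
    stopifnot(length(window) == 2L, window[2] > window[1])
    x <- pmin(pmax(x, window[1]), window[2])
    return((x - window[1]) / (window[2] - window[1]))
  }
  lo <- min(x); hi <- max(x)
  if (lo >= 0 && hi <= 1) return(x)
  if (hi - lo < .Machine$double.eps) return(array(0, dim(x)))
  (x - lo) / (hi - lo)
}
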