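#' Device geometry of an SD-OCT macular cube
#'
#' Describes the sampling grid of a macular cube: number of B-scans, A-scans
#' per B-scan, depth pixels per A-scan, and the physical en face field. Two
#' named presets cover the common commercial protocols: `"spectralis"`
#' (97 B-scans of 512 A-scans) and `"cirrus"` (128 B-scans of 512 A-scans),
#' both over a 6 mm x 6 mm field. The Spectralis en face field of view is
#' assumed equal to the Cirrus one; override `field_x_mm`/`field_y_mm` for
#' other protocols.
#'
#' En face pixel spacings are derived as
#' `um_per_px_x = 1000 * field_x_mm / n_ascans` (fast axis, along a B-scan)
#' and `um_per_px_y = 1000 * field_y_mm / n_bscans` (slow axis, across
#' B-scans). The slow axis is typically 4-5x coarser, which is why lesion
#' measurements must be anisotropy-corrected (see
#' [greatest_linear_dimension()]).
#'
#' @param preset `"spectralis"`, `"cirrus"`, or `NULL` for a custom grid.
#' @param n_bscans,n_ascans,n_depth Grid dimensions; required when `preset`
#'   is `NULL`. `n_depth` defaults to 496 (Spectralis preset) or 1024
#'   (Cirrus preset).
#' @param field_x_mm,field_y_mm Physical en face field size in millimetres.
#' @return An object of class `oct_geometry`: a list with the grid counts,
#'   field size, and derived `um_per_px_x` / `um_per_px_y` spacings.
#' @examples
#' oct_geometry("spectralis")
#' oct_geometry(n_bscans = 10, n_ascans = 64, n_depth = 32)
#' @export
oct_geometry <- function(preset = NULL, n_bscans = NULL, n_ascans = NULL,
                         n_depth = NULL, field_x_mm = 6, field_y_mm = 6) {
  if (!is.null(preset)) {
    dims <- switch(preset,
      spectralis = list(n_bscans = 97L, n_ascans = 512L, n_depth = 496L),
      cirrus     = list(n_bscans = 128L, n_ascans = 512L, n_depth = 1024L),
      stop("unknown geometry preset: '", preset,
           "' (expected \"spectralis\" or \"cirrus\")", call. = FALSE)
    )
    if (is.null(n_bscans)) n_bscans <- dims$n_bscans
    if (is.null(n_ascans)) n_ascans <- dims$n_ascans
    if (is.null(n_depth))  n_depth  <- dims$n_depth
  }
  if (is.null(n_bscans) || is.null(n_ascans) || is.null(n_depth)) {
    stop("supply a preset or all of n_bscans, n_ascans, n_depth",
         call. = FALSE)
  }
  counts <- c(n_bscans = n_bscans, n_ascans = n_ascans, n_depth = n_depth)
  if (any(counts < 1) || any(counts != as.integer(counts))) {
    stop("grid counts must be positive integers", call. = FALSE)
  }
  if (field_x_mm <= 0 || field_y_mm <= 0) {
    stop("field size must be positive", call. = FALSE)
  }
  structure(
    list(
      n_bscans = as.integer(n_bscans),
      n_ascans = as.integer(n_ascans),
      n_depth = as.integer(n_depth),
      field_x_mm = as.numeric(field_x_mm),
      field_y_mm = as.numeric(field_y_mm),
      um_per_px_x = 1000 * field_x_mm / n_ascans,
      um_per_px_y = 1000 * field_y_mm / n_bscans,
      preset = if (is.null(preset)) NA_character_ else preset
    ),
    class = "oct_geometry"
  )
}

#' @export
print.oct_geometry <- function(x, ...) {
  cat(sprintf(
    "<oct_geometry%s> %d B-scans x %d A-scans x %d depth px over %.1f x %.1f mm\n",
    if (is.na(x$preset)) "" else paste0(": ", x$preset),
    x$n_bscans, x$n_ascans, x$n_depth, x$field_x_mm, x$field_y_mm
  ))
  cat(sprintf("  en face spacing: %.2f um/px (x), %.2f um/px (y)\n",
              x$um_per_px_x, x$um_per_px_y))
  invisible(x)
}

assert_geometry <- function(geometry) {
  if (!inherits(geometry, "oct_geometry")) {
    stop("`geometry` must be an oct_geometry object", call. = FALSE)
  }
  invisible(geometry)
}
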