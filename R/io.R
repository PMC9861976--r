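#' Read and write intensity cubes as multipage TIFF
#'
#' A cube is a list of `n_bscans` matrices, each `n_depth x n_ascans`.
#' Integer-valued data in `[0, 255]` round-trips losslessly through 8-bit
#' pages; other data is written as 32-bit float.
#'
#' @param cube List of equally-sized numeric matrices.
#' @param path TIFF file path.
#' @return `read_cube()` returns the list of matrices; `write_cube()`
#'   returns `path` invisibly.
#' @export
write_cube <- function(cube, path) {
  dims <- vapply(cube, dim, integer(2))
  if (nrow(unique(t(dims))) != 1) {
    stop("ragged page sizes: all B-scans must share one shape",
         call. = FALSE)
  }
  ints <- all(vapply(cube, function(m) all(m == round(m)) &&
                       min(m) >= 0 && max(m) <= 255, TRUE))
  if (ints) {
    tiff::writeTIFF(lapply(cube, function(m) m / 255), path,
                    bits.per.sample = 8)
  } else {
    tiff::writeTIFF(cube, path, bits.per.sample = 32, reduce = FALSE)
  }
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, dim, integer(2))
  if (nrow(unique(t(dims))) != 1) {
    stop("ragged page sizes in ", path, call. = FALSE)
  }
  attr(pages, "integer_range") <- NULL
  pages
}

#' Read and write layer boundary tables as CSV
#'
#' The boundary dialect is one row per (B-scan, A-scan) with columns
#' `bscan_index`, `ascan_index` (0-based integers) and real-valued
#' `ez_row`, `rpe_row`, `bm_row`; a blank cell marks an undefined boundary
#' (such columns are never flagged as GA). Values round-trip to 1e-6.
#'
#' @param layers Layer tibble.
#' @param path CSV file path.
#' @param geometry Optional [oct_geometry()] used to validate row ranges.
#' @return `read_layers()` returns the layer tibble.
#' @export
write_layers <- function(layers, path) {
  readr::write_csv(
    layers[, c("bscan_index", "ascan_index", "ez_row", "rpe_row", "bm_row")],
    path)
  invisible(path)
}

#' @rdname write_layers
#' @export
read_layers <- function(path, geometry = NULL) {
  layers <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("bscan_index", "ascan_index", "ez_row", "rpe_row", "bm_row")
  missing_cols <- setdiff(req, names(layers))
  if (length(missing_cols) > 0) {
    stop("layer CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(layers[, c("bscan_index", "ascan_index")])
  if (any(dup)) {
    d <- layers[which(dup)[1], ]
    stop(sprintf("duplicate (bscan %d, ascan %d) row in %s",
                 d$bscan_index, d$ascan_index, path), call. = FALSE)
  }
  if (!is.null(geometry)) {
    assert_geometry(geometry)
    for (col in c("ez_row", "rpe_row", "bm_row")) {
      bad <- which(!is.na(layers[[col]]) &
                     (layers[[col]] < 0 | layers[[col]] >= geometry$n_depth))
      if (length(bad) > 0) {
        stop(sprintf(
          "out-of-range %s at (bscan %d, ascan %d): %g not in [0, %d)",
          col, layers$bscan_index[bad[1]], layers$ascan_index[bad[1]],
          layers[[col]][bad[1]], geometry$n_depth), call. = FALSE)
      }
    }
  }
  layers
}

geometry_to_list <- function(geometry) {
  geometry[c("n_bscans", "n_ascans", "n_depth", "field_x_mm", "field_y_mm")]
}

geometry_from_list <- function(x) {
  oct_geometry(NULL, n_bscans = x$n_bscans, n_ascans = x$n_ascans,
               n_depth = x$n_depth, field_x_mm = x$field_x_mm,
               field_y_mm = x$field_y_mm)
}

#' Read and write en face maps
#'
#' Binary maps are stored as 0/255 PNG; confidence maps as 32-bit float
#' TIFF. A JSON sidecar (`<path>.json`) records the geometry and map kind.
#'
#' @param map An [enface_map()].
#' @param path Image file path (`.png` for binary, `.tif`/`.tiff` for
#'   confidence).
#' @return `read_enface()` returns the [enface_map()].
#' @export
write_enface <- function(map, path) {
  kind <- attr(map, "kind")
  vals <- unclass(map)
  if (kind %in% c("truth", "prediction")) {
    png::writePNG(matrix(as.numeric(vals), nrow(vals), ncol(vals)),
                  path)  # 0/1 -> 0/255 grayscale
  } else {
    tiff::writeTIFF(vals, path, bits.per.sample = 32)
  }
  sidecar <- list(kind = kind,
                  geometry = geometry_to_list(attr(map, "geometry")))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_enface
#' @export
read_enface <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"),
                                 simplifyVector = TRUE)
  geometry <- geometry_from_list(sidecar$geometry)
  vals <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    round(png::readPNG(path))
  } else {
    tiff::readTIFF(path)
  }
  enface_map(vals, geometry, kind = sidecar$kind)
}

#' Serialize a lesion report
#'
#' Writes the per-lesion table as CSV (one row per lesion) and the full
#' report -- lesion table plus area summaries -- as JSON.
#'
#' @param report A `lesion_report`.
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @return The report, invisibly.
#' @export
write_lesion_report <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "lesion_report"))
  if (!is.null(csv_path)) readr::write_csv(report$lesions, csv_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(lesions = report$lesions,
           area_percent_all = report$area_percent_all,
           area_percent_crora_only = report$area_percent_crora_only,
           threshold_um = report$threshold_um),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}

#' Pipeline configuration files
#'
#' YAML configuration covering every tunable of the pipeline; values
#' omitted from the file keep the documented module defaults. Unknown keys
#' are rejected.
#'
#' @param path YAML file path.
#' @param overrides Named list applied on top of the file (e.g. parsed CLI
#'   flags).
#' @return Named list of configuration values.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown) > 0) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(user)] <- user
  }
  cfg[names(overrides)] <- overrides
  stopifnot(cfg$tol_px >= 0, cfg$thickness_px >= 1,
            cfg$connectivity %in% c(4, 8), cfg$threshold_um > 0,
            cfg$binarize_threshold >= 0, cfg$binarize_threshold <= 1)
  cfg
}

default_config <- function() {
  list(
    preset = "spectralis",
    tol_px = 0.5,
    thickness_px = 10L,
    connectivity = 8L,
    threshold_um = 250,
    binarize_threshold = 0.5,
    icc_variant = "agreement",
    seed = 1L
  )
}
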