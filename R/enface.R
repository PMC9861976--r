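#' En face map container
#'
#' A 2-D en face view of the macular cube: one row per B-scan (no vertical
#' rescaling), columns along the fast axis, values either binary or model
#' confidence in `[0, 1]`.
#'
#' @param values Numeric matrix with `n_bscans` rows.
#' @param geometry An [oct_geometry()].
#' @param kind One of `"truth"`, `"prediction"`, `"confidence"`,
#'   `"intensity"`.
#' @return An `enface_map` object (matrix with attributes).
#' @export
enface_map <- function(values, geometry,
                       kind = c("truth", "prediction", "confidence",
                                "intensity")) {
  assert_geometry(geometry)
  kind <- match.arg(kind)
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  if (nrow(values) != geometry$n_bscans) {
    stop("en face map must have one row per B-scan (", geometry$n_bscans,
         "), got ", nrow(values), call. = FALSE)
  }
  if (kind %in% c("truth", "prediction") &&
      !all(values %in% c(0, 1))) {
    stop("binary en face map contains values other than 0/1", call. = FALSE)
  }
  if (kind == "confidence" && (min(values) < 0 || max(values) > 1)) {
    stop("confidence values must lie in [0, 1]", call. = FALSE)
  }
  structure(values, class = c("enface_map", "matrix"),
            geometry = geometry, kind = kind)
}

#' @export
as.matrix.enface_map <- function(x, ...) {
  v <- unclass(x)
  attr(v, "geometry") <- NULL
  attr(v, "kind") <- NULL
  v
}

#' @export
print.enface_map <- function(x, ...) {
  cat(sprintf("<enface_map: %s> %d x %d, %.1f%% positive\n",
              attr(x, "kind"), nrow(x), ncol(x),
              100 * mean(x > if (attr(x, "kind") == "intensity") Inf else 0)))
  invisible(x)
}

# Partition assignment of source columns to target columns for block-max
# resizing: 0-based source column j belongs to target floor(j * target / W).
block_assignment <- function(W, target_width) {
  floor((0:(W - 1)) * target_width / W)
}

#' Compile per-B-scan GA masks into an en face GA map
#'
#' Three steps, matching how en face ground truth is assembled from B-scan
#' masks: (1) each mask is reduced to a row by taking the maximum over depth
#' in every column; (2) the row is resized horizontally to `target_width`
#' by block maximum (each target column takes the max of the source columns
#' assigned to it; binary masks must not be interpolated, which would
#' create fractional values and erase single-column lesions); (3) row `b`
#' of the map is the reduced row of B-scan `b` -- one vertical pixel per
#' B-scan, no vertical rescaling.
#'
#' @param masks A `ga_mask_stack` from [mask_volume()] /
#'   [project_to_bscans()], or a plain list of `ga_mask` objects.
#' @param geometry An [oct_geometry()]; defaults to the stack's attribute.
#' @param target_width Width of the en face map; defaults to the mask width
#'   (identity resize).
#' @param kind Map kind label, default `"truth"`.
#' @return An [enface_map()] with `n_bscans` rows and `target_width`
#'   columns.
#' @export
compile_enface <- function(masks, geometry = attr(masks, "geometry"),
                           target_width = NULL, kind = "truth") {
  assert_geometry(geometry)
  widths <- vapply(masks, function(m) ncol(m$mask), 0L)
  if (length(unique(widths)) != 1) {
    stop("masks have inconsistent widths", call. = FALSE)
  }
  W <- widths[1]
  if (is.null(target_width)) target_width <- W
  if (target_width < 1) stop("target_width must be positive", call. = FALSE)
  if (target_width > W) {
    stop("target_width exceeds the mask width; block-max resize only ",
         "shrinks", call. = FALSE)
  }
  assign_to <- factor(block_assignment(W, target_width),
                      levels = 0:(target_width - 1))
  rows <- vapply(masks, function(m) {
    colmax <- as.integer(colSums(m$mask) > 0)
    as.integer(vapply(split(colmax, assign_to), max, 0L))
  }, integer(target_width))
  enface_map(t(rows), geometry, kind = kind)
}

#' Binarize a confidence map
#'
#' @param map An [enface_map()] or numeric matrix.
#' @param threshold Confidence cut; pixels `>= threshold` become positive.
#'   The positive set shrinks monotonically as the threshold rises.
#' @return A binary map of the same shape (an `enface_map` of kind
#'   `"prediction"` when the input carries a geometry).
#' @export
binarize <- function(map, threshold = 0.5) {
  vals <- (unclass(map) >= threshold) * 1L
  dim(vals) <- dim(map)
  g <- attr(map, "geometry")
  if (!is.null(g)) enface_map(vals, g, kind = "prediction") else vals
}

#' Binary GA presence
#'
#' A map or mask is called GA-positive iff it has at least one positive
#' pixel -- any number of labelled pixels counts as presence. Confidence
#' inputs are binarized at `threshold` first.
#'
#' @param x An [enface_map()], `ga_mask`, or binary matrix.
#' @param threshold Binarization threshold for confidence inputs.
#' @return Logical scalar.
#' @export
detect_presence <- function(x, threshold = 0.5) {
  if (inherits(x, "ga_mask")) x <- x$mask
  if (length(x) == 0) stop("empty input", call. = FALSE)
  if (identical(attr(x, "kind"), "confidence")) x <- binarize(x, threshold)
  any(unclass(x) > 0)
}

#' Project an en face map back onto B-scans along the BM line
#'
#' Inverse of [compile_enface()] at en face resolution: every positive map
#' pixel `(b, x)` marks the B-scan columns assigned to map column `x`
#' (nearest-source-column expansion when the map is narrower than the
#' B-scan), and each marked column receives a `thickness_px` band centered
#' on the BM row, with the same band convention as [build_bscan_mask()].
#' At matched widths, `compile_enface(project_to_bscans(M))` reproduces `M`
#' exactly.
#'
#' @param map Binary [enface_map()].
#' @param layers Layer tibble supplying `bm_row` per column.
#' @param geometry An [oct_geometry()]; defaults to the map's.
#' @param thickness_px Band thickness in pixels.
#' @return A `ga_mask_stack`.
#' @export
project_to_bscans <- function(map, layers,
                              geometry = attr(map, "geometry"),
                              thickness_px = 10) {
  assert_geometry(geometry)
  if (!all(unclass(map) %in% c(0, 1))) {
    stop("projection requires a binary map; binarize() it first",
         call. = FALSE)
  }
  W <- geometry$n_ascans
  assign_to <- block_assignment(W, ncol(map))
  masks <- lapply(0:(geometry$n_bscans - 1), function(b) {
    sub <- layers[layers$bscan_index == b, ]
    sub <- sub[order(sub$ascan_index), ]
    if (nrow(sub) != W) {
      stop("missing BM rows for B-scan ", b, call. = FALSE)
    }
    ga_cols <- unclass(map)[b + 1, assign_to + 1] > 0
    ga_cols[is.na(sub$bm_row) & ga_cols] <- FALSE
    build_bscan_mask(ga_cols, sub$bm_row, geometry$n_depth, thickness_px,
                     bscan_index = b)
  })
  structure(masks, class = "ga_mask_stack", geometry = geometry)
}

#' Mean-projection en face intensity image
#'
#' Averages each A-scan over depth, giving the standard en face projection
#' of the whole cube (no custom sub-RPE slab). Atrophic columns appear
#' bright through sub-BM hypertransmission, which is the contrast the
#' en face segmentation model learns from.
#'
#' @param intensity List of B-scan matrices (`n_depth` x `n_ascans`), e.g.
#'   `phantom$intensity`.
#' @param geometry An [oct_geometry()].
#' @return An [enface_map()] of kind `"intensity"`.
#' @export
enface_intensity <- function(intensity, geometry) {
  assert_geometry(geometry)
  rows <- vapply(intensity, colMeans, numeric(geometry$n_ascans))
  enface_map(t(rows), geometry, kind = "intensity")
}
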