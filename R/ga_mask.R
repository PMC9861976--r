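#' Detect GA columns as confluence of the EZ, RPE and BM lines
#'
#' Flags each A-scan column in which the three retinal boundary lines are
#' concurrent: the EZ-RPE thickness (`rpe_row - ez_row`) and the RPE-BM
#' thickness (`bm_row - rpe_row`) are both at most `tol_px`. Since boundary
#' rows are sub-pixel reals, "zero thickness" is read as thickness below
#' half a pixel by default. Columns where any boundary is undefined (`NA`)
#' are never flagged: the rule requires all three lines to be present and
#' concurrent.
#'
#' @param layers Tibble with columns `bscan_index`, `ascan_index`, `ez_row`,
#'   `rpe_row`, `bm_row` (see [render_layers()] / [read_layers()]).
#' @param tol_px Per-gap concurrence tolerance in depth pixels
#'   (default 0.5). The flagged set grows monotonically with `tol_px`.
#' @return The input tibble with a logical `ga` column appended.
#' @export
detect_confluence <- function(layers, tol_px = 0.5) {
  stopifnot(tol_px >= 0)
  req <- c("bscan_index", "ascan_index", "ez_row", "rpe_row", "bm_row")
  missing_cols <- setdiff(req, names(layers))
  if (length(missing_cols) > 0) {
    stop("layers is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dplyr::mutate(
    layers,
    ga = !is.na(.data$ez_row) & !is.na(.data$rpe_row) & !is.na(.data$bm_row) &
      (.data$rpe_row - .data$ez_row) <= tol_px &
      (.data$bm_row - .data$rpe_row) <= tol_px
  )
}

# Half-up rounding; round() would use banker's rounding, which makes mask
# placement depend on the parity of the nearest even row.
round_half_up <- function(x) floor(x + 0.5)

#' Rasterize GA columns into a dilated B-scan ground-truth mask
#'
#' For every flagged column with BM at (sub-pixel) row `r`, the mask is a
#' vertical band of `thickness_px` pixels centered on the BM line: 0-based
#' rows `[round(r) - floor(t/2), round(r) + ceiling(t/2))`, intersected with
#' the image. With the default even thickness of 10 the band covers 5 pixels
#' above the rounded BM row and 4 below it plus the row itself; any fixed
#' convention satisfies "centered on", and this one is documented and
#' tested. Unflagged columns are all zero.
#'
#' @param ga_columns Logical vector of flagged columns.
#' @param bm_row Numeric vector of BM row positions, same length.
#' @param n_depth Image depth in pixels.
#' @param thickness_px Band thickness in pixels (default 10).
#' @param bscan_index Optional 0-based B-scan index carried on the mask.
#' @return An object of class `ga_mask`: list with the logical `mask`
#'   matrix (`n_depth` x `n_ascans`), `ga_columns`, `bm_row`, and
#'   `bscan_index`.
#' @export
build_bscan_mask <- function(ga_columns, bm_row, n_depth, thickness_px = 10,
                             bscan_index = NA_integer_) {
  stopifnot(thickness_px >= 1, n_depth >= 1)
  if (length(ga_columns) != length(bm_row)) {
    stop("ga_columns and bm_row lengths differ", call. = FALSE)
  }
  nx <- length(ga_columns)
  mask <- matrix(FALSE, n_depth, nx)
  up <- floor(thickness_px / 2)
  down <- ceiling(thickness_px / 2)
  for (j in which(ga_columns & !is.na(bm_row))) {
    r <- round_half_up(bm_row[j])
    lo <- max(0, r - up)
    hi <- min(n_depth - 1, r + down - 1)
    if (lo <= hi) mask[(lo + 1):(hi + 1), j] <- TRUE
  }
  structure(
    list(mask = mask, ga_columns = ga_columns, bm_row = bm_row,
         bscan_index = bscan_index),
    class = "ga_mask"
  )
}

#' Build dilated GA ground-truth masks for a whole volume
#'
#' Applies [detect_confluence()] and [build_bscan_mask()] to every B-scan of
#' a layer table, preserving B-scan order. This is the rule-based
#' ground-truth generator: layer confluence defines GA, and the mask is the
#' 10-pixel band on the BM line used for model training and en face
#' compilation.
#'
#' @inheritParams detect_confluence
#' @param geometry An [oct_geometry()]; supplies `n_ascans` (validated) and
#'   `n_depth`.
#' @param thickness_px Band thickness passed to [build_bscan_mask()].
#' @return An object of class `ga_mask_stack`: list of `ga_mask`, one per
#'   B-scan, with the geometry attached as an attribute.
#' @export
mask_volume <- function(layers, geometry, tol_px = 0.5, thickness_px = 10) {
  assert_geometry(geometry)
  flagged <- detect_confluence(layers, tol_px)
  bscans <- sort(unique(flagged$bscan_index))
  expected <- 0:(geometry$n_bscans - 1)
  if (!identical(as.integer(bscans), expected)) {
    stop("layer table does not cover B-scans 0..", geometry$n_bscans - 1,
         call. = FALSE)
  }
  split_idx <- split(seq_len(nrow(flagged)), flagged$bscan_index)
  masks <- lapply(expected, function(b) {
    rows <- split_idx[[as.character(b)]]
    sub <- flagged[rows, ]
    sub <- sub[order(sub$ascan_index), ]
    if (nrow(sub) != geometry$n_ascans) {
      stop("B-scan ", b, " has ", nrow(sub), " columns, expected ",
           geometry$n_ascans, call. = FALSE)
    }
    build_bscan_mask(sub$ga, sub$bm_row, geometry$n_depth, thickness_px,
                     bscan_index = b)
  })
  structure(masks, class = "ga_mask_stack", geometry = geometry)
}
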