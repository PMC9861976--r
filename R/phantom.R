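#' Sample elliptical atrophic lesions within the en face field
#'
#' Draws reproducible lesion specifications for the phantom generator. Each
#' lesion is an ellipse in physical en face coordinates (micrometres, origin
#' at the corner of the field). The *full* major axis (twice the larger
#' semi-axis) is drawn uniformly from `axis_range_um`, the minor/major aspect
#' ratio uniformly from `aspect_range`, and the orientation uniformly in
#' `[0, pi)`. Centers are resampled until every pairwise center distance
#' exceeds the sum of the two bounding radii plus `gap_um`, so lesions stay
#' disjoint en face components.
#'
#' @param geometry An [oct_geometry()].
#' @param n_lesions Number of lesions (0 gives an empty specification).
#' @param axis_range_um Range of the full major-axis length, in micrometres.
#' @param aspect_range Range of the minor/major semi-axis ratio.
#' @param gap_um Minimum clearance between lesion bounding circles.
#' @param seed Optional integer seed; the global RNG state is restored on
#'   exit.
#' @param max_tries Bounded rejection-sampling retries per lesion before the
#'   packing is declared infeasible.
#' @return A tibble with one row per lesion: `center_x_um`, `center_y_um`,
#'   `semi_axis_a_um` (major), `semi_axis_b_um` (minor), `rotation_rad`.
#' @examples
#' g <- oct_geometry("spectralis")
#' sample_lesions(g, 3, seed = 1)
#' @export
sample_lesions <- function(geometry, n_lesions,
                           axis_range_um = c(100, 600),
                           aspect_range = c(0.4, 1),
                           gap_um = 150,
                           seed = NULL,
                           max_tries = 500L) {
  assert_geometry(geometry)
  stopifnot(n_lesions >= 0, length(axis_range_um) == 2,
            all(axis_range_um > 0), diff(axis_range_um) >= 0)
  if (!is.null(seed)) withr::local_seed(seed)
  empty <- tibble::tibble(
    center_x_um = numeric(), center_y_um = numeric(),
    semi_axis_a_um = numeric(), semi_axis_b_um = numeric(),
    rotation_rad = numeric()
  )
  if (n_lesions == 0) return(empty)

  fx <- 1000 * geometry$field_x_mm
  fy <- 1000 * geometry$field_y_mm
  out <- empty
  for (i in seq_len(n_lesions)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      a <- stats::runif(1, axis_range_um[1], axis_range_um[2]) / 2
      b <- a * stats::runif(1, aspect_range[1], aspect_range[2])
      if (2 * a + 2 > min(fx, fy)) {
        stop("lesion axis range exceeds the en face field", call. = FALSE)
      }
      cx <- stats::runif(1, a, fx - a)
      cy <- stats::runif(1, a, fy - a)
      ok <- TRUE
      if (nrow(out) > 0) {
        d <- sqrt((out$center_x_um - cx)^2 + (out$center_y_um - cy)^2)
        ok <- all(d > out$semi_axis_a_um + a + gap_um)
      }
      if (ok) {
        out <- dplyr::bind_rows(out, tibble::tibble(
          center_x_um = cx, center_y_um = cy,
          semi_axis_a_um = a, semi_axis_b_um = b,
          rotation_rad = stats::runif(1, 0, pi)
        ))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place ", n_lesions, " disjoint lesions after ",
           max_tries, " tries; reduce n_lesions or axis_range_um",
           call. = FALSE)
    }
  }
  out
}

# Ellipse membership of physical points (micrometres), vectorized over points.
inside_any_lesion <- function(x_um, y_um, lesions) {
  if (nrow(lesions) == 0) return(rep(FALSE, length(x_um)))
  inside <- rep(FALSE, length(x_um))
  for (i in seq_len(nrow(lesions))) {
    dx <- x_um - lesions$center_x_um[i]
    dy <- y_um - lesions$center_y_um[i]
    th <- lesions$rotation_rad[i]
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    inside <- inside |
      (u^2 / lesions$semi_axis_a_um[i]^2 +
         v^2 / lesions$semi_axis_b_um[i]^2 <= 1)
  }
  inside
}

#' Analytic en face lesion footprint
#'
#' Rasterizes the union of lesion ellipses onto the en face grid. A pixel
#' `(b, x)` (0-based B-scan row, A-scan column) is positive iff the physical
#' center of that grid cell, at `((x + 0.5) * um_per_px_x,
#' (b + 0.5) * um_per_px_y)`, lies inside at least one ellipse. This
#' pixel-center rule is the truth oracle every downstream stage is checked
#' against; it makes rasterization unambiguous at lesion boundaries.
#'
#' @inheritParams sample_lesions
#' @param lesions Lesion tibble as returned by [sample_lesions()].
#' @return A binary integer matrix with `n_bscans` rows and `n_ascans`
#'   columns.
#' @export
analytic_enface <- function(geometry, lesions) {
  assert_geometry(geometry)
  xs <- (seq_len(geometry$n_ascans) - 0.5) * geometry$um_per_px_x
  ys <- (seq_len(geometry$n_bscans) - 0.5) * geometry$um_per_px_y
  grid_x <- rep(xs, each = geometry$n_bscans)
  grid_y <- rep(ys, times = geometry$n_ascans)
  m <- matrix(as.integer(inside_any_lesion(grid_x, grid_y, lesions)),
              nrow = geometry$n_bscans)
  m
}

# Smooth low-frequency undulation field over the (b, x) grid: a seeded sum of
# separable sinusoids, rescaled so max |u| equals `amp` (0 if amp == 0).
undulation_field <- function(geometry, amp, n_waves = 3L) {
  nb <- geometry$n_bscans
  nx <- geometry$n_ascans
  u <- matrix(0, nb, nx)
  if (amp <= 0) return(u)
  for (k in seq_len(n_waves)) {
    fx <- stats::runif(1, 0.5, 2.5)
    fb <- stats::runif(1, 0.5, 2.5)
    phx <- stats::runif(1, 0, 2 * pi)
    phb <- stats::runif(1, 0, 2 * pi)
    w <- stats::runif(1, 0.5, 1)
    u <- u + w *
      (sin(2 * pi * fb * (seq_len(nb) - 0.5) / nb + phb) %o%
         sin(2 * pi * fx * (seq_len(nx) - 0.5) / nx + phx))
  }
  u * (amp / max(abs(u)))
}

#' Render per-B-scan retinal layer boundaries for a phantom
#'
#' Produces EZ, RPE and BM boundary row positions (sub-pixel reals, row 0 at
#' the vitreous side) for every column of every B-scan. Outside lesions the
#' three boundaries ride a shared smooth undulation with fixed positive
#' EZ-RPE and RPE-BM separations; at any column whose en face pixel center
#' falls inside a lesion ellipse all three boundaries collapse onto the BM
#' row, so the measured EZ-RPE and RPE-BM thicknesses are exactly zero.
#' This zero-thickness confluence is the rule-based definition of geographic
#' atrophy that [detect_confluence()] later recovers.
#'
#' @inheritParams analytic_enface
#' @param smooth_amp_px Peak amplitude of the BM undulation, in depth pixels.
#' @param ez_rpe_px,rpe_bm_px Healthy EZ-RPE and RPE-BM separations in depth
#'   pixels.
#' @param bm_center_frac BM resting depth as a fraction of `n_depth`.
#' @param seed Optional seed for the undulation phases.
#' @return A tibble with columns `bscan_index`, `ascan_index` (0-based),
#'   `ez_row`, `rpe_row`, `bm_row`.
#' @export
render_layers <- function(geometry, lesions,
                          smooth_amp_px = 6,
                          ez_rpe_px = 8, rpe_bm_px = 5,
                          bm_center_frac = 0.55,
                          seed = NULL) {
  assert_geometry(geometry)
  if (!is.null(seed)) withr::local_seed(seed)
  nb <- geometry$n_bscans
  nx <- geometry$n_ascans
  bm0 <- bm_center_frac * geometry$n_depth
  u <- undulation_field(geometry, smooth_amp_px)
  bm <- bm0 + u
  if (min(bm) - ez_rpe_px - rpe_bm_px < 1 || max(bm) > geometry$n_depth - 2) {
    stop("undulation amplitude pushes boundaries out of the depth range",
         call. = FALSE)
  }
  truth <- analytic_enface(geometry, lesions) == 1
  ez <- bm - rpe_bm_px - ez_rpe_px
  rpe <- bm - rpe_bm_px
  ez[truth] <- bm[truth]
  rpe[truth] <- bm[truth]
  tibble::tibble(
    bscan_index = rep(0:(nb - 1), times = nx),
    ascan_index = rep(0:(nx - 1), each = nb),
    ez_row = as.vector(ez),
    rpe_row = as.vector(rpe),
    bm_row = as.vector(bm)
  ) |>
    dplyr::arrange(.data$bscan_index, .data$ascan_index)
}

#' Render a synthetic B-scan reflectivity image
#'
#' Builds a banded intensity image from one B-scan's layer boundaries:
#' inner retina above the EZ line, a bright EZ band, an RPE band, and the
#' choroid below BM. In columns where the boundaries are confluent (atrophy)
#' the EZ/RPE bands have zero height and the sub-BM choroid is rendered
#' `hyper_gain` times brighter, emulating hypertransmission of light through
#' the atrophic RPE. Before noise, the sub-BM mean intensity ratio between
#' confluent and non-confluent columns is exactly `hyper_gain`.
#'
#' @param layers Layer tibble (as from [render_layers()]) for the whole
#'   volume or a single B-scan.
#' @param geometry An [oct_geometry()].
#' @param bscan_index Which B-scan to render (0-based).
#' @param hyper_gain Sub-BM brightness factor in atrophic columns; must
#'   exceed 1 so the lesion has learnable contrast.
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param seed Optional seed for the noise.
#' @return A numeric matrix of size `n_depth` x `n_ascans` with values
#'   approximately in `[0, 1]`.
#' @export
render_intensity <- function(layers, geometry, bscan_index = 0,
                             hyper_gain = 2, noise_sd = 0.05, seed = NULL) {
  assert_geometry(geometry)
  if (hyper_gain <= 1) {
    stop("hyper_gain must be > 1 (no hypertransmission contrast otherwise)",
         call. = FALSE)
  }
  ls <- dplyr::filter(layers, .data$bscan_index == !!bscan_index) |>
    dplyr::arrange(.data$ascan_index)
  if (nrow(ls) != geometry$n_ascans) {
    stop("layer set for B-scan ", bscan_index, " has ", nrow(ls),
         " columns, expected ", geometry$n_ascans, call. = FALSE)
  }
  if (!is.null(seed)) withr::local_seed(seed)
  nd <- geometry$n_depth
  nx <- geometry$n_ascans
  rows <- matrix(seq_len(nd) - 0.5, nd, nx)  # pixel centers, 0-based rows
  confluent <- (ls$rpe_row - ls$ez_row) <= 1e-9 &
    (ls$bm_row - ls$rpe_row) <= 1e-9
  lv <- phantom_band_levels()
  # paint from the deepest band up; confluent columns keep zero-height
  # EZ/RPE bands and a hypertransmissive choroid
  img <- matrix(rep(lv$choroid * ifelse(confluent, hyper_gain, 1),
                    each = nd), nd, nx)
  img[rows < rep(ls$bm_row, each = nd)] <- lv$rpe
  img[rows < rep(ls$rpe_row, each = nd)] <- lv$ez
  img[rows < rep(ls$ez_row, each = nd)] <- lv$inner
  if (noise_sd > 0) img <- img + stats::rnorm(length(img), sd = noise_sd)
  img
}

phantom_band_levels <- function() {
  list(inner = 0.30, ez = 0.85, rpe = 0.75, choroid = 0.20)
}

#' Simulate a complete synthetic macular cube
#'
#' One-call phantom generator: samples lesions, renders layer boundaries,
#' optionally renders every B-scan's intensity image, and attaches the
#' analytic en face truth footprint. All randomness is derived from `seed`,
#' so identical arguments reproduce the volume bit for bit.
#'
#' @inheritParams sample_lesions
#' @inheritParams render_intensity
#' @param n_lesions Number of elliptical lesions.
#' @param smooth_amp_px Layer undulation amplitude in depth pixels.
#' @param render Logical; render intensity B-scans (the slow part)? Layer
#'   boundaries and the truth map are always produced.
#' @return An object of class `oct_phantom`: list with `geometry`, `lesions`
#'   (tibble), `layers` (tibble), `intensity` (list of `n_depth x n_ascans`
#'   matrices, or `NULL`), `truth_enface` (binary matrix), and `seed`.
#' @examples
#' ph <- simulate_phantom(oct_geometry(n_bscans = 12, n_ascans = 64,
#'                                     n_depth = 48),
#'                        n_lesions = 1, seed = 3, render = FALSE)
#' sum(ph$truth_enface)
#' @export
simulate_phantom <- function(geometry, n_lesions = 3,
                             axis_range_um = c(100, 600),
                             aspect_range = c(0.4, 1),
                             smooth_amp_px = 6,
                             hyper_gain = 2, noise_sd = 0.05,
                             render = TRUE, seed = NULL) {
  assert_geometry(geometry)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  lesions <- sample_lesions(geometry, n_lesions, axis_range_um,
                            aspect_range, seed = seed)
  layers <- render_layers(geometry, lesions, smooth_amp_px = smooth_amp_px,
                          seed = seed + 1L)
  truth <- analytic_enface(geometry, lesions)
  intensity <- NULL
  if (render) {
    intensity <- lapply(0:(geometry$n_bscans - 1), function(b) {
      render_intensity(layers, geometry, b, hyper_gain = hyper_gain,
                       noise_sd = noise_sd, seed = seed + 2L + b)
    })
  }
  structure(
    list(geometry = geometry, lesions = lesions, layers = layers,
         intensity = intensity, truth_enface = truth, seed = seed),
    class = "oct_phantom"
  )
}

#' @export
print.oct_phantom <- function(x, ...) {
  cat(sprintf("<oct_phantom> seed %d, %d lesion(s), %s\n", x$seed,
              nrow(x$lesions),
              if (is.null(x$intensity)) "boundaries only" else
                "with intensity cube"))
  print(x$geometry)
  invisible(x)
}
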