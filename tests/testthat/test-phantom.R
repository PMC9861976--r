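test_that("lesion sampling is reproducible, bounded, and packable", {
  g <- oct_geometry("spectralis")
  expect_equal(nrow(sample_lesions(g, 0)), 0)
  l1 <- sample_lesions(g, 5, axis_range_um = c(100, 600), seed = 11)
  l2 <- sample_lesions(g, 5, axis_range_um = c(100, 600), seed = 11)
  expect_identical(l1, l2)
  full_axes <- 2 * l1$semi_axis_a_um
  expect_true(all(full_axes >= 100 & full_axes <= 600))
  expect_true(all(l1$semi_axis_b_um <= l1$semi_axis_a_um))
  # lesions fit inside the field
  fx <- 1000 * g$field_x_mm
  expect_true(all(l1$center_x_um - l1$semi_axis_a_um >= 0))
  expect_true(all(l1$center_x_um + l1$semi_axis_a_um <= fx))
  # pairwise separation keeps components distinct
  d <- as.matrix(stats::dist(cbind(l1$center_x_um, l1$center_y_um)))
  bound <- outer(l1$semi_axis_a_um, l1$semi_axis_a_um, "+")
  expect_true(all(d[upper.tri(d)] > bound[upper.tri(bound)]))
  # infeasible packing errors out
  expect_error(
    sample_lesions(tiny_geometry(6, 6, 8, fx = 0.5, fy = 0.5), 8,
                   axis_range_um = c(400, 400), max_tries = 10),
    "axis range|disjoint")
})

test_that("layer rendering collapses all three boundaries inside lesions", {
  g <- tiny_geometry(20, 80, 60)
  lesions <- sample_lesions(g, 2, axis_range_um = c(600, 1500), seed = 2)
  layers <- render_layers(g, lesions, seed = 3)
  truth <- analytic_enface(g, lesions)
  inside <- truth[cbind(layers$bscan_index + 1, layers$ascan_index + 1)] == 1
  expect_true(any(inside) && any(!inside))
  expect_equal(layers$rpe_row[inside] - layers$ez_row[inside],
               rep(0, sum(inside)))
  expect_equal(layers$bm_row[inside] - layers$rpe_row[inside],
               rep(0, sum(inside)))
  expect_true(all(layers$rpe_row[!inside] - layers$ez_row[!inside] > 0))
  expect_true(all(layers$bm_row[!inside] - layers$rpe_row[!inside] > 0))
  # anatomical ordering everywhere, equality only inside lesions
  expect_true(all(layers$ez_row <= layers$rpe_row))
  expect_true(all(layers$rpe_row <= layers$bm_row))
  expect_true(all(layers$bm_row < g$n_depth & layers$ez_row >= 0))
  # excessive undulation is caught
  expect_error(render_layers(g, lesions, smooth_amp_px = 60, seed = 1),
               "out of the depth range")
})

test_that("confluent columns equal the analytic footprint exactly", {
  g <- tiny_geometry(16, 64, 50)
  lesions <- sample_lesions(g, 3, axis_range_um = c(300, 1200), seed = 5)
  layers <- render_layers(g, lesions, seed = 6)
  flagged <- detect_confluence(layers)
  got <- matrix(FALSE, g$n_bscans, g$n_ascans)
  got[cbind(flagged$bscan_index + 1, flagged$ascan_index + 1)] <- flagged$ga
  expect_identical(got, analytic_enface(g, lesions) == 1)
})

test_that("hypertransmission contrast below BM equals the gain", {
  g <- tiny_geometry(8, 128, 64)
  lesions <- tibble::tibble(center_x_um = 1500, center_y_um = 3000,
                            semi_axis_a_um = 700, semi_axis_b_um = 700,
                            rotation_rad = 0)
  layers <- render_layers(g, lesions, smooth_amp_px = 0, seed = 1)
  flagged <- detect_confluence(dplyr::filter(layers, bscan_index == 4))
  img <- render_intensity(layers, g, 4, hyper_gain = 2, noise_sd = 0)
  sub_bm <- function(j) {
    r0 <- ceiling(flagged$bm_row[j]) + 2
    mean(img[r0:g$n_depth, j])
  }
  les <- which(flagged$ga)
  hea <- which(!flagged$ga)
  expect_gt(length(les), 0)
  ratio <- mean(vapply(les, sub_bm, 0)) / mean(vapply(hea, sub_bm, 0))
  expect_equal(ratio, 2, tolerance = 1e-12)
  # with noise, the empirical ratio stays within 5%
  img_n <- render_intensity(layers, g, 4, hyper_gain = 2, noise_sd = 0.05,
                            seed = 9)
  ratio_n <- mean(vapply(les, function(j) {
    r0 <- ceiling(flagged$bm_row[j]) + 2
    mean(img_n[r0:g$n_depth, j])
  }, 0)) / mean(vapply(hea, function(j) {
    r0 <- ceiling(flagged$bm_row[j]) + 2
    mean(img_n[r0:g$n_depth, j])
  }, 0))
  expect_equal(ratio_n, 2, tolerance = 0.05)
  # deterministic per seed; gain <= 1 rejected
  expect_identical(img_n,
                   render_intensity(layers, g, 4, hyper_gain = 2,
                                    noise_sd = 0.05, seed = 9))
  expect_error(render_intensity(layers, g, 4, hyper_gain = 1),
               "hyper_gain")
})

test_that("analytic footprint rasterization matches ellipse area and unions", {
  g <- oct_geometry("cirrus")
  expect_true(all(analytic_enface(g, sample_lesions(g, 0)) == 0))
  one <- tibble::tibble(center_x_um = 3000, center_y_um = 3000,
                        semi_axis_a_um = 800, semi_axis_b_um = 500,
                        rotation_rad = 0.4)
  m <- analytic_enface(g, one)
  raster_area <- sum(m) * g$um_per_px_x * g$um_per_px_y
  analytic_area <- pi * 800 * 500
  # rasterization error is bounded by a one-pixel band around the perimeter
  perimeter <- pi * (3 * (800 + 500) - sqrt((3 * 800 + 500) * (800 + 3 * 500)))
  band <- perimeter * max(g$um_per_px_x, g$um_per_px_y)
  expect_lt(abs(raster_area - analytic_area), band)
  two <- sample_lesions(g, 2, axis_range_um = c(400, 900), seed = 8)
  m12 <- analytic_enface(g, two)
  m1 <- analytic_enface(g, two[1, ])
  m2 <- analytic_enface(g, two[2, ])
  expect_identical(m12, pmax(m1, m2))
})

test_that("phantom volumes are bit-identical for identical seeds", {
  g <- tiny_geometry(10, 40, 48)
  p1 <- simulate_phantom(g, n_lesions = 2, axis_range_um = c(300, 900),
                         seed = 42)
  p2 <- simulate_phantom(g, n_lesions = 2, axis_range_um = c(300, 900),
                         seed = 42)
  expect_identical(p1, p2)
  expect_length(p1$intensity, g$n_bscans)
})
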