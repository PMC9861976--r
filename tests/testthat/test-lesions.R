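test_that("connectivity controls whether diagonal contact joins lesions", {
  m <- matrix(0L, 6, 6)
  m[2, 2] <- 1L; m[3, 3] <- 1L  # touch only diagonally
  expect_equal(max(label_components(m, 8)$label), 1)
  expect_equal(max(label_components(m, 4)$label), 2)
  expect_equal(nrow(label_components(matrix(0L, 5, 5))), 0)
  expect_error(label_components(matrix(0.5, 2, 2)), "binary")
  expect_error(label_components(m, 6), "connectivity")
})

test_that("component labeling agrees with a flood-fill oracle", {
  set.seed(19)
  for (rep in 1:25) {
    m <- matrix(as.integer(runif(32 * 32) < runif(1, 0.2, 0.6)), 32, 32)
    for (conn in c(4, 8)) {
      px <- label_components(m, conn)
      lab_pkg <- matrix(0L, 32, 32)
      if (nrow(px) > 0) {
        lab_pkg[cbind(px$bscan_index + 1, px$ascan_index + 1)] <- px$label
      }
      lab_or <- oracle_label(m, conn)
      expect_identical(label_partition(lab_pkg), label_partition(lab_or))
    }
  }
})

test_that("two well-separated ellipses form two components", {
  g <- tiny_geometry(24, 96, 20)
  lesions <- tibble::tibble(
    center_x_um = c(1500, 4500), center_y_um = c(1500, 4500),
    semi_axis_a_um = c(600, 500), semi_axis_b_um = c(400, 500),
    rotation_rad = c(0.3, 1.2))
  px <- label_components(analytic_enface(g, lesions))
  expect_equal(max(px$label), 2)
})

test_that("greatest linear dimension recovers analytic diameters", {
  for (preset in c("spectralis", "cirrus")) {
    g <- oct_geometry(preset)
    # rasterized disc of diameter 400 um
    disc <- tibble::tibble(center_x_um = 3000, center_y_um = 3000,
                           semi_axis_a_um = 200, semi_axis_b_um = 200,
                           rotation_rad = 0)
    px <- label_components(analytic_enface(g, disc))
    gld <- greatest_linear_dimension(px, g)
    # quantization of the coarse (slow) axis bounds the attainable accuracy
    expect_lt(abs(gld - 400), max(g$um_per_px_x, g$um_per_px_y) / 2)
    # and the estimate equals an independent long-hand moments computation
    pts <- cbind((px$ascan_index + 0.5) * g$um_per_px_x,
                 (px$bscan_index + 0.5) * g$um_per_px_y)
    cov_lh <- matrix(0, 2, 2)
    ctr <- colMeans(pts)
    for (r in seq_len(nrow(pts))) {
      d <- pts[r, ] - ctr
      cov_lh <- cov_lh + d %o% d
    }
    lam <- max(eigen(cov_lh / nrow(pts))$values)
    expect_equal(gld, 4 * sqrt(lam), tolerance = 1e-12)
    # rotated ellipse, full major axis 500 um at 45 degrees
    ell <- tibble::tibble(center_x_um = 3000, center_y_um = 3000,
                          semi_axis_a_um = 250, semi_axis_b_um = 120,
                          rotation_rad = pi / 4)
    pxe <- label_components(analytic_enface(g, ell))
    glde <- greatest_linear_dimension(pxe, g)
    expect_lt(abs(glde - 500) / 500, 0.05)
  }
})

test_that("the same physical lesion measures alike on both device grids", {
  sp <- oct_geometry("spectralis")
  ci <- oct_geometry("cirrus")
  lesion <- tibble::tibble(center_x_um = 2800, center_y_um = 3200,
                           semi_axis_a_um = 230, semi_axis_b_um = 150,
                           rotation_rad = 1.1)
  g_sp <- greatest_linear_dimension(
    label_components(analytic_enface(sp, lesion)), sp)
  g_ci <- greatest_linear_dimension(
    label_components(analytic_enface(ci, lesion)), ci)
  expect_lt(abs(g_sp - g_ci), max(sp$um_per_px_y, ci$um_per_px_y))
})

test_that("degenerate and feret measurements behave as documented", {
  g <- oct_geometry("spectralis")
  one <- tibble::tibble(bscan_index = 5L, ascan_index = 9L)
  expect_equal(greatest_linear_dimension(one, g),
               max(g$um_per_px_x, g$um_per_px_y))
  # feret on a horizontal two-pixel pair equals the center distance
  two <- tibble::tibble(bscan_index = c(3L, 3L), ascan_index = c(10L, 19L))
  expect_equal(greatest_linear_dimension(two, g, method = "feret"),
               9 * g$um_per_px_x)
  # feret and moments agree within a few percent on a blob
  disc <- tibble::tibble(center_x_um = 3000, center_y_um = 3000,
                         semi_axis_a_um = 400, semi_axis_b_um = 400,
                         rotation_rad = 0)
  px <- label_components(analytic_enface(g, disc))
  expect_equal(greatest_linear_dimension(px, g, "feret"),
               greatest_linear_dimension(px, g, "moments"),
               tolerance = 0.08)
  expect_error(greatest_linear_dimension(one[0, ], g), "empty")
})

test_that("the CAM comparator is >= at threshold and monotone", {
  expect_equal(classify_cam(300), "cRORA")
  expect_equal(classify_cam(200), "iRORA")
  expect_equal(classify_cam(250), "cRORA")
  expect_equal(classify_cam(250, strict = TRUE), "iRORA")
  expect_error(classify_cam(0), "positive")
  # raising the threshold never converts iRORA -> cRORA
  set.seed(6)
  gld <- runif(50, 50, 600)
  c1 <- classify_cam(gld, 250)
  c2 <- classify_cam(gld, 350)
  expect_true(all(!(c1 == "iRORA" & c2 == "cRORA")))
})

test_that("area summaries drop exactly the sub-threshold lesions' share", {
  g <- tiny_geometry(60, 256, 20)
  expect_equal(glance(measure_lesions(
    enface_map(matrix(0L, 60, 256), g, "truth"), g))$area_percent_all, 0)
  lesions <- tibble::tibble(
    center_x_um = c(1500, 4500), center_y_um = c(1500, 4500),
    semi_axis_a_um = c(150, 75), semi_axis_b_um = c(120, 60),
    rotation_rad = 0)  # 300-um cRORA and 150-um iRORA
  rep <- measure_lesions(enface_map(analytic_enface(g, lesions), g,
                                    "truth"), g)
  expect_setequal(rep$lesions$cam_class, c("cRORA", "iRORA"))
  expect_lt(rep$area_percent_crora_only, rep$area_percent_all)
  small_share <- 100 *
    rep$lesions$area_px[rep$lesions$cam_class == "iRORA"] / (60 * 256)
  expect_equal(rep$area_percent_all - rep$area_percent_crora_only,
               small_share)
  # a single cRORA lesion makes the two percentages equal
  solo <- measure_lesions(enface_map(analytic_enface(g, lesions[1, ]), g,
                                     "truth"), g)
  expect_equal(solo$area_percent_all, solo$area_percent_crora_only)
  # tidy/glance accessors expose the same numbers
  expect_equal(nrow(tidy(rep)), 2)
  expect_equal(glance(rep)$n_crora, 1)
})
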