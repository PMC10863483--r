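test_that("projection of a coplanar circular region is the identity", {
  reg <- disc_region(rx = 12.5, n = 256)
  circ <- best_fit_circle(c(0, 0, 0), 12.5, c(0, 0, 1))
  fr <- suppressWarnings(compute_frame(reg, list(superior = c(1, 0, 0),
                                                 anterior = c(0, 1, 0))))
  ctr <- project_contour(reg, circ, fr)
  expect_lt(abs(abs(glenoidbl:::polygon_area(ctr$polygon)) / (pi * 12.5^2) - 1),
            0.001)
  expect_equal(max(abs(sqrt(rowSums(ctr$polygon^2)) - 12.5)), 0, tolerance = 1e-9)
})

test_that("projected area of a tilted disc is foreshortened by cos(angle)", {
  Rm <- rotation_matrix(c(0, 1, 0), 10 * pi / 180)  # tilt about the short axis
  reg <- disc_region(rx = 12.5, n = 256, transform = function(v) v %*% t(Rm))
  circ <- best_fit_circle(c(0, 0, 0), 12.5, c(0, 0, 1))
  fr <- list(origin = c(0, 0, 0), long_axis = c(1, 0, 0),
             short_axis = c(0, 1, 0), normal_axis = c(0, 0, 1))
  class(fr) <- "anatomical_frame"
  ctr <- project_contour(reg, circ, fr)
  expect_lt(abs(abs(glenoidbl:::polygon_area(ctr$polygon)) /
                  (pi * 12.5^2 * cos(10 * pi / 180)) - 1), 0.002)
})

test_that("degenerate projections are rejected", {
  v <- rbind(c(0, 0, 0), c(1e-4, 0, 0), c(0, 1e-4, 0), c(0, 0, 1))
  mesh <- triangle_surface(v, rbind(c(1, 2, 3), c(1, 2, 4), c(2, 3, 4), c(1, 3, 4)))
  reg <- glenoid_region(mesh, 1:3, boundary_loop = 1:3, triangle_ids = 1L)
  circ <- best_fit_circle(c(0, 0, 0), 12.5, c(0, 0, 1))
  fr <- structure(list(origin = c(0, 0, 0), long_axis = c(1, 0, 0),
                       short_axis = c(0, 1, 0), normal_axis = c(0, 0, 1)),
                  class = "anatomical_frame")
  expect_error(project_contour(reg, circ, fr), "degenerate projection")
})

test_that("linear bone loss matches chord geometry", {
  full <- make_contour(chord_polygon(12.5), 12.5)
  lin0 <- linear_bone_loss(full)
  # the 720-gon test contour is inscribed: sagitta ~1.2e-4 mm is the floor
  expect_lt(lin0$defect_diameter_mm, 1e-3)
  expect_lt(lin0$ratio_percent, 0.01)

  cut <- make_contour(chord_polygon(12.5, a = 8.5), 12.5)
  lin <- linear_bone_loss(cut)
  expect_equal(lin$defect_diameter_mm, 4.0, tolerance = 1e-3)
  expect_equal(lin$ratio_percent, 16.0, tolerance = 0.01)
  expect_equal(lin$bfc_diameter_mm, 25)

  half <- make_contour(chord_polygon(12.5, a = 0), 12.5)
  linh <- linear_bone_loss(half)
  expect_equal(linh$defect_diameter_mm, 12.5, tolerance = 1e-3)
  expect_equal(linh$ratio_percent, 50.0, tolerance = 0.01)
})

test_that("area bone loss matches the circular-segment closed form", {
  r <- 12.5
  full <- area_bone_loss(make_contour(chord_polygon(r), r))
  expect_lt(full$ratio_percent, 0.1)

  cut <- area_bone_loss(make_contour(chord_polygon(r, a = 8.5), r))
  truth <- segment_area(r, 8.5)
  expect_equal(cut$defect_area_mm2, truth, tolerance = 0.002)
  expect_equal(cut$ratio_percent, 100 * truth / (pi * r^2), tolerance = 0.02)

  half <- area_bone_loss(make_contour(chord_polygon(r, a = 0), r))
  expect_equal(half$ratio_percent, 50, tolerance = 0.1)
})

test_that("defect area agrees with a Monte-Carlo estimate", {
  set.seed(99)
  r <- 12.5; a <- 8.5
  est <- area_bone_loss(make_contour(chord_polygon(r, a), r))$defect_area_mm2
  # sample the segment's bounding box
  h <- sqrt(r^2 - a^2)
  n <- 2e5
  x <- runif(n, a, r); y <- runif(n, -h, h)
  inside <- x^2 + y^2 <= r^2
  mc <- mean(inside) * (r - a) * 2 * h
  expect_lt(abs(est / mc - 1), 0.005)
})

test_that("linear and area ratios follow the analytic chord relations", {
  r <- 12.5
  for (frac in seq(0, 0.9, by = 0.1)) {
    a <- frac * r
    ctr <- make_contour(chord_polygon(r, a = a, n = 1440), r)
    lin <- linear_bone_loss(ctr)$ratio_percent
    ar <- area_bone_loss(ctr)$ratio_percent
    expect_lt(abs(lin - 100 * (1 - frac) / 2), 1)
    expect_lt(abs(ar - 100 * (acos(frac) - frac * sqrt(1 - frac^2)) / pi), 1)
  }
})

test_that("both ratios increase as the chord moves toward the centre", {
  r <- 12.5
  res <- t(vapply(seq(0.9, 0, by = -0.15), function(frac) {
    ctr <- make_contour(chord_polygon(r, a = frac * r), r)
    c(linear_bone_loss(ctr)$ratio_percent, area_bone_loss(ctr)$ratio_percent)
  }, numeric(2)))
  expect_true(all(diff(res[, 1]) > 0))
  expect_true(all(diff(res[, 2]) > 0))
})

test_that("ratios are scale invariant; absolute metrics scale as s and s^2", {
  s <- 3.7
  c1 <- make_contour(chord_polygon(12.5, a = 8.5), 12.5)
  c2 <- make_contour(chord_polygon(12.5, a = 8.5) * s, 12.5 * s)
  l1 <- linear_bone_loss(c1); l2 <- linear_bone_loss(c2)
  a1 <- area_bone_loss(c1); a2 <- area_bone_loss(c2)
  expect_equal(l2$ratio_percent, l1$ratio_percent, tolerance = 1e-6)
  expect_equal(a2$ratio_percent, a1$ratio_percent, tolerance = 1e-6)
  expect_equal(l2$defect_diameter_mm, s * l1$defect_diameter_mm, tolerance = 1e-6)
  expect_equal(a2$defect_area_mm2, s^2 * a1$defect_area_mm2, tolerance = 1e-6)
})

test_that("outputs are clamped to [0, 100] percent", {
  # contour larger than the circle: no defect, not negative
  big <- make_contour(chord_polygon(14), 12.5)
  expect_lt(area_bone_loss(big)$ratio_percent, 0.01)
  expect_gte(area_bone_loss(big)$ratio_percent, 0)
  expect_equal(linear_bone_loss(big)$ratio_percent, 0)
  # tiny sliver of a contour: defect approaches but never exceeds 100%
  tiny <- make_contour(chord_polygon(12.5, a = 0.95 * 12.5) , 12.5)
  expect_lte(area_bone_loss(tiny)$ratio_percent, 100)
  expect_lte(linear_bone_loss(tiny)$ratio_percent, 100)
})

test_that("anterior-only restriction ignores posterior rim loss", {
  # defect on the posterior side (chord mirrored): full search sees it,
  # anterior-restricted search does not
  poly <- chord_polygon(12.5, a = 8.5)
  poly[, 1] <- -poly[, 1]
  ctr <- make_contour(poly[rev(seq_len(nrow(poly))), ], 12.5)
  expect_gt(linear_bone_loss(ctr)$ratio_percent, 15)
  expect_lt(linear_bone_loss(ctr, anterior_only = TRUE)$ratio_percent, 1)
})
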