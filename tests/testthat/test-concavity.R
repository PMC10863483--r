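test_that("central cross-section follows the analytic cap meridian", {
  st <- intact_stages()
  ph <- intact_phantom()
  cut <- cross_section(st$region, st$frame, st$circle, 0)
  rs <- ph$ground_truth$cap_sphere_radius_mm
  d <- ph$spec$cap_depth_mm
  pr <- cut$profile
  on_cap <- abs(pr[, 1]) <= 12.4
  z_true <- (rs - d) - sqrt(rs^2 - pr[on_cap, 1]^2)
  expect_lt(max(abs(pr[on_cap, 2] - z_true)), ph$spec$mesh_edge_mm)
  # the polyline lies exactly in the cut plane
  lc <- sweep(cut$points3d, 2, st$circle$center) %*% st$frame$long_axis
  expect_lt(max(abs(lc - 0)), 1e-9)
})

test_that("cuts outside the circle radius are rejected", {
  st <- intact_stages()
  expect_error(cross_section(st$region, st$frame, st$circle,
                             1.5 * st$circle$radius), "cut misses region")
})

test_that("a flat articular face yields zero depth", {
  flat <- generate_phantom(phantom_spec(cap_depth_mm = 0,
                                        superior_extension = FALSE,
                                        mesh_edge_mm = 1))
  ids <- flat$ground_truth$articular_vertex_ids
  reg <- isolate_glenoid_region(flat$scapula, vertex_mask = ids)
  fr <- suppressWarnings(compute_frame(reg, phantom_hint()))
  circ <- best_fit_circle(c(0, 0, 0), 12.5, c(0, 0, 1))
  cut <- supporting_line_depth(cross_section(reg, fr, circ, 0))
  expect_lt(cut$depth_mm, 1e-9)
  expect_equal(nrow(cut$contact_points), nrow(cut$profile))
  prof <- concavity_profile(reg, fr, circ)
  expect_lt(prof$mean_depth_mm, 1e-9)
})

test_that("supporting line depth recovers an analytic arc sagitta", {
  # arc with chord 25 and sagitta 2: r = (2^2 + 12.5^2)/(2*2)
  r <- (4 + 156.25) / 4
  u <- seq(-12.5, 12.5, length.out = 401)
  w <- (r - 2) - sqrt(r^2 - u^2)
  cut <- structure(list(offset_mm = 0, profile = cbind(u, w)),
                   class = "concavity_cut")
  out <- supporting_line_depth(cut)
  expect_equal(out$depth_mm, 2, tolerance = 1e-6)
  expect_equal(out$chord_mm, 25, tolerance = 1e-6)
  expect_equal(nrow(out$contact_points), 2L)

  straight <- structure(list(offset_mm = 0,
                             profile = cbind(u, rep(0.5, length(u)))),
                        class = "concavity_cut")
  s <- supporting_line_depth(straight)
  expect_equal(s$depth_mm, 0)
  expect_equal(nrow(s$contact_points), length(u))
})

test_that("asymmetric profiles match the brute-force supporting-line oracle", {
  r <- (4 + 156.25) / 4
  u <- seq(-12.5, 7.3, length.out = 301)  # anterior rim cut away
  w <- (r - 2) - sqrt(r^2 - u^2)
  cut <- supporting_line_depth(
    structure(list(offset_mm = 0, profile = cbind(u, w)),
              class = "concavity_cut"))
  # oracle: distance from every point to the u-parallel line through max w
  oracle <- max(max(w) - w)
  expect_equal(cut$depth_mm, oracle, tolerance = 1e-12)
  expect_equal(nrow(cut$contact_points), 1L)   # single touch point
  expect_true(is.na(cut$chord_mm))
})

test_that("10-cut mean depth matches the analytic profile", {
  st <- intact_stages()
  gt <- intact_phantom()$ground_truth
  expect_lt(abs(st$profile$mean_depth_mm / gt$true_mean_depth_mm - 1), 0.05)
  expect_equal(length(st$profile$cuts), 10L)
  expect_equal(st$profile$mean_depth_mm,
               mean(vapply(st$profile$cuts, function(c) c$depth_mm, numeric(1))),
               tolerance = 1e-12)
  # off-centre cuts of a symmetric cap are shallower than the central cut
  central <- supporting_line_depth(cross_section(st$region, st$frame,
                                                 st$circle, 0))
  expect_lte(st$profile$mean_depth_mm, central$depth_mm + 1e-9)

  single <- concavity_profile(st$region, st$frame, st$circle, n_cuts = 1)
  expect_equal(single$mean_depth_mm, central$depth_mm, tolerance = 1e-12)
})

test_that("failed cuts are skipped; too many failures abort", {
  ph <- intact_phantom()
  ids <- ph$ground_truth$articular_vertex_ids
  band <- ids[abs(ph$scapula$vertices[ids, 1]) < 1.6]  # narrow central band
  reg <- isolate_glenoid_region(ph$scapula, vertex_mask = band)
  fr <- structure(list(origin = c(0, 0, -2), long_axis = c(1, 0, 0),
                       short_axis = c(0, 1, 0), normal_axis = c(0, 0, 1)),
                  class = "anatomical_frame")
  circ <- best_fit_circle(c(0, 0, 0), 12.5, c(0, 0, 1))
  # cuts span +-2.5 mm; the band only covers +-1.6 mm, so edge cuts fail
  w <- capture_warnings(prof <- concavity_profile(reg, fr, circ, n_cuts = 10,
                                                  span_fraction = 0.2))
  expect_true(any(grepl("skipped", w)))
  expect_lt(length(prof$cuts), 10L)
  expect_gte(length(prof$cuts), 5L)
  # with a much wider span most cuts miss -> not measurable
  expect_error(suppressWarnings(
    concavity_profile(reg, fr, circ, n_cuts = 10, span_fraction = 0.9)),
    "concavity not measurable")
})

test_that("BSSR closed forms and domain errors", {
  expect_equal(compute_bssr(0, 25)$bssr_percent, 0)
  b <- compute_bssr(2.5, 25)          # 5-12-13 construction
  expect_equal(b$radius_of_curvature_mm, 32.5)
  expect_equal(b$rim_angle_deg, asin(5 / 13) * 180 / pi)
  expect_equal(b$bssr_percent, 100 * 5 / 12, tolerance = 1e-12)
  expect_equal(compute_bssr(1, 25)$bssr_percent, 100 * 25 / 155.25,
               tolerance = 1e-12)
  expect_error(compute_bssr(13, 25), "depth exceeds circular-arc model")
  expect_error(compute_bssr(NA, 25), "finite")
  expect_error(compute_bssr(1, 0), "chord")
  alt <- compute_bssr(2, 25, ratio_fn = function(d, c) 7 * d)
  expect_equal(alt$bssr_percent, 14)
  expect_equal(alt$model, "user-supplied")
})

test_that("BSSR is monotone in depth and chord, with the right limits", {
  ds <- seq(0.5, 5, length.out = 10)
  cs <- seq(12, 40, length.out = 10)
  for (cc in cs) {
    vals <- vapply(ds, function(d) compute_bssr(d, cc)$bssr_percent, numeric(1))
    expect_true(all(diff(vals) > 0))
  }
  for (d in ds) {
    vals <- vapply(cs[cs > 2 * d], function(cc) compute_bssr(d, cc)$bssr_percent,
                   numeric(1))
    expect_true(all(diff(vals) < 0))
  }
  # limits: bssr -> 0 as d -> 0; grows beyond any bound as d -> chord/2
  expect_lt(compute_bssr(1e-9, 25)$bssr_percent, 1e-6)
  expect_gt(compute_bssr(12.5 - 1e-9, 25)$bssr_percent, 1e3)
})
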