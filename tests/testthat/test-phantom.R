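test_that("phantom generation is deterministic for a fixed spec", {
  sp <- phantom_spec(jitter_sd_mm = 0.2, seed = 7, mesh_edge_mm = 1)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$scapula$vertices, b$scapula$vertices)
  expect_identical(a$scapula$triangles, b$scapula$triangles)
  # a different jitter seed moves articular vertices
  c_ <- generate_phantom(phantom_spec(jitter_sd_mm = 0.2, seed = 8,
                                      mesh_edge_mm = 1))
  expect_false(identical(a$scapula$vertices, c_$scapula$vertices))
})

test_that("ground truth follows the closed forms and depends only on the spec", {
  gt <- phantom_ground_truth(phantom_spec(defect_offset_mm = 8.5))
  expect_equal(gt$true_linear_ratio_percent, 16)
  expect_equal(gt$true_area_ratio_percent,
               100 * segment_area(12.5, 8.5) / (pi * 12.5^2))
  expect_equal(gt$true_area_ratio_percent, 10.3, tolerance = 0.03)
  expect_equal(gt$cap_sphere_radius_mm, 40.0625)
  expect_equal(gt$true_central_depth_mm, 2)
  expect_equal(gt$true_bssr_percent, 100 * 2 * 2 * 12.5 / (12.5^2 - 4))

  none <- phantom_ground_truth(phantom_spec())
  expect_identical(none$true_linear_ratio_percent, 0)
  expect_identical(none$true_area_ratio_percent, 0)

  # purity: the ground truth carried by a generated phantom equals the
  # direct closed-form evaluation, tessellation notwithstanding
  ph <- defect_phantom()
  direct <- phantom_ground_truth(ph$spec)
  for (f in c("true_linear_ratio_percent", "true_area_ratio_percent",
              "true_mean_depth_mm", "true_bssr_percent")) {
    expect_identical(ph$ground_truth[[f]], direct[[f]])
  }
})

test_that("invalid phantom specs are rejected naming the field", {
  expect_error(phantom_spec(bfc_radius_mm = -1), "bfc_radius_mm")
  expect_error(phantom_spec(cap_depth_mm = 13), "cap_depth_mm")
  expect_error(phantom_spec(defect_offset_mm = 12.5), "defect_offset_mm")
  expect_error(phantom_spec(mesh_edge_mm = 2), "mesh_edge_mm")
  expect_error(phantom_spec(slab_thickness_mm = 1), "slab_thickness_mm")
  expect_error(phantom_spec(jitter_sd_mm = -0.1), "jitter_sd_mm")
})

test_that("phantom solids are watertight with exact rim and chord sampling", {
  ph <- defect_phantom()
  expect_true(is_watertight(ph$scapula))
  v <- ph$scapula$vertices
  rho <- sqrt(v[, 1]^2 + v[, 2]^2)
  # rim vertices exist exactly on the circle in the spared sectors
  on_rim <- abs(rho - 12.5) < 1e-9 & v[, 3] > -1e-9
  expect_gt(sum(on_rim), 100)
  # chord wall is exactly at y = a
  expect_gt(length(ph$ground_truth$defect_edge_vertex_ids), 10)
  expect_true(all(abs(v[ph$ground_truth$defect_edge_vertex_ids, 2] - 8.5) < 1e-9))
})

test_that("voxelization matches analytic volumes and round-trips", {
  sph <- icosphere(radius = 10, subdivisions = 4)
  vol <- voxelize_phantom(sph, 0.625)
  count <- sum(vol$labels == 1L)
  expect_lt(abs(count / ((4 / 3) * pi * 1000 / 0.625^3) - 1), 0.02)
  # read/write round trip preserves the voxel count (voxelizer as oracle)
  p <- tempfile(fileext = ".nii.gz")
  write_label_volume(vol, p)
  back <- read_label_volume(p, c(background = 0L, scapula = 1L))
  expect_identical(sum(back$labels == 1L), count)
  # voxelize -> extract_surface round trip preserves enclosed volume
  m <- extract_surface(vol, "scapula")
  expect_lt(abs(mesh_volume(m) / mesh_volume(sph) - 1), 0.03)

  open_mesh <- triangle_surface(sph$vertices, sph$triangles[-1, ])
  expect_error(voxelize_phantom(open_mesh, 0.625), "open mesh")
  # spacing coarser than the solid leaves too few voxels downstream
  tiny <- voxelize_phantom(icosphere(radius = 1.2, subdivisions = 3), 2)
  expect_error(extract_surface(tiny, "scapula"), "degenerate mask")
})

test_that("pipeline recovers phantom parameters across the design grid", {
  hint <- phantom_hint()
  grid <- expand.grid(R = c(10, 12.5, 15), d = c(1, 2, 3),
                      afrac = c(NA, 0.5, 0.68, 0.85))
  for (i in seq_len(nrow(grid))) {
    R <- grid$R[i]; d <- grid$d[i]
    a <- if (is.na(grid$afrac[i])) NA else grid$afrac[i] * R
    ph <- generate_phantom(phantom_spec(bfc_radius_mm = R, cap_depth_mm = d,
                                        defect_offset_mm = a))
    st <- measure_stages(ph, tau = 0.3)
    gt <- ph$ground_truth
    info <- sprintf("R=%g d=%g a=%s", R, d, a)
    expect_lt(abs(st$circle$radius / R - 1), 0.01, label = paste("radius", info))
    expect_lt(abs(st$linear$ratio_percent - gt$true_linear_ratio_percent), 1,
              label = paste("linear", info))
    expect_lt(abs(st$area$ratio_percent - gt$true_area_ratio_percent), 1,
              label = paste("area", info))
    bssr <- compute_bssr(st$profile$mean_depth_mm, st$profile$mean_chord_mm)
    if (is.na(a)) {
      # symmetric cap: the PCA frame is unbiased and depth is recovered
      expect_lt(abs(st$profile$mean_depth_mm / gt$true_mean_depth_mm - 1), 0.05,
                label = paste("depth", info))
      expect_lt(abs(bssr$bssr_percent / gt$true_bssr_percent - 1), 0.05,
                label = paste("bssr", info))
    } else {
      # anterior defects tilt the PCA normal (nonzero short/normal
      # covariance); the supporting-line depth then shifts by up to about
      # sin(tilt) * R. Check the measurement against that mechanistic bound.
      tilt <- acos(min(1, abs(st$frame$normal_axis[3])))
      bound <- 1.5 * sin(tilt) * R + 0.05 * gt$true_mean_depth_mm
      expect_lt(abs(st$profile$mean_depth_mm - gt$true_mean_depth_mm), bound,
                label = paste("depth-tilt", info))
      # with the untilted anatomical frame the depth is recovered
      fr0 <- structure(list(origin = st$frame$origin, long_axis = c(1, 0, 0),
                            short_axis = c(0, 1, 0), normal_axis = c(0, 0, 1)),
                       class = "anatomical_frame")
      prof0 <- suppressWarnings(concavity_profile(st$region, fr0, st$circle))
      expect_lt(abs(prof0$mean_depth_mm / gt$true_mean_depth_mm - 1), 0.05,
                label = paste("depth-untilted", info))
    }
  }
})

test_that("recovered ratios are robust to segmentation-like jitter", {
  base <- defect_stages()
  lin0 <- base$linear$ratio_percent
  area0 <- base$area$ratio_percent
  drift <- t(vapply(1:20, function(s) {
    ph <- generate_phantom(phantom_spec(defect_offset_mm = 8.5,
                                        jitter_sd_mm = 0.2, seed = s))
    reg <- isolate_glenoid_region(ph$scapula, ph$humerus, max_distance = 1.0)
    fr <- suppressWarnings(compute_frame(reg, phantom_hint()))
    circ <- fit_best_circle(select_posteroinferior_rim(reg, fr), frame = fr)
    ctr <- suppressWarnings(project_contour(reg, circ, fr))
    c(lin = linear_bone_loss(ctr)$ratio_percent,
      area = area_bone_loss(ctr)$ratio_percent)
  }, numeric(2)))
  expect_lt(median(abs(drift[, "lin"] - lin0)), 2)
  expect_lt(median(abs(drift[, "area"] - area0)), 2)
})
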