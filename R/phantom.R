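#' Synthetic glenoid phantom specification
#'
#' Defines a glenoid-like solid with closed-form ground truth: a spherical-cap
#' articular concavity (chord radius `bfc_radius_mm`, central sagitta
#' `cap_depth_mm`) sunk into a bone slab, an optional superior trapezoidal
#' extension making the outline pear-shaped (so the inferior circle, not the
#' whole outline, is the best-fit circle), and an optional anterior planar
#' defect: all material anterior to the chord `short-axis = defect_offset_mm`
#' is removed and the cut face re-capped by a vertical wall, the canonical
#' bony Bankart geometry. Optional Gaussian jitter along surface normals of
#' the articular vertices models segmentation surface noise.
#'
#' World axes: x = superior (long axis), y = anterior (short axis),
#' z = lateral (normal axis, toward the humeral head); right-handed with
#' long x short = normal. The whole top face, superior extension included,
#' lies on the articular sphere: the articular surface is pear-shaped (as
#' real glenoids are), which keeps its principal axes well defined, and the
#' inferior rim circle sits exactly in the z = 0 plane.
#'
#' @param bfc_radius_mm radius R of the inferior rim circle (mm).
#' @param cap_depth_mm central concavity depth d (mm), `0 <= d < R`.
#' @param defect_offset_mm anterior chord distance a from the centre (mm),
#'   `0 <= a < R`, or `NA` for no defect.
#' @param superior_extension add the superior extension (default `TRUE`).
#' @param slab_thickness_mm bone slab thickness (must exceed `cap_depth_mm`).
#' @param mesh_edge_mm target mesh resolution (`<= R / 10`).
#' @param jitter_sd_mm Gaussian vertex jitter SD (articular vertices only).
#' @param seed RNG seed for the jitter.
#' @param voxel_spacing_mm voxel size used by [voxelize_phantom()]
#'   (default 0.625, a typical CT slice thickness).
#' @return validated list of class `phantom_spec`.
#' @export
phantom_spec <- function(bfc_radius_mm = 12.5, cap_depth_mm = 2,
                         defect_offset_mm = NA, superior_extension = TRUE,
                         slab_thickness_mm = 5, mesh_edge_mm = 0.5,
                         jitter_sd_mm = 0, seed = 1L,
                         voxel_spacing_mm = 0.625) {
  chk <- function(ok, field, msg) {
    if (!ok) stop(sprintf("invalid phantom spec: %s %s", field, msg), call. = FALSE)
  }
  chk(is.finite(bfc_radius_mm) && bfc_radius_mm > 0, "bfc_radius_mm", "must be > 0")
  chk(is.finite(cap_depth_mm) && cap_depth_mm >= 0 &&
        cap_depth_mm < bfc_radius_mm, "cap_depth_mm", "must satisfy 0 <= d < R")
  chk(is.na(defect_offset_mm) ||
        (defect_offset_mm >= 0 && defect_offset_mm < bfc_radius_mm),
      "defect_offset_mm", "must satisfy 0 <= a < R (or NA)")
  chk(mesh_edge_mm > 0 && mesh_edge_mm <= bfc_radius_mm / 10,
      "mesh_edge_mm", "must be in (0, R/10]")
  chk(slab_thickness_mm > cap_depth_mm, "slab_thickness_mm",
      "must exceed cap_depth_mm")
  chk(jitter_sd_mm >= 0, "jitter_sd_mm", "must be >= 0")
  chk(voxel_spacing_mm > 0, "voxel_spacing_mm", "must be > 0")
  structure(list(bfc_radius_mm = bfc_radius_mm, cap_depth_mm = cap_depth_mm,
                 defect_offset_mm = defect_offset_mm,
                 superior_extension = isTRUE(superior_extension),
                 slab_thickness_mm = slab_thickness_mm,
                 mesh_edge_mm = mesh_edge_mm, jitter_sd_mm = jitter_sd_mm,
                 seed = as.integer(seed),
                 voxel_spacing_mm = voxel_spacing_mm),
            class = "phantom_spec")
}

cap_sphere_radius <- function(R, d) if (d <= 0) Inf else (d^2 + R^2) / (2 * d)

#' Closed-form phantom ground truth
#'
#' Pure function of the specification (independent of the tessellation):
#' the linear and area bone-loss ratios of a chord defect, the analytic
#' concavity depth profile d(y) = R_s - sqrt((R_s - d)^2 + y^2) with
#' R_s = (d^2 + R^2) / (2 d) the cap sphere radius, its mean over the
#' configured cut offsets, and the circular-arc BSSR of the central cut
#' (depth d, chord 2 R).
#'
#' @param spec a [phantom_spec()].
#' @param n_cuts,span_fraction cut configuration mirrored from
#'   [concavity_profile()] defaults.
#' @return list of class `phantom_ground_truth`.
#' @export
phantom_ground_truth <- function(spec, n_cuts = 10, span_fraction = 0.2) {
  R <- spec$bfc_radius_mm; d <- spec$cap_depth_mm; a <- spec$defect_offset_mm
  rs <- cap_sphere_radius(R, d)
  if (is.na(a)) {
    lin <- 0; area <- 0
  } else {
    lin <- 100 * (R - a) / (2 * R)
    area <- 100 * (R^2 * acos(a / R) - a * sqrt(R^2 - a^2)) / (pi * R^2)
  }
  depth_fun <- function(y) {
    if (d <= 0) return(rep(0, length(y)))
    rs - sqrt((rs - d)^2 + y^2)
  }
  offsets <- if (n_cuts == 1) 0 else {
    seq(-span_fraction * R, span_fraction * R, length.out = n_cuts)
  }
  bssr <- if (d <= 0) 0 else 100 * (2 * d * R) / (R^2 - d^2)
  structure(list(bfc_radius_mm = R, bfc_diameter_mm = 2 * R,
                 bfc_area_mm2 = pi * R^2,
                 true_linear_ratio_percent = lin,
                 true_area_ratio_percent = area,
                 cap_sphere_radius_mm = rs,
                 true_depth_profile = depth_fun,
                 cut_offsets_mm = offsets,
                 true_central_depth_mm = d,
                 true_mean_depth_mm = mean(depth_fun(offsets)),
                 true_chord_mm = 2 * R,
                 true_bssr_percent = bssr),
            class = "phantom_ground_truth")
}

# radial extent of the outline from the star centre s along direction theta;
# the outline is (circle of radius R about the origin, union the superior
# trapezoid) clipped to the anterior half-plane y <= a
outline_radius <- function(theta, s, R, a, extension) {
  ux <- cos(theta); uy <- sin(theta)
  su <- s[1] * ux + s[2] * uy
  t_circle <- -su + sqrt(pmax(su^2 + R^2 - sum(s^2), 0))
  t_out <- t_circle
  if (extension) {
    x0 <- 0.4 * R; w0 <- sqrt(R^2 - x0^2)
    x1 <- 1.6 * R; w1 <- 0.5 * R
    corners <- rbind(c(x0, w0), c(x1, w1), c(x1, -w1), c(x0, -w0))
    for (i in seq_along(theta)) {
      ts <- numeric(0)
      for (e in 1:4) {
        p1 <- corners[e, ]; p2 <- corners[if (e == 4) 1 else e + 1, ]
        dd <- p2 - p1
        det <- -ux[i] * dd[2] + uy[i] * dd[1]
        if (abs(det) < 1e-14) next
        rhs <- p1 - s
        t <- (-rhs[1] * dd[2] + rhs[2] * dd[1]) / det
        w <- (ux[i] * rhs[2] - uy[i] * rhs[1]) / det
        if (t > 0 && w >= -1e-12 && w <= 1 + 1e-12) ts <- c(ts, t)
      }
      if (length(ts) >= 2 && min(ts) <= t_circle[i] + 1e-9) {
        t_out[i] <- max(t_out[i], max(ts))
      }
    }
  }
  if (!is.na(a)) {
    t_half <- ifelse(uy > 1e-12, (a - s[2]) / uy, Inf)
    t_out <- pmin(t_out, t_half)
  }
  t_out
}

#' Generate a synthetic glenoid phantom
#'
#' Builds the watertight scapula-like solid, a humeral-head proxy sphere
#' (radius R_s at the cap's centre of curvature, for articular-region
#' isolation), and the closed-form ground truth. The polar surface grid
#' places vertices exactly on the rim circle and on the defect chord, so the
#' tessellation introduces no spurious bone loss. Deterministic for a fixed
#' spec (jitter is seeded).
#'
#' @param spec a [phantom_spec()].
#' @return list with `scapula`, `humerus` ([triangle_surface()]s),
#'   `ground_truth` (a [phantom_ground_truth()] extended with
#'   `articular_vertex_ids` and `defect_edge_vertex_ids`) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  R <- spec$bfc_radius_mm; d <- spec$cap_depth_mm; a <- spec$defect_offset_mm
  edge <- spec$mesh_edge_mm
  rs <- cap_sphere_radius(R, d)
  s <- if (is.na(a)) c(0, 0) else c(0, (a - R) / 2)   # star centre

  rmax_est <- if (spec$superior_extension) 1.7 * R else R
  n_theta <- max(64L, as.integer(ceiling(2 * pi * rmax_est / edge)))
  theta <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  r_out <- outline_radius(theta, s, R, a, spec$superior_extension)
  ux <- cos(theta); uy <- sin(theta)
  n_r <- max(8L, as.integer(ceiling(max(r_out) / edge)))

  # the whole top face lies on the articular sphere (the superior extension
  # is articular too, making the face pear-shaped and its principal axes
  # well defined); the inferior rim sits exactly at z = 0
  top_z_fun <- function(x, y) {
    if (d <= 0) return(rep(0, length(x)))
    rho2 <- x^2 + y^2
    (rs - d) - sqrt(pmax(rs^2 - rho2, 0))
  }

  # --- vertex table: top centre, top rings, bottom centre, bottom rings ----
  top_xy <- matrix(0, 1 + n_r * n_theta, 2)
  top_xy[1, ] <- s
  for (j in seq_len(n_theta)) {
    t <- seq(0, r_out[j], length.out = n_r + 1)[-1]
    rows <- 1 + (j - 1) * n_r + seq_len(n_r)
    top_xy[rows, 1] <- s[1] + t * ux[j]
    top_xy[rows, 2] <- s[2] + t * uy[j]
  }
  top_z <- top_z_fun(top_xy[, 1], top_xy[, 2])
  n_top <- nrow(top_xy)
  zb <- -spec$slab_thickness_mm
  verts <- rbind(cbind(top_xy, top_z), cbind(top_xy, zb))
  bot_off <- n_top

  tid <- function(i, j) {           # top vertex id at ring i (0 = centre)
    if (i == 0) 1L else as.integer(1L + (j - 1L) * n_r + i)
  }
  bid <- function(i, j) bot_off + tid(i, j)

  jn <- c(seq_len(n_theta)[-1], 1L)  # j+1 with wraparound
  ring1 <- vapply(seq_len(n_theta), function(j) tid(1, j), integer(1))
  # top fan + annuli (outward normal +z): CCW seen from +z
  fan <- cbind(rep(1L, n_theta), ring1, ring1[jn])
  ann <- matrix(0L, 2 * n_theta * (n_r - 1), 3)
  row <- 1L
  for (j in seq_len(n_theta)) {
    for (i in seq_len(n_r - 1)) {
      A <- tid(i, j); B <- tid(i, jn[j]); C <- tid(i + 1, jn[j]); D <- tid(i + 1, j)
      ann[row, ] <- c(A, D, C); ann[row + 1L, ] <- c(A, C, B)
      row <- row + 2L
    }
  }
  # bottom (outward -z): reversed winding
  fan_b <- cbind(rep(bot_off + 1L, n_theta), bot_off + ring1[jn], bot_off + ring1)
  ann_b <- bot_off + ann[, c(1, 3, 2)]
  # wall between top ring n_r and bottom ring n_r (outward radial)
  wall <- matrix(0L, 2 * n_theta, 3)
  for (j in seq_len(n_theta)) {
    Tj <- tid(n_r, j); Tj1 <- tid(n_r, jn[j])
    Bj <- bid(n_r, j); Bj1 <- bid(n_r, jn[j])
    wall[2 * j - 1, ] <- c(Bj, Bj1, Tj1)
    wall[2 * j, ] <- c(Bj, Tj1, Tj)
  }
  faces <- rbind(fan, ann, fan_b, ann_b, wall)

  # ground-truth vertex sets: the whole top face is articular
  articular <- seq_len(n_top)
  defect_edge <- if (is.na(a)) integer(0) else {
    which(abs(top_xy[, 2] - a) < 1e-9)
  }

  # seeded jitter along the cap-sphere outward normal, articular vertices only
  if (spec$jitter_sd_mm > 0) {
    set.seed(spec$seed)
    amp <- stats::rnorm(length(articular), 0, spec$jitter_sd_mm)
    if (d > 0) {
      ctr <- c(0, 0, rs - d)
      nrm <- cbind(ctr[1] - verts[articular, 1],
                   ctr[2] - verts[articular, 2],
                   ctr[3] - verts[articular, 3])
      nrm <- nrm / sqrt(rowSums(nrm^2))
    } else {
      nrm <- matrix(rep(c(0, 0, 1), each = length(articular)), ncol = 3)
    }
    verts[articular, ] <- verts[articular, ] + amp * nrm
  }

  scapula <- triangle_surface(verts, faces)
  humerus <- icosphere(center = c(0, 0, if (is.finite(rs)) rs - d else 10 * R),
                       radius = if (is.finite(rs)) rs else 10 * R,
                       subdivisions = 4)
  gt <- phantom_ground_truth(spec)
  gt$articular_vertex_ids <- articular
  gt$defect_edge_vertex_ids <- defect_edge
  list(scapula = scapula, humerus = humerus, ground_truth = gt, spec = spec)
}

#' Subdivided icosahedron sphere mesh
#'
#' @param center,radius sphere geometry (mm).
#' @param subdivisions recursive 4-way subdivisions of the icosahedron
#'   (level k gives `20 * 4^k` triangles).
#' @return a [triangle_surface()].
#' @export
icosphere <- function(center = c(0, 0, 0), radius = 1, subdivisions = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(subdivisions)) {
    env <- new.env(hash = TRUE)
    vv <- v
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (exists(key, env, inherits = FALSE)) return(get(key, env))
      p <- (vv[i, ] + vv[j, ]) / 2
      p <- p / sqrt(sum(p^2))
      vv <<- rbind(vv, p)
      assign(key, nrow(vv), env)
      nrow(vv)
    }
    newf <- matrix(0L, nrow(f) * 4, 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newf[(t - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(c, ca, bc), c(ab, bc, ca))
    }
    v <- vv; f <- newf
  }
  triangle_surface(sweep(v * radius, 2, center, `+`), f)
}

#' Voxelize a closed mesh into a label volume
#'
#' Classifies voxel centres by x-ray crossing parity and assigns the scapula
#' label, emulating a CT-derived segmentation map. The grid is the mesh
#' bounding box padded by 5 voxels, axis-aligned (identity direction).
#'
#' @param mesh a closed (watertight) [triangle_surface()].
#' @param spacing_mm scalar or length-3 voxel size in mm.
#' @param role label role to assign (default `"scapula"`).
#' @return a [label_volume()].
#' @export
voxelize_phantom <- function(mesh, spacing_mm = 0.625, role = "scapula") {
  validate_surface(mesh)
  if (!is_watertight(mesh)) {
    stop("open mesh rejected: voxelization needs a watertight surface",
         call. = FALSE)
  }
  sp <- rep(as.numeric(spacing_mm), length.out = 3)
  lo <- apply(mesh$vertices, 2, min) - 5 * sp
  hi <- apply(mesh$vertices, 2, max) + 5 * sp
  dims <- as.integer(ceiling((hi - lo) / sp)) + 1L
  res <- .cpp_voxelize(mesh$vertices, mesh$triangles - 1L, lo, sp, dims)
  if (isTRUE(res$odd_parity)) {
    warning("odd ray-crossing parity encountered; mesh may graze voxel rays",
            call. = FALSE)
  }
  lt <- c(background = 0L, scapula = 1L)
  names(lt)[2] <- role
  label_volume(res$labels, sp, lo, diag(3), lt)
}
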