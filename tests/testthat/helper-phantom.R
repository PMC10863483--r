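# Shared phantom fixtures, built once per test run and cached.
#
# The phantom humeral-head proxy is perfectly congruent with the articular
# cap (zero joint space), so articular isolation uses a tight selection
# distance: 0.3 mm for noise-free phantoms, 1.0 mm under vertex jitter
# (several sigmas of the surface noise). Real CTs, with cartilage space and
# incongruence, use the 6 mm default instead.

.phantom_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .phantom_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .phantom_cache)
  }
  get(key, envir = .phantom_cache)
}

phantom_hint <- function() list(superior = c(1, 0, 0), anterior = c(0, 1, 0))

intact_phantom <- function() cached("intact", generate_phantom(phantom_spec()))

defect_phantom <- function() {
  cached("defect", generate_phantom(phantom_spec(defect_offset_mm = 8.5)))
}

# run the measurement stages explicitly (unit tests poke at intermediates)
measure_stages <- function(ph, tau = 0.3, n_cuts = 10) {
  reg <- isolate_glenoid_region(ph$scapula, ph$humerus, max_distance = tau)
  fr <- suppressWarnings(compute_frame(reg, phantom_hint()))
  rim <- select_posteroinferior_rim(reg, fr)
  circ <- fit_best_circle(rim, frame = fr)
  ctr <- project_contour(reg, circ, fr)
  list(region = reg, frame = fr, circle = circ, contour = ctr,
       linear = linear_bone_loss(ctr), area = area_bone_loss(ctr),
       profile = suppressWarnings(concavity_profile(reg, fr, circ, n_cuts)))
}

intact_stages <- function() cached("intact_stages", measure_stages(intact_phantom()))
defect_stages <- function() cached("defect_stages", measure_stages(defect_phantom()))

# planar disc mesh (fan triangulation), for frame/projection unit tests;
# returns a glenoid_region covering the whole disc
disc_region <- function(rx = 12.5, ry = rx, n = 180, rings = 6,
                        transform = identity) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  v <- rbind(c(0, 0, 0))
  for (i in seq_len(rings)) {
    v <- rbind(v, cbind(rx * (i / rings) * cos(th), ry * (i / rings) * sin(th), 0))
  }
  jn <- c(seq_len(n)[-1], 1L)
  id <- function(i, j) if (i == 0) 1L else as.integer(1L + (i - 1L) * n + j)
  f <- cbind(1L, vapply(seq_len(n), function(j) id(1, j), integer(1)),
             vapply(seq_len(n), function(j) id(1, jn[j]), integer(1)))
  for (i in seq_len(rings - 1)) {
    for (j in seq_len(n)) {
      f <- rbind(f, c(id(i, j), id(i + 1, j), id(i + 1, jn[j])),
                 c(id(i, j), id(i + 1, jn[j]), id(i, jn[j])))
    }
  }
  v <- transform(v)
  mesh <- triangle_surface(v, f)
  loop <- vapply(seq_len(n), function(j) id(rings, j), integer(1))
  glenoid_region(mesh, seq_len(nrow(v)), loop, seq_len(nrow(f)))
}

# contour_projection built directly from a polygon (unit tests of the
# 1D/2D metrics use analytic contours, not pipeline output)
make_contour <- function(polygon, radius) {
  structure(list(polygon = polygon, circle_radius = radius,
                 center = c(0, 0, 0), u = c(0, 1, 0), v = c(1, 0, 0)),
            class = "contour_projection")
}

# disc polygon with an optional chord cut at u = a (anterior)
chord_polygon <- function(r, a = NA, n = 720) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  p <- cbind(r * cos(th), r * sin(th))
  if (!is.na(a)) {
    phi <- acos(a / r)
    keep <- th >= phi & th <= 2 * pi - phi   # the arc spared by the chord
    p <- rbind(c(a, r * sin(phi)),           # chord top endpoint
               p[keep, , drop = FALSE],      # arc, counter-clockwise
               c(a, -r * sin(phi)))          # chord bottom endpoint
  }
  p
}

# exact circular-segment defect area for a chord at distance a
segment_area <- function(r, a) r^2 * acos(a / r) - a * sqrt(r^2 - a^2)

rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -axis[3], axis[2]),
             c(axis[3], 0, -axis[1]),
             c(-axis[2], axis[1], 0))
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# independent brute-force oracle for the circle fit: exhaustive centre grid
# at 0.001 mm (two-stage), with the radius profiled out exactly
# (r* = mean point-centre distance minimises the radial least squares)
grid_circle_oracle <- function(pts, start, half1 = 0.4, step1 = 0.005) {
  obj <- function(cx, cy) {
    d <- sqrt((pts[, 1] - cx)^2 + (pts[, 2] - cy)^2)
    sum((d - mean(d))^2)
  }
  search <- function(ctr, half, step) {
    g <- expand.grid(cx = seq(ctr[1] - half, ctr[1] + half, by = step),
                     cy = seq(ctr[2] - half, ctr[2] + half, by = step))
    vals <- mapply(obj, g$cx, g$cy)
    unlist(g[which.min(vals), ])
  }
  c1 <- search(start, half1, step1)
  c2 <- search(c1, 2 * step1, 0.001)
  d <- sqrt((pts[, 1] - c2[1])^2 + (pts[, 2] - c2[2])^2)
  c(cx = unname(c2[1]), cy = unname(c2[2]), r = mean(d))
}
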