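#' Glenoid articular region of a scapular mesh
#'
#' @param parent the scapular [triangle_surface()].
#' @param vertex_ids integer ids of vertices forming the articular face.
#' @param boundary_loop ordered vertex ids of the region border cycle.
#' @param triangle_ids ids of triangles fully inside the region.
#' @return An object of class `glenoid_region`.
#' @export
glenoid_region <- function(parent, vertex_ids, boundary_loop, triangle_ids) {
  if (!all(boundary_loop %in% vertex_ids)) {
    stop("boundary vertices must belong to the region", call. = FALSE)
  }
  structure(list(parent = parent,
                 vertex_ids = sort(unique(as.integer(vertex_ids))),
                 boundary_loop = as.integer(boundary_loop),
                 triangle_ids = as.integer(triangle_ids)),
            class = "glenoid_region")
}

#' @export
print.glenoid_region <- function(x, ...) {
  cat(sprintf("glenoid_region: %d vertices, %d triangles, border loop of %d\n",
              length(x$vertex_ids), length(x$triangle_ids),
              length(x$boundary_loop)))
  invisible(x)
}

region_vertices <- function(region) {
  region$parent$vertices[region$vertex_ids, , drop = FALSE]
}

boundary_points <- function(region) {
  region$parent$vertices[region$boundary_loop, , drop = FALSE]
}

#' Isolate the glenoid articular region
#'
#' Selects the articular face of the scapula as the set of vertices lying
#' within `max_distance` of the humeral head surface, or, when no humerus is
#' available, by geodesic growth from a seed point bounded by dihedral-angle
#' creases. An explicit `vertex_mask` bypasses both heuristics (the
#' programmatic analogue of manual outline refinement). The largest connected
#' component of the selection is kept.
#'
#' `max_distance` defaults to 6 mm, sized for real glenohumeral joints where
#' cartilage and incongruence separate the subchondral surfaces; for highly
#' congruent geometry (e.g. a phantom head lying on the socket) a tighter
#' threshold is appropriate.
#'
#' @param scapula scapular [triangle_surface()].
#' @param humerus humeral [triangle_surface()], or `NULL`.
#' @param seed 3D point (mm) near the articular surface, or `NULL`.
#' @param max_distance selection distance in mm.
#' @param vertex_mask explicit integer vertex ids or logical mask; overrides
#'   the heuristics.
#' @param crease_deg dihedral-angle bound (degrees) for seed growth.
#' @return a [glenoid_region()].
#' @export
isolate_glenoid_region <- function(scapula, humerus = NULL, seed = NULL,
                                   max_distance = 6, vertex_mask = NULL,
                                   crease_deg = 12) {
  validate_surface(scapula)
  nv <- nrow(scapula$vertices)
  if (!is.null(vertex_mask)) {
    if (is.logical(vertex_mask)) vertex_mask <- which(vertex_mask)
    sel <- as.integer(vertex_mask)
  } else if (!is.null(humerus)) {
    validate_surface(humerus)
    d <- .cpp_point_mesh_distance(scapula$vertices, humerus$vertices,
                                  humerus$triangles - 1L)
    sel <- which(d <= max_distance)
  } else if (!is.null(seed)) {
    sel <- grow_from_seed(scapula, seed, max_distance, crease_deg)
  } else {
    stop("provide a humerus mesh, a seed point, or an explicit vertex_mask",
         call. = FALSE)
  }
  if (length(sel) == 0) stop("no articular region found", call. = FALSE)

  comps <- vertex_components(scapula, sel)
  sizes <- vapply(comps, length, integer(1))
  main <- comps[[which.max(sizes)]]
  if (length(comps) > 1 && max(sizes) < 0.8 * length(sel)) {
    warning("articular selection is fragmented; keeping the largest component",
            call. = FALSE)
  }
  sel <- main
  keep <- logical(nv); keep[sel] <- TRUE
  f <- scapula$triangles
  tri_ids <- which(keep[f[, 1]] & keep[f[, 2]] & keep[f[, 3]])
  if (length(tri_ids) == 0) stop("no articular region found", call. = FALSE)
  loops <- boundary_loops(scapula, tri_ids)
  if (length(loops) == 0) stop("no articular region found (closed selection)",
                               call. = FALSE)
  len <- vapply(loops, function(l) {
    p <- scapula$vertices[c(l, l[1]), , drop = FALSE]
    sum(sqrt(rowSums(diff(p)^2)))
  }, numeric(1))
  # drop selected vertices that ended up in no region triangle
  used <- unique(as.integer(f[tri_ids, ]))
  glenoid_region(scapula, intersect(sel, used), loops[[which.max(len)]], tri_ids)
}

# Geodesic growth from the triangle nearest to `seed`, over the triangle
# adjacency (dual) graph; shared edges whose dihedral angle exceeds
# `crease_deg` act as barriers, so the flood stops at the articular margin.
# The seed must lie within `max_distance` of the mesh. Returns vertex ids of
# the flooded triangles.
grow_from_seed <- function(mesh, seed, max_distance, crease_deg) {
  seed <- as.numeric(seed)
  d2 <- colSums((t(mesh$vertices) - seed)^2)
  if (sqrt(min(d2)) > max_distance) return(integer())
  start_vertex <- which.min(d2)

  f <- mesh$triangles
  e1 <- mesh$vertices[f[, 2], ] - mesh$vertices[f[, 1], ]
  e2 <- mesh$vertices[f[, 3], ] - mesh$vertices[f[, 1], ]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n <- n / sqrt(rowSums(n^2))

  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  tri_of_edge <- rep(seq_len(nrow(f)), 3)
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  ord <- order(key)
  tri_s <- tri_of_edge[ord]
  key_s <- key[ord]
  grp_start <- which(!duplicated(key_s))
  grp_end <- c(grp_start[-1] - 1L, length(key_s))
  cosmin <- cos(crease_deg * pi / 180)
  two <- which(grp_end - grp_start + 1L == 2L)
  t1 <- tri_s[grp_start[two]]
  t2 <- tri_s[grp_start[two] + 1L]
  smooth <- rowSums(n[t1, , drop = FALSE] * n[t2, , drop = FALSE]) >= cosmin
  adj <- split(c(t2[smooth], t1[smooth]), c(t1[smooth], t2[smooth]))

  start_tris <- which(f[, 1] == start_vertex | f[, 2] == start_vertex |
                        f[, 3] == start_vertex)
  visited <- logical(nrow(f))
  visited[start_tris] <- TRUE
  frontier <- start_tris
  while (length(frontier) > 0) {
    nb <- unique(unlist(adj[as.character(frontier)], use.names = FALSE))
    nb <- nb[!visited[nb]]
    visited[nb] <- TRUE
    frontier <- nb
  }
  unique(as.integer(f[visited, ]))
}

#' Anatomical frame of the glenoid
#'
#' Principal-component frame of the articular vertices: eigenvectors of the
#' vertex covariance ordered by descending eigenvalue give the long
#' (superoinferior), short (anteroposterior) and normal (mediolateral) axes.
#' Eigenvectors are sign-ambiguous, so `orientation_hint` supplies the
#' approximate superior and anterior directions (e.g. from image axes and the
#' shoulder side); the normal axis completes a right-handed triad
#' (`long x short`).
#'
#' @param region a [glenoid_region()] with at least 10 vertices.
#' @param orientation_hint list with unit-ish vectors `superior` and
#'   `anterior`; they must be non-zero and non-parallel.
#' @return An object of class `anatomical_frame` with `origin` (vertex
#'   centroid), `long_axis`, `short_axis`, `normal_axis`.
#' @export
compute_frame <- function(region,
                          orientation_hint = list(superior = c(1, 0, 0),
                                                  anterior = c(0, 1, 0))) {
  pts <- region_vertices(region)
  if (nrow(pts) < 10) stop("region must have at least 10 vertices", call. = FALSE)
  sup <- as.numeric(orientation_hint$superior)
  ant <- as.numeric(orientation_hint$anterior)
  if (sqrt(sum(sup^2)) < 1e-12 || sqrt(sum(ant^2)) < 1e-12) {
    stop("orientation hints must be non-zero", call. = FALSE)
  }
  sup <- sup / sqrt(sum(sup^2)); ant <- ant / sqrt(sum(ant^2))
  if (abs(sum(sup * ant)) > 1 - 1e-9) {
    stop("orientation hints must not be parallel", call. = FALSE)
  }
  ctr <- colMeans(pts)
  ev <- eigen(stats::cov(pts), symmetric = TRUE)
  vals <- ev$values
  if (any(diff(vals) / max(vals[1], .Machine$double.eps) > -0.01)) {
    # two eigenvalues within 1% relative: direction split is data-deficient
    warning("ambiguous axes: near-degenerate vertex covariance", call. = FALSE)
  }
  vecs <- ev$vectors
  # deterministic tie-break: lexicographic sign normalisation before hints
  for (i in 1:3) {
    v <- vecs[, i]
    nz <- which(abs(v) > 1e-12)[1]
    if (v[nz] < 0) vecs[, i] <- -v
  }
  long <- vecs[, 1]; short <- vecs[, 2]
  if (sum(long * sup) < 0) long <- -long
  if (sum(short * ant) < 0) short <- -short
  normal <- c(long[2] * short[3] - long[3] * short[2],
              long[3] * short[1] - long[1] * short[3],
              long[1] * short[2] - long[2] * short[1])
  normal <- normal / sqrt(sum(normal^2))
  structure(list(origin = ctr, long_axis = long, short_axis = short,
                 normal_axis = normal),
            class = "anatomical_frame")
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat("anatomical_frame\n")
  cat(sprintf("  origin: (%.2f, %.2f, %.2f) mm\n",
              x$origin[1], x$origin[2], x$origin[3]))
  for (nm in c("long_axis", "short_axis", "normal_axis")) {
    cat(sprintf("  %-11s (%+.4f, %+.4f, %+.4f)\n", nm,
                x[[nm]][1], x[[nm]][2], x[[nm]][3]))
  }
  invisible(x)
}

frame_coords <- function(frame, pts, origin = frame$origin) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  rel <- sweep(pts, 2, origin, `-`)
  cbind(long = as.numeric(rel %*% frame$long_axis),
        short = as.numeric(rel %*% frame$short_axis),
        normal = as.numeric(rel %*% frame$normal_axis))
}

#' Posteroinferior rim vertices
#'
#' Splits the region border by the frame's long and short axes and returns
#' the border vertices in the posteroinferior quadrant (long-axis and
#' short-axis coordinates both strictly negative relative to the frame
#' origin) -- the quarter of the rim spared by anterior defects, used to fit
#' the best-fit circle.
#'
#' @param region a [glenoid_region()].
#' @param frame an [compute_frame()] result.
#' @return matrix of 3D points (>= 8 rows).
#' @export
select_posteroinferior_rim <- function(region, frame) {
  bp <- boundary_points(region)
  if (nrow(bp) == 0) stop("region has no boundary loop", call. = FALSE)
  uv <- frame_coords(frame, bp)
  keep <- uv[, "long"] < 0 & uv[, "short"] < 0
  pts <- bp[keep, , drop = FALSE]
  if (nrow(pts) < 8) {
    stop(sprintf("insufficient rim support: %d posteroinferior border vertices (need >= 8)",
                 nrow(pts)), call. = FALSE)
  }
  pts
}

#' Best-fit circle
#'
#' @param center 3D point, mm.
#' @param radius positive radius, mm.
#' @param plane_normal unit normal of the circle plane.
#' @return An object of class `best_fit_circle`, with derived fields
#'   `diameter` and `area`.
#' @export
best_fit_circle <- function(center, radius, plane_normal) {
  if (!is.finite(radius) || radius <= 0) stop("radius must be > 0", call. = FALSE)
  plane_normal <- as.numeric(plane_normal)
  plane_normal <- plane_normal / sqrt(sum(plane_normal^2))
  structure(list(center = as.numeric(center), radius = radius,
                 plane_normal = plane_normal,
                 diameter = 2 * radius, area = pi * radius^2),
            class = "best_fit_circle")
}

#' @export
print.best_fit_circle <- function(x, ...) {
  cat(sprintf("best_fit_circle: r = %.3f mm (d = %.3f mm, area = %.2f mm^2)\n",
              x$radius, x$diameter, x$area))
  invisible(x)
}

#' Fit the inferior best-fit circle to rim points
#'
#' Points are projected onto their own least-squares plane; an algebraic
#' (Kasa) circle fit provides the start for a damped Gauss-Newton refinement
#' of `sum((|p - c| - r)^2)`, which removes the algebraic fit's bias on
#' partial arcs. The step is halved until the RMS radial residual does not
#' increase, so the residual is non-increasing across iterations.
#'
#' @param rim_points n x 3 matrix of rim points (n >= 8 unless `override`).
#' @param override a [best_fit_circle()] returned verbatim when supplied
#'   (models manual refinement of the automatic estimate).
#' @param frame optional [compute_frame()] result; when given, the circle
#'   normal is oriented along the frame normal axis.
#' @param max_iter,tol Gauss-Newton controls.
#' @return a [best_fit_circle()].
#' @export
fit_best_circle <- function(rim_points, override = NULL, frame = NULL,
                            max_iter = 50, tol = 1e-10) {
  if (!is.null(override)) {
    stopifnot(inherits(override, "best_fit_circle"))
    return(override)
  }
  pts <- matrix(as.numeric(rim_points), ncol = 3)
  if (nrow(pts) < 3) stop("degenerate circle: need at least 3 points", call. = FALSE)
  ctr <- colMeans(pts)
  rel <- sweep(pts, 2, ctr, `-`)
  sv <- svd(rel)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1)) {
    stop("degenerate circle: rim points are collinear", call. = FALSE)
  }
  e1 <- sv$v[, 1]; e2 <- sv$v[, 2]; nrm <- sv$v[, 3]
  x <- rel %*% e1; y <- rel %*% e2

  # algebraic (Kasa) fit: x^2 + y^2 = 2 a x + 2 b y + c
  A <- cbind(2 * x, 2 * y, 1)
  rhs <- x^2 + y^2
  sol <- qr.solve(A, rhs)
  cx <- sol[1]; cy <- sol[2]
  r <- sqrt(max(sol[3] + cx^2 + cy^2, .Machine$double.eps))

  rms <- function(p) {
    d <- sqrt((x - p[1])^2 + (y - p[2])^2)
    sqrt(mean((d - p[3])^2))
  }
  par <- c(cx, cy, r)
  cur <- rms(par)
  history <- cur
  for (it in seq_len(max_iter)) {
    d <- sqrt((x - par[1])^2 + (y - par[2])^2)
    d[d < 1e-12] <- 1e-12
    res <- d - par[3]
    J <- cbind(-(x - par[1]) / d, -(y - par[2]) / d, -1)
    step <- tryCatch(qr.solve(J, -res), error = function(e) rep(0, 3))
    lam <- 1
    repeat {
      cand <- par + lam * step
      if (cand[3] > 0 && rms(cand) <= cur + 1e-15) break
      lam <- lam / 2
      if (lam < 1e-8) { cand <- par; break }
    }
    improved <- cur - rms(cand)
    par <- cand
    cur <- rms(par)
    history <- c(history, cur)
    if (improved < tol) break
  }
  if (!is.finite(par[3]) || par[3] > 1e3) {
    stop("degenerate circle: fitted radius exceeds 1e3 mm", call. = FALSE)
  }
  center3 <- ctr + par[1] * e1 + par[2] * e2
  if (!is.null(frame) && sum(nrm * frame$normal_axis) < 0) nrm <- -nrm
  out <- best_fit_circle(center3, par[3], nrm)
  attr(out, "rms_history") <- history   # per-iteration RMS radial residual
  out
}
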