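# --- 2D polygon utilities (shoelace area, point-in-polygon, clipping) -------

polygon_area <- function(p) {
  # signed shoelace area; positive for counter-clockwise polygons
  n <- nrow(p)
  x <- p[, 1]; y <- p[, 2]
  xn <- x[c(2:n, 1)]; yn <- y[c(2:n, 1)]
  sum(x * yn - xn * y) / 2
}

points_in_polygon <- function(pts, poly) {
  # even-odd crossing rule, vectorised over query points
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(pts))
  px <- pts[, 1]; py <- pts[, 2]
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

dist_to_polygon <- function(pts, poly) {
  # Euclidean distance from each point to the polygon boundary
  n <- nrow(poly)
  best <- rep(Inf, nrow(pts))
  px <- pts[, 1]; py <- pts[, 2]
  j <- n
  for (i in seq_len(n)) {
    ax <- poly[j, 1]; ay <- poly[j, 2]
    bx <- poly[i, 1]; by <- poly[i, 2]
    dx <- bx - ax; dy <- by - ay
    l2 <- dx * dx + dy * dy
    t <- if (l2 > 0) pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / l2)) else 0
    d2 <- (px - (ax + t * dx))^2 + (py - (ay + t * dy))^2
    best <- pmin(best, d2)
    j <- i
  }
  sqrt(best)
}

clip_halfplane <- function(poly, a, b, c) {
  # keep side a*x + b*y <= c (one Sutherland-Hodgman pass, vectorised)
  n <- nrow(poly)
  if (n == 0) return(poly)
  v <- a * poly[, 1] + b * poly[, 2] - c
  nxt <- c(seq_len(n)[-1], 1L)
  pin <- v <= 0
  crossing <- xor(pin, pin[nxt])
  t <- v / (v - v[nxt])
  ip <- poly + t * (poly[nxt, , drop = FALSE] - poly)
  keep_v <- which(pin); keep_c <- which(crossing)
  # emit the kept vertex at slot 2i-1 and the edge crossing at slot 2i
  ord <- order(c(2 * keep_v - 1, 2 * keep_c))
  rbind(poly[keep_v, , drop = FALSE], ip[keep_c, , drop = FALSE])[ord, ,
                                                                  drop = FALSE]
}

clip_polygon_convex <- function(subject, clip) {
  # Sutherland-Hodgman: clip a simple polygon against a convex,
  # counter-clockwise clip polygon
  n <- nrow(clip)
  out <- subject
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    # inside of CCW edge i->j is the left side
    dx <- clip[j, 1] - clip[i, 1]; dy <- clip[j, 2] - clip[i, 2]
    # left of edge: dx*(y - yi) - dy*(x - xi) >= 0  ->  dy*x - dx*y <= dy*xi - dx*yi
    out <- clip_halfplane(out, dy, -dx, dy * clip[i, 1] - dx * clip[i, 2])
    if (nrow(out) == 0) break
  }
  out
}

regular_polygon <- function(radius, n, center = c(0, 0)) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

polygon_self_intersects <- function(p) {
  n <- nrow(p)
  if (n < 4) return(FALSE)
  seg <- cbind(p, p[c(2:n, 1), , drop = FALSE]) # x1 y1 x2 y2
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    if (i == 1) js <- js[js != n]      # skip edges sharing a vertex
    if (length(js) == 0) next
    x1 <- seg[i, 1]; y1 <- seg[i, 2]; x2 <- seg[i, 3]; y2 <- seg[i, 4]
    x3 <- seg[js, 1]; y3 <- seg[js, 2]; x4 <- seg[js, 3]; y4 <- seg[js, 4]
    d1 <- (x2 - x1) * (y3 - y1) - (y2 - y1) * (x3 - x1)
    d2 <- (x2 - x1) * (y4 - y1) - (y2 - y1) * (x4 - x1)
    d3 <- (x4 - x3) * (y1 - y3) - (y4 - y3) * (x1 - x3)
    d4 <- (x4 - x3) * (y2 - y3) - (y4 - y3) * (x2 - x3)
    hit <- (d1 * d2 < 0) & (d3 * d4 < 0)
    if (any(hit)) return(TRUE)
  }
  FALSE
}

# --- contour projection ------------------------------------------------------

#' Project the glenoid contour onto the best-fit-circle plane
#'
#' Orthogonally projects the region boundary loop onto the circle plane and
#' expresses it in a 2D chart centred at the circle centre, with u along the
#' (in-plane) short axis and v along the long axis. Orientation is normalised
#' positive (counter-clockwise).
#'
#' @param region a [glenoid_region()].
#' @param circle a [best_fit_circle()].
#' @param frame an [compute_frame()] result (defines the chart axes).
#' @return An object of class `contour_projection`: `polygon` (n x 2, mm),
#'   `circle_radius`, and the 3D chart (`center`, `u`, `v`).
#' @export
project_contour <- function(region, circle, frame) {
  bp <- boundary_points(region)
  n <- circle$plane_normal
  u <- frame$short_axis - sum(frame$short_axis * n) * n
  if (sqrt(sum(u^2)) < 1e-9) stop("frame short axis is normal to the circle plane",
                                  call. = FALSE)
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  rel <- sweep(bp, 2, circle$center, `-`)
  poly <- cbind(rel %*% u, rel %*% v)
  # drop near-duplicate consecutive points
  nrep <- nrow(poly)
  d <- sqrt(rowSums((poly - poly[c(2:nrep, 1), , drop = FALSE])^2))
  poly <- poly[d > 1e-9, , drop = FALSE]
  if (nrow(poly) < 3 || abs(polygon_area(poly)) < 1) {
    stop("degenerate projection: contour collapses on the circle plane",
         call. = FALSE)
  }
  if (polygon_area(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  if (polygon_self_intersects(poly)) {
    warning("projected contour self-intersects; proceeding with the raw polygon",
            call. = FALSE)
  }
  structure(list(polygon = poly, circle_radius = circle$radius,
                 center = circle$center, u = u, v = v),
            class = "contour_projection")
}

#' @export
print.contour_projection <- function(x, ...) {
  cat(sprintf("contour_projection: %d vertices, area %.2f mm^2 (BFC r = %.2f mm)\n",
              nrow(x$polygon), polygon_area(x$polygon), x$circle_radius))
  invisible(x)
}

# --- 1D and 2D bone loss -----------------------------------------------------

#' Linear (1D) glenoid bone loss
#'
#' The best-fit circle boundary is sampled densely; samples falling outside
#' the projected glenoid contour indicate missing rim, and the defect
#' diameter is the maximum distance from such a sample to the contour. For a
#' straight (chord-like) anterior defect this equals the classical
#' perpendicular rim-to-circle distance. The ratio to the BFC diameter is the
#' relative linear bone loss.
#'
#' @param contour a [project_contour()] result.
#' @param n_samples number of circle boundary samples.
#' @param anterior_only restrict the search to the anterior half-plane
#'   (u > 0), mimicking the manual technique; default `FALSE` (any missing
#'   arc counts).
#' @return list of class `linear_bone_loss`: `bfc_diameter_mm`,
#'   `defect_diameter_mm`, `ratio_percent`.
#' @export
linear_bone_loss <- function(contour, n_samples = 2048, anterior_only = FALSE) {
  r <- contour$circle_radius
  samp <- regular_polygon(r, n_samples)
  if (anterior_only) samp <- samp[samp[, 1] > 0, , drop = FALSE]
  outside <- !points_in_polygon(samp, contour$polygon)
  defect <- 0
  if (any(outside)) {
    defect <- max(dist_to_polygon(samp[outside, , drop = FALSE], contour$polygon))
  }
  defect <- min(max(defect, 0), 2 * r)
  structure(list(bfc_diameter_mm = 2 * r,
                 defect_diameter_mm = defect,
                 ratio_percent = 100 * defect / (2 * r)),
            class = "linear_bone_loss")
}

#' Area (2D) glenoid bone loss
#'
#' The defect area is the BFC area minus the area of the projected glenoid
#' contour inside the BFC, computed by clipping the contour polygon against
#' the circle (represented as a regular polygon whose relative area error is
#' below 1e-5). The ratio to the BFC area is the relative area bone loss
#' (surface-based method).
#'
#' @param contour a [project_contour()] result.
#' @param n_polygon number of circle polygon vertices.
#' @return list of class `area_bone_loss`: `bfc_area_mm2`, `defect_area_mm2`,
#'   `ratio_percent`.
#' @export
area_bone_loss <- function(contour, n_polygon = 1024) {
  r <- contour$circle_radius
  circle <- regular_polygon(r, n_polygon)
  inter <- clip_polygon_convex(contour$polygon, circle)
  inter_area <- if (nrow(inter) >= 3) abs(polygon_area(inter)) else 0
  if (!is.finite(inter_area)) stop("polygon clipping failed", call. = FALSE)
  bfc_area <- pi * r^2
  defect <- min(max(bfc_area - inter_area, 0), bfc_area)
  structure(list(bfc_area_mm2 = bfc_area,
                 defect_area_mm2 = defect,
                 ratio_percent = 100 * defect / bfc_area),
            class = "area_bone_loss")
}

#' @export
print.linear_bone_loss <- function(x, ...) {
  cat(sprintf("linear bone loss: defect %.2f mm / BFC %.2f mm = %.1f%%\n",
              x$defect_diameter_mm, x$bfc_diameter_mm, x$ratio_percent))
  invisible(x)
}

#' @export
print.area_bone_loss <- function(x, ...) {
  cat(sprintf("area bone loss: defect %.2f mm^2 / BFC %.2f mm^2 = %.1f%%\n",
              x$defect_area_mm2, x$bfc_area_mm2, x$ratio_percent))
  invisible(x)
}
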