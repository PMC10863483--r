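#' Cross-section of the articular region
#'
#' Intersects the articular-region triangles with the plane whose long-axis
#' coordinate (relative to the BFC centre) equals `offset_mm`; the plane is
#' spanned by the short and normal axes, i.e. the cut runs along the short
#' axis, as in standardized axial reslicing perpendicular to the glenoid long
#' axis. Intersection segments are chained into polylines and the longest one
#' is returned, expressed in (u, w) coordinates with u along the short axis
#' and w along the normal axis (lateral positive).
#'
#' @param region a [glenoid_region()] (only articular triangles participate).
#' @param frame an [compute_frame()] result.
#' @param circle a [best_fit_circle()]; the cut stack is centred on its
#'   centre and bounded by its radius.
#' @param offset_mm signed plane offset along the long axis
#'   (|offset| < circle radius).
#' @return An object of class `concavity_cut` with `offset_mm` and `profile`
#'   (ordered n x 2 polyline); depth fields are filled by
#'   [supporting_line_depth()].
#' @export
cross_section <- function(region, frame, circle, offset_mm = 0) {
  if (abs(offset_mm) >= circle$radius) {
    stop("cut misses region: |offset| must be below the BFC radius", call. = FALSE)
  }
  mesh <- region$parent
  f <- mesh$triangles[region$triangle_ids, , drop = FALSE]
  lc <- as.numeric(sweep(mesh$vertices, 2, circle$center, `-`) %*% frame$long_axis)
  d <- lc - offset_mm
  d[d == 0] <- 1e-12   # vertices exactly on the plane: nudge to one side
  d1 <- d[f[, 1]]; d2 <- d[f[, 2]]; d3 <- d[f[, 3]]
  cut <- (d1 > 0) + (d2 > 0) + (d3 > 0)
  hit <- which(cut == 1L | cut == 2L)
  if (length(hit) == 0) stop("cut misses region", call. = FALSE)

  seg_p <- vector("list", length(hit))
  seg_key <- vector("list", length(hit))
  edge_cross <- function(i, j) {
    t <- d[i] / (d[i] - d[j])
    p <- mesh$vertices[i, ] + t * (mesh$vertices[j, ] - mesh$vertices[i, ])
    list(p = p, key = paste(min(i, j), max(i, j)))
  }
  for (s in seq_along(hit)) {
    tri <- f[hit[s], ]
    sgn <- d[tri] > 0
    solo <- tri[sgn == (sum(sgn) == 1L)]
    pair <- setdiff(tri, solo)
    a <- edge_cross(solo, pair[1]); b <- edge_cross(solo, pair[2])
    seg_p[[s]] <- rbind(a$p, b$p)
    seg_key[[s]] <- c(a$key, b$key)
  }

  # chain segments whose endpoints share a crossed mesh edge
  keys <- do.call(rbind, seg_key)
  polylines <- chain_segments(keys)
  lengths_mm <- vapply(polylines, function(pl) {
    pts <- polyline_points(pl, keys, seg_p)
    sum(sqrt(rowSums(diff(pts)^2)))
  }, numeric(1))
  best <- polylines[[which.max(lengths_mm)]]
  if (max(lengths_mm) < 5) stop("cut too short: polyline below 5 mm", call. = FALSE)
  pts3 <- polyline_points(best, keys, seg_p)
  rel <- sweep(pts3, 2, circle$center, `-`)
  profile <- cbind(u = as.numeric(rel %*% frame$short_axis),
                   w = as.numeric(rel %*% frame$normal_axis))
  structure(list(offset_mm = offset_mm, profile = profile,
                 points3d = pts3,
                 depth_mm = NA_real_, chord_mm = NA_real_,
                 contact_points = NULL),
            class = "concavity_cut")
}

# Chain a set of segments (rows of edge-key pairs) into ordered node paths.
# Returns a list of integer vectors of segment indices in walk order.
chain_segments <- function(keys) {
  nodes <- unique(as.vector(keys))
  a <- match(keys[, 1], nodes); b <- match(keys[, 2], nodes)
  inc <- split(rep(seq_len(nrow(keys)), 2), c(a, b))
  used <- rep(FALSE, nrow(keys))
  deg <- lengths(inc)
  paths <- list()
  walk <- function(seg, node) {
    path <- seg
    used[seg] <<- TRUE
    cur <- if (a[seg] == node) b[seg] else a[seg]
    repeat {
      nxt <- NA_integer_
      for (cand in inc[[as.character(cur)]]) if (!used[cand]) { nxt <- cand; break }
      if (is.na(nxt)) break
      used[nxt] <<- TRUE
      path <- c(path, nxt)
      cur <- if (a[nxt] == cur) b[nxt] else a[nxt]
    }
    path
  }
  # start walks at open ends first so open polylines are traversed end-to-end
  for (n1 in which(deg == 1)) {
    seg <- inc[[as.character(n1)]][1]
    if (!used[seg]) paths[[length(paths) + 1]] <- walk(seg, n1)
  }
  for (s in seq_len(nrow(keys))) {
    if (!used[s]) paths[[length(paths) + 1]] <- walk(s, a[s])
  }
  paths
}

polyline_points <- function(path, keys, seg_p) {
  # reconstruct ordered 3D points of a chained path of segments
  if (length(path) == 1) return(seg_p[[path]])
  first_keys <- keys[path[1], ]
  second_keys <- keys[path[2], ]
  start_key <- setdiff(first_keys, second_keys)
  if (length(start_key) == 0) start_key <- first_keys[1]  # 2-segment loop
  cur <- start_key[1]
  pts <- matrix(numeric(0), 0, 3)
  for (s in path) {
    k <- keys[s, ]
    p <- seg_p[[s]]
    if (k[1] == cur) { pts <- rbind(pts, p); cur <- k[2] }
    else { pts <- rbind(pts, p[2:1, ]); cur <- k[1] }
  }
  # consecutive segments share endpoints; drop the duplicates
  keep <- c(TRUE, sqrt(rowSums(diff(pts)^2)) > 1e-12)
  pts[keep, , drop = FALSE]
}

#' Supporting-line concavity depth of a cut
#'
#' The supporting line is parallel to the short axis and touches the profile
#' from the lateral side without intersecting it, i.e. the line w = max(w).
#' The concavity depth is the distance from that line to the farthest
#' (deepest) profile point; the contact points are the profile points on the
#' line (within `contact_tol`), and the chord is their maximal u-separation.
#'
#' @param cut a [cross_section()] result with >= 3 profile points.
#' @param contact_tol touch tolerance in mm.
#' @return the cut with `depth_mm`, `chord_mm` (NA when fewer than two
#'   contacts) and `contact_points` filled.
#' @export
supporting_line_depth <- function(cut, contact_tol = 1e-6) {
  pr <- cut$profile
  if (nrow(pr) < 3) stop("profile must have at least 3 points", call. = FALSE)
  wmax <- max(pr[, 2])
  cut$depth_mm <- wmax - min(pr[, 2])
  contacts <- pr[pr[, 2] >= wmax - contact_tol, , drop = FALSE]
  cut$contact_points <- contacts
  cut$chord_mm <- if (nrow(contacts) >= 2) {
    max(contacts[, 1]) - min(contacts[, 1])
  } else NA_real_
  cut
}

#' Concavity profile over parallel cuts
#'
#' Repeats [cross_section()] + [supporting_line_depth()] over `n_cuts` planes
#' evenly spaced within `span_fraction` of the BFC radius on either side of
#' the BFC centre, and averages depths (and chords) over the successful cuts.
#' Cuts that fail (miss the region, or produce a too-short polyline) are
#' skipped with a warning; more than half must succeed.
#'
#' Per-cut chords with fewer than two supporting-line contacts fall back to
#' the BFC diameter (flagged in `chord_source`).
#'
#' @param region,frame,circle as in [cross_section()].
#' @param n_cuts number of cut planes (default 10).
#' @param span_fraction half-span of cut offsets as a fraction of the BFC
#'   radius (default 0.2).
#' @param contact_tol touch tolerance passed to [supporting_line_depth()].
#' @return An object of class `concavity_profile`: `cuts`, `mean_depth_mm`,
#'   `mean_chord_mm`, `chord_source`.
#' @export
concavity_profile <- function(region, frame, circle, n_cuts = 10,
                              span_fraction = 0.2, contact_tol = 1e-6) {
  if (n_cuts < 1) stop("n_cuts must be >= 1", call. = FALSE)
  offsets <- if (n_cuts == 1) 0 else {
    seq(-span_fraction * circle$radius, span_fraction * circle$radius,
        length.out = n_cuts)
  }
  cuts <- vector("list", length(offsets))
  ok <- logical(length(offsets))
  for (i in seq_along(offsets)) {
    res <- tryCatch({
      supporting_line_depth(cross_section(region, frame, circle, offsets[i]),
                            contact_tol)
    }, error = function(e) {
      warning(sprintf("cut at offset %.2f mm skipped: %s",
                      offsets[i], conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (!is.null(res)) {
      cuts[[i]] <- res
      ok[i] <- TRUE
    }
  }
  if (sum(ok) < length(offsets) / 2) {
    stop("concavity not measurable: more than half of the cuts failed",
         call. = FALSE)
  }
  good <- cuts[ok]
  depths <- vapply(good, function(c) c$depth_mm, numeric(1))
  chords <- vapply(good, function(c) c$chord_mm, numeric(1))
  chord_source <- ifelse(is.na(chords), "bfc_diameter_fallback", "contacts")
  chords[is.na(chords)] <- 2 * circle$radius
  structure(list(cuts = good, offsets = offsets[ok],
                 mean_depth_mm = mean(depths),
                 mean_chord_mm = mean(chords),
                 chord_source = chord_source),
            class = "concavity_profile")
}

#' @export
print.concavity_profile <- function(x, ...) {
  cat(sprintf("concavity_profile: %d cuts, mean depth %.3f mm, mean chord %.2f mm\n",
              length(x$cuts), x$mean_depth_mm, x$mean_chord_mm))
  invisible(x)
}

#' Bony shoulder stability ratio (BSSR)
#'
#' Models the glenoid cross-section as a circular arc of depth d and
#' half-chord c = chord/2. The arc's radius of curvature is
#' r = (d^2 + c^2) / (2 d), the rim angle is alpha = asin(c / r), and the
#' stability ratio -- the maximal dislocating force the bony concavity can
#' resist relative to the compressive load in the concavity-compression
#' mechanism -- is 100 * tan(alpha). An alternative depth/chord -> ratio
#' function can be substituted via `ratio_fn` since the arc model is this
#' package's reconstruction of the published method.
#'
#' @param depth_mm concavity depth d >= 0 (mm).
#' @param chord_mm concavity diameter (chord) > 0 (mm); depth must not
#'   exceed the half-chord (a deeper profile is no longer a minor arc).
#' @param ratio_fn optional `function(depth_mm, chord_mm)` returning a
#'   percentage, replacing the circular-arc model.
#' @return An object of class `bssr_result`: `depth_mm`, `chord_mm`,
#'   `radius_of_curvature_mm`, `rim_angle_deg`, `bssr_percent`, `model`.
#' @export
compute_bssr <- function(depth_mm, chord_mm, ratio_fn = NULL) {
  if (!is.finite(depth_mm) || !is.finite(chord_mm)) {
    stop("depth and chord must be finite", call. = FALSE)
  }
  if (depth_mm < 0) stop("depth must be >= 0", call. = FALSE)
  if (chord_mm <= 0) stop("chord must be > 0", call. = FALSE)
  if (!is.null(ratio_fn)) {
    return(structure(list(depth_mm = depth_mm, chord_mm = chord_mm,
                          radius_of_curvature_mm = NA_real_,
                          rim_angle_deg = NA_real_,
                          bssr_percent = ratio_fn(depth_mm, chord_mm),
                          model = "user-supplied"),
                     class = "bssr_result"))
  }
  c_half <- chord_mm / 2
  if (depth_mm == 0) {
    return(structure(list(depth_mm = 0, chord_mm = chord_mm,
                          radius_of_curvature_mm = Inf, rim_angle_deg = 0,
                          bssr_percent = 0, model = "circular-arc tan(alpha)"),
                     class = "bssr_result"))
  }
  if (depth_mm > c_half) {
    stop("depth exceeds circular-arc model: depth must be <= chord / 2",
         call. = FALSE)
  }
  r <- (depth_mm^2 + c_half^2) / (2 * depth_mm)
  alpha <- asin(min(c_half / r, 1))
  structure(list(depth_mm = depth_mm, chord_mm = chord_mm,
                 radius_of_curvature_mm = r,
                 rim_angle_deg = alpha * 180 / pi,
                 bssr_percent = 100 * tan(alpha),
                 model = "circular-arc tan(alpha)"),
            class = "bssr_result")
}

#' @export
print.bssr_result <- function(x, ...) {
  cat(sprintf("BSSR: %.2f%% (depth %.2f mm, chord %.2f mm, r = %.2f mm, alpha = %.1f deg)\n",
              x$bssr_percent, x$depth_mm, x$chord_mm,
              x$radius_of_curvature_mm, x$rim_angle_deg))
  cat(sprintf("  model: %s\n", x$model))
  invisible(x)
}
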