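#' Triangle surface mesh
#'
#' Constructs a triangle surface in physical millimetre coordinates. This is
#' the geometric currency of the package: bone surfaces extracted from label
#' volumes, phantom solids and articular subregions are all
#' `triangle_surface` objects.
#'
#' @param vertices numeric matrix, n x 3, vertex positions in mm.
#' @param triangles integer matrix, m x 3, 1-based indices into `vertices`.
#' @param check if `TRUE` (default), validate invariants: finite coordinates,
#'   valid indices, at least 4 vertices, and no triangle with area below
#'   1e-9 mm^2.
#' @return An object of class `triangle_surface` with elements `vertices`
#'   and `triangles`.
#' @export
triangle_surface <- function(vertices, triangles, check = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(triangles) <- NULL
  if (ncol(vertices) != 3L || ncol(triangles) != 3L) {
    stop("vertices and triangles must have 3 columns", call. = FALSE)
  }
  obj <- structure(list(vertices = vertices, triangles = triangles),
                   class = "triangle_surface")
  if (check) validate_surface(obj)
  obj
}

#' @rdname triangle_surface
#' @param x a `triangle_surface`.
#' @export
validate_surface <- function(x) {
  v <- x$vertices; f <- x$triangles
  if (nrow(f) == 0L) stop("empty mesh: no triangles", call. = FALSE)
  if (nrow(v) < 4L) stop("mesh must have at least 4 vertices", call. = FALSE)
  if (!all(is.finite(v))) stop("non-finite vertex coordinates", call. = FALSE)
  if (min(f) < 1L || max(f) > nrow(v)) {
    stop("triangle indices out of range", call. = FALSE)
  }
  a <- triangle_areas(x)
  if (any(a < 1e-9)) {
    stop(sprintf("mesh contains %d degenerate triangle(s) with area < 1e-9 mm^2",
                 sum(a < 1e-9)), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.triangle_surface <- function(x, ...) {
  cat(sprintf("triangle_surface: %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  cat(sprintf("  area %.2f mm^2, %swatertight\n",
              mesh_area(x), if (is_watertight(x)) "" else "not "))
  invisible(x)
}

triangle_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$triangles
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Surface area and enclosed volume
#'
#' `mesh_area()` sums triangle areas; `mesh_volume()` sums signed tetrahedron
#' volumes against the origin and returns the absolute value, which equals
#' the enclosed volume for a closed, consistently oriented surface.
#'
#' @param mesh a [triangle_surface()].
#' @return scalar, mm^2 (area) or mm^3 (volume).
#' @export
mesh_area <- function(mesh) sum(triangle_areas(mesh))

#' @rdname mesh_area
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$triangles
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  det <- a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
         a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
         a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])
  abs(sum(det)) / 6
}

mesh_edges <- function(mesh) {
  f <- mesh$triangles
  rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
}

#' Watertightness test
#'
#' A surface is watertight when every undirected edge is shared by exactly
#' two triangles.
#'
#' @param mesh a [triangle_surface()].
#' @return logical scalar.
#' @export
is_watertight <- function(mesh) {
  e <- mesh_edges(mesh)
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

# One Laplacian smoothing pass: each vertex moves halfway toward the mean of
# its edge-connected neighbours. Used optionally after isosurface extraction.
laplacian_smooth_once <- function(mesh, lambda = 0.5) {
  e <- mesh_edges(mesh)
  nv <- nrow(mesh$vertices)
  acc <- matrix(0, nv, 3)
  for (col in 1:3) {
    acc[, col] <- tabulate_sum(e[, 1], mesh$vertices[e[, 2], col], nv)
  }
  cnt <- tabulate(e[, 1], nbins = nv)
  has <- cnt > 0
  target <- mesh$vertices
  target[has, ] <- acc[has, ] / cnt[has]
  mesh$vertices <- mesh$vertices + lambda * (target - mesh$vertices)
  mesh
}

tabulate_sum <- function(index, values, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(values, index)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# Connected components of the vertex graph restricted to `vertex_ids`,
# using union-find over triangle edges.
vertex_components <- function(mesh, vertex_ids) {
  keep <- logical(nrow(mesh$vertices))
  keep[vertex_ids] <- TRUE
  f <- mesh$triangles
  tri_in <- keep[f[, 1]] & keep[f[, 2]] & keep[f[, 3]]
  e <- rbind(f[tri_in, c(1, 2), drop = FALSE],
             f[tri_in, c(2, 3), drop = FALSE],
             f[tri_in, c(3, 1), drop = FALSE])
  parent <- seq_len(nrow(mesh$vertices))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]   # path halving
      i <- parent[i]
    }
    i
  }
  if (nrow(e) > 0) {
    for (r in seq_len(nrow(e))) {
      a <- find(e[r, 1]); b <- find(e[r, 2])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(vertex_ids, function(i) as.integer(find(i)), integer(1))
  split(vertex_ids, roots)
}

# Boundary loops of a triangle subset: edges used by exactly one triangle,
# chained into closed cycles. Returns a list of ordered vertex-id vectors.
boundary_loops <- function(mesh, tri_ids) {
  f <- mesh$triangles[tri_ids, , drop = FALSE]
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  bkey <- names(tab)[tab == 1L]
  if (length(bkey) == 0) return(list())
  be <- e[match(bkey, key), , drop = FALSE]
  nxt <- new.env(hash = TRUE)
  for (r in seq_len(nrow(be))) {
    k <- as.character(be[r, 1])
    assign(k, c(if (exists(k, nxt, inherits = FALSE)) get(k, nxt) else integer(), be[r, 2]), nxt)
    k2 <- as.character(be[r, 2])
    assign(k2, c(if (exists(k2, nxt, inherits = FALSE)) get(k2, nxt) else integer(), be[r, 1]), nxt)
  }
  used <- new.env(hash = TRUE)
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  loops <- list()
  for (r in seq_len(nrow(be))) {
    if (exists(ekey(be[r, 1], be[r, 2]), used, inherits = FALSE)) next
    loop <- c(be[r, 1], be[r, 2])
    assign(ekey(be[r, 1], be[r, 2]), TRUE, used)
    repeat {
      cur <- loop[length(loop)]
      nbs <- get(as.character(cur), nxt)
      nb <- NA_integer_
      for (cand in nbs) {
        if (!exists(ekey(cur, cand), used, inherits = FALSE)) { nb <- cand; break }
      }
      if (is.na(nb)) break
      assign(ekey(cur, nb), TRUE, used)
      if (nb == loop[1]) break
      loop <- c(loop, nb)
    }
    if (length(loop) >= 3) loops[[length(loops) + 1]] <- loop
  }
  loops
}
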