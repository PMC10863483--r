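#' Labelled voxel volume
#'
#' A CT-segmentation-style label map with physical geometry. Voxel indices
#' are 0-based; the world position of voxel (i, j, k) is
#' `origin + direction %*% (c(i, j, k) * spacing)`, all in mm, LPS axes.
#'
#' @param labels 3D integer array of label values.
#' @param spacing numeric length 3, voxel size in mm (strictly positive).
#' @param origin numeric length 3, world position of voxel (0,0,0) in mm.
#' @param direction 3x3 orthonormal axis direction cosines.
#' @param label_table named integer vector mapping roles to label values,
#'   e.g. `c(background = 0, scapula = 1, humerus = 2)`.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing, origin = c(0, 0, 0),
                         direction = diag(3),
                         label_table = c(background = 0L, scapula = 1L)) {
  labels <- as.array(labels)
  storage.mode(labels) <- "integer"
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  direction <- as.matrix(direction)
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array", call. = FALSE)
  if (any(spacing <= 0)) stop("spacing must be strictly positive", call. = FALSE)
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6) {
    stop("direction matrix is not orthonormal", call. = FALSE)
  }
  label_table <- vapply(label_table, as.integer, integer(1))
  present <- unique(as.integer(labels))
  unknown <- setdiff(present, label_table)
  if (length(unknown) > 0) {
    stop(sprintf("voxel value(s) %s not present in label_table",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  structure(list(labels = labels, spacing = spacing, origin = origin,
                 direction = direction, label_table = label_table),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("label_volume: %s voxels at %s mm\n",
              paste(dim(x$labels), collapse = " x "),
              paste(signif(x$spacing, 4), collapse = " x ")))
  for (nm in names(x$label_table)) {
    cat(sprintf("  %s = %d (%d voxels)\n", nm, x$label_table[[nm]],
                sum(x$labels == x$label_table[[nm]])))
  }
  invisible(x)
}

#' Map voxel indices to world coordinates
#'
#' @param volume a [label_volume()].
#' @param idx n x 3 matrix of 0-based voxel indices (may be fractional).
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(volume, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep(idx %*% diag(volume$spacing) %*% t(volume$direction), 2,
        volume$origin, `+`)
}

#' @rdname voxel_to_world
#' @param world n x 3 matrix of world coordinates in mm.
#' @export
world_to_voxel <- function(volume, world) {
  world <- matrix(as.numeric(world), ncol = 3)
  sweep(world, 2, volume$origin, `-`) %*% volume$direction %*%
    diag(1 / volume$spacing)
}

role_label <- function(volume, role) {
  if (!role %in% names(volume$label_table)) {
    stop(sprintf("label not found: %s", role), call. = FALSE)
  }
  volume$label_table[[role]]
}

#' Read and write segmentation label volumes
#'
#' Reads NIfTI (`.nii`, `.nii.gz`) or NRRD (`.nrrd`) label volumes into a
#' [label_volume()] in LPS world coordinates. NIfTI stores RAS geometry; the
#' first two world axes are negated on the way in/out. Voxel values must be
#' integers (tolerance 1e-6) and every requested role must be present.
#'
#' @param path file path; format chosen by extension.
#' @param label_config named integer vector mapping roles to label values.
#' @return `read_label_volume()` returns a [label_volume()];
#'   `write_label_volume()` returns `path` invisibly.
#' @export
read_label_volume <- function(path,
                              label_config = c(background = 0L, scapula = 1L,
                                               humerus = 2L)) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    raw <- read_nifti_lps(path)
  } else if (grepl("\\.nrrd$", lower)) {
    raw <- read_nrrd_lps(path)
  } else {
    stop("unsupported volume format (expected .nii, .nii.gz or .nrrd)",
         call. = FALSE)
  }
  vals <- raw$data
  if (max(abs(vals - round(vals))) > 1e-6) {
    stop("volume contains non-integer voxel values", call. = FALSE)
  }
  labels <- array(as.integer(round(vals)), dim = dim(vals))
  present <- unique(as.integer(labels))
  label_config <- vapply(label_config, as.integer, integer(1))
  for (nm in setdiff(names(label_config), "background")) {
    if (!label_config[[nm]] %in% present) {
      stop(sprintf("label not found: %s", nm), call. = FALSE)
    }
  }
  keep <- label_config[label_config %in% present | names(label_config) == "background"]
  extra <- setdiff(present, keep)
  if (length(extra) > 0) {
    keep <- c(keep, stats::setNames(extra, paste0("label", extra)))
  }
  label_volume(labels, raw$spacing, raw$origin, raw$direction, keep)
}

#' @rdname read_label_volume
#' @param volume a [label_volume()].
#' @export
write_label_volume <- function(volume, path) {
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    write_nifti_lps(volume, path)
  } else if (grepl("\\.nrrd$", lower)) {
    write_nrrd_lps(volume, path)
  } else {
    stop("unsupported volume format (expected .nii, .nii.gz or .nrrd)",
         call. = FALSE)
  }
  invisible(path)
}

# NIfTI geometry is RAS; our convention is LPS: negate the first two world
# axes of the affine in both directions.
ras_lps <- diag(c(-1, -1, 1))

read_nifti_lps <- function(path) {
  img <- RNifti::readNifti(path)
  # voxel (0-based) -> RAS world; prefer the sform (exact affine) over the
  # quaternion form, which cannot carry shear and loses precision
  aff <- RNifti::xform(img, useQuaternionFirst = FALSE)
  data <- array(as.numeric(img), dim = dim(img))
  lin <- ras_lps %*% aff[1:3, 1:3]
  spacing <- sqrt(colSums(lin^2))
  direction <- sweep(lin, 2, spacing, `/`)
  origin <- as.numeric(ras_lps %*% aff[1:3, 4])
  list(data = data, spacing = spacing, origin = origin, direction = direction)
}

write_nifti_lps <- function(volume, path) {
  lin <- ras_lps %*% (volume$direction %*% diag(volume$spacing))
  aff <- rbind(cbind(lin, as.numeric(ras_lps %*% volume$origin)), c(0, 0, 0, 1))
  img <- RNifti::asNifti(volume$labels, datatype = "int16",
                         pixdim = volume$spacing)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
}

# Minimal NRRD reader/writer: 3D, raw or gzip encoding, little endian,
# LPS space. Covers the label maps this package writes and the common output
# of segmentation tools.
read_nrrd_lps <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD", magic)) stop("not an NRRD file", call. = FALSE)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexpr(":=?", line), invert = TRUE)[[1]]
    hdr[[tolower(trimws(kv[1]))]] <- trimws(kv[2])
  }
  sizes <- as.integer(strsplit(hdr$sizes, "\\s+")[[1]])
  if (length(sizes) != 3) stop("only 3D NRRD volumes are supported", call. = FALSE)
  type <- hdr$type
  enc <- tolower(hdr$encoding)
  n <- prod(sizes)
  payload <- readBin(con, "raw", n = 1e9)
  if (enc == "gzip" || enc == "gz") payload <- memDecompress(payload, type = "gzip")
  else if (!enc %in% c("raw")) stop(sprintf("unsupported NRRD encoding: %s", enc), call. = FALSE)
  reader <- switch(type,
    "signed char" = , "int8" = , "int8_t" = function(r) readBin(r, "integer", n, size = 1, signed = TRUE),
    "uchar" = , "unsigned char" = , "uint8" = , "uint8_t" = function(r) readBin(r, "integer", n, size = 1, signed = FALSE),
    "short" = , "signed short" = , "int16" = , "int16_t" = function(r) readBin(r, "integer", n, size = 2, signed = TRUE, endian = "little"),
    "int" = , "signed int" = , "int32" = , "int32_t" = function(r) readBin(r, "integer", n, size = 4, endian = "little"),
    "float" = function(r) readBin(r, "double", n, size = 4, endian = "little"),
    "double" = function(r) readBin(r, "double", n, size = 8, endian = "little"),
    stop(sprintf("unsupported NRRD type: %s", type), call. = FALSE))
  data <- array(as.numeric(reader(payload)), dim = sizes)
  spacing <- c(1, 1, 1); direction <- diag(3); origin <- c(0, 0, 0)
  parse_vec <- function(s) as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]])
  if (!is.null(hdr[["space directions"]])) {
    cols <- regmatches(hdr[["space directions"]],
                       gregexpr("\\([^)]*\\)", hdr[["space directions"]]))[[1]]
    lin <- vapply(cols, parse_vec, numeric(3))
    spacing <- sqrt(colSums(lin^2))
    direction <- sweep(lin, 2, spacing, `/`)
    dimnames(direction) <- NULL
  } else if (!is.null(hdr$spacings)) {
    spacing <- as.numeric(strsplit(hdr$spacings, "\\s+")[[1]])
  }
  if (!is.null(hdr[["space origin"]])) origin <- parse_vec(hdr[["space origin"]])
  space <- tolower(hdr$space %||% "left-posterior-superior")
  if (space %in% c("right-anterior-superior", "ras")) {
    direction <- ras_lps %*% direction
    origin <- as.numeric(ras_lps %*% origin)
  }
  list(data = data, spacing = spacing, origin = origin, direction = direction)
}

write_nrrd_lps <- function(volume, path) {
  lin <- volume$direction %*% diag(volume$spacing)
  vec <- function(v) sprintf("(%.17g,%.17g,%.17g)", v[1], v[2], v[3])
  hdr <- c(
    "NRRD0004",
    "# written by glenoidbl",
    "type: int32",
    "dimension: 3",
    "space: left-posterior-superior",
    sprintf("sizes: %s", paste(dim(volume$labels), collapse = " ")),
    sprintf("space directions: %s %s %s", vec(lin[, 1]), vec(lin[, 2]), vec(lin[, 3])),
    "kinds: domain domain domain",
    "endian: little",
    "encoding: raw",
    sprintf("space origin: %s", vec(volume$origin)),
    "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  writeBin(as.integer(volume$labels), con, size = 4, endian = "little")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract a bone surface from a label volume
#'
#' Builds the isosurface of the binary mask for `role`. The mask is first
#' anti-aliased with a small Gaussian (sigma of one voxel by default) so the
#' iso-0.5 surface tracks the true boundary at sub-voxel accuracy instead of
#' the staircase of the raw binary mask; the surface is then extracted by
#' marching tetrahedra, which is watertight for solid masks by construction.
#'
#' @param volume a [label_volume()].
#' @param role label role to extract (must map to >= 27 voxels).
#' @param iso_smoothing apply one Laplacian smoothing pass to the extracted
#'   mesh (default `FALSE`; smoothing biases measurements and is cosmetic).
#' @param sigma_vox anti-aliasing Gaussian sigma in voxels.
#' @return a [triangle_surface()] in world mm coordinates.
#' @export
extract_surface <- function(volume, role = "scapula", iso_smoothing = FALSE,
                            sigma_vox = 1.0) {
  lab <- role_label(volume, role)
  mask <- volume$labels == lab
  if (sum(mask) < 27L) {
    stop(sprintf("degenerate mask: role '%s' has %d voxel(s), need >= 27",
                 role, sum(mask)), call. = FALSE)
  }
  # pad so the isosurface closes even when the mask touches the array edge
  d <- dim(mask)
  pad <- as.integer(ceiling(3 * sigma_vox) + 1)
  field <- array(0, d + 2L * pad)
  field[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <-
    as.numeric(mask)
  field <- .cpp_blur3d(field, sigma_vox)
  level <- 0.5
  eps <- 1e-3
  near <- abs(field - level) < eps
  field[near] <- level + eps
  surf <- .cpp_marching_tetrahedra(field, level)
  idx <- surf$vertices - pad   # back to 0-based indices of the original grid
  world <- voxel_to_world(volume, idx)
  mesh <- triangle_surface(world, surf$triangles + 1L, check = FALSE)
  if (iso_smoothing) mesh <- laplacian_smooth_once(mesh)
  validate_surface(mesh)
  mesh
}

#' Read and write surface meshes (PLY, STL)
#'
#' ASCII and binary-little-endian PLY, and ASCII or binary STL. Units are
#' assumed mm. The STL reader deduplicates shared vertices (STL stores
#' per-facet corners).
#'
#' @param path file path; format chosen by extension.
#' @param mesh a [triangle_surface()].
#' @param binary write binary PLY/STL (default `FALSE`, ASCII).
#' @return `read_mesh()` returns a [triangle_surface()]; `write_mesh()`
#'   returns `path` invisibly.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lower <- tolower(path)
  if (grepl("\\.ply$", lower)) read_ply(path)
  else if (grepl("\\.stl$", lower)) read_stl(path)
  else stop("unsupported mesh format (expected .ply or .stl)", call. = FALSE)
}

#' @rdname read_mesh
#' @export
write_mesh <- function(mesh, path, binary = FALSE) {
  validate_surface(mesh)
  lower <- tolower(path)
  if (grepl("\\.ply$", lower)) write_ply(mesh, path, binary)
  else if (grepl("\\.stl$", lower)) write_stl(mesh, path, binary)
  else stop("unsupported mesh format (expected .ply or .stl)", call. = FALSE)
  invisible(path)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  lines <- character()
  repeat {
    l <- readLines(con, n = 1)
    lines <- c(lines, l)
    if (identical(l, "end_header")) break
    if (length(lines) > 1000) stop("unparseable PLY header", call. = FALSE)
  }
  if (!identical(lines[1], "ply")) stop("not a PLY file", call. = FALSE)
  fmt <- sub("^format\\s+", "", grep("^format", lines, value = TRUE)[1])
  nv <- as.integer(sub(".*vertex\\s+", "", grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub(".*face\\s+", "", grep("^element face", lines, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop("unparseable PLY header", call. = FALSE)
  if (nf == 0) stop("empty mesh: PLY file has no faces", call. = FALSE)
  if (grepl("^ascii", fmt)) {
    txt <- readLines(con)
    vtx <- do.call(rbind, lapply(txt[seq_len(nv)], function(s)
      as.numeric(strsplit(trimws(s), "\\s+")[[1]][1:3])))
    fac <- do.call(rbind, lapply(txt[nv + seq_len(nf)], function(s) {
      tok <- as.integer(strsplit(trimws(s), "\\s+")[[1]])
      if (tok[1] != 3L) stop("only triangle PLY faces are supported", call. = FALSE)
      tok[2:4]
    }))
  } else if (grepl("binary_little_endian", fmt)) {
    vtx <- matrix(readBin(con, "double", nv * 3, size = 4, endian = "little"),
                  ncol = 3, byrow = TRUE)
    fac <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- readBin(con, "integer", 1, size = 1, signed = FALSE)
      if (cnt != 3L) stop("only triangle PLY faces are supported", call. = FALSE)
      fac[i, ] <- readBin(con, "integer", 3, size = 4, endian = "little")
    }
  } else stop("unsupported PLY format variant", call. = FALSE)
  triangle_surface(vtx, fac + 1L)
}

write_ply <- function(mesh, path, binary = FALSE) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$triangles)
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
           "comment written by glenoidbl (units mm)",
           sprintf("element vertex %d", nv),
           "property float x", "property float y", "property float z",
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices",
           "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    writeBin(as.numeric(t(mesh$vertices)), con, size = 4, endian = "little")
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(mesh$triangles[i, ] - 1L), con, size = 4, endian = "little")
    }
  } else {
    v <- apply(mesh$vertices, 1, function(r) sprintf("%.9g %.9g %.9g", r[1], r[2], r[3]))
    f <- apply(mesh$triangles - 1L, 1, function(r) sprintf("3 %d %d %d", r[1], r[2], r[3]))
    writeLines(c(hdr, v, f), path)
  }
  invisible(path)
}

read_stl <- function(path) {
  sz <- file.size(path)
  con <- file(path, "rb")
  head80 <- readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  is_binary <- length(ntri) == 1 && !is.na(ntri) && sz == 84 + 50 * as.numeric(ntri)
  close(con)
  if (is_binary) {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 84)
    corners <- matrix(0, ntri * 3, 3)
    for (i in seq_len(ntri)) {
      rec <- readBin(con, "double", 12, size = 4, endian = "little")
      readBin(con, "raw", 2)
      corners[(i - 1) * 3 + 1:3, ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    }
  } else {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
    if (length(vl) == 0) stop("empty mesh: STL file has no facets", call. = FALSE)
    corners <- do.call(rbind, lapply(vl, function(s)
      as.numeric(strsplit(trimws(sub("^\\s*vertex\\s+", "", s)), "\\s+")[[1]][1:3])))
    ntri <- nrow(corners) / 3
  }
  if (ntri == 0) stop("empty mesh: STL file has no facets", call. = FALSE)
  key <- apply(corners, 1, function(r) paste(sprintf("%.9g", r), collapse = "_"))
  uidx <- !duplicated(key)
  vmap <- match(key, key[uidx])
  vtx <- corners[uidx, , drop = FALSE]
  fac <- matrix(vmap, ncol = 3, byrow = TRUE)
  triangle_surface(vtx, fac)
}

write_stl <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices; f <- mesh$triangles
  n <- (v[f[, 2], ] - v[f[, 1], ])
  m <- (v[f[, 3], ] - v[f[, 1], ])
  nor <- cbind(n[, 2] * m[, 3] - n[, 3] * m[, 2],
               n[, 3] * m[, 1] - n[, 1] * m[, 3],
               n[, 1] * m[, 2] - n[, 2] * m[, 1])
  len <- sqrt(rowSums(nor^2)); len[len == 0] <- 1
  nor <- nor / len
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(c(nor[i, ], t(v[f[i, ], ]))), con, size = 4, endian = "little")
      writeBin(raw(2), con)
    }
  } else {
    out <- c("solid glenoidbl")
    for (i in seq_len(nrow(f))) {
      out <- c(out,
               sprintf("  facet normal %.9g %.9g %.9g", nor[i, 1], nor[i, 2], nor[i, 3]),
               "    outer loop",
               sprintf("      vertex %.9g %.9g %.9g",
                       v[f[i, ], 1], v[f[i, ], 2], v[f[i, ], 3]),
               "    endloop", "  endfacet")
    }
    writeLines(c(out, "endsolid glenoidbl"), path)
  }
  invisible(path)
}
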