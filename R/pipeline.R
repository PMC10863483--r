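#' Run configuration
#'
#' All pipeline tunables with validated defaults. Unknown names are rejected.
#'
#' @param ... overrides of the defaults:
#' \describe{
#'   \item{max_distance}{articular selection distance to the humeral head,
#'     mm (default 6; use a tighter value for highly congruent joints).}
#'   \item{crease_deg}{dihedral-angle bound for seed growth, degrees (12).}
#'   \item{n_cuts}{number of concavity cuts (10).}
#'   \item{span_fraction}{cut half-span as a fraction of the BFC radius (0.2).}
#'   \item{circle_samples}{BFC boundary samples for the 1D metric (2048).}
#'   \item{circle_polygon}{BFC polygon vertices for the 2D metric (1024).}
#'   \item{contact_tol}{supporting-line touch tolerance, mm (1e-6).}
#'   \item{anterior_only}{restrict the 1D defect search to the anterior
#'     half-plane (FALSE).}
#'   \item{iso_smoothing}{Laplacian pass after surface extraction (FALSE).}
#'   \item{smoothing_sigma}{mask anti-aliasing sigma in voxels (1).}
#'   \item{measure_concavity}{compute the 3D concavity/BSSR block (TRUE).}
#'   \item{labels}{named integer label mapping (background/scapula/humerus).}
#' }
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    max_distance = 6, crease_deg = 12, n_cuts = 10L, span_fraction = 0.2,
    circle_samples = 2048L, circle_polygon = 1024L, contact_tol = 1e-6,
    anterior_only = FALSE, iso_smoothing = FALSE, smoothing_sigma = 1,
    measure_concavity = TRUE,
    labels = c(background = 0L, scapula = 1L, humerus = 2L))
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]])) {
    over <- over[[1]]
  }
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, over)
  # YAML round-trips named vectors as named lists
  if (is.list(cfg$labels)) cfg$labels <- unlist(cfg$labels)
  cfg$labels <- vapply(cfg$labels, as.integer, integer(1))
  chk <- function(ok, key, msg) {
    if (!ok) stop(sprintf("invalid config: %s %s", key, msg), call. = FALSE)
  }
  chk(cfg$max_distance > 0, "max_distance", "must be > 0")
  chk(cfg$crease_deg > 0 && cfg$crease_deg <= 180, "crease_deg", "must be in (0, 180]")
  chk(cfg$n_cuts >= 1, "n_cuts", "must be >= 1")
  chk(cfg$span_fraction > 0 && cfg$span_fraction < 1, "span_fraction",
      "must be in (0, 1)")
  chk(cfg$circle_samples >= 64, "circle_samples", "must be >= 64")
  chk(cfg$circle_polygon >= 64, "circle_polygon", "must be >= 64")
  chk(cfg$contact_tol > 0, "contact_tol", "must be > 0")
  chk(cfg$smoothing_sigma > 0, "smoothing_sigma", "must be > 0")
  chk(is.logical(cfg$anterior_only) && is.logical(cfg$iso_smoothing) &&
        is.logical(cfg$measure_concavity), "flags", "must be logical")
  chk(all(c("background", "scapula") %in% names(cfg$labels)), "labels",
      "must name background and scapula")
  cfg$n_cuts <- as.integer(cfg$n_cuts)
  cfg$circle_samples <- as.integer(cfg$circle_samples)
  cfg$circle_polygon <- as.integer(cfg$circle_polygon)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  run_config(yaml::read_yaml(path))
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$labels <- as.list(x$labels)  # keep names: yaml drops them from vectors
  yaml::write_yaml(x, path)
  invisible(path)
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

#' Measure glenoid bone loss and stability from a segmentation
#'
#' The central measurement pipeline: surface extraction (for volume input),
#' articular-region isolation, principal-component anatomical frame,
#' posteroinferior-rim best-fit circle, contour projection, linear (1D) and
#' area (2D) bone loss, parallel-cut concavity profile and BSSR.
#'
#' Right-side shoulders are mirrored (first world axis negated) before
#' measurement so that every glenoid is processed in left-shoulder
#' convention with a right-handed frame whose normal points at the humeral
#' head; all reported metrics are mirror-invariant.
#'
#' @param scapula scapular [triangle_surface()], or a [label_volume()]
#'   containing scapula (and optionally humerus) labels, or a path to one.
#' @param humerus optional humeral [triangle_surface()] (ignored for volume
#'   input when the volume has a humerus label).
#' @param side `"left"` or `"right"`.
#' @param orientation_hint list with `superior` and `anterior` world
#'   direction hints. Default is LPS axes: superior (0,0,1),
#'   anterior (0,-1,0).
#' @param seed optional 3D articular seed point (used when no humerus is
#'   available).
#' @param vertex_mask explicit articular vertex selection (overrides the
#'   heuristics).
#' @param overrides optional named list (or JSON file path) of manual
#'   refinements: `circle` (list with `center`, `radius`, `plane_normal`)
#'   and/or `vertex_mask`.
#' @param config a [run_config()].
#' @return An object of class `glenoid_measurement` with the fitted circle,
#'   the metric blocks and full provenance. Use `print()`, `summary()`,
#'   [write_report()] or `plot()` on it.
#' @export
measure_glenoid <- function(scapula, humerus = NULL, side = c("left", "right"),
                            orientation_hint = list(superior = c(0, 0, 1),
                                                    anterior = c(0, -1, 0)),
                            seed = NULL, vertex_mask = NULL, overrides = NULL,
                            config = run_config()) {
  side <- match.arg(side)
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  if (is.character(overrides)) {
    overrides <- jsonlite::read_json(overrides, simplifyVector = TRUE)
  }

  if (is.character(scapula)) {
    scapula <- stage("read", read_label_volume(scapula, config$labels))
  }
  if (inherits(scapula, "label_volume")) {
    vol <- scapula
    scapula <- stage("extract_surface",
                     extract_surface(vol, "scapula", config$iso_smoothing,
                                     config$smoothing_sigma))
    if (is.null(humerus) && "humerus" %in% names(vol$label_table) &&
        sum(vol$labels == vol$label_table[["humerus"]]) >= 27) {
      humerus <- stage("extract_surface",
                       extract_surface(vol, "humerus", config$iso_smoothing,
                                       config$smoothing_sigma))
    }
  }
  validate_surface(scapula)

  mirrored <- FALSE
  if (side == "right") {
    mirrored <- TRUE
    mirror <- function(m) { m$vertices[, 1] <- -m$vertices[, 1]; m }
    scapula <- mirror(scapula)
    if (!is.null(humerus)) humerus <- mirror(humerus)
    if (!is.null(seed)) seed[1] <- -seed[1]
    orientation_hint <- lapply(orientation_hint, function(v) {
      v[1] <- -v[1]; v
    })
  }

  if (!is.null(overrides$vertex_mask)) vertex_mask <- overrides$vertex_mask
  region <- stage("isolate_glenoid_region",
                  isolate_glenoid_region(scapula, humerus, seed,
                                         config$max_distance, vertex_mask,
                                         config$crease_deg))
  frame <- stage("compute_frame", compute_frame(region, orientation_hint))
  circle_override <- NULL
  if (!is.null(overrides$circle)) {
    circle_override <- best_fit_circle(overrides$circle$center,
                                       overrides$circle$radius,
                                       overrides$circle$plane_normal)
  }
  circle <- if (!is.null(circle_override)) {
    circle_override
  } else {
    rim <- stage("select_posteroinferior_rim",
                 select_posteroinferior_rim(region, frame))
    stage("fit_best_circle", fit_best_circle(rim, frame = frame))
  }
  contour <- stage("project_contour", project_contour(region, circle, frame))
  lin <- stage("linear_bone_loss",
               linear_bone_loss(contour, config$circle_samples,
                                config$anterior_only))
  area <- stage("area_bone_loss", area_bone_loss(contour, config$circle_polygon))

  concavity <- NULL; bssr <- NULL
  if (config$measure_concavity) {
    concavity <- stage("concavity_profile",
                       concavity_profile(region, frame, circle, config$n_cuts,
                                         config$span_fraction,
                                         config$contact_tol))
    bssr <- stage("compute_bssr",
                  compute_bssr(concavity$mean_depth_mm, concavity$mean_chord_mm))
  }

  structure(list(
    circle = circle, frame = frame, region = region, contour = contour,
    linear = lin, area = area, concavity = concavity, bssr = bssr,
    provenance = list(
      software = list(name = "glenoidbl",
                      version = as.character(utils::packageVersion("glenoidbl"))),
      side = side, mirrored = mirrored,
      circle_source = if (is.null(circle_override)) "fitted" else "override",
      region_source = if (!is.null(vertex_mask)) "override"
                      else if (!is.null(humerus)) "humerus_distance"
                      else "seed_growth",
      config = unclass(config), config_hash = config_hash(config),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))),
    class = "glenoid_measurement")
}

#' @export
print.glenoid_measurement <- function(x, ...) {
  cat("glenoid measurement\n")
  cat(sprintf("  BFC: diameter %.2f mm, area %.2f mm^2 (%s)\n",
              x$circle$diameter, x$circle$area, x$provenance$circle_source))
  cat(sprintf("  1D: defect %.2f mm, bone loss %.1f%%\n",
              x$linear$defect_diameter_mm, x$linear$ratio_percent))
  cat(sprintf("  2D: defect %.2f mm^2, bone loss %.1f%%\n",
              x$area$defect_area_mm2, x$area$ratio_percent))
  if (!is.null(x$bssr)) {
    cat(sprintf("  3D: depth %.2f mm, chord %.2f mm, BSSR %.1f%%\n",
                x$concavity$mean_depth_mm, x$concavity$mean_chord_mm,
                x$bssr$bssr_percent))
  } else {
    cat("  3D: not measured\n")
  }
  invisible(x)
}

#' @export
summary.glenoid_measurement <- function(object, ...) {
  x <- object
  df <- data.frame(
    parameter = c("bfc_diameter_mm", "bfc_area_mm2", "defect_diameter_mm",
                  "linear_ratio_percent", "defect_area_mm2",
                  "area_ratio_percent",
                  if (!is.null(x$bssr)) c("concavity_depth_mm",
                                          "concavity_chord_mm",
                                          "bssr_percent")),
    value = c(x$circle$diameter, x$circle$area, x$linear$defect_diameter_mm,
              x$linear$ratio_percent, x$area$defect_area_mm2,
              x$area$ratio_percent,
              if (!is.null(x$bssr)) c(x$concavity$mean_depth_mm,
                                      x$concavity$mean_chord_mm,
                                      x$bssr$bssr_percent)))
  class(df) <- c("summary.glenoid_measurement", class(df))
  df
}

#' En-face plot of a glenoid measurement
#'
#' Draws the projected glenoid contour, the best-fit circle and the defect
#' annotation in the BFC-plane chart (u anterior, v superior).
#'
#' @param x a [measure_glenoid()] result.
#' @param ... passed to `plot.default`.
#' @export
plot.glenoid_measurement <- function(x, ...) {
  poly <- x$contour$polygon
  r <- x$circle$radius
  th <- seq(0, 2 * pi, length.out = 361)
  graphics::plot(NA, xlim = range(c(poly[, 1], r, -r)) * 1.1,
                 ylim = range(c(poly[, 2], r, -r)) * 1.1,
                 asp = 1, xlab = "u, anterior (mm)", ylab = "v, superior (mm)",
                 main = sprintf("glenoid en face: 1D %.1f%%, 2D %.1f%%",
                                x$linear$ratio_percent, x$area$ratio_percent),
                 ...)
  graphics::polygon(poly[, 1], poly[, 2], col = grDevices::adjustcolor("firebrick", 0.25),
                    border = "firebrick")
  graphics::lines(r * cos(th), r * sin(th), col = "forestgreen", lwd = 2)
  graphics::points(0, 0, pch = 3, col = "forestgreen")
  invisible(x)
}

#' Write and read a measurement report (JSON)
#'
#' All metrics, parameters, software version and provenance (including any
#' manual overrides) at full numeric precision; keys are stable. Two runs on
#' identical inputs produce byte-identical files except the timestamp.
#'
#' @param measurement a [measure_glenoid()] result.
#' @param path output JSON path.
#' @return `write_report()` returns `path` invisibly; `read_report()` the
#'   parsed report list.
#' @export
write_report <- function(measurement, path) {
  stopifnot(inherits(measurement, "glenoid_measurement"))
  x <- measurement
  rep_ <- list(
    software = x$provenance$software,
    timestamp = x$provenance$timestamp,
    side = x$provenance$side,
    provenance = list(mirrored = x$provenance$mirrored,
                      circle_source = x$provenance$circle_source,
                      region_source = x$provenance$region_source,
                      config_hash = x$provenance$config_hash),
    config = x$provenance$config,
    bfc = list(center = as.numeric(x$circle$center),
               radius_mm = x$circle$radius,
               diameter_mm = x$circle$diameter,
               area_mm2 = x$circle$area,
               plane_normal = as.numeric(x$circle$plane_normal)),
    linear = unclass(x$linear),
    area = unclass(x$area))
  if (!is.null(x$bssr)) {
    rep_$concavity <- list(
      n_cuts = length(x$concavity$cuts),
      offsets_mm = as.numeric(x$concavity$offsets),
      depths_mm = vapply(x$concavity$cuts, function(c) c$depth_mm, numeric(1)),
      mean_depth_mm = x$concavity$mean_depth_mm,
      mean_chord_mm = x$concavity$mean_chord_mm,
      chord_source = x$concavity$chord_source)
    rep_$bssr <- unclass(x$bssr)
  }
  writeLines(jsonlite::toJSON(rep_, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"), path)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Export the projected contour polygon for debugging
#'
#' @param measurement a [measure_glenoid()] result.
#' @param path CSV path (columns u, v in mm).
#' @export
export_contour_csv <- function(measurement, path) {
  poly <- measurement$contour$polygon
  utils::write.csv(data.frame(u = poly[, 1], v = poly[, 2]), path,
                   row.names = FALSE)
  invisible(path)
}

#' Export per-cut concavity measurements for debugging
#'
#' @param measurement a [measure_glenoid()] result (with concavity block).
#' @param path CSV path (columns offset_mm, depth_mm, chord_mm).
#' @export
export_cuts_csv <- function(measurement, path) {
  if (is.null(measurement$concavity)) stop("no concavity block", call. = FALSE)
  cuts <- measurement$concavity$cuts
  utils::write.csv(data.frame(
    offset_mm = vapply(cuts, function(c) c$offset_mm, numeric(1)),
    depth_mm = vapply(cuts, function(c) c$depth_mm, numeric(1)),
    chord_mm = vapply(cuts, function(c) c$chord_mm, numeric(1))), path,
    row.names = FALSE)
  invisible(path)
}
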