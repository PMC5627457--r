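#' Arena configuration
#'
#' An `arena_config` bundles everything the tracker and the analytics need
#' to know about one experimental setup: the arena floor rectangle in pixel
#' coordinates, the pixel-to-cm calibration, the frame rate, the two
#' compartment polygons, the two stimulus-zone segments (the front walls of
#' the triangular stimulus chambers), and the detection parameters.
#'
#' Coordinate convention: pixel coordinates are 0-based, x rightward,
#' y downward (image convention). Exported times are in seconds and
#' positions in cm.
#'
#' @param arena_rect named numeric vector `c(x0, y0, width, height)` (px):
#'   the arena floor area within the video frame.
#' @param px_per_cm pixels per centimetre (> 0).
#' @param frame_rate video frame rate in frames/s (default 30).
#' @param compartments named list of exactly two polygons (matrices with
#'   columns x, y, px) tiling the arena floor. If `NULL`, defaults to the
#'   two halves of the arena split by the perpendicular bisector of the
#'   line joining the stimulus-zone centres.
#' @param stimulus_zones named list of exactly two line segments (2 x 2
#'   matrices, one endpoint per row, px) marking the chamber front walls.
#' @param contact_distance_px maximum distance (px) from the subject's body
#'   boundary (or head point) to a zone that still counts as contact. The
#'   inequality is closed: distance <= `contact_distance_px` is contact.
#' @param detection_threshold_low,detection_threshold_high grayscale
#'   cutoffs in \[0, 255\]; subject pixels are those at or below the
#'   threshold (darker). The low threshold captures the body but not the
#'   brighter tail; the high threshold includes the tail.
#' @param min_blob_area_px smallest acceptable subject component (px).
#' @param max_cable_width_px widest cable (px) removed by the wired-animal
#'   algorithm's morphological opening.
#' @param gap_merge_s investigation gaps strictly shorter than this are
#'   merged into the flanking bout (default 0.5 s).
#' @param bin_width_s width of the time bins used for binned investigation
#'   time and transition counts (default 20 s).
#' @param arena_size_cm physical arena floor size `c(width, height)` in cm;
#'   informational (default 37 x 22 cm).
#' @param invert set `TRUE` for a light subject on a dark background; the
#'   frame is inverted before thresholding.
#'
#' @return an object of class `arena_config` (a named list).
#' @seealso [default_arena_config()], [read_arena_config()], [px_to_cm()]
#' @export
arena_config <- function(arena_rect,
                         px_per_cm,
                         frame_rate = 30,
                         stimulus_zones,
                         compartments = NULL,
                         contact_distance_px = 2,
                         detection_threshold_low = 90,
                         detection_threshold_high = 160,
                         min_blob_area_px = 50,
                         max_cable_width_px = 2,
                         gap_merge_s = 0.5,
                         bin_width_s = 20,
                         arena_size_cm = c(37, 22),
                         invert = FALSE) {
  arena_rect <- as_arena_rect(arena_rect)
  stimulus_zones <- as_zone_list(stimulus_zones)
  if (is.null(compartments)) {
    compartments <- default_compartments(arena_rect, stimulus_zones)
  }
  compartments <- as_polygon_list(compartments, "compartments")

  cfg <- structure(
    list(
      arena_rect = arena_rect,
      px_per_cm = as.numeric(px_per_cm),
      frame_rate = as.numeric(frame_rate),
      stimulus_zones = stimulus_zones,
      compartments = compartments,
      contact_distance_px = as.numeric(contact_distance_px),
      detection_threshold_low = as.numeric(detection_threshold_low),
      detection_threshold_high = as.numeric(detection_threshold_high),
      min_blob_area_px = as.numeric(min_blob_area_px),
      max_cable_width_px = as.numeric(max_cable_width_px),
      gap_merge_s = as.numeric(gap_merge_s),
      bin_width_s = as.numeric(bin_width_s),
      arena_size_cm = as.numeric(arena_size_cm),
      invert = isTRUE(invert)
    ),
    class = "arena_config"
  )
  validate_arena_config(cfg)
}

as_arena_rect <- function(x) {
  x <- unlist(x)
  if (is.null(names(x)) || !all(c("x0", "y0", "width", "height") %in% names(x))) {
    if (length(x) == 4) names(x) <- c("x0", "y0", "width", "height")
    else stop("arena_rect must be c(x0, y0, width, height)", call. = FALSE)
  }
  as.numeric(x[c("x0", "y0", "width", "height")]) |>
    stats::setNames(c("x0", "y0", "width", "height"))
}

as_zone_list <- function(zones) {
  if (!is.list(zones) || length(zones) != 2) {
    stop("config error: stimulus_zones must be a named list of exactly 2 segments",
         call. = FALSE)
  }
  if (is.null(names(zones)) || any(names(zones) == "")) {
    names(zones) <- c("stim1", "stim2")
  }
  lapply(zones, function(z) {
    z <- matrix(as.numeric(unlist(z)), ncol = 2, byrow = !is.matrix(z))
    if (nrow(z) != 2) {
      stop("config error: each stimulus zone must be a segment (2 endpoints)",
           call. = FALSE)
    }
    colnames(z) <- c("x", "y")
    z
  })
}

as_polygon_list <- function(polys, what) {
  if (!is.list(polys) || length(polys) != 2) {
    stop(sprintf("config error: %s must be a named list of exactly 2 polygons", what),
         call. = FALSE)
  }
  if (is.null(names(polys)) || any(names(polys) == "")) {
    names(polys) <- paste0("compartment", seq_along(polys))
  }
  lapply(polys, function(p) {
    p <- matrix(as.numeric(unlist(p)), ncol = 2, byrow = !is.matrix(p))
    if (nrow(p) < 3) {
      stop(sprintf("config error: each of %s needs >= 3 vertices", what),
           call. = FALSE)
    }
    colnames(p) <- c("x", "y")
    p
  })
}

# Sutherland-Hodgman clip of a polygon against the half-plane
# {p : dot(p - point, normal) <= 0}
clip_halfplane <- function(poly, point, normal) {
  n <- nrow(poly)
  sgn <- (poly[, 1] - point[1]) * normal[1] + (poly[, 2] - point[2]) * normal[2]
  out <- list()
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a_in <- sgn[i] <= 1e-12
    b_in <- sgn[j] <= 1e-12
    if (a_in) out[[length(out) + 1L]] <- poly[i, ]
    if (xor(a_in, b_in)) {
      t <- sgn[i] / (sgn[i] - sgn[j])
      out[[length(out) + 1L]] <- poly[i, ] + t * (poly[j, ] - poly[i, ])
    }
  }
  m <- do.call(rbind, out)
  colnames(m) <- c("x", "y")
  m
}

# Two halves of the arena split by the perpendicular bisector of the
# segment joining the zone centres (each compartment is "half of the arena").
default_compartments <- function(arena_rect, zones) {
  c1 <- colMeans(zones[[1]])
  c2 <- colMeans(zones[[2]])
  mid <- (c1 + c2) / 2
  d <- c2 - c1
  if (sqrt(sum(d^2)) < 1e-9) {
    stop("geometry error: stimulus zones coincide; cannot derive compartments",
         call. = FALSE)
  }
  arena_poly <- rect_polygon(arena_rect)
  out <- list(
    clip_halfplane(arena_poly, mid, d),
    clip_halfplane(arena_poly, mid, -d)
  )
  names(out) <- paste0("compartment", 1:2)
  out
}

#' Validate an arena configuration
#'
#' Checks all geometric invariants: stimulus zones and compartments lie
#' inside the arena rectangle (up to the contact tolerance), the two zones
#' are disjoint and separated by more than twice the contact distance, the
#' compartments are disjoint and together cover the arena floor, and the
#' two detection thresholds are ordered.
#'
#' @param cfg an `arena_config`.
#' @return `cfg`, invisibly unchanged, if valid; otherwise an error
#'   describing the violated rule.
#' @export
validate_arena_config <- function(cfg) {
  stopifnot(inherits(cfg, "arena_config"))
  r <- cfg$arena_rect
  if (any(!is.finite(r)) || r[["width"]] <= 0 || r[["height"]] <= 0) {
    stop("geometry error: arena_rect must have positive width and height",
         call. = FALSE)
  }
  if (!is.finite(cfg$px_per_cm) || cfg$px_per_cm <= 0) {
    stop("config error: px_per_cm must be > 0", call. = FALSE)
  }
  if (cfg$frame_rate <= 0) stop("config error: frame_rate must be > 0", call. = FALSE)
  if (cfg$detection_threshold_low > cfg$detection_threshold_high) {
    stop("config error: detection_threshold_low must be <= detection_threshold_high",
         call. = FALSE)
  }
  if (cfg$contact_distance_px < 0) {
    stop("config error: contact_distance_px must be >= 0", call. = FALSE)
  }

  tol <- cfg$contact_distance_px
  inside_rect <- function(pts, tol) {
    all(pts[, 1] >= r[["x0"]] - tol & pts[, 1] <= r[["x0"]] + r[["width"]] + tol &
          pts[, 2] >= r[["y0"]] - tol & pts[, 2] <= r[["y0"]] + r[["height"]] + tol)
  }
  for (nm in names(cfg$stimulus_zones)) {
    if (!inside_rect(cfg$stimulus_zones[[nm]], tol)) {
      stop(sprintf("geometry error: stimulus zone '%s' lies outside arena_rect", nm),
           call. = FALSE)
    }
  }
  for (nm in names(cfg$compartments)) {
    if (!inside_rect(cfg$compartments[[nm]], 1e-6)) {
      stop(sprintf("geometry error: compartment '%s' lies outside arena_rect", nm),
           call. = FALSE)
    }
  }

  sep <- segment_segment_distance(cfg$stimulus_zones[[1]], cfg$stimulus_zones[[2]])
  if (sep <= 2 * cfg$contact_distance_px) {
    stop(sprintf(paste0(
      "geometry error: stimulus zones must be disjoint and separated by more ",
      "than 2*contact_distance_px (separation %.2f px, required > %.2f px); ",
      "single-stimulus contact labelling is ill-defined otherwise"),
      sep, 2 * cfg$contact_distance_px), call. = FALSE)
  }

  area <- function(p) {
    x <- p[, 1]; y <- p[, 2]
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }
  a_arena <- r[["width"]] * r[["height"]]
  a_comp <- sum(vapply(cfg$compartments, area, numeric(1)))
  if (abs(a_comp - a_arena) > 0.02 * a_arena) {
    stop(sprintf(paste0(
      "geometry error: compartments must be disjoint and together cover the ",
      "arena (compartment area %.0f px^2 vs arena %.0f px^2)"),
      a_comp, a_arena), call. = FALSE)
  }
  # grid probe: interior points must fall in exactly one compartment
  gx <- r[["x0"]] + r[["width"]] * (seq_len(17) - 0.382) / 17
  gy <- r[["y0"]] + r[["height"]] * (seq_len(13) - 0.382) / 13
  g <- as.matrix(expand.grid(x = gx, y = gy))
  hits <- points_in_polygon(g, cfg$compartments[[1]]) +
    points_in_polygon(g, cfg$compartments[[2]])
  if (mean(hits != 1) > 0.05) {
    stop("geometry error: compartments overlap or leave part of the arena uncovered",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Build a ready-to-use configuration for a standard frame
#'
#' Places the arena floor centred in a `frame_width_px` x `frame_height_px`
#' video frame with the physical aspect ratio of a 37 x 22 cm arena, puts
#' the two stimulus-zone segments across two opposite corners (the front
#' walls of 12-cm isosceles triangular chambers), and derives the two
#' compartments as the arena halves split between the zones.
#'
#' @param frame_width_px,frame_height_px video frame size in pixels.
#' @param corners which opposite corner pair holds the chambers:
#'   `"tl-br"` (top-left and bottom-right) or `"tr-bl"`.
#' @param chamber_leg_cm length of the triangular chamber's wall-aligned
#'   legs in cm (default 12).
#' @param margin_px minimum margin between the frame border and the arena.
#' @inheritParams arena_config
#' @param ... passed on to [arena_config()] (thresholds, contact distance,
#'   frame rate, ...).
#' @return an `arena_config`.
#' @examples
#' cfg <- default_arena_config(320, 240)
#' cfg$arena_rect
#' @export
default_arena_config <- function(frame_width_px = 320,
                                 frame_height_px = 240,
                                 corners = c("tl-br", "tr-bl"),
                                 chamber_leg_cm = 12,
                                 margin_px = 8,
                                 arena_size_cm = c(37, 22),
                                 ...) {
  corners <- match.arg(corners)
  px_per_cm <- min((frame_width_px - 2 * margin_px) / arena_size_cm[1],
                   (frame_height_px - 2 * margin_px) / arena_size_cm[2])
  w <- arena_size_cm[1] * px_per_cm
  h <- arena_size_cm[2] * px_per_cm
  x0 <- (frame_width_px - w) / 2
  y0 <- (frame_height_px - h) / 2
  leg <- chamber_leg_cm * px_per_cm
  x1 <- x0 + w; y1 <- y0 + h
  zones <- if (corners == "tl-br") {
    list(stim1 = rbind(c(x0 + leg, y0), c(x0, y0 + leg)),
         stim2 = rbind(c(x1 - leg, y1), c(x1, y1 - leg)))
  } else {
    list(stim1 = rbind(c(x1 - leg, y0), c(x1, y0 + leg)),
         stim2 = rbind(c(x0 + leg, y1), c(x0, y1 - leg)))
  }
  arena_config(
    arena_rect = c(x0 = x0, y0 = y0, width = w, height = h),
    px_per_cm = px_per_cm,
    stimulus_zones = zones,
    arena_size_cm = arena_size_cm,
    ...
  )
}

#' Read / write arena configurations
#'
#' Configurations are stored as YAML (`.yml`/`.yaml`) or JSON (`.json`).
#' All geometry is in pixels, physical sizes in cm. Loading validates every
#' geometric invariant; a missing field or a violated rule is an error
#' naming the field or rule.
#'
#' @param path file path; the extension selects the dialect.
#' @return [read_arena_config()] returns a validated `arena_config`;
#'   [write_arena_config()] returns `path` invisibly.
#' @export
read_arena_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config error: file '%s' does not exist", path), call. = FALSE)
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  required <- c("arena_rect", "px_per_cm", "stimulus_zones")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop(sprintf("config error: missing field(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  pairlist_to_matrix <- function(x) {
    do.call(rbind, lapply(x, function(p) as.numeric(unlist(p))))
  }
  zones <- lapply(raw$stimulus_zones, pairlist_to_matrix)
  comps <- if (!is.null(raw$compartments)) {
    lapply(raw$compartments, pairlist_to_matrix)
  } else NULL
  arena_config(
    arena_rect = unlist(raw$arena_rect),
    px_per_cm = raw$px_per_cm,
    frame_rate = raw$frame_rate %||% 30,
    stimulus_zones = zones,
    compartments = comps,
    contact_distance_px = raw$contact_distance_px %||% 2,
    detection_threshold_low = raw$detection_threshold_low %||% 90,
    detection_threshold_high = raw$detection_threshold_high %||% 160,
    min_blob_area_px = raw$min_blob_area_px %||% 50,
    max_cable_width_px = raw$max_cable_width_px %||% 2,
    gap_merge_s = raw$gap_merge_s %||% 0.5,
    bin_width_s = raw$bin_width_s %||% 20,
    arena_size_cm = raw$arena_size_cm %||% c(37, 22),
    invert = raw$invert %||% FALSE
  )
}

#' @rdname read_arena_config
#' @param cfg an `arena_config` to serialize.
#' @export
write_arena_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "arena_config"))
  matrix_to_pairlist <- function(m) {
    lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
  }
  out <- list(
    arena_rect = as.list(cfg$arena_rect),
    px_per_cm = cfg$px_per_cm,
    frame_rate = cfg$frame_rate,
    stimulus_zones = lapply(cfg$stimulus_zones, matrix_to_pairlist),
    compartments = lapply(cfg$compartments, matrix_to_pairlist),
    contact_distance_px = cfg$contact_distance_px,
    detection_threshold_low = cfg$detection_threshold_low,
    detection_threshold_high = cfg$detection_threshold_high,
    min_blob_area_px = cfg$min_blob_area_px,
    max_cable_width_px = cfg$max_cable_width_px,
    gap_merge_s = cfg$gap_merge_s,
    bin_width_s = cfg$bin_width_s,
    arena_size_cm = cfg$arena_size_cm,
    invert = cfg$invert
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(out, path, precision = 12)
  }
  invisible(path)
}

#' Convert pixel coordinates to centimetres
#'
#' Linear scaling by `1 / px_per_cm` with the origin at the arena
#' rectangle's top-left corner.
#'
#' @param xy a length-2 numeric `c(x, y)`, a 2-column matrix, or a data
#'   frame with columns `x` and `y`, in pixels.
#' @param cfg an `arena_config`.
#' @return coordinates in cm, same shape as the input.
#' @examples
#' cfg <- default_arena_config(320, 240)
#' px_to_cm(unname(cfg$arena_rect[c("x0", "y0")]), cfg)  # (0, 0)
#' @export
px_to_cm <- function(xy, cfg) {
  stopifnot(inherits(cfg, "arena_config"))
  origin <- cfg$arena_rect[c("x0", "y0")]
  if (is.data.frame(xy)) {
    xy$x <- (xy$x - origin[["x0"]]) / cfg$px_per_cm
    xy$y <- (xy$y - origin[["y0"]]) / cfg$px_per_cm
    return(xy)
  }
  if (is.matrix(xy)) {
    xy[, 1] <- (xy[, 1] - origin[["x0"]]) / cfg$px_per_cm
    xy[, 2] <- (xy[, 2] - origin[["y0"]]) / cfg$px_per_cm
    return(xy)
  }
  (as.numeric(xy) - as.numeric(origin)) / cfg$px_per_cm
}

#' @export
print.arena_config <- function(x, ...) {
  r <- x$arena_rect
  cat("<arena_config>\n")
  cat(sprintf("  arena: %.0f x %.0f px at (%.0f, %.0f); %.3g px/cm (%g x %g cm)\n",
              r[["width"]], r[["height"]], r[["x0"]], r[["y0"]],
              x$px_per_cm, x$arena_size_cm[1], x$arena_size_cm[2]))
  cat(sprintf("  frame rate: %g fps; thresholds low/high: %g/%g; min blob: %g px\n",
              x$frame_rate, x$detection_threshold_low,
              x$detection_threshold_high, x$min_blob_area_px))
  cat(sprintf("  zones: %s; contact distance: %g px\n",
              paste(names(x$stimulus_zones), collapse = ", "),
              x$contact_distance_px))
  cat(sprintf("  compartments: %s; gap merge: %g s; bin width: %g s\n",
              paste(names(x$compartments), collapse = ", "),
              x$gap_merge_s, x$bin_width_s))
  invisible(x)
}
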