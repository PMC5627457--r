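# Per-frame segmentation of the subject and zone-contact detection.
# Frames are height x width numeric matrices, gray 0-255, row = y + 1,
# col = x + 1 (0-based image coordinates, y downward). EBImage stores
# images [x, y], so frames are transposed at the EBImage boundary.

frame_to_image <- function(frame) EBImage::Image(t(frame))

#' Segment the subject in one frame
#'
#' Thresholds the frame (subject pixels are those at or below the
#' threshold — darker), restricts to the arena rectangle, labels
#' connected components and keeps the largest component with area at
#' least `min_area`. Ties on area are broken by distance to the previous
#' centroid, then by lowest label index.
#'
#' @param frame numeric matrix (gray 0-255, rows = image rows).
#' @param threshold grayscale cutoff in \[0, 255\].
#' @param min_area smallest acceptable component area (px).
#' @param cfg an `arena_config`; pixels outside `arena_rect` are ignored
#'   and `invert` flips the polarity for light-on-dark subjects.
#' @param prev_centroid optional `c(x, y)` of the previous frame's
#'   subject, used only for tie-breaking.
#' @return logical matrix of the subject mask, or `NULL` when no
#'   acceptable component exists.
#' @export
segment_subject <- function(frame, threshold, min_area, cfg,
                            prev_centroid = NULL) {
  stopifnot(inherits(cfg, "arena_config"))
  r <- cfg$arena_rect
  if (r[["x0"]] + r[["width"]] > ncol(frame) + 1e-6 ||
      r[["y0"]] + r[["height"]] > nrow(frame) + 1e-6) {
    stop("input error: frame is smaller than the configured arena_rect",
         call. = FALSE)
  }
  if (threshold < 0 || threshold > 255) {
    stop("input error: threshold outside the 0-255 grayscale range",
         call. = FALSE)
  }
  if (cfg$invert) frame <- 255 - frame
  mask <- frame <= threshold
  # zero outside the arena floor
  xs <- seq_len(ncol(frame)) - 1L
  ys <- seq_len(nrow(frame)) - 1L
  mask[, !(xs >= r[["x0"]] & xs <= r[["x0"]] + r[["width"]])] <- FALSE
  mask[!(ys >= r[["y0"]] & ys <= r[["y0"]] + r[["height"]]), ] <- FALSE
  if (!any(mask)) return(NULL)
  lab <- EBImage::imageData(EBImage::bwlabel(frame_to_image(mask)))
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area)
  if (length(keep) == 0) return(NULL)
  best <- keep[areas[keep] == max(areas[keep])]
  if (length(best) > 1 && !is.null(prev_centroid)) {
    d <- vapply(best, function(l) {
      idx <- which(lab == l, arr.ind = TRUE)   # [x+1, y+1]
      sum((colMeans(idx) - 1 - prev_centroid)^2)
    }, numeric(1))
    best <- best[d == min(d)]
  }
  best <- min(best)
  t(lab == best)
}

mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)   # [row = y+1, col = x+1]
  c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1)
}

mask_boundary <- function(mask) {
  oc <- EBImage::ocontour(frame_to_image(mask))
  pts <- do.call(rbind, oc)             # [x, y], 0-based
  colnames(pts) <- c("x", "y")
  pts
}

#' Contact label from a set of boundary points
#'
#' A point set is in contact with zone k when its minimum distance to the
#' zone segment is at most `contact_distance_px` (closed inequality). If
#' both zones qualify the nearer one wins; an exact tie is labelled
#' `"none"`.
#'
#' @param pts matrix of points (columns x, y, px).
#' @param zones named list of two zone segments.
#' @param contact_distance_px contact tolerance (px).
#' @return one of `"none"` or the zone names.
#' @noRd
contact_label <- function(pts, zones, contact_distance_px) {
  d <- vapply(zones, function(z) min(dist_to_segment(pts, z)), numeric(1))
  qual <- d <= contact_distance_px
  if (!any(qual)) return("none")
  if (sum(qual) == 1) return(names(zones)[qual])
  if (d[1] == d[2]) return("none")
  names(zones)[which.min(d)]
}

#' Body-boundary contact with the stimulus zones
#'
#' @param boundary matrix of subject outline points (columns x, y, px),
#'   e.g. from the segmented mask's contour.
#' @param zones named list of the two stimulus-zone segments.
#' @param contact_distance_px contact tolerance (px, closed inequality).
#' @return `"none"` or a zone name.
#' @export
body_contact <- function(boundary, zones, contact_distance_px) {
  contact_label(boundary, zones, contact_distance_px)
}

#' Head-point contact with the stimulus zones
#'
#' As [body_contact()] but measuring only the head point, which avoids
#' false interactions caused by random contact of the rest of the body
#' with the zones.
#'
#' @param head `c(x, y)` head point (px).
#' @inheritParams body_contact
#' @return `"none"` or a zone name.
#' @export
head_contact <- function(head, zones, contact_distance_px) {
  contact_label(rbind(as.numeric(head)), zones, contact_distance_px)
}

#' Moment-based ellipse fit of a subject mask
#'
#' Fits the image-moment ellipse (centre, axes, orientation) and returns
#' its two major-axis endpoints — the candidate head and tail positions,
#' with no distinction between the two at this stage.
#'
#' @param mask logical subject mask.
#' @return list with `center` (`c(x, y)`), `semi_axes`
#'   (`c(major, minor)`), `theta` (radians from +x toward +y) and
#'   `endpoints` (2 x 2 matrix, one endpoint per row).
#'   A degenerate mask (too few pixels, or collinear) is a fit error.
#' @export
fit_body_ellipse <- function(mask) {
  if (is.null(mask) || sum(mask) < 5) {
    stop("fit error: mask too small for an ellipse fit", call. = FALSE)
  }
  m <- EBImage::computeFeatures.moment(frame_to_image(mask) * 1)
  if (is.null(m) || nrow(m) != 1 || !all(is.finite(m[1, ])) ||
      m[1, "m.majoraxis"] <= 0) {
    stop("fit error: degenerate mask (collinear or empty)", call. = FALSE)
  }
  center <- c(m[1, "m.cx"] - 1, m[1, "m.cy"] - 1)
  a <- m[1, "m.majoraxis"] / 2
  b <- a * sqrt(max(0, 1 - m[1, "m.eccentricity"]^2))
  theta <- m[1, "m.theta"]
  u <- unit_vec(theta)
  list(
    center = center,
    semi_axes = c(a, b),
    theta = theta,
    endpoints = rbind(center + a * u, center - a * u)
  )
}

#' Decide which major-axis endpoint is the head
#'
#' The mask at the higher threshold includes the brighter tail; the lower
#' threshold does not. The endpoint farther from the extra (tail) region
#' is the head. When no tail pixels are visible the endpoint closer to
#' the previous head is taken (temporal continuity); with neither
#' disambiguator available the head is undetermined for this frame.
#'
#' @param endpoints 2 x 2 matrix from [fit_body_ellipse()] on the
#'   low-threshold mask.
#' @param high_mask,low_mask logical masks at the two thresholds.
#' @param previous_head optional `c(x, y)` from the last determined frame.
#' @param min_tail_px smallest tail-pixel count considered evidence.
#' @return `c(x, y)` head point, or `NULL` when undetermined.
#' @export
resolve_head_tail <- function(endpoints, high_mask, low_mask,
                              previous_head = NULL, min_tail_px = 4) {
  extra <- high_mask & !low_mask
  if (sum(extra) >= min_tail_px) {
    idx <- which(extra, arr.ind = TRUE)
    tail_c <- c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1)
    d <- sqrt(rowSums((endpoints - rep(tail_c, each = 2))^2))
    return(endpoints[which.max(d), ])
  }
  if (!is.null(previous_head) && all(is.finite(previous_head))) {
    d <- sqrt(rowSums((endpoints - rep(previous_head, each = 2))^2))
    return(endpoints[which.min(d), ])
  }
  NULL
}

#' Remove a thin cable from a subject mask
#'
#' Morphological opening with a disc of radius
#' `ceiling(max_cable_width_px / 2)` removes elongated protrusions no
#' wider than the cable; the largest remaining component is kept and then
#' dilated by the same disc and intersected with the original mask, which
#' restores the eroded outer shell of genuine body parts (including the
#' tail) while the cable can only regrow a stub of at most the disc
#' radius at its attachment point. On a cable-free mask the body area
#' changes by well under 15%.
#'
#' @param mask logical subject mask.
#' @param max_cable_width_px widest cable to remove (px).
#' @return logical mask; may be empty if the mask was all cable.
#' @export
remove_cable <- function(mask, max_cable_width_px = 2) {
  r <- ceiling(max_cable_width_px / 2)
  # diamond (4-neighbourhood) element: removes the thin cable at any
  # orientation but spares diagonal body parts (tail) one pixel wider
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "diamond")
  img <- frame_to_image(mask)                      # [x, y] space
  opened <- EBImage::imageData(EBImage::opening(img, brush)) > 0
  if (!any(opened)) return(t(opened))
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(opened * 1)))
  areas <- tabulate(lab[lab > 0])
  kept <- lab == which.max(areas)
  grown <- EBImage::imageData(
    EBImage::dilate(EBImage::Image(kept * 1), brush)
  ) > 0
  t(grown & EBImage::imageData(img) > 0)
}

#' Track a subject through a video
#'
#' Runs one of the three tracking algorithms over every frame:
#' \describe{
#'   \item{`body`}{segments the whole animal at the high threshold and
#'     labels contact from the body boundary.}
#'   \item{`head`}{additionally fits the body ellipse at the low
#'     threshold, resolves head vs tail from the high-threshold tail
#'     region, and labels contact from the head point only. Frames with
#'     an undetermined head get contact `"none"`.}
#'   \item{`wired_body`}{as `body` after removing the cable by
#'     morphological opening.}
#' }
#' Frames without an acceptable subject blob are marked invalid, carry no
#' state except the previous head, and contribute nothing to any time
#' total. Tracking is a pure function of (frames, config, algorithm).
#'
#' @param video a file path (multi-page TIFF stack or frame directory,
#'   see [read_video()]), a list of frame matrices, or a
#'   `height x width x n` array (gray 0-255).
#' @param cfg an `arena_config`.
#' @param algorithm `"body"`, `"head"` or `"wired_body"`.
#' @return a `tracking_result`: tibble with columns `frame`, `time_s`,
#'   `valid`, `cx_px`, `cy_px`, `head_x_px`, `head_y_px`, `contact`,
#'   `algorithm`, one row per frame, with the config attached as an
#'   attribute. A warning is raised when over 20% of frames are invalid.
#' @export
track <- function(video, cfg, algorithm = c("body", "head", "wired_body")) {
  stopifnot(inherits(cfg, "arena_config"))
  algorithm <- match.arg(algorithm)
  frames <- if (is.character(video)) {
    read_video(video)
  } else if (is.array(video) && length(dim(video)) == 3) {
    lapply(seq_len(dim(video)[3]), function(i) video[, , i])
  } else if (is.list(video)) {
    video
  } else {
    stop("input error: video must be a path, a list of frames, or a 3-D array",
         call. = FALSE)
  }
  n <- length(frames)
  if (n == 0) stop("input error: empty video", call. = FALSE)
  dims <- dim(frames[[1]])
  zones <- cfg$stimulus_zones
  cd <- cfg$contact_distance_px
  thr_lo <- cfg$detection_threshold_low
  thr_hi <- cfg$detection_threshold_high

  valid <- logical(n)
  cx <- cy <- hx <- hy <- rep(NA_real_, n)
  contact <- rep("none", n)
  prev_centroid <- NULL
  prev_head <- NULL

  for (i in seq_len(n)) {
    f <- frames[[i]]
    if (!identical(dim(f), dims)) {
      stop("input error: frame size changes mid-video", call. = FALSE)
    }
    if (algorithm == "head") {
      low <- segment_subject(f, thr_lo, cfg$min_blob_area_px, cfg,
                             prev_centroid)
      if (is.null(low)) next
      high <- segment_subject(f, thr_hi, cfg$min_blob_area_px, cfg,
                              prev_centroid)
      fit <- tryCatch(fit_body_ellipse(low), error = function(e) NULL)
      if (is.null(fit)) next
      valid[i] <- TRUE
      cx[i] <- fit$center[1]; cy[i] <- fit$center[2]
      prev_centroid <- fit$center
      head <- resolve_head_tail(fit$endpoints, high %||% low, low, prev_head)
      if (!is.null(head)) {
        hx[i] <- head[1]; hy[i] <- head[2]
        prev_head <- head
        contact[i] <- head_contact(head, zones, cd)
      }
    } else {
      mask <- segment_subject(f, thr_hi, cfg$min_blob_area_px, cfg,
                              prev_centroid)
      if (is.null(mask)) next
      if (algorithm == "wired_body") {
        mask <- remove_cable(mask, cfg$max_cable_width_px)
        if (sum(mask) < cfg$min_blob_area_px) next
      }
      valid[i] <- TRUE
      cen <- mask_centroid(mask)
      cx[i] <- cen[1]; cy[i] <- cen[2]
      prev_centroid <- cen
      contact[i] <- body_contact(mask_boundary(mask), zones, cd)
    }
  }
  if (mean(!valid) > 0.2) {
    warning(sprintf("%.0f%% of frames had no acceptable subject blob",
                    100 * mean(!valid)))
  }
  out <- tibble::tibble(
    frame = seq_len(n) - 1L,
    time_s = (seq_len(n) - 1L) / cfg$frame_rate,
    valid = valid,
    cx_px = cx, cy_px = cy,
    head_x_px = hx, head_y_px = hy,
    contact = contact,
    algorithm = algorithm
  )
  structure(out, config = cfg, frame_count = n,
            class = c("tracking_result", class(out)))
}

#' Write a tracking result as CSV
#'
#' @param track a `tracking_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tracking <- function(track, path) {
  utils::write.csv(as.data.frame(track), path, row.names = FALSE)
  invisible(path)
}

#' Read a per-frame tracking CSV back into a tracking result
#'
#' @param path CSV written by [write_tracking()].
#' @param cfg the `arena_config` the tracking was produced with.
#' @return a `tracking_result` tibble.
#' @export
read_tracking <- function(path, cfg) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- tibble::as_tibble(df)
  structure(out, config = cfg, frame_count = nrow(out),
            class = c("tracking_result", class(out)))
}
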