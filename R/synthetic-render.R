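# Renders a behavior script as a synthetic top-view video: a dark
# elliptical mouse on a light arena floor, with an optional brighter tail
# (between the two detection thresholds, to exercise the dual-threshold
# head/tail logic) and an optional thin dark cable from the head to a
# fixed anchor. The per-frame ground-truth log is computed from the
# rendered geometry, not the commanded script, to keep the oracle honest.

#' Parameters of the synthetic video renderer
#'
#' Gray levels are 0-255. The defaults satisfy
#' body < low threshold < tail < high threshold < background for the
#' default [arena_config()] thresholds (90/160), so the low threshold
#' captures the body without the tail and the high threshold includes it.
#'
#' @param frame_width_px,frame_height_px frame size (px).
#' @param frame_rate frames per second.
#' @param body_semi_axes_px mouse ellipse semi-axes `c(major, minor)`.
#' @param body_gray,tail_gray,background_gray,cable_gray gray levels.
#' @param tail_length_px,tail_width_px tail geometry; `tail_length_px = 0`
#'   renders a tailless mouse.
#' @param cable_width_px,cable_anchor cable geometry; `cable_anchor` is a
#'   `c(x, y)` point (px) or `NULL` for an unwired animal.
#' @param noise_sd Gaussian pixel-noise standard deviation (gray levels).
#' @param speed_px_s roaming speed of the body centre.
#' @param jitter_px small per-frame pose jitter during investigation.
#' @param seed RNG seed for the pose planner and noise.
#' @return a `render_params` list.
#' @export
render_params <- function(frame_width_px = 320,
                          frame_height_px = 240,
                          frame_rate = 30,
                          body_semi_axes_px = c(16, 7),
                          body_gray = 40,
                          tail_gray = 120,
                          background_gray = 210,
                          cable_gray = 45,
                          tail_length_px = 22,
                          tail_width_px = 3,
                          cable_width_px = 2,
                          cable_anchor = NULL,
                          noise_sd = 3,
                          speed_px_s = 150,
                          jitter_px = 0.4,
                          seed = 1L) {
  p <- list(
    frame_width_px = as.integer(frame_width_px),
    frame_height_px = as.integer(frame_height_px),
    frame_rate = frame_rate,
    body_semi_axes_px = body_semi_axes_px,
    body_gray = body_gray, tail_gray = tail_gray,
    background_gray = background_gray, cable_gray = cable_gray,
    tail_length_px = tail_length_px, tail_width_px = tail_width_px,
    cable_width_px = cable_width_px, cable_anchor = cable_anchor,
    noise_sd = noise_sd, speed_px_s = speed_px_s, jitter_px = jitter_px,
    seed = as.integer(seed)
  )
  if (!(p$body_gray < p$tail_gray && p$tail_gray < p$background_gray)) {
    stop("config error: require body_gray < tail_gray < background_gray",
         call. = FALSE)
  }
  structure(p, class = "render_params")
}

unit_vec <- function(theta) c(cos(theta), sin(theta))

# Plan one pose (centre + heading) per frame from a behavior script.
# Investigation segments pin the nose onto the target zone with the body
# axis perpendicular to it; roam segments follow a smooth waypoint walk
# through the central arena, away from both zones.
plan_poses <- function(script, cfg, render) {
  fr <- render$frame_rate
  a <- render$body_semi_axes_px[1]
  session_length_s <- max(script$end_s)
  n <- round(session_length_s * fr)
  t <- (seq_len(n) - 1L) / fr
  seg_idx <- findInterval(t, script$start_s)

  r <- cfg$arena_rect
  center_arena <- c(r[["x0"]] + r[["width"]] / 2, r[["y0"]] + r[["height"]] / 2)
  zone_normal <- function(z) {
    mid <- colMeans(z)
    d <- z[2, ] - z[1, ]
    nrm <- c(-d[2], d[1]) / sqrt(sum(d^2))
    # orient away from the arena centre (into the chamber corner)
    if (sum((mid + nrm - center_arena)^2) <
        sum((mid - nrm - center_arena)^2)) {
      nrm <- -nrm
    }
    nrm
  }
  zones <- cfg$stimulus_zones
  normals <- lapply(zones, zone_normal)

  sample_waypoint <- function() {
    c(stats::runif(1, r[["x0"]] + 0.25 * r[["width"]],
                   r[["x0"]] + 0.75 * r[["width"]]),
      stats::runif(1, r[["y0"]] + 0.25 * r[["height"]],
                   r[["y0"]] + 0.75 * r[["height"]]))
  }
  # per-segment fixed nose anchor on the zone (fraction along the wall)
  seg_frac <- stats::runif(nrow(script), 0.35, 0.65)

  step <- render$speed_px_s / fr
  pos <- center_arena
  heading <- 0
  waypoint <- sample_waypoint()
  cx <- cy <- th <- numeric(n)
  for (i in seq_len(n)) {
    s <- seg_idx[i]
    if (script$state[s] == "investigate") {
      k <- if (script$stimulus[s] == names(zones)[1]) 1L else 2L
      z <- zones[[k]]
      nose <- z[1, ] + seg_frac[s] * (z[2, ] - z[1, ])
      heading <- atan2(normals[[k]][2], normals[[k]][1])
      pos <- nose - a * unit_vec(heading)
      if (render$jitter_px > 0) {
        pos <- pos + stats::rnorm(2, 0, render$jitter_px)
      }
    } else {
      d <- waypoint - pos
      dist <- sqrt(sum(d^2))
      if (dist < 6) {
        waypoint <- sample_waypoint()
        d <- waypoint - pos
        dist <- sqrt(sum(d^2))
      }
      mv <- d / max(dist, 1e-9) * min(step, dist)
      pos <- pos + mv
      if (dist > 1e-6) heading <- atan2(d[2], d[1])
    }
    cx[i] <- pos[1]; cy[i] <- pos[2]; th[i] <- heading
  }
  tibble::tibble(frame = seq_len(n) - 1L, time_s = t,
                 cx_px = cx, cy_px = cy, theta = th)
}

# paint pixels within width/2 of the segment p->q (gray level `value`)
paint_segment <- function(frame, p, q, width, value) {
  h <- nrow(frame); w <- ncol(frame)
  half <- width / 2
  x0 <- max(0, floor(min(p[1], q[1]) - half - 1))
  x1 <- min(w - 1, ceiling(max(p[1], q[1]) + half + 1))
  y0 <- max(0, floor(min(p[2], q[2]) - half - 1))
  y1 <- min(h - 1, ceiling(max(p[2], q[2]) + half + 1))
  if (x1 < x0 || y1 < y0) return(frame)
  xs <- x0:x1; ys <- y0:y1
  grid <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  d <- dist_to_segment(grid, rbind(p, q))
  sel <- d <= half
  if (any(sel)) {
    frame[cbind(grid[sel, 2] + 1L, grid[sel, 1] + 1L)] <- value
  }
  frame
}

paint_ellipse <- function(frame, center, semi_axes, theta, value) {
  h <- nrow(frame); w <- ncol(frame)
  a <- semi_axes[1]; b <- semi_axes[2]
  x0 <- max(0, floor(center[1] - a - 1)); x1 <- min(w - 1, ceiling(center[1] + a + 1))
  y0 <- max(0, floor(center[2] - a - 1)); y1 <- min(h - 1, ceiling(center[2] + a + 1))
  if (x1 < x0 || y1 < y0) return(frame)
  xs <- x0:x1; ys <- y0:y1
  dx <- outer(rep(1, length(ys)), xs - center[1])
  dy <- outer(ys - center[2], rep(1, length(xs)))
  ct <- cos(theta); st <- sin(theta)
  u <- dx * ct + dy * st
  v <- -dx * st + dy * ct
  sel <- (u / a)^2 + (v / b)^2 <= 1
  sub <- frame[ys + 1L, xs + 1L, drop = FALSE]
  sub[sel] <- value
  frame[ys + 1L, xs + 1L] <- sub
  frame
}

# ground-truth contact from the rendered geometry: the body boundary is
# the ellipse outline plus the tail outline (the whole-animal silhouette
# the high threshold sees); the head is the nose point.
truth_contact <- function(pose, cfg, render) {
  a <- render$body_semi_axes_px[1]
  b <- render$body_semi_axes_px[2]
  u <- unit_vec(pose$theta)
  center <- c(pose$cx_px, pose$cy_px)
  nose <- center + a * u
  pts <- ellipse_polygon(center, c(a, b), pose$theta, 48L)
  area_body <- pi * a * b
  centroid <- center
  if (render$tail_length_px > 0) {
    base <- center - a * u
    tip <- base - render$tail_length_px * u
    tt <- seq(0, 1, length.out = 12)
    tail_pts <- cbind(base[1] + tt * (tip[1] - base[1]),
                      base[2] + tt * (tip[2] - base[2]))
    pts <- rbind(pts, tail_pts)
    # whole-silhouette centroid: what a body-based tracker measures
    area_tail <- render$tail_length_px * render$tail_width_px
    centroid <- (area_body * center + area_tail * (base + tip) / 2) /
      (area_body + area_tail)
  }
  list(
    body = contact_label(pts, cfg$stimulus_zones, cfg$contact_distance_px),
    head = contact_label(rbind(nose), cfg$stimulus_zones,
                         cfg$contact_distance_px),
    nose = nose,
    centroid = centroid
  )
}

#' Render a behavior script (or explicit poses) as a synthetic video
#'
#' Produces one grayscale frame per pose: background, body ellipse,
#' optional tail drawn opposite the nose, optional cable from the nose to
#' a fixed anchor, plus Gaussian pixel noise. The ground-truth log
#' (centroid, head and contact labels per frame) is derived from the
#' rendered geometry.
#'
#' @param script a `behavior_script` from [simulate_behavior()], or a
#'   pose tibble with columns `frame`, `time_s`, `cx_px`, `cy_px`,
#'   `theta` (radians, nose direction) for scripted scenarios.
#' @param cfg an `arena_config` consistent with the frame size.
#' @param render a [render_params()].
#' @param path optional file path; when given, the frames are written as
#'   an 8-bit multi-page TIFF stack (the package's image-stack video
#'   format) and the ground-truth log as `<path>.truth.csv`.
#' @return invisible list with `frames` (list of `height x width`
#'   matrices, gray 0-255), `truth` and `path`. The truth tibble carries,
#'   per frame, the whole-silhouette centroid `cx_px`/`cy_px` (what a
#'   body-based tracker measures), the ellipse centre
#'   `center_x_px`/`center_y_px`, the nose `head_x_px`/`head_y_px`, and
#'   the `contact`/`head_contact` labels from the rendered geometry.
#' @export
render_video <- function(script, cfg, render = render_params(), path = NULL) {
  stopifnot(inherits(cfg, "arena_config"))
  if (!(render$body_gray <= cfg$detection_threshold_low &&
        cfg$detection_threshold_low < render$tail_gray &&
        render$tail_gray <= cfg$detection_threshold_high &&
        cfg$detection_threshold_high < render$background_gray)) {
    stop(paste0("config error: gray levels must satisfy body <= low threshold",
                " < tail <= high threshold < background"), call. = FALSE)
  }
  local_seed(render$seed, {
    poses <- if (inherits(script, "behavior_script")) {
      plan_poses(script, cfg, render)
    } else {
      script
    }
    n <- nrow(poses)
    h <- render$frame_height_px; w <- render$frame_width_px
    a <- render$body_semi_axes_px[1]; b <- render$body_semi_axes_px[2]
    frames <- vector("list", n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      p <- poses[i, ]
      f <- matrix(render$background_gray, nrow = h, ncol = w)
      u <- unit_vec(p$theta)
      nose <- c(p$cx_px, p$cy_px) + a * u
      if (!is.null(render$cable_anchor)) {
        f <- paint_segment(f, nose, render$cable_anchor,
                           render$cable_width_px, render$cable_gray)
      }
      if (render$tail_length_px > 0) {
        base <- c(p$cx_px, p$cy_px) - a * u
        tip <- base - render$tail_length_px * u
        f <- paint_segment(f, base, tip, render$tail_width_px,
                           render$tail_gray)
      }
      f <- paint_ellipse(f, c(p$cx_px, p$cy_px), c(a, b), p$theta,
                         render$body_gray)
      if (render$noise_sd > 0) {
        f <- f + matrix(stats::rnorm(h * w, 0, render$noise_sd), h, w)
        f[] <- pmin(255, pmax(0, f))
      }
      # frames are 8-bit video: store as integer gray levels
      f[] <- round(f)
      storage.mode(f) <- "integer"
      frames[[i]] <- f
      tc <- truth_contact(p, cfg, render)
      truth[[i]] <- list(frame = p$frame, time_s = p$time_s,
                         cx_px = tc$centroid[1], cy_px = tc$centroid[2],
                         center_x_px = p$cx_px, center_y_px = p$cy_px,
                         head_x_px = tc$nose[1], head_y_px = tc$nose[2],
                         contact = tc$body, head_contact = tc$head)
    }
    truth <- dplyr::bind_rows(truth)
    if (!is.null(path)) {
      write_video(frames, path)
      utils::write.csv(truth, paste0(path, ".truth.csv"), row.names = FALSE)
    }
    invisible(list(frames = frames, truth = truth, path = path))
  })
}

#' Read / write image-stack videos
#'
#' The package's native video format is an 8-bit grayscale multi-page
#' TIFF stack (one page per frame); [read_video()] also accepts a
#' directory of alphabetically ordered PNG/TIFF frames. RGB input is
#' converted to luminance.
#'
#' @param path a TIFF stack or a directory of frame images.
#' @return [read_video()]: list of `height x width` numeric matrices with
#'   gray values 0-255. [write_video()]: `path`, invisibly.
#' @export
read_video <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("I/O error: video '%s' does not exist", path), call. = FALSE)
  }
  to_gray <- function(m) {
    if (length(dim(m)) == 3) {
      # luminance from RGB planes
      m <- 0.2126 * m[, , 1] + 0.7152 * m[, , 2] + 0.0722 * m[, , 3]
    }
    m <- round(m * 255)
    storage.mode(m) <- "integer"
    m
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             full.names = TRUE, ignore.case = TRUE))
    if (length(files) == 0) {
      stop(sprintf("I/O error: no frame images found in '%s'", path),
           call. = FALSE)
    }
    frames <- lapply(files, function(fp) {
      img <- if (grepl("\\.png$", fp, ignore.case = TRUE)) {
        as.array(EBImage::readImage(fp))
      } else {
        tiff::readTIFF(fp)
      }
      if (grepl("\\.png$", fp, ignore.case = TRUE)) {
        # EBImage arrays are [x, y(, c)]; transpose to image rows
        img <- if (length(dim(img)) == 3) aperm(img, c(2, 1, 3)) else t(img)
      }
      to_gray(img)
    })
    return(frames)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, to_gray)
}

#' @rdname read_video
#' @param frames list of `height x width` matrices, gray 0-255.
#' @export
write_video <- function(frames, path) {
  ok <- tryCatch({
    tiff::writeTIFF(lapply(frames, function(f) f / 255), path,
                    bits.per.sample = 8L, compression = "none")
    TRUE
  }, error = function(e) {
    stop(sprintf("I/O error: cannot write video '%s': %s", path,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(path)
}

#' Scripted scenario poses
#'
#' Hand-built pose tables for targeted tracker checks:
#' `scenario_tail_contact()` parks the mouse with its rump toward a
#' stimulus zone so that only the tail end is within contact distance for
#' `contact_s` seconds in the middle of the session (the false-interaction
#' class the head-directionality algorithm exists to remove);
#' `scenario_straight_path()` walks the centroid along a straight line of
#' known physical length for distance calibration;
#' `scenario_parked()` keeps the mouse at a fixed pose away from both
#' zones (with a wired render, place the cable anchor behind a zone so
#' the cable sweeps it while the mouse stays far away).
#'
#' @param cfg an `arena_config`.
#' @param render a [render_params()].
#' @param duration_s scenario length (s).
#' @param contact_s tail-contact time in the middle of the scenario (s).
#' @param zone which stimulus zone the tail touches (1 or 2).
#' @return a pose tibble for [render_video()].
#' @export
scenario_tail_contact <- function(cfg, render, duration_s = 10,
                                  contact_s = 3, zone = 1L) {
  fr <- render$frame_rate
  n <- round(duration_s * fr)
  t <- (seq_len(n) - 1L) / fr
  a <- render$body_semi_axes_px[1]
  z <- cfg$stimulus_zones[[zone]]
  mid <- colMeans(z)
  d <- z[2, ] - z[1, ]
  nrm <- c(-d[2], d[1]) / sqrt(sum(d^2))
  r <- cfg$arena_rect
  center_arena <- c(r[["x0"]] + r[["width"]] / 2, r[["y0"]] + r[["height"]] / 2)
  if (sum((mid + nrm - center_arena)^2) < sum((mid - nrm - center_arena)^2)) {
    nrm <- -nrm   # nrm points into the chamber corner
  }
  # facing away from the zone: tail tip just inside contact distance
  theta <- atan2(-nrm[2], -nrm[1])
  u <- unit_vec(theta)
  tail_tip_target <- mid + nrm * max(0, cfg$contact_distance_px - 1)
  center_near <- tail_tip_target + (a + render$tail_length_px) * u
  center_far <- center_arena
  t0 <- (duration_s - contact_s) / 2
  t1 <- t0 + contact_s
  near <- t >= t0 & t < t1
  tibble::tibble(
    frame = seq_len(n) - 1L, time_s = t,
    cx_px = ifelse(near, center_near[1], center_far[1]),
    cy_px = ifelse(near, center_near[2], center_far[2]),
    theta = theta
  )
}

#' @rdname scenario_tail_contact
#' @param length_cm physical path length for the straight walk (cm).
#' @export
scenario_straight_path <- function(cfg, render, length_cm = 20,
                                   duration_s = 10) {
  fr <- render$frame_rate
  n <- round(duration_s * fr)
  t <- (seq_len(n) - 1L) / fr
  r <- cfg$arena_rect
  len_px <- length_cm * cfg$px_per_cm
  y <- r[["y0"]] + r[["height"]] / 2
  x0 <- r[["x0"]] + (r[["width"]] - len_px) / 2
  frac <- (seq_len(n) - 1L) / (n - 1L)
  tibble::tibble(
    frame = seq_len(n) - 1L, time_s = t,
    cx_px = x0 + frac * len_px, cy_px = y, theta = 0
  )
}

#' @rdname scenario_tail_contact
#' @param at optional fixed centre `c(x, y)` (px); default arena centre.
#' @export
scenario_parked <- function(cfg, render, duration_s = 10, at = NULL) {
  fr <- render$frame_rate
  n <- round(duration_s * fr)
  r <- cfg$arena_rect
  at <- at %||% c(r[["x0"]] + r[["width"]] / 2, r[["y0"]] + r[["height"]] / 2)
  tibble::tibble(
    frame = seq_len(n) - 1L, time_s = (seq_len(n) - 1L) / fr,
    cx_px = at[1], cy_px = at[2], theta = 0
  )
}
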