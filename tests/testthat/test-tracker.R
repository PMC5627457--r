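blank_frame <- function(cfg, value = 210) {
  matrix(value, nrow = 240, ncol = 320)
}

test_that("segmentation keeps the largest dark arena component above min area", {
  cfg <- std_cfg()
  # uniform white frame: nothing to segment
  expect_null(segment_subject(blank_frame(cfg), 160, 50, cfg))
  # one dark ellipse: recovered area within 5% of the painted pixel count
  f <- blank_frame(cfg)
  f <- socialtrackr:::paint_ellipse(f, c(160, 120), c(16, 7), 0.6, 40)
  painted <- sum(f < 160)
  m <- segment_subject(f, 160, 50, cfg)
  expect_false(is.null(m))
  expect_lt(abs(sum(m) - painted) / painted, 0.05)
  # a small dark speck below min_area is ignored
  f2 <- f
  f2[50:51, 50:51] <- 40
  m2 <- segment_subject(f2, 160, 50, cfg)
  expect_equal(sum(m2), sum(m))
  # frame smaller than the configured arena is an input error
  expect_error(segment_subject(matrix(210, 10, 10), 160, 50, cfg),
               "input error")
})

test_that("moment ellipse fit recovers orientation and axis endpoints", {
  cfg <- std_cfg()
  for (deg in c(0, 37, 118)) {
    th <- deg * pi / 180
    f <- blank_frame(cfg)
    f <- socialtrackr:::paint_ellipse(f, c(160, 120), c(16, 7), th, 40)
    fit <- fit_body_ellipse(segment_subject(f, 160, 50, cfg))
    # orientation modulo pi within 2 degrees
    dtheta <- abs(((fit$theta - th + pi / 2) %% pi) - pi / 2)
    expect_lt(dtheta * 180 / pi, 2)
    # endpoints within 2 px of the rendered nose/rump
    nose <- c(160, 120) + 16 * c(cos(th), sin(th))
    rump <- c(160, 120) - 16 * c(cos(th), sin(th))
    d_to <- function(p) min(sqrt(rowSums((fit$endpoints -
                                            rep(p, each = 2))^2)))
    expect_lt(d_to(nose), 2)
    expect_lt(d_to(rump), 2)
  }
  # degenerate masks are fit errors
  expect_error(fit_body_ellipse(matrix(FALSE, 5, 5)), "fit error")
  m1 <- matrix(FALSE, 5, 5); m1[3, 3] <- TRUE
  expect_error(fit_body_ellipse(m1), "fit error")
})

test_that("head/tail resolution prefers tail evidence, then continuity", {
  low <- matrix(FALSE, 60, 60)
  low[26:34, 11:49] <- TRUE                 # horizontal body
  high <- low
  high[28:31, 50:58] <- TRUE                # tail extends to the right
  ep <- rbind(c(10, 29.5), c(49, 29.5))     # (x, y) endpoints
  head <- resolve_head_tail(ep, high, low)
  expect_equal(head, c(10, 29.5))           # far from the tail region
  # no tail pixels: fall back to the endpoint nearest the previous head
  head2 <- resolve_head_tail(ep, low, low, previous_head = c(47, 30))
  expect_equal(head2, c(49, 29.5))
  # first frame, no tail: undetermined
  expect_null(resolve_head_tail(ep, low, low))
})

test_that("contact rules: closed inequality, nearer zone, head vs body", {
  cfg <- std_cfg()
  zones <- cfg$stimulus_zones
  cd <- cfg$contact_distance_px
  z1 <- zones[[1]]
  mid <- colMeans(z1)
  # far from both zones
  far <- rbind(c(160, 120))
  expect_equal(body_contact(far, zones, cd), "none")
  # a boundary point exactly on zone 1
  expect_equal(body_contact(rbind(mid), zones, cd), "stim1")
  # at exactly the contact distance: still contact (closed inequality)
  d <- z1[2, ] - z1[1, ]
  nrm <- c(-d[2], d[1]) / sqrt(sum(d^2))
  expect_equal(body_contact(rbind(mid + cd * nrm), zones, cd), "stim1")
  # head far while rump touches: head algorithm says none
  expect_equal(head_contact(c(160, 120), zones, cd), "none")
  expect_equal(head_contact(colMeans(zones[[2]]), zones, cd), "stim2")
})

test_that("cable removal strips thin protrusions but not the body", {
  # fat blob: opening changes area by well under 15%
  m <- matrix(FALSE, 80, 80)
  m[30:50, 20:60] <- TRUE
  m2 <- remove_cable(m, 2)
  expect_lt(abs(sum(m2) - sum(m)) / sum(m), 0.15)
  # blob + 2-px cable: cable pixels removed, centroid almost unmoved
  mc <- m
  mc[39:40, 61:80] <- TRUE
  m3 <- remove_cable(mc, 2)
  c_free <- socialtrackr:::mask_centroid(m)
  c_rm <- socialtrackr:::mask_centroid(m3)
  expect_lt(sqrt(sum((c_free - c_rm)^2)), 3)
  expect_lt(sum(m3), sum(mc) - 20)
})

test_that("body tracking recovers scripted contact labels on rendered video", {
  fix <- short_session()
  tr <- track(fix$video$frames, fix$cfg, "body")
  expect_equal(nrow(tr), length(fix$video$frames))
  expect_true(all(diff(tr$frame) == 1))
  expect_gte(mean(tr$contact == fix$video$truth$contact), 0.95)
  expect_true(all(tr$valid))
  # centroid tracks the rendered silhouette centroid closely
  err <- sqrt((tr$cx_px - fix$video$truth$cx_px)^2 +
                (tr$cy_px - fix$video$truth$cy_px)^2)
  expect_lt(median(err), 1.5)
  # determinism: tracking the same frames twice is identical
  tr2 <- track(fix$video$frames, fix$cfg, "body")
  expect_identical(as.data.frame(tr), as.data.frame(tr2))
})

test_that("head tracking recovers the nose and its contact labels", {
  fix <- short_session()
  tr <- track(fix$video$frames, fix$cfg, "head")
  expect_gte(mean(tr$contact == fix$video$truth$head_contact), 0.95)
  determined <- is.finite(tr$head_x_px)
  expect_gt(mean(determined), 0.9)
  err <- sqrt((tr$head_x_px - fix$video$truth$head_x_px)^2 +
                (tr$head_y_px - fix$video$truth$head_y_px)^2)
  expect_lt(median(err, na.rm = TRUE), 3)
  # head contact implies body contact on the same frame (head is on the body)
  trb <- track(fix$video$frames, fix$cfg, "body")
  hk <- tr$contact != "none"
  expect_true(all(trb$contact[hk] == tr$contact[hk]))
})

test_that("an empty arena yields all-invalid frames and zero investigation", {
  cfg <- std_cfg()
  frames <- lapply(1:30, function(i) blank_frame(cfg))
  expect_warning(tr <- track(frames, cfg, "body"), "no acceptable subject")
  expect_true(all(!tr$valid))
  expect_true(all(tr$contact == "none"))
  s <- session_summary(labels_from_tracking(tr), bin_width_s = 1)
  expect_equal(sum(s$totals$investigation_s), 0)
})

test_that("body and wired tracking agree on tail-free, cable-free video", {
  cfg <- std_cfg()
  script <- simulate_behavior(behavior_params(
    session_length_s = 10, phase_boundary_s = 4, seed = 33
  ))
  rv <- render_video(script, cfg, render_params(seed = 33,
                                                tail_length_px = 0))
  trb <- track(rv$frames, cfg, "body")
  trw <- track(rv$frames, cfg, "wired_body")
  # opening barely perturbs a fat convex blob: labels and centroids agree
  # within the cable-removal area tolerance
  expect_gte(mean(trw$contact == trb$contact), 0.97)
  err <- sqrt((trw$cx_px - trb$cx_px)^2 + (trw$cy_px - trb$cy_px)^2)
  expect_lt(median(err, na.rm = TRUE), 1)
})

test_that("tracking CSVs round-trip and preserve the schema", {
  fix <- short_session()
  tr <- track(fix$video$frames[1:30], fix$cfg, "body")
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracking(tr, path)
  back <- read_tracking(path, fix$cfg)
  expect_equal(names(back),
               c("frame", "time_s", "valid", "cx_px", "cy_px",
                 "head_x_px", "head_y_px", "contact", "algorithm"))
  expect_equal(back$contact, tr$contact)
  expect_equal(back$cx_px, tr$cx_px, tolerance = 1e-9)
})
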