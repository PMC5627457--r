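#' Per-frame investigation label series
#'
#' The hinge between tracking and analytics: one label per video frame,
#' each `"none"`, `"stim1"` or `"stim2"` (or the configured zone names).
#' Stored as a tibble with columns `frame` (0-based), `time_s` and
#' `label`, carrying the frame rate and a gap-correction flag as
#' attributes.
#'
#' @param labels character vector of per-frame labels.
#' @param frame_rate frames per second (> 0).
#' @param corrected has gap correction already been applied?
#' @param stimuli the two stimulus label values; anything else is treated
#'   as non-investigation.
#' @return a `label_series` tibble.
#' @seealso [correct_gaps()], [extract_bouts()]
#' @export
label_series <- function(labels, frame_rate,
                         corrected = FALSE,
                         stimuli = c("stim1", "stim2")) {
  labels <- as.character(labels)
  if (length(labels) < 1) stop("label series must have length >= 1", call. = FALSE)
  if (!is.numeric(frame_rate) || frame_rate <= 0) {
    stop("frame_rate must be > 0", call. = FALSE)
  }
  if (length(stimuli) != 2) stop("exactly 2 stimulus labels required", call. = FALSE)
  out <- tibble::tibble(
    frame = seq_along(labels) - 1L,
    time_s = (seq_along(labels) - 1L) / frame_rate,
    label = labels
  )
  structure(out,
            frame_rate = as.numeric(frame_rate),
            corrected = isTRUE(corrected),
            stimuli = as.character(stimuli),
            class = c("label_series", class(out)))
}

series_frame_rate <- function(series) attr(series, "frame_rate", exact = TRUE)
series_stimuli <- function(series) attr(series, "stimuli", exact = TRUE)
is_corrected <- function(series) isTRUE(attr(series, "corrected", exact = TRUE))

#' Merge short interruptions in investigation of a stimulus
#'
#' Any maximal run of frames not labelled with stimulus k, strictly
#' shorter than `gap_merge_s` and flanked on both sides by stimulus k, is
#' relabelled k, so that the interruption does not break the investigation
#' bout. At 30 fps and the default 0.5 s this merges gaps of up to 14
#' frames; a 15-frame gap (exactly 0.5 s) is not merged. A gap containing
#' any frame of the other stimulus is never merged (a visit to the other
#' stimulus always breaks the bout) unless `merge_across_other = TRUE`.
#' Correction is applied independently per stimulus, left to right.
#'
#' @param series an uncorrected [label_series()].
#' @param gap_merge_s gaps strictly shorter than this (s) are merged.
#' @param merge_across_other also merge gaps containing other-stimulus
#'   frames (not the default; it would silently delete transitions).
#' @return a corrected `label_series`.
#' @export
correct_gaps <- function(series, gap_merge_s = 0.5, merge_across_other = FALSE) {
  stopifnot(inherits(series, "label_series"))
  if (is_corrected(series)) {
    return(series)   # idempotent: nothing left to merge
  }
  fr <- series_frame_rate(series)
  stimuli <- series_stimuli(series)
  labels <- series$label
  for (k in stimuli) {
    other <- setdiff(stimuli, k)
    r <- rle(labels == k)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    n_runs <- length(r$lengths)
    for (i in seq_len(n_runs)) {
      if (r$values[i]) next                      # a k-run, not a gap
      if (i == 1L || i == n_runs) next           # not flanked on both sides
      if (!r$values[i - 1L] || !r$values[i + 1L]) next
      if (r$lengths[i] / fr >= gap_merge_s) next # strict < rule
      gap <- labels[starts[i]:ends[i]]
      if (!merge_across_other && any(gap %in% other)) next
      labels[starts[i]:ends[i]] <- k
    }
  }
  label_series(labels, fr, corrected = TRUE, stimuli = stimuli)
}

#' Extract investigation bouts from a corrected label series
#'
#' One bout per maximal run of frames labelled with the same stimulus.
#' Bout times are half-open `[start_s, end_s)` intervals derived from
#' frame indices at the series frame rate, so per-stimulus bout durations
#' sum exactly to that stimulus's total frame count / frame rate.
#'
#' @param series a gap-corrected [label_series()].
#' @return tibble with columns `stimulus`, `start_s`, `end_s`,
#'   `duration_s`, time-ordered and non-overlapping.
#' @export
extract_bouts <- function(series) {
  stopifnot(inherits(series, "label_series"))
  if (!is_corrected(series)) {
    stop("extract_bouts() expects a gap-corrected series; run correct_gaps() first",
         call. = FALSE)
  }
  fr <- series_frame_rate(series)
  stimuli <- series_stimuli(series)
  r <- rle(series$label)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values %in% stimuli
  tibble::tibble(
    stimulus = r$values[keep],
    start_s = (starts[keep] - 1L) / fr,
    end_s = ends[keep] / fr,
    duration_s = r$lengths[keep] / fr
  )
}

#' Intervals between consecutive investigations of the same stimulus
#'
#' For each stimulus, every gap between the end of one of its bouts and
#' the start of the next that is strictly longer than `gap_merge_s`
#' becomes an interval (shorter gaps were merged away by gap correction).
#' By default an interval may span bouts of the other stimulus; set
#' `allow_spanning = FALSE` to keep only gaps free of any investigation.
#'
#' @param bouts a time-ordered bout tibble from [extract_bouts()].
#' @param gap_merge_s intervals must exceed this duration (s).
#' @param allow_spanning may intervals contain other-stimulus bouts?
#' @return tibble with columns `stimulus`, `start_s`, `end_s`,
#'   `duration_s`, ordered by `start_s`.
#' @export
extract_intervals <- function(bouts, gap_merge_s = 0.5, allow_spanning = TRUE) {
  out <- bouts |>
    dplyr::arrange(.data$start_s) |>
    dplyr::group_by(.data$stimulus) |>
    dplyr::mutate(gap_start = .data$end_s,
                  gap_end = dplyr::lead(.data$start_s)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$gap_end),
                  .data$gap_end - .data$gap_start > gap_merge_s) |>
    dplyr::transmute(
      stimulus = .data$stimulus,
      start_s = .data$gap_start,
      end_s = .data$gap_end,
      duration_s = .data$gap_end - .data$gap_start
    ) |>
    dplyr::arrange(.data$start_s)
  if (!allow_spanning && nrow(out) > 0) {
    free <- purrr::map_lgl(seq_len(nrow(out)), function(i) {
      !any(bouts$stimulus != out$stimulus[i] &
             bouts$start_s < out$end_s[i] &
             bouts$end_s > out$start_s[i])
    })
    out <- out[free, ]
  }
  out
}

#' Transitions between stimuli
#'
#' A transition is the start of every bout whose stimulus differs from the
#' immediately preceding bout's stimulus — the moment the subject starts a
#' fresh investigation after returning from the other stimulus. The first
#' bout of a session is not a transition, and repeated bouts of the same
#' stimulus produce none.
#'
#' @param bouts a time-ordered bout tibble from [extract_bouts()].
#' @return tibble with columns `time_s`, `from`, `to`, chronologically
#'   ordered.
#' @export
extract_transitions <- function(bouts) {
  bouts <- dplyr::arrange(bouts, .data$start_s)
  if (nrow(bouts) < 2) {
    return(tibble::tibble(time_s = numeric(), from = character(),
                          to = character()))
  }
  prev <- bouts$stimulus[-nrow(bouts)]
  cur <- bouts$stimulus[-1]
  chg <- which(cur != prev)
  tibble::tibble(
    time_s = bouts$start_s[chg + 1L],
    from = prev[chg],
    to = cur[chg]
  )
}

#' Time spent in each compartment
#'
#' Assigns every valid frame to a compartment by a point-in-polygon test
#' on the body centroid; frames whose centroid falls in neither
#' compartment (on-edge numerical misses or excursions outside the floor
#' polygoning) and invalid frames are reported as `"none"`, so the times
#' always sum to the session duration.
#'
#' @param track a tracking result from [track()] (or any tibble with
#'   `valid`, `cx_px`, `cy_px`).
#' @param cfg an `arena_config`.
#' @return tibble with columns `region` (the two compartment names plus
#'   `"none"`) and `time_s`.
#' @export
compartment_occupancy <- function(track, cfg) {
  stopifnot(inherits(cfg, "arena_config"))
  fr <- cfg$frame_rate
  comp_names <- names(cfg$compartments)
  assigned <- rep("none", nrow(track))
  ok <- track$valid & is.finite(track$cx_px) & is.finite(track$cy_px)
  if (any(ok)) {
    pts <- cbind(track$cx_px[ok], track$cy_px[ok])
    in1 <- points_in_polygon(pts, cfg$compartments[[1]])
    in2 <- points_in_polygon(pts, cfg$compartments[[2]])
    a <- rep("none", nrow(pts))
    a[in1] <- comp_names[1]                # on-edge: lower index wins
    a[!in1 & in2] <- comp_names[2]
    assigned[ok] <- a
  }
  counts <- table(factor(assigned, levels = c(comp_names, "none")))
  tibble::tibble(
    region = names(counts),
    time_s = as.numeric(counts) / fr
  )
}

#' Build a label series from a tracking result
#'
#' @param track a tracking result from [track()].
#' @param corrected mark the series as already corrected (only for ground
#'   truth series known to contain no spurious gaps).
#' @return a [label_series()].
#' @export
labels_from_tracking <- function(track, corrected = FALSE) {
  cfg <- attr(track, "config", exact = TRUE)
  fr <- if (!is.null(cfg)) cfg$frame_rate else attr(track, "frame_rate")
  stimuli <- if (!is.null(cfg)) names(cfg$stimulus_zones) else c("stim1", "stim2")
  label_series(track$contact, fr, corrected = corrected, stimuli = stimuli)
}
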