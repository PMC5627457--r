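#' Investigation time per time bin
#'
#' Apportions each bout's duration to consecutive half-open time bins
#' `[k*w, (k+1)*w)` by exact temporal overlap, per stimulus. Investigation
#' time is conventionally binned in 20-s bins across the 5-min test.
#'
#' @param bouts bout tibble from [extract_bouts()].
#' @param bin_width_s bin width in seconds (default 20).
#' @param session_length_s total session duration in seconds. If not a
#'   multiple of `bin_width_s` the last bin is truncated (with a warning).
#' @param stimuli stimulus labels to report (defaults to those present).
#' @return tibble with columns `stimulus`, `bin`, `bin_start_s`, `time_s`;
#'   per-stimulus `time_s` sums to that stimulus's total bout time.
#' @export
binned_time <- function(bouts, bin_width_s = 20, session_length_s,
                        stimuli = NULL) {
  if (session_length_s %% bin_width_s != 0) {
    warning("session_length_s is not a multiple of bin_width_s; last bin truncated")
  }
  n_bins <- ceiling(session_length_s / bin_width_s)
  starts <- (seq_len(n_bins) - 1L) * bin_width_s
  if (is.null(stimuli)) stimuli <- sort(unique(bouts$stimulus))
  grid <- tidyr::expand_grid(stimulus = stimuli,
                             bin = seq_len(n_bins))
  grid$bin_start_s <- starts[grid$bin]
  grid$time_s <- purrr::map2_dbl(grid$stimulus, grid$bin_start_s, function(s, b0) {
    b1 <- min(b0 + bin_width_s, session_length_s)
    rows <- bouts$stimulus == s
    sum(pmax(0, pmin(bouts$end_s[rows], b1) - pmax(bouts$start_s[rows], b0)))
  })
  grid
}

#' Relative duration of investigation (RDI)
#'
#' The preference index: the difference between the investigation
#' durations toward the two stimuli divided by their sum. The classical
#' definition takes the absolute value; the signed variant
#' `(d_a - d_b) / (d_a + d_b)` is the default here because directional
#' analyses (testing an RDI against zero, or correlating RDI with other
#' signed quantities) are only meaningful with the sign kept. The sign
#' convention is first-listed stimulus minus second.
#'
#' @param d_a,d_b non-negative investigation durations (s); vectorized.
#' @param signed keep the sign (default) or return the absolute value.
#' @return value in \[-1, 1\] (signed) or \[0, 1\] (unsigned); `NA` when
#'   both durations are zero.
#' @examples
#' rdi(10, 10)            # 0
#' rdi(10, 0)             # 1
#' rdi(1, 3)              # -0.5
#' rdi(1, 3, signed = FALSE)  # 0.5
#' @export
rdi <- function(d_a, d_b, signed = TRUE) {
  if (any(d_a < 0, na.rm = TRUE) || any(d_b < 0, na.rm = TRUE)) {
    stop("domain error: investigation durations must be >= 0", call. = FALSE)
  }
  s <- d_a + d_b
  out <- ifelse(s == 0, NA_real_, (d_a - d_b) / s)
  if (signed) out else abs(out)
}

#' RDI computed from prolonged inter-investigation intervals
#'
#' Applies [rdi()] to the per-stimulus total time spent in intervals
#' longer than `prolonged_threshold_s`. Because the preferred stimulus
#' accumulates less time in prolonged intervals, this index runs opposite
#' in sign to the duration-based RDI across subjects.
#'
#' @param intervals interval tibble from [extract_intervals()].
#' @param prolonged_threshold_s intervals strictly longer than this count
#'   (default 20 s).
#' @param stimuli the two stimulus labels, in sign order (defaults to the
#'   sorted labels present).
#' @inheritParams rdi
#' @return a single RDI value; `NA` if neither stimulus has prolonged
#'   intervals.
#' @export
rdi_by_intervals <- function(intervals, prolonged_threshold_s = 20,
                             signed = TRUE, stimuli = NULL) {
  if (is.null(stimuli)) stimuli <- sort(unique(intervals$stimulus))
  if (length(stimuli) == 0) return(NA_real_)
  long <- intervals[intervals$duration_s > prolonged_threshold_s, ]
  tot <- function(s) sum(long$duration_s[long$stimulus == s])
  rdi(tot(stimuli[1]), tot(stimuli[min(2, length(stimuli))]), signed = signed)
}

duration_categories <- function(edges_s, unit = "s") {
  if (is.unsorted(edges_s, strictly = TRUE)) {
    stop("config error: category edges must be strictly increasing", call. = FALSE)
  }
  breaks <- c(0, edges_s, Inf)
  labs <- character(length(breaks) - 1L)
  labs[1] <- sprintf("<=%g%s", edges_s[1], unit)
  if (length(edges_s) > 1) {
    for (i in 2:length(edges_s)) {
      labs[i] <- sprintf("(%g,%g]%s", edges_s[i - 1], edges_s[i], unit)
    }
  }
  labs[length(labs)] <- sprintf(">%g%s", edges_s[length(edges_s)], unit)
  list(breaks = breaks, labels = labs)
}

#' Total investigation time by bout-duration category
#'
#' Assigns each bout's full duration to the category containing it.
#' Categories are `(0, e1], (e1, e2], ..., (e_last, Inf)`: with the
#' default edges the first category is the short bouts (<= 6 s) and the
#' last the long bouts (> 19 s). Per-stimulus category totals sum to the
#' stimulus's total investigation time.
#'
#' @param bouts bout tibble from [extract_bouts()].
#' @param edges_s strictly increasing category edges (s).
#' @param stimuli stimulus labels to report (defaults to those present).
#' @return tibble with columns `stimulus`, `category`, `time_s`, `n`.
#' @export
bout_duration_histogram <- function(bouts, edges_s = c(6, 12.5, 19),
                                    stimuli = NULL) {
  duration_histogram(bouts, edges_s, stimuli)
}

#' Interval counts and total time by interval-duration category
#'
#' As [bout_duration_histogram()] but for inter-investigation intervals;
#' with the default edges the categories are short (<= 10 s), middle and
#' long (> 20 s) intervals. Both the number of intervals and their total
#' time are reported per stimulus and category.
#'
#' @param intervals interval tibble from [extract_intervals()].
#' @param edges_s strictly increasing category edges (s).
#' @inheritParams bout_duration_histogram
#' @return tibble with columns `stimulus`, `category`, `time_s`, `n`.
#' @export
interval_duration_histogram <- function(intervals, edges_s = c(10, 20),
                                        stimuli = NULL) {
  duration_histogram(intervals, edges_s, stimuli)
}

duration_histogram <- function(events, edges_s, stimuli = NULL) {
  cats <- duration_categories(edges_s)
  if (is.null(stimuli)) stimuli <- sort(unique(events$stimulus))
  events$category <- cut(events$duration_s, breaks = cats$breaks,
                         labels = cats$labels, right = TRUE)
  tidyr::expand_grid(stimulus = stimuli,
                     category = factor(cats$labels, levels = cats$labels)) |>
    dplyr::left_join(
      events |>
        dplyr::group_by(.data$stimulus, .data$category) |>
        dplyr::summarise(time_s = sum(.data$duration_s), n = dplyr::n(),
                         .groups = "drop"),
      by = c("stimulus", "category")
    ) |>
    dplyr::mutate(time_s = dplyr::coalesce(.data$time_s, 0),
                  n = dplyr::coalesce(.data$n, 0L))
}

#' Transition counts per time bin and per analysis window
#'
#' Histograms transition times into half-open bins `[k*w, (k+1)*w)` and
#' totals them over named analysis windows (by default the first and the
#' last two minutes of a 5-min test).
#'
#' @param transitions transition tibble from [extract_transitions()].
#' @param bin_width_s bin width (s).
#' @param session_length_s session duration (s).
#' @param windows named list of `c(start_s, end_s)` half-open windows.
#' @return list with `per_bin` (tibble `bin`, `bin_start_s`, `n`),
#'   `per_window` (tibble `window`, `start_s`, `end_s`, `n`) and
#'   `total` (count).
#' @export
transition_dynamics <- function(transitions, bin_width_s = 20,
                                session_length_s = 300,
                                windows = list(early = c(0, 120),
                                               late = c(180, 300))) {
  n_bins <- ceiling(session_length_s / bin_width_s)
  starts <- (seq_len(n_bins) - 1L) * bin_width_s
  per_bin <- tibble::tibble(
    bin = seq_len(n_bins),
    bin_start_s = starts,
    n = vapply(starts, function(b0) {
      sum(transitions$time_s >= b0 & transitions$time_s < b0 + bin_width_s)
    }, integer(1))
  )
  per_window <- tibble::tibble(
    window = names(windows),
    start_s = vapply(windows, `[`, numeric(1), 1),
    end_s = vapply(windows, `[`, numeric(1), 2)
  )
  per_window$n <- vapply(seq_len(nrow(per_window)), function(i) {
    sum(transitions$time_s >= per_window$start_s[i] &
          transitions$time_s < per_window$end_s[i])
  }, integer(1))
  list(per_bin = per_bin, per_window = per_window,
       total = nrow(transitions))
}

#' Exploration- vs interaction-phase summary
#'
#' Splits the session into an early exploration phase (many transitions,
#' short bouts) and a later interaction phase (few transitions, long
#' bouts, mainly with the preferred stimulus) and summarises each:
#' transition count, mean transitions per bin, and per-stimulus time in
#' short (<= `short_max_s`), middle and long (> `long_min_s`) bouts.
#' Bouts are assigned to the phase containing their start time and are not
#' split across phases, because bout duration is itself the analysed
#' quantity.
#'
#' @param bouts bout tibble from [extract_bouts()].
#' @param transitions transition tibble from [extract_transitions()].
#' @param exploration_window,interaction_window disjoint half-open
#'   `c(start_s, end_s)` windows (defaults: first 2 min; minutes 2-5).
#' @param short_max_s,long_min_s bout-duration cut-offs (s).
#' @param bin_width_s bin width for the per-bin transition rate (s).
#' @return tibble with one row per (phase, stimulus) and columns
#'   `phase`, `stimulus`, `transitions`, `transitions_per_bin`,
#'   `short_bout_s`, `middle_bout_s`, `long_bout_s`, `total_bout_s`.
#' @export
phase_summary <- function(bouts, transitions,
                          exploration_window = c(0, 120),
                          interaction_window = c(120, 300),
                          short_max_s = 6, long_min_s = 19,
                          bin_width_s = 20) {
  windows <- list(exploration = exploration_window,
                  interaction = interaction_window)
  if (max(exploration_window[1], interaction_window[1]) <
      min(exploration_window[2], interaction_window[2])) {
    stop("config error: exploration and interaction windows overlap",
         call. = FALSE)
  }
  stimuli <- sort(unique(bouts$stimulus))
  if (length(stimuli) == 0) stimuli <- character(0)
  purrr::imap_dfr(windows, function(w, phase) {
    in_w <- bouts$start_s >= w[1] & bouts$start_s < w[2]
    b <- bouts[in_w, ]
    n_tr <- sum(transitions$time_s >= w[1] & transitions$time_s < w[2])
    n_bins <- (w[2] - w[1]) / bin_width_s
    rows <- if (length(stimuli) == 0) {
      tibble::tibble(stimulus = character(), short_bout_s = numeric(),
                     middle_bout_s = numeric(), long_bout_s = numeric(),
                     total_bout_s = numeric())
    } else {
      purrr::map_dfr(stimuli, function(s) {
        d <- b$duration_s[b$stimulus == s]
        tibble::tibble(
          stimulus = s,
          short_bout_s = sum(d[d <= short_max_s]),
          middle_bout_s = sum(d[d > short_max_s & d <= long_min_s]),
          long_bout_s = sum(d[d > long_min_s]),
          total_bout_s = sum(d)
        )
      })
    }
    dplyr::mutate(rows, phase = phase, transitions = n_tr,
                  transitions_per_bin = n_tr / n_bins,
                  .before = 1)
  })
}

#' Open-field measures: distance traveled and center/periphery ratio
#'
#' Total distance is the sum of Euclidean step lengths between consecutive
#' valid-frame body centroids, in cm (steps spanning invalid frames are
#' skipped). The center region is the centred rectangle similar to the
#' arena with a quarter of its area (sides scaled by 1/2); the ratio is
#' time inside it over time in the outer three quarters, the standard
#' open-field anxiety proxy.
#'
#' @param track a tracking result from [track()].
#' @param cfg an `arena_config`.
#' @return tibble with columns `total_distance_cm`,
#'   `center_time_s`, `periphery_time_s`, `center_periphery_ratio`
#'   (`NA` when no time was spent in the periphery).
#' @export
open_field_metrics <- function(track, cfg) {
  stopifnot(inherits(cfg, "arena_config"))
  ok <- track$valid & is.finite(track$cx_px) & is.finite(track$cy_px)
  x <- track$cx_px[ok]
  y <- track$cy_px[ok]
  idx <- track$frame[ok]
  consecutive <- diff(idx) == 1L
  dist_px <- sum(sqrt(diff(x)^2 + diff(y)^2)[consecutive])
  r <- cfg$arena_rect
  cx0 <- r[["x0"]] + r[["width"]] / 4
  cy0 <- r[["y0"]] + r[["height"]] / 4
  inner <- x >= cx0 & x <= cx0 + r[["width"]] / 2 &
    y >= cy0 & y <= cy0 + r[["height"]] / 2
  t_in <- sum(inner) / cfg$frame_rate
  t_out <- sum(!inner) / cfg$frame_rate
  tibble::tibble(
    total_distance_cm = dist_px / cfg$px_per_cm,
    center_time_s = t_in,
    periphery_time_s = t_out,
    center_periphery_ratio = if (t_out > 0) t_in / t_out else NA_real_
  )
}
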