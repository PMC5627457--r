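#' Summarise one session end to end
#'
#' Runs the full analytics chain for a single animal: gap correction,
#' bout/interval/transition extraction, binned investigation time, both
#' RDI variants, duration histograms, transition dynamics, phase summary,
#' and (when a tracking result is supplied) compartment occupancy and
#' open-field measures.
#'
#' @param series a raw or corrected [label_series()]; if raw, gap
#'   correction with `gap_merge_s` is applied first.
#' @param track optional tracking result from [track()] for the spatial
#'   metrics.
#' @param cfg optional `arena_config` (required with `track`); supplies
#'   `gap_merge_s` and `bin_width_s` defaults.
#' @param session_length_s session duration (s); defaults to the series
#'   length.
#' @param gap_merge_s,bin_width_s analysis parameters (defaults from
#'   `cfg`, else 0.5 s and 20 s).
#' @param bout_edges_s,interval_edges_s duration-category edges.
#' @param exploration_window,interaction_window phase windows (s).
#' @param prolonged_threshold_s threshold for the interval-based RDI (s).
#' @param label free-text session identifier.
#' @return a `session_summary` object: a list with per-stimulus totals,
#'   the event tables, every derived metric, and the parameters used.
#' @seealso [tidy.session_summary()], [glance.session_summary()],
#'   [pool_group()]
#' @export
session_summary <- function(series,
                            track = NULL,
                            cfg = NULL,
                            session_length_s = NULL,
                            gap_merge_s = NULL,
                            bin_width_s = NULL,
                            bout_edges_s = c(6, 12.5, 19),
                            interval_edges_s = c(10, 20),
                            exploration_window = c(0, 120),
                            interaction_window = NULL,
                            prolonged_threshold_s = 20,
                            label = "session") {
  stopifnot(inherits(series, "label_series"))
  gap_merge_s <- gap_merge_s %||% (if (!is.null(cfg)) cfg$gap_merge_s else 0.5)
  bin_width_s <- bin_width_s %||% (if (!is.null(cfg)) cfg$bin_width_s else 20)
  fr <- series_frame_rate(series)
  session_length_s <- session_length_s %||% (nrow(series) / fr)
  interaction_window <- interaction_window %||%
    c(exploration_window[2], session_length_s)
  stimuli <- series_stimuli(series)

  if (!is_corrected(series)) series <- correct_gaps(series, gap_merge_s)
  bouts <- extract_bouts(series)
  intervals <- extract_intervals(bouts, gap_merge_s)
  transitions <- extract_transitions(bouts)

  totals <- tibble::tibble(
    stimulus = stimuli,
    investigation_s = vapply(stimuli, function(s) {
      sum(bouts$duration_s[bouts$stimulus == s])
    }, numeric(1), USE.NAMES = FALSE)
  )
  binned <- binned_time(bouts, bin_width_s, session_length_s, stimuli = stimuli)
  dyn <- transition_dynamics(transitions, bin_width_s, session_length_s,
                             windows = list(exploration = exploration_window,
                                            interaction = interaction_window))
  spatial <- if (!is.null(track)) {
    stopifnot(!is.null(cfg))
    list(compartments = compartment_occupancy(track, cfg),
         open_field = open_field_metrics(track, cfg))
  } else {
    list(compartments = NULL, open_field = NULL)
  }

  structure(
    list(
      label = label,
      stimuli = stimuli,
      session_length_s = session_length_s,
      frame_rate = fr,
      params = list(gap_merge_s = gap_merge_s, bin_width_s = bin_width_s,
                    bout_edges_s = bout_edges_s,
                    interval_edges_s = interval_edges_s,
                    exploration_window = exploration_window,
                    interaction_window = interaction_window,
                    prolonged_threshold_s = prolonged_threshold_s),
      totals = totals,
      binned = binned,
      bouts = bouts,
      intervals = intervals,
      transitions = transitions,
      rdi_time = rdi(totals$investigation_s[1], totals$investigation_s[2]),
      rdi_intervals = rdi_by_intervals(intervals, prolonged_threshold_s,
                                       stimuli = stimuli),
      bout_histogram = bout_duration_histogram(bouts, bout_edges_s,
                                               stimuli = stimuli),
      interval_histogram = interval_duration_histogram(intervals,
                                                       interval_edges_s,
                                                       stimuli = stimuli),
      transitions_per_bin = dyn$per_bin,
      transitions_per_window = dyn$per_window,
      total_transitions = dyn$total,
      phases = phase_summary(bouts, transitions,
                             exploration_window, interaction_window,
                             bout_edges_s[1], bout_edges_s[length(bout_edges_s)],
                             bin_width_s),
      compartments = spatial$compartments,
      open_field = spatial$open_field
    ),
    class = "session_summary"
  )
}

#' @export
print.session_summary <- function(x, ...) {
  cat(sprintf("<session_summary> %s (%.0f s at %g fps)\n",
              x$label, x$session_length_s, x$frame_rate))
  t <- x$totals
  cat(sprintf("  investigation: %s\n",
              paste(sprintf("%s %.1f s", t$stimulus, t$investigation_s),
                    collapse = ", ")))
  cat(sprintf("  RDI (time) %.3f; RDI (prolonged intervals) %.3f\n",
              x$rdi_time, x$rdi_intervals))
  cat(sprintf("  bouts %d, intervals %d, transitions %d\n",
              nrow(x$bouts), nrow(x$intervals), x$total_transitions))
  if (!is.null(x$open_field)) {
    cat(sprintf("  distance %.1f cm; center/periphery %.3f\n",
                x$open_field$total_distance_cm,
                x$open_field$center_periphery_ratio))
  }
  invisible(x)
}

#' Tidy a session summary into one long tibble
#'
#' One row per (metric, stimulus, bin-or-category) combination, suitable
#' for export and for group-level statistics in any stats package.
#'
#' @param x a `session_summary`.
#' @param ... unused.
#' @return tibble with columns `session`, `metric`, `stimulus`, `index`,
#'   `value`.
#' @export
tidy.session_summary <- function(x, ...) {
  rows <- list(
    tibble::tibble(metric = "investigation_s", stimulus = x$totals$stimulus,
                   index = NA_character_, value = x$totals$investigation_s),
    tibble::tibble(metric = "binned_time_s", stimulus = x$binned$stimulus,
                   index = as.character(x$binned$bin_start_s),
                   value = x$binned$time_s),
    tibble::tibble(metric = "rdi_time", stimulus = NA_character_,
                   index = NA_character_, value = x$rdi_time),
    tibble::tibble(metric = "rdi_intervals", stimulus = NA_character_,
                   index = NA_character_, value = x$rdi_intervals),
    tibble::tibble(metric = "bout_time_s", stimulus = x$bout_histogram$stimulus,
                   index = as.character(x$bout_histogram$category),
                   value = x$bout_histogram$time_s),
    tibble::tibble(metric = "interval_time_s",
                   stimulus = x$interval_histogram$stimulus,
                   index = as.character(x$interval_histogram$category),
                   value = x$interval_histogram$time_s),
    tibble::tibble(metric = "interval_count",
                   stimulus = x$interval_histogram$stimulus,
                   index = as.character(x$interval_histogram$category),
                   value = as.numeric(x$interval_histogram$n)),
    tibble::tibble(metric = "transitions_per_bin", stimulus = NA_character_,
                   index = as.character(x$transitions_per_bin$bin_start_s),
                   value = as.numeric(x$transitions_per_bin$n)),
    tibble::tibble(metric = "transitions", stimulus = NA_character_,
                   index = x$transitions_per_window$window,
                   value = as.numeric(x$transitions_per_window$n)),
    tibble::tibble(metric = "total_transitions", stimulus = NA_character_,
                   index = NA_character_, value = as.numeric(x$total_transitions))
  )
  if (!is.null(x$compartments)) {
    rows <- c(rows, list(
      tibble::tibble(metric = "compartment_time_s",
                     stimulus = NA_character_,
                     index = x$compartments$region,
                     value = x$compartments$time_s)
    ))
  }
  if (!is.null(x$open_field)) {
    of <- x$open_field
    rows <- c(rows, list(
      tibble::tibble(metric = c("total_distance_cm", "center_periphery_ratio"),
                     stimulus = NA_character_, index = NA_character_,
                     value = c(of$total_distance_cm, of$center_periphery_ratio))
    ))
  }
  dplyr::bind_rows(rows) |>
    dplyr::mutate(session = x$label, .before = 1)
}

#' One-row overview of a session
#'
#' @param x a `session_summary`.
#' @param ... unused.
#' @return a one-row tibble with the headline per-session quantities.
#' @export
glance.session_summary <- function(x, ...) {
  t <- x$totals
  tibble::tibble(
    session = x$label,
    session_length_s = x$session_length_s,
    investigation_stim1_s = t$investigation_s[1],
    investigation_stim2_s = t$investigation_s[2],
    rdi_time = x$rdi_time,
    rdi_intervals = x$rdi_intervals,
    n_bouts = nrow(x$bouts),
    n_intervals = nrow(x$intervals),
    total_transitions = as.numeric(x$total_transitions),
    total_distance_cm = if (!is.null(x$open_field))
      x$open_field$total_distance_cm else NA_real_,
    center_periphery_ratio = if (!is.null(x$open_field))
      x$open_field$center_periphery_ratio else NA_real_
  )
}

#' Pool session summaries across animals
#'
#' Computes the group mean and SEM (sample SD / sqrt(n)) for every binned
#' and scalar metric, and Pearson correlations (with two-sided p values)
#' for requested across-subject scatter pairs such as transitions vs RDI.
#' Missing values are excluded pairwise.
#'
#' @param summaries list of `session_summary` objects with identical
#'   binning (>= 2).
#' @param pairs list of length-2 character vectors naming columns of the
#'   per-session [glance.session_summary()] table to correlate, e.g.
#'   `list(c("total_transitions", "rdi_time"))`.
#' @return a `group_summary`: list with `per_session` (glance rows),
#'   `binned` (mean/SEM per stimulus and bin), `scalars` (mean/SEM per
#'   metric), `correlations` (tibble `x`, `y`, `n`, `r`, `p`) and `n`.
#' @export
pool_group <- function(summaries,
                       pairs = list(c("total_transitions", "rdi_time"))) {
  if (length(summaries) < 2) {
    stop("input error: pooling needs at least 2 session summaries", call. = FALSE)
  }
  ok <- vapply(summaries, inherits, logical(1), "session_summary")
  if (!all(ok)) stop("input error: all elements must be session summaries",
                     call. = FALSE)
  key <- function(s) paste(s$params$bin_width_s, s$session_length_s,
                           paste(s$stimuli, collapse = "|"))
  if (length(unique(vapply(summaries, key, character(1)))) != 1) {
    stop("input error: sessions have inconsistent binning or stimuli",
         call. = FALSE)
  }
  sem <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2) return(NA_real_)
    stats::sd(v) / sqrt(length(v))
  }
  long <- purrr::map_dfr(summaries, tidy)
  binned <- long |>
    dplyr::filter(.data$metric %in% c("binned_time_s", "transitions_per_bin")) |>
    dplyr::group_by(.data$metric, .data$stimulus, .data$index) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sem = sem(.data$value), .groups = "drop") |>
    dplyr::mutate(bin_start_s = as.numeric(.data$index)) |>
    dplyr::arrange(.data$metric, .data$stimulus, .data$bin_start_s)
  scalars <- long |>
    dplyr::filter(!.data$metric %in% c("binned_time_s", "transitions_per_bin")) |>
    dplyr::group_by(.data$metric, .data$stimulus, .data$index) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sem = sem(.data$value), .groups = "drop")
  per_session <- purrr::map_dfr(summaries, glance)
  correlations <- purrr::map_dfr(pairs, function(p) {
    xv <- per_session[[p[1]]]
    yv <- per_session[[p[2]]]
    keep <- is.finite(xv) & is.finite(yv)
    if (sum(keep) < 3) {
      return(tibble::tibble(x = p[1], y = p[2], n = sum(keep),
                            r = NA_real_, p = NA_real_))
    }
    ct <- stats::cor.test(xv[keep], yv[keep], method = "pearson")
    tibble::tibble(x = p[1], y = p[2], n = sum(keep),
                   r = unname(ct$estimate), p = ct$p.value)
  })
  structure(
    list(n = length(summaries), per_session = per_session, binned = binned,
         scalars = scalars, correlations = correlations),
    class = "group_summary"
  )
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> n = %d sessions\n", x$n))
  rt <- x$scalars[x$scalars$metric == "rdi_time", ]
  if (nrow(rt) == 1) {
    cat(sprintf("  mean RDI (time) %.3f +/- %.3f SEM\n", rt$mean, rt$sem))
  }
  tt <- x$scalars[x$scalars$metric == "total_transitions", ]
  if (nrow(tt) == 1) {
    cat(sprintf("  mean transitions %.1f +/- %.1f SEM\n", tt$mean, tt$sem))
  }
  if (nrow(x$correlations) > 0) {
    for (i in seq_len(nrow(x$correlations))) {
      cr <- x$correlations[i, ]
      cat(sprintf("  r(%s, %s) = %.2f (p = %.3g, n = %d)\n",
                  cr$x, cr$y, cr$r, cr$p, cr$n))
    }
  }
  invisible(x)
}

#' @export
tidy.group_summary <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::select(x$binned, "metric", "stimulus", "index", "mean", "sem"),
    x$scalars
  )
}

#' @export
glance.group_summary <- function(x, ...) {
  g <- function(m) {
    row <- x$scalars[x$scalars$metric == m & is.na(x$scalars$stimulus), ]
    if (nrow(row) >= 1) row$mean[1] else NA_real_
  }
  tibble::tibble(
    n = x$n,
    mean_rdi_time = g("rdi_time"),
    mean_rdi_intervals = g("rdi_intervals"),
    mean_total_transitions = g("total_transitions")
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
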