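# Seeded generative model of two-chamber investigation behavior.
# Sessions alternate roam and investigate segments with exponential
# durations; the segment rates change once at the phase boundary,
# emulating the early exploration phase (many transitions, short bouts)
# and the later interaction phase (few transitions, long bouts).

#' Parameters of the behavior simulator
#'
#' Durations are exponential with the given means; all defaults emulate a
#' 5-min two-chamber test with a 2-min exploration phase (short bouts,
#' frequent switching) followed by a 3-min interaction phase (long bouts,
#' rare switching).
#'
#' @param session_length_s session duration (default 300 s).
#' @param phase_boundary_s when the rates switch (default 120 s).
#' @param explore_bout_s,interact_bout_s mean investigation-bout duration
#'   per phase; length 1 or 2 (per stimulus: stim1, stim2).
#' @param explore_roam_s,interact_roam_s mean roam (non-investigation)
#'   duration per phase.
#' @param explore_switch,interact_switch transition propensity per phase:
#'   the probability that the next bout's stimulus is chosen afresh rather
#'   than repeating the last one.
#' @param preference p in \[0, 1\]: probability that a fresh choice
#'   targets stim1.
#' @param recognition_difficulty in \[0, 1\]: jointly raises the
#'   transition propensity toward 1 and pulls the preference toward 0.5,
#'   emulating a subject that struggles to discriminate the stimuli (an
#'   SNP-style difficulty knob).
#' @param seed RNG seed for [simulate_behavior()].
#' @return a `behavior_params` list.
#' @export
behavior_params <- function(session_length_s = 300,
                            phase_boundary_s = 120,
                            explore_bout_s = 2.5,
                            interact_bout_s = 8,
                            explore_roam_s = 3,
                            interact_roam_s = 4.5,
                            explore_switch = 0.95,
                            interact_switch = 0.6,
                            preference = 0.75,
                            recognition_difficulty = 0,
                            seed = 1L) {
  p <- list(
    session_length_s = session_length_s,
    phase_boundary_s = phase_boundary_s,
    explore_bout_s = rep_len(explore_bout_s, 2),
    interact_bout_s = rep_len(interact_bout_s, 2),
    explore_roam_s = explore_roam_s,
    interact_roam_s = interact_roam_s,
    explore_switch = explore_switch,
    interact_switch = interact_switch,
    preference = preference,
    recognition_difficulty = recognition_difficulty,
    seed = as.integer(seed)
  )
  dur <- c(p$explore_bout_s, p$interact_bout_s, p$explore_roam_s,
           p$interact_roam_s, p$session_length_s)
  if (any(dur <= 0)) stop("config error: all durations must be > 0", call. = FALSE)
  pr <- c(p$explore_switch, p$interact_switch, p$preference,
          p$recognition_difficulty)
  if (any(pr < 0 | pr > 1)) {
    stop("config error: probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(p, class = "behavior_params")
}

# evaluate/restore RNG state around seeded code
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate a behavior script
#'
#' Draws alternating roam/investigate segments until the session is
#' filled. Each investigate segment's stimulus is chosen afresh with the
#' phase's transition propensity (Bernoulli(preference) for stim1) and
#' otherwise repeats the previous stimulus; segment durations are
#' exponential with the phase's means. Reproducible given the seed.
#'
#' @param params a [behavior_params()].
#' @return a `behavior_script`: tibble with columns `state` (`"roam"`,
#'   `"investigate"`), `stimulus` (`NA` for roam), `start_s`, `end_s`,
#'   tiling `[0, session_length_s)`.
#' @export
simulate_behavior <- function(params = behavior_params()) {
  stopifnot(inherits(params, "behavior_params"))
  d <- params$recognition_difficulty
  adj_switch <- function(s) s + d * (1 - s)
  adj_pref <- params$preference + d * (0.5 - params$preference)
  local_seed(params$seed, {
    t <- 0
    cur_stim <- NA_character_
    rows <- list()
    while (t < params$session_length_s) {
      explore <- t < params$phase_boundary_s
      roam_mean <- if (explore) params$explore_roam_s else params$interact_roam_s
      bout_mean <- if (explore) params$explore_bout_s else params$interact_bout_s
      switch_p <- adj_switch(if (explore) params$explore_switch else
        params$interact_switch)

      roam_d <- stats::rexp(1, 1 / roam_mean)
      t_roam_end <- min(t + roam_d, params$session_length_s)
      rows[[length(rows) + 1L]] <- list(state = "roam",
                                        stimulus = NA_character_,
                                        start_s = t, end_s = t_roam_end)
      t <- t_roam_end
      if (t >= params$session_length_s) break

      fresh <- is.na(cur_stim) || stats::runif(1) < switch_p
      if (fresh) {
        cur_stim <- if (stats::runif(1) < adj_pref) "stim1" else "stim2"
      }
      k <- if (cur_stim == "stim1") 1L else 2L
      bout_d <- stats::rexp(1, 1 / bout_mean[k])
      t_bout_end <- min(t + bout_d, params$session_length_s)
      rows[[length(rows) + 1L]] <- list(state = "investigate",
                                        stimulus = cur_stim,
                                        start_s = t, end_s = t_bout_end)
      t <- t_bout_end
    }
    out <- dplyr::bind_rows(rows)
    structure(out, params = params,
              class = c("behavior_script", class(out)))
  })
}

#' Quantize a behavior script to per-frame labels and ground-truth events
#'
#' Frame i (0-based) takes the label of the segment containing time
#' `i / frame_rate`. Ground-truth bouts are the maximal runs of
#' stimulus-labelled frames in the quantized series (no gap merging),
#' ground-truth transitions the starts of runs whose stimulus differs from
#' the previous stimulus run. These are the oracles the event-extraction
#' tests compare against.
#'
#' @param script a `behavior_script` (or any tibble with `state`,
#'   `stimulus`, `start_s`, `end_s` tiling the session).
#' @param frame_rate frames per second.
#' @param corrected mark the returned series as gap-corrected (the
#'   quantized script contains no spurious sub-gap interruptions to merge,
#'   so `TRUE` lets [extract_bouts()] run on it directly).
#' @return list with `series` (a [label_series()]), `bouts`,
#'   `transitions` (ground-truth tibbles in the events-module schemas).
#' @export
script_to_labels <- function(script, frame_rate = 30, corrected = TRUE) {
  session_length_s <- max(script$end_s)
  n <- round(session_length_s * frame_rate)
  t <- (seq_len(n) - 1L) / frame_rate
  idx <- findInterval(t, script$start_s)
  lab <- ifelse(script$state[idx] == "investigate", script$stimulus[idx],
                "none")
  series <- label_series(lab, frame_rate, corrected = corrected)

  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != "none"
  bouts <- tibble::tibble(
    stimulus = r$values[keep],
    start_s = (starts[keep] - 1L) / frame_rate,
    end_s = ends[keep] / frame_rate,
    duration_s = r$lengths[keep] / frame_rate
  )
  stim_seq <- bouts$stimulus
  chg <- which(stim_seq[-1] != stim_seq[-length(stim_seq)])
  transitions <- tibble::tibble(
    time_s = bouts$start_s[chg + 1L],
    from = stim_seq[chg],
    to = stim_seq[chg + 1L]
  )
  list(series = series, bouts = bouts, transitions = transitions)
}
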