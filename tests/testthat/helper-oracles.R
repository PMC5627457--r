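# Independent brute-force oracles for the event-extraction chain.
# Deliberately written as naive frame-by-frame loops, sharing no code
# with the package implementation.

# gap correction: relabel every gap of frames != k that is strictly
# shorter than gap_s, flanked by k on both sides, and free of the other
# stimulus
oracle_correct_gaps <- function(labels, frame_rate, gap_s = 0.5,
                                stimuli = c("stim1", "stim2")) {
  out <- labels
  n <- length(labels)
  for (k in stimuli) {
    other <- setdiff(stimuli, k)
    i <- 1L
    while (i <= n) {
      if (out[i] != k) { i <- i + 1L; next }
      # find end of this k-run
      j <- i
      while (j < n && out[j + 1L] == k) j <- j + 1L
      # gap after the run
      g0 <- j + 1L
      g1 <- g0
      while (g1 <= n && out[g1] != k) g1 <- g1 + 1L
      # g1 is the next k frame (or n+1)
      if (g1 <= n && g0 <= n && g1 > g0) {
        gap_len <- g1 - g0
        gap <- labels[g0:(g1 - 1L)]
        if (gap_len / frame_rate < gap_s && !any(gap %in% other)) {
          out[g0:(g1 - 1L)] <- k
        }
      }
      i <- max(j + 1L, g0)
    }
  }
  out
}

# bouts as maximal runs of stimulus frames, scanned frame by frame
oracle_bouts <- function(labels, frame_rate,
                         stimuli = c("stim1", "stim2")) {
  rows <- list()
  n <- length(labels)
  i <- 1L
  while (i <= n) {
    if (labels[i] %in% stimuli) {
      j <- i
      while (j < n && labels[j + 1L] == labels[i]) j <- j + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        stimulus = labels[i],
        start_s = (i - 1L) / frame_rate,
        end_s = j / frame_rate,
        duration_s = (j - i + 1L) / frame_rate
      )
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(rows) == 0) {
    return(data.frame(stimulus = character(), start_s = numeric(),
                      end_s = numeric(), duration_s = numeric()))
  }
  do.call(rbind, rows)
}

# transition count = number of changes in the bout-stimulus sequence
oracle_transitions <- function(bout_stimuli) {
  if (length(bout_stimuli) < 2) return(0L)
  sum(bout_stimuli[-1] != bout_stimuli[-length(bout_stimuli)])
}

# same-stimulus gaps longer than gap_s, by explicit pairwise scan
oracle_intervals <- function(bouts, gap_s = 0.5) {
  rows <- list()
  for (k in unique(bouts$stimulus)) {
    b <- bouts[bouts$stimulus == k, ]
    b <- b[order(b$start_s), ]
    if (nrow(b) < 2) next
    for (i in seq_len(nrow(b) - 1L)) {
      span <- b$start_s[i + 1L] - b$end_s[i]
      if (span > gap_s) {
        rows[[length(rows) + 1L]] <- data.frame(
          stimulus = k, start_s = b$end_s[i], end_s = b$start_s[i + 1L],
          duration_s = span
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(stimulus = character(), start_s = numeric(),
                      end_s = numeric(), duration_s = numeric()))
  }
  out <- do.call(rbind, rows)
  out[order(out$start_s), ]
}

# random label series with run-structured labels (mixed lengths)
random_labels <- function(n_frames, mean_run = 10) {
  labs <- character(0)
  while (length(labs) < n_frames) {
    state <- sample(c("none", "stim1", "stim2"), 1,
                    prob = c(0.5, 0.25, 0.25))
    len <- 1L + stats::rgeom(1, 1 / mean_run)
    labs <- c(labs, rep(state, len))
  }
  labs[seq_len(n_frames)]
}

# random bout sets on [0, session_s) for conservation checks
random_bouts <- function(session_s = 300, n_max = 30) {
  n <- sample.int(n_max, 1)
  edges <- sort(stats::runif(2 * n, 0, session_s))
  starts <- edges[seq(1, 2 * n, by = 2)]
  ends <- edges[seq(2, 2 * n, by = 2)]
  keep <- ends > starts
  tibble::tibble(
    stimulus = sample(c("stim1", "stim2"), sum(keep), replace = TRUE),
    start_s = starts[keep], end_s = ends[keep],
    duration_s = ends[keep] - starts[keep]
  )
}
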