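test_that("binned time apportions bouts by exact overlap and conserves totals", {
  b <- tibble::tibble(stimulus = "stim1", start_s = 25, end_s = 45,
                      duration_s = 20)
  bt <- binned_time(b, 20, 300)
  expect_equal(bt$time_s[bt$bin_start_s == 20], 15)
  expect_equal(bt$time_s[bt$bin_start_s == 40], 5)
  expect_equal(sum(bt$time_s), 20)
  # no bouts: all-zero series over the full session
  bt0 <- binned_time(b[0, ], 20, 300, stimuli = c("stim1", "stim2"))
  expect_equal(nrow(bt0), 2 * 15)
  expect_true(all(bt0$time_s == 0))
  # conservation over random bout sets
  set.seed(201)
  for (i in 1:100) {
    rb <- random_bouts(300)
    bt <- binned_time(rb, 20, 300)
    for (k in unique(rb$stimulus)) {
      expect_equal(sum(bt$time_s[bt$stimulus == k]),
                   sum(rb$duration_s[rb$stimulus == k]), tolerance = 1e-9)
    }
  }
})

test_that("RDI has its closed-form values, symmetry, and domain guards", {
  expect_equal(rdi(10, 10), 0)
  expect_equal(rdi(10, 0), 1)
  expect_equal(rdi(3, 1), 0.5)
  expect_equal(rdi(1, 3), -0.5)
  expect_equal(rdi(1, 3, signed = FALSE), 0.5)
  expect_true(is.na(rdi(0, 0)))
  expect_error(rdi(-1, 2), "domain error")
  # signed antisymmetry and unsigned symmetry on random pairs
  set.seed(202)
  a <- runif(50, 0, 100); b <- runif(50, 0, 100)
  expect_equal(rdi(a, b), -rdi(b, a))
  expect_equal(rdi(a, b, signed = FALSE), rdi(b, a, signed = FALSE))
  expect_true(all(abs(rdi(a, b)) <= 1))
})

test_that("interval-based RDI uses prolonged-interval totals", {
  iv <- tibble::tibble(stimulus = c("stim1", "stim2"),
                       start_s = c(0, 0), end_s = c(30, 10),
                       duration_s = c(30, 10))
  # both intervals exceed 20 s? only stim1's does at the default threshold
  expect_equal(rdi_by_intervals(iv, prolonged_threshold_s = 5), 0.5)
  expect_true(is.na(rdi_by_intervals(iv, prolonged_threshold_s = 50)))
})

test_that("bout-duration categories use closed-at-6 / open-at-19 boundaries", {
  b <- tibble::tibble(stimulus = "stim1",
                      start_s = 0, end_s = 1,
                      duration_s = c(6, 19.5, 19, 3, 12))
  h <- bout_duration_histogram(b)
  expect_equal(h$n[h$category == "<=6s"], 2L)      # 6.0 and 3
  expect_equal(h$n[h$category == ">19s"], 1L)      # 19.5 only: 19 is middle
  expect_equal(h$n[h$category == "(12.5,19]s"], 1L)
  expect_equal(sum(h$time_s), sum(b$duration_s))
  expect_error(bout_duration_histogram(b, edges_s = c(10, 5)),
               "config error")
  # conservation on random bout sets
  set.seed(203)
  for (i in 1:100) {
    rb <- random_bouts(300)
    h <- bout_duration_histogram(rb)
    for (k in unique(rb$stimulus)) {
      expect_equal(sum(h$time_s[h$stimulus == k]),
                   sum(rb$duration_s[rb$stimulus == k]), tolerance = 1e-9)
    }
  }
})

test_that("interval-duration categories partition counts and times", {
  iv <- tibble::tibble(stimulus = "stim1", start_s = 0, end_s = 1,
                       duration_s = c(5, 25, 15))
  h <- interval_duration_histogram(iv)
  expect_equal(h$n[h$category == "<=10s"], 1L)
  expect_equal(h$n[h$category == ">20s"], 1L)
  expect_equal(sum(h$n), 3L)
  expect_equal(sum(h$time_s), 45)
})

test_that("transition dynamics bins counts and window totals consistently", {
  tr <- tibble::tibble(time_s = c(10, 30, 50), from = "stim1", to = "stim2")
  dyn <- transition_dynamics(tr, 20, 300)
  expect_equal(dyn$per_bin$n[1:4], c(1L, 1L, 1L, 0L))
  expect_equal(dyn$total, 3)
  # windows that partition the session account for every transition
  dyn2 <- transition_dynamics(tr, 20, 300,
                              windows = list(a = c(0, 120), b = c(120, 300)))
  expect_equal(sum(dyn2$per_window$n), dyn2$total)
  dyn0 <- transition_dynamics(tr[0, ], 20, 300)
  expect_true(all(dyn0$per_bin$n == 0))
})

test_that("phase summaries partition bout time by window and duration class", {
  b <- tibble::tibble(
    stimulus = c("stim1", "stim1", "stim2", "stim1"),
    start_s = c(10, 50, 130, 200),
    end_s = c(14, 75, 135, 203),
    duration_s = c(4, 25, 5, 3)
  )
  tr <- extract_transitions(b)
  ps <- phase_summary(b, tr)
  expl1 <- ps[ps$phase == "exploration" & ps$stimulus == "stim1", ]
  # the 25-s bout starting at 50 s belongs to exploration by start time
  expect_equal(expl1$long_bout_s, 25)
  expect_equal(expl1$short_bout_s, 4)
  inter <- ps[ps$phase == "interaction", ]
  expect_equal(sum(inter$total_bout_s), 8)
  # short + middle + long always equals the window total
  expect_equal(ps$short_bout_s + ps$middle_bout_s + ps$long_bout_s,
               ps$total_bout_s)
  # bouts all in exploration leave interaction empty
  b2 <- b[b$start_s < 120, ]
  ps2 <- phase_summary(b2, extract_transitions(b2))
  expect_true(all(ps2$total_bout_s[ps2$phase == "interaction"] == 0))
  expect_error(phase_summary(b, tr, exploration_window = c(0, 200),
                             interaction_window = c(100, 300)),
               "config error")
})

test_that("open-field metrics: distance, center region, degenerate ratio", {
  cfg <- std_cfg()
  r <- cfg$arena_rect
  center <- c(r[["x0"]] + r[["width"]] / 2, r[["y0"]] + r[["height"]] / 2)
  # stationary: zero distance; always in center: ratio undefined
  tr <- tibble::tibble(frame = 0:89, valid = TRUE,
                       cx_px = center[1], cy_px = center[2])
  of <- open_field_metrics(tr, cfg)
  expect_equal(of$total_distance_cm, 0)
  expect_equal(of$periphery_time_s, 0)
  expect_true(is.na(of$center_periphery_ratio))
  # a known straight path in pixels converts exactly to cm
  n <- 101
  tr <- tibble::tibble(frame = seq_len(n) - 1L, valid = TRUE,
                       cx_px = seq(r[["x0"]] + 10, r[["x0"]] + 10 + 200,
                                   length.out = n),
                       cy_px = center[2])
  of <- open_field_metrics(tr, cfg)
  expect_equal(of$total_distance_cm, 200 / cfg$px_per_cm, tolerance = 1e-9)
  # steps spanning invalid frames are skipped
  tr$valid[51] <- FALSE
  of2 <- open_field_metrics(tr, cfg)
  expect_lt(of2$total_distance_cm, of$total_distance_cm)
})

test_that("group pooling computes means, SEMs and Pearson correlations", {
  mk <- function(seed) {
    gt <- script_to_labels(simulate_behavior(behavior_params(seed = seed)), 30)
    session_summary(gt$series, label = paste0("s", seed))
  }
  s1 <- mk(1)
  g <- pool_group(list(s1, s1))
  expect_equal(g$n, 2)
  expect_true(all(g$binned$sem == 0))            # identical sessions
  expect_true(all(g$scalars$sem[is.finite(g$scalars$sem)] == 0))
  # perfectly linear pairs give r = 1
  g3 <- pool_group(list(mk(2), mk(3), mk(4), mk(5)),
                   pairs = list(c("n_bouts", "n_bouts")))
  expect_equal(g3$correlations$r, 1)
  # Pearson r on a 5-point set matches the closed form
  x <- c(1, 2, 4, 5, 7); y <- c(2, 1, 5, 4, 9)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  ps <- purrr::map(1:5, mk)
  for (i in 1:5) {
    ps[[i]]$total_transitions <- x[i]
    ps[[i]]$rdi_time <- y[i]
  }
  g5 <- pool_group(ps, pairs = list(c("total_transitions", "rdi_time")))
  expect_equal(g5$correlations$r, r_hand, tolerance = 1e-12)
  # fewer than 2 sessions or inconsistent binning are input errors
  expect_error(pool_group(list(s1)), "input error")
  s_short <- session_summary(
    script_to_labels(simulate_behavior(
      behavior_params(session_length_s = 100, seed = 9)), 30)$series
  )
  expect_error(pool_group(list(s1, s_short)), "input error")
})

test_that("session summaries respect their internal conservation laws", {
  gt <- script_to_labels(simulate_behavior(behavior_params(seed = 77)), 30)
  s <- session_summary(gt$series)
  for (k in s$stimuli) {
    tot <- s$totals$investigation_s[s$totals$stimulus == k]
    expect_equal(sum(s$binned$time_s[s$binned$stimulus == k]), tot,
                 tolerance = 1e-9)
    expect_equal(sum(s$bout_histogram$time_s[s$bout_histogram$stimulus == k]),
                 tot, tolerance = 1e-9)
  }
  expect_true(abs(s$rdi_time) <= 1)
  expect_equal(nrow(s$transitions), s$total_transitions)
  # tidy/glance expose the same headline numbers
  td <- tidy(s)
  expect_equal(td$value[td$metric == "rdi_time"], s$rdi_time)
  gl <- glance(s)
  expect_equal(gl$total_transitions, as.numeric(s$total_transitions))
})

test_that("difficulty knob induces the transitions-vs-RDI anticorrelation", {
  # difficulty grid at otherwise default parameters: transitions rise while
  # |RDI| falls, so across subjects the correlation is clearly negative
  ds <- seq(0, 0.95, length.out = 45)
  v <- t(mapply(function(d, k) {
    gt <- script_to_labels(simulate_behavior(behavior_params(
      recognition_difficulty = d, seed = 923 + 7000 + k
    )), 30)
    b <- gt$bouts
    c(nrow(extract_transitions(b)),
      rdi(sum(b$duration_s[b$stimulus == "stim1"]),
          sum(b$duration_s[b$stimulus == "stim2"]), signed = FALSE))
  }, ds, seq_along(ds)))
  expect_lt(cor(v[, 1], v[, 2]), -0.2)
})
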