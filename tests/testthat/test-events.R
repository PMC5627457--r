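ls30 <- function(labels, corrected = FALSE) {
  label_series(labels, 30, corrected = corrected)
}

test_that("gap correction merges sub-half-second gaps and respects the strict boundary", {
  # 14 frames at 30 fps (< 0.5 s) merges into one run
  s <- ls30(c(rep("stim1", 30), rep("none", 14), rep("stim1", 30)))
  b <- extract_bouts(correct_gaps(s))
  expect_equal(nrow(b), 1)
  expect_equal(b$duration_s, 74 / 30)
  # 15 frames (exactly 0.5 s) does not merge: strict inequality
  s <- ls30(c(rep("stim1", 30), rep("none", 15), rep("stim1", 30)))
  b <- extract_bouts(correct_gaps(s))
  expect_equal(nrow(b), 2)
  # a gap containing the other stimulus is never merged
  s <- ls30(c(rep("stim1", 30), rep("stim2", 5), rep("stim1", 30)))
  b <- extract_bouts(correct_gaps(s))
  expect_equal(b$stimulus, c("stim1", "stim2", "stim1"))
  # ... unless explicitly requested
  b2 <- extract_bouts(correct_gaps(s, merge_across_other = TRUE))
  expect_equal(b2$stimulus, "stim1")
})

test_that("gap correction matches the brute-force oracle on random series", {
  set.seed(101)
  for (i in 1:300) {
    labs <- random_labels(sample(c(60, 150, 400), 1), mean_run = 8)
    got <- correct_gaps(ls30(labs))$label
    expect_identical(got, oracle_correct_gaps(labs, 30))
  }
})

test_that("gap correction is idempotent and monotone in the merge window", {
  set.seed(102)
  for (i in 1:50) {
    labs <- random_labels(300, mean_run = 6)
    once <- correct_gaps(ls30(labs))
    expect_identical(correct_gaps(once)$label, once$label)
    # larger windows never lose investigation time nor add bouts
    small <- extract_bouts(correct_gaps(ls30(labs), gap_merge_s = 0.3))
    large <- extract_bouts(correct_gaps(ls30(labs), gap_merge_s = 1.0))
    for (k in c("stim1", "stim2")) {
      expect_gte(sum(large$duration_s[large$stimulus == k]),
                 sum(small$duration_s[small$stimulus == k]))
    }
    expect_lte(nrow(large), nrow(small))
  }
})

test_that("bout extraction is exact run-length decoding with time conservation", {
  expect_equal(nrow(extract_bouts(ls30(rep("none", 50), corrected = TRUE))), 0)
  b <- extract_bouts(ls30(
    c(rep("none", 10), rep("stim1", 60), rep("none", 10), rep("stim2", 30)),
    corrected = TRUE
  ))
  expect_equal(b$stimulus, c("stim1", "stim2"))
  expect_equal(b$duration_s, c(2, 1))
  expect_equal(b$start_s, c(10 / 30, 80 / 30))
  # oracle equivalence + conservation on random series
  set.seed(103)
  for (i in 1:200) {
    labs <- random_labels(sample(c(50, 200, 600), 1))
    b <- extract_bouts(ls30(labs, corrected = TRUE))
    o <- oracle_bouts(labs, 30)
    expect_equal(as.data.frame(b), o, ignore_attr = TRUE)
    for (k in c("stim1", "stim2")) {
      expect_equal(sum(b$duration_s[b$stimulus == k]),
                   sum(labs == k) / 30, tolerance = 1e-12)
    }
  }
  # extraction requires a corrected series
  expect_error(extract_bouts(ls30(rep("stim1", 10))), "corrected")
})

test_that("intervals are same-stimulus gaps above the merge window", {
  b <- tibble::tibble(stimulus = c("stim1", "stim1"),
                      start_s = c(0, 3), end_s = c(2, 4),
                      duration_s = c(2, 1))
  iv <- extract_intervals(b)
  expect_equal(iv$duration_s, 1)
  expect_equal(iv$stimulus, "stim1")
  # an interval may span a bout of the other stimulus
  b <- tibble::tibble(stimulus = c("stim1", "stim2", "stim1"),
                      start_s = c(0, 2.1, 6), end_s = c(2, 5, 7),
                      duration_s = c(2, 2.9, 1))
  iv <- extract_intervals(b)
  expect_equal(iv[iv$stimulus == "stim1", ]$duration_s, 4)
  # ... unless spanning is disallowed
  iv2 <- extract_intervals(b, allow_spanning = FALSE)
  expect_equal(nrow(iv2[iv2$stimulus == "stim1", ]), 0)
  # one bout per stimulus yields no intervals
  b <- tibble::tibble(stimulus = c("stim1", "stim2"),
                      start_s = c(0, 5), end_s = c(2, 6),
                      duration_s = c(2, 1))
  expect_equal(nrow(extract_intervals(b)), 0)
})

test_that("transitions are stimulus changes in the bout sequence", {
  mkb <- function(stims) {
    n <- length(stims)
    tibble::tibble(stimulus = stims, start_s = seq_len(n) * 10,
                   end_s = seq_len(n) * 10 + 5, duration_s = 5)
  }
  expect_equal(nrow(extract_transitions(mkb("stim1"))), 0)
  tr <- extract_transitions(mkb(c("stim1", "stim2", "stim2", "stim1")))
  expect_equal(nrow(tr), 2)
  expect_equal(tr$time_s, c(20, 40))
  expect_equal(tr$from, c("stim1", "stim2"))
  expect_equal(nrow(extract_transitions(mkb(c("stim1", "stim1", "stim1")))), 0)
})

test_that("event extraction matches oracles end to end on random series", {
  set.seed(104)
  for (i in 1:200) {
    labs <- oracle_correct_gaps(random_labels(sample(c(80, 300), 1)), 30)
    b <- extract_bouts(ls30(labs, corrected = TRUE))
    expect_equal(nrow(extract_transitions(b)),
                 oracle_transitions(b$stimulus))
    expect_equal(as.data.frame(extract_intervals(b)),
                 oracle_intervals(as.data.frame(b)), ignore_attr = TRUE)
  }
})

test_that("compartment occupancy assigns centroids by polygon and conserves time", {
  cfg <- std_cfg()
  n <- 90
  # a fixed centroid inside compartment 1
  c1 <- colMeans(cfg$compartments[[1]])
  tr <- tibble::tibble(frame = seq_len(n) - 1L, valid = TRUE,
                       cx_px = c1[1], cy_px = c1[2])
  occ <- compartment_occupancy(tr, cfg)
  expect_equal(occ$time_s[occ$region == "compartment1"], n / 30)
  expect_equal(occ$time_s[occ$region == "compartment2"], 0)
  # alternating halves split time evenly
  c2 <- colMeans(cfg$compartments[[2]])
  tr <- tibble::tibble(frame = seq_len(n) - 1L, valid = TRUE,
                       cx_px = rep(c(c1[1], c2[1]), length.out = n),
                       cy_px = rep(c(c1[2], c2[2]), length.out = n))
  occ <- compartment_occupancy(tr, cfg)
  expect_equal(occ$time_s[occ$region == "compartment1"],
               occ$time_s[occ$region == "compartment2"])
  expect_equal(sum(occ$time_s), n / 30)
  # invalid frames count as unassigned but total time is conserved
  tr$valid[1:30] <- FALSE
  occ <- compartment_occupancy(tr, cfg)
  expect_equal(occ$time_s[occ$region == "none"], 1)
  expect_equal(sum(occ$time_s), n / 30)
})
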