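# Shared rendered fixtures, built once per test run and memoized.
# Everything is generated in code at test time; nothing binary ships in
# the repository.

.fixture_cache <- new.env(parent = emptyenv())

memoize <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

std_cfg <- function() default_arena_config(320, 240)

# 20-s rendered session used by most tracker tests
short_session <- function() {
  memoize("short_session", function() {
    cfg <- std_cfg()
    script <- simulate_behavior(behavior_params(
      session_length_s = 20, phase_boundary_s = 8, seed = 11
    ))
    rv <- render_video(script, cfg, render_params(seed = 11))
    list(cfg = cfg, script = script, video = rv)
  })
}

# 60-s scripted sessions for the label-recovery acceptance check;
# written to disk so only one video's frames are in memory at a time
acceptance_sessions <- function() {
  memoize("acceptance_sessions", function() {
    cfg <- std_cfg()
    lapply(c(21L, 22L), function(seed) {
      script <- simulate_behavior(behavior_params(
        session_length_s = 60, phase_boundary_s = 25, seed = seed
      ))
      path <- tempfile(sprintf("acc%d_", seed), fileext = ".tif")
      rv <- render_video(script, cfg, render_params(seed = seed),
                         path = path)
      truth <- rv$truth
      rm(rv); gc(verbose = FALSE)
      list(script = script, path = path, truth = truth, seed = seed)
    })
  })
}

# matched wired / unwired 20-s renders of the same script
wired_pair <- function() {
  memoize("wired_pair", function() {
    cfg <- std_cfg()
    script <- simulate_behavior(behavior_params(
      session_length_s = 20, phase_boundary_s = 8, seed = 31
    ))
    free <- render_video(script, cfg, render_params(seed = 31))
    wired <- render_video(script, cfg, render_params(
      seed = 31, cable_anchor = c(160, 4)
    ))
    list(cfg = cfg, script = script, free = free, wired = wired)
  })
}

# tail-only-contact scenario render (10 s, 3 s of tail contact)
tail_scenario <- function() {
  memoize("tail_scenario", function() {
    cfg <- std_cfg()
    rp <- render_params(seed = 41)
    poses <- scenario_tail_contact(cfg, rp, duration_s = 10, contact_s = 3)
    rv <- render_video(poses, cfg, rp)
    list(cfg = cfg, poses = poses, video = rv)
  })
}
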