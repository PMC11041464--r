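test_that("the threshold follows the closed-form decay law on a stream
           that never fires, and fires at the floor", {
  th0 <- 0.660
  cfg <- trigger_config(th0)
  state <- new_trigger_state(cfg)
  fired_at <- NA
  for (t in 1:60) {
    res <- trigger_step(state, 0, cfg)
    state <- res$state
    if (!is.null(res$event)) {
      fired_at <- t
      expect_equal(res$event$threshold_at_stim, 0)
      break
    }
    expect_equal(state$current_threshold,
                 max(0, th0 - 0.05 * max(0, t - 30)))
    if (t <= 30) expect_equal(state$current_threshold, th0)
  }
  # first tick at which the decayed threshold reaches the floor:
  # th0 - 0.05 (t - 30) <= 0  <=>  t >= 30 + th0 / 0.05
  expect_identical(fired_at, as.integer(ceiling(30 + th0 / 0.05)))
})

test_that("maximal coherence always fires and resets the threshold", {
  cfg <- trigger_config(0.9)
  state <- new_trigger_state(cfg)
  state$current_threshold <- 0.4       # mid-decay
  state$seconds_since_last_stimulus <- 45
  res <- trigger_step(state, 1.0, cfg)
  expect_false(is.null(res$event))
  expect_true(res$event$modified)
  expect_equal(res$state$current_threshold, 0.9)
  expect_equal(res$state$seconds_since_last_stimulus, 0)
  expect_identical(res$state$phase, "paused")
})

test_that("stepping while paused and out-of-range coherence are contract
           violations", {
  cfg <- trigger_config(0.5)
  state <- new_trigger_state(cfg)
  expect_error(trigger_step(state, 1.5, cfg), "\\[0, 1\\]")
  state$phase <- "paused"
  expect_error(trigger_step(state, 0.5, cfg), "paused")
})

test_that("config invariants are enforced", {
  expect_error(trigger_config(0.5, delta = -0.1), "delta")
  expect_error(trigger_config(0.5, pause = 40), "pause < modification_onset")
  expect_error(trigger_config(1.2), "<= 1")
  expect_error(trigger_config(0.5, threshold_floor = 0.6), "threshold_floor")
})

test_that("a perfectly coherent source yields stimuli spaced by one
           analysis tick plus the pause", {
  pair <- const_pair(1, duration = 120, seed = 31)
  cfg <- trigger_config(0.9)
  res <- run_session(pair, cfg, seed = 32)
  expect_identical(nrow(res$events), 10L)
  expect_equal(res$events$time_s, seq(1, by = 11, length.out = 10))
  expect_equal(res$inter_stimulus_intervals[-1], rep(11, 9))
  expect_equal(res$total_time, 100 + 10)
  expect_true(all(!res$events$modified))
})

test_that("every stimulus satisfies the trigger condition and sessions
           are reproducible under a seed", {
  base <- generate_eeg_pair(synth_config(duration = 180, seed = 33))
  cal <- calibrate(base$ch1, base$ch2)
  eeg <- generate_eeg_pair(synth_config(duration = 900, seed = 34))
  cfg <- trigger_config(cal$initial_threshold)
  r1 <- run_session(eeg, cfg, seed = 35)
  r2 <- run_session(eeg, cfg, seed = 35)
  expect_identical(r1$events, r2$events)
  expect_true(all(r1$events$coh_at_stim >= r1$events$threshold_at_stim))
  expect_identical(r1$events$modified,
                   r1$events$threshold_at_stim < cal$initial_threshold)
  # pause: no two stimuli closer than pause + 1 s
  expect_true(all(diff(r1$events$time_s) >= 11))
})

test_that("the session terminates within the liveness bound when the
           floor is zero", {
  cfg <- trigger_config(0.8, n_stimuli = 3L)
  state <- new_trigger_state(cfg)
  bound <- 3 * (30 + 0.8 / 0.05 + 10 + 1)
  events <- 0
  for (t in 1:bound) {
    if (state$phase == "done") break
    if (state$phase == "paused") {
      state <- cohtms:::pause_tick(state)
      next
    }
    res <- trigger_step(state, 0, cfg)   # worst case: silent stream
    state <- res$state
    if (!is.null(res$event)) events <- events + 1
  }
  expect_identical(events, 3)
  expect_identical(state$phase, "done")
})

test_that("a too-short record raises a partial-session error carrying the
           events so far", {
  pair <- const_pair(1, duration = 30, seed = 36)
  cfg <- trigger_config(0.9)          # would need ~110 s for 10 stimuli
  err <- tryCatch(run_session(pair, cfg, seed = 37),
                  cohtms_partial_session = identity)
  expect_s3_class(err, "cohtms_partial_session")
  expect_s3_class(err$result, "session_result")
  expect_gt(nrow(err$result$events), 0)
  expect_lt(nrow(err$result$events), 10)
})

test_that("a silent stream logs recharge events at the standby limit", {
  cfg <- trigger_config(0.9, delta = 0.001)   # decays too slowly to fire
  state <- new_trigger_state(cfg)
  for (t in 1:130) state <- trigger_step(state, 0, cfg)$state
  expect_identical(state$recharge_events, c(60, 120))
})

test_that("control sessions draw integer intervals on the stated support
           and never gate on coherence", {
  pair <- const_pair(0.8, duration = 400, seed = 38)
  cfg <- trigger_config(0.99)          # would almost never fire if gated
  res <- run_control_session(pair, cfg, seed = 39)
  expect_identical(nrow(res$events), 10L)
  iv <- res$inter_stimulus_intervals
  expect_true(all(iv >= 25 & iv <= 35 & iv == round(iv)))
  expect_equal(res$total_time, sum(iv))
  expect_true(all(is.na(res$events$threshold_at_stim)))

  # uniform-interval mean: 10,000 seeded draws within 3 SEs of 30 s
  draws <- withr::with_seed(40, sample(25:35, 10000, replace = TRUE))
  se <- sqrt(10) / sqrt(10000)         # var of discrete uniform on 25..35
  expect_lt(abs(mean(draws) - 30), 3 * se)
})

test_that("counting stimuli below the initial threshold reproduces the
           bundled worked examples", {
  ref <- ref_stimulus_coherence()
  counts <- vapply(split(ref, ref$participant), function(d) {
    count_below_threshold(d$coh, d$initial_threshold[1])
  }, numeric(1))
  expect_identical(counts[["1"]], 4)
  expect_identical(counts[["7"]], 9)
  expect_identical(count_below_threshold(ref$coh, 0), 0L)
})
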