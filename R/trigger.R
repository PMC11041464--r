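#' Trigger timing configuration
#'
#' All timing constants of the per-second trigger loop: the calibrated
#' initial threshold, the adaptive decay applied when no stimulus has
#' occurred for \code{modification_onset} seconds, the post-stimulus
#' analysis pause, the stimulator recharge limit, and the session length
#' in stimuli.
#'
#' @param initial_threshold Calibrated Coh(beta) threshold in
#'   \code{[0, 1]}.
#' @param delta Threshold decrement per second once the modification
#'   onset has passed (default 0.05); strictly positive.
#' @param modification_onset Seconds without a stimulus after which the
#'   threshold starts to decay (default 30).
#' @param pause Analysis pause after each stimulus, in seconds
#'   (default 10); must be shorter than \code{modification_onset}.
#' @param recharge_limit Stimulator standby limit in seconds (default
#'   60); reaching it without a stimulus logs a recharge event.
#' @param n_stimuli Stimuli per session (default 10).
#' @param threshold_floor Lower bound of the decaying threshold (default
#'   0, which guarantees the session terminates).
#' @return A list of class \code{"trigger_config"}.
#' @export
trigger_config <- function(initial_threshold, delta = 0.05,
                           modification_onset = 30, pause = 10,
                           recharge_limit = 60, n_stimuli = 10L,
                           threshold_floor = 0) {
  stopifnot(length(initial_threshold) == 1L, is.finite(initial_threshold))
  if (delta <= 0) stop("delta must be > 0", call. = FALSE)
  if (!(pause < modification_onset && modification_onset <= recharge_limit))
    stop("require pause < modification_onset <= recharge_limit",
         call. = FALSE)
  if (!(threshold_floor >= 0 && threshold_floor <= initial_threshold &&
        initial_threshold <= 1))
    stop("require 0 <= threshold_floor <= initial_threshold <= 1",
         call. = FALSE)
  if (n_stimuli < 1L) stop("n_stimuli must be >= 1", call. = FALSE)
  structure(list(initial_threshold = initial_threshold, delta = delta,
                 modification_onset = modification_onset, pause = pause,
                 recharge_limit = recharge_limit,
                 n_stimuli = as.integer(n_stimuli),
                 threshold_floor = threshold_floor),
            class = "trigger_config")
}

#' Fresh trigger state for a session
#'
#' @param cfg A [trigger_config()].
#' @return A list of class \code{"trigger_state"}: current_threshold,
#'   seconds_since_last_stimulus, stimuli_delivered, phase (one of
#'   \code{"analyzing"}, \code{"paused"}, \code{"done"}), pause_remaining,
#'   recharge_events (seconds-since-stimulus values at which the
#'   stimulator would have been recharged).
#' @export
new_trigger_state <- function(cfg) {
  stopifnot(inherits(cfg, "trigger_config"))
  structure(list(current_threshold = cfg$initial_threshold,
                 seconds_since_last_stimulus = 0,
                 stimuli_delivered = 0L,
                 phase = "analyzing",
                 pause_remaining = 0L,
                 recharge_events = numeric(0)),
            class = "trigger_state")
}

#' One analysis tick of the trigger state machine
#'
#' Advances the state by one second of analysis. The per-section clock
#' (seconds since the last stimulus, or since session start before the
#' first one) advances; once it exceeds \code{modification_onset} the
#' threshold decays by \code{delta} per tick, never below
#' \code{threshold_floor}. The incoming coherence value is then compared
#' against the (possibly decayed) threshold: if \code{coh >= threshold} a
#' stimulus event is emitted, the threshold resets to its initial value,
#' the clock restarts and analysis pauses for \code{pause} seconds. If
#' the clock reaches a multiple of \code{recharge_limit} without a
#' stimulus, a recharge event is logged (non-blocking).
#'
#' Consequences: the threshold never decays at or before the onset; on a
#' stream that never fires, the threshold at integer tick \eqn{t} equals
#' \eqn{\max(\mathrm{floor},\; \theta_0 - \delta \cdot \max(0, t -
#' \mathrm{onset}))}.
#'
#' @param state A [new_trigger_state()] in the \code{"analyzing"} phase.
#' @param coh Band coherence of the current 1-s window, in \code{[0, 1]}.
#' @param cfg The [trigger_config()].
#' @return List with \code{state} (updated) and \code{event}
#'   (\code{NULL}, or a one-row data frame with \code{coh_at_stim},
#'   \code{threshold_at_stim}, \code{modified}).
#' @export
trigger_step <- function(state, coh, cfg) {
  stopifnot(inherits(state, "trigger_state"), inherits(cfg, "trigger_config"))
  if (state$phase != "analyzing")
    stop("trigger_step called while phase is '", state$phase,
         "': the runner must skip paused ticks", call. = FALSE)
  if (!is.finite(coh) || coh < 0 || coh > 1)
    stop("coherence value must lie in [0, 1]", call. = FALSE)
  clock <- state$seconds_since_last_stimulus + 1
  thr <- state$current_threshold
  if (clock > cfg$modification_onset)
    thr <- max(cfg$threshold_floor, thr - cfg$delta)
  if (coh >= thr) {
    event <- data.frame(coh_at_stim = coh, threshold_at_stim = thr,
                        modified = thr < cfg$initial_threshold)
    state$stimuli_delivered <- state$stimuli_delivered + 1L
    state$current_threshold <- cfg$initial_threshold
    state$seconds_since_last_stimulus <- 0
    if (state$stimuli_delivered >= cfg$n_stimuli) {
      state$phase <- "done"
    } else {
      state$phase <- "paused"
      state$pause_remaining <- as.integer(cfg$pause)
    }
    return(list(state = state, event = event))
  }
  state$current_threshold <- thr
  state$seconds_since_last_stimulus <- clock
  if (clock >= cfg$recharge_limit && clock %% cfg$recharge_limit == 0)
    state$recharge_events <- c(state$recharge_events, clock)
  list(state = state, event = NULL)
}

# One paused tick: the analysis is suspended but wall-clock time (and
# thus the per-section clock feeding the modification onset) advances.
pause_tick <- function(state) {
  stopifnot(state$phase == "paused")
  state$seconds_since_last_stimulus <- state$seconds_since_last_stimulus + 1
  state$pause_remaining <- state$pause_remaining - 1L
  if (state$pause_remaining <= 0L) state$phase <- "analyzing"
  state
}

# Assemble a session_result from an event data frame.
session_result <- function(events, total_time, condition,
                           recharge_times = numeric(0)) {
  intervals <- if (nrow(events)) diff(c(0, events$time_s)) else numeric(0)
  structure(list(events = events,
                 inter_stimulus_intervals = intervals,
                 total_time = total_time,
                 condition = condition,
                 recharge_times = recharge_times),
            class = "session_result")
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("<session_result> %s: %d stimuli in %g s\n",
              x$condition, nrow(x$events), x$total_time))
  if (nrow(x$events)) {
    cat(sprintf("  mean interval %.1f s, mean Coh(beta) at stimulation %.3f\n",
                mean(x$inter_stimulus_intervals), mean(x$events$coh_at_stim)))
  }
  invisible(x)
}

partial_session_error <- function(events, total_time, condition, why) {
  cond <- structure(
    class = c("cohtms_partial_session", "error", "condition"),
    list(message = paste0("EEG source exhausted before the session ",
                          "completed (", why, "); ", nrow(events),
                          " events delivered"),
         call = sys.call(-1),
         result = session_result(events, total_time, condition)))
  stop(cond)
}

empty_events <- function() {
  data.frame(time_s = numeric(0), coh_at_stim = numeric(0),
             threshold_at_stim = numeric(0), modified = logical(0),
             mep_mV = numeric(0))
}

prepare_channels <- function(eeg, dsp, prefiltered) {
  stopifnot(is.list(eeg), !is.null(eeg$ch1), !is.null(eeg$ch2))
  if (!is.null(eeg$fs) && eeg$fs != dsp$fs)
    stop("EEG sampling rate (", eeg$fs, " Hz) does not match dsp fs (",
         dsp$fs, " Hz)", call. = FALSE)
  if (prefiltered) return(list(ch1 = eeg$ch1, ch2 = eeg$ch2))
  list(ch1 = bandpass_filter(eeg$ch1, dsp$fs, dsp$filter_band[1],
                             dsp$filter_band[2], dsp$filter_order,
                             dsp$zero_phase),
       ch2 = bandpass_filter(eeg$ch2, dsp$fs, dsp$filter_band[1],
                             dsp$filter_band[2], dsp$filter_order,
                             dsp$zero_phase))
}

#' Run a coherence-triggered stimulation session
#'
#' The closed-loop protocol as a discrete 1-second tick loop: at each
#' analyzing tick the band coherence of the most recent 1-s window is
#' computed and fed to [trigger_step()]; each emitted stimulus draws an
#' MEP amplitude from the coherence-dependent model at the coherence
#' observed at stimulation time; analysis pauses for \code{cfg$pause}
#' seconds after each stimulus; the session ends after
#' \code{cfg$n_stimuli} stimuli. Event times are integer seconds from
#' session start.
#'
#' If the EEG record runs out before the session completes, an error of
#' class \code{"cohtms_partial_session"} is signalled whose
#' \code{$result} element carries the partial [session_result].
#'
#' @param eeg A list with \code{ch1}, \code{ch2} (and optionally
#'   \code{fs}), e.g. an [generate_eeg_pair()] output or a recording.
#' @param cfg A [trigger_config()].
#' @param mep A [mep_model()]; its own \code{seed} should normally be
#'   \code{NULL} so draws follow the session seed.
#' @param dsp A [dsp_params()].
#' @param seed Optional integer seed for the whole session (MEP draws).
#' @param prefiltered Set \code{TRUE} if the channels are already
#'   bandpass-filtered.
#' @return A list of class \code{"session_result"}: \code{events} (data
#'   frame with \code{time_s}, \code{coh_at_stim},
#'   \code{threshold_at_stim}, \code{modified}, \code{mep_mV}),
#'   \code{inter_stimulus_intervals}, \code{total_time} (last stimulus
#'   time plus the final pause), \code{condition}, \code{recharge_times}.
#' @export
run_session <- function(eeg, cfg, mep = mep_model(), dsp = dsp_params(),
                        seed = NULL, prefiltered = FALSE) {
  run <- function() {
    ch <- prepare_channels(eeg, dsp, prefiltered)
    coh <- coh_series(ch$ch1, ch$ch2, dsp)
    state <- new_trigger_state(cfg)
    events <- empty_events()
    recharges <- numeric(0)
    for (t in seq_along(coh)) {
      if (state$phase == "paused") {
        state <- pause_tick(state)
        next
      }
      n_rech <- length(state$recharge_events)
      res <- trigger_step(state, coh[t], cfg)
      state <- res$state
      if (length(state$recharge_events) > n_rech)
        recharges <- c(recharges, t)
      if (!is.null(res$event)) {
        ev <- res$event
        ev$time_s <- t
        ev$mep_mV <- simulate_mep(ev$coh_at_stim, mep)
        events <- rbind(events,
                        ev[, c("time_s", "coh_at_stim", "threshold_at_stim",
                               "modified", "mep_mV")])
        if (state$phase == "done") break
      }
    }
    if (state$phase != "done")
      partial_session_error(events, length(coh), "coherence_triggered",
                            sprintf("%d of %d stimuli", nrow(events),
                                    cfg$n_stimuli))
    session_result(events,
                   total_time = events$time_s[nrow(events)] + cfg$pause,
                   condition = "coherence_triggered",
                   recharge_times = recharges)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Run a random-interval control session
#'
#' The open-loop control condition: stimuli are delivered at uniformly
#' drawn integer-second intervals in \code{[interval_low,
#' interval_high]}, ignoring the coherence. The band coherence of the
#' window preceding each stimulus is still recorded (it is needed for
#' post-hoc analysis and drives the MEP model), but never gates the
#' trigger; \code{threshold_at_stim} and \code{modified} are \code{NA}
#' for control events.
#'
#' @inheritParams run_session
#' @param interval_low,interval_high Interval support in seconds
#'   (defaults 25 and 35).
#' @return A \code{"session_result"} with condition
#'   \code{"random_control"}; \code{total_time} is the sum of the drawn
#'   intervals.
#' @export
run_control_session <- function(eeg, cfg, mep = mep_model(),
                                dsp = dsp_params(),
                                interval_low = 25, interval_high = 35,
                                seed = NULL, prefiltered = FALSE) {
  if (!(interval_low < interval_high))
    stop("require interval_low < interval_high", call. = FALSE)
  run <- function() {
    ch <- prepare_channels(eeg, dsp, prefiltered)
    coh <- coh_series(ch$ch1, ch$ch2, dsp)
    intervals <- sample(seq.int(interval_low, interval_high),
                        cfg$n_stimuli, replace = TRUE)
    times <- cumsum(intervals)
    ok <- times <= length(coh)
    events <- empty_events()
    if (any(ok)) {
      tt <- times[ok]
      cc <- coh[tt]
      events <- data.frame(time_s = tt, coh_at_stim = cc,
                           threshold_at_stim = NA_real_,
                           modified = NA,
                           mep_mV = simulate_mep(cc, mep))
    }
    if (!all(ok))
      partial_session_error(events, length(coh), "random_control",
                            sprintf("%d of %d stimuli", sum(ok),
                                    cfg$n_stimuli))
    session_result(events, total_time = sum(intervals),
                   condition = "random_control")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Count coherence values strictly below a threshold
#'
#' For a series of per-stimulus coherence values, counts how many fell
#' strictly below the initial trigger threshold — i.e. how often the
#' stimulus can only have been delivered because the threshold had been
#' modified downward.
#'
#' @param values Coherence values in \code{[0, 1]}.
#' @param threshold Threshold to compare against.
#' @return Integer count.
#' @export
count_below_threshold <- function(values, threshold) {
  stopifnot(is.numeric(values), is.numeric(threshold),
            length(threshold) == 1L)
  if (any(!is.finite(values)) || any(values < 0 | values > 1))
    stop("coherence values must lie in [0, 1]", call. = FALSE)
  sum(values < threshold)
}
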