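#' Simulate one synthetic participant through the full protocol
#'
#' Runs the complete pipeline for a single synthetic participant:
#' generate a baseline record, calibrate the trigger threshold
#' (\code{target_count} crossings over the baseline), generate a session
#' record from the same generative model, and run the
#' coherence-triggered session and the random-interval control session
#' on that record. Sub-seeds for the baseline, the session EEG, the MEP
#' draws and the control intervals are fanned out deterministically from
#' \code{seed} (see [derive_seed()]) so that paired conditions share the
#' same EEG realization.
#'
#' @param seed Master seed for this participant.
#' @param synth_args Named list of overrides for [synth_config()]
#'   (other than \code{duration} and \code{seed}).
#' @param mep A [mep_model()] (its seed is ignored; draws follow the
#'   session sub-seed).
#' @param dsp A [dsp_params()].
#' @param baseline_duration Baseline length in seconds.
#' @param target_count Desired baseline crossing count.
#' @param session_duration Length of the generated session record (s);
#'   must exceed the worst-case session length.
#' @param n_stimuli Stimuli per session.
#' @param control \code{TRUE} to also run the control session.
#' @return A list with \code{calibration}, \code{triggered},
#'   \code{control} (or \code{NULL}), and \code{seed}.
#' @export
simulate_participant <- function(seed, synth_args = list(),
                                 mep = mep_model(), dsp = dsp_params(),
                                 baseline_duration = 180,
                                 target_count = 6L,
                                 session_duration = 900,
                                 n_stimuli = 10L, control = TRUE) {
  make_pair <- function(duration, sub) {
    cfg <- do.call(synth_config,
                   c(list(duration = duration, fs = dsp$fs,
                          seed = derive_seed(seed, sub)), synth_args))
    generate_eeg_pair(cfg)
  }
  baseline <- make_pair(baseline_duration, 1L)
  cal <- calibrate(baseline$ch1, baseline$ch2, dsp, target_count)
  session_eeg <- make_pair(session_duration, 2L)
  tcfg <- trigger_config(initial_threshold = cal$initial_threshold,
                         n_stimuli = n_stimuli)
  mep_free <- mep
  mep_free$seed <- NULL
  triggered <- run_session(session_eeg, tcfg, mep_free, dsp,
                           seed = derive_seed(seed, 3L))
  ctrl <- NULL
  if (control)
    ctrl <- run_control_session(session_eeg, tcfg, mep_free, dsp,
                                seed = derive_seed(seed, 4L))
  list(calibration = cal, triggered = triggered, control = ctrl,
       seed = seed)
}

#' Simulate a full multi-participant study
#'
#' Repeats [simulate_participant()] for \code{n_participants} synthetic
#' participants and tabulates the per-participant evaluation quantities:
#' the calibrated threshold, the MEP amplitude CV under each condition,
#' the mean coherence at stimulation, the number of
#' threshold-modified stimuli, and the session times.
#'
#' @param n_participants Number of synthetic participants.
#' @param seed Master study seed; participant \eqn{i} uses sub-seed
#'   \code{derive_seed(seed, 100 + i)}.
#' @inheritParams simulate_participant
#' @return A data frame with one row per participant and attributes
#'   \code{sessions} (the raw per-participant results).
#' @export
simulate_study <- function(n_participants = 7L, seed = 1L,
                           synth_args = list(), mep = mep_model(),
                           dsp = dsp_params(), baseline_duration = 180,
                           target_count = 6L, session_duration = 900,
                           n_stimuli = 10L) {
  sessions <- lapply(seq_len(n_participants), function(i) {
    simulate_participant(derive_seed(seed, 100L + i),
                         synth_args = synth_args, mep = mep, dsp = dsp,
                         baseline_duration = baseline_duration,
                         target_count = target_count,
                         session_duration = session_duration,
                         n_stimuli = n_stimuli)
  })
  rows <- lapply(seq_along(sessions), function(i) {
    s <- sessions[[i]]
    trig <- s$triggered
    ctrl <- s$control
    data.frame(
      participant = i,
      initial_threshold = s$calibration$initial_threshold,
      cv_triggered = summarize_condition(trig$events$mep_mV)$cv,
      cv_control = summarize_condition(ctrl$events$mep_mV)$cv,
      mean_coh_triggered = mean_coh(trig$events$coh_at_stim),
      mean_coh_control = mean_coh(ctrl$events$coh_at_stim),
      n_modified = sum(trig$events$modified),
      time_triggered = trig$total_time,
      time_control = ctrl$total_time)
  })
  out <- do.call(rbind, rows)
  attr(out, "sessions") <- sessions
  out
}

#' Evaluate a pair of sessions the way the protocol reports results
#'
#' Computes, for a (triggered, control) session pair: the MEP amplitude
#' summaries and their two-sided variance-ratio test, the per-stimulus
#' interval summaries, the mean coherence at stimulation, and the count
#' of threshold-modified stimuli.
#'
#' @param triggered,control \code{"session_result"} objects.
#' @param alpha Significance level for the variance-ratio test.
#' @return A list of class \code{"session_evaluation"}.
#' @export
evaluate_sessions <- function(triggered, control, alpha = 0.05) {
  stopifnot(inherits(triggered, "session_result"),
            inherits(control, "session_result"))
  structure(list(
    mep_triggered = summarize_condition(triggered$events$mep_mV),
    mep_control = summarize_condition(control$events$mep_mV),
    mep_f_test = variance_ratio_test(triggered$events$mep_mV,
                                     control$events$mep_mV, alpha),
    intervals_triggered =
      summarize_condition(triggered$inter_stimulus_intervals),
    intervals_control =
      summarize_condition(control$inter_stimulus_intervals),
    mean_coh_triggered = mean_coh(triggered$events$coh_at_stim),
    mean_coh_control = mean_coh(control$events$coh_at_stim),
    n_modified = sum(triggered$events$modified)),
    class = "session_evaluation")
}

#' @export
print.session_evaluation <- function(x, ...) {
  cat("<session_evaluation>\n")
  cat(sprintf("  MEP CV: triggered %.3f vs control %.3f (F = %.3g, p = %.3g)\n",
              x$mep_triggered$cv, x$mep_control$cv,
              x$mep_f_test$f_statistic, x$mep_f_test$p_value))
  cat(sprintf("  mean Coh(beta) at stimulation: %.3f vs %.3f; %d modified stimuli\n",
              x$mean_coh_triggered, x$mean_coh_control, x$n_modified))
  cat(sprintf("  per-stimulus time CV: triggered %.3f vs control %.3f\n",
              x$intervals_triggered$cv, x$intervals_control$cv))
  invisible(x)
}
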