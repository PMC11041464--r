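#' Default run configuration
#'
#' The fully populated nested configuration: \code{dsp}, \code{synth},
#' \code{trigger}, \code{mep} sections plus a master \code{seed} and an
#' \code{output_dir}. [load_config()] merges a (possibly partial) YAML
#' file over these defaults and validates the result.
#'
#' @return Nested list of class \code{"run_config"}.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    output_dir = ".",
    dsp = list(fs = 500, band_low = 14, band_high = 30,
               filter_low = 1, filter_high = 30, filter_order = 4,
               seg_len = 250, overlap = 0.5, taper = "hann",
               detrend = TRUE, zero_phase = FALSE),
    synth = list(duration = 600, mixing_mean = 0.8, drift_amplitude = 0.15,
                 drift_period = 40, alpha_power = 1, beta_power = 1,
                 pink_power = 1),
    trigger = list(initial_threshold = NA, delta = 0.05,
                   modification_onset = 30, pause = 10,
                   recharge_limit = 60, n_stimuli = 10,
                   threshold_floor = 0,
                   interval_low = 25, interval_high = 35,
                   target_count = 6, baseline_duration = 180),
    mep = list(mu = 1.0, sigma_max = 0.6, sigma_min = 0.1)),
    class = "run_config")
}

merge_section <- function(defaults, user, path) {
  for (key in names(user)) {
    if (!key %in% names(defaults))
      stop("unknown configuration key: ", paste(c(path, key), collapse = "."),
           call. = FALSE)
    if (is.list(defaults[[key]]) && !is.null(defaults[[key]])) {
      if (!is.list(user[[key]]))
        stop("configuration key ", paste(c(path, key), collapse = "."),
             " must be a section", call. = FALSE)
      defaults[[key]] <- merge_section(defaults[[key]], user[[key]],
                                       c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

validate_config <- function(cfg) {
  # delegate to the constructors so every invariant is checked in one place
  with(cfg$dsp, dsp_params(fs = fs, band = c(band_low, band_high),
                           filter_band = c(filter_low, filter_high),
                           filter_order = filter_order, seg_len = seg_len,
                           overlap = overlap, taper = taper,
                           detrend = detrend, zero_phase = zero_phase))
  with(cfg$synth, synth_config(duration = duration,
                               fs = cfg$dsp$fs,
                               mixing_mean = mixing_mean,
                               drift_amplitude = drift_amplitude,
                               drift_period = drift_period,
                               alpha_power = alpha_power,
                               beta_power = beta_power,
                               pink_power = pink_power))
  with(cfg$mep, mep_model(mu = mu, sigma_max = sigma_max,
                          sigma_min = sigma_min))
  tr <- cfg$trigger
  thr <- if (is.null(tr$initial_threshold) || is.na(tr$initial_threshold))
    0.5 else tr$initial_threshold
  trigger_config(initial_threshold = thr, delta = tr$delta,
                 modification_onset = tr$modification_onset,
                 pause = tr$pause, recharge_limit = tr$recharge_limit,
                 n_stimuli = tr$n_stimuli,
                 threshold_floor = min(tr$threshold_floor, thr))
  if (!(tr$interval_low < tr$interval_high))
    stop("trigger.interval_low must be below trigger.interval_high",
         call. = FALSE)
  if (tr$target_count < 1 || tr$target_count > tr$baseline_duration)
    stop("trigger.target_count must lie in [1, baseline_duration]",
         call. = FALSE)
  invisible(cfg)
}

#' Load and validate a run configuration
#'
#' Reads a YAML file, merges it over [default_config()] (an empty file
#' yields the defaults), rejects unknown keys by name, and validates
#' every section through the corresponding constructor.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated \code{"run_config"}.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("configuration file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  if (!is.list(user))
    stop("configuration file must contain a YAML mapping", call. = FALSE)
  cfg <- merge_section(unclass(default_config()), user, character(0))
  cfg <- structure(cfg, class = "run_config")
  validate_config(cfg)
  cfg
}

#' Write a run configuration to YAML
#'
#' Inverse of [load_config()]: a written file loads back to an identical
#' configuration.
#'
#' @param cfg A \code{"run_config"}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# dsp_params from a run_config
config_dsp <- function(cfg) {
  with(cfg$dsp, dsp_params(fs = fs, band = c(band_low, band_high),
                           filter_band = c(filter_low, filter_high),
                           filter_order = filter_order, seg_len = seg_len,
                           overlap = overlap, taper = taper,
                           detrend = detrend, zero_phase = zero_phase))
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Write a session event log as CSV
#'
#' One row per stimulus with columns \code{time_s}, \code{coh_at_stim},
#' \code{threshold_at_stim}, \code{modified}, \code{mep_mV}; numeric
#' fields are written at full precision so [read_session_csv()]
#' reproduces the session exactly. Two comment lines (\code{#condition},
#' \code{#total_time}) carry the session metadata.
#'
#' @param result A \code{"session_result"}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_session_csv <- function(result, path) {
  stopifnot(inherits(result, "session_result"))
  ev <- result$events
  lines <- c(sprintf("#condition,%s", result$condition),
             sprintf("#total_time,%s", fmt_num(result$total_time)),
             "time_s,coh_at_stim,threshold_at_stim,modified,mep_mV")
  if (nrow(ev)) {
    rows <- sprintf("%s,%s,%s,%s,%s",
                    fmt_num(ev$time_s), fmt_num(ev$coh_at_stim),
                    fmt_num(ev$threshold_at_stim),
                    ifelse(is.na(ev$modified), "NA",
                           ifelse(ev$modified, "TRUE", "FALSE")),
                    fmt_num(ev$mep_mV))
    lines <- c(lines, rows)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a session event log written by [write_session_csv()]
#'
#' @param path Path to the CSV file.
#' @return A \code{"session_result"} equal to the one written.
#' @export
read_session_csv <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  get_meta <- function(key) {
    row <- meta[startsWith(meta, paste0("#", key, ","))]
    if (length(row) != 1L)
      stop("malformed session CSV: missing #", key, " line", call. = FALSE)
    sub(paste0("^#", key, ","), "", row)
  }
  condition <- get_meta("condition")
  total_time <- as.numeric(get_meta("total_time"))
  body <- lines[!startsWith(lines, "#")]
  ev <- utils::read.csv(text = paste(body, collapse = "\n"),
                        colClasses = c(time_s = "numeric",
                                       coh_at_stim = "numeric",
                                       threshold_at_stim = "numeric",
                                       modified = "logical",
                                       mep_mV = "numeric"))
  session_result(ev, total_time = total_time, condition = condition)
}

#' Read a two-channel EEG recording from delimited text
#'
#' Expects a header line naming the two channel columns (defaults
#' \code{P3}, \code{C4}) and one row per sample.
#'
#' @param path Path to a CSV/TSV file.
#' @param fs Sampling rate of the recording (Hz).
#' @param channels Names of the two channel columns.
#' @param sep Field separator (\code{","} or \code{"\t"}).
#' @return A list with \code{ch1}, \code{ch2}, \code{fs}.
#' @export
read_eeg_csv <- function(path, fs = 500, channels = c("P3", "C4"),
                         sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep)
  missing <- setdiff(channels, names(df))
  if (length(missing))
    stop("channel column(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  list(ch1 = as.numeric(df[[channels[1]]]),
       ch2 = as.numeric(df[[channels[2]]]), fs = fs)
}

#' Write a reproducibility manifest for a run
#'
#' Records the package version, the master seed, the full configuration
#' and its MD5 digest — enough to reproduce the run bit-exactly.
#'
#' @param path Output JSON path.
#' @param cfg The \code{"run_config"} used.
#' @param seed Master seed of the run.
#' @return \code{path}, invisibly.
#' @export
write_run_manifest <- function(path, cfg, seed) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  digest <- unname(tools::md5sum(tmp))
  jsonlite::write_json(
    list(package = "cohtms",
         version = as.character(utils::packageVersion("cohtms")),
         seed = seed, config_md5 = digest, config = unclass(cfg)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Bundled worked example: per-stimulus coherence of seven participants
#'
#' The per-stimulus beta-band coherence values, initial trigger
#' thresholds and reported per-participant means recorded in the
#' seven-participant validation experiment of the coherence-gated
#' trigger protocol. Useful as a regression fixture for [mean_coh()]
#' and [count_below_threshold()].
#'
#' @return Data frame with columns \code{participant},
#'   \code{initial_threshold}, \code{stimulus} (1-10), \code{coh},
#'   \code{reported_mean}.
#' @export
ref_stimulus_coherence <- function() {
  path <- system.file("extdata", "stimulus_coherence.csv",
                      package = "cohtms", mustWork = TRUE)
  utils::read.csv(path)
}

#' Bundled worked example: MEP amplitude CV pairs of seven participants
#'
#' Per-participant coefficients of variation of the MEP amplitude under
#' the coherence-triggered and random-interval control conditions, from
#' the same validation experiment as [ref_stimulus_coherence()].
#'
#' @return Data frame with columns \code{participant},
#'   \code{cv_triggered}, \code{cv_control}.
#' @export
ref_mep_cv <- function() {
  path <- system.file("extdata", "mep_cv.csv", package = "cohtms",
                      mustWork = TRUE)
  utils::read.csv(path)
}

#' Derive a bounded sub-seed from a master seed
#'
#' Deterministic fan-out of one master seed into per-component streams
#' (baseline, session EEG, MEP draws, control intervals) so that
#' ablations share noise realizations. The result always lies in
#' \code{[0, 2^31 - 2]}.
#'
#' @param seed Master integer seed.
#' @param k Stream index (non-negative integer).
#' @return Integer sub-seed.
#' @export
derive_seed <- function(seed, k) {
  as.integer((abs(as.numeric(seed)) * 7919 + as.numeric(k) * 104729 + 12345) %%
               2147483646)
}
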