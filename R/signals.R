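#' Construct a single-modality signal recording
#'
#' A time-stamped univariate series with a per-sample validity mask and event
#' markers (one per trial) for one participant and one modality.
#'
#' @param modality one of `"pupil"`, `"scr"`, `"hr"`.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param time_s,value numeric vectors (times strictly increasing).
#' @param valid logical per-sample validity mask (all valid by default).
#' @param events data.frame with columns `trial_id`, `onset_s` (and
#'   optionally `stimulus_id`); onsets must lie within the recording span.
#' @param participant_id identifier.
#' @return Object of class `signal_recording`.
#' @export
signal_recording <- function(modality, sampling_rate, time_s, value,
                             valid = NULL, events = NULL,
                             participant_id = NA_character_) {
  modality <- match.arg(modality, c("pupil", "scr", "hr"))
  if (sampling_rate <= 0) {
    stop("invalid parameter: sampling_rate must be > 0", call. = FALSE)
  }
  if (length(time_s) != length(value)) stop("time/value length mismatch",
                                            call. = FALSE)
  if (any(diff(time_s) <= 0)) stop("times must be strictly increasing",
                                   call. = FALSE)
  if (is.null(valid)) valid <- rep(TRUE, length(value))
  if (is.null(events)) {
    events <- data.frame(trial_id = character(), onset_s = numeric())
  }
  if (nrow(events) &&
      (min(events$onset_s) < min(time_s) || max(events$onset_s) > max(time_s))) {
    stop("event onset outside the recording span", call. = FALSE)
  }
  structure(list(modality = modality, sampling_rate = sampling_rate,
                 time_s = time_s, value = value, valid = valid,
                 events = events, participant_id = participant_id),
            class = "signal_recording")
}

#' @export
print.signal_recording <- function(x, ...) {
  cat(sprintf("<signal_recording> %s, %s, %g Hz, %d samples, %d events\n",
              x$participant_id, x$modality, x$sampling_rate,
              length(x$value), nrow(x$events)))
  invisible(x)
}

# Event-related pupil response kernel: smooth saturating change after onset,
# zero before. A plateau shape keeps the peak close to the stimulus-window
# mean, so even strong constrictions stay inside the physiological 2-10 mm
# validity range when scaled to match a trial feature.
.pupil_kernel <- function(rel_t, tau_s = 0.6) {
  k <- numeric(length(rel_t))
  pos <- rel_t > 0
  k[pos] <- 1 - exp(-rel_t[pos] / tau_s)
  k
}

# Bi-exponential skin-conductance wave starting at rel_t = 0.
.scr_wave <- function(rel_t, tau_rise = 0.75, tau_decay = 2) {
  w <- numeric(length(rel_t))
  pos <- rel_t > 0
  w[pos] <- exp(-rel_t[pos] / tau_decay) - exp(-rel_t[pos] / tau_rise)
  w
}

#' Back-generate raw per-trial signals from a trial table
#'
#' Emits, per participant, a pupil recording (150 Hz by default) and a
#' skin-conductance recording (10 Hz) with one event per trial, plus pre/post
#' heart-rate window means. Each trial's raw signal is constructed so that
#' feature extraction recovers the trial-table feature: the pupil dilation is
#' scaled so the stimulus-window mean minus the baseline-window mean equals
#' the `pupil` feature; the skin-conductance wave's trough-to-peak amplitude
#' on the sample grid equals the `scr` feature (onset latency inside the 1-6 s
#' scoring window); the heart-rate windows differ by exactly the `hr` feature.
#'
#' Optional blinks are inserted as invalid runs (value 0) with uniform-random
#' onsets and lengths in `blink_gap_range`, exercising both sides of the
#' interpolation gap limit.
#'
#' @param trial_table a table from [generate_trial_table()] (or with the same
#'   feature columns).
#' @param preprocess a [preprocess_params()] (defines the scoring windows the
#'   construction honours).
#' @param sampling_rates named vector, Hz for pupil and scr.
#' @param noise_sd named vector, additive Gaussian noise SD per modality.
#' @param blink_rate expected blinks per second of pupil recording (0 = none).
#' @param blink_gap_range blink gap length range in seconds.
#' @param scr_onset_latency latency of the phasic wave after stimulus onset
#'   (s); must put the wave inside the scoring window.
#' @param tonic_scr,pupil_base tonic skin-conductance level (uS) and baseline
#'   pupil diameter (mm).
#' @param seed integer seed or `NULL`.
#' @return Object of class `signal_set`: lists `pupil` and `scr` of
#'   [signal_recording()]s keyed by participant, data.frame `hr`
#'   (`participant_id`, `trial_id`, `stimulus_id`, `pre_bpm`, `post_bpm`),
#'   and the `trials` index.
#' @export
generate_raw_signals <- function(trial_table,
                                 preprocess = preprocess_params(),
                                 sampling_rates = c(pupil = 150, scr = 10),
                                 noise_sd = c(pupil = 0, scr = 0),
                                 blink_rate = 0,
                                 blink_gap_range = c(0.1, 0.4),
                                 scr_onset_latency = 1.5,
                                 tonic_scr = 2, pupil_base = 5,
                                 seed = NULL) {
  if (any(sampling_rates <= 0)) {
    stop("invalid parameter: sampling rates must be > 0", call. = FALSE)
  }
  need <- c("participant_id", "stimulus_id", "pupil", "scr", "hr")
  missing_cols <- setdiff(need, names(trial_table))
  if (length(missing_cols)) {
    stop(sprintf("trial table lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  fs_p <- sampling_rates[["pupil"]]
  fs_s <- sampling_rates[["scr"]]
  slot <- 10                                   # seconds per trial slot
  pre_span <- 2                                # recording lead-in per trial
  post_span <- 6.5
  rel_p <- seq(-1.5, post_span, by = 1 / fs_p)
  rel_s <- seq(-pre_span, 7.5, by = 1 / fs_s)
  kb <- .pupil_kernel(rel_p)
  bw <- preprocess$baseline_window
  sw <- preprocess$stimulus_window
  eps_p <- 0.5 / fs_p                   # same edge tolerance as extraction
  k_base <- mean(kb[rel_p >= bw[1] - eps_p & rel_p <= bw[2] + eps_p])
  k_stim <- mean(kb[rel_p >= sw[1] - eps_p & rel_p <= sw[2] + eps_p])
  wave <- .scr_wave(rel_s - scr_onset_latency)
  wave_max <- max(wave)
  if (scr_onset_latency <= preprocess$scr_window[1] ||
      scr_onset_latency >= preprocess$scr_window[2]) {
    stop("scr_onset_latency must lie inside the scoring window", call. = FALSE)
  }

  participants <- unique(trial_table$participant_id)
  pupil_recs <- list()
  scr_recs <- list()
  hr_rows <- list()
  trial_rows <- list()
  for (p in participants) {
    rows <- which(trial_table$participant_id == p)
    n_t <- length(rows)
    onsets <- (seq_len(n_t) - 1) * slot + pre_span
    trial_ids <- sprintf("%s_%s", p, trial_table$stimulus_id[rows])
    t_p <- as.vector(vapply(onsets, function(o) o + rel_p,
                            numeric(length(rel_p))))
    v_p <- pupil_base +
      as.vector(vapply(seq_len(n_t), function(i) {
        a <- trial_table$pupil[rows[i]] / (k_stim - k_base)
        a * kb
      }, numeric(length(rel_p))))
    valid_p <- rep(TRUE, length(v_p))
    if (noise_sd[["pupil"]] > 0) v_p <- v_p + rnorm(length(v_p),
                                                    sd = noise_sd[["pupil"]])
    if (blink_rate > 0) {
      dur <- length(rel_p) / fs_p
      for (i in seq_len(n_t)) {
        n_blinks <- rpois(1, blink_rate * dur)
        if (n_blinks == 0) next
        offset <- (i - 1) * length(rel_p)
        starts <- runif(n_blinks, 0, dur - blink_gap_range[2])
        lens <- runif(n_blinks, blink_gap_range[1], blink_gap_range[2])
        for (bi in seq_len(n_blinks)) {
          j0 <- offset + 1L + floor(starts[bi] * fs_p)
          j1 <- min(offset + length(rel_p), j0 + ceiling(lens[bi] * fs_p) - 1L)
          v_p[j0:j1] <- 0
          valid_p[j0:j1] <- FALSE
        }
      }
    }
    ev <- data.frame(trial_id = trial_ids, onset_s = onsets,
                     stimulus_id = trial_table$stimulus_id[rows],
                     stringsAsFactors = FALSE)
    pupil_recs[[p]] <- signal_recording("pupil", fs_p, t_p, v_p,
                                        valid = valid_p, events = ev,
                                        participant_id = p)
    t_s <- as.vector(vapply(onsets, function(o) o + rel_s,
                            numeric(length(rel_s))))
    v_s <- tonic_scr +
      as.vector(vapply(seq_len(n_t), function(i) {
        a <- if (wave_max > 0) trial_table$scr[rows[i]] / wave_max else 0
        a * wave
      }, numeric(length(rel_s))))
    if (noise_sd[["scr"]] > 0) v_s <- v_s + rnorm(length(v_s),
                                                  sd = noise_sd[["scr"]])
    scr_recs[[p]] <- signal_recording("scr", fs_s, t_s, v_s, events = ev,
                                      participant_id = p)
    pre <- 70 + rnorm(1, sd = 5)
    hr_rows[[p]] <- data.frame(participant_id = p, trial_id = trial_ids,
                               stimulus_id = trial_table$stimulus_id[rows],
                               pre_bpm = pre,
                               post_bpm = pre + trial_table$hr[rows],
                               stringsAsFactors = FALSE)
    trial_rows[[p]] <- ev[, c("trial_id", "stimulus_id")]
    trial_rows[[p]]$participant_id <- p
  }
  structure(list(pupil = pupil_recs, scr = scr_recs,
                 hr = do.call(rbind, c(hr_rows, list(make.row.names = FALSE))),
                 trials = do.call(rbind, c(trial_rows,
                                           list(make.row.names = FALSE)))),
            class = "signal_set")
}
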