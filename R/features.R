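#' Preprocessing parameters for autonomic feature extraction
#'
#' @param pupil_valid_range physiologically valid pupil diameters (mm);
#'   samples outside are treated as blinks/invalid.
#' @param max_interp_gap longest invalid run that is linearly interpolated
#'   (seconds); longer runs stay invalid and are excluded from means.
#' @param baseline_window pupil baseline window relative to stimulus onset
#'   (s); the default straddles onset (-1 to +1). Use
#'   `baseline_mode = "pre_onset"` for a conventional pre-onset-only window.
#' @param stimulus_window window whose mean corrected pupil diameter is the
#'   trial feature (s, relative to onset).
#' @param scr_window window scanned for phasic skin-conductance responses
#'   (s after onset).
#' @param scr_min_amplitude minimum trough-to-peak rise counted as a response
#'   (microsiemens); smaller rises score 0.
#' @param smooth_width moving-average smoother width in samples (0 = off).
#' @param baseline_mode `"straddle"` (default) or `"pre_onset"`.
#' @return Object of class `preprocess_params`.
#' @export
preprocess_params <- function(pupil_valid_range = c(2, 10),
                              max_interp_gap = 0.150,
                              baseline_window = c(-1, 1),
                              stimulus_window = c(0, 6),
                              scr_window = c(1, 6),
                              scr_min_amplitude = 0.01,
                              smooth_width = 0L,
                              baseline_mode = c("straddle", "pre_onset")) {
  baseline_mode <- match.arg(baseline_mode)
  if (baseline_mode == "pre_onset" && identical(baseline_window, c(-1, 1))) {
    baseline_window <- c(-1, 0)
  }
  p <- list(pupil_valid_range = sort(pupil_valid_range),
            max_interp_gap = max_interp_gap,
            baseline_window = baseline_window,
            stimulus_window = stimulus_window,
            scr_window = scr_window,
            scr_min_amplitude = scr_min_amplitude,
            smooth_width = as.integer(smooth_width),
            baseline_mode = baseline_mode)
  for (w in c("baseline_window", "stimulus_window", "scr_window")) {
    if (diff(p[[w]]) <= 0) {
      stop(sprintf("%s must have positive length", w), call. = FALSE)
    }
  }
  if (p$max_interp_gap <= 0) stop("max_interp_gap must be > 0", call. = FALSE)
  structure(p, class = "preprocess_params")
}

#' Interpolate short invalid runs in a pupil recording
#'
#' Samples outside the valid range, or masked invalid, are grouped into runs.
#' Runs no longer than `max_gap` with valid neighbours on both sides are
#' replaced by linear interpolation between those neighbours and marked
#' valid; longer (or edge) runs remain flagged invalid and are excluded from
#' downstream window means. Valid samples are never altered.
#'
#' @param series a pupil [signal_recording()].
#' @param valid_range interval of physiologically valid values.
#' @param max_gap longest interpolated run, seconds.
#' @return The recording with interpolated values, an updated validity mask,
#'   and counts `n_interpolated` / `n_still_invalid`.
#' @export
interpolate_invalid <- function(series, valid_range = c(2, 10),
                                max_gap = 0.150) {
  stopifnot(inherits(series, "signal_recording"))
  v <- series$value
  ok <- series$valid & v >= valid_range[1] & v <= valid_range[2]
  if (!any(ok)) stop("empty signal: all samples invalid", call. = FALSE)
  n_interp <- 0L
  if (any(!ok)) {
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    max_run <- max_gap * series$sampling_rate + 1e-9
    for (i in seq_along(r$values)) {
      if (r$values[i]) next
      len <- r$lengths[i]
      interior <- starts[i] > 1L && ends[i] < length(v)
      if (interior && len <= max_run) {
        lo <- starts[i] - 1L
        hi <- ends[i] + 1L
        v[starts[i]:ends[i]] <- approx(
          x = series$time_s[c(lo, hi)], y = v[c(lo, hi)],
          xout = series$time_s[starts[i]:ends[i]])$y
        ok[starts[i]:ends[i]] <- TRUE
        n_interp <- n_interp + len
      }
    }
  }
  out <- series
  out$value <- v
  out$valid <- ok
  out$n_interpolated <- n_interp
  out$n_still_invalid <- sum(!ok)
  out
}

#' Moving-average smoother for a signal recording
#'
#' Optional plain centered moving average (the windowed amplitude features
#' are the statistics of interest; smoothing is off by default).
#'
#' @param series a [signal_recording()].
#' @param width odd window width in samples (<= 1 returns the input).
#' @return The smoothed recording.
#' @export
smooth_signal <- function(series, width = 0L) {
  stopifnot(inherits(series, "signal_recording"))
  width <- as.integer(width)
  if (width <= 1L) return(series)
  if (width %% 2L == 0L) width <- width + 1L
  k <- rep(1 / width, width)
  out <- series
  out$value <- as.vector(stats::filter(series$value, k, sides = 2))
  pad <- (width - 1L) %/% 2L
  n <- length(series$value)
  out$value[seq_len(pad)] <- series$value[seq_len(pad)]
  out$value[(n - pad + 1L):n] <- series$value[(n - pad + 1L):n]
  out
}

#' Subtractive baseline correction of one pupil trial
#'
#' Subtracts the mean of the valid samples inside the baseline window
#' (relative to onset) from the trial segment, and returns the mean corrected
#' valid diameter inside the stimulus window as the trial feature. A trial
#' with no valid baseline sample is flagged missing, never zero-filled.
#'
#' @param series a pupil [signal_recording()] (after [interpolate_invalid()]).
#' @param onset stimulus onset time (s).
#' @param params a [preprocess_params()].
#' @return List: `feature` (mm, `NA` when missing), `baseline_mean`,
#'   `corrected` (data.frame `time_s`, `value`, `valid` for the trial
#'   segment), `n_baseline_valid`, `flag` (`"ok"`, `"no_baseline"`,
#'   `"no_stimulus_samples"`).
#' @export
baseline_correct_pupil <- function(series, onset,
                                   params = preprocess_params()) {
  stopifnot(inherits(series, "signal_recording"))
  t <- series$time_s - onset
  bw <- params$baseline_window
  sw <- params$stimulus_window
  seg <- t >= min(bw[1], sw[1]) & t <= max(bw[2], sw[2])
  eps <- 0.5 / series$sampling_rate      # half-sample tolerance at window edges
  in_base <- t >= bw[1] - eps & t <= bw[2] + eps & series$valid
  if (!any(in_base)) {
    return(list(feature = NA_real_, baseline_mean = NA_real_,
                corrected = NULL, n_baseline_valid = 0L,
                flag = "no_baseline"))
  }
  base <- mean(series$value[in_base])
  corrected <- data.frame(time_s = series$time_s[seg],
                          value = series$value[seg] - base,
                          valid = series$valid[seg])
  in_stim <- t >= sw[1] - eps & t <= sw[2] + eps & series$valid
  if (!any(in_stim)) {
    return(list(feature = NA_real_, baseline_mean = base,
                corrected = corrected, n_baseline_valid = sum(in_base),
                flag = "no_stimulus_samples"))
  }
  list(feature = mean(series$value[in_stim]) - base,
       baseline_mean = base,
       corrected = corrected,
       n_baseline_valid = sum(in_base),
       flag = "ok")
}

#' Trough-to-peak phasic skin-conductance amplitude
#'
#' Scans the scoring window (1-6 s after onset by default) for the largest
#' rise from a preceding trough to a peak (equivalently, the maximum over
#' samples of value minus running minimum). Rises below the
#' minimum-amplitude criterion score 0; the amplitude is never negative.
#'
#' @param series an scr [signal_recording()].
#' @param onset stimulus onset time (s).
#' @param params a [preprocess_params()].
#' @return Amplitude in microsiemens (`NA` when the window is outside the
#'   recording).
#' @export
score_scr_trough_to_peak <- function(series, onset,
                                     params = preprocess_params()) {
  stopifnot(inherits(series, "signal_recording"))
  w <- params$scr_window
  tol <- 1 / series$sampling_rate
  t <- series$time_s - onset
  if (min(t) > w[1] + tol || max(t) < w[2] - tol) {
    return(NA_real_)                       # missing-trial flag
  }
  eps <- 0.5 / series$sampling_rate
  idx <- which(t >= w[1] - eps & t <= w[2] + eps)
  if (length(idx) < 2L) return(NA_real_)
  x <- series$value[idx]
  amp <- max(x - cummin(x))
  if (amp < params$scr_min_amplitude) 0 else amp
}

#' Heart-rate change score
#'
#' Post-stimulus minus pre-stimulus mean heart rate, so that stimulus-evoked
#' deceleration is negative.
#'
#' @param pre,post mean heart rate (bpm) in the pre-stimulus (fixation) and
#'   post-onset windows; vectors are handled elementwise.
#' @return `post - pre` (delta bpm).
#' @export
hr_difference_score <- function(pre, post) {
  stopifnot(length(pre) == length(post))
  post - pre
}

#' Extract the per-trial autonomic features from raw recordings
#'
#' Runs blink interpolation and baseline correction on the pupil recordings,
#' trough-to-peak scoring on the skin-conductance recordings, and the
#' pre/post difference on the heart-rate windows, aligning the three
#' modalities by trial id. Trials failing a precondition carry missing
#' markers in that cell (never silent zeros) plus a quality flag.
#'
#' @param recordings a `signal_set` from [generate_raw_signals()] (or with
#'   the same structure).
#' @param params a [preprocess_params()].
#' @return A data.frame with one row per trial (`participant_id`,
#'   `stimulus_id`, `trial_id`, `pupil`, `scr`, `hr`, `pupil_flag`), with a
#'   `quality` attribute (counts of interpolated/invalid pupil samples and
#'   missing cells per modality).
#' @export
extract_trial_features <- function(recordings, params = preprocess_params()) {
  trials <- recordings$trials
  pupil_ids <- unlist(lapply(recordings$pupil, function(r) r$events$trial_id),
                      use.names = FALSE)
  scr_ids <- unlist(lapply(recordings$scr, function(r) r$events$trial_id),
                    use.names = FALSE)
  hr_ids <- recordings$hr$trial_id
  all_ids <- trials$trial_id
  unmatched <- unique(c(setdiff(all_ids, pupil_ids), setdiff(all_ids, scr_ids),
                        setdiff(all_ids, hr_ids),
                        setdiff(c(pupil_ids, scr_ids, hr_ids), all_ids)))
  if (length(unmatched)) {
    stop(sprintf("event manifests disagree; unmatched trial id(s): %s",
                 paste(unmatched, collapse = ", ")), call. = FALSE)
  }
  n_interp <- 0L
  n_invalid <- 0L
  out <- vector("list", length(recordings$pupil))
  names(out) <- names(recordings$pupil)
  for (p in names(recordings$pupil)) {
    prec <- interpolate_invalid(recordings$pupil[[p]],
                                valid_range = params$pupil_valid_range,
                                max_gap = params$max_interp_gap)
    if (params$smooth_width > 1L) prec <- smooth_signal(prec,
                                                        params$smooth_width)
    n_interp <- n_interp + prec$n_interpolated
    n_invalid <- n_invalid + prec$n_still_invalid
    srec <- recordings$scr[[p]]
    ev <- prec$events
    pupil_feat <- numeric(nrow(ev))
    pupil_flag <- character(nrow(ev))
    scr_feat <- numeric(nrow(ev))
    for (i in seq_len(nrow(ev))) {
      bc <- baseline_correct_pupil(prec, ev$onset_s[i], params)
      pupil_feat[i] <- bc$feature
      pupil_flag[i] <- bc$flag
      scr_feat[i] <- score_scr_trough_to_peak(srec, srec$events$onset_s[
        match(ev$trial_id[i], srec$events$trial_id)], params)
    }
    hr_sub <- recordings$hr[match(ev$trial_id, recordings$hr$trial_id), ]
    out[[p]] <- data.frame(participant_id = p,
                           stimulus_id = ev$stimulus_id,
                           trial_id = ev$trial_id,
                           pupil = pupil_feat,
                           scr = scr_feat,
                           hr = hr_difference_score(hr_sub$pre_bpm,
                                                    hr_sub$post_bpm),
                           pupil_flag = pupil_flag,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  attr(res, "quality") <- list(
    pupil_samples_interpolated = n_interp,
    pupil_samples_invalid = n_invalid,
    n_missing = vapply(c(pupil = "pupil", scr = "scr", hr = "hr"),
                       function(m) sum(is.na(res[[m]])), integer(1)))
  res
}
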