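# Shared fixture builders (all programmatic; no stored data).

affect_vars <- c("subjective_valence", "subjective_arousal",
                 "pupil", "scr", "hr")

# Small random trial-like table with the five affective columns and ids.
random_trial_table <- function(n_participants = 5, n_stimuli = 8, seed = 1,
                               sigma = NULL) {
  set.seed(seed)
  n <- n_participants * n_stimuli
  if (is.null(sigma)) {
    a <- matrix(rnorm(25), 5)
    sigma <- crossprod(a) + diag(5)
  }
  x <- matrix(rnorm(n * 5), n, 5) %*% chol(sigma)
  colnames(x) <- affect_vars
  out <- data.frame(
    participant_id = rep(sprintf("P%02d", seq_len(n_participants)),
                         each = n_stimuli),
    stimulus_id = rep(sprintf("S%02d", seq_len(n_stimuli)), n_participants),
    valence_category = factor(rep(rep(c("negative", "neutral", "positive"),
                                      length.out = n_stimuli),
                                  n_participants)),
    x
  )
  out
}

# Trial table with an exact crossed-random-intercept regression structure for
# mixed-model recovery tests (predictors on their own scale, no z-scoring).
make_regression_table <- function(seed, n_participants = 51, n_stimuli = 56,
                                  b_valence = 0.03, b_arousal = 0.36,
                                  b_interaction = 0.16, b_brightness = -0.96,
                                  sd_participant = 0.5, sd_stimulus = 0.3,
                                  sd_resid = 1) {
  set.seed(seed)
  n <- n_participants * n_stimuli
  pid <- rep(sprintf("P%02d", seq_len(n_participants)), each = n_stimuli)
  sid <- rep(sprintf("S%02d", seq_len(n_stimuli)), n_participants)
  v <- rnorm(n)
  a <- rnorm(n)
  br <- rnorm(n_stimuli)[rep(seq_len(n_stimuli), n_participants)]
  up <- rnorm(n_participants, sd = sd_participant)[
    rep(seq_len(n_participants), each = n_stimuli)]
  us <- rnorm(n_stimuli, sd = sd_stimulus)[rep(seq_len(n_stimuli),
                                               n_participants)]
  data.frame(
    participant_id = pid, stimulus_id = sid,
    subjective_valence = v, subjective_arousal = a, brightness = br,
    pupil = b_valence * v + b_arousal * a + b_interaction * v * a +
      b_brightness * br + up + us + rnorm(n, sd = sd_resid)
  )
}

# Three well-separated Gaussian blobs in 2-D.
make_blobs <- function(n_per = 60, sep = 8, sd = 1, seed = 1) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(sep, 0), c(sep / 2, sep))
  x <- do.call(rbind, lapply(1:3, function(k) {
    cbind(rnorm(n_per, centers[k, 1], sd), rnorm(n_per, centers[k, 2], sd))
  }))
  colnames(x) <- c("dim1", "dim2")
  list(x = x, label = factor(rep(c("A", "B", "C"), each = n_per)))
}

# Independent brute-force MFA oracle: explicit standardization, group first
# eigenvalues from the correlation submatrices, global solution via svd of
# the weighted matrix (a different numerical route than the implementation).
mfa_oracle <- function(x, groups) {
  n <- nrow(x)
  z <- x
  for (j in seq_len(ncol(x))) {
    z[, j] <- (x[, j] - mean(x[, j])) / sd(x[, j])
  }
  lambda1 <- vapply(groups, function(g) {
    max(eigen(cor(x[, g, drop = FALSE]), symmetric = TRUE,
              only.values = TRUE)$values)
  }, numeric(1))
  wcol <- rep(1 / lambda1, lengths(groups))
  xw <- z %*% diag(sqrt(wcol))
  sv <- svd(xw)
  list(eigenvalues = sv$d^2 / (n - 1),
       scores = xw %*% sv$v,
       lambda1 = lambda1)
}

# Build a flat signal recording holding one trial; the event marker is only
# attached when the onset lies inside the recording span.
flat_recording <- function(value, fs = 150, t0 = -1.5, modality = "pupil",
                           onset = 0, trial_id = "T1", valid = NULL) {
  tt <- t0 + (seq_along(value) - 1) / fs
  ev <- if (onset >= min(tt) && onset <= max(tt)) {
    data.frame(trial_id = trial_id, onset_s = onset)
  } else NULL
  signal_recording(modality, fs, tt, value, valid = valid, events = ev,
                   participant_id = "P01")
}
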