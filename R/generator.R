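#' Parameters of the synthetic trial-table generator
#'
#' The generator draws trial-level data from a linear two-factor latent model
#' with crossed participant and stimulus random intercepts. A shared affect
#' factor `f1` loads on all five observed variables (subjective valence and
#' arousal, pupil, skin conductance, heart rate); an orienting factor `f2`
#' loads on the autonomic variables only. Pupil additionally receives a
#' valence-by-arousal interaction term and a brightness confound;
#' skin-conductance amplitudes are log-normal (the linear model acts on the
#' log scale), which keeps them nonnegative while preserving a monotone link
#' to the latent factors.
#'
#' Part of the shared factor is a deterministic function of the stimulus
#' norms (`stimulus_affect_share`), so that stimulus categories carry signal
#' into the affective space; the remainder is trial-level. Subjective
#' residuals may be correlated (`rho_va`, negative by default: more negative
#' stimuli tend to be experienced as more arousing).
#'
#' @param n_participants,n_stimuli design size (defaults 51 x 56).
#' @param loadings_f1 named numeric, loading of the shared affect factor on
#'   each observed variable, in observed units per factor SD.
#' @param loadings_f2 named numeric, loadings of the autonomic-only orienting
#'   factor (zero on subjective variables by default).
#' @param interaction named numeric `c(pupil=, scr=)`: coefficients of the
#'   product of the standardized latent valence and arousal signals. The SCR
#'   interaction acts on the log-amplitude scale.
#' @param brightness_coef effect of standardized image brightness on pupil
#'   (mm per z; negative: brighter images constrict the pupil).
#' @param sd_participant,sd_stimulus named nonnegative numerics: random
#'   intercept SDs per variable.
#' @param sd_resid named positive numerics: residual SDs per variable.
#' @param rho_va correlation of the valence and arousal residuals, in (-1, 1).
#' @param stimulus_affect_share proportion (0..1) of the shared factor's
#'   variance carried by the stimulus norms.
#' @param scr_log_mean location of the log SCR amplitude (median amplitude =
#'   `exp(scr_log_mean)` microsiemens).
#' @param rating_limits slider limits for the subjective ratings.
#' @param norm_valence_mean,norm_valence_sd,norm_arousal_mean,norm_arousal_sd
#'   moments of the stimulus norms on the 1-9 normative scale.
#' @param valence_cut_points,arousal_cut_points category cut points on the
#'   normative 1-9 scales.
#' @param missing_rate probability that a trial row is missing completely at
#'   random.
#' @param keep_latents retain the latent factor columns `f1`, `f2` in the
#'   trial table (for recovery tests).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return An object of class `generator_params` (a validated list).
#' @seealso [generate_stimuli()], [generate_trial_table()],
#'   [implied_covariance()], [null_generator_params()]
#' @export
generator_params <- function(n_participants = 51,
                             n_stimuli = 56,
                             loadings_f1 = c(subjective_valence = -2.5,
                                             subjective_arousal = 2.6,
                                             pupil = 0.16,
                                             scr = 0.26,
                                             hr = -0.8),
                             loadings_f2 = c(subjective_valence = 0,
                                             subjective_arousal = 0,
                                             pupil = -0.18,
                                             scr = 0.54,
                                             hr = -2.7),
                             interaction = c(pupil = 0.03, scr = 0),
                             brightness_coef = -0.10,
                             sd_participant = c(subjective_valence = 1.2,
                                                subjective_arousal = 1.2,
                                                pupil = 0.08,
                                                scr = 0.30,
                                                hr = 1.5),
                             sd_stimulus = c(subjective_valence = 0.4,
                                             subjective_arousal = 0.4,
                                             pupil = 0.02,
                                             scr = 0.07,
                                             hr = 0.4),
                             sd_resid = c(subjective_valence = 1.5,
                                          subjective_arousal = 1.6,
                                          pupil = 0.15,
                                          scr = 0.35,
                                          hr = 2.5),
                             rho_va = -0.1,
                             stimulus_affect_share = 0.4,
                             scr_log_mean = log(0.3),
                             rating_limits = c(-10, 10),
                             norm_valence_mean = 5.07, norm_valence_sd = 1.92,
                             norm_arousal_mean = 4.66, norm_arousal_sd = 1.19,
                             valence_cut_points = c(4, 6),
                             arousal_cut_points = c(4.2, 5.2),
                             missing_rate = 0,
                             keep_latents = FALSE,
                             seed = NULL) {
  p <- list(n_participants = as.integer(n_participants),
            n_stimuli = as.integer(n_stimuli),
            loadings_f1 = .complete_var_vec(loadings_f1, "loadings_f1"),
            loadings_f2 = .complete_var_vec(loadings_f2, "loadings_f2"),
            interaction = .complete_var_vec(interaction, "interaction",
                                            allowed = c("pupil", "scr")),
            brightness_coef = brightness_coef,
            sd_participant = .complete_var_vec(sd_participant, "sd_participant"),
            sd_stimulus = .complete_var_vec(sd_stimulus, "sd_stimulus"),
            sd_resid = .complete_var_vec(sd_resid, "sd_resid"),
            rho_va = rho_va,
            stimulus_affect_share = stimulus_affect_share,
            scr_log_mean = scr_log_mean,
            rating_limits = sort(rating_limits),
            norm_valence_mean = norm_valence_mean,
            norm_valence_sd = norm_valence_sd,
            norm_arousal_mean = norm_arousal_mean,
            norm_arousal_sd = norm_arousal_sd,
            valence_cut_points = sort(valence_cut_points),
            arousal_cut_points = sort(arousal_cut_points),
            missing_rate = missing_rate,
            keep_latents = isTRUE(keep_latents),
            seed = if (is.null(seed)) NULL else as.integer(seed))
  class(p) <- "generator_params"
  validate_generator_params(p)
  p
}

# Fill a (possibly partial) named parameter vector up to the five affective
# variables, zero elsewhere.
.complete_var_vec <- function(x, what, allowed = .affect_vars) {
  out <- setNames(numeric(length(allowed)), allowed)
  if (length(x)) {
    if (is.null(names(x)) && length(x) == length(allowed)) {
      names(x) <- allowed
    }
    bad <- setdiff(names(x), allowed)
    if (length(bad)) {
      stop(sprintf("unknown variable(s) in %s: %s", what,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    out[names(x)] <- x
  }
  out
}

#' @rdname generator_params
#' @param x object to validate.
#' @export
validate_generator_params <- function(x) {
  stopifnot(inherits(x, "generator_params"))
  if (x$n_participants < 1L) stop("n_participants must be >= 1", call. = FALSE)
  if (x$n_stimuli < 3L) {
    stop("invalid design: n_stimuli must be >= 3 (one per valence category)",
         call. = FALSE)
  }
  if (any(x$sd_participant < 0) || any(x$sd_stimulus < 0)) {
    stop("random-intercept SDs must be nonnegative", call. = FALSE)
  }
  if (any(x$sd_resid <= 0)) stop("residual SDs must be positive", call. = FALSE)
  if (abs(x$rho_va) >= 1) {
    stop(paste0("parameterization error in the subjective residual block: ",
                "rho_va must lie in (-1, 1)"), call. = FALSE)
  }
  if (x$stimulus_affect_share < 0 || x$stimulus_affect_share > 1) {
    stop("stimulus_affect_share must be in [0, 1]", call. = FALSE)
  }
  if (x$missing_rate < 0 || x$missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  }
  # The implied linear-latent covariance is PSD by construction except for the
  # residual block, which the rho_va check above guards; verify numerically
  # anyway so bad edits fail loudly.
  ev <- eigen(.linear_latent_cov(x), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("parameterization error: implied latent covariance is not positive",
         " semi-definite", call. = FALSE)
  }
  invisible(x)
}

#' Generator parameters with no cross-variable structure
#'
#' The calibration null: all factor loadings, interaction coefficients and the
#' residual valence-arousal correlation are zero, so the five observed
#' variables are mutually independent (random intercepts and residual noise
#' remain, so the hierarchical structure is intact). Used to calibrate
#' permutation tests and mixed-model type-I error.
#'
#' @param ... overrides passed to [generator_params()].
#' @return A `generator_params` object.
#' @export
null_generator_params <- function(...) {
  zero <- setNames(numeric(5), .affect_vars)
  defaults <- list(loadings_f1 = zero, loadings_f2 = zero,
                   interaction = c(pupil = 0, scr = 0),
                   rho_va = 0, stimulus_affect_share = 0)
  args <- modifyList(defaults, list(...))
  do.call(generator_params, args)
}

#' Generate a normed stimulus set
#'
#' Draws stimulus norms from truncated normal distributions on the 1-9
#' normative scale (defaults match a typical wide-range emotional image set:
#' valence M = 5.07, SD = 1.92; arousal M = 4.66, SD = 1.19), assigns
#' valence/arousal categories from fixed cut points, and attaches an
#' independent standardized brightness covariate.
#'
#' @param n_stimuli number of stimuli (>= 3).
#' @param seed integer seed or `NULL`.
#' @param valence_cut_points,arousal_cut_points two cut points each on the 1-9
#'   scale; categories are a deterministic function of the norms given these.
#' @param norm_valence_mean,norm_valence_sd,norm_arousal_mean,norm_arousal_sd
#'   moments of the (untruncated) normative distributions.
#' @return A data.frame with columns `stimulus_id`, `norm_valence`,
#'   `norm_arousal`, `valence_category`, `arousal_category`, `brightness`.
#' @export
generate_stimuli <- function(n_stimuli = 56, seed = NULL,
                             valence_cut_points = c(4, 6),
                             arousal_cut_points = c(4.2, 5.2),
                             norm_valence_mean = 5.07, norm_valence_sd = 1.92,
                             norm_arousal_mean = 4.66, norm_arousal_sd = 1.19) {
  n_stimuli <- as.integer(n_stimuli)
  if (n_stimuli < 3L) {
    stop("invalid design: n_stimuli must be >= 3 (one per valence category)",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  nv <- .rtrunc_norm(n_stimuli, norm_valence_mean, norm_valence_sd, 1, 9)
  na <- .rtrunc_norm(n_stimuli, norm_arousal_mean, norm_arousal_sd, 1, 9)
  br <- rnorm(n_stimuli)
  data.frame(
    stimulus_id = sprintf("S%02d", seq_len(n_stimuli)),
    norm_valence = nv,
    norm_arousal = na,
    valence_category = categorize_norms(nv, sort(valence_cut_points),
                                        c("negative", "neutral", "positive")),
    arousal_category = categorize_norms(na, sort(arousal_cut_points),
                                        c("low", "medium", "high")),
    brightness = br,
    stringsAsFactors = FALSE
  )
}

#' Assign categories from norm cut points
#'
#' @param x numeric norms.
#' @param cut_points two increasing cut points.
#' @param labels three category labels (low-to-high).
#' @return factor with the three labels.
#' @export
categorize_norms <- function(x, cut_points, labels) {
  stopifnot(length(cut_points) == 2L, length(labels) == 3L)
  cut(x, breaks = c(-Inf, cut_points, Inf), labels = labels, right = TRUE)
}

.rtrunc_norm <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# Normal score of a norm value within its truncated distribution: exactly
# standard normal when norms come from .rtrunc_norm, and a deterministic
# monotone function of the norm for user-supplied stimuli.
.norm_score <- function(x, mean, sd, lo = 1, hi = 9) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  p <- (pnorm(x, mean, sd) - plo) / (phi - plo)
  qnorm(pmin(pmax(p, 1e-12), 1 - 1e-12))
}

# Stimulus affect drive: standardized combination of the norm scores
# (negative valence and high arousal increase affective intensity).
.stimulus_affect_score <- function(stimuli, params) {
  zv <- .norm_score(stimuli$norm_valence, params$norm_valence_mean,
                    params$norm_valence_sd)
  za <- .norm_score(stimuli$norm_arousal, params$norm_arousal_mean,
                    params$norm_arousal_sd)
  (-zv + za) / sqrt(2)
}

#' Generate a synthetic trial table
#'
#' Simulates one trial per participant-stimulus pair under the linear
#' two-factor latent model described in [generator_params()]. Each observed
#' variable is the sum of its factor loadings times the latent factors, a
#' participant random intercept, a stimulus random intercept, the stated
#' interaction/confound terms, and residual noise; skin conductance is
#' exponentiated from its latent scale; ratings are clipped to the slider
#' limits.
#'
#' @param stimuli a stimulus set from [generate_stimuli()] (generated from
#'   `params` when `NULL`).
#' @param params a [generator_params()] object.
#' @return A trial-table data.frame with one row per participant-stimulus
#'   pair (minus missing trials if `missing_rate > 0`) and columns
#'   `participant_id`, `stimulus_id`, `valence_category`, `arousal_category`,
#'   `subjective_valence`, `subjective_arousal`, `pupil`, `scr`, `hr`,
#'   `brightness` (plus `f1`, `f2` when `keep_latents`).
#' @export
generate_trial_table <- function(stimuli = NULL, params = generator_params()) {
  validate_generator_params(params)
  if (!is.null(params$seed)) set.seed(params$seed)
  if (is.null(stimuli)) {
    stimuli <- generate_stimuli(
      params$n_stimuli, seed = NULL,
      valence_cut_points = params$valence_cut_points,
      arousal_cut_points = params$arousal_cut_points,
      norm_valence_mean = params$norm_valence_mean,
      norm_valence_sd = params$norm_valence_sd,
      norm_arousal_mean = params$norm_arousal_mean,
      norm_arousal_sd = params$norm_arousal_sd)
  }
  n_p <- params$n_participants
  n_s <- nrow(stimuli)
  n <- n_p * n_s
  pid <- rep(sprintf("P%02d", seq_len(n_p)), each = n_s)
  sidx <- rep(seq_len(n_s), times = n_p)

  h <- params$stimulus_affect_share
  u <- .stimulus_affect_score(stimuli, params)
  f1 <- sqrt(h) * u[sidx] + sqrt(1 - h) * rnorm(n)
  f2 <- rnorm(n)

  b_part <- matrix(rnorm(n_p * 5L), n_p, 5L) %*% diag(params$sd_participant)
  b_stim <- matrix(rnorm(n_s * 5L), n_s, 5L) %*% diag(params$sd_stimulus)
  colnames(b_part) <- colnames(b_stim) <- .affect_vars

  e <- matrix(rnorm(n * 5L), n, 5L)
  # correlate the subjective residuals
  rho <- params$rho_va
  e[, 2L] <- rho * e[, 1L] + sqrt(1 - rho^2) * e[, 2L]
  e <- e %*% diag(params$sd_resid)
  colnames(e) <- .affect_vars

  lat <- outer(f1, params$loadings_f1) + outer(f2, params$loadings_f2) +
    b_part[rep(seq_len(n_p), each = n_s), ] + b_stim[sidx, ] + e
  colnames(lat) <- .affect_vars

  # valence x arousal interaction regressor on the standardized latent scale
  sig <- .linear_latent_cov(params)
  zv <- lat[, "subjective_valence"] / sqrt(sig[1L, 1L])
  za <- lat[, "subjective_arousal"] / sqrt(sig[2L, 2L])
  p_int <- zv * za

  brightness <- stimuli$brightness[sidx]
  pupil <- lat[, "pupil"] + params$interaction[["pupil"]] * p_int +
    params$brightness_coef * brightness
  scr <- exp(params$scr_log_mean + lat[, "scr"] +
               params$interaction[["scr"]] * p_int)
  lim <- params$rating_limits
  out <- data.frame(
    participant_id = pid,
    stimulus_id = stimuli$stimulus_id[sidx],
    valence_category = stimuli$valence_category[sidx],
    arousal_category = stimuli$arousal_category[sidx],
    subjective_valence = pmin(pmax(lat[, "subjective_valence"], lim[1]), lim[2]),
    subjective_arousal = pmin(pmax(lat[, "subjective_arousal"], lim[1]), lim[2]),
    pupil = pupil,
    scr = scr,
    hr = lat[, "hr"],
    brightness = brightness,
    stringsAsFactors = FALSE
  )
  if (params$keep_latents) {
    out$f1 <- f1
    out$f2 <- f2
  }
  # realized stimulus random intercepts, for analyses whose inferential
  # target is conditional on the stimulus set (see implied_covariance)
  rownames(b_stim) <- stimuli$stimulus_id
  attr(out, "stimulus_effects") <- b_stim
  if (params$missing_rate > 0) {
    keep <- runif(n) >= params$missing_rate
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}
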