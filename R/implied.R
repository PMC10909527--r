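# Population moments implied by the generator model.

# Covariance of the five linear latent variables (before the SCR
# exponentiation, pupil interaction/brightness terms and rating clipping).
# Marginally the stimulus-level component is h * l1 l1' + diag(sd_stimulus^2);
# conditional on a realized stimulus set it is replaced by the realized
# covariance of the stimulus-level means (stim_cov), with the shared factor's
# trial-level remainder (1 - h) kept marginal.
.linear_latent_cov <- function(params, stim_cov = NULL) {
  l1 <- params$loadings_f1
  l2 <- params$loadings_f2
  h <- params$stimulus_affect_share
  sig <- tcrossprod(l2) +
    diag(params$sd_participant^2 + params$sd_resid^2)
  if (is.null(stim_cov)) {
    sig <- sig + tcrossprod(l1) + diag(params$sd_stimulus^2)
  } else {
    sig <- sig + (1 - h) * tcrossprod(l1) + stim_cov
  }
  off <- params$rho_va * params$sd_resid[[1L]] * params$sd_resid[[2L]]
  sig[1L, 2L] <- sig[1L, 2L] + off
  sig[2L, 1L] <- sig[2L, 1L] + off
  dimnames(sig) <- list(.affect_vars, .affect_vars)
  sig
}

#' Population covariance of the observed variables implied by the generator
#'
#' Closed-form covariance matrix of the five observed variables
#' (`subjective_valence`, `subjective_arousal`, `pupil`, `scr`, `hr`) under a
#' [generator_params()] model: the linear-latent covariance plus exact
#' corrections for the log-normal skin-conductance transform, the pupil
#' valence-by-arousal product term, and the brightness confound. Rating
#' clipping is ignored (negligible at default scales; see the methods
#' vignette).
#'
#' With `stimuli` supplied, the stimulus-level variance component is
#' conditioned on the realized stimulus affect scores (and, when
#' `stimulus_effects` is also given, on the realized stimulus random
#' intercepts), giving the population target of analyses that treat the
#' stimulus set as fixed by design (e.g. participant-level cluster
#' bootstrap, which resamples participants only).
#'
#' @param params a [generator_params()] object.
#' @param stimuli optional stimulus set; when given, the covariance is
#'   conditional on its realized affect scores.
#' @param stimulus_effects optional realized stimulus random-intercept matrix
#'   (stimuli x variables), as attached by [generate_trial_table()] in the
#'   `"stimulus_effects"` attribute; requires `stimuli`.
#' @return A 5x5 covariance matrix with the affective variables as dimnames.
#' @export
implied_covariance <- function(params, stimuli = NULL,
                               stimulus_effects = NULL) {
  validate_generator_params(params)
  if (params$interaction[["scr"]] != 0) {
    stop("implied_covariance has a closed form only when the SCR interaction ",
         "coefficient is 0 (the log-SCR model must stay linear-Gaussian)",
         call. = FALSE)
  }
  stim_cov <- NULL
  if (!is.null(stimuli)) {
    u <- .stimulus_affect_score(stimuli, params)
    h <- params$stimulus_affect_share
    m <- outer(sqrt(h) * u, params$loadings_f1)
    if (!is.null(stimulus_effects)) {
      stopifnot(nrow(stimulus_effects) == nrow(stimuli))
      m <- m + stimulus_effects[, .affect_vars, drop = FALSE]
    }
    mc <- sweep(m, 2L, colMeans(m))
    stim_cov <- crossprod(mc) / nrow(m)
    if (is.null(stimulus_effects)) {
      stim_cov <- stim_cov + diag(params$sd_stimulus^2)
    }
    dimnames(stim_cov) <- list(.affect_vars, .affect_vars)
  } else if (!is.null(stimulus_effects)) {
    stop("stimulus_effects requires stimuli", call. = FALSE)
  }
  sig_m <- .linear_latent_cov(params)           # marginal (defines z-scaling)
  sig <- .linear_latent_cov(params, stim_cov)   # possibly conditional
  sd_vm <- sqrt(sig_m[1L, 1L])
  sd_am <- sqrt(sig_m[2L, 2L])

  # product regressor P = (N_v / sd_vm) * (N_a / sd_am); zero-mean jointly
  # normal factors give Cov(P, linear) = 0, Var(P) = v1*v2 + c^2, and
  # Cov(P, e^X) = E[e^X] * Cov(Z1, X) * Cov(Z2, X).
  v1 <- sig[1L, 1L] / sd_vm^2
  v2 <- sig[2L, 2L] / sd_am^2
  cva <- sig[1L, 2L] / (sd_vm * sd_am)
  var_p <- v1 * v2 + cva^2

  out <- sig
  bp <- params$interaction[["pupil"]]
  bb <- params$brightness_coef
  out["pupil", "pupil"] <- out["pupil", "pupil"] + bp^2 * var_p + bb^2

  # log-normal SCR: scr = exp(mu + N_s)
  s2 <- sig["scr", "scr"]
  m <- exp(s2 / 2)
  escale <- exp(params$scr_log_mean)
  for (v in .affect_vars) {
    if (v == "scr") next
    out["scr", v] <- out[v, "scr"] <- escale * m * sig["scr", v]
  }
  out["scr", "scr"] <- escale^2 * m^2 * (exp(s2) - 1)
  # pupil product term against the log-normal SCR
  c_vs <- sig[1L, "scr"] / sd_vm
  c_as <- sig[2L, "scr"] / sd_am
  out["pupil", "scr"] <- out["pupil", "scr"] + bp * escale * m * c_vs * c_as
  out["scr", "pupil"] <- out["pupil", "scr"]
  out
}

#' Population eigenstructure of the group-weighted affective space
#'
#' Computes the population analogue of the fitted MFA: the implied correlation
#' matrix of the observed variables, per-group first eigenvalues and weights,
#' and the eigenvalues of the group-weighted correlation matrix.
#'
#' @inheritParams implied_covariance
#' @param spec a [group_spec()]; only the active quantitative groups are used.
#' @return A list with `correlation`, `group_first_eigenvalues`,
#'   `group_weights`, and `eigenvalues` (of the weighted matrix, decreasing).
#' @export
implied_mfa_eigenvalues <- function(params, spec = group_spec(),
                                    stimuli = NULL, stimulus_effects = NULL) {
  sig <- implied_covariance(params, stimuli = stimuli,
                            stimulus_effects = stimulus_effects)
  r <- cov2cor(sig)
  vars <- unlist(spec$groups, use.names = FALSE)
  r <- r[vars, vars]
  lambda1 <- vapply(spec$groups, function(g) {
    eigen(r[g, g, drop = FALSE], symmetric = TRUE, only.values = TRUE)$values[1L]
  }, numeric(1))
  wcol <- rep(1 / lambda1, lengths(spec$groups))
  d <- diag(sqrt(wcol))
  ev <- eigen(d %*% r %*% d, symmetric = TRUE, only.values = TRUE)$values
  list(correlation = r,
       group_first_eigenvalues = lambda1,
       group_weights = 1 / lambda1,
       eigenvalues = ev)
}
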