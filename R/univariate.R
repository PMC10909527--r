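#' Specification of a trial-level mixed model
#'
#' @param response response column name.
#' @param fixed character vector of fixed-effect terms (R formula syntax,
#'   e.g. `"subjective_valence*subjective_arousal"`, `"brightness"`).
#' @param random grouping columns entering as crossed random intercepts.
#' @param standardize z-score the numeric predictors before fitting (the
#'   response is left on its own scale); recorded in the fit metadata.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(response, fixed,
                       random = c("participant_id", "stimulus_id"),
                       standardize = TRUE) {
  rhs <- paste(fixed, collapse = " + ")
  vars <- all.vars(as.formula(paste("~", rhs)))
  if (response %in% vars) {
    stop("response cannot appear among the fixed terms", call. = FALSE)
  }
  structure(list(response = response, fixed = fixed, random = random,
                 standardize = isTRUE(standardize),
                 predictors = vars),
            class = "model_spec")
}

#' Fit a trial-level linear mixed model with crossed random intercepts
#'
#' REML fit of `response ~ fixed + (1|participant) + (1|stimulus)` via
#' `lmerTest`, with Satterthwaite approximate p-values. Rows with missing
#' model columns are dropped and counted. Degenerate (zero) variance
#' components are reported as 0, not errors; non-convergence is flagged in
#' the metadata, never silent.
#'
#' @param table trial table.
#' @param spec a [model_spec()].
#' @return Object of class `coef_table`: data.frame `coefficients` (term,
#'   estimate, se, df, t, p), `varcor` (random-effect SDs incl. residual),
#'   `vcov` (fixed-effect covariance), `predictor_sd` (SDs used for
#'   z-scoring), `meta` (n_used, n_dropped, converged, messages, df_method,
#'   standardized).
#' @export
fit_trial_lmm <- function(table, spec) {
  stopifnot(inherits(spec, "model_spec"))
  cols <- unique(c(spec$response, spec$predictors, spec$random))
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols)) {
    stop(sprintf("missing model column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  d <- table[, cols, drop = FALSE]
  keep <- complete.cases(d)
  n_dropped <- sum(!keep)
  d <- d[keep, , drop = FALSE]
  for (g in spec$random) {
    d[[g]] <- factor(d[[g]])
    if (nlevels(d[[g]]) < 2L) {
      stop(sprintf("degenerate random structure: grouping factor %s has < 2 levels", g),
           call. = FALSE)
    }
  }
  pred_sd <- setNames(rep(NA_real_, length(spec$predictors)), spec$predictors)
  for (v in spec$predictors) {
    if (is.numeric(d[[v]])) {
      pred_sd[v] <- sd(d[[v]])
      if (spec$standardize) d[[v]] <- (d[[v]] - mean(d[[v]])) / pred_sd[v]
    }
  }
  rhs <- paste(spec$fixed, collapse = " + ")
  # rank check on the fixed design before handing to the optimizer
  mm <- model.matrix(as.formula(paste("~", rhs)), d)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    dropped_cols <- colnames(mm)[setdiff(seq_len(ncol(mm)),
                                         qr_mm$pivot[seq_len(qr_mm$rank)])]
    stop(sprintf("rank-deficient fixed design; collinear term(s): %s",
                 paste(dropped_cols, collapse = ", ")), call. = FALSE)
  }
  fml <- as.formula(paste(spec$response, "~", rhs, "+",
                          paste(sprintf("(1 | %s)", spec$random),
                                collapse = " + ")))
  fit <- lmerTest::lmer(fml, data = d, REML = TRUE)
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  converged <- is.null(msgs) && fit@optinfo$conv$opt == 0
  sm <- summary(fit)$coefficients
  co <- data.frame(term = rownames(sm),
                   estimate = sm[, "Estimate"],
                   se = sm[, "Std. Error"],
                   df = sm[, "df"],
                   t = sm[, "t value"],
                   p = pmin(pmax(sm[, "Pr(>|t|)"], .Machine$double.xmin), 1),
                   row.names = NULL)
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(coefficients = co,
                 varcor = vc[, c("grp", "sdcor")],
                 vcov = as.matrix(vcov(fit)),
                 predictor_sd = pred_sd,
                 spec = spec,
                 meta = list(n_used = nrow(d), n_dropped = n_dropped,
                             converged = converged,
                             messages = msgs %||% character(),
                             df_method = "Satterthwaite",
                             standardized = spec$standardize)),
            class = "coef_table")
}

#' @export
print.coef_table <- function(x, ...) {
  cat(sprintf("Trial-level LMM: %s ~ %s (+ crossed intercepts: %s)\n",
              x$spec$response, paste(x$spec$fixed, collapse = " + "),
              paste(x$spec$random, collapse = ", ")))
  printCoefmat(as.matrix(x$coefficients[, -1]),
               P.values = TRUE, has.Pvalue = TRUE)
  if (!x$meta$converged) cat("NOTE: convergence flagged:",
                             paste(x$meta$messages, collapse = "; "), "\n")
  invisible(x)
}

#' Fit the coherence model suite
#'
#' The trial-level models of autonomic-subjective coherence: each autonomic
#' feature regressed on subjective valence, arousal and their interaction
#' (plus brightness for pupil), the single-predictor heart-rate models, and
#' the pairwise cross-signal models -- all with crossed participant and
#' stimulus random intercepts.
#'
#' @param table trial table.
#' @param standardize z-score predictors (default TRUE).
#' @return Named list of [fit_trial_lmm()] results, class `coherence_suite`.
#' @export
coherence_model_suite <- function(table, standardize = TRUE) {
  va <- "subjective_valence * subjective_arousal"
  specs <- list(
    pupil_valence_arousal = model_spec("pupil", c(va, "brightness"),
                                       standardize = standardize),
    scr_valence_arousal = model_spec("scr", va, standardize = standardize),
    hr_valence = model_spec("hr", "subjective_valence",
                            standardize = standardize),
    hr_arousal = model_spec("hr", "subjective_arousal",
                            standardize = standardize),
    hr_valence_arousal = model_spec("hr", c("subjective_valence",
                                            "subjective_arousal"),
                                    standardize = standardize),
    scr_on_hr = model_spec("scr", "hr", standardize = standardize),
    scr_on_pupil = model_spec("scr", "pupil", standardize = standardize),
    pupil_on_hr = model_spec("pupil", "hr", standardize = standardize),
    pupil_on_scr = model_spec("pupil", "scr", standardize = standardize)
  )
  fits <- lapply(specs, function(s) fit_trial_lmm(table, s))
  class(fits) <- "coherence_suite"
  fits
}

#' Simple slopes of a moderated effect
#'
#' Slope of the focal predictor at fixed moderator levels, from a fitted
#' [fit_trial_lmm()] with a product term:
#' `slope(m) = b_focal + m * sd_moderator * b_interaction`, with delta-method
#' standard errors from the coefficient covariance.
#'
#' @param model a `coef_table`.
#' @param predictor focal predictor term name.
#' @param moderator moderator term name.
#' @param levels moderator levels in SD units (default -1 and +1).
#' @return data.frame with `level_sd`, `slope`, `se`.
#' @export
simple_slopes <- function(model, predictor, moderator, levels = c(-1, 1)) {
  stopifnot(inherits(model, "coef_table"))
  terms <- model$coefficients$term
  int_term <- c(paste(predictor, moderator, sep = ":"),
                paste(moderator, predictor, sep = ":"))
  int_term <- int_term[int_term %in% terms]
  if (!length(int_term)) {
    stop("model has no product term for this predictor/moderator pair",
         call. = FALSE)
  }
  if (!predictor %in% terms) {
    stop(sprintf("predictor %s not in model", predictor), call. = FALSE)
  }
  b <- setNames(model$coefficients$estimate, terms)
  v <- model$vcov
  # on the standardized scale the moderator SD is 1; otherwise use the
  # training SD recorded at fit time
  msd <- if (model$meta$standardized) 1 else model$predictor_sd[[moderator]]
  out <- lapply(levels, function(m) {
    w <- m * msd
    slope <- b[[predictor]] + w * b[[int_term]]
    se <- sqrt(v[predictor, predictor] + w^2 * v[int_term, int_term] +
                 2 * w * v[predictor, int_term])
    data.frame(level_sd = m, slope = slope, se = se)
  })
  do.call(rbind, out)
}
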