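#' Configuration of the full affective-space pipeline
#'
#' A validated bundle of per-stage settings. The master `seed` fully
#' determines every stochastic step: each stage draws its own child seed from
#' it through a fixed deterministic sequence, so stages are individually
#' reproducible and mutually decoupled.
#'
#' @param mode `"synthetic"` (default; the generator supplies the data) or
#'   `"real"` (read `input` as a trial-table CSV).
#' @param outdir output directory (created if needed).
#' @param input path to a trial-table CSV (real mode).
#' @param generator a [generator_params()].
#' @param preprocess a [preprocess_params()].
#' @param groups a [group_spec()].
#' @param n_boot,n_perm,alpha,strata,unit,n_dims inference settings.
#' @param split,k_range,ntree validation settings.
#' @param aggregation aggregation variants to run in addition to the
#'   trial-level fit (subset of `"participant"`, `"stimulus"`,
#'   `"participant_valence"`, `"participant_arousal"`).
#' @param brightness_adjust residualize pupil on brightness (via a crossed
#'   random-intercept model) before the MFA.
#' @param use_raw_signals synthesize raw signals and re-extract the autonomic
#'   features instead of using the generator's features directly.
#' @param seed master integer seed.
#' @param jobs parallelism degree for the resampling stages (never changes
#'   results).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "real"),
                            outdir = tempfile("affectspace_run_"),
                            input = NULL,
                            generator = generator_params(),
                            preprocess = preprocess_params(),
                            groups = group_spec(),
                            n_boot = 10000L, n_perm = 10000L, alpha = 0.05,
                            strata = c("participant_id", "valence_category"),
                            unit = "participant_id", n_dims = 2L,
                            split = 0.7, k_range = 2:8, ntree = 500L,
                            aggregation = character(),
                            brightness_adjust = TRUE,
                            use_raw_signals = FALSE,
                            seed = 1L, jobs = 1L) {
  mode <- match.arg(mode)
  if (mode == "real" && is.null(input)) {
    stop("real mode needs an input trial-table path", call. = FALSE)
  }
  structure(list(mode = mode, outdir = outdir, input = input,
                 generator = generator, preprocess = preprocess,
                 groups = groups,
                 inference = list(n_boot = as.integer(n_boot),
                                  n_perm = as.integer(n_perm),
                                  alpha = alpha, strata = strata,
                                  unit = unit, n_dims = as.integer(n_dims)),
                 validation = list(split = split, k_range = k_range,
                                   ntree = as.integer(ntree)),
                 aggregation = aggregation,
                 brightness_adjust = isTRUE(brightness_adjust),
                 use_raw_signals = isTRUE(use_raw_signals),
                 seed = as.integer(seed), jobs = as.integer(jobs)),
            class = "pipeline_config")
}

# Stage seeds: a fixed deterministic sequence from the master seed.
.stage_seed <- function(config, stage) {
  stages <- c(simulate = 1L, features = 2L, univariate = 3L, mfa = 4L,
              infer = 5L, validate = 6L)
  .child_seed(config$seed, 104729L * stages[[stage]])
}

# Residualize pupil on brightness with crossed random intercepts, so the
# luminance confound does not enter the affective space.
.residualize_pupil <- function(table) {
  fit <- lme4::lmer(pupil ~ brightness + (1 | participant_id) +
                      (1 | stimulus_id), data = table, REML = TRUE)
  adj <- table
  # keep the random-effect structure: subtract only the brightness part
  beta <- lme4::fixef(fit)[["brightness"]]
  adj$pupil <- table$pupil - beta * table$brightness
  adj
}

#' Run the full affective-space pipeline
#'
#' Executes the stages in order -- simulate/ingest, (optional) raw-signal
#' feature extraction, univariate coherence models, trial-level MFA (plus
#' requested aggregation variants), bootstrap + permutation inference, and
#' classification/clustering validation -- writing every intermediate table
#' (CSV), every report (JSON) and a run manifest into `config$outdir`.
#' Rerunning with the same config reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$outdir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  say <- function(...) {
    msg <- sprintf(...)
    message(msg)
    writeLines(msg, log_con)
  }
  stage <- "simulate"
  result <- list()
  ledger <- list()
  tryCatch({
    say("[simulate] mode = %s", config$mode)
    if (config$mode == "synthetic") {
      gp <- config$generator
      gp$seed <- .stage_seed(config, "simulate")
      stimuli <- generate_stimuli(
        gp$n_stimuli, seed = gp$seed,
        valence_cut_points = gp$valence_cut_points,
        arousal_cut_points = gp$arousal_cut_points,
        norm_valence_mean = gp$norm_valence_mean,
        norm_valence_sd = gp$norm_valence_sd,
        norm_arousal_mean = gp$norm_arousal_mean,
        norm_arousal_sd = gp$norm_arousal_sd)
      gp2 <- gp
      gp2$seed <- .child_seed(gp$seed, 1L)
      tab <- generate_trial_table(stimuli, gp2)
      result$stimuli <- stimuli
      write.csv(stimuli, file.path(config$outdir, "stimuli.csv"),
                row.names = FALSE)
    } else {
      tab <- read_trial_table(config$input)
    }
    result$trial_table <- tab
    write_trial_table(tab, file.path(config$outdir, "trial_table.csv"))
    ledger$simulate <- list(rows_in = nrow(tab), rows_used = nrow(tab),
                            rows_dropped = 0L)
    say("[simulate] %d trials", nrow(tab))

    if (config$use_raw_signals) {
      stage <- "features"
      say("[features] raw-signal round trip")
      sigs <- generate_raw_signals(tab, preprocess = config$preprocess,
                                   seed = .stage_seed(config, "features"))
      feats <- extract_trial_features(sigs, config$preprocess)
      keep_cols <- setdiff(names(tab), c("pupil", "scr", "hr"))
      tab <- merge(tab[, keep_cols],
                   feats[, c("participant_id", "stimulus_id",
                             "pupil", "scr", "hr")],
                   by = c("participant_id", "stimulus_id"), sort = TRUE)
      result$trial_table <- tab
      result$feature_quality <- attr(feats, "quality")
      .write_json(attr(feats, "quality"),
                  file.path(config$outdir, "feature_quality.json"))
      write_trial_table(tab, file.path(config$outdir,
                                       "trial_table_extracted.csv"))
      ledger$features <- list(rows_in = nrow(feats),
                              rows_used = sum(complete.cases(
                                feats[, c("pupil", "scr", "hr")])),
                              rows_dropped = sum(!complete.cases(
                                feats[, c("pupil", "scr", "hr")])))
    }

    stage <- "univariate"
    say("[univariate] coherence model suite")
    suite <- coherence_model_suite(tab)
    result$univariate <- suite
    suite_summary <- lapply(suite, function(f) {
      list(coefficients = f$coefficients, converged = f$meta$converged,
           n_used = f$meta$n_used, n_dropped = f$meta$n_dropped)
    })
    .write_json(suite_summary, file.path(config$outdir, "univariate.json"))
    for (nm in names(suite)) {
      write.csv(suite[[nm]]$coefficients,
                file.path(config$outdir, sprintf("coefficients_%s.csv", nm)),
                row.names = FALSE)
    }
    ledger$univariate <- list(rows_in = nrow(tab),
                              rows_used = suite[[1L]]$meta$n_used,
                              rows_dropped = suite[[1L]]$meta$n_dropped)

    stage <- "mfa"
    mfa_tab <- tab
    if (config$brightness_adjust && "brightness" %in% names(tab)) {
      say("[mfa] residualizing pupil on brightness")
      mfa_tab <- .residualize_pupil(tab)
    }
    say("[mfa] trial-level fit")
    fit <- fit_mfa(mfa_tab, config$groups)
    result$mfa <- fit
    .write_mfa_outputs(fit, config$outdir, "trial")
    result$mfa_variants <- list()
    for (ag in config$aggregation) {
      say("[mfa] aggregation variant: %s", ag)
      agg <- aggregate_table(mfa_tab, by = ag, spec = config$groups)
      vfit <- fit_mfa(agg, group_spec(groups = config$groups$groups,
                                      supplementary = intersect(
                                        config$groups$supplementary,
                                        names(agg))))
      result$mfa_variants[[ag]] <- vfit
      .write_mfa_outputs(vfit, config$outdir, ag)
    }
    ledger$mfa <- list(rows_in = nrow(mfa_tab),
                       rows_used = fit$meta$n_rows,
                       rows_dropped = fit$meta$n_dropped)

    stage <- "infer"
    say("[infer] %d bootstrap / %d permutation replicates",
        config$inference$n_boot, config$inference$n_perm)
    inf <- inference_report(mfa_tab, config$groups,
                            n_boot = config$inference$n_boot,
                            n_perm = config$inference$n_perm,
                            alpha = config$inference$alpha,
                            strata = config$inference$strata,
                            unit = config$inference$unit,
                            seed = .stage_seed(config, "infer"),
                            n_dims = config$inference$n_dims,
                            jobs = config$jobs)
    result$inference <- inf
    .write_json(list(eigenvalues = inf$eigenvalues,
                     p_eigenvalues_all = inf$p_eigenvalues_all,
                     loadings = lapply(inf$loadings, function(m)
                       as.data.frame(as.table(m))),
                     n_boot = inf$n_boot, n_perm = inf$n_perm,
                     n_boot_dropped = inf$n_boot_dropped,
                     alignment = inf$alignment,
                     retained = inf$retained),
                file.path(config$outdir, "inference.json"))
    write.csv(inf$eigenvalues,
              file.path(config$outdir, "inference_eigenvalues.csv"),
              row.names = FALSE)
    say("[infer] retained dimensions: %d", inf$retained)

    stage <- "validate"
    say("[validate] classification and clustering")
    n_dims <- max(config$inference$n_dims, 1L)
    sc <- result$mfa$scores[, seq_len(min(n_dims, ncol(result$mfa$scores))),
                            drop = FALSE]
    lab <- result$mfa$supp_data$valence_category
    vseed <- .stage_seed(config, "validate")
    cls <- classify_space(sc, lab, split = config$validation$split,
                          ntree = config$validation$ntree, seed = vseed)
    clu <- cluster_space(sc, k_range = config$validation$k_range,
                         labels = lab, seed = .child_seed(vseed, 1L))
    result$classification <- cls
    result$clustering <- clu
    .write_json(list(
      classification = list(oob_accuracy = cls$oob_accuracy,
                            test_accuracy = cls$test_accuracy,
                            auc = as.list(cls$auc),
                            importance = as.list(cls$importance),
                            chisq = cls$chisq),
      clustering = list(k = clu$k, silhouette = clu$silhouette,
                        between_variance_pct = clu$between_variance_pct,
                        by_k = clu$by_k, chisq = clu$chisq)),
      file.path(config$outdir, "validation.json"))
    write.csv(as.data.frame(cls$confusion),
              file.path(config$outdir, "confusion.csv"), row.names = FALSE)
    if (!is.null(clu$contingency)) {
      write.csv(as.data.frame(clu$contingency),
                file.path(config$outdir, "cluster_contingency.csv"),
                row.names = FALSE)
    }

    manifest <- list(
      package_version = as.character(utils::packageVersion("affectspace")),
      mode = config$mode,
      seed = config$seed,
      stage_seeds = lapply(setNames(nm = c("simulate", "features",
                                           "univariate", "mfa", "infer",
                                           "validate")),
                           function(s) .stage_seed(config, s)),
      inference = config$inference,
      validation = config$validation,
      aggregation = config$aggregation,
      brightness_adjust = config$brightness_adjust,
      row_ledger = ledger,
      warnings = list(bootstrap_replicates_dropped = inf$n_boot_dropped)
    )
    .write_json(manifest, file.path(config$outdir, "manifest.json"))
    say("[done] all stages complete")
    message(sprintf("outputs in %s", config$outdir))
  }, error = function(e) {
    stop(sprintf("pipeline aborted in stage '%s': %s (partial outputs in %s)",
                 stage, conditionMessage(e), config$outdir), call. = FALSE)
  })
  invisible(result)
}

.write_mfa_outputs <- function(fit, outdir, tag) {
  pre <- function(name) file.path(outdir, sprintf("mfa_%s_%s.csv", tag, name))
  write.csv(data.frame(dim = seq_along(fit$eigenvalues),
                       eigenvalue = fit$eigenvalues,
                       percent_variance = fit$percent_variance),
            pre("eigenvalues"), row.names = FALSE)
  vs <- data.frame(variable = rownames(fit$variables$correlation),
                   fit$variables$correlation,
                   cos2 = fit$variables$cos2,
                   contribution = fit$variables$contribution)
  write.csv(vs, pre("variables"), row.names = FALSE)
  gs <- data.frame(group = rownames(fit$groups$contribution),
                   weight = fit$groups$weights,
                   fit$groups$contribution)
  write.csv(gs, pre("groups"), row.names = FALSE)
  write.csv(data.frame(fit$supp_data, fit$scores), pre("scores"),
            row.names = FALSE)
  write.csv(fit$partial_axes, pre("partial_axes"), row.names = FALSE)
  for (g in names(fit$partial_coordinates)) {
    write.csv(data.frame(fit$supp_data, fit$partial_coordinates[[g]]),
              pre(sprintf("partial_%s", g)), row.names = FALSE)
  }
  .write_json(list(eigenvalues = fit$eigenvalues,
                   percent_variance = fit$percent_variance,
                   group_weights = as.list(fit$groups$weights),
                   group_contribution = as.data.frame(fit$groups$contribution),
                   n_rows = fit$meta$n_rows,
                   n_dropped = fit$meta$n_dropped,
                   aggregation = fit$meta$aggregation),
              file.path(outdir, sprintf("mfa_%s.json", tag)))
  invisible(NULL)
}
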