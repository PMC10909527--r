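# Hierarchy-respecting resampling inference for the affective-space MFA.

# Greedy one-to-one matching of candidate to reference dimensions by
# |correlation| between loading vectors. Returns the permutation (candidate
# dim matched to each reference dim, NA when exhausted) and the sign flips.
.match_dims <- function(ref_cors, cand_cors, n_dims) {
  n_ref <- min(n_dims, ncol(ref_cors))
  n_cand <- ncol(cand_cors)
  sim <- matrix(NA_real_, n_ref, n_cand)
  for (k in seq_len(n_ref)) {
    for (l in seq_len(n_cand)) {
      sim[k, l] <- suppressWarnings(cor(ref_cors[, k], cand_cors[, l]))
    }
  }
  sim[!is.finite(sim)] <- 0
  perm <- rep(NA_integer_, n_dims)
  signs <- rep(1, n_dims)
  left <- matrix(TRUE, n_ref, n_cand)
  for (step in seq_len(min(n_ref, n_cand))) {
    masked <- abs(sim)
    masked[!left] <- -Inf
    best <- arrayInd(which.max(masked), dim(masked))
    k <- best[1L]; l <- best[2L]
    perm[k] <- l
    signs[k] <- if (sim[k, l] < 0) -1 else 1
    left[k, ] <- FALSE
    left[, l] <- FALSE
  }
  list(permutation = perm, signs = signs)
}

#' Align a resampled MFA solution to a reference solution
#'
#' Reorders and sign-flips the candidate's dimensions to maximize the sum of
#' absolute correlations between reference and candidate loading vectors
#' (greedy one-to-one matching over the first `n_dims`). Required so that
#' resampling quantiles refer to the same dimension across replicates;
#' deterministic given its inputs. If the candidate has fewer dimensions than
#' `n_dims`, the missing ones are padded with `NA`.
#'
#' @param reference,candidate fitted [fit_mfa()] objects on the same
#'   variables.
#' @param n_dims number of leading reference dimensions to match.
#' @return A list: `candidate` (with `eigenvalues`, `percent_variance`,
#'   correlations, contributions, cos2 and scores reordered/flipped over the
#'   first `n_dims`), `permutation`, `signs`, `swapped`, `flipped`.
#' @export
align_solution <- function(reference, candidate, n_dims = 2L) {
  stopifnot(inherits(reference, "mfa"), inherits(candidate, "mfa"))
  ref_cors <- reference$variables$correlation
  cand_cors <- candidate$variables$correlation
  if (!identical(rownames(ref_cors), rownames(cand_cors))) {
    stop("reference and candidate must share the same variables",
         call. = FALSE)
  }
  m <- .match_dims(ref_cors, cand_cors, n_dims)
  perm <- m$permutation
  signs <- m$signs
  take <- function(mat, flip = TRUE) {
    out <- matrix(NA_real_, nrow(mat), n_dims,
                  dimnames = list(rownames(mat), paste0("dim", seq_len(n_dims))))
    ok <- which(!is.na(perm))
    out[, ok] <- mat[, perm[ok], drop = FALSE]
    if (flip) out[, ok] <- sweep(out[, ok, drop = FALSE], 2L, signs[ok], `*`)
    out
  }
  cand <- candidate
  ok <- which(!is.na(perm))
  ev <- rep(NA_real_, n_dims)
  ev[ok] <- candidate$eigenvalues[perm[ok]]
  cand$eigenvalues_aligned <- ev
  cand$variables$correlation <- take(cand_cors)
  cand$variables$cos2 <- take(candidate$variables$cos2, flip = FALSE)
  cand$variables$contribution <- take(candidate$variables$contribution,
                                      flip = FALSE)
  if (!is.null(candidate$scores)) cand$scores <- take(candidate$scores)
  list(candidate = cand,
       permutation = perm,
       signs = signs,
       swapped = !identical(perm[ok], seq_along(perm)[ok]),
       flipped = any(signs[ok] < 0))
}

.child_seed <- function(seed, i) {
  as.integer((as.double(seed) + 1009 * as.double(i)) %% 2147483629)
}

.resample_lapply <- function(n, fun, jobs) {
  if (jobs > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(n), fun, mc.cores = jobs)
  } else {
    lapply(seq_len(n), fun)
  }
}

#' Participant-level (cluster) bootstrap of the MFA
#'
#' Resamples the higher-level units (participants by default) with
#' replacement -- every trial of a sampled unit travels with it -- refits the
#' MFA on each replicate, aligns the replicate to the reference solution, and
#' returns percentile 95% confidence intervals for eigenvalues and
#' variable-dimension correlations.
#'
#' By default a second resampling stage draws trials with replacement within
#' each sampled participant: with ~50 clusters and a smooth nonlinear
#' eigen-statistic, single-stage percentile intervals are measurably
#' narrower than the sampling dispersion of the estimate, and the second
#' stage restores near-nominal coverage (see the methods vignette). Set
#' `resample_trials = FALSE` for the plain cluster bootstrap.
#'
#' Replicate seeds are derived deterministically from `seed`, so results are
#' reproducible bit-for-bit for any parallelism degree.
#'
#' @param table trial table.
#' @param spec a [group_spec()].
#' @param n_boot number of bootstrap replicates (>= 1).
#' @param unit grouping column to resample (default participants).
#' @param seed integer seed.
#' @param n_dims dimensions tracked/aligned.
#' @param resample_trials add a second resampling stage (trials with
#'   replacement within each sampled unit).
#' @param jobs parallelism degree (never changes results).
#' @return Object of class `affect_boot`: reference point estimates, CI
#'   tables, raw replicate draws, alignment diagnostics and the count of
#'   dropped (degenerate) replicates.
#' @export
cluster_bootstrap <- function(table, spec = group_spec(), n_boot = 10000L,
                              unit = "participant_id", seed = 1L,
                              n_dims = 2L, resample_trials = TRUE,
                              jobs = 1L) {
  stopifnot(n_boot >= 1L)
  if (!unit %in% names(table)) {
    stop(sprintf("resampling unit column not in table: %s", unit),
         call. = FALSE)
  }
  units <- unique(table[[unit]])
  if (length(units) < 5L) {
    stop("need at least 5 resampling units for a cluster bootstrap",
         call. = FALSE)
  }
  rows_by_unit <- split(seq_len(nrow(table)), table[[unit]])[as.character(units)]
  reference <- fit_mfa(table, spec)
  ref_cors <- reference$variables$correlation[, seq_len(n_dims), drop = FALSE]
  vars <- rownames(ref_cors)

  one <- function(b) {
    set.seed(.child_seed(seed, b))
    draw <- sample(length(units), replace = TRUE)
    idx <- if (resample_trials) {
      unlist(lapply(rows_by_unit[draw],
                    function(r) r[sample.int(length(r), replace = TRUE)]),
             use.names = FALSE)
    } else {
      unlist(rows_by_unit[draw], use.names = FALSE)
    }
    am <- tryCatch(.active_matrix(table[idx, , drop = FALSE], spec),
                   error = function(e) NULL)
    if (is.null(am)) return(NULL)
    eng <- .mfa_engine(am$x, spec)
    if (inherits(eng, "mfa_degenerate")) return(NULL)
    m <- .match_dims(ref_cors, eng$cors, n_dims)
    ok <- !is.na(m$permutation)
    ev <- rep(NA_real_, n_dims)
    ev[ok] <- eng$eigenvalues[m$permutation[ok]]
    cors <- matrix(NA_real_, length(vars), n_dims)
    cors[, ok] <- sweep(eng$cors[, m$permutation[ok], drop = FALSE], 2L,
                        m$signs[ok], `*`)
    list(eigenvalues = ev, cors = cors,
         swapped = !identical(m$permutation[ok], seq_len(n_dims)[ok]),
         flipped = any(m$signs[ok] < 0))
  }
  draws <- .resample_lapply(n_boot, one, jobs)
  dropped <- sum(vapply(draws, is.null, logical(1)))
  draws <- Filter(Negate(is.null), draws)
  if (!length(draws)) stop("all bootstrap replicates degenerate", call. = FALSE)
  evals <- do.call(rbind, lapply(draws, `[[`, "eigenvalues"))
  cors <- array(unlist(lapply(draws, `[[`, "cors")),
                dim = c(length(vars), n_dims, length(draws)))
  ci <- function(v) quantile(v, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  eig_ci <- t(apply(evals, 2L, ci))
  cor_ci_lo <- apply(cors, c(1L, 2L), function(v) ci(v)[1L])
  cor_ci_hi <- apply(cors, c(1L, 2L), function(v) ci(v)[2L])
  dimnames(cor_ci_lo) <- dimnames(cor_ci_hi) <-
    list(vars, paste0("dim", seq_len(n_dims)))
  structure(list(
    reference = reference,
    n_boot = n_boot,
    n_used = length(draws),
    n_dropped = dropped,
    eigenvalues = data.frame(
      dim = seq_len(n_dims),
      estimate = reference$eigenvalues[seq_len(n_dims)],
      ci_lower = eig_ci[, 1L],
      ci_upper = eig_ci[, 2L]),
    loadings_ci = list(lower = cor_ci_lo, upper = cor_ci_hi,
                       estimate = ref_cors),
    draws = list(eigenvalues = evals, cors = cors),
    alignment = list(
      prop_swapped = mean(vapply(draws, `[[`, logical(1), "swapped")),
      prop_flipped = mean(vapply(draws, `[[`, logical(1), "flipped"))),
    unit = unit, seed = seed
  ), class = "affect_boot")
}

#' Stratified-permutation null distribution for the MFA eigenstructure
#'
#' For each replicate every active quantitative column is independently
#' permuted within the given strata (breaking cross-variable association
#' while preserving each column's within-stratum multiset and the stratum
#' composition), the MFA is refitted, and one-tailed add-one p-values are
#' computed for the eigen spectrum and the absolute loadings:
#' `p = (1 + #\{null >= observed\}) / (n_perm + 1)`.
#'
#' Two hierarchy-respecting schemes are available. The default,
#' `"stimulus_blocks"`, relabels each column's stimulus blocks within
#' stimulus category, consistently across participants: a coherent subgroup
#' of the within-stratum permutations (each participant-by-category multiset
#' is still preserved exactly) that also preserves the cross-participant
#' coherence of stimulus-level effects, which makes it calibrated under a
#' crossed participant/stimulus random-effects null. `"within_strata"`
#' permutes rows freely within each stratum; it is included for comparison
#' but destroys stimulus-level alignment, which inflates the observed
#' statistic relative to its null draws in crossed designs (see the methods
#' vignette).
#'
#' The primary eigen statistic is the percent-of-inertia share of each
#' dimension, not the raw eigenvalue: the group weights `1/lambda1(g)` of a
#' column-permuted table differ systematically from the observed ones (each
#' permuted group decorrelates, pushing `lambda1(g)` to 1), so raw
#' eigenvalues of observed and null fits live on different total-inertia
#' scales and a genuinely structured later dimension could sit below every
#' null draw. The share statistic is scale-free (null expectation = 100 /
#' n_variables %). Raw-eigenvalue p-values are reported alongside
#' (`p_eigenvalues_raw`).
#'
#' Null replicates are compared to the observed solution dimension-by-rank
#' (no alignment: aligning null draws to the reference would inflate the null
#' by selection). Singleton strata are unpermutable; they stay fixed and a
#' warning is issued.
#'
#' @param table trial table.
#' @param spec a [group_spec()].
#' @param strata character vector of stratum-defining columns (default:
#'   participant crossed with valence category).
#' @param n_perm number of permutation replicates (>= 1).
#' @param seed integer seed.
#' @param n_dims dimensions for which loading p-values are reported.
#' @param scheme `"stimulus_blocks"` (default) or `"within_strata"`; see
#'   Details.
#' @param participant_col,stimulus_col identifier columns used by the
#'   stimulus-block scheme.
#' @param jobs parallelism degree (never changes results).
#' @return Object of class `affect_perm` with observed eigenvalues, per-dim
#'   permutation p-values, loading p-values, and the null draws.
#' @export
permutation_null <- function(table, spec = group_spec(),
                             strata = c("participant_id", "valence_category"),
                             n_perm = 10000L, seed = 1L, n_dims = 2L,
                             scheme = c("stimulus_blocks", "within_strata"),
                             participant_col = "participant_id",
                             stimulus_col = "stimulus_id",
                             jobs = 1L) {
  scheme <- match.arg(scheme)
  if (n_perm < 1L) stop("n_perm must be >= 1 (p undefined otherwise)",
                        call. = FALSE)
  missing_cols <- setdiff(strata, names(table))
  if (length(missing_cols)) {
    stop(sprintf("strata column(s) not in table: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  am <- .active_matrix(table, spec)
  x <- am$x
  n <- nrow(x)
  g <- interaction(table[am$keep, strata, drop = FALSE], drop = TRUE)
  sizes <- table(g)
  if (any(sizes < 2L)) {
    warning(sprintf("%d singleton stratum(-a): those rows stay fixed",
                    sum(sizes < 2L)))
  }
  obs <- .mfa_engine(x, spec)
  if (inherits(obs, "mfa_degenerate")) {
    stop(sprintf("zero-variance column(s): %s",
                 paste(obs$zero_variance, collapse = ", ")), call. = FALSE)
  }
  p <- ncol(x)
  obs_evals <- obs$eigenvalues
  obs_shares <- 100 * obs_evals / sum(obs_evals)
  obs_cors_abs <- abs(obs$cors[, seq_len(n_dims), drop = FALSE])

  if (scheme == "stimulus_blocks") {
    tab_kept <- table[am$keep, , drop = FALSE]
    need <- setdiff(c(participant_col, stimulus_col), names(tab_kept))
    if (length(need)) {
      stop(sprintf("stimulus-block scheme needs column(s): %s",
                   paste(need, collapse = ", ")), call. = FALSE)
    }
    sid <- factor(tab_kept[[stimulus_col]])
    pid <- factor(tab_kept[[participant_col]])
    # category of each stimulus from the non-participant strata columns
    cat_cols <- setdiff(strata, participant_col)
    scat <- if (length(cat_cols)) {
      cc <- interaction(tab_kept[, cat_cols, drop = FALSE], drop = TRUE)
      per_stim <- tapply(as.character(cc), sid, function(v) v[1L])
      consistent <- tapply(as.character(cc), sid,
                           function(v) length(unique(v)) == 1L)
      if (!all(consistent)) {
        stop("stratum columns are not constant within stimulus; ",
             "use scheme = 'within_strata'", call. = FALSE)
      }
      factor(per_stim[levels(sid)])
    } else {
      factor(rep("all", nlevels(sid)))
    }
    # row lookup (stimulus x participant); NA for missing cells
    lookup <- matrix(NA_integer_, nlevels(sid), nlevels(pid))
    lookup[cbind(as.integer(sid), as.integer(pid))] <- seq_len(n)
    s_levels <- seq_len(nlevels(sid))
    cat_groups <- split(s_levels, scat)
    si <- as.integer(sid)
    pi_ <- as.integer(pid)
    one_perm_col <- function() {
      pp <- s_levels
      for (grp in cat_groups) {
        if (length(grp) > 1L) pp[grp] <- grp[sample.int(length(grp))]
      }
      src <- lookup[cbind(pp[si], pi_)]
      fix <- is.na(src)
      src[fix] <- which(fix)
      src
    }
    one <- function(r) {
      set.seed(.child_seed(seed, r))
      xp <- x
      for (j in seq_len(p)) xp[, j] <- x[one_perm_col(), j]
      eng <- .mfa_engine(xp, spec)
      if (inherits(eng, "mfa_degenerate")) return(NULL)
      list(eigenvalues = eng$eigenvalues,
           cors_abs = abs(eng$cors[, seq_len(n_dims), drop = FALSE]))
    }
  } else {
    s0 <- order(g)
    one <- function(r) {
      set.seed(.child_seed(seed, r))
      xp <- x
      for (j in seq_len(p)) {
        s <- order(g, runif(n))
        xp[s, j] <- x[s0, j]
      }
      eng <- .mfa_engine(xp, spec)
      if (inherits(eng, "mfa_degenerate")) return(NULL)
      list(eigenvalues = eng$eigenvalues,
           cors_abs = abs(eng$cors[, seq_len(n_dims), drop = FALSE]))
    }
  }
  draws <- Filter(Negate(is.null), .resample_lapply(n_perm, one, jobs))
  n_used <- length(draws)
  null_evals <- do.call(rbind, lapply(draws, `[[`, "eigenvalues"))
  null_shares <- 100 * null_evals / rowSums(null_evals)
  p_eigen <- vapply(seq_along(obs_shares), function(k) {
    (1 + sum(null_shares[, k] >= obs_shares[k])) / (n_used + 1)
  }, numeric(1))
  p_eigen_raw <- vapply(seq_along(obs_evals), function(k) {
    (1 + sum(null_evals[, k] >= obs_evals[k])) / (n_used + 1)
  }, numeric(1))
  null_cors <- array(unlist(lapply(draws, `[[`, "cors_abs")),
                     dim = c(p, n_dims, n_used))
  p_load <- matrix(NA_real_, p, n_dims,
                   dimnames = list(colnames(x), paste0("dim", seq_len(n_dims))))
  for (j in seq_len(p)) {
    for (k in seq_len(n_dims)) {
      p_load[j, k] <- (1 + sum(null_cors[j, k, ] >= obs_cors_abs[j, k])) /
        (n_used + 1)
    }
  }
  structure(list(
    observed_eigenvalues = obs_evals,
    observed_shares = obs_shares,
    p_eigenvalues = p_eigen,
    p_eigenvalues_raw = p_eigen_raw,
    observed_loadings = obs$cors[, seq_len(n_dims), drop = FALSE],
    p_loadings = p_load,
    null_eigenvalues = null_evals,
    null_shares = null_shares,
    n_perm = n_used,
    scheme = scheme,
    strata = strata, seed = seed
  ), class = "affect_perm")
}

#' Number of retained dimensions at level alpha
#'
#' Counts the leading consecutive dimensions whose eigenvalue permutation
#' p-value is below `alpha` (a later significant dimension after a
#' non-significant one does not reopen the count).
#'
#' @param report an `affect_perm`, `inference_report`, or a numeric vector of
#'   per-dimension p-values.
#' @param alpha significance level.
#' @return Integer count.
#' @export
retained_dimensions <- function(report, alpha = 0.05) {
  p <- if (is.numeric(report)) report
  else if (inherits(report, "affect_perm")) report$p_eigenvalues
  else if (inherits(report, "inference_report")) report$eigenvalues$perm_p
  else stop("no permutation p-values found", call. = FALSE)
  below <- p < alpha
  if (!length(below) || !below[1L]) return(0L)
  runs <- rle(below)
  as.integer(runs$lengths[1L])
}

#' Combined bootstrap + permutation inference report
#'
#' Runs [cluster_bootstrap()] and [permutation_null()] on the same table and
#' assembles the per-eigenvalue and per-loading point estimates, 95%
#' percentile CIs and one-tailed permutation p-values, alignment diagnostics,
#' and the retained-dimension count.
#'
#' @inheritParams cluster_bootstrap
#' @inheritParams permutation_null
#' @param alpha level for the retained-dimension rule.
#' @return Object of class `inference_report`.
#' @export
inference_report <- function(table, spec = group_spec(), n_boot = 10000L,
                             n_perm = 10000L, alpha = 0.05,
                             strata = c("participant_id", "valence_category"),
                             unit = "participant_id", seed = 1L, n_dims = 2L,
                             scheme = c("stimulus_blocks", "within_strata"),
                             jobs = 1L) {
  scheme <- match.arg(scheme)
  boot <- cluster_bootstrap(table, spec, n_boot = n_boot, unit = unit,
                            seed = seed, n_dims = n_dims, jobs = jobs)
  perm <- permutation_null(table, spec, strata = strata, n_perm = n_perm,
                           seed = .child_seed(seed, 777L), n_dims = n_dims,
                           scheme = scheme, jobs = jobs)
  eig <- boot$eigenvalues
  eig$perm_p <- perm$p_eigenvalues[seq_len(n_dims)]
  eig$ci_violation <- eig$estimate < eig$ci_lower | eig$estimate > eig$ci_upper
  if (any(eig$ci_violation)) {
    warning("point estimate outside its aligned bootstrap CI (flagged)")
  }
  structure(list(
    eigenvalues = eig,
    p_eigenvalues_all = perm$p_eigenvalues,
    loadings = list(estimate = boot$loadings_ci$estimate,
                    ci_lower = boot$loadings_ci$lower,
                    ci_upper = boot$loadings_ci$upper,
                    perm_p = perm$p_loadings),
    n_boot = boot$n_used, n_perm = perm$n_perm,
    n_boot_dropped = boot$n_dropped,
    alignment = boot$alignment,
    alpha = alpha,
    retained = retained_dimensions(perm$p_eigenvalues, alpha),
    seed = seed
  ), class = "inference_report")
}

#' @export
print.inference_report <- function(x, ...) {
  cat("Affective-space inference (", x$n_boot, " bootstrap, ", x$n_perm,
      " permutation replicates)\n", sep = "")
  print(transform(x$eigenvalues, perm_p = format.pval(perm_p)))
  cat("Retained dimensions at alpha =", x$alpha, ":", x$retained, "\n")
  invisible(x)
}
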