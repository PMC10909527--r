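#' Variable-group specification for the affective-space MFA
#'
#' Partitions the quantitative columns of a trial table into named groups
#' (by default the autonomic features and the subjective ratings), and lists
#' categorical columns to project as supplementary (never used in fitting).
#'
#' @param groups named list of character vectors; disjoint, non-empty.
#' @param supplementary categorical columns projected post hoc.
#' @return An object of class `group_spec`.
#' @export
group_spec <- function(groups = list(
                         subjective = c("subjective_valence",
                                        "subjective_arousal"),
                         autonomic = c("pupil", "scr", "hr")),
                       supplementary = c("valence_category",
                                         "arousal_category",
                                         "participant_id", "stimulus_id")) {
  if (!length(groups) || is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("groups must be a non-empty named list", call. = FALSE)
  }
  if (any(lengths(groups) == 0L)) stop("empty variable group", call. = FALSE)
  all_vars <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_vars)) {
    stop("variable groups must be disjoint", call. = FALSE)
  }
  if (length(intersect(all_vars, supplementary))) {
    stop("supplementary columns cannot be in an active group", call. = FALSE)
  }
  structure(list(groups = groups, supplementary = supplementary),
            class = "group_spec")
}

# Extract and validate the active-variable matrix: complete cases only,
# every column present with nonzero variance.
.active_matrix <- function(table, spec) {
  vars <- unlist(spec$groups, use.names = FALSE)
  missing_cols <- setdiff(vars, names(table))
  if (length(missing_cols)) {
    stop(sprintf("missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  x <- as.matrix(table[, vars, drop = FALSE])
  if (!is.numeric(x)) stop("active columns must be numeric", call. = FALSE)
  keep <- complete.cases(x)
  n_dropped <- sum(!keep)
  x <- x[keep, , drop = FALSE]
  if (nrow(x) < 3L) stop("need at least 3 complete rows", call. = FALSE)
  sds <- apply(x, 2L, sd)
  if (any(sds == 0)) {
    stop(sprintf("zero-variance column(s): %s",
                 paste(vars[sds == 0], collapse = ", ")), call. = FALSE)
  }
  list(x = x, keep = keep, n_dropped = n_dropped, vars = vars)
}

#' Standardize active variables and apply MFA group weights
#'
#' Each active column is centered and scaled to unit variance; each group's
#' columns are then multiplied by `1/sqrt(lambda1(g))`, where `lambda1(g)` is
#' the first eigenvalue of the group's standardized covariance, so that after
#' weighting every group's sub-table has first eigenvalue exactly 1 and no
#' group can dominate the global decomposition.
#'
#' @param table a trial table (data.frame).
#' @param spec a [group_spec()].
#' @return A list: `x_weighted` (n x p matrix), `group_first_eigenvalues`,
#'   `group_weights` (`1/lambda1`), `column_weights` (per active column),
#'   `centers`, `scales`, `rows_kept` (logical on the input rows),
#'   `n_dropped`.
#' @export
standardize_and_weight <- function(table, spec = group_spec()) {
  am <- .active_matrix(table, spec)
  z <- scale(am$x)
  n <- nrow(z)
  lambda1 <- vapply(spec$groups, function(g) {
    zg <- z[, g, drop = FALSE]
    eigen(crossprod(zg) / (n - 1), symmetric = TRUE,
          only.values = TRUE)$values[1L]
  }, numeric(1))
  wcol <- setNames(rep(1 / lambda1, lengths(spec$groups)), am$vars)
  xw <- sweep(z, 2L, sqrt(wcol), `*`)
  list(x_weighted = xw,
       group_first_eigenvalues = lambda1,
       group_weights = 1 / lambda1,
       column_weights = wcol,
       centers = attr(z, "scaled:center"),
       scales = attr(z, "scaled:scale"),
       rows_kept = am$keep,
       n_dropped = am$n_dropped)
}

# Core decomposition shared by fit_mfa and the resampling layer.
# Takes a complete numeric matrix (columns ordered as unlist(groups)).
# Returns eigenvalues, eigenvectors (weighted space), variable-dimension
# correlations and column weights, with a deterministic sign convention:
# the variable with the largest |correlation| loads positively.
.mfa_engine <- function(x, spec) {
  n <- nrow(x)
  vars <- colnames(x)
  z <- scale(x)
  sds <- attr(z, "scaled:scale")
  if (any(sds == 0)) {
    return(structure(list(zero_variance = vars[sds == 0]),
                     class = "mfa_degenerate"))
  }
  lambda1 <- vapply(spec$groups, function(g) {
    zg <- z[, g, drop = FALSE]
    eigen(crossprod(zg) / (n - 1), symmetric = TRUE,
          only.values = TRUE)$values[1L]
  }, numeric(1))
  wcol <- rep(1 / lambda1, lengths(spec$groups))
  xw <- sweep(z, 2L, sqrt(wcol), `*`)
  cmat <- crossprod(xw) / (n - 1)
  ee <- eigen(cmat, symmetric = TRUE)
  evals <- pmax(ee$values, 0)
  v <- ee$vectors
  # correlation of (unweighted, standardized) variable j with dimension s:
  # sqrt(lambda_s) * v_js / sqrt(w_j)
  cors <- sweep(sweep(v, 2L, sqrt(evals), `*`), 1L, sqrt(wcol), `/`)
  for (s in seq_along(evals)) {
    if (evals[s] <= .Machine$double.eps) next
    j <- which.max(abs(cors[, s]))
    if (cors[j, s] < 0) {
      v[, s] <- -v[, s]
      cors[, s] <- -cors[, s]
    }
  }
  dimnames(v) <- list(vars, paste0("dim", seq_along(evals)))
  dimnames(cors) <- dimnames(v)
  list(eigenvalues = evals, vectors = v, cors = cors,
       column_weights = setNames(wcol, vars),
       group_first_eigenvalues = lambda1,
       z = z, x_weighted = xw)
}

#' Fit the group-weighted Multiple Factor Analysis
#'
#' Centers and scales every active column, weights each group by the inverse
#' of its first separate eigenvalue, and eigendecomposes the weighted
#' covariance. Reports eigenvalues, percent variance, row scores, per-variable
#' correlations/cos2/contributions, per-group weights and contributions,
#' partial row coordinates per group, partial-axes correlations, and
#' supplementary category barycentres.
#'
#' Dimension signs follow a deterministic convention (the variable with the
#' largest absolute correlation loads positively), so results are
#' platform-stable.
#'
#' @param table trial table (data.frame); rows with a missing active cell are
#'   dropped with a logged count.
#' @param spec a [group_spec()].
#' @param n_dims number of dimensions to retain in the output (all by
#'   default; truncated to the rank with a warning if larger).
#' @return An object of class `mfa`, a list with fields `eigenvalues`,
#'   `percent_variance`, `scores`, `variables` (correlation, cos2,
#'   contribution arrays), `groups` (weights, contributions),
#'   `partial_coordinates` (list per group), `partial_axes`, `supplementary`,
#'   and `meta`.
#' @export
fit_mfa <- function(table, spec = group_spec(), n_dims = NULL) {
  am <- .active_matrix(table, spec)
  eng <- .mfa_engine(am$x, spec)
  if (inherits(eng, "mfa_degenerate")) {
    stop(sprintf("zero-variance column(s): %s",
                 paste(eng$zero_variance, collapse = ", ")), call. = FALSE)
  }
  evals <- eng$eigenvalues
  rank <- sum(evals > max(evals) * 1e-12)
  if (is.null(n_dims)) n_dims <- rank
  if (n_dims > rank) {
    warning(sprintf("n_dims = %d exceeds rank %d; truncated", n_dims, rank))
    n_dims <- rank
  }
  ds <- seq_len(n_dims)
  v <- eng$vectors[, ds, drop = FALSE]
  cors <- eng$cors[, ds, drop = FALSE]
  scores <- eng$x_weighted %*% v
  colnames(scores) <- colnames(v)

  contrib <- 100 * v^2
  cos2 <- cors^2
  gindex <- rep(names(spec$groups), lengths(spec$groups))
  gcontrib <- rowsum(contrib, gindex)[names(spec$groups), , drop = FALSE]

  n_groups <- length(spec$groups)
  partial <- lapply(spec$groups, function(g) {
    pc <- n_groups * eng$x_weighted[, g, drop = FALSE] %*%
      v[g, , drop = FALSE]
    colnames(pc) <- colnames(v)
    pc
  })

  supp_data <- table[am$keep, intersect(spec$supplementary, names(table)),
                     drop = FALSE]

  res <- structure(list(
    eigenvalues = evals,
    percent_variance = 100 * evals / sum(evals),
    n_dims = n_dims,
    scores = scores,
    variables = list(correlation = cors, cos2 = cos2, contribution = contrib),
    groups = list(weights = eng$group_first_eigenvalues^-1,
                  first_eigenvalues = eng$group_first_eigenvalues,
                  contribution = gcontrib),
    column_weights = eng$column_weights,
    vectors = v,
    partial_coordinates = partial,
    supp_data = supp_data,
    spec = spec,
    meta = list(n_rows = nrow(scores), n_dropped = am$n_dropped,
                aggregation = attr(table, "aggregation") %||% "trial")
  ), class = "mfa")
  res$partial_axes <- partial_axes(res, table[am$keep, , drop = FALSE], spec)
  res$supplementary <- lapply(
    setNames(nm = intersect(spec$supplementary, names(supp_data))),
    function(col) project_supplementary(res, col))
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mfa <- function(x, ...) {
  cat("Multiple Factor Analysis (", x$meta$n_rows, " rows, ",
      length(x$spec$groups), " groups, ", x$n_dims, " dims)\n", sep = "")
  cat("Eigenvalues:", format(round(x$eigenvalues, 4)), "\n")
  cat("Percent variance:", format(round(x$percent_variance, 2)), "\n")
  cat("Group contributions (%):\n")
  print(round(x$groups$contribution, 2))
  invisible(x)
}

#' Per-group partial row coordinates
#'
#' The partial coordinate of a row for group g is the number of groups times
#' the projection of the row's group-g weighted profile onto the global axes;
#' partial coordinates average across groups to the global coordinate
#' (barycentre identity).
#'
#' @param result a fitted [fit_mfa()] object.
#' @return Named list (one matrix per group) of partial coordinates.
#' @export
partial_coordinates <- function(result) {
  stopifnot(inherits(result, "mfa"))
  result$partial_coordinates
}

#' Correlations between separate-group PCA dimensions and global dimensions
#'
#' Runs a separate (unweighted, standardized) principal component analysis in
#' each variable group and correlates its dimension scores with the global
#' MFA dimension scores.
#'
#' @param result a fitted [fit_mfa()] object.
#' @param table the table the result was fitted to.
#' @param spec the [group_spec()] used.
#' @return A data.frame with columns `group`, `partial_dim`, `global_dim`,
#'   `correlation`.
#' @export
partial_axes <- function(result, table, spec = result$spec) {
  stopifnot(inherits(result, "mfa"))
  am <- .active_matrix(table, spec)
  z <- scale(am$x)
  out <- list()
  for (g in names(spec$groups)) {
    zg <- z[, spec$groups[[g]], drop = FALSE]
    pg <- eigen(crossprod(zg) / (nrow(zg) - 1), symmetric = TRUE)
    keep <- pg$values > max(pg$values) * 1e-12
    sg <- zg %*% pg$vectors[, keep, drop = FALSE]
    cc <- cor(sg, result$scores)
    for (k in seq_len(ncol(sg))) {
      for (s in seq_len(ncol(result$scores))) {
        out[[length(out) + 1L]] <- data.frame(
          group = g, partial_dim = k, global_dim = s,
          correlation = cc[k, s], stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Project a supplementary categorical variable
#'
#' Category coordinates are barycentres (means) of the rows' global
#' coordinates; per-group barycentres from the partial coordinates are also
#' returned, so group (dis)agreement about a category can be quantified.
#'
#' @param result a fitted [fit_mfa()] object.
#' @param categorical a column name stored with the fit, or a vector aligned
#'   with the retained rows.
#' @return A list with `coordinates` (levels x dims), `partial` (list per
#'   group), and `counts`.
#' @export
project_supplementary <- function(result, categorical) {
  stopifnot(inherits(result, "mfa"))
  if (is.character(categorical) && length(categorical) == 1L) {
    if (!categorical %in% names(result$supp_data)) {
      stop(sprintf("unknown supplementary column: %s", categorical),
           call. = FALSE)
    }
    categorical <- result$supp_data[[categorical]]
  }
  f <- factor(categorical)
  if (length(f) != nrow(result$scores)) {
    stop("categorical must have one value per retained row", call. = FALSE)
  }
  if (anyNA(f)) {
    stop("categorical has undefined (NA) levels on retained rows",
         call. = FALSE)
  }
  bary <- function(m) {
    b <- rowsum(m, f) / as.vector(table(f))
    b[levels(f), , drop = FALSE]
  }
  list(coordinates = bary(result$scores),
       partial = lapply(result$partial_coordinates, bary),
       counts = table(f))
}

#' Aggregate a trial table for the MFA sensitivity variants
#'
#' Cell means of all active quantitative variables (plus brightness when
#' present) per grouping key. Standardization happens downstream, within each
#' variant. Empty cells are dropped (with a logged count when missingness
#' removed whole cells).
#'
#' @param table trial table.
#' @param by one of `"participant"`, `"stimulus"`,
#'   `"participant_valence"` (participant x valence category),
#'   `"participant_arousal"`, or a character vector of grouping columns.
#' @param spec a [group_spec()] naming the active columns.
#' @return Aggregated data.frame; attribute `aggregation` records the level.
#' @export
aggregate_table <- function(table, by = "stimulus", spec = group_spec()) {
  key_cols <- switch(paste(by, collapse = "+"),
    participant = "participant_id",
    stimulus = "stimulus_id",
    participant_valence = c("participant_id", "valence_category"),
    participant_arousal = c("participant_id", "arousal_category"),
    by)
  missing_cols <- setdiff(key_cols, names(table))
  if (length(missing_cols)) {
    stop(sprintf("grouping column(s) not in table: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  vars <- intersect(c(unlist(spec$groups, use.names = FALSE), "brightness"),
                    names(table))
  full_cells <- unique(table[, key_cols, drop = FALSE])
  agg <- aggregate(table[, vars, drop = FALSE],
                   by = table[, key_cols, drop = FALSE],
                   FUN = mean, na.rm = TRUE)
  # propagate categories that are constant within cells (e.g. stimulus-level
  # aggregation keeps the stimulus categories)
  for (cc in c("valence_category", "arousal_category")) {
    if (cc %in% names(table) && !cc %in% key_cols) {
      u <- tapply(as.character(table[[cc]]),
                  interaction(table[, key_cols, drop = FALSE], drop = TRUE),
                  function(v) if (length(unique(v)) == 1L) v[1L] else NA)
      key <- interaction(agg[, key_cols, drop = FALSE], drop = TRUE)
      val <- unname(u[as.character(key)])
      if (!anyNA(val)) agg[[cc]] <- val
    }
  }
  # all-NA cells yield NaN means; mark them missing so downstream
  # complete-case handling counts them
  for (v in vars) agg[[v]][is.nan(agg[[v]])] <- NA
  n_dropped <- nrow(full_cells) - nrow(agg)
  attr(agg, "aggregation") <- paste(by, collapse = "+")
  attr(agg, "n_cells_dropped") <- max(n_dropped, 0L)
  agg
}
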