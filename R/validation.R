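#' Classify stimulus class from the affective-space dimensions
#'
#' Trains a random forest on a stratified training split of the retained
#' dimension scores and reports out-of-bag accuracy, held-out accuracy,
#' one-vs-rest separability (AUC) per class from the forest's vote
#' proportions, permutation variable importance (mean decrease in accuracy)
#' per dimension, and a chi-square test of the held-out confusion matrix
#' against independence.
#'
#' @param scores numeric matrix (rows x retained dimensions).
#' @param labels class labels (e.g. valence category), one per row.
#' @param split training proportion in (0, 1).
#' @param ntree,mtry forest size and features per split (defaults 500 and
#'   `floor(sqrt(p))`).
#' @param seed integer seed.
#' @return Object of class `space_classification`: `oob_accuracy`,
#'   `test_accuracy`, `auc` (per class + `macro`), `importance`,
#'   `confusion`, `chisq` (statistic, df, p), `split`, `n_train`, `n_test`.
#' @export
classify_space <- function(scores, labels, split = 0.7, ntree = 500L,
                           mtry = NULL, seed = 1L) {
  scores <- as.matrix(scores)
  if (is.null(colnames(scores))) {
    colnames(scores) <- paste0("dim", seq_len(ncol(scores)))
  }
  y <- factor(labels)
  if (nlevels(y) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (split <= 0 || split >= 1) stop("split must be in (0, 1)", call. = FALSE)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(scores))))
  set.seed(as.integer(seed))
  train_idx <- NULL
  for (attempt in 1:2) {
    idx <- unlist(lapply(split(seq_along(y), y), function(i) {
      sample(i, max(1L, round(split * length(i))))
    }), use.names = FALSE)
    if (all(levels(y) %in% y[idx]) && length(idx) < length(y)) {
      train_idx <- idx
      break
    }
  }
  if (is.null(train_idx)) {
    stop("could not build a stratified split containing every class",
         call. = FALSE)
  }
  rf <- randomForest::randomForest(x = scores[train_idx, , drop = FALSE],
                                   y = y[train_idx],
                                   ntree = ntree, mtry = mtry,
                                   importance = TRUE)
  oob <- 1 - rf$err.rate[ntree, "OOB"]
  test_x <- scores[-train_idx, , drop = FALSE]
  test_y <- y[-train_idx]
  pred <- predict(rf, test_x)
  votes <- predict(rf, test_x, type = "prob")
  acc <- mean(pred == test_y)
  auc <- vapply(levels(y), function(cl) {
    resp <- factor(test_y == cl, levels = c(FALSE, TRUE))
    if (length(unique(resp)) < 2L) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(resp, votes[, cl], quiet = TRUE,
                                   direction = "<")))
  }, numeric(1))
  auc <- c(auc, macro = mean(auc, na.rm = TRUE))
  confusion <- table(true = test_y, predicted = pred)
  chisq <- suppressWarnings(chisq.test(confusion))
  structure(list(
    oob_accuracy = unname(oob),
    test_accuracy = acc,
    auc = auc,
    importance = rf$importance[, "MeanDecreaseAccuracy"],
    confusion = confusion,
    chisq = list(statistic = unname(chisq$statistic),
                 df = unname(chisq$parameter),
                 p = unname(chisq$p.value)),
    split = split, n_train = length(train_idx),
    n_test = length(test_y),
    ntree = ntree, mtry = mtry
  ), class = "space_classification")
}

#' Mean silhouette width of a clustering
#'
#' For each point, `a` is its mean distance to its own cluster (excluding
#' itself) and `b` the smallest mean distance to another cluster; the
#' silhouette is `(b - a) / max(a, b)` (0 for singleton clusters), averaged
#' over points.
#'
#' @param x numeric matrix of coordinates, or a `dist` object.
#' @param cluster integer cluster assignment per point.
#' @return Mean silhouette in `[-1, 1]`.
#' @export
silhouette_score <- function(x, cluster) {
  m <- if (inherits(x, "dist")) as.matrix(x) else as.matrix(dist(x))
  cluster <- as.integer(factor(cluster))
  n <- nrow(m)
  stopifnot(length(cluster) == n)
  k <- max(cluster)
  if (k < 2L) return(0)
  sums <- t(rowsum(t(m), cluster))          # n x k: summed distance to each cluster
  counts <- tabulate(cluster, k)
  s <- numeric(n)
  for (i in seq_len(n)) {
    ci <- cluster[i]
    if (counts[ci] <= 1L) { s[i] <- 0; next }
    a <- sums[i, ci] / (counts[ci] - 1L)
    b <- min(sums[i, -ci] / counts[-ci])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Data-driven clustering of the affective-space dimensions
#'
#' k-means with many restarts for each candidate k; the reported solution is
#' the k with the highest mean silhouette. Reports the silhouette, percent
#' between-cluster variance, per-cluster means of each (standardized)
#' dimension, and -- when labels are supplied -- the cluster-by-class
#' chi-square test of correspondence.
#'
#' @param scores numeric matrix (rows x retained dimensions).
#' @param k_range candidate cluster counts (subset of `2..n-1`).
#' @param labels optional a-priori class labels for the correspondence test.
#' @param nstart random restarts per k.
#' @param seed integer seed.
#' @return Object of class `space_clustering`: `k`, `silhouette`,
#'   `between_variance_pct`, `cluster` (assignments at the chosen k),
#'   `centers`, `profile` (per-cluster means of standardized dims), `by_k`
#'   (silhouette and between-variance per candidate k), and `chisq` when
#'   labels are given.
#' @export
cluster_space <- function(scores, k_range = 2:8, labels = NULL,
                          nstart = 25L, seed = 1L) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  k_range <- k_range[k_range >= 2L & k_range <= n - 1L]
  if (!length(k_range)) stop("k_range must lie in [2, n_rows - 1]",
                             call. = FALSE)
  set.seed(as.integer(seed))
  d <- dist(scores)
  fits <- list()
  by_k <- data.frame(k = integer(), silhouette = numeric(),
                     between_variance_pct = numeric())
  for (k in k_range) {
    km <- tryCatch(kmeans(scores, centers = k, nstart = nstart,
                          iter.max = 50L),
                   error = function(e) NULL)
    if (is.null(km)) {
      warning(sprintf("k = %d skipped (degenerate solution)", k))
      next
    }
    fits[[as.character(k)]] <- km
    by_k <- rbind(by_k, data.frame(
      k = k,
      silhouette = silhouette_score(d, km$cluster),
      between_variance_pct = 100 * km$betweenss / km$totss))
  }
  if (!nrow(by_k)) stop("no candidate k produced a clustering", call. = FALSE)
  best <- by_k$k[which.max(by_k$silhouette)]
  km <- fits[[as.character(best)]]
  z <- scale(scores)
  profile <- rowsum(z, km$cluster) / as.vector(table(km$cluster))
  out <- list(
    k = best,
    silhouette = by_k$silhouette[by_k$k == best],
    between_variance_pct = by_k$between_variance_pct[by_k$k == best],
    cluster = km$cluster,
    centers = km$centers,
    profile = profile,
    by_k = by_k
  )
  if (!is.null(labels)) {
    tab <- table(cluster = km$cluster, class = factor(labels))
    cs <- suppressWarnings(chisq.test(tab))
    out$contingency <- tab
    out$chisq <- list(statistic = unname(cs$statistic),
                      df = unname(cs$parameter),
                      p = unname(cs$p.value))
  }
  structure(out, class = "space_clustering")
}
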