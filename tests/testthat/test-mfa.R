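spec2 <- group_spec(groups = list(
  subjective = c("subjective_valence", "subjective_arousal"),
  autonomic = c("pupil", "scr", "hr")),
  supplementary = "valence_category")

test_that("group weighting gives each weighted group a unit first eigenvalue", {
  # single-variable group: weight exactly 1
  tab <- random_trial_table(seed = 2)
  sw1 <- standardize_and_weight(tab, group_spec(
    groups = list(p = "pupil", rest = c("scr", "hr")),
    supplementary = character()))
  expect_equal(unname(sw1$group_first_eigenvalues["p"]), 1)

  # two perfectly correlated variables: lambda1 = 2, weight 1/sqrt(2) on cols
  tab2 <- tab
  tab2$scr <- 2 * tab2$pupil + 3
  sw2 <- standardize_and_weight(tab2, group_spec(
    groups = list(dup = c("pupil", "scr"), rest = "hr"),
    supplementary = character()))
  expect_equal(unname(sw2$group_first_eigenvalues["dup"]), 2, tolerance = 1e-12)
  expect_equal(unname(sw2$column_weights[["pupil"]]), 0.5, tolerance = 1e-12)

  # property: after weighting, every group's first eigenvalue is exactly 1
  for (s in 1:5) {
    tabr <- random_trial_table(seed = s)
    sw <- standardize_and_weight(tabr, spec2)
    for (g in names(spec2$groups)) {
      xg <- sw$x_weighted[, spec2$groups[[g]], drop = FALSE]
      l1 <- max(eigen(crossprod(xg) / (nrow(xg) - 1), symmetric = TRUE,
                      only.values = TRUE)$values)
      expect_equal(l1, 1, tolerance = 1e-10)
    }
  }
})

test_that("eigenvalues and scores match the brute-force oracle to 1e-10", {
  for (s in 1:20) {
    n <- sample(8:50, 1)
    tab <- random_trial_table(n_participants = 1, n_stimuli = n, seed = 100 + s)
    fit <- fit_mfa(tab, spec2)
    orc <- mfa_oracle(as.matrix(tab[, affect_vars]), spec2$groups)
    expect_equal(fit$eigenvalues, orc$eigenvalues, tolerance = 1e-10)
    # scores agree per dimension up to the sign convention
    for (k in seq_len(ncol(fit$scores))) {
      if (fit$eigenvalues[k] < 1e-8) next
      a <- fit$scores[, k]
      b <- orc$scores[, k]
      expect_equal(abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2)), 1,
                   tolerance = 1e-10)
    }
  }
})

test_that("MFA algebraic identities hold", {
  tab <- random_trial_table(seed = 9)
  fit <- fit_mfa(tab, spec2)

  # contributions sum to 100 per dimension, for variables and groups
  expect_equal(unname(colSums(fit$variables$contribution)),
               rep(100, fit$n_dims), tolerance = 1e-10)
  expect_equal(unname(colSums(fit$groups$contribution)),
               rep(100, fit$n_dims), tolerance = 1e-10)

  # with all dimensions retained each variable's cos2 sums to 1
  expect_equal(unname(rowSums(fit$variables$cos2)), rep(1, 5),
               tolerance = 1e-10)

  # total inertia identity: sum of eigenvalues = sum_g p_g / lambda1(g)
  expect_equal(sum(fit$eigenvalues),
               sum(lengths(spec2$groups) / fit$groups$first_eigenvalues),
               tolerance = 1e-10)

  # barycentre identity: mean of partial coordinates = global coordinate
  pc <- partial_coordinates(fit)
  expect_equal((pc$subjective + pc$autonomic) / 2, unclass(fit$scores),
               tolerance = 1e-10, ignore_attr = TRUE)

  # contribution formula: 100 * weight * cor^2 / eigenvalue
  w <- fit$column_weights
  for (k in seq_len(fit$n_dims)) {
    expect_equal(fit$variables$contribution[, k],
                 100 * w * fit$variables$correlation[, k]^2 /
                   fit$eigenvalues[k],
                 tolerance = 1e-8)
  }

  # deterministic sign convention: strongest variable loads positively
  for (k in seq_len(fit$n_dims)) {
    j <- which.max(abs(fit$variables$correlation[, k]))
    expect_gt(fit$variables$correlation[j, k], 0)
  }
})

test_that("single-group MFA reduces to principal components", {
  tab <- random_trial_table(seed = 4)
  fit <- fit_mfa(tab, group_spec(groups = list(all = affect_vars),
                                 supplementary = character()))
  pc <- prcomp(scale(as.matrix(tab[, affect_vars])))
  for (k in 1:5) {
    a <- fit$scores[, k]
    b <- pc$x[, k]
    expect_equal(abs(cor(a, b)), 1, tolerance = 1e-8)
  }
  # partial axes of the single group correlate perfectly with global dims
  pa <- fit$partial_axes
  for (k in 1:5) {
    expect_equal(abs(pa$correlation[pa$partial_dim == k & pa$global_dim == k]),
                 1, tolerance = 1e-8)
  }
  expect_true(all(abs(pa$correlation) <= 1 + 1e-12))
})

test_that("duplicated groups give coincident partial points", {
  tab <- random_trial_table(seed = 6)
  tab$p2 <- tab$pupil
  tab$s2 <- tab$scr
  tab$h2 <- tab$hr
  spec_dup <- group_spec(groups = list(a = c("pupil", "scr", "hr"),
                                       b = c("p2", "s2", "h2")),
                         supplementary = "valence_category")
  fit <- fit_mfa(tab, spec_dup)
  pc <- partial_coordinates(fit)
  expect_equal(pc$a, pc$b, tolerance = 1e-8)
  expect_equal(pc$a, unclass(fit$scores), tolerance = 1e-8,
               ignore_attr = TRUE)
  # divergence between group barycentres is zero for duplicated groups
  proj <- project_supplementary(fit, "valence_category")
  expect_equal(proj$partial$a, proj$partial$b, tolerance = 1e-8)
})

test_that("supplementary projection returns barycentres with sane geometry", {
  tab <- random_trial_table(seed = 8)
  fit <- fit_mfa(tab, spec2)
  one <- project_supplementary(fit, factor(rep("all", nrow(fit$scores))))
  expect_equal(unname(one$coordinates[1, ]), rep(0, fit$n_dims),
               tolerance = 1e-10)

  expect_error(project_supplementary(fit, rep(NA, nrow(fit$scores))),
               "undefined")
  expect_error(project_supplementary(fit, "not_a_column"), "unknown")

  # planted table: category barycentres are ordered along the dimension that
  # carries subjective valence
  p <- generator_params(seed = 31)
  tabp <- generate_trial_table(params = p)
  fitp <- fit_mfa(tabp, n_dims = 2)
  val_dim <- which.max(abs(fitp$variables$correlation["subjective_valence", ]))
  proj <- project_supplementary(fitp, "valence_category")
  co <- proj$coordinates[c("negative", "neutral", "positive"), val_dim]
  expect_true(all(diff(co) > 0) || all(diff(co) < 0))
})

test_that("aggregation variants produce cell means at the right granularity", {
  p <- generator_params(seed = 17)
  tab <- generate_trial_table(params = p)
  by_stim <- aggregate_table(tab, "stimulus")
  expect_equal(nrow(by_stim), 56)
  i <- which(tab$stimulus_id == by_stim$stimulus_id[1])
  expect_equal(by_stim$pupil[1], mean(tab$pupil[i]))
  expect_true("valence_category" %in% names(by_stim))

  by_pv <- aggregate_table(tab, "participant_valence")
  expect_lte(nrow(by_pv), 51 * 3)

  # aggregating an already aggregated (noise-free per cell) table is idempotent
  again <- aggregate_table(by_stim, "stimulus")
  expect_equal(again$pupil, by_stim$pupil, tolerance = 1e-12)

  # the aggregate feeds straight back into the MFA
  fit <- fit_mfa(by_stim, group_spec(supplementary = "valence_category"))
  expect_equal(fit$meta$n_rows, 56)
  expect_error(aggregate_table(tab, "nonexistent_column"), "grouping")
})

test_that("degenerate inputs fail with named errors; rank truncation warns", {
  tab <- random_trial_table(seed = 10)
  tab$scr <- 1
  expect_error(fit_mfa(tab, spec2), "scr")

  tab2 <- random_trial_table(seed = 11)
  tab2$hr <- NA_real_
  expect_error(fit_mfa(tab2, spec2), "at least 3 complete rows")

  tab3 <- random_trial_table(seed = 12)
  tab3$hr[1:5] <- NA
  fit3 <- fit_mfa(tab3, spec2)
  expect_equal(fit3$meta$n_dropped, 5L)
  expect_equal(fit3$meta$n_rows, nrow(tab3) - 5L)

  tab4 <- random_trial_table(seed = 13)
  tab4$subjective_arousal <- tab4$subjective_valence  # rank-deficient pair
  expect_warning(fit_mfa(tab4, spec2, n_dims = 5), "truncated")
})
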