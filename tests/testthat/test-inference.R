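test_that("alignment recovers identity, swaps and sign flips", {
  p <- generator_params(n_participants = 10, n_stimuli = 12, seed = 19)
  tab <- generate_trial_table(params = p)
  ref <- fit_mfa(tab, n_dims = 3)

  al <- align_solution(ref, ref, n_dims = 3)
  expect_equal(al$permutation, 1:3)
  expect_false(al$swapped)
  expect_false(al$flipped)
  expect_equal(al$candidate$variables$correlation,
               ref$variables$correlation[, 1:3])

  # constructed candidate: dims 1 and 2 swapped, dim 1 negated
  cand <- ref
  sw <- c(2, 1, 3)
  cand$eigenvalues <- ref$eigenvalues[c(sw, 4, 5)]
  cand$variables$correlation <- ref$variables$correlation[, sw]
  cand$variables$correlation[, 1] <- -cand$variables$correlation[, 1]
  cand$variables$cos2 <- cand$variables$correlation^2
  cand$variables$contribution <- ref$variables$contribution[, sw]
  cand$scores <- ref$scores[, sw]
  cand$scores[, 1] <- -cand$scores[, 1]
  al2 <- align_solution(ref, cand, n_dims = 3)
  expect_equal(al2$permutation, c(2L, 1L, 3L))
  expect_true(al2$swapped)
  expect_true(al2$flipped)
  expect_equal(al2$candidate$variables$correlation,
               ref$variables$correlation[, 1:3], tolerance = 1e-12)
  expect_equal(al2$candidate$eigenvalues_aligned, ref$eigenvalues[1:3])
})

test_that("greedy matching equals exhaustive matching on planted replicates", {
  p <- generator_params(n_participants = 12, n_stimuli = 14, seed = 29)
  tab <- generate_trial_table(params = p)
  ref <- fit_mfa(tab)
  ref_cors <- ref$variables$correlation[, 1:3]
  perms3 <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                 c(3, 2, 1))
  for (s in 1:10) {
    set.seed(s)
    shuffle <- sample(3)
    signs <- sample(c(-1, 1), 3, replace = TRUE)
    cand_cors <- sweep(ref_cors[, shuffle], 2, signs, `*`) +
      matrix(rnorm(15, sd = 0.05), 5, 3)
    greedy <- affectspace:::.match_dims(ref_cors, cand_cors, 3)
    # exhaustive oracle over all 3! assignments
    score <- function(pp) sum(abs(vapply(1:3, function(k)
      cor(ref_cors[, k], cand_cors[, pp[k]]), numeric(1))))
    best <- perms3[[which.max(vapply(perms3, score, numeric(1)))]]
    expect_equal(greedy$permutation, as.integer(best))
  }
})

test_that("bootstrap on identical participants collapses to the point estimate", {
  base <- random_trial_table(n_participants = 1, n_stimuli = 12, seed = 33)
  tab <- do.call(rbind, lapply(1:6, function(i) {
    b <- base
    b$participant_id <- sprintf("P%02d", i)
    b
  }))
  bt <- cluster_bootstrap(tab, group_spec(supplementary = "valence_category"),
                          n_boot = 10, seed = 1, n_dims = 2,
                          resample_trials = FALSE)
  expect_equal(bt$eigenvalues$ci_lower, bt$eigenvalues$estimate,
               tolerance = 1e-12)
  expect_equal(bt$eigenvalues$ci_upper, bt$eigenvalues$estimate,
               tolerance = 1e-12)
})

test_that("degenerate bootstrap replicates are dropped and counted", {
  # one informative participant among constant ones: replicates that omit it
  # have a zero-variance column and must be dropped, never silently kept
  tab <- random_trial_table(n_participants = 6, n_stimuli = 10, seed = 35)
  flat <- tab$participant_id != "P01"
  tab$pupil[flat] <- 1
  bt <- cluster_bootstrap(tab, group_spec(supplementary = "valence_category"),
                          n_boot = 40, seed = 2, n_dims = 2,
                          resample_trials = FALSE)
  expect_gt(bt$n_dropped, 0)
  expect_equal(bt$n_used + bt$n_dropped, 40L)
})

test_that("resampling is reproducible and independent of the parallelism degree", {
  p <- generator_params(n_participants = 8, n_stimuli = 10, seed = 41)
  tab <- generate_trial_table(params = p)
  b1 <- cluster_bootstrap(tab, n_boot = 15, seed = 7, n_dims = 2)
  b2 <- cluster_bootstrap(tab, n_boot = 15, seed = 7, n_dims = 2)
  b3 <- cluster_bootstrap(tab, n_boot = 15, seed = 7, n_dims = 2, jobs = 2)
  expect_identical(b1$draws, b2$draws)
  expect_identical(b1$draws, b3$draws)
  p1 <- permutation_null(tab, n_perm = 15, seed = 7, n_dims = 2)
  p2 <- permutation_null(tab, n_perm = 15, seed = 7, n_dims = 2, jobs = 2)
  expect_identical(p1$null_eigenvalues, p2$null_eigenvalues)
})

test_that("permutation schemes preserve the stratum multisets", {
  # a column that is constant within every stratum cannot change under a
  # stratum-respecting permutation, so its eigen contribution is invariant
  p <- generator_params(n_participants = 6, n_stimuli = 12, seed = 43)
  tab <- generate_trial_table(params = p)
  g <- interaction(tab$participant_id, tab$valence_category, drop = TRUE)
  for (scheme in c("stimulus_blocks", "within_strata")) {
    pr <- permutation_null(tab, n_perm = 20, seed = 3, n_dims = 2,
                           scheme = scheme)
    expect_true(all(pr$p_eigenvalues >= 1 / 21 & pr$p_eigenvalues <= 1))
    expect_true(all(pr$p_loadings >= 1 / 21 & pr$p_loadings <= 1))
  }
})

test_that("a perfectly collinear planted table is maximally extreme", {
  # cross-group duplicated signal: observed leading share beats every null draw
  set.seed(44)
  n <- 300
  z <- rnorm(n)
  tab <- data.frame(
    participant_id = rep(sprintf("P%02d", 1:10), each = 30),
    stimulus_id = rep(sprintf("S%02d", 1:30), 10),
    valence_category = factor(rep("all", n)),
    subjective_valence = z, subjective_arousal = z + rnorm(n, sd = 1e-6),
    pupil = z + rnorm(n, sd = 1e-6), scr = abs(z) + 0.01,
    hr = -z + rnorm(n, sd = 1e-6))
  pr <- permutation_null(tab, n_perm = 99, seed = 5, n_dims = 1)
  expect_equal(pr$p_eigenvalues[1], 1 / 100)
  expect_error(permutation_null(tab, n_perm = 0), "n_perm")
})

test_that("singleton strata warn and stay fixed", {
  tab <- random_trial_table(n_participants = 4, n_stimuli = 6, seed = 45)
  expect_warning(
    permutation_null(tab, strata = c("participant_id", "stimulus_id"),
                     n_perm = 5, seed = 1, n_dims = 1,
                     scheme = "within_strata"),
    "singleton")
})

test_that("the retained-dimension rule counts leading significant dimensions", {
  expect_equal(retained_dimensions(c(0.001, 0.004, 0.62, 0.8)), 2L)
  expect_equal(retained_dimensions(c(0.06, 0.01)), 0L)
  expect_equal(retained_dimensions(c(0.01, 0.20, 0.01)), 1L)
  expect_equal(retained_dimensions(c(0.01, 0.01, 0.01), alpha = 0.05), 3L)
})

test_that("the combined inference report is coherent", {
  p <- generator_params(n_participants = 10, n_stimuli = 12, seed = 47)
  tab <- generate_trial_table(params = p)
  rep_ <- inference_report(tab, n_boot = 30, n_perm = 30, seed = 11,
                           n_dims = 2)
  eig <- rep_$eigenvalues
  expect_equal(nrow(eig), 2L)
  expect_true(all(eig$ci_lower <= eig$ci_upper))
  expect_true(all(eig$perm_p >= 1 / 31 & eig$perm_p <= 1))
  expect_true(all(dim(rep_$loadings$perm_p) == c(5, 2)))
  expect_true(rep_$retained %in% 0:5)
  expect_true(is.numeric(rep_$alignment$prop_swapped))
  # deterministic under the same seed
  rep2 <- inference_report(tab, n_boot = 30, n_perm = 30, seed = 11,
                           n_dims = 2)
  expect_equal(rep_$eigenvalues, rep2$eigenvalues)
})
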