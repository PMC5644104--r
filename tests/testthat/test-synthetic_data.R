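test_that("generation is deterministic under a fixed seed", {
  s1 <- simulate_associations(generator_params(n_d = 10, n_m = 25, seed = 3))
  s2 <- simulate_associations(generator_params(n_d = 10, n_m = 25, seed = 3))
  expect_identical(s1$A, s2$A)
  expect_identical(s1$ds_symptom, s2$ds_symptom)
  s3 <- simulate_associations(generator_params(n_d = 10, n_m = 25, seed = 4))
  expect_false(identical(s1$A, s3$A))
})

test_that("the deterministic limit produces exact group blocks", {
  p <- generator_params(n_d = 10, n_m = 20, p_in = 1, p_out = 0,
                        symptom_noise_sd = 0, seed = 1)
  sim <- simulate_associations(p)
  matched <- outer(((seq_len(5) - 1) %% 5 + 1)[sim$disease_groups],
                   sim$microbe_groups, "==")
  expect_equal(bare(sim$A), bare(matched * 1))
  # identical within-group profiles have Gaussian similarity exactly 1
  DSg <- gaussian_disease_similarity(sim$A)
  same <- outer(sim$disease_groups, sim$disease_groups, "==")
  expect_true(all(DSg[same] == 1))
  # symptom similarity without noise is exactly block structured
  expect_true(all(sim$ds_symptom[same & !diag(10)] == 0.6))
  expect_true(all(sim$ds_symptom[!same] == 0.1))
})

test_that("matched-block density matches p_in within binomial tolerance", {
  p <- generator_params(seed = 1)  # defaults: 39 x 292
  sim <- simulate_associations(p)
  matched <- outer(((seq_len(5) - 1) %% 5 + 1)[sim$disease_groups],
                   sim$microbe_groups, "==")
  n_in <- sum(matched)
  dens <- sum(sim$A[matched]) / n_in
  tol <- 3 * sqrt(p$p_in * (1 - p$p_in) / n_in)
  expect_lt(abs(dens - p$p_in), tol + 0.01)  # +0.01 covers rescue additions
})

test_that("every profile is nonzero and the symptom matrix is valid", {
  sim <- simulate_associations(generator_params(n_d = 15, n_m = 200,
                                                p_in = 0.05, p_out = 0,
                                                seed = 9))
  expect_true(all(rowSums(sim$A) >= 1))
  expect_true(all(colSums(sim$A) >= 1))
  expect_silent(validate_similarity(sim$ds_symptom, tol = 1e-12))
  expect_true(all(sim$ds_symptom >= 0 & sim$ds_symptom <= 1))
  expect_equal(unname(diag(sim$ds_symptom)), rep(1, 15))
})

test_that("parameter violations are rejected", {
  expect_error(generator_params(p_in = 0.1, p_out = 0.2), "p_out",
               class = "mda_usage_error")
  expect_error(generator_params(n_d = 0), "positive",
               class = "mda_usage_error")
  expect_error(generator_params(symptom_noise_sd = -1), "nonnegative",
               class = "mda_usage_error")
})

test_that("the block-membership oracle bounds what any scorer can attain", {
  # Under the generator, cells are i.i.d. Bernoulli given block membership,
  # so ranking by the planted membership is Bayes optimal; its LOOCV AUC is
  # the ceiling for every model. Background (p_out) positives and the
  # exchangeability of masked positives with matched-block zeros keep this
  # ceiling well below 1.
  sim <- simulate_associations(generator_params(seed = 1))
  matched <- outer(((seq_len(5) - 1) %% 5 + 1)[sim$disease_groups],
                   sim$microbe_groups, "==")
  block_oracle <- function(At) matrix(as.numeric(matched), nrow(At),
                                      dimnames = dimnames(At))
  ceiling_auc <- loocv(sim$A, block_oracle)$auc
  hybrid_auc <- loocv(sim$A,
                      make_scorer("ngrhmda", ds_symptom = sim$ds_symptom))$auc
  expect_lt(ceiling_auc, 0.9)
  expect_gt(ceiling_auc, 0.8)
  expect_lte(hybrid_auc, ceiling_auc)
  expect_gt(hybrid_auc, 0.5)
})

test_that("the hybrid score picks up the planted block contrast", {
  sim <- simulate_associations(generator_params(n_d = 20, n_m = 50, seed = 1))
  cs <- component_scores(sim$A, sim$ds_symptom)
  matched <- outer(((seq_len(5) - 1) %% 5 + 1)[sim$disease_groups],
                   sim$microbe_groups, "==")
  # matched-block candidate cells outscore background candidate cells
  expect_gt(mean(cs$s[matched & sim$A == 0]),
            mean(cs$s[!matched & sim$A == 0]))
  expect_gt(mean(cs$ns[matched & sim$A == 0]),
            mean(cs$ns[!matched & sim$A == 0]))
  # known associations outscore the candidate pool on the full fit
  expect_gt(mean(cs$s[sim$A == 1]), mean(cs$s[sim$A == 0]))
})
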