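test_that("ROC/AUC handles degenerate and tied score lists", {
  expect_equal(roc_and_auc(1, 0)$auc, 1)
  expect_equal(roc_and_auc(0.5, 0.5)$auc, 0.5)  # tie convention
  expect_equal(roc_and_auc(c(3, 1), c(2, 0))$auc, 0.75)
  expect_error(roc_and_auc(numeric(0), 1), "nonempty",
               class = "mda_data_error")
})

test_that("trapezoid ROC AUC equals pairwise concordance on random scores", {
  set.seed(30)
  for (rep in 1:200) {
    n <- sample(1:8, 1); m <- sample(1:12, 1)
    # coarse grid forces plenty of ties
    test <- sample(0:4, n, replace = TRUE) / 2
    cand <- sample(0:4, m, replace = TRUE) / 2
    r <- roc_and_auc(test, cand)
    expect_equal(r$auc, concordance_oracle(test, cand), tolerance = 1e-12)
    pts <- r$roc_points
    expect_equal(unlist(pts[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(pts[nrow(pts), ]), c(fpr = 1, tpr = 1))
    expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(31)
  test <- runif(6); cand <- runif(15)
  a0 <- roc_and_auc(test, cand)$auc
  expect_equal(roc_and_auc(exp(3 * test), exp(3 * cand))$auc, a0)
  expect_equal(roc_and_auc(rank(c(test, cand))[1:6],
                           rank(c(test, cand))[-(1:6)])$auc, a0)
})

test_that("LOOCV with an oracle scorer is perfect and with ties is partial", {
  A <- toy_A()
  oracle <- function(At) A  # ranks each held-out pair above every candidate
  res <- loocv(A, oracle)
  expect_identical(res$auc, 1)
  expect_equal(res$n_test, 2)
  expect_equal(res$n_candidates, 2)
  # ROC integrates to the AUC
  pts <- res$roc_points
  expect_equal(sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2),
               res$auc)
  expect_error(loocv(matrix(c(1, 0, 0, 0), 2, 2,
                            dimnames = dimnames(A)), oracle),
               "at least 2", class = "mda_data_error")
})

test_that("LOOCV pools per-run candidate comparisons as in exhaustive counting", {
  # 3x1 matrix, two positives; a scorer keyed on which pair is masked
  A <- matrix(c(1, 1, 0), 3, 1, dimnames = list(c("d1", "d2", "d3"), "m1"))
  scorer <- function(At) {
    if (At["d1", "m1"] == 0) matrix(c(3, 2, 0), 3, 1, dimnames = dimnames(At))
    else matrix(c(2, 1, 0), 3, 1, dimnames = dimnames(At))
  }
  # run 1 (d1 masked): held-out 3 vs candidate {0}; run 2: 1 vs {0}
  expect_equal(loocv(A, scorer)$auc, 1)
  scorer2 <- function(At) {
    if (At["d1", "m1"] == 0) matrix(c(3, 2, 2), 3, 1, dimnames = dimnames(At))
    else matrix(c(2, 1, 2), 3, 1, dimnames = dimnames(At))
  }
  # run 1: 3 vs {2} concordant; run 2: 1 vs {2} discordant -> (1 + 0) / 2
  expect_equal(loocv(A, scorer2)$auc, 0.5)
})

test_that("a multi-model scorer shares masked runs and names its results", {
  sim <- simulate_associations(generator_params(n_d = 6, n_m = 10, seed = 5))
  res <- loocv(sim$A, make_scorer("all", ds_symptom = sim$ds_symptom))
  expect_named(res, c("ngrhmda", "neighbor", "graph"))
  for (r in res) expect_true(r$auc >= 0 && r$auc <= 1)
})

test_that("k-fold folds partition positives with near-equal sizes", {
  set.seed(32)
  for (n_pos in c(11, 25, 40)) {
    folds <- make_cv_folds(n_pos, 5, seed = 1)
    expect_length(folds, n_pos)
    sizes <- tabulate(folds, 5)
    expect_lte(diff(range(sizes)), 1)
  }
  expect_error(make_cv_folds(3, 5, 1), "n_folds", class = "mda_usage_error")
})

test_that("k-fold CV is exact for an oracle scorer and reproducible", {
  sim <- simulate_associations(generator_params(n_d = 6, n_m = 10, seed = 6))
  oracle <- function(At) sim$A
  res <- kfold_cv(sim$A, oracle, n_folds = 5, n_repeats = 3, seed = 2)
  expect_equal(unname(res$mean_auc), 1)
  expect_equal(unname(res$sd_auc), 0)
  r1 <- kfold_cv(sim$A, make_scorer("neighbor", ds_symptom = sim$ds_symptom),
                 n_folds = 5, n_repeats = 2, seed = 3)
  r2 <- kfold_cv(sim$A, make_scorer("neighbor", ds_symptom = sim$ds_symptom),
                 n_folds = 5, n_repeats = 2, seed = 3)
  expect_identical(r1$per_repeat, r2$per_repeat)
})

test_that("a random scorer centres k-fold AUC at one half", {
  sim <- simulate_associations(generator_params(n_d = 20, n_m = 50, seed = 1))
  res <- kfold_cv(sim$A, random_scorer(7), n_folds = 5, n_repeats = 50,
                  seed = 11)
  expect_lt(abs(unname(res$mean_auc) - 0.5), 0.03)
})

test_that("Gaussian kernels are retrained on the masked matrix by default", {
  sim <- simulate_associations(generator_params(n_d = 8, n_m = 14, seed = 7))
  A <- sim$A
  p <- which(A == 1)[1]
  At <- A; At[p] <- 0
  # masking changes the similarity input
  expect_false(isTRUE(all.equal(gaussian_disease_similarity(A),
                                gaussian_disease_similarity(At))))
  # dynamic and frozen-kernel scorers disagree on the masked run
  dyn <- make_scorer("neighbor", ds_symptom = sim$ds_symptom)
  frozen <- make_scorer("neighbor", ds_symptom = sim$ds_symptom,
                        static_from = A)
  expect_false(isTRUE(all.equal(dyn(At), frozen(At))))
  # frozen similarities reproduce the full-matrix model on the full matrix
  expect_equal(dyn(A), frozen(A))
})
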