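# Ranking-based cross-validation. Held-out positive associations are ranked
# against the candidate set (all cells with no known evidence in the
# ORIGINAL matrix); AUC is the concordance over (held-out, candidate) score
# pairs with ties credited 1/2.

#' ROC curve and AUC from positive and candidate scores
#'
#' Sweeps thresholds over all distinct scores and integrates the ROC curve
#' by the trapezoid rule. Ties between a positive and a candidate score
#' count one half, so the trapezoid AUC equals the Mann-Whitney concordance
#' statistic exactly.
#'
#' @param test_scores scores of held-out positive pairs.
#' @param candidate_scores scores of candidate (unknown) pairs.
#' @return a `ranking_result` list with `auc`, `roc_points` (data frame of
#'   `fpr`, `tpr` from (0,0) to (1,1)), `test_scores`, `candidate_scores`.
#' @examples
#' roc_and_auc(c(3, 1), c(2, 0))$auc  # 0.75
#' @export
roc_and_auc <- function(test_scores, candidate_scores) {
  if (length(test_scores) == 0L || length(candidate_scores) == 0L)
    stop_data("both test and candidate score lists must be nonempty")
  scores <- c(test_scores, candidate_scores)
  lab <- rep(c(1L, 0L), c(length(test_scores), length(candidate_scores)))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  lab <- lab[ord]
  idx <- cumsum(rle(s)$lengths)  # last index of each tie group
  tpr <- c(0, cumsum(lab)[idx] / length(test_scores))
  fpr <- c(0, cumsum(1L - lab)[idx] / length(candidate_scores))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  structure(list(auc = auc,
                 roc_points = data.frame(fpr = fpr, tpr = tpr),
                 test_scores = test_scores,
                 candidate_scores = candidate_scores),
            class = "ranking_result")
}

# Fraction of `cand_sorted` strictly below each element of `x`, plus half
# the ties (midrank convention). `cand_sorted` must be sorted increasingly.
candidate_position <- function(x, cand_sorted) {
  less <- findInterval(x, cand_sorted, left.open = TRUE)
  leq <- findInterval(x, cand_sorted)
  (less + 0.5 * (leq - less)) / length(cand_sorted)
}

# Empirical-CDF ROC for per-run normalized candidate ranks. `v` holds, for
# each held-out positive, the fraction of candidates scoring above it
# (midranked); the ROC is the CDF of v and its trapezoid area equals
# 1 - mean(v), the pooled per-run concordance AUC.
rank_roc_points <- function(v) {
  n <- length(v)
  vs <- sort(v)
  ux <- unique(vs)
  cdf <- findInterval(ux, vs) / n
  fpr <- c(0, rep(ux, each = 2L))
  tpr <- c(0, as.vector(rbind(c(0, utils::head(cdf, -1L)), cdf)))
  if (ux[length(ux)] < 1) {
    fpr <- c(fpr, 1)
    tpr <- c(tpr, 1)
  }
  data.frame(fpr = fpr, tpr = tpr)
}

# Normalize a scorer's output to a named list of score matrices.
scorer_output <- function(sc, dims) {
  if (is.matrix(sc)) sc <- list(score = sc)
  if (!is.list(sc) || is.null(names(sc)) || any(!nzchar(names(sc))))
    stop_data("scorer must return a matrix or a named list of matrices")
  for (m in sc) {
    if (!is.matrix(m) || !identical(dim(m), dims))
      stop_data("scorer output shape does not match the association matrix")
  }
  sc
}

#' Leave-one-out cross-validation
#'
#' Masks each known association in turn, retrains the scorer on the masked
#' matrix, and ranks the held-out pair's score against the scores (from the
#' same masked run) of all candidate pairs, i.e. every cell that is 0 in the
#' original matrix. The AUC is the concordance over all (held-out,
#' candidate) pairs with ties counted 1/2; the ROC curve is the empirical
#' distribution of normalized candidate ranks and integrates exactly to the
#' AUC.
#'
#' @param A binary association matrix with at least 2 positives.
#' @param scorer function of one argument (the masked training matrix)
#'   returning a score matrix of the same shape, or a named list of such
#'   matrices to evaluate several models on shared masked runs.
#' @return if the scorer returns one matrix, an `mda_cv_result` list with
#'   `auc`, `roc_points`, `test_scores`, `candidate_rank` (per-positive
#'   fraction of candidates scoring above, midranked), `n_test`,
#'   `n_candidates`; if it returns a named list, a named list of such
#'   results.
#' @export
loocv <- function(A, scorer) {
  validate_association(A)
  pos <- which(A == 1)
  if (length(pos) < 2L)
    stop_data("leave-one-out cross-validation needs at least 2 positives")
  cand <- which(A == 0)
  if (length(cand) == 0L)
    stop_data("no candidate pairs: the association matrix is all ones")
  first <- TRUE
  nms <- NULL
  u <- NULL  # per-name fraction of candidates below each held-out score
  ts <- NULL
  for (k in seq_along(pos)) {
    At <- A
    At[pos[k]] <- 0
    sc <- scorer_output(scorer(At), dim(A))
    if (first) {
      nms <- names(sc)
      u <- matrix(NA_real_, length(pos), length(nms), dimnames = list(NULL, nms))
      ts <- u
      first <- FALSE
    }
    for (nm in nms) {
      m <- sc[[nm]]
      ts[k, nm] <- m[pos[k]]
      u[k, nm] <- candidate_position(m[pos[k]], sort(m[cand]))
    }
  }
  res <- lapply(nms, function(nm) {
    v <- 1 - u[, nm]  # fraction of candidates above each held-out score
    structure(list(auc = mean(u[, nm]),
                   roc_points = rank_roc_points(v),
                   test_scores = ts[, nm],
                   candidate_rank = v,
                   n_test = length(pos),
                   n_candidates = length(cand)),
              class = "mda_cv_result")
  })
  names(res) <- nms
  if (length(res) == 1L && identical(nms, "score")) res[[1L]] else res
}

#' Fold assignment for repeated k-fold cross-validation
#'
#' Partitions `n_positives` indices into `n_folds` folds whose sizes differ
#' by at most one, uniformly at random under the given seed.
#'
#' @param n_positives number of known associations.
#' @param n_folds number of folds.
#' @param seed RNG seed.
#' @return integer vector of fold labels, length `n_positives`.
#' @export
make_cv_folds <- function(n_positives, n_folds, seed) {
  if (n_folds < 2 || n_folds > n_positives)
    stop_usage("n_folds must lie in [2, number of positives]")
  with_seed(seed, sample(rep(seq_len(n_folds), length.out = n_positives)))
}

#' Repeated k-fold cross-validation
#'
#' Per repetition, the known associations are partitioned into `n_folds`
#' roughly equal folds; each fold is masked in turn, the scorer retrained on
#' the remaining folds, and the fold's held-out scores compared against the
#' candidate scores from that same run. The concordant-pair counts of all
#' folds in a repetition pool into one AUC per repetition; the summary is
#' their mean and standard deviation. Fold assignment for repetition `r`
#' uses seed `seed + r - 1`.
#'
#' @inheritParams loocv
#' @param n_folds number of folds (default 5).
#' @param n_repeats number of random re-partitions (default 100).
#' @param seed base RNG seed for fold assignment.
#' @return an `mda_kfold_result` list with `mean_auc`, `sd_auc` (named by
#'   scorer output) and `per_repeat` (matrix, repetitions by scorer names).
#' @export
kfold_cv <- function(A, scorer, n_folds = 5, n_repeats = 100, seed = 1) {
  validate_association(A)
  pos <- which(A == 1)
  if (n_folds < 2 || n_folds > length(pos))
    stop_usage("n_folds must lie in [2, number of positives]")
  cand <- which(A == 0)
  per_repeat <- NULL
  nms <- NULL
  for (r in seq_len(n_repeats)) {
    folds <- make_cv_folds(length(pos), n_folds, seed + r - 1L)
    conc <- NULL
    for (f in seq_len(n_folds)) {
      test <- pos[folds == f]
      At <- A
      At[test] <- 0
      sc <- scorer_output(scorer(At), dim(A))
      if (is.null(nms)) {
        nms <- names(sc)
        per_repeat <- matrix(NA_real_, n_repeats, length(nms),
                             dimnames = list(NULL, nms))
      }
      if (is.null(conc)) conc <- stats::setNames(numeric(length(nms)), nms)
      for (nm in nms) {
        m <- sc[[nm]]
        conc[nm] <- conc[nm] +
          sum(candidate_position(m[test], sort(m[cand])))
      }
    }
    per_repeat[r, ] <- conc / length(pos)
  }
  structure(list(mean_auc = colMeans(per_repeat),
                 sd_auc = apply(per_repeat, 2L, stats::sd),
                 per_repeat = per_repeat,
                 n_folds = n_folds, n_repeats = n_repeats, seed = seed),
            class = "mda_kfold_result")
}

#' Build a scorer for cross-validation
#'
#' Returns a function of the masked training matrix suitable for [loocv()]
#' and [kfold_cv()]. For similarity-based models the Gaussian kernels are
#' recomputed from each masked matrix (no information leaks from the
#' held-out pairs); pass `static_from` to instead freeze the similarities
#' computed once from a reference matrix. The symptom-based disease
#' similarity, an external input, is static by nature.
#'
#' @param model one of `"ngrhmda"`, `"neighbor"`, `"graph"`,
#'   `"neighbor_no_symptom"`, `"svd"`, `"lfm"`, `"katz"`, or `"all"` (the
#'   hybrid plus both single models, sharing each masked run).
#' @param ds_symptom symptom-based disease similarity, if used.
#' @param kernel a [kernel_params()] object.
#' @param diffusion a [diffusion_params()] object.
#' @param use_symptom_similarity whether to integrate `ds_symptom` into the
#'   disease similarity (default: whenever it is supplied).
#' @param static_from optional association matrix from which similarities
#'   are precomputed once and reused for every masked run.
#' @param svd_rank rank for `model = "svd"` (default `"full"`).
#' @param lfm list of arguments forwarded to [lfm_scores()].
#' @param katz list of arguments forwarded to [katz_scores()].
#' @return a scorer function; for `model = "all"` it returns a named list
#'   of score matrices (`ngrhmda`, `neighbor`, `graph`).
#' @export
make_scorer <- function(model = "ngrhmda", ds_symptom = NULL,
                        kernel = kernel_params(),
                        diffusion = diffusion_params(),
                        use_symptom_similarity = !is.null(ds_symptom),
                        static_from = NULL,
                        svd_rank = "full", lfm = list(), katz = list()) {
  aliases <- c(neighbor_only = "neighbor", "neighbor-nosym" = "neighbor_no_symptom",
               graph_only = "graph")
  if (model %in% names(aliases)) model <- aliases[[model]]
  model <- match.arg(model, c("ngrhmda", "neighbor", "graph",
                              "neighbor_no_symptom", "svd", "lfm", "katz",
                              "all"))
  cfg_model <- switch(model,
                      neighbor = "neighbor_only",
                      graph = "graph_only",
                      neighbor_no_symptom = "neighbor_no_symptom",
                      "ngrhmda")
  config <- model_config(model = cfg_model, kernel = kernel,
                         diffusion = diffusion,
                         use_symptom_similarity = use_symptom_similarity)
  static_sims <- if (!is.null(static_from))
    compute_similarities(static_from, ds_symptom, config)
  sims_for <- function(At) static_sims %||%
    compute_similarities(At, ds_symptom, config)
  switch(model,
    svd = function(At) svd_scores(At, rank = svd_rank),
    lfm = function(At) do.call(lfm_scores, c(list(A = At), lfm)),
    katz = function(At) {
      sims <- sims_for(At)
      do.call(katz_scores, c(list(A = At, DS = sims$DS, MS = sims$MS), katz))
    },
    all = function(At) {
      sims <- sims_for(At)
      nb <- neighbor_predict(At, sims$DS, sims$MS)
      gs <- graph_predict(At, sims$DS, sims$MS, config$diffusion)
      list(ngrhmda = combine_scores(nb$ns, gs), neighbor = nb$ns, graph = gs)
    },
    function(At) {
      sims <- sims_for(At)
      nb <- neighbor_predict(At, sims$DS, sims$MS)
      switch(model,
             neighbor = nb$ns,
             neighbor_no_symptom = nb$ns,
             graph = graph_predict(At, sims$DS, sims$MS, config$diffusion),
             ngrhmda = combine_scores(
               nb$ns, graph_predict(At, sims$DS, sims$MS, config$diffusion)))
    })
}

#' Uniform random scorer
#'
#' Assigns i.i.d. uniform(0, 1) scores to every cell, with a private RNG
#' stream so repeated cross-validation runs are reproducible and do not
#' disturb the caller's RNG.
#'
#' @param seed RNG seed of the private stream.
#' @return a scorer function for [loocv()]/[kfold_cv()].
#' @export
random_scorer <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- NULL
  function(At) {
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit({
      if (had) assign(".Random.seed", old, envir = genv)
      else if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    })
    if (is.null(env$state)) set.seed(seed)
    else assign(".Random.seed", env$state, envir = genv)
    m <- matrix(stats::runif(length(At)), nrow(At), ncol(At),
                dimnames = dimnames(At))
    env$state <- get(".Random.seed", envir = genv, inherits = FALSE)
    m
  }
}
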