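# Synthetic association and symptom-similarity generator with planted
# block structure: disease groups paired with microbe groups share
# associations at a higher rate than background, and symptom similarity is
# elevated within disease groups. This is the statistical structure the
# recommender assumes (similar diseases share microbes), so the planted
# signal is learnable end to end.

#' Generator parameters
#'
#' Defaults emulate the scale of the curated human microbe-disease
#' association catalog the method targets: 39 diseases by 292 microbes,
#' sparse, with block-correlated structure.
#'
#' @param n_d,n_m numbers of diseases and microbes (defaults 39, 292).
#' @param n_disease_groups,n_microbe_groups numbers of planted groups
#'   (defaults 5, 5); disease group `k` is paired with microbe group
#'   `((k - 1) %% n_microbe_groups) + 1`.
#' @param p_in association probability within matched group pairs
#'   (default 0.25).
#' @param p_out background association probability (default 0.01).
#' @param symptom_in,symptom_out mean symptom similarity within/between
#'   disease groups (defaults 0.6, 0.1).
#' @param symptom_noise_sd Gaussian noise on the symptom similarity
#'   (default 0.05); values are clipped to `[0, 1]` after noise.
#' @param seed RNG seed.
#' @return a `generator_params` list.
#' @export
generator_params <- function(n_d = 39, n_m = 292,
                             n_disease_groups = 5, n_microbe_groups = 5,
                             p_in = 0.25, p_out = 0.01,
                             symptom_in = 0.6, symptom_out = 0.1,
                             symptom_noise_sd = 0.05, seed = 1) {
  if (n_d < 1 || n_m < 1 || n_disease_groups < 1 || n_microbe_groups < 1)
    stop_usage("dimensions and group counts must be positive")
  if (!(p_out >= 0 && p_out <= p_in && p_in <= 1))
    stop_usage("need 0 <= p_out <= p_in <= 1")
  if (symptom_noise_sd < 0) stop_usage("symptom_noise_sd must be nonnegative")
  structure(list(n_d = n_d, n_m = n_m,
                 n_disease_groups = n_disease_groups,
                 n_microbe_groups = n_microbe_groups,
                 p_in = p_in, p_out = p_out,
                 symptom_in = symptom_in, symptom_out = symptom_out,
                 symptom_noise_sd = symptom_noise_sd, seed = seed),
            class = "generator_params")
}

#' Generate a synthetic association matrix with planted structure
#'
#' Diseases and microbes are assigned to groups cyclically; `A[i, j]` is
#' Bernoulli(`p_in`) when disease `i`'s group is paired with microbe `j`'s
#' group and Bernoulli(`p_out`) otherwise. Any all-zero row or column is
#' rescued with one association at a matched cell (the Gaussian kernels
#' need nonzero profiles). The symptom similarity is
#' `symptom_in`/`symptom_out` by disease-group co-membership plus Gaussian
#' noise, symmetrized, unit diagonal, clipped to `[0, 1]`.
#'
#' @param params a [generator_params()] object.
#' @return list with `A` (binary association matrix), `ds_symptom`
#'   (symptom-style disease similarity), `disease_groups`,
#'   `microbe_groups` (named integer vectors), and `params`.
#' @export
simulate_associations <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  p <- params
  disease_ids <- sprintf("D%03d", seq_len(p$n_d))
  microbe_ids <- sprintf("M%04d", seq_len(p$n_m))
  dg <- rep_len(seq_len(p$n_disease_groups), p$n_d)
  mg <- rep_len(seq_len(p$n_microbe_groups), p$n_m)
  matched_mg <- ((seq_len(p$n_disease_groups) - 1L) %% p$n_microbe_groups) + 1L
  with_seed(p$seed, {
    matched <- outer(matched_mg[dg], mg, "==")
    prob <- ifelse(matched, p$p_in, p$p_out)
    A <- matrix(stats::rbinom(length(prob), 1L, prob), p$n_d, p$n_m,
                dimnames = list(disease_ids, microbe_ids))
    # rescue empty profiles with one matched association
    for (i in which(rowSums(A) == 0)) {
      cols <- which(matched[i, ])
      if (length(cols) == 0L) cols <- seq_len(p$n_m)
      A[i, cols[sample.int(length(cols), 1L)]] <- 1L
    }
    for (j in which(colSums(A) == 0)) {
      rows <- which(matched[, j])
      if (length(rows) == 0L) rows <- seq_len(p$n_d)
      A[rows[sample.int(length(rows), 1L)], j] <- 1L
    }
    base <- matrix(p$symptom_out, p$n_d, p$n_d)
    base[outer(dg, dg, "==")] <- p$symptom_in
    noise <- matrix(stats::rnorm(p$n_d^2, sd = p$symptom_noise_sd), p$n_d, p$n_d)
    M <- (base + noise + t(base + noise)) / 2
    M <- pmin(pmax(M, 0), 1)
    diag(M) <- 1
    dimnames(M) <- list(disease_ids, disease_ids)
    attr(M, "kind") <- "disease_symptom"
    storage.mode(A) <- "double"
    list(A = A,
         ds_symptom = M,
         disease_groups = stats::setNames(dg, disease_ids),
         microbe_groups = stats::setNames(mg, microbe_ids),
         params = p)
  })
}
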