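# Comparison scorers: truncated SVD reconstruction, a latent factor model
# fitted by full-gradient descent, and a truncated Katz index on the
# similarity-augmented heterogeneous network.

#' SVD reconstruction scores
#'
#' Reconstructs the association matrix from its top singular triplets and
#' uses the reconstruction as the score matrix.
#'
#' @param A binary association matrix.
#' @param rank `"full"` (default) or an integer in `[1, min(n_d, n_m)]`.
#' @return score matrix with `model_tag = "svd"`.
#' @export
svd_scores <- function(A, rank = "full") {
  validate_association(A)
  kmax <- min(dim(A))
  k <- if (identical(rank, "full")) kmax else rank
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > kmax || k != round(k))
    stop_usage("rank must be 'full' or an integer in [1, ", kmax, "]")
  sv <- svd(A)
  S <- sv$u[, seq_len(k), drop = FALSE] %*%
    (sv$d[seq_len(k)] * t(sv$v[, seq_len(k), drop = FALSE]))
  dimnames(S) <- dimnames(A)
  attr(S, "model_tag") <- "svd"
  S
}

#' Latent factor model scores
#'
#' Factorizes `A ~ P %*% t(Q)` with `n_factors` latent dimensions by
#' full-gradient descent on the squared error over every matrix cell (zeros
#' act as weak negatives) plus an L2 penalty on both factor matrices. The
#' factor count may exceed `min(n_d, n_m)` (overcomplete factorizations are
#' allowed). The per-epoch penalized loss is recorded in `attr(, "loss")`;
#' the fitted factors are kept in `attr(, "P")` and `attr(, "Q")`.
#'
#' @param A binary association matrix.
#' @param n_factors latent dimension (default 100).
#' @param learning_rate gradient-descent step size (default 0.01).
#' @param l2_penalty L2 regularization weight (default 0.01).
#' @param n_epochs number of full-gradient steps (default 200).
#' @param seed RNG seed for the factor initialization.
#' @return score matrix `P %*% t(Q)` with `model_tag = "lfm"` and
#'   attributes `loss`, `P`, `Q`.
#' @export
lfm_scores <- function(A, n_factors = 100, learning_rate = 0.01,
                       l2_penalty = 0.01, n_epochs = 200, seed = 1) {
  validate_association(A)
  if (n_factors < 1 || n_epochs < 1 || learning_rate <= 0 || l2_penalty < 0)
    stop_usage("invalid latent factor model parameters")
  n_d <- nrow(A); n_m <- ncol(A)
  fit <- with_seed(seed, {
    P <- matrix(stats::rnorm(n_d * n_factors, sd = 0.1), n_d, n_factors)
    Q <- matrix(stats::rnorm(n_m * n_factors, sd = 0.1), n_m, n_factors)
    loss <- numeric(n_epochs)
    for (epoch in seq_len(n_epochs)) {
      E <- A - tcrossprod(P, Q)
      loss[epoch] <- sum(E^2) + l2_penalty * (sum(P^2) + sum(Q^2))
      if (!is.finite(loss[epoch]))
        stop_data("latent factor training diverged (non-finite loss); ",
                  "try a smaller learning_rate")
      Pn <- P + learning_rate * (2 * E %*% Q - 2 * l2_penalty * P)
      Qn <- Q + learning_rate * (2 * crossprod(E, P) - 2 * l2_penalty * Q)
      P <- Pn; Q <- Qn
    }
    list(P = P, Q = Q, loss = loss)
  })
  S <- tcrossprod(fit$P, fit$Q)
  dimnames(S) <- dimnames(A)
  attr(S, "model_tag") <- "lfm"
  attr(S, "loss") <- fit$loss
  attr(S, "P") <- fit$P
  attr(S, "Q") <- fit$Q
  S
}

#' Truncated Katz scores on the heterogeneous network
#'
#' Builds the similarity-augmented adjacency
#' `H = rbind(cbind(DS, A), cbind(t(A), MS))` and sums damped walk counts
#' `sum_{l=1}^{L} katz_beta^l * H^l`; the upper-right `n_d x n_m` block is
#' the score matrix. With the default `max_path_length = 3` the similarity
#' blocks contribute to disease-microbe paths.
#'
#' @param A binary association matrix.
#' @param DS disease similarity.
#' @param MS microbe similarity.
#' @param katz_beta walk damping factor (default 0.01).
#' @param max_path_length maximum walk length `L >= 1` (default 3).
#' @return score matrix with `model_tag = "katz"`.
#' @export
katz_scores <- function(A, DS, MS, katz_beta = 0.01, max_path_length = 3) {
  if (nrow(DS) != nrow(A) || nrow(MS) != ncol(A))
    stop_data("similarity shapes do not match the association matrix")
  if (katz_beta <= 0) stop_usage("katz_beta must be positive")
  if (max_path_length < 1 || max_path_length != round(max_path_length))
    stop_usage("max_path_length must be a positive integer")
  n_d <- nrow(A); n_m <- ncol(A)
  H <- rbind(cbind(DS, A), cbind(t(A), MS))
  Hl <- H
  S <- katz_beta * H
  if (max_path_length > 1) {
    for (l in seq(2, max_path_length)) {
      Hl <- Hl %*% H
      S <- S + katz_beta^l * Hl
    }
  }
  out <- S[seq_len(n_d), n_d + seq_len(n_m), drop = FALSE]
  dimnames(out) <- dimnames(A)
  attr(out, "model_tag") <- "katz"
  out
}
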