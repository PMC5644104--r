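# Two-step similarity-weighted diffusion on the disease-microbe bipartite
# graph. Mass placed on microbe nodes is distributed to disease nodes
# through the similarity-weighted adjacencies (step 1) and returned to
# microbe nodes (step 2), yielding the GS score matrix.

#' Diffusion damping factors
#'
#' `alpha` and `beta` are convex-combination weights balancing the
#' microbe-similarity-weighted adjacency (`A %*% MS`) against the
#' disease-similarity-weighted adjacency (`DS %*% A`) in diffusion steps 1
#' and 2 respectively.
#'
#' @param alpha,beta reals in `[0, 1]` (default 0.5 each).
#' @return a `diffusion_params` list.
#' @export
diffusion_params <- function(alpha = 0.5, beta = 0.5) {
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1)
    stop_usage("alpha must lie in [0, 1]")
  if (!is.numeric(beta) || beta < 0 || beta > 1)
    stop_usage("beta must lie in [0, 1]")
  structure(list(alpha = alpha, beta = beta), class = "diffusion_params")
}

#' Similarity-weighted adjacency matrices
#'
#' `a_d = DS %*% A` and `a_m = A %*% MS`, both the same shape as `A`.
#'
#' @param A binary association matrix.
#' @param DS disease similarity (rows of `A`).
#' @param MS microbe similarity (columns of `A`).
#' @return list with components `a_d` and `a_m`.
#' @export
weighted_adjacencies <- function(A, DS, MS) {
  if (nrow(DS) != nrow(A) || ncol(DS) != nrow(A))
    stop_data("disease similarity shape does not match association matrix rows")
  if (nrow(MS) != ncol(A) || ncol(MS) != ncol(A))
    stop_data("microbe similarity shape does not match association matrix columns")
  a_d <- DS %*% A
  a_m <- A %*% MS
  dimnames(a_d) <- dimnames(A)
  dimnames(a_m) <- dimnames(A)
  list(a_d = a_d, a_m = a_m)
}

# Divide each column by its sum; all-zero columns stay zero (0/0 := 0).
normalize_columns <- function(M) {
  cs <- colSums(M)
  cs[cs == 0] <- Inf
  sweep(M, 2L, cs, "/")
}

# Divide each row by its sum; all-zero rows stay zero.
normalize_rows <- function(M) {
  rs <- rowSums(M)
  rs[rs == 0] <- Inf
  M / rs
}

#' Diffusion step 1: weight diseases by their associated microbes
#'
#' For each disease `d_i`, microbes transfer their weighted connection
#' degrees back to disease nodes:
#' `s(d_i) = alpha * sum_j a_m[i,j] * A[,j] / colsum_j(a_m)
#'         + (1 - alpha) * sum_j a_d[i,j] * A[,j] / colsum_j(a_d)`,
#' with any zero column sum contributing nothing. The result is an
#' `n_d x n_d` matrix whose column `i` is the weight vector `s(d_i)`.
#'
#' @param A binary association matrix.
#' @param wa output of [weighted_adjacencies()].
#' @param params a [diffusion_params()] object.
#' @return `n_d x n_d` disease weight matrix.
#' @export
diffuse_step1 <- function(A, wa, params = diffusion_params()) {
  if (!identical(dim(wa$a_d), dim(A)) || !identical(dim(wa$a_m), dim(A)))
    stop_data("weighted adjacency shapes do not match the association matrix")
  alpha <- params$alpha
  # column i of the result is A %*% (a_x[i, ] / colsums), i.e. A %*% t(colnorm)
  S1 <- alpha * A %*% t(normalize_columns(wa$a_m)) +
    (1 - alpha) * A %*% t(normalize_columns(wa$a_d))
  dimnames(S1) <- list(rownames(A), rownames(A))
  S1
}

#' Diffusion step 2: return disease weights to microbes
#'
#' `s'(m_j) = beta * sum_k a_m[k,j] * s(d_k) / rowsum_k(a_m)
#'          + (1 - beta) * sum_k a_d[k,j] * s(d_k) / rowsum_k(a_d)`,
#' with zero row sums contributing nothing. Joining the `n_m` column
#' vectors `s'(m_j)` gives the `n_d x n_m` graph score matrix GS.
#'
#' @param step1 disease weight matrix from [diffuse_step1()].
#' @param wa output of [weighted_adjacencies()].
#' @param params a [diffusion_params()] object.
#' @return GS score matrix with `model_tag = "graph"`.
#' @export
diffuse_step2 <- function(step1, wa, params = diffusion_params()) {
  if (nrow(step1) != nrow(wa$a_d) || ncol(step1) != nrow(wa$a_d))
    stop_data("step-1 weight matrix shape does not match the adjacencies")
  beta <- params$beta
  Mret <- beta * normalize_rows(wa$a_m) + (1 - beta) * normalize_rows(wa$a_d)
  GS <- step1 %*% Mret
  dimnames(GS) <- dimnames(wa$a_d)
  attr(GS, "model_tag") <- "graph"
  GS
}

#' Graph-based prediction
#'
#' Composition of [weighted_adjacencies()], [diffuse_step1()] and
#' [diffuse_step2()].
#'
#' @inheritParams weighted_adjacencies
#' @param params a [diffusion_params()] object.
#' @return GS score matrix.
#' @export
graph_predict <- function(A, DS, MS, params = diffusion_params()) {
  wa <- weighted_adjacencies(A, DS, MS)
  diffuse_step2(diffuse_step1(A, wa, params), wa, params)
}
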