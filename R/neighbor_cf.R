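# Neighbor-based collaborative filtering: disease-side (user-based) and
# microbe-side (item-based) scores and their average.

#' Disease-neighbor collaborative-filtering scores
#'
#' `S_disease(d_i, m_j) = sum_k DS(d_i, d_k) * A(k, j) / n_d`: each cell is
#' the disease-similarity-weighted count of diseases associated with microbe
#' `m_j`, normalized by the fixed number of diseases (not by the similarity
#' sum). Known positive pairs are scored like any other cell.
#'
#' @param A binary association matrix.
#' @param DS disease-disease similarity aligned with `A`'s rows.
#' @return score matrix with `model_tag = "disease_cf"`.
#' @export
disease_cf_scores <- function(A, DS) {
  if (nrow(DS) != nrow(A) || ncol(DS) != nrow(A))
    stop_data("disease similarity shape does not match association matrix rows")
  S <- DS %*% A / nrow(A)
  dimnames(S) <- dimnames(A)
  attr(S, "model_tag") <- "disease_cf"
  S
}

#' Microbe-neighbor collaborative-filtering scores
#'
#' `S_microbe(d_i, m_j) = sum_k MS(m_j, m_k) * A(i, k) / n_m`, the mirror of
#' [disease_cf_scores()] over microbes.
#'
#' @param A binary association matrix.
#' @param MS microbe-microbe similarity aligned with `A`'s columns.
#' @return score matrix with `model_tag = "microbe_cf"`.
#' @export
microbe_cf_scores <- function(A, MS) {
  if (nrow(MS) != ncol(A) || ncol(MS) != ncol(A))
    stop_data("microbe similarity shape does not match association matrix columns")
  S <- tcrossprod(A, MS) / ncol(A)  # S[i,j] = sum_k A[i,k] MS[j,k]
  dimnames(S) <- dimnames(A)
  attr(S, "model_tag") <- "microbe_cf"
  S
}

#' Neighbor-based prediction
#'
#' Computes both collaborative-filtering score matrices and their
#' elementwise mean `NS`.
#'
#' @inheritParams disease_cf_scores
#' @param MS microbe-microbe similarity.
#' @return list with components `s_disease`, `s_microbe` and `ns`
#'   (`model_tag = "neighbor"`).
#' @export
neighbor_predict <- function(A, DS, MS) {
  sd_ <- disease_cf_scores(A, DS)
  sm <- microbe_cf_scores(A, MS)
  ns <- (sd_ + sm) / 2
  attr(ns, "model_tag") <- "neighbor"
  list(s_disease = sd_, s_microbe = sm, ns = ns)
}
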