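# Gaussian interaction-profile kernel similarities and their integration
# with an external symptom-based disease similarity.

#' Gaussian interaction-profile kernel parameters
#'
#' The kernel bandwidth for each axis is normalized by the mean squared
#' association-profile norm: `gamma_d = gamma_prime_d / mean_k(||A[k,]||^2)`
#' (and analogously over columns for microbes). Under the default
#' `scaled_product` convention the similarity is
#' `exp(-gamma * ||profile_i - profile_j||^2)`, which is scale invariant in
#' the profiles; `as_printed_division` instead computes
#' `exp(-||profile_i - profile_j||^2 / gamma)`.
#'
#' @param gamma_prime_d,gamma_prime_m positive bandwidth inputs (default 0.5
#'   for both axes).
#' @param exponent_convention `"scaled_product"` (default) or
#'   `"as_printed_division"`.
#' @return a `kernel_params` list.
#' @export
kernel_params <- function(gamma_prime_d = 0.5, gamma_prime_m = 0.5,
                          exponent_convention = c("scaled_product",
                                                  "as_printed_division")) {
  exponent_convention <- match.arg(exponent_convention)
  if (!is.numeric(gamma_prime_d) || gamma_prime_d <= 0)
    stop_usage("gamma_prime_d must be positive")
  if (!is.numeric(gamma_prime_m) || gamma_prime_m <= 0)
    stop_usage("gamma_prime_m must be positive")
  structure(list(gamma_prime_d = gamma_prime_d,
                 gamma_prime_m = gamma_prime_m,
                 exponent_convention = exponent_convention),
            class = "kernel_params")
}

# Kernel over the rows of a profile matrix P.
gip_kernel <- function(P, gamma_prime, convention) {
  sq <- rowSums(P^2)
  denom <- mean(sq)
  if (denom == 0)
    stop_data("all association profiles are zero: kernel bandwidth ",
              "denominator mean(||profile||^2) is zero")
  gamma <- gamma_prime / denom
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(P)
  d2[d2 < 0] <- 0  # numerical noise from the expansion
  K <- if (convention == "scaled_product") exp(-gamma * d2) else exp(-d2 / gamma)
  K <- (K + t(K)) / 2
  diag(K) <- 1
  dimnames(K) <- list(rownames(P), rownames(P))
  K
}

#' Gaussian kernel disease similarity
#'
#' Similarity between two diseases as a Gaussian function of the Euclidean
#' distance between their binary microbe-association profiles (matrix rows),
#' with the bandwidth normalized by the mean squared row norm.
#'
#' @param A binary association matrix (diseases in rows).
#' @param params a [kernel_params()] object.
#' @return symmetric disease-by-disease similarity with unit diagonal,
#'   `kind = "disease_gaussian"`.
#' @examples
#' A <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("d1", "d2"), c("m1", "m2")))
#' gaussian_disease_similarity(A)[1, 2]  # exp(-1)
#' @export
gaussian_disease_similarity <- function(A, params = kernel_params()) {
  validate_association(A)
  K <- gip_kernel(A, params$gamma_prime_d, params$exponent_convention)
  attr(K, "kind") <- "disease_gaussian"
  K
}

#' Gaussian kernel microbe similarity
#'
#' Mirror of [gaussian_disease_similarity()] over the columns of `A`
#' (disease-association profiles of microbes).
#'
#' @inheritParams gaussian_disease_similarity
#' @return symmetric microbe-by-microbe similarity, `kind = "microbe_gaussian"`.
#' @export
gaussian_microbe_similarity <- function(A, params = kernel_params()) {
  validate_association(A)
  K <- gip_kernel(t(A), params$gamma_prime_m, params$exponent_convention)
  attr(K, "kind") <- "microbe_gaussian"
  K
}

#' Integrate Gaussian and symptom-based disease similarity
#'
#' Plain elementwise average of the two disease similarities; no
#' renormalization is applied.
#'
#' @param ds_gaussian Gaussian-kernel disease similarity.
#' @param ds_symptom symptom-based disease similarity on the same
#'   identifiers in the same order.
#' @return averaged similarity, `kind = "disease_integrated"`.
#' @export
integrate_disease_similarity <- function(ds_gaussian, ds_symptom) {
  if (!identical(dim(ds_gaussian), dim(ds_symptom)))
    stop_data("disease similarity matrices have different shapes")
  if (!is.null(rownames(ds_gaussian)) && !is.null(rownames(ds_symptom)) &&
      !identical(rownames(ds_gaussian), rownames(ds_symptom)))
    stop_data("disease similarity matrices are indexed by different identifiers")
  DS <- (ds_gaussian + ds_symptom) / 2
  attr(DS, "kind") <- "disease_integrated"
  DS
}
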