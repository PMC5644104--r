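# Correlation analysis of association neighborhoods: how internally similar
# are the disease cluster of each microbe and the microbe cluster of each
# disease, relative to the global similarity-profile correlation baseline.

#' Similarity-profile feature vectors
#'
#' Each entity is represented by its column of the similarity matrix, so
#' entity `i`'s feature vector is the vector of its similarities to all
#' entities.
#'
#' @param sim square similarity matrix.
#' @return matrix whose column `i` is entity `i`'s feature vector.
#' @export
feature_vectors <- function(sim) {
  validate_similarity(sim, tol = 1e-8)
  sim
}

#' Cluster-correlation report
#'
#' For each entity on the chosen axis with at least `min_degree`
#' associations, collects the similarity-profile feature vectors of its
#' partners, computes the Pearson correlation of every unordered pair, and
#' averages them into a cluster score. The baseline is the mean of the full
#' pairwise correlation matrix of all feature vectors (diagonal included by
#' default). Entities whose cluster score differs from the baseline by more
#' than `highlight_sd` standard deviations of the cluster-score
#' distribution are flagged `"above"` or `"below"`.
#'
#' @param A binary association matrix.
#' @param sim similarity matrix of the PARTNER axis: the disease similarity
#'   for `axis = "disease_clusters_per_microbe"`, the microbe similarity
#'   for `axis = "microbe_clusters_per_disease"`.
#' @param axis which clusters to analyze.
#' @param min_degree minimum number of associations (>= 2) for an entity to
#'   be analyzed.
#' @param highlight_sd highlight threshold in cluster-score standard
#'   deviations (default 1).
#' @param baseline_diagonal include the correlation-matrix diagonal in the
#'   baseline mean (default `TRUE`).
#' @return a `cluster_correlation` list with `report` (data frame:
#'   `entity_id`, `degree`, `cluster_score`, `flag`), `baseline`,
#'   `overall_mean`, `sd`, `axis`, and `n_constant` (feature-vector pairs
#'   with zero variance, whose correlation is defined as 0).
#' @export
cluster_scores <- function(A, sim,
                           axis = c("disease_clusters_per_microbe",
                                    "microbe_clusters_per_disease"),
                           min_degree = 2, highlight_sd = 1,
                           baseline_diagonal = TRUE) {
  axis <- match.arg(axis)
  validate_association(A)
  if (min_degree < 2) stop_usage("min_degree must be at least 2")
  if (axis == "disease_clusters_per_microbe") {
    if (nrow(sim) != nrow(A))
      stop_data("expected a disease similarity matrix for this axis")
    degrees <- colSums(A)
    entity_ids <- colnames(A)
    partners_of <- function(j) which(A[, j] == 1)
  } else {
    if (nrow(sim) != ncol(A))
      stop_data("expected a microbe similarity matrix for this axis")
    degrees <- rowSums(A)
    entity_ids <- rownames(A)
    partners_of <- function(i) which(A[i, ] == 1)
  }
  C <- suppressWarnings(stats::cor(feature_vectors(sim)))
  n_constant <- sum(!is.finite(C))
  if (n_constant > 0) {
    C[!is.finite(C)] <- 0
    message("cluster_scores: ", n_constant,
            " correlation entries involved a constant feature vector; set to 0")
  }
  keep <- which(degrees >= min_degree)
  if (length(keep) == 0L)
    stop_data("no entity has degree >= ", min_degree)
  scores <- vapply(keep, function(e) {
    p <- partners_of(e)
    sub <- C[p, p, drop = FALSE]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
  baseline <- if (baseline_diagonal) mean(C) else mean(C[row(C) != col(C)])
  sdv <- stats::sd(scores)
  flag <- rep("none", length(scores))
  if (is.finite(sdv) && sdv > 0) {
    flag[scores > baseline + highlight_sd * sdv] <- "above"
    flag[scores < baseline - highlight_sd * sdv] <- "below"
  }
  structure(list(
    report = data.frame(entity_id = entity_ids[keep],
                        degree = as.integer(degrees[keep]),
                        cluster_score = scores,
                        flag = flag,
                        stringsAsFactors = FALSE),
    baseline = baseline,
    overall_mean = mean(scores),
    sd = sdv,
    axis = axis,
    n_constant = n_constant
  ), class = "cluster_correlation")
}
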