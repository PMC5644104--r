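# The hybrid recommender: similarity computation, the two single models,
# and their unweighted average.

#' Model configuration
#'
#' Bundles kernel and diffusion parameters with the model selector. The
#' `model` field picks the pipeline output: the hybrid average
#' (`"ngrhmda"`), one of the single models (`"neighbor_only"`,
#' `"graph_only"`), or the neighbor model with the symptom similarity
#' ablated (`"neighbor_no_symptom"`, which uses the Gaussian disease
#' similarity alone, not averaged with zeros).
#'
#' @param model one of `"ngrhmda"`, `"neighbor_only"`, `"graph_only"`,
#'   `"neighbor_no_symptom"`.
#' @param kernel a [kernel_params()] object.
#' @param diffusion a [diffusion_params()] object.
#' @param use_symptom_similarity if `TRUE` (default) the disease similarity
#'   is the average of the Gaussian kernel and the symptom-based matrix;
#'   if `FALSE` the Gaussian kernel is used alone.
#' @return a `model_config` list.
#' @export
model_config <- function(model = c("ngrhmda", "neighbor_only", "graph_only",
                                   "neighbor_no_symptom"),
                         kernel = kernel_params(),
                         diffusion = diffusion_params(),
                         use_symptom_similarity = TRUE) {
  model <- match.arg(model)
  stopifnot(inherits(kernel, "kernel_params"),
            inherits(diffusion, "diffusion_params"))
  structure(list(model = model, kernel = kernel, diffusion = diffusion,
                 use_symptom_similarity = isTRUE(use_symptom_similarity)),
            class = "model_config")
}

# Disease/microbe similarities for a (possibly masked) training matrix.
compute_similarities <- function(A, ds_symptom = NULL, config = model_config()) {
  ds_g <- gaussian_disease_similarity(A, config$kernel)
  ms <- gaussian_microbe_similarity(A, config$kernel)
  use_sym <- config$use_symptom_similarity &&
    config$model != "neighbor_no_symptom"
  if (use_sym) {
    if (is.null(ds_symptom))
      stop_data("use_symptom_similarity is TRUE but no symptom-based ",
                "disease similarity was supplied")
    ds <- integrate_disease_similarity(ds_g, ds_symptom)
  } else {
    ds <- ds_g
  }
  list(DS = ds, MS = ms, DS_gaussian = ds_g)
}

#' Average the neighbor and graph score matrices
#'
#' `S = (NS + GS) / 2`, elementwise.
#'
#' @param ns neighbor-model score matrix.
#' @param gs graph-model score matrix.
#' @return combined score matrix with `model_tag = "ngrhmda"`.
#' @export
combine_scores <- function(ns, gs) {
  if (!identical(dim(ns), dim(gs)))
    stop_data("score matrices have different shapes")
  S <- (ns + gs) / 2
  attr(S, "model_tag") <- "ngrhmda"
  S
}

#' All component score matrices of the hybrid model
#'
#' Computes the similarities once and returns every intermediate: the two
#' collaborative-filtering matrices, their average `ns`, the diffusion
#' matrix `gs`, the hybrid average `s`, and the similarities used.
#'
#' @param A binary association matrix.
#' @param ds_symptom symptom-based disease similarity (required when
#'   `config$use_symptom_similarity` is `TRUE`).
#' @param config a [model_config()] object.
#' @return list with components `s_disease`, `s_microbe`, `ns`, `gs`, `s`,
#'   `similarities`.
#' @export
component_scores <- function(A, ds_symptom = NULL, config = model_config()) {
  validate_association(A)
  sims <- compute_similarities(A, ds_symptom, config)
  nb <- neighbor_predict(A, sims$DS, sims$MS)
  gs <- graph_predict(A, sims$DS, sims$MS, config$diffusion)
  list(s_disease = nb$s_disease, s_microbe = nb$s_microbe, ns = nb$ns,
       gs = gs, s = combine_scores(nb$ns, gs), similarities = sims)
}

#' End-to-end association prediction
#'
#' Runs the full pipeline and returns the score matrix selected by
#' `config$model`.
#'
#' @inheritParams component_scores
#' @return score matrix, `model_tag` recording the selected model.
#' @examples
#' sim <- simulate_associations(generator_params(n_d = 10, n_m = 20, seed = 1))
#' S <- predict_associations(sim$A, sim$ds_symptom)
#' @export
predict_associations <- function(A, ds_symptom = NULL, config = model_config()) {
  cs <- component_scores(A, ds_symptom, config)
  out <- switch(config$model,
                ngrhmda = cs$s,
                neighbor_only = cs$ns,
                neighbor_no_symptom = cs$ns,
                graph_only = cs$gs)
  attr(out, "model_tag") <- config$model
  out
}
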