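# Loading, validation and serialization of association and similarity data.
#
# Conventions used throughout the package:
#   * the association matrix A is binary with diseases as rows and microbes
#     as columns; dimnames carry the identifiers;
#   * similarity matrices are square, symmetric, identifier-indexed, with the
#     similarity kind stored in attr(, "kind");
#   * score matrices share A's shape and dimnames, with the producing model
#     recorded in attr(, "model_tag").

#' Validate a binary disease-by-microbe association matrix
#'
#' Checks that `A` is a numeric matrix with entries in \{0, 1\}, at least one
#' row and column, and unique identifiers on both axes.
#'
#' @param A numeric matrix, diseases in rows, microbes in columns, with
#'   dimnames giving the identifiers.
#' @return `A`, invisibly, if valid; otherwise an error.
#' @export
validate_association <- function(A) {
  if (!is.matrix(A) || !is.numeric(A))
    stop_data("association matrix must be a numeric matrix")
  if (nrow(A) < 1L || ncol(A) < 1L)
    stop_data("association matrix must have at least one disease and one microbe")
  if (!all(A %in% c(0, 1)))
    stop_data("association matrix entries must all be 0 or 1")
  ids <- dimnames(A)
  if (is.null(ids) || is.null(ids[[1L]]) || is.null(ids[[2L]]))
    stop_data("association matrix must carry disease and microbe identifiers as dimnames")
  if (anyDuplicated(ids[[1L]]))
    stop_data("duplicate disease identifiers")
  if (anyDuplicated(ids[[2L]]))
    stop_data("duplicate microbe identifiers")
  invisible(A)
}

#' Validate a square symmetric similarity matrix
#'
#' @param S numeric square matrix with identical row and column identifiers.
#' @param kind optional similarity kind to record in `attr(S, "kind")`; one
#'   of `"disease_gaussian"`, `"disease_symptom"`, `"disease_integrated"`,
#'   `"microbe_gaussian"`.
#' @param tol symmetry tolerance (default `1e-12`).
#' @return `S` (with `kind` attribute if supplied), invisibly.
#' @export
validate_similarity <- function(S, kind = NULL, tol = 1e-12) {
  if (!is.matrix(S) || !is.numeric(S) || nrow(S) != ncol(S))
    stop_data("similarity matrix must be a square numeric matrix")
  if (!all(is.finite(S)))
    stop_data("similarity matrix contains non-finite entries")
  if (max(abs(S - t(S))) > tol)
    stop_data("similarity matrix is not symmetric within tolerance ", format(tol))
  ids <- dimnames(S)
  if (!is.null(ids) && !identical(ids[[1L]], ids[[2L]]))
    stop_data("similarity matrix row and column identifiers differ")
  if (!is.null(kind)) attr(S, "kind") <- kind
  invisible(S)
}

#' Load a microbe-disease association edge list
#'
#' Reads a TSV edge list, collapses duplicate (disease, microbe) rows to a
#' single association, and builds the binary disease-by-microbe adjacency
#' matrix. Any evidence/PMID columns are ignored. Identifiers are sorted
#' lexicographically (C locale) so the axis order is deterministic.
#'
#' @param path path to a tab-separated file with a header row.
#' @param disease_col,microbe_col column names holding the disease and
#'   microbe identifiers (defaults `"disease"`, `"microbe"`).
#' @return the binary association matrix with identifiers as dimnames and an
#'   `edge_report` attribute `c(raw = <rows read>, distinct = <unique pairs>)`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("disease\tmicrobe", "d1\tm1", "d2\tm2", "d1\tm1"), tf)
#' A <- load_edge_list(tf)
#' attr(A, "edge_report")  # raw 3, distinct 2
#' @export
load_edge_list <- function(path, disease_col = "disease", microbe_col = "microbe") {
  if (!file.exists(path)) stop_data("edge list file not found: ", path)
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                      stringsAsFactors = FALSE, check.names = FALSE,
                      colClasses = "character"),
    error = function(e) stop_data("cannot read edge list ", path, ": ",
                                  conditionMessage(e))
  )
  for (col in c(disease_col, microbe_col)) {
    if (!col %in% names(df))
      stop_data("edge list is missing required column '", col, "'")
  }
  if (nrow(df) == 0L) stop_data("edge list ", path, " contains no edges")
  raw <- nrow(df)
  pairs <- unique(df[, c(disease_col, microbe_col)])
  disease_ids <- sort(unique(pairs[[disease_col]]), method = "radix")
  microbe_ids <- sort(unique(pairs[[microbe_col]]), method = "radix")
  A <- matrix(0, length(disease_ids), length(microbe_ids),
              dimnames = list(disease_ids, microbe_ids))
  A[cbind(match(pairs[[disease_col]], disease_ids),
          match(pairs[[microbe_col]], microbe_ids))] <- 1
  attr(A, "edge_report") <- c(raw = raw, distinct = nrow(pairs))
  validate_association(A)
  A
}

#' Write an association matrix back to an edge list
#'
#' Inverse of [load_edge_list()]: one row per association, sorted by
#' (disease, microbe) identifier.
#'
#' @param A binary association matrix.
#' @param path output TSV path.
#' @param disease_col,microbe_col header names to write.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(A, path, disease_col = "disease", microbe_col = "microbe") {
  validate_association(A)
  idx <- which(A == 1, arr.ind = TRUE)
  df <- data.frame(disease = rownames(A)[idx[, 1L]],
                   microbe = colnames(A)[idx[, 2L]],
                   stringsAsFactors = FALSE)
  df <- df[order(df$disease, df$microbe, method = "radix"), , drop = FALSE]
  names(df) <- c(disease_col, microbe_col)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a precomputed similarity matrix
#'
#' Reads a dense square CSV (identifiers in the first row and column),
#' symmetrizes it, and reindexes it to `expected_ids`. Identifiers absent
#' from the file are filled with zero rows/columns (including a zero
#' diagonal) under `missing_policy = "zero"`, or raise an error under
#' `missing_policy = "error"`. Asymmetry beyond `1e-8` is an error; smaller
#' asymmetry is removed as `(M + t(M)) / 2`.
#'
#' @param path CSV path.
#' @param expected_ids identifier vector defining the output order.
#' @param missing_policy `"zero"` (default) or `"error"`.
#' @param kind similarity kind label (default `"disease_symptom"`).
#' @return similarity matrix indexed by `expected_ids`.
#' @export
load_similarity <- function(path, expected_ids,
                            missing_policy = c("zero", "error"),
                            kind = "disease_symptom") {
  missing_policy <- match.arg(missing_policy)
  if (!file.exists(path)) stop_data("similarity file not found: ", path)
  m <- tryCatch(
    as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE)),
    error = function(e) stop_data("cannot read similarity ", path, ": ",
                                  conditionMessage(e))
  )
  if (nrow(m) != ncol(m)) stop_data("similarity file is not square: ", path)
  if (!setequal(rownames(m), colnames(m)))
    stop_data("similarity row and column headers do not match in ", path)
  m <- m[, rownames(m), drop = FALSE]
  storage.mode(m) <- "double"
  if (!all(is.finite(m))) stop_data("similarity file has non-finite entries")
  asym <- max(abs(m - t(m)))
  if (asym > 1e-8)
    stop_data("similarity matrix asymmetry ", format(asym),
              " exceeds tolerance 1e-8")
  m <- (m + t(m)) / 2
  missing <- setdiff(expected_ids, rownames(m))
  if (length(missing) && missing_policy == "error")
    stop_data("similarity file is missing identifiers: ",
              paste(missing, collapse = ", "))
  out <- matrix(0, length(expected_ids), length(expected_ids),
                dimnames = list(expected_ids, expected_ids))
  common <- intersect(expected_ids, rownames(m))
  out[common, common] <- m[common, common]
  validate_similarity(out, kind = kind, tol = 1e-8)
  attr(out, "kind") <- kind
  out
}

#' Write a similarity matrix as CSV
#'
#' @param sim similarity matrix with identifier dimnames.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(sim, path) {
  utils::write.csv(as.data.frame(sim), path, quote = FALSE)
  invisible(path)
}

#' Write ranked predictions
#'
#' Emits a TSV with columns `disease_id`, `microbe_id`, `score`,
#' `known_flag`, sorted by score descending within each disease with stable
#' ties broken by (disease_id, microbe_id). Scores are printed with 6
#' significant digits.
#'
#' @param scores score matrix aligned with `known`.
#' @param known binary association matrix flagging known pairs.
#' @param path output TSV path.
#' @return the written data frame, invisibly.
#' @export
write_scores <- function(scores, known, path) {
  validate_association(known)
  if (!identical(dim(scores), dim(known)))
    stop_data("score and association matrices have different shapes")
  df <- data.frame(
    disease_id = rep(rownames(known), times = ncol(known)),
    microbe_id = rep(colnames(known), each = nrow(known)),
    score = as.vector(scores),
    known_flag = as.integer(as.vector(known)),
    stringsAsFactors = FALSE
  )
  ord <- order(df$disease_id, -xtfrm(df$score), df$microbe_id, method = "radix")
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  out <- df
  out$score <- sprintf("%.6g", df$score)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
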