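# Lightweight S3 containers for the WNN workflow. These mirror the slots a
# multimodal analysis needs to carry between steps: raw counts, normalized
# matrices + embeddings, neighbor graphs, bandwidths, modality weights, and
# the final weighted graph.

#' Construct a counts matrix container
#'
#' Wraps a non-negative features x cells count matrix together with feature
#' and cell identifiers and a modality tag. Sparse (`dgCMatrix`) and dense
#' matrices are both accepted.
#'
#' @param values features x cells matrix of non-negative counts.
#' @param feature_ids character vector of feature names (defaults to rownames).
#' @param cell_ids character vector of unique cell names (defaults to colnames).
#' @param modality one of `"rna"`, `"protein"`, `"atac"`, `"other"`.
#' @return an object of class `CountsMatrix`.
#' @export
counts_matrix <- function(values, feature_ids = rownames(values),
                          cell_ids = colnames(values),
                          modality = c("rna", "protein", "atac", "other")) {
  modality <- match.arg(modality)
  if (is.null(feature_ids))
    feature_ids <- as.character(sprintf("feature%d", seq_len(nrow(values))))
  if (is.null(cell_ids))
    cell_ids <- as.character(sprintf("cell%d", seq_len(ncol(values))))
  if (length(feature_ids) != nrow(values))
    stopf("feature_ids length (%d) does not match rows (%d)", length(feature_ids), nrow(values))
  if (length(cell_ids) != ncol(values))
    stopf("cell_ids length (%d) does not match columns (%d)", length(cell_ids), ncol(values))
  if (anyDuplicated(cell_ids)) stopf("cell_ids must be unique")
  if (length(values) > 0 && min(values) < 0) stopf("counts must be non-negative")
  rownames(values) <- feature_ids
  colnames(values) <- cell_ids
  structure(
    list(values = values, feature_ids = feature_ids, cell_ids = cell_ids,
         modality_tag = modality),
    class = "CountsMatrix"
  )
}

#' @export
print.CountsMatrix <- function(x, ...) {
  cat(sprintf("CountsMatrix [%s]: %d features x %d cells (%s)\n",
              x$modality_tag, nrow(x$values), ncol(x$values),
              if (methods::is(x$values, "sparseMatrix")) "sparse" else "dense"))
  invisible(x)
}

#' @export
dim.CountsMatrix <- function(x) dim(x$values)

new_modality_view <- function(normalized, embedding, reduction_tag,
                              loadings = NULL, singular_values = NULL) {
  stopifnot(ncol(embedding) >= 2)
  structure(
    list(normalized = normalized, embedding = embedding, d = ncol(embedding),
         reduction_tag = reduction_tag, loadings = loadings,
         singular_values = singular_values,
         zero_cells = attr(embedding, "zero_rows")),
    class = "ModalityView"
  )
}

#' @export
print.ModalityView <- function(x, ...) {
  cat(sprintf("ModalityView: %d cells embedded in %d dims (%s)\n",
              nrow(x$embedding), x$d, x$reduction_tag))
  invisible(x)
}

new_neighbor_graph <- function(indices, distances, k, self_excluded = TRUE,
                               backend = "exact") {
  structure(
    list(indices = indices, distances = distances, k = k,
         self_excluded = self_excluded, backend = backend),
    class = "NeighborGraph"
  )
}

#' @export
print.NeighborGraph <- function(x, ...) {
  cat(sprintf("NeighborGraph: %d cells, k = %d (%s backend, self %s)\n",
              nrow(x$indices), x$k, x$backend,
              if (x$self_excluded) "excluded" else "included"))
  invisible(x)
}

#' @export
print.WeightSet <- function(x, ...) {
  cat(sprintf("WeightSet: %d cells x %d modalities (%s)\n",
              nrow(x$weights), ncol(x$weights),
              paste(colnames(x$weights), collapse = ", ")))
  cat("mean weights:", paste(sprintf("%s=%.3f", colnames(x$weights),
                                     colMeans(x$weights)), collapse = " "), "\n")
  invisible(x)
}

#' @export
print.WnnGraph <- function(x, ...) {
  cat(sprintf("WnnGraph: %d cells, k = %d, candidate width %d\n",
              nrow(x$indices), x$k, x$candidate_width))
  invisible(x)
}

#' @export
print.SpcaModel <- function(x, ...) {
  cat(sprintf("SpcaModel: %d features -> %d supervised components\n",
              nrow(x$U), ncol(x$U)))
  invisible(x)
}
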