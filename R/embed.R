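# Dimensional reduction per modality. Both reducers return a ModalityView
# whose `embedding` rows are L2-normalized, so every downstream Euclidean
# distance lives on the unit sphere (equivalent to cosine distance on scores).

# Truncated SVD dispatcher: dense/base for small problems (exact, stable near
# full rank), irlba otherwise.
truncated_svd <- function(x, d) {
  small <- min(dim(x)) <= 100 || d > min(dim(x)) / 2
  if (small) {
    s <- svd(x, nu = d, nv = d)
    list(u = s$u, d = s$d[seq_len(d)], v = s$v)
  } else {
    s <- irlba::irlba(x, nv = d)
    list(u = s$u, d = s$d, v = s$v)
  }
}

#' PCA embedding of a normalized modality
#'
#' Computes the top-`d` principal-component scores of the cells (features are
#' the variables), optionally centering and unit-variance scaling each feature
#' first, then L2-normalizes each cell's score vector. Scaling is the default
#' for RNA and protein modalities, mirroring the standard workflow.
#'
#' @param normalized features x cells matrix (output of [log_normalize()] or
#'   [clr_normalize()]).
#' @param d number of components (>= 2, < min(features, cells)).
#' @param center_scale logical; center and scale features before PCA.
#' @return a `ModalityView` with `embedding` (cells x d, unit rows), raw
#'   `scores`, feature `loadings` and `singular_values`.
#' @export
pca_embed <- function(normalized, d, center_scale = TRUE) {
  x <- as.matrix(normalized)
  if (d < 2) stopf("d must be >= 2")
  if (d >= min(dim(x)))
    stopf("d = %d must be < min(features, cells) = %d", d, min(dim(x)))
  if (center_scale) {
    mu <- rowMeans(x)
    sds <- matrixStats::rowSds(x)
    sds[sds == 0] <- 1
    x <- (x - mu) / sds
  } else {
    x <- x - rowMeans(x)  # PCA always centers; scaling is the option
  }
  s <- truncated_svd(t(x), d)   # cells x features
  tol <- max(dim(x)) * .Machine$double.eps * s$d[1]
  attainable <- sum(s$d > tol)
  if (attainable < d)
    stopf("d = %d exceeds the numerical rank; attainable rank is %d", d, attainable)
  scores <- s$u %*% diag(s$d, d, d)
  rownames(scores) <- colnames(normalized)
  colnames(scores) <- paste0("PC", seq_len(d))
  emb <- l2_normalize_rows(scores)
  view <- new_modality_view(normalized, emb, "pca",
                            loadings = s$v, singular_values = s$d)
  view$scores <- scores
  view
}

#' LSI embedding of a TF-IDF matrix
#'
#' Decomposes the TF-IDF matrix by truncated SVD, standardizes each retained
#' component's cell scores to mean 0 / sd 1, optionally drops the first
#' component (which typically tracks per-cell sequencing depth), and
#' L2-normalizes the rows. This is the standard scATAC-seq reduction.
#'
#' @param tfidf_matrix peaks x cells matrix from [tfidf_normalize()].
#' @param d number of retained components.
#' @param drop_first drop component 1 (default TRUE).
#' @return a `ModalityView` with standardized, L2-normalized `embedding`.
#' @export
lsi_embed <- function(tfidf_matrix, d, drop_first = TRUE) {
  n_comp <- d + as.integer(drop_first)
  if (d < 2) stopf("d must be >= 2")
  if (n_comp > min(dim(tfidf_matrix)))
    stopf("d + drop_first = %d exceeds min(dim) = %d", n_comp, min(dim(tfidf_matrix)))
  s <- truncated_svd(Matrix::t(tfidf_matrix), n_comp)  # cells x peaks
  scores <- s$u %*% diag(s$d, n_comp, n_comp)
  keep <- if (drop_first) seq(2, n_comp) else seq_len(n_comp)
  scores <- scores[, keep, drop = FALSE]
  sds <- matrixStats::colSds(scores)
  if (any(sds == 0))
    stopf("LSI component(s) %s are constant (sd 0); reduce d",
          paste(keep[sds == 0], collapse = ", "))
  scores <- scale(scores)  # per-component mean 0, sd 1
  rownames(scores) <- colnames(tfidf_matrix)
  colnames(scores) <- paste0("LSI", keep)
  emb <- l2_normalize_rows(scores)
  view <- new_modality_view(tfidf_matrix, emb, "lsi",
                            loadings = s$v, singular_values = s$d)
  view$scores <- scores[, , drop = FALSE]
  view
}
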