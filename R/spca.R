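# Supervised PCA of the reference transcriptome against the WNN graph
# kernel. The Hilbert-Schmidt Independence Criterion between the linear
# kernel of the projected expression and a response kernel L is
#   HSIC(K, L) = tr(K H L H) / (n - 1)^2 ,  H = I - ee^T / n ,
# and maximizing tr(U^T X H L H X^T U) subject to U^T U = I is solved by the
# top-d eigenvectors of X H L H X^T. Setting L to the Jaccard SNN matrix of
# the WNN graph makes the supervised components the transcriptomic
# directions that best reproduce the joint multimodal structure.

#' Select variable features by standardized dispersion
#'
#' Ranks features by the z-scored log variance-to-mean ratio within bins of
#' mean expression (the classic dispersion method), returning the top
#' `n_features` names. Used to restrict the sPCA input.
#'
#' @param x normalized features x cells matrix.
#' @param n_features number of features to keep (default 2000).
#' @param n_bins number of mean-expression bins (default 20).
#' @return character vector of feature names (or indices if unnamed).
#' @export
select_variable_features <- function(x, n_features = 2000, n_bins = 20) {
  x <- as.matrix(x)
  mu <- rowMeans(x)
  v <- matrixStats::rowVars(x)
  disp <- ifelse(mu > 0, v / mu, 0)
  bins <- cut(mu, breaks = n_bins, labels = FALSE)
  z <- numeric(length(mu))
  for (b in unique(bins)) {
    sel <- bins == b
    m <- mean(disp[sel]); s <- stats::sd(disp[sel])
    z[sel] <- if (is.na(s) || s == 0) 0 else (disp[sel] - m) / s
  }
  ord <- order(z, decreasing = TRUE)[seq_len(min(n_features, nrow(x)))]
  if (!is.null(rownames(x))) rownames(x)[ord] else ord
}

#' Fit a supervised PCA model
#'
#' Computes the top-`d` eigenvectors `U` of `X H L H X^T`, where `X` is the
#' (variable-feature) normalized expression matrix, `H` the cell-centering
#' matrix, and `L` a cell-cell similarity kernel — here, the Jaccard SNN
#' matrix of the WNN graph. `H L H` is never materialized: `X H` is plain
#' row-centering, and `L` stays sparse. With `L = I` the model reduces
#' exactly to ordinary PCA of the cell-centered matrix.
#'
#' @param X normalized expression, features x cells (restrict to variable
#'   features first; see [select_variable_features()]).
#' @param L sparse symmetric cells x cells kernel (symmetrized if not).
#' @param d number of supervised components.
#' @return an `SpcaModel`: loadings `U` (features x d, orthonormal),
#'   `eigenvalues` (descending), `feature_ids`, `centering_means`, and the
#'   L2-normalized reference `scores` (cells x d).
#' @export
spca_fit <- function(X, L, d) {
  X <- as.matrix(X)
  f <- nrow(X); n <- ncol(X)
  if (d > f) stopf("d = %d exceeds the number of features (%d)", d, f)
  if (nrow(L) != n || ncol(L) != n) stopf("L must be cells x cells (%d)", n)
  if (max(abs(L - Matrix::t(L))) > 1e-8) L <- (L + Matrix::t(L)) / 2
  mu <- rowMeans(X)
  Xc <- X - mu                      # X H: center over cells
  A <- as.matrix(Xc %*% L)          # f x n, sparse product
  # (X H) L (X H)^T; the second H is absorbed because rows of Xc are centered
  M <- tcrossprod(A - rowMeans(A), Xc)
  M <- (M + t(M)) / 2
  use_rspectra <- requireNamespace("RSpectra", quietly = TRUE) && d < f / 3 && f > 200
  if (use_rspectra) {
    es <- RSpectra::eigs_sym(M, k = d)
    vals <- es$values; vecs <- es$vectors
  } else {
    es <- eigen(M, symmetric = TRUE)
    vals <- es$values[seq_len(d)]; vecs <- es$vectors[, seq_len(d), drop = FALSE]
  }
  tol <- max(f, n) * .Machine$double.eps * max(abs(vals[1]), 1)
  attainable <- sum(vals > tol)
  if (attainable < d)
    stopf("d = %d exceeds the numerical rank of XHLHX^T; attainable rank is %d",
          d, attainable)
  rownames(vecs) <- rownames(X)
  colnames(vecs) <- paste0("SPC", seq_len(d))
  scores <- crossprod(Xc, vecs)     # cells x d
  rownames(scores) <- colnames(X)
  model <- structure(
    list(U = vecs, eigenvalues = vals,
         feature_ids = rownames(X), centering_means = mu,
         scores = l2_normalize_rows(scores),
         trained_on = sprintf("%d features x %d cells", f, n)),
    class = "SpcaModel")
  model
}

#' Project a query dataset through a supervised PCA model
#'
#' Centers the query with the reference feature means and applies `U^T`.
#' Query features are intersected with the model's; model features missing
#' from the query contribute 0 after centering (with a warning when the
#' overlap is below 50%). Rows of the result are L2-normalized, matching the
#' reference scores.
#'
#' @param model an `SpcaModel`.
#' @param X_query normalized query expression, features x cells, rownames
#'   required when the feature sets differ.
#' @return query embedding, cells x d with unit rows.
#' @export
spca_project <- function(model, X_query) {
  X_query <- as.matrix(X_query)
  feats <- model$feature_ids
  if (is.null(rownames(X_query))) {
    if (nrow(X_query) != length(feats))
      stopf("unnamed query features must match the model's feature count")
    rownames(X_query) <- feats
  }
  shared <- intersect(feats, rownames(X_query))
  if (length(shared) == 0) stopf("no feature overlap between query and model")
  frac <- length(shared) / length(feats)
  if (frac < 0.5)
    warnf("only %.0f%% of model features found in query; missing features contribute 0",
          100 * frac)
  idx <- match(shared, feats)
  Xc <- X_query[shared, , drop = FALSE] - model$centering_means[idx]
  scores <- crossprod(Xc, model$U[idx, , drop = FALSE])
  rownames(scores) <- colnames(X_query)
  l2_normalize_rows(scores)
}
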