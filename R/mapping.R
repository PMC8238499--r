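# Reference mapping: mutual-nearest-neighbor anchors between the reference
# and a projected query, weighted-vote label transfer, and visualization of
# the query in the reference UMAP layout (or a de-novo merged layout).

#' Find mutual-nearest-neighbor anchors between reference and query
#'
#' A pair (r, q) is an anchor when q is among the `k_anchor` nearest query
#' cells of r and r is among the `k_anchor` nearest reference cells of q, in
#' the shared (sPCA) embedding. Each anchor is scored by the Jaccard overlap
#' of the two cells' `k_score`-neighborhoods in the combined embedding, a
#' value in \[0, 1\] (high overlap = consistent local structure).
#'
#' @param ref_embedding reference cells x d matrix (L2-normalized rows).
#' @param query_embedding query cells x d matrix in the same space.
#' @param k_anchor mutuality neighborhood size (default 5).
#' @param k_score neighborhood size for the anchor score (default 30).
#' @return an `AnchorSet`: data frame `pairs` (ref, query, score).
#' @export
find_anchors <- function(ref_embedding, query_embedding, k_anchor = 5,
                         k_score = 30) {
  nr <- nrow(ref_embedding); nq <- nrow(query_embedding)
  if (ncol(ref_embedding) != ncol(query_embedding))
    stopf("embeddings have different dimensionality")
  ka <- min(k_anchor, nr, nq)
  r2q <- RANN::nn2(query_embedding, ref_embedding, k = ka)$nn.idx
  q2r <- RANN::nn2(ref_embedding, query_embedding, k = ka)$nn.idx
  pairs <- do.call(rbind, lapply(seq_len(nr), function(r) {
    qs <- r2q[r, ]
    hit <- qs[apply(q2r[qs, , drop = FALSE] == r, 1, any)]
    if (length(hit)) cbind(ref = r, query = hit) else NULL
  }))
  if (is.null(pairs) || nrow(pairs) == 0)
    stopf("no mutual-nearest-neighbor anchors found; try a larger k_anchor")
  # score: Jaccard of k_score-neighborhoods in the combined embedding
  comb <- rbind(ref_embedding, query_embedding)
  ks <- min(k_score, nrow(comb) - 1)
  g <- build_knn(comb, k = ks)
  nbr <- cbind(g$indices, seq_len(nrow(comb)))  # sets include self
  score <- vapply(seq_len(nrow(pairs)), function(p) {
    a <- nbr[pairs[p, 1], ]
    b <- nbr[pairs[p, 2] + nr, ]
    length(intersect(a, b)) / length(union(a, b))
  }, numeric(1))
  structure(list(pairs = data.frame(ref = pairs[, 1], query = pairs[, 2],
                                    score = score),
                 k_anchor = k_anchor, k_score = k_score),
            class = "AnchorSet")
}

#' @export
print.AnchorSet <- function(x, ...) {
  cat(sprintf("AnchorSet: %d anchors (mean score %.3f)\n",
              nrow(x$pairs), mean(x$pairs$score)))
  invisible(x)
}

#' Transfer reference labels to query cells by weighted anchor vote
#'
#' Each query cell collects its `k_weight` nearest anchors (by distance to
#' the anchors' query-side cells in the shared embedding). Each anchor votes
#' for its reference cell's label with weight
#' `exp(-d^2 / (2 * d_k^2)) * (score + 1e-6)`, a Gaussian kernel whose
#' bandwidth is the distance to the `k_weight`-th anchor, times the anchor
#' quality score. Votes are accumulated per label and normalized to sum to
#' 1; the prediction is the argmax (ties broken by label order).
#'
#' @param anchors an `AnchorSet`.
#' @param ref_labels factor/character labels of the reference cells.
#' @param query_embedding query cells x d matrix (same space as the anchors).
#' @param k_weight anchors per query cell (default 50; reduced with a
#'   warning if fewer anchors exist).
#' @param score_threshold optional minimum winning score; query cells below
#'   it are labelled `"unassigned"` (default `NULL`, off).
#' @return a `LabelTransfer`: `predicted_label` per query cell and
#'   `prediction_scores` (query x labels, rows sum to 1).
#' @export
transfer_labels <- function(anchors, ref_labels, query_embedding,
                            k_weight = 50, score_threshold = NULL) {
  pairs <- anchors$pairs
  if (nrow(pairs) < 1) stopf("need at least one anchor")
  if (k_weight > nrow(pairs)) {
    warnf("k_weight = %d exceeds the %d available anchors; using all",
          k_weight, nrow(pairs))
    k_weight <- nrow(pairs)
  }
  labels <- as.character(ref_labels)[pairs$ref]
  lab_levels <- if (is.factor(ref_labels)) levels(ref_labels) else sort(unique(labels))
  anchor_pos <- query_embedding[pairs$query, , drop = FALSE]
  nq <- nrow(query_embedding)
  nn <- RANN::nn2(anchor_pos, query_embedding, k = k_weight)
  scores <- matrix(0, nq, length(lab_levels),
                   dimnames = list(rownames(query_embedding), lab_levels))
  for (q in seq_len(nq)) {
    a_idx <- nn$nn.idx[q, ]
    d <- nn$nn.dists[q, ]
    bw <- d[k_weight]
    if (bw == 0) bw <- 1             # all anchors coincide with the cell
    w <- exp(-d^2 / (2 * bw^2)) * (pairs$score[a_idx] + 1e-6)
    tab <- rowsum(w, labels[a_idx])
    scores[q, rownames(tab)] <- tab[, 1]
  }
  scores <- scores / rowSums(scores)
  pred <- lab_levels[max.col(scores, ties.method = "first")]
  if (!is.null(score_threshold)) {
    win <- scores[cbind(seq_len(nq), max.col(scores, ties.method = "first"))]
    pred[win < score_threshold] <- "unassigned"
  }
  structure(list(predicted_label = pred, prediction_scores = scores),
            class = "LabelTransfer")
}

#' Fit a UMAP model on the reference embedding
#'
#' Thin wrapper over `uwot::umap` with `ret_model = TRUE`, so query cells
#' can later be placed into the same layout. Seeded for reproducibility.
#'
#' @param ref_embedding reference cells x d matrix.
#' @param n_neighbors,min_dist standard UMAP parameters.
#' @param seed RNG seed (default 42).
#' @return a uwot model object (opaque handle).
#' @export
fit_reference_umap <- function(ref_embedding, n_neighbors = 30L,
                               min_dist = 0.3, seed = 42) {
  if (!requireNamespace("uwot", quietly = TRUE))
    stopf("fit_reference_umap requires the 'uwot' package")
  set.seed(seed)
  uwot::umap(as.matrix(ref_embedding), n_neighbors = n_neighbors,
             min_dist = min_dist, ret_model = TRUE)
}

#' Place query cells in a reference UMAP layout (or a de-novo merged one)
#'
#' In `"reference"` mode the query is transformed through the fitted
#' reference model (`uwot::umap_transform`), landing each query cell near
#' its reference neighbors; populations absent from the reference are pushed
#' to cluster boundaries. In `"de-novo"` mode a fresh UMAP is fitted on the
#' merged reference + query embeddings, letting novel populations stay
#' distinct; both blocks of coordinates are returned.
#'
#' @param ref_umap_model model from [fit_reference_umap()] (`"reference"`
#'   mode) or the reference embedding matrix (`"de-novo"` mode).
#' @param query_embedding query cells x d matrix.
#' @param mode `"reference"` or `"de-novo"`.
#' @param seed RNG seed.
#' @return `"reference"`: query cells x 2 coordinates. `"de-novo"`: list
#'   with `ref` and `query` coordinate blocks from the merged fit.
#' @export
embed_query_umap <- function(ref_umap_model, query_embedding,
                             mode = c("reference", "de-novo"), seed = 42) {
  if (!requireNamespace("uwot", quietly = TRUE))
    stopf("embed_query_umap requires the 'uwot' package")
  mode <- match.arg(mode)
  set.seed(seed)
  if (mode == "reference") {
    if (!is.list(ref_umap_model) || is.null(ref_umap_model$embedding))
      stopf("reference mode requires a uwot model from fit_reference_umap()")
    uwot::umap_transform(as.matrix(query_embedding), ref_umap_model)
  } else {
    ref_emb <- as.matrix(ref_umap_model)
    if (ncol(ref_emb) != ncol(query_embedding))
      stopf("reference and query embeddings have different dimensionality")
    merged <- rbind(ref_emb, as.matrix(query_embedding))
    coords <- uwot::umap(merged, n_neighbors = 30L, min_dist = 0.3)
    list(ref = coords[seq_len(nrow(ref_emb)), , drop = FALSE],
         query = coords[nrow(ref_emb) + seq_len(nrow(query_embedding)), ,
                        drop = FALSE])
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
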