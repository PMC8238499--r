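# The weighted-nearest-neighbor core: within/cross-modality neighborhood
# predictions, exponential-kernel affinities with per-cell bandwidth and
# local connectivity, softmax modality weights, and the WNN graph itself.
# The implementation is written once for M >= 2 modalities; the two-modality
# formulas are the M = 2 special case.

WNN_EPSILON <- 1e-4  # ratio denominator guard (fixed)

# Mean of embedding rows over each cell's neighbor set: the neighborhood
# "prediction" of the cell's profile in that embedding.
average_over_neighbors <- function(embedding, indices) {
  k <- ncol(indices)
  out <- embedding[indices[, 1], , drop = FALSE]
  if (k > 1) for (j in 2:k) out <- out + embedding[indices[, j], , drop = FALSE]
  out / k
}

#' Within- and cross-modality neighborhood predictions
#'
#' For every ordered pair of modalities (m, n), predicts each cell's
#' modality-m embedding as the arithmetic mean of the modality-m embeddings
#' of its k nearest neighbors *in modality n*. `predictions[[m]][[n]]` with
#' m == n is the within-modality prediction; m != n is the cross-modality
#' prediction.
#'
#' @param views list of `ModalityView`s over the same cells.
#' @param graphs list of `NeighborGraph`s, one per view, same k.
#' @return a `PredictionSet`: nested list `predictions[[m]][[n]]` of
#'   cells x d_m matrices.
#' @export
modality_predictions <- function(views, graphs) {
  M <- length(views)
  stopifnot(M == length(graphs), M >= 2)
  n <- nrow(views[[1]]$embedding)
  for (m in seq_len(M)) {
    if (nrow(views[[m]]$embedding) != n || nrow(graphs[[m]]$indices) != n)
      stopf("modality %d does not share the common cell set (n = %d)", m, n)
    if (graphs[[m]]$k != graphs[[1]]$k)
      stopf("all graphs must use the same k")
  }
  preds <- lapply(seq_len(M), function(m) {
    lapply(seq_len(M), function(nn)
      average_over_neighbors(views[[m]]$embedding, graphs[[nn]]$indices))
  })
  structure(list(predictions = preds, k = graphs[[1]]$k), class = "PredictionSet")
}

# Exponential affinity between each cell's profile and a predicted profile,
# with local connectivity (distance to first neighbor) subtracted and the
# per-cell bandwidth in the denominator:
#   theta_i = exp(-max(d_i - d_first_i, 0) / (sigma_i - d_first_i))
theta_kernel <- function(d, bandwidths) {
  if (any(!is.finite(d))) stopf("non-finite distances in affinity computation")
  num <- pmax(d - bandwidths$d_first, 0)
  den <- bandwidths$sigma - bandwidths$d_first
  exp(-num / den)
}

#' Affinity between cells and predicted profiles
#'
#' Converts Euclidean prediction errors to affinities in (0, 1\] with the
#' exponential kernel used by UMAP: the distance to the first nearest
#' neighbor ("local connectivity") is subtracted from the error and the
#' result is scaled by the cell-specific bandwidth. Errors at or below the
#' first-neighbor distance give affinity exactly 1.
#'
#' @param view the `ModalityView` whose embedding the prediction targets.
#' @param prediction cells x d matrix of predicted profiles.
#' @param bandwidths `BandwidthSet` for this view.
#' @return numeric vector of per-cell affinities in (0, 1\].
#' @export
prediction_affinity <- function(view, prediction, bandwidths) {
  emb <- get_embedding(view)
  d <- sqrt(rowSums((emb - prediction)^2))
  theta_kernel(d, bandwidths)
}

#' Per-cell modality weights
#'
#' For each modality m, the within-modality affinity is compared with each
#' cross-modality affinity through the ratio
#' `s_mn(i) = theta_mm(i) / (theta_mn(i) + eps)`; a large ratio means the
#' cell's modality-m neighborhood describes its state better than the
#' modality-n neighborhood does. The ratios are softmax-normalized across
#' all ordered pairs, giving non-negative per-cell weights that sum to 1
#' across modalities. With two modalities this reduces to the familiar
#' `w_1 = exp(s_1) / (exp(s_1) + exp(s_2))`.
#'
#' @param views list of `ModalityView`s (M >= 2).
#' @param graphs matching list of `NeighborGraph`s.
#' @param bandwidths matching list of `BandwidthSet`s.
#' @param modality_names optional names for the weight columns.
#' @return a `WeightSet`: `weights` (cells x M, rows sum to 1), the affinity
#'   matrix `theta` (`theta[[m]][[n]]`), ratio list `s`, and `epsilon`.
#' @export
modality_weights <- function(views, graphs, bandwidths, modality_names = NULL) {
  M <- length(views)
  stopifnot(M >= 2, length(graphs) == M, length(bandwidths) == M)
  preds <- modality_predictions(views, graphs)
  n <- nrow(views[[1]]$embedding)
  theta <- lapply(seq_len(M), function(m)
    lapply(seq_len(M), function(nn)
      prediction_affinity(views[[m]], preds$predictions[[m]][[nn]], bandwidths[[m]])))
  # ratios s[[m]][[n]] for n != m
  s <- lapply(seq_len(M), function(m)
    lapply(seq_len(M), function(nn) {
      if (nn == m) return(NULL)
      theta[[m]][[m]] / (theta[[m]][[nn]] + WNN_EPSILON)
    }))
  # stable softmax over all M*(M-1) ratios per cell
  smat <- do.call(cbind, unlist(lapply(seq_len(M), function(m)
    s[[m]][seq_len(M)[-m]]), recursive = FALSE))
  owner <- rep(seq_len(M), each = M - 1)
  mx <- matrixStats::rowMaxs(smat)
  esmat <- exp(smat - mx)
  weights <- sapply(seq_len(M), function(m)
    rowSums(esmat[, owner == m, drop = FALSE]))
  weights <- weights / rowSums(weights)
  if (is.null(modality_names)) modality_names <- paste0("modality", seq_len(M))
  colnames(weights) <- modality_names
  structure(list(weights = weights, theta = theta, s = s,
                 epsilon = WNN_EPSILON, predictions = preds),
            class = "WeightSet")
}

# Affinity between cell i and a set of candidate cells in one modality,
# using cell i's bandwidth and local connectivity.
cell_cell_theta <- function(emb, i, candidates, sigma_i, d_first_i) {
  d <- dist_to_cells(emb, i, candidates)
  exp(-pmax(d - d_first_i, 0) / (sigma_i - d_first_i))
}

#' The weighted-nearest-neighbor graph
#'
#' Scores, for each cell i, every candidate j in the union of the
#' per-modality `candidate_width`-nearest-neighbor lists with the weighted
#' similarity `theta_weighted(i, j) = sum_m w_m(i) * theta_m(i, j)`, where
#' each `theta_m` reuses the exponential kernel with cell i's bandwidth and
#' local connectivity, and keeps the k most similar cells. The similarity is
#' asymmetric because it depends on cell i's weights and kernels.
#'
#' @param views list of `ModalityView`s.
#' @param weights a `WeightSet` from [modality_weights()].
#' @param bandwidths matching list of `BandwidthSet`s.
#' @param candidate_graphs list of `NeighborGraph`s with
#'   k = `candidate_width` supplying the candidate lists (built internally
#'   when NULL).
#' @param k neighbors kept per cell (default 20).
#' @param candidate_width per-modality candidate list width (default 200;
#'   clamped to n - 1 with a warning).
#' @param exact_cutoff passed to [build_knn()] when candidate graphs are
#'   built internally.
#' @return a `WnnGraph`: `indices`, `similarities` (non-increasing along
#'   rows), `snn` (Jaccard matrix of the WNN neighbor sets), plus the
#'   weights used.
#' @export
wnn_graph <- function(views, weights, bandwidths, candidate_graphs = NULL,
                      k = 20, candidate_width = 200, exact_cutoff = 5000) {
  M <- length(views)
  n <- nrow(views[[1]]$embedding)
  if (candidate_width > n - 1) {
    warnf("candidate_width = %d clamped to n - 1 = %d", candidate_width, n - 1)
    candidate_width <- n - 1
  }
  if (is.null(candidate_graphs))
    candidate_graphs <- lapply(views, build_knn, k = candidate_width,
                               exact_cutoff = exact_cutoff)
  w <- weights$weights
  embs <- lapply(views, get_embedding)
  idx <- matrix(0L, n, k)
  sim <- matrix(0, n, k)
  warned_pool <- FALSE
  for (i in seq_len(n)) {
    cand <- unique(unlist(lapply(candidate_graphs, function(g)
      g$indices[i, seq_len(min(candidate_width, g$k))])))
    cand <- cand[cand != i]
    score <- numeric(length(cand))
    for (m in seq_len(M)) {
      th <- cell_cell_theta(embs[[m]], i, cand,
                            bandwidths[[m]]$sigma[i], bandwidths[[m]]$d_first[i])
      score <- score + w[i, m] * th
    }
    kk <- min(k, length(cand))
    if (kk < k && !warned_pool) {
      warnf("candidate pool smaller than k for some cells; keeping all candidates")
      warned_pool <- TRUE
    }
    ord <- order(-score, cand)[seq_len(kk)]
    idx[i, seq_len(kk)] <- cand[ord]
    sim[i, seq_len(kk)] <- score[ord]
    if (kk < k && kk > 0) {  # pad with the weakest candidate to keep shape
      idx[i, seq((kk + 1), k)] <- cand[ord[kk]]
      sim[i, seq((kk + 1), k)] <- score[ord[kk]]
    }
  }
  graph <- structure(
    list(indices = idx, similarities = sim, k = k,
         candidate_width = candidate_width, weights = w,
         snn = NULL),
    class = c("WnnGraph", "NeighborGraph"))
  graph$distances <- 1 - sim  # for downstream consumers expecting distances
  graph$snn <- jaccard_snn(graph)
  graph
}

#' Run the full WNN workflow on two or more modality views
#'
#' Convenience wrapper chaining [build_knn()], [jaccard_snn()],
#' [kernel_bandwidth()], [modality_weights()] and [wnn_graph()]. With M = 2
#' this is the two-modality workflow; with M >= 3 every pairwise
#' cross-modality prediction participates in the softmax.
#'
#' @param views named list of `ModalityView`s (M >= 2) over the same cells.
#' @param k neighbors per cell for the modality graphs and the WNN graph
#'   (default 20).
#' @param candidate_width per-modality WNN candidate list width (default 200).
#' @param n_bw cells averaged for the kernel bandwidth (default 20).
#' @param prune Jaccard pruning threshold for the per-modality SNN matrices
#'   (default 0).
#' @param exact_cutoff exact-KNN cutoff passed to [build_knn()].
#' @return list with `weights` (`WeightSet`), `graph` (`WnnGraph`), and the
#'   intermediate `graphs`, `snn`, `bandwidths` per modality.
#' @export
run_wnn <- function(views, k = 20, candidate_width = 200, n_bw = 20,
                    prune = 0, exact_cutoff = 5000) {
  M <- length(views)
  stopifnot(M >= 2)
  n <- nrow(views[[1]]$embedding)
  width <- min(candidate_width, n - 1)
  # one KNN search per modality at the candidate width; slice out the k-graph
  cand_graphs <- lapply(views, build_knn, k = max(k, width),
                        exact_cutoff = exact_cutoff)
  graphs <- lapply(cand_graphs, function(g)
    new_neighbor_graph(g$indices[, seq_len(k), drop = FALSE],
                       g$distances[, seq_len(k), drop = FALSE],
                       k, backend = g$backend))
  snn <- lapply(graphs, jaccard_snn, prune = prune)
  bandwidths <- lapply(seq_len(M), function(m)
    kernel_bandwidth(views[[m]], graphs[[m]], snn[[m]], n_bw = n_bw))
  nms <- names(views)
  if (is.null(nms)) nms <- paste0("modality", seq_len(M))
  weights <- modality_weights(views, graphs, bandwidths, modality_names = nms)
  graph <- wnn_graph(views, weights, bandwidths,
                     candidate_graphs = cand_graphs,
                     k = k, candidate_width = width,
                     exact_cutoff = exact_cutoff)
  list(weights = weights, graph = graph, graphs = graphs, snn = snn,
       bandwidths = bandwidths)
}
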