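# Per-modality KNN graphs, Jaccard shared-nearest-neighbor similarities, and
# the cell-specific kernel bandwidths used by the exponential affinity kernel.

#' Build a k-nearest-neighbor graph on a modality embedding
#'
#' Exact Euclidean KNN (dense distance matrix, ties broken stably by cell
#' index) for up to `exact_cutoff` cells; a kd-tree backend (RANN) beyond
#' that. Distances are Euclidean on the L2-normalized embedding, so they are
#' monotone in cosine distance on the raw scores. Cells are excluded from
#' their own neighbor lists.
#'
#' @param view a `ModalityView`, or a bare cells x d embedding matrix.
#' @param k number of neighbors (default 20); must be < n_cells.
#' @param exact_cutoff use the exact backend for n <= this many cells
#'   (default 5000).
#' @return a `NeighborGraph` with `indices` and `distances` (cells x k,
#'   ascending distance along each row).
#' @export
build_knn <- function(view, k = 20, exact_cutoff = 5000) {
  emb <- get_embedding(view)
  n <- nrow(emb)
  if (k >= n) stopf("k = %d must be smaller than the number of cells (%d)", k, n)
  if (n <= exact_cutoff) {
    dm <- dense_dist(emb)
    idx <- matrix(0L, n, k)
    dst <- matrix(0, n, k)
    for (i in seq_len(n)) {
      di <- dm[i, ]
      di[i] <- Inf                       # self excluded
      ord <- order(di, seq_len(n))[seq_len(k)]  # stable tie-break by index
      idx[i, ] <- ord
      dst[i, ] <- di[ord]
    }
    new_neighbor_graph(idx, dst, k, backend = "exact")
  } else {
    nn <- RANN::nn2(emb, k = k + 1)
    # drop self (first column, or wherever it lands among exact ties)
    idx <- matrix(0L, n, k); dst <- matrix(0, n, k)
    for (i in seq_len(n)) {
      row <- nn$nn.idx[i, ]
      keep <- which(row != i)
      if (length(keep) > k) keep <- keep[seq_len(k)]
      idx[i, ] <- row[keep]
      dst[i, ] <- nn$nn.dists[i, keep]
    }
    new_neighbor_graph(idx, dst, k, backend = "kdtree")
  }
}

#' Jaccard shared-nearest-neighbor matrix
#'
#' For each pair of cells, the Jaccard index of their k-neighbor sets,
#' `|N(i) n N(j)| / |N(i) u N(j)|`. By the common SNN convention each set
#' includes the cell itself, so `J(i, i) = 1`. Entries at or below `prune`
#' are dropped. Only pairs that share at least one neighbor can have a
#' nonzero entry, so the result is sparse.
#'
#' @param graph a `NeighborGraph`.
#' @param prune entries <= this value are set to zero (default 0, i.e. keep
#'   all nonzero overlaps).
#' @param include_self include each cell in its own neighbor set (default
#'   TRUE).
#' @return symmetric sparse `dgCMatrix` of Jaccard indices in \[0, 1\].
#' @export
jaccard_snn <- function(graph, prune = 0, include_self = TRUE) {
  stopifnot(inherits(graph, "NeighborGraph"))
  n <- nrow(graph$indices)
  k <- graph$k
  j <- as.integer(t(graph$indices))
  i <- rep(seq_len(n), each = k)
  if (include_self) {
    i <- c(i, seq_len(n))
    j <- c(j, seq_len(n))
  }
  A <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  sizes <- Matrix::rowSums(A)
  inter <- Matrix::tcrossprod(A)            # |N(i) n N(j)| on shared pairs
  # tcrossprod returns symmetric storage; expand so summary() covers both
  # triangles
  inter <- methods::as(inter, "generalMatrix")
  trip <- Matrix::summary(methods::as(inter, "CsparseMatrix"))
  jac <- trip$x / (sizes[trip$i] + sizes[trip$j] - trip$x)
  jac[jac <= prune] <- 0
  out <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = jac, dims = c(n, n))
  Matrix::drop0(out)
}

#' Cell-specific kernel bandwidths from low-Jaccard neighborhoods
#'
#' For each cell, identify the `n_bw` cells with the *lowest* nonzero Jaccard
#' similarity — cells that share some neighborhood structure but are unlikely
#' to occupy the same molecular state (a large-margin heuristic). Ties on the
#' Jaccard value are broken toward the *furthest* Euclidean distance. The
#' bandwidth is the mean Euclidean distance from the cell to the selected
#' set. Cells with fewer than `n_bw` nonzero-Jaccard partners use all that
#' are available (one aggregate warning); cells with none fall back to the
#' distance to their k-th neighbor and are flagged. Bandwidths are floored at
#' `d_first + 1e-10` so the kernel denominator `sigma - d_first` is strictly
#' positive.
#'
#' @param view `ModalityView` (or embedding matrix) the graph was built on.
#' @param graph the `NeighborGraph` for that view.
#' @param snn the [jaccard_snn()] matrix derived from `graph`.
#' @param n_bw number of low-Jaccard cells to average over (default 20).
#' @return a `BandwidthSet`: list with `sigma`, `d_first`, and logical
#'   `fallback` per cell.
#' @export
kernel_bandwidth <- function(view, graph, snn, n_bw = 20) {
  emb <- get_embedding(view)
  n <- nrow(emb)
  stopifnot(nrow(graph$indices) == n, nrow(snn) == n)
  snn <- methods::as(snn, "CsparseMatrix")
  sigma <- numeric(n)
  fallback <- logical(n)
  short <- 0L
  p <- snn@p; ridx <- snn@i; xval <- snn@x
  for (cell in seq_len(n)) {
    # column `cell` of the symmetric SNN = its nonzero-Jaccard partners
    span <- seq.int(p[cell] + 1L, length.out = p[cell + 1L] - p[cell])
    partners <- ridx[span] + 1L
    jac <- xval[span]
    keep <- partners != cell
    partners <- partners[keep]; jac <- jac[keep]
    if (length(partners) == 0L) {
      sigma[cell] <- graph$distances[cell, graph$k]
      fallback[cell] <- TRUE
      next
    }
    d <- dist_to_cells(emb, cell, partners)
    if (length(partners) < n_bw) {
      short <- short + 1L
      sel <- seq_along(partners)
    } else {
      sel <- order(jac, -d)[seq_len(n_bw)]
    }
    sigma[cell] <- mean(d[sel])
  }
  if (short > 0)
    warnf("%d cell(s) had fewer than %d nonzero-Jaccard partners; used all available", short, n_bw)
  d_first <- graph$distances[, 1]
  sigma <- pmax(sigma, d_first + 1e-10)
  structure(list(sigma = sigma, d_first = d_first, fallback = fallback),
            class = "BandwidthSet")
}
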