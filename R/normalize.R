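# Per-modality normalization. Each transform takes a features x cells counts
# matrix (bare or CountsMatrix) and returns a matrix of the same shape.

#' Log-normalize RNA counts
#'
#' Scales each cell to `scale_factor` total counts and applies `log1p`:
#' `out_ij = ln(1 + scale_factor * x_ij / colsum_j)`. This is the standard
#' library-size normalization for scRNA-seq; it is invariant to per-cell
#' rescaling of counts and maps zero counts to zero.
#'
#' @param counts features x cells non-negative counts (`CountsMatrix` or matrix).
#' @param scale_factor positive scale applied after depth division (default 1e4).
#' @return normalized matrix, same dimensions and dimnames; sparse in, sparse out.
#' @export
log_normalize <- function(counts, scale_factor = 1e4) {
  x <- as_feature_matrix(counts)
  if (scale_factor <= 0) stopf("scale_factor must be positive")
  libsize <- Matrix::colSums(x)
  if (any(libsize == 0))
    stopf("cell(s) with zero library size: %s; filter before normalizing",
          paste(utils::head(which(libsize == 0), 5), collapse = ", "))
  if (methods::is(x, "sparseMatrix")) {
    x <- methods::as(x, "CsparseMatrix")
    # operate on the nonzero slots to preserve sparsity
    percell <- rep.int(libsize, diff(x@p))
    x@x <- log1p(scale_factor * x@x / percell)
    x
  } else {
    log1p(scale_factor * sweep(x, 2, libsize, "/"))
  }
}

#' Centered log-ratio normalization for protein (ADT) counts
#'
#' Within-cell CLR with a +1 pseudocount and natural log:
#' `out_ij = ln(x_ij + 1) - mean_i ln(x_ij + 1)`, so every output column
#' (cell) sums to zero. The margin is configurable: `margin = 1` centers
#' within each feature instead (an alternative dialect used for large panels).
#'
#' @param counts features x cells non-negative ADT counts.
#' @param margin 2 (default) to center within cells, 1 to center within features.
#' @return dense normalized matrix with zero-sum columns (margin = 2).
#' @export
clr_normalize <- function(counts, margin = 2) {
  x <- as.matrix(as_feature_matrix(counts))
  if (min(x) < 0) stopf("counts must be non-negative")
  if (!margin %in% c(1, 2)) stopf("margin must be 1 (features) or 2 (cells)")
  lx <- log1p(x)
  if (margin == 2) {
    sweep(lx, 2, colMeans(lx), "-")
  } else {
    sweep(lx, 1, rowMeans(lx), "-")
  }
}

#' TF-IDF normalization for scATAC peak counts
#'
#' Term frequency is each peak's share of its cell's total accessibility;
#' inverse document frequency up-weights rarely accessible peaks. The default
#' IDF is `n_cells / rowsum_i` (total accessibility of the peak); the
#' alternative `"binary"` uses `n_cells / n_cells_with_peak`. The result is
#' `ln(1 + scale_factor * TF * IDF)`, preserving the sparsity pattern.
#' Peaks with zero total accessibility have undefined IDF and are dropped
#' with a warning.
#'
#' @param peaks features x cells non-negative (typically sparse) counts.
#' @param scale_factor positive scale inside the log (default 1e4).
#' @param idf_method `"counts"` (default, n_cells / total counts of the peak)
#'   or `"binary"` (n_cells / number of cells with the peak).
#' @return sparse normalized matrix (peaks with zero totals removed).
#' @export
tfidf_normalize <- function(peaks, scale_factor = 1e4,
                            idf_method = c("counts", "binary")) {
  idf_method <- match.arg(idf_method)
  x <- as_feature_matrix(peaks)
  x <- Matrix::Matrix(x, sparse = TRUE)
  x <- methods::as(methods::as(x, "generalMatrix"), "CsparseMatrix") * 1.0
  libsize <- Matrix::colSums(x)
  if (any(libsize == 0))
    stopf("cell(s) with zero total accessibility: %s",
          paste(utils::head(which(libsize == 0), 5), collapse = ", "))
  rowtot <- Matrix::rowSums(x)
  if (any(rowtot == 0)) {
    warnf("dropping %d peak(s) with zero total accessibility (IDF undefined)",
          sum(rowtot == 0))
    x <- x[rowtot > 0, , drop = FALSE]
    rowtot <- rowtot[rowtot > 0]
  }
  n <- ncol(x)
  idf <- if (idf_method == "counts") n / rowtot
         else n / Matrix::rowSums(x > 0)
  ij <- Matrix::summary(x)
  x@x <- log1p(scale_factor * (x@x / libsize[ij$j]) * idf[ij$i])
  x
}

#' Flag intra-sample doublets by neighborhood doublet fraction
#'
#' Cells whose neighborhoods (typically on the protein embedding, where
#' inter-individual doublets are verified) contain more than `threshold`
#' known doublets are flagged as probable intra-sample doublets. Known
#' doublets always remain flagged. The comparison is strict (`>`).
#'
#' @param graph a [build_knn()] `NeighborGraph` (conventionally on the ADT
#'   embedding).
#' @param known_doublet logical per cell; verified doublets.
#' @param threshold fraction in (0, 1); default 0.20.
#' @return logical per cell: flagged doublets (union of known and inferred).
#' @export
flag_intra_sample_doublets <- function(graph, known_doublet, threshold = 0.20) {
  stopifnot(inherits(graph, "NeighborGraph"))
  if (threshold <= 0 || threshold >= 1) stopf("threshold must be in (0, 1)")
  n <- nrow(graph$indices)
  if (length(known_doublet) != n)
    stopf("known_doublet length (%d) != number of cells (%d)", length(known_doublet), n)
  frac <- rowMeans(matrix(known_doublet[graph$indices], nrow = n))
  (frac > threshold) | known_doublet
}
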