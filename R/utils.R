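# Internal helpers shared across modules.

#' L2-normalize the rows of a matrix
#'
#' Rows with zero norm are left as zero vectors and reported via the
#' `"zero_rows"` attribute so callers can flag degenerate cells.
#'
#' @param x numeric matrix (cells x dims).
#' @return matrix of the same shape with unit-norm rows; attribute
#'   `zero_rows` holds the indices of all-zero rows (integer(0) if none).
#' @keywords internal
l2_normalize_rows <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  zero <- which(nrm == 0)
  nrm[nrm == 0] <- 1
  out <- x / nrm
  attr(out, "zero_rows") <- zero
  out
}

# Accept a ModalityView, any list carrying an $embedding, or a bare matrix.
get_embedding <- function(v) {
  if (is.list(v) && !is.null(v$embedding)) v$embedding else as.matrix(v)
}

# Euclidean distances from one cell to a set of cells in an embedding.
dist_to_cells <- function(embedding, i, idx) {
  if (length(idx) == 0L) return(numeric(0))
  di <- embedding[idx, , drop = FALSE] -
    matrix(embedding[i, ], nrow = length(idx), ncol = ncol(embedding), byrow = TRUE)
  sqrt(rowSums(di^2))
}

# Full Euclidean distance matrix between rows of a (cells x d) embedding.
# Cheaper than stats::dist for the sizes used here and returns a plain matrix.
dense_dist <- function(x, y = NULL) {
  if (is.null(y)) y <- x
  sx <- rowSums(x^2)
  sy <- rowSums(y^2)
  d2 <- outer(sx, sy, "+") - 2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Extract counts values + ids from a CountsMatrix or bare matrix.
as_feature_matrix <- function(x) {
  if (inherits(x, "CountsMatrix")) x$values else x
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
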