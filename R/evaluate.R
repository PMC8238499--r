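# Evaluation and downstream procedures: graph clustering interface,
# noise-robustness simulation, cross-cluster edge counts, neighbor-prediction
# correlation, neighborhood-homogeneity metrics, and the perturbation score.

#' Cluster cells on a Jaccard/SNN graph
#'
#' Runs Leiden community detection (modularity objective) on the
#' Jaccard-weighted graph. Community detection is delegated to igraph; this
#' function fixes the seed so results are reproducible.
#'
#' @param snn sparse symmetric SNN matrix (e.g. `wnn$graph$snn`).
#' @param resolution resolution parameter (default 1).
#' @param seed RNG seed (default 42).
#' @param n_iterations Leiden iterations (default 10).
#' @return integer cluster labels per cell (1-based).
#' @export
cluster_graph <- function(snn, resolution = 1, seed = 42, n_iterations = 10) {
  if (nrow(snn) == 0) stopf("empty graph")
  adj <- methods::as(snn, "CsparseMatrix")
  Matrix::diag(adj) <- 0
  adj <- Matrix::drop0(adj)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE)
  set.seed(seed)
  comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution,
                                 n_iterations = n_iterations)
  as.integer(igraph::membership(comm))
}

#' Add Gaussian noise to a modality matrix
#'
#' Element-wise independent N(0, sd^2) noise, applied to the normalized
#' matrix immediately before its dimensional reduction — the standard way to
#' titrate down one modality's information content in robustness analyses.
#'
#' @param x numeric matrix.
#' @param sd noise standard deviation (>= 0; 0 is the identity).
#' @param seed RNG seed (default 42).
#' @return matrix of the same shape.
#' @export
add_modality_noise <- function(x, sd, seed = 42) {
  if (sd < 0) stopf("sd must be >= 0")
  if (sd == 0) return(x)
  x <- as.matrix(x)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  x + matrix(stats::rnorm(length(x), 0, sd), nrow(x), ncol(x))
}

#' Count graph edges between two clusters
#'
#' Counts KNN-graph edges joining cells of label `a` with cells of label
#' `b`. KNN rows are directed (i -> each of its neighbors), which is the
#' default convention; `directed = FALSE` collapses reciprocal pairs.
#'
#' @param graph a `NeighborGraph` or `WnnGraph`.
#' @param labels per-cell labels covering all cells.
#' @param a,b the two cluster labels.
#' @param directed count directed edges (default TRUE).
#' @return integer edge count.
#' @export
cross_cluster_edges <- function(graph, labels, a, b, directed = TRUE) {
  labels <- as.character(labels)
  n <- nrow(graph$indices)
  if (length(labels) != n) stopf("labels must cover all %d cells", n)
  if (!a %in% labels || !b %in% labels)
    stopf("label '%s' not present", if (!a %in% labels) a else b)
  li <- rep(labels, times = ncol(graph$indices))
  lj <- labels[as.vector(graph$indices)]
  hits <- (li == a & lj == b) | (li == b & lj == a)
  cnt <- sum(hits)
  if (!directed) {
    # collapse reciprocal pairs: count unique unordered pairs
    ii <- rep(seq_len(n), times = ncol(graph$indices))[hits]
    jj <- as.vector(graph$indices)[hits]
    cnt <- length(unique(paste(pmin(ii, jj), pmax(ii, jj))))
  }
  cnt
}

#' Correlation between measured features and their neighbor-average predictions
#'
#' For each feature, predicts each cell's value as the mean over its graph
#' neighbors and reports the correlation between predicted and measured
#' values — a graph-quality benchmark: a graph that links molecularly
#' matched cells predicts withheld features well. Zero-variance features get
#' NA.
#'
#' @param graph a `NeighborGraph` or `WnnGraph`.
#' @param features features x cells matrix sharing the graph's cells.
#' @return data frame with `feature`, `pearson`, `spearman`.
#' @export
neighbor_prediction_correlation <- function(graph, features) {
  features <- as.matrix(features)
  n <- nrow(graph$indices)
  if (ncol(features) != n) stopf("features must have %d columns (cells)", n)
  pred <- average_over_neighbors(t(features), graph$indices)  # cells x features
  meas <- t(features)
  pe <- sp <- numeric(ncol(meas))
  for (f in seq_len(ncol(meas))) {
    if (stats::sd(meas[, f]) == 0 || stats::sd(pred[, f]) == 0) {
      pe[f] <- sp[f] <- NA_real_
    } else {
      pe[f] <- stats::cor(pred[, f], meas[, f], method = "pearson")
      sp[f] <- stats::cor(pred[, f], meas[, f], method = "spearman")
    }
  }
  data.frame(feature = rownames(features) %||% paste0("f", seq_len(ncol(meas))),
             pearson = pe, spearman = sp)
}

#' Variable genes within a neighborhood, by dropout or sd residuals
#'
#' Measures the transcriptomic homogeneity of a cell subset (e.g. the pooled
#' neighbors of one cluster under a candidate graph). Fits the trend of
#' per-gene dropout rate (`mode = "dropout"`) or per-gene sd (`mode = "sd"`)
#' against mean expression with a Gaussian kernel smoother and calls genes
#' variable when the residual exceeds the threshold (0.1 for dropout, 0.5
#' for sd). Fewer variable genes = a more homogeneous neighborhood. The
#' smoother bandwidth defaults to a Silverman-rule estimate on the mean
#' expression values.
#'
#' @param expr normalized genes x cells matrix.
#' @param cell_subset indices (or logical) of the cells to assess (>= 50).
#' @param mode `"dropout"` or `"sd"`.
#' @param threshold residual threshold; default 0.1 (dropout) / 0.5 (sd).
#' @param bandwidth kernel smoother bandwidth (default Silverman on means).
#' @return data frame with `gene`, `mean_expr`, `metric`, `fitted`,
#'   `residual`, `variable`; all-zero genes are excluded.
#' @export
neighborhood_variable_genes <- function(expr, cell_subset,
                                        mode = c("dropout", "sd"),
                                        threshold = NULL, bandwidth = NULL) {
  mode <- match.arg(mode)
  if (is.null(threshold)) threshold <- if (mode == "dropout") 0.1 else 0.5
  x <- as.matrix(expr)[, cell_subset, drop = FALSE]
  if (ncol(x) < 50) stopf("need >= 50 cells in the subset (got %d)", ncol(x))
  keep <- rowSums(x != 0) > 0
  if (any(!keep)) message(sum(!keep), " all-zero gene(s) excluded")
  x <- x[keep, , drop = FALSE]
  mu <- rowMeans(x)
  metric <- if (mode == "dropout") rowMeans(x == 0) else matrixStats::rowSds(x)
  if (is.null(bandwidth)) {
    # stats::ksmooth scales its bandwidth so the kernel quartiles sit at
    # +/- 0.25 * bandwidth; convert a Silverman sd to that scale, then halve
    # it — Silverman targets density estimation and over-smooths the steep
    # dropout/sd trends this fit follows
    bandwidth <- max(stats::bw.nrd0(mu), 1e-3) / 0.3706506 / 2
  }
  fit <- stats::ksmooth(mu, metric, kernel = "normal", bandwidth = bandwidth,
                        x.points = mu)
  fitted <- fit$y[match(mu, fit$x)]
  resid <- metric - fitted
  data.frame(gene = rownames(x) %||% paste0("g", seq_len(nrow(x))),
             mean_expr = mu, metric = metric, fitted = fitted,
             residual = resid, variable = resid > threshold,
             row.names = NULL)
}

#' Per-cell perturbation score between two conditions
#'
#' Quantifies the magnitude of a condition response within one cell type
#' without relying on per-gene significance. Genes with initial evidence of
#' differential expression (Wilcoxon rank-sum, BH-adjusted p < `p_thresh`)
#' define a pseudobulk difference vector (condition B mean minus condition A
#' mean) normalized to unit length; each cell's transcriptome on those genes
#' is projected onto the vector and the projection magnitude is its score.
#' An empty gene set returns a zero-vector result with status
#' `"no response detected"` rather than an error.
#'
#' @param expr normalized genes x cells matrix.
#' @param condition per-cell condition with exactly two levels (e.g. day 0 /
#'   day 3).
#' @param celltype per-cell type labels.
#' @param target_type the cell type to score.
#' @param p_thresh BH-adjusted p-value cutoff for the gene set (default 0.1).
#' @param min_cells minimum cells per condition within the type (default 20).
#' @return a `PerturbationResult`: `genes`, unit `vector`, per-cell `score`
#'   (NA outside the target type), `summary` (mean score per condition), and
#'   `status`.
#' @export
perturbation_score <- function(expr, condition, celltype, target_type,
                               p_thresh = 0.1, min_cells = 20) {
  expr <- as.matrix(expr)
  sel <- celltype == target_type
  cond <- factor(condition[sel])
  if (nlevels(cond) != 2) stopf("need exactly two conditions in '%s'", target_type)
  if (min(table(cond)) < min_cells)
    stopf("both conditions need >= %d cells in '%s'", min_cells, target_type)
  x <- expr[, sel, drop = FALSE]
  grp <- cond == levels(cond)[2]
  pvals <- apply(x, 1, function(g) {
    if (stats::sd(g) == 0) return(1)
    stats::wilcox.test(g[grp], g[!grp], exact = FALSE)$p.value
  })
  padj <- stats::p.adjust(pvals, method = "BH")
  genes <- which(padj < p_thresh)
  if (length(genes) == 0) {
    score <- rep(NA_real_, length(condition))
    score[sel] <- 0
    return(structure(list(genes = character(0), vector = numeric(0),
                          score = score,
                          summary = stats::setNames(c(0, 0), levels(cond)),
                          status = "no response detected"),
                     class = "PerturbationResult"))
  }
  delta <- rowMeans(x[genes, grp, drop = FALSE]) -
    rowMeans(x[genes, !grp, drop = FALSE])
  v <- delta / sqrt(sum(delta^2))
  score <- rep(NA_real_, length(condition))
  score[sel] <- as.vector(crossprod(x[genes, , drop = FALSE], v))
  structure(list(genes = rownames(expr)[genes] %||% genes, vector = v,
                 score = score,
                 summary = tapply(score[sel], cond, mean),
                 status = "ok"),
            class = "PerturbationResult")
}

#' @export
print.PerturbationResult <- function(x, ...) {
  cat(sprintf("PerturbationResult (%s): %d genes; condition means %s\n",
              x$status, length(x$genes),
              paste(sprintf("%s=%.3f", names(x$summary), x$summary),
                    collapse = " ")))
  invisible(x)
}
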