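# Seeded generator of multimodal single-cell datasets with known ground
# truth. Clusters live on log-scale centroids per modality; an "asymmetry
# map" forces chosen cluster pairs to share their centroid exactly in all
# but one modality, so the pair is separable only there (the CD4/CD8-vs-cDC
# situation in CITE-seq panels: anti-CD4/CD8 antibodies split T cells that
# the transcriptome blends, while dendritic cells split only in RNA).

#' Describe one modality of a simulation design
#'
#' @param n_features number of features (genes / proteins / peaks).
#' @param marker_frac fraction of features carrying a cluster-specific shift
#'   (default 0.15; surface-protein panels are denser, RNA sparser).
#' @param effect_size sd of the log-scale marker shifts (default 2, i.e.
#'   typical markers move several fold).
#' @param within_sd within-cluster Gaussian sd on the log/embedding scale
#'   (gaussian mode only; default 1).
#' @param baseline_log_mean,baseline_log_sd log-scale mean/sd of per-feature
#'   baseline expression (NB mode).
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param modality tag: `"rna"`, `"protein"`, `"atac"`, `"other"`.
#' @return a `modality_design` list.
#' @export
modality_design <- function(n_features, marker_frac = 0.15, effect_size = 2,
                            within_sd = 1, baseline_log_mean = log(0.5),
                            baseline_log_sd = 1, dispersion = 0.5,
                            modality = "other") {
  stopifnot(n_features >= 2, marker_frac > 0, marker_frac <= 1,
            effect_size >= 0, within_sd >= 0, dispersion > 0)
  structure(list(n_features = n_features, marker_frac = marker_frac,
                 effect_size = effect_size, within_sd = within_sd,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 dispersion = dispersion, modality = modality),
            class = "modality_design")
}

#' Build a multimodal simulation design
#'
#' @param n_cells total cells.
#' @param clusters named numeric vector of cluster proportions (sum to 1).
#' @param modalities named list of [modality_design()] objects (>= 2 for WNN).
#' @param asymmetry list of `list(pair = c(a, b), separable_in = modality)`
#'   entries; the pair shares its centroid exactly in every *other* modality.
#' @param mode `"nb"` (negative-binomial counts through the normalization
#'   path) or `"gaussian"` (log-scale matrices fed to PCA directly).
#' @param seed integer seed; centroids are derived deterministically from it
#'   so reference and query draws share generative parameters.
#' @return a `SimDesign` object.
#' @export
sim_design <- function(n_cells, clusters, modalities,
                       asymmetry = list(), mode = c("nb", "gaussian"),
                       seed = 42) {
  mode <- match.arg(mode)
  stopifnot(n_cells >= 0, length(clusters) >= 1,
            !is.null(names(clusters)), length(modalities) >= 1,
            !is.null(names(modalities)))
  if (abs(sum(clusters) - 1) > 1e-8) stopf("cluster proportions must sum to 1")
  for (a in asymmetry) {
    if (!all(a$pair %in% names(clusters)))
      stopf("asymmetry pair (%s) not in cluster names", paste(a$pair, collapse = ", "))
    if (length(a$separable_in) < 1 || !all(a$separable_in %in% names(modalities)))
      stopf("pair (%s) must be separable in at least one named modality",
            paste(a$pair, collapse = ", "))
    if (all(names(modalities) %in% a$separable_in) && length(names(modalities)) == 0)
      stopf("inconsistent asymmetry map")
  }
  structure(list(n_cells = n_cells, clusters = clusters,
                 modalities = modalities, asymmetry = asymmetry,
                 mode = mode, seed = seed),
            class = "SimDesign")
}

#' The standard two-modality asymmetric fixture
#'
#' Six equal clusters, an RNA-like modality (200 features) and a protein-like
#' modality (25 features), n = 2000 by default. Clusters A/B share their RNA
#' centroid (separable only in protein, like CD4/CD8 T cells); clusters C/D
#' share their protein centroid (separable only in RNA, like cDCs under an
#' immunophenotype panel without a cDC marker).
#'
#' @param n_cells total cells (default 2000).
#' @param mode `"nb"` or `"gaussian"` (default `"nb"`).
#' @param seed design seed (default 42).
#' @return a `SimDesign`.
#' @export
asymmetric6_design <- function(n_cells = 2000, mode = "nb", seed = 42) {
  sim_design(
    n_cells = n_cells,
    clusters = stats::setNames(rep(1 / 6, 6), LETTERS[1:6]),
    modalities = list(
      rna = modality_design(1000, marker_frac = 0.1, effect_size = 2.5,
                            baseline_log_mean = log(8), baseline_log_sd = 1,
                            dispersion = 0.1, modality = "rna"),
      adt = modality_design(25, marker_frac = 0.4, effect_size = 2,
                            baseline_log_mean = log(20), baseline_log_sd = 0.5,
                            dispersion = 0.1, modality = "protein")
    ),
    asymmetry = list(
      list(pair = c("A", "B"), separable_in = "adt"),
      list(pair = c("C", "D"), separable_in = "rna")
    ),
    mode = mode, seed = seed
  )
}

# Deterministic generative parameters (baselines + centroids) from the
# design seed, with the asymmetry map applied.
design_centroids <- function(design, extra_clusters = NULL) {
  cl_names <- names(design$clusters)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(design$seed)
  out <- lapply(design$modalities, function(md) {
    baseline <- stats::rnorm(md$n_features, md$baseline_log_mean, md$baseline_log_sd)
    cen <- sapply(cl_names, function(cl) {
      shift <- numeric(md$n_features)
      mk <- sample.int(md$n_features, max(2, round(md$marker_frac * md$n_features)))
      shift[mk] <- stats::rnorm(length(mk), 0, md$effect_size)
      shift
    })
    list(baseline = baseline, centroids = cen)
  })
  # asymmetry: pair shares centroids in every modality it is NOT separable in
  for (a in design$asymmetry) {
    for (m in setdiff(names(design$modalities), a$separable_in)) {
      out[[m]]$centroids[, a$pair[2]] <- out[[m]]$centroids[, a$pair[1]]
    }
  }
  out
}

# Deterministic cluster sizes by largest remainder, then cell draws.
cluster_sizes <- function(props, n) {
  raw <- props * n
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    ord <- order(raw - sizes, decreasing = TRUE)
    sizes[ord[seq_len(rem)]] <- sizes[ord[seq_len(rem)]] + 1
  }
  sizes
}

draw_cells <- function(md, param, labels, mode, prefix = "cell") {
  n <- length(labels)
  mu_log <- param$centroids[, labels, drop = FALSE] + param$baseline
  if (mode == "gaussian") {
    vals <- mu_log + matrix(stats::rnorm(md$n_features * n, 0, md$within_sd),
                            md$n_features, n)
  } else {
    vals <- matrix(stats::rnbinom(md$n_features * n, mu = exp(as.vector(mu_log)),
                                  size = 1 / md$dispersion),
                   md$n_features, n)
  }
  rownames(vals) <- paste0(md$modality, "_f", seq_len(md$n_features))
  if (n > 0) colnames(vals) <- paste0(prefix, seq_len(n))
  vals
}

#' Simulate a multimodal dataset from a design
#'
#' Centroids and baselines are derived from `design$seed`, so repeated calls
#' (and [simulate_query()]) share the same generative parameters; the cell
#' draws use `seed`. In `"nb"` mode each modality is returned as a
#' `CountsMatrix`; in `"gaussian"` mode as a plain log-scale matrix suitable
#' for [pca_embed()] with `center_scale = FALSE`.
#'
#' @param design a `SimDesign`.
#' @param seed seed for the cell draws (default: the design seed).
#' @return list with `modalities` (named list of matrices/CountsMatrix),
#'   `labels` (factor), `design`, `seed`.
#' @export
simulate_multimodal <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "SimDesign"))
  params <- design_centroids(design)
  sizes <- cluster_sizes(design$clusters, design$n_cells)
  labels <- factor(rep(names(design$clusters), sizes),
                   levels = names(design$clusters))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  mods <- lapply(names(design$modalities), function(m) {
    vals <- draw_cells(design$modalities[[m]], params[[m]], as.character(labels),
                       design$mode)
    if (design$mode == "nb")
      counts_matrix(vals, modality = design$modalities[[m]]$modality)
    else vals
  })
  names(mods) <- names(design$modalities)
  list(modalities = mods, labels = labels, design = design, seed = seed)
}

#' Simulate a query dataset matching a reference design
#'
#' Draws new cells from the same generative parameters (same centroids and
#' baselines, new seed). Optionally adds a novel cluster absent from the
#' reference, with its own centroids in every modality.
#'
#' @param design the reference `SimDesign`.
#' @param n_query number of query cells.
#' @param novel_cluster optional `list(name =, proportion =)` for a
#'   population absent from the reference.
#' @param seed seed for the query draws (must differ from the reference run
#'   for an honest held-out set).
#' @return same shape as [simulate_multimodal()].
#' @export
simulate_query <- function(design, n_query, novel_cluster = NULL, seed = 1000) {
  stopifnot(inherits(design, "SimDesign"), n_query >= 0)
  params <- design_centroids(design)
  props <- design$clusters
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  if (!is.null(novel_cluster)) {
    if (novel_cluster$name %in% names(props))
      stopf("novel cluster name '%s' collides with a reference cluster", novel_cluster$name)
    props <- c(props * (1 - novel_cluster$proportion),
               stats::setNames(novel_cluster$proportion, novel_cluster$name))
    for (m in names(design$modalities)) {
      md <- design$modalities[[m]]
      shift <- numeric(md$n_features)
      mk <- sample.int(md$n_features, max(2, round(md$marker_frac * md$n_features)))
      shift[mk] <- stats::rnorm(length(mk), 0, md$effect_size)
      params[[m]]$centroids <- cbind(params[[m]]$centroids,
                                     stats::setNames(data.frame(shift), novel_cluster$name))
      params[[m]]$centroids <- as.matrix(params[[m]]$centroids)
    }
  }
  sizes <- cluster_sizes(props, n_query)
  labels <- factor(rep(names(props), sizes), levels = names(props))
  mods <- lapply(names(design$modalities), function(m) {
    vals <- draw_cells(design$modalities[[m]], params[[m]], as.character(labels),
                       design$mode, prefix = "query")
    if (design$mode == "nb")
      counts_matrix(vals, modality = design$modalities[[m]]$modality)
    else vals
  })
  names(mods) <- names(design$modalities)
  list(modalities = mods, labels = labels, design = design, seed = seed)
}
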