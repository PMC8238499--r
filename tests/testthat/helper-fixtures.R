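# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- fn()
  .fixture_cache[[key]]
}

# Small two-modality gaussian-mode dataset for fast kernel/graph tests.
small_views <- function(n = 120, seed = 7) {
  memo(sprintf("small_%d_%d", n, seed), function() {
    des <- sim_design(
      n_cells = n,
      clusters = stats::setNames(rep(1 / 3, 3), c("A", "B", "C")),
      modalities = list(
        m1 = modality_design(40, marker_frac = 0.3, effect_size = 3,
                             within_sd = 1, modality = "other"),
        m2 = modality_design(15, marker_frac = 0.5, effect_size = 3,
                             within_sd = 1, modality = "other")
      ),
      mode = "gaussian", seed = seed
    )
    sim <- simulate_multimodal(des)
    views <- lapply(sim$modalities, function(x)
      pca_embed(x, d = 8, center_scale = FALSE))
    list(views = views, labels = sim$labels, sim = sim, design = des)
  })
}

# The standard NB-counts fixture, processed through the normalization path.
fixture_wnn_input <- function(n = 2000, seed = 42) {
  memo(sprintf("fix_%d_%d", n, seed), function() {
    sim <- simulate_multimodal(asymmetric6_design(n, seed = seed))
    rna <- log_normalize(sim$modalities$rna)
    adt <- clr_normalize(sim$modalities$adt)
    list(sim = sim,
         rna_norm = rna, adt_norm = adt,
         rna_view = pca_embed(as.matrix(rna), d = 30),
         adt_view = pca_embed(adt, d = 18))
  })
}

fixture_wnn <- function(n = 2000, seed = 42) {
  memo(sprintf("wnn_%d_%d", n, seed), function() {
    fx <- fixture_wnn_input(n, seed)
    res <- suppressWarnings(
      run_wnn(list(rna = fx$rna_view, adt = fx$adt_view), k = 20))
    c(fx, list(res = res))
  })
}

# Mapping-oriented design: the two special pairs are separable only in RNA
# (degenerate in protein), so an RNA-projected query can in principle be
# mapped perfectly while the WNN reference must still rescue the pairs from
# the uninformative protein modality.
mapping_design <- function(n = 2000, seed = 42) {
  base <- asymmetric6_design(n, seed = seed)
  sim_design(n_cells = n, clusters = base$clusters,
             modalities = base$modalities,
             asymmetry = list(list(pair = c("A", "B"), separable_in = "rna"),
                              list(pair = c("C", "D"), separable_in = "rna")),
             mode = "nb", seed = seed)
}

adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  nn <- choose(sum(tab), 2)
  expected <- ai * bj / nn
  (nij - expected) / ((ai + bj) / 2 - expected)
}

mean_silhouette <- function(emb, labels, pair = NULL) {
  if (!is.null(pair)) {
    sel <- labels %in% pair
    emb <- emb[sel, , drop = FALSE]
    labels <- droplevels(factor(labels[sel]))
  }
  s <- cluster::silhouette(as.integer(factor(labels)), stats::dist(emb))
  mean(s[, 3])
}
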