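test_that("graph clustering separates disconnected cliques and recovers truth", {
  # two disconnected 10-cliques
  n <- 20
  J <- matrix(0, n, n)
  J[1:10, 1:10] <- 0.5; J[11:20, 11:20] <- 0.5
  diag(J) <- 1
  Js <- Matrix::Matrix(J, sparse = TRUE)
  for (res in c(0.5, 1, 2)) {
    cl <- cluster_graph(Js, resolution = res)
    expect_equal(length(unique(cl)), 2)
    expect_equal(length(unique(cl[1:10])), 1)
  }
  expect_error(cluster_graph(Matrix::Matrix(matrix(0, 0, 0), sparse = TRUE)),
               "empty")

  # synthetic 6 clusters: ARI vs ground truth
  fx <- fixture_wnn(2000)
  cl <- cluster_graph(fx$res$graph$snn, resolution = 1)
  expect_gte(adjusted_rand(cl, fx$sim$labels), 0.95)

  # cluster count non-decreasing in resolution
  counts <- sapply(c(0.25, 0.5, 1, 2), function(r)
    length(unique(cluster_graph(fx$res$graph$snn, resolution = r))))
  expect_true(all(diff(counts) >= 0))

  # determinism under a fixed seed
  expect_identical(cluster_graph(fx$res$graph$snn, seed = 3),
                   cluster_graph(fx$res$graph$snn, seed = 3))
})

test_that("modality noise injection is calibrated, seeded, and identity at 0", {
  x <- matrix(rnorm(100 * 80), 100, 80)
  expect_identical(add_modality_noise(x, 0), x)
  y1 <- add_modality_noise(x, 2, seed = 5)
  y2 <- add_modality_noise(x, 2, seed = 5)
  expect_identical(y1, y2)
  expect_lt(abs(stats::sd(y1 - x) - 2) / 2, 0.05)
  expect_error(add_modality_noise(x, -1), "sd")
})

test_that("cross-cluster edge counts follow the directed KNN convention", {
  # 3 a-cells each pointing at 2 b-cells; b-cells point among themselves
  idx <- rbind(c(4, 5), c(4, 6), c(5, 6), c(5, 6), c(4, 6), c(4, 5))
  g <- multiweave:::new_neighbor_graph(idx, matrix(1, 6, 2), 2)
  labs <- rep(c("a", "b"), each = 3)
  expect_equal(cross_cluster_edges(g, labs, "a", "b"), 6)
  expect_equal(cross_cluster_edges(g, labs, "a", "b", directed = FALSE), 6)
  expect_error(cross_cluster_edges(g, labs, "a", "zz"), "not present")

  # well-separated synthetic clusters have no cross edges
  emb <- rbind(matrix(rnorm(60, 0, 0.1), 30, 2),
               matrix(rnorm(60, 20, 0.1), 30, 2))
  gw <- build_knn(emb, k = 5)
  expect_equal(cross_cluster_edges(gw, rep(c("p", "q"), each = 30), "p", "q"), 0)
})

test_that("neighbor-average prediction correlation benchmarks graph quality", {
  # disconnected cliques with a clique-constant feature: correlation 1
  emb <- rbind(matrix(rnorm(40, 0, 0.1), 20, 2),
               matrix(rnorm(40, 50, 0.1), 20, 2))
  g <- build_knn(emb, k = 5)
  feat <- matrix(rep(c(1, 5), each = 20), nrow = 1)
  out <- neighbor_prediction_correlation(g, feat)
  expect_equal(out$pearson, 1)

  # pure-noise feature: near-zero correlation
  set.seed(60)
  noise <- matrix(rnorm(2000), nrow = 1)
  gbig <- build_knn(matrix(rnorm(4000), 2000, 2), k = 10)
  outn <- neighbor_prediction_correlation(gbig, noise)
  expect_lt(abs(outn$pearson), 0.1)

  # 10-cell toy against hand-computed neighbor means
  set.seed(61)
  e10 <- matrix(rnorm(20), 10, 2)
  g10 <- build_knn(e10, k = 3)
  f10 <- matrix(rnorm(10), 1, 10)
  pred <- sapply(1:10, function(i) mean(f10[g10$indices[i, ]]))
  out10 <- neighbor_prediction_correlation(g10, f10)
  expect_equal(out10$pearson, cor(pred, as.numeric(f10)))
  expect_equal(out10$spearman, cor(pred, as.numeric(f10), method = "spearman"))

  # zero-variance feature reported as missing
  fz <- rbind(f10, 3)
  expect_true(is.na(neighbor_prediction_correlation(g10, fz)$pearson[2]))
})

test_that("neighborhood variable-gene calls control false positives and find signal", {
  set.seed(62)
  # homogeneous population: few variable calls
  lam <- exp(rnorm(300, 0, 1))
  null_counts <- matrix(rpois(300 * 200, lam), 300, 200)
  nv <- neighborhood_variable_genes(log1p(null_counts), seq_len(200),
                                    mode = "dropout")
  expect_lte(mean(nv$variable), 0.01)

  # planted mixture: 50 on/off marker genes spread over the mean-expression
  # axis (markers at a single mean would define the local trend themselves)
  set.seed(63)
  lam2 <- exp(rnorm(300, 0.5, 1))
  lam_a <- lam2; lam_a[1:50] <- 0.02           # off in population A
  a <- matrix(rpois(300 * 100, lam_a), 300, 100)
  lam_b <- lam2
  lam_b[1:50] <- exp(rnorm(50, log(10), 1))    # on in population B
  b <- matrix(rpois(300 * 100, lam_b), 300, 100)
  mix <- log1p(cbind(a, b))
  rownames(mix) <- paste0("g", 1:300)
  nv2 <- neighborhood_variable_genes(mix, seq_len(200), mode = "dropout")
  called <- nv2$gene[nv2$variable]
  expect_gte(mean(paste0("g", 1:50) %in% called), 0.8)
  expect_lte(mean(nv2$variable[!nv2$gene %in% paste0("g", 1:50)]), 0.02)

  # sd mode: the 0.5-residual threshold is deliberately conservative
  nv3 <- neighborhood_variable_genes(mix, seq_len(200), mode = "sd")
  expect_gte(mean(paste0("g", 1:50) %in% nv3$gene[nv3$variable]), 0.5)

  # a gene exactly on the fitted trend has residual ~0 and is not variable
  expect_true(all(abs(nv$residual[!nv$variable]) <= 0.1 + 1e-12 |
                    nv$residual[!nv$variable] < 0))
  expect_error(neighborhood_variable_genes(mix, 1:10), ">= 50 cells")
})

test_that("perturbation scores separate planted responses and stay null under permutation", {
  set.seed(63)
  n_genes <- 300; n_cells <- 200
  expr <- matrix(rnorm(n_genes * n_cells), n_genes, n_cells,
                 dimnames = list(paste0("g", 1:n_genes), NULL))
  cond <- rep(c("d0", "d3"), each = n_cells / 2)
  ct <- rep("T", n_cells)
  expr[1:62, cond == "d3"] <- expr[1:62, cond == "d3"] + 1  # 62-gene shift

  pr <- perturbation_score(expr, cond, ct, "T")
  expect_equal(pr$status, "ok")
  expect_true(all(pr$genes %in% rownames(expr)))
  expect_equal(sum(pr$vector^2), 1, tolerance = 1e-12)
  within_sd <- mean(tapply(pr$score[ct == "T"], cond, sd))
  sep <- abs(diff(tapply(pr$score[ct == "T"], cond, mean)))
  expect_gt(sep / within_sd, 3)

  # dot-product arithmetic: a cell equal to the condition-B pseudobulk
  # scores ||delta||_2 higher than one equal to the condition-A pseudobulk
  kept <- match(pr$genes, rownames(expr))
  pbA <- rowMeans(expr[kept, cond == "d0"]); pbB <- rowMeans(expr[kept, cond == "d3"])
  diffAB <- sum((pbB - pbA) * pr$vector)
  expect_equal(diffAB, sqrt(sum((pbB - pbA)^2)), tolerance = 1e-10)

  # permuted labels: no response detected (or negligible separation)
  set.seed(64)
  pn <- perturbation_score(expr[63:300, ], sample(cond), ct, "T")
  if (pn$status == "ok") {
    expect_lt(abs(diff(pn$summary)) / mean(tapply(pn$score[ct == "T"], cond, sd)), 0.5)
  } else {
    expect_equal(pn$status, "no response detected")
    expect_true(all(pn$score[ct == "T"] == 0))
  }
  expect_error(perturbation_score(expr, cond, ct, "absent"), "two conditions")
})
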