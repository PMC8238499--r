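test_that("neighborhood predictions are neighbor means", {
  set.seed(30)
  e1 <- matrix(rnorm(10), 5, 2)
  e2 <- matrix(rnorm(10), 5, 2)
  v1 <- list(embedding = e1); v2 <- list(embedding = e2)
  g1 <- build_knn(e1, k = 2); g2 <- build_knn(e2, k = 2)
  ps <- modality_predictions(list(v1, v2), list(g1, g2))
  # hand-averaged within prediction for cell 1 in modality 1
  expect_equal(ps$predictions[[1]][[1]][1, ],
               colMeans(e1[g1$indices[1, ], ]))
  # cross prediction: modality 1 profile averaged over modality 2 neighbors
  expect_equal(ps$predictions[[1]][[2]][3, ],
               colMeans(e1[g2$indices[3, ], ]))

  # k = 1: prediction equals the single neighbor's embedding
  g1a <- build_knn(e1, k = 1); g2a <- build_knn(e2, k = 1)
  psa <- modality_predictions(list(v1, v2), list(g1a, g2a))
  expect_equal(psa$predictions[[1]][[1]], e1[g1a$indices[, 1], ])

  # identical modalities: within equals cross
  psb <- modality_predictions(list(v1, v1), list(g1, g1))
  expect_equal(psb$predictions[[1]][[1]], psb$predictions[[1]][[2]])

  expect_error(modality_predictions(list(v1, list(embedding = e2[1:4, ])),
                                    list(g1, build_knn(e2[1:4, ], k = 2))),
               "cell set")
})

test_that("the exponential affinity kernel clamps at local connectivity", {
  bw <- list(sigma = c(2, 2, 2), d_first = c(0.5, 0.5, 0.5))
  emb <- matrix(0, 3, 2)
  # prediction errors: 0, exactly d_first, and d_first + (sigma - d_first)
  pred <- rbind(c(0, 0), c(0.5, 0), c(2, 0))
  th <- prediction_affinity(emb, pred, bw)
  expect_equal(th, c(1, 1, exp(-1)))
  expect_error(prediction_affinity(emb, rbind(c(Inf, 0), c(0, 0), c(0, 0)), bw),
               "non-finite")
})

test_that("modality weights are a softmax of affinity ratios", {
  fx <- small_views(60)
  views <- fx$views
  graphs <- lapply(views, build_knn, k = 5)
  snns <- lapply(graphs, jaccard_snn)
  bws <- suppressWarnings(lapply(1:2, function(m)
    kernel_bandwidth(views[[m]], graphs[[m]], snns[[m]], n_bw = 5)))
  w <- modality_weights(views, graphs, bws)
  expect_true(all(abs(rowSums(w$weights) - 1) < 1e-9))
  expect_true(all(w$weights >= 0))

  # duplicated modality: symmetry forces (0.5, 0.5)
  wd <- modality_weights(list(views[[1]], views[[1]]),
                         list(graphs[[1]], graphs[[1]]),
                         list(bws[[1]], bws[[1]]))
  expect_equal(unname(wd$weights), matrix(0.5, nrow(wd$weights), 2))

  # closed-form softmax check on the returned ratios: w1 = e^s1/(e^s1+e^s2)
  s1 <- w$s[[1]][[2]]; s2 <- w$s[[2]][[1]]
  expect_equal(w$weights[, 1], exp(s1 - pmax(s1, s2)) /
                 (exp(s1 - pmax(s1, s2)) + exp(s2 - pmax(s1, s2))),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("every WNN quantity matches the naive dense oracle (two modalities)", {
  fx <- small_views(120)
  embs <- lapply(fx$views, function(v) v$embedding)
  res <- suppressWarnings(run_wnn(fx$views, k = 6, candidate_width = 200, n_bw = 6))
  o <- oracle_weights(embs, k = 6, n_bw = 6)

  for (m in 1:2) {
    expect_equal(res$graphs[[m]]$indices, o$knns[[m]]$indices)
    expect_equal(res$bandwidths[[m]]$sigma, o$sigmas[[m]], tolerance = 1e-10)
    for (nb in 1:2)
      expect_equal(res$weights$theta[[m]][[nb]], o$theta[, m, nb],
                   tolerance = 1e-10, ignore_attr = TRUE)
  }
  expect_equal(unname(res$weights$weights), o$weights, tolerance = 1e-10)

  # candidate truncation loses nothing when candidate_width >= n - 1
  ow <- oracle_wnn_topk(embs, o$weights, o$sigmas, o$d1, k = 6)
  expect_equal(res$graph$indices, ow$indices)
  expect_equal(res$graph$similarities, ow$similarities, tolerance = 1e-10)
  expect_true(all(res$graph$similarities >= 0 & res$graph$similarities <= 1 + 1e-12))
  expect_true(all(apply(res$graph$similarities, 1, function(r) all(diff(r) <= 1e-12))))
})

test_that("three-modality weights match the formula oracle and reduce correctly", {
  set.seed(31)
  n <- 40
  lab <- rep(1:2, each = n / 2)
  mk <- function(d, sep) {
    x <- matrix(rnorm(n * d), n, d)
    if (sep) x[lab == 2, 1] <- x[lab == 2, 1] + 4
    multiweave:::l2_normalize_rows(x)
  }
  embs <- list(mk(5, TRUE), mk(4, TRUE), mk(6, FALSE))
  views <- lapply(embs, function(e) list(embedding = e))
  res <- suppressWarnings(run_wnn(views, k = 4, n_bw = 4))
  o <- oracle_weights(embs, k = 4, n_bw = 4)
  expect_equal(unname(res$weights$weights), o$weights, tolerance = 1e-10)
  expect_true(all(abs(rowSums(res$weights$weights) - 1) < 1e-9))

  # three identical modalities -> (1/3, 1/3, 1/3)
  vi <- list(views[[1]], views[[1]], views[[1]])
  ri <- suppressWarnings(run_wnn(vi, k = 4, n_bw = 4))
  expect_equal(unname(ri$weights$weights), matrix(1 / 3, n, 3))
})

test_that("permuting modality order permutes weights and preserves the graph", {
  fx <- small_views(80)
  r12 <- suppressWarnings(run_wnn(fx$views, k = 5, n_bw = 5))
  r21 <- suppressWarnings(run_wnn(rev(fx$views), k = 5, n_bw = 5))
  expect_equal(unname(r12$weights$weights), unname(r21$weights$weights[, 2:1]))
  expect_equal(r12$graph$indices, r21$graph$indices)
  expect_equal(r12$graph$similarities, r21$graph$similarities, tolerance = 1e-12)
})

test_that("degenerate weights reduce the WNN graph to one modality's ranking", {
  fx <- small_views(80)
  views <- fx$views
  res <- suppressWarnings(run_wnn(list(views[[1]], views[[1]]), k = 5, n_bw = 5))
  # identical modalities: WNN graph equals either modality's KNN (up to ties)
  g <- build_knn(views[[1]], k = 5)
  same <- mean(sapply(seq_len(nrow(g$indices)), function(i)
    length(intersect(res$graph$indices[i, ], g$indices[i, ])) / 5))
  expect_gt(same, 0.95)
})
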