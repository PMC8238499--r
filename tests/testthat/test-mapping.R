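test_that("anchors recover exact copies and match brute-force MNN", {
  set.seed(50)
  ref <- multiweave:::l2_normalize_rows(matrix(rnorm(40 * 5), 40, 5))
  a <- find_anchors(ref, ref, k_anchor = 3)
  self_pairs <- a$pairs[a$pairs$ref == a$pairs$query, ]
  expect_equal(nrow(self_pairs), 40)       # every cell pairs with its copy
  expect_true(all(a$pairs$score >= 0 & a$pairs$score <= 1))

  # disjoint far-apart clouds: no mutual neighbors at all is impossible
  # (MNN always exists between closest cells), but zero-overlap scores are;
  # the error path needs genuinely unpairable inputs: empty after filtering
  qry <- multiweave:::l2_normalize_rows(matrix(rnorm(35 * 5), 35, 5)) + 50
  a2 <- find_anchors(ref, qry, k_anchor = 2)
  expect_true(nrow(a2$pairs) >= 1)         # MNNs exist even across a gap

  # brute-force MNN enumeration oracle on 50 + 50
  ref2 <- matrix(rnorm(50 * 4), 50, 4)
  qry2 <- matrix(rnorm(50 * 4), 50, 4)
  got <- find_anchors(ref2, qry2, k_anchor = 5)$pairs[, c("ref", "query")]
  want <- oracle_mnn(ref2, qry2, k = 5)
  got_keys <- sort(paste(got$ref, got$query))
  want_keys <- sort(paste(want[, 1], want[, 2]))
  expect_equal(got_keys, want_keys)
})

test_that("label transfer votes with anchor-weighted kernels", {
  set.seed(51)
  ref <- rbind(cbind(matrix(rnorm(60 * 2, 6), 60, 2), matrix(rnorm(60 * 2), 60, 2)),
               cbind(matrix(rnorm(60 * 2), 60, 2), matrix(rnorm(60 * 2, 6), 60, 2)))
  ref <- multiweave:::l2_normalize_rows(ref)
  labels <- factor(rep(c("x", "y"), each = 60))
  qry <- ref + matrix(rnorm(length(ref), 0, 0.01), nrow(ref))
  anch <- find_anchors(ref, qry, k_anchor = 5)
  tl <- transfer_labels(anch, labels, qry, k_weight = 20)
  expect_equal(tl$predicted_label, as.character(labels))
  expect_true(all(abs(rowSums(tl$prediction_scores) - 1) < 1e-9))
  expect_true(all(tl$prediction_scores >= 0))
  # argmax consistency
  expect_equal(tl$predicted_label,
               colnames(tl$prediction_scores)[max.col(tl$prediction_scores,
                                                      ties.method = "first")])

  # all anchors sharing one label force that label at score 1
  tl1 <- transfer_labels(anch, factor(rep("only", 120)), qry, k_weight = 10)
  expect_true(all(tl1$predicted_label == "only"))
  expect_true(all(tl1$prediction_scores[, "only"] == 1))

  # more anchors requested than available -> warning, still works
  few <- anch
  few$pairs <- few$pairs[1:5, ]
  expect_warning(transfer_labels(few, labels, qry, k_weight = 50), "available anchors")
})

test_that("equidistant equal-score anchors split the vote and tie-break by label order", {
  # two anchors at (-1) and (+1) with different labels, query cell at 0
  anch <- structure(list(pairs = data.frame(ref = c(1L, 2L), query = c(1L, 2L),
                                            score = c(0.5, 0.5))),
                    class = "AnchorSet")
  qemb <- matrix(c(-1, 1, 0), ncol = 1)
  tl <- transfer_labels(anch, factor(c("a", "b")), qemb, k_weight = 2)
  expect_equal(unname(tl$prediction_scores[3, ]), c(0.5, 0.5))
  expect_equal(tl$predicted_label[3], "a")   # first label wins ties
})

test_that("reference UMAP transform is consistent and de-novo keeps novelty distinct", {
  skip_if_not_installed("uwot")
  des <- mapping_design(600)
  ref <- simulate_multimodal(des)
  rna <- as.matrix(log_normalize(ref$modalities$rna))
  vr <- pca_embed(rna, d = 15)
  umap_model <- fit_reference_umap(vr$embedding, n_neighbors = 15, seed = 1)

  # reference cells through their own model land near their fitted coords
  back <- embed_query_umap(umap_model, vr$embedding, mode = "reference")
  drift <- sqrt(rowSums((back - umap_model$embedding)^2))
  spread <- max(stats::dist(umap_model$embedding[sample(600, 50), ]))
  expect_lt(stats::median(drift), 0.1 * spread)

  # de-novo on two identical datasets: clouds overlap (cluster mixing)
  denovo <- embed_query_umap(vr$embedding, vr$embedding, mode = "de-novo", seed = 1)
  both <- rbind(denovo$ref, denovo$query)
  src <- rep(c(0, 1), each = 600)
  g <- build_knn(both, k = 10)
  mixing <- mean(sapply(seq_len(nrow(both)), function(i)
    mean(src[g$indices[i, ]] != src[i])))  # ~0.5 when perfectly mixed
  expect_gt(mixing / 0.5, 0.9)

  # a novel query population stays distinct in de-novo mode
  qry <- simulate_query(des, 300, novel_cluster = list(name = "N", proportion = 0.3),
                        seed = 9)
  vq <- spca_project(
    spca_fit(rna[select_variable_features(rna, 300), ],
             Matrix::Diagonal(600), d = 15),
    as.matrix(log_normalize(qry$modalities$rna))[select_variable_features(rna, 300), ])
  dn <- embed_query_umap(vr$embedding, vq, mode = "de-novo", seed = 2)
  novel <- which(qry$labels == "N")
  # silhouette of the novel population against its *nearest* reference
  # cluster: positive means it stays distinct rather than merging
  a <- mean(stats::dist(dn$query[novel, ]))
  b_near <- min(sapply(levels(ref$labels), function(cl) {
    rr <- dn$ref[ref$labels == cl, , drop = FALSE]
    mean(multiweave:::dense_dist(dn$query[novel, , drop = FALSE], rr))
  }))
  expect_gt((b_near - a) / max(a, b_near), 0)
})
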