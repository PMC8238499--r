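# Naive dense re-implementations used as independent oracles. Everything is
# written with explicit loops and set arithmetic, sharing no code with the
# package internals beyond base R.

oracle_dist <- function(a, b) sqrt(sum((a - b)^2))

oracle_knn <- function(emb, k) {
  n <- nrow(emb)
  idx <- matrix(0L, n, k); dst <- matrix(0, n, k)
  for (i in seq_len(n)) {
    d <- sapply(seq_len(n), function(j) oracle_dist(emb[i, ], emb[j, ]))
    d[i] <- Inf
    ord <- order(d, seq_len(n))[1:k]
    idx[i, ] <- ord; dst[i, ] <- d[ord]
  }
  list(indices = idx, distances = dst, k = k)
}

oracle_jaccard <- function(knn, include_self = TRUE) {
  n <- nrow(knn$indices)
  sets <- lapply(seq_len(n), function(i) {
    s <- knn$indices[i, ]
    if (include_self) s <- c(s, i)
    s
  })
  J <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    J[i, j] <- length(intersect(sets[[i]], sets[[j]])) /
      length(union(sets[[i]], sets[[j]]))
  }
  J
}

oracle_bandwidth <- function(emb, knn, n_bw = 20, include_self = TRUE) {
  n <- nrow(emb)
  J <- oracle_jaccard(knn, include_self)
  sigma <- numeric(n)
  for (i in seq_len(n)) {
    jac <- J[i, ]
    cand <- setdiff(which(jac > 0), i)
    if (length(cand) == 0) {
      sigma[i] <- knn$distances[i, knn$k]
    } else {
      d <- sapply(cand, function(j) oracle_dist(emb[i, ], emb[j, ]))
      sel <- if (length(cand) < n_bw) seq_along(cand)
             else order(jac[cand], -d)[1:n_bw]
      sigma[i] <- mean(d[sel])
    }
  }
  pmax(sigma, knn$distances[, 1] + 1e-10)
}

# Direct transcription of the modality-weight formulas for M >= 2.
oracle_weights <- function(embs, k, n_bw = 20) {
  M <- length(embs)
  n <- nrow(embs[[1]])
  knns <- lapply(embs, oracle_knn, k = k)
  sigmas <- lapply(seq_len(M), function(m) oracle_bandwidth(embs[[m]], knns[[m]], n_bw))
  d1 <- lapply(knns, function(g) g$distances[, 1])
  theta <- function(m, nbr_mod, i) {
    pred <- colMeans(embs[[m]][knns[[nbr_mod]]$indices[i, ], , drop = FALSE])
    d <- oracle_dist(embs[[m]][i, ], pred)
    exp(-max(d - d1[[m]][i], 0) / (sigmas[[m]][i] - d1[[m]][i]))
  }
  w <- matrix(0, n, M)
  th <- array(0, c(n, M, M))
  for (i in seq_len(n)) {
    for (m in seq_len(M)) for (nb in seq_len(M)) th[i, m, nb] <- theta(m, nb, i)
    s <- c()
    owner <- c()
    for (m in seq_len(M)) for (nb in seq_len(M)) if (nb != m) {
      s <- c(s, th[i, m, m] / (th[i, m, nb] + 1e-4))
      owner <- c(owner, m)
    }
    es <- exp(s - max(s))
    for (m in seq_len(M)) w[i, m] <- sum(es[owner == m])
    w[i, ] <- w[i, ] / sum(w[i, ])
  }
  list(weights = w, theta = th, knns = knns, sigmas = sigmas, d1 = d1)
}

# WNN top-k scoring every other cell (no candidate truncation).
oracle_wnn_topk <- function(embs, w, sigmas, d1, k) {
  M <- length(embs)
  n <- nrow(embs[[1]])
  idx <- matrix(0L, n, k); sim <- matrix(0, n, k)
  for (i in seq_len(n)) {
    cand <- setdiff(seq_len(n), i)
    score <- sapply(cand, function(j) {
      s <- 0
      for (m in seq_len(M)) {
        d <- oracle_dist(embs[[m]][i, ], embs[[m]][j, ])
        s <- s + w[i, m] *
          exp(-max(d - d1[[m]][i], 0) / (sigmas[[m]][i] - d1[[m]][i]))
      }
      s
    })
    ord <- order(-score, cand)[1:k]
    idx[i, ] <- cand[ord]; sim[i, ] <- score[ord]
  }
  list(indices = idx, similarities = sim)
}

oracle_mnn <- function(ref, query, k) {
  nr <- nrow(ref); nq <- nrow(query)
  r2q <- t(sapply(seq_len(nr), function(r) {
    d <- sapply(seq_len(nq), function(q) oracle_dist(ref[r, ], query[q, ]))
    order(d)[1:k]
  }))
  q2r <- t(sapply(seq_len(nq), function(q) {
    d <- sapply(seq_len(nr), function(r) oracle_dist(ref[r, ], query[q, ]))
    order(d)[1:k]
  }))
  pairs <- NULL
  for (r in seq_len(nr)) for (q in r2q[r, ]) {
    if (r %in% q2r[q, ]) pairs <- rbind(pairs, c(r, q))
  }
  pairs
}
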