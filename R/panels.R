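# Targeted immunophenotype panel selection: greedy forward selection of 1-10
# surface markers with balanced (class-weighted) ridge logistic regression,
# scored by 5-fold cross-validation, reporting the in-silico enrichment each
# panel achieves at a 0.5 decision boundary.

# Balanced class weights: each class contributes half the total weight.
balanced_weights <- function(y) {
  tab <- table(y)
  w <- 0.5 / tab[as.character(y)]
  as.numeric(w) * length(y)
}

# Ridge logistic fit on a fixed feature set; returns a function scoring new
# data plus the coefficients. lambda is chosen from a small grid by the CV
# caller; here we fit all grid values at once.
ridge_logistic <- function(x, y, weights, lambda_grid) {
  xm <- as.matrix(x)
  if (ncol(xm) == 1) xm <- cbind(xm, .pad = 0)  # glmnet needs >= 2 columns
  glmnet::glmnet(xm, y, family = "binomial", alpha = 0,
                 lambda = sort(lambda_grid, decreasing = TRUE),
                 weights = weights, standardize = TRUE)
}

predict_ridge <- function(fit, x, lambda) {
  xm <- as.matrix(x)
  if (ncol(xm) == 1) xm <- cbind(xm, .pad = 0)
  as.numeric(stats::predict(fit, newx = xm, s = lambda, type = "response"))
}

# 5-fold CV balanced accuracy of a candidate feature set, maximized over the
# ridge grid.
cv_panel_score <- function(x, y, folds, lambda_grid) {
  accs <- matrix(NA_real_, max(folds), length(lambda_grid))
  for (f in seq_len(max(folds))) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) next
    w <- balanced_weights(y[tr])
    fit <- ridge_logistic(x[tr, , drop = FALSE], y[tr], w, lambda_grid)
    for (l in seq_along(lambda_grid)) {
      p <- predict_ridge(fit, x[!tr, , drop = FALSE], lambda_grid[l]) > 0.5
      yt <- y[!tr] == levels(factor(y))[2]
      sens <- if (any(yt)) mean(p[yt]) else NA
      spec <- if (any(!yt)) mean(!p[!yt]) else NA
      accs[f, l] <- mean(c(sens, spec), na.rm = TRUE)
    }
  }
  best <- which.max(colMeans(accs, na.rm = TRUE))
  list(score = max(colMeans(accs, na.rm = TRUE)), lambda = lambda_grid[best])
}

#' Select a targeted marker panel for one cluster
#'
#' Greedy forward selection of up to `max_size` markers separating
#' `target` cells from the rest, using balanced ridge logistic regression
#' scored by 5-fold cross-validated balanced accuracy. Abundant clusters are
#' first downsampled so no cluster exceeds `abundance_cap` of all cells
#' (seeded). The first `n_positive_first` selected markers are required to
#' be positive markers (higher mean in the target and positive fitted
#' coefficient). For each panel size the function reports precision, recall
#' and enrichment fold (precision / target prevalence) of the in-silico gate
#' at a 0.5 decision boundary.
#'
#' @param adt normalized proteins x cells matrix.
#' @param labels per-cell cluster labels.
#' @param target the cluster to enrich for.
#' @param max_size maximum panel size (default 10).
#' @param n_positive_first how many leading markers must be positive
#'   (default 5).
#' @param abundance_cap per-cluster share cap before selection (default 0.05;
#'   clusters above it are downsampled).
#' @param lambda_grid ridge penalty grid searched inside the CV (default
#'   `c(0.1, 0.01, 0.001)`).
#' @param seed RNG seed for downsampling and fold assignment.
#' @return a `PanelResult`: `markers` (ordered), `metrics` (per panel size:
#'   cv_score, precision, recall, enrichment), `coefficients` of the final
#'   fit, `prevalence`.
#' @export
select_marker_panel <- function(adt, labels, target, max_size = 10,
                                n_positive_first = 5, abundance_cap = 0.05,
                                lambda_grid = c(0.1, 0.01, 0.001), seed = 42) {
  adt <- as.matrix(adt)
  labels <- as.character(labels)
  if (!target %in% labels) stopf("target cluster '%s' not present", target)
  if (length(unique(labels)) < 2) stopf("need >= 2 clusters")
  set.seed(seed)
  # downsample abundant clusters (never below the cap; the target is exempt
  # unless it is itself abundant)
  n <- length(labels)
  keep <- unlist(lapply(split(seq_len(n), labels), function(idx) {
    cap <- ceiling(abundance_cap * n)
    lab <- labels[idx[1]]
    if (lab != target && length(idx) > cap) sample(idx, cap) else idx
  }))
  keep <- sort(keep)
  x_all <- t(adt[, keep, drop = FALSE])     # cells x proteins
  y <- factor(ifelse(labels[keep] == target, "target", "other"),
              levels = c("other", "target"))
  prevalence <- mean(y == "target")
  folds <- sample(rep(seq_len(5), length.out = nrow(x_all)))
  remaining <- colnames(x_all) %||% paste0("p", seq_len(ncol(x_all)))
  colnames(x_all) <- remaining
  target_mean <- colMeans(x_all[y == "target", , drop = FALSE])
  other_mean <- colMeans(x_all[y == "other", , drop = FALSE])
  positive <- target_mean > other_mean

  chosen <- character(0)
  metrics <- data.frame()
  last_score <- -Inf
  for (size in seq_len(min(max_size, ncol(x_all)))) {
    need_positive <- size <= n_positive_first
    cands <- remaining
    if (need_positive) cands <- cands[positive[cands]]
    if (length(cands) == 0) break
    res <- lapply(cands, function(mk) {
      cv_panel_score(x_all[, c(chosen, mk), drop = FALSE], y, folds, lambda_grid)
    })
    sc <- vapply(res, `[[`, numeric(1), "score")
    ord <- order(-sc)
    pick <- NA_character_
    for (o in ord) {
      mk <- cands[o]
      if (need_positive) {
        fit <- ridge_logistic(x_all[, c(chosen, mk), drop = FALSE], y,
                              balanced_weights(y), lambda_grid)
        cf <- stats::coef(fit, s = res[[o]]$lambda)[mk, 1]
        if (cf <= 0) next
      }
      pick <- mk
      pick_score <- sc[o]; pick_lambda <- res[[o]]$lambda
      break
    }
    if (is.na(pick)) break
    chosen <- c(chosen, pick)
    remaining <- setdiff(remaining, pick)
    last_score <- pick_score
    # in-silico gate metrics at 0.5 on the (downsampled) data
    fit <- ridge_logistic(x_all[, chosen, drop = FALSE], y,
                          balanced_weights(y), lambda_grid)
    p <- predict_ridge(fit, x_all[, chosen, drop = FALSE], pick_lambda) > 0.5
    tp <- sum(p & y == "target")
    precision <- if (any(p)) tp / sum(p) else 0
    recall <- tp / sum(y == "target")
    metrics <- rbind(metrics, data.frame(
      size = size, marker = pick, cv_score = pick_score,
      precision = precision, recall = recall,
      enrichment = precision / prevalence))
  }
  final_fit <- ridge_logistic(x_all[, chosen, drop = FALSE], y,
                              balanced_weights(y), lambda_grid)
  cf <- stats::coef(final_fit, s = min(lambda_grid))
  structure(list(cluster_id = target, markers = chosen, metrics = metrics,
                 coefficients = cf, prevalence = prevalence),
            class = "PanelResult")
}

#' @export
print.PanelResult <- function(x, ...) {
  cat(sprintf("PanelResult for '%s': %d markers (prevalence %.3f)\n",
              x$cluster_id, length(x$markers), x$prevalence))
  print(x$metrics, row.names = FALSE)
  invisible(x)
}
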