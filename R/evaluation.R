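#' Rank-based ROC curve and AUC
#'
#' AUC is the tie-corrected Mann-Whitney statistic: the probability that a
#' random positive outscores a random negative, ties counted 1/2.  ROC
#' points come from a threshold sweep over the distinct scores (plus the
#' (0,0) and (1,1) endpoints).
#'
#' @param pos_scores,neg_scores numeric vectors of scores of the positive
#'   and negative samples; both must be nonempty.
#' @return list with `auc` (scalar) and `roc_points` (data.frame with
#'   columns `fpr`, `tpr`, monotone from (0,0) to (1,1)).
#' @export
roc_auc <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0L || length(neg_scores) == 0L)
    stop("empty score list")
  np <- length(pos_scores); nn <- length(neg_scores)
  r <- rank(c(pos_scores, neg_scores))
  auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
  thr <- sort(unique(c(pos_scores, neg_scores)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(pos_scores >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg_scores >= t), numeric(1))
  list(auc = auc,
       roc_points = data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1)))
}

#' Rank of a held-out pair among candidates
#'
#' Average-rank convention over the union of the pair and its candidate
#' set: `1 + #{candidates scoring strictly higher} + #{ties}/2`.
#'
#' @param scores numeric score matrix.
#' @param pair integer vector `c(row, col)` of the held-out pair.
#' @param candidates two-column integer matrix of candidate (row, col)
#'   indices; must not contain `pair`.
#' @return the (possibly half-integer) rank.
#' @export
rank_of_pair <- function(scores, pair, candidates) {
  if (any(candidates[, 1L] == pair[1L] & candidates[, 2L] == pair[2L]))
    stop("held-out pair must not be in the candidate set")
  s <- scores[pair[1L], pair[2L]]
  cs <- scores[candidates]
  1 + sum(cs > s) + sum(cs == s) / 2
}

new_cv_report <- function(protocol, per_unit_auc, roc_points, per_test_ranks,
                          seed = NA, repeats = NA, k = NA) {
  structure(list(protocol = protocol,
                 per_unit_auc = per_unit_auc,
                 mean_auc = mean(per_unit_auc),
                 sd_auc = if (length(per_unit_auc) > 1L) stats::sd(per_unit_auc) else 0,
                 roc_points = roc_points,
                 per_test_ranks = per_test_ranks,
                 seed = seed, repeats = repeats, k = k),
            class = "lmi_cv_report")
}

#' @export
print.lmi_cv_report <- function(x, ...) {
  cat(sprintf("%s report: mean AUC %.4f +/- %.4f (%d unit%s)\n", x$protocol,
              x$mean_auc, x$sd_auc, length(x$per_unit_auc),
              if (length(x$per_unit_auc) == 1L) "" else "s"))
  invisible(x)
}

#' Leave-one-out cross-validation
#'
#' Each known interaction is removed in turn, the method is retrained on the
#' remaining edges, and the held-out pair is ranked among all unidentified
#' pairs of the full grid (candidate-set size `nl*nm - |edges|` in every
#' iteration).  The global AUC uses the threshold-on-rank construction:
#' with candidate count c and average rank r_i of test sample i,
#' `AUC = mean((c + 1 - r_i) / c)`; ROC points sweep integer rank
#' thresholds (`fpr = t/c`, `tpr = frac(r_i <= t)`).
#'
#' @param network an [lmi_network].
#' @param method a scoring closure `function(network) -> score matrix`,
#'   e.g. from [lmi_method()].
#' @return an `lmi_cv_report` (protocol `"loocv"`, one global AUC).
#' @export
loocv <- function(network, method) {
  edges <- edge_indices(network)
  cand <- nonedge_indices(network)
  cc <- nrow(cand)
  ranks <- numeric(nrow(edges))
  for (i in seq_len(nrow(edges))) {
    A_train <- network$A
    A_train[edges[i, 1L], edges[i, 2L]] <- 0
    net_train <- lmi_network(network$lnc_ids, network$mir_ids, A_train)
    scores <- method(net_train)
    ranks[i] <- rank_of_pair(scores, edges[i, ], cand)
  }
  auc <- mean((cc + 1 - ranks) / cc)
  thr <- c(0, sort(unique(ceiling(ranks))), cc)
  roc <- data.frame(fpr = pmin(thr / cc, 1),
                    tpr = vapply(thr, function(t) mean(ranks <= t), numeric(1)))
  roc <- roc[order(roc$fpr, roc$tpr), ]
  per_test <- data.frame(lncRNA = network$lnc_ids[edges[, 1L]],
                         miRNA = network$mir_ids[edges[, 2L]],
                         rank = ranks, stringsAsFactors = FALSE)
  new_cv_report("loocv", auc, roc, per_test)
}

#' Repeated k-fold cross-validation
#'
#' Known edges are partitioned uniformly at random into k folds per repeat
#' (RNG seeded `seed + repeat` for each repeat).  For each fold the method
#' is retrained on the other k-1 folds and the AUC of the held-out
#' positives against all unidentified pairs of the full grid is recorded;
#' the report carries all per-fold AUCs with their mean and SD.  ROC points
#' are pooled over the folds of the first repeat.
#'
#' @inheritParams loocv
#' @param k number of folds (default 5).
#' @param repeats number of random re-partitions (default 50).
#' @param seed base RNG seed.
#' @return an `lmi_cv_report` (protocol `"kfold"`).
#' @export
kfold_cv <- function(network, method, k = 5L, repeats = 50L, seed = 1L) {
  edges <- edge_indices(network)
  ne <- nrow(edges)
  if (k < 2L) stop("k must be >= 2")
  if (k > ne) stop("k exceeds the number of known edges")
  cand <- nonedge_indices(network)
  aucs <- numeric(0)
  pool_pos <- pool_neg <- numeric(0)
  for (r in seq_len(repeats)) {
    old <- local_seed(seed + r)
    fold <- sample(rep(seq_len(k), length.out = ne))
    restore_seed(old)
    for (f in seq_len(k)) {
      test <- edges[fold == f, , drop = FALSE]
      A_train <- network$A
      A_train[test] <- 0
      net_train <- lmi_network(network$lnc_ids, network$mir_ids, A_train)
      scores <- method(net_train)
      res <- roc_auc(scores[test], scores[cand])
      aucs <- c(aucs, res$auc)
      if (r == 1L) {
        pool_pos <- c(pool_pos, scores[test])
        pool_neg <- c(pool_neg, scores[cand])
      }
    }
  }
  roc <- roc_auc(pool_pos, pool_neg)$roc_points
  new_cv_report("kfold", aucs, roc, per_test_ranks = NULL,
                seed = seed, repeats = repeats, k = k)
}
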