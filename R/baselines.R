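#' Memory-based collaborative filtering scores
#'
#' lncRNA-based CF scores pair (a, b) as the similarity-weighted average of
#' the other lncRNAs' observed interactions with miRNA b:
#' `sum_{l != a} sim(a, l) * A(l, b) / sum_{l != a} sim(a, l)`; miRNA-based
#' CF is the symmetric construction over miRNA neighborhoods.
#' Self-similarity is excluded from the neighborhood sum.  An entity whose
#' off-diagonal similarities sum to zero gets a zero score row/column (with
#' a message).
#'
#' @param network an [lmi_network].
#' @param sim prepared similarity matrix aligned to the chosen side.
#' @param side `"lnc"` or `"mir"`.
#' @param quiet suppress the zero-denominator message.
#' @return nl x nm score matrix.
#' @export
cf_scores <- function(network, sim, side = c("lnc", "mir"), quiet = FALSE) {
  side <- match.arg(side)
  A <- network$A
  S <- unclass(sim)
  n_side <- if (side == "lnc") nrow(A) else ncol(A)
  if (nrow(S) != n_side) stop("similarity does not match the chosen side")
  diag(S) <- 0
  den <- rowSums(S)
  zero <- den == 0
  if (any(zero) && !quiet)
    message(sprintf("cf_scores: %d %s entities have zero neighborhood weight",
                    sum(zero), side))
  den[zero] <- 1
  scores <- if (side == "lnc") (S %*% A) / den else t(t(A %*% S) / den)
  if (side == "lnc") scores[zero, ] <- 0 else scores[, zero] <- 0
  dimnames(scores) <- dimnames(A)
  attr(scores, "provenance") <- list(method = paste0("cf_", side))
  scores
}

#' Truncated-SVD scores
#'
#' Rank-`rank` reconstruction of the adjacency matrix, shifted by its global
#' minimum so all scores are nonnegative (a rank shift leaves the ranking
#' unchanged).
#'
#' @param network an [lmi_network].
#' @param rank truncation rank, `1 <= rank <= min(nl, nm)`.
#' @return nl x nm score matrix.
#' @export
svd_scores <- function(network, rank = 20L) {
  A <- network$A
  if (rank < 1L || rank > min(dim(A))) stop("rank out of range")
  sv <- svd(A, nu = rank, nv = rank)
  rec <- sv$u %*% (sv$d[seq_len(rank)] * t(sv$v))
  shift <- min(rec)
  rec <- rec - shift
  dimnames(rec) <- dimnames(A)
  attr(rec, "provenance") <- list(method = "svd", rank = rank, shift = shift)
  rec
}

#' Latent-factor-model scores
#'
#' Fits `A ~ P %*% t(Q)` by stochastic gradient descent over ALL cells of
#' the grid (implicit feedback: unknown pairs are treated as 0), minimizing
#' the squared error plus an L2 penalty.  Scores are `P %*% t(Q)` shifted to
#' be nonnegative.  Initialization and the cell-visit order are drawn from
#' R's RNG, so results are reproducible given `seed`.
#'
#' @param network an [lmi_network].
#' @param factors number of latent factors (default 20).
#' @param reg L2 regularization weight (default 0.01).
#' @param lr SGD learning rate (default 0.01).
#' @param epochs number of passes over the grid (default 200).
#' @param seed integer RNG seed.
#' @return nl x nm score matrix; the per-epoch objective trajectory is in
#'   attribute `loss`.
#' @export
lfm_scores <- function(network, factors = 20L, reg = 0.01, lr = 0.01,
                       epochs = 200L, seed = 1L) {
  if (factors < 1L) stop("factors must be >= 1")
  A <- network$A
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  P <- matrix(stats::rnorm(nrow(A) * factors, sd = 0.1), nrow(A), factors)
  Q <- matrix(stats::rnorm(ncol(A) * factors, sd = 0.1), ncol(A), factors)
  ord <- sample.int(length(A)) - 1L  # 0-based cell ids, fixed across epochs
  loss <- lfm_sgd(A, P, Q, ord, reg, lr, as.integer(epochs))
  scores <- tcrossprod(P, Q)
  shift <- min(scores)
  scores <- scores - shift
  dimnames(scores) <- dimnames(A)
  attr(scores, "loss") <- loss
  attr(scores, "provenance") <- list(method = "lfm", factors = factors,
                                     reg = reg, lr = lr, epochs = epochs,
                                     seed = seed, shift = shift)
  scores
}

#' Katz scores on the heterogeneous graph
#'
#' Builds the heterogeneous adjacency
#' `M = rbind(cbind(LS0, A), cbind(t(A), MS0))` where `LS0`/`MS0` are the
#' similarity matrices with zeroed diagonals (so self-loops do not inflate
#' walk counts) and scores the lncRNA-miRNA block of
#' `sum_{k=1..kmax} beta^k * M^k`.
#'
#' @param network an [lmi_network].
#' @param LS,MS prepared similarity matrices.
#' @param beta walk damping factor (default 0.01); values at or above
#'   1/spectral-radius trigger a warning, not an error.
#' @param kmax maximum walk length (default 4).
#' @return nl x nm score matrix.
#' @export
katz_scores <- function(network, LS, MS, beta = 0.01, kmax = 4L) {
  if (kmax < 1L) stop("kmax must be >= 1")
  A <- network$A
  LS0 <- unclass(LS); diag(LS0) <- 0
  MS0 <- unclass(MS); diag(MS0) <- 0
  M <- rbind(cbind(LS0, A), cbind(t(A), MS0))
  sr <- max(abs(eigen(M, only.values = TRUE)$values))
  if (sr > 0 && beta >= 1 / sr)
    warning(sprintf("beta = %g >= 1/spectral radius (%g); Katz series may diverge",
                    beta, 1 / sr))
  acc <- matrix(0, nrow(M), ncol(M))
  Mk <- diag(nrow(M))
  for (k in seq_len(kmax)) {
    Mk <- Mk %*% M
    acc <- acc + beta^k * Mk
  }
  nl <- nrow(A)
  scores <- acc[seq_len(nl), nl + seq_len(ncol(A)), drop = FALSE]
  dimnames(scores) <- dimnames(A)
  attr(scores, "provenance") <- list(method = "katz", beta = beta, kmax = kmax)
  scores
}

#' Scoring-method constructors
#'
#' Wraps every scorer of the package into a closure `function(network) ->
#' score matrix`, so cross-validation drivers can retrain any method on a
#' perturbed network.  `"random"` scores pairs with iid uniforms (a floor
#' baseline for evaluation).
#'
#' @param method one of `"eplmi"`, `"cf_lnc"`, `"cf_mir"`, `"svd"`,
#'   `"lfm"`, `"katz"`, `"random"`.
#' @param lnc_sim,mir_sim prepared similarity matrices (as required by the
#'   method).
#' @param params named list of method parameters overriding the defaults
#'   (`epsilon`, `rank`, `factors`, `reg`, `lr`, `epochs`, `beta`, `kmax`,
#'   `seed`).
#' @return a function of one argument (an [lmi_network]) returning a score
#'   matrix.
#' @export
lmi_method <- function(method, lnc_sim = NULL, mir_sim = NULL, params = list()) {
  p <- utils::modifyList(list(epsilon = 1e-11, rank = 20L, factors = 20L,
                              reg = 0.01, lr = 0.01, epochs = 200L,
                              beta = 0.01, kmax = 4L, seed = 1L), params)
  switch(match.arg(method, c("eplmi", "cf_lnc", "cf_mir", "svd", "lfm",
                             "katz", "random")),
    eplmi  = function(net) eplmi_scores(net, lnc_sim, mir_sim, p$epsilon),
    cf_lnc = function(net) cf_scores(net, lnc_sim, "lnc", quiet = TRUE),
    cf_mir = function(net) cf_scores(net, mir_sim, "mir", quiet = TRUE),
    svd    = function(net) svd_scores(net, p$rank),
    lfm    = function(net) lfm_scores(net, p$factors, p$reg, p$lr, p$epochs,
                                      p$seed),
    katz   = function(net) katz_scores(net, lnc_sim, mir_sim, p$beta, p$kmax),
    random = function(net) {
      old <- local_seed(p$seed)
      on.exit(restore_seed(old))
      matrix(stats::runif(length(net$A)), nrow(net$A), ncol(net$A),
             dimnames = dimnames(net$A))
    })
}

# Save/restore the global RNG state so seeded helpers do not disturb the
# caller's stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
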