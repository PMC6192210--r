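# Independent oracles used to check the package implementations.  These are
# deliberately naive (explicit loops, brute-force enumeration) and share no
# code with the package.

# Needleman-Wunsch with affine gaps (Gotoh), gap of length L costing
# open + (L - 1) * extend, end gaps penalized.
nw_affine_oracle <- function(s1, s2, match = 2, mismatch = -1,
                             gap_open = -0.5, gap_extend = -0.1) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -Inf
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)  # X: gap in s2, Y: gap in s1
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- gap_open + (i - 1) * gap_extend
  for (j in seq_len(m)) Y[1, j + 1] <- gap_open + (j - 1) * gap_extend
  for (i in seq_len(n)) for (j in seq_len(m)) {
    sub <- if (a[i] == b[j]) match else mismatch
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + sub
    X[i + 1, j + 1] <- max(M[i, j + 1] + gap_open, X[i, j + 1] + gap_extend,
                           Y[i, j + 1] + gap_open)
    Y[i + 1, j + 1] <- max(M[i + 1, j] + gap_open, Y[i + 1, j] + gap_extend,
                           X[i + 1, j] + gap_open)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Pearson correlation from the raw definition (explicit sums).
pearson_oracle <- function(x, y) {
  n <- length(x)
  dx <- x - sum(x) / n
  dy <- y - sum(y) / n
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Two-way diffusion by explicit enumeration of all two-hop resource paths.
# Shares are recomputed with scalar loops from the weighted matrix W:
# forward share of entity a in miRNA m's column, backward share of miRNA m
# in lncRNA l's row, landing on the observed adjacency A.
diffusion_oracle <- function(A, LS, MS, eps = 1e-11) {
  nl <- nrow(A); nm <- ncol(A)
  mat_prod <- function(X, Y) {            # scalar-loop matrix product
    Z <- matrix(0, nrow(X), ncol(Y))
    for (i in seq_len(nrow(X))) for (j in seq_len(ncol(Y)))
      Z[i, j] <- sum(X[i, ] * Y[, j])
    Z
  }
  one_network <- function(W) {
    colshare <- matrix(0, nl, nm); rowshare <- matrix(0, nl, nm)
    for (m in seq_len(nm)) colshare[, m] <- W[, m] / sum(W[, m])
    for (l in seq_len(nl)) rowshare[l, ] <- W[l, ] / sum(W[l, ])
    SS_lnc <- matrix(0, nl, nm); SS_mir <- matrix(0, nl, nm)
    for (a in seq_len(nl)) for (b in seq_len(nm)) {
      acc_l <- 0; acc_m <- 0
      for (m in seq_len(nm)) for (l in seq_len(nl)) {
        acc_l <- acc_l + colshare[a, m] * rowshare[l, m] * A[l, b]
        acc_m <- acc_m + A[a, m] * colshare[l, m] * rowshare[l, b]
      }
      SS_lnc[a, b] <- acc_l; SS_mir[a, b] <- acc_m
    }
    (SS_lnc + SS_mir) / 2
  }
  A_l <- mat_prod(LS, A); A_l[A_l == 0] <- eps
  A_m <- mat_prod(A, MS); A_m[A_m == 0] <- eps
  (one_network(A_l) + one_network(A_m)) / 2
}

# AUC by brute-force comparison of every positive/negative pair.
auc_bruteforce <- function(pos, neg) {
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Random prepared similarity matrix (symmetric, nonnegative, unit diagonal).
random_prepared_sim <- function(n, ids = sprintf("e%d", seq_len(n))) {
  M <- matrix(runif(n * n), n, n)
  M <- (M + t(M)) / 2
  diag(M) <- 1
  dimnames(M) <- list(ids, ids)
  prepare_similarity(M)
}

# Random bipartite network guaranteed to have at least one edge.
random_network <- function(nl, nm, p = 0.4) {
  repeat {
    A <- matrix(rbinom(nl * nm, 1, p), nl, nm)
    if (sum(A) > 0) break
  }
  lmi_network(sprintf("L%d", seq_len(nl)), sprintf("M%d", seq_len(nm)), A)
}

# Default-preset similarities for a synthetic dataset.
dataset_sims <- function(ds) {
  list(LS = prepare_similarity(pearson_similarity(ds$lnc_profiles, quiet = TRUE)),
       MS = prepare_similarity(pearson_similarity(ds$mir_profiles, quiet = TRUE)))
}
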