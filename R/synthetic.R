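#' Generate a planted-block bipartite dataset
#'
#' Emulates the structure the method assumes in real data: groups
#' ("blocks") of lncRNAs preferentially interact with paired groups of
#' miRNAs, and entities within a block share an expression template, so
#' within-block profile correlation exceeds between-block correlation.
#' Entities are assigned to blocks round-robin; edge (l, m) is Bernoulli
#' `p_in` when their blocks are paired, else `p_out`; the profile of an
#' entity in block k is the block template (standard normal of length
#' `n_conditions`, scaled by `block_signal`, drawn once per block per side)
#' plus iid Gaussian noise of sd `noise_sd`.  Condition counts default to
#' the 22 tissue/cell-line conditions typical of lncRNA panels and the 172
#' of miRNA panels.
#'
#' @param n_lnc,n_mir numbers of lncRNAs and miRNAs (defaults 60, 40).
#' @param n_blocks number of paired blocks (default 4).
#' @param p_in,p_out within-/between-block edge probabilities (defaults
#'   0.5, 0.03; `p_out < p_in` required).
#' @param n_conditions_lnc,n_conditions_mir profile lengths (22, 172).
#' @param block_signal template scale (default 1).
#' @param noise_sd profile noise sd (default 0.5).
#' @param seed integer RNG seed; regeneration with the same parameters and
#'   seed is bit-identical.
#' @return an `lmi_synthetic_dataset`: `network` ([lmi_network]),
#'   `lnc_profiles`, `mir_profiles` (matrices), `lnc_blocks`, `mir_blocks`
#'   (named integer vectors) and `params`.
#' @export
generate_dataset <- function(n_lnc = 60L, n_mir = 40L, n_blocks = 4L,
                             p_in = 0.5, p_out = 0.03,
                             n_conditions_lnc = 22L, n_conditions_mir = 172L,
                             block_signal = 1, noise_sd = 0.5, seed = 1L) {
  if (n_blocks > min(n_lnc, n_mir)) stop("n_blocks exceeds a side size")
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) stop("need 0 <= p_out < p_in <= 1")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  params <- list(n_lnc = n_lnc, n_mir = n_mir, n_blocks = n_blocks,
                 p_in = p_in, p_out = p_out,
                 n_conditions_lnc = n_conditions_lnc,
                 n_conditions_mir = n_conditions_mir,
                 block_signal = block_signal, noise_sd = noise_sd,
                 seed = seed)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  lnc_ids <- sprintf("L%03d", seq_len(n_lnc))
  mir_ids <- sprintf("M%03d", seq_len(n_mir))
  lb <- stats::setNames(((seq_len(n_lnc) - 1L) %% n_blocks) + 1L, lnc_ids)
  mb <- stats::setNames(((seq_len(n_mir) - 1L) %% n_blocks) + 1L, mir_ids)
  sample_A <- function() {
    p <- ifelse(outer(lb, mb, "=="), p_in, p_out)
    matrix(stats::rbinom(n_lnc * n_mir, 1L, p), n_lnc, n_mir)
  }
  A <- sample_A()
  if (sum(A) == 0) A <- sample_A()
  if (sum(A) == 0) stop("empty network after sampling (twice)")
  profiles <- function(blocks, nc, ids) {
    tmpl <- matrix(stats::rnorm(n_blocks * nc), n_blocks, nc) * block_signal
    out <- tmpl[blocks, , drop = FALSE] +
      matrix(stats::rnorm(length(blocks) * nc, sd = noise_sd),
             length(blocks), nc)
    dimnames(out) <- list(ids, sprintf("C%03d", seq_len(nc)))
    out
  }
  structure(list(network = lmi_network(lnc_ids, mir_ids, A),
                 lnc_profiles = profiles(lb, n_conditions_lnc, lnc_ids),
                 mir_profiles = profiles(mb, n_conditions_mir, mir_ids),
                 lnc_blocks = lb, mir_blocks = mb, params = params),
            class = "lmi_synthetic_dataset")
}

#' @export
print.lmi_synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic planted-block dataset (%d blocks, seed %d)\n",
              x$params$n_blocks, x$params$seed))
  print(x$network)
  invisible(x)
}

#' Remove a fraction of edges from a synthetic dataset
#'
#' Uniformly removes `round(fraction * edges)` edges (sampling without
#' replacement) and records the removed pairs as ground truth for recovery
#' experiments.
#'
#' @param dataset an `lmi_synthetic_dataset`.
#' @param fraction fraction of edges to remove, in [0, 1).
#' @param seed integer RNG seed.
#' @return the dataset with the degraded `network` and a `removed` element
#'   (two-column index matrix into the adjacency).
#' @export
degrade_dataset <- function(dataset, fraction, seed = 1L) {
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  net <- dataset$network
  edges <- edge_indices(net)
  n_rm <- round(fraction * nrow(edges))
  if (n_rm >= nrow(edges)) stop("removal would empty the network")
  old <- local_seed(seed)
  rm_idx <- if (n_rm > 0) sample.int(nrow(edges), n_rm) else integer(0)
  restore_seed(old)
  removed <- edges[rm_idx, , drop = FALSE]
  A <- net$A
  A[removed] <- 0
  dataset$network <- lmi_network(net$lnc_ids, net$mir_ids, A)
  dataset$removed <- removed
  dataset
}

#' Degree-preserving shuffle of a bipartite network
#'
#' Randomizes the edge set while preserving both degree sequences via
#' checkerboard swaps: repeatedly pick two edges (i1, j1), (i2, j2) with
#' distinct rows and columns and, if (i1, j2) and (i2, j1) are non-edges,
#' replace the pair with them.  Used as the null model for the coherence
#' analysis.
#'
#' @param network an [lmi_network].
#' @param seed integer RNG seed.
#' @param n_swaps number of attempted swaps (default `10 * edges`).
#' @return the shuffled [lmi_network].
#' @export
shuffle_network <- function(network, seed = 1L, n_swaps = NULL) {
  A <- network$A
  edges <- which(A == 1, arr.ind = TRUE)
  ne <- nrow(edges)
  if (is.null(n_swaps)) n_swaps <- 10L * ne
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  picks <- matrix(sample.int(ne, 2L * n_swaps, replace = TRUE), ncol = 2L)
  for (s in seq_len(n_swaps)) {
    e1 <- edges[picks[s, 1L], ]; e2 <- edges[picks[s, 2L], ]
    if (e1[1L] == e2[1L] || e1[2L] == e2[2L]) next
    if (A[e1[1L], e2[2L]] == 1 || A[e2[1L], e1[2L]] == 1) next
    A[e1[1L], e1[2L]] <- 0; A[e2[1L], e2[2L]] <- 0
    A[e1[1L], e2[2L]] <- 1; A[e2[1L], e1[2L]] <- 1
    edges[picks[s, 1L], ] <- c(e1[1L], e2[2L])
    edges[picks[s, 2L], ] <- c(e2[1L], e1[2L])
  }
  lmi_network(network$lnc_ids, network$mir_ids, A)
}
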