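#' Weighted interaction networks
#'
#' Projects the two similarity spaces onto the bipartite adjacency:
#' `A_l = LS %*% A` (entry (i, j) is the total similarity between lncRNA i
#' and the lncRNAs known to interact with miRNA j) and `A_m = A %*% MS`
#' (symmetric construction on the miRNA side).  Zeros are then replaced by a
#' tiny `epsilon` so that every later column/row normalization is
#' well-defined.
#'
#' @param network an [lmi_network].
#' @param LS,MS prepared similarity matrices for the lncRNA (nl x nl) and
#'   miRNA (nm x nm) sides; see [prepare_similarity()].
#' @param epsilon positive replacement for zero weights (default 1e-11).
#' @return list with elements `A_l`, `A_m` (strictly positive nl x nm
#'   matrices) and `epsilon`.
#' @export
weighted_networks <- function(network, LS, MS, epsilon = 1e-11) {
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (!is_prepared(LS) || !is_prepared(MS))
    stop("similarities must be prepared (see prepare_similarity)")
  A <- network$A
  if (nrow(LS) != nrow(A)) stop("LS dimension does not match nl")
  if (nrow(MS) != ncol(A)) stop("MS dimension does not match nm")
  A_l <- unclass(LS) %*% A
  A_m <- A %*% unclass(MS)
  A_l[A_l == 0] <- epsilon
  A_m[A_m == 0] <- epsilon
  list(A_l = A_l, A_m = A_m, epsilon = epsilon)
}

#' Forward resource shares
#'
#' Normalizes a strictly positive weighted bipartite matrix into the two
#' share matrices used by the diffusion: `C` divides each column by its sum
#' (columns of `C` sum to 1; row a of `C` is lncRNA a's share of every
#' miRNA's incoming resource) and `R` divides each row by its sum (rows of
#' `R` sum to 1; column b of `R` is miRNA b's share of every lncRNA's
#' outgoing resource).
#'
#' @param W strictly positive numeric matrix (nl x nm).
#' @return list with matrices `C` and `R`.
#' @export
forward_resources <- function(W) {
  if (any(W <= 0)) stop("weighted matrix must be strictly positive")
  list(C = sweep(W, 2L, colSums(W), "/"),
       R = W / rowSums(W))
}

#' Two-way diffusion scores
#'
#' For each weighted network W in `{A_l, A_m}`, with `C`, `R` from
#' [forward_resources()], resource flows forward from one side of the
#' bipartite graph and backward to the side it started from, landing on the
#' observed adjacency:
#' `SS_lnc(W) = (C %*% t(R)) %*% A` (start on the lncRNA side) and
#' `SS_mir(W) = A %*% (t(C) %*% R)` (start on the miRNA side).  The final
#' score matrix averages the four terms with equal weights.  Because the
#' columns of `C` and the rows of `R` each sum to one, every term conserves
#' the total mass of `A`, so `sum(SS)` equals the number of known edges.
#'
#' @param network an [lmi_network].
#' @param pair output of [weighted_networks()] built from `network`.
#' @return nl x nm numeric score matrix.
#' @export
two_way_diffusion <- function(network, pair) {
  A <- network$A
  if (!all(dim(pair$A_l) == dim(A)) || !all(dim(pair$A_m) == dim(A)))
    stop("weighted networks do not match the network shape")
  SS <- matrix(0, nrow(A), ncol(A), dimnames = dimnames(A))
  for (W in list(pair$A_l, pair$A_m)) {
    res <- forward_resources(W)
    SS <- SS + (res$C %*% t(res$R)) %*% A + A %*% (crossprod(res$C, res$R))
  }
  SS / 4
}

#' EPLMI interaction scores
#'
#' The full two-way diffusion pipeline: build the weighted networks from the
#' two similarity spaces, normalize them into resource shares, and diffuse
#' forward/backward from both sides ([weighted_networks()] then
#' [two_way_diffusion()]).  Known pairs are scored alongside unknown pairs;
#' no masking of training edges is applied.
#'
#' @inheritParams weighted_networks
#' @return nl x nm score matrix with a `provenance` attribute recording the
#'   method name and parameters.
#' @export
eplmi_scores <- function(network, LS, MS, epsilon = 1e-11) {
  pair <- weighted_networks(network, LS, MS, epsilon)
  SS <- two_way_diffusion(network, pair)
  attr(SS, "provenance") <- list(method = "eplmi", epsilon = epsilon,
                                 lnc_sim = attr(LS, "kind"),
                                 mir_sim = attr(MS, "kind"))
  SS
}
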