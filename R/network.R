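#' Bipartite lncRNA-miRNA interaction network
#'
#' Container for a binary bipartite adjacency matrix `A` (`nl x nm`) together
#' with the ordered identifier lists of its two node classes.  `A[i, j] = 1`
#' iff the interaction between the i-th lncRNA and the j-th miRNA is known.
#'
#' @param lnc_ids character vector of unique lncRNA identifiers (rows).
#' @param mir_ids character vector of unique miRNA identifiers (columns).
#' @param adjacency numeric 0/1 matrix of dimension
#'   `length(lnc_ids) x length(mir_ids)`.
#' @return An object of class `lmi_network` with elements `lnc_ids`,
#'   `mir_ids` and `A` (the adjacency matrix, with dimnames set).
#' @export
lmi_network <- function(lnc_ids, mir_ids, adjacency) {
  lnc_ids <- as.character(lnc_ids)
  mir_ids <- as.character(mir_ids)
  if (anyDuplicated(lnc_ids)) stop("duplicate lncRNA ids")
  if (anyDuplicated(mir_ids)) stop("duplicate miRNA ids")
  A <- as.matrix(adjacency)
  storage.mode(A) <- "double"
  if (nrow(A) != length(lnc_ids) || ncol(A) != length(mir_ids))
    stop("adjacency dimensions do not match id lists")
  if (!all(A %in% c(0, 1))) stop("adjacency entries must be 0 or 1")
  if (sum(A) < 1) stop("no interactions")
  dimnames(A) <- list(lnc_ids, mir_ids)
  structure(list(lnc_ids = lnc_ids, mir_ids = mir_ids, A = A),
            class = "lmi_network")
}

#' @export
print.lmi_network <- function(x, ...) {
  cat(sprintf(
    "lncRNA-miRNA interaction network: %d lncRNAs x %d miRNAs, %d edges (%d unidentified pairs)\n",
    length(x$lnc_ids), length(x$mir_ids), n_edges(x), n_unidentified(x)))
  invisible(x)
}

#' Edge and candidate counts
#'
#' `n_edges` counts known interactions; `n_unidentified` counts the pairs of
#' the full `nl x nm` grid with no known interaction, i.e.
#' `nl * nm - n_edges`.
#'
#' @param network an `lmi_network`.
#' @return integer count.
#' @export
n_edges <- function(network) as.integer(sum(network$A))

#' @rdname n_edges
#' @export
n_unidentified <- function(network) {
  as.integer(length(network$lnc_ids) * length(network$mir_ids)) - n_edges(network)
}

#' Known / unknown pair indices
#'
#' @param network an `lmi_network`.
#' @return two-column integer matrix of (row, col) indices into the adjacency.
#' @export
edge_indices <- function(network) which(network$A == 1, arr.ind = TRUE)

#' @rdname edge_indices
#' @export
nonedge_indices <- function(network) which(network$A == 0, arr.ind = TRUE)
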