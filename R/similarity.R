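new_similarity <- function(values, kind, prepared = FALSE) {
  stopifnot(nrow(values) == ncol(values))
  structure(values, kind = kind, prepared = prepared,
            class = c("lmi_similarity", class(matrix())))
}

#' @export
print.lmi_similarity <- function(x, ...) {
  cat(sprintf("%s similarity matrix over %d entities%s\n", attr(x, "kind"),
              nrow(x), if (isTRUE(attr(x, "prepared"))) " (prepared)" else ""))
  print(unclass(x)[seq_len(min(5L, nrow(x))), seq_len(min(5L, ncol(x))), drop = FALSE])
  invisible(x)
}

is_prepared <- function(S) isTRUE(attr(S, "prepared"))

#' Expression-profile similarity (Pearson correlation)
#'
#' Pairwise Pearson correlation of expression profiles across the N
#' conditions.  Pairs where either profile is constant have undefined
#' correlation and are assigned similarity 0 (with a message); the diagonal
#' is always 1.
#'
#' @param profiles numeric matrix entities x conditions (N >= 2), e.g. from
#'   [read_expression_profiles()].
#' @param quiet suppress the constant-profile message.
#' @return a square symmetric similarity matrix (kind `"expression"`).
#' @export
pearson_similarity <- function(profiles, quiet = FALSE) {
  profiles <- as.matrix(profiles)
  if (ncol(profiles) < 2L) stop("need N >= 2 conditions")
  S <- suppressWarnings(stats::cor(t(profiles)))
  const <- apply(profiles, 1L, function(r) max(r) == min(r))
  if (any(const)) {
    if (!quiet)
      message(sprintf("%d constant profiles assigned similarity 0: %s",
                      sum(const),
                      paste(rownames(profiles)[const], collapse = ", ")))
    S[const, ] <- 0
    S[, const] <- 0
  }
  S[is.na(S)] <- 0
  diag(S) <- 1
  S <- (S + t(S)) / 2  # remove floating-point asymmetry
  dimnames(S) <- list(rownames(profiles), rownames(profiles))
  new_similarity(S, "expression")
}

#' Annotation-set overlap similarity
#'
#' For entities a, b with term sets A, B the `product` normalization scores
#' `|A n B| / (|A| * |B|)` and the `geometric` normalization scores
#' `|A n B| / sqrt(|A| * |B|)` (Ochiai coefficient).  Under `product`,
#' identical sets of size n score only 1/n, which motivates the geometric
#' alternative; both are exposed.
#'
#' @param sets named list mapping entity id to a character vector of terms
#'   (see [read_annotation_sets()]); every set must be nonempty.
#' @param normalization `"product"` (default) or `"geometric"`.
#' @return a square symmetric similarity matrix (kind `"functional"`).
#' @export
set_overlap_similarity <- function(sets, normalization = c("product", "geometric")) {
  normalization <- match.arg(normalization)
  if (any(lengths(sets) == 0L)) stop("empty annotation set")
  ids <- names(sets)
  n <- length(ids)
  S <- matrix(0, n, n, dimnames = list(ids, ids))
  sizes <- lengths(sets)
  for (i in seq_len(n)) for (j in i:n) {
    ov <- length(intersect(sets[[i]], sets[[j]]))
    den <- if (normalization == "product") sizes[i] * sizes[j]
           else sqrt(sizes[i] * sizes[j])
    S[i, j] <- S[j, i] <- ov / den
  }
  new_similarity(S, "functional")
}

#' Global-alignment sequence similarity
#'
#' Needleman-Wunsch global alignment with affine gap penalties (match 2,
#' mismatch -1, gap open -0.5, gap extension -0.1 by default, i.e. a gap of
#' length L scores `open + (L - 1) * extend`).  With
#' `normalization = "self_geometric"` the raw score S(a,b) is normalized to
#' `S(a,b) / sqrt(S(a,a) * S(b,b))` and clipped to the unit interval; the
#' raw self-score is `2 * nchar(seq)`.
#'
#' @param seqs named character vector of nucleotide sequences over
#'   A/C/G/T/U/N (see [read_fasta()]); U is treated as T.
#' @param match,mismatch,gap_open,gap_extend alignment scores;
#'   `gap_open <= gap_extend <= 0` is required for affine semantics.
#' @param normalization `"self_geometric"` (default) or `"none"` (raw
#'   scores; such a matrix cannot be marked prepared without rescaling).
#' @return a square symmetric similarity matrix (kind `"sequence"`).
#' @export
sequence_similarity <- function(seqs, match = 2, mismatch = -1,
                                gap_open = -0.5, gap_extend = -0.1,
                                normalization = c("self_geometric", "none")) {
  normalization <- match.arg(normalization)
  if (length(seqs) < 1L) stop("need at least one sequence")
  if (any(!nzchar(seqs))) stop("empty sequence")
  if (!(gap_open <= gap_extend && gap_extend <= 0))
    stop("need gap_open <= gap_extend <= 0 for affine gap semantics")
  seqs <- chartr("u", "T", chartr("U", "T", toupper(seqs)))
  ids <- names(seqs)
  alpha <- sort(unique(strsplit(paste(seqs, collapse = ""), "")[[1L]]))
  sub <- matrix(mismatch, length(alpha), length(alpha),
                dimnames = list(alpha, alpha))
  diag(sub) <- match
  n <- length(seqs)
  S <- matrix(0, n, n, dimnames = list(ids, ids))
  # Biostrings charges gapOpening + L * gapExtension for a gap of length L;
  # the stated convention charges open + (L - 1) * extend.
  go <- -(gap_open - gap_extend)
  ge <- -gap_extend
  for (i in seq_len(n)) {
    S[i, i] <- match * nchar(seqs[[i]])
    if (i < n) {
      sc <- Biostrings::score(Biostrings::pairwiseAlignment(
        rep(seqs[[i]], n - i), seqs[(i + 1):n], type = "global",
        substitutionMatrix = sub, gapOpening = go, gapExtension = ge,
        scoreOnly = FALSE))
      S[i, (i + 1):n] <- S[(i + 1):n, i] <- sc
    }
  }
  if (normalization == "self_geometric") {
    d <- sqrt(diag(S))
    S <- S / outer(d, d)
    S[S < 0] <- 0
    S[S > 1] <- 1
    diag(S) <- 1
  }
  new_similarity(S, "sequence")
}

#' Prepare a similarity matrix for diffusion
#'
#' Diffusion distributes nonnegative resource shares, so negative
#' similarities (possible under Pearson correlation) are clipped to 0, the
#' diagonal is overwritten with the self-similarity, and symmetry is
#' re-asserted.
#'
#' @param S a similarity matrix.
#' @param clip_negative clip negative entries to 0 (default `TRUE`).
#' @param self_similarity value written on the diagonal (default 1).
#' @param tol symmetry tolerance; larger asymmetry is an error.
#' @return the prepared similarity matrix (`prepared` flag set).
#' @export
prepare_similarity <- function(S, clip_negative = TRUE, self_similarity = 1,
                               tol = 1e-9) {
  kind <- attr(S, "kind") %||% "custom"
  M <- unclass(S)
  attr(M, "kind") <- attr(M, "prepared") <- NULL
  if (nrow(M) != ncol(M)) stop("similarity matrix must be square")
  if (max(abs(M - t(M))) > tol) stop("similarity matrix is asymmetric")
  if (clip_negative) M[M < 0] <- 0
  diag(M) <- self_similarity
  M <- (M + t(M)) / 2
  if (any(!is.finite(M))) stop("non-finite similarity values")
  new_similarity(M, kind, prepared = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
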