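#' @importFrom utils read.table write.table
NULL

# Detect the field delimiter of a delimited text file: tab wins if the first
# non-empty line contains one, otherwise comma.
detect_delim <- function(path) {
  first <- readLines(path, n = 50L, warn = FALSE)
  first <- first[nzchar(trimws(first))]
  if (length(first) == 0L) stop("no interactions: file '", path, "' is empty")
  if (grepl("\t", first[[1L]])) "\t" else ","
}

#' Read a two-column interaction table
#'
#' Reads a delimited text file whose rows are `(lncRNA id, miRNA id)` pairs,
#' collapses duplicated pairs to a single edge, and assembles the bipartite
#' adjacency matrix.  Identifier order on both sides is first-appearance
#' order in the file.
#'
#' @param path path to a TSV/CSV file with at least two columns.
#' @param delim field delimiter; `NULL` (default) auto-detects tab vs comma.
#' @param header `"auto"` (default) treats the first row as a header when
#'   neither of its tokens reappears in the corresponding data column;
#'   `TRUE`/`FALSE` force the choice.
#' @param quiet suppress the row/edge count message.
#' @return an [lmi_network].
#' @export
read_interaction_table <- function(path, delim = NULL, header = "auto",
                                   quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delim)) delim <- detect_delim(path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no interactions: file '", path, "' is empty")
  parts <- strsplit(lines, delim, fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    p <- p[nzchar(p)]
    if (length(p) < 2L)
      stop("malformed row at line ", i, ": fewer than 2 non-empty columns")
    parts[[i]] <- p[1:2]
  }
  tab <- do.call(rbind, parts)
  if (identical(header, "auto")) {
    header <- nrow(tab) > 1L &&
      !(tab[1L, 1L] %in% tab[-1L, 1L]) && !(tab[1L, 2L] %in% tab[-1L, 2L])
  }
  if (isTRUE(header)) {
    if (nrow(tab) < 2L) stop("no interactions: header only")
    tab <- tab[-1L, , drop = FALSE]
  }
  n_raw <- nrow(tab)
  dup <- duplicated(paste(tab[, 1L], tab[, 2L], sep = "\r"))
  tab <- tab[!dup, , drop = FALSE]
  lnc_ids <- unique(tab[, 1L])
  mir_ids <- unique(tab[, 2L])
  A <- matrix(0, length(lnc_ids), length(mir_ids))
  A[cbind(match(tab[, 1L], lnc_ids), match(tab[, 2L], mir_ids))] <- 1
  if (!quiet)
    message(sprintf("read %d rows, %d distinct interactions (%d lncRNAs, %d miRNAs)",
                    n_raw, nrow(tab), length(lnc_ids), length(mir_ids)))
  lmi_network(lnc_ids, mir_ids, A)
}

#' Read an expression-profile table
#'
#' First column: entity identifier; header row: condition labels; remaining
#' cells: numeric expression levels.  Rows containing any missing or
#' non-numeric value are dropped (with a message); duplicated entity ids are
#' an error.
#'
#' @inheritParams read_interaction_table
#' @return numeric matrix (entities x conditions) with entity ids as
#'   rownames and condition labels as colnames.
#' @export
read_expression_profiles <- function(path, delim = NULL, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delim)) delim <- detect_delim(path)
  df <- read.table(path, sep = delim, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character",
                   comment.char = "", quote = "\"")
  if (ncol(df) < 3L) stop("expression table needs >= 2 conditions")
  ids <- trimws(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate entity id: ",
                               ids[duplicated(ids)][1L])
  vals <- suppressWarnings(
    vapply(df[-1L], function(col) as.numeric(col), numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(ids, colnames(df)[-1L]))
  ok <- apply(vals, 1L, function(r) all(is.finite(r)))
  if (!quiet && any(!ok))
    message(sprintf("dropped %d entities with missing/non-numeric values: %s",
                    sum(!ok), paste(ids[!ok], collapse = ", ")))
  vals <- vals[ok, , drop = FALSE]
  if (nrow(vals) == 0L) stop("no complete expression profiles in ", path)
  vals
}

#' Read annotation sets
#'
#' Each row: `entity<TAB>term1,term2,...`.  Terms are deduplicated per
#' entity; repeated rows for an entity are unioned; rows with an empty term
#' list are skipped with a warning.
#'
#' @param path path to the annotation file.
#' @return named list mapping entity id to a character vector of terms.
#' @export
read_annotation_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    p <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    id <- trimws(p[1L])
    terms <- if (length(p) >= 2L) trimws(strsplit(p[2L], ",", fixed = TRUE)[[1L]]) else character(0)
    terms <- terms[nzchar(terms)]
    if (!nzchar(id) || length(terms) == 0L) {
      warning("skipping line ", i, ": empty entity or term list")
      next
    }
    sets[[id]] <- unique(c(sets[[id]], terms))
  }
  sets
}

#' Read sequences from FASTA
#'
#' The identifier is the header token up to the first whitespace; sequences
#' are upper-cased and may use U or T.
#'
#' @param path path to an (uncompressed) FASTA file.
#' @return named character vector of nucleotide sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) stop("duplicate sequence id: ",
                               ids[duplicated(ids)][1L])
  if (any(!nzchar(seqs))) stop("empty sequence record in ", path)
  names(seqs) <- ids
  seqs
}

#' Restrict a network to entities with available features
#'
#' Drops entities absent from the supplied keep-lists (e.g. entities without
#' an expression profile), removes their edges, and then drops entities left
#' without any edge.
#'
#' @param network an [lmi_network].
#' @param lnc_keep,mir_keep character vectors of ids to retain on each side;
#'   `NULL` keeps every entity on that side.
#' @param quiet suppress the dropped-count message.
#' @return the restricted [lmi_network].
#' @export
align_entities <- function(network, lnc_keep = NULL, mir_keep = NULL,
                           quiet = FALSE) {
  li <- if (is.null(lnc_keep)) rep(TRUE, length(network$lnc_ids))
        else network$lnc_ids %in% lnc_keep
  mi <- if (is.null(mir_keep)) rep(TRUE, length(network$mir_ids))
        else network$mir_ids %in% mir_keep
  A <- network$A[li, mi, drop = FALSE]
  if (sum(A) == 0) stop("restriction leaves zero edges")
  keep_l <- rowSums(A) > 0
  keep_m <- colSums(A) > 0
  A <- A[keep_l, keep_m, drop = FALSE]
  if (!quiet)
    message(sprintf("align_entities: dropped %d lncRNAs, %d miRNAs",
                    length(network$lnc_ids) - nrow(A),
                    length(network$mir_ids) - ncol(A)))
  lmi_network(rownames(A), colnames(A), A)
}

#' Write ranked score tables
#'
#' Writes two TSV files: `<prefix>_candidates.tsv`, the per-miRNA ranked
#' candidate lncRNAs among unidentified pairs, and `<prefix>_known.tsv`, the
#' scores of all known pairs ranked globally.  Ties are broken by
#' lexicographic lncRNA id, so output is deterministic.
#'
#' @param scores numeric score matrix shaped like `network$A`.
#' @param network the [lmi_network] the scores refer to.
#' @param prefix output path prefix.
#' @return invisibly, the two file paths written.
#' @export
write_score_table <- function(scores, network, prefix) {
  if (!all(dim(scores) == dim(network$A))) stop("score/network shape mismatch")
  fmt <- function(x) sprintf("%.12g", x)
  idx <- nonedge_indices(network)
  cand <- data.frame(lncRNA = network$lnc_ids[idx[, 1L]],
                     miRNA  = network$mir_ids[idx[, 2L]],
                     score  = scores[idx], stringsAsFactors = FALSE)
  cand <- cand[order(match(cand$miRNA, network$mir_ids),
                     -cand$score, cand$lncRNA), , drop = FALSE]
  cand$rank <- stats::ave(seq_len(nrow(cand)), cand$miRNA, FUN = seq_along)
  cand <- cand[, c("rank", "lncRNA", "miRNA", "score")]
  idx2 <- edge_indices(network)
  known <- data.frame(lncRNA = network$lnc_ids[idx2[, 1L]],
                      miRNA  = network$mir_ids[idx2[, 2L]],
                      score  = scores[idx2], stringsAsFactors = FALSE)
  known <- known[order(-known$score, known$lncRNA, known$miRNA), , drop = FALSE]
  known <- cbind(rank = seq_len(nrow(known)), known)
  paths <- paste0(prefix, c("_candidates.tsv", "_known.tsv"))
  for (p in seq_along(paths)) {
    d <- list(cand, known)[[p]]
    d$score <- fmt(d$score)
    write.table(d, paths[[p]], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
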