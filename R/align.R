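## Pairwise and progressive multiple alignment over the 12-state alphabet.

#' Construct a sequence-structure alignment
#'
#' Equal-length gapped rows of encoded states.  Row values are state indices
#' 0..11, `-1` for a gap, `-2` for a masked (missing) site.
#'
#' @param ids Character vector of taxon identifiers (unique).
#' @param rows Integer matrix, one row per taxon.
#' @return Object of class `ss_alignment`: list with `ids`, `rows`
#'   (dimnames set to ids) and column count `L`.
#' @export
ss_alignment <- function(ids, rows) {
  rows <- as.matrix(rows)
  storage.mode(rows) <- "integer"
  if (length(ids) != nrow(rows)) stop("ids and rows disagree in length")
  if (anyDuplicated(ids)) stop("duplicate taxon id in alignment")
  if (any(rows < MISSING_STATE | rows > 11L, na.rm = TRUE))
    stop("invalid state code in alignment rows")
  if (ncol(rows) > 0L && any(colSums(rows != GAP_STATE) == 0L))
    stop("alignment contains an all-gap column")
  rownames(rows) <- ids
  structure(list(ids = as.character(ids), rows = rows, L = ncol(rows)),
            class = "ss_alignment")
}

#' @export
print.ss_alignment <- function(x, ...) {
  cat(sprintf("<ss_alignment> %d rows x %d columns\n", length(x$ids), x$L))
  invisible(x)
}

## Column-score matrix between two state vectors; gap/missing rows score 0.
.pair_score_matrix <- function(sa, sb, scores) {
  S <- matrix(0, length(sa), length(sb))
  va <- sa >= 0L; vb <- sb >= 0L
  if (any(va) && any(vb))
    S[va, vb] <- scores[sa[va] + 1L, sb[vb] + 1L]
  S
}

## Fraction of mismatching states among columns where both rows carry a
## real (non-gap, non-missing) state; NA when no such column exists.
.p_distance <- function(ra, rb) {
  use <- ra >= 0L & rb >= 0L
  if (!any(use)) return(NA_real_)
  mean(ra[use] != rb[use])
}

#' Globally align two encoded sequences
#'
#' Gotoh three-state dynamic programming with affine gaps over the 12-state
#' alphabet: a gap run of length k costs `gap_open + (k-1) * gap_extend`,
#' terminal gaps are penalized like internal ones, and ties are broken
#' deterministically (diagonal, then gap in `b`, then gap in `a`).
#'
#' @param a,b `ss_encoded` objects (see [encode_record()]).
#' @param m An `ss_scoring` matrix (default [default_scoring_matrix()]).
#' @return List with `alignment` (a two-row [ss_alignment()]) and `score`
#'   (the optimal global score).
#' @export
align_pair <- function(a, b, m = default_scoring_matrix()) {
  S <- .pair_score_matrix(a$states, b$states, m$scores)
  res <- .gotoh_align(S, m$gap_open, m$gap_extend)
  ra <- ifelse(res$a_idx == 0L, GAP_STATE, a$states[pmax(res$a_idx, 1L)])
  rb <- ifelse(res$b_idx == 0L, GAP_STATE, b$states[pmax(res$b_idx, 1L)])
  list(alignment = ss_alignment(c(a$id, b$id), rbind(ra, rb)),
       score = res$score)
}

## Internal profile block used by progressive alignment: rows of already
## aligned member sequences ("once a gap, always a gap").
.block_counts <- function(rows) {
  L <- ncol(rows)
  C <- matrix(0, 12, L)
  for (i in seq_len(nrow(rows))) {
    v <- rows[i, ]
    ok <- which(v >= 0L)
    if (length(ok))
      C[cbind(v[ok] + 1L, ok)] <- C[cbind(v[ok] + 1L, ok)] + 1
  }
  C
}

.merge_blocks <- function(A, B, m) {
  Ca <- .block_counts(A$rows); Cb <- .block_counts(B$rows)
  S <- crossprod(Ca, m$scores %*% Cb) / (nrow(A$rows) * nrow(B$rows))
  res <- .gotoh_align(S, m$gap_open, m$gap_extend)
  take <- function(rows, idx) {
    out <- matrix(GAP_STATE, nrow(rows), length(idx))
    nz <- idx > 0L
    out[, nz] <- rows[, idx[nz], drop = FALSE]
    out
  }
  list(ids = c(A$ids, B$ids),
       rows = rbind(take(A$rows, res$a_idx), take(B$rows, res$b_idx)))
}

#' Progressive multiple sequence-structure alignment
#'
#' Builds a guide tree by Neighbor-Joining on pairwise p-distances (fraction
#' of mismatched non-gap aligned states in the [align_pair()] alignment),
#' then aligns profiles up the guide tree.  Profile-profile column scores are
#' the arithmetic mean of all residue-pair scores between the two columns,
#' with gaps contributing 0, using the same affine gap scheme; gaps once
#' introduced are never removed.  Output row order equals input order, and
#' de-gapping any output row recovers its input exactly (asserted).
#'
#' @param encs List of `ss_encoded` objects (>= 2, unique ids).
#' @param m An `ss_scoring` matrix.
#' @return An [ss_alignment()].
#' @export
align_msa <- function(encs, m = default_scoring_matrix()) {
  n <- length(encs)
  if (n < 2L) stop("need at least 2 sequences to align")
  ids <- vapply(encs, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate sequence id")
  if (n == 2L) {
    aln <- align_pair(encs[[1]], encs[[2]], m)$alignment
    return(aln)
  }
  ## guide distances from pairwise alignments
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    pa <- align_pair(encs[[i]], encs[[j]], m)
    p <- .p_distance(pa$alignment$rows[1, ], pa$alignment$rows[2, ])
    if (is.na(p)) p <- 0.75
    D[i, j] <- D[j, i] <- p
  }
  guide <- neighbor_joining(ss_dist(ids, D))
  guide <- ape::root(guide, outgroup = ids[1], resolve.root = TRUE)
  ## postorder merge of profile blocks
  blocks <- lapply(encs, function(e)
    list(ids = e$id, rows = matrix(e$states, nrow = 1)))
  names(blocks) <- ids
  merge_node <- function(node) {
    kids <- guide$edge[guide$edge[, 1] == node, 2]
    sub <- lapply(kids, function(k) {
      if (k <= length(guide$tip.label)) blocks[[guide$tip.label[k]]]
      else merge_node(k)
    })
    out <- sub[[1]]
    for (k in seq_along(sub)[-1]) out <- .merge_blocks(out, sub[[k]], m)
    out
  }
  res <- merge_node(length(guide$tip.label) + 1L)
  rows <- res$rows[match(ids, res$ids), , drop = FALSE]
  aln <- ss_alignment(ids, rows)
  ## invariant: de-gapping each row recovers its input
  for (i in seq_len(n)) {
    v <- aln$rows[i, ]
    stopifnot(identical(as.integer(v[v != GAP_STATE]), encs[[i]]$states))
  }
  aln
}

#' Write an alignment to file
#'
#' Two formats: `write_alignment_fasta()` writes one character per state
#' (letters `A`..`L` in canonical state order, `-` for gaps, `?` for missing
#' sites); `write_alignment_split()` writes the gapped nucleotide rows as
#' FASTA plus a parallel gapped dot-bracket file.
#'
#' @param aln An [ss_alignment()].
#' @param path Output path (for the split form, the dot-bracket file gets
#'   extension `.struct` appended to `path_struct` if given).
#' @export
write_alignment_fasta <- function(aln, path) {
  lines <- character(0)
  for (i in seq_along(aln$ids)) {
    v <- aln$rows[i, ]
    ch <- rep("?", length(v))
    ch[v == GAP_STATE] <- "-"
    ok <- v >= 0L
    ch[ok] <- ALPHA12[v[ok] + 1L]
    lines <- c(lines, paste0(">", aln$ids[i]), paste(ch, collapse = ""))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_alignment_fasta
#' @param path_seq,path_struct Paths for the gapped nucleotide FASTA and the
#'   gapped dot-bracket file.
#' @export
write_alignment_split <- function(aln, path_seq, path_struct) {
  seq_lines <- character(0); str_lines <- character(0)
  for (i in seq_along(aln$ids)) {
    v <- aln$rows[i, ]
    nt <- rep("-", length(v)); st <- rep("-", length(v))
    nt[v == MISSING_STATE] <- "N"; st[v == MISSING_STATE] <- "."
    ok <- v >= 0L
    nt[ok] <- NT_CHARS[v[ok] %/% 3L + 1L]
    st[ok] <- STRUCT_CHARS[v[ok] %% 3L + 1L]
    seq_lines <- c(seq_lines, paste0(">", aln$ids[i]), paste(nt, collapse = ""))
    str_lines <- c(str_lines, paste0(">", aln$ids[i]), paste(st, collapse = ""))
  }
  writeLines(seq_lines, path_seq)
  writeLines(str_lines, path_struct)
  invisible(path_seq)
}
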