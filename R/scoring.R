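## 12x12 sequence-structure scoring matrices for alignment.

new_scoring <- function(scores, gap_open, gap_extend) {
  scores <- as.matrix(scores)
  if (!all(dim(scores) == c(12L, 12L)))
    stop(sprintf("scoring matrix must be 12x12, got %dx%d",
                 nrow(scores), ncol(scores)))
  if (max(abs(scores - t(scores))) > 1e-9) {
    idx <- which(abs(scores - t(scores)) > 1e-9, arr.ind = TRUE)[1, ]
    stop(sprintf("scoring matrix asymmetric at cell (%s, %s)",
                 STATE_LABELS[idx[1]], STATE_LABELS[idx[2]]))
  }
  if (any(!is.finite(scores))) stop("scoring matrix entries must be finite")
  if (!(gap_open <= gap_extend && gap_extend < 0))
    stop("gap penalties must satisfy gap_open <= gap_extend < 0")
  dimnames(scores) <- list(STATE_LABELS, STATE_LABELS)
  structure(list(scores = scores, gap_open = gap_open, gap_extend = gap_extend),
            class = "ss_scoring")
}

#' @export
print.ss_scoring <- function(x, ...) {
  cat("<ss_scoring> 12x12 sequence-structure scoring matrix\n")
  cat(sprintf("  gap_open %.4g, gap_extend %.4g\n", x$gap_open, x$gap_extend))
  print(round(x$scores[1:4, 1:4], 2))
  cat("  ...\n")
  invisible(x)
}

#' Build the default composite sequence-structure scoring matrix
#'
#' The score of aligning joint states (a, x) and (b, y) is the weighted sum
#' of a nucleotide term and a structural term:
#' `w_seq * S_nt(a, b) + w_str * S_st(x, y)` with `S_nt` = +2 match / -1
#' mismatch and `S_st` = +2 identical context, -2 unpaired vs paired, -1
#' between the two paired contexts `(` and `)`.  This composite is the
#' package's stand-in for a published ITS2 sequence-structure matrix, whose
#' numeric entries are not publicly tabulated; user-supplied matrices via
#' [read_scoring_matrix()] are first-class.
#'
#' @param w_seq,w_str Non-negative weights of the two terms (default 1 each;
#'   they must not both be zero).
#' @param gap_open,gap_extend Affine gap penalties (first gap position costs
#'   `gap_open`, each further position `gap_extend`).
#' @return An `ss_scoring` object.
#' @examples
#' m <- default_scoring_matrix()
#' m$scores["A.", "A."]  # 4
#' m$scores["A(", "A)"]  # 1
#' @export
default_scoring_matrix <- function(w_seq = 1, w_str = 1,
                                   gap_open = -8, gap_extend = -2) {
  if (w_seq < 0 || w_str < 0) stop("weights must be non-negative")
  if (w_seq == 0 && w_str == 0) stop("weights must not both be zero")
  s_nt <- matrix(-1, 4, 4); diag(s_nt) <- 2
  s_st <- matrix(c( 2, -2, -2,
                   -2,  2, -1,
                   -2, -1,  2), 3, 3, byrow = TRUE)
  nt_of <- rep(0:3, each = 3) + 1L
  st_of <- rep(0:2, times = 4) + 1L
  scores <- w_seq * s_nt[nt_of, nt_of] + w_str * s_st[st_of, st_of]
  new_scoring(scores, gap_open, gap_extend)
}

#' Estimate a log-odds scoring matrix from reference alignments
#'
#' Counts all aligned residue pairs across all columns of the reference
#' alignments (gaps and missing sites skipped), symmetrizes the count table,
#' normalizes to pair frequencies, mixes in the pseudocount as uniform prior
#' mass (`p = (f + pseudocount/144) / (1 + pseudocount)`), and converts to
#' half-bit log-odds: `score[i, j] = 2 * log2(p_ij / (q_i * q_j))` rounded
#' to 2 decimals, with `q` the marginal background.  Expressing the
#' pseudocount on the frequency scale makes the estimate invariant to
#' duplicating the entire reference set.  Gap penalties are passed through
#' from the defaults.
#'
#' @param reference List of [ss_alignment][align_msa()] objects (each with at
#'   least 2 rows).
#' @param pseudocount Positive total prior mass spread uniformly over the
#'   144 cells.
#' @param gap_open,gap_extend Gap penalties for the returned matrix.
#' @return An `ss_scoring` object.
#' @export
estimate_logodds_matrix <- function(reference, pseudocount = 1,
                                    gap_open = -8, gap_extend = -2) {
  if (inherits(reference, "ss_alignment")) reference <- list(reference)
  if (!length(reference)) stop("need at least one reference alignment")
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be positive")
  counts <- matrix(0, 12, 12)
  for (aln in reference) {
    rows <- aln$rows
    if (nrow(rows) < 2L) stop("reference alignment needs >= 2 rows")
    n <- nrow(rows)
    for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
      ra <- rows[a, ]; rb <- rows[b, ]
      use <- ra >= 0L & rb >= 0L
      if (!any(use)) next
      idx <- ra[use] * 12L + rb[use] + 1L
      counts <- counts + matrix(tabulate(idx, 144L), 12, 12, byrow = TRUE)
    }
  }
  if (sum(counts) == 0) stop("no countable aligned residue pairs in reference")
  counts <- (counts + t(counts)) / 2
  p <- (counts / sum(counts) + pseudocount / 144) / (1 + pseudocount)
  q <- rowSums(p)
  scores <- round(2 * log2(p / outer(q, q)), 2)
  new_scoring(scores, gap_open, gap_extend)
}

#' Read / write a scoring matrix file
#'
#' Plain-text format: a header row with the 12 state labels, then 12 rows of
#' `label value*12`, then `gap_open <value>` and `gap_extend <value>` lines.
#' `read_scoring_matrix(write_scoring_matrix(m, path))` reproduces `m`
#' exactly (decimal text round-trip).
#'
#' @param path File path.
#' @return `read_scoring_matrix`: an `ss_scoring` object.
#' @export
read_scoring_matrix <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  gl <- grep("^gap_(open|extend)\\b", lines)
  kv <- strsplit(lines[gl], "\\s+")
  gaps <- setNames(vapply(kv, function(x) as.numeric(x[2]), 0),
                   vapply(kv, `[`, "", 1))
  if (!all(c("gap_open", "gap_extend") %in% names(gaps)))
    stop("matrix file must contain gap_open and gap_extend lines")
  body <- lines[-gl]
  hdr <- strsplit(body[1], "\\s+")[[1]]
  if (!identical(hdr, STATE_LABELS))
    stop("matrix file header must list the 12 state labels in canonical order")
  rows <- strsplit(body[-1], "\\s+")
  if (length(rows) != 12L)
    stop(sprintf("matrix file must have 12 data rows, found %d", length(rows)))
  m <- matrix(NA_real_, 12, 12)
  for (i in seq_len(12)) {
    if (length(rows[[i]]) != 13L || rows[[i]][1] != STATE_LABELS[i])
      stop(sprintf("malformed matrix row %d", i))
    m[i, ] <- as.numeric(rows[[i]][-1])
  }
  new_scoring(m, gaps[["gap_open"]], gaps[["gap_extend"]])
}

#' @rdname read_scoring_matrix
#' @param m An `ss_scoring` object.
#' @export
write_scoring_matrix <- function(m, path) {
  fmt <- function(x) formatC(x, format = "g", digits = 17)
  lines <- c(paste(STATE_LABELS, collapse = "\t"),
             vapply(seq_len(12), function(i)
               paste(c(STATE_LABELS[i], fmt(m$scores[i, ])), collapse = "\t"),
               character(1)),
             paste("gap_open", fmt(m$gap_open)),
             paste("gap_extend", fmt(m$gap_extend)))
  writeLines(lines, path)
  invisible(path)
}
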