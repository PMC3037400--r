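## Simplified homology-based structure annotation: map a template's base
## pairs onto a query through a nucleotide-level global alignment.

ALLOWED_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

#' Transfer a secondary structure from a template to a query
#'
#' The query is globally aligned to the template sequence at nucleotide
#' level (match +2, mismatch -1, gap open -8, gap extend -2, same Gotoh
#' machinery as the 12-state aligner).  Each template base pair (i, j) is
#' kept iff both positions map to non-gap query positions whose nucleotides
#' can pair (Watson-Crick or G-U wobble); all other query positions become
#' unpaired.  The kept pairs are a subset of a nested set, so the predicted
#' structure is always balanced.  If the fraction of template pairs kept
#' falls below `min_transfer` the transfer is rejected with an error whose
#' condition carries the fraction (field `fraction`).
#'
#' @param query Nucleotide string (T is normalized to U) or a single named
#'   element of [read_fasta_seqs()] output.
#' @param template An [ss_record()] with a trusted structure.
#' @param min_transfer Minimum acceptable fraction of transferred pairs
#'   (default 0.75, the conventional helix-transfer threshold of
#'   homology-based ITS2 annotation).
#' @param query_id Identifier for the predicted record.
#' @return Object of class `ss_transfer`: list with `record` (the predicted
#'   [ss_record()]), `fraction_transferred`, `template_id`, and `alignment`
#'   (list of the two gapped character rows).
#' @export
transfer_structure <- function(query, template, min_transfer = 0.75,
                               query_id = "query") {
  if (!is.null(names(query)) && length(query) == 1L) {
    query_id <- names(query)
    query <- unname(query)
  }
  query <- chartr("tT", "uU", toupper(query))
  if (!nchar(query)) stop("empty query sequence")
  if (!all(strsplit(query, "")[[1]] %in% NT_CHARS))
    stop("query contains non-ACGU characters")
  qs <- match(strsplit(query, "")[[1]], NT_CHARS)
  ts <- match(strsplit(template$seq, "")[[1]], NT_CHARS)
  if (anyNA(ts)) stop("template sequence contains non-ACGU characters")
  s_nt <- matrix(-1, 4, 4); diag(s_nt) <- 2
  S <- s_nt[qs, ts, drop = FALSE]
  res <- .gotoh_align(S, -8, -2)
  ## template position -> query position (0 = gap)
  t2q <- integer(nchar(template$seq))
  t2q[res$b_idx[res$b_idx > 0L]] <- res$a_idx[res$b_idx > 0L]
  pairs <- validate_dotbracket(template$struct)
  struct <- rep(".", nchar(query))
  kept <- 0L
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      qi <- t2q[pairs[r, "i"] + 1L]
      qj <- t2q[pairs[r, "j"] + 1L]
      if (qi == 0L || qj == 0L) next
      duo <- paste0(NT_CHARS[qs[qi]], NT_CHARS[qs[qj]])
      if (!duo %in% ALLOWED_PAIRS) next
      struct[qi] <- "("; struct[qj] <- ")"
      kept <- kept + 1L
    }
    fraction <- kept / nrow(pairs)
  } else {
    fraction <- 1   # nothing to transfer counts as full transfer
  }
  if (fraction < min_transfer) {
    cond <- structure(class = c("ss_transfer_error", "error", "condition"),
                      list(message = sprintf(
                        "structure transfer below threshold: %.3f < %.3f",
                        fraction, min_transfer), call = sys.call(-1),
                        fraction = fraction))
    stop(cond)
  }
  gap_row <- function(chars, idx) {
    out <- rep("-", length(idx))
    out[idx > 0L] <- chars[idx[idx > 0L]]
    paste(out, collapse = "")
  }
  structure(list(
    record = ss_record(query_id, query, paste(struct, collapse = "")),
    fraction_transferred = fraction,
    template_id = template$id,
    alignment = list(query = gap_row(strsplit(query, "")[[1]], res$a_idx),
                     template = gap_row(strsplit(template$seq, "")[[1]],
                                        res$b_idx))),
    class = "ss_transfer")
}

#' @export
print.ss_transfer <- function(x, ...) {
  cat(sprintf("<ss_transfer> template '%s', %.1f%% of pairs transferred\n",
              x$template_id, 100 * x$fraction_transferred))
  print(x$record)
  invisible(x)
}

#' Write a structure-transfer report as TSV
#'
#' @param results List of `ss_transfer` objects.
#' @param path Output path.
#' @export
write_transfer_report <- function(results, path) {
  df <- data.frame(
    query = vapply(results, function(r) r$record$id, ""),
    template = vapply(results, function(r) r$template_id, ""),
    fraction_transferred = vapply(results, function(r) r$fraction_transferred, 0),
    structure = vapply(results, function(r) r$record$struct, ""))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
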