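## Vienna-style sequence-structure records and the 12-state encoding.

#' Create a sequence-structure record
#'
#' A record pairs one taxon's nucleotide sequence with a same-length
#' dot-bracket secondary structure.  On construction the sequence is
#' case-folded and DNA-style `T` is normalized to `U` (ITS2 is an rRNA
#' transcript; one alphabet is used internally).
#'
#' @param id Non-empty taxon identifier.
#' @param seq Nucleotide string; `T`/`t` are converted to `U`.
#' @param struct Dot-bracket string over `.`, `(`, `)`; must be balanced and
#'   the same length as `seq`.
#' @param validate If `FALSE`, skip the bracket-balance check (used by the
#'   simulator's free mode, which can produce unbalanced decoded structures);
#'   the record is then flagged with attribute `unbalanced`.
#' @return An object of class `ss_record`: a list with elements `id`, `seq`,
#'   `struct`.
#' @seealso [read_vienna()], [encode_record()]
#' @export
ss_record <- function(id, seq, struct, validate = TRUE) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("record id must be a non-empty string")
  seq <- chartr("tT", "uU", toupper(seq))
  seq <- toupper(seq)
  if (nchar(seq) != nchar(struct))
    stop(sprintf("record '%s': sequence length (%d) != structure length (%d)",
                 id, nchar(seq), nchar(struct)))
  bad <- setdiff(strsplit(struct, "")[[1]], STRUCT_CHARS)
  if (length(bad))
    stop(sprintf("record '%s': invalid structure character '%s'", id, bad[1]))
  unbalanced <- FALSE
  if (nchar(struct)) {
    ok <- tryCatch({ validate_dotbracket(struct); TRUE },
                   error = function(e) FALSE)
    if (!ok) {
      if (validate)
        stop(sprintf("record '%s': unbalanced dot-bracket structure", id))
      unbalanced <- TRUE
    }
  }
  r <- structure(list(id = id, seq = seq, struct = struct),
                 class = "ss_record")
  if (unbalanced) attr(r, "unbalanced") <- TRUE
  r
}

#' @export
print.ss_record <- function(x, ...) {
  cat(sprintf("<ss_record> %s (%d nt)\n", x$id, nchar(x$seq)))
  cat(" ", x$seq, "\n ", x$struct, "\n", sep = "")
  invisible(x)
}

#' Validate a dot-bracket string and extract its base pairs
#'
#' Checks that every `(` is closed by a later `)` with proper nesting and
#' returns the implied pair table.
#'
#' @param struct Dot-bracket string over `.`, `(`, `)`.
#' @return Integer matrix with columns `i`, `j` (0-based positions, `i < j`),
#'   one row per base pair; zero rows for a fully unpaired structure.
#' @examples
#' validate_dotbracket("(((...)))")
#' @export
validate_dotbracket <- function(struct) {
  chars <- strsplit(struct, "")[[1]]
  bad <- which(!chars %in% STRUCT_CHARS)
  if (length(bad))
    stop(sprintf("invalid structure character '%s' at position %d",
                 chars[bad[1]], bad[1] - 1L))
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  acc <- list()
  for (k in seq_along(chars)) {
    if (chars[k] == "(") {
      stack <- c(stack, k)
    } else if (chars[k] == ")") {
      if (!length(stack))
        stop(sprintf("unmatched ')' at position %d", k - 1L))
      acc[[length(acc) + 1L]] <- c(stack[length(stack)] - 1L, k - 1L)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack))
    stop(sprintf("unmatched '(' at position %d", stack[1] - 1L))
  if (length(acc)) {
    pairs <- do.call(rbind, acc)
    dimnames(pairs) <- list(NULL, c("i", "j"))
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  }
  pairs
}

#' Ambiguity policy for non-ACGU nucleotides
#'
#' How IUPAC ambiguity codes (N, R, Y, ...) are handled when encoding:
#' `"mask_as_missing"` (default) replaces the site with a missing marker that
#' is ignored in counts and distances; `"drop_record"` rejects the whole
#' record with a diagnostic.  Characters that are not IUPAC nucleotide codes
#' are always a hard error.
#'
#' @param mode `"mask_as_missing"` or `"drop_record"`.
#' @return An object of class `ss_ambiguity_policy`.
#' @export
ambiguity_policy <- function(mode = c("mask_as_missing", "drop_record")) {
  mode <- match.arg(mode)
  structure(list(mode = mode), class = "ss_ambiguity_policy")
}

#' Read Vienna-style sequence-structure records
#'
#' Parses a plain-text file of records of the form `>id` / sequence line /
#' dot-bracket line, the format exported by the ITS2 Database.  `T` is
#' normalized to `U` and sequences are upper-cased; file order is preserved.
#' Records whose sequence and structure lengths differ, or whose brackets are
#' unbalanced (including partial structures), are rejected with a warning
#' naming the record; a duplicated id is a hard error.
#'
#' @param path Path to the record file.
#' @return List of [ss_record()] objects (class `ss_recordset`).
#' @examples
#' f <- system.file("extdata/example_synthetic.vienna", package = "ssphylo")
#' read_vienna(f)
#' @export
read_vienna <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(structure(list(), class = "ss_recordset"))
  hdr <- grep("^>", lines)
  if (!length(hdr) || hdr[1] != 1L)
    stop("malformed record file: does not start with a '>' header")
  recs <- list()
  ids <- character(0)
  bounds <- c(hdr, length(lines) + 1L)
  for (k in seq_along(hdr)) {
    block <- lines[bounds[k]:(bounds[k + 1L] - 1L)]
    id <- sub("^>\\s*", "", block[1])
    id <- trimws(sub("\\s.*$", "", id))
    if (length(block) != 3L) {
      warning(sprintf("record '%s' rejected: expected sequence + structure lines", id))
      next
    }
    if (id %in% ids) stop(sprintf("duplicate record id '%s'", id))
    r <- tryCatch(ss_record(id, trimws(block[2]), trimws(block[3])),
                  error = function(e) e)
    if (inherits(r, "error")) {
      warning(sprintf("record '%s' rejected: %s", id, conditionMessage(r)))
      next
    }
    ids <- c(ids, id)
    recs[[length(recs) + 1L]] <- r
  }
  structure(recs, class = "ss_recordset")
}

#' @export
print.ss_recordset <- function(x, ...) {
  cat(sprintf("<ss_recordset> %d records\n", length(x)))
  for (r in utils::head(x, 5)) cat(sprintf("  %s (%d nt)\n", r$id, nchar(r$seq)))
  if (length(x) > 5) cat(sprintf("  ... and %d more\n", length(x) - 5L))
  invisible(x)
}

#' Write Vienna-style sequence-structure records
#'
#' @param records List of [ss_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vienna <- function(records, path) {
  out <- unlist(lapply(records, function(r) c(paste0(">", r$id), r$seq, r$struct)))
  writeLines(out, path)
  invisible(path)
}

#' Read a plain FASTA file of nucleotide sequences
#'
#' Sequence-only input for the structure-transfer path.  Sequences are
#' upper-cased with `T` normalized to `U`.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta_seqs <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA headers found")
  ids <- trimws(sub("\\s.*$", "", sub("^>\\s*", "", lines[hdr])))
  bounds <- c(hdr, length(lines) + 1L)
  seqs <- vapply(seq_along(hdr), function(k) {
    paste(lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)], collapse = "")
  }, character(1))
  if (anyDuplicated(ids)) stop("duplicate FASTA id")
  setNames(chartr("tT", "uU", toupper(gsub("\\s", "", seqs))), ids)
}

#' Encode a record into the 12-state joint alphabet
#'
#' Maps each position of a sequence-structure record onto the joint state
#' `3 * nt_index + struct_index` with nucleotides ordered (A, C, G, U) and
#' structural contexts ordered (`.`, `(`, `)`).  IUPAC ambiguity codes are
#' handled per `policy`; any other character is an error.
#'
#' @param record An [ss_record()].
#' @param policy An [ambiguity_policy()]; default masks ambiguous sites as
#'   missing.
#' @return Object of class `ss_encoded`: list with `id` and integer vector
#'   `states` over 0..11 (missing sites are `-2`).
#' @examples
#' encode_record(ss_record("x", "GACU", "(..)"))$states  # 7 0 3 11
#' @export
encode_record <- function(record, policy = ambiguity_policy()) {
  chars <- strsplit(record$seq, "")[[1]]
  nt <- match(chars, NT_CHARS) - 1L
  ambig <- is.na(nt) & chars %in% IUPAC_AMBIG
  if (any(is.na(nt) & !ambig))
    stop(sprintf("record '%s': non-IUPAC character '%s'",
                 record$id, chars[which(is.na(nt) & !ambig)[1]]))
  if (any(ambig) && policy$mode == "drop_record")
    stop(sprintf("record '%s' rejected: IUPAC ambiguity code '%s' (policy drop_record)",
                 record$id, chars[which(ambig)[1]]))
  st <- match(strsplit(record$struct, "")[[1]], STRUCT_CHARS) - 1L
  states <- 3L * nt + st
  states[ambig] <- MISSING_STATE
  structure(list(id = record$id, states = as.integer(states)),
            class = "ss_encoded")
}

#' Decode a 12-state vector back to a sequence-structure record
#'
#' Inverse of [encode_record()].  Machine-generated state vectors can decode
#' to an unbalanced structure; that yields a warning flag (attribute
#' `unbalanced` on the record), not an error.  Missing states decode to `N`
#' with an unpaired context.
#'
#' @param enc An `ss_encoded` object.
#' @return An [ss_record()]; attribute `unbalanced` is `TRUE` when the
#'   decoded structure fails the bracket-balance check.
#' @export
decode_record <- function(enc) {
  states <- enc$states
  seq_chars <- character(length(states))
  struct_chars <- character(length(states))
  miss <- states == MISSING_STATE
  seq_chars[miss] <- "N"
  struct_chars[miss] <- "."
  ok <- !miss
  if (any(states[ok] < 0L | states[ok] > 11L))
    stop("invalid state index in encoded sequence")
  seq_chars[ok] <- NT_CHARS[states[ok] %/% 3L + 1L]
  struct_chars[ok] <- STRUCT_CHARS[states[ok] %% 3L + 1L]
  r <- ss_record(enc$id, paste(seq_chars, collapse = ""),
                 paste(struct_chars, collapse = ""), validate = FALSE)
  if (isTRUE(attr(r, "unbalanced")))
    warning(sprintf("record '%s': decoded structure is unbalanced", enc$id))
  r
}

#' Encode a set of records
#'
#' @param records List of [ss_record()]s.
#' @param policy An [ambiguity_policy()].  With mode `"drop_record"`,
#'   offending records are dropped with a warning rather than aborting the
#'   whole set.
#' @return List of `ss_encoded` objects.
#' @export
encode_records <- function(records, policy = ambiguity_policy()) {
  out <- list()
  for (r in records) {
    e <- tryCatch(encode_record(r, policy), error = function(err) err)
    if (inherits(e, "error")) {
      if (policy$mode == "drop_record" &&
          grepl("ambiguity code", conditionMessage(e))) {
        warning(conditionMessage(e))
        next
      }
      stop(e)
    }
    out[[length(out) + 1L]] <- e
  }
  out
}
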