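## Profiles (column state-frequency summaries of aligned groups) and
## Profile Neighbor-Joining.

#' Build a profile from alignment rows
#'
#' A profile summarizes a group of aligned sequences column-wise: for each
#' column, the fraction of members in each of the 12 states plus a gap
#' fraction (missing sites count towards the gap fraction, so the 13 numbers
#' sum to one).
#'
#' @param aln An [ss_alignment()].
#' @param name Profile name.
#' @param members Character vector of member taxon ids (>= 1, all in `aln`).
#' @return Object of class `ss_profile`: list with `name`, `members`, and
#'   `freq`, a 13 x L matrix (rows 1..12 the states, row 13 the gap fraction).
#' @export
profile_from_members <- function(aln, name, members) {
  idx <- match(members, aln$ids)
  if (anyNA(idx))
    stop(sprintf("unknown profile member '%s'", members[which(is.na(idx))[1]]))
  if (!length(members)) stop("profile needs at least one member")
  rows <- aln$rows[idx, , drop = FALSE]
  n <- nrow(rows)
  freq <- matrix(0, 13, ncol(rows))
  for (i in seq_len(n)) {
    v <- rows[i, ]
    ok <- which(v >= 0L)
    if (length(ok))
      freq[cbind(v[ok] + 1L, ok)] <- freq[cbind(v[ok] + 1L, ok)] + 1
    freq[13L, v < 0L] <- freq[13L, v < 0L] + 1
  }
  freq <- freq / n
  structure(list(name = name, members = as.character(members), freq = freq),
            class = "ss_profile")
}

#' @export
print.ss_profile <- function(x, ...) {
  cat(sprintf("<ss_profile> '%s': %d members, %d columns\n",
              x$name, length(x$members), ncol(x$freq)))
  invisible(x)
}

#' Build profiles from a profile definition
#'
#' Applies a named definition (profile name -> member ids) to an alignment.
#' Member lists must be disjoint and all ids known.  Taxa not covered by any
#' profile pass through as singleton pseudo-profiles, so the reduced entity
#' set has `#profiles + #non-members` elements (defined profiles first, then
#' non-members in alignment order).
#'
#' @param aln An [ss_alignment()].
#' @param defn Named list of member-id character vectors (see
#'   [read_profile_definition()]).
#' @return List with `profiles` (the defined profiles) and `entities` (the
#'   full reduced entity list of `ss_profile` objects).
#' @export
build_profiles <- function(aln, defn) {
  if (!length(defn) || is.null(names(defn)) || any(!nzchar(names(defn))))
    stop("profile definition must be a named list")
  all_members <- unlist(defn, use.names = FALSE)
  if (anyDuplicated(all_members))
    stop(sprintf("overlapping profile definitions: '%s' occurs twice",
                 all_members[duplicated(all_members)][1]))
  unknown <- setdiff(all_members, aln$ids)
  if (length(unknown)) stop(sprintf("unknown member id '%s'", unknown[1]))
  profiles <- lapply(names(defn), function(nm)
    profile_from_members(aln, nm, defn[[nm]]))
  rest <- setdiff(aln$ids, all_members)
  singles <- lapply(rest, function(id) profile_from_members(aln, id, id))
  list(profiles = profiles, entities = c(profiles, singles))
}

#' ML distance between two profiles
#'
#' Expected divergence counts are accumulated over columns where both
#' profiles have gap fraction at most 0.5:
#' `F_xy = sum_c f_p,x(c) * f_q,y(c)`, then the counts are handed to
#' [ml_distance()] (non-integer counts allowed).  For two singleton profiles
#' this reduces exactly to the sequence-pair ML distance.
#'
#' @param p,q `ss_profile` objects with equal column counts.
#' @param model A `gtr12` model.
#' @param t_max Saturation bound.
#' @return The ML distance `t_hat` (numeric scalar).
#' @export
profile_distance <- function(p, q, model = jc12_model(), t_max = 20) {
  if (ncol(p$freq) != ncol(q$freq)) stop("profiles differ in column count")
  use <- p$freq[13L, ] <= 0.5 & q$freq[13L, ] <= 0.5
  if (!any(use))
    stop(sprintf("no usable columns between profiles '%s' and '%s'",
                 p$name, q$name))
  F <- p$freq[1:12, use, drop = FALSE] %*% t(q$freq[1:12, use, drop = FALSE])
  ml_distance(list(F = F, N = sum(F)), model, t_max)$t_hat
}

## Entity labels for NJ tie-breaking: lexicographically smallest member.
.entity_labels <- function(entities)
  vapply(entities, function(e) sort(e$members)[1], "")

.profile_dist_matrix <- function(entities, model, t_max = 20, freqs = NULL) {
  n <- length(entities)
  labs <- .entity_labels(entities)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    p <- entities[[i]]; q <- entities[[j]]
    if (!is.null(freqs)) { p$freq <- freqs[[i]]; q$freq <- freqs[[j]] }
    D[i, j] <- D[j, i] <- profile_distance(p, q, model, t_max)
  }
  ss_dist(labs, D)
}

## Column bootstrap over entity frequency matrices; returns split counts
## keyed like tree_bipartitions(), or errors after too many degenerate draws.
.bootstrap_profiles <- function(entities, model, B, seed, t_max = 20) {
  L <- ncol(entities[[1]]$freq)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed %% .Machine$integer.max)
  counts <- new.env(parent = emptyenv())
  redraws <- 0L
  b <- 0L
  while (b < B) {
    cols <- sample.int(L, L, replace = TRUE)
    freqs <- lapply(entities, function(e) e$freq[, cols, drop = FALSE])
    d <- tryCatch(.profile_dist_matrix(entities, model, t_max, freqs = freqs),
                  error = function(e) NULL)
    if (is.null(d)) {
      redraws <- redraws + 1L
      if (redraws > 10L * B) stop("too many degenerate bootstrap replicates")
      next
    }
    tr <- neighbor_joining(d)
    for (k in names(tree_bipartitions(tr))) {
      cur <- if (is.null(counts[[k]])) 0L else counts[[k]]
      assign(k, cur + 1L, envir = counts)
    }
    b <- b + 1L
  }
  setNames(vapply(ls(counts), function(k) counts[[k]], 0L), ls(counts))
}

#' Profile Neighbor-Joining
#'
#' Iterative NJ with automatic profiling: (1) build the NJ tree of the
#' current entities and bootstrap it; (2) every maximal clade (canonical
#' split side) with support at or above `support_threshold` percent is
#' collapsed into a profile; (3) distances are recomputed between profiles;
#' the loop stops when no new profile forms, fewer than four entities
#' remain, or `max_iter` is reached.  The final tree is the NJ tree of the
#' remaining entities with each multi-member profile re-expanded by splicing
#' in the NJ subtree of its members (built from member-only distances on the
#' original alignment, midpoint-rooted) at the profile's leaf.
#'
#' With an unreachable threshold (> 100) or `max_iter = 0` the result is
#' byte-identical, as Newick, to plain [neighbor_joining()] on
#' [distance_matrix()].
#'
#' @param aln An [ss_alignment()] with at least 4 rows.
#' @param model A `gtr12` model.
#' @param support_threshold Percent support needed to freeze a clade into a
#'   profile (default 70, a conventionally "well-supported" level).
#' @param B Bootstrap replicates per iteration (default 100).
#' @param max_iter Maximum profiling iterations (default 10).
#' @param seed Integer seed (per-iteration streams are derived from it).
#' @param t_max Saturation bound for distances.
#' @return An unrooted `ape::phylo`.
#' @export
profile_neighbor_joining <- function(aln, model = jc12_model(),
                                     support_threshold = 70, B = 100,
                                     max_iter = 10, seed = 1, t_max = 20) {
  if (length(aln$ids) < 4L) stop("profile NJ needs at least 4 rows")
  entities <- lapply(aln$ids, function(id) profile_from_members(aln, id, id))
  iter <- 0L
  while (iter < max_iter && length(entities) >= 4L) {
    iter <- iter + 1L
    d <- .profile_dist_matrix(entities, model, t_max)
    tr <- neighbor_joining(d)
    counts <- .bootstrap_profiles(entities, model, B,
                                  (seed + iter) %% .Machine$integer.max, t_max)
    splits <- tree_bipartitions(tr)
    supp <- vapply(names(splits), function(k)
      100 * (if (k %in% names(counts)) counts[[k]] else 0L) / B, 0)
    good <- splits[supp >= support_threshold]
    if (!length(good)) break
    ## canonical sides form a laminar family; keep the maximal ones
    keep <- vapply(seq_along(good), function(i)
      !any(vapply(seq_along(good), function(j)
        i != j && all(good[[i]] %in% good[[j]]), TRUE)), TRUE)
    good <- good[keep]
    labs <- .entity_labels(entities)
    merged_any <- FALSE
    new_entities <- entities
    drop <- logical(length(entities))
    for (side in good) {
      hit <- which(labs %in% side)
      if (length(hit) < 2L) next
      members <- sort(unlist(lapply(entities[hit], `[[`, "members")))
      new_entities[[hit[1]]] <-
        profile_from_members(aln, paste0("profile_", sort(members)[1]), members)
      drop[hit[-1]] <- TRUE
      merged_any <- TRUE
    }
    if (!merged_any) break
    entities <- new_entities[!drop]
  }
  d <- .profile_dist_matrix(entities, model, t_max)
  tree <- neighbor_joining(d)
  ## re-expand multi-member profiles
  full_d <- NULL
  for (e in entities) {
    if (length(e$members) < 2L) next
    if (is.null(full_d)) full_d <- distance_matrix(aln, model, t_max)
    sub <- .member_subtree(full_d, e$members)
    tree <- .splice_at_tip(tree, sort(e$members)[1], sub)
  }
  tree
}

## Rooted subtree of a profile's members from the full distance matrix.
.member_subtree <- function(full_d, members) {
  members <- sort(members)
  idx <- match(members, full_d$labels)
  if (length(members) == 2L) {
    h <- full_d$D[idx[1], idx[2]] / 2
    return(ape::read.tree(text = sprintf("(%s:%s,%s:%s);",
                                         members[1], .fmt_len(h),
                                         members[2], .fmt_len(h))))
  }
  sub <- neighbor_joining(ss_dist(members, full_d$D[idx, idx, drop = FALSE]))
  phangorn::midpoint(sub)
}

## Replace the tip `label` of `tree` by the rooted subtree `sub`, keeping the
## tip's branch length as the stem of the spliced subtree.
.splice_at_tip <- function(tree, label, sub) {
  tip <- match(label, tree$tip.label)
  if (is.na(tip)) stop(sprintf("tip '%s' not found for splicing", label))
  ## bind.tree keeps the tip's edge (the profile stem) and grafts `sub` at
  ## its end; no root.edge so the stem length is preserved exactly
  sub$root.edge <- NULL
  ape::bind.tree(tree, sub, where = tip, position = 0)
}

#' Read / write a profile definition file
#'
#' One profile per line: `name<TAB>id1,id2,...` — the format a
#' cartoon-to-profile converter would emit.
#'
#' @param path File path.
#' @return `read_profile_definition`: named list of member-id vectors.
#' @export
read_profile_definition <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  if (any(lengths(parts) != 2L)) stop("profile definition lines must be 'name<TAB>ids'")
  nm <- vapply(parts, `[`, "", 1)
  if (anyDuplicated(nm)) stop("duplicate profile name")
  setNames(lapply(parts, function(p) strsplit(p[2], ",")[[1]]), nm)
}

#' @rdname read_profile_definition
#' @param defn Named list of member-id vectors.
#' @export
write_profile_definition <- function(defn, path) {
  writeLines(sprintf("%s\t%s", names(defn),
                     vapply(defn, paste, "", collapse = ",")), path)
  invisible(path)
}
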