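## Neighbor-Joining, bipartition support, bootstrap, outgroup rooting.
## Trees are ape "phylo" objects throughout; Newick is the wire format.

.fmt_len <- function(x) sprintf("%.12g", x)

#' Neighbor-Joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with selection criterion
#' `Q(i, j) = (n - 2) D_ij - sum_k D_ik - sum_k D_jk` and the standard
#' two-point branch-length formulas.  Deterministic tie-breaking: among pairs
#' minimizing Q, the pair whose (sorted) cluster labels are lexicographically
#' smallest is joined (a cluster is labelled by its lexicographically
#' smallest member leaf).  Negative branch lengths are clamped to zero with
#' the deficit left unredistributed.  The result is unrooted (trifurcating
#' basal node).
#'
#' @param d An [ss_dist()] object, or a symmetric labelled matrix.
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(d) {
  if (is.matrix(d)) d <- ss_dist(rownames(d), d)
  D <- d$D
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  if (any(is.na(D))) stop("NaN in distance matrix")
  labels <- d$labels            # tie-break labels (smallest member leaf)
  nwk <- labels                 # growing newick fragment per cluster
  while (n > 3L) {
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q == qmin, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    l1 <- pmin(labels[cand[, 1]], labels[cand[, 2]])
    l2 <- pmax(labels[cand[, 1]], labels[cand[, 2]])
    pick <- order(l1, l2)[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    bj <- D[i, j] - bi
    new_nwk <- sprintf("(%s:%s,%s:%s)", nwk[i], .fmt_len(max(bi, 0)),
                       nwk[j], .fmt_len(max(bj, 0)))
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    nwk <- c(nwk[keep], new_nwk)
    labels <- c(labels[keep], min(labels[c(i, j)]))
    n <- n - 1L
  }
  ## final three-cluster join: three-point formulas around a central node
  a <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  c3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 nwk[1], .fmt_len(max(a, 0)), nwk[2], .fmt_len(max(b, 0)),
                 nwk[3], .fmt_len(max(c3, 0)))
  ape::read.tree(text = txt)
}

#' Non-trivial bipartitions (splits) of a tree
#'
#' One split per internal edge, canonicalized as the leaf side that does
#' *not* contain the lexicographically smallest leaf label.  Splits are an
#' unrooted notion: they are invariant under re-rooting.
#'
#' @param tree An `ape::phylo`.
#' @return Named list of sorted character vectors; names are `|`-joined keys.
#' @export
tree_bipartitions <- function(tree) {
  tips <- tree$tip.label
  n <- length(tips)
  smallest <- sort(tips)[1]
  pp <- ape::prop.part(tree)
  out <- list()
  for (cl in pp) {
    side <- tips[cl]
    if (length(side) < 2L || length(side) > n - 2L) next
    if (smallest %in% side) side <- setdiff(tips, side)
    if (length(side) < 2L) next
    side <- sort(side)
    out[[paste(side, collapse = "|")]] <- side
  }
  out
}

## Distances between rows of a raw state matrix; returns NULL if some pair
## has no usable column (bootstrap replicates get redrawn on that).
.dist_from_rows <- function(rows, ids, model, t_max = 20) {
  n <- nrow(rows)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    use <- rows[i, ] >= 0L & rows[j, ] >= 0L
    if (!any(use)) return(NULL)
    idx <- rows[i, use] * 12L + rows[j, use] + 1L
    F <- matrix(tabulate(idx, 144L), 12, 12, byrow = TRUE)
    D[i, j] <- D[j, i] <- ml_distance(list(F = F, N = sum(F)), model, t_max)$t_hat
  }
  ss_dist(ids, D)
}

## Annotate internal nodes of `tree` with support percentages for their
## splits (integer labels, FigTree-compatible Newick dialect).
.annotate_support <- function(tree, support) {
  nnode <- tree$Nnode
  ntip <- length(tree$tip.label)
  labs <- rep("", nnode)
  for (nd in seq_len(nnode) + ntip) {
    cl <- ape::extract.clade(tree, nd)$tip.label
    side <- cl
    smallest <- sort(tree$tip.label)[1]
    if (smallest %in% side) side <- setdiff(tree$tip.label, side)
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(support))
      labs[nd - ntip] <- as.character(round(support[[key]]))
  }
  tree$node.label <- labs
  tree
}

#' Bootstrap support for a Neighbor-Joining tree
#'
#' Resamples alignment columns with replacement (B replicates, seeded
#' deterministic stream), rebuilds the ML distance matrix and NJ tree per
#' replicate, and reports for each split of the original-data NJ tree the
#' percentage of replicates containing it.  A replicate in which some pair
#' of rows shares no usable column is redrawn (at most `10 * B` redraws).
#'
#' @param aln An [ss_alignment()] with at least 4 rows.
#' @param model A `gtr12` model.
#' @param B Number of replicates (default 100).
#' @param seed Integer seed for the resampling stream.
#' @param t_max Saturation bound for distances.
#' @return List with `tree` (original NJ tree, internal nodes labelled with
#'   integer support percentages) and `support` (named vector, percent per
#'   split key).
#' @export
bootstrap_support <- function(aln, model = jc12_model(), B = 100, seed = 1,
                              t_max = 20) {
  if (length(aln$ids) < 4L) stop("bootstrap needs at least 4 rows")
  if (B < 1L) stop("B must be >= 1")
  d0 <- distance_matrix(aln, model, t_max)
  tree0 <- neighbor_joining(d0)
  res <- .bootstrap_rows(aln$rows, aln$ids, model, B, seed, t_max)
  splits0 <- tree_bipartitions(tree0)
  support <- setNames(vapply(names(splits0), function(k) {
    100 * sum(res$counts[k], na.rm = TRUE) / B
  }, 0), names(splits0))
  list(tree = .annotate_support(tree0, as.list(support)), support = support)
}

## Shared bootstrap engine over a raw row matrix; returns split counts.
.bootstrap_rows <- function(rows, ids, model, B, seed, t_max = 20) {
  L <- ncol(rows)
  counts <- new.env(parent = emptyenv())
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed %% .Machine$integer.max)
  redraws <- 0L
  b <- 0L
  while (b < B) {
    cols <- sample.int(L, L, replace = TRUE)
    d <- .dist_from_rows(rows[, cols, drop = FALSE], ids, model, t_max)
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
  cnt <- setNames(vapply(ls(counts), function(k) counts[[k]], 0L), ls(counts))
  list(counts = cnt, redraws = redraws)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    rm(".Random.seed", envir = globalenv())
}

#' Root a tree with an outgroup
#'
#' If the outgroup forms a clade in the unrooted tree, the root is placed at
#' the midpoint of the edge separating it from the ingroup.  Otherwise a
#' non-monophyly warning is emitted and the tree is rooted on the terminal
#' edge of the first outgroup taxon (input order).
#'
#' @param tree An `ape::phylo`.
#' @param outgroup Character vector of leaf labels (non-empty, proper subset
#'   of the leaves).
#' @return A rooted `ape::phylo` whose root has two children; the separating
#'   edge length is split in half across the root.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  tips <- tree$tip.label
  unknown <- setdiff(outgroup, tips)
  if (length(unknown))
    stop(sprintf("unknown outgroup id '%s'", unknown[1]))
  if (length(outgroup) == 0L) stop("empty outgroup")
  if (setequal(outgroup, tips)) stop("outgroup cannot contain all leaves")
  og <- outgroup
  mono <- length(og) == 1L || length(og) == length(tips) - 1L
  if (!mono) {
    smallest <- sort(tips)[1]
    side <- sort(og)
    if (smallest %in% side) side <- sort(setdiff(tips, og))
    mono <- paste(side, collapse = "|") %in% names(tree_bipartitions(tree))
  }
  if (!mono) {
    warning(sprintf("outgroup is not monophyletic; rooting on the edge of '%s'",
                    og[1]))
    og <- og[1]
  }
  rt <- ape::root(tree, outgroup = og, resolve.root = TRUE)
  ## split the separating edge evenly across the new root
  rootnode <- length(rt$tip.label) + 1L
  re <- which(rt$edge[, 1] == rootnode)
  if (length(re) == 2L) {
    tot <- sum(rt$edge.length[re])
    rt$edge.length[re] <- tot / 2
  }
  rt
}

#' Read / write Newick trees
#'
#' Thin wrappers over ape's Newick parser/serializer; branch lengths and
#' internal-node support labels survive a write-read-write round trip
#' byte-identically.
#'
#' @param path File path.
#' @return `read_newick`: an `ape::phylo`.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  ape::read.tree(path)
}

#' @rdname read_newick
#' @param tree An `ape::phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
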