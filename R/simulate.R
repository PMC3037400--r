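## Random trees and CTMC sequence-structure evolution under the 12-state
## model: the package's source of test data with known history.

#' Sample a random tree
#'
#' Topology by sequential random joins (each step joins a uniformly chosen
#' pair of clusters), then i.i.d. exponential branch lengths with the given
#' mean assigned to every edge of the unrooted tree.  Deterministic given the
#' seed; the caller's RNG state is left untouched.
#'
#' @param n_taxa Number of leaves (>= 2); labels are `t1..tn`.
#' @param mean_branch Mean of the exponential branch-length distribution
#'   (default 0.1 expected substitutions per site, a moderate ITS2-like
#'   divergence).
#' @param seed Integer seed.
#' @return An `ape::phylo`; unrooted (basal trifurcation) for `n_taxa >= 3`,
#'   a two-leaf cherry for `n_taxa == 2`.
#' @export
sample_tree <- function(n_taxa, mean_branch = 0.1, seed = 1) {
  if (n_taxa < 2L) stop("need at least 2 taxa")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed %% .Machine$integer.max)
  frags <- paste0("t", seq_len(n_taxa))
  while (length(frags) > 1L) {
    pair <- sort(sample.int(length(frags), 2L))
    frags <- c(frags[-pair],
               sprintf("(%s:1,%s:1)", frags[pair[1]], frags[pair[2]]))
  }
  tree <- ape::read.tree(text = paste0(frags, ";"))
  if (n_taxa >= 3L) tree <- ape::unroot(tree)
  tree$edge.length <- rexp(nrow(tree$edge), rate = 1 / mean_branch)
  if (n_taxa == 2L) {
    len <- rexp(1, rate = 1 / mean_branch)   # one edge, split across the root
    tree$edge.length <- rep(len / 2, 2)
  }
  tree
}

## exp(Q t) for a reversible chain restricted to a subset of states.
.expm_rev <- function(Qsub, pisub, t) {
  d <- sqrt(pisub)
  B <- Qsub * outer(d, 1 / d)
  B <- (B + t(B)) / 2
  eg <- eigen(B, symmetric = TRUE)
  P <- (eg$vectors / d) %*% (exp(eg$values * t) * t(eg$vectors * d))
  P[P < 0] <- 0; P[P > 1] <- 1
  P
}

#' Evolve sequence-structure data along a tree
#'
#' Continuous-time Markov chain simulation of the 12-state model, site by
#' site, down the tree.  Two modes:
#'
#' * `"free"`: root states i.i.d. from the equilibrium frequencies; every
#'   site evolves over all 12 states.  Decoded structures can be unbalanced
#'   (the per-record warning is suppressed; this mode exists for testing the
#'   model machinery, not for producing valid Vienna files).
#' * `"structure_locked"`: a balanced dot-bracket `template` fixes each
#'   column's structural context; substitutions are restricted to the four
#'   nucleotides sharing that context, using the conditional (restricted,
#'   re-diagonalized) rate matrix.  Outputs are always valid records.
#'
#' There is no indel process, so the true alignment is the raw site matrix.
#'
#' @param tree An `ape::phylo` with branch lengths (substitutions per site).
#' @param model A `gtr12` model.
#' @param L Number of sites; when `NULL`, drawn uniformly from 128..483 (the
#'   observed ITS2 length range across the Chlorophyta) unless a template
#'   fixes it.
#' @param mode `"free"` or `"structure_locked"`.
#' @param template Dot-bracket string (required in locked mode; its length
#'   overrides `L`).
#' @param seed Integer seed; the simulation is deterministic given
#'   (tree, model, L, mode, template, seed).
#' @return List with `records` (list of [ss_record()]s, one per leaf, in
#'   `tree$tip.label` order), `alignment` (the true [ss_alignment()]) and
#'   `tree`.
#' @export
evolve_seqstruct <- function(tree, model = jc12_model(), L = NULL,
                             mode = c("free", "structure_locked"),
                             template = NULL, seed = 1) {
  mode <- match.arg(mode)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed %% .Machine$integer.max)
  if (mode == "structure_locked") {
    if (is.null(template)) stop("structure_locked mode requires a template")
    validate_dotbracket(template)
    if (!is.null(L) && L != nchar(template))
      stop("template length must equal L")
    L <- nchar(template)
  }
  if (is.null(L)) L <- sample(128:483, 1L)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  states <- matrix(NA_integer_, ntip + nnode, L)   # 0-based states
  root <- ntip + 1L

  if (mode == "free") {
    states[root, ] <- sample.int(12L, L, replace = TRUE, prob = model$pi) - 1L
    step <- function(parent_states, len) {
      P <- transition_matrix(model, len)
      out <- integer(L)
      for (s in unique(parent_states)) {
        idx <- which(parent_states == s)
        out[idx] <- sample.int(12L, length(idx), replace = TRUE,
                               prob = P[s + 1L, ]) - 1L
      }
      out
    }
  } else {
    st_groups <- match(strsplit(template, "")[[1]], STRUCT_CHARS) - 1L
    subsets <- lapply(0:2, function(g) which(rep(0:2, times = 4) == g))
    cond <- lapply(subsets, function(sub) {
      Qc <- model$Q[sub, sub]
      diag(Qc) <- 0
      diag(Qc) <- -rowSums(Qc)
      pic <- model$pi[sub] / sum(model$pi[sub])
      list(sub = sub, Q = Qc, pi = pic)
    })
    rs <- integer(L)
    for (g in 0:2) {
      cols <- which(st_groups == g)
      if (!length(cols)) next
      cm <- cond[[g + 1L]]
      rs[cols] <- cm$sub[sample.int(4L, length(cols), replace = TRUE,
                                    prob = cm$pi)] - 1L
    }
    states[root, ] <- rs
    step <- function(parent_states, len) {
      out <- integer(L)
      for (g in 0:2) {
        cols <- which(st_groups == g)
        if (!length(cols)) next
        cm <- cond[[g + 1L]]
        P <- .expm_rev(cm$Q, cm$pi, len)
        ps <- parent_states[cols]
        for (k in seq_len(4L)) {
          idx <- which(ps == cm$sub[k] - 1L)
          if (length(idx))
            out[cols[idx]] <- cm$sub[sample.int(4L, length(idx), replace = TRUE,
                                                prob = P[k, ])] - 1L
        }
      }
      out
    }
  }

  edges <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(edges$edge))) {
    par <- edges$edge[e, 1]; child <- edges$edge[e, 2]
    states[child, ] <- step(states[par, ], edges$edge.length[e])
  }

  ids <- tree$tip.label
  recs <- lapply(seq_len(ntip), function(i)
    suppressWarnings(decode_record(
      structure(list(id = ids[i], states = states[i, ]), class = "ss_encoded"))))
  list(records = recs,
       alignment = ss_alignment(ids, states[seq_len(ntip), , drop = FALSE]),
       tree = tree)
}
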