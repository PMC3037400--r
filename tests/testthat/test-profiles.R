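make_aln <- function(n = 6, L = 120, seed = 1, tree = NULL, mean_branch = 0.1) {
  if (is.null(tree)) tree <- sample_tree(n, mean_branch, seed = seed)
  evolve_seqstruct(tree, L = L, mode = "free", seed = seed + 100)$alignment
}

test_that("profile frequencies are column-wise member fractions", {
  aln <- ss_alignment(c("a", "b", "c"),
                      rbind(c(0L, 5L, -1L), c(0L, 7L, -1L), c(1L, 2L, 3L)))
  p <- profile_from_members(aln, "p", c("a", "b"))
  expect_equal(colSums(p$freq), rep(1, 3))       # states + gap sum to 1
  expect_equal(p$freq[1, 1], 1)                  # both A. in column 1
  expect_equal(p$freq[6, 2], 0.5)                # split column: two 0.5 entries
  expect_equal(p$freq[8, 2], 0.5)
  expect_equal(p$freq[13, 3], 1)                 # members all-gap in column 3
  # single member and duplicated member rows give the same indicators
  s <- profile_from_members(aln, "s", "a")
  dup <- ss_alignment(c("a", "b", "c"),
                      rbind(c(0L, 5L, -1L), c(0L, 5L, -1L), c(1L, 2L, 3L)))
  p2 <- profile_from_members(dup, "d", c("a", "b"))
  expect_equal(p2$freq, s$freq)
})

test_that("build_profiles validates the definition and passes non-members through", {
  aln <- make_aln(6)
  defn <- list(g1 = c("t1", "t2"), g2 = c("t3", "t4"))
  res <- build_profiles(aln, defn)
  expect_length(res$profiles, 2L)
  expect_length(res$entities, 4L)   # 2 profiles + t5, t6
  expect_error(build_profiles(aln, list(g = c("t1", "zz"))), "unknown")
  expect_error(build_profiles(aln, list(g = "t1", h = c("t1", "t2"))),
               "overlapping")
})

test_that("singleton profile distances equal plain sequence distances", {
  aln <- make_aln(5)
  m <- jc12_model()
  d_seq <- distance_matrix(aln, m)
  singles <- lapply(aln$ids, function(id) profile_from_members(aln, id, id))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_identical(profile_distance(singles[[i]], singles[[j]], m),
                     d_seq$D[i, j])
  }
  # profile vs itself with zero internal variation
  expect_equal(profile_distance(singles[[1]], singles[[1]], m), 0)
})

test_that("expected divergence counts follow the stated cross-product formula", {
  fp <- matrix(0, 13, 2); fq <- matrix(0, 13, 2)
  fp[1, 1] <- 0.5; fp[4, 1] <- 0.5; fp[7, 2] <- 1      # col1: A./C. 50:50, col2: G.
  fq[1, 1] <- 1;   fq[10, 2] <- 0.75; fq[13, 2] <- 0.25
  p <- structure(list(name = "p", members = "p", freq = fp), class = "ss_profile")
  q <- structure(list(name = "q", members = "q", freq = fq), class = "ss_profile")
  F <- fp[1:12, ] %*% t(fq[1:12, ])
  expect_equal(F[1, 1], 0.5)       # A. vs A. from column 1
  expect_equal(F[7, 10], 0.75)     # G. vs U. from column 2
  # ml_distance on these counts is what profile_distance reports
  expect_equal(profile_distance(p, q),
               ml_distance(list(F = F, N = sum(F)), jc12_model())$t_hat)
})

test_that("PNJ with unreachable threshold or max_iter 0 is byte-identical to NJ", {
  for (s in 1:3) {
    aln <- make_aln(6, seed = s)
    nj <- ape::write.tree(neighbor_joining(distance_matrix(aln)))
    pnj <- profile_neighbor_joining(aln, support_threshold = 101, B = 10, seed = s)
    expect_identical(ape::write.tree(pnj), nj)
    pnj0 <- profile_neighbor_joining(aln, max_iter = 0, B = 10, seed = s)
    expect_identical(ape::write.tree(pnj0), nj)
  }
})

test_that("PNJ freezes well-separated clades into profiles and re-expands them", {
  # two 4-taxon clades separated by a long internal branch
  tree <- ape::read.tree(text = paste0(
    "(((a1:0.02,a2:0.02):0.02,(a3:0.02,a4:0.02):0.02):0.5,",
    "((b1:0.02,b2:0.02):0.02,(b3:0.02,b4:0.02):0.02):0.5);"))
  sim <- evolve_seqstruct(tree, L = 1500, mode = "free", seed = 21)
  tr <- profile_neighbor_joining(sim$alignment, B = 30, seed = 4,
                                 support_threshold = 70, max_iter = 1)
  expect_setequal(tr$tip.label, tree$tip.label)
  sp <- names(tree_bipartitions(tr))
  expect_true("b1|b2|b3|b4" %in% sp)   # the non-canonical side holds the a's
})

test_that("profile definition files round-trip", {
  defn <- list(grpA = c("t1", "t2", "t3"), grpB = c("t4", "t5"))
  f <- withr::local_tempfile()
  write_profile_definition(defn, f)
  expect_identical(read_profile_definition(f), defn)
  writeLines("noTabHere", f)
  expect_error(read_profile_definition(f), "TAB")
})
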