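test_that("NJ reconstructs an additive quartet exactly", {
  labs <- c("A", "B", "C", "D")
  D <- matrix(0, 4, 4, dimnames = list(labs, labs))
  D["A", "B"] <- 3; D["A", "C"] <- 5; D["A", "D"] <- 6
  D["B", "C"] <- 6; D["B", "D"] <- 7; D["C", "D"] <- 7
  D <- D + t(D)
  tr <- neighbor_joining(D)
  expect_identical(sort(names(tree_bipartitions(tr))), "C|D")  # AB|CD split
  pl <- ape::cophenetic.phylo(tr)[labs, labs]
  expect_equal(pl, D, tolerance = 1e-12)
  edge_of <- function(t, tip) t$edge.length[t$edge[, 2] == match(tip, t$tip.label)]
  expect_equal(vapply(labs, edge_of, 0, t = tr), c(A = 1, B = 2, C = 3, D = 4))
})

test_that("three-taxon NJ uses the three-point formulas", {
  labs <- c("x", "y", "z")
  D <- matrix(c(0, 4, 6, 4, 0, 8, 6, 8, 0), 3, dimnames = list(labs, labs))
  tr <- neighbor_joining(D)
  edge_of <- function(tip) tr$edge.length[tr$edge[, 2] == match(tip, tr$tip.label)]
  expect_equal(edge_of("x"), (4 + 6 - 8) / 2)
  expect_equal(edge_of("y"), (4 + 8 - 6) / 2)
  expect_equal(edge_of("z"), (6 + 8 - 4) / 2)
  expect_error(neighbor_joining(D[1:2, 1:2]), "at least 3")
})

test_that("complete ties resolve deterministically to a valid binary tree", {
  labs <- paste0("t", 1:5)
  D <- matrix(1, 5, 5, dimnames = list(labs, labs)); diag(D) <- 0
  t1 <- ape::write.tree(neighbor_joining(D))
  t2 <- ape::write.tree(neighbor_joining(D))
  expect_identical(t1, t2)
  tr <- neighbor_joining(D)
  expect_true(ape::is.binary(tr))
  expect_true(all(tr$edge.length >= 0))
})

test_that("NJ is consistent on random additive matrices and matches ape::nj", {
  for (s in 1:15) {
    n <- sample(4:12, 1)
    tr <- sample_tree(n, mean_branch = 0.4, seed = s)
    D <- ape::cophenetic.phylo(tr)
    est <- neighbor_joining(ss_dist(rownames(D), D))
    expect_equal(phangorn::RF.dist(est, tr), 0)
    # path lengths reproduce the additive input exactly
    expect_equal(ape::cophenetic.phylo(est)[rownames(D), colnames(D)], D,
                 tolerance = 1e-9)
    # independent implementation agrees on the topology
    expect_equal(phangorn::RF.dist(est, ape::nj(as.dist(D))), 0)
  }
})

test_that("bipartitions: counts, canonical sides, invariance under re-rooting", {
  tr <- sample_tree(8, seed = 2)
  sp <- tree_bipartitions(tr)
  expect_length(sp, 8 - 3)   # unrooted binary: n - 3 non-trivial splits
  smallest <- sort(tr$tip.label)[1]
  expect_false(any(vapply(sp, function(s) smallest %in% s, TRUE)))
  rt <- root_with_outgroup(tr, tr$tip.label[3])
  expect_identical(sort(names(tree_bipartitions(rt))), sort(names(sp)))
})

test_that("bootstrap support: determinism, defaults, and clean-signal certainty", {
  expect_identical(formals(bootstrap_support)$B, 100)
  qt <- quartet_tree()
  sim <- evolve_seqstruct(qt, L = 2000, mode = "free", seed = 42)
  b1 <- bootstrap_support(sim$alignment, B = 50, seed = 7)
  b2 <- bootstrap_support(sim$alignment, B = 50, seed = 7)
  expect_identical(b1$support, b2$support)
  expect_gte(b1$support[["t3|t4"]], 95)
  b3 <- bootstrap_support(sim$alignment, B = 50, seed = 8)
  expect_gte(b3$support[["t3|t4"]], 95)
  # support values land on the tree as integer node labels
  expect_true(any(b1$tree$node.label == as.character(round(b1$support[[1]]))))
  # an alignment whose every column carries the same signal: 100% everywhere
  base <- rbind(c(0L, 1L), c(0L, 1L), c(5L, 8L), c(5L, 8L))
  aln <- ss_alignment(paste0("s", 1:4), base[, rep(1:2, 50)])
  bs <- bootstrap_support(aln, B = 25, seed = 1)
  expect_true(all(bs$support == 100))
})

test_that("outgroup rooting splits the separating edge at its midpoint", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:4);")
  rt <- root_with_outgroup(tr, "A")
  expect_true(ape::is.rooted(rt))
  root_edges <- rt$edge.length[rt$edge[, 1] == length(rt$tip.label) + 1L]
  expect_equal(root_edges[1], root_edges[2])
  # {C,D} and {A,B} give the same root edge
  r1 <- root_with_outgroup(tr, c("C", "D"))
  r2 <- root_with_outgroup(tr, c("A", "B"))
  expect_identical(sort(names(tree_bipartitions(r1))),
                   sort(names(tree_bipartitions(r2))))
  # non-monophyletic outgroup: warn, fall back to the first id's edge
  expect_warning(r3 <- root_with_outgroup(tr, c("A", "C")), "not monophyletic")
  kids <- r3$edge[r3$edge[, 1] == length(r3$tip.label) + 1L, 2]
  expect_true(match("A", r3$tip.label) %in% kids)
  expect_error(root_with_outgroup(tr, "Z"), "unknown")
  expect_error(root_with_outgroup(tr, c("A", "B", "C", "D")), "all leaves")
})

test_that("Newick write-read-write is idempotent and keeps support labels", {
  qt <- quartet_tree()
  sim <- evolve_seqstruct(qt, L = 500, mode = "free", seed = 5)
  bs <- bootstrap_support(sim$alignment, B = 20, seed = 3)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_newick(bs$tree, f1)
  t2 <- read_newick(f1)
  write_newick(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(t2$node.label, bs$tree$node.label)
})
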