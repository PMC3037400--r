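# Shared fixtures: all test data is generated in code.

# Exhaustive enumeration of all global alignments of two state vectors under
# affine gap costs (gap run of length k costs go + (k-1)*ge).  Independent
# oracle for the Gotoh recursion; exponential, only for short sequences.
brute_force_score <- function(sa, sb, m) {
  S <- matrix(0, length(sa), length(sb))
  if (length(sa) && length(sb)) S[] <- m$scores[sa + 1L, sb + 1L]
  go <- m$gap_open; ge <- m$gap_extend
  la <- length(sa); lb <- length(sb)
  rec <- function(i, j, last) {
    if (i == la && j == lb) return(0)
    best <- -Inf
    if (i < la && j < lb) best <- max(best, S[i + 1L, j + 1L] + rec(i + 1L, j + 1L, 0L))
    if (i < la) best <- max(best, (if (last == 1L) ge else go) + rec(i + 1L, j, 1L))
    if (j < lb) best <- max(best, (if (last == 2L) ge else go) + rec(i, j + 1L, 2L))
    best
  }
  rec(0L, 0L, 0L)
}

enc <- function(id, states) {
  structure(list(id = id, states = as.integer(states)), class = "ss_encoded")
}

# Random valid sequence-structure record: a stem-loop of `n_stem` pairs with
# an unpaired loop and tail, random nucleotides.
random_record <- function(id, n_stem = 3, n_loop = 4, n_tail = 3) {
  struct <- paste0(strrep("(", n_stem), strrep(".", n_loop),
                   strrep(")", n_stem), strrep(".", n_tail))
  seq <- paste(sample(c("A", "C", "G", "U"), nchar(struct), TRUE), collapse = "")
  ss_record(id, seq, struct)
}

# Random valid GTR model.
random_gtr <- function() {
  pi <- runif(12, 0.3, 1); pi <- pi / sum(pi)
  R <- matrix(runif(144, 0.2, 2), 12, 12)
  R <- (R + t(R)) / 2; diag(R) <- 0
  gtr_model(pi, R)
}

# Quartet with a long internal branch: the clean-signal tree for
# bootstrap / topology-recovery checks.
quartet_tree <- function(internal = 0.1, terminal = 0.05) {
  ape::read.tree(text = sprintf(
    "((t1:%g,t2:%g):%g,t3:%g,t4:%g);",
    terminal, terminal, internal, terminal, terminal))
}

# Divergence counts implied by the 12-state symmetric model at observed
# different-fraction p, for N sites.
jc12_counts <- function(p, N = 1000) {
  F <- matrix(N * p / 132, 12, 12)
  diag(F) <- N * (1 - p) / 12
  list(F = F, N = N)
}

jc12_closed_form <- function(p) -(11 / 12) * log(1 - (12 / 11) * p)
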