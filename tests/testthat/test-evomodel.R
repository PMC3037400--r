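test_that("the 12-state JC analogue has the hand-derived rate matrix", {
  m <- jc12_model()
  off <- m$Q[row(m$Q) != col(m$Q)]
  expect_equal(unname(off), rep(1 / 11, 132))
  expect_equal(unname(diag(m$Q)), rep(-1, 12))
})

test_that("GTR construction satisfies its invariants for random models", {
  set.seed(2)
  for (k in 1:10) {
    m <- random_gtr()
    expect_equal(sum(m$pi), 1)
    expect_equal(max(abs(rowSums(m$Q))), 0, tolerance = 1e-12)
    expect_equal(-sum(m$pi * diag(m$Q)), 1, tolerance = 1e-12)
    # detailed balance pi_i Q_ij == pi_j Q_ji, and stationarity pi Q == 0
    flux <- m$pi * m$Q          # recycles pi down columns: pi_i * Q_ij
    expect_equal(max(abs(flux - t(flux))), 0, tolerance = 1e-12)
    expect_equal(max(abs(m$pi %*% m$Q)), 0, tolerance = 1e-12)
  }
  # reducible R rejected
  R <- matrix(0, 12, 12); R[1, 2] <- R[2, 1] <- 1
  expect_error(gtr_model(rep(1 / 12, 12), R), "reducible")
})

test_that("transition matrices are stochastic, start at I and converge to pi", {
  set.seed(3)
  m <- random_gtr()
  expect_equal(transition_matrix(m, 0), diag(12), ignore_attr = TRUE)
  for (t in c(0.01, 0.5, 3)) {
    P <- transition_matrix(m, t)
    expect_equal(max(abs(rowSums(P) - 1)), 0, tolerance = 1e-10)
    expect_true(all(P >= 0 & P <= 1))
    # pi is a left fixed vector of P(t)
    expect_equal(as.numeric(m$pi %*% P), unname(m$pi), tolerance = 1e-12)
  }
  P <- transition_matrix(m, 500)
  expect_equal(max(abs(sweep(P, 2, m$pi))), 0, tolerance = 1e-6)
  expect_error(transition_matrix(m, -1), "non-negative")
})

test_that("Chapman-Kolmogorov holds and P(t) matches a dense expm oracle", {
  set.seed(4)
  m <- random_gtr()
  for (k in 1:5) {
    s <- runif(1, 0, 2); t <- runif(1, 0, 2)
    expect_equal(transition_matrix(m, s) %*% transition_matrix(m, t),
                 transition_matrix(m, s + t), tolerance = 1e-8)
  }
  expect_equal(transition_matrix(m, 0.73),
               as.matrix(Matrix::expm(m$Q * 0.73)),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("divergence counting uses pairwise deletion", {
  ra <- c(0L, 5L, 11L, 3L, -1L, 7L, 7L, 2L, -2L, 9L)
  rb <- c(0L, 5L, 10L, 3L, 4L, -1L, 7L, 2L, 1L, -1L)
  cnt <- count_divergence(ra, rb)
  expect_equal(cnt$N, 6)   # columns 5, 6, 9, 10 dropped
  expect_equal(sum(diag(cnt$F)), 5)
  expect_equal(cnt$F[12, 11], 1)  # state 11 vs 10
  ident <- count_divergence(rep(2L, 10), rep(2L, 10))
  expect_equal(sum(diag(ident$F)), 10)
  expect_equal(sum(ident$F) - sum(diag(ident$F)), 0)
  expect_error(count_divergence(c(-1L, -1L), c(0L, 1L)), "no usable")
})

test_that("ML distance matches the 12-state JC closed form on a p grid", {
  m <- jc12_model()
  for (p in seq(0.05, 0.60, by = 0.05)) {
    ml <- ml_distance(jc12_counts(p), m)
    expect_equal(ml$t_hat, jc12_closed_form(p), tolerance = 1e-4)
    expect_false(ml$saturated)
  }
  # identical sequences and saturation
  expect_equal(ml_distance(jc12_counts(0), m)$t_hat, 0)
  sat <- ml_distance(jc12_counts(0.93), m)
  expect_true(sat$saturated)
  expect_equal(sat$t_hat, 20)
})

test_that("distance estimator is consistent as L grows", {
  m <- jc12_model()
  two <- ape::read.tree(text = "(a:0.15,b:0.15);")
  med_err <- vapply(c(500L, 2000L, 10000L), function(L) {
    errs <- vapply(1:8, function(s) {
      sim <- evolve_seqstruct(two, m, L = L, mode = "free", seed = s + 7 * L)
      d <- distance_matrix(sim$alignment, m)
      abs(d$D[1, 2] - 0.3)
    }, 0)
    stats::median(errs)
  }, 0)
  expect_true(med_err[3] < med_err[1])
  # and a single long simulation lands within 3 standard errors
  sim <- evolve_seqstruct(two, m, L = 10000, mode = "free", seed = 11)
  d <- distance_matrix(sim$alignment, m)
  p <- 11 / 12 * (1 - exp(-12 / 11 * 0.3))
  se <- sqrt(p * (1 - p) / 10000) / abs(1 - 12 / 11 * p)  # delta method
  expect_lt(abs(d$D[1, 2] - 0.3), 3 * se)
})

test_that("distance_matrix agrees with ml_distance pair by pair", {
  set.seed(6)
  rows <- matrix(sample(0:11, 3 * 200, TRUE), 3, 200)
  aln <- ss_alignment(c("a", "b", "c"), rows)
  m <- jc12_model()
  d <- distance_matrix(aln, m)
  cnt <- count_divergence(rows[1, ], rows[2, ])
  expect_equal(d$D[1, 2], ml_distance(cnt, m)$t_hat)
  expect_equal(d$D, t(d$D))
  ident <- ss_alignment(c("a", "b"), rbind(rows[1, ], rows[1, ]))
  expect_equal(max(distance_matrix(ident, m)$D), 0)
})

test_that("GTR estimation recovers the generating model", {
  set.seed(12)
  truth <- random_gtr()
  tr <- sample_tree(8, mean_branch = 0.15, seed = 11)
  sim <- evolve_seqstruct(tr, truth, L = 5000, mode = "free", seed = 12)
  est <- estimate_gtr(sim$alignment)
  expect_lt(max(abs(est$pi - truth$pi)), 0.02)
  # estimate invariant to row order
  perm <- sample(8)
  aln2 <- ss_alignment(sim$alignment$ids[perm],
                       sim$alignment$rows[perm, ])
  expect_equal(estimate_gtr(aln2)$Q, est$Q)
  # degenerate: identical rows -> warning, uniform exchangeabilities
  ident <- ss_alignment(c("a", "b"), rbind(0:11, 0:11))
  expect_warning(dm <- estimate_gtr(ident), "pseudocounts")
  off <- dm$R[row(dm$R) != col(dm$R)]
  expect_true(all(abs(off / off[1] - 1) < 1e-9))
})

test_that("model files round-trip exactly", {
  set.seed(13)
  m <- random_gtr()
  f <- withr::local_tempfile()
  write_gtr_model(m, f)
  m2 <- read_gtr_model(f)
  expect_identical(m2$pi, m$pi)
  expect_identical(m2$Q, m$Q)
  writeLines(c("pi A. 0.5", "nonsense"), f)
  expect_error(read_gtr_model(f), "malformed")
})
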