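test_that("default composite matrix matches the stated formula", {
  m <- default_scoring_matrix()
  expect_equal(m$scores["A.", "A."], 4)   # 2 + 2
  expect_equal(m$scores["A(", "A)"], 1)   # 2 + (-1)
  expect_equal(m$scores["A(", "C."], -3)  # -1 + (-2)
  expect_true(isSymmetric(m$scores))
  expect_error(default_scoring_matrix(w_seq = -1), "non-negative")
  expect_error(default_scoring_matrix(0, 0), "both be zero")
  # weights scale the two terms independently
  m2 <- default_scoring_matrix(w_seq = 2, w_str = 0.5)
  expect_equal(m2$scores["A.", "A."], 2 * 2 + 0.5 * 2)
})

test_that("log-odds estimation rewards observed identities", {
  # all observed pairs are (A., A.): its diagonal entry must dominate its row
  aln <- ss_alignment(c("a", "b"), rbind(0L, 0L))
  m <- estimate_logodds_matrix(list(aln), pseudocount = 1)
  expect_true(all(m$scores[1, 1] > m$scores[1, -1]))
  expect_true(isSymmetric(m$scores))
})

test_that("log-odds scores shrink toward zero for random pairs and huge pseudocounts", {
  set.seed(7)
  max_abs <- vapply(c(200L, 5000L), function(L) {
    rows <- rbind(sample(0:11, L, TRUE), sample(0:11, L, TRUE))
    m <- estimate_logodds_matrix(list(ss_alignment(c("a", "b"), rows)), 1)
    max(abs(m$scores))
  }, 0)
  expect_lt(max_abs[2], max_abs[1])
  # pseudocount -> infinity limit: uniform table, all-zero scores
  rows <- rbind(sample(0:11, 50, TRUE), sample(0:11, 50, TRUE))
  m <- estimate_logodds_matrix(list(ss_alignment(c("a", "b"), rows)), 1e9)
  expect_true(all(abs(m$scores) < 0.02))
})

test_that("log-odds estimation is invariant to row order and reference duplication", {
  set.seed(8)
  rows <- matrix(sample(0:11, 60, TRUE), 3, 20)
  a1 <- ss_alignment(c("a", "b", "c"), rows)
  a2 <- ss_alignment(c("c", "b", "a"), rows[3:1, ])
  expect_equal(estimate_logodds_matrix(list(a1))$scores,
               estimate_logodds_matrix(list(a2))$scores)
  expect_equal(estimate_logodds_matrix(list(a1, a1))$scores,
               estimate_logodds_matrix(list(a1))$scores)
})

test_that("scoring matrix files round-trip exactly and reject malformed input", {
  m <- default_scoring_matrix()
  f <- withr::local_tempfile()
  write_scoring_matrix(m, f)
  m2 <- read_scoring_matrix(f)
  expect_identical(m2$scores, m$scores)
  expect_identical(m2$gap_open, m$gap_open)
  # wrong dimension
  lines <- readLines(f)
  writeLines(lines[-3], f)
  expect_error(read_scoring_matrix(f), "12 data rows")
  # asymmetric cell is named
  m3 <- m; m3$scores[1, 2] <- 99
  writeLines(c(paste(STATE_LABELS, collapse = "\t"),
               vapply(1:12, function(i)
                 paste(c(STATE_LABELS[i], m3$scores[i, ]), collapse = "\t"), ""),
               "gap_open -8", "gap_extend -2"), f)
  expect_error(read_scoring_matrix(f), "asymmetric at cell")
  # non-negative gap penalties rejected
  write_scoring_matrix(m, f)
  lines <- sub("^gap_open.*", "gap_open 1", readLines(f))
  writeLines(lines, f)
  expect_error(read_scoring_matrix(f), "gap")
})
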