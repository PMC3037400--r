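## 12-state general time reversible substitution model: rate matrix,
## transition probabilities, ML pairwise distances, model estimation.

#' Build a 12-state GTR model
#'
#' Constructs the rate matrix `Q[i, j] = R[i, j] * pi[j]` (i != j) with
#' diagonal set so rows sum to zero, scaled so the expected substitution rate
#' at stationarity is one: `-sum(pi * diag(Q)) == 1`.  Reversibility
#' (detailed balance `pi_i Q_ij == pi_j Q_ji`) holds by construction.  The
#' symmetric eigendecomposition of `Q` is cached on the object so transition
#' probabilities are cheap to evaluate repeatedly.
#'
#' @param pi Equilibrium frequencies: 12 positive values summing to 1.
#' @param R Symmetric non-negative 12x12 exchangeability matrix, zero
#'   diagonal, irreducible (every state reachable).
#' @return Object of class `gtr12` with elements `pi`, `R`, `Q` and cached
#'   spectral factors.
#' @examples
#' m <- jc12_model()          # uniform pi, uniform R
#' range(m$Q[row(m$Q) != col(m$Q)])  # all off-diagonals 1/11
#' @export
gtr_model <- function(pi, R) {
  pi <- as.numeric(pi)
  if (length(pi) != 12L || any(pi <= 0) || abs(sum(pi) - 1) > 1e-8)
    stop("pi must be 12 positive frequencies summing to 1")
  pi <- pi / sum(pi)
  R <- as.matrix(R)
  if (!all(dim(R) == c(12L, 12L))) stop("R must be 12x12")
  if (max(abs(R - t(R))) > 1e-9) stop("R must be symmetric")
  if (any(R < 0)) stop("R must be non-negative")
  if (any(diag(R) != 0)) stop("R must have a zero diagonal")
  ## irreducibility: the graph over nonzero R entries must be connected
  adj <- R > 0
  reach <- logical(12); reach[1] <- TRUE
  repeat {
    new <- reach | apply(adj[, reach, drop = FALSE], 1, any)
    if (identical(new, reach)) break
    reach <- new
  }
  if (!all(reach)) stop("R is reducible: some state is unreachable")
  Q <- R * rep(pi, each = 12L)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  if (mu <= 0) stop("degenerate rate matrix")
  Q <- Q / mu
  dimnames(Q) <- list(STATE_LABELS, STATE_LABELS)
  ## reversible Q is similar to a symmetric matrix: B = D^(1/2) Q D^(-1/2)
  d <- sqrt(pi)
  B <- Q * outer(d, 1 / d)
  B <- (B + t(B)) / 2
  eg <- eigen(B, symmetric = TRUE)
  structure(list(pi = setNames(pi, STATE_LABELS), R = R, Q = Q,
                 evals = eg$values,
                 V = eg$vectors / d,          # D^(-1/2) U
                 W = t(eg$vectors * d)),      # U' D^(1/2)
            class = "gtr12")
}

#' 12-state Jukes-Cantor analogue
#'
#' Uniform equilibrium frequencies and uniform exchangeabilities; the bundled
#' default model used when no fitted or user-supplied model is given (the
#' numeric parameters of published ITS2-specific GTR models are not publicly
#' tabulated).
#'
#' @return A `gtr12` model.
#' @export
jc12_model <- function() {
  R <- matrix(1, 12, 12); diag(R) <- 0
  gtr_model(rep(1 / 12, 12), R)
}

#' @export
print.gtr12 <- function(x, ...) {
  cat("<gtr12> 12-state GTR substitution model\n")
  cat("  pi:", paste(sprintf("%s=%.3f", STATE_LABELS, x$pi), collapse = " "), "\n")
  cat(sprintf("  expected rate at stationarity: %.6f\n", -sum(x$pi * diag(x$Q))))
  invisible(x)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Computed from the cached symmetric eigendecomposition; entries are clipped
#' into \[0, 1\] (numerical noise up to ~1e-12 can fall outside).
#'
#' @param model A `gtr12` model.
#' @param t Non-negative evolutionary time (expected substitutions per site).
#' @return 12x12 row-stochastic matrix.
#' @export
transition_matrix <- function(model, t) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("t must be a single non-negative number")
  P <- model$V %*% (exp(model$evals * t) * model$W)
  P[P < 0] <- 0
  P[P > 1] <- 1
  dimnames(P) <- list(STATE_LABELS, STATE_LABELS)
  P
}

#' Divergence counts between two aligned rows
#'
#' Site-pattern counts under pairwise deletion: a column contributes iff both
#' rows carry a real state (not gap, not missing).
#'
#' @param row_a,row_b Equal-length integer vectors of alignment row codes.
#' @return List with `F` (12x12 count matrix, rows = states of `row_a`) and
#'   `N` (number of counted columns).
#' @export
count_divergence <- function(row_a, row_b) {
  if (length(row_a) != length(row_b)) stop("rows differ in length")
  use <- row_a >= 0L & row_b >= 0L
  if (!any(use)) stop("no usable columns (all gapped or missing)")
  idx <- row_a[use] * 12L + row_b[use] + 1L
  F <- matrix(tabulate(idx, 144L), 12, 12, byrow = TRUE,
              dimnames = list(STATE_LABELS, STATE_LABELS))
  list(F = F, N = sum(F))
}

#' Maximum-likelihood pairwise distance
#'
#' Maximizes `l(t) = sum_xy F_xy * log(pi_x * P_xy(t))` over `t` in
#' `[0, t_max]` by bracketed one-dimensional optimization (tolerance 1e-9 on
#' t, tighter than the 1e-8 contract).  If the optimum sits at the upper
#' bound the pair is flagged as saturated and `t_max` returned.  `F` may
#' contain non-integer expected counts (profile distances).
#'
#' @param counts List with `F` (12x12) and `N` as from [count_divergence()].
#' @param model A `gtr12` model.
#' @param t_max Upper bound of the search interval (default 20).
#' @return List with `t_hat` and logical `saturated`.
#' @export
ml_distance <- function(counts, model, t_max = 20) {
  F <- counts$F
  if (sum(F) <= 0) stop("empty divergence counts")
  if (sum(F) - sum(diag(F)) == 0)
    return(list(t_hat = 0, saturated = FALSE))
  lpi <- log(model$pi)
  nz <- F > 0
  loglik <- function(t) {
    P <- transition_matrix(model, t)
    lp <- suppressWarnings(log(P))
    lp[P == 0] <- -1e10   # finite penalty keeps the optimizer stable at t ~ 0
    sum(F[nz] * (lpi[row(F)[nz]] + lp[nz]))
  }
  opt <- optimize(loglik, interval = c(0, t_max), maximum = TRUE, tol = 1e-9)
  t_hat <- opt$maximum
  ## optimize() never returns the endpoint itself; treat a solution pinned
  ## against the bound as saturated
  if (t_hat >= t_max - 1e-5 && loglik(t_max) >= opt$objective - 1e-9)
    return(list(t_hat = t_max, saturated = TRUE))
  list(t_hat = t_hat, saturated = FALSE)
}

#' Distance matrix container
#'
#' @param labels Taxon labels.
#' @param D Symmetric non-negative matrix with zero diagonal.
#' @param saturated Logical matrix of per-cell saturation flags (optional).
#' @return Object of class `ss_dist`.
#' @export
ss_dist <- function(labels, D, saturated = NULL) {
  D <- as.matrix(D)
  if (nrow(D) != length(labels)) stop("labels and D disagree")
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix must be symmetric")
  if (any(diag(D) != 0)) stop("distance matrix diagonal must be zero")
  if (any(D < 0)) stop("distances must be non-negative")
  if (any(is.na(D))) stop("NaN/NA in distance matrix")
  dimnames(D) <- list(labels, labels)
  if (is.null(saturated)) saturated <- matrix(FALSE, nrow(D), ncol(D))
  structure(list(labels = as.character(labels), D = D, saturated = saturated),
            class = "ss_dist")
}

#' @export
print.ss_dist <- function(x, ...) {
  cat(sprintf("<ss_dist> %d taxa", length(x$labels)))
  if (any(x$saturated)) cat(sprintf(", %d saturated pairs", sum(x$saturated) / 2))
  cat("\n")
  invisible(x)
}

#' All pairwise ML distances of an alignment
#'
#' @param aln An [ss_alignment()] with at least 2 rows.
#' @param model A `gtr12` model.
#' @param t_max Saturation bound passed to [ml_distance()].
#' @return An [ss_dist()] object.
#' @export
distance_matrix <- function(aln, model = jc12_model(), t_max = 20) {
  n <- length(aln$ids)
  if (n < 2L) stop("need at least 2 rows")
  D <- matrix(0, n, n)
  sat <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    cnt <- tryCatch(count_divergence(aln$rows[i, ], aln$rows[j, ]),
                    error = function(e)
                      stop(sprintf("pair (%s, %s): %s", aln$ids[i], aln$ids[j],
                                   conditionMessage(e)), call. = FALSE))
    ml <- ml_distance(cnt, model, t_max)
    D[i, j] <- D[j, i] <- ml$t_hat
    sat[i, j] <- sat[j, i] <- ml$saturated
  }
  ss_dist(aln$ids, D, sat)
}

#' Estimate a GTR model from an alignment
#'
#' Counting estimator: divergence counts are pooled over all row pairs whose
#' p-distance is below 0.75 (saturated pairs carry little signal and bias the
#' exchangeabilities), symmetrized, and converted to frequencies and
#' exchangeabilities: `pi` from the marginal state frequencies (plus
#' pseudocount), `R_xy = (F_xy + F_yx + 2 * pseudocount) / (2 pi_x pi_y)`.
#' The result is normalized through [gtr_model()].  This is a deliberately
#' simple, self-contained estimator, not a joint ML fit over a tree.
#'
#' @param aln An [ss_alignment()] with >= 2 rows.
#' @param pseudocount Positive pseudocount (default 1).
#' @return A `gtr12` model.
#' @export
estimate_gtr <- function(aln, pseudocount = 1) {
  n <- length(aln$ids)
  if (n < 2L) stop("need at least 2 rows")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  F <- matrix(0, 12, 12)
  used <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    p <- .p_distance(aln$rows[i, ], aln$rows[j, ])
    if (is.na(p) || p >= 0.75) next
    F <- F + count_divergence(aln$rows[i, ], aln$rows[j, ])$F
    used <- used + 1L
  }
  if (used == 0L) stop("all row pairs are saturated (p-distance >= 0.75)")
  F <- (F + t(F)) / 2
  if (sum(F) - sum(diag(F)) == 0)
    warning("no substitutions observed; exchangeabilities driven by pseudocounts only")
  marg <- rowSums(F) + pseudocount
  pi <- marg / sum(marg)
  R <- (2 * F + 2 * pseudocount) / (2 * outer(pi, pi))
  diag(R) <- 0
  gtr_model(pi, R)
}

#' Read / write a GTR model file
#'
#' Key-value text: 12 lines `pi <label> <value>` followed by 66 lines
#' `R <label> <label> <value>` for the upper triangle, in canonical state
#' order.  Values round-trip through decimal text exactly.
#'
#' @param path File path.
#' @return `read_gtr_model`: a `gtr12` model.
#' @export
read_gtr_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  tok <- strsplit(lines, "\\s+")
  pi <- setNames(rep(NA_real_, 12), STATE_LABELS)
  R <- matrix(0, 12, 12, dimnames = list(STATE_LABELS, STATE_LABELS))
  for (tk in tok) {
    if (tk[1] == "pi" && length(tk) == 3L) {
      pi[tk[2]] <- as.numeric(tk[3])
    } else if (tk[1] == "R" && length(tk) == 4L) {
      R[tk[2], tk[3]] <- R[tk[3], tk[2]] <- as.numeric(tk[4])
    } else stop(sprintf("malformed model file line: '%s'", paste(tk, collapse = " ")))
  }
  if (any(is.na(pi))) stop("model file missing pi entries")
  gtr_model(pi, R)
}

#' @rdname read_gtr_model
#' @param model A `gtr12` model.
#' @export
write_gtr_model <- function(model, path) {
  fmt <- function(x) formatC(x, format = "g", digits = 17)
  lines <- sprintf("pi %s %s", STATE_LABELS, fmt(model$pi))
  for (i in 1:11) for (j in (i + 1L):12L)
    lines <- c(lines, sprintf("R %s %s %s", STATE_LABELS[i], STATE_LABELS[j],
                              fmt(model$R[i, j])))
  writeLines(lines, path)
  invisible(path)
}

#' Write a distance matrix in square PHYLIP format
#'
#' Relaxed PHYLIP: first line the number of taxa, then one line per taxon
#' with the label (whitespace-delimited, not truncated to 10 characters)
#' followed by the row of distances.
#'
#' @param d An [ss_dist()] object.
#' @param path Output path.
#' @export
write_phylip <- function(d, path) {
  n <- length(d$labels)
  lines <- c(sprintf("%5d", n),
             vapply(seq_len(n), function(i)
               paste(c(formatC(d$labels[i], width = -12),
                       sprintf("%.8f", d$D[i, ])), collapse = "  "),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}
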