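# Independent brute-force oracles used across the suite.  Everything here
# is deliberately naive (enumeration, closed forms) and shares no code with
# the implementation paths it checks.

# All integer compositions of A into J nonnegative parts.
compositions <- function(A, J) {
  if (J == 1) return(matrix(A, 1, 1))
  out <- list()
  for (k in 0:A) {
    rest <- compositions(A - k, J - 1)
    out[[length(out) + 1]] <- cbind(k, rest)
  }
  do.call(rbind, out)
}

# Exhaustive min/max of the KL specialization sum_j (n_j/A) log((n_j/A)/q_j)
# over all integer allocations of A interactions to the partners q.
kl_extremes_exhaustive <- function(A, q) {
  alloc <- compositions(A, length(q))
  vals <- apply(alloc, 1, function(n) {
    p <- n / A
    keep <- p > 0
    sum(p[keep] * log(p[keep] / q[keep]))
  })
  c(min = min(vals), max = max(vals))
}

# All integer tables with the given margins (small cases only).
enumerate_tables <- function(row_margins, col_margins) {
  nr <- length(row_margins)
  if (nr == 1) {
    tb <- matrix(col_margins, 1)
    return(list(tb))
  }
  out <- list()
  first_rows <- compositions(row_margins[1], length(col_margins))
  for (r in seq_len(nrow(first_rows))) {
    fr <- first_rows[r, ]
    if (any(fr > col_margins)) next
    for (rest in enumerate_tables(row_margins[-1], col_margins - fr))
      out[[length(out) + 1]] <- rbind(fr, rest, deparse.level = 0)
  }
  out
}

# Exact fixed-margin (Fisher-Yates) probability of one table.
table_probability <- function(tb) {
  m <- sum(tb)
  exp(sum(lfactorial(rowSums(tb))) + sum(lfactorial(colSums(tb))) -
        lfactorial(m) - sum(lfactorial(tb)))
}

# All set partitions of n elements, as membership vectors (restricted
# growth strings).
set_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return()
    }
    for (lab in seq_len(maxlab + 1))
      rec(c(prefix, lab), max(maxlab, lab))
  }
  rec(integer(0), 0)
  out
}

# Newman weighted modularity computed straight from the definition.
modularity_oracle <- function(W, membership) {
  tw <- sum(W) / 2
  deg <- rowSums(W)
  sum(vapply(unique(membership), function(c) {
    inc <- membership == c
    sum(W[inc, inc]) / (2 * tw) - (sum(deg[inc]) / (2 * tw))^2
  }, numeric(1)))
}

# Best partition by exhaustive search (n <= 8).
best_partition_oracle <- function(W) {
  parts <- set_partitions(nrow(W))
  qs <- vapply(parts, function(p) modularity_oracle(W, p), numeric(1))
  list(Q = max(qs), membership = parts[[which.max(qs)]])
}

# Tiny worked interaction matrix used in several role tests.
toy_matrix <- function() {
  matrix(c(2, 1, 0, 1), 2, 2,
         dimnames = list(c("a1", "a2"), c("p1", "p2")))
}

# A small random correlation matrix (empirical, hence valid PSD).
random_correlation <- function(N, n = 50) {
  cor(matrix(rnorm(n * N), n, N))
}
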