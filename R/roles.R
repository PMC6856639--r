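#' Validate an interaction matrix
#'
#' Animal taxa as rows, plant species as columns, nonnegative integer
#' interaction counts in the cells.  All-zero rows and columns are dropped
#' with a warning, since no index is defined for taxa without interactions.
#'
#' @param x numeric matrix with dimnames.
#' @return The validated integer matrix (class `interaction_matrix`).
#' @export
as_interaction_matrix <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0) || any(x != round(x)))
    nw_stop("interaction matrix must contain nonnegative integer counts")
  if (is.null(rownames(x)))
    rownames(x) <- sprintf("animal_%02d", seq_len(nrow(x)))
  if (is.null(colnames(x)))
    colnames(x) <- sprintf("plant_%02d", seq_len(ncol(x)))
  zr <- rowSums(x) == 0; zc <- colSums(x) == 0
  if (any(zr) || any(zc)) {
    warning("dropping all-zero rows/columns: ",
            paste(c(rownames(x)[zr], colnames(x)[zc]), collapse = ", "))
    x <- x[!zr, !zc, drop = FALSE]
  }
  if (nrow(x) == 0 || ncol(x) == 0)
    nw_stop("interaction matrix has no nonzero rows/columns")
  structure(x, class = c("interaction_matrix", class(matrix())))
}

# Orient the matrix so focal taxa are rows.
orient <- function(matrix, level = c("rows", "columns")) {
  level <- match.arg(level)
  m <- unclass(matrix)
  if (level == "columns") t(m) else m
}

#' Frequency-based role indices
#'
#' For each focal taxon: degree (number of partners with positive counts),
#' species strength (sum over partners of the partner's dependence on the
#' focal taxon, `sum_j a_ij / A_j` with `A_j` the partner's total), and
#' partner diversity (Shannon entropy, natural log, of the focal taxon's
#' partner-use proportions `p'_ij = a_ij / A_i`).
#'
#' @param matrix interaction matrix (see [as_interaction_matrix()]).
#' @param level `"rows"` (animals) or `"columns"` (plants) as focal taxa.
#' @return data.frame with columns `taxon`, `degree`, `species_strength`,
#'   `partner_diversity`.
#' @export
#' @examples
#' m <- matrix(c(2, 1, 0, 1), 2, 2, dimnames = list(c("a1", "a2"),
#'                                                  c("p1", "p2")))
#' frequency_indices(m, "rows")
frequency_indices <- function(matrix, level = c("rows", "columns")) {
  m <- orient(matrix, level)
  A_focal <- rowSums(m)
  A_partner <- colSums(m)
  degree <- rowSums(m > 0)
  strength <- as.numeric((m / rep(A_partner, each = nrow(m))) %*%
                           rep(1, ncol(m)))
  p <- m / A_focal
  pd <- apply(p, 1, function(q) { q <- q[q > 0]; -sum(q * log(q)) })
  data.frame(taxon = rownames(m), degree = as.integer(degree),
             species_strength = strength, partner_diversity = pd,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Complementary specialization d'
#'
#' The raw specialization of focal taxon `i` is the Kullback-Leibler
#' divergence of its partner-use distribution from partner availability,
#' `d_i = sum_j p'_ij log(p'_ij / q_j)` with `q_j = A_j / m`.  It is
#' standardized to \[0, 1\] between the feasible minimum and maximum over
#' integer allocations of the taxon's `A_i` interactions across partners:
#' the maximum concentrates all interactions on the rarest partner (the
#' vertex of the simplex with smallest `q`, exact because the objective is
#' convex), and the minimum is found by exact greedy marginal allocation
#' (one interaction at a time to the partner with the smallest cost
#' increment, optimal for a separable convex objective).  `d' = 0` whenever
#' the feasible maximum equals the minimum.
#'
#' @inheritParams frequency_indices
#' @return data.frame with columns `taxon`, `d_raw`, `d_min`, `d_max`,
#'   `d_prime`.
#' @export
d_prime <- function(matrix, level = c("rows", "columns")) {
  m <- orient(matrix, level)
  A <- rowSums(m)
  if (any(A == 0)) nw_stop("d_prime: empty row for taxon ",
                           paste(rownames(m)[A == 0], collapse = ", "))
  q <- colSums(m) / sum(m)
  d_raw <- vapply(seq_len(nrow(m)), function(i) {
    p <- m[i, ] / A[i]
    keep <- p > 0
    sum(p[keep] * log(p[keep] / q[keep]))
  }, numeric(1))
  d_max <- vapply(A, function(a) log(1 / min(q)), numeric(1))
  d_min <- vapply(A, function(a) kl_min_allocation(a, q), numeric(1))
  dp <- ifelse(d_max - d_min <= 1e-12, 0,
               (d_raw - d_min) / (d_max - d_min))
  dp <- pmin(pmax(dp, 0), 1)
  data.frame(taxon = rownames(m), d_raw = d_raw, d_min = d_min,
             d_max = d_max, d_prime = dp, row.names = NULL,
             stringsAsFactors = FALSE)
}

# Minimum of sum_j (n_j/A) log((n_j/A)/q_j) over integer allocations
# sum n_j = A, by greedy marginal allocation (exact: the objective is
# separable and convex in n).
kl_min_allocation <- function(A, q) {
  J <- length(q)
  f <- function(n, j) if (n == 0) 0 else (n / A) * log(n / (A * q[j]))
  n <- integer(J)
  delta <- vapply(seq_len(J), function(j) f(1, j) - f(0, j), numeric(1))
  for (step in seq_len(A)) {
    j <- which.min(delta)
    n[j] <- n[j] + 1L
    delta[j] <- f(n[j] + 1L, j) - f(n[j], j)
  }
  sum(vapply(seq_len(J), function(j) f(n[j], j), numeric(1)))
}

#' One-mode projection of the bipartite network
#'
#' Two same-level taxa are linked if they share at least one interaction
#' partner with positive counts; the projection is unweighted and has no
#' self-loops.
#'
#' @inheritParams frequency_indices
#' @return An undirected [igraph][igraph::make_graph] graph whose vertices
#'   are the focal-level taxa.
#' @export
one_mode_projection <- function(matrix, level = c("rows", "columns")) {
  m <- orient(matrix, level)
  inc <- (m > 0) * 1
  adj <- (inc %*% t(inc)) > 0
  diag(adj) <- FALSE
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

#' Path-based role indices from the one-mode projection
#'
#' Betweenness is standard shortest-path betweenness centrality normalized
#' by `(n - 1) * (n - 2) / 2` (0 for all taxa when `n < 3`).  The node
#' specialization index (NSI) of a taxon is the mean shortest-path length
#' to all other *reachable* same-level taxa; unreachable pairs are excluded
#' from the mean with a warning, and a `reachable_all` flag records whether
#' any exclusion happened.
#'
#' @param projection an undirected igraph graph (see
#'   [one_mode_projection()]).
#' @return data.frame with columns `taxon`, `betweenness`, `nsi`,
#'   `reachable_all`.
#' @export
projection_indices <- function(projection) {
  n <- igraph::vcount(projection)
  taxa <- igraph::V(projection)$name
  btw <- if (n < 3) rep(0, n)
         else igraph::betweenness(projection, directed = FALSE,
                                  normalized = TRUE)
  D <- igraph::distances(projection)
  diag(D) <- NA
  reachable <- is.finite(D)
  nsi <- vapply(seq_len(n), function(i) {
    d <- D[i, reachable[i, ]]
    if (length(d) == 0) NA_real_ else mean(d)
  }, numeric(1))
  reach_all <- rowSums(!reachable, na.rm = TRUE) == 1  # only the diagonal
  if (n > 1 && any(!reach_all))
    warning("projection not connected; unreachable pairs excluded from NSI")
  data.frame(taxon = taxa, betweenness = as.numeric(btw), nsi = nsi,
             reachable_all = reach_all, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Species-level role indices for every taxon of both trophic levels
#'
#' Assembles the six indices of the realized Eltonian niche -- degree,
#' species strength, betweenness, partner diversity, node specialization
#' index and complementary specialization d' -- for the row (animal) and
#' column (plant) taxa of an interaction matrix.
#'
#' @param matrix interaction matrix (coerced with
#'   [as_interaction_matrix()]).
#' @return data.frame with one row per taxon: `taxon`, `trophic_level`,
#'   `degree`, `species_strength`, `betweenness`, `partner_diversity`,
#'   `nsi`, `d_prime`, `reachable_all`.
#' @export
#' @examples
#' m <- matrix(c(2, 1, 0, 1), 2, 2, dimnames = list(c("a1", "a2"),
#'                                                  c("p1", "p2")))
#' species_level(m)
species_level <- function(matrix) {
  matrix <- as_interaction_matrix(matrix)
  one <- function(level, label) {
    fi <- frequency_indices(matrix, level)
    dp <- d_prime(matrix, level)
    pi <- projection_indices(one_mode_projection(matrix, level))
    out <- merge(merge(fi, dp[, c("taxon", "d_prime")], by = "taxon"),
                 pi, by = "taxon")
    out$trophic_level <- label
    out
  }
  res <- rbind(one("rows", "animal"), one("columns", "plant"))
  res <- res[order(match(res$trophic_level, c("animal", "plant")),
                   res$taxon), ]
  rownames(res) <- NULL
  res[, c("taxon", "trophic_level", "degree", "species_strength",
          "betweenness", "partner_diversity", "nsi", "d_prime",
          "reachable_all")]
}
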