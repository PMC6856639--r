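#' The ten niche-position/role indices
#'
#' Column order of the index matrix relating the three niche types:
#' realized Grinnellian (environmental marginality and volume), fundamental
#' Eltonian (trait marginality and volume), realized Eltonian (the six
#' network roles).
#'
#' @export
niche_index_names <- c("grinnellian_marginality", "grinnellian_volume",
                       "trait_marginality", "trait_volume",
                       "degree", "species_strength", "betweenness",
                       "partner_diversity", "nsi", "d_prime")

#' Assemble the taxa-by-10-indices matrix
#'
#' Outer join on taxon of the two niche-space summaries (environment and
#' trait) and the network role table; taxa missing one niche type carry
#' `NA` in its columns (correlations are later computed pairwise-complete).
#'
#' @param grinnellian,trait data.frames from [niche_summaries()] (columns
#'   `taxon`, `marginality`, `volume`); either may be `NULL`.
#' @param roles data.frame from [species_level()] for one trophic level.
#' @return Numeric matrix, taxa (rows, named) x the 10 columns of
#'   [niche_index_names].
#' @export
assemble_index_matrix <- function(grinnellian, trait, roles) {
  pick <- function(df, cols, prefix) {
    if (is.null(df)) return(NULL)
    if (anyDuplicated(df$taxon))
      nw_stop("assemble_index_matrix: duplicate taxon rows")
    out <- df[, c("taxon", cols)]
    names(out)[-1] <- paste0(prefix, cols)
    out
  }
  parts <- list(pick(grinnellian, c("marginality", "volume"), "grinnellian_"),
                pick(trait, c("marginality", "volume"), "trait_"),
                pick(roles, c("degree", "species_strength", "betweenness",
                              "partner_diversity", "nsi", "d_prime"), ""))
  parts <- Filter(Negate(is.null), parts)
  merged <- Reduce(function(a, b) merge(a, b, by = "taxon", all = TRUE),
                   parts)
  m <- matrix(NA_real_, nrow(merged), length(niche_index_names),
              dimnames = list(merged$taxon, niche_index_names))
  for (cn in niche_index_names)
    if (cn %in% names(merged)) m[, cn] <- as.numeric(merged[[cn]])
  m
}

#' Pairwise Pearson correlations among index columns
#'
#' Pearson's product-moment correlation on pairwise-complete observations;
#' the two-sided p-value comes from `t = r * sqrt(n - 2) / sqrt(1 - r^2)`
#' against a Student-t reference with `n - 2` degrees of freedom.  Pairs
#' with fewer than `min_n` complete observations or zero variance are
#' skipped with a warning.
#'
#' @param index_matrix numeric matrix, taxa x indices.
#' @param min_n minimum pairwise-complete sample size (default 3).
#' @return data.frame with columns `index1`, `index2`, `r`, `t`, `p`, `n`.
#' @export
pairwise_correlations <- function(index_matrix, min_n = 3) {
  cols <- colnames(index_matrix)
  out <- list()
  for (i in seq_along(cols)[-length(cols)]) {
    for (j in seq((i + 1), length(cols))) {
      x <- index_matrix[, i]; y <- index_matrix[, j]
      keep <- complete.cases(x, y)
      n <- sum(keep)
      if (n < min_n) {
        warning(sprintf("pair %s/%s skipped: only %d complete observations",
                        cols[i], cols[j], n))
        next
      }
      if (sd(x[keep]) == 0 || sd(y[keep]) == 0) {
        warning(sprintf("pair %s/%s skipped: zero variance", cols[i],
                        cols[j]))
        next
      }
      r <- cor(x[keep], y[keep])
      res <- r_to_t(r, n)
      out[[length(out) + 1]] <- data.frame(index1 = cols[i],
                                           index2 = cols[j], r = r,
                                           t = res["t"], p = res["p"],
                                           n = n, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(index1 = character(), index2 = character(),
                      r = numeric(), t = numeric(), p = numeric(),
                      n = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# t statistic and two-sided p for a Pearson r at sample size n.
r_to_t <- function(r, n) {
  df <- n - 2
  t <- if (abs(r) >= 1) Inf * sign(r) else r * sqrt(df) / sqrt(1 - r^2)
  c(t = t, p = 2 * pt(-abs(t), df))
}

# r2 from t, guarding the perfect-correlation limit.
t_r2 <- function(t, df) ifelse(is.infinite(t), 1, t^2 / (t^2 + df))

#' Convert a t statistic to the coefficient of determination
#'
#' The algebraic identity `r^2 = t^2 / (t^2 + df)` linking a correlation
#' test statistic and its explained variance.
#'
#' @param t t statistic.
#' @param df degrees of freedom (`n - 2`).
#' @return r-squared.
#' @export
#' @examples
#' t_to_r2(4.296, 15)  # 0.552
t_to_r2 <- function(t, df) t_r2(t, df)

#' Significance-filtered r-squared-weighted correlation network
#'
#' One node per index; an edge joins two indices iff their correlation is
#' significant at `alpha` (two-sided, uncorrected), weighted by `r^2` with
#' the correlation sign kept as an edge attribute.
#'
#' @param correlations data.frame from [pairwise_correlations()].
#' @param alpha significance threshold (default 0.05).
#' @param nodes character vector of node names (default
#'   [niche_index_names]); isolated indices stay in the graph as isolated
#'   nodes.
#' @return An undirected igraph graph with edge attributes `weight`
#'   (`r^2`), `r` and `sign`.
#' @export
build_correlation_network <- function(correlations, alpha = 0.05,
                                      nodes = niche_index_names) {
  sig <- correlations[!is.na(correlations$p) & correlations$p < alpha, ,
                      drop = FALSE]
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (nrow(sig)) {
    g <- igraph::add_edges(g, rbind(match(sig$index1, nodes),
                                    match(sig$index2, nodes)))
    g <- igraph::set_edge_attr(g, "weight", value = sig$r^2)
    g <- igraph::set_edge_attr(g, "r", value = sig$r)
    g <- igraph::set_edge_attr(g, "sign", value = sign(sig$r))
  }
  g
}

#' Greedy weighted-modularity partition
#'
#' Agglomerative Clauset-Newman-Moore-style community detection on edge
#' weights: starting from singleton communities, repeatedly merge the pair
#' of connected communities with the largest modularity gain, all the way
#' to a single community, and keep the partition with the highest
#' modularity seen along the merge path.  A local refinement pass then
#' moves single nodes between communities while any move improves
#' modularity (a Kernighan-Lin-style polish that repairs the occasional
#' greedy misstep on small graphs).  Isolated nodes form singleton
#' modules; an edgeless network has `Q = 0` by convention.
#'
#' @param network an undirected igraph graph with a `weight` edge attribute
#'   (unweighted graphs get weight 1).
#' @param exact_max_n up to this many vertices the optimum partition is
#'   found by exhaustive search over all set partitions; beyond it the
#'   greedy agglomeration with refinement is used.
#' @return List with `membership` (named integer vector) and `Q`.
#' @export
modularity_partition <- function(network, exact_max_n = 8) {
  n <- igraph::vcount(network)
  nodes <- igraph::V(network)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  if (igraph::ecount(network) == 0)
    return(list(membership = setNames(seq_len(n), nodes), Q = 0))
  W <- igraph::as_adjacency_matrix(network, attr =
    if ("weight" %in% igraph::edge_attr_names(network)) "weight" else NULL,
    sparse = FALSE)
  if (n <= exact_max_n) {
    best <- exact_partition(W)
    memb <- as.integer(factor(best$membership,
                              levels = unique(best$membership)))
    return(list(membership = setNames(memb, nodes), Q = best$Q))
  }
  comm <- seq_len(n)
  best <- list(membership = comm, Q = weighted_modularity(W, comm))
  repeat {
    labs <- sort(unique(comm))
    if (length(labs) == 1) break
    gain_best <- -Inf; pick <- NULL
    for (ai in seq_along(labs)[-length(labs)]) {
      for (bi in seq((ai + 1), length(labs))) {
        a <- labs[ai]; b <- labs[bi]
        if (sum(W[comm == a, comm == b, drop = FALSE]) == 0) next
        trial <- comm; trial[trial == b] <- a
        gain <- weighted_modularity(W, trial)
        if (gain > gain_best + 1e-12) { gain_best <- gain; pick <- c(a, b) }
      }
    }
    if (is.null(pick)) break  # remaining communities disconnected
    comm[comm == pick[2]] <- pick[1]
    if (gain_best > best$Q + 1e-12)
      best <- list(membership = comm, Q = gain_best)
  }
  best <- refine_partition(W, best)
  memb <- as.integer(factor(best$membership,
                            levels = unique(best$membership)))
  list(membership = setNames(memb, nodes), Q = best$Q)
}

# Exhaustive maximization over all set partitions (restricted growth
# strings); feasible for small vertex counts only.
exact_partition <- function(W) {
  n <- nrow(W)
  best <- list(membership = rep(1L, n), Q = weighted_modularity(W, rep(1L, n)))
  rec <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      q <- weighted_modularity(W, prefix)
      if (q > best$Q + 1e-15) best <<- list(membership = prefix, Q = q)
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1L))
      rec(c(prefix, lab), max(maxlab, lab))
  }
  rec(integer(0), 0L)
  best
}

# Single-node and node-pair moves (including into a fresh singleton
# community) until no move raises modularity.
refine_partition <- function(W, best) {
  n <- nrow(W)
  groups <- c(as.list(seq_len(n)),
              if (n >= 2) combn(n, 2, simplify = FALSE))
  repeat {
    improved <- FALSE
    for (vs in groups) {
      targets <- setdiff(unique(c(best$membership,
                                  max(best$membership) + 1)),
                         unique(best$membership[vs]))
      for (tc in targets) {
        trial <- best$membership
        trial[vs] <- tc
        q <- weighted_modularity(W, trial)
        if (q > best$Q + 1e-12) {
          best <- list(membership = trial, Q = q)
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  best
}

# Newman weighted modularity of a membership vector given the (symmetric)
# weight matrix: Q = sum_c (w_c/W - (s_c/2W)^2), W = total edge weight.
weighted_modularity <- function(W, membership) {
  tw <- sum(W) / 2
  if (tw == 0) return(0)
  deg <- rowSums(W)
  Q <- 0
  for (c in unique(membership)) {
    in_c <- membership == c
    Q <- Q + sum(W[in_c, in_c]) / (2 * tw) - (sum(deg[in_c]) / (2 * tw))^2
  }
  Q
}

#' Eigenvalue-variance integration index
#'
#' The integration of a set of indices is the variance of the eigenvalues
#' of their correlation matrix (population variance over the N
#' eigenvalues); it equals `(N - 1)` times the mean squared off-diagonal
#' correlation.  The sample-size-corrected value subtracts the expectation
#' under independence, `(N - 1) / (n_effective - 1)`, floored at 0.
#'
#' @param correlation_matrix full symmetric N x N correlation matrix; `NA`
#'   off-diagonal cells (pairs that could not be computed) are imputed as 0
#'   with a warning.
#' @param n_effective effective sample size (e.g. the median pairwise n).
#' @return List with `raw` and `corrected`.
#' @export
#' @examples
#' R <- matrix(c(1, 0.5, 0.5, 1), 2)
#' integration_index(R, n_effective = 21)  # raw 0.25, corrected 0.20
integration_index <- function(correlation_matrix, n_effective) {
  R <- as.matrix(correlation_matrix)
  if (nrow(R) != ncol(R) ||
      !isTRUE(all.equal(R, t(R), check.attributes = FALSE,
                        tolerance = 1e-8)))
    nw_stop("integration_index: correlation matrix must be symmetric")
  diag(R) <- 1
  if (anyNA(R)) {
    warning("integration_index: NA correlations imputed as 0")
    R[is.na(R)] <- 0
  }
  ev <- eigen((R + t(R)) / 2, symmetric = TRUE, only.values = TRUE)$values
  raw <- mean((ev - mean(ev))^2)
  corrected <- raw
  if (!missing(n_effective) && is_number(n_effective) && n_effective > 1)
    corrected <- max(0, raw - (nrow(R) - 1) / (n_effective - 1))
  list(raw = raw, corrected = corrected)
}

#' Cross-scale correlation of indices over shared taxa
#'
#' For each of the 10 indices, Pearson correlation between the values a
#' taxon obtains at the local and at the regional scale, reported as `t`,
#' `df`, `p` and `r^2` (the layout of the study's scale-comparison table).
#'
#' @param local_matrix,regional_matrix index matrices (taxa x indices) for
#'   the two scales.
#' @param min_n minimum shared-taxon sample size per index (default 3).
#' @return data.frame with columns `index`, `t`, `df`, `p`, `r2`, `n`;
#'   indices with too few shared taxa carry `NA` statistics.
#' @export
cross_scale_correlation <- function(local_matrix, regional_matrix,
                                    min_n = 3) {
  shared <- intersect(rownames(local_matrix), rownames(regional_matrix))
  cols <- intersect(colnames(local_matrix), colnames(regional_matrix))
  rows <- lapply(cols, function(cn) {
    x <- local_matrix[shared, cn]; y <- regional_matrix[shared, cn]
    keep <- complete.cases(x, y)
    n <- sum(keep)
    if (n < min_n || sd(x[keep]) == 0 || sd(y[keep]) == 0)
      return(data.frame(index = cn, t = NA_real_, df = NA_integer_,
                        p = NA_real_, r2 = NA_real_, n = n,
                        stringsAsFactors = FALSE))
    r <- cor(x[keep], y[keep])
    res <- r_to_t(r, n)
    data.frame(index = cn, t = unname(res["t"]), df = n - 2L,
               p = unname(res["p"]), r2 = r^2,
               n = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlation of indices with interaction frequency
#'
#' Pearson correlation of each index column with the taxa's total number of
#' interactions, with a significance flag at `alpha` (the layout of the
#' study's abundance table).
#'
#' @param totals named numeric vector of total interactions per taxon.
#' @param index_matrix taxa x indices matrix.
#' @param alpha significance threshold for the flag.
#' @return data.frame with columns `index`, `r`, `p`, `n`, `significant`.
#' @export
abundance_correlation <- function(totals, index_matrix, alpha = 0.05) {
  taxa <- intersect(names(totals), rownames(index_matrix))
  rows <- lapply(colnames(index_matrix), function(cn) {
    x <- totals[taxa]; y <- index_matrix[taxa, cn]
    keep <- complete.cases(x, y)
    n <- sum(keep)
    if (n < 3 || sd(x[keep]) == 0 || sd(y[keep]) == 0) {
      warning(sprintf("abundance_correlation: index %s skipped", cn))
      return(data.frame(index = cn, r = NA_real_, p = NA_real_, n = n,
                        significant = NA, stringsAsFactors = FALSE))
    }
    r <- cor(x[keep], y[keep])
    res <- r_to_t(r, n)
    data.frame(index = cn, r = r, p = unname(res["p"]), n = n,
               significant = unname(res["p"]) < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full correlation matrix from the pairwise table
#'
#' @param correlations data.frame from [pairwise_correlations()].
#' @param nodes index names (default [niche_index_names]).
#' @return Symmetric matrix with `NA` for missing pairs and unit diagonal.
#' @export
correlation_matrix <- function(correlations, nodes = niche_index_names) {
  R <- matrix(NA_real_, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  diag(R) <- 1
  for (k in seq_len(nrow(correlations))) {
    i <- correlations$index1[k]; j <- correlations$index2[k]
    R[i, j] <- R[j, i] <- correlations$r[k]
  }
  R
}
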