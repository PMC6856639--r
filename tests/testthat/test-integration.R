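fake_summary <- function(taxa, seed = 1) {
  set.seed(seed)
  data.frame(taxon = taxa, marginality = runif(length(taxa)),
             volume = runif(length(taxa)))
}

fake_roles <- function(taxa, seed = 2) {
  set.seed(seed)
  data.frame(taxon = taxa, degree = sample(1:5, length(taxa), TRUE),
             species_strength = runif(length(taxa), 0, 2),
             betweenness = runif(length(taxa)),
             partner_diversity = runif(length(taxa), 0, 1.5),
             nsi = runif(length(taxa), 1, 2),
             d_prime = runif(length(taxa)))
}

test_that("the index matrix outer-joins niche types with NA for missing taxa", {
  g <- fake_summary(c("a", "b"))
  tr <- fake_summary(c("a", "b", "c"), seed = 3)
  ro <- fake_roles(c("b", "c", "d"))
  im <- assemble_index_matrix(g, tr, ro)
  expect_setequal(rownames(im), c("a", "b", "c", "d"))
  expect_equal(colnames(im), niche_index_names)
  expect_true(is.na(im["d", "grinnellian_marginality"]))
  expect_true(is.na(im["a", "degree"]))
  expect_false(anyNA(im["b", ]))

  im2 <- assemble_index_matrix(fake_summary("x"), NULL,
                               fake_roles("y"))
  expect_true(all(is.na(im2["x", c("degree", "trait_marginality")])))

  expect_error(assemble_index_matrix(fake_summary(c("a", "a")), tr, ro),
               "duplicate")
  full <- assemble_index_matrix(fake_summary(c("a", "b")),
                                fake_summary(c("a", "b"), 4),
                                fake_roles(c("a", "b")))
  expect_false(anyNA(full))
})

test_that("pairwise Pearson correlations carry exact t-based p-values", {
  im <- cbind(x = c(1, 2, 3), y = c(1, 2, 4))
  pc <- pairwise_correlations(im)
  expect_equal(pc$r, 0.981981, tolerance = 1e-5)
  expect_equal(pc$n, 3L)
  # cross-check p against R's reference implementation
  ct <- cor.test(im[, 1], im[, 2])
  expect_equal(pc$p, ct$p.value, tolerance = 1e-10)

  same <- cbind(a = 1:5, b = 1:5)
  expect_equal(pairwise_correlations(same)$r, 1)

  expect_warning(pairwise_correlations(cbind(a = c(1, 1, 1), b = 1:3)),
                 "zero variance")
  expect_warning(pairwise_correlations(cbind(a = c(1, NA, NA, 2),
                                             b = c(1, 2, 3, NA))),
                 "complete observations")
})

test_that("t-to-r2 conversion obeys the identity r2 = t2/(t2+df)", {
  set.seed(8)
  for (k in 1:20) {
    x <- rnorm(12); y <- rnorm(12) + 0.5 * x
    ct <- cor.test(x, y)
    expect_equal(t_to_r2(unname(ct$statistic), unname(ct$parameter)),
                 unname(ct$estimate)^2, tolerance = 1e-10)
  }
})

test_that("correlation networks keep only significant edges weighted by r2", {
  cors <- data.frame(index1 = c("degree", "nsi"),
                     index2 = c("d_prime", "betweenness"),
                     r = c(0.9, 0.5), t = NA, p = c(0.01, 0.2), n = 10)
  g <- build_correlation_network(cors, alpha = 0.05)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 0.81)
  expect_equal(igraph::E(g)$sign, 1)
  expect_equal(igraph::vcount(g), 10)

  all_sig <- do.call(rbind, lapply(1:9, function(i)
    do.call(rbind, lapply((i + 1):10, function(j)
      data.frame(index1 = niche_index_names[i],
                 index2 = niche_index_names[j],
                 r = 0.8, t = NA, p = 0.001, n = 10)))))
  expect_equal(igraph::ecount(build_correlation_network(all_sig)), 45)
})

test_that("greedy modularity equals the exhaustive optimum on small graphs", {
  # two disconnected triangles
  W <- matrix(0, 6, 6)
  for (e in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)))
    W[e[1], e[2]] <- W[e[2], e[1]] <- 1
  g <- igraph::graph_from_adjacency_matrix(W, "undirected", weighted = TRUE)
  part <- modularity_partition(g)
  oracle <- best_partition_oracle(W)
  expect_equal(part$Q, oracle$Q, tolerance = 1e-12)
  expect_equal(length(unique(part$membership)), 2)
  expect_equal(unname(part$membership[1:3]),
               unname(rep(part$membership[1], 3)))

  # complete equal-weight graph: optimum is one module, Q = 0
  K <- matrix(1, 5, 5); diag(K) <- 0
  gk <- igraph::graph_from_adjacency_matrix(K, "undirected", weighted = TRUE)
  pk <- modularity_partition(gk)
  expect_equal(pk$Q, best_partition_oracle(K)$Q, tolerance = 1e-12)
  expect_equal(length(unique(pk$membership)), 1)

  # weighted random graphs, n <= 7: exact path equals the oracle, and the
  # greedy path never exceeds it
  set.seed(13)
  for (rep in 1:5) {
    n <- sample(4:7, 1)
    A <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (runif(1) < 0.5) A[i, j] <- A[j, i] <- runif(1)
    if (sum(A) == 0) next
    ga <- igraph::graph_from_adjacency_matrix(A, "undirected",
                                              weighted = TRUE)
    q_oracle <- best_partition_oracle(A)$Q
    expect_equal(modularity_partition(ga)$Q, q_oracle, tolerance = 1e-9)
    expect_lte(modularity_partition(ga, exact_max_n = 0)$Q,
               q_oracle + 1e-9)
  }

  # greedy path on a 10-node graph with a known analytic optimum:
  # two disconnected 5-cliques split into their cliques with Q = 1/2
  C2 <- matrix(0, 10, 10)
  C2[1:5, 1:5] <- 1; C2[6:10, 6:10] <- 1; diag(C2) <- 0
  gc2 <- igraph::graph_from_adjacency_matrix(C2, "undirected",
                                             weighted = TRUE)
  pc2 <- modularity_partition(gc2)       # 10 nodes: greedy + refinement
  expect_equal(pc2$Q, 0.5, tolerance = 1e-12)
  expect_equal(length(unique(pc2$membership)), 2)

  # single edge and edgeless conventions
  g1 <- igraph::make_graph(c("u", "v"), directed = FALSE)
  p1 <- modularity_partition(g1)
  expect_equal(length(unique(p1$membership)), 1)
  ge <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(ge)$name <- c("x", "y", "z")
  pe <- modularity_partition(ge)
  expect_equal(pe$Q, 0)
  expect_equal(length(unique(pe$membership)), 3)
})

test_that("integration is the eigenvalue variance with finite-sample correction", {
  expect_equal(integration_index(diag(4), 10)$raw, 0)

  R <- matrix(c(1, 0.5, 0.5, 1), 2)
  ii <- integration_index(R, n_effective = 21)
  expect_equal(ii$raw, 0.25)                # eigenvalues 1.5 and 0.5
  expect_equal(ii$corrected, 0.25 - 1 / 20)

  set.seed(17)
  for (k in 1:10) {
    N <- sample(3:10, 1)
    R <- random_correlation(N)
    ii <- integration_index(R, 50)
    off <- R[upper.tri(R)]
    expect_equal(ii$raw, (N - 1) * mean(off^2) * 1, tolerance = 1e-10)
  }

  expect_error(integration_index(matrix(c(1, 0.2, 0.5, 1), 2), 10),
               "symmetric")
  expect_warning(
    ii_na <- integration_index(matrix(c(1, NA, NA, 1), 2), 10), "imputed")
  expect_equal(ii_na$raw, 0)
})

test_that("corrected integration of pure noise is centred on zero", {
  set.seed(19)
  vals <- replicate(200, {
    im <- matrix(rnorm(30 * 10), 30, 10)
    R <- cor(im)
    integration_index(R, 30)$raw - (10 - 1) / (30 - 1)
  })
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 3 * se + 0.01)
})

test_that("cross-scale correlations report t, df, p and r2 per index", {
  set.seed(23)
  loc <- matrix(rnorm(17 * 10), 17,
                dimnames = list(sprintf("t%02d", 1:17), niche_index_names))
  reg <- loc + matrix(rnorm(17 * 10, 0, 0.5), 17)
  rownames(reg) <- rownames(loc)
  cs <- cross_scale_correlation(loc, reg)
  expect_equal(cs$df, rep(15L, 10))
  expect_equal(cs$r2, t_to_r2(cs$t, cs$df), tolerance = 1e-12)

  ident <- cross_scale_correlation(loc, loc)
  expect_equal(ident$r2, rep(1, 10))

  anti <- cross_scale_correlation(loc, -loc)
  expect_equal(anti$r2, rep(1, 10))
  expect_true(all(anti$t < 0))

  few <- cross_scale_correlation(loc[1:2, , drop = FALSE],
                                 reg[1:2, , drop = FALSE])
  expect_true(all(is.na(few$p)))
})

test_that("interaction-frequency correlations behave and are label-invariant", {
  set.seed(29)
  taxa <- sprintf("t%02d", 1:15)
  degree <- sample(1:10, 15, TRUE)
  im <- matrix(NA_real_, 15, 10, dimnames = list(taxa, niche_index_names))
  im[, "degree"] <- degree
  im[, "d_prime"] <- runif(15)
  totals <- setNames(degree * 20 + rpois(15, 3), taxa)
  # columns that are all-NA or constant are flagged
  expect_warning(abundance_correlation(totals, im[, c("degree", "nsi")]),
                 "nsi")
  ac <- suppressWarnings(abundance_correlation(totals, im))
  expect_gt(ac$r[ac$index == "degree"], 0.9)
  expect_true(ac$significant[ac$index == "degree"])

  perm <- sample(15)
  ac2 <- suppressWarnings(abundance_correlation(totals[perm], im[perm, ]))
  expect_equal(ac$r, ac2$r, tolerance = 1e-12)
})
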