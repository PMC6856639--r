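test_that("frequency indices match hand-computed values on the toy matrix", {
  fi <- frequency_indices(toy_matrix(), "rows")
  expect_equal(fi$degree, c(1L, 2L))
  expect_equal(fi$species_strength, c(2 / 3, 1 / 3 + 1))
  expect_equal(fi$partner_diversity, c(0, log(2)))

  # dependencies sum to 1 per partner: strengths sum to the number of
  # plant columns with positive totals
  set.seed(5)
  m <- matrix(rpois(30, 2), 5, 6,
              dimnames = list(paste0("a", 1:5), paste0("p", 1:6)))
  m <- m[, colSums(m) > 0, drop = FALSE]
  m <- m[rowSums(m) > 0, , drop = FALSE]
  expect_equal(sum(frequency_indices(m, "rows")$species_strength), ncol(m))

  one <- matrix(3L, 1, 1, dimnames = list("a", "p"))
  fi1 <- frequency_indices(one, "rows")
  expect_equal(unlist(fi1[, -1], use.names = FALSE), c(1, 1, 0))
})

test_that("d' hits its analytic extremes", {
  even <- matrix(1L, 2, 2, dimnames = list(c("a1", "a2"), c("p1", "p2")))
  expect_equal(d_prime(even, "rows")$d_prime, c(0, 0))

  excl <- matrix(c(2L, 0L, 0L, 2L), 2, 2,
                 dimnames = list(c("a1", "a2"), c("p1", "p2")))
  expect_equal(d_prime(excl, "rows")$d_prime, c(1, 1))
  expect_equal(d_prime(excl, "columns")$d_prime, c(1, 1))

  single <- matrix(c(2L, 3L), 2, 1,
                   dimnames = list(c("a1", "a2"), "p1"))
  expect_equal(d_prime(single, "rows")$d_prime, c(0, 0))
})

test_that("d' min/max allocations agree with exhaustive enumeration", {
  set.seed(11)
  for (J in 2:4) {
    for (rep in 1:5) {
      q <- as.vector(rmultinom(1, 20, runif(J) + 0.2)) + 1
      q <- q / sum(q)
      for (A in c(1, 3, 7, 12)) {
        ex <- kl_extremes_exhaustive(A, q)
        expect_equal(nicheweb:::kl_min_allocation(A, q), unname(ex["min"]),
                     tolerance = 1e-12)
        expect_equal(log(1 / min(q)), unname(ex["max"]), tolerance = 1e-12)
      }
    }
  }
})

test_that("one-mode projection links taxa sharing at least one partner", {
  m <- matrix(c(1, 1, 0, 0, 1, 1), 3, 2,
              dimnames = list(c("a1", "a2", "a3"), c("p1", "p2")))
  g <- one_mode_projection(m, "rows")
  el <- igraph::as_edgelist(g)
  expect_equal(nrow(el), 2)
  expect_true(all(apply(el, 1, paste, collapse = "-") %in%
                    c("a1-a2", "a2-a3")))

  diag3 <- diag(3)
  dimnames(diag3) <- list(paste0("a", 1:3), paste0("p", 1:3))
  expect_equal(igraph::ecount(one_mode_projection(diag3, "rows")), 0)

  allone <- matrix(1, 4, 1, dimnames = list(paste0("a", 1:4), "p"))
  expect_equal(igraph::ecount(one_mode_projection(allone, "rows")),
               choose(4, 2))
})

test_that("betweenness and NSI follow shortest-path enumeration", {
  m <- matrix(c(1, 1, 0, 0, 1, 1), 3, 2,
              dimnames = list(c("a1", "a2", "a3"), c("p1", "p2")))
  pi <- projection_indices(one_mode_projection(m, "rows"))
  expect_equal(pi$betweenness, c(0, 1, 0))
  expect_equal(pi$nsi, c(1.5, 1, 1.5))
  expect_true(all(pi$reachable_all))

  two <- matrix(1, 2, 1, dimnames = list(c("a1", "a2"), "p"))
  expect_equal(projection_indices(one_mode_projection(two, "rows"))$betweenness,
               c(0, 0))

  full <- matrix(1, 4, 1, dimnames = list(paste0("a", 1:4), "p"))
  pif <- projection_indices(one_mode_projection(full, "rows"))
  expect_equal(pif$betweenness, rep(0, 4))
  expect_equal(pif$nsi, rep(1, 4))
})

test_that("NSI excludes unreachable taxa with a warning and flags them", {
  m <- matrix(c(1, 1, 0, 0, 0, 1), 3, 2,
              dimnames = list(paste0("a", 1:3), paste0("p", 1:2)))
  # a1-a2 share p1; a3 visits only p2 and shares nothing
  g <- one_mode_projection(m, "rows")
  expect_warning(pi <- projection_indices(g), "not connected")
  expect_equal(pi$nsi[1:2], c(1, 1))
  expect_true(is.na(pi$nsi[3]))
  expect_false(any(pi$reachable_all))
})

test_that("tree-projection betweenness is consistent with path counting", {
  # star a2 center with leaves a1, a3, a4: all shortest leaf-leaf paths
  # pass through a2
  m <- matrix(c(1, 1, 0, 0,
                0, 1, 1, 0,
                0, 1, 0, 1), 4, 3,
              dimnames = list(paste0("a", 1:4), paste0("p", 1:3)))
  pi <- projection_indices(one_mode_projection(m, "rows"))
  n <- 4
  interior_pairs <- choose(3, 2)              # leaf pairs routed via a2
  expect_equal(sum(pi$betweenness) * (n - 1) * (n - 2) / 2, interior_pairs)
})

test_that("species_level assembles all six indices for both levels", {
  sl <- species_level(toy_matrix())
  expect_setequal(sl$taxon, c("a1", "a2", "p1", "p2"))
  a <- sl[sl$trophic_level == "animal", ]
  expect_equal(a$degree, c(1L, 2L))
  expect_equal(a$species_strength, c(2 / 3, 4 / 3))
  expect_equal(a$partner_diversity, c(0, log(2)))
  p <- sl[sl$trophic_level == "plant", ]
  expect_equal(p$degree, c(2L, 1L))

  # permuting rows permutes labels but not values
  perm <- toy_matrix()[c(2, 1), ]
  sl2 <- species_level(perm)
  expect_equal(sl2[order(sl2$taxon), ], sl[order(sl$taxon), ],
               ignore_attr = TRUE)

  # all-zero column dropped with a warning
  m0 <- cbind(toy_matrix(), p3 = c(0L, 0L))
  expect_warning(sl3 <- species_level(m0), "p3")
  expect_false("p3" %in% sl3$taxon)
})

test_that("proportion-based indices are invariant to count scaling", {
  set.seed(7)
  m <- matrix(rpois(20, 3), 4, 5,
              dimnames = list(paste0("a", 1:4), paste0("p", 1:5)))
  m <- m[rowSums(m) > 0, colSums(m) > 0]
  s1 <- species_level(m)
  s3 <- species_level(m * 5L)
  for (cn in c("degree", "species_strength", "partner_diversity",
               "betweenness", "nsi"))
    expect_equal(s1[[cn]], s3[[cn]], tolerance = 1e-12)
  # d' raw KL part is scale-free; the integer min/max standardization uses
  # the actual totals, so compare the raw divergences
  expect_equal(d_prime(m, "rows")$d_raw, d_prime(m * 5L, "rows")$d_raw)
})
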