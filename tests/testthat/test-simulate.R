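test_that("sites are evenly spaced, seeded, and aspects fold to [0, 180]", {
  cfg <- sim_config(n_sites = 8, temp_range = c(5, 15), temp_noise_sd = 0,
                    seed = 1)
  st <- generate_sites(cfg, "regional")
  expect_equal(st$temperature, seq(5, 15, length.out = 8))

  cfg2 <- sim_config(n_sites = 30, seed = 7)
  st2 <- generate_sites(cfg2, "regional")
  expect_true(all(st2$aspect >= 0 & st2$aspect <= 180))
  expect_false(anyDuplicated(st2$site_id) > 0)

  expect_identical(generate_sites(cfg2, "regional"),
                   generate_sites(cfg2, "regional"))
  expect_error(sim_config(n_sites = 1), class = "nicheweb_config_error")
})

test_that("abundance surfaces peak at the optimum and flatten as breadth grows", {
  cfg <- sim_config(seed = 1)
  sites <- data.frame(site_id = c("s1", "s2", "s3"), scale = "regional",
                      temperature = c(5, 10, 15), aspect = c(90, 90, 90))
  taxa <- data.frame(taxon_id = "t1", trophic_level = "plant",
                     opt_temperature = 10, opt_aspect = 90,
                     breadth_temperature = 2, breadth_aspect = 60,
                     baseline_abundance = 5)
  mu <- nicheweb:::expected_abundance(taxa, sites)
  expect_equal(unname(which.max(mu[1, ])), 2)

  taxa$breadth_temperature <- 1e9
  taxa$breadth_aspect <- 1e9
  mu_flat <- nicheweb:::expected_abundance(taxa, sites)
  expect_equal(max(mu_flat) - min(mu_flat), 0, tolerance = 1e-9)

  expect_error(generate_abundances(taxa, sites[0, ], seed = 1),
               "empty site")
})

test_that("realized counts are Poisson around the Gaussian response mean", {
  sites <- data.frame(site_id = c("s1", "s2"), scale = "regional",
                      temperature = c(10, 14.292), aspect = c(90, 90))
  # breadth 2: site 2 sits where the kernel is exp(-0.5*(4.292/2)^2) = 0.1
  taxa <- data.frame(taxon_id = "t1", trophic_level = "plant",
                     opt_temperature = 10, opt_aspect = 90,
                     breadth_temperature = 2, breadth_aspect = 1e9,
                     baseline_abundance = 5)
  mu <- nicheweb:::expected_abundance(taxa, sites)
  draws <- t(sapply(1:1000, function(s) generate_abundances(taxa, sites,
                                                            seed = s)[1, ]))
  for (p in 1:2) {
    se <- sqrt(mu[1, p] / 1000)
    expect_lt(abs(mean(draws[, p]) - mu[1, p]), 3 * se)
  }
})

test_that("interaction rates reduce to abundance products when uncoupled", {
  cfg <- sim_config(n_plants = 3, n_animals = 2, coupling_theta = 0,
                    matching_gamma = 0, total_interactions = 50, seed = 5)
  pa <- matrix(c(3L, 1L, 0L, 2L, 2L, 2L), 3, 2,
               dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  aa <- matrix(c(4L, 1L, 0L, 3L), 2, 2,
               dimnames = list(c("a1", "a2"), c("s1", "s2")))
  gi <- generate_interactions(pa, aa, positions = NULL, traits = NULL,
                              cfg, seed = 9)
  expect_equal(gi$rates, outer(rowSums(aa), rowSums(pa)))

  gi2 <- generate_interactions(pa, aa, positions = NULL, traits = NULL,
                               cfg, seed = 9)
  expect_identical(gi$matrix, gi2$matrix)
  expect_identical(gi$per_site, gi2$per_site)

  expect_error(generate_interactions(0 * pa, aa, NULL, NULL, cfg, seed = 1),
               "no co-occurring")
})

test_that("aggregate matrix margins equal sums of per-site margins", {
  cfg <- sim_config(n_plants = 6, n_animals = 4, seed = 11)
  sim <- simulate_community(cfg, scales = "regional")
  long <- sim$interactions
  agg <- tapply(long$count, list(long$animal, long$plant), sum,
                default = 0L)
  per_animal <- tapply(long$count, long$animal, sum)
  expect_equal(as.vector(rowSums(agg)[names(per_animal)]),
               as.vector(per_animal))
  expect_equal(sum(agg), cfg$total_interactions)
})

test_that("strong coupling starves environmentally mismatched pairs", {
  cfg <- sim_config(n_plants = 2, n_animals = 2, coupling_theta = 25,
                    matching_gamma = 0, total_interactions = 100, seed = 1)
  # one plant-animal pair at each gradient extreme
  pos <- list(plants = rbind(p1 = c(0.05, 0.1), p2 = c(0.95, 0.9)),
              animals = rbind(a1 = c(0.05, 0.1), a2 = c(0.95, 0.9)))
  pa <- matrix(5L, 2, 2, dimnames = list(c("p1", "p2"), c("s1", "s2")))
  aa <- matrix(5L, 2, 2, dimnames = list(c("a1", "a2"), c("s1", "s2")))
  cross <- sapply(1:500, function(s) {
    m <- generate_interactions(pa, aa, pos, NULL, cfg, seed = s)$matrix
    (m["a1", "p2"] + m["a2", "p1"]) / sum(m)
  })
  expect_lt(mean(cross), 0.05)
})

test_that("the simulated raw tables pass input validation and emulate the field format", {
  sim <- simulate_community(sim_config(n_plants = 6, n_animals = 4,
                                       seed = 21))
  report <- validate_inputs(sim[c("sites", "cover", "traits",
                                  "interactions", "pollen", "taxonomy")])
  expect_equal(nrow(report), 0)
  expect_true(all(c("regional", "local") %in% sim$sites$scale))
  # symbolic Braun-Blanquet codes round-trip through the parser
  expect_true(all(convert_cover(sim$cover$cover) > 0))
  # non-pollinator families exist and fail the pollen filter
  kept <- filter_pollinators(sim$pollen, sim$taxonomy)
  expect_lt(length(kept), sim$config$n_animals)
})
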