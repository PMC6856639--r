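#' Configuration for the synthetic community generator
#'
#' Bundles and validates every knob of the synthetic plant--flower-visitor
#' community.  The defaults describe an alpine study design: a regional
#' elevational gradient of 8 sites spanning 5--15 degrees C of mean seasonal
#' soil temperature, and a local set of 30 plots within a single meadow
#' spanning a narrow microclimatic range, with aspect folded onto a 0--180
#' degree north--south axis at both scales.
#'
#' @param n_sites number of regional sites (transects); at least 2.
#' @param n_sites_local number of local plots; at least 2.
#' @param n_plants number of plant species.
#' @param n_animals number of animal taxa (families).
#' @param species_per_family number of insect species pooled into each family.
#' @param temp_range numeric length 2, regional mean seasonal temperature
#'   range in degrees C.
#' @param temp_range_local numeric length 2, local (microclimatic) range.
#' @param temp_noise_sd standard deviation of site-level noise added to the
#'   evenly spaced temperatures (degrees C).
#' @param temp_breadth,aspect_breadth default Gaussian niche breadths of the
#'   taxa on the temperature (degrees C) and aspect (degrees) axes.
#' @param coupling_theta strength (>= 0) of the environment-distance penalty
#'   on interaction rates; 0 makes interactions environment-independent.
#' @param matching_gamma strength (>= 0, per mm) of the trait-matching
#'   penalty on |proboscis length - nectar depth|.
#' @param strict_matching logical; if `TRUE`, links with proboscis shorter
#'   than the nectar tube are forbidden outright.
#' @param total_interactions total number of interaction events allocated
#'   over (site, animal, plant) cells at each scale.
#' @param n_nonpollinators number of animal families generated with pollen
#'   loads too small to pass the pollinator filter (mean category <= 1).
#' @param seed integer master seed; every stream of randomness is derived
#'   from it (see Details).
#'
#' @details All randomness flows from `seed` through a fixed stream-splitting
#' rule: stage `k` of the generator reseeds with
#' `(seed + 1000003 * k) mod (2^31 - 1)`, so adding or reordering draws in
#' one stage never perturbs another.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_plants = 6, n_animals = 4, seed = 42)
#' cfg$coupling_theta
sim_config <- function(n_sites = 8, n_sites_local = 30,
                       n_plants = 12, n_animals = 8, species_per_family = 2,
                       temp_range = c(5, 15), temp_range_local = c(8, 12),
                       temp_noise_sd = 0.3,
                       temp_breadth = 3, aspect_breadth = 60,
                       coupling_theta = 2, matching_gamma = 0.3,
                       strict_matching = FALSE,
                       total_interactions = 1000, n_nonpollinators = 1,
                       seed = 1L) {
  cfg <- list(n_sites = as.integer(n_sites),
              n_sites_local = as.integer(n_sites_local),
              n_plants = as.integer(n_plants),
              n_animals = as.integer(n_animals),
              species_per_family = as.integer(species_per_family),
              temp_range = as.numeric(temp_range),
              temp_range_local = as.numeric(temp_range_local),
              temp_noise_sd = temp_noise_sd,
              temp_breadth = temp_breadth, aspect_breadth = aspect_breadth,
              coupling_theta = coupling_theta,
              matching_gamma = matching_gamma,
              strict_matching = isTRUE(strict_matching),
              total_interactions = as.integer(total_interactions),
              n_nonpollinators = as.integer(n_nonpollinators),
              seed = as.integer(seed))
  with(cfg, {
    if (n_sites < 2 || n_sites_local < 2)
      nw_stop("invalid config: need at least 2 sites per scale",
              class = "nicheweb_config_error")
    if (n_plants < 1 || n_animals < 1 || species_per_family < 1 ||
        total_interactions < 1)
      nw_stop("invalid config: counts must be >= 1",
              class = "nicheweb_config_error")
    if (coupling_theta < 0 || matching_gamma < 0)
      nw_stop("invalid config: coupling_theta and matching_gamma must be >= 0",
              class = "nicheweb_config_error")
    if (temp_breadth <= 0 || aspect_breadth <= 0)
      nw_stop("invalid config: niche breadths must be strictly positive",
              class = "nicheweb_config_error")
    if (n_nonpollinators >= n_animals)
      nw_stop("invalid config: need at least one pollinating family",
              class = "nicheweb_config_error")
  })
  structure(cfg, class = "sim_config")
}

# Stream-splitting rule: one derived seed per generator stage.
substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 1000003 * k) %% 2147483647)
}

#' Generate study sites along an environmental gradient
#'
#' Site temperatures are evenly spaced over the configured range with
#' additive Gaussian noise; aspect is drawn uniformly on \[0, 180\] degrees
#' (north 0, south 180, east/west folded to 90).  Elevation is attached as
#' metadata by a linear lapse mapping from temperature.
#'
#' @param config a [sim_config()] object.
#' @param scale `"regional"` (transects) or `"local"` (plots).
#' @param seed optional integer; defaults to the config's stream for sites.
#' @return A data.frame with columns `site_id`, `scale`, `temperature`,
#'   `aspect`, `elevation`.
#' @export
generate_sites <- function(config, scale = c("regional", "local"),
                           seed = NULL) {
  scale <- match.arg(scale)
  n <- if (scale == "regional") config$n_sites else config$n_sites_local
  rng <- if (scale == "regional") config$temp_range else config$temp_range_local
  if (n < 2)
    nw_stop("invalid config: n_sites must be >= 2",
            class = "nicheweb_config_error")
  if (is.null(seed))
    seed <- substream_seed(config$seed, if (scale == "regional") 1L else 11L)
  set.seed(seed)
  temperature <- seq(rng[1], rng[2], length.out = n) +
    rnorm(n, 0, config$temp_noise_sd)
  aspect <- runif(n, 0, 180)
  prefix <- if (scale == "regional") "R" else "L"
  data.frame(site_id = sprintf("%s%02d", prefix, seq_len(n)),
             scale = scale,
             temperature = temperature,
             aspect = aspect,
             elevation = round(2600 - 140 * (temperature - min(rng))),
             stringsAsFactors = FALSE)
}

# Ground-truth niche and trait parameters for one trophic level.
# Optima are spread evenly over the regional gradient (with jitter) so the
# pool contains both central and marginal taxa.
generate_taxa <- function(config, level = c("plant", "animal"), seed) {
  level <- match.arg(level)
  n <- if (level == "plant") config$n_plants else config$n_animals
  rng <- config$temp_range
  set.seed(seed)
  span <- diff(rng)
  opt_t <- seq(rng[1] + 0.05 * span, rng[2] - 0.05 * span, length.out = n) +
    rnorm(n, 0, 0.05 * span)
  opt_a <- runif(n, 10, 170)
  id <- if (level == "plant") sprintf("plant_%02d", seq_len(n))
        else sprintf("fam_%02d", seq_len(n))
  out <- data.frame(taxon_id = id, trophic_level = level,
                    opt_temperature = opt_t, opt_aspect = opt_a,
                    breadth_temperature = config$temp_breadth,
                    breadth_aspect = config$aspect_breadth,
                    baseline_abundance = exp(rnorm(n, log(5), 0.4)),
                    stringsAsFactors = FALSE)
  if (level == "plant") {
    out$nectar_depth <- ifelse(runif(n) < 0.25, 0, runif(n, 1, 10))
    out$nectar_width <- runif(n, 1, 8)
    out$anther_position <- runif(n, -2, 5)
  } else {
    out$proboscis_length <- runif(n, 0.5, 14)
    out$head_width <- runif(n, 1, 5)
    out$body_length <- runif(n, 3, 20)
  }
  out
}

#' Draw taxon abundances over sites from Gaussian niche responses
#'
#' The expected abundance of taxon `j` at site `p` is
#' `baseline * exp(-0.5 * sum_k ((x_pk - opt_k) / breadth_k)^2)` over the
#' temperature and aspect axes; realized counts are Poisson with that mean.
#'
#' @param taxa data.frame of ground-truth parameters as produced by the
#'   generator (columns `taxon_id`, `opt_temperature`, `opt_aspect`,
#'   `breadth_temperature`, `breadth_aspect`, `baseline_abundance`).
#' @param sites data.frame of sites (see [generate_sites()]).
#' @param seed integer seed.
#' @return Integer matrix, taxa (rows, named) by sites (columns, named).
#' @export
generate_abundances <- function(taxa, sites, seed) {
  if (is.null(sites) || nrow(sites) == 0)
    nw_stop("generate_abundances: empty site list")
  if (!all(taxa$breadth_temperature > 0) || !all(taxa$breadth_aspect > 0))
    nw_stop("generate_abundances: niche breadths must be strictly positive")
  mu <- expected_abundance(taxa, sites)
  set.seed(seed)
  counts <- matrix(rpois(length(mu), mu), nrow = nrow(mu),
                   dimnames = dimnames(mu))
  counts
}

# Expected (Poisson-mean) abundance surface, taxa x sites.
expected_abundance <- function(taxa, sites) {
  zt <- outer(taxa$opt_temperature, sites$temperature, "-") /
    taxa$breadth_temperature
  za <- outer(taxa$opt_aspect, sites$aspect, "-") / taxa$breadth_aspect
  mu <- taxa$baseline_abundance * exp(-0.5 * (zt^2 + za^2))
  dimnames(mu) <- list(taxa$taxon_id, sites$site_id)
  mu
}

# Standardize true optima onto the unit square used by the coupling kernel:
# temperature by the regional gradient range, aspect by [0, 180].
true_positions <- function(taxa, config) {
  pos <- cbind(temperature = (taxa$opt_temperature - config$temp_range[1]) /
                 diff(config$temp_range),
               aspect = taxa$opt_aspect / 180)
  rownames(pos) <- taxa$taxon_id
  pos
}

#' Draw plant--animal interaction counts
#'
#' Pair rates combine total abundances with two optional penalties: an
#' environment-distance kernel `exp(-theta * D_env(i, j))` on the Euclidean
#' distance between the taxa's standardized environmental positions, and a
#' trait-matching kernel `exp(-gamma * |proboscis_i - nectar_depth_j|)`.
#' With `theta = gamma = 0` the rate of cell `(i, j)` is proportional to the
#' product of the two taxa's total abundances alone, so interactions are
#' independent of the environment and the fixed-margin null model holds
#' exactly.  `total_interactions` events are allocated over cells by a
#' single multinomial draw; each pair's events are then spread over sites in
#' proportion to the per-site co-occurrence products `a_pi * a_pj`.
#'
#' @param plant_abundance,animal_abundance integer matrices taxa x sites
#'   (shared site columns).
#' @param positions list with elements `plants` and `animals`: matrices of
#'   standardized environmental positions (rows named by taxon).
#' @param traits list with `nectar_depth` (named by plant) and
#'   `proboscis_length` (named by animal), in mm; either may be `NULL` when
#'   `matching_gamma = 0`.
#' @param config a [sim_config()] object.
#' @param seed integer seed.
#' @return A list with `matrix` (animals x plants aggregate counts),
#'   `per_site` (3-d array animals x plants x sites) and `rates` (the
#'   unnormalized cell rates).
#' @export
generate_interactions <- function(plant_abundance, animal_abundance,
                                  positions, traits = NULL, config,
                                  seed) {
  A_j <- rowSums(plant_abundance)   # plant totals
  A_i <- rowSums(animal_abundance)  # animal totals
  rate <- outer(A_i, A_j)
  if (config$coupling_theta > 0) {
    D <- position_distances(positions$animals[names(A_i), , drop = FALSE],
                            positions$plants[names(A_j), , drop = FALSE])
    rate <- rate * exp(-config$coupling_theta * D)
  }
  if (config$matching_gamma > 0 || config$strict_matching) {
    mm <- abs(outer(traits$proboscis_length[names(A_i)],
                    traits$nectar_depth[names(A_j)], "-"))
    rate <- rate * exp(-config$matching_gamma * mm)
    if (config$strict_matching) {
      forbidden <- outer(traits$proboscis_length[names(A_i)],
                         traits$nectar_depth[names(A_j)], "<")
      rate[forbidden] <- 0
    }
  }
  if (all(rate == 0))
    nw_stop("generate_interactions: all rates zero (no co-occurring taxa)")
  set.seed(seed)
  counts <- rmultinom(1, config$total_interactions, as.vector(rate))
  mat <- matrix(counts, nrow = nrow(rate), dimnames = dimnames(rate))
  per_site <- array(0L, dim = c(dim(mat), ncol(plant_abundance)),
                    dimnames = c(dimnames(mat),
                                 list(colnames(plant_abundance))))
  idx <- which(mat > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    w <- animal_abundance[i, ] * plant_abundance[j, ]
    if (all(w == 0)) w <- animal_abundance[i, ] + plant_abundance[j, ]
    if (all(w == 0)) w <- rep(1, length(w))
    per_site[i, j, ] <- rmultinom(1, mat[i, j], w)
  }
  list(matrix = mat, per_site = per_site, rates = rate)
}

# Pairwise Euclidean distances between two position matrices (rows).
position_distances <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

#' Simulate a complete field-study-shaped dataset
#'
#' Generates, from a single seed, every raw table the analysis pipeline
#' consumes: sites at one or two spatial scales, Braun-Blanquet-style plant
#' cover records (counts of 10 and 50 are emitted as the symbolic codes
#' `"r"` and `"+"` to exercise the parser), individual-level morphological
#' traits, species-level interaction counts per site, pollen-load category
#' records, and a species-to-family taxonomy map for the insects.  Taxa are
#' shared across scales so cross-scale correlations are defined.
#'
#' @param config a [sim_config()] object.
#' @param scales character vector, subset of `c("regional", "local")`.
#' @return A list of class `community_sim` with elements `sites`, `cover`,
#'   `traits`, `interactions`, `pollen`, `taxonomy`, `config` and `truth`
#'   (ground-truth parameters and standardized optima).
#' @export
#' @examples
#' sim <- simulate_community(sim_config(n_plants = 6, n_animals = 4, seed = 3))
#' head(sim$interactions)
simulate_community <- function(config = sim_config(),
                               scales = c("regional", "local")) {
  scales <- match.arg(scales, several.ok = TRUE)
  plants <- generate_taxa(config, "plant", substream_seed(config$seed, 2L))
  fams <- generate_taxa(config, "animal", substream_seed(config$seed, 3L))
  # insect species nested in families; species share the family's niche,
  # with slight trait perturbations
  sp <- do.call(rbind, lapply(seq_len(nrow(fams)), function(k) {
    s <- fams[rep(k, config$species_per_family), ]
    s$family <- s$taxon_id
    s$taxon_id <- sprintf("%s_sp%d", s$family, seq_len(nrow(s)))
    s$baseline_abundance <- s$baseline_abundance / config$species_per_family
    s
  }))
  set.seed(substream_seed(config$seed, 4L))
  sp$proboscis_length <- pmax(0.3, sp$proboscis_length *
                                exp(rnorm(nrow(sp), 0, 0.05)))
  taxonomy <- data.frame(species = sp$taxon_id, family = sp$family,
                         stringsAsFactors = FALSE)

  sites <- list(); cover <- list(); inter <- list()
  for (sc in scales) {
    off <- if (sc == "regional") 0L else 10L
    st <- generate_sites(config, sc)
    pa <- generate_abundances(plants, st, substream_seed(config$seed, 5L + off))
    aa <- generate_abundances(sp, st, substream_seed(config$seed, 6L + off))
    gi <- generate_interactions(
      pa, aa,
      positions = list(plants = true_positions(plants, config),
                       animals = true_positions(sp, config)),
      traits = list(nectar_depth = setNames(plants$nectar_depth,
                                            plants$taxon_id),
                    proboscis_length = setNames(sp$proboscis_length,
                                                sp$taxon_id)),
      config, substream_seed(config$seed, 7L + off))
    sites[[sc]] <- st
    cover[[sc]] <- cover_table(pa, sc)
    inter[[sc]] <- per_site_long(gi$per_site)
  }
  sites <- do.call(rbind, sites)
  cover <- do.call(rbind, cover)
  inter <- do.call(rbind, inter)
  rownames(sites) <- rownames(cover) <- rownames(inter) <- NULL

  traits <- rbind(
    trait_individuals(plants, c("nectar_depth", "nectar_width",
                                "anther_position"),
                      substream_seed(config$seed, 8L)),
    trait_individuals(sp, c("proboscis_length", "head_width", "body_length"),
                      substream_seed(config$seed, 9L)))
  pollen <- pollen_records(sp, fams$taxon_id[seq_len(config$n_nonpollinators)],
                           substream_seed(config$seed, 10L))
  structure(list(sites = sites, cover = cover, traits = traits,
                 interactions = inter, pollen = pollen, taxonomy = taxonomy,
                 config = config,
                 truth = list(plants = plants, families = fams, species = sp,
                              plant_positions = true_positions(plants, config),
                              family_positions = true_positions(fams, config))),
            class = "community_sim")
}

# Plant cover records: abundance counts back-converted to percent cover
# (count / 100); counts of 10 and 50 become the symbolic codes "r" and "+".
cover_table <- function(plant_abundance, scale) {
  idx <- which(plant_abundance > 0, arr.ind = TRUE)
  cnt <- plant_abundance[idx]
  cov <- as.character(cnt / 100)
  cov[cnt == 10] <- "r"
  cov[cnt == 50] <- "+"
  data.frame(site = colnames(plant_abundance)[idx[, 2]],
             taxon = rownames(plant_abundance)[idx[, 1]],
             cover = cov, stringsAsFactors = FALSE)
}

per_site_long <- function(per_site) {
  idx <- which(per_site > 0, arr.ind = TRUE)
  data.frame(animal = dimnames(per_site)[[1]][idx[, 1]],
             plant = dimnames(per_site)[[2]][idx[, 2]],
             site = dimnames(per_site)[[3]][idx[, 3]],
             count = per_site[idx], stringsAsFactors = FALSE)
}

# Individual-level trait measurements, 7-10 individuals per species.
trait_individuals <- function(taxa, trait_cols, seed) {
  set.seed(seed)
  out <- lapply(seq_len(nrow(taxa)), function(k) {
    n <- sample(7:10, 1)
    rows <- lapply(trait_cols, function(tr) {
      mu <- taxa[[tr]][k]
      sdv <- max(0.08 * abs(mu), 0.05)
      val <- rnorm(n, mu, sdv)
      if (tr %in% c("nectar_width", "proboscis_length", "head_width",
                    "body_length"))
        val <- pmax(val, 0.05)
      if (tr == "nectar_depth")
        val <- if (mu == 0) rep(0, n) else pmax(val, 0)
      data.frame(taxon = taxa$taxon_id[k],
                 individual = sprintf("%s_i%02d", taxa$taxon_id[k], seq_len(n)),
                 trait = tr, value = val,
                 trophic_level = taxa$trophic_level[k],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  do.call(rbind, out)
}

# Pollen-load categories (0-4) on four body regions for 5 individuals per
# species; species of "non-pollinator" families get loads with mean <= 1.
pollen_records <- function(species, nonpollinator_families, seed) {
  set.seed(seed)
  out <- lapply(seq_len(nrow(species)), function(k) {
    low <- species$family[k] %in% nonpollinator_families
    n <- 5L
    draw <- function(m) {
      if (low) sample(0:1, m, replace = TRUE, prob = c(0.8, 0.2))
      else sample(0:4, m, replace = TRUE, prob = c(0.05, 0.2, 0.3, 0.3, 0.15))
    }
    data.frame(species = species$taxon_id[k],
               individual = sprintf("%s_p%02d", species$taxon_id[k],
                                    seq_len(n)),
               head = draw(n), thorax = draw(n), abdomen = draw(n),
               legs = draw(n), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' One simulated edge-length experiment
#'
#' Fast taxon-level path through the generator and the null-model test,
#' used for calibration and power studies: generate sites, Gaussian-niche
#' abundances and interactions at one scale, derive every taxon's realized
#' Grinnellian position from its abundance surface (so positions are fixed
#' inputs, independent of the drawn interaction table), and run
#' [edge_length_test()] on the aggregate matrix.
#'
#' @param config a [sim_config()]; its `seed` drives every stream.
#' @param n_sims number of Patefield null tables.
#' @param scale which site layout to use.
#' @return List with the `test` (class `edge_length_test`), the aggregate
#'   `matrix`, the realized `positions`, the standardized site `env`, the
#'   ground `truth` parameter tables and the `abundances`.
#' @export
#' @examples
#' ex <- simulate_edge_experiment(sim_config(coupling_theta = 0, seed = 4,
#'                                           matching_gamma = 0),
#'                                n_sims = 99)
#' ex$test$p_value
simulate_edge_experiment <- function(config = sim_config(), n_sims = 500,
                                     scale = "regional") {
  seed <- config$seed
  plants <- generate_taxa(config, "plant", substream_seed(seed, 2L))
  animals <- generate_taxa(config, "animal", substream_seed(seed, 3L))
  st <- generate_sites(config, scale)
  pa <- generate_abundances(plants, st, substream_seed(seed, 5L))
  aa <- generate_abundances(animals, st, substream_seed(seed, 6L))
  gi <- generate_interactions(
    pa, aa,
    positions = list(plants = true_positions(plants, config),
                     animals = true_positions(animals, config)),
    traits = list(nectar_depth = setNames(plants$nectar_depth,
                                          plants$taxon_id),
                  proboscis_length = setNames(animals$proboscis_length,
                                              animals$taxon_id)),
    config, substream_seed(seed, 7L))
  env <- cbind(temperature = standardize_environment(st$temperature),
               aspect = standardize_environment(st$aspect))
  rownames(env) <- st$site_id
  pos_of <- function(ab) {
    taxa <- rownames(ab)[rowSums(ab) > 0]
    t(vapply(taxa, function(tx)
      niche_position(build_weighted_cloud(tx, env, ab[tx, ])),
      numeric(ncol(env))))
  }
  positions <- rbind(pos_of(pa), pos_of(aa))
  m <- gi$matrix
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  test <- edge_length_test(m, positions, n_sims = n_sims,
                           seed = substream_seed(seed, 101L))
  list(test = test, matrix = m, positions = positions, env = env,
       truth = list(plants = plants, animals = animals),
       abundances = list(plants = pa, animals = aa))
}
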