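# Expected CSV schemas (column names) for the raw input tables.
input_schemas <- list(
  sites = c("site_id", "scale", "temperature", "aspect"),
  cover = c("site", "taxon", "cover"),
  traits = c("taxon", "individual", "trait", "value", "trophic_level"),
  interactions = c("animal", "plant", "site", "count"),
  pollen = c("species", "individual", "head", "thorax", "abdomen", "legs"),
  taxonomy = c("species", "family"))

#' Read and check one raw input table
#'
#' @param path CSV file path.
#' @param what one of `"sites"`, `"cover"`, `"traits"`, `"interactions"`,
#'   `"pollen"`, `"taxonomy"`.
#' @return data.frame with the validated schema.
#' @export
read_input_table <- function(path, what = names(input_schemas)) {
  what <- match.arg(what)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(input_schemas[[what]], names(df))
  if (length(missing))
    nw_stop(sprintf("%s: missing column(s) %s in %s", what,
                    paste(missing, collapse = ", "), path),
            class = "nicheweb_schema_error")
  df
}

#' Validate a set of raw input tables
#'
#' Schema, type and referential checks: every interaction taxon must appear
#' in the cover (plants) or taxonomy (animal species) tables, counts must
#' be nonnegative integers, sites must exist, aspects must lie in
#' \[0, 180\].  Problems are collected, not thrown.
#'
#' @param tables named list of data.frames (as in a `community_sim`), or a
#'   named list of CSV paths.
#' @return data.frame report with columns `table`, `row`, `issue`; zero
#'   rows when everything is clean.
#' @export
validate_inputs <- function(tables) {
  if (is.character(tables[[1]]))
    tables <- Map(read_input_table, tables, names(tables))
  rep_ <- list()
  add <- function(tab, row, issue)
    rep_[[length(rep_) + 1]] <<- data.frame(table = tab, row = row,
                                            issue = issue,
                                            stringsAsFactors = FALSE)
  for (nm in names(input_schemas)) {
    if (is.null(tables[[nm]])) { add(nm, NA, "table missing"); next }
    missing <- setdiff(input_schemas[[nm]], names(tables[[nm]]))
    if (length(missing))
      add(nm, NA, paste("missing columns:", paste(missing, collapse = ", ")))
  }
  st <- tables$sites
  if (!is.null(st) && all(c("aspect", "site_id") %in% names(st))) {
    bad <- which(st$aspect < 0 | st$aspect > 180 | !is.finite(st$aspect))
    for (r in bad) add("sites", r, "aspect outside [0, 180]")
    for (sc in unique(st$scale))
      if (anyDuplicated(st$site_id[st$scale == sc]))
        add("sites", NA, paste("duplicate site_id within scale", sc))
  }
  it <- tables$interactions
  if (!is.null(it) && all(input_schemas$interactions %in% names(it))) {
    bad <- which(it$count < 0 | it$count != round(it$count))
    for (r in bad) add("interactions", r, "count not a nonnegative integer")
    if (!is.null(st)) {
      unk <- which(!(it$site %in% st$site_id))
      for (r in unk) add("interactions", r, paste("unknown site", it$site[r]))
    }
    if (!is.null(tables$cover)) {
      unk <- which(!(it$plant %in% tables$cover$taxon))
      for (r in unk)
        add("interactions", r, paste("plant not in cover table:",
                                     it$plant[r]))
    }
    if (!is.null(tables$taxonomy)) {
      unk <- which(!(it$animal %in% tables$taxonomy$species))
      for (r in unk)
        add("interactions", r, paste("animal not in taxonomy:", it$animal[r]))
    }
  }
  if (length(rep_) == 0)
    return(data.frame(table = character(), row = integer(),
                      issue = character()))
  out <- do.call(rbind, rep_)
  rownames(out) <- NULL
  out
}

#' Run the full niche analysis
#'
#' Orchestrates, per spatial scale: preprocessing (cover conversion, pollen
#' filter, family pooling), the realized Grinnellian and fundamental
#' Eltonian niche summaries, the species-level network roles, the
#' correlation-network integration, and the fixed-margin edge-length null
#' test; plus cross-scale and interaction-frequency correlations when both
#' scales run.
#'
#' @param config a named list (or path to a YAML/JSON file) with elements:
#'   `simulate` (arguments to [sim_config()]) *or* `inputs` (named CSV
#'   paths: sites, cover, traits, interactions, pollen, taxonomy);
#'   `scales` (default both); `alpha` (default 0.05); `alpha_grid`
#'   (default `seq(0, 0.5, 0.05)`); `n_sims` (default 10000); `seed`
#'   (required: the analysis contains stochastic stages); `outdir`
#'   (optional output directory).
#' @return A list of class `nicheweb_run` with one element per scale
#'   (`niches`, `roles`, `index_matrices`, `correlations`, `networks`,
#'   `integration`, `edge_test`, ...), plus `cross_scale`,
#'   `abundance_cor` and `manifest`.
#' @export
run_pipeline <- function(config) {
  config <- load_run_config(config)
  if (is.null(config$seed))
    nw_stop("run_pipeline: config must set a seed (the null-model and ",
            "simulation stages are stochastic)",
            class = "nicheweb_config_error")
  raw <- if (!is.null(config$simulate)) {
    args <- config$simulate
    args$seed <- config$seed
    simulate_community(do.call(sim_config, args), scales = config$scales)
  } else if (!is.null(config$inputs)) {
    tabs <- Map(read_input_table, config$inputs,
                names(config$inputs))
    structure(tabs, class = "community_raw")
  } else nw_stop("run_pipeline: config needs a 'simulate' or 'inputs' block",
                 class = "nicheweb_config_error")
  report <- validate_inputs(raw[names(input_schemas)])
  if (nrow(report))
    nw_stop("run_pipeline: input validation failed at stage 'validate': ",
            paste(utils::head(apply(report, 1, paste, collapse = " "), 5),
                  collapse = "; "))
  kept <- filter_pollinators(raw$pollen, raw$taxonomy)
  per_scale <- lapply(config$scales, function(sc)
    analyze_scale(raw, sc, kept, config))
  names(per_scale) <- config$scales
  out <- list(scales = per_scale, pollinator_families = kept,
              config = config)
  if (length(config$scales) == 2) {
    out$cross_scale <- lapply(c(animal = "animal", plant = "plant"),
      function(lv) cross_scale_correlation(
        per_scale$local$index_matrices[[lv]],
        per_scale$regional$index_matrices[[lv]]))
  }
  out$manifest <- run_manifest(config)
  class(out) <- "nicheweb_run"
  if (!is.null(config$outdir)) write_outputs(out, config$outdir)
  out
}

# Defaults + file loading for the run configuration.
load_run_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- list(scales = c("regional", "local"), alpha = 0.05,
                   alpha_grid = seq(0, 0.5, by = 0.05), n_sims = 10000,
                   seed = NULL, outdir = NULL)
  config <- modifyList(defaults, config)
  config$scales <- match.arg(config$scales, c("regional", "local"),
                             several.ok = TRUE)
  config
}

# One scale: preprocessing -> niches -> roles -> integration -> edge test.
analyze_scale <- function(raw, scale, kept_families, config) {
  sites <- raw$sites[raw$sites$scale == scale, , drop = FALSE]
  cover <- raw$cover[raw$cover$site %in% sites$site_id, , drop = FALSE]
  inter <- raw$interactions[raw$interactions$site %in% sites$site_id, ,
                            drop = FALSE]
  if (nrow(inter) == 0)
    nw_stop("analyze_scale: no interactions at scale '", scale, "'")

  pooled <- pool_to_family(inter, raw$traits, raw$taxonomy)
  inter <- pooled$interactions[pooled$interactions$animal %in%
                                 kept_families, , drop = FALSE]
  traits <- pooled$traits

  env <- cbind(temperature = standardize_environment(sites$temperature),
               aspect = standardize_environment(sites$aspect))
  rownames(env) <- sites$site_id

  plant_ab <- abundance_from_cover(cover)
  animal_ab <- abundance_from_interactions(inter)
  rb_cfg <- range_box_config(alpha_grid = config$alpha_grid)

  grinnellian <- list(
    plant = niche_summaries(grinnellian_clouds(plant_ab, env), rb_cfg),
    animal = niche_summaries(grinnellian_clouds(animal_ab, env), rb_cfg))

  mat <- as_interaction_matrix(interaction_totals(inter))
  roles <- species_level(mat)

  trait_summ <- lapply(c(plant = "plant", animal = "animal"), function(lv) {
    taxa <- if (lv == "plant") rownames(plant_ab) else rownames(animal_ab)
    tt <- traits[traits$trophic_level == lv & traits$taxon %in% taxa, ,
                 drop = FALSE]
    tt <- standardize_traits(tt)
    taxa_here <- sort(unique(tt$taxon))
    clouds <- lapply(taxa_here, trait_cloud, trait_table = tt)
    names(clouds) <- taxa_here
    niche_summaries(clouds, rb_cfg)
  })

  index_matrices <- lapply(c(animal = "animal", plant = "plant"),
    function(lv) assemble_index_matrix(
      grinnellian[[lv]], trait_summ[[lv]],
      roles[roles$trophic_level == lv, , drop = FALSE]))

  integ <- lapply(index_matrices, function(im) {
    cors <- pairwise_correlations(im)
    net <- build_correlation_network(cors, alpha = config$alpha)
    part <- modularity_partition(net)
    n_eff <- if (nrow(cors)) stats::median(cors$n) else NA
    ii <- integration_index(correlation_matrix(cors), n_effective = n_eff)
    list(correlations = cors, network = net, modules = part$membership,
         Q = part$Q, integration = ii, n_effective = n_eff)
  })

  positions <- rbind(position_table(grinnellian$plant),
                     position_table(grinnellian$animal))
  et <- edge_length_test(mat, positions, n_sims = config$n_sims,
                         seed = substream_seed(config$seed,
                                               if (scale == "regional") 101L
                                               else 102L))

  totals <- list(animal = rowSums(mat), plant = colSums(mat))
  abund_cor <- lapply(c(animal = "animal", plant = "plant"), function(lv)
    abundance_correlation(totals[[lv]], index_matrices[[lv]],
                          alpha = config$alpha))

  list(scale = scale, env = env, matrix = mat,
       niches = list(grinnellian = grinnellian, trait = trait_summ),
       roles = roles, index_matrices = index_matrices,
       integration = integ, edge_test = et, abundance_cor = abund_cor)
}

# Grinnellian clouds for every taxon of an abundance table.
grinnellian_clouds <- function(abundance, env) {
  taxa <- rownames(abundance)[rowSums(abundance) > 0]
  clouds <- lapply(taxa, function(tx)
    build_weighted_cloud(tx, env, abundance[tx, ]))
  names(clouds) <- taxa
  clouds
}

# Aggregate long interactions over sites into an animals x plants matrix.
interaction_totals <- function(interactions) {
  ag <- aggregate(count ~ animal + plant, data = interactions, FUN = sum)
  animals <- sort(unique(ag$animal)); plants <- sort(unique(ag$plant))
  m <- matrix(0L, length(animals), length(plants),
              dimnames = list(animals, plants))
  m[cbind(match(ag$animal, animals), match(ag$plant, plants))] <-
    as.integer(ag$count)
  m
}

# taxon x dimension position matrix from a niche_summaries data.frame.
position_table <- function(summ) {
  jc <- grep("^J_", names(summ))
  pos <- as.matrix(summ[, jc, drop = FALSE])
  rownames(pos) <- summ$taxon
  colnames(pos) <- sub("^J_", "", names(summ)[jc])
  pos
}

# Minimal FNV-1a hash of the JSON-serialized config, for the manifest.
config_hash <- function(config) {
  bytes <- utf8ToInt(as.character(jsonlite::toJSON(config,
                                                   auto_unbox = TRUE)))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(h, b) * 16777619) %% 2^32
  sprintf("%08x", h)
}

run_manifest <- function(config) {
  list(package = "nicheweb",
       version = as.character(packageVersion("nicheweb")),
       r_version = as.character(getRversion()),
       seed = config$seed, alpha = config$alpha, n_sims = config$n_sims,
       scales = config$scales,
       config_hash = config_hash(config[setdiff(names(config), "outdir")]))
}

#' @export
print.nicheweb_run <- function(x, ...) {
  cat("<nicheweb_run>\n")
  for (sc in names(x$scales)) {
    s <- x$scales[[sc]]
    cat(sprintf("  %s: %d animal x %d plant taxa, %d interactions\n", sc,
                nrow(s$matrix), ncol(s$matrix), sum(s$matrix)))
    cat(sprintf("    edge test: <E_r> = %.4f, null <E_e> = %.4f, p = %.4g\n",
                s$edge_test$observed, s$edge_test$null_mean,
                s$edge_test$p_value))
    for (lv in names(s$integration))
      cat(sprintf("    %s indices: Q = %.3f, integration = %.3f (corrected %.3f)\n",
                  lv, s$integration[[lv]]$Q,
                  s$integration[[lv]]$integration$raw,
                  s$integration[[lv]]$integration$corrected))
  }
  invisible(x)
}

# Write the artifact bundle: CSV tables plus JSON results.
write_outputs <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, file) write.csv(df, file.path(outdir, file),
                                    row.names = FALSE)
  # positions live in spaces of different dimension (2 environmental axes,
  # 3 traits); pad to generic J1..J3 with the axis names recorded in `dims`
  flatten_summary <- function(df) {
    jc <- grep("^J_", names(df))
    J <- matrix(NA_real_, nrow(df), 3,
                dimnames = list(NULL, paste0("J", 1:3)))
    J[, seq_along(jc)] <- as.matrix(df[, jc, drop = FALSE])
    cbind(df[, "taxon", drop = FALSE], as.data.frame(J),
          dims = paste(sub("^J_", "", names(df)[jc]), collapse = "|"),
          df[, c("marginality", "volume", "V")])
  }
  niches <- do.call(rbind, lapply(names(run$scales), function(sc) {
    s <- run$scales[[sc]]
    do.call(rbind, lapply(c("grinnellian", "trait"), function(nt)
      do.call(rbind, lapply(names(s$niches[[nt]]), function(lv)
        cbind(data.frame(scale = sc, niche_type = nt, trophic_level = lv),
              flatten_summary(s$niches[[nt]][[lv]]))))))
  }))
  w(niches, "niches.csv")
  roles <- do.call(rbind, lapply(names(run$scales), function(sc)
    cbind(data.frame(scale = sc), run$scales[[sc]]$roles)))
  w(roles, "roles.csv")
  cors <- do.call(rbind, lapply(names(run$scales), function(sc)
    do.call(rbind, lapply(names(run$scales[[sc]]$integration), function(lv) {
      df <- run$scales[[sc]]$integration[[lv]]$correlations
      if (nrow(df)) cbind(data.frame(scale = sc, trophic_level = lv), df)
    }))))
  w(cors, "correlations.csv")
  nets <- lapply(run$scales, function(s) lapply(s$integration, function(ig) {
    el <- igraph::as_data_frame(ig$network, what = "edges")
    list(nodes = igraph::V(ig$network)$name, edges = el,
         modules = as.list(ig$modules), Q = ig$Q,
         integration = ig$integration, n_effective = ig$n_effective)
  }))
  jsonlite::write_json(nets, file.path(outdir, "network.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(run$cross_scale)) {
    t1 <- do.call(rbind, lapply(names(run$cross_scale), function(lv)
      cbind(data.frame(trophic_level = lv), run$cross_scale[[lv]])))
    w(t1, "table1.csv")
  }
  t2 <- do.call(rbind, lapply(names(run$scales), function(sc)
    do.call(rbind, lapply(names(run$scales[[sc]]$abundance_cor),
      function(lv) cbind(data.frame(scale = sc, trophic_level = lv),
                         run$scales[[sc]]$abundance_cor[[lv]])))))
  w(t2, "table2.csv")
  et <- lapply(run$scales, function(s) {
    x <- s$edge_test
    list(observed = x$observed, null_mean = x$null_mean,
         null_quantiles = as.list(x$null_quantiles), p_value = x$p_value,
         n_sims = x$n_sims, seed = x$seed)
  })
  jsonlite::write_json(et, file.path(outdir, "edgetest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(run$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Write a simulated community to the raw CSV schemas
#'
#' @param sim a `community_sim` from [simulate_community()].
#' @param dir output directory (created if needed).
#' @return Named vector of the written file paths.
#' @export
write_community <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(sites = "sites.csv", cover = "cover.csv", traits = "traits.csv",
             interactions = "interactions.csv", pollen = "pollen.csv",
             taxonomy = "taxonomy.csv")
  for (nm in names(files))
    write.csv(sim[[nm]], file.path(dir, files[nm]), row.names = FALSE)
  setNames(file.path(dir, files), names(files))
}
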