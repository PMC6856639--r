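#' Convert Braun-Blanquet-style cover records to percent cover
#'
#' The symbolic codes of the modified abundance-dominance scale are replaced
#' by small percentages: `"+"` becomes 0.5 and `"r"` becomes 0.1; numeric
#' values (given as numbers or numeric strings) pass through unchanged.
#'
#' @param cover character or numeric vector of cover records.
#' @return Numeric vector of percent cover in (0, 100].
#' @export
#' @examples
#' convert_cover(c("+", "r", "12.5"))
convert_cover <- function(cover) {
  if (is.numeric(cover)) {
    out <- as.numeric(cover)
  } else {
    cover <- trimws(as.character(cover))
    out <- suppressWarnings(as.numeric(cover))
    out[cover == "+"] <- 0.5
    out[cover == "r"] <- 0.1
    bad <- is.na(out) & !is.na(cover)
    if (any(bad))
      nw_stop("convert_cover: unknown cover code(s): ",
              paste(unique(cover[bad]), collapse = ", "),
              class = "nicheweb_parse_error")
  }
  if (any(out <= 0 | out > 100, na.rm = TRUE))
    nw_stop("convert_cover: percent cover must lie in (0, 100]",
            class = "nicheweb_parse_error")
  out
}

#' Turn percent cover into integer abundance
#'
#' Percent cover (often below 1 percent) is multiplied by 100 and rounded to
#' the nearest integer, halves away from zero.  A result of 0 marks the
#' taxon as absent at that site.
#'
#' @param percent numeric vector of percent cover, `>= 0`.
#' @return Integer vector of abundances.
#' @export
#' @examples
#' integerize_abundance(c(0.1, 0.5, 100, 0.004))
integerize_abundance <- function(percent) {
  if (any(percent < 0, na.rm = TRUE))
    nw_stop("integerize_abundance: negative percent cover")
  as.integer(floor(percent * 100 + 0.5))
}

#' Keep insect taxa that plausibly act as pollinators
#'
#' Pollen loads on four body regions (head, thorax, abdomen, legs) are
#' scored in categories 0--4.  A pooled taxon (family) is kept if and only
#' if the mean category over all body regions of all individuals of all its
#' member species is strictly greater than 1.
#'
#' @param pollen_records data.frame with columns `species`, `individual`,
#'   `head`, `thorax`, `abdomen`, `legs` (integer categories 0--4).
#' @param taxonomy data.frame with columns `species`, `family`.
#' @param taxa optional character vector of pooled taxa that must be
#'   evaluable; any of them lacking pollen records is an error.
#' @return Character vector of kept pooled taxa (families), with the
#'   per-taxon means as an attribute `means`.
#' @export
filter_pollinators <- function(pollen_records, taxonomy, taxa = NULL) {
  regions <- c("head", "thorax", "abdomen", "legs")
  if (!all(regions %in% names(pollen_records)))
    nw_stop("filter_pollinators: pollen records need columns ",
            paste(regions, collapse = ", "))
  vals <- as.matrix(pollen_records[, regions])
  if (any(vals != round(vals)) || any(vals < 0) || any(vals > 4))
    nw_stop("filter_pollinators: categories must be integers in 0..4")
  fam <- taxonomy$family[match(pollen_records$species, taxonomy$species)]
  if (anyNA(fam))
    nw_stop("filter_pollinators: species without taxonomy entry: ",
            paste(unique(pollen_records$species[is.na(fam)]), collapse = ", "))
  means <- tapply(as.vector(vals), rep(fam, times = length(regions)), mean)
  if (!is.null(taxa)) {
    missing <- setdiff(taxa, names(means))
    if (length(missing))
      nw_stop("filter_pollinators: no pollen records for taxa: ",
              paste(missing, collapse = ", "))
  }
  kept <- names(means)[means > 1]
  attr(kept, "means") <- means
  kept
}

#' Pool insect species into families
#'
#' Interaction counts are summed over the member species of each family;
#' trait individuals are concatenated (every phenotyped individual is
#' retained under the family label).  Plants stay at species level.
#'
#' @param interactions data.frame with columns `animal`, `plant`, `site`,
#'   `count`, with `animal` at species level.
#' @param traits data.frame with columns `taxon`, `individual`, `trait`,
#'   `value` (and optionally `trophic_level`); only animal rows are relabeled.
#' @param taxonomy data.frame with columns `species`, `family`.
#' @return List with pooled `interactions` and `traits`.
#' @export
pool_to_family <- function(interactions, traits, taxonomy) {
  map <- setNames(taxonomy$family, taxonomy$species)
  unmapped <- setdiff(unique(interactions$animal), names(map))
  if (length(unmapped))
    nw_stop("pool_to_family: species missing from taxonomy: ",
            paste(unmapped, collapse = ", "))
  interactions$animal <- unname(map[interactions$animal])
  pooled <- aggregate(count ~ animal + plant + site, data = interactions,
                      FUN = sum)
  if (!is.null(traits)) {
    is_animal <- traits$taxon %in% names(map)
    traits$taxon[is_animal] <- unname(map[traits$taxon[is_animal]])
  }
  list(interactions = pooled, traits = traits)
}

#' Standardize values to the unit interval
#'
#' Range standardization `x' = (x - min) / (max - min)`, applied separately
#' per dimension and per species pool by the caller.  A degenerate dimension
#' (all values equal) is mapped to 0.5 with a warning.
#'
#' @param values numeric vector (length >= 2).
#' @return Numeric vector in \[0, 1\].
#' @export
#' @examples
#' standardize_environment(c(10, 15, 20))
standardize_environment <- function(values) {
  if (length(values) < 2)
    nw_stop("standardize_environment: need at least 2 values")
  rng <- range(values, na.rm = TRUE)
  if (!all(is.finite(rng)))
    nw_stop("standardize_environment: values must be finite")
  if (rng[1] == rng[2]) {
    warning("standardize_environment: degenerate dimension (max = min); ",
            "all values set to 0.5")
    return(rep(0.5, length(values)))
  }
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Mean seasonal temperature from a logger series
#'
#' Raw 30-minute soil-temperature recordings are reduced to a single site
#' value by a plain arithmetic mean.
#'
#' @param recordings numeric vector of temperature recordings.
#' @return Single numeric mean.
#' @export
seasonal_mean_temperature <- function(recordings) {
  mean(recordings, na.rm = TRUE)
}

#' Site-by-taxon abundance from cover records
#'
#' @param cover data.frame with columns `site`, `taxon`, `cover` (symbolic
#'   or percent; see [convert_cover()]).
#' @return Integer matrix taxa x sites (zero where absent).
#' @export
abundance_from_cover <- function(cover) {
  cover$value <- integerize_abundance(convert_cover(cover$cover))
  abundance_matrix(cover$taxon, cover$site, cover$value)
}

#' Site-by-taxon animal abundance from interaction counts
#'
#' Animal abundance per site is the number of interactions observed there.
#'
#' @param interactions data.frame with columns `animal`, `site`, `count`.
#' @return Integer matrix animal taxa x sites.
#' @export
abundance_from_interactions <- function(interactions) {
  abundance_matrix(interactions$animal, interactions$site,
                   interactions$count)
}

# Long (taxon, site, value) -> dense integer matrix, summing duplicates.
abundance_matrix <- function(taxon, site, value) {
  taxa <- sort(unique(taxon)); sites <- sort(unique(site))
  m <- matrix(0L, length(taxa), length(sites), dimnames = list(taxa, sites))
  for (r in seq_along(value))
    m[taxon[r], site[r]] <- m[taxon[r], site[r]] + as.integer(value[r])
  m
}
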