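#' Abundance-weighted environmental cloud of one taxon
#'
#' The realized Grinnellian niche of taxon `j` is represented by a matrix
#' with `V = sum_p a_pj` rows: the standardized (temperature', aspect') row
#' of every site where the taxon occurs is replicated `a_pj` times, so
#' simple column means of the cloud are the abundance-weighted niche
#' position.
#'
#' @param taxon taxon identifier (for labeling).
#' @param env matrix of standardized site environments (sites x dimensions,
#'   rows named by site, values in \[0, 1\]).
#' @param abundance named integer vector of the taxon's abundance per site
#'   (names matching `env` rows; sites absent from the vector count as 0).
#' @return A `weighted_cloud`: the V x d matrix with attributes `taxon`,
#'   `niche_type = "grinnellian"` and `V`.
#' @export
#' @examples
#' env <- matrix(c(0.2, 0.8, 0.1, 0.9), 2, 2,
#'               dimnames = list(c("s1", "s2"), c("temperature", "aspect")))
#' build_weighted_cloud("t1", env, c(s1 = 2, s2 = 1))
build_weighted_cloud <- function(taxon, env, abundance) {
  abundance <- abundance[abundance > 0]
  if (length(abundance) == 0 || sum(abundance) == 0)
    nw_stop("build_weighted_cloud: taxon '", taxon, "' absent from pool")
  missing <- setdiff(names(abundance), rownames(env))
  if (length(missing))
    nw_stop("build_weighted_cloud: sites without environment: ",
            paste(missing, collapse = ", "))
  rows <- rep(match(names(abundance), rownames(env)), times = abundance)
  cloud <- env[rows, , drop = FALSE]
  rownames(cloud) <- NULL
  structure(cloud, taxon = taxon, niche_type = "grinnellian",
            V = as.integer(sum(abundance)), class = "weighted_cloud")
}

#' Morphological trait cloud of one taxon
#'
#' The fundamental Eltonian niche: one row per phenotyped individual
#' (unweighted).  For pooled animal taxa the individuals of all member
#' species enter together.
#'
#' @param taxon taxon identifier.
#' @param trait_table data.frame with columns `taxon`, `individual`,
#'   `trait`, `value` (long format; values already standardized if desired).
#' @return A `weighted_cloud` with `niche_type = "trait"` and one column
#'   per trait.
#' @export
trait_cloud <- function(taxon, trait_table) {
  tt <- trait_table[trait_table$taxon == taxon, , drop = FALSE]
  if (nrow(tt) == 0)
    nw_stop("trait_cloud: no phenotyped individuals for taxon '", taxon, "'")
  traits <- sort(unique(tt$trait))
  inds <- unique(tt$individual)
  cloud <- matrix(NA_real_, length(inds), length(traits),
                  dimnames = list(NULL, traits))
  cloud[cbind(match(tt$individual, inds), match(tt$trait, traits))] <- tt$value
  if (anyNA(cloud))
    nw_stop("trait_cloud: incomplete trait measurements for taxon '",
            taxon, "'")
  structure(cloud, taxon = taxon, niche_type = "trait",
            V = nrow(cloud), class = "weighted_cloud")
}

#' @export
print.weighted_cloud <- function(x, ...) {
  cat(sprintf("<weighted_cloud> taxon %s, %s niche, V = %d, d = %d\n",
              attr(x, "taxon"), attr(x, "niche_type"), attr(x, "V"),
              ncol(x)))
  invisible(x)
}

#' Niche position of a cloud
#'
#' The (abundance-weighted) mean position `J`: the column means of the cloud
#' matrix.  Replication of site rows encodes the abundance weighting, so a
#' plain mean suffices.
#'
#' @param cloud a `weighted_cloud` (or plain numeric matrix).
#' @return Named numeric vector `J` of length d.
#' @export
niche_position <- function(cloud) {
  if (is.null(dim(cloud)) || nrow(cloud) == 0)
    nw_stop("niche_position: empty cloud")
  colMeans(unclass(cloud))
}

#' Marginality of taxa within a species pool
#'
#' The pool centroid `c` is the unweighted arithmetic mean of the taxa's
#' positions `J`; the marginality of taxon `j` is the Euclidean distance
#' `||J_j - c||`.  Computed separately per trophic level, niche type and
#' spatial scale by the caller.
#'
#' @param positions matrix of positions, taxa (rows, named) x dimensions.
#' @return Named numeric vector of marginalities (`>= 0`), with the centroid
#'   as attribute `centroid`.
#' @export
#' @examples
#' J <- rbind(a = c(0.2, 0.2), b = c(0.6, 0.6))
#' marginality(J)  # both sqrt(0.08)
marginality <- function(positions) {
  positions <- as.matrix(positions)
  if (nrow(positions) == 0)
    nw_stop("marginality: no taxon positions")
  centroid <- colMeans(positions)
  M <- sqrt(rowSums(sweep(positions, 2, centroid)^2))
  attr(M, "centroid") <- centroid
  M
}

#' Dynamic-range-box configuration
#'
#' @param alpha_grid increasing quantile levels in \[0, 0.5\]; the default
#'   grid is 0, 0.05, ..., 0.5.
#' @param aggregation how per-dimension lengths combine into a per-alpha
#'   size: `"mean"` (default) or `"product"`.
#' @param global_ranges optional d x 2 matrix of per-dimension \[lo, hi\]
#'   pooled ranges; when `NULL` it is computed from the pooled clouds of the
#'   trophic level by [niche_summaries()].
#' @return A list of class `range_box_config`.
#' @export
range_box_config <- function(alpha_grid = seq(0, 0.5, by = 0.05),
                             aggregation = c("mean", "product"),
                             global_ranges = NULL) {
  aggregation <- match.arg(aggregation)
  if (any(alpha_grid < 0 | alpha_grid > 0.5))
    nw_stop("range_box_config: alpha levels must lie in [0, 0.5]",
            class = "nicheweb_config_error")
  if (is.unsorted(alpha_grid, strictly = TRUE))
    nw_stop("range_box_config: alpha_grid must be strictly increasing",
            class = "nicheweb_config_error")
  structure(list(alpha_grid = alpha_grid, aggregation = aggregation,
                 global_ranges = global_ranges),
            class = "range_box_config")
}

#' Niche volume by dynamic range boxes
#'
#' For each dimension `k` and quantile level `alpha`, the occupied length is
#' `(Q_{1-alpha} - Q_alpha) / (hi_k - lo_k)` (linear-interpolation
#' quantiles), clipped to \[0, 1\]; a degenerate global dimension
#' (`hi_k = lo_k`) contributes length 0.  Per-alpha sizes aggregate over
#' dimensions by mean (default) or product, and the volume is the mean over
#' the alpha grid; it always lies in \[0, 1\].
#'
#' @param cloud a `weighted_cloud` or numeric matrix (rows = points).
#' @param config a [range_box_config()]; `global_ranges` must be set here
#'   (d x 2 matrix).
#' @return Single numeric volume in \[0, 1\].
#' @export
range_box_volume <- function(cloud, config = range_box_config()) {
  x <- unclass(cloud)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  if (nrow(x) == 0) nw_stop("range_box_volume: empty cloud")
  gr <- config$global_ranges
  if (is.null(gr))
    nw_stop("range_box_volume: config$global_ranges must be provided",
            class = "nicheweb_config_error")
  gr <- matrix(as.numeric(gr), ncol = 2)
  if (nrow(gr) != ncol(x))
    nw_stop("range_box_volume: global_ranges rows must match cloud columns")
  alphas <- config$alpha_grid
  len <- matrix(0, length(alphas), ncol(x))
  for (k in seq_len(ncol(x))) {
    width <- gr[k, 2] - gr[k, 1]
    if (width <= 0) next  # degenerate dimension: length 0
    qs <- quantile(x[, k], probs = c(alphas, 1 - alphas), type = 7,
                   names = FALSE)
    lo <- qs[seq_along(alphas)]
    hi <- qs[length(alphas) + seq_along(alphas)]
    len[, k] <- pmin(pmax((hi - lo) / width, 0), 1)
  }
  per_alpha <- if (config$aggregation == "mean") rowMeans(len)
               else apply(len, 1, prod)
  mean(per_alpha)
}

#' Niche summaries (position, marginality, volume) for a species pool
#'
#' Builds the clouds of every taxon of one trophic level and niche type,
#' then derives position `J`, marginality `M_j` (distance to the centroid of
#' the taxa's positions) and the dynamic-range-box volume `vol(j)`.  The
#' same code path serves the realized Grinnellian niche (abundance-weighted
#' environmental clouds) and the fundamental Eltonian niche (trait clouds).
#'
#' @param clouds named list of `weighted_cloud` objects, one per taxon, all
#'   with identical column sets.
#' @param config a [range_box_config()]; if its `global_ranges` is `NULL`,
#'   the per-dimension ranges of the pooled rows of all clouds are used.
#' @return data.frame with columns `taxon`, one `J_<dim>` column per
#'   dimension, `marginality`, `volume`, `V`.
#' @export
niche_summaries <- function(clouds, config = range_box_config()) {
  if (length(clouds) == 0) nw_stop("niche_summaries: no clouds")
  if (is.null(config$global_ranges)) {
    pooled <- do.call(rbind, lapply(clouds, unclass))
    config$global_ranges <- cbind(apply(pooled, 2, min),
                                  apply(pooled, 2, max))
  }
  J <- t(vapply(clouds, niche_position, numeric(ncol(clouds[[1]]))))
  rownames(J) <- names(clouds)
  M <- marginality(J)
  vol <- vapply(clouds, range_box_volume, numeric(1), config = config)
  out <- data.frame(taxon = names(clouds), J, marginality = as.numeric(M),
                    volume = as.numeric(vol),
                    V = vapply(clouds, function(cl) nrow(unclass(cl)),
                               integer(1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  names(out)[1 + seq_len(ncol(J))] <- paste0("J_", colnames(J))
  out
}

#' Standardize a long trait table to the unit interval per trait
#'
#' Each trait is range-standardized across the pooled individuals of all
#' taxa of a trophic level, mirroring the environmental standardization, so
#' Euclidean geometry in trait space is not dominated by the largest-unit
#' trait.
#'
#' @param trait_table long data.frame (`taxon`, `individual`, `trait`,
#'   `value`).
#' @return The table with `value` standardized within each trait.
#' @export
standardize_traits <- function(trait_table) {
  for (tr in unique(trait_table$trait)) {
    i <- trait_table$trait == tr
    trait_table$value[i] <- standardize_environment(trait_table$value[i])
  }
  trait_table
}
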