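#' Edge length between two niche positions
#'
#' Euclidean distance between a plant's and an animal's position in the
#' standardized Grinnellian niche space.
#'
#' @param plant_J,animal_I numeric position vectors of equal length.
#' @return Nonnegative distance.
#' @export
#' @examples
#' edge_length(c(0, 0), c(0.3, 0.4))  # 0.5
edge_length <- function(plant_J, animal_I) {
  if (length(plant_J) != length(animal_I))
    nw_stop("edge_length: dimension mismatch")
  sqrt(sum((plant_J - animal_I)^2))
}

# Distance matrix (animals x plants) between position rows, with an error
# listing taxa that lack a position.
edge_length_matrix <- function(matrix, positions) {
  need <- c(rownames(matrix), colnames(matrix))
  missing <- setdiff(need, rownames(positions))
  if (length(missing))
    nw_stop("positions missing for taxa: ", paste(missing, collapse = ", "))
  position_distances(positions[rownames(matrix), , drop = FALSE],
                     positions[colnames(matrix), , drop = FALSE])
}

#' Interaction-weighted mean edge length
#'
#' `<E> = sum_ij a_ij E(i, j) / sum_ij a_ij`: the mean niche-space distance
#' between interacting partners, weighted by interaction frequency.
#'
#' @param matrix interaction matrix (animals x plants, named).
#' @param positions matrix of niche positions, rows named by taxon
#'   (covering every row and column taxon of `matrix`).
#' @return Single numeric weighted mean edge length.
#' @export
weighted_mean_edge_length <- function(matrix, positions) {
  m <- sum(matrix)
  if (m == 0) nw_stop("weighted_mean_edge_length: matrix sums to zero")
  D <- edge_length_matrix(matrix, positions)
  sum(matrix * D) / m
}

#' Random two-way tables with fixed margins (Patefield algorithm)
#'
#' Draws integer tables from the fixed-margin (multivariate
#' hypergeometric) distribution by Patefield's sequential conditional
#' hypergeometric filling, as implemented in [stats::r2dtable()].  Margins
#' are reproduced exactly on every draw; zero margins yield all-zero
#' rows/columns.
#'
#' @param row_margins,col_margins nonnegative integer margin vectors with
#'   equal sums.
#' @param n number of tables to draw.
#' @param seed optional integer seed (restores the RNG state afterwards).
#' @return List of `n` integer matrices.
#' @export
patefield_sample <- function(row_margins, col_margins, n = 1, seed = NULL) {
  if (any(row_margins < 0) || any(col_margins < 0) ||
      any(row_margins != round(row_margins)) ||
      any(col_margins != round(col_margins)))
    nw_stop("patefield_sample: margins must be nonnegative integers")
  if (sum(row_margins) != sum(col_margins))
    nw_stop("patefield_sample: row and column margin sums differ")
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
  }
  r2dtable(n, as.integer(row_margins), as.integer(col_margins))
}

#' Fixed-margin null-model test for environmental assortment of interactions
#'
#' Tests whether the observed interaction-weighted mean edge length
#' `<E_r>` in the standardized Grinnellian niche space is shorter than
#' expected under random interactions.  `n_sims` random tables with the
#' observed row and column sums are generated with Patefield's algorithm;
#' for each, the weighted mean expected edge length `<E_e>` is computed
#' with the same (fixed) taxon positions.  The one-tailed permutation
#' p-value uses the add-one estimator with a weak inequality:
#' `p = (1 + #[<E_e> <= <E_r>]) / (1 + n_sims)`; interactions assort
#' environmentally ("shorter than expected") when `p < 0.05`.
#'
#' @param matrix interaction matrix (animals x plants, named, nonnegative
#'   integers).
#' @param positions matrix of niche positions (rows named by taxon,
#'   covering all taxa of `matrix`).
#' @param n_sims number of null tables (default 10000).
#' @param seed optional integer seed for the null draws.
#' @return Object of class `edge_length_test`: a list with `observed`,
#'   `null` (the `<E_e>` samples), `null_mean`, `null_quantiles`
#'   (2.5/50/97.5 percent), `p_value`, `n_sims`, `seed`, `significant`.
#' @export
#' @examples
#' m <- matrix(c(5, 0, 1, 4), 2, 2,
#'             dimnames = list(c("a1", "a2"), c("p1", "p2")))
#' pos <- rbind(a1 = c(0.1, 0.1), a2 = c(0.9, 0.9),
#'              p1 = c(0.2, 0.1), p2 = c(0.8, 0.9))
#' edge_length_test(m, pos, n_sims = 200, seed = 1)
edge_length_test <- function(matrix, positions, n_sims = 10000,
                             seed = NULL) {
  if (!is_number(n_sims) || n_sims < 1)
    nw_stop("edge_length_test: n_sims must be >= 1",
            class = "nicheweb_config_error")
  m <- sum(matrix)
  if (m == 0) nw_stop("edge_length_test: matrix sums to zero")
  D <- edge_length_matrix(matrix, positions)
  observed <- sum(matrix * D) / m
  tables <- patefield_sample(rowSums(matrix), colSums(matrix), n = n_sims,
                             seed = seed)
  nulls <- vapply(tables, function(tb) sum(tb * D) / m, numeric(1))
  p <- (1 + sum(nulls <= observed)) / (1 + n_sims)
  structure(list(observed = observed, null = nulls, null_mean = mean(nulls),
                 null_quantiles = quantile(nulls, c(0.025, 0.5, 0.975)),
                 p_value = p, n_sims = as.integer(n_sims), seed = seed,
                 significant = p < 0.05),
            class = "edge_length_test")
}

#' @export
print.edge_length_test <- function(x, digits = 4, ...) {
  cat("Fixed-margin (Patefield) test of weighted mean edge length\n\n")
  cat(sprintf("  observed <E_r>: %.*f\n", digits, x$observed))
  cat(sprintf("  null <E_e> mean: %.*f  (2.5%%/50%%/97.5%%: %s)\n", digits,
              x$null_mean,
              paste(formatC(x$null_quantiles, digits = digits,
                            format = "f"), collapse = " / ")))
  cat(sprintf("  n_sims: %d,  one-tailed p (shorter than expected): %.4g%s\n",
              x$n_sims, x$p_value, if (x$significant) "  *" else ""))
  invisible(x)
}
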