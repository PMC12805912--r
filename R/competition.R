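#' Normalised patristic distances from a Newick tree
#'
#' Computes the patristic distance (sum of branch lengths along the path)
#' between every pair of leaves and scales the matrix by its maximum, so
#' distances lie in [0, 1] with the most distant pair at exactly 1. The tree
#' should be ultrametric (time-calibrated) for the distances to be comparable
#' across pairs, but ultrametricity is not enforced.
#'
#' @param tree A Newick string, a path to a Newick file, or an
#'   [ape::read.tree()] `phylo` object. Branch lengths are required.
#' @return A list of class `"nichepart_phylo_dist"` with `species`,
#'   `distances` (symmetric matrix, zero diagonal, entries in [0, 1]) and
#'   `max_distance` (the raw normalising constant).
#' @examples
#' patristic_distances("((A:1,B:1):1,C:2);")$distances
#' @export
patristic_distances <- function(tree) {
  phy <- if (inherits(tree, "phylo")) {
    tree
  } else if (file.exists(tree)) {
    ape::read.tree(tree)
  } else {
    ape::read.tree(text = tree)
  }
  if (is.null(phy) || is.null(phy$edge.length)) {
    abort("Tree could not be parsed or lacks branch lengths.",
          class = "nichepart_tree_error")
  }
  if (anyDuplicated(phy$tip.label)) {
    abort("Duplicate leaf labels in tree.", class = "nichepart_tree_error")
  }
  if (length(phy$tip.label) < 2L) {
    abort("At least 2 leaves are required.", class = "nichepart_tree_error")
  }
  D <- ape::cophenetic.phylo(phy)
  dmax <- max(D)
  if (dmax <= 0) {
    abort("All patristic distances are zero; tree has no branch length signal.",
          class = "nichepart_tree_error")
  }
  structure(list(species = rownames(D), distances = D / dmax,
                 max_distance = dmax),
            class = "nichepart_phylo_dist")
}

#' Gaussian phylogenetic competition kernel
#'
#' `alpha(d) = exp(-d^2 / (2 sigma2_alpha))`: the per-capita competitive
#' weight of a species at normalised phylogenetic distance `d` from the
#' focal. Conspecifics (`d = 0`) weigh 1; the default decay rate
#' `sigma2_alpha = 0.05` makes the most distant pair (`d = 1`) weigh
#' `exp(-10)`.
#'
#' @param d Nonnegative normalised distance(s).
#' @param sigma2_alpha Decay-rate parameter (> 0), default 0.05.
#' @return Weight(s) in (0, 1].
#' @examples
#' alpha_kernel(0)            # 1
#' alpha_kernel(1)            # exp(-10)
#' @export
alpha_kernel <- function(d, sigma2_alpha = 0.05) {
  if (sigma2_alpha <= 0) {
    abort("sigma2_alpha must be > 0.", class = "nichepart_validation_error")
  }
  if (any(d < 0)) {
    abort("Distances must be nonnegative.", class = "nichepart_validation_error")
  }
  exp(-d^2 / (2 * sigma2_alpha))
}

#' Effective abundance of competitors (Nz)
#'
#' The competition index for a focal species in one season:
#' `Nz = sum over species present of N(z') * alpha(z, z')`, where `N(z')` is
#' the observed absolute abundance and `alpha` the Gaussian kernel of
#' normalised phylogenetic distance. The focal species' own abundance enters
#' with weight 1 (intraspecific competition), so `Nz >= N(focal)`. Censuses
#' with a `year` column are averaged within season before summing; species
#' absent from the census in that season contribute 0.
#'
#' @param census A data frame with columns `species`, `season`, `abundance`
#'   and optionally `year`.
#' @param dist A `"nichepart_phylo_dist"` from [patristic_distances()].
#' @param focal Focal species (must be a leaf of the tree).
#' @param season Season to evaluate.
#' @param sigma2_alpha Kernel decay rate (default 0.05).
#' @return The effective abundance (a single nonnegative number).
#' @export
effective_abundance <- function(census, dist, focal, season,
                                sigma2_alpha = 0.05) {
  stopifnot(inherits(dist, "nichepart_phylo_dist"))
  if (!focal %in% dist$species) {
    abort(sprintf("Focal species '%s' absent from distance matrix.", focal),
          class = "nichepart_coverage_error")
  }
  if (any(census$abundance < 0)) {
    abort("Abundances must be nonnegative.", class = "nichepart_validation_error")
  }
  missing <- setdiff(unique(census$species), dist$species)
  if (length(missing) > 0L) {
    abort(sprintf("Census species absent from distance matrix: %s",
                  paste(missing, collapse = ", ")),
          class = "nichepart_coverage_error")
  }
  seasonal <- census |>
    dplyr::filter(.data$season == !!season) |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(abundance = mean(.data$abundance), .groups = "drop")
  if (nrow(seasonal) == 0L) return(0)
  d <- dist$distances[focal, seasonal$species]
  sum(seasonal$abundance * alpha_kernel(d, sigma2_alpha))
}

#' Competition-index table for all species and seasons
#'
#' Convenience wrapper computing [effective_abundance()] for every
#' species x season combination present in the census, with seasonal percent
#' changes per species.
#'
#' @inheritParams effective_abundance
#' @return A tibble: species, season, `Nz`, and per-species percent change of
#'   breeding relative to non-breeding.
#' @export
competition_table <- function(census, dist, sigma2_alpha = 0.05) {
  combos <- dplyr::distinct(census, .data$species, .data$season)
  out <- combos |>
    dplyr::mutate(Nz = purrr::map2_dbl(
      .data$species, .data$season,
      ~ effective_abundance(census, dist, .x, .y, sigma2_alpha)))
  wide <- tidyr::pivot_wider(out, names_from = "season", values_from = "Nz")
  if (all(.seasons %in% names(wide))) {
    wide <- dplyr::mutate(
      wide,
      pct_increase_breeding = percent_change(.data$non_breeding, .data$breeding))
    out <- dplyr::left_join(
      out, dplyr::select(wide, dplyr::all_of(c("species", "pct_increase_breeding"))),
      by = "species")
  }
  out
}
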