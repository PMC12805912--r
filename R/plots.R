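#' Plot a standardised isotope dataset
#'
#' Scatter of z-scored (d13C, d15N) values coloured by species and shaped by
#' tissue, faceted by season.
#'
#' @param object A `"nichepart_std"` dataset from [standardize()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nichepart_std
#' @export
autoplot.nichepart_std <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$z13C, .data$z15N,
                                       colour = .data$species,
                                       shape = .data$tissue)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~season) +
    ggplot2::labs(x = expression(paste("z-scored ", delta^13, "C")),
                  y = expression(paste("z-scored ", delta^15, "N"))) +
    ggplot2::theme_minimal()
}

#' Plot posterior niche-metric distributions
#'
#' @param object A `"nichepart_metrics"` tibble (one or several groups bound
#'   together).
#' @param ... Unused.
#' @return A ggplot object: densities of WIC, BIC, TNW and IS per group.
#' @method autoplot nichepart_metrics
#' @export
autoplot.nichepart_metrics <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              dplyr::all_of(c("WIC", "BIC", "TNW", "IS")),
                              names_to = "metric", values_to = "value")
  grp <- if (all(c("species", "season") %in% names(long))) {
    ggplot2::aes(.data$value, fill = interaction(.data$species, .data$season))
  } else {
    ggplot2::aes(.data$value)
  }
  ggplot2::ggplot(long, grp) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = "posterior draw value", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot posterior-mean niche ellipses for fitted groups
#'
#' Draws, for each fitted group, the total-niche ellipse (covariance
#' `G + R`) and the within-individual ellipse (covariance `R`) at the given
#' coverage, both centred on the posterior-mean marginal centroid. Mirrors
#' the standard outer/inner ellipse display of niche-partitioning figures.
#'
#' @param fits A list of `"nichepart_fit"` objects.
#' @param coverage Ellipse coverage (default 0.67).
#' @param n_vertices Polygon resolution.
#' @return A ggplot object.
#' @export
plot_niche_ellipses <- function(fits, coverage = 0.67, n_vertices = 200L) {
  paths <- purrr::map(fits, function(f) {
    d <- f$draws
    centroid <- c(mean(d$mc1), mean(d$mc2))
    G <- matrix(c(mean(d$g11), mean(d$g12), mean(d$g12), mean(d$g22)), 2L)
    R <- matrix(c(mean(d$r11), mean(d$r12), mean(d$r12), mean(d$r22)), 2L)
    make <- function(cov, level) {
      P <- ellipse_polygon(ellipse_spec(centroid, cov, coverage), n_vertices)
      tibble::tibble(z13C = P[, 1L], z15N = P[, 2L],
                     species = f$species, season = f$season, level = level)
    }
    dplyr::bind_rows(make(G + R, "total (G + R)"), make(R, "within (R)"))
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(paths, ggplot2::aes(.data$z13C, .data$z15N,
                                      colour = .data$species,
                                      linetype = .data$level)) +
    ggplot2::geom_path() +
    ggplot2::facet_wrap(~season) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = expression(paste("z-scored ", delta^13, "C")),
                  y = expression(paste("z-scored ", delta^15, "N")),
                  linetype = "ellipse") +
    ggplot2::theme_minimal()
}

#' Plot draw-wise directional overlap distributions
#'
#' @param object A `"nichepart_overlap"` tibble from [posterior_overlap()].
#' @param ... Unused.
#' @return A ggplot object with one histogram per direction.
#' @method autoplot nichepart_overlap
#' @export
autoplot.nichepart_overlap <- function(object, ...) {
  lab <- attr(object, "labels")
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              dplyr::all_of(c("a_in_b", "b_in_a")),
                              names_to = "direction", values_to = "overlap") |>
    dplyr::mutate(direction = ifelse(
      .data$direction == "a_in_b",
      sprintf("%s within %s", lab$a, lab$b),
      sprintf("%s within %s", lab$b, lab$a)))
  ggplot2::ggplot(long, ggplot2::aes(100 * .data$overlap)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "white") +
    ggplot2::facet_wrap(~direction, ncol = 1L) +
    ggplot2::labs(x = "directional niche overlap (%)", y = "draws") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
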