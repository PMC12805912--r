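#' Sum of eigenvalues of a symmetric matrix
#'
#' The within- and between-individual niche components are defined as the sum
#' of the eigenvalues of the residual (`R`) and random-effect (`G`)
#' covariance matrices; for a symmetric matrix this equals the trace.
#'
#' @param M A square symmetric matrix (2x2 in this package's models).
#' @param tol Symmetry tolerance.
#' @return The sum of the eigenvalues of `M`.
#' @examples
#' eigen_sum(matrix(c(2, 1, 1, 2), 2))  # eigenvalues 3 and 1 -> 4
#' @export
eigen_sum <- function(M, tol = 1e-8) {
  M <- check_symmetric(M, tol = tol, arg = "M")
  sum(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
}

#' Draw-wise niche metrics from a fitted group posterior
#'
#' For every retained draw computes WIC = eigen-sum of `R` (within-individual
#' component), BIC = eigen-sum of `G` (between-individual component),
#' TNW = WIC + BIC (total niche width) and IS = BIC/TNW (individual
#' specialisation, in [0, 1]; higher = individuals occupy narrower, more
#' distinct subsets of the population niche). Metrics are computed per draw
#' and then summarised, so the posterior mean of IS is a mean of ratios, not
#' a ratio of means. Draws with TNW = 0 (IS undefined) are dropped with their
#' count recorded in the `n_excluded` attribute.
#'
#' @param post A `"nichepart_fit"` object, or a data frame of draws with
#'   columns `g11`, `g12`, `g22`, `r11`, `r12`, `r22`.
#' @return A tibble of class `"nichepart_metrics"`, one row per draw with
#'   `WIC`, `BIC`, `TNW`, `IS` (plus group labels when available). Summaries
#'   via [summarise_metrics()] or [glance()].
#' @examples
#' draws <- tibble::tibble(g11 = 1, g12 = 0, g22 = 0.7,
#'                         r11 = 0.5, r12 = 0, r22 = 0.5)
#' metrics_from_posterior(draws)  # WIC 1, BIC 1.7, TNW 2.7, IS 0.6296
#' @export
metrics_from_posterior <- function(post) {
  if (inherits(post, "nichepart_fit")) {
    draws <- post$draws
    labels <- list(species = post$species, season = post$season)
  } else {
    draws <- tibble::as_tibble(post)
    labels <- list()
  }
  need <- c("g11", "g22", "r11", "r22")
  if (!all(need %in% names(draws))) {
    abort(sprintf("Draws must contain columns %s.", paste(need, collapse = ", ")),
          class = "nichepart_validation_error")
  }
  if (nrow(draws) < 1L) {
    abort("At least one draw is required.", class = "nichepart_validation_error")
  }
  out <- draws |>
    dplyr::mutate(
      WIC = .data$r11 + .data$r22,
      BIC = .data$g11 + .data$g22,
      TNW = .data$WIC + .data$BIC,
      IS = ifelse(.data$TNW == 0, NA_real_, .data$BIC / .data$TNW)
    )
  n_excluded <- sum(is.na(out$IS))
  out <- dplyr::filter(out, !is.na(.data$IS))
  if (length(labels) > 0L) {
    out <- dplyr::mutate(out, species = labels$species, season = labels$season,
                         .before = 1L)
  }
  keep <- intersect(c("species", "season", "chain", "draw",
                      "WIC", "BIC", "TNW", "IS"), names(out))
  out <- dplyr::select(out, dplyr::all_of(keep))
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("nichepart_metrics", class(out))
  out
}

#' Posterior summaries of niche metrics
#'
#' @param metrics A `"nichepart_metrics"` tibble (see
#'   [metrics_from_posterior()]), possibly several groups bound together.
#' @return A tibble with one row per group x metric: posterior mean, SD
#'   (the reported "SE"), and central 95% interval.
#' @export
summarise_metrics <- function(metrics) {
  keys <- intersect(c("species", "season"), names(metrics))
  metrics |>
    tidyr::pivot_longer(dplyr::all_of(c("WIC", "BIC", "TNW", "IS")),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "metric")))) |>
    dplyr::summarise(
      mean = mean(.data$value), sd = sd(.data$value),
      q2.5 = unname(quantile(.data$value, 0.025)),
      q97.5 = unname(quantile(.data$value, 0.975)),
      .groups = "drop"
    )
}

#' @method glance nichepart_metrics
#' @export
glance.nichepart_metrics <- function(x, ...) {
  tibble::tibble(
    n_draws = nrow(x), n_excluded = attr(x, "n_excluded") %||% 0L,
    WIC_mean = mean(x$WIC), BIC_mean = mean(x$BIC),
    TNW_mean = mean(x$TNW), IS_mean = mean(x$IS)
  )
}

#' Percent change and fold ratio
#'
#' `percent_change(before, after)` returns `100 * (after - before) / before`;
#' `fold_ratio(a, b)` returns `a / b`. These are the arithmetic used for all
#' seasonal and interspecific effect summaries (e.g. an IS drop from 0.541 to
#' 0.112 is a -79.3% change; TNW 3.06 vs 1.39 is a 2.2-fold difference).
#'
#' @param before,after,a,b Nonzero denominators required (`before`, `b`).
#' @return A single number (percent for `percent_change`).
#' @export
percent_change <- function(before, after) {
  if (any(before == 0)) {
    abort("percent_change() requires before != 0.", class = "nichepart_domain_error")
  }
  100 * (after - before) / before
}

#' @rdname percent_change
#' @export
fold_ratio <- function(a, b) {
  if (any(b == 0)) {
    abort("fold_ratio() requires b != 0.", class = "nichepart_domain_error")
  }
  a / b
}
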