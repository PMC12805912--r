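#' Prey taxon richness per season
#'
#' The number of taxa with a positive count in the season's pooled
#' prey-count table.
#'
#' @param counts A data frame with columns `taxon`, `season`, `count`.
#' @param season Season to evaluate.
#' @return An integer richness.
#' @export
richness <- function(counts, season) {
  validate_prey_counts(counts)
  sum(counts$count[counts$season == season] > 0)
}

#' Inverse (reciprocal) Simpson diversity per season
#'
#' `D = 1 / sum(p_i^2)` over the season's pooled taxon proportions. Bounded
#' by `1 <= D <= richness`, with equality at a single taxon and at a uniform
#' community respectively.
#'
#' @inheritParams richness
#' @return The inverse Simpson index (a single number >= 1).
#' @examples
#' tab <- data.frame(taxon = c("a", "b"), season = "breeding", count = c(9, 1))
#' inverse_simpson(tab, "breeding")  # 1/(0.81 + 0.01)
#' @export
inverse_simpson <- function(counts, season) {
  validate_prey_counts(counts)
  x <- counts$count[counts$season == season]
  total <- sum(x)
  if (total <= 0) {
    abort(sprintf("No positive counts in season '%s'; diversity undefined.",
                  season),
          class = "nichepart_diversity_error")
  }
  p <- x / total
  1 / sum(p^2)
}

validate_prey_counts <- function(counts) {
  need <- c("taxon", "season", "count")
  if (!all(need %in% names(counts))) {
    abort(sprintf("Prey counts need columns %s.", paste(need, collapse = ", ")),
          class = "nichepart_schema_error")
  }
  if (any(counts$count < 0)) {
    abort("Counts must be nonnegative.", class = "nichepart_validation_error")
  }
  key <- paste(counts$taxon, counts$season)
  if (anyDuplicated(key)) {
    abort("Taxa must be unique within season.",
          class = "nichepart_validation_error")
  }
  invisible(counts)
}

#' Seasonal contrast in prey richness and diversity
#'
#' Percent difference of richness and inverse Simpson diversity in the
#' non-breeding season relative to the breeding season, with a bootstrap
#' interval obtained by resampling individual prey items (multinomial draws
#' of the pooled counts) within each season.
#'
#' @param counts A prey-count table covering both seasons.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param conf Interval coverage (default 0.95).
#' @param seed Integer seed for the resampling.
#' @return A tibble with one row per index (`richness`,
#'   `inverse_simpson`): the two seasonal values, the percent change
#'   (non-breeding relative to breeding), and bootstrap interval bounds.
#' @export
seasonal_contrast <- function(counts, n_boot = 1000L, conf = 0.95,
                              seed = NULL) {
  validate_prey_counts(counts)
  present <- intersect(.seasons, unique(counts$season))
  if (length(present) < 2L) {
    abort("Both seasons must be present in the prey-count table.",
          class = "nichepart_config_error")
  }
  value <- function(tab) {
    c(richness = sum(tab$count > 0),
      inverse_simpson = {
        p <- tab$count / sum(tab$count); 1 / sum(p^2)
      })
  }
  tab_b <- counts[counts$season == "breeding", ]
  tab_n <- counts[counts$season == "non_breeding", ]
  obs_b <- value(tab_b); obs_n <- value(tab_n)
  pct <- 100 * (obs_n - obs_b) / obs_b

  resample <- function(tab) {
    n <- sum(tab$count)
    tab$count <- as.vector(stats::rmultinom(1L, n, tab$count / n))
    value(tab)
  }
  boots <- with_seed_if(seed, {
    purrr::map(seq_len(n_boot), function(i) {
      rb <- resample(tab_b); rn <- resample(tab_n)
      100 * (rn - rb) / rb
    })
  })
  bm <- do.call(rbind, boots)
  a <- (1 - conf) / 2
  tibble::tibble(
    index = c("richness", "inverse_simpson"),
    breeding = unname(obs_b), non_breeding = unname(obs_n),
    pct_change = unname(pct),
    boot_low = apply(bm, 2L, quantile, probs = a),
    boot_high = apply(bm, 2L, quantile, probs = 1 - a)
  )
}
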