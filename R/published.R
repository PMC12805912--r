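#' Published niche summaries for the two-cormorant study system
#'
#' Posterior-mean niche components (TNW, WIC, BIC, IS) and directional niche
#' overlap percentages reported for the resident red-legged cormorant
#' (*P. gaimardi*) and the dispersive imperial shag (*L. atriceps*) in the
#' non-breeding and breeding seasons, as shipped in
#' `inst/extdata/cormorant_niche_summary.csv`. These summary values are the
#' inputs to the arithmetic consistency checks (fold ratios and percent
#' changes between groups) and anchor the default synthetic study design.
#'
#' @return A tibble: species, season, n, TNW, WIC, BIC, IS, overlap_pct.
#' @examples
#' pub <- published_niche_summary()
#' with(pub, fold_ratio(TNW[species == "L_atriceps" & season == "non_breeding"],
#'                      TNW[species == "P_gaimardi" & season == "non_breeding"]))
#' @export
published_niche_summary <- function() {
  path <- system.file("extdata", "cormorant_niche_summary.csv",
                      package = "nichepart", mustWork = TRUE)
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
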