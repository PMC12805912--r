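#' Configuration for the bivariate mixed-model sampler
#'
#' Defaults match the analysis settings of the study system: 100,000
#' iterations per chain, burn-in 5,000, thinning 10, and five independent
#' chains for the Gelman-Rubin diagnostic. `test_config()` returns a reduced
#' desk-scale configuration used throughout the examples and tests.
#'
#' @param n_iterations Total Gibbs iterations per chain.
#' @param thin Thinning interval (>= 1); draws are retained at iterations
#'   `burn_in + thin, burn_in + 2*thin, ...`.
#' @param burn_in Iterations discarded before retention (< `n_iterations`).
#' @param n_chains Number of independent chains.
#' @param prior_G,prior_R Inverse-Wishart priors, each a list with `scale`
#'   (2x2 PSD) and `df` (> 1). The default identity scale with df = 3 is
#'   weakly informative on z-scored data.
#' @param fixed_effects Character subset of `c("intercept", "campaign")`.
#' @param psrf_threshold Convergence cut for the potential scale reduction
#'   factor (default 1.1).
#' @param seed Integer seed; chain `c` uses `seed + c - 1`.
#' @return A list of class `"nichepart_config"`.
#' @export
mm_config <- function(n_iterations = 100000L, thin = 10L, burn_in = 5000L,
                      n_chains = 5L,
                      prior_G = list(scale = diag(2), df = 3),
                      prior_R = list(scale = diag(2), df = 3),
                      fixed_effects = c("intercept", "campaign"),
                      psrf_threshold = 1.1,
                      seed = 1L) {
  stopifnot(thin >= 1L, burn_in >= 0L, n_chains >= 1L)
  if (burn_in >= n_iterations) {
    abort("burn_in must be smaller than n_iterations.",
          class = "nichepart_config_error")
  }
  if (prior_G$df <= 1 || prior_R$df <= 1) {
    abort("Inverse-Wishart prior df must exceed dimension - 1 = 1.",
          class = "nichepart_config_error")
  }
  if (!"intercept" %in% fixed_effects) {
    abort("fixed_effects must include the intercept.",
          class = "nichepart_config_error")
  }
  prior_G$scale <- check_psd(as.matrix(prior_G$scale), arg = "prior_G$scale")
  prior_R$scale <- check_psd(as.matrix(prior_R$scale), arg = "prior_R$scale")
  structure(list(n_iterations = as.integer(n_iterations), thin = as.integer(thin),
                 burn_in = as.integer(burn_in), n_chains = as.integer(n_chains),
                 prior_G = prior_G, prior_R = prior_R,
                 fixed_effects = fixed_effects,
                 psrf_threshold = psrf_threshold, seed = as.integer(seed)),
            class = "nichepart_config")
}

#' @rdname mm_config
#' @export
test_config <- function(n_iterations = 20000L, thin = 10L, burn_in = 2000L,
                        n_chains = 3L, seed = 1L, ...) {
  mm_config(n_iterations = n_iterations, thin = thin, burn_in = burn_in,
            n_chains = n_chains, seed = seed, ...)
}

#' Fit the Bayesian bivariate mixed model to one species x season group
#'
#' Fits, by Gibbs sampling, the model `y_it = X beta + b_i + e_it` where
#' `y_it` is the (z13C, z15N) pair of individual `i` in tissue record `t`,
#' `b_i ~ N2(0, G)` is an individual random intercept and `e_it ~ N2(0, R)`
#' a residual; `G` is the between-individual and `R` the within-individual
#' covariance. The sampler cycles: (1) fixed effects from their conditional
#' matrix normal; (2) individual intercepts from conditional normals;
#' (3) `G ~ IW(scale + sum b_i b_i', df + n_individuals)`;
#' (4) `R ~ IW(scale + sum e_it e_it', df + n_records)`.
#' Tissue is deliberately not a fixed effect: standardisation removes tissue
#' means and the residual multi-tissue scatter is the repeated-measures
#' signal that defines the within-individual component.
#'
#' @param data A standardised dataset (see [standardize()]) restricted to one
#'   species x season group, or any data frame with `individual_id`,
#'   `campaign` and `z13C`/`z15N` columns.
#' @param config A [mm_config()] object.
#' @param species,season Optional filters applied to `data` before fitting.
#' @return An object of class `"nichepart_fit"`: posterior draws (one row per
#'   retained draw: chain, iteration, `mu1`, `mu2`, campaign effects, `g11`,
#'   `g12`, `g22`, `r11`, `r12`, `r22`, marginal centroid `mc1`, `mc2`),
#'   plus a convergence report. See [tidy.nichepart_fit()] and
#'   [glance.nichepart_fit()].
#' @examples
#' truth <- default_study_design()[1, ]
#' std <- standardize(simulate_isotopes(truth, seed = 1))
#' fit <- fit_group(std, test_config(n_iterations = 2000, burn_in = 500,
#'                                   n_chains = 2, seed = 1))
#' glance(fit)
#' @export
fit_group <- function(data, config = mm_config(), species = NULL, season = NULL) {
  if (!is.null(species)) data <- dplyr::filter(data, .data$species == !!species)
  if (!is.null(season)) data <- dplyr::filter(data, .data$season == !!season)
  if (nrow(data) == 0L) {
    abort("No records left after filtering.", class = "nichepart_config_error")
  }
  if (length(unique(data$species)) > 1L || length(unique(data$season)) > 1L) {
    abort("fit_group() expects a single species x season group; filter first.",
          class = "nichepart_config_error")
  }
  vcols <- if (all(c("z13C", "z15N") %in% names(data))) c("z13C", "z15N")
           else c("d13C", "d15N")
  Y <- as.matrix(data[, vcols])
  id <- as.integer(factor(data$individual_id,
                          levels = unique(data$individual_id)))
  n_ind <- max(id)
  if (n_ind < 3L) {
    abort("At least 3 individuals are required.",
          class = "nichepart_identifiability_error")
  }
  if (max(tabulate(id)) < 2L) {
    abort(paste("Every individual has a single record; the between-individual",
                "covariance G is unidentifiable without repeated measures."),
          class = "nichepart_identifiability_error")
  }
  use_campaign <- "campaign" %in% config$fixed_effects &&
    length(unique(data$campaign)) > 1L
  if (use_campaign) {
    camp <- factor(data$campaign, levels = unique(data$campaign))
    X <- stats::model.matrix(~camp)
    beta_names <- c("mu", paste0("beta_", levels(camp)[-1L]))
    camp_levels <- levels(camp)
  } else {
    X <- matrix(1, nrow(Y), 1L)
    beta_names <- "mu"
    camp_levels <- unique(data$campaign)
  }

  chains <- purrr::map(seq_len(config$n_chains), function(ch) {
    withr::with_seed(config$seed + ch - 1L, {
      gibbs_chain(Y, X, id, config)
    })
  })
  p <- ncol(X)
  par_names <- c(paste0(rep(beta_names, each = 2L), c("_1", "_2")),
                 "g11", "g12", "g22", "r11", "r12", "r22")
  par_names[1:2] <- c("mu1", "mu2")
  draws <- purrr::imap(chains, function(m, ch) {
    colnames(m) <- par_names
    tibble::as_tibble(m) |>
      dplyr::mutate(chain = ch, draw = dplyr::row_number(), .before = 1L)
  }) |>
    dplyr::bind_rows()
  # Marginal centroid: intercept plus the equal-weight average of campaign
  # deviations (reference campaign contributes 0).
  if (use_campaign) {
    dev1 <- as.matrix(draws[, paste0("beta_", camp_levels[-1L], "_1")])
    dev2 <- as.matrix(draws[, paste0("beta_", camp_levels[-1L], "_2")])
    draws$mc1 <- draws$mu1 + rowSums(dev1) / length(camp_levels)
    draws$mc2 <- draws$mu2 + rowSums(dev2) / length(camp_levels)
  } else {
    draws$mc1 <- draws$mu1
    draws$mc2 <- draws$mu2
  }

  convergence <- NULL
  converged <- NA
  if (config$n_chains >= 2L) {
    scalar_pars <- c("mu1", "mu2", "g11", "g12", "g22", "r11", "r12", "r22")
    psrf <- purrr::map_dbl(scalar_pars, function(par) {
      gelman_rubin(split(draws[[par]], draws$chain))
    })
    convergence <- tibble::tibble(parameter = scalar_pars, psrf = psrf)
    converged <- all(psrf < config$psrf_threshold)
    if (!converged) {
      warn(sprintf("PSRF above %.2f for: %s", config$psrf_threshold,
                   paste(scalar_pars[psrf >= config$psrf_threshold],
                         collapse = ", ")),
           class = "nichepart_convergence_warning")
    }
  }
  structure(list(
    species = unique(data$species), season = unique(data$season),
    draws = draws, config = config, convergence = convergence,
    converged = converged, n_individuals = n_ind, n_records = nrow(Y),
    n_effective_draws = nrow(draws), campaigns = camp_levels
  ), class = "nichepart_fit")
}

# One Gibbs chain. Y: N x 2 responses; X: N x p fixed-effect design;
# id: individual index 1..n per row. Returns the retained-draw matrix with
# columns (vec beta by row, g11, g12, g22, r11, r12, r22).
gibbs_chain <- function(Y, X, id, config) {
  N <- nrow(Y); p <- ncol(X); n_ind <- max(id)
  C <- solve(crossprod(X))
  Lc <- t(chol(C))
  ks <- tabulate(id, n_ind)
  by_k <- split(seq_len(n_ind), ks)
  S0G <- config$prior_G$scale; df0G <- config$prior_G$df
  S0R <- config$prior_R$scale; df0R <- config$prior_R$df

  B <- C %*% crossprod(X, Y)
  b <- matrix(0, n_ind, 2L)
  E0 <- Y - X %*% B
  Rm <- stats::cov(E0) + diag(1e-6, 2L)
  Gm <- diag(0.5, 2L)

  n_keep <- (config$n_iterations - config$burn_in) %/% config$thin
  out <- matrix(NA_real_, n_keep, 2L * p + 6L)
  keep <- 0L
  idf <- factor(id, levels = seq_len(n_ind))

  for (t in seq_len(config$n_iterations)) {
    # fixed effects | b, R
    U <- Y - b[id, , drop = FALSE]
    Bhat <- C %*% crossprod(X, U)
    B <- Bhat + Lc %*% matrix(rnorm(2L * p), p, 2L) %*% chol(Rm)
    # random intercepts | beta, G, R (grouped by replicate count)
    Rres <- Y - X %*% B
    S <- rowsum(Rres, idf)
    Ginv <- solve(Gm); Rinv <- solve(Rm)
    for (kname in names(by_k)) {
      k <- as.integer(kname)
      idx <- by_k[[kname]]
      V <- solve(Ginv + k * Rinv)
      M <- S[idx, , drop = FALSE] %*% Rinv %*% V
      b[idx, ] <- M + matrix(rnorm(2L * length(idx)), length(idx), 2L) %*%
        chol(V)
    }
    # G | b
    Gm <- rinvwishart(df0G + n_ind, S0G + crossprod(b))
    # R | residuals
    E <- Rres - b[id, , drop = FALSE]
    Rm <- rinvwishart(df0R + N, S0R + crossprod(E))
    if (t > config$burn_in && (t - config$burn_in) %% config$thin == 0L) {
      keep <- keep + 1L
      out[keep, ] <- c(t(B), Gm[1L], Gm[2L], Gm[4L], Rm[1L], Rm[2L], Rm[4L])
    }
  }
  out
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Computes `PSRF = sqrt(((n - 1)/n * W + B/n) / W)` across chains, with `W`
#' the mean within-chain variance and `B = n * var(chain means)`. Values near
#' 1 indicate the chains have mixed; the conventional cut used by
#' [fit_group()] is 1.1.
#'
#' @param chains A list of numeric vectors (equal length >= 2), one per chain.
#' @return The PSRF (a single number).
#' @examples
#' gelman_rubin(list(c(1, 2, 3), c(1, 2, 3)))  # sqrt(2/3)
#' @export
gelman_rubin <- function(chains) {
  if (length(chains) < 2L) {
    abort("At least 2 chains are required.", class = "nichepart_config_error")
  }
  n <- unique(lengths(chains))
  if (length(n) != 1L || n < 2L) {
    abort("Chains must have equal length >= 2.", class = "nichepart_config_error")
  }
  W <- mean(purrr::map_dbl(chains, var))
  if (W == 0) {
    abort("Zero within-chain variance in all chains; PSRF undefined.",
          class = "nichepart_psrf_error")
  }
  B <- n * var(purrr::map_dbl(chains, mean))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @export
print.nichepart_fit <- function(x, ...) {
  cat(sprintf("<nichepart_fit> %s / %s\n", x$species, x$season))
  cat(sprintf("  %d individuals, %d records, %d retained draws (%d chains)\n",
              x$n_individuals, x$n_records, x$n_effective_draws,
              x$config$n_chains))
  if (!is.null(x$convergence)) {
    cat(sprintf("  max PSRF %.3f (%s)\n", max(x$convergence$psrf),
                if (isTRUE(x$converged)) "converged" else "NOT converged"))
  }
  invisible(x)
}

#' Tidy posterior summaries of a fitted group model
#'
#' @param x A `"nichepart_fit"` object.
#' @param ... Unused.
#' @return A tibble with one row per scalar parameter: posterior mean, SD,
#'   and central 95% interval, plus the PSRF where available.
#' @method tidy nichepart_fit
#' @export
tidy.nichepart_fit <- function(x, ...) {
  pars <- setdiff(names(x$draws), c("chain", "draw"))
  out <- purrr::map(pars, function(p) {
    v <- x$draws[[p]]
    tibble::tibble(parameter = p, estimate = mean(v), std.error = sd(v),
                   conf.low = unname(quantile(v, 0.025)),
                   conf.high = unname(quantile(v, 0.975)))
  }) |> dplyr::bind_rows()
  if (!is.null(x$convergence)) {
    out <- dplyr::left_join(out, x$convergence, by = "parameter")
  }
  out
}

#' One-row summary of a fitted group model
#'
#' @param x A `"nichepart_fit"` object.
#' @param ... Unused.
#' @return A tibble: group labels, sizes, retained draws, max PSRF,
#'   convergence flag.
#' @method glance nichepart_fit
#' @export
glance.nichepart_fit <- function(x, ...) {
  tibble::tibble(
    species = x$species, season = x$season,
    n_individuals = x$n_individuals, n_records = x$n_records,
    n_chains = x$config$n_chains, n_draws = x$n_effective_draws,
    max_psrf = if (is.null(x$convergence)) NA_real_ else max(x$convergence$psrf),
    converged = x$converged
  )
}
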