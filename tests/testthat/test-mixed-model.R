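test_that("gelman_rubin matches the direct formula and limiting behaviour", {
  # identical chains: B = 0 -> PSRF = sqrt((n-1)/n)
  expect_equal(gelman_rubin(list(c(1, 2, 3), c(1, 2, 3))), sqrt(2 / 3))
  # same-distribution chains: PSRF near 1
  withr::with_seed(1, {
    ch <- list(rnorm(1e4), rnorm(1e4), rnorm(1e4))
    expect_lt(gelman_rubin(ch), 1.05)
    # disjoint supports dominate between-chain variance
    expect_gt(gelman_rubin(list(rnorm(100, 0), rnorm(100, 100))), 10)
  })
  expect_error(gelman_rubin(list(c(1, 1), c(1, 1))),
               class = "nichepart_psrf_error")
  expect_error(gelman_rubin(list(c(1, 2))), class = "nichepart_config_error")
})

test_that("fits are deterministic under a fixed seed and count retained draws correctly", {
  rec <- simulate_isotopes(tiny_truth(n = 10L), seed = 2)
  cfg <- fast_config(seed = 3)
  f1 <- fit_group(rec, cfg)
  f2 <- fit_group(rec, cfg)
  expect_identical(f1$draws, f2$draws)
  expect_equal(f1$n_effective_draws,
               cfg$n_chains * ((cfg$n_iterations - cfg$burn_in) %/% cfg$thin))
})

test_that("every stored G and R draw is symmetric PSD", {
  rec <- simulate_isotopes(tiny_truth(n = 12L), seed = 4)
  f <- fit_group(rec, fast_config(seed = 4))
  d <- f$draws
  for (i in seq_len(nrow(d))) {
    G <- matrix(c(d$g11[i], d$g12[i], d$g12[i], d$g22[i]), 2)
    R <- matrix(c(d$r11[i], d$r12[i], d$r12[i], d$r22[i]), 2)
    ev <- c(eigen(G, symmetric = TRUE, only.values = TRUE)$values,
            eigen(R, symmetric = TRUE, only.values = TRUE)$values)
    if (min(ev) <= -1e-10) fail(sprintf("non-PSD draw at row %d", i))
  }
  succeed()
})

test_that("unidentifiable and undersized designs are refused", {
  rec <- simulate_isotopes(tiny_truth(n = 10L, tissues = "t1"), seed = 1)
  expect_error(fit_group(rec, fast_config()),
               class = "nichepart_identifiability_error")
  rec2 <- simulate_isotopes(tiny_truth(n = 2L), seed = 1)
  expect_error(fit_group(rec2, fast_config()),
               class = "nichepart_identifiability_error")
})

test_that("posterior concentrates near planted covariance traces", {
  truth <- tiny_truth(n = 60L, G = diag(0.5, 2), R = diag(1, 2),
                      tissues = paste0("t", 1:4))
  rec <- simulate_isotopes(truth, seed = 2)
  f <- fit_group(rec, mm_config(n_iterations = 4000, burn_in = 1000,
                                thin = 5, n_chains = 2, seed = 2))
  g <- glance(metrics_from_posterior(f))
  expect_equal(g$WIC_mean, 2, tolerance = 0.10)
  expect_equal(g$BIC_mean, 1, tolerance = 0.35)
})

test_that("a null G truth collapses the between-individual component", {
  truth <- tiny_truth(n = 40L, G = matrix(0, 2, 2), R = diag(1, 2),
                      tissues = paste0("t", 1:3))
  rec <- simulate_isotopes(truth, seed = 6)
  f <- fit_group(rec, fast_config(seed = 6))
  g <- glance(metrics_from_posterior(f))
  # posterior floor from the weakly-informative prior plus finite-sample
  # noise in the 40 individual means; far below any planted signal
  expect_lt(g$BIC_mean, 0.4)
  expect_lt(g$IS_mean, 0.15)
})

test_that("posterior SD of trace(G) shrinks as individuals are added", {
  sds <- purrr::map_dbl(c(15L, 120L), function(n) {
    rec <- simulate_isotopes(tiny_truth(n = n, G = diag(0.5, 2)), seed = 9)
    f <- fit_group(rec, fast_config(seed = 9, n_chains = 1L))
    m <- metrics_from_posterior(f)
    sd(m$BIC)
  })
  expect_lt(sds[2], sds[1])
})

test_that("central 90% interval for trace(G) covers the truth at nominal-ish rate", {
  # 40 reduced-scale replicates; band 80-98% per the calibration property
  hits <- purrr::map_lgl(seq_len(40L), function(i) {
    rec <- simulate_isotopes(tiny_truth(n = 25L, G = diag(0.5, 2), R = diag(1, 2)),
                             seed = 500L + i)
    f <- fit_group(rec, mm_config(n_iterations = 1200, burn_in = 400, thin = 4,
                                  n_chains = 1L, seed = 500L + i))
    m <- metrics_from_posterior(f)
    q <- quantile(m$BIC, c(0.05, 0.95))
    q[1] <= 1 && 1 <= q[2]
  })
  expect_gte(mean(hits), 0.80)
  expect_lte(mean(hits), 0.98)
})

test_that("campaign fixed effects are estimated and folded into the marginal centroid", {
  truth <- group_truth("sp", "breeding", 30L, mu = c(0, 0),
                       G = diag(0.3, 2), R = diag(0.5, 2),
                       tissues = paste0("t", 1:3),
                       campaigns = c("c1", "c2"),
                       campaign_effects = list(c1 = c(0, 0), c2 = c(2, 0)))
  rec <- simulate_isotopes(truth, seed = 12)
  f <- fit_group(rec, fast_config(seed = 12))
  td <- tidy(f)
  beta1 <- td$estimate[td$parameter == "beta_c2_1"]
  expect_equal(beta1, 2, tolerance = 0.5)
  # marginal centroid averages campaign deviations: mu + beta/2
  expect_equal(mean(f$draws$mc1), mean(f$draws$mu1) + beta1 / 2,
               tolerance = 1e-8)
})

test_that("config invariants are enforced", {
  expect_error(mm_config(n_iterations = 100, burn_in = 200),
               class = "nichepart_config_error")
  expect_error(mm_config(prior_G = list(scale = diag(2), df = 1)),
               class = "nichepart_config_error")
  expect_error(mm_config(fixed_effects = "campaign"),
               class = "nichepart_config_error")
})
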