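test_that("ellipse areas follow the chi-squared(2) closed form and det scaling", {
  e <- ellipse_spec(c(0, 0), diag(2), coverage = 0.67)
  expect_equal(ellipse_area(e), pi * (-2 * log(0.33)))
  P <- ellipse_polygon(e, 360L)
  expect_lt(abs(nichepart:::polygon_area(P) - ellipse_area(e)) / ellipse_area(e),
            0.001)
  # det scaling: diag(4, 1) doubles the identity-covariance area
  e2 <- ellipse_spec(c(0, 0), diag(c(4, 1)), coverage = 0.67)
  expect_equal(ellipse_area(e2), 2 * ellipse_area(e))
  expect_error(ellipse_polygon(ellipse_spec(c(0, 0), matrix(c(1, 1, 1, 1), 2))),
               class = "nichepart_degenerate_ellipse_error")
})

test_that("the 67% ellipse contains 67% of bivariate-normal mass (Monte-Carlo)", {
  Sigma <- matrix(c(2, 0.8, 0.8, 1), 2)
  e <- ellipse_spec(c(1, -1), Sigma, coverage = 0.67)
  P <- ellipse_polygon(e, 360L)
  withr::with_seed(13, {
    pts <- MASS::mvrnorm(1e5, mu = c(1, -1), Sigma = Sigma)
  })
  frac <- mean(in_convex_polygon(pts, P))
  expect_equal(frac, 0.67, tolerance = 0.015)
})

test_that("directional overlap handles identity, disjoint and nested geometries", {
  e <- ellipse_spec(c(0, 0), diag(2))
  expect_equal(directional_overlap(e, e), 1.0)
  far <- ellipse_spec(c(100, 0), diag(2))
  expect_equal(directional_overlap(e, far), 0.0)
  # concentric similar ellipses: small fully inside big; big covered by
  # area ratio = det^{1/2} ratio = 1/4
  big <- ellipse_spec(c(0, 0), 4 * diag(2))
  expect_equal(directional_overlap(e, big), 1.0)
  expect_equal(directional_overlap(big, e), 0.25, tolerance = 0.01)
})

test_that("polygon overlap agrees with a rejection-sampling oracle on random pairs", {
  withr::with_seed(21, {
    for (i in seq_len(20L)) {
      a <- ellipse_spec(rnorm(2, sd = 0.8), random_psd() + diag(0.3, 2))
      b <- ellipse_spec(rnorm(2, sd = 0.8), random_psd() + diag(0.3, 2))
      got <- directional_overlap(a, b, n_vertices = 360L)
      oracle <- mc_overlap(a, b, n = 40000L)
      # absolute agreement; the oracle itself carries ~0.0025 MC noise
      expect_lt(abs(got - oracle), 0.012)
    }
  })
})

test_that("intersection area is shared: area(a) ov(a,b) = area(b) ov(b,a)", {
  withr::with_seed(22, {
    for (i in seq_len(10L)) {
      a <- ellipse_spec(rnorm(2, sd = 0.5), random_psd() + diag(0.2, 2))
      b <- ellipse_spec(rnorm(2, sd = 0.5), random_psd() + diag(0.2, 2))
      lhs <- ellipse_area(a) * directional_overlap(a, b)
      rhs <- ellipse_area(b) * directional_overlap(b, a)
      if (lhs > 0) expect_lt(abs(lhs - rhs) / lhs, 1e-6) else expect_equal(rhs, 0)
    }
  })
})

test_that("posterior overlap pairs draws by index and recovers planted geometry", {
  rec <- simulate_isotopes(tiny_truth(n = 15L), seed = 30)
  f <- fit_group(rec, fast_config(seed = 30, n_chains = 1L))
  ov <- posterior_overlap(f, f)
  expect_true(all(ov$a_in_b == 1 & ov$b_in_a == 1))

  # far-separated groups overlap (almost) nowhere
  t_far <- group_truth("sp2", "breeding", 15L, mu = c(10, 10),
                       G = diag(0.5, 2), R = diag(1, 2),
                       tissues = paste0("t", 1:3))
  f_far <- fit_group(simulate_isotopes(t_far, seed = 31),
                     fast_config(seed = 31, n_chains = 1L))
  ovf <- glance(posterior_overlap(f, f_far))
  expect_lt(ovf$a_in_b_pct, 1)
  expect_lt(ovf$b_in_a_pct, 1)

  # nested: narrow group inside a 4x broader one at a shared centroid
  t_broad <- group_truth("sp3", "breeding", 40L, mu = c(0, 0),
                         G = diag(2, 2), R = diag(4, 2),
                         tissues = paste0("t", 1:3))
  f_broad <- fit_group(simulate_isotopes(t_broad, seed = 32),
                       fast_config(seed = 32, n_chains = 1L))
  ovn <- glance(posterior_overlap(f, f_broad))
  expect_gt(ovn$a_in_b_pct, 90)   # narrow within broad
  expect_lt(ovn$b_in_a_pct, 40)   # broad within narrow

  # draw-count mismatch is a pairing error, not silently resampled
  f_short <- fit_group(rec, mm_config(n_iterations = 600, burn_in = 100,
                                      thin = 5, n_chains = 1L, seed = 1))
  expect_error(posterior_overlap(f, f_short), class = "nichepart_pairing_error")
})

test_that("overlaps stay within [0, 1] across a posterior", {
  rec <- simulate_isotopes(tiny_truth(n = 12L), seed = 33)
  f1 <- fit_group(rec, fast_config(seed = 33, n_chains = 1L))
  t2 <- group_truth("spB", "breeding", 12L, mu = c(0.5, 0.2),
                    G = diag(0.4, 2), R = diag(0.8, 2),
                    tissues = paste0("t", 1:3))
  f2 <- fit_group(simulate_isotopes(t2, seed = 34),
                  fast_config(seed = 34, n_chains = 1L))
  ov <- posterior_overlap(f1, f2)
  expect_true(all(ov$a_in_b >= 0 & ov$a_in_b <= 1))
  expect_true(all(ov$b_in_a >= 0 & ov$b_in_a <= 1))
})
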