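test_that("unit conversions round-trip exactly", {
  expect_equal(rate_to_molar(1), 6.02214076e8, tolerance = 1e-12)
  expect_equal(rate_to_molar(0), 0)
  k <- c(0.3, 26.4, 1e4)
  expect_equal(molar_to_rate(rate_to_molar(k)), k, tolerance = 1e-12)
})

test_that("effective diffusion slows with the bound-time fraction", {
  expect_equal(effective_diffusion(8, 2, 6), 6)
  expect_equal(effective_diffusion(8, 0, 6), 8) # no binding limit
  expect_equal(effective_diffusion(10, 5, 5), 5)
})

test_that("absorbing-sphere rate is the Smoluchowski value", {
  # 4 pi * 6 * 0.35 = 26.39 um^3/s -> 1.589e10 /M/s
  expect_equal(absorbing_sphere_rate(6, 0.35),
    rate_to_molar(4 * pi * 6 * 0.35),
    tolerance = 1e-12
  )
  expect_equal(absorbing_sphere_rate(6, 0.35) / 1e10, 1.589, tolerance = 1e-3)
  expect_equal(absorbing_sphere_rate(6, 0), 0)
  expect_equal(
    absorbing_sphere_rate(12, 0.35) / absorbing_sphere_rate(6, 0.35), 2,
    tolerance = 1e-12
  )
})

test_that("kappa interpolation reproduces both limiting forms", {
  d <- 6
  a <- 1e-3
  v <- (4 * pi / 3) * 0.35^3 / 19200
  # perfect-association limit: kappa -> 4 pi D a / v
  expect_equal(site_rate_kappa(d, a, v, lambda = 1e6 * d / a^2),
    4 * pi * d * a / v,
    tolerance = 1e-5
  )
  # low-efficiency limit: kappa -> lambda (4 pi / 3) a^3 / v
  lam_small <- 1e-6 * d / a^2
  expect_equal(site_rate_kappa(d, a, v, lambda = lam_small),
    lam_small * (4 * pi / 3) * a^3 / v,
    tolerance = 1e-6
  )
  # harmonic-mean identity at lambda = 3 D / a^2
  expect_equal(site_rate_kappa(d, a, v, lambda = 3 * d / a^2),
    0.5 * 4 * pi * d * a / v,
    tolerance = 1e-12
  )
})

test_that("reactive-sphere rate has the right limits and tanh factor", {
  d <- 6
  r_t <- 0.35
  # huge kappa -> absorbing sphere within 1%
  expect_equal(locus_binding_rate(d, r_t, 1e9),
    absorbing_sphere_rate(d, r_t),
    tolerance = 0.01
  )
  # small kappa -> volume-reaction limit within 1%
  k_small <- 1e-6
  expect_equal(locus_binding_rate(d, r_t, k_small) / k_small,
    rate_to_molar((4 * pi / 3) * r_t^3),
    tolerance = 0.01
  )
  # x = 1: factor (1 - tanh 1) = 0.23840 of the absorbing-sphere value
  kappa_x1 <- d / r_t^2
  expect_equal(
    locus_binding_rate(d, r_t, kappa_x1) / absorbing_sphere_rate(d, r_t),
    1 - tanh(1),
    tolerance = 1e-9
  )
  # continuity across the series switchover
  x_lo <- 0.9999e-4
  x_hi <- 1.0001e-4
  k_lo <- d * (x_lo / r_t)^2
  k_hi <- d * (x_hi / r_t)^2
  jump <- abs(
    locus_binding_rate(d, r_t, k_lo) / locus_binding_rate(d, r_t, k_hi) *
      (x_hi / x_lo)^2 - 1
  )
  expect_lt(jump, 1e-6)
  # monotone increasing in kappa
  ks <- 10^seq(-3, 8, length.out = 40)
  vals <- vapply(ks, function(k) locus_binding_rate(d, r_t, k), numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("lambda extraction inverts the reaction-limited forward map", {
  lam <- extract_lambda(9.2e4, n_sites = 19200, a = 1e-3, d = 6)
  expect_equal(lam$lambda, 1.9, tolerance = 0.01)
  expect_lt(lam$regime_ratio, 1e-6)
  expect_true(lam$reaction_limited)
  # inverse proportionality in N
  expect_equal(
    extract_lambda(9.2e4, 2 * 19200, 1e-3)$lambda, lam$lambda / 2,
    tolerance = 1e-12
  )
  # round trip: forward reaction-limited rate -> lambda
  k_fwd <- rate_to_molar(lam$lambda * (4 * pi / 3) * 19200 * (1e-3)^3)
  expect_equal(k_fwd, 9.2e4, tolerance = 1e-9)
  expect_warning(extract_lambda(1e10, 10, 1e-3, d = 6), "questionable")
})

test_that("sliding length follows the 1D span convention", {
  expect_equal(sliding_length(1e5, 0.158), sqrt(4 * 1e5 * 0.158),
    tolerance = 1e-12
  )
  expect_equal(sliding_length(1e5, 0.158), 251.4, tolerance = 1e-3)
  expect_equal(sliding_length(1e6, 0.158), 795.0, tolerance = 1e-3)
  expect_equal(sliding_length(1e5, 0), 0)
})

test_that("facilitated-diffusion rate and p-inversion are consistent", {
  # p = 1, 200 inserts, 500 bp, c_DNA = 1e-2 M, cycle 8 s -> 1.25e6 /M/s
  expect_equal(fd_association_rate(1, 200, 500, 1e-2, 2, 6), 1.25e6)
  expect_equal(fd_association_rate(0, 200, 500, 1e-2, 2, 6), 0)
  k <- fd_association_rate(0.3, 200, 500, 1e-2, 2, 6)
  sp <- solve_p(k, 200, 500, 1e-2, 2, 6)
  expect_equal(sp$p_raw, 0.3, tolerance = 1e-12)
  expect_true(sp$in_range)
  # out-of-range inversion is clipped and flagged
  sp2 <- solve_p(1e8, 200, 500, 1e-2, 2, 6)
  expect_false(sp2$in_range)
  expect_equal(sp2$p, 1)
})

test_that("single-molecule search time and visit count", {
  t_search <- search_time_single(9.2e4, 500)
  expect_equal(t_search, 3.27e6, tolerance = 1e-3)
  expect_equal(signif(t_search, 1), 3e6)
  expect_equal(nonspecific_visits(t_search, 0.125), 4.09e5, tolerance = 1e-3)
  expect_equal(search_time_single(9.2e4, 1000) / t_search, 2,
    tolerance = 1e-12
  )
})

test_that("diffusion-limited nonspecific association time", {
  tau <- diffusion_limited_ns_time(8, 1e-3, 1e-2)
  expect_equal(tau, 2.0756e-5, tolerance = 1e-4)
  expect_equal(10^round(log10(tau)), 1e-5) # order of magnitude
  expect_equal(diffusion_limited_ns_time(8, 1e-3, 0.5e-2) / tau, 2,
    tolerance = 1e-12
  )
})

test_that("the model report assembles all derived quantities", {
  rep <- search_model_report()
  expect_true(all(c(
    "d_eff", "lambda", "sliding_length", "p_specific",
    "search_time_single"
  ) %in% rep$quantity))
  expect_equal(rep$value[rep$quantity == "d_eff"], 6)
  expect_true(all(is.finite(rep$value)))
})
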