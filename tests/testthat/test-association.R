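test_that("monoexponential fits are exact on noiseless data", {
  tg <- seq(0, 400, 5)
  for (pars in list(c(0.01, 80, 3), c(0.05, 500, 0))) {
    y <- pars[3] + pars[2] * (1 - exp(-pars[1] * tg))
    f <- fit_monoexponential_rise(tg, y)
    expect_equal(f$k_obs, pars[1], tolerance = 1e-6)
    expect_equal(f$plateau, pars[2], tolerance = 1e-4)
    expect_equal(f$baseline, pars[3], tolerance = 1e-4)
  }
  # decay variant: dissociation with tau = 16 s under 5% noise
  tg2 <- seq(0, 80, 1)
  y2 <- withr::with_seed(81, {
    100 * exp(-tg2 / 16) + rnorm(length(tg2), sd = 5)
  })
  f2 <- fit_monoexponential_rise(tg2, y2, form = "decay")
  expect_equal(f2$tau_s, 16, tolerance = 0.1)
  # constant series flagged with k ~ 0
  expect_warning(
    f3 <- fit_monoexponential_rise(tg, rep(5, length(tg))),
    "constant"
  )
  expect_true(f3$flat)
  expect_equal(f3$k_obs, 0)
  expect_error(fit_monoexponential_rise(1:3, 1:3), "5 time points")
})

test_that("estimator bias is small at realistic signal-to-noise", {
  tg <- seq(0, 400, 10)
  k_true <- 0.01
  ks <- withr::with_seed(82, vapply(1:200, function(i) {
    y <- 100 * (1 - exp(-k_true * tg)) + rnorm(length(tg), sd = 5)
    fit_monoexponential_rise(tg, y)$k_obs
  }, numeric(1)))
  expect_equal(mean(ks), k_true, tolerance = 0.02)
})

test_that("FCS amplitude converts to concentration as a pure unit change", {
  # g0 = 0.1, V = 0.5 fl -> 10 molecules -> 3.32e-8 M
  expect_equal(concentration_from_fcs(0.1, 0.5e-15), 3.3211e-8,
    tolerance = 1e-4
  )
  expect_equal(concentration_from_fcs(0.01, 0.5e-15), 3.3211e-7,
    tolerance = 1e-4
  )
  # single molecule, and exact halving when the volume doubles
  expect_equal(
    concentration_from_fcs(1, 0.5e-15) / concentration_from_fcs(1, 1e-15),
    2,
    tolerance = 1e-12
  )
  expect_error(concentration_from_fcs(0), "positive")
})

test_that("k_obs versus concentration regression recovers k_a and k_off", {
  # exact collinear points -> exact slope and intercept
  cM <- c(1e-9, 1e-8, 6e-7)
  rec <- tibble::tibble(c_M = cM, k_obs = 9.2e4 * cM + 1e-3)
  f <- fit_association_constant(rec)
  expect_equal(f$k_a, 9.2e4, tolerance = 1e-9)
  expect_equal(f$k_off, 1e-3, tolerance = 1e-9)
  # 30 synthetic cells over 1-600 nM with 10% noise: truth within 2 s.e.
  cells <- withr::with_seed(83, {
    c30 <- 10^runif(30, log10(1e-9), log10(6e-7))
    k30 <- (9.2e4 * c30 + 1e-3) * (1 + rnorm(30, sd = 0.1))
    tibble::tibble(c_M = c30, k_obs = k30)
  })
  f30 <- fit_association_constant(cells)
  expect_lt(abs(f30$k_a - 9.2e4), 2 * f30$k_a_se)
  expect_lt(abs(f30$k_off - 1e-3), 2 * f30$k_off_se)
  # degenerate design
  expect_error(
    fit_association_constant(
      tibble::tibble(c_M = rep(1e-8, 5), k_obs = 1:5)
    ),
    "factor 5"
  )
  expect_error(fit_association_constant(rec[1:2, ]), "3 cells")
})

test_that("regression coverage: truth inside 2 s.e. in >= 93% of repeats", {
  # enough repetitions that sampling error is small against the 93% bound
  hits <- withr::with_seed(84, vapply(1:1500, function(i) {
    c30 <- 10^runif(30, log10(1e-9), log10(6e-7))
    k30 <- (9.2e4 * c30 + 1e-3) * (1 + rnorm(30, sd = 0.1))
    f <- fit_association_constant(tibble::tibble(c_M = c30, k_obs = k30))
    abs(f$k_a - 9.2e4) < 2 * f$k_a_se
  }, logical(1)))
  expect_gte(mean(hits), 0.93)
})

test_that("per-cell pipeline: simulate, fit k_obs, regress", {
  cells <- withr::with_seed(85, {
    cM <- 10^runif(12, log10(5e-9), log10(6e-7))
    purrr::imap(cM, function(cc, i) {
      simulate_locus_timecourse(9.2e4, 1e-3, cc,
        a_plateau = 1000,
        noise_sd = 20, t_grid = seq(0, 900, 5),
        cell_id = sprintf("cell_%02d", i)
      )
    }) |> purrr::list_rbind()
  })
  kobs <- fit_kobs(cells)
  expect_equal(nrow(kobs), 12)
  f <- fit_association_constant(kobs)
  expect_equal(f$k_a, 9.2e4, tolerance = 0.15)
  expect_equal(glance(f)$n_cells, 12)
})

test_that("occupancy ratio and insert-versus-site scaling", {
  expect_equal(occupancy_ratio(5450, 60), 90.8, tolerance = 1e-3)
  expect_equal(occupancy_ratio(3, 3), 1)
  rep <- site_scaling_report(
    ratio_ka = 9.2 / 2.2, ratio_sites = 19200 / 210,
    ratio_inserts = 200 / 30
  )
  expect_equal(rep$classification, "inserts")
  expect_lt(rep$log_dist_inserts, rep$log_dist_sites)
})
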