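test_that("survival probability equals counting on small duration sets", {
  sp <- survival_probability(c(1, 2, 3))
  expect_equal(sp$times_s, c(1, 2, 3))
  expect_equal(sp$sp, c(2 / 3, 1 / 3, 0))
  sp1 <- survival_probability(5)
  expect_equal(sp1$sp, 0)
  # brute-force counting oracle on random multisets <= 100 entries
  for (seed in 1:3) {
    d <- withr::with_seed(seed, round(rexp(80, 1), 2) + 0.01)
    sp <- survival_probability(d)
    expect_equal(sp$sp, sp_bruteforce(d, sp$times_s), tolerance = 1e-12)
  }
  # all-censored input errors
  ev <- tibble::tibble(duration_s = c(1, 2), censored = TRUE, protocol = "x")
  expect_error(survival_probability(ev), "uncensored")
})

test_that("empirical SP converges to the true survival (Glivenko-Cantelli)", {
  d <- withr::with_seed(71, rexp(1e4, 1))
  sp <- survival_probability(d)
  expect_lt(max(abs(sp$sp - exp(-sp$times_s))), 0.02)
})

test_that("anchor renormalization scales time-lapse curves correctly", {
  # time-lapse curve already equal to continuous at anchor -> scale 1
  tt <- c(0.1, 0.5, 1, 2, 5)
  cont <- tibble::tibble(
    times_s = tt, sp = exp(-tt), protocol = "continuous", scale = 1
  )
  tl <- tibble::tibble(
    times_s = tt, sp = exp(-tt), protocol = "tl_1", scale = 1
  )
  m <- merge_survival_curves(cont, tl, anchor_s = 1)
  expect_equal(
    m$sp, exp(-m$times_s),
    tolerance = 1e-9
  )
  # forced arithmetic: SP_cont(1) = 0.05, SP_tl(1) = 0.5 -> scale 0.1
  cont2 <- tibble::tibble(
    times_s = c(0.1, 1), sp = c(0.9, 0.05), protocol = "continuous",
    scale = 1
  )
  tl2 <- tibble::tibble(
    times_s = c(1, 10, 50), sp = c(0.5, 0.2, 0.1), protocol = "tl_1",
    scale = 1
  )
  m2 <- merge_survival_curves(cont2, tl2, anchor_s = 1)
  above <- m2[m2$times_s > 1, ]
  expect_equal(above$sp, c(0.02, 0.01), tolerance = 1e-12)
  expect_equal(above$scale, c(0.1, 0.1), tolerance = 1e-12)
  # zero at anchor cannot be renormalized
  tl_bad <- tibble::tibble(
    times_s = c(1, 2), sp = c(0, 0), protocol = "tl_0.5", scale = 1
  )
  expect_error(
    merge_survival_curves(cont2, tl_bad, anchor_s = 1), "tl_0.5"
  )
})

test_that("merged survival tracks the generative dwell spectrum", {
  # the dwell mixture observed through all four imaging protocols, with
  # observation windows long enough to cover the 0.1-100 s band
  mix <- dwell_mixture(
    list(dwell_exponential(6.36), dwell_power_law(0.1, 100, -0.7)),
    c(0.95, 0.05)
  )
  kin <- kinetics_config(dwell = mix)
  pr_c <- imaging_protocol(bleach_rate_continuous = 0)
  tt <- simulate_tracks(kin, pr_c, n_tracks = 1000, duration_s = 30, seed = 502)
  ev_c <- detect_binding_events(tt, interval_s = pr_c$interval_s)
  sp_c <- survival_probability(ev_c, spans = track_spans(tt))
  sp_tl <- purrr::map(
    list(c(0.1, 120, 350), c(0.5, 300, 250), c(1.0, 600, 250)),
    function(conf) {
      pr <- protocol_timelapse(conf[1], bleach_rate_continuous = 0)
      ttl <- simulate_tracks(kin, pr,
        n_tracks = conf[3], duration_s = conf[2],
        seed = 500 + round(conf[1] * 10)
      )
      ev <- detect_immobile_timelapse(ttl, interval_s = conf[1])
      suppressWarnings(survival_probability(ev, spans = track_spans(ttl)))
    }
  )
  merged <- suppressWarnings(merge_survival_curves(
    sp_c, sp_tl,
    anchor_s = 1, short_time_rate = 6.36
  ))
  keep <- merged$times_s >= 0.1 & merged$times_s <= 100 & merged$sp > 0
  ratio <- merged$sp[keep] / dwell_survival(mix, merged$times_s[keep])
  # within a factor 1.5 of the generative survival across the band
  expect_gt(mean(ratio > 1 / 1.5 & ratio < 1.5), 0.9)
  expect_true(all(ratio > 0.5 & ratio < 2)) # no gross excursions
  med <- tapply(
    ratio,
    cut(merged$times_s[keep], c(0.1, 0.3, 1, 3, 10, 30, 100)),
    stats::median
  )
  expect_true(all(med > 1 / 1.5 & med < 1.5))
  # renormalization preserves ordering/monotonicity up to sampling noise:
  # the isotonic projection changes the merged curve only marginally
  iso <- -stats::isoreg(merged$times_s, -merged$sp)$yf
  expect_lt(max(abs(iso - merged$sp) / pmax(merged$sp, 1e-12)), 0.5)
})

test_that("power-law fitting inverts exact curves and flags exponentials", {
  tt <- 10^seq(-1, 2, length.out = 30)
  sp_pl <- tibble::tibble(times_s = tt, sp = tt^(-0.7))
  expect_equal(fit_powerlaw(sp_pl)$gamma, -0.7, tolerance = 1e-9)
  # constant SP -> exponent 0
  sp_c <- tibble::tibble(times_s = tt, sp = 0.5)
  expect_equal(fit_powerlaw(sp_c)$gamma, 0, tolerance = 1e-9)
  # exponential decay is steeper than any observed power law on (0.1, 1)
  tt2 <- seq(0.1, 1, 0.05)
  sp_e <- tibble::tibble(times_s = tt2, sp = exp(-6.36 * tt2))
  expect_lt(fit_powerlaw(sp_e, range_s = c(0.1, 1))$gamma, -1)
  expect_error(fit_powerlaw(sp_pl[1:3, ]), "at least")
})

test_that("integrating the survival probability returns the mean dwell", {
  # exponential mean: SP = exp(-t/2) densely sampled to 30 s -> ~2
  tt <- seq(0.01, 30, 0.01)
  sp <- tibble::tibble(times_s = tt, sp = exp(-tt / 2))
  expect_equal(mean_binding_time(sp, tail_policy = "truncate"), 2,
    tolerance = 0.01
  )
  # hand trapezoid: {(0,1),(1,0.5),(2,0)} -> 1.0
  sp2 <- tibble::tibble(times_s = c(0, 1, 2), sp = c(1, 0.5, 0))
  expect_equal(mean_binding_time(sp2, tail_policy = "truncate"), 1,
    tolerance = 1e-12
  )
  # generative mixture SP integrates to the analytic mixture mean
  mix <- dwell_mixture(
    list(dwell_exponential(6.36), dwell_power_law(0.1, 100, -0.7)),
    c(0.95, 0.05)
  )
  tg <- 10^seq(-3, 2, length.out = 400)
  spm <- tibble::tibble(times_s = tg, sp = dwell_survival(mix, tg))
  expect_equal(
    mean_binding_time(spm, tail_policy = "power_law", t_stop = 100),
    dwell_mean(mix),
    tolerance = 0.15
  )
  # non-monotone input is isotonically projected with a warning
  sp3 <- tibble::tibble(times_s = 1:4, sp = c(0.9, 0.5, 0.6, 0.1))
  expect_warning(v <- mean_binding_time(sp3, tail_policy = "truncate"),
    "monotone"
  )
  expect_true(is.finite(v))
})

test_that("bound/free partition identities hold", {
  p <- partition_times(2, 0.75)
  expect_equal(p$tau_3d, 6)
  expect_equal(p$visit_rate, 0.125)
  expect_equal(p$visit_rate * (p$tau_1d + p$tau_3d), 1, tolerance = 1e-12)
  expect_equal(partition_times(1, 0.5)$tau_3d, 1)
  expect_equal(partition_times(1, 0.9)$tau_3d, 9, tolerance = 1e-12)
  expect_error(partition_times(1, 1), "strictly")
})
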