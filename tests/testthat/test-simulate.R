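test_that("no motion and no noise gives identical positions", {
  kin <- kinetics_config(
    diffusion_states = tibble::tibble(d = 0, weight = 1),
    d_bound = 0, mean_unbound_s = 6
  )
  pr <- imaging_protocol(loc_sigma_um = 0, bleach_rate_continuous = 0)
  tr <- simulate_trajectory(kin, pr, duration_s = 0.5, seed = 1)
  expect_true(all(tr$x_um == tr$x_um[1]))
  expect_true(all(tr$y_um == tr$y_um[1]))
  expect_identical(tr$frame, seq_len(nrow(tr)) - 1L)
})

test_that("a single free state reproduces the Brownian MSD slope", {
  kin <- kinetics_config(
    diffusion_states = tibble::tibble(d = 8, weight = 1),
    mean_unbound_s = 1e9
  )
  pr <- imaging_protocol(loc_sigma_um = 0, bleach_rate_continuous = 0)
  tr <- simulate_tracks(kin, pr, n_tracks = 500, duration_s = 0.15, seed = 4)
  msd <- compute_msd(tr, max_lag = 5)
  ens <- dplyr::summarise(dplyr::group_by(msd, lag),
    msd_um2 = mean(msd_um2), .groups = "drop"
  )
  use <- ens$lag %in% 2:5
  slope <- coef(lm(ens$msd_um2[use] ~ I(ens$lag[use] / 197)))[[2]]
  expect_equal(slope / 4, 8, tolerance = 0.03)
})

test_that("two-state switching yields the stationary mobile fraction", {
  # tau_3D = 6 s, exponential dwell mean 2 s => mobile fraction 75%
  kin <- kinetics_config(
    mean_unbound_s = 6, dwell = dwell_exponential(0.5)
  )
  pr <- imaging_protocol(
    interval_s = 0.1, loc_sigma_um = 0,
    bleach_rate_continuous = 0
  )
  tr <- simulate_tracks(kin, pr, n_tracks = 150, duration_s = 60, seed = 11)
  expect_equal(100 * mean(!tr$bound_truth), 75, tolerance = 2 / 75)
})

test_that("trajectories are reproducible under a fixed seed", {
  kin <- kinetics_config()
  pr <- protocol_continuous()
  expect_identical(
    simulate_trajectory(kin, pr, 1, seed = 5),
    simulate_trajectory(kin, pr, 1, seed = 5)
  )
})

test_that("continuous-imaging bleaching gives the expected track duration", {
  # 0.34 1/s decay => mean observed duration ~ 1/0.34 = 2.9 s
  kin <- kinetics_config(
    diffusion_states = tibble::tibble(d = 1, weight = 1),
    mean_unbound_s = 1e9
  )
  pr <- protocol_continuous() # bleach 0.34 1/s
  tr <- simulate_tracks(kin, pr, n_tracks = 400, duration_s = 60, seed = 6)
  dur <- dplyr::summarise(dplyr::group_by(tr, track_id),
    d = max(t_s), .groups = "drop"
  )$d
  expect_equal(mean(dur), 1 / 0.34, tolerance = 0.12)
})

test_that("frames to bleach are protocol independent (geometric in frames)", {
  kin <- kinetics_config(
    diffusion_states = tibble::tibble(d = 1, weight = 1),
    mean_unbound_s = 1e9
  )
  mean_frames <- vapply(c(1 / 197, 0.1, 1), function(iv) {
    pr <- imaging_protocol(interval_s = iv)
    tr <- simulate_tracks(kin, pr,
      n_tracks = 300,
      duration_s = 1e4 * iv, seed = round(1e4 * iv)
    )
    mean(dplyr::summarise(dplyr::group_by(tr, track_id),
      n = dplyr::n(), .groups = "drop"
    )$n)
  }, numeric(1))
  # same per-frame Bernoulli parameter: E[frames] = 1/p ~ 580 for all
  p_b <- bleach_frame_prob(protocol_continuous())
  expect_equal(mean_frames, rep(1 / p_b, 3), tolerance = 0.1)
})

test_that("apply_imaging_protocol subsamples a dense path deterministically", {
  dense <- tibble::tibble(
    t_s = seq(0, 1, 1e-4),
    x_um = seq(0, 1, 1e-4) * 2, # x = 2 t
    y_um = 0
  )
  pr <- imaging_protocol(
    interval_s = 0.05, exposure_s = 0.005,
    loc_sigma_um = 0, bleach_rate_continuous = 0
  )
  obs <- apply_imaging_protocol(dense, pr)
  expect_equal(obs$x_um, obs$t_s * 2, tolerance = 1e-9)
  expect_equal(nrow(obs), 21)
  # shorter than one frame -> empty
  short <- dense[dense$t_s < 0.04, ]
  expect_equal(nrow(apply_imaging_protocol(short, pr)), 0)
})

test_that("locus time course follows I(t) = A(1 - exp(-k_obs t))", {
  tg <- seq(0, 600, 5)
  # c = 0: relaxation rate is exactly k_off
  tc0 <- simulate_locus_timecourse(9.2e4, 1e-3, 0,
    a_plateau = 100,
    t_grid = tg, seed = 1
  )
  expect_equal(tc0$intensity, 100 * (1 - exp(-1e-3 * tg)), tolerance = 1e-12)
  # k_a c + k_off at c = 100 nM: 9.2e4 * 1e-7 + 1e-3 = 0.0102 1/s
  tc <- simulate_locus_timecourse(9.2e4, 1e-3, 100e-9,
    a_plateau = 100,
    t_grid = tg, seed = 1
  )
  expect_equal(tc$intensity, 100 * (1 - exp(-0.0102 * tg)), tolerance = 1e-12)
  # noiseless fit recovers the curve pointwise
  fit <- fit_monoexponential_rise(tc)
  expect_equal(fit$fitted, tc$intensity, tolerance = 1e-6)
  expect_error(
    simulate_locus_timecourse(1, 1, 1, a_plateau = -5, t_grid = tg),
    "nonnegative"
  )
})
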