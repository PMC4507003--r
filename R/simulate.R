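# Two-state diffusion/binding trajectory simulator --------------------------

#' Kinetic configuration of the two-state search model
#'
#' Proteins alternate between a mobile phase (3D diffusion projected on the
#' imaging plane) and a DNA-bound phase. Unbound durations are exponential
#' with mean `mean_unbound_s`; bound durations follow a
#' [dwell model][dwell_models]. During a mobile phase the diffusion
#' coefficient is drawn once from a finite mixture, which generates the
#' multi-population structure of the instantaneous diffusion-coefficient
#' histogram; bound phases move with `d_bound`, emulating slow chromatin
#' motion.
#'
#' Defaults reproduce the measured TetR kinetics: mobile mixture
#' D = 8 and 1 um^2/s with weights 33:43 (the fast and intermediate
#' populations), mean unbound time 6 s and exponential bound dwell with rate
#' 6.36 1/s (mean residence about 157 ms on random sequences). The bound
#' state is essentially immobile (`d_bound = 2e-4` um^2/s, rms motion about
#' 30 nm over 1 s): this is the regime in which stably bound molecules stay
#' within one pixel between time-lapse frames, as the immobility criterion
#' of the time-lapse analysis requires; the apparent mobility of the
#' quasi-immobile population in instantaneous diffusion-coefficient
#' histograms is then dominated by localization error and short-trajectory
#' statistics rather than by `d_bound` itself.
#'
#' @param diffusion_states A data frame with columns `d` (um^2/s) and
#'   `weight` for the mobile-phase mixture; weights must be nonnegative and
#'   sum to 1.
#' @param d_bound Diffusion coefficient while bound (um^2/s, >= 0).
#' @param mean_unbound_s Mean duration of mobile phases (s, > 0).
#' @param dwell A [dwell model][dwell_models] for bound-phase durations.
#' @return An object of class `kinetics_config`.
#' @export
#' @examples
#' kinetics_config()
kinetics_config <- function(diffusion_states = tibble::tibble(
                              d = c(8, 1),
                              weight = c(33, 43) / 76
                            ),
                            d_bound = 2e-4,
                            mean_unbound_s = 6,
                            dwell = dwell_exponential(6.36)) {
  diffusion_states <- tibble::as_tibble(diffusion_states)
  stopifnot(
    all(c("d", "weight") %in% names(diffusion_states)),
    all(diffusion_states$d >= 0), all(diffusion_states$weight >= 0),
    abs(sum(diffusion_states$weight) - 1) < 1e-9,
    is.numeric(d_bound), d_bound >= 0,
    is.numeric(mean_unbound_s), mean_unbound_s > 0,
    inherits(dwell, "dwell_model")
  )
  structure(
    list(
      diffusion_states = diffusion_states,
      d_bound = d_bound,
      mean_unbound_s = mean_unbound_s,
      dwell = dwell
    ),
    class = "kinetics_config"
  )
}

#' @export
print.kinetics_config <- function(x, ...) {
  cat(sprintf(
    "<kinetics_config> %d mobile states, D_bound %.3g um^2/s, tau_3D %.3g s, dwell '%s'\n",
    nrow(x$diffusion_states), x$d_bound, x$mean_unbound_s, x$dwell$type
  ))
  invisible(x)
}

# Alternating mobile/bound phases covering [0, duration_s].
# Returns a tibble(state, t_start, t_end, d) where d is the phase diffusion
# coefficient. The initial state is drawn from the stationary occupancy
# tau_3D : tau_1D when the dwell mean is finite, otherwise mobile.
simulate_phases <- function(kin, duration_s) {
  tau_b <- dwell_mean(kin$dwell)
  p_bound0 <- if (is.finite(tau_b)) {
    tau_b / (tau_b + kin$mean_unbound_s)
  } else {
    0
  }
  state <- if (stats::runif(1) < p_bound0) "bound" else "mobile"
  states <- character(0)
  durs <- numeric(0)
  total <- 0
  # draw in blocks to limit R-level looping
  while (total < duration_s) {
    n_blk <- max(8L, ceiling((duration_s - total) /
      (kin$mean_unbound_s + min(tau_b, kin$mean_unbound_s)) * 2))
    mob <- stats::rexp(n_blk, rate = 1 / kin$mean_unbound_s)
    bnd <- sample_bound_dwell(kin$dwell, n_blk)
    blk <- if (state == "mobile") {
      as.vector(rbind(mob, bnd))
    } else {
      as.vector(rbind(bnd, mob))
    }
    states <- c(states, rep(
      if (state == "mobile") c("mobile", "bound") else c("bound", "mobile"),
      n_blk
    ))
    durs <- c(durs, blk)
    total <- total + sum(blk)
    state <- states[length(states)]
    state <- if (state == "mobile") "bound" else "mobile" # next block start
  }
  t_end <- cumsum(durs)
  keep <- seq_len(which(t_end >= duration_s)[1])
  t_end <- pmin(t_end[keep], duration_s)
  t_start <- c(0, t_end[-length(t_end)])
  st <- states[keep]
  d <- ifelse(st == "bound", kin$d_bound, NA_real_)
  n_mobile <- sum(st == "mobile")
  if (n_mobile > 0) {
    pick <- sample.int(nrow(kin$diffusion_states), n_mobile,
      replace = TRUE, prob = kin$diffusion_states$weight
    )
    d[st == "mobile"] <- kin$diffusion_states$d[pick]
  }
  tibble::tibble(state = st, t_start = t_start, t_end = t_end, d = d)
}

#' Simulate an observed single-molecule trajectory
#'
#' Generates a two-state (diffusing/bound) trajectory and observes it through
#' an imaging protocol: positions are recorded at frame times with Gaussian
#' localization noise, and the track is truncated by photobleaching (a
#' per-frame Bernoulli trial whose probability is set by the
#' continuous-imaging bleach rate; see [bleach_frame_prob()]). Within each
#' frame interval displacements are exact Brownian increments with per-axis
#' variance `2 * integral of D(t) dt`, where `D(t)` is piecewise constant over
#' phases; mobile-phase D is drawn once per phase from the configured mixture.
#' Motion is simulated in the 2D imaging plane.
#'
#' @param kin A [kinetics_config()].
#' @param protocol An [imaging_protocol()].
#' @param duration_s Wall-clock duration to simulate (s, > 0); the observed
#'   track may end earlier if the fluorophore bleaches.
#' @param seed Optional integer seed for reproducibility.
#' @param track_id Identifier stored in the output (default 1).
#' @return A tibble with columns `track_id`, `frame` (0-based), `t_s`,
#'   `x_um`, `y_um` and the simulation truth label `bound_truth` (logical,
#'   state at the frame time).
#' @export
#' @examples
#' tr <- simulate_trajectory(kinetics_config(), protocol_continuous(),
#'   duration_s = 1, seed = 7
#' )
#' head(tr)
simulate_trajectory <- function(kin, protocol, duration_s, seed = NULL,
                                track_id = 1L) {
  stopifnot(
    inherits(kin, "kinetics_config"),
    inherits(protocol, "imaging_protocol"),
    duration_s > 0
  )
  run <- function() {
    dt <- protocol$interval_s
    n_frames <- floor(duration_s / dt) + 1L
    p_b <- bleach_frame_prob(protocol)
    if (p_b > 0) {
      n_frames <- min(n_frames, stats::rgeom(1L, p_b) + 1L)
    }
    t_frames <- (seq_len(n_frames) - 1L) * dt
    phases <- simulate_phases(kin, max(t_frames) + dt)
    # cumulative integral of D over time at phase knots
    cum_d <- c(0, cumsum(phases$d * (phases$t_end - phases$t_start)))
    knots <- c(phases$t_start[1], phases$t_end)
    cd <- stats::approx(knots, cum_d, xout = t_frames, rule = 2)$y
    var_step <- 2 * diff(cd)
    step_sd <- sqrt(pmax(var_step, 0))
    x <- cumsum(c(0, stats::rnorm(n_frames - 1L, sd = step_sd)))
    y <- cumsum(c(0, stats::rnorm(n_frames - 1L, sd = step_sd)))
    if (protocol$loc_sigma_um > 0) {
      x <- x + stats::rnorm(n_frames, sd = protocol$loc_sigma_um)
      y <- y + stats::rnorm(n_frames, sd = protocol$loc_sigma_um)
    }
    idx <- findInterval(t_frames, phases$t_start)
    tibble::tibble(
      track_id = track_id,
      frame = seq_len(n_frames) - 1L,
      t_s = t_frames,
      x_um = x,
      y_um = y,
      bound_truth = phases$state[idx] == "bound"
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate an ensemble of trajectories
#'
#' Convenience wrapper around [simulate_trajectory()] drawing `n_tracks`
#' independent tracks under one seed.
#'
#' @inheritParams simulate_trajectory
#' @param n_tracks Number of tracks.
#' @return A tibble of stacked trajectories with distinct `track_id`.
#' @export
simulate_tracks <- function(kin, protocol, n_tracks, duration_s,
                            seed = NULL) {
  run <- function() {
    purrr::map(seq_len(n_tracks), function(i) {
      simulate_trajectory(kin, protocol, duration_s, track_id = i)
    }) |> purrr::list_rbind()
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Observe a dense true path through an imaging protocol
#'
#' Subsamples a densely simulated path at the protocol frame times (linear
#' interpolation between dense samples), adds localization noise, and
#' truncates the track at photobleaching. The per-frame bleaching probability
#' is identical across protocols because bleaching occurs during exposures
#' only (see [bleach_frame_prob()]).
#'
#' @param path A data frame with columns `t_s`, `x_um`, `y_um` and optionally
#'   `bound_truth`, sampled at least 10 times finer than the protocol
#'   interval.
#' @param protocol An [imaging_protocol()].
#' @param seed Optional integer seed.
#' @param track_id Identifier stored in the output.
#' @return A trajectory tibble as in [simulate_trajectory()]; empty (zero
#'   rows) if the path is shorter than one frame interval.
#' @export
apply_imaging_protocol <- function(path, protocol, seed = NULL,
                                   track_id = 1L) {
  stopifnot(
    is.data.frame(path),
    all(c("t_s", "x_um", "y_um") %in% names(path)),
    inherits(protocol, "imaging_protocol")
  )
  empty <- tibble::tibble(
    track_id = integer(0), frame = integer(0), t_s = numeric(0),
    x_um = numeric(0), y_um = numeric(0), bound_truth = logical(0)
  )
  if (nrow(path) < 2L || max(path$t_s) < protocol$interval_s) {
    return(empty)
  }
  dense_dt <- stats::median(diff(path$t_s))
  if (dense_dt > protocol$interval_s / 10) {
    stop("dense path must be sampled at least 10x finer than the protocol interval.",
      call. = FALSE
    )
  }
  run <- function() {
    dt <- protocol$interval_s
    n_frames <- floor(max(path$t_s) / dt) + 1L
    p_b <- bleach_frame_prob(protocol)
    if (p_b > 0) {
      n_frames <- min(n_frames, stats::rgeom(1L, p_b) + 1L)
    }
    t_frames <- (seq_len(n_frames) - 1L) * dt
    x <- stats::approx(path$t_s, path$x_um, xout = t_frames)$y
    y <- stats::approx(path$t_s, path$y_um, xout = t_frames)$y
    if (protocol$loc_sigma_um > 0) {
      x <- x + stats::rnorm(n_frames, sd = protocol$loc_sigma_um)
      y <- y + stats::rnorm(n_frames, sd = protocol$loc_sigma_um)
    }
    bt <- if ("bound_truth" %in% names(path)) {
      path$bound_truth[pmax(findInterval(t_frames, path$t_s), 1L)]
    } else {
      NA
    }
    tibble::tibble(
      track_id = track_id,
      frame = seq_len(n_frames) - 1L,
      t_s = t_frames, x_um = x, y_um = y, bound_truth = bt
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a locus-filling intensity time course for one cell
#'
#' The fluorescence intensity at a multi-site target locus after switching
#' binding on relaxes as `I(t) = A * (1 - exp(-(k_a * c + k_off) * t))`, a
#' single exponential with observed rate `k_obs = k_a * c + k_off`.
#'
#' @param k_a Association rate constant (1/M/s).
#' @param k_off Dissociation rate (1/s).
#' @param c_M Nuclear protein concentration (M, >= 0).
#' @param a_plateau Intensity plateau (arbitrary units, > 0).
#' @param noise_sd Gaussian noise s.d. added to each point (>= 0).
#' @param t_grid Increasing vector of measurement times (s).
#' @param seed Optional integer seed.
#' @param cell_id Identifier stored in the output.
#' @return A tibble with columns `cell_id`, `c_M`, `t_s`, `intensity`.
#' @export
#' @examples
#' simulate_locus_timecourse(9.2e4, 1e-3, 100e-9,
#'   t_grid = seq(0, 300, 10), seed = 1
#' )
simulate_locus_timecourse <- function(k_a, k_off, c_M, a_plateau = 1000,
                                      noise_sd = 0, t_grid, seed = NULL,
                                      cell_id = "cell_1") {
  stopifnot(
    k_a >= 0, k_off >= 0, c_M >= 0,
    all(diff(t_grid) > 0)
  )
  if (a_plateau < 0 || noise_sd < 0) {
    stop("plateau and noise must be nonnegative.", call. = FALSE)
  }
  run <- function() {
    k_obs <- k_a * c_M + k_off
    intensity <- a_plateau * (1 - exp(-k_obs * t_grid))
    if (noise_sd > 0) {
      intensity <- intensity + stats::rnorm(length(t_grid), sd = noise_sd)
    }
    tibble::tibble(
      cell_id = cell_id, c_M = c_M, t_s = as.numeric(t_grid),
      intensity = intensity
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
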