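# Survival probability of bound-event durations ------------------------------

#' Empirical survival probability of binding-event durations
#'
#' `SP(tau)` is the probability of staying bound longer than `tau`
#' (complementary cumulative distribution), evaluated at the sorted unique
#' observed durations with `SP(0) = 1` implicit. Censored events (truncated
#' by photobleaching or the trajectory ends) are dropped by default.
#'
#' Dropping censored events biases the raw distribution towards short
#' durations, because an event of duration `d` is observed complete only if
#' it fits inside a track's observed span (photobleaching and the finite
#' movie length both truncate tracks). Given the realized spans `T_i`, the
#' number of observable complete events of duration `d` is proportional to
#' `sum_i max(T_i - d, 0)`, so supplying the per-track spans (`spans`)
#' weights every event by the inverse of that availability and removes the
#' bias exactly, including the photobleaching contribution (track ends by
#' bleaching are part of the realized spans).
#'
#' @param events Event tibble with `duration_s` and optionally `censored`,
#'   or a numeric vector of durations.
#' @param spans Optional numeric vector of per-track observed spans (s) of
#'   the dataset the events came from (see [track_spans()]); enables the
#'   finite-observation correction described above.
#' @param protocol_label Label stored in the output (default taken from the
#'   events' `protocol` column, else `"events"`).
#' @param censor_policy `"drop"` (default) or `"include"`.
#' @return A tibble with columns `times_s`, `sp`, `protocol`, `scale`
#'   (renormalization factor, 1 here), non-increasing in `times_s`.
#' @export
#' @examples
#' survival_probability(c(1, 2, 3))
survival_probability <- function(events, spans = NULL,
                                 protocol_label = NULL,
                                 censor_policy = c("drop", "include")) {
  censor_policy <- match.arg(censor_policy)
  if (is.data.frame(events)) {
    if (is.null(protocol_label) && "protocol" %in% names(events) &&
      nrow(events) > 0) {
      protocol_label <- events$protocol[1]
    }
    if ("censored" %in% names(events) && censor_policy == "drop") {
      events <- events[!events$censored, , drop = FALSE]
    }
    d <- events$duration_s
  } else {
    d <- as.numeric(events)
  }
  if (is.null(protocol_label)) protocol_label <- "events"
  if (length(d) < 1L) {
    stop("no uncensored events: cannot build a survival probability.",
      call. = FALSE
    )
  }
  w <- rep(1, length(d))
  if (!is.null(spans)) {
    avail <- vapply(d, function(di) sum(pmax(spans - di, 0)), numeric(1))
    ok <- avail > 0
    if (!all(ok)) {
      rlang::warn(sprintf(
        "%d events as long as the longest track span dropped (no availability).",
        sum(!ok)
      ))
      d <- d[ok]
      avail <- avail[ok]
    }
    w <- 1 / avail
  }
  times <- sort(unique(d))
  sp <- vapply(times, function(tt) sum(w[d > tt]), numeric(1)) / sum(w)
  tibble::tibble(
    times_s = times, sp = sp, protocol = protocol_label, scale = 1
  )
}

#' Observed span of every trajectory
#'
#' @param traj A trajectory tibble.
#' @return A numeric vector of per-track observed time spans (s).
#' @export
track_spans <- function(traj) {
  stopifnot(is.data.frame(traj), all(c("track_id", "t_s") %in% names(traj)))
  dplyr::summarise(dplyr::group_by(traj, .data$track_id),
    span = max(.data$t_s) - min(.data$t_s), .groups = "drop"
  )$span
}

# log-log interpolation of a survival curve at time t0 (NA outside support)
sp_at <- function(times, sp, t0) {
  if (t0 < min(times) || t0 > max(times)) {
    return(NA_real_)
  }
  pos <- sp > 0
  if (sum(pos) < 2) {
    return(NA_real_)
  }
  10^stats::approx(log10(times[pos]), log10(sp[pos]), xout = log10(t0))$y
}

#' Merge continuous and time-lapse survival curves into the full SP
#'
#' Builds the full survival probability covering short and long binding
#' events. Each time-lapse curve is renormalized so that it agrees with the
#' already-merged curve at its anchor (interpolating both in log-time /
#' log-SP), then the merged curve takes the continuous points below the
#' anchor and the scaled time-lapse points above it; points at identical
#' times are averaged in log-SP.
#'
#' Arms are processed in order of their first covered time. An arm covering
#' `anchor_s` is anchored there against the continuous curve; an arm whose
#' first point lies above `anchor_s` (its interval is too coarse to measure
#' shorter dwells) is anchored at its first covered time against the curve
#' merged so far, which by then includes the finer time-lapse arms. With
#' every arm covering the anchor this reduces to renormalizing each
#' time-lapse curve against continuous imaging at the single anchor.
#'
#' Continuous-imaging event detection cannot see events shorter than its
#' detection floor, so the empirical continuous SP is conditional on
#' exceeding that floor. When `short_time_rate` (the bleach-corrected
#' short-time dissociation rate, e.g. from [fit_event_rate()] +
#' [correct_bleaching()]) is supplied, the continuous curve is rescaled by
#' `exp(-short_time_rate * floor)` so that it estimates the unconditional SP;
#' the anchor scaling then propagates this to the time-lapse curves.
#'
#' @param continuous Survival tibble from continuous imaging.
#' @param timelapse A survival tibble (possibly several protocols stacked,
#'   distinguished by `protocol`) or a list of them.
#' @param anchor_s Anchor time (s, default 1).
#' @param short_time_rate Optional short-time dissociation rate (1/s) for
#'   the detection-floor renormalization described above.
#' @return A merged survival tibble (`times_s`, `sp`, `protocol`, `scale`),
#'   where `protocol` records the curve each point came from and `scale` the
#'   factor applied to it.
#' @export
merge_survival_curves <- function(continuous, timelapse, anchor_s = 1.0,
                                  short_time_rate = NULL) {
  stopifnot(is.data.frame(continuous))
  if (is.data.frame(timelapse)) timelapse <- list(timelapse)
  tl <- purrr::list_rbind(purrr::map(timelapse, tibble::as_tibble)) |>
    dplyr::group_split(.data$protocol)
  cont <- dplyr::arrange(tibble::as_tibble(continuous), .data$times_s)
  cont_scale <- 1
  if (!is.null(short_time_rate)) {
    floor_s <- min(cont$times_s)
    cont_scale <- exp(-short_time_rate * floor_s)
    cont$sp <- cont$sp * cont_scale
    cont$scale <- cont_scale
  }
  sp_cont_anchor <- sp_at(cont$times_s, cont$sp, anchor_s)
  if (is.na(sp_cont_anchor) || sp_cont_anchor <= 0) {
    stop("continuous survival curve is not defined (or zero) at the anchor.",
      call. = FALSE
    )
  }
  consolidate <- function(x) {
    x |>
      dplyr::filter(.data$sp > 0) |>
      dplyr::group_by(.data$times_s) |>
      dplyr::summarise(
        sp = 10^mean(log10(.data$sp)),
        protocol = .data$protocol[1],
        scale = .data$scale[1],
        .groups = "drop"
      ) |>
      dplyr::arrange(.data$times_s)
  }
  # ladder anchoring: arms in order of first covered time, each scaled to
  # the curve merged so far at its own anchor
  for (g in tl) {
    if (!any(g$sp > 0)) {
      stop(sprintf(
        "cannot renormalize protocol '%s': survival is zero everywhere.",
        g$protocol[1]
      ), call. = FALSE)
    }
  }
  first_time <- vapply(
    tl, function(g) min(g$times_s[g$sp > 0]), numeric(1)
  )
  scaled <- list()
  for (g in tl[order(first_time)]) {
    g <- dplyr::arrange(g, .data$times_s)
    a_g <- max(anchor_s, min(g$times_s[g$sp > 0]))
    ref_curve <- consolidate(dplyr::bind_rows(cont, scaled))
    ref <- sp_at(ref_curve$times_s, ref_curve$sp, a_g)
    s_tl <- sp_at(g$times_s, g$sp, a_g)
    if (is.na(ref) || ref <= 0 || is.na(s_tl) || s_tl <= 0) {
      stop(sprintf(
        "cannot renormalize protocol '%s': survival undefined or zero at anchor %g s.",
        g$protocol[1], a_g
      ), call. = FALSE)
    }
    k <- ref / s_tl
    scaled[[length(scaled) + 1]] <-
      dplyr::mutate(g, sp = .data$sp * k, scale = k)
  }
  # final assembly: continuous below the anchor, time-lapse arms above
  consolidate(dplyr::bind_rows(
    dplyr::filter(cont, .data$times_s <= anchor_s),
    dplyr::filter(dplyr::bind_rows(scaled), .data$times_s > anchor_s)
  ))
}

#' Fit the power-law exponent of a survival curve
#'
#' Least-squares slope of `log10(SP)` versus `log10(t)` restricted to a time
#' range; a broadly distributed dwell-time spectrum shows up as an exponent
#' around -0.7, while a single off-rate gives a much steeper (super-power-law)
#' decay over any decade it spans.
#'
#' @param sp A survival tibble (`times_s`, `sp`).
#' @param range_s Two-element time range (s), default `c(0.1, 100)`.
#' @param min_points Minimum points required inside the range (default 5).
#' @return A one-row tibble: `gamma`, `se`, `n_points`.
#' @export
fit_powerlaw <- function(sp, range_s = c(0.1, 100), min_points = 5) {
  stopifnot(is.data.frame(sp), all(c("times_s", "sp") %in% names(sp)))
  use <- sp$times_s >= range_s[1] & sp$times_s <= range_s[2] & sp$sp > 0
  if (sum(use) < min_points) {
    stop(sprintf(
      "need at least %d positive survival points in [%g, %g] s (got %d).",
      min_points, range_s[1], range_s[2], sum(use)
    ), call. = FALSE)
  }
  fit <- stats::lm(log10(sp$sp[use]) ~ log10(sp$times_s[use]))
  est <- suppressWarnings(summary(fit))$coefficients # exact fits warn
  tibble::tibble(
    gamma = est[2, 1], se = est[2, 2], n_points = sum(use)
  )
}

#' Mean bound time from the integrated survival probability
#'
#' The mean dwell time equals the integral of the survival probability.
#' `SP(0) = 1` is prepended, the observed grid is integrated with the
#' trapezoidal rule, and the unobserved tail beyond the last point is
#' handled by `tail_policy`: `"power_law"` extends the curve as
#' `SP_last * (t / t_last)^gamma` up to `t_stop` (then zero), integrated in
#' closed form, with `gamma` fitted to the last decade of the curve when not
#' supplied; `"truncate"` stops at the last observed point. Non-monotone
#' input (merge noise) is projected onto the closest non-increasing curve
#' before integration, with a warning.
#'
#' @param sp A survival tibble (`times_s`, `sp`).
#' @param tail_policy `"power_law"` (default) or `"truncate"`.
#' @param t_stop Upper end of the power-law extension (s, default 100, the
#'   time scale where nonspecific dwell times meet the specific binding
#'   time).
#' @param gamma Optional power-law exponent for the tail; fitted from the
#'   curve's last decade when `NULL`.
#' @return The mean bound time `tau_1D` (s).
#' @export
#' @examples
#' tt <- seq(0.01, 30, 0.01)
#' mean_binding_time(
#'   tibble::tibble(times_s = tt, sp = exp(-tt / 2)),
#'   tail_policy = "truncate"
#' ) # ~2
mean_binding_time <- function(sp, tail_policy = c("power_law", "truncate"),
                              t_stop = 100, gamma = NULL) {
  tail_policy <- match.arg(tail_policy)
  stopifnot(is.data.frame(sp), all(c("times_s", "sp") %in% names(sp)))
  sp <- dplyr::arrange(tibble::as_tibble(sp), .data$times_s)
  s <- sp$sp
  if (any(diff(s) > 0)) {
    rlang::warn("survival curve is not monotone; applying isotonic decreasing projection.")
    s <- -stats::isoreg(sp$times_s, -s)$yf
  }
  tt <- sp$times_s
  if (tt[1] > 0) {
    tt <- c(0, tt)
    s <- c(1, s)
  }
  total <- pracma::trapz(tt, s)
  if (tail_policy == "power_law" && utils::tail(s, 1) > 0 &&
    utils::tail(tt, 1) < t_stop) {
    t_last <- utils::tail(tt, 1)
    s_last <- utils::tail(s, 1)
    if (is.null(gamma)) {
      gamma <- fit_powerlaw(
        tibble::tibble(times_s = tt, sp = s),
        range_s = c(t_last / 10, t_last), min_points = 3
      )$gamma
    }
    tail_int <- if (abs(1 + gamma) < 1e-12) {
      s_last * t_last * log(t_stop / t_last)
    } else {
      s_last * t_last * ((t_stop / t_last)^(1 + gamma) - 1) / (1 + gamma)
    }
    total <- total + tail_int
  }
  total
}

#' Partition the search cycle into bound and free times
#'
#' With a fraction `f_mobile` of molecules diffusing at steady state, the
#' mean free time is `tau_3D = tau_1D * f_mobile / (1 - f_mobile)` and
#' nonspecific sites are visited at rate `1 / (tau_1D + tau_3D)`.
#'
#' @param tau_1d Mean nonspecific bound time (s, > 0).
#' @param f_mobile Mobile fraction, strictly between 0 and 1.
#' @return A one-row tibble: `tau_1d`, `tau_3d`, `visit_rate`.
#' @export
#' @examples
#' partition_times(2, 0.75) # tau_3d = 6 s, visit_rate = 0.125 /s
partition_times <- function(tau_1d, f_mobile) {
  stopifnot(tau_1d > 0)
  if (f_mobile <= 0 || f_mobile >= 1) {
    stop("`f_mobile` must lie strictly between 0 and 1.", call. = FALSE)
  }
  tau_3d <- tau_1d * f_mobile / (1 - f_mobile)
  tibble::tibble(
    tau_1d = tau_1d, tau_3d = tau_3d,
    visit_rate = 1 / (tau_1d + tau_3d)
  )
}
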