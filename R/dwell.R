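# Dwell-time models for nonspecific DNA binding -----------------------------

#' Dwell-time models for bound phases
#'
#' Three generative models for the duration of nonspecific DNA-binding events:
#'
#' * `dwell_exponential(rate)`: a single off-rate, i.e. durations are
#'   exponential with mean `1/rate`. This is the behaviour expected on
#'   completely random sequences.
#' * `dwell_power_law(t_min, t_cut, gamma)`: survival probability
#'   `SP(t) = (t/t_min)^gamma` on `[t_min, t_cut]` (with `gamma < 0`), 1 below
#'   `t_min` and 0 above `t_cut`; the truncation at `t_cut` leaves a point
#'   mass there of size `(t_cut/t_min)^gamma`. This captures the broad tail
#'   of binding times produced by quasi-consensus (decoy) sites.
#' * `dwell_energy_landscape(tau0, e0)`: binding energies `E` are exponential
#'   with mean `e0` and the duration is `tau0 * exp(E)`, which implies the
#'   power-law tail `SP(t) = (t/tau0)^(-1/e0)` for `t > tau0`. Exponentially
#'   distributed binding energies are the standard microscopic rationale for
#'   power-law dwell times.
#' * `dwell_mixture(models, weights)`: a finite mixture of the above, e.g. a
#'   majority of short exponential events plus a minority power-law tail.
#'
#' @param rate Off-rate (1/s), positive.
#' @param t_min,t_cut Support of the truncated power law (s), `t_min < t_cut`.
#' @param gamma Power-law survival exponent, negative (e.g. -0.7).
#' @param tau0 Attempt time scale (s), positive.
#' @param e0 Mean binding energy in kT units, positive; the implied survival
#'   exponent is `-1/e0`.
#' @param models A list of dwell models.
#' @param weights Mixture weights, nonnegative, summing to 1.
#'
#' @return An object of class `dwell_model`.
#' @seealso [sample_bound_dwell()], [dwell_mean()], [dwell_survival()]
#' @name dwell_models
NULL

#' @rdname dwell_models
#' @export
dwell_exponential <- function(rate) {
  stopifnot(is.numeric(rate), length(rate) == 1L, is.finite(rate), rate > 0)
  structure(list(type = "exponential", rate = rate), class = "dwell_model")
}

#' @rdname dwell_models
#' @export
dwell_power_law <- function(t_min, t_cut, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma >= 0) {
    stop("`gamma` must be a negative survival exponent (e.g. -0.7).",
      call. = FALSE
    )
  }
  if (!is.numeric(t_min) || !is.numeric(t_cut) || t_min <= 0 ||
    t_cut <= t_min) {
    stop("power-law support is degenerate: need 0 < t_min < t_cut.",
      call. = FALSE
    )
  }
  structure(
    list(type = "power_law", t_min = t_min, t_cut = t_cut, gamma = gamma),
    class = "dwell_model"
  )
}

#' @rdname dwell_models
#' @export
dwell_energy_landscape <- function(tau0, e0) {
  stopifnot(
    is.numeric(tau0), length(tau0) == 1L, tau0 > 0,
    is.numeric(e0), length(e0) == 1L, e0 > 0
  )
  structure(
    list(type = "energy_landscape", tau0 = tau0, e0 = e0),
    class = "dwell_model"
  )
}

#' @rdname dwell_models
#' @export
dwell_mixture <- function(models, weights) {
  stopifnot(
    is.list(models), length(models) >= 1L,
    all(vapply(models, inherits, logical(1), "dwell_model")),
    is.numeric(weights), length(weights) == length(models),
    all(weights >= 0), abs(sum(weights) - 1) < 1e-9
  )
  structure(
    list(type = "mixture", models = models, weights = weights),
    class = "dwell_model"
  )
}

#' @export
print.dwell_model <- function(x, ...) {
  cat("<dwell_model>", x$type, "\n")
  invisible(x)
}

#' Sample bound-phase durations
#'
#' Draws i.i.d. dwell times from a [dwell model][dwell_models].
#'
#' @param model A `dwell_model`.
#' @param n Number of durations to draw (>= 1).
#' @param seed Optional integer seed; when supplied the draw is reproducible
#'   and the global random-number state is left untouched.
#' @return A numeric vector of `n` durations (s).
#' @export
#' @examples
#' mean(sample_bound_dwell(dwell_exponential(6.36), 1e4, seed = 1))
sample_bound_dwell <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "dwell_model"), n >= 1)
  n <- as.integer(n)
  draw <- function() {
    switch(model$type,
      exponential = stats::rexp(n, rate = model$rate),
      power_law = {
        u <- stats::runif(n)
        atom <- (model$t_cut / model$t_min)^model$gamma
        ifelse(u < atom, model$t_cut, model$t_min * u^(1 / model$gamma))
      },
      energy_landscape = {
        model$tau0 * exp(stats::rexp(n, rate = 1 / model$e0))
      },
      mixture = {
        comp <- sample.int(length(model$models), n,
          replace = TRUE, prob = model$weights
        )
        out <- numeric(n)
        for (j in seq_along(model$models)) {
          idx <- which(comp == j)
          if (length(idx)) {
            out[idx] <- sample_bound_dwell(model$models[[j]], length(idx))
          }
        }
        out
      },
      stop("unknown dwell model type", call. = FALSE)
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Mean of a dwell-time model
#'
#' Closed-form mean dwell time. The energy-landscape model has infinite mean
#' when `e0 >= 1` (survival exponent shallower than -1).
#'
#' @param model A `dwell_model`.
#' @return The mean duration (s), possibly `Inf`.
#' @export
dwell_mean <- function(model) {
  stopifnot(inherits(model, "dwell_model"))
  switch(model$type,
    exponential = 1 / model$rate,
    power_law = {
      g <- model$gamma
      r <- model$t_cut / model$t_min
      tail <- if (abs(1 + g) < 1e-12) {
        model$t_min * log(r)
      } else {
        model$t_min * (r^(1 + g) - 1) / (1 + g)
      }
      model$t_min + tail
    },
    energy_landscape = {
      if (model$e0 >= 1) Inf else model$tau0 / (1 - model$e0)
    },
    mixture = sum(model$weights * vapply(model$models, dwell_mean, numeric(1)))
  )
}

#' Analytic survival probability of a dwell-time model
#'
#' `SP(t) = P(duration > t)`, the complementary cumulative distribution.
#' Used as the generative oracle when validating the empirical
#' survival-probability pipeline.
#'
#' @param model A `dwell_model`.
#' @param t Numeric vector of times (s).
#' @return `SP(t)` for each element of `t`.
#' @export
dwell_survival <- function(model, t) {
  stopifnot(inherits(model, "dwell_model"), is.numeric(t))
  switch(model$type,
    exponential = exp(-model$rate * t),
    power_law = {
      sp <- rep(1, length(t))
      inside <- t >= model$t_min & t < model$t_cut
      sp[inside] <- (t[inside] / model$t_min)^model$gamma
      sp[t >= model$t_cut] <- 0
      sp
    },
    energy_landscape = {
      sp <- rep(1, length(t))
      above <- t > model$tau0
      sp[above] <- (t[above] / model$tau0)^(-1 / model$e0)
      sp
    },
    mixture = {
      comps <- vapply(
        model$models, dwell_survival, numeric(length(t)),
        t = t
      )
      if (length(t) == 1L) comps <- matrix(comps, nrow = 1L)
      as.numeric(comps %*% model$weights)
    }
  )
}
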