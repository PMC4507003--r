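# Mobility-population classification ----------------------------------------

# One EM run for a univariate Gaussian mixture with k components.
em_gauss_mix <- function(x, mu, sigma, w, tol = 1e-6, max_iter = 500) {
  n <- length(x)
  k <- length(mu)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    dens <- vapply(
      seq_len(k),
      function(j) w[j] * stats::dnorm(x, mu[j], sigma[j]),
      numeric(n)
    )
    rowsum_d <- rowSums(dens)
    ll <- sum(log(pmax(rowsum_d, .Machine$double.xmin)))
    resp <- dens / pmax(rowsum_d, .Machine$double.xmin)
    nk <- colSums(resp)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sigma <- sqrt(pmax(
      colSums(resp * (outer(x, mu, "-"))^2) / nk, 1e-6
    ))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll)) break
    ll_old <- ll
  }
  list(mu = mu, sigma = sigma, w = w, loglik = ll, iter = iter)
}

#' Classify mobility populations from instantaneous diffusion coefficients
#'
#' Fits a `k`-component Gaussian mixture to `log10(D_inst)` by
#' expectation-maximization (5 random restarts from quantile-spread initial
#' means, relative log-likelihood tolerance 1e-6) with the sole purpose of
#' estimating the characteristic diffusion coefficient of each population and
#' its relative abundance. Components are reported in decreasing mean, so
#' population 1 is the fastest. Non-positive `D_inst` values cannot enter the
#' log-scale histogram; they are excluded and counted.
#'
#' @param dinst A numeric vector of instantaneous diffusion coefficients, or
#'   a data frame with a `d_inst` column (e.g. from [fit_dinst()]).
#' @param k Number of components (default 3).
#' @param seed Optional integer seed controlling the restarts.
#' @param n_restarts Number of EM restarts (default 5).
#' @return An object of class `mobility_fit` with elements `populations` (a
#'   tibble with `population`, `d_um2_s` = `10^mean`, `fraction`, `mean_log10`,
#'   `sd_log10`), `loglik`, `n_used`, `n_excluded`, and the raw component
#'   parameters. Methods: [tidy()][generics::tidy], [glance()][generics::glance],
#'   [autoplot()][ggplot2::autoplot], `print`.
#' @export
#' @examples
#' x <- 10^c(rnorm(300, 0.9, 0.3), rnorm(400, 0, 0.3), rnorm(200, -1, 0.3))
#' classify_populations(x, k = 3, seed = 1)
classify_populations <- function(dinst, k = 3, seed = NULL, n_restarts = 5) {
  if (is.data.frame(dinst)) {
    stopifnot("d_inst" %in% names(dinst))
    dinst <- dinst$d_inst
  }
  dinst <- dinst[!is.na(dinst)]
  pos <- dinst[dinst > 0]
  n_excluded <- length(dinst) - length(pos)
  if (length(pos) < 10 * k) {
    stop(sprintf(
      "need at least %d positive D_inst values for a %d-component fit (got %d).",
      10 * k, k, length(pos)
    ), call. = FALSE)
  }
  x <- log10(pos)
  run <- function() {
    best <- NULL
    qs <- stats::quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
    spread <- stats::sd(x) / k
    for (r in seq_len(n_restarts)) {
      mu0 <- qs + if (r == 1) 0 else stats::rnorm(k, sd = spread)
      fit <- em_gauss_mix(x,
        mu = sort(mu0), sigma = rep(stats::sd(x) / k, k),
        w = rep(1 / k, k)
      )
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    best
  }
  best <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  if (!all(is.finite(c(best$mu, best$sigma, best$w)))) {
    stop("mixture fit did not converge to finite parameters.", call. = FALSE)
  }
  ord <- order(best$mu, decreasing = TRUE)
  populations <- tibble::tibble(
    population = seq_len(k),
    d_um2_s = 10^best$mu[ord],
    fraction = best$w[ord],
    mean_log10 = best$mu[ord],
    sd_log10 = best$sigma[ord]
  )
  structure(
    list(
      populations = populations,
      loglik = best$loglik,
      n_used = length(pos),
      n_excluded = n_excluded,
      iterations = best$iter,
      log10_d = x
    ),
    class = "mobility_fit"
  )
}

#' @export
print.mobility_fit <- function(x, ...) {
  cat(sprintf(
    "<mobility_fit> %d components on %d trajectories (%d non-positive excluded)\n",
    nrow(x$populations), x$n_used, x$n_excluded
  ))
  print(x$populations)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.mobility_fit <- function(x, ...) {
  x$populations
}

#' @export
glance.mobility_fit <- function(x, ...) {
  tibble::tibble(
    k = nrow(x$populations),
    loglik = x$loglik,
    n_used = x$n_used,
    n_excluded = x$n_excluded,
    iterations = x$iterations
  )
}
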