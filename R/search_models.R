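# Closed-form target-search rate models -------------------------------------

AVOGADRO <- 6.02214076e23

#' Convert a volumetric rate to molar units (and back)
#'
#' Kinetic rate constants computed in `um^3/s` (diffusion coefficients in
#' `um^2/s`, radii in um) convert to `1/M/s` via Avogadro's number and the
#' `1e15 um^3` per litre.
#'
#' @param k_vol Rate in `um^3/s` (>= 0).
#' @param k_molar Rate in `1/M/s` (>= 0).
#' @return The converted rate.
#' @export
#' @examples
#' rate_to_molar(1) # ~6.022e8 /M/s
rate_to_molar <- function(k_vol) {
  stopifnot(all(k_vol >= 0))
  k_vol * AVOGADRO / 1e15
}

#' @rdname rate_to_molar
#' @export
molar_to_rate <- function(k_molar) {
  stopifnot(all(k_molar >= 0))
  k_molar * 1e15 / AVOGADRO
}

#' Effective diffusion coefficient of an intermittently binding searcher
#'
#' A protein alternating between free diffusion (coefficient `d1`, mean phase
#' `tau_3d`) and immobile nonspecific binding (mean phase `tau_1d`) moves at
#' long times with `D = d1 * tau_3d / (tau_1d + tau_3d)`.
#'
#' @param d1 Free diffusion coefficient (um^2/s).
#' @param tau_1d Mean bound time (s, >= 0).
#' @param tau_3d Mean free time (s, > 0).
#' @return Effective diffusion coefficient (um^2/s).
#' @export
#' @examples
#' effective_diffusion(8, 2, 6) # 6
effective_diffusion <- function(d1, tau_1d, tau_3d) {
  stopifnot(d1 > 0, tau_1d >= 0, tau_3d > 0)
  d1 * tau_3d / (tau_1d + tau_3d)
}

#' Diffusion-limited association rate to an absorbing sphere
#'
#' Smoluchowski rate `k_a = 4 pi D r_t` for a perfectly absorbing spherical
#' locus of radius `r_t`, the upper bound reached when binding inside the
#' locus is instantaneous.
#'
#' @param d Effective diffusion coefficient (um^2/s).
#' @param r_t Locus radius (um).
#' @return Association rate constant (1/M/s).
#' @export
#' @examples
#' absorbing_sphere_rate(6, 0.35) # ~1.6e10 /M/s
absorbing_sphere_rate <- function(d, r_t) {
  stopifnot(d > 0, r_t >= 0)
  rate_to_molar(4 * pi * d * r_t)
}

#' Per-unit-time binding rate inside the clustered-target locus
#'
#' `kappa` is the probability per unit time that a searcher inside the locus
#' binds a target sequence of capture radius `a`, given the elementary volume
#' `v` per site and the binding efficiency `lambda` (probability per unit
#' time of binding when within distance `a` of a site). The two limiting
#' limits are `4 pi D a / v` for perfect association (`lambda >> D/a^2`) and
#' `lambda * (4 pi / 3) a^3 / v` in the low-efficiency regime
#' (`lambda << D/a^2`); the interior is interpolated as the harmonic mean of
#' the two limits, which is exact in both.
#'
#' @param d Diffusion coefficient (um^2/s).
#' @param a Capture radius of one target sequence (um, default 1e-3 = 1 nm).
#' @param v Elementary volume per site (um^3), `(4 pi / 3) r_t^3 / N`.
#' @param lambda Binding probability per unit time within distance `a` (1/s).
#' @return `kappa` (1/s).
#' @export
site_rate_kappa <- function(d, a, v, lambda) {
  stopifnot(d > 0, a > 0, v > 0, lambda >= 0)
  k_perfect <- 4 * pi * d * a / v
  k_reaction <- lambda * (4 * pi / 3) * a^3 / v
  if (k_reaction == 0) {
    return(0)
  }
  1 / (1 / k_perfect + 1 / k_reaction)
}

#' Association rate to a uniformly reactive spherical locus
#'
#' Association rate constant to a sphere of radius `r_t` inside which the
#' searcher binds at rate `kappa` per unit time (classical uniformly
#' reactive sphere): `k_a = 4 pi D r_t (1 - tanh(x)/x)` with
#' `x = r_t sqrt(kappa / D)`. The `kappa -> Inf` limit is the absorbing
#' sphere; for small `kappa` the rate reduces to the volume-reaction limit
#' `(4 pi / 3) r_t^3 kappa`.
#'
#' @param d Diffusion coefficient (um^2/s).
#' @param r_t Locus radius (um).
#' @param kappa Binding rate inside the locus (1/s).
#' @return Association rate constant (1/M/s).
#' @export
locus_binding_rate <- function(d, r_t, kappa) {
  stopifnot(d > 0, r_t > 0, kappa >= 0)
  x <- r_t * sqrt(kappa / d)
  f <- if (x < 1e-4) {
    x^2 / 3 - 2 * x^4 / 15 # series of 1 - tanh(x)/x
  } else {
    1 - tanh(x) / x
  }
  rate_to_molar(4 * pi * d * r_t * f)
}

#' Binding efficiency from a measured reaction-limited rate
#'
#' In the reaction-limited regime the association rate is
#' `k_a = (4 pi / 3) lambda N a^3`, independent of transport; inverting for
#' `lambda` converts a measured `k_a` into the per-site binding efficiency.
#' When `d` is supplied the regime assumption `lambda << D / a^2` is checked
#' and a warning is raised if it fails (the value is still returned).
#'
#' @param k_a_meas Measured association rate constant (1/M/s).
#' @param n_sites Number of specific sites `N`.
#' @param a Capture radius (um, default 1e-3).
#' @param d Optional diffusion coefficient (um^2/s) for the regime check.
#' @return A one-row tibble: `lambda` (1/s), `regime_ratio`
#'   (`lambda a^2 / D`, `NA` without `d`), `reaction_limited`.
#' @export
#' @examples
#' extract_lambda(9.2e4, 19200, d = 6)
extract_lambda <- function(k_a_meas, n_sites, a = 1e-3, d = NULL) {
  stopifnot(k_a_meas > 0, n_sites > 0, a > 0)
  lambda <- molar_to_rate(k_a_meas) / ((4 * pi / 3) * n_sites * a^3)
  ratio <- if (is.null(d)) NA_real_ else lambda * a^2 / d
  ok <- is.na(ratio) || ratio < 0.1
  if (!ok) {
    rlang::warn(sprintf(
      "reaction-limited assumption questionable: lambda a^2 / D = %.3g is not << 1.",
      ratio
    ))
  }
  tibble::tibble(
    lambda = lambda, regime_ratio = ratio,
    reaction_limited = ok
  )
}

#' Sliding length of a nonspecifically bound searcher
#'
#' Genomic span scanned by 1D diffusion during one nonspecific binding
#' event: `ell_SL = sqrt(4 D_SL tau_RS)` (span convention for 1D Brownian
#' motion over the residence time on random sequences).
#'
#' @param d_sl 1D sliding diffusion coefficient (bp^2/s).
#' @param tau_rs Mean residence time on random sequences (s, >= 0).
#' @return Sliding length (bp).
#' @export
#' @examples
#' sliding_length(1e5, 0.158) # ~251 bp
sliding_length <- function(d_sl, tau_rs) {
  stopifnot(d_sl > 0, tau_rs >= 0)
  sqrt(4 * d_sl * tau_rs)
}

#' Facilitated-diffusion association rate with sliding over inserts
#'
#' With the nonspecific association to DNA as the limiting step, a searcher
#' attaches to nonspecific DNA at rate `1/tau_3d`, scans `ell_sl` base pairs,
#' and binds a specific site with probability `p` when the excursion overlaps
#' one of the `n_inserts` insert regions:
#' `k_a = p * n_inserts * ell_sl / (c_dna * (tau_1d + tau_3d))` with `c_dna`
#' the molar concentration of genomic base pairs.
#'
#' @param p Specific-binding probability per overlapping excursion, in
#'   `[0, 1]`.
#' @param n_inserts Number of inserts.
#' @param ell_sl Sliding length (bp).
#' @param c_dna Genomic base-pair concentration (M).
#' @param tau_1d,tau_3d Mean bound and free phase durations (s).
#' @return Association rate constant (1/M/s).
#' @export
#' @examples
#' fd_association_rate(1, 200, 500, 1e-2, 2, 6) # 1.25e6
fd_association_rate <- function(p, n_inserts, ell_sl, c_dna, tau_1d,
                                tau_3d) {
  stopifnot(p >= 0, p <= 1, n_inserts > 0, ell_sl >= 0, c_dna > 0,
    tau_1d >= 0, tau_3d > 0)
  p * n_inserts * ell_sl / (c_dna * (tau_1d + tau_3d))
}

#' @rdname fd_association_rate
#' @param k_a_meas Measured association rate constant (1/M/s) to invert for
#'   `p`.
#' @return `solve_p()` returns a one-row tibble: `p_raw` (the inverted
#'   value), `p` (clipped to `[0, 1]`), `in_range`.
#' @export
solve_p <- function(k_a_meas, n_inserts, ell_sl, c_dna, tau_1d, tau_3d) {
  stopifnot(k_a_meas >= 0, n_inserts > 0, ell_sl > 0, c_dna > 0)
  p_raw <- k_a_meas * c_dna * (tau_1d + tau_3d) / (n_inserts * ell_sl)
  tibble::tibble(
    p_raw = p_raw,
    p = min(max(p_raw, 0), 1),
    in_range = p_raw >= 0 && p_raw <= 1
  )
}

#' Mean search time of a single molecule and nonspecific visits en route
#'
#' One molecule in a nucleus of volume `v_nuc` corresponds to a concentration
#' `1 / (N_A v_nuc)`; the mean time to bind the target is
#' `T = 1 / (k_a c)`, during which the searcher visits nonspecific sites
#' `T * visit_rate` times.
#'
#' @param k_a Association rate constant (1/M/s).
#' @param v_nuc_um3 Nuclear volume (um^3, default 500).
#' @return Mean search time (s).
#' @export
#' @examples
#' search_time_single(9.2e4) / 86400 # ~38 days
search_time_single <- function(k_a, v_nuc_um3 = 500) {
  stopifnot(k_a > 0, v_nuc_um3 > 0)
  c_one <- 1 / (AVOGADRO * v_nuc_um3 * 1e-15)
  1 / (k_a * c_one)
}

#' @rdname search_time_single
#' @param t_search Search time (s).
#' @param visit_rate Nonspecific visit rate `1/(tau_1d + tau_3d)` (1/s).
#' @return `nonspecific_visits()` returns the expected number of nonspecific
#'   sites visited.
#' @export
nonspecific_visits <- function(t_search, visit_rate) {
  stopifnot(t_search >= 0, visit_rate >= 0)
  t_search * visit_rate
}

#' Diffusion-limited nonspecific association time
#'
#' Time scale `1 / (D a c_dna)` for a diffusion-limited encounter with
#' nonspecific DNA at base-pair concentration `c_dna` and capture radius
#' `a`; comparing it with the measured mean free time reveals how inefficient
#' nonspecific association is.
#'
#' @param d Diffusion coefficient (um^2/s).
#' @param a Capture radius (um).
#' @param c_dna Genomic base-pair concentration (M).
#' @return Time (s).
#' @export
#' @examples
#' diffusion_limited_ns_time(8, 1e-3, 1e-2) # ~2e-5 s
diffusion_limited_ns_time <- function(d, a, c_dna) {
  stopifnot(d > 0, a > 0, c_dna > 0)
  n_per_um3 <- c_dna * AVOGADRO / 1e15
  1 / (d * a * n_per_um3)
}

#' Full search-model report
#'
#' Evaluates every derived quantity of the clustered-target and
#' facilitated-diffusion models from one parameter set, in consistent molar
#' units.
#'
#' @param d1 Free diffusion coefficient (um^2/s).
#' @param tau_1d,tau_3d Mean bound and free times (s).
#' @param r_t Locus radius (um).
#' @param n_sites Number of specific sites.
#' @param n_inserts Number of inserts.
#' @param a Capture radius (um).
#' @param c_dna Genomic base-pair concentration (M).
#' @param d_sl 1D sliding diffusion coefficient (bp^2/s).
#' @param tau_rs Residence time on random sequences (s).
#' @param k_a_meas Measured association rate constant (1/M/s).
#' @param v_nuc_um3 Nuclear volume (um^3).
#' @return A tibble with columns `quantity`, `value`, `units`.
#' @export
search_model_report <- function(d1 = 8, tau_1d = 2, tau_3d = 6,
                                r_t = 0.35, n_sites = 19200,
                                n_inserts = 200, a = 1e-3, c_dna = 1e-2,
                                d_sl = 1e5, tau_rs = 0.158,
                                k_a_meas = 9.2e4, v_nuc_um3 = 500) {
  d_eff <- effective_diffusion(d1, tau_1d, tau_3d)
  visit <- 1 / (tau_1d + tau_3d)
  k_abs <- absorbing_sphere_rate(d_eff, r_t)
  lam <- extract_lambda(k_a_meas, n_sites, a, d = d_eff)
  ell <- sliding_length(d_sl, tau_rs)
  p <- solve_p(k_a_meas, n_inserts, ell, c_dna, tau_1d, tau_3d)
  t_search <- search_time_single(k_a_meas, v_nuc_um3)
  tibble::tibble(
    quantity = c(
      "d_eff", "visit_rate", "k_a_absorbing_sphere", "lambda",
      "lambda_regime_ratio", "sliding_length", "p_specific",
      "search_time_single", "nonspecific_visits",
      "diffusion_limited_ns_time"
    ),
    value = c(
      d_eff, visit, k_abs, lam$lambda, lam$regime_ratio, ell, p$p_raw,
      t_search, nonspecific_visits(t_search, visit),
      diffusion_limited_ns_time(d1, a, c_dna)
    ),
    units = c(
      "um^2/s", "1/s", "1/M/s", "1/s", "", "bp", "", "s", "", "s"
    )
  )
}
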