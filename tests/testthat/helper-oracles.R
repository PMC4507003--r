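# Independent brute-force oracles used across the suite.

TETO <- "TCCCTATCAGTGATAGAGA" # canonical 19-bp tetO operator

# Exhaustive displacement-pair MSD (oracle for compute_msd)
msd_bruteforce <- function(x, y, max_lag) {
  vapply(seq_len(max_lag), function(k) {
    n <- length(x)
    pairs <- vapply(seq_len(n - k), function(i) {
      (x[i + k] - x[i])^2 + (y[i + k] - y[i])^2
    }, numeric(1))
    mean(pairs)
  }, numeric(1))
}

# Counting oracle for the empirical survival probability
sp_bruteforce <- function(durations, t) {
  vapply(t, function(tt) sum(durations > tt), numeric(1)) / length(durations)
}

# O(G*L) window-by-window scanner (oracle for scan_contiguous_matches)
scan_bruteforce <- function(genome, motif, min_len) {
  L <- nchar(motif)
  gg <- strsplit(genome, "")[[1]]
  mp <- strsplit(motif, "")[[1]]
  mm <- strsplit(reverse_complement(motif), "")[[1]]
  lr <- function(m) {
    if (!any(m)) {
      return(0L)
    }
    r <- rle(m)
    max(r$lengths[r$values])
  }
  out <- list()
  for (s in seq_len(length(gg) - L + 1)) {
    win <- gg[s:(s + L - 1)]
    rp <- lr(win == mp)
    rm <- lr(win == mm)
    if (max(rp, rm) >= min_len) {
      plus <- rp >= rm
      out[[length(out) + 1]] <- data.frame(
        start = s - 1L,
        strand = if (plus) "+" else "-",
        match_len = max(rp, rm),
        mismatches = if (plus) sum(win != mp) else sum(win != mm)
      )
    }
  }
  if (!length(out)) {
    return(data.frame(
      start = integer(0), strand = character(0),
      match_len = integer(0), mismatches = integer(0)
    ))
  }
  do.call(rbind, out)
}

# a simple synthetic trajectory: Brownian steps with optional static
# (bound) stretches; returns tibble in the package's trajectory dialect
make_track <- function(n, d, dt, bound_idx = integer(0), sigma = 0,
                       track_id = 1L, seed = 1) {
  withr::with_seed(seed, {
    step_sd <- rep(sqrt(2 * d * dt), n - 1)
    step_sd[bound_idx[bound_idx < n]] <- 0
    x <- cumsum(c(0, stats::rnorm(n - 1, sd = step_sd)))
    y <- cumsum(c(0, stats::rnorm(n - 1, sd = step_sd)))
    if (sigma > 0) {
      x <- x + stats::rnorm(n, sd = sigma)
      y <- y + stats::rnorm(n, sd = sigma)
    }
    tibble::tibble(
      track_id = track_id, frame = seq_len(n) - 1L,
      t_s = (seq_len(n) - 1L) * dt, x_um = x, y_um = y
    )
  })
}
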