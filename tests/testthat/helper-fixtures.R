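# Shared fixture builders; all deterministic given the seed argument.

# a short evoked sweep with two stimuli and known component amplitudes
make_ppr_sweep <- function(ratio, interval_ms, noise_sd = 0, seed = NULL,
                           tau_decay = 40) {
  gen_evoked_sweep(
    data.frame(latency = c(3, 3), amplitude = c(100, 100 * ratio),
               tau_rise = 2, tau_decay = tau_decay, stim = c(1, 2)),
    noise_sd = noise_sd, stim_times = c(0.1, 0.1 + interval_ms / 1000),
    duration = 0.6, seed = seed)
}

# brute-force autocorrelogram oracle: explicit shift-and-correlate on the
# binned counts, no shared code with autocorrelogram()
oracle_autocorrelogram <- function(times, duration, bin_width, max_lag) {
  n_bins <- floor(duration / bin_width)
  counts <- integer(n_bins)
  for (t in times) {
    b <- min(floor(t / bin_width) + 1L, n_bins)
    counts[b] <- counts[b] + 1L
  }
  n_lags <- min(floor(max_lag / bin_width), n_bins - 3L)
  vapply(seq_len(n_lags), function(j) {
    a <- counts[1:(n_bins - j)]
    b <- counts[(1 + j):n_bins]
    suppressWarnings(stats::cor(a, b))
  }, numeric(1))
}

# exhaustive two-sided Fisher p: enumerate every table with the observed
# margins, compute each probability from log-factorials, sum those no more
# probable than the observed table
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; n <- r1 + r2
  lp <- function(aa) {
    bb <- r1 - aa; cc <- c1 - aa; dd <- r2 - cc
    lgamma(r1 + 1) + lgamma(r2 + 1) + lgamma(c1 + 1) + lgamma(n - c1 + 1) -
      lgamma(n + 1) - lgamma(aa + 1) - lgamma(bb + 1) - lgamma(cc + 1) -
      lgamma(dd + 1)
  }
  support <- max(0, c1 - r2):min(c1, r1)
  probs <- exp(vapply(support, lp, numeric(1)))
  p_obs <- probs[match(a, support)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}
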