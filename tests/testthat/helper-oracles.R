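# Independent brute-force oracles, kept deliberately literal: they restate
# the analysis rules sample by sample / assignment by assignment, without
# sharing code with the package internals.

# Literal spike detection: scan every sample, collect contiguous
# suprathreshold excursions, timestamp at the extremum, apply the
# keep-first refractory rule, then the amplitude gate.
oracle_detect <- function(x, sigma, sampling_rate, config) {
  dev <- if (config$polarity == "neg") -x else abs(x)
  thr <- config$threshold_k * sigma
  n <- length(x)
  peaks <- integer()
  i <- 1L
  while (i <= n) {
    if (dev[i] > thr) {
      j <- i
      while (j < n && dev[j + 1L] > thr) j <- j + 1L
      best <- i
      for (k in i:j) if (dev[k] > dev[best]) best <- k
      if (best > 1L && best < n) peaks <- c(peaks, best)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  times <- (peaks - 1L) / sampling_rate
  accepted <- integer()
  last <- -Inf
  for (k in seq_along(times)) {
    if (times[k] - last >= config$refractory - 1e-12) {
      accepted <- c(accepted, peaks[k])
      last <- times[k]
    }
  }
  amp <- dev[accepted]
  ok <- amp >= config$amplitude_gate
  list(times = (accepted[ok] - 1L) / sampling_rate, amplitudes = amp[ok])
}

# Exact two-sided signed-rank p by direct enumeration of every sign vector
# (n <= 16). Mid-ranks for tied |d|; zeros dropped by the caller.
oracle_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  lower <- mean(v_all <= v_obs + 1e-9)
  upper <- mean(v_all >= v_obs - 1e-9)
  min(1, 2 * min(lower, upper))
}

# Dense direct convolution of a binned count vector with a kernel
# (full/open length).
oracle_conv <- function(counts, kern) {
  out <- numeric(length(counts) + length(kern) - 1L)
  for (i in seq_along(counts)) {
    for (j in seq_along(kern)) {
      out[i + j - 1L] <- out[i + j - 1L] + counts[i] * kern[j]
    }
  }
  out
}

# Random test trace: white noise plus biphasic templates at given times.
make_trace <- function(n, sampling_rate, spike_times, spike_amps, noise_sd,
                       seed) {
  withr::with_seed(seed, {
    x <- rnorm(n, sd = noise_sd)
    tpl <- spike_template(sampling_rate)
    half <- (length(tpl) - 1L) %/% 2L
    for (k in seq_along(spike_times)) {
      ci <- round(spike_times[k] * sampling_rate) + 1L
      lo <- max(1L, ci - half); hi <- min(n, ci + half)
      seg <- (lo - ci + half + 1L):(hi - ci + half + 1L)
      x[lo:hi] <- x[lo:hi] + spike_amps[k] * tpl[seg]
    }
    x
  })
}
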