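#' Robust noise floor (Donoho's rule)
#'
#' Estimates the noise standard deviation of a filtered trace as
#' `median(|x|) / 0.6745` — the median absolute signal rescaled to be
#' consistent for Gaussian noise. Because spikes are sparse, the median is
#' essentially blind to them, making this the standard robust noise floor
#' for high-pass extracellular data.
#'
#' @param signal numeric vector, a filtered single-channel trace (uV).
#' @return noise s.d. estimate in uV.
#' @export
estimate_noise_sigma <- function(signal) {
  if (!length(signal)) stop("cannot estimate a noise floor from an empty trace")
  median(abs(signal)) / 0.6745
}

# Find contiguous threshold excursions of `x` and return the index of the
# absolute extremum of each. Excursions whose extremum falls on the first
# or last sample are dropped (unresolvable peak).
.excursion_extrema <- function(x, thr, polarity = "abs") {
  dev <- if (polarity == "neg") pmax(-x, 0) else abs(x)
  above <- dev > thr
  if (!any(above)) return(integer())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  peaks <- integer(length(runs))
  for (k in seq_along(runs)) {
    i0 <- starts[runs[k]]; i1 <- ends[runs[k]]
    peaks[k] <- i0 + which.max(dev[i0:i1]) - 1L
  }
  peaks[peaks > 1L & peaks < length(x)]
}

# Forward scan: keep a timestamp only if it is >= refractory after the last
# accepted one (keep-first rule).
.refractory_filter <- function(times, refractory) {
  if (refractory <= 0 || length(times) < 2L) return(seq_along(times))
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= refractory - 1e-12) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  which(keep)
}

#' Detect multi-unit spikes on one filtered channel
#'
#' The detection contract, applied in order:
#' 1. find contiguous excursions where the signal deviation exceeds
#'    `threshold_k * sigma`; deviation is `-x` by default
#'    (`polarity = "neg"`: extracellular spikes are negative-leading, and
#'    the zero-phase filter rings symmetrically, so rectified detection
#'    would let a sub-gate pre-ring lobe claim the refractory slot of its
#'    own spike), or `|x|` with `polarity = "abs"`;
#' 2. timestamp each excursion at its absolute extremum (sample-aligned;
#'    extrema on the first/last sample are discarded);
#' 3. forward-scan the timestamps, discarding any that falls less than the
#'    refractory period (2 ms) after the last *accepted* one — keep-first;
#' 4. discard events whose extremum deviation is below the amplitude gate
#'    (40 uV).
#'
#' With `sigma = 0` every excursion above 0 passes stage 1 and the gate
#' still applies.
#'
#' @param signal filtered single-channel trace (uV).
#' @param sigma the channel's noise floor (uV), e.g. from
#'   [estimate_noise_sigma()].
#' @param sampling_rate Hz.
#' @param config an [analysis_config()].
#' @param channel_id label for the returned train.
#' @return A [spike_train()].
#' @export
detect_spikes <- function(signal, sigma, sampling_rate,
                          config = analysis_config(), channel_id = "ch") {
  if (sigma < 0) stop("sigma must be >= 0")
  peaks <- .excursion_extrema(signal, config$threshold_k * sigma,
                              config$polarity)
  times <- (peaks - 1L) / sampling_rate
  keep <- .refractory_filter(times, config$refractory)
  peaks <- peaks[keep]
  dev <- if (config$polarity == "neg") -signal[peaks] else abs(signal[peaks])
  ok <- dev >= config$amplitude_gate
  spike_train(channel_id, times[keep][ok], dev[ok], noise_sigma = sigma)
}

#' Detect spikes on every channel of a conditioned recording
#'
#' Estimates the per-channel noise floor with [estimate_noise_sigma()] and
#' runs [detect_spikes()] on each channel. Deterministic given its inputs.
#'
#' @param session a preprocessed [recording_session()].
#' @param config an [analysis_config()].
#' @return Named list of [spike_train()], one per channel.
#' @export
detect_all <- function(session, config = analysis_config()) {
  stopifnot(inherits(session, "recording_session"))
  trains <- vector("list", session$n_channels)
  for (i in seq_len(session$n_channels)) {
    x <- session$samples[i, ]
    sigma <- if (session$n_samples) estimate_noise_sigma(x) else 0
    trains[[i]] <- detect_spikes(x, sigma, session$sampling_rate, config,
                                 channel_id = session$channel_ids[i])
  }
  names(trains) <- session$channel_ids
  trains
}

#' Match detected spike times to ground truth
#'
#' Greedy chronological matching: walks both sorted time vectors and pairs a
#' detected spike with a ground-truth spike when they are within `tol`
#' seconds; each spike matches at most once.
#'
#' @param truth,detected sorted spike time vectors (seconds).
#' @param tol matching tolerance in seconds (default 0.001).
#' @return list with `n_matched`, `recall` and `precision`.
#' @export
match_spike_times <- function(truth, detected, tol = 0.001) {
  i <- 1L; j <- 1L; m <- 0L
  nt <- length(truth); nd <- length(detected)
  while (i <= nt && j <= nd) {
    d <- detected[j] - truth[i]
    if (abs(d) <= tol + 1e-12) {
      m <- m + 1L; i <- i + 1L; j <- j + 1L
    } else if (d > 0) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  list(n_matched = m,
       recall = if (nt) m / nt else NA_real_,
       precision = if (nd) m / nd else NA_real_)
}
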