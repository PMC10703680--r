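#' Biphasic spike template
#'
#' Difference-of-Gaussians biphasic waveform with ~1.5 ms support: a sharp
#' negative-leading trough followed by a broader positive rebound with a
#' 3:1 trough-to-peak ratio. Normalized so the trough equals -1; multiply by
#' a positive amplitude to get a spike with that trough depth in uV.
#'
#' @param sampling_rate Hz.
#' @param span template support in seconds (default 0.0015).
#' @return numeric vector of odd length, trough at the center sample.
#' @export
spike_template <- function(sampling_rate, span = 0.0015) {
  half <- floor(span * sampling_rate / 2)
  t <- (-half:half) / sampling_rate
  w <- -exp(-(t / 1.5e-4)^2 / 2) +
    (1 / 3) * exp(-((t - 4e-4) / 2.5e-4)^2 / 2)
  w / abs(min(w))
}

# Inhomogeneous Poisson spike times on [0, duration] for one unit:
# rate = base_rate outside pulses, base_rate * multiplier inside pulses,
# realized by thinning a homogeneous process at the maximum rate, then
# enforcing a refractory period by keep-first deletion.
.one_unit_times <- function(duration, base_rate, multiplier, protocol,
                            refractory = 0.002) {
  rmax <- base_rate * max(1, multiplier)
  if (rmax <= 0) return(numeric())
  n <- rpois(1L, rmax * duration)
  if (n == 0L) return(numeric())
  t <- sort(runif(n, 0, duration))
  if (multiplier != 1 && !is.null(protocol)) {
    rate <- ifelse(in_pulse(t, protocol), base_rate * multiplier, base_rate)
    t <- t[runif(n) < rate / rmax]
  } else if (multiplier <= 1 || is.null(protocol)) {
    # homogeneous at base_rate; thin if rmax > base_rate (multiplier < 1
    # outside-pulse case cannot occur: rmax = base_rate then)
    t <- t
  }
  if (refractory > 0 && length(t) > 1L) {
    t <- t[.refractory_filter(t, refractory)]
  }
  t
}

#' Simulate a ground-truthed multichannel extracellular recording
#'
#' Each channel carries `units_per_channel` independent units firing as
#' Poisson processes (thinned to a 2 ms refractory). On responder channels
#' the unit rate is multiplied by `rate_multiplier` while a light pulse is
#' on. Every spike inserts a biphasic template ([spike_template()]) scaled
#' to the unit's amplitude, on top of white Gaussian noise. Bad channels
#' carry no units and have their noise s.d. set to `bad_sigma_factor` times
#' the empirical median s.d. of the good channels, so they violate the
#' 2x-median rejection rule by construction.
#'
#' @param n_channels number of channels (default 64, as on a 4-shank x
#'   16-site probe; geometry is attached when `n_channels` is a multiple
#'   of 16).
#' @param duration recording length in seconds; must cover both protocol
#'   windows.
#' @param protocol a [stimulation_protocol()].
#' @param units_per_channel units summed on each channel (default 2).
#' @param base_rate per-unit baseline rate in Hz (default 2).
#' @param rate_multiplier pulse-time rate multiplier on responder channels
#'   (> 0; 1 = no modulation).
#' @param amplitude_range uV interval for per-unit trough amplitudes
#'   (default c(80, 150)).
#' @param noise_sigma per-channel noise s.d. in uV (default 5).
#' @param responder_channels integer indices of modulated channels
#'   (default none).
#' @param bad_channels integer indices of constructed bad channels
#'   (default none).
#' @param bad_sigma_factor noise inflation of bad channels relative to the
#'   median good-channel s.d. (default 3; anything > 2 guarantees
#'   rejection at the default factor).
#' @param sampling_rate Hz (default 30000).
#' @param seed integer seed; all randomness flows from it.
#' @return list with `session` (a [recording_session()]) and `truth`
#'   (class `ephys_ground_truth`): per-unit spike times, unit-to-channel
#'   map, amplitudes, responder/bad channel sets, noise sigmas and the
#'   multiplier.
#' @export
simulate_ephys <- function(n_channels = 64, duration = 1200,
                           protocol = default_protocol(),
                           units_per_channel = 2, base_rate = 2,
                           rate_multiplier = 1,
                           amplitude_range = c(80, 150), noise_sigma = 5,
                           responder_channels = integer(),
                           bad_channels = integer(),
                           bad_sigma_factor = 3,
                           sampling_rate = 30000, seed = 1L) {
  if (base_rate < 0) stop("base_rate must be >= 0")
  if (rate_multiplier <= 0) stop("rate_multiplier must be > 0")
  if (!is.null(protocol)) {
    if (protocol$stimulation_window[2] > duration + 1e-9 ||
        protocol$baseline_window[2] > duration + 1e-9) {
      stop("protocol windows exceed the recording duration")
    }
  }
  responder_channels <- as.integer(responder_channels)
  bad_channels <- as.integer(bad_channels)
  good <- setdiff(seq_len(n_channels), bad_channels)
  n_samples <- round(duration * sampling_rate)

  withr::with_seed(as.integer(seed), {
    template <- spike_template(sampling_rate)
    half <- (length(template) - 1L) %/% 2L
    samples <- matrix(0, n_channels, n_samples)
    unit_times <- list(); unit_channel <- integer(); unit_amp <- numeric()
    u <- 0L
    for (ch in good) {
      mult <- if (ch %in% responder_channels) rate_multiplier else 1
      for (k in seq_len(units_per_channel)) {
        u <- u + 1L
        tt <- .one_unit_times(duration, base_rate, mult, protocol)
        amp <- runif(1, amplitude_range[1], amplitude_range[2])
        unit_times[[u]] <- tt
        unit_channel[u] <- ch
        unit_amp[u] <- amp
        if (length(tt)) {
          centers <- round(tt * sampling_rate) + 1L
          for (ci in centers) {
            lo <- max(1L, ci - half); hi <- min(n_samples, ci + half)
            seg <- (lo - ci + half + 1L):(hi - ci + half + 1L)
            samples[ch, lo:hi] <- samples[ch, lo:hi] + amp * template[seg]
          }
        }
      }
      samples[ch, ] <- samples[ch, ] + rnorm(n_samples, sd = noise_sigma)
    }
    # bad channels: inflated pure noise, pegged to the realized good-channel s.d.
    sigma_bad <- noise_sigma * bad_sigma_factor
    if (length(bad_channels)) {
      good_sd <- vapply(good, function(ch) sd(samples[ch, ]), numeric(1))
      sigma_bad <- bad_sigma_factor * median(good_sd)
      for (ch in bad_channels) {
        samples[ch, ] <- rnorm(n_samples, sd = sigma_bad)
      }
    }
    geometry <- NULL
    if (n_channels %% 16L == 0L) {
      geometry <- data.frame(shank = rep(seq_len(n_channels / 16L), each = 16L),
                             site = rep(seq_len(16L), n_channels / 16L))
    }
    session <- recording_session(samples, sampling_rate, geometry = geometry)
    noise_by_channel <- rep(noise_sigma, n_channels)
    noise_by_channel[bad_channels] <- sigma_bad
    truth <- structure(
      list(unit_spike_times = unit_times, unit_channel_map = unit_channel,
           unit_amplitudes = unit_amp,
           responder_channels = responder_channels,
           bad_channels = bad_channels,
           rate_multiplier = rate_multiplier,
           noise_sigma = noise_by_channel,
           channel_ids = session$channel_ids),
      class = "ephys_ground_truth"
    )
    list(session = session, truth = truth)
  })
}

#' Ground-truth spike times pooled per channel
#'
#' @param truth an `ephys_ground_truth`.
#' @param channel integer channel index.
#' @return sorted numeric vector of that channel's true spike times.
#' @export
truth_channel_times <- function(truth, channel) {
  sel <- which(truth$unit_channel_map == channel)
  sort(unlist(truth$unit_spike_times[sel], use.names = FALSE))
}

#' Simulate spike trains only (no voltage synthesis)
#'
#' The train-level counterpart of [simulate_ephys()]: one pooled multi-unit
#' train per channel, with pulse-locked modulation on responder channels.
#' Useful for statistical calibration studies where only rates matter.
#'
#' @inheritParams simulate_ephys
#' @return Named list of [spike_train()] objects.
#' @export
simulate_spike_trains <- function(n_channels = 16, duration = 1200,
                                  protocol = default_protocol(),
                                  units_per_channel = 1, base_rate = 2,
                                  rate_multiplier = 1,
                                  responder_channels = integer(),
                                  seed = 1L) {
  withr::with_seed(as.integer(seed), {
    trains <- vector("list", n_channels)
    for (ch in seq_len(n_channels)) {
      mult <- if (ch %in% responder_channels) rate_multiplier else 1
      tt <- sort(unlist(lapply(seq_len(units_per_channel), function(k)
        .one_unit_times(duration, base_rate, mult, protocol)),
        use.names = FALSE))
      tt <- tt[!duplicated(tt)]
      trains[[ch]] <- spike_train(sprintf("ch%02d", ch), tt)
    }
    names(trains) <- vapply(trains, `[[`, character(1), "channel_id")
    trains
  })
}
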