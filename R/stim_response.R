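.count_in_window <- function(times, w) {
  sum(times >= w[1] & times < w[2])
}

#' Classify channels as active and as optogenetic responders
#'
#' Activity: a channel is active when its spike count over the stimulation
#' window corresponds to at least `active_rate_min` (5 spikes/min, 0.0833
#' Hz; the criterion is `>=`, so exactly 5/min qualifies). Responders:
#' among active channels, those whose firing rate changes by at least
#' `responder_fraction` (10%) from the baseline rate.
#'
#' The rate the responder criterion compares against baseline is chosen by
#' `config$responder_epoch`:
#' * `"pulses"` (default): the rate within the union of light-pulse
#'   intervals. With 500 ms pulses every 10 s the pulses occupy 5% of the
#'   stimulation window, so modulation confined to pulse time is diluted
#'   20-fold in the whole-window rate; evaluating at pulse time makes the
#'   evoked change directly observable.
#' * `"window"`: the mean rate over the whole stimulation window (the
#'   literal whole-period reading).
#' Both rates are returned regardless.
#'
#' A silent baseline with stimulation spikes (`baseline_rate = 0`) is a
#' responder by definition; its `relative_change` is reported as `NA`
#' (undefined), never as a number.
#'
#' @param trains list of [spike_train()] objects.
#' @param protocol a [stimulation_protocol()].
#' @param config an [analysis_config()].
#' @return data.frame (one row per channel): `channel`, `baseline_rate`,
#'   `stim_rate` (whole-window), `pulse_rate`, `n_baseline`, `n_stim`,
#'   `active`, `responder`, `relative_change`, `direction`.
#' @export
classify_channels <- function(trains, protocol, config = analysis_config()) {
  stopifnot(inherits(protocol, "stimulation_protocol"))
  bw <- protocol$baseline_window; sw <- protocol$stimulation_window
  dur_b <- diff(bw); dur_s <- diff(sw)
  if (dur_b <= 0 || dur_s <= 0) stop("zero-length protocol window")
  pi_tab <- pulse_intervals(protocol)
  dur_p <- attr(pi_tab, "total")

  rows <- lapply(trains, function(tr) {
    nb <- .count_in_window(tr$times, bw)
    ns <- .count_in_window(tr$times, sw)
    np <- sum(in_pulse(tr$times, protocol))
    baseline_rate <- nb / dur_b
    stim_rate <- ns / dur_s
    pulse_rate <- if (dur_p > 0) np / dur_p else NA_real_
    active <- ns + 1e-9 >= config$active_rate_min * dur_s
    r_cmp <- if (config$responder_epoch == "pulses") pulse_rate else stim_rate
    if (baseline_rate > 0) {
      rel <- (r_cmp - baseline_rate) / baseline_rate
      responder <- active && abs(rel) >= config$responder_fraction - 1e-12
    } else {
      rel <- NA_real_
      responder <- active && isTRUE(r_cmp > 0)
    }
    direction <- if (is.na(rel)) {
      if (responder) "increase" else "none"
    } else if (rel > 0) "increase" else if (rel < 0) "decrease" else "none"
    data.frame(channel = tr$channel_id, baseline_rate = baseline_rate,
               stim_rate = stim_rate, pulse_rate = pulse_rate,
               n_baseline = nb, n_stim = ns,
               active = active, responder = responder,
               relative_change = rel, direction = direction)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize one organoid's channel classification
#'
#' Mean baseline/stimulation rates are averaged over active channels only;
#' the responder percentage is `100 * n_responding / n_active`. With no
#' active channels the means and percentage are `NA` (explicit sentinel,
#' not 0).
#'
#' @param summaries a channel-summary data.frame from [classify_channels()].
#' @param organoid_id label.
#' @return one-row data.frame: `organoid`, `mean_rate_baseline`,
#'   `mean_rate_stim`, `n_channels`, `n_active`, `n_responding`,
#'   `percent_responding`.
#' @export
summarize_organoid <- function(summaries, organoid_id = "organoid") {
  act <- summaries[summaries$active, , drop = FALSE]
  n_active <- nrow(act)
  n_resp <- sum(act$responder)
  data.frame(
    organoid = organoid_id,
    mean_rate_baseline = if (n_active) mean(act$baseline_rate) else NA_real_,
    mean_rate_stim = if (n_active) mean(act$stim_rate) else NA_real_,
    n_channels = nrow(summaries),
    n_active = n_active,
    n_responding = n_resp,
    percent_responding = if (n_active) 100 * n_resp / n_active else NA_real_
  )
}

#' Smoothed population event trace
#'
#' Binarizes each active channel's spike train onto a 1 ms grid (a bin is 1
#' if the channel fired at least once in it), sums the binary rasters
#' across channels, and convolves with a normalized (unit-mass) 100 ms
#' kernel — a 101-bin boxcar by default, or a Gaussian truncated to the
#' same support with `config$kernel_shape = "gaussian"`. The output grid is
#' padded by half the kernel on both sides so that kernel mass — and hence
#' the total count of occupied (channel, bin) pairs — is conserved exactly.
#'
#' @param trains list of [spike_train()] (active channels).
#' @param config an [analysis_config()].
#' @param t_start,t_end time range of the binning grid (defaults: 0 to the
#'   last spike).
#' @return list of class `population_event_trace` with `times` (bin
#'   centers, s), `values`, `bin_width` and `total_mass`.
#' @export
population_event_trace <- function(trains, config = analysis_config(),
                                   t_start = 0, t_end = NULL) {
  bw <- config$bin_width
  all_t <- unlist(lapply(trains, `[[`, "times"), use.names = FALSE)
  if (is.null(t_end)) {
    t_end <- if (length(all_t)) max(all_t) + bw else t_start + bw
  }
  n_bins <- max(1L, as.integer(ceiling((t_end - t_start) / bw)))
  counts <- numeric(n_bins)
  for (tr in trains) {
    t <- tr$times[tr$times >= t_start & tr$times < t_start + n_bins * bw]
    if (!length(t)) next
    idx <- unique(pmin(n_bins, floor((t - t_start) / bw) + 1L))
    counts[idx] <- counts[idx] + 1  # binarized per channel, then summed
  }
  k_bins <- as.integer(round(config$kernel_width / bw)) + 1L
  kern <- if (config$kernel_shape == "gaussian") {
    half <- (k_bins - 1L) / 2
    g <- exp(-((seq_len(k_bins) - 1 - half) / (half / 2.5))^2 / 2)
    g / sum(g)
  } else {
    rep(1 / k_bins, k_bins)
  }
  values <- .conv_open(counts, kern)
  pad <- (k_bins - 1L) / 2
  times <- (seq_along(values) - 1 - pad) * bw + t_start + bw / 2
  structure(list(times = times, values = values, bin_width = bw,
                 total_mass = sum(values) ),
            class = "population_event_trace")
}

# full ("open") linear convolution, FFT-based for long inputs
.conv_open <- function(x, k) {
  if (length(x) >= 1024L) {
    # stats::convolve(type = "open") computes sum x[i] k[j] at lag i+j
    return(convolve(x, rev(k), type = "open"))
  }
  n <- length(x) + length(k) - 1L
  out <- numeric(n)
  for (i in seq_along(k)) {
    out[i:(i + length(x) - 1L)] <- out[i:(i + length(x) - 1L)] + x * k[i]
  }
  out
}

#' @export
print.population_event_trace <- function(x, ...) {
  cat(sprintf("population_event_trace: %d bins of %g ms, total mass %.6g\n",
              length(x$values), 1000 * x$bin_width, x$total_mass))
  invisible(x)
}
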