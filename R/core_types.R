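#' Multichannel extracellular recording
#'
#' Container for a block of extracellular voltage data. Voltages are stored
#' in microvolts (conversion from acquisition units happens exactly once, at
#' read time), times in seconds, and the sample matrix is channel-major:
#' one row per channel.
#'
#' @param samples numeric matrix, channels x samples, in uV.
#' @param sampling_rate sampling rate in Hz (scalar, > 0).
#' @param channel_ids unique channel labels; defaults to `ch01`, `ch02`, ...
#' @param geometry optional data.frame with columns `shank` and `site`
#'   (one row per channel), e.g. a 4-shank x 16-site probe layout.
#'
#' @return An object of class `recording_session` with elements `samples`,
#'   `sampling_rate`, `channel_ids`, `geometry`, `n_channels`, `n_samples`
#'   and `duration` (seconds).
#' @export
recording_session <- function(samples, sampling_rate, channel_ids = NULL,
                              geometry = NULL) {
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1L)
  storage.mode(samples) <- "double"
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be a single positive number (Hz)")
  }
  n_ch <- nrow(samples)
  if (is.null(channel_ids)) channel_ids <- sprintf("ch%02d", seq_len(n_ch))
  channel_ids <- as.character(channel_ids)
  if (length(channel_ids) != n_ch) {
    stop("channel_ids length must match the number of channels")
  }
  if (anyDuplicated(channel_ids)) stop("channel_ids must be unique")
  if (!is.null(geometry)) {
    geometry <- as.data.frame(geometry)
    if (nrow(geometry) != n_ch || !all(c("shank", "site") %in% names(geometry))) {
      stop("geometry must have one row per channel with columns 'shank' and 'site'")
    }
  }
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         channel_ids = channel_ids, geometry = geometry,
         n_channels = n_ch, n_samples = ncol(samples),
         duration = ncol(samples) / sampling_rate),
    class = "recording_session"
  )
}

#' @export
print.recording_session <- function(x, ...) {
  cat(sprintf("recording_session: %d channels x %d samples @ %g Hz (%.2f s)\n",
              x$n_channels, x$n_samples, x$sampling_rate, x$duration))
  invisible(x)
}

#' Pulsed optogenetic stimulation protocol
#'
#' Describes when light pulses occur and which time windows count as the
#' baseline and the stimulation period. The canonical protocol is a 500 ms
#' pulse every 10 s for 10 min, following a 10 min baseline.
#'
#' @param pulse_onsets pulse start times in seconds, strictly increasing.
#' @param pulse_duration pulse length in seconds (> 0).
#' @param baseline_window numeric length-2, `[t0, t1]` of the baseline period.
#' @param stimulation_window numeric length-2, `[t0, t1]` of the stimulation
#'   period; all pulses must fall inside it and the two windows must not
#'   overlap.
#' @return An object of class `stimulation_protocol`.
#' @export
stimulation_protocol <- function(pulse_onsets, pulse_duration,
                                 baseline_window, stimulation_window) {
  pulse_onsets <- as.numeric(pulse_onsets)
  if (length(pulse_onsets) && is.unsorted(pulse_onsets, strictly = TRUE)) {
    stop("pulse_onsets must be strictly increasing")
  }
  if (!is.numeric(pulse_duration) || pulse_duration <= 0) {
    stop("pulse_duration must be positive")
  }
  if (length(pulse_onsets) > 1L &&
      any(diff(pulse_onsets) < pulse_duration - 1e-12)) {
    stop("pulses overlap: onsets must be spaced by at least pulse_duration")
  }
  chk_win <- function(w, nm) {
    if (length(w) != 2L || !is.numeric(w) || w[2] <= w[1]) {
      stop(sprintf("%s must be a numeric [t0, t1] with t1 > t0", nm))
    }
    as.numeric(w)
  }
  baseline_window <- chk_win(baseline_window, "baseline_window")
  stimulation_window <- chk_win(stimulation_window, "stimulation_window")
  if (max(baseline_window[1], stimulation_window[1]) <
      min(baseline_window[2], stimulation_window[2])) {
    stop("baseline_window and stimulation_window must not overlap")
  }
  if (length(pulse_onsets) &&
      (min(pulse_onsets) < stimulation_window[1] - 1e-12 ||
       max(pulse_onsets) + pulse_duration > stimulation_window[2] + 1e-12)) {
    stop("all pulses must lie within stimulation_window")
  }
  structure(
    list(pulse_onsets = pulse_onsets, pulse_duration = pulse_duration,
         baseline_window = baseline_window,
         stimulation_window = stimulation_window),
    class = "stimulation_protocol"
  )
}

#' @export
print.stimulation_protocol <- function(x, ...) {
  cat(sprintf(paste0("stimulation_protocol: %d pulses of %g ms, baseline ",
                     "[%g, %g] s, stimulation [%g, %g] s\n"),
              length(x$pulse_onsets), 1000 * x$pulse_duration,
              x$baseline_window[1], x$baseline_window[2],
              x$stimulation_window[1], x$stimulation_window[2]))
  invisible(x)
}

#' Default pulse protocol: 500 ms pulses every 10 s for 10 min
#'
#' Convenience constructor for the canonical stimulation schedule: a
#' baseline window of `baseline_duration` seconds starting at 0, followed by
#' a stimulation window of `stimulation_duration` seconds in which a pulse of
#' `pulse_duration` seconds is triggered every `period` seconds.
#'
#' @param baseline_duration seconds of baseline (default 600).
#' @param stimulation_duration seconds of stimulation (default 600).
#' @param period seconds between pulse onsets (default 10).
#' @param pulse_duration pulse length in seconds (default 0.5).
#' @return A [stimulation_protocol()].
#' @export
default_protocol <- function(baseline_duration = 600,
                             stimulation_duration = 600,
                             period = 10, pulse_duration = 0.5) {
  t0 <- baseline_duration
  onsets <- seq(t0, t0 + stimulation_duration - pulse_duration, by = period)
  stimulation_protocol(onsets, pulse_duration,
                       baseline_window = c(0, baseline_duration),
                       stimulation_window = c(t0, t0 + stimulation_duration))
}

#' Union of pulse intervals of a protocol
#'
#' @param protocol a [stimulation_protocol()].
#' @return data.frame with columns `start`, `end` (seconds), plus the total
#'   pulse time as attribute `"total"`.
#' @keywords internal
pulse_intervals <- function(protocol) {
  d <- data.frame(start = protocol$pulse_onsets,
                  end = protocol$pulse_onsets + protocol$pulse_duration)
  attr(d, "total") <- nrow(d) * protocol$pulse_duration
  d
}

#' Is each time inside a light pulse?
#'
#' @param times numeric vector of times (seconds).
#' @param protocol a [stimulation_protocol()].
#' @return logical vector.
#' @export
in_pulse <- function(times, protocol) {
  if (!length(protocol$pulse_onsets)) return(rep(FALSE, length(times)))
  i <- findInterval(times, protocol$pulse_onsets)
  ok <- i >= 1L
  out <- rep(FALSE, length(times))
  out[ok] <- times[ok] - protocol$pulse_onsets[i[ok]] < protocol$pulse_duration
  out
}

#' Per-ROI fluorescence recording
#'
#' @param traces numeric matrix, ROIs x frames (arbitrary fluorescence units).
#' @param frame_interval seconds per frame (default 0.065, i.e. 65 ms
#'   exposure).
#' @param roi_ids unique ROI labels; defaults to `roi001`, ...
#' @param condition free-text condition label (e.g. "control").
#' @return An object of class `calcium_recording`.
#' @export
calcium_recording <- function(traces, frame_interval = 0.065, roi_ids = NULL,
                              condition = "unlabeled") {
  if (!is.matrix(traces)) traces <- matrix(traces, nrow = 1L)
  storage.mode(traces) <- "double"
  if (!is.numeric(frame_interval) || frame_interval <= 0) {
    stop("frame_interval must be positive (seconds per frame)")
  }
  n_roi <- nrow(traces)
  if (is.null(roi_ids)) roi_ids <- sprintf("roi%03d", seq_len(n_roi))
  roi_ids <- as.character(roi_ids)
  if (length(roi_ids) != n_roi || anyDuplicated(roi_ids)) {
    stop("roi_ids must be unique and match the number of trace rows")
  }
  structure(
    list(traces = traces, frame_interval = frame_interval,
         roi_ids = roi_ids, condition = as.character(condition)[1L],
         n_rois = n_roi, n_frames = ncol(traces),
         duration = ncol(traces) * frame_interval),
    class = "calcium_recording"
  )
}

#' @export
print.calcium_recording <- function(x, ...) {
  cat(sprintf("calcium_recording [%s]: %d ROIs x %d frames @ %g ms/frame (%.1f s)\n",
              x$condition, x$n_rois, x$n_frames, 1000 * x$frame_interval,
              x$duration))
  invisible(x)
}

#' Per-channel multi-unit spike train
#'
#' @param channel_id channel label.
#' @param times spike times in seconds, strictly increasing.
#' @param amplitudes absolute voltage deviation at each spike extremum (uV).
#' @param noise_sigma the channel's robust noise s.d. estimate (uV).
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(channel_id, times, amplitudes = numeric(length(times)),
                        noise_sigma = NA_real_) {
  times <- as.numeric(times)
  if (length(times) > 1L && is.unsorted(times, strictly = TRUE)) {
    stop("spike times must be strictly increasing")
  }
  if (length(amplitudes) != length(times)) {
    stop("amplitudes must have one value per spike")
  }
  structure(
    list(channel_id = as.character(channel_id), times = times,
         amplitudes = as.numeric(amplitudes),
         noise_sigma = as.numeric(noise_sigma)),
    class = "spike_train"
  )
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("spike_train %s: %d spikes, sigma = %.3g uV\n",
              x$channel_id, length(x$times), x$noise_sigma))
  invisible(x)
}
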