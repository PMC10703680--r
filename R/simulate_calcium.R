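#' Double-exponential calcium transient kernel
#'
#' `g(t) = exp(-t / decay) - exp(-t / rise)` for `t >= 0` (0 before),
#' normalized to unit peak. The raw kernel peaks at
#' `t* = log(decay / rise) * rise * decay / (decay - rise)`.
#'
#' @param t times in seconds (may be negative; kernel is causal).
#' @param rise,decay time constants in seconds, `rise < decay`. Defaults
#'   0.2 and 1.5 s, representative of a slow indicator (GCaMP6s-like).
#' @return kernel values with unit peak.
#' @export
double_exp_kernel <- function(t, rise = 0.2, decay = 1.5) {
  if (rise >= decay) stop("kernel_rise must be smaller than kernel_decay")
  tp <- kernel_peak_time(rise, decay)
  peak <- exp(-tp / decay) - exp(-tp / rise)
  out <- ifelse(t >= 0, exp(-t / decay) - exp(-t / rise), 0)
  out / peak
}

#' @rdname double_exp_kernel
#' @export
kernel_peak_time <- function(rise = 0.2, decay = 1.5) {
  if (rise >= decay) stop("kernel_rise must be smaller than kernel_decay")
  log(decay / rise) * rise * decay / (decay - rise)
}

#' Width of the transient kernel at a fraction of its peak
#'
#' Solves `g(t) = fraction` on both sides of the peak of the unit-peak
#' double-exponential kernel by root bracketing; the width at 5% of peak is
#' the analytic ground truth for the measured event duration.
#'
#' @inheritParams double_exp_kernel
#' @param fraction height fraction (default 0.05).
#' @return width in seconds.
#' @export
kernel_width_at_fraction <- function(rise = 0.2, decay = 1.5, fraction = 0.05) {
  stopifnot(fraction > 0, fraction < 1)
  tp <- kernel_peak_time(rise, decay)
  g <- function(t) double_exp_kernel(t, rise, decay) - fraction
  left <- stats::uniroot(g, c(0, tp), tol = 1e-12)$root
  hi <- tp
  while (g(hi) > 0) hi <- hi * 2 + decay
  right <- stats::uniroot(g, c(tp, hi), tol = 1e-12)$root
  right - left
}

#' Simulate ground-truthed GCaMP-like fluorescence traces
#'
#' Each ROI receives Poisson-timed calcium events; every event adds an
#' amplitude-scaled unit-peak double-exponential transient
#' ([double_exp_kernel()]). Traces are sampled every `frame_interval`
#' seconds (65 ms default), offset by a nonnegative baseline, and corrupted
#' with white Gaussian noise. The analytic width of the kernel at 5% of
#' peak is stored as the true event duration.
#'
#' @param n_rois number of ROIs (default 50).
#' @param duration seconds (default 390, i.e. 6.5 min).
#' @param frame_interval seconds per frame (default 0.065).
#' @param event_rate events per minute per ROI (default 3).
#' @param kernel_rise,kernel_decay transient time constants in seconds
#'   (defaults 0.2 and 1.5; `rise < decay` required).
#' @param amplitude peak height of one event (arbitrary units, default 5).
#' @param noise_sigma noise s.d. (default 0.5).
#' @param baseline nonnegative offset added to every trace (default 10).
#' @param seed integer seed.
#' @return list with `recording` (a [calcium_recording()]) and `truth`
#'   (class `calcium_ground_truth`): per-ROI event times, amplitudes,
#'   kernel parameters and `true_duration` (width at 5% of peak).
#' @export
simulate_calcium <- function(n_rois = 50, duration = 390,
                             frame_interval = 0.065, event_rate = 3,
                             kernel_rise = 0.2, kernel_decay = 1.5,
                             amplitude = 5, noise_sigma = 0.5,
                             baseline = 10, seed = 1L) {
  if (kernel_rise >= kernel_decay) {
    stop("kernel_rise must be smaller than kernel_decay")
  }
  if (baseline < 0) stop("baseline must be nonnegative")
  n_frames <- as.integer(floor(duration / frame_interval))
  frame_t <- (seq_len(n_frames) - 1L) * frame_interval
  withr::with_seed(as.integer(seed), {
    traces <- matrix(baseline, n_rois, n_frames)
    event_times <- vector("list", n_rois)
    support <- kernel_decay * 12   # transient negligible beyond this
    for (i in seq_len(n_rois)) {
      n_ev <- rpois(1L, event_rate / 60 * duration)
      tt <- sort(runif(n_ev, 0, duration))
      event_times[[i]] <- tt
      for (t0 in tt) {
        sel <- which(frame_t >= t0 & frame_t <= t0 + support)
        if (length(sel)) {
          traces[i, sel] <- traces[i, sel] +
            amplitude * double_exp_kernel(frame_t[sel] - t0,
                                          kernel_rise, kernel_decay)
        }
      }
      if (noise_sigma > 0) {
        traces[i, ] <- traces[i, ] + rnorm(n_frames, sd = noise_sigma)
      }
    }
    recording <- calcium_recording(traces, frame_interval)
    truth <- structure(
      list(event_times = event_times,
           amplitudes = rep(amplitude, n_rois),
           kernel_rise = kernel_rise, kernel_decay = kernel_decay,
           noise_sigma = noise_sigma, baseline = baseline,
           true_duration = kernel_width_at_fraction(kernel_rise,
                                                    kernel_decay, 0.05)),
      class = "calcium_ground_truth"
    )
    list(recording = recording, truth = truth)
  })
}
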