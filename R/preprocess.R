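#' Reject channels with inflated noise
#'
#' Computes each channel's standard deviation on the raw, unfiltered signal
#' and removes channels whose s.d. strictly exceeds `factor` times the
#' median s.d. across all channels (median taken before any removal; for an
#' even channel count, the mean of the two central order statistics).
#' Quality control runs on the raw signal, before filtering and referencing.
#'
#' @param session a [recording_session()] with at least 2 channels.
#' @param factor rejection multiple of the median s.d. (default 2).
#' @return list with `session` (retained channels) and `report`, a
#'   `preprocess_report` holding `channel_sd`, `median_sd`,
#'   `removed_channels` and the rejection factor.
#' @export
reject_bad_channels <- function(session, factor = 2) {
  stopifnot(inherits(session, "recording_session"))
  if (session$n_channels < 2L) {
    stop("channel QC needs at least 2 channels (median s.d. is not meaningful)")
  }
  # channel-wise sd (one row copied at a time: long recordings stay cheap)
  channel_sd <- vapply(seq_len(session$n_channels),
                       function(i) sd(session$samples[i, ]), numeric(1))
  names(channel_sd) <- session$channel_ids
  med <- median(channel_sd)
  bad <- channel_sd > factor * med
  keep <- which(!bad)
  out <- recording_session(session$samples[keep, , drop = FALSE],
                           session$sampling_rate,
                           channel_ids = session$channel_ids[keep],
                           geometry = if (!is.null(session$geometry))
                             session$geometry[keep, , drop = FALSE])
  report <- structure(
    list(channel_sd = channel_sd, median_sd = med, factor = factor,
         removed_channels = session$channel_ids[bad],
         filter_spec = NULL),
    class = "preprocess_report"
  )
  list(session = out, report = report)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf("preprocess_report: median s.d. %.3g uV, removed %d of %d channels (> %gx)\n",
              x$median_sd, length(x$removed_channels), length(x$channel_sd),
              x$factor))
  if (length(x$removed_channels)) {
    cat("  removed:", paste(x$removed_channels, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Zero-phase Butterworth bandpass
#'
#' Applies an order-`order` Butterworth bandpass (default 300-3000 Hz)
#' forward and backward (`signal::filtfilt`), so the net phase is zero and
#' spike timestamps are not shifted; the effective magnitude response is
#' that of twice the design order.
#'
#' @param session a [recording_session()].
#' @param low,high band edges in Hz; `high` must be below Nyquist.
#' @param order Butterworth design order (default 4).
#' @return A filtered [recording_session()] of identical shape.
#' @export
bandpass <- function(session, low = 300, high = 3000, order = 4) {
  stopifnot(inherits(session, "recording_session"))
  nyq <- session$sampling_rate / 2
  if (high >= nyq) {
    stop(sprintf("band edge %g Hz violates the Nyquist limit (%g Hz at %g Hz sampling)",
                 high, nyq, session$sampling_rate))
  }
  if (low <= 0 || low >= high) stop("need 0 < low < high")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  out <- session$samples
  # filtfilt allocates ~10x its input in temporaries; on multi-GB inputs
  # collect after every channel so the transient footprint stays bounded
  big <- length(out) > 5e7
  for (i in seq_len(session$n_channels)) {
    out[i, ] <- signal::filtfilt(bf, session$samples[i, ])
    if (big) gc(FALSE)
  }
  recording_session(out, session$sampling_rate, session$channel_ids,
                    session$geometry)
}

#' Common median reference
#'
#' Subtracts the across-channel median from every channel at each sample,
#' removing artifacts shared across the probe. Exact property: after
#' referencing, the across-channel median is 0 at every sample (exactly so
#' for odd channel counts).
#'
#' @param session a [recording_session()] with >= 2 channels.
#' @return A referenced [recording_session()].
#' @export
common_median_reference <- function(session) {
  stopifnot(inherits(session, "recording_session"))
  if (session$n_channels < 2L) {
    stop("common median reference needs at least 2 channels")
  }
  med <- col_medians_cpp(session$samples)
  out <- sweep_cols_cpp(session$samples, med)
  dimnames(out) <- dimnames(session$samples)
  recording_session(out, session$sampling_rate, session$channel_ids,
                    session$geometry)
}

#' Full conditioning chain: QC, bandpass, common median reference
#'
#' Runs the three conditioning stages in their fixed order — quality
#' control on the raw signal, zero-phase bandpass, then common median
#' reference. (Referencing after filtering and filtering after QC is the
#' contract; the stages are not commutative.)
#'
#' @param session a raw [recording_session()].
#' @param config an [analysis_config()].
#' @return list with `session` (conditioned) and `report` (QC report with
#'   `filter_spec` filled in).
#' @export
preprocess <- function(session, config = analysis_config()) {
  qc <- reject_bad_channels(session, factor = config$bad_channel_factor)
  s <- bandpass(qc$session, low = config$band_low, high = config$band_high,
                order = config$filter_order)
  qc$session <- NULL   # long recordings: free the unfiltered copy early
  s <- common_median_reference(s)
  qc$report$filter_spec <- list(band = c(config$band_low, config$band_high),
                                order = config$filter_order,
                                phase = "zero (forward-backward)")
  list(session = s, report = qc$report)
}
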