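.sidecar_required <- c("n_channels", "sampling_rate", "dtype", "uv_per_bit",
                       "byte_order", "interleaved")

.dtype_size <- function(dtype) {
  switch(dtype,
         int16 = 2L,
         int32 = 4L,
         stop("unsupported sample dtype in sidecar: ", dtype))
}

#' Read a flat-binary extracellular recording
#'
#' Reads a flat binary file of integer samples together with its JSON
#' sidecar. The sidecar must declare `n_channels`, `sampling_rate`, `dtype`
#' (`"int16"` or `"int32"`), `uv_per_bit` (microvolts per least-significant
#' bit), `byte_order` (`"little"`/`"big"`) and `interleaved` (`true` when
#' frames are channel-interleaved: ch1 s1, ch2 s1, ..., chN s1, ch1 s2, ...).
#' Optional keys: `channel_ids`, `geometry` (lists `shank`, `site`).
#' Scaling to microvolts happens here, exactly once.
#'
#' @param binary_path path to the sample payload.
#' @param sidecar_path path to the JSON sidecar (default: `binary_path` +
#'   `".json"`).
#' @return A [recording_session()] in microvolts.
#' @export
read_recording <- function(binary_path, sidecar_path = paste0(binary_path, ".json")) {
  if (!file.exists(binary_path)) stop("recording file not found: ", binary_path)
  if (!file.exists(sidecar_path)) stop("sidecar file not found: ", sidecar_path)
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  missing <- setdiff(.sidecar_required, names(meta))
  if (length(missing)) {
    stop("sidecar is missing required key(s): ", paste(missing, collapse = ", "))
  }
  n_ch <- as.integer(meta$n_channels)
  size <- .dtype_size(meta$dtype)
  endian <- match.arg(meta$byte_order, c("little", "big"))
  nbytes <- file.size(binary_path)
  frame_bytes <- n_ch * size
  if (nbytes %% frame_bytes != 0) {
    stop(sprintf(
      "format error: file length %d is not divisible by frame size %d (n_channels x %d bytes)",
      nbytes, frame_bytes, size))
  }
  n_samples <- as.integer(nbytes / frame_bytes)
  raw_vals <- readBin(binary_path, what = "integer", n = n_ch * n_samples,
                      size = size, signed = TRUE, endian = endian)
  if (isTRUE(meta$interleaved)) {
    m <- matrix(as.double(raw_vals), nrow = n_ch)
  } else {
    m <- matrix(as.double(raw_vals), ncol = n_ch)
    m <- t(m)
  }
  if (n_samples == 0L) m <- matrix(numeric(0), nrow = n_ch, ncol = 0L)
  m <- m * as.numeric(meta$uv_per_bit)
  geometry <- NULL
  if (!is.null(meta$geometry)) {
    geometry <- data.frame(shank = as.integer(meta$geometry$shank),
                           site = as.integer(meta$geometry$site))
  }
  sess <- recording_session(m, sampling_rate = as.numeric(meta$sampling_rate),
                            channel_ids = meta$channel_ids, geometry = geometry)
  attr(sess, "uv_per_bit") <- as.numeric(meta$uv_per_bit)
  sess
}

#' Write a recording as flat binary + JSON sidecar
#'
#' Quantizes microvolt samples to integers at `uv_per_bit` and writes the
#' channel-interleaved payload plus a sidecar that [read_recording()] can
#' consume. Samples that already sit on the `uv_per_bit` grid (e.g. anything
#' read from disk) round-trip bit-exactly.
#'
#' @param session a [recording_session()].
#' @param binary_path output payload path.
#' @param sidecar_path output sidecar path (default: payload + `".json"`).
#' @param uv_per_bit quantization step in uV/LSB (default 0.195, a common
#'   acquisition scale at 16-bit resolution).
#' @param dtype `"int16"` or `"int32"`.
#' @return Invisibly, the sidecar metadata list.
#' @export
write_recording <- function(session, binary_path,
                            sidecar_path = paste0(binary_path, ".json"),
                            uv_per_bit = 0.195, dtype = "int16") {
  stopifnot(inherits(session, "recording_session"))
  size <- .dtype_size(dtype)
  vals <- round(session$samples / uv_per_bit)
  lim <- if (size == 2L) 32767 else 2147483647
  if (length(vals) && max(abs(vals)) > lim) {
    stop("samples exceed the representable range at this uv_per_bit/dtype")
  }
  # interleave: column-major walk of the channels x samples matrix
  writeBin(as.integer(vals), binary_path, size = size, endian = "little")
  meta <- list(n_channels = session$n_channels,
               sampling_rate = session$sampling_rate,
               dtype = dtype, uv_per_bit = uv_per_bit,
               byte_order = "little", interleaved = TRUE,
               channel_ids = session$channel_ids)
  if (!is.null(session$geometry)) {
    meta$geometry <- list(shank = session$geometry$shank,
                          site = session$geometry$site)
  }
  jsonlite::write_json(meta, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(meta)
}

#' Write a stimulation protocol to JSON / read it back
#'
#' @param protocol a [stimulation_protocol()].
#' @param path output path.
#' @return `write_protocol` invisibly returns `path`; `read_protocol`
#'   returns a [stimulation_protocol()].
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "stimulation_protocol"))
  jsonlite::write_json(unclass(protocol), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  stimulation_protocol(x$pulse_onsets, x$pulse_duration,
                       x$baseline_window, x$stimulation_window)
}

#' Read a trace table CSV as a calcium recording
#'
#' Expects one column per ROI (header = ROI id) and one row per frame.
#'
#' @param path CSV path.
#' @param frame_interval seconds per frame.
#' @param condition condition label.
#' @return A [calcium_recording()].
#' @export
read_calcium_csv <- function(path, frame_interval = 0.065,
                             condition = "unlabeled") {
  d <- read.csv(path, check.names = FALSE)
  calcium_recording(t(as.matrix(d)), frame_interval = frame_interval,
                    roi_ids = colnames(d), condition = condition)
}

#' Spike trains as a flat table
#'
#' @param trains list of [spike_train()] objects.
#' @return data.frame with columns `channel`, `time_s`, `amplitude_uV`.
#' @export
spikes_to_table <- function(trains) {
  if (!length(trains)) {
    return(data.frame(channel = character(), time_s = numeric(),
                      amplitude_uV = numeric()))
  }
  do.call(rbind, lapply(trains, function(tr) {
    data.frame(channel = rep(tr$channel_id, length(tr$times)),
               time_s = tr$times, amplitude_uV = tr$amplitudes)
  }))
}

#' Write pipeline outputs plus a reproducibility manifest
#'
#' Emits delimited text tables (spikes: `channel, time_s, amplitude_uV`
#' with microsecond-precision times; channel summaries: one row per channel;
#' calcium events: `roi, peak_time_s, amplitude, duration_s`) and a JSON
#' manifest recording the full effective configuration, its hash and the
#' seed, so that two runs with identical configuration and seed are
#' byte-identical.
#'
#' @param spikes list of [spike_train()] (or `NULL` to skip).
#' @param summaries channel-summary data.frame (or `NULL`).
#' @param events calcium event data.frame (or `NULL`).
#' @param out_dir output directory (created if needed).
#' @param config an [analysis_config()].
#' @return Invisibly, the manifest list.
#' @export
write_tables <- function(spikes = NULL, summaries = NULL, events = NULL,
                         out_dir, config = analysis_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  files <- character()
  if (!is.null(spikes)) {
    tab <- spikes_to_table(spikes)
    tab$time_s <- sprintf("%.6f", tab$time_s)
    p <- file.path(out_dir, "spikes.csv")
    write.csv(tab, p, row.names = FALSE, quote = FALSE)
    files <- c(files, spikes = p)
  }
  if (!is.null(summaries)) {
    p <- file.path(out_dir, "channel_summaries.csv")
    write.csv(summaries, p, row.names = FALSE, quote = FALSE)
    files <- c(files, summaries = p)
  }
  if (!is.null(events)) {
    ev <- data.frame(roi = events$roi, peak_time_s = sprintf("%.6f", events$peak_time),
                     amplitude = events$peak_height,
                     duration_s = sprintf("%.6f", events$duration))
    p <- file.path(out_dir, "calcium_events.csv")
    write.csv(ev, p, row.names = FALSE, quote = FALSE)
    files <- c(files, events = p)
  }
  manifest <- list(package = "orgephys",
                   version = as.character(utils::packageVersion("orgephys")),
                   config = unclass(config),
                   config_hash = config_hash(config),
                   seed = config$seed,
                   files = as.list(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
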