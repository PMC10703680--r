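.config_defaults <- function() {
  list(
    band_low            = 300,      # Hz, bandpass lower edge
    band_high           = 3000,     # Hz, bandpass upper edge
    filter_order        = 4L,       # Butterworth design order
    threshold_k         = 5,        # detection threshold, s.d. multiples
    refractory          = 0.002,    # s, minimum spacing between spikes
    amplitude_gate      = 40,       # uV, minimum spike extremum
    active_rate_min     = 5 / 60,   # Hz, >= 5 spikes per minute
    responder_fraction  = 0.10,     # >= 10% rate change from baseline
    bin_width           = 0.001,    # s, population-trace bin
    kernel_width        = 0.100,    # s, population-trace smoothing kernel
    bad_channel_factor  = 2,        # x median s.d. for channel rejection
    peak_width_fraction = 0.05,     # calcium width measured at 5% of height
    seed                = 1L,
    # implementation choices exposed as configuration
    polarity            = "neg",    # "neg" or "abs" spike detection polarity
    responder_epoch     = "pulses", # "pulses" or "window" responder rate
    kernel_shape        = "boxcar", # "boxcar" or "gaussian" smoothing kernel
    ca_threshold_k      = 3,        # calcium peak threshold, s.d. multiples
    ca_baseline_percentile = 0.10,  # calcium baseline quantile
    ca_min_separation   = 2L        # frames, minimum peak separation
  )
}

#' Analysis configuration
#'
#' Bundle of every analysis constant with defaults matching the published
#' pipeline: 300-3000 Hz order-4 Butterworth band, a 5 s.d. detection
#' threshold over the median-based noise floor, a 2 ms refractory rule, a
#' 40 uV amplitude gate, activity at >= 5 spikes/min (0.0833 Hz), responders
#' at a >= 10% rate change, 1 ms population bins with a normalized 100 ms
#' kernel, channel rejection above 2x the median s.d., and calcium event
#' width measured at 5% of peak height.
#'
#' @param ... named values overriding any default (unknown names error).
#' @return An object of class `analysis_config` (a validated named list).
#' @export
#' @examples
#' cfg <- analysis_config()
#' cfg$threshold_k
#' analysis_config(refractory = 0)$refractory
analysis_config <- function(...) {
  defaults <- .config_defaults()
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(names(over) == ""))) {
    stop("all configuration overrides must be named")
  }
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- modifyList(defaults, over)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  need_pos <- c("band_low", "band_high", "threshold_k", "amplitude_gate",
                "active_rate_min", "responder_fraction", "bin_width",
                "kernel_width", "bad_channel_factor", "peak_width_fraction",
                "ca_threshold_k")
  for (k in need_pos) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("configuration key '%s' must be a positive number", k))
    }
  }
  if (cfg$band_low >= cfg$band_high) {
    stop("configuration key 'band_low' must be below 'band_high'")
  }
  if (!is.numeric(cfg$refractory) || cfg$refractory < 0) {
    stop("configuration key 'refractory' must be >= 0 (0 disables it)")
  }
  if (cfg$filter_order < 1) stop("configuration key 'filter_order' must be >= 1")
  cfg$filter_order <- as.integer(cfg$filter_order)
  if (cfg$peak_width_fraction >= 1) {
    stop("configuration key 'peak_width_fraction' must be in (0, 1)")
  }
  if (cfg$ca_baseline_percentile <= 0 || cfg$ca_baseline_percentile >= 1) {
    stop("configuration key 'ca_baseline_percentile' must be in (0, 1)")
  }
  cfg$polarity <- match.arg(cfg$polarity, c("neg", "abs"))
  cfg$responder_epoch <- match.arg(cfg$responder_epoch, c("pulses", "window"))
  cfg$kernel_shape <- match.arg(cfg$kernel_shape, c("boxcar", "gaussian"))
  cfg$ca_min_separation <- as.integer(cfg$ca_min_separation)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "analysis_config")
}

#' Load an analysis configuration from a YAML file
#'
#' Keys absent from the file keep their defaults; unknown keys are an error
#' (no silent typo tolerance). CLI-style overrides are applied after the
#' file. Note the Nyquist constraint (`band_high` < sampling_rate / 2) is
#' checked where the filter is applied, not at load time, because the
#' sampling rate is a property of the data.
#'
#' @param path path to a YAML file of flat `key: value` pairs, or `NULL`
#'   for pure defaults.
#' @param overrides named list applied on top of the file.
#' @return An [analysis_config()].
#' @export
load_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
  }
  vals <- modifyList(vals, as.list(overrides))
  do.call(analysis_config, vals)
}

#' Stable hash of a configuration
#'
#' MD5 over a canonical text rendering; changes if and only if some
#' configuration value changes.
#'
#' @param cfg an [analysis_config()].
#' @return 32-character hex string.
#' @export
config_hash <- function(cfg) {
  stopifnot(inherits(cfg, "analysis_config"))
  keys <- sort(names(cfg))
  txt <- paste(sprintf("%s=%s", keys,
                       vapply(cfg[keys], function(v)
                         paste(format(v, digits = 17), collapse = ","),
                         character(1))),
               collapse = "\n")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("analysis_config:\n")
  for (k in names(x)) cat(sprintf("  %-22s %s\n", k, paste(x[[k]], collapse = " ")))
  invisible(x)
}
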