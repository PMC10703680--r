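write_sidecar <- function(path, n_channels, sampling_rate = 30000,
                          uv_per_bit = 0.195, ...) {
  meta <- c(list(n_channels = n_channels, sampling_rate = sampling_rate,
                 dtype = "int16", uv_per_bit = uv_per_bit,
                 byte_order = "little", interleaved = TRUE), list(...))
  jsonlite::write_json(meta, path, auto_unbox = TRUE)
}

test_that("interleaved int16 payloads are de-interleaved and scaled to uV", {
  bin <- tempfile(); sc <- paste0(bin, ".json")
  writeBin(as.integer(c(1, 10, 2, 20, 3, 30, 4, 40)), bin, size = 2,
           endian = "little")
  write_sidecar(sc, n_channels = 2)
  s <- read_recording(bin, sc)
  expect_equal(s$n_channels, 2L)
  expect_equal(s$n_samples, 4L)
  expect_equal(s$samples[1, ], c(0.195, 0.390, 0.585, 0.780))
  expect_equal(s$samples[2, ], 0.195 * c(10, 20, 30, 40))
  expect_equal(s$duration, 4 / 30000)
})

test_that("an empty payload with a valid sidecar yields a 0-sample session", {
  bin <- tempfile(); sc <- paste0(bin, ".json")
  file.create(bin)
  write_sidecar(sc, n_channels = 4)
  s <- read_recording(bin, sc)
  expect_equal(s$n_samples, 0L)
  expect_equal(s$n_channels, 4L)
  expect_equal(s$sampling_rate, 30000)
})

test_that("malformed inputs are rejected with informative errors", {
  bin <- tempfile(); sc <- paste0(bin, ".json")
  writeBin(as.integer(1:6), bin, size = 2, endian = "little")
  write_sidecar(sc, n_channels = 4)  # 6 samples not divisible by 4
  expect_error(read_recording(bin, sc), "not divisible")
  jsonlite::write_json(list(n_channels = 2), sc, auto_unbox = TRUE)
  expect_error(read_recording(bin, sc), "missing required key")
  expect_error(read_recording(tempfile(), sc), "not found")
})

test_that("write/read round-trip is bit-exact for integer payloads", {
  withr::with_seed(11, {
    vals <- matrix(sample(-2000:2000, 3 * 50, replace = TRUE), nrow = 3)
  })
  s0 <- recording_session(vals * 0.195, 30000)
  bin <- tempfile()
  write_recording(s0, bin, uv_per_bit = 0.195)
  s1 <- read_recording(bin)
  expect_identical(s1$samples, s0$samples)
  expect_identical(s1$channel_ids, s0$channel_ids)
  # payload bytes themselves round-trip too
  bin2 <- tempfile()
  write_recording(s1, bin2, uv_per_bit = 0.195)
  expect_identical(readBin(bin, "raw", file.size(bin)),
                   readBin(bin2, "raw", file.size(bin2)))
})

test_that("config defaults match the published analysis constants", {
  cfg <- load_config(NULL)
  expect_equal(cfg$band_low, 300)
  expect_equal(cfg$band_high, 3000)
  expect_equal(cfg$filter_order, 4L)
  expect_equal(cfg$threshold_k, 5)
  expect_equal(cfg$refractory, 0.002)
  expect_equal(cfg$amplitude_gate, 40)
  expect_equal(cfg$active_rate_min, 5 / 60)
  expect_equal(cfg$responder_fraction, 0.10)
  expect_equal(cfg$bin_width, 0.001)
  expect_equal(cfg$kernel_width, 0.100)
  expect_equal(cfg$bad_channel_factor, 2)
  expect_equal(cfg$peak_width_fraction, 0.05)
  # an empty file is the same as no file
  f <- tempfile(fileext = ".yaml"); file.create(f)
  expect_equal(unclass(load_config(f)), unclass(load_config(NULL)))
})

test_that("config loading honours files and overrides, rejects unknown keys", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("threshold_k: 4.5", "amplitude_gate: 30"), f)
  cfg <- load_config(f)
  expect_equal(cfg$threshold_k, 4.5)
  expect_equal(cfg$amplitude_gate, 30)
  expect_equal(cfg$refractory, 0.002)  # untouched default
  cfg2 <- load_config(f, overrides = list(refractory = 0))
  expect_equal(cfg2$refractory, 0)     # boundary: disables gating
  writeLines("treshold_k: 4", f)       # typo must not pass silently
  expect_error(load_config(f), "unknown configuration key")
  expect_error(analysis_config(band_low = 4000, band_high = 3000), "band_low")
  # Nyquist violations surface at filter time, not at load time
  cfg3 <- analysis_config(band_high = 20000)
  s <- recording_session(matrix(rnorm(2 * 300), 2), 30000)
  expect_error(bandpass(s, high = cfg3$band_high), "Nyquist")
})

test_that("config hash changes iff a value changes", {
  h0 <- config_hash(analysis_config())
  expect_identical(h0, config_hash(analysis_config()))
  expect_false(h0 == config_hash(analysis_config(threshold_k = 5.0001)))
  expect_false(h0 == config_hash(analysis_config(seed = 2L)))
})

test_that("write_tables emits headers, microsecond times and a manifest", {
  out <- tempfile()
  cfg <- analysis_config()
  # empty spike set -> header-only table, valid manifest
  m0 <- write_tables(spikes = list(), out_dir = out, config = cfg)
  tab0 <- read.csv(file.path(out, "spikes.csv"))
  expect_equal(nrow(tab0), 0L)
  expect_equal(names(tab0), c("channel", "time_s", "amplitude_uV"))
  expect_true(file.exists(file.path(out, "manifest.json")))
  # 3 spikes on 2 channels -> 3 data rows at microsecond precision
  trains <- list(spike_train("a", c(0.1234567, 0.5), c(50, 60)),
                 spike_train("b", 1.25, 70))
  write_tables(spikes = trains, out_dir = out, config = cfg)
  tab <- read.csv(file.path(out, "spikes.csv"),
                  colClasses = c(time_s = "character"))
  expect_equal(nrow(tab), 3L)
  expect_identical(tab$time_s[1], "0.123457")
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_identical(man$config_hash, config_hash(cfg))
  expect_equal(man$config$threshold_k, 5)
})

test_that("protocol JSON round-trips", {
  p <- default_protocol()
  f <- tempfile(fileext = ".json")
  write_protocol(p, f)
  q <- read_protocol(f)
  expect_equal(q$pulse_onsets, p$pulse_onsets)
  expect_equal(q$pulse_duration, p$pulse_duration)
  expect_equal(q$baseline_window, p$baseline_window)
})

test_that("protocol invariants are enforced", {
  expect_error(stimulation_protocol(c(10, 10.2), 0.5, c(0, 10), c(10, 30)),
               "overlap")
  expect_error(stimulation_protocol(5, 0.5, c(0, 10), c(10, 30)),
               "within stimulation_window")
  expect_error(stimulation_protocol(12, 0.5, c(0, 15), c(10, 30)),
               "must not overlap")
})
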