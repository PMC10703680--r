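even_train <- function(id, n, w) {
  if (n == 0) return(spike_train(id, numeric(0)))
  spike_train(id, seq(w[1], w[2] - 1e-6, length.out = n))
}

test_that("activity boundary: exactly 5 spikes/min qualifies, one fewer does not", {
  pro <- default_protocol()
  cfg <- analysis_config(responder_epoch = "window")
  trains <- list(even_train("a", 50, c(600, 1200)),   # exactly 5 / min
                 even_train("b", 49, c(600, 1200)))
  cs <- classify_channels(trains, pro, cfg)
  expect_true(cs$active[cs$channel == "a"])
  expect_false(cs$active[cs$channel == "b"])
})

test_that("responder boundary: a 10% whole-window rate change qualifies", {
  pro <- default_protocol()
  cfg <- analysis_config(responder_epoch = "window")
  mk <- function(id, nb, ns) {
    spike_train(id, c(seq(0, 599.999, length.out = nb),
                      seq(600, 1199.999, length.out = ns)))
  }
  cs <- classify_channels(list(mk("up10", 600, 660),    # +10.0%
                               mk("up9", 600, 659),     # +9.8%
                               mk("down10", 600, 540)), # -10.0%
                          pro, cfg)
  expect_true(cs$responder[cs$channel == "up10"])
  expect_equal(cs$relative_change[cs$channel == "up10"], 0.10)
  expect_false(cs$responder[cs$channel == "up9"])
  expect_true(cs$responder[cs$channel == "down10"])  # change is two-sided
  expect_identical(cs$direction[cs$channel == "down10"], "decrease")
})

test_that("a silent baseline with stimulation spikes is a responder with NA change", {
  pro <- default_protocol()
  cs <- classify_channels(list(even_train("a", 120, c(600, 1200))), pro,
                          analysis_config())
  expect_true(cs$active)
  expect_true(cs$responder)
  expect_true(is.na(cs$relative_change))
})

test_that("pulse-epoch responder rate sees modulation the window rate dilutes", {
  pro <- default_protocol(60, 60)   # 6 pulses x 0.5 s in a 60 s window
  base <- seq(0, 59.99, length.out = 120)                   # 2 Hz baseline
  stim_bg <- seq(60, 119.99, length.out = 120)              # 2 Hz background
  in_p <- pro$pulse_onsets + 0.21    # one extra evoked spike per pulse
  tr <- spike_train("a", sort(c(base, stim_bg, in_p)))
  cs_p <- classify_channels(list(tr), pro, analysis_config())
  cs_w <- classify_channels(list(tr), pro,
                            analysis_config(responder_epoch = "window"))
  expect_true(cs_p$responder)        # pulse rate roughly doubles baseline
  expect_false(cs_w$responder)       # whole-window rate changes by only ~5%
  expect_gt(cs_p$pulse_rate, 1.5 * cs_p$baseline_rate)
})

test_that("organoid summaries use active channels and explicit sentinels", {
  pro <- default_protocol()
  cfg <- analysis_config(responder_epoch = "window")
  trains <- list(even_train("a", 1200, c(600, 1200)),  # 2 Hz, active
                 even_train("b", 3, c(600, 1200)))     # inactive
  cs <- classify_channels(trains, pro, cfg)
  s <- summarize_organoid(cs, "org1")
  expect_equal(s$n_active, 1L)
  expect_equal(s$mean_rate_stim, 2)        # means equal that channel's rates
  expect_equal(s$mean_rate_baseline, 0)
  # no active channels -> NA sentinels, not zeros
  s0 <- summarize_organoid(classify_channels(list(even_train("a", 3, c(600, 1200))),
                                             pro, cfg), "empty")
  expect_equal(s0$n_active, 0L)
  expect_true(is.na(s0$mean_rate_stim))
  expect_true(is.na(s0$percent_responding))
})

test_that("responder percentage matches the printed worked example", {
  # 235 of 315 active channels responding -> 74.6%
  mk_summary <- function(n_active, n_resp, n_inactive = 10) {
    data.frame(channel = sprintf("c%03d", seq_len(n_active + n_inactive)),
               baseline_rate = 1, stim_rate = 1.5, pulse_rate = 2,
               n_baseline = 600, n_stim = 900,
               active = rep(c(TRUE, FALSE), c(n_active, n_inactive)),
               responder = rep(c(TRUE, FALSE, FALSE),
                               c(n_resp, n_active - n_resp, n_inactive)),
               relative_change = 0.5, direction = "increase")
  }
  s <- summarize_organoid(mk_summary(315, 235), "striatal")
  expect_equal(s$percent_responding, 100 * 235 / 315)
  expect_gte(s$percent_responding, 74)
})

test_that("percent responding ignores channel order and inactive content", {
  pro <- default_protocol(60, 60)
  cfg <- analysis_config(responder_epoch = "window")
  tr1 <- even_train("a", 240, c(60, 120))    # 4 Hz stim
  tr1$times <- c(seq(0, 59.99, length.out = 120), tr1$times)  # 2 Hz baseline
  tr2 <- even_train("b", 120, c(60, 120))    # flat 2 Hz
  tr2$times <- c(seq(0, 59.99, length.out = 120), tr2$times)
  quiet <- even_train("q", 2, c(60, 120))    # inactive, arbitrary content
  s1 <- summarize_organoid(classify_channels(list(tr1, tr2, quiet), pro, cfg))
  s2 <- summarize_organoid(classify_channels(list(quiet, tr2, tr1), pro, cfg))
  expect_equal(s1$percent_responding, 50)
  expect_equal(s2$percent_responding, s1$percent_responding)
})

test_that("population trace conserves kernel mass on occupied channel-bins", {
  cfg <- analysis_config()
  # no spikes -> all zeros
  p0 <- population_event_trace(list(spike_train("a", numeric(0))), cfg)
  expect_equal(sum(p0$values), 0)
  # one spike -> unit mass
  p1 <- population_event_trace(list(spike_train("a", 0.5)), cfg)
  expect_equal(sum(p1$values), 1, tolerance = 1e-12)
  # two spikes of one channel in the same 1 ms bin count once (binarized);
  # the same bin on two channels counts twice
  p2 <- population_event_trace(list(spike_train("a", c(0.5001, 0.5004))), cfg)
  expect_equal(sum(p2$values), 1, tolerance = 1e-12)
  p3 <- population_event_trace(list(spike_train("a", 0.5001),
                                    spike_train("b", 0.5004)), cfg)
  expect_equal(sum(p3$values), 2, tolerance = 1e-12)
  # grid step is exactly the bin width
  expect_equal(unique(round(diff(p1$times), 12)), cfg$bin_width)
})

test_that("population trace equals a dense convolution oracle", {
  cfg <- analysis_config()
  withr::with_seed(8, {
    trains <- lapply(1:4, function(i)
      spike_train(paste0("c", i), sort(runif(60, 0, 2))))
  })
  p <- population_event_trace(trains, cfg, t_start = 0, t_end = 2)
  n_bins <- 2000
  counts <- numeric(n_bins)
  for (tr in trains) {
    idx <- unique(floor(tr$times / 0.001) + 1)
    counts[idx] <- counts[idx] + 1
  }
  want <- oracle_conv(counts, rep(1 / 101, 101))
  expect_equal(p$values, want, tolerance = 1e-10)
  expect_equal(sum(p$values), sum(counts), tolerance = 1e-9)
})

test_that("exact signed-rank p values match enumeration and wilcox.test", {
  # all-positive n = 7 and the W- = 3, n = 8 reference configurations
  expect_equal(paired_wilcoxon(rep(0, 7), 1:7)$p_value, 2 / 2^7)
  expect_equal(paired_wilcoxon(rep(0, 8), c(1, 2, -3, 4:8))$p_value, 10 / 256)
  # random cases, including ties in |d|
  withr::with_seed(5, {
    for (rep in 1:12) {
      n <- sample(4:10, 1)
      d <- sample(c(-6:-1, 1:6), n, replace = TRUE)
      p_pkg <- paired_wilcoxon(numeric(n), d)$p_value
      expect_equal(p_pkg, oracle_wilcoxon_p(d), tolerance = 1e-12)
      if (!any(duplicated(abs(d))) ) {
        p_ref <- suppressWarnings(
          stats::wilcox.test(d, exact = TRUE)$p.value)
        expect_equal(p_pkg, p_ref, tolerance = 1e-12)
      }
    }
  })
})

test_that("signed-rank edge cases: antisymmetry, zeros, large n", {
  # statistic at its median -> p = 1
  expect_equal(paired_wilcoxon(numeric(4), c(-2, -1, 1, 2))$p_value, 1)
  expect_warning(p0 <- paired_wilcoxon(c(1, 2, 3), c(1, 2, 3)), "zero")
  expect_equal(p0$p_value, 1)
  # zero differences are dropped before ranking
  expect_equal(paired_wilcoxon(c(0, rep(0, 7)), c(0, 1:7))$p_value, 2 / 2^7)
  # above the exact limit the normal approximation tracks wilcox.test
  withr::with_seed(6, { a <- rnorm(30); b <- a + rnorm(30, 0.4) })
  p_pkg <- paired_wilcoxon(a, b)$p_value
  p_ref <- stats::wilcox.test(b, a, paired = TRUE, exact = FALSE,
                              correct = TRUE)$p.value
  expect_equal(p_pkg, p_ref, tolerance = 1e-9)
})
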