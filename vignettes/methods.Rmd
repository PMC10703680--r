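---
title: "Methods: from raw probe voltage and fluorescence traces to circuit metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw probe voltage and fluorescence traces to circuit metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

orgephys analyzes two kinds of recordings from fused neural organoids
("assembloids") in which a ventral-midbrain compartment projects into
striatal and cortical tissue: extracellular voltage from silicon probes
during pulsed optogenetic stimulation of the midbrain compartment, and
GCaMP-like fluorescence traces from confocal imaging. This vignette is the
package's own account of the models, the parameters that matter, the
numerical choices, and what the synthetic data can and cannot show.

## 1. The electrophysiology chain

The conditioning and detection chain runs in a fixed order; the stages are
not commutative and the default path does not allow reordering.

**Channel quality control.** Each channel's standard deviation is computed
on the raw, unfiltered signal over the whole recording. Channels whose s.d.
strictly exceeds `bad_channel_factor` (default 2) times the median s.d.
across all channels are removed. The median is taken before any removal;
for an even channel count it is the mean of the two central order
statistics. QC runs before filtering because broken or high-impedance
electrodes are identified by their broadband noise, which filtering would
partially hide.

**Bandpass filter.** An order-4 Butterworth design with a 300-3000 Hz band,
applied forward and backward (`signal::filtfilt`). Zero-phase application
was chosen so that spike timestamps are not shifted by the filter's group
delay; the price is that the effective magnitude response is that of twice
the design order, which is documented here rather than hidden. The
upper band edge must sit below Nyquist; this is checked where the filter
meets data, not at configuration load time, because the sampling rate is a
property of the recording.

**Common median reference.** At every sample the across-channel median is
subtracted from every channel, removing artifacts shared across the probe
(e.g. photoelectric transients from the stimulation light). After
referencing, the across-channel median is zero at every sample — exactly so
for odd channel counts, and to rounding for even ones.

**Noise floor.** Per channel, `sigma = median(|x|) / 0.6745` on the
filtered trace — the median absolute signal rescaled so the estimator is
consistent for Gaussian noise. Because spikes are rare, the median is
essentially blind to them; on a 3-million-sample Gaussian trace the
estimate is within 1% of the true s.d. (tested).

**Spike detection.** Four stages, applied strictly in order:

1. contiguous excursions where the deviation exceeds `threshold_k * sigma`
   (default 5 s.d.);
2. one timestamp per excursion at its absolute extremum, sample-aligned
   (no sub-sample interpolation; extrema falling on the first or last
   sample are unresolvable and dropped);
3. a forward scan discarding any timestamp less than `refractory`
   (default 2 ms) after the last *accepted* one — the keep-first reading of
   a refractory rule, which a chronological scan realizes deterministically;
4. an amplitude gate: events whose extremum deviation is below
   `amplitude_gate` (default 40 uV) are discarded.

**Polarity.** Detection deviation is `-x` by default (`polarity = "neg"`).
Extracellular spikes are negative-leading, and the choice is not cosmetic
here: a zero-phase filter rings symmetrically, so a negative-leading spike
acquires a positive pre-ring. Under rectified (`"abs"`) detection that
pre-ring can cross threshold, win the refractory slot (stage 3 runs before
the gate), and then die at the gate — silently deleting the true spike.
On high-SNR synthetic recordings this costs tens of percent of recall;
with negative-polarity detection the same recordings are recovered at
greater than 99% recall and precision. Rectified detection remains
available via configuration.

**A property the rule order does not guarantee.** Raising `threshold_k`
does not always lower the spike count: a sub-gate noise excursion can claim
a refractory slot at a low threshold and vanish at a higher one, releasing
the real spike that follows it. The amplitude gate, being the final stage,
is unconditionally monotone. The tests assert exactly these two statements
(gate monotonicity on noisy traces, threshold monotonicity on isolated
events), and the detector is verified event-for-event against a literal
brute-force implementation of the four rules on random traces.

## 2. Stimulus-response classification

The pulse protocol is 500 ms light pulses every 10 s for 10 min, after a
10 min baseline. Rates are counts divided by window duration.

* **Active channel**: spike count over the stimulation window of at least
  `active_rate_min` (5 spikes/min = 0.0833 Hz) times the window duration.
  The criterion is inclusive: exactly 5 spikes/min qualifies.
* **Responder**: an active channel whose firing rate changes by at least
  `responder_fraction` (10%) from baseline, in either direction. The
  direction is recorded separately for reporting.

**Which rate the responder criterion compares** is configurable
(`responder_epoch`), and the default deserves explanation. The pulses
occupy 5% of the stimulation window (500 ms every 10 s). Any rate change
confined to pulse time is therefore diluted twenty-fold in the
whole-window mean: a doubling during pulses moves the window rate by only
~5%, below the 10% criterion. Real tissue can respond beyond the pulse
(synaptic reverberation, slow neuromodulation), which the generator
deliberately does not model — it multiplies the rate only while the light
is on, because no response-latency or adaptation kinetics are available to
parameterize anything richer. Evaluating the responder rate within the
union of pulse intervals (`responder_epoch = "pulses"`, the default) makes
the modeled effect observable; the literal whole-window reading
(`"window"`) is retained and is what the per-organoid mean rates and the
paired test consume. Both rates appear in every channel summary. The cost
of the pulse-epoch reading is a noisier null (only ~30 s of pulse time
accumulates over a 10-min stimulation), so unmodulated channels are
misclassified as responders more often at low firing rates; the organoid
percentage should be read accordingly.

**Per-organoid summary.** Mean baseline and stimulation rates are averaged
over active channels; the responder percentage is
`100 * n_responding / n_active`. With no active channels the summary
reports `NA`, never 0 — silence and "no evidence" are different things.

**Population event trace.** Each active channel's train is binarized onto
a 1 ms grid (a bin is 1 if the channel fired at least once in it), the
binary rasters are summed across channels, and the sum is convolved with a
unit-mass 100 ms kernel — a 101-bin boxcar by default (the simplest kernel
consistent with sliding-window smoothing; a Gaussian of the same support is
available). The output grid is padded by half the kernel on each side, so
total mass exactly equals the number of occupied (channel, bin) pairs; mass
conservation is asserted in the tests and would fail under same-length
truncation.

**Paired signed-rank test.** Per-organoid baseline vs stimulation rates are
compared with a two-sided Wilcoxon signed-rank test. Zero differences are
dropped; tied absolute differences get mid-ranks. For n up to 25 the p
value is exact, from the distribution of the positive-rank sum over all
2^n sign assignments (computed by shift-convolution over doubled
mid-ranks, which enumerates that set without the 2^n loop). The exact
two-sided p for n = 7 concordant pairs is 2/128 = 0.015625, and for n = 8
with a negative-rank sum of 3 it is 10/256 = 0.0390625 — the reference
values the tests pin. Above n = 25 a normal approximation with tie and
continuity corrections is used. With small n, the exact test's attainable
significance levels are coarse: at n = 8 the largest level not exceeding
0.05 is 10/256 = 3.9%, so a well-calibrated null simulation should reject
near 3.9%, not 5.0%.

## 3. Calcium transients

The package starts from extracted per-ROI traces (the source-extraction
step that produces them is a different tool's job) sampled at 65 ms per
frame for up to 6.5 min.

Per ROI: baseline is the 10th percentile of the trace (robust to sparse
positive-going events; fluorescence offsets are arbitrary, so no absolute
zero is assumed); noise is `median(|x - baseline|)/0.6745`; candidate peaks
are local maxima at least `ca_threshold_k` (3) s.d. above baseline and at
least 2 frames apart. Candidates not separated by a dip below 50% of the
smaller candidate's height are merged (the higher maximum survives). This
prominence rule is load-bearing: without it, every noise wiggle riding on
one slow suprathreshold transient counts as an event, and on default
synthetic traces the raw local-maximum rule reported roughly eight times
the true event count. On flat noisy traces the surviving false-event rate
is below 0.005 per minute (tested), an order of magnitude under the 0.05
per minute acceptance bound.

**Duration** is the width of the peak at 5% of its height above baseline
(`peak_width_fraction`), with crossings located by linear interpolation
between frames. Measuring relative to the local baseline makes the duration
exactly invariant to affine transforms of the trace (gain and offset), a
property the tests assert. Where two events overlap at the 5% level the
boundary is the inter-peak minimum — a split by definition, not censoring;
only widths clipped at the trace edges carry a `censored` flag. Two exact
geometric checks anchor the implementation: a symmetric triangular peak of
base width w has width 0.95 w at the 5% level (similar triangles, exact
under linear interpolation), and a noiseless double-exponential transient
reproduces the kernel's analytic width at 5% of peak within one frame.

On noisy traces the measured duration is biased slightly low: a 5% level
sits inside the noise band, so the crossing is found where noise first dips
below the level rather than where the mean trace does. At the default
synthetic signal-to-noise ratio (peak 5, noise 0.5) the mean measured
duration is roughly 20% below the analytic kernel width. This is a property
of the 5%-width definition on noisy data, not of the implementation, and it
cancels in between-condition comparisons made at equal noise.

**Frequency** is events per minute per ROI, with zero-event ROIs reported
as 0 (requiring the full ROI list, so silent ROIs are not silently
dropped). Group comparisons (e.g. control vs chronic vs withdrawal
conditions) use one-way fixed-effects ANOVA followed by Tukey's HSD
(`stats::aov` + `TukeyHSD`); the tests check the F = t-squared identity on
two groups, Tukey-vs-unadjusted ordering, and a 1000-replicate null
calibration of the ANOVA rejection rate.

## 4. The synthetic generators

Both generators draw all randomness from one integer seed and return the
ground truth exactly as generated.

**Ephys.** Default geometry follows the recording hardware: 64 channels as
4 shanks of 16 sites, 30 kHz sampling. Each channel carries 2 independent
units firing as homogeneous Poisson processes at 2 Hz, thinned to a 2 ms
refractory (keep-first, mirroring the detection-side convention; thinning
removes under 1% of events at these rates). On responder channels the rate
is multiplied by `rate_multiplier` while a pulse is on — a rectangular,
memoryless response model, adopted because nothing richer can be
parameterized from available information. Each spike adds a
difference-of-Gaussians biphasic template (1.5 ms support, negative-leading
trough, 3:1 trough-to-peak ratio) scaled to the unit's amplitude, drawn
once per unit from 80-150 uV; white Gaussian noise (5 uV s.d.) is added per
channel. Constructed bad channels carry no units and have noise pinned to 3
times the realized median s.d. of the good channels, so they violate the 2x
rejection rule by construction and QC can be tested exactly. What is *not*
modeled: spike waveform variability, bursting, cross-channel correlation,
drift, line noise, or stimulation artifacts — so passing recovery tests
demonstrate the pipeline's rules, not robustness to every pathology of real
recordings.

**Calcium.** Poisson event times per ROI (default 3 events/min) each add an
amplitude-scaled double-exponential transient with rise 0.2 s and decay
1.5 s — representative of a slow indicator; configuration, not a claim
about any particular dataset. Traces are sampled at 65 ms per frame, offset
by a nonnegative baseline, and corrupted with white Gaussian noise. The
analytic width of the kernel at 5% of peak is stored as the true duration.
Not modeled: photobleaching, motion, neuropil contamination, or
indicator saturation.

## 5. Problem sizes and numerical choices

The heavy study-condition checks run at sizes chosen to exercise the full
64-channel pipeline comfortably on a single CPU:

* end-to-end spike recovery: 64 channels at 8 kHz, 3 min baseline + 3 min
  stimulation (18 pulses), multiplier 2, ~90,000 true spikes; the method is
  scale-free in sampling rate provided the 3 kHz band edge sits below
  Nyquist, and recall/precision are rate-independent given the SNR;
* null calibration: 200 simulated experiments of 8 organoids x 16
  channels at the spike-train level — the signed-rank test consumes only
  rates, which the train layer fully determines, so no voltage synthesis
  is needed;
* false-event calibration: 100 flat noisy ROIs of 6.5 min.

Numerical conventions: times are seconds (sample index / sampling rate),
voltages are uV converted exactly once at read time; window membership is
half-open `[t0, t1)`; count-threshold comparisons use a 1e-9 absolute
guard so that exact boundary counts (50 spikes in 600 s at 5/min) are not
lost to floating-point division; refractory comparisons use a 1e-12 guard
for the same reason. Bandpass filtering collects temporaries after every
channel on multi-gigabyte inputs, bounding transient memory at roughly
three matrix copies.

## 6. Known limitations

* The responder criterion's whole-window reading and pulse-epoch reading
  disagree whenever responses are pulse-locked; both are computed, and the
  choice is explicit configuration (section 2).
* The 40 uV amplitude gate is measured from zero (the filtered signal's
  reference), one of two defensible readings of a gate "from the noise
  floor"; the alternative (40 uV above `threshold_k * sigma`) can be
  emulated by raising the gate.
* Exact signed-rank p values above n = 25 fall back to a normal
  approximation; at the organoid counts of interest (7-25) the test is
  always exact.
* Measured calcium durations are biased low on noisy traces (section 3);
  comparisons across conditions at equal noise are unaffected.
* The simulators are statistical, not biophysical; they validate rules and
  estimators, not robustness to real-tissue artifacts.
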