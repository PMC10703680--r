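#' Detect calcium transient events and measure width-at-5%-height duration
#'
#' Per ROI: the baseline is the 10th percentile of the trace; the noise
#' s.d. is `median(|x - baseline|) / 0.6745`; candidate peaks are local
#' maxima at least `threshold_k` s.d. above baseline, separated by at least
#' `min_separation` frames (the higher peak wins a conflict). Candidates
#' that are not separated by a dip below `merge_fraction` (default 50%) of
#' the smaller candidate's height above baseline are merged into one event
#' (the higher maximum is kept) — without this prominence rule, every noise
#' wiggle riding on a slow suprathreshold transient would count as its own
#' event. Each event's duration is the width of its peak at
#' `width_fraction` (default 5%) of its height above baseline, with
#' crossings located by linear interpolation between frames; where two
#' events overlap at that level the boundary is the inter-peak minimum
#' (a split, not censoring). Widths clipped at a trace edge are flagged
#' `censored` rather than dropped.
#'
#' Duration is invariant to affine transforms of the trace (gain and
#' offset): the measurement level scales with peak height above baseline.
#'
#' @param recording a [calcium_recording()] with >= 10 frames per ROI.
#' @param threshold_k peak threshold in s.d. multiples (default 3).
#' @param width_fraction height fraction for the duration (default 0.05).
#' @param min_separation minimum frames between peaks (default 2).
#' @param baseline_percentile baseline quantile (default 0.10).
#' @param merge_fraction dip depth (as a fraction of the smaller peak's
#'   height) required to keep two candidates as separate events
#'   (default 0.5).
#' @return data.frame of class `calcium_event_table`: `roi`, `peak_time`
#'   (s), `peak_height` (units above baseline), `duration` (s),
#'   `censored`, `condition`.
#' @export
detect_calcium_events <- function(recording, threshold_k = 3,
                                  width_fraction = 0.05,
                                  min_separation = 2L,
                                  baseline_percentile = 0.10,
                                  merge_fraction = 0.5) {
  stopifnot(inherits(recording, "calcium_recording"))
  if (recording$n_frames < 10L) stop("need at least 10 frames per ROI")
  dt <- recording$frame_interval
  out <- list()
  for (i in seq_len(recording$n_rois)) {
    x <- recording$traces[i, ]
    b <- as.numeric(quantile(x, baseline_percentile, names = FALSE))
    sigma <- median(abs(x - b)) / 0.6745
    thr <- b + threshold_k * sigma
    peaks <- .local_maxima(x, thr, min_separation)
    peaks <- .merge_shallow_peaks(x, peaks, b, merge_fraction)
    if (!length(peaks)) next
    for (k in seq_along(peaks)) {
      p <- peaks[k]
      height <- x[p] - b
      level <- b + width_fraction * height
      lo_lim <- if (k > 1L) .interpeak_min(x, peaks[k - 1L], p) else 1L
      hi_lim <- if (k < length(peaks)) .interpeak_min(x, p, peaks[k + 1L])
                else length(x)
      left <- .cross_left(x, p, level, lo_lim, at_edge = (k == 1L))
      right <- .cross_right(x, p, level, hi_lim,
                            at_edge = (k == length(peaks)))
      out[[length(out) + 1L]] <- data.frame(
        roi = recording$roi_ids[i],
        peak_time = (p - 1L) * dt,
        peak_height = height,
        duration = (right$t - left$t) * dt,
        censored = left$censored || right$censored,
        condition = recording$condition
      )
    }
  }
  tab <- if (length(out)) do.call(rbind, out) else
    data.frame(roi = character(), peak_time = numeric(),
               peak_height = numeric(), duration = numeric(),
               censored = logical(), condition = character())
  rownames(tab) <- NULL
  class(tab) <- c("calcium_event_table", "data.frame")
  tab
}

# Local maxima above thr with a minimum index separation; on conflict the
# higher peak is kept (ties: the earlier).
.local_maxima <- function(x, thr, min_sep) {
  n <- length(x)
  if (n < 3L) return(integer())
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] &
                  x[2:(n - 1L)] >= x[3:n]) + 1L
  cand <- cand[x[cand] >= thr]
  if (length(cand) < 2L || min_sep <= 1L) return(cand)
  ord <- cand[order(-x[cand], cand)]
  taken <- integer()
  for (p in ord) {
    if (!length(taken) || all(abs(taken - p) >= min_sep)) taken <- c(taken, p)
  }
  sort(taken)
}

.interpeak_min <- function(x, p1, p2) {
  p1 + which.min(x[p1:p2]) - 1L
}

# Merge candidate peaks whose inter-peak minimum stays above
# baseline + merge_fraction * (smaller height): one noisy event, keep the
# higher maximum.
.merge_shallow_peaks <- function(x, peaks, b, merge_fraction) {
  if (length(peaks) < 2L) return(peaks)
  kept <- peaks[1L]
  for (q in peaks[-1L]) {
    p <- kept[length(kept)]
    m <- .interpeak_min(x, p, q)
    h_small <- min(x[p], x[q]) - b
    if (x[m] - b > merge_fraction * h_small) {
      if (x[q] > x[p]) kept[length(kept)] <- q
    } else {
      kept <- c(kept, q)
    }
  }
  kept
}

# Walk left from peak p to the first frame at/below `level` (bounded by
# lo_lim); interpolate the crossing. Returns fractional frame index
# (1-based) and a censoring flag. Stopping at an inter-peak split boundary
# is definitional; only stopping at the trace edge censors the width.
.cross_left <- function(x, p, level, lo_lim, at_edge = TRUE) {
  i <- p
  while (i > lo_lim && x[i] > level) i <- i - 1L
  if (x[i] > level) return(list(t = as.numeric(i), censored = at_edge))
  if (i == p) return(list(t = as.numeric(p), censored = FALSE))
  # crossing between i and i+1
  frac <- (level - x[i]) / (x[i + 1L] - x[i])
  list(t = i + frac, censored = FALSE)
}

.cross_right <- function(x, p, level, hi_lim, at_edge = TRUE) {
  i <- p
  while (i < hi_lim && x[i] > level) i <- i + 1L
  if (x[i] > level) return(list(t = as.numeric(i), censored = at_edge))
  if (i == p) return(list(t = as.numeric(p), censored = FALSE))
  frac <- (x[i - 1L] - level) / (x[i - 1L] - x[i])
  list(t = i - 1L + frac, censored = FALSE)
}

#' Per-ROI calcium event frequency
#'
#' @param events a [detect_calcium_events()] table.
#' @param recording_duration seconds of recording.
#' @param roi_ids all ROI labels (so ROIs with zero events report 0).
#' @return data.frame with `roi` and `frequency` (events per minute).
#' @export
event_frequency <- function(events, recording_duration, roi_ids = NULL) {
  if (recording_duration <= 0) stop("recording_duration must be positive")
  if (is.null(roi_ids)) roi_ids <- unique(events$roi)
  counts <- table(factor(events$roi, levels = roi_ids))
  data.frame(roi = roi_ids,
             frequency = as.numeric(counts) / recording_duration * 60,
             row.names = NULL)
}

#' Compare event metrics across conditions (one-way ANOVA + Tukey)
#'
#' One-way fixed-effects ANOVA over condition groups followed by Tukey's
#' honestly-significant-difference pairwise comparisons (studentized-range
#' adjusted p values), the standard follow-up for multi-group metric
#' comparisons such as event duration or frequency across treatment
#' conditions.
#'
#' @param values_by_condition named list of numeric vectors (>= 2 groups,
#'   each >= 2 values).
#' @return list of class `group_comparison`: `F_statistic`, `anova_p`,
#'   `df`, `pairwise` (data.frame with `comparison`, `diff`, `p_adj`),
#'   `group_means`.
#' @export
compare_groups <- function(values_by_condition) {
  if (!is.list(values_by_condition) || length(values_by_condition) < 2L) {
    stop("need a named list of at least 2 groups")
  }
  if (is.null(names(values_by_condition)) ||
      any(names(values_by_condition) == "")) {
    stop("every group must be named")
  }
  sizes <- lengths(values_by_condition)
  if (any(sizes < 2L)) stop("every group needs at least 2 values")
  d <- data.frame(
    value = unlist(values_by_condition, use.names = FALSE),
    group = factor(rep(names(values_by_condition), sizes),
                   levels = names(values_by_condition))
  )
  fit <- aov(value ~ group, data = d)
  s <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  structure(
    list(F_statistic = s[["F value"]][1], anova_p = s[["Pr(>F)"]][1],
         df = c(between = s[["Df"]][1], within = s[["Df"]][2]),
         pairwise = data.frame(comparison = rownames(tk),
                               diff = tk[, "diff"],
                               p_adj = tk[, "p adj"],
                               row.names = NULL),
         group_means = vapply(values_by_condition, mean, numeric(1))),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df["between"], x$df["within"], x$F_statistic, x$anova_p))
  cat("Tukey HSD adjusted pairwise p values:\n")
  for (i in seq_len(nrow(x$pairwise))) {
    cat(sprintf("  %-20s diff = %8.4g  p_adj = %.4g\n",
                x$pairwise$comparison[i], x$pairwise$diff[i],
                x$pairwise$p_adj[i]))
  }
  invisible(x)
}
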