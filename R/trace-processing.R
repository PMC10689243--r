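#' Build a flicker stimulus schedule
#'
#' Recordings consist of trials of LED flicker stimulation: within each
#' trial the 40-Hz flicker is on for `on_s` seconds then off for `off_s`,
#' repeated for the trial duration. Dark trials carry a single `dark` epoch.
#'
#' @param n_trials number of flicker trials.
#' @param trial_s trial duration in seconds (default 85, giving 17 flicker
#'   events per trial at 3 s on / 2 s off).
#' @param on_s,off_s flicker on/off durations within a trial, seconds.
#' @param flicker_hz nominal flicker frequency (metadata only; the 40-Hz
#'   carrier is not resolved at imaging frame rates).
#' @param start_s start time of the first trial, seconds.
#' @param is_dummy logical flag marking a dummy schedule used to build the
#'   false-positive null on dark-period data.
#' @return A data.frame of class `stim_schedule` with columns `start_s`,
#'   `end_s`, `label` (`"flicker_on"` or `"dark"`); epochs are half-open
#'   `[start, end)` and non-overlapping. Attributes `flicker_hz`, `is_dummy`.
#' @export
stimulus_schedule <- function(n_trials = 3, trial_s = 85, on_s = 3, off_s = 2,
                              flicker_hz = 40, start_s = 0, is_dummy = FALSE) {
  stopifnot(n_trials >= 1, trial_s > 0, on_s > 0, off_s >= 0)
  per_trial <- floor(trial_s / (on_s + off_s))
  onsets <- as.vector(outer((seq_len(per_trial) - 1) * (on_s + off_s),
                            (seq_len(n_trials) - 1) * trial_s, `+`)) + start_s
  sched <- data.frame(start_s = onsets, end_s = onsets + on_s,
                      label = "flicker_on", stringsAsFactors = FALSE)
  sched <- sched[order(sched$start_s), , drop = FALSE]
  rownames(sched) <- NULL
  structure(sched, class = c("stim_schedule", "data.frame"),
            flicker_hz = flicker_hz, is_dummy = is_dummy)
}

#' Dummy schedule for the dark-period null
#'
#' Copies the epoch structure of a real stimulus schedule, optionally shifted
#' in time, and flags it as a dummy. Applied to dark-period activity it
#' yields the false-positive rate used to threshold visual responsivity.
#'
#' @param schedule a [stimulus_schedule()].
#' @param shift_s time shift applied to every epoch, seconds.
#' @return A `stim_schedule` with `is_dummy = TRUE`.
#' @export
dummy_schedule <- function(schedule, shift_s = 0) {
  stopifnot(inherits(schedule, "stim_schedule"))
  out <- schedule
  out$start_s <- out$start_s + shift_s
  out$end_s <- out$end_s + shift_s
  attr(out, "is_dummy") <- TRUE
  out
}

#' Zero sub-threshold delta-F/F0 values
#'
#' @param values percent delta-F/F0.
#' @param threshold_pct values strictly below this level are set to 0.
#' @return Thresholded values (idempotent).
#' @export
apply_dff_threshold <- function(values, threshold_pct = 15) {
  values[values < threshold_pct] <- 0
  values
}

#' Compute thresholded delta-F/F0 from raw fluorescence
#'
#' Background-subtracts a raw ROI trace, estimates a slowly drifting baseline
#' F0 as a running low percentile, converts to percent delta-F/F0 and zeroes
#' sub-threshold values. This is the signal-processing step shared by all
#' downstream cellular and spine activity metrics.
#'
#' @param raw numeric vector of raw ROI fluorescence (a.u. per frame).
#' @param background background ROI fluorescence, same length as `raw` (or a
#'   single constant level).
#' @param rate_hz frames per second.
#' @param drift_window_s window for the running-percentile baseline, seconds.
#' @param threshold_pct percent delta-F/F0 below which values are zeroed.
#' @param baseline_quantile percentile (as a fraction) defining F0 within the
#'   running window.
#' @param threshold_mode `"absolute"`: `threshold_pct` is percent delta-F/F0;
#'   `"relative_max"`: the floor is `threshold_pct`% of the trace maximum.
#' @return A [dff_trace()].
#' @examples
#' f <- rep(100, 400); f[200:210] <- 160
#' d <- compute_dff(f, background = 0, rate_hz = 10)
#' max(d$values)  # ~60% dFF transient
#' @export
compute_dff <- function(raw, background = 0, rate_hz,
                        drift_window_s = 30, threshold_pct = 15,
                        baseline_quantile = 0.10,
                        threshold_mode = c("absolute", "relative_max")) {
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(is.numeric(raw), length(raw) >= 2L, all(is.finite(raw)), rate_hz > 0)
  if (length(background) == 1L) background <- rep(background, length(raw))
  stopifnot(length(background) == length(raw))
  f <- raw - background
  win <- max(3L, min(length(f), as.integer(round(drift_window_s * rate_hz))))
  f0 <- running_quantile(f, win, baseline_quantile)
  if (any(f0 <= 0)) {
    stop(sprintf("baseline F0 <= 0 at frame %d (F0 = %.4g); trace rejected",
                 which(f0 <= 0)[1], min(f0)))
  }
  dff <- 100 * (f - f0) / f0
  floor_pct <- if (threshold_mode == "absolute") threshold_pct else
    threshold_pct / 100 * max(dff)
  dff <- apply_dff_threshold(dff, floor_pct)
  dff_trace(dff, rate_hz, threshold_pct = threshold_pct,
            f0_definition = list(drift_window_s = drift_window_s,
                                 baseline_quantile = baseline_quantile,
                                 threshold_mode = threshold_mode))
}

# Centered running quantile over a window of `win` frames (edge windows
# clipped). Evaluated at anchor frames every win/8 and linearly
# interpolated in between: the baseline is slow by construction, and this
# keeps the cost far below the exact per-frame rolling quantile.
running_quantile <- function(f, win, prob) {
  n <- length(f)
  half <- win %/% 2L
  step <- max(1L, win %/% 8L)
  anchors <- unique(c(seq(1L, n, by = step), n))
  q <- vapply(anchors, function(i) {
    stats::quantile(f[max(1L, i - half):min(n, i + half)], prob, names = FALSE)
  }, numeric(1))
  if (length(anchors) == 1L) return(rep(q, n))
  stats::approx(anchors, q, xout = seq_len(n), rule = 2)$y
}

# Frames (0-based start times) of a trace, seconds.
frame_times <- function(dff) (seq_along(dff$values) - 1L) / dff$rate_hz

# Trapezoidal integral of a dff trace over [t0, t1), with linear
# interpolation at the window edges so partitions add exactly.
window_integral <- function(tt, vals, t0, t1) {
  t0 <- max(t0, tt[1]); t1 <- min(t1, tt[length(tt)])
  if (t1 <= t0) return(0)
  inside <- tt > t0 & tt < t1
  xs <- c(t0, tt[inside], t1)
  ys <- stats::approx(tt, vals, xout = xs, rule = 2)$y
  trapz(xs, ys)
}

#' Activity as area under the delta-F/F0 curve per second
#'
#' The core activity metric: the trapezoidal integral of the thresholded
#' delta-F/F0 trace over a time window, divided by the window duration
#' (units %*s/s). Windows can be the full trace, the flicker-on epochs of a
#' schedule, or everything outside them (dark).
#'
#' @param dff a [dff_trace()].
#' @param schedule optional [stimulus_schedule()]; `NULL` integrates the full
#'   trace.
#' @param window `"all"`, `"visual"` (flicker-on epochs only) or `"dark"`
#'   (complement of the flicker-on epochs within the trace extent).
#' @return AUC per second (nonnegative scalar).
#' @export
activity_auc <- function(dff, schedule = NULL, window = c("all", "visual", "dark")) {
  window <- match.arg(window)
  stopifnot(inherits(dff, "dff_trace"))
  tt <- frame_times(dff)
  t_end <- tt[length(tt)]
  if (is.null(schedule) || window == "all") {
    epochs <- data.frame(start_s = 0, end_s = t_end)
  } else {
    on <- schedule[schedule$label == "flicker_on", , drop = FALSE]
    if (window == "visual") {
      epochs <- on[, c("start_s", "end_s")]
    } else {
      bounds <- sort(unique(pmin(pmax(c(0, on$start_s, on$end_s, t_end), 0), t_end)))
      gaps <- data.frame(start_s = bounds[-length(bounds)], end_s = bounds[-1])
      in_on <- vapply(seq_len(nrow(gaps)), function(i)
        any(gaps$start_s[i] >= on$start_s - 1e-12 & gaps$end_s[i] <= on$end_s + 1e-12),
        logical(1))
      epochs <- gaps[!in_on, , drop = FALSE]
    }
  }
  epochs$start_s <- pmax(epochs$start_s, 0)
  epochs$end_s <- pmin(epochs$end_s, t_end)
  epochs <- epochs[epochs$end_s > epochs$start_s, , drop = FALSE]
  if (nrow(epochs) == 0L) stop("empty integration window")
  total <- sum(vapply(seq_len(nrow(epochs)), function(i)
    window_integral(tt, dff$values, epochs$start_s[i], epochs$end_s[i]), numeric(1)))
  total / sum(epochs$end_s - epochs$start_s)
}

#' Detect calcium events in a thresholded trace
#'
#' An event is a maximal contiguous run of suprathreshold (nonzero) frames of
#' at least `min_width_frames` frames; its amplitude is the run maximum and
#' its time the run onset.
#'
#' @param dff a [dff_trace()].
#' @param min_width_frames minimum run length counted as an event (default 2,
#'   suppressing single-frame noise).
#' @return A list of class `activity_summary`: `event_times` (s, onsets,
#'   strictly increasing), `event_amplitudes` (% dFF), `frequency_hz`
#'   (events per second of trace), `auc_per_s` (full-trace AUC rate),
#'   `duration_s`.
#' @export
detect_events <- function(dff, min_width_frames = 2L) {
  stopifnot(inherits(dff, "dff_trace"))
  active <- dff$values > 0
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_width_frames
  onsets <- starts[keep]
  amps <- vapply(which(keep), function(i)
    max(dff$values[starts[i]:ends[i]]), numeric(1))
  dur <- length(dff$values) / dff$rate_hz
  structure(
    list(event_times = (onsets - 1L) / dff$rate_hz,
         event_amplitudes = amps,
         frequency_hz = length(onsets) / dur,
         auc_per_s = activity_auc(dff),
         duration_s = dur),
    class = "activity_summary"
  )
}

#' @export
print.activity_summary <- function(x, ...) {
  cat(sprintf("activity_summary: %d events in %.1f s (%.3g Hz), AUC %.3g %%.s/s\n",
              length(x$event_times), x$duration_s, x$frequency_hz, x$auc_per_s))
  invisible(x)
}

#' Normalize activity values to a baseline
#'
#' Two conventions are used for comparing post-overstimulation activity with
#' baseline: subtracting each cell's own baseline value, or dividing by the
#' mean of the baseline population.
#'
#' @param values numeric vector of activity values (e.g. AUC per second).
#' @param baseline_values baseline values; in `"subtract"` mode, per-cell
#'   (same length as `values`); in `"divide"` mode the divisor is
#'   `mean(baseline_values)`.
#' @param mode `"subtract"` or `"divide"`.
#' @return Normalized values.
#' @export
normalize_to_baseline <- function(values, baseline_values,
                                  mode = c("subtract", "divide")) {
  mode <- match.arg(mode)
  stopifnot(length(baseline_values) >= 1L)
  if (mode == "subtract") {
    stopifnot(length(values) == length(baseline_values))
    values - baseline_values
  } else {
    m <- mean(baseline_values)
    if (!is.finite(m) || m <= 0) stop("baseline mean must be > 0 for divide mode")
    values / m
  }
}

#' Classify cells by activity level against a reference distribution
#'
#' Labels transient frequencies as low / middle / high relative to quartiles
#' of a reference population (conventionally the young-adult control
#' distribution): low for values at or below Q1, middle on (Q1, Q3], high
#' above Q3.
#'
#' @param frequencies transient frequencies (Hz) to classify.
#' @param reference_frequencies reference distribution defining the quartiles.
#' @return Factor with levels `low`, `middle`, `high`; attribute `quartiles`.
#' @export
classify_activity_levels <- function(frequencies, reference_frequencies) {
  stopifnot(length(frequencies) >= 1L, length(reference_frequencies) >= 1L)
  q <- stats::quantile(reference_frequencies, c(0.25, 0.75), names = FALSE)
  labels <- ifelse(frequencies <= q[1], "low",
                   ifelse(frequencies <= q[2], "middle", "high"))
  structure(factor(labels, levels = c("low", "middle", "high")),
            quartiles = c(Q1 = q[1], Q3 = q[2]))
}
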