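#' Detect miniature synaptic events in a voltage trace
#'
#' Threshold detector for miniature postsynaptic potentials recorded under
#' action-potential blockade. The noise RMS is estimated robustly (MAD of
#' the baseline-subtracted trace); deflections of the condition-appropriate
#' sign strictly exceeding `threshold_sigma` times that RMS are events.
#' The trace is pre-smoothed with a short moving average before
#' thresholding; amplitudes are read from the unsmoothed trace. Crossings
#' shorter than `min_width_ms` are discarded and events closer than
#' `merge_ms` are merged.
#'
#' @param values membrane potential, mV per sample.
#' @param rate_hz sampling rate (recordings are digitized at 20 kHz).
#' @param polarity `"excitatory"` (depolarizing events, mEPSP at -70 mV) or
#'   `"inhibitory"` (the deflection sign recorded at +10 mV); determined by
#'   the holding condition, never inferred from the data.
#' @param threshold_sigma detection threshold in multiples of the noise RMS
#'   (default 2.5). The convention is strictly greater: a deflection at
#'   exactly the threshold is not an event.
#' @param min_width_ms minimum suprathreshold duration (default 1 ms).
#' @param merge_ms events with onsets closer than this to the previous
#'   event's end are merged (default 2 ms).
#' @param smooth_ms moving-average width applied before thresholding
#'   (default 0.5 ms).
#' @param direction_sign internal override of the deflection sign (+1/-1);
#'   by default +1 for excitatory and -1 for inhibitory.
#' @return A list of class `mini_train`: `event_times` (s, at peaks),
#'   `amplitudes` (mV, peak deflection from the median baseline),
#'   `event_auc` (mV*s deflection area per event), `frequency_hz`,
#'   `rms_noise`, `duration_s`, `polarity`.
#' @export
detect_minis <- function(values, rate_hz = 20000,
                         polarity = c("excitatory", "inhibitory"),
                         threshold_sigma = 2.5, min_width_ms = 1,
                         merge_ms = 2, smooth_ms = 0.5,
                         direction_sign = NULL) {
  polarity <- match.arg(polarity)
  stopifnot(all(is.finite(values)), rate_hz > 0)
  duration_s <- length(values) / rate_hz
  if (duration_s < 1) stop("trace must be at least 1 s long")
  sgn <- if (!is.null(direction_sign)) sign(direction_sign) else
    if (polarity == "excitatory") 1 else -1
  defl <- sgn * (values - stats::median(values))
  rms <- stats::mad(defl)
  if (rms == 0) stop("noise RMS is zero; cannot set a detection threshold")
  k <- max(1L, as.integer(round(smooth_ms / 1000 * rate_hz)))
  smoothed <- if (k > 1L)
    stats::filter(defl, rep(1 / k, k), sides = 2) else defl
  smoothed[is.na(smoothed)] <- 0
  above <- as.vector(smoothed) > threshold_sigma * rms
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  min_w <- max(1L, as.integer(round(min_width_ms / 1000 * rate_hz)))
  keep <- which(r$values & r$lengths >= min_w)
  if (length(keep) > 1L) {
    gap <- max(1L, as.integer(round(merge_ms / 1000 * rate_hz)))
    merged_s <- starts[keep[1]]; merged_e <- ends[keep[1]]
    for (k2 in keep[-1]) {
      if (starts[k2] - merged_e[length(merged_e)] <= gap) {
        merged_e[length(merged_e)] <- ends[k2]
      } else {
        merged_s <- c(merged_s, starts[k2]); merged_e <- c(merged_e, ends[k2])
      }
    }
  } else {
    merged_s <- starts[keep]; merged_e <- ends[keep]
  }
  peak_idx <- amps <- aucs <- numeric(length(merged_s))
  for (i in seq_along(merged_s)) {
    seg <- merged_s[i]:merged_e[i]
    peak_idx[i] <- seg[which.max(defl[seg])]
    amps[i] <- max(defl[seg])
    aucs[i] <- sum(pmax(defl[seg], 0)) / rate_hz
  }
  structure(
    list(event_times = (peak_idx - 1) / rate_hz, amplitudes = amps,
         event_auc = aucs,
         frequency_hz = length(merged_s) / duration_s,
         rms_noise = rms, duration_s = duration_s, polarity = polarity),
    class = "mini_train"
  )
}

#' Build a mini train from pre-extracted events
#'
#' @param event_times event times in seconds (strictly increasing).
#' @param amplitudes event amplitudes in mV (> 0).
#' @param duration_s recording duration, seconds.
#' @param polarity `"excitatory"` or `"inhibitory"`.
#' @return A `mini_train`.
#' @export
mini_train <- function(event_times, amplitudes, duration_s,
                       polarity = c("excitatory", "inhibitory")) {
  polarity <- match.arg(polarity)
  stopifnot(length(event_times) == length(amplitudes),
            all(amplitudes > 0), duration_s > 0,
            !is.unsorted(event_times, strictly = TRUE))
  structure(
    list(event_times = event_times, amplitudes = amplitudes,
         event_auc = NULL, frequency_hz = length(event_times) / duration_s,
         rms_noise = NA_real_, duration_s = duration_s, polarity = polarity),
    class = "mini_train"
  )
}

#' @export
print.mini_train <- function(x, ...) {
  cat(sprintf("mini_train (%s): %d events in %.1f s (%.3g Hz), mean amp %.3g mV\n",
              x$polarity, length(x$event_times), x$duration_s, x$frequency_hz,
              mean(x$amplitudes)))
  invisible(x)
}

#' Functional synaptic excitation-inhibition ratio
#'
#' The primary estimator is the amplitude-frequency product quotient
#' \deqn{E{:}I = (mEPSP_{amp} \times mEPSP_{freq}) /
#'       (mIPSP_{amp} \times mIPSP_{freq}).}
#' An AUC-based variant divides the summed excitatory event area per second
#' by the inhibitory one (available only for trains carrying event areas).
#'
#' @param epsp,ipsp `mini_train` objects, or lists with `amp` (mV) and
#'   `freq` (Hz) elements.
#' @param estimator `"product"` (amplitude x frequency, default) or `"auc"`.
#' @return A list of class `ei_ratio`: `value` plus the component echo
#'   (`epsp_amp`, `epsp_freq`, `ipsp_amp`, `ipsp_freq`).
#' @examples
#' ei_ratio(list(amp = 0.5, freq = 2), list(amp = 1, freq = 1))$value  # 1
#' @export
ei_ratio <- function(epsp, ipsp, estimator = c("product", "auc")) {
  estimator <- match.arg(estimator)
  comp <- function(x) {
    if (inherits(x, "mini_train"))
      list(amp = mean(x$amplitudes), freq = x$frequency_hz,
           auc_rate = if (!is.null(x$event_auc)) sum(x$event_auc) / x$duration_s else NULL)
    else list(amp = x$amp, freq = x$freq, auc_rate = x$auc_rate)
  }
  e <- comp(epsp); i <- comp(ipsp)
  if (estimator == "product") {
    stopifnot(e$amp > 0, e$freq > 0, i$amp > 0, i$freq > 0)
    value <- (e$amp * e$freq) / (i$amp * i$freq)
  } else {
    if (is.null(e$auc_rate) || is.null(i$auc_rate))
      stop("auc estimator requires event areas (detect_minis output)")
    stopifnot(i$auc_rate > 0)
    value <- e$auc_rate / i$auc_rate
  }
  structure(list(value = value, estimator = estimator,
                 epsp_amp = e$amp, epsp_freq = e$freq,
                 ipsp_amp = i$amp, ipsp_freq = i$freq),
            class = "ei_ratio")
}

#' @export
print.ei_ratio <- function(x, ...) {
  cat(sprintf("E:I ratio = %.4g [%s] (E: %.3g mV x %.3g Hz; I: %.3g mV x %.3g Hz)\n",
              x$value, x$estimator, x$epsp_amp, x$epsp_freq,
              x$ipsp_amp, x$ipsp_freq))
  invisible(x)
}

#' Inter-event intervals of a mini train
#'
#' @param train a `mini_train` with at least 2 events.
#' @return A list: `iei` (successive differences, s), `mean`, `median`,
#'   `ecdf` (a [stats::ecdf()] for cumulative-distribution export).
#' @export
iei_distribution <- function(train) {
  stopifnot(inherits(train, "mini_train"))
  if (length(train$event_times) < 2L) stop("need at least 2 events for IEIs")
  iei <- diff(train$event_times)
  list(iei = iei, mean = mean(iei), median = stats::median(iei),
       ecdf = stats::ecdf(iei))
}
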