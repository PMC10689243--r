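#' Fit the dendrite scaling coefficient for spine signal extraction
#'
#' Spine ROIs contain a global dendritic component (back-propagating
#' activity) in addition to spine-local signal. The scaling coefficient
#' kappa is the robust (Theil-Sen) slope of the spine trace on the dendrite
#' trace, restricted to frames where the dendrite is active, so spine-only
#' events do not bias the fit. Kappa is clipped at zero.
#'
#' @param spine,dendrite [dff_trace()] objects (or numeric vectors) of equal
#'   length.
#' @param active_min dendrite values above this count as active frames
#'   (default 0: any suprathreshold frame of a thresholded trace).
#' @param max_frames cap on active frames entering the pairwise-slope median;
#'   above it frames are subsampled evenly (deterministic).
#' @return kappa (scalar >= 0). If the dendrite is never active, 0 with a
#'   warning.
#' @export
fit_dendrite_scaling <- function(spine, dendrite, active_min = 0, max_frames = 400L) {
  s <- if (inherits(spine, "dff_trace")) spine$values else as.numeric(spine)
  d <- if (inherits(dendrite, "dff_trace")) dendrite$values else as.numeric(dendrite)
  stopifnot(length(s) == length(d))
  idx <- which(d > active_min)
  if (length(idx) < 2L) {
    warning("dendrite never active; kappa set to 0")
    return(0)
  }
  if (length(idx) > max_frames) {
    idx <- idx[unique(round(seq(1L, length(idx), length.out = max_frames)))]
  }
  x <- d[idx]; y <- s[idx]
  pairs <- utils::combn(length(x), 2L)
  dx <- x[pairs[2L, ]] - x[pairs[1L, ]]
  dy <- y[pairs[2L, ]] - y[pairs[1L, ]]
  ok <- abs(dx) > .Machine$double.eps
  if (!any(ok)) {
    warning("dendrite active frames have no spread; kappa set to 0")
    return(0)
  }
  max(stats::median(dy[ok] / dx[ok]), 0)
}

#' Remove the scaled dendritic component from a spine trace
#'
#' The corrected spine signal is `max(spine - kappa * dendrite, 0)`,
#' re-thresholded at the trace threshold, so that it is pointwise between 0
#' and the raw spine trace.
#'
#' @param spine,dendrite [dff_trace()] objects of equal length and rate.
#' @param kappa dendrite scaling coefficient; fitted via
#'   [fit_dendrite_scaling()] when `NULL`.
#' @return The corrected spine [dff_trace()], with attribute `kappa`.
#' @export
subtract_dendrite <- function(spine, dendrite, kappa = NULL) {
  stopifnot(inherits(spine, "dff_trace"), inherits(dendrite, "dff_trace"),
            length(spine$values) == length(dendrite$values),
            isTRUE(all.equal(spine$rate_hz, dendrite$rate_hz)))
  if (is.null(kappa)) kappa <- fit_dendrite_scaling(spine, dendrite)
  stopifnot(kappa >= 0)
  corrected <- pmax(spine$values - kappa * dendrite$values, 0)
  corrected <- apply_dff_threshold(corrected, spine$threshold_pct)
  out <- dff_trace(corrected, spine$rate_hz, threshold_pct = spine$threshold_pct,
                   f0_definition = spine$f0_definition)
  attr(out, "kappa") <- kappa
  out
}

#' Fraction of stimulus events with a time-locked response
#'
#' For every flicker-on epoch of a schedule, asks whether at least one event
#' onset falls inside the response window `[epoch start, epoch end +
#' response_window_s)`.
#'
#' @param dff a (dendrite-corrected) [dff_trace()].
#' @param schedule a [stimulus_schedule()] with at least one flicker-on epoch.
#' @param response_window_s extension of the response window past stimulus
#'   offset, seconds.
#' @param min_width_frames passed to [detect_events()].
#' @return Fraction in `[0, 1]` of stimulus events with a time-locked
#'   response.
#' @export
timelocked_fraction <- function(dff, schedule, response_window_s = 0.5,
                                min_width_frames = 2L) {
  stopifnot(inherits(schedule, "stim_schedule"))
  on <- schedule[schedule$label == "flicker_on", , drop = FALSE]
  if (nrow(on) == 0L) stop("schedule has no flicker-on epochs")
  ev <- detect_events(dff, min_width_frames)$event_times
  hit <- vapply(seq_len(nrow(on)), function(i)
    any(ev >= on$start_s[i] & ev < on$end_s[i] + response_window_s), logical(1))
  mean(hit)
}

#' Classify spines as visually responsive against a dummy-stimulus null
#'
#' Each spine's time-locked fraction under the real stimulus is compared with
#' a null distribution of false-positive fractions obtained by aligning the
#' same spines' dark-period activity to a dummy schedule. A spine is labeled
#' visual when its fraction exceeds both the 80th percentile of the null
#' fractions and a fixed floor (responses on more than 20% of stimulus
#' events); all others are nonvisual.
#'
#' @param corrected list of dendrite-corrected [dff_trace()] (one per spine).
#' @param schedule the real [stimulus_schedule()].
#' @param dark list of [dff_trace()] of the same spines recorded in the dark.
#' @param dummy a [dummy_schedule()] applied to the dark traces.
#' @param null_percentile percentile of the null false-positive fractions
#'   used as threshold (default 0.80).
#' @param min_fraction fixed floor on the time-locked fraction (default 0.20).
#' @param response_window_s see [timelocked_fraction()].
#' @return A data.frame, one row per spine: `timelocked_fraction`,
#'   `null_fraction`, `null_threshold`, `min_fraction`, `label`
#'   (`"visual"`/`"nonvisual"`).
#' @export
classify_responsivity <- function(corrected, schedule, dark, dummy,
                                  null_percentile = 0.80, min_fraction = 0.20,
                                  response_window_s = 0.5) {
  if (inherits(corrected, "dff_trace")) corrected <- list(corrected)
  if (inherits(dark, "dff_trace")) dark <- list(dark)
  stopifnot(length(corrected) == length(dark), length(corrected) >= 1L)
  frac <- vapply(corrected, timelocked_fraction, numeric(1),
                 schedule = schedule, response_window_s = response_window_s)
  null_frac <- vapply(dark, timelocked_fraction, numeric(1),
                      schedule = dummy, response_window_s = response_window_s)
  thr <- stats::quantile(null_frac, null_percentile, names = FALSE)
  cutoff <- pmax(thr, min_fraction)
  data.frame(
    spine = seq_along(corrected),
    timelocked_fraction = frac,
    null_fraction = null_frac,
    null_threshold = thr,
    min_fraction = min_fraction,
    label = ifelse(frac > cutoff, "visual", "nonvisual"),
    stringsAsFactors = FALSE
  )
}

#' Spatial clustering of spine function along a branch
#'
#' For each anchor spine on a branch and each positional offset n, records
#' whether the spine n positions away (both directions, where defined)
#' matches the anchor's visual/nonvisual label (match = 1, non-match = 0),
#' and averages per offset. A null distribution is built by shuffling the
#' labels along the branch.
#'
#' @param labels ordered character/factor vector of per-spine labels along
#'   one branch (length >= 2).
#' @param max_offset largest positional offset (default `length(labels) - 1`).
#' @param n_shuffles number of label shuffles for the null.
#' @param seed RNG seed for the shuffles.
#' @return A list of class `clustering_curve`: `offset`, `match_prob`
#'   (observed mean match probability per offset), `null_match` (n_shuffles x
#'   n_offsets matrix), `null_mean`, and `p_value` per offset (two-sided
#'   rank of the observed value within the shuffle distribution).
#' @export
clustering_probability <- function(labels, max_offset = length(labels) - 1L,
                                   n_shuffles = 1000L, seed = 1L) {
  n <- length(labels)
  if (n < 2L) stop("branch must carry at least 2 spines")
  max_offset <- min(max_offset, n - 1L)
  labels <- as.character(labels)
  match_curve <- function(lab) {
    vapply(seq_len(max_offset), function(k) {
      mean(lab[seq_len(n - k)] == lab[seq_len(n - k) + k])
    }, numeric(1))
  }
  observed <- match_curve(labels)
  set.seed(seed)
  null_match <- vapply(seq_len(n_shuffles),
                       function(i) match_curve(sample(labels)),
                       numeric(max_offset))
  # keep shuffles in rows for any max_offset (vapply drops to a vector at 1)
  null_match <- t(matrix(null_match, nrow = max_offset))
  p <- vapply(seq_len(max_offset), function(k) {
    lo <- mean(null_match[, k] <= observed[k])
    hi <- mean(null_match[, k] >= observed[k])
    min(1, 2 * min(lo, hi))
  }, numeric(1))
  structure(
    list(offset = seq_len(max_offset), match_prob = observed,
         null_match = null_match, null_mean = colMeans(null_match),
         p_value = p, n_shuffles = n_shuffles),
    class = "clustering_curve"
  )
}

#' @export
print.clustering_curve <- function(x, ...) {
  cat(sprintf("clustering_curve (%d shuffles)\n", x$n_shuffles))
  print(data.frame(offset = x$offset, match_prob = x$match_prob,
                   null_mean = x$null_mean, p = x$p_value), row.names = FALSE)
  invisible(x)
}
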