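#' Session metrics for the rodent continuous performance task
#'
#' From per-session outcome counts: hit rate `HR = hits / (hits + misses)`,
#' false-alarm rate `FAR = mistakes / (mistakes + correct_rejections)` and
#' `performance = HR - FAR`. Correction trials are assumed already excluded
#' from the counts.
#'
#' @param hits,misses,mistakes,correct_rejections nonnegative counts,
#'   scalars or equal-length vectors (one element per session).
#' @return A data.frame: `hits`, `misses`, `mistakes`, `correct_rejections`,
#'   `hr`, `far`, `performance`. A zero denominator yields `NA` for the
#'   affected metric with a warning.
#' @examples
#' session_metrics(30, 10, 20, 60)  # HR 0.75, FAR 0.25, performance 0.5
#' @export
session_metrics <- function(hits, misses, mistakes, correct_rejections) {
  counts <- cbind(hits, misses, mistakes, correct_rejections)
  stopifnot(all(counts >= 0))
  hr_den <- counts[, 1] + counts[, 2]
  far_den <- counts[, 3] + counts[, 4]
  if (any(hr_den == 0) || any(far_den == 0))
    warning("zero denominator; affected metrics are NA")
  hr <- ifelse(hr_den > 0, counts[, 1] / hr_den, NA_real_)
  far <- ifelse(far_den > 0, counts[, 3] / far_den, NA_real_)
  data.frame(hits = counts[, 1], misses = counts[, 2],
             mistakes = counts[, 3], correct_rejections = counts[, 4],
             hr = hr, far = far, performance = hr - far)
}

#' Learning rate across task sessions
#'
#' The slope of an ordinary least-squares fit of session performance
#' (HR - FAR) on the 1-based session index. Sessions with undefined
#' performance are dropped from the fit and counted.
#'
#' @param performance per-session performance values, in session order, or a
#'   [session_metrics()] data.frame.
#' @param sessions session indices (default `1:length`).
#' @return A list of class `learning_rate`: `slope` (performance units per
#'   session), `intercept`, `r_squared`, `n_sessions`, `n_dropped`, `fit`
#'   (the `lm` object).
#' @export
learning_rate <- function(performance, sessions = NULL) {
  if (is.data.frame(performance)) performance <- performance$performance
  if (is.null(sessions)) sessions <- seq_along(performance)
  stopifnot(length(sessions) == length(performance))
  ok <- is.finite(performance)
  n_dropped <- sum(!ok)
  if (sum(ok) < 2L) stop("need at least 2 sessions with defined performance")
  if (length(unique(sessions[ok])) < 2L) stop("need at least 2 distinct sessions")
  fit <- stats::lm(performance[ok] ~ sessions[ok])
  ss_tot <- sum((performance[ok] - mean(performance[ok]))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2,
         n_sessions = sum(ok), n_dropped = n_dropped, fit = fit),
    class = "learning_rate"
  )
}

#' @export
print.learning_rate <- function(x, ...) {
  cat(sprintf("learning_rate: slope = %+.4g per session (intercept %.4g, R2 = %.3f, n = %d%s)\n",
              x$slope, x$intercept, x$r_squared, x$n_sessions,
              if (x$n_dropped) sprintf(", %d dropped", x$n_dropped) else ""))
  invisible(x)
}
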