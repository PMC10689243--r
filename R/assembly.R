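#' Pairwise calcium correlations in a population recording
#'
#' Pearson correlation (with its two-sided p-value) between every pair of
#' thresholded calcium traces, optionally restricted to the frames inside
#' the flicker-on epochs of a schedule (or their complement).
#'
#' @param traces numeric matrix, frames x neurons (columns named by neuron
#'   id), or a list of [dff_trace()] of equal length/rate.
#' @param rate_hz frames per second; required when `traces` is a bare matrix
#'   and a schedule window is used.
#' @param schedule optional [stimulus_schedule()] restricting the frames.
#' @param window `"all"`, `"visual"` or `"dark"`.
#' @return A list of class `pair_correlations`: `r` and `p` symmetric
#'   matrices (diagonal `NA`), `n_frames`. Pairs involving a zero-variance
#'   trace are `NA` in both matrices.
#' @export
pairwise_correlations <- function(traces, rate_hz = NULL, schedule = NULL,
                                  window = c("all", "visual", "dark")) {
  window <- match.arg(window)
  if (is.list(traces) && !is.matrix(traces)) {
    stopifnot(all(vapply(traces, inherits, logical(1), "dff_trace")))
    rate_hz <- traces[[1]]$rate_hz
    mat <- do.call(cbind, lapply(traces, `[[`, "values"))
    if (!is.null(names(traces))) colnames(mat) <- names(traces)
  } else {
    mat <- as.matrix(traces)
  }
  n <- ncol(mat)
  if (n < 2L) stop("need at least 2 neurons")
  if (!is.null(schedule) && window != "all") {
    stopifnot(!is.null(rate_hz))
    tt <- (seq_len(nrow(mat)) - 1L) / rate_hz
    on <- schedule[schedule$label == "flicker_on", , drop = FALSE]
    in_on <- Reduce(`|`, lapply(seq_len(nrow(on)), function(i)
      tt >= on$start_s[i] & tt < on$end_s[i]))
    keep <- if (window == "visual") in_on else !in_on
    if (!any(keep)) stop("empty correlation window")
    mat <- mat[keep, , drop = FALSE]
  }
  r <- matrix(NA_real_, n, n, dimnames = list(colnames(mat), colnames(mat)))
  p <- r
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      if (stats::sd(mat[, i]) == 0 || stats::sd(mat[, j]) == 0) next
      ct <- stats::cor.test(mat[, i], mat[, j], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  structure(list(r = r, p = p, n_frames = nrow(mat)),
            class = "pair_correlations")
}

#' Per-neuron assembly association strength
#'
#' A pair of neurons counts as correlated when its Pearson coefficient is
#' positive and significant. For each excitatory neuron the mean qualifying
#' correlation with excitatory partners (E-E) and with inhibitory partners
#' (E-I) is reported; for each inhibitory neuron, the I-I mean. Neurons with
#' no qualifying partner in a channel are `NA` (undefined), never 0.
#'
#' @param pc a [pairwise_correlations()] result.
#' @param classes character vector (`"excitatory"`/`"inhibitory"`) per
#'   neuron, in column order.
#' @param alpha per-pair significance level (two-sided, uncorrected by
#'   default, matching the analysis convention).
#' @param p_adjust optional multiple-testing correction method passed to
#'   [stats::p.adjust()] over the upper-triangle p-values (e.g. `"BH"`);
#'   `"none"` (default) leaves them uncorrected.
#' @return A data.frame, one row per neuron: `neuron`, `class`, `ee`, `ei`,
#'   `ii` (channel means; `NA` where undefined or not applicable), and
#'   qualifying-pair counts `n_ee`, `n_ei`, `n_ii`.
#' @export
assembly_strength <- function(pc, classes, alpha = 0.05, p_adjust = "none") {
  stopifnot(inherits(pc, "pair_correlations"))
  n <- ncol(pc$r)
  stopifnot(length(classes) == n, all(classes %in% c("excitatory", "inhibitory")))
  p <- pc$p
  if (p_adjust != "none") {
    ut <- upper.tri(p)
    p[ut] <- stats::p.adjust(p[ut], method = p_adjust)
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  qualifies <- !is.na(pc$r) & pc$r > 0 & !is.na(p) & p < alpha
  chan_mean <- function(i, partner_class) {
    sel <- qualifies[i, ] & classes == partner_class
    sel[i] <- FALSE
    if (!any(sel)) c(NA_real_, 0) else c(mean(pc$r[i, sel]), sum(sel))
  }
  out <- data.frame(neuron = if (!is.null(colnames(pc$r))) colnames(pc$r) else
    as.character(seq_len(n)), class = classes, stringsAsFactors = FALSE)
  ee <- t(vapply(seq_len(n), chan_mean, numeric(2), partner_class = "excitatory"))
  ii <- t(vapply(seq_len(n), chan_mean, numeric(2), partner_class = "inhibitory"))
  exc <- classes == "excitatory"
  out$ee <- ifelse(exc, ee[, 1], NA_real_)
  out$n_ee <- ifelse(exc, ee[, 2], NA_real_)
  out$ei <- ifelse(exc, ii[, 1], NA_real_)
  out$n_ei <- ifelse(exc, ii[, 2], NA_real_)
  out$ii <- ifelse(!exc, ii[, 1], NA_real_)
  out$n_ii <- ifelse(!exc, ii[, 2], NA_real_)
  out
}

#' Normalize assembly strengths to a baseline session
#'
#' Post-overstimulation association strengths divided by the matched
#' baseline values, per neuron and channel. Undefined values propagate; a
#' zero baseline yields `NA` with a warning, never infinity.
#'
#' @param baseline,poststim [assembly_strength()] tables with matching
#'   `neuron` ids.
#' @return A data.frame: `neuron`, `class`, `ee_ratio`, `ei_ratio`,
#'   `ii_ratio`.
#' @export
normalize_session_change <- function(baseline, poststim) {
  stopifnot(setequal(baseline$neuron, poststim$neuron))
  post <- poststim[match(baseline$neuron, poststim$neuron), ]
  ratio <- function(a, b) {
    bad <- !is.na(b) & b == 0
    if (any(bad)) warning("zero baseline value; ratio undefined")
    ifelse(is.na(a) | is.na(b) | b == 0, NA_real_, a / b)
  }
  data.frame(neuron = baseline$neuron, class = baseline$class,
             ee_ratio = ratio(post$ee, baseline$ee),
             ei_ratio = ratio(post$ei, baseline$ei),
             ii_ratio = ratio(post$ii, baseline$ii),
             stringsAsFactors = FALSE)
}
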