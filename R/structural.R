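#' Detect peaks in a 1-D fluorescence intensity profile
#'
#' Profiles drawn along dendrites are normalized to the background level;
#' maximal runs exceeding `1 + rel_threshold` times background are peaks.
#' Peak width - the spine-size proxy - is the spatial extent of the profile
#' at the threshold crossing (linearly interpolated), the center is the
#' position of the run maximum, the height is the maximum in background
#' units, and density is the peak count divided by the profile length.
#'
#' @param positions positions along the dendrite, micrometres, strictly
#'   increasing (>= 3 samples).
#' @param intensity fluorescence intensity, a.u., same length.
#' @param background_level background fluorescence, a.u. (> 0).
#' @param rel_threshold fractional threshold above background (default 0.15:
#'   peaks exceed 115% of background).
#' @param min_width_um minimum peak width retained (default 0.1 um),
#'   suppressing single-sample noise crossings.
#' @return A list of class `peak_set`: data.frame `peaks` (`center_um`,
#'   `width_um`, `height`, in background units), `density_per_um`,
#'   `length_um`, `rel_threshold`.
#' @examples
#' x <- seq(0, 10, by = 0.02)
#' y <- 100 * (1 + 0.8 * exp(-(x - 5)^2 / (2 * 0.3^2)))
#' profile_peaks(x, y, background_level = 100)
#' @export
profile_peaks <- function(positions, intensity, background_level,
                          rel_threshold = 0.15, min_width_um = 0.1) {
  stopifnot(length(positions) >= 3L, length(intensity) == length(positions),
            !is.unsorted(positions, strictly = TRUE),
            background_level > 0, rel_threshold > 0)
  z <- intensity / background_level
  thr <- 1 + rel_threshold
  above <- z > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  cross <- function(i1, i2) {
    # linear interpolation of the position where z crosses thr between samples
    positions[i1] + (thr - z[i1]) * (positions[i2] - positions[i1]) / (z[i2] - z[i1])
  }
  rows <- lapply(keep, function(k) {
    s <- starts[k]; e <- ends[k]
    left <- if (s > 1L) cross(s - 1L, s) else positions[s]
    right <- if (e < length(z)) cross(e + 1L, e) else positions[e]
    pk <- s - 1L + which.max(z[s:e])
    data.frame(center_um = positions[pk], width_um = right - left, height = z[pk])
  })
  peaks <- if (length(rows)) do.call(rbind, rows) else
    data.frame(center_um = numeric(0), width_um = numeric(0), height = numeric(0))
  peaks <- peaks[peaks$width_um >= min_width_um, , drop = FALSE]
  rownames(peaks) <- NULL
  len <- positions[length(positions)] - positions[1]
  structure(list(peaks = peaks, density_per_um = nrow(peaks) / len,
                 length_um = len, rel_threshold = rel_threshold),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set: %d peaks on %.1f um (density %.3g /um)\n",
              nrow(x$peaks), x$length_um, x$density_per_um))
  if (nrow(x$peaks)) print(x$peaks, row.names = FALSE)
  invisible(x)
}

#' Per-spine colocalized protein level
#'
#' Matches synaptic-protein peaks to spine peaks by center distance and
#' reports, per spine, the ratio of the matched protein peak height to the
#' spine width. Spines without a protein peak within tolerance are reported
#' with `NA`.
#'
#' @param protein,spines [profile_peaks()] results from the protein and
#'   spine channels of the same dendrite (same spatial frame).
#' @param tolerance_um maximum center distance counted as colocalized.
#' @return A data.frame, one row per spine peak: `center_um`, `width_um`,
#'   `protein_height`, `ratio` (= protein height / spine width, `NA` if
#'   unmatched).
#' @export
colocalized_ratio <- function(protein, spines, tolerance_um = 0.25) {
  stopifnot(inherits(protein, "peak_set"), inherits(spines, "peak_set"))
  sp <- spines$peaks
  pr <- protein$peaks
  out <- data.frame(center_um = sp$center_um, width_um = sp$width_um,
                    protein_height = NA_real_, ratio = NA_real_)
  if (nrow(sp) == 0L || nrow(pr) == 0L) return(out)
  for (i in seq_len(nrow(sp))) {
    d <- abs(pr$center_um - sp$center_um[i])
    j <- which.min(d)
    if (d[j] <= tolerance_um) {
      out$protein_height[i] <- pr$height[j]
      out$ratio[i] <- pr$height[j] / sp$width_um[i]
    }
  }
  out
}

# Two-sample Kolmogorov-Smirnov distance: sup of |Fx - Fy| over the pooled
# sample points. Values closer than a small relative tolerance are treated
# as ties so that exactly scaled copies of a sample are at distance 0 in
# spite of floating-point rounding.
ks_distance <- function(x, y, tol = 1e-9) {
  sx <- sort(x)
  sy <- sort(y)
  pooled <- sort(c(sx, sy))
  tol_abs <- tol * max(abs(pooled), 1)
  Fx <- findInterval(pooled + tol_abs, sx) / length(sx)
  Fy <- findInterval(pooled + tol_abs, sy) / length(sy)
  max(abs(Fx - Fy))
}

#' Fit a multiplicative synaptic scaling factor
#'
#' Tests whether an overstimulated population of synaptic measures is a
#' multiplicatively scaled version of its control population. A seed factor
#' is taken as the ratio of medians, then a grid of candidate factors around
#' the seed is searched for the one minimizing the two-sample
#' Kolmogorov-Smirnov distance between the scaled control distribution and
#' the overstimulated sample. Ties resolve to the smallest factor.
#'
#' @param control_values,stim_values positive numeric samples (e.g. spine
#'   widths) from control and overstimulated conditions.
#' @param grid_span factors searched are `seed * [grid_span[1],
#'   grid_span[2]]`.
#' @param grid_step absolute step of the factor grid.
#' @return A list of class `scaling_fit`: `factor` (the minimizing scale),
#'   `ks_distance`, `seed_factor` (median ratio), `seed_ks`, `grid` (record
#'   of the search: `factor`, `ks`).
#' @examples
#' set.seed(1)
#' ctrl <- rlnorm(300, 0, 0.4)
#' fit_scaling_factor(ctrl, 0.8 * ctrl)$factor  # 0.8
#' @export
fit_scaling_factor <- function(control_values, stim_values,
                               grid_span = c(0.5, 1.5), grid_step = 0.001) {
  stopifnot(length(control_values) >= 1L, length(stim_values) >= 1L,
            all(control_values > 0), all(stim_values > 0))
  seed <- stats::median(stim_values) / stats::median(control_values)
  # the seed itself is always a candidate so the returned KS can never
  # exceed the seed's
  grid <- sort(unique(c(seq(seed * grid_span[1], seed * grid_span[2],
                            by = grid_step), seed)))
  ks <- vapply(grid, function(f) ks_distance(f * control_values, stim_values),
               numeric(1))
  best <- which.min(ks)  # which.min returns the first (smallest factor) on ties
  structure(
    list(factor = grid[best], ks_distance = ks[best],
         seed_factor = seed, seed_ks = ks_distance(seed * control_values, stim_values),
         grid = data.frame(factor = grid, ks = ks),
         n_control = length(control_values), n_stim = length(stim_values)),
    class = "scaling_fit"
  )
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("scaling_fit: factor = %.4g (KS = %.4g); seed = %.4g (KS = %.4g)\n",
              x$factor, x$ks_distance, x$seed_factor, x$seed_ks))
  cat(sprintf("  grid: %d candidates in [%.4g, %.4g], n = %d vs %d\n",
              nrow(x$grid), min(x$grid$factor), max(x$grid$factor),
              x$n_control, x$n_stim))
  invisible(x)
}

#' @export
plot.scaling_fit <- function(x, ...) {
  graphics::plot(x$grid$factor, x$grid$ks, type = "l",
                 xlab = "scaling factor", ylab = "KS distance", ...)
  graphics::abline(v = x$factor, col = "red3")
  graphics::abline(v = x$seed_factor, lty = 2, col = "grey50")
  invisible(x)
}

#' Structural excitation-inhibition ratio
#'
#' The structural synaptic E:I ratio of a dendrite is the area under its
#' background-normalized spine-channel profile divided by the area under its
#' background-normalized VGAT (inhibitory puncta) profile.
#'
#' @param spine_positions,spine_intensity spine-channel profile (um, a.u.).
#' @param vgat_positions,vgat_intensity VGAT-channel profile.
#' @param spine_background,vgat_background background levels (> 0).
#' @return A list of class `structural_ei`: `spine_integral`,
#'   `vgat_integral` (trapezoidal AUC of intensity/background), `ratio`.
#' @export
structural_ei <- function(spine_positions, spine_intensity, spine_background,
                          vgat_positions, vgat_intensity, vgat_background) {
  stopifnot(spine_background > 0, vgat_background > 0)
  spine_integral <- trapz(spine_positions, spine_intensity / spine_background)
  vgat_integral <- trapz(vgat_positions, vgat_intensity / vgat_background)
  if (vgat_integral <= 0) stop("VGAT integral must be positive")
  structure(list(spine_integral = spine_integral, vgat_integral = vgat_integral,
                 ratio = spine_integral / vgat_integral),
            class = "structural_ei")
}

#' @export
print.structural_ei <- function(x, ...) {
  cat(sprintf("structural E:I = %.4g (spine %.4g / VGAT %.4g)\n",
              x$ratio, x$spine_integral, x$vgat_integral))
  invisible(x)
}

#' Quantify c-Fos expression
#'
#' A neuron is c-Fos positive when its intensity exceeds background by more
#' than 20%. Intensities are also normalized to the group mean and, when a
#' pooled control distribution is supplied, split into weak (at or below its
#' 30th percentile) versus strong expressers.
#'
#' @param intensities per-neuron c-Fos intensities, a.u.
#' @param background background intensity (> 0).
#' @param control_pool optional pooled normalized control distribution used
#'   for the weak/strong split.
#' @param positive_margin fractional margin over background defining
#'   positivity (default 0.2).
#' @param weak_percentile percentile of `control_pool` at or below which
#'   expression counts as weak (default 0.30).
#' @return A list of class `cfos_measure`: data.frame `neurons` (`intensity`,
#'   `positive`, `normalized`, `expression` weak/strong or `NA`),
#'   `positive_fraction`, `positive_pct`.
#' @export
cfos_quantify <- function(intensities, background, control_pool = NULL,
                          positive_margin = 0.2, weak_percentile = 0.30) {
  stopifnot(length(intensities) >= 1L, background > 0)
  positive <- intensities > (1 + positive_margin) * background
  normalized <- intensities / mean(intensities)
  expression <- rep(NA_character_, length(intensities))
  if (!is.null(control_pool)) {
    cutoff <- stats::quantile(control_pool, weak_percentile, names = FALSE)
    expression <- ifelse(normalized <= cutoff, "weak", "strong")
  }
  structure(
    list(neurons = data.frame(intensity = intensities, positive = positive,
                              normalized = normalized, expression = expression,
                              stringsAsFactors = FALSE),
         positive_fraction = mean(positive),
         positive_pct = 100 * mean(positive)),
    class = "cfos_measure"
  )
}

#' Bootstrap the c-Fos positive percentage
#'
#' Resamples the per-neuron positivity flags with replacement in small
#' batches, recording the percent positive per replicate.
#'
#' @param positive_flags logical vector of per-neuron positivity.
#' @param n_boot number of bootstrap replicates (default 500).
#' @param batch neurons drawn (with replacement) per replicate (default 10).
#' @param seed RNG seed.
#' @return A list: `replicates` (percent positive per replicate), `mean`,
#'   `sd`, `ci` (2.5/97.5 percentiles).
#' @export
cfos_bootstrap <- function(positive_flags, n_boot = 500L, batch = 10L, seed = 1L) {
  stopifnot(length(positive_flags) >= 1L, n_boot >= 1L, batch >= 1L)
  flags <- as.logical(positive_flags)
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(i)
    100 * mean(sample(flags, batch, replace = TRUE)), numeric(1))
  list(replicates = reps, mean = mean(reps), sd = stats::sd(reps),
       ci = stats::quantile(reps, c(0.025, 0.975), names = FALSE))
}
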