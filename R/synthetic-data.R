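#' Scenario specification for the synthetic-data generators
#'
#' Bundles the master seed, the experimental scenario and the planted effect
#' sizes and noise parameters used by every generator. Effect directions
#' follow the study design the analyses assume: after overstimulation young
#' adults homeostatically reduce cellular activity, weaken excitatory minis,
#' gain inhibitory mini frequency, inhibitory (VGAT) puncta and E-I
#' assembly coupling, and downscale spine sizes multiplicatively; in late
#' adults those compensations are reduced or inverted (activity up, E-E
#' coupling up, no multiplicative downscaling). Magnitudes are round-number
#' ground truth for recovery tests, not estimates of real data.
#'
#' @param scenario one of `"young_control"`, `"young_stim"`, `"old_control"`,
#'   `"old_stim"`, `"custom"`.
#' @param seed master seed; generators derive their streams from it.
#' @param ... for `scenario = "custom"` (or to override a preset), any of
#'   the effect/noise fields listed below.
#' @return A list of class `generator_spec` with fields: `activity_gain`
#'   (post/baseline multiplier on calcium event rate), `weaken_fraction`
#'   (fraction of spines weakened after overstimulation), `mepsp_amp_gain`,
#'   `mipsp_freq_gain`, `vgat_density_gain`, `ee_corr_shift`,
#'   `ei_corr_shift` (additive shifts on planted pairwise correlations),
#'   `rcpt_slope` (planted learning slope per session), `scaling_factor`
#'   (multiplicative spine-size factor vs control), plus noise parameters
#'   `trace_noise_sd` (percent dFF), `kernel_tau_s` (calcium indicator decay,
#'   s), `drift_pct_per_min` (baseline drift), `measurement_cv`.
#' @export
generator_spec <- function(scenario = c("young_control", "young_stim",
                                        "old_control", "old_stim", "custom"),
                           seed = 1L, ...) {
  scenario <- match.arg(scenario)
  base <- list(
    scenario = scenario, seed = as.integer(seed),
    activity_gain = 1, weaken_fraction = 0.5,
    mepsp_amp_gain = 1, mipsp_freq_gain = 1, vgat_density_gain = 1,
    ee_corr_shift = 0, ei_corr_shift = 0,
    rcpt_slope = 0.05, scaling_factor = 1,
    trace_noise_sd = 2, kernel_tau_s = 1.5,
    drift_pct_per_min = 10, measurement_cv = 0.2
  )
  preset <- switch(scenario,
    young_control = list(),
    young_stim = list(activity_gain = 0.7, weaken_fraction = 0.8,
                      mepsp_amp_gain = 0.8, mipsp_freq_gain = 1.5,
                      vgat_density_gain = 1.3, ei_corr_shift = 0.1,
                      scaling_factor = 0.8),
    old_control = list(),
    old_stim = list(activity_gain = 1.3, weaken_fraction = 0.5,
                    mepsp_amp_gain = 1.2, mipsp_freq_gain = 0.7,
                    vgat_density_gain = 0.8, ee_corr_shift = 0.15,
                    rcpt_slope = 0.03, scaling_factor = 1),
    custom = list()
  )
  base[names(preset)] <- preset
  dots <- list(...)
  stopifnot(all(names(dots) %in% names(base)))
  base[names(dots)] <- dots
  stopifnot(all(vapply(base[-1], function(x)
    is.numeric(x) && all(is.finite(x)), logical(1))))
  structure(base, class = "generator_spec")
}

#' @export
print.generator_spec <- function(x, ...) {
  cat(sprintf("generator_spec: %s (seed %d)\n", x$scenario, x$seed))
  eff <- unlist(x[c("activity_gain", "weaken_fraction", "mepsp_amp_gain",
                    "mipsp_freq_gain", "vgat_density_gain", "ee_corr_shift",
                    "ei_corr_shift", "rcpt_slope", "scaling_factor")])
  print(eff)
  invisible(x)
}

# Convolve a spike/event indicator with a single-exponential calcium kernel.
calcium_convolve <- function(impulses, rate_hz, tau_s) {
  decay <- exp(-1 / (rate_hz * tau_s))
  as.numeric(stats::filter(impulses, decay, method = "recursive"))
}

#' Generate raw cellular calcium traces with known ground truth
#'
#' Emulates GCaMP6s-like recordings: per cell, Poisson calcium events whose
#' rate is multiplied by `1 + tuning` during flicker-on epochs, convolved
#' with a single-exponential decay kernel, riding on a noisy, slowly
#' drifting baseline. A background ROI trace (baseline + drift + noise, no
#' events) is included.
#'
#' @param spec a [generator_spec()]; its `activity_gain` multiplies the
#'   event rate (emulating a post-overstimulation session), `kernel_tau_s`,
#'   `trace_noise_sd` and `drift_pct_per_min` set the trace structure.
#' @param n_cells number of cells.
#' @param duration_s recording length, seconds.
#' @param rate_hz imaging frame rate.
#' @param schedule optional [stimulus_schedule()] used for visual
#'   modulation.
#' @param event_rate_hz baseline calcium event rate per cell.
#' @param amp_pct transient amplitude in percent of baseline fluorescence.
#' @param baseline_f baseline fluorescence, a.u.
#' @param tuning_range per-cell visual tuning drawn uniformly from this
#'   range (rate multiplier during flicker is `1 + tuning`).
#' @return A list: `traces` (list of numeric raw fluorescence vectors),
#'   `background` (numeric vector), `rate_hz`, and `truth` (data.frame with
#'   per-cell `tuning`, `n_events`, plus list-column `event_times`).
#' @export
gen_cell_traces <- function(spec, n_cells = 20, duration_s = 120, rate_hz = 6,
                            schedule = NULL, event_rate_hz = 0.1,
                            amp_pct = 80, baseline_f = 100,
                            tuning_range = c(0, 3)) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  n_frames <- as.integer(round(duration_s * rate_hz))
  tt <- (seq_len(n_frames) - 1) / rate_hz
  in_on <- rep(FALSE, n_frames)
  if (!is.null(schedule)) {
    on <- schedule[schedule$label == "flicker_on", , drop = FALSE]
    for (i in seq_len(nrow(on)))
      in_on <- in_on | (tt >= on$start_s[i] & tt < on$end_s[i])
  }
  drift_per_frame <- spec$drift_pct_per_min / 100 * baseline_f / (60 * rate_hz)
  tuning <- stats::runif(n_cells, tuning_range[1], tuning_range[2])
  base_rate <- event_rate_hz * spec$activity_gain
  traces <- vector("list", n_cells)
  event_times <- vector("list", n_cells)
  for (c_i in seq_len(n_cells)) {
    rate <- base_rate * ifelse(in_on, 1 + tuning[c_i], 1) / rate_hz
    impulses <- stats::rpois(n_frames, rate)
    transients <- calcium_convolve(impulses, rate_hz, spec$kernel_tau_s)
    drift <- drift_per_frame * seq_len(n_frames)
    noise <- stats::rnorm(n_frames, 0, spec$trace_noise_sd / 100 * baseline_f)
    traces[[c_i]] <- baseline_f * (1 + amp_pct / 100 * transients) + drift + noise
    event_times[[c_i]] <- tt[impulses > 0]
  }
  background <- baseline_f / 2 + drift_per_frame * seq_len(n_frames) / 2 +
    stats::rnorm(n_frames, 0, spec$trace_noise_sd / 100 * baseline_f / 2)
  truth <- data.frame(cell = seq_len(n_cells), tuning = tuning,
                      n_events = vapply(event_times, length, integer(1)))
  truth$event_times <- event_times
  list(traces = traces, background = background, rate_hz = rate_hz,
       truth = truth)
}

#' Generate paired spine/dendrite traces with a known mixing coefficient
#'
#' Spine and dendrite activity are built directly on the thresholded
#' delta-F/F0 scale: the dendrite shows global (back-propagating) events,
#' partly stimulus-locked; each spine has spine-local events whose
#' probability of following a flicker epoch is its planted coupling; the
#' measured spine trace is `spine_only + kappa * dendrite + noise`.
#'
#' @param spec a [generator_spec()].
#' @param n_spines number of spines.
#' @param schedule a [stimulus_schedule()]; required.
#' @param kappa true dendritic mixing coefficient (>= 0).
#' @param coupling per-spine probability that a flicker epoch evokes a
#'   spine-local event; scalar or length-`n_spines` vector.
#' @param duration_s,rate_hz trace geometry (spine imaging runs at 30 Hz).
#' @param spont_rate_hz rate of spontaneous (non-locked) spine events.
#' @param dend_rate_hz rate of spontaneous dendritic events.
#' @param dend_stim_p probability a flicker epoch evokes a dendritic event.
#' @param amp_pct event amplitude, percent dFF.
#' @param threshold_pct threshold applied to the returned traces.
#' @return A list: `spines` (list of measured spine [dff_trace()]),
#'   `dendrite` ([dff_trace()]), `spine_only` (list of noise-free local
#'   signals), `truth` (data.frame: `spine`, `kappa`, `coupling`).
#' @export
gen_spine_dendrite <- function(spec, n_spines = 10, schedule,
                               kappa = 0.7, coupling = 0.5,
                               duration_s = NULL, rate_hz = 30,
                               spont_rate_hz = 0.05, dend_rate_hz = 0.1,
                               dend_stim_p = 0.5, amp_pct = 60,
                               threshold_pct = 15) {
  stopifnot(inherits(spec, "generator_spec"), inherits(schedule, "stim_schedule"),
            kappa >= 0)
  set.seed(spec$seed + 1L)
  coupling <- rep_len(coupling, n_spines)
  on <- schedule[schedule$label == "flicker_on", , drop = FALSE]
  if (is.null(duration_s)) duration_s <- max(on$end_s) + 5
  n_frames <- as.integer(round(duration_s * rate_hz))
  tt <- (seq_len(n_frames) - 1) / rate_hz
  kern_events <- function(onsets_s, amp) {
    imp <- numeric(n_frames)
    idx <- pmin(pmax(round(onsets_s * rate_hz) + 1, 1), n_frames)
    imp[idx] <- imp[idx] + 1
    amp * calcium_convolve(imp, rate_hz, spec$kernel_tau_s)
  }
  # dendritic (global) signal
  d_spont <- tt[stats::rpois(n_frames, dend_rate_hz / rate_hz) > 0]
  d_stim <- on$start_s[stats::runif(nrow(on)) < dend_stim_p]
  d_stim <- d_stim + stats::runif(length(d_stim), 0, 0.5)
  dend_vals <- kern_events(sort(c(d_spont, d_stim)), amp_pct)
  spines <- spine_only <- vector("list", n_spines)
  for (s_i in seq_len(n_spines)) {
    evoked <- on$start_s[stats::runif(nrow(on)) < coupling[s_i]]
    evoked <- evoked + stats::runif(length(evoked), 0, 0.5)
    spont <- tt[stats::rpois(n_frames, spont_rate_hz / rate_hz) > 0]
    local <- kern_events(sort(c(evoked, spont)), amp_pct)
    noise <- stats::rnorm(n_frames, 0, spec$trace_noise_sd)
    measured <- pmax(local + kappa * dend_vals + noise, 0)
    spine_only[[s_i]] <- dff_trace(apply_dff_threshold(local, threshold_pct),
                                   rate_hz, threshold_pct)
    spines[[s_i]] <- dff_trace(apply_dff_threshold(measured, threshold_pct),
                               rate_hz, threshold_pct)
  }
  list(spines = spines,
       dendrite = dff_trace(apply_dff_threshold(dend_vals, threshold_pct),
                            rate_hz, threshold_pct),
       spine_only = spine_only,
       truth = data.frame(spine = seq_len(n_spines), kappa = kappa,
                          coupling = coupling))
}

#' Generate miniature synaptic event trains and optional voltage traces
#'
#' Exponential inter-event intervals at the planted rate and lognormal
#' amplitudes; the scenario's `mepsp_amp_gain` / `mipsp_freq_gain` multiply
#' the excitatory amplitude and inhibitory rate respectively. Optionally
#' synthesizes a raw voltage trace: Gaussian noise of planted RMS plus a
#' fast-rise/exponential-decay waveform per event.
#'
#' @param spec a [generator_spec()].
#' @param n_cells number of cells (one train per cell).
#' @param polarity `"excitatory"` or `"inhibitory"`.
#' @param duration_s recording length per cell.
#' @param rate_hz baseline event rate before scenario gains.
#' @param amp_mv mean event amplitude before gains, mV.
#' @param amp_cv lognormal coefficient of variation of amplitudes.
#' @param voltage if `TRUE`, also return raw voltage traces.
#' @param sample_rate_hz voltage sampling rate.
#' @param noise_rms_mv RMS of the Gaussian voltage noise.
#' @param decay_ms event decay time constant in the voltage waveform.
#' @return A list: `trains` (list of [mini_train()]), `truth` (planted
#'   `rate_hz`, `amp_mv` after gains), and `voltages` (list of numeric, if
#'   requested).
#' @export
gen_minis <- function(spec, n_cells = 10,
                      polarity = c("excitatory", "inhibitory"),
                      duration_s = 60, rate_hz = 1, amp_mv = 0.5,
                      amp_cv = 0.3, voltage = FALSE,
                      sample_rate_hz = 20000, noise_rms_mv = 0.05,
                      decay_ms = 5) {
  stopifnot(inherits(spec, "generator_spec"))
  polarity <- match.arg(polarity)
  set.seed(spec$seed + 2L)
  true_rate <- rate_hz * if (polarity == "inhibitory") spec$mipsp_freq_gain else 1
  true_amp <- amp_mv * if (polarity == "excitatory") spec$mepsp_amp_gain else 1
  sdlog <- sqrt(log(1 + amp_cv^2))
  trains <- voltages <- vector("list", n_cells)
  for (c_i in seq_len(n_cells)) {
    times <- cumsum(stats::rexp(ceiling(true_rate * duration_s * 3) + 20,
                                true_rate))
    times <- times[times < duration_s]
    amps <- true_amp * stats::rlnorm(length(times), -sdlog^2 / 2, sdlog)
    trains[[c_i]] <- mini_train(times, amps, duration_s, polarity)
    if (voltage) {
      n <- as.integer(duration_s * sample_rate_hz)
      v <- stats::rnorm(n, 0, noise_rms_mv)
      decay <- exp(-1 / (sample_rate_hz * decay_ms / 1000))
      imp <- numeric(n)
      idx <- pmin(pmax(round(times * sample_rate_hz) + 1, 1), n)
      imp[idx] <- imp[idx] + amps
      wave <- as.numeric(stats::filter(imp, decay, method = "recursive"))
      sgn <- if (polarity == "excitatory") 1 else -1
      voltages[[c_i]] <- v + sgn * wave
    }
  }
  out <- list(trains = trains,
              truth = list(rate_hz = true_rate, amp_mv = true_amp,
                           polarity = polarity))
  if (voltage) out$voltages <- voltages
  out
}

#' Generate dendritic intensity profiles with planted structure
#'
#' Gaussian bumps on a constant background: a spine channel with planted
#' peak positions/widths, a colocalized synaptic-protein channel with
#' planted per-spine levels, and a VGAT channel with its own density. The
#' scenario's `scaling_factor` multiplies spine widths and
#' `vgat_density_gain` the VGAT density.
#'
#' @param spec a [generator_spec()].
#' @param n_dendrites number of dendrites.
#' @param length_um profile length, micrometres.
#' @param spacing_um sample spacing.
#' @param spine_density_per_um planted spine density before gains.
#' @param width_um mean planted spine width (full width at the 15%-above-
#'   background level) before the scaling factor.
#' @param width_cv coefficient of variation of planted widths.
#' @param height planted spine peak height, in background units above 1.
#' @param protein_height mean planted protein peak height (background
#'   units above 1); per-spine levels are lognormal around it.
#' @param vgat_density_per_um planted VGAT puncta density before gains.
#' @param background background level, a.u.
#' @param noise_sd additive profile noise, in background units.
#' @return A list of per-dendrite lists, each with `positions`, `spine`,
#'   `protein`, `vgat` intensity vectors, `background`, and a `truth` list
#'   (`spine_centers`, `spine_widths`, `protein_levels`, `vgat_centers`).
#' @export
gen_profiles <- function(spec, n_dendrites = 10, length_um = 20,
                         spacing_um = 0.02, spine_density_per_um = 0.4,
                         width_um = 0.8, width_cv = 0.2, height = 1.0,
                         protein_height = 1.0, vgat_density_per_um = 0.5,
                         background = 100, noise_sd = 0.02) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed + 3L)
  x <- seq(0, length_um, by = spacing_um)
  # sigma such that the bump crosses 1.15x background at the planted width:
  # 1 + h*exp(-(w/2)^2 / (2 s^2)) = 1.15  =>  s = w / (2 sqrt(2 log(h/0.15)))
  sigma_for <- function(w, h) w / (2 * sqrt(2 * log(h / 0.15)))
  bumps <- function(centers, widths, heights) {
    z <- numeric(length(x))
    for (i in seq_along(centers)) {
      s <- sigma_for(widths[i], heights[i])
      z <- z + heights[i] * exp(-(x - centers[i])^2 / (2 * s^2))
    }
    z
  }
  lapply(seq_len(n_dendrites), function(d) {
    n_sp <- max(1L, stats::rpois(1, spine_density_per_um * length_um))
    centers <- sort(stats::runif(n_sp, 1, length_um - 1))
    # enforce separation so planted peaks stay resolvable
    centers <- centers[c(TRUE, diff(centers) > 1.5)]
    n_sp <- length(centers)
    widths <- spec$scaling_factor * width_um *
      stats::rlnorm(n_sp, -log(1 + width_cv^2) / 2, sqrt(log(1 + width_cv^2)))
    prot <- protein_height * stats::rlnorm(n_sp, 0, spec$measurement_cv)
    n_vg <- max(1L, stats::rpois(1, vgat_density_per_um * spec$vgat_density_gain *
                                   length_um))
    vg_centers <- sort(stats::runif(n_vg, 0.5, length_um - 0.5))
    spine_z <- 1 + bumps(centers, widths, rep(height, n_sp)) +
      stats::rnorm(length(x), 0, noise_sd)
    prot_z <- 1 + bumps(centers, widths, prot) +
      stats::rnorm(length(x), 0, noise_sd)
    vgat_z <- 1 + bumps(vg_centers, rep(0.6, n_vg), rep(height, n_vg)) +
      stats::rnorm(length(x), 0, noise_sd)
    list(positions = x, spine = background * spine_z,
         protein = background * prot_z, vgat = background * vgat_z,
         background = background,
         truth = list(spine_centers = centers, spine_widths = widths,
                      protein_levels = prot, vgat_centers = vg_centers))
  })
}

#' Generate touchscreen task session counts with a planted learning slope
#'
#' Per animal and session, hits/misses are binomial draws around a hit rate
#' that climbs linearly at the scenario's planted slope, and
#' mistakes/correct rejections binomial draws at a flat false-alarm rate, so
#' the expected performance trajectory has slope `rcpt_slope`.
#'
#' @param spec a [generator_spec()]; `rcpt_slope` is the planted slope.
#' @param n_animals number of animals.
#' @param n_sessions sessions per animal (testing runs over seven daily
#'   sessions).
#' @param trials_per_session target trials; split evenly between S+ and S-
#'   presentations.
#' @param hr0 hit rate at session 1.
#' @param far false-alarm rate (flat across sessions).
#' @return A data.frame: `animal`, `session`, `hits`, `misses`, `mistakes`,
#'   `correct_rejections`; attribute `truth` (list with `slope`, `hr0`,
#'   `far`).
#' @export
gen_rcpt <- function(spec, n_animals = 20, n_sessions = 7,
                     trials_per_session = 100, hr0 = 0.4, far = 0.2) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed + 4L)
  n_target <- floor(trials_per_session / 2)
  n_nontarget <- trials_per_session - n_target
  rows <- expand.grid(session = seq_len(n_sessions), animal = seq_len(n_animals))
  hr <- pmin(pmax(hr0 + spec$rcpt_slope * (rows$session - 1), 0.01), 0.99)
  hits <- stats::rbinom(nrow(rows), n_target, hr)
  mistakes <- stats::rbinom(nrow(rows), n_nontarget, far)
  out <- data.frame(animal = rows$animal, session = rows$session,
                    hits = hits, misses = n_target - hits,
                    mistakes = mistakes,
                    correct_rejections = n_nontarget - mistakes)
  attr(out, "truth") <- list(slope = spec$rcpt_slope, hr0 = hr0, far = far)
  out
}

#' Generate a population recording with planted block correlations
#'
#' Draws frames from a zero-mean Gaussian factor model with a shared
#' factor (driving the cross-class E-I correlation) plus one factor per
#' class, chosen so pairwise correlations have constant blocks: `rho_ee`
#' within excitatory pairs, `rho_ii` within inhibitory pairs and `rho_ei`
#' across. Traces are then shifted to a nonnegative activity scale. The
#' scenario's `ee_corr_shift` / `ei_corr_shift` are added to the respective
#' planted blocks. The factor construction requires
#' `rho_ei <= min(rho_ee, rho_ii)` (any stronger cross-block correlation
#' would not be a valid correlation structure for constant blocks).
#'
#' @param spec a [generator_spec()].
#' @param n_exc,n_inh numbers of excitatory and inhibitory neurons.
#' @param n_frames frames to draw.
#' @param rho_ee,rho_ei,rho_ii planted block correlations before scenario
#'   shifts.
#' @return A list: `traces` (frames x neurons matrix), `classes`, `truth`
#'   (realized planted block values).
#' @export
gen_population <- function(spec, n_exc = 15, n_inh = 5, n_frames = 1000,
                           rho_ee = 0.25, rho_ei = 0.15, rho_ii = 0.35) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed + 5L)
  ee <- rho_ee + spec$ee_corr_shift
  ei <- rho_ei + spec$ei_corr_shift
  stopifnot(ei >= 0, ei <= min(ee, rho_ii), ee < 1, rho_ii < 1)
  n <- n_exc + n_inh
  classes <- rep(c("excitatory", "inhibitory"), c(n_exc, n_inh))
  # loadings: shared factor gives rho_ei; class factors top up to rho_ee/ii
  f_shared <- stats::rnorm(n_frames)
  f_e <- stats::rnorm(n_frames)
  f_i <- stats::rnorm(n_frames)
  eps <- matrix(stats::rnorm(n_frames * n), n_frames, n)
  load_class <- c(rep(sqrt(ee - ei), n_exc), rep(sqrt(rho_ii - ei), n_inh))
  resid <- sqrt(1 - ei - load_class^2)
  f_class <- cbind(matrix(f_e, n_frames, n_exc), matrix(f_i, n_frames, n_inh))
  z <- sqrt(ei) * f_shared + t(t(f_class) * load_class) + t(t(eps) * resid)
  traces <- pmax(z + 3, 0)  # shift to a nonnegative activity-like scale
  colnames(traces) <- sprintf("n%02d", seq_len(n))
  list(traces = traces, classes = classes,
       truth = list(rho_ee = ee, rho_ei = ei, rho_ii = rho_ii))
}
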