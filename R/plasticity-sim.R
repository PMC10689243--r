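#' Configuration for the two-compartment plasticity simulation
#'
#' Builds the parameter set for the rate-model neuron with somatic and
#' dendritic compartments. The postsynaptic rate r evolves as
#' \deqn{\tau\, dr/dt = -r + [I_{soma} + [I_{dend}]_+]_+}
#' with \eqn{I_{soma} = I_{ffw} + r_{exc} - r_{inh}} and
#' \eqn{I_{dend} = \frac{1}{N}\sum_i w_i r_i - I_{inh}}. Each dendritic weight
#' follows
#' \deqn{dw_i/dt = A_1 r_i (r_i - r_0)\, r\, (1 - I_{inh}) - A_2 r,}
#' a Hebbian term gated by dendritic inhibition plus an activity-proportional
#' homeostatic downscaling term. Presynaptic rates are
#' \eqn{r_i(t) = r_0 + v_i + \alpha r(t) + \zeta(t)} with the visual drive
#' \eqn{v_i} present only while the flicker stimulus is on (alternating
#' `T_on` / `T_off` step epochs).
#'
#' Two regimes are bundled: in young adults overstimulation both raises
#' dendritic inhibition (`I_inh_stim = 0.4`) and strengthens downscaling
#' (`A2 = 0.56e-4`); in late adults inhibition stays at its baseline 0.2 and
#' downscaling is weaker (`A2 = 0.48e-4`).
#'
#' @param regime `"young"` or `"old"`; presets `A2` and `I_inh_stim`
#'   accordingly. Individual arguments override the preset.
#' @param tau integration time constant of the network (steps).
#' @param I_ffw feedforward somatic input.
#' @param r0 baseline firing rate.
#' @param N number of presynaptic excitatory inputs.
#' @param T_steps total number of integration steps.
#' @param dt step size, in the same arbitrary unit as `tau`.
#' @param T_on,T_off stimulus on/off epoch durations in steps.
#' @param A1 Hebbian learning rate.
#' @param A2 homeostatic downscaling rate; defaults by regime.
#' @param I_inh_baseline dendritic inhibition before overstimulation.
#' @param I_inh_stim dendritic inhibition during overstimulation (the value
#'   used by the simulated overstimulation phase); defaults by regime.
#' @param alpha feedback gain from postsynaptic rate onto presynaptic rates.
#' @param w_init_sd s.d. of the Gaussian noise on initial weights (w = 1 + xi).
#' @param presyn_noise_sd s.d. of the per-step Gaussian noise zeta on
#'   presynaptic rates.
#' @param soma_noise_max upper bound of the per-step uniform(0, max) noise on
#'   the somatic aggregate excitatory and inhibitory rates (drawn
#'   independently for the two).
#' @param gate_stimulus logical; if `TRUE` (default) the visual drive v_i
#'   enters presynaptic rates only during `T_on` epochs, if `FALSE` it is
#'   always on.
#' @param rectify_presyn logical; rectify presynaptic rates at zero before
#'   they enter the dendritic input and the Hebbian term (default `TRUE`).
#' @param seed RNG seed for the run.
#' @return A list of class `sim_config`.
#' @seealso [simulate_plasticity()]
#' @export
sim_config <- function(regime = c("young", "old"),
                       tau = 10, I_ffw = 0.5, r0 = 1, N = 200,
                       T_steps = 10000, dt = 1, T_on = 100, T_off = 100,
                       A1 = 1e-4, A2 = NULL,
                       I_inh_baseline = 0.2, I_inh_stim = NULL,
                       alpha = 0.1, w_init_sd = 0.1, presyn_noise_sd = 0.1,
                       soma_noise_max = 0.1,
                       gate_stimulus = TRUE, rectify_presyn = TRUE,
                       seed = 1L) {
  regime <- match.arg(regime)
  if (is.null(A2)) A2 <- if (regime == "young") 0.56e-4 else 0.48e-4
  if (is.null(I_inh_stim)) I_inh_stim <- if (regime == "young") 0.4 else 0.2
  cfg <- list(regime = regime, tau = tau, I_ffw = I_ffw, r0 = r0, N = as.integer(N),
              T_steps = as.integer(T_steps), dt = dt,
              T_on = as.integer(T_on), T_off = as.integer(T_off),
              A1 = A1, A2 = A2,
              I_inh_baseline = I_inh_baseline, I_inh_stim = I_inh_stim,
              alpha = alpha, w_init_sd = w_init_sd,
              presyn_noise_sd = presyn_noise_sd, soma_noise_max = soma_noise_max,
              gate_stimulus = isTRUE(gate_stimulus),
              rectify_presyn = isTRUE(rectify_presyn),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$tau > 0, cfg$N >= 1L, cfg$T_steps >= 1L, cfg$dt > 0,
    cfg$T_on >= 1L, cfg$T_off >= 1L,
    cfg$A1 >= 0, cfg$A2 >= 0, cfg$r0 >= 0,
    cfg$I_inh_baseline >= 0, cfg$I_inh_baseline < 1,
    cfg$I_inh_stim >= 0, cfg$I_inh_stim < 1,
    cfg$w_init_sd >= 0, cfg$presyn_noise_sd >= 0, cfg$soma_noise_max >= 0
  )
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config (%s regime): N = %d inputs, T = %d steps, dt = %g\n",
              x$regime, x$N, x$T_steps, x$dt))
  cat(sprintf("  A1 = %g, A2 = %g, I_inh = %g (baseline %g), alpha = %g, tau = %g\n",
              x$A1, x$A2, x$I_inh_stim, x$I_inh_baseline, x$alpha, x$tau))
  invisible(x)
}

#' Simulate the two-compartment Hebbian/homeostatic neuron
#'
#' Explicit Euler integration of the rate and weight dynamics described in
#' [sim_config()], over the overstimulation phase: dendritic inhibition is
#' held at `I_inh_stim` throughout and the flicker stimulus alternates
#' `T_on` steps on, `T_off` steps off, starting with an on epoch.
#'
#' Per step, with state `(r, w)`: presynaptic noise zeta is redrawn for every
#' input, the two somatic uniform noises are redrawn, presynaptic rates are
#' formed (and rectified at zero when `rectify_presyn`), the dendritic input
#' is the weight-weighted mean rate minus inhibition, and the nested
#' rectification \eqn{[I_{soma} + [I_{dend}]_+]_+} drives the rate update.
#' The plasticity update uses the same step's presynaptic rates and the
#' pre-update postsynaptic rate. Weights are not clipped at zero; negative
#' excursions are retained and counted in the result.
#'
#' @param config a [sim_config()].
#' @param record `"full"` to keep the whole T x N weight and presynaptic rate
#'   trajectories, `"ends"` to keep only initial and final weights (rate
#'   trajectory is always kept).
#' @param noise optional list with pre-drawn noise arrays, used to share a
#'   noise stream with an external reference integrator: `zeta` (N x T),
#'   `u_exc`, `u_inh` (length T), `xi` (length N), `v` (length N). When
#'   supplied the RNG is not touched.
#' @return A list of class `plasticity_sim` with elements `v` (visual
#'   responsiveness per input), `w0` and `wT` (initial/final weights), `W`
#'   (T x N weight trajectory when `record = "full"`), `r` (postsynaptic rate,
#'   length T), `r_pre` (N x T presynaptic rates when `record = "full"`),
#'   `n_negative_weights` (count of inputs ever negative), and `config`.
#' @examples
#' cfg <- sim_config("young", N = 20, T_steps = 200, seed = 42)
#' sim <- simulate_plasticity(cfg)
#' mean(sim$wT - sim$w0)
#' @export
simulate_plasticity <- function(config, record = c("full", "ends"), noise = NULL) {
  validate_sim_config(config)
  record <- match.arg(record)
  N <- config$N; Tn <- config$T_steps; dt <- config$dt

  if (is.null(noise)) {
    set.seed(config$seed)
    v <- stats::runif(N, 0, 1)
    xi <- stats::rnorm(N, 0, config$w_init_sd)
    zeta <- matrix(stats::rnorm(N * Tn, 0, config$presyn_noise_sd), nrow = N)
    u_exc <- stats::runif(Tn, 0, config$soma_noise_max)
    u_inh <- stats::runif(Tn, 0, config$soma_noise_max)
  } else {
    v <- noise$v; xi <- noise$xi; zeta <- noise$zeta
    u_exc <- noise$u_exc; u_inh <- noise$u_inh
    stopifnot(length(v) == N, length(xi) == N,
              nrow(zeta) == N, ncol(zeta) == Tn,
              length(u_exc) == Tn, length(u_inh) == Tn)
  }

  w <- 1 + xi
  w0 <- w
  r <- config$r0
  I_inh <- config$I_inh_stim
  # stimulus gate: on for the first T_on of every (T_on + T_off) cycle
  cycle <- (seq_len(Tn) - 1L) %% (config$T_on + config$T_off)
  gate <- if (config$gate_stimulus) as.numeric(cycle < config$T_on) else rep(1, Tn)

  keep_full <- record == "full"
  r_traj <- numeric(Tn)
  W <- if (keep_full) matrix(NA_real_, nrow = Tn, ncol = N) else NULL
  r_pre <- if (keep_full) matrix(NA_real_, nrow = N, ncol = Tn) else NULL
  ever_negative <- rep(FALSE, N)
  heb_gain <- config$A1 * (1 - I_inh)

  for (t in seq_len(Tn)) {
    r_i <- config$r0 + gate[t] * v + config$alpha * r + zeta[, t]
    if (config$rectify_presyn) r_i[r_i < 0] <- 0
    I_dend <- mean(w * r_i) - I_inh
    I_soma <- config$I_ffw + (config$r0 + u_exc[t]) - (config$r0 + u_inh[t])
    drive <- max(I_soma + max(I_dend, 0), 0)
    r_new <- r + dt / config$tau * (-r + drive)
    w <- w + dt * (heb_gain * r_i * (r_i - config$r0) * r - config$A2 * r)
    if (!is.finite(r_new) || any(!is.finite(w))) {
      bad <- if (!is.finite(r_new)) "postsynaptic rate" else
        sprintf("weight of input %d", which(!is.finite(w))[1])
      stop(sprintf("non-finite state at step %d: %s", t, bad))
    }
    r <- r_new
    ever_negative <- ever_negative | w < 0
    r_traj[t] <- r
    if (keep_full) {
      W[t, ] <- w
      r_pre[, t] <- r_i
    }
  }

  structure(
    list(v = v, w0 = w0, wT = w, W = W, r = r_traj, r_pre = r_pre,
         n_negative_weights = sum(ever_negative), config = config),
    class = "plasticity_sim"
  )
}

#' @export
print.plasticity_sim <- function(x, ...) {
  cfg <- x$config
  dw <- x$wT - x$w0
  cat(sprintf("plasticity_sim (%s regime): N = %d, T = %d, seed = %d\n",
              cfg$regime, cfg$N, cfg$T_steps, cfg$seed))
  cat(sprintf("  mean weight change: %+.4g (range %+.4g to %+.4g)\n",
              mean(dw), min(dw), max(dw)))
  cat(sprintf("  final rate: %.4g; inputs ever below zero weight: %d\n",
              x$r[length(x$r)], x$n_negative_weights))
  invisible(x)
}

#' @export
plot.plasticity_sim <- function(x, ...) {
  dw <- x$wT - x$w0
  graphics::plot(x$v, dw, xlab = "visual responsiveness v",
                 ylab = expression(Delta * w), ...)
  graphics::abline(h = 0, lty = 2, col = "grey50")
  invisible(x)
}

#' Bin weight change by visual responsiveness
#'
#' Groups presynaptic inputs into equal-width bins on the responsiveness
#' scale `[0, 1]` and averages the total weight change per bin, the analysis
#' used to ask whether visually driven synapses strengthen more than
#' nonvisual ones.
#'
#' @param result a [simulate_plasticity()] result.
#' @param n_bins number of equal-width bins on `[0, 1]` (>= 2).
#' @return A data.frame with columns `bin`, `v_lo`, `v_hi`, `v_mid`, `n`
#'   (inputs in bin), `mean_dw`. Empty bins are retained with `n = 0` and
#'   `mean_dw = NA`.
#' @export
weight_change_by_responsivity <- function(result, n_bins = 10) {
  stopifnot(inherits(result, "plasticity_sim"), n_bins >= 2)
  breaks <- seq(0, 1, length.out = n_bins + 1)
  idx <- cut(result$v, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  dw <- result$wT - result$w0
  n <- tabulate(idx, nbins = n_bins)
  mean_dw <- vapply(seq_len(n_bins), function(b) {
    if (n[b] == 0L) NA_real_ else mean(dw[idx == b])
  }, numeric(1))
  data.frame(bin = seq_len(n_bins),
             v_lo = breaks[-length(breaks)], v_hi = breaks[-1],
             v_mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
             n = n, mean_dw = mean_dw)
}

# Shared engine for the reinstatement sweeps: runs each parameter level over
# the same set of per-seed substreams and normalizes per-bin mean weight
# change to the late-adult reference run (the base configuration itself).
run_sweep <- function(base, parameter, levels, n_seeds, n_bins) {
  if (length(levels) == 0L) stop("levels must be nonempty")
  if (is.unsorted(levels, strictly = TRUE)) stop("levels must be strictly increasing")
  # substream seeds derived from the base seed so all levels share them
  set.seed(base$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_seeds)
  run_level <- function(value) {
    cfg <- base
    if (parameter == "I_inh") cfg$I_inh_stim <- value else cfg$A2 <- value
    acc <- matrix(0, nrow = n_bins, ncol = n_seeds)
    cnt <- matrix(0, nrow = n_bins, ncol = n_seeds)
    mean_dw <- numeric(n_seeds)
    for (k in seq_len(n_seeds)) {
      cfg$seed <- seeds[k]
      sim <- simulate_plasticity(cfg, record = "ends")
      mean_dw[k] <- mean(sim$wT - sim$w0)
      b <- weight_change_by_responsivity(sim, n_bins)
      acc[, k] <- ifelse(b$n > 0, b$mean_dw, 0)
      cnt[, k] <- b$n
    }
    list(bin_dw = rowSums(acc * cnt) / pmax(rowSums(cnt), 1),
         bin_n = rowSums(cnt), mean_dw = mean(mean_dw))
  }
  ref_value <- if (parameter == "I_inh") base$I_inh_stim else base$A2
  ref <- run_level(ref_value)
  per_level <- lapply(levels, function(lev) {
    if (isTRUE(all.equal(lev, ref_value))) ref else run_level(lev)
  })
  safe_ratio <- function(x, ref) {
    out <- x / ref
    out[rep_len(abs(ref) <= 1e-12, length(x))] <- NA_real_
    out
  }
  curves <- lapply(seq_along(levels), function(i) {
    lev <- per_level[[i]]
    data.frame(level = levels[i], bin = seq_len(n_bins),
               v_mid = (seq_len(n_bins) - 0.5) / n_bins,
               n = lev$bin_n, mean_dw = lev$bin_dw,
               normalized_dw = safe_ratio(lev$bin_dw, ref$bin_dw))
  })
  structure(
    list(parameter = parameter, levels = levels,
         mean_dw = vapply(per_level, `[[`, numeric(1), "mean_dw"),
         normalized_mean_dw = safe_ratio(
           vapply(per_level, `[[`, numeric(1), "mean_dw"), ref$mean_dw),
         binned = do.call(rbind, curves),
         reference = list(value = ref_value, mean_dw = ref$mean_dw,
                          bin_dw = ref$bin_dw),
         n_seeds = n_seeds, base = base),
    class = "plasticity_sweep"
  )
}

#' @export
print.plasticity_sweep <- function(x, ...) {
  cat(sprintf("plasticity_sweep over %s (%d matched seeds)\n", x$parameter, x$n_seeds))
  print(data.frame(level = x$levels, mean_dw = x$mean_dw,
                   normalized = x$normalized_mean_dw), row.names = FALSE)
  invisible(x)
}

#' Reinstatement sweep over dendritic inhibition
#'
#' Starting from the late-adult configuration, progressively raises the
#' dendritic inhibition level and measures the change in synaptic weights
#' relative to the late-adult reference run (the first level), using matched
#' per-seed noise substreams spawned from the base seed.
#'
#' @param base a late-adult [sim_config()] (its `seed` spawns the substreams;
#'   the run at the base parameter value is the normalization reference).
#' @param levels strictly increasing inhibition levels
#'   (default `c(0.2, 0.3, 0.4, 0.5)`).
#' @param n_seeds number of matched seeds per level.
#' @param n_bins responsiveness bins for the binned curves.
#' @return A `plasticity_sweep`: overall and per-responsivity-bin mean weight
#'   change per level, normalized to the late-adult reference run. Bins whose
#'   reference change is ~0 are reported `NA`, never infinite.
#' @export
sweep_inhibition <- function(base, levels = c(0.2, 0.3, 0.4, 0.5),
                             n_seeds = 20, n_bins = 5) {
  stopifnot(inherits(base, "sim_config"))
  run_sweep(base, "I_inh", levels, n_seeds, n_bins)
}

#' Reinstatement sweep over homeostatic downscaling
#'
#' As [sweep_inhibition()], but inhibition stays fixed at the late-adult
#' value while the downscaling rate A2 is raised from its weak late-adult
#' value through stronger levels.
#'
#' @param base a late-adult [sim_config()].
#' @param levels strictly increasing A2 levels (default
#'   `c(0.6, 0.7, 0.8, 0.9) * 1e-4`); normalization is to the run at the
#'   base `A2`.
#' @param n_seeds,n_bins see [sweep_inhibition()].
#' @return A `plasticity_sweep`.
#' @export
sweep_downscaling <- function(base, levels = c(0.6, 0.7, 0.8, 0.9) * 1e-4,
                              n_seeds = 20, n_bins = 5) {
  stopifnot(inherits(base, "sim_config"))
  run_sweep(base, "A2", levels, n_seeds, n_bins)
}
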