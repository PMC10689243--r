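# Brute-force reference integrator for the two-compartment rate model.
# Deliberately naive (scalar loops, no shortcuts) and fed the same pre-drawn
# noise arrays as the package integrator, so agreement checks are per-element.
oracle_simulate <- function(cfg, noise) {
  N <- cfg$N; Tn <- cfg$T_steps; dt <- cfg$dt
  w <- 1 + noise$xi
  r <- cfg$r0
  W <- matrix(NA_real_, Tn, N)
  r_traj <- numeric(Tn)
  for (t in 1:Tn) {
    phase <- (t - 1) %% (cfg$T_on + cfg$T_off)
    g <- if (cfg$gate_stimulus) as.numeric(phase < cfg$T_on) else 1
    r_i <- numeric(N)
    for (i in 1:N) {
      ri <- cfg$r0 + g * noise$v[i] + cfg$alpha * r + noise$zeta[i, t]
      r_i[i] <- if (cfg$rectify_presyn && ri < 0) 0 else ri
    }
    I_dend <- sum(w * r_i) / N - cfg$I_inh_stim
    I_soma <- cfg$I_ffw + (cfg$r0 + noise$u_exc[t]) - (cfg$r0 + noise$u_inh[t])
    inner <- if (I_dend > 0) I_dend else 0
    drive <- I_soma + inner
    if (drive < 0) drive <- 0
    r_new <- r + dt / cfg$tau * (-r + drive)
    for (i in 1:N) {
      heb <- cfg$A1 * r_i[i] * (r_i[i] - cfg$r0) * r * (1 - cfg$I_inh_stim)
      w[i] <- w[i] + dt * (heb - cfg$A2 * r)
    }
    r <- r_new
    W[t, ] <- w
    r_traj[t] <- r
  }
  list(W = W, r = r_traj)
}

# Draw a complete noise bundle for a config (used to share streams between
# the package integrator and the oracle).
draw_noise <- function(cfg, seed) {
  set.seed(seed)
  list(v = runif(cfg$N), xi = rnorm(cfg$N, 0, cfg$w_init_sd),
       zeta = matrix(rnorm(cfg$N * cfg$T_steps, 0, cfg$presyn_noise_sd),
                     nrow = cfg$N),
       u_exc = runif(cfg$T_steps, 0, cfg$soma_noise_max),
       u_inh = runif(cfg$T_steps, 0, cfg$soma_noise_max))
}

# Zeroed noise bundle with weights forced to exactly 1 and v as given.
silent_noise <- function(cfg, v = 0) {
  list(v = rep(v, cfg$N), xi = rep(0, cfg$N),
       zeta = matrix(0, cfg$N, cfg$T_steps),
       u_exc = rep(0, cfg$T_steps), u_inh = rep(0, cfg$T_steps))
}
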