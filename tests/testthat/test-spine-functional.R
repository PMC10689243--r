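make_dff <- function(v, rate = 30) dff_trace(v, rate, threshold_pct = 15)

test_that("an exact mixture recovers its scaling coefficient", {
  set.seed(1)
  d <- apply_dff_threshold(abs(rnorm(600, 30, 25)), 15)
  expect_equal(fit_dendrite_scaling(0.5 * d, d), 0.5, tolerance = 1e-10)
  expect_warning(k0 <- fit_dendrite_scaling(d, rep(0, 600)), "never active")
  expect_equal(k0, 0)
})

test_that("kappa is recovered from a noisy generator mixture", {
  # spine-local events here are spontaneous (not stimulus-locked), so they
  # rarely coincide with the dendritic events the fit conditions on
  spec <- generator_spec("young_control", seed = 21)
  gs <- gen_spine_dendrite(spec, n_spines = 6, schedule = stimulus_schedule(3, 85),
                           kappa = 0.7, coupling = 0, spont_rate_hz = 0.08)
  kappas <- vapply(gs$spines, fit_dendrite_scaling, numeric(1),
                   dendrite = gs$dendrite)
  expect_true(all(kappas >= 0.6 & kappas <= 0.8))
})

test_that("dendrite subtraction is safe and exact in the limiting cases", {
  set.seed(2)
  dend <- make_dff(apply_dff_threshold(abs(rnorm(900, 30, 25)), 15))
  # pure back-propagating signal: corrected is identically zero
  spine_bap <- make_dff(0.6 * dend$values)
  corr <- subtract_dendrite(spine_bap, dend, kappa = 0.6)
  expect_equal(corr$values, rep(0, 900))
  # spine-only events with a silent dendrite pass through unchanged
  silent <- make_dff(rep(0, 900))
  spine_only <- make_dff(apply_dff_threshold(abs(rnorm(900, 20, 20)), 15))
  expect_equal(subtract_dendrite(spine_only, silent, kappa = 0.7)$values,
               spine_only$values)
  # pointwise bounded by the raw spine trace and nonnegative
  mixed <- make_dff(apply_dff_threshold(spine_only$values + 0.7 * dend$values, 15))
  corr2 <- subtract_dendrite(mixed, dend)
  expect_true(all(corr2$values <= mixed$values + 1e-12))
  expect_true(all(corr2$values >= 0))
})

test_that("subtraction retains spine-only events and rejects coincident ones", {
  rate <- 30
  n <- 2700  # 90 s
  kern <- exp(-(0:120) / (rate * 1.5))
  place <- function(onsets) {
    v <- rep(0, n)
    for (o in onsets) {
      idx <- o:min(o + 120, n)
      v[idx] <- v[idx] + 60 * kern[seq_along(idx)]
    }
    v
  }
  spine_onsets <- seq(100, 1400, length.out = 10)
  dend_onsets <- seq(1600, 2600, length.out = 10)
  dend <- place(dend_onsets)
  spine <- place(spine_onsets) + 0.7 * dend
  corr <- subtract_dendrite(make_dff(apply_dff_threshold(spine, 15)),
                            make_dff(apply_dff_threshold(dend, 15)))
  ev <- detect_events(corr)$event_times
  n_spine <- sum(vapply(spine_onsets / rate, function(t0)
    any(abs(ev - t0) < 0.5), logical(1)))
  n_spurious <- sum(vapply(ev, function(t)
    all(abs(t - spine_onsets / rate) >= 0.5), logical(1)))
  expect_gte(n_spine, 9)
  expect_lte(n_spurious, 1)
})

test_that("time-locked fractions follow the schedule arithmetic", {
  sched <- stimulus_schedule(n_trials = 3, trial_s = 80, on_s = 3, off_s = 2)
  expect_equal(nrow(sched), 48L)  # 16 flicker events per 80 s trial
  rate <- 30
  n_frames <- ceiling(max(sched$end_s) + 5) * rate
  # responses on the first 20 stimulus events only
  v <- rep(0, n_frames)
  for (o in sched$start_s[1:20]) {
    idx <- round(o * rate) + 5 + 0:8
    v[idx] <- 60
  }
  frac <- timelocked_fraction(make_dff(v), sched)
  expect_equal(frac, 20 / 48)
  expect_equal(round(frac, 4), 0.4167)
  # a spine responding to every event is visual for any threshold below 1
  v_all <- rep(0, n_frames)
  for (o in sched$start_s) v_all[round(o * rate) + 5 + 0:8] <- 60
  expect_equal(timelocked_fraction(make_dff(v_all), sched), 1)
})

test_that("null-coupled spines are rarely labeled visual", {
  spec <- generator_spec("young_control", seed = 33)
  sched <- stimulus_schedule(n_trials = 3, trial_s = 85)
  gs <- gen_spine_dendrite(spec, n_spines = 60, schedule = sched,
                           kappa = 0, coupling = 0, spont_rate_hz = 0.08,
                           dend_rate_hz = 0, dend_stim_p = 0)
  dummy <- dummy_schedule(sched)
  spec2 <- generator_spec("young_control", seed = 34)
  dark <- gen_spine_dendrite(spec2, n_spines = 60, schedule = sched,
                             kappa = 0, coupling = 0, spont_rate_hz = 0.08,
                             dend_rate_hz = 0, dend_stim_p = 0)
  res <- classify_responsivity(gs$spines, sched, dark$spines, dummy)
  expect_true(all(res$timelocked_fraction >= 0 & res$timelocked_fraction <= 1))
  # by the 80th-percentile construction plus the 20% floor
  se2 <- 2 * sqrt(0.2 * 0.8 / 60)
  expect_lte(mean(res$label == "visual"), 0.2 + se2)
})

test_that("time-locked fraction increases with generator coupling", {
  sched <- stimulus_schedule(n_trials = 3, trial_s = 85)
  levels <- c(0, 0.2, 0.4, 0.6, 0.8)
  med <- vapply(seq_along(levels), function(i) {
    spec <- generator_spec("young_control", seed = 40 + i)
    gs <- gen_spine_dendrite(spec, n_spines = 20, schedule = sched,
                             kappa = 0, coupling = levels[i],
                             dend_rate_hz = 0, dend_stim_p = 0)
    median(vapply(gs$spines, timelocked_fraction, numeric(1), schedule = sched))
  }, numeric(1))
  expect_gt(cor(levels, med, method = "spearman"), 0)
})

test_that("clustering probabilities match closed forms", {
  expect_error(clustering_probability("V"), "at least 2")
  allsame <- clustering_probability(rep("V", 6), n_shuffles = 10)
  expect_equal(allsame$match_prob, rep(1, 5))
  alt <- clustering_probability(rep(c("V", "N"), 5), n_shuffles = 10)
  expect_equal(alt$match_prob[1], 0)
  expect_equal(alt$match_prob[2], 1)
  # random labels p(V) = 0.3: offset-1 match probability -> p^2 + q^2 = 0.58
  set.seed(8)
  m1 <- replicate(600, {
    lab <- sample(c("V", "N"), 8, replace = TRUE, prob = c(0.3, 0.7))
    clustering_probability(lab, max_offset = 1, n_shuffles = 1)$match_prob
  })
  expect_equal(mean(m1), 0.3^2 + 0.7^2, tolerance = 0.02)
})

test_that("the shuffle null covers exchangeable branches", {
  set.seed(5)
  covered <- replicate(60, {
    lab <- sample(c("V", "N"), 10, replace = TRUE)
    cc <- clustering_probability(lab, max_offset = 1, n_shuffles = 200,
                                 seed = sample.int(1e6, 1))
    q <- quantile(cc$null_match[, 1], c(0.025, 0.975))
    cc$match_prob[1] >= q[1] && cc$match_prob[1] <= q[2]
  })
  expect_gte(mean(covered), 0.9)
})
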