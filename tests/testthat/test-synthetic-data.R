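test_that("generators are pure functions of spec and seed", {
  spec <- generator_spec("young_stim", seed = 42)
  sched <- stimulus_schedule(2, 40)
  a <- gen_cell_traces(spec, n_cells = 3, duration_s = 30, rate_hz = 6,
                       schedule = sched)
  b <- gen_cell_traces(spec, n_cells = 3, duration_s = 30, rate_hz = 6,
                       schedule = sched)
  expect_identical(a$traces, b$traces)
  expect_identical(a$truth$tuning, b$truth$tuning)
  g1 <- gen_spine_dendrite(spec, 3, sched)
  g2 <- gen_spine_dendrite(spec, 3, sched)
  expect_identical(g1$spines[[1]]$values, g2$spines[[1]]$values)
  expect_identical(gen_minis(spec, 2)$trains[[1]]$event_times,
                   gen_minis(spec, 2)$trains[[1]]$event_times)
  expect_identical(gen_profiles(spec, 2)[[1]]$spine,
                   gen_profiles(spec, 2)[[1]]$spine)
  expect_identical(gen_rcpt(spec, 3)$hits, gen_rcpt(spec, 3)$hits)
  expect_identical(gen_population(spec)$traces, gen_population(spec)$traces)
  # different seeds differ
  spec2 <- generator_spec("young_stim", seed = 43)
  expect_false(identical(gen_minis(spec2, 2)$trains[[1]]$event_times,
                         gen_minis(spec, 2)$trains[[1]]$event_times))
})

test_that("scenario presets plant effects with the expected directions", {
  yc <- generator_spec("young_control")
  ys <- generator_spec("young_stim")
  oc <- generator_spec("old_control")
  os <- generator_spec("old_stim")
  # young overstimulation: activity down, mEPSP amplitude down, mIPSP
  # frequency up, VGAT up, E-I coupling up, multiplicative downscaling
  expect_lt(ys$activity_gain, yc$activity_gain)
  expect_lt(ys$mepsp_amp_gain, 1)
  expect_gt(ys$mipsp_freq_gain, 1)
  expect_gt(ys$vgat_density_gain, 1)
  expect_gt(ys$ei_corr_shift, 0)
  expect_equal(ys$ee_corr_shift, 0)
  expect_lt(ys$scaling_factor, 1)
  # late-adult overstimulation: activity up, mEPSP amplitude up, mIPSP
  # frequency down, VGAT down, E-E coupling up, no downscaling
  expect_gt(os$activity_gain, oc$activity_gain)
  expect_gt(os$mepsp_amp_gain, 1)
  expect_lt(os$mipsp_freq_gain, 1)
  expect_lt(os$vgat_density_gain, 1)
  expect_gt(os$ee_corr_shift, 0)
  expect_equal(os$ei_corr_shift, 0)
  expect_equal(os$scaling_factor, 1)
  # more weakened spines in young than late adults after overstimulation
  expect_gt(ys$weaken_fraction, os$weaken_fraction)
  expect_error(generator_spec("custom", nonsense_field = 1))
})

test_that("noise-free cell traces reduce to baseline plus drift", {
  spec <- generator_spec("custom", seed = 5, trace_noise_sd = 0,
                         drift_pct_per_min = 12)
  g <- gen_cell_traces(spec, n_cells = 2, duration_s = 20, rate_hz = 10,
                       event_rate_hz = 0)
  tr <- g$traces[[1]]
  drift <- 12 / 100 * 100 / (60 * 10) * seq_along(tr)
  expect_equal(tr, 100 + drift, tolerance = 1e-12)
  expect_equal(g$truth$n_events, c(0L, 0L))
})

test_that("a planted rate doubling during flicker shows up in the AUC split", {
  # one 85 s flicker trial followed by 85 s of darkness; event rate doubles
  # during flicker-on epochs (tuning = 1)
  sched <- stimulus_schedule(n_trials = 1, trial_s = 85)
  spec <- generator_spec("young_control", seed = 8)
  g <- gen_cell_traces(spec, n_cells = 200, duration_s = 170, rate_hz = 6,
                       schedule = sched, event_rate_hz = 0.3,
                       tuning_range = c(1, 1))
  wins <- vapply(g$traces, function(f) {
    d <- compute_dff(f, g$background, rate_hz = g$rate_hz)
    activity_auc(d, sched, "visual") > activity_auc(d, sched, "dark")
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("generated minis match their planted rate and scenario gains", {
  spec <- generator_spec("young_control", seed = 19)
  g <- gen_minis(spec, n_cells = 30, duration_s = 60, rate_hz = 1)
  counts <- vapply(g$trains, function(t) length(t$event_times), numeric(1))
  expect_equal(mean(counts), 60, tolerance = 3 * sqrt(60 / 30) / 60)
  # inhibitory frequency gain of the young stim scenario
  ys <- generator_spec("young_stim", seed = 19)
  gi <- gen_minis(ys, n_cells = 30, polarity = "inhibitory", duration_s = 60)
  expect_equal(gi$truth$rate_hz, 1.5)
  expect_lt(gen_minis(ys, 1)$truth$amp_mv, gen_minis(spec, 1)$truth$amp_mv)
})

test_that("generated profiles carry recoverable planted structure", {
  spec <- generator_spec("young_control", seed = 23)
  prs <- gen_profiles(spec, n_dendrites = 20)
  rec <- vapply(prs, function(pr) {
    pk <- profile_peaks(pr$positions, pr$spine, pr$background)
    c(found = nrow(pk$peaks), planted = length(pr$truth$spine_centers))
  }, numeric(2))
  expect_equal(sum(rec["found", ]), sum(rec["planted", ]),
               tolerance = 0.15 * sum(rec["planted", ]))
  # planted widths match detected widths per dendrite
  pr <- prs[[1]]
  pk <- profile_peaks(pr$positions, pr$spine, pr$background)
  matched <- vapply(pr$truth$spine_centers, function(c0) {
    d <- abs(pk$peaks$center_um - c0)
    if (min(d) < 0.3) pk$peaks$width_um[which.min(d)] else NA_real_
  }, numeric(1))
  ok <- !is.na(matched)
  expect_gt(cor(matched[ok], pr$truth$spine_widths[ok]), 0.8)
})

test_that("planted protein levels are recoverable through colocalization", {
  spec <- generator_spec("young_control", seed = 31)
  prs <- gen_profiles(spec, n_dendrites = 15, noise_sd = 0.01)
  planted <- recovered <- numeric(0)
  for (pr in prs) {
    sp <- profile_peaks(pr$positions, pr$spine, pr$background)
    prot <- profile_peaks(pr$positions, pr$protein, pr$background)
    cr <- colocalized_ratio(prot, sp, tolerance_um = 0.3)
    for (i in seq_along(pr$truth$spine_centers)) {
      d <- abs(cr$center_um - pr$truth$spine_centers[i])
      if (length(d) && min(d) < 0.3 && !is.na(cr$ratio[which.min(d)])) {
        planted <- c(planted, pr$truth$protein_levels[i] /
                       pr$truth$spine_widths[i])
        recovered <- c(recovered, cr$ratio[which.min(d)])
      }
    }
  }
  expect_gt(length(planted), 20)
  expect_gt(cor(planted, recovered, method = "spearman"), 0.8)
})

test_that("profile scaling scenarios are recovered by the KS fit", {
  ctrl_spec <- generator_spec("young_control", seed = 44)
  stim_spec <- generator_spec("young_stim", seed = 45)
  widths_of <- function(spec) {
    unlist(lapply(gen_profiles(spec, n_dendrites = 30), function(pr)
      profile_peaks(pr$positions, pr$spine, pr$background)$peaks$width_um))
  }
  fit <- fit_scaling_factor(widths_of(ctrl_spec), widths_of(stim_spec))
  expect_equal(fit$factor, 0.8, tolerance = 0.08)
})

test_that("rCPT counts respect their planted rates", {
  spec <- generator_spec("young_control", seed = 55)
  rc <- gen_rcpt(spec, n_animals = 50, n_sessions = 7, trials_per_session = 100)
  expect_true(all(rc$hits + rc$misses == 50))
  expect_true(all(rc$mistakes + rc$correct_rejections == 50))
  m <- session_metrics(rc$hits, rc$misses, rc$mistakes, rc$correct_rejections)
  s1 <- rc$session == 1
  expect_equal(mean(m$hr[s1]), attr(rc, "truth")$hr0, tolerance = 0.03)
  expect_equal(mean(m$far), attr(rc, "truth")$far, tolerance = 0.02)
})
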