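test_that("peak detection handles flat, rectangular and Gaussian profiles", {
  x <- seq(0, 10, by = 0.01)
  # flat profile at background: no peaks
  flat <- profile_peaks(x, rep(100, length(x)), 100)
  expect_equal(nrow(flat$peaks), 0L)
  expect_equal(flat$density_per_um, 0)
  # rectangular bump of width 1.0 um at twice background
  y <- rep(100, length(x))
  y[x >= 3 & x < 4] <- 200
  rect <- profile_peaks(x, y, 100)
  expect_equal(nrow(rect$peaks), 1L)
  expect_equal(rect$peaks$width_um, 1.0, tolerance = 0.02)
  expect_equal(rect$density_per_um, 0.1)
  # Gaussian bump: width equals the analytic 1.15x-background crossing
  s <- 0.3
  g <- 100 * (1 + 0.5 * exp(-(x - 5)^2 / (2 * s^2)))
  analytic <- 2 * s * sqrt(2 * log(0.5 / 0.15))
  gp <- profile_peaks(x, g, 100)
  expect_equal(nrow(gp$peaks), 1L)
  expect_equal(gp$peaks$width_um, analytic, tolerance = 0.01)
  expect_equal(gp$peaks$center_um, 5, tolerance = 0.01)
  expect_error(profile_peaks(c(0, 1), c(1, 2), 100))
})

test_that("peak detection is invariant to a common intensity rescaling", {
  spec <- generator_spec("young_control", seed = 12)
  pr <- gen_profiles(spec, n_dendrites = 1)[[1]]
  a <- profile_peaks(pr$positions, pr$spine, pr$background)
  b <- profile_peaks(pr$positions, 5.5 * pr$spine, 5.5 * pr$background)
  expect_equal(a$peaks, b$peaks, tolerance = 1e-12)
})

test_that("colocalization ratios divide protein height by spine width", {
  x <- seq(0, 10, by = 0.01)
  bump <- function(c0, h, s = 0.25) h * exp(-(x - c0)^2 / (2 * s^2))
  spines <- profile_peaks(x, 100 * (1 + bump(3, 1) + bump(7, 1)), 100)
  protein <- profile_peaks(x, 100 * (1 + bump(3.05, 2)), 100)
  cr <- colocalized_ratio(protein, spines, tolerance_um = 0.25)
  expect_equal(nrow(cr), 2L)
  expect_equal(cr$ratio[1], protein$peaks$height[1] / spines$peaks$width_um[1])
  expect_true(is.na(cr$ratio[2]))  # no protein peak near the second spine
  # disjoint frames: everything undefined
  far <- profile_peaks(x, 100 * (1 + bump(9.5, 2)), 100)
  expect_true(all(is.na(colocalized_ratio(far, spines)$ratio[1])))
})

test_that("exact multiplicative pairs are identified on the factor grid", {
  set.seed(3)
  ctrl <- rlnorm(500, 0, 0.4)
  for (s_true in c(0.6, 0.8, 1.0, 1.25)) {
    fit <- fit_scaling_factor(ctrl, s_true * ctrl)
    expect_lt(abs(fit$factor - s_true), 0.001 + 1e-9)
    expect_lt(fit$ks_distance, 1e-12)
    expect_lte(fit$ks_distance, fit$seed_ks)
  }
  expect_error(fit_scaling_factor(c(1, -1), c(1, 2)))
})

test_that("a noisy resampled scaling factor is recovered near the truth", {
  set.seed(7)
  ctrl <- rlnorm(500, 0, 0.4)
  stim <- 0.75 * sample(ctrl, 500, replace = TRUE) * rnorm(500, 1, 0.05)
  fit <- fit_scaling_factor(ctrl, stim)
  expect_true(fit$factor >= 0.72 && fit$factor <= 0.78)
  # KS distance agrees with the standard two-sample statistic
  expect_equal(fit$ks_distance,
               unname(suppressWarnings(
                 ks.test(fit$factor * ctrl, stim)$statistic)),
               tolerance = 1e-9)
})

test_that("structural E:I is the ratio of normalized profile integrals", {
  x <- seq(0, 10, by = 0.01)
  ei <- structural_ei(x, rep(200, length(x)), 100, x, rep(200, length(x)), 100)
  expect_equal(ei$ratio, 1)
  ei2 <- structural_ei(x, rep(300, length(x)), 100, x, rep(150, length(x)), 100)
  expect_equal(ei2$ratio, 2)
  expect_error(structural_ei(x, rep(1, length(x)), 100, x, rep(0, length(x)), 100))
})

test_that("planted structural E:I is recovered from generated profiles", {
  # spine and VGAT channels built to a known integral ratio of 0.6
  x <- seq(0, 20, by = 0.02)
  set.seed(11)
  ratios <- replicate(100, {
    spine <- 100 * (1.2 + 0.05 * rnorm(length(x)))
    vgat <- 100 * (2.0 + 0.05 * rnorm(length(x)))
    structural_ei(x, spine, 100, x, vgat, 100)$ratio
  })
  expect_equal(mean(ratios), 0.6, tolerance = 0.1 * 0.6)
})

test_that("c-Fos positivity uses the 20%-above-background rule", {
  m <- cfos_quantify(c(1.0, 1.1, 1.3) * 50, background = 50)
  expect_equal(m$positive_fraction, 1 / 3)
  expect_equal(cfos_quantify(c(1.0, 1.19, 1.2) * 10, 10)$positive_fraction, 0)
  # planted 40% positives at 1.5x background
  set.seed(5)
  n <- 300
  pos <- runif(n) < 0.4
  inten <- ifelse(pos, 1.5, 1.0) * 100 * rnorm(n, 1, 0.03)
  frac <- cfos_quantify(inten, 100)$positive_fraction
  expect_equal(frac, 0.4, tolerance = 3 * sqrt(0.4 * 0.6 / n))
})

test_that("weak/strong expression splits at the control 30th percentile", {
  set.seed(6)
  control_pool <- rlnorm(500, 0, 0.3)
  m <- cfos_quantify(rlnorm(400, 0, 0.3) * 80, background = 50,
                     control_pool = control_pool)
  cutoff <- quantile(control_pool, 0.3, names = FALSE)
  expect_identical(m$neurons$expression == "weak",
                   m$neurons$normalized <= cutoff)
})

test_that("the bootstrap distribution matches binomial closed forms", {
  # all positive: degenerate at 100%
  b <- cfos_bootstrap(rep(TRUE, 40), n_boot = 100, batch = 10)
  expect_equal(b$replicates, rep(100, 100))
  expect_equal(cfos_bootstrap(TRUE, n_boot = 50)$sd, 0)
  # true fraction 0.5, batch 10: replicate s.d. ~ sqrt(0.25/10)*100
  flags <- rep(c(TRUE, FALSE), 100)
  b2 <- cfos_bootstrap(flags, n_boot = 500, batch = 10, seed = 2)
  expect_equal(b2$mean, 50, tolerance = 3 * 15.81 / sqrt(500) / 50 * 100)
  expect_equal(b2$sd, sqrt(0.25 / 10) * 100, tolerance = 0.1 * 15.81)
  # bootstrap mean converges to the empirical fraction
  flags2 <- runif(200) < 0.37
  b3 <- cfos_bootstrap(flags2, n_boot = 1e4, batch = 10, seed = 3)
  expect_lt(abs(b3$mean - 100 * mean(flags2)), 1)
})
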