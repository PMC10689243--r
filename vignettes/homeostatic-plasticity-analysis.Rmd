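---
title: "Methods: homeostatic plasticity simulation and analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homeostatic plasticity simulation and analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homeoscale)
```

This vignette documents the models, conventions and numerical choices
behind `homeoscale`: a two-compartment plasticity simulator and the suite
of analysis procedures used to quantify homeostatic regulation of cortical
activity — calcium trace metrics, dendritic spine signal extraction,
assembly correlations, structural synaptic measures, miniature-event
statistics and touchscreen behavior — together with the synthetic-data
generators the test suite runs them against.

## The two-compartment plasticity model

A single postsynaptic rate neuron receives somatic input
$I_{soma} = I_{ffw} + r_{exc} - r_{inh}$ and dendritic input
$I_{dend} = \frac{1}{N}\sum_i w_i r_i - I_{inh}$, and integrates

$$\tau \frac{dr}{dt} = -r + [\, I_{soma} + [ I_{dend} ]_+ \,]_+$$

with nested rectification exactly as written (the inner bracket prevents a
net-inhibited dendrite from withdrawing somatic drive; the outer keeps the
rate drive nonnegative). Weights follow

$$\frac{dw_i}{dt} = A_1\, r_i (r_i - r_0)\, r\, (1 - I_{inh}) - A_2\, r$$

— a presynaptically thresholded Hebbian term, gated by dendritic
inhibition, plus homeostatic downscaling proportional to postsynaptic
activity. Presynaptic rates are
$r_i(t) = r_0 + v_i + \alpha r(t) + \zeta(t)$, with visual responsiveness
$v_i \sim U(0,1)$ drawn once per run.

Parameters and defaults (all in the model's arbitrary time unit, with
$dt = 1$ and $\tau = 10$): $I_{ffw} = 0.5$, $r_0 = 1$, $N = 200$ inputs,
$T = 10{,}000$ steps, stimulus alternating $T_{on} = T_{off} = 100$ steps,
$A_1 = 10^{-4}$, $\alpha = 0.1$. The two age regimes differ only in their
response to overstimulation: young adults raise dendritic inhibition to
$I_{inh} = 0.4$ and downscale at $A_2 = 0.56\times10^{-4}$; late adults
keep $I_{inh} = 0.2$ and downscale at $A_2 = 0.48\times10^{-4}$. The
simulator models the overstimulation phase only, with the initial weights
$w_i = 1 + \xi$, $\xi \sim N(0, 0.1)$, standing for the baseline state.

Design choices where the model statement left room:

- **Stimulus gating.** The presynaptic rate equation lists $v_i$
  unconditionally, while the stimulus description alternates the visual
  drive on/off over $T_{on}/T_{off}$. We implement the gated form ($v_i$
  present only during on-epochs, starting with an on-epoch), which
  reconciles both statements; `gate_stimulus = FALSE` restores the
  ungated variant.
- **Somatic noise.** $r_{exc}$ and $r_{inh}$ each carry uniform $(0, 0.1)$
  noise. A single shared draw would cancel exactly in
  $r_{exc} - r_{inh}$ and make the terms inert, so the two are drawn
  independently each step; their difference is a symmetric triangular
  jitter around zero.
- **Noise schedule.** $\xi$ is drawn once at initialization; $\zeta$ is
  redrawn per step and per input; the somatic uniforms per step. With a
  supplied noise bundle (`noise =`) the integrator is a deterministic map,
  which is how the test suite checks it element-for-element against an
  independent brute-force integrator.
- **Rectification of presynaptic rates.** With noise s.d. 0.1, $r_i$ can
  go negative; negative rates are unphysical and would flip the sign of
  the Hebbian product, so $r_i$ is rectified at zero before entering the
  dendritic sum and the weight update (`rectify_presyn = FALSE` disables
  this).
- **No weight clipping.** Weights may cross zero; excursions are counted
  and reported (`n_negative_weights`) rather than clipped, since clipping
  would distort the sweep monotonicity the model is used to demonstrate.
- **Update order.** Explicit Euler: each step computes presynaptic rates
  from the pre-update $r$, then the rate update and the weight update both
  from that same state. A non-finite state aborts with the step index and
  offending quantity.

### Reinstatement sweeps

`sweep_inhibition()` and `sweep_downscaling()` start from the late-adult
configuration and raise $I_{inh}$ through $\{0.2, 0.3, 0.4, 0.5\}$ or
$A_2$ through $\{0.6, 0.7, 0.8, 0.9\}\times10^{-4}$. The downscaling
levels are read as $\times 10^{-4}$ so they bracket the regime values
($0.48$–$0.56 \times 10^{-4}$); any other magnitude would either not move
the model or destroy it. Each level runs the same per-seed substreams
(spawned from the base seed, so levels are matched-seed by construction)
and reports mean weight change overall and per responsiveness bin,
normalized to the late-adult reference run. A reference bin with change
within $10^{-12}$ of zero yields `NA`, never infinity. Because the
reference run *is* the base configuration, a level equal to the base value
normalizes to exactly 1.

The two sweeps are summarized differently on purpose: inhibition
suppresses the Hebbian term, whose magnitude grows with $v$, so its effect
is compared across bins as the *absolute* change from the reference;
downscaling subtracts a $v$-independent amount, so its bin profile is
compared as *relative* change, which is largest where the reference change
is smallest (the nonvisual bins).

## Calcium trace processing

`compute_dff()` background-subtracts, estimates a drifting baseline
$F_0$ as a running 10th percentile over a 30 s window (both configurable
and recorded in the output), forms $100\,(F - F_0)/F_0$ and zeroes values
below 15 %ΔF/F₀. Conventions:

- The 15% threshold is an **absolute** ΔF/F₀ floor; a
  `threshold_mode = "relative_max"` variant (15% of the trace maximum) is
  provided since the printed "(15%)" admits either reading.
- The running percentile is evaluated at anchor frames every eighth of the
  window and linearly interpolated; the baseline is slow by construction,
  so this changes nothing at transient timescales and keeps multi-cell
  processing fast. A nonpositive $F_0$ anywhere rejects the trace with a
  diagnostic rather than producing unbounded ratios.
- Thresholding is idempotent, and ΔF/F₀ is invariant to a common positive
  rescaling of raw and background (both are asserted in tests).
- Frames are 0-based; all epoch windows are half-open `[start, end)`
  seconds.

Activity is quantified as the trapezoidal AUC of the thresholded trace per
second (`activity_auc()`), over the full trace, the flicker-on epochs, or
their complement; epoch edges are interpolated so a partition of a window
integrates additively. Events (`detect_events()`) are maximal
suprathreshold runs of at least 2 frames — single-frame blips are treated
as noise. Baseline normalization supports both conventions in use:
per-cell subtraction and division by the baseline-population mean.
Activity classes are quartile bands of a reference (control) distribution
with closed-left boundaries: low $\le Q_1 <$ middle $\le Q_3 <$ high.

## Spine signal extraction and visual responsivity

The spine ROI signal mixes spine-local calcium with the global dendritic
signal. `fit_dendrite_scaling()` estimates the mixing coefficient
$\kappa$ as a Theil–Sen (median-of-pairwise-slopes) fit of spine on
dendrite restricted to dendrite-active frames: the median slope resists
spine-only events that would inflate an ordinary least-squares slope.
Above 400 active frames the fit subsamples evenly (deterministically).
$\kappa$ is clipped at zero, and a never-active dendrite yields
$\kappa = 0$ with a warning. `subtract_dendrite()` returns
$\max(\text{spine} - \kappa\,\text{dendrite}, 0)$ re-thresholded, so the
corrected trace is pointwise between 0 and the raw spine trace.

`classify_responsivity()` computes, per spine, the fraction of stimulus
events followed by a time-locked event onset. The response window is
`[stimulus onset, offset + 0.5 s)`; the half-second extension accommodates
the slow indicator rise and is configurable since no window is canonical.
The null is built by scoring the same spines' dark-period activity against
a dummy schedule with the identical epoch structure. A spine is visual iff
its fraction exceeds **both** the 80th percentile of the null fractions
and the fixed 0.20 floor — the conjunctive reading of the two published
criteria; the `max()` of the two cutoffs makes the floor binding exactly
when the null is permissive. By construction at most ~20% of null-coupled
spines can pass, which the calibration test checks at 200 synthetic
spines.

Spatial clustering along a branch (`clustering_probability()`) scores
label matches at each positional offset (both directions, no wraparound;
ends contribute only defined offsets) and compares against a
label-shuffling null; for exchangeable labels the observed match
probability falls inside the central 95% of the shuffle distribution, a
property the tests verify. Comparing observed and shuffled distributions
formally is delegated to a standard rank-sum test.

## Assembly correlations

`pairwise_correlations()` computes Pearson $r$ and two-sided $p$ for every
neuron pair on thresholded (not binarized) traces, optionally restricted
to flicker-on frames. Pairs with a zero-variance member are undefined and
excluded downstream. A pair qualifies for assembly strength when
$r > 0$ and $p < 0.05$, uncorrected — no multiple-testing procedure is
applied by default because none is part of the published convention; a
Benjamini–Hochberg option exists behind `p_adjust = "BH"`. Channel means
(E–E and E–I per excitatory neuron, I–I per inhibitory neuron) average
only qualifying partners, and a neuron with none is `NA`, never 0 — a zero
would masquerade as "present but uncorrelated". Session change is the
post/baseline ratio per neuron and channel; a zero baseline is undefined
with a warning.

## Structural quantification

Intensity profiles along dendrites are normalized to background;
`profile_peaks()` finds maximal runs exceeding 1.15× background. Width —
the spine-size proxy — is measured at the threshold crossing (linearly
interpolated between samples), not at half-maximum, matching the
">15% of background" peak definition; peaks narrower than 0.1 µm are
discarded as single-sample noise. Density is peak count over profile
length. Peak measures are invariant to a common rescaling of profile and
background. Colocalization matches protein peaks to spine peaks within
0.25 µm (no published distance exists; the value is of the order of a
spine head) and reports protein peak height over spine width, `NA` for
unmatched spines.

The multiplicative scaling test seeds a factor at the ratio of medians,
then grid-searches factors over seed × [0.5, 1.5] in steps of 0.001
(the seed itself is always a candidate), minimizing the two-sample
Kolmogorov–Smirnov distance between the scaled control sample and the
overstimulated sample; ties resolve to the smallest factor. The KS
distance treats values closer than a $10^{-9}$ relative tolerance as tied
so that an exactly scaled copy of a sample sits at distance zero despite
floating-point rounding; `stats::ks.test` serves as the independent
cross-check in tests. Only multiplicative scaling is implemented — the
claim under test is multiplicative; an additive variant would be a
straightforward extension.

Structural E:I is the trapezoidal integral of the background-normalized
spine-channel profile over that of the VGAT channel. c-Fos positivity is
intensity > 1.2× background; weak expressers are those at or below the
30th percentile of the pooled normalized control distribution (values
normalized to their group mean before pooling; the boundary is closed).
The bootstrap resamples positivity flags in batches of 10, 500 times,
recording percent positive per replicate — at a true fraction of one half
the replicate spread has the binomial closed form
$\sqrt{0.25/10}\times100 \approx 15.8$ percentage points, which the tests
check.

## Miniature events and the E:I ratio

`detect_minis()` thresholds deflections of the holding-condition sign
(polarity is metadata, never inferred) at 2.5× the noise RMS, estimated
robustly as the MAD of the median-subtracted trace — event-free segments
are not identifiable a priori, and the MAD is insensitive to the sparse
events themselves. The comparison is strictly greater: a deflection at
exactly threshold is not an event. Three stabilizers, all documented
defaults: a 0.5 ms moving-average pre-smoothing before thresholding
(amplitudes are read from the unsmoothed trace), a 1 ms minimum event
width, and a 2 ms merge of adjacent crossings. On Gaussian noise these
make false events vanishingly rare while keeping recall at planted
5×RMS events essentially complete.

The primary E:I estimator is
$(mEPSP_{amp} \times mEPSP_{freq})/(mIPSP_{amp} \times mIPSP_{freq})$;
an AUC-based alternative (summed event area per second, E over I) is
exposed via `estimator = "auc"` since both appear in practice. The ratio
is exactly homogeneous — linear in each excitatory component, inverse in
each inhibitory one — and requires all four components positive.

## Behavior

`session_metrics()` computes HR, FAR and performance from already-filtered
counts (correction trials, which always re-present the non-target, are
excluded upstream by the task design). `learning_rate()` is the OLS slope
of performance on the 1-based session index — session index, not calendar
day, is the abscissa; sessions with undefined performance are dropped and
counted, never imputed.

## The synthetic-data generators

Every analysis has a generator producing its inputs with known ground
truth, all pure functions of a `generator_spec()` (scenario + master
seed):

- **Cell traces**: Poisson events, rate multiplied by $1 +$ tuning during
  flicker-on epochs, convolved with a single-exponential calcium kernel
  ($\tau = 1.5$ s, GCaMP6s-like), on a baseline with linear drift
  (10 %/min default) and Gaussian noise, plus a background ROI.
- **Spine/dendrite pairs**: built directly on the ΔF/F₀ scale as
  spine-local events (stimulus-coupled with planted probability) plus
  $\kappa \times$ dendrite plus noise.
- **Minis**: exponential inter-event intervals, lognormal amplitudes
  (mean-preserving parameterization), optional raw 20 kHz voltage with
  planted RMS noise and exponential-decay waveforms.
- **Profiles**: Gaussian bumps whose σ is set so the 1.15×background
  crossing width equals the planted width; colocalized protein levels;
  independent VGAT puncta.
- **rCPT sessions**: binomial outcome counts around a hit rate climbing at
  the planted slope and a flat false-alarm rate over seven sessions of 100
  trials.
- **Populations**: a Gaussian factor model (shared + class factors) with
  constant planted correlation blocks, valid by construction provided
  $\rho_{EI} \le \min(\rho_{EE}, \rho_{II})$.

Scenario presets (`young_control`, `young_stim`, `old_control`,
`old_stim`) plant effects whose *signs* encode the study design the
analyses assume — young overstimulation: activity down, mEPSP amplitude
down, mIPSP frequency up, VGAT density up, E–I coupling up, spine sizes
scaled by 0.8; late-adult overstimulation: activity up, mEPSP amplitude
up, mIPSP frequency down, VGAT down, E–E coupling up, no multiplicative
scaling. Magnitudes are round numbers serving as recovery-test ground
truth, not estimates of any real dataset. What the generators deliberately
do **not** emulate: imaging artifacts (motion, bleaching,
neuropil contamination), bursty or non-Poisson event statistics,
indicator nonlinearity and saturation, correlated noise across ROIs, and
electrode drift. Passing recovery tests therefore demonstrates internal
consistency of the estimators under the assumed statistical structure, not
robustness to everything real data can do.

## Problem sizes and tolerances

The test suite runs the simulator's oracle-equivalence check at $N = 20$,
$T = 500$ (agreement $\le 10^{-12}$ per element on a shared noise stream)
and the regime/sweep properties at the full $N = 200$, $T = 10{,}000$ over
20 matched seeds. Recovery checks use 200 null-coupled spines, 200
synthetic animals, 50 population seeds, 100 dendrites, and 500-sample
scaling fits — sizes at which Monte Carlo error is small against the
planted effects while the whole suite stays comfortably fast on one CPU.
The acceptance script (`scripts/acceptance.R`) recomputes the same
quantities with 5 simulator seeds per condition. Closed-form checks
(hand-integrated weight decay, AUC additivity, binomial bootstrap spread)
are asserted at $10^{-9}$–$10^{-10}$ relative; statistical checks at 2–3
standard errors of their own sampling noise.

## Known limitations

- The simulator is a rate model; no spiking, conductances, dendritic
  nonlinearities beyond the two rectifications, or fitting to recorded
  data.
- Image-plane processing (registration, ROI segmentation), calcium
  deconvolution and orientation/direction selectivity are out of scope;
  inputs are assumed to be extracted traces, profiles and counts.
- The responsivity null threshold is estimated from the supplied spine
  population; with few spines the 80th percentile is coarse.
- The Theil–Sen fit subsamples above 400 active frames; for pathological
  activity patterns the even subsampling could interact with periodic
  stimuli.
- `fit_scaling_factor()` assumes positive-valued measures; distributions
  with atoms at zero need pre-filtering.
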