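---
title: "Inferring perceptual segmentation maps from same/different judgments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring perceptual segmentation maps from same/different judgments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perceptseg)
```

perceptseg analyzes a trial-based paradigm for measuring how observers
subjectively segment images. An observer is instructed to divide an image
into K perceptual segments; on each trial two locations are cued and the
observer answers whether they fall in the *same* or *different* segments.
This vignette explains the estimation model, the statistics built on top of
it, the synthetic study conditions used for testing, and the numerical
choices the package makes where the design was genuinely open.

## The probabilistic segmentation map

The image is analyzed on a coarse grid (15×15 by default; the number of
trials a block needs is `cells * (K - 1)`, i.e. 225, 450, 675, 900 for
K = 2..5). Each cell $i$ carries a probability vector $p_i$ over the K
segment labels, parameterized by unconstrained scores through a softmax.
A trial cueing cells $i$ and $j$ is predicted to elicit "same" with
probability $s_{ij} = \sum_k p_{ik} p_{jk}$ — the chance that two
independent label draws from the two cells coincide. The fit maximizes

$$\mathcal{L} = \sum_{t} \big[ y_t \log s_{ij} + (1-y_t)\log(1-s_{ij}) \big]
  \;-\; \lambda \sum_{(i \sim j)} \lVert p_i - p_j \rVert^2,$$

where the penalty runs over 4-neighbor cell pairs and $\lambda = 5$ by
default. The penalty encodes the prior that perceptual segments are
spatially coherent, and it is what lets 225 binary answers constrain 225
label distributions. This estimator is the package's own: it is the
simplest model consistent with the paradigm (pairwise same-probability,
Bernoulli likelihood, smoothness prior), and its adequacy is established
behaviorally — on synthetic observers it recovers ground-truth maps with
median cell agreement above 95% at the standard schedule.

Derived objects: `argmax_map()` assigns each cell its most probable label
(ties break to the lowest label index, so results are deterministic);
`entropy_map()` reports the per-cell Shannon entropy in bits, a map of
*perceptual uncertainty* bounded by $\log_2 K$; `mean_uncertainty()`
averages it and rescales to percent of that maximum. All logs are base 2
throughout the package, so entropies and mutual information are in bits
and the entropy bound is exactly $\log_2 K$.

### Numerical choices

* **Optimization.** L-BFGS-B with the analytic gradient, initialized at
  uniform probabilities plus seeded Gaussian noise of magnitude $10^{-2}$
  to break the label-permutation symmetry. Convergence uses a relative
  objective tolerance of $10^{-9}$. This is deliberately strict: at looser
  tolerances (around $10^{-6}$) the optimizer can halt while the label
  field is still near the symmetric initialization, which looks converged
  but recovers maps barely above chance. The strict tolerance costs
  fractions of a second per block and removes that failure mode.
* **Label identifiability.** Segment indices carry no meaning across
  observers. `match_labels()` finds the label bijection maximizing cell
  agreement (exhaustive over K! ≤ 120 permutations) and is used only for
  evaluation against simulated ground truth, never for participant-facing
  output.
* **Coordinates.** Pixels are 0-based with x = column, y = row; grid cells
  are half-open with the final edge closed, so border pixels belong to the
  last cell.
* **Cue schedules.** `generate_cue_pairs()` balances cue endpoints so the
  per-cell usage counts differ by at most one; every cell is then
  constrained by data rather than only by the smoothness prior.

## Map similarity: Information Gain

`mutual_information()` computes the MI (bits) of the joint label histogram
of two maps over co-located cells; it is symmetric and invariant to
relabeling either map, which is exactly what comparing two observers
requires. Raw MI is biased by finite cell counts, so similarity is
reported as **Information Gain** against a spatial-shuffle null:
`information_gain()` permutes the spatial locations of one map's values
(n_perm = 10,000 by default, preserving the value marginals), and

$$\mathrm{IG} = 100 \cdot \frac{\mathrm{MI}_{obs} -
 \overline{\mathrm{MI}}_{null}}{\overline{\mathrm{MI}}_{null}} \; \%.$$

An IG of 0% means two maps are no more similar than two random maps with
the same label composition; genuinely shared spatial structure produces
IG in the $10^3$–$10^4\%$ range because the null mean is a small
finite-sample bias. The one-tailed p-value uses the add-one convention
$(1 + \#\{null \ge obs\})/(n_{perm}+1)$ so it is never zero. Continuous
(entropy) maps are first quantized into 8 equal-width bins over the pooled
range of both maps — MI needs discrete marginals, and pooling the range
keeps the two maps on a common scale. When the null mean is zero (e.g. a
constant map) the result is flagged `degenerate` with IG set to 0 rather
than raising an error.

Under the null (comparing a map to a shuffle of itself) the test is
calibrated: across seeded repetitions the rejection rate at α = 0.05 stays
near nominal, which the test suite checks over 200 repetitions.

## Screening structureless blocks

An observer who ignores the task produces responses unrelated to cue
positions. Such blocks must be excluded, and the natural screen is that
their maps lack *predictive* structure. A subtlety: the smoothness prior
makes even noise-fitted maps look spatially smooth, so no statistic of the
fitted map alone separates random responders from genuine segmenters.
`flag_structureless_block()` therefore cross-validates: it fits a map to
the odd-numbered trials and scores the inconsistency rate of the held-out
even-numbered trials against that map, comparing it (one-tailed) to the
null distribution obtained by shuffling the held-out responses relative to
their cue pairs — the same surrogate construction used to emulate random
responding. A genuine segmenter's held-out rate sits far below every
shuffled rate; a random responder's does not, and the block is flagged
(p > 0.05). The training fit scales λ by `n_train / trial_schedule(K)` so
the per-trial strength of the prior matches the full-schedule default;
without this the penalty dominates the halved likelihood and minimal
blocks collapse to a single label. `classify_consistency()` provides the
underlying per-trial consistent/inconsistent classification and the
block-level inconsistency rate.

## Reaction-time analyses

RT distributions are right-skewed, so central tendency uses medians with
percentile-bootstrap CIs (9,999 resamples; data are sorted before
resampling so results are invariant to trial order). `filter_rts()` drops
trials whose log-RT lies strictly above the within-block 90th percentile
(linear-interpolation percentile; the log base and time unit cannot change
the removed set). The filter's grouping is per block by default, with
pooled filtering available by passing `by = character()`.
`zscore_by_block()` standardizes each participant-by-stimulus block to
mean 0, SD 1 before pooling learning curves, flagging zero-variance blocks
instead of failing. `sliding_mean()` tracks the pooled learning curve with
a 500-trial window; `fit_trial_constant()` fits $RT = \alpha \cdot
2^{-t/\tau}$ by nonlinear least squares on the original scale — τ is the
number of trials that halves the reaction time. The fit initializes from
the exact log-linear regression (the global optimum for noiseless data)
and refines with Levenberg–Marquardt, so noiseless recovery is exact and
the fit is scale-equivariant. `inconsistency_delay()` estimates how much
longer inconsistent trials take, with a bootstrap CI.

## Gaze analyses

`clean_gaze()` removes blink samples and samples outside the image.
`gaze_density()` builds a per-pixel dwell map: each retained sample
carries one sampling interval (2 ms at 500 Hz) spread by an isotropic
Gaussian (σ = 10 px, truncated at 4σ as a square window). Kernels are
renormalized over in-image pixels, so total dwell time is conserved
exactly even at the border — boundary behavior is otherwise arbitrary and
mass conservation is the property downstream statistics rely on.
`downsample_density()` sums contained pixels into 15×15 cells
(mass-preserving). **Coverage** is deliberately threshold-free: the
percent of grid cells visited by at least one raw sample within a
cumulative window (`coverage_curve()` for the 1–10 s series, truncated at
the participant-determined viewing end). No fixation/saccade event parsing
is performed anywhere — dwell density, not event statistics, is the
analysis target.

## EEG analyses

The package consumes cleaned epochs (−500..1000 ms at 512 Hz, 64
channels); raw-signal preprocessing is upstream and out of scope.
`exclude_by_rt()` first drops the slowest 10% of epochs
(`ceiling(0.1 n)`, ties by epoch order) and then any epoch with RT above
2.5 s — in that order, since the percentile must be computed on the full
set. `rereference_average()` subtracts the channel mean at every time
point; `baseline_correct()` subtracts the −100..0 ms mean per channel and
epoch (a −25..0 ms window is available when short inter-trial intervals
contaminate the longer baseline; the two differ only by a per-channel
constant per epoch). `compute_erp()` averages epochs and optionally
collapses a channel subset — the occipital/parieto-occipital set
`O1, Oz, O2, PO7, PO3, POz, PO4, PO8` is the standard choice for
segmentation-related activity — and `average_erps()` aggregates with equal
weight per unit so participants with more blocks do not dominate cohorts.

Cohort statistics use Welch (unequal-variance) t-tests throughout, the
conservative default when only "independent-samples t-test" is specified.
`pointwise_ttest_windows()` tests every time sample and reports contiguous
runs of p < 0.05 lasting at least 50 ms, suppressing transient
fluctuations; `gfp()` implements Global Field Power as the spatial
*population* standard deviation across electrodes (so two channels at
±1 µV give exactly 1 µV), which is invariant to any common time-varying
offset and hence to re-referencing; `gfp_interval_tests()` samples the GFP
at 50-ms intervals (nearest sample, no interpolation) and tests each
point, uncorrected by design. The corrected alternative is
`cluster_permutation_test()`: pointwise tests form space-time clusters
(channel adjacency from a Delaunay triangulation of the 2-D layout,
built in-package with the Bowyer–Watson construction; positive and
negative effects clustered separately), clusters are scored by summed t,
and p-values come from the permutation distribution of the maximum
absolute cluster mass. `topomap_frame()` extracts per-channel values at a
time point, clipped to ±10 µV for display while keeping raw values.

## Synthetic study conditions

The generators encode one fixed set of study conditions; they are the
package's test bed, not tunable fixtures.

* **Ground truth.** Seeded Voronoi partitions of the grid: spatially
  compact K-region maps with every label present.
* **Textures.** A single white-noise image filtered by a spatially varying
  oriented band-pass filter, giving each region a controlled orientation
  and spatial frequency with continuous seams.
* **Observer.** Each cue independently samples a label from its cell (the
  true label with probability `certainty = 0.85`, others uniform);
  "same" iff the samples match; with probability `lapse = 0.05` the
  response is replaced by a fair coin. These values put inconsistency
  rates in the 0.2–0.5 band typical of human blocks. RTs follow
  $\alpha\,2^{-t/\tau}$ with multiplicative lognormal noise
  (sd 0.1 on the log scale); the NT-like preset uses α = 0.9 s, τ = 18.4
  trials, the ASD-like preset α = 1.2 s, τ = 21.9 trials, matching the
  slower-and-slower-learning contrast the paradigm is designed to detect.
* **Gaze.** Fixation centers are Gaussian around the image center
  (spread 55 px NT-like vs 85 px ASD-like; viewing 9 vs 10.5 s) at a
  typical free-viewing rate of ~3 fixations/s, joined by constant-velocity
  saccade paths and sampled at 500 Hz. Saccade samples matter: without
  them coverage is limited by the fixation count and the spread contrast
  never reaches the coverage statistic. With them, 5-s coverages land
  around 25% vs 37%, and the ASD-like > NT-like ordering is robust across
  seeds. The generator is distributional — it knows nothing about image
  content, so it cannot emulate saliency-driven gaze.
* **EEG.** Epochs are Gaussian-bump components weighted by a posterior
  scalp profile plus seeded 1/f-with-white-floor noise (~8 µV RMS per
  sample). The NT-like preset has a small 200-ms anticipatory component
  and a 6 µV main component at 350 ms; the ASD-like preset shifts
  latencies +75 ms and scales amplitudes ×0.7. With 8 simulated subjects
  per cohort this reproduces the qualitative pattern the statistics are
  built to detect: later onset, lower amplitude, significant pointwise and
  GFP differences inside the 250–400 ms image-presentation window.

What passing tests on these generators shows — and what it does not: the
pipeline recovers known structure under its own observer model and detects
injected cohort contrasts at realistic noise levels. Real data add
everything the generators omit (content-driven gaze, non-stationary
attention, correlated cue sampling, ERP component variability across
subjects), so the tests validate the machinery, not any empirical claim
about human cohorts.

## Problem sizes and reproducibility

Every stochastic operation takes an explicit seed; `run_pipeline()`
derives per-stage seeds from one master seed, so a configuration reproduces
byte-identically. The test suite runs the heavier property checks at
deliberately moderate sizes chosen as the smallest that exercise the
claims — e.g. 20 seeded blocks for map recovery at twice the minimum
schedule, 200 repetitions for IG null calibration with 199 permutations
each, 20 seeds × 8 subjects per cohort for the EEG contrast — while
single-shot analyses use the full defaults (10,000 IG permutations, 9,999
bootstrap resamples).

## Known limitations

* The estimator is a faithful independent implementation of the paradigm's
  published description, not a numerical replica of any reference code;
  equivalence is behavioral (map recovery), not bitwise.
* MI-based similarity is computed on the analysis grid only; pixel-level
  similarity is out of scope.
* No multiple-testing correction is applied across images or across
  pointwise/GFP tests (by design, mirroring the uncorrected reporting
  convention); the cluster permutation test is the corrected option.
* The gaze module analyzes the initial free-viewing epoch; trial-period
  gaze and fixation-related potentials are out of scope.
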