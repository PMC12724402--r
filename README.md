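# perceptseg

Tools for characterizing **perceptual segmentation** — how an observer
subjectively partitions an image into segments — from trial-based
same/different judgments, with companion analyses for reaction times,
eye-tracking, and trial-locked EEG.

In the underlying paradigm an observer is told to mentally divide an image
into K segments. On each trial two locations are cued and the observer
reports whether they belong to the *same* or *different* segments. Many
such trials over a 15×15 analysis grid let us reconstruct, for every grid
cell, the probability that the observer assigned it to each segment. The
package is aimed at visual psychophysicists and cognitive neuroscientists
running this paradigm (for example, to compare neurotypical and autistic
cohorts), and at anyone who wants a fully synthetic, seedable test bed for
the complete analysis chain.

## The model and statistics

**Map inference.** Cell `i` carries a label distribution
`p_i = softmax(z_i)` over K segments. A trial cueing cells `i, j` is
predicted "same" with probability `s_ij = Σ_k p_ik p_jk`, and the fit
maximizes the penalized Bernoulli log-likelihood

```
L(z) = Σ_trials [ y log s_ij + (1−y) log(1−s_ij) ] − λ Σ_(i~j) ‖p_i − p_j‖²
```

with λ = 5 smoothing over the 4-neighborhood (L-BFGS-B, analytic
gradient). The **segmentation map** is the per-cell argmax; the
**uncertainty map** is the per-cell Shannon entropy `H_i = −Σ p log₂ p`
(max `log₂ K`).

**Information Gain (IG).** Map similarity is the mutual information
between two label maps, referenced to a spatial-shuffle permutation null:

```
IG% = 100 · (MI_obs − mean(MI_null)) / mean(MI_null)
```

where the null permutes the spatial locations of one map's values
(marginals preserved; one-tailed permutation test). IG ≈ 0% means two maps
are no more alike than random maps; structured agreement produces values
in the thousands of percent.

**Companion analyses.** Reaction times: within-block 90th-percentile
log-RT filtering, bootstrap medians (9,999 resamples), z-scored learning
curves, and the trial-constant fit `RT = α·2^(−t/τ)` (τ = trials to halve
RT). Gaze: Gaussian kernel dwell-density maps (σ = 10 px), mass-preserving
downsampling to the analysis grid, and cumulative %-image-coverage curves.
EEG: RT-based epoch exclusion, average reference, baseline correction,
ERP aggregation, pointwise Welch-t significance windows with a 50-ms
duration criterion, Global Field Power tests at 50-ms intervals, and
cluster-based permutation tests over Delaunay channel adjacency.

Every data modality has a seedable synthetic generator (`cohort_preset()`
bundles NT-like and ASD-like study conditions), so the whole pipeline runs
end to end without human data.

## Worked example

```r
library(perceptseg)

trial_schedule(2)                 # trials needed for K = 2 on a 15x15 grid
#> [1] 225

gt  <- make_ground_truth_map(K = 2, seed = 11)
obs <- observer_params(gt, certainty = 0.85, lapse = 0.05, seed = 11)
blk <- simulate_observer_block(obs, stimulus("demo", K = 2, category = "texture"),
                               n_trials = 450, cohort = "NT")

fit <- fit_prob_map(blk, fit_config(lambda_smooth = 5, seed = 1))
seg <- argmax_map(fit$pmap)
match_labels(seg, gt)$agreement   # cell agreement with the ground truth
#> [1] 0.9866667

mean_uncertainty(entropy_map(fit$pmap))   # % of the log2(K) maximum
#> [1] 53.16667

classify_consistency(blk, seg)$rate       # trials contradicting the map
#> [1] 0.2555556

information_gain(seg, gt, n_perm = 10000, seed = 1)
#> <ig_result> MI = 0.3756 bits, null = 0.0037 +/- 0.0050 bits
#>   IG = 10124.0%, p = 9.999e-05 (10000 permutations)

fit_trial_constant(filter_rts(tibble::as_tibble(blk)))
#> <rt_fit> alpha = 0.8322 s, tau = 19.25 trials (n = 405, nlsLM)
```

The fitted map recovers the simulated observer's partition almost exactly
(98.7% of cells after label matching); its IG against the ground truth is
four orders of magnitude above the shuffle null. The inconsistency rate
(~0.26) reflects the observer's response noise, and the recovered trial
constant (19.3) is close to the generating value of 18.4 trials. Shuffling
the responses destroys the cue–response link, and the same block is then
flagged as structureless:

```r
flag <- flag_structureless_block(shuffle_responses(blk, seed = 5),
                                 fit_config(seed = 1), n_perm = 999, seed = 2)
flag$flagged
#> [1] TRUE
```

`run_pipeline(run_config(seed = 1))` chains simulate → infer → analyze for
two synthetic cohorts and returns tidy result tables for every statistic
family (maps, similarity, RT, gaze coverage, EEG windows). A command-line
wrapper lives at `inst/cli/perceptseg.R`.

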