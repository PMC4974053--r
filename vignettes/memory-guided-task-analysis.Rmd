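---
title: "Analyzing trial-structured calcium imaging from a memory-guided go/no-go task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing trial-structured calcium imaging from a memory-guided go/no-go task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgtask)
```

`mgtask` implements a complete analysis chain for two-photon calcium
imaging recorded while an animal performs a memory-guided go/no-go visual
discrimination: a 2 s stimulus (target or non-target), a randomly
interleaved 0/3/6 s delay, and a 1.5 s response window. This vignette
explains the models and procedures, the parameters that matter, the design
choices made where the design was genuinely open, and what the synthetic
benchmarks do and do not demonstrate about real data.

## The synthetic-data generator

Because every downstream stage needs trial-structured input,
`generate_session()` and `generate_traces()` simulate the study conditions
directly. The trial table draws stimulus identity (P(target) = 0.5 by
default), a delay uniform over {0, 3, 6} s, and a lick according to
configurable hit and false-alarm probabilities (defaults 0.9 and 0.2, in
the range a well-trained animal shows); outcomes follow deterministically.
Epoch boundaries (stimulus on/off, spout in/out) are carried per trial.

Traces are built from six response archetypes: four enhanced (stimulus-
driven, stimulus+response, delay-driven, response-driven) and two
suppressed (early and late delay-sensitive suppression). Each archetype is
a piecewise epoch drive convolved with a causal exponential whose half-
decay time (default 1.5 s, constrained > 1 s) emulates a slow genetically
encoded indicator; kernels are normalized to peak magnitude one, enhanced
kernels are nonnegative, suppressed nonpositive, and the delay-driven
kernel's suprathreshold duration grows parametrically with the delay. The
drive shapes are a package design: only cluster-average time courses are
ever observable, so the kernels are defined qualitatively (onset epoch,
sustain, delay scaling) rather than fit to any particular dataset.

Per neuron, the generator draws an archetype from a mixture (the
`region_mixture()` presets encode the qualitative regional differences —
primary visual cortex rich in stimulus-driven and early-suppressed cells,
frontal motor cortex rich in delay/response-driven and late-suppressed
cells — and are package defaults, not measured proportions), a lognormal
peak ΔF/F amplitude (meanlog log 0.6, sdlog 0.4, i.e. typical peaks of
0.4–1), a preferred trial type, and a selectivity ratio: Beta(1, 4) for
enhanced neurons (strongly selective) and Beta(4, 1.5) for suppressed ones
(weakly selective), mirroring the qualitative finding that suppressed
populations are far less selective. Noise is i.i.d. Gaussian on ΔF/F
(default sd 0.10); no published value exists for single-trial noise, so
this default is documented rather than asserted. A single master seed
expands into per-component substreams, so enlarging one part of a
simulation never perturbs another.

What the generator does *not* emulate — correlated noise across neurons,
slow drift, z-motion, nonlinear indicator saturation, behavioral
covariates such as running — bounds what passing tests show: they
demonstrate correctness of the *procedures* under the stated conditions,
not robustness to every pathology of in-vivo data.

`generate_movie()` renders disk somata (radius 6 µm at 2 µm/px by
default) without overlap, modulates each by a supplied trace, applies a
recorded integer-pixel drift, and adds Gaussian shot noise;
`generate_video_frames()` produces 300 × 200 behavior-camera frames with
an optional injected movement blob, flagged in the ground truth.

## Behavioral statistics

Sensitivity is d′ = Φ⁻¹(R_HIT) − Φ⁻¹(R_FA) rather than percent correct,
separating discrimination from lick bias. Rates of exactly 0 or 1 are
clipped to 1/(2N) and 1 − 1/(2N) (the log-linear correction) — the
standard finite-sample rule, chosen because no specific correction is
prescribed for this analysis. Sessions pass quality control iff d′ > 1
and R_HIT − R_FA > 30%, both strict. Photoinhibition sessions are compared
with two-sided paired t-tests on per-session laser-OFF vs laser-ON d′ (and
hit/false-alarm rates), Bonferroni-corrected; the default family is the
three task epochs, configurable via `n_comparisons`. Per-delay d′ is
computed per session and then aggregated, the conservative reading when a
pooled alternative is equally defensible.

## The imaging front end

Registration maximizes the 2-D cross-correlation of each frame with the
pixel-wise mean image over integer shifts (subpixel refinement is out of
scope). A mean built from drifting frames is itself blurred, which can
bias the peak by a pixel; `register_movie()` therefore refines the
reference once by default (`n_passes = 2`), after which planted integer
shifts are recovered exactly. The anchor of a mean reference is arbitrary,
so recovered shifts are meaningful relative to one another (tests compare
them anchored to frame one).

The activity map scores every pixel by temporal skewness × mean
correlation with its four neighbors, floored at zero and rescaled to
[0, 1]. This statistic is this package's choice for "pixels containing
transient, spatially coherent signal" — cited formulations of activity
maps differ, and ours is declared, not claimed equivalent to any.
Segmentation applies a local-mean adaptive threshold (window 12 px, offset
0.05), labels connected components, iteratively re-thresholds oversized
components at the median of their own scores, and keeps components of
20–500 px (≈ soma areas at 2 µm/px).

Neuropil correction is F_corr = F_soma − 0.7 F_neuropil with the annulus
0–15 µm from the ROI border and all ROI pixels excluded (distances in µm
via the configured pixel size; the annulus is widened with a warning if
exclusions empty it). F₀ is the mode of the fluorescence density —
estimator-ambiguous in general, implemented as the midpoint of the tallest
Freedman–Diaconis histogram bin with a KDE alternative behind
`method = "kde"`. Duplicate ROIs across planes (trace correlation > 0.5
and XY distance < 12.5 µm) are resolved by repeatedly dropping the member
with the lower mean fluorescence (more likely out of the focal plane);
exact ties keep the lower index for determinism, making the procedure
order-independent.

## Trial-locked significance

A slow indicator keeps genuine transients above baseline for many samples,
so the classifier combines a *weak* per-sample test with a *duration*
requirement: per time sample, delay, and correct trial type (hit, CR),
each trial's sample value is compared with that trial's mean pre-stimulus
baseline by a two-sided Wilcoxon signed-rank test at p < 0.05 (the pairing
against the per-trial baseline mean is this package's reading of "sample
vs baseline"); a delay qualifies when ≥ 10 samples are significant in the
same direction within its trace — counted, not necessarily consecutive,
which is the literal reading; a `consecutive` switch implements the
stricter variant — and a neuron is significant when ≥ 2 of 3 delays
qualify for some trial type and direction, on both the corrected and
uncorrected ΔF/F (guarding against correction artifacts). Strata with
fewer than 5 correct trials are excluded.

`significance_chance_level()` computes the criterion's false-positive
probability exactly under per-sample independence: with q the binomial
tail P(Bin(65, 0.025) ≥ 10), the union bound over two directions, two
trial types and the 2-of-3 delay rule gives 4·(3q²(1−q) + q³) ≈ 2.8×10⁻¹⁰,
below the 10⁻⁹ design bound; a 10⁴-neuron Gaussian null simulation in the
acceptance suite yields zero positives. The vectorized signed-rank engine
assumes continuous data (rows with zero differences fall back to
`stats::wilcox.test`) and is tested for exact agreement with it.

## Normalization, clustering, indices

Responses are normalized by subtracting the mean baseline (1 s before
stimulus onset) and dividing by the maximum (enhanced) or |minimum|
(suppressed) of the trial-averaged trace. Clustering operates on the
normalized preferred-type average for the longest delay (the most
informative condition; concatenating delays is a caller-side option),
projected onto the first 20 principal components, with Ward linkage on
Euclidean distances (`hclust(method = "ward.D2")`, the Ward variant
appropriate for raw distances). After cutting at K clusters every neuron
is re-categorized to the cluster mean with which its trace correlates
best, iterating mean updates to stability (≤ 10 rounds; the assignment
step never lowers a neuron's correlation to its assigned mean). `choose_k`
returns the smallest K at which K + 1 produces a pair of cluster means
correlating above 0.9 (numerically identical means always count as
overlapping, so identical inputs give K = 1).

The selectivity index uses R = time-integrated baseline-subtracted
response over the stimulus-through-response window, sign-flipped for
suppressed neurons and rectified at zero, averaged over correct trials of
each type; the window itself is a documented package choice. Preference
ties break toward hit. Onset latency linearly interpolates the mean trace
to 1 kHz and takes the first sample of the earliest ≥ 1 s run entirely
beyond baseline mean ± 1σ; interpolation places the crossing between the
native 5 Hz samples, so latencies are approximate at that resolution. The
population summary is the first local maximum of a Gaussian KDE
(Silverman bandwidth) exceeding 10% of the global peak — robust to the
long right tail of latency distributions. Delay modulation fits a least-
squares line to the integrated ΔF/F (stimulus onset to spout extension)
versus delay; DMI counts positive- and negative-slope neurons (zero
slopes in neither), with the sign convention flipped for suppressed
populations.

## Population decoding and state-space axes

The ideal observer compares error trials with correct trials that share
the *other* task variable: stimulus contrasts are miss-vs-CR and FA-vs-hit
(different stimulus, same response), choice contrasts miss-vs-hit and
FA-vs-CR (same stimulus, different response); available symmetric pairs
are averaged. Correct trials are scored by distance to the leave-one-out
mean of the remaining correct trials, error trials by distance to the
all-correct template; the auROC of the two distance samples (rank-based,
exactly the Mann–Whitney statistic) is the discriminability. Curves
average over random neuron subsets (population sizes 1–100), and are
reported folded as max(a, 1 − a) with the raw value retained. Shuffle
nulls permute labels within each contrast pair, one random subset per
permutation; time points are significant when the mean curve exceeds the
97.5% null quantile for ≥ 3 consecutive points, the run-length rule
compensating for multiple comparisons across time. Experiments with fewer
than three error trials of a type are excluded.

Task axes come from per-time regression of every neuron's single-trial
response on coded stimulus (±1) and choice (±1). The per-time coefficient
vectors are combined by a squared-norm-weighted average over time — in
simulations this is considerably less noisy than any single time point,
so it is the default; the maximal-norm time point remains available via
`t_select = "max_norm"` — then de-noised by projection onto the first 10
principal components of the condition averages and orthogonalized by
Gram–Schmidt, stimulus first (both counts and order configurable; the
10-PC default is a choice, as no PC count is prescribed for this step).
Collinear codes (no error trials) raise an informative error. Trajectory
separations (hit − CR along each axis) get a permutation band from
label-shuffled refits of the axes, since the axes themselves depend on
the labels.

## Movement-video analysis

Per epoch (Pre, Delay, Response), D_CR averages |CR_f − mean(CR without
f)| over frames f, D_Hit averages |Hit_f − mean(CR without f)| with the
same leave-one-out templates (surplus Hit frames reuse a seeded random CR
exclusion), and D_Sub = |D_Hit − D_CR| isolates condition-specific
movement, including stable postural shifts. Frames are not intensity-
normalized by default. Mean D_Sub per epoch is compared across sessions
by paired t-tests with Bonferroni correction over the three epoch pairs;
fewer than three sessions yields descriptive output only.

## Orchestration, problem sizes, reproducibility

`run_pipeline()` executes generation → behavior → significance →
clustering → indices → decoding → trajectories → movement from one
validated configuration (`default_config()`, YAML via `read_config()`)
and one seed, writing CSV/JSON outputs plus a resolved-config echo.
Defaults keep simulations at desk scale — 300 trials, a few hundred
neurons, tens of decoding iterations, 100–200 permutations — sizes chosen
so a full run completes in well under a minute on one core while leaving
every statistical conclusion stable under seed changes; the acceptance
script uses 10⁴ neurons for the null simulation and 600 for clustering
recovery. All randomness flows through seeded substreams, and identical
configuration plus seed reproduces every output bit for bit.

## Known limitations

Integer-pixel registration only; the activity-map statistic is a declared
substitute for cited formulations; trace tensors are kept in memory (no
HDF5 backend); the significance engine's exactness assumes continuous
data; synthetic benchmarks do not exercise correlated noise or z-motion;
and the movement analysis measures pixel differences, not pose.
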