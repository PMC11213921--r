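---
title: "Models and methods in locustal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in locustal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locustal)
```

`locustal` analyses two kinds of data from studies of social plasticity
in desert locusts: arena trajectories from four-patch foraging assays,
and calcium-imaging movies of antennal-lobe (AL) projection neurons
(PNs). This vignette explains the models, their assumptions, the
tunable parameters and the numerical choices. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The cue-integration choice model

A locust choosing among four patches (food `Lvs`, conspecifics `Lct`,
both `LvsLct`, empty `Ctr`) integrates four information classes —
socio-visual, food-visual, socio-olfactory, food-olfactory — each with
a positive reliability $C_i$. A patch $x$ advertising class $i$
(availability $w = 1$) is judged good with probability

$$P(x\ \mathrm{good}\mid C_i) = \frac{1}{1 + C_i^{-w}},$$

so an absent cue ($w = 0$) contributes an uninformative factor $1/2$.
The per-class judgements multiply, and normalizing across patches
yields the choice probabilities $P_x$. The *information reliability
score* is $\log_{10} C_i$: positive means attraction, negative
aversion, zero indifference.

`fit_reliability()` minimizes the squared error between $P_x$ and the
observed mean quarter occupancy, jointly across all sensory conditions
with one shared reliability vector per dataset (per-condition
availability matrices encode which cues each stimulus container lets
through). The search runs on $\log_{10} C \in [-1, 1]$ with
multi-start L-BFGS-B; the objective is a smooth 4-parameter surface on
a box, for which derivative-based local search from several random
starts reliably finds the global minimum, so the specific optimizer is
interchangeable machinery. Repetitions (`n_repeats`, 5000 for a full
analysis) resample animals with replacement and re-draw the starting
points, so the 2.5/97.5-percentile band reflects both sampling and
search variability. Whether to fit conditions jointly (the default
here) or separately is genuinely open; joint fitting uses all
constraints to pin down the four parameters and is the only identified
choice when single conditions leave classes unobserved.

## Behavioral maps

Trajectories are smoothed with a truncated Gaussian (half-width 2 s,
$\sigma = 2/3$ s, renormalized partial kernels at the edges). Visit
density deposits one unit per frame on a 1000×1000 grid and smooths
with a 2-D Gaussian of s.d. 78 grid pixels (filter size = grid size
minus one); the kernel is clipped at the grid edge, and maps are
normalized by frame count, not retained mass. The grid units of the
kernel width and the boundary mode are assumptions: the arena bounding
box is rescaled linearly onto the grid, and edge mass is allowed to
fall off the map.

Quarter occupancies split the arena along the two diagonals through
its center (patches sit at 90° spacing near the wall) and are reported
in canonical patch order regardless of the physical patch placement,
so rotated configurations pool directly. For per-animal occupancy
inside the model fit the package counts (smoothed) trajectory frames
per quarter directly: the smoothing kernel is symmetric across the
straight quarter boundaries, so the two routes agree far below fit
tolerance (this equivalence is asserted in the test suite), at a small
fraction of the cost of 50 per-animal full-grid convolutions.

## Synthetic data: what it emulates, what it does not

`generate_choice_trajectories()` draws each agent's target patch with
the model probabilities evaluated at known reliabilities, dwells near
the target through an Ornstein–Uhlenbeck walk (`ou_theta = 0.12`,
`ou_sd = 0.6` cm per frame at 25 fps in a 90 cm arena), and re-draws
targets at `switching_rate = 1e-3` per frame. Long dwells keep transit
time a ~1–2% fraction, so stationary quarter occupancy converges to
$P_x$; the suite checks max deviation < 0.02 at 50 agents × 10⁵
frames. The walk does not emulate wall-following, thigmotaxis, pauses
or speed changes of real locusts — recovery tests therefore show that
the fitting machinery inverts the model, not that real locusts obey
it.

`generate_calcium_movies()` plants non-overlapping Gaussian-disc cell
bodies (σ = radius/2, support truncated where the disc falls below
10⁻³ so the background is exactly flat) whose time courses follow
motif templates (two phasic, sustained, delayed, two inhibitory,
silent), with Gaussian noise, a linear bleaching trend and integer
rigid jitter. Defaults (baseline 100, amplitude 0.8 ΔF/F, noise s.d.
2% of baseline, 1 Hz, 40 frames, onset at frame 11) are chosen for
testability at desk scale; raw-noise statistics of real recordings are
not reported anywhere we could anchor them. Optics (PSF, depth
sections), neuropil texture and non-rigid deformation are not
emulated.

## Imaging preprocessing

Fixed order: 3×3 median → Gaussian blur (σ = 1 px, reflect boundary)
→ linear detrend of the per-frame median intensity (slope only, with
zero-based frame index, so F₀ stays on the raw intensity scale) →
rigid alignment by phase correlation against the stimulus-mean
template with parabolic subpixel refinement (estimated shifts below
0.05 px are treated as zero rather than resampled) → a trailing
3-frame temporal box filter → ΔF/F₀ with F₀ the mean of the five
frames immediately preceding onset. The box filter is trailing
(causal) rather than centered so that the last baseline frame never
mixes in post-onset signal; with a centered window the plateau
response (F 10 → 16) would read (16 − 10.4)/10.4 instead of the
correct 0.6. The same filtered trace feeds both the numerator and the
baseline. Pixels whose baseline falls below 10⁻⁶ of the dynamic range
are masked and counted. Non-rigid motion correction is out of scope:
the package implements the phase-difference rigid alignment only, and
its synthetic jitter is rigid by construction.

## Granule segmentation

The field of view is partitioned from the standard-deviation
projection (population form) over the concatenated stimulus set.
8-connected regional maxima and minima seed a Voronoi partition
(plateaus contribute one seed at their centroid; candidate plateaus
that touch an equal-valued pixel with a greater neighbor are not
extrema). A light Gaussian smoothing of the projection
(`smooth_sd = 1` px) suppresses single-pixel noise extrema before
seeding; at 0 the seed density on noisy data roughly doubles with no
gain in recovery.

Boundary refinement compares, for every pixel on a granule border, the
root *median* squared error between the pixel's trace and the mean
trace of its home versus neighboring granules over the concatenated
stimulus set, and reassigns on strict improvement. Updates are
synchronous per iteration (visiting order cannot matter) and granule
means are recomputed once per iteration, for at most 50 iterations;
granules below 5 px fuse into the neighbor with the longest shared
border. Because the median is insensitive to brief transients, phasic
responses barely move boundaries, while sustained activity sculpts
them; on noiseless cells the converged boundary tracks the disc's
mid-amplitude contour, so only the near-peak core of a planted cell is
label-determined — the purity invariants in the tests are phrased over
pixels within 1 px of the true center for exactly this reason.

Granules are called active per stimulus by Otsu's threshold (256-bin
histogram over the observed magnitude range; when the criterion is
flat across an empty histogram gap the midpoint of the maximal plateau
is taken) on the window-mean ΔF/F₀, with a response floor of
0.02 ΔF/F₀: Otsu always splits a distribution, and the floor keeps
genuinely silent stimuli from yielding spurious active calls. Seed
type (maximum- vs minimum-seeded) is reported for filtering background
granules out of pooled statistics but does not bar an active call —
after refinement a minimum-seeded granule can legitimately own
responsive pixels. Otsu on granule magnitudes (rather than on pixelwise
projections) is the implemented reading of an ambiguous choice; the
threshold function is exported so the pixel-level variant is one call
away.

## Response vectors, motifs, and the VRC elbow

Response matrices (units × stimuli, window-mean ΔF/F₀ over 10 frames
post-onset at 1 Hz — the window length is a configuration default, not
a claim) are normalized per animal: subtract the animal minimum,
square root ("root-transform" is read as the square root; no other
root is suggested anywhere), center and scale the animal's entries,
then rescale each unit's row to [−1, 1]. PCA retains PCs explaining ≥
99% of variance (95% for map-consistency analysis, 83% for the
classifier — all three thresholds are stated study constants).

k-means uses squared Euclidean distance, replicated random
initializations (best of `replicates`; 500 in a full analysis, fewer
in tests where planted structure is strong), a Lloyd batch phase and
an online phase that moves single points with immediate centroid
updates until stable. The cluster count k ∈ 2..20 maximizes the
perpendicular distance of the Variance Ratio Criterion curve

$$VRC(k) = \frac{SSB\,(N-k)}{SSW\,(k-1)}$$

from the chord joining its first and last points; ties break to the
smaller k, and non-finite values (SSW = 0) are excluded from the chord
with a warning. Motifs are the same machinery applied to z-scored
(unit, stimulus) temporal profiles; motif ids are re-indexed by (peak
sign, peak magnitude, peak latency) ascending so that ids are
comparable across runs.

## Synergy and phenotype classification

Bliss scores use the half-concentration expectation
$f_{exp} = f_1/2 + f_2/2 - (f_1/2)(f_2/2)$ and
$score = 100(f_3 - f_{exp})$, computed frame-wise; the window summary
is the mean frame-wise score over the analysis window (the paper
compares proportions and plots time courses, leaving the scalarization
open — the mean is the least structured choice). Units with identical
motifs across all three stimuli are computed but excluded from pooled
summaries. The strongly-synergistic fraction thresholds at one
standard deviation of the pooled score distribution (pooling across
phenotypes, the default reading).

Phenotype classification flattens each animal's motif-transition
matrices (default ordered pairs Lct→Laa, Lct→LaaLct, Laa→LaaLct) into
a feature vector, reduces by PCA retaining ≥ 83% of variance — refit
inside every leave-one-out training fold, so the held-out animal never
leaks into the projection (a compatibility flag restores the
all-animals PCA) — and applies a linear discriminant with a shared
*diagonal* covariance and uniform class priors (the size-compensation
reading of class weighting). Score ties predict the globally rarer
class. The classifier is deliberately low-variance: with tens of
animals and thousands of raw features, full-covariance LDA would be
degenerate.

## Statistics

Randomization tests use $T = |\bar{x}|/(\sigma_x/\sqrt{n})$ for paired
differences (null: random sign flips) and Welch-style
$T = |\bar z - \bar y| / \sqrt{\sigma_z^2/n + \sigma_y^2/m}$ for two
samples (null: random label reassignment preserving group sizes),
with B resamples drawn with replacement, σ on the n−1 denominator, and
$p = \max(\#\{T^* \ge T\}, 1)/B$ — ties count toward rejection, and
the smallest achievable p is exactly 1/B (B = 10⁷ for full-scale
inference). The cited bootstrap-randomization literature leaves the
exact resampling scheme open; the schemes above are declared, not
claimed identical. Grand means are means of animal means with
5000-sample percentile bootstrap intervals; multiplicity is handled by
Bonferroni.

## Problem sizes and known limitations

The test suite and acceptance script run everything at desk scale: 20
recovery datasets of 50 agents × 10⁴ frames, 96×96 px movies with 20
cells, 300 motif rows, 15 animals per phenotype class, B = 10⁵ for
oracle comparisons and B = 10⁷ only for the p-floor check. These sizes
were chosen so the whole pipeline exercises in minutes; all thresholds
are stated above, none is tuned to a particular seed.

Known limitations: the package does not reproduce the source study's
real-data numbers (those require the deposited imaging dataset);
Fourier shifting wraps at frame borders (acceptable for jitter ≪ frame
size); the refinement equilibrium splits Gaussian-profile cells at
mid-amplitude, so granule areas under-estimate cell areas; and the
behavior generator's stationarity argument fails if dwell and transit
times become comparable (switching_rate ≳ 0.01 at these speeds).
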