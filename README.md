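# locustal

Analysis pipeline for studying social plasticity in desert locusts
(*Schistocerca gregaria*) from two complementary data streams:

- **Behavior** — trajectories of single locusts choosing among four
  patches (food `Lvs`, conspecifics `Lct`, both `LvsLct`, empty
  control `Ctr`), turned into visit-density maps, quarter occupancies,
  and fitted cue reliabilities.
- **Imaging** — calcium movies of antennal-lobe projection neurons
  (PNs), turned into ΔF/F₀ stacks, activity granules, odor response
  vectors, temporal response motifs, Bliss synergy scores, and a
  phenotype (gregarious vs solitarious) classifier.

A synthetic-data module generates both input types with known ground
truth, so the whole pipeline is testable end to end without any
external download.

## The models at the core

**Patch choice.** Each of four information classes (socio-visual,
food-visual, socio-olfactory, food-olfactory) has a reliability
*C&#7522;* > 0. A patch *x* advertising class *i* (availability *w* ∈
{0, 1}) is judged good with probability 1/(1 + C&#7522;⁻ʷ); the class
factors multiply and normalize across patches into choice
probabilities *P&#8339;*. Fitting log₁₀ *C* ∈ [−1, 1] to observed
quarter occupancies yields an information reliability score per class
(positive = attraction, negative = aversion).

**Granule segmentation.** The s.d.-projection of the concatenated
stimulus set is partitioned by the Voronoi diagram of its regional
maxima and minima; boundaries are refined iteratively by comparing
each border pixel's root-median-squared trace error against its home
versus neighboring granule means; granules below 5 px are fused.
Active granules per stimulus are called by Otsu's threshold on
window-mean ΔF/F₀.

**Clustering.** Response vectors and temporal motifs are clustered by
replicated k-means (with an online update phase) in PCA space, with
the cluster count chosen at the elbow of the Variance Ratio Criterion
VRC(k) = SSB·(N−k) / (SSW·(k−1)), k ∈ 2..20.

**Synergy.** Mixture interactions use the Bliss independence score
with half-concentration components: f_expected = f₁/2 + f₂/2 −
(f₁/2)(f₂/2), score = 100·(f₃ − f_expected).

**Statistics.** Bootstrap randomization tests (sign-flip for paired,
label permutation for two-sample) with p = max(count ≥ T, 1)/B,
grand-mean bootstrap CIs, Bonferroni adjustment.

## Worked example

```r
library(locustal)

# simulate 20 animals under known reliabilities: strong attraction to
# the socio-visual class (score 1), indifference elsewhere; the three
# sensory conditions (both cues, olfaction only, vision only) are
# what disentangles the four classes, so simulate and fit all three
spec <- agent_spec(n_agents = 20, n_frames = 20000,
                   true_C = c(10, 1, 1, 1), seed = 7)
occ <- list()
for (cond in names(spec$W_set)) {
  spec$seed <- 7 + match(cond, names(spec$W_set))
  sim <- generate_choice_trajectories(spec, cond)
  occ[[cond]] <- occupancy_from_frames(
    smooth_trajectory(sim$trajectories), sim$config)
}
round(colMeans(occ$VisOlf), 3)
#>    Lvs    Lct LvsLct    Ctr
#>  0.181  0.246  0.357  0.215

est <- fit_reliability(occ, n_repeats = 100, seed = 1)
print(est)
#> Reliability estimate (log10 C), n_repeats = 100
#>   socio_visual     +0.914  [+0.454, +1.000]
#>   food_visual      +0.153  [-0.169, +0.529]
#>   socio_olfactory  -0.089  [-0.261, +0.151]
#>   food_olfactory   +0.057  [-0.189, +0.261]
```

The patches advertising the socio-visual class (`Lct`, `LvsLct`) draw
extra occupancy when vision is available, and the fitted score for
that class recovers the planted value 1 within its band while the
other classes stay near 0. A single condition alone cannot separate
the visual from the olfactory class at the same patch — joint fitting
across conditions is what identifies them.

The imaging arm runs the same way from planted movies:

```r
scene <- scene_spec(n_cells = 12, noise_sd = 2, seed = 3)
movies <- generate_calcium_movies(scene)
dffs <- lapply(movies$movies, preprocess_movie)
gmap <- segment_granules(dffs)
print(gmap)
#> granule_map: 136 granules (67 max-seeded) on 64 x 64 px
resp <- granule_responses(gmap, dffs[["Lct"]])
table(resp$active)
#> FALSE  TRUE
#>   123    13
```

A single-command synthetic demo of both arms, with ground-truth
recovery checks in its report:

```r
run_pipeline(run_config(mode = "synthetic-demo", out = "demo", seed = 1))
```

or from a shell: `Rscript inst/cli/locustal.R simulate --out demo`.

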