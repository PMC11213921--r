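Package: locustal
Title: Locust Antennal-Lobe Imaging and Foraging-Choice Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for studying social plasticity in desert
    locusts from behavior and calcium imaging. Implements a Bayesian
    cue-integration model of patch choice with reliability-score fitting,
    trajectory smoothing and visit-density mapping, delta-F/F0 preprocessing
    of antennal-lobe calcium movies, Voronoi-based activity-granule
    segmentation with iterative boundary refinement, Variance Ratio Criterion
    (Calinski-Harabasz) elbow selection for k-means clustering of odor
    response vectors and temporal response motifs, Bliss-independence synergy
    scoring of odor-mixture responses, motif-transition phenotype
    classification by diagonal linear discriminant analysis, and bootstrap
    randomization tests. A synthetic-data module generates behavioral
    trajectories and planted-cell calcium movies with known ground truth so
    every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    EBImage,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
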