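Package: homeoscale
Title: Homeostatic Synaptic Scaling and Hebbian Plasticity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying homeostatic regulation of cortical activity
    after sensory overstimulation. Implements a two-compartment rate-model
    simulator with Hebbian potentiation gated by dendritic inhibition and an
    activity-proportional homeostatic downscaling term, together with the
    accompanying analysis procedures: thresholded delta-F/F0 calcium trace
    processing and activity metrics, dendritic spine signal extraction by
    scaled dendrite subtraction with dummy-stimulus null classification of
    visual responsivity, spatial clustering of spine function along branches,
    functional assembly correlation analysis for excitatory and inhibitory
    populations, structural quantification of spines and inhibitory puncta
    from 1-D fluorescence intensity profiles including a multiplicative
    scaling-factor fit by Kolmogorov-Smirnov distance, miniature synaptic
    event detection with excitation-inhibition ratio estimation, touchscreen
    continuous-performance-task metrics, and a synthetic data generator with
    known ground truth for every input the pipelines consume.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
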