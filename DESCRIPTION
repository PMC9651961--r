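Package: ehconn
Title: Entorhinal-Hippocampal Functional Connectivity Analysis on Synthetic BOLD Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for seed-to-voxel semipartial functional
    connectivity in the entorhinal-hippocampal circuitry. Generates synthetic
    4D BOLD phantoms with known ground-truth connectivity gradients and task
    content biases, runs per-subject task GLMs with spike detection, computes
    band-pass filtered semipartial seed-to-voxel correlation maps, derives
    entorhinal seed regions by winner-take-all parcellation of group T-maps,
    segments subiculum and CA1 along the transversal axis, and applies a
    hierarchical repeated-measures ANOVA testing cascade with
    Benjamini-Hochberg false-discovery-rate correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
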