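Package: neuroarbor
Title: Dendritic Arbor Morphometry and Evoked Field Potential Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify dendritic remodeling of cortical pyramidal
    neurons from 3D fluorescence image stacks, and to parameterize evoked
    field excitatory postsynaptic potentials (fEPSPs). The image pipeline
    chains histogram normalization, Perona-Malik anisotropic diffusion,
    multiscale Frangi vesselness filtering and thresholding into a binary
    mask, distills the mask into a skeleton graph by 3D topological
    thinning, simplifies the graph under a two-term volume-fidelity versus
    segment-parsimony objective, and computes apical/basal and
    branch-order morphometry (lengths, process counts, bifurcations per
    order). The electrophysiology module decomposes fEPSP traces by
    independent Boltzmann fits of the rising and decay phases (peak, 67
    percent rise time, decay time, 30-ms area under the curve) and computes
    pharmacological blockade percentages across aCSF, CNQX and
    CNQX+ifenprodil conditions. A synthetic-data module generates
    ground-truth dendritic trees rendered as noisy anisotropic voxel
    stacks and kinetic-template fEPSPs with AMPA/GluN2B/GluN2A components,
    so every stage is testable by parameter recovery. Group comparisons
    use Mann-Whitney U tests, one-way ANOVA with Bonferroni-corrected
    post hoc tests, and mean +/- SEM summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
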