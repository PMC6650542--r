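# neuroarbor

Dendritic arbor morphometry from 3D fluorescence image stacks, and
Boltzmann decomposition of evoked field excitatory postsynaptic potentials
(fEPSPs) — the two quantitative readouts used to characterize
maturation-like remodeling of cortical pyramidal neurons (e.g. after
chronic antidepressant treatment, where arbors shorten and the synaptic
NMDA-receptor composition shifts from GluN2B toward GluN2A).

The package is aimed at labs that image single fluorescently labeled
neurons as TIFF z-stacks and record extracellular fEPSPs under sequential
pharmacological blockade (CNQX to remove the AMPA component, then
ifenprodil to remove the GluN2B component), and want a scriptable,
testable version of the full analysis chain.

## What it computes

**Imaging chain.** For a stack `I` with physical voxel spacing:
histogram normalization to `[0, 1]` → Perona–Malik diffusion
(conductance `exp(-(∇I/κ)²)`, κ = 0.1, step 0.99/|N|) → multiscale Frangi
vesselness (Hessian eigenvalues `|λ1| ≤ |λ2| ≤ |λ3|`, bright-tube
polarity, α = β = 0.5, c = half the maximum Hessian norm) → threshold →
single-object validation. The binary mask is thinned to a voxel curve
(topology-preserving simple-point removal), converted to a spatial graph,
and simplified under the two-term objective

    E = mean distance of mask voxels to the skeleton (µm) + λ · #segments

by greedy polyline-vertex decimation (λ = 0.5 µm/segment). On the rooted
tree, the longest soma-to-tip path (in µm) of each soma-emanating subtree
is the primary process; branches off an order-k path start order k+1
paths, recursively. Reported per neuron: total/apical/basal length, and
per-order process counts, lengths and bifurcations.

**fEPSP chain.** Onset by a sustained 3σ baseline-deviation rule; split
at the extremum; independent Boltzmann fits
`B(t) = A2 + (A1−A2)/(1+exp((t−t50)/k))` of rise and decay; peak = rise
plateau `A2`; rise time = closed-form time to 67% of peak; decay time =
time back to 33% of peak; AUC = ∫|V| over 30 ms from onset; blockade
percentage = `(1 − AUC_drug/AUC_ref)·100`, per slice, then mean ± SEM.

**Statistics.** Mann–Whitney U (exact by enumeration for pooled n ≤ 24
without ties, otherwise corrected normal approximation), one-way ANOVA
with Bonferroni-corrected pairwise t-tests, mean ± SEM summary tables.

**Synthetic data.** A first-class module generates ground-truth dendritic
trees (depth-limited Galton–Watson process) rendered as noisy anisotropic
8-bit stacks with known tube masks, and fEPSPs composed of
AMPA/GluN2B/GluN2A difference-of-exponentials components that the
pharmacological conditions remove selectively — so every stage of the
package is testable by parameter recovery. File formats: multi-page TIFF
(stacks), SWC (morphologies), CSV + JSON sidecar (waveforms), CSV
(morphometry tables).

## Worked example

```r
library(neuroarbor)

# a ground-truth neuron: 3 basal trunks + apical trunk, 1.2 µm tubes
params <- tree_gen_params(n_basal_trunks = 3, apical_trunk_length = 18,
                          branch_probability = 0.6, mean_segment_length = 7,
                          segments_per_branch = 2, max_depth = 3,
                          radius = 1.2, min_separation = 5,
                          bbox = c(-44, 44, -32, 54, -26, 26), rng_seed = 42)
tree <- sample_tree(params)
measure_tree(tree)
#> <morphometry> total 139.3 um (apical 97.4, basal 41.9); processes 1/2/3+: 4/2/1

# render into a noisy 8-bit stack and run the full reconstruction
scene <- render_stack(tree, render_params(noise_sd = 10, rng_seed = 1))
cfg <- segmentation_config(frangi_scales = c(0.8, 1.2), threshold = 0.1)
res <- reconstruct_neuron(scene$stack, scene$soma_xyz, scene$apical_ref_xyz, cfg)
res$morphometry
#> <morphometry> total 133.8 um (apical 93.3, basal 40.5); processes 1/2/3+: 4/2/1
res$morphometry$orders
#>   order n_processes length_um n_bifurcations
#> 1     1           4  85.90247              2
#> 2     2           2  36.64679              1
#> 3     3           1  11.22497              0
```

The recovered total (133.8 µm) is within 5% of ground truth (139.3 µm)
and the per-order process counts (4 primary, 2 secondary, 1 tertiary) and
bifurcation counts are exact — the package's headline guarantee on
well-separated arbors.

```r
# fEPSP parameterization and pharmacological blockade
w <- simulate_fepsp(fepsp_sim_params(condition = "aCSF", noise_sd_mV = 0.01,
                                     rng_seed = 7))
analyze_fepsp(w)
#> <fepsp_params:aCSF> peak -0.632 mV, rise 0.383 ms, decay NA ms, AUC 14.174 mV*ms

aucs <- sapply(c("aCSF", "CNQX", "CNQX+ifenprodil"), function(cc) {
  wc <- simulate_fepsp(fepsp_sim_params(condition = cc, noise_sd_mV = 0))
  suppressWarnings(analyze_fepsp(wc))$auc_mVms
})
round(blockade_percent(aucs[-1], aucs["aCSF"]), 1)
#>            CNQX CNQX+ifenprodil
#>            29.7            55.8
```

The peak is the fitted rise plateau (signed, negative-going); the decay
time is `NA` because the slow NMDA tail does not return to 33% of peak
within the trace — reported honestly rather than extrapolated. CNQX
removes the AMPA share of the 30-ms integrated response (29.7% here, set
by the component amplitudes), and adding ifenprodil removes the GluN2B
share on top.

```r
# a planted 35% basal-length reduction, n = 8 vs 8
cohort <- simulate_cohort(effect = 0.35, n_per_group = 8, rng_seed = 3)
basal <- function(trees) sapply(trees, tree_system_length, "basal")
mann_whitney(basal(cohort$control), basal(cohort$treated))
#> <Mann-Whitney U> statistic=61 p=0.001088 (n=8/8, exact)
```

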