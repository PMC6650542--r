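---
title: "Methods: 3D dendritic morphometry and fEPSP decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D dendritic morphometry and fEPSP decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`neuroarbor` quantifies two complementary readouts of cortical pyramidal
neuron remodeling: the geometry of the dendritic arbor, reconstructed in 3D
from single-neuron fluorescence z-stacks, and the shape of evoked field
excitatory postsynaptic potentials (fEPSPs) recorded extracellularly under
sequential pharmacological blockade. This vignette explains the models and
procedures, the parameters that matter, and the limits of what the
synthetic-data tests demonstrate.

## The imaging chain

### Segmentation

A raw 8-bit stack passes through four deterministic stages:

1. **Histogram normalization** (`normalize_stack`): the full-stack
   `[min, max]` range is mapped linearly onto `[0, 1]`. This removes
   acquisition-gain variability between samples; a constant stack is a
   degenerate input and is refused.
2. **Perona–Malik anisotropic diffusion** (`anisotropic_diffusion`):
   explicit edge-preserving smoothing on the 6-neighborhood with
   exponential conductance `g(d) = exp(-(d/kappa)^2)`. The two free
   parameters are the conductance threshold `kappa = 0.1` (normalized
   intensity units: gradients well below 0.1 diffuse freely, step edges of
   height ~0.8 are preserved) and the time-step factor `0.99`, applied as
   `0.99 / |neighborhood|` per iteration so the explicit scheme stays
   stable. Ten iterations by default. The scheme is in flux form under
   zero-flux boundaries, so total intensity is conserved to numerical
   precision and values never leave the input range. A `slicewise` flag
   runs the same scheme per z-slice (4-neighborhood) for stacks whose
   z-sampling is too coarse for volumetric smoothing.
3. **Frangi vesselness** (`frangi_vesselness`): multiscale Hessian
   eigenvalue filtering for bright tubes, with `alpha = beta = 0.5` and
   the structureness scale `c` set to half the maximum Hessian Frobenius
   norm. Derivatives are computed in physical micrometers (the Gaussian
   sigma is converted per axis by the voxel spacing), so anisotropic
   stacks — z typically coarser than xy — are differentiated correctly.
   Two numerical choices matter:
   * second derivatives carry the `sigma^2` scale normalization, and
   * `c` is shared across the whole scale space rather than recomputed per
     scale. A per-scale `c` silently renormalizes each scale's response
     and destroys scale selection; with a shared `c` the response of a
     tube of radius r peaks at the configured scale nearest r.
   The default scales `{1, 2, 4}` µm cover the caliber range of apical
   trunks down to terminal branchlets; for phantoms of a single known
   radius the tests use scales bracketing that radius.
4. **Threshold** (`binarize`): a scalar in `(0, 1)` applied to the
   vesselness map. The original workflow used a manually chosen threshold;
   to keep the pipeline scriptable the threshold is a configuration value
   (default 0.1) and `suggest_threshold` provides an Otsu-based suggestion
   computed on the nonzero vesselness histogram.

`validate_object` then reproduces the manual sanity check as a report: the
number of 26-connected components, speckle removal below
`min_component_size` (default 100 voxels — a tube fragment of ~2 µm at the
default sampling; anything smaller is noise), whether distinct retained
objects would touch after 1-voxel dilation, and a `potential_contact` flag
raised when a retained component is held together by a single articulation
voxel (the signature of two neurons touching at a point, which
26-connectivity alone cannot distinguish from one neuron).

### Skeletonization

`extract_initial_skeleton` thins the validated mask to a one-voxel-wide
curve by iterative 6-subiteration removal of *simple points* (points whose
deletion preserves both foreground 26-connectivity and background
6-connectivity in their neighborhood). Two anchoring rules stop geometric
erosion: voxels with at most one foreground neighbor, and voxels with
exactly two mutually adjacent neighbors. The second rule is essential: a
two-voxel-wide ribbon otherwise "unzips" from its free end — every deletion
is topologically legal, but the branch retracts entirely.

The voxel curve becomes a spatial graph by taking the minimum spanning tree
of the 26-adjacency graph (edge weight = physical length with a
deterministic index tie-break). The MST removes the staircase triangles a
digital curve inevitably contains and breaks any residual thinning loop.
Nodes sit at voxels of degree ≠ 2; chains become polylines in µm. Three
cleanup passes mirror what a human tracer does implicitly:

* `merge_junction_clusters` (radius 2 µm) collapses junction pairs that
  thinning split across a voxel or two;
* `prune_spurs` (3 µm) deletes terminal stubs shorter than any plausible
  branch — thinning artifacts at tube caps;
* `merge_soma_cluster` (radius 3 µm) contracts everything near the
  user-designated soma position into a single soma node, since the trunks
  of a real neuron emanate from an extended soma, not a point.

Terminal branches are extended outward by half the local radius (read from
the distance transform at the tip). Vesselness decays at tube end caps, so
the thresholded mask — and hence the skeleton — systematically stops short
of the true tip; on noise-free phantoms the half-radius compensation
centers the length error near zero (it was calibrated there, see
"Synthetic data" below).

### Skeleton reduction

The raw skeleton is simplified under a two-term objective,

&nbsp;&nbsp;&nbsp;&nbsp;E = fidelity + λ · (number of polyline segments),

where fidelity is the mean distance (µm) of foreground mask voxels to the
skeleton: a balance between representing the segmented volume and using as
few segments as possible. `reduce_skeleton` performs greedy
Douglas–Peucker-style removals of interior polyline vertices (lowest index
first, for determinism), accepting any removal with ΔE ≤ 0, with a hard
cap on the fidelity term (default 1.5 µm — roughly the mean mask-voxel
distance of a perfectly centered skeleton in a 2 µm-caliber tube, plus
headroom). Each mask voxel is assigned once to its initially nearest edge
and the assignment is kept fixed; this makes ΔE local to an edge and the
whole reduction linear-ish in skeleton size, at the cost of a slight
overestimate of the fidelity term near junctions. E is non-increasing over
accepted steps by construction (the accepted values are logged in the
`E_log` attribute), only interior vertices are touched so connectivity and
acyclicity are preserved, and λ = 0.5 µm/segment by default: large enough
to flatten voxel staircases (whose removal costs almost no fidelity), small
enough never to straighten a genuine bend of a branch. On 12-vertex test
polylines the greedy result's E lands within 5% of the exhaustive
all-subsets optimum, and in practice at the optimum itself.

The exact weight and fidelity metric behind the published description of
this trade-off are not recoverable from the text; the implemented E is a
faithful but non-unique reading, which is why the tests pin its
*properties* (monotone E, λ-monotonicity of segment counts, near-optimality
on small instances) rather than specific values.

### Morphometry

`orient_tree` roots the skeleton at the soma node (refusing cyclic or
disconnected graphs), `label_apical` flags the soma-emanating subtree
containing a user-supplied apical reference point — everything else is
basal — and `assign_orders` implements the recursive longest-path rule:
the longest (in µm, not edge count, since µm is the reported unit)
root-to-leaf path of each soma-emanating subtree is the primary process;
edges branching off an order-k path root subtrees whose longest paths are
order k+1. Ties between equally long paths break toward the smallest leaf
node id, a documented arbitrary choice that makes labels reproducible
under renumbering-free conditions. `measure` then reports total, apical
and basal length, and per order: process counts (counted as maximal
same-order paths — the reading of "number of processes per category"
adopted here), lengths, and bifurcation counts (branch nodes attributed to
the order of their incoming edge; the soma is not a bifurcation).
Categories of order ≥ 3 aggregate into "higher" while per-order detail up
to order 5 is retained.

Soma and apical designations are manual in the original workflow; here
they are physical coordinates supplied to `reconstruct_neuron`. A
heuristic fallback (soma = node of maximal distance-transform radius) is
deliberately not the default: on phantoms without a soma blob it is
meaningless, and on real data it should be an explicit user choice.

## The fEPSP chain

fEPSPs are negative-going. All fits run on signed mV; reported peaks keep
their sign and the area under the curve (AUC) reports magnitude.

* **Onset** (`detect_onset`): the published analysis takes "time 0" at the
  beginning of the fEPSP without defining it; the implemented criterion is
  the first post-stimulus time at which |V − baseline mean| exceeds 3
  baseline standard deviations continuously for 0.5 ms, after a 1 ms
  stimulus-artifact blanking window. All three numbers are configurable.
  Under the 3σ-sustained rule, pure baseline noise triggers a false onset
  in well under 5% of traces.
* **Split** (`split_at_extremum`): rise = [onset, most negative sample],
  decay = [extremum, end], sharing the extremum sample. An extremum on the
  final sample means the decay is truncated: a warning, and no decay fit.
* **Boltzmann fits** (`fit_boltzmann`): each segment is independently fit
  with `B(t) = A2 + (A1 − A2) / (1 + exp((t − t50)/k))` (early plateau A1,
  late plateau A2, half-transition t50 where B = (A1+A2)/2, slope k > 0)
  by Levenberg–Marquardt least squares. Initialization comes from the
  segment endpoints and mid-level crossing with `k = duration/10`, with up
  to five deterministically jittered restarts. The fit is box-constrained:
  t50 inside the segment's time span, plateaus within 1.5× the voltage
  range. The constraint is not cosmetic — the rise segment starts at the
  event onset, so the sigmoid's foot lies outside the data window and an
  unconstrained A1 drifts to arbitrary values that poison the rise-time
  inversion. The low-level `minpack.lm::nls.lm` optimizer is used because
  the formula-interface wrapper cannot represent an exactly-zero-residual
  solution.
* **Parameters** (`compute_params`): peak = the rise fit's late plateau
  A2; rise time = time after onset at which the fitted rise reaches 67%
  of the peak, by closed-form inversion
  `t(y) = t50 + k·log((y − A1)/(A2 − y))`; decay time = time after the
  extremum at which the fitted decay returns to 33% of peak — a convention
  of this package mirroring the 67% rise criterion, since no published
  definition exists. When the fitted decay plateau never reaches the 33%
  level (normal for slow NMDA-receptor tails inside an 80 ms trace) the
  decay time is `NA` with a warning rather than an extrapolated guess.
  AUC = trapezoidal integral of |V − baseline| over the 30 ms following
  onset, with linearly interpolated window edges.
* **Blockade** (`blockade_percent`, `blockade_summary`): percentage block
  of the integrated response, `(1 − AUC_drug/AUC_reference)·100`, computed
  per slice and then aggregated as mean ± SEM. Per-slice-first ordering
  matters: the mean of ratios is not the ratio of means, and published
  blockade percentages are only consistent with the per-slice reading.

## Statistics

`mann_whitney` computes U from rank sums and takes the exact two-sided
p-value (full enumeration distribution) whenever the pooled sample is ≤ 24
without ties, otherwise the normal approximation with tie and continuity
correction; both paths are exposed because published morphology p-values
do not state which was used. `anova_bonferroni` is one-way ANOVA followed
by pooled-variance pairwise t-tests with Bonferroni multiplication capped
at 1 — the structure of the published electrophysiology analysis (its
Methods section says two-way, its figure legend one-way; the legend
matches the reported contrasts and is followed here). `summarize_groups`
produces mean ± SEM tables with the chosen test attached. The significance
threshold default is α = 0.05.

## Synthetic data: what it emulates, and what it does not

`sample_tree` grows ground-truth arbors by a depth-limited Galton–Watson
process: each process is a chain of straight segments; each branch tip of
depth d < `max_depth` bifurcates with probability p. One trunk is apical
(fixed trunk length before its first bifurcation), `n_basal_trunks` are
basal. `render_stack` rasterizes the tree as tubes in physical µm
(anisotropic spacing handled exactly), applies a Gaussian PSF, adds
Gaussian noise, and quantizes to 8 bits, returning the noise-free tube
mask as ground truth. `simulate_fepsp` builds traces from three
peak-normalized difference-of-exponentials components with the condition
logic of sequential blockade: CNQX removes AMPA; CNQX + ifenprodil removes
AMPA and GluN2B, leaving GluN2A.

Default choices, made once at design time:

* **Cohort generator defaults** (`branch_probability = 0.9`, 5 basal
  trunks, 2 segments of ~6 µm per branch, depth 3, 20% lognormal
  between-neuron scale variability): chosen so the between-neuron
  coefficient of variation of total basal length is ~0.25, the value
  implied by published group SEMs for layer-V pyramidal basal arbors, and
  so that basal trunks essentially always bifurcate, as real basal
  dendrites do. Under these conditions a planted 35% basal reduction at
  n = 8 vs 8 is detected by the Mann–Whitney test in roughly 85–90% of
  replicates — comparable to the sensitivity of the published design.
* **Imaging phantoms** use a sparser tree (3 basal trunks, p = 0.6,
  1.2 µm radius) with a rejection-sampling guarantee of ≥ 5 µm centerline
  clearance between branches at tree distance ≥ 2 edges, because the
  end-to-end recovery guarantee is explicitly conditional on inter-branch
  spacing of at least 4 tube radii: branches that run closer than the
  PSF-blurred tube diameter merge in any intensity-based segmentation.
* **Stack geometry**: tests render 192×192×64 voxels at 0.5×0.5×1.0 µm —
  a desk-scale stand-in for full-frame acquisitions, chosen so a complete
  render–segment–skeletonize–measure cycle takes seconds. Full-size stacks
  are supported through `render_params`. The published z-step of 0.1 µm
  with a 5×/0.12 NA macro objective is physically surprising (two orders
  of magnitude below the axial resolution); z-spacing is therefore a free
  parameter rather than a hard-coded constant.
* **fEPSP kinetics** (τ_rise/τ_decay: AMPA 0.5/8 ms, GluN2A 3/50 ms,
  GluN2B 7/250 ms): textbook-order time constants reproducing the key
  qualitative facts — AMPA dominates the fast peak, GluN2A rises and
  decays faster than GluN2B. Amplitudes (−0.45/−0.15/−0.25 mV) give an
  aCSF peak near −0.6 mV, the magnitude typical of layer II–III field
  recordings.

What passing tests do **not** show about real data: phantoms have constant
tube radius, no spines, no neighboring neurons, no depth-dependent
attenuation, no shot noise, and branching statistics far simpler than a
real arbor; fEPSP templates have no fiber volley, stimulus artifact decay,
or population-spike contamination. Recovery numbers on synthetic data are
an upper bound on real-data performance, and the manual soma/apical
designations remain genuinely manual choices on real stacks.

## Degenerate inputs and numerical conventions

Constant stacks, empty masks, multi-component masks, cyclic "trees",
constant fit segments and zero reference AUCs all raise typed errors
(`degenerate_input`, `precondition_error`, `topology_error`,
`fit_failure`, ...) rather than propagating NaN. Voxel (i, j, k) is
centered at ((i − ½)·Δx, ...) µm; all lengths are arc lengths of polylines
in µm to 1e-6; seeds make every generator a pure function of its
parameters.

## Problem sizes used in the shipped checks

The test suite and the acceptance script use 6–10 rendered neurons at
192×192×64 voxels, 3–5 noisy renders for overlap scores, 100–500 random
cases for the enumeration and branch-order oracles, 100–200 Monte-Carlo
replicates for fit recovery and cohort power, and exhaustive search over
all 1024 subsets of a 12-vertex polyline for the reduction benchmark —
sizes at which every oracle is computable exactly and a full run completes
on a laptop in a few minutes.
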