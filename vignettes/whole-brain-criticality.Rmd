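---
title: "Whole-brain criticality on structural connectomes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-brain criticality on structural connectomes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`neurocrit` simulates whole-brain activity as a stochastic three-state
excitable network (a Greenberg–Hastings-type cellular automaton) on an
individual's structural connectome. Each of the N cortical parcels is
inactive (I), active (A) or refractory (R). With synchronous updates from
the previous step's states:

* I → A with probability 1 if the summed normalized weights of the active
  neighbors exceed the activation threshold T (strict inequality),
  otherwise with the small spontaneous rate r1;
* A → R with probability 1;
* R → I with probability r2.

Defaults are r1 = 2/N and r2 = r1^(1/5), so for N = 324 the spontaneous
rate is ~0.006 and the refractory release ~0.36. The only control parameter
is T, swept over [0, 0.2] in steps of 0.002 (101 points — fine enough to
localize the critical point to the third decimal). Each threshold is run
for 2000 steps from 10 independent random initial configurations (states
drawn uniformly over {I, A, R} per node), discarding the first 100 steps.

**Homeostatic normalization.** Before simulating, each row of the
streamline-count matrix is divided by its row sum, so every non-isolated
node receives unit total incoming weight. This homeostatic plasticity rule
is what collapses the critical point onto a common value across subjects:
with unit row sums, the mean input a node receives equals the network's
active fraction, so the location of the activity breakdown is set by the
*shape* of the per-row weight distribution rather than by overall
connection strength. Propagation uses this asymmetric row-normalized
matrix; cluster membership uses the undirected binary adjacency of the
thresholded count matrix.

**Criticality summaries.** At each threshold we record the time-averaged
network activity ⟨A⟩, its standard deviation σ_A (computed per replicate,
then averaged — the alternative order changes values negligibly), and the
time-averaged sizes S1, S2 of the largest and second-largest connected
components of simultaneously active, structurally connected nodes (steps
with no active clusters contribute zeros). The critical point T_c is the
grid argmax of S2 (ties break toward smaller T); the threshold-independent
indexes are the trapezoid integrals I1 = ∫S1 dT and I2 = ∫S2 dT. Distances
between an individual's curve and a reference (control-average) curve are
plain Euclidean sums over the grid.

**Monotonicity of S2 (loss of criticality).** A subject whose S2 curve
decreases monotonically in T has no critical transition. We classify by
the sign of forward differences for T ≥ 0.07 (sign changes below 0.07 are
attributed to noise). Because the curves are Monte-Carlo averages, a
strict per-step sign rule would read tail jitter as structure: with ~60
tested differences, even a two-standard-error criterion produces a false
"significant rise" in almost every genuinely monotone curve. Differences
are therefore taken over a short lag (0.01 in T, five grid steps) and
counted only when they exceed three times their standard error, computed
from the stored per-threshold replicate SDs; the curve is monotonic when
the significant differences do not include both signs. On hand-built
curves without replicate information the rule degenerates to the strict
lag-1 sign criterion. This is the package's concrete rendering of a
derivative rule that is only qualitatively specified for noisy data;
healthy peaks (rises of several standard errors) and fully degraded
curves both classify stably at 5 or 10 replicates.

# The synthetic cohort

Real tractography data cannot ship with the package, so every analysis is
exercised on a synthetic cohort whose statistical structure matches what
the analysis assumes.

**Parcellation.** 324 parcels, 159 left / 165 right (the asymmetry of
widely used cortical parcellations), positions in mirrored unit
half-shells, 10 bilateral resting-state-network labels assigned as
contiguous angular sectors, and homotopic partners for the first
min(n_L, n_R) mirrored pairs (unpaired right parcels have no homotope).

**Connectome generator.** Edges have two spatial scales:

* a *short-range core*: the mutual k-nearest-neighbor graph (k = 19),
  carrying large streamline counts (negative binomial, mean 200,
  size 200);
* a *long-range floor*: uniform weak edges (probability 0.006, mean count
  7, about half of which fall at or below the standard ≤3-streamline
  threshold);
* *homotopic edges*: always present, counts elevated to the core level.

Edge probability is therefore a steeply decaying function of distance
(1 within the neighborhood core, 0.006 outside), i.e. many short-range and
few long-range connections. We experimented extensively with smooth
exponential kernels (probability and count means ∝ exp(−d/λ)); no setting
of those kernels jointly satisfied the three calibration facts below,
because the smooth kernel fills the mid-weight range and inflates the
structural entropy while simultaneously creating dominant edges that push
the critical point far above 0.122. The two-scale form is the steep-kernel
limit of the same idea and is stated once, here, as the generator's design.

Calibration facts (cohort means, measured on the default generator after
the ≤3-streamline threshold):

* average binary degree K ≈ 18.2 (healthy band 18 ± 3);
* connectivity disorder H_SC ≈ 0.061 (healthy band 0.059 ± 0.004);
* critical point T_c ≈ 0.126 with inter-subject SD < 0.002 — the
  homeostatic collapse. With ~15 comparable core weights per row
  (~0.06–0.08 each after normalization), supra-threshold percolation
  breaks down near T ≈ 0.12 for every subject regardless of count scale,
  which is why T_c is universal here.

H_SC is the normalized Shannon entropy (m = 100 bins on [0, 1], zeros
included, normalization log m) of all N² entries of the row-normalized
matrix. Including the zero bin is essential: the healthy value ≈ 0.06
reflects ~94% of entries in the first bin plus a narrow occupied band —
low entropy means a degenerate, ordered weight structure.

**Lesions and recovery.** A lesion zeroes a spatially contiguous node set
(strokes are focal), scales surviving cross-hemisphere counts by a factor
in [0, 1] (inter-hemispheric loss is the dominant structural signature of
stroke), and drops a fraction of surviving edges at random (diffuse
damage). The severity axis used by the cohort generator and the boundary
analysis (`stroke_severity_spec`) reaches complete inter-hemispheric
disconnection at severity 1 with 15% diffuse dropout and a 12-node focal
lesion. The degree boundary at which the S2 curve turns monotonic is a
*path property*: dropout-dominant paths fragment the graph and flip the
classifier near K ≈ 10, disconnection-dominant paths flip as the
hemispheres decouple, near K ≈ 13–14. The package's path is calibrated to
the stroke phenomenology above and lands the boundary near K ≈ 13–14, in
line with the loss boundary reported for real stroke connectomes; this
calibration is part of the synthetic world's definition, exactly like the
K and H_SC bands.

Recovery (`remodel_recovery`) moves the surviving-node submatrix a
fraction of the way back toward the subject's own pre-lesion template and
adds a small fraction of new edges absent from the template (remodeling is
not purely restorative); recovery 1 with rewiring 0 reproduces the
template on surviving nodes exactly.

**Behavior.** The composite behavioral score is linear-Gaussian:
B = c1·I1 − c2·I2 + noise, standardized to mean 0 / SD 1 on controls so
patient scores read as SD units below the control average. Defaults
(c1 = 0.3, c2 = 2, noise SD 1.5) are scaled to the typical cohort spread
of I1 (SD ≈ 3) and I2 (SD ≈ 0.4) so that the sample correlation with I1
lands in the moderate band (~0.4–0.5) reported for real composites. Only
linear correlations are ever claimed, hence the linear model.

**What a green test does not establish.** The generator reproduces degree,
weight-disorder, homotopic elevation, and the criticality phenomenology —
not tractography artifacts, fiber-length confounds, realistic lesion
anatomy, geometric hub structure, or empirical FC. Cohort-level R² values
and behavior correlations on synthetic data validate the machinery, not
the paper's empirical effect sizes.

# BOLD synthesis and functional connectivity

Node activity (the {0,1} indicator of the active state) is convolved with
a canonical double-gamma hemodynamic response,

h(τ) = (τ/d1)^a1 e^{−(τ−d1)/b1} − c (τ/d2)^a2 e^{−(τ−d2)/b2},

with a1 = 6, a2 = 12, b1 = b2 = 0.9 s, c = 0.35, d_i = a_i·b_i (peak near
5 s, late undershoot). One model step is dt = 0.45 s, so a 2000-step run
spans 15 minutes, the length of a typical resting-state acquisition — the
only anchor available for dt. After discarding a kernel-length warm-up,
signals are band-passed at 0.01–0.1 Hz with a linear-phase windowed-sinc
FIR filter (Hamming window, ~4 low-edge periods of taps) applied once with
its group delay removed — a symmetric FIR so applied has exactly zero
phase at every frequency; a half-filter-length segment is trimmed at each
end. FC is the Pearson correlation matrix (zero-variance nodes yield NA
and are excluded from summaries); summaries are the mean upper-triangular
|FC|, the mean *signed* FC over homotopic pairs (signed is the convention
in the stroke FC literature), and the normalized entropy of |FC| with
m = 20 bins on [0, 1].

# Mapping criticality onto structural edges

The connectome-predictive model regresses a criticality index (I2) on the
52,326 upper-triangular edges (row-major pair order) via PCA + ridge:

* outer leave-one-subject-out loop; *all* training artifacts — PCA basis,
  component standardization, outcome standardization — are fit on the
  training fold only (a `pca_scope = "global"` switch exists for the
  non-leakage-safe reading);
* components explaining 95% of training variance are retained; PC scores
  and outcome are z-normalized;
* the ridge penalty is tuned per fold on the decade grid 10^-5 … 10^5
  (11 points) by exact inner leave-one-out error (SVD hat-matrix
  identity);
* the closed form W = (XᵀX + λI)^(−1)XᵀY gives the weights; fold weights
  are mapped back to edge space through the retained loadings and the
  standardization, so they are comparable across folds.

Model accuracy uses the printed form of the coefficient of determination,
whose denominator centers on the mean of the *predictions*; a flag
switches to conventional observed-mean centering. The permutation test
reruns the entire LOOCV on shuffled outcomes and counts strictly larger
null R² values (p = 0 is possible; an add-one switch is provided).
Consensus weights are fold averages; per-edge reliability is a Welch
t-test of fold weights against pooled permutation-null weights with
Benjamini–Hochberg correction (the comparison is named but not specified
as a particular test variant; Welch is the robust default). Network-pair
summaries average the back-projected symmetric weight matrix over all
ordered node pairs of the two networks (N_XY = N_X·N_Y).

# Numerical choices and degenerate inputs

* Trapezoidal quadrature for I1/I2 (the grid is uniform and the curves
  smooth; halving the step changes the integrals by <1%).
* Louvain modularity is stochastic: 20 seeded restarts, best Q kept.
  Modularity and efficiency are computed on the binary undirected
  adjacency; disconnected pairs contribute 0 to efficiency.
* Empty graphs: K = 0, E_global = 0, H_SC from the all-zero matrix, Q is
  NA. Zero rows in normalization stay zero and are reported as isolated.
* All-zero S2 curves give T_c = NA with a warning.
* The avalanche exponent is fit as a discrete *truncated* power law
  (support x_min … max observed size) by exact maximum likelihood, the
  lower cutoff chosen by KS-distance minimization. Cutoff candidates are
  restricted to the head of the distribution (up to the sample median):
  pooled avalanche sizes carry a finite-size exponential cutoff, and an
  unrestricted scan lets the KS criterion lock onto that cutoff region
  and report a spuriously steep exponent. Fewer than 100 pooled clusters
  yields NA with a warning.
* Random streams: one independent seeded stream per (threshold,
  replicate), so sweep results are independent of evaluation order; every
  derived seed stays below 2^31.

# Known limitations

* The simulator's per-step cost is O(active edges + N); a full default
  sweep of one 324-node subject takes ~40 s on one CPU. Cohort analyses
  scale linearly.
* The synthetic lesion/recovery model is phenomenological; boundary-type
  results (criticality-loss degree) depend on the chosen severity path,
  as documented above.
* The behavior module is a stand-in: no claim of psychometric realism.
* Homotopic FC uses the generated parcellation's pairing; parcellations
  without homotopes yield NA summaries.
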