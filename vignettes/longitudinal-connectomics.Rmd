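---
title: "Methods: longitudinal connectome analysis with normative Z-scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal connectome analysis with normative Z-scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longconn)
```

## The analytical problem

`longconn` asks whether brain network organization changes between two
scans of the same patient, referenced against a cross-sectional cohort of
healthy controls. The inputs are streamline-count connectomes: square,
symmetric, nonnegative matrices whose entry $w_{ij}$ counts tractography
streamlines between parcels $i$ and $j$ of a multi-resolution atlas
(five nested scales; per hemisphere, the atlas carries seven thalamic
subregions, a head/body/tail hippocampus split, and four brainstem
parcels). Because healthy children's connectomes change with age, raw
early-vs-late comparisons would conflate development with disease: every
feature is therefore expressed relative to an age- and sex-adjusted
normative model fitted on the controls, and only the *adjusted* quantities
are compared between scans.

The pipeline has four analysis blocks, all driven by
`run_longitudinal_analysis()`:

1. **Global metrics** — mean degree (mean nodal strength), weighted
   transitivity, modularity $Q$, global efficiency, and the means of nodal
   average and modal controllability. Patients' age/sex-adjusted residuals
   are compared early vs late with a paired Wilcoxon signed-rank test and
   Cohen's $d$; subgroup heterogeneity (histopathology, seizure freedom)
   is probed with Kruskal–Wallis on the residual changes.
2. **Nodal burden** — strength, participation coefficient, eigenvector
   centrality, local efficiency, average and modal controllability per
   parcel; each parcel's Z-score is computed from per-parcel normative
   models, and the per-subject count of parcels with $|Z| > 2$ (total,
   $Z > +2$, $Z < -2$) is the quantity compared between scans.
3. **Thalamocortical connectivity** — streamline sums from each
   hemisphere's thalamic parcels to its ipsilateral cortical lobes (10
   hemisphere–lobe pairs), Z-scored and compared; plus a within-patient
   "z-of-z" that standardizes the ten per-lobe Z-changes inside each
   patient and asks, via a one-sample t-test, whether the epilepsy-affected
   lobe's change stands out.
4. **Thalamic modal controllability** — Z-scores of the fourteen thalamic
   parcels' modal controllability; the paired test runs on each patient's
   mean thalamic Z (per-parcel tables are also emitted).

Significance uses a fixed threshold $P < 0.01$ as the multiple-comparison
policy; raw p-values are always emitted alongside the thresholded flag.

## Metric definitions and conventions

Definitions follow the weighted forms standard in the brain-connectivity
literature; several were genuinely open choices and are recorded here.

* **Degree is weighted strength.** "Degree" denotes the sum (and "mean
  degree" the mean) of streamline weights, not binary edge counts.
* **Transitivity** uses the Onnela geometric-mean triangle intensity over
  the binary triplet count: with $\hat w = w / \max(w)$,
  $T = \sum_i (\hat W^{1/3})^3_{ii} \big/ \sum_i k_i (k_i - 1)$.
* **Paths are reciprocal weights.** Shortest-path lengths use edge length
  $1/w$; global efficiency averages $1/d_{ij}$ over ordered pairs with
  unreachable pairs contributing 0, and local efficiency is the global
  efficiency of each node's neighbour-induced subgraph.
* **Communities** come from Louvain at resolution $\gamma = 1$ with an
  explicit RNG seed (Louvain's sweep order is stochastic; the seed makes
  runs reproducible). The participation coefficient of a connectome uses
  that same connectome's partition. $Q$ is Newman's weighted modularity of
  the returned partition, computed by its defining formula.
* **Eigenvector centrality** is the Perron eigenvector (power iteration on
  a spectrally shifted matrix so bipartite-like graphs converge),
  normalized to unit Euclidean norm.

### Network controllability

Dynamics are the discrete-time linear system
$x(t+1) = A\,x(t) + B\,u(t)$ with $A = W / (1 + \lambda_{\max}(W))$, which
for nonnegative symmetric $W$ guarantees spectral radius $< 1$, and
single-node input $B = e_i$. No additional stabilization offset is added.
For symmetric $A$ with eigenpairs $(\lambda_j, v_j)$:

* **Average controllability** is the trace of the infinite-horizon
  controllability Gramian,
  $\mathrm{AC}_i = \sum_j v_{ij}^2 / (1 - \lambda_j^2) \ge 1$ — the closed
  form of the discrete Lyapunov solution, so one eigendecomposition serves
  all nodes. Tests verify it against 500-term series summation.
* **Modal controllability** is
  $\phi_i = \sum_j (1 - \lambda_j^2)\, v_{ij}^2 \in (0, 1]$, using the
  discrete-time $1 - \lambda^2$ weighting for consistency with the
  normalization above. The continuous-time variant and the exact scheme
  behind any particular in-house implementation vary across the
  literature; this convention is the package's documented default.

## Normative modelling

Per feature (a global metric, a parcel-metric pair, a lobe sum), an
ordinary least-squares fit — a Gaussian identity-link GLM — of
`feature ~ age + sex` on controls, with female as the sex baseline and no
age–sex interaction; an optional `age^2` term is available via
`analysis_config(age2 = TRUE)` but off by default, the minimal reading of
"age and sex adjustment". Nodal models are independent per (parcel,
metric); no spatial shrinkage. Patient Z-scores are
$z = (r - \bar r_c) / s_c$ where $r$ is the patient's residual and
$\bar r_c, s_c$ the control residual moments, so control training
Z-scores have mean 0 and SD 1 by construction. Patients younger than the
youngest control are extrapolated (with a warning available at the lower
API level) rather than refused; the young-patient sensitivity analysis
(`exclude_age_below = 6`) is the principled handling. Abnormality counts
are *strictly* outside $\pm 2$ — ties at exactly 2.0 are measure-zero, and
strictness makes the count deterministic.

Global metrics are compared as raw residuals (their scales are already
interpretable); nodal, thalamocortical and thalamic-controllability
features are compared as Z-scores. The z-of-z includes the affected lobe
itself in the within-patient mean/SD, and each patient contributes one
value, from the affected hemisphere and lobe.

## Statistical machinery

The paired Wilcoxon signed-rank test drops zero differences, uses the
exact null distribution for $n \le 25$ without ties (validated in the test
suite against full $2^n$ sign enumeration), and otherwise the normal
approximation with tie and continuity corrections. Cohen's $d$ for paired
data is $\overline{d} / s_d$ on the difference scores ($n-1$ SD); the
average-marginal-SD variant is available via
`analysis_config(d_denominator = "average_sd")`. Kruskal–Wallis drops
subgroups with fewer than two members. All pipeline outputs are
deterministic given seed and configuration, which the test suite checks
byte-for-byte.

## What the synthetic cohort emulates

The generator (`generate_control_cohort()`, `generate_patient_pairs()`)
exists so every stage can be exercised and calibrated without clinical
data. Defaults mirror the study conditions the pipeline targets: 57
controls, 23 patient pairs, control ages 6–18, patient early-scan ages
3–16 (so some patients are younger than every control), and a log-normal
inter-scan interval with median 1.15 years and sdlog 0.67 (interquartile
range roughly 0.78–1.93 years).

The anatomical backbone is a weighted block structure over the synthetic
parcellation: strong within-lobe cortical blocks (expected weight 30),
weaker between-lobe (6), homologous cross-hemisphere (10) and diffuse
cross-hemisphere (1.5) connections, ipsilateral thalamocortical bundles
(12), hippocampal–temporal connections, and brainstem–thalamic links.
These values were chosen once so that modularity and participation are
non-degenerate (Louvain recovers lobe-like communities) and thalamocortical
sums are well-populated; they are parameters of
`simulation_manifest()`, not calibrated quantities.

A scan's matrix is
$w_{ij} = b_{ij} \exp\!\big(\beta_a (a - 10) + \beta_s \mathbb{1}[\text{male}]
+ u + e_{ij} + s + \varepsilon_{ij}\big)$, with age slope
$\beta_a = 0.015$/year and male offset $\beta_s = 0.05$ on the log-weight
scale, a subject-level global scalar $u \sim N(0, 0.1^2)$ and subject-level
edge effects $e_{ij} \sim N(0, 0.1^2)$ (both shared between a patient's two
scans), and a *session* scalar $s \sim N(0, 0.05^2)$ plus edge noise
$\varepsilon_{ij} \sim N(0, 0.1^2)$ drawn fresh per scan. The session
term is essential: it represents scanner/tractography test–retest
variability, the dominant within-pair noise for aggregate features.
Without it the paired tests operate at unrealistically high precision and
read the small curvature mismatch between the exponential generative age
effect and the linear normative model as a longitudinal change; with it,
the null cohort is correctly calibrated (verified over 100 replicates in
the acceptance suite) while an injected 1-SD effect remains detected in
essentially every replicate.

Injected effects (`effect_spec()`) multiply the targeted edges by
$\exp(m \sigma_u)$, so the magnitude $m$ is approximately in units of the
between-subject SD of the targeted aggregate feature. Targets cover global
strength, nodal subsets, out-of-lobe (participation-raising) connections,
single thalamocortical lobes, and thalamic rows (modal controllability).

What the generator does **not** emulate: distance-dependent connection
probability, tractography false-positive structure, scanner drift,
integer-valued counts, or realistic case–control baseline differences.
Passing tests therefore demonstrate the *statistical machinery* —
calibration, power, bookkeeping, determinism — not biological fidelity of
any particular effect size.

## Numerical choices and problem sizes

* Symmetry: up to $10^{-6}$ relative Frobenius asymmetry is repaired by
  averaging at read time (floating-point artifacts); more is rejected as
  wrong data. Validated objects must be symmetric to $10^{-9}$.
* Diagonals are zeroed on read: self-connections are discarded, as all
  implemented metrics assume.
* Efficiency denominators use ordered pairs $n(n-1)$; for symmetric
  matrices this equals the unordered convention and is stated for
  bit-reproducibility.
* Degenerate inputs: all-zero networks are an error for modularity,
  eigenvector centrality and `global_metrics()`; zero-strength nodes get
  participation 0; nodes with fewer than two neighbours get local
  efficiency 0; all-zero paired differences and zero-SD effect sizes
  yield `NA` rows in result tables rather than aborting a run.
* The synthetic parcellation uses 2/3/5/8/12 cortical parcels per lobe
  per hemisphere at scales 1–5 (44–144 parcels in total) — large enough
  for non-trivial community and controllability structure, small enough
  that the replicate-heavy calibration tests (100 null + 100 effect
  replicates at 57 + 23×2 scans each) and the full acceptance script
  (scale-3 primary analysis plus a five-scale global sweep) run in
  minutes on one CPU.

## Limitations

The normative model is linear in age; strongly non-linear maturation would
leak into patient Z-scores (the `age2` option is a partial remedy). The
paired tests treat scans as exchangeable under the null and cannot
separate true change from test–retest variability — the same caveat that
applies to the clinical design this pipeline serves. Louvain partitions,
while seeded and reproducible, are a single draw from a degenerate
optimization landscape; participation coefficients inherit that
variability across configurations.
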