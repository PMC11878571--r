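# longconn

Longitudinal analysis of weighted structural connectomes with
control-referenced normative modelling.

## What it is for

In longitudinal neuroimaging studies of focal epilepsy (and other
progressive network disorders), each patient has an early and a late
diffusion-MRI scan, and the question is whether brain network organization
changes between them beyond normal development. `longconn` implements the
complete analysis for streamline-count connectomes:

- **Graph metrics** on weighted adjacency matrices: strength / mean degree,
  Onnela weighted transitivity, Louvain modularity *Q*, global and local
  efficiency (edge length 1/w), participation coefficient, eigenvector
  centrality.
- **Network controllability** under discrete-time linear dynamics
  x(t+1) = A x(t) + B u(t), A = W/(1 + λ_max): average controllability
  (Gramian trace, AC_i = Σ_j v_ij²/(1 − λ_j²)) and modal controllability
  (φ_i = Σ_j (1 − λ_j²) v_ij²).
- **Normative modelling**: per-feature OLS fits of `feature ~ age + sex` on
  healthy controls; patients are expressed as residuals and Z-scores
  z = (r − r̄_c)/s_c, and the burden of "abnormal" parcels (|Z| > 2) is
  counted per subject.
- **Thalamocortical profiling**: streamline sums from each thalamus to its
  ipsilateral cortical lobes (10 hemisphere–lobe pairs), their Z-score
  changes, and a within-patient "z-of-z" asking whether the
  epilepsy-affected lobe changes more than the other nine.
- **Paired statistics**: exact/approximate Wilcoxon signed-rank tests on
  early-vs-late residuals, Z-scores and burden counts, Cohen's *d* on
  difference scores, Kruskal–Wallis subgroup tests, a fixed P < 0.01
  significance policy, and a sensitivity sweep across the five atlas
  scales reported as −log10 p.
- **A synthetic cohort generator** with injectable ground-truth effects,
  so calibration, power and end-to-end behaviour are testable without any
  clinical data.

Inputs are plain text: dense delimited or MatrixMarket connectivity
matrices, a TSV parcellation table (hemisphere, lobe, structure class; 7
thalamic and 3 hippocampal parcels per hemisphere, 4 brainstem parcels),
and a TSV cohort table (age, sex, group, timepoint, histopathology,
seizure freedom, affected lobe). See `vignettes/longitudinal-connectomics.Rmd`
for the full methods account.

## Worked example

```r
library(longconn)

# A synthetic study cohort: 57 controls, 23 early/late patient pairs,
# scale-3 parcellation (74 parcels), no injected effect.
cohort <- generate_study_cohort(scale = 3, seed = 1)
res <- run_longitudinal_analysis(cohort, analysis_config(scale = 3, seed = 1))
res
```

```
<longitudinal_analysis> scale 3, 23 patient pairs, alpha 0.01

Global metrics (paired Wilcoxon on age/sex-adjusted residuals):
                        metric n_pairs median_early median_late p_value
1                  mean_degree      23     4.01e+00   -1.34e+01  0.0354
2                 transitivity      23     1.55e-03   -2.50e-05  0.7768
3                 modularity_q      23    -4.97e-04   -2.47e-04  0.6221
4            global_efficiency      23     1.18e-01   -2.60e-01  0.0449
5 mean_average_controllability      23     2.58e-02   -9.25e-02  0.0354
6   mean_modal_controllability      23     6.33e-05    6.18e-05  0.3146
  cohens_d significant
1  -0.4466       FALSE
2  -0.0363       FALSE
3   0.1119       FALSE
4  -0.4454       FALSE
5  -0.4452       FALSE
6   0.2088       FALSE

Nodal burden comparisons: 0 of 18 significant at P < 0.01

Affected-lobe z-of-z: mean -0.027, one-sample t P = 0.883
```

Read: with no injected effect, none of the six global metrics crosses the
P < 0.01 threshold (the 0.035s are the kind of sub-threshold fluctuation a
23-pair cohort produces), no abnormal-node burden comparison is
significant, and the affected lobe's thalamocortical change is
indistinguishable from the patient's other lobes (z-of-z ≈ 0). Injecting
an effect changes that:

```r
eff <- effect_spec("global_strength", magnitude = 1)   # +1 SD, late scans
cohort2 <- generate_study_cohort(scale = 3, seed = 1, effects = list(eff))
run_longitudinal_analysis(cohort2, analysis_config(scale = 3, seed = 1,
                                                   analyses = "global"))
# mean_degree: median_early 4.01, median_late 29.3,
#              p_value 0.00188, cohens_d 0.785, significant TRUE
```

A thin CLI wraps the same functions after installation:
`longconn simulate --out data --seed 1`, `longconn run --data data --out
results --scale 3`, `longconn sensitivity --data data --out results
--scales 1,2,3 --exclude-age-below 6`.

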