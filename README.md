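# epicoloc

Within-patient co-localisation of grey-matter volume and white-matter
connectivity abnormalities in temporal lobe epilepsy (TLE).

## The problem

In TLE, grey-matter atrophy (regional volume loss, most prominently in the
ipsilateral hippocampus) and white-matter disruption (reduced fractional
anisotropy, FA, along tracts) are both common — but group-level maps of the
two cannot say whether they occur *in the same patients at connected
locations*. `epicoloc` implements a within-patient analysis pipeline for
tabular neuroimaging derivatives:

1. **Harmonization** — parametric empirical-Bayes ComBat removes
   scanner-batch location/scale effects per feature while preserving
   biological covariates.
2. **Normative z-scoring** — per feature, a robust (Huber) regression of
   healthy controls on covariates (age, sex, and intracranial volume for
   volumes; age, sex for FA); every subject's feature is expressed as
   `z = (observed − predicted) / σ_control`.
3. **Ipsi/contra flipping** — after z-scoring against the same anatomical
   hemisphere in controls, right-lateralised patients have homologous
   regions and mirrored edges relabelled so analyses pool by side of seizure
   onset.
4. **Group effect sizes** — per-feature Cohen's d
   `d = (x̄_P − x̄_C)/s_pooled`, plus lobe-level aggregation relating edge and
   endpoint-volume abnormality.
5. **Hierarchical models** — a two-level random-intercepts-and-slopes model
   (REML, `lme4`): the connection z-score `C_ijk` of subject `k` is modelled
   by indicators of one (`V′`) or two (`V″`) volumetrically abnormal
   endpoints,

       C_ijk = a_k + b_k V′_ijk + c_k V″_ijk + ε_ijk,
       a_k = α₀ + u_k,  b_k = β₀ + v_k,  c_k = γ₀ + w_k,

   with shuffle and healthy-control null fits, a β₀ = γ₀ contrast, and a
   threshold scan over τ ∈ {−1.0, …, −2.5}. The mirrored volume-direction
   model explains mean endpoint volume z by a binary edge-abnormality
   indicator.
6. **Co-localisation** — per patient, a Dice-style overlap between node
   abnormalities and incident edge abnormalities (as-printed formula without
   the conventional factor 2; maximum 0.5), ranked against a
   count-preserving permutation null of the edge labels:
   `score = mean(DS_actual > DS_null)` over 5,000 permutations. Hemispheric
   decomposition and a paired Wilcoxon ipsi-vs-contra test follow.
7. **Clinical associations** — Pearson correlation of burden and
   co-localisation with epilepsy duration; Cohen's d + Mann-Whitney U for
   surgical outcome (ILAE 1 vs 2+) and secondary generalisation.

A seeded synthetic-cohort generator emulates the assumed data structure (two
scanner batches, covariate effects, planted ipsilateral atrophy and FA
reduction with tunable node-edge coupling κ, duration weakly correlated with
abnormality load), so the full pipeline is testable without patient data.

## Worked example

```r
library(epicoloc)

cfg <- run_config(
  cohort  = cohort_config(n_controls = 40, n_patients = 48, seed = 2),
  outdir  = "run1", n_perm = 300, seed = 7, satterthwaite = FALSE)
report <- run_pipeline(cfg)

report$hlm$edge_patients$fixed[, c("term", "estimate", "se")]
#>          term    estimate         se
#> 1 (Intercept) -0.03033208 0.01051069
#> 2      vprime -0.05018912 0.01478439
#> 3     vdouble -0.22168059 0.07947547

report$coloc[c("n_defined", "frac_colocalised")]
#> $n_defined        [1] 48
#> $frac_colocalised [1] 0.1041667
```

Reading: relative to connections between two normal regions, FA z-scores are
~0.05 lower for connections touching one abnormal region (`vprime`) and
~0.22 lower between two abnormal regions (`vdouble`) — the generator plants
only 60 abnormal edges per patient, so the population intercept sits near 0
rather than at the deep reductions seen in real cohorts. All 48 synthetic
patients had defined co-localisation scores and ~10% exceeded the 0.95
"co-localised" cutoff at this small simulated size and coupling κ = 0.8. Artifacts (`z_*.tsv`,
`region_d.tsv`, `edge_d.tsv`, `coloc.tsv`, `associations.tsv`, `hlm.json`,
`report.json`) land in `outdir`.

The same pipeline runs from the command line:

```sh
Rscript inst/cli/epicoloc run-all --outdir run1 --seed 7 --n-perm 300
```

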