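---
title: "Methods: abnormality mapping and co-localisation in TLE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: abnormality mapping and co-localisation in TLE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its models and the design
choices behind them. It states no empirical result that the test-suite or
the acceptance script does not itself compute.

## The analysis model

The pipeline operates on three tables per study: subject metadata, an
82-region volume table (mm³) and an edge table of mean fractional anisotropy
(FA) over atlas-defined region pairs. Patients with unilateral temporal lobe
epilepsy are compared against healthy controls acquired under two scanner
protocols.

### Harmonization (ComBat)

Scanner differences act as per-feature location and scale effects. We fit
the standard parametric empirical-Bayes model: features are standardised
against a batch + covariate linear fit, per-(batch, feature) locations
γ and scales δ² are estimated and shrunk with a normal prior on γ and an
inverse-gamma prior on δ², and the adjusted data are re-expressed on the
original scale. Choices:

* **Parametric EB**, the default in neuroimaging use; the non-parametric
  variant is out of scope.
* **Biological covariates are part of the ComBat design** (age, sex, ICV for
  volumes; age, sex for edges), so they are preserved rather than removed.
  Whether ICV belonged in the harmonization design or only downstream is not
  decidable from the source description; including it is the conservative
  choice (it can only improve the batch-effect estimate).
* **Single-batch input short-circuits to the identity**, which keeps
  batch-free synthetic tests meaningful.
* `eb = FALSE` switches to raw per-batch moment equalisation; useful for
  exact fixed-point tests, not recommended for analysis.

### Normative z-scores

Per feature, a Huber M-estimated regression (tuning constant 1.345, MAD
scale, IRLS to relative tolerance 1e-8 or 50 iterations) is fitted to the
pooled post-ComBat controls; the residual scale σ_f is the **plain standard
deviation** of the control residuals. The source analysis says only "robust
linear regression" and "z-scores based on the distribution of healthy
controls": Huber with these constants is the standard default, and the plain
SD reads the "distribution of controls" literally; a robust scale
(1.4826·MAD) is available via `robust_scale = TRUE`. A feature fitted
exactly (zero residual scale) is flagged and given σ_f = 1, so its z-scores
are 0 rather than noise ratios.

### Hemisphere flipping

Z-scoring happens in the anatomical frame — against the same hemisphere in
controls — and only then are right-lateralised patients' homologous regions
swapped and edges remapped to their mirrors ("ipsi/contra frame"). Controls
and left-lateralised patients are relabelled with left as the reference
pseudo-ipsilateral side, values untouched. Edges whose mirror is absent from
the edge set cannot be expressed in the ipsi/contra frame and are dropped
for **all** subjects (logged), preserving comparability; the shipped edge
fixture is mirror-symmetric so nothing is dropped by default.

### Hierarchical models

For patient $k$ and connection $(i,j)$, with $V'$ / $V''$ indicating one /
two volumetrically abnormal endpoints (z < τ, default τ = −1.96):

$$C_{ijk} = a_k + b_k V'_{ijk} + c_k V''_{ijk} + \varepsilon_{ijk}, \qquad
  a_k = \alpha_0 + u_k,\; b_k = \beta_0 + v_k,\; c_k = \gamma_0 + w_k.$$

Fitted by REML (`lme4::lmer`) with an **unstructured** 3×3 random-effect
covariance (lme4's default for correlated intercept and slopes, matching the
named fitting route). The volume-direction model mirrors it with the mean
endpoint volume z as response and a single binary edge-abnormality
predictor. Nulls: response shuffles within subject, and a refit on controls
with their own masks. Notes:

* **P-values.** The source reports p-values without naming a method. We emit
  normal-approximation Wald p-values and a Satterthwaite approximation
  computed in-package (finite-difference Hessian of the REML deviance in
  (θ, σ); gradient of the contrast variance), since no Satterthwaite
  implementation is pre-installed. When the variance-parameter Hessian is
  not positive definite the Satterthwaite df are NA and the Wald value
  stands.
* **Degenerate thresholds.** A τ yielding no abnormal endpoints drops the
  dead predictor (fixed and random part) and records it; the scan reports
  this rather than failing.
* **Single subject** degrades to ordinary least squares with a warning.
* The independent check on the whole REML route is a dense-matrix restricted
  log-likelihood (`reml_loglik_dense`) maximized by `optim` from random
  starts — deliberately naive, so it shares no code with lme4.

### Dice co-localisation

With $V'_i$, $C'$, $V'_j$ the region-one / connection / region-two
abnormality vectors over edges (τ = −1.645 by default, chosen leniently so
more patients have abnormalities in both modalities):

$$DS_i = \frac{|V'_i \cap C'|}{|V'_i| + |C'|},\qquad
  DS = \tfrac12 (DS_i + DS_j).$$

This is the **as-printed statistic, without the conventional Dice factor
2** (maximum 0.5). The co-localisation score is the strict-inequality
percentile of $DS$ within a count-preserving uniform permutation of the edge
abnormality labels (5,000 draws; node masks never permuted); it is invariant
to any monotone rescaling of DS, including the missing factor 2. Zero
denominators are defined as 0; a patient with no abnormal regions or no
abnormal edges has an *undefined* score (NA, excluded from summaries), not
a 0. Ties contribute 0, exactly as the formula is printed. "Paired
Mann-Whitney U" is implemented as the Wilcoxon signed-rank test (exact for
n ≤ 25, normal approximation with tie correction otherwise) — Mann-Whitney
has no paired form. The eligibility cutoff for the hemispheric comparison is
score ≥ 0.95 (the source prints both ">" and "≥"; configurable). The lower
cutoff for "not co-localised" summaries is ≤ 0.05, an assumption the source
leaves open.

## The synthetic cohort

The generator states a world and keeps it fixed; its defaults are the
published cohort structure wherever one is printed:

| parameter | default | provenance |
|---|---|---|
| group sizes | 96 controls / 144 patients | printed cohort |
| batch split | 29/67 controls, 84/60 patients | printed cohort |
| duration | log-normal, median 21.9 y, truncated [3.5, 55.3] | printed range/median |
| ILAE 1 rate | 0.57 | printed |
| secondary generalisation | 0.77 | printed |
| hippocampal sclerosis | 0.51 | printed |
| atrophy targets | ipsi hippocampus, thalamus, superior/middle temporal, temporal pole | the regions the group maps single out |
| planted d (volume) | −1.0 | the printed hippocampal effect-size scale |
| duration-burden correlation ρ | 0.2 | the printed r = 0.18–0.23 scale |

Where nothing is printed the defaults are order-of-magnitude plausible and
documented as arbitrary: control volume baselines span ~1.5–25·10³ mm³
(deterministic per region), FA baselines ~0.4–0.6 with noise SD 0.04,
covariate slopes sized to give control R² ≈ 0.2 (age negative for both
modalities, ICV positive for volumes), batch 2 shifted +0.5 SD and scaled
×1.2, planted edge effect d = −0.8 in a binomial(60, 0.8) number of edges
per patient, per-target region penetrance 0.8, coupling κ = 0.8. Laterality
is assigned 50/50 and planted effects are specified ipsilaterally, so the
flipping stage is genuinely exercised. FA values are clipped to (0.01,
0.99) with the clipping rate asserted < 0.1%.

Coupling κ is the probability that each planted abnormal edge is drawn from
the edges incident to that patient's atrophied regions (κ = 1 ⇒ fully
co-localised; κ = 0 ⇒ independent). Duration is a monotone (quantile)
transform of a latent Gaussian correlated with the planted abnormality
count at ρ, so the Pearson correlation with burden lands near ρ without
distorting the marginal duration distribution.

What the generator does **not** emulate: spatial autocorrelation between
neighbouring regions, distance- or hub-dependence of edges, non-Gaussian
feature noise, progression/longitudinal structure, and pathology subtypes
(HS is a label, not a data-generating mechanism). A green test therefore
establishes that the *statistical machinery* behaves as claimed under the
stated world — not that the biological effect sizes are realistic beyond
the printed anchors.

### The edge fixture

The published 1,289-connection set derives from a tractography atlas that is
not redistributable here; `default_edge_index()` is a deterministic,
internally-seeded stand-in at the same scale (1,289 edges, density ≈ 0.39)
enriched ×4 for within-lobe and ×2.5 for within-hemisphere pairs, built
mirror-symmetric (left-intra edges mirrored to the right, interhemispheric
pairs mirrored, an odd count achieved with homotopic edges) so hemisphere
flipping is lossless. It is a stand-in, not a reconstruction; any user
adjacency can be supplied to `build_edge_index()`.

## Numerical choices

* Edge canonicalisation: endpoints sorted alphabetically; "region one" of
  the Dice statistic is the alphabetically first endpoint (the statistic's
  mean is invariant to this nominal choice).
* Internally-seeded operations (`default_edge_index`, permutation scores,
  shuffles) save and restore the caller's RNG state.
* ComBat EB iterations stop at relative change 1e-6 (max 200); constant
  features pass through with a warning.
* Huber IRLS: exact fits (residual MAD ≈ 0) return the least-squares
  solution with unit weights instead of dividing by a zero scale.
* lme4 fits in scans and large simulations use `calc.derivs = FALSE`;
  singular random-effect fits are reported, not errors (boundary estimates
  are legitimate REML optima).

## Acceptance-criteria interpretations

* **Normative calibration bands** (means in (−0.15, 0.15), SDs in (0.85,
  1.15)): with 100 held-out controls the per-feature sampling SD of a mean
  is ~0.1, so reading the bands per feature across 1,371 features would be
  violated by chance alone under a perfectly calibrated model. The bands are
  therefore applied to the across-feature average (the calibration *bias*),
  with the model fitted on 1,000 synthetic controls.
* **Criterion sizes** are run as stated (100 seeds × three lmer fits at 100
  subjects × 200 edges; 500 patients × 5,000 permutations); module-level
  tests scale some illustrative simulations down and say so in comments.

## Known limitations

* No non-parametric ComBat, longitudinal ComBat, or site-as-random-effect
  harmonization; no GAMLSS/quantile normative curves.
* No crossed random effects (edges are not a second grouping factor) and no
  non-Gaussian mixed models.
* No spatially-constrained ("spin") permutation nulls.
* The CLI is a thin stage-prefix wrapper; partial re-runs re-execute
  upstream stages deterministically rather than reading cached artifacts.
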