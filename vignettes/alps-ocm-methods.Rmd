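---
title: "Methods: phantom-validated DTI-ALPS and the one-carbon-metabolism analysis plan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom-validated DTI-ALPS and the one-carbon-metabolism analysis plan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alpsocm)
```

This vignette is the package's own account of its models, the parameters
that matter, and the design decisions taken where the methodology left
genuine latitude. Nothing here states an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. The signal model and the phantom

Diffusion-weighted MRI signal in a voxel with symmetric diffusion tensor
$D$ (mm²/s) follows the mono-exponential tensor model
$$S(b, g) = S_0 \exp(-b\, g^\top D g),$$
with $b$ in s/mm² and $g$ a unit gradient direction. `make_phantom()`
synthesizes this signal on a voxel grid into which spherical regions of
known diagonal tensors have been painted, then (optionally) corrupts it
with Rician noise — the magnitude of a complex Gaussian perturbation,
$\tilde S = \sqrt{(S + \epsilon_1)^2 + \epsilon_2^2}$, the standard noise
model for magnitude MRI. `noise_sigma = 0` is reserved for oracle tests,
where fits must agree with ground truth to numerical precision.

Assumptions and deliberate simplifications:

* The phantom lives directly in template space on a 1 mm isotropic RAS
  grid (x left→right, y posterior→anterior, z inferior→superior), grid
  centered on the origin. Registration is therefore not modeled; the ALPS
  computation only ever needs template-space tensor maps.
* The default acquisition is 64 unit directions at b = 1000 s/mm² plus
  5 b = 0 volumes. The direction table is a spherical Fibonacci layout:
  deterministic, near-uniform, and full-rank for the second-order design —
  any valid 64-direction set is equivalent for tensor estimation.
* Default region tensors are `diag(1.2, 0.8, 1.6)e-3` (projection,
  z-dominant) and `diag(1.2, 1.6, 0.8)e-3` mm²/s (association,
  y-dominant) on an isotropic `0.8e-3` background. These are *fixture*
  values chosen so the ground-truth ALPS index is hand-computable
  (`mean(1.2, 1.2)/mean(0.8, 0.8) = 1.5`), not literature diffusivities.
* No anatomy, eddy-current/susceptibility artifacts, multi-shell schemes,
  or scanner k-space effects are simulated.

## 2. Tensor fitting

`fit_tensor()` is log-linear least squares: regressing $\ln S$ on
$[1, -b(g_x^2, 2g_xg_y, 2g_xg_z, g_y^2, 2g_yg_z, g_z^2)]$ yields the six
unique tensor components directly. The default is WLS with weights equal
to the squared signal predicted by an initial OLS pass — the usual
variance stabilization for log-transformed data; OLS is retained for
oracle tests. Numerical choices:

* **Signal floor.** Signals at or below zero (possible in noise-dominated
  voxels after motion resampling or noise) are clamped to
  `floor_frac * S0` (default `1e-6` of the per-voxel mean b = 0 signal)
  before the log, so background voxels degrade gracefully instead of
  raising errors.
* **Eigenvalue clamping.** Negative eigenvalues from noisy fits are
  clamped to zero for the MD/FA maps only; the raw tensor is retained.
  FA is additionally clipped into [0, 1]. This matches common
  tensor-tool behavior while preserving the fit itself.
* **Eigenvalues** are computed by the closed-form trigonometric method for
  symmetric 3×3 matrices, vectorized over voxels; non-finite tensors
  propagate NaN, which downstream ROI extraction treats as failed fits.
* A rank-deficient direction set (fewer than 6 independent quadratic
  forms) is an error, not a warning.

At SNR 30 (Rician, $\sigma = S_0/30$) the per-voxel diagonal components
carry ≈3% sampling SD with ≈0.4% bias under this protocol — an estimator-
variance floor, not a fixable bias (a background-σ Rician correction was
evaluated and does not help). The pipeline consumes tensors as ROI means,
which is why accuracy at SNR 30 is asserted on region-mean components
(median error well under 2%) and on the end-to-end ALPS index (within 1%),
not per voxel.

## 3. Motion QC

Framewise displacement is the Power-style sum of absolute frame-to-frame
changes of the six rigid-body parameters, rotations converted to arc
length on a 50 mm sphere (a typical head radius); the formula is a
declared choice, since "FD" alone does not pin one down. Three rule
families with defaults:

| rule | trigger | default |
|---|---|---|
| flag | FD or rotation delta too large | FD > 1.5 mm or Δrot > 2° |
| replace | absolute position off reference | trans > 2 mm or rot > 2° |
| exclude | subject unusable | >15% flagged or mean FD > 1.5 mm |

Thresholds are strict inequalities: a volume at exactly FD = 1.5 mm is not
flagged. "Replacement" is implemented as removal from the tensor fit
(`drop_volumes`): Gaussian-process outlier *interpolation* would add a
model dependency with no effect on ROI means at phantom scale. The flag
rule uses parameter deltas (like FD); the replace rule uses absolute
position relative to the reference volume, matching the semantics of
"volumes affected by" excessive motion. Note that a single mid-series
excursion produces deltas on both the outgoing and returning frame, so
isolated spikes flag two volumes; monotonicity of the rules is guaranteed
(and tested) under uniform scaling of a trace, which is the perturbation
that preserves the delta structure.

## 4. ROI placement and the ALPS index

`make_sphere_mask()` includes a voxel iff its center is within
`diameter/2` of the sphere center — no partial-volume weighting, so masks
are exactly reproducible by lattice enumeration (a 5 mm sphere on a 1 mm
grid centered on a voxel center is exactly 81 voxels). The two ROI
descriptions in circulation ("5 mm spherical ROIs" vs "5 mm diameter")
are resolved as *diameter* = 5 mm, configurable. Real-template MNI
centers are study-specific configuration; the shipped defaults are
placeholders consistent with the phantom geometry, and all tests use
phantom-consistent configurations so correctness never depends on
literature coordinates. Left/right assignment follows RAS: x < 0 is left;
left/right centers must mirror in x.

ROI diffusivities are arithmetic means of Dxx/Dyy/Dzz over in-mask voxels
*after* excluding failed fits (mean-after-exclusion; the count is
reported). The unilateral index is
`mean(Dx_proj, Dx_assoc)/mean(Dy_proj, Dz_assoc)`; the whole-brain value
is the mean of the two sides. A non-positive input diffusivity is an
error — it signals a degenerate fit and is never silently clipped. The
index is scale-invariant in $D$ by construction, equals 1 exactly under
isotropy, and mirroring the field in x swaps the unilateral indices; all
three are tested properties.

## 5. Cognitive scoring

Raw scores are converted to Z-scores with the *control group's* mean and
SD per test — always recomputed from the NC rows of the supplied table
(never hard-coded), so synthetic cohorts are self-referencing; tables
without control rows (e.g. an AD-only analysis set) must supply a
reference table explicitly. Timed tests (TMT-A/B, Stroop A/B/C) have
their Z-scores negated so higher always means better; the orientation is
an involution. Domain composites are means of constituent oriented
Z-scores under listwise deletion *within domain*: a subject missing any
constituent test loses that domain's composite and nothing else. MMSE and
MoCA are carried as single "global" measures, never composited; ADL and
CDR pass through unscored (they gate diagnosis, not composites).
Internal consistency is Cronbach's alpha on complete-case covariances; a
standardized variant (unit-variance items) is available behind a flag.

## 6. The synthetic cohort generator

`make_cohort()` draws, per group, a multivariate Gaussian on the
standardized scale (Gaussian copula) with a validated positive-definite
target correlation matrix, then maps to raw units. Defaults encode the
study conditions:

* **Group sizes** 68 / 75 / 67 (NC / AD-MCI / AD-D) and group-wise
  biomarker and ALPS distributions (e.g. folate medians 12.22 / 10.92 /
  8.66 ng/mL; ALPS 1.26 ± 0.13 / 1.21 ± 0.14 / 1.16 ± 0.15). Biomarker
  SDs are IQR/1.35 conversions, since only medians and quartiles are
  reported for them.
* **Correlation targets** (within group): folate↔ALPS 0.212,
  Hcy↔ALPS −0.299, plus biomarker- and ALPS-by-cognition entries (e.g.
  ALPS↔memory 0.339). Pairs the study does not report but that a joint
  positive-definite matrix needs were chosen once — folate↔Hcy −0.30
  (physiology), an inter-domain cognitive correlation of 0.40 (the
  positive manifold), folate↔memory 0.15, ALPS↔MMSE 0.20 — and not
  revisited.
* **Interaction.** The folate × ALPS moderation is planted *after* the
  main-effect draw, on the standardized scale:
  `memory += 0.17 · z(folate) · z(ALPS)` and `MoCA += 0.184 · z(folate) ·
  z(ALPS)`. This slightly inflates the outcome variance (≈1.5%), so the
  standardized coefficient recovered by regression is attenuated by the
  same factor — visible as ≈0.002 in the Monte-Carlo means, well inside
  the recovery tolerance.
* **Raw test scores** invert the scoring map: `raw = m + s·z` for
  points-based tests and `raw = m − s·z` for timed ones, with
  within-domain item deviations drawn once per domain and centered per
  subject, so the mean of item Z-scores equals the latent domain score
  exactly. Group-level cognitive deficits are injected as latent mean
  shifts in control-SD units taken from the study's group medians.
* **Binary columns** (sex, APOE ε4, vascular flags) are Bernoulli draws at
  the reported fractions; missingness is completely at random per test.
* Biomarker marginals are Gaussian by default (a declared
  simplification — the true family is unknowable from medians/IQRs); a
  flag switches folate/B12/Hcy to moment-matched log-normals.

What passing tests therefore do and do not show: they demonstrate that the
*pipeline* recovers known planted structure (correlations, interaction,
risk-group ordering, group means) without bias at the study's sample
sizes — not that real cohorts satisfy Gaussian copula assumptions, MCAR
missingness, or exact mirror symmetry of hemispheric ALPS.

## 7. The statistical plan

* **Normality gating** uses Shapiro–Wilk at α = 0.05: Pearson vs Spearman
  for correlations (for partial correlations the gate is applied to the
  residuals, and the decision is recorded), ANOVA vs Kruskal–Wallis for
  three-group comparisons, t vs Mann–Whitney for two groups and post-hocs.
* **FDR** is Benjamini–Hochberg — the standard reading of "the FDR
  procedure" — applied within declared families: the 3 biomarkers × 3 ALPS
  indices block is one family; the 6 predictors × 7 cognitive outcomes
  grid is another.
* **Partial correlation** is residualization on an intercept plus
  covariates (age, sex, education, APOE ε4 as 0/1), with
  $t = r\sqrt{(n-2-k)/(1-r^2)}$ on $n-2-k$ df; with zero covariates it
  reduces exactly to the simple correlation. The biomarker–ALPS block is
  unadjusted by default, with a switch for the adjusted variant, since
  reasonable readings of the plan differ.
* **Moderation regression** standardizes outcome and continuous
  predictors before fitting and forms the interaction from the
  standardized factors — a β of 0.17 is only plausible on the
  standardized scale; `standardized = FALSE` restores raw-unit fitting.
  The design-column order is fixed (intercept, folate, ALPS, interaction,
  age, sex, education, APOE).
* **Risk strata**: medians computed within the analysis set; ties go to
  the "high" side (≥), so a constant variable empties the high-risk
  stratum (warned, contrasts restricted). Post-hoc contrasts use
  Bonferroni × 3 (all pairwise contrasts of three groups).
* **Stratified analyses** (sex, age < 60 / ≥ 60, NC vs pooled AD) reuse
  the two-group comparison machinery behind a config-driven row filter.

## 8. Problem sizes and calibration choices

The shipped tests and the acceptance script use: a 32³ voxel phantom for
end-to-end ALPS checks, a 12³ single-region phantom for the 100-seed
SNR-30 fit accuracy study, 200 Monte-Carlo replicates at n = 142 for
effect-size recovery (Monte-Carlo SE of the mean correlation ≈ 0.006,
comfortably inside the ±0.03 recovery band), and 1000 replicates for the
type-I calibration of the omnibus and interaction tests. Recovery of
within-group targets is asserted on single-population analysis sets:
pooling two clinical subgroups with different means inflates the pooled
correlation above the within-group target (a Simpson effect of ≈ +0.035
at the default group separation), which is a property of pooling, not of
the generator.

## 9. Known limitations

* Single-shell, single-tensor model only; no free-water correction,
  tract profiling, or FA-skeleton ROI auto-placement.
* Replaced volumes are dropped, not interpolated; with very aggressive
  motion this shrinks the design rather than imputing it.
* The trilinear resampler in `apply_motion()` pads with a constant
  background; large excursions lose edge content, as in real scans.
* Cronbach's alpha on two-to-three-item domains is a coarse consistency
  summary; the generator's item model (shared latent + centered
  deviations) makes it optimistic relative to real batteries.
* The generator's Gaussian copula cannot represent tail dependence or
  floor/ceiling effects (e.g. MMSE ceilings in controls), so printed
  global-scale medians are emulated only on the latent scale.
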