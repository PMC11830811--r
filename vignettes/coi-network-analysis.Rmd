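---
title: "Hypothesis-driven connection-of-interest network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hypothesis-driven connection-of-interest network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coinet)
library(dplyr)
```

## The analysis problem

`coinet` implements a hypothesis-driven resting-state connectivity analysis
for two-period, two-treatment cross-over drug trials, together with the
synthetic data needed to validate every stage against known ground truth.
The scientific question it serves: does a drug change functional
connectivity *specifically* in the connections that a disease model says
matter, rather than diffusely across the brain?

The disease model here is the CLIPST circuitry of mood regulation
(corticolimbic-insular-striatal-pallidal-thalamic): 15 named regions and 39
connections of interest (COIs) out of the 105 unordered region pairs. The
pipeline has five stages:

1. **Stage-1 dual regression** — all region masks plus CSF and WM nuisance
   masks are regressed *jointly* onto each volume of a 4D scan, giving one
   time series per region. Joint regression (unlike per-mask averaging)
   separates overlapping masks and removes nuisance signal in the same
   least-squares solve.
2. **Partial-correlation connectivity** — per scan, the sample correlation
   matrix \(S\) of the \(T \times K\) region series is inverted
   (optionally with an L2 ridge) and normalized,
   \(r_{ij} = -P_{ij}/\sqrt{P_{ii}P_{jj}}\) with \(P = (S + \lambda I)^{-1}\),
   the correlation between regions \(i\) and \(j\) with all other regions
   partialled out. Values are Fisher-transformed, \(z = \operatorname{atanh}(r)\),
   optionally scaled by \(\sqrt{T - (K-2) - 3}\) to an approximately
   standard-normal statistic.
3. **Baseline-corrected cross-over contrasts** — each post-dose \(z\) has
   the same period's pre-dose scan subtracted; the three acute post-dose
   scans (50/80/165 min) are pooled by their mean; the 24-h scan is the
   delayed value. Per connection and phase, a paired t-test compares
   active vs control across subjects (\(t = \bar d / (s_d/\sqrt n)\),
   \(df = n - 1\), two-sided).
4. **COI enrichment** — significant connections at threshold \(\alpha\) are
   counted inside (\(k_{in}\) of 39) and outside (\(k_{out}\) of 66) the COI
   set, and the one-sided exact tail
   \(P[X \ge k_{in}]\), \(X \sim \mathrm{Hypergeom}(N{=}105, K{=}39, m{=}k_{in}{+}k_{out})\),
   is computed in log space from `lchoose()` terms. This is the pipeline's
   inferential safeguard: **no per-connection multiple-testing correction is
   applied**, deliberately — the count-based exact test, not the individual
   p-values, carries the confirmatory claim.
5. **Noncompartmental PK** — Cmax/Tmax, linear-trapezoidal AUC0-last,
   terminal log-linear slope \(\lambda_z\), half-life \(\ln 2/\lambda_z\),
   extrapolated AUC0-inf, and apparent clearance dose/AUC0-inf.

## What the synthetic-data generator emulates

Real scans for this design are not redistributable, so the generator is a
first-class module. It emulates the study conditions: 16 subjects, two
periods, balanced treatment order, one baseline plus four post-dose scans
per period, each scan a 220-frame series over the 15 CLIPST regions
(TR 2.34 s as metadata).

* **Generative model.** Each scan is drawn from a stationary zero-mean
  Gaussian graphical model: a precision matrix is built from requested
  partial correlations (identity diagonal, \(P_{ij} = -r_{ij}\)), repaired
  to positive definiteness by adding the smallest multiple of the identity
  that lifts the minimum eigenvalue to \(10^{-6}\), and sampled via its
  Cholesky factor. Temporal autocorrelation is off by default; a per-node
  AR(1) coefficient is available (`ar`). This is the simplest model whose
  estimand *is* the partial correlation the analysis measures.
* **Repair semantics.** The identity repair shrinks all requested partial
  correlations uniformly: for the full 39-edge CLIPST graph at \(r = 0.2\)
  the raw minimum eigenvalue is \(-0.399\), so every realized edge is
  \(0.2/1.399 \approx 0.143\). The realized values are recorded in the
  ground-truth object (`$edges$r_realized`); tests assert them against an
  eigendecomposition oracle rather than the nominal request.
* **Treatment effects** are injected on the Fisher-z scale
  (\(r' = \tanh(\operatorname{atanh}(r) + \delta_z)\)) because that is the
  analysis scale, then mapped back through the precision edit and re-repaired.
  Acute-phase effects touch only the 50/80/165-min scans of the active
  period; delayed effects only the 24-h scan.
* **Subject heterogeneity**: each subject's edge strengths are perturbed
  once by \(N(0, 0.05^2)\) on the r scale and shared across all of that
  subject's scans. This is what makes the paired, baseline-corrected
  design informative in simulation; without it any between-subject
  variance component would vanish.
* **Volumes.** Small 3D grids with one rectangular weight blob per region
  plus CSF/WM blobs; a row of background voxels is kept empty so the
  dual-regression intercept column stays identifiable. Optional overlap
  bleeds blobs into neighbours to exercise the joint solve.
* **PK profiles** come from the zero-order-infusion biexponential closed
  form with multiplicative lognormal error (mean-1 parameterization);
  pre-dose samples report 0.

What the generator does **not** emulate: hemodynamics, head motion,
physiological noise, scanner drift, registration error, or anatomical
realism of the masks. Passing tests therefore demonstrate correctness of
the estimators and the inferential chain under the stated model — not
robustness to fMRI artifacts, which are assumed handled upstream.

## Parameter defaults and why

| Parameter | Default | Rationale |
|---|---|---|
| `n_subjects` | 16 | study size |
| `t_per_scan` | 220 | acquisition protocol (8 min 55 s at TR 2.34 s) |
| `base_r` | 0.2 | weak-to-moderate baseline coupling on COI edges |
| `subject_sd` | 0.05 | between-subject edge variability on the r scale |
| `ridge` | 0 | exact inversion; enables 1e-10 oracle tests. 0.1 gives FSLNets-style shrinkage |
| `normalize` | TRUE | z magnitudes comparable across scan lengths; enrichment is invariant to this monotone rescaling |
| `alpha` | 0.05 | per-connection two-sided threshold feeding the counts |
| PK `A`, `B` | 463, 45.7 ng/ml | with `alpha` 0.065/min, `beta` 0.0022/min: C(40 min) = 208.6 ng/ml and *trapezoidal* AUC0-last = 557 ng·h/ml on the 9-point schedule |
| `infusion_duration` | 40 min | dosing protocol |
| `noise_cv` | 0 | assay error off unless requested |

The PK macro constants were solved against the *sparse-schedule trapezoidal*
AUC rather than the analytic integral, because trapezoidal AUC0-last is the
quantity NCA reports; the terminal rate 0.0022/min corresponds to a 5.25-h
half-life and 0.065/min to a 10.7-min distribution half-life, typical for
an IV ketamine profile.

## Numerical choices and degenerate inputs

* Partial correlation requires \(T > K + 2\) at ridge 0 and errors on
  zero-variance columns or a singular correlation matrix (suggesting a
  ridge). The correlation — not covariance — matrix is inverted, so the
  measure is invariant to per-region affine rescaling.
* The exact tail is accumulated by log-sum-exp over `lchoose()` terms:
  exact to double precision for any table, verified against exhaustive
  subset enumeration for all tables with \(N \le 12\).
* The paired t-test errors when all differences are identical (zero
  variance) rather than returning an infinite t. Subjects missing any scan
  of a phase are dropped listwise for that phase, with a message.
* Cmax ties break to the earliest time. Pre-dose PK samples are excluded
  from integrals; a zero anchor at \(t = 0\) is inserted when no sample
  sits there (dosing-time anchoring). \(\lambda_z\) selection maximizes
  adjusted \(R^2\) over post-Tmax suffixes with \(\ge 3\) positive
  concentrations, ties to the longer suffix, with an explicit override.
  Zeros before Tmax stay in the trapezoids but never enter the log-linear
  fit; a nonpositive terminal slope is an error.
* Voxel grids are compared by shape; dual-regression rank deficiency is
  reported with the names of the collinear maps.
* All randomness flows from one root seed through deterministic
  per-subject and per-scan substreams, so identical configs reproduce
  bit-identical studies and reports.

## Open design points resolved here

* **Acute pooling** is the mean of the three baseline-corrected values:
  the reported tests carry \(df = n - 1 = 15\), which implies one pooled
  value per subject rather than concatenated scans.
* **Two-sided per-connection tests**, \(\alpha = 0.05\): consistent with
  every reported significant connection and no directional hypothesis.
* **One-sided enrichment tail** in the enrichment direction; for the
  4/39-vs-0/66 and 3/39-vs-0/66 tables the standard two-sided Fisher
  convention returns the same number, so the choice is verifiable.
* **Both z conventions** (raw `atanh` and standard-normal scaled) are
  exposed because the upstream tooling's exact scaling is not recoverable;
  the enrichment result is invariant to the choice.
* **The COI grid is data, not code** — shipped as an editable JSON
  (`inst/extdata/clipst_coi_grid.json`) so ambiguous cells can be
  corrected without touching the package.
* **Stage-2 dual regression** (re-deriving subject spatial maps) is
  omitted: stage 1 already yields the per-region time series this analysis
  consumes.

## Validation strategy and problem sizes

The test suite validates each stage against an independent oracle:
residual-regression partial correlations (equality to 1e-10 at ridge 0),
pseudoinverse spatial recovery for dual regression, exhaustive subset
enumeration for the exact test, closed-form integrals for NCA, and
`stats::t.test` / `stats::fisher.test` as reference implementations for
the hand-built statistics. Monte-Carlo suites check calibration at the
study's own dimensions (16 subjects, T = 220, K = 15): type-I error of the
per-connection tests over 500 null replicate studies (accepted in
0.05 ± 0.02) and power above 0.8 for a \(\delta_z = 1.0\) acute effect
over 200 replicates. Published per-connection t statistics cannot be
reproduced without the raw subject data; the two printed enrichment
p-values (0.0172 acute, 0.0488 delayed) are reproduced exactly from their
printed counts.

## Known limitations

* The Gaussian graphical model has no hemodynamic or motion structure;
  calibration results transfer to real data only insofar as preprocessing
  upstream removes those artifacts.
* The identity PD repair shrinks strong requested graphs noticeably
  (documented above); requests near the PD boundary are realized
  conservatively.
* Listwise deletion for missing scans is the only missing-data policy.
* No sparse (graphical-lasso) or time-varying connectivity estimation; no
  compartmental or population PK modeling.
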