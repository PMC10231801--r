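---
title: "Modelling XDP natural history: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling XDP natural history: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(xdprogress)
```

## The scientific problem

X-linked dystonia-parkinsonism (XDP) is a neurodegenerative movement
disorder affecting men of Panay ancestry, caused by an SVA retrotransposon
insertion in *TAF1* whose hexamer repeat length is inversely related to age
at onset. Natural-history cohorts for XDP are small, follow-up is short
(here: four visits at 6-month intervals), patients enrol at very different
stages of disease, and age at onset is known only through recall. The
package implements an analysis pipeline built around that situation:

1. a catalogue of 107 clinical measures (MDS-UPDRS Parts 1-3, the BFM
   dystonia scales, EAT-10 and CPIB questionnaires, and quantitative
   oromotor measures) with their value kinds — ordinal, positive real, or
   count;
2. first-versus-last change testing per measure with FDR control;
3. Bayesian estimation of the full measure correlation matrix under
   missingness;
4. principal-variables selection of a minimal measure battery;
5. a hierarchical Bayesian symptom-trajectory model with a latent age at
   onset and rate of progression per gene-positive subject (entry-time
   realignment);
6. per-category rate refits that profile each subject's progression pattern.

Because the underlying patient data are not public, the package ships a
synthetic-cohort generator that emulates the cohort's structure and provides
ground-truth latents, so every stage is testable end to end.

## The trajectory model

For subject $i$, measure $j$, visit $t$, with $\mathrm{Age}_{it}$ in years,
the latent quantities are $\mathrm{Onset}_i$ (age at onset, years) and
$\mathrm{Rate}_i > 0$ (a relative progression rate). Progression enters
every likelihood through the realigned covariate
$\mathrm{Rate}_i\,[\mathrm{Age}_{it}-\mathrm{Onset}_i]_+$, where
$[x]_+ = \max(x, 0)$: before onset (and for gene-negative subjects, whose
onset never arrives) only the age term acts, which is what lets
gene-negative and pre-symptomatic subjects inform the normal-ageing
coefficients.

* Ordinal measures (cumulative logit, $K$ levels $c_1 < \dots < c_K$):
  $\mathrm{logit}\,P(Y_{ijt} \in \{c_1,\dots,c_k\}) =
  \alpha_{jk} + \beta_{j1}\mathrm{Age}_{it} +
  \beta_{j2}\mathrm{Rate}_i[\mathrm{Age}_{it}-\mathrm{Onset}_i]_+$,
  with $K-1$ free increasing thresholds (the $K$-th cumulative probability
  is 1 by construction, so only $K-1$ thresholds are parameterized, as a
  first cut-point plus positive increments).
* Positive real measures: $\log Y_{ijt} \sim
  \mathrm{Normal}(\alpha_j + \beta_{j1}\mathrm{Age}_{it} +
  \beta_{j2}\mathrm{Rate}_i[\cdot]_+,\ \sigma_j)$.
* Count measures: $Y_{ijt} \sim \mathrm{Poisson}\big(\lambda_{ijt}
  \log(1+e^{\alpha_j + \beta_{j1}\mathrm{Age}_{it} +
  \beta_{j2}\mathrm{Rate}_i[\cdot]_+})\big)$, with offset
  $\lambda_{ijt} = 1$ for lip strength and the paired DDK duration for the
  DDK syllable counts. The softplus link is evaluated in the numerically
  safe form $\max(x,0)+\log(1+e^{-|x|})$.

Missing observations are simply dropped from the likelihood; under the
model's conditional independences this is exactly marginalization, and it
assumes missingness at random (the missingness here is dominated by
logistical factors, so this is a mild assumption).

### Identifiability and priors

The product $\beta_{j2}\mathrm{Rate}_i$ is invariant to rescaling all rates
by $c$ and all $\beta_{j2}$ by $1/c$. The prior
$\mathrm{Rate}_i \sim \mathrm{LogNormal}(0, 0.5)$ anchors the geometric
mean of the rates near 1 and resolves the scale; $\beta_{j2}$ is
unconstrained. We verify post fit that the geometric mean of estimated
rates stays within a factor of 2 of 1.

The latent onset is informed by three sources, mirroring the information
actually available in such a cohort:

* reported onset: $\mathrm{Reported}_i \sim
  \mathrm{Normal}(\mathrm{Onset}_i + \mathrm{lag}, s)$ with a shared
  reporting lag $\mathrm{lag} \ge 0$ (truncated normal prior centred at
  7.5 years, reflecting that patients notice symptoms years after the
  measurable departure from normal trajectories);
* SVA repeat size: $\mathrm{Onset}_i \sim
  \mathrm{Normal}(a + b\,\mathrm{repeat}^{c}_i, \tau)$ with the repeat size
  centred at the cohort mean; missing repeat sizes are given a normal prior
  at the centre with the observed spread and sampled;
* all observed measures, through the likelihoods above.

All remaining priors are weakly informative normals / half-normals whose
scales live in one auditable list (`trajectory_priors()`). Ages are centred
at 40 years (about the cohort mean onset) inside the linear predictors for
sampler conditioning; reported intercepts and thresholds are de-centred, so
user-facing parameters refer to raw age. Posterior means are used as point
estimates throughout.

Sampling is Markov chain Monte Carlo via JAGS (rjags), with per-chain
seeds, default 2 chains x 500 kept draws after 500 adaptation and 500
burn-in iterations. Convergence is monitored by split-Rhat on every latent
(warning above 1.1) plus effective sample sizes; with the default short
chains the latents' point estimates are stable but Rhat can exceed 1.1 on
slowly mixing rate parameters — for publication-grade runs increase
`n_burn`/`n_draws`. A subject whose estimated onset lies beyond his last
visit has no post-onset data: his rate posterior correctly reverts to the
prior, and downstream summaries should treat it as uninformative.

The per-subject progression summary is
$\mathrm{Rate}_i[\mathrm{age}-\mathrm{Onset}_i]_+$: zero until the
estimated onset, then linear at the estimated rate.

## Change testing

For each of 99 test units (the 107 measures with the ten strongly
correlated CPIB items collapsed to their sum, plus participant weight),
first and last values per symptomatic gene-positive subject are formed with
last-observation-carried-forward / next-observation-carried-backward
imputation; subjects with fewer than two observed timepoints are excluded.
The Wilcoxon signed-rank statistic is reported as the sum of signed ranks
$W$ (so it can be negative, e.g. for weight loss); zeros are removed (the
reduced-sample procedure) and tied absolute differences get average ranks.
The p-value is exact (from the signed-rank null distribution,
$P(|W| \ge |w|)$) for tie-free samples up to $n = 25$, otherwise a normal
approximation with tie-corrected variance and no continuity correction —
the latter choice keeps results bit-for-bit reproducible and is verified
against exhaustive sign-flip enumeration in the tests. FDR is controlled
with the Benjamini-Hochberg step-up adjustment (monotone cumulative-min
form); untestable units (all differences zero) carry no p-value and do not
count toward the number of tests.

## Correlation under missingness

The correlation analysis uses one row per symptomatic subject-visit over
102 variables (the 99 units plus repeat size, reported onset and height;
subject-level constants are replicated across visits — they then contribute
no within-subject variation, and their correlations are interpreted on the
pooled scale). Measures that improve with severity (CPIB, the DDK
measures, lip and tongue strength, maximum phonation time, height, weight,
BMI) are negated first so all variables point in the same clinical
direction.

Each column is passed through a rank-based inverse-normal transform (Blom
offsets, average ranks for ties): the exact marginal transforms of the
original analysis are not published, and the rank transform is monotone,
robust for ordinal scales, and makes the multivariate-normal working model
reasonable. The model is then conjugate — normal prior on the mean,
inverse-Wishart on the covariance centred at the identity with the minimal
extra degree of freedom (mild shrinkage) — and is sampled by Gibbs:
missing entries are drawn coordinate-wise from their univariate full
conditionals (via the precision matrix, so one matrix inversion per sweep
suffices), then mean and covariance from their closed forms. Every draw's
correlation matrix is symmetric PSD with unit diagonal, hence so is the
posterior-mean matrix — the estimate is a valid correlation matrix by
construction, unlike pairwise-complete sample correlations. 95% credible
half-widths come from the draw quantiles; split-Rhat across chains is
reported. Variables are clustered on the distance $1-r$ with average
linkage (linkage unspecified in the original analysis; average is the
stable conventional choice, used consistently for subject clustering too).

## Principal variables

The explained variance of a subset $S$ of variables is
$\mathrm{PVE}(S) = 100 \cdot \mathrm{tr}\big(R_{\cdot S} R_{SS}^{-1}
R_{S\cdot}\big)/p$ — the average squared multiple correlation of all $p$
variables on $S$. Selection is greedy forward over blocks (bilateral
left/right items and DDK count/duration pairs move as one block); among
tied increments (tolerance $10^{-6}$) a block containing a measure with a
significant change wins — significance is a preference, not a filter,
since the published battery contains measures that did not reach
significance individually. "PVE alone" is the block by itself; "PVE
jointly" is the leave-one-out increment within the final selection, an
order-free attribution whose sum is close to, but not exactly, the total
(this is documented rather than renormalized). The published 15-group /
21-measure battery is encoded as a reference for comparison
(`reference_battery()`); reproducing it exactly from synthetic data is not
expected, since it depends on the real cohort's correlation matrix.

## Rate heterogeneity

Per-category rates $\mathrm{Rate}_{ig}$ come from refitting the trajectory
model independently to each of 13 pre-defined measure categories with every
subject's onset frozen at the global fit's estimate — the common time
realignment across categories. The default category scheme (rigidity, rest
tremor, other tremor, bradykinesia, limb dystonia, axial dystonia, speech,
swallowing, gait, non-motor, daily-living motor, quantitative oromotor,
BMI) is assembled from the catalogue's clinical groupings; the original
category definitions are not published, so the scheme is a package default
and fully overridable. BMI joins here (modelled log-normally) although it
is excluded from the global model, which preserves the weight-based
validation of the progression summary. Rates are not re-standardized per
category; the shared onsets provide the common scale. Subject profiles are
compared by Euclidean distance and clustered with average linkage, and
subjects are also ordered by their average rate across categories (ties
broken by subject id).

## The synthetic cohort generator

`simulate_cohort()` draws cohorts from the generative version of the
trajectory model, with defaults emulating the study conditions:

* 29 symptomatic gene-positive, 7 pre-symptomatic gene-positive and 51
  gene-negative men; 4 visits at 0.5-year spacing (with a small positive
  jitter so visit ages are strictly increasing);
* SVA repeat sizes uniform on 36-52; true onset
  $\sim \mathrm{Normal}(98 - 1.5\,\mathrm{repeat}, 5)$, giving reported
  onsets centred near age 39 and an onset-repeat correlation near $-0.7$;
* reported onset = true onset + truncated-normal lag (mean 7.5 y, sd 3 y,
  bounded at 0), matching the observed 5-10-year reporting lag;
* symptomatic subjects enrol about 4 years (gamma-distributed) after their
  reported onset; pre-symptomatic men enrol young (before onset by
  construction); gene-negative ages centre near 36;
* $\mathrm{Rate}_i \sim \mathrm{LogNormal}(0, 0.5)$; per-category rates
  default to the global rate (`category_rate_sd = 0`), so the global
  model's single-rate assumption holds exactly unless heterogeneity is
  planted deliberately;
* per-measure coefficients drawn once per cohort, with progression-effect
  magnitudes log-normal across measures (some measures progress strongly,
  many barely — the heterogeneity visible in which measures reach
  significance on real data); signs follow each measure's severity
  direction;
* 9% missing completely at random, with a DDK count masked whenever its
  offset duration is masked, and BMI masked with weight.

What the generator does *not* emulate: informative missingness, female
carriers, rater effects, within-subject test-retest correlation beyond the
latent trend, or floor/ceiling management by clinicians. The last point
matters for interpretation: because visits are conditionally independent
given the latent trajectory, visit-to-visit noise is larger than on real
rating scales, so fewer measures reach first-versus-last significance on a
default synthetic cohort than the nine reported on real data. Passing
tests therefore demonstrate the machinery's correctness and calibration
under the model's own assumptions, not real-data effect sizes.

## Numerical choices and degenerate inputs

* Softplus and all likelihoods are overflow-safe; Poisson means get a
  $10^{-10}$ floor inside the sampler.
* Exact signed-rank p-values switch to the tie-corrected normal
  approximation when ties are present or $n > 25$; no continuity
  correction.
* Zero-variance variables are dropped (with a warning) before correlation
  estimation; `pve()` falls back to a pseudo-inverse on singular subsets.
* Ordinal measures need $K \ge 3$ levels in the trajectory fit (the
  threshold-increment parameterization); the default catalogue satisfies
  this everywhere.
* Problem sizes in the test-suite and acceptance runs are deliberately
  reduced (20 measures, 40 subjects, 2 chains x 500 draws for the
  trajectory recovery; 4 categories for the heterogeneity checks; 100-200
  replicates for the FDR simulation); these sizes give stable Monte-Carlo
  margins for the properties being checked while keeping runs short.

## Known limitations

* The original supplementary details (exact priors, the exact
  multivariate-normal missing-data model, the 13 category definitions, the
  marginal transforms) are unavailable; the corresponding choices here are
  declared package defaults, not reconstructions.
* Short default chains favour speed; mixing on per-subject rates is slow,
  and split-Rhat warnings should be taken seriously for substantive use.
* The pipeline treats visits as conditionally independent given the
  latent trajectory; serial correlation in residuals is not modelled.
* First-versus-last testing discards interior visits by design (matching
  the original analysis); a longitudinal mixed model would use them but is
  out of scope.
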