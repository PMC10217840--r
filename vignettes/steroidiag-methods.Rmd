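---
title: "Methods: steroidome diagnostics of AD and T2DM"
author: "steroidiag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: steroidome diagnostics of AD and T2DM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`steroidiag` analyzes serum steroidome and clinical-chemistry panels across
the four diagnostic cells formed by Alzheimer's disease (A±) and type 2
diabetes (D±), separately per sex. This vignette documents the models, the
choices behind every tunable parameter, what the synthetic-cohort generator
does and does not emulate, and the numerical decisions a maintainer would
want written down.

## 1. Power transformation

Concentration-like variables are right-skewed, so every metric variable is
mapped to a near-Gaussian scale before modelling with the one-parameter
Box–Cox family

$$y = \frac{(x + c)^\lambda - 1}{\lambda} \quad (\lambda \neq 0), \qquad
  y = \log(x + c) \quad (\lambda = 0),$$

with $\lambda$ maximizing the profile log-likelihood
$-\tfrac{n}{2}\log\hat\sigma^2(\lambda) + (\lambda - 1)\sum\log(x_i + c)$.
The shift $c$ is 0 for strictly positive samples and $10^{-6} - \min x$
otherwise. The search is a 0.01-step grid over $[-3, 3]$ followed by
golden-section refinement to $10^{-4}$ — deterministic, and bracketing
guarantees no grid point beats the returned optimum. Group summaries
computed on the transformed scale are mapped back through the exact inverse
("retransformed means"); for a log fit the retransformed mean is the
geometric mean and retransformed intervals are right-skewed.

Choices made where several readings were defensible:

* **Family and criterion.** One-parameter Box–Cox with maximum likelihood.
  A two-parameter (joint shift) or Yeo–Johnson search would handle signed
  data more elegantly but none of the panel variables need it.
* **Pooling.** $\lambda$ is fitted once per variable on each sex's pooled
  data (all four groups together), since the transformation is a
  measurement-scale decision, not a group-level one. Fitting per group
  would break the comparability of group means on the transformed scale.
* **$\lambda = 1$ is treated as an exact affine identity** (defined for all
  reals), so toy data and derived ratios with non-positive values can be
  analyzed untransformed without artificial domain errors.

## 2. Age-adjusted ANCOVA screen

Per variable, on the transformed scale:

$$y \sim AD + T2DM + AD{\times}T2DM + \mathrm{age},$$

with sum-to-zero factor coding and type III (marginal) F-tests, the
convention that matches standard factorial ANCOVA output for unbalanced
designs (cells of 7 vs 47 subjects here). Group summaries are least-squares
(adjusted) means evaluated at the sample mean age with t-based 95% CIs,
back-transformed to original units. Age itself is screened with the same
model minus the covariate (a plain two-way ANOVA). All 6 pairwise contrasts
of adjusted means are tested with a Bonferroni correction at family-wise
0.05, per variable — no across-variable multiplicity control is applied, by
design, mirroring how such screens are reported.

Numerical note: before fitting, the transformed response is standardized
(affine rescaling changes no F, p, or contrast); this keeps the residual
sum of squares well away from rounding level when an extreme $\lambda$
compresses the response range. A covariate with zero variance is dropped
(the model degenerates to the two-way ANOVA it nests). The fit errors if
any diagnostic cell has no usable subject, and the screen collects such
failures per variable without aborting.

Missing data are handled complete-case per model: a subject is dropped from
a given ANCOVA or OPLS fit only if it misses a variable that fit uses; the
effective n is recorded in every result.

## 3. OPLS discriminant models

For a pair of groups (case coded 1, control 0, then centered) with
standardized predictors $X$:

$$X = T_p P_p^\top + T_0 P_0^\top + E, \qquad y = T_p b + f,$$

a single predictive component (binary outcome) plus $K$ orthogonal
components capturing predictor covariation unrelated to the class — the
appropriate structure for steroid panels where metabolic-pathway neighbours
are strongly correlated. The implementation is the standard NIPALS-type
sequence: predictive weight $w \propto X^\top y$; per orthogonal component,
the loading part orthogonal to $w$ is split off and deflated; with $K = 0$
the model reduces exactly to single-component PLS ($t_p = Xw$,
$w = X^\top y / \lVert X^\top y\rVert$), which the tests pin against a
brute-force oracle. The decomposition identities (exact reconstruction,
$T_0 \perp T_p$, $R^2Y = \mathrm{corr}(y, t_p)^2$) hold to machine
precision and are asserted on every fit in the test suite.

Defaults, all exposed in `opls_config()`:

* **Cross-validation: 7-fold, stratified, seeded round-robin.** Q² =
  1 − PRESS/SS on the coded outcome. Seven folds is the conventional
  default in this model family and keeps at least one member of the n = 7
  comorbidity group in most training splits; fold count is reduced with a
  warning whenever a training split would lose a class.
* **Orthogonal components: add while ΔQ² > 0.01** (starting at K = 0,
  capped at min(n − 2, p − 1, 5)). The 1% improvement rule is the common
  stopping heuristic for component inclusion; `q2_tol = Inf` degenerates to
  K = 0 by construction.
* **VIP pruning at threshold 1.** VIP_j = √(p·w_j²/‖w‖²) for the single
  predictive component, so mean(VIP²) = 1 and the threshold 1 reads
  "above-average importance". Pruning iterates (drop all below threshold,
  refit) and stops early if a pruning step would cost more than `q2_tol`
  of cross-validated Q² — protection against discarding many weakly but
  jointly informative predictors at once.
* **Hotelling T² screening, α = 0.05, applied once.** Scores of the initial
  fit are tested against the F-based ellipse
  $d(n-1)/(n-d)\,F_{1-\alpha}(d, n-d)$; flagged subjects are excluded and
  the model refitted. One pass, not iterated — repeated trimming walks into
  the bulk of the data.
* **LLR calibration.** The predictive score is mapped to the log likelihood
  ratio of pathology presence by univariate logistic regression of class on
  $t_p$; probabilities are the logistic transform of LLR. |LLR| is capped
  at 15 so perfectly separated training sets yield finite output
  (probability within ~3·10⁻⁷ of 0/1). Classification threshold is
  probability 0.5, ties classified negative.
* **Loading statistics.** Per-predictor component loadings are expressed as
  correlations with the predictive score (the scale-free form, directly
  comparable across refits); their t-statistics are jackknife estimates
  over the CV folds (loading / jackknife SE). Published tables of this
  model family print t values whose exact recipe is not recoverable, so
  numeric agreement of t values is not claimed — signs and significance
  patterns are.

## 4. Evaluation

Sensitivity and specificity are in-sample by default (held-out CV
predictions are also stored), with Wald 95% intervals
$\hat p \pm 1.96\sqrt{\hat p(1-\hat p)/n}$ **not clipped** to [0, 1]. The
unclipped convention is deliberate: published footers of this model family
show bounds like 1.026 and −0.132, and clipping would silently change
printed widths. Explained variability is reported as 100·R²Y with the
identity R²Y = corr(y, t_p)², which also lets the percentage be recovered
from a printed dependent-variable loading (e.g. 0.782² → 61.2%).

## 5. The synthetic-cohort generator

Patient-level steroidome data are not publicly available, so the package
ships calibrations transcribed from published group summaries: per sex, the
four group sizes (women 41/41/47/7, men 18/33/25/7), each variable's
retransformed mean and 95% CI per group, and per-model component loadings.

Generation, per subject $i$ in group $k$: a latent class-axis position
$u_i \sim N(0,1)$, and per variable $j$ on the calibration scale

$$z_{ij} = \mu_{jk} + \sigma_{jk}\left(a_j u_i + \sqrt{1 - a_j^2}\,
  \varepsilon_{ij}\right), \qquad a_j = s \cdot R_j,$$

with $\varepsilon_{ij}$ unit Gaussian noise, $R_j$ the calibrated loading of
the configured model pair (0 for variables outside it), and strength
$s = 1$ by default. Values are mapped back to original units. The
calibration scale is natural log for strictly positive analytes and
identity for anthropometric measures — the originally fitted $\lambda$
values are unknowable, and these are the canonical scales for the two
variable classes. Within-group SDs come from the printed CIs:
$\sigma = h\sqrt{n}/t_{0.975,\,n-1}$ with $h$ the transformed-scale CI
half-width, using each group's own n (6 df for the n = 7 cells). Age is
drawn per group from its calibrated mean and CI-derived SD, independent of
the class axis — it enters the models as a covariate/predictor through its
group-mean differences only.

What this emulates: the published marginal group structure (large-sample
retransformed means converge to the printed values), the sign/magnitude
pattern of class-axis correlations, and exact group sizes
(calibration n × multiplier). What it does not: assay error structure,
drug-treatment effects, the full between-variable covariance beyond one
axis, heavy tails (a Student-t noise option exists for robustness checks
only), and any within-subject link between age and the biochemistry beyond
group means. The printed CIs are CIs of age-adjusted means, so deriving
within-group SDs from them ignores the adjustment; the approximation is
accepted and its consequences are measured, not assumed, by the tests.
Consequently, green tests demonstrate that the pipeline recovers structure
this generator encodes — not that it would behave identically on the
original cohort.

One measured consequence worth recording: under these calibrated SDs the
Bonferroni contrast of cortisol between AD-only and T2DM-only women sits
near the detection boundary (~82% flag rate over 200 replicates, vs ~88%
for the contrast against controls), so pairwise-verdict recovery is
asserted per contrast at the 80% level rather than jointly.

## 6. Problem sizes and determinism

The test suite uses cohorts at the calibrated sizes (136 women, 83 men),
toy designs of 20–100 subjects per cell for closed-form oracles, 50-dataset
sweeps for the Q² ≤ R²Y inequality, 100 replicates for loading-sign
recovery, 200 replicates for the age-ANOVA and cortisol-verdict
Monte-Carlos, and 2000 replicates for CI coverage — sizes chosen so each
stochastic assertion has comfortable margin while the whole suite stays
fast. Every stochastic step (generator, fold assignment) takes an explicit
seed and restores the caller's RNG state, so identical seeds give
byte-identical cohorts, fold splits, Q² values and reports.

## 7. Known limitations

* Single predictive component only (binary outcomes); no multi-class
  variant, no O2-PLS, no kernel extensions.
* The ANCOVA screen controls multiplicity within, not across, variables —
  matching its descriptive role.
* Jackknife-over-folds t-statistics are a pragmatic stand-in for an
  unspecified published recipe; treat them as ordering/significance guides.
* The generator's one-axis covariance is a deliberate simplification; OPLS
  orthogonal components fitted on synthetic cohorts reflect that axis, not
  the richer latent structure of real steroid panels.
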