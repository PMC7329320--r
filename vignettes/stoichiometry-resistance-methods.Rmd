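---
title: "Methods: stoichiometric control of microbial functional-gene abundance and its resistance to global change"
author: "StoichResist maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stoichiometric control of functional-gene resistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(StoichResist)
```

## The scientific setting

Functional-gene copy numbers are the working proxy for the size of the soil
microbial populations that carry out C, N and P cycling: glycoside-hydrolase
genes (*fungcbhIR*, *GH74*, *GH31*, *GH51*) for organic-matter decomposition,
*amoA*/*nifH*/*narG*/*nirK*/*nirS*/*nosZ*/*norB* for the N cycle, and
*phoD*/*phoC*/*BPP*/*pqqC* for P mineralization and dissolution, with
bacterial 16S and fungal ITS as biomass markers. Across a multi-site design,
two questions arise: (i) what drives the spatial pattern of these
populations — climate (MAT, MAP) or soil C:N:P stoichiometry — and (ii) how
resistant is each population to an imposed disturbance (drying-wetting
cycles, +4.5 °C warming, N deposition at 25 kg N ha⁻¹ yr⁻¹), and what
predicts that resistance? This package implements the full inference chain
for both questions and a generative simulator of the study design.

## The resistance index

For control value $C_0 > 0$ and treated-minus-control difference $D_0$,

$$RS = 1 - \frac{2\,|D_0|}{C_0 + |D_0|}.$$

$RS$ is monotone decreasing in $|D_0|$, equals 1 iff $D_0 = 0$, equals 0 when
$|D_0| = C_0$ (a 100 % change) and tends to, without attaining, $-1$ as
$|D_0| \to \infty$. Three numerical conventions matter:

* $C_0 \le 0$ is an **error**, not $RS = -1$: the index is standardized by
  the control value and is undefined without one. Affected records are
  reported and excluded, never silently dropped.
* $RS$ is computed on raw copy numbers, not log-transformed abundances — the
  index formula is applied exactly as written.
* The index depends only on the relative change, so multiplicative
  disturbances give $RS$ values that are independent of a gene's absolute
  abundance scale.

## Group aggregation

Two aggregations of per-gene values to a C/N/P-cycling group are provided.
For abundances, the share-based normalization

$$x' = \frac{1}{n}\sum_{g=1}^{n} \frac{x_{ig}}{\sum_i x_{ig}}$$

yields scores that sum to 1 across samples and are invariant to rescaling any
single gene — appropriate when genes differ by orders of magnitude in copy
number. For resistance the default is the per-site arithmetic mean of
member-gene $RS$: the share-based form presumes nonnegative inputs while $RS$
can be negative. An alternative (`mode = "eq2"`) shifts $RS$ by $+1$ and then
applies the share normalization; both are exposed because the choice of
group-level aggregation is genuinely open, and the mean is the default
because it preserves the $RS$ scale and admits an exact brute-force oracle.

## Variance partitioning

Per group, the samples × genes matrix (log₁₀-transformed by default — qPCR
copy numbers span orders of magnitude, and the transform is switchable) is
Hellinger-transformed (square root of row proportions) and partitioned
between the climate set $M = \{MAT, MAP\}$ and the stoichiometry set
$S = \{TC, TN, TP, C/N, C/P, N/P\}$. With Ezekiel-adjusted multivariate
$R^2_{adj}$ values $a_M$, $a_S$, $a_{M\cup S}$, the unique fractions are
$a_{M\cup S} - a_S$ and $a_{M\cup S} - a_M$, the shared fraction is
$a_M + a_S - a_{M\cup S}$, and the residual completes the sum to exactly 1.
Adjusted fractions can be slightly negative; they are reported as computed
and flagged rather than truncated, so the identity always holds. Within-set
collinearity is a hard, named error (the raw totals and ratios are not
linearly dependent, but degenerate inputs should fail loudly); between-set
overlap in the union fit is handled by projecting onto the joint column space
and adjusting by its effective rank.

Significance of each unique fraction uses Freedman–Lane residual permutation:
rows of the reduced-model residuals are permuted, added back to the
reduced-model fit, and the semipartial $R^2$ recomputed, with
$p = (1 + \#\{stat^* \ge stat\})/(1 + n_{perm})$; 999 permutations by
default. This scheme keeps the nominal type-I error under the null (the test
suite verifies a rejection rate within [0.03, 0.07] at $\alpha = 0.05$ over
500 null simulations with 99 permutations).

## Random-forest predictor importance

Group resistance per site is regressed on the eight drivers with regression
forests (500 trees, `mtry = max(1, floor(p/3))`, bootstrap with
replacement). Importance is the out-of-bag permutation importance averaged
over trees, reported as a percentage of the forest's out-of-bag MSE (raw,
possibly negative values and a percent-of-total normalization over positive
importances are emitted alongside, since the axis convention for published
MPI values varies). A predictor that never reaches an out-of-bag evaluation
in a very small forest contributes zero. Significance refits the entire
forest to row-permutations of the response (99 by default); a faster variant
fits each null forest with a fifth of the trees and is labelled as an
approximation in the output.

## Path analysis

The models are recursive observed-variable path models, estimated by
per-equation OLS on standardized variables — exactly the ML solution for a
recursive system with uncorrelated errors, and fully checkable against an
independent regression oracle, which is why a general latent-variable SEM
engine is not used. The model-implied correlation matrix is assembled from
the path coefficients with exogenous covariances fixed at their observed
values and endogenous residual variances chosen consistently with the
correlation metric; fit is judged by
$\chi^2 = (n-1)\,F_{ML}$, $df$ = distinct moments − free parameters,
$RMSEA = \sqrt{\max(\chi^2 - df, 0)/(df\,(n-1))}$ (defined as 0 with a
saturated flag at $df = 0$, where the formula is 0/0), Fisher's P
(good fit when $0.05 < P \le 1$), and $AIC = \chi^2 + 2\,q$. Residual
correlations among stoichiometry variables are not modelled (the default
a-priori graph does not include them), which is why an a-priori model over
strongly inter-correlated drivers can carry a large $\chi^2$ even when every
path is real — the pruning analysis, not absolute fit, is the inferential
target.

Backward pruning removes, one at a time, the least-significant edge with
$p \ge \alpha$ (ties broken by smaller $|\beta|$, then lexicographic edge
name) and refits until all retained edges are significant; the a-priori and
optimal fits are both returned. Pruning to an edgeless model is a warning,
not an error.

## The simulator: what it emulates

`generateExperiment()` reproduces the study conditions: 54 sites × 4
treatments = 216 samples by default, with

* climate drawn uniformly over MAT ∈ [0, 20] °C and MAP ∈ [100, 1600] mm —
  a realistic continental gradient for the cropping systems being emulated;
* log-scale soil total C and N depending on gradient-standardized MAP
  (slopes 0.35 and 0.40) and weakly negatively on MAT (−0.15, −0.10) with
  log-normal noise (SD 0.25), total P near-independent (SD 0.30) — so that
  climate genuinely drives stoichiometry and a path model has something to
  recover; ratios are computed from the totals, making the ratio identities
  exact by construction;
* log₁₀ gene abundance = intercept + Σ (slope × standardized predictor) +
  Gaussian noise (SD 0.25 log₁₀ units). Effect slopes default to magnitude
  0.3 and encode the observed sign structure: TN, C/P, N/P positive for all
  functional genes; TC positive for *amoA-b*, *nifH*, *narG*, *nirS*,
  *nosZ*; TP negative for *phoD*, *pqqC*; C/N negative for *phoD*, *phoC*,
  *pqqC*, *nirK*, *fungcbhIR*, *GH74*; climate linked only to *nirK*,
  *phoC*, *pqqC*, *fungcbhIR*; biomass markers positive with most genes and
  the bacteria:fungi ratio linked to the C-cycling genes. Only the signs are
  constrained by observation; the magnitudes are free parameters chosen once.
* disturbance as multiplicative suppression: treated = control × e^(−m),
  with m = per-gene baseline + stressor-specific standardized driver slopes
  (+ group-specific extras) + noise (SD 0.1), floored at 0. Baselines
  (0.3–0.9 on the log scale) encode the observed resistance orderings (e.g.
  C-cycling genes least resistant to N deposition, *phoD*/*phoC* least
  resistant to drying-wetting); driver slopes (−0.25 for the stressor's
  primary driver: MAP for drying-wetting, MAT for warming, C/P with TC and
  TN for N deposition; TC/TN/C:N additionally for the P-cycling group)
  make resistance linearly predictable from stoichiometry and climate, as
  the downstream forest and path analyses expect.

Because RS depends only on the relative change, the generated resistance
depends only on m — abundance noise cancels — which keeps the
signal-to-noise of the resistance analyses interpretable.

All randomness flows from a single user seed through named substreams, so
identical (config, seed) pairs give bit-identical experiments and stage-level
reruns match pipeline-level runs.

**What it does not emulate.** There is no incubation physics: no moisture
curves, temperature kinetics, dose-response to the N addition, spatial
autocorrelation between sites, compositional constraints among genes, or
qPCR measurement error structure beyond log-normal noise. Treatment metadata
(+4.5 °C, 25 kg N ha⁻¹ yr⁻¹, 50 % WHC, 4 × (2-day wet + 5-day dry), 1-month
incubation) are carried as annotations only. Consequently, passing tests
demonstrate that the inference chain recovers structure that is present by
construction — they do not validate the biological model against field data.
Marginal correlations of genes with predictors they have no configured slope
on can still be nonzero (the predictors are correlated among themselves);
sign recovery is therefore guaranteed for partial regression coefficients,
and for marginal correlations only for the strongest configured
gene-predictor pairs.

## qPCR conventions

Standard curves are OLS fits of Cq on log₁₀ copies; efficiency is
$E = 10^{-1/slope} - 1$, monotone in the slope. The exact published form of
"efficiency correction of abundances" is not standardized, so the package
adopts a documented ratio-to-ideal convention,
corrected = observed × (2/(1+E))^Cq_ref with Cq_ref the gene's mean observed
Cq equivalent: it is the identity at E = 1, preserves rank order within a
gene, and is switchable off (`method = "none"`). Cq values outside the
calibration range are extrapolated with a warning rather than rejected.

## Statistical-test choices

Resistance comparisons across the three stressors use Kruskal–Wallis with a
Dunn rank-based post-hoc (implemented in-package, with ties correction) and
Benjamini–Hochberg correction across genes: RS is bounded and typically
skewed, so rank tests are the safer default; a Welch ANOVA / pairwise t-test
alternative sits behind `method = "anova"`.

## Problem sizes used by the test suite

The suite verifies the analytic identities exactly and the statistical
properties at deliberately chosen sizes: 10⁶-point grids for the index
bounds; 1,000 random matrices for the normalization identity; 200 random
instances (n = 60, 4–16 responses) for the variance-partitioning oracle;
500 null simulations at 99 permutations for each permutation-calibration
check; 100/50/20 seeded replicates of the full 54-site design for the
qualitative variance-partitioning, importance-ranking and path-pruning
reproductions; and n = 5,000 for path-coefficient recovery (±0.03). The
pruning reproduction expects both direct climate → resistance paths (true
nulls) to be dropped in a run, an event with probability ≈ 0.9 under the
per-edge 5 % retention rate, and therefore requires success in at least 15
of 20 runs.

## Known limitations

* The efficiency-correction rule and the group-resistance aggregation are
  documented conventions, not community standards; both are switchable.
* The path models are observed-variable only: no latent variables, bootstrap
  standard errors, modification indices or residual covariances.
* Importance p-values at 99 permutations have a resolution of 0.01; use more
  permutations for publication-grade claims.
* The simulator's effect magnitudes are plausible but invented; analyses of
  real data should treat the defaults purely as a power-analysis scaffold.
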