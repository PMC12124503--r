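---
title: "Undesired-child classification and under-five morbidity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Undesired-child classification and under-five morbidity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(undesired)
```

## The problem

In high-fertility survey populations, a child can be "undesired" in a
precise, preference-based sense: the mother has stated an ideal family
composition — `B_m` boys, `G_m` girls and `N_m` children of either
gender, so an ideal family size `C_m = B_m + G_m + N_m` — and her actual
birth history can exceed it.  This package implements that
classification and the downstream analysis of five under-five morbidity
outcomes (diarrhea, fever, cough, short/rapid breathing, acute
respiratory infection, all on a two-week recall) for DHS-style
microdata: prevalence tabulation, a binary-association stage
(tetrachoric correlation, KMO, Bartlett, PCA), a multivariate probit
model over the correlated outcomes, and random-forest / neural-network
classification with variable importance.

Because the survey the methodology targets is access-restricted, the
package ships a synthetic-population generator with known ground truth.
Every stage is validated against either a closed form, an independent
oracle implementation, or the generator's analytic truth.

## The undesiredness classification

Two classifiers are provided, because the source methodology states two
inequivalent rules and never reconciles them.

**Static, mother level.**  With living counts at survey time
(`C_i` living children, `B_i` boys, `G_i` girls, `C_i = B_i + G_i`):

* excess parity: `C_i − C_m > 0`;
* excess boys: `B_i − (B_m + N_m) > 0`; girls symmetrically;
* dual excess: by default a sex flag together with the parity flag
  (`sex_and_parity`); alternatively both sex flags (`both_sexes`).

**Sequential, child level.**  Each child is judged *at the moment of
its birth* and the flag is never revised:

* *gender excess*: the count of living same-sex children including the
  newborn exceeds the sex quota plus the either-gender slots not already
  consumed by the other sex.  Either-gender slots are consumed greedily
  in birth order once a sex quota fills — this is the unique reading
  that reproduces the canonical six-child illustration (ideal 2 boys +
  1 girl + 1 either; four boys, a death, a girl, a sixth child), in
  which three boys fill the two boy slots plus the either slot before
  any girl is born, the fourth boy is gender-excess only, and the sixth
  child is excess in both gender and parity;
* *parity excess*: living children including the newborn exceed `C_m`;
* a death frees the deceased child's slot for *subsequent* births but
  never retroactively clears a flag;
* children of unknown sex count for parity and are excluded from the
  gender computation.

The two dual-excess readings conflict in the source ("an excess of both
genders" vs. a child "excessive in both gender composition and total
number"); `sex_and_parity` is the default because only it is exercised
by the worked illustration, and both are selectable via `dual_rule`.

The sequential rule is implemented twice: an event-loop version
(`classify_children_sequential`) for arbitrary birth/death sequences,
and a vectorised population version (`classify_population`) for whole
tables.  The test suite proves them identical, and proves both
equivalent to an independent slot-consumption simulator (a different
algorithm that re-assigns all living children to slots at every birth)
exhaustively over all preference triples with `C_m ≤ 4` and all birth
sequences of length ≤ 5, plus 1,000 random death-bearing sequences.

## The synthetic population ("stated world")

`sim_config()` fixes the generator's world.  Defaults are chosen once:

* **sex ratio** 0.512 male — the conventional male live-birth fraction;
* **under-five death probability** 0.074 per child, i.i.d. — the
  Pakistani under-five mortality level of the survey era (~74 per
  1,000 live births); deaths are realised immediately after the child's
  own birth row, the event order the sequential classifier assumes;
* **ideal-family distribution**: ten son-skewed triples with modal
  ideal family size 4, truncated at the eligibility cap of 9 (the
  survey excludes mothers wanting more than nine children);
* **births per mother**: support 0–8 (generator cap 12), mean ≈ 3.8;
* **covariate marginals** (education, wealth, residence, province,
  maternal age group, media exposure, employment, health-worker visit,
  child age): PDHS-like proportions, generated independently of
  preferences and outcomes so the ground truth stays analytically
  tractable;
* **morbidity outcomes**: drawn from the latent-Gaussian model below,
  with the published multivariate-probit coefficient table as the
  generating `beta` and its residual correlations as `Sigma` — the
  stated world *is* the published fit;
* **treatment flags** (postnatal check 0.28, vitamin A 0.26, diarrhea
  treatment 0.46, fever/cough treatment 0.40): independent Bernoullis,
  since the source restricts the multivariate stage to morbidity.

What a green test does and does not establish: the generator emulates
truncated preferences, sequential births, under-five deaths and
latent-Gaussian correlated outcomes, but **not** survey weights or the
two-stage cluster design, household structure, preference–fertility
feedback (covariates influence outcomes only through `beta`), or recall
error.  Green tests certify the algorithms against this stated world,
not against the restricted survey.

**Analytic oracle.**  `analytic_excess_prevalence()` computes the exact
expected prevalence of each excess category by dynamic programming over
the state (living boys, living girls, category-flag bits), enumerating
preference triple × birth count × sex sequence × death pattern.  It is
exact for the default dual rule; for `both_sexes` the child-level dual
flag depends on the mother's final state and the function refuses
(documented error) rather than approximate.

## Moment summaries and tables

Sample variance uses `n − 1`; skewness and kurtosis are standardised
third and fourth central moments with denominator `n`, and kurtosis is
*not* excess-corrected (a normal shape reads ≈ 3, matching the
published table's convention).  Constant variables report variance 0
and undefined (`NA`) shape moments.  Percentages are kept at full
precision internally and rounded only for presentation.

The morbidity-by-excess table is emitted with both semantics present in
the source contract: the epidemiologically meaningful
`P(outcome | flag)` columns, and the flag split among outcome-positive
children, which is the published layout and obeys the
No% + Yes% = 100 complementarity (one published row violating it is
treated as an erratum; complementarity is enforced).

## Tetrachoric correlation, KMO, Bartlett, PCA

The tetrachoric coefficient is the maximum-likelihood estimate under
the bivariate-normal threshold model: thresholds fixed at the normal
quantiles of the 2×2 margins, and the latent correlation maximising the
multinomial likelihood of the four cells, searched in (−0.999, 0.999).
The bivariate normal CDF is computed in-package with 64-node
Gauss–Legendre quadrature on the tetrachoric integral
`Φ₂(h,k,ρ) = Φ(h)Φ(k) + (2π)⁻¹ ∫₀^ρ φ₂(h,k,r) dr`; it agrees with an
independent quadrature implementation to ~1e−8 and with closed-form
orthant probabilities to 1e−10.  The estimator is validated against a
0.001-step grid search on 200 random tables.  Zero margins return `NA`
with a warning; empty cells can push the estimate to the search bound
and are flagged.  The pairwise matrix receives a
nearest-positive-semidefinite repair (eigenvalue clipping at 1e−8,
rescaled to unit diagonal, flagged) before inversion-based statistics.

KMO is `Σr² / (Σr² + Σq²)` over off-diagonal entries with `q` the
anti-image partial correlations; Bartlett's sphericity statistic is
`−(n − 1 − (2p+5)/6)·log det R` on `p(p−1)/2` degrees of freedom.  PCA
is the eigendecomposition of the correlation matrix (scale-free, hence
usable on unstandardised binary indicators); the retained set defaults
to the components before the largest successive eigenvalue drop
(automated elbow), overridable by `n_keep`; variable contributions are
`100·loading²` per component; selection keeps variables whose average
contribution across retained components exceeds the uniform expectation
`100/p`.  The mixed covariates are mapped to binary indicators by a
single documented recode before this stage.

## Multivariate probit by GHK simulated maximum likelihood

For outcome `j` of child `i`, the latent model is
`y*_ij = X_i β_j + ε_ij`, `ε_i ~ MVN(0, Σ)` with unit variances, and
`y_ij = 1{y*_ij > 0}`.  The likelihood of an outcome pattern is a
multivariate-normal rectangle probability, estimated by the GHK
recursive importance sampler: signs are absorbed into the covariance,
its Cholesky factor drives sequential truncated-normal draws, and the
product of conditional univariate probabilities is averaged over `R`
draws.  The univariate case is returned analytically (`Φ(μ)` to
machine precision).

Numerical choices:

* **Common random numbers**: one seeded `n × J × R` uniform array is
  fixed for the whole optimisation, so the simulated surface is smooth.
* **Parameterisation**: correlations enter through `tanh`, with a
  positive-definiteness check (penalty value on failure) for `J > 2`.
* **Starting values**: independent univariate probit fits, zero
  correlations.
* **Gradient**: central differences in (μ, ρ)-space — `J` column
  perturbations of the linear index plus one per correlation pair —
  chained through the design matrix (`∂logP/∂β_jc = x_c·∂logP/∂μ_j`).
  This costs `2(J + J(J−1)/2)` likelihood evaluations per gradient
  instead of two per coefficient, which is what makes the `J = 5`
  pipeline fit tractable in pure R.
* **Standard errors**: BHHH/OPG (inverse outer product of
  per-observation scores at the optimum), asymptotically equivalent to
  the Hessian-based covariance at an interior optimum and far cheaper
  at `J(k+1) + J(J−1)/2` parameters; t-values are referred to the
  standard normal (at n in the thousands the distinction from t is
  immaterial).
* **Degenerate inputs**: an all-0 or all-1 outcome aborts with the
  outcome named; incomplete rows are dropped listwise; per-observation
  probabilities are floored at 1e−12 before logging.
* **Defaults**: `R = 100` for fitting (10,000 for reported single
  probabilities); the spec-level invariant `R ≥ 25` is the floor used
  by the scaled pipeline runs.

Recovery is verified on generated data (`J = 3`, `n = 4,000`,
`ρ = 0.3/0.2/0.1`): every coefficient and correlation within 0.1, and
the `Σ = I` fit collapses onto the univariate probits.
`format_fit()` emits the published report layout
(`b_j_k` coefficient rows, `R_j_k` correlation rows; Estimate,
Std.Error, t values, Pr(>t)).

## Random forest and neural network

No tree or network package is assumed: both learners are implemented
in-package and oracle-tested.

The forest grows CART-style trees on bootstrap resamples, trying
`mtry = ⌊√p⌋` random features per split, maximising the Gini impurity
decrease, with minimum node size 5 and depth cap 12; prediction is the
majority vote of per-tree class votes.  Mean-decrease-Gini importance
accumulates each split's impurity decrease (weighted by node share)
per feature across trees.  The network has one hidden logistic layer
(default width 8) with the node rule `M = XW − b`, `Y = 1/(1+e^{−M})`,
trained by full-batch gradient descent on cross-entropy
(200 epochs, rate 0.1, seeded uniform initialisation, standardised
inputs).  Mean-decrease-accuracy importance is seeded permutation
importance on the held-out test set (5 repeats), defined for both
learners; Gini importance is refused for the network.  The split is
stratified by outcome (70/30), the probability threshold is 0.5, and
the positive class is outcome = 1.  The source omits every one of these
hyperparameters; all sit in configuration, none hard-coded.

Sanity contracts: ≥ 90 % test accuracy on well-separated Gaussian
blobs for both learners; accuracy within 5 points of the majority rate
on a null outcome; a planted causal feature ranks first under both
importance measures; seeded runs are bit-reproducible.

## Pipeline

`run_pipeline()` sequences simulate (or load + schema-validate) →
eligibility filter (ideal > 9 dropped with children; child-level
outcome analysis restricted to under-fives) → classify → tables →
association/PCA → multivariate probit → ML, writing each stage's CSV /
JSON artifact and a manifest with package version, seed, per-stage row
counts, the filter report and an MD5 hash of every artifact.  Stage
seeds are derived deterministically from the global seed, so identical
configurations produce identical manifests.  DHS-style numeric sex
codes (1/2) are remapped to M/F with a recorded warning; a missing
required column is fatal with the column named.  Records are treated as
unweighted throughout (the source tabulations state no weighting).

## Known limitations

* The analytic prevalence oracle covers only the default dual rule.
* The GHK fit's OPG standard errors can differ from Hessian-based ones
  in small samples or near boundaries.
* The tetrachoric estimator fixes thresholds at the empirical margins
  (two-step ML), the standard desk-scale choice; full-information ML
  would differ negligibly at these sample sizes.
* The generator's independence assumptions (covariates ⫫ preferences,
  i.i.d. deaths) are deliberate simplifications that keep the ground
  truth enumerable; they are not claims about the survey population.
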