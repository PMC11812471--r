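---
title: "Genetic diagnostics for AMD: weighted PRS and Mondrian cross-conformal status prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic diagnostics for AMD: weighted PRS and Mondrian cross-conformal status prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amdprs)
```

## The problem

Age-related macular degeneration is a complex disease: late-stage
disease (geographic atrophy and/or neovascular AMD) arises from many
genetic variants of mostly small effect together with age and
environment. Because a few loci — notably *CFH* and *ARMS2*/*HTRA1* —
carry unusually strong effects and heritability is high for a complex
trait, a panel-based polygenic risk score is informative enough to
support *diagnostic* questioning: given a symptomatic person, does the
genotype support an AMD diagnosis? It is explicitly not a prognostic
instrument; no onset-time prediction is attempted anywhere in this
package.

This package implements the full analysis chain — panel curation, PRS
computation, risk-quintile assignment, Mondrian cross-conformal status
prediction from (PRS, age, sex), and stratified evaluation — together
with a synthetic cohort generator, because the consortium data on which
the original analysis rests are access-restricted.

## The score

For individual $i$ with risk-allele dosages $d_{ij} \in \{0,1,2\}$ over
panel variants $j$ with effect weights $w_j$,

$$\mathrm{PRS}_i \;=\; \frac{\sum_j d_{ij}\, w_j}{\bar{w}}, \qquad
\bar w = \tfrac1p \sum_j w_j .$$

Dividing by the mean effect size makes the score read as "number of risk
alleles of average effect", which is the scale on which the published
quintile cuts (25.3, 29.9, 34.5, 39.1) are expressed.

**Effect-size scale.** The source material says only that risk alleles
are "weighted by their effect size". We take $w_j = \ln \mathrm{OR}_j$
(the additive log-odds scale, consistent with summing per-allele
contributions of a logistic disease model); weighting by the raw OR is
selectable via `variant_panel(weight_scale = "or")` since the original
scale is not stated.

**Orientation.** Panels print protective ORs (e.g. 0.71). At load time
every such record is flipped: the risk allele becomes the other allele
of the pair, the OR is inverted, and any supplied risk-allele frequency
becomes its complement. After orientation all weights are $\ge 0$, so
the PRS is monotone in every dosage and thresholds are interpretable.
Orientation is idempotent.

**Missing genotypes.** The published analysis handled unreliable
variants by excluding them up front (five of 52 lead variants fail the
diagnostic assay's coverage, leaving the 47 actually used). A deployed
tool still needs a rule for sporadic missing calls: the default
`impute_freq` policy substitutes the Hardy–Weinberg expectation
$2f_j$; the `zero` policy counts zero risk alleles and warns, because
it biases scores downward. Separately, `qc_strong_effect()` fails a run
when a *strong* variant (oriented OR ≥ 1.3 by default) is missing in
more than 5% of individuals — dropping a strong locus silently would
gut the score's predictive power, while weak loci matter little
individually.

**Quintile boundaries.** The published caption defines group 1 as
PRS ≤ 25.3 and group 2 as 25.31–29.9, so intervals are implemented
closed on the right: group $k \in 2..4$ iff $c_{k-1} < \mathrm{PRS} \le
c_k$. Re-derived thresholds use `stats::quantile` type 7 (linear
interpolation), applied consistently for derivation and assignment.
Whether the original cuts came from controls only or the full cohort is
not stated; the package ships them as constants and can re-derive from
any reference vector.

## Mondrian cross-conformal prediction

Status is predicted from three features (PRS, age, sex). The training
data are split into $k = 5$ stratified folds; for each fold an
L2-regularized logistic model (glmnet, $\alpha = 0$, fixed small
$\lambda = 10^{-3}$ on standardized features) is fitted on the other
folds, and the held-out fold contributes calibration nonconformity
scores stored **per true class** — the Mondrian taxonomy. For a test
point $x$ under hypothesized label $y$,

$$p_{\text{fold}}(x, y) = \frac{\#\{\alpha^{(y)}_{\text{cal}} \ge
\alpha(x,y)\} + 1}{n_{\text{cal},y} + 1}, \qquad
\alpha(x, y) = 1 - \hat P(y \mid x),$$

and the reported p-value is the arithmetic mean over folds. The
prediction set at significance $\varepsilon$ keeps every label with
$p > \varepsilon$; the point label is the larger p-value, with exact
ties reported as `"undecided"` rather than silently broken — the set,
not a forced binary call, is the primitive. `prob_affected` is the
fold-averaged $\hat P(\text{case} \mid x)$ of the underlying
classifier: the conformal p-values carry the validity guarantee, the
probability carries the clinical interpretation, and the package
reports both rather than conflating them.

Because calibration is per class, validity is *class-conditional*:
cases and controls are each guaranteed their error rate, so the
guarantee survives the label shift between a 59%-case training clinic
cohort and a 46%-case validation cohort.

Design choices left open by the source material and decided here: the
underlying learner (ridge logistic — three features, monotone biology,
no architecture is claimed), the nonconformity score (probability
score; a margin option exists, but with two classes the margin is a
strictly monotone transform of the probability score and yields
*identical* p-values — the test suite asserts this equivalence), the
fold count (5) and the aggregation rule (arithmetic mean, the common
cross-conformal combination). All four are configuration-exposed.

## The synthetic cohort: what it emulates and what it does not

`make_iamdgc_preset()` generates the package's stated world:

- 47 biallelic variants: two strong loci (oriented OR 2.4 and 2.8,
  standing in for *CFH* rs10922109 and *ARMS2*/*HTRA1*) and 45 weak
  loci with ORs log-normal around 1.2, several stored protective to
  exercise orientation; risk-allele frequencies uniform on
  (0.10, 0.60), fixed once by an internal seed. The five excluded
  low-coverage variants appear in the 52-variant table with their
  published ORs (1.47, 0.71, 1.12, 0.9, 0.76).
- Genotypes: independent Binomial(2, $f_j$) dosages (Hardy–Weinberg).
  The panel holds *independent* GWAS signals, so LD simulation would
  add nothing testable.
- Phenotypes: logistic liability
  $\mathrm{logit}\, P(\text{case}) = b_0 + \sum_j d_{ij}\beta_j +
  0.08\,( \text{age} - 75) + 0.10 \cdot 1[\text{F}]$ with $\beta_j$
  equal to the panel log-ORs; ages truncated-normal $N(75, 10^2)$ on
  [50, 95] (AMD is defined in the 50+ population); sex balanced. The
  intercept centres an average-genotype, reference-age individual at
  $P = 0.5$ so simulated pools are roughly balanced.
- Cohort totals 1,667/1,148 (training) and 14,209/16,566 (validation)
  are hit exactly by stratified resampling from pools — the pipeline
  consumes labelled cohorts, so ascertainment is not modelled.

Under this world the case PRS distribution sits about one SD above the
controls with heavy overlap, and the fitted pipeline lands near 73%
sensitivity / 74% specificity — close to, but *not a reproduction of*,
the published 72.1%/75.7%, which were computed on restricted real data.
A green test here establishes that the machinery is correct and that
the qualitative findings (overlap, unreliable middle quintiles, age
dependence of high-risk errors) emerge from the stated mechanism; it
establishes nothing about real-cohort percentages, ancestry effects
(the source analysis is European-only), genotyping error, relatedness,
population structure, or smoking (deliberately excluded throughout).

One visible difference from the published figure: the synthetic PRS
distribution is centred near 37 rather than ~32, so under the published
constant cuts the lowest risk group is thin. Analyses that need
balanced quintile occupancy (the stratified error-rate direction tests)
therefore derive cuts from the cohort itself via
`derive_quintile_thresholds()`; the published constants remain the
shipped preset and are tested exactly at their printed boundaries.

## Numerical and validity notes

- **p-value mechanics.** Calibration scores are kept sorted;
  $\#\{s \ge \alpha\}$ uses `findInterval(..., left.open = TRUE)`, so a
  test point that duplicates a calibration score counts its own tie —
  the conservative convention. p-values lie in $(0, 1]$; with $n$
  calibration scores the smallest attainable value is $1/(n+1)$, which
  bounds how small a usable $\varepsilon$ can be.
- **Validity tolerance.** The acceptance suite checks class-conditional
  empirical error $\le \varepsilon + 3\sqrt{\varepsilon(1 -
  \varepsilon)/n_{\text{class}}}$ pooled over 20 seed replicates of the
  preset. Pooling matters: within one replicate all test points share
  one calibration set, so the per-seed error carries an additional
  fluctuation of order $\sqrt{\varepsilon(1-\varepsilon)/n_{\text{cal}, y}}$
  (calibration classes are only ~1,100–1,700 here) that the
  $n_{\text{class}}$-based binomial term does not cover; a per-seed
  bound is therefore occasionally exceeded even by a predictor that is
  exactly valid in expectation. The pooled empirical errors track
  $\varepsilon$ to within a few parts per thousand at
  $\varepsilon \in \{0.05, 0.1, 0.2, 0.3\}$.
- **Degenerate inputs.** A panel whose mean effect weight is $\le 0$
  (all ORs 1) cannot be normalized — hard error. Constant reference
  vectors yield non-ascending quintile cuts — hard error. A class with
  fewer than $k$ members cannot stratify into $k$ calibration folds
  without emptying one — hard error, since the Mondrian guarantee
  would silently break.
- **Determinism.** Every stochastic operation takes an explicit seed;
  the CLI derives per-stage seeds from one root seed, and identical
  config + seed reproduces byte-identical artifacts (tested).

## Evaluation conventions

"Undecided" point labels count as errors for both classes in confusion
metrics and stratified tables — conservative, and consistent with
reporting a binary status. Stratified tables default to the pooled
risk-group layout {1}, {2,3}, {4,5} with age bins [50,60], (60,70],
(70,80], (80,95] (the narrative bands of the published error analysis)
and flag strata below $n = 73$, the smallest subgroup size reported
there; a per-group layout and custom bins are supported. The
stratum-size-weighted mean of stratum error rates equals the overall
error rate to machine precision (tested), and sensitivity/specificity
are permutation-invariant.

## Known limitations

The generator draws variants independently, ignores ascertainment,
relatedness, genotyping error and ancestry structure, and its age/sex
composition is a stand-in — none of these invalidate the pipeline
tests, but projections computed from synthetic occupancy fractions are
illustrative arithmetic, not epidemiology. The conformal model uses
three features only; adding covariates (e.g. smoking) is out of scope
by design. The YAML config of an earlier design sketch became JSON so
the package runs on a guaranteed-offline dependency set.
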