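---
title: "Methods: gut dysbiosis, imidazole propionate and obstructive CAD"
author: "cadmb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gut dysbiosis, imidazole propionate and obstructive CAD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`cadmb` implements the downstream statistical analysis used in
cross-sectional HIV cohort studies that relate gut microbiota composition
and the microbial metabolite imidazole propionate (ImP, plasma, nM) to
obstructive coronary artery disease (CAD, stenosis at or above 50% on CT
angiography; "nonobstructive" is 1--49%, and the reference group for the
regression models pools nonobstructive and no-CAD participants). Everything
downstream of a denoised ASV table is in scope: rarefaction, alpha and beta
diversity, differential abundance, a log-ratio dysbiosis index, a bootstrap
random-forest ranking of ImP-predictive taxa, adjusted logistic models with
ROC comparison, and bootstrap mediation. Upstream read processing, the
wet-lab assays and image acquisition are not: the CAD group label, ImP and
IL-6 concentrations are inputs.

Because cohorts of this kind are typically not publicly deposited, the
package ships a synthetic cohort generator with the same statistical
structure, so that every stage can be exercised and tested end to end
without any download.

# The synthetic cohort generator

`generate_cohort()` draws, from one master seed, an ASV count table, a
taxonomy map, a random rooted phylogeny, clinical covariates and ImP.
The master seed is split into named sub-streams (counts, tree, covariates,
ImP), so a stage can be regenerated in isolation.

**Composition.** Genus base proportions use a two-tier scheme. The twelve
genera of the dysbiosis index (three numerator, nine denominator; see below)
receive guaranteed base proportions drawn uniformly from 0.5% to 3%: an
abundance-ratio index can only ever be constructed from genera that are
consistently detected in a cohort, so modelling them as rare would not
emulate the study population that produced one. The remaining "filler"
genera share the leftover mass through a symmetric Dirichlet with
concentration 0.3, which produces the sparse, heavy-tailed genus spectrum
typical of 16S data. ASVs are allocated to genera (at least one each,
extras proportional to genus abundance) and split within a genus by stick
breaking with Beta(1, 5) sticks.

**Group effect.** In the obstructive group the numerator genera are
multiplied by `effect_up` and the denominator genera by `effect_down`,
then proportions are renormalised. The underlying study reports no fold
changes for its index genera, so two configurations are distinguished.
The *defaults* (1.2 and 0.85) are calibrated once so that the resulting
index discriminates obstructive CAD at the scale real cohorts report —
AUC around 0.7-0.8 and single-digit odds ratios — because an index that
separated the outcome perfectly would make the logistic stage degenerate
and would not resemble any observational biomarker. The *strong planted
configuration* (3 and 0.3) is what the detection benchmarks use: it asks
whether the differential-abundance stage recovers all planted genera, not
whether the cohort is realistic.

**Counts.** Per-sample compositions are drawn from a Dirichlet centred on
the group composition with total concentration `overdispersion` (default
200), then counts from a multinomial at a per-sample depth that is negative
binomial (mean 20 000 reads, size 5) floored at 6248 so that, by default,
no sample falls below the rarefaction depth of 6247.

**ImP.** log-ImP = log(15) + `imp_coupling` x (standardised summed relative
abundance of the producer genera, *R. gnavus* and *Veillonella*) + Gaussian
noise (`imp_noise_sd`). Defaults 0.4 and 0.8 give a weak-to-moderate
positive rank correlation between the dysbiosis index and ImP, of the size
one sees in observational metabolite data; the baseline puts the cohort
median near 15 nM with an upper quartile in the tens of nM.

**Confounding.** Age (years), Framingham score and HIV duration (years) are
Gaussian with a mean shift of `confounding_shift` standard deviations in
the obstructive group (default 0.5 SD); CD4-nadir-below-200, statin and
abacavir flags are Bernoulli with a `confounding_shift` log-odds shift;
MSM, antibiotics and sex are unshifted. Setting `confounding_shift = 0`
together with `effect_up = effect_down = 1` and `imp_coupling = 0` makes
the three groups fully exchangeable — the null configuration used by the
calibration tests.

**What the generator does not emulate.** Read-level error, chimeras and
contaminants; phylogenetic signal in abundances (the tree is independent of
the composition); genus correlation structure beyond compositional
closure; longitudinal structure; missing data. Passing tests therefore
demonstrate that the statistics do what they claim on data with the assumed
dependence structure — not that the pipeline is robust to every artefact of
real 16S data.

# Diversity and ordination

Rarefaction subsamples each sample without replacement to a fixed depth
(default 6247 counts), one seeded draw per analysis; samples below depth
are dropped and itemised. All downstream analyses run on the rarefied
table. Observed ASVs, Shannon (natural log) and Faith phylogenetic
diversity are the alpha metrics; Faith PD uses the root-inclusive
convention (the stem from the observed subtree to the root is counted),
stated explicitly because toolkits differ. Beta diversity is Bray-Curtis,
ordinated by classical PCoA: eigendecomposition of the double-centred
squared-distance Gram matrix, with negative eigenvalues reported but
excluded from the variance-explained denominator, and no Cailliez
correction.

Group differences in beta diversity use one-factor PERMANOVA on squared
distances (Anderson's pseudo-F), pairwise between named groups. The
permutation p-value uses the add-one estimator, which cannot return zero.
When a two-group design has no more distinct label splits than the
requested permutations — C(n, n1) at most `n_permutations` — the null
distribution is enumerated exhaustively over all splits instead of sampled,
and p is the exact proportion of splits with F at least the observed value.
Covariate-adjusted and multi-factor PERMANOVA are out of scope.

# Differential abundance (LEfSe-style)

Analysis is at genus level on relative abundances, one-vs-one between two
named CAD groups. A Kruskal-Wallis screen at alpha = 0.05 (raw, no
multiplicity correction, as in the original LEfSe) is followed by an LDA
effect size: over 30 subsampled (two-thirds per class) fits of a two-class
Fisher discriminant on features scaled to counts-per-million, each
feature's effect is the average of its raw class-mean difference and its
own contribution |w_f x diff_f| to the class-mean gap along the unit
discriminant axis, averaged over subsamples and reported as a signed
log10 score with threshold 2.0. Two numerical safeguards matter here: the
pooled within-class scatter is ridge-regularised (relative ridge 1e-6),
and a tiny feature-scaled jitter (SD 0.01% of the feature mean) is added
before each fit. Without them a feature with near-zero within-class
variance acquires an enormous discriminant weight and can inherit the
score of a genuinely differential feature fitted alongside it. Scoring
each feature by its own projected contribution, rather than its share of
the total gap, is what keeps a no-signal feature below threshold even
when it is co-fitted with strong signal. There is no subclass
(within-class) stage: the study design has none, which is a documented
deviation from full LEfSe.

# The CAD-related dysbiosis index

The index is the natural log of the ratio of summed relative abundances,
numerator over denominator:

* numerator (enriched in obstructive CAD): *Veillonella*,
  *Ruminococcus gnavus*, *Alistipes*;
* denominator (depleted): *Prevotella 9*, *Megasphaera*, *Moryella*,
  *Catenibacterium*, *Fusicatenibacter*, *Ruminococcaceae UCG-005*,
  *Ruminococcaceae UCG-009*, *Lachnospiraceae ND3007 group*,
  *Eubacterium xylanophilum group*.

A pseudocount (default 1e-6) is added to both sums so the index stays
finite on sparse samples while perturbing typical values by well under 1%.
Genus names are matched after normalising case, punctuation and spacing,
with an alias table for known spelling variants of the composite labels.
The index is computed on the rarefied genus table — the same substrate as
the diversity analyses; whether the original analysis used pre- or
post-rarefaction proportions is unstated, and the index depends only on
proportions, so the choice is second-order.

"Elevated" means strictly above the empirical 75th percentile, computed by
linear interpolation between order statistics (the type-7 convention);
with distinct values this flags at most a quarter of the cohort, and with
heavy ties it can flag none, which is why the convention is documented.
Quartile assignment for the ImP-by-index analysis uses the same
convention. Correlations are Spearman with average ranks and the
t-approximation p-value; the quartile trend test is the Spearman
correlation of quartile rank with ImP.

# Ranking taxa predictive of ImP

`rf_bootstrap_rank()` repeats, for each of 200 bootstrap resamples of the
cohort: fit a random-forest regression of ImP on genus abundances (500
trees, mtry = floor(p/3), out-of-bag permutation importance; the `ranger`
engine, single-threaded with explicit seeds so runs are reproducible),
assign each taxon a direction by the sign of its Spearman correlation with
ImP within the resample, and record the top 20 taxa by importance within
each direction. Taxa are ranked by selection frequency with ties broken by
mean importance. "Most positive or negative predictive" is thus
operationalised as importance magnitude split by marginal correlation
sign, since forests do not natively sign their predictors. Taxon columns
are sorted by name internally, making the ranking invariant to the column
order of the input table. Abundances enter untransformed (relative) by
default with a log10 option.

# Association and mediation models

Logistic models use obstructive CAD versus the pooled reference group.
Exposure is "highest quartile versus the rest" for both the index and ImP.
Model 1 adjusts for the Framingham score, HIV duration, mode of
transmission (MSM flag), CD4 nadir below 200, statins, abacavir,
antibiotics and IL-6; model 2 adds age and sex. Scalings the source
analysis leaves unstated are fixed here as: Framingham and IL-6
standardised per SD, HIV duration per 5 years, age per 10 years. Fits are
maximum likelihood (IRLS) with Wald 95% CIs — chosen over profile CIs for
speed and determinism. Quasi-complete separation (diverging coefficients
or exploding standard errors) is detected and raised as an explicit error;
the pipeline records such a model as a failure object and continues with
the remaining models. ROC curves sweep the unique score values; the AUC is
the trapezoidal integral, which gives ties half credit and equals the
Mann-Whitney concordance probability exactly.

Mediation (index -> ImP -> obstructive CAD) uses the linear
product-of-coefficients estimator with the binary outcome in
linear-probability form, mirroring the behaviour of the commonly used
implementation it follows: a from `m ~ x + C`, (c', b) from
`y ~ x + m + C`, c from `y ~ x + C`; indirect = a x b, direct = c',
total = c, and total = direct + indirect holds exactly on every draw.
Percentile bootstrap (default 1000 row resamples) provides CIs and a
two-sided p. One calibration property deserves note: under the *complete*
null (both paths absent) the product estimator is conservative — its p
concentrates away from small values, a well-known property of a x b
inference rather than a defect — while on the boundary null (exposure
moves the mediator, mediator does not move the outcome) the p-value is
approximately uniform. The test suite checks exactly these two
behaviours. A counterfactual logit-outcome estimator is deliberately not
the default, to keep the additive identity exact.

# Pipeline, reproducibility and problem sizes

`run_all()` chains all stages, derives one named seed per stochastic stage
from the master seed, and returns a manifest (configuration, seeds, group
sizes, per-stage shapes, dropped samples) alongside the results; re-running
the same configuration reproduces every output bit-identically.
`summarize_cohort()` reports median (IQR) with Kruskal-Wallis p for
continuous covariates and n (%) with Fisher's exact p for binary ones.

The default configuration is the study scale: 254 participants split
114 / 80 / 60 (no CAD / nonobstructive / obstructive), 500 ASVs in 60
genera, rarefaction depth 6247, 999 PERMANOVA permutations, 30 LDA
subsamples, 200 forest resamples, 1000 mediation bootstraps. The test
suite runs calibration and detection simulations at sizes chosen to keep a
full run to a few minutes while preserving the stated replicate counts
where a count is part of the property being checked (for example 500
logistic coverage replicates, 50 planted-detection cohorts, 200 forest
resamples); null-calibration cohorts use 20-sample groups and shallower
depth, which affects power but not the level of the tests being calibrated.

# Known limitations

* The LDA effect size is a faithful *style* reimplementation, not a
  byte-level port of LEfSe; scores agree in scale and ranking behaviour
  but not digit-for-digit with the original tool.
* The linear-probability outcome model in mediation is a deliberate
  simplification; odds-ratio-scale mediation is not provided.
* PERMANOVA is one-factor only; confounder-adjusted beta-diversity testing
  is out of scope.
* The generator's effect sizes are placeholders; nothing in the package
  estimates them from real data, and reported detection rates are
  statements about the planted configuration only.
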