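---
title: "Modelling leukocyte telomere length reference ranges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling leukocyte telomere length reference ranges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telobands)
```

## The problem

Telomeres shorten with every round of DNA replication, and in blood this
loss is measurable across the whole human lifespan. Flow FISH (flow
cytometry with a fluorescent telomere-repeat probe, calibrated against an
internal control of known telomere length) yields a median telomere length
(MTL, in kilobases) for each leukocyte population in a sample. Clinical use
of such measurements — most prominently screening for inherited telomerase
deficiencies — requires an age-specific reference: a 70-year-old with 6 kb
lymphocyte telomeres is unremarkable, a 10-year-old with the same value is
not. `telobands` builds that reference from cross-sectional cohort data and
evaluates individual samples against it.

Six leukocyte populations are modelled: total lymphocytes, granulocytes
(whose telomere length serves as a surrogate for the hematopoietic stem
cell compartment), CD20+ B cells, CD45RA+CD20− "naive" T cells, CD45RA−
memory T cells and CD45RA+CD57+ mature NK/T cells.

## The hinged piecewise-linear age model

Telomere attrition is far from linear over a lifetime: the loss rate is
roughly an order of magnitude higher in the first year of life than in
adulthood, with an intermediate rate through childhood. The package
models MTL versus age as a continuous three-segment piecewise-linear
curve with slope changes ("hinges") fixed at 1 and 18 years:

$$
\mathrm{MTL}(a) = \beta_0 + \beta_1 \min(a, 1)
 + \beta_2\,\mathrm{clamp}(a - 1,\, 0,\, 17)
 + \beta_3 \max(a - 18,\, 0)
$$

so $\beta_0$ is the MTL at birth and $\beta_1, \beta_2, \beta_3$ are the
attrition rates (kb/yr) in infancy, childhood and adulthood. Because every
basis function is continuous in age, any coefficient vector yields a curve
continuous at both hinges — continuity is structural, not a constraint to
be enforced. The breakpoints are fixed a priori (the infancy hinge follows
the deceleration of growth around the first birthday, the second the end of
puberty); `fit_piecewise()` deliberately does not search for them.

Fitting is ordinary least squares on this 4-column basis via QR
decomposition (`stats::lm.fit`). The design is rank-deficient when the data
do not span a segment, and the error names the unidentifiable segment.
`compare_to_polynomial()` implements the model-selection diagnostic that
motivates this parameterisation: against polynomial alternatives of degree
1–4 it reports each model's mean squared error and the mean residual per
age segment; on data with a genuinely hinged mean the polynomial either
underfits infancy or oscillates in adulthood.

```{r fit-example}
cohort <- generate_cohort(default_healthy_config(seed = 1))
lym <- cohort[cohort$subset == "lymphocytes", ]
fit <- fit_piecewise(lym$age_years, lym$mtl_kb)
fit$params
```

## Percentile reference bands

Reference percentiles are built by *vertical shift*: the fitted curve is
moved up or down by an empirical quantile of its own residuals, one shift
$\delta_q$ per level $q$ (default levels 1st, 10th, 50th, 90th, 99th). The
quantile is taken at nearest rank, $\delta_q = r_{(\lceil qn \rceil)}$, so
that exactly $\lceil qn \rceil$ of the $n$ reference points lie at or below
the shifted curve — a band is defined by how many data points it spans, not
by an interpolation formula. Consequences worth noting:

* all bands are parallel to the fitted trend (the spread is modelled as
  age-constant within a subset);
* in-sample coverage between two bands is a counting identity,
  $(\lceil q_{hi} n\rceil - \lceil q_{lo} n\rceil)/n$, exact for tie-free
  residuals — this is property-tested, with residuals stored so that they
  agree bitwise with `mtl_kb - predict(params, age)`;
* a tie on the band curve counts as covered (comparisons are
  strictly-above the lower band, at-or-below the upper).

An interpolated quantile would differ from the nearest-rank choice by at
most one order statistic; the counting definition is adopted because it
makes the band's span statement literally true. A per-segment variant
(separate shifts within each age segment) is not provided: parallel global
bands are the only construction consistent with age-constant spreads, and
the homoscedastic generator below would make a segmented option untestable
against anything.

## The age-adjusted deficit and the carrier screen

For an individual of age $a$ with measurement $m$, the age-adjusted
deficit is
$$\Delta\mathrm{tel} = m - \widehat{\mathrm{MTL}}(a),$$
the vertical distance to the healthy regression estimate; deficits are
negative. `screen_cohort()` reports, per record, the expected MTL, the
deficit, the empirical percentile (fraction of reference residuals at or
below the record's residual; 0 and 100 print as `<1st` / `>99th`) and a
flag for MTL strictly below the 1st-percentile band — the operating point
at which telomerase-mutation carriers separate almost completely from
healthy individuals. The reference fit always comes from healthy subjects
only; carriers and relatives are never part of the reference. Ages beyond
the reference range are extrapolated on the adult segment with a warning.
Whether the median or mean curve anchors the deficit is immaterial under
the symmetric noise model used here, where they coincide.

## Inference

* `nested_f_test()` — does a factor (sex, carrier status, family
  relationship) change the age trend? It compares the pooled piecewise fit
  against fully separate fits per factor level (all four coefficients
  stratified, with shared breakpoints), and refers
  $F = \frac{(RSS_1 - RSS_2)/(df_1 - df_2)}{RSS_2/df_2}$ to
  $F_{df_1-df_2,\ df_2}$. For a two-level factor this is $F(4,\,n-8)$.
  A stratified intercept-only shift would be a weaker alternative; full
  stratification is used because the question is whether the *curves*
  differ, not just their height.
* `one_way_anova()` and `tukey_hsd()` — cross-subset comparisons at a
  single age point (e.g. cord blood). Tukey's studentized-range p-values
  use `stats::ptukey` with the Tukey–Kramer standard error for unequal
  group sizes; with two groups the procedure reduces exactly to the pooled
  t-test ($q = \sqrt{2}\,|t|$).
* `two_sample_t()` — two-tailed pooled-variance t-test, with the
  convention that two constant, equal samples give $p = 1$.

## What the synthetic generator emulates

No public accession exists for cohort data of this kind, so the package
ships a generator (`generate_cohort()`) that realises the data-generating
model the analysis assumes, parameterised by `default_healthy_config()`
and `default_affected_config()`:

* **Trends.** Subset-specific hinged curves; e.g. lymphocytes start at
  11.2 kb and lose 1.190, 0.126 and 0.043 kb/yr over the three segments.
  Slopes are configured in bp/yr and divided by 1000 on construction — all
  internal storage is kb, one unit everywhere.
* **Spread.** Gaussian, homoscedastic within subset, independent across
  subsets within a subject. The noise SD is chosen so the central 80% of
  the noise law matches the configured 10th–90th spread:
  $\sigma = w_{10-90} / (z_{0.9} - z_{0.1})$, e.g. $2.45/2.563 = 0.956$ kb
  for lymphocytes. A Gaussian is consistent with the use of t-tests on
  this kind of data; real measurements also carry within-subject
  correlation across subsets and possible age-dependent variance, which
  the generator deliberately does not reproduce — passing tests therefore
  validate the pipeline's arithmetic and calibration, not distributional
  claims about real blood.
* **Cohort density.** Ages 0–102, eight subjects per age-year (uniform
  within each year bin), with the age-0 bin oversampled to 58 cord-blood
  subjects, mirroring how reference studies oversample birth; ~874
  subjects in all. The steep infancy slope is identifiable only because of
  that cord-blood mass: a flat 8/age-year design leaves fewer than twenty
  points below the first hinge, roughly doubling the Monte-Carlo spread of
  the fitted infancy slope. Cord blood is encoded as age 0 exactly.
* **Sex.** A female-minus-male offset per subset (default +0.3 kb, +0.4
  for naive T cells where the effect is strongest, +0.1 for granulocytes
  where it is weakest), applied as ±offset/2 so the pooled-sex mean stays
  on the configured trend. The values are plausible magnitudes chosen
  once, not published estimates.
* **Carriers and relatives.** Additive age-adjusted deficits per group and
  subset: hTERT carriers lose 2.3–3.1 kb depending on subset, hTERC
  carriers 2.1–3.3 kb, non-carrier relatives 0.6–1.1 kb. A pooled carrier
  cohort is composed as 37 hTERT + 23 hTERC subjects, whose weighted
  deficits reproduce the pooled values (e.g. −3.2 kb for naive T cells).
  Ages follow truncated normals on the adult segment (19–102 years),
  centred at 41 (carriers) and 45 (relatives) with SD 12 — the SD is a
  package choice of a realistic adult family-cohort spread; truncation at
  19 lifts realised means by about a year.

Generation is bit-reproducible for a fixed seed, and setting all SDs to
zero yields data exactly on the configured curves — the basis of the
parameter-recovery tests.

## Flow-FISH calibration

`mtl_from_fluorescence()` converts fluorescence to kb by the
background-subtracted ratio to the internal control:
$\mathrm{MTL} = L_{ctrl} \cdot f \cdot
(S_{s} - B_{s})/(S_{c} - B_{c})$. The control telomere length is a
property of the control cell batch and has no default. The full
protocol-level correction chain between control and sample cells (for
instance DNA ploidy differences) is collapsed into the single
multiplicative factor $f$ (default 1). Duplicate runs merge by arithmetic
mean, flagged when their spread exceeds a tolerance (default 10% of the
mean). Negative background-subtracted signals clamp to 0 kb with a
warning; a control signal at or below its background is an error.

## Numerical choices and problem sizes

Reporting precision follows field convention: predictions at 0.1 kb,
slopes at 1 bp/yr. F-tail probabilities come from `stats::pf` and
studentized-range tails from `stats::ptukey`. Residuals are stored as
`y - X %*% beta` so in-sample band counts are exact rather than subject to
floating-point boundary flips. The test suite works at the default cohort
size (~874 subjects) for single-cohort checks, 20–60 replicate cohorts for
bias and power properties, and 2000 small-cohort (n = 60) replicates for
the type-I-error calibration of the nested F-test; the acceptance script
averages stochastic summaries over 50 replicate cohorts to report expected
recovery with small Monte-Carlo error.

## Limitations

* Bands are age-constant in width; LMS-style (Box–Cox) growth-chart
  quantiles and age-varying spreads are out of scope.
* Breakpoints are fixed, not estimated; data with genuinely different
  hinge ages would need refitting with other breakpoints supplied.
* The generator is cross-sectional only (one record per subject and
  subset) and draws subset noises independently.
* Published p-values from the original clinical cohorts are not
  reproducible here — that data was never deposited — so inferential
  machinery is validated by calibration and power properties on synthetic
  data instead.
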