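# telobands

Age-specific reference ranges for leukocyte telomere length, and screening
of individual samples against them.

Median telomere length (MTL, kb) in blood cells — measured by flow FISH,
i.e. flow cytometry with a fluorescent telomere-repeat probe calibrated
against an internal control — declines with age at a rate that changes
sharply around the first birthday and again at the end of puberty. A raw
MTL value is therefore uninterpretable without an age-matched reference.
`telobands` is for researchers and clinical labs who need to build such
references from cross-sectional cohorts and to place patients on them, for
example when screening families for inherited telomerase (hTERT/hTERC)
deficiencies.

The core model is a continuous three-segment piecewise-linear ("hinged")
regression of MTL on age, with breakpoints fixed at 1 and 18 years:

    MTL(a) = b0 + b1*min(a,1) + b2*clamp(a-1, 0, 17) + b3*max(a-18, 0)

fitted by ordinary least squares per leukocyte subset (lymphocytes,
granulocytes, CD20+ B cells, CD45RA+CD20− naive T, CD45RA− memory T,
CD45RA+CD57+ mature NK/T). Percentile reference bands (1st/10th/50th/90th/
99th) are vertical shifts of the fitted curve by nearest-rank residual
quantiles, so the band at level q spans exactly ceil(q·n) of the n
reference points. An individual's age-adjusted deficit is

    Δtel = MTL_measured − MTL_expected(age)

and the carrier screen flags samples below the 1st-percentile band.
Supporting statistics: nested-model ANOVA F-tests for factor effects on
the whole age trend (F(4, n−8) for a two-level factor), one-way ANOVA with
Tukey HSD, pooled t-tests, and flow-FISH fluorescence calibration. A
synthetic cohort generator with subset-specific published-style trends
makes the entire pipeline testable without clinical data.

## Worked example

```r
library(telobands)

# a healthy reference cohort: ~874 subjects, ages 0-102, six subsets
cohort <- generate_cohort(default_healthy_config(seed = 42))
lym <- cohort[cohort$subset == "lymphocytes", ]

fit <- fit_piecewise(lym$age_years, lym$mtl_kb)
fit
#> Piecewise fit: n = 874, RSS = 835.6099 kb^2, residual df = 870
#> Hinged piecewise-linear telomere trend
#>   intercept (birth): 11.354 kb
#>   slopes: [0,1] -1.2619 | (1,18] -0.1339 | >18 -0.0415 kb/yr

bands <- reference_bands(fit)
bands
#> Percentile reference bands (vertical shifts, kb):
#>   0.01   0.10   0.50   0.90   0.99
#> -2.346 -1.208 -0.009  1.271  2.333

round(band_value(bands, 0.90, 50) - band_value(bands, 0.10, 50), 2)
#> [1] 2.48   # 10th-90th percentile width, kb

# screen simulated telomerase-mutation carriers against the reference
carriers <- generate_cohort(default_affected_config(seed = 43),
                            c(carrier_TERT = 37, carrier_TERC = 23))
scr <- screen_cohort(carriers[carriers$subset == "lymphocytes", ],
                     list(lymphocytes = bands))
round(mean(scr$delta_kb), 2)
#> [1] -2.7   # mean age-adjusted lymphocyte deficit, kb
mean(scr$below_first_percentile)
#> [1] 0.6333333   # fraction below the healthy 1st percentile

# does sex change the naive-T age trend?
nt <- cohort[cohort$subset == "naiveT_CD45RAposCD20neg", ]
nested_f_test(nt$age_years, nt$mtl_kb, nt$sex)
#> Nested piecewise-model ANOVA (F vs M)
#>   RSS pooled 1103.340 (df 870) | stratified 1067.515 (df 866)
#>   F(4,866) = 7.266, p = 9.35e-06
```

Reading the output: the fitted birth intercept (11.35 kb) and segment
slopes (−1.26, −0.13, −0.04 kb/yr) recover the generating lymphocyte
trend; the band shifts show a ~2.5 kb spread between the 10th and 90th
percentiles; simulated carriers sit ~2.7 kb below their age expectation
and mostly under the 1st percentile; and the stratified-by-sex model fits
the naive-T data significantly better than the pooled one.

A command-line wrapper over the same functions is installed at
`system.file("cli/telobands.R", package = "telobands")` with subcommands
`simulate | calibrate | fit | bands | screen | test | run`.

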