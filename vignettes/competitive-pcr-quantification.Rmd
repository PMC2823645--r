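---
title: "Quantifying gene expression from competitive PCR titrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gene expression from competitive PCR titrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcpcr)
```

## The measurement model

Real-competitive PCR quantifies a transcript by co-amplifying its cDNA
with a synthetic competitor that differs by a single base, so that both
templates amplify with essentially the same efficiency. After primer
extension and mass-spectrometric readout, each product contributes a peak
whose normalized area is reported as a *frequency* `f`; the frequencies of
all products of an assay sum to 1. For a one-product expression assay,

$$y = \log_{10}\frac{f}{1-f} = \log_{10}\frac{[\text{cDNA}]}{[\text{competitor}]},$$

so when the competitor is titrated over a serial dilution with
log-concentration $x$, the logit frequency is linear in $x$ with slope
$-1$ under ideal co-amplification. The *equivalence point* (EC50) is the
competitor concentration $10^{x_0}$ at which $y(x_0) = 0$, i.e. `f = 0.5`:
it equals the transcript concentration and is the assay's readout of
abundance. A larger $x_0$ — more competitor needed to balance the cDNA —
means more transcript.

`titration_fit()` fits $y$ on $x$ by least-squares polynomial regression
(degree 1 by default), pooling all titration points of all animals of one
assay. With a high/low treatment group the default model gives each group
its own intercept and a shared polynomial — the treatment enters as an
additive covariate — which stabilises small ladders; independent per-group
fits are available with `shared_slope = FALSE`. The slope is estimated
rather than fixed at $-1$, absorbing mild efficiency differences between
target and competitor.

Fold changes are differences of equivalence points on the log10 scale,
normalized by a housekeeping assay measured on the same animals:

$$\log_{10}\mathrm{FC} = (x_0^{\text{high}} - x_0^{\text{low}})
 - (x_0^{\text{hk,high}} - x_0^{\text{hk,low}}), \qquad
 \mathrm{FC} = 10^{\log_{10}\mathrm{FC}}.$$

The housekeeping contrast removes group-level differences in cDNA loading.
`fc_from_log10()` enforces the display contract that a printed fold change
is `10^log10FC` rounded to one decimal.

## Preprocessing

Two cleaning rules run before any fitting (`qge_preprocess()`):

* printing replicates of a titration point are collapsed to their
  **median** (robust to a single failed spot);
* points with no detected signal (missing frequency) and points with
  frequency exactly 0 or 1 are removed. The logit is undefined at the
  boundaries; clamping them would silently bias slopes, so they are
  dropped and counted in the QC report instead. Ladders left with fewer
  than `min_points` (default 3: two for a line, one for residual degrees
  of freedom) are reported as unfittable rather than crashing the panel.

Preprocessing is idempotent, and the only value-altering operation is the
replicate median.

## Bootstrap inference

`qge()` attaches bootstrap bias, standard error, a percentile confidence
interval and a p-value to every normalized log10 fold change. Each
replicate recomputes the *whole* chain — titration refit, equivalence
interpolation, housekeeping normalization — so the interval reflects all
stages jointly. Bias is `mean(replicates) - estimate` and is reported, not
subtracted; the two-sided p-value doubles the smaller bootstrap tail
probability of the normalized contrast crossing zero and is floored at
`1/B`. `B = 4000` is the default; the calibration experiments in the test
suite use `B = 500` for speed.

Two resampling schemes are implemented, and the choice matters:

* **`resample = "residual"` (default).** Residuals of the fitted titration
  regression are resampled onto the fitted values and the model is refit.
  Because the design matrix is fixed, each replicate's coefficients are a
  rank-one update of the point estimate, which makes thousands of
  replicates cheap. This is the classical bootstrap of a fitted titration
  model and is correctly specified when measurement noise acts per
  titration point — the situation the synthetic generator emulates. The
  test suite verifies its size empirically: under a true-null gene
  (10 animals per group, logit noise SD 0.15) the empirical type-I error
  at $\alpha = 0.05$ over 200 simulations stays within binomial Monte
  Carlo bounds, and 95% intervals cover a simulated 2.6-fold change in at
  least 90 of 100 simulations.
* **`resample = "animal"`.** Whole animals (ladders) are resampled with
  replacement within each group, with one joint animal resample per
  replicate applied to every assay so the gene–housekeeping correlation
  induced by shared animals survives the normalization. This is the right
  scheme when animal-level biological variance dominates the measurement
  noise (set `loading_sd > 0` in the generator to emulate that). Its cost
  is the usual small-sample property of percentile intervals: with around
  ten animals per group they are anti-conservative by a few points of
  type-I error, an $O(1/n)$ effect of the resampling unit count, not of
  this implementation. With the group sizes of a typical expression study
  (tens of animals) the two schemes converge; we default to the residual
  scheme because it is calibrated under the package's own measurement
  model at any group size.

The equivalence point of a degree-1 fit is `-intercept/slope` in closed
form; for higher degrees the real root of the fitted polynomial inside the
observed concentration range is taken, with a warning when the root must
be extrapolated beyond the ladder.

## Allele-specific expression

A two-allele assay yields three frequencies per point (allele 1, allele 2,
competitor) summing to 1. For a heterozygote, the relative expression of
allele 1 is the unweighted mean of $f_1/(f_1+f_2)$ across the titration
range — the competitor amount cancels from the ratio, so all points are
equally informative and averaging them is appropriate under the assumption
that the allelic ratio is constant along the titration (a
precision-weighted mean changes nothing in the balanced designs simulated
here). Summing the two allele frequencies reconstructs a one-product
ladder for total expression that feeds `qge()` unchanged.

`ase_fit()` tests allelic imbalance with fixed effects for treatment and
allele. The response is ambiguous in principle and both readings are
implemented:

* `response = "ratio"` (default): rows are sample × allele carrying the
  allele share $r$ and $1-r$ (logit10 scale by default). The two rows of a
  sample are complementary, so the treatment *main* effect is structurally
  zero and reported as `NA`; differential allelic expression between
  groups is the treatment × allele interaction.
* `response = "level"`: each allele's expression level against the
  competitor, mean $\mathrm{logit}_{10}\,f_a/(f_a+f_c)$ over points, which
  gives the treatment main effect its usual total-expression meaning.

Homozygotes carry no allele-specific information and are skipped with a
reason code. An assay whose second product is never detected (an isoform
assay with a silent isoform, for example) is flagged "not detected" rather
than modelled.

## Association analysis

`assoc_fit()` fits ordinary least squares
`ln(androstenone) ~ sire + genotype + hys + bulbo` for one SNP. Sire is a
fixed effect so genotype effects are not confounded with sire selection;
`hys` is the combined herd–year–season batch factor; bulbo-urethral gland
length enters as a continuous covariate — it is a length measurement
proxying sexual maturity, and fitting it as a covariate matches the
general-linear-model procedure the analysis follows. Genotype
least-squares means are computed with **emmeans** and back-transformed
with a bare `exp()`, which estimates the *median* of the skewed trait
distribution; no lognormal-mean correction is applied, and the standard
error is carried over by the delta method ($e^{\hat\mu}\,\mathrm{SE}$).
The genotype effect is judged by its overall F-test (`drop1`); empty
genotype classes are dropped from reporting; no multiple-testing
correction is applied across SNPs, matching the single-candidate-gene
setting. Hardy-Weinberg equilibrium is checked per SNP by the chi-square
of observed genotype counts against $p^2, 2pq, q^2$ with 1 degree of
freedom.

## What the synthetic generator emulates — and what it does not

The generator (`simulate_expression()`, `simulate_ase()`,
`simulate_genotypes()`, `simulate_phenotypes()`) reproduces the
statistical structure the estimators assume:

* an 11-point, 7-fold competitor dilution from 4.04e-11 M (1.43e-19 M at
  the last point — about single molecules in a 5 µL reaction, the natural
  lower end of a titration), configurable via `ladder_design()`;
* frequencies generated from the logit-linear measurement model with
  **additive Gaussian noise on the logit scale**, the scale the model
  fits, so the fitted model is correctly specified; two printing
  replicates per point; optional missingness (`dropout_rate`) and an
  optional per-animal loading offset (`loading_sd`) shared across assays —
  exactly the artefact housekeeping normalization removes;
* two-allele assays whose three frequencies sum to 1 exactly;
* genotypes under Hardy-Weinberg equilibrium and log-normal phenotypes
  with additive sire, batch, covariate and genotype effects, with breed
  presets matching population means of 1.17 µg/g (SD 1.10) and 3.22 µg/g
  (SD 2.69) and extreme-tail selection of 3% / 4.5% per tail (6% and 9% of
  animals in total).

The per-point noise magnitude of the real assay is not published; the
default `noise_sd = 0.1` (logit10 units) is this package's assumption, and
the calibration experiments state their noise explicitly. The generator
does **not** model PCR efficiency differences, saturation at the ladder
extremes, peak-calling artefacts, or correlated noise along a ladder —
so passing tests demonstrate correctness of the estimators under the
stated model, not robustness to those real-data effects.

Group sizes default to 48 + 48 animals per breed (the scale of an extreme-
phenotype expression study); the Monte Carlo experiments in the test suite
and acceptance script use 10 animals per group, 200 null replicates and
100 coverage replicates with `B = 500`, and association calibration with
1000–2000 animals — sizes chosen so the full suite runs in minutes while
keeping Monte Carlo error well inside the asserted bounds.

## Numerical choices and degenerate inputs

* All randomness flows from per-scenario integer seeds; identical seeds
  give byte-identical tables, and the RNG state of the session is restored
  afterwards.
* The degree-1 titration fit inside `qge()` uses closed-form normal
  equations on per-animal sufficient statistics; the test suite
  cross-checks it against an independent `lm()` fit.
* Bootstrap replicates that cannot be fitted (degenerate resample,
  singular design, no real root) are dropped; if more than 20% of a
  gene's replicates fail, inference for that gene is aborted with a
  diagnostic rather than reported from the remainder.
* Equivalence roots of higher-degree fits prefer the real root inside the
  observed ladder; ties go to the root nearest the ladder centre.
* Frequencies exactly 0/1 never enter a fit; ratios at the boundaries are
  clamped at 1e-12 only for the logit of the ASE response.
* A monomorphic SNP yields `NA` with reason `"monomorphic"` from the
  Hardy-Weinberg test; a SNP with a single observed genotype class is an
  error, never a one-class "result"; genotype/sire aliasing is reported as
  a rank-deficiency error naming the aliased terms.

## A worked example

```{r example}
sc <- expression_scenario(n_per_group = 12,
                          true_log10_fc = c(STAR = 1.13, CYP17A1 = 0.46),
                          noise_sd = 0.1, seed = 42)
panel <- simulate_expression(sc)
fit <- qge(panel, B = 1000, seed = 42)
fit
```

The printed table mirrors the conventional reporting layout: fold change,
log10 fold change, bootstrap bias, standard error, and p-value, with
significance flagged at P < 0.05.

## Known limitations

* Absolute copy-number calibration and cross-chip normalization are out of
  scope; all quantities are relative to the housekeeping reference.
* The fold-change estimator assumes the housekeeping transcript is truly
  invariant between groups; a regulated reference biases every gene by the
  same shift.
* Percentile intervals from animal-level resampling should be treated as
  approximate below roughly 20 animals per group (see above).
* The association model is a fixed-effects approximation; variance-
  component animal models and haplotype analyses are deliberately not
  implemented.
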