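---
title: "Measuring and interpreting type I error in product-term interaction scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and interpreting type I error in product-term interaction scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A SNP-by-genome interaction scan holds one *repeating* SNP `x` fixed and
pairs it with every genome (*non-repeating*) SNP `z`, fitting the
product-term model

    y = b0 + b1*x + b2*z + b3*x*z + e

and testing `b3 = 0` with a 1-df test for each pair. The scan-level summary
of type I error is the genomic inflation factor computed on the interaction
term,

    lambda_3 = median(t_3^2) / median(chisq_1),

with `median(chisq_1) = qchisq(0.5, 1) = 0.4549...` (0.455 in conventional
rounded arithmetic; `lambdascan` supports both denominators and records
which was used).

Unlike a main-effect scan, where the tests are essentially independent and
lambda hugs 1 under the null, the interaction tests within one scan are
*correlated*: every product term shares the repeating component `x`. Any
small finite-sample bias in the `b3` test — most importantly the bias caused
by unequal phenotype variance across the repeating SNP's genotype classes
(heteroskedasticity, including the purely stochastic kind that arises in any
finite sample) — is repeated across the whole scan instead of averaging out.
The consequence is that `lambda_3` under a true null can range far from 1,
more so at small sample size and low repeating-SNP minor allele frequency
(MAF). A `lambda_3` of 1.2 from an interaction scan is therefore not
evidence of population substructure or systematic error the way it would be
in a GWAS, and `lambda_3` must never be used to rescale the test statistics
(the package deliberately offers no such adjustment: part of the apparent
bias is pure non-independence, and "correcting" it would inject real bias).

`lambdascan` implements the full measurement-and-interpretation loop:

1. simulate matched null datasets (`simulate_study_data()`),
2. run the scans (`run_study()`) with OLS or heteroskedasticity-consistent
   (HC0/HC3) covariance and sparse-cell filtering,
3. summarize each scan into `lambda_3`, observed alpha and Q-Q coordinates,
4. diagnose heteroskedasticity and leverage (`genotypic_variance_ratios()`,
   `leverage_comparison()`), and
5. interpret an observed `lambda_3` against a simulation-based empirical
   null distribution (`build_null_distribution()`, `compare_lambda()`).

## The null simulator

Null datasets contain **no SNP effects, no linkage disequilibrium, no
relatedness and no population substructure** — deliberately, so that the
lambda variation they produce is the *minimal* disturbance attributable to
the scan design itself. Genotypes are independent draws from Hardy-Weinberg
proportions `((1-p)^2, 2p(1-p), p^2)` given each SNP's MAF `p`; MAFs come
from either a grid (`maf_grid(0.05, 0.5, 0.01)` is the 46-point panel used
for broad repeating-SNP spectra) or an empirical list sampled with
replacement. Phenotypes are either independent standard-normal draws or
independently permuted copies of user-supplied trait columns (each column
gets its own permutation, which preserves every marginal distribution while
destroying all cross-column and genotype-phenotype structure).

Features of real data the simulator does **not** emulate: linkage
disequilibrium (so it cannot produce the LD-driven false positives near the
repeating SNP), genotyping error and missingness patterns, non-normal or
outlier-laden phenotypes, and real covariance between traits. Passing the
package's property tests on simulated data therefore demonstrates the
behaviour of the *method under its own stated null*, not the absence of
those artifacts in any real dataset.

Randomness discipline: every generator takes one master seed; each SNP
column, trait column and permutation uses a substream seed derived
deterministically from (master seed, counter), so a single column can be
regenerated without replaying the stream and all outputs are byte-identical
under a fixed seed.

`default_maf_spectrum()` is a deterministic synthetic stand-in for a
genotyping panel's MAF distribution (log-uniform over [0.05, 0.5], so low
frequencies are over-represented as in real panels). It is not derived from
any cohort; supply `maf_empirical()` with real panel MAFs when available.

## Models, estimators and filters

Four designs are supported: main-effect only (`I`), two-locus (`II`),
product-term (`III`, the default) and the additive+dominance model (`IV`)
whose 4-df F test constrains all four product terms; dominance coding is
1 for heterozygotes. Fits use a rank-revealing pivoted QR (R's `qr()`),
never explicit normal-equations inversion; rank deficiency raises a
structured error naming the offending columns, which the scan engine
converts to a `singular` skip. We use QR pivoting rather than an SVD cutoff
for rank detection: it is the standard, well-tested numerical path in R and
carries column identity through pivoting, which the skip diagnostics need.

Coefficient covariance is `(X'X)^-1 X' W X (X'X)^-1` with `W` equal to the
pooled residual variance (OLS), per-observation squared residuals (HC0), or
leverage-adjusted squared residuals `e_i^2/(1-h_ii)^2` (HC3). HC1/HC2 are
not provided: the evaluated estimators are HC0 and HC3, HC3 being the
leverage-adjusted form that performs best in small samples. P-values for
the 1-df product-term test use the t reference with `n - k` df under all
three covariances; for HC covariances this is a documented approximation
(the exact finite-sample reference is unknown), consistent with how
standard regression software reports HC-based tests. The multi-df joint
tests (2-df and 4-df) are RSS-based OLS F tests only — HC versions are out
of scope because HC inference is evaluated on the product term alone.

Filter order in a scan is fixed and documented: (1) minor-allele recode of
every SNP on the full analyzed sample, (2) genome-wide MAF threshold on the
sample MAF (boundary inclusive), (3) per-pair complete-case subset, (4)
per-pair minimum cell-count filter, (5) fit. Sample MAF is *not* recomputed
after per-pair drops, and the repeating SNP's own column is excluded from
the non-repeating iteration (self-pairing is degenerate); SNPs correlated
with the repeating SNP are retained.

The minimum cell-count filter drops all subjects belonging to populated
two-locus genotype cells with fewer than `min_cell_count` members, in a
single pass (counts are computed once and not re-evaluated after dropping;
empty cells impose no constraint). The default is 0 for OLS and 5 for
HC0/HC3: HC estimators represent an entire cell's variance contribution by
a handful of residuals, and sparse cells are exactly where they destabilize
— a scan with HC3, no filtering and MAF-0.01 genome SNPs reliably produces
extreme P-value outliers that OLS does not. Raising the minimum (25 is a
useful stress value) suppresses the remaining outliers at the cost of
subjects.

Skipped pairs (`monomorphic`, `singular`, `insufficient_cells`) are recorded
as rows, never dropped silently; lambda and observed-alpha denominators use
non-skipped rows only and the skip count is carried in every lambda record.

## Inflation statistics and diagnostics

`lambda_from_tstats()` is used for the 1-df t tests; `lambda_from_pvalues()`
maps F-test P-values to chi-square(1) deviates first, putting multi-df tests
on the same scale. An even-length median is the mean of the two central
order statistics. P-values of exactly 0 are capped at 1e-300 with a
warning. `observed_alpha()` counts P *strictly* below the level (a
documented convention). Q-Q coordinates use the `(i - 0.5)/m` expected
quantiles.

`genotypic_variance_ratios()` orders the repeating SNP's genotype classes by
size (ties broken by dosage ascending, a documented choice) and reports the
three pairwise phenotype-variance ratios using `n - 1` variances; classes
with fewer than 2 subjects have their variance flagged absent. The key
direction, which the package's tests reproduce in controlled simulation:
when the most-populated class is *less* variable than the least-populated
one (`ratio_1_3 < 1`), `lambda_3` inflates, and the mirrored pattern
deflates it. Even homoskedastically generated data shows this association
at modest n through purely stochastic variance-ratio deviations — it
attenuates as n grows.

`leverage_comparison()` reports the per-cell maximum hat value under the
two-locus and product-term designs; adding the product column can only
enlarge the column space, so leverage never decreases, and the increase
concentrates in sparse double-minor cells. This is the mechanism connecting
the product term to HC instability: HC3's leverage adjustment divides by
`(1 - h_ii)^2` exactly where `h_ii` is largest.

## Interpreting an observed lambda

`build_null_distribution()` simulates a matched-size dataset and collects
`lambda_3` from every (repeating SNP, phenotype) scan; `compare_lambda()`
places an observed value in that distribution, reporting a mid-rank
percentile `100*(r + 0.5*ties)/B` and a two-sided permutation-style tail
probability `2*min(r+1, B-r+1)/(B+1)` capped at 1. No accept/reject verdict
is attached — the package reports where the value falls and how extreme it
is, and the analyst judges it against the distribution's spread. Because
the null spread depends strongly on repeating-SNP MAF, `nearest_band`
matching (default band ±0.05, at least 20 reference values required)
restricts the comparison to scans with a similar repeating MAF; an
unmatched comparison is anti-conservative for low-MAF repeating SNPs. The
null genome can be smaller than the real one — lambda is a median, whose
precision grows slowly with the number of tests — but at least a few
hundred SNPs are needed before the per-scan median stabilizes (a warning
fires below 100).

## Numerical and design choices

* Grid spectra are expanded by integer index arithmetic (no floating-point
  step drift); endpoints are inclusive.
* MAF draws from an empirical spectrum are with replacement.
* Simulated SNPs whose realized sample MAF is 0 are kept in the matrix and
  skipped by the scan engine, keeping generation side-effect free.
* HC3 with any `h_ii = 1` raises a structured extreme-leverage error
  (converted to a skip in scans): that observation fully determines a
  coefficient.
* Lambda records store which denominator (exact vs 0.455) produced them.
* The genotype interchange format is a dosage TSV with a leading
  `subject_id` column (ids are required to align phenotype tables), a
  provenance comment header, and a companion SNP-metadata TSV. VCF import
  is GT-only and convenience-only: multi-allelic records are skipped with a
  count, and dosages are recoded to the sample minor allele downstream.

## Problem sizes used by the test suite

The packaged property suite runs the study-scale checks at a reduced scale
chosen to exercise every documented pattern on one CPU: genome 2,000 SNPs,
10 repeating SNPs (MAF 0.05-0.5 step 0.05), 5 phenotypes, n = 1,053 and
5,000; the outlier stress uses a log-uniform MAF 0.01-0.5 genome with a
MAF-0.06 repeating SNP; the calibration check uses 399 independent
mini-datasets (n = 300, 250 SNPs). The qualitative patterns (spread
narrowing with n and MAF, HC3 range narrowing, HC3 outlier creation,
heteroskedasticity direction) are scale-stable; the reduced scale trades
only precision of the lambda estimates, not the direction of any effect.

## Known limitations

* The t reference for HC-based 1-df tests is approximate in small samples.
* The empirical-null comparison assumes the analyst's real data differ from
  the simulator's null only in ways the simulator models (no LD, no
  substructure); a real dataset violating these can land outside the null
  distribution for reasons other than interaction-test miscalibration.
* No covariates in scan models: phenotypes are assumed to be pre-adjusted
  residuals.
* No resampling-based inference; at scan scale it is computationally
  impractical, which is precisely the niche of the HC estimators evaluated
  here.
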