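---
title: "HLA-I evolutionary divergence as an immunotherapy biomarker: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HLA-I evolutionary divergence as an immunotherapy biomarker: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

hedstrat implements a germline-to-outcome biomarker workflow for immune
checkpoint blockade (ICB) cohorts. The driving idea is the divergent
allele advantage: a patient whose two HLA class I alleles at a locus are
more dissimilar in their peptide-binding region can present a broader
immunopeptidome, which may translate into better tumor recognition under
checkpoint blockade. The workflow quantifies that dissimilarity (HED),
derives the tumor-side features it is usually combined with (TMB, CNA
burden, MSI status), finds data-driven cutpoints, and runs the survival,
contingency, correlation and expression analyses that evaluate HED — alone
and jointly with TMB — as a predictive biomarker.

This vignette records the models, the tunable parameters, and the design
decisions, including the places where the method description in the
underlying literature is ambiguous and the package had to choose.

## The Grantham distance

The amino-acid distance between residues $i$ and $j$ is

$$D(i,j) = \rho\left[\alpha\,(c_i-c_j)^2 + \beta\,(p_i-p_j)^2 +
\gamma\,(v_i-v_j)^2\right]^{1/2}$$

where $c$ is side-chain atomic composition, $p$ polarity and $v$
molecular volume. The classic weights are $\alpha = 1.833$,
$\beta = 0.1018$, $\gamma = 0.000399$; the property values for the 20
canonical residues are embedded as a versioned fixture
(`grantham_properties()`), so the matrix is rebuilt from first principles
at load time rather than shipped as opaque numbers.

Two modes are provided:

* `"published-integer"` (default): entries rounded half-up to integers,
  matching the classic integer matrix used by the HED scripts circulating
  in the field.
* `"continuous"`: full precision, for sensitivity analysis.

**Scale factor.** The constant most often quoted for $\rho$ is 50.723.
Evaluating the formula on the property fixture shows that this constant
rounds the Trp–Cys entry to 214, whereas the published integer matrix
prints 215. Calibrating $\rho$ so that the mean of the 190 off-diagonal
distances is exactly 100 gives $\rho = 50.78988\ldots$, which reproduces
both landmark entries (Leu–Ile = 5, Trp–Cys = 215) and every other
integer entry our tests check. The calibrated value is therefore the
default; any fixed $\rho$ can be supplied through `grantham_params()`.
`calibrate_rho()` exposes the calibration so its result can be logged.

## HED

For one locus, HED is the mean per-site Grantham distance between the
aligned peptide-binding-region (PBR) sequences of the patient's two
alleles — the concatenation of the exon-2 and exon-3 protein segments,
which form the variable walls of the peptide-binding groove. Mean HED is
the arithmetic mean of the three locus values at HLA-A, -B and -C.

Decisions worth knowing:

* **Allele resolution.** Allele names are truncated to two-field
  resolution (`B*15:01:01:02N` → `B*15:01`) before lookup; protein
  variation within a two-field group is ignored, consistent with analyses
  at genotype level.
* **Homozygosity** is defined as identical two-field names; a homozygous
  locus has HED 0 by definition, without requiring a sequence lookup.
  Differently named but sequence-identical alleles count as heterozygous
  with HED 0.
* **Gap sites** (`-` in either aligned sequence) are excluded from both
  the numerator and the compared-sites denominator; if more than 5% of
  sites are excluded a warning is raised, since that suggests a
  misaligned library.
* **Mean over all loci.** Mean HED averages all three loci including
  homozygous zeros. Averaging only heterozygous loci is a defensible
  alternative, but the all-loci mean matches the definition "the mean
  divergence at HLA-A, HLA-B and HLA-C" literally, so it is what
  `profile_patient()` computes.
* **Coordinates.** The exon sidecar uses 1-based inclusive protein
  coordinates; the default synthetic PBR length is 182 (≈90 aa exon 2 +
  ≈92 aa exon 3). A real annotation always wins over the default.

## Tumor genomic features

A somatic SNV counts toward TMB iff it is exonic, nonsynonymous or
stopgain, has depth ≥ 40 and sample variant allele fraction ≥ 0.03, and
every *available* population allele frequency (ExAC, gnomAD, 1000
Genomes) is ≤ 0.002. All boundaries are inclusive. Two readings had to be
fixed:

* "Allele frequency" appears twice in the filter list; the ≥ 0.03 filter
  is read as the sample VAF and the ≤ 0.002 filter as population
  frequency — the only reading under which both filters are meaningful.
* A missing population frequency means "not observed in that database"
  and passes that sub-filter (the usual annotation convention); the count
  of such records is reported. When several databases report a value the
  filter applies conjunctively.

TMB = passing mutations × 10⁶ / callable bases, where callable bases are
exonic positions with depth ≥ 40; indels are excluded (the count is a
filtered-SNV count). CNA burden is the number of genes with a copy-number
gain or loss. MSI is called from the five-locus PCR panel (BAT-25,
BAT-26, D2S123, D5S346, D17S250): two or more unstable loci is MSI-H,
otherwise MSS. Durable clinical benefit (DCB) is CR, PR, or SD lasting
≥ 24 weeks; PD or shorter SD is NDB.

The rejection tally attributes each rejected record to the first failing
filter in the documented order (region, effect, depth, VAF, population
frequency); the passing set itself is order-independent, which the tests
verify by permuting the cascade.

## Cutpoints and stratification

**Maximally selected rank statistics.** `maxstat_cutpoint()` scans every
distinct biomarker value whose split (`> c` vs `≤ c`) leaves at least
`ceil(minprop · n)` patients per side and computes the standardized
log-rank statistic $|Z|$ at each candidate; the returned cutpoint
maximizes $|Z|$. `minprop` defaults to 0.1, the convention of the
cutpoint tools used in this literature. Ties are broken toward the
smallest candidate (the scan is deterministic and order-invariant). No
p-value adjustment for the selection is applied: the cutpoint is used for
stratification, and significance is assessed downstream by log-rank and
Cox models on the dichotomized groups — a deliberate echo of how such
cutpoints are used in practice, and a known source of optimism if the
scan p-value were reported directly.

**Youden index.** For the binary DCB endpoint, `youden_cutpoint()` scans
observed scores with the convention "positive call iff score strictly
greater than the threshold" and maximizes J = sensitivity + specificity −
1. The default direction assumes higher scores predict benefit;
`direction = "auto"` flips the scan with a warning when the AUC is below
0.5.

**Joint groups.** With cutpoints for HED and TMB, patients fall into
`both_high` (both strictly above), `both_low` (neither above) or
`single_high`. Boundary values are low — `dichotomize()` is
strict-greater everywhere, so HED = 8.61 at cutpoint 8.61 is "low".

**Association tests.** The 2×2 DCB comparison uses Fisher's exact test or
Pearson's chi-square without continuity correction; `method = "auto"`
selects Fisher when any expected cell is below 5. Per-gene driver
mutation comparisons are two-sided Fisher tests with the conditional-MLE
odds ratio, reported without multiplicity adjustment (the downstream
interpretation thresholds are deliberately lenient screens). Spearman
correlations use midranks and the t-approximation for the two-sided p.

## Survival models

Kaplan–Meier estimation (Greenwood variance; median = first time the
curve reaches 0.5, undefined if never), the two-group log-rank test, and
Cox proportional-hazards fits are delegated to the survival package,
which is also what cohort analyses in this field use directly. Efron tie
handling is the default (better small-sample behavior than Breslow; the
literature this workflow follows does not state a choice). Times are
months; event = 1 is death/progression. In the multivariable model the
covariates enter as binaries at their stated cutpoints by default
(HED-high, TMB-high, MSI-H); continuous entry is possible by passing the
raw columns. Internal consistency is tested: the square of the
standardized log-rank score used by the maxstat scan equals the log-rank
chi-square, and the Cox score test at β = 0 matches the log-rank
statistic in tie-free data.

## Expression panel

Counts are normalized in two steps: reads per million over the panel
(each sample column sums to 10⁶), then a per-sample housekeeping ratio to
an internal control: ratio = geometric mean of the control's 10
housekeeping-gene RPM over the sample's, applied to all genes. The
geometric mean was chosen over the arithmetic mean because it is robust
to a single dominant housekeeping gene; after normalization the sample's
housekeeping geometric mean equals the control's exactly, which the tests
assert to 1e−9. Housekeeping genes with zero RPM are dropped from the
mean with a warning. The log transform is log2(nRPM + 1); the unit
pseudocount keeps zeros at zero and is configurable only by
pre-transforming.

Differential expression between HED groups runs on the log matrix with an
empirical-Bayes moderated t-statistic (limma), i.e. per-gene variances
shrunk toward a panel-wide prior; a plain Welch t-test is available since
the exact prior of any given historical analysis is not reproducible. A
gene is called iff |log2FC| > log2(1.5) = 0.5849625 (strictly) and raw
p < 0.05 — deliberately *unadjusted*, mirroring the filtering convention
this type of panel analysis uses; Benjamini–Hochberg adjustment is
applied only in the over-representation step, which is a plain
hypergeometric upper-tail test against user-supplied GMT gene sets (no
pathway database is bundled, so analyses are reproducible offline).

## The synthetic cohort

`simulate_cohort()` generates every input the pipeline consumes, under a
single integer seed with full determinism. Its defaults are the study
conditions the package is organized around: 84 patients with germline
typing, 76 with tumor profiling, a 395-gene panel with 10 housekeeping
genes, reference cutpoints 8.61 (HLA-B HED) and 5.22 mut/Mb (TMB).
Choices the generator makes:

* **Allele library**: per locus an ancestral 182-aa PBR sequence with
  alleles derived by random substitutions; the substitution count targets
  the per-locus mean pairwise divergence (A 6, B 9, C 3 — ordered as
  observed in real cohorts, with HLA-C least divergent) and the pool is
  redrawn until the realized mean is within ±20% of target.
* **Survival**: exponential event times with hazard
  $h_0 e^{\beta_1 [\mathrm{HED\ high}] + \beta_2 [\mathrm{TMB\ high}]}$
  and independent exponential censoring. Defaults: baseline median OS 10
  months, both log-HRs log 0.5 (high groups protective), censoring rate
  0.03/month. Exponential baselines are the simplest
  proportional-hazards-consistent choice; a Weibull extension would only
  change the time scale, not the group contrasts the tests measure.
* **DCB**: logistic in the two high-group indicators, intercept at a 16%
  both-low response rate and +1.1 log-odds per high flag, which places
  the subgroup rates in the realistic 16–63% range.
* **Variants**: each sample draws its expected TMB from a log-normal
  (median 3.5 mut/Mb), its passing records from a Poisson at that rate,
  plus deliberately failing records for each filter (so every branch of
  the cascade is exercised); population frequencies have a point mass at
  0 plus a tail beyond 0.002 so that filter has bite.
* **Expression**: negative-binomial counts, stable high-expressed
  housekeeping genes, and a 10% DE fraction between HED groups with
  log2 fold changes in [0.7, 1.6] seeded in the high group.

What the generator does **not** emulate: real HLA allele and haplotype
frequencies or linkage, locus-specific substitution patterns, mutational
signatures, copy-number segmentation structure, batch effects, or
informative censoring. Passing tests therefore demonstrate that the
estimators recover what the generative models put in — cutpoints, hazard
ratios, DE genes, calibrated error rates — not that any biological claim
holds in real cohorts.

## Problem sizes and numerical choices

The test and acceptance runs use cohorts of 40–200 patients for cutpoint
oracle checks, n = 500 with ~30% censoring for hazard-ratio recovery
(true HR 2, accepted within [1.7, 2.35]), 2,000 replicates of n = 84 for
log-rank null calibration (5% ± 2%), 300 true-positive and 2,000 null
genes at n = 25 per group for DE power and false-positive calibration,
and 1,000 random sequence pairs for the HED brute-force comparison
(agreement to 1e−12). These sizes make every estimator's sampling
behavior visible while keeping a full run in minutes on one core.

Convergence and degenerate-input handling: Cox fits use the survival
package's Newton iterations with relative log-likelihood tolerance 1e−9
and up to 100 iterations; constant covariates, zero-event data, constant
biomarkers in the cutpoint scans, zero-total expression samples, all-gap
sequence pairs and single-class outcomes all raise typed errors rather
than returning silently degenerate numbers. An all-tied Kruskal–Wallis
input returns H = 0, p = 1 by convention.

## Known limitations

* HED is computed from a user-supplied allele library; genotype calling
  from reads, class II loci and allele imputation are out of scope.
* The deposited patient-level tables of the motivating cohorts are under
  controlled access, so the reference cutpoints (8.61, 5.22, 10.19) are
  carried as configuration constants and reproduced only structurally on
  synthetic data; the acceptance check against the real tables runs only
  when a user supplies them locally.
* No time-dependent ROC, competing risks, bootstrap cutpoint intervals,
  or pathway-topology enrichment.
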