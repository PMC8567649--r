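# hedstrat

Germline HLA class I evolutionary divergence (HED) as an immunotherapy
biomarker, implemented as a tested analysis workflow for immune
checkpoint blockade (ICB) cohorts.

A patient's two HLA-I alleles at a locus jointly define which tumor
peptides can be presented to T cells; the more physicochemically
divergent the two alleles' peptide-binding regions, the broader the
presentable immunopeptidome. hedstrat quantifies this divergence from
allele protein sequences, combines it with tumor genomic features, and
runs the downstream biomarker analyses. It is aimed at translational
researchers who have HLA genotypes, somatic variant calls and clinical
outcomes for an ICB-treated cohort and want the full
stratification-and-survival analysis — plus a seeded synthetic-cohort
generator so the entire pipeline is testable without patient data.

## What it computes

**HED.** For locus ℓ with aligned peptide-binding-region (exon 2 + 3)
sequences x, y of the two alleles:

    HED_ℓ = (1/L) Σ_s D(x_s, y_s)

where D is the Grantham amino-acid distance

    D(i,j) = ρ [α(c_i−c_j)² + β(p_i−p_j)² + γ(v_i−v_j)²]^½

built from side-chain composition (c), polarity (p) and volume (v) with
α = 1.833, β = 0.1018, γ = 0.000399 and ρ calibrated so the matrix mean
is 100 (which reproduces the classic integer matrix, e.g. D(L,I) = 5,
D(W,C) = 215). Homozygous loci have HED 0; mean HED averages the A, B
and C loci.

**Tumor features.** TMB = filtered somatic SNVs × 10⁶ / callable bases
(exonic, nonsynonymous/stopgain, depth ≥ 40, VAF ≥ 0.03, population
AF ≤ 0.002); CNA burden = genes with copy-number gain or loss; MSI-H =
instability at ≥ 2 of 5 PCR microsatellite loci; DCB = CR/PR or SD ≥ 24
weeks.

**Stratification and inference.** Optimal survival cutpoints by
maximally selected rank statistics (standardized log-rank scan), TMB
cutpoint by the Youden index on DCB, joint HED×TMB groups
(both-high / single-high / both-low, strict `>` at the cutpoints),
Kaplan–Meier / log-rank / multivariable Cox models, Fisher and
chi-square DCB tests, Spearman correlations, per-gene driver mutation
comparisons, and immune-panel expression analysis (RPM + housekeeping
normalization, moderated differential expression, hypergeometric gene-set
over-representation).

## Worked example

The analysis is organized as numbered drivers under `analysis/`, each a
thin script over the package functions:

```sh
Rscript analysis/01_simulate_cohort.R   # write a synthetic input bundle
Rscript analysis/02_hed_profiles.R
Rscript analysis/03_tumor_features.R
Rscript analysis/04_stratification.R
Rscript analysis/05_survival.R
Rscript analysis/06_expression.R
```

Stage 4, on the default synthetic cohort (84 patients, 76 with tumor
profiling), prints:

```
maxstat HLA-B HED cutpoint: 8.84 (|Z| = 2.64 over 45 candidates)
Youden TMB cutpoint: 4.14 mut/Mb (J = 0.29)

   both_low single_high   both_high        <NA>
         34          33           9           8
DCB rate high vs low HLA-B HED: 52% vs 29% (chi2 p = 0.0426)
DCB both-high vs both-low: Fisher p = 0.000636
```

The cutpoint scan lands near the generator's HED-high threshold (8.61),
the durable-benefit rate is significantly higher in the HED-high group,
and the joint biomarker separates responders more sharply than either
marker alone. Stage 5 then shows the same structure in survival terms
(HED-high hazard ratio ≈ 0.31 for OS in the multivariable Cox model,
log-rank p = 0.008), and stage 6 finds the seeded differentially
expressed genes, all up-regulated in the HED-high group, with the
planted gene set at the top of the over-representation table.

Equivalent programmatic use:

```r
library(hedstrat)
cohort <- simulate_cohort(sim_config(seed = 1))
res <- run_hed_pipeline(cohort)
res$cutpoints$hed_cut          # maxstat cutpoint for HLA-B HED
res$survival$forest            # HR / CI / p table
head(res$expression$deg)       # per-gene DE results
```

`run_hed_pipeline()` also accepts a directory containing the plain-text
input bundle (FASTA + TSV/GMT tables; see `write_cohort_bundle()` for
the layout) and can write all result tables plus a JSON run report.

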