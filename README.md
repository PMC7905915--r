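# estroPRS

Case-control association and polygenic risk modelling for candidate
panels of estrogen-metabolism and GWAS-identified breast cancer
variants.

Breast cancer is estrogen-dependent: parent estrogens (E1, E2) drive
ER-mediated proliferation, and their catechol metabolites (2-/4-hydroxy
estrogens) are directly genotoxic. Functional polymorphisms in the
enzymes that control estrogen homeostasis (CYP1A1, CYP1B1, CYP19A1,
COMT, SULT1A1, UGT2B7, HSD17B1) are therefore natural candidate risk
variants alongside common GWAS loci. estroPRS implements the complete
analysis chain for a study of this design and asks the central
question: does adding enzyme-gene SNPs to a GWAS-SNP polygenic score
improve breast cancer risk discrimination?

The package provides:

- **QC** — Hardy–Weinberg goodness-of-fit chi-square and exact
  conditional tests on control genotypes, call rates (`hweChisq`,
  `hweExact`, `hweReport`);
- **association** — genotype-distribution chi-square tests, genotype
  and per-allele odds ratios with Woolf CIs and Haldane–Anscombe
  zero-cell handling, logistic cross-check (`associationTable`,
  `genotypeOR`, `perAlleleOR`, `perAlleleLogistic`);
- **polygenic risk scores** — PRS = Σ βk·xk with per-allele-OR (or
  log-OR) weights, within-gene LD pruning with the risk-variant
  substitution rule, scoring and evaluation by Student's t-test and
  ROC/AUC with DeLong CIs (`ldPrune`, `buildPRSModel`, `scoreCohort`,
  `compareScores`, `rocAUC`);
- **estrogen profiling** — per-analyte group tests, OPLS-DA with
  unit-variance scaling and 7-fold cross-validated Q², VIP biomarker
  selection (`compareAnalytes`, `oplsDA`, `vipScores`);
- **synthetic cohorts** — genotypes drawn under HWE at specified
  control MAFs and per-allele ORs, log-normal estrogen panels with
  group fold-changes (`simulateGenotypes`, `simulateEstrogens`);
- **data** — the published genotype count tables of a 15-SNP panel
  (140 cases / 140 controls) bundled as plain text (`bundledCounts`,
  `bundledPanel`), plus readers/writers for delimited genotype tables
  and biallelic VCF.

Cohorts are `SummarizedExperiment`-derived S4 objects
(`GenotypeCohort`, `EstrogenPanel`) holding minor-allele dosage or
concentration assays with case/control labels in `colData`.

## Worked example

Association analysis of the bundled count tables:

```r
library(estroPRS)
assoc <- associationTable(bundledCounts())
subset(assoc, dist_p < 0.05,
       c(rs_id, dist_p, het_or, het_ci_low, het_ci_high,
         allele_or, allele_p))
#>      rs_id  dist_p het_or het_ci_low het_ci_high allele_or allele_p
#>  rs1048943 0.00653   2.22      1.306       3.765     1.425 0.094006
#>  rs1056827 0.00434   1.20      0.729       1.968     1.611 0.023285
#>  rs1056836 0.00201   0.37      0.206       0.667     0.427 0.000717
#>  rs1042028 0.02666   2.21      1.204       4.051     1.971 0.009269
```

Four SNPs differ in genotype distribution between cases and controls
(p < 0.05): the SULT1A1 heterozygote carries a 2.21-fold (1.20–4.05)
odds of disease, the CYP1B1 rs1056836 heterozygote is protective
(OR 0.37), and the per-allele model puts the strongest minor-allele
effects at SULT1A1 (OR 1.97 per T allele) and CYP1B1 rs1056827
(OR 1.61 per A allele).

The full pipeline on a synthetic cohort drawn at the bundled study's
allele frequencies and effect sizes:

```r
res <- runPipeline(list(simulate = list(n_cases = 140, n_controls = 140),
                        simulate_estrogens = list(n_per_group = 49),
                        seed = 1),
                   out_dir = "run1")
#> simulated cohort: 140 cases / 140 controls, seed 1
#> HWE QC: 1 of 15 SNPs flagged at alpha = 0.05
#> association: 5 SNPs with genotype-distribution p < 0.05
#> PRS: built 2 model(s) under scheme 'or'
#> model M1: case 5.76 +/- 0.18 vs control 5.13 +/- 0.18, p = 0.0134, AUC = 59.6%
#> model M2: case 10.82 +/- 0.24 vs control 9.07 +/- 0.24, p = 6.6e-07, AUC = 65.8%
#> OPLS-DA: R2X = 0.253, R2Y = 0.563, Q2 = 0.416; VIP > 1: 2-OHE2, 4-OHE2, E2, E1, 2/4-OHE1
```

M2 (GWAS + enzyme SNPs, 13 variants) separates cases from controls far
more clearly than M1 (6 GWAS SNPs): a larger case–control score gap, a
t-test p-value five orders of magnitude smaller, and a higher AUC —
the package's reproduction of the study design's central claim. The
OPLS-DA stage recovers exactly the five analytes simulated with a
case fold-change (E1, E2, 2/4-OHE1, 2-OHE2, 4-OHE2) as VIP > 1
biomarkers. Artifacts (HWE report, association tables, model files,
scores, evaluation, estrogen reports, JSON run summary) are written to
`run1/`.

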