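---
title: "Methods: case-control association, polygenic scores and estrogen profiling with estroPRS"
author: "estroPRS authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-control association, polygenic scores and estrogen profiling with estroPRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estroPRS)
```

# The scientific problem

Breast cancer risk has a polygenic component, and estrogen exposure is a
major environmental driver: parent estrogens (E1, E2) stimulate
ER-mediated proliferation, while their catechol metabolites (2-/4-hydroxy
estrogens) form DNA adducts and are directly genotoxic. Estrogen
homeostasis is controlled by a small set of metabolizing enzymes (phase I
hydroxylation by CYP1A1/CYP1B1/CYP19A1, phase II conjugation by COMT,
SULT1A1, UGT2B7, and the reductive HSD17B1), so functional polymorphisms
in these genes are natural candidate risk variants alongside the common
GWAS-identified breast cancer loci.

estroPRS implements the full analysis chain for a candidate-panel
case-control study of this design:

1. **Hardy-Weinberg QC** of control genotypes,
2. **per-SNP association** (genotype-distribution tests, genotype and
   per-allele odds ratios),
3. **polygenic risk score (PRS)** construction, comparing a
   GWAS-SNP-only model (M1) against the same model augmented with
   estrogen-enzyme SNPs (M2),
4. **discrimination analysis** (t-test on scores, ROC/AUC), and
5. **serum estrogen profiling** (per-analyte tests, OPLS-DA, VIP
   biomarker selection).

The package bundles the published genotype count tables of a 15-SNP
panel measured in 140 breast cancer cases and 140 matched controls as a
worked reference dataset, and a synthetic-cohort generator so that the
stages requiring individual-level data can be exercised and calibrated.

# Data containers

`GenotypeCohort` and `EstrogenPanel` extend `SummarizedExperiment`:
rows are SNPs (with panel metadata: rs ID, gene, major/minor allele,
category) or analytes, columns are subjects, and `colData(x)$group`
holds the case/control label. Genotypes are stored as **minor-allele
dosages** 0/1/2 (or `NA` for a missing call). The minor allele is fixed
per panel from control-group frequencies, not re-estimated per dataset,
so dosage coding is stable across cohorts; genotype strings are treated
as unordered pairs ("GA" = "AG") because capillary genotyping assays
carry no phase. Missing calls use a configurable token (default `"NA"`)
and are excluded pairwise per SNP.

# Hardy-Weinberg QC

`hweChisq()` is the classical goodness-of-fit test: with observed
minor-allele frequency $q$, expected genotype counts are
$n(1-q)^2, 2nq(1-q), nq^2$ and the statistic is referred to
$\chi^2_1$, without a continuity correction — the standard convention
for biallelic HWE testing. `hweExact()` is the exact conditional test:
given the observed allele counts, the p-value sums the probabilities of
all heterozygote configurations no more probable than the observed one.
Both are reported side by side by `hweReport()` because the chi-square
is anti-conservative at small expected minor-homozygote counts; SNPs
failing HWE in controls at $\alpha = 0.05$ are flagged, never
auto-dropped (a departure signals genotyping error, but the decision to
exclude belongs to the analyst). A monomorphic sample fits HWE
trivially ($\chi^2 = 0$, $p = 1$) rather than erroring, so batch
reports never abort on fixed markers.

On the bundled control counts the package's HWE p-values do not match
the values printed alongside the original panel metadata (e.g. COMT:
printed 1.000, chi-square 0.460, exact 0.433); the computation behind
the printed values is unstated, so the package reports its own values
and does not force agreement.

# Association statistics

Odds ratios are cross-product ratios with the Woolf confidence
interval,
$$\exp\left(\log\tfrac{ad}{bc} \pm z_{1-\alpha/2}
\sqrt{\tfrac1a+\tfrac1b+\tfrac1c+\tfrac1d}\right),$$
and a Wald p-value on the log scale. This closed form was chosen over
an iterative logistic fit because it reproduces the published genotype
ORs exactly (e.g. SULT1A1 CT vs CC: 2.21, 1.20–4.05) and a univariate
logistic fit on the collapsed 2×2 table gives the numerically identical
estimate; `perAlleleLogistic()` provides the individual-level logistic
fit as a cross-check. When any cell is zero, all four cells receive the
Haldane–Anscombe +0.5 and the result is flagged — deterministic and
conventional. The per-allele model collapses genotypes to allele counts
(minor alleles = 2×minor-hom + het) before forming the 2×2 table; the
effect allele is always the control-group minor allele, which
reproduces the published per-allele ORs including rows whose printed
risk/reference labels are inverted. Genotype-distribution tests are
Pearson chi-square on the 2×3 table (2×2 when a genotype class is
absent from both groups). P-values are reported raw, matching the
original single-panel analysis; Bonferroni columns are available behind
a flag.

Known non-reproducible printed values (documented, not asserted): the
CYP1A1 rs1048943 genotype ORs (printed 2.37/1.10 vs computed
2.22/0.69), the zero-cell CYP1B1 rs1056827 homozygote OR (printed 6.90;
Haldane-corrected cross-product 24.13), the MAP3K1 per-allele OR
(printed 1.00 vs computed 1.24), and the HCN1 row, whose values match
no reference orientation.

# The synthetic cohort generator

`simulateGenotypes()` draws control genotypes per SNP from HWE
proportions at the control MAF $p_0$ and case genotypes from HWE at
$$p_1 = \frac{\mathrm{OR}\,p_0}{1 + p_0(\mathrm{OR}-1)},$$
the frequency whose allele-scale odds are OR times the control odds.
This allele-based scheme (rather than a logistic liability model) is
the exact generative dual of the per-allele estimator, so parameter
recovery is a clean oracle: the allele-count cross-product OR is a
consistent estimator of the generating `per_allele_or` (recovered
within 2% at n = 20 000/group in the acceptance suite). SNPs are
independent — the modelling stage prunes linkage disequilibrium before
scoring and treats SNPs as independent contributors, so simulating LD
would add nothing the pipeline consumes. The default specification
table (`defaultSNPSimSpec()`) is derived at run time from the bundled
counts, so synthetic cohorts mirror the reference study's allele
structure.

`simulateEstrogens()` draws log-normal concentrations (control median,
log-scale SD, case fold-change per analyte). Defaults
(`defaultEstrogenSimSpec()`): typical premenopausal serum medians in
pg/mL, log-SD 0.5 (≈50% coefficient of variation, the usual spread of
serum steroid panels), fold-change 1.8 for E1, E2, 2-OHE2 and 4-OHE2,
1.5 for 2/4-OHE1, and 1.0 elsewhere — the qualitative case-control
disturbance reported for breast cancer serum. The published figure
legend names ten analytes while the text counts eleven; the package
takes the eleventh as E3 (estriol, the 16α-hydroxylation product of
E2), the natural remaining member of such LC-MS/MS panels. The
generator uses a single `n_per_group` for both groups and ignores
menstrual-phase structure (the reference study pooled follicular and
luteal samples without stating how); it emulates marginal log-normal
levels and a pure location shift, not between-analyte correlation, so
passing tests demonstrate correctness of the statistical machinery, not
distributional realism of real serum panels.

Both generators are bit-reproducible under a fixed seed.

# Polygenic risk scores

The score is the weighted dosage sum
$$\mathrm{PRS} = \sum_k \beta_k x_k,$$
with $x_k \in \{0,1,2\}$ the minor-allele count. Following the
reference study's definition, the default weight is the per-allele OR
itself (scheme `"or"`); the conventional log-OR weighting is available
as scheme `"log_or"`. Both are offered because the study's printed
group means could not be reconstructed from its own tables under either
scheme, so neither can claim exact fidelity; the package treats the
choice as a documented flag. Under `"or"` weights all scores are
non-negative and adding one risk allele at SNP k increases the score by
exactly $\beta_k$.

`ldPrune()` implements the panel's pruning rule: within a gene, keep
the variant with the lowest per-allele p-value; if that winner is
protective (OR < 1) and a risk variant exists in the same gene,
substitute the risk variant — on the bundled panel this keeps rs1048943
(CYP1A1) and swaps rs1056836 for rs1056827 (CYP1B1), giving the 13-SNP
M2 panel. M1 is the 6 GWAS SNPs; M2 adds the 7 enzyme SNPs.

Weights are estimated in-sample by default, as in the reference
analysis; `scoreCohort()` also accepts externally built models
(`readPRSModel()`) for train/test designs. A subject missing a call at
any model SNP is excluded with a message rather than imputed. Scores
are raw sums, not standardized.

# Evaluation

`compareScores()` reports group means ± SEM, per-group Shapiro–Wilk
p-values (reported, not gating), and Student's equal-variance t-test —
the classical form, matching an analysis that explicitly checks
normality first; Welch is a flag. `rocAUC()` builds the empirical ROC
with the convention higher score ⇒ predicted case, ties counted 0.5, so
the AUC equals the normalized Mann–Whitney U statistic; the 95% CI is
DeLong's (deterministic, unlike a bootstrap). AUC is invariant under
strictly monotone score transforms, so the `"or"` vs `"log_or"` choice
changes AUC only when it re-ranks subjects.

The study's printed PRS means, t-test p-value and AUCs (62.18% M2 vs
54.56% M1) require the unavailable individual-level genotypes, so the
package tests the directional claim instead: on synthetic cohorts at
the bundled MAFs/ORs (n = 140/140), mean AUC(M2) exceeds mean AUC(M1)
and case scores exceed control scores under M2 across 100 seeds. With
seed 1 the acceptance run measures mean AUCs of ≈56% (M1) and ≈65%
(M2), bracketing the published values.

# Estrogen profiling: OPLS-DA and VIP

`compareAnalytes()` applies Student's t-test per analyte on raw
concentrations (the reference analysis reports raw means ± SEM;
Welch and log-scale analyses are trivial variations the user can apply
to transformed panels).

`oplsDA()` implements orthogonal projections to latent structures
discriminant analysis for a single two-level response: the analyte
matrix is mean-centred and unit-variance scaled (the de-facto default
for discriminant metabolomics; the reference software's setting is
unstated), the class is coded ±1 and centred, and class-orthogonal
variation is removed component by component (weight
$w \propto X^\top y$; orthogonal weight = component loading minus its
projection on $w$) before one predictive PLS component is fitted on the
filtered matrix. With zero orthogonal components the fit reduces
exactly to single-component PLS-DA, which is the equivalence oracle
used in the tests. $R^2X$ counts predictive plus orthogonal captured
variance; $R^2Y$ is the class variance explained by the predictive
component; $Q^2$ comes from 7-fold cross-validation with
contiguous-block folds after a seeded shuffle (the convention of the
commercial software used in this field; the seed is exposed and the
global RNG state is restored). Degenerate inputs fail loudly:
zero-variance analytes are an error (rank deficiency), and fewer than
three subjects per group is refused.

VIP is the total-component variant:
$$\mathrm{VIP}_j = \sqrt{p\,\frac{\sum_a \mathrm{SSY}_a w_{ja}^2}
{\sum_a \mathrm{SSY}_a}},$$
summing predictive and orthogonal components weighted by the class
variance each explains; because every weight vector has unit norm, the
squared VIPs always average to 1 (asserted to 1e-8 on every fit).
Analytes with VIP > 1.0 are flagged as candidate biomarkers;
a predictive-only VIP is available behind a flag. The published
$R^2X/R^2Y/Q^2$ and VIP values cannot be reproduced without the raw
serum data and are not asserted; the tests instead check the
qualitative outcome (the five analytes given a fold-change are the ones
selected in the majority of seeds) and the permutation property
(mean $Q^2 \le 0$ under shuffled labels).

# The pipeline

`runPipeline()` chains the stages with a single config (list or
JSON/YAML file) and writes delimited-text artifacts plus a JSON run
summary that enumerates every flag in effect (weight scheme, t-test
form, CI method, scaling), so results are auditable. Exactly one cohort
source is allowed per run; counts-only input runs QC and association
and skips scoring with an explanatory log line — the pipeline makes the
dependency on individual-level data explicit rather than fabricating
subjects from counts. Identical config and seed give byte-identical
artifacts (log lines deliberately carry no wall-clock time). Stage
failures abort with a stage-named diagnostic and retain earlier
artifacts.

# Numerical choices and problem sizes

- Woolf CI z-quantile from `qnorm`, no rounding until report writers
  (2 decimals for ORs/CIs, 3 for p-values, matching conventional
  reporting).
- Exact-HWE ties: configurations with probability within 1e-12 of the
  observed one count as "no more probable".
- The test and acceptance suites use: 20 000/group cohorts for
  parameter recovery (10–20 seeds), 2 000 replicates for type-I
  calibration, 100 seeds of 140/140 cohorts for the M1/M2 directional
  claim, 200 score sets for the AUC oracle, 200 permutations for the
  $Q^2$ property, and full enumeration of all genotype configurations
  with n ≤ 10 for the exact-HWE oracle — sizes chosen so each property
  is measured well inside its Monte-Carlo error at interactive
  runtimes.

# Known limitations

- No covariate adjustment (age, BMI), no dominant/recessive collapsed
  models, no trend test, no imputation, phasing or strand-flip
  resolution, no LD/haplotype simulation.
- In-sample weighting overstates discrimination relative to external
  validation; the package supports external weights but the bundled
  workflow mirrors the single-cohort design.
- The synthetic generators emulate the marginal structure the
  estimators assume; conclusions about real data still require real
  data.
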