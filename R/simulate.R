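#' @include association.R
NULL

#' Default SNP simulation specifications
#'
#' One row per panel SNP: the control minor-allele frequency computed
#' from the bundled control genotype counts and the per-allele odds
#' ratio computed from the bundled count tables by [perAlleleOR()].
#' Synthetic cohorts drawn at these parameters mirror the bundled
#' study's allele-frequency structure.
#'
#' @return data.frame with columns `rs_id`, `control_maf`,
#'   `per_allele_or`.
#' @export
#' @examples
#' defaultSNPSimSpec()
defaultSNPSimSpec <- function() {
  tabs <- bundledCounts()
  rows <- lapply(names(tabs), function(id) {
    ctrl <- tabs[[id]][, "control"]
    data.frame(rs_id = id,
               control_maf = (2 * ctrl[[3]] + ctrl[[2]]) /
                 (2 * sum(ctrl)),
               per_allele_or = perAlleleOR(tabs[[id]])$or,
               row.names = NULL)
  })
  do.call(rbind, rows)
}

## case minor-allele frequency implied by a per-allele odds ratio:
## odds_case = OR * odds_control on the allele scale
.caseMAF <- function(p0, or) or * p0 / (1 + p0 * (or - 1))

#' Simulate a case-control genotype cohort
#'
#' Control genotypes are drawn per SNP from Hardy-Weinberg proportions
#' at the control minor-allele frequency `p0`; case genotypes from
#' Hardy-Weinberg proportions at the shifted frequency
#' `p1 = OR * p0 / (1 + p0 * (OR - 1))`, the allele frequency whose
#' allele-scale odds are `OR` times the control odds. This makes the
#' allele-counting per-allele OR a consistent estimator of the
#' generating `per_allele_or`. SNPs are drawn independently (no linkage
#' disequilibrium).
#'
#' @param specs data.frame with columns `rs_id`, `control_maf` in
#'   (0, 0.5\], `per_allele_or` > 0 (see [defaultSNPSimSpec()]).
#' @param n_cases,n_controls group sizes (>= 1).
#' @param seed integer seed; identical seed and spec give an identical
#'   cohort.
#' @param panel optional SNP metadata to attach; defaults to the rows of
#'   [bundledPanel()] matching `specs$rs_id`, with placeholder A/B
#'   alleles for rs IDs outside the bundled panel.
#' @return A [GenotypeCohort-class] with controls first.
#' @export
#' @examples
#' coh <- simulateGenotypes(defaultSNPSimSpec(), 140, 140, seed = 1)
#' coh
simulateGenotypes <- function(specs, n_cases, n_controls, seed,
                              panel = NULL) {
  specs <- as.data.frame(specs)
  stopifnot(all(c("rs_id", "control_maf", "per_allele_or") %in%
                  colnames(specs)))
  if (n_cases < 1 || n_controls < 1)
    stop("n_cases and n_controls must be >= 1")
  if (any(specs$control_maf <= 0 | specs$control_maf > 0.5))
    stop("control_maf must be in (0, 0.5]")
  if (any(specs$per_allele_or <= 0))
    stop("per_allele_or must be positive")
  if (is.null(panel)) {
    ref <- bundledPanel()
    idx <- match(specs$rs_id, ref$rs_id)
    panel <- data.frame(rs_id = specs$rs_id,
                        gene = NA_character_,
                        major_allele = "A", minor_allele = "B",
                        category = NA_character_)
    hit <- !is.na(idx)
    panel[hit, c("gene", "major_allele", "minor_allele", "category")] <-
      ref[idx[hit], c("gene", "major_allele", "minor_allele",
                      "category")]
  }
  set.seed(seed)
  p1 <- .caseMAF(specs$control_maf, specs$per_allele_or)
  nsnp <- nrow(specs)
  # HWE genotype draw == binomial(2, p) on the minor-allele count
  ctrl <- vapply(seq_len(nsnp), function(i)
    stats::rbinom(n_controls, 2L, specs$control_maf[i]),
    integer(n_controls))
  case <- vapply(seq_len(nsnp), function(i)
    stats::rbinom(n_cases, 2L, p1[i]), integer(n_cases))
  d <- cbind(t(matrix(ctrl, ncol = nsnp)), t(matrix(case, ncol = nsnp)))
  rownames(d) <- specs$rs_id
  GenotypeCohort(d,
                 group = rep(c("control", "case"),
                             c(n_controls, n_cases)),
                 panel = panel,
                 subject_ids = c(sprintf("ctrl%04d", seq_len(n_controls)),
                                 sprintf("case%04d", seq_len(n_cases))))
}

#' Default estrogen panel simulation specification
#'
#' Log-normal concentration parameters for the 11 serum analytes of
#' [estrogenAnalytes()]. Control medians are typical premenopausal serum
#' levels (pg/mL); the log-scale SD of 0.5 corresponds to a coefficient
#' of variation of roughly 50%, the usual spread of serum steroid
#' panels. Case/control fold-changes elevate the parent estrogens (E1,
#' E2) and the genotoxic catechol metabolites (2-OHE2, 4-OHE2) by 1.8x
#' and 2/4-OHE1 by 1.5x, the qualitative disturbance of estrogen
#' homeostasis reported in breast cancer serum; the remaining analytes
#' are unchanged.
#'
#' @return data.frame with columns `analyte`, `control_median`,
#'   `sdlog`, `fold_change`.
#' @export
defaultEstrogenSimSpec <- function() {
  analytes <- estrogenAnalytes()
  med <- c(E1 = 80, E2 = 100, E3 = 12, `16a-OHE1` = 15,
           `2/4-OHE1` = 50, `2-OHE2` = 20, `4-OHE2` = 10,
           `2-MeOE1` = 8, `4-MeOE1` = 5, `2-MeOE2` = 6, `4-MeOE2` = 4)
  fc <- c(E1 = 1.8, E2 = 1.8, E3 = 1.0, `16a-OHE1` = 1.0,
          `2/4-OHE1` = 1.5, `2-OHE2` = 1.8, `4-OHE2` = 1.8,
          `2-MeOE1` = 1.0, `4-MeOE1` = 1.0, `2-MeOE2` = 1.0,
          `4-MeOE2` = 1.0)
  data.frame(analyte = analytes,
             control_median = unname(med[analytes]),
             sdlog = 0.5,
             fold_change = unname(fc[analytes]),
             row.names = NULL)
}

#' Simulate a case-control serum estrogen panel
#'
#' Concentrations are log-normal: controls with median
#' `control_median` and log-scale SD `sdlog`; cases identical except
#' the median is multiplied by `fold_change`.
#'
#' @param spec data.frame with columns `analyte`, `control_median` (> 0,
#'   pg/mL), `sdlog` (> 0), `fold_change` (> 0); see
#'   [defaultEstrogenSimSpec()].
#' @param n_per_group subjects per group (>= 2).
#' @param seed integer seed.
#' @return An [EstrogenPanel-class] with controls first.
#' @export
#' @examples
#' simulateEstrogens(defaultEstrogenSimSpec(), 50, seed = 1)
simulateEstrogens <- function(spec, n_per_group, seed) {
  spec <- as.data.frame(spec)
  stopifnot(all(c("analyte", "control_median", "sdlog",
                  "fold_change") %in% colnames(spec)))
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  if (any(spec$control_median <= 0) || any(spec$sdlog <= 0) ||
      any(spec$fold_change <= 0))
    stop("medians, sdlog and fold_change must be positive")
  set.seed(seed)
  n <- n_per_group
  conc <- vapply(seq_len(nrow(spec)), function(i) {
    mu <- log(spec$control_median[i])
    c(stats::rlnorm(n, mu, spec$sdlog[i]),
      stats::rlnorm(n, mu + log(spec$fold_change[i]), spec$sdlog[i]))
  }, numeric(2 * n))
  conc <- t(conc)
  rownames(conc) <- spec$analyte
  EstrogenPanel(conc,
                group = rep(c("control", "case"), each = n),
                subject_ids = c(sprintf("ctrl%04d", seq_len(n)),
                                sprintf("case%04d", seq_len(n))))
}
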