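#' @include cohort-io.R
NULL

#' Odds ratio with Woolf confidence interval from a 2x2 table
#'
#' Cross-product odds ratio `(a*d)/(b*c)` with the Woolf (log-scale
#' asymptotic) confidence interval
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` and a Wald p-value
#' on the log scale. When any cell is zero, 0.5 is added to all four
#' cells (Haldane-Anscombe) and `correction_applied` is set.
#'
#' @param a exposed-genotype cases.
#' @param b reference-genotype cases.
#' @param c exposed-genotype controls.
#' @param d reference-genotype controls.
#' @param conf_level confidence level (default 0.95).
#' @param comparison label describing the contrast.
#' @return one-row data.frame: `comparison`, `or`, `ci_low`, `ci_high`,
#'   `p_value`, `correction_applied`.
#' @export
#' @examples
#' genotypeOR(37, 98, 20, 117)   # OR 2.21 (1.20-4.05)
genotypeOR <- function(a, b, c, d, conf_level = 0.95,
                       comparison = "exposed vs reference") {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stop("cell counts must be non-negative")
  if ((a + b == 0) || (c + d == 0) || (a + c == 0) || (b + d == 0))
    stop("a margin of the 2x2 table is entirely zero; OR undefined")
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- (cells["a"] * cells["d"]) / (cells["b"] * cells["c"])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  wald <- log(or) / se
  data.frame(comparison = comparison,
             or = unname(or),
             ci_low = unname(exp(log(or) - z * se)),
             ci_high = unname(exp(log(or) + z * se)),
             p_value = 2 * stats::pnorm(-abs(unname(wald))),
             correction_applied = corrected,
             row.names = NULL)
}

#' Chi-square test of genotype distribution between groups
#'
#' Pearson chi-square (no continuity correction) on the 2x3 group-by-
#' genotype contingency table; a genotype class absent from both groups
#' is dropped first, reducing the degrees of freedom to 1.
#'
#' @param table a [genotypeCountTable()].
#' @return list with `chi_square`, `df`, `p_value`.
#' @export
#' @examples
#' genotypeDistributionTest(
#'   genotypeCountTable(c(100, 31, 9), c(80, 55, 5)))  # p = 0.007
genotypeDistributionTest <- function(table) {
  stopifnot(nrow(table) == 3, ncol(table) == 2)
  if (any(colSums(table) == 0))
    stop("each group needs at least one subject")
  m <- table[rowSums(table) > 0, , drop = FALSE]
  if (nrow(m) < 2)
    stop("degenerate table: a single genotype class present")
  res <- suppressWarnings(stats::chisq.test(t(m), correct = FALSE))
  list(chi_square = unname(res$statistic),
       df = unname(res$parameter),
       p_value = res$p.value)
}

#' Per-allele (allele-counting) odds ratio
#'
#' Collapses a genotype count table to per-group allele counts (minor
#' alleles = 2 x minor-hom + het) and returns the odds ratio for the
#' minor allele with the Woolf interval, the classical per-allele model
#' of case-control SNP association. A univariate logistic fit on the
#' collapsed table gives the numerically identical estimate; see
#' [perAlleleLogistic()] for the individual-level fit.
#'
#' @inheritParams genotypeDistributionTest
#' @param conf_level confidence level.
#' @return one-row data.frame as in [genotypeOR()].
#' @export
#' @examples
#' perAlleleOR(bundledCounts()[["rs1042028"]])  # OR 1.97 (1.18-3.29)
perAlleleOR <- function(table, conf_level = 0.95) {
  stopifnot(nrow(table) == 3, ncol(table) == 2)
  if (any(colSums(table) == 0))
    stop("each group needs at least one subject")
  minor <- 2 * table["minor_hom", ] + table["het", ]
  major <- 2 * table["major_hom", ] + table["het", ]
  genotypeOR(a = minor[["case"]], b = major[["case"]],
             c = minor[["control"]], d = major[["control"]],
             conf_level = conf_level,
             comparison = "minor vs major allele")
}

#' Per-allele odds ratio by logistic regression
#'
#' Univariate logistic regression of case status on the minor-allele
#' dosage (0/1/2); the per-allele OR is `exp(slope)` with a Wald
#' confidence interval. Cross-checks the allele-counting estimator of
#' [perAlleleOR()] on individual-level data.
#'
#' @param cohort a [GenotypeCohort-class] containing both groups.
#' @param rs_id SNP identifier in the cohort's panel.
#' @param conf_level confidence level.
#' @return one-row data.frame as in [genotypeOR()].
#' @export
perAlleleLogistic <- function(cohort, rs_id, conf_level = 0.95) {
  d <- dosage(cohort)
  if (!rs_id %in% rownames(d))
    stop("unknown rs_id: ", rs_id)
  x <- d[rs_id, ]
  y <- as.integer(groupLabels(cohort) == "case")
  keep <- !is.na(x)
  x <- x[keep]; y <- y[keep]
  if (length(unique(y)) < 2)
    stop("cohort must contain both cases and controls")
  if (length(unique(x)) < 2)
    stop("SNP ", rs_id, " is monomorphic; per-allele OR undefined")
  fit <- stats::glm(y ~ x, family = stats::binomial())
  co <- summary(fit)$coefficients
  beta <- co["x", "Estimate"]; se <- co["x", "Std. Error"]
  if (abs(beta) > 20 || se > 1e2)
    stop("complete separation: logistic per-allele OR unstable for ",
         rs_id)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(comparison = "minor vs major allele (logistic)",
             or = exp(beta),
             ci_low = exp(beta - z * se),
             ci_high = exp(beta + z * se),
             p_value = co["x", "Pr(>|z|)"],
             correction_applied = FALSE,
             row.names = NULL)
}

#' Full association table for a panel of SNPs
#'
#' For each genotype count table: the genotype-distribution chi-square
#' test, heterozygote and minor-homozygote odds ratios against the
#' major-homozygote reference, and the per-allele odds ratio. A SNP
#' whose tests fail (degenerate counts) is reported with `NA` statistics
#' rather than aborting the batch.
#'
#' @param tables named list of [genotypeCountTable()]s, e.g.
#'   [bundledCounts()].
#' @param conf_level confidence level for all intervals.
#' @param bonferroni if `TRUE`, add Bonferroni-adjusted columns for the
#'   distribution and per-allele p-values.
#' @return data.frame with one row per SNP, in input order.
#' @export
#' @examples
#' assoc <- associationTable(bundledCounts())
#' assoc[assoc$dist_p < 0.05, c("rs_id", "dist_p", "allele_or")]
associationTable <- function(tables, conf_level = 0.95,
                             bonferroni = FALSE) {
  blank <- function() data.frame(
    comparison = NA_character_, or = NA_real_, ci_low = NA_real_,
    ci_high = NA_real_, p_value = NA_real_, correction_applied = NA)
  rows <- lapply(seq_along(tables), function(i) {
    tab <- tables[[i]]
    id <- names(tables)[i]
    if (is.null(id)) id <- attr(tab, "rs_id")
    dist <- tryCatch(genotypeDistributionTest(tab),
                     error = function(e)
                       list(chi_square = NA_real_, df = NA_integer_,
                            p_value = NA_real_))
    het <- tryCatch(
      genotypeOR(tab["het", "case"], tab["major_hom", "case"],
                 tab["het", "control"], tab["major_hom", "control"],
                 conf_level, "het vs major-hom"),
      error = function(e) blank())
    hom <- tryCatch(
      genotypeOR(tab["minor_hom", "case"], tab["major_hom", "case"],
                 tab["minor_hom", "control"], tab["major_hom", "control"],
                 conf_level, "minor-hom vs major-hom"),
      error = function(e) blank())
    allele <- tryCatch(perAlleleOR(tab, conf_level),
                       error = function(e) blank())
    data.frame(rs_id = id,
               dist_chi_square = dist$chi_square,
               dist_df = dist$df,
               dist_p = dist$p_value,
               het_or = het$or, het_ci_low = het$ci_low,
               het_ci_high = het$ci_high, het_p = het$p_value,
               hom_or = hom$or, hom_ci_low = hom$ci_low,
               hom_ci_high = hom$ci_high, hom_p = hom$p_value,
               hom_corrected = hom$correction_applied,
               allele_or = allele$or,
               allele_ci_low = allele$ci_low,
               allele_ci_high = allele$ci_high,
               allele_p = allele$p_value,
               row.names = NULL)
  })
  if (!length(rows)) return(data.frame())
  out <- do.call(rbind, rows)
  if (bonferroni && nrow(out)) {
    out$dist_p_bonf <- stats::p.adjust(out$dist_p, "bonferroni")
    out$allele_p_bonf <- stats::p.adjust(out$allele_p, "bonferroni")
  }
  out
}

#' Write an association report as delimited text
#'
#' Emits the association table with ORs and interval bounds rounded to
#' 2 decimals and p-values to 3, the conventional reporting format for
#' case-control genotype tables.
#'
#' @param assoc output of [associationTable()].
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
writeAssociationReport <- function(assoc, path, sep = "\t") {
  out <- assoc
  orc <- grep("_or$|_ci_", colnames(out))
  pc <- grep("_p$|_chi_square$", colnames(out))
  out[orc] <- lapply(out[orc], round, 2)
  out[pc] <- lapply(out[pc], round, 3)
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
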