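#' @include cohort-io.R
NULL

#' Hardy-Weinberg goodness-of-fit chi-square test
#'
#' Compares observed genotype counts to the counts expected under
#' Hardy-Weinberg equilibrium at the observed allele frequencies, using
#' the classical goodness-of-fit chi-square with 1 degree of freedom and
#' no continuity correction. A monomorphic sample fits HWE trivially and
#' returns chi-square 0, p 1.
#'
#' @param counts integer vector of length 3: (major-hom, het, minor-hom)
#'   genotype counts, typically the control column of a
#'   [genotypeCountTable()].
#' @return list with `chi_square`, `df` (1), `p_chisq`, `observed_het`,
#'   `expected_het`, and the minor-allele frequency `maf`.
#' @seealso [hweExact()] for the exact conditional alternative.
#' @export
#' @examples
#' hweChisq(c(91, 42, 7))   # chi-square 0.547, p 0.460
hweChisq <- function(counts) {
  counts <- as.integer(counts)
  stopifnot(length(counts) == 3, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("all genotype counts are zero")
  q <- (2 * counts[3] + counts[2]) / (2 * n)    # minor-allele frequency
  if (q == 0 || q == 1) {
    return(list(chi_square = 0, df = 1L, p_chisq = 1,
                observed_het = counts[2], expected_het = 0, maf = q))
  }
  expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  chi <- sum((counts - expected)^2 / expected)
  list(chi_square = chi, df = 1L,
       p_chisq = stats::pchisq(chi, df = 1, lower.tail = FALSE),
       observed_het = counts[2], expected_het = expected[2], maf = q)
}

## log choose(n, k) via lgamma, vectorised
.lchoose <- function(n, k) lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1)

#' Exact test of Hardy-Weinberg equilibrium
#'
#' The exact conditional test: conditional on the observed allele
#' counts, the probability of each compatible heterozygote count is
#' computed, and the p-value sums the probabilities of all configurations
#' no more probable than the one observed. Preferred over the chi-square
#' when expected minor-homozygote counts are small.
#'
#' @inheritParams hweChisq
#' @return the exact p-value in \[0, 1\].
#' @export
#' @examples
#' hweExact(c(91, 42, 7))
hweExact <- function(counts) {
  counts <- as.integer(counts)
  stopifnot(length(counts) == 3, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("all genotype counts are zero")
  n_minor <- 2 * counts[3] + counts[2]
  n_major <- 2 * counts[1] + counts[2]
  rare <- min(n_minor, n_major)
  if (rare == 0) return(1)
  # heterozygote counts sharing the observed allele counts have the
  # parity of the rare-allele count
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- .lchoose(n, (rare - hets) / 2) +
    .lchoose(n - (rare - hets) / 2, hets) +
    hets * log(2) - .lchoose(2 * n, rare)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(counts[2], hets)]
  min(1, sum(p[p <= obs + 1e-12]))
}

#' Per-SNP call rate
#'
#' @param cohort a [GenotypeCohort-class].
#' @param rs_id SNP identifier in the cohort's panel.
#' @return the non-missing fraction of calls, in \[0, 1\].
#' @export
callRate <- function(cohort, rs_id) {
  d <- dosage(cohort)
  if (!rs_id %in% rownames(d))
    stop("unknown rs_id: ", rs_id)
  mean(!is.na(d[rs_id, ]))
}

#' Hardy-Weinberg QC report for a panel of count tables
#'
#' Runs [hweChisq()] and [hweExact()] on the control genotype counts of
#' each SNP and flags (never drops) SNPs departing from HWE at `alpha`.
#' HWE is tested in controls only: a departure there signals genotyping
#' error, whereas case genotypes are expected to deviate under a true
#' association.
#'
#' @param tables list of [genotypeCountTable()]s (e.g. [bundledCounts()])
#'   or a [GenotypeCohort-class], which is aggregated first.
#' @param alpha flagging level for the chi-square p-value (default 0.05).
#' @return data.frame with one row per SNP: control counts, `maf`,
#'   `chi_square`, `p_chisq`, `p_exact`, `call_rate` (NA for count-table
#'   input), `hwe_flag`.
#' @export
#' @examples
#' head(hweReport(bundledCounts()))
hweReport <- function(tables, alpha = 0.05) {
  cr <- NULL
  if (is(tables, "GenotypeCohort")) {
    cohort <- tables
    ids <- rownames(dosage(cohort))
    cr <- vapply(ids, callRate, numeric(1), cohort = cohort)
    tables <- lapply(ids, countsFromCohort, cohort = cohort)
    names(tables) <- ids
  }
  rows <- lapply(names(tables), function(id) {
    ctrl <- tables[[id]][, "control"]
    h <- hweChisq(ctrl)
    data.frame(rs_id = id,
               control_major_hom = ctrl[[1]],
               control_het = ctrl[[2]],
               control_minor_hom = ctrl[[3]],
               maf = h$maf,
               chi_square = h$chi_square,
               p_chisq = h$p_chisq,
               p_exact = hweExact(ctrl),
               call_rate = if (is.null(cr)) NA_real_ else cr[[id]],
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$hwe_flag <- out$p_chisq < alpha
  out
}
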