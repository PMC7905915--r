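#' @include AllClasses.R
NULL

#' Bundled 15-SNP estrogen-metabolism panel metadata
#'
#' The candidate-gene panel genotyped in the bundled breast cancer
#' case-control study: 9 SNPs in estrogen-metabolizing enzyme genes
#' (CYP19A1, CYP1A1, CYP1B1, HSD17B1, COMT, SULT1A1, UGT2B7) and 6
#' GWAS-identified breast cancer risk SNPs (ZNF365, FGFR2, RAD51B, TOX3,
#' MAP3K1, HCN1). The major/minor orientation is fixed from the control
#' genotype frequencies of the bundled counts, so dosage coding is stable
#' across cohorts. Known label discrepancies in the published tables
#' (alias rs numbers, the HCN1 allele labels, the TOX3/CASC16 gene name)
#' are recorded in the `note` and `gene_alias` columns.
#'
#' @return data.frame with columns `rs_id`, `gene`, `gene_alias`,
#'   `chromosome_position`, `domain`, `major_allele`, `minor_allele`,
#'   `category` (`"enzyme"` or `"gwas"`), `metabolized_species`, `note`.
#' @export
#' @examples
#' table(bundledPanel()$category)
bundledPanel <- function() {
  path <- system.file("extdata", "snp_panel.tsv", package = "estroPRS",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Construct a genotype count table for one SNP
#'
#' The elementary case-control summary consumed by the association
#' stage: genotype counts (major-homozygote, heterozygote,
#' minor-homozygote) per group.
#'
#' @param control,case integer vectors of length 3, counts ordered
#'   (major-hom, het, minor-hom).
#' @param rs_id SNP identifier attached as an attribute.
#' @return 3x2 integer matrix with rownames `major_hom`, `het`,
#'   `minor_hom` and colnames `control`, `case`.
#' @export
#' @examples
#' genotypeCountTable(c(117, 20, 3), c(98, 37, 5), "rs1042028")
genotypeCountTable <- function(control, case, rs_id = NA_character_) {
  stopifnot(length(control) == 3, length(case) == 3)
  if (any(control < 0) || any(case < 0))
    stop("genotype counts must be non-negative")
  m <- cbind(control = as.integer(control), case = as.integer(case))
  rownames(m) <- c("major_hom", "het", "minor_hom")
  attr(m, "rs_id") <- rs_id
  m
}

#' Bundled genotype count tables (140 cases / 140 controls)
#'
#' The published per-SNP genotype counts for the 15-SNP panel of
#' [bundledPanel()], from a case-control study of 140 premenopausal
#' breast cancer patients and 140 matched healthy women. Counts are
#' stored by dosage class (major-homozygote, heterozygote,
#' minor-homozygote) using the panel's allele orientation; every column
#' sums to 140.
#'
#' @return Named list of 15 count tables (see [genotypeCountTable()]),
#'   in panel order.
#' @export
#' @examples
#' bundledCounts()[["rs1042028"]]
bundledCounts <- function() {
  path <- system.file("extdata", "genotype_counts.tsv",
                      package = "estroPRS", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    genotypeCountTable(
      control = unlist(tab[i, c("control_major_hom", "control_het",
                                "control_minor_hom")]),
      case = unlist(tab[i, c("case_major_hom", "case_het",
                             "case_minor_hom")]),
      rs_id = tab$rs_id[i])
  })
  names(out) <- tab$rs_id
  out
}

## recode one column of two-allele genotype strings ("GA", "AG", "NA")
## to minor-allele counts; unknown allele characters are an error.
.recodeCalls <- function(calls, major, minor, rs_id, missing_code = "NA") {
  out <- rep(NA_integer_, length(calls))
  live <- !(is.na(calls) | calls == missing_code)
  cc <- calls[live]
  if (any(nchar(cc) != 2))
    stop("genotype calls for ", rs_id, " must be two-allele strings")
  a1 <- substr(cc, 1, 1)
  a2 <- substr(cc, 2, 2)
  ok <- c(major, minor)
  bad <- unique(c(a1[!a1 %in% ok], a2[!a2 %in% ok]))
  if (length(bad))
    stop("allele(s) ", paste(bad, collapse = ", "), " for ", rs_id,
         " not in panel alleles ", major, "/", minor)
  out[live] <- (a1 == minor) + (a2 == minor)
  out
}

#' Read a genotype cohort from a delimited text table
#'
#' Expects a header `subject_id, group, <rs_id>, ...` and one row per
#' subject; genotype cells are unordered two-allele strings (`"GA"` is
#' equivalent to `"AG"`) or the missing code. Calls are recoded to
#' minor-allele counts using the panel's allele definitions; an allele
#' character not declared for the SNP is an error rather than a silent
#' missing value.
#'
#' @param path file path.
#' @param panel SNP metadata as from [bundledPanel()]; the file may
#'   contain any subset of its rs IDs.
#' @param sep field separator (default tab).
#' @param missing_code token for a missing call (default `"NA"`).
#' @return A [GenotypeCohort-class].
#' @seealso [writeGenotypeTable()], [readGenotypeVCF()]
#' @export
readGenotypeTable <- function(path, panel, sep = "\t",
                              missing_code = "NA") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  if (!all(c("subject_id", "group") %in% colnames(tab)))
    stop("header must start with subject_id, group")
  snp_cols <- setdiff(colnames(tab), c("subject_id", "group"))
  panel <- as.data.frame(panel)
  unknown <- setdiff(snp_cols, panel$rs_id)
  if (length(unknown))
    stop("SNPs not in panel: ", paste(unknown, collapse = ", "))
  if (anyDuplicated(tab$subject_id))
    stop("duplicate subject ID in ", path)
  sub_panel <- panel[match(snp_cols, panel$rs_id), , drop = FALSE]
  d <- vapply(seq_along(snp_cols), function(j) {
    .recodeCalls(tab[[snp_cols[j]]], sub_panel$major_allele[j],
                 sub_panel$minor_allele[j], snp_cols[j], missing_code)
  }, integer(nrow(tab)))
  d <- matrix(d, ncol = length(snp_cols),
              dimnames = list(tab$subject_id, snp_cols))
  GenotypeCohort(t(d), group = tab$group, panel = sub_panel,
                 subject_ids = tab$subject_id)
}

#' Write a genotype cohort as a delimited text table
#'
#' Inverse of [readGenotypeTable()]: dosages are expanded back to
#' two-allele genotype strings (major allele first) using the cohort's
#' panel.
#'
#' @param cohort a [GenotypeCohort-class].
#' @param path output file path.
#' @param sep field separator.
#' @param missing_code token written for a missing call.
#' @return `path`, invisibly.
#' @export
writeGenotypeTable <- function(cohort, path, sep = "\t",
                               missing_code = "NA") {
  d <- dosage(cohort)
  pan <- snpPanel(cohort)
  calls <- vapply(seq_len(nrow(d)), function(i) {
    g <- c(paste0(pan$major_allele[i], pan$major_allele[i]),
           paste0(pan$major_allele[i], pan$minor_allele[i]),
           paste0(pan$minor_allele[i], pan$minor_allele[i]))
    out <- rep(missing_code, ncol(d))
    live <- !is.na(d[i, ])
    out[live] <- g[d[i, live] + 1L]
    out
  }, character(ncol(d)))
  tab <- data.frame(subject_id = colnames(d),
                    group = as.character(groupLabels(cohort)),
                    matrix(calls, ncol = nrow(d),
                           dimnames = list(NULL, rownames(d))),
                    check.names = FALSE)
  utils::write.table(tab, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Maps the GT field of biallelic records to minor-allele dosages using
#' the panel's allele definitions (matching REF/ALT against major/minor
#' in either orientation). Multi-allelic records are rejected. Group
#' labels are not stored in VCF, so they are supplied separately.
#'
#' @param path VCF file path (uncompressed or bgzipped).
#' @param panel SNP metadata as from [bundledPanel()]; records are
#'   matched by ID.
#' @param group per-subject labels, `"control"`/`"case"`, in VCF sample
#'   order.
#' @return A [GenotypeCohort-class].
#' @export
readGenotypeVCF <- function(path, panel, group) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("readGenotypeVCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE)))
    stop("multi-allelic VCF records are not supported: ",
         paste(fix$ID[grepl(",", fix$ALT, fixed = TRUE)],
               collapse = ", "))
  panel <- as.data.frame(panel)
  idx <- match(fix$ID, panel$rs_id)
  if (anyNA(idx))
    stop("VCF records not in panel: ",
         paste(fix$ID[is.na(idx)], collapse = ", "))
  pan <- panel[idx, , drop = FALSE]
  gt <- vcfR::extract.gt(v)                       # variants x samples
  alt_dose <- matrix(NA_integer_, nrow(gt), ncol(gt),
                     dimnames = dimnames(gt))
  live <- !is.na(gt)
  alleles <- strsplit(gsub("|", "/", gt[live], fixed = TRUE), "/",
                      fixed = TRUE)
  alt_dose[live] <- vapply(alleles, function(a) sum(a == "1"),
                           integer(1))
  d <- alt_dose
  for (i in seq_len(nrow(pan))) {
    if (fix$REF[i] == pan$major_allele[i] &&
        fix$ALT[i] == pan$minor_allele[i]) {
      # ALT is the minor allele: dosage as-is
    } else if (fix$REF[i] == pan$minor_allele[i] &&
               fix$ALT[i] == pan$major_allele[i]) {
      d[i, ] <- 2L - alt_dose[i, ]
    } else {
      stop("VCF REF/ALT ", fix$REF[i], "/", fix$ALT[i], " for ",
           fix$ID[i], " do not match panel alleles")
    }
  }
  GenotypeCohort(d, group = group, panel = pan,
                 subject_ids = colnames(gt))
}

#' Aggregate a cohort into a per-SNP genotype count table
#'
#' @param cohort a [GenotypeCohort-class].
#' @param rs_id SNP identifier present in the cohort's panel.
#' @return A [genotypeCountTable()]: 3x2 counts with missing calls
#'   excluded, so each column sums to the group's non-missing call
#'   count.
#' @export
#' @examples
#' panel <- bundledPanel()[1, ]
#' d <- matrix(c(0L, 1L, 1L, 2L), nrow = 1,
#'             dimnames = list(panel$rs_id, NULL))
#' coh <- GenotypeCohort(d, rep(c("control", "case"), each = 2), panel)
#' countsFromCohort(coh, panel$rs_id)
countsFromCohort <- function(cohort, rs_id) {
  d <- dosage(cohort)
  if (!rs_id %in% rownames(d))
    stop("unknown rs_id: ", rs_id)
  x <- d[rs_id, ]
  grp <- groupLabels(cohort)
  cnt <- function(g) tabulate(x[grp == g & !is.na(x)] + 1L, nbins = 3L)
  genotypeCountTable(cnt("control"), cnt("case"), rs_id)
}
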