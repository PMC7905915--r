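#' @include association.R
NULL

#' SNPs of the default polygenic score models
#'
#' `m1SNPs()` returns the 6 GWAS-identified breast cancer risk SNPs that
#' form risk model M1. `m2SNPs()` returns the 13 SNPs of model M2: M1
#' plus 7 estrogen-metabolizing enzyme gene SNPs, one per gene after
#' linkage-disequilibrium pruning of the CYP1A1 and CYP1B1 pairs (see
#' [ldPrune()]).
#'
#' @return character vector of rs IDs.
#' @export
#' @examples
#' m1SNPs()
#' setdiff(m2SNPs(), m1SNPs())
m1SNPs <- function() {
  c("rs10822013", "rs2981579", "rs3784099", "rs3803662", "rs889312",
    "rs981782")
}

#' @rdname m1SNPs
#' @export
m2SNPs <- function() {
  c(m1SNPs(),
    "rs1048943", "rs1056827", "rs1042028", "rs700519", "rs4680",
    "rs605059", "rs7439366")
}

#' Prune linked candidate SNPs within genes
#'
#' For SNPs on the same gene, keeps the variant with the lowest
#' per-allele p-value. If the winner is protective (per-allele OR < 1)
#' and a risk variant (OR > 1) exists in the same gene, the risk
#' variant is kept instead, so that all retained score contributions
#' point in the risk direction.
#'
#' @param candidates data.frame with columns `rs_id`, `gene`,
#'   `allele_or`, `allele_p` (e.g. a subset of [associationTable()]
#'   merged with the panel's `gene` column).
#' @return the pruned data.frame, one row per gene, in first-appearance
#'   gene order.
#' @export
#' @examples
#' assoc <- associationTable(bundledCounts())
#' cand <- merge(assoc, bundledPanel()[, c("rs_id", "gene")],
#'               by = "rs_id", sort = FALSE)
#' ldPrune(cand)$rs_id
ldPrune <- function(candidates) {
  candidates <- as.data.frame(candidates)
  stopifnot(all(c("rs_id", "gene", "allele_or", "allele_p") %in%
                  colnames(candidates)))
  keep <- lapply(unique(candidates$gene), function(g) {
    grp <- candidates[candidates$gene == g, , drop = FALSE]
    grp <- grp[!is.na(grp$allele_p), , drop = FALSE]
    if (!nrow(grp)) return(NULL)
    win <- grp[which.min(grp$allele_p), , drop = FALSE]
    if (win$allele_or < 1) {
      risk <- grp[grp$allele_or > 1, , drop = FALSE]
      if (nrow(risk))
        win <- risk[which.min(risk$allele_p), , drop = FALSE]
    }
    win
  })
  do.call(rbind, keep)
}

#' Build a polygenic risk score model from association results
#'
#' Weights beta_k come from the per-allele association results: under
#' the default `"or"` scheme beta_k is the per-allele odds ratio for the
#' minor allele itself; under `"log_or"` it is `log(OR)`, the
#' conventional additive-log-odds alternative. The effect allele is the
#' panel's minor allele.
#'
#' @param assoc output of [associationTable()] (must contain
#'   `allele_or` and `allele_p`).
#' @param snp_ids rs IDs to include, in model order (e.g. [m1SNPs()]).
#' @param scheme `"or"` or `"log_or"`.
#' @param name model name.
#' @param panel SNP metadata supplying the effect (minor) allele;
#'   default [bundledPanel()].
#' @return A [PRSModel-class].
#' @export
#' @examples
#' assoc <- associationTable(bundledCounts())
#' buildPRSModel(assoc, m1SNPs(), name = "M1")
buildPRSModel <- function(assoc, snp_ids, scheme = c("or", "log_or"),
                          name = "PRS", panel = bundledPanel()) {
  scheme <- match.arg(scheme)
  idx <- match(snp_ids, assoc$rs_id)
  if (anyNA(idx))
    stop("no association result for: ",
         paste(snp_ids[is.na(idx)], collapse = ", "))
  or <- assoc$allele_or[idx]
  if (anyNA(or))
    stop("per-allele OR unavailable for: ",
         paste(snp_ids[is.na(or)], collapse = ", "))
  pan_idx <- match(snp_ids, panel$rs_id)
  w <- data.frame(rs_id = snp_ids,
                  effect_allele = ifelse(is.na(pan_idx), NA_character_,
                                         panel$minor_allele[pan_idx]),
                  beta = if (scheme == "or") or else log(or),
                  scheme = scheme,
                  p_value = assoc$allele_p[idx],
                  row.names = NULL)
  new("PRSModel", name = name, weights = w)
}

#' Read/write a polygenic score model as delimited text
#'
#' @param model a [PRSModel-class].
#' @param path file path.
#' @param sep field separator.
#' @return `writePRSModel` returns `path` invisibly; `readPRSModel`
#'   returns a [PRSModel-class].
#' @export
writePRSModel <- function(model, path, sep = "\t") {
  utils::write.table(prsWeights(model), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writePRSModel
#' @param name model name for the read model.
#' @export
readPRSModel <- function(path, name = "PRS", sep = "\t") {
  w <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  new("PRSModel", name = name, weights = w)
}

#' Score a cohort under a polygenic risk score model
#'
#' Computes `PRS = sum_k beta_k * x_k` per subject, where `x_k` is the
#' minor-allele dosage at model SNP k. A subject missing a call at any
#' model SNP has no defined score and is excluded with a message (no
#' imputation). Scores are reported raw, without centring.
#'
#' @param cohort a [GenotypeCohort-class] covering all model SNPs.
#' @param model a [PRSModel-class].
#' @return data.frame (`subject_id`, `group`, `model`, `score`), one
#'   row per scored subject.
#' @export
#' @examples
#' assoc <- associationTable(bundledCounts())
#' m1 <- buildPRSModel(assoc, m1SNPs(), name = "M1")
#' coh <- simulateGenotypes(defaultSNPSimSpec(), 30, 30, seed = 1)
#' head(scoreCohort(coh, m1))
scoreCohort <- function(cohort, model) {
  w <- prsWeights(model)
  d <- dosage(cohort)
  miss <- setdiff(w$rs_id, rownames(d))
  if (length(miss))
    stop("model SNP(s) absent from cohort: ",
         paste(miss, collapse = ", "))
  x <- d[w$rs_id, , drop = FALSE]
  incomplete <- colSums(is.na(x)) > 0
  if (any(incomplete))
    message(sum(incomplete),
            " subject(s) with missing model genotypes excluded")
  x <- x[, !incomplete, drop = FALSE]
  data.frame(subject_id = colnames(x),
             group = as.character(groupLabels(cohort))[!incomplete],
             model = model@name,
             score = as.numeric(crossprod(x, w$beta)),
             row.names = NULL)
}
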