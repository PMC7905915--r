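#' @include AllClasses.R
NULL

#' Minor-allele dosage matrix of a cohort
#'
#' @param x a [GenotypeCohort-class]
#' @return integer matrix, SNPs x subjects, entries 0/1/2/NA.
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname dosage
#' @export
setMethod("dosage", "GenotypeCohort", function(x) assay(x, "dosage"))

#' Case/control group labels
#'
#' @param x a [GenotypeCohort-class] or [EstrogenPanel-class]
#' @return factor with levels `control`, `case`.
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @rdname groupLabels
#' @export
setMethod("groupLabels", "SummarizedExperiment",
          function(x) colData(x)$group)

#' @rdname groupLabels
#' @export
setMethod("groupLabels", "OPLSDAResult", function(x) x@groups)

#' SNP panel metadata of a cohort
#'
#' @param x a [GenotypeCohort-class]
#' @return data.frame of per-SNP metadata (rs_id, gene, alleles, ...).
#' @export
setGeneric("snpPanel", function(x) standardGeneric("snpPanel"))

#' @rdname snpPanel
#' @export
setMethod("snpPanel", "GenotypeCohort",
          function(x) as.data.frame(rowData(x)))

#' Concentration matrix of an estrogen panel
#'
#' @param x an [EstrogenPanel-class]
#' @return numeric matrix, analytes x subjects, pg/mL.
#' @export
setGeneric("concentrations", function(x) standardGeneric("concentrations"))

#' @rdname concentrations
#' @export
setMethod("concentrations", "EstrogenPanel", function(x) assay(x, "conc"))

#' Polygenic score weights table
#'
#' @param x a [PRSModel-class]
#' @return data.frame with columns rs_id, effect_allele, beta, scheme,
#'   p_value.
#' @export
setGeneric("prsWeights", function(x) standardGeneric("prsWeights"))

#' @rdname prsWeights
#' @export
setMethod("prsWeights", "PRSModel", function(x) x@weights)

setMethod("show", "GenotypeCohort", function(object) {
  g <- table(groupLabels(object))
  cat("GenotypeCohort:", nrow(object), "SNPs x", ncol(object),
      "subjects (", g[["case"]], "cases /", g[["control"]],
      "controls )\n")
  rd <- rowData(object)
  if ("category" %in% colnames(rd)) {
    tab <- table(rd$category)
    cat("  panel:", paste(sprintf("%d %s", tab, names(tab)),
                          collapse = ", "), "\n")
  }
  miss <- sum(is.na(assay(object, "dosage")))
  cat("  missing calls:", miss, "\n")
})

setMethod("show", "EstrogenPanel", function(object) {
  g <- table(groupLabels(object))
  cat("EstrogenPanel:", nrow(object), "analytes x", ncol(object),
      "subjects (", g[["case"]], "cases /", g[["control"]],
      "controls )\n")
  cat("  analytes:", paste(utils::head(rownames(object), 5),
                           collapse = ", "),
      if (nrow(object) > 5) "..." else "", "\n")
})

setMethod("show", "PRSModel", function(object) {
  w <- object@weights
  cat("PRSModel", object@name, ":", nrow(w), "SNPs, scheme",
      unique(w$scheme), "\n")
  print(utils::head(w, 6), row.names = FALSE)
  if (nrow(w) > 6) cat("  ...\n")
})

setMethod("show", "OPLSDAResult", function(object) {
  cat("OPLSDAResult: 1 predictive +", object@nOrtho,
      "orthogonal component(s),", length(object@analytes), "analytes\n")
  cat(sprintf("  R2X(cum) = %.3f, R2Y(cum) = %.3f, Q2(cum) = %.3f\n",
              object@R2X, object@R2Y, object@Q2))
  sel <- object@analytes[object@vip > 1]
  cat("  VIP > 1:", if (length(sel)) paste(sel, collapse = ", ")
      else "(none)", "\n")
})
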