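#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData assays
#' @importFrom S4Vectors DataFrame metadata
NULL

.GROUP_LEVELS <- c("control", "case")

#' The default serum estrogen analyte panel
#'
#' Eleven estrogen species quantified in serum by LC-MS/MS: the parent
#' estrogens (E1, E2, E3), the 16-alpha and catechol (2-/4-hydroxy)
#' metabolites, and the methoxylated detoxification products.
#'
#' @return Character vector of the 11 analyte names.
#' @export
#' @examples
#' estrogenAnalytes()
estrogenAnalytes <- function() {
  c("E1", "E2", "E3", "16a-OHE1", "2/4-OHE1", "2-OHE2", "4-OHE2",
    "2-MeOE1", "4-MeOE1", "2-MeOE2", "4-MeOE2")
}

#' GenotypeCohort: subjects by SNPs minor-allele dosages
#'
#' An S4 container for an individual-level case-control genotype cohort,
#' extending [SummarizedExperiment::SummarizedExperiment]. Rows are SNPs
#' (with panel metadata in `rowData`: `rs_id`, `gene`, `major_allele`,
#' `minor_allele`, `category`), columns are subjects, and the single
#' `"dosage"` assay stores minor-allele counts (0, 1, 2, or `NA` for a
#' missing call). Case/control status lives in `colData(x)$group`.
#'
#' @slot .Data see [SummarizedExperiment::SummarizedExperiment]
#' @name GenotypeCohort-class
#' @aliases GenotypeCohort-class
#' @exportClass GenotypeCohort
setClass("GenotypeCohort", contains = "SummarizedExperiment")

setValidity("GenotypeCohort", function(object) {
  msg <- character()
  if (!("dosage" %in% assayNames(object)))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- assay(object, "dosage")
    bad <- d[!is.na(d)]
    if (length(bad) && !all(bad %in% c(0L, 1L, 2L)))
      msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  }
  cd <- colData(object)
  if (!("group" %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'group'")
  else if (!all(as.character(cd$group) %in% .GROUP_LEVELS))
    msg <- c(msg, "group labels must be 'control' or 'case'")
  rd <- rowData(object)
  need <- c("rs_id", "major_allele", "minor_allele")
  if (!all(need %in% colnames(rd)))
    msg <- c(msg, "rowData must contain rs_id, major_allele, minor_allele")
  else {
    if (anyDuplicated(rd$rs_id))
      msg <- c(msg, "duplicate rs_id in panel")
    if (any(rd$major_allele == rd$minor_allele))
      msg <- c(msg, "major and minor allele must differ")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeCohort
#'
#' @param dosage integer matrix of minor-allele counts, SNPs x subjects
#'   (values 0/1/2/NA). Row names are taken as rs IDs when `panel` rows
#'   have none.
#' @param group character or factor of per-subject labels, `"control"` or
#'   `"case"`.
#' @param panel data.frame of per-SNP metadata with at least `rs_id`,
#'   `major_allele`, `minor_allele` (see [bundledPanel()]); one row per
#'   dosage row, matched by `rs_id` against `rownames(dosage)` when both
#'   are present.
#' @param subject_ids optional character vector of subject identifiers;
#'   defaults to `colnames(dosage)` or `S1..Sn`.
#' @return A [GenotypeCohort-class] object.
#' @export
#' @examples
#' panel <- bundledPanel()[1:2, ]
#' d <- matrix(c(0L, 1L, 2L, 0L), nrow = 2,
#'             dimnames = list(panel$rs_id, c("s1", "s2")))
#' GenotypeCohort(d, group = c("control", "case"), panel = panel)
GenotypeCohort <- function(dosage, group, panel, subject_ids = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  panel <- as.data.frame(panel)
  if (nrow(panel) != nrow(dosage))
    stop("panel has ", nrow(panel), " SNPs but dosage has ",
         nrow(dosage), " rows")
  if (!is.null(rownames(dosage))) {
    idx <- match(rownames(dosage), panel$rs_id)
    if (anyNA(idx))
      stop("dosage rows not in panel: ",
           paste(rownames(dosage)[is.na(idx)], collapse = ", "))
    panel <- panel[idx, , drop = FALSE]
  } else {
    rownames(dosage) <- panel$rs_id
  }
  if (is.null(subject_ids))
    subject_ids <- colnames(dosage)
  if (is.null(subject_ids))
    subject_ids <- paste0("S", seq_len(ncol(dosage)))
  if (anyDuplicated(subject_ids))
    stop("duplicate subject IDs")
  colnames(dosage) <- subject_ids
  group <- factor(as.character(group), levels = .GROUP_LEVELS)
  if (anyNA(group))
    stop("group labels must be 'control' or 'case'")
  if (length(group) != ncol(dosage))
    stop("length(group) must equal the number of subjects")
  se <- SummarizedExperiment(
    assays = list(dosage = dosage),
    rowData = DataFrame(panel, row.names = panel$rs_id),
    colData = DataFrame(group = group, row.names = subject_ids))
  new("GenotypeCohort", se)
}

#' EstrogenPanel: subjects by analyte serum concentrations
#'
#' An S4 container for a case-control serum estrogen panel, extending
#' [SummarizedExperiment::SummarizedExperiment]. Rows are analytes,
#' columns are subjects, and the `"conc"` assay stores strictly positive
#' concentrations in pg/mL. Group labels live in `colData(x)$group`.
#'
#' @name EstrogenPanel-class
#' @aliases EstrogenPanel-class
#' @exportClass EstrogenPanel
setClass("EstrogenPanel", contains = "SummarizedExperiment")

setValidity("EstrogenPanel", function(object) {
  msg <- character()
  if (!("conc" %in% assayNames(object)))
    msg <- c(msg, "assay 'conc' is required")
  else {
    cc <- assay(object, "conc")
    if (any(!is.finite(cc)) || any(cc <= 0))
      msg <- c(msg, "concentrations must be finite and strictly positive")
  }
  cd <- colData(object)
  if (!("group" %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'group'")
  else if (!all(as.character(cd$group) %in% .GROUP_LEVELS))
    msg <- c(msg, "group labels must be 'control' or 'case'")
  if (length(msg)) msg else TRUE
})

#' Construct an EstrogenPanel
#'
#' @param conc numeric matrix of concentrations (pg/mL), analytes x
#'   subjects, strictly positive. Row names are analyte names; defaults
#'   to [estrogenAnalytes()] when absent and the matrix has 11 rows.
#' @param group per-subject labels, `"control"` or `"case"`.
#' @param subject_ids optional subject identifiers.
#' @return An [EstrogenPanel-class] object.
#' @export
#' @examples
#' set.seed(1)
#' conc <- matrix(rlnorm(22, 3, 0.4), nrow = 11)
#' EstrogenPanel(conc, group = c("control", "case"))
EstrogenPanel <- function(conc, group, subject_ids = NULL) {
  conc <- as.matrix(conc)
  if (is.null(rownames(conc))) {
    if (nrow(conc) == length(estrogenAnalytes()))
      rownames(conc) <- estrogenAnalytes()
    else
      rownames(conc) <- paste0("analyte", seq_len(nrow(conc)))
  }
  if (is.null(subject_ids))
    subject_ids <- colnames(conc)
  if (is.null(subject_ids))
    subject_ids <- paste0("S", seq_len(ncol(conc)))
  colnames(conc) <- subject_ids
  group <- factor(as.character(group), levels = .GROUP_LEVELS)
  if (anyNA(group))
    stop("group labels must be 'control' or 'case'")
  if (length(group) != ncol(conc))
    stop("length(group) must equal the number of subjects")
  se <- SummarizedExperiment(
    assays = list(conc = conc),
    colData = DataFrame(group = group, row.names = subject_ids))
  new("EstrogenPanel", se)
}

#' PRSModel: an ordered set of per-SNP polygenic score weights
#'
#' Holds the weights beta_k of a polygenic risk score
#' PRS = sum_k beta_k x_k, where x_k is the minor-allele count (0, 1, 2)
#' at SNP k. Under the `"or"` scheme beta_k is the per-allele odds ratio
#' itself; under `"log_or"` it is the natural log odds ratio.
#'
#' @slot name model name (e.g. `"M1"`).
#' @slot weights data.frame with columns `rs_id`, `effect_allele`,
#'   `beta`, `scheme`, `p_value`.
#' @name PRSModel-class
#' @aliases PRSModel-class
#' @exportClass PRSModel
setClass("PRSModel",
         representation(name = "character", weights = "data.frame"))

setValidity("PRSModel", function(object) {
  w <- object@weights
  msg <- character()
  need <- c("rs_id", "effect_allele", "beta", "scheme", "p_value")
  if (!all(need %in% colnames(w)))
    return(paste("weights must have columns",
                 paste(need, collapse = ", ")))
  if (anyDuplicated(w$rs_id))
    msg <- c(msg, "duplicate rs_id in model")
  if (!all(w$scheme %in% c("or", "log_or")))
    msg <- c(msg, "scheme must be 'or' or 'log_or'")
  if (any(!is.finite(w$beta)))
    msg <- c(msg, "weights must be finite")
  if (any(w$scheme == "or" & w$beta <= 0))
    msg <- c(msg, "'or' scheme weights must be positive")
  if (length(msg)) msg else TRUE
})

#' OPLSDAResult: a fitted OPLS-DA model of an analyte panel
#'
#' Orthogonal projections to latent structures discriminant analysis with
#' one predictive component and `nOrtho` orthogonal components, fitted to
#' a two-group analyte panel after mean centering and unit-variance
#' scaling.
#'
#' @slot analytes analyte names (the model variables).
#' @slot groups per-subject group factor.
#' @slot scoresPred predictive component scores (one per subject).
#' @slot loadingsPred,weightsPred predictive loadings/weights per analyte.
#' @slot scoresOrtho,loadingsOrtho,weightsOrtho orthogonal component
#'   scores (subjects x k) and loadings/weights (analytes x k).
#' @slot yLoading regression loading of the centred class response on the
#'   predictive scores.
#' @slot R2X,R2Y,Q2 cumulative explained X variance, explained Y
#'   variance, and 7-fold cross-validated predicted Y variance.
#' @slot vip variable importance in projection, one value per analyte
#'   (mean squared VIP is 1 by construction).
#' @slot center,scale the column centring/scaling applied before fitting.
#' @slot nOrtho number of orthogonal components.
#' @name OPLSDAResult-class
#' @aliases OPLSDAResult-class
#' @exportClass OPLSDAResult
setClass("OPLSDAResult",
         representation(analytes = "character",
                        groups = "factor",
                        scoresPred = "numeric",
                        loadingsPred = "numeric",
                        weightsPred = "numeric",
                        scoresOrtho = "matrix",
                        loadingsOrtho = "matrix",
                        weightsOrtho = "matrix",
                        yLoading = "numeric",
                        R2X = "numeric",
                        R2Y = "numeric",
                        Q2 = "numeric",
                        vip = "numeric",
                        center = "numeric",
                        scale = "numeric",
                        nOrtho = "integer"))

setValidity("OPLSDAResult", function(object) {
  msg <- character()
  if (object@R2X < 0 || object@R2X > 1)
    msg <- c(msg, "R2X must be in [0, 1]")
  if (object@R2Y < 0 || object@R2Y > 1)
    msg <- c(msg, "R2Y must be in [0, 1]")
  if (length(object@vip) != length(object@analytes))
    msg <- c(msg, "one VIP value per analyte required")
  if (length(msg)) msg else TRUE
})
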