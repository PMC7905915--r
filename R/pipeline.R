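#' @include evaluation.R estrogen-profile.R simulate.R genotype-qc.R
NULL

.readConfigFile <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Run the full case-control analysis pipeline
#'
#' Orchestrates the analysis chain in order: cohort input or
#' simulation, Hardy-Weinberg QC, per-SNP association, polygenic score
#' model construction and scoring, score evaluation (t-test, ROC/AUC),
#' and optional estrogen panel profiling. Every stage writes a
#' delimited-text artifact into `out_dir`, plus a machine-readable JSON
#' run summary recording the options in effect; identical config and
#' seed give identical artifacts.
#'
#' Exactly one cohort source must be configured:
#' \describe{
#'   \item{`cohort`}{a [GenotypeCohort-class] (individual-level mode).}
#'   \item{`genotype_file`}{path to a table for [readGenotypeTable()].}
#'   \item{`counts`}{a named list of [genotypeCountTable()]s, or the
#'     string `"bundled"` for [bundledCounts()] (counts-only mode:
#'     QC and association run, but scoring and evaluation need
#'     individual-level data and are skipped with a log line).}
#'   \item{`simulate`}{list with `n_cases`, `n_controls` and optionally
#'     `specs` (default [defaultSNPSimSpec()]); requires `seed`.}
#' }
#' Further fields: `seed`, `weight_scheme` (`"or"`/`"log_or"`),
#' `alpha` (default 0.05), `welch`, `models` (named list of rs-ID
#' vectors; default M1/M2), `estrogen_panel` (an
#' [EstrogenPanel-class]) or `simulate_estrogens` (list with
#' `n_per_group` and optionally `spec`).
#'
#' @param config list as above, or path to a JSON/YAML file with the
#'   scalar fields.
#' @param out_dir output directory, created if needed.
#' @return invisibly, a list with the per-stage results (`hwe`,
#'   `association`, `models`, `scores`, `evaluation`, `estrogen`) and
#'   the run summary.
#' @export
#' @examples
#' \donttest{
#' res <- runPipeline(list(simulate = list(n_cases = 60,
#'                                         n_controls = 60),
#'                         seed = 1),
#'                    out_dir = tempfile())
#' res$evaluation
#' }
runPipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1)
    config <- .readConfigFile(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  # log lines carry no wall-clock time so that identical config + seed
  # gives byte-identical artifacts
  say <- function(...) {
    line <- paste0(...)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  sources <- c("cohort", "genotype_file", "counts", "simulate")
  have <- sources[vapply(sources, function(s) !is.null(config[[s]]),
                         logical(1))]
  if (length(have) != 1)
    stop("configure exactly one of ",
         paste(sources, collapse = ", "), " (got ",
         if (length(have)) paste(have, collapse = "+") else "none", ")")

  alpha <- if (is.null(config$alpha)) 0.05 else config$alpha
  scheme <- if (is.null(config$weight_scheme)) "or"
            else config$weight_scheme
  welch <- isTRUE(config$welch)

  cohort <- NULL
  counts <- NULL
  stage("input", {
    if (have == "cohort") {
      cohort <- config$cohort
    } else if (have == "genotype_file") {
      panel <- if (is.null(config$panel)) bundledPanel()
               else config$panel
      cohort <- readGenotypeTable(config$genotype_file, panel)
    } else if (have == "counts") {
      counts <- if (identical(config$counts, "bundled"))
        bundledCounts() else config$counts
      say("counts-only mode: ", length(counts), " SNP count tables")
    } else {
      if (is.null(config$seed))
        stop("simulation runs require a seed")
      specs <- if (is.null(config$simulate$specs)) defaultSNPSimSpec()
               else config$simulate$specs
      cohort <- simulateGenotypes(specs,
                                  n_cases = config$simulate$n_cases,
                                  n_controls = config$simulate$n_controls,
                                  seed = config$seed)
      say("simulated cohort: ", config$simulate$n_cases, " cases / ",
          config$simulate$n_controls, " controls, seed ", config$seed)
    }
    if (!is.null(cohort)) {
      counts <- lapply(rownames(dosage(cohort)), countsFromCohort,
                       cohort = cohort)
      names(counts) <- rownames(dosage(cohort))
    }
  })

  hwe <- stage("qc", {
    h <- hweReport(if (is.null(cohort)) counts else cohort,
                   alpha = alpha)
    utils::write.table(h, file.path(out_dir, "hwe_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    say("HWE QC: ", sum(h$hwe_flag), " of ", nrow(h),
        " SNPs flagged at alpha = ", alpha)
    h
  })

  assoc <- stage("association", {
    a <- associationTable(counts)
    writeAssociationReport(a, file.path(out_dir, "association.tsv"))
    say("association: ", sum(a$dist_p < alpha, na.rm = TRUE),
        " SNPs with genotype-distribution p < ", alpha)
    a
  })

  model_defs <- if (is.null(config$models))
    list(M1 = m1SNPs(), M2 = m2SNPs()) else config$models
  models <- stage("prs", {
    ms <- lapply(names(model_defs), function(nm)
      buildPRSModel(assoc, model_defs[[nm]], scheme = scheme,
                    name = nm))
    names(ms) <- names(model_defs)
    for (nm in names(ms))
      writePRSModel(ms[[nm]],
                    file.path(out_dir, paste0("model_", nm, ".tsv")))
    say("PRS: built ", length(ms), " model(s) under scheme '", scheme,
        "'")
    ms
  })

  scores <- NULL
  evaluation <- NULL
  if (is.null(cohort)) {
    say("evaluation skipped: counts-only input has no individual-level",
        " genotypes to score")
  } else {
    scores <- stage("scoring", {
      s <- lapply(models, scoreCohort, cohort = cohort)
      all_s <- do.call(rbind, s)
      utils::write.table(all_s, file.path(out_dir, "scores.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      s
    })
    evaluation <- stage("evaluation", {
      ev <- do.call(evaluateModels, c(unname(scores),
                                      list(welch = welch)))
      utils::write.table(ev, file.path(out_dir, "evaluation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      for (i in seq_len(nrow(ev)))
        say(sprintf("model %s: case %.2f +/- %.2f vs control %.2f +/- %.2f, p = %.3g, AUC = %.1f%%",
                    ev$model[i], ev$mean_case[i], ev$sem_case[i],
                    ev$mean_control[i], ev$sem_control[i],
                    ev$p_value[i], 100 * ev$auc[i]))
      ev
    })
  }

  estrogen <- NULL
  epanel <- config$estrogen_panel
  if (is.null(epanel) && !is.null(config$simulate_estrogens)) {
    if (is.null(config$seed))
      stop("simulation runs require a seed")
    es <- config$simulate_estrogens
    epanel <- simulateEstrogens(
      if (is.null(es$spec)) defaultEstrogenSimSpec() else es$spec,
      n_per_group = es$n_per_group,
      seed = config$seed + 1L)
  }
  if (!is.null(epanel)) {
    estrogen <- stage("estrogen", {
      cmp <- compareAnalytes(epanel, welch = welch)
      fit <- oplsDA(epanel)
      vip <- vipScores(fit)
      utils::write.table(cmp,
                         file.path(out_dir, "estrogen_comparison.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(analyte = names(vip$vip), vip = vip$vip),
        file.path(out_dir, "estrogen_vip.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      say(sprintf("OPLS-DA: R2X = %.3f, R2Y = %.3f, Q2 = %.3f; VIP > 1: %s",
                  fit@R2X, fit@R2Y, fit@Q2,
                  paste(vip$biomarkers, collapse = ", ")))
      list(comparison = cmp, fit = fit, vip = vip)
    })
  }

  summary <- list(
    input_mode = have,
    seed = config$seed,
    alpha = alpha,
    weight_scheme = scheme,
    t_test = if (welch) "welch" else "student",
    auc_ci = "delong",
    opls_scaling = "unit-variance",
    n_snps = length(counts),
    models = lapply(models, function(m) prsWeights(m)$rs_id),
    significant_snps =
      assoc$rs_id[!is.na(assoc$dist_p) & assoc$dist_p < alpha],
    log = log_lines)
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(hwe = hwe, association = assoc, models = models,
                 scores = scores, evaluation = evaluation,
                 estrogen = estrogen, summary = summary))
}
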