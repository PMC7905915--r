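#' @include prs.R
NULL

#' Compare polygenic score distributions between groups
#'
#' Reports per-group mean and standard error of the mean, Shapiro-Wilk
#' normality p-values (reported, not used to gate the test), and the
#' independent two-sample t-test on the scores — Student's
#' equal-variance form by default, the classical choice when normality
#' has been explicitly checked; set `welch = TRUE` for the
#' unequal-variance form.
#'
#' @param scores data.frame from [scoreCohort()] (columns `group`,
#'   `score`), or any data.frame with those columns.
#' @param welch use the Welch t-test instead of Student's.
#' @return list with `model`, `mean_control`, `sem_control`,
#'   `mean_case`, `sem_case`, `shapiro_p_control`, `shapiro_p_case`,
#'   `t_statistic`, `df`, `p_value`.
#' @export
#' @examples
#' s <- data.frame(group = rep(c("control", "case"), each = 20),
#'                 score = c(rnorm(20, 4.5), rnorm(20, 4.8)))
#' compareScores(s)
compareScores <- function(scores, welch = FALSE) {
  ctrl <- scores$score[scores$group == "control"]
  case <- scores$score[scores$group == "case"]
  if (length(ctrl) < 2 || length(case) < 2)
    stop("each group needs at least 2 subjects")
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  shap <- function(x) {
    if (length(x) < 3 || length(unique(x)) < 2) return(NA_real_)
    stats::shapiro.test(x)$p.value
  }
  tt <- if (stats::sd(c(ctrl, case)) == 0)
    list(statistic = c(t = 0), parameter = c(df = length(ctrl) +
                                               length(case) - 2),
         p.value = 1)
  else stats::t.test(case, ctrl, var.equal = !welch)
  list(model = if ("model" %in% names(scores))
         as.character(scores$model[1]) else NA_character_,
       mean_control = mean(ctrl), sem_control = sem(ctrl),
       mean_case = mean(case), sem_case = sem(case),
       shapiro_p_control = shap(ctrl), shapiro_p_case = shap(case),
       t_statistic = unname(tt$statistic),
       df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Empirical ROC curve and AUC for a score set
#'
#' Builds the empirical ROC over all observed score thresholds with the
#' convention that a higher score predicts case status; the AUC
#' (trapezoid rule, ties counted 0.5 — equivalently the normalized
#' Mann-Whitney U statistic) and its DeLong 95% confidence interval are
#' computed with \pkg{pROC}. Identical scores in both groups yield AUC
#' 0.5 with a degenerate interval and a warning.
#'
#' @param scores data.frame with columns `group` and `score`.
#' @param conf_level confidence level for the DeLong interval.
#' @return list with `auc`, `ci_low`, `ci_high`, and a `curve`
#'   data.frame (`threshold`, `sensitivity`, `fpr`) ordered along the
#'   curve.
#' @export
#' @examples
#' s <- data.frame(group = rep(c("control", "case"), each = 50),
#'                 score = c(rnorm(50), rnorm(50, 1)))
#' rocAUC(s)$auc
rocAUC <- function(scores, conf_level = 0.95) {
  grp <- factor(as.character(scores$group), levels = .GROUP_LEVELS)
  x <- scores$score
  if (!all(table(grp) > 0))
    stop("both groups must be non-empty")
  if (stats::sd(x) == 0) {
    warning("all scores identical; AUC degenerate at 0.5")
    return(list(auc = 0.5, ci_low = NA_real_, ci_high = NA_real_,
                curve = data.frame(threshold = c(Inf, -Inf),
                                   sensitivity = c(0, 1),
                                   fpr = c(0, 1))))
  }
  r <- pROC::roc(response = grp, predictor = x,
                 levels = c("control", "case"), direction = "<",
                 quiet = TRUE)
  ci <- as.numeric(pROC::ci.auc(r, conf.level = conf_level,
                                method = "delong"))
  ord <- order(r$thresholds, decreasing = TRUE)   # (0,0) -> (1,1)
  list(auc = as.numeric(pROC::auc(r)),
       ci_low = ci[1], ci_high = ci[3],
       curve = data.frame(threshold = r$thresholds[ord],
                          sensitivity = r$sensitivities[ord],
                          fpr = 1 - r$specificities[ord]))
}

#' Evaluate one or more score sets
#'
#' Convenience wrapper: per model, the group comparison of
#' [compareScores()] and the discrimination summary of [rocAUC()].
#'
#' @param ... score data.frames from [scoreCohort()].
#' @param welch passed to [compareScores()].
#' @return data.frame with one row per model: group means and SEMs, t
#'   statistic and p-value, AUC and its confidence interval.
#' @export
evaluateModels <- function(..., welch = FALSE) {
  sets <- list(...)
  rows <- lapply(sets, function(s) {
    cmp <- compareScores(s, welch = welch)
    roc <- rocAUC(s)
    data.frame(model = cmp$model,
               mean_control = cmp$mean_control,
               sem_control = cmp$sem_control,
               mean_case = cmp$mean_case,
               sem_case = cmp$sem_case,
               t_statistic = cmp$t_statistic,
               p_value = cmp$p_value,
               auc = roc$auc, auc_ci_low = roc$ci_low,
               auc_ci_high = roc$ci_high,
               row.names = NULL)
  })
  do.call(rbind, rows)
}
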