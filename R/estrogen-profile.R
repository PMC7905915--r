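#' @include AllGenerics.R
NULL

#' Per-analyte group comparison of an estrogen panel
#'
#' Two-sample t-test per analyte on raw concentrations (Student's
#' equal-variance form by default; `welch = TRUE` for the
#' unequal-variance form), with group means, SEMs, and the conventional
#' significance tiers at p < 0.05 and p < 0.01.
#'
#' @param panel an [EstrogenPanel-class] with at least 2 subjects per
#'   group.
#' @param welch use the Welch t-test.
#' @return data.frame, one row per analyte: `analyte`, `mean_control`,
#'   `sem_control`, `mean_case`, `sem_case`, `t_statistic`, `p_value`,
#'   `tier` (`""`, `"*"` or `"**"`).
#' @export
#' @examples
#' pan <- simulateEstrogens(defaultEstrogenSimSpec(), 50, seed = 1)
#' compareAnalytes(pan)
compareAnalytes <- function(panel, welch = FALSE) {
  grp <- groupLabels(panel)
  if (sum(grp == "control") < 2 || sum(grp == "case") < 2)
    stop("each group needs at least 2 subjects")
  cc <- concentrations(panel)
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  rows <- lapply(rownames(cc), function(a) {
    ctrl <- cc[a, grp == "control"]
    case <- cc[a, grp == "case"]
    tt <- if (stats::sd(c(ctrl, case)) == 0)
      list(statistic = c(t = 0), p.value = 1)
    else stats::t.test(case, ctrl, var.equal = !welch)
    p <- tt$p.value
    data.frame(analyte = a,
               mean_control = mean(ctrl), sem_control = sem(ctrl),
               mean_case = mean(case), sem_case = sem(case),
               t_statistic = unname(tt$statistic),
               p_value = p,
               tier = if (p < 0.01) "**" else if (p < 0.05) "*" else "",
               row.names = NULL)
  })
  do.call(rbind, rows)
}

## orthogonal-signal-corrected PLS of a single centred response y on a
## centred/scaled predictor matrix X (subjects x analytes); the
## workhorse behind oplsDA and its cross-validation
.oplsCore <- function(X, y, n_ortho) {
  Xr <- X
  p <- ncol(X)
  w_o <- matrix(0, p, 0); p_o <- matrix(0, p, 0)
  t_o <- matrix(0, nrow(X), 0)
  for (k in seq_len(n_ortho)) {
    w <- crossprod(Xr, y)
    w <- w / sqrt(sum(w^2))
    t_p <- Xr %*% w
    pl <- crossprod(Xr, t_p) / sum(t_p^2)
    wo <- pl - as.numeric(crossprod(w, pl)) * w
    nw <- sqrt(sum(wo^2))
    if (nw < 1e-10) break          # no orthogonal variation left
    wo <- wo / nw
    to <- Xr %*% wo
    po <- crossprod(Xr, to) / sum(to^2)
    Xr <- Xr - to %*% t(po)
    w_o <- cbind(w_o, wo); p_o <- cbind(p_o, po)
    t_o <- cbind(t_o, to)
  }
  w <- crossprod(Xr, y)
  w <- w / sqrt(sum(w^2))
  t_p <- as.numeric(Xr %*% w)
  pl <- as.numeric(crossprod(Xr, t_p) / sum(t_p^2))
  c_y <- sum(y * t_p) / sum(t_p^2)
  list(w = as.numeric(w), p = pl, t = t_p, c_y = c_y,
       w_o = w_o, p_o = p_o, t_o = t_o)
}

## predict centred y for new (already centred/scaled) rows
.oplsPredict <- function(fit, Xnew) {
  if (ncol(fit$w_o) > 0) {
    for (k in seq_len(ncol(fit$w_o))) {
      tko <- Xnew %*% fit$w_o[, k]
      Xnew <- Xnew - tko %*% t(fit$p_o[, k])
    }
  }
  as.numeric(Xnew %*% fit$w) * fit$c_y
}

#' Fit an OPLS-DA model to a two-group analyte panel
#'
#' Orthogonal projections to latent structures discriminant analysis:
#' the analyte matrix is mean-centred and unit-variance scaled, the
#' class response coded numerically and centred, then class-orthogonal
#' variation is removed component by component before a single
#' predictive PLS component is fitted on the filtered matrix. With
#' `n_orthogonal = 0` the fit reduces to single-component PLS-DA.
#'
#' Reported summaries: `R2X` (fraction of scaled X variance captured by
#' all modelled components), `R2Y` (fraction of class variance explained
#' by the predictive component), and `Q2` (cross-validated R2Y from
#' 7-fold CV with contiguous-block folds after a seeded shuffle of
#' subject order).
#'
#' @param panel an [EstrogenPanel-class] with >= 3 subjects per group.
#' @param n_orthogonal number of orthogonal components (default 1).
#' @param n_folds cross-validation folds for Q2 (default 7).
#' @param cv_seed seed for the CV fold shuffle.
#' @return An [OPLSDAResult-class].
#' @export
#' @examples
#' pan <- simulateEstrogens(defaultEstrogenSimSpec(), 50, seed = 1)
#' fit <- oplsDA(pan)
#' fit
oplsDA <- function(panel, n_orthogonal = 1, n_folds = 7, cv_seed = 7) {
  grp <- groupLabels(panel)
  if (sum(grp == "control") < 3 || sum(grp == "case") < 3)
    stop("each group needs at least 3 subjects")
  X <- t(concentrations(panel))              # subjects x analytes
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("analyte(s) with zero variance: ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  ctr <- colMeans(X)
  Xs <- scale(X, center = ctr, scale = sds)
  y <- ifelse(grp == "case", 1, -1)
  y <- y - mean(y)
  n_orthogonal <- as.integer(n_orthogonal)
  fit <- .oplsCore(Xs, y, n_orthogonal)
  k_o <- ncol(fit$w_o)

  ssx <- sum(Xs^2)
  ssx_pred <- sum(fit$t^2) * sum(fit$p^2)
  ssx_orth <- if (k_o > 0)
    sum(vapply(seq_len(k_o), function(k)
      sum(fit$t_o[, k]^2) * sum(fit$p_o[, k]^2), numeric(1)))
  else 0
  R2X <- (ssx_pred + ssx_orth) / ssx
  ssy <- sum(y^2)
  ssy_pred <- fit$c_y^2 * sum(fit$t^2)
  R2Y <- ssy_pred / ssy

  # Q2 by k-fold CV: seeded shuffle, then contiguous blocks; the global
  # RNG state is restored afterwards
  n <- nrow(Xs)
  if (exists(".Random.seed", envir = globalenv())) {
    rs <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", rs, envir = globalenv()), add = TRUE)
  }
  set.seed(cv_seed)
  perm <- sample.int(n)
  folds <- split(perm, cut(seq_len(n), breaks = n_folds, labels = FALSE))
  press <- 0
  for (f in folds) {
    tr <- setdiff(seq_len(n), f)
    if (length(unique(grp[tr])) < 2) next
    ctr_tr <- colMeans(X[tr, , drop = FALSE])
    sd_tr <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    sd_tr[sd_tr == 0] <- 1
    Xtr <- scale(X[tr, , drop = FALSE], ctr_tr, sd_tr)
    y_raw <- ifelse(grp == "case", 1, -1)
    ytr <- y_raw[tr] - mean(y_raw[tr])
    cvfit <- .oplsCore(Xtr, ytr, n_orthogonal)
    Xte <- scale(X[f, , drop = FALSE], ctr_tr, sd_tr)
    yhat <- .oplsPredict(cvfit, Xte)
    press <- press + sum((y_raw[f] - mean(y_raw[tr]) - yhat)^2)
  }
  Q2 <- 1 - press / ssy

  # total-VIP: predictive + orthogonal weights, weighted by the Y
  # variance each component explains
  p_var <- ncol(Xs)
  ssy_comp <- ssy_pred
  W2 <- matrix(fit$w^2, ncol = 1)
  if (k_o > 0) {
    ssy_o <- vapply(seq_len(k_o), function(k)
      sum(y * fit$t_o[, k])^2 / sum(fit$t_o[, k]^2), numeric(1))
    ssy_comp <- c(ssy_comp, ssy_o)
    W2 <- cbind(W2, fit$w_o^2)
  }
  vip <- sqrt(p_var * as.numeric(W2 %*% ssy_comp) / sum(ssy_comp))
  names(vip) <- colnames(Xs)

  new("OPLSDAResult",
      analytes = colnames(Xs),
      groups = grp,
      scoresPred = stats::setNames(fit$t, rownames(Xs)),
      loadingsPred = stats::setNames(fit$p, colnames(Xs)),
      weightsPred = stats::setNames(fit$w, colnames(Xs)),
      scoresOrtho = fit$t_o,
      loadingsOrtho = fit$p_o,
      weightsOrtho = fit$w_o,
      yLoading = fit$c_y,
      R2X = R2X, R2Y = R2Y, Q2 = Q2,
      vip = vip,
      center = ctr, scale = sds,
      nOrtho = k_o)
}

#' VIP scores and biomarker selection from an OPLS-DA fit
#'
#' Variable importance in projection:
#' `VIP_j = sqrt(p * sum_a SSY_a w_ja^2 / sum_a SSY_a)` over the
#' retained components, where `SSY_a` is the class variance explained by
#' component a and `w_a` the unit-norm component weights, so that the
#' squared VIPs average to 1. Analytes with VIP above the threshold are
#' flagged as candidate biomarkers. With `predictive_only = TRUE` the
#' sum runs over the predictive component alone.
#'
#' @param model a fitted [OPLSDAResult-class].
#' @param threshold biomarker cutoff (default 1.0).
#' @param predictive_only restrict the VIP sum to the predictive
#'   component.
#' @return list with `vip` (named vector) and `biomarkers` (analytes
#'   with VIP > threshold, in decreasing VIP order).
#' @export
#' @examples
#' pan <- simulateEstrogens(defaultEstrogenSimSpec(), 50, seed = 1)
#' vipScores(oplsDA(pan))$biomarkers
vipScores <- function(model, threshold = 1.0, predictive_only = FALSE) {
  stopifnot(is(model, "OPLSDAResult"))
  vip <- model@vip
  if (predictive_only) {
    p_var <- length(model@analytes)
    vip <- sqrt(p_var * model@weightsPred^2)
    names(vip) <- model@analytes
  }
  sel <- vip[vip > threshold]
  list(vip = vip,
       biomarkers = names(sel)[order(sel, decreasing = TRUE)])
}
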