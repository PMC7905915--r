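test_that("per-analyte comparisons report means, SEMs and tiers", {
  cc <- matrix(rep(c(1, 2, 3, 4), each = 4), nrow = 4, byrow = TRUE)
  rownames(cc) <- paste0("a", 1:4)
  pan <- EstrogenPanel(cc, group = rep(c("control", "case"), each = 2))
  cmp <- compareAnalytes(pan)
  # identical groups per analyte: t = 0, p = 1
  expect_true(all(cmp$t_statistic == 0))
  expect_true(all(cmp$p_value == 1))
  expect_true(all(cmp$tier == ""))
  expect_equal(cmp$mean_control, c(1, 2, 3, 4))
})

test_that("a strong fold-change is detected with p < 0.01 almost surely", {
  spec <- defaultEstrogenSimSpec()
  spec$sdlog <- 0.2
  spec$fold_change[spec$analyte == "E2"] <- 2
  hits <- vapply(1:100, function(s) {
    pan <- simulateEstrogens(spec, 50, seed = 4000 + s)
    cmp <- compareAnalytes(pan)
    row <- cmp[cmp$analyte == "E2", ]
    row$mean_case > row$mean_control && row$p_value < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("shuffled labels give a calibrated p distribution", {
  pan <- simulateEstrogens(defaultEstrogenSimSpec(), 40, seed = 8)
  cc <- concentrations(pan)
  set.seed(9)
  ps <- replicate(300, {
    shuffled <- EstrogenPanel(cc, group = sample(
      rep(c("control", "case"), each = 40)))
    compareAnalytes(shuffled)$p_value[1]
  })
  expect_gt(mean(ps < 0.05), 0.02)
  expect_lt(mean(ps < 0.05), 0.09)
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("OPLS-DA separates constructed separable clouds", {
  set.seed(17)
  n <- 30
  cc <- matrix(rlnorm(11 * 2 * n, 3, 0.1), nrow = 11)
  rownames(cc) <- estrogenAnalytes()
  # one analyte carries complete separation
  cc["E2", ] <- c(rlnorm(n, 2, 0.1), rlnorm(n, 5, 0.1))
  pan <- EstrogenPanel(cc, group = rep(c("control", "case"), each = n))
  fit <- oplsDA(pan)
  grp <- groupLabels(fit)
  expect_gt(fit@R2Y, 0.9)
  expect_gt(min(fit@scoresPred[grp == "case"]),
            max(fit@scoresPred[grp == "control"]))
})

test_that("predictive scores are orthogonal to every orthogonal component", {
  pan <- simulateEstrogens(defaultEstrogenSimSpec(), 40, seed = 18)
  for (k in 1:3) {
    fit <- oplsDA(pan, n_orthogonal = k)
    for (j in seq_len(fit@nOrtho))
      expect_lt(abs(sum(fit@scoresPred * fit@scoresOrtho[, j])), 1e-8)
  }
})

test_that("zero orthogonal components reduce to single-component PLS-DA", {
  pan <- simulateEstrogens(defaultEstrogenSimSpec(), 35, seed = 19)
  fit <- oplsDA(pan, n_orthogonal = 0)
  X <- scale(t(concentrations(pan)))
  y <- ifelse(groupLabels(pan) == "case", 1, -1)
  y <- y - mean(y)
  ref <- plsOneComp(X, y)
  # weights are sign-fixed by construction (w ~ X'y), so compare directly
  expect_equal(unname(fit@weightsPred), ref$w, tolerance = 1e-10)
  expect_equal(unname(fit@scoresPred), ref$t, tolerance = 1e-10)
  expect_equal(unname(fit@loadingsPred), ref$p, tolerance = 1e-10)
  expect_equal(fit@yLoading, ref$c, tolerance = 1e-10)
})

test_that("fit summaries respect their ranges and invariances", {
  pan <- simulateEstrogens(defaultEstrogenSimSpec(), 49, seed = 20)
  fit <- oplsDA(pan)
  expect_true(fit@R2X >= 0 && fit@R2X <= 1)
  expect_true(fit@R2Y >= 0 && fit@R2Y <= 1)
  expect_lte(fit@Q2, fit@R2Y)
  # invariant to analyte and subject order
  cc <- concentrations(pan)
  perm_r <- sample(nrow(cc)); perm_c <- sample(ncol(cc))
  pan2 <- EstrogenPanel(cc[perm_r, perm_c],
                        group = as.character(groupLabels(pan))[perm_c])
  fit2 <- oplsDA(pan2)
  expect_equal(fit2@R2X, fit@R2X, tolerance = 1e-10)
  expect_equal(fit2@R2Y, fit@R2Y, tolerance = 1e-10)
  expect_equal(fit2@vip[fit@analytes], fit@vip, tolerance = 1e-10)
  # rank-deficient input is an explicit error
  cc0 <- cc; cc0[1, ] <- 5
  expect_error(oplsDA(EstrogenPanel(cc0, groupLabels(pan))),
               "zero variance")
})

test_that("VIP normalization and biomarker selection behave", {
  pan <- simulateEstrogens(defaultEstrogenSimSpec(), 49, seed = 21)
  fit <- oplsDA(pan)
  expect_equal(sum(fit@vip^2), 11, tolerance = 1e-8)
  v <- vipScores(fit)
  expect_setequal(names(v$vip), estrogenAnalytes())
  expect_true(all(v$vip[v$biomarkers] > 1))
  vp <- vipScores(fit, predictive_only = TRUE)
  expect_equal(sum(vp$vip^2), 11, tolerance = 1e-8)
})

test_that("exactly the shifted analytes exceed VIP 1 in most seeds", {
  truth <- c("E1", "E2", "2/4-OHE1", "2-OHE2", "4-OHE2")
  hits <- vapply(1:40, function(s) {
    pan <- simulateEstrogens(defaultEstrogenSimSpec(), 49,
                             seed = 6000 + s)
    sel <- vipScores(oplsDA(pan))$biomarkers
    setequal(sel, truth)
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("uninformative analytes have expected VIP below 1", {
  spec <- defaultEstrogenSimSpec()
  vips <- vapply(1:30, function(s) {
    pan <- simulateEstrogens(spec, 49, seed = 7000 + s)
    oplsDA(pan)@vip[["E3"]]     # E3 carries no fold-change
  }, numeric(1))
  expect_lt(mean(vips), 1)
})

test_that("permuted labels drive Q2 to zero or below on average", {
  pan <- simulateEstrogens(defaultEstrogenSimSpec(), 40, seed = 22)
  cc <- concentrations(pan)
  set.seed(23)
  q2 <- replicate(60, {
    shuffled <- EstrogenPanel(cc, group = sample(
      rep(c("control", "case"), each = 40)))
    oplsDA(shuffled)@Q2
  })
  expect_lte(mean(q2), 0)
})
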