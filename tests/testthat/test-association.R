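test_that("cross-product OR with Woolf CI reproduces published values", {
  # SULT1A1 rs1042028 CT vs CC
  r <- genotypeOR(37, 98, 20, 117)
  expect_equal(round(r$or, 2), 2.21)
  expect_equal(round(r$ci_low, 2), 1.20)
  expect_equal(round(r$ci_high, 2), 4.05)
  expect_false(r$correction_applied)
  # CYP1B1 rs1056836 GC vs GG: protective
  r <- genotypeOR(21, 116, 44, 90)
  expect_equal(round(r$or, 2), 0.37)
  expect_equal(round(r$ci_low, 2), 0.21)
  expect_equal(round(r$ci_high, 2), 0.67)
  # symmetric table
  expect_equal(genotypeOR(10, 10, 10, 10)$or, 1.0)
})

test_that("zero cells get the Haldane-Anscombe correction", {
  # CYP1B1 rs1056827 AA vs CC: zero control minor-homs
  r <- genotypeOR(10, 80, 0, 92)
  expect_true(r$correction_applied)
  expect_equal(r$or, (10.5 * 92.5) / (0.5 * 80.5), tolerance = 1e-12)
  expect_equal(round(r$or, 2), 24.13)
  expect_true(r$ci_low <= r$or && r$or <= r$ci_high)
  # an empty margin stays an error even with the correction policy
  expect_error(genotypeOR(0, 0, 5, 5), "margin")
})

test_that("group-swap reciprocity holds for uncorrected tables", {
  set.seed(7)
  for (i in 1:20) {
    cells <- sample(1:50, 4)
    r1 <- genotypeOR(cells[1], cells[2], cells[3], cells[4])
    r2 <- genotypeOR(cells[2], cells[1], cells[4], cells[3])
    expect_equal(r1$or * r2$or, 1, tolerance = 1e-12)
    expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  }
})

test_that("genotype distribution test reproduces published p-values", {
  p <- function(ctrl, case)
    genotypeDistributionTest(genotypeCountTable(ctrl, case))$p_value
  expect_equal(round(p(c(100, 31, 9), c(80, 55, 5)), 3), 0.007)
  expect_equal(round(p(c(90, 44, 6), c(116, 21, 3)), 3), 0.002)
  expect_equal(round(p(c(92, 48, 0), c(80, 50, 10)), 3), 0.004)
  # identical columns
  r <- genotypeDistributionTest(genotypeCountTable(c(50, 30, 20),
                                                   c(50, 30, 20)))
  expect_equal(r$chi_square, 0)
  expect_equal(r$p_value, 1)
  # a class empty in both groups drops to df = 1
  r <- genotypeDistributionTest(genotypeCountTable(c(90, 50, 0),
                                                   c(70, 70, 0)))
  expect_equal(r$df, 1)
  expect_error(genotypeDistributionTest(
    genotypeCountTable(c(90, 0, 0), c(70, 0, 0))), "degenerate")
})

test_that("chi-square p decreases as the effect scales up", {
  base <- c(80, 50, 10)
  shift <- function(f) {
    # move f case subjects from major-hom to minor-hom
    genotypeCountTable(base, base + c(-f, 0, f))
  }
  ps <- vapply(0:5, function(f)
    genotypeDistributionTest(shift(f))$p_value, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("per-allele OR reproduces the published per-allele model", {
  tabs <- bundledCounts()
  expected <- c(rs1042028 = 1.97, rs1056827 = 1.61, rs1048943 = 1.43,
                rs700519 = 1.15, rs2981579 = 1.24, rs981782 = 1.20,
                rs4680 = 1.31, rs605059 = 1.09, rs7439366 = 1.09,
                rs10822013 = 0.87, rs3784099 = 1.03, rs3803662 = 0.98)
  for (id in names(expected))
    expect_equal(round(perAlleleOR(tabs[[id]])$or, 2),
                 unname(expected[id]), info = id)
  # Woolf CI for the strongest enzyme signal, checked against the hand
  # formula exp(log(OR) +/- z * sqrt(sum of reciprocal cells))
  r <- perAlleleOR(tabs[["rs1042028"]])
  se <- sqrt(1 / 47 + 1 / 233 + 1 / 26 + 1 / 254)
  expect_equal(r$ci_low, exp(log(r$or) - qnorm(0.975) * se),
               tolerance = 1e-12)
  expect_equal(round(r$ci_low, 2), 1.18)
  expect_equal(round(r$ci_high, 2), 3.28)
})

test_that("per-allele OR symmetries hold", {
  tab <- genotypeCountTable(c(50, 30, 20), c(50, 30, 20))
  expect_equal(perAlleleOR(tab)$or, 1.0)
  # allele-label swap reverses the table rows: reciprocal OR
  tab2 <- genotypeCountTable(c(60, 30, 10), c(40, 35, 25))
  swapped <- genotypeCountTable(c(10, 30, 60), c(25, 35, 40))
  expect_equal(perAlleleOR(tab2)$or * perAlleleOR(swapped)$or, 1,
               tolerance = 1e-12)
})

test_that("logistic per-allele fit agrees with allele counting", {
  spec <- data.frame(rs_id = "rsT1", control_maf = 0.25,
                     per_allele_or = 1.6)
  coh <- simulateGenotypes(spec, 20000, 20000, seed = 9,
                           panel = toyPanel(1))
  counting <- perAlleleOR(countsFromCohort(coh, "rsT1"))
  logistic <- perAlleleLogistic(coh, "rsT1")
  expect_equal(logistic$or, counting$or, tolerance = 0.02)
  expect_equal(logistic$or, 1.6, tolerance = 0.05)
  # identical group frequencies: OR ~ 1
  null <- simulateGenotypes(
    data.frame(rs_id = "rsT1", control_maf = 0.3, per_allele_or = 1),
    5000, 5000, seed = 10, panel = toyPanel(1))
  expect_equal(perAlleleLogistic(null, "rsT1")$or, 1, tolerance = 0.1)
  # monomorphic SNP is an error, not an OR
  mono <- GenotypeCohort(
    matrix(0L, 1, 8, dimnames = list("rsT1", NULL)),
    rep(c("control", "case"), 4), toyPanel(1))
  expect_error(perAlleleLogistic(mono, "rsT1"), "monomorphic")
})

test_that("association table assembles all SNPs and flags the right hits", {
  assoc <- associationTable(bundledCounts())
  expect_equal(nrow(assoc), 15)
  expect_equal(assoc$rs_id, names(bundledCounts()))
  hits <- assoc$rs_id[assoc$dist_p < 0.05]
  expect_setequal(hits, c("rs1048943", "rs1056827", "rs1056836",
                          "rs1042028"))
  expect_true(assoc$hom_corrected[assoc$rs_id == "rs1056827"])
  expect_equal(nrow(associationTable(list())), 0)
  # batch tolerates a degenerate SNP without aborting
  degen <- c(bundledCounts()[1:2],
             list(bad = genotypeCountTable(c(10, 0, 0), c(10, 0, 0))))
  out <- associationTable(degen)
  expect_equal(nrow(out), 3)
  expect_true(is.na(out$dist_p[3]))
  expect_false(anyNA(out$dist_p[1:2]))
})

test_that("report writer rounds to the conventional precision", {
  assoc <- associationTable(bundledCounts()[1:3])
  path <- withr::local_tempfile(fileext = ".tsv")
  writeAssociationReport(assoc, path)
  back <- read.delim(path)
  expect_equal(back$allele_or, round(assoc$allele_or, 2))
  expect_equal(back$dist_p, round(assoc$dist_p, 3))
})
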