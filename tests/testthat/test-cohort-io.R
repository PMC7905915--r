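test_that("genotype calls are recoded to minor-allele counts", {
  panel <- bundledPanel()
  tab <- data.frame(subject_id = c("s1", "s2", "s3", "s4"),
                    group = c("control", "control", "case", "case"),
                    rs700519 = c("GG", "GA", "AG", "AA"),
                    rs1042028 = c("CC", "CT", "NA", "TT"),
                    check.names = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  coh <- readGenotypeTable(path, panel)
  # unordered pairs: "GA" and "AG" both carry one minor allele
  expect_identical(unname(dosage(coh)["rs700519", ]), c(0L, 1L, 1L, 2L))
  expect_identical(unname(dosage(coh)["rs1042028", ]),
                   c(0L, 1L, NA, 2L))
  expect_equal(callRate(coh, "rs1042028"), 0.75)
  expect_equal(callRate(coh, "rs700519"), 1.0)
})

test_that("unknown alleles and duplicate subjects are errors", {
  panel <- bundledPanel()
  tab <- data.frame(subject_id = c("s1", "s2"),
                    group = c("control", "case"),
                    rs700519 = c("GT", "GG"),   # T not an allele here
                    check.names = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readGenotypeTable(path, panel), "allele")
  tab$rs700519 <- c("GG", "GA")
  tab$subject_id <- c("s1", "s1")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readGenotypeTable(path, panel), "duplicate")
})

test_that("write-then-read round-trips a cohort", {
  coh <- simulateGenotypes(defaultSNPSimSpec(), 6, 5, seed = 11)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeGenotypeTable(coh, path)
  back <- readGenotypeTable(path, bundledPanel())
  expect_identical(dosage(back), dosage(coh))
  expect_identical(as.character(groupLabels(back)),
                   as.character(groupLabels(coh)))
})

test_that("counts aggregate correctly, excluding missing calls", {
  panel <- toyPanel(1)
  d <- matrix(c(0L, 1L, NA, 2L, 1L), nrow = 1,
              dimnames = list(panel$rs_id, NULL))
  coh <- GenotypeCohort(d, c("control", "control", "control",
                             "case", "case"), panel)
  tab <- countsFromCohort(coh, "rsT1")
  expect_equal(unname(tab[, "control"]), c(1, 1, 0))
  expect_equal(unname(tab[, "case"]), c(0, 1, 1))
  expect_equal(sum(tab), 4)  # the missing control call is excluded
  expect_error(countsFromCohort(coh, "rsX"), "unknown")
})

test_that("recode-then-aggregate equals a direct hand count", {
  coh <- simulateGenotypes(defaultSNPSimSpec()[1:4, ], 17, 23, seed = 3)
  d <- dosage(coh)
  grp <- groupLabels(coh)
  for (id in rownames(d)) {
    tab <- countsFromCohort(coh, id)
    for (g in c("control", "case"))
      for (k in 0:2) {
        hand <- 0
        for (j in seq_len(ncol(d)))
          if (grp[j] == g && !is.na(d[id, j]) && d[id, j] == k)
            hand <- hand + 1
        expect_equal(unname(tab[k + 1, g]), hand)
      }
  }
})

test_that("a deterministic cohort aggregates back to its counts", {
  tabs <- bundledCounts()
  coh <- cohortFromCounts(tabs)
  expect_equal(ncol(coh), 280)
  for (id in names(tabs))
    expect_equal(countsFromCohort(coh, id), tabs[[id]],
                 ignore_attr = TRUE)
})

test_that("bundled fixture matches the published margins", {
  tabs <- bundledCounts()
  expect_length(tabs, 15)
  expect_true(all(vapply(tabs, function(t) all(colSums(t) == 140),
                         logical(1))))
  expect_equal(unname(tabs[["rs1042028"]][, "control"]), c(117, 20, 3))
  expect_equal(unname(tabs[["rs1042028"]][, "case"]), c(98, 37, 5))
  expect_equal(tabs[["rs1056827"]]["minor_hom", "control"], 0)
  panel <- bundledPanel()
  expect_equal(sum(panel$category == "enzyme"), 9)
  expect_equal(sum(panel$category == "gwas"), 6)
  expect_false(anyDuplicated(panel$rs_id) > 0)
  expect_true(all(panel$major_allele != panel$minor_allele))
})

test_that("VCF genotypes map to dosages with orientation handling", {
  panel <- bundledPanel()
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "s1", "s2", "s3", sep = "\t"),
           # ALT = minor allele
           paste("15", "51507968", "rs700519", "G", "A", ".", ".", ".",
                 "GT", "0/0", "0/1", "1/1", sep = "\t"),
           # REF = minor allele: dosage flips
           paste("16", "28617514", "rs1042028", "T", "C", ".", ".", ".",
                 "GT", "0/0", "0/1", "./.", sep = "\t"))
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  coh <- readGenotypeVCF(path, panel,
                         group = c("control", "case", "case"))
  expect_identical(unname(dosage(coh)["rs700519", ]), c(0L, 1L, 2L))
  expect_identical(unname(dosage(coh)["rs1042028", ]), c(2L, 1L, NA))

  multi <- c(vcf[1:4],
             paste("22", "19951271", "rs4680", "G", "A,C", ".", ".",
                   ".", "GT", "0/0", "0/1", "0/2", sep = "\t"))
  writeLines(multi, path)
  expect_error(readGenotypeVCF(path, panel,
                               group = c("control", "case", "case")),
               "multi-allelic")
})

test_that("cohort validity rejects malformed objects", {
  panel <- toyPanel(1)
  d <- matrix(3L, nrow = 1, dimnames = list(panel$rs_id, NULL))
  expect_error(GenotypeCohort(d, "case", panel), "dosage")
  d <- matrix(1L, nrow = 1, dimnames = list(panel$rs_id, NULL))
  expect_error(GenotypeCohort(d, "patient", panel), "control")
  bad <- panel; bad$minor_allele <- bad$major_allele
  expect_error(GenotypeCohort(d, "case", bad), "differ")
})
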