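# Independent oracles used across the suite. These deliberately take the
# slow, enumerative route so they share no code with the implementation.

# Exact HWE p-value by full enumeration of genotype sequences: list every
# vector in {0,1,2}^n, weight it by its HWE probability at an arbitrary
# allele frequency, condition on the observed minor-allele count, and sum
# the conditional probabilities of heterozygote counts no more probable
# than the observed one.
.enumCache <- new.env()

hweEnumTable <- function(n, p = 0.3) {
  key <- as.character(n)
  if (!is.null(.enumCache[[key]])) return(.enumCache[[key]])
  grid <- as.matrix(expand.grid(rep(list(0:2), n)))
  m <- rowSums(grid)
  hets <- rowSums(grid == 1)
  w <- p^m * (1 - p)^(2 * n - m) * 2^hets
  agg <- aggregate(list(w = w), list(m = m, het = hets), sum)
  .enumCache[[key]] <- agg
  agg
}

hweExactEnum <- function(counts, p = 0.3) {
  n <- sum(counts)
  minor <- 2 * counts[3] + counts[2]
  agg <- hweEnumTable(n, p)
  sub <- agg[agg$m == minor, ]
  prob <- sub$w / sum(sub$w)
  obs <- prob[sub$het == counts[2]]
  sum(prob[prob <= obs + 1e-12])
}

# AUC as the tie-corrected pairwise comparison count.
aucPairwise <- function(case, control) {
  cmp <- outer(case, control, ">") + 0.5 * outer(case, control, "==")
  mean(cmp)
}

# Single-component NIPALS PLS1 on a centred/scaled matrix: for one
# response the weight vector is proportional to X'y and NIPALS converges
# in a single pass.
plsOneComp <- function(X, y) {
  w <- crossprod(X, y)
  w <- w / sqrt(sum(w^2))
  t1 <- as.numeric(X %*% w)
  p1 <- as.numeric(crossprod(X, t1) / sum(t1^2))
  c1 <- sum(y * t1) / sum(t1^2)
  list(w = as.numeric(w), t = t1, p = p1, c = c1)
}

# Deterministic cohort whose per-SNP dosage vectors enumerate a set of
# genotype count tables exactly (no randomness).
cohortFromCounts <- function(tables, panel = bundledPanel()) {
  expand <- function(tab, col) {
    rep(0:2, tab[, col])
  }
  n_ctrl <- sum(tables[[1]][, "control"])
  n_case <- sum(tables[[1]][, "case"])
  d <- t(vapply(tables, function(tab)
    c(expand(tab, "control"), expand(tab, "case")),
    integer(n_ctrl + n_case)))
  rownames(d) <- names(tables)
  pan <- panel[match(names(tables), panel$rs_id), ]
  GenotypeCohort(d, group = rep(c("control", "case"),
                                c(n_ctrl, n_case)),
                 panel = pan)
}

toyPanel <- function(n = 2) {
  data.frame(rs_id = paste0("rsT", seq_len(n)),
             gene = paste0("GENE", seq_len(n)),
             major_allele = rep(c("G", "C"), length.out = n),
             minor_allele = rep(c("A", "T"), length.out = n),
             category = "enzyme")
}
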