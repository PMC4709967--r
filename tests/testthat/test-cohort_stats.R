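toy_matrix <- function(n1 = 10, n3 = 10, genes = c("gA", "gB"),
                       fill = 0) {
  m <- matrix(fill, n1 + n3, length(genes),
              dimnames = list(sprintf("s%02d", seq_len(n1 + n3)), genes))
  cohort_matrix(m, rep(c("I", "III"), c(n1, n3)))
}

test_that("gene frequencies and landscape bands classify correctly", {
  cm <- toy_matrix(10, 10, genes = c("g1", "g2", "g3", "g4", "g5"))
  cm$mut[1:3, "g1"] <- 1   # 15% -> mountain
  cm$mut[1:2, "g2"] <- 1   # 10% -> mountain (inclusive lower edge)
  cm$mut[1, "g3"] <- 1     # 5%  -> hill (inclusive lower edge)
  tab <- gene_frequency_table(cm)
  expect_equal(tab$frequency[tab$gene == "g1"], 0.15)
  expect_equal(tab$class[tab$gene == "g1"], "mountain")
  expect_equal(tab$class[tab$gene == "g2"], "mountain")
  expect_equal(tab$class[tab$gene == "g3"], "hill")
  expect_true(is.na(tab$class[tab$gene == "g4"]))
  expect_equal(tab$n_mutated[tab$gene == "g5"], 0)
})

test_that("printed percentages round half-up at the requested precision", {
  expect_equal(cohort_frequency(22, 104, 0), 21)
  expect_equal(cohort_frequency(6, 36, 1), 16.7)
  expect_equal(cohort_frequency(46, 104, 0), 44)
  expect_equal(cohort_frequency(8, 104, 0), 8)
  expect_equal(cohort_frequency(0, 57, 2), 0)
  # half-up, not banker's rounding
  expect_equal(cohort_frequency(1, 8, 0), 13)  # 12.5 -> 13
  expect_equal(cohort_frequency(25, 1000, 0), 3)  # 2.5 -> 3
})

test_that("SMG combination summary partitions the cohort", {
  cm <- toy_matrix(3, 2, genes = c("A", "B"))
  cm$mut[1, "A"] <- 1
  cm$mut[2, "A"] <- 1
  cm$mut[3, c("A", "B")] <- 1
  cm$mut[5, "B"] <- 1
  res <- smg_combination_summary(cm, c("A", "B"))
  expect_equal(res$n_zero, 1)
  expect_equal(res$n_one, 3)
  expect_equal(res$n_two_plus, 1)
  expect_equal(res$n_combinations, 3) # {A}, {A,B}, {B}
  expect_equal(res$n_zero + res$n_one + res$n_two_plus, 5)
  expect_error(smg_combination_summary(cm, "missing"), "unknown")
})

test_that("stage association builds the 2x2 table and matches the oracle", {
  cm <- toy_matrix(6, 6, genes = "gA")
  cm$mut[c(1:3, 7), "gA"] <- 1 # 3/6 stage I vs 1/6 stage III
  res <- stage_association_test(cm, "gA")
  expect_equal(unname(res$table["I", ]), c(3, 3))
  expect_equal(unname(res$table["III", ]), c(1, 5))
  expect_equal(res$p.value, fisher_oracle_two_sided(3, 3, 1, 5),
               tolerance = 1e-12)
  one <- stage_association_test(cm, "gA", "stage1_enriched")
  expect_equal(one$p.value, fisher_oracle_greater(3, 3, 1, 5),
               tolerance = 1e-12)
  # equal proportions carry no signal
  cm2 <- toy_matrix(5, 5, genes = "gA")
  cm2$mut[c(1:2, 6:7), "gA"] <- 1
  expect_equal(stage_association_test(cm2, "gA")$p.value, 1)
  # gene-set feature: any member mutation counts
  cm3 <- toy_matrix(4, 4, genes = c("gA", "gB"))
  cm3$mut[1, "gA"] <- 1; cm3$mut[2, "gB"] <- 1
  res3 <- stage_association_test(cm3, c("gA", "gB"))
  expect_equal(unname(res3$table["I", "yes"]), 2)
})

test_that("family-wise stage tests apply Benjamini-Hochberg", {
  set.seed(81)
  cm <- toy_matrix(20, 20, genes = paste0("g", 1:5))
  cm$mut[] <- rbinom(length(cm$mut), 1, 0.3)
  fam <- stage_association_family(
    cm, setNames(as.list(paste0("g", 1:5)), paste0("g", 1:5)))
  expect_equal(fam$p.adjust, p.adjust(fam$p.value, "BH"))
  expect_true(all(fam$p.adjust >= fam$p.value))
  expect_true(all(fam$p.adjust <= 1))
})

test_that("pathway enrichment is upper-tail hypergeometric with BH", {
  universe <- paste0("g", 1:20)
  pws <- list(all = universe, small = paste0("g", 1:5))
  mutated <- paste0("g", 1:5)
  res <- pathway_enrichment(mutated, pws, universe)
  # a pathway equal to the universe always fully overlaps: p = 1
  expect_equal(res$p.value[res$pathway == "all"], 1)
  # universe 20, pathway 5, mutated 5, overlap 4 (exclude g5 from overlap)
  pws2 <- list(pw = c(paste0("g", 1:4), "g20"))
  res2 <- pathway_enrichment(mutated, pws2, universe)
  hand <- sum(dhyper(4:5, 5, 15, 5))
  expect_equal(res2$p.value, hand, tolerance = 1e-12)
  expect_error(pathway_enrichment("gX", pws, universe), "universe")
  # textbook BH arithmetic
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
})

test_that("burden comparison is one-sided with reported direction", {
  # fully tied groups are uninformative
  expect_equal(compare_burden(rep(0.2, 4), rep(0.2, 4))$p.value, 1)
  # equal-but-spread groups: no evidence either (p frozen from the
  # subset-enumeration oracle)
  expect_equal(compare_burden(c(1, 2, 3), c(1, 2, 3))$p.value,
               rank_sum_oracle(c(1, 2, 3), c(1, 2, 3), "greater"))
  expect_gte(compare_burden(c(1, 2, 3), c(1, 2, 3))$p.value, 0.5)
  r <- compare_burden(1:3 / 10, 4:6 / 10)
  expect_equal(r$p.value, 1 / 20)
  expect_equal(r$direction, "stage3 > stage1")
  set.seed(82)
  b1 <- rnorm(40, 0.1, 0.05); b3 <- rnorm(40, 0.3, 0.05)
  r2 <- compare_burden(b1, b3)
  expect_lt(r2$p.value, 1e-6)
  expect_equal(r2$direction, "stage3 > stage1")
})

test_that("mutation spectrum folds purine references onto pyrimidines", {
  expect_equal(unname(mutation_spectrum("G", "A")["C>T"]), 1L)
  expect_equal(sum(mutation_spectrum(character(0), character(0))), 0L)
  ref <- c("C", "C", "G", "T", "A", "A", "G", "T", "C", "G", "T", "A")
  alt <- c("A", "T", "T", "G", "C", "G", "A", "C", "G", "C", "A", "T")
  sp <- mutation_spectrum(ref, alt)
  # hand tally: C>A:1 C>T:1 G>T(=C>A):1 T>G:1 A>C(=T>G):1 A>G(=T>C):1
  #             G>A(=C>T):1 T>C:1 C>G:1 G>C(=C>G):1 T>A:1 A>T(=T>A):1
  expect_equal(unname(sp), c(2L, 2L, 2L, 2L, 2L, 2L))
  expect_equal(sum(sp), 12L)
  expect_error(mutation_spectrum("C", "C"), "invalid")
})

test_that("null stage tests reject at roughly the nominal rate", {
  set.seed(83)
  n_feat <- 400
  cm <- toy_matrix(26, 26, genes = sprintf("g%03d", 1:n_feat))
  cm$mut[] <- rbinom(length(cm$mut), 1, 0.3)
  ps <- vapply(sprintf("g%03d", 1:n_feat), function(g) {
    stage_association_test(cm, g)$p.value
  }, numeric(1))
  rate <- mean(ps < 0.05)
  # Fisher is conservative on discrete tables: the rate must not exceed
  # the binomial 99.5% bound at alpha 0.05 and should not collapse to 0
  expect_lt(rate, 0.05 + 2.58 * sqrt(0.05 * 0.95 / n_feat))
  expect_gt(rate, 0)
})
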