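make_obs <- function(n_alt, n_ref, mapq = 60, baseq = 35,
                     offset5 = NULL, read_length = 90L,
                     alt_strand = NULL) {
  n <- n_alt + n_ref
  if (is.null(offset5)) offset5 <- rep(45L, n)
  strand <- rep(c("+", "-"), length.out = n)
  if (!is.null(alt_strand) && n_alt > 0) {
    strand[seq_len(n_alt)] <- alt_strand
  }
  data.frame(allele = rep(c("alt", "ref"), c(n_alt, n_ref)),
             mapq = rep_len(mapq, n), baseq = rep_len(baseq, n),
             offset5 = rep_len(offset5, n),
             read_length = rep_len(read_length, n),
             strand = strand, stringsAsFactors = FALSE)
}

test_that("allele-frequency contrast test matches the enumeration oracle", {
  expect_equal(vaf_contrast_test(10, 90, 10, 90), 1.0)
  expect_equal(vaf_contrast_test(10, 90, 1, 99),
               fisher_oracle_two_sided(10, 90, 1, 99), tolerance = 1e-12)
  set.seed(31)
  for (rep_i in 1:60) {
    tot <- sample(4:40, 1)
    cells <- as.vector(stats::rmultinom(1, tot, c(1, 3, 2, 4)))
    if (cells[1] + cells[2] == 0 || cells[3] + cells[4] == 0) next
    expect_equal(do.call(vaf_contrast_test, as.list(cells)),
                 do.call(fisher_oracle_two_sided, as.list(cells)),
                 tolerance = 1e-12)
  }
  expect_error(vaf_contrast_test(0, 0, 5, 5), "zero-depth")
})

test_that("strand-bias test matches the enumeration oracle", {
  expect_equal(strand_bias_test(5, 5, 50, 50), 1.0)
  p <- strand_bias_test(20, 0, 40, 48)
  expect_equal(p, fisher_oracle_two_sided(20, 0, 40, 48),
               tolerance = 1e-12)
  expect_lt(p, 1e-4) # rejected at the strand alpha
  p2 <- strand_bias_test(3, 2, 30, 25)
  expect_equal(p2, fisher_oracle_two_sided(3, 2, 30, 25),
               tolerance = 1e-12)
  expect_gt(p2, 0.5) # retained
  expect_error(strand_bias_test(0, 0, 0, 0), "all counts zero")
})

test_that("quality support tests follow the signed-rank null", {
  # values at the reference carry no information: criterion must fail
  expect_equal(mapq_support_test(rep(30, 10)), 1)
  expect_equal(baseq_support_test(rep(20, 6)), 1)
  expect_equal(mapq_support_test(rep(60, 10)), 2^-10)
  expect_equal(baseq_support_test(rep(38, 10)), 2^-10)
  x <- c(rep(60, 8), rep(10, 2))
  expect_equal(mapq_support_test(x), signed_rank_oracle(x, 30),
               tolerance = 1e-12)
  expect_error(mapq_support_test(numeric(0)))
})

test_that("read-end enrichment is detected and exchangeability retained", {
  # identically-placed alt and ref reads: no enrichment signal
  alt <- make_obs(8, 0, offset5 = c(10, 20, 30, 40, 50, 60, 70, 80))
  ref <- make_obs(0, 8, offset5 = c(10, 20, 30, 40, 50, 60, 70, 80))
  expect_gte(read_end_enrichment_test(alt, ref), 0.5)
  # all alt within 2 bp of an end vs central ref: strong enrichment
  alt2 <- make_obs(8, 0, offset5 = c(0, 1, 2, 88, 89, 87, 1, 88))
  ref2 <- make_obs(0, 8, offset5 = c(40, 42, 44, 46, 48, 50, 41, 43))
  p <- read_end_enrichment_test(alt2, ref2)
  expect_equal(p, rank_sum_oracle(
    pmin(alt2$offset5, 89 - alt2$offset5),
    pmin(ref2$offset5, 89 - ref2$offset5), "less"), tolerance = 1e-12)
  expect_lt(p, 0.1)
  # a single central alt read cannot look end-enriched
  expect_gt(read_end_enrichment_test(make_obs(1, 0, offset5 = 45),
                                     ref2), 0.1)
})

test_that("adjacency rule removes both members of close pairs", {
  expect_equal(adjacency_filter("chr1", 100), TRUE)
  expect_equal(adjacency_filter(rep("chr1", 3), c(100, 105, 200)),
               c(FALSE, FALSE, TRUE))
  # distance 11 is strictly over 10: both retained
  expect_equal(adjacency_filter(rep("chr1", 2), c(100, 111)), c(TRUE, TRUE))
  # boundary: distance exactly 10 removes the pair
  expect_equal(adjacency_filter(rep("chr1", 2), c(100, 110)),
               c(FALSE, FALSE))
  # chromosomes are independent
  expect_equal(adjacency_filter(c("chr1", "chr2"), c(100, 105)),
               c(TRUE, TRUE))
  # keep-first retains the left member
  expect_equal(adjacency_filter(rep("chr1", 3), c(100, 105, 200),
                                keep = "first"), c(TRUE, FALSE, TRUE))
})

test_that("evaluate_site applies depth, VAF and count gates", {
  th <- snv_thresholds()
  # normal depth below 10 fails criterion i regardless of anything else
  s <- site_evidence("chr1", 500, "C", "T", make_obs(25, 75), make_obs(0, 9))
  v <- evaluate_site(s, th)
  expect_false(v$c1)
  expect_false(v$pass)
  # clean constructed site passes overall
  set.seed(41)
  clean <- simulate_site_evidence("clean_somatic")$site
  expect_true(evaluate_site(clean, th)$pass)
  # tumor VAF 8%: fails discovery, passes validation criterion ii
  s8 <- site_evidence("chr1", 500, "C", "T", make_obs(8, 92),
                      make_obs(0, 100))
  expect_false(evaluate_site(s8, th, mode = "discovery")$c2)
  expect_true(evaluate_site(s8, th, mode = "validation")$c2)
  expect_error(evaluate_site(
    site_evidence("chr1", 1, "C", "T", make_obs(5, 5),
                  make_obs(0, 0)[0, ])), "normal evidence")
})

test_that("reads supporting neither allele count toward depth only", {
  tum <- make_obs(20, 70)
  other <- make_obs(0, 10)
  other$allele <- "other"
  s <- site_evidence("chr1", 1, "C", "T", rbind(tum, other),
                     make_obs(0, 100))
  v <- evaluate_site(s)
  expect_equal(v$tumor_depth, 100)
  expect_equal(v$tumor_alt, 20)
  expect_equal(v$tumor_vaf, 0.20)
})

test_that("filter_cohort applies adjacency and labels failures", {
  set.seed(42)
  sites <- lapply(1:6, function(i) {
    ls <- simulate_site_evidence("clean_somatic")
    ls$site$pos <- c(100, 105, 300, 400, 500, 600)[i]
    ls$site
  })
  res <- filter_cohort(sites)
  expect_equal(nrow(res$verdicts), 6)
  expect_false(any(res$pass[1:2])) # 100/105 removed by adjacency
  expect_equal(res$verdicts$filter[1], "c4")
  expect_true(all(res$verdicts$filter[res$pass] == "PASS"))
})

test_that("verdicts are a pure function of the evidence", {
  set.seed(43)
  s <- simulate_site_evidence("clean_somatic")$site
  expect_identical(evaluate_site(s), evaluate_site(s))
})
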