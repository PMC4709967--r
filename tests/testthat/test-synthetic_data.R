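small_cfg <- function(...) {
  sim_config(n_stage1 = 8L, n_stage3 = 8L, n_ah = 4L, n_genes = 20L,
             n_sites = 12L, n_reads = 20L,
             genome = data.frame(chrom = "chr1", length = 100000L),
             planted_cnv_regions = data.frame(
               chrom = "chr1", start = 20000L, end = 30000L,
               mean_cn = 3.2, stage = "both", frac = 0.5),
             ...)
}

test_that("invalid configurations are rejected", {
  expect_error(sim_config(background_rate = 1.2), "rates")
  expect_error(sim_config(site_class_mix = c(clean_somatic = 1)),
               "six site classes")
  mix <- c(clean_somatic = 0.5, germline = 0.2, low_vaf = 0.1,
           strand_artifact = 0.1, readend_artifact = 0.1,
           lowqual_artifact = 0.1)
  expect_error(sim_config(site_class_mix = mix), "sum to 1")
  expect_error(sim_config(genome = data.frame(chrom = character(),
                                              length = integer())),
               "genome")
  expect_error(simulate_site_evidence("weird"), "unknown site class")
})

test_that("identical config and seed reproduce identical cohorts", {
  cfg <- small_cfg(seed = 9L)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))
  s3 <- simulate_cohort(small_cfg(seed = 10L))
  expect_false(identical(s1$cohort$mut, s3$cohort$mut))
})

test_that("zero rates give an all-zero mutation matrix", {
  cfg <- small_cfg(seed = 3L, background_rate = 0,
                   planted_genes = data.frame(
                     gene = character(), rate_stage1 = numeric(),
                     rate_stage3 = numeric()))
  sim <- simulate_cohort(cfg)
  expect_true(all(sim$cohort$mut == 0))
})

test_that("planted stage-biased rates are recovered within binomial bands", {
  cfg <- sim_config(seed = 1L, n_stage1 = 51L, n_stage3 = 53L,
                    n_sites = 6L, n_reads = 5L, n_ah = 2L)
  sim <- simulate_cohort(cfg)
  k1 <- sum(sim$cohort$mut[sim$cohort$stage == "I", "gene001"])
  k3 <- sum(sim$cohort$mut[sim$cohort$stage == "III", "gene001"])
  # exact central 99% binomial intervals at the configured rates
  expect_true(k1 >= qbinom(0.005, 51, 0.35) &&
                k1 <= qbinom(0.995, 51, 0.35))
  expect_true(k3 >= qbinom(0.005, 53, 0.08) &&
                k3 <= qbinom(0.995, 53, 0.08))
})

test_that("empirical gene frequencies converge to configured rates", {
  cfg <- sim_config(seed = 5L, n_stage1 = 2500L, n_stage3 = 2500L,
                    n_genes = 10L, n_sites = 6L, n_reads = 5L, n_ah = 2L,
                    planted_genes = data.frame(gene = "gene001",
                                               rate_stage1 = 0.35,
                                               rate_stage3 = 0.08))
  sim <- simulate_cohort(cfg)
  f1 <- mean(sim$cohort$mut[sim$cohort$stage == "I", "gene001"])
  f3 <- mean(sim$cohort$mut[sim$cohort$stage == "III", "gene001"])
  bg <- mean(sim$cohort$mut[, "gene005"])
  expect_equal(f1, 0.35, tolerance = 0.1)
  expect_equal(f3, 0.08, tolerance = 0.3)
  expect_equal(bg, 0.03, tolerance = 0.35)
})

test_that("planted amplification lifts the in-region copy number", {
  cfg <- small_cfg(seed = 11L)
  sim <- simulate_cohort(cfg)
  in_means <- out_means <- numeric(0)
  for (s in names(sim$segments)) {
    seg <- sim$segments[[s]]
    in_means <- c(in_means, per_bp_mean_cn(seg, "chr1", 20000, 30000))
    left <- per_bp_mean_cn(seg, "chr1", 0, 20000)
    right <- per_bp_mean_cn(seg, "chr1", 30000, 100000)
    out_means <- c(out_means, (20000 * left + 70000 * right) / 90000)
  }
  # carriers raise the pooled in-region mean well above the outside mean
  expect_gt(mean(in_means), mean(out_means))
  expect_gt(mean(in_means), 2.2) # ~50% carriers at CN 3.2
})

test_that("site classes violate exactly the criteria they are built for", {
  cfg <- sim_config()
  set.seed(91)
  germ <- simulate_site_evidence("germline", cfg)
  v <- evaluate_site(germ$site)
  expect_equal(germ$truth_class, "germline")
  expect_gte(v$normal_vaf, 0.02)
  expect_false(v$c2)
  low <- simulate_site_evidence("low_vaf", cfg)
  expect_lt(evaluate_site(low$site)$tumor_vaf, 0.10)
  strand <- simulate_site_evidence("strand_artifact", cfg)
  expect_lt(evaluate_site(strand$site)$p9, 1e-4)
  re <- simulate_site_evidence("readend_artifact", cfg)
  vre <- evaluate_site(re$site)
  expect_lt(vre$p7, 0.1)
  expect_false(vre$c7)
  lq <- simulate_site_evidence("lowqual_artifact", cfg)
  expect_false(evaluate_site(lq$site)$c6)
  clean <- simulate_site_evidence("clean_somatic", cfg)
  expect_true(evaluate_site(clean$site)$pass)
})

test_that("standalone site seeds reproduce byte-identical evidence", {
  a <- simulate_site_evidence("clean_somatic", seed = 77L)
  b <- simulate_site_evidence("clean_somatic", seed = 77L)
  expect_identical(a, b)
})

test_that("simulated read records carry plausible QC structure", {
  cfg <- small_cfg(seed = 13L)
  sim <- simulate_cohort(cfg)
  expect_equal(nrow(sim$reads), 20)
  expect_true(all(nchar(sim$reads$seq) == cfg$read_length))
  expect_true(all(lengths(sim$reads$qual) == cfg$read_length))
  m <- compute_lane_metrics(sim$reads)
  expect_true(check_lane(m)$overall)
})

test_that("pathways partition the simulated gene universe", {
  sim <- simulate_cohort(small_cfg(seed = 15L))
  expect_setequal(unlist(sim$pathways), sim$genes$gene)
  expect_equal(sum(lengths(sim$pathways)), nrow(sim$genes))
})
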