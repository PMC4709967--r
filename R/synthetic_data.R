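#' Synthetic staged-cohort generator
#'
#' Generates every input the pipeline consumes, with the statistical
#' structure the analysis assumes: a two-stage tumor cohort (51 stage I
#' and 53 stage III samples by default) with planted stage-biased mutated
#' genes, per-sample absolute copy-number segments with planted recurrent
#' amplification/deletion regions, candidate SNV sites with per-read
#' tumor/normal evidence drawn from six labelled site classes, qPCR Ct
#' tables for atypical-hyperplasia validation samples, and FASTQ-like read
#' records for the QC gates. Everything is driven by a single seed and is
#' reproducible.
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' Defaults mirror the study design the pipeline targets: cohort sizes
#' 51/53, overdispersed sequencing depth around 100x (negative binomial),
#' 90-bp reads, one strongly stage-I-biased mutated gene (rates 0.35 vs
#' 0.08), a planted amplification (mean copy number 3.2, 40\% carrier
#' frequency, stage I) and a planted deletion (mean 1.0, 40\%, stage III),
#' and a higher rate of random altered segments in stage III than stage I
#' so that stage III carries the larger copy-number burden.
#'
#' @param seed RNG seed.
#' @param n_stage1,n_stage3 tumor cohort sizes by stage.
#' @param n_ah number of atypical-hyperplasia validation samples (qPCR).
#' @param genome data frame with `chrom`, `length` (bp).
#' @param n_genes number of genes in the mutation matrix.
#' @param planted_genes data frame `gene`, `rate_stage1`, `rate_stage3`.
#' @param background_rate per-gene per-sample mutation probability for
#'   unplanted genes.
#' @param planted_cnv_regions data frame `chrom`, `start`, `end`,
#'   `mean_cn`, `stage` (`"stage1"`, `"stage3"` or `"both"`), `frac`
#'   (carrier fraction within the biased stage).
#' @param alt_seg_rate_stage1,alt_seg_rate_stage3 probability that a
#'   background segment is altered (random gain or loss) by stage.
#' @param site_class_mix named proportions over the six site classes
#'   `clean_somatic`, `germline`, `low_vaf`, `strand_artifact`,
#'   `readend_artifact`, `lowqual_artifact`; must sum to 1.
#' @param n_sites number of candidate SNV sites to draw.
#' @param depth_mean,depth_size negative-binomial depth parameters.
#' @param read_length read length in bp.
#' @param clean_vaf expected tumor variant allele frequency of clean
#'   somatic sites.
#' @param normal_error background alt-read rate in normal tissue.
#' @param seg_len_bp mean background segment length.
#' @param cn_sigma Gaussian jitter (SD) around segment copy-number means.
#' @param n_reads,qc_n_rate,qc_adaptor_rate read-record generator settings.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_stage1 = 51L, n_stage3 = 53L, n_ah = 36L,
                       genome = data.frame(
                         chrom = c("chr1", "chr2"),
                         length = c(500000L, 500000L)),
                       n_genes = 100L,
                       planted_genes = data.frame(
                         gene = "gene001",
                         rate_stage1 = 0.35, rate_stage3 = 0.08),
                       background_rate = 0.03,
                       planted_cnv_regions = data.frame(
                         chrom = c("chr1", "chr2"),
                         start = c(100000L, 200000L),
                         end = c(120000L, 220000L),
                         mean_cn = c(3.2, 1.0),
                         stage = c("stage1", "stage3"),
                         frac = c(0.4, 0.4)),
                       alt_seg_rate_stage1 = 0.02,
                       alt_seg_rate_stage3 = 0.10,
                       site_class_mix = c(clean_somatic = 0.5,
                                          germline = 0.15,
                                          low_vaf = 0.1,
                                          strand_artifact = 0.1,
                                          readend_artifact = 0.1,
                                          lowqual_artifact = 0.05),
                       n_sites = 240L,
                       depth_mean = 100, depth_size = 20,
                       read_length = 90L,
                       clean_vaf = 0.25,
                       normal_error = 0.001,
                       seg_len_bp = 50000L,
                       cn_sigma = 0.15,
                       n_reads = 200L,
                       qc_n_rate = 0.005,
                       qc_adaptor_rate = 0.01) {
  cfg <- as.list(environment())
  classes <- c("clean_somatic", "germline", "low_vaf", "strand_artifact",
               "readend_artifact", "lowqual_artifact")
  if (!setequal(names(cfg$site_class_mix), classes)) {
    stop("site_class_mix must name the six site classes")
  }
  if (any(cfg$site_class_mix < 0) ||
      abs(sum(cfg$site_class_mix) - 1) > 1e-9) {
    stop("site class proportions must be in [0,1] and sum to 1")
  }
  rates <- c(cfg$planted_genes$rate_stage1, cfg$planted_genes$rate_stage3,
             cfg$background_rate, cfg$alt_seg_rate_stage1,
             cfg$alt_seg_rate_stage3, cfg$planted_cnv_regions$frac)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (nrow(cfg$genome) == 0 || any(cfg$genome$length <= 0)) {
    stop("genome must be non-empty with positive lengths")
  }
  structure(cfg, class = "sim_config")
}

.site_classes <- c("clean_somatic", "germline", "low_vaf",
                   "strand_artifact", "readend_artifact",
                   "lowqual_artifact")

# one read-observation block with given alt count and per-class quirks
.draw_obs <- function(n_alt, n_ref, read_length,
                      mapq_pool = c(60, 50, 40),
                      mapq_prob = c(0.85, 0.1, 0.05),
                      alt_baseq_pool = 28:40,
                      alt_strand_prob = 0.5,
                      alt_near_end = FALSE,
                      end_window = 5L) {
  n <- n_alt + n_ref
  offs <- sample.int(read_length, n, replace = TRUE) - 1L
  if (alt_near_end && n_alt > 0) {
    ends <- c(seq_len(end_window) - 1L,
              read_length - seq_len(end_window))
    offs[seq_len(n_alt)] <- sample(ends, n_alt, replace = TRUE)
  }
  strand <- ifelse(stats::runif(n) < 0.5, "+", "-")
  if (n_alt > 0) {
    strand[seq_len(n_alt)] <-
      ifelse(stats::runif(n_alt) < alt_strand_prob, "+", "-")
  }
  data.frame(
    allele = rep(c("alt", "ref"), c(n_alt, n_ref)),
    mapq = sample(mapq_pool, n, replace = TRUE, prob = mapq_prob),
    baseq = c(if (n_alt) sample(alt_baseq_pool, n_alt, replace = TRUE),
              if (n_ref) sample(28:40, n_ref, replace = TRUE)),
    offset5 = offs, read_length = read_length, strand = strand,
    stringsAsFactors = FALSE)
}

#' Simulate read evidence for one labelled candidate site
#'
#' Each site class is constructed to violate a specific somatic-filter
#' criterion (or none): `clean_somatic` satisfies all nine criteria by
#' construction (depths >= 10, tumor VAF >= 10\% with >= 3 alt reads,
#' normal VAF < 2\%, high alt MAPQ/baseQ, uniform read positions, balanced
#' strands); `germline` carries the tumor allele fraction in the normal;
#' `low_vaf` stays below 10\% tumor VAF; `strand_artifact` puts all alt
#' reads on one strand (with at least 20 alt reads, the count below which
#' an all-one-strand configuration cannot breach the 1e-4 rejection
#' threshold); `readend_artifact` places alt calls within 5 bp of a read
#' end; `lowqual_artifact` draws alt base qualities below 20.
#'
#' Class-defining properties hold by construction rather than merely in
#' expectation: count constraints are floored/capped, clean-site read
#' positions are redrawn while they would trip the read-end enrichment
#' test, and strand-artifact backgrounds are redrawn while the strand test
#' would fail to reject. The truth label is recorded independently of any
#' filter output.
#'
#' @param class one of the six site-class labels.
#' @param config a [sim_config()] (depth/read-length/VAF parameters).
#' @param seed optional seed for standalone use; `NULL` leaves the RNG
#'   stream untouched (for use inside [simulate_cohort()]).
#' @param chrom,pos locus to stamp on the site.
#' @return list of class `labeled_site` with elements `site`
#'   (a [site_evidence()]) and `truth_class`.
#' @export
simulate_site_evidence <- function(class, config = sim_config(),
                                   seed = NULL,
                                   chrom = "chr1", pos = 1000L) {
  if (!class %in% .site_classes) stop("unknown site class: ", class)
  if (!is.null(seed)) set.seed(seed)
  L <- config$read_length
  depth_t <- max(10L, stats::rnbinom(1, size = config$depth_size,
                                     mu = config$depth_mean))
  depth_n <- max(10L, stats::rnbinom(1, size = config$depth_size,
                                     mu = config$depth_mean))

  # tumor alt count by class
  alt_t <- switch(class,
    low_vaf = min(stats::rbinom(1, depth_t, 0.05),
                  as.integer(ceiling(0.10 * depth_t)) - 1L),
    germline = stats::rbinom(1, depth_t, 0.5),
    { # all other classes: somatic-like VAF, floored to satisfy ii-iii
      a <- stats::rbinom(1, depth_t, config$clean_vaf)
      max(a, 3L, as.integer(ceiling(0.10 * depth_t)))
    })
  # strand artifacts must carry enough alt reads for an all-one-strand
  # configuration to be rejectable at alpha 1e-4 (needs ~18 against a
  # balanced background; floored at 20)
  if (class == "strand_artifact") alt_t <- max(alt_t, 20L)
  alt_t <- max(0L, min(alt_t, depth_t))

  # normal alt count: sequencing noise, capped below 2% VAF except germline
  alt_n <- if (class == "germline") {
    stats::rbinom(1, depth_n, 0.5)
  } else {
    min(stats::rbinom(1, depth_n, config$normal_error),
        max(0L, as.integer(ceiling(0.02 * depth_n)) - 1L))
  }

  tumor_obs <- .draw_obs(
    alt_t, depth_t - alt_t, L,
    alt_baseq_pool = if (class == "lowqual_artifact") 5:18 else 28:40,
    alt_strand_prob = if (class == "strand_artifact") {
      if (stats::runif(1) < 0.5) 1 else 0
    } else 0.5,
    alt_near_end = class == "readend_artifact")

  # class-defining properties are guaranteed by construction, not just in
  # expectation: clean sites must not trip the read-end enrichment test
  # (positions are redrawn while they do), and strand artifacts must
  # actually breach the strand-bias rejection threshold (the balanced
  # background is redrawn while they do not).
  if (class == "clean_somatic" && alt_t > 0) {
    for (try in 1:100) {
      alt_rows <- which(tumor_obs$allele == "alt")
      ref_rows <- which(tumor_obs$allele == "ref")
      p7 <- read_end_enrichment_test(tumor_obs[alt_rows, , drop = FALSE],
                                     tumor_obs[ref_rows, , drop = FALSE])
      if (p7 >= 0.1) break
      tumor_obs$offset5 <- sample.int(L, nrow(tumor_obs),
                                      replace = TRUE) - 1L
    }
  }
  if (class == "strand_artifact" && alt_t > 0) {
    for (try in 1:100) {
      alt_rows <- tumor_obs$allele == "alt"
      ref_rows <- tumor_obs$allele == "ref"
      p9 <- strand_bias_test(sum(tumor_obs$strand[alt_rows] == "+"),
                             sum(tumor_obs$strand[alt_rows] == "-"),
                             sum(tumor_obs$strand[ref_rows] == "+"),
                             sum(tumor_obs$strand[ref_rows] == "-"))
      if (p9 < 1e-4) break
      tumor_obs$strand[ref_rows] <-
        ifelse(stats::runif(sum(ref_rows)) < 0.5, "+", "-")
    }
  }
  normal_obs <- .draw_obs(alt_n, depth_n - alt_n, L)

  structure(list(site = site_evidence(chrom, pos, "C", "T",
                                      tumor_obs, normal_obs),
                 truth_class = class),
            class = "labeled_site")
}

.sample_ids <- function(cfg) {
  n <- cfg$n_stage1 + cfg$n_stage3
  sprintf("T%03d", seq_len(n))
}

.simulate_mutations <- function(cfg, samples, stage) {
  genes <- sprintf("gene%03d", seq_len(cfg$n_genes))
  rate1 <- stats::setNames(rep(cfg$background_rate, cfg$n_genes), genes)
  rate3 <- rate1
  pg <- cfg$planted_genes
  if (nrow(pg)) {
    if (!all(pg$gene %in% genes)) stop("planted gene outside gene set")
    rate1[pg$gene] <- pg$rate_stage1
    rate3[pg$gene] <- pg$rate_stage3
  }
  mut <- vapply(genes, function(g) {
    p <- ifelse(stage == "I", rate1[[g]], rate3[[g]])
    stats::rbinom(length(samples), 1L, p)
  }, integer(length(samples)))
  rownames(mut) <- samples
  cohort_matrix(mut, stage)
}

.simulate_segments_one <- function(cfg, stage, carrier_regions) {
  alt_rate <- if (stage == "I") cfg$alt_seg_rate_stage1 else
    cfg$alt_seg_rate_stage3
  segs <- list()
  for (i in seq_len(nrow(cfg$genome))) {
    len <- cfg$genome$length[i]
    chrom <- cfg$genome$chrom[i]
    bounds <- unique(sort(c(
      seq(0L, len, by = cfg$seg_len_bp), len,
      carrier_regions$start[carrier_regions$chrom == chrom],
      carrier_regions$end[carrier_regions$chrom == chrom])))
    start <- bounds[-length(bounds)]
    end <- bounds[-1L]
    base <- rep(2, length(start))
    altered <- stats::runif(length(start)) < alt_rate
    base[altered] <- sample(c(1.0, 3.0), sum(altered), replace = TRUE)
    cr <- carrier_regions[carrier_regions$chrom == chrom, , drop = FALSE]
    if (nrow(cr)) {
      for (j in seq_len(nrow(cr))) {
        inside <- start >= cr$start[j] & end <= cr$end[j]
        base[inside] <- cr$mean_cn[j]
      }
    }
    cn <- pmax(0, stats::rnorm(length(start), base, cfg$cn_sigma))
    segs[[i]] <- data.frame(chrom = chrom, start = start, end = end,
                            copy_number = cn, stringsAsFactors = FALSE)
  }
  do.call(rbind, segs)
}

.simulate_ct <- function(cfg, qpcr_genes = c("AMP1", "DEL1"),
                         true_cn_draw) {
  samples <- c("CAL", sprintf("AH%03d", seq_len(cfg$n_ah)))
  rows <- list()
  for (s in samples) {
    ct_ref_base <- stats::rnorm(1, 25, 0.3)
    for (rep_i in 1:3) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, assay = "reference", gene = "RNaseP",
        ct = ct_ref_base + stats::rnorm(1, 0, 0.05),
        replicate = rep_i, calibrator = s == "CAL",
        stringsAsFactors = FALSE)
    }
    for (g in qpcr_genes) {
      cn <- if (s == "CAL") 2 else true_cn_draw(g)
      for (rep_i in 1:3) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample = s, assay = "target", gene = g,
          ct = ct_ref_base - log2(cn / 2) + stats::rnorm(1, 0, 0.05),
          replicate = rep_i, calibrator = s == "CAL",
          stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, rows)
  structure(df, class = c("ct_table", "data.frame"))
}

.simulate_reads <- function(cfg) {
  qpool <- c(2:20, 30:40)
  qprob <- c(rep(0.002, 19), rep((1 - 0.038) / 11, 11))
  seqs <- character(cfg$n_reads)
  quals <- vector("list", cfg$n_reads)
  # lane-wide base pool with exactly balanced composition, so the GC/AT
  # separation of a passing lane stays near zero at any read count
  total <- cfg$n_reads * cfg$read_length
  pool <- sample(rep(c("A", "C", "G", "T"), length.out = total))
  for (i in seq_len(cfg$n_reads)) {
    b <- pool[((i - 1) * cfg$read_length + 1):(i * cfg$read_length)]
    nmask <- stats::runif(cfg$read_length) < cfg$qc_n_rate
    b[nmask] <- "N"
    seqs[i] <- paste(b, collapse = "")
    quals[[i]] <- sample(qpool, cfg$read_length, replace = TRUE,
                         prob = qprob)
  }
  read_records(seqs, quals,
               adaptor = stats::runif(cfg$n_reads) < cfg$qc_adaptor_rate)
}

#' Simulate a full staged cohort
#'
#' Draws, under a single seed: the binary mutation matrix with stage
#' labels; per-tumor-sample copy-number segment sets with planted
#' recurrent regions; labelled candidate SNV sites with per-read
#' tumor/normal evidence (site loci are spaced 1 kb apart so the
#' adjacency rule is not triggered by construction); a triplicate qPCR Ct
#' table over atypical-hyperplasia samples with one amplified and one
#' deleted assay; FASTQ-like read records; gene models tiled along the
#' genome; and a pathway database partitioning the gene set.
#'
#' @param config a [sim_config()] object.
#' @return list of class `sim_cohort` with elements `cohort`
#'   (a [cohort_matrix()]), `segments` (named list of per-sample segment
#'   data frames), `sites` (list of `labeled_site`), `ct`
#'   (a [ct_table()]), `reads` (a [read_records()] frame), `genes`
#'   (gene-model data frame), `pathways` (named list), and `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  samples <- .sample_ids(cfg)
  stage <- rep(c("I", "III"), c(cfg$n_stage1, cfg$n_stage3))

  cohort <- .simulate_mutations(cfg, samples, stage)

  # carriers of each planted region, drawn within the biased stage
  segments <- vector("list", length(samples))
  names(segments) <- samples
  pr <- cfg$planted_cnv_regions
  carrier <- matrix(FALSE, length(samples), max(1L, nrow(pr)))
  if (nrow(pr)) {
    for (j in seq_len(nrow(pr))) {
      eligible <- switch(pr$stage[j],
                         stage1 = stage == "I",
                         stage3 = stage == "III",
                         both = rep(TRUE, length(samples)))
      carrier[eligible, j] <- stats::runif(sum(eligible)) < pr$frac[j]
    }
  }
  for (i in seq_along(samples)) {
    cr <- if (nrow(pr)) pr[carrier[i, seq_len(nrow(pr))], , drop = FALSE]
      else pr
    segments[[i]] <- .simulate_segments_one(cfg, stage[i], cr)
  }

  # labelled candidate sites, 1 kb apart along the genome
  n_per_class <- round(cfg$site_class_mix * cfg$n_sites)
  class_seq <- rep(names(n_per_class), n_per_class)
  sites <- vector("list", length(class_seq))
  for (i in seq_along(class_seq)) {
    sites[[i]] <- simulate_site_evidence(
      class_seq[i], cfg, seed = NULL,
      chrom = cfg$genome$chrom[1],
      pos = i * 1000L)
  }

  ct <- .simulate_ct(cfg, true_cn_draw = function(g) {
    if (g == "AMP1") {
      if (stats::runif(1) < 0.4) 3.2 else 2
    } else {
      if (stats::runif(1) < 0.3) {
        if (stats::runif(1) < 0.5) 0.2 else 1.0
      } else 2
    }
  })

  reads <- .simulate_reads(cfg)

  # gene models: tile n_genes along the genome in 2-kb intervals
  per_chrom <- ceiling(cfg$n_genes / nrow(cfg$genome))
  gene_rows <- list()
  g <- 0L
  for (i in seq_len(nrow(cfg$genome))) {
    k <- min(per_chrom, cfg$n_genes - g)
    if (k <= 0) break
    starts <- round(seq(0, cfg$genome$length[i] - 2000, length.out = k))
    gene_rows[[i]] <- data.frame(
      gene = sprintf("gene%03d", g + seq_len(k)),
      chrom = cfg$genome$chrom[i],
      start = as.integer(starts), end = as.integer(starts + 2000L),
      stringsAsFactors = FALSE)
    g <- g + k
  }
  genes <- do.call(rbind, gene_rows)

  pw_id <- sprintf("pw%02d", ((seq_len(cfg$n_genes) - 1L) %/% 10L) + 1L)
  pathways <- split(genes$gene, pw_id)

  structure(list(cohort = cohort, segments = segments, sites = sites,
                 ct = ct, reads = reads, genes = genes,
                 pathways = pathways, config = cfg),
            class = "sim_cohort")
}
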