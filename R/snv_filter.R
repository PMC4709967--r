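#' High-confidence somatic SNV filtering from tumor/normal read evidence
#'
#' Nine read-level criteria decide whether a candidate single-nucleotide
#' variant is a high-confidence somatic call:
#' \enumerate{
#'   \item tumor and normal depth both >= 10x;
#'   \item tumor variant allele frequency (VAF) >= 10\% (5\% in validation
#'     mode) and normal VAF < 2\%;
#'   \item at least 3 tumor reads support the alternate allele;
#'   \item no other candidate within 10 bp on the same chromosome
#'     (applied cohort-wide by [adjacency_filter()]);
#'   \item mapping qualities of alt-supporting tumor reads significantly
#'     above 30 (one-sided signed-rank, p < 0.2);
#'   \item base qualities of alt-supporting tumor reads significantly above
#'     20 (one-sided signed-rank, p < 0.05);
#'   \item alt calls not enriched within 5 bp of read ends (one-sided
#'     rank-sum on distance to nearest read end, reject at p < 0.1);
#'   \item tumor-vs-normal allele-frequency contrast significant
#'     (two-sided Fisher, p < 0.05);
#'   \item no strand bias of alt vs ref reads (two-sided Fisher; the site is
#'     rejected at p < 0.0001).
#' }
#' All alpha comparisons are strict (`p < alpha`), and count/VAF thresholds
#' are inclusive exactly as written above.
#'
#' @name snv_filter
NULL

#' Thresholds for the somatic SNV filter
#'
#' Defaults are the discovery-mode values; `validation_min_vaf` replaces
#' `min_tumor_vaf` when a site is evaluated in validation (deep targeted
#' re-sequencing) mode so that low-frequency mutations are retained.
#'
#' @param min_depth minimum tumor and normal depth (reads).
#' @param min_tumor_vaf minimum tumor VAF in discovery mode.
#' @param max_normal_vaf tumor sites must show normal VAF strictly below this.
#' @param min_alt_reads minimum alt-supporting tumor reads.
#' @param min_adjacent_distance_bp candidates closer than or equal to this
#'   are mutually removed.
#' @param mapq_ref_value,mapq_alpha reference MAPQ and alpha for criterion v.
#' @param baseq_ref_value,baseq_alpha reference base quality and alpha for
#'   criterion vi.
#' @param readend_window_bp read-end window (bp) used by the simulator's
#'   artifact class; the test itself ranks distances.
#' @param readend_alpha rejection alpha for criterion vii.
#' @param vaf_contrast_alpha alpha for criterion viii.
#' @param strand_alpha rejection alpha for criterion ix.
#' @param validation_min_vaf tumor VAF floor in validation mode.
#' @return list of class `snv_thresholds`.
#' @export
snv_thresholds <- function(min_depth = 10L,
                           min_tumor_vaf = 0.10,
                           max_normal_vaf = 0.02,
                           min_alt_reads = 3L,
                           min_adjacent_distance_bp = 10L,
                           mapq_ref_value = 30, mapq_alpha = 0.2,
                           baseq_ref_value = 20, baseq_alpha = 0.05,
                           readend_window_bp = 5L, readend_alpha = 0.1,
                           vaf_contrast_alpha = 0.05,
                           strand_alpha = 0.0001,
                           validation_min_vaf = 0.05) {
  th <- list(min_depth = min_depth, min_tumor_vaf = min_tumor_vaf,
             max_normal_vaf = max_normal_vaf, min_alt_reads = min_alt_reads,
             min_adjacent_distance_bp = min_adjacent_distance_bp,
             mapq_ref_value = mapq_ref_value, mapq_alpha = mapq_alpha,
             baseq_ref_value = baseq_ref_value, baseq_alpha = baseq_alpha,
             readend_window_bp = readend_window_bp,
             readend_alpha = readend_alpha,
             vaf_contrast_alpha = vaf_contrast_alpha,
             strand_alpha = strand_alpha,
             validation_min_vaf = validation_min_vaf)
  alphas <- c(th$mapq_alpha, th$baseq_alpha, th$readend_alpha,
              th$vaf_contrast_alpha, th$strand_alpha)
  if (any(alphas <= 0 | alphas >= 1)) stop("alphas must lie in (0, 1)")
  if (th$min_depth < 1 || th$min_alt_reads < 1) {
    stop("count thresholds must be positive")
  }
  structure(th, class = "snv_thresholds")
}

#' Per-read observation table for one candidate site
#'
#' Builds the evidence container the nine criteria judge: a tumor and a
#' normal set of per-read observations. Observation data frames carry the
#' columns `allele` (`"ref"`, `"alt"` or `"other"`), `mapq`, `baseq`,
#' `offset5` (0-based offset of the variant position from the 5' read end),
#' `read_length` and `strand` (`"+"`/`"-"`).
#'
#' @param chrom,pos,ref,alt locus (1-based position) and alleles.
#' @param tumor_obs,normal_obs per-read observation data frames.
#' @return object of class `site_evidence`.
#' @export
site_evidence <- function(chrom, pos, ref, alt, tumor_obs, normal_obs) {
  for (obs in list(tumor_obs, normal_obs)) {
    stopifnot(is.data.frame(obs),
              all(c("allele", "mapq", "baseq", "offset5", "read_length",
                    "strand") %in% names(obs)))
    if (nrow(obs) &&
        any(obs$offset5 < 0 | obs$offset5 >= obs$read_length)) {
      stop("offset5 must satisfy 0 <= offset5 < read_length")
    }
  }
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 ref = ref, alt = alt,
                 tumor_obs = tumor_obs, normal_obs = normal_obs),
            class = "site_evidence")
}

.allele_counts <- function(obs) {
  c(depth = nrow(obs),
    alt = sum(obs$allele == "alt"),
    ref = sum(obs$allele == "ref"))
}

#' Tumor-vs-normal allele-frequency contrast (criterion viii)
#'
#' Two-sided Fisher exact test on the 2x2 alt/ref-by-sample table.
#'
#' @param tumor_alt,tumor_ref,normal_alt,normal_ref allele counts.
#' @return the p-value.
#' @export
vaf_contrast_test <- function(tumor_alt, tumor_ref, normal_alt, normal_ref) {
  counts <- c(tumor_alt, tumor_ref, normal_alt, normal_ref)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (tumor_alt + tumor_ref == 0 || normal_alt + normal_ref == 0) {
    stop("zero-depth sample")
  }
  stats::fisher.test(matrix(counts, nrow = 2, byrow = TRUE))$p.value
}

#' Strand-bias test for alt-supporting reads (criterion ix)
#'
#' Two-sided Fisher exact test of strand distribution of alt vs ref reads.
#' The caller rejects the site when the p-value falls below `strand_alpha`.
#'
#' @param alt_fwd,alt_rev,ref_fwd,ref_rev strand counts.
#' @return the p-value.
#' @export
strand_bias_test <- function(alt_fwd, alt_rev, ref_fwd, ref_rev) {
  counts <- c(alt_fwd, alt_rev, ref_fwd, ref_rev)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("all counts zero")
  stats::fisher.test(matrix(counts, nrow = 2, byrow = TRUE))$p.value
}

#' Mapping-quality support test (criterion v)
#'
#' One-sided signed-rank test that alt-read mapping qualities exceed the
#' reference value (default 30). Values exactly at the reference are
#' uninformative; if all are, p = 1 and the criterion fails.
#'
#' @param alt_mapqs mapping qualities of alt-supporting tumor reads.
#' @param ref_value reference MAPQ.
#' @return the p-value.
#' @export
mapq_support_test <- function(alt_mapqs, ref_value = 30) {
  if (length(alt_mapqs) == 0) stop("no alt-supporting reads")
  signed_rank_test(alt_mapqs, mu = ref_value, alternative = "greater")$p.value
}

#' Base-quality support test (criterion vi)
#'
#' As [mapq_support_test()] with reference value 20.
#'
#' @param alt_baseqs base qualities of alt-supporting tumor reads.
#' @param ref_value reference base quality.
#' @return the p-value.
#' @export
baseq_support_test <- function(alt_baseqs, ref_value = 20) {
  if (length(alt_baseqs) == 0) stop("no alt-supporting reads")
  signed_rank_test(alt_baseqs, mu = ref_value, alternative = "greater")$p.value
}

#' Read-end enrichment test (criterion vii)
#'
#' Each observation is scored by its distance to the nearest read end,
#' `min(offset5, read_length - 1 - offset5)`; a one-sided rank-sum test asks
#' whether alt distances are smaller than ref distances. The caller rejects
#' the site when p < `readend_alpha`.
#'
#' @param alt_obs,ref_obs observation data frames (see [site_evidence()]).
#' @return the p-value.
#' @export
read_end_enrichment_test <- function(alt_obs, ref_obs) {
  if (nrow(alt_obs) == 0 || nrow(ref_obs) == 0) stop("empty read group")
  d_alt <- pmin(alt_obs$offset5, alt_obs$read_length - 1 - alt_obs$offset5)
  d_ref <- pmin(ref_obs$offset5, ref_obs$read_length - 1 - ref_obs$offset5)
  rank_sum_test(d_alt, d_ref, alternative = "less")$p.value
}

#' Adjacency filter over candidate positions (criterion iv)
#'
#' Removes every candidate whose nearest neighbour on the same chromosome
#' lies within `min_distance` bp: the distance between adjacent somatic SNVs
#' must be strictly over 10 bp, and both members of a close pair are removed
#' (`keep = "none"`). `keep = "first"` retains the left member of each close
#' pair instead.
#'
#' @param chrom chromosome of each candidate.
#' @param pos 1-based position of each candidate.
#' @param min_distance maximum disallowed distance (bp), default 10.
#' @param keep `"none"` (default) or `"first"`.
#' @return logical vector: `TRUE` for retained candidates.
#' @export
adjacency_filter <- function(chrom, pos, min_distance = 10L,
                             keep = c("none", "first")) {
  keep <- match.arg(keep)
  stopifnot(length(chrom) == length(pos))
  retain <- rep(TRUE, length(pos))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    o <- idx[order(pos[idx])]
    p <- pos[o]
    if (length(p) < 2) next
    gap <- diff(p)
    close_pair <- gap <= min_distance
    if (keep == "none") {
      bad <- logical(length(p))
      bad[which(close_pair)] <- TRUE
      bad[which(close_pair) + 1L] <- TRUE
      retain[o[bad]] <- FALSE
    } else {
      # greedy left-to-right: drop the right member of each remaining pair
      alive <- rep(TRUE, length(p))
      last <- p[1]
      for (i in seq_along(p)[-1]) {
        if (p[i] - last <= min_distance) alive[i] <- FALSE else last <- p[i]
      }
      retain[o] <- alive
    }
  }
  retain
}

#' Evaluate the nine somatic criteria at one site
#'
#' Applies criteria i-iii and v-ix to a [site_evidence()] object. Criterion
#' iv (adjacency) is a cohort-level property and is reported as `NA` here;
#' [filter_cohort()] fills it in. Reads with `allele == "other"` count
#' toward depth but belong to neither the alt nor the ref group.
#'
#' @param site a [site_evidence()] object.
#' @param thresholds an [snv_thresholds()] object.
#' @param mode `"discovery"` (tumor VAF >= 10\%) or `"validation"`
#'   (tumor VAF >= 5\%).
#' @return one-row data frame of class `filter_verdict` with per-criterion
#'   flags `c1`..`c9`, p-values `p5`..`p9`, and `pass` (the conjunction;
#'   `NA` criterion iv is treated as pass at site level).
#' @export
evaluate_site <- function(site, thresholds = snv_thresholds(),
                          mode = c("discovery", "validation")) {
  mode <- match.arg(mode)
  stopifnot(inherits(site, "site_evidence"))
  th <- thresholds
  if (nrow(site$normal_obs) == 0) stop("missing normal evidence")
  tc <- .allele_counts(site$tumor_obs)
  nc <- .allele_counts(site$normal_obs)
  tumor_vaf <- tc[["alt"]] / tc[["depth"]]
  normal_vaf <- if (nc[["depth"]] > 0) nc[["alt"]] / nc[["depth"]] else NA
  min_vaf <- if (mode == "validation") th$validation_min_vaf else
    th$min_tumor_vaf

  c1 <- tc[["depth"]] >= th$min_depth && nc[["depth"]] >= th$min_depth
  c2 <- tumor_vaf >= min_vaf && normal_vaf < th$max_normal_vaf
  c3 <- tc[["alt"]] >= th$min_alt_reads

  alt_obs <- site$tumor_obs[site$tumor_obs$allele == "alt", , drop = FALSE]
  ref_obs <- site$tumor_obs[site$tumor_obs$allele == "ref", , drop = FALSE]

  p5 <- if (nrow(alt_obs)) {
    mapq_support_test(alt_obs$mapq, th$mapq_ref_value)
  } else NA_real_
  p6 <- if (nrow(alt_obs)) {
    baseq_support_test(alt_obs$baseq, th$baseq_ref_value)
  } else NA_real_
  p7 <- if (nrow(alt_obs) && nrow(ref_obs)) {
    read_end_enrichment_test(alt_obs, ref_obs)
  } else NA_real_
  p8 <- vaf_contrast_test(tc[["alt"]], tc[["ref"]], nc[["alt"]], nc[["ref"]])
  p9 <- if (nrow(alt_obs) && nrow(ref_obs)) {
    strand_bias_test(sum(alt_obs$strand == "+"), sum(alt_obs$strand == "-"),
                     sum(ref_obs$strand == "+"), sum(ref_obs$strand == "-"))
  } else NA_real_

  c5 <- !is.na(p5) && p5 < th$mapq_alpha
  c6 <- !is.na(p6) && p6 < th$baseq_alpha
  c7 <- is.na(p7) || p7 >= th$readend_alpha      # reject when enriched
  c9 <- is.na(p9) || p9 >= th$strand_alpha       # reject when biased
  c8 <- p8 < th$vaf_contrast_alpha

  out <- data.frame(chrom = site$chrom, pos = site$pos,
                    ref = site$ref, alt = site$alt,
                    tumor_depth = tc[["depth"]], tumor_alt = tc[["alt"]],
                    normal_depth = nc[["depth"]], normal_alt = nc[["alt"]],
                    tumor_vaf = unname(tumor_vaf),
                    normal_vaf = unname(normal_vaf),
                    c1 = c1, c2 = c2, c3 = c3, c4 = NA,
                    c5 = c5, c6 = c6, c7 = c7, c8 = c8, c9 = c9,
                    p5 = p5, p6 = p6, p7 = p7, p8 = p8, p9 = p9,
                    stringsAsFactors = FALSE)
  out$pass <- with(out, c1 & c2 & c3 & c5 & c6 & c7 & c8 & c9 &
                     (is.na(c4) | c4))
  class(out) <- c("filter_verdict", class(out))
  out
}

#' Filter a cohort of candidate SNV sites
#'
#' Evaluates every site, applies the cohort-level adjacency rule, and
#' returns the verdict table plus the set of passing sites. The `filter`
#' column holds `"PASS"` or the name of the first failed criterion, ready
#' for a VCF FILTER field.
#'
#' @param sites list of [site_evidence()] objects.
#' @param thresholds an [snv_thresholds()] object.
#' @param mode `"discovery"` or `"validation"`.
#' @param adjacency_keep passed to [adjacency_filter()].
#' @return list with `verdicts` (data frame, one row per site) and
#'   `pass` (logical vector).
#' @export
filter_cohort <- function(sites, thresholds = snv_thresholds(),
                          mode = c("discovery", "validation"),
                          adjacency_keep = "none") {
  mode <- match.arg(mode)
  verdicts <- do.call(rbind, lapply(sites, evaluate_site,
                                    thresholds = thresholds, mode = mode))
  verdicts$c4 <- adjacency_filter(verdicts$chrom, verdicts$pos,
                                  thresholds$min_adjacent_distance_bp,
                                  keep = adjacency_keep)
  verdicts$pass <- with(verdicts,
                        c1 & c2 & c3 & c4 & c5 & c6 & c7 & c8 & c9)
  crit <- paste0("c", 1:9)
  verdicts$filter <- apply(verdicts[crit], 1L, function(f) {
    bad <- names(f)[!f]
    if (length(bad) == 0) "PASS" else bad[1L]
  })
  list(verdicts = verdicts, pass = verdicts$pass)
}
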