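#' Readers, writers and the end-to-end pipeline
#'
#' Plain-text interchange formats: a minimal VCF 4.2 subset for candidate
#' SNV sites (FILTER holds `PASS` or the first failed criterion), a
#' per-read evidence TSV, BED-like segment TSVs (0-based half-open),
#' sample metadata, Ct tables and GMT pathway files. [run_pipeline()]
#' composes the stages (QC, SNV filtering, copy-number significance, qPCR
#' validation, cohort statistics) over a simulated or on-disk input set
#' and writes a manifest with file hashes for reproducibility checks.
#'
#' @name io_pipeline
NULL

#' Write candidate SNV sites as minimal VCF 4.2
#'
#' @param sites data frame with `chrom`, `pos` (1-based), `ref`, `alt`,
#'   and optionally `filter` (default `.`) and `info` (default `.`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snv_vcf <- function(sites, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=oncostage",
    paste0("##FILTER=<ID=PASS,Description=\"All somatic criteria met\">"),
    paste0("##FILTER=<ID=c", 1:9, ",Description=\"Failed somatic ",
           "criterion ", c("depth", "allele frequency", "alt read count",
                           "adjacency", "mapping quality", "base quality",
                           "read-end enrichment", "tumor/normal contrast",
                           "strand bias"), "\">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  filt <- if ("filter" %in% names(sites)) sites$filter else "."
  info <- if ("info" %in% names(sites)) sites$info else "."
  body <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".",
                filt, info, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a minimal VCF back into a site table
#'
#' Accepts the subset written by [write_snv_vcf()]. Malformed data lines
#' abort with the offending line number.
#'
#' @param path VCF file path.
#' @return data frame with `chrom`, `pos`, `ref`, `alt`, `filter`, `info`.
#' @export
read_snv_vcf <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "##fileformat=VCF")) {
    stop("not a VCF file: ", path)
  }
  body_idx <- which(!startsWith(lines, "#"))
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 8L)
  if (length(bad)) {
    stop("malformed VCF line(s): ",
         paste(body_idx[bad], collapse = ", "), " in ", path)
  }
  m <- do.call(rbind, fields)
  pos <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(pos)) {
    stop("malformed VCF line(s): non-integer POS at line ",
         paste(body_idx[is.na(pos)], collapse = ", "), " in ", path)
  }
  data.frame(chrom = m[, 1], pos = pos, ref = m[, 4], alt = m[, 5],
             filter = m[, 7], info = m[, 8], stringsAsFactors = FALSE)
}

#' Write/read the per-read evidence TSV
#'
#' One row per read observation: `site_id`, `chrom`, `pos`, `ref`, `alt`,
#' `role` (tumor/normal), `allele` (ref/alt/other), `mapq`, `baseq`,
#' `offset5`, `read_length`, `strand`.
#'
#' @param sites list of [site_evidence()] objects (or `labeled_site`s).
#' @param path file path.
#' @return `path` invisibly / the reconstructed list of
#'   [site_evidence()] objects.
#' @export
write_site_evidence <- function(sites, path) {
  rows <- lapply(seq_along(sites), function(i) {
    s <- sites[[i]]
    if (inherits(s, "labeled_site")) s <- s$site
    both <- rbind(cbind(role = "tumor", s$tumor_obs),
                  cbind(role = "normal", s$normal_obs))
    cbind(site_id = i, chrom = s$chrom, pos = s$pos, ref = s$ref,
          alt = s$alt, both)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_site_evidence
#' @export
read_site_evidence <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(split(df, df$site_id), function(d) {
    obs_cols <- c("allele", "mapq", "baseq", "offset5", "read_length",
                  "strand")
    site_evidence(d$chrom[1], d$pos[1], d$ref[1], d$alt[1],
                  d[d$role == "tumor", obs_cols],
                  d[d$role == "normal", obs_cols])
  })
}

#' Write/read BED-like copy-number segments (0-based half-open)
#'
#' A single TSV with columns `sample`, `chrom`, `start`, `end`,
#' `copy_number`.
#'
#' @param segment_sets named list of per-sample segment data frames.
#' @param path file path.
#' @return `path` invisibly / named list of segment data frames.
#' @export
write_segments <- function(segment_sets, path) {
  df <- do.call(rbind, lapply(names(segment_sets), function(s) {
    cbind(sample = s, segment_sets[[s]])
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- split(df[c("chrom", "start", "end", "copy_number")], df$sample)
  lapply(out, function(d) { rownames(d) <- NULL; d })
}

#' Read a GMT pathway file
#'
#' Thin wrapper over [fgsea::gmtPathways()].
#'
#' @param path GMT file path.
#' @return named list of gene sets.
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)

#' Write a GMT pathway file
#'
#' @param pathways named list of gene sets.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(names(pathways), function(nm) {
    paste(c(nm, nm, pathways[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles the stage parameter sets and the master seed. Every threshold
#' defaults to its standard printed value. A YAML file with any subset of
#' the fields `seed`, `snv`, `qc`, `cnv`, `landscape`, `sim`, `mode` can
#' be loaded with [read_pipeline_config()].
#'
#' @param seed master seed; every stage derives a named substream from it.
#' @param sim a [sim_config()] (its own seed is overridden by `seed`).
#' @param snv an [snv_thresholds()] object.
#' @param qc a [qc_thresholds()] object.
#' @param cnv a [cnv_params()] object.
#' @param landscape a [landscape_params()] object.
#' @param mode SNV filter mode, `"discovery"` or `"validation"`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, sim = sim_config(seed = seed),
                            snv = snv_thresholds(),
                            qc = qc_thresholds(), cnv = cnv_params(),
                            landscape = landscape_params(),
                            mode = "discovery") {
  sim$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), sim = sim, snv = snv, qc = qc,
                 cnv = cnv, landscape = landscape, mode = mode),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- pipeline_config(seed = if (is.null(y$seed)) 1L else y$seed)
  replace_fields <- function(obj, upd) {
    for (nm in names(upd)) obj[[nm]] <- upd[[nm]]
    obj
  }
  if (!is.null(y$snv)) cfg$snv <- replace_fields(cfg$snv, y$snv)
  if (!is.null(y$qc)) cfg$qc <- replace_fields(cfg$qc, y$qc)
  if (!is.null(y$cnv)) cfg$cnv <- replace_fields(cfg$cnv, y$cnv)
  if (!is.null(y$landscape)) {
    cfg$landscape <- replace_fields(cfg$landscape, y$landscape)
  }
  if (!is.null(y$mode)) cfg$mode <- y$mode
  cfg
}

# named substream seeds, kept below 2^31
.stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, cnv = 202L, stats = 303L)
  (as.integer(seed) + offsets[[stage]] * 1000L) %% .Machine$integer.max
}

#' Run the full pipeline on a simulated cohort
#'
#' Simulates all inputs from the config seed, then runs, in order: lane
#' and read QC; somatic SNV filtering with cohort-level adjacency;
#' marker-matrix construction, G-scores, permutation significance and
#' region merging; per-sample copy-number burdens with a stage
#' comparison; qPCR copy-number validation; and cohort statistics
#' (landscape table, stage-association tests on the planted gene and on
#' every pathway, pathway enrichment). Stage outputs are written to
#' `outdir` as plain-text tables together with a manifest of MD5 hashes;
#' rerunning with the same config reproduces identical files.
#'
#' @param config a [pipeline_config()] object.
#' @param outdir output directory (created if missing).
#' @return list of class `pipeline_report` with the stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim_cfg <- config$sim
  sim_cfg$seed <- .stage_seed(config$seed, "simulate")
  sim <- simulate_cohort(sim_cfg)

  # --- QC ---------------------------------------------------------------
  lane <- compute_lane_metrics(sim$reads)
  lane_check <- check_lane(lane, config$qc)
  read_filter <- filter_reads(sim$reads, config$qc)

  # --- somatic SNV filter ----------------------------------------------
  site_list <- lapply(sim$sites, `[[`, "site")
  truth <- vapply(sim$sites, `[[`, character(1), "truth_class")
  snv <- filter_cohort(site_list, config$snv, mode = config$mode)
  snv$verdicts$truth_class <- truth
  recovery <- tapply(snv$pass, truth, mean)

  # --- copy number ------------------------------------------------------
  cnv_par <- config$cnv
  cnv_par$seed <- .stage_seed(config$seed, "cnv")
  mm <- make_marker_matrix(sim$segments, sim$config$genome, cnv_par)
  track <- gscore_track(mm, cnv_par)
  regions <- list(amp = significant_regions(track, "amp"),
                  del = significant_regions(track, "del"))
  burdens <- vapply(sim$segments, scna_burden, numeric(1),
                    params = cnv_par)
  stage <- sim$cohort$stage
  burden_cmp <- compare_burden(burdens[stage == "I"],
                               burdens[stage == "III"])

  # --- qPCR validation --------------------------------------------------
  qpcr <- cohort_cn_table(sim$ct, cnv_par)

  # --- cohort statistics ------------------------------------------------
  landscape <- gene_frequency_table(sim$cohort, config$landscape)
  features <- c(
    stats::setNames(as.list(sim$config$planted_genes$gene),
                    sim$config$planted_genes$gene),
    sim$pathways)
  stage_tests <- stage_association_family(sim$cohort, features,
                                          sidedness = "two_sided")
  mutated_genes <- landscape$gene[landscape$n_mutated > 0]
  enrichment <- pathway_enrichment(mutated_genes, sim$pathways,
                                   universe = sim$genes$gene)

  # --- outputs + manifest ----------------------------------------------
  write_snv_vcf(snv$verdicts[snv$pass, , drop = FALSE],
                file.path(outdir, "somatic_snvs.vcf"))
  utils::write.table(snv$verdicts, file.path(outdir, "snv_verdicts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(track, file.path(outdir, "gscore_track.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(landscape, file.path(outdir, "landscape.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(stage_tests, file.path(outdir, "stage_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(enrichment, file.path(outdir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(qpcr, file.path(outdir, "qpcr_cn.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_segments(sim$segments, file.path(outdir, "segments.tsv"))
  files <- list.files(outdir, full.names = TRUE)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(outdir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  structure(list(lane_metrics = lane, lane_check = lane_check,
                 read_filter_kept = nrow(read_filter$kept),
                 snv = snv, recovery = recovery,
                 track = track, regions = regions,
                 burdens = burdens, burden_comparison = burden_cmp,
                 qpcr = qpcr, landscape = landscape,
                 stage_tests = stage_tests, enrichment = enrichment,
                 manifest = manifest, outdir = outdir),
            class = "pipeline_report")
}
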