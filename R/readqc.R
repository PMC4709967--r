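#' Sequencing quality-control gates
#'
#' Lane-, read- and sample-level QC applied before somatic variant calling.
#' Lane gates: sequencing error rate <= 2.5%, Q20 >= 80%, Q30 >= 75%,
#' GC/AT separation <= 0.4%. Read gates: adaptor rate <= 10% (batch rule;
#' adaptor-flagged reads are discarded), per-read N rate <= 10%, per-read
#' low-quality-base rate (Q < 5) <= 50%. Sample gates: mean depth >= 30x
#' (WGS) or >= 100x (WES), mapping rate >= 95%, mismatch rate <= 10%.
#' All comparisons are inclusive, exactly as stated.
#'
#' @name readqc
NULL

#' QC thresholds
#'
#' @param max_error_rate lane sequencing error rate ceiling.
#' @param min_q20,min_q30 minimum fraction of bases at Q>=20 / Q>=30.
#' @param max_gc_at_separation ceiling on |GC fraction - AT fraction|.
#' @param max_adaptor_rate ceiling on the fraction of adaptor-flagged reads.
#' @param max_n_rate per-read ceiling on the fraction of N bases.
#' @param lowqual_base_q bases with quality strictly below this are
#'   "low quality".
#' @param max_lowqual_rate per-read ceiling on the low-quality-base fraction.
#' @param min_depth_wgs,min_depth_wes minimum mean depth by assay mode.
#' @param min_mapping_rate minimum alignment rate.
#' @param max_mismatch_rate maximum mismatch rate.
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(max_error_rate = 0.025,
                          min_q20 = 0.80, min_q30 = 0.75,
                          max_gc_at_separation = 0.004,
                          max_adaptor_rate = 0.10,
                          max_n_rate = 0.10,
                          lowqual_base_q = 5L, max_lowqual_rate = 0.50,
                          min_depth_wgs = 30, min_depth_wes = 100,
                          min_mapping_rate = 0.95,
                          max_mismatch_rate = 0.10) {
  th <- list(max_error_rate = max_error_rate, min_q20 = min_q20,
             min_q30 = min_q30, max_gc_at_separation = max_gc_at_separation,
             max_adaptor_rate = max_adaptor_rate, max_n_rate = max_n_rate,
             lowqual_base_q = lowqual_base_q,
             max_lowqual_rate = max_lowqual_rate,
             min_depth_wgs = min_depth_wgs, min_depth_wes = min_depth_wes,
             min_mapping_rate = min_mapping_rate,
             max_mismatch_rate = max_mismatch_rate)
  rates <- unlist(th[c("max_error_rate", "min_q20", "min_q30",
                       "max_gc_at_separation", "max_adaptor_rate",
                       "max_n_rate", "max_lowqual_rate",
                       "min_mapping_rate", "max_mismatch_rate")])
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (th$lowqual_base_q < 0) stop("quality cutoffs must be non-negative")
  structure(th, class = "qc_thresholds")
}

#' Read records
#'
#' A read record set is a data frame with columns `seq` (character over
#' A/C/G/T/N), `qual` (list column of integer Phred qualities, one per
#' base) and `adaptor` (logical adaptor flag). [read_fastq()] builds one
#' from a Sanger Phred+33 FASTQ file.
#'
#' @param seq character vector of read sequences.
#' @param qual list of integer vectors, per-base qualities.
#' @param adaptor logical adaptor flags (default all `FALSE`).
#' @return data frame of class `read_records`.
#' @export
read_records <- function(seq, qual, adaptor = rep(FALSE, length(seq))) {
  stopifnot(length(seq) == length(qual), length(seq) == length(adaptor))
  if (any(nchar(seq) != lengths(qual))) {
    stop("base and quality sequences must have equal length")
  }
  structure(data.frame(seq = seq, qual = I(qual), adaptor = adaptor,
                       stringsAsFactors = FALSE),
            class = c("read_records", "data.frame"))
}

#' Read a FASTQ file into read records
#'
#' Sanger Phred+33 encoding. Optionally flags reads containing a given
#' adapter sequence (exact substring match, adapter length >= 10 nt).
#'
#' @param path FASTQ file path.
#' @param adapter adapter sequence to flag, or `NULL` for no flagging.
#' @return a [read_records()] data frame.
#' @export
read_fastq <- function(path, adapter = NULL) {
  sset <- Biostrings::readDNAStringSet(path, format = "fastq",
                                       with.qualities = TRUE)
  quals <- S4Vectors::mcols(sset)$qualities
  qint <- lapply(as.character(quals), function(q) utf8ToInt(q) - 33L)
  seqs <- as.character(sset)
  adaptor <- rep(FALSE, length(seqs))
  if (!is.null(adapter)) {
    if (nchar(adapter) < 10) stop("adapter must be at least 10 nt")
    adaptor <- Biostrings::vcountPattern(adapter, sset) > 0
  }
  rr <- read_records(unname(seqs), unname(qint), adaptor)
  rownames(rr) <- NULL
  rr
}

#' Lane-level metrics from read records
#'
#' The sequencing error rate is the mean Phred-implied per-base error
#' probability, Q20/Q30 are the fractions of bases at or above those
#' qualities, GC and AT fractions are computed over non-N bases, and the
#' adaptor rate is the fraction of adaptor-flagged reads.
#'
#' @param reads a [read_records()] data frame.
#' @return list of class `lane_metrics` with fields `error_rate`,
#'   `q20_fraction`, `q30_fraction`, `gc_fraction`, `at_fraction`,
#'   `adaptor_rate`.
#' @export
compute_lane_metrics <- function(reads) {
  if (nrow(reads) == 0) stop("empty read set")
  q <- unlist(reads$qual)
  bases <- strsplit(paste(reads$seq, collapse = ""), "")[[1]]
  non_n <- bases != "N"
  gc <- sum(bases %in% c("G", "C")) / sum(non_n)
  at <- sum(bases %in% c("A", "T")) / sum(non_n)
  structure(list(error_rate = mean(10^(-q / 10)),
                 q20_fraction = mean(q >= 20),
                 q30_fraction = mean(q >= 30),
                 gc_fraction = gc, at_fraction = at,
                 adaptor_rate = mean(reads$adaptor)),
            class = "lane_metrics")
}

#' Lane QC gate
#'
#' @param metrics a `lane_metrics` list (see [compute_lane_metrics()]).
#' @param thresholds a [qc_thresholds()] object.
#' @return list with per-criterion logical flags (`error_rate`, `q20`,
#'   `q30`, `gc_at_separation`) and `overall`.
#' @export
check_lane <- function(metrics, thresholds = qc_thresholds()) {
  th <- thresholds
  flags <- list(
    error_rate = metrics$error_rate <= th$max_error_rate,
    q20 = metrics$q20_fraction >= th$min_q20,
    q30 = metrics$q30_fraction >= th$min_q30,
    gc_at_separation =
      abs(metrics$gc_fraction - metrics$at_fraction) <=
        th$max_gc_at_separation + 1e-12) # FP guard on a computed quantity
  flags$overall <- all(unlist(flags))
  flags
}

#' Read-level filter
#'
#' Adaptor-flagged reads are discarded (reason `"adaptor"`); remaining
#' reads are discarded when their N rate exceeds 10% (reason `"n_rate"`)
#' or their low-quality-base rate (Q < 5) exceeds 50% (reason
#' `"lowqual_rate"`). The reason names the first failed rule. The batch
#' adaptor rate (fraction of flagged reads) is reported with its own pass
#' flag.
#'
#' @param reads a [read_records()] data frame.
#' @param thresholds a [qc_thresholds()] object.
#' @return list with `kept` and `discarded` read-record data frames,
#'   `reason` (character, one per discarded read), `adaptor_rate` and
#'   `adaptor_ok`.
#' @export
filter_reads <- function(reads, thresholds = qc_thresholds()) {
  th <- thresholds
  n_rate <- vapply(seq_len(nrow(reads)), function(i) {
    b <- strsplit(reads$seq[i], "")[[1]]
    mean(b == "N")
  }, numeric(1))
  lowq_rate <- vapply(reads$qual, function(q) mean(q < th$lowqual_base_q),
                      numeric(1))
  reason <- rep(NA_character_, nrow(reads))
  reason[lowq_rate > th$max_lowqual_rate] <- "lowqual_rate"
  reason[n_rate > th$max_n_rate] <- "n_rate"
  reason[reads$adaptor] <- "adaptor"
  drop <- !is.na(reason)
  list(kept = reads[!drop, , drop = FALSE],
       discarded = reads[drop, , drop = FALSE],
       reason = reason[drop],
       adaptor_rate = mean(reads$adaptor),
       adaptor_ok = mean(reads$adaptor) <= th$max_adaptor_rate)
}

#' Sample-level QC gate
#'
#' @param mean_depth mean sequencing depth.
#' @param mapping_rate fraction of reads aligned.
#' @param mismatch_rate fraction of mismatching bases.
#' @param mode `"wgs"` (depth >= 30) or `"wes"` (depth >= 100).
#' @param thresholds a [qc_thresholds()] object.
#' @return list of per-criterion flags plus `overall`.
#' @export
check_sample <- function(mean_depth, mapping_rate, mismatch_rate,
                         mode = c("wgs", "wes"),
                         thresholds = qc_thresholds()) {
  mode <- match.arg(mode)
  th <- thresholds
  min_depth <- if (mode == "wgs") th$min_depth_wgs else th$min_depth_wes
  flags <- list(depth = mean_depth >= min_depth,
                mapping_rate = mapping_rate >= th$min_mapping_rate,
                mismatch_rate = mismatch_rate <= th$max_mismatch_rate)
  flags$overall <- all(unlist(flags))
  flags
}
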