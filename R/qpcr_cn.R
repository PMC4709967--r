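#' Comparative (delta-delta-Ct) qPCR copy-number inference
#'
#' Copy number is quantified relative to a diploid reference assay (RNase
#' P) and a diploid calibrator sample: replicate Ct values are averaged
#' first, then `dCt(s) = Ct_target(s) - Ct_ref(s)`,
#' `ddCt = dCt(s) - dCt(calibrator)` and `CN = 2 * 2^(-ddCt)`.
#' Amplification efficiency is fixed at 2.0 (no efficiency correction).
#' An inferred copy number below 0.3 flags a homozygous deletion.
#'
#' @name qpcr_cn
NULL

#' Build a Ct table
#'
#' @param sample sample identifier per measurement.
#' @param assay `"target"` or `"reference"`.
#' @param gene target gene name (use the reference gene's name, e.g.
#'   `"RNaseP"`, for reference rows).
#' @param ct cycle-threshold value (> 0).
#' @param replicate replicate index.
#' @param calibrator logical, is this the calibrator sample.
#' @return data frame of class `ct_table`.
#' @export
ct_table <- function(sample, assay, gene, ct, replicate = 1L,
                     calibrator = FALSE) {
  stopifnot(all(assay %in% c("target", "reference")), all(ct > 0))
  df <- data.frame(sample = sample, assay = assay, gene = gene, ct = ct,
                   replicate = replicate, calibrator = calibrator,
                   stringsAsFactors = FALSE)
  if (!any(df$calibrator)) stop("at least one calibrator sample required")
  structure(df, class = c("ct_table", "data.frame"))
}

.mean_ct <- function(ct, sample_id, assay, gene = NULL) {
  rows <- ct$sample == sample_id & ct$assay == assay
  if (assay == "target" && !is.null(gene)) rows <- rows & ct$gene == gene
  if (!any(rows)) return(NA_real_)
  mean(ct$ct[rows])
}

#' Infer copy number for one gene in one sample
#'
#' @param ct a [ct_table()] data frame.
#' @param gene target gene.
#' @param sample sample identifier.
#' @param homdel_threshold copy number strictly below this flags a
#'   homozygous deletion (default 0.3).
#' @return list with `copy_number`, `ddct`, `homozygous_deletion`.
#' @export
ddct_copy_number <- function(ct, gene, sample, homdel_threshold = 0.3) {
  cal <- unique(ct$sample[ct$calibrator])
  if (length(cal) == 0) stop("no calibrator sample in Ct table")
  cal <- cal[1L]
  ct_t <- .mean_ct(ct, sample, "target", gene)
  ct_r <- .mean_ct(ct, sample, "reference")
  ct_tc <- .mean_ct(ct, cal, "target", gene)
  ct_rc <- .mean_ct(ct, cal, "reference")
  if (anyNA(c(ct_r, ct_rc))) stop("missing reference assay")
  if (anyNA(c(ct_t, ct_tc))) stop("missing target assay for gene ", gene)
  ddct <- (ct_t - ct_r) - (ct_tc - ct_rc)
  cn <- 2 * 2^(-ddct)
  list(copy_number = cn, ddct = ddct,
       homozygous_deletion = cn < homdel_threshold)
}

#' Cohort copy-number table from qPCR assays
#'
#' Computes per-gene, per-sample copy numbers with replicate mean and SD
#' of the target Ct, and amplification/deletion/homozygous-deletion flags
#' using the copy-number thresholds of [cnv_params()].
#'
#' @param ct a [ct_table()] data frame.
#' @param params a [cnv_params()] object supplying the 1.5/2.5 thresholds.
#' @param homdel_threshold homozygous-deletion cutoff (default 0.3).
#' @return data frame with one row per (gene, sample).
#' @export
cohort_cn_table <- function(ct, params = cnv_params(),
                            homdel_threshold = 0.3) {
  genes <- unique(ct$gene[ct$assay == "target"])
  samples <- unique(ct$sample)
  grid <- expand.grid(gene = genes, sample = samples,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid$gene[i]; s <- grid$sample[i]
    tgt <- ct$ct[ct$sample == s & ct$assay == "target" & ct$gene == g]
    if (length(tgt) == 0) return(NULL)
    res <- ddct_copy_number(ct, g, s, homdel_threshold)
    data.frame(gene = g, sample = s,
               ct_mean = mean(tgt), ct_sd = stats::sd(tgt),
               n_replicates = length(tgt),
               copy_number = res$copy_number,
               status = call_gain_loss(res$copy_number, params),
               homozygous_deletion = res$homozygous_deletion,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
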