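#' Somatic/germline classification of small indels
#'
#' A candidate indel is annotated as germline when any normal sample shows
#' evidence for the event at the same locus, and somatic otherwise; with
#' no normal coverage anywhere the call is unevaluable. "Any evidence" is
#' at least `min_support` supporting reads (default 1; the default is
#' deliberately aggressive and a higher value can be set to absorb
#' sequencing noise). Local realignment happens upstream: this module
#' consumes post-realignment supporting/total read counts.
#'
#' @name indel_filter
NULL

#' Classify one indel candidate
#'
#' @param tumor_support alt-supporting tumor reads.
#' @param normal_support vector of supporting reads, one per normal sample.
#' @param normal_total vector of total reads per normal sample.
#' @param min_support minimum normal supporting reads that count as
#'   germline evidence (default 1).
#' @return `"somatic"`, `"germline"` or `"unevaluable"`.
#' @export
classify_indel <- function(tumor_support, normal_support, normal_total,
                           min_support = 1L) {
  stopifnot(length(normal_support) == length(normal_total),
            length(normal_support) >= 1L)
  if (any(normal_support > normal_total)) {
    stop("supporting reads cannot exceed total reads")
  }
  covered <- normal_total > 0
  if (!any(covered)) return("unevaluable")
  if (any(normal_support >= min_support & covered)) "germline" else "somatic"
}

#' Classify a cohort of indel candidates against a panel of normals
#'
#' @param candidates data frame with columns `id`, `tumor_support` and a
#'   list column `normal_support` plus `normal_total` (integer vectors per
#'   candidate, one entry per normal sample).
#' @param min_support passed to [classify_indel()].
#' @return list with `calls` (data frame `id`, `class`) and `counts`
#'   (named vector over somatic/germline/unevaluable summing to the
#'   number of candidates).
#' @export
classify_indel_cohort <- function(candidates, min_support = 1L) {
  cls <- vapply(seq_len(nrow(candidates)), function(i) {
    classify_indel(candidates$tumor_support[i],
                   candidates$normal_support[[i]],
                   candidates$normal_total[[i]], min_support)
  }, character(1))
  counts <- c(somatic = sum(cls == "somatic"),
              germline = sum(cls == "germline"),
              unevaluable = sum(cls == "unevaluable"))
  list(calls = data.frame(id = candidates$id, class = cls,
                          stringsAsFactors = FALSE),
       counts = counts)
}
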