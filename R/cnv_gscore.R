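#' GISTIC-style copy-number significance over 1-kb marker windows
#'
#' Per-sample absolute copy-number segments (diploid = 2) are projected
#' onto fixed 1-kb windows ("markers"); per-marker amplification and
#' deletion G-scores combine the frequency of alteration across samples
#' with its mean amplitude, and significance is assessed against a
#' permutation-derived null built from independent per-sample circular
#' shifts (which preserve each sample's segment autocorrelation). A marker
#' is significant when its G-score exceeds 0.1 *and* its empirical
#' permutation p falls below 0.05; adjacent significant markers are merged
#' into regions. Copy numbers <= 1.5 are deletions and >= 2.5
#' amplifications (inclusive).
#'
#' @name cnv_gscore
NULL

#' Parameters for copy-number significance analysis
#'
#' @param del_threshold copy number at or below which a deletion is called.
#' @param amp_threshold copy number at or above which an amplification is
#'   called.
#' @param marker_window_bp marker window size (bp).
#' @param gscore_cutoff minimum G-score (strictly exceeded) for
#'   significance.
#' @param perm_alpha permutation p-value threshold (strictly below).
#' @param n_permutations number of per-sample circular-shift permutations.
#' @param seed RNG seed for the permutation null.
#' @return list of class `cnv_params`.
#' @export
cnv_params <- function(del_threshold = 1.5, amp_threshold = 2.5,
                       marker_window_bp = 1000L, gscore_cutoff = 0.1,
                       perm_alpha = 0.05, n_permutations = 1000L,
                       seed = 1L) {
  if (!(del_threshold < 2 && 2 < amp_threshold)) {
    stop("need del_threshold < 2 < amp_threshold")
  }
  if (marker_window_bp < 1) stop("marker window must be >= 1 bp")
  structure(list(del_threshold = del_threshold,
                 amp_threshold = amp_threshold,
                 marker_window_bp = as.integer(marker_window_bp),
                 gscore_cutoff = gscore_cutoff, perm_alpha = perm_alpha,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "cnv_params")
}

.validate_segments <- function(segments) {
  stopifnot(is.data.frame(segments),
            all(c("chrom", "start", "end", "copy_number") %in%
                  names(segments)))
  if (any(segments$start >= segments$end)) {
    stop("malformed segment interval (start >= end)")
  }
  if (any(segments$copy_number < 0)) stop("copy numbers must be >= 0")
  invisible(segments)
}

.seg_granges <- function(segments) {
  # BED-like 0-based half-open -> GRanges (1-based closed)
  GenomicRanges::GRanges(
    segments$chrom,
    IRanges::IRanges(start = segments$start + 1L, end = segments$end),
    copy_number = segments$copy_number)
}

# overlap-length-weighted mean CN of `segments` over query intervals,
# counting uncovered query bp at `fill` (NA fill -> NA when uncovered,
# weighted mean over covered part otherwise).
.weighted_cn <- function(query_gr, seg_gr, fill = NA_real_) {
  hits <- GenomicRanges::findOverlaps(query_gr, seg_gr)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(query_gr)[q], GenomicRanges::ranges(seg_gr)[s]))
  cn <- seg_gr$copy_number[s]
  wsum <- as.numeric(tapply(ov * cn, factor(q, seq_along(query_gr)), sum,
                            default = 0))
  wlen <- as.numeric(tapply(ov, factor(q, seq_along(query_gr)), sum,
                            default = 0))
  wsum[is.na(wsum)] <- 0; wlen[is.na(wlen)] <- 0
  qw <- IRanges::width(GenomicRanges::ranges(query_gr))
  if (is.na(fill)) {
    out <- ifelse(wlen > 0, wsum / wlen, NA_real_)
  } else {
    out <- (wsum + (qw - wlen) * fill) / qw
  }
  out
}

#' Gene-level copy number from segments
#'
#' Overlap-length-weighted mean copy number of one sample's segments over
#' each gene interval; genes with no covering segment get `NA`.
#'
#' @param segments data frame with `chrom`, `start`, `end` (0-based
#'   half-open bp) and `copy_number`.
#' @param genes data frame with `gene`, `chrom`, `start`, `end` (same
#'   convention).
#' @return named numeric vector of per-gene copy numbers.
#' @export
gene_copy_number <- function(segments, genes) {
  .validate_segments(segments)
  if (any(genes$start >= genes$end)) stop("malformed gene interval")
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
  cn <- .weighted_cn(gene_gr, .seg_granges(segments), fill = NA_real_)
  stats::setNames(cn, genes$gene)
}

#' Call gain/loss status from a copy number
#'
#' @param copy_number numeric vector of absolute copy numbers.
#' @param params a [cnv_params()] object.
#' @return character vector in `{"deletion", "neutral", "amplification"}`.
#' @export
call_gain_loss <- function(copy_number, params = cnv_params()) {
  out <- rep("neutral", length(copy_number))
  out[copy_number <= params$del_threshold] <- "deletion"
  out[copy_number >= params$amp_threshold] <- "amplification"
  out[is.na(copy_number)] <- NA_character_
  out
}

#' Project per-sample segments onto fixed marker windows
#'
#' Tiles each chromosome into `marker_window_bp` windows (the trailing
#' partial window is kept) and assigns each window the overlap-weighted
#' mean copy number of the sample's segments, with uncovered base pairs
#' counted at the neutral copy number 2.
#'
#' @param segment_sets named list of per-sample segment data frames.
#' @param genome data frame with `chrom` and `length` (bp).
#' @param params a [cnv_params()] object.
#' @return list with `markers` (data frame `chrom`, `start`, `end`) and
#'   `cn` (markers x samples matrix).
#' @export
make_marker_matrix <- function(segment_sets, genome,
                               params = cnv_params()) {
  if (nrow(genome) == 0 || any(genome$length <= 0)) {
    stop("genome must contain chromosomes of positive length")
  }
  w <- params$marker_window_bp
  markers <- do.call(rbind, lapply(seq_len(nrow(genome)), function(i) {
    starts <- seq(0L, genome$length[i] - 1L, by = w)
    data.frame(chrom = genome$chrom[i], start = starts,
               end = pmin(starts + w, genome$length[i]),
               stringsAsFactors = FALSE)
  }))
  marker_gr <- GenomicRanges::GRanges(
    markers$chrom, IRanges::IRanges(markers$start + 1L, markers$end))
  cn <- vapply(segment_sets, function(seg) {
    .validate_segments(seg)
    .weighted_cn(marker_gr, .seg_granges(seg), fill = 2)
  }, numeric(length(marker_gr)))
  if (is.null(dim(cn))) cn <- matrix(cn, ncol = length(segment_sets))
  colnames(cn) <- names(segment_sets)
  list(markers = markers, cn = cn)
}

#' Per-marker amplification and deletion G-scores
#'
#' For each marker, `G_amp = frequency x mean amplitude`, where frequency
#' is the fraction of samples called amplified (CN >= `amp_threshold`) and
#' amplitude is `CN - 2` in those samples; equivalently the mean over all
#' samples of the amplification excess restricted to amplified samples.
#' `G_del` is symmetric with amplitude `2 - CN` at CN <= `del_threshold`.
#'
#' @param cn markers x samples copy-number matrix.
#' @param params a [cnv_params()] object.
#' @return data frame with `g_amp` and `g_del`, one row per marker.
#' @export
gscore <- function(cn, params = cnv_params()) {
  if (length(cn) == 0) stop("empty marker matrix")
  amp <- (cn >= params$amp_threshold) * pmax(cn - 2, 0)
  del <- (cn <= params$del_threshold) * pmax(2 - cn, 0)
  data.frame(g_amp = rowMeans(amp), g_del = rowMeans(del))
}

#' Permutation null for G-scores
#'
#' Applies `n_permutations` independent per-sample circular shifts of each
#' sample's marker vector (preserving within-sample segment structure) and
#' counts, per marker, how often the permuted G-score reaches the observed
#' one. Empirical p-values use the add-one correction
#' `(1 + #exceedances) / (1 + n_permutations)` and are therefore never
#' below `1 / (1 + n_permutations)`.
#'
#' @param cn markers x samples copy-number matrix.
#' @param params a [cnv_params()] object (`n_permutations >= 100`).
#' @return data frame with `p_amp` and `p_del`, one row per marker.
#' @export
permutation_null <- function(cn, params = cnv_params()) {
  if (params$n_permutations < 100) stop("need at least 100 permutations")
  m <- nrow(cn); s <- ncol(cn)
  obs <- gscore(cn, params)
  amp <- (cn >= params$amp_threshold) * pmax(cn - 2, 0)
  del <- (cn <= params$del_threshold) * pmax(2 - cn, 0)
  exceed_amp <- integer(m); exceed_del <- integer(m)
  rows <- 0:(m - 1L)
  cols <- rep(seq_len(s), each = m)
  set.seed(params$seed)
  for (b in seq_len(params$n_permutations)) {
    shifts <- sample.int(m, s, replace = TRUE) - 1L
    idx <- (outer(rows, shifts, "+") %% m) + 1L
    flat <- cbind(as.vector(idx), cols)
    ga <- rowMeans(matrix(amp[flat], m, s))
    gd <- rowMeans(matrix(del[flat], m, s))
    exceed_amp <- exceed_amp + (ga >= obs$g_amp)
    exceed_del <- exceed_del + (gd >= obs$g_del)
  }
  data.frame(p_amp = (1 + exceed_amp) / (1 + params$n_permutations),
             p_del = (1 + exceed_del) / (1 + params$n_permutations))
}

#' G-score track with significance flags
#'
#' Convenience wrapper: computes G-scores and permutation p-values for a
#' marker matrix and flags markers significant when `G > gscore_cutoff`
#' (strict) and `p < perm_alpha` (strict), separately for amplification
#' and deletion.
#'
#' @param marker_matrix result of [make_marker_matrix()].
#' @param params a [cnv_params()] object.
#' @return data frame of class `gscore_track`: marker coordinates,
#'   `g_amp`, `g_del`, `p_amp`, `p_del`, `sig_amp`, `sig_del`.
#' @export
gscore_track <- function(marker_matrix, params = cnv_params()) {
  g <- gscore(marker_matrix$cn, params)
  p <- permutation_null(marker_matrix$cn, params)
  out <- cbind(marker_matrix$markers, g, p)
  out$sig_amp <- g$g_amp > params$gscore_cutoff & p$p_amp < params$perm_alpha
  out$sig_del <- g$g_del > params$gscore_cutoff & p$p_del < params$perm_alpha
  class(out) <- c("gscore_track", class(out))
  out
}

#' Merge significant markers into regions
#'
#' Adjacent significant markers (per chromosome, per direction) are merged
#' into maximal runs; each region records its peak (maximum-G) marker.
#'
#' @param track a [gscore_track()] data frame.
#' @param direction `"amp"` or `"del"`.
#' @return data frame with `chrom`, `start`, `end`, `n_markers`,
#'   `peak_start`, `peak_end`, `peak_g`.
#' @export
significant_regions <- function(track, direction = c("amp", "del")) {
  direction <- match.arg(direction)
  sig <- if (direction == "amp") track$sig_amp else track$sig_del
  g <- if (direction == "amp") track$g_amp else track$g_del
  out <- list()
  for (ch in unique(track$chrom)) {
    i <- which(track$chrom == ch & sig)
    if (length(i) == 0) next
    i <- i[order(track$start[i])]
    runs <- cumsum(c(1L, diff(i) != 1L))
    for (r in split(i, runs)) {
      peak <- r[which.max(g[r])]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = min(track$start[r]), end = max(track$end[r]),
        n_markers = length(r), peak_start = track$start[peak],
        peak_end = track$end[peak], peak_g = g[peak],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_markers = integer(),
                      peak_start = integer(), peak_end = integer(),
                      peak_g = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Per-sample copy-number alteration burden
#'
#' Length-weighted fraction of the assayed genome (total segment length)
#' with copy number at or below the deletion threshold or at or above the
#' amplification threshold.
#'
#' @param segments one sample's segment data frame.
#' @param params a [cnv_params()] object.
#' @return burden in `[0, 1]`.
#' @export
scna_burden <- function(segments, params = cnv_params()) {
  .validate_segments(segments)
  len <- segments$end - segments$start
  altered <- segments$copy_number <= params$del_threshold |
    segments$copy_number >= params$amp_threshold
  sum(len[altered]) / sum(len)
}
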