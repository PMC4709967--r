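#' Cohort-level mutation and copy-number statistics
#'
#' Statistics over a samples x genes binary mutation matrix with tumor
#' stage labels: mutation-landscape frequency classes ("mountains" at
#' >= 10\% of samples, "hills" at 5-10\%, a low band at 2-5\%),
#' significantly-mutated-gene (SMG) combination summaries, per-gene and
#' per-gene-set stage-association Fisher tests with Benjamini-Hochberg
#' correction, hypergeometric pathway enrichment, rank-based comparison of
#' per-sample copy-number burdens between stages, and the six-class
#' pyrimidine-folded substitution spectrum.
#'
#' @name cohort_stats
NULL

#' Cohort mutation matrix
#'
#' @param mut samples x genes binary matrix (1 = sample carries >= 1
#'   non-silent mutation in the gene); rownames are sample ids, colnames
#'   gene ids.
#' @param stage per-sample stage labels, a subset of `{"I", "III", "AH"}`.
#' @return list of class `cohort_matrix` with elements `mut` and `stage`.
#' @export
cohort_matrix <- function(mut, stage) {
  mut <- as.matrix(mut)
  if (!all(mut %in% c(0, 1))) stop("mutation matrix must be binary")
  if (length(stage) != nrow(mut)) stop("one stage label per sample")
  stage <- factor(stage, levels = c("I", "III", "AH"))
  if (anyNA(stage)) stop("stages must be I, III or AH")
  structure(list(mut = mut, stage = stage), class = "cohort_matrix")
}

#' Landscape frequency bands
#'
#' @param mountain_min minimum cohort frequency of a "mountain" gene.
#' @param hill_band half-open frequency band `[lo, hi)` of "hill" genes.
#' @param low_band half-open band of low-frequency genes.
#' @return list of class `landscape_params`.
#' @export
landscape_params <- function(mountain_min = 0.10,
                             hill_band = c(0.05, 0.10),
                             low_band = c(0.02, 0.05)) {
  if (!(low_band[1] < low_band[2] && low_band[2] <= hill_band[1] &&
        hill_band[1] < hill_band[2] && hill_band[2] <= mountain_min)) {
    stop("bands must be ordered and disjoint")
  }
  structure(list(mountain_min = mountain_min, hill_band = hill_band,
                 low_band = low_band), class = "landscape_params")
}

#' Per-gene mutation frequency and landscape class
#'
#' @param cm a [cohort_matrix()].
#' @param params a [landscape_params()] object.
#' @return data frame with `gene`, `n_mutated`, `frequency`, `class`
#'   (`"mountain"`, `"hill"`, `"low"` or `NA` below the low band).
#' @export
gene_frequency_table <- function(cm, params = landscape_params()) {
  k <- colSums(cm$mut)
  n <- nrow(cm$mut)
  f <- k / n
  cls <- rep(NA_character_, length(f))
  cls[f >= params$low_band[1] & f < params$low_band[2]] <- "low"
  cls[f >= params$hill_band[1] & f < params$hill_band[2]] <- "hill"
  cls[f >= params$mountain_min] <- "mountain"
  data.frame(gene = colnames(cm$mut), n_mutated = unname(k),
             frequency = unname(f), class = cls, stringsAsFactors = FALSE)
}

#' Cohort mutation frequency as a printed percentage
#'
#' `100 * k / n`, rounded half-up to the requested number of decimals
#' (matching how frequencies are conventionally printed, e.g. 22/104 ->
#' 21\%).
#'
#' @param k number of mutated samples.
#' @param n cohort size.
#' @param decimals decimal places (default 0).
#' @return the rounded percentage.
#' @export
cohort_frequency <- function(k, n, decimals = 0L) {
  x <- 100 * k / n
  m <- 10^decimals
  floor(x * m + 0.5) / m
}

#' Summary of SMG combinations across the cohort
#'
#' Partitions samples by the number of significantly mutated genes they
#' carry (0, 1, >= 2) and counts the distinct non-empty SMG subsets
#' observed.
#'
#' @param cm a [cohort_matrix()].
#' @param smg_genes character vector of SMG identifiers (must be columns
#'   of the matrix).
#' @return list with `n_zero`, `n_one`, `n_two_plus`,
#'   `n_combinations`.
#' @export
smg_combination_summary <- function(cm, smg_genes) {
  missing_genes <- setdiff(smg_genes, colnames(cm$mut))
  if (length(missing_genes)) {
    stop("unknown SMGs: ", paste(missing_genes, collapse = ", "))
  }
  sub <- cm$mut[, smg_genes, drop = FALSE]
  per_sample <- rowSums(sub)
  combos <- apply(sub, 1L, function(r) paste(smg_genes[r == 1],
                                             collapse = "+"))
  list(n_zero = sum(per_sample == 0),
       n_one = sum(per_sample == 1),
       n_two_plus = sum(per_sample >= 2),
       n_combinations = length(unique(combos[per_sample > 0])))
}

#' Stage-association Fisher test for a gene or gene set
#'
#' Builds the 2x2 table (stage I vs stage III) x (mutated vs not), where a
#' sample counts as mutated for a gene set when it carries a mutation in
#' any member gene, and applies Fisher's exact test. One-sided
#' `"stage1_enriched"` tests over-representation in stage I;
#' `"stage3_enriched"` the reverse; default two-sided.
#'
#' @param cm a [cohort_matrix()] with both stage I and III samples.
#' @param feature gene name or character vector of genes (a set).
#' @param sidedness `"two_sided"`, `"stage1_enriched"` or
#'   `"stage3_enriched"`.
#' @return list with `table` (2x2), `odds_ratio` (conditional MLE),
#'   `p.value`.
#' @export
stage_association_test <- function(cm, feature,
                                   sidedness = c("two_sided",
                                                 "stage1_enriched",
                                                 "stage3_enriched")) {
  sidedness <- match.arg(sidedness)
  stage1 <- cm$stage == "I"; stage3 <- cm$stage == "III"
  if (!any(stage1) || !any(stage3)) stop("both stage groups must be non-empty")
  genes <- intersect(feature, colnames(cm$mut))
  if (length(genes) == 0) stop("feature genes absent from matrix")
  has_mut <- rowSums(cm$mut[, genes, drop = FALSE]) > 0
  tab <- matrix(c(sum(has_mut & stage1), sum(!has_mut & stage1),
                  sum(has_mut & stage3), sum(!has_mut & stage3)),
                nrow = 2, byrow = TRUE,
                dimnames = list(stage = c("I", "III"),
                                mutated = c("yes", "no")))
  alt <- switch(sidedness, two_sided = "two.sided",
                stage1_enriched = "greater", stage3_enriched = "less")
  ft <- stats::fisher.test(tab, alternative = alt)
  list(table = tab, odds_ratio = unname(ft$estimate), p.value = ft$p.value)
}

#' Stage-association tests over a family of features with BH correction
#'
#' @param cm a [cohort_matrix()].
#' @param features named list: each element a gene or gene set.
#' @param sidedness passed to [stage_association_test()].
#' @return data frame with `feature`, `n_stage1`, `n_stage3`,
#'   `odds_ratio`, `p.value`, `p.adjust` (Benjamini-Hochberg).
#' @export
stage_association_family <- function(cm, features,
                                     sidedness = "two_sided") {
  rows <- lapply(names(features), function(nm) {
    res <- stage_association_test(cm, features[[nm]], sidedness)
    data.frame(feature = nm,
               n_stage1 = res$table["I", "yes"],
               n_stage3 = res$table["III", "yes"],
               odds_ratio = res$odds_ratio, p.value = res$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p.adjust <- stats::p.adjust(out$p.value, method = "BH")
  out
}

#' Hypergeometric pathway enrichment with Benjamini-Hochberg correction
#'
#' Upper-tail hypergeometric test of the overlap between the mutated gene
#' set and each pathway, against a background universe.
#'
#' @param mutated character vector of mutated genes (subset of the
#'   universe).
#' @param pathways named list of pathway gene sets (subsets of the
#'   universe).
#' @param universe character vector, the background gene universe.
#' @return data frame with `pathway`, `pathway_size`, `overlap`,
#'   `p.value`, `p.adjust`.
#' @export
pathway_enrichment <- function(mutated, pathways, universe) {
  if (!all(mutated %in% universe)) stop("mutated genes must lie in universe")
  if (!all(unlist(pathways) %in% universe)) {
    stop("pathway genes must lie in universe")
  }
  N <- length(universe); n_mut <- length(mutated)
  rows <- lapply(names(pathways), function(nm) {
    pw <- pathways[[nm]]
    k <- length(intersect(mutated, pw))
    p <- stats::phyper(k - 1, length(pw), N - length(pw), n_mut,
                       lower.tail = FALSE)
    data.frame(pathway = nm, pathway_size = length(pw), overlap = k,
               p.value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p.adjust <- stats::p.adjust(out$p.value, method = "BH")
  out
}

#' Compare copy-number burdens between stages
#'
#' One-sided Mann-Whitney rank-sum test (exact for groups of at most 10,
#' tie-corrected normal approximation otherwise) that stage III burdens
#' exceed stage I burdens, with the observed direction reported.
#'
#' @param burden_stage1,burden_stage3 numeric burden vectors.
#' @return list with `p.value` (one-sided, stage III > stage I),
#'   `direction` (`"stage3 > stage1"` or `"stage1 >= stage3"`), medians.
#' @export
compare_burden <- function(burden_stage1, burden_stage3) {
  res <- rank_sum_test(burden_stage3, burden_stage1,
                       alternative = "greater")
  m1 <- stats::median(burden_stage1); m3 <- stats::median(burden_stage3)
  list(p.value = res$p.value,
       direction = if (m3 > m1) "stage3 > stage1" else "stage1 >= stage3",
       median_stage1 = m1, median_stage3 = m3)
}

#' Six-class pyrimidine-folded mutation spectrum
#'
#' Counts single-nucleotide substitutions in the six pyrimidine-context
#' classes C>A, C>G, C>T, T>A, T>C, T>G; purine-reference substitutions
#' are folded onto their reverse complement (e.g. G>A counts as C>T).
#'
#' @param ref,alt character vectors of reference and alternate bases.
#' @return named integer vector over the six classes.
#' @export
mutation_spectrum <- function(ref, alt) {
  stopifnot(length(ref) == length(alt))
  classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  counts <- stats::setNames(integer(6), classes)
  if (length(ref) == 0) return(counts)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  purine <- ref %in% c("A", "G")
  r <- ifelse(purine, comp[ref], ref)
  a <- ifelse(purine, comp[alt], alt)
  key <- paste0(r, ">", a)
  if (!all(key %in% classes)) stop("invalid substitution (ref == alt or non-ACGT)")
  tab <- table(factor(key, levels = classes))
  counts[] <- as.integer(tab)
  counts
}
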