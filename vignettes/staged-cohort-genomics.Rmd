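---
title: "Methods: stage-associated somatic variant and copy-number analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stage-associated somatic variant and copy-number analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncostage)
```

`oncostage` re-implements, as tested reusable components, the core
computations of a staged tumor-cohort genomics workflow: read-evidence
filtering of somatic single-nucleotide variants, sequencing QC gates,
germline-evidence classification of small indels, a GISTIC-style
copy-number significance score with a permutation null, comparative-Ct
qPCR copy-number inference, and cohort-level stage-association
statistics. A fully seeded synthetic-cohort generator supplies every
input, so the entire workflow runs and is testable without access to any
controlled sequencing data. This vignette documents the statistical
models, the places where the underlying procedures were under-specified
and a concrete reading had to be fixed, and what the synthetic data can
and cannot establish.

## The somatic SNV filter

A candidate SNV is judged on tumor and normal per-read observations
(allele, mapping quality, base quality, offset from the 5' read end,
strand). Nine criteria are applied; all alpha comparisons are strict
(`p < alpha`) and all count/fraction thresholds inclusive, exactly as
conventionally printed:

1. tumor and normal depth ≥ 10×;
2. tumor VAF ≥ 10% (≥ 5% in validation mode, so that deep targeted
   re-sequencing retains low-frequency mutations) and normal VAF < 2%;
3. ≥ 3 alt-supporting tumor reads;
4. distance between adjacent candidates strictly over 10 bp;
5. alt-read mapping qualities significantly above 30 (p < 0.2);
6. alt-read base qualities significantly above 20 (p < 0.05);
7. alt calls not enriched within 5 bp of read ends (p < 0.1);
8. significant tumor-vs-normal allele-frequency contrast
   (Fisher exact, p < 0.05);
9. no strand bias of alt vs ref reads (Fisher exact; the site is
   rejected at p < 0.0001).

**Rank tests against a constant.** Criteria 5-6 name a rank test of a
sample against a constant. A two-sample rank-sum test needs two samples,
so the only coherent reading of "significantly higher than 30" is a
one-sample, one-sided Wilcoxon signed-rank test against the constant.
We drop zero differences (observations exactly at the reference carry no
information; if all are dropped the criterion fails with p = 1; Pratt's
method is the known alternative and changes none of the package's
decisions at these alphas). Because quality scores are small integers,
ties are ubiquitous, and `stats::wilcox.test` refuses exact p-values
under ties; the package therefore computes the exact conditional null
(given the tie pattern) by a generating-function convolution over
doubled midranks for up to 25 informative observations, and a
tie-corrected normal approximation with continuity correction beyond.
The same machinery backs the two-sample rank-sum test (exact for groups
of ≤ 10), used by criterion 7 and by the copy-number burden comparison.
Enumeration oracles (all `2^n` sign assignments, all `choose(m+n, m)`
group assignments) verify both to 1e-12 in the test suite.

**Criterion 7 direction.** The read-end rule is implemented as a
one-sided rank-sum test that alt distances-to-nearest-read-end
(`min(offset5, read_length - 1 - offset5)`) are smaller than ref
distances, with rejection when that test is significant at p < 0.1.

**Criterion 4 pair handling.** The adjacency rule is a property of a
pair, not of one member, so both members of a ≤ 10 bp pair are removed
by default; `keep = "first"` offers the greedy alternative. It is
applied cohort-wide after the per-site criteria (the order does not
change the final set).

**Sidedness.** The criterion texts do not state sidedness for the two
Fisher tests; both are two-sided, the common default for contrast and
bias tests. Reads supporting neither allele count toward depth but join
neither the alt nor the ref group in the per-read tests.

## Sequencing QC gates

Lane gates: sequencing error rate ≤ 2.5% (computed as the mean
Phred-implied per-base error probability), Q20 ≥ 80%, Q30 ≥ 75%, and
GC/AT separation ≤ 0.4%. "GC/AT separation" has no standard formula; it
is implemented as `|GC fraction − AT fraction|` over non-N bases, the
simplest reading. Read gates: adaptor rate ≤ 10% as a batch rule
(adaptor-flagged reads are discarded; flagging is either upstream or by
exact substring match of an adapter of ≥ 10 nt — full trimmer internals
are out of scope), per-read N rate ≤ 10%, and per-read low-quality-base
rate (Q < 5) ≤ 50%. Sample gates: mean depth ≥ 30× (WGS) or ≥ 100×
(WES), mapping rate ≥ 95%, mismatch rate ≤ 10%. A one-part-in-10^12
guard is used in the separation comparison so that boundary values pass
regardless of floating-point representation.

## Copy-number significance (G-scores)

Per-sample absolute copy-number segments (diploid = 2; 0-based
half-open BED convention) are projected onto fixed 1-kb marker windows;
each window takes the overlap-length-weighted mean copy number, with
uncovered base pairs counted at the neutral value 2 (this avoids
spurious deletions from missing data; trailing partial windows are
kept). Copy number ≤ 1.5 is called a deletion and ≥ 2.5 an
amplification, inclusive.

The per-marker amplification score is

$$G_\text{amp}(m) = f(m) \cdot \bar a(m),$$

the frequency of amplified samples times their mean amplitude
(`CN − 2`); deletions are scored symmetrically with amplitude `2 − CN`.
Note that frequency × mean-over-altered is algebraically identical to
the sum of amplitudes divided by the sample count, so the two variants
sometimes described separately are one formula; no switch is provided.

Significance uses a permutation null built from independent per-sample
circular shifts of each sample's marker vector. Shifting preserves each
sample's within-genome segment structure (autocorrelation), which an
i.i.d. marker shuffle would destroy and thereby inflate false
positives. Empirical p-values use the add-one correction
`(1 + #{null G ≥ observed G}) / (1 + B)` and are never zero. A marker
is significant only when **both** `G > 0.1` (strict) and `p < 0.05`
(strict) hold: the printed equivalence between the two cutoffs is a
property of one particular data set and is deliberately not assumed, so
the conditions are applied conjunctively. Adjacent significant markers
merge into regions with a max-G peak marker. The per-sample SCNA burden
is the length-weighted fraction of the assayed genome at or beyond
either threshold.

Under an exchangeable null the per-marker permutation p-values are
approximately uniform; the acceptance suite checks this with a
Kolmogorov–Smirnov statistic against U(0,1) at 500 markers × 40 samples
and 1,000 permutations (1% critical value `1.628/sqrt(500)`), and
verifies that a planted amplification of mean copy number 3.2 carried by
40% of samples is recovered as significant.

## qPCR copy number (comparative Ct)

Replicate Ct values are averaged on the Ct scale first (the standard
order; averaging after exponentiation is not equivalent and a test
fixture demonstrates the difference), then
`dCt(s) = Ct_target(s) − Ct_reference(s)`,
`ddCt = dCt(s) − dCt(calibrator)` and `CN = 2 · 2^(−ddCt)`, with the
reference assay (RNase P) and the calibrator sample both treated as
diploid. Amplification efficiency is fixed at 2.0 since no efficiency
correction is part of the procedure. Copy number < 0.3 flags a
homozygous deletion; the 1.5/2.5 thresholds flag loss and gain. Which
sample serves as calibrator is an open choice; a pooled-normal
calibrator is assumed and any sample can be designated.

## Cohort statistics

The cohort is a samples × genes binary matrix of non-silent mutation
indicators with stage labels (I, III, or atypical hyperplasia).
Landscape classes: "mountains" at ≥ 10% cohort frequency, "hills" at
5–10% (lower edge inclusive), a low band at 2–5%. Printed percentages
round half-up (22/104 → 21%, 6/36 → 16.7%), matching how such
frequencies are conventionally reported. Stage association uses
Fisher's exact test on the (stage I vs III) × (mutated vs not) table; a
gene-set feature counts a sample as mutated when any member gene is.
Two-sided tests are the default, with pre-specified-direction one-sided
tests available — on reconstructed stage-biased tables the one-sided
form is the one that satisfies the published significance bounds, and
both are reported. Benjamini–Hochberg correction is applied across any
supplied feature family. Pathway enrichment is the upper-tail
hypergeometric probability of the overlap between mutated genes and
each pathway against a background universe, BH-corrected across
pathways. The copy-number burden comparison is a one-sided Mann–Whitney
test (the underlying procedure names no statistic; Mann–Whitney is the
standard choice for a shifted-burden alternative, and published
machine-epsilon p-value floors are not treated as reproduction
targets). Mutation spectra use the standard six pyrimidine-context
classes with purine-reference substitutions folded onto their reverse
complements.

## The synthetic cohort generator

`sim_config()` fixes the study conditions: 51 stage I and 53 stage III
tumors; a planted gene mutated at 35% vs 8% by stage over a 3%
background; planted recurrent copy-number regions (an amplification of
mean CN 3.2 biased to stage I and a deletion of mean CN 1.0 biased to
stage III, 40% carrier frequency within the biased stage) over
Gaussian-jittered diploid segments (σ = 0.15, floored at 0); a higher
random segment-alteration rate in stage III (10% vs 2%) so stage III
carries the larger SCNA burden; sequencing depth negative-binomial with
mean 100 (the deep-exome scale; overdispersion size 20) and 90-bp
reads; six candidate-site classes mixed 50/15/10/10/10/5; and 36
atypical-hyperplasia qPCR samples assayed in triplicate with Ct noise
of 0.05 cycles on a reference baseline near cycle 25. Everything flows
from a single seed through named per-stage substreams, and identical
configurations reproduce byte-identical outputs.

Site classes are *criteria-defined*: each class either satisfies all
nine somatic criteria or violates one specific criterion, and these
defining properties hold **by construction**, not merely in
expectation. Count constraints are enforced by flooring/capping the
drawn counts (clean sites keep tumor VAF ≥ 10% with ≥ 3 alt reads and
normal VAF < 2%; low-VAF sites stay below 10%). Positional and strand
properties are enforced by resampling: clean sites redraw read offsets
while the read-end test would reject them (a level-0.1 test rejects
roughly one exchangeable draw in ten, so without this guarantee a
"clean" label would disagree with its own definition at that rate), and
strand-artifact sites carry at least 20 alt reads — the scale at which
an all-one-strand configuration can breach the 1e-4 rejection threshold
at all (at typical depths the bound becomes attainable near 18 alt
reads) — and redraw their balanced background while the strand test
fails to reject. Truth labels are recorded independently of any filter
output, and the class-separability results should be read accordingly:
they demonstrate that the filter agrees with the class definitions, not
a detection rate on artifacts too weak to be detectable in principle.

The generator deliberately does not model tumor purity or clonal
structure, contamination, alignment or mapping error (evidence arrives
post-alignment), indel realignment, sequence-context error profiles, or
realistic genome-scale coverage variation; read base composition is
drawn from a balanced lane-wide pool, so GC-biased lanes must be
constructed explicitly. Conclusions from passing tests therefore
transfer to real data only insofar as real evidence resembles these
idealized classes.

## Numerical choices and problem sizes

Exact rank-test nulls are used up to 25 (one-sample) / 10-per-group
(two-sample) observations, normal approximations with tie and
continuity corrections beyond; empirical permutation p-values are
never below `1/(1+B)`; Fisher p-values come from `stats::fisher.test`
and are verified against full hypergeometric enumeration to 1e-12 for
tables with small totals. Default problem sizes throughout the test and
acceptance suites — 500 sites per class, 500–1,000 markers, 40–104
samples, 1,000 permutations — were chosen as the smallest scales at
which the stochastic properties under test are stable across seeds.

## Known limitations

The G-score normalization and permutation scheme of the original
GISTIC-style analysis are not fully specified by its description;
region counts obtained on real cohorts depend on additional merging
heuristics and are not reproduction targets here. The indel module
classifies post-realignment support counts only. The "any evidence"
germline rule (1 supporting read in any normal) is aggressive under
sequencing noise; the `min_support` knob exists for that reason but
defaults to the literal rule.
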