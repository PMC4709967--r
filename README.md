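# oncostage

Stage-associated somatic variant filtering and copy-number significance
for tumor cohorts.

Tumor cohorts profiled at different clinical stages (e.g. AJCC stage I
vs stage III esophageal squamous cell carcinoma, plus premalignant
atypical-hyperplasia validation samples) pose a recurring set of
computational tasks: deciding which candidate single-nucleotide
variants are genuine somatic events from raw tumor/normal read
evidence; gating sequencing lanes, reads and samples on quality;
separating somatic from germline indels; finding recurrently amplified
or deleted genomic regions and asking whether copy-number burden
differs by stage; validating copy-number calls by qPCR; and testing
genes and pathways for stage-biased mutation. `oncostage` implements
this workflow as composable, tested R functions, driven by a fully
seeded synthetic-cohort generator so that every stage runs without any
external or controlled-access data.

## What it computes

- **Somatic SNV filter** (`evaluate_site`, `filter_cohort`): nine
  read-level criteria — tumor/normal depth ≥ 10×; tumor VAF ≥ 10 % (5 %
  in validation mode) with normal VAF < 2 %; ≥ 3 alt reads; > 10 bp
  between adjacent candidates; alt-read MAPQ significantly above 30
  (one-sided signed-rank, p < 0.2) and base quality above 20
  (p < 0.05); no read-end enrichment (one-sided rank-sum, reject at
  p < 0.1); significant tumor/normal allele-frequency contrast (Fisher,
  p < 0.05); no strand bias (Fisher, reject at p < 1e-4). Exact
  conditional rank-test nulls are computed even under ties.
- **QC gates** (`check_lane`, `filter_reads`, `check_sample`): error
  rate ≤ 2.5 %, Q20 ≥ 80 %, Q30 ≥ 75 %, GC/AT separation ≤ 0.4 %;
  per-read N-rate and low-quality rules; per-sample depth/mapping/
  mismatch rules.
- **Indel classification** (`classify_indel`): germline iff any normal
  shows supporting evidence at the locus.
- **Copy-number significance** (`make_marker_matrix`, `gscore_track`,
  `significant_regions`, `scna_burden`): segments projected onto 1-kb
  marker windows; per-marker score
  `G = frequency × mean amplitude` of amplification (CN ≥ 2.5) or
  deletion (CN ≤ 1.5); permutation null from per-sample circular
  shifts; significant iff `G > 0.1` **and** empirical `p < 0.05`.
- **qPCR copy number** (`ddct_copy_number`): comparative Ct,
  `CN = 2·2^(−ΔΔCt)` against a diploid reference assay and calibrator;
  CN < 0.3 flags homozygous deletion.
- **Cohort statistics** (`gene_frequency_table`,
  `stage_association_test`, `pathway_enrichment`, `compare_burden`,
  `mutation_spectrum`, `smg_combination_summary`): mutation-landscape
  classes (mountains ≥ 10 %, hills 5–10 %), Fisher stage tests with
  Benjamini–Hochberg correction, hypergeometric pathway enrichment,
  one-sided rank-sum burden comparison, six-class pyrimidine-folded
  spectra.
- **Synthetic cohorts** (`sim_config`, `simulate_cohort`,
  `simulate_site_evidence`): a 51 + 53 two-stage cohort with planted
  stage-biased genes (35 % vs 8 %), planted CNV regions, six
  criteria-defined candidate-site classes, qPCR Ct tables and QC read
  records — all byte-reproducible from one seed.

See `vignettes/staged-cohort-genomics.Rmd` for the full model
descriptions and design decisions.

## Worked example

```r
library(oncostage)

cfg <- pipeline_config(seed = 1)
cfg$sim$n_sites <- 60L
cfg$cnv$n_permutations <- 500L
rep <- run_pipeline(cfg, outdir = "pipeline_out")

round(rep$recovery, 3)
#>    clean_somatic         germline          low_vaf lowqual_artifact
#>                1                0                0                0
#> readend_artifact  strand_artifact
#>                0                0

signif(rep$burden_comparison$p.value, 3); rep$burden_comparison$direction
#> [1] 1.13e-11
#> [1] "stage3 > stage1"

head(rep$stage_tests[order(rep$stage_tests$p.value), ], 1)
#>  feature n_stage1 n_stage3 odds_ratio      p.value    p.adjust
#>  gene001       17        3   8.172807 0.0003724944 0.004097438

rep$regions$amp
#>  chrom  start    end n_markers peak_start peak_end    peak_g
#>   chr1 100000 120000        20     100000   101000 0.2948915
```

Reading the output: every labelled clean somatic site passed the
nine-criterion filter and every artifact class was rejected
(`recovery`); stage III samples carry significantly more copy-number
burden than stage I; the planted stage-biased gene (`gene001`, mutated
in 17/51 stage I vs 3/53 stage III samples in this draw) is the top
stage-associated feature; and the planted amplification is recovered as
one significant 20-kb region whose peak marker reaches a G-score of
0.29. `pipeline_out/` holds the VCF of passing sites, the verdict and
G-score tables, and a manifest of MD5 hashes — rerunning the same
config reproduces identical files.

A thin command-line wrapper is provided at
`inst/scripts/run_pipeline.R`:

```sh
Rscript inst/scripts/run_pipeline.R --config sim.yaml --seed 1 --outdir out/
```

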