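# necmgs

Shotgun-metagenomics quantification and statistics for studying long-term
gut-microbiota dysbiosis after necrotizing enterocolitis (NEC), exercised
end to end on a fully synthetic cohort with known ground truth.

NEC is an acute intestinal disease of preterm neonates, treated either
medically or by surgical resection. Studies of NEC survivors compare the
gut microbiota of three groups of children — preterm controls, medically
treated NEC and surgically treated NEC — and ask whether NEC, or rather
its treatment, leaves a lasting imprint: lower species diversity, higher
dominance of single taxa, and an association between neonatal antibiotic
exposure and later diversity. `necmgs` reimplements that analysis chain
as a tested, reproducible R package for methodologists who want to probe
each rule of the pipeline rather than rerun it on protected patient data.

## What the package computes

**Quantification.** Reads are profiled with the metagenomic species (MGS)
model: a reference catalog of genes is partitioned into MGSs, each with a
100-gene *signature* set. A read pair counts toward a gene when uniquely
mapped (MAPQ ≥ 20, identity ≥ 95 %, aligned length ≥ 100 bp, ≤ 10
unaligned bases; if both mates map uniquely to different genes, read 1's
gene is counted). An MGS is detected in a sample only if at least 3 of
its signature genes receive reads; surviving counts are divided by the
mean effective signature-gene length (L − r + 1) and normalized per
sample to 100 %. Rarefaction draws a fixed number of signature-gene
counts per sample without replacement (protocol default 524 050).
Upstream, the HQNH filter keeps read pairs in which neither mate maps to
the host and both mates remain ≥ 100 bp after adapter/quality (Phred
< 30) end-trimming. MGS taxonomy is assigned per rank from blast-like
hits with rank-specific thresholds: identity ≥ PID(rank), at least
M(rank) % of member genes on the taxon, at most D(rank) % on any other.

**Diversity.** Per sample: Shannon H = −Σ pᵢ ln pᵢ, Simpson dominance
λ = Σ pᵢ², richness, Berger–Parker dominance max pᵢ, and the Lorenz
curve/Gini coefficient; between samples: Bray–Curtis dissimilarity,
rarefaction curves and centered PCA.

**Inference.** Fisher's exact test (two-sided, point-probability method),
Mann–Whitney U, Kruskal–Wallis, Spearman correlation, Hedges' g and
Bonferroni correction, plus a per-taxon screen with significance tiers.

**Rule mining.** Continuous clinical and diversity variables are cut into
equal-width interval bins and association rules *antecedent ⇒ Shannon
bin* are scored by support (% of all children matching both sides) and
confidence (% of antecedent-matching children also in the consequent),
e.g. with n = 39 every support is a multiple of 100/39 ≈ 2.56 %.

**Synthetic cohort.** `simulate_cohort()` reproduces the study design (24
controls, 7 medical NEC, 8 surgical NEC; antibiotic-day medians 10/28/36)
and `simulate_truth_profiles()` draws true compositions whose evenness
decreases, and dominance increases, from control to surgical NEC, with
antibiotic days negatively coupled to Shannon diversity.
`simulate_alignments()` emits the alignment evidence for any read depth,
so the whole quantification chain can be tested against known truth.

## Worked example

```r
library(necmgs)
library(dplyr)

cfg <- nec_config(seed = 101, depth = 5000,
                  catalog_args = list(n_mgs = 30, genes_per_mgs = 60,
                                      signature_size = 20))
b <- run_nec_pipeline(cfg)

b$diversity |>
  group_by(group) |>
  summarise(median_shannon = median(shannon),
            median_simpson = median(simpson),
            median_bpd = median(berger_parker))
#>   group        median_shannon median_simpson median_bpd
#> 1 control                2.81         0.0912      0.212
#> 2 nec_medical            2.67         0.0944      0.194
#> 3 nec_surgical           2.04         0.223       0.414
b$kw_shannon$p
#> 3.46e-05
```

The surgical-NEC group shows the expected contrast: about 0.8 nats less
Shannon entropy than controls and roughly double the dominance, with a
Kruskal–Wallis p-value far below 0.05. The mined rules read the same
way — e.g. the top rule says every child in the lowest antibiotic bin
fell in a high-Shannon bin:

```r
head(tidy(b$rules), 2)
#>   antecedent                  consequent        n_antecedent n_joint support confidence
#> 1 antibiotic_days_bin=[3, 22) shannon_bin=[...]           28      28    71.8        100
#> 2 group=control               shannon_bin=[...]           24      24    61.5        100
```

Single statistics work on plain vectors or tibbles:

```r
fisher_exact_2x2(4, 3, 1, 23)   # 0.005 — abdominal surgery, medical NEC vs control
alpha_diversity(tibble::tibble(sample_id = "a", s1 = 50, s2 = 25, s3 = 25))
#>   sample_id shannon simpson richness berger_parker  gini
#> 1 a            1.04   0.375        3           0.5 0.167
```

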