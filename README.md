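# snquant

Paralog-resolved quantification of spliceosomal snRNA isoforms from short
RNA-seq reads.

## The problem

Spliceosomal snRNAs (U1, U2, U4, U5) are expressed from small families of
near-identical gene copies — sequences that differ at a handful of
nucleotide positions, and in some cases not at all. Short reads from these
genes map to several family members at once, so generic aligners assign
them arbitrarily and per-copy expression estimates come out wrong. The
biological signal of interest is the *composition* of each subtype's
population: what fraction of the U5 pool, say, comes from each
distinguishable isoform, and how that composition shifts across
developmental stages from heterogeneous expression toward dominance of a
single isoform.

snquant is for transcriptomicists who need those fractions from bulk
short-read data without hand-curating read assignments. It treats
ambiguity explicitly:

1. **Catalog** — gene copies with byte-identical sequences are collapsed
   into isoform groups; for a read length *k*, *diagnostic regions* are
   computed: maximal intervals of read-start positions whose *k*-mer
   matches exactly one subset of groups.
2. **Assignment** — each read is matched exactly (no mismatches) against a
   *k*-mer index and assigned the full subset of groups containing it,
   giving per-sample *class counts*; a mismatch-tolerant screen separately
   estimates how many reads point to unannotated variants.
3. **Estimation** — with `A[c,g]` the number of read starts in group `g`
   producing class `c` and `n_c` the observed class counts, per-start
   intensities solve the non-negative least-squares system
   `min ‖A s − n‖₂, s ≥ 0`, and fractions are `f_g = s_g / Σ s_h`. Groups
   no read class can separate are lumped into a composite, with a warning.
   Families where every group has unique regions may instead use the
   direct singleton-class estimator (`mode = "unique"`).
4. **Dominance** — per ordered stage, mean fractions with across-replicate
   SDs, and the *dominance SD*: the standard deviation of the fraction
   vector across a subtype's groups (0 for even expression, `√(1/G)`-scale
   when one isoform dominates), tracked along the stage order.

A seeded synthetic-data generator (families with planted variable sites,
Dirichlet stage mixtures with a rising dominant isoform, error-bearing
reads with truth tables) makes the whole pipeline testable without any
external accession.

## Worked example

Four genes, two of them identical, quantified over three stages:

```r
library(snquant)

fam <- generate_family(4, 150, 4, identical_partition = list(c(1, 2), 3, 4),
                       family = "U9", seed = 8)
groups <- collapse_identical(fam$genes)
groups$group_id
#> [1] "U9:g01/g02" "U9:g03"     "U9:g04"

mix <- generate_mixture_trajectory(3, c("embryo", "larva", "adult"), seed = 9)
idx <- build_index(groups, 33)
design <- build_design_matrix(diagnostic_regions(groups, 33), groups)

est <- list()
for (i in 1:3) {
  st <- rownames(mix$fractions)[i]
  sim <- simulate_reads(setNames(groups$sequence, groups$group_id),
                        mix$fractions[st, ], 20000, 33, seed = 10 + i)
  est[[st]] <- estimate_fractions(assign_reads(sim$reads, idx, st), design)
}
est$adult
#> Fraction estimate for adult ( linear_system , 20000 informative reads )
#> U9:g01/g02     U9:g03     U9:g04
#>     0.7184     0.1574     0.1243

trajectory(lapply(names(est), function(s) aggregate_stage(est[[s]], s)),
           family = "U9")
#> Dominance trajectory for U9 ( non-decreasing )
#>   stage dominance_sd dominant_group dominant_fraction
#>  embryo   0.05397294     U9:g01/g02         0.3956402
#>   larva   0.31745791     U9:g01/g02         0.6945166
#>   adult   0.33387131     U9:g01/g02         0.7183808
```

The two identical genes are reported as one measurable group
(`U9:g01/g02`). The adult estimate (0.7184, 0.1574, 0.1243) recovers the
planted mixture (0.7193, 0.1607, 0.1200) to well within sampling error at
20,000 reads, and the dominance SD rises across stages as the dominant
isoform takes over — the developmental switching signature.

## The analysis workflow

`analysis/` holds the study as numbered drivers over the package; each
writes its tables under `results/study/`:

```sh
Rscript analysis/01_simulate_study.R   # plant family, mixtures, FASTQs, sheet
Rscript analysis/02_build_catalog.R    # groups, variable sites, regions
Rscript analysis/03_assign_estimate.R  # class counts, per-sample fractions
Rscript analysis/04_stage_dominance.R  # stage summaries, dominance trajectory
Rscript analysis/05_variant_screen.R   # mismatch screen
```

`run_pipeline()` performs steps 2–5 as one call from a config (R list or
YAML); `simulate_and_run()` adds data generation and a truth-recovery
report.

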