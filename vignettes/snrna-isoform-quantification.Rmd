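---
title: "Quantifying snRNA isoform fractions from short reads: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying snRNA isoform fractions from short reads: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snquant)
```

## The problem

Spliceosomal snRNAs are encoded by small families of near-identical gene
copies — in *Drosophila*, five U1 genes, six U2, three U4, seven U5 — whose
mature sequences differ at only a handful of positions, and some copies not
at all. A short RNA-seq read therefore often fits several paralogs equally
well, and a generic mapper distributes such reads arbitrarily, corrupting
per-copy expression estimates. Yet the quantity of biological interest is
exactly the *fractional* contribution of each distinguishable isoform to its
subtype's population, and how that composition shifts across development
from heterogeneous expression toward dominance of a single isoform.

snquant makes the ambiguity explicit instead of hiding it. Gene copies with
byte-identical sequences are collapsed into a single measurable **isoform
group**; every read is assigned — by exact match, no mismatches tolerated —
to the *subset* of groups that contain it; and the subset-level counts are
deconvolved into group fractions.

## The quantification model

Fix a family with groups $g = 1, \dots, G$ and a read length $k$. For every
group and every valid read start $p \in \{1, \dots, L_g - k + 1\}$ the
$k$-mer starting at $p$ occurs in some subset $S$ of the family's groups; a
maximal run of consecutive starts with the same subset is a **diagnostic
region**. Read starts are modelled as uniform over valid starts, so if
$A_{cg}$ denotes the number of starts in group $g$ whose $k$-mer yields
match class $c$ (the sum of that group's region widths for class $c$), the
expected count in class $c$ is

$$\mathbb{E}[n_c] \;=\; \sum_g A_{cg}\, s_g,$$

with $s_g$ the per-start read intensity of group $g$. The estimator solves

$$\hat s \;=\; \arg\min_{s \ge 0} \;\lVert A s - n \rVert_2$$

by non-negative least squares (`pracma::lsqnonneg`) and reports fractions
$\hat f_g = \hat s_g / \sum_h \hat s_h$. Two special cases matter:

* **Fully distinguishable families** (each group has a region unique to
  itself, the U1/U4/U5 situation): the singleton-class counts alone
  determine the answer, and the `mode = "unique"` estimator
  $\hat f_g \propto n_{\{g\}} / A_{\{g\}g}$ is available. When class counts
  sit exactly at their expectation the two estimators coincide; under
  sampling noise the linear system also uses the ambiguous classes and is
  the default.
* **Structurally confounded groups** (identical columns of $A$ — no read
  class whatsoever separates them, the situation that forces lumping of
  U2-like pairs): the groups are merged into a composite with a
  concatenated id, with a warning, rather than returning an arbitrary
  split of an unidentifiable quantity.

Normalisation uses a per-group length weight fixed at 1: snRNA paralogs
within a family have near-identical lengths, so the number of valid starts
is essentially shared; the weight is exposed as `length_weights` for
families where that assumption fails.

### Read assignment

The exact-match classifier is a $k$-mer table: every $k$-mer of every group
sequence maps to the subset of groups containing it. A read longer than $k$
is trimmed at the 3′ end (real libraries mix 33–51-nt reads; one fixed $k$
per run keeps class semantics coherent); a read shorter than $k$ is counted
separately as too short and treated as unmapped. Each read contributes to
exactly one class — its full matched subset; apportioning is left entirely
to the linear system. $k$-mers containing `N` match nothing. Matching is
forward-strand: snRNA references are given in sense orientation.

### Stage aggregation and the dominance statistic

Samples are pooled by developmental stage (the sample sheet assigns
stages; e.g. 0–8 / 8–16 / 16–24 h embryo pools). Per stage, the mean
fraction vector is the arithmetic mean over replicates, renormalised; the
across-replicate SD (always the $n-1$ form) is reported only when at least
two samples are available. Count tables are sufficient statistics, so
high-variance replicate sets can alternatively be summed with
`pool_counts()` before estimation — concatenating reads and summing counts
give identical estimates.

Isoform dominance at one stage is summarised as the SD of the mean fraction
vector *across the groups*:

$$\mathrm{SD}(f) = \sqrt{\tfrac{1}{G-1}\sum_g (f_g - 1/G)^2},$$

0 when all isoforms are expressed evenly and maximal when one isoform
carries the whole population. `trajectory()` evaluates it per stage on the
stage mean vectors (one value per stage, not an average of per-sample SDs),
reports each stage's dominant group (ties broken lexicographically, with a
warning) and a trend flag that is true when the SD is non-decreasing along
the stage order. The $n-1$ denominator is a convention choice — nothing in
the statistic's use depends on it, and a `denominator = "population"`
switch is provided.

### Variant screen

A separate mismatch-tolerant pass guards the catalog itself: every read is
scanned end-to-end against every group at every offset (substitutions
only, no indels) and the percentage of aligned reads whose best placement
contains at least one mismatch is reported. A noticeable percentage would
indicate expressed sequence variants absent from the catalog. "Percentage"
is ambiguous between an all-reads and an aligned-reads denominator; the
aligned-read figure is primary and both are emitted.

## The synthetic-data generator

Real inputs for this kind of study are large external RNA-seq accessions,
so the package carries a generator that plants known truth at the study's
scale and makes every stage of the pipeline testable offline:

* **Families**: one random backbone of length 100–250 nt; a chosen
  partition of genes into identical-sequence cells; a handful of planted
  variable columns whose per-cell residues make every pair of cells
  differ somewhere (specs that cannot distinguish their cells are rejected
  as infeasible). This reproduces the structural facts that drive the
  method: identical copies, few variable sites, shared differences.
* **Trajectories**: one fraction vector per stage from a symmetric
  Dirichlet whose concentration decays geometrically from 5 to 0.3 across
  stages, the sampled maximum swapped into the designated dominant group,
  and stages ordered by ascending dominant fraction. Early stages are
  thus heterogeneous and late stages dominated — by construction the
  *dominant fraction* is non-decreasing; the dominance SD usually rises
  too, but is not forced to, since the minor fractions still fluctuate.
  An `alpha_schedule = "uniform"` flag gives exact $1/G$ mixtures.
* **Reads**: source group drawn from the stage mixture, start uniform
  over valid starts, each base independently substituted (always to a
  different base) with probability `error_rate`; no indels, constant 'I'
  qualities. A truth table (source group, start, error count) accompanies
  every FASTQ.

Default study conditions mirror an Illumina-style design: a 7-group family
of length 165 nt with 6 variable sites, 48-nt reads, 50,000 reads per
sample, stage plan `early_emb/mid_emb/late_emb` ×4, `L3` ×2, `pharate` ×4.

What the generator deliberately does *not* emulate: non-uniform coverage
profiles along the snRNA (unknown for real libraries and assumed flat),
indels, quality-dependent errors, colorspace chemistry, and RIP-seq
enrichment. Passing tests therefore demonstrate correctness of the
*assignment-and-deconvolution machinery* under the stated read model, not
robustness to real-library coverage bias.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere a user sees them.
* Fraction vectors are renormalised to sum to 1 within 1e-9; test
  comparisons use 1e-6 unless an example is exact.
* Non-negativity is enforced by constrained least squares, never by
  clamping, so estimates are well-defined at the boundary.
* Zero informative reads, empty FASTA, ragged alignments, overlapping
  region sets and mixed group sets all raise immediate errors rather than
  propagating NaNs; malformed FASTQ errors name the offending record.
* Alignment of unequal-length sequences uses global alignment with match
  +1 / mismatch −1 / gap −2 and traceback ties broken toward the
  diagonal, threaded progressively onto the longest sequence. Equal-length
  inputs (the usual snRNA case) bypass alignment entirely, and a
  user-supplied aligned FASTA is always taken verbatim.
* Determinism: every stochastic function takes an explicit integer seed
  and touches the RNG only inside `withr::with_seed`; pipeline runs are
  byte-reproducible, and the run manifest records a config hash with paths
  reduced to basenames so relocated copies of the same run are recognised.
* Within-family uniqueness stands in for genome-wide unique mappability;
  cross-family k-mer collisions are checked once at catalog build and
  warned about.

## Problem sizes used by the test-suite and benchmark

The packaged validation uses 20 seeded random families (2–5 groups,
120–200 nt, $k \in \{33, 48\}$) checked read-for-read against a naive
substring-search oracle; 50 independently seeded recovery studies of the
default 7-group design (5 stages × 2 replicates × 50,000 error-free
reads), requiring every fraction within ±0.02 of truth in ≥95% of
replicates; and a 50,000-read error run at rate 0.005 checked against the
closed-form exact-match survival $1 - (1-e)^k$. These sizes give binomial
standard errors comfortably below the tolerances they are checked against
(e.g. SE ≈ 0.002 on a fraction at 50,000 reads).

## Known limitations

* Uniform read starts are an assumption, not an observation; strongly
  biased coverage would re-weight the design matrix and is not modelled.
* Family-level uniqueness ignores pseudogenes and repetitive flanks that
  genome-wide mapping would have to confront.
* Fractions only: absolute abundances, bootstrap uncertainty and formal
  trend tests are out of scope; the across-replicate SD is the only
  dispersion reported.
* The variant screen finds substitution variants within read length of a
  known paralog; novel genes diverged by indels or rearrangement are
  invisible to it.
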