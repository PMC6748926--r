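---
title: "Methods: core microbiome, selection and proteome allocation in soda-lake mats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: core microbiome, selection and proteome allocation in soda-lake mats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sodamat)
```

`sodamat` re-implements, as tested and composable functions, the downstream
computations of a multi-lake soda-lake microbial-mat survey: core-microbiome
detection, MAG abundance estimation, a diversifying-selection screen,
cross-region genome matching, and metaproteome resource allocation. This
vignette records the models, the parameters that matter, the numerical
choices, and what the synthetic data do and do not establish.

## Core microbiome

An OTU is *present in a lake* when its raw count reaches `min_count`
(default 1) in at least one sample of that lake, pooling all sampling years.
This pooling reflects how multi-year surveys state "found in all lakes": a
taxon seen in any year counts as a resident. The core set is the intersection
of per-lake presence. `min_count` is exposed because single-read detections
are fragile; raising it can only shrink the core (a tested monotonicity).

Two summary fractions are reported. The *richness fraction* divides the core
size by the number of OTUs with nonzero total count over the whole table —
the closest literal reading of "the region's species richness". The *read
fraction* is computed over reads pooled across all samples; whether such a
statistic should be pooled or averaged per sample is usually unstated in
survey reports, so the per-sample mean is also returned
(`read_fraction_per_sample_mean`).

Bray–Curtis dissimilarities are computed on per-sample relative abundances
(sequencing depth varies between samples); a raw-count mode exists for
sensitivity. The computation is delegated to `vegan::vegdist`, and the test
suite checks it against a brute-force per-pair loop to 1e-12. Rare-OTU
exclusion retains an OTU only if it reaches the threshold (default 1%)
relative abundance in at least one sample — the complement of "below 1% in
all samples". 16S and 18S tables are processed separately: relative
abundances of Bacteria and Eukaryotes are not comparable across amplicons, so
the package never merges markers. Ordination (NMDS) is out of scope; the
dissimilarity matrix is exported for external tools.

## MAG relative sequence abundance

The estimator is

\[
\text{abundance} = \frac{\bar d \cdot G}{N},
\]

where \(\bar d\) is the MAG's length-weighted mean contig depth
\(\sum_i \ell_i d_i / \sum_i \ell_i\), \(G\) the MAG assembly size (sum of
its contig lengths — the quantity actually available, not an estimated
complete-genome size), and \(N\) the total nucleotides sequenced in the
sample. Length weighting is the depth-table convention and the only
aggregation that conserves nucleotides: splitting a contig in two leaves the
estimate unchanged (tested). When \(N\) is not supplied it is computed as
\(\sum_i \ell_i d_i\) over all contigs, in which case MAG abundances plus the
unbinned remainder sum to exactly 1. Whether "total nucleotides" means pre-
or post-QC bases is a data-provenance question; the function simply takes the
number it is given.

Variant co-occurrence treats a variant as present where its abundance
strictly exceeds `min_abundance`. The default 0 means "any nonzero evidence",
which is deliberately permissive: the scientific claim being checked is that
near-identical genome variants are *not* mutually exclusive across samples,
so the default favours detecting presence and the threshold is exposed for
stricter analyses.

## Diversifying-selection screen

The screen consumes in-frame alignments of 2–5 variants of one gene. A *SNP*
is an alignment column with at least two distinct states in `{A,C,G,T}` and
no gap or `N` in any row — a per-gene column count, not a pairwise-difference
count. Columns containing a gap or `N` anywhere are excluded from both the
SNP count and the denominator of "positions" (indels are not SNPs and break
the frame). The consensus state is the majority, ties resolved to the
lexicographically smallest base so results are deterministic.

Each SNP is classified against the *consensus codon* — the codon built from
column consensuses, with the variable column substituted — under the
bacterial genetic code (translation table 11; all screened genomes are
bacterial). Stop gain and stop loss are protein-changing and therefore
non-synonymous. A multi-allelic SNP is non-synonymous if *any* alternative
state is non-synonymous (conservative toward detecting diversification; a
flag requires all). This column-independent classification is the simplest
deterministic reading; path-dependent codon-path counting in the
Nei–Gojobori style is a known alternative and is intentionally out of scope,
as are dN/dS rate models.

A gene is *diversified* only when all three strict inequalities hold:
more than 50 SNPs, more than 1% of considered positions polymorphic, and a
non-synonymous SNP fraction above 0.825. The boundary behaviour is pinned by
engineered fixtures: genes constructed with exactly 50 SNPs, exactly 1.0%
polymorphic positions, or a non-synonymous fraction of exactly 0.825
(66/80) all fail. The 0.825 bar sits well above the neutral expectation of a
typical CDS (`expected_neutral_nonsyn_fraction()` enumerates all \(3L\)
substitutions; values around 0.70–0.77 are typical), so genes under neutral
substitution rarely pass — the simulated neutral genomes in
`analysis/04_selection_screen.R` illustrate both the typical failure and the
occasional chance passer.

## Cross-region matching

`estimate_ani()` is a deliberately small fragment-recruitment estimator: the
query is cut into non-overlapping 1020-bp fragments; each fragment is seeded
onto the reference by exact 16-mer match and scored by ungapped identity at
the implied offset; fragments reaching 80% identity are recruited; ANI is the
mean identity of recruited fragments and the aligned fraction is the
recruited share. The defaults echo common ANI practice at desk scale. The
estimator is *directional* (fragmentation follows the query) — swapping
arguments can change the aligned fraction, and a test documents this. With
ungapped extension only, it is appropriate for substitution-divergent
genomes; for indel-rich real genomes a precomputed ANI table should be used
instead of this estimator. Self-comparison is exactly 100 whenever the
fragment length divides the genome.

Genetic distance is defined as \(100 - \text{ANI}\) (percent). The
distance–abundance relationship is tested with the product-moment Pearson
correlation; the two-sided p-value uses
\(t = r\sqrt{(n-2)/(1-r^2)}\) on \(n-2\) degrees of freedom (via
`stats::cor.test`), which the tests check against a 10,000-draw permutation
oracle. The abundance transform (identity or log10) is an explicit argument
because real analyses differ; the generator plants divergence on the log10
scale, and recovery is tested with that transform.

## Metaproteome allocation

Identification filtering discards records with FDR strictly above 0.05
("FDR > 5% discarded" — a record at exactly 0.05 is retained), with fewer
than 2 unique peptides, or without a protein-unique peptide; every rejection
is logged with its reason and filtering is idempotent. Peptide-level
filtering is out of scope: the input is a protein-level table.

"Normalised spectral abundances" is implemented as NSAF:
\(a_i = (c_i/L_i)/\sum_j (c_j/L_j)\), length-normalised spectral counts
renormalised to sum to 1. A plain count-fraction mode exists for sensitivity,
and doubling all lengths leaves shares unchanged (tested ratio property).
Technical replicates should be summed into one count column before
normalisation; a per-replicate analysis simply passes a different column. A
MAG's metaproteome share divides the summed abundances of its proteins by
the summed abundances of all proteins — the denominator is explicit so
pre-normalised and raw vectors behave identically. Within-MAG category
shares sum to 1 with unlabelled proteins pooled as `"other"`, and
housekeeping normalisation divides a category's share by the combined share
of ribosomal proteins, translation factors and chaperones in the same MAG,
making expression comparable between MAGs of different absolute abundance
(scale invariance is tested).

## Synthetic data: what it emulates, and what it does not

The generators define the study conditions under which the pipeline is
validated:

- `simulate_otu_table()` — default 4 lakes × 3 years (one sample per lake and
  year), 500 OTUs with lognormal mean abundances (sdlog 1.2), a planted core
  of 20% boosted 10× in abundance, 50,000 reads per sample drawn
  multinomially, and mild lognormal year-to-year wobble (sdlog 0.3). Non-core
  OTUs are *structurally* absent from at least one lake, not merely rare, so
  core recovery is exactly decidable; with these depths the planted core is
  recovered exactly at `min_count = 1`, and the boosted core accounts for
  roughly 80% of reads — the regime of interest, where few shared taxa carry
  most of the sequencing signal. The lognormal shape is a standard
  rank-abundance stand-in, not an inference about any real community.
- `simulate_genome()` / `mutate_genome()` — random genomes with non-
  overlapping in-frame CDSs (ATG start, no internal stop, table 11). Mutation
  modes `synonymous_only` / `nonsynonymous_only` draw only substitutions of
  the planted class; these constrained modes mutate at most one site per
  codon, because two same-codon hits would make the column-independent
  consensus-codon classification ambiguous, and the point of the planted
  classes is exact recoverability. Neutral mode is unconstrained and its
  mutation count is binomial (tested against the 3-sigma envelope).
- `simulate_region_pair()` — 48 matched pairs of 10-kb genomes by default;
  divergence declines 3 percentage points per log10-abundance decade around a
  6% base with 0.5% Gaussian noise, clamped to [0, 30]%. The *realised*
  substitution fraction of each pair is recorded as truth, so ANI recovery is
  compared against what was actually planted.
- `simulate_psm_table()` — 8 MAGs plus an unbinned remainder with
  Dirichlet-like shares; within each bin, category weights (including the
  housekeeping trio) are split exactly across proteins, and spectral counts
  are drawn multinomially from *length-weighted* abundances so that NSAF
  inverts the sampling design. Planted filter violators carry exactly one
  violated rule each.

All generators draw from per-generator seed-derived streams, so adding draws
to one never perturbs another, and every generator is byte-deterministic
under a fixed seed (tested).

What passing these tests does **not** show about real data: no read-level
error model, chimeras, indels, misbinning, shared k-mer artefacts between
unrelated genomes, peptide-to-protein inference ambiguity, or compositional
coupling between markers. The synthetic surface validates the *arithmetic
and decision rules* of the pipeline — thresholds, normalisations,
conservation properties, estimator inversion — not the upstream measurement
process.

## Numerical choices and degenerate inputs

- Problem sizes in the test suite and acceptance script (50-kb genomes for
  ANI recovery, 10-kb genomes for the 48-pair correlation, 10,000-draw
  calibrations and permutation oracles) were chosen as the smallest sizes at
  which sampling noise is comfortably below the tested tolerances.
- Zero considered positions (an all-gap/N gene) yields `diversified = FALSE`
  with a diagnostic flag, never an error or a silent pass.
- ANI with no recruited fragment returns `ani = NA` with
  `aligned_fraction = 0` — an explicit sentinel, not 0% identity.
- Zero housekeeping share returns `NA` with a warning from
  `housekeeping_normalize()`.
- Ties in `best_match()` break by higher aligned fraction, then
  lexicographic id, so matching is deterministic.
- Relative abundances divide by `max(column sum, 1)` so all-zero samples
  propagate zeros rather than NaNs.

## Known limitations

- The ANI estimator has no gapped extension and a single seed length; it is a
  calibration-grade tool for substitution-divergent synthetic genomes, not a
  replacement for production ANI software on real assemblies.
- The screen classifies each polymorphic column independently against the
  consensus codon; simultaneous same-codon substitutions are interpreted
  column-wise.
- The SNP-position denominator (gap-free columns) and the column-based SNP
  definition are documented interpretation choices; pairwise-difference
  counting would give different numbers on the same alignment.
- Proteome accounting assumes protein-level records with trustworthy
  unique-peptide counts; no protein inference is performed.
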