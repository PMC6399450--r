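---
title: "Marker-gene OTU profiling: models, parameters and design choices"
author: "motulite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-gene OTU profiling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

motulite profiles microbial communities from shotgun metagenomes using ten
universal, single-copy, protein-coding phylogenetic marker genes (MGs;
COG0012, COG0016, COG0018, COG0172, COG0215, COG0495, COG0525, COG0533,
COG0541, COG0552). Because every prokaryotic genome carries each of these
genes exactly once, read coverage of a marker gene is directly proportional
to the abundance of the cells carrying it — no genome-length or copy-number
normalization is needed, and species without sequenced reference genomes can
be profiled from marker genes assembled out of metagenomes.

The database is a three-level hierarchy. Marker genes are clustered
per COG family into species-level **marker gene clusters (MGCs)** at 96.5%
nucleotide identity. MGCs of the ten different COGs that belong to the same
species are grouped into a **mOTU** (marker-gene-based operational taxonomic
unit): for reference genomes the grouping is known from species clustering of
the genomes (specI-style), for metagenome-derived MGCs it is inferred by
co-abundance binning. A mOTU must hold 6–10 MGCs, at most one per COG; MGCs
that cannot be binned are pooled into a single "unbinned" group, written as
`"-1"` in profiles, which quantifies organisms that are detected but not
resolved to a species bin.

## Profiling workflow

Reads aligned to the marker-gene database (SAM input; the package does not
run an aligner) pass through:

1. **Alignment filtering.** Identity = (aligned length − edit distance) /
   aligned length, with the aligned length counted over CIGAR M/=/X columns.
   Records need ≥ 97% identity and ≥ `-l` bases aligned (default 75).
   The edit distance comes from the NM tag, reconstructed from the MD string
   when NM is absent; the per-mate score comes from the AS tag, with
   `aligned_length − 2·NM` as a deterministic, aligner-agnostic fallback.
2. **Insert assignment.** Scores are aggregated per MGC (best alignment per
   mate per MGC, summed over mates); the best-scoring MGC set per insert
   determines a `unique` or `multiple` flag.
3. **Multi-mapper redistribution.** Multiple-flagged inserts are split among
   their best MGCs proportionally to the unique-alignment profile, uniformly
   when none of their targets has unique support. The redistribution is
   single-pass (no EM iteration). Counts are conserved exactly: the MGC
   counts sum to the number of assigned inserts. A consequence worth noting:
   per-MGC counts after redistribution are not strictly monotone under
   stricter filters, because dropping alignments elsewhere re-weights the
   surviving shares; the unique profile and the totals are monotone, and the
   tests assert monotonicity there.
4. **mOTU aggregation.** A mOTU's abundance is the median of its *detected*
   (nonzero) MGC abundances, required to number at least `-g` (default 3).
   We take the median over detected slots rather than all 6–10 slots so that
   the `-g` detection threshold retains its meaning for mOTUs with many
   MGCs; `detected_only = FALSE` switches to the all-slot median. The
   unbinned `"-1"` abundance is the median of the ten per-COG sums of
   unbinned-MGC abundances.

Three output units are produced: `base.coverage` (aligned bases / centroid
coding length), `insert.raw_counts` (integer counts, rounded half away from
zero for platform stability), and `insert.scaled_counts` (coverages rescaled
so the mOTU rows, including `"-1"`, sum to the number of aligned inserts —
coverage-shaped values with count-like totals). Parameter presets trade
precision for recall: high-precision (`-l 140 -g 6`) through max-recall
(`-l 30 -g 1`).

Multi-mapped inserts contribute to base coverage with the same fractional
weights as to counts; the symmetric treatment is a package choice where the
workflow description is silent.

## Clustering

Pairwise global nucleotide identities use Needleman–Wunsch alignment with a
fixed scheme (match +1, mismatch −1, linear gap −2) so that test expectations
are exact; identity is matching columns over all alignment columns. Genome
distances are the gene-length-weighted mean of per-MG distances. Clustering
is average-linkage agglomeration halted when the minimal average
inter-cluster distance exceeds the cutoff (0.035 ≡ 96.5% identity), with
ties broken by the lexicographically smallest label pair for determinism.
Open-reference clustering first assigns metagenomic MGs to existing
reference MGCs (greedily, in decreasing order of best identity, so earlier
joiners are visible to later candidates — the interleaving is a package
choice), then clusters the remainder de novo; alignments under 20 gap-free
columns count as identity 0. The centroid (medoid) of an MGC maximizes mean
identity to the other members, ties resolved lexicographically.

## Co-abundance binning

MGCs of one species co-vary across samples. Per biome, within-sample
relative abundances are computed, optionally log-transformed with a
pseudocount of half the smallest nonzero relative abundance (the transform
literature states "log-transformed relative abundance" without a pseudocount
rule; half the minimum keeps zeros below every observed value), and MGCs
detected in fewer than the biome's prevalence minimum are dropped. Shipped
biome defaults: gut 5/Pearson/log, ocean 5/Pearson/raw, oral 50/Pearson/raw,
vaginal 5/Pearson/log, skin 10/Spearman/log.

Correlations are made comparable across biomes by FDR calibration against
labelled reference pairs (same species cluster or not): the empirical FDR of
the region `corr ≥ t` is monotonized with the standard q-value construction
(minimum over less-extreme thresholds) and the calibrated association is
`1 − FDR`, applied as a step function. Binning proceeds greedily from the
strongest association down to a calibrated cutoff of 0.8 — interpreted on
the `1 − FDR` scale, i.e. stop once the empirical FDR exceeds 0.2 — merging
two groups only if the union keeps at most one MGC per COG. Seed groups
(reference MGCs grouped by species cluster) are only ever extended. Groups
of ≥ 6 MGCs become mOTUs. Binning quality is estimated by resampled k-fold
cross-validation in which held-out reference MGCs are re-binned blind and
pair-level same-species prediction is scored as an AUROC.

## Taxonomy

Marker genes are annotated from protein-homology hit tables by a weighted
lowest common ancestor: hits within 90% of the best bitscore are kept, and
walking up from species the deepest taxon covering ≥ 75% of the retained
bitscore sum wins. MGCs inherit their best-scoring member's lineage. A
meta-mOTU is annotated per rank when ≥ 3 MGCs carry a name there, by
plurality with a lexicographic tie-break, flagged consistent when the
plurality reaches half of the annotated MGCs (non-strict ≥, a package
choice). Ranks are finally forced coherent top-down so lineages stay
gap-free.

## SNV profiling

Only unique-flagged inserts are piled up against one centroid sequence per
MGC, over coding positions only (padding excluded). The filter cascade uses
five parameters: per sample and mOTU, horizontal coverage ≥ `fb` (default
80%) and vertical coverage ≥ `fd` (5×); per mOTU, ≥ `fm` retained samples
(2); per position, depth ≥ `fc` (5 reads) in ≥ `fp` (0.9) of retained
samples. A retained position is reported as a SNV when at least one retained
sample shows ≥ 2 alternative reads (`min_alt`, configurable — pileup-level
thresholds are not part of the published filter set). At multi-allelic
positions only the most frequent alternative allele across samples is kept.
Distances per mOTU over pairwise-complete positions: Manhattan (sum of
absolute frequency differences) and major-allele (fraction of shared
positions differing by more than 50% — normalized by shared positions so
values are comparable across sample pairs with different coverage).

## Evaluation metrics

Precision/recall are computed on presence sets (abundance above a
threshold, default 0), with precision 1 by convention when nothing is
predicted. MAE is averaged over the union of taxa present in either vector;
optional re-normalization re-scales both vectors to sum 1 over detected
taxa, the convention of profiling evaluation frameworks whose exchange
format cannot represent an unknown fraction — it penalizes profilers that
report one. Shannon diversity uses natural logarithms over nonzero relative
abundances. The log-Euclidean profile distance adds a pseudocount of half
the smallest nonzero value. MAG quality is `completeness − 5·contamination`
with QS > 50 kept; MAG-to-mOTU assignment requires ≥ 3 marker-gene hits to
binned MGCs and a strict majority (> 50%, so a 3–3 split is inconsistent).

## The synthetic-data generator

The generator is first-class, tested code and defines the study conditions
for everything above. Defaults: 20 species — 10 "known" (ref-mOTUs) and 10
"unknown", of which 6 are represented as meta-mOTUs and 4 only as unbinned
MGCs; marker genes of 750 nt with 50 nt genomic padding, embedded between
150 nt random spacers (genomes ≈ 9.2 kb); species marker genes diverge 13%
per site from a shared ancestor (pairwise identity ≈ 0.76, safely below the
90% planted-separation bound) and MGC members 0.4% (≥ 99% identity);
paired 150 nt reads with 350 ± 30 nt inserts, 50,000 inserts per sample,
substitution-only errors (no indels, keeping edit-distance arithmetic
exact); log-normal community abundances (meanlog 0, sdlog 1). Co-abundance
matrices give every species a log-normal trajectory across samples shared by
its ten MGC rows plus i.i.d. log-scale noise (σ = 0.1 over 30 samples in the
planted-recovery setting). Strain mixtures place 80 variant positions on a
second haplotype and mix the two haplotypes per sample; expected
whole-genome Manhattan distances (`n_variants · |p_i − p_j|`) are the ground
truth for the marker-gene concordance check. An option assigns the largest
abundance draws to chosen species, used to study communities whose unbinned
fraction dominates.

What the simulator does *not* emulate: indels and structural variation,
quality-score–dependent errors, chimeric inserts, conserved-region
cross-species mis-mapping, uneven genome sizes, and real phylogenetic
sequence structure. Passing tests therefore demonstrate correctness of the
algorithms under clean planted structure, not field performance on real
metagenomes.

## Numerical choices and problem sizes

Ties are broken lexicographically throughout (agglomeration pairs, centroid
choice, plurality names, LCA candidates) so all results are deterministic;
integer rounding is half-away-from-zero; scaled-count conservation is exact
to floating-point (asserted at 1e-6). The test and acceptance workloads use
desk-scale sizes chosen to exercise every code path with comfortable
statistical margins: 10 samples × 50,000 inserts for recovery, 30 samples
for binning, 10 strain mixtures × 1,200 inserts for SNV concordance,
hundreds of randomized instances for each brute-force oracle comparison.

## Known limitations

The profiler consumes SAM produced by an external aligner and trusts its
scores; redistribution is single-pass rather than iterative; the SNV caller
handles substitutions only; CAMI-format output carries lineage strings
rather than numeric taxon ids; and the binning cross-validation scores
held-out pairs by association value rather than re-running the full greedy
binning inside every fold.
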