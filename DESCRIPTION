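Package: motulite
Title: Marker-Gene OTU Profiling, Binning and SNV Analysis for Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Species-level taxonomic profiling of shotgun metagenomes from ten
    universal single-copy phylogenetic marker genes (MGs). Implements the full
    marker-gene OTU (mOTU) stack at desk scale: filtering of read alignments
    against a marker-gene database, redistribution of multi-mapped inserts,
    marker-gene-cluster (MGC) and mOTU abundance profiles in three units,
    average-linkage and open-reference clustering of marker genes into MGCs,
    co-abundance binning of MGCs into species-level mOTUs with FDR-calibrated
    association scores, weighted lowest-common-ancestor taxonomy, single
    nucleotide variant (SNV) profiling with Manhattan and major-allele
    distances, profiler evaluation metrics (precision/recall, mean absolute
    error, Shannon diversity), and a synthetic-data generator that produces
    databases, alignments, co-abundance matrices and strain mixtures with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    data.table,
    vegan,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
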