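#' Simulation configuration
#'
#' Desk-scale defaults for the synthetic-data generator: 20 species of which
#' 10 are "known" (reference mOTUs) and 10 "unknown" (no reference genome);
#' of the unknowns, `n_meta` are represented as metagenomic mOTUs and the
#' remainder only as unbinned MGCs. Marker genes are 750 nt with 50 nt of
#' genomic padding on each side; reads are 150 nt paired with a 350 +/- 30 nt
#' insert size. Sequencing errors are uniform substitutions (no indels), so
#' edit-distance arithmetic stays exact.
#'
#' @param n_species Total species.
#' @param n_known Species with reference representation (ref-mOTUs).
#' @param n_meta Unknown species binned as meta-mOTUs; the remaining
#'   `n_species - n_known - n_meta` unknown species exist in the database
#'   only as unbinned MGCs (mOTU id `"-1"`).
#' @param mg_length Coding length (nt) of every marker gene.
#' @param pad Non-coding padding retained on each side of a gene.
#' @param spacer Intergenic spacer length in the synthetic genomes.
#' @param intersp_div Per-site divergence of each species from the ancestral
#'   marker gene (keeps inter-species identity well below 90%).
#' @param intrasp_div Per-site divergence between members of one MGC (keeps
#'   intra-species identity above 99%).
#' @param members_per_mgc Marker gene sequences per MGC (extra members are
#'   mutated copies; only the first is embedded in the genome).
#' @param read_length,insert_mean,insert_sd Read/insert geometry (nt).
#' @param error_rate Per-base substitution error rate.
#' @param abund_meanlog,abund_sdlog Log-normal community abundance
#'   parameters.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_species = 20L, n_known = 10L, n_meta = 6L,
                       mg_length = 750L, pad = 50L, spacer = 150L,
                       intersp_div = 0.13, intrasp_div = 0.004,
                       members_per_mgc = 1L,
                       read_length = 150L, insert_mean = 350,
                       insert_sd = 30, error_rate = 0,
                       abund_meanlog = 0, abund_sdlog = 1) {
  stopifnot(n_species >= 1, n_known + n_meta <= n_species,
            error_rate >= 0, error_rate <= 1, pad <= 100)
  structure(as.list(environment()), class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

random_dna <- function(n) sample(BASES, n, replace = TRUE)

# substitute a `div` fraction of positions with a different base
mutate_seq <- function(chars, div) {
  if (div <= 0) return(chars)
  n <- length(chars)
  k <- rbinom(1, n, div)
  if (k == 0) return(chars)
  idx <- sample.int(n, k)
  # uniform over the three other bases, vectorized
  shift <- sample.int(3L, k, replace = TRUE)
  chars[idx] <- BASES[(match(chars[idx], BASES) - 1L + shift) %% 4L + 1L]
  chars
}

#' Simulate a marker-gene profiling database with known ground truth
#'
#' Builds `n_species` synthetic genomes, each carrying one marker gene per
#' COG family embedded between random spacers, and the matching `motu_db`:
#' known species become ref-mOTUs, `n_meta` unknown species meta-mOTUs, and
#' the remaining unknown species contribute only unbinned MGCs. Species
#' marker genes diverge `intersp_div` from a shared ancestor per COG;
#' additional MGC members (when `members_per_mgc > 1`) diverge
#' `intrasp_div` from the species gene. Deterministic given `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List of class `sim_db`: `db` (`motu_db`), `genomes` (named list
#'   of character vectors), `loci` (data.frame: species, cog, mg_id, coding
#'   and padded genome spans, 0-based half-open), `species` (data.frame:
#'   species_id, role `ref`/`meta`/`unbinned`, motu_id).
#' @export
simulate_database <- function(config = sim_config(), seed = 1L) {
  set.seed(seed)
  cf <- config
  n_unb <- cf$n_species - cf$n_known - cf$n_meta
  roles <- c(rep("ref", cf$n_known), rep("meta", cf$n_meta),
             rep("unbinned", n_unb))
  sp_ids <- sprintf("sp%02d", seq_len(cf$n_species))
  motu_ids <- ifelse(roles == "ref",
                     sprintf("ref_motu_%02d", seq_len(cf$n_species)),
              ifelse(roles == "meta",
                     sprintf("meta_motu_%02d", seq_len(cf$n_species)),
                     UNBINNED))
  ancestors <- lapply(MG_COGS, function(cg) random_dna(cf$mg_length))
  names(ancestors) <- MG_COGS

  genomes <- list()
  loci <- list()
  genes <- list()
  seqs <- character(0)
  for (k in seq_len(cf$n_species)) {
    sp <- sp_ids[k]
    lineage <- paste("Bacteria", sprintf("Phylum%02d", (k - 1) %/% 5 + 1),
                     sprintf("Class%02d", (k - 1) %/% 5 + 1),
                     sprintf("Order%02d", (k - 1) %/% 2 + 1),
                     sprintf("Family%02d", (k - 1) %/% 2 + 1),
                     sprintf("Genus%02d", k), sp, sep = ";")
    parts <- list(random_dna(cf$spacer))
    cursor <- cf$spacer
    for (cg in MG_COGS) {
      gene <- mutate_seq(ancestors[[cg]], cf$intersp_div)
      parts <- c(parts, list(gene, random_dna(cf$spacer)))
      gs <- cursor; ge <- cursor + cf$mg_length
      cursor <- ge + cf$spacer
      mg_id <- paste(sp, cg, "m1", sep = ".")
      mgc_id <- paste0("mgc_", sp, "_", cg)
      loci[[length(loci) + 1L]] <- data.frame(
        species = sp, cog = cg, mg_id = mg_id,
        coding_start = gs, coding_end = ge,
        pad_start = gs - cf$pad, pad_end = ge + cf$pad,
        stringsAsFactors = FALSE)
      genes[[length(genes) + 1L]] <- data.frame(
        mg_id = mg_id, cog = cg,
        source = if (roles[k] == "ref") "reference" else "metagenome",
        mgc_id = mgc_id, motu_id = motu_ids[k],
        coding_start = cf$pad, coding_end = cf$pad + cf$mg_length,
        taxonomy = lineage, stringsAsFactors = FALSE)
    }
    genome <- unlist(parts)
    genomes[[sp]] <- genome
    for (li in loci[vapply(loci, function(x) x$species == sp, logical(1))]) {
      padded <- genome[(li$pad_start + 1):li$pad_end]
      seqs[li$mg_id] <- paste(padded, collapse = "")
      if (cf$members_per_mgc > 1) {
        for (mi in 2:cf$members_per_mgc) {
          ex_id <- paste(sp, li$cog, paste0("m", mi), sep = ".")
          seqs[ex_id] <- paste(mutate_seq(padded, cf$intrasp_div),
                               collapse = "")
          g1 <- genes[[which(vapply(genes, function(g) {
            g$mg_id == li$mg_id
          }, logical(1)))]]
          g1$mg_id <- ex_id
          genes[[length(genes) + 1L]] <- g1
        }
      }
    }
  }
  loci <- do.call(rbind, loci)
  genes <- do.call(rbind, genes)
  structure(list(db = build_database(genes, seqs), genomes = genomes,
                 loci = loci,
                 species = data.frame(species_id = sp_ids, role = roles,
                                      motu_id = motu_ids,
                                      stringsAsFactors = FALSE),
                 config = cf, seed = seed),
            class = "sim_db")
}

#' Simulate community relative abundances
#'
#' Log-normal species abundances normalized to sum to 1. When
#' `high_abundance_species` is given, the largest draws are assigned to
#' those species (e.g. to study communities where species lacking mOTU
#' membership dominate).
#'
#' @param sim A `sim_db`.
#' @param seed Integer seed.
#' @param high_abundance_species Optional character vector of species ids to
#'   receive the largest abundance draws.
#' @return Named numeric vector (species id -> fraction, sums to 1).
#' @export
simulate_abundances <- function(sim, seed = 1L,
                                high_abundance_species = NULL) {
  set.seed(seed)
  cf <- sim$config
  sp <- sim$species$species_id
  x <- rlnorm(length(sp), cf$abund_meanlog, cf$abund_sdlog)
  if (!is.null(high_abundance_species)) {
    stopifnot(all(high_abundance_species %in% sp))
    ord <- order(-x)
    ranked <- x[ord]
    out <- numeric(length(sp))
    hi <- match(high_abundance_species, sp)
    out[hi] <- ranked[seq_along(hi)]
    out[-hi] <- ranked[-seq_along(hi)]
    x <- out
  }
  stats::setNames(x / sum(x), sp)
}

#' Ground-truth mOTU-level profile for simulated abundances
#'
#' Maps species abundances to the profiling taxa: each binned species to its
#' mOTU id and the mass of unbinned species pooled into the `"-1"` row.
#'
#' @param sim A `sim_db`.
#' @param abundances Named species abundance vector ([simulate_abundances()]).
#' @return Named numeric vector over mOTU ids plus `"-1"`.
#' @export
truth_profile <- function(sim, abundances) {
  motu <- sim$species$motu_id[match(names(abundances),
                                    sim$species$species_id)]
  out <- tapply(abundances, motu, sum)
  stats::setNames(as.numeric(out), names(out))
}

# Generate paired-read alignments of `n` inserts from one genome against its
# padded marker-gene loci; returns a data.frame of SAM fields (no header).
# `ref_seqs`: named character vector of padded reference sequences used for
# mismatch (NM) counting — not necessarily from the same haplotype as
# `genome`.
reads_from_genome <- function(genome, loci, n, cf, ref_seqs,
                              insert_prefix = "ins", exact = TRUE) {
  if (n == 0) return(NULL)
  L <- length(genome)
  ilen <- pmin(pmax(round(rnorm(n, cf$insert_mean, cf$insert_sd)),
                    cf$read_length), L)
  start <- floor(runif(n) * (L - ilen + 1))  # 0-based
  rl <- cf$read_length
  ends <- start + ilen
  reads <- rbind(
    data.frame(ins = seq_len(n), mate = 1L, a = start,
               b = pmin(start + rl, ends)),
    data.frame(ins = seq_len(n), mate = 2L, a = pmax(ends - rl, start),
               b = ends))
  out <- list()
  gstr <- paste(genome, collapse = "")
  for (i in seq_len(nrow(loci))) {
    li <- loci[i, ]
    ov_a <- pmax(reads$a, li$pad_start)
    ov_b <- pmin(reads$b, li$pad_end)
    hit <- which(ov_b - ov_a >= 1L)
    if (length(hit) == 0) next
    r <- reads[hit, ]
    oa <- ov_a[hit]; ob <- ov_b[hit]
    alen <- ob - oa
    lclip <- oa - r$a
    rclip <- r$b - ob
    cigar <- paste0(ifelse(lclip > 0, paste0(lclip, "S"), ""),
                    alen, "M",
                    ifelse(rclip > 0, paste0(rclip, "S"), ""))
    seq <- substring(gstr, r$a + 1, r$b)
    if (exact) {
      nm <- rep(0L, length(hit))
    } else {
      ref_aln <- substring(ref_seqs[li$mg_id], oa - li$pad_start + 1,
                           ob - li$pad_start)
      qry_aln <- substring(gstr, oa + 1, ob)
      nm <- mapply(function(a, b) {
        sum(utf8ToInt(a) != utf8ToInt(b))
      }, ref_aln, qry_aln, USE.NAMES = FALSE)
    }
    out[[length(out) + 1L]] <- data.frame(
      qname = paste0(insert_prefix, "_", r$ins),
      flag = ifelse(r$mate == 1L, 99L, 147L),
      rname = li$mg_id, pos = oa - li$pad_start + 1L,
      cigar = cigar, seq = seq, nm = nm, alen = alen,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) NULL else do.call(rbind, out)
}

# Apply uniform substitution errors to SAM-record sequences, updating NM for
# errors inside the aligned (M) span. Assumes the simulator's xS yM zS cigars.
apply_errors <- function(recs, error_rate) {
  if (is.null(recs) || error_rate <= 0) return(recs)
  for (i in seq_len(nrow(recs))) {
    chars <- strsplit(recs$seq[i], "")[[1]]
    k <- rbinom(1, length(chars), error_rate)
    if (k == 0) next
    idx <- sample.int(length(chars), k)
    chars[idx] <- vapply(chars[idx], function(b) {
      sample(setdiff(BASES, b), 1)
    }, character(1))
    recs$seq[i] <- paste(chars, collapse = "")
    lclip <- ifelse(grepl("^\\d+S", recs$cigar[i]),
                    as.integer(sub("S.*", "", recs$cigar[i])), 0L)
    in_aln <- idx > lclip & idx <= lclip + recs$alen[i]
    recs$nm[i] <- recs$nm[i] + sum(in_aln)
  }
  recs
}

# Write simulator alignment records as a headered SAM file.
write_sam <- function(recs, db, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", names(db$seqs), "\tLN:",
                  Biostrings::width(db$seqs)))
  body <- character(0)
  if (!is.null(recs) && nrow(recs) > 0) {
    score <- recs$alen - 2L * recs$nm
    body <- paste(recs$qname, recs$flag, recs$rname, recs$pos, 60L,
                  recs$cigar, "*", 0L, 0L, recs$seq, "*",
                  paste0("NM:i:", recs$nm), paste0("AS:i:", score),
                  sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Simulate one metagenomic sample as SAM alignments
#'
#' Draws paired-end inserts from the species genomes proportionally to the
#' given abundances; reads overlapping a padded marker-gene locus yield SAM
#' records against that species' marker gene with exact CIGAR/NM/AS fields.
#' Reads falling entirely between loci are not emitted (they would not map
#' to the marker-gene database).
#'
#' @param sim A `sim_db`.
#' @param abundances Named species abundance vector.
#' @param n_inserts Number of inserts to draw (default 50000).
#' @param seed Integer seed.
#' @param path Output SAM path (default a tempfile).
#' @return List with `sam` (path), `truth` (mOTU-level truth profile) and
#'   `n_inserts`.
#' @export
simulate_sample <- function(sim, abundances, n_inserts = 50000L, seed = 1L,
                            path = tempfile(fileext = ".sam")) {
  set.seed(seed)
  cf <- sim$config
  if (n_inserts == 0) {
    write_sam(NULL, sim$db, path)
    return(list(sam = path, truth = truth_profile(sim, abundances),
                n_inserts = 0L))
  }
  counts <- table(factor(sample(names(abundances), n_inserts,
                                replace = TRUE, prob = abundances),
                         levels = names(abundances)))
  ref_seqs <- stats::setNames(as.character(sim$db$seqs),
                              names(sim$db$seqs))
  recs <- list()
  for (sp in names(counts)) {
    n <- counts[[sp]]
    if (n == 0) next
    r <- reads_from_genome(sim$genomes[[sp]],
                           sim$loci[sim$loci$species == sp, ], n, cf,
                           ref_seqs, insert_prefix = sp,
                           exact = cf$error_rate == 0)
    r <- apply_errors(r, cf$error_rate)
    recs[[sp]] <- r
  }
  recs <- do.call(rbind, recs)
  write_sam(recs, sim$db, path)
  list(sam = path, truth = truth_profile(sim, abundances),
       n_inserts = n_inserts)
}

#' Simulate a cross-sample MGC co-abundance matrix
#'
#' Every species follows its own log-normal abundance trajectory across
#' samples; each of its MGC rows is that trajectory plus i.i.d. Gaussian
#' noise on the log scale. This is the planted structure the co-abundance
#' binner is expected to recover.
#'
#' @param sim A `sim_db`.
#' @param n_samples Number of samples (default 30).
#' @param noise_sd Log-scale noise standard deviation (default 0.1).
#' @param seed Integer seed.
#' @param biome Biome label for all samples (default `"gut"`).
#' @return List with `matrix` (MGC x sample), `biome_of_sample`,
#'   `mgc_species` (named: MGC -> species), `seed_groups` (species cluster
#'   groupings of the reference MGCs).
#' @export
simulate_coabundance <- function(sim, n_samples = 30L, noise_sd = 0.1,
                                 seed = 1L, biome = "gut") {
  set.seed(seed)
  cf <- sim$config
  sp <- sim$species$species_id
  traj <- matrix(rnorm(length(sp) * n_samples, cf$abund_meanlog,
                       cf$abund_sdlog),
                 nrow = length(sp),
                 dimnames = list(sp, sprintf("s%02d", seq_len(n_samples))))
  mgcs <- sim$db$mgcs$mgc_id
  mgc_sp <- sub("^mgc_(sp[0-9]+)_.*$", "\\1", mgcs)
  m <- exp(traj[mgc_sp, , drop = FALSE] +
             matrix(rnorm(length(mgcs) * n_samples, 0, noise_sd),
                    nrow = length(mgcs)))
  rownames(m) <- mgcs
  ref_sp <- sim$species$species_id[sim$species$role == "ref"]
  seed_groups <- lapply(ref_sp, function(s) sort(mgcs[mgc_sp == s]))
  names(seed_groups) <- ref_sp
  list(matrix = m,
       biome_of_sample = stats::setNames(rep(biome, n_samples),
                                         colnames(m)),
       mgc_species = stats::setNames(mgc_sp, mgcs),
       seed_groups = seed_groups)
}

#' Simulate protein reference hits for taxonomic annotation
#'
#' For each marker gene, emits a hit table resembling a translated homology
#' search against a protein reference: near-best hits from the true species
#' and its genus, plus lower-scoring outliers from other lineages.
#'
#' @param sim A `sim_db`.
#' @param seed Integer seed.
#' @return data.frame with columns `query_mg`, `lineage`, `bitscore`.
#' @export
simulate_protein_hits <- function(sim, seed = 1L) {
  set.seed(seed)
  g <- sim$db$genes
  out <- list()
  for (i in seq_len(nrow(g))) {
    lin <- lineage_parse(g$taxonomy[i])
    top <- runif(1, 150, 250)
    hits <- data.frame(
      query_mg = g$mg_id[i],
      lineage = c(lineage_format(lin),
                  lineage_format(replace(lin, 7, paste0(lin[7], "_rel"))),
                  "Bacteria;PhylumXX;ClassXX;OrderXX;FamilyXX;GenusXX;spXX"),
      bitscore = c(top, top * runif(1, 0.92, 0.99),
                   top * runif(1, 0.3, 0.6)),
      stringsAsFactors = FALSE)
    out[[i]] <- hits
  }
  do.call(rbind, out)
}

#' Simulate strain mixtures for SNV benchmarking
#'
#' One species, two haplotypes: haplotype B differs from the reference
#' haplotype A at `n_variants` random genome positions. Each sample mixes
#' the haplotypes at a given proportion; reads are drawn as in
#' [simulate_sample()] and aligned against the species' (haplotype A)
#' marker genes. The expected whole-genome Manhattan distance between two
#' samples is `n_variants * |p_i - p_j|`, returned as the ground truth
#' against which marker-gene-restricted SNV distances can be compared.
#'
#' @param sim A `sim_db`.
#' @param species Species id (default: first species).
#' @param proportions Haplotype-B fraction per sample (default
#'   `seq(0, 1, length.out = 10)`).
#' @param n_variants Number of haplotype-differentiating positions
#'   (default 80).
#' @param n_inserts Inserts per sample (default 1200).
#' @param seed Integer seed.
#' @param dir Output directory for the per-sample SAM files.
#' @return List with `sams` (named paths), `proportions`,
#'   `variant_positions` (0-based genome positions), `wg_manhattan`
#'   (expected whole-genome distance matrix), `species`.
#' @export
simulate_strains <- function(sim, species = sim$species$species_id[1],
                             proportions = seq(0, 1, length.out = 10),
                             n_variants = 80L, n_inserts = 1200L,
                             seed = 1L, dir = tempfile("strains")) {
  set.seed(seed)
  cf <- sim$config
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genomeA <- sim$genomes[[species]]
  var_pos <- sort(sample.int(length(genomeA), n_variants))  # 1-based
  genomeB <- genomeA
  genomeB[var_pos] <- vapply(genomeA[var_pos], function(b) {
    sample(setdiff(BASES, b), 1)
  }, character(1))
  loci <- sim$loci[sim$loci$species == species, ]
  ref_seqs <- stats::setNames(as.character(sim$db$seqs),
                              names(sim$db$seqs))
  samples <- sprintf("mix%02d", seq_along(proportions))
  sams <- stats::setNames(file.path(dir, paste0(samples, ".sam")), samples)
  for (i in seq_along(proportions)) {
    nB <- rbinom(1, n_inserts, proportions[i])
    recs <- rbind(
      reads_from_genome(genomeA, loci, n_inserts - nB, cf, ref_seqs,
                        insert_prefix = paste0(samples[i], "A"),
                        exact = TRUE),
      reads_from_genome(genomeB, loci, nB, cf, ref_seqs,
                        insert_prefix = paste0(samples[i], "B"),
                        exact = FALSE))
    write_sam(recs, sim$db, sams[i])
  }
  n <- length(proportions)
  wg <- outer(proportions, proportions,
              function(a, b) n_variants * abs(a - b))
  dimnames(wg) <- list(samples, samples)
  list(sams = sams, proportions = stats::setNames(proportions, samples),
       variant_positions = var_pos - 1L, wg_manhattan = wg,
       species = species)
}
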