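#' Parameter presets for the profiler
#'
#' Named presets trading precision against recall: each sets the minimum
#' alignment length `-l` and the minimum number of detected MGCs per mOTU
#' `-g`.
#'
#' @format Named list of lists with elements `min_length` and `min_mgcs`.
#' @export
PROFILER_PRESETS <- list(
  high_precision = list(min_length = 140L, min_mgcs = 6L),
  default        = list(min_length = 100L, min_mgcs = 3L),
  recall         = list(min_length = 75L,  min_mgcs = 3L),
  high_recall    = list(min_length = 50L,  min_mgcs = 2L),
  max_recall     = list(min_length = 30L,  min_mgcs = 1L)
)

# round half away from zero (platform-stable integer rounding for counts)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# mismatch + indel count from an MD string plus CIGAR insertions
nm_from_md <- function(md, cigar_ins) {
  toks <- regmatches(md, gregexpr("\\^[A-Z]+|[A-Z]|[0-9]+", md))[[1]]
  mism <- sum(toks %in% c("A", "C", "G", "T", "N"))
  dels <- sum(nchar(sub("^\\^", "", toks[startsWith(toks, "^")])))
  mism + dels + cigar_ins
}

#' Parse a SAM file and filter alignments by identity and length
#'
#' Reads per-sample alignments of metagenomic reads against the marker gene
#' database, computes the aligned length of each record from its CIGAR
#' (M/=/X columns) and the nucleotide identity as
#' `(aligned_length - edit_distance) / aligned_length`, and retains records
#' with `identity >= min_identity` and `aligned_length >= min_length`.
#' The edit distance is taken from the NM tag; if NM is absent it is
#' reconstructed from the MD string plus CIGAR insertions; records carrying
#' neither are a hard error. The per-mate alignment score is the AS tag when
#' present, else `aligned_length - 2 * NM`.
#'
#' @param sam_path Path to a headered SAM (or BAM) file. Paired mates share
#'   their QNAME.
#' @param min_identity Minimum nucleotide identity (default 0.97).
#' @param min_length Minimum alignment length in bp (default 75; `-l`).
#' @return data.frame of alignment records: `insert_id`, `mate` (1, 2 or 0
#'   for single-end), `target_mg`, `pos` (1-based leftmost on target),
#'   `cigar`, `seq`, `aligned_length`, `aligned_bases`, `ref_start`,
#'   `ref_end` (0-based half-open span on target), `nm`, `identity`, `score`.
#' @export
parse_and_filter <- function(sam_path, min_identity = 0.97,
                             min_length = 75L) {
  bam <- if (grepl("\\.bam$", sam_path, ignore.case = TRUE)) {
    sam_path
  } else {
    dest <- tempfile(fileext = "")
    Rsamtools::asBam(sam_path, dest, overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    tag = c("NM", "AS", "MD"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(x$qname)
  empty <- data.frame(
    insert_id = character(0), mate = integer(0), target_mg = character(0),
    pos = integer(0), cigar = character(0), seq = character(0),
    aligned_length = integer(0), aligned_bases = integer(0),
    ref_start = integer(0), ref_end = integer(0), nm = integer(0),
    identity = numeric(0), score = numeric(0), stringsAsFactors = FALSE)
  if (n == 0) return(empty)

  # aligned length over M/=/X columns: query width inside soft clips minus
  # inserted bases
  qw <- GenomicAlignments::cigarWidthAlongQuerySpace(
    x$cigar, after.soft.clipping = TRUE)
  ins <- integer(n)
  has_i <- grepl("I", x$cigar, fixed = TRUE)
  if (any(has_i)) {
    ins[has_i] <- vapply(
      GenomicAlignments::explodeCigarOpLengths(x$cigar[has_i], ops = "I"),
      sum, integer(1))
  }
  aligned_len <- qw - ins
  ref_width <- GenomicAlignments::cigarWidthAlongReferenceSpace(x$cigar)

  nm <- x$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, n)
  md <- x$tag$MD
  if (is.null(md)) md <- rep(NA_character_, n)
  need_md <- is.na(nm)
  if (any(need_md & is.na(md))) {
    bad <- x$qname[need_md & is.na(md)][1]
    stop("alignment record lacks both NM and MD tags: read ", bad)
  }
  if (any(need_md)) {
    nm[need_md] <- mapply(nm_from_md, md[need_md], ins[need_md])
  }
  as_tag <- x$tag$AS
  if (is.null(as_tag)) as_tag <- rep(NA_integer_, n)
  score <- ifelse(is.na(as_tag), aligned_len - 2 * nm, as_tag)

  mate <- integer(n)
  paired <- bitwAnd(x$flag, 1L) > 0L
  mate[paired & bitwAnd(x$flag, 64L) > 0L] <- 1L
  mate[paired & bitwAnd(x$flag, 128L) > 0L] <- 2L

  identity <- (aligned_len - nm) / aligned_len
  rec <- data.frame(
    insert_id = x$qname, mate = mate, target_mg = as.character(x$rname),
    pos = x$pos, cigar = x$cigar, seq = as.character(x$seq),
    aligned_length = as.integer(aligned_len),
    aligned_bases = as.integer(aligned_len),
    ref_start = x$pos - 1L, ref_end = x$pos - 1L + ref_width,
    nm = as.integer(nm), identity = identity, score = as.numeric(score),
    stringsAsFactors = FALSE)
  keep <- rec$aligned_length >= min_length & rec$identity >= min_identity
  rec <- rec[keep, , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Determine the best-scoring MGC(s) for every insert
#'
#' Alignment scores are aggregated at the MGC level: for each insert and MGC
#' the best per-mate score to any member of that MGC is summed over mates
#' (mates hitting different members of one MGC count as one target). The
#' insert's score is the maximum over MGCs; inserts whose maximum is attained
#' by a single MGC are flagged `unique`, otherwise `multiple`.
#'
#' @param records Alignment records from [parse_and_filter()].
#' @param db A `motu_db` object.
#' @return data.frame of class `insert_assignments` with one row per
#'   (insert, best-scoring MGC): `insert_id`, `mgc_id`, `insert_score`,
#'   `n_best`, `flag` (`"unique"`/`"multiple"`).
#' @export
assign_inserts <- function(records, db) {
  empty <- structure(
    data.frame(insert_id = character(0), mgc_id = character(0),
               insert_score = numeric(0), n_best = integer(0),
               flag = character(0), stringsAsFactors = FALSE),
    class = c("insert_assignments", "data.frame"))
  if (nrow(records) == 0) return(empty)
  dt <- data.table::as.data.table(records[, c("insert_id", "mate",
                                              "target_mg", "score")])
  dt[, mgc_id := mg_to_mgc(db, target_mg)]
  # best score per (insert, mgc, mate), then summed over mates per MGC
  per_mate <- dt[, .(s = max(score)), by = .(insert_id, mgc_id, mate)]
  per_mgc <- per_mate[, .(mgc_score = sum(s)), by = .(insert_id, mgc_id)]
  per_mgc[, best := max(mgc_score), by = insert_id]
  best <- per_mgc[mgc_score == best]
  best[, n_best := .N, by = insert_id]
  best[, flag := ifelse(n_best == 1L, "unique", "multiple")]
  out <- as.data.frame(best[, .(insert_id, mgc_id, insert_score = mgc_score,
                                n_best, flag)])
  out <- out[order(out$insert_id, out$mgc_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("insert_assignments", "data.frame")
  out
}

# Fractional weight of every assignment row: 1 for unique inserts; for
# multiple-flagged inserts the insert is distributed among its best-scoring
# MGCs proportionally to the unique-alignment profile (uniformly if all its
# targets have zero unique counts).
redistribution_weights <- function(assignments) {
  a <- as.data.frame(assignments)
  if (nrow(a) == 0) return(numeric(0))
  uniq <- table(a$mgc_id[a$flag == "unique"])
  u <- as.numeric(uniq[a$mgc_id])
  u[is.na(u)] <- 0
  w <- rep(1, nrow(a))
  mult <- a$flag == "multiple"
  if (any(mult)) {
    us <- stats::ave(u, a$insert_id, FUN = sum)
    w[mult] <- ifelse(us[mult] > 0, u[mult] / us[mult], 1 / a$n_best[mult])
  }
  w
}

#' MGC insert counts with multi-mapper redistribution
#'
#' Counts of inserts per MGC: the unique-alignment profile plus the
#' fractional contributions of multiple-flagged inserts, each distributed
#' among its best-scoring MGCs in proportion to the unique profile (uniform
#' split when none of its targets has unique support). The counts sum exactly
#' to the number of assigned inserts.
#'
#' @param assignments From [assign_inserts()].
#' @return Named numeric vector, MGC id -> count.
#' @export
mgc_insert_counts <- function(assignments) {
  a <- as.data.frame(assignments)
  if (nrow(a) == 0) return(stats::setNames(numeric(0), character(0)))
  w <- redistribution_weights(assignments)
  counts <- tapply(w, a$mgc_id, sum)
  stats::setNames(as.numeric(counts), names(counts))
}

#' MGC base coverages
#'
#' Mean per-base coverage of each MGC: total aligned bases divided by the
#' coding length of the MGC's centroid sequence. Only alignments to an
#' insert's best-scoring MGC(s) contribute; within an MGC the single
#' highest-scoring member alignment per mate is counted, and multiple-flagged
#' inserts contribute with the same fractional weights as in
#' [mgc_insert_counts()].
#'
#' @param records From [parse_and_filter()].
#' @param assignments From [assign_inserts()].
#' @param db A `motu_db` object.
#' @return Named numeric vector, MGC id -> coverage.
#' @export
mgc_base_coverage <- function(records, assignments, db) {
  a <- as.data.frame(assignments)
  if (nrow(a) == 0) return(stats::setNames(numeric(0), character(0)))
  a$w <- redistribution_weights(assignments)
  dt <- data.table::as.data.table(
    records[, c("insert_id", "mate", "target_mg", "score", "aligned_bases")])
  dt[, mgc_id := mg_to_mgc(db, target_mg)]
  # keep the single best member alignment per (insert, mgc, mate);
  # deterministic tie-break by member id then position order
  data.table::setorder(dt, insert_id, mgc_id, mate, -score, target_mg)
  best <- unique(dt, by = c("insert_id", "mgc_id", "mate"))
  bases <- best[, .(bases = sum(aligned_bases)), by = .(insert_id, mgc_id)]
  m <- merge(data.table::as.data.table(a), bases,
             by = c("insert_id", "mgc_id"), all.x = TRUE)
  m[is.na(bases), bases := 0]
  cov <- m[, .(bases = sum(w * bases)), by = mgc_id]
  len <- coding_length(db, db$mgcs$centroid[match(cov$mgc_id,
                                                  db$mgcs$mgc_id)])
  stats::setNames(cov$bases / len, cov$mgc_id)
}

#' Aggregate MGC abundances into a mOTU profile
#'
#' A mOTU's abundance is the median of its detected (nonzero) MGC abundances,
#' provided at least `min_mgcs` of them are detected (`-g`); otherwise 0. The
#' unbinned group `"-1"` is the median of the ten per-COG sums of
#' unbinned-MGC abundances. For the `insert.raw_counts` unit all values are
#' rounded to integers (half away from zero).
#'
#' @param mgc_values Named numeric vector of per-MGC abundances (MGCs absent
#'   from the vector count as 0).
#' @param db A `motu_db` object.
#' @param min_mgcs Minimum number of detected MGCs per mOTU (default 3).
#' @param unit One of `"base.coverage"`, `"insert.raw_counts"`,
#'   `"insert.scaled_counts"`.
#' @param total_aligned_inserts Number of inserts aligned to MGCs (stored in
#'   the profile; required for scaling).
#' @param detected_only If `TRUE` (default) the median is taken over detected
#'   MGC slots only; if `FALSE` over all of the mOTU's MGC slots.
#' @return Object of class `motu_profile`: list with `unit`, `mgc_values`
#'   (complete over the database's MGCs), `motu_values` (including `"-1"`),
#'   `total_aligned_inserts` and `params`.
#' @export
motu_profile <- function(mgc_values, db, min_mgcs = 3L,
                         unit = c("base.coverage", "insert.raw_counts",
                                  "insert.scaled_counts"),
                         total_aligned_inserts = NA_real_,
                         detected_only = TRUE) {
  unit <- match.arg(unit)
  full <- stats::setNames(rep(0, nrow(db$mgcs)), db$mgcs$mgc_id)
  known <- intersect(names(mgc_values), names(full))
  full[known] <- mgc_values[known]

  vals_of <- function(motu) full[db$mgcs$mgc_id[db$mgcs$motu_id == motu]]
  motu_val <- vapply(db$motus$motu_id, function(m) {
    v <- vals_of(m)
    det <- v > 0
    if (sum(det) < min_mgcs) return(0)
    if (detected_only) stats::median(v[det]) else stats::median(v)
  }, numeric(1))

  unb <- db$mgcs[db$mgcs$motu_id == UNBINNED, , drop = FALSE]
  cog_sums <- vapply(MG_COGS, function(cg) {
    sum(full[unb$mgc_id[unb$cog == cg]])
  }, numeric(1))
  motu_val <- c(motu_val, stats::setNames(stats::median(cog_sums), UNBINNED))

  if (unit == "insert.raw_counts") {
    full <- round_half_away(full)
    motu_val <- round_half_away(motu_val)
  }
  structure(list(unit = unit, mgc_values = full, motu_values = motu_val,
                 total_aligned_inserts = total_aligned_inserts,
                 params = list(min_mgcs = min_mgcs,
                               detected_only = detected_only)),
            class = "motu_profile")
}

#' Scale a coverage profile to insert counts
#'
#' Converts a `base.coverage` profile into `insert.scaled_counts`: coverages
#' are rescaled so that the mOTU values (including the unbinned `"-1"` row)
#' sum to the number of inserts aligned to MGCs. Scaled counts keep the
#' relative proportions of coverages while retaining count-like totals.
#'
#' @param profile A `motu_profile` with unit `base.coverage`.
#' @param total_aligned_inserts Total number of aligned inserts.
#' @return A `motu_profile` with unit `insert.scaled_counts`.
#' @export
scale_counts <- function(profile, total_aligned_inserts) {
  stopifnot(inherits(profile, "motu_profile"))
  if (profile$unit != "base.coverage") {
    stop("scale_counts expects a base.coverage profile, got ", profile$unit)
  }
  tot_m <- sum(profile$motu_values)
  tot_g <- sum(profile$mgc_values)
  if (total_aligned_inserts > 0 && tot_m == 0) {
    stop("cannot scale: zero total coverage with nonzero insert count")
  }
  sc_m <- if (tot_m > 0) total_aligned_inserts / tot_m else 0
  sc_g <- if (tot_g > 0) total_aligned_inserts / tot_g else 0
  structure(list(unit = "insert.scaled_counts",
                 mgc_values = profile$mgc_values * sc_g,
                 motu_values = profile$motu_values * sc_m,
                 total_aligned_inserts = total_aligned_inserts,
                 params = profile$params),
            class = "motu_profile")
}

#' Relative abundances of mOTUs
#'
#' @param profile A `motu_profile` (scaled or raw counts).
#' @param include_unbinned If `TRUE`, fractions are taken over all rows
#'   including the unbinned `"-1"` group; if `FALSE`, the `"-1"` row is
#'   dropped and the remaining mOTUs are re-normalized to sum to 1 (the
#'   "re-normalized on detected taxa" convention of reference-dependent
#'   evaluation frameworks, which cannot represent the unknown fraction).
#' @return Named numeric vector of fractions (all zero for an empty profile).
#' @export
relative_abundance <- function(profile, include_unbinned = TRUE) {
  stopifnot(inherits(profile, "motu_profile"))
  v <- profile$motu_values
  if (!include_unbinned) v <- v[names(v) != UNBINNED]
  tot <- sum(v)
  if (tot == 0) return(v)
  v / tot
}

#' Profile one sample end to end
#'
#' Runs the full taxonomic profiling workflow on one SAM file: alignment
#' filtering, best-MGC assignment of inserts, multi-mapper redistribution,
#' and mOTU profiles in all three units.
#'
#' @param sam_path Path to the sample's SAM/BAM alignments against `db`.
#' @param db A `motu_db` object.
#' @param min_identity Minimum nucleotide identity (default 0.97).
#' @param min_length Minimum alignment length (`-l`, default 75).
#' @param min_mgcs Minimum detected MGCs per mOTU (`-g`, default 3).
#' @param preset Optional name from [PROFILER_PRESETS]; overrides
#'   `min_length`/`min_mgcs`.
#' @return List with elements `base.coverage`, `insert.raw_counts`,
#'   `insert.scaled_counts` (each a `motu_profile`), plus `records` and
#'   `assignments`.
#' @export
profile_sample <- function(sam_path, db, min_identity = 0.97,
                           min_length = 75L, min_mgcs = 3L, preset = NULL) {
  if (!is.null(preset)) {
    stopifnot(preset %in% names(PROFILER_PRESETS))
    min_length <- PROFILER_PRESETS[[preset]]$min_length
    min_mgcs <- PROFILER_PRESETS[[preset]]$min_mgcs
  }
  rec <- parse_and_filter(sam_path, min_identity, min_length)
  asg <- assign_inserts(rec, db)
  total <- length(unique(asg$insert_id))
  counts <- mgc_insert_counts(asg)
  cov <- mgc_base_coverage(rec, asg, db)
  p_raw <- motu_profile(counts, db, min_mgcs, "insert.raw_counts", total)
  p_cov <- motu_profile(cov, db, min_mgcs, "base.coverage", total)
  p_sc <- scale_counts(p_cov, total)
  p_sc$params$min_mgcs <- min_mgcs
  list(base.coverage = p_cov, insert.raw_counts = p_raw,
       insert.scaled_counts = p_sc, records = rec, assignments = asg)
}

#' @export
print.motu_profile <- function(x, ...) {
  nz <- sum(x$motu_values > 0)
  cat(sprintf("motu_profile [%s]: %d/%d mOTU rows nonzero, total inserts %s\n",
              x$unit, nz, length(x$motu_values),
              format(x$total_aligned_inserts)))
  invisible(x)
}

#' Write a mOTU profile as TSV
#'
#' Columns `motu_id`, `taxonomy`, `value`, with a `#`-prefixed header. The
#' unbinned group is written as id `"-1"` with the taxonomy `unassigned`.
#'
#' @param profile A `motu_profile`.
#' @param db A `motu_db`.
#' @param path Output path.
#' @export
write_profile <- function(profile, db, path) {
  v <- profile$motu_values
  tax <- c(db$motus$taxonomy[match(setdiff(names(v), UNBINNED),
                                   db$motus$motu_id)], "unassigned")
  out <- data.frame(motu_id = names(v), taxonomy = tax, value = unname(v))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#motu_id\ttaxonomy\tvalue  (unit: ", profile$unit, ")"),
             con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(profile)
}

#' Write a profile in CAMI/Bioboxes profiling format
#'
#' Emits the rank-aggregated percentage profile (`@@TAXID RANK TAXPATH
#' TAXPATHSN PERCENTAGE`). The format has no slot for the unknown fraction,
#' so the unbinned `"-1"` row is dropped and abundances are re-normalized
#' over the detected taxa.
#'
#' @param profile A `motu_profile`.
#' @param db A `motu_db`.
#' @param path Output path.
#' @param sample_id Sample identifier written to the header.
#' @export
write_cami <- function(profile, db, path, sample_id = "sample") {
  rel <- relative_abundance(profile, include_unbinned = FALSE)
  rel <- rel[rel > 0]
  lin <- lapply(db$motus$taxonomy[match(names(rel), db$motus$motu_id)],
                lineage_parse)
  rows <- list()
  for (d in seq_along(TAX_RANKS)) {
    paths <- vapply(lin, function(l) {
      if (is.na(l[d])) NA_character_ else paste(l[1:d], collapse = "|")
    }, character(1))
    ok <- !is.na(paths)
    if (!any(ok)) next
    agg <- tapply(rel[ok], paths[ok], sum)
    rows[[d]] <- data.frame(taxid = sub(".*\\|", "", names(agg)),
                            rank = TAX_RANKS[d], taxpath = names(agg),
                            pct = as.numeric(agg) * 100)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("@SampleID:", sample_id), "@Version:0.9.1",
               paste0("@Ranks:", paste(TAX_RANKS, collapse = "|")),
               "@@TAXID\tRANK\tTAXPATH\tTAXPATHSN\tPERCENTAGE"), con)
  for (r in rows) {
    if (is.null(r)) next
    utils::write.table(
      data.frame(r$taxid, r$rank, r$taxpath, r$taxpath,
                 formatC(r$pct, format = "f", digits = 6)),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(profile)
}
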