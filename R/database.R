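#' The ten universal single-copy marker gene (MG) COG families
#'
#' Ten protein-coding, universally occurring, single-copy phylogenetic marker
#' genes suitable for metagenomic short-read profiling. Every marker gene in a
#' profiling database belongs to exactly one of these families.
#'
#' @format Character vector of 10 COG identifiers.
#' @export
MG_COGS <- c("COG0012", "COG0016", "COG0018", "COG0172", "COG0215",
             "COG0495", "COG0525", "COG0533", "COG0541", "COG0552")

#' Sentinel mOTU id for unbinned marker gene clusters
#' @export
UNBINNED <- "-1"

# Maximum padding allowed on either side of the coding region of a marker
# gene sequence (non-coding genomic context retained to reduce mapping
# artifacts at gene boundaries).
MAX_PAD <- 100L

#' Construct a profiling database from a gene table and sequences
#'
#' Internal constructor shared by [read_database()] and the simulator. Builds
#' the three-level hierarchy (marker gene -> MGC -> mOTU), derives per-MGC
#' centroids, and validates all structural invariants.
#'
#' @param genes data.frame with columns `mg_id`, `cog`, `source`
#'   (`reference`/`metagenome`), `mgc_id`, `motu_id` (`"-1"` for unbinned),
#'   `coding_start`, `coding_end` (0-based half-open, within the padded
#'   sequence), `taxonomy` (semicolon-separated lineage, may be `""`).
#' @param seqs Named `Biostrings::DNAStringSet` (or named character vector) of
#'   padded marker gene sequences; names must match `genes$mg_id`.
#' @return An object of class `motu_db`: list with elements `genes`, `seqs`,
#'   `mgcs` (one row per MGC with its centroid member), `motus` (one row per
#'   mOTU), and `unbinned_mgcs` (character vector of MGC ids).
#' @export
build_database <- function(genes, seqs) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  need <- c("mg_id", "cog", "source", "mgc_id", "motu_id",
            "coding_start", "coding_end", "taxonomy")
  miss <- setdiff(need, names(genes))
  if (length(miss) > 0) {
    stop("gene table is missing columns: ", paste(miss, collapse = ", "))
  }
  genes <- genes[order(genes$mg_id), need, drop = FALSE]
  rownames(genes) <- NULL
  genes$coding_start <- as.integer(genes$coding_start)
  genes$coding_end <- as.integer(genes$coding_end)
  genes$motu_id <- as.character(genes$motu_id)

  errs <- character(0)
  if (anyDuplicated(genes$mg_id)) {
    errs <- c(errs, paste0("duplicated mg_id: ",
                           paste(unique(genes$mg_id[duplicated(genes$mg_id)]),
                                 collapse = ", ")))
  }
  if (!setequal(names(seqs), genes$mg_id)) {
    errs <- c(errs, "FASTA ids and manifest mg_ids do not match")
  }
  bad_cog <- !(genes$cog %in% MG_COGS)
  if (any(bad_cog)) {
    errs <- c(errs, paste0("unknown COG type for: ",
                           paste(genes$mg_id[bad_cog], collapse = ", ")))
  }
  bad_src <- !(genes$source %in% c("reference", "metagenome"))
  if (any(bad_src)) {
    errs <- c(errs, paste0("bad source for: ",
                           paste(genes$mg_id[bad_src], collapse = ", ")))
  }
  if (length(errs) > 0) stop(paste(errs, collapse = "; "))

  seqs <- seqs[genes$mg_id]
  seq_len_nt <- Biostrings::width(seqs)
  bad_span <- genes$coding_start < 0L | genes$coding_end > seq_len_nt |
    genes$coding_start >= genes$coding_end
  if (any(bad_span)) {
    errs <- c(errs, paste0("coding span out of bounds for: ",
                           paste(genes$mg_id[bad_span], collapse = ", ")))
  }
  bad_pad <- genes$coding_start > MAX_PAD |
    (seq_len_nt - genes$coding_end) > MAX_PAD
  if (any(bad_pad)) {
    errs <- c(errs, paste0("padding exceeds ", MAX_PAD, " nt for: ",
                           paste(genes$mg_id[bad_pad], collapse = ", ")))
  }

  # MGC level: all members share one COG type.
  mgc_split <- split(genes, genes$mgc_id)
  mgc_rows <- lapply(names(mgc_split), function(id) {
    g <- mgc_split[[id]]
    if (length(unique(g$cog)) > 1) {
      return(paste0("MGC ", id, " spans multiple COG types"))
    }
    if (length(unique(g$motu_id)) > 1) {
      return(paste0("MGC ", id, " members assigned to different mOTUs"))
    }
    data.frame(mgc_id = id, cog = g$cog[1],
               kind = if (any(g$source == "reference")) "ref" else "meta",
               motu_id = g$motu_id[1],
               centroid = mgc_centroid(g$mg_id, seqs),
               n_members = nrow(g), stringsAsFactors = FALSE)
  })
  is_err <- vapply(mgc_rows, is.character, logical(1))
  errs <- c(errs, unlist(mgc_rows[is_err]))
  if (length(errs) > 0) stop(paste(errs, collapse = "; "))
  mgcs <- do.call(rbind, mgc_rows)
  mgcs <- mgcs[order(mgcs$mgc_id), , drop = FALSE]
  rownames(mgcs) <- NULL

  # mOTU level: 6-10 MGCs, at most one per COG type.
  binned <- mgcs[mgcs$motu_id != UNBINNED, , drop = FALSE]
  motu_split <- split(binned, binned$motu_id)
  motu_rows <- lapply(names(motu_split), function(id) {
    m <- motu_split[[id]]
    if (nrow(m) < 6 || nrow(m) > 10) {
      return(paste0("mOTU ", id, " has ", nrow(m),
                    " MGCs (must have 6-10)"))
    }
    if (anyDuplicated(m$cog)) {
      return(paste0("mOTU ", id, " has more than one MGC of COG ",
                    paste(unique(m$cog[duplicated(m$cog)]), collapse = ",")))
    }
    tax <- genes$taxonomy[genes$mgc_id %in% m$mgc_id]
    tax <- tax[nzchar(tax)]
    data.frame(motu_id = id,
               kind = if (any(m$kind == "ref")) "ref" else "meta",
               n_mgcs = nrow(m),
               taxonomy = if (length(tax) > 0) tax[1] else "",
               stringsAsFactors = FALSE)
  })
  is_err <- vapply(motu_rows, is.character, logical(1))
  errs <- c(errs, unlist(motu_rows[is_err]))
  if (length(errs) > 0) stop(paste(errs, collapse = "; "))
  motus <- do.call(rbind, motu_rows)
  if (is.null(motus)) {
    motus <- data.frame(motu_id = character(0), kind = character(0),
                        n_mgcs = integer(0), taxonomy = character(0),
                        stringsAsFactors = FALSE)
  } else {
    motus <- motus[order(motus$motu_id), , drop = FALSE]
    rownames(motus) <- NULL
  }

  structure(list(genes = genes, seqs = seqs, mgcs = mgcs, motus = motus,
                 unbinned_mgcs = mgcs$mgc_id[mgcs$motu_id == UNBINNED]),
            class = "motu_db")
}

# Centroid (medoid) of an MGC: member maximizing mean global identity to the
# other members; ties broken by lexicographic id. Singletons are their own
# centroid.
mgc_centroid <- function(member_ids, seqs) {
  member_ids <- sort(member_ids)
  if (length(member_ids) == 1) return(member_ids)
  idm <- identity_matrix(seqs[member_ids])
  pick_centroid(member_ids, idm)
}

#' Read a marker-gene profiling database
#'
#' Loads padded marker gene sequences (FASTA) and the tab-separated manifest
#' describing the gene -> MGC -> mOTU hierarchy, validates all structural
#' invariants (unique ids, one COG type per MGC, 6-10 MGCs per mOTU, coding
#' spans within bounds) and derives per-MGC centroids.
#'
#' @param fasta_path Path to nucleotide FASTA of padded MG sequences.
#' @param manifest_path Path to the tab-separated manifest with a
#'   `#`-prefixed header line and columns `mg_id`, `cog`, `source`, `mgc_id`,
#'   `motu_id`, `coding_start`, `coding_end`, `taxonomy`.
#' @return A `motu_db` object (see [build_database()]).
#' @export
read_database <- function(fasta_path, manifest_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  lines <- readLines(manifest_path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0 || !startsWith(lines[1], "#")) {
    stop("manifest must start with a '#'-prefixed header line")
  }
  header <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  genes <- utils::read.table(text = lines[-1], sep = "\t",
                             col.names = header, colClasses = "character",
                             quote = "", comment.char = "")
  build_database(genes, seqs)
}

#' Write a profiling database in canonical form
#'
#' Inverse of [read_database()]: emits the FASTA and manifest with rows and
#' sequences sorted by `mg_id`, so that write -> read -> write is
#' byte-identical.
#'
#' @param db A `motu_db` object.
#' @param fasta_path,manifest_path Output paths.
#' @return Invisibly, `db`.
#' @export
write_database <- function(db, fasta_path, manifest_path) {
  stopifnot(inherits(db, "motu_db"))
  g <- db$genes[order(db$genes$mg_id), , drop = FALSE]
  Biostrings::writeXStringSet(db$seqs[g$mg_id], fasta_path, width = 70L)
  con <- file(manifest_path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(g), collapse = "\t")), con)
  utils::write.table(g, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(db)
}

#' Reduce a database to one centroid sequence per MGC
#'
#' The SNV-calling reference: keeps only the centroid (medoid) member of every
#' MGC so variants are called against a single reference sequence per MGC.
#' MGC and mOTU structure is unchanged.
#'
#' @param db A `motu_db` object.
#' @return A `motu_db` with exactly one marker gene per MGC.
#' @export
centroid_database <- function(db) {
  stopifnot(inherits(db, "motu_db"))
  keep <- db$genes$mg_id %in% db$mgcs$centroid
  build_database(db$genes[keep, , drop = FALSE], db$seqs[db$genes$mg_id[keep]])
}

#' @export
print.motu_db <- function(x, ...) {
  cat(sprintf(paste0("motu_db: %d marker genes, %d MGCs (%d unbinned), ",
                     "%d mOTUs (%d ref / %d meta)\n"),
              nrow(x$genes), nrow(x$mgcs), length(x$unbinned_mgcs),
              nrow(x$motus), sum(x$motus$kind == "ref"),
              sum(x$motus$kind == "meta")))
  invisible(x)
}

# Coding length (nt) of a marker gene.
coding_length <- function(db, mg_id) {
  i <- match(mg_id, db$genes$mg_id)
  db$genes$coding_end[i] - db$genes$coding_start[i]
}

# MGC id for each mg_id.
mg_to_mgc <- function(db, mg_id) {
  db$genes$mgc_id[match(mg_id, db$genes$mg_id)]
}
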