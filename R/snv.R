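#' SNV filter parameters
#'
#' The five-parameter filter cascade applied to marker-gene pileups before
#' allele frequencies are reported.
#'
#' @param fb Minimum horizontal coverage (% of the mOTU's centroid positions
#'   covered at least once) per sample and mOTU (default 80).
#' @param fd Minimum vertical coverage (mean reads per position) per sample
#'   and mOTU (default 5).
#' @param fm Minimum number of samples meeting both criteria per mOTU
#'   (default 2).
#' @param fc Minimum per-position depth for a position to count in a sample
#'   (default 5).
#' @param fp Minimum proportion of retained samples meeting `fc` at a
#'   position (default 0.9).
#' @param min_alt Minimum alternative-allele reads in at least one retained
#'   sample for a position to be reported as a SNV (default 2).
#' @return List of class `snv_params`.
#' @export
snv_params <- function(fb = 80, fd = 5, fm = 2L, fc = 5, fp = 0.9,
                       min_alt = 2L) {
  stopifnot(fb >= 0, fb <= 100, fp >= 0, fp <= 1, fd >= 0, fm >= 0, fc >= 0)
  structure(list(fb = fb, fd = fd, fm = fm, fc = fc, fp = fp,
                 min_alt = min_alt), class = "snv_params")
}

#' Restrict alignment records to inserts flagged as unique
#'
#' SNV calling only uses inserts with a single best-scoring MGC; records of
#' multiple-flagged inserts are dropped entirely.
#'
#' @param records From [parse_and_filter()].
#' @param assignments From [assign_inserts()].
#' @return The subset of `records`.
#' @export
unique_records <- function(records, assignments) {
  uniq <- unique(assignments$insert_id[assignments$flag == "unique"])
  records[records$insert_id %in% uniq, , drop = FALSE]
}

#' Per-position base counts over MGC centroid sequences
#'
#' Walks the CIGAR of every alignment (only inserts flagged as unique
#' alignments should be passed; see [unique_records()]) to lay read bases
#' onto the reference, and counts A/C/G/T per coding position of each
#' centroid. Padded (non-coding) positions are excluded; positions are
#' 0-based within the coding region.
#'
#' @param records Filtered alignment records ([parse_and_filter()]) against
#'   a centroid database.
#' @param db The centroid `motu_db` ([centroid_database()]).
#' @return `data.table` with columns `mg_id`, `pos`, `A`, `C`, `G`, `T`,
#'   `depth`.
#' @export
pileup <- function(records, db) {
  empty <- data.table::data.table(mg_id = character(0), pos = integer(0),
                                  A = 0L, C = 0L, G = 0L, T = 0L,
                                  depth = 0L)
  if (nrow(records) == 0) return(empty)
  ref_len <- stats::setNames(Biostrings::width(db$seqs), names(db$seqs))
  if (any(records$ref_end > ref_len[records$target_mg])) {
    stop("alignment extends beyond reference bounds")
  }
  layered <- GenomicAlignments::sequenceLayer(
    Biostrings::DNAStringSet(records$seq), records$cigar)
  chars <- strsplit(as.character(layered), "", fixed = TRUE)
  widths <- lengths(chars)
  mg <- rep(records$target_mg, widths)
  pos0 <- unlist(lapply(seq_len(nrow(records)), function(i) {
    seq.int(records$ref_start[i], length.out = widths[i])
  }))
  dt <- data.table::data.table(mg_id = mg, refpos = pos0,
                               base = unlist(chars))
  gi <- match(dt$mg_id, db$genes$mg_id)
  dt[, pos := refpos - db$genes$coding_start[gi]]
  clen <- db$genes$coding_end[gi] - db$genes$coding_start[gi]
  dt <- dt[pos >= 0L & pos < clen & base %in% c("A", "C", "G", "T")]
  counts <- dt[, .N, by = .(mg_id, pos, base)]
  wide <- data.table::dcast(counts, mg_id + pos ~ base, value.var = "N",
                            fill = 0L)
  for (b in c("A", "C", "G", "T")) {
    if (!b %in% names(wide)) wide[, (b) := 0L]
  }
  wide[, depth := A + C + G + T]
  data.table::setcolorder(wide, c("mg_id", "pos", "A", "C", "G", "T",
                                  "depth"))
  data.table::setorder(wide, mg_id, pos)
  wide[]
}

#' Horizontal and vertical coverage per sample and mOTU
#'
#' Pools the coding positions of all centroid sequences of each mOTU:
#' horizontal coverage is the percentage of positions covered by at least
#' one read, vertical coverage the mean number of reads per position.
#'
#' @param pileups Named list of per-sample pileups ([pileup()]).
#' @param db The centroid `motu_db`.
#' @return data.frame with columns `sample_id`, `motu_id`, `horizontal`
#'   (percent) and `vertical`.
#' @export
coverage_summary <- function(pileups, db) {
  motu_len <- vapply(db$motus$motu_id, function(m) {
    cent <- db$mgcs$centroid[db$mgcs$motu_id == m]
    sum(coding_length(db, cent))
  }, numeric(1))
  out <- expand.grid(sample_id = names(pileups),
                     motu_id = db$motus$motu_id,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mgc_motu <- stats::setNames(db$mgcs$motu_id, db$mgcs$centroid)
  out$horizontal <- 0
  out$vertical <- 0
  for (s in names(pileups)) {
    pu <- pileups[[s]]
    if (nrow(pu) == 0) next
    pm <- mgc_motu[pu$mg_id]
    cov_pos <- tapply(pu$depth > 0, pm, sum)
    tot_reads <- tapply(as.numeric(pu$depth), pm, sum)
    i <- out$sample_id == s
    m <- out$motu_id[i]
    h <- as.numeric(cov_pos[m]); h[is.na(h)] <- 0
    v <- as.numeric(tot_reads[m]); v[is.na(v)] <- 0
    out$horizontal[i] <- 100 * h / motu_len[m]
    out$vertical[i] <- v / motu_len[m]
  }
  out
}

#' Call SNVs and build the filtered allele frequency table
#'
#' Applies the filter cascade: a sample is retained for a mOTU if its
#' horizontal coverage is at least `fb` percent and its vertical coverage at
#' least `fd`; a mOTU is retained if at least `fm` samples survive; a
#' position is retained if its depth reaches `fc` in at least a fraction
#' `fp` of the retained samples. A retained position becomes a SNV row when
#' at least one retained sample shows the alternative allele in `min_alt`
#' or more reads. The alternative allele is the most frequent non-reference
#' base pooled over retained samples (other alleles are dropped); frequencies
#' are alternative reads over depth, `NA` where a sample's depth is below
#' `fc`.
#'
#' @param pileups Named list of per-sample pileups.
#' @param db The centroid `motu_db`.
#' @param params An [snv_params()] object.
#' @return Object of class `snv_table`: list with `rows` (data.frame
#'   `motu_id`, `mg_id`, `pos`, `ref`, `alt`), `freq` (matrix rows x retained
#'   samples, `NA` = missing), `retained` (data.frame `motu_id`,
#'   `sample_id`), `coverage` (the [coverage_summary()]), and `params`.
#' @export
call_and_filter <- function(pileups, db, params = snv_params()) {
  stopifnot(inherits(params, "snv_params"))
  cov <- coverage_summary(pileups, db)
  keep <- cov$horizontal >= params$fb & cov$vertical >= params$fd
  ret <- cov[keep, c("motu_id", "sample_id")]
  n_ret <- table(ret$motu_id)
  motus <- names(n_ret)[n_ret >= params$fm]

  rows <- list(); freqs <- list()
  for (m in sort(motus)) {
    samples <- sort(ret$sample_id[ret$motu_id == m])
    cents <- db$mgcs$centroid[db$mgcs$motu_id == m]
    for (mg in sort(cents)) {
      clen <- coding_length(db, mg)
      gi <- match(mg, db$genes$mg_id)
      cstart <- db$genes$coding_start[gi]
      refseq <- strsplit(substr(as.character(db$seqs[[mg]]),
                                cstart + 1, cstart + clen), "")[[1]]
      depth <- matrix(0, nrow = clen, ncol = length(samples),
                      dimnames = list(NULL, samples))
      cnt <- lapply(c("A", "C", "G", "T"), function(b) depth)
      names(cnt) <- c("A", "C", "G", "T")
      for (s in samples) {
        pu <- as.data.frame(pileups[[s]])
        pu <- pu[pu$mg_id == mg & pu$pos < clen, , drop = FALSE]
        if (nrow(pu) == 0) next
        depth[pu$pos + 1L, s] <- pu$depth
        for (b in c("A", "C", "G", "T")) cnt[[b]][pu$pos + 1L, s] <- pu[[b]]
      }
      pos_ok <- rowSums(depth >= params$fc) >= params$fp * length(samples)
      if (!any(pos_ok)) next
      for (p in which(pos_ok)) {
        ref <- refseq[p]
        alts <- setdiff(c("A", "C", "G", "T"), ref)
        alt_tot <- vapply(alts, function(b) sum(cnt[[b]][p, ]), numeric(1))
        if (max(alt_tot) == 0) next
        alt <- alts[order(-alt_tot, alts)][1]
        per_sample_alt <- vapply(samples, function(s) cnt[[alt]][p, s],
                                 numeric(1))
        if (max(per_sample_alt) < params$min_alt) next
        f <- per_sample_alt / depth[p, ]
        f[depth[p, ] < params$fc] <- NA
        rows[[length(rows) + 1L]] <- data.frame(
          motu_id = m, mg_id = mg, pos = p - 1L, ref = ref, alt = alt,
          stringsAsFactors = FALSE)
        freqs[[length(freqs) + 1L]] <- f
      }
    }
  }
  all_samples <- sort(unique(ret$sample_id))
  if (length(rows) == 0) {
    freq <- matrix(numeric(0), nrow = 0, ncol = length(all_samples),
                   dimnames = list(NULL, all_samples))
    rows_df <- data.frame(motu_id = character(0), mg_id = character(0),
                          pos = integer(0), ref = character(0),
                          alt = character(0))
  } else {
    rows_df <- do.call(rbind, rows)
    freq <- matrix(NA_real_, nrow = nrow(rows_df),
                   ncol = length(all_samples),
                   dimnames = list(NULL, all_samples))
    for (i in seq_along(freqs)) freq[i, names(freqs[[i]])] <- freqs[[i]]
  }
  structure(list(rows = rows_df, freq = freq, retained = ret,
                 coverage = cov, params = params), class = "snv_table")
}

#' Manhattan and major-allele distances between strain populations
#'
#' For every mOTU in the table and every pair of its retained samples,
#' distances are computed over the SNV positions with non-missing
#' frequencies in both samples: the Manhattan distance is the sum of
#' absolute allele frequency differences; the major-allele distance is the
#' fraction of shared positions whose allele frequency differs by more than
#' 50%. Pairs with no shared positions get `NA`.
#'
#' @param table An `snv_table` from [call_and_filter()].
#' @return Named list (per mOTU) of lists with symmetric matrices
#'   `manhattan` and `major_allele`.
#' @export
snv_distances <- function(table) {
  stopifnot(inherits(table, "snv_table"))
  out <- list()
  for (m in sort(unique(table$rows$motu_id))) {
    samples <- sort(table$retained$sample_id[table$retained$motu_id == m])
    if (length(samples) < 2) next
    f <- table$freq[table$rows$motu_id == m, samples, drop = FALSE]
    n <- length(samples)
    mann <- matrix(0, n, n, dimnames = list(samples, samples))
    major <- mann
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        ok <- !is.na(f[, i]) & !is.na(f[, j])
        if (!any(ok)) {
          mann[i, j] <- mann[j, i] <- NA
          major[i, j] <- major[j, i] <- NA
        } else {
          d <- abs(f[ok, i] - f[ok, j])
          mann[i, j] <- mann[j, i] <- sum(d)
          major[i, j] <- major[j, i] <- mean(d > 0.5)
        }
      }
    }
    out[[m]] <- list(manhattan = mann, major_allele = major)
  }
  out
}

#' Write SNV results in the standard output layout
#'
#' Produces, under `dir`: the horizontal coverage table (`<name>.cov.tab`),
#' the vertical coverage table (`<name>.perc.tab`), a `<name>.log` run
#' summary, per-mOTU filtered allele frequency tables under `filtered-<name>/`
#' and per-mOTU distance matrices under `distances-<name>/` (Manhattan as
#' `*.mann.dist`, major-allele as `*.allele.dist`).
#'
#' @param table An `snv_table`.
#' @param dir Output directory (created if needed).
#' @param name Basename for the output files (default `"snv"`).
#' @export
write_snv_results <- function(table, dir, name = "snv") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wide <- function(values_col) {
    stats::reshape(table$coverage[, c("sample_id", "motu_id", values_col)],
                   direction = "wide", idvar = "motu_id",
                   timevar = "sample_id")
  }
  utils::write.table(wide("horizontal"),
                     file.path(dir, paste0(name, ".cov.tab")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(wide("vertical"),
                     file.path(dir, paste0(name, ".perc.tab")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(sprintf("samples: %d",
                       length(unique(table$coverage$sample_id))),
               sprintf("mOTUs retained: %d",
                       length(unique(table$rows$motu_id))),
               sprintf("SNV rows: %d", nrow(table$rows)),
               sprintf("filters: fb=%g fd=%g fm=%d fc=%g fp=%g min_alt=%d",
                       table$params$fb, table$params$fd, table$params$fm,
                       table$params$fc, table$params$fp,
                       table$params$min_alt)),
             file.path(dir, paste0(name, ".log")))
  fdir <- file.path(dir, paste0("filtered-", name))
  ddir <- file.path(dir, paste0("distances-", name))
  dir.create(fdir, showWarnings = FALSE)
  dir.create(ddir, showWarnings = FALSE)
  dists <- snv_distances(table)
  for (m in unique(table$rows$motu_id)) {
    sel <- table$rows$motu_id == m
    tab <- cbind(table$rows[sel, , drop = FALSE],
                 table$freq[sel, , drop = FALSE])
    utils::write.table(tab, file.path(fdir, paste0(m, ".freq.tab")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(dists[[m]])) {
      utils::write.table(dists[[m]]$manhattan,
                         file.path(ddir, paste0(m, ".mann.dist")),
                         sep = "\t", quote = FALSE)
      utils::write.table(dists[[m]]$major_allele,
                         file.path(ddir, paste0(m, ".allele.dist")),
                         sep = "\t", quote = FALSE)
    }
  }
  invisible(table)
}
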