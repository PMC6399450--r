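# Shared fixtures: a tiny handcrafted database, constructors for alignment
# records / assignments / pileups, and independent brute-force oracles used
# to cross-check the implementation.

# Two species (one ref, one meta) with 6 MGCs each, plus two unbinned MGCs.
# Sequences are 200 nt, unpadded (coding span = whole sequence).
toy_db <- function() {
  set.seed(4242)
  cogs6 <- MG_COGS[1:6]
  rows <- list()
  seqs <- character(0)
  for (sp in c("A", "B")) {
    for (i in 1:6) {
      id <- paste0("mg", sp, i)
      rows[[id]] <- data.frame(
        mg_id = id, cog = cogs6[i],
        source = if (sp == "A") "reference" else "metagenome",
        mgc_id = paste0("MGC_", sp, i),
        motu_id = paste0("motu", sp),
        coding_start = 0L, coding_end = 200L,
        taxonomy = paste0("Bacteria;P1;C1;O1;F1;G", sp, ";sp", sp),
        stringsAsFactors = FALSE)
      seqs[id] <- paste(sample(c("A", "C", "G", "T"), 200, TRUE),
                        collapse = "")
    }
  }
  for (i in 1:2) {
    id <- paste0("mgU", i)
    rows[[id]] <- data.frame(
      mg_id = id, cog = MG_COGS[i], source = "metagenome",
      mgc_id = paste0("MGC_U", i), motu_id = "-1",
      coding_start = 0L, coding_end = 200L, taxonomy = "",
      stringsAsFactors = FALSE)
    seqs[id] <- paste(sample(c("A", "C", "G", "T"), 200, TRUE),
                      collapse = "")
  }
  build_database(do.call(rbind, rows), seqs)
}

# Alignment-record data.frame with the profiler's column layout.
make_records <- function(insert_id, mate, target_mg, score,
                         aligned_bases = 100L, pos = 1L, cigar = NULL,
                         seq = NULL, nm = 0L) {
  n <- length(insert_id)
  if (is.null(cigar)) cigar <- paste0(aligned_bases, "M")
  if (is.null(seq)) {
    seq <- vapply(aligned_bases, function(k) {
      paste(rep("A", k), collapse = "")
    }, character(1))
  }
  data.frame(insert_id = insert_id, mate = mate, target_mg = target_mg,
             pos = pos, cigar = cigar, seq = seq,
             aligned_length = aligned_bases, aligned_bases = aligned_bases,
             ref_start = pos - 1L, ref_end = pos - 1L + aligned_bases,
             nm = nm, identity = 1, score = score,
             stringsAsFactors = FALSE)
}

# insert_assignments object from (insert_id, mgc_id, flag) triples.
make_assignments <- function(insert_id, mgc_id,
                             insert_score = rep(100, length(insert_id))) {
  df <- data.frame(insert_id = insert_id, mgc_id = mgc_id,
                   insert_score = insert_score, stringsAsFactors = FALSE)
  nb <- table(df$insert_id)
  df$n_best <- as.integer(nb[df$insert_id])
  df$flag <- ifelse(df$n_best == 1L, "unique", "multiple")
  class(df) <- c("insert_assignments", "data.frame")
  df
}

# Brute-force multi-mapper redistribution: materialize every insert's
# fractional share explicitly.
oracle_insert_counts <- function(assignments) {
  a <- as.data.frame(assignments)
  res <- stats::setNames(rep(0, length(unique(a$mgc_id))),
                         sort(unique(a$mgc_id)))
  uniq <- a[a$flag == "unique", ]
  u <- table(uniq$mgc_id)
  for (i in seq_len(nrow(uniq))) {
    res[uniq$mgc_id[i]] <- res[uniq$mgc_id[i]] + 1
  }
  for (ins in unique(a$insert_id[a$flag == "multiple"])) {
    targets <- a$mgc_id[a$insert_id == ins]
    uu <- as.numeric(u[targets])
    uu[is.na(uu)] <- 0
    share <- if (sum(uu) > 0) uu / sum(uu) else rep(1 / length(targets),
                                                    length(targets))
    res[targets] <- res[targets] + share
  }
  res
}

# Random redistribution instance with <= `max_inserts` inserts.
random_assignment_instance <- function(max_inserts = 20L, n_mgcs = 4L) {
  mgcs <- paste0("M", seq_len(n_mgcs))
  n <- sample.int(max_inserts, 1)
  ins <- character(0); tgt <- character(0)
  for (i in seq_len(n)) {
    k <- if (stats::runif(1) < 0.5) 1L else sample(2:min(4L, n_mgcs), 1)
    ins <- c(ins, rep(sprintf("i%02d", i), k))
    tgt <- c(tgt, sample(mgcs, k))
  }
  make_assignments(ins, tgt)
}

# Naive average-linkage agglomeration that recomputes every inter-cluster
# mean from the original matrix (independent of the Lance-Williams update
# used by the implementation).
oracle_average_linkage <- function(d, cutoff) {
  clusters <- lapply(rownames(d), identity)
  repeat {
    if (length(clusters) < 2) break
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        avg <- mean(d[clusters[[i]], clusters[[j]]])
        lab <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        cand <- list(avg = avg, i = i, j = j, lab = lab)
        if (is.null(best) || avg < best$avg ||
            (avg == best$avg &&
             (lab[1] < best$lab[1] ||
              (lab[1] == best$lab[1] && lab[2] < best$lab[2])))) {
          best <- cand
        }
      }
    }
    if (best$avg > cutoff) break
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    clusters <- clusters[-c(best$i, best$j)]
    clusters[[length(clusters) + 1]] <- merged
  }
  lapply(clusters, sort)
}

# canonical form of a partition for set comparison
canon_partition <- function(clusters) {
  s <- lapply(unname(clusters), function(x) sort(unname(x)))
  s[order(vapply(s, `[`, character(1), 1))]
}

# Exhaustive weighted-LCA oracle: evaluate the bitscore coverage of every
# (rank, prefix) among retained hits and take the deepest covering taxon.
oracle_weighted_lca <- function(hits, keep_frac = 0.9, cover_frac = 0.75) {
  keep <- hits$bitscore >= keep_frac * max(hits$bitscore)
  hits <- hits[keep, , drop = FALSE]
  lin <- lapply(hits$lineage, lineage_parse)
  total <- sum(hits$bitscore)
  for (d in 7:1) {
    prefixes <- unique(stats::na.omit(vapply(lin, function(l) {
      if (is.na(l[d])) NA_character_ else paste(l[1:d], collapse = ";")
    }, character(1))))
    if (length(prefixes) == 0) next
    cov <- vapply(prefixes, function(p) {
      sum(hits$bitscore[vapply(lin, function(l) {
        !is.na(l[d]) && paste(l[1:d], collapse = ";") == p
      }, logical(1))])
    }, numeric(1))
    ok <- cov >= cover_frac * total
    if (any(ok)) {
      cand <- names(cov)[ok]
      best <- cand[order(-cov[ok], cand)][1]
      return(lineage_parse(best))
    }
  }
  lineage_parse("")
}

# random lineage drawing names from a small pool so hits share ancestors
random_lineage <- function() {
  paste("Bacteria",
        paste0("P", sample(1:2, 1)), paste0("C", sample(1:2, 1)),
        paste0("O", sample(1:3, 1)), paste0("F", sample(1:3, 1)),
        paste0("G", sample(1:4, 1)), paste0("s", sample(1:6, 1)),
        sep = ";")
}

# Write SAM text lines to a temp file; returns the path.
write_sam_text <- function(lines, sq = c(mgA1 = 200L)) {
  hdr <- c("@HD\tVN:1.6",
           paste0("@SQ\tSN:", names(sq), "\tLN:", sq))
  path <- tempfile(fileext = ".sam")
  writeLines(c(hdr, lines), path)
  path
}

sam_line <- function(qname, flag, rname, pos, cigar, seq,
                     tags = "NM:i:0\tAS:i:100") {
  paste(qname, flag, rname, pos, 60, cigar, "*", 0, 0, seq, "*", tags,
        sep = "\t")
}

dna <- function(n, base = "A") paste(rep(base, n), collapse = "")

# Pileup rows covering `positions` (0-based) of marker gene `mg` at `depth`
# reads of the reference base, with optional alt counts:
# alt = data.frame(pos, base, count).
pileup_for <- function(db, mg, positions, depth, alt = NULL) {
  gi <- match(mg, db$genes$mg_id)
  cs <- db$genes$coding_start[gi]
  refseq <- strsplit(as.character(db$seqs[[mg]]), "")[[1]]
  base_cols <- c("A", "C", "G", "T")
  m <- matrix(0L, nrow = length(positions), ncol = 4,
              dimnames = list(NULL, base_cols))
  refb <- refseq[cs + positions + 1]
  for (i in seq_along(positions)) m[i, refb[i]] <- depth
  if (!is.null(alt)) {
    for (r in seq_len(nrow(alt))) {
      i <- match(alt$pos[r], positions)
      m[i, refb[i]] <- m[i, refb[i]] - alt$count[r]
      m[i, alt$base[r]] <- m[i, alt$base[r]] + alt$count[r]
    }
  }
  out <- data.frame(mg_id = mg, pos = as.integer(positions),
                    A = m[, "A"], C = m[, "C"], G = m[, "G"], T = m[, "T"],
                    stringsAsFactors = FALSE)
  out$depth <- out$A + out$C + out$G + out$T
  out
}

# Pileups fully covering motuA's centroids of toy_db() at a given depth,
# with an optional fraction of positions missing.
motuA_pileup <- function(db, depth = 10, frac = 1) {
  do.call(rbind, lapply(paste0("mgA", 1:6), function(mg) {
    pileup_for(db, mg, seq_len(round(200 * frac)) - 1L, depth)
  }))
}

# small simulated database shared across tests (built once)
.fixture_env <- new.env()
small_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_database(
      sim_config(n_species = 6, n_known = 3, n_meta = 2), seed = 101)
  }
  .fixture_env$sim
}
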