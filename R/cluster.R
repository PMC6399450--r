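#' Global pairwise nucleotide identity
#'
#' Needleman-Wunsch global alignment of two nucleotide sequences with a fixed
#' scoring scheme (match +1, mismatch -1, linear gap penalty -2). Identity is
#' the number of matching columns divided by the total number of alignment
#' columns (gaps included), so it is symmetric in its arguments.
#'
#' @param seq_a,seq_b Nucleotide sequences (character or `DNAString`),
#'   ACGTN alphabet only.
#' @return List with `identity` (fraction of alignment columns that match)
#'   and `aligned_bases` (number of gap-free alignment columns).
#' @export
global_identity <- function(seq_a, seq_b) {
  seq_a <- toupper(as.character(seq_a))
  seq_b <- toupper(as.character(seq_b))
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  if (grepl("[^ACGTN]", seq_a) || grepl("[^ACGTN]", seq_b)) {
    stop("sequences must contain only A, C, G, T or N")
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq_a), Biostrings::DNAString(seq_b),
    type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2)
  p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  ncol_al <- length(p)
  nmatch <- sum(p == s & p != "-")
  list(identity = nmatch / ncol_al,
       aligned_bases = sum(p != "-" & s != "-"))
}

# Symmetric identity matrix over a named DNAStringSet (diagonal 1).
identity_matrix <- function(seqs, min_aligned = 0L) {
  ids <- names(seqs)
  n <- length(ids)
  m <- matrix(1, n, n, dimnames = list(ids, ids))
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      gi <- global_identity(seqs[[i]], seqs[[j]])
      idy <- if (gi$aligned_bases < min_aligned) 0 else gi$identity
      m[i, j] <- m[j, i] <- idy
    }
  }
  m
}

#' Length-weighted genome distance from per-marker-gene identities
#'
#' Genome-to-genome distance used for species (specI-style) clustering:
#' one minus the gene-length-weighted arithmetic mean of the individual
#' marker gene sequence identities shared by the two genomes.
#'
#' @param lengths Numeric vector of marker gene lengths (nt).
#' @param identities Numeric vector of per-gene identities in `[0, 1]`.
#' @return Distance in `[0, 1]`.
#' @export
genome_distance <- function(lengths, identities) {
  if (length(lengths) == 0) stop("at least one shared marker gene required")
  stopifnot(length(lengths) == length(identities))
  1 - sum(lengths * identities) / sum(lengths)
}

#' Average-linkage agglomerative clustering with a distance cutoff
#'
#' UPGMA-style agglomeration: repeatedly merge the pair of clusters with the
#' smallest average inter-cluster distance (arithmetic mean over all
#' cross-cluster member pairs), stopping when that minimum exceeds `cutoff`.
#' Ties are broken by the lexicographically smallest (sorted) pair of cluster
#' labels, so the result is deterministic. The default cutoff 0.035
#' corresponds to the species-level threshold of 96.5% nucleotide identity.
#'
#' @param d Symmetric distance matrix with zero diagonal and row/column
#'   names, or a `dist` object.
#' @param cutoff Maximum average linkage distance at which clusters are still
#'   merged.
#' @return Object of class `cluster_set`: list with `clusters` (list of
#'   member id vectors, each sorted; list ordered by first member) and
#'   `cutoff`.
#' @export
average_linkage <- function(d, cutoff = 0.035) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("x", seq_len(nrow(d)))
  }
  if (any(is.na(d)) || any(is.nan(d))) stop("distance matrix contains NA/NaN")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric")

  members <- lapply(rownames(d), identity)
  names(members) <- rownames(d)
  sizes <- stats::setNames(rep(1L, nrow(d)), rownames(d))
  dm <- d
  diag(dm) <- Inf

  while (length(members) > 1) {
    # smallest average distance; ties by lexicographically smallest pair
    labs <- names(members)
    min_val <- min(dm)
    if (min_val > cutoff) break
    hits <- which(dm == min_val, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    pairs <- cbind(labs[hits[, 1]], labs[hits[, 2]])
    pairs <- t(apply(pairs, 1, sort))
    ord <- order(pairs[, 1], pairs[, 2])
    a <- pairs[ord[1], 1]; b <- pairs[ord[1], 2]

    # Lance-Williams update for (size-weighted) average linkage
    na <- sizes[[a]]; nb <- sizes[[b]]
    others <- setdiff(labs, c(a, b))
    new_d <- (na * dm[a, others] + nb * dm[b, others]) / (na + nb)
    names(new_d) <- others
    merged <- sort(c(members[[a]], members[[b]]))
    members[[a]] <- NULL; members[[b]] <- NULL
    sizes <- sizes[others]
    dm <- dm[others, others, drop = FALSE]
    lab <- merged[1]
    members[[lab]] <- merged
    sizes[[lab]] <- na + nb
    dm <- rbind(cbind(dm, unname(new_d)), c(unname(new_d), Inf))
    rownames(dm)[nrow(dm)] <- colnames(dm)[ncol(dm)] <- lab
  }
  clusters <- unname(members[order(names(members))])
  structure(list(clusters = clusters, cutoff = cutoff), class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d clusters at cutoff %.4g\n",
              length(x$clusters), x$cutoff))
  invisible(x)
}

# Membership vector (cluster index per id) from a cluster_set.
cluster_membership <- function(cs) {
  idx <- rep(seq_along(cs$clusters), lengths(cs$clusters))
  stats::setNames(idx, unlist(cs$clusters))
}

#' Open-reference clustering of metagenomic marker genes
#'
#' Augments pre-existing reference MGCs with metagenome-derived marker genes
#' (meta-MGs), then clusters the remainder de novo into meta-MGCs. A meta-MG
#' joins the reference MGC to which its average-linkage distance (mean
#' distance to current members) is within `1 - identity_cutoff`; candidates
#' are processed greedily in order of decreasing best identity, so earlier
#' joiners are visible to later ones. Pairwise alignments spanning fewer than
#' `min_aligned` bases are treated as identity 0. Remaining meta-MGs are
#' clustered by [average_linkage()] at the same cutoff.
#'
#' @param ref_mgcs Named list of `DNAStringSet` (or named character vectors),
#'   one element per reference MGC, all of one COG type.
#' @param meta_mgs Named `DNAStringSet` (or named character vector) of
#'   metagenomic marker genes of the same COG type.
#' @param identity_cutoff Species-level identity threshold (default 0.965).
#' @param min_aligned Minimum gap-free aligned bases for an alignment to
#'   count (default 20).
#' @return List with `ref` (named list: MGC id -> member ids, including any
#'   joined meta-MGs) and `meta` (`cluster_set` over the remaining meta-MGs).
#' @export
open_reference_cluster <- function(ref_mgcs, meta_mgs,
                                   identity_cutoff = 0.965,
                                   min_aligned = 20L) {
  as_set <- function(x) {
    if (is.character(x)) Biostrings::DNAStringSet(x) else x
  }
  ref_members <- lapply(ref_mgcs, function(x) names(as_set(x)))
  all_seqs <- c(do.call(c, unname(lapply(ref_mgcs, as_set))),
                as_set(meta_mgs))
  cutoff <- 1 - identity_cutoff

  pair_identity <- function(a, b) {
    gi <- global_identity(all_seqs[[a]], all_seqs[[b]])
    if (gi$aligned_bases < min_aligned) 0 else gi$identity
  }

  meta_ids <- names(as_set(meta_mgs))
  # best average identity of each meta-MG to each ref-MGC (initial members)
  best <- vapply(meta_ids, function(m) {
    if (length(ref_members) == 0) return(0)
    max(vapply(ref_members, function(mem) {
      mean(vapply(mem, pair_identity, numeric(1), a = m))
    }, numeric(1)))
  }, numeric(1))

  unplaced <- character(0)
  for (m in meta_ids[order(-best, meta_ids)]) {
    if (length(ref_members) > 0) {
      avg_d <- vapply(ref_members, function(mem) {
        1 - mean(vapply(mem, pair_identity, numeric(1), a = m))
      }, numeric(1))
      j <- which.min(avg_d)
      if (avg_d[j] <= cutoff) {
        ref_members[[j]] <- sort(c(ref_members[[j]], m))
        next
      }
    }
    unplaced <- c(unplaced, m)
  }

  if (length(unplaced) > 0) {
    idm <- identity_matrix(all_seqs[unplaced], min_aligned = min_aligned)
    meta_cs <- average_linkage(1 - idm, cutoff = cutoff)
  } else {
    meta_cs <- structure(list(clusters = list(), cutoff = cutoff),
                         class = "cluster_set")
  }
  list(ref = ref_members, meta = meta_cs)
}

#' Pick the centroid (medoid) member of an MGC
#'
#' The member with the highest mean identity to the other members; ties are
#' broken by lexicographically smallest id. A singleton is its own centroid.
#'
#' @param member_ids Character vector of member ids.
#' @param identities Symmetric identity matrix indexed by member id.
#' @return The centroid member id.
#' @export
pick_centroid <- function(member_ids, identities) {
  member_ids <- sort(member_ids)
  if (length(member_ids) == 1) return(member_ids)
  mean_id <- vapply(member_ids, function(i) {
    mean(identities[i, setdiff(member_ids, i)])
  }, numeric(1))
  member_ids[which.max(mean_id)]  # which.max takes first = lexicographic tie
}
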