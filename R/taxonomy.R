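#' Bitscore-weighted lowest common ancestor of protein hits
#'
#' Annotates a marker gene from its protein reference hits. Hits with a
#' bitscore below `keep_frac` of the best hit are dropped; walking from the
#' species rank upward, the annotation is the deepest taxon whose summed
#' bitscore covers at least `cover_frac` of the total bitscore of the
#' retained hits, which excludes outlier taxa among near-best hits.
#'
#' @param hits data.frame with columns `lineage` (semicolon-separated, may be
#'   truncated) and `bitscore` (> 0).
#' @param keep_frac Retain hits with bitscore >= `keep_frac` x max
#'   (default 0.90).
#' @param cover_frac Minimum covered fraction of the retained bitscore sum
#'   (default 0.75).
#' @return Lineage vector (see [lineage_parse()]); fully unannotated when
#'   there are no hits or no taxon reaches coverage at any rank.
#' @export
weighted_lca <- function(hits, keep_frac = 0.90, cover_frac = 0.75) {
  if (is.null(hits) || nrow(hits) == 0) return(lineage_empty())
  stopifnot(all(hits$bitscore > 0))
  keep <- hits$bitscore >= keep_frac * max(hits$bitscore)
  hits <- hits[keep, , drop = FALSE]
  lin <- t(vapply(hits$lineage, lineage_parse,
                  character(length(TAX_RANKS))))
  total <- sum(hits$bitscore)
  for (d in rev(seq_along(TAX_RANKS))) {
    has <- !is.na(lin[, d])
    if (!any(has)) next
    key <- apply(lin[has, seq_len(d), drop = FALSE], 1, paste,
                 collapse = ";")
    cover <- tapply(hits$bitscore[has], key, sum)
    cover <- sort(cover, decreasing = TRUE)  # ties: lexicographic via sort
    best <- names(cover)[order(-cover, names(cover))][1]
    if (cover[best] >= cover_frac * total) {
      return(lineage_parse(best))
    }
  }
  lineage_empty()
}

#' Transfer the best member annotation to an MGC
#'
#' An MGC inherits the lineage of the member marker gene whose top retained
#' bitscore is highest; ties are broken by lexicographically smallest member
#' id.
#'
#' @param members data.frame with columns `mg_id`, `lineage`
#'   (semicolon-separated; `""` for unannotated members) and `top_score`
#'   (best retained bitscore of that member, `NA` when unannotated).
#' @return Lineage vector; unannotated when no member is annotated.
#' @export
annotate_mgc <- function(members) {
  ok <- !is.na(members$top_score) & nzchar(members$lineage)
  if (!any(ok)) return(lineage_empty())
  m <- members[ok, , drop = FALSE]
  m <- m[order(-m$top_score, m$mg_id), , drop = FALSE]
  lineage_parse(m$lineage[1])
}

#' Consensus taxonomy of a meta-mOTU from its MGC annotations
#'
#' Per rank, the mOTU is annotated only if at least `min_annotated` MGCs
#' carry a name at that rank; the annotation is the plurality name
#' (lexicographic tie-break) and the rank is flagged consistent when the
#' plurality accounts for at least `consensus_frac` of the annotated MGCs.
#' Ranks are then forced consistent top-down: a rank is blanked (together
#' with everything below it) if its chosen name never co-occurs with the
#' chosen name of its parent rank in any member lineage.
#'
#' @param mgc_lineages Character vector of semicolon-separated MGC lineages
#'   (may include `""` for unannotated MGCs).
#' @param min_annotated Minimum annotated MGCs per rank (default 3).
#' @param consensus_frac Agreement fraction for consistency (default 0.5,
#'   non-strict).
#' @return List with `lineage` (lineage vector) and `consistent` (named
#'   logical per annotated rank; `NA` at unannotated ranks).
#' @export
annotate_meta_motu <- function(mgc_lineages, min_annotated = 3L,
                               consensus_frac = 0.5) {
  lin <- t(vapply(mgc_lineages, lineage_parse,
                  character(length(TAX_RANKS))))
  chosen <- rep(NA_character_, length(TAX_RANKS))
  consistent <- rep(NA, length(TAX_RANKS))
  names(chosen) <- names(consistent) <- TAX_RANKS
  for (d in seq_along(TAX_RANKS)) {
    vals <- lin[!is.na(lin[, d]), d]
    if (length(vals) < min_annotated) next
    tab <- table(vals)
    top <- names(tab)[order(-tab, names(tab))][1]
    chosen[d] <- top
    consistent[d] <- (max(tab) >= consensus_frac * length(vals))
  }
  # top-down lineage coherence: child must co-occur with the chosen parent
  for (d in seq_along(TAX_RANKS)) {
    if (is.na(chosen[d])) { chosen[d:length(chosen)] <- NA; break }
    if (d > 1) {
      co <- !is.na(lin[, d]) & lin[, d] == chosen[d] &
        !is.na(lin[, d - 1]) & lin[, d - 1] == chosen[d - 1]
      if (!any(co)) { chosen[d:length(chosen)] <- NA; break }
    }
  }
  consistent[is.na(chosen)] <- NA
  list(lineage = lineage_validate(chosen), consistent = consistent)
}
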