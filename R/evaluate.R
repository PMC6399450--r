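# Align two named abundance vectors on the union of their taxa.
union_vectors <- function(truth, predicted) {
  taxa <- sort(union(names(truth), names(predicted)))
  t <- stats::setNames(rep(0, length(taxa)), taxa)
  p <- t
  t[names(truth)] <- truth
  p[names(predicted)] <- predicted
  list(truth = t, predicted = p, taxa = taxa)
}

#' Presence/absence precision and recall of a taxonomic profile
#'
#' True positives are taxa present (abundance above `presence_threshold`) in
#' both truth and prediction; false positives are predicted-only, false
#' negatives truth-only. Precision is `TP / (TP + FP)` (1 by convention when
#' nothing is predicted) and recall `TP / (TP + FN)`.
#'
#' @param truth,predicted Named numeric vectors of relative abundances.
#' @param presence_threshold Abundance above which a taxon counts as present
#'   (default 0).
#' @return List with `precision`, `recall`, `tp`, `fp`, `fn`.
#' @export
precision_recall <- function(truth, predicted, presence_threshold = 0) {
  ts <- names(truth)[truth > presence_threshold]
  ps <- names(predicted)[predicted > presence_threshold]
  tp <- length(intersect(ts, ps))
  fp <- length(setdiff(ps, ts))
  fn <- length(setdiff(ts, ps))
  list(precision = if (tp + fp == 0) 1 else tp / (tp + fp),
       recall = if (tp + fn == 0) 1 else tp / (tp + fn),
       tp = tp, fp = fp, fn = fn)
}

#' Mean absolute error between true and predicted relative abundances
#'
#' The mean over the union of taxa of the absolute difference between
#' predicted and true relative abundance. With `renormalize = TRUE` both
#' vectors are first re-scaled to sum to 1 over their detected (nonzero)
#' taxa — the convention of evaluation frameworks that cannot represent an
#' unknown fraction, which penalizes profilers that account for it.
#'
#' @param truth,predicted Named numeric vectors.
#' @param renormalize Re-scale each vector to sum 1 before comparing
#'   (default `FALSE`).
#' @return Mean absolute error.
#' @export
mae <- function(truth, predicted, renormalize = FALSE) {
  if (renormalize) {
    if (sum(truth) > 0) truth <- truth / sum(truth)
    if (sum(predicted) > 0) predicted <- predicted / sum(predicted)
  }
  v <- union_vectors(truth, predicted)
  mean(abs(v$predicted - v$truth))
}

#' Shannon diversity index of a profile
#'
#' `H' = -sum(p log p)` over the taxa with nonzero abundance, computed with
#' the natural logarithm after normalizing to relative abundances.
#'
#' @param profile Named or unnamed numeric vector of abundances.
#' @return Shannon index.
#' @export
shannon <- function(profile) {
  if (all(profile == 0)) stop("Shannon index of an all-zero profile")
  as.numeric(vegan::diversity(profile[profile > 0], index = "shannon"))
}

#' Distance between two taxonomic profiles
#'
#' Supported metrics: `log-euclidean` (Euclidean distance of log-transformed
#' relative abundances after adding a pseudocount of half the smallest
#' nonzero value across both profiles), `bray-curtis` and `canberra`.
#'
#' @param a,b Named numeric vectors on a shared taxon space.
#' @param metric One of `"log-euclidean"`, `"bray-curtis"`, `"canberra"`.
#' @return Distance (numeric scalar).
#' @export
profile_distance <- function(a, b,
                             metric = c("log-euclidean", "bray-curtis",
                                        "canberra")) {
  metric <- match.arg(metric)
  v <- union_vectors(a, b)
  m <- rbind(v$truth, v$predicted)
  if (metric == "log-euclidean") {
    nz <- m[m > 0]
    pseudo <- if (length(nz) > 0) 0.5 * min(nz) else 1
    return(sqrt(sum((log(m[1, ] + pseudo) - log(m[2, ] + pseudo))^2)))
  }
  idx <- if (metric == "bray-curtis") "bray" else "canberra"
  as.numeric(vegan::vegdist(m, method = idx))
}

#' Proportion of profiles whose nearest neighbour is their paired profile
#'
#' For paired profile sets (e.g. metagenomes and metatranscriptomes of the
#' same samples): the fraction of profiles in `set_a` whose closest profile
#' in `set_b` is the intended pair. Ties count as failures.
#'
#' @param set_a,set_b Named lists of named abundance vectors; names define
#'   the intended pairing (bijective).
#' @param metric Passed to [profile_distance()].
#' @return Fraction in `[0, 1]`.
#' @export
best_match_rate <- function(set_a, set_b, metric = "log-euclidean") {
  stopifnot(setequal(names(set_a), names(set_b)))
  hits <- vapply(names(set_a), function(s) {
    d <- vapply(names(set_b), function(t) {
      profile_distance(set_a[[s]], set_b[[t]], metric)
    }, numeric(1))
    sum(d < d[s]) == 0 && sum(d == d[s]) == 1
  }, logical(1))
  mean(hits)
}

#' AUROC separating intra- from inter-individual distances
#'
#' Quantifies the individuality of strain populations: the area under the
#' ROC curve for predicting "same individual" from a small distance, with a
#' bootstrap confidence interval obtained by resampling pairs.
#'
#' @param distances Numeric vector of pairwise distances.
#' @param same_individual Logical vector: `TRUE` for intra-individual pairs.
#' @param n_boot Bootstrap resamples for the CI (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed for the bootstrap.
#' @return List with `auroc`, `ci` (length-2 vector), `n_boot`, `seed`.
#' @export
individuality_auroc <- function(distances, same_individual, n_boot = 1000L,
                                conf = 0.95, seed = 1L) {
  stopifnot(length(distances) == length(same_individual))
  if (!any(same_individual) || all(same_individual)) {
    stop("need both intra- and inter-individual pairs")
  }
  auc <- rank_auc(-distances, same_individual)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(length(distances), replace = TRUE)
    if (!any(same_individual[idx]) || all(same_individual[idx])) {
      return(NA_real_)
    }
    rank_auc(-distances[idx], same_individual[idx])
  }, numeric(1))
  probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  list(auroc = auc,
       ci = as.numeric(stats::quantile(boots, probs, na.rm = TRUE)),
       n_boot = n_boot, seed = seed)
}

#' Quality score of a metagenome-assembled genome
#'
#' `QS = completeness - 5 x contamination`; MAGs with QS above 50 are
#' considered good quality.
#'
#' @param completeness,contamination Percentages in `[0, 100]`.
#' @return List with `qs` and `keep` (`QS > 50`).
#' @export
mag_quality <- function(completeness, contamination) {
  stopifnot(completeness >= 0, completeness <= 100,
            contamination >= 0, contamination <= 100)
  qs <- completeness - 5 * contamination
  list(qs = qs, keep = qs > 50)
}

#' Assign a MAG to a mOTU from its marker gene hits
#'
#' Marker genes extracted from a MAG are matched against the MGC database
#' (hits are expected to be pre-thresholded at identity >= 0.96 and query
#' coverage >= 0.7). Hits to unbinned MGCs are discarded; a MAG with fewer
#' than 3 mOTU-assigned hits is `UNASSIGNED`; otherwise it is assigned to
#' the mOTU matched by a strict majority (> 50%) of its hits, or flagged
#' `INCONSISTENT` when no majority exists.
#'
#' @param mgc_hits Character vector of matched MGC ids (one per MAG marker
#'   gene).
#' @param db A `motu_db`.
#' @return A mOTU id, `"UNASSIGNED"` or `"INCONSISTENT"`.
#' @export
assign_mag <- function(mgc_hits, db) {
  motu <- db$mgcs$motu_id[match(mgc_hits, db$mgcs$mgc_id)]
  motu <- motu[!is.na(motu) & motu != UNBINNED]
  if (length(motu) < 3) return("UNASSIGNED")
  tab <- table(motu)
  if (max(tab) > length(motu) / 2) {
    return(names(tab)[which.max(tab)])
  }
  "INCONSISTENT"
}
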