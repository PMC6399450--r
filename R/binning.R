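#' Biome-specific co-abundance correlation settings
#'
#' Default per-biome parameters for MGC co-abundance analysis: the prevalence
#' filter (minimum number of samples in which an MGC must be detected), the
#' abundance transform and the correlation measure.
#'
#' @format Named list of lists with `prevalence_min`, `transform`
#'   (`"raw"`/`"log"`) and `correlation` (`"pearson"`/`"spearman"`).
#' @export
BIOME_CONFIGS <- list(
  gut     = list(prevalence_min = 5L,  transform = "log", correlation = "pearson"),
  ocean   = list(prevalence_min = 5L,  transform = "raw", correlation = "pearson"),
  oral    = list(prevalence_min = 50L, transform = "raw", correlation = "pearson"),
  vaginal = list(prevalence_min = 5L,  transform = "log", correlation = "pearson"),
  skin    = list(prevalence_min = 10L, transform = "log", correlation = "spearman")
)

# canonical pair key (unordered)
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Pairwise MGC co-abundance correlations within one biome
#'
#' Columns are first converted to within-sample relative abundances; for the
#' `log` transform a pseudocount of half the smallest nonzero relative
#' abundance in the matrix is added before taking logs. MGCs detected
#' (abundance > 0) in fewer than `prevalence_min` samples are dropped, which
#' guards against spurious correlations between low-prevalence MGCs.
#'
#' @param mat Non-negative MGC x sample abundance matrix (rownames = MGC ids)
#'   restricted to the samples of one biome.
#' @param config List with `prevalence_min`, `transform`, `correlation`
#'   (see [BIOME_CONFIGS]).
#' @return data.frame with columns `a`, `b` (MGC ids, `a < b`) and `corr`.
#'   Empty (with a warning) when the biome has fewer than 3 samples.
#' @export
biome_correlations <- function(mat, config) {
  empty <- data.frame(a = character(0), b = character(0), corr = numeric(0))
  if (ncol(mat) < 3) {
    warning("fewer than 3 samples in biome; no correlations computed")
    return(empty)
  }
  prev <- rowSums(mat > 0)
  keep <- prev >= config$prevalence_min
  if (sum(keep) < 2) return(empty)
  totals <- colSums(mat)
  rel <- sweep(mat, 2, ifelse(totals > 0, totals, 1), "/")
  x <- rel[keep, , drop = FALSE]
  if (config$transform == "log") {
    nz <- rel[rel > 0]
    pseudo <- if (length(nz) > 0) 0.5 * min(nz) else 1
    x <- log(x + pseudo)
  }
  cm <- stats::cor(t(x), method = config$correlation)
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  data.frame(a = rownames(cm)[idx[, 1]], b = rownames(cm)[idx[, 2]],
             corr = cm[idx], stringsAsFactors = FALSE)
}

# Build the step function mapping a correlation to its FDR-calibrated
# association, from labelled reference pairs. labelled: data.frame with
# columns `corr` and `same` (logical: members of the same species cluster).
fdr_calibrator <- function(labelled) {
  if (is.null(labelled) || nrow(labelled) == 0) {
    stop("FDR calibration requires labelled reference pairs")
  }
  o <- order(-labelled$corr)
  c_sorted <- labelled$corr[o]
  cum_false <- cumsum(!labelled$same[o])
  r <- rle(c_sorted)
  ends <- cumsum(r$lengths)  # last index of each distinct threshold
  ths <- r$values            # descending
  n_tot <- ends
  n_false <- cum_false[ends]
  fdr <- n_false / n_tot
  # q-value monotonization: FDR non-increasing in the threshold
  q <- rev(cummin(rev(fdr)))
  asc <- rev(ths)
  n <- length(ths)
  function(corr) {
    j <- findInterval(corr, asc)  # count of thresholds <= corr
    idx <- ifelse(j == 0L, n, n - j + 1L)
    1 - q[idx]
  }
}

#' FDR-calibrate correlation values against labelled reference pairs
#'
#' Transforms raw correlations into an FDR-calibrated association in
#' `[0, 1]`, so that across biomes the same association value corresponds to
#' the same empirical false discovery rate. For a threshold t the FDR is the
#' fraction of labelled different-species pairs among labelled pairs with
#' correlation >= t, monotonized (non-increasing in t) with the standard
#' q-value construction; the calibrated association is `1 - FDR`.
#'
#' @param correlations Numeric vector of correlations to calibrate.
#' @param labelled data.frame with columns `corr` and `same` (logical) for
#'   reference MGC pairs whose species co-membership is known.
#' @return Numeric vector of calibrated associations, non-decreasing in the
#'   input correlation.
#' @export
fdr_calibrate <- function(correlations, labelled) {
  fdr_calibrator(labelled)(correlations)
}

#' Combine per-biome calibrated associations
#'
#' A pair's association is the maximum of its FDR-calibrated association
#' values across the biomes in which it survived prevalence filtering; pairs
#' surviving in no biome are absent.
#'
#' @param per_biome Named list of data.frames with columns `a`, `b`,
#'   `calibrated`.
#' @return data.frame with columns `a`, `b`, `calibrated`.
#' @export
combine_biomes <- function(per_biome) {
  all <- do.call(rbind, unname(per_biome))
  if (is.null(all) || nrow(all) == 0) {
    return(data.frame(a = character(0), b = character(0),
                      calibrated = numeric(0)))
  }
  key <- pair_key(all$a, all$b)
  best <- tapply(all$calibrated, key, max)
  first <- !duplicated(key)
  out <- data.frame(a = pmin(all$a, all$b)[first],
                    b = pmax(all$a, all$b)[first],
                    stringsAsFactors = FALSE)
  out$calibrated <- as.numeric(best[pair_key(out$a, out$b)])
  out[order(out$a, out$b), , drop = FALSE]
}

#' Greedy co-abundance binning of MGCs into mOTUs
#'
#' Starting from seed groups (reference MGCs grouped by their species
#' cluster), pairs are processed in order of decreasing calibrated
#' association (ties by pair id) down to `cutoff`. A merge is applied only
#' if the united group would still contain at most one MGC per COG type,
#' so seed groups are only ever extended, never split. Groups with at least
#' `min_size` MGCs become mOTUs; all other MGCs remain unbinned.
#'
#' @param associations data.frame with columns `a`, `b`, `calibrated`.
#' @param seed_groups Named list of character vectors (may be empty).
#' @param mgc_cogs Named character vector: MGC id -> COG type, covering every
#'   MGC under consideration.
#' @param cutoff Minimum calibrated association for a merge (default 0.8,
#'   i.e. stop once the empirical FDR exceeds 0.2).
#' @param min_size Minimum number of MGCs per retained group (default 6).
#' @return List with `motus` (named list of member id vectors) and
#'   `unbinned` (character vector).
#' @export
greedy_bin <- function(associations, seed_groups, mgc_cogs,
                       cutoff = 0.8, min_size = 6L) {
  ids <- names(mgc_cogs)
  parent <- stats::setNames(seq_along(ids), ids)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  cogs_of <- stats::setNames(as.list(unname(mgc_cogs)), ids)
  union_groups <- function(a, b) {
    ra <- find(match(a, ids)); rb <- find(match(b, ids))
    if (ra == rb) return(TRUE)
    ca <- cogs_of[[ra]]; cb <- cogs_of[[rb]]
    if (length(intersect(ca, cb)) > 0) return(FALSE)
    parent[rb] <<- ra
    cogs_of[[ra]] <<- c(ca, cb)
    TRUE
  }
  for (g in seed_groups) {
    g <- g[g %in% ids]
    if (length(g) > 1) for (m in g[-1]) union_groups(g[1], m)
  }
  a <- associations[associations$calibrated >= cutoff &
                      associations$a %in% ids & associations$b %in% ids, ,
                    drop = FALSE]
  if (nrow(a) > 0) {
    a <- a[order(-a$calibrated, pair_key(a$a, a$b)), , drop = FALSE]
    for (i in seq_len(nrow(a))) union_groups(a$a[i], a$b[i])
  }
  roots <- vapply(seq_along(ids), find, numeric(1))
  groups <- split(ids, roots)
  big <- lengths(groups) >= min_size
  motus <- unname(groups[big])
  motus <- lapply(motus, sort)
  motus <- motus[order(vapply(motus, `[`, character(1), 1))]
  names(motus) <- sprintf("bin_%03d", seq_along(motus))
  list(motus = motus, unbinned = sort(unlist(unname(groups[!big]),
                                             use.names = FALSE)))
}

# Rank-based (Mann-Whitney) AUROC of scores for a binary truth; higher
# scores should indicate the positive class. Ties get midranks.
rank_auc <- function(scores, truth) {
  np <- sum(truth); nn <- sum(!truth)
  if (np == 0 || nn == 0) stop("AUROC needs both classes")
  r <- rank(scores)
  (sum(r[truth]) - np * (np + 1) / 2) / (np * nn)
}

#' Cross-validated quality of the co-abundance binning signal
#'
#' Resampled k-fold cross-validation over the reference MGCs: in each fold
#' the held-out reference MGCs are stripped of their species labels and
#' treated as metagenomic MGCs; the calibration is rebuilt from the retained
#' labelled pairs and the held-out pairs are scored by their combined
#' calibrated association. Pair-level prediction of same-species membership
#' is summarized as an AUROC per resample.
#'
#' @param mats Named list of MGC x sample abundance matrices, one per biome
#'   (names must appear in `configs`).
#' @param seed_groups Named list: species cluster -> reference MGC ids.
#' @param configs Named list of biome configurations (default
#'   [BIOME_CONFIGS] subset by the names of `mats`).
#' @param folds Number of folds (default 5).
#' @param resamples Number of random fold assignments (default 100).
#' @param seed Integer seed for the fold assignments.
#' @return List with `auroc` (mean), `sd`, and `per_resample`.
#' @export
binning_cross_validation <- function(mats, seed_groups,
                                     configs = BIOME_CONFIGS[names(mats)],
                                     folds = 5L, resamples = 100L,
                                     seed = 1L) {
  if (length(seed_groups) < 2) stop("need at least 2 seed groups")
  ref_ids <- sort(unlist(seed_groups, use.names = FALSE))
  group_of <- stats::setNames(
    rep(names(seed_groups), lengths(seed_groups)),
    unlist(seed_groups, use.names = FALSE))

  # correlations do not depend on the fold split: compute once per biome
  corr_by_biome <- lapply(names(mats), function(bm) {
    biome_correlations(mats[[bm]], configs[[bm]])
  })
  names(corr_by_biome) <- names(mats)

  score_heldout <- function(held) {
    kept <- setdiff(ref_ids, held)
    per_biome <- lapply(corr_by_biome, function(cb) {
      lab_idx <- cb$a %in% kept & cb$b %in% kept
      if (!any(lab_idx)) return(NULL)
      labelled <- data.frame(
        corr = cb$corr[lab_idx],
        same = group_of[cb$a[lab_idx]] == group_of[cb$b[lab_idx]])
      ho <- cb$a %in% held & cb$b %in% held  # only held-out pairs are scored
      if (!any(ho)) return(NULL)
      data.frame(a = cb$a[ho], b = cb$b[ho],
                 calibrated = fdr_calibrate(cb$corr[ho], labelled))
    })
    comb <- combine_biomes(Filter(Negate(is.null), per_biome))
    hpairs <- t(utils::combn(sort(held), 2))
    key <- pair_key(hpairs[, 1], hpairs[, 2])
    sc <- stats::setNames(comb$calibrated, pair_key(comb$a, comb$b))[key]
    sc[is.na(sc)] <- 0  # filtered everywhere: no co-abundance evidence
    data.frame(score = as.numeric(sc),
               truth = group_of[hpairs[, 1]] == group_of[hpairs[, 2]])
  }

  set.seed(seed)
  per_resample <- vapply(seq_len(resamples), function(r) {
    fold <- sample(rep_len(seq_len(folds), length(ref_ids)))
    scored <- do.call(rbind, lapply(seq_len(folds), function(f) {
      held <- ref_ids[fold == f]
      if (length(held) < 2) return(NULL)
      score_heldout(held)
    }))
    rank_auc(scored$score, scored$truth)
  }, numeric(1))
  list(auroc = mean(per_resample), sd = stats::sd(per_resample),
       per_resample = per_resample)
}
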