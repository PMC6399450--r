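test_that("biome correlations apply prevalence filtering and transforms", {
  m <- rbind(x = c(1, 2, 3, 4, 5, 6),
             y = c(2, 4, 6, 8, 10, 12),
             rare = c(5, 0, 0, 0, 0, 0))
  colnames(m) <- paste0("s", 1:6)
  cfg <- list(prevalence_min = 5L, transform = "log",
              correlation = "pearson")
  cb <- biome_correlations(m, cfg)
  # proportional rows correlate perfectly; the rare MGC is filtered out
  expect_equal(cb$corr[cb$a == "x" & cb$b == "y"], 1.0, tolerance = 1e-9)
  expect_false("rare" %in% c(cb$a, cb$b))
  # anti-correlated vectors under raw pearson
  m2 <- rbind(p = c(1, 2, 3, 4), q = c(4, 3, 2, 1))
  colnames(m2) <- paste0("s", 1:4)
  # columns are re-normalized to relative abundance first, which here makes
  # the two rows exact mirrors
  cb2 <- biome_correlations(
    m2, list(prevalence_min = 1L, transform = "raw",
             correlation = "pearson"))
  expect_equal(cb2$corr, -1, tolerance = 1e-9)
  expect_warning(
    out <- biome_correlations(m[, 1:2], cfg), "fewer than 3")
  expect_equal(nrow(out), 0L)
})

test_that("FDR calibration reproduces the empirical false discovery rate", {
  lab <- data.frame(corr = c(rep(0.9, 9), 0.95),
                    same = c(rep(TRUE, 9), FALSE))
  expect_equal(fdr_calibrate(0.85, lab), 0.9)
  # only true pairs at or above the query correlation
  lab2 <- data.frame(corr = c(0.99, 0.98, 0.5), same = c(TRUE, TRUE, FALSE))
  expect_equal(fdr_calibrate(0.98, lab2), 1.0)
  # calibrated association is non-decreasing in the correlation
  set.seed(14)
  lab3 <- data.frame(corr = stats::runif(200, -1, 1),
                     same = sample(c(TRUE, FALSE), 200, TRUE))
  x <- sort(stats::runif(50, -1, 1))
  cal <- fdr_calibrate(x, lab3)
  expect_true(all(diff(cal) >= -1e-12))
  expect_error(fdr_calibrate(0.5, lab3[0, ]), "labelled")
})

test_that("cross-biome combination takes the maximum calibrated value", {
  gut <- data.frame(a = c("m1", "m1"), b = c("m2", "m3"),
                    calibrated = c(0.85, 0.7))
  ocean <- data.frame(a = "m1", b = "m2", calibrated = 0.95)
  comb <- combine_biomes(list(gut = gut, ocean = ocean))
  expect_equal(comb$calibrated[comb$a == "m1" & comb$b == "m2"], 0.95)
  expect_equal(comb$calibrated[comb$a == "m1" & comb$b == "m3"], 0.7)
  expect_equal(nrow(comb), 2L)  # pairs filtered everywhere are absent
})

test_that("greedy binning respects the one-MGC-per-COG constraint", {
  cogs <- stats::setNames(c(MG_COGS[1:6], MG_COGS[1], MG_COGS[1:2]),
                          c(paste0("c", 1:6), "dup1", "s1", "s2"))
  # chain of 6 MGCs with distinct COGs binds into one mOTU
  chain <- data.frame(a = paste0("c", 1:5), b = paste0("c", 2:6),
                      calibrated = seq(0.99, 0.95, length.out = 5))
  res <- greedy_bin(chain, list(), cogs, cutoff = 0.8, min_size = 6)
  expect_length(res$motus, 1)
  expect_setequal(res$motus[[1]], paste0("c", 1:6))
  # same-COG pairs are never merged, no matter the association
  clash <- rbind(chain, data.frame(a = "c1", b = "dup1", calibrated = 0.999))
  res2 <- greedy_bin(clash, list(), cogs, cutoff = 0.8, min_size = 6)
  expect_false("dup1" %in% unlist(res2$motus))
  # groups below min_size stay unbinned
  small <- data.frame(a = "s1", b = "s2", calibrated = 0.99)
  res3 <- greedy_bin(small, list(), cogs, cutoff = 0.8, min_size = 6)
  expect_true(all(c("s1", "s2") %in% res3$unbinned))
  # associations below the cutoff are ignored
  weak <- data.frame(a = paste0("c", 1:5), b = paste0("c", 2:6),
                     calibrated = rep(0.79, 5))
  expect_length(greedy_bin(weak, list(), cogs, 0.8, 6)$motus, 0)
})

test_that("seed groups are extended but never split", {
  sim <- small_sim()
  co <- simulate_coabundance(sim, n_samples = 25, noise_sd = 0.1, seed = 6)
  cb <- biome_correlations(co$matrix, BIOME_CONFIGS$gut)
  ref <- unlist(co$seed_groups, use.names = FALSE)
  lab <- cb$a %in% ref & cb$b %in% ref
  labelled <- data.frame(
    corr = cb$corr[lab],
    same = co$mgc_species[cb$a[lab]] == co$mgc_species[cb$b[lab]])
  assoc <- data.frame(a = cb$a, b = cb$b,
                      calibrated = fdr_calibrate(cb$corr, labelled))
  cogs <- stats::setNames(sim$db$mgcs$cog, sim$db$mgcs$mgc_id)
  res <- greedy_bin(assoc, co$seed_groups, cogs)
  memb <- rep(names(res$motus), lengths(res$motus))
  names(memb) <- unlist(res$motus)
  for (g in co$seed_groups) {
    expect_length(unique(memb[g]), 1)
  }
  # invariant: no group carries two MGCs of one COG
  for (grp in res$motus) {
    expect_false(anyDuplicated(cogs[grp]) > 0)
  }
})

test_that("cross-validation is deterministic given the seed", {
  sim <- small_sim()
  co <- simulate_coabundance(sim, n_samples = 20, noise_sd = 0.15, seed = 9)
  cv1 <- binning_cross_validation(list(gut = co$matrix), co$seed_groups,
                                  resamples = 5, seed = 11)
  cv2 <- binning_cross_validation(list(gut = co$matrix), co$seed_groups,
                                  resamples = 5, seed = 11)
  expect_identical(cv1$per_resample, cv2$per_resample)
  expect_error(binning_cross_validation(list(gut = co$matrix),
                                        co$seed_groups[1]),
               "at least 2")
})
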