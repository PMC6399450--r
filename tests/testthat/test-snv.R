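test_that("pileup counts bases per coding position from unique inserts", {
  db <- toy_db()
  ref <- as.character(db$seqs[["mgA1"]])
  # 5 identical perfect reads covering positions 0..99
  rec <- make_records(sprintf("i%d", 1:5), 0L, rep("mgA1", 5), rep(60, 5),
                      aligned_bases = 100L, seq = substr(ref, 1, 100))
  asg <- assign_inserts(rec, db)
  pu <- pileup(unique_records(rec, asg), db)
  expect_equal(nrow(pu), 100L)
  expect_true(all(pu$depth == 5L))
  refb <- strsplit(substr(ref, 1, 100), "")[[1]]
  for (b in c("A", "C", "G", "T")) {
    expect_equal(pu[[b]], ifelse(refb == b, 5L, 0L))
  }
  # one read with a substitution at coding position 10
  mut <- refb
  mut[11] <- setdiff(c("A", "C", "G", "T"), mut[11])[1]
  rec2 <- rbind(rec, make_records("i6", 0L, "mgA1", 60,
                                  aligned_bases = 100L,
                                  seq = paste(mut, collapse = "")))
  pu2 <- pileup(unique_records(rec2, assign_inserts(rec2, db)), db)
  row10 <- pu2[pu2$pos == 10L, ]
  expect_equal(row10$depth, 6L)
  expect_equal(row10[[refb[11]]], 5L)
  expect_equal(row10[[mut[11]]], 1L)
})

test_that("multiple-flagged inserts contribute nothing to the pileup", {
  db <- toy_db()
  rec <- make_records(c("m", "m"), c(1L, 1L), c("mgA1", "mgB1"), c(60, 60),
                      aligned_bases = 100L)
  asg <- assign_inserts(rec, db)
  expect_equal(nrow(pileup(unique_records(rec, asg), db)), 0L)
})

test_that("padding is excluded and out-of-bounds alignments error", {
  sim <- small_sim()  # padded genes: coding span [50, 800) of 850
  mg <- sim$db$genes$mg_id[1]
  ref <- as.character(sim$db$seqs[[mg]])
  # read covering the first 100 reference positions: 50 are padding
  rec <- make_records("i1", 0L, mg, 60, aligned_bases = 100L,
                      seq = substr(ref, 1, 100))
  pu <- pileup(rec, sim$db)
  expect_equal(nrow(pu), 50L)
  expect_equal(range(pu$pos), c(0L, 49L))
  bad <- make_records("i2", 0L, mg, 60, aligned_bases = 100L,
                      pos = 10000L, seq = substr(ref, 1, 100))
  expect_error(pileup(bad, sim$db), "beyond reference")
})

test_that("coverage summary reports horizontal percent and mean depth", {
  db <- toy_db()  # motuA: 6 centroids x 200 nt = 1200 positions
  pu <- rbind(pileup_for(db, "mgA1", 0:169, depth = 10),
              pileup_for(db, "mgA2", 0:199, depth = 10))
  cs <- coverage_summary(list(s1 = pu), db)
  a <- cs[cs$motu_id == "motuA" & cs$sample_id == "s1", ]
  expect_equal(a$horizontal, 100 * 370 / 1200)
  expect_equal(a$vertical, 10 * 370 / 1200)
  b <- cs[cs$motu_id == "motuB" & cs$sample_id == "s1", ]
  expect_equal(b$horizontal, 0)
  expect_equal(b$vertical, 0)
})

test_that("the filter cascade applies fb, fd, fm, fc and fp", {
  db <- toy_db()
  full <- motuA_pileup(db, depth = 10)
  low <- motuA_pileup(db, depth = 10, frac = 0.79)
  # sample below fb = 80% horizontal coverage is dropped
  tab <- call_and_filter(list(s1 = full, s2 = full, s3 = low), db,
                         snv_params())
  expect_setequal(unique(tab$retained$sample_id[
    tab$retained$motu_id == "motuA"]), c("s1", "s2"))
  # a mOTU with a single retained sample is dropped by fm = 2
  tab2 <- call_and_filter(list(s1 = full, s2 = low), db, snv_params())
  expect_equal(nrow(tab2$rows), 0L)
  # fd: shallow but complete coverage fails the vertical filter
  shallow <- motuA_pileup(db, depth = 4)
  tab3 <- call_and_filter(list(s1 = shallow, s2 = shallow), db,
                          snv_params())
  expect_equal(nrow(tab3$retained), 0L)
})

test_that("position retention honours fc depth in an fp fraction of samples", {
  db <- toy_db()
  # 10 samples; one SNV position with depth >= 5 in 9 of 10 -> 0.9 >= fp
  mk <- function(dp_at_snv) {
    pu <- motuA_pileup(db, depth = 10)
    i <- which(pu$mg_id == "mgA1" & pu$pos == 7L)
    ref <- c("A", "C", "G", "T")[which.max(pu[i, c("A", "C", "G", "T")])]
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    pu[i, ref] <- dp_at_snv - min(3L, dp_at_snv)
    pu[i, alt] <- min(3L, dp_at_snv)
    pu$depth <- pu$A + pu$C + pu$G + pu$T
    pu
  }
  pus <- c(lapply(1:9, function(i) mk(10L)), list(mk(4L)))
  names(pus) <- sprintf("s%02d", 1:10)
  tab <- call_and_filter(pus, db, snv_params())
  hit <- tab$rows$mg_id == "mgA1" & tab$rows$pos == 7L
  expect_true(any(hit))
  # the low-depth sample is missing (NA) at that position
  expect_true(is.na(tab$freq[which(hit), "s10"]))
  expect_equal(unname(tab$freq[which(hit), "s01"]), 0.3)
  # with one more failing sample the proportion drops below fp = 0.9
  pus2 <- c(lapply(1:8, function(i) mk(10L)),
            list(mk(4L), mk(4L)))
  names(pus2) <- sprintf("s%02d", 1:10)
  tab2 <- call_and_filter(pus2, db, snv_params())
  expect_false(any(tab2$rows$mg_id == "mgA1" & tab2$rows$pos == 7L))
})

test_that("tightening any filter never adds SNV rows", {
  db <- toy_db()
  set.seed(61)
  mk_noisy <- function() {
    pu <- motuA_pileup(db, depth = sample(6:12, 1),
                       frac = stats::runif(1, 0.85, 1))
    idx <- sample(nrow(pu), 40)
    for (i in idx) {
      ref <- c("A", "C", "G", "T")[which.max(pu[i, c("A", "C", "G", "T")])]
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      k <- sample(0:3, 1)
      pu[i, ref] <- pu[i, ref] - k
      pu[i, alt] <- pu[i, alt] + k
    }
    pu$depth <- pu$A + pu$C + pu$G + pu$T
    pu
  }
  pus <- lapply(1:6, function(i) mk_noisy())
  names(pus) <- sprintf("s%d", 1:6)
  base <- nrow(call_and_filter(pus, db, snv_params())$rows)
  tighter <- list(snv_params(fb = 95), snv_params(fd = 8),
                  snv_params(fm = 5), snv_params(fc = 8),
                  snv_params(fp = 1), snv_params(min_alt = 4))
  for (p in tighter) {
    expect_lte(nrow(call_and_filter(pus, db, p)$rows), base)
  }
})

test_that("SNV distances match hand-computed values", {
  tab <- structure(list(
    rows = data.frame(motu_id = c("m", "m"), mg_id = c("g", "g"),
                      pos = c(1L, 2L), ref = c("A", "A"),
                      alt = c("C", "C")),
    freq = matrix(c(0.8, 0.2, 0.1, 0.1), nrow = 2,
                  dimnames = list(NULL, c("s1", "s2"))),
    retained = data.frame(motu_id = c("m", "m"),
                          sample_id = c("s1", "s2"))),
    class = "snv_table")
  d <- snv_distances(tab)$m
  # diffs {0.7, 0.1}: manhattan 0.8; one of two positions above 0.5
  expect_equal(d$manhattan["s1", "s2"], 0.8)
  expect_equal(d$major_allele["s1", "s2"], 0.5)
  expect_equal(diag(d$manhattan), c(s1 = 0, s2 = 0))
  # identical vectors -> zero distances
  tab$freq <- matrix(c(0.3, 0.6, 0.3, 0.6), nrow = 2,
                     dimnames = list(NULL, c("s1", "s2")))
  d2 <- snv_distances(tab)$m
  expect_equal(d2$manhattan["s1", "s2"], 0)
  expect_equal(d2$major_allele["s1", "s2"], 0)
  # maximally different frequencies
  tab$freq <- matrix(c(0, 1, 1, 0), nrow = 2,
                     dimnames = list(NULL, c("s1", "s2")))
  expect_equal(snv_distances(tab)$m$manhattan["s1", "s2"], 2)
  # missing cells are excluded pairwise; no shared positions -> NA
  tab$freq <- matrix(c(NA, 0.5, 0.5, NA), nrow = 2,
                     dimnames = list(NULL, c("s1", "s2")))
  expect_true(is.na(snv_distances(tab)$m$manhattan["s1", "s2"]))
})

test_that("snv output files follow the documented layout", {
  db <- toy_db()
  pus <- list(s1 = motuA_pileup(db, 10), s2 = motuA_pileup(db, 10))
  # plant one real SNV
  i <- which(pus$s1$mg_id == "mgA1" & pus$s1$pos == 3L)
  ref <- c("A", "C", "G", "T")[which.max(pus$s1[i, c("A", "C", "G", "T")])]
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  pus$s1[i, ref] <- 6L; pus$s1[i, alt] <- 4L
  tab <- call_and_filter(pus, db, snv_params())
  out <- tempfile("snvout")
  write_snv_results(tab, out)
  expect_true(file.exists(file.path(out, "snv.cov.tab")))
  expect_true(file.exists(file.path(out, "snv.perc.tab")))
  expect_true(file.exists(file.path(out, "snv.log")))
  expect_true(file.exists(file.path(out, "filtered-snv", "motuA.freq.tab")))
  expect_true(file.exists(file.path(out, "distances-snv",
                                    "motuA.mann.dist")))
  expect_true(file.exists(file.path(out, "distances-snv",
                                    "motuA.allele.dist")))
})
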