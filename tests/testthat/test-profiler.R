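test_that("alignment filter applies the identity and length thresholds", {
  lines <- c(
    sam_line("r97", 0, "mgA1", 1, "100M", dna(100), "NM:i:3\tAS:i:94"),
    sam_line("r74", 0, "mgA1", 1, "74M", dna(74), "NM:i:0\tAS:i:74"),
    sam_line("r96", 0, "mgA1", 1, "100M", dna(100), "NM:i:4\tAS:i:92"),
    sam_line("rclip", 0, "mgA1", 1, "20S100M", dna(120), "NM:i:0\tAS:i:100"))
  rec <- parse_and_filter(write_sam_text(lines), 0.97, 75L)
  expect_setequal(rec$insert_id, c("r97", "rclip"))
  expect_equal(rec$identity[rec$insert_id == "r97"], 0.97)
  # soft clips do not count toward the aligned length
  expect_equal(rec$aligned_length[rec$insert_id == "rclip"], 100L)
  # thresholds are inclusive
  rec2 <- parse_and_filter(write_sam_text(lines), 0.97, 74L)
  expect_true("r74" %in% rec2$insert_id)
})

test_that("edit distance falls back to MD when NM is absent", {
  lines <- c(
    sam_line("rmd", 0, "mgA1", 1, "100M", dna(100), "MD:Z:50A49"),
    sam_line("rmd2", 0, "mgA1", 1, "100M", dna(100), "MD:Z:10A5C83"))
  rec <- parse_and_filter(write_sam_text(lines), 0.9, 50L)
  expect_equal(rec$nm[rec$insert_id == "rmd"], 1L)
  expect_equal(rec$nm[rec$insert_id == "rmd2"], 2L)
  # AS absent: score falls back to aligned_length - 2 * NM
  expect_equal(rec$score[rec$insert_id == "rmd"], 98)
  bad <- sam_line("rbad", 0, "mgA1", 1, "100M", dna(100), "XX:i:1")
  expect_error(parse_and_filter(write_sam_text(bad)), "rbad")
})

test_that("mates are identified from SAM flags", {
  lines <- c(
    sam_line("p1", 99, "mgA1", 1, "100M", dna(100)),
    sam_line("p1", 147, "mgA1", 50, "100M", dna(100)),
    sam_line("s1", 0, "mgA1", 1, "100M", dna(100)))
  rec <- parse_and_filter(write_sam_text(lines), 0.9, 50L)
  expect_equal(sort(rec$mate[rec$insert_id == "p1"]), c(1L, 2L))
  expect_equal(rec$mate[rec$insert_id == "s1"], 0L)
})

test_that("insert assignment aggregates mate scores at the MGC level", {
  db <- toy_db()
  # mate1->MGC_A1 60, mate2->MGC_A1 60, mate1->MGC_B1 50 -> unique to A1
  rec <- make_records(c("i1", "i1", "i1"), c(1L, 2L, 1L),
                      c("mgA1", "mgA1", "mgB1"), c(60, 60, 50))
  a <- assign_inserts(rec, db)
  expect_equal(nrow(a), 1L)
  expect_equal(a$mgc_id, "MGC_A1")
  expect_equal(a$flag, "unique")
  expect_equal(a$insert_score, 120)

  # equal best score to two MGCs -> multiple with both targets
  rec2 <- make_records(c("i2", "i2"), c(1L, 1L), c("mgA1", "mgB1"),
                       c(70, 70))
  a2 <- assign_inserts(rec2, db)
  expect_equal(nrow(a2), 2L)
  expect_setequal(a2$mgc_id, c("MGC_A1", "MGC_B1"))
  expect_true(all(a2$flag == "multiple"))

  # both mates on one MGC sum to a single target; within a (mate, MGC)
  # pair only the best alignment counts
  rec3 <- make_records(c("i3", "i3", "i3"), c(1L, 2L, 2L),
                       c("mgA1", "mgA1", "mgA1"), c(50, 55, 40))
  a3 <- assign_inserts(rec3, db)
  expect_equal(a3$flag, "unique")
  expect_equal(a3$insert_score, 105)

  # single-end read with one hit -> unique
  a4 <- assign_inserts(make_records("s", 0L, "mgA1", 80), db)
  expect_equal(a4$flag, "unique")
})

test_that("multi-mapper redistribution follows the unique profile", {
  # uniques A=3, B=1; 4 inserts best to {A,B} -> A=6, B=2
  a <- make_assignments(
    c("u1", "u2", "u3", "u4",
      rep(c("m1", "m2", "m3", "m4"), each = 2)),
    c("A", "A", "A", "B",
      rep(c("A", "B"), times = 4)))
  counts <- mgc_insert_counts(a)
  expect_equal(counts[["A"]], 6)
  expect_equal(counts[["B"]], 2)

  # no multiples: counts equal the unique profile
  a2 <- make_assignments(c("u1", "u2"), c("A", "B"))
  expect_equal(sort(mgc_insert_counts(a2)), c(A = 1, B = 1))

  # all-zero unique support splits uniformly
  a3 <- make_assignments(c("m", "m"), c("A", "B"))
  expect_equal(unname(mgc_insert_counts(a3)), c(0.5, 0.5))
})

test_that("redistribution matches the brute-force oracle and conserves mass", {
  set.seed(20)
  for (k in 1:60) {
    a <- random_assignment_instance()
    counts <- mgc_insert_counts(a)
    oracle <- oracle_insert_counts(a)
    expect_equal(counts[names(oracle)], oracle, tolerance = 1e-12)
    expect_equal(sum(counts), length(unique(a$insert_id)),
                 tolerance = 1e-12)
  }
})

test_that("base coverage divides aligned bases by centroid coding length", {
  db <- toy_db()  # coding length 200
  # 10 unique inserts x 100 aligned bases on MGC_A1 -> coverage 5
  rec <- make_records(sprintf("i%02d", 1:10), 0L, rep("mgA1", 10),
                      rep(60, 10), aligned_bases = 100L)
  a <- assign_inserts(rec, db)
  cov <- mgc_base_coverage(rec, a, db)
  expect_equal(cov[["MGC_A1"]], 10 * 100 / 200)
  # linearity: doubling the alignments doubles coverage
  rec2 <- rbind(rec, make_records(sprintf("j%02d", 1:10), 0L,
                                  rep("mgA1", 10), rep(60, 10),
                                  aligned_bases = 100L))
  cov2 <- mgc_base_coverage(rec2, assign_inserts(rec2, db), db)
  expect_equal(cov2[["MGC_A1"]], 2 * cov[["MGC_A1"]])
  # no alignments -> empty coverage
  expect_length(mgc_base_coverage(rec[0, ], a[0, ], db), 0)
})

test_that("mOTU abundance is the median of detected MGCs above -g", {
  db <- toy_db()
  vals <- c(MGC_A1 = 2, MGC_A2 = 4, MGC_A3 = 6)  # 3 detected of 6 slots
  p <- motu_profile(vals, db, min_mgcs = 3, unit = "base.coverage")
  expect_equal(p$motu_values[["motuA"]], 4)
  expect_equal(p$motu_values[["motuB"]], 0)
  # below the detection threshold the mOTU is zeroed
  p2 <- motu_profile(vals[1:2], db, min_mgcs = 3, unit = "base.coverage")
  expect_equal(p2$motu_values[["motuA"]], 0)
  # all-slot median alternative
  p3 <- motu_profile(vals, db, min_mgcs = 3, unit = "base.coverage",
                     detected_only = FALSE)
  expect_equal(p3$motu_values[["motuA"]], 1)  # median of {2,4,6,0,0,0}
})

test_that("the unbinned row is the median of per-COG sums", {
  db <- toy_db()  # unbinned: MGC_U1 (COG0012), MGC_U2 (COG0016)
  p <- motu_profile(c(MGC_U1 = 30, MGC_U2 = 10), db, 3, "base.coverage")
  # COG sums: {30, 10, 0 x 8} -> median 0
  expect_equal(p$motu_values[["-1"]], 0)
  sim <- small_sim()  # one whole unbinned species: all 10 COGs populated
  unb <- sim$db$mgcs$mgc_id[sim$db$mgcs$motu_id == "-1"]
  v <- stats::setNames(seq(10, 100, by = 10), unb)
  p2 <- motu_profile(v, sim$db, 3, "base.coverage")
  expect_equal(p2$motu_values[["-1"]], stats::median(seq(10, 100, 10)))
  # all-zero unbinned -> 0
  p3 <- motu_profile(c(MGC_A1 = 5), db, 1, "base.coverage")
  expect_equal(p3$motu_values[["-1"]], 0)
})

test_that("raw counts are rounded half away from zero", {
  db <- toy_db()
  vals <- c(MGC_A1 = 2.5, MGC_A2 = 2.5, MGC_A3 = 2.5)
  p <- motu_profile(vals, db, 3, "insert.raw_counts")
  expect_equal(p$motu_values[["motuA"]], 3)
  expect_equal(unname(p$mgc_values["MGC_A1"]), 3)
})

test_that("scaled counts preserve proportions and total inserts", {
  db <- toy_db()
  p <- motu_profile(c(MGC_A1 = 2, MGC_A2 = 2, MGC_A3 = 2,
                      MGC_B1 = 6, MGC_B2 = 6, MGC_B3 = 6),
                    db, 3, "base.coverage")
  sc <- scale_counts(p, 40)
  expect_equal(sc$motu_values[["motuA"]], 10)
  expect_equal(sc$motu_values[["motuB"]], 30)
  expect_equal(sum(sc$motu_values), 40)
  # all-zero coverage with zero inserts -> all zero
  p0 <- motu_profile(numeric(0), db, 3, "base.coverage")
  expect_equal(sum(scale_counts(p0, 0)$motu_values), 0)
  # inconsistent inputs are an error
  expect_error(scale_counts(p0, 10), "zero total coverage")
  expect_error(scale_counts(sc, 40), "base.coverage")
})

test_that("relative abundance handles the unbinned row per flag", {
  db <- toy_db()
  p <- motu_profile(c(MGC_A1 = 2, MGC_A2 = 2, MGC_A3 = 2,
                      MGC_U1 = 30, MGC_U2 = 30), db, 3, "base.coverage")
  p$motu_values <- c(motuA = 30, motuB = 10, "-1" = 60)
  incl <- relative_abundance(p, include_unbinned = TRUE)
  expect_equal(unname(incl[c("motuA", "motuB", "-1")]), c(0.3, 0.1, 0.6))
  excl <- relative_abundance(p, include_unbinned = FALSE)
  expect_equal(unname(excl[c("motuA", "motuB")]), c(0.75, 0.25))
  # with a zero unbinned row both conventions coincide
  p$motu_values <- c(motuA = 30, motuB = 10, "-1" = 0)
  expect_equal(relative_abundance(p, FALSE),
               relative_abundance(p, TRUE)[c("motuA", "motuB")])
})

test_that("tightening filters never increases unique counts or totals", {
  sim <- small_sim()
  ab <- simulate_abundances(sim, seed = 3)
  s <- simulate_sample(sim, ab, n_inserts = 3000, seed = 4)
  at <- function(l, min_id = 0.97) {
    rec <- parse_and_filter(s$sam, min_id, l)
    asg <- assign_inserts(rec, sim$db)
    u <- table(asg$mgc_id[asg$flag == "unique"])
    list(unique = u, total = length(unique(asg$insert_id)),
         counts = mgc_insert_counts(asg))
  }
  loose <- at(75L)
  for (l in c(100L, 140L)) {
    tight <- at(l)
    # the unique-alignment profile shrinks monotonically per MGC ...
    common <- intersect(names(tight$unique), names(loose$unique))
    expect_true(all(tight$unique[common] <= loose$unique[common]))
    expect_length(setdiff(names(tight$unique), names(loose$unique)), 0)
    # ... and so does the total assigned insert mass
    expect_lte(tight$total, loose$total)
    expect_lte(sum(tight$counts), sum(loose$counts) + 1e-9)
  }
})
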