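test_that("levenshtein follows the recursive definition and matches adist", {
  expect_equal(levenshtein("", "ACG"), 3)
  expect_equal(levenshtein("ACG", ""), 3)
  expect_equal(levenshtein("", ""), 0)
  expect_equal(levenshtein("ACGT", "ACGT"), 0)
  expect_equal(levenshtein("GGTC", "GTTC"), 1)
  set.seed(101)
  for (i in 1:60) {
    a <- rand_dna(sample(0:12, 1))
    b <- rand_dna(sample(0:12, 1))
    expect_equal(levenshtein(a, b), as.integer(adist(a, b)))
    expect_equal(levenshtein(a, b), levenshtein(b, a))  # symmetry
    expect_equal(levenshtein(a, a), 0)
  }
  # triangle inequality on random triples
  for (i in 1:30) {
    a <- rand_dna(sample(1:10, 1)); b <- rand_dna(sample(1:10, 1))
    c <- rand_dna(sample(1:10, 1))
    expect_lte(levenshtein(a, c), levenshtein(a, b) + levenshtein(b, c))
  }
})

test_that("build_pattern computes mismatch position sets with IUPAC semantics", {
  p <- build_pattern("ACGT")
  expect_equal(p$mismatch_masks$A, c(1L, 2L, 3L))
  expect_equal(p$mismatch_masks$C, c(0L, 2L, 3L))
  expect_equal(p$mismatch_masks$G, c(0L, 1L, 3L))
  expect_equal(p$mismatch_masks$T, c(0L, 1L, 2L))
  # plain-ACGT pattern: position absent from mask[c] iff pattern[i] == c
  expect_equal(p$mismatch_masks$N, 0:3)  # read N mismatches non-N positions
  pn <- build_pattern("NNNN")
  for (b in c("A", "C", "G", "T", "N"))
    expect_equal(pn$mismatch_masks[[b]], integer(0))
  # degenerate codes: R = A or G
  pr <- build_pattern("RC")
  expect_false(0L %in% pr$mismatch_masks$A)
  expect_false(0L %in% pr$mismatch_masks$G)
  expect_true(0L %in% pr$mismatch_masks$C)
  expect_error(build_pattern(""), "non-empty")
  expect_error(build_pattern("ACXG"), "IUPAC")
})

test_that("oracle_find enumerates full hits and suffix overlaps", {
  p0 <- search_params(max_differences = 0)
  hits <- oracle_find("TTACGTTT", "ACGT", p0)
  full <- hits[hits$matched_pattern_length == 4, ]
  expect_equal(nrow(full), 1L)
  expect_equal(full$end, 6L)
  expect_equal(full$start, 2L)
  expect_equal(full$differences, 0L)

  hits <- oracle_find("ACGT", "ACGT", p0)
  expect_equal(nrow(hits), 1L)
  expect_equal(c(hits$start, hits$end), c(0L, 4L))

  p1 <- search_params(max_differences = 1)
  hits <- oracle_find("TTACTTTT", "ACGT", p1)
  expect_true(any(hits$differences == 1 & hits$matched_pattern_length == 4))

  # suffix overlap: read ends with a 5 nt exact prefix of the pattern
  rd <- paste0(rand_dna(20), "ACGTA")
  hits <- find_matches(rd, "ACGTACGG", search_params(error_ratio = 0.1))
  ov <- hits[hits$matched_pattern_length < 8, ]
  expect_true(any(ov$start == 20 & ov$end == 25 & ov$differences == 0))
})

test_that("cutoff search equals the full-matrix oracle on random instances", {
  set.seed(202)
  for (i in 1:300) {
    inst <- rand_instance()
    a <- find_matches(inst$read, inst$pattern, inst$params)
    b <- oracle_find(inst$read, inst$pattern, inst$params)
    expect_identical(candidate_key(a), candidate_key(b))
  }
})

test_that("degenerate and trivial inputs behave", {
  expect_equal(nrow(find_matches("TTTT", "CCCC",
                                 search_params(max_differences = 0))), 0L)
  hit <- find_matches("ACGTACG", "ACGTACG",
                      search_params(max_differences = 0))
  full <- hit[hit$matched_pattern_length == 7, ]
  expect_equal(nrow(full), 1L)
  expect_equal(c(full$start, full$end, full$differences), c(0L, 7L, 0L))
  expect_error(find_matches("", "ACGT"), "non-empty")
})

test_that("structural properties of the DP matrix hold", {
  set.seed(303)
  for (i in 1:40) {
    inst <- rand_instance(max_m = 10L, max_n = 50L)
    om <- oracle_matrix(inst$read, inst$pattern, inst$params)
    C <- om$C
    nr <- nrow(C); nc <- ncol(C)
    # Lemma: values along every diagonal are monotonically non-decreasing
    for (d in (-(nr - 2)):(nc - 2)) {
      i0 <- max(1L, 1L - d); j0 <- i0 + d
      len <- min(nr - i0, nc - j0)
      if (len < 1) next
      vals <- C[cbind(i0 + 0:len, j0 + 0:len)]
      expect_true(all(diff(vals) >= 0))
    }
    # cutoff property: lac advances by at most one row per column
    lac <- om$lac_per_column
    expect_true(all(diff(lac) <= 1))
  }
})

test_that("expected queue occupancy is O(k) on random sequence", {
  set.seed(404)
  for (i in 1:20) {
    k <- sample(0:4, 1)
    res <- find_matches(rand_dna(200), rand_dna(16),
                        search_params(max_differences = k))
    expect_lte(attr(res, "mean_active"), 5 * (k + 1))
  }
})

test_that("weighted search keeps the unweighted candidate set and adds penalties", {
  set.seed(505)
  pen <- penalty_params()
  for (i in 1:60) {
    inst <- rand_instance(max_m = 12L, max_n = 60L)
    q <- sample(0:45, nchar(inst$read), replace = TRUE)
    a <- find_matches(inst$read, inst$pattern, inst$params)
    b <- find_weighted_matches(inst$read, q, inst$pattern, inst$params)
    expect_identical(candidate_key(a), candidate_key(b))
    expect_true(all(b$penalty >= b$differences * pen$p_min - 1e-9))
    expect_identical(candidate_key(b),
                     candidate_key(oracle_find(inst$read, inst$pattern,
                                               inst$params, qual = q)))
  }
  expect_error(find_weighted_matches("ACGT", c(30L, 30L), "AC"),
               "length")
})

test_that("weighted candidates carry the minimum-penalty alignment", {
  # one mismatch at q=40 with no indels: penalty is exactly P_max
  pen <- penalty_params()
  rd <- "TTACGTACGTT"
  mut <- rd
  substr(mut, 5, 5) <- "A"  # pattern pos 3 mismatch
  hits <- find_weighted_matches(mut, rep(40L, nchar(mut)), "ACGTACG",
                                search_params(max_differences = 1))
  full <- hits[hits$matched_pattern_length == 7 & hits$differences == 1 &
               hits$start == 2, ]
  expect_equal(min(full$penalty), pen$p_max, tolerance = 1e-12)
  # perfect match: penalty 0 whatever the qualities
  hits <- find_weighted_matches("TTACGTT", sample(0:40, 7), "ACG",
                                search_params(max_differences = 0))
  expect_true(all(hits$penalty[hits$differences == 0] == 0))
})

test_that("read N is a mismatch everywhere except against pattern N", {
  p0 <- search_params(max_differences = 0)
  # read N against pattern A is a difference, so no exact hit exists
  expect_equal(nrow(find_matches("TTNACGT", "AACG", p0)), 0L)
  # but pattern N accepts read N (and anything else)
  expect_equal(nrow(find_matches("ANGT", "ANGT", p0)), 1L)
  # a read-N mismatch is penalized at the floor P_min, not P(q)
  pen <- penalty_params()
  hits <- find_weighted_matches("AANGT", rep(40L, 5), "AAAGT",
                                search_params(max_differences = 1))
  full <- hits[hits$matched_pattern_length == 5 & hits$start == 0, ]
  expect_equal(min(full$penalty), pen$p_min, tolerance = 1e-12)
})

test_that("a suffix overlap of length 1/e tolerates exactly floor(L*e) differences", {
  params <- search_params(error_ratio = 0.1, min_overlap = 3)
  adapter <- "ACGTACGTACGTACGTACG"
  # 10 nt overlap with one planted mismatch: floor(10 * 0.1) = 1 admissible
  ov <- substr(adapter, 1, 10)
  substr(ov, 5, 5) <- setdiff(BASES, substr(ov, 5, 5))[1]
  rd <- paste0(rand_dna(30), ov)
  hits <- find_matches(rd, adapter, params)
  expect_true(any(hits$start == 30 & hits$differences == 1))
  # two mismatches exceed the bound: no candidate spanning the overlap
  ov2 <- ov
  substr(ov2, 8, 8) <- setdiff(BASES, substr(ov2, 8, 8))[1]
  rd2 <- paste0(rand_dna(30), ov2)
  hits2 <- find_matches(rd2, adapter, params)
  expect_false(any(hits2$start == 30 & hits2$end == 40))
})
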