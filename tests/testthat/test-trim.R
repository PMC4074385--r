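ADAPTER1 <- "AGATCGGAAGAGCACACGT"   # 19 nt
ADAPTER2 <- "AGATCGGAAGAGCGTCGTG"

test_that("revcomp applies the full IUPAC complement and is an involution", {
  expect_equal(revcomp("ACGT"), "ACGT")
  expect_equal(revcomp("AAC"), "GTT")
  expect_equal(revcomp("RY"), "RY")
  expect_equal(revcomp(""), "")
  set.seed(707)
  iupac <- strsplit("ACGTRYSWKMBDHVN", "")[[1]]
  for (i in 1:30) {
    s <- paste(sample(iupac, sample(1:25, 1), TRUE), collapse = "")
    expect_equal(revcomp(revcomp(s)), s)
    expect_equal(revcomp(s),
                 as.character(Biostrings::reverseComplement(
                   Biostrings::DNAString(s))))
  }
  expect_error(revcomp("ACXGT"), "IUPAC")
})

test_that("trim_single trims at the adapter start and leaves clean reads alone", {
  set.seed(808)
  # 20 nt insert + full 19 nt adapter + filler, error-free
  insert <- rand_dna(20)
  rd <- flat_read(paste0(insert, ADAPTER1, rand_dna(11)))
  ts <- trim_single(rd, ADAPTER1, search_params(error_ratio = 0.1))
  expect_equal(ts$decision$mode, "tail3")
  expect_equal(ts$decision$trim_index, 20L)
  expect_equal(ts$read$seq, insert)
  expect_equal(length(ts$read$qual), 20L)

  # no admissible candidate: unchanged
  clean <- flat_read(paste(rep("AC", 25), collapse = ""))
  ts <- trim_single(clean, "GGGTTTGGGTTTGGG", search_params())
  expect_equal(ts$decision$mode, "none")
  expect_equal(ts$read$seq, clean$seq)

  # primer-dimer: exact adapter from position 0 trims to an empty read
  ts <- trim_single(flat_read(paste0(ADAPTER1, rand_dna(31))), ADAPTER1,
                    search_params(error_ratio = 0.1))
  expect_equal(ts$decision$trim_index, 0L)
  expect_equal(ts$read$seq, "")
})

test_that("trim_single honors min_overlap at the 3' end", {
  set.seed(809)
  params <- search_params(error_ratio = 0.1, min_overlap = 3)
  insert <- rand_dna(40)
  # 3 nt exact adapter prefix at the very end: trimmed at the overlap start
  rd <- flat_read(paste0(insert, substr(ADAPTER1, 1, 3)))
  ts <- trim_single(rd, ADAPTER1, params)
  expect_equal(ts$decision$mode, "tail3")
  expect_equal(ts$decision$trim_index, 40L)
  # 2 nt overlap is below min_overlap: untouched
  rd2 <- flat_read(paste0(insert, substr(ADAPTER1, 1, 2)))
  ts2 <- trim_single(rd2, ADAPTER1, params)
  expect_equal(ts2$decision$mode, "none")
})

test_that("pe_score is the three-term sum of the printed scoring scheme", {
  set.seed(909)
  pen <- penalty_params()
  a1 <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA"   # 33 nt: tails are prefixes
  a2 <- "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGT"
  insert <- 30L; rl <- 50L
  pr <- make_pe_pair(insert, a1, a2, rl)
  # tails are exact adapter prefixes (20 nt), prefixes exact revcomp mates
  s <- pe_score(pr, a1, a2, insert)
  expect_equal(s, (20 + 20 + 30) * pen$p_max, tolerance = 1e-9)
  # idx = 0: empty third term, tails are the whole reads
  s0 <- pe_score(pr, a1, a2, 0)
  q <- pr$read1$qual
  expect_equal(s0, pscore(pr$read1$seq, a1, q) +
                   pscore(pr$read2$seq, a2, pr$read2$qual),
               tolerance = 1e-9)
  # one planted q=40 mismatch in read2's tail lowers the score by P_max
  pr2 <- pr
  pos <- insert + 5L
  old <- substr(pr2$read2$seq, pos, pos)
  substr(pr2$read2$seq, pos, pos) <- setdiff(BASES, old)[1]
  s2 <- pe_score(pr2, a1, a2, insert)
  expect_equal(s - s2, pen$p_max, tolerance = 1e-9)
  expect_error(pe_score(pr, a1, a2, 51), "range")
})

test_that("trim_pair recovers the read-through boundary and spares clean pairs", {
  set.seed(1010)
  params <- search_params(error_ratio = 0.1)
  # error-free read-through: insert 30 < read length 50
  pr <- make_pe_pair(30L, ADAPTER1, ADAPTER2, 50L)
  tp <- trim_pair(pr, ADAPTER1, ADAPTER2, params)
  expect_equal(tp$decision$mode, "pe")
  expect_equal(tp$decision$trim_index, 30L)
  expect_equal(nchar(tp$pair$read1$seq), 30L)
  expect_equal(nchar(tp$pair$read2$seq), 30L)
  expect_equal(tp$pair$read1$seq, revcomp(tp$pair$read2$seq))

  # insert >= read length: unchanged
  pr <- make_pe_pair(80L, ADAPTER1, ADAPTER2, 50L)
  tp <- trim_pair(pr, ADAPTER1, ADAPTER2, params)
  expect_equal(tp$decision$mode, "none")
  expect_equal(nchar(tp$pair$read1$seq), 50L)

  # adapter dimer (insert 0): both mates trimmed to empty
  pr <- make_pe_pair(0L, ADAPTER1, ADAPTER2, 50L)
  tp <- trim_pair(pr, ADAPTER1, ADAPTER2, params)
  expect_equal(tp$decision$trim_index, 0L)
  expect_equal(nchar(tp$pair$read1$seq), 0L)

  # 1-2 nt overlaps are still recovered through the pair evidence
  for (ins in c(48L, 49L)) {
    pr <- make_pe_pair(ins, ADAPTER1, ADAPTER2, 50L)
    tp <- trim_pair(pr, ADAPTER1, ADAPTER2, params)
    expect_equal(tp$decision$trim_index, ins)
  }
})

test_that("pair evidence dominates: non-complementary prefixes are rejected", {
  set.seed(1111)
  params <- search_params(error_ratio = 0.1)
  # both reads end in an exact 4 nt adapter prefix, but the retained
  # prefixes are unrelated random sequence: no trim may be reported
  r1 <- flat_read(paste0(rand_dna(46), substr(ADAPTER1, 1, 4)), id = "x/1")
  r2 <- flat_read(paste0(rand_dna(46), substr(ADAPTER2, 1, 4)), id = "x/2")
  tp <- trim_pair(read_pair(r1, r2), ADAPTER1, ADAPTER2, params)
  expect_equal(tp$decision$mode, "none")
})

test_that("trim_lmp splits at the junction after the PE stage", {
  set.seed(1212)
  junction <- "CTGTCTCTTATACACATCT"
  params <- search_params(error_ratio = 0.1)
  mk <- function(jpos, rl = 150L) {
    g <- rand_dna(rl - nchar(junction))
    paste0(substr(g, 1, jpos), junction,
           substr(g, jpos + 1, nchar(g)))
  }
  pr <- read_pair(flat_read(mk(100L), id = "l/1"),
                  flat_read(mk(40L), id = "l/2"))
  res <- trim_lmp(pr, junction, ADAPTER1, ADAPTER2, params)
  expect_equal(res$categories, c("junction_found", "junction_found"))
  expect_equal(nchar(res$pair$read1$seq), 100L)
  expect_equal(nchar(res$pair$read2$seq), 40L)

  # no junction anywhere: stage 2 changes nothing
  pr <- read_pair(flat_read(rand_dna(150), id = "m/1"),
                  flat_read(rand_dna(150), id = "m/2"))
  res <- trim_lmp(pr, junction, ADAPTER1, ADAPTER2, params)
  expect_equal(res$categories, c("no_junction", "no_junction"))
  expect_equal(nchar(res$pair$read1$seq), 150L)

  # junction at position 0: empty retained prefix
  pr <- read_pair(flat_read(mk(0L), id = "e/1"),
                  flat_read(mk(70L), id = "e/2"))
  res <- trim_lmp(pr, junction, ADAPTER1, ADAPTER2, params)
  expect_equal(res$categories[1], "empty_after_trim")
  expect_equal(nchar(res$pair$read1$seq), 0L)
})

test_that("after junction splitting no admissible full junction remains", {
  set.seed(1313)
  junction <- "CTGTCTCTTATACACATCT"
  params <- search_params(error_ratio = 0.1)
  for (i in 1:25) {
    jpos <- sample(0:131, 1)
    g <- rand_dna(150 - nchar(junction))
    s <- paste0(substr(g, 1, jpos), junction, substr(g, jpos + 1, nchar(g)))
    pr <- read_pair(flat_read(s, id = "i/1"),
                    flat_read(rand_dna(150), id = "i/2"))
    res <- trim_lmp(pr, junction, ADAPTER1, ADAPTER2, params)
    out <- res$pair$read1$seq
    if (nchar(out) == 0L) next
    again <- find_weighted_matches(out, res$pair$read1$qual, junction, params)
    span <- again$end - again$start
    again <- again[again$matched_pattern_length == nchar(junction) &
                   again$differences <= floor(span * params$error_ratio), ,
                   drop = FALSE]
    expect_equal(nrow(again), 0L)
  }
})

test_that("filter_min_length keeps counts conserved", {
  df <- reads_df(paste0("r", 1:10), c(rep("ACGTACGT", 7), "AC", "A", ""))
  fl <- filter_min_length(df, 3)
  expect_equal(nrow(fl$kept), 7L)
  expect_equal(fl$discarded, 3L)
  expect_equal(nrow(fl$kept) + fl$discarded, nrow(df))
  expect_equal(filter_min_length(df, 0)$discarded, 0L)
  expect_equal(filter_min_length(reads_df("z", ""), 1)$discarded, 1L)
  # paired: both (default) vs any
  d1 <- reads_df(c("a/1", "b/1"), c("ACGT", "AC"))
  d2 <- reads_df(c("a/2", "b/2"), c("ACGT", "ACGT"))
  expect_equal(filter_min_length(list(d1, d2), 3)$discarded, 1L)
  expect_equal(filter_min_length(list(d1, d2), 3, "any")$discarded, 0L)
})

test_that("trimmed output is always a prefix with synchronized qualities", {
  set.seed(1414)
  for (i in 1:20) {
    n <- sample(30:60, 1)
    seq <- rand_dna(n)
    q <- sample(2:40, n, replace = TRUE)
    rd <- read_record("p", seq, q)
    ts <- trim_single(rd, ADAPTER1, search_params())
    L <- nchar(ts$read$seq)
    expect_equal(ts$read$seq, substr(seq, 1, L))
    expect_equal(ts$read$qual, q[seq_len(L)])
  }
})
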