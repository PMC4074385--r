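reads_offset <- function(reads, phred_offset = NULL) {
  if (!is.null(phred_offset)) return(as.integer(phred_offset))
  off <- attr(reads, "phred_offset")
  if (is.null(off)) 33L else as.integer(off)
}

#' Trim an adapter from every read in a table
#'
#' Vectorised driver over [trim_single()] for data.frames as produced by
#' [read_fastq()] or [simulate_dataset()] (columns `id`, `seq`, `qual`
#' with qualities in encoded form).
#'
#' @param reads data.frame with `id`, `seq`, `qual`.
#' @param pattern Adapter ([build_pattern()] or string).
#' @param params [search_params()].
#' @param penalty [penalty_params()].
#' @param phred_offset Quality encoding offset (default: the table's
#'   `phred_offset` attribute, else 33).
#' @return List with `reads` (trimmed table) and `decisions` (data.frame
#'   `read_id`, `mode`, `trim_index`, `input_length`, `output_length`).
#' @export
trim_reads <- function(reads, pattern, params = search_params(),
                       penalty = penalty_params(), phred_offset = NULL) {
  pattern <- as_pattern(pattern)
  off <- reads_offset(reads, phred_offset)
  quals <- decode_quals(reads$qual, off)
  n <- nrow(reads)
  mode <- character(n); tidx <- integer(n)
  inlen <- nchar(reads$seq); outlen <- integer(n)
  out <- reads
  for (i in seq_len(n)) {
    rec <- read_record(reads$id[i], reads$seq[i], quals[[i]])
    ts <- trim_single(rec, pattern, params, penalty)
    mode[i] <- ts$decision$mode
    tidx[i] <- ts$decision$trim_index
    outlen[i] <- nchar(ts$read$seq)
    if (mode[i] != "none") {
      out$seq[i] <- ts$read$seq
      out$qual[i] <- substr(reads$qual[i], 1L, outlen[i])
    }
  }
  attr(out, "phred_offset") <- off
  list(reads = out,
       decisions = data.frame(read_id = reads$id, mode = mode,
                              trim_index = tidx, input_length = inlen,
                              output_length = outlen))
}

#' Jointly trim every pair in a pair of tables
#'
#' Vectorised driver over [trim_pair()]; mates are matched by row.
#'
#' @param reads1,reads2 Mate tables (`id`, `seq`, `qual`).
#' @param pattern1,pattern2 Adapters.
#' @inheritParams trim_reads
#' @return List with `reads1`, `reads2` (trimmed) and `decisions1`,
#'   `decisions2` (per-read, as in [trim_reads()]).
#' @export
trim_pairs <- function(reads1, reads2, pattern1, pattern2,
                       params = search_params(),
                       penalty = penalty_params(), phred_offset = NULL) {
  stopifnot(nrow(reads1) == nrow(reads2))
  pattern1 <- as_pattern(pattern1); pattern2 <- as_pattern(pattern2)
  off <- reads_offset(reads1, phred_offset)
  q1 <- decode_quals(reads1$qual, off)
  q2 <- decode_quals(reads2$qual, off)
  n <- nrow(reads1)
  mode <- character(n); tidx <- integer(n)
  in1 <- nchar(reads1$seq); in2 <- nchar(reads2$seq)
  out1 <- reads1; out2 <- reads2
  o1 <- in1; o2 <- in2
  for (i in seq_len(n)) {
    pr <- read_pair(read_record(reads1$id[i], reads1$seq[i], q1[[i]]),
                    read_record(reads2$id[i], reads2$seq[i], q2[[i]]))
    tp <- trim_pair(pr, pattern1, pattern2, params, penalty)
    mode[i] <- tp$decision$mode
    tidx[i] <- tp$decision$trim_index
    if (mode[i] != "none") {
      idx <- tp$decision$trim_index
      o1[i] <- idx; o2[i] <- idx
      out1$seq[i] <- tp$pair$read1$seq
      out1$qual[i] <- substr(reads1$qual[i], 1L, idx)
      out2$seq[i] <- tp$pair$read2$seq
      out2$qual[i] <- substr(reads2$qual[i], 1L, idx)
    }
  }
  attr(out1, "phred_offset") <- off
  attr(out2, "phred_offset") <- off
  list(reads1 = out1, reads2 = out2,
       decisions1 = data.frame(read_id = reads1$id, mode = mode,
                               trim_index = tidx, input_length = in1,
                               output_length = o1),
       decisions2 = data.frame(read_id = reads2$id, mode = mode,
                               trim_index = tidx, input_length = in2,
                               output_length = o2))
}

#' Trim every long-mate-pair in a pair of tables
#'
#' Vectorised driver over [trim_lmp()]: paired-end adapter trimming
#' followed by per-read junction splitting.
#'
#' @inheritParams trim_pairs
#' @param junction Junction adapter.
#' @return List with `reads1`, `reads2` (processed), `categories1`,
#'   `categories2` (per-read junction labels) and `decisions1`,
#'   `decisions2`.
#' @export
trim_lmp_pairs <- function(reads1, reads2, junction, pattern1, pattern2,
                           params = search_params(),
                           penalty = penalty_params(),
                           phred_offset = NULL) {
  stopifnot(nrow(reads1) == nrow(reads2))
  junction <- as_pattern(junction)
  pattern1 <- as_pattern(pattern1); pattern2 <- as_pattern(pattern2)
  off <- reads_offset(reads1, phred_offset)
  q1 <- decode_quals(reads1$qual, off)
  q2 <- decode_quals(reads2$qual, off)
  n <- nrow(reads1)
  cat1 <- character(n); cat2 <- character(n)
  in1 <- nchar(reads1$seq); in2 <- nchar(reads2$seq)
  o1 <- integer(n); o2 <- integer(n)
  out1 <- reads1; out2 <- reads2
  for (i in seq_len(n)) {
    pr <- read_pair(read_record(reads1$id[i], reads1$seq[i], q1[[i]]),
                    read_record(reads2$id[i], reads2$seq[i], q2[[i]]))
    res <- trim_lmp(pr, junction, pattern1, pattern2, params, penalty)
    cat1[i] <- res$categories[1]; cat2[i] <- res$categories[2]
    o1[i] <- nchar(res$pair$read1$seq); o2[i] <- nchar(res$pair$read2$seq)
    out1$seq[i] <- res$pair$read1$seq
    out1$qual[i] <- substr(reads1$qual[i], 1L, o1[i])
    out2$seq[i] <- res$pair$read2$seq
    out2$qual[i] <- substr(reads2$qual[i], 1L, o2[i])
  }
  attr(out1, "phred_offset") <- off
  attr(out2, "phred_offset") <- off
  list(reads1 = out1, reads2 = out2, categories1 = cat1, categories2 = cat2,
       decisions1 = data.frame(read_id = reads1$id, category = cat1,
                               input_length = in1, output_length = o1),
       decisions2 = data.frame(read_id = reads2$id, category = cat2,
                               input_length = in2, output_length = o2))
}
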