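# shared fixture builders (all data is generated in code at test time)

BASES <- c("A", "C", "G", "T")

rand_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# a random (read, pattern, params) instance; half the time an adapter copy
# is planted so that hits are common
rand_instance <- function(max_m = 16L, max_n = 100L) {
  m <- sample(4:max_m, 1)
  n <- sample(20:max_n, 1)
  pat <- rand_dna(m)
  rd <- rand_dna(n)
  if (runif(1) < 0.5) {
    at <- sample.int(n - m + 1L, 1)
    substr(rd, at, at + m - 1L) <- pat
  }
  list(read = rd, pattern = pat,
       params = search_params(error_ratio = runif(1, 0, 0.3),
                              max_differences = sample(0:4, 1)))
}

# canonical string form of a candidate set for multiset comparison
candidate_key <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  sort(sprintf("%d:%d:%d:%d", df$start, df$end, df$differences,
               df$matched_pattern_length))
}

# build a read record with flat qualities
flat_read <- function(seq, q = 40L, id = "r") {
  read_record(id, seq, rep(q, nchar(seq)))
}

# write a small FASTQ file; returns the path
write_tmp_fastq <- function(records, ext = ".fastq") {
  path <- tempfile(fileext = ext)
  write_fastq(records, path)
  path
}

reads_df <- function(id, seq, q = 40L) {
  df <- data.frame(id = id, seq = seq,
                   qual = vapply(nchar(seq),
                                 function(n) encode_quals(rep(q, n)),
                                 character(1)))
  attr(df, "phred_offset") <- 33L
  df
}

# an error-free read-through pair: insert + adapter + random filler
make_pe_pair <- function(insert, adapter1, adapter2, read_length, q = 40L) {
  frag <- rand_dna(insert)
  pad <- function(core, adapter) {
    need <- read_length - nchar(core)
    if (need <= 0L) return(substr(core, 1L, read_length))
    ad <- substr(adapter, 1L, need)
    paste0(core, ad, rand_dna(need - nchar(ad)))
  }
  read_pair(flat_read(pad(frag, adapter1), q, "p/1"),
            flat_read(pad(revcomp(frag), adapter2), q, "p/2"))
}
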