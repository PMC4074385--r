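#' Decode FASTQ quality strings to integer Phred scores
#'
#' @param qual Character vector of encoded quality strings.
#' @param phred_offset 33 (Sanger/Illumina 1.8+) or 64 (Illumina 1.3-1.7).
#' @return List of integer vectors.
#' @export
decode_quals <- function(qual, phred_offset = 33L) {
  stopifnot(phred_offset %in% c(33L, 64L))
  lapply(qual, function(s) {
    if (nchar(s) == 0L) integer(0) else utf8ToInt(s) - as.integer(phred_offset)
  })
}

#' Encode integer Phred scores as a quality string
#'
#' @param qual Integer vector of Phred scores (all >= 0).
#' @inheritParams decode_quals
#' @export
encode_quals <- function(qual, phred_offset = 33L) {
  if (length(qual) == 0L) return("")
  if (any(qual < 0L)) stop("negative quality cannot be encoded")
  intToUtf8(as.integer(qual) + as.integer(phred_offset))
}

is_gzip <- function(path) {
  magic <- readBin(path, "raw", n = 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

#' Read a 4-line FASTQ file
#'
#' Plain or gzip input (auto-detected from the magic bytes). Strict 4-line
#' records: the header must start with `@`, the separator line with `+`,
#' and sequence and quality must have equal length; violations raise an
#' error naming the offending line. Multi-line (wrapped) FASTQ is rejected
#' rather than silently joined. Header comments after the identifier are
#' preserved verbatim. Records are processed in bounded-size chunks, so
#' memory does not grow with file size when a `callback` is used.
#'
#' @param path Input file.
#' @param phred_offset 33 or 64 (see [detect_quality_offset()] to guess).
#' @param chunk_size Records read per chunk.
#' @param callback Optional `function(chunk_df)` invoked per chunk; when
#'   supplied the function returns the total record count instead of a
#'   data.frame.
#' @return data.frame with columns `id`, `seq`, `qual` (qualities kept in
#'   encoded form; decode with [decode_quals()]) and attribute
#'   `phred_offset` - or the record count when `callback` is given.
#' @export
read_fastq <- function(path, phred_offset = 33L, chunk_size = 100000L,
                       callback = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  stopifnot(phred_offset %in% c(33L, 64L))
  con <- gzfile(path, "rt")  # reads plain files transparently too
  on.exit(close(con))
  out <- list()
  total <- 0L
  lineno <- 0L
  repeat {
    lines <- readLines(con, n = 4L * chunk_size)
    if (length(lines) == 0L) break
    if (length(lines) %% 4L != 0L)
      stop("truncated FASTQ record at line ", lineno + length(lines),
           " of ", path)
    idx <- seq(1L, length(lines), by = 4L)
    hdr <- lines[idx]
    seqs <- lines[idx + 1L]
    plus <- lines[idx + 2L]
    quals <- lines[idx + 3L]
    bad <- which(!startsWith(hdr, "@"))
    if (length(bad) > 0L)
      stop("record does not start with '@' at line ",
           lineno + (bad[1] - 1L) * 4L + 1L, " of ", path)
    bad <- which(!startsWith(plus, "+"))
    if (length(bad) > 0L)
      stop("missing '+' separator at line ",
           lineno + (bad[1] - 1L) * 4L + 3L, " of ", path)
    bad <- which(nchar(seqs) != nchar(quals))
    if (length(bad) > 0L)
      stop("sequence/quality length mismatch at line ",
           lineno + (bad[1] - 1L) * 4L + 2L, " of ", path)
    chunk <- data.frame(id = substring(hdr, 2L), seq = seqs, qual = quals)
    attr(chunk, "phred_offset") <- as.integer(phred_offset)
    total <- total + nrow(chunk)
    lineno <- lineno + length(lines)
    if (is.null(callback)) out[[length(out) + 1L]] <- chunk
    else callback(chunk)
  }
  if (!is.null(callback)) return(total)
  res <- if (length(out) == 0L)
    data.frame(id = character(0), seq = character(0), qual = character(0))
  else do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "phred_offset") <- as.integer(phred_offset)
  res
}

#' Write reads as a 4-line FASTQ file
#'
#' @param records data.frame with `id`, `seq`, `qual` (encoded) columns.
#' @param path Output file; gzip-compressed when it ends in `.gz` or
#'   `gzip = TRUE`.
#' @param phred_offset Offset the `qual` column is encoded with (recorded
#'   for round-trip checking; qualities are written as-is).
#' @param gzip Force gzip on/off; default by file extension.
#' @return Number of records written, invisibly.
#' @export
write_fastq <- function(records, path, phred_offset = 33L, gzip = NULL) {
  if (is.null(gzip)) gzip <- grepl("\\.gz$", path)
  con <- if (gzip) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  n <- nrow(records)
  if (n > 0L) {
    lines <- character(4L * n)
    lines[seq(1L, 4L * n, by = 4L)] <- paste0("@", records$id)
    lines[seq(2L, 4L * n, by = 4L)] <- records$seq
    lines[seq(3L, 4L * n, by = 4L)] <- "+"
    lines[seq(4L, 4L * n, by = 4L)] <- records$qual
    writeLines(lines, con, sep = "\n")
  }
  invisible(n)
}

#' Read synchronized paired FASTQ files
#'
#' @param path1,path2 Mate-1 / mate-2 files.
#' @inheritParams read_fastq
#' @return List of two data.frames as from [read_fastq()]; record counts
#'   and identifiers (up to the mate suffix) are verified, and a
#'   synchronization error names the first offending record index.
#' @export
read_paired <- function(path1, path2, phred_offset = 33L) {
  r1 <- read_fastq(path1, phred_offset)
  r2 <- read_fastq(path2, phred_offset)
  if (nrow(r1) != nrow(r2))
    stop("paired files out of sync: ", nrow(r1), " vs ", nrow(r2),
         " records (first missing record index ",
         min(nrow(r1), nrow(r2)) + 1L, ")")
  id1 <- vapply(r1$id, core_id, character(1), USE.NAMES = FALSE)
  id2 <- vapply(r2$id, core_id, character(1), USE.NAMES = FALSE)
  bad <- which(id1 != id2)
  if (length(bad) > 0L)
    stop("mate identifier mismatch at record ", bad[1], ": '",
         r1$id[bad[1]], "' vs '", r2$id[bad[1]], "'")
  list(r1, r2)
}

#' Guess the Phred quality offset from a sample of records
#'
#' Any quality character below ASCII 59 implies offset 33; samples lying
#' entirely at or above ASCII 64 imply offset 64; a sample confined to the
#' ambiguous 59-63 band defaults to 33 with a warning.
#'
#' @param qual Character vector of encoded quality strings (>= 1).
#' @return 33 or 64.
#' @export
detect_quality_offset <- function(qual) {
  qual <- qual[nchar(qual) > 0L]
  if (length(qual) == 0L) stop("empty quality sample")
  codes <- utf8ToInt(paste(qual, collapse = ""))
  if (any(codes < 59L)) return(33L)
  if (all(codes >= 64L)) return(64L)
  warning("quality characters confined to the ambiguous ASCII 59-63 band; ",
          "assuming Phred+33")
  33L
}
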