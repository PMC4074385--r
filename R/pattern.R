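IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGTN"
)

#' Precompute an adapter pattern with per-base mismatch position sets
#'
#' Builds the search pattern used by [find_matches()] and friends: for each
#' possible read base (A, C, G, T, N) the set of 0-based pattern positions
#' that do \emph{not} accept that base. These are the bit-vectors of the
#' bit-masked matcher; pattern positions with degenerate IUPAC codes are
#' absent from the mismatch set of every base in their degeneracy set. A
#' read 'N' carries no evidence and is treated as a mismatch everywhere
#' except against a pattern 'N'.
#'
#' @param adapter Adapter (or junction) sequence; IUPAC nucleotide codes,
#'   case-insensitive ('U' is read as 'T').
#' @return An object of class `adapter_pattern`: a list with elements
#'   `sequence` (uppercased input), `length`, and `mismatch_masks`
#'   (named list of 0-based integer position vectors for A, C, G, T, N).
#' @examples
#' p <- build_pattern("ACGT")
#' p$mismatch_masks$A   # 1 2 3: every position but the first mismatches A
#' @export
build_pattern <- function(adapter) {
  if (!is.character(adapter) || length(adapter) != 1L || is.na(adapter) ||
      nchar(adapter) < 1L)
    stop("adapter must be a single non-empty string")
  seq <- toupper(adapter)
  chars <- strsplit(seq, "")[[1]]
  bad <- !chars %in% names(IUPAC_CODES)
  if (any(bad))
    stop("invalid IUPAC character(s) in adapter: ",
         paste(unique(chars[bad]), collapse = ", "))
  seq <- chartr("U", "T", seq)
  m <- nchar(seq)
  masks <- lapply(c("A", "C", "G", "T", "N"), function(b) {
    hit <- vapply(chars, function(pc) {
      grepl(b, IUPAC_CODES[[pc]], fixed = TRUE)
    }, logical(1), USE.NAMES = FALSE)
    unname(which(!hit)) - 1L
  })
  names(masks) <- c("A", "C", "G", "T", "N")
  structure(
    list(sequence = seq, length = m, mismatch_masks = masks),
    class = "adapter_pattern"
  )
}

#' @export
print.adapter_pattern <- function(x, ...) {
  cat("<adapter_pattern> ", x$sequence, " (", x$length, " nt)\n", sep = "")
  invisible(x)
}

as_pattern <- function(x) {
  if (inherits(x, "adapter_pattern")) x else build_pattern(x)
}

#' Reverse complement of an IUPAC nucleotide string
#'
#' Full IUPAC complement table (R<->Y, S<->S, W<->W, K<->M, B<->V, D<->H,
#' N<->N); vectorised; an involution.
#'
#' @param seq Character vector of IUPAC nucleotide strings.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("AAC")  # "GTT"
#' @export
revcomp <- function(seq) {
  if (!is.character(seq)) stop("seq must be a character vector")
  bad <- grepl("[^ACGTURYSWKMBDHVNacgturyswkmbdhvn]", seq)
  if (any(bad))
    stop("non-IUPAC character in sequence: ",
         substr(seq[bad][1], 1, 40))
  comp <- chartr("ACGTURYSWKMBDHVNacgturyswkmbdhvn",
                 "TGCAAYRSWMKVHDBNtgcaayrswmkvhdbn", seq)
  vapply(comp, function(s) {
    if (nchar(s) == 0L) return("")
    intToUtf8(rev(utf8ToInt(s)))
  }, character(1), USE.NAMES = FALSE)
}
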