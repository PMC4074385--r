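#' Construct a read record
#'
#' @param id Read identifier (header text without the leading `@`).
#' @param seq Nucleotide string.
#' @param qual Integer Phred qualities, one per base.
#' @return List of class `read_record`.
#' @export
read_record <- function(id, seq, qual) {
  qual <- as.integer(qual)
  if (nchar(seq) != length(qual))
    stop("sequence and quality lengths differ for read '", id, "'")
  structure(list(id = id, seq = toupper(seq), qual = qual),
            class = "read_record")
}

#' Construct a read pair
#'
#' Mate identifiers must agree up to a trailing `/1` / `/2` (or other mate
#' tag after whitespace).
#'
#' @param read1,read2 [read_record()] objects.
#' @export
read_pair <- function(read1, read2) {
  if (core_id(read1$id) != core_id(read2$id))
    stop("mate identifiers disagree: '", read1$id, "' vs '", read2$id, "'")
  structure(list(read1 = read1, read2 = read2,
                 readLen = c(nchar(read1$seq), nchar(read2$seq))),
            class = "read_pair")
}

core_id <- function(id) {
  id <- sub("[ \t].*$", "", id)
  sub("/[12]$", "", id)
}

trim_decision <- function(mode, trim_index = NA_integer_, score = NA_real_,
                          differences = NA_integer_) {
  structure(list(mode = mode, trim_index = as.integer(trim_index),
                 score = score, differences = as.integer(differences)),
            class = "trim_decision")
}

truncate_record <- function(read, idx) {
  read$seq <- substr(read$seq, 1L, idx)
  read$qual <- read$qual[seq_len(idx)]
  read
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  if (nchar(a) == 0L) return(0L)
  sum(charToRaw(a) != charToRaw(b))
}

# decision-layer admissibility: the error ratio applies to the aligned span
admissible_matches <- function(matches, error_ratio) {
  span <- matches$end - matches$start
  matches[matches$differences <= floor_ratio(span * error_ratio), ,
          drop = FALSE]
}

#' Trim a 3' adapter from a single read
#'
#' Runs the quality-weighted k-difference search (full occurrences and 3'
#' suffix overlaps), keeps the candidates whose difference count is within
#' the error ratio over their aligned span, and trims at the start of the
#' candidate maximising the span fitness `span * P_max - penalty`; ties go
#' to the longer matched pattern length, then the smaller start. Returns
#' the unchanged read when no admissible candidate exists.
#'
#' @param read A [read_record()].
#' @param pattern Adapter ([build_pattern()] or string).
#' @param params [search_params()].
#' @param penalty [penalty_params()].
#' @return List with elements `decision` (a `trim_decision`) and `read`
#'   (the possibly truncated record).
#' @export
trim_single <- function(read, pattern, params = search_params(),
                        penalty = penalty_params()) {
  pattern <- as_pattern(pattern)
  m <- find_weighted_matches(read$seq, read$qual, pattern, params, penalty)
  m <- admissible_matches(m, params$error_ratio)
  if (nrow(m) == 0L)
    return(list(decision = trim_decision("none"), read = read))
  span <- m$end - m$start
  score <- span * penalty$p_max - m$penalty
  ord <- order(-score, -m$matched_pattern_length, m$start)
  best <- m[ord[1L], ]
  list(decision = trim_decision("tail3", best$start, score[ord[1L]],
                                best$differences),
       read = truncate_record(read, best$start))
}

#' Paired-end joint trimming score at a candidate position
#'
#' `score(idx) = pscore(read1[idx..], adapter1) + pscore(read2[idx..],
#' adapter2) + pscore(read1[0..idx), revcomp(read2[0..idx)))`: the fitness
#' of both read tails as adapter sequence plus the fitness of the retained
#' prefixes as reverse-complementary mates (mismatches in the third term
#' are charged at the smaller of the two base qualities).
#'
#' @param pair A [read_pair()].
#' @param pattern1,pattern2 Adapters for mate 1 / mate 2.
#' @param idx Candidate trim position, `0 <= idx <= min(read lengths)`.
#' @param penalty [penalty_params()].
#' @return Numeric score.
#' @export
pe_score <- function(pair, pattern1, pattern2, idx,
                     penalty = penalty_params()) {
  pattern1 <- as_pattern(pattern1); pattern2 <- as_pattern(pattern2)
  n1 <- pair$readLen[1]; n2 <- pair$readLen[2]
  idx <- as.integer(idx)
  if (idx < 0L || idx > min(n1, n2))
    stop("idx out of range [0, ", min(n1, n2), "]")
  r1 <- pair$read1; r2 <- pair$read2
  tail1 <- substr(r1$seq, idx + 1L, n1)
  tail2 <- substr(r2$seq, idx + 1L, n2)
  s <- pscore(tail1, pattern1$sequence, r1$qual[seq_len(n1 - idx) + idx],
              penalty) +
       pscore(tail2, pattern2$sequence, r2$qual[seq_len(n2 - idx) + idx],
              penalty)
  if (idx > 0L) {
    pre1 <- substr(r1$seq, 1L, idx)
    pre2rc <- revcomp(substr(r2$seq, 1L, idx))
    s <- s + pscore(pre1, pre2rc, r1$qual[seq_len(idx)], penalty,
                    qy = rev(r2$qual[seq_len(idx)]))
  }
  s
}

# one component of PE admissibility: adapter fit of `read` at idx.
# Prefer an actual search occurrence starting at idx; otherwise align the
# (pattern-length-capped) tail against the adapter directly.
pe_component <- function(read, cands, idx, pattern, params, penalty) {
  n <- nchar(read$seq)
  at <- cands[cands$start == idx, , drop = FALSE]
  if (nrow(at) > 0L) {
    span <- at$end - at$start
    ok <- at$differences <= floor_ratio(span * params$error_ratio)
    if (any(ok)) return(list(ok = TRUE, differences = min(at$differences[ok])))
  }
  tail_len <- n - idx
  if (tail_len == 0L) return(list(ok = TRUE, differences = 0L))
  L <- min(pattern$length, tail_len)
  x <- substr(read$seq, idx + 1L, idx + L)
  al <- prefix_align(x, read$qual[idx + seq_len(L)], pattern$sequence, penalty)
  list(ok = al$differences <= floor_ratio(L * params$error_ratio),
       differences = al$differences)
}

#' Joint adapter trimming of a read pair
#'
#' Candidate trim positions are the union of admissible adapter occurrence
#' starts in either mate (searched with `min_overlap` relaxed to 1 nt: the
#' pair evidence below substitutes for overlap length). A candidate idx is
#' accepted only if all three component alignments stay within the error
#' ratio over their spans - mate-1 tail vs adapter1, mate-2 tail vs
#' adapter2, and retained prefix of mate 1 vs the reverse complement of
#' mate 2's retained prefix - and the accepted candidate maximising
#' [pe_score()] is applied to both mates (both truncated at idx).
#'
#' @inheritParams pe_score
#' @param params [search_params()].
#' @return List with `decision` and `pair`.
#' @export
trim_pair <- function(pair, pattern1, pattern2, params = search_params(),
                      penalty = penalty_params()) {
  pattern1 <- as_pattern(pattern1); pattern2 <- as_pattern(pattern2)
  pe_params <- params
  pe_params$min_overlap <- 1L
  r1 <- pair$read1; r2 <- pair$read2
  nmin <- min(pair$readLen)
  c1 <- find_weighted_matches(r1$seq, r1$qual, pattern1, pe_params, penalty)
  c2 <- find_weighted_matches(r2$seq, r2$qual, pattern2, pe_params, penalty)
  idxs <- sort(unique(c(c1$start, c2$start)))
  idxs <- idxs[idxs <= nmin]
  best_idx <- NA_integer_; best_score <- -Inf; best_diff <- NA_integer_
  for (idx in idxs) {
    k1 <- pe_component(r1, c1, idx, pattern1, params, penalty)
    if (!k1$ok) next
    k2 <- pe_component(r2, c2, idx, pattern2, params, penalty)
    if (!k2$ok) next
    d3 <- 0L
    if (idx > 0L) {
      # the retained prefixes of a true read-through pair are reverse
      # complements in register: check them positionwise (an indel-tolerant
      # alignment would accept the shifted near-copies that inserts a few
      # bases longer than the read produce)
      d3 <- hamming(substr(r1$seq, 1L, idx),
                    revcomp(substr(r2$seq, 1L, idx)))
      if (d3 > floor_ratio(idx * params$error_ratio)) next
    }
    sc <- pe_score(pair, pattern1, pattern2, idx, penalty)
    if (sc > best_score || (sc == best_score && idx > best_idx)) {
      best_score <- sc
      best_idx <- idx
      best_diff <- k1$differences + k2$differences + d3
    }
  }
  if (is.na(best_idx))
    return(list(decision = trim_decision("none"), pair = pair))
  pair$read1 <- truncate_record(r1, best_idx)
  pair$read2 <- truncate_record(r2, best_idx)
  pair$readLen <- c(best_idx, best_idx)
  list(decision = trim_decision("pe", best_idx, best_score, best_diff),
       pair = pair)
}

#' Nextera long-mate-pair trimming: adapters, then junction splitting
#'
#' Stage 1 trims read-through adapters exactly as [trim_pair()]. Stage 2
#' searches each processed mate independently for the junction adapter
#' (full occurrences and 3' suffix overlaps) and retains the prefix before
#' the junction start. Each mate is labelled `junction_found`,
#' `no_junction`, or `empty_after_trim` (junction at position 0, or an
#' already-empty read).
#'
#' @inheritParams trim_pair
#' @param junction Junction adapter ([build_pattern()] or string).
#' @return List with `pair` (processed), `categories` (character of length
#'   2), `pe_decision` (stage 1) and `junction_decisions` (stage 2, per
#'   mate).
#' @export
trim_lmp <- function(pair, junction, pattern1, pattern2,
                     params = search_params(), penalty = penalty_params()) {
  junction <- as_pattern(junction)
  st1 <- trim_pair(pair, pattern1, pattern2, params, penalty)
  pair <- st1$pair
  cats <- character(2)
  decs <- vector("list", 2)
  for (i in 1:2) {
    rd <- if (i == 1) pair$read1 else pair$read2
    if (nchar(rd$seq) == 0L) {
      cats[i] <- "empty_after_trim"
      decs[[i]] <- trim_decision("none")
      next
    }
    ts <- trim_single(rd, junction, params, penalty)
    if (ts$decision$mode == "none") {
      cats[i] <- "no_junction"
      decs[[i]] <- ts$decision
    } else {
      decs[[i]] <- trim_decision("junction", ts$decision$trim_index,
                                 ts$decision$score, ts$decision$differences)
      cats[i] <- if (ts$decision$trim_index == 0L) "empty_after_trim"
                 else "junction_found"
      if (i == 1) pair$read1 <- ts$read else pair$read2 <- ts$read
    }
  }
  pair$readLen <- c(nchar(pair$read1$seq), nchar(pair$read2$seq))
  list(pair = pair, categories = cats, pe_decision = st1$decision,
       junction_decisions = decs)
}

#' Length filter for trimmed reads
#'
#' @param x For single-end input a data.frame with a `seq` column; for
#'   paired input a list of two such data.frames (mates aligned by row).
#' @param l_min Minimum retained length (>= 0).
#' @param pair_policy Keep a pair when `"both"` mates (default) or `"any"`
#'   mate satisfies the bound.
#' @return List with `kept` (same shape as `x`) and `discarded` (count of
#'   reads, or of pairs for paired input).
#' @export
filter_min_length <- function(x, l_min, pair_policy = c("both", "any")) {
  pair_policy <- match.arg(pair_policy)
  stopifnot(l_min >= 0)
  if (is.data.frame(x)) {
    keep <- nchar(x$seq) >= l_min
    return(list(kept = x[keep, , drop = FALSE], discarded = sum(!keep)))
  }
  stopifnot(is.list(x), length(x) == 2L)
  ok1 <- nchar(x[[1]]$seq) >= l_min
  ok2 <- nchar(x[[2]]$seq) >= l_min
  keep <- if (pair_policy == "both") ok1 & ok2 else ok1 | ok2
  list(kept = list(x[[1]][keep, , drop = FALSE],
                   x[[2]][keep, , drop = FALSE]),
       discarded = sum(!keep))
}
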