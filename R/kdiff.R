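#' Search parameters for k-difference adapter matching
#'
#' The stringency of the matcher: a full-length pattern occurrence in a read
#' of length n is admitted with up to `k = floor(n * error_ratio)` unit-cost
#' differences (capped at pattern length − 1), and a 3' suffix overlap of
#' aligned length L with up to `floor(L * error_ratio)` differences. Setting
#' `max_differences` fixes k directly instead of deriving it from the read
#' length; it also caps the differences of suffix overlaps, since the cutoff
#' search never explores cells beyond k.
#'
#' @param error_ratio Maximum fraction of differences per aligned length;
#'   in `[0, 1)`. Default 0.1, the usual stringency for Illumina adapters.
#' @param min_overlap Shortest reportable 3' suffix overlap (nt). Overlaps
#'   of 1-2 nt match random sequence with probability >= 1/16, so the
#'   default is 3.
#' @param max_differences Optional integer fixing k directly.
#' @return A list of class `search_params`.
#' @export
search_params <- function(error_ratio = 0.1, min_overlap = 3L,
                          max_differences = NULL) {
  stopifnot(is.numeric(error_ratio), length(error_ratio) == 1L,
            error_ratio >= 0, error_ratio < 1)
  min_overlap <- as.integer(min_overlap)
  stopifnot(min_overlap >= 1L)
  if (!is.null(max_differences)) {
    max_differences <- as.integer(max_differences)
    stopifnot(max_differences >= 0L)
  }
  structure(list(error_ratio = error_ratio, min_overlap = min_overlap,
                 max_differences = max_differences),
            class = "search_params")
}

floor_ratio <- function(x) as.integer(floor(x + 1e-9))

effective_k <- function(n, m, params) {
  k <- if (is.null(params$max_differences)) floor_ratio(n * params$error_ratio)
       else params$max_differences
  min(k, m - 1L)
}

#' Levenshtein distance between two strings
#'
#' Unit-cost edit distance (substitutions, insertions, deletions) by the
#' classic dynamic programming recurrence; `max(|a|, |b|)` when either
#' string is empty.
#'
#' @param a,b Character strings.
#' @return Non-negative integer distance.
#' @examples
#' levenshtein("GGTC", "GTTC")  # 1
#' @export
levenshtein <- function(a, b) {
  stopifnot(is.character(a), length(a) == 1L, is.character(b), length(b) == 1L)
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  la <- length(ca); lb <- length(cb)
  if (la == 0L || lb == 0L) return(max(la, lb))
  prev <- 0:lb
  for (i in seq_len(la)) {
    cur <- integer(lb + 1L)
    cur[1L] <- i
    for (j in seq_len(lb)) {
      cur[j + 1L] <- min(prev[j] + (ca[i] != cb[j]),
                         prev[j + 1L] + 1L,
                         cur[j] + 1L)
    }
    prev <- cur
  }
  as.integer(prev[lb + 1L])
}

read_base_class <- function(chars) {
  cl <- match(chars, c("A", "C", "G", "T"))
  cl[is.na(cl)] <- 5L
  cl
}

# Full-matrix reference implementation of the (extended) k-difference
# search. Computes every cell of the (m+1) x (n+1) matrix with the same
# start/penalty propagation conventions as the cutoff search, and is kept
# permanently as the independent test oracle for find_matches().
oracle_dp <- function(read, pattern, params = search_params(), qual = NULL,
                      penalty = penalty_params()) {
  pattern <- as_pattern(pattern)
  n <- nchar(read); m <- pattern$length
  stopifnot(n >= 1L)
  weighted <- !is.null(qual)
  if (weighted && length(qual) != n)
    stop("quality vector length does not match read length")
  k <- effective_k(n, m, params)

  # mismatch lookup: m x 5 (A C G T N)
  mm <- matrix(TRUE, m, 5L)
  for (bi in seq_along(c("A", "C", "G", "T", "N"))) {
    b <- c("A", "C", "G", "T", "N")[bi]
    mm[, bi] <- seq_len(m) %in% (pattern$mismatch_masks[[b]] + 1L)
  }
  rchars <- strsplit(toupper(read), "")[[1]]
  rclass <- read_base_class(rchars)
  lut <- penalty_lut(penalty)
  mispen <- if (weighted) {
    ifelse(rclass == 5L, penalty$p_min,
           lut[pmin(pmax(qual, 0L), length(lut) - 1L) + 1L])
  } else rep(0, n)

  C <- matrix(0L, m + 1L, n + 1L)
  S <- matrix(0L, m + 1L, n + 1L)
  W <- matrix(0, m + 1L, n + 1L)
  D <- matrix(0L, m, n)  # mismatch indicators actually used
  C[, 1L] <- 0:m
  S[, 1L] <- 0L
  W[, 1L] <- (0:m) * penalty$delta
  S[1L, ] <- 0:n

  for (j in seq_len(n)) {
    cj <- j + 1L
    for (i in seq_len(m)) {
      ci <- i + 1L
      d <- mm[i, rclass[j]]
      D[i, j] <- as.integer(d)
      if (!d) {
        C[ci, cj] <- C[ci - 1L, cj - 1L]
        S[ci, cj] <- S[ci - 1L, cj - 1L]
        W[ci, cj] <- W[ci - 1L, cj - 1L]
      } else {
        diag <- C[ci - 1L, cj - 1L] + 1L
        up <- C[ci - 1L, cj] + 1L
        left <- C[ci, cj - 1L] + 1L
        v <- min(diag, up, left)
        C[ci, cj] <- v
        S[ci, cj] <- if (diag == v) S[ci - 1L, cj - 1L]
                     else if (up == v) S[ci - 1L, cj]
                     else S[ci, cj - 1L]
        w <- Inf
        if (diag == v) w <- min(w, W[ci - 1L, cj - 1L] + mispen[j])
        if (up == v)   w <- min(w, W[ci - 1L, cj] + penalty$delta)
        if (left == v) w <- min(w, W[ci, cj - 1L] + penalty$delta)
        W[ci, cj] <- w
      }
    }
  }

  lac <- apply(C, 2L, function(col) {
    live <- which(col <= k)
    max(live) - 1L
  })

  list(C = C, S = S, W = W, delta = D, lac_per_column = lac, k = k,
       n = n, m = m, weighted = weighted)
}

oracle_candidates <- function(dp, params) {
  n <- dp$n; m <- dp$m; k <- dp$k
  hits <- which(dp$C[m + 1L, -1L] <= k)
  out <- list(
    start = dp$S[m + 1L, hits + 1L],
    end = as.integer(hits),
    differences = dp$C[m + 1L, hits + 1L],
    penalty = if (dp$weighted) dp$W[m + 1L, hits + 1L] else rep(0, length(hits)),
    matched_pattern_length = rep(m, length(hits))
  )
  sl <- integer(0); el <- integer(0); dl <- integer(0); wl <- numeric(0)
  ml <- integer(0)
  last <- dp$C[, n + 1L]
  for (i in seq_len(m - 1L)) {
    v <- last[i + 1L]
    if (v > k) next
    L <- n - dp$S[i + 1L, n + 1L]
    if (L < params$min_overlap) next
    if (v > floor_ratio(L * params$error_ratio)) next
    sl <- c(sl, dp$S[i + 1L, n + 1L]); el <- c(el, n)
    dl <- c(dl, v)
    wl <- c(wl, if (dp$weighted) dp$W[i + 1L, n + 1L] else 0)
    ml <- c(ml, i)
  }
  data.frame(
    start = as.integer(c(out$start, sl)),
    end = as.integer(c(out$end, el)),
    differences = as.integer(c(out$differences, dl)),
    penalty = as.numeric(c(out$penalty, wl)),
    matched_pattern_length = as.integer(c(out$matched_pattern_length, ml))
  )
}

#' Reference (full-matrix) k-difference search
#'
#' Computes the complete dynamic programming matrix and reports every
#' full-pattern occurrence with at most k differences plus every 3' suffix
#' overlap within the error-ratio bound. Quadratic in time and space; used
#' as the ground truth that the cutoff search [find_matches()] is tested
#' against, and useful for inspecting the matrix itself (see
#' [oracle_matrix()]).
#'
#' @param read Nucleotide string (length >= 1).
#' @param pattern An [build_pattern()] object or adapter string.
#' @param params [search_params()].
#' @param qual Optional integer Phred qualities (same length as `read`);
#'   when supplied, candidates carry quality-weighted penalties.
#' @param penalty [penalty_params()].
#' @return data.frame with columns `start`, `end` (0-based, half-open),
#'   `differences`, `penalty`, `matched_pattern_length`.
#' @export
oracle_find <- function(read, pattern, params = search_params(),
                        qual = NULL, penalty = penalty_params()) {
  dp <- oracle_dp(read, pattern, params, qual, penalty)
  oracle_candidates(dp, params)
}

#' Full dynamic programming matrix of the reference search
#'
#' @inheritParams oracle_find
#' @return List with the (m+1) x (n+1) cost matrix `C`, the mismatch
#'   indicator matrix `delta`, the last-active-cell index per column
#'   `lac_per_column` (0-based rows), the alignment-start matrix `S`, the
#'   penalty matrix `W`, and the threshold `k`.
#' @export
oracle_matrix <- function(read, pattern, params = search_params(),
                          qual = NULL, penalty = penalty_params()) {
  dp <- oracle_dp(read, pattern, params, qual, penalty)
  dp[c("C", "delta", "lac_per_column", "S", "W", "k")]
}

search_result <- function(res) {
  df <- data.frame(
    start = as.integer(res$start),
    end = as.integer(res$end),
    differences = as.integer(res$differences),
    penalty = as.numeric(res$penalty),
    matched_pattern_length = as.integer(res$matched_pattern_length)
  )
  attr(df, "k") <- res$k
  attr(df, "mean_active") <- res$mean_active
  df
}

#' Bit-masked k-difference search (Ukkonen cutoff)
#'
#' Finds every substring of `read` within k unit-cost differences of the
#' full pattern, and every read suffix matching a pattern prefix within the
#' error-ratio bound (`floor(L * error_ratio)` differences for an aligned
#' suffix of length L, at least `min_overlap` long). The column vector is
#' maintained as a queue of the active cells above the cutoff boundary;
#' matched cells copy their diagonal precursor without recomputation and
#' cells that exceed k are masked dead and never revisited. Expected
#' O(k n) time, O(m) space.
#'
#' @inheritParams oracle_find
#' @return data.frame as in [oracle_find()], with attributes `k` (the
#'   effective threshold) and `mean_active` (mean live cells per column,
#'   the sparsity the cutoff achieves).
#' @examples
#' find_matches("TTACGTTT", build_pattern("ACGT"),
#'              search_params(max_differences = 0))
#' @export
find_matches <- function(read, pattern, params = search_params()) {
  pattern <- as_pattern(pattern)
  res <- kdiff_search_cpp(toupper(read), integer(0), pattern$sequence,
                          params$error_ratio, params$min_overlap,
                          if (is.null(params$max_differences)) -1L
                          else params$max_differences,
                          numeric(1), 0, 0)
  search_result(res)
}

#' Quality-weighted k-difference search
#'
#' Identical candidate set to [find_matches()] (admissibility is governed by
#' the unit-cost difference count), but each candidate carries the minimum
#' accumulated quality penalty among equal-difference alignments ending at
#' its position: `P(q)` per mismatched read base (see [mismatch_penalty()]),
#' `delta` per indel, and the mismatch floor `P_min` for 'N' calls.
#'
#' @inheritParams oracle_find
#' @param qual Integer Phred qualities, same length as `read`.
#' @export
find_weighted_matches <- function(read, qual, pattern,
                                  params = search_params(),
                                  penalty = penalty_params()) {
  pattern <- as_pattern(pattern)
  if (length(qual) != nchar(read))
    stop("quality vector length (", length(qual),
         ") does not match read length (", nchar(read), ")")
  res <- kdiff_search_cpp(toupper(read), as.integer(qual), pattern$sequence,
                          params$error_ratio, params$min_overlap,
                          if (is.null(params$max_differences)) -1L
                          else params$max_differences,
                          penalty_lut(penalty), penalty$p_min, penalty$delta)
  search_result(res)
}
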