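#' Quality penalty parameters
#'
#' The mismatch penalty scheme on the -log10 scale: a mismatch against a
#' base called with Phred quality q costs `P(q)`, the negative log
#' probability that the base is actually a match given the sequencing error
#' model (see [mismatch_penalty()]). `P_min = -log10(1/3)` is the floor (a
#' wholly uninformative call still disagrees), `P_max = -log10(10^(40/-10)/3)`
#' the ceiling reached at q = 40, and indels cost a flat `delta = P_max`.
#'
#' @param delta Indel penalty; defaults to `P_max`.
#' @param quality_cap Quality at which the penalty saturates (40).
#' @return List of class `penalty_params` with `p_min`, `p_max`, `delta`,
#'   `quality_cap`.
#' @export
penalty_params <- function(delta = NULL, quality_cap = 40L) {
  p_min <- -log10(1 / 3)
  p_max <- -log10(10^(quality_cap / (-10)) / 3)
  if (is.null(delta)) delta <- p_max
  stopifnot(delta >= 0)
  structure(list(p_min = p_min, p_max = p_max, delta = delta,
                 quality_cap = as.integer(quality_cap)),
            class = "penalty_params")
}

#' Mismatch penalty as a function of base-call quality
#'
#' Piecewise-linear in q between the floor and ceiling:
#' `P(q) = P_min` for q <= 0, `P_min + q/40 * (P_max - P_min)` for
#' 0 < q < 40, and `P_max` for q >= 40. On the open interval this equals
#' the closed form `-log10(10^(q/-10) / 3)`: the negative log probability
#' that the base is truly a match (sequencing error to one of three
#' alternatives) given error probability `10^(-q/10)`.
#'
#' @param q Integer Phred quality (vectorised; any integers accepted).
#' @param params [penalty_params()].
#' @return Numeric penalties in `[P_min, P_max]`.
#' @examples
#' mismatch_penalty(20)  # -log10(10^(-2)/3) = 2.4771...
#' @export
mismatch_penalty <- function(q, params = penalty_params()) {
  cap <- params$quality_cap
  frac <- pmin(pmax(q / cap, 0), 1)
  params$p_min + frac * (params$p_max - params$p_min)
}

# penalty lookup by integer quality 0..93 (Phred+33 printable range)
penalty_lut <- function(params = penalty_params()) {
  mismatch_penalty(0:93, params)
}

#' Alignment fitness score of a sequence span against a target
#'
#' `pscore(x, y) = |x| * P_max - penalty(x, y)`, where `penalty(x, y)` is
#' the minimum accumulated penalty of aligning all of `x` against a prefix
#' of `y` (the unaligned tail of `y` is free): quality-weighted mismatch
#' penalties plus `delta` per indel. The maximum `|x| * P_max` is attained
#' exactly when `x` matches (a prefix of) `y` without differences; an empty
#' `x` scores 0. When `qy` is supplied (aligning one read span against
#' another), a mismatch is charged at the smaller of the two base qualities
#' - the lower-confidence call most plausibly explains the disagreement.
#'
#' @param x Query span (e.g. a read tail or retained prefix).
#' @param y Target (adapter sequence, IUPAC allowed, or another read span).
#' @param qx Integer Phred qualities for `x` (same length).
#' @param params [penalty_params()].
#' @param qy Optional qualities for `y`.
#' @return Numeric score `<= |x| * P_max`.
#' @export
pscore <- function(x, y, qx, params = penalty_params(), qy = NULL) {
  if (length(qx) != nchar(x))
    stop("quality vector length (", length(qx),
         ") does not match sequence length (", nchar(x), ")")
  if (nchar(x) == 0L) return(0)
  al <- penalty_align_cpp(toupper(x), as.integer(qx), toupper(y),
                          if (is.null(qy)) integer(0) else as.integer(qy),
                          penalty_lut(params), params$p_min, params$delta)
  nchar(x) * params$p_max - al$penalty
}

# penalty + unit differences of x vs a prefix of y (shared kernel)
prefix_align <- function(x, qx, y, params, qy = NULL) {
  if (nchar(x) == 0L) return(list(penalty = 0, differences = 0L))
  penalty_align_cpp(toupper(x), as.integer(qx), toupper(y),
                    if (is.null(qy)) integer(0) else as.integer(qy),
                    penalty_lut(params), params$p_min, params$delta)
}
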