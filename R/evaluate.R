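#' Confusion counts for trimming evaluation
#'
#' The six categories a read can fall into when its trimmed length is
#' compared with the ground truth: `TP` (contaminated, trimmed at the true
#' boundary), `FP_ft` (clean but trimmed - false trimming), `FP_ot`
#' (contaminated, over-trimmed), `FN_fr` (contaminated, untrimmed - false
#' retaining), `FN_ut` (contaminated, under-trimmed), `TN` (clean,
#' untrimmed). `FP = FP_ft + FP_ot`, `FN = FN_fr + FN_ut`.
#'
#' @param TP,FP_ft,FP_ot,FN_fr,FN_ut,TN Non-negative integer counts.
#' @return List of class `confusion_counts` with the six categories plus
#'   derived `FP`, `FN` and `total`.
#' @export
confusion_counts <- function(TP = 0L, FP_ft = 0L, FP_ot = 0L,
                             FN_fr = 0L, FN_ut = 0L, TN = 0L) {
  v <- vapply(list(TP, FP_ft, FP_ot, FN_fr, FN_ut, TN), function(x) {
    x <- as.numeric(x)
    stopifnot(length(x) == 1L, x >= 0)
    x
  }, numeric(1))
  names(v) <- c("TP", "FP_ft", "FP_ot", "FN_fr", "FN_ut", "TN")
  structure(c(as.list(v),
              list(FP = v[["FP_ft"]] + v[["FP_ot"]],
                   FN = v[["FN_fr"]] + v[["FN_ut"]],
                   total = sum(v))),
            class = "confusion_counts")
}

#' Classify one read against its ground truth
#'
#' @param contaminated Logical (or 0/1): does the read truly carry adapter?
#' @param true_trim_index True boundary (NA for clean reads).
#' @param observed_length Length of the read after trimming.
#' @param read_length Original (untrimmed) read length.
#' @param tolerance Allowed deviation (bp) from the true boundary still
#'   counted as correct; default 0 (exact).
#' @return One of `"TP"`, `"FP_ft"`, `"FP_ot"`, `"FN_fr"`, `"FN_ut"`,
#'   `"TN"`.
#' @export
classify_read <- function(contaminated, true_trim_index, observed_length,
                          read_length, tolerance = 0L) {
  stopifnot(tolerance >= 0L)
  if (observed_length > read_length)
    stop("observed length (", observed_length,
         ") exceeds the original read length (", read_length, ")")
  if (contaminated) {
    if (abs(observed_length - true_trim_index) <= tolerance) return("TP")
    if (observed_length == read_length) return("FN_fr")
    if (observed_length < true_trim_index - tolerance) return("FP_ot")
    return("FN_ut")
  }
  if (observed_length < read_length) return("FP_ft") else return("TN")
}

#' Classify a whole dataset
#'
#' @param manifest Ground-truth data.frame (`read_id`, `insert_length`,
#'   `true_trim_index`, `contaminated`).
#' @param observed data.frame with `read_id` and `output_length`; reads
#'   present in the manifest but absent here (e.g. removed by a length
#'   filter) are scored with observed length 0.
#' @param read_length Original read length.
#' @param tolerance See [classify_read()].
#' @return [confusion_counts()].
#' @export
classify_reads <- function(manifest, observed, read_length, tolerance = 0L) {
  obs <- observed$output_length[match(manifest$read_id, observed$read_id)]
  obs[is.na(obs)] <- 0L
  if (any(obs > read_length))
    stop("observed length exceeds the original read length")
  contaminated <- manifest$contaminated == 1L
  tti <- manifest$true_trim_index
  cat <- character(nrow(manifest))
  tp <- contaminated & abs(obs - tti) <= tolerance
  fn_fr <- contaminated & !tp & obs == read_length
  fp_ot <- contaminated & !tp & !fn_fr & obs < tti - tolerance
  fn_ut <- contaminated & !tp & !fn_fr & !fp_ot
  fp_ft <- !contaminated & obs < read_length
  tn <- !contaminated & !fp_ft
  confusion_counts(TP = sum(tp), FP_ft = sum(fp_ft), FP_ot = sum(fp_ot),
                   FN_fr = sum(fn_fr), FN_ut = sum(fn_ut), TN = sum(tn))
}

#' Trimming quality metrics
#'
#' Positive predictive value `PPV = TP / (TP + FP_ft + FP_ot + FN_ut)`
#' (note the denominator counts under-trimmed reads: any read whose
#' boundary was moved wrongly counts against precision), sensitivity
#' `Sen = TP / (TP + FN_fr + FN_ut + FP_ot)`, specificity
#' `Spec = TN / (TN + FP_ft)`, and the Matthews correlation coefficient
#' `mCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' A metric whose denominator is zero is reported as NA.
#'
#' @param counts [confusion_counts()].
#' @return List of class `metric_set`: `PPV`, `Sen`, `Spec` in `[0, 1]`,
#'   `mCC` in `[-1, 1]` (NA where undefined).
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$total == 0) stop("no reads to evaluate (all counts zero)")
  sdiv <- function(num, den) if (den > 0) num / den else NA_real_
  ppv <- sdiv(counts$TP, counts$TP + counts$FP_ft + counts$FP_ot +
                           counts$FN_ut)
  sen <- sdiv(counts$TP, counts$TP + counts$FN_fr + counts$FN_ut +
                           counts$FP_ot)
  spec <- sdiv(counts$TN, counts$TN + counts$FP_ft)
  denom <- (counts$TP + counts$FP) * (counts$TP + counts$FN) *
           (counts$TN + counts$FP) * (counts$TN + counts$FN)
  mcc <- if (denom > 0)
    (counts$TP * counts$TN - counts$FP * counts$FN) / sqrt(denom)
  else NA_real_
  structure(list(PPV = ppv, Sen = sen, Spec = spec, mCC = mcc),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.4f", v)
  cat("PPV = ", fmt(x$PPV), "  Sen = ", fmt(x$Sen),
      "  Spec = ", fmt(x$Spec), "  mCC = ", fmt(x$mCC), "\n", sep = "")
  invisible(x)
}

#' ROC sweep over trimming stringencies
#'
#' Re-runs the trimmer on a simulated dataset at each error ratio in the
#' grid, classifies every read against the manifest, and reports the false
#' positive rate `FPR = FP / (FP + TN)` and the true positive rate
#' (sensitivity) per stringency.
#'
#' @param sim Output of [simulate_dataset()] (or a compatible list with
#'   `reads1`, `reads2`, `manifest`).
#' @param grid Numeric vector of error ratios in `[0, 1)`.
#' @param mode `"se"` or `"pe"`.
#' @param adapter1,adapter2 Adapters (default: the simulation's).
#' @param min_overlap,tolerance Passed through to the trimmer / classifier.
#' @return data.frame with columns `e`, `FP`, `TP`, `FPR`, `TPR`, sorted
#'   by `e`.
#' @export
roc_sweep <- function(sim, grid, mode = c("pe", "se"),
                      adapter1 = NULL, adapter2 = NULL,
                      min_overlap = 3L, tolerance = 0L) {
  mode <- match.arg(mode)
  stopifnot(length(grid) >= 1L, all(grid >= 0), all(grid < 1))
  if (is.null(adapter1)) adapter1 <- sim$config$adapter1
  if (is.null(adapter2)) adapter2 <- sim$config$adapter2
  p1 <- build_pattern(adapter1); p2 <- build_pattern(adapter2)
  rl <- sim$config$read_length
  grid <- sort(grid)
  rows <- lapply(grid, function(e) {
    params <- search_params(error_ratio = e, min_overlap = min_overlap)
    obs <- if (mode == "pe") {
      tp <- trim_pairs(sim$reads1, sim$reads2, p1, p2, params)
      rbind(tp$decisions1[, c("read_id", "output_length")],
            tp$decisions2[, c("read_id", "output_length")])
    } else {
      d1 <- trim_reads(sim$reads1, p1, params)$decisions
      d2 <- trim_reads(sim$reads2, p2, params)$decisions
      rbind(d1[, c("read_id", "output_length")],
            d2[, c("read_id", "output_length")])
    }
    cc <- classify_reads(sim$manifest, obs, rl, tolerance)
    met <- compute_metrics(cc)
    data.frame(e = e, FP = cc$FP, TP = cc$TP,
               FPR = if (cc$FP + cc$TN > 0) cc$FP / (cc$FP + cc$TN)
                     else NA_real_,
               TPR = met$Sen)
  })
  do.call(rbind, rows)
}
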