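#' Standard adapter defaults used by the simulator
#'
#' TruSeq-style indexed adapter starts as read out at the 3' end of mate 1
#' and mate 2, and the Nextera transposase mosaic-end sequence used as the
#' default junction adapter in long-mate-pair simulations.
#' @name sim_adapters
#' @keywords internal
NULL

DEFAULT_ADAPTER1 <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA"
DEFAULT_ADAPTER2 <- "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGT"
DEFAULT_JUNCTION <- "CTGTCTCTTATACACATCT"

#' Fragment-length mean achieving a target contamination fraction
#'
#' Fragments are drawn Normal(mean, sd) (floored to integers, truncated at
#' 0); a read is adapter-contaminated exactly when its fragment is shorter
#' than the read length, so the mean solving
#' `P(L < read_length) = target` is
#' `read_length - qnorm(target) * fragment_sd`.
#'
#' @param target Desired contaminated fraction, in (0, 1).
#' @param read_length Read length (nt).
#' @param fragment_sd Fragment-length standard deviation (nt).
#' @return The fragment mean (nt).
#' @export
solve_contamination_fraction <- function(target, read_length, fragment_sd) {
  stopifnot(target > 0, target < 1, read_length >= 1, fragment_sd >= 0)
  read_length - qnorm(target) * fragment_sd
}

#' Simulation configuration
#'
#' Defines a paired-end (or long-mate-pair) sequencing experiment over a
#' uniform-random reference: fragment positions uniform, lengths
#' truncated-normal, read-through into the adapter whenever the fragment is
#' shorter than the read, followed by random filler. The defaults emulate a
#' 100 bp + 100 bp paired-end run in which about 36% of reads carry
#' adapter sequence, with flat Q25 qualities and quality-driven
#' substitution errors.
#'
#' @param n_pairs Number of read pairs.
#' @param read_length Read length (nt).
#' @param genome_length Length of the random reference (nt).
#' @param contamination Target contaminated fraction used to place the
#'   fragment-length mean when `fragment_mean` is NULL.
#' @param fragment_mean Fragment mean (nt); overrides `contamination`.
#' @param fragment_sd Fragment standard deviation (nt).
#' @param adapter1,adapter2 Adapter read out after mate-1 / mate-2 inserts.
#' @param junction Junction adapter (LMP mode).
#' @param error_model `"error_free"` or `"quality_driven"` (substitution
#'   probability `10^(-q/10)` per base, applied to insert, adapter and
#'   filler alike).
#' @param mean_quality Flat per-base Phred quality.
#' @param mode `"PE"` (read-through pairs) or `"LMP"` (junction-bearing
#'   pairs, no read-through).
#' @param motif Optional adapter-like motif planted in the reference to
#'   study homology-driven false positives.
#' @param motif_copies Number of planted copies.
#' @param seed Integer RNG seed; identical configs give identical output.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_pairs = 5000L, read_length = 100L,
                       genome_length = 100000L, contamination = 0.36,
                       fragment_mean = NULL, fragment_sd = 50,
                       adapter1 = DEFAULT_ADAPTER1,
                       adapter2 = DEFAULT_ADAPTER2,
                       junction = DEFAULT_JUNCTION,
                       error_model = c("quality_driven", "error_free"),
                       mean_quality = 25L,
                       mode = c("PE", "LMP"),
                       motif = NULL, motif_copies = 0L,
                       seed = 1L) {
  error_model <- match.arg(error_model)
  mode <- match.arg(mode)
  stopifnot(n_pairs >= 1L, read_length >= 1L, fragment_sd >= 0,
            genome_length >= read_length)
  if (is.null(fragment_mean))
    fragment_mean <- solve_contamination_fraction(contamination, read_length,
                                                  fragment_sd)
  if (mode == "LMP" && is.null(junction))
    stop("LMP mode requires a junction sequence")
  structure(list(
    n_pairs = as.integer(n_pairs), read_length = as.integer(read_length),
    genome_length = as.integer(genome_length),
    fragment_mean = fragment_mean, fragment_sd = fragment_sd,
    adapter1 = toupper(adapter1), adapter2 = toupper(adapter2),
    junction = if (is.null(junction)) NULL else toupper(junction),
    error_model = error_model, mean_quality = as.integer(mean_quality),
    mode = mode, motif = motif, motif_copies = as.integer(motif_copies),
    seed = as.integer(seed)
  ), class = "sim_config")
}

random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

apply_errors <- function(seq, q) {
  n <- nchar(seq)
  if (n == 0L) return(seq)
  p <- 10^(-q / 10)
  hit <- which(runif(n) < p)
  if (length(hit) == 0L) return(seq)
  chars <- strsplit(seq, "")[[1]]
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

pad_read <- function(core, adapter, read_length) {
  need <- read_length - nchar(core)
  if (need <= 0L) return(substr(core, 1L, read_length))
  ad <- substr(adapter, 1L, need)
  fill <- random_dna(need - nchar(ad))
  paste0(core, ad, fill)
}

#' Simulate a paired dataset with ground truth
#'
#' Generates a uniform-random reference and draws read pairs according to
#' the configuration. In PE mode mate 1 reads the fragment's forward
#' strand and mate 2 its reverse complement; fragments shorter than the
#' read length run through into the adapter and then random filler, and the
#' manifest records the true trim index (= insert length). In LMP mode
#' each mate carries the junction adapter at a uniformly placed internal
#' position (the junction always fits entirely inside the read) and the
#' manifest's true trim index is the junction start. Identical
#' configurations (including seed) give identical output.
#'
#' @param config A [sim_config()].
#' @return List with `reads1`, `reads2` (data.frames with `id`, `seq`,
#'   `qual` encoded at Phred+33) and `manifest` (one row per read:
#'   `read_id`, `insert_length`, `true_trim_index`, `contaminated`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  rl <- config$read_length
  genome <- random_dna(config$genome_length)
  if (!is.null(config$motif) && config$motif_copies > 0L) {
    for (i in seq_len(config$motif_copies)) {
      at <- sample.int(config$genome_length - nchar(config$motif), 1L)
      substr(genome, at, at + nchar(config$motif) - 1L) <- config$motif
    }
  }
  n <- config$n_pairs
  q <- config$mean_quality
  qual_str <- encode_quals(rep(q, rl), 33L)
  seqs1 <- character(n); seqs2 <- character(n)
  ins <- integer(n); trim1 <- integer(n); trim2 <- integer(n)

  if (config$mode == "PE") {
    flen <- pmax(0L, as.integer(floor(rnorm(n, config$fragment_mean,
                                            config$fragment_sd))))
    flen <- pmin(flen, config$genome_length)
    for (i in seq_len(n)) {
      fl <- flen[i]
      at <- sample.int(config$genome_length - max(fl, 1L) + 1L, 1L)
      frag <- substr(genome, at, at + fl - 1L)
      seqs1[i] <- pad_read(frag, config$adapter1, rl)
      seqs2[i] <- pad_read(revcomp(frag), config$adapter2, rl)
      ins[i] <- fl
      trim1[i] <- trim2[i] <- if (fl < rl) fl else NA_integer_
    }
  } else {
    jl <- nchar(config$junction)
    if (jl >= rl) stop("junction must be shorter than the read length")
    for (i in seq_len(n)) {
      for (mate in 1:2) {
        jpos <- sample.int(rl - jl + 1L, 1L) - 1L  # 0 .. rl - jl
        gl <- rl - jl - jpos
        at <- sample.int(config$genome_length - rl + 1L, 1L)
        pre <- substr(genome, at, at + jpos - 1L)
        post <- if (gl > 0L) substr(genome, at + jpos, at + jpos + gl - 1L)
                else ""
        s <- paste0(pre, config$junction, post)
        if (mate == 1) { seqs1[i] <- s; trim1[i] <- jpos }
        else { seqs2[i] <- s; trim2[i] <- jpos }
      }
      ins[i] <- NA_integer_
    }
  }

  if (config$error_model == "quality_driven") {
    for (i in seq_len(n)) {
      seqs1[i] <- apply_errors(seqs1[i], q)
      seqs2[i] <- apply_errors(seqs2[i], q)
    }
  }

  ids <- sprintf("sim%06d", seq_len(n))
  reads1 <- data.frame(id = paste0(ids, "/1"), seq = seqs1, qual = qual_str)
  reads2 <- data.frame(id = paste0(ids, "/2"), seq = seqs2, qual = qual_str)
  attr(reads1, "phred_offset") <- 33L
  attr(reads2, "phred_offset") <- 33L
  tti <- c(rbind(trim1, trim2))
  ivec <- if (config$mode == "PE") rep(ins, each = 2L) else tti
  manifest <- data.frame(
    read_id = c(rbind(reads1$id, reads2$id)),
    insert_length = ivec,
    true_trim_index = tti,
    contaminated = as.integer(!is.na(tti))
  )
  list(reads1 = reads1, reads2 = reads2, manifest = manifest,
       config = config)
}

#' Write / read a ground-truth manifest
#'
#' Tab-separated with a header; `true_trim_index` is empty for clean reads.
#' @param manifest data.frame as produced by [simulate_dataset()].
#' @param path File path.
#' @export
write_manifest <- function(manifest, path) {
  out <- manifest
  out$true_trim_index <- ifelse(is.na(out$true_trim_index), "",
                                as.character(out$true_trim_index))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(nrow(manifest))
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "integer", "integer",
                                         "integer"),
                          na.strings = "")
  df
}
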