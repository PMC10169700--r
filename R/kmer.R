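## K-mer survey genome-size estimation:
## genome size = total k-mer number / k-mer depth.

#' Build a canonical k-mer multiplicity histogram from reads
#'
#' Every length-k window free of N contributes its canonical form (the
#' lexicographic minimum of the k-mer and its reverse complement), so both
#' strands count together.
#'
#' @param reads character vector of read sequences, or a path to a
#'   FASTA/FASTQ file.
#' @param k k-mer size (default 17).
#' @return a \code{kmer_histogram}: data.frame (\code{multiplicity},
#'   \code{n_kmers}) plus \code{k}, \code{total_kmers},
#'   \code{distinct_kmers} attributes.
#' @export
build_kmer_histogram <- function(reads, k = 17L) {
  k <- as.integer(k)
  stopifnot(k >= 1L)
  if (length(reads) == 1L && file.exists(reads)) reads <- read_reads(reads)
  res <- count_canonical_kmers(reads, k)
  h <- data.frame(multiplicity = res$multiplicity, n_kmers = res$n_kmers)
  structure(h, k = k, total_kmers = res$total_kmers,
            distinct_kmers = res$distinct_kmers,
            class = c("kmer_histogram", "data.frame"))
}

## Read sequences from FASTA or FASTQ (plain text).
read_reads <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, ">")) {
    unname(read_fasta(path))
  } else if (startsWith(first, "@")) {
    lines <- readLines(path)
    if (length(lines) %% 4L != 0L)
      format_error("FASTQ file %s: line count not a multiple of 4", path)
    toupper(lines[seq(2L, length(lines), by = 4L)])
  } else format_error("unrecognized reads format: %s", path)
}

#' Estimate genome size from a k-mer histogram
#'
#' Applies \code{genome size = total k-mer number / k-mer depth} after
#' excluding k-mers below an error cutoff. Depth is the histogram peak
#' (mode of the multiplicity distribution above the cutoff, robust to
#' error k-mers) or the coverage-weighted mean multiplicity, matching the
#' literal averaging formula.
#'
#' @param histogram a \code{kmer_histogram}.
#' @param depth_mode \code{"histogram_peak"} (default) or \code{"mean"}.
#' @param error_cutoff minimum multiplicity retained; \code{NULL} (default)
#'   uses the first local minimum of the histogram (the error trough), or 1
#'   when the histogram has no trough.
#' @return a \code{kmer_survey_estimate}: \code{genome_size_bp},
#'   \code{depth}, \code{depth_mode_used}, \code{error_cutoff},
#'   \code{total_kmers_used}.
#' @export
estimate_genome_size <- function(histogram,
                                 depth_mode = c("histogram_peak", "mean"),
                                 error_cutoff = NULL) {
  depth_mode <- match.arg(depth_mode)
  if (nrow(histogram) == 0L) stop("empty k-mer histogram")
  h <- histogram[order(histogram$multiplicity), , drop = FALSE]
  if (is.null(error_cutoff)) {
    # first local minimum of the observed histogram (the error trough)
    error_cutoff <- 1L
    if (nrow(h) > 1L) {
      rise <- which(diff(h$n_kmers) > 0)
      if (length(rise)) error_cutoff <- h$multiplicity[rise[1L]]
    }
  }
  keep <- h$multiplicity >= error_cutoff
  if (!any(keep)) stop("error cutoff removed every k-mer")
  hk <- h[keep, , drop = FALSE]
  total <- sum(hk$multiplicity * hk$n_kmers)
  depth <- switch(depth_mode,
    histogram_peak = hk$multiplicity[which.max(hk$n_kmers)],
    mean = total / sum(hk$n_kmers))
  if (depth <= 0) stop("estimated depth is zero")
  structure(list(genome_size_bp = total / depth, depth = depth,
                 depth_mode_used = depth_mode,
                 error_cutoff = as.integer(error_cutoff),
                 total_kmers_used = total, k = attr(histogram, "k")),
            class = "kmer_survey_estimate")
}

#' @export
print.kmer_survey_estimate <- function(x, ...) {
  cat(sprintf(paste0("<kmer_survey_estimate> k=%d  depth=%.3g (%s, cutoff ",
                     "%d)  genome size = %.0f bp\n"),
              x$k, x$depth, x$depth_mode_used, x$error_cutoff,
              x$genome_size_bp))
  invisible(x)
}

#' Write a k-mer histogram and estimate to TSV
#'
#' @param histogram a \code{kmer_histogram}.
#' @param estimate a \code{kmer_survey_estimate}.
#' @param hist_path,estimate_path output paths.
#' @export
write_kmer_survey <- function(histogram, estimate, hist_path, estimate_path) {
  write.table(as.data.frame(histogram), hist_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  est <- data.frame(k = estimate$k, depth = estimate$depth,
                    depth_mode = estimate$depth_mode_used,
                    error_cutoff = estimate$error_cutoff,
                    total_kmers_used = estimate$total_kmers_used,
                    genome_size_bp = sprintf("%.10g", estimate$genome_size_bp))
  write.table(est, estimate_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(estimate_path)
}
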