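## Strand-aware promoter windows around the annotated TSS.

#' Promoter window configuration
#'
#' The scan region runs from \code{upstream} bases before the TSS to
#' \code{downstream} bases from the TSS (the TSS base is the first
#' downstream base), realized as a half-open window of total width
#' \code{upstream + downstream}.
#'
#' @param upstream bases strictly upstream of the TSS (default 500).
#' @param downstream bases from the TSS inclusive onwards (default 100).
#' @return a list with elements \code{upstream}, \code{downstream}.
#' @export
promoter_window <- function(upstream = 500L, downstream = 100L) {
  upstream <- as.integer(upstream); downstream <- as.integer(downstream)
  stopifnot(upstream >= 0L, downstream >= 0L, upstream + downstream >= 1L)
  list(upstream = upstream, downstream = downstream)
}

#' Extract promoter windows for every gene
#'
#' For a + strand gene with 0-based TSS \code{t} the genomic interval is
#' \code{[t - upstream, t + downstream)}; for a - strand gene the TSS is the
#' gene's last base and the mirrored interval is extracted and
#' reverse-complemented, so returned sequences read in transcription
#' orientation with the TSS at index \code{upstream} (0-based). Intervals
#' are clipped at chromosome bounds and flagged.
#'
#' @param genome named character vector of chromosome sequences.
#' @param genes gene data.frame from [read_gff3_genes()].
#' @param window a [promoter_window()].
#' @return data.frame with columns \code{gene_id}, \code{chrom}, \code{start},
#'   \code{end} (0-based half-open, forward strand), \code{strand},
#'   \code{clipped}, \code{sequence}.
#' @export
extract_promoters <- function(genome, genes, window = promoter_window()) {
  unknown <- setdiff(unique(genes$chrom), names(genome))
  if (length(unknown))
    stop(sprintf("chromosome '%s' not present in genome", unknown[1L]))
  chrlen <- setNames(nchar(genome), names(genome))
  up <- window$upstream; down <- window$downstream
  plus <- genes$strand == "+"
  tss <- ifelse(plus, genes$start, genes$end - 1L)
  raw_start <- ifelse(plus, tss - up, tss - down + 1L)
  raw_end <- ifelse(plus, tss + down, tss + up + 1L)
  if (any(genes$end > chrlen[genes$chrom]) || any(genes$start < 0L))
    stop("gene outside chromosome bounds")
  start <- pmax(raw_start, 0L)
  end <- pmin(raw_end, chrlen[genes$chrom])
  clipped <- start != raw_start | end != raw_end
  seqs <- substring(genome[genes$chrom], start + 1L, end)
  seqs[!plus] <- revcomp(seqs[!plus])
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = as.integer(start), end = as.integer(end),
             strand = genes$strand, clipped = clipped, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write promoters as FASTA
#'
#' @param promoters data.frame from [extract_promoters()].
#' @param path output FASTA path.
#' @export
write_promoters_fasta <- function(promoters, path) {
  ids <- sprintf("%s %s:%d-%d(%s)%s", promoters$gene_id, promoters$chrom,
                 promoters$start, promoters$end, promoters$strand,
                 ifelse(promoters$clipped, " clipped", ""))
  write_fasta(setNames(promoters$sequence, ids), path)
}
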