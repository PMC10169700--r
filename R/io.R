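## Readers and writers for the standard formats the pipeline touches.
## Coordinate convention: GFF3 is 1-based inclusive on disk; everything
## internal is 0-based half-open. The conversion happens here, once.

format_error <- function(...) {
  stop(structure(class = c("florinet_format_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}

#' Read a FASTA file
#'
#' Sequences are uppercased on read (soft-masking is discarded) and validated
#' against the A/C/G/T/N alphabet.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences; names are record ids.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) format_error("FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) format_error("empty FASTA file: %s", path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) format_error("FASTA record with empty id in %s", path)
  if (anyDuplicated(ids))
    format_error("duplicate FASTA id '%s' in %s", ids[duplicated(ids)][1L], path)
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    i <- which(bad)[1L]
    ch <- regmatches(seqs[i], regexpr("[^ACGTN]", seqs[i]))
    format_error("record '%s' contains illegal character '%s'", ids[i], ch)
  }
  if (any(nchar(seqs) < 1L))
    format_error("record '%s' has an empty sequence", ids[nchar(seqs) < 1L][1L])
  setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read gene records from a GFF3 file
#'
#' Only rows with feature type \code{gene} are consumed; all other rows are
#' ignored. 1-based inclusive coordinates on disk are converted to the
#' package-internal 0-based half-open convention.
#'
#' @param path path to a GFF3 file.
#' @return data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{start} (0-based), \code{end} (half-open exclusive), \code{strand}.
#' @export
read_gff3_genes <- function(path) {
  if (!file.exists(path)) format_error("GFF3 file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  out <- list()
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L)
      format_error("GFF3 line %d: expected 9 tab-separated columns", i)
    if (f[3L] != "gene") next
    start <- suppressWarnings(as.integer(f[4L]))
    end <- suppressWarnings(as.integer(f[5L]))
    if (is.na(start) || is.na(end) || start < 1L)
      format_error("GFF3 line %d: invalid coordinates", i)
    if (end < start)
      format_error("GFF3 line %d: end (%d) < start (%d)", i, end, start)
    if (!f[7L] %in% c("+", "-"))
      format_error("GFF3 line %d: strand must be '+' or '-', got '%s'", i, f[7L])
    m <- regmatches(f[9L], regexpr("(^|;)\\s*ID=[^;]+", f[9L]))
    if (length(m) == 0L)
      format_error("GFF3 line %d: gene row lacks an ID attribute", i)
    id <- sub("^.*ID=", "", m)
    out[[length(out) + 1L]] <-
      data.frame(gene_id = id, chrom = f[1L], start = start - 1L, end = end,
                 strand = f[7L], stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  genes <- do.call(rbind, out)
  if (anyDuplicated(genes$gene_id))
    format_error("duplicate gene id '%s'",
                 genes$gene_id[duplicated(genes$gene_id)][1L])
  rownames(genes) <- NULL
  genes
}

#' Write gene records to GFF3
#'
#' @param genes data.frame as returned by [read_gff3_genes()] (0-based
#'   half-open coordinates).
#' @param path output path.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("%s\tflorinet\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, genes$start + 1L, genes$end, genes$strand,
                     genes$gene_id), con)
  invisible(path)
}

#' Read motif models from a minimal MEME motif file
#'
#' Parses the minimal MEME motif interchange format (version line, optional
#' alphabet/background, \code{MOTIF} blocks with a letter-probability
#' matrix). Rows must sum to 1 within \code{tol}; they are renormalized
#' after validation because published files carry rounded probabilities.
#'
#' @param path path to a MEME motif file.
#' @param tol row-sum tolerance.
#' @return list of motif models: each a list with \code{motif_id},
#'   \code{width}, \code{matrix} (width x 4, columns A,C,G,T), \code{n_sites}.
#' @export
read_meme_motifs <- function(path, tol = 1e-3) {
  if (!file.exists(path)) format_error("MEME motif file not found: %s", path)
  lines <- readLines(path)
  motif_at <- grep("^MOTIF\\b", lines)
  if (length(motif_at) == 0L) format_error("no MOTIF blocks in %s", path)
  motifs <- vector("list", length(motif_at))
  for (k in seq_along(motif_at)) {
    i <- motif_at[k]
    id <- strsplit(trimws(lines[i]), "\\s+")[[1L]][2L]
    if (is.na(id)) format_error("MOTIF line %d lacks an identifier", i)
    j <- i + 1L
    while (j <= length(lines) && !grepl("letter-probability matrix", lines[j]))
      j <- j + 1L
    if (j > length(lines))
      format_error("motif '%s': no letter-probability matrix", id)
    hdr <- lines[j]
    w_decl <- as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", hdr))
    nsites <- if (grepl("nsites=", hdr))
      as.integer(sub(".*nsites=\\s*(\\d+).*", "\\1", hdr)) else NA_integer_
    rows <- list()
    j <- j + 1L
    while (j <= length(lines) &&
           grepl("^\\s*[0-9.eE+-]+(\\s+[0-9.eE+-]+){3}\\s*$", lines[j])) {
      rows[[length(rows) + 1L]] <- as.numeric(strsplit(trimws(lines[j]), "\\s+")[[1L]])
      j <- j + 1L
    }
    if (length(rows) == 0L) format_error("motif '%s': empty matrix", id)
    mat <- do.call(rbind, rows)
    if (!is.na(w_decl) && nrow(mat) != w_decl)
      format_error("motif '%s': matrix has %d rows but w=%d declared",
                   id, nrow(mat), w_decl)
    if (any(mat < 0)) format_error("motif '%s': negative probability", id)
    sums <- rowSums(mat)
    if (any(abs(sums - 1) > tol))
      format_error("motif '%s': row %d sums to %.4f (tolerance %g)",
                   id, which(abs(sums - 1) > tol)[1L], sums[abs(sums - 1) > tol][1L], tol)
    mat <- mat / sums
    colnames(mat) <- DNA_BASES
    motifs[[k]] <- motif_model(id, mat, n_sites = nsites)
  }
  motifs
}

#' Construct a motif model
#'
#' @param motif_id motif identifier.
#' @param matrix width x 4 probability matrix (columns A,C,G,T).
#' @param n_sites optional number of sites the matrix was built from.
#' @return a \code{motif_model} object.
#' @export
motif_model <- function(motif_id, matrix, n_sites = NA_integer_) {
  stopifnot(ncol(matrix) == 4L, nrow(matrix) >= 1L, all(matrix >= 0))
  if (any(abs(rowSums(matrix) - 1) > 1e-6))
    stop("motif matrix rows must sum to 1")
  colnames(matrix) <- DNA_BASES
  structure(list(motif_id = motif_id, width = nrow(matrix),
                 matrix = matrix, n_sites = n_sites),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif_model> %s  width %d  consensus %s\n",
              x$motif_id, x$width, consensus_string(x)))
  invisible(x)
}

#' Consensus string of a motif model
#'
#' @param motif a \code{motif_model}.
#' @return character scalar: the most probable base per column.
#' @export
consensus_string <- function(motif) {
  paste0(DNA_BASES[apply(motif$matrix, 1L, which.max)], collapse = "")
}

#' Write motif models in minimal MEME format
#'
#' @param motifs list of \code{motif_model}s.
#' @param path output path.
#' @param background length-4 background distribution written to the header.
#' @export
write_meme_motifs <- function(motifs, path, background = rep(0.25, 4)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "", "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f", background[1L],
                       background[2L], background[3L], background[4L]), ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s", m$motif_id), con)
    ns <- if (is.na(m$n_sites)) 20L else m$n_sites
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       m$width, ns), con)
    writeLines(apply(m$matrix, 1L, function(r) sprintf("%.6f %.6f %.6f %.6f",
                                                       r[1L], r[2L], r[3L], r[4L])), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Construct a count matrix with condition labels
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param conditions named character vector mapping sample id to condition.
#' @return a \code{count_matrix} object.
#' @export
count_matrix <- function(counts, conditions) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts))) format_error("duplicate gene ids")
  if (any(counts < 0) || any(counts != round(counts)))
    format_error("counts must be nonnegative integers")
  missing <- setdiff(colnames(counts), names(conditions))
  if (length(missing))
    format_error("sample '%s' has no condition label", missing[1L])
  storage.mode(counts) <- "integer"
  structure(list(counts = counts,
                 conditions = conditions[colnames(counts)]),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s:%d", names(table(x$conditions)),
                            table(x$conditions)), collapse = " ")))
  invisible(x)
}

#' Read a gene-by-sample count matrix with condition labels
#'
#' @param path TSV with gene ids in the first column and a header of sample
#'   ids.
#' @param condition_map_path two-column TSV (\code{sample}, \code{condition}).
#' @return a \code{count_matrix} object.
#' @export
read_count_matrix <- function(path, condition_map_path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) format_error("count matrix needs >= 1 sample column")
  genes <- as.character(tab[[1L]])
  if (anyDuplicated(genes))
    format_error("duplicate gene id '%s'", genes[duplicated(genes)][1L])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m)) format_error("non-numeric cell in count matrix")
  bad <- which(m != round(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad))
    format_error("non-integer count at gene '%s', sample '%s'",
                 genes[bad[1L, 1L]], colnames(m)[bad[1L, 2L]])
  rownames(m) <- genes
  cmap <- read.delim(condition_map_path, stringsAsFactors = FALSE)
  conditions <- setNames(as.character(cmap[[2L]]), as.character(cmap[[1L]]))
  count_matrix(m, conditions)
}

#' Write a count matrix and its condition map
#'
#' @param cm a \code{count_matrix}.
#' @param counts_path output TSV for counts.
#' @param conditions_path output TSV for the sample-to-condition map.
#' @export
write_count_matrix <- function(cm, counts_path, conditions_path) {
  tab <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample = names(cm$conditions),
                         condition = unname(cm$conditions)),
              conditions_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(counts_path)
}

#' Read gene sets from a two-column TSV
#'
#' @param path TSV with columns \code{set_name}, \code{gene_id}.
#' @return named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) format_error("empty gene-set table: %s", path)
  sets <- split(as.character(tab[[2L]]), as.character(tab[[1L]]))
  lapply(sets, unique)
}

#' Write gene sets to a two-column TSV
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gene_sets <- function(sets, path) {
  tab <- data.frame(set_name = rep(names(sets), lengths(sets)),
                    gene_id = unlist(sets, use.names = FALSE))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TF-to-motif mapping table
#'
#' @param path TSV with columns \code{tf}, \code{motif_id}.
#' @return data.frame with columns \code{tf}, \code{motif_id}.
#' @export
read_tf_map <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  names(tab)[1:2] <- c("tf", "motif_id")
  tab
}

#' Write a TF-to-motif mapping table
#'
#' @param tf_map data.frame with columns \code{tf}, \code{motif_id}.
#' @param path output path.
#' @export
write_tf_map <- function(tf_map, path) {
  write.table(tf_map[, c("tf", "motif_id")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a TRN edge table
#'
#' Rows are sorted by (tf, target) so equal networks serialize to identical
#' bytes.
#'
#' @param trn a \code{trn} object (see [assemble_trn()]).
#' @param path output TSV path.
#' @export
write_edge_table <- function(trn, path) {
  e <- trn$edges
  cols <- c("tf", "target", "rho", "sign", "n_hits", "motif_hit",
            "coexpressed", "deg_criterion", "floral_criterion")
  if (nrow(e)) {
    e <- e[order(e$tf, e$target), cols, drop = FALSE]
    e$rho <- sprintf("%.10g", e$rho)
  } else {
    e <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  }
  write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TRN edge table written by [write_edge_table()]
#'
#' @param path edge table TSV.
#' @param comparison optional comparison label to attach.
#' @return a \code{trn} object.
#' @export
read_edge_table <- function(path, comparison = NA_character_) {
  e <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(tf = "character", target = "character"))
  for (fl in c("motif_hit", "coexpressed", "deg_criterion", "floral_criterion"))
    e[[fl]] <- as.logical(e[[fl]])
  new_trn(comparison, e)
}

#' Read a precomputed differential-expression table
#'
#' Lets any external DE caller substitute for the built-in NB test.
#'
#' @param path TSV with columns \code{gene_id}, \code{log2_fold_change},
#'   \code{p_value}, \code{fdr}.
#' @param fc_threshold,alpha,criterion thresholds used to set \code{is_deg};
#'   see [de_config()].
#' @return data.frame of DE records.
#' @export
read_de_table <- function(path, fc_threshold = 2, alpha = 0.05,
                          criterion = c("FDR", "raw_p")) {
  criterion <- match.arg(criterion)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "log2_fold_change", "p_value", "fdr")
  if (!all(need %in% names(tab)))
    format_error("DE table must have columns: %s", paste(need, collapse = ", "))
  crit <- if (criterion == "FDR") tab$fdr else tab$p_value
  tab$is_deg <- !is.na(crit) & crit <= alpha &
    abs(tab$log2_fold_change) >= log2(fc_threshold)
  tab
}
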