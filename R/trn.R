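## TRN assembly: motif-supported candidate edges refined by three criteria —
## (i) TF-target coexpression (|Spearman rho| above a threshold),
## (ii) at least one gene of the pair differentially expressed,
## (iii) at least one gene of the pair on the curated floral gene list.

#' TRN assembly configuration
#'
#' @param rho_threshold Spearman correlation threshold (default 0.9).
#' @param rho_mode \code{"absolute"} retains edges with |rho| above the
#'   threshold so negatively correlated (repression-like) pairs survive
#'   (default); \code{"signed"} requires rho itself above the threshold.
#' @param sample_scope \code{"pair_conditions"} computes correlations over
#'   the samples of the two conditions in the comparison (default);
#'   \code{"all_samples"} uses every sample.
#' @param deg_rule character vector of DE comparison names whose DEG calls
#'   satisfy criterion (ii); defaults to both supplied comparisons.
#' @return list of settings.
#' @export
trn_config <- function(rho_threshold = 0.9,
                       rho_mode = c("absolute", "signed"),
                       sample_scope = c("pair_conditions", "all_samples"),
                       deg_rule = NULL) {
  stopifnot(rho_threshold > 0, rho_threshold <= 1)
  list(rho_threshold = rho_threshold, rho_mode = match.arg(rho_mode),
       sample_scope = match.arg(sample_scope), deg_rule = deg_rule)
}

#' Spearman correlation between TFs and all genes
#'
#' Computed on normalized counts with average ranks for ties. Constant
#' expression vectors yield NA (undefined), never 0.
#'
#' @param cm a \code{count_matrix}.
#' @param tf_set character vector of TF gene ids present in the matrix.
#' @param samples optional sample ids restricting the scope (>= 3 required).
#' @return numeric matrix, TFs in rows, all genes in columns; the TF's own
#'   column is NA.
#' @export
compute_coexpression <- function(cm, tf_set, samples = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.null(samples)) samples <- colnames(cm$counts)
  if (length(samples) < 3L) stop("need >= 3 samples in scope")
  norm <- normalize_counts(cm$counts[, samples, drop = FALSE])$normalized
  tf_set <- intersect(tf_set, rownames(norm))
  rho <- suppressWarnings(
    cor(t(norm[tf_set, , drop = FALSE]), t(norm), method = "spearman"))
  rho <- matrix(rho, nrow = length(tf_set),
                dimnames = list(tf_set, rownames(norm)))
  for (tf in tf_set) rho[tf, tf] <- NA_real_   # no self-edges
  rho
}

new_trn <- function(comparison, edges) {
  nodes <- sort(unique(c(edges$tf, edges$target)))
  structure(list(comparison = comparison, edges = edges, nodes = nodes),
            class = "trn")
}

#' @export
print.trn <- function(x, ...) {
  cat(sprintf("<trn> comparison %s: %d nodes, %d edges (%d +, %d -)\n",
              x$comparison, length(x$nodes), nrow(x$edges),
              sum(x$edges$sign == "+"), sum(x$edges$sign == "-")))
  invisible(x)
}

#' Assemble a TRN for one condition comparison
#'
#' A candidate edge (tf, target) exists iff at least one motif hit for the
#' TF's motif lies in the target's promoter. The edge is retained iff
#' criterion (i) the pair is coexpressed per \code{config}, AND (ii) the TF
#' or the target is a DEG in at least one of the comparisons named by
#' \code{config$deg_rule}, AND (iii) the TF or the target is in the floral
#' gene set. Multiple hits collapse to one edge (hit count kept); the edge
#' sign is the sign of rho.
#'
#' @param hits motif hit data.frame from [scan_promoters()].
#' @param rho_table TF x gene matrix from [compute_coexpression()].
#' @param de_list named list of DE data.frames (one per comparison, e.g.
#'   \code{list("I_vs_C" = ..., "F_vs_C" = ...)}).
#' @param tf_map data.frame with columns \code{tf}, \code{motif_id}.
#' @param floral_set character vector of floral-related gene ids.
#' @param config a [trn_config()].
#' @param comparison label for the network (e.g. \code{"C-F"}).
#' @return a \code{trn} object.
#' @export
assemble_trn <- function(hits, rho_table, de_list, tf_map, floral_set,
                         config = trn_config(), comparison = NA_character_) {
  deg_rule <- config$deg_rule %||% names(de_list)
  missing_cmp <- setdiff(deg_rule, names(de_list))
  if (length(missing_cmp))
    stop(sprintf("deg_rule names unknown DE comparison '%s'", missing_cmp[1L]))
  degs <- unique(unlist(lapply(de_list[deg_rule], function(d)
    d$gene_id[d$is_deg])))
  empty <- data.frame(tf = character(), target = character(),
                      rho = numeric(), sign = character(),
                      n_hits = integer(), motif_hit = logical(),
                      coexpressed = logical(), deg_criterion = logical(),
                      floral_criterion = logical(), stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(new_trn(comparison, empty))

  mapped <- tf_map[tf_map$motif_id %in% hits$motif_id |
                     tf_map$tf %in% rownames(rho_table), , drop = FALSE]
  unmapped_tfs <- setdiff(rownames(rho_table), tf_map$tf)
  if (length(unmapped_tfs))
    warning(sprintf("%d TF(s) without a mapped motif excluded (e.g. '%s')",
                    length(unmapped_tfs), unmapped_tfs[1L]))
  motif_of <- setNames(tf_map$motif_id, tf_map$tf)

  edges <- empty
  for (tf in intersect(rownames(rho_table), names(motif_of))) {
    h <- hits[hits$motif_id == motif_of[[tf]] & hits$gene_id != tf, ,
              drop = FALSE]
    if (nrow(h) == 0L) next
    tgt_hits <- table(h$gene_id)
    for (target in names(tgt_hits)) {
      if (!target %in% colnames(rho_table)) next
      rho <- rho_table[tf, target]
      if (is.na(rho)) next                     # undefined rho: edge dropped
      coex <- if (config$rho_mode == "absolute")
        abs(rho) > config$rho_threshold else rho > config$rho_threshold
      deg_ok <- (tf %in% degs) || (target %in% degs)
      flo_ok <- (tf %in% floral_set) || (target %in% floral_set)
      if (coex && deg_ok && flo_ok)
        edges <- rbind(edges, data.frame(
          tf = tf, target = target, rho = rho,
          sign = if (rho >= 0) "+" else "-",
          n_hits = as.integer(tgt_hits[[target]]),
          motif_hit = TRUE, coexpressed = TRUE, deg_criterion = TRUE,
          floral_criterion = TRUE, stringsAsFactors = FALSE))
    }
  }
  edges <- edges[order(edges$tf, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  new_trn(comparison, edges)
}

#' Build one comparison's TRN from a count matrix and hits
#'
#' Convenience wrapper: selects the samples of the two conditions (per
#' \code{config$sample_scope}), computes coexpression and applies
#' [assemble_trn()].
#'
#' @param hits motif hits.
#' @param cm a \code{count_matrix}.
#' @param pair length-2 character vector of condition labels, e.g.
#'   \code{c("C","F")}.
#' @param de_list named list of DE tables (see [assemble_trn()]).
#' @param tf_map TF-to-motif map.
#' @param floral_set floral gene ids.
#' @param config a [trn_config()].
#' @return a \code{trn} object with comparison label \code{"A-B"}.
#' @export
build_comparison_trn <- function(hits, cm, pair, de_list, tf_map, floral_set,
                                 config = trn_config()) {
  stopifnot(length(pair) == 2L)
  samples <- if (config$sample_scope == "pair_conditions")
    names(cm$conditions)[cm$conditions %in% pair]
  else colnames(cm$counts)
  rho <- compute_coexpression(cm, tf_map$tf, samples = samples)
  assemble_trn(hits, rho, de_list, tf_map, floral_set, config,
               comparison = paste(pair, collapse = "-"))
}
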