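## FIMO-style PWM scanning: log-odds scores against a 0-order background
## with exact p-values from a position-wise dynamic-programming convolution
## over discretized column scores.

encode_dna <- function(seq) {
  codes <- match(strsplit(seq, "", fixed = TRUE)[[1L]], DNA_BASES)
  codes  # N (or any non-ACGT) becomes NA and poisons overlapping windows
}

## Floor for log-odds of zero-probability cells (bits); far below any
## attainable threshold so tail probabilities above it are unaffected.
LOG_ODDS_FLOOR <- -64

#' Build a log-odds scoring model with an exact null distribution
#'
#' Log-odds are \code{log2(((p + pseudocount * bg) / (1 + pseudocount)) / bg)}
#' per cell. Scores are discretized to \code{granularity} bits and the exact
#' tail probability of every achievable discretized score under the
#' background is obtained by convolving the column score distributions.
#'
#' @param motif a \code{motif_model}.
#' @param background length-4 probability vector over A,C,G,T.
#' @param pseudocount fraction of background mixed into each column
#'   (FIMO-style; default 0.1).
#' @param granularity score discretization unit in bits (default 1/1000).
#' @return a \code{scoring_model}: log-odds matrix, integer score matrix,
#'   tail distribution and its integer offset.
#' @export
build_scoring_model <- function(motif, background = rep(0.25, 4),
                                pseudocount = 0.1, granularity = 1e-3) {
  stopifnot(length(background) == 4L, all(background >= 0),
            abs(sum(background) - 1) < 1e-6)
  if (any(background == 0) && pseudocount == 0)
    stop("zero background frequency with zero pseudocount: log-odds undefined")
  if (any(background == 0))
    stop("zero background frequency: every base must have positive probability")
  p <- sweep(motif$matrix, 2L, background, function(pr, bg)
    (pr + pseudocount * bg) / (1 + pseudocount))
  lo <- log2(sweep(p, 2L, background, "/"))
  lo[lo < LOG_ODDS_FLOOR] <- LOG_ODDS_FLOOR
  sint <- round(lo / granularity)
  storage.mode(sint) <- "integer"
  w <- motif$width
  omin <- apply(sint, 1L, min)
  tmat <- sint - omin                       # nonnegative shifted scores
  pmf <- 1
  for (i in seq_len(w)) {
    m <- max(tmat[i, ])
    new <- numeric(length(pmf) + m)
    for (b in 1:4) {
      sh <- tmat[i, b]
      idx <- seq_along(pmf) + sh
      new[idx] <- new[idx] + background[b] * pmf
    }
    pmf <- new
  }
  tail <- rev(cumsum(rev(pmf)))             # tail[j] = P(T >= j - 1)
  tail <- pmin(tail, 1)
  structure(list(motif_id = motif$motif_id, width = w, log_odds = lo,
                 prob = p, score_int = sint, granularity = granularity,
                 background = background, base = sum(omin), tail = tail),
            class = "scoring_model")
}

#' Exact p-value of a score under a scoring model
#'
#' @param model a \code{scoring_model}.
#' @param score_bits score in bits (will be discretized to the model's
#'   granularity).
#' @return P(score >= \code{score_bits}) under the background model.
#' @export
motif_pvalue <- function(model, score_bits) {
  sint <- round(score_bits / model$granularity)
  pvalue_int(model, sint)
}

pvalue_int <- function(model, sint) {
  t <- sint - model$base
  ifelse(t <= 0, 1,
         ifelse(t >= length(model$tail), 0, model$tail[pmax(t, 1L) + 1L]))
}

## Smallest integer score whose tail probability is <= p_threshold,
## or NA if no achievable score passes.
min_passing_score <- function(model, p_threshold) {
  pass <- which(model$tail <= p_threshold)
  if (length(pass) == 0L) return(NA_integer_)
  model$base + pass[1L] - 1L
}

reverse_complement_motif <- function(motif) {
  m <- motif$matrix[rev(seq_len(motif$width)), rev(1:4), drop = FALSE]
  colnames(m) <- DNA_BASES
  motif_model(motif$motif_id, m, motif$n_sites)
}

## Integer window scores at every start offset; NA where a window overlaps
## an N or the promoter is shorter than the motif.
window_scores_int <- function(codes, sint) {
  w <- nrow(sint)
  n_win <- length(codes) - w + 1L
  if (n_win < 1L) return(integer(0))
  sc <- numeric(n_win)
  for (j in seq_len(w))
    sc <- sc + sint[j, ][codes[j:(j + n_win - 1L)]]
  sc
}

#' Scan promoters with motif scoring models
#'
#' Every window position on both strands of each promoter is scored;
#' windows overlapping an N are skipped. Hits with exact p-value at or
#' below \code{p_threshold} are returned sorted by (gene, motif, offset,
#' strand). Offsets are 0-based within the promoter in transcription
#' orientation.
#'
#' @param promoters data.frame from [extract_promoters()], or a named
#'   character vector of promoter sequences.
#' @param scoring_models list of \code{scoring_model}s (forward strand);
#'   reverse-strand models are derived internally.
#' @param p_threshold per-test p-value cutoff (default 1e-5, no
#'   multiple-testing correction, matching a raw FIMO-style cutoff).
#' @param both_strands scan the reverse strand of the promoter too
#'   (default TRUE).
#' @return data.frame with columns \code{gene_id}, \code{motif_id},
#'   \code{offset}, \code{strand}, \code{score_bits}, \code{p_value}.
#' @export
scan_promoters <- function(promoters, scoring_models, p_threshold = 1e-5,
                           both_strands = TRUE) {
  stopifnot(p_threshold >= 0, p_threshold <= 1)
  if (is.data.frame(promoters))
    seqs <- setNames(promoters$sequence, promoters$gene_id)
  else seqs <- promoters
  empty <- data.frame(gene_id = character(), motif_id = character(),
                      offset = integer(), strand = character(),
                      score_bits = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE)
  if (p_threshold == 0 || length(seqs) == 0L) return(empty)
  codes_list <- lapply(seqs, encode_dna)
  out <- list()
  for (fwd in scoring_models) {
    strands <- list(`+` = fwd)
    if (both_strands) {
      # pseudocount is already baked into fwd$prob, so pass 0 here
      rc_motif <- reverse_complement_motif(motif_model(fwd$motif_id, fwd$prob))
      strands$`-` <- build_scoring_model(rc_motif, fwd$background,
                                         pseudocount = 0,
                                         granularity = fwd$granularity)
    }
    for (st in names(strands)) {
      model <- strands[[st]]
      smin <- min_passing_score(model, p_threshold)
      if (is.na(smin)) next
      for (g in names(codes_list)) {
        sc <- window_scores_int(codes_list[[g]], model$score_int)
        hit <- which(!is.na(sc) & sc >= smin)
        if (length(hit) == 0L) next
        out[[length(out) + 1L]] <- data.frame(
          gene_id = g, motif_id = model$motif_id, offset = hit - 1L,
          strand = st,
          score_bits = sc[hit] * model$granularity,
          p_value = pvalue_int(model, sc[hit]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) return(empty)
  hits <- do.call(rbind, out)
  hits <- hits[order(hits$gene_id, hits$motif_id, hits$offset, hits$strand), ]
  rownames(hits) <- NULL
  hits
}

#' Estimate a 0-order background from promoter sequences
#'
#' @param promoters data.frame from [extract_promoters()] or character
#'   vector of sequences.
#' @return length-4 base frequency vector over A,C,G,T (Ns ignored).
#' @export
estimate_background <- function(promoters) {
  seqs <- if (is.data.frame(promoters)) promoters$sequence else promoters
  tab <- table(factor(unlist(strsplit(paste(seqs, collapse = ""), "",
                                      fixed = TRUE)), levels = DNA_BASES))
  as.numeric(tab) / sum(tab)
}

#' Write motif hits to TSV
#'
#' @param hits data.frame from [scan_promoters()].
#' @param path output path.
#' @export
write_hits <- function(hits, path) {
  h <- hits
  if (nrow(h)) {
    h$score_bits <- sprintf("%.10g", h$score_bits)
    h$p_value <- sprintf("%.10g", h$p_value)
  }
  write.table(h, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read motif hits from TSV
#'
#' @param path hits TSV written by [write_hits()].
#' @return data.frame of hits.
#' @export
read_hits <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(gene_id = "character", motif_id = "character",
                            strand = "character"))
}
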