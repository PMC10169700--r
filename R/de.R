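## Median-of-ratios normalization and a self-contained negative-binomial
## Wald test applying the DEG definition: fold change >= 2 at FDR <= 0.05
## (or raw p <= 0.05 as an alternative criterion).

#' Differential-expression configuration
#'
#' @param fc_threshold minimum fold change (default 2).
#' @param alpha significance level (default 0.05).
#' @param criterion \code{"FDR"} applies \code{alpha} to BH-adjusted
#'   p-values (default); \code{"raw_p"} to unadjusted p-values.
#' @return a list of settings.
#' @export
de_config <- function(fc_threshold = 2, alpha = 0.05,
                      criterion = c("FDR", "raw_p")) {
  stopifnot(fc_threshold >= 1, alpha > 0, alpha < 1)
  list(fc_threshold = fc_threshold, alpha = alpha,
       criterion = match.arg(criterion))
}

#' Median-of-ratios size factors and normalized counts
#'
#' The reference is the per-gene geometric mean over samples; genes with any
#' zero count are excluded from the reference set. Each sample's size factor
#' is the median over reference genes of count/reference.
#'
#' @param cm a \code{count_matrix} or plain integer matrix.
#' @return list with \code{size_factors} (named numeric) and
#'   \code{normalized} (matrix of counts divided by size factors).
#' @export
normalize_counts <- function(cm) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else cm
  if (ncol(counts) < 2L) stop("need >= 2 samples to normalize")
  allpos <- rowSums(counts == 0L) == 0L
  if (!any(allpos))
    stop("normalization error: no gene has all-positive counts")
  ref <- exp(rowMeans(log(counts[allpos, , drop = FALSE])))
  sf <- apply(counts[allpos, , drop = FALSE], 2L, function(col)
    median(col / ref))
  list(size_factors = sf,
       normalized = sweep(counts, 2L, sf, "/"))
}

## Method-of-moments NB dispersion pooled across the two conditions,
## computed on normalized counts. Negative estimates fall back to Poisson
## (dispersion floored at `floor`).
pooled_dispersion <- function(norm_a, norm_b, floor = 1e-8) {
  mom <- function(m) {
    mu <- rowMeans(m)
    s2 <- apply(m, 1L, var)
    (s2 - mu) / pmax(mu, floor)^2
  }
  na <- ncol(norm_a); nb <- ncol(norm_b)
  alpha <- ((na - 1) * mom(norm_a) + (nb - 1) * mom(norm_b)) / (na + nb - 2)
  pmax(alpha, floor)
}

#' Negative-binomial Wald test between two conditions
#'
#' Per gene, a pooled method-of-moments dispersion is estimated on
#' normalized counts and a Wald test is applied to the log2 fold change of
#' normalized group means (condition \code{b} over \code{a}). The Wald
#' statistic is referred to a t distribution with \code{n_a + n_b - 2}
#' degrees of freedom, the small-sample reference appropriate when the
#' variance is estimated. Benjamini-Hochberg FDR is computed across all
#' tested genes; genes with zero counts in every sample are reported
#' untested (NA p-value and FDR).
#'
#' @param cm a \code{count_matrix}.
#' @param condition_a,condition_b condition labels; fold change is
#'   \code{b} over \code{a}.
#' @param config a [de_config()].
#' @return data.frame with columns \code{gene_id}, \code{base_mean_a},
#'   \code{base_mean_b}, \code{log2_fold_change}, \code{p_value},
#'   \code{fdr}, \code{is_deg}, \code{tested}.
#' @export
test_differential_expression <- function(cm, condition_a, condition_b,
                                         config = de_config()) {
  stopifnot(inherits(cm, "count_matrix"))
  sa <- names(cm$conditions)[cm$conditions == condition_a]
  sb <- names(cm$conditions)[cm$conditions == condition_b]
  if (length(sa) == 0L) stop(sprintf("condition '%s' absent", condition_a))
  if (length(sb) == 0L) stop(sprintf("condition '%s' absent", condition_b))
  if (length(sa) < 2L || length(sb) < 2L)
    stop("both conditions need >= 2 samples")
  sub <- cm$counts[, c(sa, sb), drop = FALSE]
  norm <- normalize_counts(sub)$normalized
  norm_a <- norm[, sa, drop = FALSE]
  norm_b <- norm[, sb, drop = FALSE]
  na <- length(sa); nb <- length(sb)
  mu_a <- rowMeans(norm_a); mu_b <- rowMeans(norm_b)
  alpha_g <- pooled_dispersion(norm_a, norm_b)
  lfc <- log2((mu_b + 0.5) / (mu_a + 0.5))
  se2 <- (1 / log(2)^2) *
    ((1 / pmax(mu_a, 0.5) + alpha_g) / na +
     (1 / pmax(mu_b, 0.5) + alpha_g) / nb)
  tstat <- lfc / sqrt(se2)
  p <- 2 * pt(-abs(tstat), df = na + nb - 2)
  tested <- rowSums(sub) > 0L
  p[!tested] <- NA_real_
  lfc[!tested] <- NA_real_
  fdr <- rep(NA_real_, length(p))
  fdr[tested] <- p.adjust(p[tested], method = "BH")
  crit <- if (config$criterion == "FDR") fdr else p
  is_deg <- !is.na(crit) & crit <= config$alpha &
    abs(lfc) >= log2(config$fc_threshold)
  data.frame(gene_id = rownames(sub), base_mean_a = mu_a, base_mean_b = mu_b,
             log2_fold_change = lfc, p_value = p, fdr = fdr,
             is_deg = is_deg, tested = tested,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a DE table to TSV
#'
#' @param de data.frame from [test_differential_expression()].
#' @param path output path.
#' @export
write_de_table <- function(de, path) {
  d <- de
  for (col in c("base_mean_a", "base_mean_b", "log2_fold_change",
                "p_value", "fdr"))
    if (col %in% names(d)) d[[col]] <- sprintf("%.10g", d[[col]])
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
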