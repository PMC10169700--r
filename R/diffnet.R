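## Differential network comparison: node classes distinguishing two TRNs
## and hypergeometric enrichment of TF families among distinguishing nodes.

## Signed neighbor multiset of every node (TF side and target side pooled).
signed_neighbors <- function(trn) {
  e <- trn$edges
  nb <- list()
  for (i in seq_len(nrow(e))) {
    nb[[e$tf[i]]] <- c(nb[[e$tf[i]]], paste0(e$target[i], e$sign[i]))
    nb[[e$target[i]]] <- c(nb[[e$target[i]]], paste0(e$tf[i], e$sign[i]))
  }
  lapply(nb, sort)
}

edge_keys <- function(trn) {
  if (nrow(trn$edges) == 0L) return(character(0))
  paste(trn$edges$tf, trn$edges$target, trn$edges$sign, sep = "\t")
}

#' Compare two TRNs node by node
#'
#' A node is \emph{rewired} iff it is present in both networks with a
#' different signed neighbor set. The \emph{distinguishing} set is the
#' union of nodes unique to either network and the rewired nodes.
#'
#' @param trn_a,trn_b \code{trn} objects sharing a gene-id namespace.
#' @return a \code{network_comparison}: node classes
#'   (\code{nodes_only_a}, \code{nodes_only_b}, \code{rewired_nodes},
#'   \code{distinguishing_nodes}, \code{shared_identical_nodes}),
#'   \code{universe} (union of both node sets) and the edges unique to
#'   each network.
#' @export
compare_networks <- function(trn_a, trn_b) {
  only_a <- setdiff(trn_a$nodes, trn_b$nodes)
  only_b <- setdiff(trn_b$nodes, trn_a$nodes)
  shared <- intersect(trn_a$nodes, trn_b$nodes)
  nb_a <- signed_neighbors(trn_a)
  nb_b <- signed_neighbors(trn_b)
  rewired <- shared[vapply(shared, function(n)
    !identical(nb_a[[n]], nb_b[[n]]), logical(1))]
  distinguishing <- sort(unique(c(only_a, only_b, rewired)))
  ka <- edge_keys(trn_a); kb <- edge_keys(trn_b)
  structure(list(
    nodes_only_a = sort(only_a), nodes_only_b = sort(only_b),
    rewired_nodes = sort(rewired),
    distinguishing_nodes = distinguishing,
    shared_identical_nodes = sort(setdiff(shared, rewired)),
    universe = sort(union(trn_a$nodes, trn_b$nodes)),
    edges_only_a = trn_a$edges[!ka %in% kb, , drop = FALSE],
    edges_only_b = trn_b$edges[!kb %in% ka, , drop = FALSE]),
    class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  cat(sprintf(paste0("<network_comparison> universe %d nodes: %d only in A, ",
                     "%d only in B, %d rewired, %d distinguishing\n"),
              length(x$universe), length(x$nodes_only_a),
              length(x$nodes_only_b), length(x$rewired_nodes),
              length(x$distinguishing_nodes)))
  invisible(x)
}

## Odds ratio of the 2x2 table (k, n-k; K-k, N-K-n+k) with a Haldane 0.5
## correction when any cell is zero.
table_odds_ratio <- function(N, K, n, k) {
  a <- k; b <- n - k; c <- K - k; d <- N - K - n + k
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  list(odds_ratio = (a * d) / (b * c), haldane_corrected = corrected)
}

#' Hypergeometric enrichment of a gene family among distinguishing nodes
#'
#' Upper-tail (over-representation) hypergeometric test of the overlap
#' between the distinguishing node set and a family within the node
#' universe, with the odds ratio of the corresponding 2x2 table.
#'
#' @param comparison a \code{network_comparison}, or a character vector of
#'   distinguishing nodes.
#' @param family_set character vector of family member gene ids (must be a
#'   subset of the universe).
#' @param universe node universe; defaults to the comparison's union of
#'   both networks' nodes.
#' @return list with the 2x2 \code{table}, \code{odds_ratio},
#'   \code{haldane_corrected}, \code{p_value} and the counts
#'   \code{N}, \code{K}, \code{n}, \code{k}.
#' @export
node_family_enrichment <- function(comparison, family_set, universe = NULL) {
  dist_nodes <- if (inherits(comparison, "network_comparison"))
    comparison$distinguishing_nodes else comparison
  if (is.null(universe)) {
    if (!inherits(comparison, "network_comparison"))
      stop("universe must be given when comparison is a plain node set")
    universe <- comparison$universe
  }
  if (length(setdiff(family_set, universe)))
    stop("family set is not a subset of the universe")
  dist_nodes <- intersect(dist_nodes, universe)
  N <- length(universe); K <- length(family_set)
  n <- length(dist_nodes); k <- length(intersect(dist_nodes, family_set))
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  or <- table_odds_ratio(N, K, n, k)
  tab <- matrix(c(k, n - k, K - k, N - K - n + k), nrow = 2L, byrow = TRUE,
                dimnames = list(c("distinguishing", "not_distinguishing"),
                                c("in_family", "not_in_family")))
  list(table = t(tab), odds_ratio = or$odds_ratio,
       haldane_corrected = or$haldane_corrected, p_value = p,
       N = N, K = K, n = n, k = k)
}

#' Enrichment of several families with BH correction across families
#'
#' @param comparison a \code{network_comparison}.
#' @param families named list of gene-id vectors (family sets are
#'   intersected with the universe).
#' @param universe node universe (default: union of both networks' nodes).
#' @return data.frame with one row per family: counts, odds ratio, raw p
#'   and BH-adjusted p across families.
#' @export
family_enrichment <- function(comparison, families, universe = NULL) {
  if (is.null(universe)) universe <- comparison$universe
  rows <- lapply(names(families), function(fam) {
    fs <- intersect(families[[fam]], universe)
    r <- node_family_enrichment(comparison, fs, universe)
    data.frame(family = fam, N = r$N, K = r$K, n = r$n, k = r$k,
               odds_ratio = r$odds_ratio,
               haldane_corrected = r$haldane_corrected,
               p_value = r$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p_value, method = "BH")
  out
}
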