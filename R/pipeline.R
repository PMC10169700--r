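## End-to-end orchestration: simulate (or load) -> promoters -> scan -> DE
## -> one TRN per comparison -> differential network report, with a
## manifest that makes a run reproducible from its config and seed.

#' Pipeline configuration
#'
#' Either a \code{simulate} block (a [synthetic_config()]) or an
#' \code{inputs} list of file paths (\code{genome}, \code{genes},
#' \code{motifs}, \code{tf_map}, \code{counts}, \code{conditions},
#' \code{gene_sets}) must be supplied.
#'
#' @param out_dir output directory.
#' @param simulate a [synthetic_config()], or \code{NULL} when reading
#'   real inputs.
#' @param inputs named list of input paths (ignored when \code{simulate}
#'   is given).
#' @param window a [promoter_window()].
#' @param p_threshold motif scan p-value cutoff (default 1e-5).
#' @param de a [de_config()].
#' @param trn a [trn_config()].
#' @param comparisons list of length-2 condition pairs; one TRN is built
#'   per pair (default C-I and C-F).
#' @param seed master seed; overrides the simulate block's seed.
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(out_dir, simulate = synthetic_config(),
                            inputs = NULL, window = promoter_window(),
                            p_threshold = 1e-5, de = de_config(),
                            trn = trn_config(),
                            comparisons = list(c("C", "I"), c("C", "F")),
                            seed = NULL) {
  if (is.null(simulate) && is.null(inputs))
    stop("configuration error: either 'simulate' or 'inputs' must be given")
  if (is.null(simulate)) {
    need <- c("genome", "genes", "motifs", "tf_map", "counts", "conditions",
              "gene_sets")
    for (f in need)
      if (is.null(inputs[[f]]))
        stop(sprintf("configuration error: inputs$%s is missing", f))
    for (f in need)
      if (!file.exists(inputs[[f]]))
        stop(sprintf("configuration error: inputs$%s file not found: %s",
                     f, inputs[[f]]))
  }
  if (!is.null(seed) && !is.null(simulate)) simulate$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, simulate = simulate, inputs = inputs,
                 window = window, p_threshold = p_threshold, de = de,
                 trn = trn, comparisons = comparisons,
                 seed = if (is.null(simulate)) seed else simulate$seed),
            class = "pipeline_config")
}

de_pair_name <- function(pair) paste0(pair[2L], "_vs_", pair[1L])

## Score a recovered network against the planted truth. Recall is taken
## over the true edges expressible in that comparison's sample scope
## (F-program family edges count only for comparisons involving F).
score_network <- function(trn, truth) {
  relevant <- truth$true_edges
  if (!grepl("F", trn$comparison))
    relevant <- relevant[relevant$active_in == "all", , drop = FALSE]
  true_key <- paste(relevant$tf, relevant$target)
  true_sign <- setNames(relevant$sign, true_key)
  got_key <- paste(trn$edges$tf, trn$edges$target)
  tp <- got_key %in% true_key
  sign_ok <- trn$edges$sign[tp] == true_sign[got_key[tp]]
  list(n_edges = nrow(trn$edges), n_true = nrow(relevant),
       precision = if (nrow(trn$edges)) mean(tp) else NA_real_,
       recall = sum(tp) / nrow(relevant),
       sign_agreement = if (any(tp)) mean(sign_ok) else NA_real_)
}

## Fraction of planted sites recovered by the scan (same gene, motif,
## offset and strand).
score_sites <- function(hits, truth) {
  site_key <- with(truth$planted_sites,
                   paste(gene, motif_id, offset, strand))
  hit_key <- with(hits, paste(gene_id, motif_id, offset, strand))
  mean(site_key %in% hit_key)
}

#' Run the full analysis pipeline
#'
#' Writes every stage output under \code{config$out_dir} together with a
#' machine-readable report (\code{report.json}) and a manifest
#' (\code{manifest.json}: config echo, seed, output checksums). Identical
#' config and seed produce byte-identical stage outputs and manifest.
#'
#' @param config a [pipeline_config()].
#' @return the report, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- "load_inputs"
  report <- list(seed = config$seed)
  tryCatch({
    if (!is.null(config$simulate)) {
      stage <- "simulate"
      ds <- simulate_dataset(config$simulate,
                             out_dir = file.path(out, "inputs"))
      genome <- ds$genome; genes <- ds$genes; motifs <- ds$motifs
      tf_map <- ds$tf_map; cm <- ds$cm; gene_sets <- ds$gene_sets
      truth <- ds$truth
    } else {
      genome <- read_fasta(config$inputs$genome)
      genes <- read_gff3_genes(config$inputs$genes)
      motifs <- read_meme_motifs(config$inputs$motifs)
      tf_map <- read_tf_map(config$inputs$tf_map)
      cm <- read_count_matrix(config$inputs$counts, config$inputs$conditions)
      gene_sets <- read_gene_sets(config$inputs$gene_sets)
      truth <- NULL
    }

    stage <- "promoters"
    promoters <- extract_promoters(genome, genes, config$window)
    write_promoters_fasta(promoters, file.path(out, "promoters.fasta"))

    stage <- "scan"
    models <- lapply(motifs, build_scoring_model)
    hits <- scan_promoters(promoters, models, config$p_threshold)
    write_hits(hits, file.path(out, "hits.tsv"))
    report$n_motif_hits <- nrow(hits)

    stage <- "de"
    de_pairs <- unique(c(lapply(config$comparisons, identity),
                         list(c("I", "F"))))
    de_list <- list()
    for (pair in de_pairs) {
      nm <- de_pair_name(pair)
      de_list[[nm]] <- test_differential_expression(cm, pair[1L], pair[2L],
                                                    config$de)
      write_de_table(de_list[[nm]], file.path(out, sprintf("de_%s.tsv", nm)))
    }
    report$deg_counts <- lapply(de_list, function(d) {
      up <- sum(d$is_deg & d$log2_fold_change > 0, na.rm = TRUE)
      down <- sum(d$is_deg & d$log2_fold_change < 0, na.rm = TRUE)
      list(up = up, down = down, total = up + down)
    })

    stage <- "trn"
    deg_rule_names <- vapply(config$comparisons, de_pair_name, "")
    trns <- list()
    for (pair in config$comparisons) {
      cfg <- config$trn
      cfg$deg_rule <- cfg$deg_rule %||% deg_rule_names
      net <- build_comparison_trn(hits, cm, pair, de_list, tf_map,
                                  gene_sets$floral %||% character(0), cfg)
      label <- paste(pair, collapse = "-")
      trns[[label]] <- net
      write_edge_table(net, file.path(out, sprintf(
        "trn_%s.tsv", gsub("-", "", label))))
    }
    report$trn_sizes <- lapply(trns, function(net)
      list(nodes = length(net$nodes), edges = nrow(net$edges)))

    if (length(trns) >= 2L) {
      stage <- "diff"
      cmpnet <- compare_networks(trns[[1L]], trns[[2L]])
      fams <- gene_sets[setdiff(names(gene_sets), "floral")]
      enrich <- family_enrichment(cmpnet, fams)
      write.table(enrich, file.path(out, "diff_enrichment.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      node_classes <- data.frame(
        node = cmpnet$universe,
        class = ifelse(cmpnet$universe %in% cmpnet$nodes_only_a, "only_a",
                ifelse(cmpnet$universe %in% cmpnet$nodes_only_b, "only_b",
                ifelse(cmpnet$universe %in% cmpnet$rewired_nodes, "rewired",
                       "shared_identical"))))
      write.table(node_classes, file.path(out, "diff_nodes.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      report$distinguishing_nodes <- cmpnet$distinguishing_nodes
      report$n_distinguishing <- length(cmpnet$distinguishing_nodes)
      report$enrichment <- enrich
    }

    if (!is.null(truth)) {
      stage <- "truth_scoring"
      report$site_recovery <- score_sites(hits, truth)
      report$network_recovery <- lapply(trns, score_network, truth = truth)
      for (nm in intersect(names(de_list), names(truth$de_genes))) {
        d <- de_list[[nm]]
        planted <- truth$de_genes[[nm]]$gene
        report$de_recovery[[nm]] <- list(
          power = mean(planted %in% d$gene_id[d$is_deg]),
          n_planted = length(planted))
      }
    }
  }, error = function(e) {
    manifest <- list(failed_stage = stage, error = conditionMessage(e))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)))
  })

  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  files <- sort(setdiff(list.files(out, recursive = TRUE),
                        "manifest.json"))
  checksums <- tools::md5sum(file.path(out, files))
  manifest <- list(seed = config$seed,
                   config = config_echo(config),
                   files = as.list(setNames(unname(checksums), files)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

## Config echo for the manifest: everything except the output path, so two
## runs of the same config into different directories produce identical
## manifests apart from nothing at all.
config_echo <- function(config) {
  echo <- unclass(config)
  echo$out_dir <- NULL
  echo$simulate <- if (!is.null(echo$simulate)) unclass(echo$simulate)
  echo
}
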