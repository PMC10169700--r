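## Seeded synthetic dataset: genome + annotation, motifs with planted
## promoter sites, NB counts with planted regulatory and condition
## structure, gene lists, reads — plus the ground truth needed to score
## every downstream stage. Each sub-generator runs on its own RNG stream
## derived from the master seed, so stages are mutually isolated.

#' Synthetic dataset configuration
#'
#' Defaults define the package's reference study conditions: a 0.5 Mb
#' two-chromosome genome carrying 300 genes, 20 TFs with width-10 motifs
#' (~1.8 bits/column), 150 planted TF-target edges (one regulator per
#' target so the Spearman criterion is attainable), three conditions
#' (C/I/F) with 4 replicates each, NB dispersion 0.1, and a 5-TF
#' "differential family" active only under the flowered (F) program.
#'
#' @param seed master seed; every artifact is reproducible from it.
#' @param n_chrom,chrom_len chromosome number and length (bp).
#' @param n_genes,n_tfs total genes and TF genes among them.
#' @param motif_width,motif_ic motif width (bp) and target information
#'   content (bits/column).
#' @param n_true_edges planted TF-target edges (includes family edges).
#' @param frac_negative_edges fraction of repression-like (negative) edges
#'   among always-active edges.
#' @param replicates_per_condition replicates for each of C, I, F.
#' @param planted_fold_change condition fold change planted on TF activity
#'   for I and F samples (>= 2).
#' @param nb_dispersion NB dispersion; 0 gives the noiseless limit
#'   (deterministic expected counts).
#' @param mean_expression baseline mean count.
#' @param read_length,coverage,error_rate shotgun read simulation settings.
#' @param n_family_tfs,family_targets_per_tf size of the planted
#'   differential TF family and targets per family TF.
#' @param tf_activity_sd spread of the latent per-sample TF activity
#'   (stratified draw, wide enough that rank correlations near 1 are
#'   attainable at n = 8).
#' @param tf_effect,target_effect log-scale effect of activity on the TF's
#'   own expression and on target expression.
#' @param family_activity_shift mean activity of family TFs in F samples.
#' @param silent_mean mean count of family genes outside the F program.
#' @return a validated \code{synthetic_config} list.
#' @export
synthetic_config <- function(seed = 1L, n_chrom = 2L, chrom_len = 250000L,
                             n_genes = 300L, n_tfs = 20L,
                             motif_width = 10L, motif_ic = 1.8,
                             n_true_edges = 150L,
                             frac_negative_edges = 0.25,
                             replicates_per_condition = 4L,
                             planted_fold_change = 4,
                             nb_dispersion = 0.1, mean_expression = 100,
                             read_length = 100L, coverage = 30,
                             error_rate = 0,
                             n_family_tfs = 5L, family_targets_per_tf = 4L,
                             tf_activity_sd = 0.5, tf_effect = 2,
                             target_effect = 3, family_activity_shift = 2,
                             silent_mean = 0.02) {
  cfg <- list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
              chrom_len = as.integer(chrom_len),
              n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
              motif_width = as.integer(motif_width), motif_ic = motif_ic,
              n_true_edges = as.integer(n_true_edges),
              frac_negative_edges = frac_negative_edges,
              conditions = c("C", "I", "F"),
              replicates_per_condition = as.integer(replicates_per_condition),
              planted_fold_change = planted_fold_change,
              nb_dispersion = nb_dispersion,
              mean_expression = mean_expression,
              read_length = as.integer(read_length), coverage = coverage,
              error_rate = error_rate,
              n_family_tfs = as.integer(n_family_tfs),
              family_targets_per_tf = as.integer(family_targets_per_tf),
              tf_activity_sd = tf_activity_sd, tf_effect = tf_effect,
              target_effect = target_effect,
              family_activity_shift = family_activity_shift,
              silent_mean = silent_mean)
  stopifnot(cfg$replicates_per_condition >= 2L,
            cfg$planted_fold_change >= 1,
            cfg$nb_dispersion >= 0, cfg$error_rate >= 0, cfg$error_rate < 1,
            cfg$frac_negative_edges >= 0, cfg$frac_negative_edges <= 1,
            cfg$motif_width >= 1L, cfg$n_tfs >= 1L,
            cfg$n_family_tfs <= cfg$n_tfs)
  n_fam_edges <- cfg$n_family_tfs * cfg$family_targets_per_tf
  if (cfg$n_true_edges < n_fam_edges)
    stop("n_true_edges smaller than the family edge count")
  if (cfg$n_true_edges > cfg$n_genes - cfg$n_tfs)
    stop("not enough non-TF genes for one distinct target per edge")
  # capacity: each gene needs its length (<= 400 bp) plus 600 bp clearance
  per_chrom <- ceiling(cfg$n_genes / cfg$n_chrom)
  if (600L + per_chrom * (400L + 600L) > cfg$chrom_len)
    stop(sprintf(
      "sizing error: %d genes per chromosome cannot be placed in %d bp",
      per_chrom, cfg$chrom_len))
  if (cfg$read_length > cfg$chrom_len)
    stop("read_length exceeds chromosome length")
  structure(cfg, class = "synthetic_config")
}

## Stratified latent activity: a random permutation of an equally spaced
## grid spanning +-sqrt(3)*sd (variance sd^2) plus a small jitter, so
## adjacent activity levels are well separated and rank correlations near
## +-1 are attainable at small n.
strat_activity <- function(n, sd) {
  if (n == 1L) return(rnorm(1L, 0, sd))
  sample(seq(-sqrt(3) * sd, sqrt(3) * sd, length.out = n)) +
    rnorm(n, 0, 0.1 * sd)
}

#' Generate a random genome with non-overlapping annotated genes
#'
#' Background sequence is i.i.d. uniform; genes (200-400 bp) are placed on
#' both strands with >= 600 bp clearance on each side so every promoter
#' window is unclipped.
#'
#' @param config a [synthetic_config()].
#' @return list with \code{genome} (named character vector) and
#'   \code{genes} (data.frame as from [read_gff3_genes()]).
#' @export
generate_genome_annotation <- function(config) {
  with_seed(derive_seed(config$seed, "genome"), {
    genome <- setNames(vapply(seq_len(config$n_chrom), function(i)
      paste(sample(DNA_BASES, config$chrom_len, replace = TRUE),
            collapse = ""), character(1)),
      sprintf("chr%02d", seq_len(config$n_chrom)))
    n_per <- diff(round(seq(0, config$n_genes, length.out = config$n_chrom + 1L)))
    rows <- list()
    gi <- 0L
    for (ci in seq_len(config$n_chrom)) {
      lens <- sample(200:400, n_per[ci], replace = TRUE)
      base_need <- 600L + sum(lens + 600L)
      slack <- config$chrom_len - base_need
      if (slack < 0L) stop("sizing error: genes cannot be placed")
      extra <- if (n_per[ci] > 0L && slack > 0L)
        floor(runif(n_per[ci], 0, slack / n_per[ci])) else rep(0L, n_per[ci])
      cursor <- 600L
      for (g in seq_len(n_per[ci])) {
        gi <- gi + 1L
        start <- cursor
        end <- start + lens[g]
        rows[[gi]] <- data.frame(
          gene_id = sprintf("g%03d", gi), chrom = names(genome)[ci],
          start = start, end = end, strand = sample(c("+", "-"), 1L),
          stringsAsFactors = FALSE)
        cursor <- end + 600L + extra[g]
      }
    }
    list(genome = genome, genes = do.call(rbind, rows))
  })
}

## Solve for the consensus-base probability giving the target per-column
## information content (uniform background; other bases share the rest).
ic_to_delta <- function(ic) {
  stopifnot(ic > 0, ic <= 2)
  if (ic == 2) return(1)
  f <- function(d) {
    r <- (1 - d) / 3
    2 + d * log2(d) + ifelse(r > 0, 3 * r * log2(r), 0) - ic
  }
  stats::uniroot(f, c(0.2500001, 0.9999999))$root
}

#' Generate TF motifs and plant binding sites for every true edge
#'
#' Picks the TF genes (including the differential family), builds one motif
#' per TF at the configured information content, draws the planted edge
#' set (one distinct target per edge), and writes each edge's consensus
#' site into the target's promoter window at a recorded offset and strand.
#'
#' @param config a [synthetic_config()].
#' @param genome,genes from [generate_genome_annotation()].
#' @return list: \code{motifs}, \code{tf_map}, \code{genome} (with planted
#'   sites), \code{truth} (edges, sites, family, gene sets).
#' @export
generate_motif_set_and_sites <- function(config, genome, genes) {
  w <- config$motif_width
  window <- promoter_window()
  if (window$upstream + window$downstream < w)
    stop("promoter window shorter than the motif")
  with_seed(derive_seed(config$seed, "motifs"), {
    tf_genes <- sort(sample(genes$gene_id, config$n_tfs))
    family_tfs <- sort(sample(tf_genes, config$n_family_tfs))
    normal_tfs <- setdiff(tf_genes, family_tfs)
    delta <- ic_to_delta(config$motif_ic)
    motifs <- lapply(seq_along(tf_genes), function(i) {
      cons <- sample(4L, w, replace = TRUE)
      mat <- matrix((1 - delta) / 3, nrow = w, ncol = 4L,
                    dimnames = list(NULL, DNA_BASES))
      mat[cbind(seq_len(w), cons)] <- delta
      motif_model(sprintf("M%02d", i), mat, n_sites = 20L)
    })
    tf_map <- data.frame(tf = tf_genes,
                         motif_id = vapply(motifs, `[[`, "", "motif_id"),
                         stringsAsFactors = FALSE)

    n_fam_edges <- config$n_family_tfs * config$family_targets_per_tf
    n_norm_edges <- config$n_true_edges - n_fam_edges
    non_tf <- setdiff(genes$gene_id, tf_genes)
    targets <- sample(non_tf, config$n_true_edges)
    fam_targets <- targets[seq_len(n_fam_edges)]
    norm_targets <- targets[-seq_len(n_fam_edges)]
    edges <- rbind(
      data.frame(tf = rep(family_tfs, each = config$family_targets_per_tf),
                 target = fam_targets, sign = "+", active_in = "F",
                 stringsAsFactors = FALSE),
      data.frame(tf = sample(rep(normal_tfs, length.out = n_norm_edges)),
                 target = norm_targets,
                 sign = ifelse(runif(n_norm_edges) < config$frac_negative_edges,
                               "-", "+"),
                 active_in = "all", stringsAsFactors = FALSE))

    # plant one consensus site per edge in the target's promoter
    promoters <- extract_promoters(genome, genes, window)
    rownames(promoters) <- promoters$gene_id
    motif_of <- setNames(motifs, tf_genes)
    sites <- list()
    for (i in seq_len(nrow(edges))) {
      tf <- edges$tf[i]; target <- edges$target[i]
      cons <- consensus_string(motif_of[[tf]])
      off <- sample.int(window$upstream + window$downstream - w + 1L, 1L) - 1L
      site_strand <- sample(c("+", "-"), 1L)
      pr <- promoters[target, ]
      if (pr$strand == "+") {
        fs <- pr$start + off
        fwd_seq <- if (site_strand == "+") cons else revcomp(cons)
      } else {
        fs <- pr$end - off - w
        fwd_seq <- if (site_strand == "+") revcomp(cons) else cons
      }
      substr(genome[[pr$chrom]], fs + 1L, fs + w) <- fwd_seq
      sites[[i]] <- data.frame(gene = target, offset = off,
                               strand = site_strand,
                               motif_id = motif_of[[tf]]$motif_id,
                               stringsAsFactors = FALSE)
    }

    floral_extra <- sample(setdiff(non_tf, targets),
                           max(0L, round(0.1 * length(non_tf))))
    gene_sets <- list(
      floral = sort(unique(c(tf_genes, floral_extra))),
      AP2_ERF = family_tfs,
      TCP = sort(sample(normal_tfs, min(3L, length(normal_tfs)))),
      TF = tf_genes)
    truth <- list(tf_genes = tf_genes, family_tfs = family_tfs,
                  true_edges = edges,
                  planted_sites = do.call(rbind, sites),
                  differential_family = family_tfs,
                  gene_sets = gene_sets)
    list(motifs = motifs, tf_map = tf_map, genome = genome, truth = truth)
  })
}

#' Simulate the gene-by-sample count matrix with planted structure
#'
#' Per-sample latent activity drives each TF's own expression
#' (\code{tf_effect} x activity on the log scale) and its targets
#' (\code{target_effect}, signed). Normal TFs get a condition offset of
#' \code{log(planted_fold_change)} (random direction) in I and F samples;
#' family TFs and their targets are silent outside F and driven by a
#' shifted activity within F. Counts are NB with the configured
#' dispersion; dispersion 0 gives deterministic expected counts (the
#' noiseless limit).
#'
#' @param config a [synthetic_config()].
#' @param truth ground truth from [generate_motif_set_and_sites()].
#' @return list: \code{cm} (a \code{count_matrix}) and \code{truth}
#'   augmented with analytic per-comparison DE gene sets.
#' @export
simulate_expression_matrix <- function(config, truth) {
  reps <- config$replicates_per_condition
  conds <- rep(config$conditions, each = reps)
  samples <- paste0(conds, rep(seq_len(reps), times = length(config$conditions)))
  n <- length(samples)
  if (is.null(truth$all_genes))
    stop("truth$all_genes must list every gene id")
  with_seed(derive_seed(config$seed, "expression"), {
    all_genes <- truth$all_genes
    logmu <- matrix(log(config$mean_expression) + rnorm(length(all_genes), 0, 0.5),
                    nrow = length(all_genes), ncol = n,
                    dimnames = list(all_genes, samples))
    lfc_I <- setNames(numeric(length(all_genes)), all_genes)
    lfc_F <- setNames(numeric(length(all_genes)), all_genes)
    in_IF <- conds %in% c("I", "F")
    in_F <- conds == "F"
    shift <- log(config$planted_fold_change)

    normal_tfs <- setdiff(truth$tf_genes, truth$family_tfs)
    activity <- matrix(0, nrow = length(truth$tf_genes), ncol = n,
                       dimnames = list(truth$tf_genes, samples))
    for (tf in normal_tfs) {
      dir <- sample(c(1, -1), 1L)
      # fresh stratified grid per condition: well-separated activity ranks
      # within every condition block, plus the planted condition offset
      activity[tf, ] <- unlist(lapply(config$conditions, function(cc)
        strat_activity(reps, config$tf_activity_sd))) +
        dir * shift * in_IF
      logmu[tf, ] <- logmu[tf, ] + config$tf_effect * activity[tf, ]
      lfc_I[tf] <- lfc_I[tf] + config$tf_effect * dir * shift / log(2)
      lfc_F[tf] <- lfc_F[tf] + config$tf_effect * dir * shift / log(2)
    }
    for (tf in truth$family_tfs) {
      a_F <- strat_activity(sum(in_F), config$tf_activity_sd) +
        config$family_activity_shift
      activity[tf, in_F] <- a_F
      logmu[tf, ] <- log(config$silent_mean)
      logmu[tf, in_F] <- log(config$mean_expression) + config$tf_effect * a_F
      lfc_F[tf] <- log2(config$mean_expression *
                          exp(config$tf_effect * config$family_activity_shift) /
                          config$silent_mean)
    }
    for (i in seq_len(nrow(truth$true_edges))) {
      e <- truth$true_edges[i, ]
      s <- if (e$sign == "+") 1 else -1
      if (e$active_in == "all") {
        logmu[e$target, ] <- log(config$mean_expression) +
          s * config$target_effect * activity[e$tf, ]
        dir <- sign(lfc_I[e$tf])
        lfc_I[e$target] <- s * config$target_effect * dir * abs(shift) / log(2)
        lfc_F[e$target] <- lfc_I[e$target]
      } else {
        logmu[e$target, ] <- log(config$silent_mean)
        logmu[e$target, in_F] <- log(config$mean_expression) +
          config$target_effect * activity[e$tf, in_F]
        lfc_F[e$target] <- log2(config$mean_expression *
                                  exp(config$target_effect *
                                        config$family_activity_shift) /
                                  config$silent_mean)
      }
    }
    mu <- exp(logmu)
    counts <- if (config$nb_dispersion > 0)
      matrix(rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
             nrow = nrow(mu), dimnames = dimnames(mu))
    else round(mu)
    storage.mode(counts) <- "integer"
    cm <- count_matrix(counts, setNames(conds, samples))
    truth$de_genes <- list(
      I_vs_C = data.frame(gene = names(lfc_I)[abs(lfc_I) >= 1],
                          log2fc = unname(lfc_I[abs(lfc_I) >= 1]),
                          stringsAsFactors = FALSE),
      F_vs_C = data.frame(gene = names(lfc_F)[abs(lfc_F) >= 1],
                          log2fc = unname(lfc_F[abs(lfc_F) >= 1]),
                          stringsAsFactors = FALSE))
    list(cm = cm, truth = truth)
  })
}

#' Simulate error-free (or uniformly erroneous) shotgun reads
#'
#' Reads are sampled uniformly from both strands at the configured
#' coverage; with \code{error_rate} 0 every read is an exact substring of
#' the genome or its reverse complement.
#'
#' @param config a [synthetic_config()].
#' @param genome named character vector of chromosome sequences.
#' @return named character vector of read sequences.
#' @export
simulate_reads <- function(config, genome) {
  rl <- config$read_length
  if (any(nchar(genome) < rl)) stop("read_length exceeds chromosome length")
  total_len <- sum(nchar(genome))
  n_reads <- ceiling(config$coverage * total_len / rl)
  with_seed(derive_seed(config$seed, "reads"), {
    chrom <- sample(names(genome), n_reads, replace = TRUE,
                    prob = nchar(genome))
    pos <- floor(runif(n_reads) * (nchar(genome)[chrom] - rl + 1)) + 1L
    seqs <- substring(genome[chrom], pos, pos + rl - 1L)
    minus <- runif(n_reads) < 0.5
    if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
    if (config$error_rate > 0) {
      for (i in which(runif(n_reads) < 1 - (1 - config$error_rate)^rl)) {
        npos <- which(runif(rl) < config$error_rate)
        for (j in npos) {
          cur <- substr(seqs[i], j, j)
          substr(seqs[i], j, j) <- sample(setdiff(DNA_BASES, cur), 1L)
        }
      }
    }
    setNames(seqs, sprintf("read%07d", seq_len(n_reads)))
  })
}

#' Write reads as FASTQ
#'
#' @param reads named character vector of read sequences.
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  qual <- vapply(nchar(reads), function(n)
    paste(rep("I", n), collapse = ""), character(1))
  writeLines(paste0("@", names(reads), "\n", reads, "\n+\n", qual), con)
  invisible(path)
}

#' Generate the complete synthetic dataset
#'
#' Runs every sub-generator and (optionally) writes all artifacts plus the
#' ground truth to a directory: genome.fasta, genes.gff3, motifs.meme,
#' tf_map.tsv, counts.tsv, conditions.tsv, genesets.tsv, reads.fastq,
#' truth.json.
#'
#' @param config a [synthetic_config()].
#' @param out_dir output directory; \code{NULL} skips writing.
#' @param include_reads also simulate and write shotgun reads.
#' @return list: \code{genome}, \code{genes}, \code{motifs}, \code{tf_map},
#'   \code{cm}, \code{gene_sets}, \code{reads} (or NULL), \code{truth}.
#' @export
simulate_dataset <- function(config = synthetic_config(), out_dir = NULL,
                             include_reads = FALSE) {
  ga <- generate_genome_annotation(config)
  ms <- generate_motif_set_and_sites(config, ga$genome, ga$genes)
  ms$truth$all_genes <- ga$genes$gene_id
  ex <- simulate_expression_matrix(config, ms$truth)
  reads <- if (include_reads) simulate_reads(config, ms$genome) else NULL
  out <- list(genome = ms$genome, genes = ga$genes, motifs = ms$motifs,
              tf_map = ms$tf_map, cm = ex$cm,
              gene_sets = ex$truth$gene_sets, reads = reads,
              truth = ex$truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(out$genome, file.path(out_dir, "genome.fasta"))
    write_gff3(out$genes, file.path(out_dir, "genes.gff3"))
    write_meme_motifs(out$motifs, file.path(out_dir, "motifs.meme"))
    write_tf_map(out$tf_map, file.path(out_dir, "tf_map.tsv"))
    write_count_matrix(out$cm, file.path(out_dir, "counts.tsv"),
                       file.path(out_dir, "conditions.tsv"))
    write_gene_sets(out$gene_sets, file.path(out_dir, "genesets.tsv"))
    if (!is.null(reads)) write_fastq(reads, file.path(out_dir, "reads.fastq"))
    truth_json <- out$truth
    jsonlite::write_json(truth_json, file.path(out_dir, "truth.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  out
}
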