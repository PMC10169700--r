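small_cfg <- function(seed = 3L, ...) {
  synthetic_config(seed = seed, n_chrom = 1L, chrom_len = 60000L,
                   n_genes = 40L, n_tfs = 6L, n_true_edges = 20L,
                   n_family_tfs = 2L, family_targets_per_tf = 2L,
                   coverage = 5, ...)
}

test_that("generation is byte-identical for equal seeds", {
  a <- simulate_dataset(small_cfg())
  b <- simulate_dataset(small_cfg())
  expect_identical(a$genome, b$genome)
  expect_identical(a$genes, b$genes)
  expect_identical(lapply(a$motifs, `[[`, "matrix"),
                   lapply(b$motifs, `[[`, "matrix"))
  expect_identical(a$cm$counts, b$cm$counts)
  expect_identical(simulate_reads(small_cfg(), a$genome),
                   simulate_reads(small_cfg(), b$genome))
  c <- simulate_dataset(small_cfg(seed = 4L))
  expect_false(identical(a$cm$counts, c$cm$counts))
})

test_that("genes are placed on both strands with promoter clearance", {
  ds <- simulate_dataset(small_cfg())
  expect_equal(nrow(ds$genes), 40L)
  expect_setequal(unique(ds$genes$strand), c("+", "-"))
  pr <- extract_promoters(ds$genome, ds$genes)
  expect_false(any(pr$clipped))
})

test_that("impossible gene placements raise a sizing error", {
  expect_error(synthetic_config(n_genes = 1000L, chrom_len = 20000L),
               "sizing")
})

test_that("planted sites carry the exact consensus in the promoter", {
  ds <- simulate_dataset(small_cfg())
  pr <- extract_promoters(ds$genome, ds$genes)
  rownames(pr) <- pr$gene_id
  cons_of <- setNames(vapply(ds$motifs, consensus_string, ""),
                      vapply(ds$motifs, `[[`, "", "motif_id"))
  st <- ds$truth$planted_sites
  w <- small_cfg()$motif_width
  for (i in seq_len(nrow(st))) {
    sub <- substr(pr[st$gene[i], "sequence"], st$offset[i] + 1L,
                  st$offset[i] + w)
    expected <- if (st$strand[i] == "+") cons_of[[st$motif_id[i]]]
                else revcomp(cons_of[[st$motif_id[i]]])
    expect_identical(sub, expected)
  }
})

test_that("expression matrix has the contracted dimensions and labels", {
  ds <- simulate_dataset(small_cfg())
  expect_equal(dim(ds$cm$counts), c(40L, 12L))
  expect_equal(unname(table(ds$cm$conditions)[c("C", "I", "F")]),
               rep(4L, 3), ignore_attr = TRUE)
  expect_true(all(ds$truth$true_edges$tf %in% ds$tf_map$tf))
})

test_that("the noiseless limit gives rank correlation exactly +-1", {
  cfg <- small_cfg(nb_dispersion = 0, mean_expression = 1e5)
  ds <- simulate_dataset(cfg)
  sc <- names(ds$cm$conditions)[ds$cm$conditions %in% c("C", "F")]
  edges <- ds$truth$true_edges
  always <- edges[edges$active_in == "all", ]
  for (i in seq_len(nrow(always))) {
    r <- suppressWarnings(cor(ds$cm$counts[always$tf[i], sc],
                              ds$cm$counts[always$target[i], sc],
                              method = "spearman"))
    expect_equal(r, if (always$sign[i] == "+") 1 else -1)
  }
})

test_that("planted condition effects are at least two-fold in the truth", {
  ds <- simulate_dataset(small_cfg())
  for (cmp in names(ds$truth$de_genes))
    expect_true(all(abs(ds$truth$de_genes[[cmp]]$log2fc) >= 1))
})

test_that("error-free reads are exact substrings at the right total volume", {
  cfg <- small_cfg()
  ds <- simulate_dataset(cfg)
  reads <- simulate_reads(cfg, ds$genome)
  total <- sum(nchar(reads))
  expect_gte(total, cfg$coverage * sum(nchar(ds$genome)))
  expect_lt(total, cfg$coverage * sum(nchar(ds$genome)) + cfg$read_length)
  fwd <- ds$genome[[1]]
  rc <- revcomp(fwd)
  for (r in reads[sample(length(reads), 25)])
    expect_true(grepl(r, fwd, fixed = TRUE) || grepl(r, rc, fixed = TRUE))
})

test_that("dataset files round-trip through the on-disk formats", {
  dir <- tempfile()
  ds <- simulate_dataset(small_cfg(), out_dir = dir)
  expect_identical(read_fasta(file.path(dir, "genome.fasta")), ds$genome)
  expect_equal(read_gff3_genes(file.path(dir, "genes.gff3")), ds$genes)
  cm <- read_count_matrix(file.path(dir, "counts.tsv"),
                          file.path(dir, "conditions.tsv"))
  expect_identical(cm$counts, ds$cm$counts)
  expect_identical(read_gene_sets(file.path(dir, "genesets.tsv")),
                   ds$gene_sets[sort(names(ds$gene_sets))])
  motifs <- read_meme_motifs(file.path(dir, "motifs.meme"))
  expect_equal(motifs[[1]]$matrix, ds$motifs[[1]]$matrix, tolerance = 1e-4)
})
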