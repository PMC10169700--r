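test_that("coexpression reproduces hand-computed Spearman values", {
  x <- c(1L, 2L, 3L, 4L, 5L)
  rows <- rbind(tf1 = x * 10L, same = x * 3L, rev = rev(x) + 7L,
                mixed = c(2L, 1L, 4L, 3L, 5L))
  colnames(rows) <- paste0("s", 1:5)
  cm <- sf1_count_matrix(rows, 5L)
  rho <- compute_coexpression(cm, "tf1")
  expect_equal(rho["tf1", "same"], 1)
  expect_equal(rho["tf1", "rev"], -1)
  # rho = 1 - 6*4/(5*24) = 0.8
  expect_equal(rho["tf1", "mixed"], 0.8)
  expect_true(is.na(rho["tf1", "tf1"]))  # self-correlation excluded
})

test_that("constant expression yields NA, never zero", {
  rows <- rbind(tf1 = c(1L, 5L, 2L, 9L, 4L), flat = rep(3L, 5))
  colnames(rows) <- paste0("s", 1:5)
  cm <- sf1_count_matrix(rows, 5L)
  rho <- compute_coexpression(cm, "tf1")
  expect_true(is.na(rho["tf1", "flat"]))
  expect_error(compute_coexpression(cm, "tf1", samples = c("s1", "s2")),
               ">= 3")
})

toy_inputs <- function() {
  hits <- data.frame(
    gene_id = c("g1", "g2"), motif_id = c("M1", "M1"),
    offset = c(10L, 20L), strand = "+", score_bits = 12, p_value = 1e-6,
    stringsAsFactors = FALSE)
  rho <- matrix(NA_real_, nrow = 2, ncol = 5,
                dimnames = list(c("TF1", "TF2"),
                                c("TF1", "TF2", "g1", "g2", "g3")))
  rho["TF1", "g1"] <- 0.93; rho["TF1", "g2"] <- -0.92
  rho["TF2", "g3"] <- 0.95
  de <- list(F_vs_C = data.frame(gene_id = c("g1", "TF1"), is_deg = TRUE,
                                 stringsAsFactors = FALSE))
  tf_map <- data.frame(tf = c("TF1", "TF2"), motif_id = c("M1", "M2"),
                       stringsAsFactors = FALSE)
  list(hits = hits, rho = rho, de = de, tf_map = tf_map,
       floral = c("TF1"))
}

test_that("the three refinement criteria select exactly the right edges", {
  ti <- toy_inputs()
  trn <- assemble_trn(ti$hits, ti$rho, ti$de, ti$tf_map, ti$floral,
                      trn_config(), "C-F")
  # TF1->g1: hit + rho .93 + g1 DEG + TF1 floral;
  # TF1->g2: hit + |rho| .92 (absolute mode) + TF1 DEG + TF1 floral;
  # TF2->g3: rho .95 but no motif hit -> excluded
  expect_equal(trn$edges$tf, c("TF1", "TF1"))
  expect_equal(trn$edges$target, c("g1", "g2"))
  expect_equal(trn$edges$sign, c("+", "-"))
  expect_equal(trn$nodes, c("TF1", "g1", "g2"))
})

test_that("criteria (ii) and (iii) gate edges even at high correlation", {
  ti <- toy_inputs()
  # no DEGs anywhere and no floral genes: nothing survives
  de_none <- list(F_vs_C = data.frame(gene_id = character(),
                                      is_deg = logical()))
  trn <- assemble_trn(ti$hits, ti$rho, de_none, ti$tf_map, character(0),
                      trn_config(), "C-F")
  expect_equal(nrow(trn$edges), 0L)
  # floral only: TF1->g2 passes via TF1; TF1->g1 fails criterion (ii)... but
  # g1 is not floral and not DEG, so only the TF1-floral edges survive
  trn2 <- assemble_trn(ti$hits, ti$rho, de_none, ti$tf_map, "TF1",
                       trn_config(), "C-F")
  expect_equal(nrow(trn2$edges), 0L)  # criterion (ii) still fails for both
})

test_that("signed mode drops negative correlations that absolute mode keeps", {
  ti <- toy_inputs()
  trn_signed <- assemble_trn(ti$hits, ti$rho, ti$de, ti$tf_map, ti$floral,
                             trn_config(rho_mode = "signed"), "C-F")
  expect_equal(trn_signed$edges$target, "g1")
})

test_that("empty hit lists give empty networks", {
  ti <- toy_inputs()
  trn <- assemble_trn(ti$hits[0, ], ti$rho, ti$de, ti$tf_map, ti$floral,
                      trn_config(), "C-F")
  expect_equal(nrow(trn$edges), 0L)
  expect_length(trn$nodes, 0L)
})

test_that("TFs without a mapped motif are excluded with a warning", {
  ti <- toy_inputs()
  expect_warning(
    assemble_trn(ti$hits, ti$rho, ti$de, ti$tf_map[1, ], ti$floral,
                 trn_config(), "C-F"),
    "without a mapped motif")
})

test_that("tightening any criterion never adds edges", {
  ds <- default_pipeline_run()$dataset
  hits <- scan_promoters(extract_promoters(ds$genome, ds$genes),
                         lapply(ds$motifs, build_scoring_model))
  de <- list(F_vs_C = test_differential_expression(ds$cm, "C", "F"))
  samples <- names(ds$cm$conditions)[ds$cm$conditions %in% c("C", "F")]
  rho <- compute_coexpression(ds$cm, ds$tf_map$tf, samples)
  floral <- ds$gene_sets$floral
  edge_keys <- function(trn) paste(trn$edges$tf, trn$edges$target)

  prev <- NULL
  for (th in c(0.8, 0.9, 0.95, 0.99)) {
    k <- edge_keys(assemble_trn(hits, rho, de, ds$tf_map, floral,
                                trn_config(rho_threshold = th), "C-F"))
    if (!is.null(prev)) expect_true(all(k %in% prev))
    prev <- k
  }
  base <- assemble_trn(hits, rho, de, ds$tf_map, floral, trn_config(), "C-F")
  # shrink the DEG set
  de_small <- list(F_vs_C = de$F_vs_C[seq_len(50), ])
  small <- assemble_trn(hits, rho, de_small, ds$tf_map, floral,
                        trn_config(), "C-F")
  expect_true(all(edge_keys(small) %in% edge_keys(base)))
  # shrink the floral set
  flo <- assemble_trn(hits, rho, de, ds$tf_map, floral[1:5],
                      trn_config(), "C-F")
  expect_true(all(edge_keys(flo) %in% edge_keys(base)))
})

test_that("assembly is invariant to input row order", {
  ti <- toy_inputs()
  a <- assemble_trn(ti$hits, ti$rho, ti$de, ti$tf_map, ti$floral,
                    trn_config(), "C-F")
  b <- assemble_trn(ti$hits[rev(seq_len(nrow(ti$hits))), ],
                    ti$rho[2:1, ], ti$de, ti$tf_map[2:1, ], ti$floral,
                    trn_config(), "C-F")
  expect_identical(a$edges, b$edges)
})
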