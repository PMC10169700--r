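test_that("median-of-ratios size factors: symmetry and closed form", {
  m <- matrix(c(10L, 10L, 20L, 20L, 5L, 5L), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  expect_equal(unname(normalize_counts(m)$size_factors), c(1, 1))

  # B = 2 x A exactly: geometric-mean reference gives (1/sqrt(2), sqrt(2))
  a <- c(10L, 40L, 100L)
  m2 <- cbind(s1 = a, s2 = 2L * a)
  rownames(m2) <- paste0("g", 1:3)
  expect_equal(unname(normalize_counts(m2)$size_factors),
               c(1 / sqrt(2), sqrt(2)))
})

test_that("genes with a zero are excluded from the reference but normalized", {
  m <- cbind(s1 = c(10L, 0L, 30L), s2 = c(10L, 50L, 30L))
  rownames(m) <- paste0("g", 1:3)
  nr <- normalize_counts(m)
  expect_equal(unname(nr$size_factors), c(1, 1))  # zero gene not in reference
  expect_equal(unname(nr$normalized["g2", ]), c(0, 50))

  allzero <- cbind(s1 = c(0L, 5L), s2 = c(3L, 0L))
  rownames(allzero) <- c("g1", "g2")
  expect_error(normalize_counts(allzero), "all-positive")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(61)
  m <- matrix(rnbinom(200 * 6, mu = 50, size = 5), nrow = 200,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:6)))
  ours <- normalize_counts(m)$size_factors
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  # DESeq2 takes the median on the log scale; with an even reference-gene
  # count the averaged middle pair differs in the ~6th decimal
  expect_equal(unname(ours), unname(ref), tolerance = 1e-4)
})

test_that("identical groups give zero fold change and no DEG calls", {
  block <- matrix(rep(c(10L, 60L, 25L, 90L), each = 4), nrow = 4, byrow = TRUE)
  m <- cbind(block, block)
  dimnames(m) <- list(paste0("g", 1:4), paste0("s", 1:8))
  cm <- count_matrix(m, setNames(rep(c("C", "F"), each = 4), colnames(m)))
  de <- test_differential_expression(cm, "C", "F")
  expect_equal(de$log2_fold_change, rep(0, 4))
  expect_false(any(de$is_deg))
})

test_that("swapping condition labels negates fold changes, keeps p-values", {
  set.seed(71)
  m <- matrix(rnbinom(100 * 8, mu = 80, size = 10), nrow = 100,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:8)))
  cm <- count_matrix(m, setNames(rep(c("C", "F"), each = 4), colnames(m)))
  ab <- test_differential_expression(cm, "C", "F")
  ba <- test_differential_expression(cm, "F", "C")
  expect_equal(ba$log2_fold_change, -ab$log2_fold_change, tolerance = 1e-10)
  expect_equal(ba$p_value, ab$p_value, tolerance = 1e-10)
})

test_that("FDR column equals the step-up formula applied to the p-values", {
  set.seed(73)
  m <- matrix(rnbinom(300 * 8, mu = 60, size = 8), nrow = 300,
              dimnames = list(paste0("g", 1:300), paste0("s", 1:8)))
  m[1:20, 5:8] <- m[1:20, 5:8] * 4L
  cm <- count_matrix(m, setNames(rep(c("C", "F"), each = 4), colnames(m)))
  de <- test_differential_expression(cm, "C", "F")
  tested <- de$tested
  expect_equal(de$fdr[tested], naive_bh(de$p_value[tested]), tolerance = 1e-12)
  expect_true(all(de$fdr[tested] >= de$p_value[tested]))
})

test_that("all-zero genes are reported untested", {
  m <- rbind(g1 = rep(0L, 8), g2 = rep(c(5L, 50L), 4),
             g3 = rep(c(8L, 9L), 4))
  colnames(m) <- paste0("s", 1:8)
  cm <- count_matrix(m, setNames(rep(c("C", "F"), 4), colnames(m)))
  de <- test_differential_expression(cm, "C", "F")
  expect_false(de$tested[de$gene_id == "g1"])
  expect_true(is.na(de$p_value[de$gene_id == "g1"]))
  expect_true(all(de$tested[de$gene_id != "g1"]))
})

test_that("is_deg honors both the fold-change and significance criteria", {
  set.seed(79)
  m <- matrix(rnbinom(400 * 8, mu = 100, size = 1 / 0.05), nrow = 400)
  m[1:30, 5:8] <- matrix(rnbinom(30 * 4, mu = 400, size = 20), nrow = 30)   # 4-fold
  m[31:60, 5:8] <- matrix(rnbinom(30 * 4, mu = 160, size = 20), nrow = 30)  # 1.6-fold
  dimnames(m) <- list(paste0("g", 1:400), paste0("s", 1:8))
  cm <- count_matrix(m, setNames(rep(c("C", "F"), each = 4), colnames(m)))
  de_fdr <- test_differential_expression(cm, "C", "F")
  # sub-threshold fold changes are never DEGs however significant
  sub_fc <- abs(de_fdr$log2_fold_change) < 1
  expect_false(any(de_fdr$is_deg[sub_fc]))
  # raw-p criterion is at least as permissive as FDR at the same alpha
  de_raw <- test_differential_expression(cm, "C", "F",
                                         de_config(criterion = "raw_p"))
  expect_true(all(which(de_fdr$is_deg) %in% which(de_raw$is_deg)))
  # errors: absent condition, too few replicates
  expect_error(test_differential_expression(cm, "C", "X"), "absent")
})
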