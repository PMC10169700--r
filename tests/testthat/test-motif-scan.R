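test_that("uniform motif against uniform background scores zero everywhere", {
  m <- motif_model("U", matrix(0.25, nrow = 3, ncol = 4,
                               dimnames = list(NULL, c("A", "C", "G", "T"))))
  sm <- build_scoring_model(m, pseudocount = 0)
  expect_true(all(sm$log_odds == 0))
  expect_equal(motif_pvalue(sm, 0), 1)
})

test_that("maximum-score p-value equals the background mass of the top word", {
  # both columns favor A (0.7 vs 0.1): only "AA" attains the maximum,
  # so P(score >= max) = 1/16 under the uniform background
  mat <- matrix(c(0.7, 0.1, 0.1, 0.1), nrow = 2, ncol = 4, byrow = TRUE)
  colnames(mat) <- c("A", "C", "G", "T")
  sm <- build_scoring_model(motif_model("AA", mat), pseudocount = 0)
  # query at the maximum reportable (discretized) score, as the scanner does
  smax <- sum(apply(sm$score_int, 1, max)) * sm$granularity
  expect_equal(motif_pvalue(sm, smax), 0.0625)
})

test_that("tail distribution is a valid nonincreasing survival function", {
  set.seed(31)
  for (w in c(2L, 5L, 9L)) {
    sm <- build_scoring_model(random_motif(w))
    expect_true(all(diff(sm$tail) <= 1e-12))
    expect_equal(sm$tail[1], 1)     # tail at minimum achievable score
    expect_equal(motif_pvalue(sm, -1e9), 1)
    expect_equal(motif_pvalue(sm, 1e9), 0)
  }
})

test_that("DP tail probabilities match exhaustive enumeration", {
  set.seed(17)
  for (rep in 1:5) {
    w <- sample(2:4, 1)
    motif <- random_motif(w, concentration = 0.5)
    sm <- build_scoring_model(motif)
    enum <- enum_motif_scores(motif)
    g <- sm$granularity
    for (s in sample(enum$scores, 20, replace = TRUE)) {
      dp <- motif_pvalue(sm, s)
      lo <- enum_motif_tail(enum, s + (w + 1) * g / 2)
      hi <- enum_motif_tail(enum, s - (w + 1) * g / 2)
      expect_gte(dp, lo - 1e-12)
      expect_lte(dp, hi + 1e-12)
    }
  }
})

test_that("zero background frequency is rejected", {
  m <- random_motif(3)
  expect_error(build_scoring_model(m, background = c(0.5, 0.5, 0, 0),
                                   pseudocount = 0), "background")
})

test_that("a planted high-information consensus yields exactly one hit", {
  set.seed(23)
  w <- 10L
  delta <- 0.97
  cons <- sample(4L, w, replace = TRUE)
  mat <- matrix((1 - delta) / 3, nrow = w, ncol = 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  mat[cbind(seq_len(w), cons)] <- delta
  motif <- motif_model("planted", mat)
  sm <- build_scoring_model(motif)
  promoter <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                    collapse = "")
  cons_str <- paste(c("A", "C", "G", "T")[cons], collapse = "")
  substr(promoter, 38, 38 + w - 1) <- cons_str     # offset 37 (0-based)
  hits <- scan_promoters(c(gX = promoter), list(sm), p_threshold = 1e-5)
  fwd <- hits[hits$strand == "+", ]
  expect_equal(nrow(fwd), 1L)
  expect_equal(fwd$offset, 37L)
  expect_lte(fwd$p_value, 1e-5)
})

test_that("degenerate scans behave: short promoters, zero threshold, Ns", {
  sm <- build_scoring_model(random_motif(8))
  expect_equal(nrow(scan_promoters(c(g = "ACGT"), list(sm))), 0L)
  expect_equal(nrow(scan_promoters(c(g = strrep("ACGT", 50)), list(sm),
                                   p_threshold = 0)), 0L)
  # a window overlapping an N can never be a hit
  cons <- consensus_string(motif_model("c", sm$prob))
  withN <- paste0(strrep("A", 20), sub("^.", "N", cons), strrep("A", 20))
  hitsN <- scan_promoters(setNames(withN, "g"), list(sm), p_threshold = 1)
  expect_false(any(hitsN$offset == 20L & hitsN$strand == "+"))
})

test_that("scanning is strand-symmetric", {
  set.seed(41)
  motif <- random_motif(6, concentration = 0.4)
  sm_f <- build_scoring_model(motif)
  seqs <- c(p1 = paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                       collapse = ""))
  hits <- scan_promoters(seqs, list(sm_f), p_threshold = 1e-2)
  hits_rc <- scan_promoters(setNames(revcomp(seqs), names(seqs)),
                            list(sm_f), p_threshold = 1e-2)
  # a (+) hit at offset o maps to a (-) hit at L - o - w on the mirror
  L <- nchar(seqs)
  w <- motif$width
  key <- function(h, flip) {
    off <- if (flip) L - h$offset - w else h$offset
    st <- if (flip) chartr("+-", "-+", h$strand) else h$strand
    sort(paste(off, st, round(h$score_bits, 3)))
  }
  expect_identical(key(hits_rc, TRUE), key(hits, FALSE))
})

test_that("lowering the p-value threshold never adds hits", {
  set.seed(53)
  models <- lapply(c(5L, 8L), function(w) build_scoring_model(random_motif(w, 0.4)))
  seqs <- setNames(replicate(5, paste(sample(c("A", "C", "G", "T"), 400,
                                             replace = TRUE), collapse = "")),
                   paste0("g", 1:5))
  prev <- NULL
  for (th in c(1e-2, 1e-3, 1e-4, 1e-5)) {
    h <- scan_promoters(seqs, models, p_threshold = th)
    keys <- paste(h$gene_id, h$motif_id, h$offset, h$strand)
    if (!is.null(prev)) expect_true(all(keys %in% prev))
    prev <- keys
  }
})
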