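expr_from_log2 <- function(log2_vals) {
  # build an expression matrix whose log2(x + 1) equals log2_vals exactly
  make_expr(2^log2_vals - 1)
}

test_that("emt_score is mesenchymal mean minus epithelial mean", {
  log2_vals <- matrix(c(2, 4, 1, 3), ncol = 1,
                      dimnames = list(c("M1", "M2", "E1", "E2"), "s1"))
  sig <- emt_signature(epithelial = c("E1", "E2"),
                       mesenchymal = c("M1", "M2"))
  expect_equal(as.numeric(emt_score(expr_from_log2(log2_vals), sig)), 1.0)
  flat <- matrix(5, 4, 2, dimnames = list(c("M1", "M2", "E1", "E2"),
                                          c("s1", "s2")))
  expect_equal(as.numeric(emt_score(expr_from_log2(flat), sig)), c(0, 0))
  # swapping the sets negates every score
  swapped <- emt_signature(epithelial = c("M1", "M2"),
                           mesenchymal = c("E1", "E2"))
  x <- expr_from_log2(log2_vals)
  expect_equal(as.numeric(emt_score(x, swapped)), -as.numeric(emt_score(x, sig)))
  absent <- emt_signature("E1", "ZZZ")
  expect_error(emt_score(x, absent), "absent")
})

test_that("median_split uses the ties-to-low rule", {
  expect_equal(sum(median_split(setNames(1:10, paste0("s", 1:10))) == "high"),
               5L)
  g <- median_split(setNames(c(1, 2, 2, 3), paste0("s", 1:4)))
  expect_equal(names(g[g == "high"]), "s4")
  expect_equal(sum(g == "low"), 3L)
  expect_error(median_split(setNames(rep(2, 6), paste0("s", 1:6))),
               "cannot split")
  expect_error(median_split(setNames(1:3, paste0("s", 1:3))), ">= 4")
})

test_that("rank_metric matches the signal-to-noise formula by hand", {
  log2_vals <- rbind(G1 = c(5, 6, 7, 1, 2, 3),
                     G2 = c(2, 2.5, 3, 2, 2.5, 3))
  colnames(log2_vals) <- paste0("s", 1:6)
  groups <- setNames(rep(c("high", "low"), each = 3), paste0("s", 1:6))
  metric <- rank_metric(expr_from_log2(log2_vals), groups)
  s2n_hand <- function(hi, lo) {
    sd_hi <- max(sd(hi), 0.2 * abs(mean(hi)), 0.2)
    sd_lo <- max(sd(lo), 0.2 * abs(mean(lo)), 0.2)
    (mean(hi) - mean(lo)) / (sd_hi + sd_lo)
  }
  expect_equal(metric[["G1"]], s2n_hand(c(5, 6, 7), c(1, 2, 3)))
  expect_equal(metric[["G2"]], 0)
  expect_gt(metric[["G1"]], 0)
  expect_equal(names(metric)[1], "G1")  # sorted descending
})

test_that("gsea_es hits the extreme-concentration bounds", {
  ranked <- setNames(seq(10, 1), sprintf("G%02d", 1:10))
  expect_equal(gsea_es(ranked, "G01", weight = 0), 1.0)
  expect_equal(gsea_es(ranked, "G10", weight = 0), -1.0)
  expect_error(gsea_es(ranked, "ZZ"), "no members")
  expect_error(gsea_es(ranked, names(ranked)), "entire")
})

test_that("gsea_es equals the brute-force running sum on a worked list", {
  ranked <- setNames(c(5, 4, 3, 2, 1), sprintf("G%d", 1:5))
  set <- c("G1", "G3")
  # by hand: hits at ranks 1 and 3 with weights 5/8 and 3/8, misses -1/3
  run <- cumsum(c(5 / 8, -1 / 3, 3 / 8, -1 / 3, -1 / 3))
  expect_equal(gsea_es(ranked, set, weight = 1), run[which.max(abs(run))])
  expect_equal(gsea_es(ranked, set, weight = 1), es_brute(ranked, set))
})

test_that("gsea_es matches enumeration over every subset of a 10-gene list", {
  set.seed(41)
  ranked <- sort(rnorm(10), decreasing = TRUE)
  names(ranked) <- sprintf("G%02d", 1:10)
  for (mask in 1:1022) {  # all non-empty proper subsets of 10 genes
    members <- names(ranked)[bitwAnd(mask, 2^(0:9)) > 0]
    expect_equal(gsea_es(ranked, members), es_brute(ranked, members))
  }
})

test_that("gsea significance is deterministic and finds planted shifts", {
  set.seed(42)
  n <- 200
  genes <- sprintf("G%03d", 1:200)
  vals <- matrix(2^rnorm(200 * n, 6), nrow = 200,
                 dimnames = list(genes, sprintf("S%03d", 1:n)))
  set_genes <- genes[1:20]
  groups <- setNames(rep(c("high", "low"), each = n / 2), colnames(vals))
  vals[set_genes, groups == "high"] <- vals[set_genes, groups == "high"] * 2
  x <- make_expr(vals)
  r1 <- gsea_significance(x, groups, set_genes, n_perm = 400, seed = 7)
  r2 <- gsea_significance(x, groups, set_genes, n_perm = 400, seed = 7)
  expect_identical(r1$es, r2$es)
  expect_identical(r1$p_value, r2$p_value)
  expect_gt(r1$es, 0)
  expect_lte(r1$p_value, 0.01)
  # gene_set permutation mode agrees on the direction
  r3 <- gsea_significance(x, groups, set_genes, n_perm = 400,
                          perm_type = "gene_set", seed = 7)
  expect_gt(r3$es, 0)
  expect_lte(r3$p_value, 0.01)
})

test_that("signature_score is the mean z-score of the set genes", {
  log2_vals <- rbind(A = c(1, 2, 3, 4), B = c(4, 3, 2, 1),
                     C = c(2, 2, 2, 2))
  colnames(log2_vals) <- paste0("s", 1:4)
  x <- expr_from_log2(log2_vals)
  single <- signature_score(x, "A")
  expect_equal(as.numeric(single),
               as.numeric(scale(c(1, 2, 3, 4))))
  # constant gene contributes zero
  expect_equal(as.numeric(signature_score(x, "C")), rep(0, 4))
  both <- signature_score(x, c("A", "B"))
  z <- (scale(c(1, 2, 3, 4)) + scale(c(4, 3, 2, 1))) / 2
  expect_equal(as.numeric(both), as.numeric(z))
  expect_error(signature_score(x, "ZZ"), "absent")
})

test_that("score correlations recover planted EMT loadings", {
  spec <- cohort_spec(300, 10, c("NEG", "POS", sprintf("BG%02d", 1:30)),
                      emt_loadings = c(NEG = -0.5, POS = 0.5),
                      epithelial_set = sprintf("EPI%02d", 1:50),
                      mesenchymal_set = sprintf("MES%02d", 1:50),
                      seed = 43)
  co <- generate_cohort(spec)
  sig <- emt_signature(spec$epithelial_set, spec$mesenchymal_set)
  scores <- emt_score(co$tumor, sig)
  # the score tracks the generating factor
  f_e <- setNames(co$truth$factors$tumor$f_e, co$truth$factors$tumor$sample)
  expect_gt(spearman(scores[names(f_e)], f_e)$estimate, 0.8)
  recs <- score_correlation_scan(co$tumor, scores,
                                 genes = c("NEG", "POS", "BG01", "BG02"))
  expect_equal(recs$direction[recs$gene == "POS"], "+")
  expect_equal(recs$direction[recs$gene == "NEG"], "-")
  expect_true(all(recs$significant[recs$gene %in% c("POS", "NEG")]))
  one <- score_correlation(co$tumor$values["POS", ], scores, gene = "POS")
  expect_equal(one$direction, "+")
  few <- setNames(1:5, names(scores)[1:5])
  expect_message(expect_null(score_correlation(few, scores)), "skipped")
})

test_that("gsea nominal p is uniform under label permutation", {
  set.seed(44)
  p_vals <- numeric(200)
  n <- 40
  for (i in 1:200) {
    vals <- matrix(2^rnorm(60 * n, 6), nrow = 60,
                   dimnames = list(sprintf("G%02d", 1:60),
                                   sprintf("S%02d", 1:n)))
    groups <- setNames(sample(rep(c("high", "low"), each = n / 2)),
                       colnames(vals))
    p_vals[i] <- gsea_significance(make_expr(vals), groups,
                                   sprintf("G%02d", 1:12), n_perm = 100,
                                   seed = 4000 + i)$p_value
  }
  expect_gt(suppressWarnings(ks.test(p_vals, "punif")$p.value), 0.01)
})
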