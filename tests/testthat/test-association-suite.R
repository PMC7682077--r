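make_paired <- function(tumor_vals, normal_vals, genes) {
  n <- ncol(tumor_vals)
  dimnames(tumor_vals) <- list(genes, sprintf("S%03d.T", 1:n))
  dimnames(normal_vals) <- list(genes, sprintf("S%03d.N", 1:ncol(normal_vals)))
  list(t = make_expr(tumor_vals, "tumor"),
       n = make_expr(normal_vals, "normal"))
}

test_that("equal tumor and normal expression gives FC = 1 and no calls", {
  set.seed(21)
  vals <- matrix(runif(5 * 20, 1, 100), nrow = 5)
  pp <- make_paired(vals, vals, sprintf("G%d", 1:5))
  de <- differential_expression(pp$t, pp$n)
  expect_true(all(de$estimate == 1))
  expect_true(all(de$direction == "none"))
  expect_false(any(de$significant))
})

test_that("a planted 4x gene is recovered with the signed FC convention", {
  set.seed(22)
  normal <- matrix(2^rnorm(6 * 20, mean = 6, sd = 0.2), nrow = 6)
  tumor <- normal * c(4, rep(1, 5))  # gene 1 exactly 4x
  pp <- make_paired(tumor, normal, sprintf("G%d", 1:6))
  de <- differential_expression(pp$t, pp$n)
  g1 <- de[de$gene == "G1", ]
  expect_equal(g1$estimate, 4.0)
  expect_true(g1$significant)
  expect_equal(g1$direction, "+")
  # and the down-regulated mirror: FC(t, n) = -FC(n, t)
  de_rev <- differential_expression(pp$n, pp$t,
                                    pair_pattern = "[.][TN]$")
  expect_equal(de_rev$estimate[de_rev$gene == "G1"], -4.0)
})

test_that("the fold gate blocks small shifts regardless of p", {
  set.seed(23)
  normal <- matrix(2^rnorm(2 * 200, mean = 8, sd = 0.05), nrow = 2)
  tumor <- normal * c(1.4, 1)
  pp <- make_paired(tumor, normal, c("G1", "G2"))
  de <- differential_expression(pp$t, pp$n)
  g1 <- de[de$gene == "G1", ]
  expect_lt(g1$p, 1e-10)           # tiny p ...
  expect_false(g1$significant)     # ... still not called (|FC| <= 1.5)
})

test_that("cohorts with too few pairs are skipped", {
  set.seed(24)
  vals <- matrix(runif(3 * 4, 1, 10), nrow = 3)
  pp <- make_paired(vals, vals, c("A", "B", "C"))
  expect_message(de <- differential_expression(pp$t, pp$n), "skipped")
  expect_null(de)
})

test_that("family_summary reproduces the printed percent conventions", {
  recs <- rbind(
    data.frame(gene = "HSP90AA1", cohort = sprintf("C%02d", 1:19),
               endpoint = "DE", estimate = 2, p = 0.001, fdr = 0.01,
               direction = "+", significant = TRUE),
    data.frame(gene = "TRAP1", cohort = c("C01", "C02"), endpoint = "DE",
               estimate = -2, p = 0.001, fdr = 0.01, direction = "-",
               significant = TRUE),
    data.frame(gene = "HSPB1", cohort = sprintf("C%02d", 1:14),
               endpoint = "DE", estimate = 2, p = 0.001, fdr = 0.01,
               direction = "+", significant = TRUE),
    data.frame(gene = "HSPB2", cohort = sprintf("C%02d", 1:85),
               endpoint = "DE", estimate = -2, p = 0.001, fdr = 0.01,
               direction = "-", significant = TRUE)
  )
  fam <- family_summary(recs, load_catalog("default"))
  hsp90 <- fam[fam$family == "HSP90", ]
  expect_equal(hsp90$n_up + hsp90$n_down, 21L)
  expect_equal(hsp90$percent_up, 90.5)   # 19/21
  hsp20 <- fam[fam$family == "HSP20", ]
  expect_equal(hsp20$n_up + hsp20$n_down, 99L)
  expect_equal(hsp20$percent_down, 85.9) # 85/99
  empty <- family_summary(recs[0, ], load_catalog("default"))
  expect_true(all(empty$n_total == 0L))
})

test_that("survival p values are calibrated under the null", {
  set.seed(25)
  p_lr <- p_cox <- numeric(200)
  for (i in 1:200) {
    n <- 60
    cl <- data.frame(sample = sprintf("s%02d", 1:n),
                     os_time = rexp(n, 0.01),
                     os_event = rbinom(n, 1, 0.7))
    x <- setNames(2^rnorm(n, 6), cl$sample)
    p_lr[i] <- survival_association(x, cl, "logrank_median")$p
    p_cox[i] <- survival_association(x, cl, "cox")$p
  }
  expect_gt(ks.test(p_lr, "punif")$p.value, 0.01)
  expect_gt(ks.test(p_cox, "punif")$p.value, 0.01)
})

test_that("a planted hazard is recovered and all-censored data degenerates", {
  spec <- cohort_spec(300, 10, c("RISK", sprintf("BG%02d", 1:40)),
                      survival = list(baseline_rate = 0.001,
                                      coefficients = c(RISK = 0.8),
                                      censoring_rate = 0.3),
                      seed = 26)
  co <- generate_cohort(spec)
  scan <- survival_scan(co$tumor, co$clinical, method = "cox")
  risk <- scan[scan$gene == "RISK", ]
  expect_true(risk$significant)
  expect_equal(risk$direction, "+")
  # null genes stay mostly quiet
  expect_lte(sum(scan$significant[scan$gene != "RISK"]), 3)
  cl0 <- co$clinical
  cl0$os_event <- 0L
  x <- setNames(co$tumor$values["RISK", ], colnames(co$tumor$values))
  deg <- survival_association(x, cl0, "cox")
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)
})

test_that("clinical group tests gate small groups and detect shifts", {
  set.seed(27)
  x <- setNames(rnorm(64), sprintf("s%02d", 1:64))
  labels <- setNames(rep(c("A", "B", "C"), c(30, 30, 4)), names(x))
  x[31:60] <- x[31:60] + 2   # B shifted by 2 sd
  rec <- clinical_group_association(x, labels, endpoint = "stage")
  expect_equal(rec$n, 60L)   # group C (4 samples) dropped
  expect_lt(rec$p, 1e-6)
  expect_equal(rec$direction, "+")
  only_small <- setNames(rep(c("A", "B"), c(4, 4)), sprintf("s%02d", 1:8))
  expect_message(
    expect_null(clinical_group_association(x[1:8], only_small)),
    "skipped")
  # three groups run through ANOVA with direction "none"
  l3 <- setNames(rep(c("A", "B", "C"), c(20, 20, 24)), names(x))
  r3 <- clinical_group_association(x, l3)
  expect_equal(r3$direction, "none")
})

test_that("marker correlation flags scaled copies and planted loadings", {
  set.seed(28)
  n <- 100
  marker <- 2^rnorm(n, 6)
  vals <- rbind(MKI67 = marker, COPY = 3 * marker,
                NOISE = 2^rnorm(n, 6))
  colnames(vals) <- sprintf("S%03d", 1:n)
  recs <- marker_correlation(make_expr(vals))
  copy <- recs[recs$gene == "COPY", ]
  expect_equal(copy$estimate, 1)
  expect_equal(copy$direction, "+")
  expect_true(copy$significant)
  expect_false("MKI67" %in% recs$gene)  # marker excluded from targets
  expect_error(marker_correlation(make_expr(vals), marker_gene = "ABSENT"),
               "ABSENT")
})

test_that("planted proliferation loadings are recovered across seeds", {
  hits <- 0L
  for (seed in 1:10) {
    spec <- cohort_spec(300, 10, c("P1", sprintf("BG%02d", 1:30)),
                        prolif_loadings = c(P1 = 0.5), seed = 400 + seed)
    co <- generate_cohort(spec)
    recs <- marker_correlation(co$tumor)
    r <- recs[recs$gene == "P1", ]
    if (r$significant && r$direction == "+") hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("dependency background is the per-line mean and shifts linearly", {
  screen <- rbind(A = c(0.9, 1.2), B = c(1.1, 0.8), C = c(1.0, 1.0))
  colnames(screen) <- c("L1", "L2")
  bg <- dependency_background(screen)
  expect_equal(unname(bg), c(1.0, 1.0))
  shifted <- dependency_background(screen + 0.5)
  expect_equal(unname(shifted), c(1.5, 1.5))
  expect_error(dependency_background(screen[1, , drop = FALSE]), ">= 2")
})

test_that("dependency differences find planted essentials, one-sided", {
  set.seed(29)
  n_lines <- 100
  screen <- matrix(1 + rnorm(50 * n_lines, sd = 0.05), nrow = 50,
                   dimnames = list(sprintf("G%02d", 1:50),
                                   sprintf("L%03d", 1:n_lines)))
  screen["G01", ] <- screen["G01", ] - 0.6  # essential
  screen["G02", ] <- screen["G02", ] + 0.6  # "anti-essential"
  recs <- dependency_difference(screen)
  g1 <- recs[recs$gene == "G01", ]
  expect_equal(g1$estimate, 0.6, tolerance = 0.05)
  expect_true(g1$significant)
  g2 <- recs[recs$gene == "G02", ]
  expect_lt(g2$estimate, 0)
  expect_false(g2$significant)  # one-sided difference gate
  # invariance to a per-line constant shift
  recs2 <- dependency_difference(sweep(screen, 2, rnorm(n_lines), "+"))
  expect_equal(recs2$estimate, recs$estimate, tolerance = 1e-12)
  flat <- dependency_difference(
    matrix(1, 3, 4, dimnames = list(c("A", "B", "C"), paste0("L", 1:4))),
    genes = "A")
  expect_equal(flat$estimate, 0)
  expect_false(flat$significant)
})

test_that("mRNA-protein concordance reports the percent convention", {
  set.seed(30)
  n <- 30
  genes <- sprintf("G%02d", 1:57)
  mrna <- matrix(2^rnorm(57 * n, 6), nrow = 57,
                 dimnames = list(genes, sprintf("S%02d", 1:n)))
  protein <- mrna
  # 8 genes perfectly anti-correlated: excluded by the signed Rs > 0.3 rule
  protein[50:57, ] <- t(apply(mrna[50:57, ], 1,
                              function(r) max(r) + min(r) - r))
  res <- paired_feature_correlation(make_expr(mrna),
                                    make_expr(protein, "tumor"))
  expect_equal(res$n_tested, 57L)
  expect_equal(res$n_significant, 49L)
  expect_equal(res$percent, 86.0)
  ident <- paired_feature_correlation(make_expr(mrna), make_expr(mrna))
  expect_true(all(ident$records$estimate == 1))
  expect_equal(ident$percent, 100.0)
  # independent matrices stay near zero
  indep <- matrix(2^rnorm(57 * n, 6), nrow = 57,
                  dimnames = dimnames(mrna))
  null <- paired_feature_correlation(make_expr(mrna), make_expr(indep))
  expect_lte(null$percent, 5)
})
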