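rec_tbl <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(gene = r[[1]], cohort = r[[2]], endpoint = "x",
               estimate = ifelse(r[[3]] == "+", 0.5, -0.5), p = 0.001,
               fdr = 0.01, direction = r[[3]], significant = r[[4]],
               stringsAsFactors = FALSE)
  }))
}

test_that("classify_dual assigns quadrants only when both axes call", {
  prolif <- rec_tbl(list("DNAJC9", "LUAD", "+", TRUE),
                    list("GENE2", "LUAD", "+", TRUE),
                    list("GENE3", "LUAD", "-", TRUE))
  emt <- rec_tbl(list("DNAJC9", "LUAD", "-", TRUE),
                 list("GENE2", "LUAD", "+", FALSE),
                 list("GENE3", "LUAD", "-", TRUE))
  calls <- classify_dual(prolif, emt)
  expect_equal(calls$quadrant[calls$gene == "DNAJC9"], "P+M-")
  expect_equal(calls$quadrant[calls$gene == "GENE2"], "none")
  expect_equal(calls$quadrant[calls$gene == "GENE3"], "P-M-")
})

test_that("classify_dual matches manual enumeration on an 8-instance table", {
  spec <- list(
    list("A", "C1", "+", TRUE, "+", TRUE, "P+M+"),
    list("A", "C2", "+", TRUE, "-", TRUE, "P+M-"),
    list("B", "C1", "-", TRUE, "+", TRUE, "P-M+"),
    list("B", "C2", "-", TRUE, "-", TRUE, "P-M-"),
    list("C", "C1", "+", TRUE, "+", FALSE, "none"),
    list("C", "C2", "+", FALSE, "+", TRUE, "none"),
    list("D", "C1", "-", TRUE, "-", TRUE, "P-M-"),
    list("D", "C2", "+", TRUE, "-", TRUE, "P+M-"))
  prolif <- do.call(rbind, lapply(spec, function(s) {
    rec_tbl(list(s[[1]], s[[2]], s[[3]], s[[4]]))
  }))
  emt <- do.call(rbind, lapply(spec, function(s) {
    rec_tbl(list(s[[1]], s[[2]], s[[5]], s[[6]]))
  }))
  calls <- classify_dual(prolif, emt)
  want <- vapply(spec, `[[`, "", 7)
  got <- calls$quadrant[match(paste(vapply(spec, `[[`, "", 1),
                                    vapply(spec, `[[`, "", 2)),
                              paste(calls$gene, calls$cohort))]
  expect_equal(got, want)
  dup <- rbind(prolif, prolif[1, ])
  expect_error(classify_dual(dup, emt), "duplicate")
})

test_that("quadrant calls are antisymmetric under negating one axis", {
  set.seed(51)
  random_tbl <- function(genes) {
    do.call(rbind, lapply(genes, function(g) {
      rec_tbl(list(g, "C1", sample(c("+", "-"), 1),
                   sample(c(TRUE, FALSE), 1)))
    }))
  }
  for (i in 1:10) {
    genes <- sprintf("G%02d", 1:30)
    prolif <- random_tbl(genes)
    emt <- random_tbl(genes)
    calls <- classify_dual(prolif, emt)
    emt_neg <- emt
    emt_neg$direction <- chartr("+-", "-+", emt_neg$direction)
    emt_neg$estimate <- -emt_neg$estimate
    flipped <- classify_dual(prolif, emt_neg)
    # negating the EMT axis flips the M sign of every call, nothing else
    expected <- ifelse(calls$quadrant == "none", "none",
                       paste0(substr(calls$quadrant, 1, 2), "M",
                              chartr("+-", "-+",
                                     substr(calls$quadrant, 4, 4))))
    expect_equal(flipped$quadrant, expected)
  }
})

test_that("tally_consistency counts quadrant classes and runs the GOF test", {
  calls <- data.frame(
    gene = sprintf("G%d", 1:4), cohort = "C1",
    quadrant = c("P+M+", "P+M+", "P+M+", "P+M-"),
    stringsAsFactors = FALSE)
  tl <- tally_consistency(calls)
  expect_equal(tl$n_consistent, 3L)
  expect_equal(tl$n_opposite, 1L)
  expect_equal(unname(tl$counts["P+M+"]), 3L)
  empty <- tally_consistency(calls[0, ])
  expect_equal(empty$n_consistent + empty$n_opposite, 0L)
  expect_null(empty$chisq)
  # input order never changes the tallies
  shuffled <- tally_consistency(calls[sample(nrow(calls)), ])
  expect_equal(shuffled$counts, tl$counts)
})

test_that("the published opposite-vs-consistent tally gives chi-squared 63", {
  calls <- data.frame(
    gene = sprintf("G%03d", 1:567), cohort = "C1",
    quadrant = c(rep("P+M-", 200), rep("P-M+", 178),
                 rep("P+M+", 100), rep("P-M-", 89)),
    stringsAsFactors = FALSE)
  tl <- tally_consistency(calls)
  expect_equal(tl$n_opposite, 378L)
  expect_equal(tl$n_consistent, 189L)
  expect_equal(tl$chisq$statistic, 63)
})

test_that("direction matrices build from significant records only", {
  prolif <- rec_tbl(list("A", "C1", "+", TRUE), list("B", "C1", "-", FALSE))
  emt <- rec_tbl(list("A", "C1", "-", TRUE), list("A", "C2", "-", TRUE))
  dm <- build_direction_matrix(list(proliferation = prolif, EMT = emt))
  expect_equal(nrow(dm), 3L)  # B's non-significant record dropped
  expect_setequal(dm$hallmark, c("proliferation", "EMT"))
  expect_error(
    build_direction_matrix(list(EMT = rbind(emt, emt[1, ]))),
    "duplicate")
  # round-trip through the written TSV reproduces the matrix
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(dm, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- utils::read.delim(path, stringsAsFactors = FALSE)
  expect_equal(back, as.data.frame(dm), ignore_attr = TRUE)
})

test_that("the >= 5 hallmark filter keeps broad, consistent genes", {
  mk <- function(gene, dir, hallmarks, cohorts = 1) {
    do.call(rbind, lapply(hallmarks, function(h) {
      data.frame(gene = gene, hallmark = h,
                 cohort = sprintf("C%d", seq_len(cohorts)),
                 direction = dir, stringsAsFactors = FALSE)
    }))
  }
  dm <- rbind(
    mk("BROAD9", "+", sprintf("H%d", 1:9), cohorts = 2),
    mk("FIVE", "+", sprintf("H%d", 1:5)),
    mk("FOUR", "+", sprintf("H%d", 1:4)),
    mk("NEG6", "-", sprintf("H%d", 1:6)),
    mk("MIXED", "+", sprintf("H%d", 1:5)),
    mk("MIXED", "-", sprintf("H%d", 1:2)))
  class(dm) <- c("direction_matrix", "data.frame")
  out <- consistent_direction_filter(dm, min_hallmarks = 5)
  expect_setequal(out$gene[out$direction == "+"],
                  c("BROAD9", "FIVE", "MIXED"))
  expect_equal(out$gene[out$rank == 1], "BROAD9")
  expect_false("FOUR" %in% out$gene)
  expect_true("NEG6" %in% out$gene[out$direction == "-"])
  # strict mode drops hallmarks with opposing cohorts
  strict <- consistent_direction_filter(dm, min_hallmarks = 5,
                                        strict = TRUE)
  expect_false("MIXED" %in% strict$gene[strict$direction == "+"] &&
                 all(strict$n_hallmarks[strict$gene == "MIXED"] >= 5))
})
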