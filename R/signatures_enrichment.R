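# Formula-defined signature scores (EMT, generic hallmark z-scores) and a
# weighted Kolmogorov-Smirnov GSEA engine for median-split phenotypes.

#' EMT signature
#'
#' Disjoint, non-empty epithelial and mesenchymal gene sets. The EMT score
#' is mean(mesenchymal) - mean(epithelial) on log2(x + 1) expression, so
#' higher = more mesenchymal.
#'
#' @param epithelial,mesenchymal Character vectors of gene symbols.
#' @return An `emt_signature` list.
#' @export
emt_signature <- function(epithelial, mesenchymal) {
  epithelial <- unique(epithelial)
  mesenchymal <- unique(mesenchymal)
  if (!length(epithelial) || !length(mesenchymal)) {
    stop("both signature sets must be non-empty")
  }
  if (length(intersect(epithelial, mesenchymal))) {
    stop("epithelial and mesenchymal sets must be disjoint")
  }
  structure(list(epithelial = epithelial, mesenchymal = mesenchymal),
            class = "emt_signature")
}

#' Per-sample EMT score
#'
#' For each sample, the mean log2(x + 1) expression over the present
#' mesenchymal genes minus the mean over the present epithelial genes.
#' Missing signature genes are logged; a set entirely absent from the
#' matrix is an error.
#'
#' @param expr Expression matrix.
#' @param sig An [emt_signature()].
#' @return Named numeric vector of per-sample scores (attribute
#'   `score_name = "EMT"`).
#' @export
emt_score <- function(expr, sig) {
  stopifnot(inherits(sig, "emt_signature"))
  vals <- log2(ex_values(expr) + 1)
  e <- intersect(sig$epithelial, rownames(vals))
  m <- intersect(sig$mesenchymal, rownames(vals))
  if (!length(e)) stop("epithelial set entirely absent from the matrix")
  if (!length(m)) stop("mesenchymal set entirely absent from the matrix")
  n_missing <- (length(sig$epithelial) - length(e)) +
    (length(sig$mesenchymal) - length(m))
  if (n_missing > 0) {
    message(n_missing, " signature gene(s) absent from the matrix")
  }
  score <- colMeans(vals[m, , drop = FALSE]) -
    colMeans(vals[e, , drop = FALSE])
  attr(score, "score_name") <- "EMT"
  score
}

#' Median split of a gene's expression
#'
#' Samples strictly above the median go to `"high"`, the rest (ties
#' included) to `"low"`. Needs >= 4 samples and both groups non-empty
#' (constant expression, or a median equal to the maximum, cannot be
#' split).
#'
#' @param expr_gene Named numeric vector of one gene's expression.
#' @return Named character vector of `"high"` / `"low"` labels.
#' @export
median_split <- function(expr_gene) {
  if (length(expr_gene) < 4L) stop("median split needs >= 4 samples")
  med <- stats::median(expr_gene)
  groups <- ifelse(expr_gene > med, "high", "low")
  if (!any(groups == "high") || !any(groups == "low")) {
    stop("cannot split: no samples above the median")
  }
  names(groups) <- names(expr_gene)
  groups
}

#' Signal-to-noise ranking metric for a two-group comparison
#'
#' Per gene, `(mean_high - mean_low) / (sd_high + sd_low)` on log2(x + 1)
#' expression, with each group's sd floored at `max(0.2 * |mean|, 0.2)`
#' (the standard GSEA variance floor), sorted descending. Both groups need
#' >= 3 samples.
#'
#' @param expr Expression matrix.
#' @param groups Named `"high"`/`"low"` labels as from [median_split()].
#' @return Named numeric vector of metric values, sorted descending.
#' @export
rank_metric <- function(expr, groups) {
  vals <- log2(ex_values(expr) + 1)
  shared <- intersect(colnames(vals), names(groups))
  g <- groups[shared]
  hi <- shared[g == "high"]
  lo <- shared[g == "low"]
  if (length(hi) < 3L || length(lo) < 3L) {
    stop("both groups need >= 3 samples")
  }
  s2n <- s2n_metric(vals[, hi, drop = FALSE], vals[, lo, drop = FALSE])
  sort(s2n, decreasing = TRUE)
}

# Vectorized signal-to-noise with the GSEA sd floor.
s2n_metric <- function(hi_mat, lo_mat) {
  m_hi <- rowMeans(hi_mat)
  m_lo <- rowMeans(lo_mat)
  sd_hi <- apply(hi_mat, 1L, stats::sd)
  sd_lo <- apply(lo_mat, 1L, stats::sd)
  sd_hi <- pmax(sd_hi, 0.2 * abs(m_hi), 0.2)
  sd_lo <- pmax(sd_lo, 0.2 * abs(m_lo), 0.2)
  (m_hi - m_lo) / (sd_hi + sd_lo)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list accumulating `|r_j|^p / sum_hits |r|^p` at set
#' members and `-1 / (N - N_H)` at non-members; the enrichment score is the
#' maximum-magnitude (signed) deviation of the running sum. With
#' `weight = 0` this is the classic unweighted KS statistic. If every hit
#' has `|r| = 0` the hit increments fall back to equal weights.
#'
#' @param ranked Named metric vector sorted decreasing (from
#'   [rank_metric()]).
#' @param gene_set Character vector of set members; must intersect the
#'   ranked list but not cover it entirely.
#' @param weight Exponent p on `|r|` (default 1, the GSEA default).
#' @return The enrichment score in \[-1, 1\].
#' @export
gsea_es <- function(ranked, gene_set, weight = 1) {
  hits <- names(ranked) %in% gene_set
  n <- length(ranked)
  n_hit <- sum(hits)
  if (n_hit == 0L) stop("gene set has no members in the ranked list")
  if (n_hit == n) stop("gene set covers the entire ranked list")
  w <- abs(ranked)^weight
  denom <- sum(w[hits])
  if (denom == 0) {
    w[] <- 1
    denom <- n_hit
  }
  steps <- ifelse(hits, w / denom, -1 / (n - n_hit))
  running <- cumsum(steps)
  mx <- max(running)
  mn <- min(running)
  # maximum-magnitude signed deviation; an exact tie resolves positive
  unname(if (mx + mn >= -1e-12) mx else mn)
}

#' GSEA significance for a median-split phenotype
#'
#' Observed enrichment of `gene_set` in the ranked comparison of the two
#' groups, with a permutation null: `perm_type = "phenotype"` relabels the
#' samples (group sizes preserved) and recomputes the metric per
#' permutation; `perm_type = "gene_set"` draws random same-size sets from
#' the ranked universe (for small cohorts). NES is the observed ES divided
#' by the mean |null ES| of the same sign; the nominal p is
#' `(1 + #same-sign null ES at least as extreme) / (1 + #same-sign nulls)`.
#' With no same-sign nulls, p falls back to `1 / (1 + n_perm)` and NES is
#' NA.
#'
#' @param expr Expression matrix.
#' @param groups `"high"`/`"low"` labels as from [median_split()].
#' @param gene_set Character vector of set members.
#' @param n_perm Number of permutations (default 1000; < 100 warns).
#' @param perm_type `"phenotype"` (default) or `"gene_set"`.
#' @param weight KS weight exponent (default 1).
#' @param seed Seed for the permutation stream.
#' @return An `enrichment_result`: `es`, `nes`, `p_value`, `n_perm`,
#'   `perm_type`, `seed`, `set_size`.
#' @export
gsea_significance <- function(expr, groups, gene_set, n_perm = 1000,
                              perm_type = c("phenotype", "gene_set"),
                              weight = 1, seed = 1L) {
  perm_type <- match.arg(perm_type)
  if (n_perm < 100) warning("n_perm < 100 gives a coarse nominal p")
  vals <- log2(ex_values(expr) + 1)
  shared <- intersect(colnames(vals), names(groups))
  g <- groups[shared]
  hi <- g == "high"
  if (sum(hi) < 3L || sum(!hi) < 3L) stop("both groups need >= 3 samples")
  mat <- vals[, shared, drop = FALSE]
  obs_metric <- sort(s2n_metric(mat[, hi, drop = FALSE],
                                mat[, !hi, drop = FALSE]),
                     decreasing = TRUE)
  es <- gsea_es(obs_metric, gene_set, weight = weight)
  set_size <- sum(names(obs_metric) %in% gene_set)
  null_es <- with_seed(seed, {
    if (perm_type == "phenotype") {
      n_hi <- sum(hi)
      vapply(seq_len(n_perm), function(b) {
        idx <- sample.int(ncol(mat), n_hi)
        metric <- sort(s2n_metric(mat[, idx, drop = FALSE],
                                  mat[, -idx, drop = FALSE]),
                       decreasing = TRUE)
        gsea_es(metric, gene_set, weight = weight)
      }, numeric(1L))
    } else {
      universe <- names(obs_metric)
      vapply(seq_len(n_perm), function(b) {
        gsea_es(obs_metric, sample(universe, set_size), weight = weight)
      }, numeric(1L))
    }
  })
  same_sign <- null_es[sign(null_es) == sign(es)]
  if (length(same_sign)) {
    nes <- es / mean(abs(same_sign))
    p <- (1 + sum(abs(same_sign) >= abs(es))) / (1 + length(same_sign))
  } else {
    nes <- NA_real_
    p <- 1 / (1 + n_perm)
  }
  structure(list(es = es, nes = nes, p_value = p, n_perm = n_perm,
                 perm_type = perm_type, seed = seed, set_size = set_size),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment_result> ES=%.3f NES=%.3f p=%.4g (%s, %d perms, set=%d)\n",
    x$es, x$nes, x$p_value, x$perm_type, x$n_perm, x$set_size))
  invisible(x)
}

#' GSEA scan over median-split phenotype genes
#'
#' For each phenotype gene, splits the samples at its median expression and
#' tests the enrichment of `gene_set` between the two groups; BH across
#' phenotype genes within the cohort. Per-gene seeds are derived as
#' `seed + index`.
#'
#' @param expr Expression matrix.
#' @param phenotype_genes Genes whose median split defines the groups.
#' @param gene_set Character vector of set members.
#' @param set_name Label stored in the records.
#' @inheritParams gsea_significance
#' @param fdr_max FDR gate.
#' @return Data frame: phenotype_gene, cohort, set, es, nes, p, fdr,
#'   direction, significant, n_perm, seed.
#' @export
gsea_scan <- function(expr, phenotype_genes, gene_set, set_name = "set",
                      n_perm = 1000, perm_type = c("phenotype", "gene_set"),
                      weight = 1, seed = 1L, fdr_max = 0.05) {
  perm_type <- match.arg(perm_type)
  vals <- ex_values(expr)
  phenotype_genes <- intersect(phenotype_genes, rownames(vals))
  rows <- lapply(seq_along(phenotype_genes), function(i) {
    g <- phenotype_genes[i]
    groups <- median_split(vals[g, ])
    r <- gsea_significance(expr, groups, gene_set, n_perm = n_perm,
                           perm_type = perm_type, weight = weight,
                           seed = seed + i)
    data.frame(phenotype_gene = g, cohort = ex_cohort(expr),
               set = set_name, es = r$es, nes = r$nes, p = r$p_value,
               n_perm = r$n_perm, seed = r$seed, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  out$direction <- ifelse(out$es > 0, "+", ifelse(out$es < 0, "-", "none"))
  out$significant <- out$fdr < fdr_max
  out
}

#' Mean z-score signature score
#'
#' Per sample, the mean over present set genes of the gene's log2(x + 1)
#' expression z-scored across samples (genes constant across samples score
#' 0). The simple, swappable default used for generic hallmark signatures.
#'
#' @param expr Expression matrix.
#' @param gene_set Character vector; at least one member must be present.
#' @param score_name Name stored in the `"score_name"` attribute.
#' @return Named numeric vector of per-sample scores.
#' @export
signature_score <- function(expr, gene_set, score_name = "signature") {
  vals <- log2(ex_values(expr) + 1)
  present <- intersect(gene_set, rownames(vals))
  if (!length(present)) stop("gene set entirely absent from the matrix")
  sub <- vals[present, , drop = FALSE]
  mu <- rowMeans(sub)
  sdv <- apply(sub, 1L, stats::sd)
  z <- (sub - mu) / ifelse(sdv == 0, Inf, sdv)
  score <- colMeans(z)
  attr(score, "score_name") <- score_name
  score
}

#' Correlation between a gene and a per-sample score
#'
#' Spearman correlation of one gene's expression with a sample score vector
#' (EMT, hallmark, ...) over the shared samples; significant when
#' `|Rs| > rs_min` and `FDR < fdr_max` (the FDR is attached by the scan
#' wrapper). Fewer than 10 shared samples skips the gene.
#'
#' @param expr_gene Named expression vector.
#' @param scores Named score vector (e.g. from [emt_score()]).
#' @param rs_min,fdr_max Significance gates.
#' @param gene,cohort,endpoint Labels stamped on the record.
#' @return A one-row association record, or `NULL` when skipped.
#' @export
score_correlation <- function(expr_gene, scores, rs_min = 0.3,
                              fdr_max = 0.05, gene = "gene",
                              cohort = "cohort", endpoint = "score_corr") {
  shared <- intersect(names(expr_gene), names(scores))
  if (length(shared) < 10L) {
    message("gene ", gene, ": fewer than 10 shared samples; skipped")
    return(NULL)
  }
  fit <- spearman(expr_gene[shared], scores[shared])
  rec <- assoc_record(gene, cohort, endpoint, fit$estimate, fit$p_value,
                      direction = direction_of(fit$estimate),
                      n = fit$n, degenerate = fit$degenerate)
  adjust_records(rec, endpoint_thresholds(rs_score = rs_min, fdr = fdr_max))
}

#' Score-correlation scan over a gene panel
#'
#' @param expr Expression matrix.
#' @param scores Named score vector.
#' @param genes Panel (default all genes).
#' @inheritParams score_correlation
#' @return Association records, BH-adjusted across genes within the cohort.
#' @export
score_correlation_scan <- function(expr, scores, genes = NULL, rs_min = 0.3,
                                   fdr_max = 0.05, endpoint = "score_corr") {
  vals <- ex_values(expr)
  genes <- intersect(genes %||% rownames(vals), rownames(vals))
  shared <- intersect(colnames(vals), names(scores))
  if (length(shared) < 10L) {
    message("fewer than 10 shared samples; scan skipped")
    return(NULL)
  }
  records <- do.call(rbind, lapply(genes, function(g) {
    fit <- spearman(vals[g, shared], scores[shared])
    assoc_record(g, ex_cohort(expr), endpoint, fit$estimate, fit$p_value,
                 direction = direction_of(fit$estimate), n = fit$n,
                 degenerate = fit$degenerate)
  }))
  adjust_records(records,
                 endpoint_thresholds(rs_score = rs_min, fdr = fdr_max))
}
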