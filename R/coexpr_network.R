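# Per-cohort co-expression networks among a gene panel, tumor/normal edge
# classification, and the sample-size-matched resampling null for network
# disruption.

#' Build a co-expression network for one cohort/condition
#'
#' Tests all gene pairs of the panel with Spearman correlation, adjusts the
#' p values with Benjamini-Hochberg over all tested pairs within this
#' cohort, and keeps pairs with `Rs > rs_min` and `FDR < fdr_max` as edges.
#' The significance rule is signed (positive Rs) by default; set
#' `use_abs = TRUE` to admit strong negative correlations too. Cohorts with
#' fewer than `min_samples` samples are skipped (returns `NULL` with a
#' message). Panel genes absent from the matrix are logged and skipped.
#'
#' @param expr An [expression_matrix()] (or bare named matrix).
#' @param genes Gene panel; default all genes in `expr`.
#' @param rs_min Spearman threshold (default 0.3).
#' @param fdr_max FDR threshold (default 0.05).
#' @param min_samples Minimum sample count (default 10).
#' @param use_abs Use `|Rs| > rs_min` instead of the signed rule.
#' @return A `coexpr_network` (edges with Rs/p/FDR, thresholds, counts), or
#'   `NULL` when the cohort is skipped.
#' @export
build_network <- function(expr, genes = NULL, rs_min = 0.3, fdr_max = 0.05,
                          min_samples = 10, use_abs = FALSE) {
  vals <- ex_values(expr)
  if (ncol(vals) < min_samples) {
    message("cohort ", ex_cohort(expr), "/", ex_condition(expr),
            " skipped: ", ncol(vals), " samples < min_samples = ",
            min_samples)
    return(NULL)
  }
  genes <- genes %||% rownames(vals)
  missing <- setdiff(genes, rownames(vals))
  if (length(missing)) {
    message("skipping ", length(missing),
            " panel gene(s) absent from the matrix")
    genes <- setdiff(genes, missing)
  }
  if (length(genes) < 2L) stop("need at least two panel genes present")
  mat <- vals[genes, , drop = FALSE]
  constant <- apply(mat, 1L, function(r) stats::sd(r) == 0)
  if (any(constant)) {
    message("skipping ", sum(constant), " constant gene(s)")
    mat <- mat[!constant, , drop = FALSE]
    genes <- rownames(mat)
    if (length(genes) < 2L) stop("need at least two non-constant genes")
  }
  sm <- spearman_matrix(mat)
  ut <- upper.tri(sm$rs)
  idx <- which(ut, arr.ind = TRUE)
  pairs <- data.frame(
    gene_a = genes[idx[, 1L]], gene_b = genes[idx[, 2L]],
    rs = sm$rs[ut], p = sm$p[ut], stringsAsFactors = FALSE
  )
  cp <- canonical_pairs(pairs$gene_a, pairs$gene_b)
  pairs$gene_a <- cp$gene_a
  pairs$gene_b <- cp$gene_b
  pairs$fdr <- bh_adjust(pairs$p)
  passes <- if (use_abs) abs(pairs$rs) > rs_min else pairs$rs > rs_min
  edges <- pairs[passes & pairs$fdr < fdr_max, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(
    cohort = ex_cohort(expr), condition = ex_condition(expr),
    genes = genes, edges = edges, n_samples = sm$n,
    n_tested = nrow(pairs),
    thresholds = list(rs_min = rs_min, fdr_max = fdr_max,
                      min_samples = min_samples, use_abs = use_abs)
  ), class = "coexpr_network")
}

#' @export
print.coexpr_network <- function(x, ...) {
  cat(sprintf(
    "<coexpr_network> %s/%s: %d edges of %d tested pairs (%d genes, n=%d)\n",
    x$cohort, x$condition, nrow(x$edges), x$n_tested, length(x$genes),
    x$n_samples))
  invisible(x)
}

# Fast edge count for the resampling null: no object construction.
count_edges <- function(mat, rs_min, fdr_max, use_abs = FALSE) {
  sm <- spearman_matrix(mat)
  ut <- upper.tri(sm$rs)
  rs <- sm$rs[ut]
  fdr <- bh_adjust(sm$p[ut])
  passes <- if (use_abs) abs(rs) > rs_min else rs > rs_min
  sum(passes & fdr < fdr_max)
}

#' Ratio of normal to tumor edge counts
#'
#' Reported to two decimal places; a zero tumor count gives `Inf` (flagged
#' complete disruption).
#'
#' @param n_normal,n_tumor Edge counts.
#' @return Fold decrease, rounded to 2 decimals.
#' @export
fold_decrease <- function(n_normal, n_tumor) {
  if (n_tumor == 0) return(Inf)
  round(n_normal / n_tumor, 2L)
}

#' Classify tumor/normal edge differences
#'
#' Assigns every tested pair of the shared gene universe to
#' `tumor_only` / `normal_only` / `shared` / `neither` and reports the
#' normal-to-tumor fold decrease in edge count.
#'
#' @param tumor_net,normal_net `coexpr_network`s over the same gene
#'   universe.
#' @return A `network_comparison`: per-pair classes, class counts,
#'   `fold_decrease`.
#' @export
compare_networks <- function(tumor_net, normal_net) {
  stopifnot(inherits(tumor_net, "coexpr_network"),
            inherits(normal_net, "coexpr_network"))
  if (!setequal(tumor_net$genes, normal_net$genes)) {
    stop("networks must share the same gene universe")
  }
  genes <- sort(tumor_net$genes)
  idx <- utils::combn(genes, 2L)
  keys <- pair_keys(idx[1L, ], idx[2L, ])
  in_t <- keys %in% pair_keys(tumor_net$edges$gene_a, tumor_net$edges$gene_b)
  in_n <- keys %in% pair_keys(normal_net$edges$gene_a,
                              normal_net$edges$gene_b)
  class <- ifelse(in_t & in_n, "shared",
                  ifelse(in_t, "tumor_only",
                         ifelse(in_n, "normal_only", "neither")))
  classes <- data.frame(gene_a = idx[1L, ], gene_b = idx[2L, ],
                        class = class, stringsAsFactors = FALSE)
  counts <- c(shared = sum(class == "shared"),
              tumor_only = sum(class == "tumor_only"),
              normal_only = sum(class == "normal_only"),
              neither = sum(class == "neither"))
  structure(list(
    cohort = tumor_net$cohort,
    classes = classes,
    counts = counts,
    n_edges_tumor = nrow(tumor_net$edges),
    n_edges_normal = nrow(normal_net$edges),
    fold_decrease = fold_decrease(nrow(normal_net$edges),
                                  nrow(tumor_net$edges))
  ), class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  cat(sprintf(
    "<network_comparison> %s: normal %d vs tumor %d edges (%.2f-fold decrease)\n",
    x$cohort, x$n_edges_normal, x$n_edges_tumor, x$fold_decrease))
  print(x$counts)
  invisible(x)
}

#' Size-matched resampling null for network disruption
#'
#' Each iteration subsamples the larger condition without replacement down
#' to the smaller condition's sample size, rebuilds both networks at the
#' matched size, and records the two edge counts. The empirical p for "the
#' normal network has at least as many edges as the tumor network only by
#' sample-size artefact" is
#' `(1 + #iterations with normal_edges <= tumor_edges) / (1 + n_iter)`
#' (add-one correction, so p is never zero). Iteration i is seeded as
#' `seed + i` so individual iterations are rerunnable.
#'
#' @param tumor_expr,normal_expr Expression matrices for the two conditions.
#' @param genes Gene panel (default: intersection of row names).
#' @param n_iter Number of resampling iterations (default 1000).
#' @param seed Master seed.
#' @inheritParams build_network
#' @return A `resampling_null`: iteration table, empirical p, matched size.
#' @export
resampling_null <- function(tumor_expr, normal_expr, genes = NULL,
                            n_iter = 1000, seed = 1L, rs_min = 0.3,
                            fdr_max = 0.05, min_samples = 10,
                            use_abs = FALSE) {
  tv <- ex_values(tumor_expr)
  nv <- ex_values(normal_expr)
  genes <- genes %||% intersect(rownames(tv), rownames(nv))
  genes <- intersect(intersect(genes, rownames(tv)), rownames(nv))
  if (length(genes) < 2L) stop("need at least two shared panel genes")
  m <- min(ncol(tv), ncol(nv))
  if (m < min_samples) {
    stop("matched sample size ", m, " < min_samples = ", min_samples)
  }
  tv <- tv[genes, , drop = FALSE]
  nv <- nv[genes, , drop = FALSE]
  counts <- matrix(NA_integer_, nrow = n_iter, ncol = 2L,
                   dimnames = list(NULL, c("n_edges_normal_sub",
                                           "n_edges_tumor_sub")))
  for (i in seq_len(n_iter)) {
    with_seed(seed + i, {
      ti <- if (ncol(tv) > m) tv[, sample(ncol(tv), m), drop = FALSE] else tv
      ni <- if (ncol(nv) > m) nv[, sample(ncol(nv), m), drop = FALSE] else nv
      counts[i, ] <- c(count_edges(ni, rs_min, fdr_max, use_abs),
                       count_edges(ti, rs_min, fdr_max, use_abs))
    })
  }
  p <- (1 + sum(counts[, 1L] <= counts[, 2L])) / (1 + n_iter)
  structure(list(
    n_iter = n_iter, counts = as.data.frame(counts), empirical_p = p,
    seed = seed, matched_size = m, genes = genes,
    thresholds = list(rs_min = rs_min, fdr_max = fdr_max, use_abs = use_abs)
  ), class = "resampling_null")
}

#' @export
print.resampling_null <- function(x, ...) {
  cat(sprintf(
    "<resampling_null> %d iterations at matched n=%d: empirical p = %.4g\n",
    x$n_iter, x$matched_size, x$empirical_p))
  invisible(x)
}

#' Overlap between co-expression edges and a PPI edge list
#'
#' @param net A `coexpr_network` or a data frame with columns
#'   `gene_a`, `gene_b` (unique pairs).
#' @param ppi Canonical PPI edge list as from [read_ppi()].
#' @return List with `overlap`, `total` and `percent` (1 decimal place).
#' @export
ppi_overlap <- function(net, ppi) {
  pairs <- if (inherits(net, "coexpr_network")) net$edges else net
  if (is.null(pairs) || nrow(pairs) == 0L) {
    stop("network has no edges; PPI overlap undefined")
  }
  keys <- unique(pair_keys(pairs$gene_a, pairs$gene_b))
  ppi_keys <- if (nrow(ppi)) pair_keys(ppi$gene_a, ppi$gene_b) else character()
  overlap <- sum(keys %in% ppi_keys)
  list(overlap = overlap, total = length(keys),
       percent = round(100 * overlap / length(keys), 1L))
}
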