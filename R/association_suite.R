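# Gene x cohort x endpoint association records: differential expression,
# survival and clinical-group tests, proliferation-marker correlation,
# dependency-screen comparison and mRNA-protein concordance. All results use
# one long format (gene, cohort, endpoint, estimate, p, fdr, direction,
# significant) with BH adjustment within each (cohort, endpoint) stratum.

assoc_record <- function(gene, cohort, endpoint, estimate, p,
                         direction = "none", n = NA_integer_,
                         degenerate = FALSE) {
  data.frame(gene = gene, cohort = cohort, endpoint = endpoint,
             estimate = estimate, p = p, fdr = NA_real_,
             direction = direction, significant = NA,
             n = n, degenerate = degenerate, stringsAsFactors = FALSE)
}

direction_of <- function(x) {
  ifelse(is.na(x) | x == 0, "none", ifelse(x > 0, "+", "-"))
}

#' Endpoint significance thresholds
#'
#' The per-endpoint gates applied after FDR adjustment: differential
#' expression needs `|FC| > fc` and `FDR < fdr`; marker correlation
#' `|Rs| > rs_marker`; score correlation `|Rs| > rs_score`; mRNA-protein
#' concordance `Rs > rs_mrna_protein` (signed); dependency
#' `difference > diff`; survival and clinical-group endpoints need only
#' `FDR < fdr`.
#'
#' @param fc,fdr,rs_marker,rs_score,rs_mrna_protein,diff Threshold values.
#' @return Named list of thresholds.
#' @export
endpoint_thresholds <- function(fc = 1.5, fdr = 0.05, rs_marker = 0.2,
                                rs_score = 0.3, rs_mrna_protein = 0.3,
                                diff = 0.5) {
  list(fc = fc, fdr = fdr, rs_marker = rs_marker, rs_score = rs_score,
       rs_mrna_protein = rs_mrna_protein, diff = diff)
}

# BH within each (cohort, endpoint) stratum, then endpoint-specific gates.
# Degenerate records keep p but are never significant.
adjust_records <- function(records, thresholds = endpoint_thresholds()) {
  if (is.null(records) || nrow(records) == 0L) return(records)
  records$fdr <- NA_real_
  for (s in split(seq_len(nrow(records)),
                  paste(records$cohort, records$endpoint, sep = "\r"))) {
    records$fdr[s] <- bh_adjust(records$p[s])
  }
  est <- abs(records$estimate)
  gate <- rep(TRUE, nrow(records))
  de <- records$endpoint == "DE"
  gate[de] <- est[de] > thresholds$fc
  mk <- grepl("^marker_corr", records$endpoint)
  gate[mk] <- est[mk] > thresholds$rs_marker
  sc <- grepl("^score_corr", records$endpoint)
  gate[sc] <- est[sc] > thresholds$rs_score
  mp <- records$endpoint == "mrna_protein"
  gate[mp] <- records$estimate[mp] > thresholds$rs_mrna_protein
  dp <- records$endpoint == "dependency"
  gate[dp] <- records$estimate[dp] > thresholds$diff
  records$significant <- !records$degenerate & !is.na(records$fdr) &
    records$fdr < thresholds$fdr & gate & !is.na(records$estimate)
  records
}

# Strip a trailing condition suffix to recover the shared patient prefix.
sample_prefix <- function(ids, pattern = "[._-](T|N|tumor|normal)$") {
  sub(pattern, "", ids, ignore.case = TRUE)
}

#' Differential expression between tumor and paired normal samples
#'
#' The signed fold change comes from linear-scale means:
#' `FC = mean_T / mean_N` when the ratio is >= 1, else
#' `FC = -mean_N / mean_T`, so `|FC| > fc_min` gates both directions and the
#' sign is the direction. The p value is a t test on `log2(x + 1)` — paired
#' by default, matching tumor/normal samples on the identifier prefix
#' obtained by stripping a trailing condition suffix (unmatched samples are
#' dropped with a message). BH runs across genes within the cohort. Cohorts
#' with fewer than `min_pairs` pairs are skipped (`NULL`); genes with a zero
#' normal and tumor mean are flagged degenerate and excluded from the
#' significant set.
#'
#' @param tumor,normal Expression matrices for the two conditions.
#' @param paired Paired t test on matched samples (default) or unpaired.
#' @param fc_min,fdr_max Significance gates (`|FC| > fc_min`,
#'   `FDR < fdr_max`).
#' @param min_pairs Minimum number of (paired) samples.
#' @param pair_pattern Regex stripped from sample ids to find the shared
#'   prefix in paired mode.
#' @return Association records with `endpoint = "DE"`, `estimate` = signed
#'   FC and a `log2fc` column, or `NULL` when skipped.
#' @export
differential_expression <- function(tumor, normal, paired = TRUE,
                                    fc_min = 1.5, fdr_max = 0.05,
                                    min_pairs = 5,
                                    pair_pattern = "[._-](T|N|tumor|normal)$") {
  tv <- ex_values(tumor)
  nv <- ex_values(normal)
  genes <- intersect(rownames(tv), rownames(nv))
  if (!length(genes)) stop("no shared genes between conditions")
  tv <- tv[genes, , drop = FALSE]
  nv <- nv[genes, , drop = FALSE]
  if (paired) {
    tp <- sample_prefix(colnames(tv), pair_pattern)
    np <- sample_prefix(colnames(nv), pair_pattern)
    shared <- intersect(tp, np)
    dropped <- (ncol(tv) - length(shared)) + (ncol(nv) - length(shared))
    if (dropped > 0) message("dropped ", dropped, " unmatched sample(s)")
    if (length(shared) < min_pairs) {
      message("cohort skipped: ", length(shared), " pairs < min_pairs = ",
              min_pairs)
      return(NULL)
    }
    tv <- tv[, match(shared, tp), drop = FALSE]
    nv <- nv[, match(shared, np), drop = FALSE]
  } else if (ncol(tv) < min_pairs || ncol(nv) < min_pairs) {
    message("cohort skipped: fewer than ", min_pairs,
            " samples in a condition")
    return(NULL)
  }
  lt <- log2(tv + 1)
  ln <- log2(nv + 1)
  cohort <- ex_cohort(tumor)
  records <- do.call(rbind, lapply(seq_along(genes), function(i) {
    mt <- mean(tv[i, ])
    mn <- mean(nv[i, ])
    if (mn == 0 && mt == 0) {
      return(assoc_record(genes[i], cohort, "DE", NA_real_, 1,
                          degenerate = TRUE))
    }
    fc <- if (mn == 0 || (mt > 0 && mt / mn >= 1)) mt / mn else -mn / mt
    tt <- if (paired) t_test(lt[i, ], ln[i, ], paired = TRUE)
          else t_test(lt[i, ], ln[i, ], paired = FALSE)
    rec <- assoc_record(genes[i], cohort, "DE", fc, tt$p_value,
                        direction = direction_of(log2(abs(fc)) * sign(fc)),
                        n = tt$n, degenerate = !is.finite(fc))
    rec
  }))
  # direction from the signed FC: |FC| = 1 means no change
  records$direction <- ifelse(is.na(records$estimate), "none",
                              ifelse(abs(records$estimate) == 1, "none",
                                     ifelse(records$estimate > 1, "+", "-")))
  records$log2fc <- ifelse(is.na(records$estimate), NA_real_,
                           sign(records$estimate) *
                             log2(pmax(abs(records$estimate),
                                       .Machine$double.eps)))
  adjust_records(records, endpoint_thresholds(fc = fc_min, fdr = fdr_max))
}

#' Family-level tallies of significant differential expression
#'
#' Counts significant up/down instances per catalog family over all cohorts
#' and reports the percentages to one decimal place. Genes absent from the
#' catalog are tallied under `"unassigned"` with a message.
#'
#' @param records Association records carrying `direction` and
#'   `significant` (typically `endpoint == "DE"` rows).
#' @param catalog An `hsp_catalog`.
#' @return Data frame: family, n_up, n_down, n_total, percent_up,
#'   percent_down.
#' @export
family_summary <- function(records, catalog) {
  fam_levels <- unique(catalog$family)
  if (is.null(records) || nrow(records) == 0L) {
    return(data.frame(family = fam_levels,
                      n_up = 0L, n_down = 0L, n_total = 0L,
                      percent_up = NA_real_, percent_down = NA_real_,
                      stringsAsFactors = FALSE))
  }
  sig <- records[records$significant %in% TRUE &
                   records$direction %in% c("+", "-"), , drop = FALSE]
  fam <- catalog$family[match(sig$gene, catalog$gene)]
  if (anyNA(fam)) {
    message(sum(is.na(fam)), " significant record(s) from gene(s) absent ",
            "from the catalog tallied as 'unassigned'")
    fam[is.na(fam)] <- "unassigned"
  }
  fam_levels <- unique(c(fam_levels, unique(fam)))
  out <- do.call(rbind, lapply(fam_levels, function(f) {
    up <- sum(fam == f & sig$direction == "+")
    down <- sum(fam == f & sig$direction == "-")
    total <- up + down
    data.frame(family = f, n_up = up, n_down = down, n_total = total,
               percent_up = if (total) round(100 * up / total, 1L) else NA_real_,
               percent_down = if (total) round(100 * down / total, 1L) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Survival association for one gene
#'
#' `method = "logrank_median"` dichotomizes expression at the median (ties
#' to the low group) and runs the two-group log-rank test; the direction is
#' the sign of the excess deaths in the high-expression group (so `"+"`
#' means high expression, worse survival). `method = "cox"` fits the
#' univariate Cox model on continuous expression; the direction is the sign
#' of the log hazard ratio.
#'
#' @param expr_gene Named numeric vector of one gene's expression (names =
#'   sample ids).
#' @param clinical Clinical table ([read_clinical()]).
#' @param method `"logrank_median"` or `"cox"`.
#' @param gene,cohort Labels stamped on the record.
#' @return A one-row association record with `endpoint = "OS"`; fewer than
#'   2 events gives a degenerate record.
#' @export
survival_association <- function(expr_gene, clinical,
                                 method = c("logrank_median", "cox"),
                                 gene = "gene", cohort = "cohort") {
  method <- match.arg(method)
  shared <- intersect(names(expr_gene), clinical$sample)
  x <- expr_gene[shared]
  cl <- clinical[match(shared, clinical$sample), , drop = FALSE]
  if (length(shared) < 4L || sum(cl$os_event) < 2L ||
      stats::sd(x) == 0) {
    return(assoc_record(gene, cohort, "OS", NA_real_, 1,
                        n = length(shared), degenerate = TRUE))
  }
  if (method == "cox") {
    fit <- cox_ph(cl$os_time, cl$os_event, x)
    return(assoc_record(gene, cohort, "OS", fit$estimate, fit$p_value,
                        direction = direction_of(log(fit$estimate)),
                        n = length(shared), degenerate = fit$degenerate))
  }
  grp <- tryCatch(median_split(x), error = function(e) NULL)
  if (is.null(grp)) {
    return(assoc_record(gene, cohort, "OS", NA_real_, 1,
                        n = length(shared), degenerate = TRUE))
  }
  hi <- grp == "high"
  fit <- logrank(cl$os_time[!hi], cl$os_event[!hi],
                 cl$os_time[hi], cl$os_event[hi])
  assoc_record(gene, cohort, "OS", fit$estimate, fit$p_value,
               direction = direction_of(fit$estimate),
               n = length(shared), degenerate = fit$degenerate)
}

#' Survival scan over a gene panel
#'
#' Applies [survival_association()] per gene and BH-adjusts across genes
#' within the cohort.
#'
#' @param expr Expression matrix.
#' @param clinical Clinical table.
#' @param genes Panel (default all genes).
#' @inheritParams survival_association
#' @param fdr_max FDR gate.
#' @return Association records.
#' @export
survival_scan <- function(expr, clinical, genes = NULL,
                          method = c("logrank_median", "cox"),
                          fdr_max = 0.05) {
  method <- match.arg(method)
  vals <- ex_values(expr)
  genes <- intersect(genes %||% rownames(vals), rownames(vals))
  records <- do.call(rbind, lapply(genes, function(g) {
    survival_association(vals[g, ], clinical, method = method, gene = g,
                         cohort = ex_cohort(expr))
  }))
  adjust_records(records, endpoint_thresholds(fdr = fdr_max))
}

#' Clinical-group association for one gene
#'
#' Unpaired t test for two groups, one-way ANOVA for more, after dropping
#' groups smaller than `min_group`. For two groups the direction is the
#' sign of the mean difference (second level minus first); ANOVA directions
#' are `"none"`.
#'
#' @param expr_gene Named expression vector.
#' @param labels Named categorical vector (names = sample ids), e.g. stage.
#' @param min_group Minimum group size (default 5).
#' @param endpoint Endpoint label (e.g. `"stage"`).
#' @param gene,cohort Labels stamped on the record.
#' @return A one-row record, or `NULL` when fewer than 2 eligible groups
#'   remain.
#' @export
clinical_group_association <- function(expr_gene, labels, min_group = 5,
                                       endpoint = "group", gene = "gene",
                                       cohort = "cohort") {
  shared <- intersect(names(expr_gene), names(labels))
  x <- expr_gene[shared]
  g <- as.character(labels[shared])
  keep_levels <- names(which(table(g) >= min_group))
  keep <- g %in% keep_levels
  x <- x[keep]
  g <- g[keep]
  if (length(unique(g)) < 2L) {
    message("gene ", gene, ": fewer than 2 groups with >= ", min_group,
            " samples; skipped")
    return(NULL)
  }
  groups <- split(x, g)
  if (length(groups) == 2L) {
    fit <- t_test(groups[[2L]], groups[[1L]], paired = FALSE)
    return(assoc_record(gene, cohort, endpoint, fit$estimate, fit$p_value,
                        direction = direction_of(fit$estimate),
                        n = length(x), degenerate = fit$degenerate))
  }
  fit <- anova_oneway(groups)
  assoc_record(gene, cohort, endpoint, fit$statistic, fit$p_value,
               direction = "none", n = length(x),
               degenerate = fit$degenerate)
}

#' Clinical-group scan over a gene panel
#'
#' @param expr Expression matrix.
#' @param clinical Clinical table containing `column`.
#' @param column Name of the categorical clinical column.
#' @param genes Panel (default all genes).
#' @inheritParams clinical_group_association
#' @param fdr_max FDR gate.
#' @return Association records (endpoint = `column`), BH-adjusted within
#'   the cohort.
#' @export
clinical_scan <- function(expr, clinical, column, genes = NULL,
                          min_group = 5, fdr_max = 0.05) {
  if (!column %in% colnames(clinical)) {
    stop("clinical table has no column '", column, "'")
  }
  vals <- ex_values(expr)
  genes <- intersect(genes %||% rownames(vals), rownames(vals))
  labels <- stats::setNames(as.character(clinical[[column]]),
                            clinical$sample)
  records <- do.call(rbind, lapply(genes, function(g) {
    clinical_group_association(vals[g, ], labels, min_group = min_group,
                               endpoint = column, gene = g,
                               cohort = ex_cohort(expr))
  }))
  if (is.null(records)) return(NULL)
  adjust_records(records, endpoint_thresholds(fdr = fdr_max))
}

#' Correlation with the proliferation marker
#'
#' Spearman correlation of every target gene with the proliferation marker
#' (default MKI67) across samples; significant when `|Rs| > rs_min` and
#' `FDR < fdr_max` (BH across targets). The marker itself is excluded from
#' the targets.
#'
#' @param expr Expression matrix.
#' @param target_genes Panel (default: all genes except the marker).
#' @param marker_gene Marker symbol (default `"MKI67"`).
#' @param rs_min,fdr_max Significance gates.
#' @param endpoint Endpoint label (default `"marker_corr"`).
#' @return Association records with `estimate` = Rs.
#' @export
marker_correlation <- function(expr, target_genes = NULL,
                               marker_gene = "MKI67", rs_min = 0.2,
                               fdr_max = 0.05, endpoint = "marker_corr") {
  vals <- ex_values(expr)
  if (!marker_gene %in% rownames(vals)) {
    stop("marker gene '", marker_gene, "' absent from the matrix")
  }
  targets <- setdiff(target_genes %||% rownames(vals), marker_gene)
  missing <- setdiff(targets, rownames(vals))
  if (length(missing)) {
    message("skipping ", length(missing), " absent target gene(s)")
    targets <- setdiff(targets, missing)
  }
  marker <- vals[marker_gene, ]
  records <- do.call(rbind, lapply(targets, function(g) {
    fit <- spearman(vals[g, ], marker)
    assoc_record(g, ex_cohort(expr), endpoint, fit$estimate, fit$p_value,
                 direction = direction_of(fit$estimate), n = fit$n,
                 degenerate = fit$degenerate)
  }))
  adjust_records(records,
                 endpoint_thresholds(rs_marker = rs_min, fdr = fdr_max))
}

#' Per-cell-line background proliferation score
#'
#' The background score of a cell line is the mean proliferation score over
#' all genes assayed in that line.
#'
#' @param screen Genes x cell lines numeric score matrix (higher = more
#'   proliferation after knockout).
#' @return Named numeric vector of per-line backgrounds.
#' @export
dependency_background <- function(screen) {
  if (!is.matrix(screen) || !is.numeric(screen)) {
    stop("`screen` must be a numeric genes x cell-lines matrix")
  }
  if (ncol(screen) < 1L) stop("screen has no cell lines")
  if (nrow(screen) < 2L) stop("need >= 2 genes per line for a background")
  colMeans(screen)
}

#' Dependency difference from the per-line background
#'
#' For each gene, `difference = mean over lines of (background_line -
#' score_gene,line)`; a positive difference means knockout lowers
#' proliferation below the line's background (the gene is
#' proliferation-promoting / essential). The p value is a paired t test of
#' the gene's scores against the per-line backgrounds, BH-adjusted across
#' genes; significance uses the one-sided difference gate
#' `difference > diff_min` with `FDR < fdr_max`.
#'
#' @param screen Genes x cell lines score matrix.
#' @param genes Genes to test (default all rows).
#' @param diff_min,fdr_max Significance gates.
#' @param cohort Label stamped on the records.
#' @return Association records with `endpoint = "dependency"`.
#' @export
dependency_difference <- function(screen, genes = NULL, diff_min = 0.5,
                                  fdr_max = 0.05, cohort = "screen") {
  bg <- dependency_background(screen)
  genes <- genes %||% rownames(screen)
  missing <- setdiff(genes, rownames(screen))
  if (length(missing)) {
    stop("gene(s) absent from the screen: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  records <- do.call(rbind, lapply(genes, function(g) {
    s <- screen[g, ]
    ok <- is.finite(s)
    if (sum(ok) < 2L) {
      return(assoc_record(g, cohort, "dependency", NA_real_, 1,
                          n = sum(ok), degenerate = TRUE))
    }
    d <- bg[ok] - s[ok]
    fit <- t_test(bg[ok], s[ok], paired = TRUE)
    assoc_record(g, cohort, "dependency", mean(d), fit$p_value,
                 direction = direction_of(mean(d)), n = sum(ok),
                 degenerate = fit$degenerate && mean(d) == 0)
  }))
  adjust_records(records, endpoint_thresholds(diff = diff_min,
                                              fdr = fdr_max))
}

#' mRNA-protein concordance across shared samples
#'
#' Per-gene Spearman correlation between an mRNA and a protein expression
#' matrix over their shared samples; significant when `Rs > rs_min` (signed)
#' and `FDR < fdr_max`. Also reports the percent of tested genes that are
#' significantly concordant, to one decimal place.
#'
#' @param mrna,protein Expression matrices sharing samples and genes.
#' @param rs_min,fdr_max Significance gates.
#' @return List: `records`, `n_significant`, `n_tested`, `percent`.
#' @export
paired_feature_correlation <- function(mrna, protein, rs_min = 0.3,
                                       fdr_max = 0.05) {
  mv <- ex_values(mrna)
  pv <- ex_values(protein)
  shared <- intersect(colnames(mv), colnames(pv))
  if (!length(shared)) stop("no shared samples between mRNA and protein")
  if (length(shared) < 3L) stop("need >= 3 shared samples")
  genes <- intersect(rownames(mv), rownames(pv))
  if (!length(genes)) stop("no shared genes between mRNA and protein")
  records <- do.call(rbind, lapply(genes, function(g) {
    fit <- spearman(mv[g, shared], pv[g, shared])
    assoc_record(g, ex_cohort(mrna), "mrna_protein", fit$estimate,
                 fit$p_value, direction = direction_of(fit$estimate),
                 n = length(shared), degenerate = fit$degenerate)
  }))
  records <- adjust_records(
    records, endpoint_thresholds(rs_mrna_protein = rs_min, fdr = fdr_max))
  n_sig <- sum(records$significant)
  list(records = records, n_significant = n_sig, n_tested = nrow(records),
       percent = round(100 * n_sig / nrow(records), 1L))
}
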