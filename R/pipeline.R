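# End-to-end orchestration from a config: catalog -> networks -> DE and
# clinical associations -> marker/dependency -> scores/enrichment -> dual
# function and hallmark candidates, with per-stage seeds fanned out from a
# single master seed and a run report.

#' Build a pipeline configuration
#'
#' Collects the input paths, thresholds and seeds for [run_pipeline()].
#' Thresholds default to the pipeline's standard gates (co-expression
#' Rs > 0.3, marker |Rs| > 0.2, score |Rs| > 0.3, |FC| > 1.5, FDR < 0.05,
#' dependency difference > 0.5, >= 10 samples for networks, >= 5 pairs for
#' DE, >= 5 per clinical group). Per-stage seeds are derived from the
#' master seed by fixed offsets (+1 resampling, +2 GSEA), so stages are
#' individually rerunnable with identical randomness.
#'
#' @param expression_tumor,expression_normal Paths to expression TSVs.
#' @param clinical Optional path to a clinical TSV.
#' @param dependency Optional path to a dependency-score TSV.
#' @param emt_gmt Path to a GMT whose first two sets are the epithelial and
#'   mesenchymal signatures.
#' @param hallmark_gmt Optional path to a GMT of hallmark sets.
#' @param catalog Path to a catalog TSV or `"default"`.
#' @param ppi Optional path to a PPI TSV.
#' @param cohort Cohort label.
#' @param out_dir Output directory.
#' @param thresholds Named list overriding any of `rs_coexpr`, `rs_marker`,
#'   `rs_score`, `fc`, `fdr`, `diff`, `min_samples`, `min_pairs`,
#'   `min_group`.
#' @param marker_gene Proliferation marker symbol.
#' @param n_resample Resampling-null iterations.
#' @param n_perm GSEA permutations.
#' @param gsea_genes Phenotype genes for the (expensive) GSEA stage; NULL
#'   skips it and the EMT axis uses score correlation only.
#' @param min_hallmarks Gate for the candidate filter.
#' @param stratify_by Optional clinical column; association stages are
#'   rerun per stratum.
#' @param seed Master seed.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(expression_tumor, expression_normal,
                            clinical = NULL, dependency = NULL,
                            emt_gmt, hallmark_gmt = NULL,
                            catalog = "default", ppi = NULL,
                            cohort = "cohort", out_dir = tempfile("hspdual_"),
                            thresholds = list(), marker_gene = "MKI67",
                            n_resample = 1000, n_perm = 1000,
                            gsea_genes = NULL, min_hallmarks = 5,
                            stratify_by = NULL, seed = 1L) {
  thr <- list(rs_coexpr = 0.3, rs_marker = 0.2, rs_score = 0.3, fc = 1.5,
              fdr = 0.05, diff = 0.5, min_samples = 10, min_pairs = 5,
              min_group = 5)
  unknown <- setdiff(names(thresholds), names(thr))
  if (length(unknown)) {
    stop("unknown threshold(s): ", paste(unknown, collapse = ", "))
  }
  thr[names(thresholds)] <- thresholds
  if (any(vapply(thr, function(v) !is.numeric(v) || v <= 0, logical(1L)))) {
    stop("all thresholds must be positive numbers")
  }
  cfg <- list(
    expression_tumor = expression_tumor,
    expression_normal = expression_normal,
    clinical = clinical, dependency = dependency, emt_gmt = emt_gmt,
    hallmark_gmt = hallmark_gmt, catalog = catalog, ppi = ppi,
    cohort = cohort, out_dir = out_dir, thresholds = thr,
    marker_gene = marker_gene, n_resample = n_resample, n_perm = n_perm,
    gsea_genes = gsea_genes, min_hallmarks = min_hallmarks,
    stratify_by = stratify_by, seed = as.integer(seed)
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from JSON
#'
#' Keys mirror the arguments of [pipeline_config()]; relative paths are
#' resolved against the JSON file's directory.
#'
#' @param path Path to a JSON config.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p) || identical(p, "default")) return(p)
    if (file.exists(p)) p else file.path(base, p)
  }
  for (key in c("expression_tumor", "expression_normal", "clinical",
                "dependency", "emt_gmt", "hallmark_gmt", "catalog", "ppi")) {
    if (!is.null(raw[[key]])) raw[[key]] <- resolve(raw[[key]])
  }
  if (!is.null(raw$thresholds)) raw$thresholds <- as.list(raw$thresholds)
  do.call(pipeline_config, raw)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  plain <- unclass(config)
  plain$out_dir <- NULL
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

require_path <- function(path, what, stage) {
  if (is.null(path)) return(NULL)
  if (!identical(path, "default") && !file.exists(path)) {
    stop("[", stage, "] missing ", what, ": ", path)
  }
  path
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order on the configured inputs and
#' writes every result table as TSV into `out_dir`: per-condition networks
#' and their comparison, the resampling null, the long association table
#' (DE, survival, clinical groups, marker and score correlations,
#' dependency differences), per-sample scores, optional GSEA enrichments,
#' dual-function calls with consistency tally, and multi-hallmark
#' candidates. A `stratify_by` clinical column additionally reruns the
#' marker/EMT association stages per stratum (endpoints suffixed
#' `@stratum`). Any format error aborts with the stage name and file.
#'
#' @param config A `pipeline_config`.
#' @return A `run_report`: per-stage row counts, skipped stages with
#'   reasons, seeds, wall-clock seconds and the config hash. The report is
#'   also written to `report.json` in `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  thr <- config$thresholds
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stages <- list()
  skipped <- list()
  note <- function(stage, rows) stages[[stage]] <<- rows
  skip <- function(stage, why) skipped[[stage]] <<- why

  # catalog + expression
  require_path(config$catalog, "catalog", "catalog")
  catalog <- load_catalog(config$catalog)
  require_path(config$expression_tumor, "tumor expression", "input")
  require_path(config$expression_normal, "normal expression", "input")
  tumor <- read_expression(config$expression_tumor, condition = "tumor",
                           cohort = config$cohort)
  normal <- read_expression(config$expression_normal, condition = "normal",
                            cohort = config$cohort)
  family_genes <- intersect(catalog$gene, rownames(ex_values(tumor)))
  note("catalog", nrow(catalog))

  # co-expression networks + comparison + resampling null
  net_t <- build_network(tumor, family_genes, rs_min = thr$rs_coexpr,
                         fdr_max = thr$fdr, min_samples = thr$min_samples)
  net_n <- build_network(normal, family_genes, rs_min = thr$rs_coexpr,
                         fdr_max = thr$fdr, min_samples = thr$min_samples)
  if (!is.null(net_t) && !is.null(net_n)) {
    write_tsv(net_t$edges, file.path(out_dir, "network_tumor.tsv"))
    write_tsv(net_n$edges, file.path(out_dir, "network_normal.tsv"))
    cmp <- compare_networks(net_t, net_n)
    write_tsv(cmp$classes, file.path(out_dir, "network_comparison.tsv"))
    note("coexpr", nrow(net_t$edges) + nrow(net_n$edges))
    null <- resampling_null(tumor, normal, genes = family_genes,
                            n_iter = config$n_resample,
                            seed = config$seed + 1L,
                            rs_min = thr$rs_coexpr, fdr_max = thr$fdr,
                            min_samples = thr$min_samples)
    nd <- cbind(iteration = seq_len(null$n_iter), null$counts)
    write_tsv(nd, file.path(out_dir, "resampling_null.tsv"))
    note("resampling", null$n_iter)
    disruption <- list(fold_decrease = cmp$fold_decrease,
                       empirical_p = null$empirical_p)
  } else {
    skip("coexpr", "a condition has fewer samples than min_samples")
    disruption <- NULL
  }

  if (!is.null(config$ppi) && !is.null(net_n)) {
    require_path(config$ppi, "PPI table", "ppi")
    ppi <- read_ppi(config$ppi)
    ov <- tryCatch(ppi_overlap(net_n, ppi), error = function(e) NULL)
    if (!is.null(ov)) {
      disruption$ppi_percent <- ov$percent
      note("ppi_overlap", ov$total)
    } else skip("ppi_overlap", "normal network has no edges")
  }

  records <- list()

  # differential expression + family tallies
  de <- differential_expression(tumor, normal, paired = TRUE,
                                fc_min = thr$fc, fdr_max = thr$fdr,
                                min_pairs = thr$min_pairs)
  if (!is.null(de)) {
    de_fam <- de[de$gene %in% family_genes, , drop = FALSE]
    records$de <- de_fam
    fam <- family_summary(de_fam, catalog)
    write_tsv(fam, file.path(out_dir, "family_summary.tsv"))
    note("de", nrow(de_fam))
  } else skip("de", "fewer pairs than min_pairs")

  # clinical endpoints
  clin <- NULL
  if (!is.null(config$clinical)) {
    require_path(config$clinical, "clinical table", "clinical")
    clin <- read_clinical(config$clinical)
    os <- survival_scan(tumor, clin, genes = family_genes,
                        method = "logrank_median", fdr_max = thr$fdr)
    os_cox <- survival_scan(tumor, clin, genes = family_genes,
                            method = "cox", fdr_max = thr$fdr)
    os_cox$endpoint <- "OS_cox"
    records$os <- os
    records$os_cox <- os_cox
    note("survival", nrow(os) + nrow(os_cox))
    for (column in intersect(c("stage", "grade", "subtype"),
                             colnames(clin))) {
      cg <- clinical_scan(tumor, clin, column, genes = family_genes,
                          min_group = thr$min_group, fdr_max = thr$fdr)
      if (!is.null(cg)) {
        records[[paste0("clin_", column)]] <- cg
        note(paste0("clinical_", column), nrow(cg))
      } else skip(paste0("clinical_", column), "fewer than 2 groups")
    }
  } else skip("clinical", "no clinical table configured")

  # proliferation axis
  prolif <- NULL
  if (config$marker_gene %in% rownames(ex_values(tumor))) {
    prolif <- marker_correlation(tumor, target_genes = family_genes,
                                 marker_gene = config$marker_gene,
                                 rs_min = thr$rs_marker, fdr_max = thr$fdr)
    records$marker <- prolif
    note("marker_corr", nrow(prolif))
  } else skip("marker_corr", paste0("marker ", config$marker_gene,
                                    " absent"))

  # dependency screen
  if (!is.null(config$dependency)) {
    require_path(config$dependency, "dependency table", "dependency")
    dep_df <- utils::read.delim(config$dependency, check.names = FALSE)
    screen <- as.matrix(dep_df[, -1L, drop = FALSE])
    rownames(screen) <- dep_df[[1L]]
    dep <- dependency_difference(screen,
                                 genes = intersect(family_genes,
                                                   rownames(screen)),
                                 diff_min = thr$diff, fdr_max = thr$fdr,
                                 cohort = config$cohort)
    records$dependency <- dep
    note("dependency", nrow(dep))
  } else skip("dependency", "no dependency table configured")

  # EMT axis: score + correlations (+ optional GSEA)
  require_path(config$emt_gmt, "EMT signature GMT", "emt")
  emt_sets <- read_gmt(config$emt_gmt)
  if (length(emt_sets) < 2L) stop("[emt] GMT needs >= 2 sets: ",
                                  config$emt_gmt)
  sig <- emt_signature(emt_sets[[1L]], emt_sets[[2L]])
  scores <- emt_score(tumor, sig)
  score_tab <- data.frame(sample = names(scores), score_name = "EMT",
                          value = unname(scores), stringsAsFactors = FALSE)
  emt_rec <- score_correlation_scan(tumor, scores, genes = family_genes,
                                    rs_min = thr$rs_score,
                                    fdr_max = thr$fdr,
                                    endpoint = "score_corr_EMT")
  records$emt <- emt_rec
  note("emt_score", nrow(emt_rec))

  if (!is.null(config$gsea_genes)) {
    enr <- gsea_scan(tumor, intersect(config$gsea_genes, family_genes),
                     gene_set = sig$mesenchymal, set_name = "MESENCHYMAL",
                     n_perm = config$n_perm, seed = config$seed + 2L,
                     fdr_max = thr$fdr)
    write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
    note("gsea", nrow(enr))
  } else skip("gsea", "no phenotype genes configured")

  # hallmark scores
  hallmark_records <- list(proliferation = prolif, EMT = emt_rec)
  if (!is.null(config$hallmark_gmt)) {
    require_path(config$hallmark_gmt, "hallmark GMT", "hallmarks")
    hsets <- read_gmt(config$hallmark_gmt)
    for (nm in names(hsets)) {
      hs <- tryCatch(signature_score(tumor, hsets[[nm]], score_name = nm),
                     error = function(e) NULL)
      if (is.null(hs)) next
      score_tab <- rbind(score_tab,
                         data.frame(sample = names(hs), score_name = nm,
                                    value = unname(hs),
                                    stringsAsFactors = FALSE))
      hr <- score_correlation_scan(tumor, hs, genes = family_genes,
                                   rs_min = thr$rs_score,
                                   fdr_max = thr$fdr,
                                   endpoint = paste0("score_corr_", nm))
      hallmark_records[[nm]] <- hr
      records[[paste0("hallmark_", nm)]] <- hr
    }
    note("hallmarks", length(hsets))
  } else skip("hallmarks", "no hallmark GMT configured")
  write_tsv(score_tab, file.path(out_dir, "scores.tsv"))

  # dual-function classification
  dual <- NULL
  if (!is.null(prolif) && !is.null(emt_rec)) {
    dual <- classify_dual(prolif, emt_rec)
    write_tsv(dual, file.path(out_dir, "dual_calls.tsv"))
    tally <- tally_consistency(dual)
    note("dual", sum(dual$quadrant != "none"))
    dirmat <- build_direction_matrix(
      Filter(Negate(is.null), hallmark_records))
    write_tsv(as.data.frame(dirmat),
              file.path(out_dir, "direction_matrix.tsv"))
    candidates <- consistent_direction_filter(
      dirmat, min_hallmarks = config$min_hallmarks)
    write_tsv(candidates, file.path(out_dir, "candidates.tsv"))
    note("candidates", nrow(candidates))
  } else {
    skip("dual", "needs both the marker and EMT association stages")
    tally <- NULL
  }

  # stratified reruns of the association stages
  if (!is.null(config$stratify_by) && !is.null(clin) &&
      config$stratify_by %in% colnames(clin)) {
    strata <- split(clin$sample, clin[[config$stratify_by]])
    for (s in names(strata)) {
      ids <- intersect(strata[[s]], colnames(ex_values(tumor)))
      if (length(ids) < thr$min_samples) {
        skip(paste0("stratum_", s), "fewer samples than min_samples")
        next
      }
      sub <- expression_matrix(ex_values(tumor)[, ids, drop = FALSE],
                               condition = "tumor",
                               cohort = config$cohort)
      mk <- marker_correlation(sub, target_genes = family_genes,
                               marker_gene = config$marker_gene,
                               rs_min = thr$rs_marker, fdr_max = thr$fdr,
                               endpoint = paste0("marker_corr@", s))
      sc <- score_correlation_scan(sub, emt_score(sub, sig),
                                   genes = family_genes,
                                   rs_min = thr$rs_score,
                                   fdr_max = thr$fdr,
                                   endpoint = paste0("score_corr_EMT@", s))
      records[[paste0("stratum_", s)]] <- rbind(mk, sc)
      note(paste0("stratum_", s), nrow(mk) + nrow(sc))
    }
  }

  # the single long-format association table
  long <- do.call(rbind, lapply(Filter(Negate(is.null), records),
                                function(df) {
    df[, c("gene", "cohort", "endpoint", "estimate", "p", "fdr",
           "direction", "significant")]
  }))
  rownames(long) <- NULL
  write_tsv(long, file.path(out_dir, "associations.tsv"))

  report <- structure(list(
    cohort = config$cohort,
    stages = stages,
    skipped = skipped,
    disruption = disruption,
    tally = if (!is.null(tally)) {
      list(n_opposite = tally$n_opposite, n_consistent = tally$n_consistent)
    } else NULL,
    seed = config$seed,
    seeds = list(resampling = config$seed + 1L, gsea = config$seed + 2L),
    config_hash = config_hash(config),
    elapsed_s = round(proc.time()[["elapsed"]] - t0, 2L),
    out_dir = out_dir
  ), class = "run_report")
  writeLines(jsonlite::toJSON(unclass(report), auto_unbox = TRUE,
                              pretty = TRUE, digits = NA),
             file.path(out_dir, "report.json"))
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> cohort=%s seed=%d hash=%s (%.1fs)\n",
              x$cohort, x$seed, x$config_hash, x$elapsed_s))
  for (s in names(x$stages)) {
    cat(sprintf("  %-18s %d rows\n", s, x$stages[[s]]))
  }
  for (s in names(x$skipped)) {
    cat(sprintf("  %-18s skipped: %s\n", s, x$skipped[[s]]))
  }
  invisible(x)
}

#' Simulate a cohort and write its fixture bundle
#'
#' Thin wrapper over [emit_fixture_bundle()] with an optional seed
#' override.
#'
#' @param spec A [cohort_spec()] (default [default_cohort_spec()]).
#' @param out_dir Output directory.
#' @param seed Optional seed overriding `spec$seed`.
#' @return The bundle manifest, invisibly.
#' @export
simulate_cohort <- function(spec = default_cohort_spec(), out_dir,
                            seed = NULL) {
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  emit_fixture_bundle(spec, out_dir)
}
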