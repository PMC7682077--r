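# Recovery metrics against the planted truth of a synthetic cohort; used by
# the property tests and the acceptance run.

#' Co-expression recovery against planted block edges
#'
#' Sensitivity = fraction of planted within-block pairs (restricted to the
#' network's gene panel) recovered as edges; the false-edge rate = fraction
#' of reported edges that are not planted. Meaningful when the panel
#' contains no genes with latent-factor loadings, so that every non-block
#' pair is population-null.
#'
#' @param net A `coexpr_network`.
#' @param truth Planted truth from [generate_cohort()].
#' @return List: `sensitivity`, `false_edge_rate`, `n_planted`, `n_edges`.
#' @export
coexpr_recovery <- function(net, truth) {
  stopifnot(inherits(net, "coexpr_network"))
  edges <- truth$edges
  planted <- edges[edges$gene_a %in% net$genes &
                     edges$gene_b %in% net$genes, , drop = FALSE]
  planted_keys <- pair_keys(planted$gene_a, planted$gene_b)
  edge_keys <- pair_keys(net$edges$gene_a, net$edges$gene_b)
  sens <- if (length(planted_keys)) {
    mean(planted_keys %in% edge_keys)
  } else NA_real_
  fer <- if (length(edge_keys)) {
    mean(!(edge_keys %in% planted_keys))
  } else 0
  list(sensitivity = sens, false_edge_rate = fer,
       n_planted = length(planted_keys), n_edges = length(edge_keys))
}

#' Differential-expression direction recovery
#'
#' Fraction of planted DE genes called significant with the planted
#' direction.
#'
#' @param records DE association records.
#' @param truth Planted truth from [generate_cohort()].
#' @return List: `recovery`, `n_planted`, plus the null false-positive rate
#'   among unplanted genes.
#' @export
de_recovery <- function(records, truth) {
  de <- truth$de
  idx <- match(de$gene, records$gene)
  hit <- !is.na(idx) & records$significant[idx] %in% TRUE &
    records$direction[idx] == de$direction
  nulls <- setdiff(records$gene, de$gene)
  fp <- records$significant[match(nulls, records$gene)] %in% TRUE
  list(recovery = mean(hit), n_planted = nrow(de),
       null_fp_rate = if (length(nulls)) mean(fp) else NA_real_)
}

#' Quadrant-call recovery for planted dual-function genes
#'
#' Recall = fraction of planted dual-function genes whose call matches the
#' planted quadrant; precision = fraction of called planted genes whose
#' quadrant is right; the null call rate = fraction of unloaded family
#' genes receiving any quadrant.
#'
#' @param calls Calls from [classify_dual()].
#' @param truth Planted truth from [generate_cohort()].
#' @param null_genes Optional unloaded genes for the null call rate.
#' @return List: `recall`, `precision`, `n_planted`, `null_call_rate`.
#' @export
quadrant_recovery <- function(calls, truth, null_genes = NULL) {
  q <- truth$quadrants
  q <- q[q$quadrant != "none", , drop = FALSE]
  idx <- match(q$gene, calls$gene)
  got <- ifelse(is.na(idx), "none", calls$quadrant[idx])
  recall <- mean(got == q$quadrant)
  called <- got != "none"
  precision <- if (any(called)) {
    mean(got[called] == q$quadrant[called])
  } else NA_real_
  null_rate <- if (!is.null(null_genes)) {
    ni <- match(intersect(null_genes, calls$gene), calls$gene)
    if (length(ni)) mean(calls$quadrant[ni] != "none") else NA_real_
  } else NA_real_
  list(recall = recall, precision = precision, n_planted = nrow(q),
       null_call_rate = null_rate)
}
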