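# Readers/writers for every external format the pipeline touches (tab
# separated, UTF-8, '.' decimal) plus the gene-family catalog. Gene symbols
# are matched exactly and case-sensitively; no alias resolution is attempted.

#' Construct an expression matrix for one cohort and condition
#'
#' Wraps a genes x samples numeric matrix together with its condition tag
#' (`"tumor"` or `"normal"`) and cohort label. Values are platform units
#' (RSEM/TPM/FPKM/...); they are cohort-local and must never be compared
#' across datasets.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample identifiers). All values must be
#'   finite and non-negative; duplicate gene or sample names are rejected.
#'   Missing cells are not permitted.
#' @param condition `"tumor"` or `"normal"`.
#' @param cohort Cohort label, e.g. a cancer-type code.
#' @return An `expr_matrix` object.
#' @export
expression_matrix <- function(values, condition = c("tumor", "normal"),
                              cohort = "cohort") {
  condition <- match.arg(condition)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` needs gene rownames and sample colnames")
  }
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("expression matrix must have at least one gene and one sample")
  }
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g)) {
    stop("duplicate gene row(s): ", paste(dup_g, collapse = ", "))
  }
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s)) {
    stop("duplicate sample column(s): ", paste(dup_s, collapse = ", "))
  }
  if (any(!is.finite(values))) stop("expression values must be finite")
  if (any(values < 0)) stop("expression values must be non-negative")
  structure(list(values = values, condition = condition, cohort = cohort),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples | cohort=%s condition=%s\n",
              nrow(x$values), ncol(x$values), x$cohort, x$condition))
  invisible(x)
}

# Accept either an expr_matrix or a bare named matrix.
ex_values <- function(x) {
  if (inherits(x, "expr_matrix")) x$values
  else if (is.matrix(x) && is.numeric(x)) x
  else stop("expected an `expr_matrix` or a numeric matrix")
}

ex_condition <- function(x) if (inherits(x, "expr_matrix")) x$condition else NA_character_
ex_cohort <- function(x) if (inherits(x, "expr_matrix")) x$cohort else "cohort"

#' Read an expression TSV
#'
#' Expects a header row of sample identifiers with gene symbols in the first
#' column. Duplicate genes, non-numeric or missing cells, and negative values
#' are format errors naming the offending row/column (upstream imputation is
#' out of scope).
#'
#' @param path Path to a tab-separated file.
#' @inheritParams expression_matrix
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, condition = c("tumor", "normal"),
                            cohort = "cohort") {
  condition <- match.arg(condition)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", quote = "")
  if (ncol(raw) < 2L) {
    stop("malformed header in ", path,
         ": need a gene column plus at least one sample column")
  }
  genes <- raw[[1L]]
  samples <- colnames(raw)[-1L]
  dup <- unique(genes[duplicated(genes)])
  if (length(dup)) {
    stop("duplicate gene row(s) in ", path, ": ", paste(dup, collapse = ", "))
  }
  vals <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw)))
  )
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(genes, samples))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)
    stop("non-numeric or missing value in ", path, " at gene '",
         genes[bad[1L, 1L]], "', sample '", samples[bad[1L, 2L]], "'")
  }
  expression_matrix(vals, condition = condition, cohort = cohort)
}

#' Write an expression matrix to TSV
#'
#' @param x An [expression_matrix()] (or bare named matrix).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  vals <- ex_values(x)
  df <- data.frame(gene = rownames(vals), vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard MSigDB-style GMT: one set per line, tab-separated
#' `name<TAB>description<TAB>member...`. Duplicate members within a line are
#' deduplicated with a warning; a line with fewer than three fields or no
#' non-empty members is a format error.
#'
#' @param path Path to a GMT file.
#' @return Named list of unique member character vectors, with the line
#'   descriptions kept in the `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descriptions <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    members <- if (length(fields) >= 3L) fields[-(1:2)][nzchar(fields[-(1:2)])] else character()
    if (length(fields) < 3L || !length(members)) {
      stop("GMT format error in ", path, " line ", i,
           ": need name, description and at least one member")
    }
    if (anyDuplicated(members)) {
      warning("GMT set '", fields[1L], "' has duplicate members; deduplicated")
      members <- unique(members)
    }
    if (fields[1L] %in% names(sets)) {
      stop("GMT format error in ", path, ": duplicate set name '", fields[1L], "'")
    }
    sets[[fields[1L]]] <- members
    descriptions[[fields[1L]]] <- fields[2L]
  }
  attr(sets, "descriptions") <- descriptions
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors (as from [read_gmt()]).
#' @param path Output path.
#' @param descriptions Optional named character vector of per-set
#'   descriptions; defaults to the set names.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("`sets` must be a named list")
  }
  descriptions <- descriptions %||% attr(sets, "descriptions") %||%
    stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]] %||% nm, sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Load a gene-family catalog
#'
#' TSV with columns `gene`, `family`, `subfamily` (subfamily may be empty).
#' `path = "default"` loads the packaged HSP reference catalog: 82 chaperone
#' genes in 9 families/sub-families (HSP10, HSP20, HSP40 split into
#' DNAJA/DNAJB/DNAJC, HSP60, HSP70, HSP90, large HSPs). The packaged list is
#' a reference set and is editable: all analyses take the catalog as input.
#'
#' @param path Path to a catalog TSV, or `"default"`.
#' @return A data frame of class `hsp_catalog` with columns `gene`, `family`,
#'   `subfamily`.
#' @export
load_catalog <- function(path = "default") {
  if (identical(path, "default")) {
    path <- system.file("extdata", "hsp_catalog.tsv", package = "hspdual",
                        mustWork = TRUE)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          colClasses = "character", fill = TRUE)
  need <- c("gene", "family")
  if (!all(need %in% colnames(df))) {
    stop("catalog ", path, " must have columns gene, family[, subfamily]")
  }
  if (!"subfamily" %in% colnames(df)) df$subfamily <- ""
  df$subfamily[is.na(df$subfamily)] <- ""
  df <- df[, c("gene", "family", "subfamily")]
  dup <- unique(df$gene[duplicated(df$gene)])
  if (length(dup)) {
    stop("catalog format error: gene(s) assigned more than once: ",
         paste(dup, collapse = ", "))
  }
  if (any(!nzchar(df$gene)) || any(!nzchar(df$family))) {
    stop("catalog format error: empty gene or family field")
  }
  sub <- df[nzchar(df$subfamily), , drop = FALSE]
  if (nrow(sub)) {
    fam_per_sub <- tapply(sub$family, sub$subfamily,
                          function(f) length(unique(f)))
    if (any(fam_per_sub > 1L)) {
      stop("catalog format error: subfamily assigned to multiple families: ",
           paste(names(fam_per_sub)[fam_per_sub > 1L], collapse = ", "))
    }
  }
  class(df) <- c("hsp_catalog", "data.frame")
  df
}

#' Tally catalog family sizes
#'
#' @param catalog An `hsp_catalog` from [load_catalog()].
#' @param by `"family"` or `"subfamily"` (subfamily tallies only genes with a
#'   subfamily label).
#' @return Named integer vector of counts, with the total gene count in the
#'   `"total"` attribute.
#' @export
family_sizes <- function(catalog, by = c("family", "subfamily")) {
  by <- match.arg(by)
  x <- catalog[[by]]
  x <- x[nzchar(x)]
  out <- vapply(split(x, x), length, integer(1L))
  attr(out, "total") <- nrow(catalog)
  out
}

#' Write a gene-family catalog
#'
#' @param catalog An `hsp_catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  utils::write.table(as.data.frame(catalog), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' TSV with one row per sample: columns `sample`, `os_time` (days, >= 0),
#' `os_event` (0/1), plus optional categorical columns (stage, grade,
#' subtype, ...).
#'
#' @param path Path to a clinical TSV.
#' @return A data frame with validated columns.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  need <- c("sample", "os_time", "os_event")
  if (!all(need %in% colnames(df))) {
    stop("clinical table ", path, " must have columns ",
         paste(need, collapse = ", "))
  }
  validate_clinical(df, where = path)
}

validate_clinical <- function(df, where = "clinical table") {
  dup <- unique(df$sample[duplicated(df$sample)])
  if (length(dup)) {
    stop(where, ": duplicate sample row(s): ", paste(dup, collapse = ", "))
  }
  if (!is.numeric(df$os_time) || any(!is.finite(df$os_time)) ||
      any(df$os_time < 0)) {
    stop(where, ": os_time must be finite and non-negative")
  }
  if (!all(df$os_event %in% c(0, 1))) {
    stop(where, ": os_event must be 0/1")
  }
  df$os_event <- as.integer(df$os_event)
  df
}

#' Write a clinical table
#'
#' @param clinical Data frame as returned by [read_clinical()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Canonical (lexicographic) order for unordered gene pairs; the shared key
# format used by networks, PPI overlap and truth tables.
canonical_pairs <- function(gene_a, gene_b) {
  a <- pmin(gene_a, gene_b)
  b <- pmax(gene_a, gene_b)
  data.frame(gene_a = a, gene_b = b, stringsAsFactors = FALSE)
}

pair_keys <- function(gene_a, gene_b) {
  cp <- canonical_pairs(gene_a, gene_b)
  paste(cp$gene_a, cp$gene_b, sep = "\r")
}

#' Read a protein-protein interaction edge list
#'
#' TSV with columns `gene_a`, `gene_b` (unordered pairs). Pairs are stored
#' canonically (lexicographic order) and deduplicated; self-pairs are a
#' format error.
#'
#' @param path Path to a PPI TSV.
#' @return Data frame with canonical columns `gene_a`, `gene_b`.
#' @export
read_ppi <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          colClasses = "character")
  if (!all(c("gene_a", "gene_b") %in% colnames(df))) {
    stop("PPI table ", path, " must have columns gene_a, gene_b")
  }
  if (any(df$gene_a == df$gene_b)) {
    stop("PPI format error in ", path, ": self-pair(s) present")
  }
  cp <- canonical_pairs(df$gene_a, df$gene_b)
  cp <- cp[!duplicated(pair_keys(cp$gene_a, cp$gene_b)), , drop = FALSE]
  rownames(cp) <- NULL
  cp
}

#' Write a PPI edge list
#'
#' @param ppi Data frame with columns `gene_a`, `gene_b`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ppi <- function(ppi, path) {
  utils::write.table(ppi[, c("gene_a", "gene_b")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
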