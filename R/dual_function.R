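# Combine per-hallmark association tables into quadrant calls, consistency
# tallies, the gene x hallmark x cohort direction matrix, and the
# multi-hallmark candidate ranking.

#' Quadrant classification over two hallmark axes
#'
#' Joins two association tables (e.g. proliferation = marker correlation,
#' EMT = score correlation) on (gene, cohort). Instances significant on
#' both axes get a quadrant from the two direction signs — `P+M+` promotes
#' both, `P+M-` promotes the first axis while suppressing the second, and
#' so on; everything else is `"none"`. Conflicting duplicate records are an
#' error.
#'
#' @param prolif,emt Association records for the two axes (`gene`,
#'   `cohort`, `direction`, `significant`).
#' @param axis_names Length-2 labels stored on the calls.
#' @return Data frame: gene, cohort, axis1, dir1, axis2, dir2, quadrant.
#' @export
classify_dual <- function(prolif, emt,
                          axis_names = c("proliferation", "EMT")) {
  check_dup <- function(df, label) {
    key <- paste(df$gene, df$cohort, sep = "\r")
    if (anyDuplicated(key)) {
      stop("conflicting duplicate records on (gene, cohort) in ", label)
    }
    key
  }
  kp <- check_dup(prolif, axis_names[1L])
  ke <- check_dup(emt, axis_names[2L])
  keys <- union(kp, ke)
  ip <- match(keys, kp)
  ie <- match(keys, ke)
  sig1 <- !is.na(ip) & prolif$significant[ip] %in% TRUE
  sig2 <- !is.na(ie) & emt$significant[ie] %in% TRUE
  dir1 <- ifelse(is.na(ip), "none", prolif$direction[ip])
  dir2 <- ifelse(is.na(ie), "none", emt$direction[ie])
  both <- sig1 & sig2 & dir1 %in% c("+", "-") & dir2 %in% c("+", "-")
  quadrant <- rep("none", length(keys))
  quadrant[both] <- paste0("P", dir1[both], "M", dir2[both])
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  out <- data.frame(gene = parts[, 1L], cohort = parts[, 2L],
                    axis1 = axis_names[1L], dir1 = dir1,
                    axis2 = axis_names[2L], dir2 = dir2,
                    quadrant = quadrant, stringsAsFactors = FALSE)
  out[order(out$gene, out$cohort), , drop = FALSE]
}

#' Consistency tally of quadrant calls
#'
#' Consistent = both axes in the same direction (`P+M+`, `P-M-`); opposite
#' = the two mixed quadrants. A chi-squared goodness-of-fit on
#' (n_opposite, n_consistent) against `expected_proportions` (default 1:1)
#' tests whether opposite-direction instances dominate; with no calls the
#' tally is zero and the test is skipped (`NULL`).
#'
#' @param calls Calls from [classify_dual()].
#' @param expected_proportions Expectation for the chi-squared test
#'   (default equal).
#' @return A `consistency_tally`: per-quadrant counts, `n_consistent`,
#'   `n_opposite`, per-gene cohort counts and the `chisq` test.
#' @export
tally_consistency <- function(calls, expected_proportions = NULL) {
  quadrants <- c("P+M+", "P+M-", "P-M+", "P-M-")
  called <- calls[calls$quadrant %in% quadrants, , drop = FALSE]
  counts <- vapply(quadrants, function(q) sum(called$quadrant == q),
                   integer(1L))
  n_consistent <- counts[["P+M+"]] + counts[["P-M-"]]
  n_opposite <- counts[["P+M-"]] + counts[["P-M+"]]
  per_gene <- if (nrow(called)) {
    tab <- table(called$gene)
    data.frame(gene = names(tab), n_cohorts = as.integer(tab),
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene = character(), n_cohorts = integer(),
               stringsAsFactors = FALSE)
  }
  test <- if (n_consistent + n_opposite > 0) {
    chi_square_gof(c(n_opposite, n_consistent), expected_proportions)
  } else NULL
  structure(list(counts = counts, n_consistent = n_consistent,
                 n_opposite = n_opposite, per_gene = per_gene,
                 chisq = test),
            class = "consistency_tally")
}

#' @export
print.consistency_tally <- function(x, ...) {
  cat(sprintf("<consistency_tally> opposite %d vs consistent %d\n",
              x$n_opposite, x$n_consistent))
  print(x$counts)
  if (!is.null(x$chisq)) {
    cat(sprintf("  chi-squared = %.4g, p = %.3g\n", x$chisq$statistic,
                x$chisq$p_value))
  }
  invisible(x)
}

#' Gene x hallmark x cohort direction matrix
#'
#' Stacks per-hallmark association tables, keeping only significant records,
#' into long form with one direction per (gene, hallmark, cohort) triple.
#' Duplicate triples are an error.
#'
#' @param records_by_hallmark Named list of association record tables, one
#'   per hallmark (each already thresholded by its own endpoint rules).
#' @return Data frame of class `direction_matrix`: gene, hallmark, cohort,
#'   direction.
#' @export
build_direction_matrix <- function(records_by_hallmark) {
  if (is.null(names(records_by_hallmark)) ||
      any(!nzchar(names(records_by_hallmark)))) {
    stop("`records_by_hallmark` must be a named list (names = hallmarks)")
  }
  rows <- lapply(names(records_by_hallmark), function(h) {
    df <- records_by_hallmark[[h]]
    if (is.null(df) || nrow(df) == 0L) return(NULL)
    sig <- df[df$significant %in% TRUE & df$direction %in% c("+", "-"), ,
              drop = FALSE]
    if (!nrow(sig)) return(NULL)
    data.frame(gene = sig$gene, hallmark = h, cohort = sig$cohort,
               direction = sig$direction, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(), hallmark = character(),
                      cohort = character(), direction = character(),
                      stringsAsFactors = FALSE)
  }
  key <- paste(out$gene, out$hallmark, out$cohort, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (gene, hallmark, cohort) record(s)")
  }
  class(out) <- c("direction_matrix", "data.frame")
  out
}

#' Multi-hallmark consistent-direction candidates
#'
#' For each gene and direction, counts the hallmarks with at least one
#' cohort significantly associated in that direction and keeps genes
#' reaching `min_hallmarks`. Candidates are ranked by (hallmark count,
#' total cohort instances), both descending. `strict = TRUE` counts only
#' hallmarks with no opposing cohort anywhere.
#'
#' @param dirmat A [build_direction_matrix()] result.
#' @param min_hallmarks Minimum number of hallmarks (default 5).
#' @param strict Require no opposing cohorts within a counted hallmark.
#' @return Data frame: gene, direction, n_hallmarks, n_instances, rank.
#' @export
consistent_direction_filter <- function(dirmat, min_hallmarks = 5,
                                        strict = FALSE) {
  empty <- data.frame(gene = character(), direction = character(),
                      n_hallmarks = integer(), n_instances = integer(),
                      rank = integer(), stringsAsFactors = FALSE)
  if (nrow(dirmat) == 0L) return(empty)
  rows <- list()
  for (dir in c("+", "-")) {
    sub <- dirmat[dirmat$direction == dir, , drop = FALSE]
    if (!nrow(sub)) next
    for (g in unique(sub$gene)) {
      gh <- unique(sub$hallmark[sub$gene == g])
      if (strict) {
        opp <- dirmat[dirmat$gene == g & dirmat$direction != dir, ,
                      drop = FALSE]
        gh <- setdiff(gh, unique(opp$hallmark))
      }
      n_inst <- sum(sub$gene == g & sub$hallmark %in% gh)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, direction = dir, n_hallmarks = length(gh),
        n_instances = n_inst, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[out$n_hallmarks >= min_hallmarks, , drop = FALSE]
  if (!nrow(out)) return(empty)
  out <- out[order(-out$n_hallmarks, -out$n_instances, out$gene), ,
             drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
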