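# Synthetic paired tumor/normal cohorts with planted, recoverable structure:
# equicorrelated co-expression blocks (tumor-side disruption), planted
# differential expression, a proliferation latent factor read out by the
# marker gene, an epithelial/mesenchymal latent factor, expression-linked
# survival, and a dependency screen with planted essential genes. Emulates
# the shape of TCGA/GTEx/Achilles-style inputs so every pipeline stage is
# testable without downloads.

#' Specify a synthetic cohort
#'
#' The generative model works on the log2 scale. For gene g and sample s,
#' `log2 x_gs = baseline_g + a_g * F_p(s) + b_g * F_e(s) + e_gs`, where `F_p`
#' and `F_e` are standard-normal proliferation and EMT factors, `a`/`b` the
#' per-gene loadings, and `e_gs` noise with standard deviation `noise_sd`.
#' Genes in a co-expression block share correlated noise: within a block the
#' noise is equicorrelated Gaussian with the block's condition-specific
#' `rho`, so the expression correlation of two otherwise-unloaded block
#' members equals `rho` (tumor-side disruption is `rho_tumor < rho_normal`).
#' The marker gene is a noiseless readout of `F_p` (loading 1); epithelial
#' and mesenchymal signature genes load -1/+1 on `F_e`. Tumor samples add
#' `de_effects` (log2 fold changes). Emitted values are `2^log2signal`, hence
#' non-negative; rank-based downstream statistics are insensitive to the
#' monotone choice of scale.
#'
#' Survival times are exponential with log hazard
#' `sum_g coef_g * standardized expression`, with independent exponential
#' censoring calibrated to the requested censoring rate. Dependency scores
#' are `1 - essentiality_g + N(0, dependency_noise_sd^2)` per cell line
#' (higher = more proliferation after knockout, so essential genes score
#' low).
#'
#' @param n_tumor,n_normal Sample counts.
#' @param genes Character vector of gene symbols (family + background genes;
#'   the marker and signature genes are appended automatically if absent).
#' @param coexpr_blocks List of blocks, each
#'   `list(genes =, rho_normal =, rho_tumor =)` with rho in \[0, 1); block
#'   memberships must be disjoint.
#' @param de_effects Named numeric vector of planted log2 fold changes
#'   (tumor minus normal).
#' @param prolif_loadings,emt_loadings Named numeric loadings on the
#'   proliferation / EMT factor.
#' @param epithelial_set,mesenchymal_set Disjoint character vectors of
#'   signature genes (loadings -1 / +1 on the EMT factor).
#' @param marker_gene Proliferation marker symbol (default `"MKI67"`).
#' @param noise_sd Noise standard deviation (log2 scale), > 0 for realistic
#'   data; 0 is allowed for degenerate-limit checks.
#' @param baseline_range Range of per-gene log2 baselines (uniform).
#' @param survival List: `baseline_rate` (events/day), `coefficients` (named
#'   log-hazard per standardized expression), `censoring_rate` in \[0, 1).
#' @param dependency List: `n_cell_lines`, `effects` (named essentiality),
#'   `noise_sd`.
#' @param seed Integer master seed; fixed seed gives byte-identical output.
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_tumor, n_normal, genes,
                        coexpr_blocks = list(),
                        de_effects = numeric(),
                        prolif_loadings = numeric(),
                        emt_loadings = numeric(),
                        epithelial_set = character(),
                        mesenchymal_set = character(),
                        marker_gene = "MKI67",
                        noise_sd = 1,
                        baseline_range = c(3, 8),
                        survival = list(baseline_rate = 0.001,
                                        coefficients = numeric(),
                                        censoring_rate = 0.3),
                        dependency = list(n_cell_lines = 100,
                                          effects = numeric(),
                                          noise_sd = 0.1),
                        seed = 1L) {
  stopifnot(n_tumor >= 1L, n_normal >= 1L, noise_sd >= 0)
  if (length(intersect(epithelial_set, mesenchymal_set))) {
    stop("epithelial and mesenchymal sets must be disjoint")
  }
  genes <- unique(c(genes, marker_gene, epithelial_set, mesenchymal_set))
  block_members <- unlist(lapply(coexpr_blocks, `[[`, "genes"))
  if (anyDuplicated(block_members)) {
    stop("spec error: co-expression block memberships must be disjoint")
  }
  if (!all(block_members %in% genes)) {
    stop("spec error: block members must be listed in `genes`")
  }
  for (b in coexpr_blocks) {
    if (b$rho_normal < 0 || b$rho_normal >= 1 ||
        b$rho_tumor < 0 || b$rho_tumor >= 1) {
      stop("spec error: block rho values must lie in [0, 1)")
    }
  }
  for (nm in c("de_effects", "prolif_loadings", "emt_loadings")) {
    v <- get(nm)
    if (length(v) && (is.null(names(v)) || !all(names(v) %in% genes))) {
      stop("spec error: `", nm, "` must be named by genes in `genes`")
    }
  }
  prolif <- stats::setNames(rep(0, length(genes)), genes)
  prolif[names(prolif_loadings)] <- prolif_loadings
  prolif[marker_gene] <- 1
  emt <- stats::setNames(rep(0, length(genes)), genes)
  emt[names(emt_loadings)] <- emt_loadings
  emt[epithelial_set] <- -1
  emt[mesenchymal_set] <- 1
  structure(list(
    n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
    genes = genes, coexpr_blocks = coexpr_blocks,
    de_effects = de_effects, prolif_loadings = prolif, emt_loadings = emt,
    epithelial_set = epithelial_set, mesenchymal_set = mesenchymal_set,
    marker_gene = marker_gene, noise_sd = noise_sd,
    baseline_range = baseline_range, survival = survival,
    dependency = dependency, seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Default synthetic study conditions
#'
#' The packaged reference conditions used throughout the tests and the
#' acceptance run: the 82-gene HSP catalog plus 500 background genes at
#' n = 400 tumor and 400 normal samples with unit noise. Planted structure,
#' by catalog position:
#' * genes 1-20: a "disrupted" block, rho 0.7 in normal vs 0.1 in tumor;
#' * genes 21-30 and 31-40: blocks with rho 0.6 vs 0.2;
#' * genes 41-48 / 49-56: differential expression, log2FC +1.5 / -1.5;
#' * genes 57-80: dual-function genes, 6 per quadrant, proliferation/EMT
#'   loadings of (+-0.5, +-0.5);
#' * genes 81, 82: survival log-hazard coefficients +0.8 / -0.8;
#' * MKI67 marker plus 50 epithelial and 50 mesenchymal signature genes;
#' * essentiality 1.85 / 1.08 / 0.99 planted on HSPE1, HSPA9, DNAJC9 in a
#'   100-cell-line dependency screen.
#'
#' @param seed Master seed.
#' @param n_tumor,n_normal Sample counts.
#' @param n_background Number of uncorrelated background genes.
#' @return A [cohort_spec()].
#' @export
default_cohort_spec <- function(seed = 1L, n_tumor = 400L, n_normal = 400L,
                                n_background = 500L) {
  catalog <- load_catalog("default")
  fam <- catalog$gene
  background <- sprintf("BG%04d", seq_len(n_background))
  epithelial <- sprintf("EPI%03d", 1:50)
  mesenchymal <- sprintf("MES%03d", 1:50)
  blocks <- list(
    list(genes = fam[1:20], rho_normal = 0.7, rho_tumor = 0.1),
    list(genes = fam[21:30], rho_normal = 0.6, rho_tumor = 0.2),
    list(genes = fam[31:40], rho_normal = 0.6, rho_tumor = 0.2)
  )
  de <- stats::setNames(c(rep(1.5, 8), rep(-1.5, 8)), fam[41:56])
  quad <- fam[57:80]
  prolif <- stats::setNames(rep(c(0.5, 0.5, -0.5, -0.5), each = 6), quad)
  emt <- stats::setNames(rep(c(0.5, -0.5, 0.5, -0.5), each = 6), quad)
  surv_coef <- stats::setNames(c(0.8, -0.8), fam[81:82])
  ess <- stats::setNames(c(1.85, 1.08, 0.99),
                         c("HSPE1", "HSPA9", "DNAJC9"))
  cohort_spec(
    n_tumor = n_tumor, n_normal = n_normal,
    genes = c(fam, background),
    coexpr_blocks = blocks,
    de_effects = de,
    prolif_loadings = prolif,
    emt_loadings = emt,
    epithelial_set = epithelial,
    mesenchymal_set = mesenchymal,
    noise_sd = 1,
    survival = list(baseline_rate = 0.001, coefficients = surv_coef,
                    censoring_rate = 0.3),
    dependency = list(n_cell_lines = 100L, effects = ess, noise_sd = 0.1),
    seed = seed
  )
}

# Log2-scale signal for one condition. Factors and noise are drawn inside;
# the caller controls the RNG stream.
simulate_condition <- function(spec, n, baseline, condition) {
  genes <- spec$genes
  G <- length(genes)
  f_p <- stats::rnorm(n)
  f_e <- stats::rnorm(n)
  log2e <- matrix(baseline, nrow = G, ncol = n,
                  dimnames = list(genes, NULL)) +
    outer(spec$prolif_loadings, f_p) +
    outer(spec$emt_loadings, f_e)
  block_genes <- unlist(lapply(spec$coexpr_blocks, `[[`, "genes"))
  plain <- setdiff(genes, c(block_genes, spec$marker_gene))
  if (length(plain) && spec$noise_sd > 0) {
    log2e[plain, ] <- log2e[plain, , drop = FALSE] +
      matrix(stats::rnorm(length(plain) * n, sd = spec$noise_sd),
             nrow = length(plain))
  }
  rho_field <- if (condition == "tumor") "rho_tumor" else "rho_normal"
  for (b in spec$coexpr_blocks) {
    k <- length(b$genes)
    rho <- b[[rho_field]]
    shared <- stats::rnorm(n)
    eps <- matrix(stats::rnorm(k * n), nrow = k)
    term <- sqrt(rho) * matrix(shared, nrow = k, ncol = n, byrow = TRUE) +
      sqrt(1 - rho) * eps
    log2e[b$genes, ] <- log2e[b$genes, , drop = FALSE] +
      spec$noise_sd * term
  }
  if (condition == "tumor" && length(spec$de_effects)) {
    log2e[names(spec$de_effects), ] <-
      log2e[names(spec$de_effects), , drop = FALSE] + spec$de_effects
  }
  suffix <- if (condition == "tumor") "T" else "N"
  colnames(log2e) <- sprintf("S%04d.%s", seq_len(n), suffix)
  list(log2 = log2e, f_p = f_p, f_e = f_e)
}

#' Generate a synthetic cohort
#'
#' Draws the paired tumor/normal expression matrices, clinical table and
#' dependency screen from a [cohort_spec()], together with the planted
#' ground truth. Tumor and normal samples `S0001.T` / `S0001.N` share a
#' sample prefix so paired analyses can match them. A fixed seed gives
#' byte-identical output.
#'
#' @param spec A [cohort_spec()].
#' @return List with elements `tumor` and `normal`
#'   ([expression_matrix()]s), `clinical` (data frame with `sample`,
#'   `os_time`, `os_event`, `stage`, `subtype`), `dependency` (genes x cell
#'   lines score matrix) and `truth` (planted edges, DE directions, quadrant
#'   labels, essential genes and the latent factor scores per sample).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    genes <- spec$genes
    baseline <- stats::runif(length(genes), spec$baseline_range[1L],
                             spec$baseline_range[2L])
    names(baseline) <- genes
    normal <- simulate_condition(spec, spec$n_normal, baseline, "normal")
    tumor <- simulate_condition(spec, spec$n_tumor, baseline, "tumor")
    tumor_x <- expression_matrix(2^tumor$log2, condition = "tumor",
                                 cohort = "SYN")
    normal_x <- expression_matrix(2^normal$log2, condition = "normal",
                                  cohort = "SYN")

    clinical <- simulate_clinical(spec, tumor$log2)
    dependency <- simulate_dependency(spec)
    truth <- build_truth(spec, tumor, normal)
    list(tumor = tumor_x, normal = normal_x, clinical = clinical,
         dependency = dependency, truth = truth)
  })
}

simulate_clinical <- function(spec, tumor_log2) {
  n <- ncol(tumor_log2)
  coefs <- spec$survival$coefficients
  lp <- rep(0, n)
  for (g in names(coefs)) {
    x <- tumor_log2[g, ]
    if (stats::sd(x) > 0) lp <- lp + coefs[[g]] * as.numeric(scale(x))
  }
  rate <- spec$survival$baseline_rate * exp(lp)
  t_event <- stats::rexp(n, rate = rate)
  cens <- spec$survival$censoring_rate
  if (cens > 0) {
    # exponential censoring; exponential-vs-exponential gives
    # P(censored) = rate_c / (rate_c + rate_t), calibrated at the typical
    # (median-hazard) subject
    rate_c <- spec$survival$baseline_rate * exp(stats::median(lp)) *
      cens / (1 - cens)
    t_cens <- stats::rexp(n, rate = rate_c)
  } else {
    t_cens <- rep(Inf, n)
  }
  data.frame(
    sample = colnames(tumor_log2),
    os_time = pmin(t_event, t_cens),
    os_event = as.integer(t_event <= t_cens),
    stage = sample(c("I", "II", "III"), n, replace = TRUE),
    subtype = sample(c("A", "B"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

simulate_dependency <- function(spec) {
  dep <- spec$dependency
  genes <- setdiff(spec$genes,
                   c(spec$epithelial_set, spec$mesenchymal_set))
  eff <- stats::setNames(rep(0, length(genes)), genes)
  keep <- intersect(names(dep$effects), genes)
  eff[keep] <- dep$effects[keep]
  m <- dep$n_cell_lines
  scores <- matrix(1 - eff, nrow = length(genes), ncol = m) +
    matrix(stats::rnorm(length(genes) * m, sd = dep$noise_sd),
           nrow = length(genes))
  dimnames(scores) <- list(genes, sprintf("CL%03d", seq_len(m)))
  scores
}

build_truth <- function(spec, tumor, normal) {
  edges <- do.call(rbind, lapply(spec$coexpr_blocks, function(b) {
    if (length(b$genes) < 2L) return(NULL)
    idx <- utils::combn(b$genes, 2L)
    cbind(canonical_pairs(idx[1L, ], idx[2L, ]),
          rho_normal = b$rho_normal, rho_tumor = b$rho_tumor)
  }))
  if (is.null(edges)) {
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        rho_normal = numeric(), rho_tumor = numeric())
  }
  de <- data.frame(
    gene = names(spec$de_effects),
    log2fc = unname(spec$de_effects),
    direction = ifelse(spec$de_effects > 0, "+", "-"),
    stringsAsFactors = FALSE
  )
  sig_genes <- c(spec$marker_gene, spec$epithelial_set, spec$mesenchymal_set)
  loaded <- setdiff(
    unique(c(names(spec$prolif_loadings)[spec$prolif_loadings != 0],
             names(spec$emt_loadings)[spec$emt_loadings != 0])),
    sig_genes)
  quadrants <- data.frame(
    gene = loaded,
    prolif_loading = unname(spec$prolif_loadings[loaded]),
    emt_loading = unname(spec$emt_loadings[loaded]),
    quadrant = quadrant_label(sign(spec$prolif_loadings[loaded]),
                              sign(spec$emt_loadings[loaded])),
    stringsAsFactors = FALSE
  )
  list(
    edges = edges,
    de = de,
    quadrants = quadrants,
    essential_genes = names(spec$dependency$effects)[
      spec$dependency$effects > 0],
    survival_coefficients = as.list(spec$survival$coefficients),
    factors = list(
      tumor = data.frame(sample = colnames(tumor$log2), f_p = tumor$f_p,
                         f_e = tumor$f_e, stringsAsFactors = FALSE),
      normal = data.frame(sample = colnames(normal$log2), f_p = normal$f_p,
                          f_e = normal$f_e, stringsAsFactors = FALSE)
    )
  )
}

# Quadrant label from the two direction signs; 0 on either axis gives "none".
quadrant_label <- function(prolif_sign, emt_sign) {
  out <- rep("none", length(prolif_sign))
  ok <- prolif_sign != 0 & emt_sign != 0
  out[ok] <- paste0("P", ifelse(prolif_sign[ok] > 0, "+", "-"),
                    "M", ifelse(emt_sign[ok] > 0, "+", "-"))
  out
}

#' Write a synthetic fixture bundle to disk
#'
#' Generates the cohort and writes every pipeline input in its external
#' format: tumor/normal expression TSVs, clinical TSV, dependency TSV, the
#' EMT signature GMT, a small synthetic "hallmark" GMT (background-gene
#' sets for exercising the hallmark stages), the gene-family catalog, a PPI
#' edge list derived from a fixed fraction of the planted block pairs, the
#' planted-truth JSON and a manifest with md5 checksums.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest (named file list plus checksums), invisibly written
#'   to `manifest.json` as well.
#' @export
emit_fixture_bundle <- function(spec, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) stop("cannot create ", out_dir)
  }
  cohort <- generate_cohort(spec)
  path <- function(f) file.path(out_dir, f)
  write_expression(cohort$tumor, path("expression_tumor.tsv"))
  write_expression(cohort$normal, path("expression_normal.tsv"))
  write_clinical(cohort$clinical, path("clinical.tsv"))
  dep <- data.frame(gene = rownames(cohort$dependency), cohort$dependency,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(dep, path("dependency.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_gmt(list(EPITHELIAL = spec$epithelial_set,
                 MESENCHYMAL = spec$mesenchymal_set),
            path("emt_signature.gmt"))
  hallmarks <- synthetic_hallmark_sets(spec)
  write_gmt(hallmarks, path("hallmarks.gmt"))
  catalog <- load_catalog("default")
  catalog <- catalog[catalog$gene %in% spec$genes, , drop = FALSE]
  if (!nrow(catalog)) {
    catalog <- data.frame(gene = spec$genes, family = "unassigned",
                          subfamily = "", stringsAsFactors = FALSE)
  }
  write_catalog(catalog, path("catalog.tsv"))
  edges <- cohort$truth$edges
  ppi <- if (nrow(edges)) {
    keep <- seq_len(floor(0.55 * nrow(edges)))
    edges[keep, c("gene_a", "gene_b"), drop = FALSE]
  } else {
    data.frame(gene_a = character(), gene_b = character())
  }
  write_ppi(ppi, path("ppi.tsv"))
  jsonlite::write_json(cohort$truth, path("truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  files <- c("expression_tumor.tsv", "expression_normal.tsv",
             "clinical.tsv", "dependency.tsv", "emt_signature.gmt",
             "hallmarks.gmt", "catalog.tsv", "ppi.tsv", "truth.json")
  manifest <- list(
    seed = spec$seed,
    n_tumor = spec$n_tumor,
    n_normal = spec$n_normal,
    files = as.list(stats::setNames(files, sub("\\..*$", "", files))),
    md5 = as.list(stats::setNames(
      unname(tools::md5sum(vapply(files, path, character(1L)))), files))
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

# Deterministic synthetic hallmark gene sets drawn from the background genes
# (marks the bundle's hallmark inputs as synthetic stand-ins).
synthetic_hallmark_sets <- function(spec, n_sets = 4L, set_size = 30L) {
  bg <- grep("^BG", spec$genes, value = TRUE)
  if (length(bg) < n_sets * set_size) {
    bg <- setdiff(spec$genes, c(spec$marker_gene, spec$epithelial_set,
                                spec$mesenchymal_set))
  }
  names <- paste0("SYN_HALLMARK_", c("STEMNESS", "ANGIOGENESIS", "HYPOXIA",
                                     "INFLAMMATION")[seq_len(n_sets)])
  with_seed(spec$seed + 7L, {
    sets <- lapply(seq_len(n_sets), function(i) {
      sort(sample(bg, min(set_size, length(bg))))
    })
    stats::setNames(sets, names)
  })
}
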