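# Independent brute-force oracles, kept deliberately naive and separate from
# the implementation paths they check.

# Benjamini-Hochberg by direct evaluation of the step-up definition.
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)  # position of p[i] in the sorted order
    cand <- vapply(rank_i:m, function(j) p[ord[j]] * m / j, numeric(1))
    q[i] <- min(1, min(cand))
  }
  q
}

# Weighted-KS enrichment score by explicit running-sum enumeration.
es_brute <- function(ranked, gene_set, weight = 1) {
  n <- length(ranked)
  hits <- names(ranked) %in% gene_set
  w <- abs(ranked)^weight
  denom <- sum(w[hits])
  if (denom == 0) {
    w[] <- 1
    denom <- sum(hits)
  }
  run <- 0
  mx <- -Inf
  mn <- Inf
  for (j in seq_len(n)) {
    run <- run + if (hits[j]) unname(w[j]) / denom else -1 / (n - sum(hits))
    mx <- max(mx, run)
    mn <- min(mn, run)
  }
  if (mx + mn >= -1e-12) mx else mn
}

# Two-group log-rank O-E and V by hand enumeration over distinct event times.
logrank_brute <- function(time_a, event_a, time_b, event_b) {
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp <- rep(c(0, 1), c(length(time_a), length(time_b)))
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp == 1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & grp == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(o_minus_e = o_minus_e, v = v, chisq = o_minus_e^2 / v)
}

# Breslow log partial likelihood for a single covariate.
breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    dead <- event == 1 & time == t
    ll <- ll + sum(beta * x[dead]) -
      sum(dead) * log(sum(exp(beta * x[at_risk])))
  }
  ll
}

# Small helper: expression matrix from a genes x samples matrix of values.
make_expr <- function(vals, condition = "tumor", cohort = "TEST") {
  expression_matrix(vals, condition = condition, cohort = cohort)
}

# Random well-formed expression matrix.
random_expr <- function(n_genes = 6, n_samples = 8, condition = "tumor",
                        cohort = "TEST") {
  vals <- matrix(round(stats::runif(n_genes * n_samples, 0, 100), 4),
                 nrow = n_genes,
                 dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                                 sprintf("S%03d", seq_len(n_samples))))
  make_expr(vals, condition, cohort)
}

# Tiny two-block cohort spec used by several module tests.
tiny_spec <- function(seed = 1, n_tumor = 60, n_normal = 60, ...) {
  cohort_spec(
    n_tumor = n_tumor, n_normal = n_normal,
    genes = c(sprintf("FAM%02d", 1:20), sprintf("BG%03d", 1:30)),
    coexpr_blocks = list(
      list(genes = sprintf("FAM%02d", 1:8), rho_normal = 0.7,
           rho_tumor = 0.1)),
    de_effects = c(FAM09 = 2, FAM10 = -2),
    epithelial_set = sprintf("EPI%02d", 1:10),
    mesenchymal_set = sprintf("MES%02d", 1:10),
    seed = seed, ...)
}
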