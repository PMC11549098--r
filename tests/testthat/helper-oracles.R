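# Independent brute-force oracles, deliberately written element-by-element
# so they share no code path with the package internals.

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sxx <- syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  r <- sxy / sqrt(sxx * syy)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), n - 2))
}

# BH step-up by direct enumeration of the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (k in seq_len(m)) {
    vals <- vapply(k:m, function(j) m * p[o[j]] / j, 0)
    adj[o[k]] <- min(1, min(vals))
  }
  adj
}

oracle_zscore <- function(auc, control_rows) {
  lg <- log2(auc)
  z <- lg
  for (j in seq_len(ncol(lg))) {
    mu <- mean(lg[control_rows, j])
    sdv <- sd(lg[control_rows, j])
    for (i in seq_len(nrow(lg))) z[i, j] <- (lg[i, j] - mu) / sdv
  }
  z
}

# Small fixture: random positive AUC table with metadata
make_toy_table <- function(n_case = 3, n_control = 4, M = 5, seed = 1) {
  set.seed(seed)
  n <- n_case + n_control
  auc <- matrix(2^(rnorm(n * M, 20, 1)), n, M,
                dimnames = list(sprintf("s%02d", 1:n), sprintf("met%02d", 1:M)))
  meta <- data.frame(sample_id = rownames(auc),
                     group = c(rep("control", n_control), rep("case", n_case)),
                     sex = rep(c("M", "F"), length.out = n),
                     cohort = "toy", stringsAsFactors = FALSE)
  sample_table(auc, meta)
}

make_toy_pmap <- function(mets, n_pathways = 2) {
  suppressMessages(pathway_map(mets, rep(sprintf("pw%d", seq_len(n_pathways)),
                                         length.out = length(mets))))
}

# Full-path edge counting used to cross-check the fast resampling internals
slow_edge_count <- function(zm, pmap, rows, q_threshold, scope, sign) {
  tbl <- adjust_pvalues(pairwise_correlations(zm[rows, , drop = FALSE]))
  net <- build_network(tbl, pmap, q_threshold = q_threshold,
                       sign = sign, scope = scope)
  nrow(net$edges)
}
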