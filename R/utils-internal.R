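# Internal helpers shared across modules: canonical pair indexing, fast
# correlation of subsamples, and the significance machinery used by the
# resampling loops. The fast path is exactly equivalent (same significant
# edge set) to pairwise_correlations() + adjust_pvalues() + build_network();
# tests assert this equivalence.

# Canonical unordered-pair index for M metabolites, column-major upper
# triangle: pair k has endpoints (row[k], col[k]) with row < col, and `ut`
# are the matching linear indices into an M x M matrix.
.pair_info <- function(M, metabolites = NULL) {
  stopifnot(M >= 2)
  list(
    M = M,
    m = M * (M - 1L) / 2L,
    row = sequence(seq_len(M - 1L)),
    col = rep.int(2:M, seq_len(M - 1L)),
    ut = which(upper.tri(matrix(FALSE, M, M))),
    metabolites = metabolites
  )
}

# Pearson correlations of the columns of Zs over all pairs, as the upper
# triangle vector. Columns that are constant in this subsample yield r = 0
# for every pair that touches them (the pair is kept so the test count m
# stays fixed across resamples).
.corr_upper <- function(Zs, pinfo) {
  n <- nrow(Zs)
  cm <- colMeans(Zs)
  Zc <- Zs - rep(cm, each = n)
  ss <- sqrt(colSums(Zc * Zc))
  bad <- !is.finite(ss) | ss <= 0
  ss[bad] <- 1
  Zc <- Zc / rep(ss, each = n)
  rv <- crossprod(Zc)[pinfo$ut]
  rv[rv > 1] <- 1
  rv[rv < -1] <- -1
  if (any(bad)) {
    badpair <- bad[pinfo$row] | bad[pinfo$col]
    rv[badpair] <- 0
  } else {
    badpair <- NULL
  }
  list(r = rv, badpair = badpair)
}

# Two-sided p-value for Pearson r at n observations via the t transform
# t = r * sqrt((n-2) / (1-r^2)) on n-2 degrees of freedom. |r| = 1 is
# clamped to the smallest positive double so log-scale reporting never
# sees a zero.
.pearson_p <- function(r, n) {
  df <- n - 2
  a <- abs(r)
  tt <- a * sqrt(df / pmax(1 - a * a, 0))
  p <- 2 * stats::pt(tt, df, lower.tail = FALSE)
  p[p < .Machine$double.xmin] <- .Machine$double.xmin
  p
}

.storey_lambda_default <- seq(0.05, 0.90, by = 0.05)

# Shared pi0 logic: `tail_counts[k]` = number of p-values > lambda[k] out of
# m tests. Cubic smoothing spline over the lambda grid, evaluated at the
# largest lambda; estimates >= 1 or unstable fits fall back to pi0 = 1
# (q-values then coincide with BH).
.pi0_from_tail_counts <- function(tail_counts, m, lambda) {
  if (m < 100L) return(1)
  pi0_l <- tail_counts / (m * (1 - lambda))
  if (all(pi0_l <= 0)) return(1)
  fit <- try(stats::smooth.spline(lambda, pi0_l, df = 3), silent = TRUE)
  if (inherits(fit, "try-error")) return(1)
  pi0 <- stats::predict(fit, x = max(lambda))$y
  if (!is.finite(pi0) || pi0 >= 1 || pi0 <= 0) return(1)
  pi0
}

# Significant pairs of a subsample at q < q_threshold without materialising
# p-values for all m pairs. Because p is strictly decreasing in |r| at fixed
# n, (i) the pi0 tail counts #\{p > lambda\} equal #\{|r| < r_lambda\}, and
# (ii) a pair can only reach q < t when p <= t / pi0, which maps to an |r|
# cutoff. Both conversions use the same pt()/qt() pair as the full path, so
# the selected edge set is identical.
.sig_pairs <- function(rv, n, pinfo, q_threshold, lambda = .storey_lambda_default) {
  m <- pinfo$m
  df <- n - 2
  a <- abs(rv)
  tl <- stats::qt(1 - lambda / 2, df)
  rl <- tl / sqrt(df + tl * tl)
  # tail_counts[k] = #|r| < r_lambda[k], via one binning pass: findInterval
  # counts thresholds <= a, so #(bin <= j-1) elements lie strictly below the
  # j-th ascending threshold (rl descends with lambda, hence the reversal)
  rs <- rev(rl)
  bin <- findInterval(a, rs)
  cnt_lt <- cumsum(tabulate(bin + 1L, nbins = length(rs) + 1L))[seq_along(rs)]
  tail_counts <- cnt_lt[length(rs) + 1L - seq_along(lambda)]
  pi0 <- .pi0_from_tail_counts(tail_counts, m, lambda)

  pcut <- min(1, q_threshold / pi0 * (1 + 1e-9))
  if (pcut >= 1) {
    cand <- seq_len(m)
  } else {
    tcut <- stats::qt(1 - pcut / 2, df)
    rcut <- (tcut / sqrt(df + tcut * tcut)) * (1 - 1e-12)
    cand <- which(a >= rcut)
  }
  if (!length(cand)) return(list(idx = integer(0), pi0 = pi0))

  p <- .pearson_p(rv[cand], n)
  o <- order(p, method = "radix")
  vals <- pi0 * m * p[o] / seq_along(o)
  qtr <- rev(cummin(rev(vals)))
  # Ranks beyond the candidate set have p > pcut, hence pi0*m*p/j > t for
  # every such j; they can neither be significant nor lower qtr below t.
  sig <- cand[o][qtr < q_threshold]
  list(idx = sig, pi0 = pi0)
}

# Signed / scoped edge counts for a subsample given precomputed pathway
# agreement over pairs. Returns c(pos_in, pos_out, neg_in, neg_out).
.count_edges <- function(rv, sig_idx, same_path) {
  if (!length(sig_idx)) return(c(pos_in = 0L, pos_out = 0L, neg_in = 0L, neg_out = 0L))
  pos <- rv[sig_idx] > 0
  inp <- same_path[sig_idx]
  c(pos_in = sum(pos & inp), pos_out = sum(pos & !inp),
    neg_in = sum(!pos & inp), neg_out = sum(!pos & !inp))
}

.filter_count <- function(counts, scope, sign) {
  keep_scope <- switch(scope, `in` = c(TRUE, FALSE), out = c(FALSE, TRUE), both = c(TRUE, TRUE))
  keep_sign <- switch(sign, `+` = c(TRUE, FALSE), `-` = c(FALSE, TRUE), both = c(TRUE, TRUE))
  mask <- c(keep_sign[1] & keep_scope, keep_sign[2] & keep_scope)
  sum(counts[mask])
}

# Independent RNG substream per (size index, replicate) derived from a
# master seed by modular hashing, so extending the size grid never perturbs
# draws already taken.
.substream_seed <- function(master, i, j) {
  s <- (abs(as.numeric(master)) %% 2147483647) + 1
  s <- (s * 48271) %% 2147483647
  (s + i * 1000003 + j * 7919) %% 2147483647
}

# One-shot fast count over all rows of a z matrix; the building block the
# resampling loop applies per subsample, factored out so its equivalence to
# the full pipeline can be asserted directly.
.fast_count <- function(zm, pmap, q_threshold, scope, sign) {
  pinfo <- .pair_info(ncol(zm), colnames(zm))
  pw <- .pathway_of(colnames(zm), pmap)
  same_path <- pw[pinfo$row] == pw[pinfo$col]
  cu <- .corr_upper(zm, pinfo)
  sig <- .sig_pairs(cu$r, nrow(zm), pinfo, q_threshold)
  .filter_count(.count_edges(cu$r, sig$idx, same_path),
                .match_arg_scope(scope), .match_arg_sign(sign))
}

.match_arg_sign <- function(sign) {
  sign <- as.character(sign)
  if (sign %in% c("pos", "positive")) sign <- "+"
  if (sign %in% c("neg", "negative")) sign <- "-"
  match.arg(sign, c("both", "+", "-"))
}

.match_arg_scope <- function(scope) {
  match.arg(as.character(scope), c("both", "out", "in"))
}

# Pathway lookup with a hard error on any metabolite the map does not cover
# (the map must be total on the node universe it is used with).
.pathway_of <- function(metabolites, pmap) {
  pw <- unname(pmap[metabolites])
  if (anyNA(pw)) {
    stop("pathway map is missing metabolites: ",
         paste(utils::head(metabolites[is.na(pw)], 5), collapse = ", "),
         call. = FALSE)
  }
  pw
}
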