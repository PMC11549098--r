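#' All pairwise Pearson correlations between metabolites
#'
#' Computes the product-moment correlation, and its two-sided p-value from
#' the t transform `t = r * sqrt((n-2)/(1-r^2))` on `n - 2` degrees of
#' freedom, for every unordered metabolite pair. Pairs are stored in
#' canonical form (first id the one that comes first in column order) so
#' exports are bit-stable. Pairs in which either metabolite is constant over
#' the selected samples are kept with `r = 0`, `p = 1`, so the test count
#' `m = M(M-1)/2` is identical across subsamples and multiple-testing
#' adjustments stay comparable.
#'
#' @param z A `zmatrix` (see [zscore_transform()]) or a plain numeric matrix
#'   with samples in rows.
#' @param sample_subset Optional character vector of sample ids (or integer
#'   row indices) to correlate; at least 4 samples are required.
#' @return A data frame of class `corr_table` with columns `met_a`, `met_b`,
#'   `r`, `p`, `n_obs`, one row per pair.
#' @export
pairwise_correlations <- function(z, sample_subset = NULL) {
  zm <- if (inherits(z, "zmatrix")) z$z else as.matrix(z)
  if (!is.null(sample_subset)) {
    if (is.character(sample_subset)) {
      missing_ids <- setdiff(sample_subset, rownames(zm))
      if (length(missing_ids)) stop("unknown sample id(s): ", paste(missing_ids, collapse = ", "))
    }
    zm <- zm[sample_subset, , drop = FALSE]
  }
  n <- nrow(zm)
  if (n < 4) stop("at least 4 samples are required (got ", n, ")")
  pinfo <- .pair_info(ncol(zm), colnames(zm))
  cu <- .corr_upper(zm, pinfo)
  p <- .pearson_p(cu$r, n)
  if (!is.null(cu$badpair)) p[cu$badpair] <- 1
  mets <- colnames(zm)
  out <- data.frame(met_a = mets[pinfo$row], met_b = mets[pinfo$col],
                    r = cu$r, p = p, n_obs = n,
                    stringsAsFactors = FALSE)
  class(out) <- c("corr_table", "data.frame")
  attr(out, "m") <- pinfo$m
  out
}

#' Benjamini-Hochberg FDR and Storey q-values for a correlation table
#'
#' Adds `fdr` (BH step-up over all `M(M-1)/2` tests) and `q` (Storey
#' q-value) columns. The Storey null proportion pi0 is estimated on a lambda
#' grid 0.05-0.90 (step 0.05) with a cubic smoothing-spline extrapolated to
#' the largest lambda; estimates at or above 1, or unstable fits (including
#' small test families, m < 100), fall back to pi0 = 1, in which case the
#' q-values equal the BH FDR exactly.
#'
#' @param tbl A `corr_table` from [pairwise_correlations()].
#' @param pi0 Optional fixed null proportion in (0, 1]; bypasses estimation.
#' @return The table with `fdr` and `q` columns and a `pi0` attribute.
#' @export
adjust_pvalues <- function(tbl, pi0 = NULL) {
  stopifnot(inherits(tbl, "corr_table"))
  p <- tbl$p
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  tbl$fdr <- stats::p.adjust(p, method = "BH")
  if (is.null(pi0)) pi0 <- storey_pi0(p)
  tbl$q <- storey_qvalue(p, pi0 = pi0)
  attr(tbl, "pi0") <- pi0
  attr(tbl, "adjusted") <- TRUE
  tbl
}

#' Storey estimate of the null proportion pi0
#'
#' `pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))` over a lambda grid,
#' smoothed with a cubic spline and read off at the largest lambda.
#' Estimates `>= 1`, non-finite fits, or families of fewer than 100 tests
#' return the conservative `pi0 = 1`.
#'
#' @param p Numeric vector of p-values.
#' @param lambda Grid of tuning values in (0, 1).
#' @return A scalar in (0, 1].
#' @export
storey_pi0 <- function(p, lambda = .storey_lambda_default) {
  m <- length(p)
  tail_counts <- vapply(lambda, function(l) sum(p > l), numeric(1))
  .pi0_from_tail_counts(tail_counts, m, lambda)
}

#' Storey q-values
#'
#' `q(i) = min_\{j >= i\} pi0 * m * p_(j) / j` over p-values sorted
#' ascending, capped at 1. With `pi0 = 1` this is exactly the BH adjusted
#' p-value.
#'
#' @param p Numeric vector of p-values.
#' @param pi0 Null proportion; estimated via [storey_pi0()] when `NULL`.
#' @return Numeric vector of q-values aligned with `p`.
#' @export
storey_qvalue <- function(p, pi0 = NULL) {
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (is.null(pi0)) pi0 <- storey_pi0(p)
  m <- length(p)
  o <- order(p, method = "radix")
  vals <- pi0 * m * p[o] / seq_len(m)
  qs <- pmin(rev(cummin(rev(vals))), 1)
  out <- numeric(m)
  out[o] <- qs
  out
}

#' @export
print.corr_table <- function(x, ...) {
  cat("<corr_table> ", nrow(x), " metabolite pairs, n = ", x$n_obs[1],
      " samples", if (isTRUE(attr(x, "adjusted")))
        sprintf(", pi0 = %.3f", attr(x, "pi0")), "\n", sep = "")
  NextMethod()
}
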