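#' Ramped subsample size grid
#'
#' Sizes start at `start` (default 4, the smallest sample count with a
#' defined correlation test) and increase by `step` (default 2) up to
#' `n - 1`; when the arithmetic ramp does not land on `n - 1` exactly, it is
#' appended, so the largest subsample always has one sample withheld. For
#' example, 22 samples give 4, 6, ..., 20, 21 and 31 samples give 4, 6, ...,
#' 30.
#'
#' @param n Number of available samples (must be at least 5).
#' @param start,step Ramp origin and increment.
#' @return Strictly increasing integer vector of subset sizes.
#' @export
ramp_sizes <- function(n, start = 4, step = 2) {
  if (n < 5) stop("`n` must be at least 5 for a valid ramp (got ", n, ")")
  if (start < 4) stop("`start` must be at least 4")
  sizes <- seq.int(start, n - 1L, by = step)
  if (sizes[length(sizes)] != n - 1L) sizes <- c(sizes, n - 1L)
  as.integer(sizes)
}

#' Edge counts under ramped random resampling
#'
#' For each subset size and replicate, draws a random subsample (without
#' replacement by default; `replacement = TRUE` gives the with-replacement
#' variant), recomputes all pairwise correlations and their Storey q-values
#' within the subsample (the test family `m = M(M-1)/2` is fixed), and
#' counts the edges with `q < q_threshold` that pass the scope and sign
#' filters. Per-size mean, median, SD, SEM and the coefficient of variation
#' `cv = SEM / mean` are tabulated. Each (size, replicate) cell draws from
#' its own RNG substream derived from `seed`, so the full counts array is
#' reproducible and extending the grid does not perturb existing draws.
#'
#' @param z A `zmatrix` (typically already restricted to one group via
#'   [subset_samples()]) or a plain samples-by-metabolites matrix.
#' @param pmap A [pathway_map()] covering all metabolites.
#' @param sizes Integer vector of subset sizes; defaults to
#'   [ramp_sizes()]`(n)`. Must not exceed `n - 1`.
#' @param replicates Random subsamples per size (default 50).
#' @param q_threshold Significance threshold on the q-value (default 0.05).
#' @param scope Count `"out"`-of-pathway edges (default, the growth-curve
#'   convention), `"in"`, or `"both"`.
#' @param sign Count `"+"`, `"-"`, or `"both"` (default) edge signs.
#' @param replacement Draw subsamples with replacement (default `FALSE`).
#' @param seed Master integer seed.
#' @param group Optional group label carried into the result.
#' @return Object of class `vnet_curve`: list with `counts` (data frame
#'   `size, replicate, count`), `stats` (per-size summary), and `settings`.
#' @export
resample_edge_counts <- function(z, pmap, sizes = NULL, replicates = 50,
                                 q_threshold = 0.05, scope = "out",
                                 sign = "both", replacement = FALSE,
                                 seed = 1, group = NULL) {
  zm <- if (inherits(z, "zmatrix")) z$z else as.matrix(z)
  n <- nrow(zm)
  if (is.null(sizes)) sizes <- ramp_sizes(n)
  sizes <- as.integer(sizes)
  if (is.unsorted(sizes, strictly = TRUE)) stop("`sizes` must be strictly increasing")
  if (min(sizes) < 4) stop("subset sizes below 4 are not admissible")
  if (max(sizes) > n - 1L)
    stop("largest subset size (", max(sizes), ") exceeds n - 1 = ", n - 1L)
  if (replicates < 1) stop("`replicates` must be >= 1")
  scope <- .match_arg_scope(scope)
  sign <- .match_arg_sign(sign)

  pinfo <- .pair_info(ncol(zm), colnames(zm))
  pw <- .pathway_of(colnames(zm), pmap)
  same_path <- pw[pinfo$row] == pw[pinfo$col]

  counts <- matrix(0L, nrow = replicates, ncol = length(sizes))
  for (i in seq_along(sizes)) {
    for (j in seq_len(replicates)) {
      set.seed(.substream_seed(seed, i, j))
      rows <- sample.int(n, sizes[i], replace = replacement)
      cu <- .corr_upper(zm[rows, , drop = FALSE], pinfo)
      sig <- .sig_pairs(cu$r, sizes[i], pinfo, q_threshold)
      counts[j, i] <- .filter_count(.count_edges(cu$r, sig$idx, same_path),
                                    scope, sign)
    }
  }
  df <- data.frame(size = rep(sizes, each = replicates),
                   replicate = rep(seq_len(replicates), length(sizes)),
                   count = as.integer(counts))
  mu <- colMeans(counts)
  sdv <- apply(counts, 2, stats::sd)
  sem <- sdv / sqrt(replicates)
  stats_df <- data.frame(size = sizes, mean = mu,
                         median = apply(counts, 2, stats::median),
                         sd = sdv, sem = sem,
                         cv = ifelse(mu > 0, sem / mu, NA_real_))
  structure(list(counts = df, stats = stats_df,
                 settings = list(replicates = replicates,
                                 replacement = replacement,
                                 q_threshold = q_threshold, scope = scope,
                                 sign = sign, seed = seed, n_samples = n,
                                 group = group)),
            class = "vnet_curve")
}

#' @export
print.vnet_curve <- function(x, ...) {
  s <- x$settings
  cat("<vnet_curve>", if (!is.null(s$group)) paste0(" [", s$group, "]"),
      " sizes ", min(x$stats$size), "-", max(x$stats$size), " (",
      nrow(x$stats), " sizes x ", s$replicates, " replicates, ",
      if (s$replacement) "with" else "without", " replacement), q < ",
      format(s$q_threshold), ", scope=", s$scope, ", sign=", s$sign, "\n", sep = "")
  print(x$stats, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.vnet_curve <- function(x, fit = NULL, add = FALSE, col = "forestgreen", ...) {
  st <- x$stats
  if (!add) {
    plot(st$size, st$mean, type = "n", xlab = "subsample size (samples)",
         ylab = sprintf("edges with q < %g", x$settings$q_threshold), ...)
  }
  graphics::arrows(st$size, st$mean - st$sem, st$size, st$mean + st$sem,
                   angle = 90, code = 3, length = 0.03, col = col)
  graphics::points(st$size, st$mean, pch = 19, col = col)
  if (!is.null(fit)) graphics::abline(stats::coef(fit), col = col, lty = 2)
  invisible(x)
}

#' Fit the network growth line and read off the growth rate
#'
#' Ordinary least squares of significant-edge count on subsample size,
#' `y = m x + b`. The slope `m` (edges gained per added sample) is the
#' network growth rate. By default the line is fitted through all raw
#' replicate points; `fit_on = "size_means"` fits through the per-size mean
#' counts, which yields an identical slope under balanced replicates but a
#' differently scaled standard error (the label travels with the object).
#'
#' @param curve A `vnet_curve`.
#' @param fit_on `"raw_points"` (default) or `"size_means"`.
#' @return Object of class `vnet_fit` supporting `coef()`, `predict()`,
#'   `residuals()`, `summary()`, `plot()` and `print()`. `coef()` returns
#'   `(intercept, slope)`; the slope is the growth rate.
#' @export
fit_vnet <- function(curve, fit_on = c("raw_points", "size_means")) {
  stopifnot(inherits(curve, "vnet_curve"))
  fit_on <- match.arg(fit_on)
  if (length(unique(curve$counts$size)) < 2)
    stop("at least 2 distinct subset sizes are required to fit a line")
  dat <- if (fit_on == "raw_points") {
    data.frame(size = curve$counts$size, count = curve$counts$count)
  } else {
    data.frame(size = curve$stats$size, count = curve$stats$mean)
  }
  lmfit <- stats::lm(count ~ size, data = dat)
  # exact fits (e.g. constant counts) are legitimate here; silence the
  # "essentially perfect fit" note
  sm <- suppressWarnings(summary(lmfit))
  ct <- sm$coefficients
  structure(list(slope = unname(ct["size", "Estimate"]),
                 intercept = unname(ct["(Intercept)", "Estimate"]),
                 slope_se = unname(ct["size", "Std. Error"]),
                 intercept_se = unname(ct["(Intercept)", "Std. Error"]),
                 r_squared = sm$r.squared,
                 n_points = nrow(dat), fit_on = fit_on,
                 lm = lmfit, settings = curve$settings),
            class = "vnet_fit")
}

#' @export
coef.vnet_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.vnet_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$lm))
  if (is.numeric(newdata)) newdata <- data.frame(size = newdata)
  stats::predict(object$lm, newdata = newdata)
}

#' @export
residuals.vnet_fit <- function(object, ...) stats::residuals(object$lm)

#' @export
print.vnet_fit <- function(x, ...) {
  cat("<vnet_fit> growth rate = ", sprintf("%.4g", x$slope), " +/- ",
      sprintf("%.2g", x$slope_se), " edges/sample (intercept ",
      sprintf("%.4g", x$intercept), ", r^2 = ", sprintf("%.3f", x$r_squared),
      ", fit on ", x$fit_on, ", ", x$n_points, " points)\n", sep = "")
  invisible(x)
}

#' @export
plot.vnet_fit <- function(x, col = "forestgreen", ...) {
  dat <- x$lm$model
  plot(dat$size, dat$count, pch = 19, col = col,
       xlab = "subsample size (samples)", ylab = "significant edges", ...)
  graphics::abline(x$intercept, x$slope, col = col, lty = 2)
  invisible(x)
}

#' @export
summary.vnet_fit <- function(object, ...) {
  print(object)
  cat("settings: q < ", format(object$settings$q_threshold), ", scope=",
      object$settings$scope, ", sign=", object$settings$sign, ", ",
      object$settings$replicates, " replicates ",
      if (object$settings$replacement) "with" else "without",
      " replacement\n", sep = "")
  invisible(object)
}

#' Test the difference between two network growth rates
#'
#' Pools the replicate points of two growth curves and fits
#' `count ~ size * group`; the group-by-size interaction is the slope
#' difference, reported with its standard error and t-test p-value (method
#' tag `"interaction-ols"`). Curves must have been computed with the same
#' q-threshold, scope and sign settings. When both curves are identical the
#' difference is 0 and the p-value 1; a residual-free degenerate fit reports
#' p = 1 for a zero difference and the smallest positive double otherwise.
#'
#' @param curveA,curveB `vnet_curve` objects.
#' @param fit_on `"raw_points"` (default) or `"size_means"`.
#' @return Object of class `vnet_comparison` with the two slopes, their
#'   difference (A - B), standard error, t statistic and p-value.
#' @export
compare_vnet <- function(curveA, curveB, fit_on = c("raw_points", "size_means")) {
  stopifnot(inherits(curveA, "vnet_curve"), inherits(curveB, "vnet_curve"))
  fit_on <- match.arg(fit_on)
  for (key in c("q_threshold", "scope", "sign")) {
    if (!identical(curveA$settings[[key]], curveB$settings[[key]]))
      stop("curves differ in setting '", key, "'; refusing to compare")
  }
  pick <- function(cv) if (fit_on == "raw_points") {
    data.frame(size = cv$counts$size, count = cv$counts$count)
  } else {
    data.frame(size = cv$stats$size, count = cv$stats$mean)
  }
  da <- pick(curveA); db <- pick(curveB)
  dat <- rbind(cbind(da, grp = 0), cbind(db, grp = 1))
  lmfit <- stats::lm(count ~ size * grp, data = dat)
  ct <- suppressWarnings(summary(lmfit))$coefficients
  slope_a <- unname(ct["size", "Estimate"])
  diff_ba <- if ("size:grp" %in% rownames(ct)) unname(ct["size:grp", "Estimate"]) else 0
  se <- if ("size:grp" %in% rownames(ct)) unname(ct["size:grp", "Std. Error"]) else NaN
  tval <- if ("size:grp" %in% rownames(ct)) unname(ct["size:grp", "t value"]) else NaN
  pval <- if ("size:grp" %in% rownames(ct)) unname(ct["size:grp", "Pr(>|t|)"]) else NaN
  if (!is.finite(pval)) {
    pval <- if (abs(diff_ba) < 1e-12) 1 else .Machine$double.xmin
  }
  pval <- min(max(pval, .Machine$double.xmin), 1)
  structure(list(slope_a = slope_a, slope_b = slope_a + diff_ba,
                 slope_diff = -diff_ba,   # A - B
                 se = se, statistic = tval, p_value = pval,
                 method = "interaction-ols", fit_on = fit_on,
                 n_points = nrow(dat)),
            class = "vnet_comparison")
}

#' @export
print.vnet_comparison <- function(x, ...) {
  cat("<vnet_comparison> slope A = ", sprintf("%.4g", x$slope_a),
      ", slope B = ", sprintf("%.4g", x$slope_b),
      ", diff (A-B) = ", sprintf("%.4g", x$slope_diff),
      " +/- ", sprintf("%.2g", x$se),
      ", p = ", format(x$p_value, digits = 3),
      " (", x$method, ", ", x$fit_on, ")\n", sep = "")
  invisible(x)
}

#' Write a growth curve as TSV plus a JSON settings sidecar
#'
#' @param curve A `vnet_curve`.
#' @param path Output TSV path (`size, replicate, count`); the sidecar is
#'   written next to it with extension `.json`.
#' @return `path`, invisibly.
#' @export
write_vnet_curve <- function(curve, path) {
  stopifnot(inherits(curve, "vnet_curve"))
  utils::write.table(curve$counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- sub("\\.[^.]+$", "", path)
  jsonlite::write_json(list(settings = curve$settings, per_size = curve$stats),
                       paste0(sidecar, ".json"), auto_unbox = TRUE, digits = 10)
  invisible(path)
}
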