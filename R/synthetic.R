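#' Configure a synthetic metabolomics cohort
#'
#' The generator uses a latent pathway-factor model. Each pathway j has a
#' standard-normal factor f_j per sample; metabolite i of pathway j is
#' `x_i = sqrt(rho_within) f_j + sum_k l_ik f_k + sqrt(resid_i) e_i` with
#' independent standard-normal noise e_i and residual variance chosen so
#' every metabolite has unit variance. Cross-pathway hub links add a signed
#' loading `sign * sqrt(strength)` of one metabolite onto a foreign
#' pathway's factor, creating signed spokes to every metabolite of that
#' pathway. Case samples are shifted by `mean_shift` (in SD = z units) and
#' may use a different within-pathway correlation, giving group differences
#' in both means and network density. Abundances are
#' `AUC = 2^(log2_mean + log2_sd * x)`, strictly positive log-normal values,
#' and population correlations follow in closed form from the loading
#' vectors.
#'
#' @param n_case,n_control Group sizes.
#' @param pathways Named integer vector: pathway name -> metabolite count.
#'   Default: 50 pathways of 9 metabolites (about the scale of a broad
#'   targeted metabolomics panel).
#' @param rho_within Within-pathway correlation in `[0, 1)`; a single value
#'   or `c(control = , case = )`.
#' @param hub_links `NULL` or a data frame with columns `metabolite`,
#'   `target_pathway`, `sign` (`"+"`/`"-"`), `strength` in `[0, 1)`, and
#'   optionally `group` (`"both"` default, `"case"`, or `"control"`).
#' @param mean_shift Case-minus-control shift in z units; scalar or named
#'   per-metabolite vector.
#' @param log2_mean,log2_sd Base-2 log abundance location and scale; scalar
#'   or per-metabolite.
#' @param seed Integer seed stored in the config; generation is
#'   deterministic given the config.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_case = 20, n_control = 20,
                             pathways = NULL,
                             rho_within = 0.3, hub_links = NULL,
                             mean_shift = 0, log2_mean = 20, log2_sd = 1,
                             seed = 1) {
  if (is.null(pathways)) {
    pathways <- stats::setNames(rep(9L, 50), sprintf("pw%02d", 1:50))
  }
  stopifnot(!is.null(names(pathways)), all(pathways >= 1))
  if (length(rho_within) == 1) rho_within <- c(control = rho_within, case = rho_within)
  if (is.null(names(rho_within))) names(rho_within) <- c("control", "case")
  stopifnot(all(rho_within >= 0 & rho_within < 1))
  mets <- unlist(lapply(names(pathways), function(p)
    sprintf("%s_m%02d", p, seq_len(pathways[[p]]))), use.names = FALSE)
  pw_of <- rep(names(pathways), times = as.integer(pathways))
  names(pw_of) <- mets

  if (!is.null(hub_links)) {
    hub_links <- as.data.frame(hub_links)
    need <- c("metabolite", "target_pathway", "sign", "strength")
    if (!all(need %in% names(hub_links)))
      stop("hub_links needs columns: ", paste(need, collapse = ", "))
    if (is.null(hub_links$group)) hub_links$group <- "both"
    stopifnot(all(hub_links$metabolite %in% mets),
              all(hub_links$target_pathway %in% names(pathways)),
              all(hub_links$sign %in% c("+", "-")),
              all(hub_links$strength >= 0 & hub_links$strength < 1),
              all(hub_links$group %in% c("both", "case", "control")))
    own <- pw_of[hub_links$metabolite]
    if (any(own == hub_links$target_pathway))
      stop("hub_links may only target foreign pathways")
  }
  cfg <- structure(list(n_case = n_case, n_control = n_control,
                        pathways = pathways, metabolites = mets,
                        pathway_of = pw_of, rho_within = rho_within,
                        hub_links = hub_links, mean_shift = mean_shift,
                        log2_mean = log2_mean, log2_sd = log2_sd, seed = seed),
                   class = "synthetic_config")
  for (g in c("control", "case")) .loading_matrix(cfg, g)  # PSD validation
  cfg
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config> ", length(x$metabolites), " metabolites in ",
      length(x$pathways), " pathways; n = ", x$n_control, " control + ",
      x$n_case, " case; rho_within = ",
      paste(sprintf("%s %.2f", names(x$rho_within), x$rho_within), collapse = ", "),
      "; ", if (is.null(x$hub_links)) "no" else nrow(x$hub_links),
      " hub links\n", sep = "")
  invisible(x)
}

# Loading matrix (metabolites x pathway factors) for one group; errors if
# any metabolite's total loading leaves no residual variance (the implied
# covariance would not be positive definite).
.loading_matrix <- function(cfg, group) {
  M <- length(cfg$metabolites)
  K <- length(cfg$pathways)
  L <- matrix(0, M, K, dimnames = list(cfg$metabolites, names(cfg$pathways)))
  rho <- cfg$rho_within[[group]]
  L[cbind(seq_len(M), match(cfg$pathway_of, names(cfg$pathways)))] <- sqrt(rho)
  hl <- cfg$hub_links
  if (!is.null(hl)) {
    hl <- hl[hl$group %in% c("both", group), , drop = FALSE]
    for (i in seq_len(nrow(hl))) {
      L[hl$metabolite[i], hl$target_pathway[i]] <-
        L[hl$metabolite[i], hl$target_pathway[i]] +
        ifelse(hl$sign[i] == "+", 1, -1) * sqrt(hl$strength[i])
    }
  }
  tot <- rowSums(L * L)
  if (any(tot >= 1)) {
    bad <- cfg$metabolites[tot >= 1]
    stop("implied covariance is not positive definite: total loading >= 1 for ",
         paste(utils::head(bad, 5), collapse = ", "),
         "; reduce rho_within or hub_link strengths")
  }
  L
}

#' Generate a synthetic cohort with known network structure
#'
#' Draws the latent-factor model declared in a [synthetic_config()] and
#' returns a drop-in [sample_table()], the matching [pathway_map()], and the
#' analytic ground-truth edge set. Identical configs (including seed)
#' produce bit-identical tables.
#'
#' @param cfg A `synthetic_config`.
#' @return List with elements `table` (a `sample_table`), `pmap` (a
#'   `pathway_map`), and `truth` (a `truth_network`, see [truth_edges()]).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  M <- length(cfg$metabolites)
  if (length(cfg$mean_shift) == 1) {
    shift <- stats::setNames(rep(cfg$mean_shift, M), cfg$metabolites)
  } else {
    shift <- stats::setNames(rep(0, M), cfg$metabolites)
    shift[names(cfg$mean_shift)] <- cfg$mean_shift
  }
  l2m <- rep(cfg$log2_mean, length.out = M)
  l2s <- rep(cfg$log2_sd, length.out = M)

  set.seed(cfg$seed %% 2147483647)
  draw <- function(n, group) {
    if (n == 0) return(NULL)
    L <- .loading_matrix(cfg, group)
    resid <- sqrt(1 - rowSums(L * L))
    Fm <- matrix(stats::rnorm(n * ncol(L)), n, ncol(L))
    E <- matrix(stats::rnorm(n * M), n, M)
    X <- Fm %*% t(L) + E * rep(resid, each = n)
    if (group == "case") X <- X + rep(shift, each = n)
    X
  }
  Xc <- draw(cfg$n_control, "control")
  Xa <- draw(cfg$n_case, "case")
  X <- rbind(Xc, Xa)
  ids <- c(if (cfg$n_control) sprintf("ctrl_%03d", seq_len(cfg$n_control)),
           if (cfg$n_case) sprintf("case_%03d", seq_len(cfg$n_case)))
  rownames(X) <- ids
  colnames(X) <- cfg$metabolites
  auc <- 2^(rep(l2m, each = nrow(X)) + rep(l2s, each = nrow(X)) * X)
  dimnames(auc) <- dimnames(X)
  meta <- data.frame(sample_id = ids,
                     group = c(rep("control", cfg$n_control),
                               rep("case", cfg$n_case)),
                     sex = "M", cohort = "synthetic",
                     stringsAsFactors = FALSE)
  pmap <- suppressMessages(pathway_map(cfg$metabolites, unname(cfg$pathway_of)))
  list(table = sample_table(auc, meta), pmap = pmap,
       truth = truth_edges(cfg))
}

#' Ground-truth population edges implied by a synthetic config
#'
#' The population correlation of two metabolites is the inner product of
#' their factor-loading vectors (all metabolites have unit variance by
#' construction). Pairs with a nonzero population correlation are listed
#' with their sign; with no hub links these are exactly the within-pathway
#' pairs.
#'
#' @param cfg A `synthetic_config`.
#' @param group `"control"` (default) or `"case"`.
#' @return Data frame of class `truth_network` with columns
#'   `met_a, met_b, r_pop, sign, scope`.
#' @export
truth_edges <- function(cfg, group = "control") {
  stopifnot(inherits(cfg, "synthetic_config"))
  group <- match.arg(group, c("control", "case"))
  L <- .loading_matrix(cfg, group)
  R <- L %*% t(L)
  pinfo <- .pair_info(nrow(R), rownames(R))
  rv <- R[pinfo$ut]
  nz <- which(abs(rv) > 1e-12)
  pw <- cfg$pathway_of
  out <- data.frame(met_a = cfg$metabolites[pinfo$row[nz]],
                    met_b = cfg$metabolites[pinfo$col[nz]],
                    r_pop = rv[nz],
                    sign = ifelse(rv[nz] > 0, "+", "-"),
                    stringsAsFactors = FALSE)
  out$scope <- ifelse(pw[out$met_a] == pw[out$met_b], "in", "out")
  rownames(out) <- NULL
  class(out) <- c("truth_network", "data.frame")
  attr(out, "group") <- group
  out
}

#' Dense-vs-sparse recovery experiment
#'
#' End-to-end power check of the pipeline against planted truth. For each
#' seed, two cohorts are generated (control arms of `cfg_dense` and
#' `cfg_sparse`, which should differ only in declared parameters) and three
#' recoveries are scored: (1) the network growth rate of the dense cohort
#' exceeds that of the sparse cohort; (2) when `hub_pathway` is given, the
#' +r/-r ratio of that hub in the dense network, compared with the ratio
#' implied by the dense config's truth edges; (3) metabolites carrying hub
#' links present only in the dense config are recovered among the top-k
#' hypercorrelators of dense-vs-sparse.
#'
#' @param cfg_dense,cfg_sparse `synthetic_config` objects over the same
#'   metabolite universe.
#' @param n_seeds Number of independent repetitions (default 20).
#' @param replicates,q_threshold,scope,sign Passed to
#'   [resample_edge_counts()] (scope defaults to `"both"` here: with purely
#'   within-pathway structure the growth signal lives in in-pathway edges).
#' @param hub_pathway Optional pathway for the ratio recovery.
#' @param k Hypercorrelator list size (default 15).
#' @param seed Master seed; per-repetition seeds are derived from it.
#' @return Object of class `recovery_report`: per-seed table plus summary
#'   fractions.
#' @export
recovery_experiment <- function(cfg_dense, cfg_sparse, n_seeds = 20,
                                replicates = 50, q_threshold = 0.05,
                                scope = "both", sign = "both",
                                hub_pathway = NULL, k = 15, seed = 1) {
  stopifnot(inherits(cfg_dense, "synthetic_config"),
            inherits(cfg_sparse, "synthetic_config"))
  if (!identical(cfg_dense$metabolites, cfg_sparse$metabolites))
    stop("configs must share the same metabolite universe")
  planted <- setdiff(
    if (is.null(cfg_dense$hub_links)) character(0) else unique(cfg_dense$hub_links$metabolite),
    if (is.null(cfg_sparse$hub_links)) character(0) else unique(cfg_sparse$hub_links$metabolite))

  truth_ratio <- NA_real_
  if (!is.null(hub_pathway)) {
    tr <- truth_edges(cfg_dense)
    pw <- cfg_dense$pathway_of
    hub_mask <- pw[tr$met_a] == hub_pathway | pw[tr$met_b] == hub_pathway
    truth_ratio <- sum(tr$sign[hub_mask] == "+") / sum(tr$sign[hub_mask] == "-")
  }

  res <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    cfg_d <- cfg_dense; cfg_d$seed <- .substream_seed(seed, 1L, s)
    cfg_s <- cfg_sparse; cfg_s$seed <- .substream_seed(seed, 2L, s)
    coh_d <- generate_cohort(cfg_d)
    coh_s <- generate_cohort(cfg_s)
    zd <- subset_samples(zscore_transform(coh_d$table), group = "control")
    zs <- subset_samples(zscore_transform(coh_s$table), group = "control")
    sizes <- ramp_sizes(min(nrow(zd$z), nrow(zs$z)))
    cv_d <- resample_edge_counts(zd, coh_d$pmap, sizes = sizes,
                                 replicates = replicates,
                                 q_threshold = q_threshold, scope = scope,
                                 sign = sign, seed = .substream_seed(seed, 3L, s))
    cv_s <- resample_edge_counts(zs, coh_s$pmap, sizes = sizes,
                                 replicates = replicates,
                                 q_threshold = q_threshold, scope = scope,
                                 sign = sign, seed = .substream_seed(seed, 4L, s))
    v_d <- fit_vnet(cv_d)$slope
    v_s <- fit_vnet(cv_s)$slope

    net_d <- build_network(adjust_pvalues(pairwise_correlations(zd)),
                           coh_d$pmap, q_threshold = q_threshold, group = "dense")
    ratio_d <- NA_real_
    if (!is.null(hub_pathway)) {
      hub <- extract_hub(net_d, hub_pathway)
      ratio_d <- if (hub$n_neg > 0) hub$n_pos / hub$n_neg else Inf
    }
    topk_hits <- NA_real_
    if (length(planted)) {
      net_s <- build_network(adjust_pvalues(pairwise_correlations(zs)),
                             coh_s$pmap, q_threshold = q_threshold, group = "sparse")
      rk <- rank_hypercorrelators(net_d, net_s, k = k)
      topk_hits <- mean(planted %in% rk$metabolite[rk$top_k])
    }
    res[[s]] <- data.frame(seed = s, vnet_dense = v_d, vnet_sparse = v_s,
                           hub_ratio = ratio_d, topk_recovery = topk_hits)
  }
  per_seed <- do.call(rbind, res)
  structure(list(per_seed = per_seed,
                 fraction_vnet_dense_gt_sparse = mean(per_seed$vnet_dense >
                                                      per_seed$vnet_sparse),
                 hub_ratio_truth = truth_ratio,
                 hub_ratio_median = stats::median(per_seed$hub_ratio),
                 topk_recovery_mean = mean(per_seed$topk_recovery),
                 planted = planted, hub_pathway = hub_pathway,
                 settings = list(n_seeds = n_seeds, replicates = replicates,
                                 q_threshold = q_threshold, scope = scope,
                                 sign = sign, k = k, seed = seed)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report> ", x$settings$n_seeds, " seeds\n",
      "  growth rate dense > sparse: ",
      sprintf("%.0f%%", 100 * x$fraction_vnet_dense_gt_sparse), "\n", sep = "")
  if (!is.null(x$hub_pathway)) {
    cat("  hub '", x$hub_pathway, "' +r/-r: median ",
        sprintf("%.3g", x$hub_ratio_median), " vs truth ",
        sprintf("%.3g", x$hub_ratio_truth), "\n", sep = "")
  }
  if (length(x$planted)) {
    cat("  planted hypercorrelators in top-", x$settings$k, ": ",
        sprintf("%.0f%%", 100 * x$topk_recovery_mean), "\n", sep = "")
  }
  invisible(x)
}

#' Write a synthetic cohort to the delimited formats the readers accept
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named list of the three file paths (`auc`, `metadata`,
#'   `pathways`), invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  auc_path <- file.path(dir, "auc.csv")
  meta_path <- file.path(dir, "metadata.csv")
  pw_path <- file.path(dir, "pathways.csv")
  auc <- data.frame(sample_id = rownames(cohort$table$auc),
                    cohort$table$auc, check.names = FALSE)
  utils::write.csv(auc, auc_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$table$meta, meta_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(metabolite_id = names(cohort$pmap),
                              pathway = as.character(cohort$pmap)),
                   pw_path, row.names = FALSE, quote = FALSE)
  invisible(list(auc = auc_path, metadata = meta_path, pathways = pw_path))
}
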