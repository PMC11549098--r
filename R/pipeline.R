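#' Read and validate a pipeline run configuration
#'
#' The config is a YAML file (or an equivalent named list) with either an
#' `input` block (`auc`, `metadata`, `pathways` file paths) or a `synthetic`
#' block (arguments for [synthetic_config()]), plus analysis settings:
#'
#' ```yaml
#' synthetic: {n_case: 20, n_control: 20, rho_within: [0.3, 0.5], seed: 7}
#' stratify_sex: false
#' q_network: 0.05      # global network threshold
#' q_hubs: 0.05         # hub analyses
#' q_vnet: 0.05         # growth-rate analyses
#' hub_pathways: [pw01]
#' hypercorrelator_k: 15
#' vnet: {replicates: 50, replacement: false, scope: out, sign: both}
#' seed: 1
#' output_dir: out
#' ```
#'
#' Validation (thresholds in (0, 1], hub pathways present, k within range)
#' happens before any computation.
#'
#' @param path Path to a YAML file.
#' @return A validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  validate_run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param config A named list with the fields above.
#' @export
validate_run_config <- function(config) {
  defaults <- list(stratify_sex = FALSE, q_network = 0.05, q_hubs = 0.05,
                   q_vnet = 0.05, hub_pathways = list(),
                   hypercorrelator_k = 15,
                   vnet = list(replicates = 50, replacement = FALSE,
                               scope = "out", sign = "both"),
                   seed = 1, output_dir = "mcorrnet_out")
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  for (nm in names(defaults$vnet)) {
    if (is.null(config$vnet[[nm]])) config$vnet[[nm]] <- defaults$vnet[[nm]]
  }
  if (is.null(config$input) == is.null(config$synthetic))
    stop("config needs exactly one of `input` or `synthetic`")
  for (qk in c("q_network", "q_hubs", "q_vnet")) {
    qv <- config[[qk]]
    if (!is.numeric(qv) || qv <= 0 || qv > 1)
      stop("`", qk, "` must lie in (0, 1]")
  }
  config$vnet$scope <- .match_arg_scope(config$vnet$scope)
  config$vnet$sign <- .match_arg_sign(config$vnet$sign)
  class(config) <- "run_config"
  config
}

#' Run the full analysis pipeline and write a report bundle
#'
#' Loads or generates the cohort, derives z-scores, and per group builds the
#' q-thresholded network, its summary, the requested pathway hubs with
#' +r/-r ratios, the case-vs-control hypercorrelator ranking, and the
#' growth curve and fitted growth rate on a shared size grid truncated to
#' `min(n_case, n_control) - 1` (so both groups are compared at equal
#' subsample sizes). The group comparison tests (edge-count permutation
#' test and growth-rate slope test) complete the bundle. All outputs are
#' plain text (TSV/JSON); given the same config the bundle is
#' byte-identical across runs.
#'
#' @param config A `run_config`, a bare named list, or a YAML file path.
#' @param out_dir Output directory; defaults to `config$output_dir`.
#' @return The summary list (also written as `summary.json`), invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  if (is.null(out_dir)) out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$synthetic)) {
    cfg <- do.call(synthetic_config, config$synthetic)
    cohort <- generate_cohort(cfg)
    tab <- cohort$table; pmap <- cohort$pmap
  } else {
    tab <- read_sample_table(config$input$auc, config$input$metadata)
    pmap <- read_pathway_map(config$input$pathways)
  }
  missing_pw <- setdiff(colnames(tab$auc), names(pmap))
  if (length(missing_pw))
    stop("pathway map does not cover: ", paste(utils::head(missing_pw, 5), collapse = ", "))
  bad_hubs <- setdiff(unlist(config$hub_pathways), unique(unname(pmap[colnames(tab$auc)])))
  if (length(bad_hubs))
    stop("unknown hub pathway(s): ", paste(bad_hubs, collapse = ", "))

  z <- zscore_transform(tab, by_sex = isTRUE(config$stratify_sex))
  groups <- intersect(c("control", "case"), unique(tab$meta$group))
  zg <- lapply(stats::setNames(groups, groups),
               function(g) subset_samples(z, group = g))

  settings_echo <- unclass(config)
  settings_echo$output_dir <- NULL  # echo analysis settings, not the destination
  summary_out <- list(settings = settings_echo, groups = list())
  nets <- list()
  for (g in groups) {
    tblg <- adjust_pvalues(pairwise_correlations(zg[[g]]))
    net <- build_network(tblg, pmap, q_threshold = config$q_network, group = g)
    nets[[g]] <- net
    export_edges(net, file.path(out_dir, paste0("edges_", g, ".tsv")), "tsv")
    sm <- summarize_network(net)
    hubs_out <- list()
    for (hp in unlist(config$hub_pathways)) {
      hub <- extract_hub(build_network(tblg, pmap, q_threshold = config$q_hubs,
                                       group = g), hp)
      rat <- suppressWarnings(plus_minus_ratio(hub, n_boot = 0))
      utils::write.table(hub$edges, file.path(out_dir, paste0("hub_", hp, "_", g, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      hubs_out[[hp]] <- list(n_edges = nrow(hub$edges), n_pos = hub$n_pos,
                             n_neg = hub$n_neg,
                             ratio = if (is.finite(rat$ratio)) rat$ratio else "Inf")
    }
    summary_out$groups[[g]] <- list(
      n_samples = nrow(zg[[g]]$z),
      n_edges = nrow(net$edges),
      edge_counts = list(pos_in = unname(sm$counts["+", "in"]),
                         pos_out = unname(sm$counts["+", "out"]),
                         neg_in = unname(sm$counts["-", "in"]),
                         neg_out = unname(sm$counts["-", "out"])),
      pi0 = net$pi0, hubs = hubs_out)
  }

  if (length(groups) == 2) {
    sizes <- ramp_sizes(min(vapply(zg, function(x) nrow(x$z), 0)))
    fits <- list()
    curves <- list()
    for (g in groups) {
      cv <- resample_edge_counts(zg[[g]], pmap, sizes = sizes,
                                 replicates = config$vnet$replicates,
                                 q_threshold = config$q_vnet,
                                 scope = config$vnet$scope,
                                 sign = config$vnet$sign,
                                 replacement = isTRUE(config$vnet$replacement),
                                 seed = .substream_seed(config$seed, match(g, groups), 0L),
                                 group = g)
      write_vnet_curve(cv, file.path(out_dir, paste0("vnet_curve_", g, ".tsv")))
      fit <- fit_vnet(cv)
      curves[[g]] <- cv
      fits[[g]] <- list(slope = fit$slope, slope_se = fit$slope_se,
                        intercept = fit$intercept, r_squared = fit$r_squared)
    }
    vc <- compare_vnet(curves[[1]], curves[[2]])
    nc <- compare_networks(zg[[1]], zg[[2]], q_threshold = config$q_network,
                           n_perm = 200, seed = config$seed)
    rk <- if ("case" %in% groups) {
      rank_hypercorrelators(nets[["case"]], nets[["control"]],
                            k = config$hypercorrelator_k)
    } else NULL
    if (!is.null(rk)) {
      utils::write.table(rk, file.path(out_dir, "hypercorrelators.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    summary_out$vnet <- fits
    summary_out$vnet_comparison <- list(slope_diff = vc$slope_diff, se = vc$se,
                                        p_value = vc$p_value, method = vc$method)
    summary_out$network_comparison <- list(
      diff = as.list(nc$diff), p_value = as.list(nc$p_value), n_perm = nc$n_perm)
  }

  jsonlite::write_json(summary_out, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(summary_out)
}
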