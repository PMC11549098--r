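#' Recompute the published cohort network statistics from supplementary data
#'
#' Applies the male-only network recipes to the study's own metabolomics
#' tables when a local copy of the journal supplementary data is available
#' (the tables are distributed as journal supplementary files only and are
#' not bundled here). Expected layout under `data_dir`: one subdirectory per
#' cohort (`newborn`, `fiveyr`), each holding `auc.csv` (samples x
#' metabolites AUC), `metadata.csv` (`sample_id, group, sex, cohort`), and
#' `pathways.csv` (`metabolite_id, pathway`).
#'
#' Per cohort the function z-scores log2 AUCs against the male controls,
#' builds the male case and control networks at the figure-specific
#' thresholds (positive networks at q < 1e-5 for newborns and q < 0.01 for
#' 5-year-olds; negative networks at q < 0.01 and q < 0.05), counts their
#' edges, extracts the requested pathway hubs at q < 0.05 with their +r/-r
#' ratios, and estimates the positive out-of-pathway network growth rate.
#'
#' @param data_dir Directory containing the cohort subdirectories.
#' @param hub_pathways Pathway names to profile (default purine, ceramide,
#'   phosphatidylinositol-lipid labels as used in the annotation files).
#' @param replicates,seed Growth-curve resampling settings.
#' @return Nested list of edge counts, hub counts/ratios and growth rates,
#'   by cohort and group.
#' @export
reproduce_reported_statistics <- function(data_dir,
                                          hub_pathways = c("Purines", "Ceramides",
                                                           "PI lipids"),
                                          replicates = 50, seed = 1) {
  cohorts <- c("newborn", "fiveyr")
  missing_dirs <- cohorts[!dir.exists(file.path(data_dir, cohorts))]
  if (length(missing_dirs)) {
    stop("supplementary data not found under '", data_dir, "' (missing: ",
         paste(missing_dirs, collapse = ", "),
         "); place the journal supplementary AUC tables there as documented")
  }
  pos_q <- c(newborn = 1e-5, fiveyr = 0.01)
  neg_q <- c(newborn = 0.01, fiveyr = 0.05)
  out <- list()
  for (co in cohorts) {
    d <- file.path(data_dir, co)
    tab <- read_sample_table(file.path(d, "auc.csv"), file.path(d, "metadata.csv"))
    pmap <- read_pathway_map(file.path(d, "pathways.csv"))
    z <- zscore_transform(tab)
    zg <- list(control = subset_samples(z, group = "control", sex = "M"),
               case = subset_samples(z, group = "case", sex = "M"))
    res <- list()
    for (g in names(zg)) {
      tbl <- adjust_pvalues(pairwise_correlations(zg[[g]]))
      net05 <- build_network(tbl, pmap, q_threshold = 0.05, group = g)
      res[[g]] <- list(
        pos_edges = nrow(build_network(tbl, pmap, q_threshold = pos_q[[co]],
                                       sign = "+")$edges),
        neg_edges = nrow(build_network(tbl, pmap, q_threshold = neg_q[[co]],
                                       sign = "-")$edges),
        edges_q05 = nrow(net05$edges),
        hubs = lapply(stats::setNames(intersect(hub_pathways, unclass(pmap)),
                                      intersect(hub_pathways, unclass(pmap))),
                      function(hp) {
                        hub <- extract_hub(net05, hp)
                        list(n_edges = nrow(hub$edges), n_pos = hub$n_pos,
                             n_neg = hub$n_neg,
                             ratio = if (hub$n_neg) hub$n_pos / hub$n_neg else Inf)
                      }),
        vnet_pos_out = fit_vnet(resample_edge_counts(
          zg[[g]], pmap, replicates = replicates, q_threshold = 0.05,
          scope = "out", sign = "+", seed = seed, group = g))$slope)
    }
    out[[co]] <- res
  }
  out
}
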