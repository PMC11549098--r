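#' Extract a pathway hub-and-spoke subnetwork
#'
#' The hub of a pathway is the set of all network edges touching at least
#' one metabolite of that pathway. Edges with both endpoints in the pathway
#' are the hub's in-pathway core; edges with one endpoint outside are its
#' spokes, tallied by partner pathway.
#'
#' @param net A `metab_network` built with both signs and both scopes.
#' @param pathway Pathway name; must exist in the network's pathway map.
#' @return Object of class `hub_result` with the hub nodes, edge table (with
#'   a `hub_part` column, `"core"` or `"spoke"`), sign counts, and the
#'   partner-pathway tally. A pathway with no metabolites in the network
#'   yields an empty result with a warning.
#' @export
extract_hub <- function(net, pathway) {
  stopifnot(inherits(net, "metab_network"))
  pw <- structure(net$nodes$pathway, names = net$nodes$metabolite)
  if (!pathway %in% net$nodes$pathway)
    stop("pathway '", pathway, "' not present in the network's pathway map")
  hub_nodes <- net$nodes$metabolite[net$nodes$pathway == pathway]
  e <- net$edges
  in_a <- e$met_a %in% hub_nodes
  in_b <- e$met_b %in% hub_nodes
  he <- e[in_a | in_b, , drop = FALSE]
  if (!nrow(he)) warning("pathway '", pathway, "' has no edges in this network")
  he$hub_part <- ifelse((he$met_a %in% hub_nodes) & (he$met_b %in% hub_nodes),
                        "core", "spoke")
  rownames(he) <- NULL
  spokes <- he[he$hub_part == "spoke", , drop = FALSE]
  partner <- ifelse(spokes$met_a %in% hub_nodes, spokes$met_b, spokes$met_a)
  partner_pw <- unname(pw[partner])
  tally <- if (nrow(spokes)) {
    tb <- table(pathway = partner_pw, sign = factor(spokes$sign, c("+", "-")))
    data.frame(partner_pathway = rep(rownames(tb), 2),
               sign = rep(colnames(tb), each = nrow(tb)),
               n_edges = as.integer(tb), stringsAsFactors = FALSE)
  } else {
    data.frame(partner_pathway = character(0), sign = character(0),
               n_edges = integer(0))
  }
  tally <- tally[tally$n_edges > 0 | rep(nrow(tally) == 0, nrow(tally)), , drop = FALSE]
  rownames(tally) <- NULL
  structure(list(pathway = pathway,
                 nodes = intersect(hub_nodes,
                                   net$nodes$metabolite[net$nodes$degree > 0]),
                 all_pathway_metabolites = hub_nodes,
                 edges = he,
                 n_pos = sum(he$sign == "+"), n_neg = sum(he$sign == "-"),
                 partner_tally = tally,
                 q_threshold = net$q_threshold, group = net$group,
                 sign_filter = net$sign_filter, scope_filter = net$scope_filter,
                 pmap = net$pmap),
            class = "hub_result")
}

#' @export
print.hub_result <- function(x, ...) {
  cat("<hub_result> '", x$pathway, "'", if (!is.null(x$group)) paste0(" [", x$group, "]"),
      ": ", nrow(x$edges), " hub edges (", sum(x$edges$hub_part == "core"),
      " in-pathway, ", sum(x$edges$hub_part == "spoke"), " spokes), +", x$n_pos,
      " / -", x$n_neg, "\n", sep = "")
  invisible(x)
}

#' Spoke tally of a hub by partner pathway and edge sign
#'
#' @param hub A `hub_result`.
#' @return Data frame `(partner_pathway, sign, n_edges)` with an attribute
#'   `n_partner_pathways`, the number of distinct partner pathways.
#' @export
hub_partner_tally <- function(hub) {
  stopifnot(inherits(hub, "hub_result"))
  out <- hub$partner_tally
  attr(out, "n_partner_pathways") <- length(unique(out$partner_pathway))
  out
}

#' Positive-to-negative edge ratio of a hub, with bootstrap uncertainty
#'
#' The +r/-r ratio is the count of positive hub edges divided by the count
#' of negative hub edges -- a measure of the net stimulatory vs inhibitory
#' correlation balance of a pathway. The point estimate comes from the
#' full-sample hub; the standard error, when requested, is the SD of the
#' ratio over bootstrap resamples of the samples (rows resampled with
#' replacement, correlations, q-values, network and hub recomputed per
#' replicate).
#'
#' @param hub A `hub_result` from a network built with `sign = "both"` and
#'   `scope = "both"`.
#' @param z The `zmatrix` the network was built from (same sample set);
#'   required when `n_boot > 0`.
#' @param n_boot Bootstrap replicates (default 200; 0 skips the bootstrap).
#' @param seed Integer seed for the bootstrap.
#' @return Object of class `ratio_estimate` with `ratio`, `se`, the edge
#'   counts, and the bootstrap draws. A hub with zero negative edges yields
#'   `ratio = Inf` with `se = NA` and a warning.
#' @export
plus_minus_ratio <- function(hub, z = NULL, n_boot = 200, seed = 1) {
  stopifnot(inherits(hub, "hub_result"))
  if (hub$sign_filter != "both" || hub$scope_filter != "both")
    stop("the ratio needs a hub from an unfiltered (both signs, both scopes) network")
  if (hub$n_neg == 0) {
    warning("hub has zero negative edges; ratio is infinite, se undefined")
    return(structure(list(ratio = Inf, se = NA_real_, n_pos = hub$n_pos,
                          n_neg = 0L, n_boot = 0L, seed = seed,
                          boot = numeric(0), pathway = hub$pathway),
                     class = "ratio_estimate"))
  }
  ratio <- hub$n_pos / hub$n_neg
  se <- NA_real_
  boot <- numeric(0)
  if (n_boot > 0) {
    if (is.null(z)) stop("`z` is required for the bootstrap")
    zm <- if (inherits(z, "zmatrix")) z$z else as.matrix(z)
    pinfo <- .pair_info(ncol(zm), colnames(zm))
    pw <- .pathway_of(colnames(zm), hub$pmap)
    hub_col <- pw == hub$pathway
    touches <- hub_col[pinfo$row] | hub_col[pinfo$col]
    n <- nrow(zm)
    boot <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      set.seed(.substream_seed(seed, 1L, b))
      rows <- sample.int(n, n, replace = TRUE)
      cu <- .corr_upper(zm[rows, , drop = FALSE], pinfo)
      sig <- .sig_pairs(cu$r, n, pinfo, hub$q_threshold)
      idx <- sig$idx[touches[sig$idx]]
      np <- sum(cu$r[idx] > 0)
      nn <- length(idx) - np
      boot[b] <- if (nn > 0) np / nn else NA_real_
    }
    ok <- is.finite(boot)
    if (sum(ok) < n_boot / 2)
      warning("more than half of the bootstrap replicates had no negative hub edges")
    se <- stats::sd(boot[ok])
  }
  structure(list(ratio = ratio, se = se, n_pos = hub$n_pos, n_neg = hub$n_neg,
                 n_boot = n_boot, seed = seed, boot = boot,
                 pathway = hub$pathway),
            class = "ratio_estimate")
}

#' @export
print.ratio_estimate <- function(x, ...) {
  cat("<ratio_estimate> '", x$pathway, "': +r/-r = ",
      if (is.finite(x$ratio)) sprintf("%.3g", x$ratio) else "Inf",
      if (is.finite(x$se)) sprintf(" +/- %.2g (bootstrap, %d reps)", x$se, x$n_boot),
      "  [+", x$n_pos, " / -", x$n_neg, "]\n", sep = "")
  invisible(x)
}

#' Ratio of two +r/-r ratios with delta-method uncertainty
#'
#' Fold change between two ratio estimates (e.g., the developmental reversal
#' of a pathway hub between two ages), with a first-order propagated
#' standard error when both inputs carry one.
#'
#' @param a,b `ratio_estimate` objects, or bare numbers.
#' @param se_a,se_b Optional standard errors when `a`/`b` are numbers.
#' @return List with `fold` (= a / b) and `se`.
#' @export
ratio_fold_change <- function(a, b, se_a = NULL, se_b = NULL) {
  va <- if (inherits(a, "ratio_estimate")) a$ratio else a
  vb <- if (inherits(b, "ratio_estimate")) b$ratio else b
  sa <- if (inherits(a, "ratio_estimate")) a$se else se_a
  sb <- if (inherits(b, "ratio_estimate")) b$se else se_b
  fold <- va / vb
  se <- if (!is.null(sa) && !is.null(sb) && is.finite(sa) && is.finite(sb)) {
    abs(fold) * sqrt((sa / va)^2 + (sb / vb)^2)
  } else NA_real_
  list(fold = fold, se = se)
}

#' Rank hypercorrelator metabolites between two networks
#'
#' A hypercorrelator is a metabolite whose out-of-pathway connectivity is
#' most increased in network A relative to network B. Every metabolite of
#' the shared node universe is ranked by the difference (A - B) in its
#' out-of-pathway significant-edge count, descending, with a deterministic
#' alphabetical tie-break; the first `k` are flagged.
#'
#' @param netA,netB `metab_network` objects over the same node universe.
#' @param k Size of the leading set (default 15).
#' @param include_in_pathway Count in-pathway edges too (sensitivity option;
#'   default counts out-of-pathway edges only).
#' @return Data frame of class `hypercorrelator_ranking` with columns
#'   `metabolite, pathway, edges_a, edges_b, diff, rank, top_k`.
#' @export
rank_hypercorrelators <- function(netA, netB, k = 15, include_in_pathway = FALSE) {
  stopifnot(inherits(netA, "metab_network"), inherits(netB, "metab_network"))
  if (!setequal(netA$nodes$metabolite, netB$nodes$metabolite))
    stop("networks must share the same node universe")
  mets <- sort(netA$nodes$metabolite)
  if (k > length(mets)) stop("`k` exceeds the number of metabolites")
  deg <- function(net) {
    e <- net$edges
    if (!include_in_pathway) e <- e[e$scope == "out", , drop = FALSE]
    tb <- table(factor(c(e$met_a, e$met_b), levels = mets))
    as.integer(tb)
  }
  da <- deg(netA); db <- deg(netB)
  pw <- structure(netA$nodes$pathway, names = netA$nodes$metabolite)
  out <- data.frame(metabolite = mets, pathway = unname(pw[mets]),
                    edges_a = da, edges_b = db, diff = da - db,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$diff, out$metabolite), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$top_k <- out$rank <= k
  rownames(out) <- NULL
  class(out) <- c("hypercorrelator_ranking", "data.frame")
  attr(out, "k") <- k
  attr(out, "include_in_pathway") <- include_in_pathway
  out
}
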