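#' Build a signed, q-thresholded metabolite correlation network
#'
#' Metabolites are nodes; an edge is a pair whose Storey q-value falls below
#' `q_threshold`. Edges are signed by the sign of r and scoped `"in"` when
#' both endpoints share an annotated pathway, `"out"` otherwise. Optional
#' sign and scope filters restrict the retained edge set (used, e.g., to
#' build a positive-only out-of-pathway network).
#'
#' @param tbl A `corr_table` that has been through [adjust_pvalues()].
#' @param pmap A [pathway_map()] covering every metabolite in `tbl`.
#' @param q_threshold Edges require `q < q_threshold` (default 0.05).
#' @param sign `"both"`, `"+"`, or `"-"` (aliases `"pos"`/`"neg"`).
#' @param scope `"both"`, `"in"`, or `"out"`.
#' @param group Optional label for the sample group the network describes.
#' @return An object of class `metab_network`: list with `edges` (data frame
#'   `met_a, met_b, r, p, fdr, q, sign, scope`), `nodes` (metabolite,
#'   pathway, degree over the full node universe), the threshold, filters,
#'   and the pathway map.
#' @export
build_network <- function(tbl, pmap, q_threshold = 0.05,
                          sign = "both", scope = "both", group = NULL) {
  stopifnot(inherits(tbl, "corr_table"))
  if (!isTRUE(attr(tbl, "adjusted")))
    stop("run adjust_pvalues() before build_network()")
  if (!is.numeric(q_threshold) || q_threshold < 0 || q_threshold > 1)
    stop("`q_threshold` must lie in [0, 1]")
  sign <- .match_arg_sign(sign)
  scope <- .match_arg_scope(scope)
  mets <- unique(c(tbl$met_a, tbl$met_b))
  pw <- .pathway_of(mets, pmap)
  names(pw) <- mets

  e <- tbl[tbl$q < q_threshold & tbl$r != 0, , drop = FALSE]
  e <- as.data.frame(e)
  e$sign <- ifelse(e$r > 0, "+", "-")
  e$scope <- ifelse(pw[e$met_a] == pw[e$met_b], "in", "out")
  if (sign != "both") e <- e[e$sign == sign, , drop = FALSE]
  if (scope != "both") e <- e[e$scope == scope, , drop = FALSE]
  rownames(e) <- NULL

  deg <- table(factor(c(e$met_a, e$met_b), levels = mets))
  nodes <- data.frame(metabolite = mets, pathway = unname(pw),
                      degree = as.integer(deg), stringsAsFactors = FALSE)
  structure(list(edges = e, nodes = nodes, q_threshold = q_threshold,
                 sign_filter = sign, scope_filter = scope,
                 group = group, n_samples = tbl$n_obs[1],
                 pi0 = attr(tbl, "pi0"),
                 pmap = pmap),
            class = "metab_network")
}

#' @export
print.metab_network <- function(x, ...) {
  cat("<metab_network>", if (!is.null(x$group)) paste0(" [", x$group, "]"),
      " ", nrow(x$edges), " edges among ", sum(x$nodes$degree > 0), "/",
      nrow(x$nodes), " metabolites (q < ", format(x$q_threshold), ")\n", sep = "")
  tb <- table(x$edges$sign, x$edges$scope)
  if (nrow(x$edges)) print(tb)
  invisible(x)
}

#' Tabulate a network by edge sign and pathway scope
#'
#' Counts edges in each sign-by-scope cell, tallies per-pathway connected
#' nodes and incident edges, and, when a node classification is supplied
#' (e.g., lipid vs polar), reports the number and fraction of edges incident
#' to at least one node of each class.
#'
#' @param net A `metab_network`.
#' @param node_classes Optional named character vector mapping metabolite id
#'   to a class label.
#' @return An object of class `network_summary`.
#' @export
summarize_network <- function(net, node_classes = NULL) {
  stopifnot(inherits(net, "metab_network"))
  e <- net$edges
  counts <- matrix(0L, 2, 2, dimnames = list(sign = c("+", "-"), scope = c("in", "out")))
  if (nrow(e)) {
    tb <- table(factor(e$sign, c("+", "-")), factor(e$scope, c("in", "out")))
    counts[] <- as.integer(tb)
  }
  pw <- structure(net$nodes$pathway, names = net$nodes$metabolite)
  pathways <- sort(unique(net$nodes$pathway))
  per_pw <- data.frame(
    pathway = pathways,
    n_nodes = vapply(pathways, function(p)
      sum(net$nodes$degree > 0 & net$nodes$pathway == p), integer(1)),
    n_edges = vapply(pathways, function(p)
      sum(pw[e$met_a] == p | pw[e$met_b] == p), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  class_frac <- NULL
  if (!is.null(node_classes)) {
    cls_a <- unname(node_classes[e$met_a])
    cls_b <- unname(node_classes[e$met_b])
    lv <- sort(unique(stats::na.omit(unname(node_classes))))
    n_edges <- vapply(lv, function(k)
      sum(cls_a %in% k | cls_b %in% k), integer(1))
    class_frac <- data.frame(class = lv, n_edges = n_edges,
                             fraction = if (nrow(e)) n_edges / nrow(e) else NA_real_,
                             row.names = NULL, stringsAsFactors = FALSE)
  }
  structure(list(counts = counts, total = sum(counts), per_pathway = per_pw,
                 class_fraction = class_frac, q_threshold = net$q_threshold,
                 group = net$group),
            class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat("<network_summary>", if (!is.null(x$group)) paste0(" [", x$group, "]"),
      " total edges: ", x$total, "\n", sep = "")
  print(x$counts)
  if (!is.null(x$class_fraction)) {
    cat("edges incident to node classes:\n")
    print(x$class_fraction, row.names = FALSE)
  }
  invisible(x)
}

#' Permutation test for edge-count differences between two groups
#'
#' Counts q-thresholded edges (positive, negative, total) in each group,
#' then builds a permutation null by shuffling group labels over the pooled
#' samples and rebuilding both networks for each permutation. Two-sided
#' p-values use the add-one estimator `p = (1 + #\{|diff_perm| >=
#' |diff_obs|\}) / (1 + n_perm)`. Pearson correlations are invariant to the
#' per-metabolite affine z-scoring, so permuting rows of the z matrices is
#' equivalent to re-deriving z-scores under each relabelling.
#'
#' @param zA,zB `zmatrix` objects for the two groups; identical metabolite
#'   sets and disjoint samples are required.
#' @param q_threshold Edge inclusion threshold on the Storey q-value.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed; results are reproducible given the seed.
#' @return Object of class `network_comparison` with observed counts,
#'   differences (A - B) and permutation p-values for positive, negative and
#'   total edge counts.
#' @export
compare_networks <- function(zA, zB, q_threshold = 0.05, n_perm = 1000, seed = 1) {
  stopifnot(inherits(zA, "zmatrix"), inherits(zB, "zmatrix"))
  if (!identical(colnames(zA$z), colnames(zB$z)))
    stop("the two groups must share an identical metabolite set")
  if (length(intersect(rownames(zA$z), rownames(zB$z))))
    stop("groups must be disjoint sample sets")
  if (n_perm < 1) stop("`n_perm` must be >= 1")
  nA <- nrow(zA$z); nB <- nrow(zB$z)
  if (nA < 4 || nB < 4) stop("each group needs at least 4 samples")
  pooled <- rbind(zA$z, zB$z)
  pinfo <- .pair_info(ncol(pooled), colnames(pooled))

  count_signed <- function(rows) {
    cu <- .corr_upper(pooled[rows, , drop = FALSE], pinfo)
    sig <- .sig_pairs(cu$r, length(rows), pinfo, q_threshold)
    pos <- sum(cu$r[sig$idx] > 0)
    c(pos = pos, neg = length(sig$idx) - pos, total = length(sig$idx))
  }
  obs_A <- count_signed(seq_len(nA))
  obs_B <- count_signed(nA + seq_len(nB))
  obs_diff <- obs_A - obs_B

  set.seed(seed %% 2147483647)
  exceed <- c(pos = 0L, neg = 0L, total = 0L)
  for (b in seq_len(n_perm)) {
    lab <- sample.int(nA + nB, nA)
    d <- count_signed(lab) - count_signed(setdiff(seq_len(nA + nB), lab))
    exceed <- exceed + (abs(d) >= abs(obs_diff))
  }
  structure(list(counts_a = obs_A, counts_b = obs_B, diff = obs_diff,
                 p_value = (1 + exceed) / (1 + n_perm),
                 n_perm = n_perm, seed = seed, q_threshold = q_threshold),
            class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  cat("<network_comparison> q < ", format(x$q_threshold), ", ", x$n_perm,
      " permutations\n", sep = "")
  out <- data.frame(edges = names(x$diff),
                    group_a = as.integer(x$counts_a),
                    group_b = as.integer(x$counts_b),
                    diff = as.integer(x$diff),
                    p_perm = as.numeric(x$p_value))
  print(out, row.names = FALSE)
  invisible(x)
}

#' Export network edges for chord-diagram and graph tools
#'
#' Formats: `"tsv"` writes the full edge attribute table (`met_a, met_b, r,
#' p, fdr, q, sign, scope`); `"sif"` writes tab-delimited
#' `node1 pos|neg node2` triples for Cytoscape-style viewers;
#' `"circos_links"` writes whitespace-delimited chord links
#' `pathway start end pathway start end color=<red|blue>` with 0-based
#' half-open integer rim slots, metabolites ordered along the rim by
#' `rim_order` (default: pathway, then metabolite id).
#'
#' @param net A `metab_network`.
#' @param path Output file path.
#' @param format One of `"tsv"`, `"sif"`, `"circos_links"`.
#' @param rim_order Optional permutation of the node set fixing rim order.
#' @return The path, invisibly.
#' @export
export_edges <- function(net, path, format = c("tsv", "sif", "circos_links"),
                         rim_order = NULL) {
  stopifnot(inherits(net, "metab_network"))
  format <- match.arg(format)
  e <- net$edges
  if (format == "tsv") {
    utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "sif") {
    lines <- paste(e$met_a, ifelse(e$sign == "+", "pos", "neg"), e$met_b, sep = "\t")
    writeLines(lines, path)
  } else {
    nodes <- net$nodes
    if (is.null(rim_order)) {
      rim_order <- nodes$metabolite[order(nodes$pathway, nodes$metabolite)]
    } else if (!setequal(rim_order, nodes$metabolite) ||
               length(rim_order) != nrow(nodes)) {
      stop("`rim_order` must be a permutation of the node set")
    }
    pw <- structure(nodes$pathway, names = nodes$metabolite)
    rim_pw <- pw[rim_order]
    slot <- stats::ave(seq_along(rim_order), rim_pw, FUN = seq_along) - 1L
    names(slot) <- rim_order
    lines <- paste(rim_pw[e$met_a], slot[e$met_a], slot[e$met_a] + 1L,
                   rim_pw[e$met_b], slot[e$met_b], slot[e$met_b] + 1L,
                   paste0("color=", ifelse(e$sign == "+", "red", "blue")))
    writeLines(lines, path)
  }
  invisible(path)
}
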