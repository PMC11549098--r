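make_adjusted <- function(n = 12, M = 8, seed = 1, rho = 0) {
  set.seed(seed)
  zm <- matrix(rnorm(n * M), n, M, dimnames = list(NULL, sprintf("m%02d", 1:M)))
  if (rho > 0) {
    f <- rnorm(n)
    zm <- sqrt(rho) * f + sqrt(1 - rho) * zm
    colnames(zm) <- sprintf("m%02d", 1:M)
  }
  adjust_pvalues(pairwise_correlations(zm))
}

test_that("network edges respect the q threshold, signs and pathway scope", {
  tbl <- make_adjusted(n = 20, M = 8, seed = 2, rho = 0.5)
  pmap <- make_toy_pmap(sprintf("m%02d", 1:8), 2)
  net <- build_network(tbl, pmap, q_threshold = 0.05)
  expect_true(all(net$edges$q < 0.05))
  expect_true(all(net$edges$r != 0))
  expect_identical(net$edges$sign, ifelse(net$edges$r > 0, "+", "-"))
  same <- unname(pmap[net$edges$met_a] == pmap[net$edges$met_b])
  expect_identical(net$edges$scope, ifelse(same, "in", "out"))

  expect_identical(nrow(build_network(tbl, pmap, q_threshold = 0)$edges), 0L)
  pos <- build_network(tbl, pmap, sign = "+")
  expect_true(all(pos$edges$sign == "+"))
  inn <- build_network(tbl, pmap, scope = "in")
  expect_true(all(inn$edges$scope == "in"))

  expect_error(build_network(make_adjusted(seed = 3),
                             suppressMessages(pathway_map("m01", "p"))),
               "missing metabolites")
  expect_error(build_network(pairwise_correlations(matrix(rnorm(24), 6, 4,
                             dimnames = list(NULL, paste0("m", 1:4)))),
                             make_toy_pmap(paste0("m", 1:4))),
               "adjust_pvalues")
})

test_that("tighter q thresholds give nested edge sets", {
  tbl <- make_adjusted(n = 25, M = 10, seed = 5, rho = 0.4)
  pmap <- make_toy_pmap(sprintf("m%02d", 1:10), 3)
  key <- function(net) paste(net$edges$met_a, net$edges$met_b)
  e1 <- key(build_network(tbl, pmap, q_threshold = 0.01))
  e2 <- key(build_network(tbl, pmap, q_threshold = 0.05))
  e3 <- key(build_network(tbl, pmap, q_threshold = 0.20))
  expect_true(all(e1 %in% e2))
  expect_true(all(e2 %in% e3))
})

test_that("network summary counts partition the edge set", {
  tbl <- make_adjusted(n = 25, M = 10, seed = 6, rho = 0.5)
  pmap <- make_toy_pmap(sprintf("m%02d", 1:10), 3)
  net <- build_network(tbl, pmap)
  sm <- summarize_network(net)
  expect_identical(sum(sm$counts), nrow(net$edges))
  expect_identical(sm$total, nrow(net$edges))

  empty <- summarize_network(build_network(tbl, pmap, q_threshold = 0))
  expect_identical(sum(empty$counts), 0L)

  # class fractions by hand: edges touching >= 1 node of the class
  cls <- setNames(rep(c("lipid", "polar"), 5), sprintf("m%02d", 1:10))
  sm2 <- summarize_network(net, node_classes = cls)
  lipid_by_hand <- sum(cls[net$edges$met_a] == "lipid" |
                       cls[net$edges$met_b] == "lipid")
  got <- sm2$class_fraction
  expect_identical(got$n_edges[got$class == "lipid"], lipid_by_hand)
  expect_equal(got$fraction[got$class == "lipid"],
               lipid_by_hand / nrow(net$edges))
})

test_that("edge exports round-trip and honour rim ordering", {
  dir <- withr::local_tempdir()
  tbl <- make_adjusted(n = 20, M = 9, seed = 7, rho = 0.5)
  pmap <- make_toy_pmap(sprintf("m%02d", 1:9), 3)
  net <- build_network(tbl, pmap)
  expect_gt(nrow(net$edges), 1)

  tsv <- file.path(dir, "edges.tsv")
  export_edges(net, tsv, "tsv")
  back <- read.delim(tsv, stringsAsFactors = FALSE)
  expect_identical(back$met_a, net$edges$met_a)
  expect_identical(back$met_b, net$edges$met_b)
  expect_equal(back$r, net$edges$r, tolerance = 1e-6)

  sif <- file.path(dir, "edges.sif")
  export_edges(net, sif, "sif")
  lines <- readLines(sif)
  expect_length(lines, nrow(net$edges))
  expect_true(all(grepl("\t(pos|neg)\t", lines)))

  rim <- net$nodes$metabolite[order(net$nodes$pathway, net$nodes$metabolite)]
  circ <- file.path(dir, "edges.circos")
  export_edges(net, circ, "circos_links", rim_order = rim)
  parts <- strsplit(readLines(circ), " ")
  expect_true(all(lengths(parts) == 7))
  # rim slot of each endpoint equals its 0-based position within its pathway
  slot_of <- function(met) {
    pw <- pmap[met]
    sum(pmap[rim] == pw & cumsum(rim == met) == 0)
  }
  for (k in seq_len(min(5, length(parts)))) {
    ea <- net$edges$met_a[k]
    expect_identical(parts[[k]][1], unname(pmap[ea]))
    expect_identical(as.integer(parts[[k]][2]), slot_of(ea))
    expect_identical(parts[[k]][7],
                     paste0("color=", ifelse(net$edges$sign[k] == "+", "red", "blue")))
  }
  expect_error(export_edges(net, tsv, "graphml"), "arg")
  expect_error(export_edges(net, circ, "circos_links", rim_order = rim[-1]),
               "permutation")
})

test_that("identical groups give zero observed difference and large p", {
  cfg <- synthetic_config(n_case = 10, n_control = 10,
                          pathways = setNames(rep(5L, 4), paste0("p", 1:4)),
                          rho_within = 0.5, seed = 21)
  coh <- generate_cohort(cfg)
  z <- zscore_transform(coh$table)
  zc <- subset_samples(z, group = "control")
  zc2 <- zc
  rownames(zc2$z) <- paste0("dup_", rownames(zc$z))
  zc2$meta$sample_id <- rownames(zc2$z)
  cmp <- compare_networks(zc, zc2, n_perm = 30, seed = 5)
  expect_identical(unname(cmp$diff["total"]), 0L)
  expect_gte(cmp$p_value[["total"]], 0.5)
  expect_error(compare_networks(zc, zc, n_perm = 10), "disjoint")
  expect_error(compare_networks(zc, zc2, n_perm = 0), "n_perm")
})

test_that("a planted dense-vs-sparse pair is detected by the permutation test", {
  hits <- 0L
  for (s in 1:5) {
    dense <- generate_cohort(synthetic_config(
      n_case = 0, n_control = 16, pathways = setNames(rep(6L, 5), paste0("p", 1:5)),
      rho_within = 0.7, seed = 100 + s))
    sparse <- generate_cohort(synthetic_config(
      n_case = 0, n_control = 16, pathways = setNames(rep(6L, 5), paste0("p", 1:5)),
      rho_within = 0.0, seed = 200 + s))
    zd <- zscore_transform(dense$table)
    zs <- zscore_transform(sparse$table)
    rownames(zs$z) <- paste0("sp_", rownames(zs$z))
    cmp <- compare_networks(zd, zs, n_perm = 99, seed = s)
    hits <- hits + (cmp$p_value[["total"]] < 0.05)
  }
  expect_gte(hits, 4L)
})
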