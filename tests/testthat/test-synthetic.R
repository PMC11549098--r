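test_that("config validation enforces the factor-model variance budget", {
  expect_error(synthetic_config(pathways = setNames(c(3L, 3L), c("a", "b")),
                                rho_within = 0.8,
                                hub_links = data.frame(metabolite = "a_m01",
                                                       target_pathway = "b",
                                                       sign = "+",
                                                       strength = 0.3)),
               "positive definite.*a_m01")
  expect_error(synthetic_config(rho_within = 1), "rho_within")
  expect_error(synthetic_config(hub_links = data.frame(metabolite = "pw01_m01",
                                                       target_pathway = "pw01",
                                                       sign = "+", strength = 0.1)),
               "foreign")
})

test_that("identical configs generate bit-identical cohorts", {
  cfg <- synthetic_config(n_case = 5, n_control = 6,
                          pathways = setNames(rep(4L, 3), c("a", "b", "c")),
                          rho_within = 0.4, seed = 99)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$table$auc, c2$table$auc)
  cfg2 <- cfg; cfg2$seed <- 100
  expect_false(identical(generate_cohort(cfg2)$table$auc, c1$table$auc))
})

test_that("truth edges follow the loading algebra", {
  # no hub links: truth = exactly the within-pathway pairs at r = rho
  cfg <- synthetic_config(pathways = setNames(c(3L, 4L), c("a", "b")),
                          rho_within = 0.35, seed = 1)
  tr <- truth_edges(cfg)
  expect_identical(nrow(tr), 9L)  # C(3,2) + C(4,2)
  expect_true(all(tr$scope == "in"))
  expect_equal(tr$r_pop, rep(0.35, nrow(tr)), tolerance = 1e-12)

  # a negative foreign loading creates all-negative cross edges of size
  # sqrt(strength * rho)
  cfg2 <- synthetic_config(pathways = setNames(c(3L, 4L), c("a", "b")),
                           rho_within = 0.25,
                           hub_links = data.frame(metabolite = "a_m01",
                                                  target_pathway = "b",
                                                  sign = "-", strength = 0.36),
                           seed = 1)
  tr2 <- truth_edges(cfg2)
  cross <- tr2[tr2$scope == "out", ]
  expect_identical(nrow(cross), 4L)
  expect_true(all(cross$sign == "-"))
  expect_equal(cross$r_pop, rep(-sqrt(0.36 * 0.25), 4), tolerance = 1e-12)

  # rho = 0, no links: empty truth network
  cfg0 <- synthetic_config(pathways = setNames(c(3L, 3L), c("a", "b")),
                           rho_within = 0, seed = 1)
  expect_identical(nrow(truth_edges(cfg0)), 0L)
})

test_that("empirical correlations converge to the configured population values", {
  # 2-metabolite pathway at rho = 0.81: population r = 0.81
  cfg <- synthetic_config(n_case = 0, n_control = 100,
                          pathways = setNames(c(2L, 3L), c("a", "b")),
                          rho_within = 0.81, seed = 5)
  tr <- truth_edges(cfg)
  expect_equal(tr$r_pop[tr$met_a == "a_m01" & tr$met_b == "a_m02"], 0.81)
  coh <- generate_cohort(cfg)
  lg <- log2(coh$table$auc)
  expect_lt(abs(cor(lg[, "a_m01"], lg[, "a_m02"]) - 0.81), 0.15)

  # Monte-Carlo check of the closed form on a mixed config at large n
  cfg2 <- synthetic_config(n_case = 0, n_control = 5000,
                           pathways = setNames(c(4L, 4L, 4L), c("a", "b", "c")),
                           rho_within = c(control = 0.5, case = 0.5),
                           hub_links = data.frame(
                             metabolite = c("a_m01", "b_m02"),
                             target_pathway = c("b", "c"),
                             sign = c("+", "-"),
                             strength = c(0.2, 0.3)),
                           seed = 6)
  coh2 <- generate_cohort(cfg2)
  emp <- cor(log2(coh2$table$auc))
  L <- mcorrnet:::.loading_matrix(cfg2, "control")
  pop <- L %*% t(L); diag(pop) <- 1
  expect_lt(max(abs(emp - pop)), 0.05)
})

test_that("independent metabolites stay uncorrelated in finite samples", {
  cfg <- synthetic_config(n_case = 0, n_control = 50,
                          pathways = setNames(rep(5L, 4), paste0("p", 1:4)),
                          rho_within = 0, seed = 17)
  coh <- generate_cohort(cfg)
  expect_identical(nrow(coh$truth), 0L)
  r <- cor(log2(coh$table$auc))
  expect_lt(mean(abs(r[upper.tri(r)])), 0.2)
})

test_that("generated controls satisfy the z-matrix contract and case shifts apply", {
  cfg <- synthetic_config(n_case = 40, n_control = 40,
                          pathways = setNames(rep(5L, 4), paste0("p", 1:4)),
                          rho_within = 0.3, mean_shift = 1.5, seed = 29)
  coh <- generate_cohort(cfg)
  z <- zscore_transform(coh$table)
  ctrl <- coh$table$meta$group == "control"
  expect_lt(max(abs(colMeans(z$z[ctrl, ]))), 1e-9)
  expect_lt(max(abs(apply(z$z[ctrl, ], 2, sd) - 1)), 1e-9)
  # case z-scores sit near the planted shift (in control-SD units)
  expect_gt(mean(z$z[!ctrl, ]), 0.75)
  expect_lt(abs(mean(z$z[!ctrl, ]) - 1.5), 0.6)
})

test_that("synthetic cohorts written to disk re-enter the pipeline unchanged", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(n_case = 4, n_control = 5,
                          pathways = setNames(rep(3L, 3), c("a", "b", "c")),
                          rho_within = 0.4, seed = 55)
  coh <- generate_cohort(cfg)
  paths <- write_cohort(coh, dir)
  tab <- read_sample_table(paths$auc, paths$metadata)
  pm <- suppressMessages(read_pathway_map(paths$pathways))
  expect_equal(tab$auc, coh$table$auc, tolerance = 1e-6)
  expect_identical(unname(pm[names(coh$pmap)]), as.character(coh$pmap))
})

test_that("exchangeable dense configs give a balanced growth-rate ordering", {
  cfg <- synthetic_config(n_case = 0, n_control = 12,
                          pathways = setNames(rep(5L, 4), paste0("p", 1:4)),
                          rho_within = 0.5, seed = 1)
  rep_out <- recovery_experiment(cfg, cfg, n_seeds = 8, replicates = 6,
                                 scope = "both", seed = 42)
  frac <- rep_out$fraction_vnet_dense_gt_sparse
  expect_gte(frac, 0.125)  # binomial noise band around 1/2 at 8 seeds
  expect_lte(frac, 0.875)
})
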