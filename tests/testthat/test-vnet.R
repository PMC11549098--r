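test_that("the ramp reproduces the worked subsample grids", {
  expect_identical(ramp_sizes(22), c(seq(4L, 20L, 2L), 21L))
  expect_identical(ramp_sizes(31), seq(4L, 30L, 2L))
  expect_identical(ramp_sizes(5), 4L)
  expect_error(ramp_sizes(4), "at least 5")
  s <- ramp_sizes(40)
  expect_true(all(diff(s) > 0))
  expect_identical(max(s), 39L)
  expect_identical(min(s), 4L)
})

test_that("resampled edge counts are reproducible and well-formed", {
  cfg <- synthetic_config(n_case = 0, n_control = 14,
                          pathways = setNames(rep(5L, 6), paste0("p", 1:6)),
                          rho_within = 0.5, seed = 31)
  coh <- generate_cohort(cfg)
  z <- zscore_transform(coh$table)
  cv1 <- resample_edge_counts(z, coh$pmap, replicates = 8, scope = "both", seed = 4)
  cv2 <- resample_edge_counts(z, coh$pmap, replicates = 8, scope = "both", seed = 4)
  expect_identical(cv1$counts, cv2$counts)
  cv3 <- resample_edge_counts(z, coh$pmap, replicates = 8, scope = "both", seed = 5)
  expect_false(identical(cv1$counts, cv3$counts))

  expect_identical(nrow(cv1$counts), 8L * nrow(cv1$stats))
  st <- cv1$stats
  expect_equal(st$cv[st$mean > 0], (st$sem / st$mean)[st$mean > 0])
  expect_equal(st$sem, st$sd / sqrt(8))

  # extending the size grid preserves the draws of shared sizes
  sizes_short <- cv1$stats$size[1:3]
  cv_short <- resample_edge_counts(z, coh$pmap, sizes = sizes_short,
                                   replicates = 8, scope = "both", seed = 4)
  expect_identical(cv_short$counts$count,
                   cv1$counts$count[cv1$counts$size %in% sizes_short])

  expect_error(resample_edge_counts(z, coh$pmap, sizes = c(4, 14),
                                    replicates = 4), "exceeds n - 1")
  expect_error(resample_edge_counts(z, coh$pmap, replicates = 0), "replicates")
})

test_that("fast significant-edge sets equal the full-path network edge sets", {
  cfg <- synthetic_config(n_case = 0, n_control = 24,
                          pathways = setNames(rep(6L, 7), paste0("p", 1:7)),
                          rho_within = 0.45,
                          hub_links = data.frame(metabolite = "p1_m01",
                                                 target_pathway = "p3",
                                                 sign = "-", strength = 0.3),
                          seed = 19)
  coh <- generate_cohort(cfg)
  z <- zscore_transform(coh$table)
  for (s in 1:6) {
    set.seed(100 + s)
    rows <- rownames(z$z)[sample(24, sample(6:20, 1))]
    zs <- subset_samples(z, sample_ids = rows)
    for (filt in list(c("both", "both"), c("out", "both"),
                      c("both", "+"), c("in", "-"))) {
      for (qt in c(0.05, 0.01)) {
        slow <- slow_edge_count(z$z, coh$pmap, rows, qt, filt[1], filt[2])
        fast <- mcorrnet:::.fast_count(zs$z, coh$pmap, qt, filt[1], filt[2])
        expect_identical(fast, slow)
      }
    }
  }
})

test_that("growth-line fits recover exact lines and degenerate slopes", {
  sizes <- c(4, 6, 8, 10)
  counts <- data.frame(size = rep(sizes, each = 3),
                       replicate = rep(1:3, 4),
                       count = as.integer(10 * rep(sizes, each = 3) + 3))
  curve <- structure(list(counts = counts,
                          stats = data.frame(size = sizes,
                                             mean = 10 * sizes + 3,
                                             median = 10 * sizes + 3,
                                             sd = 0, sem = 0, cv = 0),
                          settings = list(replicates = 3, replacement = FALSE,
                                          q_threshold = 0.05, scope = "out",
                                          sign = "both", seed = 1,
                                          n_samples = 11, group = NULL)),
                     class = "vnet_curve")
  fit <- fit_vnet(curve)
  expect_equal(fit$slope, 10, tolerance = 1e-10)
  expect_equal(fit$intercept, 3, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(unname(coef(fit)), c(3, 10), tolerance = 1e-10)
  expect_equal(unname(predict(fit, c(12, 20))), c(123, 203), tolerance = 1e-8)

  flat <- curve
  flat$counts$count <- 7L
  flat$stats$mean <- 7
  expect_equal(fit_vnet(flat)$slope, 0, tolerance = 1e-12)

  single <- curve
  single$counts <- single$counts[single$counts$size == 4, ]
  expect_error(fit_vnet(single), "2 distinct")
})

test_that("raw-point and size-mean fits give the same slope under balance", {
  cfg <- synthetic_config(n_case = 0, n_control = 16,
                          pathways = setNames(rep(5L, 6), paste0("p", 1:6)),
                          rho_within = 0.5, seed = 8)
  coh <- generate_cohort(cfg)
  z <- zscore_transform(coh$table)
  cv <- resample_edge_counts(z, coh$pmap, replicates = 10, scope = "both", seed = 2)
  f_raw <- fit_vnet(cv, "raw_points")
  f_mean <- fit_vnet(cv, "size_means")
  expect_equal(f_raw$slope, f_mean$slope, tolerance = 1e-9)
  expect_equal(f_raw$intercept, f_mean$intercept, tolerance = 1e-9)
})

test_that("block-correlated cohorts show monotone network growth", {
  cfg <- synthetic_config(n_case = 0, n_control = 30,
                          pathways = setNames(rep(10L, 10), sprintf("p%02d", 1:10)),
                          rho_within = 0.6, seed = 13)
  coh <- generate_cohort(cfg)
  z <- zscore_transform(coh$table)
  cv <- resample_edge_counts(z, coh$pmap, replicates = 15, scope = "both", seed = 3)
  rho_s <- cor(cv$stats$size, cv$stats$mean, method = "spearman")
  expect_gt(rho_s, 0.9)
  expect_gt(fit_vnet(cv)$slope, 0)
})

test_that("slope comparison is null for identical curves and errors on mismatched settings", {
  cfg <- synthetic_config(n_case = 0, n_control = 14,
                          pathways = setNames(rep(5L, 5), paste0("p", 1:5)),
                          rho_within = 0.5, seed = 3)
  coh <- generate_cohort(cfg)
  z <- zscore_transform(coh$table)
  cv <- resample_edge_counts(z, coh$pmap, replicates = 6, scope = "both", seed = 2)
  same <- compare_vnet(cv, cv)
  expect_equal(same$slope_diff, 0, tolerance = 1e-10)
  expect_gte(same$p_value, 0.99)

  cv2 <- resample_edge_counts(z, coh$pmap, replicates = 6, scope = "out", seed = 2)
  expect_error(compare_vnet(cv, cv2), "scope")
})

test_that("doubling the cohort sample-wise adds edges at every size", {
  cfg <- synthetic_config(n_case = 0, n_control = 12,
                          pathways = setNames(rep(6L, 6), paste0("p", 1:6)),
                          rho_within = 0.5, seed = 23)
  coh <- generate_cohort(cfg)
  z <- zscore_transform(coh$table)
  z2 <- z
  z2$z <- rbind(z$z, z$z)
  rownames(z2$z) <- c(rownames(z$z), paste0("dup_", rownames(z$z)))
  z2$meta <- rbind(z$meta, transform(z$meta, sample_id = paste0("dup_", sample_id)))
  sizes <- ramp_sizes(12)
  cv1 <- resample_edge_counts(z, coh$pmap, sizes = sizes, replicates = 12,
                              scope = "both", seed = 6)
  cv2 <- resample_edge_counts(z2, coh$pmap, sizes = sizes, replicates = 12,
                              scope = "both", seed = 6)
  # duplication increases the per-size edge yield ...
  expect_true(all(cv2$stats$mean >= cv1$stats$mean - 2))
  # ... and on its own full ramp (which extends to 2n - 1) the growth rate
  # is at least the original's
  cv2_full <- resample_edge_counts(z2, coh$pmap, replicates = 12,
                                   scope = "both", seed = 6)
  expect_gte(fit_vnet(cv2_full)$slope, fit_vnet(cv1)$slope - 1e-9)
})
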