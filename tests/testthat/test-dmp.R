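test_that("perfectly separated probes return the sentinel statistic", {
  v <- matrix(rep(c(0.8, 0.3), 4), 1)
  m <- tiny_paired(v)
  fit <- fit_probe_model(v[1, ], m$samples)
  expect_equal(fit$effect, 0.5, tolerance = 1e-10)
  expect_gte(fit$stat, 1e5)
})

test_that("a probe identical in tumor and normal has zero tissue effect", {
  v <- matrix(rep(c(0.4, 0.4), 4), 1)
  m <- tiny_paired(v)
  fit <- fit_probe_model(v[1, ], m$samples)
  expect_equal(fit$effect, 0, tolerance = 1e-12)
  expect_equal(fit$stat, 0)
})

test_that("model coefficients match an independent pseudoinverse oracle", {
  set.seed(42)
  v <- matrix(round(runif(6), 2), 1)  # 3 pairs, printed values
  m <- tiny_paired(v, cancer_type = c("CA", "CA", "CB"))
  fit <- fit_probe_model(v[1, ], m$samples)
  X <- fit$design$X_full
  oracle <- drop(pracma::pinv(X) %*% v[1, ])
  expect_equal(unname(fit$coefficients), oracle, tolerance = 1e-8)
})

test_that("rank-deficient designs raise an informative error", {
  v <- matrix(runif(8), 1)
  m <- tiny_paired(v, cancer_type = c("CA", "CA", "CB", "CB"))
  s <- m$samples
  s$tissue_type <- rep("tumor", 8)  # no normals at all
  expect_error(fit_probe_model(v[1, ], s), "both tissue types")
})

test_that("exchangeable probes get empirical P of one, and P is never zero", {
  set.seed(3)
  v <- rbind(rep(c(0.8, 0.3), 10),              # strong effect
             rep(runif(10), each = 2)[1:20])    # tumor == normal per pair
  m <- tiny_paired(v)
  tab <- permutation_null(m, n_perm = 199, seed = 5)
  expect_equal(tab$p_emp[2], 1)
  expect_true(all(tab$p_emp > 0))
  expect_equal(min(tab$p_emp), 1 / 200)  # strong probe hits the floor
})

test_that("a planted strong probe attains the minimum possible P", {
  set.seed(11)
  n_pairs <- 30
  tumor <- 0.7 + rnorm(n_pairs, 0, 0.03)
  normal <- 0.2 + rnorm(n_pairs, 0, 0.03)
  v <- matrix(rbind(tumor, normal), 1)  # interleave T/N
  m <- tiny_paired(matrix(as.vector(rbind(tumor, normal)), 1))
  tab <- permutation_null(m, n_perm = 1000, seed = 11)
  expect_equal(tab$p_emp[1], 1 / 1001)
})

test_that("unpaired tumors are rejected with the offending patient named", {
  v <- matrix(runif(4), 1)
  m <- tiny_paired(v)
  s <- m$samples[-2, ]  # drop P01's normal
  m2 <- beta_matrix(m$values[, -2, drop = FALSE], s)
  expect_error(permutation_null(m2, 10, 1), "P01")
})

test_that("delta-beta medians follow the definition", {
  m1 <- tiny_paired(matrix(c(0.8, 0.3), 1))
  expect_equal(unname(compute_delta_beta(m1)$median), 0.5)
  m3 <- tiny_paired(matrix(c(0.4, 0.2, 0.6, 0.2, 0.8, 0.2), 1))
  expect_equal(unname(compute_delta_beta(m3)$median), 0.4)
  m4 <- tiny_paired(matrix(c(0.2, 0.3, 0.3, 0.3, 0.6, 0.3, 0.8, 0.3), 1))
  expect_equal(unname(compute_delta_beta(m4)$median), 0.15)
})

test_that("thresholds equal an independent sort-and-interpolate oracle", {
  set.seed(5)
  hyper_pool <- rnorm(10000, 0.3, 0.25)
  hypo_pool <- rnorm(10000, -0.25, 0.2)
  thr <- derive_thresholds(hyper_pool, hypo_pool, 0.05)
  expect_equal(thr$hyper_threshold, abs(oracle_quantile(hyper_pool, 0.05)),
               tolerance = 1e-12)
  expect_equal(thr$hypo_threshold, -abs(oracle_quantile(hypo_pool, 0.95)),
               tolerance = 1e-12)
})

test_that("threshold edge cases behave as documented", {
  # symmetric pool: mirror rule reduces to the mirrored quantile
  x <- c(seq(-1, -0.01, length.out = 500), seq(0.01, 1, length.out = 500))
  thr <- derive_thresholds(x, x, 0.05)
  expect_equal(thr$hyper_threshold, abs(oracle_quantile(x, 0.05)),
               tolerance = 1e-12)
  # degenerate constant pools warn (once per side) and return the constant
  expect_warning(
    expect_warning(thr2 <- derive_thresholds(c(0.2, 0.2, 0.2),
                                             c(-0.2, -0.2, -0.2), 0.05),
                   "hyper pool"),
    "hypo pool")
  expect_equal(thr2$hyper_threshold, 0.2)
  expect_error(derive_thresholds(numeric(0), 1), "nonempty")
  expect_error(derive_thresholds(1, -1, percentile = 0.6), "percentile")
})

test_that("conserved calls respect the poised and threshold gates", {
  thr <- structure(list(hyper_threshold = 0.175, hypo_threshold = -0.145,
                        percentile = 0.05), class = "delta_beta_thresholds")
  tab <- data.frame(probe_id = c("a", "b", "c", "d", "e"),
                    obs_stat = 1,
                    p_emp = c(0.0005, 0.0005, 0.002, 0.0005, 0.0005),
                    median_delta_beta = c(0.30, 0.10, 0.40, -0.30, 0))
  out <- select_conserved(tab, thr, 0.001)
  expect_equal(out$conserved, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(out$direction, c("hyper", "hyper", "hyper", "hypo", "hypo"))
  expect_true(all(out$poised[out$conserved]))
  # zero median delta-beta takes the hypo branch and is never conserved
  expect_equal(out$direction[5], "hypo")
})

test_that("raising thresholds never adds conserved probes", {
  set.seed(7)
  tab <- data.frame(probe_id = sprintf("p%03d", 1:200),
                    obs_stat = 1,
                    p_emp = runif(200, 1e-4, 0.01),
                    median_delta_beta = rnorm(200, 0, 0.3))
  thr1 <- structure(list(hyper_threshold = 0.1, hypo_threshold = -0.1,
                         percentile = 0.05), class = "delta_beta_thresholds")
  thr2 <- structure(list(hyper_threshold = 0.2, hypo_threshold = -0.2,
                         percentile = 0.05), class = "delta_beta_thresholds")
  c1 <- select_conserved(tab, thr1, 0.001)$conserved
  c2 <- select_conserved(tab, thr2, 0.001)$conserved
  expect_true(all(which(c2) %in% which(c1)))
})

test_that("too few permutations for the poised cutoff raises a warning", {
  tab <- data.frame(probe_id = "a", obs_stat = 1, p_emp = 0.5,
                    median_delta_beta = 0.1)
  attr(tab, "n_perm") <- 100L
  thr <- structure(list(hyper_threshold = 0.1, hypo_threshold = -0.1,
                        percentile = 0.05), class = "delta_beta_thresholds")
  expect_warning(select_conserved(tab, thr, 0.001), "attainable")
})

test_that("genomic-context fractions sum to one per direction", {
  tab <- data.frame(probe_id = sprintf("p%d", 1:5),
                    direction = c(rep("hypo", 4), "hyper"),
                    conserved = c(rep(TRUE, 4), TRUE))
  ann <- data.frame(probe_id = sprintf("p%d", 1:5),
                    island_relation = c("open_sea", "open_sea", "island",
                                        "shore", "island"),
                    region = c("TSS", "TSS", "gene_body", "other", "TSS"),
                    stringsAsFactors = FALSE)
  ctx <- annotate_dmp_context(tab, ann)
  hypo_island <- ctx[ctx$direction == "hypo" & ctx$family == "island_relation", ]
  expect_equal(hypo_island$fraction[hypo_island$category == "open_sea"], 0.5)
  expect_equal(sum(hypo_island$fraction), 1)
  hyper_island <- ctx[ctx$direction == "hyper" & ctx$family == "island_relation", ]
  expect_equal(hyper_island$fraction[hyper_island$category == "island"], 1)
  # empty conserved set: empty summary, no division by zero
  tab0 <- transform(tab, conserved = FALSE)
  expect_equal(nrow(annotate_dmp_context(tab0, ann)), 0)
})

test_that("the dmp_call driver ties the stages together reproducibly", {
  cfg <- sim_config(n_pairs = 15, n_probes = 400, seed = 17)
  sim <- simulate_paired_cohort(cfg)
  # low-noise generator: the poised pools sit clear of zero, so the mirror
  # rule warns that it degenerates; that is expected here
  f1 <- suppressWarnings(dmp_call(sim$beta, n_perm = 300, p_threshold = 0.01,
                                  seed = 5))
  f2 <- suppressWarnings(dmp_call(sim$beta, n_perm = 300, p_threshold = 0.01,
                                  seed = 5))
  expect_identical(f1$table, f2$table)
  expect_s3_class(f1, "dmp_fit")
  expect_true(all(f1$table$p_emp > 0 & f1$table$p_emp <= 1))
  expect_output(print(f1), "dmp_fit")
  s <- summary(f1)
  expect_equal(s$min_attainable_p, 1 / 301)
})
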