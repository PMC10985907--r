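test_that("median split sends ties low and rejects degenerate input", {
  expect_equal(as.character(median_split(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  expect_equal(as.character(median_split(c(1, 2, 2, 4))),
               c("low", "low", "low", "high"))
  expect_error(median_split(5), ">= 2")
  expect_error(median_split(rep(1, 10)), "degenerate")
})

test_that("the Cox coefficient matches a brute-force partial-likelihood grid", {
  time <- c(2, 5, 8, 11)
  event <- c(1, 1, 1, 1)
  x <- c(1, 0, 1, 0)
  cs <- cox_survival(factor(ifelse(x == 1, "high", "low"),
                            levels = c("low", "high")), time, event)
  grid <- seq(-5, 5, by = 1e-3)
  ll <- vapply(grid, oracle_cox_loglik, numeric(1), time = time,
               event = event, x = x)
  expect_equal(cs$coef, grid[which.max(ll)], tolerance = 1e-3)
  expect_error(cox_survival(factor(c("a", "a", "b", "b")), time,
                            c(1, 1, 0, 0)), "at least one event")
})

test_that("a planted group hazard ratio is recovered", {
  cfg <- sim_config(n_probes = 60, k_true = 2, hazard_log_hr = log(2),
                    censor_rate = 0.2, seed = 3)
  sim <- simulate_signature_cohort(cfg, n_samples = 500)
  clin <- simulate_clinical(cfg, sim$truth, hazard_on = "median_split")
  g <- median_split(sim$truth$true_H[1, ])
  cs <- cox_survival(g, clin$os_time, clin$os_event)
  expect_gt(cs$hr, 1.6); expect_lt(cs$hr, 2.5)
})

test_that("two-group comparisons use the exact null when appropriate", {
  gc <- group_compare(c(1, 2, 3, 4, 5, 6),
                      c("a", "a", "a", "b", "b", "b"))
  expect_equal(gc$p, 0.1)
  expect_equal(gc$p, oracle_wilcox_p(c(1, 2, 3), c(4, 5, 6)))
  same <- group_compare(c(1, 2, 3, 1, 2, 3),
                        rep(c("a", "b"), each = 3))
  expect_equal(same$p, 1)
  expect_error(group_compare(1:3, rep("a", 3)), "two nonempty")
})

test_that("exact and approximate Wilcoxon paths agree for moderate n", {
  set.seed(4)
  a <- rnorm(10); b <- rnorm(10, 0.5)
  gc <- group_compare(c(a, b), rep(c("a", "b"), each = 10))  # exact path
  approx <- suppressWarnings(wilcox.test(a, b, exact = FALSE,
                                         correct = TRUE)$p.value)
  expect_lt(abs(gc$p - approx), 0.01)
})

test_that("meta-effects combine per-stratum Spearman on the Fisher-z scale", {
  set.seed(5)
  n1 <- 103; n2 <- 53
  act <- c(rnorm(n1), rnorm(n2))
  feat <- data.frame(f = act + c(rnorm(n1, 0, 1.2), rnorm(n2, 0, 2)))
  ct <- rep(c("A", "B"), c(n1, n2))
  tc <- time_correlation(act, feat, ct)
  st <- tc$per_stratum
  # independent arithmetic oracle from the reported per-stratum estimates
  zi <- atanh(st$rho); wi <- st$n - 3
  expect_equal(tc$meta$rho_meta, tanh(sum(wi * zi) / sum(wi)),
               tolerance = 1e-12)
  # identical stratum estimates collapse to that value
  x <- c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5)
  y <- c(1, 2, 3, 5, 4, 1, 2, 3, 5, 4)
  tc2 <- time_correlation(x, data.frame(f = y), rep(c("A", "B"), each = 5))
  expect_equal(tc2$meta$rho_meta, tc2$per_stratum$rho[1], tolerance = 1e-12)
})

test_that("single-stratum and constant-feature cases are flagged", {
  x <- rnorm(20); y <- x + rnorm(20)
  expect_warning(tc <- time_correlation(x, data.frame(f = y),
                                        rep("A", 20)), "single")
  expect_equal(tc$meta$rho_meta, tc$per_stratum$rho, tolerance = 1e-12)
  feat <- data.frame(f = c(rep(1, 10), rnorm(10)))
  # the degenerate stratum is dropped, which also leaves a single stratum
  expect_warning(
    expect_warning(time_correlation(rnorm(20), feat,
                                    rep(c("A", "B"), each = 10)),
                   "constant"),
    "single")
})

test_that("variance attribution matches the one-way decomposition", {
  H <- rbind(c(rep(1, 5), rep(3, 5)))  # constant within groups
  expect_equal(unname(variance_attribution(H, rep(c("A", "B"), each = 5))), 1)
  expect_equal(unname(variance_attribution(H, rep("A", 10))), 0)
  # permuted labels: fraction ~ (g-1)/(n-1) in expectation
  set.seed(6)
  a <- rnorm(60)
  fr <- replicate(300, variance_attribution(rbind(a), sample(rep(1:3, 20))))
  expect_lt(abs(mean(fr) - 2 / 59), 0.01)
})

test_that("the saturated logistic model reproduces the cross-product odds ratio", {
  y <- rep(c(1, 0, 1, 0), c(30, 10, 10, 30))
  x <- rep(c(1, 1, 0, 0), c(30, 10, 10, 30))
  out <- ici_multivariate(y, x)
  expect_equal(out$odds_ratio[out$term == "score"], 9, tolerance = 1e-6)
})

test_that("the multivariate response model recovers planted coefficients", {
  cfg <- sim_config(n_probes = 60, k_true = 2, ici_c0 = -0.5,
                    ici_c1 = -0.8, ici_c2 = 0.5, ici_c3 = 0.3, seed = 7)
  sim <- simulate_signature_cohort(cfg, n_samples = 600)
  clin <- simulate_clinical(cfg, sim$truth)
  z <- scale(sim$truth$true_H[1, ])[, 1]
  out <- ici_multivariate(clin$response, z, clin$tp53_status,
                          clin$foxa1_expr)
  est <- out$estimate[out$term == "score"]
  expect_lt(est, 0)
  expect_lt(out$p[out$term == "score"], 0.05)
  # linear-probability option reports the same sign
  lin <- ici_multivariate(clin$response, z, clin$tp53_status,
                          clin$foxa1_expr, family = "linear")
  expect_lt(lin$estimate[lin$term == "score"], 0)
})

test_that("GES ranks a perfect predictor first and scores are affine-invariant", {
  set.seed(8)
  n <- 120
  act <- rnorm(n)
  expr <- matrix(rnorm(n * 30), n, 30,
                 dimnames = list(NULL, sprintf("G%02d", 1:30)))
  expr[, 1] <- act
  ges <- derive_ges(expr, act, n_genes = 1, seed = 2)
  expect_equal(ges$genes$gene[1], "G01")
  expect_equal(ges$auc, 1)
  # per-gene affine rescaling leaves scores unchanged
  expr2 <- sweep(sweep(expr, 2, runif(30, 0.5, 2), "*"), 2, rnorm(30), "+")
  ges2 <- derive_ges(expr2, act, n_genes = 1, seed = 2)
  expect_equal(ges_score(ges2, expr2), ges_score(ges, expr),
               tolerance = 1e-10)
})

test_that("a null GES has chance-level held-out AUC", {
  set.seed(9)
  n <- 400
  act <- rnorm(n)
  expr <- matrix(rnorm(n * 100), n, 100,
                 dimnames = list(NULL, sprintf("G%03d", 1:100)))
  ges <- derive_ges(expr, act, n_genes = 20, seed = 3)
  expect_gt(ges$auc, 0.3); expect_lt(ges$auc, 0.7)
})

test_that("planted signal genes dominate the GES selection", {
  set.seed(10)
  n <- 300
  act <- rnorm(n)
  expr <- matrix(rnorm(n * 1000), n, 1000,
                 dimnames = list(NULL, sprintf("G%04d", 1:1000)))
  signal <- 1:50
  expr[, signal] <- expr[, signal] + act  # shifted with activity
  ges <- derive_ges(expr, act, n_genes = 50, seed = 4)
  expect_gte(mean(ges$genes$gene %in% sprintf("G%04d", signal)), 0.8)
  expect_error(derive_ges(expr, act, n_genes = 2000), "exceeds")
})

test_that("high-score fractions are computed per group", {
  s <- c(1, 2, 3, 4)
  out <- ges_fraction(s, rep("A", 4), threshold = 0)
  expect_equal(out$fraction_high, 1)
  out2 <- ges_fraction(s, rep(c("A", "B"), 2))  # threshold = median 2.5
  expect_equal(sum(out2$n * out2$fraction_high) / sum(out2$n), 0.5)
  set.seed(11)
  sc <- c(rbinom(500, 1, 0.3), rbinom(500, 1, 0.7)) + rnorm(1000, 0, 1e-3)
  fr <- ges_fraction(sc, rep(c("lo", "hi"), each = 500), threshold = 0.5)
  expect_lt(abs(fr$fraction_high[fr$group == "lo"] - 0.3), 0.05)
  expect_lt(abs(fr$fraction_high[fr$group == "hi"] - 0.7), 0.05)
})

test_that("association tests are invariant to sample-order permutation", {
  set.seed(12)
  n <- 80
  act <- rnorm(n)
  time <- rexp(n, 0.01); ev <- rbinom(n, 1, 0.8)
  g <- median_split(act)
  perm <- sample(n)
  a <- cox_survival(g, time, ev)
  b <- cox_survival(g[perm], time[perm], ev[perm])
  expect_equal(a$hr, b$hr, tolerance = 1e-10)
  gc1 <- group_compare(act, g)
  gc2 <- group_compare(act[perm], g[perm])
  expect_equal(gc1$p, gc2$p, tolerance = 1e-12)
})
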