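test_that("an exact rank-1 matrix is recovered to machine-level error", {
  set.seed(1)
  e <- runif(30); h <- runif(8)
  V <- e %o% h
  fit <- meth_nmf(V, 1, n_runs = 3, seed = 2, tol = 1e-12, max_iter = 2000)
  expect_lte(fit$rel_error, 1e-6)
  cs <- sum(fit$E[, 1] * e) / sqrt(sum(fit$E[, 1]^2) * sum(e^2))
  expect_gte(cs, 1 - 1e-8)
})

test_that("full-rank factorization of a small matrix reaches the noise floor", {
  set.seed(2)
  V <- matrix(runif(100, 0.1, 1), 10, 10)
  fit <- meth_nmf(V, 10, n_runs = 5, seed = 3, objective = "frobenius",
                  tol = 1e-12, max_iter = 5000)
  expect_lte(fit$rel_error, 0.02)
})

test_that("the multiplicative-update objective is non-increasing", {
  set.seed(3)
  V <- matrix(runif(600), 30, 20)
  for (obj in c("kl", "frobenius")) {
    fit <- meth_nmf(V, 3, n_runs = 1, seed = 4, objective = obj)
    expect_true(all(diff(fit$trace) <= 1e-8))
  }
})

test_that("factorizations are deterministic in (seed, n_runs, k)", {
  set.seed(5)
  V <- matrix(runif(300), 30, 10)
  f1 <- meth_nmf(V, 2, n_runs = 3, seed = 9)
  f2 <- meth_nmf(V, 2, n_runs = 3, seed = 9)
  expect_identical(f1$E, f2$E)
  expect_identical(f1$H, f2$H)
})

test_that("degenerate factorization inputs error", {
  expect_error(meth_nmf(matrix(0, 4, 4), 2), "all-zero")
  expect_error(meth_nmf(matrix(1, 4, 4), 0), "k must lie")
  expect_error(meth_nmf(matrix(-1, 4, 4), 2), "nonnegative")
})

test_that("normalization transfers scale from E to H without changing the product", {
  m <- list(E = cbind(c(2, 3, 5)), H = rbind(c(1, 1)))
  out <- normalize_model(m)
  expect_equal(unname(out$E[, 1]), c(0.2, 0.3, 0.5))
  expect_equal(unname(out$H[1, ]), c(10, 10))
  expect_equal(out$E %*% out$H, m$E %*% m$H)
  # already normalized -> unchanged; idempotent
  again <- normalize_model(out)
  expect_equal(again, out)
  expect_error(normalize_model(list(E = cbind(c(0, 0)), H = rbind(1))),
               "all-zero")
})

test_that("probe and sample assignment uses argmax with low-index ties", {
  m <- list(E = rbind(c(0.1, 0.7, 0.2), c(0.5, 0.5, 0)),
            H = cbind(c(0, 0, 3), c(1, 1, 1)), k = 3L)
  colnames(m$E) <- rownames(m$H) <- paste0("Sig", 1:3)
  rownames(m$E) <- c("p1", "p2"); colnames(m$H) <- c("s1", "s2")
  a <- assign_dmps_and_samples(m, top_n = 1)
  expect_equal(unname(a$probe_assignment), c(2, 1))  # tie -> lowest index
  expect_equal(unname(a$sample_assignment), c(3, 1))
})

test_that("cosine and Spearman similarity match their definitions", {
  E1 <- cbind(a = c(1, 0, 1), b = c(0, 1, 0))
  E2 <- cbind(c = c(1, 1, 0), d = c(1, 0, 1))
  rownames(E1) <- rownames(E2) <- c("p1", "p2", "p3")
  s <- signature_similarity(E1, E2)
  expect_equal(s$cosine["a", "c"], 0.5)        # (1,0,1).(1,1,0) / 2
  expect_equal(s$cosine["a", "d"], 1)          # identical columns
  expect_equal(s$cosine["b", "d"], 0)          # disjoint support
  expect_equal(nrow(s$matching), 2)
  expect_setequal(s$matching$sig1, c("a", "b"))
  rownames(E2) <- c("q1", "q2", "q3")
  expect_error(signature_similarity(E1, E2), "intersection")
})

test_that("NNLS projection recovers activities on consistent systems", {
  set.seed(6)
  E <- matrix(runif(40), 20, 2)
  E <- sweep(E, 2, colSums(E), "/")
  rownames(E) <- sprintf("p%02d", 1:20)
  h <- cbind(c(2, 0.5), c(1, 3))
  V <- E %*% h
  rownames(V) <- rownames(E)
  H <- project_signatures(V, E)
  expect_equal(unname(H), unname(h), tolerance = 1e-6, ignore_attr = TRUE)
  # single signature scaled by 2
  H1 <- project_signatures(2 * E[, 1, drop = FALSE], E[, 1, drop = FALSE])
  expect_equal(unname(H1[1, 1]), 2, tolerance = 1e-8)
  # zero matrix -> zero activities
  H0 <- project_signatures(V * 0, E)
  expect_true(all(H0 == 0))
  # too few shared probes
  expect_error(project_signatures(V[1:5, ], E), "probes present")
})

test_that("rank selection follows the documented decision rule", {
  d <- data.frame(k = 2:4, cophenetic = c(0.99, 0.99, 0.80),
                  silhouette = c(0.9, 0.9, 0.5))
  expect_equal(select_rank(d), 3)  # largest before the sustained drop
  d2 <- data.frame(k = 2:5, cophenetic = 0.99, silhouette = 0.9)
  expect_equal(select_rank(d2), 2)  # no drop: tie toward smallest
  d3 <- data.frame(k = 4, cophenetic = 0.99, silhouette = 0.9)
  expect_equal(select_rank(d3), 4)  # single candidate
  d4 <- data.frame(k = 2:5, cophenetic = c(0.97, 0.98, 1.0, 0.999),
                   silhouette = c(0.85, 0.9, 1.0, 0.87))
  expect_equal(select_rank(d4), 4)  # no drop: silhouette peak decides
  d5 <- data.frame(k = 2:3, cophenetic = c(0.5, 0.6),
                   silhouette = c(0.2, 0.1))
  expect_warning(k5 <- select_rank(d5), "floors")
  expect_equal(k5, 3)
})

test_that("perfectly stable consensus gives binary matrices and cophenetic one", {
  # two well-separated blocks: every run assigns samples identically
  set.seed(8)
  E <- cbind(c(rep(1, 15), rep(0, 15)), c(rep(0, 15), rep(1, 15)))
  H <- cbind(matrix(rep(c(5, 0.1), 10), 2), matrix(rep(c(0.1, 5), 10), 2))
  V <- (E / 15) %*% H + matrix(runif(600, 0, 0.01), 30, 20)
  surv <- rank_survey(V, k_range = 2, n_runs = 4, seed = 10)
  C <- attr(surv, "consensus")[["2"]]
  expect_true(all(C %in% c(0, 1)))
  expect_equal(surv$cophenetic[1], 1)
  expect_error(rank_survey(V, 2, n_runs = 1), "n_runs")
})

test_that("a k=1 survey records the silhouette as missing", {
  set.seed(9)
  V <- matrix(runif(200, 0.2, 0.8), 20, 10)
  surv <- rank_survey(V, k_range = 1:2, n_runs = 3, seed = 2)
  expect_true(is.na(surv$silhouette[surv$k == 1]))
})

test_that("best-of-runs matches an exhaustive multi-start baseline", {
  set.seed(10)
  V <- matrix(runif(48, 0.1, 1), 6, 8)
  fit <- meth_nmf(V, 6, n_runs = 30, seed = 7, objective = "frobenius",
                  tol = 1e-10, max_iter = 2000)
  # exhaustive baseline: 200 independent starts of the bare update loop
  set.seed(123)
  best <- Inf
  for (r in 1:200) {
    E0 <- matrix(runif(36, 0.01, 1), 6, 6)
    H0 <- matrix(runif(48, 0.01, 1), 6, 8)
    res <- methsig:::.nmf_mu_cpp(V, E0, H0, 2000L, 1e-10, "frobenius")
    err <- norm(V - res$E %*% res$H, "F") / norm(V, "F")
    best <- min(best, err)
  }
  expect_lte(fit$rel_error, best + 1e-4)
})

test_that("models keep nonnegativity and column-stochastic weights", {
  set.seed(11)
  V <- matrix(runif(400, 0, 1), 40, 10)
  for (k in c(2, 4)) {
    fit <- meth_nmf(V, k, n_runs = 2, seed = k)
    expect_true(all(fit$E >= 0), all(fit$H >= 0))
    expect_equal(unname(colSums(fit$E)), rep(1, k), tolerance = 1e-9)
    H2 <- predict(fit, V)
    expect_equal(dim(H2), dim(fit$H))
  }
})

test_that("orientation comparison flags constant input and handles k = 1", {
  expect_warning(out <- compare_beta_orientation(matrix(0.5, 10, 6), 2),
                 "degenerate")
  expect_equal(nrow(out$matching), 0)
  set.seed(12)
  e <- runif(30); h <- runif(10, 0.2, 1)
  V <- pmin(e %o% h, 1)
  cmp <- compare_beta_orientation(V, 1, n_runs = 2, seed = 3)
  expect_equal(nrow(cmp$matching), 1)
})
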