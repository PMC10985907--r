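# Methylation-signature extraction by nonnegative matrix factorization.
# V (probes x samples) ~ E (probes x k) %*% H (k x samples); E holds
# per-probe signature weights (column-normalized to sum to 1), H per-sample
# activities. Factorization is multiplicative-update NMF (generalized
# Kullback-Leibler objective by default, Frobenius optional), best objective
# over n_runs random restarts; rank is selected from consensus-clustering
# diagnostics (cophenetic correlation + average silhouette width).

#' Nonnegative matrix factorization of a methylation matrix
#'
#' Runs `n_runs` multiplicative-update factorizations from random nonnegative
#' initializations (one derived sub-seed per run) and keeps the run with the
#' lowest objective. The returned model is column-normalized: each E column
#' sums to 1 with the scale moved into the matching H row, leaving `E %*% H`
#' unchanged.
#'
#' @param V nonnegative matrix (probes x samples) or a [beta_matrix].
#' @param k rank (number of signatures), `1 <= k <= min(dim(V))`.
#' @param n_runs random restarts (default 30).
#' @param seed integer master seed; run r uses sub-stream `nmf_run_<r>`.
#' @param objective `"kl"` (generalized Kullback-Leibler, default) or
#'   `"frobenius"`.
#' @param orientation `"beta"` or `"one_minus_beta"`; with the latter, `1 - V`
#'   is factorized (methylation-loss signatures).
#' @param max_iter,tol update-loop limits: at most `max_iter` iterations,
#'   stopping when the relative objective decrease over 10 iterations falls
#'   below `tol`.
#' @return `meth_nmf` object with elements `E`, `H`, `k`, `objective`,
#'   `objective_value`, `rel_error` (relative Frobenius reconstruction error),
#'   `orientation`, `n_runs`, `seed`, `trace` (objective values of the best
#'   run).
#' @export
meth_nmf <- function(V, k, n_runs = 30L, seed = 1L,
                     objective = c("kl", "frobenius"),
                     orientation = c("beta", "one_minus_beta"),
                     max_iter = 500L, tol = 1e-6) {
  objective <- match.arg(objective)
  orientation <- match.arg(orientation)
  if (inherits(V, "beta_matrix")) V <- V$values
  V <- as.matrix(V)
  if (any(V < 0)) stop("V must be nonnegative")
  if (orientation == "one_minus_beta") {
    if (max(V) > 1) stop("one_minus_beta orientation needs V in [0, 1]")
    V <- 1 - V
  }
  if (all(V == 0)) stop("all-zero matrix cannot be factorized")
  k <- as.integer(k)
  if (k < 1L || k > min(dim(V))) stop("k must lie in 1..min(dim(V))")

  best <- NULL
  scale0 <- sqrt(mean(V) / k)
  for (r in seq_len(n_runs)) {
    set.seed(substream_seed(seed, paste0("nmf_run_", r)))
    E0 <- matrix(runif(nrow(V) * k, 0.1, 1) * scale0, nrow(V), k)
    H0 <- matrix(runif(k * ncol(V), 0.1, 1) * scale0, k, ncol(V))
    fit <- .nmf_mu_cpp(V, E0, H0, as.integer(max_iter), tol, objective)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  E <- best$E; H <- best$H
  dimnames(E) <- list(rownames(V), paste0("Sig", seq_len(k)))
  dimnames(H) <- list(paste0("Sig", seq_len(k)), colnames(V))
  m <- structure(list(E = E, H = H, k = k, objective = objective,
                      objective_value = best$objective,
                      rel_error = norm(V - E %*% H, "F") / norm(V, "F"),
                      orientation = orientation, n_runs = as.integer(n_runs),
                      seed = as.integer(seed), trace = best$trace,
                      iterations = best$iterations),
                 class = "meth_nmf")
  normalize_model(m)
}

#' Rescale a signature model so every E column sums to one
#'
#' Divides each column of E by its sum and multiplies the matching H row by
#' the same factor; `E %*% H` is unchanged. Idempotent.
#'
#' @param m a `meth_nmf` model (or any list with E and H).
#' @return The normalized model.
#' @export
normalize_model <- function(m) {
  cs <- colSums(m$E)
  if (any(cs == 0)) stop("all-zero signature column; cannot normalize")
  m$E <- sweep(m$E, 2, cs, "/")
  m$H <- sweep(m$H, 1, cs, "*")
  m
}

#' @export
print.meth_nmf <- function(x, ...) {
  cat(sprintf("meth_nmf: k = %d signatures over %d probes x %d samples (%s orientation)\n",
              x$k, nrow(x$E), ncol(x$H), x$orientation))
  cat(sprintf("  objective (%s): %.6g after %d iterations (best of %d runs); rel. reconstruction error %.4f\n",
              x$objective, x$objective_value, x$iterations, x$n_runs,
              x$rel_error))
  invisible(x)
}

#' @export
#' @method coef meth_nmf
coef.meth_nmf <- function(object, ...) object$E

#' @export
fitted.meth_nmf <- function(object, ...) object$E %*% object$H

#' @export
summary.meth_nmf <- function(object, ...) {
  asg <- assign_dmps_and_samples(object)
  out <- list(k = object$k, dims = c(nrow(object$E), ncol(object$H)),
              rel_error = object$rel_error,
              probes_per_signature = table(asg$probe_assignment),
              samples_per_signature = table(asg$sample_assignment))
  class(out) <- "summary.meth_nmf"
  out
}

#' @export
print.summary.meth_nmf <- function(x, ...) {
  cat(sprintf("Signature model: k = %d, %d probes x %d samples, rel. error %.4f\n",
              x$k, x$dims[1], x$dims[2], x$rel_error))
  cat("Probes per signature:\n"); print(x$probes_per_signature)
  cat("Samples per signature:\n"); print(x$samples_per_signature)
  invisible(x)
}

#' Assign probes and samples to signatures
#'
#' Each probe goes to the signature with the largest weight in its E row and
#' each sample to the signature with the largest activity in its H column
#' (ties break toward the lowest signature index). Also reports each
#' signature's top-weighted probes (its up-/down-DMPs, depending on the
#' factorization orientation).
#'
#' @param m a normalized `meth_nmf` model.
#' @param top_n how many top probes to report per signature (default 25).
#' @return list with `probe_assignment`, `sample_assignment` (named integer
#'   vectors) and `top_probes` (list of character vectors per signature).
#' @export
assign_dmps_and_samples <- function(m, top_n = 25L) {
  probe_assignment <- apply(m$E, 1, which.max)
  sample_assignment <- apply(m$H, 2, which.max)
  top_probes <- lapply(seq_len(m$k), function(s) {
    w <- m$E[, s]
    names(sort(w, decreasing = TRUE))[seq_len(min(top_n, length(w)))]
  })
  names(top_probes) <- colnames(m$E)
  list(probe_assignment = probe_assignment,
       sample_assignment = sample_assignment, top_probes = top_probes)
}

#' Consensus-clustering rank survey
#'
#' For each candidate rank, runs `n_runs` factorizations, assigns samples to
#' signatures by maximal activity, and averages the co-assignment indicator
#' into a consensus matrix. Reports the cophenetic correlation between
#' consensus dissimilarities (1 - consensus) and the cophenetic distances of
#' their average-linkage dendrogram, plus the average silhouette width of the
#' k-cut of that dendrogram against the consensus dissimilarity (undefined at
#' k = 1 and recorded as `NA`).
#'
#' @inheritParams meth_nmf
#' @param k_range integer vector of candidate ranks.
#' @param max_iter,tol per-run update limits (survey runs may use looser
#'   limits than the final fit).
#' @return `rank_diagnostics`: data.frame with `k`, `cophenetic`,
#'   `silhouette`, plus the chosen rank from [select_rank()] as attribute
#'   `chosen_k` and the consensus matrices as attribute `consensus`.
#' @export
rank_survey <- function(V, k_range = 2:6, n_runs = 30L, seed = 1L,
                        objective = c("kl", "frobenius"),
                        orientation = c("beta", "one_minus_beta"),
                        max_iter = 100L, tol = 1e-4) {
  objective <- match.arg(objective)
  orientation <- match.arg(orientation)
  if (n_runs < 2L) stop("consensus undefined for n_runs < 2")
  if (inherits(V, "beta_matrix")) V <- V$values
  if (!length(k_range)) stop("empty k_range")
  if (any(k_range < 1L | k_range > min(dim(V))))
    stop("k_range outside 1..min(dim(V))")

  n <- ncol(V)
  res <- data.frame(k = as.integer(k_range), cophenetic = NA_real_,
                    silhouette = NA_real_)
  consensus_list <- list()
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    C <- matrix(0, n, n)
    for (r in seq_len(n_runs)) {
      fit <- meth_nmf(V, k, n_runs = 1L,
                      seed = substream_seed(seed, sprintf("survey_k%d_r%d", k, r)),
                      objective = objective, orientation = orientation,
                      max_iter = max_iter, tol = tol)
      a <- apply(fit$H, 2, which.max)
      C <- C + outer(a, a, "==")
    }
    C <- C / n_runs
    consensus_list[[as.character(k)]] <- C
    d <- as.dist(1 - C)
    hc <- hclust(d, method = "average")
    cd <- cophenetic(hc)
    res$cophenetic[i] <- if (sd(d) == 0 || sd(cd) == 0) 1 else cor(d, cd)
    if (k >= 2) {
      cl <- cutree(hc, k = min(k, n))
      if (length(unique(cl)) >= 2) {
        sil <- cluster::silhouette(cl, d)
        res$silhouette[i] <- mean(sil[, "sil_width"])
      }
    }
  }
  structure(res, class = c("rank_diagnostics", "data.frame"),
            chosen_k = select_rank(res), consensus = consensus_list)
}

#' Select the signature rank from consensus diagnostics
#'
#' Candidates are ranks whose cophenetic correlation and average silhouette
#' width both meet the floors (a missing silhouette, as at k = 1, excludes
#' the rank). If the cophenetic profile shows a sustained drop (a value more
#' than `drop` below the running maximum), the chosen rank is the largest
#' candidate before the first drop. With no drop the cophenetic profile does
#' not discriminate — consensus clustering by maximal activity stays stable
#' above the true rank because surplus signatures rarely win the argmax — and
#' the choice falls to the candidate with the highest silhouette width (the
#' k-cut quality degrades once the cut splits real blocks), with exact ties
#' breaking toward the smallest k. If nothing passes the floors, the rank
#' with the highest cophenetic value is returned with a warning.
#'
#' @param d a `rank_diagnostics` data.frame (columns k, cophenetic,
#'   silhouette).
#' @param cophenetic_floor,silhouette_floor minimum acceptable diagnostics
#'   (defaults 0.95 and 0.80).
#' @param drop sustained-drop margin on the cophenetic profile (default 0.05).
#' @return The chosen rank (integer).
#' @export
select_rank <- function(d, cophenetic_floor = 0.95, silhouette_floor = 0.80,
                        drop = 0.05) {
  stopifnot(all(c("k", "cophenetic", "silhouette") %in% names(d)))
  d <- d[order(d$k), , drop = FALSE]
  pass <- !is.na(d$cophenetic) & d$cophenetic >= cophenetic_floor &
    !is.na(d$silhouette) & d$silhouette >= silhouette_floor
  run_max <- cummax(ifelse(is.na(d$cophenetic), -Inf, d$cophenetic))
  drop_at <- which(d$cophenetic < c(-Inf, run_max[-length(run_max)]) - drop)
  before_drop <- if (length(drop_at)) seq_len(min(drop_at) - 1L)
                 else seq_len(nrow(d))
  cand <- intersect(which(pass), before_drop)
  if (!length(cand)) {
    warning("no rank passes the diagnostic floors; returning argmax cophenetic")
    return(d$k[which.max(d$cophenetic)])
  }
  if (length(drop_at)) return(d$k[max(cand)])
  best_sil <- max(d$silhouette[cand])
  d$k[cand[which(d$silhouette[cand] == best_sil)[1]]]
}

#' Cosine and Spearman similarity between two signature weight sets
#'
#' Aligns the two models on their shared probes, computes pairwise cosine
#' similarity and Spearman correlation between weight columns, and matches
#' signatures greedily by descending cosine with each signature used once.
#'
#' @param E1,E2 probes x k weight matrices with probe ids as row names.
#' @return list with `cosine` (k1 x k2), `spearman` (k1 x k2), and `matching`
#'   (data.frame sig1, sig2, cosine, spearman).
#' @export
signature_similarity <- function(E1, E2) {
  shared <- intersect(rownames(E1), rownames(E2))
  if (!length(shared)) stop("empty probe intersection")
  A <- E1[shared, , drop = FALSE]; B <- E2[shared, , drop = FALSE]
  cs <- cosine_columns(A, B)
  sp <- cor(A, B, method = "spearman")
  m <- matrix(cs, nrow(cs), ncol(cs))
  pairs <- list()
  for (step in seq_len(min(dim(cs)))) {
    ij <- which(m == max(m), arr.ind = TRUE)[1, ]
    pairs[[step]] <- data.frame(sig1 = rownames(cs)[ij[1]] %||% ij[1],
                                sig2 = colnames(cs)[ij[2]] %||% ij[2],
                                cosine = cs[ij[1], ij[2]],
                                spearman = sp[ij[1], ij[2]],
                                stringsAsFactors = FALSE)
    m[ij[1], ] <- -Inf; m[, ij[2]] <- -Inf
  }
  list(cosine = cs, spearman = sp, matching = do.call(rbind, pairs))
}

#' Project fixed signature weights onto a new cohort
#'
#' Per-sample nonnegative least squares: each new sample's activity vector is
#' `argmin_{h >= 0} ||E h - v||_2`. Rows are aligned on shared probes; the
#' call errors when fewer than `min_probe_frac` of E's probes are present.
#'
#' @param V_new nonnegative matrix (probes x samples) or [beta_matrix].
#' @param E probes x k weight matrix with probe-id row names.
#' @param min_probe_frac minimum fraction of E's probes required (default
#'   0.5).
#' @return k x samples activity matrix; the number of dropped probes is
#'   attached as attribute `n_dropped`.
#' @export
project_signatures <- function(V_new, E, min_probe_frac = 0.5) {
  if (inherits(V_new, "beta_matrix")) V_new <- V_new$values
  V_new <- as.matrix(V_new)
  if (is.null(rownames(E)) || is.null(rownames(V_new))) {
    if (nrow(E) != nrow(V_new))
      stop("without probe ids, V_new must have exactly E's probe rows")
    Es <- as.matrix(E); Vs <- V_new
    shared <- seq_len(nrow(E))
  } else {
    shared <- intersect(rownames(E), rownames(V_new))
    if (length(shared) < min_probe_frac * nrow(E))
      stop(sprintf("only %d of %d signature probes present (< %g%%)",
                   length(shared), nrow(E), 100 * min_probe_frac))
    Es <- as.matrix(E)[shared, , drop = FALSE]
    Vs <- V_new[shared, , drop = FALSE]
  }
  H <- matrix(0, ncol(Es), ncol(Vs),
              dimnames = list(colnames(E), colnames(V_new)))
  for (i in seq_len(ncol(Vs)))
    H[, i] <- pracma::lsqnonneg(Es, Vs[, i])$x
  attr(H, "n_dropped") <- nrow(E) - length(shared)
  H
}

#' @export
#' @method predict meth_nmf
#' @describeIn project_signatures `predict()` method: project a fitted
#'   signature model onto new data (defaults to the training activities when
#'   `newdata` is missing).
predict.meth_nmf <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$H)
  V <- if (inherits(newdata, "beta_matrix")) newdata$values else newdata
  if (object$orientation == "one_minus_beta") V <- 1 - V
  project_signatures(V, object$E, ...)
}

#' Compare factorizations of beta against 1 - beta
#'
#' Factorizes both V and 1 - V at the same rank, matches signatures across
#' orientations by cosine similarity of their activity rows, and reports the
#' per-pair Spearman correlation of activities. High |correlation| indicates
#' the two orientations recover the same sample-level structure.
#'
#' @inheritParams meth_nmf
#' @return list with the two models, and `matching` (data.frame sig_beta,
#'   sig_one_minus, cosine, spearman). A constant V is flagged degenerate and
#'   correlations are reported missing.
#' @export
compare_beta_orientation <- function(V, k, n_runs = 10L, seed = 1L,
                                     objective = c("kl", "frobenius"),
                                     max_iter = 500L, tol = 1e-6) {
  objective <- match.arg(objective)
  if (inherits(V, "beta_matrix")) V <- V$values
  if (max(V) > 1 || min(V) < 0) stop("V must lie in [0, 1]")
  if (sd(as.numeric(V)) == 0) {
    warning("constant matrix; orientation comparison is degenerate")
    return(list(fit_beta = NULL, fit_one_minus = NULL,
                matching = data.frame(sig_beta = character(0),
                                      sig_one_minus = character(0),
                                      cosine = numeric(0),
                                      spearman = numeric(0))))
  }
  f1 <- meth_nmf(V, k, n_runs = n_runs, seed = seed, objective = objective,
                 orientation = "beta", max_iter = max_iter, tol = tol)
  f2 <- meth_nmf(V, k, n_runs = n_runs, seed = seed, objective = objective,
                 orientation = "one_minus_beta", max_iter = max_iter,
                 tol = tol)
  cs <- cosine_columns(t(f1$H), t(f2$H))
  m <- cs
  pairs <- list()
  for (step in seq_len(k)) {
    ij <- which(m == max(m), arr.ind = TRUE)[1, ]
    rho <- suppressWarnings(cor(f1$H[ij[1], ], f2$H[ij[2], ],
                                method = "spearman"))
    pairs[[step]] <- data.frame(sig_beta = rownames(f1$H)[ij[1]],
                                sig_one_minus = rownames(f2$H)[ij[2]],
                                cosine = cs[ij[1], ij[2]], spearman = rho,
                                stringsAsFactors = FALSE)
    m[ij[1], ] <- -Inf; m[, ij[2]] <- -Inf
  }
  list(fit_beta = f1, fit_one_minus = f2,
       matching = do.call(rbind, pairs))
}

#' Per-signature sample proportions by cancer type
#'
#' Shares of each cancer type among the samples assigned to each signature.
#'
#' @param m a `meth_nmf` model.
#' @param cancer_types per-sample cancer-type labels aligned to `m$H` columns.
#' @return data.frame signature x cancer_type with counts and fractions.
#' @export
signature_sample_proportions <- function(m, cancer_types) {
  a <- assign_dmps_and_samples(m)$sample_assignment
  tb <- table(signature = colnames(m$E)[a], cancer_type = cancer_types)
  df <- as.data.frame(tb, stringsAsFactors = FALSE)
  tot <- rowsum(df$Freq, df$signature)
  df$fraction <- df$Freq / tot[df$signature, 1]
  names(df)[names(df) == "Freq"] <- "count"
  df
}

#' @export
plot.meth_nmf <- function(x, type = c("activities", "weights"), ...) {
  type <- match.arg(type)
  if (type == "activities") {
    graphics::barplot(x$H, beside = FALSE, col = seq_len(x$k) + 1,
                      border = NA, xlab = "sample", ylab = "activity",
                      main = sprintf("Signature activities (k = %d)", x$k),
                      names.arg = rep("", ncol(x$H)), ...)
    graphics::legend("topright", legend = rownames(x$H),
                     fill = seq_len(x$k) + 1, bty = "n", cex = 0.8)
  } else {
    graphics::matplot(x$E, type = "h", lty = 1, col = seq_len(x$k) + 1,
                      xlab = "probe index", ylab = "weight",
                      main = "Signature probe weights", ...)
  }
  invisible(x)
}
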