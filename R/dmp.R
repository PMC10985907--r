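# Conserved DMP calling. Per probe, the tissue effect is assessed in the
# linear model
#   beta = b0 + b1*TY + b2*CY + b3*(TY:CY) + TO + e
# where TY is tissue type (tumor = 1), CY cancer type, and TO the tissue
# origin, modeled as the patient blocking factor of the matched design (TO
# absorbs the CY main effects, which are constant within a patient). The
# statistic fed to the permutation null is the joint F for the tissue-effect
# columns (TY and all TY:CY interactions); with a single cancer type it
# reduces to |t| of TY. Significance comes from a within-pair label-swap
# permutation null with the add-one empirical P estimator.

# Design matrices for the probe model. Returns the full model (patient
# blocks + TY + TY:CY), the reduced model (patient blocks only), and the
# tissue-effect column indices.
build_dmp_design <- function(samples) {
  if (!all(c("tumor", "normal") %in% samples$tissue_type))
    stop("design needs both tissue types")
  patient <- factor(samples$patient_id)
  ty <- as.numeric(samples$tissue_type == "tumor")
  cy <- factor(samples$cancer_type)
  Xr <- stats::model.matrix(~ 0 + patient)
  colnames(Xr) <- paste0("TO_", levels(patient))
  tissue_cols <- cbind(TY = ty)
  if (nlevels(cy) > 1) {
    inter <- stats::model.matrix(~ 0 + cy)[, -1, drop = FALSE] * ty
    colnames(inter) <- paste0("TY:CY_", levels(cy)[-1])
    tissue_cols <- cbind(tissue_cols, inter)
  }
  Xf <- cbind(Xr, tissue_cols)
  qf <- qr(Xf)
  if (qf$rank < ncol(Xf)) {
    aliased <- colnames(Xf)[qf$pivot[seq.int(qf$rank + 1L, ncol(Xf))]]
    stop("rank-deficient design; aliased term(s): ",
         paste(aliased, collapse = ", "))
  }
  list(X_full = Xf, X_reduced = Xr,
       df1 = ncol(tissue_cols), df2 = nrow(Xf) - ncol(Xf),
       n_tissue_cols = ncol(tissue_cols),
       single_cancer_type = nlevels(cy) == 1)
}

# residual sums of squares of Y (samples x probes) under an orthonormal basis
.rss <- function(Q, Y) {
  pmax(colSums(Y^2) - colSums(crossprod(Q, Y)^2), 0)
}

# joint tissue-effect statistic for a samples x probes matrix.
# F = ((RSS_r - RSS_f)/df1) / (RSS_f/df2); zero residual -> sentinel 1e12.
.tissue_stat <- function(Qf, Qr, Y, df1, df2, single_ct) {
  rss_f <- .rss(Qf, Y); rss_r <- .rss(Qr, Y)
  num <- pmax(rss_r - rss_f, 0)
  stat <- numeric(ncol(Y))
  zero_num <- num <= 1e-12
  zero_den <- rss_f <= 1e-12
  ok <- !zero_num & !zero_den
  stat[ok] <- (num[ok] / df1) / (rss_f[ok] / df2)
  stat[!zero_num & zero_den] <- 1e12
  if (single_ct) stat <- sqrt(stat)  # |t| of TY when df1 == 1
  stat
}

#' Fit the per-probe tissue-effect model
#'
#' Least-squares fit of one probe's beta values on tissue type, cancer type,
#' their interaction and the patient blocking factor; returns the statistic
#' used by the permutation test together with the full-model coefficients.
#'
#' @param probe_values numeric vector, one beta per sample.
#' @param samples sample sheet rows aligned to `probe_values`.
#' @return list with `stat` (joint tissue-effect F, or |t| of TY for a single
#'   cancer type; residual-free fits return the sentinel 1e12 or its square
#'   root), `coefficients` (full-model least-squares solution), `effect` (TY
#'   coefficient), and the design.
#' @export
fit_probe_model <- function(probe_values, samples) {
  d <- build_dmp_design(samples)
  y <- matrix(probe_values, ncol = 1)
  qf <- qr(d$X_full)
  beta <- qr.coef(qf, y)[, 1]
  Qf <- qr.Q(qr(d$X_full)); Qr <- qr.Q(qr(d$X_reduced))
  stat <- .tissue_stat(Qf, Qr, y, d$df1, d$df2, d$single_cancer_type)
  list(stat = stat, coefficients = beta, effect = unname(beta["TY"]),
       design = d)
}

#' Within-pair permutation null for the tissue effect
#'
#' For each of `n_perm` rounds the tumor/normal roles are swapped
#' independently per pair with probability 1/2 (the same swap pattern applied
#' to every probe, preserving inter-probe correlation), the tissue-effect
#' statistic is recomputed, and the empirical P per probe is the add-one
#' estimator `(1 + #{permuted >= observed}) / (1 + n_perm)`, so the smallest
#' attainable P is `1/(n_perm + 1)`.
#'
#' @param m a paired [beta_matrix] (every tumor needs a matched normal).
#' @param n_perm permutation rounds (>= 1; default 1000).
#' @param seed integer seed.
#' @return data.frame with `probe_id`, `obs_stat`, `p_emp`; `n_perm` kept as
#'   an attribute.
#' @export
permutation_null <- function(m, n_perm = 1000L, seed = 1L) {
  stopifnot(n_perm >= 1L)
  pairs <- paired_index(m)
  d <- build_dmp_design(m$samples)
  Qf <- qr.Q(qr(d$X_full)); Qr <- qr.Q(qr(d$X_reduced))
  Y <- t(m$values)
  obs <- .tissue_stat(Qf, Qr, Y, d$df1, d$df2, d$single_cancer_type)

  set.seed(seed)
  n <- nrow(Y)
  count <- numeric(ncol(Y))
  base_idx <- seq_len(n)
  for (r in seq_len(n_perm)) {
    swap <- runif(nrow(pairs)) < 0.5
    idx <- base_idx
    idx[pairs$tumor[swap]] <- pairs$normal[swap]
    idx[pairs$normal[swap]] <- pairs$tumor[swap]
    stat_p <- .tissue_stat(Qf, Qr, Y[idx, , drop = FALSE],
                           d$df1, d$df2, d$single_cancer_type)
    count <- count + (stat_p >= obs)
  }
  out <- data.frame(probe_id = rownames(m$values), obs_stat = obs,
                    p_emp = (1 + count) / (1 + n_perm),
                    stringsAsFactors = FALSE)
  attr(out, "n_perm") <- as.integer(n_perm)
  out
}

#' Per-pair and median delta-beta
#'
#' Delta-beta of a probe in a pair is the tumor beta minus the matched normal
#' beta; the probe's effect estimate is the median over pairs.
#'
#' @param m a paired [beta_matrix].
#' @return list with `median` (per-probe median delta-beta) and `per_pair`
#'   (probes x pairs matrix of per-pair differences).
#' @export
compute_delta_beta <- function(m) {
  pairs <- paired_index(m)
  if (!nrow(pairs)) stop("no tumor/normal pairs")
  dd <- m$values[, pairs$tumor, drop = FALSE] -
    m$values[, pairs$normal, drop = FALSE]
  colnames(dd) <- pairs$patient_id
  list(median = apply(dd, 1, median), per_pair = dd)
}

#' Mirrored-percentile delta-beta thresholds
#'
#' The conservation cutoff for hyper-DMPs is the magnitude of the lower
#' `percentile` quantile of the pooled per-pair delta-beta values of all
#' poised hyper-DMPs (the "5% extreme of low methylation"); the hypo cutoff
#' mirrors it with the upper quantile of the poised hypo pool. Quantiles use
#' the linear-interpolation definition.
#'
#' @param per_pair_deltas_hyper,per_pair_deltas_hypo pooled per-pair
#'   delta-beta values over the poised hyper- / hypo-DMPs (vectors or
#'   matrices; flattened).
#' @param percentile tail fraction in (0, 0.5); default 0.05.
#' @return `delta_beta_thresholds`: list with positive `hyper_threshold`,
#'   negative `hypo_threshold`, and `percentile`.
#' @export
derive_thresholds <- function(per_pair_deltas_hyper, per_pair_deltas_hypo,
                              percentile = 0.05) {
  if (!length(per_pair_deltas_hyper) || !length(per_pair_deltas_hypo))
    stop("nonempty delta-beta pools required")
  if (percentile <= 0 || percentile >= 0.5)
    stop("percentile must lie in (0, 0.5)")
  q_lo <- quantile(as.numeric(per_pair_deltas_hyper), percentile,
                   names = FALSE, type = 7)
  if (q_lo >= 0)
    warning("lower quantile of the hyper pool is nonnegative; ",
            "the mirror rule degenerates to a plain quantile cutoff")
  q_hi <- quantile(as.numeric(per_pair_deltas_hypo), 1 - percentile,
                   names = FALSE, type = 7)
  if (q_hi <= 0)
    warning("upper quantile of the hypo pool is nonpositive; ",
            "the mirror rule degenerates to a plain quantile cutoff")
  structure(list(hyper_threshold = abs(q_lo), hypo_threshold = -abs(q_hi),
                 percentile = percentile),
            class = "delta_beta_thresholds")
}

#' @export
print.delta_beta_thresholds <- function(x, ...) {
  cat(sprintf("delta-beta thresholds (mirrored %g%% rule): hyper > %.4f, hypo < %.4f\n",
              100 * x$percentile, x$hyper_threshold, x$hypo_threshold))
  invisible(x)
}

#' Flag poised and conserved DMPs
#'
#' A probe is poised when its empirical permutation P is below `p_threshold`;
#' direction is the sign of the median delta-beta (exact zeros fall in the
#' hypo branch and can never be conserved). Conserved hyper-DMPs are poised
#' probes with median delta-beta strictly above the hyper threshold; conserved
#' hypo-DMPs mirror this below the (negative) hypo threshold.
#'
#' @param tab data.frame with `p_emp` and `median_delta_beta` populated.
#' @param thr a [derive_thresholds()] result.
#' @param p_threshold poised cutoff (default 0.001).
#' @return `tab` with `direction`, `poised`, `conserved` columns filled.
#' @export
select_conserved <- function(tab, thr, p_threshold = 0.001) {
  stopifnot(all(c("p_emp", "median_delta_beta") %in% names(tab)))
  n_perm <- attr(tab, "n_perm")
  if (!is.null(n_perm) && 1 / (1 + n_perm) >= p_threshold)
    warning(sprintf(
      "minimum attainable empirical P is 1/%d = %.4g >= p_threshold %g; no probe can be poised",
      n_perm + 1L, 1 / (1 + n_perm), p_threshold))
  tab$direction <- ifelse(tab$median_delta_beta > 0, "hyper", "hypo")
  tab$poised <- tab$p_emp < p_threshold
  tab$conserved <- tab$poised &
    ((tab$direction == "hyper" & tab$median_delta_beta > thr$hyper_threshold) |
     (tab$direction == "hypo" & tab$median_delta_beta < thr$hypo_threshold))
  tab
}

#' Genomic-context summary of conserved DMPs
#'
#' Per direction, the fractions of conserved DMPs across CpG-island relation
#' and genomic region categories (each family of fractions sums to 1).
#'
#' @param tab DMP table with `conserved` and `direction` set.
#' @param annotation probe annotation covering every conserved DMP.
#' @return data.frame with `direction`, `family` (`island_relation` or
#'   `region`), `category`, `count`, `fraction`.
#' @export
annotate_dmp_context <- function(tab, annotation) {
  keep <- tab[tab$conserved, , drop = FALSE]
  if (!nrow(keep))
    return(data.frame(direction = character(0), family = character(0),
                      category = character(0), count = integer(0),
                      fraction = numeric(0), stringsAsFactors = FALSE))
  hit <- match(keep$probe_id, annotation$probe_id)
  if (anyNA(hit))
    stop("unannotated DMP(s): ",
         paste(utils::head(keep$probe_id[is.na(hit)], 5), collapse = ", "))
  ann <- annotation[hit, , drop = FALSE]
  out <- list()
  for (dir in unique(keep$direction)) {
    sel <- keep$direction == dir
    for (fam in c("island_relation", "region")) {
      tb <- table(ann[[fam]][sel])
      out[[length(out) + 1L]] <- data.frame(
        direction = dir, family = fam, category = names(tb),
        count = as.integer(tb), fraction = as.numeric(tb) / sum(tb),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Call conserved DMPs from a paired cohort
#'
#' The full DMP workflow: per-probe tissue-effect statistics, the within-pair
#' permutation null, median delta-beta, mirrored-percentile thresholds derived
#' from the poised sets, and the conserved flags.
#'
#' @param m a paired, QC'd [beta_matrix].
#' @param n_perm permutation rounds (default 1000).
#' @param p_threshold poised cutoff on the empirical P (default 0.001).
#' @param percentile threshold tail fraction (default 0.05).
#' @param threshold_source `"per_pair"` pools per-pair delta-beta values of
#'   the poised probes (default); `"median"` uses the distribution of their
#'   median delta-beta instead.
#' @param seed integer seed for the permutation stream.
#' @return `dmp_fit` object: `table` (probe_id, obs_stat, p_emp,
#'   median_delta_beta, direction, poised, conserved), `thresholds`,
#'   `context` (genomic-context summary when annotation is attached), and the
#'   call parameters.
#' @export
dmp_call <- function(m, n_perm = 1000L, p_threshold = 0.001,
                     percentile = 0.05,
                     threshold_source = c("per_pair", "median"), seed = 1L) {
  threshold_source <- match.arg(threshold_source)
  tab <- permutation_null(m, n_perm = n_perm, seed = seed)
  db <- compute_delta_beta(m)
  tab$median_delta_beta <- db$median
  poised <- tab$p_emp < p_threshold
  hyper_p <- poised & db$median > 0
  hypo_p <- poised & db$median <= 0
  if (!any(hyper_p) || !any(hypo_p)) {
    warning("empty poised set in at least one direction; ",
            "falling back to fixed thresholds +/-0.1")
    thr <- structure(list(hyper_threshold = 0.1, hypo_threshold = -0.1,
                          percentile = percentile),
                     class = "delta_beta_thresholds")
  } else if (threshold_source == "per_pair") {
    thr <- derive_thresholds(db$per_pair[hyper_p, , drop = FALSE],
                             db$per_pair[hypo_p, , drop = FALSE], percentile)
  } else {
    thr <- derive_thresholds(db$median[hyper_p], db$median[hypo_p],
                             percentile)
  }
  tab <- select_conserved(tab, thr, p_threshold)
  ctx <- if (!is.null(m$annotation))
    annotate_dmp_context(tab, m$annotation) else NULL
  structure(list(table = tab, thresholds = thr, context = ctx,
                 n_perm = as.integer(n_perm), p_threshold = p_threshold,
                 percentile = percentile, threshold_source = threshold_source,
                 n_pairs = nrow(paired_index(m)), seed = seed),
            class = "dmp_fit")
}

#' @export
print.dmp_fit <- function(x, ...) {
  tb <- x$table
  cat(sprintf("dmp_fit: %d probes, %d pairs, %d permutations\n",
              nrow(tb), x$n_pairs, x$n_perm))
  cat(sprintf("  poised (P < %g): %d  |  conserved hyper: %d, conserved hypo: %d\n",
              x$p_threshold, sum(tb$poised),
              sum(tb$conserved & tb$direction == "hyper"),
              sum(tb$conserved & tb$direction == "hypo")))
  print(x$thresholds)
  invisible(x)
}

#' @export
summary.dmp_fit <- function(object, ...) {
  tb <- object$table
  out <- list(
    n_probes = nrow(tb), n_pairs = object$n_pairs,
    n_poised = sum(tb$poised),
    n_conserved_hyper = sum(tb$conserved & tb$direction == "hyper"),
    n_conserved_hypo = sum(tb$conserved & tb$direction == "hypo"),
    thresholds = object$thresholds,
    min_attainable_p = 1 / (1 + object$n_perm),
    context = object$context)
  class(out) <- "summary.dmp_fit"
  out
}

#' @export
print.summary.dmp_fit <- function(x, ...) {
  cat(sprintf("Conserved DMP calling on %d probes, %d pairs\n",
              x$n_probes, x$n_pairs))
  cat(sprintf("  poised: %d; conserved: %d hyper / %d hypo; min attainable P = %.4g\n",
              x$n_poised, x$n_conserved_hyper, x$n_conserved_hypo,
              x$min_attainable_p))
  print(x$thresholds)
  if (!is.null(x$context) && nrow(x$context)) {
    cat("Genomic context of conserved DMPs:\n")
    print(x$context, row.names = FALSE)
  }
  invisible(x)
}
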