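# Clinical and immune associations of signature activities: median-split
# survival (Cox), Wilcoxon contrasts, per-cancer Spearman meta-effects,
# tissue-origin variance attribution, the ICI multivariate response model,
# and the gene-expression surrogate (GES) of an activity for
# transcriptome-only cohorts.

#' Median split of activities
#'
#' `high` means strictly above the median; values at or below the median
#' (including exact ties) are `low`. Stratification (e.g. per cancer type) is
#' the caller's job: pass one stratum at a time.
#'
#' @param activity numeric vector, length >= 2.
#' @return factor with levels `low`, `high`.
#' @export
median_split <- function(activity) {
  if (length(activity) < 2) stop("need >= 2 samples to split")
  if (sd(activity) == 0) stop("degenerate split: constant activity")
  factor(ifelse(activity > median(activity), "high", "low"),
         levels = c("low", "high"))
}

#' Cox proportional-hazards contrast between activity groups
#'
#' Fits a proportional-hazards model with the binary group as its only
#' covariate (Breslow tie handling); the hazard ratio is high vs low with the
#' Wald test P.
#'
#' @param groups factor from [median_split()] (reference = first level).
#' @param os_time,os_event survival time and event indicator (1 = death).
#' @return list with `hr`, `ci` (95% Wald), `p`, `coef`, `n_event`.
#' @export
cox_survival <- function(groups, os_time, os_event) {
  groups <- as.factor(groups)
  ev <- tapply(os_event, groups, sum)
  if (any(is.na(ev)) || any(ev < 1))
    stop("each group needs at least one event")
  fit <- coxph(Surv(os_time, os_event) ~ groups, ties = "breslow")
  b <- coef(fit)[1]
  se <- sqrt(stats::vcov(fit)[1, 1])
  list(hr = exp(unname(b)),
       ci = exp(unname(b) + c(-1, 1) * qnorm(0.975) * se),
       p = unname(2 * pnorm(-abs(b / se))),
       coef = unname(b), n_event = sum(os_event))
}

#' Two-group Wilcoxon rank-sum comparison
#'
#' Two-sided; exact null when the combined sample is small (n <= 20) and
#' tie-free, tie-corrected normal approximation otherwise.
#'
#' @param values numeric vector.
#' @param labels two-level grouping aligned to `values`.
#' @return list with `statistic` (W), `p`, and the group sizes.
#' @export
group_compare <- function(values, labels) {
  labels <- as.factor(droplevels(as.factor(labels)))
  if (nlevels(labels) != 2) stop("exactly two nonempty groups required")
  a <- values[labels == levels(labels)[1]]
  b <- values[labels == levels(labels)[2]]
  if (!length(a) || !length(b)) stop("one group is empty")
  exact <- (length(a) + length(b)) <= 20 &&
    !any(duplicated(c(a, b)))
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = !exact))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n = c(length(a), length(b)))
}

#' Per-cancer Spearman correlations with an inverse-variance meta-effect
#'
#' Within each cancer type (>= `min_n` samples, both variables non-constant)
#' the Spearman correlation between activity and each feature is computed;
#' the meta-effect combines the per-stratum estimates on the Fisher-z scale
#' with weights `n - 3` and is back-transformed. Meta P values are
#' BH-adjusted across features.
#'
#' @param activity per-sample activities.
#' @param features data.frame or matrix of per-sample feature columns.
#' @param cancer_types per-sample stratum labels.
#' @param min_n minimum usable stratum size (default 4).
#' @return list with `per_stratum` (feature, cancer_type, n, rho) and `meta`
#'   (feature, n_strata, rho_meta, z, p, fdr).
#' @export
time_correlation <- function(activity, features, cancer_types, min_n = 4L) {
  features <- as.data.frame(features)
  per <- list(); meta <- list()
  for (f in names(features)) {
    x <- features[[f]]
    rows <- list()
    for (ct in unique(cancer_types)) {
      sel <- cancer_types == ct & !is.na(x) & !is.na(activity)
      n <- sum(sel)
      if (n < min_n) next
      if (sd(activity[sel]) == 0 || sd(x[sel]) == 0) {
        warning(sprintf("constant values in stratum %s for %s; excluded",
                        ct, f))
        next
      }
      rho <- cor(activity[sel], x[sel], method = "spearman")
      rows[[ct]] <- data.frame(feature = f, cancer_type = ct, n = n,
                               rho = rho, stringsAsFactors = FALSE)
    }
    if (!length(rows)) next
    st <- do.call(rbind, rows)
    per[[f]] <- st
    # Fisher-z inverse-variance combination; rho clamped off the poles
    zi <- atanh(pmin(pmax(st$rho, -0.999999), 0.999999))
    wi <- st$n - 3
    zbar <- sum(wi * zi) / sum(wi)
    se <- 1 / sqrt(sum(wi))
    if (nrow(st) < 2)
      warning(sprintf("single usable stratum for %s; meta-effect is that estimate", f))
    meta[[f]] <- data.frame(feature = f, n_strata = nrow(st),
                            rho_meta = tanh(zbar), z = zbar / se,
                            p = 2 * pnorm(-abs(zbar / se)),
                            stringsAsFactors = FALSE)
  }
  meta_df <- if (length(meta)) do.call(rbind, meta) else
    data.frame(feature = character(0), n_strata = integer(0),
               rho_meta = numeric(0), z = numeric(0), p = numeric(0))
  meta_df$fdr <- p.adjust(meta_df$p, method = "BH")
  rownames(meta_df) <- NULL
  list(per_stratum = if (length(per)) do.call(rbind, c(per, make.row.names = FALSE)) else NULL,
       meta = meta_df)
}

#' Fraction of activity variance attributable to tissue origin
#'
#' One-way decomposition per signature: between-cancer-type sum of squares
#' over total sum of squares.
#'
#' @param H k x samples activity matrix (or a single activity vector).
#' @param cancer_types per-sample labels.
#' @return named numeric vector of variance fractions per signature.
#' @export
variance_attribution <- function(H, cancer_types) {
  if (is.null(dim(H))) H <- matrix(H, 1, dimnames = list("Sig1", NULL))
  g <- factor(cancer_types)
  apply(H, 1, function(a) {
    tot <- sum((a - mean(a))^2)
    if (tot == 0 || nlevels(g) < 2) return(0)
    gm <- tapply(a, g, mean)
    ns <- tabulate(g)
    sum(ns * (gm - mean(a))^2) / tot
  })
}

#' Multivariate model of immunotherapy response
#'
#' Logistic regression (IRLS via `glm`) of binary response on signature
#' score, TP53 mutation status and FOXA1 expression; odds ratios and Wald P
#' per predictor. A linear-probability fit is available for parity with the
#' Gaussian-error formulation.
#'
#' @param response binary response (1/`"responder"` = responder).
#' @param score per-sample signature activity or GES score.
#' @param tp53_status 0/1 mutation status (optional).
#' @param foxa1_expr continuous expression (optional).
#' @param family `"logistic"` (default) or `"linear"`.
#' @return data.frame per predictor: estimate, odds_ratio (logistic only),
#'   se, p.
#' @export
ici_multivariate <- function(response, score, tp53_status = NULL,
                             foxa1_expr = NULL,
                             family = c("logistic", "linear")) {
  family <- match.arg(family)
  y <- if (is.numeric(response)) response
       else as.integer(response == "responder")
  stopifnot(all(y %in% 0:1))
  dat <- data.frame(y = y, score = score)
  if (!is.null(tp53_status)) dat$tp53 <- tp53_status
  if (!is.null(foxa1_expr)) dat$foxa1 <- foxa1_expr
  fml <- stats::as.formula(paste("y ~", paste(setdiff(names(dat), "y"),
                                              collapse = " + ")))
  if (family == "logistic") {
    fit <- glm(fml, data = dat, family = binomial())
    if (!fit$converged || any(abs(coef(fit)) > 20))
      stop("perfect (or quasi-perfect) separation; consider a penalized fit")
    sm <- summary(fit)$coefficients
    data.frame(term = rownames(sm), estimate = sm[, 1],
               odds_ratio = exp(sm[, 1]), se = sm[, 2], p = sm[, 4],
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    fit <- lm(fml, data = dat)
    sm <- summary(fit)$coefficients
    data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
               p = sm[, 4], row.names = NULL, stringsAsFactors = FALSE)
  }
}

#' Derive a gene-expression surrogate (GES) of an activity
#'
#' Ranks genes by |Spearman correlation| with the activity on a training
#' split, keeps the top `n_genes`, and scores a sample as the mean z-scored
#' expression over positively correlated genes minus the mean over negatively
#' correlated genes. Reports the held-out AUC of the score for separating
#' high vs low activity (median split).
#'
#' @param expression samples x genes matrix (z-scoring is per gene, so
#'   per-gene affine rescaling does not change the score).
#' @param activity per-sample activity aligned to `expression` rows.
#' @param n_genes surrogate size (e.g. 156).
#' @param train_frac fraction of samples used for gene selection (default
#'   0.5); the rest evaluates the AUC.
#' @param seed split seed.
#' @return `ges_model`: gene table (gene, rho, direction/weight), `auc`
#'   (held-out), `threshold` (median score of the training samples), and a
#'   `score()`-ready definition via [ges_score()].
#' @export
derive_ges <- function(expression, activity, n_genes = 156L,
                       train_frac = 0.5, seed = 1L) {
  expression <- as.matrix(expression)
  stopifnot(nrow(expression) == length(activity))
  if (n_genes > ncol(expression))
    stop("n_genes exceeds the number of genes")
  set.seed(substream_seed(seed, "ges_split"))
  n <- nrow(expression)
  train <- sample.int(n, max(2, round(train_frac * n)))
  test <- setdiff(seq_len(n), train)

  rho <- suppressWarnings(
    apply(expression[train, , drop = FALSE], 2, cor, y = activity[train],
          method = "spearman"))
  rho[is.na(rho)] <- 0
  sel <- order(abs(rho), decreasing = TRUE)[seq_len(n_genes)]
  genes <- data.frame(gene = colnames(expression)[sel] %||% as.character(sel),
                      rho = rho[sel], weight = sign(rho[sel]),
                      stringsAsFactors = FALSE)
  mu <- colMeans(expression[train, sel, drop = FALSE])
  sdv <- apply(expression[train, sel, drop = FALSE], 2, sd)
  sdv[sdv == 0] <- 1
  model <- structure(list(genes = genes, mu = mu, sd = sdv,
                          n_genes = as.integer(n_genes)),
                     class = "ges_model")
  test_scores <- ges_score(model, expression[test, , drop = FALSE])
  high <- activity[test] > median(activity[test])
  model$auc <- rank_auc(test_scores, high)
  model$threshold <- median(ges_score(model,
                                      expression[train, , drop = FALSE]))
  model
}

#' Score samples with a GES model
#'
#' @param model a `ges_model` from [derive_ges()].
#' @param expression samples x genes matrix containing the model's genes.
#' @return numeric per-sample scores.
#' @export
ges_score <- function(model, expression) {
  expression <- as.matrix(expression)
  g <- model$genes$gene
  miss <- setdiff(g, colnames(expression))
  if (length(miss))
    stop("expression matrix lacks GES gene(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  Z <- sweep(sweep(expression[, g, drop = FALSE], 2, model$mu), 2,
             model$sd, "/")
  pos <- model$genes$weight > 0
  sp <- if (any(pos)) rowMeans(Z[, pos, drop = FALSE]) else 0
  sn <- if (any(!pos)) rowMeans(Z[, !pos, drop = FALSE]) else 0
  sp - sn
}

#' @export
print.ges_model <- function(x, ...) {
  cat(sprintf("ges_model: %d genes (%d positive, %d negative), held-out AUC %.3f\n",
              x$n_genes, sum(x$genes$weight > 0), sum(x$genes$weight < 0),
              x$auc))
  invisible(x)
}

#' Per-group fraction of high-GES cells
#'
#' Fraction of cells whose score is strictly above the threshold, per group;
#' the default threshold is the global median of the scores. Empty groups
#' yield `NA` with a warning.
#'
#' @param scores per-cell GES scores.
#' @param grouping per-cell group labels (lesion/patient/timepoint).
#' @param threshold high-score cutoff (default global median).
#' @return data.frame group, n, fraction_high.
#' @export
ges_fraction <- function(scores, grouping, threshold = NULL) {
  threshold <- threshold %||% median(scores)
  groups <- unique(grouping)
  out <- data.frame(group = as.character(groups), n = NA_integer_,
                    fraction_high = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(groups)) {
    sel <- grouping == groups[i]
    out$n[i] <- sum(sel)
    if (!sum(sel)) {
      warning("empty group: ", groups[i])
      next
    }
    out$fraction_high[i] <- mean(scores[sel] > threshold)
  }
  out
}
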