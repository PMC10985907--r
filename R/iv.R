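# Determinant-gene identification. A gene's binary somatic mutation status is
# the instrument, its expression the endogenous mediator, and a signature
# activity the outcome; cancer type enters both stages as dummy covariates.
# Genes are screened by Wilcoxon rank-sum association of mutation status with
# activity (FDR < 0.1, mutant count > min_mut), then pass through 2SLS with
# three gates: Wu-Hausman endogeneity, weak-instrument first-stage F
# (heteroscedasticity-robust), and the 2SLS model Wald test, each
# Benjamini-Hochberg adjusted within its own family, all three FDR < 0.05.

# covariate matrix from cancer-type labels (reference = first level
# alphabetically); NULL when absent or single-level
.cy_covariates <- function(cancer_type, n) {
  if (is.null(cancer_type)) return(NULL)
  f <- factor(cancer_type)
  if (nlevels(f) < 2) return(NULL)
  X <- stats::model.matrix(~ f)[, -1, drop = FALSE]
  colnames(X) <- paste0("CY_", levels(f)[-1])
  X
}

.check_iv_inputs <- function(y, x, z, covariates) {
  n <- length(y)
  stopifnot(length(x) == n, length(z) == n)
  if (var(z) == 0) stop("degenerate instrument: mutation status is constant")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    X <- cbind(1, z, covariates)
    q <- qr(X)
    if (q$rank < ncol(X)) {
      aliased <- colnames(X)[q$pivot[seq.int(q$rank + 1L, ncol(X))]]
      stop("collinear covariate column(s): ", paste(aliased, collapse = ", "))
    }
  }
  covariates
}

#' Screen genes by mutation-status association with signature activity
#'
#' Genes with strictly more than `min_mut` mutated samples are tested by the
#' two-sided Wilcoxon rank-sum test (mutant vs wild-type activities; exact
#' null for small tie-free groups, tie-corrected normal approximation
#' otherwise), followed by Benjamini-Hochberg adjustment across the tested
#' genes.
#'
#' @param activity per-sample signature activities.
#' @param mut genes x samples binary mutation matrix, columns aligned to
#'   `activity`.
#' @param min_mut minimum mutant count, exclusive (default 10).
#' @param fdr_threshold screen FDR cutoff (default 0.1).
#' @return data.frame `gene`, `n_mut`, `screen_p`, `screen_fdr`, `pass`;
#'   only genes meeting the mutant-count rule appear.
#' @export
screen_mutation_association <- function(activity, mut, min_mut = 10L,
                                        fdr_threshold = 0.1) {
  mut <- as.matrix(mut)
  stopifnot(ncol(mut) == length(activity))
  n_mut <- rowSums(mut)
  testable <- which(n_mut > min_mut & (ncol(mut) - n_mut) > 0)
  if (!length(testable)) {
    warning("no gene exceeds the mutant-count rule; empty screen")
    return(data.frame(gene = character(0), n_mut = integer(0),
                      screen_p = numeric(0), screen_fdr = numeric(0),
                      pass = logical(0), stringsAsFactors = FALSE))
  }
  p <- vapply(testable, function(j) {
    suppressWarnings(wilcox.test(activity[mut[j, ] == 1],
                                 activity[mut[j, ] == 0])$p.value)
  }, numeric(1))
  p[is.na(p)] <- 1  # fully tied activities carry no evidence
  fdr <- p.adjust(p, method = "BH")
  data.frame(gene = rownames(mut)[testable] %||% as.character(testable),
             n_mut = as.integer(n_mut[testable]), screen_p = p,
             screen_fdr = fdr, pass = fdr < fdr_threshold,
             stringsAsFactors = FALSE)
}

#' Two-stage least squares for one gene
#'
#' Stage 1 regresses the expression `x` on the instrument `z` and covariates;
#' stage 2 regresses the activity `y` on the fitted expression and
#' covariates. The coefficient standard error uses the 2SLS-consistent
#' residual `y - [x, covariates] b` (actual `x`, not the fitted values), and
#' the model P is the Wald test of the expression coefficient.
#'
#' @param y outcome (signature activity).
#' @param x endogenous exposure (expression).
#' @param z instrument (0/1 mutation status; any numeric with variance works).
#' @param covariates optional numeric matrix (e.g. cancer-type dummies).
#' @return list with `beta_iv`, `se`, `t`, `model_p`, `df`.
#' @export
two_stage_least_squares <- function(y, x, z, covariates = NULL) {
  covariates <- .check_iv_inputs(y, x, z, covariates)
  n <- length(y)
  Z1 <- cbind(`(Intercept)` = 1, z = z, covariates)
  xhat <- drop(Z1 %*% qr.coef(qr(Z1), x))
  W <- cbind(`(Intercept)` = 1, x = xhat, covariates)
  if (n <= ncol(W)) stop("more parameters than observations")
  b <- qr.coef(qr(W), y)
  Wx <- W; Wx[, "x"] <- x
  res <- y - Wx %*% b
  df <- n - ncol(W)
  sigma2 <- sum(res^2) / df
  vcv <- sigma2 * chol2inv(chol(crossprod(W)))
  se <- sqrt(vcv[2, 2])
  tstat <- b[["x"]] / se
  list(beta_iv = b[["x"]], se = se, t = tstat,
       model_p = 2 * pt(-abs(tstat), df), df = df)
}

#' Wu-Hausman endogeneity test (augmented regression form)
#'
#' Regress the exposure on the instrument and covariates, take the residual
#' v; then regress the outcome on the exposure, covariates and v. The t-test
#' P of the v coefficient is the endogeneity P: under exogeneity it is
#' uniform, under confounding the residual carries the hidden signal.
#'
#' @inheritParams two_stage_least_squares
#' @return list with `statistic` (t of the residual term) and `p`.
#' @export
wu_hausman_test <- function(y, x, z, covariates = NULL) {
  covariates <- .check_iv_inputs(y, x, z, covariates)
  Z1 <- cbind(1, z, covariates)
  v <- drop(x - Z1 %*% qr.coef(qr(Z1), x))
  X2 <- cbind(`(Intercept)` = 1, x = x, covariates, v = v)
  fit <- stats::lm.fit(X2, y)
  df <- length(y) - ncol(X2)
  sigma2 <- sum(fit$residuals^2) / df
  vcv <- sigma2 * chol2inv(chol(crossprod(X2)))
  j <- ncol(X2)  # the v column
  tstat <- fit$coefficients[j] / sqrt(vcv[j, j])
  list(statistic = unname(tstat), p = unname(2 * pt(-abs(tstat), df)))
}

#' Weak-instrument first-stage F
#'
#' First-stage F-statistic for the instrument in the regression of exposure
#' on instrument plus covariates, with heteroscedasticity-robust (HC0)
#' variance — for a single instrument and single endogenous regressor this is
#' the robust rank Wald F. P from the F distribution with 1 numerator df.
#'
#' @inheritParams two_stage_least_squares
#' @param robust use HC0-robust variance (default `TRUE`); otherwise the
#'   classical homoscedastic F.
#' @return list with `F`, `p`, `df1`, `df2`.
#' @export
weak_instrument_test <- function(x, z, covariates = NULL, robust = TRUE) {
  covariates <- .check_iv_inputs(x, x, z, covariates)
  dat <- data.frame(x = x, z = z)
  fml <- if (is.null(covariates)) x ~ z else {
    dat <- cbind(dat, as.data.frame(covariates))
    stats::as.formula(paste("x ~ z +",
                            paste(colnames(covariates), collapse = " + ")))
  }
  fit <- lm(fml, data = dat)
  vz <- if (robust) sandwich::vcovHC(fit, type = "HC0")["z", "z"]
        else stats::vcov(fit)["z", "z"]
  bz <- coef(fit)[["z"]]
  df2 <- fit$df.residual
  Fstat <- bz^2 / vz
  if (!is.finite(Fstat)) Fstat <- 1e12  # perfect first stage
  list(F = Fstat, p = pf(Fstat, 1, df2, lower.tail = FALSE),
       df1 = 1L, df2 = df2)
}

#' Apply the triple FDR gate to IV results
#'
#' Benjamini-Hochberg adjustment is applied separately within each P-value
#' family (Wu-Hausman, weak-instrument, model) across the tested genes of a
#' signature; a gene is a determinant when all three FDRs are below
#' `gate_fdr`.
#'
#' @param results data.frame with `wu_hausman_p`, `weak_p`, `model_p`.
#' @param gate_fdr gate cutoff (default 0.05).
#' @return `results` with `fdr_wu_hausman`, `fdr_weak`, `fdr_model` and
#'   `determinant` columns.
#' @export
select_determinants <- function(results, gate_fdr = 0.05) {
  stopifnot(all(c("wu_hausman_p", "weak_p", "model_p") %in% names(results)))
  results$fdr_wu_hausman <- p.adjust(results$wu_hausman_p, method = "BH")
  results$fdr_weak <- p.adjust(results$weak_p, method = "BH")
  results$fdr_model <- p.adjust(results$model_p, method = "BH")
  results$determinant <- results$fdr_wu_hausman < gate_fdr &
    results$fdr_weak < gate_fdr & results$fdr_model < gate_fdr
  results
}

#' Identify determinant genes of a signature activity
#'
#' The full chain for one signature: mutation-association screen, per-gene
#' 2SLS with Wu-Hausman and weak-instrument tests, then the triple FDR gate.
#'
#' @param activity per-sample signature activities (named by sample).
#' @param mutations genes x samples binary matrix.
#' @param expression genes x samples expression matrix (same gene order not
#'   required; matched by row name).
#' @param cancer_type optional per-sample cancer-type labels (covariate in
#'   both stages).
#' @param signature label stored in the result (default "Sig1").
#' @param min_mut,screen_fdr screen parameters (defaults 10 and 0.1).
#' @param gate_fdr triple-gate cutoff (default 0.05).
#' @return `iv_fit` object whose `table` has one row per screened-in gene:
#'   gene, signature, screen_p, screen_fdr, beta_iv, se, model_p, wu_hausman_p,
#'   weak_f, weak_p, the three FDRs and the determinant flag.
#' @export
iv_determinants <- function(activity, mutations, expression,
                            cancer_type = NULL, signature = "Sig1",
                            min_mut = 10L, screen_fdr = 0.1,
                            gate_fdr = 0.05) {
  mutations <- as.matrix(mutations); expression <- as.matrix(expression)
  stopifnot(ncol(mutations) == length(activity),
            ncol(expression) == length(activity))
  screen <- screen_mutation_association(activity, mutations, min_mut,
                                        screen_fdr)
  genes <- screen$gene[screen$pass]
  covar <- .cy_covariates(cancer_type, length(activity))
  rows <- list()
  for (g in genes) {
    x <- expression[g, ]; z <- mutations[g, ]
    ts <- two_stage_least_squares(activity, x, z, covar)
    wh <- wu_hausman_test(activity, x, z, covar)
    wk <- weak_instrument_test(x, z, covar)
    rows[[g]] <- data.frame(
      gene = g, signature = signature,
      screen_p = screen$screen_p[screen$gene == g],
      screen_fdr = screen$screen_fdr[screen$gene == g],
      beta_iv = ts$beta_iv, se = ts$se, model_p = ts$model_p,
      wu_hausman_p = wh$p, weak_f = wk$F, weak_p = wk$p,
      stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) select_determinants(do.call(rbind, rows), gate_fdr)
  else data.frame(gene = character(0), signature = character(0),
                  screen_p = numeric(0), screen_fdr = numeric(0),
                  beta_iv = numeric(0), se = numeric(0),
                  model_p = numeric(0), wu_hausman_p = numeric(0),
                  weak_f = numeric(0), weak_p = numeric(0),
                  fdr_wu_hausman = numeric(0), fdr_weak = numeric(0),
                  fdr_model = numeric(0), determinant = logical(0),
                  stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, screen = screen, signature = signature,
                 min_mut = min_mut, screen_fdr = screen_fdr,
                 gate_fdr = gate_fdr),
            class = "iv_fit")
}

#' @export
print.iv_fit <- function(x, ...) {
  cat(sprintf("iv_fit for %s: %d genes screened, %d passed the FDR < %g screen, %d determinant\n",
              x$signature, nrow(x$screen), sum(x$screen$pass),
              x$screen_fdr, sum(x$table$determinant)))
  if (nrow(x$table))
    print(x$table[order(x$table$model_p),
                  c("gene", "beta_iv", "fdr_model", "fdr_wu_hausman",
                    "fdr_weak", "determinant")],
          row.names = FALSE, digits = 3)
  invisible(x)
}
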