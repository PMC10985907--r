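# Shared fixtures and independent oracles for the test suite. Everything is
# built in code; no data files.

# tiny paired beta matrix with hand-set values; one probe per row of `values`
tiny_paired <- function(values, cancer_type = NULL, purity = NULL) {
  n_pairs <- ncol(values) / 2
  stopifnot(n_pairs == floor(n_pairs))
  ct <- cancer_type %||% rep("CT01", n_pairs)
  samples <- do.call(rbind, lapply(seq_len(n_pairs), function(i) {
    data.frame(sample_id = c(sprintf("P%02d_T", i), sprintf("P%02d_N", i)),
               patient_id = sprintf("P%02d", i),
               tissue_type = c("tumor", "normal"),
               cancer_type = ct[i],
               purity = c(if (is.null(purity)) 0.9 else purity[i], NA),
               stringsAsFactors = FALSE)
  }))
  colnames(values) <- samples$sample_id
  rownames(values) <- sprintf("cg%07d", seq_len(nrow(values)))
  beta_matrix(values, samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent sort-and-interpolate quantile (type-7 definition, written out)
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# exhaustive two-sided Wilcoxon rank-sum p by enumerating all group splits
oracle_wilcox_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  splits <- utils::combn(length(pooled), n1)
  ws <- apply(splits, 2, function(ix) sum(rank(pooled)[ix]))
  p_lo <- mean(ws <= w_obs); p_hi <- mean(ws >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Benjamini-Hochberg step-up written from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# Breslow partial log-likelihood for a binary group covariate, no ties needed
oracle_cox_loglik <- function(b, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
  }
  ll
}
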