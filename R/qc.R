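# Sample- and probe-level quality control producing the analysis-ready beta
# matrix: purity filter on tumors, SNP / sex-chromosome / missingness probe
# filters, then per-probe median imputation.

#' Drop low-purity tumor samples
#'
#' Tumor samples are kept only when their purity is strictly greater than
#' `threshold`; tumors with missing purity are dropped. Normal samples are
#' retained regardless of purity (they carry none by definition). Sample
#' order is preserved.
#'
#' @param m a [beta_matrix].
#' @param threshold purity cutoff in \[0,1\] (default 0.6).
#' @return Filtered [beta_matrix].
#' @export
filter_samples_by_purity <- function(m, threshold = 0.6) {
  .assert_fraction(threshold, "threshold")
  s <- m$samples
  pur <- s$purity %||% rep(NA_real_, nrow(s))
  keep <- s$tissue_type != "tumor" | (!is.na(pur) & pur > threshold)
  has_tumor <- any(s$tissue_type == "tumor")
  if (!any(keep) || (has_tumor && !any(keep & s$tissue_type == "tumor")))
    stop(sprintf("no tumor samples survive the purity filter at threshold %g",
                 threshold))
  subset_samples(m, keep)
}

#' Remove SNP, sex-chromosome and high-missingness probes
#'
#' Removes, in order: probes flagged as overlapping SNPs; probes on
#' chromosomes X and Y (`chrX`/`chrY`, with bare `X`/`Y` accepted); probes
#' whose fraction of missing values is strictly greater than
#' `max_missing_frac`.
#'
#' @param m a [beta_matrix].
#' @param annotation probe annotation data.frame (defaults to the one attached
#'   to `m`); every probe of `m` must be annotated.
#' @param max_missing_frac missingness cutoff (default 0.10; strictly-greater
#'   rule, so a probe at exactly the cutoff is kept).
#' @return Filtered [beta_matrix].
#' @export
filter_probes <- function(m, annotation = NULL, max_missing_frac = 0.10) {
  .assert_fraction(max_missing_frac, "max_missing_frac")
  ann <- annotation %||% m$annotation
  if (is.null(ann)) stop("probe annotation required")
  pid <- rownames(m$values)
  hit <- match(pid, ann$probe_id)
  if (anyNA(hit))
    stop("unannotated probe(s): ",
         paste(utils::head(pid[is.na(hit)], 5), collapse = ", "))
  ann <- ann[hit, , drop = FALSE]
  keep <- !ann$snp_flag
  keep <- keep & !(ann$chrom %in% c("chrX", "chrY", "X", "Y"))
  miss_frac <- rowMeans(is.na(m$values))
  keep <- keep & miss_frac <= max_missing_frac
  subset_probes(m, keep)
}

#' Impute missing beta values with the per-probe median
#'
#' Each missing entry is replaced by the median of that probe's non-missing
#' values across all samples; non-missing entries are untouched.
#'
#' @param m a [beta_matrix]; every probe must have at least one non-missing
#'   value.
#' @return Complete [beta_matrix].
#' @export
impute_missing <- function(m) {
  v <- m$values
  all_na <- rowSums(!is.na(v)) == 0
  if (any(all_na))
    stop("all-missing probe(s) (should have been filtered): ",
         paste(utils::head(rownames(v)[all_na], 5), collapse = ", "))
  if (anyNA(v)) {
    med <- apply(v, 1, median, na.rm = TRUE)
    idx <- which(is.na(v), arr.ind = TRUE)
    v[idx] <- med[idx[, 1]]
  }
  beta_matrix(v, m$samples, m$annotation)
}

#' Full QC chain
#'
#' Purity filter, probe filters, then median imputation — in the Methods
#' order: samples are selected first, so missingness is computed on the
#' retained samples.
#'
#' @inheritParams filter_samples_by_purity
#' @inheritParams filter_probes
#' @return Analysis-ready [beta_matrix] with no missing values.
#' @export
qc_pipeline <- function(m, threshold = 0.6, annotation = NULL,
                        max_missing_frac = 0.10) {
  m <- filter_samples_by_purity(m, threshold)
  m <- filter_probes(m, annotation, max_missing_frac)
  impute_missing(m)
}
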