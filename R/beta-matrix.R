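#' Beta-value matrix with sample metadata
#'
#' The central container of the pipeline: a probes-by-samples matrix of
#' methylation fractions (beta values, in \[0,1\], `NA` allowed) together with
#' a sample sheet and, optionally, a probe annotation table.
#'
#' @param values numeric matrix, probes in rows, samples in columns. Row names
#'   are probe ids, column names sample ids.
#' @param samples data.frame with one row per column of `values`; must contain
#'   `sample_id`, `patient_id`, `tissue_type` (`"tumor"`/`"normal"`),
#'   `cancer_type`; may contain `purity`, `age`, `stage_group`, `os_time`,
#'   `os_event`, `response`.
#' @param annotation optional data.frame with `probe_id`, `chrom`, `pos`,
#'   `island_relation`, `region`, `gene`, `snp_flag`.
#' @return An object of class `beta_matrix`.
#' @export
beta_matrix <- function(values, samples, annotation = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("cg%07d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- samples$sample_id
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample_id", "patient_id", "tissue_type", "cancer_type")
  miss <- setdiff(req, names(samples))
  if (length(miss))
    stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample ids in sample sheet")
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe ids")
  if (!identical(colnames(values), as.character(samples$sample_id)))
    stop("column names of 'values' must equal samples$sample_id, in order")
  rng <- range(values, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop("beta values must lie in [0, 1]")
  bad <- !samples$tissue_type %in% c("tumor", "normal")
  if (any(bad)) stop("tissue_type must be 'tumor' or 'normal'")
  structure(list(values = values, samples = samples, annotation = annotation),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  nt <- sum(x$samples$tissue_type == "tumor")
  nn <- sum(x$samples$tissue_type == "normal")
  cat(sprintf("beta_matrix: %d probes x %d samples (%d tumor / %d normal, %d cancer types)\n",
              nrow(x$values), ncol(x$values), nt, nn,
              length(unique(x$samples$cancer_type))))
  cat(sprintf("  missing entries: %d (%.2f%%)\n", sum(is.na(x$values)),
              100 * mean(is.na(x$values))))
  if (!is.null(x$annotation)) cat("  probe annotation attached\n")
  invisible(x)
}

#' @export
dim.beta_matrix <- function(x) dim(x$values)

# subset samples by logical/integer index, keeping metadata aligned
subset_samples <- function(m, keep) {
  beta_matrix(m$values[, keep, drop = FALSE],
              m$samples[keep, , drop = FALSE],
              m$annotation)
}

# subset probes, keeping any annotation aligned
subset_probes <- function(m, keep) {
  ann <- m$annotation
  v <- m$values[keep, , drop = FALSE]
  if (!is.null(ann)) ann <- ann[match(rownames(v), ann$probe_id), , drop = FALSE]
  beta_matrix(v, m$samples, ann)
}

# tumor/normal pairing; errors on unpaired tumors
paired_index <- function(m) {
  s <- m$samples
  tum <- which(s$tissue_type == "tumor")
  nor <- which(s$tissue_type == "normal")
  match_nor <- match(s$patient_id[tum], s$patient_id[nor])
  if (anyNA(match_nor)) {
    orphans <- s$patient_id[tum][is.na(match_nor)]
    stop("unpaired tumor sample(s) for patient(s): ",
         paste(utils::head(orphans, 5), collapse = ", "))
  }
  data.frame(patient_id = s$patient_id[tum],
             tumor = tum, normal = nor[match_nor],
             stringsAsFactors = FALSE)
}
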