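# TSV readers/writers for the pipeline's external formats.
# Beta matrix: first column `probe_id`, remaining columns samples, NA for
# missing. Sample sheet / probe annotation: one row per sample / probe.

#' Write a beta matrix and its sample sheet to TSV
#'
#' @param m a [beta_matrix].
#' @param beta_file,samples_file,annotation_file output paths; annotation is
#'   written only when present and a path is given.
#' @return Invisibly, the paths written.
#' @export
write_beta_tsv <- function(m, beta_file, samples_file = NULL,
                           annotation_file = NULL) {
  df <- data.frame(probe_id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, beta_file, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(samples_file))
    write.table(m$samples, samples_file, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(annotation_file) && !is.null(m$annotation))
    write.table(m$annotation, annotation_file, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(c(beta_file, samples_file, annotation_file))
}

#' Read a beta matrix from TSV files
#'
#' @param beta_file TSV with `probe_id` column then sample columns.
#' @param samples_file TSV sample sheet.
#' @param annotation_file optional TSV probe annotation.
#' @return A [beta_matrix].
#' @export
read_beta_tsv <- function(beta_file, samples_file, annotation_file = NULL) {
  df <- read.delim(beta_file, check.names = FALSE, stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df$probe_id
  samples <- read.delim(samples_file, stringsAsFactors = FALSE)
  ann <- if (!is.null(annotation_file))
    read.delim(annotation_file, stringsAsFactors = FALSE) else NULL
  beta_matrix(v, samples, ann)
}

#' Write a numeric matrix as TSV with an id first column
#' @param x matrix with row names.
#' @param file path.
#' @param id_col name for the first column.
#' @return Invisibly, `file`.
#' @export
write_matrix_tsv <- function(x, file, id_col = "id") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a numeric matrix written by [write_matrix_tsv()]
#' @param file path.
#' @return Numeric matrix with row names from the first column.
#' @export
read_matrix_tsv <- function(file) {
  df <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- as.character(df[[1]])
  v
}

# Ground truth is written as a small directory: key/value TSV for scalars plus
# one matrix TSV per planted matrix.
write_ground_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scalars <- truth[vapply(truth, function(x)
    is.atomic(x) && is.null(dim(x)), logical(1))]
  kv <- data.frame(
    key = rep(names(scalars), lengths(scalars)),
    value = unlist(lapply(scalars, as.character), use.names = FALSE))
  write.table(kv, file.path(dir, "truth_scalars.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (nm in names(truth)) {
    x <- truth[[nm]]
    if (is.matrix(x)) {
      if (is.null(rownames(x))) rownames(x) <- seq_len(nrow(x))
      write_matrix_tsv(x, file.path(dir, paste0("truth_", nm, ".tsv")))
    }
  }
  invisible(dir)
}
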