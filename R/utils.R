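# Internal helpers: seed sub-streams, argument checks, small numerics.

#' Derive a reproducible sub-stream seed from a master seed
#'
#' One global integer seed drives a named sub-stream per simulation stage, so
#' each stage is reproducible on its own while stages stay independent.
#'
#' @param seed master integer seed.
#' @param name character stream name (e.g. `"paired"`, `"nmf_run"`).
#' @return An integer seed below 2^31, deterministic in `(seed, name)`.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name))) %% 99991L
  as.integer((abs(seed) %% 1000003L) * 2011L + h * 7919L) %% 2147483629L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(sprintf("'%s' must be a single number in [%g, %g]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}

# clip to an open interval by a hard margin
.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# cosine similarity between columns of two matrices
cosine_columns <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  num <- crossprod(A, B)
  na <- sqrt(colSums(A^2)); nb <- sqrt(colSums(B^2))
  d <- outer(na, nb)
  out <- num / d
  out[d == 0] <- 0
  out
}

# Mann-Whitney AUC of score for a binary label (TRUE = positive class)
rank_auc <- function(score, positive) {
  stopifnot(length(score) == length(positive))
  pos <- score[positive]; neg <- score[!positive]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}
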