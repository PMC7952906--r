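## Internal utilities shared across modules.

#' @useDynLib tcrlearn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

## The 20 standard amino acids, alphabetical; integer codes 1..20, pad = 21.
.AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.N_AA <- 20L
.PAD <- 21L

.aaIndex <- function(chars) match(chars, .AA)

## Canonical clone-table columns.
.CLONE_COLS <- c("sample_id", "cdr3_alpha", "cdr3_beta",
                 "v_alpha", "j_alpha", "v_beta", "d_beta", "j_beta",
                 "count", "label")
.GENE_SLOTS <- c("v_alpha", "j_alpha", "v_beta", "d_beta", "j_beta")

## Numeric-backend switch: single-precision GEMM (default, field standard for
## net training) vs plain double %*% (used by gradient-check tests).
.tcrlearn_env <- new.env(parent = emptyenv())
.tcrlearn_env$use_float <- TRUE

.useFloat <- function(on) {
  old <- .tcrlearn_env$use_float
  .tcrlearn_env$use_float <- isTRUE(on)
  invisible(old)
}

.gemm <- function(A, B) {
  if (.tcrlearn_env$use_float) .cpp_sgemm(A, B, FALSE, FALSE) else A %*% B
}
.gemm_tA <- function(A, B) {
  if (.tcrlearn_env$use_float) .cpp_sgemm(A, B, TRUE, FALSE) else crossprod(A, B)
}
.gemm_tB <- function(A, B) {
  if (.tcrlearn_env$use_float) .cpp_sgemm(A, B, FALSE, TRUE) else tcrossprod(A, B)
}

.addBias <- function(Z, b) Z + rep(b, each = nrow(Z))

.softmaxRows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

## Rank-statistic (Mann-Whitney) AUC with midrank tie handling.
.aucRank <- function(scores, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## Derive a bounded child seed from a master seed and a stream label, so all
## modules draw from named substreams of one seed.
.childSeed <- function(seed, stream, index = 0L) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream))) %% 97L
  as.integer((as.numeric(seed) * 1009 + h * 31 + index) %% 2147483647)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.isCount <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)

## Consensus string of a position-frequency matrix (ties -> first letter).
.pfmConsensus <- function(pfm) {
  paste(rownames(pfm)[apply(pfm, 2L, which.max)], collapse = "")
}
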