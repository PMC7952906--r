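## The four TCR distance featurizations: latent Euclidean, Hamming on the
## padded integer representation, Euclidean on k-mer count vectors, and a
## normalized global-alignment (identity-score) distance. Each returns a
## symmetric, zero-diagonal matrix.

.checkDistMatrix <- function(D, ids = NULL) {
  if (!is.null(ids)) dimnames(D) <- list(ids, ids)
  D
}

#' Latent Euclidean distance matrix
#'
#' `d(i, j) = ||z_i - z_j||_2` on the latent feature matrix (clones in rows).
#'
#' @param latent numeric matrix, e.g. from [extractLatent()].
#' @return `n x n` symmetric distance matrix.
#' @export
latentEuclidean <- function(latent) {
  if (any(!is.finite(latent))) .stopf("non-finite latent features")
  as.matrix(stats::dist(latent))
}

#' Hamming distance on the padded integer representation
#'
#' Counts positions (pad positions included) at which the right-padded
#' integer rows differ, so sequences of different length are comparable:
#' e.g. "CASS" vs "CAS" differ at exactly one position (S vs pad). Reported
#' as a raw mismatch count.
#'
#' @param enc an [EncodedTCRSet]; @param chain chain to compare.
#' @export
hammingDistances <- function(enc, chain = "beta") {
  chain <- match.arg(chain, c("alpha", "beta"))
  S <- if (chain == "beta") enc@seqBeta else enc@seqAlpha
  if (ncol(S) == 0L) .stopf("chain %s absent from encoded data", chain)
  n <- nrow(S)
  D <- matrix(0, n, n)
  for (p in seq_len(ncol(S)))
    D <- D + outer(S[, p], S[, p], "!=")
  .checkDistMatrix(D, rownames(S))
}

#' Euclidean distance on k-mer count vectors
#'
#' Each sequence is mapped to counts over all k-mers observed in the input;
#' the distance is Euclidean between count vectors (invariant to the k-mer
#' vocabulary ordering).
#'
#' @param seqs character vector of CDR3 strings.
#' @param k k-mer length (default 3).
#' @export
kmerDistances <- function(seqs, k = 3L) {
  k <- as.integer(k)
  short <- nchar(seqs) < k
  if (any(short))
    .stopf("sequence(s) shorter than k=%d: %s", k,
           paste(utils::head(seqs[short], 3L), collapse = ", "))
  kmers_of <- lapply(seqs, function(s) {
    n <- nchar(s)
    substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  })
  vocabulary <- sort(unique(unlist(kmers_of)))
  M <- t(vapply(kmers_of, function(km)
    tabulate(match(km, vocabulary), nbins = length(vocabulary)),
    integer(length(vocabulary))))
  as.matrix(stats::dist(M))
}

#' Normalized global-alignment distance
#'
#' Global alignment with unit match score and no mismatch or gap penalties;
#' the optimal score `s(a, b)` is the maximal number of matched positions
#' (the longest common subsequence). The distance is
#' `d(a, b) = 1 - 2 s(a, b) / (s(a, a) + s(b, b))`, symmetric, zero on the
#' diagonal and bounded in `[0, 1]`. The normalization does not guarantee
#' the triangle inequality and is isolated here for easy replacement.
#'
#' @param seqs character vector of CDR3 strings (non-empty).
#' @export
alignmentDistances <- function(seqs) {
  if (any(is.na(seqs) | !nzchar(seqs))) .stopf("empty sequence in input")
  iv <- lapply(strsplit(seqs, ""), .aaIndex)
  S <- .cpp_lcs_matrix(iv)
  len <- nchar(seqs)
  D <- 1 - 2 * S / outer(len, len, "+")
  diag(D) <- 0
  D
}

#' Write a distance matrix as square CSV with clone ids
#' @param D distance matrix; @param path output path; @param ids row ids.
#' @export
writeDistanceCsv <- function(D, path, ids = rownames(D)) {
  if (is.null(ids)) ids <- as.character(seq_len(nrow(D)))
  df <- data.frame(id = ids, D, check.names = FALSE)
  colnames(df) <- c("id", ids)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
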