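## Central S4 containers.

#' TCRCloneSet: a curated set of TCR clones
#'
#' One row per clone: sample identifier, CDR3 amino-acid sequence(s) for the
#' alpha and/or beta chain, V/D/J gene labels, a summed read/UMI count, and an
#' optional class label or continuous target. Absent fields are `NA`. Validity
#' enforces the curation contract: at least one chain present per clone, only
#' the 20 standard amino-acid letters, CDR3 length within bounds, count >= 1.
#'
#' @slot clones data.frame with the canonical columns (see [parseCloneTable()]).
#' @slot maxLength maximum admissible CDR3 length for this set.
#' @slot metadata free-form list (curation report, simulation ground truth, ...).
#' @export
setClass("TCRCloneSet",
  representation(clones = "data.frame", maxLength = "integer", metadata = "list"),
  prototype(maxLength = 40L, metadata = list())
)

setValidity("TCRCloneSet", function(object) {
  df <- object@clones
  missing_cols <- setdiff(.CLONE_COLS, names(df))
  if (length(missing_cols) > 0L)
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  if (nrow(df) == 0L) return(TRUE)
  a <- df$cdr3_alpha; b <- df$cdr3_beta
  a_present <- !is.na(a) & nzchar(a); b_present <- !is.na(b) & nzchar(b)
  if (any(!a_present & !b_present))
    return("every clone needs at least one non-empty CDR3 chain")
  seqs <- c(a[a_present], b[b_present])
  bad <- vapply(strsplit(seqs, ""), function(ch) any(!ch %in% .AA), logical(1))
  if (any(bad))
    return("CDR3 sequences must use only the 20 standard amino-acid letters")
  if (any(nchar(seqs) > object@maxLength))
    return(sprintf("CDR3 longer than maxLength (%d)", object@maxLength))
  cnt <- df$count
  if (any(is.na(cnt)) || any(cnt < 1) || any(cnt != floor(cnt)))
    return("counts must be integers >= 1")
  TRUE
})

#' GeneVocabulary: stable label-to-index mappings for V/D/J gene slots
#'
#' For each gene slot (v_alpha, j_alpha, v_beta, d_beta, j_beta) an ordered
#' character vector of observed labels; label i maps to integer i, and the
#' reserved index `length(levels) + 1` encodes an absent gene. The mapping is
#' a bijection and survives JSON round-trips (see [writeGeneVocabulary()]).
#'
#' @slot levels named list of character vectors, one per gene slot.
#' @export
setClass("GeneVocabulary", representation(levels = "list"))

setValidity("GeneVocabulary", function(object) {
  if (!all(names(object@levels) %in% .GENE_SLOTS))
    return("unknown gene slot name")
  for (lv in object@levels)
    if (anyDuplicated(lv)) return("duplicated gene label in vocabulary")
  TRUE
})

#' EncodedTCRSet: integer-encoded clones ready for a network
#'
#' Sequences are right-padded integer matrices (`n x maxLength`) with residues
#' coded 1..20 (alphabetical amino-acid order) and a distinguished pad code 21
#' past the true length. Gene slots are integer indices into a
#' [GeneVocabulary] (absent = reserved index). Decoding reproduces the source
#' CDR3 strings exactly.
#'
#' @slot seqAlpha,seqBeta integer matrices, or 0-column matrices for unused chains.
#' @slot lengthsAlpha,lengthsBeta true (unpadded) lengths, 0 when chain absent.
#' @slot genes integer matrix `n x 5` (columns = gene slots).
#' @slot counts,labels clone counts and labels carried through from the source.
#' @slot cloneIndex back-map to rows of the source [TCRCloneSet].
#' @slot vocab the [GeneVocabulary] used.
#' @slot maxLength padded length.
#' @export
setClass("EncodedTCRSet",
  representation(
    seqAlpha = "matrix", seqBeta = "matrix",
    lengthsAlpha = "integer", lengthsBeta = "integer",
    genes = "matrix", counts = "integer", labels = "ANY",
    cloneIndex = "integer", vocab = "GeneVocabulary", maxLength = "integer"
  )
)

setValidity("EncodedTCRSet", function(object) {
  n <- length(object@cloneIndex)
  for (chain in c("Alpha", "Beta")) {
    S <- slot(object, paste0("seq", chain))
    len <- slot(object, paste0("lengths", chain))
    if (ncol(S) == 0L) next
    if (nrow(S) != n || length(len) != n) return("sequence matrix shape mismatch")
    if (ncol(S) != object@maxLength) return("sequence matrix must have maxLength columns")
    for (i in seq_len(n)) {
      l <- len[i]
      if (l > 0L && any(S[i, seq_len(l)] == .PAD))
        return("pad code before the true length (padding must be right-sided)")
      if (l < object@maxLength && any(S[i, (l + 1L):object@maxLength] != .PAD))
        return("non-pad code after the true length")
    }
  }
  TRUE
})

## --- model classes: parameter containers with a config and a flat named
## parameter list (matrices/vectors), trained by the module that owns them.

#' @export
setClass("TCRFeaturizer",
  representation(config = "list", params = "list", vocab = "GeneVocabulary",
                 maxLength = "integer", dims = "list"))

#' @export
setClass("TCRVae",
  representation(featurizer = "TCRFeaturizer", params = "list",
                 config = "list", log = "data.frame"))

#' @export
setClass("TCRSequenceModel",
  representation(featurizer = "TCRFeaturizer", params = "list",
                 config = "list", classLevels = "character", log = "data.frame"))

#' @export
setClass("TCRRepertoireModel",
  representation(featurizer = "TCRFeaturizer", params = "list",
                 config = "list", classLevels = "character", log = "data.frame"))
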