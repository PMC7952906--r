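## Generics and accessors for the data containers.

#' @export
setGeneric("cloneData", function(x) standardGeneric("cloneData"))
#' Clone table of a TCRCloneSet
#' @param x a [TCRCloneSet]
#' @return data.frame, one row per clone.
#' @export
setMethod("cloneData", "TCRCloneSet", function(x) x@clones)

#' @export
setGeneric("cloneCounts", function(x) standardGeneric("cloneCounts"))
#' @export
setMethod("cloneCounts", "TCRCloneSet", function(x) x@clones$count)
#' @export
setMethod("cloneCounts", "EncodedTCRSet", function(x) x@counts)

#' @export
setGeneric("cloneLabels", function(x) standardGeneric("cloneLabels"))
#' @export
setMethod("cloneLabels", "TCRCloneSet", function(x) x@clones$label)
#' @export
setMethod("cloneLabels", "EncodedTCRSet", function(x) x@labels)

#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @export
setMethod("sampleIds", "TCRCloneSet", function(x) x@clones$sample_id)

#' @export
setGeneric("cdr3Sequences", function(x, chain = "beta") standardGeneric("cdr3Sequences"))
#' CDR3 strings of one chain
#' @param x a [TCRCloneSet]
#' @param chain `"alpha"` or `"beta"`
#' @export
setMethod("cdr3Sequences", "TCRCloneSet", function(x, chain = "beta") {
  chain <- match.arg(chain, c("alpha", "beta"))
  x@clones[[paste0("cdr3_", chain)]]
})

#' @export
setGeneric("curationReport", function(x) standardGeneric("curationReport"))
#' Row-drop and aggregation bookkeeping recorded by [parseCloneTable()]
#' @param x a [TCRCloneSet]
#' @export
setMethod("curationReport", "TCRCloneSet", function(x) x@metadata$curation)

#' @export
setGeneric("simTruth", function(x) standardGeneric("simTruth"))
#' Ground-truth motif flags recorded by the simulator
#' @param x a [TCRCloneSet] produced by [simulateSequenceDataset()]
#' @export
setMethod("simTruth", "TCRCloneSet", function(x) x@metadata$truth)

#' @export
setGeneric("geneLevels", function(x, slot) standardGeneric("geneLevels"))
#' @export
setMethod("geneLevels", "GeneVocabulary", function(x, slot) x@levels[[slot]])

#' @export
setGeneric("absentIndex", function(x, slot) standardGeneric("absentIndex"))
#' Reserved integer index coding an absent gene for a slot
#' @param x a [GeneVocabulary]; @param slot one of the five gene slot names
#' @export
setMethod("absentIndex", "GeneVocabulary", function(x, slot) {
  length(x@levels[[slot]]) + 1L
})

setMethod("length", "TCRCloneSet", function(x) nrow(x@clones))
setMethod("length", "EncodedTCRSet", function(x) length(x@cloneIndex))

setMethod("show", "TCRCloneSet", function(object) {
  df <- object@clones
  a <- sum(!is.na(df$cdr3_alpha) & nzchar(df$cdr3_alpha))
  b <- sum(!is.na(df$cdr3_beta) & nzchar(df$cdr3_beta))
  cat(sprintf("TCRCloneSet with %d clones (%d alpha, %d beta CDR3s), %d sample(s)\n",
              nrow(df), a, b, length(unique(df$sample_id))))
  if (!all(is.na(df$label)))
    cat("  labels:", paste(utils::head(unique(stats::na.omit(df$label)), 6L),
                           collapse = ", "), "\n")
  if (!is.null(object@metadata$curation))
    cat(sprintf("  curation: %d input rows, %d dropped, %d aggregated away\n",
                object@metadata$curation$n_input,
                object@metadata$curation$n_dropped,
                object@metadata$curation$n_aggregated))
})

setMethod("show", "GeneVocabulary", function(object) {
  cat("GeneVocabulary:",
      paste(sprintf("%s(%d)", names(object@levels),
                    lengths(object@levels)), collapse = " "), "\n")
})

setMethod("show", "EncodedTCRSet", function(object) {
  chains <- c(if (ncol(object@seqAlpha) > 0L) "alpha",
              if (ncol(object@seqBeta) > 0L) "beta")
  cat(sprintf("EncodedTCRSet: %d clones, chains [%s], padded length %d\n",
              length(object), paste(chains, collapse = ","), object@maxLength))
})

setMethod("show", "TCRFeaturizer", function(object) {
  cat(sprintf("TCRFeaturizer (%s pooling): feature dim %d\n",
              object@config$pooling, object@dims$feature_dim))
})
setMethod("show", "TCRVae", function(object) {
  cat(sprintf("TCRVae: latent dim %d, %d training epochs logged\n",
              object@config$latent_dim, nrow(object@log)))
})
setMethod("show", "TCRSequenceModel", function(object) {
  cat(sprintf("TCRSequenceModel (%s): %s\n", object@config$task,
              if (object@config$task == "classify")
                paste(length(object@classLevels), "classes") else "single output node"))
})
setMethod("show", "TCRRepertoireModel", function(object) {
  cat(sprintf("TCRRepertoireModel: %d concepts, classes [%s]\n",
              object@config$n_concepts, paste(object@classLevels, collapse = ", ")))
})
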