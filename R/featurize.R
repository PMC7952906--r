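## The shared TCR featurization block: trainable amino-acid embedding (dim
## 64), a three-layer convolutional stack per chain -- (kernel 5, stride 1,
## 32 maps), (kernel 3, stride 3, 64 maps), (kernel 3, stride 3, 128 maps)
## -- trainable per-slot V/D/J gene embeddings (dim 48), concatenated into a
## joint feature vector. Flatten mode feeds the VAE; global-max mode feeds
## the supervised and repertoire models and records per-kernel argmax
## positions for motif interpretation.

.DEFAULT_CONV <- list(c(5L, 1L, 32L), c(3L, 3L, 64L), c(3L, 3L, 128L))

#' Featurizer configuration
#'
#' @param pooling `"global_max"` (length-invariant motif features; records
#'   argmax positions) or `"flatten"` (used by the VAE encoder).
#' @param useAlpha,useBeta chains to featurize; at least one chain or one
#'   gene slot must be enabled.
#' @param geneSlots character subset of
#'   `c("v_alpha","j_alpha","v_beta","d_beta","j_beta")`.
#' @param aaEmbedDim,geneEmbedDim embedding widths (64 / 48).
#' @param convSpec list of `c(kernel, stride, maps)` triples; defaults to
#'   the canonical three-layer stack.
#' @return config list of class `tcr_featurizer_config`.
#' @export
featurizerConfig <- function(pooling = c("global_max", "flatten"),
                             useAlpha = FALSE, useBeta = TRUE,
                             geneSlots = character(),
                             aaEmbedDim = 64L, geneEmbedDim = 48L,
                             convSpec = .DEFAULT_CONV) {
  pooling <- match.arg(pooling)
  if (!useAlpha && !useBeta && length(geneSlots) == 0L)
    .stopf("featurizer needs at least one chain or gene slot enabled")
  stopifnot(all(geneSlots %in% .GENE_SLOTS))
  structure(list(pooling = pooling, use_alpha = useAlpha, use_beta = useBeta,
                 gene_slots = geneSlots, aa_embed_dim = as.integer(aaEmbedDim),
                 gene_embed_dim = as.integer(geneEmbedDim), conv_spec = convSpec),
            class = "tcr_featurizer_config")
}

.chainDims <- function(maxLength, convSpec) {
  L <- as.integer(maxLength); Ls <- integer(0)
  for (sp in convSpec) { L <- .convOutLen(L, sp[2]); Ls <- c(Ls, L) }
  Ls
}

.featDims <- function(config, vocab, maxLength) {
  Ls <- .chainDims(maxLength, config$conv_spec)
  maps_last <- config$conv_spec[[length(config$conv_spec)]][3]
  chain_dim <- if (config$pooling == "global_max") maps_last else Ls[length(Ls)] * maps_last
  n_chain <- sum(config$use_alpha, config$use_beta)
  list(layer_lengths = Ls, maps_last = maps_last, chain_dim = chain_dim,
       feature_dim = n_chain * chain_dim +
         config$gene_embed_dim * length(config$gene_slots))
}

#' Build a (randomly initialized) TCR featurizer
#'
#' All parameters -- the amino-acid embedding, the convolution kernels and
#' the gene embeddings -- are trainable end-to-end by the model that owns
#' the block; initialization is Glorot-uniform under the given seed.
#'
#' @param config a [featurizerConfig()].
#' @param vocab the [GeneVocabulary] the encoded data uses.
#' @param maxLength padded sequence length the block is built for.
#' @param seed initialization seed.
#' @return a [TCRFeaturizer]
#' @export
buildFeaturizer <- function(config, vocab, maxLength = 40L, seed = 1L) {
  stopifnot(inherits(config, "tcr_featurizer_config"))
  maxLength <- as.integer(maxLength)
  dims <- .featDims(config, vocab, maxLength)
  params <- .withSeed(.childSeed(seed, "featinit"), {
    p <- list(aa_embed = .glorot(.N_AA + 1L, config$aa_embed_dim))
    for (chain in c("alpha", "beta")[c(config$use_alpha, config$use_beta)]) {
      C_in <- config$aa_embed_dim
      for (li in seq_along(config$conv_spec)) {
        sp <- config$conv_spec[[li]]
        p[[sprintf("%s.conv%d.W", chain, li)]] <- .glorot(sp[1] * C_in, sp[3])
        p[[sprintf("%s.conv%d.b", chain, li)]] <- numeric(sp[3])
        C_in <- sp[3]
      }
    }
    for (sl in config$gene_slots) {
      K <- length(vocab@levels[[sl]]) + 1L   # + absent
      p[[paste0("gene.", sl)]] <- .glorot(K, config$gene_embed_dim, K)
    }
    p
  })
  methods::new("TCRFeaturizer", config = unclass(config), params = params,
               vocab = vocab, maxLength = maxLength,
               dims = dims)
}

#' Feature dimensionality of a featurizer
#' @param fz a [TCRFeaturizer]
#' @export
featureDim <- function(fz) fz@dims$feature_dim

.checkVocabMatch <- function(fz, enc) {
  if (!identical(fz@vocab@levels[fz@config$gene_slots],
                 enc@vocab@levels[fz@config$gene_slots]))
    .stopf("gene vocabulary of the encoded data does not match the featurizer")
  if (enc@maxLength != fz@maxLength)
    .stopf("encoded maxLength (%d) does not match featurizer (%d)",
           enc@maxLength, fz@maxLength)
}

.encBatch <- function(enc, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(length(enc))
  list(
    seq = list(alpha = enc@seqAlpha[rows, , drop = FALSE],
               beta = enc@seqBeta[rows, , drop = FALSE]),
    len = list(alpha = enc@lengthsAlpha[rows], beta = enc@lengthsBeta[rows]),
    genes = enc@genes[rows, , drop = FALSE],
    n = length(rows))
}

## Forward pass of the featurization block over a batch (internal).
## Returns features [n, D] plus per-chain caches for backprop; in
## global_max mode also pooled activations and argmax positions for the
## final layer, and (keepLayer1) pad-masked layer-1 activations.
.featForward <- function(fz, batch, keepLayer1 = FALSE) {
  cf <- fz@config; p <- fz@params
  n <- batch$n; L <- fz@maxLength
  chains <- c("alpha", "beta")[c(cf$use_alpha, cf$use_beta)]
  feats <- list(); chain_out <- list()
  for (chain in chains) {
    X <- batch$seq[[chain]]
    if (ncol(X) == 0L) .stopf("chain %s enabled but absent from encoded data", chain)
    len <- batch$len[[chain]]
    if (any(len == 0L))
      .stopf("clone(s) with empty %s chain cannot be featurized", chain)
    A0 <- p$aa_embed[as.vector(X), , drop = FALSE]       # [n*L, 64]
    caches <- list(); A <- A0; Lcur <- L; lens <- list(len)
    for (li in seq_along(cf$conv_spec)) {
      sp <- cf$conv_spec[[li]]
      cc <- .convForward(A, n, Lcur, p[[sprintf("%s.conv%d.W", chain, li)]],
                         p[[sprintf("%s.conv%d.b", chain, li)]], sp[1], sp[2])
      caches[[li]] <- cc
      A <- cc$H; Lcur <- cc$Lo
      lens[[li + 1L]] <- pmax(ceiling(lens[[li]] / sp[2]), 1L)
    }
    out <- list(caches = caches, idx = as.vector(X), lens = lens, L3 = Lcur)
    if (cf$pooling == "global_max") {
      mp <- .maxPool(A, n, Lcur, lens[[length(lens)]])
      out$pooled <- mp$pooled; out$arg <- mp$arg
      feats[[chain]] <- mp$pooled
    } else {
      feats[[chain]] <- .flatten(A, n, Lcur)
    }
    if (keepLayer1) {
      out$pool_layers <- lapply(seq_along(caches), function(li)
        .maxPool(caches[[li]]$H, n, caches[[li]]$Lo, lens[[li + 1L]]))
      out$pooled1 <- out$pool_layers[[1]]$pooled
      out$arg1 <- out$pool_layers[[1]]$arg
    }
    chain_out[[chain]] <- out
  }
  for (sl in cf$gene_slots)
    feats[[paste0("gene.", sl)]] <- p[[paste0("gene.", sl)]][batch$genes[, sl], , drop = FALSE]
  list(features = do.call(cbind, feats), chains = chain_out,
       blocks = vapply(feats, ncol, integer(1)), batch = batch)
}

## Backward pass: dF [n, D] -> flat named gradient list over fz params.
.featBackward <- function(fz, fw, dF) {
  cf <- fz@config; p <- fz@params
  n <- fw$batch$n; L <- fz@maxLength
  g <- list()
  off <- 0L
  for (bn in names(fw$blocks)) {
    w <- fw$blocks[[bn]]
    dBlock <- dF[, (off + 1L):(off + w), drop = FALSE]
    off <- off + w
    if (startsWith(bn, "gene.")) {
      sl <- sub("^gene\\.", "", bn)
      K <- nrow(p[[bn]])
      idx <- fw$batch$genes[, sl]
      acc <- rowsum(dBlock, group = idx)
      dG <- matrix(0, K, ncol(dBlock))
      dG[as.integer(rownames(acc)), ] <- acc
      g[[bn]] <- dG
      next
    }
    chain <- bn
    co <- fw$chains[[chain]]
    n_layers <- length(cf$conv_spec)
    last <- co$caches[[n_layers]]
    dH <- if (cf$pooling == "global_max") {
      .maxPoolBackward(dBlock, co$arg, n, co$L3, ncol(last$H))
    } else {
      .unflatten(dBlock, n, co$L3, ncol(last$H))
    }
    for (li in rev(seq_len(n_layers))) {
      cc <- co$caches[[li]]
      W <- p[[sprintf("%s.conv%d.W", chain, li)]]
      bb <- .convBackward(cc, dH, W)
      g[[sprintf("%s.conv%d.W", chain, li)]] <- bb$dW
      g[[sprintf("%s.conv%d.b", chain, li)]] <- bb$db
      dH <- bb$dA
    }
    ## embedding gradient: scatter-add by residue index (pad row included)
    acc <- rowsum(dH, group = co$idx)
    dE <- matrix(0, .N_AA + 1L, cf$aa_embed_dim)
    dE[as.integer(rownames(acc)), ] <- acc
    g$aa_embed <- if (is.null(g$aa_embed)) dE else g$aa_embed + dE
  }
  g
}

#' Run the featurization block over encoded clones
#'
#' Deterministic forward pass. In global-max mode the per-kernel pooled
#' values are invariant to where a kernel's best-matching subsequence sits
#' (pad positions are masked out of the max), and each kernel's argmax
#' position is recorded per clone.
#'
#' @param fz a [TCRFeaturizer]
#' @param enc an [EncodedTCRSet] encoded with the same vocabulary/maxLength.
#' @param layer1 also return pad-masked layer-1 pooled activations and
#'   argmax positions (used for motif extraction).
#' @return list of class `tcr_feature_batch`: `features` (n x D), and in
#'   global-max mode `pooled`/`argmax` per chain (final layer), plus
#'   `pooled1`/`argmax1` when `layer1 = TRUE`.
#' @export
featurizeTCRs <- function(fz, enc, layer1 = FALSE) {
  stopifnot(methods::is(fz, "TCRFeaturizer"), methods::is(enc, "EncodedTCRSet"))
  .checkVocabMatch(fz, enc)
  fw <- .featForward(fz, .encBatch(enc), keepLayer1 = layer1)
  out <- list(features = fw$features)
  if (fz@config$pooling == "global_max") {
    out$pooled <- lapply(fw$chains, `[[`, "pooled")
    out$argmax <- lapply(fw$chains, `[[`, "arg")
  }
  if (layer1) {
    out$pooled1 <- lapply(fw$chains, `[[`, "pooled1")
    out$argmax1 <- lapply(fw$chains, `[[`, "arg1")
  }
  structure(out, class = "tcr_feature_batch")
}

#' Save / load model checkpoints
#'
#' Versioned container embedding the class, config and parameters of a
#' model. Loading verifies the embedded config against `expected` when
#' given and fails loudly on mismatch.
#'
#' @param model a [TCRFeaturizer], [TCRVae], [TCRSequenceModel] or
#'   [TCRRepertoireModel].
#' @param path checkpoint path.
#' @export
saveCheckpoint <- function(model, path) {
  cls <- class(model)[1]
  stopifnot(cls %in% c("TCRFeaturizer", "TCRVae", "TCRSequenceModel",
                       "TCRRepertoireModel"))
  saveRDS(list(format = "tcrlearn-checkpoint", version = 1L, class = cls,
               object = model), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @param expected optional config list that must match the checkpoint's.
#' @export
loadCheckpoint <- function(path, expected = NULL) {
  x <- readRDS(path)
  if (!identical(x$format, "tcrlearn-checkpoint"))
    .stopf("%s is not a tcrlearn checkpoint", path)
  model <- x$object
  cfg <- if (methods::is(model, "TCRFeaturizer")) model@config else model@config
  if (!is.null(expected) && !identical(unclass(expected)[order(names(unclass(expected)))],
                                       cfg[order(names(cfg))]))
    .stopf("checkpoint config does not match the expected configuration")
  model
}
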