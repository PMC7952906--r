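## Variational autoencoder over the featurization block (flatten mode).
## Trained by jointly minimizing a reconstruction cross-entropy over the
## true (unpadded) sequence positions and gene slots, and the closed-form
## KL divergence between the diagonal-Gaussian posterior and a unit
## Gaussian. The latent mean is the deterministic per-clone representation
## used downstream.

#' VAE configuration
#'
#' @param latentDim latent dimensionality (>= 2).
#' @param learningRate Adam learning rate.
#' @param batchSize minibatch size.
#' @param maxEpochs,tol,patience convergence: stop when the relative
#'   improvement of the epoch total loss stays below `tol` for `patience`
#'   consecutive epochs.
#' @param hidden width of the fully connected encoder/decoder bridges.
#' @param seed seed for initialization, shuffling and reparameterized noise.
#' @export
vaeConfig <- function(latentDim = 64L, learningRate = 0.001, batchSize = 128L,
                      maxEpochs = 300L, tol = 1e-4, patience = 10L,
                      hidden = 256L, seed = 1L) {
  stopifnot(latentDim >= 2L, patience >= 1L)
  structure(list(latent_dim = as.integer(latentDim), learning_rate = learningRate,
                 batch_size = as.integer(batchSize), max_epochs = as.integer(maxEpochs),
                 tol = tol, patience = as.integer(patience),
                 hidden = as.integer(hidden), seed = as.integer(seed)),
            class = "tcr_vae_config")
}

#' Closed-form variational (KL) loss
#'
#' KL divergence between `N(mu, sigma)` (diagonal) and the unit Gaussian:
#' `0.5 * sum(mu^2 + sigma^2 - 1 - log sigma^2)`, with
#' `sigma = exp(logVar / 2)`. Zero iff `mu = 0`, `sigma = 1`.
#'
#' @param mu,logVar numeric vectors (one latent) or matrices (clones in rows).
#' @return scalar for vectors; per-clone vector for matrices.
#' @export
variationalLoss <- function(mu, logVar) {
  if (any(!is.finite(mu)) || any(!is.finite(logVar)))
    .stopf("non-finite latent parameters")
  kl <- 0.5 * (mu^2 + exp(logVar) - 1 - logVar)
  if (is.matrix(mu)) rowSums(kl) else sum(kl)
}

#' Reconstruction cross-entropy loss for one clone
#'
#' `-sum_i log S_i[target_i]` over the true (unpadded) positions of each
#' present chain plus the gene slots; pad-region predictions never enter
#' the sum. Probabilities are floored at `1e-12` before the log.
#'
#' @param enc an [EncodedTCRSet]; @param i clone row.
#' @param output list with per-chain `L x 20` probability matrices
#'   (`seq_alpha`, `seq_beta`) and optionally `genes`, a named list of
#'   per-slot probability vectors over `c(levels, absent)`.
#' @return non-negative scalar (nats).
#' @export
reconstructionLoss <- function(enc, i, output) {
  stopifnot(methods::is(enc, "EncodedTCRSet"))
  loss <- 0
  for (chain in c("alpha", "beta")) {
    S <- slot(enc, paste0("seq", toupper(substr(chain, 1, 1)),
                          substr(chain, 2, 100)))
    len <- slot(enc, paste0("lengths", toupper(substr(chain, 1, 1)),
                            substr(chain, 2, 100)))[i]
    P <- output[[paste0("seq_", chain)]]
    if (ncol(S) == 0L || len == 0L || is.null(P)) next
    tgt <- S[i, seq_len(len)]
    pr <- P[cbind(seq_len(len), tgt)]
    loss <- loss - sum(log(pmax(pr, 1e-12)))
  }
  for (sl in names(output$genes)) {
    pr <- output$genes[[sl]][enc@genes[i, sl]]
    loss <- loss - log(max(pr, 1e-12))
  }
  loss
}

.vaeInitParams <- function(fz, cfg) {
  D <- fz@dims$feature_dim; h <- cfg$hidden; d <- cfg$latent_dim
  p <- list(
    enc.W1 = .glorot(D, h), enc.b1 = numeric(h),
    enc.Wmu = .glorot(h, d), enc.bmu = numeric(d),
    enc.Wlv = .glorot(h, d), enc.blv = numeric(d),
    dec.W1 = .glorot(d, h), dec.b1 = numeric(h))
  L <- fz@maxLength
  for (chain in c("alpha", "beta")[c(fz@config$use_alpha, fz@config$use_beta)]) {
    p[[paste0("dec.seq_", chain, ".W")]] <- .glorot(h, L * .N_AA)
    p[[paste0("dec.seq_", chain, ".b")]] <- numeric(L * .N_AA)
  }
  for (sl in fz@config$gene_slots) {
    K <- length(fz@vocab@levels[[sl]]) + 1L
    p[[paste0("dec.gene.", sl, ".W")]] <- .glorot(h, K)
    p[[paste0("dec.gene.", sl, ".b")]] <- numeric(K)
  }
  p
}

## forward + (optionally) backward for one minibatch; returns losses, grads
.vaeStep <- function(fz, p, cfg, batch, eps = NULL, backprop = TRUE) {
  n <- batch$n; L <- fz@maxLength
  fw <- .featForward(fz, batch)
  F_ <- fw$features
  H1z <- .addBias(.gemm(F_, p$enc.W1), p$enc.b1); H1 <- pmax(H1z, 0)
  mu <- .addBias(.gemm(H1, p$enc.Wmu), p$enc.bmu)
  lv <- .addBias(.gemm(H1, p$enc.Wlv), p$enc.blv)
  lv <- pmin(pmax(lv, -15), 15)
  if (is.null(eps)) eps <- matrix(stats::rnorm(length(mu)), nrow(mu))
  sd_ <- exp(lv / 2)
  z <- mu + sd_ * eps
  Hdz <- .addBias(.gemm(z, p$dec.W1), p$dec.b1); Hd <- pmax(Hdz, 0)

  chains <- c("alpha", "beta")[c(fz@config$use_alpha, fz@config$use_beta)]
  recon <- 0; dHd <- matrix(0, n, ncol(Hd))
  for (chain in chains) {
    Wd <- p[[paste0("dec.seq_", chain, ".W")]]
    logits <- .addBias(.gemm(Hd, Wd), p[[paste0("dec.seq_", chain, ".b")]])
    S <- .unflatten(logits, n, L, .N_AA)            # [n*L, 20] position-major
    P <- .softmaxRows(S)
    tgt <- as.vector(batch$seq[[chain]])            # 1..20 or PAD
    valid <- tgt != .PAD
    rows_idx <- which(valid)
    recon <- recon - sum(log(pmax(P[cbind(rows_idx, tgt[rows_idx])], 1e-12))) / n
    if (backprop) {
      dS <- P
      dS[cbind(rows_idx, tgt[rows_idx])] <- dS[cbind(rows_idx, tgt[rows_idx])] - 1
      dS[!valid, ] <- 0
      dS <- dS / n
      dlogits <- .flatten(dS, n, L)
      dHd <- dHd + .gemm_tB(dlogits, Wd)
      p[[paste0("g.dec.seq_", chain, ".W")]] <- .gemm_tA(Hd, dlogits)
      p[[paste0("g.dec.seq_", chain, ".b")]] <- colSums(dlogits)
    }
  }
  for (sl in fz@config$gene_slots) {
    Wd <- p[[paste0("dec.gene.", sl, ".W")]]
    logits <- .addBias(.gemm(Hd, Wd), p[[paste0("dec.gene.", sl, ".b")]])
    P <- .softmaxRows(logits)
    tgt <- batch$genes[, sl]
    recon <- recon - sum(log(pmax(P[cbind(seq_len(n), tgt)], 1e-12))) / n
    if (backprop) {
      dP <- P; dP[cbind(seq_len(n), tgt)] <- dP[cbind(seq_len(n), tgt)] - 1
      dP <- dP / n
      dHd <- dHd + .gemm_tB(dP, Wd)
      p[[paste0("g.dec.gene.", sl, ".W")]] <- .gemm_tA(Hd, dP)
      p[[paste0("g.dec.gene.", sl, ".b")]] <- colSums(dP)
    }
  }
  kl <- sum(0.5 * (mu^2 + exp(lv) - 1 - lv)) / n
  out <- list(recon = recon, kl = kl, total = recon + kl, mu = mu, lv = lv)
  if (!backprop) return(out)

  dHdz <- dHd * (Hdz > 0)
  g <- list(dec.W1 = .gemm_tA(z, dHdz), dec.b1 = colSums(dHdz))
  dz <- .gemm_tB(dHdz, p$dec.W1)
  dmu <- dz + mu / n
  dlv <- dz * eps * 0.5 * sd_ + 0.5 * (exp(lv) - 1) / n
  dH1 <- .gemm_tB(dmu, p$enc.Wmu) + .gemm_tB(dlv, p$enc.Wlv)
  g$enc.Wmu <- .gemm_tA(H1, dmu); g$enc.bmu <- colSums(dmu)
  g$enc.Wlv <- .gemm_tA(H1, dlv); g$enc.blv <- colSums(dlv)
  dH1z <- dH1 * (H1z > 0)
  g$enc.W1 <- .gemm_tA(F_, dH1z); g$enc.b1 <- colSums(dH1z)
  dF <- .gemm_tB(dH1z, p$enc.W1)
  g <- c(g, .featBackward(fz, fw, dF))
  for (nm in names(p)) if (startsWith(nm, "g.")) {
    g[[sub("^g\\.", "", nm)]] <- p[[nm]]
  }
  out$grads <- g
  out
}

#' Train the variational autoencoder
#'
#' Joint minimization of reconstruction + variational loss with Adam
#' (learning rate 0.001 by default), reparameterized sampling during
#' training, minibatch updates, and a relative-improvement convergence
#' criterion. The run is reproducible under the config seed.
#'
#' @param enc an [EncodedTCRSet].
#' @param featConfig a [featurizerConfig()] with `pooling = "flatten"`;
#'   `NULL` builds a default from the chains/genes present in `enc`.
#' @param config a [vaeConfig()].
#' @return a [TCRVae]; `@log` holds per-epoch reconstruction/KL/total losses.
#' @export
trainVae <- function(enc, featConfig = NULL, config = vaeConfig()) {
  stopifnot(methods::is(enc, "EncodedTCRSet"), inherits(config, "tcr_vae_config"))
  if (is.null(featConfig)) {
    featConfig <- featurizerConfig(
      pooling = "flatten",
      useAlpha = ncol(enc@seqAlpha) > 0L, useBeta = ncol(enc@seqBeta) > 0L,
      geneSlots = .GENE_SLOTS[vapply(.GENE_SLOTS, function(sl)
        length(enc@vocab@levels[[sl]]) > 0L, logical(1))])
  }
  if (featConfig$pooling != "flatten")
    .stopf("the VAE featurizer must use flatten pooling")
  fz <- buildFeaturizer(featConfig, enc@vocab, enc@maxLength,
                        seed = .childSeed(config$seed, "vaefeat"))
  params <- c(fz@params,
              .withSeed(.childSeed(config$seed, "vaeinit"),
                        .vaeInitParams(fz, config)))
  n <- length(enc)
  if (n < 1L) .stopf("empty dataset")

  log_rows <- vector("list", config$max_epochs)
  .withSeed(.childSeed(config$seed, "vaetrain"), {
    st <- .adamInit(params)
    best <- Inf; stall <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      ep <- c(recon = 0, kl = 0)
      for (s0 in starts) {
        rows <- ord[s0:min(s0 + config$batch_size - 1L, n)]
        fz@params <- params[names(fz@params)]
        step <- .vaeStep(fz, params, config, .encBatch(enc, rows))
        if (!is.finite(step$total))
          .stopf("VAE training diverged (non-finite loss) at epoch %d", epoch)
        upd <- .adamStep(params, step$grads, st, config$learning_rate)
        params <- upd$params; st <- upd$state
        w <- length(rows) / n
        ep <- ep + c(step$recon, step$kl) * w
      }
      log_rows[[epoch]] <- data.frame(epoch = epoch, recon = ep[["recon"]],
                                      kl = ep[["kl"]],
                                      total = ep[["recon"]] + ep[["kl"]])
      tot <- ep[["recon"]] + ep[["kl"]]
      if (best - tot > config$tol * max(abs(best), 1)) {
        best <- tot; stall <- 0L
      } else stall <- stall + 1L
      if (is.finite(best) && stall >= config$patience) break
    }
  })
  fz@params <- params[names(fz@params)]
  vp <- params[setdiff(names(params), names(fz@params))]
  methods::new("TCRVae", featurizer = fz, params = vp, config = unclass(config),
               log = do.call(rbind, log_rows[!vapply(log_rows, is.null, logical(1))]))
}

#' Extract deterministic latent features
#'
#' Uses the posterior mean (not a sample), so identical clones always map
#' to identical latent vectors.
#'
#' @param vae a trained [TCRVae]; @param enc an [EncodedTCRSet].
#' @return matrix `n x latent_dim` of latent means; the per-clone log
#'   variances are attached as attribute `"log_var"`.
#' @export
extractLatent <- function(vae, enc) {
  stopifnot(methods::is(vae, "TCRVae"))
  fz <- vae@featurizer; p <- vae@params
  .checkVocabMatch(fz, enc)
  fw <- .featForward(fz, .encBatch(enc))
  H1 <- pmax(.addBias(.gemm(fw$features, p$enc.W1), p$enc.b1), 0)
  mu <- .addBias(.gemm(H1, p$enc.Wmu), p$enc.bmu)
  lv <- .addBias(.gemm(H1, p$enc.Wlv), p$enc.blv)
  rownames(mu) <- as.character(enc@cloneIndex)
  attr(mu, "log_var") <- lv
  mu
}

#' Write latent features as CSV (clone_index, latent_0..latent_{d-1})
#' @param latent matrix from [extractLatent()]; @param path output CSV.
#' @export
writeLatentCsv <- function(latent, path) {
  df <- data.frame(clone_index = rownames(latent) %||% seq_len(nrow(latent)))
  colnames_lat <- sprintf("latent_%d", seq_len(ncol(latent)) - 1L)
  df[colnames_lat] <- as.data.frame(unclass(latent))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
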