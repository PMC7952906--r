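## Weakly supervised whole-repertoire classifier: per-clone multi-head
## concept assignment through the adaptive ISRU activation, mean-pooled
## into per-repertoire concept proportions, fed to a classification layer.
## Includes the screening procedures: Monte-Carlo held-out-well training,
## AUC screening, Delta Prediction, pairwise variant comparison and
## per-sequence inference.

.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Adaptive inverse-square-root-unit (AISRU) activation
#'
#' `aisru(x) = L + (H - L)/2 * (1 + x / (a + (x^2)^b)^(1/(2b)))` with
#' trainable shape parameters `a > 0`, `b >= 1`: strictly increasing,
#' smooth, with limits `L` at `-Inf` and `H` at `+Inf`, and value
#' `(L + H)/2` at `x = 0`. Its gradient decays only polynomially in `|x|`,
#' avoiding the vanishing-gradient regime of the sigmoid. The `+1` shift
#' makes the range `(L, H)`; `shifted = FALSE` reproduces the unshifted
#' algebraic core, whose range under `L = 0, H = 1` is `(-0.5, 0.5)`.
#'
#' @param x numeric input (any shape).
#' @param a,b shape parameters (`a > 0`, `b >= 1`), recycled against `x`.
#' @param L,H output bounds.
#' @param shifted use the shifted form with range `(L, H)` (default).
#' @export
aisru <- function(x, a = 1, b = 1, L = 0, H = 1, shifted = TRUE) {
  if (any(a <= 0)) .stopf("aisru requires a > 0")
  if (any(b < 1)) .stopf("aisru requires b >= 1")
  g <- a + (x^2)^b
  core <- x / g^(1 / (2 * b))
  if (shifted) L + (H - L) / 2 * (1 + core) else L + (H - L) / 2 * core
}

#' Repertoire classifier configuration
#'
#' @param nConcepts number of attention heads / learned concepts.
#' @param learningRate Adam learning rate.
#' @param maxEpochs,tol,patience convergence of the training loss
#'   (relative-improvement criterion; the well count is too small for a
#'   validation split, held-out wells assess generalization instead).
#' @param batchWells wells per minibatch.
#' @param subsample clones drawn (without replacement) from each well at
#'   every training step. Stochastic bags prevent the classifier from
#'   memorizing idiosyncrasies of individual training wells -- the stable
#'   signal across subsamples is the shared sequence concept -- and keep
#'   the per-step cost independent of well size. `Inf` uses full wells.
#'   Inference always uses full wells.
#' @param countWeighted weight the pooling mean by clone counts instead of
#'   the plain per-sequence mean.
#' @param dropout dropout probability on the joint feature vector during
#'   training (inverted dropout; inference is deterministic).
#' @param l2 decoupled weight decay applied to weight matrices and
#'   embeddings each step. Together with `subsample` and `dropout` this
#'   biases training toward concepts shared across many clones rather than
#'   memorization of individual training-well clones.
#' @param shifted use the shifted AISRU (range (0,1)).
#' @param seed initialization/shuffling seed.
#' @export
repertoireConfig <- function(nConcepts = 12L, learningRate = 0.001,
                             maxEpochs = 150L, tol = 1e-3, patience = 10L,
                             batchWells = 4L, subsample = 64L,
                             countWeighted = FALSE, dropout = 0.5, l2 = 1e-3,
                             shifted = TRUE, seed = 1L) {
  structure(list(n_concepts = as.integer(nConcepts), learning_rate = learningRate,
                 max_epochs = as.integer(maxEpochs), tol = tol,
                 patience = as.integer(patience), batch_wells = as.integer(batchWells),
                 subsample = subsample,
                 count_weighted = isTRUE(countWeighted),
                 dropout = dropout, l2 = l2, shifted = isTRUE(shifted),
                 seed = as.integer(seed)),
            class = "tcr_rep_config")
}

## forward/backward over a batch of wells. wellIdx: integer well of each
## clone (1..W); y: class index per well (NULL for inference).
.repStep <- function(fz, p, cfg, batch, wellIdx, W, y = NULL, weights = NULL) {
  n <- batch$n
  fw <- .featForward(fz, batch)
  F_ <- fw$features
  drop_mask <- NULL
  if (!is.null(y) && cfg$dropout > 0) {       # inverted dropout, training only
    drop_mask <- matrix((stats::runif(length(F_)) >= cfg$dropout) /
                          (1 - cfg$dropout), nrow(F_))
    F_ <- F_ * drop_mask
  }
  X <- .addBias(.gemm(F_, p$concept.W), p$concept.b)             # [n, C]
  a <- .softplus(p$concept.ra) + 1e-4
  b <- 1 + .softplus(p$concept.rb)
  A <- rep(a, each = n); B <- rep(b, each = n)
  u <- X * X; g <- A + u^B
  core <- X / g^(1 / (2 * B))
  assign_ <- if (cfg$shifted) 0.5 * (1 + core) else 0.5 * core
  if (is.null(weights)) weights <- rep(1, n)
  wsum <- as.vector(rowsum(weights, wellIdx))
  props <- rowsum(assign_ * weights, wellIdx) / wsum              # [W, C]
  logits <- .addBias(.gemm(props, p$out.W), p$out.b)
  P <- .softmaxRows(logits)
  out <- list(fw = fw, assign = assign_, props = props, probs = P)
  if (is.null(y)) return(out)

  loss <- -sum(log(pmax(P[cbind(seq_len(W), y)], 1e-12))) / W
  dlog <- P; dlog[cbind(seq_len(W), y)] <- dlog[cbind(seq_len(W), y)] - 1
  dlog <- dlog / W
  g_ <- list(out.W = .gemm_tA(props, dlog), out.b = colSums(dlog))
  dprops <- .gemm_tB(dlog, p$out.W)                               # [W, C]
  dassign <- dprops[wellIdx, , drop = FALSE] * (weights / wsum[wellIdx])
  ## aisru backward
  dcore <- dassign * 0.5
  dX <- dcore * A * g^(-1 / (2 * B) - 1)
  lg <- log(g)
  lu <- ifelse(u > 0, log(u), 0)
  dcore_db <- core * (lg / (2 * B^2) - (u^B * lu) / (2 * B * g))
  da <- colSums(dcore * (-X / (2 * B)) * g^(-1 / (2 * B) - 1))
  db <- colSums(dcore * dcore_db)
  g_$concept.ra <- da * .sigmoid(p$concept.ra)
  g_$concept.rb <- db * .sigmoid(p$concept.rb)
  g_$concept.W <- .gemm_tA(F_, dX)
  g_$concept.b <- colSums(dX)
  dF <- .gemm_tB(dX, p$concept.W)
  if (!is.null(drop_mask)) dF <- dF * drop_mask
  out$loss <- loss
  out$grads <- c(g_, .featBackward(fz, fw, dF))
  out
}

.repInitParams <- function(fz, cfg, K, seed) {
  .withSeed(.childSeed(seed, "repinit"), {
    C <- cfg$n_concepts
    list(concept.W = .glorot(fz@dims$feature_dim, C), concept.b = numeric(C),
         concept.ra = rep(0.5413, C),   # softplus^-1(1): a starts near 1
         concept.rb = rep(-2, C),       # b starts near 1.13
         out.W = .glorot(C, K), out.b = numeric(K))
  })
}

## Train one repertoire classifier on a fixed set of wells.
## rows: clone rows of `enc` in play; wellIdx: well (1..W) of each row;
## y: class index per well; K: number of classes.
.repTrainOnce <- function(enc, rows, wellIdx, W, y, K, featConfig, cfg, seed,
                          weights = NULL) {
  fz <- buildFeaturizer(featConfig, enc@vocab, enc@maxLength,
                        seed = .childSeed(seed, "feat"))
  params <- c(fz@params, .repInitParams(fz, cfg, K, seed))
  .withSeed(.childSeed(seed, "sgd"), {
    st <- .adamInit(params)
    best <- Inf; stall <- 0L; history <- numeric(0)
    for (epoch in seq_len(cfg$max_epochs)) {
      well_ord <- sample.int(W)
      ep_loss <- 0; n_b <- 0L
      for (s0 in seq(1L, W, by = cfg$batch_wells)) {
        wb <- well_ord[s0:min(s0 + cfg$batch_wells - 1L, W)]
        sel <- which(wellIdx %in% wb)
        if (is.finite(cfg$subsample)) {
          sel <- unlist(lapply(wb, function(w) {
            ww <- sel[wellIdx[sel] == w]
            if (length(ww) > cfg$subsample) sample(ww, cfg$subsample) else ww
          }))
        }
        wmap <- match(wellIdx[sel], wb)
        fz@params <- params[names(fz@params)]
        stp <- .repStep(fz, params, cfg, .encBatch(enc, rows[sel]), wmap,
                        length(wb), y[wb],
                        weights = if (is.null(weights)) NULL else weights[rows[sel]])
        if (!is.finite(stp$loss)) .stopf("repertoire training diverged")
        upd <- .adamStep(params, stp$grads, st, cfg$learning_rate)
        params <- upd$params; st <- upd$state
        if (cfg$l2 > 0) {                      # decoupled weight decay
          decay <- 1 - cfg$learning_rate * cfg$l2
          for (nm in names(params))
            if (grepl("\\.W$", nm) || nm == "aa_embed" || startsWith(nm, "gene."))
              params[[nm]] <- params[[nm]] * decay
        }
        ep_loss <- ep_loss + stp$loss; n_b <- n_b + 1L
      }
      ep_loss <- ep_loss / n_b
      history <- c(history, ep_loss)
      if (best - ep_loss > cfg$tol * max(abs(best), 1)) { best <- ep_loss; stall <- 0L }
      else stall <- stall + 1L
      if (is.finite(best) && stall >= cfg$patience) break
    }
    fz@params <- params[names(fz@params)]
    list(fz = fz, params = params[setdiff(names(params), names(fz@params))],
         history = history)
  })
}

#' Run a trained repertoire classifier over wells
#'
#' Per-clone concept assignments (in `(0, 1)` through the AISRU heads),
#' per-well concept proportions (arithmetic mean of the well's
#' assignments, or count-weighted mean if the model was configured so) and
#' per-well class probabilities. Permutation-invariant in clone order
#' within a well.
#'
#' @param model a [TCRRepertoireModel].
#' @param enc an [EncodedTCRSet].
#' @param wells well id per clone (default: a single well).
#' @return list: `assignments` (n x concepts), `proportions` (wells x
#'   concepts), `probs` (wells x classes, rownames = well ids).
#' @export
repertoireForward <- function(model, enc, wells = NULL) {
  stopifnot(methods::is(model, "TCRRepertoireModel"))
  .checkVocabMatch(model@featurizer, enc)
  n <- length(enc)
  if (n == 0L) .stopf("empty well")
  if (is.null(wells)) wells <- rep("well_1", n)
  wf <- factor(wells, levels = unique(wells))
  weights <- if (model@config$count_weighted) as.numeric(enc@counts) else NULL
  out <- .repStep(model@featurizer, model@params, model@config, .encBatch(enc),
                  as.integer(wf), nlevels(wf), y = NULL, weights = weights)
  rownames(out$probs) <- levels(wf); colnames(out$probs) <- model@classLevels
  rownames(out$props) <- levels(wf)
  list(assignments = out$assign, proportions = out$props, probs = out$probs)
}

#' Monte-Carlo screening of cognate vs control wells
#'
#' Trains the repertoire classifier `nReps` times; in each repetition one
#' replicate well per condition is held out, the model is re-initialized
#' from a repetition-indexed seed and trained on the remaining wells
#' (binary cognate-vs-control labels), and the held-out wells are
#' predicted. Held-out predictions accumulate into the screening AUC
#' (cognate vs control wells, rank statistic) and the Delta Prediction
#' (mean held-out cognate prediction minus mean control prediction), so
#' every prediction used downstream comes from a repetition in which its
#' well was unseen during training.
#'
#' @param x a [TCRCloneSet] whose `sample_id` is the well id.
#' @param conditions named character vector, well id -> condition name.
#' @param cognate condition name treated as cognate (default `"cognate"`).
#' @param nReps Monte-Carlo repetitions (default 100).
#' @param featConfig optional [featurizerConfig()] (global max).
#' @param config a [repertoireConfig()].
#' @param seed master seed.
#' @param aucThreshold significance cutoff on the screening AUC.
#' @return list of class `tcr_screen_result`: `auc`, `delta`,
#'   `significant`, `perRep` (held-out well predictions), `perClone`
#'   (per-clone cognate scores averaged over the repetitions in which the
#'   clone's well was held out -- the out-of-train scores to use for
#'   interpretation), `model` (fit from the final repetition).
#' @export
trainRepertoireScreen <- function(x, conditions, cognate = "cognate",
                                  nReps = 100L, featConfig = NULL,
                                  config = repertoireConfig(), seed = 1L,
                                  aucThreshold = 0.90) {
  stopifnot(methods::is(x, "TCRCloneSet"))
  wells <- unique(x@clones$sample_id)
  if (!all(wells %in% names(conditions)))
    .stopf("every well needs a condition")
  conditions <- conditions[wells]
  conds <- unique(conditions)
  if (!cognate %in% conds) .stopf("no wells with the cognate condition '%s'", cognate)
  if (length(conds) < 2L) .stopf("need at least one control condition")
  reps_per_cond <- table(conditions)
  if (any(reps_per_cond < 2L))
    .stopf("every condition needs >= 2 replicate wells for held-out evaluation")
  if (any(reps_per_cond < 3L))
    .warnf("condition(s) with only 2 replicates: held-out estimates will be noisy")

  enc <- encodeTCRs(x)
  well_of_clone <- x@clones$sample_id
  featConfig <- featConfig %||% featurizerConfig(
    pooling = "global_max",
    useAlpha = ncol(enc@seqAlpha) > 0L, useBeta = ncol(enc@seqBeta) > 0L,
    geneSlots = .GENE_SLOTS[vapply(.GENE_SLOTS, function(sl)
      length(enc@vocab@levels[[sl]]) > 0L, logical(1))])
  class_levels <- c("control", "cognate")
  y_of_well <- stats::setNames(
    ifelse(conditions == cognate, 2L, 1L), wells)
  weights_all <- if (config$count_weighted) as.numeric(enc@counts) else NULL

  per_rep <- list(); last_fit <- NULL
  clone_sum <- numeric(length(enc)); clone_n <- integer(length(enc))
  for (r in seq_len(nReps)) {
    rs <- .childSeed(seed, "screenrep", r)
    held <- .withSeed(.childSeed(rs, "holdout"), {
      unname(unlist(lapply(split(wells, conditions[wells]),
                           function(wv) sample(wv, 1L))))
    })
    train_wells <- setdiff(wells, held)
    rows <- which(well_of_clone %in% train_wells)
    wf <- factor(well_of_clone[rows], levels = train_wells)
    fit <- .repTrainOnce(enc, rows, as.integer(wf), length(train_wells),
                         unname(y_of_well[train_wells]), 2L, featConfig,
                         config, rs, weights = weights_all)
    last_fit <- fit
    model <- methods::new("TCRRepertoireModel", featurizer = fit$fz,
                          params = fit$params, config = unclass(config),
                          classLevels = class_levels,
                          log = data.frame(epoch = seq_along(fit$history),
                                           loss = fit$history))
    held_rows <- which(well_of_clone %in% held)
    fwd <- repertoireForward(model, .subsetEnc(enc, held_rows),
                             wells = well_of_clone[held_rows])
    per_rep[[r]] <- data.frame(rep = r, well = rownames(fwd$probs),
                               condition = unname(conditions[rownames(fwd$probs)]),
                               prob_cognate = fwd$probs[, "cognate"],
                               row.names = NULL)
    ## held-out per-sequence scores (out-of-train interpretation contract)
    ps <- perSequenceInference(model, .subsetEnc(enc, held_rows))
    clone_sum[held_rows] <- clone_sum[held_rows] + ps
    clone_n[held_rows] <- clone_n[held_rows] + 1L
  }
  pr <- do.call(rbind, per_rep)
  is_cog <- pr$condition == cognate
  auc <- .aucRank(pr$prob_cognate, is_cog)
  delta <- mean(pr$prob_cognate[is_cog]) - mean(pr$prob_cognate[!is_cog])
  model <- methods::new("TCRRepertoireModel", featurizer = last_fit$fz,
                        params = last_fit$params, config = unclass(config),
                        classLevels = class_levels,
                        log = data.frame(epoch = seq_along(last_fit$history),
                                         loss = last_fit$history))
  per_clone <- data.frame(
    clone = seq_len(length(enc)), well = well_of_clone,
    condition = unname(conditions[well_of_clone]),
    prob_cognate = ifelse(clone_n > 0L, clone_sum / clone_n, NA_real_),
    n_heldout_reps = clone_n)
  structure(list(auc = auc, delta = delta, significant = auc > aucThreshold,
                 aucThreshold = aucThreshold, perRep = pr,
                 perClone = per_clone, model = model),
            class = "tcr_screen_result")
}

#' Per-sequence inference with a trained repertoire classifier
#'
#' Scores each clone as a singleton repertoire: its concept assignments
#' are its own proportions, so the classifier returns a cognate
#' probability per clone, ranking antigen-specific sequences above
#' background.
#'
#' @param model a [TCRRepertoireModel] (e.g. `screen$model`).
#' @param enc an [EncodedTCRSet] of clones to score.
#' @return numeric vector of per-clone cognate probabilities.
#' @export
perSequenceInference <- function(model, enc) {
  fwd <- repertoireForward(model, enc, wells = seq_len(length(enc)))
  unname(fwd$probs[, "cognate"])
}

#' Pairwise variant comparison via 1 - Delta Prediction
#'
#' For every pair of conditions, runs [trainRepertoireScreen()] with one
#' condition as cognate and the other as control, in both orientations,
#' and reports `1 - mean(Delta)`: large values mean the two repertoires
#' are hard to distinguish (similar), small values mean divergent
#' responses. The matrix is symmetric by construction; the diagonal is 1
#' by convention (a condition is indistinguishable from itself).
#'
#' @param x a [TCRCloneSet] with `sample_id` = well id.
#' @param conditions named character vector well -> condition (>= 2
#'   conditions, each with replicate wells).
#' @param nReps Monte-Carlo repetitions per orientation.
#' @param config a [repertoireConfig()].
#' @param seed master seed.
#' @return symmetric matrix of `1 - Delta Prediction` values.
#' @export
pairwiseVariantComparison <- function(x, conditions, nReps = 25L,
                                      config = repertoireConfig(), seed = 1L) {
  conds <- unique(conditions)
  if (length(conds) < 2L) .stopf("need >= 2 conditions")
  M <- matrix(1, length(conds), length(conds), dimnames = list(conds, conds))
  for (i in seq_along(conds)) for (j in seq_along(conds)) {
    if (j <= i) next
    pair_wells <- names(conditions)[conditions %in% conds[c(i, j)]]
    sub <- .subsetClones(x, x@clones$sample_id %in% pair_wells)
    d_ij <- trainRepertoireScreen(sub, conditions[pair_wells],
                                  cognate = conds[i], nReps = nReps,
                                  config = config,
                                  seed = .childSeed(seed, "pair", i * 131L + j))$delta
    d_ji <- trainRepertoireScreen(sub, conditions[pair_wells],
                                  cognate = conds[j], nReps = nReps,
                                  config = config,
                                  seed = .childSeed(seed, "pair", j * 131L + i))$delta
    M[i, j] <- M[j, i] <- 1 - (d_ij + d_ji) / 2
  }
  M
}
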