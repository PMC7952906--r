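## Supervised per-sequence model: featurization block in global-max mode
## feeding a softmax classification layer (cross-entropy) or a single-node
## regression head (mean squared error), with stratified
## train/validation/test splitting, early stopping on validation loss, and
## Monte-Carlo cross-validation. Only out-of-train predictions are used for
## downstream interpretation.

#' Training configuration for the sequence model
#'
#' @param task `"classify"` or `"regress"`.
#' @param learningRate Adam learning rate (default 0.001).
#' @param trainFrac fraction used for training (default 0.75); the
#'   remainder is split evenly into validation (early stopping) and test.
#' @param patience early stopping: stop after this many validation
#'   evaluations without improvement; best weights are restored.
#' @param maxEpochs,batchSize optimization bounds.
#' @param nMonteCarlo number of Monte-Carlo repetitions, each re-drawing
#'   the split with a fresh seed derived from the master seed.
#' @param logTarget apply `log1p` to regression targets.
#' @param seed master seed.
#' @export
trainConfig <- function(task = c("classify", "regress"), learningRate = 0.001,
                        trainFrac = 0.75, patience = 10L, maxEpochs = 150L,
                        batchSize = 64L, nMonteCarlo = 100L, logTarget = FALSE,
                        seed = 1L) {
  task <- match.arg(task)
  stopifnot(trainFrac > 0, trainFrac < 1, patience >= 1L)
  structure(list(task = task, learning_rate = learningRate,
                 train_frac = trainFrac, patience = as.integer(patience),
                 max_epochs = as.integer(maxEpochs), batch_size = as.integer(batchSize),
                 n_monte_carlo = as.integer(nMonteCarlo),
                 log_target = isTRUE(logTarget), seed = as.integer(seed)),
            class = "tcr_train_config")
}

.seqHeadForward <- function(fz, p, batch, task, classLevels) {
  fw <- .featForward(fz, batch)
  logits <- .addBias(.gemm(fw$features, p$head.W), p$head.b)
  if (task == "classify") list(fw = fw, logits = logits, probs = .softmaxRows(logits))
  else list(fw = fw, pred = logits[, 1L])
}

.seqLossGrads <- function(fz, p, batch, y, task) {
  n <- batch$n
  out <- .seqHeadForward(fz, p, batch, task, NULL)
  if (task == "classify") {
    P <- out$probs
    loss <- -sum(log(pmax(P[cbind(seq_len(n), y)], 1e-12))) / n
    dlog <- P; dlog[cbind(seq_len(n), y)] <- dlog[cbind(seq_len(n), y)] - 1
    dlog <- dlog / n
  } else {
    loss <- mean((out$pred - y)^2)
    dlog <- matrix(2 * (out$pred - y) / n, ncol = 1L)
  }
  g <- list(head.W = .gemm_tA(out$fw$features, dlog), head.b = colSums(dlog))
  dF <- .gemm_tB(dlog, p$head.W)
  list(loss = loss, grads = c(g, .featBackward(fz, out$fw, dF)))
}

.seqEvalLoss <- function(fz, p, enc, rows, y, task) {
  out <- .seqHeadForward(fz, p, .encBatch(enc, rows), task, NULL)
  if (task == "classify") {
    -mean(log(pmax(out$probs[cbind(seq_along(rows), y[rows])], 1e-12)))
  } else mean((out$pred - y[rows])^2)
}

.drawSplit <- function(y, task, trainFrac, seed) {
  n <- length(y)
  .withSeed(seed, {
    for (try_i in 1:20) {
      if (task == "classify") {
        train <- integer(0); val <- integer(0); test <- integer(0)
        for (cl in unique(y)) {
          idx <- sample(which(y == cl))
          n_tr <- max(1L, round(length(idx) * trainFrac))
          rest <- idx[-seq_len(n_tr)]
          n_val <- ceiling(length(rest) / 2)
          train <- c(train, idx[seq_len(n_tr)])
          val <- c(val, rest[seq_len(n_val)])
          test <- c(test, rest[-seq_len(n_val)])
        }
      } else {
        idx <- sample.int(n)
        n_tr <- round(n * trainFrac)
        rest <- idx[-seq_len(n_tr)]
        n_val <- ceiling(length(rest) / 2)
        train <- idx[seq_len(n_tr)]; val <- rest[seq_len(n_val)]
        test <- rest[-seq_len(n_val)]
      }
      ok <- length(val) > 0L && length(test) > 0L &&
        (task != "classify" ||
           (all(unique(y) %in% y[train]) && all(unique(y) %in% y[val])))
      if (ok) return(list(train = train, val = val, test = test))
    }
    .stopf("could not draw a split with every class present in train and validation")
  })
}

.seqTrainOnce <- function(enc, featConfig, config, y, split, seed) {
  fz <- buildFeaturizer(featConfig, enc@vocab, enc@maxLength,
                        seed = .childSeed(seed, "init"))
  K <- if (config$task == "classify") max(y) else 1L
  params <- c(fz@params,
              .withSeed(.childSeed(seed, "head"), {
                list(head.W = .glorot(fz@dims$feature_dim, K), head.b = numeric(K))
              }))
  n_tr <- length(split$train)
  .withSeed(.childSeed(seed, "sgd"), {
    st <- .adamInit(params)
    best <- Inf; best_params <- params; stall <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(split$train)
      for (s0 in seq(1L, n_tr, by = config$batch_size)) {
        rows <- ord[s0:min(s0 + config$batch_size - 1L, n_tr)]
        fz@params <- params[names(fz@params)]
        sg <- .seqLossGrads(fz, params, .encBatch(enc, rows), y[rows], config$task)
        if (!is.finite(sg$loss)) .stopf("training diverged at epoch %d", epoch)
        upd <- .adamStep(params, sg$grads, st, config$learning_rate)
        params <- upd$params; st <- upd$state
      }
      fz@params <- params[names(fz@params)]
      vl <- .seqEvalLoss(fz, params, enc, split$val, y, config$task)
      if (vl < best - 1e-6) { best <- vl; best_params <- params; stall <- 0L }
      else stall <- stall + 1L
      if (stall >= config$patience) break
    }
    fz@params <- best_params[names(fz@params)]
    list(fz = fz, params = best_params[setdiff(names(best_params), names(fz@params))],
         val_loss = best)
  })
}

#' Train the supervised sequence model with Monte-Carlo cross-validation
#'
#' Each repetition re-draws a stratified 75/12.5/12.5
#' train/validation/test split from a repetition-indexed seed, trains the
#' featurization block + head, early-stops on validation loss, and records
#' predictions on the held-out test clones. A clone's aggregated prediction
#' is the mean over repetitions in which it was held out; clones never held
#' out are reported as `NA`, not zero.
#'
#' @param enc an [EncodedTCRSet] with labels (class for `"classify"`,
#'   numeric target for `"regress"`).
#' @param featConfig a global-max [featurizerConfig()]; `NULL` builds one
#'   from the chains/genes present.
#' @param config a [trainConfig()].
#' @return list of class `tcr_seq_fit`: `model` (a [TCRSequenceModel], the
#'   repetition with best validation loss), `predictions` (aggregated
#'   held-out predictions per clone), `perRep` (long per-repetition test
#'   predictions), `metrics` (per-repetition held-out macro metrics, for
#'   classification).
#' @export
trainSequenceModel <- function(enc, featConfig = NULL, config = trainConfig()) {
  stopifnot(methods::is(enc, "EncodedTCRSet"), inherits(config, "tcr_train_config"))
  if (is.null(featConfig)) {
    featConfig <- featurizerConfig(
      pooling = "global_max",
      useAlpha = ncol(enc@seqAlpha) > 0L, useBeta = ncol(enc@seqBeta) > 0L,
      geneSlots = .GENE_SLOTS[vapply(.GENE_SLOTS, function(sl)
        length(enc@vocab@levels[[sl]]) > 0L, logical(1))])
  }
  if (featConfig$pooling != "global_max")
    .stopf("the supervised model requires global_max pooling")
  n <- length(enc)
  if (config$task == "classify") {
    labels <- as.character(enc@labels)
    if (any(is.na(labels))) .stopf("classification requires a label for every clone")
    classLevels <- sort(unique(labels))
    if (length(classLevels) < 2L) .stopf("classification requires >= 2 classes")
    y <- match(labels, classLevels)
  } else {
    y <- as.numeric(enc@labels)
    if (any(is.na(y))) .stopf("regression requires a numeric target for every clone")
    if (config$log_target) y <- log1p(y)
    classLevels <- character(0)
  }

  per_rep <- list(); metrics <- list()
  agg_sum <- matrix(0, n, max(length(classLevels), 1L))
  agg_n <- integer(n)
  best_val <- Inf; best_fit <- NULL
  for (rep_i in seq_len(config$n_monte_carlo)) {
    rs <- .childSeed(config$seed, "mcrep", rep_i)
    split <- .drawSplit(y, config$task, config$train_frac, .childSeed(rs, "split"))
    fit <- .seqTrainOnce(enc, featConfig, config, y, split, rs)
    if (fit$val_loss < best_val) { best_val <- fit$val_loss; best_fit <- fit }
    out <- .seqHeadForward(fit$fz, fit$params, .encBatch(enc, split$test),
                           config$task, classLevels)
    if (config$task == "classify") {
      P <- out$probs; colnames(P) <- classLevels
      agg_sum[split$test, ] <- agg_sum[split$test, ] + P
      per_rep[[rep_i]] <- data.frame(rep = rep_i, clone = split$test,
                                     truth = classLevels[y[split$test]], P,
                                     check.names = FALSE)
      m <- classificationMetrics(P, classLevels[y[split$test]])
      metrics[[rep_i]] <- cbind(rep = rep_i, m[m$class == "macro", -1L])
    } else {
      agg_sum[split$test, 1L] <- agg_sum[split$test, 1L] + out$pred
      per_rep[[rep_i]] <- data.frame(rep = rep_i, clone = split$test,
                                     truth = y[split$test], pred = out$pred)
      metrics[[rep_i]] <- data.frame(
        rep = rep_i, cor_spearman = suppressWarnings(
          stats::cor(out$pred, y[split$test], method = "spearman")))
    }
    agg_n[split$test] <- agg_n[split$test] + 1L
  }
  agg <- agg_sum / ifelse(agg_n > 0L, agg_n, NA_integer_)
  predictions <- data.frame(clone = seq_len(n), n_test_reps = agg_n)
  if (config$task == "classify") {
    colnames(agg) <- classLevels
    predictions <- cbind(predictions, agg)
  } else predictions$pred <- agg[, 1L]

  model <- methods::new("TCRSequenceModel", featurizer = best_fit$fz,
                        params = best_fit$params, config = unclass(config),
                        classLevels = classLevels,
                        log = do.call(rbind, metrics))
  structure(list(model = model, predictions = predictions,
                 perRep = do.call(rbind, per_rep),
                 metrics = do.call(rbind, metrics)),
            class = "tcr_seq_fit")
}

#' Predict encoded clones with a trained sequence model
#'
#' Deterministic forward pass; classification rows are softmax
#' probabilities summing to 1, supporting ranking clones by per-class
#' probability to pick the most predictive (representative) sequences.
#'
#' @param model a [TCRSequenceModel]; @param enc an [EncodedTCRSet].
#' @return data.frame of per-clone class probabilities (or `pred` for
#'   regression).
#' @export
predictSequences <- function(model, enc) {
  stopifnot(methods::is(model, "TCRSequenceModel"))
  .checkVocabMatch(model@featurizer, enc)
  out <- .seqHeadForward(model@featurizer, model@params, .encBatch(enc),
                         model@config$task, model@classLevels)
  if (model@config$task == "classify") {
    P <- as.data.frame(out$probs)
    colnames(P) <- model@classLevels
    cbind(clone = seq_len(length(enc)), P)
  } else data.frame(clone = seq_len(length(enc)), pred = out$pred)
}
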