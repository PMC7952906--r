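## Model interpretation: learned-motif extraction from max-pool argmax
## indices, kernel-to-prediction multinomial regression, exhaustive residue
## permutation sensitivity, Residue Sensitivity Logo data, and
## sensitivity-vs-annotation AUC.

## unclipped input-coordinate receptive field [start, end] of position t at
## layer l (may extend past the sequence; callers clip and flag)
.receptiveField <- function(convSpec, layer, t, maxLength) {
  Ls <- c(maxLength, .chainDims(maxLength, convSpec))
  rng <- c(t, t)
  for (l in rev(seq_len(layer))) {
    sp <- convSpec[[l]]
    pl <- .convPadLeft(Ls[l], sp[1], sp[2])
    rng <- c((rng[1] - 1L) * sp[2] + 1L - pl,
             (rng[2] - 1L) * sp[2] + sp[1] - pl)
  }
  rng
}

.rfWidth <- function(convSpec, layer) {
  w <- 1L; jump <- 1L
  for (l in seq_len(layer)) {
    w <- w + (convSpec[[l]][1] - 1L) * jump
    jump <- jump * convSpec[[l]][2]
  }
  w
}

## Phase-align harvested windows before building a PFM: a kernel may fire
## at slightly different offsets relative to its motif across clones. The
## seed is the window with the best total best-shift agreement with all
## others; every window contributes its letters in the seed frame.
.alignWindows <- function(windows, width, max_shift = NULL) {
  mat <- do.call(rbind, strsplit(windows, ""))
  n <- nrow(mat)
  if (is.null(max_shift)) max_shift <- width - 2L
  shifts <- seq(-max_shift, max_shift)
  match_at <- function(i, seed_row, s) {
    js <- seq_len(width)
    ok <- js + s >= 1L & js + s <= width
    if (!any(ok)) return(c(0L, s))
    m <- sum(mat[i, js[ok]] != "-" & mat[i, js[ok]] == seed_row[js[ok] + s])
    c(m, s)
  }
  totals <- vapply(seq_len(n), function(c_) {
    seed_row <- mat[c_, ]
    sum(vapply(seq_len(n), function(i)
      max(vapply(shifts, function(s) match_at(i, seed_row, s)[1], numeric(1))),
      numeric(1)))
  }, numeric(1))
  seed <- which.max(totals)
  seed_row <- mat[seed, ]
  counts <- matrix(0, .N_AA, width, dimnames = list(.AA, NULL))
  aligned <- character(n)
  for (i in seq_len(n)) {
    best <- c(-1L, 0L)
    for (s in shifts) {
      cand <- match_at(i, seed_row, s)
      if (cand[1] > best[1]) best <- cand
    }
    s <- best[2]
    frame_chars <- rep("-", width)
    js <- seq_len(width)
    ok <- js + s >= 1L & js + s <= width & mat[i, ] != "-"
    frame_chars[js[ok] + s] <- mat[i, js[ok]]
    aligned[i] <- paste(frame_chars, collapse = "")
    hit <- frame_chars != "-"
    if (any(hit))
      counts[cbind(match(frame_chars[hit], .AA), which(hit))] <-
        counts[cbind(match(frame_chars[hit], .AA), which(hit))] + 1
  }
  pfm <- apply(counts, 2L, function(cl)
    if (sum(cl) == 0) rep(1 / .N_AA, .N_AA) else cl / sum(cl))
  rownames(pfm) <- .AA
  list(pfm = pfm, aligned = aligned)
}

#' Kernel-to-prediction association by multinomial linear regression
#'
#' Fits each class's predicted probability as a linear function of the
#' pooled kernel activations; the coefficients measure how strongly a
#' kernel's motif drives the prediction of each class. A rank-deficient
#' design falls back to a ridge solve with a warning.
#'
#' @param activations matrix `n x M` of pooled kernel activations.
#' @param predictions matrix/data.frame `n x K` of per-class predicted
#'   probabilities (or an `n`-vector for a single output).
#' @return matrix `M x K` of coefficients (kernels in rows).
#' @export
kernelAssociation <- function(activations, predictions) {
  A <- as.matrix(activations)
  A <- sweep(A, 2L, colMeans(A))      # centered: constant kernels drop to 0
  P <- as.matrix(predictions)
  X <- cbind(1, A)
  qrX <- qr(X)
  beta <- if (qrX$rank < ncol(X)) {
    .warnf("rank-deficient activation design; using ridge fallback")
    lambda <- 1e-3
    solve(crossprod(X) + lambda * diag(ncol(X)), crossprod(X, P))
  } else qr.coef(qrX, P)
  B <- beta[-1L, , drop = FALSE]
  rownames(B) <- colnames(A) %||% sprintf("kernel_%d", seq_len(ncol(A)))
  colnames(B) <- colnames(P)
  B
}

#' Extract learned sequence motifs from a trained sequence model
#'
#' For each class: rank clones by held-out predicted probability, keep the
#' `topN` most predictive, and for the kernel most associated with the
#' class (by [kernelAssociation()] of pooled layer activations against the
#' predictions) harvest the receptive-field window at each clone's argmax
#' position. Windows clipped at sequence boundaries are padded with `-`
#' and flagged. The harvested windows give a position-frequency matrix and
#' consensus for logo rendering.
#'
#' @param fit a `tcr_seq_fit` from [trainSequenceModel()] (its aggregated
#'   held-out predictions satisfy the out-of-train interpretation
#'   contract), or a [TCRSequenceModel] plus explicit `predictions`.
#' @param enc the [EncodedTCRSet] the fit was trained on.
#' @param topN clones harvested per class.
#' @param layer convolutional layer whose kernels are interpreted
#'   (default 1: width-5 windows, the most directly readable motifs).
#' @param chain chain to harvest from.
#' @param predictions optional data.frame of per-clone per-class
#'   probabilities overriding `fit$predictions`.
#' @return list of class `tcr_motif_report`: per class the associated
#'   kernel ranking, harvested windows, PFM (columns sum to 1), consensus
#'   string, argmax positions and activations; plus the kernel width.
#' @export
extractMotifs <- function(fit, enc, topN = 25L, layer = 1L, chain = "beta",
                          predictions = NULL) {
  if (inherits(fit, "tcr_seq_fit")) {
    model <- fit$model
    if (is.null(predictions)) predictions <- fit$predictions
  } else model <- fit
  stopifnot(methods::is(model, "TCRSequenceModel"))
  if (model@featurizer@config$pooling != "global_max")
    .stopf("motif extraction requires a global_max (not flatten) model")
  if (is.null(predictions))
    .stopf("held-out predictions are required for motif extraction")
  chain <- match.arg(chain, c("alpha", "beta"))
  classes <- model@classLevels
  fz <- model@featurizer
  convSpec <- fz@config$conv_spec
  width <- .rfWidth(convSpec, layer)

  usable <- which(predictions$n_test_reps > 0L &
                    stats::complete.cases(predictions[classes]))
  if (length(usable) == 0L) .stopf("no clones with held-out predictions")
  sub <- .subsetEnc(enc, usable)
  fw <- .featForward(fz, .encBatch(sub), keepLayer1 = TRUE)
  pool <- fw$chains[[chain]]$pool_layers[[layer]]
  acts <- pool$pooled; argm <- pool$arg
  beta <- kernelAssociation(acts, as.matrix(predictions[usable, classes]))

  S <- if (chain == "beta") sub@seqBeta else sub@seqAlpha
  lens <- if (chain == "beta") sub@lengthsBeta else sub@lengthsAlpha
  res <- list()
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    kernel_rank <- order(beta[, ci], decreasing = TRUE)
    top_kernel <- kernel_rank[1L]
    ord <- order(predictions[usable, cl], decreasing = TRUE)
    pick <- ord[seq_len(min(topN, length(ord)))]
    windows <- character(0); positions <- integer(0); clipped <- logical(0)
    activations <- numeric(0)
    for (i in pick) {
      t_arg <- argm[i, top_kernel]
      rf <- .receptiveField(convSpec, layer, t_arg, fz@maxLength)
      chars <- rep("-", width)
      span <- rf[1]:rf[2]
      inside <- span >= 1L & span <= lens[i]
      chars[inside] <- .AA[S[i, span[inside]]]
      windows <- c(windows, paste(chars, collapse = ""))
      positions <- c(positions, rf[1])
      clipped <- c(clipped, any(!inside))
      activations <- c(activations, acts[i, top_kernel])
    }
    al <- .alignWindows(windows, width)
    res[[cl]] <- list(class = cl, beta = beta[, ci], kernel_rank = kernel_rank,
                      top_kernel = top_kernel, clones = usable[pick],
                      windows = windows, aligned = al$aligned,
                      positions = positions,
                      clipped = clipped, activations = activations,
                      pfm = al$pfm, consensus = .pfmConsensus(al$pfm))
  }
  structure(list(classes = res, kernel_width = width, layer = layer,
                 chain = chain), class = "tcr_motif_report")
}

.modelScorer <- function(model, class = NULL) {
  if (methods::is(model, "TCRSequenceModel")) {
    if (model@config$task == "classify") {
      if (is.null(class)) .stopf("a class must be named for a classifier")
      function(e) predictSequences(model, e)[[class]]
    } else function(e) predictSequences(model, e)$pred
  } else if (methods::is(model, "TCRRepertoireModel")) {
    function(e) perSequenceInference(model, e)
  } else .stopf("unsupported model type for sensitivity analysis")
}

#' Exhaustive residue permutation sensitivity of one clone
#'
#' For every position of each present chain and each of the 19 alternative
#' residues, the prediction delta `prediction(mutant) - prediction(wild
#' type)` is computed by a deterministic forward pass (exactly `19 x
#' length` deltas per chain, no sampling). Per position, `magnitude` is
#' the mean absolute delta and `direction` the mean signed delta.
#'
#' @param model a [TCRSequenceModel] or [TCRRepertoireModel].
#' @param enc an [EncodedTCRSet]; @param clone clone row to perturb.
#' @param class class whose probability is tracked (classifiers).
#' @return list of class `tcr_sensitivity_profile`: per chain a list with
#'   `delta` (length x 20 matrix, wild-type column 0), `magnitude`,
#'   `direction`, `wt` (residues) and the wild-type prediction.
#' @export
residueSensitivity <- function(model, enc, clone, class = NULL) {
  scorer <- .modelScorer(model, class)
  fz <- if (methods::is(model, "TCRSequenceModel")) model@featurizer else model@featurizer
  chains <- c("alpha", "beta")[c(fz@config$use_alpha, fz@config$use_beta)]
  wt_enc <- .subsetEnc(enc, clone)
  wt_pred <- scorer(wt_enc)
  out <- list()
  for (chain in chains) {
    S <- if (chain == "beta") enc@seqBeta else enc@seqAlpha
    len <- if (chain == "beta") enc@lengthsBeta[clone] else enc@lengthsAlpha[clone]
    if (len == 0L) next
    wt_row <- S[clone, ]
    muts <- list(); pos_of <- integer(0); sub_of <- integer(0)
    for (p in seq_len(len)) {
      alts <- setdiff(seq_len(.N_AA), wt_row[p])
      for (aa in alts) { pos_of <- c(pos_of, p); sub_of <- c(sub_of, aa) }
    }
    n_mut <- length(pos_of)
    rows <- rep(clone, n_mut)
    big <- .subsetEnc(enc, rows)
    Smut <- if (chain == "beta") big@seqBeta else big@seqAlpha
    Smut[cbind(seq_len(n_mut), pos_of)] <- sub_of
    if (chain == "beta") big@seqBeta <- Smut else big@seqAlpha <- Smut
    preds <- scorer(big)
    delta <- matrix(0, len, .N_AA, dimnames = list(NULL, .AA))
    delta[cbind(pos_of, sub_of)] <- preds - wt_pred
    out[[chain]] <- list(
      delta = delta,
      magnitude = vapply(seq_len(len), function(p)
        mean(abs(delta[p, -wt_row[p]])), numeric(1)),
      direction = vapply(seq_len(len), function(p)
        mean(delta[p, -wt_row[p]]), numeric(1)),
      wt = .AA[wt_row[seq_len(len)]])
  }
  structure(c(out, list(wt_prediction = wt_pred, clone = clone)),
            class = "tcr_sensitivity_profile")
}

#' Residue Sensitivity Logo rendering data
#'
#' Glyph size is proportional to the per-position mean absolute prediction
#' change; the color class is red when the average direction of change is
#' negative (most substitutions lower the prediction), blue when positive,
#' neutral at zero.
#'
#' @param profile a `tcr_sensitivity_profile` from [residueSensitivity()].
#' @return data.frame (chain, position, letter, size, direction, color).
#' @export
residueSensitivityLogo <- function(profile) {
  stopifnot(inherits(profile, "tcr_sensitivity_profile"))
  rows <- list()
  for (chain in intersect(c("alpha", "beta"), names(profile))) {
    pr <- profile[[chain]]
    rows[[chain]] <- data.frame(
      chain = chain, position = seq_along(pr$wt), letter = pr$wt,
      size = pr$magnitude, direction = pr$direction,
      color = ifelse(pr$direction < 0, "red",
                     ifelse(pr$direction > 0, "blue", "neutral")),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' AUC of sensitivity magnitude against a binary position annotation
#'
#' Rank-based AUC quantifying how well per-position sensitivity magnitude
#' predicts an external binary annotation (e.g. contact residues). With a
#' single-class annotation the result is absent (`NA`), not a number.
#'
#' @param profile a `tcr_sensitivity_profile`; @param annotation logical
#'   flags per position; @param chain which chain's profile to use.
#' @export
sensitivityAnnotationAuc <- function(profile, annotation, chain = "beta") {
  pr <- profile[[chain]]
  if (is.null(pr)) .stopf("no %s chain in the profile", chain)
  stopifnot(length(annotation) == length(pr$magnitude))
  .aucRank(pr$magnitude, as.logical(annotation))
}

#' Write motif PFMs in MEME minimal format
#'
#' @param report a `tcr_motif_report`; @param path output path.
#' @export
writeMemeMotifs <- function(report, path) {
  stopifnot(inherits(report, "tcr_motif_report"))
  con <- file(path, "wt"); on.exit(close(con))
  writeLines(c("MEME version 4", "", sprintf("ALPHABET= %s", paste(.AA, collapse = "")),
               "", "strands: +", "",
               "Background letter frequencies",
               paste(sprintf("%s %.4f", .AA, rep(1 / 20, 20)), collapse = " "), ""),
             con)
  for (cl in names(report$classes)) {
    m <- report$classes[[cl]]
    writeLines(sprintf("MOTIF %s_kernel%d %s", cl, m$top_kernel, m$consensus), con)
    writeLines(sprintf("letter-probability matrix: alength= 20 w= %d nsites= %d E= 0",
                       ncol(m$pfm), length(m$windows)), con)
    for (j in seq_len(ncol(m$pfm)))
      writeLines(paste(sprintf("%.6f", m$pfm[, j]), collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}
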