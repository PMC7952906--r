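# Build a tiny classifier fit object around a hand-set featurizer so motif
# harvesting can be checked against brute-force expectations.
handSetFit <- function(motif, enc, classLevels = c("class_1", "class_2")) {
  fz <- handSetKernelFeaturizer(motif, enc@vocab, enc@maxLength)
  fz@config$gene_slots <- character(0)
  # head: class 1 driven by kernel 1's pooled activation
  W <- matrix(0, featureDim(fz), 2L); W[1, 1] <- 5; W[1, 2] <- -5
  model <- methods::new("TCRSequenceModel", featurizer = fz,
                        params = list(head.W = W, head.b = c(-20, 20)),
                        config = unclass(trainConfig()), classLevels = classLevels,
                        log = data.frame())
  model
}

test_that("motif harvesting recovers a hand-set kernel's windows", {
  motif <- "LGETQ"
  seqs <- c("CAALGETQWNDF", "CWNLGETQDAAF", "CWNDAALGETQF", "CWWNDAAPPQRF")
  cs <- TCRCloneSet(data.frame(sample_id = "s", cdr3_beta = seqs,
                               label = c("class_1", "class_1", "class_1", "class_2"),
                               count = 1), maxLength = 16L)
  enc <- encodeTCRs(cs)
  model <- handSetFit(motif, enc)
  preds <- predictSequences(model, enc)
  predictions <- data.frame(clone = 1:4, n_test_reps = 1L,
                            class_1 = preds$class_1, class_2 = preds$class_2)
  rep_ <- suppressWarnings(
    extractMotifs(model, enc, topN = 3L, predictions = predictions))

  expect_s3_class(rep_, "tcr_motif_report")
  expect_equal(rep_$kernel_width, 5L)
  m1 <- rep_$classes$class_1
  expect_equal(m1$top_kernel, 1L)
  # harvested windows on motif-bearing clones equal the motif itself
  expect_true(all(m1$windows[!m1$clipped] == motif))
  # PFM columns sum to 1; identical windows give single-letter columns
  expect_equal(colSums(m1$pfm), rep(1, 5L))
  expect_equal(m1$consensus, motif)
  expect_true(all(apply(m1$pfm, 2, max) == 1))
  # argmax-derived window starts lie within the true sequences
  expect_true(all(m1$positions >= 1 &
                    m1$positions <= nchar(seqs[m1$clones])))

  # MEME export round-trip sanity
  f <- tempfile(fileext = ".meme")
  writeMemeMotifs(rep_, f)
  txt <- readLines(f)
  expect_true(any(grepl("MEME version", txt)))
  expect_true(any(grepl(paste0("MOTIF class_1_kernel1 ", motif), txt)))

  # flatten-mode models are rejected
  fzf <- buildFeaturizer(featurizerConfig("flatten"), enc@vocab, 16L)
  bad <- methods::new("TCRSequenceModel", featurizer = fzf,
                      params = model@params, config = unclass(trainConfig()),
                      classLevels = model@classLevels, log = data.frame())
  expect_error(extractMotifs(bad, enc, predictions = predictions), "global_max")
})

test_that("kernel association recovers planted signal and ignores noise", {
  set.seed(12)
  n <- 80L
  acts <- matrix(runif(n * 6), n)
  prob1 <- acts[, 3] * 0.8 + 0.1           # class 1 driven by kernel 3
  preds <- cbind(class_1 = prob1, class_2 = 1 - prob1)
  B <- kernelAssociation(acts, preds)
  expect_equal(unname(which.max(B[, "class_1"])), 3L)
  # a constant activation column gets ~0 coefficient (ridge fallback warns)
  acts2 <- cbind(acts, const = 1)
  expect_warning(B2 <- kernelAssociation(acts2, preds), "rank-deficient")
  expect_lt(abs(B2["const", "class_1"]), 1e-6)
  # permuting clone order leaves coefficients unchanged
  p <- sample(n)
  expect_equal(kernelAssociation(acts[p, ], preds[p, ]), B)
})

test_that("residue sensitivity is exhaustive, signed and wild-type-zero", {
  seqs <- c("CAALGETQWNDF", "CWWNDAAPPQRF")
  cs <- TCRCloneSet(data.frame(sample_id = "s", cdr3_beta = seqs,
                               label = c("class_1", "class_2"), count = 1),
                    maxLength = 16L)
  enc <- encodeTCRs(cs)
  model <- handSetFit("LGETQ", enc)
  prof <- residueSensitivity(model, enc, clone = 1L, class = "class_1")
  pr <- prof$beta
  L <- nchar(seqs[1])
  # exactly 19 deltas per position: wild-type column is zero
  expect_equal(dim(pr$delta), c(L, 20L))
  expect_equal(pr$delta[cbind(seq_len(L), match(pr$wt, colnames(pr$delta)))],
               rep(0, L))
  expect_equal(sum(pr$delta != 0 | TRUE) - L, 19L * L)  # 19 non-wt cells/row
  # magnitude >= |direction| always
  expect_true(all(pr$magnitude >= abs(pr$direction) - 1e-12))
  # the hand-set model reads mainly the motif: mutating motif positions
  # hurts the prediction and dominates the sensitivity profile
  motif_pos <- 3:7
  expect_true(all(pr$direction[motif_pos] < 0))
  expect_gt(mean(pr$magnitude[motif_pos]), mean(pr$magnitude[-motif_pos]))

  # a model that ignores its input entirely has all-zero deltas everywhere
  blind <- model
  blind@params$head.W[] <- 0
  prof0 <- residueSensitivity(blind, enc, clone = 1L, class = "class_1")
  expect_true(all(prof0$beta$delta == 0))
  expect_true(all(prof0$beta$magnitude == 0))

  # logo data: sizes from magnitude, colors from direction sign
  logo <- residueSensitivityLogo(prof)
  expect_equal(nrow(logo), L)
  expect_equal(logo$color[logo$direction < 0][1], "red")
  expect_true(all(logo$color[logo$direction == 0] == "neutral"))
  zero <- prof; zero$beta$magnitude[] <- 0; zero$beta$direction[] <- 0
  lz <- residueSensitivityLogo(zero)
  expect_true(all(lz$size == 0) && all(lz$color == "neutral"))
})

test_that("sensitivity-vs-annotation AUC matches pair counting", {
  prof <- structure(list(beta = list(magnitude = c(5, 4, 3, 2, 1, 0.5, 6, 2.5, 0.1, 0.2),
                                     direction = rep(-1, 10), wt = rep("A", 10))),
                    class = "tcr_sensitivity_profile")
  flags <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  got <- sensitivityAnnotationAuc(prof, flags)
  # exhaustive pair enumeration oracle
  pos <- which(flags); neg <- which(!flags); ok <- 0
  m <- prof$beta$magnitude
  for (i in pos) for (j in neg) ok <- ok + (m[i] > m[j]) + 0.5 * (m[i] == m[j])
  expect_equal(got, ok / (length(pos) * length(neg)))
  # perfect ranking -> 1; constant magnitudes -> 0.5 by midrank
  prof$beta$magnitude <- ifelse(flags, 2, 1)
  expect_equal(sensitivityAnnotationAuc(prof, flags), 1)
  prof$beta$magnitude <- rep(1, 10)
  expect_equal(sensitivityAnnotationAuc(prof, flags), 0.5)
  # single-class annotation -> absent
  expect_true(is.na(sensitivityAnnotationAuc(prof, rep(TRUE, 10))))
})
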