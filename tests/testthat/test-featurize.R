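test_that("feature dimensionality follows the stated block sizes", {
  fx <- motifFixture()
  vocab <- fx$enc@vocab
  # beta only, global max, three beta gene slots: 128 + 3 x 48 = 272
  fz <- buildFeaturizer(featurizerConfig("global_max",
                                         geneSlots = c("v_beta", "d_beta", "j_beta")),
                        vocab, 40L)
  expect_equal(featureDim(fz), 272L)

  # alpha + beta chains, no genes: 2 x 128 = 256
  fz2 <- buildFeaturizer(featurizerConfig("global_max", useAlpha = TRUE,
                                          useBeta = TRUE), vocab, 40L)
  expect_equal(featureDim(fz2), 256L)

  # flatten mode: maps_last x final conv length; 40 -> 14 -> 5 under the
  # stride schedule, so 128 x 5 = 640
  fz3 <- buildFeaturizer(featurizerConfig("flatten"), vocab, 40L)
  expect_equal(fz3@dims$layer_lengths, c(40L, 14L, 5L))
  expect_equal(featureDim(fz3), 640L)

  expect_error(featurizerConfig("global_max", useBeta = FALSE),
               "at least one")
})

test_that("a hand-set kernel localizes its motif shift-invariantly", {
  motif <- "LGETQ"
  # same residue multiset around the motif, placed at different offsets
  seqs <- c("CAALGETQWNDF", "CWNLGETQDAAF", "CWNDAALGETQF")
  cs <- TCRCloneSet(data.frame(sample_id = "s", cdr3_beta = seqs, count = 1),
                    maxLength = 16L)
  enc <- encodeTCRs(cs)
  fz <- handSetKernelFeaturizer(motif, enc@vocab, 16L)
  fb <- featurizeTCRs(fz, enc, layer1 = TRUE)
  pooled <- fb$pooled1$beta[, 1]
  argm <- fb$argmax1$beta[, 1]

  # brute-force oracle: activation at position t = matches of the motif
  # template over the window (t-2)..(t+2)
  brute <- function(s) {
    ch <- strsplit(s, "")[[1]]
    best <- -Inf; where <- NA
    for (t in seq_along(ch)) {
      win <- (t - 2):(t + 2)
      m <- strsplit(motif, "")[[1]]
      sc <- sum(vapply(1:5, function(j)
        win[j] >= 1 && win[j] <= length(ch) && ch[win[j]] == m[j], logical(1)))
      if (sc > best) { best <- sc; where <- t }
    }
    c(best, where)
  }
  for (i in 1:3) {
    bo <- brute(seqs[i])
    expect_equal(pooled[i], bo[1])
    expect_equal(argm[i], bo[2])
  }
  # full motif match scores 5 wherever it sits: shift invariance
  expect_equal(pooled, rep(5, 3))
  # argmax sits at the motif implant (centre of the window = offset + 2)
  expect_equal(argm, c(4L, 4L, 7L) + 2L)
  # argmax positions always lie within the true sequence (pad masking)
  expect_true(all(argm <= nchar(seqs)))

  # adding a second copy of the motif elsewhere never lowers the pooled max
  cs2 <- TCRCloneSet(data.frame(sample_id = "s",
                                cdr3_beta = c("CAALGETQWNDWWWF",
                                              "CAALGETQWLGETQF"), count = 1),
                     maxLength = 16L)
  enc2 <- encodeTCRs(cs2)
  fb2 <- featurizeTCRs(fz, enc2, layer1 = TRUE)
  expect_gte(fb2$pooled1$beta[2, 1], fb2$pooled1$beta[1, 1])
})

test_that("forward pass is deterministic and validates its inputs", {
  fx <- motifFixture()
  fz <- buildFeaturizer(featurizerConfig("global_max",
                                         geneSlots = c("v_beta", "j_beta")),
                        fx$enc@vocab, fx$enc@maxLength)
  fb1 <- featurizeTCRs(fz, fx$enc)
  fb2 <- featurizeTCRs(fz, fx$enc)
  expect_identical(fb1$features, fb2$features)

  # clones identical in sequence and genes get identical features
  twice <- tcrlearn:::.subsetEnc(fx$enc, c(3L, 3L))
  fb <- featurizeTCRs(fz, twice)
  expect_equal(fb$features[1, ], fb$features[2, ])

  # vocabulary mismatch fails loudly
  other <- TCRCloneSet(data.frame(sample_id = "s", cdr3_beta = "CASSF",
                                  v_beta = "TRBVX", count = 1))
  expect_error(featurizeTCRs(fz, encodeTCRs(other, maxLength = fx$enc@maxLength)),
               "vocabulary")

  # an empty enabled chain (all-pad row) is rejected
  bad <- fx$enc
  bad@lengthsBeta[1] <- 0L
  bad@seqBeta[1, ] <- 21L
  expect_error(featurizeTCRs(fz, bad), "empty beta")
})

test_that("backpropagation matches central finite differences (double path)", {
  old <- tcrlearn:::.useFloat(FALSE)
  on.exit(tcrlearn:::.useFloat(old))
  fx <- motifFixture(nPerClass = 4L, seed = 3L)
  enc <- fx$enc
  fz <- buildFeaturizer(featurizerConfig("global_max", geneSlots = "v_beta"),
                        enc@vocab, enc@maxLength, seed = 2L)
  y <- match(enc@labels, sort(unique(enc@labels)))
  params <- c(fz@params, tcrlearn:::.withSeed(5L, list(
    head.W = tcrlearn:::.glorot(featureDim(fz), 3L), head.b = numeric(3L))))
  batch <- tcrlearn:::.encBatch(enc)
  lossOf <- function(p) {
    fz2 <- fz; fz2@params <- p[names(fz@params)]
    tcrlearn:::.seqLossGrads(fz2, p, batch, y, "classify")$loss
  }
  sg <- local({
    fz2 <- fz; fz2@params <- params[names(fz@params)]
    tcrlearn:::.seqLossGrads(fz2, params, batch, y, "classify")
  })
  set.seed(42)
  for (nm in names(params)) {
    for (ii in sample(length(params[[nm]]), min(3L, length(params[[nm]])))) {
      h <- 1e-5
      up <- params; up[[nm]][ii] <- up[[nm]][ii] + h
      dn <- params; dn[[nm]][ii] <- dn[[nm]][ii] - h
      num <- (lossOf(up) - lossOf(dn)) / (2 * h)
      rel <- abs(sg$grads[[nm]][ii] - num) /
        max(1e-6, abs(num) + abs(sg$grads[[nm]][ii]))
      expect_lt(rel, 5e-3, label = sprintf("grad mismatch %s[%d]", nm, ii))
    }
  }
})

test_that("checkpoints embed the config and refuse mismatches", {
  fx <- motifFixture()
  cfg <- featurizerConfig("global_max", geneSlots = "v_beta")
  fz <- buildFeaturizer(cfg, fx$enc@vocab, fx$enc@maxLength)
  f <- tempfile(fileext = ".rds")
  saveCheckpoint(fz, f)
  back <- loadCheckpoint(f, expected = cfg)
  expect_equal(back@params, fz@params)
  expect_error(loadCheckpoint(f, expected = featurizerConfig("flatten")),
               "does not match")
  saveRDS(list(a = 1), f)
  expect_error(loadCheckpoint(f), "not a tcrlearn checkpoint")
})
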