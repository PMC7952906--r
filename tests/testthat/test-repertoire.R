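test_that("AISRU satisfies its contract", {
  # value 0.5 at x = 0 for any valid shape parameters
  for (a in c(0.5, 1, 4)) for (b in c(1, 2, 3))
    expect_equal(aisru(0, a, b), 0.5)
  # direct evaluation of the closed form at (1, 1, 1)
  expect_equal(aisru(1, 1, 1), 0.5 * (1 + 1 / sqrt(2)), tolerance = 1e-9)
  expect_equal(aisru(1, 1, 1), 0.85355, tolerance = 1e-5)

  # strictly increasing, bounded in (0, 1), correct limits
  x <- seq(-50, 50, length.out = 2001)
  for (pars in list(c(1, 1), c(0.3, 2), c(5, 1.5))) {
    y <- aisru(x, pars[1], pars[2])
    expect_true(all(diff(y) > 0))
    expect_true(all(y > 0 & y < 1))
  }
  expect_equal(aisru(1e8, 1, 1), 1, tolerance = 1e-6)
  expect_equal(aisru(-1e8, 1, 1), 0, tolerance = 1e-6)

  # custom bounds and the unshifted (printed) form with range (-0.5, 0.5)
  expect_equal(aisru(0, L = -1, H = 3), 1)
  y0 <- aisru(x, shifted = FALSE)
  expect_true(all(y0 > -0.5 & y0 < 0.5))
  expect_equal(aisru(0, shifted = FALSE), 0)

  # gradient decays polynomially, not exponentially: at x = 20 the slope
  # is still orders of magnitude above the sigmoid's
  slope <- (aisru(20.01, 1, 1) - aisru(19.99, 1, 1)) / 0.02
  sig_slope <- exp(-20) / (1 + exp(-20))^2
  expect_gt(slope, 100 * sig_slope)

  expect_error(aisru(1, a = 0), "a > 0")
  expect_error(aisru(1, b = 0.5), "b >= 1")
})

test_that("concept proportions are pooled means with the stated invariances", {
  fx <- motifFixture(nPerClass = 10L)
  enc <- fx$enc
  cfg <- repertoireConfig(nConcepts = 4L, seed = 2L)
  fz <- buildFeaturizer(featurizerConfig("global_max", geneSlots = "v_beta"),
                        enc@vocab, enc@maxLength, seed = 2L)
  model <- methods::new("TCRRepertoireModel", featurizer = fz,
                        params = tcrlearn:::.repInitParams(fz, cfg, 2L, 3L),
                        config = unclass(cfg),
                        classLevels = c("control", "cognate"),
                        log = data.frame())
  wells <- rep(c("w1", "w2"), each = 15L)
  fwd <- repertoireForward(model, enc, wells)

  # assignments in (0,1); proportions are arithmetic means per well
  expect_true(all(fwd$assignments > 0 & fwd$assignments < 1))
  expect_equal(fwd$proportions["w1", ],
               colMeans(fwd$assignments[1:15, ]))

  # permuting clone order within wells leaves well probabilities unchanged
  perm <- c(sample(1:15), sample(16:30))
  fwd2 <- repertoireForward(model, tcrlearn:::.subsetEnc(enc, perm),
                            wells[perm])
  expect_equal(fwd2$probs, fwd$probs, tolerance = 1e-12)

  # duplicating every clone the same number of times preserves proportions
  dup <- rep(seq_len(30L), each = 3L)
  fwd3 <- repertoireForward(model, tcrlearn:::.subsetEnc(enc, dup), wells[dup])
  expect_equal(fwd3$proportions, fwd$proportions, tolerance = 1e-12)

  # per-sequence inference: identical clones get identical scores in [0,1]
  ps <- perSequenceInference(model, tcrlearn:::.subsetEnc(enc, c(1L, 1L, 2L)))
  expect_equal(ps[1], ps[2])
  expect_true(all(ps >= 0 & ps <= 1))
  # two-class softmax: cognate and control probabilities sum to 1
  fwd_single <- repertoireForward(model, enc, wells = seq_len(30L))
  expect_equal(unname(rowSums(fwd_single$probs)), rep(1, 30L), tolerance = 1e-6)

  expect_error(repertoireForward(model, tcrlearn:::.subsetEnc(enc, integer(0))),
               "empty")
})

test_that("screen bookkeeping: held-out predictions, Delta, degenerate inputs", {
  cfg <- simulationConfig(seed = 5L, motifRate = 0.6,
                          wells = list(n_control_conditions = 1L,
                                       n_replicates = 3L, clones_per_well = 30L))
  we <- simulateWellExperiment(cfg)
  sc <- trainRepertoireScreen(we$clones, we$conditions, nReps = 2L,
                              config = repertoireConfig(maxEpochs = 8L,
                                                        learningRate = 0.01,
                                                        subsample = 16L),
                              seed = 3L)
  expect_s3_class(sc, "tcr_screen_result")
  # one held-out well per condition per repetition
  expect_equal(nrow(sc$perRep), 2L * 2L)
  expect_true(all(table(sc$perRep$rep) == 2L))
  expect_true(all(sc$perRep$prob_cognate >= 0 & sc$perRep$prob_cognate <= 1))
  expect_true(sc$auc >= 0 && sc$auc <= 1)
  expect_true(sc$delta >= -1 && sc$delta <= 1)
  expect_identical(sc$significant, sc$auc > 0.90)
  # Delta Prediction is exactly the difference of mean held-out predictions
  pc <- sc$perRep$prob_cognate[sc$perRep$condition == "cognate"]
  pn <- sc$perRep$prob_cognate[sc$perRep$condition != "cognate"]
  expect_equal(sc$delta, mean(pc) - mean(pn))

  # degenerate inputs
  one_cond <- we$conditions[we$conditions == "cognate"]
  sub <- tcrlearn:::.subsetClones(we$clones,
                                  sampleIds(we$clones) %in% names(one_cond))
  expect_error(trainRepertoireScreen(sub, one_cond), "control")
  expect_error(trainRepertoireScreen(we$clones, we$conditions,
                                     cognate = "nope"), "cognate")
})

test_that("pairwise variant comparison separates disjoint motifs, not exchangeable wells", {
  wells <- list(n_control_conditions = 2L, n_replicates = 3L,
                clones_per_well = 60L)
  weA <- simulateWellExperiment(simulationConfig(seed = 41L, nClasses = 1L,
                                                 motifs = "WDRN", motifRate = 0.7,
                                                 wells = wells))
  weB <- simulateWellExperiment(simulationConfig(seed = 42L, nClasses = 1L,
                                                 motifs = "HKEY", motifRate = 0.7,
                                                 wells = wells))
  ren <- function(we, cond, pre) {
    df <- cloneData(we$clones)
    d <- df[grepl(pre, df$sample_id), ]
    d$sample_id <- sub(pre, cond, d$sample_id)
    d
  }
  cfg <- repertoireConfig(learningRate = 0.01, subsample = 32L, dropout = 0.5,
                          l2 = 1e-3, maxEpochs = 40L, patience = 1e6L)

  # two conditions with disjoint implanted motifs: distinguishable, so
  # 1 - Delta is small; matrix symmetric with maximal diagonal
  x1 <- TCRCloneSet(rbind(ren(weA, "condA", "^cognate"),
                          ren(weB, "condB", "^cognate")), maxLength = 20L)
  wl <- unique(sampleIds(x1))
  conds1 <- stats::setNames(sub("_w[0-9]+$", "", wl), wl)
  M1 <- pairwiseVariantComparison(x1, conds1, nReps = 3L, config = cfg, seed = 5L)
  expect_equal(M1, t(M1))
  expect_equal(unname(diag(M1)), c(1, 1))
  expect_lt(M1["condA", "condB"], 0.5)

  # two background-only condition groups cut from one experiment are
  # exchangeable: Delta ~ 0, entry near 1
  x2 <- TCRCloneSet(rbind(ren(weA, "ctlX", "^control_1"),
                          ren(weA, "ctlY", "^control_2")), maxLength = 20L)
  wl2 <- unique(sampleIds(x2))
  conds2 <- stats::setNames(sub("_w[0-9]+$", "", wl2), wl2)
  M2 <- pairwiseVariantComparison(x2, conds2, nReps = 3L, config = cfg, seed = 6L)
  expect_gt(M2["ctlX", "ctlY"], 0.7)
  expect_gt(M2["ctlX", "ctlY"], M1["condA", "condB"])
})

test_that("training separates wells when the signal is strong", {
  cfg <- simulationConfig(seed = 9L, motifRate = 0.9,
                          wells = list(n_control_conditions = 2L,
                                       n_replicates = 3L, clones_per_well = 60L))
  we <- simulateWellExperiment(cfg)
  sc <- trainRepertoireScreen(we$clones, we$conditions, nReps = 3L,
                              config = repertoireConfig(maxEpochs = 40L,
                                                        learningRate = 0.01,
                                                        subsample = 32L,
                                                        patience = 1e6L),
                              seed = 4L)
  expect_gte(sc$auc, 0.9)
  expect_gt(sc$delta, 0.2)
  # per-sequence inference ranks motif clones above background
  df <- cloneData(we$clones)
  cog <- which(grepl("^cognate", df$sample_id))
  ps <- perSequenceInference(sc$model, encodeTCRs(tcrlearn:::.subsetClones(
    we$clones, grepl("^cognate", df$sample_id)),
    vocab = sc$model@featurizer@vocab,
    maxLength = sc$model@featurizer@maxLength))
  truth <- we$truth$has_motif[cog]
  expect_gt(tcrlearn:::.aucRank(ps, truth), 0.8)
})
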