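# Fixtures built in code; heavier simulated objects are cached per session.

.fixture_env <- new.env(parent = emptyenv())

# Hand-written 12-row clone table: one non-IUPAC CDR3, one 41-mer, two rows
# that aggregate (same sample, sequence and genes), plus 8 clean rows.
curationFixtureFile <- function() {
  long41 <- paste(rep("A", 39), collapse = "")
  df <- data.frame(
    sample_id = "s1",
    cdr3_beta = c("CASSLGETQYF", "CASSLGETQYF",        # aggregate, counts 3 + 5
                  "CASSXTGELFF",                        # non-IUPAC X
                  paste0("C", long41, "F"),             # 41 residues
                  "CASSPDRGYTF", "CASRGDSNQPQHF", "CASSSRSTDTQYF",
                  "CATSDLRGEQYF", "CASSYSTGDEQFF", "CASSLNRGQETQYF",
                  "CSARDWGSYEQYF", "CASSPGQGAYEQYF"),
    v_beta = c("TRBV5-1", "TRBV5-1", "TRBV7-2", "TRBV7-2",
               "TRBV12-3", "TRBV12-3", "TRBV9", "TRBV9",
               "TRBV28", "TRBV28", "TRBV19", "TRBV19"),
    j_beta = "TRBJ2-7",
    count = c(3L, 5L, 2L, 4L, 1L, 1L, 2L, 3L, 1L, 2L, 6L, 1L),
    label = rep(c("antigen_A", "antigen_B"), each = 6L),
    stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", row.names = FALSE, quote = FALSE)
  f
}

# Seeded 3-class fully-separable dataset shared by several tests.
motifFixture <- function(nPerClass = 30L, motifRate = 1.0, seed = 11L) {
  key <- sprintf("motif_%d_%g_%d", nPerClass, motifRate, seed)
  if (is.null(.fixture_env[[key]])) {
    cfg <- simulationConfig(seed = seed, nClasses = 3L, motifRate = motifRate)
    cs <- simulateSequenceDataset(cfg, nPerClass = nPerClass)
    .fixture_env[[key]] <- list(config = cfg, clones = cs,
                                enc = encodeTCRs(cs))
  }
  .fixture_env[[key]]
}

# A featurizer whose first conv-layer kernel 1 is a hand-set detector for a
# given width-5 motif (one-hot template on the embedding), so activation-scan
# expectations can be brute-forced.
handSetKernelFeaturizer <- function(motif, vocab, maxLength) {
  stopifnot(nchar(motif) == 5L)
  fc <- featurizerConfig("global_max")
  fz <- buildFeaturizer(fc, vocab, maxLength, seed = 99L)
  p <- fz@params
  # identity-style embedding: residue r -> unit vector e_r (cols 1..20); pad -> 0
  E <- matrix(0, 21, 64); E[cbind(1:20, 1:20)] <- 1
  p$aa_embed <- E
  W <- matrix(0, 5 * 64, 32)
  idx <- tcrlearn:::.aaIndex(strsplit(motif, "")[[1]])
  for (j in 1:5) W[(j - 1) * 64 + idx[j], 1] <- 1   # kernel 1 counts matches
  p$beta.conv1.W <- W
  p$beta.conv1.b <- rep(0, 32)
  fz@params <- p
  fz
}
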