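test_that("curation drops non-IUPAC and over-length rows and aggregates duplicates", {
  f <- curationFixtureFile()
  cs <- parseCloneTable(f)
  rep_ <- curationReport(cs)

  expect_equal(rep_$n_input, 12L)
  expect_equal(rep_$dropped_non_iupac, 1L)
  expect_equal(rep_$dropped_over_length, 1L)
  expect_equal(rep_$n_aggregated, 1L)
  expect_equal(length(cs), 9L)
  expect_false("CASSXTGELFF" %in% cloneData(cs)$cdr3_beta)
  expect_true(all(nchar(cloneData(cs)$cdr3_beta) <= 40L))

  agg <- cloneData(cs)[cloneData(cs)$cdr3_beta == "CASSLGETQYF", ]
  expect_equal(nrow(agg), 1L)
  expect_equal(agg$count, 8L)  # 3 + 5, reads summed

  # aggregation conservation: kept counts + dropped counts == input counts
  expect_equal(sum(cloneCounts(cs)) + rep_$dropped_total_count, 3+5+2+4+1+1+2+3+1+2+6+1)
})

test_that("same amino-acid clone with different genes is not merged", {
  df <- data.frame(sample_id = "s1", cdr3_beta = "CASSLGETQYF",
                   v_beta = c("TRBV5-1", "TRBV6-5"), count = c(2, 2))
  f <- tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(length(parseCloneTable(f)), 2L)
})

test_that("status column flags unproductive rows; without it empty CDR3s drop", {
  df <- data.frame(sample_id = "s1",
                   cdr3_beta = c("CASSLGETQYF", "CASRDSYEQYF", ""),
                   frame = c("In", "Out", "In"), count = 1)
  f <- tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", row.names = FALSE, quote = FALSE)
  cs <- parseCloneTable(f, columnMap = c(status = "frame"))
  expect_equal(length(cs), 1L)
  expect_equal(curationReport(cs)$dropped_unproductive_or_empty, 2L)
})

test_that("configuration and degenerate-input errors are explicit", {
  f <- curationFixtureFile()
  expect_error(parseCloneTable(f, columnMap = c(cdr3_beta = "no_such_col")),
               "absent from file")
  bad <- data.frame(sample_id = "s1", cdr3_beta = "CASSXXF", count = 1)
  fb <- tempfile(fileext = ".tsv")
  write.table(bad, fb, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(parseCloneTable(fb), "empty dataset")
})

test_that("write/parse round-trips clones, absent chains and comments", {
  fx <- motifFixture()
  f <- tempfile(fileext = ".tsv")
  writeCloneTable(fx$clones, f, seedComment = 11L)
  expect_match(readLines(f, n = 1L), "^# seed: 11")
  back <- parseCloneTable(f, maxLength = 20L)
  expect_equal(curationReport(back)$n_dropped, 0L)  # filter idempotence
  expect_equal(cloneData(back)$cdr3_beta, cloneData(fx$clones)$cdr3_beta)
  expect_equal(cloneData(back)$count, cloneData(fx$clones)$count)
  # absent alpha chain comes back absent
  expect_true(all(is.na(cloneData(back)$cdr3_alpha)))

  # empty clone set -> header-only file
  empty <- TCRCloneSet(data.frame(cdr3_beta = character(0)))
  fe <- tempfile(fileext = ".tsv")
  writeCloneTable(empty, fe)
  expect_length(readLines(fe), 1L)

  # csv dialect inferred from extension
  fc <- tempfile(fileext = ".csv")
  writeCloneTable(fx$clones, fc)
  expect_equal(length(parseCloneTable(fc, maxLength = 20L)), length(fx$clones))
})

test_that("encoding is right-padded, reversible and injective", {
  fx <- motifFixture()
  enc <- fx$enc
  dec <- decodeTCRs(enc)
  expect_identical(dec$cdr3_beta, cloneData(fx$clones)$cdr3_beta)
  expect_identical(dec$v_beta, cloneData(fx$clones)$v_beta)

  # "CAS" padded to length 5
  cs <- TCRCloneSet(data.frame(sample_id = "s", cdr3_beta = "CAS", count = 1),
                    maxLength = 5L)
  e <- encodeTCRs(cs)
  expect_identical(as.vector(e@seqBeta[1, ]), c(2L, 1L, 16L, 21L, 21L))
  expect_equal(e@lengthsBeta, 3L)

  # right-padding invariant: no pad before true length, only pad after
  S <- enc@seqBeta
  for (i in seq_len(5)) {
    l <- enc@lengthsBeta[i]
    expect_false(any(S[i, seq_len(l)] == 21L))
    if (l < ncol(S)) expect_true(all(S[i, (l + 1):ncol(S)] == 21L))
  }

  # injectivity on valid clones: distinct rows encode distinctly
  key <- apply(cbind(S, enc@genes), 1L, paste, collapse = ",")
  df <- cloneData(fx$clones)
  src <- paste(df$cdr3_beta, df$v_beta, df$d_beta, df$j_beta)
  expect_equal(anyDuplicated(key) > 0, anyDuplicated(src) > 0)
})

test_that("gene vocabulary is a stable bijection with a reserved absent index", {
  fx <- motifFixture()
  vocab <- geneVocabulary(fx$clones)
  lv <- geneLevels(vocab, "v_beta")
  expect_equal(anyDuplicated(lv), 0L)
  expect_equal(absentIndex(vocab, "v_beta"), length(lv) + 1L)
  enc <- encodeTCRs(fx$clones, vocab = vocab)
  expect_true(all(enc@genes[, "v_beta"] %in% seq_len(length(lv))))
  expect_true(all(enc@genes[, "v_alpha"] == absentIndex(vocab, "v_alpha")))

  # save/load stability
  f <- tempfile(fileext = ".json")
  writeGeneVocabulary(vocab, f)
  expect_identical(readGeneVocabulary(f)@levels, vocab@levels)

  # unseen gene under a fixed vocabulary is an error, not a silent remap
  other <- TCRCloneSet(data.frame(sample_id = "s", cdr3_beta = "CASSF",
                                  v_beta = "TRBV999", count = 1))
  expect_error(encodeTCRs(other, vocab = vocab), "not in vocabulary")
})
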