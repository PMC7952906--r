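## Parsing, curation, aggregation and numeric encoding of clone tables.

#' Construct a TCRCloneSet from a data.frame
#'
#' Normalizes the canonical columns (missing optional columns become `NA`),
#' then enforces the clone invariants through the class validity check.
#'
#' @param df data.frame with at least one CDR3 column.
#' @param maxLength maximum admissible CDR3 length.
#' @param metadata optional list attached to the object.
#' @return a [TCRCloneSet]
#' @export
TCRCloneSet <- function(df, maxLength = 40L, metadata = list()) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in .CLONE_COLS) if (is.null(df[[col]])) df[[col]] <- rep(NA, nrow(df))
  if (all(is.na(df$count))) df$count <- rep(1L, nrow(df))
  df$count <- as.integer(df$count)
  df$sample_id <- as.character(df$sample_id)
  for (col in c("cdr3_alpha", "cdr3_beta", .GENE_SLOTS)) {
    df[[col]] <- as.character(df[[col]])
    df[[col]][!is.na(df[[col]]) & !nzchar(df[[col]])] <- NA_character_
  }
  df <- df[, .CLONE_COLS, drop = FALSE]
  rownames(df) <- NULL
  methods::new("TCRCloneSet", clones = df, maxLength = as.integer(maxLength),
               metadata = metadata)
}

.cdr3Ok <- function(s) {
  vapply(strsplit(s, ""), function(ch) length(ch) > 0L && all(ch %in% .AA), logical(1))
}

#' Parse, filter and aggregate a delimited TCR clone table
#'
#' Reads a TSV/CSV clone table (delimiter inferred from the file extension,
#' overridable), applies the curation filters -- drop rows whose CDR3s use
#' non-IUPAC letters (`*`, `X`, `O`, or anything outside the 20 standard
#' amino acids), drop rows with a CDR3 longer than `maxLength` (default 40),
#' drop unproductive rows (flagged by an optional status column when mapped,
#' otherwise rows with no CDR3 at all) -- and merges clones with identical
#' amino-acid sequences and gene labels within a sample, summing their
#' counts. The per-reason drop counts are recorded in the curation report,
#' retrievable with [curationReport()].
#'
#' @param path file path of a delimited table with a header. Lines starting
#'   with `#` are ignored.
#' @param columnMap named character vector mapping canonical field names
#'   (`sample_id`, `cdr3_beta`, `count`, ..., optionally `status`) to the
#'   file's column names. Defaults to identity for canonical names present.
#' @param maxLength maximum CDR3 length retained.
#' @param sep field delimiter; `NULL` infers from extension
#'   (`.csv` -> comma, otherwise tab).
#' @param productiveValues values of the status column treated as productive
#'   (case-insensitive) when a status column is mapped.
#' @return a [TCRCloneSet]; its metadata holds the curation report.
#' @examples
#' tab <- data.frame(sample_id = "s1", cdr3_beta = c("CASSLGETQYF", "CASSLGETQYF"),
#'                   v_beta = "TRBV5-1", count = c(3, 5))
#' f <- tempfile(fileext = ".tsv")
#' write.table(tab, f, sep = "\t", row.names = FALSE, quote = FALSE)
#' cs <- parseCloneTable(f)
#' cloneCounts(cs)  # 8: same clone, reads summed
#' @export
parseCloneTable <- function(path, columnMap = NULL, maxLength = 40L,
                            sep = NULL, productiveValues = c("in", "true", "productive", "yes", "1")) {
  if (!file.exists(path)) .stopf("clone table not found: %s", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", na.strings = c("NA", ""))
  wanted <- c(.CLONE_COLS, "status")
  cmap <- stats::setNames(wanted, wanted)
  if (!is.null(columnMap)) {
    unknown <- setdiff(names(columnMap), wanted)
    if (length(unknown) > 0L)
      .stopf("columnMap names unknown field(s): %s", paste(unknown, collapse = ", "))
    cmap[names(columnMap)] <- columnMap
  }
  mapped_missing <- !is.null(columnMap) &
    !unname(cmap[names(columnMap)]) %in% names(raw)
  if (any(mapped_missing))
    .stopf("mapped column(s) absent from file: %s",
           paste(cmap[names(columnMap)][mapped_missing], collapse = ", "))
  df <- data.frame(row.names = seq_len(nrow(raw)))
  for (field in wanted) {
    src <- cmap[[field]]
    df[[field]] <- if (src %in% names(raw)) raw[[src]] else NA
  }
  has_cdr3_col <- any(c(cmap[["cdr3_alpha"]], cmap[["cdr3_beta"]]) %in% names(raw))
  if (!has_cdr3_col) .stopf("no CDR3 column found in %s", path)

  for (col in c("cdr3_alpha", "cdr3_beta", .GENE_SLOTS, "sample_id", "status")) {
    df[[col]] <- as.character(df[[col]])
    df[[col]][!is.na(df[[col]]) & !nzchar(df[[col]])] <- NA_character_
  }
  if (all(is.na(df$sample_id))) df$sample_id <- "sample_1"
  if (all(is.na(df$count))) df$count <- 1L
  df$count <- suppressWarnings(as.integer(df$count))
  df$count[is.na(df$count) | df$count < 1L] <- 1L

  n_input <- nrow(df)
  a_present <- !is.na(df$cdr3_alpha); b_present <- !is.na(df$cdr3_beta)

  ## unproductive: status column when mapped, else rows with no CDR3
  status_mapped <- "status" %in% names(columnMap)
  unproductive <- if (status_mapped) {
    !is.na(df$status) & !(tolower(df$status) %in% tolower(productiveValues))
  } else rep(FALSE, n_input)
  empty <- !a_present & !b_present
  drop_unprod <- unproductive | empty

  bad_letters <- rep(FALSE, n_input)
  bad_letters[a_present] <- bad_letters[a_present] | !.cdr3Ok(df$cdr3_alpha[a_present])
  bad_letters[b_present] <- bad_letters[b_present] | !.cdr3Ok(df$cdr3_beta[b_present])
  over_len <- rep(FALSE, n_input)
  over_len[a_present] <- over_len[a_present] | nchar(df$cdr3_alpha[a_present]) > maxLength
  over_len[b_present] <- over_len[b_present] | nchar(df$cdr3_beta[b_present]) > maxLength

  drop <- drop_unprod | bad_letters | over_len
  dropped_counts <- sum(df$count[drop])
  kept <- df[!drop, , drop = FALSE]
  if (nrow(kept) == 0L)
    .stopf("empty dataset: all %d rows removed by curation filters", n_input)

  ## aggregate identical clones (sequence + genes + label) within a sample
  key_cols <- c("sample_id", "cdr3_alpha", "cdr3_beta", .GENE_SLOTS, "label")
  key <- do.call(paste, c(lapply(key_cols, function(cl) {
    v <- as.character(kept[[cl]]); v[is.na(v)] <- "NA"; v
  }), sep = ""))
  first <- !duplicated(key)
  agg_counts <- tapply(kept$count, key, sum)
  out <- kept[first, setdiff(names(kept), "status"), drop = FALSE]
  out$count <- as.integer(agg_counts[key[first]])
  n_aggregated <- nrow(kept) - nrow(out)

  report <- list(
    n_input = n_input,
    dropped_non_iupac = sum(bad_letters & !drop_unprod),
    dropped_over_length = sum(over_len & !bad_letters & !drop_unprod),
    dropped_unproductive_or_empty = sum(drop_unprod),
    n_dropped = sum(drop),
    dropped_total_count = dropped_counts,
    n_aggregated = n_aggregated,
    n_clones = nrow(out)
  )
  TCRCloneSet(out, maxLength = maxLength, metadata = list(curation = report))
}

#' Write a clone table to disk
#'
#' Canonical columns, header included; absent fields written as empty
#' strings so a re-parse reproduces the clones exactly. An optional seed is
#' recorded as a `#`-prefixed comment header (ignored on parse).
#'
#' @param x a [TCRCloneSet]
#' @param path output path; `.csv` writes comma-separated, anything else tab.
#' @param seedComment optional integer recorded as `# seed: <n>`.
#' @return `path`, invisibly.
#' @export
writeCloneTable <- function(x, path, seedComment = NULL) {
  stopifnot(methods::is(x, "TCRCloneSet"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  con <- tryCatch(file(path, open = "wt"), error = function(e)
    .stopf("cannot open %s for writing", path))
  on.exit(close(con))
  if (!is.null(seedComment)) writeLines(sprintf("# seed: %d", seedComment), con)
  df <- x@clones
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Build a gene vocabulary from observed labels
#'
#' @param x a [TCRCloneSet]; levels are the sorted unique labels per slot.
#' @return a [GeneVocabulary]; slots with no observed labels get empty level
#'   sets (their absent index is 1).
#' @export
geneVocabulary <- function(x) {
  lv <- lapply(.GENE_SLOTS, function(sl) {
    v <- x@clones[[sl]]
    sort(unique(v[!is.na(v)]))
  })
  names(lv) <- .GENE_SLOTS
  methods::new("GeneVocabulary", levels = lv)
}

#' @rdname geneVocabulary
#' @param vocab a [GeneVocabulary]; @param path JSON path.
#' @export
writeGeneVocabulary <- function(vocab, path) {
  jsonlite::write_json(vocab@levels, path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname geneVocabulary
#' @export
readGeneVocabulary <- function(path) {
  lv <- jsonlite::read_json(path, simplifyVector = TRUE)
  lv <- lapply(lv, as.character)
  methods::new("GeneVocabulary", levels = lv[.GENE_SLOTS])
}

.encodeChain <- function(seqs, maxLength) {
  n <- length(seqs)
  S <- matrix(.PAD, n, maxLength)
  len <- integer(n)
  present <- !is.na(seqs)
  for (i in which(present)) {
    ch <- .aaIndex(strsplit(seqs[i], "")[[1]])
    len[i] <- length(ch)
    S[i, seq_along(ch)] <- ch
  }
  list(S = S, len = len)
}

#' Encode a TCRCloneSet into padded integer arrays
#'
#' Amino acids are coded 1..20 (alphabetical order of the one-letter
#' alphabet), right-padded with the distinguished pad code 21. Gene labels
#' become integer indices into the vocabulary; absent genes map to the
#' reserved absent index. Under a fixed vocabulary, an unseen gene label is
#' an error (no silent remap).
#'
#' @param x a [TCRCloneSet]
#' @param vocab a [GeneVocabulary] or `NULL` to build one from `x`.
#' @param maxLength padded length; defaults to the set's `maxLength`.
#' @return an [EncodedTCRSet]
#' @export
encodeTCRs <- function(x, vocab = NULL, maxLength = NULL) {
  stopifnot(methods::is(x, "TCRCloneSet"))
  if (is.null(maxLength)) maxLength <- x@maxLength
  maxLength <- as.integer(maxLength)
  if (any(nchar(stats::na.omit(c(x@clones$cdr3_alpha, x@clones$cdr3_beta))) > maxLength))
    .stopf("a CDR3 exceeds the requested maxLength (%d)", maxLength)
  if (is.null(vocab)) vocab <- geneVocabulary(x)

  n <- nrow(x@clones)
  G <- matrix(0L, n, length(.GENE_SLOTS), dimnames = list(NULL, .GENE_SLOTS))
  for (sl in .GENE_SLOTS) {
    lv <- vocab@levels[[sl]]
    v <- x@clones[[sl]]
    idx <- rep(length(lv) + 1L, n)              # absent
    seen <- !is.na(v)
    if (any(seen)) {
      m <- match(v[seen], lv)
      if (anyNA(m))
        .stopf("gene label(s) not in vocabulary for slot %s: %s", sl,
               paste(unique(v[seen][is.na(m)]), collapse = ", "))
      idx[seen] <- m
    }
    G[, sl] <- idx
  }
  ea <- .encodeChain(x@clones$cdr3_alpha, maxLength)
  eb <- .encodeChain(x@clones$cdr3_beta, maxLength)
  use_a <- any(ea$len > 0L); use_b <- any(eb$len > 0L)
  methods::new("EncodedTCRSet",
    seqAlpha = if (use_a) ea$S else matrix(integer(), n, 0L),
    seqBeta  = if (use_b) eb$S else matrix(integer(), n, 0L),
    lengthsAlpha = ea$len, lengthsBeta = eb$len,
    genes = G, counts = as.integer(x@clones$count), labels = x@clones$label,
    cloneIndex = seq_len(n), vocab = vocab, maxLength = maxLength)
}

## row-subset helpers (internal)
.subsetEnc <- function(enc, rows) {
  methods::new("EncodedTCRSet",
    seqAlpha = enc@seqAlpha[rows, , drop = FALSE],
    seqBeta = enc@seqBeta[rows, , drop = FALSE],
    lengthsAlpha = enc@lengthsAlpha[rows], lengthsBeta = enc@lengthsBeta[rows],
    genes = enc@genes[rows, , drop = FALSE], counts = enc@counts[rows],
    labels = enc@labels[rows], cloneIndex = enc@cloneIndex[rows],
    vocab = enc@vocab, maxLength = enc@maxLength)
}

.subsetClones <- function(x, keep) {
  TCRCloneSet(x@clones[keep, , drop = FALSE], maxLength = x@maxLength,
              metadata = x@metadata[setdiff(names(x@metadata), "truth")])
}

#' Decode an EncodedTCRSet back to CDR3 strings and gene labels
#'
#' @param enc an [EncodedTCRSet]
#' @return data.frame with cdr3_alpha/cdr3_beta strings (`NA` when absent)
#'   and the five gene label columns.
#' @export
decodeTCRs <- function(enc) {
  stopifnot(methods::is(enc, "EncodedTCRSet"))
  n <- length(enc)
  dec_chain <- function(S, len) {
    if (ncol(S) == 0L) return(rep(NA_character_, n))
    out <- rep(NA_character_, n)
    for (i in seq_len(n)) if (len[i] > 0L)
      out[i] <- paste(.AA[S[i, seq_len(len[i])]], collapse = "")
    out
  }
  out <- data.frame(
    cdr3_alpha = dec_chain(enc@seqAlpha, enc@lengthsAlpha),
    cdr3_beta  = dec_chain(enc@seqBeta, enc@lengthsBeta),
    stringsAsFactors = FALSE)
  for (sl in .GENE_SLOTS) {
    lv <- enc@vocab@levels[[sl]]
    idx <- enc@genes[, sl]
    v <- rep(NA_character_, n)
    ok <- idx <= length(lv)
    if (any(ok)) v[ok] <- lv[idx[ok]]
    out[[sl]] <- v
  }
  out
}
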