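## Seeded synthetic repertoire generator: motif-implanted CDR3s over a random
## background with class-correlated V/D/J usage. Stands in for antigen-sorted,
## single-cell and culture-well datasets so the whole pipeline is testable
## without external data.

.withSeed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv))
  })
  force(expr)
}

.GENE_PREFIX <- c(v_alpha = "TRAV", j_alpha = "TRAJ",
                  v_beta = "TRBV", d_beta = "TRBD", j_beta = "TRBJ")

#' Configuration for the synthetic repertoire generator
#'
#' The generated CDR3s are uniform-background amino-acid strings (length
#' drawn uniformly from `lengthRange`), optionally framed by the canonical
#' `C...F` junction termini; a configurable fraction of clones per class
#' carries the class motif as a contiguous substring at a uniformly random
#' admissible offset. Gene labels are drawn from class-tilted categorical
#' distributions; clone counts are i.i.d. geometric (a heavy-tailed
#' clone-size surrogate).
#'
#' @param seed integer master seed; the generator is deterministic given it.
#' @param nClasses number of classes.
#' @param motifs per-class motif strings (length 3-6); `NULL` draws one
#'   random 4-mer per class from the seed.
#' @param motifRate fraction of clones per class carrying the motif.
#' @param lengthRange inclusive CDR3 length bounds.
#' @param geneVocabSizes named per-slot vocabulary sizes.
#' @param geneClassBias in `[0,1]`; probability mass concentrated on a
#'   class-preferred gene per slot (0 = no class signal in gene usage).
#' @param countGeomProb geometric success probability for clone counts.
#' @param chains chains to generate; the motif is implanted in the beta
#'   chain when present, otherwise in alpha.
#' @param frame frame CDR3s with fixed C/F terminal residues.
#' @param backgroundFreqs length-20 residue probabilities (default uniform),
#'   ordered as the alphabetical amino-acid alphabet.
#' @param wells replicate structure for [simulateWellExperiment()]: list with
#'   `n_control_conditions`, `n_replicates`, `clones_per_well`.
#' @param regressionMode make the label a count proportional to motif match
#'   quality plus Poisson noise instead of a class.
#' @return a validated config list of class `tcr_sim_config`.
#' @export
simulationConfig <- function(seed = 1L, nClasses = 3L, motifs = NULL,
                             motifRate = 0.1, lengthRange = c(10L, 20L),
                             geneVocabSizes = c(v_alpha = 15L, j_alpha = 10L,
                                                v_beta = 20L, d_beta = 3L, j_beta = 12L),
                             geneClassBias = 0.5, countGeomProb = 0.3,
                             chains = "beta", frame = TRUE,
                             backgroundFreqs = NULL,
                             wells = list(n_control_conditions = 3L,
                                          n_replicates = 3L,
                                          clones_per_well = 200L),
                             regressionMode = FALSE) {
  stopifnot(.isCount(seed + 1), .isCount(nClasses))
  if (motifRate < 0 || motifRate > 1) .stopf("motifRate must be in [0,1]")
  if (geneClassBias < 0 || geneClassBias > 1) .stopf("geneClassBias must be in [0,1]")
  lengthRange <- as.integer(lengthRange)
  if (length(lengthRange) != 2L || lengthRange[1] > lengthRange[2])
    .stopf("lengthRange must be increasing bounds")
  chains <- match.arg(chains, c("beta", "alpha", "both"))
  if (is.null(motifs)) {
    motifs <- .withSeed(.childSeed(seed, "motifs"), {
      vapply(seq_len(nClasses), function(k)
        paste(sample(.AA, 4L, replace = TRUE), collapse = ""), character(1))
    })
  }
  if (length(motifs) != nClasses) .stopf("need one motif per class")
  if (any(nchar(motifs) < 3L | nchar(motifs) > 6L))
    .stopf("motifs must be 3-6 residues long")
  if (any(vapply(strsplit(motifs, ""), function(ch) any(!ch %in% .AA), logical(1))))
    .stopf("motifs must use the 20 standard amino-acid letters")
  interior <- lengthRange[1] - if (frame) 2L else 0L
  if (max(nchar(motifs)) > interior)
    .stopf("motif longer than the shortest admissible CDR3 interior")
  if (is.null(backgroundFreqs)) backgroundFreqs <- rep(1 / 20, 20L)
  if (length(backgroundFreqs) != 20L || any(backgroundFreqs < 0))
    .stopf("backgroundFreqs must be 20 non-negative probabilities")
  backgroundFreqs <- backgroundFreqs / sum(backgroundFreqs)
  structure(list(seed = as.integer(seed), n_classes = as.integer(nClasses),
                 motifs = motifs, motif_rate = motifRate,
                 length_range = lengthRange, gene_vocab_sizes = geneVocabSizes,
                 gene_class_bias = geneClassBias, count_geom_prob = countGeomProb,
                 chains = chains, frame = frame, background_freqs = backgroundFreqs,
                 wells = wells, regression_mode = isTRUE(regressionMode)),
            class = "tcr_sim_config")
}

## one background CDR3 of given length (frame applied by caller)
.randomCdr3s <- function(n, cfg) {
  len <- sample(seq(cfg$length_range[1], cfg$length_range[2]), n, replace = TRUE)
  seqs <- vapply(len, function(l) {
    core <- sample(.AA, l - if (cfg$frame) 2L else 0L,
                   replace = TRUE, prob = cfg$background_freqs)
    if (cfg$frame) paste0("C", paste(core, collapse = ""), "F")
    else paste(core, collapse = "")
  }, character(1))
  list(seqs = seqs, len = len)
}

.implantMotif <- function(seqs, motif, frame) {
  m <- nchar(motif)
  vapply(seqs, function(s) {
    l <- nchar(s)
    lo <- if (frame) 2L else 1L
    hi <- l - m + if (frame) 0L else 1L
    off <- if (hi <= lo) lo else sample(seq(lo, hi), 1L)
    paste0(substr(s, 1L, off - 1L), motif, substr(s, off + m, l))
  }, character(1), USE.NAMES = FALSE)
}

.classGenePrefs <- function(cfg) {
  ## one preferred gene per slot per class, fixed by the seed
  .withSeed(.childSeed(cfg$seed, "geneprefs"), {
    do.call(cbind, lapply(stats::setNames(nm = names(cfg$gene_vocab_sizes)),
                          function(sl) sample.int(cfg$gene_vocab_sizes[[sl]],
                                                  cfg$n_classes, replace = TRUE)))
  })
}

.drawGenes <- function(n, class_k, cfg, prefs, slots) {
  out <- list()
  for (sl in slots) {
    K <- cfg$gene_vocab_sizes[[sl]]
    p <- rep((1 - cfg$gene_class_bias) / K, K)
    p[prefs[class_k, sl]] <- p[prefs[class_k, sl]] + cfg$gene_class_bias
    idx <- sample.int(K, n, replace = TRUE, prob = p)
    out[[sl]] <- sprintf("%s%d", .GENE_PREFIX[[sl]], idx)
  }
  out
}

.motifMatchScore <- function(seqs, motif) {
  ## best sliding-window identity fraction to the motif
  m <- strsplit(motif, "")[[1]]
  vapply(strsplit(seqs, ""), function(ch) {
    L <- length(ch); w <- length(m)
    if (L < w) return(0)
    best <- 0
    for (o in seq_len(L - w + 1L))
      best <- max(best, sum(ch[o:(o + w - 1L)] == m) / w)
    best
  }, numeric(1))
}

#' Simulate a labelled per-sequence dataset
#'
#' Generates `nPerClass` clones for each class; a `motifRate` fraction carry
#' the class motif as a contiguous substring, gene usage is class-tilted,
#' counts are geometric. Ground truth (class, motif flag, implanted motif)
#' is stored in the metadata and retrievable via [simTruth()].
#'
#' @param config a [simulationConfig()].
#' @param nPerClass clones per class.
#' @return a [TCRCloneSet]; labels are `class_1..class_K`, or numeric
#'   counts in regression mode.
#' @export
simulateSequenceDataset <- function(config, nPerClass = 200L) {
  stopifnot(inherits(config, "tcr_sim_config"))
  prefs <- .classGenePrefs(config)
  chains <- switch(config$chains, beta = "beta", alpha = "alpha",
                   both = c("alpha", "beta"))
  motif_chain <- if ("beta" %in% chains) "beta" else "alpha"
  slots <- unlist(lapply(chains, function(ch)
    grep(paste0("_", substr(ch, 1L, 1L), if (ch == "beta") "eta" else "lpha"),
         .GENE_SLOTS, value = TRUE)))
  .withSeed(.childSeed(config$seed, "seqdata"), {
    rows <- list(); truth <- list()
    for (k in seq_len(config$n_classes)) {
      motif <- config$motifs[k]
      has_motif <- stats::runif(nPerClass) < config$motif_rate
      chain_seqs <- list()
      for (ch in chains) {
        rc <- .randomCdr3s(nPerClass, config)
        s <- rc$seqs
        if (ch == motif_chain && any(has_motif))
          s[has_motif] <- .implantMotif(s[has_motif], motif, config$frame)
        chain_seqs[[ch]] <- s
      }
      genes <- .drawGenes(nPerClass, k, config, prefs, slots)
      counts <- stats::rgeom(nPerClass, config$count_geom_prob) + 1L
      label <- if (config$regression_mode) {
        score <- .motifMatchScore(chain_seqs[[motif_chain]], motif)
        stats::rpois(nPerClass, lambda = 2 + 18 * score)
      } else rep(sprintf("class_%d", k), nPerClass)
      df <- data.frame(sample_id = "S1",
                       cdr3_alpha = if ("alpha" %in% chains) chain_seqs$alpha else NA,
                       cdr3_beta = if ("beta" %in% chains) chain_seqs$beta else NA,
                       count = counts, label = label, stringsAsFactors = FALSE)
      for (sl in names(genes)) df[[sl]] <- genes[[sl]]
      rows[[k]] <- df
      truth[[k]] <- data.frame(class = sprintf("class_%d", k),
                               has_motif = has_motif, motif = motif,
                               stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, lapply(rows, function(d) {
      for (col in .CLONE_COLS) if (is.null(d[[col]])) d[[col]] <- NA
      d[, .CLONE_COLS]
    }))
    tr <- do.call(rbind, truth)
    TCRCloneSet(df, maxLength = config$length_range[2],
                metadata = list(truth = tr, config = config))
  })
}

#' Simulate a replicate-well culture experiment
#'
#' Emulates splitting one T-cell pool across culture wells: all wells draw
#' their background clones from a single shared pool (as replicate wells of
#' an autologous culture share the donor's circulating repertoire), while
#' cognate wells additionally carry signal clones at `motifRate` -- fresh
#' sequences per well that share only the implanted motif, mimicking an
#' antigen-specific response whose exact clones differ between replicates.
#' Control wells (one or more control conditions) contain background only.
#'
#' @param config a [simulationConfig()]; its `wells` entry sets
#'   `n_control_conditions`, `n_replicates` (>= 2), `clones_per_well` and
#'   optionally `pool_factor` (background pool size as a multiple of
#'   `clones_per_well`, default 2).
#' @return list with `clones` (a [TCRCloneSet], `sample_id` = well id),
#'   `conditions` (named character vector well -> condition, cognate first)
#'   and `truth` (per-clone motif flag, aligned to `clones`).
#' @export
simulateWellExperiment <- function(config) {
  stopifnot(inherits(config, "tcr_sim_config"))
  w <- config$wells
  if (is.null(w$n_replicates) || w$n_replicates < 2L)
    .stopf("need at least 2 replicate wells per condition for held-out evaluation")
  n_ctrl <- w$n_control_conditions %||% 3L
  n_rep <- w$n_replicates
  n_clone <- w$clones_per_well %||% 200L
  motif <- config$motifs[1]
  prefs <- .classGenePrefs(config)
  chains <- if (config$chains == "both") c("alpha", "beta") else config$chains
  motif_chain <- if ("beta" %in% chains) "beta" else "alpha"
  slots <- .GENE_SLOTS[vapply(.GENE_SLOTS, function(sl)
    (grepl("alpha", sl) && "alpha" %in% chains) ||
      (grepl("beta", sl) && "beta" %in% chains), logical(1))]

  conds <- c("cognate", sprintf("control_%d", seq_len(n_ctrl)))
  well_ids <- unlist(lapply(conds, function(cd) sprintf("%s_w%d", cd, seq_len(n_rep))))
  cond_of <- stats::setNames(rep(conds, each = n_rep), well_ids)

  .withSeed(.childSeed(config$seed, "wells"), {
    ## one shared background pool; wells subsample it
    pool_n <- as.integer(round((w$pool_factor %||% 1) * n_clone))
    pool <- list()
    for (ch in chains) pool[[ch]] <- .randomCdr3s(pool_n, config)$seqs
    pool_genes <- .drawGenes(pool_n, 1L, config, prefs, slots)

    rows <- list(); flags <- list()
    for (wid in well_ids) {
      cognate <- cond_of[[wid]] == "cognate"
      has_motif <- cognate & (stats::runif(n_clone) < config$motif_rate)
      ## equal-split aliquot: when a large, well-mixed culture is divided,
      ## every (non-rare) clone lands in every well; wells differ in clone
      ## abundance (counts drawn per well), not in clone presence
      pick <- sample.int(pool_n, n_clone)
      chain_seqs <- list()
      for (ch in chains) {
        s <- pool[[ch]][pick]
        if (ch == motif_chain && any(has_motif)) {
          ## signal clones: fresh sequences sharing only the motif
          fresh <- .randomCdr3s(sum(has_motif), config)$seqs
          s[has_motif] <- .implantMotif(fresh, motif, config$frame)
        }
        chain_seqs[[ch]] <- s
      }
      genes <- lapply(pool_genes, function(g) g[pick])
      if (any(has_motif))
        for (sl in names(genes))
          genes[[sl]][has_motif] <- .drawGenes(sum(has_motif), 1L, config,
                                               prefs, slots)[[sl]]
      counts <- stats::rgeom(n_clone, config$count_geom_prob) + 1L
      df <- data.frame(sample_id = wid,
                       cdr3_alpha = if ("alpha" %in% chains) chain_seqs$alpha else NA,
                       cdr3_beta = if ("beta" %in% chains) chain_seqs$beta else NA,
                       count = counts, label = cond_of[[wid]],
                       stringsAsFactors = FALSE)
      for (sl in names(genes)) df[[sl]] <- genes[[sl]]
      for (col in .CLONE_COLS) if (is.null(df[[col]])) df[[col]] <- NA
      rows[[wid]] <- df[, .CLONE_COLS]
      flags[[wid]] <- has_motif
    }
    clones <- TCRCloneSet(do.call(rbind, rows), maxLength = config$length_range[2],
                          metadata = list(config = config))
    list(clones = clones, conditions = cond_of,
         truth = data.frame(well = rep(well_ids, each = n_clone),
                            has_motif = unlist(flags, use.names = FALSE),
                            stringsAsFactors = FALSE))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
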