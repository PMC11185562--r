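## Construction of paired shuffled entrapment databases (peptide- and
## protein-level, any ratio r) and of foreign-species entrapment databases.

#' Shuffling settings for entrapment generation
#'
#' Entrapment peptides are uniform random permutations of their original
#' target peptide with the C-terminal residue held fixed (so tryptic
#' boundaries are preserved); the ISB18-style variant additionally fixes
#' the N-terminal residue.  A candidate that collides with an existing
#' peptide is retried up to `maxExtraAttempts` additional times.
#'
#' @param fixCTerminal keep the C-terminal residue in place (always `TRUE`
#'   for tryptic databases).
#' @param fixNTerminal also keep the N-terminal residue in place.
#' @param maxExtraAttempts extra shuffle attempts beyond the r required
#'   successes before a target is given up on (default 20, i.e. 20+r total
#'   attempts per target).
#' @param seed integer seed making a database build reproducible.
#' @return A list with class `"ShuffleConfig"`.
#' @export
shuffleConfig <- function(fixCTerminal = TRUE, fixNTerminal = FALSE,
                          maxExtraAttempts = 20L, seed = NULL) {
  assertFlag(fixCTerminal, "fixCTerminal")
  assertFlag(fixNTerminal, "fixNTerminal")
  assertCount(maxExtraAttempts, "maxExtraAttempts")
  structure(list(fixCTerminal = fixCTerminal, fixNTerminal = fixNTerminal,
                 maxExtraAttempts = as.integer(maxExtraAttempts),
                 seed = seed),
            class = "ShuffleConfig")
}

#' Shuffle one peptide with fixed termini
#'
#' Draws a uniform random permutation of the non-fixed positions of
#' `peptide` using the current RNG stream; the amino-acid multiset is
#' preserved and fixed positions are unchanged.  Note the result may equal
#' the input (e.g. for low-complexity peptides); collision handling is the
#' caller's job.
#'
#' @param peptide a single peptide string (length >= 2, or >= 3 when both
#'   termini are fixed).
#' @param config a [shuffleConfig()]; its `seed` is ignored here (the
#'   database builders own the RNG).
#' @return The shuffled peptide string.
#' @examples
#' set.seed(1); shufflePeptide("PEPTIDEK")
#' @export
shufflePeptide <- function(peptide, config = shuffleConfig()) {
  chars <- strsplit(peptide, "")[[1]]
  n <- length(chars)
  lo <- if (config$fixNTerminal) 2L else 1L
  hi <- if (config$fixCTerminal) n - 1L else n
  if (n < 2L || hi < lo)
    stop("peptide too short to permute: ", peptide, call. = FALSE)
  idx <- lo:hi
  chars[idx] <- chars[sample(idx)]
  paste(chars, collapse = "")
}

canShuffle <- function(peptide, config) {
  n <- nchar(peptide)
  free <- n - config$fixCTerminal - config$fixNTerminal
  n >= 2L && free >= 1L
}

## Attempt to collect up to r shuffles of `peptide` that pass `ok()`, using
## at most maxExtraAttempts + r total attempts.  Returns list(entrapments,
## attempts).
collectShuffles <- function(peptide, r, config, ok) {
  budget <- config$maxExtraAttempts + r
  got <- character()
  attempts <- 0L
  while (attempts < budget && length(got) < r) {
    attempts <- attempts + 1L
    cand <- shufflePeptide(peptide, config)
    if (!(cand %in% got) && ok(cand)) got <- c(got, cand)
  }
  list(entrapments = got, attempts = attempts)
}

#' Build a paired shuffled entrapment peptide database
#'
#' For each original target peptide, up to `maxExtraAttempts + r` C-terminal
#' -fixed shuffles are attempted in order to collect `r` entrapment peptides
#' that are distinct from every original target peptide and from every
#' previously accepted entrapment peptide (global distinctness).  Targets
#' for which this fails -- typically low-complexity peptides -- are removed
#' from the database and listed in `removedTargets()`.  Peptides containing
#' non-canonical residues (B, Z, X, U, O) are not paired and are likewise
#' listed.  Targets are processed in sorted order so the build depends only
#' on the seed, not on input ordering.
#'
#' @param targets a [PeptideSet-class] or character vector of original
#'   target peptides.
#' @param r number of entrapment peptides per target (>= 1).
#' @param config a [shuffleConfig()]; set its `seed` for reproducibility.
#' @return A [PairedEntrapmentDB-class] (`level = "peptide"`,
#'   `mode = "shuffled"`).
#' @examples
#' db <- generatePairedPeptideDb(c("ACDEFGK", "LMNPQRSTK"), r = 1,
#'                               shuffleConfig(seed = 7))
#' pairTable(db)
#' @export
generatePairedPeptideDb <- function(targets, r = 1L,
                                    config = shuffleConfig()) {
  if (is(targets, "PeptideSet")) targets <- peptides(targets)
  targets <- unique(as.character(targets))
  assertCount(r, "r"); r <- as.integer(r)
  if (r < 1L) stop("r must be >= 1", call. = FALSE)
  targets <- sort(targets)
  withSeed(config$seed, {
    forbidden <- new.env(parent = emptyenv())
    for (p in targets) assign(p, TRUE, envir = forbidden)
    keep_t <- character(); keep_e <- character(); keep_copy <- integer()
    removed <- list()
    for (p in targets) {
      if (!isCanonical(p)) {
        removed[[length(removed) + 1L]] <-
          data.frame(target = p, reason = "non-canonical residues",
                     attempts = 0L)
        next
      }
      if (!canShuffle(p, config)) {
        removed[[length(removed) + 1L]] <-
          data.frame(target = p, reason = "too short to shuffle",
                     attempts = 0L)
        next
      }
      res <- collectShuffles(p, r, config,
                             ok = function(cand)
                               !exists(cand, envir = forbidden,
                                       inherits = FALSE))
      if (length(res$entrapments) < r) {
        removed[[length(removed) + 1L]] <-
          data.frame(target = p, reason = "no distinct shuffle",
                     attempts = res$attempts)
      } else {
        for (e in res$entrapments) assign(e, TRUE, envir = forbidden)
        keep_t <- c(keep_t, rep(p, r))
        keep_e <- c(keep_e, res$entrapments)
        keep_copy <- c(keep_copy, seq_len(r))
      }
    }
    removed <- if (length(removed)) do.call(rbind, removed) else
      data.frame(target = character(), reason = character(),
                 attempts = integer())
    pairs <- data.frame(target = keep_t, entrapment = keep_e,
                        entrap_id = keep_e, copy = keep_copy,
                        stringsAsFactors = FALSE)
    new("PairedEntrapmentDB", level = "peptide", r = as.numeric(r),
        mode = "shuffled", pairs = pairs, removed = removed,
        peptideMap = data.frame(),
        metadata = list(seed = config$seed, config = config,
                        n_targets = length(unique(keep_t)),
                        attempt_policy = "20+r total attempts per target"))
  })
}

#' Build a paired shuffled entrapment protein database
#'
#' Each protein is digested with zero missed cleavages and no length or
#' mass constraints.  Every distinct digested peptide is assigned `r`
#' entrapment peptides: up to `maxExtraAttempts + r` C-terminal-fixed
#' shuffles collect `n <= r` candidates distinct from the original and
#' from each other; if `0 < n < r`, the remaining `r - n` are sampled with
#' replacement from the `n`; if `n = 0` (unpermutable peptides), all `r`
#' copies equal the original peptide.  Entrapment protein `j` is the
#' concatenation of every original peptide's `j`-th entrapment in original
#' order, so a peptide shared between proteins (or repeated within one) is
#' swapped consistently everywhere, lengths are preserved, and a
#' zero-missed-cleavage digest of entrapment protein `j` returns exactly
#' the chosen entrapment peptides in order.
#'
#' @param proteins an `AAStringSet` or named character vector of protein
#'   sequences.
#' @param r number of entrapment proteins per original protein.
#' @param config a [shuffleConfig()].
#' @return A [PairedEntrapmentDB-class] (`level = "protein"`,
#'   `mode = "shuffled"`); the peptide swap map is kept in the
#'   `peptideMap` slot.
#' @export
generatePairedProteinDb <- function(proteins, r = 1L,
                                    config = shuffleConfig()) {
  seqs <- asNamedSeqs(proteins)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("proteins must be named by accession", call. = FALSE)
  assertCount(r, "r"); r <- as.integer(r)
  if (r < 1L) stop("r must be >= 1", call. = FALSE)
  frag_list <- lapply(seqs, tryptic_fragments)
  all_peps <- sort(unique(unlist(frag_list)))
  withSeed(config$seed, {
    swap <- matrix(NA_character_, nrow = length(all_peps), ncol = r,
                   dimnames = list(all_peps, NULL))
    for (p in all_peps) {
      if (!isCanonical(p) || !canShuffle(p, config)) {
        swap[p, ] <- p          # cannot be safely permuted: keep original
        next
      }
      res <- collectShuffles(p, r, config, ok = function(cand) cand != p)
      n <- length(res$entrapments)
      swap[p, ] <- if (n == 0L) rep(p, r)
        else if (n < r)
          c(res$entrapments,
            res$entrapments[sample.int(n, r - n, replace = TRUE)])
        else res$entrapments
    }
    pairs <- do.call(rbind, lapply(names(seqs), function(acc) {
      frags <- frag_list[[acc]]
      data.frame(
        target = acc,
        entrapment = vapply(seq_len(r), function(j)
          paste(swap[frags, j], collapse = ""), character(1)),
        entrap_id = if (r == 1L) paste0("ENTRAP_", acc) else
          paste0("ENTRAP_", acc, "_", seq_len(r)),
        copy = seq_len(r), stringsAsFactors = FALSE)
    }))
    pmap <- data.frame(
      peptide = rep(all_peps, each = r),
      entrapment = as.vector(t(swap)),
      copy = rep(seq_len(r), length(all_peps)),
      stringsAsFactors = FALSE)
    new("PairedEntrapmentDB", level = "protein", r = as.numeric(r),
        mode = "shuffled", pairs = pairs,
        removed = data.frame(target = character(), reason = character(),
                             attempts = integer()),
        peptideMap = pmap,
        metadata = list(seed = config$seed, config = config,
                        n_targets = length(seqs),
                        attempt_policy = "20+r total attempts per peptide"))
  })
}

#' Build a foreign-species entrapment database
#'
#' Peptide level: both databases are digested with the peptide-level
#' settings (trypsin, one missed cleavage, lengths 7-35); foreign peptides
#' equal to any original target peptide are removed; the remainder is
#' sampled uniformly without replacement to reach `r` entrapment peptides
#' per surviving original target peptide.  Protein level: foreign proteins
#' are sampled to reach `r` per original protein.  No pairing exists, so
#' only the combined, lower-bound and sample estimators apply downstream.
#'
#' @param targets original targets: a [PeptideSet-class] (peptide level) or
#'   named protein sequences (either level; digested on the fly at peptide
#'   level).
#' @param foreign named character vector or `AAStringSet` of foreign-species
#'   proteins.
#' @param r desired entrapment-to-original-target ratio (may be fractional).
#' @param level `"peptide"` or `"protein"`.
#' @param seed integer seed for the sampling.
#' @return A [PairedEntrapmentDB-class] with `mode = "foreign"` and an
#'   empty pairing (`target` column all `NA`).
#' @export
generateForeignDb <- function(targets, foreign, r = 1,
                              level = c("peptide", "protein"),
                              seed = NULL) {
  level <- match.arg(level)
  if (r <= 0) stop("r must be positive", call. = FALSE)
  if (level == "peptide") {
    tpep <- if (is(targets, "PeptideSet")) peptides(targets) else
      peptides(buildPeptideDb(targets))
    fpep <- peptides(buildPeptideDb(foreign))
    pool <- sort(setdiff(fpep, tpep))
    needed <- round(r * length(tpep))
    if (needed > length(pool))
      stop(sprintf(paste0("foreign pool too small: %d peptides available ",
                          "for %d original targets (achievable r <= %.3f)"),
                   length(pool), length(tpep),
                   length(pool) / length(tpep)), call. = FALSE)
    picked <- withSeed(seed, sample(pool, needed))
    pairs <- data.frame(target = NA_character_, entrapment = picked,
                        entrap_id = picked, copy = 1L,
                        stringsAsFactors = FALSE)
    n_targets <- length(tpep)
  } else {
    fseqs <- asNamedSeqs(foreign)
    tseqs <- asNamedSeqs(targets)
    needed <- round(r * length(tseqs))
    if (needed > length(fseqs))
      stop(sprintf(paste0("foreign pool too small: %d proteins available ",
                          "for %d original targets (achievable r <= %.3f)"),
                   length(fseqs), length(tseqs),
                   length(fseqs) / length(tseqs)), call. = FALSE)
    acc <- withSeed(seed, sample(names(fseqs), needed))
    pairs <- data.frame(target = NA_character_,
                        entrapment = unname(fseqs[acc]),
                        entrap_id = paste0("ENTRAP_", acc), copy = 1L,
                        stringsAsFactors = FALSE)
    n_targets <- length(tseqs)
  }
  new("PairedEntrapmentDB", level = level, r = as.numeric(r),
      mode = "foreign", pairs = pairs,
      removed = data.frame(target = character(), reason = character(),
                           attempts = integer()),
      peptideMap = data.frame(),
      metadata = list(seed = seed, n_targets = n_targets))
}

#' Effective entrapment-to-target ratio of a built database
#'
#' The ratio of entrapment entries to surviving original targets; equals
#' the requested `r` exactly in paired shuffled mode.
#'
#' @param db a [PairedEntrapmentDB-class].
#' @return A single number.
#' @export
effectiveRatio <- function(db) {
  stopifnot(is(db, "PairedEntrapmentDB"))
  n_targets <- if (db@mode == "shuffled")
    length(unique(db@pairs$target)) else db@metadata$n_targets
  if (is.null(n_targets) || n_targets == 0)
    stop("empty target set: effective ratio undefined", call. = FALSE)
  nrow(db@pairs) / n_targets
}

#' Write a protein-level entrapment database as FASTA
#'
#' Writes original and entrapment proteins to one FASTA, entrapment headers
#' carrying the `ENTRAP_` prefix and the paired original accession.
#'
#' @param db a protein-level [PairedEntrapmentDB-class].
#' @param proteins the original proteins (named sequences) to include.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
writeEntrapmentFasta <- function(db, proteins, path) {
  stopifnot(is(db, "PairedEntrapmentDB"), db@level == "protein")
  seqs <- c(asNamedSeqs(proteins),
            stats::setNames(db@pairs$entrapment, db@pairs$entrap_id))
  aa <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Write the target/entrapment pair table as TSV
#'
#' Wide format: one row per target, columns `target`,
#' `entrapment_1` .. `entrapment_r`.
#'
#' @param db a shuffled-mode [PairedEntrapmentDB-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writePairTable <- function(db, path) {
  stopifnot(is(db, "PairedEntrapmentDB"), db@mode == "shuffled")
  p <- db@pairs
  r <- round(db@r)
  wide <- data.frame(target = unique(p$target))
  for (j in seq_len(r))
    wide[[paste0("entrapment_", j)]] <-
      p$entrapment[p$copy == j][match(wide$target,
                                      p$target[p$copy == j])]
  write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the build manifest of a database as JSON
#'
#' Records seed, level, mode, r, entry counts, the removed-target list and
#' the retry policy, so a build can be reproduced and audited.
#'
#' @param db a [PairedEntrapmentDB-class].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeBuildManifest <- function(db, path) {
  stopifnot(is(db, "PairedEntrapmentDB"))
  manifest <- list(
    level = db@level, mode = db@mode, r = db@r,
    seed = db@metadata$seed,
    n_entrapments = nrow(db@pairs),
    n_targets = if (db@mode == "shuffled")
      length(unique(db@pairs$target)) else db@metadata$n_targets,
    removed = db@removed,
    attempt_policy = db@metadata$attempt_policy)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
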