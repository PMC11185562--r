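#' PeptideSet: a deduplicated peptide database with provenance
#'
#' Holds the unique peptides obtained from an in-silico digest of one or
#' more proteins, together with, for every peptide, the accessions of the
#' proteins it came from.  This is the "original target" peptide database
#' that entrapment construction starts from.
#'
#' @slot peptides character vector of unique, upper-case peptide sequences.
#' @slot provenance named list, one element per peptide, each a non-empty
#'   character vector of source protein accessions.
#'
#' @seealso [buildPeptideDb()], [generatePairedPeptideDb()]
#' @export
setClass("PeptideSet",
  representation(peptides = "character", provenance = "list"),
  validity = function(object) {
    msg <- character()
    if (anyDuplicated(object@peptides))
      msg <- c(msg, "duplicate peptide strings")
    if (length(object@provenance) != length(object@peptides))
      msg <- c(msg, "provenance must have one entry per peptide")
    if (length(object@provenance) &&
        any(lengths(object@provenance) == 0L))
      msg <- c(msg, "every peptide needs at least one source accession")
    if (length(msg)) msg else TRUE
  })

#' PairedEntrapmentDB: an entrapment database paired with its targets
#'
#' The central container for entrapment experiments.  In shuffled mode each
#' surviving original target (peptide or protein) is bound to exactly `r`
#' entrapment counterparts generated by constrained shuffling; in foreign
#' mode the entrapment entries are sampled from a foreign proteome and the
#' pairing is empty (only the combined, lower-bound and sample estimators
#' apply).
#'
#' @slot level `"peptide"` or `"protein"`.
#' @slot r integer entrapment-to-original-target ratio requested at build
#'   time.
#' @slot mode `"shuffled"` or `"foreign"`.
#' @slot pairs data.frame with columns `target`, `entrapment`, `entrap_id`,
#'   `copy` (1..r).  In foreign mode `target` is `NA`.
#' @slot removed data.frame with columns `target`, `reason`, `attempts`:
#'   original targets dropped because no valid entrapment could be built
#'   (or skipped because they contain non-canonical residues).
#' @slot peptideMap data.frame (protein level only): the consistent
#'   peptide-to-entrapment swap map used to assemble entrapment proteins.
#' @slot metadata list: seed, shuffle configuration, counts, and the build
#'   manifest fields.
#'
#' @seealso [generatePairedPeptideDb()], [generatePairedProteinDb()],
#'   [generateForeignDb()], [effectiveRatio()]
#' @export
setClass("PairedEntrapmentDB",
  representation(level = "character", r = "numeric", mode = "character",
                 pairs = "data.frame", removed = "data.frame",
                 peptideMap = "data.frame", metadata = "list"),
  validity = function(object) {
    msg <- character()
    if (!object@level %in% c("peptide", "protein"))
      msg <- c(msg, "level must be 'peptide' or 'protein'")
    if (!object@mode %in% c("shuffled", "foreign"))
      msg <- c(msg, "mode must be 'shuffled' or 'foreign'")
    if (length(object@r) != 1L || object@r <= 0)
      msg <- c(msg, "r must be a single positive number")
    need <- c("target", "entrapment", "entrap_id", "copy")
    if (!all(need %in% names(object@pairs)))
      msg <- c(msg, sprintf("pairs must have columns %s",
                            paste(need, collapse = ", ")))
    if (object@mode == "shuffled" && nrow(object@pairs)) {
      sizes <- table(object@pairs$target)
      if (any(sizes != round(object@r)))
        msg <- c(msg, "every target must carry exactly r entrapments")
    }
    if (length(msg)) msg else TRUE
  })

#' DiscoveryTable: scored, labeled discoveries from a search tool
#'
#' One row per reported precursor, peptide or protein (group), carrying the
#' score and/or tool-reported q-value, an original-target/entrapment label,
#' and the pairing key that links an entrapment row to its paired original
#' target.  An optional known-false flag supports simulations and
#' double-entrapment experiments where ground truth is available.
#'
#' @slot rows data.frame with columns `id`, `label` (`"original"` or
#'   `"entrapment"`), `score`, `qvalue`, `pair_key`, `known_false`.
#'
#' @seealso [DiscoveryTable()], [parseReport()], [fdpCurve()]
#' @export
setClass("DiscoveryTable",
  representation(rows = "data.frame"),
  validity = function(object) {
    rows <- object@rows
    need <- c("id", "label", "score", "qvalue", "pair_key", "known_false")
    if (!all(need %in% names(rows)))
      return(sprintf("rows must have columns %s",
                     paste(need, collapse = ", ")))
    msg <- character()
    if (!all(rows$label %in% c("original", "entrapment")))
      msg <- c(msg, "label must be 'original' or 'entrapment'")
    q <- rows$qvalue[!is.na(rows$qvalue)]
    if (length(q) && (any(q < 0) || any(q > 1)))
      msg <- c(msg, "q-values must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Construct a DiscoveryTable
#'
#' @param id character identifiers, unique per row.
#' @param label `"original"` or `"entrapment"` per row.
#' @param score numeric scores (larger is better); `NA` allowed when
#'   q-values are supplied.
#' @param qvalue tool-reported q-values in `[0, 1]`; `NA` allowed when
#'   scores are supplied.
#' @param pairKey identifier of the paired original target for entrapment
#'   rows (`NA` for unpaired rows).
#' @param knownFalse optional logical ground-truth flag (`TRUE` = known
#'   false discovery), used by [directFdp()] and the simulator.
#' @return A [DiscoveryTable-class] object.
#' @examples
#' DiscoveryTable(id = c("T1", "E1"), label = c("original", "entrapment"),
#'                score = c(9, 7), qvalue = c(0.01, 0.04), pairKey = c(NA, "T1"))
#' @export
DiscoveryTable <- function(id, label, score = NA_real_, qvalue = NA_real_,
                           pairKey = NA_character_, knownFalse = NA) {
  n <- length(id)
  rows <- data.frame(
    id = as.character(id),
    label = as.character(label),
    score = rep_len(as.numeric(score), n),
    qvalue = rep_len(as.numeric(qvalue), n),
    pair_key = rep_len(as.character(pairKey), n),
    known_false = rep_len(as.logical(knownFalse), n),
    stringsAsFactors = FALSE)
  if (all(is.na(rows$score)) && all(is.na(rows$qvalue)) && n > 0)
    stop("at least one of score/qvalue must be provided", call. = FALSE)
  new("DiscoveryTable", rows = rows)
}

## ---- accessors -----------------------------------------------------------

#' @describeIn PeptideSet-class the peptide sequences
#' @param x,object a `PeptideSet`
#' @export
setGeneric("peptides", function(x) standardGeneric("peptides"))

#' @rdname PeptideSet-class
#' @export
setMethod("peptides", "PeptideSet", function(x) x@peptides)

#' @describeIn PeptideSet-class named list mapping peptide to source
#'   accessions
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname PeptideSet-class
#' @export
setMethod("provenance", "PeptideSet", function(x) x@provenance)

#' @describeIn PairedEntrapmentDB-class the target/entrapment pair table
#' @param x,object a `PairedEntrapmentDB`
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))

#' @rdname PairedEntrapmentDB-class
#' @export
setMethod("pairTable", "PairedEntrapmentDB", function(x) x@pairs)

#' @describeIn PairedEntrapmentDB-class targets dropped during the build
#' @export
setGeneric("removedTargets", function(x) standardGeneric("removedTargets"))

#' @rdname PairedEntrapmentDB-class
#' @export
setMethod("removedTargets", "PairedEntrapmentDB", function(x) x@removed)

#' @describeIn DiscoveryTable-class the underlying data.frame
#' @export
setMethod("as.data.frame", "DiscoveryTable",
          function(x, row.names = NULL, optional = FALSE, ...) x@rows)

#' @describeIn DiscoveryTable-class number of rows
#' @export
setMethod("length", "DiscoveryTable", function(x) nrow(x@rows))

## ---- show ---------------------------------------------------------------

setMethod("show", "PeptideSet", function(object) {
  cat(sprintf("PeptideSet with %d unique peptides from %d proteins\n",
              length(object@peptides),
              length(unique(unlist(object@provenance)))))
  if (length(object@peptides))
    cat("  first:", paste(head(object@peptides, 3), collapse = ", "), "\n")
})

setMethod("show", "PairedEntrapmentDB", function(object) {
  nt <- if (object@mode == "shuffled")
    length(unique(object@pairs$target)) else
    object@metadata$n_targets %||% NA_integer_
  cat(sprintf("PairedEntrapmentDB (%s-level, %s mode)\n",
              object@level, object@mode))
  cat(sprintf("  r = %g; %s surviving targets; %d entrapment entries; %d removed\n",
              object@r, format(nt), nrow(object@pairs), nrow(object@removed)))
})

setMethod("show", "DiscoveryTable", function(object) {
  tab <- table(factor(object@rows$label, c("original", "entrapment")))
  cat(sprintf("DiscoveryTable: %d rows (%d original, %d entrapment)\n",
              nrow(object@rows), tab[["original"]], tab[["entrapment"]]))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
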