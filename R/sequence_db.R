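## FASTA ingestion and deterministic in-silico tryptic digestion.

#' Read a protein FASTA file
#'
#' Reads a standard (wrapped or unwrapped) amino-acid FASTA file into an
#' [Biostrings::AAStringSet] whose names are the accessions (first
#' whitespace-delimited token of each header); full headers are kept in the
#' `description` metadata column.  Sequences are whitespace-stripped and
#' upper-cased; file order is preserved.
#'
#' @param path path to a FASTA file.
#' @return An `AAStringSet`, one entry per FASTA record.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">A small protein", "MKR", "PEPK", ">B", "PR"), fa)
#' readFasta(fa)
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty FASTA file: ", path, call. = FALSE)
  first <- which(startsWith(trimws(lines), ">"))[1]
  if (is.na(first) || first != 1L)
    stop(sprintf("malformed FASTA header at line %d of %s: expected '>'",
                 1L, path), call. = FALSE)
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  acc <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(acc))
    stop("duplicate accession(s) in FASTA: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "),
         call. = FALSE)
  seqs <- toupper(gsub("\\s+", "", as.character(aa)))
  if (any(!nzchar(seqs)))
    stop("empty sequence for accession(s): ",
         paste(acc[!nzchar(seqs)], collapse = ", "), call. = FALSE)
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- acc
  S4Vectors::metadata(out)$description <- headers
  nonstd <- vapply(seqs, function(s) !isCanonical(s), logical(1))
  if (any(nonstd))
    message(sum(nonstd), " sequence(s) contain non-canonical residues: ",
            paste(head(acc[nonstd], 5), collapse = ", "))
  out
}

#' Digestion settings for trypsin
#'
#' Trypsin without proline suppression: cleavage after every K and R,
#' including K/R followed by P.  The peptide-level database uses one missed
#' cleavage and a 7-35 residue length window; the protein-level entrapment
#' construction digests with zero missed cleavages and no length filter.
#'
#' @param missedCleavages maximum number of internal cleavage sites
#'   retained in a peptide (non-negative integer).
#' @param minLen,maxLen inclusive peptide-length window.
#' @param applyLengthFilter whether the length window is applied.
#' @return A list with class `"DigestConfig"`.
#' @examples
#' digestConfig()                      # peptide-level defaults: 1 mc, 7-35
#' digestConfig(0, applyLengthFilter = FALSE)  # protein-level digest
#' @export
digestConfig <- function(missedCleavages = 1L, minLen = 7L, maxLen = 35L,
                         applyLengthFilter = TRUE) {
  assertCount(missedCleavages, "missedCleavages")
  assertFlag(applyLengthFilter, "applyLengthFilter")
  if (applyLengthFilter && minLen > maxLen)
    stop("minLen must not exceed maxLen", call. = FALSE)
  structure(list(enzyme = "trypsin, no proline suppression",
                 missedCleavages = as.integer(missedCleavages),
                 minLen = as.integer(minLen), maxLen = as.integer(maxLen),
                 applyLengthFilter = applyLengthFilter),
            class = "DigestConfig")
}

## 0-missed-cleavage fragments: split after every K or R.
tryptic_fragments <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  cut_after <- which(chars %in% c("K", "R"))
  bounds <- unique(c(cut_after, length(chars)))
  starts <- c(1L, head(bounds, -1L) + 1L)
  substring(sequence, starts, bounds)
}

#' In-silico tryptic digestion of one protein
#'
#' Cleaves after every K and R (proline suppression off, so K/R-P bonds are
#' cut too) and returns all peptides containing at most
#' `config$missedCleavages` internal cleavage sites, optionally restricted
#' to the configured length window.  The C-terminal peptide is kept whether
#' or not it ends in K/R.  Duplicate peptides arising at different
#' positions within the protein are each returned (deduplication happens at
#' the [PeptideSet-class] level).
#'
#' @param sequence a protein sequence (character or `AAString`).
#' @param config a [digestConfig()].
#' @return Character vector of peptides, N- to C-terminal order (all
#'   0-missed peptides first, then 1-missed, ...).
#' @examples
#' digest("MKRPEPK", digestConfig(0, applyLengthFilter = FALSE))
#' digest("MKRPEPK", digestConfig(1, applyLengthFilter = FALSE))
#' @export
digest <- function(sequence, config = digestConfig()) {
  sequence <- as.character(sequence)
  if (!nzchar(sequence)) stop("empty sequence", call. = FALSE)
  frags <- tryptic_fragments(sequence)
  out <- frags
  if (config$missedCleavages > 0L && length(frags) > 1L) {
    for (m in seq_len(min(config$missedCleavages, length(frags) - 1L))) {
      n <- length(frags) - m
      joined <- vapply(seq_len(n), function(i)
        paste(frags[i:(i + m)], collapse = ""), character(1))
      out <- c(out, joined)
    }
  }
  if (config$applyLengthFilter) {
    len <- nchar(out)
    out <- out[len >= config$minLen & len <= config$maxLen]
  }
  out
}

#' Build the original-target peptide database
#'
#' Digests every protein, pools the peptides, deduplicates them, and
#' records, for each unique peptide, the accessions of all proteins it was
#' produced from.
#'
#' @param proteins an `AAStringSet` (e.g. from [readFasta()]) or a named
#'   character vector of protein sequences.
#' @param config a [digestConfig()]; the default is the peptide-level
#'   setting (trypsin, one missed cleavage, lengths 7-35).
#' @return A [PeptideSet-class].
#' @examples
#' prots <- c(A = "MKDEQPLRSTAVWYK", B = "STAVWYKMMMMMMMR")
#' buildPeptideDb(prots)
#' @export
buildPeptideDb <- function(proteins, config = digestConfig()) {
  seqs <- asNamedSeqs(proteins)
  if (!length(seqs)) stop("empty protein collection", call. = FALSE)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("proteins must be named by accession", call. = FALSE)
  prov <- new.env(parent = emptyenv())
  peps <- character()
  for (acc in names(seqs)) {
    for (p in unique(digest(seqs[[acc]], config))) {
      if (is.null(prov[[p]])) {
        peps <- c(peps, p)
        prov[[p]] <- acc
      } else prov[[p]] <- c(prov[[p]], acc)
    }
  }
  if (!length(peps))
    warning("no peptides survive the digestion filters", call. = FALSE)
  new("PeptideSet", peptides = peps,
      provenance = stats::setNames(lapply(peps, function(p) prov[[p]]), peps))
}

#' Write a PeptideSet to disk
#'
#' Two-column TSV (`peptide`, semicolon-joined `accessions`) or a FASTA of
#' peptides (one entry per peptide, named by the peptide itself).
#'
#' @param x a [PeptideSet-class].
#' @param path output file.
#' @param format `"tsv"` or `"fasta"`.
#' @return `path`, invisibly.
#' @export
writePeptideSet <- function(x, path, format = c("tsv", "fasta")) {
  format <- match.arg(format)
  stopifnot(is(x, "PeptideSet"))
  if (format == "tsv") {
    df <- data.frame(
      peptide = peptides(x),
      accessions = vapply(provenance(x), paste, character(1),
                          collapse = ";"))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    aa <- Biostrings::AAStringSet(peptides(x))
    names(aa) <- peptides(x)
    Biostrings::writeXStringSet(aa, path)
  }
  invisible(path)
}
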