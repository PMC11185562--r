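## Parsing third-party search-tool reports into DiscoveryTables and the
## target/entrapment labeling conventions.

#' Column mapping for a search-tool report
#'
#' Declares which columns of a TSV/CSV report carry the discovery
#' identifier, score, q-value and protein group, and how
#' entrapment entries are marked (an accession prefix such as `"ENTRAP_"`,
#' or an explicit label column).  Which q-value column to map (e.g. a
#' library-wide versus per-run q-value in multi-run reports) is the
#' caller's choice.
#'
#' @param idColumn column with the discovery identifier.
#' @param scoreColumn column with the score (`NULL` if absent).
#' @param qvalueColumn column with the tool q-value (`NULL` if absent).
#' @param proteinGroupColumn column with the delimited protein-group
#'   accession list; when set, rows are labeled by the group rule of
#'   [labelProteinGroup()].
#' @param entrapmentMarker accession prefix marking entrapment entries.
#' @param labelColumn explicit label column (values `"original"` /
#'   `"entrapment"`), overriding marker detection.
#' @param pairKeyColumn optional column with the paired original target id.
#' @param groupDelimiter protein-group delimiter.
#' @return A list with class `"ColumnMap"`.
#' @export
columnMap <- function(idColumn = "id", scoreColumn = "score",
                      qvalueColumn = "qvalue",
                      proteinGroupColumn = NULL,
                      entrapmentMarker = "ENTRAP_", labelColumn = NULL,
                      pairKeyColumn = NULL, groupDelimiter = ";") {
  if (is.null(scoreColumn) && is.null(qvalueColumn))
    stop("at least one of scoreColumn/qvalueColumn must be mapped",
         call. = FALSE)
  structure(list(idColumn = idColumn, scoreColumn = scoreColumn,
                 qvalueColumn = qvalueColumn,
                 proteinGroupColumn = proteinGroupColumn,
                 entrapmentMarker = entrapmentMarker,
                 labelColumn = labelColumn, pairKeyColumn = pairKeyColumn,
                 groupDelimiter = groupDelimiter),
            class = "ColumnMap")
}

#' Label a protein group as original target or entrapment
#'
#' A protein group counts as an original-target discovery if at least one
#' member is from the original target database (i.e. lacks the entrapment
#' marker); a group consisting solely of entrapment proteins counts as an
#' entrapment discovery.  Labeling does not depend on member order.
#'
#' @param group delimited accession list (single string) or character
#'   vector of accessions.
#' @param marker entrapment accession prefix.
#' @param delimiter delimiter when `group` is a single string.
#' @return `"original"` or `"entrapment"`.
#' @examples
#' labelProteinGroup("P1;ENTRAP_P2")          # "original"
#' labelProteinGroup("ENTRAP_A;ENTRAP_B")     # "entrapment"
#' @export
labelProteinGroup <- function(group, marker = "ENTRAP_", delimiter = ";") {
  if (length(group) == 1L && grepl(delimiter, group, fixed = TRUE))
    group <- strsplit(group, delimiter, fixed = TRUE)[[1]]
  group <- trimws(group)
  group <- group[nzchar(group)]
  if (!length(group)) stop("empty protein group", call. = FALSE)
  if (any(!startsWith(group, marker))) "original" else "entrapment"
}

#' Parse a search-tool report into a DiscoveryTable
#'
#' Reads a TSV (or CSV) report, labels each row original/entrapment by the
#' configured marker, label column or protein-group rule, validates
#' q-values, and collapses duplicate identifiers to their best row (lowest
#' q-value, then highest score).
#'
#' @param path report file; tab-delimited unless it ends in `.csv`.
#' @param map a [columnMap()].
#' @return A [DiscoveryTable-class].
#' @export
parseReport <- function(path, map = columnMap()) {
  stopifnot(inherits(map, "ColumnMap"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE)
  mapped <- c(map$idColumn, map$scoreColumn, map$qvalueColumn,
              map$proteinGroupColumn, map$labelColumn, map$pairKeyColumn)
  missing_cols <- setdiff(mapped, names(df))
  if (length(missing_cols))
    stop("mapped column(s) missing from report: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  id <- as.character(df[[map$idColumn]])
  score <- if (!is.null(map$scoreColumn))
    as.numeric(df[[map$scoreColumn]]) else NA_real_
  qvalue <- if (!is.null(map$qvalueColumn))
    as.numeric(df[[map$qvalueColumn]]) else NA_real_
  if (!all(is.na(qvalue))) {
    bad <- which(!is.na(qvalue) & (qvalue < 0 | qvalue > 1))
    if (length(bad))
      stop("q-value outside [0, 1] at row(s): ",
           paste(head(bad, 10), collapse = ", "), call. = FALSE)
  }
  label <- if (!is.null(map$labelColumn)) {
    as.character(df[[map$labelColumn]])
  } else if (!is.null(map$proteinGroupColumn)) {
    vapply(as.character(df[[map$proteinGroupColumn]]),
           labelProteinGroup, character(1),
           marker = map$entrapmentMarker,
           delimiter = map$groupDelimiter, USE.NAMES = FALSE)
  } else {
    ifelse(startsWith(id, map$entrapmentMarker), "entrapment", "original")
  }
  pair <- if (!is.null(map$pairKeyColumn))
    as.character(df[[map$pairKeyColumn]]) else NA_character_
  tab <- data.frame(id = id, label = label, score = rep_len(score, nrow(df)),
                    qvalue = rep_len(qvalue, nrow(df)),
                    pair_key = rep_len(pair, nrow(df)),
                    known_false = NA, stringsAsFactors = FALSE)
  ## collapse duplicate ids to the best row: lowest q, then highest score
  ord <- order(tab$id, tab$qvalue, -xtfrm(tab$score), na.last = TRUE)
  tab <- tab[ord, , drop = FALSE]
  tab <- tab[!duplicated(tab$id), , drop = FALSE]
  tab <- tab[order(match(tab$id, id)), , drop = FALSE]
  rownames(tab) <- NULL
  new("DiscoveryTable", rows = tab)
}

#' Write a DiscoveryTable as canonical TSV
#'
#' @param table a [DiscoveryTable-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @seealso [readDiscoveryTable()] for the inverse.
#' @export
writeDiscoveryTable <- function(table, path) {
  stopifnot(is(table, "DiscoveryTable"))
  write.table(table@rows[, c("id", "label", "score", "qvalue",
                             "pair_key", "known_false")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a canonical DiscoveryTable TSV
#'
#' @param path a file written by [writeDiscoveryTable()].
#' @return A [DiscoveryTable-class].
#' @export
readDiscoveryTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  DiscoveryTable(id = df$id, label = df$label, score = df$score,
                 qvalue = df$qvalue, pairKey = as.character(df$pair_key),
                 knownFalse = df$known_false)
}
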