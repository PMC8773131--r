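#' Load a bioactive-peptide reference table
#'
#' Local TSV stand-in for a milk bioactive-peptide database: columns
#' \code{sequence}, \code{parent} (protein label plus fragment range),
#' \code{bioactivities} (semicolon-joined activity labels) and, optionally,
#' extra annotation columns (the bundled fixture adds \code{enzymes}, the
#' semicolon-joined labels of the enzymes reported to release the peptide).
#' The bundled fixture holds 30 casein-derived peptides with demonstrated
#' bioactivity (ACE inhibition, antimicrobial, antioxidant, immunomodulation,
#' DPP-IV inhibition, anxiolytic): 18 from beta-casein and 12 from
#' alphaS1-casein.
#'
#' @param path path to the table (default: bundled fixture).
#' @return data.frame of validated entries; a warning is raised for an
#'   empty table.
#' @export
#' @examples
#' nrow(loadBioactiveTable())  # 30
loadBioactiveTable <- function(path = system.file("extdata",
                                                  "bioactive_peptides.tsv",
                                                  package = "CEPspec")) {
  if (!file.exists(path)) cepStop("bioactive table not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sequence", "parent", "bioactivities")
  if (!all(need %in% names(df)))
    cepStop("bioactive table must have columns %s",
            paste(need, collapse = ", "), class = "cep_schema_error")
  if (nrow(df) == 0L) {
    warning("bioactive table '", path, "' is empty")
    return(df)
  }
  df$sequence <- toupper(df$sequence)
  if (any(!nzchar(df$sequence)))
    cepStop("bioactive table contains an empty sequence")
  if (any(!nzchar(df$bioactivities)))
    cepStop("bioactive table entry without a bioactivity label")
  key <- paste(df$sequence, df$parent)
  if (anyDuplicated(key))
    cepStop("duplicate (sequence, parent) entry: %s", key[duplicated(key)][1])
  df
}

#' Match peptides against a bioactive reference at full-length identity
#'
#' A peptide matches an entry iff the sequences are identical
#' (case-insensitive; modifications play no role). No substring or
#' similarity matching is performed — the reference criterion is 100\%
#' sequence identity.
#'
#' @param peptides character vector of peptide sequences (deduplicated
#'   internally).
#' @param table data.frame from [loadBioactiveTable()].
#' @return data.frame with one row per (peptide, matching entry): columns
#'   \code{peptide}, \code{parent}, \code{bioactivities}; zero rows when
#'   nothing matches.
#' @export
#' @examples
#' matchBioactive("LPVPQ", loadBioactiveTable())  # DPP-IV inhibition
matchBioactive <- function(peptides, table) {
  peptides <- unique(toupper(peptides))
  hit <- table[table$sequence %in% peptides, , drop = FALSE]
  out <- data.frame(peptide = hit$sequence, parent = hit$parent,
                    bioactivities = hit$bioactivities,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Summarize bioactive-peptide release for two enzymes
#'
#' Counts the distinct matched sequences per enzyme, the intersection, and
#' the exclusive sets, for one substrate. The identity
#' \code{count = shared + exclusive} holds for each enzyme.
#'
#' @param peptidesA,peptidesB peptide sequence sets observed for the two
#'   enzymes.
#' @param table bioactive reference from [loadBioactiveTable()].
#' @param labels character(2), enzyme labels for the report.
#' @return list with \code{counts} (named integer(2)), \code{nShared},
#'   \code{shared}, \code{exclusiveA}, \code{exclusiveB} and the matched
#'   sequence sets \code{matchedA}, \code{matchedB}.
#' @export
summarizeBioactive <- function(peptidesA, peptidesB, table,
                               labels = c("A", "B")) {
  stopifnot(length(labels) == 2L, labels[1] != labels[2])
  mA <- unique(matchBioactive(peptidesA, table)$peptide)
  mB <- unique(matchBioactive(peptidesB, table)$peptide)
  shared <- intersect(mA, mB)
  counts <- c(length(mA), length(mB))
  names(counts) <- labels
  list(counts = counts, nShared = length(shared), shared = shared,
       exclusiveA = setdiff(mA, mB), exclusiveB = setdiff(mB, mA),
       matchedA = mA, matchedB = mB)
}

#' Write a bioactive match report
#'
#' TSV with one row per matched peptide, annotated with the enzymes whose
#' observed peptide sets released it.
#'
#' @param matchesByEnzyme named list: enzyme label -> match data.frame from
#'   [matchBioactive()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeBioactiveReport <- function(matchesByEnzyme, path) {
  all <- unique(do.call(rbind, unname(matchesByEnzyme)))
  if (is.null(all) || nrow(all) == 0L) {
    utils::write.table(
      data.frame(peptide = character(), parent = character(),
                 bioactivities = character(), enzymes_releasing = character()),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  all$enzymes_releasing <- vapply(all$peptide, function(p) {
    who <- names(matchesByEnzyme)[vapply(matchesByEnzyme,
                                         function(m) p %in% m$peptide,
                                         logical(1))]
    paste(who, collapse = ";")
  }, character(1))
  all <- all[order(all$parent, all$peptide), , drop = FALSE]
  utils::write.table(all, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
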