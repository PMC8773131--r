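#' Parse a compact modification string
#'
#' Peptide tables carry variable modifications in a compact syntax:
#' \code{ox@<pos>} for methionine oxidation and \code{ph@<pos>} for
#' serine/threonine phosphorylation, joined by \code{";"}; an empty string
#' means no modification. Positions are 1-based within the peptide.
#'
#' @param mods modification string (possibly empty or NA).
#' @param sequence the peptide sequence the positions refer to.
#' @return data.frame with columns \code{type} ("oxidation" or
#'   "phosphorylation") and \code{position}; zero rows when unmodified.
#' @export
#' @examples
#' parseModifications("ox@2;ph@5", "AMKST")
parseModifications <- function(mods, sequence) {
  out <- data.frame(type = character(), position = integer())
  if (is.na(mods) || !nzchar(trimws(mods))) return(out)
  toks <- strsplit(trimws(mods), ";", fixed = TRUE)[[1]]
  n <- nchar(sequence)
  for (tok in toks) {
    m <- regmatches(tok, regexec("^\\s*(ox|ph)@([0-9]+)\\s*$", tok))[[1]]
    if (length(m) == 0L)
      cepStop("unparsable modification token '%s' (expected ox@<pos> or ph@<pos>)", tok)
    pos <- as.integer(m[3])
    if (pos < 1L || pos > n)
      cepStop("modification position %d outside peptide '%s' (length %d)",
              pos, sequence, n)
    res <- substr(sequence, pos, pos)
    if (m[2] == "ox" && res != "M")
      cepStop("oxidation at position %d of '%s': residue %s is not M",
              pos, sequence, res)
    if (m[2] == "ph" && !res %in% c("S", "T"))
      cepStop("phosphorylation at position %d of '%s': residue %s is not S or T",
              pos, sequence, res)
    out <- rbind(out, data.frame(
      type = if (m[2] == "ox") "oxidation" else "phosphorylation",
      position = pos))
  }
  out
}

# Internal: validate one observation row; returns NULL or an error message.
checkObservationRow <- function(sequence, modifications, time_h) {
  chars <- strsplit(sequence, "")[[1]]
  if (length(chars) == 0L) return("empty peptide sequence")
  bad <- which(!chars %in% AA20)
  if (length(bad))
    return(sprintf("illegal residue '%s' at position %d of '%s'",
                   chars[bad[1]], bad[1], sequence))
  if (is.na(time_h) || time_h < 0) return("time_h must be a non-negative number")
  err <- tryCatch({ parseModifications(modifications, sequence); NULL },
                  error = conditionMessage)
  err
}

#' Read a peptide observation table
#'
#' Reads identified-peptide lists from delimited text with a header. Required
#' columns: \code{sequence}, \code{time_h}, \code{enzyme}, \code{protein_id};
#' optional column \code{modifications} in the compact syntax of
#' [parseModifications()]. Every row is validated (alphabet, modification
#' chemistry, non-negative time); errors name the offending row. Row order is
#' preserved.
#'
#' @param path path to the table.
#' @param sep field separator; tab by default, use \code{","} for CSV.
#' @return data.frame of observations with columns \code{sequence},
#'   \code{modifications}, \code{time_h}, \code{enzyme}, \code{protein_id}.
#' @export
readPeptideTable <- function(path, sep = "\t") {
  if (!file.exists(path)) cepStop("peptide table not found: %s", path)
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          colClasses = "character",
                          check.names = FALSE, strip.white = TRUE)
  required <- c("sequence", "time_h", "enzyme", "protein_id")
  missing <- setdiff(required, names(df))
  if (length(missing))
    cepStop("peptide table '%s' is missing column(s): %s",
            path, paste(missing, collapse = ", "), class = "cep_schema_error")
  if (!"modifications" %in% names(df)) df$modifications <- ""
  df$modifications[is.na(df$modifications)] <- ""
  df$sequence <- toupper(df$sequence)
  time_h <- suppressWarnings(as.numeric(df$time_h))
  for (i in seq_len(nrow(df))) {
    err <- checkObservationRow(df$sequence[i], df$modifications[i], time_h[i])
    if (!is.null(err))
      cepStop("row %d of '%s': %s", i, path, err, class = "cep_row_error")
  }
  data.frame(sequence = df$sequence,
             modifications = df$modifications,
             time_h = time_h,
             enzyme = df$enzyme,
             protein_id = df$protein_id,
             stringsAsFactors = FALSE)
}

#' Write a peptide observation table
#'
#' Tab-separated, UTF-8, with the canonical column order; the exact inverse
#' of [readPeptideTable()], so write-then-read round-trips field for field.
#'
#' @param observations data.frame of observations.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePeptideTable <- function(observations, path) {
  cols <- c("sequence", "modifications", "time_h", "enzyme", "protein_id")
  stopifnot(all(cols %in% names(observations)))
  utils::write.table(observations[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
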