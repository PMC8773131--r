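#' Locate all exact occurrences of a peptide in a protein
#'
#' Exact substring search on the unmodified sequence (modifications play no
#' role in matching; I and L are distinct letters). Overlapping occurrences
#' are all reported, in ascending start order.
#'
#' @param peptideSequence amino-acid string, length >= 1.
#' @param protein a \linkS4class{ProteinRecord}.
#' @return data.frame with columns \code{start}, \code{end} (1-based,
#'   inclusive); zero rows when the peptide does not occur.
#' @export
#' @examples
#' prot <- proteinRecord("toy", "AAA")
#' findOccurrences("AA", prot)  # (1,2) and (2,3)
findOccurrences <- function(peptideSequence, protein) {
  stopifnot(is(protein, "ProteinRecord"), nchar(peptideSequence) >= 1L)
  hits <- matchPattern(AAString(toupper(peptideSequence)), protein@sequence)
  data.frame(start = BiocGenerics::start(hits), end = BiocGenerics::end(hits))
}

#' Map peptide observations onto their parent proteins
#'
#' Assigns fragment coordinates to every observation by exact substring
#' search against the protein named in its \code{protein_id} column. One
#' mapped row is emitted per (observation, occurrence); peptides occurring
#' at more than one position are flagged \code{ambiguous}. Observations with
#' no occurrence are never silently dropped: they are returned in a separate
#' \code{unmapped} table.
#'
#' @param observations data.frame from [readPeptideTable()].
#' @param proteins named list of \linkS4class{ProteinRecord} (names = ids),
#'   e.g. from [loadFasta()].
#' @return list with elements \code{mapped} (data.frame: \code{peptide},
#'   \code{protein_id}, \code{start}, \code{end}, \code{ambiguous},
#'   \code{time_h}, \code{enzyme}, \code{modifications}) and \code{unmapped}
#'   (the input rows that matched nowhere).
#' @export
mapObservations <- function(observations, proteins) {
  stopifnot(is.data.frame(observations))
  if (is(proteins, "ProteinRecord")) proteins <- list(proteins)
  if (is.null(names(proteins)) || any(!nzchar(names(proteins))))
    names(proteins) <- vapply(proteins, proteinId, character(1))
  unknown <- setdiff(unique(observations$protein_id), names(proteins))
  if (length(unknown))
    cepStop("unknown protein_id(s) in observations: %s",
            paste(unknown, collapse = ", "), class = "cep_lookup_error")

  mappedRows <- vector("list", nrow(observations))
  unmappedIdx <- integer()
  for (i in seq_len(nrow(observations))) {
    obs <- observations[i, ]
    occ <- findOccurrences(obs$sequence, proteins[[obs$protein_id]])
    if (nrow(occ) == 0L) {
      unmappedIdx <- c(unmappedIdx, i)
      next
    }
    mappedRows[[i]] <- data.frame(
      peptide = obs$sequence,
      protein_id = obs$protein_id,
      start = occ$start,
      end = occ$end,
      ambiguous = nrow(occ) > 1L,
      time_h = obs$time_h,
      enzyme = obs$enzyme,
      modifications = obs$modifications,
      stringsAsFactors = FALSE)
  }
  mapped <- do.call(rbind, mappedRows[!vapply(mappedRows, is.null, logical(1))])
  if (is.null(mapped))
    mapped <- data.frame(peptide = character(), protein_id = character(),
                         start = integer(), end = integer(),
                         ambiguous = logical(), time_h = numeric(),
                         enzyme = character(), modifications = character())
  rownames(mapped) <- NULL
  list(mapped = mapped, unmapped = observations[unmappedIdx, , drop = FALSE])
}

#' Write a mapped-peptide table
#'
#' @param mapped the \code{mapped} data.frame from [mapObservations()].
#' @param path output path (TSV).
#' @return \code{path}, invisibly.
#' @export
writeMappedPeptides <- function(mapped, path) {
  cols <- c("peptide", "protein_id", "start", "end", "ambiguous",
            "time_h", "enzyme")
  utils::write.table(mapped[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
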