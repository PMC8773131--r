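#' Construct a ProteinRecord
#'
#' @param id short label (used by peptide tables to name their parent).
#' @param sequence amino-acid string or \code{AAString}; uppercased.
#' @param name free-text protein name.
#' @param variantNote free-text provenance of the sequence variant.
#' @return a validated \linkS4class{ProteinRecord}.
#' @export
#' @examples
#' proteinRecord("toy", "MKVLNENLLR")
proteinRecord <- function(id, sequence, name = id, variantNote = "") {
  if (is(sequence, "AAString")) sequence <- as.character(sequence)
  new("ProteinRecord",
      id = as.character(id),
      name = as.character(name),
      sequence = AAString(toupper(sequence)),
      variantNote = as.character(variantNote))
}

#' @describeIn proteinRecord sequence length (number of residues).
#' @param x a ProteinRecord.
#' @export
setMethod("length", "ProteinRecord", function(x) length(x@sequence))

#' @export
setMethod("show", "ProteinRecord", function(object) {
  s <- as.character(object@sequence)
  cat(sprintf("ProteinRecord '%s' (%s), %d aa\n",
              object@id, object@name, nchar(s)))
  cat(" ", if (nchar(s) > 60) paste0(substr(s, 1, 57), "...") else s, "\n")
  if (nzchar(object@variantNote))
    cat("  variant:", object@variantNote, "\n")
})

#' Accessors for ProteinRecord
#'
#' @param x a \linkS4class{ProteinRecord}.
#' @return \code{proteinId}: the id label; \code{proteinSequence}: the plain
#'   character sequence.
#' @export
proteinId <- function(x) {
  stopifnot(is(x, "ProteinRecord"))
  x@id
}

#' @rdname proteinId
#' @export
proteinSequence <- function(x) {
  stopifnot(is(x, "ProteinRecord"))
  as.character(x@sequence)
}

#' Load protein references from a FASTA file
#'
#' Reads one \linkS4class{ProteinRecord} per FASTA entry, in file order.
#' Sequences are uppercased and validated against the 20-letter alphabet;
#' ambiguity codes (B, J, X, Z) and any other character are rejected with an
#' error naming the record and the offending position. The FASTA id (first
#' whitespace-delimited token of the header) becomes the record id and the
#' remainder of the header the name.
#'
#' @param path path to a FASTA file.
#' @return named list of \linkS4class{ProteinRecord} (names = ids).
#' @export
#' @examples
#' fa <- system.file("extdata", "caseins.fasta", package = "CEPspec")
#' prots <- loadFasta(fa)
#' length(prots$beta_casein)  # 209
loadFasta <- function(path) {
  if (!file.exists(path))
    cepStop("FASTA file not found: %s", path)
  set <- tryCatch(
    readAAStringSet(path),
    error = function(e) cepStop("malformed FASTA '%s': %s", path, conditionMessage(e))
  )
  if (length(set) == 0L)
    cepStop("FASTA file '%s' contains no sequences", path)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    header <- names(set)[i]
    toks <- strsplit(trimws(header), "\\s+")[[1]]
    id <- toks[1]
    nm <- if (length(toks) > 1) paste(toks[-1], collapse = " ") else id
    out[[i]] <- proteinRecord(id = id, sequence = set[[i]], name = nm)
  }
  names(out) <- vapply(out, proteinId, character(1))
  out
}

#' Bundled casein reference sequences
#'
#' The two substrates of the CEP hydrolysis assay, in mature-protein
#' numbering: bovine beta-casein (genetic variant A2, 209 residues) and
#' bovine alphaS1-casein (variant B, 199 residues). Variant choice is
#' inferred from the per-residue composition (beta-casein A2: P = 35, H = 5)
#' and from published fragment coordinates such as f(1-23) and f(170-199) on
#' alphaS1-casein; it is a documented fixture convention, not an assertion
#' about any particular substrate lot.
#'
#' @return named list with elements \code{beta_casein} and \code{as1_casein}.
#' @export
#' @examples
#' caseinReferences()$beta_casein
caseinReferences <- function() {
  loadFasta(system.file("extdata", "caseins.fasta", package = "CEPspec",
                        mustWork = TRUE))
}

#' Per-residue composition of a protein
#'
#' Counts of each of the 20 amino acids in the sequence (zeros included);
#' the denominators of the subsite cleavage probabilities.
#'
#' @param protein a \linkS4class{ProteinRecord}.
#' @return named integer vector over the 20-amino-acid alphabet, summing to
#'   the sequence length.
#' @export
#' @examples
#' residueComposition(proteinRecord("toy", "MKM"))[c("M", "K")]
setGeneric("residueComposition",
           function(protein) standardGeneric("residueComposition"))

#' @rdname residueComposition
#' @export
setMethod("residueComposition", "ProteinRecord", function(protein) {
  chars <- strsplit(proteinSequence(protein), "")[[1]]
  counts <- table(factor(chars, levels = AA20))
  out <- as.integer(counts)
  names(out) <- AA20
  out
})
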