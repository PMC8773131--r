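#' Tally subsite residues of a cleavage-site set
#'
#' For each distinct cleaved bond (P1 index \eqn{p}), the residue at
#' \eqn{p} is counted at P1 and the residue at \eqn{p+1} at P1'. Both
#' tallies therefore sum to the number of sites.
#'
#' @param sites integer vector of distinct P1 indices.
#' @param protein the substrate \linkS4class{ProteinRecord}.
#' @return data.frame with one row per amino acid (all 20): columns
#'   \code{amino_acid}, \code{total} (occurrences in the protein),
#'   \code{cleaved_P1}, \code{cleaved_P1prime}.
#' @export
#' @examples
#' tallySubsites(1L, proteinRecord("toy", "MKV"))  # P1: M = 1; P1': K = 1
tallySubsites <- function(sites, protein) {
  stopifnot(is(protein, "ProteinRecord"))
  sites <- unique(as.integer(sites))
  L <- length(protein)
  if (length(sites) && (min(sites) < 1L || max(sites) > L - 1L))
    cepStop("site index outside the bond range [1, %d]", L - 1L)
  seqc <- strsplit(proteinSequence(protein), "")[[1]]
  tallyOf <- function(residues)
    as.integer(table(factor(residues, levels = AA20)))
  data.frame(
    amino_acid = AA20,
    total = as.integer(residueComposition(protein)),
    cleaved_P1 = tallyOf(seqc[sites]),
    cleaved_P1prime = tallyOf(seqc[sites + 1L]),
    stringsAsFactors = FALSE)
}

#' Cleavage probability of a residue at a subsite
#'
#' The per-residue cleavage probability: of the \code{total} occurrences of
#' an amino acid in the substrate, the percentage found at the subsite of an
#' observed cleavage, \eqn{100 \times cleaved / total}. Undefined
#' (\code{NA}) when the residue does not occur in the protein.
#'
#' @param cleaved number of occurrences cleaved at the subsite.
#' @param total occurrences of the amino acid in the protein.
#' @return percentage (unrounded), vectorized; \code{NA} where
#'   \code{total == 0}.
#' @export
#' @examples
#' cleavageProbability(5, 6)  # 83.33...
cleavageProbability <- function(cleaved, total) {
  stopifnot(length(cleaved) == length(total))
  if (any(total < 0 | cleaved < 0))
    cepStop("counts must be non-negative")
  if (any(cleaved > total))
    cepStop("cleaved count exceeds residue total")
  ifelse(total > 0, 100 * cleaved / total, NA_real_)
}

#' Mean cleavage probability over the 20-amino-acid alphabet
#'
#' The sum of the per-residue cleavage probabilities divided by the fixed
#' divisor 20, regardless of how many amino acids actually occur in the
#' protein; residues absent from the protein (undefined \%P) contribute 0 to
#' the sum. This fixed-divisor convention is what reproduces published Kn
#' tables (see the package vignette).
#'
#' @param percents numeric vector of \%P values, one per amino acid of the
#'   alphabet (length 20; \code{NA} allowed for absent residues).
#' @return the mean percentage.
#' @export
meanCleavageProbability <- function(percents) {
  if (length(percents) != 20L)
    cepStop("expected one %%P value per amino acid of the 20-letter alphabet")
  sum(percents, na.rm = TRUE) / 20
}

#' Subsite preference coefficient Kn
#'
#' \eqn{Kn = \%Pn / \overline{\%Pn} - 1}. Positive values mark residues that
#' favour cleavage at the subsite, negative values a disfavouring effect,
#' and exactly \eqn{-1} a residue present in the substrate but never found
#' at the subsite.
#'
#' @param percentP \%P value(s) for the residue at the subsite.
#' @param meanPercent the subsite mean from [meanCleavageProbability()].
#' @return unrounded coefficient(s); use [formatKn()] for reporting.
#' @export
#' @examples
#' knCoefficient(83.3, 37.2)  # about 1.24
knCoefficient <- function(percentP, meanPercent) {
  if (!is.finite(meanPercent) || meanPercent <= 0)
    cepStop("Kn is undefined when the mean cleavage probability is zero",
            class = "cep_undefined")
  percentP / meanPercent - 1
}

#' Build a specificity table from subsite tallies
#'
#' Core computation of the specificity statistics from per-residue counts:
#' \%P per residue and subsite, the per-subsite mean (fixed divisor 20), and
#' Kn. All 20 amino acids are always computed; masking of rare residues is a
#' report-time option only ([formatSpecificityTable()]).
#'
#' @param counts data.frame as produced by [tallySubsites()] (columns
#'   \code{amino_acid}, \code{total}, \code{cleaved_P1},
#'   \code{cleaved_P1prime}).
#' @param proteinId,enzyme labels stored in the result.
#' @return a \linkS4class{SpecificityTable}.
#' @export
specificityFromCounts <- function(counts, proteinId = "protein",
                                  enzyme = "enzyme") {
  need <- c("amino_acid", "total", "cleaved_P1", "cleaved_P1prime")
  stopifnot(all(need %in% names(counts)))
  counts <- counts[match(AA20, counts$amino_acid), , drop = FALSE]
  if (any(is.na(counts$amino_acid)))
    cepStop("counts must cover the full 20-amino-acid alphabet")
  pct1 <- cleavageProbability(counts$cleaved_P1, counts$total)
  pct2 <- cleavageProbability(counts$cleaved_P1prime, counts$total)
  m1 <- meanCleavageProbability(pct1)
  m2 <- meanCleavageProbability(pct2)
  if (m1 <= 0 || m2 <= 0)
    cepStop("specificity table undefined: no cleavage observed at a subsite",
            class = "cep_undefined")
  tab <- data.frame(
    amino_acid = counts$amino_acid,
    total = counts$total,
    cleaved_P1 = counts$cleaved_P1,
    pctP1 = pct1,
    Kn_P1 = ifelse(is.na(pct1), NA_real_, pct1 / m1 - 1),
    cleaved_P1prime = counts$cleaved_P1prime,
    pctP1prime = pct2,
    Kn_P1prime = ifelse(is.na(pct2), NA_real_, pct2 / m2 - 1),
    stringsAsFactors = FALSE)
  new("SpecificityTable", proteinId = proteinId, enzyme = enzyme,
      table = tab, meanP1 = m1, meanP1prime = m2)
}

#' Build a specificity table from a cleavage-site set
#'
#' Convenience wrapper: [tallySubsites()] then [specificityFromCounts()].
#'
#' @param sites integer vector of distinct P1 indices.
#' @param protein the substrate \linkS4class{ProteinRecord}.
#' @param enzyme enzyme label.
#' @return a \linkS4class{SpecificityTable}.
#' @export
buildSpecificityTable <- function(sites, protein, enzyme = "enzyme") {
  specificityFromCounts(tallySubsites(sites, protein),
                        proteinId = proteinId(protein), enzyme = enzyme)
}

#' Accessors for SpecificityTable
#'
#' @param x a \linkS4class{SpecificityTable}.
#' @return \code{specificityValues}: the unrounded per-residue data.frame;
#'   \code{subsiteMeans}: named vector of the P1 and P1' mean \%P.
#' @export
specificityValues <- function(x) {
  stopifnot(is(x, "SpecificityTable"))
  x@table
}

#' @rdname specificityValues
#' @export
subsiteMeans <- function(x) {
  stopifnot(is(x, "SpecificityTable"))
  c(P1 = x@meanP1, P1prime = x@meanP1prime)
}

#' Format a specificity table for reporting
#'
#' Applies the report rounding conventions (\%P at one decimal via
#' [formatPercent()], Kn at two decimals via [formatKn()]) and optionally
#' masks residues occurring fewer than \code{minOccurrences} times in the
#' substrate — mirroring published tables that omit singleton residues —
#' without ever altering the computed values underneath.
#'
#' @param x a \linkS4class{SpecificityTable}.
#' @param maskBelow residues with \code{total < maskBelow} are dropped from
#'   the report (default 0 = keep all; use 2 to hide singletons and absent
#'   residues).
#' @return data.frame with rounded \code{pctP1}, \code{Kn_P1},
#'   \code{pctP1prime}, \code{Kn_P1prime}.
#' @export
formatSpecificityTable <- function(x, maskBelow = 0L) {
  tab <- specificityValues(x)
  tab$pctP1 <- formatPercent(tab$pctP1)
  tab$Kn_P1 <- formatKn(tab$Kn_P1)
  tab$pctP1prime <- formatPercent(tab$pctP1prime)
  tab$Kn_P1prime <- formatKn(tab$Kn_P1prime)
  tab[tab$total >= maskBelow, , drop = FALSE]
}

#' @export
setMethod("show", "SpecificityTable", function(object) {
  cat(sprintf("SpecificityTable: enzyme %s on %s\n",
              object@enzyme, object@proteinId))
  cat(sprintf("  sites: %d | mean %%P1 = %.2f, mean %%P1' = %.2f\n",
              sum(object@table$cleaved_P1), object@meanP1, object@meanP1prime))
  print(formatSpecificityTable(object), row.names = FALSE)
})

#' Write specificity reports
#'
#' \code{writeSpecificityTable} writes the rounded per-residue report as
#' TSV; \code{writeSpecificityJson} writes the unrounded values plus the
#' per-subsite means as JSON.
#'
#' @param x a \linkS4class{SpecificityTable}.
#' @param path output path.
#' @param maskBelow see [formatSpecificityTable()].
#' @return \code{path}, invisibly.
#' @export
writeSpecificityTable <- function(x, path, maskBelow = 0L) {
  utils::write.table(formatSpecificityTable(x, maskBelow), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSpecificityTable
#' @export
writeSpecificityJson <- function(x, path) {
  jsonlite::write_json(
    list(protein_id = x@proteinId, enzyme = x@enzyme,
         mean_pctP1 = x@meanP1, mean_pctP1prime = x@meanP1prime,
         residues = specificityValues(x)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a subsite-count table
#'
#' Long-format TSV with columns \code{enzyme}, \code{subsite} (\code{P1} or
#' \code{P1prime}), \code{amino_acid}, \code{cleaved}. The bundled fixture
#' \code{beta_casein_subsite_counts.tsv} carries the published per-residue
#' cleaved-bond tallies of the two L. casei PrtR1 enzymes on beta-casein
#' after 48 h of hydrolysis.
#'
#' @param path path to the TSV (default: the bundled beta-casein fixture).
#' @return data.frame in long format.
#' @export
readSubsiteCounts <- function(path = system.file("extdata",
                                                 "beta_casein_subsite_counts.tsv",
                                                 package = "CEPspec")) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("enzyme", "subsite", "amino_acid", "cleaved")
  if (!all(need %in% names(df)))
    cepStop("subsite count table must have columns %s",
            paste(need, collapse = ", "), class = "cep_schema_error")
  df
}

#' Specificity table from a long-format count table
#'
#' Joins per-enzyme P1/P1' cleaved tallies (e.g. from
#' [readSubsiteCounts()]) with a protein's residue composition and computes
#' the full specificity statistics. Amino acids missing from the count table
#' are taken as zero cleaved.
#'
#' @param counts long-format data.frame (\code{enzyme}, \code{subsite},
#'   \code{amino_acid}, \code{cleaved}).
#' @param protein the substrate \linkS4class{ProteinRecord}.
#' @param enzyme which enzyme's rows to use.
#' @return a \linkS4class{SpecificityTable}.
#' @export
specificityFromCountTable <- function(counts, protein, enzyme) {
  stopifnot(is(protein, "ProteinRecord"))
  counts <- counts[counts$enzyme == enzyme, , drop = FALSE]
  if (!nrow(counts))
    cepStop("no rows for enzyme '%s' in the count table", enzyme,
            class = "cep_lookup_error")
  pull <- function(subsite) {
    sub <- counts[counts$subsite == subsite, , drop = FALSE]
    v <- sub$cleaved[match(AA20, sub$amino_acid)]
    v[is.na(v)] <- 0L
    as.integer(v)
  }
  wide <- data.frame(amino_acid = AA20,
                     total = as.integer(residueComposition(protein)),
                     cleaved_P1 = pull("P1"),
                     cleaved_P1prime = pull("P1prime"))
  specificityFromCounts(wide, proteinId = proteinId(protein), enzyme = enzyme)
}
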