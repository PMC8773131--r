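#' @import methods
#' @importFrom Biostrings AAString readAAStringSet matchPattern
#' @importFrom BiocGenerics start end
NULL

# The 20-letter amino-acid alphabet, in the conventional single-letter order
# used throughout the package (reports, tallies, simulator weights).
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Mature protein reference sequence
#'
#' A protein sequence in mature-protein numbering (residue 1 is the first
#' residue of the secreted chain, after signal-peptide removal). All peptide
#' fragment coordinates in the package are 1-based and inclusive on this
#' frame, matching the conventional f(start-end) fragment notation of casein
#' peptidomics.
#'
#' @slot id short label used to join peptide tables to proteins
#'   (e.g. \code{"beta_casein"}).
#' @slot name free-text protein name.
#' @slot sequence an \linkS4class{AAString} over the 20 standard amino acids.
#' @slot variantNote free-text provenance of the exact sequence variant.
#'
#' @seealso [loadFasta()], [caseinReferences()], [residueComposition()]
#' @export
setClass("ProteinRecord",
  representation(
    id          = "character",
    name        = "character",
    sequence    = "AAString",
    variantNote = "character"
  )
)

setValidity("ProteinRecord", function(object) {
  msg <- character()
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  s <- as.character(object@sequence)
  if (nchar(s) == 0L)
    msg <- c(msg, "sequence must be non-empty")
  bad <- which(!strsplit(s, "")[[1]] %in% AA20)
  if (length(bad))
    msg <- c(msg, sprintf(
      "record '%s': illegal residue '%s' at position %d (only the 20 standard amino acids are allowed)",
      object@id, substr(s, bad[1], bad[1]), bad[1]))
  if (length(msg)) msg else TRUE
})

#' Cumulative cleavage-site time course
#'
#' Distinct cleavage sites observed at or before each time point of a
#' hydrolysis experiment, for one enzyme on one substrate. A cleavage site is
#' identified by its P1 residue index \eqn{p}: the cleaved bond lies between
#' residues \eqn{p} and \eqn{p+1}. Site sets are cumulative and therefore
#' monotone non-decreasing along the time grid.
#'
#' @slot enzyme enzyme label.
#' @slot proteinId substrate protein id.
#' @slot times numeric vector of time points (hours, ascending).
#' @slot cumulativeSites list (parallel to \code{times}) of sorted integer
#'   vectors: all distinct P1 indices seen at or before each time.
#' @slot newSites list (parallel to \code{times}) of the sites first seen at
#'   each time point.
#'
#' @seealso [buildTimeCourse()], [inferSites()]
#' @export
setClass("SiteTimeCourse",
  representation(
    enzyme          = "character",
    proteinId       = "character",
    times           = "numeric",
    cumulativeSites = "list",
    newSites        = "list"
  )
)

setValidity("SiteTimeCourse", function(object) {
  msg <- character()
  if (is.unsorted(object@times, strictly = TRUE))
    msg <- c(msg, "'times' must be strictly ascending")
  if (length(object@times) != length(object@cumulativeSites) ||
      length(object@times) != length(object@newSites))
    msg <- c(msg, "site lists must be parallel to the time grid")
  cum <- object@cumulativeSites
  if (length(cum) > 1L)
    for (i in seq_along(cum)[-1L])
      if (!all(cum[[i - 1L]] %in% cum[[i]]))
        msg <- c(msg, "cumulative site sets must be monotone non-decreasing")
  if (length(msg)) msg else TRUE
})

#' Subsite specificity table
#'
#' Per-amino-acid cleavage statistics for one enzyme/substrate pair at the P1
#' and P1' subsites: occurrence counts, cleaved-bond tallies, the cleavage
#' probability \%P (percent of occurrences of the residue found at the
#' subsite), the mean \%P over the fixed 20-amino-acid alphabet, and the
#' preference coefficient Kn = \%P / mean(\%P) - 1. Kn > 0 marks residues
#' that favour cleavage at that subsite; Kn = -1 marks residues present in
#' the substrate but never observed there.
#'
#' The \code{table} slot holds unrounded values (\code{NA} where the residue
#' is absent from the protein); rounding is applied only at report time.
#'
#' @slot proteinId substrate protein id.
#' @slot enzyme enzyme label.
#' @slot table data.frame with one row per amino acid (all 20), columns
#'   \code{amino_acid}, \code{total}, \code{cleaved_P1}, \code{pctP1},
#'   \code{Kn_P1}, \code{cleaved_P1prime}, \code{pctP1prime},
#'   \code{Kn_P1prime}.
#' @slot meanP1,meanP1prime mean cleavage probability per subsite
#'   (denominator fixed at 20).
#'
#' @seealso [buildSpecificityTable()], [specificityFromCounts()]
#' @export
setClass("SpecificityTable",
  representation(
    proteinId   = "character",
    enzyme      = "character",
    table       = "data.frame",
    meanP1      = "numeric",
    meanP1prime = "numeric"
  )
)

setValidity("SpecificityTable", function(object) {
  msg <- character()
  need <- c("amino_acid", "total", "cleaved_P1", "pctP1", "Kn_P1",
            "cleaved_P1prime", "pctP1prime", "Kn_P1prime")
  if (!all(need %in% names(object@table)))
    msg <- c(msg, "table is missing required columns")
  else {
    tb <- object@table
    if (!setequal(tb$amino_acid, AA20))
      msg <- c(msg, "table must cover the 20-amino-acid alphabet exactly")
    if (any(tb$cleaved_P1 > tb$total) || any(tb$cleaved_P1prime > tb$total))
      msg <- c(msg, "cleaved tallies cannot exceed residue totals")
  }
  if (length(msg)) msg else TRUE
})

#' Stochastic digestion model
#'
#' Generative model for in-silico partial hydrolysis of a protein. Each
#' peptide bond \eqn{p} (between residues \eqn{p} and \eqn{p+1}) carries a
#' constant hazard
#' \deqn{\lambda_p = \lambda_0 \exp(w_{P1}[r_p] + w_{P1'}[r_{p+1}]) \cdot b(p)}
#' where \eqn{r_p} is the residue at position \eqn{p}, the \eqn{w} are
#' per-residue log-weights for the P1 and P1' subsites, and \eqn{b(p)} is an
#' optional regional bias multiplier. By time \eqn{t} the bond is cleaved
#' with probability \eqn{1 - e^{-\lambda_p t}}, independently across bonds
#' and molecules. The model is log-linear in the subsite residue identities,
#' so its sufficient statistics are exactly the P1/P1' tallies the analysis
#' pipeline estimates — parameter recovery is therefore a meaningful
#' end-to-end check.
#'
#' @slot baseHazard baseline cleavage rate per bond per hour
#'   (\eqn{\lambda_0 > 0}).
#' @slot p1Weights,p1primeWeights named numeric vectors over the 20 amino
#'   acids, log-scale subsite weights (0 = no preference).
#' @slot regionBias data.frame with columns \code{lo}, \code{hi},
#'   \code{multiplier}: hazard multipliers for bonds whose P1 index falls in
#'   [lo, hi]. Zero rows means no regional bias.
#' @slot nMolecules number of substrate molecules sampled per time point.
#' @slot detectMinLen,detectMaxLen peptide-length detectability window
#'   (residues), emulating the LC-MS/MS identifiable range.
#' @slot detectProb probability an eligible fragment is observed.
#' @slot seed random seed used by [simulateDataset()] (NA = caller seeds).
#'
#' @seealso [digestionModel()], [bondHazard()], [simulateDataset()]
#' @export
setClass("DigestionModel",
  representation(
    baseHazard     = "numeric",
    p1Weights      = "numeric",
    p1primeWeights = "numeric",
    regionBias     = "data.frame",
    nMolecules     = "integer",
    detectMinLen   = "integer",
    detectMaxLen   = "integer",
    detectProb     = "numeric",
    seed           = "integer"
  )
)

setValidity("DigestionModel", function(object) {
  msg <- character()
  if (!(length(object@baseHazard) == 1L && object@baseHazard > 0))
    msg <- c(msg, "baseHazard must be a single positive rate")
  for (nm in c("p1Weights", "p1primeWeights")) {
    w <- slot(object, nm)
    if (!identical(sort(names(w)), sort(AA20)))
      msg <- c(msg, sprintf("%s must be named over the 20 amino acids", nm))
  }
  if (nrow(object@regionBias) &&
      !all(c("lo", "hi", "multiplier") %in% names(object@regionBias)))
    msg <- c(msg, "regionBias needs columns lo, hi, multiplier")
  if (object@nMolecules < 1L)
    msg <- c(msg, "nMolecules must be >= 1")
  if (!(object@detectMinLen >= 1L && object@detectMinLen <= object@detectMaxLen))
    msg <- c(msg, "need 1 <= detectMinLen <= detectMaxLen")
  if (!(object@detectProb > 0 && object@detectProb <= 1))
    msg <- c(msg, "detectProb must be in (0, 1]")
  if (length(msg)) msg else TRUE
})
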