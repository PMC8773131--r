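#' Infer cleavage sites from mapped peptide termini
#'
#' Each mapped peptide evidences up to two cleaved bonds: its N-terminal
#' boundary at start \eqn{s} evidences the bond \eqn{(s-1, s)} (P1 index
#' \eqn{s-1}) and its C-terminal boundary at end \eqn{e} the bond
#' \eqn{(e, e+1)} (P1 index \eqn{e}). Protein termini are not cleavage
#' sites, so boundaries at position 1 or at the C-terminus contribute
#' nothing. A bond is counted once no matter how many peptides (or time
#' points) evidence it.
#'
#' By default only unambiguous mappings are used, to avoid fabricating sites
#' from repeated subsequences; set \code{includeAmbiguous = TRUE} to count
#' every occurrence.
#'
#' @param mapped data.frame of mappings (from [mapObservations()]) for one
#'   protein; columns \code{start}, \code{end} (and \code{ambiguous} unless
#'   \code{includeAmbiguous}).
#' @param protein the \linkS4class{ProteinRecord} the mappings refer to.
#' @param includeAmbiguous logical; include multi-occurrence mappings.
#' @return sorted integer vector of distinct P1 indices, each in
#'   \eqn{[1, L-1]}.
#' @export
#' @examples
#' prot <- proteinRecord("toy", "RPKHPIKHQGLPQEV")
#' inferSites(data.frame(start = 2, end = 5, ambiguous = FALSE), prot)  # 1, 5
inferSites <- function(mapped, protein, includeAmbiguous = FALSE) {
  stopifnot(is(protein, "ProteinRecord"))
  L <- length(protein)
  if (nrow(mapped) == 0L) return(integer())
  if (!includeAmbiguous && "ambiguous" %in% names(mapped))
    mapped <- mapped[!mapped$ambiguous, , drop = FALSE]
  if (any(mapped$start < 1L | mapped$end > L | mapped$start > mapped$end))
    cepStop("mapping coordinates outside protein '%s' (length %d)",
            proteinId(protein), L)
  sites <- c(mapped$start[mapped$start > 1L] - 1L,
             mapped$end[mapped$end < L])
  sort(unique(as.integer(sites)))
}

#' Build a cumulative cleavage-site time course
#'
#' Groups mappings by time point and accumulates the distinct cleavage sites
#' observed at or before each time. The result is invariant under any
#' reordering of the input rows.
#'
#' @param mapped data.frame of mappings for one enzyme/protein, with a
#'   \code{time_h} column.
#' @param protein the substrate \linkS4class{ProteinRecord}.
#' @param enzyme enzyme label stored in the result (defaults to the one
#'   label present in \code{mapped}).
#' @param includeAmbiguous passed to [inferSites()].
#' @return a \linkS4class{SiteTimeCourse}.
#' @export
buildTimeCourse <- function(mapped, protein, enzyme = NULL,
                            includeAmbiguous = FALSE) {
  stopifnot(is(protein, "ProteinRecord"), "time_h" %in% names(mapped))
  if (is.null(enzyme))
    enzyme <- if (nrow(mapped)) as.character(mapped$enzyme[1]) else "unknown"
  times <- sort(unique(as.numeric(mapped$time_h)))
  cum <- vector("list", length(times))
  new <- vector("list", length(times))
  seen <- integer()
  for (i in seq_along(times)) {
    at <- mapped[mapped$time_h == times[i], , drop = FALSE]
    sites <- inferSites(at, protein, includeAmbiguous = includeAmbiguous)
    new[[i]] <- setdiff(sites, seen)
    seen <- sort(union(seen, sites))
    cum[[i]] <- seen
  }
  new("SiteTimeCourse", enzyme = enzyme, proteinId = proteinId(protein),
      times = times, cumulativeSites = cum, newSites = new)
}

#' @export
setMethod("show", "SiteTimeCourse", function(object) {
  cat(sprintf("SiteTimeCourse: enzyme %s on %s\n",
              object@enzyme, object@proteinId))
  for (i in seq_along(object@times))
    cat(sprintf("  %5g h: %3d cumulative sites (%d new)\n",
                object@times[i], length(object@cumulativeSites[[i]]),
                length(object@newSites[[i]])))
})

#' Accessors for SiteTimeCourse
#'
#' @param x a \linkS4class{SiteTimeCourse}.
#' @param time a time point of the grid; default the last (all sites).
#' @return \code{cumulativeSites}: integer vector of P1 indices observed at
#'   or before \code{time}; \code{timePoints}: the time grid.
#' @export
cumulativeSites <- function(x, time = max(x@times)) {
  stopifnot(is(x, "SiteTimeCourse"))
  i <- match(time, x@times)
  if (is.na(i)) cepStop("time %g is not on the time grid", time)
  x@cumulativeSites[[i]]
}

#' @rdname cumulativeSites
#' @export
timePoints <- function(x) {
  stopifnot(is(x, "SiteTimeCourse"))
  x@times
}

#' Fraction of cleavage sites within a sequence region
#'
#' Percentage of the given sites whose P1 index falls in the inclusive
#' residue interval [lo, hi]; used to quantify regional hydrolysis onset
#' (e.g. the C-terminal region 161-209 of beta-casein).
#'
#' @param sites integer vector of P1 indices.
#' @param lo,hi region bounds (residue indices, inclusive).
#' @return percentage (unrounded).
#' @export
regionFraction <- function(sites, lo, hi) {
  stopifnot(lo <= hi)
  if (length(sites) == 0L)
    cepStop("region fraction is undefined for an empty site set",
            class = "cep_undefined")
  100 * sum(sites >= lo & sites <= hi) / length(sites)
}

#' Fraction of peptide bonds cleaved
#'
#' Percentage of the protein's \eqn{L - 1} peptide bonds represented in the
#' site set.
#'
#' @param sites integer vector of distinct P1 indices.
#' @param protein the substrate \linkS4class{ProteinRecord}.
#' @return percentage (unrounded).
#' @export
#' @examples
#' # 63 distinct sites on a 209-residue protein: 63/208 = 30.3%
bondCoverage <- function(sites, protein) {
  stopifnot(is(protein, "ProteinRecord"))
  100 * length(unique(sites)) / (length(protein) - 1L)
}

#' Cleavage-site overlap between two enzymes
#'
#' Set overlap of the distinct sites found for two enzymes on the same
#' substrate: sizes, intersection, and the shared percentage of each side.
#'
#' @param sitesA,sitesB integer vectors of P1 indices.
#' @return list with \code{nA}, \code{nB}, \code{nShared}, \code{pctA}
#'   (shared as \% of A), \code{pctB} (shared as \% of B); a percentage is
#'   \code{NA} when its side is empty.
#' @export
siteOverlap <- function(sitesA, sitesB) {
  a <- unique(sitesA); b <- unique(sitesB)
  shared <- length(intersect(a, b))
  list(nA = length(a), nB = length(b), nShared = shared,
       pctA = if (length(a)) 100 * shared / length(a) else NA_real_,
       pctB = if (length(b)) 100 * shared / length(b) else NA_real_)
}

#' Venn overlap of peptide sequence sets
#'
#' @param peptidesA,peptidesB character vectors of peptide sequences
#'   (deduplicated internally).
#' @return list with \code{uniqueA}, \code{uniqueB}, \code{shared}
#'   (character vectors) and \code{pctSharedOfUnion} = 100 |A∩B| / |A∪B|
#'   (\code{NA} when both sets are empty).
#' @export
peptideOverlap <- function(peptidesA, peptidesB) {
  a <- unique(toupper(peptidesA)); b <- unique(toupper(peptidesB))
  shared <- intersect(a, b)
  un <- union(a, b)
  list(uniqueA = setdiff(a, b), uniqueB = setdiff(b, a), shared = shared,
       pctSharedOfUnion = if (length(un)) 100 * length(shared) / length(un)
                          else NA_real_)
}

#' Write a cleavage-site table
#'
#' One row per distinct site with its subsite residues and the first time
#' point at which it was seen. With \code{bed = TRUE} an additional
#' BED-style file is written in 0-based half-open coordinates: the bond with
#' P1 index p becomes the interval [p-1, p+1) covering its two flanking
#' residues.
#'
#' @param timeCourse a \linkS4class{SiteTimeCourse}.
#' @param protein the substrate \linkS4class{ProteinRecord}.
#' @param path output TSV path.
#' @param bed also write \code{<path>.bed}.
#' @return \code{path}, invisibly.
#' @export
writeSiteTable <- function(timeCourse, protein, path, bed = FALSE) {
  stopifnot(is(timeCourse, "SiteTimeCourse"), is(protein, "ProteinRecord"))
  seqc <- strsplit(proteinSequence(protein), "")[[1]]
  rows <- do.call(rbind, lapply(seq_along(timeCourse@times), function(i) {
    s <- timeCourse@newSites[[i]]
    if (!length(s)) return(NULL)
    data.frame(protein_id = timeCourse@proteinId, enzyme = timeCourse@enzyme,
               p1_index = s, p1_residue = seqc[s], p1prime_residue = seqc[s + 1L],
               first_seen_h = timeCourse@times[i])
  }))
  if (is.null(rows))
    rows <- data.frame(protein_id = character(), enzyme = character(),
                       p1_index = integer(), p1_residue = character(),
                       p1prime_residue = character(), first_seen_h = numeric())
  rows <- rows[order(rows$p1_index), , drop = FALSE]
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (bed && nrow(rows)) {
    bedDf <- data.frame(chrom = rows$protein_id, start = rows$p1_index - 1L,
                        end = rows$p1_index + 1L,
                        name = paste0(rows$p1_residue, rows$p1_index,
                                      "|", rows$p1prime_residue))
    utils::write.table(bedDf, paste0(path, ".bed"), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Plot a cleavage-site map
#'
#' A minimal site-map figure: the protein as a horizontal axis, one row per
#' time point, a tick at every cleavage site known by that time.
#'
#' @param timeCourse a \linkS4class{SiteTimeCourse}.
#' @param protein the substrate \linkS4class{ProteinRecord}.
#' @param ... passed to \code{plot()}.
#' @return invisibly, NULL.
#' @export
plotCleavageMap <- function(timeCourse, protein, ...) {
  L <- length(protein)
  nt <- length(timeCourse@times)
  graphics::plot(NULL, xlim = c(1, L), ylim = c(0.5, nt + 0.5),
                 xlab = "residue (P1 index)", ylab = "", yaxt = "n",
                 main = sprintf("%s on %s", timeCourse@enzyme,
                                timeCourse@proteinId), ...)
  graphics::axis(2, at = seq_len(nt),
                 labels = sprintf("%g h", timeCourse@times), las = 1)
  for (i in seq_len(nt)) {
    s <- timeCourse@cumulativeSites[[i]]
    if (length(s))
      graphics::segments(s, i - 0.35, s, i + 0.35)
  }
  invisible(NULL)
}
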