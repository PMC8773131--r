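---
title: "Profiling cell-envelope proteinase cleavage specificity from casein peptidomics"
author: "CEPspec authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling cell-envelope proteinase cleavage specificity from casein peptidomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CEPspec)
```

## The problem

Cell-envelope proteinases (CEPs) of lactic acid bacteria perform the first
cleavage of milk caseins into oligopeptides, and their cleavage-site
preferences determine which peptides — including bioactive ones — accumulate
in fermented dairy products. A peptidomics experiment incubates a purified
casein with an extracted CEP, samples the hydrolysate along a time course
(typically 0, 8, 24, 30, 48 and 56 h), and identifies the released peptides
by LC-MS/MS. CEPspec turns such identified-peptide lists into a
quantitative specificity profile.

The chain of inference is:

1. **Mapping.** Each identified peptide is located in the substrate by exact
   substring search (`findOccurrences()`, `mapObservations()`). Matching is
   on the unmodified sequence; isoleucine and leucine are distinct letters,
   since the upstream identification reports explicit sequences.
2. **Site inference.** A peptide spanning residues *s..e* evidences the
   cleaved bonds (*s*−1, *s*) and (*e*, *e*+1); bonds at the protein termini
   are not cleavage sites (`inferSites()`). Using the Schechter–Berger
   nomenclature, the bond between residues *p* and *p*+1 is the P1–P1′
   bond: residue *p* occupies subsite P1, residue *p*+1 subsite P1′. A bond
   is counted once, no matter how many peptides or time points evidence it.
3. **Specificity statistics.** For each amino acid *A* and subsite *n*, the
   cleavage probability is
   %P*n*(A) = 100 × (occurrences of *A* cleaved at subsite *n*) /
   (occurrences of *A* in the protein). The mean cleavage probability of a
   subsite is the sum of the twenty %P*n* values divided by 20, and the
   preference coefficient is K*n* = %P*n* / mean(%P*n*) − 1. K*n* > 0 marks
   residues that favour cleavage at that subsite; K*n* = −1 marks residues
   present in the substrate but never observed there.

## Conventions that matter

Several small conventions are load-bearing; published specificity tables
can only be reproduced exactly when all of them are honoured.

**The mean divides by 20, always.** The divisor of the mean cleavage
probability is the alphabet size, not the number of residue types present
in the protein. Residues absent from the substrate (cysteine in β-casein)
have undefined %P and contribute 0 to the sum. We verified this convention
numerically: back-solving mean = %P/(K*n*+1) from every row of published
PrtR1/β-casein tables concentrates tightly on the divide-by-20 mean, and no
other divisor reproduces the printed coefficients. The test suite carries
this back-solve as an independent oracle.

**Rare residues are masked only in reports.** Published tables omit
tryptophan (it occurs once in β-casein), yet the back-solve shows its %P
term is included in the means. `buildSpecificityTable()` therefore always
computes all twenty residues; `formatSpecificityTable(maskBelow = 2)`
reproduces the masked presentation without touching any computed value.

**Rounding.** Percentages are reported at one decimal and K*n* at two
decimals, rounding half away from zero (base R's `round()` rounds half to
even and disagrees on exact ties). Percentages pass through a two-decimal
intermediate: 6/11 = 54.5454…% is reported as 54.6 (54.5454 → 54.55 →
54.6), matching the observable convention of the published tables this
package reproduces. All report rounding is centralized in
`formatPercent()` and `formatKn()`; unrounded values are preserved in the
objects and the JSON reports.

**Coordinates.** Everything is 1-based and inclusive on the mature protein
sequence (signal peptide removed), matching the f(start–end) fragment
notation of casein peptidomics. The optional BED export is the single
0-based, half-open surface, and is labelled as such.

**Ambiguity policy.** Peptides that occur at more than one position are
mapped at every occurrence and flagged; site inference excludes them by
default (`includeAmbiguous = FALSE`) so that repeated subsequences cannot
fabricate sites. Caseins have little internal repetition, so for real
casein data the policy is almost always moot; the flag exists because the
right default for other substrates is not obvious, and silently counting
every occurrence seemed worse than under-counting with a documented switch.
Unmapped peptides are always returned as a table, never dropped.

## Bundled references

The package ships the two substrates in mature numbering:

* `beta_casein` — bovine β-casein, genetic variant A2, 209 residues. The
  variant was chosen because its composition (P = 35, H = 5) matches the
  per-residue occurrence counts in published specificity tables of this
  assay; the A1 variant (P67→H) would give P = 34, H = 6.
* `as1_casein` — bovine αS1-casein, variant B, 199 residues, consistent
  with published fragment coordinates such as f(1–23), f(91–100) and
  f(170–199).

This is fixture provenance by inference from composition and coordinates,
not an assertion about the substrate lot of any particular experiment.

The bioactive-peptide reference (`loadBioactiveTable()`) is a 30-row local
table of casein fragments with previously demonstrated bioactivity (ACE
inhibition, antimicrobial, antioxidant, immunomodulation, DPP-IV
inhibition, anxiolytic), matched at 100% sequence identity only — no
substring or similarity matching — because full-length identity is the
established criterion for claiming a known bioactive peptide. Users can
supply a larger table in the same three-column format.

## The digestion simulator

Because real peptidomics appendices are rarely machine-readable, the
package includes a generative model (`digestionModel()`,
`simulateDataset()`) whose statistical structure is exactly what the
analysis assumes, so that every pipeline stage is testable end to end.

Each peptide bond *p* carries a constant hazard

λ*p* = λ0 · exp(w_P1[r*p*] + w_P1′[r*p*+1]) · b(*p*)

with per-residue log-weights for both subsites and an optional regional
multiplier b. By time *t* a bond is cleaved with probability
1 − exp(−λ*p*·t), independently across bonds and molecules; the fragments
of a molecule are the maximal runs between cleaved bonds and tile the
protein exactly. Each time point digests `nMolecules` fresh molecules
(emulating aliquot sampling, and keeping time points independent for
testing); fragments within the 3–40-residue detectability window are
observed with probability `detectProb` and deduplicated into an observation
table. The model is log-linear in the subsite residue identities, so its
sufficient statistics are the P1/P1′ tallies the pipeline estimates —
parameter recovery (`recoveryExperiment()`) is therefore a meaningful
validation: simulate with known weights, run the full pipeline, and check
the Spearman rank correlation between true weights and estimated K*n*.

**Default calibration.** No kinetic constants are available for this assay,
so defaults are calibrated to the observable scale of the data the
simulator emulates and are then fixed. With the default depth (500
molecules per time point, 0/8/24/30/48/56 h grid, window 3–40, detection
probability 0.8), the baseline hazard λ0 = 5 × 10⁻⁵ per bond per hour
yields on the order of 120 distinct identified peptides from a
preference-free digestion of β-casein — the scale reported for casein
hydrolysates in this assay family — and intermediate distinct-site
coverage. λ0 is an *observable-cleavage* rate: it folds the chemical rate
and the overall inefficiency of MS identification into one constant.
This calibration matters for validation power: the distinct-site statistic
is binary per bond, so if the simulated depth saturates (every bond
eventually observed), %P approaches 100% for every residue and K*n* carries
no rank information; if depth is too shallow, the tallies are all noise.
Defaults are chosen for test power, as the generator's documentation openly
states, not as a claim of kinetic fidelity.

**What the simulator does not emulate.** MS intensities and ionization
bias; exo-peptidase trimming (real hydrolysates show peptide "ladders"
sharing termini, which is why real data yield roughly twice as many
peptides as distinct sites, while the simulator yields about one peptide
per site); phosphorylation and oxidation (the parser supports them; the
generator only emits unmodified sequences); inter-molecular competition or
enzyme saturation (bonds are independent). Passing recovery tests therefore
show that the pipeline correctly inverts data of the assumed structure —
not that real hydrolysates have that structure.

## Problem sizes and numerical choices in the test suite

The suite validates the statistics on the full published PrtR1/β-casein
tally tables (both enzymes, both subsites, every printed cell: %P exact at
one decimal, K*n* within ±0.02), maps all 30 bioactive fragments at their
printed coordinates, and runs the simulator checks at 300–600 molecules per
run — enough for the pooled 3-standard-error frequency comparison and for
rank-correlation recovery above 0.7 at the P1 subsite, while keeping the
whole suite under a minute on one core. Empirical frequency checks pool
bonds sharing a hazard value (their Bernoulli trials are exchangeable)
rather than testing 208 bonds separately, which would face a multiplicity
problem at 3 SE. The chi-square uniformity check for the preference-free
model runs at α = 0.01 with a fixed seed. The P1′ recovery correlation is
reported but only required to be positive: with β-casein's composition, the
P1′ weights land on rarer residues and the correlation is noticeably
noisier at the calibrated depth.

Degenerate inputs are signalled, not zeroed: region fractions of an empty
site set, overlap percentages of an empty side, and specificity tables with
no observed cleavage all raise a typed condition (`cep_undefined`) rather
than returning 0, because a zero would silently masquerade as "measured and
absent".

## Known limitations

* Site inference assumes every peptide terminus reflects a true cleavage
  event; in-source fragmentation or residual chemical hydrolysis would
  inflate the site set. The distinct-site convention limits, but does not
  remove, this effect.
* Published per-residue tallies can disagree with the distinct-site count
  of the same dataset (tallies summing to ~70 against ~63 distinct sites),
  since a printed table and a site map may be derived from slightly
  different peptide lists. The package reports both quantities and does
  not force agreement.
* Bioactive matching is exact identity: a peptide differing by one residue,
  or carrying a modification annotation in the reference, will not match.
* The simulator's independence assumptions make it a validation instrument,
  not a kinetic model of proteolysis.

## A worked example

```{r example, eval = FALSE}
library(CEPspec)
beta <- caseinReferences()$beta_casein

# published tallies -> full specificity table
spec <- specificityFromCountTable(readSubsiteCounts(), beta, "PRA205")
formatSpecificityTable(spec, maskBelow = 2)
subsiteMeans(spec)

# simulate, then recover known preferences end to end
model <- digestionModel(p1Weights = c(M = 2, N = 2, E = -2),
                        nMolecules = 500, seed = 1)
rec <- recoveryExperiment(beta, model)
rec$rhoP1
```
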