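# Shared fixtures and independent oracles for the test suite.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

caseins <- caseinReferences()
betaCasein <- caseins$beta_casein
as1Casein <- caseins$as1_casein

# Naive O(n*m) substring scan: the independent oracle for findOccurrences.
naiveOccurrences <- function(pep, proteinSeq) {
  n <- nchar(proteinSeq); m <- nchar(pep)
  starts <- integer()
  if (m <= n)
    for (s in seq_len(n - m + 1L))
      if (substr(proteinSeq, s, s + m - 1L) == pep) starts <- c(starts, s)
  data.frame(start = starts, end = starts + m - 1L)
}

randomProtein <- function(len, id = "rand") {
  proteinRecord(id, paste(sample(AA20, len, replace = TRUE), collapse = ""))
}

randomPeptide <- function(len) paste(sample(AA20, len, replace = TRUE),
                                     collapse = "")

# Published per-residue specificity statistics for the two PrtR1 enzymes on
# beta-casein (48 h): cleaved-bond tally, %P at one decimal, Kn at two
# decimals, for each enzyme and subsite. Used as the regression surface for
# the %P/Kn computation.
table1Printed <- local({
  aa <- c("A","G","V","L","I","M","T","S","Q","N","P","R","K","H","E","D","F","Y")
  build <- function(enzyme, subsite, cleaved, pct, kn)
    data.frame(enzyme = enzyme, subsite = subsite, amino_acid = aa,
               cleaved = cleaved, pct = pct, kn = kn)
  rbind(
    build("PRA205", "P1",
          c(2,1,3,10,1,5,2,8,10,4,8,2,5,1,3,1,2,1),
          c(40.0,20.0,15.8,45.5,10.0,83.3,22.2,50.0,50.0,80.0,22.9,50.0,45.5,20.0,15.8,25.0,22.2,25.0),
          c(0.08,-0.46,-0.58,0.22,-0.73,1.24,-0.40,0.35,0.35,1.15,-0.38,0.35,0.22,-0.46,-0.58,-0.33,-0.40,-0.33)),
    build("PRA205", "P1prime",
          c(4,3,9,10,4,2,2,7,2,2,4,1,4,3,2,4,4,2),
          c(80.0,60.0,47.4,45.5,40.0,33.3,22.2,43.8,10.0,40.0,11.4,25.0,36.4,60.0,10.5,100.0,44.4,50.0),
          c(0.86,0.40,0.10,0.06,-0.07,-0.22,-0.48,0.02,-0.77,-0.07,-0.73,-0.42,-0.15,0.40,-0.76,1.33,0.03,0.16)),
    build("2006", "P1",
          c(3,2,3,9,1,4,1,7,10,3,5,2,6,1,5,0,2,1),
          c(60.0,40.0,15.8,40.9,10.0,66.7,11.1,43.8,50.0,60.0,14.3,50.0,54.6,20.0,26.3,0.0,22.2,25.0),
          c(0.69,0.13,-0.56,0.15,-0.72,0.88,-0.69,0.23,0.41,0.69,-0.60,0.41,0.54,-0.44,-0.26,-1.00,-0.37,-0.30)),
    build("2006", "P1prime",
          c(5,3,8,8,3,2,1,7,3,1,4,1,5,3,2,4,3,2),
          c(100.0,60.0,42.1,36.4,30.0,33.3,11.1,43.8,15.0,20.0,11.4,25.0,45.5,60.0,10.5,100.0,33.3,50.0),
          c(1.42,0.45,0.02,-0.12,-0.27,-0.19,-0.73,0.06,-0.64,-0.52,-0.72,-0.40,0.10,0.45,-0.75,1.42,-0.19,0.21)))
})

# Published fragment coordinates of the bioactive peptides (from the bundled
# reference table's parent column), parsed into start/end for coordinate
# fidelity checks.
bioactiveCoordinates <- local({
  bt <- loadBioactiveTable()
  m <- regmatches(bt$parent, regexec("^(\\w+):f\\((\\d+)-(\\d+)\\)$", bt$parent))
  data.frame(sequence = bt$sequence,
             protein_id = vapply(m, `[`, character(1), 2),
             start = as.integer(vapply(m, `[`, character(1), 3)),
             end = as.integer(vapply(m, `[`, character(1), 4)),
             stringsAsFactors = FALSE)
})

# Observation table builder for synthetic inputs.
makeObservations <- function(sequences, time_h = 48, enzyme = "E1",
                             protein_id = "beta_casein", modifications = "") {
  if (length(sequences) == 0L)
    return(data.frame(sequence = character(), modifications = character(),
                      time_h = numeric(), enzyme = character(),
                      protein_id = character(), stringsAsFactors = FALSE))
  data.frame(sequence = sequences, modifications = modifications,
             time_h = time_h, enzyme = enzyme, protein_id = protein_id,
             stringsAsFactors = FALSE)
}

# Pooled empirical-vs-closed-form comparison of per-bond cleavage
# frequencies: bonds sharing a hazard value are pooled (their Bernoulli
# trials are iid), and each pooled frequency must sit within 3 standard
# errors of 1 - exp(-lambda t).
checkCleavageFrequencies <- function(protein, model, t, n) {
  lam <- bondHazard(protein, model)
  L <- length(protein)
  hits <- integer(L - 1L)
  for (i in seq_len(n)) {
    fr <- simulateMolecule(protein, model, t)
    if (nrow(fr) > 1) {
      cutAt <- fr$end[-nrow(fr)]
      hits[cutAt] <- hits[cutAt] + 1L
    }
  }
  ok <- TRUE
  for (lamVal in unique(lam)) {
    bonds <- which(lam == lamVal)
    pTrue <- -expm1(-lamVal * t)
    nTrials <- n * length(bonds)
    se <- sqrt(pTrue * (1 - pTrue) / nTrials)
    pHat <- sum(hits[bonds]) / nTrials
    if (se > 0 && abs(pHat - pTrue) > 3 * se) ok <- FALSE
  }
  ok
}
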