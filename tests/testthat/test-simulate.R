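test_that("bond hazards follow the log-linear model", {
  prot <- betaCasein
  flat <- digestionModel(baseHazard = 0.05)
  h <- bondHazard(prot, flat)
  expect_length(h, 208)
  expect_true(all(h == 0.05))

  m <- digestionModel(baseHazard = 0.05, p1Weights = c(M = 1))
  hm <- bondHazard(prot, m)
  seqc <- strsplit(proteinSequence(prot), "")[[1]]
  isM <- seqc[seq_len(208)] == "M"
  expect_equal(unname(hm[isM]), rep(0.05 * exp(1), sum(isM)))
  expect_equal(unname(hm[!isM]), rep(0.05, sum(!isM)))

  # brute-force per-bond recomputation oracle
  full <- digestionModel(baseHazard = 0.03,
                         p1Weights = c(M = 2, N = 1, E = -2),
                         p1primeWeights = c(A = 1.5, D = -1),
                         regionBias = data.frame(lo = 150, hi = 208,
                                                 multiplier = 3))
  got <- bondHazard(prot, full)
  for (p in seq_len(208)) {
    lam <- 0.03 *
      exp(full@p1Weights[[seqc[p]]] + full@p1primeWeights[[seqc[p + 1]]])
    if (p >= 150) lam <- lam * 3
    expect_equal(unname(got[p]), lam)
  }
})

test_that("single-molecule digestion tiles the protein exactly", {
  model <- digestionModel(baseHazard = 0.05, seed = 1)
  set.seed(1)
  frag0 <- simulateMolecule(betaCasein, model, 0)
  expect_identical(frag0, data.frame(start = 1L, end = 209L))

  huge <- digestionModel(baseHazard = 1e6)
  set.seed(1)
  fragAll <- simulateMolecule(betaCasein, huge, 1)
  expect_identical(nrow(fragAll), 209L)
  expect_true(all(fragAll$end - fragAll$start == 0L))

  set.seed(42)
  for (rep in 1:20) {
    fr <- simulateMolecule(betaCasein, model, sample(c(8, 24, 56), 1))
    expect_identical(fr$start[1], 1L)
    expect_identical(fr$end[nrow(fr)], 209L)
    if (nrow(fr) > 1)
      expect_identical(fr$start[-1], fr$end[-nrow(fr)] + 1L)
    expect_identical(sum(fr$end - fr$start + 1L), 209L)
  }
})

test_that("empirical per-bond cleavage frequency matches 1 - exp(-lambda t)", {
  model <- digestionModel(baseHazard = 0.02, p1Weights = c(M = 1, Q = -1))
  set.seed(123)
  expect_true(checkCleavageFrequencies(betaCasein, model, t = 24, n = 600))
})

test_that("simulated datasets are reproducible from the seed", {
  model <- digestionModel(nMolecules = 50, seed = 7)
  a <- simulateDataset(betaCasein, model, times = c(0, 8, 24))
  b <- simulateDataset(betaCasein, model, times = c(0, 8, 24))
  expect_identical(a, b)
  c <- simulateDataset(betaCasein, model, times = c(0, 8, 24), seed = 8)
  expect_false(identical(a, c))

  noSeed <- digestionModel(nMolecules = 50)
  expect_error(simulateDataset(betaCasein, noSeed, times = 0:1), "seed")

  # at t = 0 the only fragment is the intact protein, outside the 3-40
  # residue detectability window
  expect_identical(nrow(a[a$time_h == 0, ]), 0L)
})

test_that("with flat weights, cleavage events are uniform across bonds", {
  model <- digestionModel(baseHazard = 0.02)
  set.seed(31)
  counts <- integer(208)
  for (i in 1:600) {
    fr <- simulateMolecule(betaCasein, model, 24)
    if (nrow(fr) > 1) {
      cutAt <- fr$end[-nrow(fr)]
      counts[cutAt] <- counts[cutAt] + 1L
    }
  }
  gof <- suppressWarnings(chisq.test(counts))
  expect_gt(gof$p.value, 0.01)
})

test_that("inferred site sets grow monotonically along the time course", {
  model <- digestionModel(nMolecules = 100, seed = 5)
  rec <- recoveryExperiment(betaCasein, model, times = c(0, 8, 24, 48))
  cum <- rec$timeCourse@cumulativeSites
  for (i in seq_along(cum)[-1])
    expect_true(all(cum[[i - 1]] %in% cum[[i]]))
})

test_that("strong subsite preferences are recovered as top-ranked Kn values", {
  model <- digestionModel(p1Weights = c(M = 2, N = 2, E = -3),
                          nMolecules = 500, seed = 101)
  rec <- recoveryExperiment(betaCasein, model)
  vals <- specificityValues(rec$specificity)
  kn <- setNames(vals$Kn_P1, vals$amino_acid)
  kn <- kn[!is.na(kn)]
  top3 <- names(sort(kn, decreasing = TRUE))[1:3]
  expect_true(all(c("M", "N") %in% top3))
  expect_lt(kn[["E"]], 0)
})

test_that("rank correlation between true P1 weights and estimated Kn exceeds 0.7", {
  model <- digestionModel(p1Weights = c(M = 2, N = 2, K = 2,
                                        E = -2, P = -2, V = -2),
                          p1primeWeights = c(A = 2, G = 2,
                                             Q = -2, T = -2),
                          nMolecules = 500, seed = 202)
  rec <- recoveryExperiment(betaCasein, model)
  expect_gt(rec$rhoP1, 0.7)
  expect_gt(rec$rhoP1prime, 0)
})

test_that("a preference-free digestion produces no spurious strong preference for M", {
  # per-residue null envelope: Kn(M, P1) across independent preference-free
  # simulations bounds what noise alone produces; a run with an injected M
  # preference must exceed that envelope
  knM <- function(model) {
    rec <- recoveryExperiment(betaCasein, model, times = c(0, 24, 48))
    vals <- specificityValues(rec$specificity)
    vals$Kn_P1[vals$amino_acid == "M"]
  }
  nullKnM <- vapply(1:3, function(s)
    knM(digestionModel(nMolecules = 300, seed = 300 + s)), numeric(1))
  strongKnM <- knM(digestionModel(p1Weights = c(M = 3),
                                  nMolecules = 300, seed = 310))
  expect_gt(strongKnM, max(nullKnM))
})
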