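test_that("inferSites derives bonds from peptide termini, excluding protein ends", {
  # f(1-23) on the 199-aa substrate: only the C-terminal boundary is internal
  expect_identical(inferSites(data.frame(start = 1L, end = 23L,
                                         ambiguous = FALSE), as1Casein),
                   23L)
  expect_identical(inferSites(data.frame(start = 15L, end = 22L,
                                         ambiguous = FALSE), as1Casein),
                   c(14L, 22L))
  expect_identical(inferSites(data.frame(start = 1L, end = 199L,
                                         ambiguous = FALSE), as1Casein),
                   integer())
  expect_identical(inferSites(data.frame(start = integer(), end = integer(),
                                         ambiguous = logical()), as1Casein),
                   integer())
})

test_that("sites collapse to distinct bonds and never touch termini", {
  set.seed(3)
  for (rep in 1:10) {
    prot <- randomProtein(50)
    n <- 20
    starts <- sample(1:45, n, replace = TRUE)
    ends <- pmin(50L, starts + sample(2:8, n, replace = TRUE))
    sites <- inferSites(data.frame(start = starts, end = ends,
                                   ambiguous = FALSE), prot)
    expect_identical(sites, sort(unique(sites)))
    expect_true(all(sites >= 1 & sites <= 49))
    # idempotence: re-running on the duplicated input adds nothing
    again <- inferSites(data.frame(start = rep(starts, 2), end = rep(ends, 2),
                                   ambiguous = FALSE), prot)
    expect_identical(again, sites)
  }
})

test_that("ambiguous mappings are excluded by default and included on request", {
  prot <- proteinRecord("rep", "KAVKAVPQ")
  mapped <- mapObservations(makeObservations("KAV", protein_id = "rep"),
                            list(rep = prot))$mapped
  expect_identical(inferSites(mapped, prot), integer())
  expect_identical(inferSites(mapped, prot, includeAmbiguous = TRUE),
                   c(3L, 6L))
})

test_that("time courses accumulate monotonically and ignore input order", {
  obs <- rbind(
    makeObservations("FQSEEQQQ", time_h = 8),      # f(33-40): sites 32, 40
    makeObservations("SQSKVLPVPQ", time_h = 24))   # f(166-175): 165, 175
  mapped <- mapObservations(obs, caseins)$mapped
  tc <- buildTimeCourse(mapped, betaCasein, enzyme = "E1")
  expect_identical(timePoints(tc), c(8, 24))
  expect_identical(cumulativeSites(tc, 8), c(32L, 40L))
  expect_true(all(cumulativeSites(tc, 8) %in% cumulativeSites(tc, 24)))

  set.seed(99)
  for (rep in 1:5) {
    prot <- randomProtein(40, id = "p")
    n <- 12
    starts <- sample(1:35, n, replace = TRUE)
    ends <- pmin(40L, starts + sample(1:5, n, replace = TRUE))
    mp <- data.frame(peptide = "x", protein_id = "p", start = starts,
                     end = ends, ambiguous = FALSE,
                     time_h = sample(c(8, 24, 48), n, replace = TRUE),
                     enzyme = "E1")
    tc1 <- buildTimeCourse(mp, prot)
    tc2 <- buildTimeCourse(mp[sample(n), ], prot)
    expect_identical(tc1@cumulativeSites, tc2@cumulativeSites)
    cum <- tc1@cumulativeSites
    for (i in seq_along(cum)[-1])
      expect_true(all(cum[[i - 1]] %in% cum[[i]]))
    # single-time union equals one-shot inference on everything
    expect_identical(cum[[length(cum)]], inferSites(mp, prot))
  }
})

test_that("regionFraction computes regional percentages and partitions sum to 100", {
  expect_equal(regionFraction(c(5L, 100L, 200L), 161, 209), 100 / 3)
  expect_equal(regionFraction(c(5L, 100L, 200L), 1, 209), 100)
  expect_error(regionFraction(integer(), 1, 10), class = "cep_undefined")

  set.seed(5)
  for (rep in 1:10) {
    sites <- sample(1:208, sample(5:60, 1))
    cuts <- sort(sample(1:207, 3))
    lo <- c(1, cuts + 1); hi <- c(cuts, 208)
    total <- sum(mapply(function(l, h) regionFraction(sites, l, h), lo, hi))
    expect_equal(total, 100)
  }
})

test_that("bondCoverage matches the published site-count percentages", {
  expect_equal(formatPercent(bondCoverage(seq_len(63), betaCasein)), 30.3)
  expect_equal(formatPercent(bondCoverage(seq_len(66), betaCasein)), 31.7)
  expect_equal(bondCoverage(integer(), betaCasein), 0)
})

test_that("siteOverlap reproduces the published inter-enzyme shared-site percentages", {
  a <- seq_len(63)                     # 54 shared
  b <- c(seq_len(54), 100:111)         # |B| = 66
  ov <- siteOverlap(a, b)
  expect_identical(ov$nA, 63L)
  expect_identical(ov$nB, 66L)
  expect_identical(ov$nShared, 54L)
  expect_equal(formatPercent(ov$pctA), 85.7)
  expect_equal(formatPercent(ov$pctB), 81.8)

  same <- siteOverlap(1:10, 1:10)
  expect_equal(c(same$pctA, same$pctB), c(100, 100))
  disj <- siteOverlap(1:5, 6:10)
  expect_equal(c(disj$pctA, disj$pctB), c(0, 0))
  expect_true(is.na(siteOverlap(integer(), 1:3)$pctA))
})

test_that("peptideOverlap satisfies inclusion-exclusion", {
  ov <- peptideOverlap(c("X", "Y", "Z"), c("Y", "Z", "W"))
  expect_identical(sort(ov$shared), c("Y", "Z"))
  expect_equal(ov$pctSharedOfUnion, 50)
  expect_equal(peptideOverlap("A", "A")$pctSharedOfUnion, 100)
  expect_true(is.na(peptideOverlap(character(), character())$pctSharedOfUnion))

  set.seed(21)
  for (rep in 1:10) {
    a <- unique(replicate(15, randomPeptide(3)))
    b <- unique(replicate(15, randomPeptide(3)))
    ov <- peptideOverlap(a, b)
    expect_identical(length(union(a, b)),
                     length(ov$shared) + length(ov$uniqueA) + length(ov$uniqueB))
    expect_identical(length(union(a, b)),
                     length(a) + length(b) - length(ov$shared))
  }
})

test_that("site tables record subsite residues and first-seen times", {
  mapped <- mapObservations(makeObservations("VLNENLLR", time_h = 24,
                                             protein_id = "as1_casein"),
                            caseins)$mapped
  tc <- buildTimeCourse(mapped, as1Casein, enzyme = "E1")
  path <- tempfile(fileext = ".tsv")
  writeSiteTable(tc, as1Casein, path, bed = TRUE)
  tab <- read.delim(path)
  expect_identical(tab$p1_index, c(14L, 22L))
  expect_identical(tab$p1_residue, c("E", "R"))       # E14|V15, R22|F23
  expect_identical(tab$p1prime_residue, c("V", "F"))
  expect_identical(tab$first_seen_h, c(24L, 24L))
  bed <- read.delim(paste0(path, ".bed"), header = FALSE)
  expect_identical(bed$V2, c(13L, 21L))               # 0-based half-open
  expect_identical(bed$V3, c(15L, 23L))
})
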