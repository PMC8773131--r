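test_that("tallySubsites counts P1 and P1' residues of each site", {
  tal <- tallySubsites(1L, proteinRecord("toy", "MKV"))
  expect_identical(tal$cleaved_P1[tal$amino_acid == "M"], 1L)
  expect_identical(tal$cleaved_P1prime[tal$amino_acid == "K"], 1L)
  expect_identical(sum(tal$cleaved_P1), 1L)

  empty <- tallySubsites(integer(), betaCasein)
  expect_true(all(empty$cleaved_P1 == 0L & empty$cleaved_P1prime == 0L))

  set.seed(13)
  for (rep in 1:10) {
    prot <- randomProtein(60)
    sites <- sample(1:59, sample(1:30, 1))
    tal <- tallySubsites(sites, prot)
    expect_identical(sum(tal$cleaved_P1), length(unique(sites)))
    expect_identical(sum(tal$cleaved_P1prime), length(unique(sites)))
    expect_true(all(tal$cleaved_P1 <= tal$total))
    expect_true(all(tal$cleaved_P1prime <= tal$total))
  }
})

test_that("cleavageProbability matches published percentages and rejects bad counts", {
  expect_equal(formatPercent(cleavageProbability(5, 6)), 83.3)
  expect_equal(cleavageProbability(4, 4), 100)
  expect_equal(cleavageProbability(0, 4), 0)
  expect_true(is.na(cleavageProbability(0, 0)))
  expect_error(cleavageProbability(5, 4), "exceeds")
})

test_that("mean cleavage probability uses the fixed divisor 20", {
  expect_equal(meanCleavageProbability(rep(50, 20)), 50)
  expect_equal(meanCleavageProbability(c(rep(0, 19), 100)), 5)
  expect_equal(meanCleavageProbability(c(rep(50, 19), NA)), 47.5)
  expect_error(meanCleavageProbability(rep(50, 19)), "20")
})

test_that("the subsite mean is confirmed by back-solving printed %P/Kn pairs", {
  # Independent oracle: for every printed row, %P / (Kn + 1) estimates the
  # subsite mean the authors used; the estimates must concentrate on the
  # fixed-divisor-20 mean computed by the package.
  counts <- readSubsiteCounts()
  for (enz in c("PRA205", "2006")) {
    spec <- specificityFromCountTable(counts, betaCasein, enz)
    means <- subsiteMeans(spec)
    for (sub in c("P1", "P1prime")) {
      printed <- table1Printed[table1Printed$enzyme == enz &
                               table1Printed$subsite == sub, ]
      ok <- printed$kn > -1                 # back-solve undefined at Kn = -1
      backSolved <- printed$pct[ok] / (printed$kn[ok] + 1)
      expect_lt(abs(median(backSolved) - means[[sub]]), 0.5)
    }
  }
})

test_that("Kn follows the preference-coefficient formula", {
  expect_equal(formatKn(knCoefficient(83.3, 37.156)), 1.24)
  expect_equal(knCoefficient(0, 40), -1)
  expect_equal(knCoefficient(40, 40), 0)
  expect_error(knCoefficient(50, 0), class = "cep_undefined")
})

test_that("published per-residue tallies reproduce every printed %P and Kn cell", {
  counts <- readSubsiteCounts()
  for (enz in c("PRA205", "2006")) {
    spec <- specificityFromCountTable(counts, betaCasein, enz)
    vals <- specificityValues(spec)
    for (sub in c("P1", "P1prime")) {
      printed <- table1Printed[table1Printed$enzyme == enz &
                               table1Printed$subsite == sub, ]
      pctCol <- if (sub == "P1") "pctP1" else "pctP1prime"
      knCol <- if (sub == "P1") "Kn_P1" else "Kn_P1prime"
      idx <- match(printed$amino_acid, vals$amino_acid)
      expect_equal(formatPercent(vals[[pctCol]][idx]), printed$pct,
                   info = paste(enz, sub, "%P"))
      expect_true(all(abs(formatKn(vals[[knCol]][idx]) - printed$kn)
                      <= 0.02 + 1e-9),
                  info = paste(enz, sub, "Kn"))
    }
  }
})

test_that("Kn sign tracks %P against the mean, and Kn >= -1 where defined", {
  counts <- readSubsiteCounts()
  for (enz in c("PRA205", "2006")) {
    spec <- specificityFromCountTable(counts, betaCasein, enz)
    vals <- specificityValues(spec)
    means <- subsiteMeans(spec)
    ok <- !is.na(vals$Kn_P1)
    expect_true(all(vals$Kn_P1[ok] >= -1))
    expect_identical(vals$Kn_P1[ok] > 0, vals$pctP1[ok] > means[["P1"]])
    expect_identical(vals$Kn_P1[ok] == -1, vals$pctP1[ok] == 0)
  }
})

test_that("Kn is monotone in %P at fixed mean; mean is label-permutation invariant", {
  pcts <- sort(runif(10, 0, 100))
  kns <- knCoefficient(pcts, 40)
  expect_identical(order(kns), seq_along(kns))

  set.seed(17)
  x <- runif(20, 0, 100)
  expect_equal(meanCleavageProbability(x),
               meanCleavageProbability(sample(x)))
})

test_that("report masking hides rows without changing any computed value", {
  spec <- specificityFromCountTable(readSubsiteCounts(), betaCasein, "PRA205")
  full <- formatSpecificityTable(spec, maskBelow = 0)
  masked <- formatSpecificityTable(spec, maskBelow = 2)
  expect_false(any(c("W", "C") %in% masked$amino_acid))
  expect_identical(masked,
                   full[full$total >= 2, , drop = FALSE])
  # and the underlying table still carries W and C
  expect_true(all(c("W", "C") %in% specificityValues(spec)$amino_acid))
})

test_that("a site-free table is an undefined-value signal, not zeros", {
  expect_error(buildSpecificityTable(integer(), betaCasein),
               class = "cep_undefined")
})

test_that("site-derived and count-derived tables agree on synthetic sites", {
  set.seed(29)
  sites <- sort(sample(1:208, 40))
  spec <- buildSpecificityTable(sites, betaCasein, enzyme = "E1")
  tal <- tallySubsites(sites, betaCasein)
  spec2 <- specificityFromCounts(tal, proteinId = "beta_casein",
                                 enzyme = "E1")
  expect_equal(specificityValues(spec), specificityValues(spec2))
  expect_equal(subsiteMeans(spec), subsiteMeans(spec2))
})
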