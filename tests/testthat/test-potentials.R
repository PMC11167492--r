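test_that("a uniform table yields equal scores everywhere", {
  cn <- contactCounts(countContacts(StructMotif:::emptyContactsDf()))
  cn[, , , 5, 1] <- 3
  tab <- new("ContactTable", counts = cn, binning = "interval",
             binWidth = 1, maxRadius = 30)
  pot <- buildPotential(tab, familyConfig(binning = "bins", radius = 30))
  s5 <- potentialScores(pot)[, , , 5]
  expect_lt(diff(range(s5)), 1e-12)
  expect_true(all(is.finite(potentialScores(pot))))
})

test_that("an enriched triple gets the most favorable (minimum) score", {
  cn <- contactCounts(countContacts(StructMotif:::emptyContactsDf()))
  cn[, , , 5, 1] <- 2
  cn[3, 7, 11, 5, 1] <- 20
  tab <- new("ContactTable", counts = cn, binning = "interval",
             binWidth = 1, maxRadius = 30)
  pot <- buildPotential(tab, familyConfig(binning = "bins", radius = 30))
  s5 <- potentialScores(pot)[, , , 5]
  expect_equal(which(s5 == min(s5)), which(s5 < s5[1, 1, 1]))
  expect_equal(arrayInd(which.min(s5), dim(s5))[1, ], c(3L, 7L, 11L))
})

test_that("a cumulative potential equals the summed-interval construction", {
  for (seed in c(11, 12, 13)) {
    tab <- randomContactTable(seed)
    potAcc <- buildPotential(tab, familyConfig(binning = "acc", radius = 22))
    # oracle: cumulate the interval counts by hand, then score that table
    cn <- contactCounts(tab)
    cum <- aperm(apply(cn, c(1, 2, 3, 5), cumsum), c(2, 3, 4, 1, 5))
    dimnames(cum) <- dimnames(cn)
    manual <- new("ContactTable", counts = cum, binning = "interval",
                  binWidth = 1, maxRadius = 30)
    potMan <- buildPotential(manual,
                             familyConfig(binning = "bins", radius = 22))
    expect_equal(potentialScores(potAcc)[, , , 22],
                 potentialScores(potMan)[, , , 22], tolerance = 1e-12)
  }
})

test_that("taylor smoothing is the identity on fully observed profiles", {
  tab <- randomContactTable(14)
  cn <- contactCounts(tab)
  cn[2, 2, 2, , 1] <- 7          # a dense profile
  dense <- new("ContactTable", counts = cn, binning = "interval",
               binWidth = 1, maxRadius = 30)
  sm <- taylorSmooth(dense)
  expect_equal(contactCounts(sm)[2, 2, 2, , 1], cn[2, 2, 2, , 1],
               ignore_attr = TRUE)
})

test_that("a hole between equal observations is imputed to that value", {
  cn <- contactCounts(countContacts(StructMotif:::emptyContactsDf()))
  cn[1, 1, 1, c(4, 6), 1] <- 9
  tab <- new("ContactTable", counts = cn, binning = "interval",
             binWidth = 1, maxRadius = 30)
  sm <- taylorSmooth(tab)
  expect_equal(contactCounts(sm)[1, 1, 1, 5, 1], 9, tolerance = 1e-9)
  expect_equal(contactCounts(sm)[1, 1, 1, 4, 1], 9)  # observed untouched
})

test_that("a planted quadratic log-count profile is recovered in its hole", {
  cn <- contactCounts(countContacts(StructMotif:::emptyContactsDf()))
  bins <- 1:10
  prof <- exp(2 + 0.5 * bins - 0.03 * bins^2)
  cn[1, 1, 1, bins, 1] <- prof
  cn[1, 1, 1, 5, 1] <- 0
  tab <- new("ContactTable", counts = cn, binning = "interval",
             binWidth = 1, maxRadius = 30)
  sm <- taylorSmooth(tab)
  expect_equal(contactCounts(sm)[1, 1, 1, 5, 1], prof[5],
               tolerance = 1e-6)
})

test_that("the Z transform follows the substitution statistics", {
  cn <- contactCounts(countContacts(StructMotif:::emptyContactsDf()))
  cn[, 1, 1, 1, 1] <- 1
  cn[4, 1, 1, 1, 1] <- 50
  # a uniform background elsewhere keeps the amino-acid marginal from
  # cancelling the cell counts (which would flatten the scores)
  cn[, 2, 2, 2, 1] <- 100
  tab <- new("ContactTable", counts = cn, binning = "interval",
             binWidth = 1, maxRadius = 30)
  pot <- buildPotential(tab, familyConfig(binning = "bins", radius = 30))
  S <- potentialScores(pot)[, 1, 1, 1]
  Z <- pot@zscores[, 1, 1, 1]
  mu <- mean(S); sdv <- sqrt(mean((S - mu)^2))
  expect_gt(sdv, 0.01)
  expect_lt(Z[4], min(Z[-4]))   # the enriched amino acid is most favorable
  expect_equal(Z, (S - mu) / sdv, ignore_attr = TRUE)
  expect_equal(mean(Z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(Z^2)), 1, tolerance = 1e-12)
  # hand-checkable 20-vector: 19 scores equal, one different
  v <- c(0, rep(1, 19))
  zv <- (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  expect_equal(zv[1], (0 - 0.95) / sqrt(mean((v - 0.95)^2)))
})

test_that("equal substitution scores give Z = 0", {
  cn <- contactCounts(countContacts(StructMotif:::emptyContactsDf()))
  cn[, 2, 3, 4, 1] <- 6
  tab <- new("ContactTable", counts = cn, binning = "interval",
             binWidth = 1, maxRadius = 30)
  pot <- buildPotential(tab, familyConfig(binning = "bins", radius = 30))
  expect_equal(unname(pot@zscores[, 2, 3, 4]), rep(0, 20))
  expect_equal(zscoreContact(pot, "C", "CA", 3, 4), 0)
})

test_that("complex scores are additive and empty contacts score zero", {
  fx <- closedLoopFixture()
  empty <- fx$contacts[0, ]
  expect_equal(scoreComplex(fx$potential, empty),
               list(ES3DC = 0, ZES3DC = 0))
  one <- fx$contacts[1, ]
  rest <- fx$contacts[-1, ]
  all <- scoreComplex(fx$potential, fx$contacts)
  expect_equal(all$ES3DC, scoreComplex(fx$potential, one)$ES3DC +
                 scoreComplex(fx$potential, rest)$ES3DC)
  expect_equal(all$ZES3DC, scoreComplex(fx$potential, one)$ZES3DC +
                 scoreComplex(fx$potential, rest)$ZES3DC)
  expect_true(all(is.finite(unlist(all))))
})

test_that("redundancy filtering keeps one of two identical TFs", {
  tab <- randomContactTable(15)
  fr <- filterRedundancy(list(A = tab, B = tab), "family")
  expect_equal(fr$kept, "A")
  # fully disjoint TFs are all kept
  t1 <- randomContactTable(16, density = 30)
  cn <- contactCounts(countContacts(StructMotif:::emptyContactsDf()))
  cn[20, 16, 48, 30, 1] <- 1
  t2 <- new("ContactTable", counts = cn, binning = "interval",
            binWidth = 1, maxRadius = 30)
  expect_setequal(filterRedundancy(list(A = t1, B = t2), "family")$kept,
                  c("A", "B"))
})

test_that("greedy chain removal follows the worked trace", {
  mk <- function(cells) {
    cn <- contactCounts(countContacts(StructMotif:::emptyContactsDf()))
    cn[cbind(1, 1, 1, cells, 1)] <- 1
    new("ContactTable", counts = cn, binning = "interval", binWidth = 1,
        maxRadius = 30)
  }
  # A~B = 15/20 = 0.75, A~C = B~C = 2/20 = 0.1;
  # equal totals so greedy order = id order
  A <- mk(1:20); B <- mk(6:25)
  Ccn <- contactCounts(mk(c(19, 20)))
  Ccn[cbind(2, 1, 1, 1:18, 1)] <- 1
  C <- new("ContactTable", counts = Ccn, binning = "interval",
           binWidth = 1, maxRadius = 30)
  fr <- filterRedundancy(list(A = A, B = B, C = C), "family",
                         cutoff = 0.70)
  expect_equal(fr$kept, c("A", "C"))
  # idempotent
  fr2 <- filterRedundancy(fr$tables, "family", cutoff = 0.70)
  expect_equal(fr2$kept, fr$kept)
})

test_that("the general-mode default cutoff is stricter", {
  mk2 <- function(cells) {
    cn <- contactCounts(countContacts(StructMotif:::emptyContactsDf()))
    cn[cbind(1, 1, 1, cells, 1)] <- 1
    new("ContactTable", counts = cn, binning = "interval", binWidth = 1,
        maxRadius = 30)
  }
  A <- mk2(1:20); B <- mk2(11:30)   # 50% identical
  expect_equal(filterRedundancy(list(A = A, B = B), "family")$kept,
               c("A", "B"))
  expect_equal(filterRedundancy(list(A = A, B = B), "general")$kept, "A")
})

test_that("shipped family defaults mirror the parameter table", {
  df <- familyDefaults()
  expect_true(all(c("GLOBAL", "Homeodomain", "bZIP") %in% df$family))
  expect_true(all(df$radius %in% c(15, 22, 30)))
  expect_true(all(df$msaThreshold >= 0.7 & df$msaThreshold <= 1))
  hd <- familyDefaults("Homeodomain")
  expect_equal(hd$radius, 22)
  expect_equal(hd$binning, "acc")
  expect_false(hd$taylor)
  # unknown family falls back to the general row
  expect_equal(familyDefaults("NoSuchFamily")$family, "GLOBAL")
})
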