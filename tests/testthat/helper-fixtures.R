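# Shared fixtures, built once per test run. All geometry comes from the
# package's own synthetic generators.

fixtureEnv <- new.env()

memoFixture <- function(name, build) {
  if (is.null(fixtureEnv[[name]])) fixtureEnv[[name]] <- build()
  fixtureEnv[[name]]
}

# 12-bp duplex, one residue planted 10 A beyond the last step
singleContactComplex <- function() {
  memoFixture("single", function() {
    txt <- makeComplex(list(seed = 1, dnaLength = 12,
      plantedContacts = data.frame(step = 11, distance = 10,
                                   side = "axial")))
    parseComplex(txt, sourceId = "single")
  })
}

# closed-loop fixture: 8-bp duplex whose every step is contacted
closedLoopFixture <- function() {
  memoFixture("loop", function() {
    cons <- "ACGTAGGC"
    pc <- data.frame(step = 1:6, distance = c(4.3, 4.5, 4.2, 4.6, 4.4, 4.1),
                     side = "radial",
                     aa = c("R", "K", "N", "Q", "S", "E"))
    x <- parseComplex(makeComplex(list(seed = 4, dnaLength = 8,
                                       dnaSeq = cons,
                                       plantedContacts = pc)),
                      sourceId = "loop")
    cc <- extractContacts(x, maxRadius = 30)
    tab <- plantedPreferenceTable(cc, cons, enrichment = 5)
    pot <- buildPotential(tab, familyConfig(binning = "bins", radius = 30))
    list(consensus = cons, complex = x, contacts = cc, table = tab,
         potential = pot)
  })
}

# random interval contact table (sparse, seeded)
randomContactTable <- function(seed, density = 300, maxBin = 30) {
  withr::with_seed(seed, {
    cn <- contactCounts(countContacts(StructMotif:::emptyContactsDf()))
    idx <- cbind(sample(20, density, TRUE), sample(16, density, TRUE),
                 sample(48, density, TRUE), sample(maxBin, density, TRUE),
                 1L)
    for (r in seq_len(density))
      cn[idx[r, 1], idx[r, 2], idx[r, 3], idx[r, 4], idx[r, 5]] <-
        cn[idx[r, 1], idx[r, 2], idx[r, 3], idx[r, 4], idx[r, 5]] +
        sample(5, 1)
    new("ContactTable", counts = cn, binning = "interval", binWidth = 1,
        maxRadius = maxBin)
  })
}

# small motif database with an embedded sharp motif
sharpMotif <- function(width = 8, seed = 21) {
  withr::with_seed(seed, {
    m <- matrix(0.02, nrow = 4, ncol = width)
    picks <- sample(4, width, TRUE)
    for (j in seq_len(width)) m[picks[j], j] <- 0.94
    pwMotif(m, id = "planted")
  })
}

expect_contacts_equal <- function(a, b) {
  key <- function(d) paste(d$residue, d$step, round(d$distance, 9))
  expect_setequal(key(a), key(b))
}
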