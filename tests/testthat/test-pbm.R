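test_that("8-mer E-score filter partitions at the 0.45/0.37 thresholds", {
  e <- pbmExperiment(c("AAAAAAAA", "CCCCCCCC", "GGGGGGGG"),
                     c(0.46, 0.30, 0.40))
  cls <- classify8mers(e)
  expect_equal(cls$positive, "AAAAAAAA")
  expect_equal(cls$negative, "CCCCCCCC")
  expect_equal(cls$discarded, "GGGGGGGG")
  # boundary values are discarded (strict inequalities)
  eb <- pbmExperiment(c("AAAAAAAA", "TTTTTTTT"), c(0.45, 0.37))
  expect_length(classify8mers(eb)$discarded, 2)
  # all at 0.50 are positive; empty experiment gives three empty sets
  expect_length(classify8mers(pbmExperiment("ACGTACGT", 0.50))$positive, 1)
  expect_true(all(lengths(classify8mers(
    pbmExperiment(character(0), numeric(0)))) == 0))
})

test_that("the positive/negative/discarded sets partition the records", {
  pb <- makePBM(sharpMotif(8), nPositive = 8, nNegative = 30,
                nDiscarded = 5, seed = 3)
  cls <- classify8mers(pb)
  expect_equal(sort(unlist(cls, use.names = FALSE)),
               sort(pb$records$kmer))
  expect_length(cls$positive, 8)
  expect_length(cls$negative, 30)
  expect_length(cls$discarded, 5)
})

test_that("E-score validation rejects out-of-range and non-8-mer input", {
  expect_error(pbmExperiment("ACGTACGT", 0.51), "E-scores")
  expect_error(pbmExperiment("ACGT", 0.4), "8-mers")
})

test_that("the PBM reader tolerates headers and extra columns", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("8-mer\tE-score\tZ-score",
               "ACGTACGT\t0.47\t3.2",
               "TTTTACGT\t-0.11\t0.1"), f)
  pb <- readPBM(f)
  expect_equal(nrow(pb$records), 2)
  expect_equal(pb$records$escore, c(0.47, -0.11))
})

test_that("an 8-mer aligns to its own consensus at the right placement", {
  m <- sharpMotif(10, seed = 31)
  cons <- consensus(m)
  al <- align8merToSite(substr(cons, 1, 8), m)
  expect_equal(al$offset, 1)
  expect_equal(al$strand, "+")
  expect_true(al$accepted)
  # reverse complement lands at the equivalent minus-strand placement
  rc <- align8merToSite(StructMotif:::revcomp(substr(cons, 1, 8)), m)
  expect_equal(rc$strand, "-")
  expect_equal(rc$offset, 1)
  expect_equal(rc$score, al$score)
})

test_that("placement optimum matches exhaustive enumeration", {
  m <- sharpMotif(11, seed = 32)
  lp <- log(pwmMatrix(m) + 1e-6)
  for (seed in 1:5) {
    kmer <- withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), 8,
                                                TRUE), collapse = ""))
    al <- align8merToSite(kmer, m, floor = "none")
    # oracle: enumerate all offsets x strands
    scoreAt <- function(k, o) {
      ki <- match(strsplit(k, "")[[1]], c("A", "C", "G", "T"))
      sum(lp[cbind(ki, o:(o + 7))])
    }
    cand <- expand.grid(o = 1:(11 - 7), s = c("+", "-"))
    cand$score <- mapply(function(o, s)
      scoreAt(if (s == "+") kmer else StructMotif:::revcomp(kmer), o),
      cand$o, cand$s)
    expect_equal(al$score, max(cand$score))
  }
})

test_that("a PWM/site length mismatch errors", {
  m <- sharpMotif(10)
  expect_error(align8merToSite("ACGTACGT", m, templateSite = "ACGTACG"),
               "length")
})

test_that("contact extension inherits distances and flips provenance", {
  fx <- closedLoopFixture()
  pl <- list(list(kmer = "ACGTAGGC",
                  placement = list(offset = 1, strand = "+",
                                   accepted = TRUE)))
  ext <- extendContacts(fx$contacts, pl)
  expect_equal(nrow(ext), nrow(fx$contacts))
  expect_true(all(ext$provenance == "pbm"))
  expect_equal(ext$distance, fx$contacts$distance)
  # extension adds to, never removes, pdb counts
  both <- countContacts(rbind(fx$contacts, ext))
  onlyPdb <- countContacts(fx$contacts)
  expect_identical(contactCounts(both)[, , , , "pdb"],
                   contactCounts(onlyPdb)[, , , , "pdb"])
  expect_gt(sum(contactCounts(both)), sum(contactCounts(onlyPdb)))
  # abundance is non-increasing under extension
  expect_lte(contactAbundance(both), contactAbundance(onlyPdb))
})

test_that("positive 8-mers varying at one step only diversify that step", {
  fx <- closedLoopFixture()
  kmers <- c("ACGTAGGC", "ACGAAGGC", "ACGCAGGC")  # differ at position 4
  pls <- lapply(kmers, function(k)
    list(kmer = k, placement = list(offset = 1, strand = "+",
                                    accepted = TRUE)))
  ext <- extendContacts(fx$contacts, pls)
  perStep <- split(ext$dinuc, ext$step)
  nVar <- vapply(perStep, function(d) length(unique(d)), integer(1))
  expect_true(all(nVar[c("3", "4")] == 3))   # steps covering position 4
  expect_true(all(nVar[setdiff(names(nVar), c("3", "4"))] == 1))
})

test_that("a homolog map with an interface gap contributes nothing", {
  fx <- closedLoopFixture()
  # target lacks the first interface residues entirely
  tmplSeq <- paste(proteinResidues(fx$complex)$aa, collapse = "")
  hmGap <- makeHomologMap(tmplSeq, substr(tmplSeq, 4, nchar(tmplSeq)))
  pl <- list(list(kmer = "ACGTAGGC",
                  placement = list(offset = 1, strand = "+",
                                   accepted = TRUE)))
  expect_warning(ext <- extendContacts(fx$contacts, pl,
                                       homologMaps = list(hmGap)),
                 "gap")
  expect_equal(nrow(ext), 0)
  # an identity map duplicates the template counts once per placement
  hmId <- makeHomologMap(tmplSeq, tmplSeq)
  ext2 <- extendContacts(fx$contacts, pl, homologMaps = list(hmId))
  expect_equal(nrow(ext2), nrow(fx$contacts))
  expect_equal(ext2$aa, fx$contacts$aa)
})

test_that("synthetic PBM fixtures recover the planted partition exactly", {
  m <- sharpMotif(8, seed = 41)
  pb <- makePBM(m, nPositive = 6, nNegative = 20, seed = 7)
  cls <- classify8mers(pb)
  expect_length(cls$positive, 6)
  expect_length(cls$negative, 20)
  expect_length(cls$discarded, 0)
  expect_true(consensus(m) %in% cls$positive)
  # zero positives stays empty
  expect_length(classify8mers(makePBM(m, nPositive = 0, nNegative = 5,
                                      seed = 8))$positive, 0)
})
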