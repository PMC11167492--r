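test_that("a planted consensus is the best hit in a random background", {
  m <- sharpMotif(8, seed = 101)
  bg <- withr::with_seed(102,
    paste(sample(c("A", "C", "G", "T"), 420, TRUE), collapse = ""))
  seq <- paste0(substr(bg, 1, 205), consensus(m), substr(bg, 214, 420))
  hits <- scanSequence(m, seq, alpha = 1)
  expect_equal(hits$start[1], 206)
  expect_equal(hits$end[1], 213)
  # alpha = 0 retains nothing
  expect_equal(nrow(scanSequence(m, seq, alpha = 0)), 0)
  # sequences shorter than the motif give no hits
  expect_equal(nrow(scanSequence(m, "ACGT")), 0)
})

test_that("exact p-values match brute-force word enumeration", {
  for (w in 3:6) {
    m <- makeMotifDb(1, widths = w, seed = 110 + w)[[1]]
    bg <- rep(0.25, 4)
    lod <- StructMotif:::logOddsMatrix(m, bg)
    pf <- StructMotif:::exactPvalueFun(lod, bg)
    words <- as.matrix(expand.grid(rep(list(1:4), w)))
    ws <- apply(words, 1, function(r) sum(lod[cbind(r, seq_len(w))]))
    brute <- vapply(ws, function(s) mean(ws >= s - 1e-12), numeric(1))
    expect_lt(max(abs(pf(ws) - brute)), 0.02)
    expect_gt(stats::cor(pf(ws), brute), 0.999)
  }
})

test_that("N bases contribute zero log-odds", {
  m <- sharpMotif(6, seed = 115)
  hits1 <- scanSequence(m, paste0(consensus(m), "AA"), alpha = 1)
  seqN <- paste0(sub("^.", "N", consensus(m)), "AA")
  hitsN <- scanSequence(m, seqN, alpha = 1)
  h1 <- hits1[hits1$start == 1 & hits1$strand == "+", ]
  hN <- hitsN[hitsN$start == 1 & hitsN$strand == "+", ]
  lod <- StructMotif:::logOddsMatrix(m, rep(0.25, 4))
  b1 <- match(substr(consensus(m), 1, 1), c("A", "C", "G", "T"))
  expect_equal(h1$score - hN$score, unname(lod[b1, 1]), tolerance = 1e-9)
})

test_that("scanning the reverse complement mirrors hit coordinates", {
  m <- sharpMotif(7, seed = 116)
  s <- withr::with_seed(117,
    paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = ""))
  rc <- StructMotif:::revcomp(s)
  h1 <- scanSequence(m, s, alpha = 1)
  h2 <- scanSequence(m, rc, alpha = 1)
  k1 <- h1[order(h1$start, h1$strand), ]
  mirrored <- data.frame(start = 60 - h2$end + 1, end = 60 - h2$start + 1,
                         strand = ifelse(h2$strand == "+", "-", "+"),
                         score = h2$score)
  k2 <- mirrored[order(mirrored$start, mirrored$strand), ]
  expect_equal(k1$start, k2$start)
  expect_equal(k1$score, k2$score, tolerance = 1e-9)
})

test_that("bin assignment picks the largest overlap, ties to lower bin", {
  # a hit spanning 195-208 overlaps bin 10 by 6 nt and bin 11 by 8 nt
  expect_equal(StructMotif:::assignBin(195, 208), 11)
  expect_equal(StructMotif:::assignBin(181, 200), 10)
  expect_equal(StructMotif:::assignBin(201, 220), 11)
  # an exact tie (equal overlap in two bins) goes to the lower index
  expect_equal(StructMotif:::assignBin(196, 205), 10)
})

test_that("unanimous hits in the middle bin are a true positive", {
  hs <- lapply(1:100, function(i)
    data.frame(pwm = paste0("p", i), sequenceId = "s", start = 203,
               end = 212, strand = "+", score = 5, pValue = 1e-6,
               stringsAsFactors = FALSE))
  bp <- binProfile(hs)
  expect_equal(bp$counts[11], 100)
  expect_equal(bp$positives, 11L)
  expect_true(bp$predictedTrue)
  expect_equal(sum(bp$counts), 100)
})

test_that("tied maximal bins are both positive", {
  hs <- c(
    lapply(1:3, function(i)
      data.frame(pwm = "a", sequenceId = "s", start = 205, end = 212,
                 strand = "+", score = 1, pValue = 1e-6)),
    lapply(1:3, function(i)
      data.frame(pwm = "b", sequenceId = "s", start = 45, end = 52,
                 strand = "+", score = 1, pValue = 1e-6)))
  bp <- binProfile(hs)
  expect_setequal(bp$positives, c(3L, 11L))
  expect_true(bp$predictedTrue)          # one TP ...
  expect_equal(length(setdiff(bp$positives, 11L)), 1)  # ... plus one FP
})

test_that("each PWM counts once: the best hit decides its bin", {
  h <- data.frame(pwm = "p", sequenceId = "s",
                  start = c(30, 204), end = c(37, 211), strand = "+",
                  score = c(1, 9), pValue = c(1e-3, 1e-8))
  bp <- binProfile(list(h))
  expect_equal(sum(bp$counts), 1)
  expect_equal(bp$positives, 11L)
})

test_that("the averaged ROC needs two experiments and reaches AUROC 1 when perfect", {
  mkHits <- function(p) list(data.frame(
    pwm = "p", sequenceId = "s", start = 204, end = 211, strand = "+",
    score = 5, pValue = p, stringsAsFactors = FALSE))
  exps <- list(mkHits(1e-8), mkHits(1e-8), mkHits(1e-8))
  r <- chipexoROC(exps, alphas = c(1e-6, 1e-3, 0.5))
  expect_equal(r$auroc, 1)
  expect_true(all(r$curve$fprSe == 0))
  expect_error(chipexoROC(exps[1]), "2 experiments")
})

test_that("random PWMs on random sequences stay near the chance diagonal", {
  db <- makeMotifDb(8, widths = 8, seed = 120)
  mkExp <- function(s) {
    sq <- withr::with_seed(s,
      paste(sample(c("A", "C", "G", "T"), 420, TRUE), collapse = ""))
    lapply(db, function(m) scanSequence(m, sq, alpha = 1))
  }
  exps <- lapply(121:126, mkExp)
  r <- chipexoROC(exps, alphas = 10^seq(-5, -0.3, length.out = 8))
  # majority-vote calls on pure noise cannot be far from chance
  expect_gt(r$auroc, 0.15)
  expect_lt(r$auroc, 0.85)
})

test_that("BED export preserves coordinates half-open", {
  m <- sharpMotif(6, seed = 130)
  hits <- scanSequence(m, paste0("AAAA", consensus(m), "TTTT"), alpha = 1)
  f <- withr::local_tempfile(fileext = ".bed")
  bed <- writeHitsBED(hits, f)
  expect_true(file.exists(f))
  expect_equal(bed$end - bed$start, rep(6, nrow(bed)))
})
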