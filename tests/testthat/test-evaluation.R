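test_that("the normalized ranking score follows 100*(M-rank+1)/M", {
  expect_equal(normalizedRankScore(1, 2638), 100)
  expect_equal(normalizedRankScore(2638, 2638), 100 / 2638)
  expect_equal(normalizedRankScore(1320, 2638), 100 * 1319 / 2638)
  expect_equal(normalizedRankScore(1320, 2638), 50.0 - 50 / 1319 * 0 - 0,
               tolerance = 1e-9)
  # strictly decreasing in rank; 100 iff rank 1
  sc <- normalizedRankScore(1:100, 100)
  expect_true(all(diff(sc) < 0))
  expect_equal(sum(sc == 100), 1)
  expect_error(normalizedRankScore(0, 10))
  expect_error(normalizedRankScore(11, 10))
})

test_that("unanimous predictions enrich the embedded motif to score 100", {
  planted <- sharpMotif(8, seed = 81)
  db <- makeMotifDb(12, widths = 8, seed = 82, embed = planted)
  preds <- rep(list(planted), 20)
  er <- rankEnrichment(preds, db, trueId = "planted", topK = 10,
                       nNull = 150, seed = 6)
  expect_equal(er$winner, "planted")
  expect_equal(unname(er$counts["planted"]), 20)
  expect_true(er$coverage)
  expect_equal(er$normalized, 100)
})

test_that("a true motif absent from all top-K is flagged no-coverage", {
  planted <- sharpMotif(8, seed = 83)
  db <- makeMotifDb(6, widths = 8, seed = 84)
  preds <- rep(list(planted), 3)
  er <- rankEnrichment(preds, db, trueId = "M004", topK = 1,
                       alpha = 1e-6, nNull = 100, seed = 7)
  expect_false(er$coverage)
  expect_true(is.na(er$normalized))
})

test_that("count ties break by mean similarity, deterministically", {
  counts <- c(A = 5, B = 5, C = 1)
  # exercise the ordering rule directly through a degenerate database
  db <- makeMotifDb(3, widths = 8, seed = 85)
  names(db) <- c("A", "B", "C")
  for (i in 1:3) db[[i]]@id <- names(db)[i]
  # both A and B identical motifs: counts tie, meanSim ties, lexical id
  db$B@mat <- db$A@mat
  preds <- rep(list(db$A), 4)
  er1 <- rankEnrichment(preds, db, trueId = "A", topK = 2, nNull = 120,
                        seed = 8)
  er2 <- rankEnrichment(preds, db, trueId = "A", topK = 2, nNull = 120,
                        seed = 8)
  expect_identical(er1$winner, er2$winner)
  expect_equal(er1$winner, "A")
})

test_that("a single predicted PWM degenerates to plain ranking", {
  planted <- sharpMotif(8, seed = 86)
  db <- makeMotifDb(8, widths = 8, seed = 87, embed = planted)
  er <- rankEnrichment(list(planted), db, trueId = "planted", topK = 5,
                       nNull = 150, seed = 9)
  expect_true(er$coverage)
  expect_equal(er$rank, 1)
  expect_error(rankEnrichment(list(planted), list(), trueId = "x"),
               "empty")
})

test_that("nearest neighbor returns the in-bin best and honors the bins", {
  seqs <- c(T1 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQAPILSRVGDGTQDNLSGAEKAVQ",
            T2 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQAPILSRVGDGTQDNLSGAEKAVA",
            T3 = "MSTNPKPQRKTKRNTNRRPQDVKFPGG")
  db <- data.frame(id = names(seqs), seq = unname(seqs),
                   stringsAsFactors = FALSE)
  pwms <- makeMotifDb(3, widths = 8, seed = 91)
  names(pwms) <- db$id
  # the database contains the target itself -> own PWM at the 95 bin
  nn <- nearestNeighborPredict(seqs[["T1"]], db, pwms, bin = 95)
  expect_equal(nn$neighbor, "T1")
  expect_equal(nn$identity, 100)
  # no neighbor in a low-identity bin -> no prediction
  none <- nearestNeighborPredict(seqs[["T1"]], db[3, , drop = FALSE],
                                 pwms[3], bin = 95)
  expect_null(none$pwm)
  # enrichment mode returns every in-bin motif
  all95 <- nearestNeighborPredict(seqs[["T1"]], db, pwms, bin = 95,
                                  mode = "enrichment")
  expect_equal(sort(names(all95)), c("T1", "T2"))
})

test_that("the closest in-bin neighbor wins single mode", {
  # identities to the target: ~62% and ~58% by construction
  target <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQAPILSRVGDGTQDNLSG"
  mut <- function(s, k) {
    b <- strsplit(s, "")[[1]]
    b[seq_len(k)] <- "A"
    paste(b, collapse = "")
  }
  db <- data.frame(id = c("N62", "N58"),
                   seq = c(mut(target, 19), mut(target, 21)),
                   stringsAsFactors = FALSE)
  pwms <- makeMotifDb(2, widths = 8, seed = 92)
  names(pwms) <- db$id
  nn <- nearestNeighborPredict(target, db, pwms, bin = 65)
  expect_equal(nn$neighbor, "N62")
  expect_gt(nn$identity, 60)
})

test_that("trapezoidal AUROC/AUPRC agree with pROC on a random case", {
  skip_if_not_installed("pROC")
  withr::with_seed(95, {
    sc <- rnorm(200)
    lb <- runif(200) < stats::plogis(sc)
  })
  ours <- aurocScore(sc, lb)
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-9)
  expect_gte(auprcScore(sc, lb), mean(lb) * 0.5)
})

test_that("the G+C-matched sampler matches the positives' composition", {
  pos <- c("GCGCAATT", "GGCCAATT", "GCCGTTAA")
  neg <- withr::with_seed(96,
    StructMotif:::sampleNegatives(pos, 300, gcMatched = TRUE))
  gc <- function(k) mean(strsplit(k, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(mean(vapply(neg, gc, numeric(1))) -
                  mean(vapply(pos, gc, numeric(1)))), 0.02)
  expect_false(any(neg %in% pos))
})

test_that("the CV harness separates train and test and excludes tiny families", {
  td <- makeKmerBenchmarkData(10, seed = 3)
  w <- capture_warnings(
    expect_error(
      kmerBenchmark(c(td[1:2], lapply(td[1:2], function(t)
        modifyList(t, list(family = "TINY")))), minTFs = 10),
      "size filter"))
  expect_match(w, "excluded", all = TRUE)
  expect_length(w, 2)   # both undersized families are excluded
  res <- kmerBenchmark(td, config = familyConfig(binning = "bins",
                                                 radius = 30),
                       repeats = 2, seed = 2)
  expect_equal(res$n_tfs, 10)
  expect_gt(res$auroc, 0.9)
})

test_that("the parameter grid spans exactly 1488 points", {
  g <- buildParameterGrid()
  expect_equal(nrow(g), 1488)
  expect_equal(nrow(unique(g)), 1488)
  expect_equal(nrow(g), 2 * 2 * 2 * 2 * 3 * 31)
})

test_that("grid-search tie-breaking prefers score, then lowest threshold", {
  g <- buildParameterGrid()
  sub <- g[g$binning == "bins" & !g$taylor & g$db == "pdb" &
             g$scope == "family" & g$radius == 15, ]
  # identical accuracy everywhere -> the lowest threshold wins
  flat <- gridSearch(sub, function(row)
    list(nSignificant = 5, meanScore = 1))
  expect_equal(flat$config$threshold, 0.70)
  # a single grid point is returned unchanged
  one <- gridSearch(sub[10, ], function(row)
    list(nSignificant = 2, meanScore = 0.5))
  expect_equal(one$config$threshold, sub$threshold[10])
  # counts within 1 are "similar": the better mean score wins
  tricky <- gridSearch(sub[1:3, ], function(row) {
    if (row$threshold == 0.70) list(nSignificant = 5, meanScore = 1)
    else if (row$threshold == 0.71) list(nSignificant = 4, meanScore = 9)
    else list(nSignificant = 1, meanScore = 99)
  })
  expect_equal(tricky$config$threshold, 0.71)
})
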