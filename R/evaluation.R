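# Benchmarking machinery: normalized ranking score, rank-enrichment
# (majority-vote) prediction, nearest-neighbor baseline, the
# positive/negative 8-mer classification protocol and the per-family
# parameter grid search.

#' Normalized ranking score
#'
#' Transforms the rank of the true motif in a database of M motifs to a
#' 0-100 scale: \code{100 * (M - rank + 1) / M}. Rank 1 scores exactly
#' 100; the worst rank scores 100/M.
#'
#' @param rank integer rank, 1 <= rank <= M.
#' @param M database size.
#' @return numeric score.
#' @export
normalizedRankScore <- function(rank, M) {
  stopifnot(all(rank >= 1), all(rank <= M))
  100 * (M - rank + 1) / M
}

#' Rank-enrichment (majority-vote) motif prediction
#'
#' Every predicted PWM of a target is compared with all database
#' motifs; non-significant matches are removed and the \code{topK} best
#' by similarity score are selected. Selections are tallied per
#' database motif across all predicted PWMs; the winning motif is the
#' most often selected one (ties broken by higher mean similarity
#' score, then lexical id). The true motif's rank among the tallies
#' gives its normalized rank-enrichment; if it never enters any top-K
#' the prediction carries no coverage and is neglected.
#'
#' @param predicted list of predicted \linkS4class{PWMotif}.
#' @param database named list of experimental motifs.
#' @param trueId id of the target's experimental motif (optional).
#' @param topK selections kept per predicted PWM (default 10).
#' @param alpha significance level for the match filter.
#' @param nNull,seed null-sample controls for the comparisons.
#' @return list of class \code{EnrichmentResult}: \code{counts} (named,
#'   whole database), \code{winner}, \code{trueId}, \code{rank},
#'   \code{normalized}, \code{coverage}.
#' @export
rankEnrichment <- function(predicted, database, trueId = NULL, topK = 10L,
                           alpha = 0.05, nNull = 200L, seed = 1L) {
  if (!length(database)) stop("empty motif database")
  stopifnot(length(predicted) >= 1)
  cmp <- batchCompare(predicted, database, nNull = nNull, seed = seed)
  ids <- names(database)
  counts <- stats::setNames(numeric(length(ids)), ids)
  simSum <- stats::setNames(numeric(length(ids)), ids)
  n <- length(predicted)
  for (qi in seq_len(n)) {
    sub <- cmp[cmp$query == pwmId(predicted[[qi]]), , drop = FALSE]
    # queries may share ids; fall back to block slicing
    if (nrow(sub) != length(ids))
      sub <- cmp[((qi - 1) * length(ids) + 1):(qi * length(ids)), ,
                 drop = FALSE]
    sub <- sub[sub$pValue < alpha, , drop = FALSE]
    if (!nrow(sub)) next
    sub <- sub[order(-sub$score, sub$target), , drop = FALSE]
    sel <- utils::head(sub, topK)
    counts[sel$target] <- counts[sel$target] + 1
    simSum[sel$target] <- simSum[sel$target] + sel$score
  }
  meanSim <- ifelse(counts > 0, simSum / pmax(counts, 1), -Inf)
  ord <- order(-counts, -meanSim, ids)
  winner <- ids[ord][1]
  rank <- NA_integer_; normalized <- NA_real_; coverage <- FALSE
  if (!is.null(trueId)) {
    coverage <- counts[trueId] > 0
    if (coverage) {
      rank <- match(trueId, ids[ord])
      normalized <- normalizedRankScore(rank, length(ids))
    }
  }
  structure(list(counts = counts, winner = winner, trueId = trueId,
                 rank = rank, normalized = normalized,
                 coverage = unname(coverage)),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat("EnrichmentResult: winner", x$winner)
  if (!is.null(x$trueId))
    cat("; true motif", x$trueId,
        if (x$coverage) sprintf("rank %d (normalized %.1f)", x$rank,
                                x$normalized)
        else "not covered")
  cat("\n")
  invisible(x)
}

#' Nearest-neighbor motif prediction
#'
#' Assigns a target TF the experimental motif of its most
#' sequence-similar relative within an identity bin. Identity is the
#' percentage of identical residues over the global alignment length
#' (BLOSUM62, gap open 10 / extend 0.5). Bins are centered on
#' 15-95% in 10% steps: the bin at x covers identities in
#' (x-5, x+5], so the 95% bin holds relatives at 90-100% identity.
#'
#' @param targetSeq target protein sequence.
#' @param database data.frame with columns \code{id} and \code{seq}.
#' @param pwms named list of the database TFs' motifs.
#' @param bin center of the identity bin, percent (15, 25, ..., 95).
#' @param mode "single" (the best in-bin neighbor's PWM) or
#'   "enrichment" (all in-bin motifs, feeding
#'   \code{\link{rankEnrichment}}).
#' @return For "single": list(\code{pwm}, \code{neighbor},
#'   \code{identity}), with \code{pwm = NULL} when no neighbor falls in
#'   the bin. For "enrichment": the list of in-bin motifs.
#' @export
nearestNeighborPredict <- function(targetSeq, database, pwms, bin = 95,
                                   mode = c("single", "enrichment")) {
  mode <- match.arg(mode)
  stopifnot(nrow(database) >= 1)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  idy <- vapply(database$seq, function(s) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(targetSeq), Biostrings::AAString(s),
      type = "global", substitutionMatrix = BLOSUM62,
      gapOpening = 10, gapExtension = 0.5)
    Biostrings::pid(aln, type = "PID1")
  }, numeric(1))
  inBin <- which(idy > bin - 5 & idy <= bin + 5)
  if (mode == "single") {
    if (!length(inBin)) return(list(pwm = NULL, neighbor = NA, identity = NA))
    b <- inBin[order(-idy[inBin], database$id[inBin])][1]
    list(pwm = pwms[[database$id[b]]], neighbor = database$id[b],
         identity = unname(idy[b]))
  } else {
    pwms[database$id[inBin]]
  }
}

## ---- ROC / PR ----

#' Area under the ROC curve by trapezoidal integration
#' @param scores numeric scores, higher = more positive.
#' @param labels logical or 0/1 vector.
#' @return AUROC in [0,1].
#' @export
aurocScore <- function(scores, labels) {
  labels <- as.logical(labels)
  ord <- order(-scores)
  tp <- cumsum(labels[ord]); fp <- cumsum(!labels[ord])
  tpr <- c(0, tp / max(1, sum(labels)))
  fpr <- c(0, fp / max(1, sum(!labels)))
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

#' Area under the precision-recall curve by trapezoidal integration
#' @inheritParams aurocScore
#' @return AUPRC in [0,1].
#' @export
auprcScore <- function(scores, labels) {
  labels <- as.logical(labels)
  ord <- order(-scores)
  l <- labels[ord]
  tp <- cumsum(l)
  prec <- tp / seq_along(l)
  rec <- tp / max(1, sum(l))
  keep <- c(TRUE, diff(rec) > 0)
  rec <- c(0, rec[keep]); prec <- c(prec[keep][1], prec[keep])
  sum(diff(rec) * (head(prec, -1) + prec[-1]) / 2)
}

## ---- 8-mer classification benchmark ----

# thread an 8-mer onto a TF interface: substitute its dinucleotides
# along the chain steps (up to 7) and sum the per-contact Z-scores
scoreKmers <- function(potential, contacts, kmers) {
  ss <- stepScoreMatrix(potential, contacts)
  nstep <- min(ncol(ss$mat), 7L)
  vapply(kmers, function(k) {
    b <- match(strsplit(k, "")[[1]], DNA_BASES)
    tot <- 0
    for (j in seq_len(nstep)) {
      didx <- b[j] + 4L * (b[j + 1L] - 1L)
      tot <- tot + ss$mat[didx, j]
    }
    tot
  }, numeric(1), USE.NAMES = FALSE)
}

sampleNegatives <- function(positives, n, gcMatched = TRUE) {
  avoid <- positives
  out <- character(0)
  if (gcMatched) {
    gcPool <- round(mean(vapply(positives, function(p)
      sum(strsplit(p, "")[[1]] %in% c("G", "C")), numeric(1))))
  }
  guard <- 0L
  while (length(out) < n && guard < 50L * n) {
    guard <- guard + 1L
    if (gcMatched) {
      gc <- gcPool
      pos <- sample(8L, gc)
      k <- rep("x", 8)
      k[pos] <- sample(c("G", "C"), gc, replace = TRUE)
      k[k == "x"] <- sample(c("A", "T"), 8 - gc, replace = TRUE)
      k <- paste(k, collapse = "")
    } else {
      k <- paste(sample(DNA_BASES, 8, replace = TRUE), collapse = "")
    }
    if (!k %in% avoid) out <- c(out, k)
  }
  out
}

#' Positive/negative 8-mer classification benchmark
#'
#' The cross-validated protocol for testing whether a potential's
#' threading scores separate bound from unbound 8-mers: per repeat,
#' negatives are drawn at an unbalanced ratio (1/100 or 1/500) to the
#' positives, either G+C-matched or at random; a 5-fold
#' cross-validation over TFs trains the potential on the training
#' folds' contact tables - excluding any training TF whose contact
#' fingerprint is more than \code{cutoff} identical to a test TF, so a
#' TF is never scored by a potential trained on itself or a
#' near-duplicate - and scores every test 8-mer by threading it onto
#' the test TF's interface (sum of per-contact Z-scores; more negative
#' = better binding). AUROC and AUPRC are computed per repeat by
#' trapezoidal integration and averaged. Families with fewer than
#' \code{minTFs} TFs are excluded with a warning.
#'
#' @param tfData list, one element per TF:
#'   \code{list(id, family, table, contacts, positives)}.
#' @param config \code{\link{familyConfig}} used to build potentials.
#' @param ratio positives : negatives ratio (default 1/100).
#' @param gcMatched match the negatives' G+C content to the positives.
#' @param repeats,folds protocol sizes (defaults 10 and 5).
#' @param cutoff redundancy cutoff between train and test TFs.
#' @param minTFs smallest family size admitted (default 10).
#' @param shuffleLabels permute labels (null-behavior check).
#' @param seed RNG seed.
#' @return data.frame per family: \code{family}, \code{n_tfs},
#'   \code{auroc}, \code{auroc_sd}, \code{auprc}, \code{auprc_sd}.
#' @export
kmerBenchmark <- function(tfData, config = familyConfig(),
                          ratio = 1 / 100, gcMatched = TRUE,
                          repeats = 10L, folds = 5L, cutoff = 0.70,
                          minTFs = 10L, shuffleLabels = FALSE, seed = 1L) {
  fams <- vapply(tfData, `[[`, character(1), "family")
  out <- list()
  for (fam in unique(fams)) {
    tfs <- tfData[fams == fam]
    if (length(tfs) < minTFs) {
      warning("family ", fam, " has <", minTFs, " TFs; excluded")
      next
    }
    fps <- lapply(tfs, function(t) contactFingerprint(t$table))
    aurocs <- numeric(repeats); auprcs <- numeric(repeats)
    for (rep in seq_len(repeats)) {
      repSeed <- seed * 1000L + rep
      tfAuroc <- numeric(0); tfAuprc <- numeric(0)
      foldId <- withLocalSeed(repSeed,
        sample(rep_len(seq_len(folds), length(tfs))))
      for (f in seq_len(folds)) {
        test <- which(foldId == f)
        train <- which(foldId != f)
        if (!length(test) || !length(train)) next
        # redundancy rule: drop training TFs too similar to any test TF
        ok <- vapply(train, function(i) {
          all(vapply(test, function(j)
            fingerprintSimilarity(fps[[i]], fps[[j]]) <= cutoff,
            logical(1)))
        }, logical(1))
        train <- train[ok]
        if (!length(train)) next
        pooled <- mergeContactTables(lapply(tfs[train], `[[`, "table"))
        pot <- buildPotential(pooled, config)
        for (j in test) {
          pos <- tfs[[j]]$positives
          neg <- withLocalSeed(repSeed * 131L + j,
            sampleNegatives(pos, round(length(pos) / ratio), gcMatched))
          kmers <- c(pos, neg)
          z <- scoreKmers(pot, tfs[[j]]$contacts, kmers)
          sc <- -z   # more negative Z = better binding
          lb <- rep(c(TRUE, FALSE), c(length(pos), length(neg)))
          if (shuffleLabels)
            lb <- withLocalSeed(repSeed * 17L + j, sample(lb))
          # scores of different TFs are on different scales; the ROC is
          # computed per TF and averaged
          tfAuroc <- c(tfAuroc, aurocScore(sc, lb))
          tfAuprc <- c(tfAuprc, auprcScore(sc, lb))
        }
      }
      aurocs[rep] <- mean(tfAuroc)
      auprcs[rep] <- mean(tfAuprc)
    }
    out[[length(out) + 1L]] <- data.frame(
      family = fam, n_tfs = length(tfs),
      auroc = mean(aurocs), auroc_sd = sd(aurocs),
      auprc = mean(auprcs), auprc_sd = sd(auprcs),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("no family passed the size filter")
  do.call(rbind, out)
}

## ---- grid search ----

#' The full parameter grid
#'
#' All six swept axes: interval/cumulative binning, Taylor smoothing on
#' or off, contacts database (pdb or pbm-extended), family-specific or
#' general scope, interface radius (15/22/30 A) and the top-score
#' selection threshold 0.70..1.00 in steps of 0.01 - 2 x 2 x 2 x 2 x 3
#' x 31 = 1488 grid points.
#'
#' @return data.frame with one row per grid point.
#' @export
buildParameterGrid <- function() {
  expand.grid(binning = c("bins", "acc"), taylor = c(TRUE, FALSE),
              db = c("pdb", "pbm"), scope = c("family", "general"),
              radius = c(15, 22, 30),
              threshold = seq(0.70, 1.00, by = 0.01),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Per-family grid search over potential parameters
#'
#' Evaluates every grid point with the supplied accuracy function and
#' selects the winner by the three rules, in order: (i) the maximum
#' number of significant good predictions; (ii) the best mean
#' similarity score when a similar number of significant solutions
#' (within \code{similarTol}, default 1) was achieved; (iii) the lowest
#' threshold when several similar solutions remain.
#'
#' @param grid data.frame of grid points (see
#'   \code{\link{buildParameterGrid}}).
#' @param evaluate function(row) returning
#'   \code{list(nSignificant=, meanScore=)}.
#' @param similarTol count tolerance for rule (ii).
#' @return list: \code{config} (the winning row), \code{results} (the
#'   evaluated grid).
#' @export
gridSearch <- function(grid, evaluate, similarTol = 1) {
  stopifnot(nrow(grid) >= 1)
  evals <- lapply(seq_len(nrow(grid)), function(i) evaluate(grid[i, ]))
  res <- cbind(grid,
               nSignificant = vapply(evals, `[[`, numeric(1), "nSignificant"),
               meanScore = vapply(evals, `[[`, numeric(1), "meanScore"))
  cand <- which(res$nSignificant >= max(res$nSignificant) - similarTol)
  bestScore <- max(res$meanScore[cand])
  cand <- cand[res$meanScore[cand] >= bestScore - 1e-9]
  cand <- cand[order(res$threshold[cand])]
  list(config = res[cand[1], , drop = FALSE], results = res)
}
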