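# PWM scanning with exact p-values (dynamic programming over the
# discrete score distribution under the background), plus the
# ChIP-exo-style binned majority-vote binding-site caller and the
# averaged-ROC harness.

logOddsMatrix <- function(pwm, background) {
  p <- pwmMatrix(pwm)
  p <- sweep(p + 0.0001, 2, colSums(p) + 0.0004, "/")
  log2(p / background)
}

# exact null distribution of the integer-discretized score; returns a
# function mapping a raw score to P(S >= score)
exactPvalueFun <- function(lod, background, gridN = 1000L) {
  w <- ncol(lod)
  mins <- apply(lod, 2, min)
  rngTot <- sum(apply(lod, 2, max)) - sum(mins)
  step <- if (rngTot > 0) rngTot / gridN else 1
  ints <- round(sweep(lod, 2, mins, "-") / step)
  maxInt <- sum(apply(ints, 2, max))
  dist <- c(1, rep(0, maxInt))
  for (j in seq_len(w)) {
    nd <- rep(0, maxInt + 1L)
    for (b in 1:4) {
      s <- ints[b, j]
      pb <- background[b]
      if (pb == 0) next
      nd[(s + 1L):(maxInt + 1L)] <- nd[(s + 1L):(maxInt + 1L)] +
        pb * dist[1:(maxInt + 1L - s)]
    }
    dist <- nd
  }
  tail <- rev(cumsum(rev(dist)))
  function(score) {
    i <- round((score - sum(mins)) / step)
    i <- pmax(0L, pmin(maxInt, i))
    tail[i + 1L]
  }
}

#' Scan a DNA sequence with a PWM
#'
#' Log-odds scores (base 2, against the background) at every position
#' on both strands, with exact p-values from the discrete distribution
#' of PWM scores under the background (dynamic programming with the
#' score range discretized into 1000 steps). Hits with p-value below
#' \code{alpha} are retained. N bases contribute zero log-odds.
#'
#' @param pwm a \linkS4class{PWMotif}.
#' @param sequence DNA string over A,C,G,T,N.
#' @param alpha p-value threshold (default 5e-4).
#' @param background "uniform", "sequence" (composition-derived), or a
#'   length-4 vector.
#' @param sequenceId identifier for the output.
#' @return data.frame of hits: \code{pwm}, \code{sequenceId},
#'   \code{start}, \code{end} (1-based, inclusive, forward-strand
#'   coordinates), \code{strand}, \code{score}, \code{pValue}.
#' @export
scanSequence <- function(pwm, sequence, alpha = 5e-4,
                         background = "uniform", sequenceId = "seq") {
  w <- pwmWidth(pwm)
  s <- strsplit(toupper(sequence), "")[[1]]
  n <- length(s)
  empty <- data.frame(pwm = character(0), sequenceId = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0),
                      pValue = numeric(0), stringsAsFactors = FALSE)
  if (n < w) return(empty)
  bg <- if (is.numeric(background)) background / sum(background)
  else if (identical(background, "sequence")) {
    cnt <- table(factor(s[s %in% DNA_BASES], levels = DNA_BASES))
    if (sum(cnt) == 0) rep(0.25, 4) else (cnt + 1) / (sum(cnt) + 4)
  } else rep(0.25, 4)
  bg <- as.numeric(bg)
  lodF <- logOddsMatrix(pwm, bg)
  pvalF <- exactPvalueFun(lodF, bg)
  lodR <- lodF[4:1, rev(seq_len(w)), drop = FALSE]   # reverse complement
  si <- match(s, DNA_BASES)                           # NA for N
  scoreAll <- function(lod) {
    sc <- numeric(n - w + 1L)
    for (j in seq_len(w)) {
      v <- unname(lod[, j])[si[j:(j + n - w)]]
      v[is.na(v)] <- 0      # N bases contribute zero log-odds
      sc <- sc + v
    }
    sc
  }
  scF <- scoreAll(lodF)
  scR <- scoreAll(lodR)
  starts <- seq_len(n - w + 1L)
  hits <- rbind(
    data.frame(pwm = pwmId(pwm), sequenceId = sequenceId, start = starts,
               end = starts + w - 1L, strand = "+", score = scF,
               pValue = pvalF(scF), stringsAsFactors = FALSE),
    data.frame(pwm = pwmId(pwm), sequenceId = sequenceId, start = starts,
               end = starts + w - 1L, strand = "-", score = scR,
               pValue = pvalF(scR), stringsAsFactors = FALSE))
  hits <- hits[hits$pValue < alpha, , drop = FALSE]
  hits <- hits[order(hits$pValue, hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Write scan hits as BED6
#' @param hits data.frame from \code{\link{scanSequence}}.
#' @param file output path.
#' @return invisibly, the BED data.frame.
#' @export
writeHitsBED <- function(hits, file) {
  bed <- data.frame(chrom = hits$sequenceId, start = hits$start - 1L,
                    end = hits$end, name = hits$pwm,
                    score = pmin(1000, round(-10 * log10(hits$pValue))),
                    strand = hits$strand)
  write.table(bed, file, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(bed)
}

#' Binned majority-vote profile of an ensemble of PWM scans
#'
#' A window (420 nt by default) is segmented into \code{nBins} bins of
#' \code{binWidth} nt: bin b covers 1-based positions
#' [binWidth*(b-1)+1, binWidth*b], so bin 11 holds positions 201-220,
#' the central site. Each PWM contributes at most one count: its best
#' hit (lowest p-value) is assigned to the bin with the largest overlap
#' with the hit's span (ties to the lower bin index). Positive bins are
#' those achieving the maximum count; the prediction is true when the
#' middle bin is positive.
#'
#' @param hitsList list with one element per PWM: a hits data.frame
#'   (already filtered at the working alpha).
#' @param window window length (nt).
#' @param nBins,binWidth binning scheme.
#' @return list of class \code{BinProfile}: \code{counts} (length
#'   nBins), \code{positives}, \code{trueBin}, \code{predictedTrue}.
#' @export
binProfile <- function(hitsList, window = 420L, nBins = 21L,
                       binWidth = 20L) {
  counts <- rep(0L, nBins)
  for (hits in hitsList) {
    if (is.null(hits) || !nrow(hits)) next
    h <- hits[hits$start >= 1 & hits$end <= window, , drop = FALSE]
    if (!nrow(h)) next
    h <- h[order(h$pValue, h$start, h$strand), , drop = FALSE]
    b <- assignBin(h$start[1], h$end[1], nBins, binWidth)
    counts[b] <- counts[b] + 1L
  }
  positives <- if (max(counts) > 0) which(counts == max(counts)) else integer(0)
  trueBin <- (nBins + 1L) %/% 2L
  structure(list(counts = counts, positives = positives, trueBin = trueBin,
                 predictedTrue = trueBin %in% positives),
            class = "BinProfile")
}

# the bin with the largest overlap with [start, end]; ties -> lower bin
assignBin <- function(start, end, nBins = 21L, binWidth = 20L) {
  lo <- binWidth * (seq_len(nBins) - 1L) + 1L
  hi <- binWidth * seq_len(nBins)
  ov <- pmax(0L, pmin(end, hi) - pmax(start, lo) + 1L)
  which.max(ov)
}

#' @export
print.BinProfile <- function(x, ...) {
  cat("BinProfile:", sum(x$counts), "PWMs;",
      "positive bin(s):", paste(x$positives, collapse = ","),
      "; middle bin", x$trueBin,
      if (x$predictedTrue) "(hit)" else "(miss)", "\n")
  invisible(x)
}

#' Averaged ROC over binned binding-site predictions
#'
#' For each experiment (a list of per-PWM unfiltered hit tables over
#' its window) and each alpha in the sweep, hits are filtered at alpha,
#' the majority-vote bin profile is computed and scored: a positive
#' middle bin is the one true positive, every other positive bin is a
#' false positive, a silent middle bin a false negative and the
#' remaining bins true negatives. TPR and FPR are averaged across
#' experiments per alpha and the standard error is sd/sqrt(N).
#'
#' @param experiments list of experiments, each a list of per-PWM hit
#'   data.frames carrying p-values (unfiltered).
#' @param alphas p-value sweep.
#' @param window,nBins,binWidth see \code{\link{binProfile}}.
#' @return list: \code{curve} (data.frame alpha, tpr, fpr, tprSe,
#'   fprSe), \code{auroc} (trapezoid over the mean curve), \code{n}.
#' @export
chipexoROC <- function(experiments,
                       alphas = 10^seq(-6, -0.5, length.out = 12),
                       window = 420L, nBins = 21L, binWidth = 20L) {
  N <- length(experiments)
  if (N < 2) stop("at least 2 experiments are needed for a standard error")
  alphas <- sort(alphas)
  tprM <- matrix(0, nrow = N, ncol = length(alphas))
  fprM <- matrix(0, nrow = N, ncol = length(alphas))
  for (e in seq_len(N)) {
    for (a in seq_along(alphas)) {
      filt <- lapply(experiments[[e]], function(h)
        h[h$pValue < alphas[a], , drop = FALSE])
      bp <- binProfile(filt, window = window, nBins = nBins,
                       binWidth = binWidth)
      tp <- as.integer(bp$predictedTrue)
      fp <- length(setdiff(bp$positives, bp$trueBin))
      fn <- 1L - tp
      tn <- (nBins - 1L) - fp
      tprM[e, a] <- tp / (tp + fn)
      fprM[e, a] <- fp / (fp + tn)
    }
  }
  curve <- data.frame(alpha = alphas,
                      tpr = colMeans(tprM), fpr = colMeans(fprM),
                      tprSe = apply(tprM, 2, sd) / sqrt(N),
                      fprSe = apply(fprM, 2, sd) / sqrt(N))
  xs <- c(0, curve$fpr, 1); ys <- c(0, curve$tpr, 1)
  ord <- order(xs, ys)
  xs <- xs[ord]; ys <- ys[ord]
  auroc <- sum(diff(xs) * (head(ys, -1) + ys[-1]) / 2)
  list(curve = curve, auroc = auroc, n = N)
}
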