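# Motif-motif comparison: optimal ungapped alignment over offsets and
# orientations, an empirical resampled null, and the similarity score
# -log10(p).

# per-column standardized matrices -> column-by-column Pearson matrix;
# constant columns get correlation 0 against everything
colCorMatrix <- function(a, b) {
  za <- scale(a); zb <- scale(b)
  za[, attr(za, "scaled:scale") == 0] <- 0
  zb[, attr(zb, "scaled:scale") == 0] <- 0
  za[is.na(za)] <- 0; zb[is.na(zb)] <- 0
  crossprod(za, zb) / 3
}

# best ungapped alignment of query columns against target columns
# (one orientation); offset o means query col k aligns target col k+o
alignBestOffset <- function(corM, overlapMin) {
  nq <- nrow(corM); nt <- ncol(corM)
  best <- NULL
  for (o in seq(-(nq - overlapMin), nt - overlapMin)) {
    k <- max(1L, 1L - o):min(nq, nt - o)
    if (length(k) < overlapMin) next
    s <- sum(corM[cbind(k, k + o)])
    if (is.null(best) || s > best$similarity + 1e-12 ||
        (abs(s - best$similarity) <= 1e-12 && abs(o) < abs(best$offset))) {
      best <- list(similarity = s, offset = o, overlap = length(k))
    }
  }
  best
}

# optimal alignment over both orientations of the target
bestAlignment <- function(qm, tm, overlapMin = 4) {
  if (min(ncol(qm), ncol(tm)) < overlapMin)
    stop("overlap impossible: motifs shorter than the minimum overlap")
  fw <- alignBestOffset(colCorMatrix(qm, tm), overlapMin)
  tmRc <- tm[4:1, rev(seq_len(ncol(tm))), drop = FALSE]
  rv <- alignBestOffset(colCorMatrix(qm, tmRc), overlapMin)
  pick <- function(a, b) {
    if (is.null(a)) return(b)
    if (is.null(b)) return(a)
    if (a$similarity >= b$similarity - 1e-12 &&
        (a$similarity > b$similarity + 1e-12 ||
         abs(a$offset) <= abs(b$offset))) a else b
  }
  if (!is.null(fw)) fw$orientation <- "+"
  if (!is.null(rv)) rv$orientation <- "-"
  out <- pick(fw, rv)
  if (is.null(out)) stop("overlap impossible for these widths")
  out
}

# method-of-moments Dirichlet fit to motif database columns
fitDirichlet <- function(database) {
  if (is.null(database) || !length(database)) return(rep(1, 4))
  cols <- do.call(cbind, lapply(database, pwmMatrix))
  m <- rowMeans(cols)
  v <- apply(cols, 1, stats::var)
  ok <- v > 1e-12
  if (!any(ok)) return(rep(1, 4))
  a0 <- mean(m[ok] * (1 - m[ok]) / v[ok] - 1)
  a0 <- max(a0, 0.05)
  pmax(m * a0, 0.01)
}

sampleNullMotifs <- function(n, width, alpha) {
  lapply(seq_len(n), function(i) {
    g <- matrix(rgamma(4 * width, shape = alpha), nrow = 4)
    sweep(g, 2, colSums(g), "/")
  })
}

#' Compare two PWMs
#'
#' Finds the optimal ungapped alignment of the query against the target
#' over all offsets with at least \code{overlapMin} overlapping columns
#' and both orientations (target reverse-complemented); the column
#' similarity is the Pearson correlation of the probability 4-vectors
#' and the alignment similarity is its sum over the overlap. The
#' p-value is the fraction of \code{nNull} random motifs of the query's
#' width (columns resampled from a Dirichlet fitted to the target
#' database) achieving an optimal alignment at least as good, with the
#' +1/(nNull+1) correction, and the similarity score is -log10(p).
#' Ties in the optimum are broken by smaller absolute offset, then the
#' + orientation.
#'
#' @param query,target \linkS4class{PWMotif} objects.
#' @param database optional motif list used to fit the null column
#'   distribution (default: uniform Dirichlet).
#' @param nNull null sample size.
#' @param overlapMin minimum overlap columns (default 4).
#' @param seed RNG seed for the null sample.
#' @param nullOptima precomputed null optima (internal reuse across
#'   batch comparisons).
#' @return list of class \code{MotifMatch}: \code{query}, \code{target},
#'   \code{offset}, \code{orientation}, \code{overlap},
#'   \code{similarity}, \code{pValue}, \code{score}.
#' @export
comparePWMs <- function(query, target, database = NULL, nNull = 1000L,
                        overlapMin = 4L, seed = 1L, nullOptima = NULL) {
  qm <- pwmMatrix(query); tm <- pwmMatrix(target)
  obs <- bestAlignment(qm, tm, overlapMin)
  if (is.null(nullOptima)) {
    alpha <- fitDirichlet(database)
    nulls <- withLocalSeed(seed, sampleNullMotifs(nNull, ncol(qm), alpha))
    nullOptima <- vapply(nulls, function(nm)
      bestAlignment(nm, tm, overlapMin)$similarity, numeric(1))
  }
  p <- (1 + sum(nullOptima >= obs$similarity - 1e-12)) /
    (length(nullOptima) + 1)
  structure(list(query = pwmId(query), target = pwmId(target),
                 offset = obs$offset, orientation = obs$orientation,
                 overlap = obs$overlap, similarity = obs$similarity,
                 pValue = p, score = -log10(p)),
            class = "MotifMatch")
}

#' @export
print.MotifMatch <- function(x, ...) {
  cat(sprintf("MotifMatch %s vs %s: offset %+d (%s), similarity %.3f, p = %.4g, score %.3f\n",
              x$query, x$target, x$offset, x$orientation, x$similarity,
              x$pValue, x$score))
  invisible(x)
}

#' Significance of a motif match
#'
#' @param match a \code{MotifMatch}.
#' @param alpha significance level; strict inequality (p = alpha is not
#'   significant).
#' @return logical.
#' @export
isSignificant <- function(match, alpha = 0.05) {
  match$pValue < alpha
}

#' Batch motif comparison
#'
#' Compares every query against every target, reusing one null sample
#' per (query width, target) pair.
#'
#' @param queries,targets lists of \linkS4class{PWMotif}.
#' @param database motif list for the null fit (default: the targets).
#' @param nNull,overlapMin,seed see \code{\link{comparePWMs}}.
#' @param qvalues add Benjamini-Hochberg adjusted p-values (off by
#'   default).
#' @return data.frame: query, target, offset, orientation, overlap,
#'   similarity, pValue, score (and qValue when requested).
#' @export
batchCompare <- function(queries, targets, database = targets,
                         nNull = 200L, overlapMin = 4L, seed = 1L,
                         qvalues = FALSE) {
  alpha <- fitDirichlet(database)
  widths <- unique(vapply(queries, pwmWidth, numeric(1)))
  nullsByWidth <- withLocalSeed(seed, {
    stats::setNames(lapply(widths, function(w)
      sampleNullMotifs(nNull, w, alpha)), as.character(widths))
  })
  optCache <- new.env(parent = emptyenv())
  rows <- list()
  for (q in queries) {
    w <- as.character(pwmWidth(q))
    for (t in targets) {
      key <- paste(w, pwmId(t), sep = "@")
      if (is.null(optCache[[key]])) {
        tm <- pwmMatrix(t)
        optCache[[key]] <- vapply(nullsByWidth[[w]], function(nm)
          bestAlignment(nm, tm, overlapMin)$similarity, numeric(1))
      }
      m <- comparePWMs(q, t, nNull = nNull, overlapMin = overlapMin,
                       nullOptima = optCache[[key]])
      rows[[length(rows) + 1L]] <- as.data.frame(unclass(m),
                                                 stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  if (qvalues) df$qValue <- stats::p.adjust(df$pValue, method = "BH")
  df
}
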