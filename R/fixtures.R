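# Synthetic-data generators: toy TF-DNA complexes with planted contact
# geometry, PBM 8-mer tables with planted positives, and motif
# databases. Everything the test-suite consumes is built by these
# functions; no downloads are involved. Geometry aims only to satisfy
# the contact definition (an ideal B-form duplex: rise 3.4 A, twist 36
# degrees), not physical realism.

#' Generate a toy TF-DNA complex in PDB format
#'
#' Builds an ideal B-DNA duplex (rise 3.4 A, twist 36 degrees per step,
#' two antiparallel chains written 5'->3') plus protein residues placed
#' so that each planted contact's Cbeta-to-step-centroid distance
#' matches the request to within 0.01 A. An optional extra protein
#' segment with ideal helical, extended or coil backbone dihedrals can
#' be appended (placed far from the DNA so it adds no contacts).
#'
#' @param spec a list with elements:
#'   \describe{
#'     \item{seed}{RNG seed (only used when \code{dnaSeq} is absent).}
#'     \item{dnaLength}{duplex length in bp (default 12).}
#'     \item{dnaSeq}{leading-strand sequence; random if NULL.}
#'     \item{plantedContacts}{data.frame with columns \code{step},
#'       \code{distance}, and optionally \code{aa} (1-letter, default L)
#'       and \code{side} (\code{"radial"}, \code{"axial"},
#'       \code{"major"}, \code{"minor"}).}
#'     \item{nResidues}{size of the extra backbone segment (default 0).}
#'     \item{backbone}{"helix", "extended" or "coil" for that segment.}
#'     \item{mismatchAt}{optional position at which the complementary
#'       base is made non-complementary (flagged by the parser).}
#'   }
#' @return A single string of PDB-format text.
#' @export
makeComplex <- function(spec = list()) {
  L <- spec$dnaLength %||% 12L
  seed <- spec$seed %||% 1L
  seq <- spec$dnaSeq %||% withLocalSeed(seed,
    paste(sample(DNA_BASES, L, replace = TRUE), collapse = ""))
  stopifnot(nchar(seq) == L, L >= 2)
  bases <- strsplit(seq, "")[[1]]
  compBases <- unname(COMPLEMENT[bases])
  if (!is.null(spec$mismatchAt)) {
    m <- spec$mismatchAt
    compBases[m] <- if (compBases[m] == "C") "A" else "C"
  }

  theta <- (seq_len(L) - 1L) * 36 * pi / 180
  zz <- (seq_len(L) - 1L) * 3.4

  baseAtomRows <- list(); bbRows <- list()
  mkBase <- function(b, center, rhat, that) {
    gt <- GROOVE_TABLE[[b]]
    nm <- names(gt)
    tOff <- (seq_along(nm) - (length(nm) + 1) / 2) * 0.22
    sgn <- ifelse(gt == "major", 1, -1)
    data.frame(atom = nm,
               x = center[1] + sgn * 0.9 * rhat[1] + tOff * that[1],
               y = center[2] + sgn * 0.9 * rhat[2] + tOff * that[2],
               z = center[3] + sgn * 0.8,
               stringsAsFactors = FALSE)
  }
  bbNames <- c("P", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "C1'")
  mkBackbone <- function(center, rhat, that) {
    rad <- seq(8.8, 5.6, length.out = length(bbNames))
    ax <- rhat[1] * rad; ay <- rhat[2] * rad
    data.frame(atom = bbNames,
               x = ax + that[1] * 0.3 * seq_along(bbNames),
               y = ay + that[2] * 0.3 * seq_along(bbNames),
               z = center[3] + 0.1 * seq_along(bbNames),
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(L)) {
    rh <- c(cos(theta[i]), sin(theta[i]), 0)
    th <- c(-sin(theta[i]), cos(theta[i]), 0)
    cen <- c(2 * rh[1], 2 * rh[2], zz[i])
    ba <- mkBase(bases[i], cen, rh, th)
    ba$chain <- "B"; ba$resno <- i; ba$resid <- paste0("D", bases[i])
    bb <- mkBackbone(cen, rh, th)
    bb$chain <- "B"; bb$resno <- i; bb$resid <- paste0("D", bases[i])
    # paired complement at a rotated position, same rise
    th2 <- theta[i] + 154 * pi / 180
    rh2 <- c(cos(th2), sin(th2), 0)
    tt2 <- c(-sin(th2), cos(th2), 0)
    cen2 <- c(2 * rh2[1], 2 * rh2[2], zz[i])
    ba2 <- mkBase(compBases[i], cen2, rh2, tt2)
    j <- L - i + 1L   # chain C is written in its own 5'->3' order
    ba2$chain <- "C"; ba2$resno <- j; ba2$resid <- paste0("D", compBases[i])
    bb2 <- mkBackbone(cen2, rh2, tt2)
    bb2$chain <- "C"; bb2$resno <- j; bb2$resid <- paste0("D", compBases[i])
    baseAtomRows <- c(baseAtomRows, list(ba, ba2))
    bbRows <- c(bbRows, list(bb, bb2))
  }
  dnaAtoms <- do.call(rbind, c(bbRows, baseAtomRows))

  # step centroids exactly as the parser computes them
  allBase <- do.call(rbind, baseAtomRows)
  leadPos <- function(resno, chain) if (chain == "B") resno else L - resno + 1L
  allBase$pos <- ifelse(allBase$chain == "B", allBase$resno,
                        L - allBase$resno + 1L)
  stepCentroid <- function(s) {
    sub <- allBase[allBase$pos %in% c(s, s + 1L), ]
    c(mean(sub$x), mean(sub$y), mean(sub$z))
  }

  protRows <- list()
  planted <- spec$plantedContacts
  resCounter <- 0L
  if (!is.null(planted) && nrow(planted)) {
    if (is.null(planted$aa)) planted$aa <- "L"
    if (is.null(planted$side)) planted$side <- "radial"
    for (k in seq_len(nrow(planted))) {
      s <- planted$step[k]; d <- planted$distance[k]
      cen <- stepCentroid(s)
      midTheta <- (theta[s] + theta[s + 1L]) / 2
      rh <- c(cos(midTheta), sin(midTheta), 0)
      u <- switch(planted$side[k],
        radial = rh,
        axial = c(0, 0, 1),
        major = unitv(0.5 * rh + c(0, 0, 1)),
        minor = unitv(0.5 * rh - c(0, 0, 1)))
      cb <- cen + d * u
      ca <- cb + 1.53 * u
      tv <- if (abs(u[3]) > 0.99) c(1, 0, 0) else unitv(vcross(u, c(0, 0, 1)))
      wv <- unitv(vcross(u, tv))
      nAt <- ca + 1.46 * tv
      cAt <- ca + 1.52 * (-cos(69 * pi / 180) * tv + sin(69 * pi / 180) * wv)
      oAt <- cAt + 1.23 * wv
      resCounter <- resCounter + 1L
      aa3 <- AA1TO3[[planted$aa[k]]]
      protRows[[length(protRows) + 1L]] <- data.frame(
        atom = c("N", "CA", "C", "O", "CB"),
        x = c(nAt[1], ca[1], cAt[1], oAt[1], cb[1]),
        y = c(nAt[2], ca[2], cAt[2], oAt[2], cb[2]),
        z = c(nAt[3], ca[3], cAt[3], oAt[3], cb[3]),
        chain = "A", resno = resCounter, resid = aa3,
        stringsAsFactors = FALSE)
    }
  }
  # always emit a parseable protein chain (>= 3 residues)
  nRes <- max(spec$nResidues %||% 0L, 3L - resCounter)
  if (nRes > 0L) {
    bk <- spec$backbone %||% "helix"
    ang <- switch(bk, helix = c(-57, -47), extended = c(-139, 135),
                  coil = c(-150, 60))
    aa <- spec$segmentAA %||% "A"
    ch <- buildIdealChain(nRes, phi = ang[1], psi = ang[2], aa = aa,
                          origin = c(60, 0, 0))
    ch$chain <- "A"; ch$resno <- ch$resno + resCounter
    ch$resid <- AA1TO3[ch$aa]
    protRows[[length(protRows) + 1L]] <-
      ch[, c("elety", "x", "y", "z", "chain", "resno", "resid")] |>
      (\(d) { names(d)[1] <- "atom"; d })()
  }
  protAtoms <- if (length(protRows)) do.call(rbind, protRows) else NULL

  fmt <- function(df, startSerial) {
    el <- substr(df$atom, 1, 1)
    nm <- ifelse(nchar(df$atom) < 4, paste0(" ", df$atom), df$atom)
    sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            startSerial + seq_len(nrow(df)) - 1L, nm, df$resid, df$chain,
            df$resno, df$x, df$y, df$z, 1, 0, el)
  }
  lines <- character(0)
  serial <- 1L
  if (!is.null(protAtoms)) {
    lines <- c(lines, fmt(protAtoms, serial))
    serial <- serial + nrow(protAtoms)
  }
  lines <- c(lines, fmt(dnaAtoms, serial), "END")
  paste(lines, collapse = "\n")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic PBM 8-mer experiment
#'
#' Positive 8-mers are drawn from a planted motif (the consensus is
#' always seeded first) with E-scores uniform in (0.455, 0.50); negative
#' 8-mers come from the uniform background with E-scores in
#' (-0.50, 0.36); an optional discarded band gets E-scores in
#' [0.37, 0.45]. All kmers are distinct, so the E-score filter recovers
#' the planted partition exactly.
#'
#' @param motif a \linkS4class{PWMotif} of width >= 8 (the first 8
#'   columns are used).
#' @param nPositive,nNegative,nDiscarded set sizes.
#' @param seed RNG seed.
#' @param tfId identifier.
#' @return A \code{PbmExperiment}: list with \code{tfId} and
#'   \code{records} (data.frame \code{kmer}, \code{escore}).
#' @export
makePBM <- function(motif, nPositive = 10, nNegative = 50,
                    nDiscarded = 0, seed = 1, tfId = "TF1") {
  stopifnot(pwmWidth(motif) >= 8)
  m <- pwmMatrix(motif)[, 1:8, drop = FALSE]
  withLocalSeed(seed, {
    pos <- character(0)
    if (nPositive >= 1) pos <- consensus(pwMotif(m))
    guard <- 0
    while (length(pos) < nPositive && guard < 10000) {
      k <- paste(vapply(1:8, function(j)
        sample(DNA_BASES, 1, prob = m[, j]), character(1)), collapse = "")
      if (!k %in% pos) pos <- c(pos, k)
      guard <- guard + 1
    }
    rand8 <- function(n, avoid) {
      out <- character(0)
      while (length(out) < n) {
        k <- paste(sample(DNA_BASES, 8, replace = TRUE), collapse = "")
        if (!k %in% avoid && !k %in% out) out <- c(out, k)
      }
      out
    }
    neg <- rand8(nNegative, pos)
    dis <- rand8(nDiscarded, c(pos, neg))
    rec <- data.frame(
      kmer = c(pos, neg, dis),
      escore = c(runif(length(pos), 0.455, 0.50),
                 runif(length(neg), -0.50, 0.36),
                 if (nDiscarded) runif(nDiscarded, 0.37, 0.45)),
      stringsAsFactors = FALSE)
    pbmExperiment(rec$kmer, rec$escore, tfId = tfId)
  })
}

#' Generate a synthetic motif database
#'
#' Motif columns are sampled from a Dirichlet distribution; a given
#' motif can be embedded as the first entry.
#'
#' @param n number of motifs.
#' @param widths motif widths (recycled).
#' @param seed RNG seed.
#' @param embed optional \linkS4class{PWMotif} placed first.
#' @param alpha Dirichlet concentration (length 4).
#' @return Named list of \linkS4class{PWMotif}.
#' @export
makeMotifDb <- function(n, widths = 8, seed = 1, embed = NULL,
                        alpha = c(0.5, 0.5, 0.5, 0.5)) {
  widths <- rep_len(widths, n)
  db <- withLocalSeed(seed, {
    lapply(seq_len(n), function(i) {
      w <- widths[i]
      g <- matrix(rgamma(4 * w, shape = alpha), nrow = 4)
      pwMotif(sweep(g, 2, colSums(g), "/"), id = sprintf("M%03d", i),
              source = "experimental")
    })
  })
  if (!is.null(embed) && n >= 1) db[[1]] <- embed
  names(db) <- vapply(db, pwmId, character(1))
  db
}

#' Generate a synthetic TF family for the 8-mer classification benchmark
#'
#' Builds \code{nTFs} toy complexes sharing one planted binding
#' preference (the family consensus): every TF contacts the same eight
#' binding-site positions through the same amino acid per step, but at
#' TF-specific distances, so the per-TF contact fingerprints differ
#' while the pooled family potential encodes the planted consensus.
#' Each TF's positive 8-mers are the consensus and four single-base
#' mutants of it.
#'
#' @param nTFs family size (default 12).
#' @param consensusSeq planted 8-mer consensus.
#' @param seed RNG seed.
#' @param enrichment planted fold enrichment.
#' @return list of TF entries \code{list(id, family, table, contacts,
#'   positives)} suitable for \code{\link{kmerBenchmark}}.
#' @export
makeKmerBenchmarkData <- function(nTFs = 12L, consensusSeq = "ACGTAGGC",
                                  seed = 1L, enrichment = 5) {
  stopifnot(nchar(consensusSeq) == 8)
  stepAA <- c("R", "K", "N", "Q", "S", "E", "D")
  lapply(seq_len(nTFs), function(i) {
    tfSeed <- seed * 100L + i
    dists <- withLocalSeed(tfSeed,
      sample(c(3.3, 4.4, 5.5, 6.6), 7, replace = TRUE))
    pc <- data.frame(step = 1:7, distance = dists, aa = stepAA,
                     side = "radial", stringsAsFactors = FALSE)
    x <- parseComplex(makeComplex(list(seed = tfSeed, dnaLength = 8L,
                                       dnaSeq = consensusSeq,
                                       plantedContacts = pc)),
                      sourceId = sprintf("TF%02d", i))
    cc <- extractContacts(x, maxRadius = 30)
    tab <- plantedPreferenceTable(cc, consensusSeq,
                                  enrichment = enrichment)
    cb <- strsplit(consensusSeq, "")[[1]]
    mutAt <- c(1, 3, 5, 7)
    positives <- c(consensusSeq, vapply(mutAt, function(p) {
      b <- cb
      b[p] <- setdiff(DNA_BASES, b[p])[(tfSeed + p) %% 3 + 1]
      paste(b, collapse = "")
    }, character(1)))
    list(id = sprintf("TF%02d", i), family = "SYN", table = tab,
         contacts = cc, positives = unique(positives))
  })
}

#' Build a contact table with a planted dinucleotide preference
#'
#' For every extracted contact, all 16 dinucleotides receive
#' \code{baseCount} counts at the contact's (aa, env, bin) cell and the
#' dinucleotide dictated by the planted consensus at that step receives
#' \code{enrichment} times as many. A potential trained on this table
#' must rank the planted dinucleotide best at every step, which is the
#' closed-loop parameter-recovery fixture.
#'
#' @param contacts contact data.frame from \code{\link{extractContacts}}.
#' @param consensusSeq planted consensus sequence covering the contacted
#'   steps' span.
#' @param enrichment fold enrichment of the planted dinucleotide.
#' @param baseCount baseline count per cell.
#' @param maxRadius,binWidth table geometry.
#' @return A \linkS4class{ContactTable} (provenance "pdb").
#' @export
plantedPreferenceTable <- function(contacts, consensusSeq, enrichment = 5,
                                   baseCount = 20, maxRadius = 30,
                                   binWidth = 1) {
  nbins <- ceiling(maxRadius / binWidth)
  counts <- emptyContactCounts(nbins)
  smin <- min(contacts$step)
  for (k in seq_len(nrow(contacts))) {
    s <- contacts$step[k]
    j <- s - smin + 1L
    dj <- substr(consensusSeq, j, j + 1L)
    stopifnot(nchar(dj) == 2)
    bin <- min(nbins, max(1L, ceiling(contacts$distance[k] / binWidth)))
    ai <- match(contacts$aa[k], AA1)
    ei <- contacts$env[k]
    counts[ai, , ei, bin, "pdb"] <- counts[ai, , ei, bin, "pdb"] + baseCount
    di <- match(dj, DINUCS)
    counts[ai, di, ei, bin, "pdb"] <-
      counts[ai, di, ei, bin, "pdb"] + (enrichment - 1) * baseCount
  }
  new("ContactTable", counts = counts, binning = "interval",
      binWidth = binWidth, maxRadius = maxRadius)
}
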