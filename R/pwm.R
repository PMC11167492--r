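# PWM prediction from a scored TF-DNA complex: candidate binding
# sequences are scored by the sum of per-contact Z-scores, which
# decomposes over adjacent dinucleotide steps, so the search space is a
# chain with 16-state nodes and overlap-consistency edges.

# Per-step dinucleotide score matrix: 16 x (#chain steps). Chain step j
# corresponds to structural step smin+j-1; steps without contacts
# contribute zero. Site length L = span + 1 nucleotides.
stepScoreMatrix <- function(potential, contacts) {
  keep <- contacts$distance < potential@config$radius
  cc <- contacts[keep, , drop = FALSE]
  if (!nrow(cc)) stop("no contacts within the potential radius")
  smin <- min(cc$step); smax <- max(cc$step)
  nstep <- smax - smin + 1L
  mat <- matrix(0, nrow = 16L, ncol = nstep,
                dimnames = list(DINUCS, NULL))
  bins <- contactBins(potential, cc$distance)
  for (k in seq_len(nrow(cc))) {
    j <- cc$step[k] - smin + 1L
    mat[, j] <- mat[, j] +
      potential@zscores[match(cc$aa[k], AA1), , cc$env[k], bins[k]]
  }
  list(mat = mat, smin = smin, siteLength = nstep + 1L)
}

# score a vector of sequences (all of length ncol(mat)+1) against a
# step score matrix; lower = better
scoreSequencesOnSteps <- function(seqs, mat) {
  L <- ncol(mat) + 1L
  ints <- t(vapply(strsplit(seqs, ""),
                   function(s) match(s, DNA_BASES), integer(L)))
  if (L == 1L) ints <- matrix(ints, ncol = 1L)
  tot <- numeric(length(seqs))
  for (j in seq_len(L - 1L)) {
    didx <- ints[, j] + 4L * (ints[, j + 1L] - 1L)
    tot <- tot + mat[cbind(didx, j)]
  }
  tot
}

# dinucleotide index convention: dinuc "xy" (x = 5' base) has index
# match(x, bases) + 4*(match(y, bases)-1), consistent with DINUCS order
# outer(bases, bases, paste0) read column-wise.

intToSeq <- function(code, L) {
  # code in 0..4^L-1; digit j (least significant first) = base at pos j
  out <- character(length(code))
  digits <- matrix(0L, nrow = length(code), ncol = L)
  x <- code
  for (j in seq_len(L)) {
    digits[, j] <- x %% 4
    x <- x %/% 4
  }
  apply(digits, 1, function(d) paste(DNA_BASES[d + 1L], collapse = ""))
}

#' Enumerate or search candidate binding sequences and score them
#'
#' The binding site spans the contacted dinucleotide steps (site length
#' = span + 1 nucleotides). In exhaustive mode all 4^L sequences are
#' scored by the summed per-contact Z-score (lower = more favorable).
#' Because the score decomposes over adjacent dinucleotide steps,
#' \code{dp_topk} mode returns the exact top K sequences by dynamic
#' programming over a chain of 16-state nodes with overlap-consistency
#' edges; with K = 4^L it reproduces the exhaustive ranking exactly.
#' Scores are min-max normalized to [0, 1] with 1 = best; if all
#' sequences tie, every normalized score is 1.
#'
#' @param potential a \linkS4class{StatPotential}.
#' @param contacts contact data.frame of the complex.
#' @param mode "exhaustive" or "dp_topk".
#' @param K number of sequences returned in dp_topk mode.
#' @param maxExhaustive refuse exhaustive enumeration beyond this site
#'   length (default 12).
#' @return data.frame of scored sequences: \code{sequence}, \code{raw},
#'   \code{normalized}, \code{rank} (1 = best; ties broken
#'   alphabetically).
#' @export
enumerateAndScore <- function(potential, contacts,
                              mode = c("exhaustive", "dp_topk"),
                              K = 1000L, maxExhaustive = 12L) {
  mode <- match.arg(mode)
  ss <- stepScoreMatrix(potential, contacts)
  L <- ss$siteLength
  if (L < 1) stop("binding site length must be >= 1")
  if (mode == "exhaustive") {
    if (L > maxExhaustive)
      stop("exhaustive enumeration limited to site length <= ", maxExhaustive)
    code <- 0:(4^L - 1)
    # digit j = base at position j
    raw <- numeric(length(code))
    baseAt <- function(j) (code %/% 4^(j - 1)) %% 4
    for (j in seq_len(L - 1L)) {
      didx <- baseAt(j) + 4L * baseAt(j + 1L) + 1L
      raw <- raw + ss$mat[cbind(didx, j)]
    }
    seqs <- intToSeq(code, L)
  } else {
    res <- dpTopK(ss$mat, L, K)
    raw <- res$score
    seqs <- intToSeq(res$code, L)
  }
  finishScores(seqs, raw)
}

finishScores <- function(seqs, raw) {
  rng <- range(raw)
  normalized <- if (rng[2] > rng[1]) (rng[2] - raw) / (rng[2] - rng[1])
  else rep(1, length(raw))
  ord <- order(raw, seqs)
  df <- data.frame(sequence = seqs, raw = raw, normalized = normalized,
                   stringsAsFactors = FALSE)[ord, ]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

# exact top-K over the dinucleotide chain; state = base at current
# position, each state holds its K best (score, sequence-code) partial
# paths, ties broken by code (i.e. alphabetical sequence order).
dpTopK <- function(mat, L, K) {
  K <- min(K, 4^L)
  if (L == 1L) {
    return(list(score = rep(0, min(K, 4)), code = 0:(min(K, 4) - 1)))
  }
  # initialise with position 1
  states <- lapply(0:3, function(b) list(score = 0, code = b))
  for (j in 2:L) {
    newStates <- vector("list", 4)
    for (b2 in 0:3) {
      sc <- c(); cd <- c()
      for (b1 in 0:3) {
        st <- states[[b1 + 1L]]
        w <- mat[b1 + 1L + 4L * b2, j - 1L]
        sc <- c(sc, st$score + w)
        cd <- c(cd, st$code + b2 * 4^(j - 1))
      }
      ord <- order(sc, cd)[seq_len(min(K, length(sc)))]
      newStates[[b2 + 1L]] <- list(score = sc[ord], code = cd[ord])
    }
    states <- newStates
  }
  sc <- unlist(lapply(states, `[[`, "score"))
  cd <- unlist(lapply(states, `[[`, "code"))
  ord <- order(sc, cd)[seq_len(min(K, length(sc)))]
  list(score = sc[ord], code = cd[ord])
}

#' Build a PWM from top-scoring sequences
#'
#' Sequences with normalized score at or above the threshold are
#' selected; column j of the PWM is the frequency of each base at
#' position j among the selected sequences, with a pseudocount of 0.01
#' per cell added before normalization.
#'
#' @param scored data.frame from \code{\link{enumerateAndScore}}.
#' @param threshold selection cut-off on the normalized score, in
#'   [0.7, 1].
#' @param id motif id.
#' @return A \linkS4class{PWMotif} with \code{source = "predicted"}.
#' @export
buildPWM <- function(scored, threshold = 0.95, id = "predicted") {
  sel <- scored$sequence[scored$normalized >= threshold]
  if (!length(sel)) stop("threshold too high: empty selection")
  L <- nchar(sel[1])
  m <- matrix(0.01, nrow = 4, ncol = L, dimnames = list(DNA_BASES, NULL))
  for (s in sel) {
    b <- strsplit(s, "")[[1]]
    for (j in seq_len(L)) m[b[j], j] <- m[b[j], j] + 1
  }
  pwMotif(sweep(m, 2, colSums(m), "/"), id = id, source = "predicted",
          nsites = length(sel))
}

#' Predict a PWM from an annotated complex in one call
#'
#' Convenience wrapper: extract contacts, score candidate sequences and
#' build the PWM with the family configuration's threshold.
#'
#' @param x a \linkS4class{TFComplex}.
#' @param potential a \linkS4class{StatPotential}.
#' @param threshold selection threshold (default from the potential's
#'   config).
#' @param mode search mode, see \code{\link{enumerateAndScore}}.
#' @param K top-K size for dp_topk.
#' @return A \linkS4class{PWMotif}.
#' @export
predictPWM <- function(x, potential, threshold = NULL,
                       mode = c("dp_topk", "exhaustive"), K = 1000L) {
  mode <- match.arg(mode)
  threshold <- threshold %||% potential@config$threshold %||% 0.95
  contacts <- extractContacts(x, maxRadius = potential@config$radius)
  scored <- enumerateAndScore(potential, contacts, mode = mode, K = K)
  buildPWM(scored, threshold = threshold, id = x@sourceId)
}

## ---- MEME minimal motif format ----

#' Write motifs in MEME minimal format
#'
#' @param pwms a \linkS4class{PWMotif} or list of them.
#' @param file optional output path; when NULL the text is returned.
#' @return The MEME text (invisibly when written to file).
#' @export
writeMEME <- function(pwms, file = NULL) {
  if (is(pwms, "PWMotif")) pwms <- list(pwms)
  bg <- pwms[[1]]@background
  txt <- c("MEME version 4", "",
           "ALPHABET= ACGT", "",
           "strands: + -", "",
           "Background letter frequencies",
           sprintf("A %.6f C %.6f G %.6f T %.6f", bg[1], bg[2], bg[3], bg[4]),
           "")
  for (p in pwms) {
    m <- pwmMatrix(p)
    txt <- c(txt,
             paste("MOTIF", p@id),
             sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                     ncol(m), max(1, round(p@nsites))),
             apply(m, 2, function(col)
               sprintf(" %.6f %.6f %.6f %.6f", col[1], col[2], col[3], col[4])),
             "")
  }
  out <- paste(txt, collapse = "\n")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Read motifs from MEME minimal format
#'
#' Parses letter-probability matrix blocks and the background line.
#' Columns must sum to 1 within 1e-3 (they are renormalized exactly);
#' otherwise the motif is rejected with a normalization error.
#' Malformed headers raise a parse error naming the offending line.
#'
#' @param x MEME text, vector of lines, or a file path.
#' @return Named list of \linkS4class{PWMotif} with
#'   \code{source = "experimental"}.
#' @export
readMEME <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    lines <- readLines(x)
  } else {
    lines <- unlist(strsplit(paste(x, collapse = "\n"), "\n"))
  }
  if (!length(lines) || !grepl("^MEME version", lines[1]))
    stop("parse error at line 1: missing 'MEME version' header")
  bg <- rep(0.25, 4)
  bgi <- grep("^Background letter frequencies", lines)
  if (length(bgi) && bgi[1] < length(lines)) {
    tok <- strsplit(trimws(lines[bgi[1] + 1L]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(tok[seq(2, length(tok), by = 2)]))
    if (length(vals) == 4 && !anyNA(vals)) bg <- vals
  }
  starts <- grep("^MOTIF\\b", lines)
  out <- list()
  for (s in starts) {
    tok <- strsplit(trimws(lines[s]), "\\s+")[[1]]
    if (length(tok) < 2)
      stop("parse error at line ", s, ": MOTIF line lacks an identifier")
    id <- tok[2]
    h <- s + 1L
    while (h <= length(lines) && !grepl("^letter-probability matrix", lines[h])) {
      if (grepl("^MOTIF\\b", lines[h]))
        stop("parse error at line ", h, ": motif ", id,
             " has no letter-probability matrix")
      h <- h + 1L
    }
    if (h > length(lines))
      stop("parse error: motif ", id, " has no letter-probability matrix")
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[h]))
    ns <- suppressWarnings(as.numeric(sub(".*nsites=\\s*([0-9.]+).*", "\\1",
                                          lines[h])))
    if (is.na(w))
      stop("parse error at line ", h, ": cannot read motif width")
    rows <- lines[(h + 1L):(h + w)]
    m <- t(vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]][1:4]), numeric(4)))
    if (anyNA(m))
      stop("parse error after line ", h, ": malformed probability row")
    cs <- rowSums(m)
    if (any(abs(cs - 1) > 1e-3))
      stop("normalization error in motif ", id,
           ": column(s) sum to ", paste(round(cs[abs(cs - 1) > 1e-3], 3),
                                        collapse = ","))
    out[[id]] <- pwMotif(t(m), id = id, source = "experimental",
                         background = bg,
                         nsites = if (is.na(ns)) 0 else ns)
  }
  out
}
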