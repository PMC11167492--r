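#' Extract amino-acid / dinucleotide contacts from an annotated complex
#'
#' A contact joins one amino acid and one dinucleotide step (two
#' contiguous nucleotides of the leading strand plus their complements).
#' Its distance is measured from the residue's Cbeta atom to the
#' unweighted mean position of the nitrogen-base atoms of the four
#' nucleotides of the step. One contact is emitted per (residue, step)
#' pair with distance strictly below \code{maxRadius}; the groove label
#' is the groove whose atom set contains the base atom nearest to the
#' Cbeta, and the strand side records whether that nearest atom belongs
#' to the leading or the complementary strand.
#'
#' @param x a \linkS4class{TFComplex} (fully annotated).
#' @param maxRadius retain contacts with distance < this many Angstrom
#'   (default 30).
#' @return data.frame with one row per contact: \code{residue} (row
#'   index into \code{proteinResidues(x)}), \code{chain}, \code{resno},
#'   \code{aa}, \code{step}, \code{dinuc}, \code{distance},
#'   \code{hydrophobicity}, \code{ss}, \code{exposure}, \code{groove},
#'   \code{strandSide}, \code{env} (class id 1..48) and
#'   \code{provenance} ("pdb").
#' @export
extractContacts <- function(x, maxRadius = 30) {
  res <- x@residues
  st <- x@steps
  st <- st[!is.na(st$dinuc), , drop = FALSE]
  out <- list()
  if (!nrow(res) || !nrow(st) || maxRadius <= 0) {
    return(emptyContactsDf())
  }
  cb <- as.matrix(res[, c("cbx", "cby", "cbz")])
  cen <- as.matrix(st[, c("cx", "cy", "cz")])
  ba <- x@baseAtoms
  ba <- ba[!is.na(ba$groove), , drop = FALSE]
  for (i in seq_len(nrow(res))) {
    d <- sqrt(colSums((t(cen) - cb[i, ])^2))
    hit <- which(d < maxRadius)
    for (h in hit) {
      s <- st$index[h]
      sub <- ba[ba$pos %in% c(s, s + 1L), , drop = FALSE]
      if (!nrow(sub)) next
      ad <- (sub$x - cb[i, 1])^2 + (sub$y - cb[i, 2])^2 +
        (sub$z - cb[i, 3])^2
      nearest <- which.min(ad)
      groove <- sub$groove[nearest]
      side <- sub$strand[nearest]
      out[[length(out) + 1L]] <- data.frame(
        residue = i, chain = res$chain[i], resno = res$resno[i],
        aa = res$aa[i], step = s, dinuc = st$dinuc[h],
        distance = d[h],
        hydrophobicity = res$hydrophobicity[i], ss = res$ss[i],
        exposure = res$exposure[i], groove = groove, strandSide = side,
        env = envClassId(res$hydrophobicity[i], res$ss[i],
                         res$exposure[i], groove, side),
        provenance = "pdb", stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(emptyContactsDf())
  rownames2 <- NULL
  df <- do.call(rbind, out)
  rownames(df) <- rownames2
  df
}

emptyContactsDf <- function() {
  data.frame(residue = integer(0), chain = character(0),
             resno = integer(0), aa = character(0), step = integer(0),
             dinuc = character(0), distance = numeric(0),
             hydrophobicity = character(0), ss = character(0),
             exposure = character(0), groove = character(0),
             strandSide = character(0), env = integer(0),
             provenance = character(0), stringsAsFactors = FALSE)
}

#' Count contacts into a ContactTable
#'
#' Interval binning puts a contact at distance d into bin x when
#' x-1 < d <= x (bin width 1 A by default); cumulative binning at
#' threshold x counts every contact with d <= x, so the cumulative count
#' at x equals the interval counts summed over bins 1..x.
#'
#' @param contacts contact data.frame from \code{\link{extractContacts}}
#'   (or \code{\link{extendContacts}}); the \code{provenance} column
#'   routes counts into the "pdb" or "pbm" layer.
#' @param binning "interval" or "cumulative".
#' @param binWidth bin width, Angstrom.
#' @param maxRadius largest distance retained.
#' @return A \linkS4class{ContactTable}.
#' @export
countContacts <- function(contacts, binning = c("interval", "cumulative"),
                          binWidth = 1, maxRadius = 30) {
  binning <- match.arg(binning)
  nbins <- ceiling(maxRadius / binWidth)
  counts <- emptyContactCounts(nbins)
  if (nrow(contacts)) {
    keep <- contacts$distance <= maxRadius & !is.na(contacts$dinuc)
    cc <- contacts[keep, , drop = FALSE]
    if (nrow(cc)) {
      bin <- pmax(1L, ceiling(cc$distance / binWidth))
      idx <- cbind(match(cc$aa, AA1), match(cc$dinuc, DINUCS), cc$env,
                   bin, match(cc$provenance, c("pdb", "pbm")))
      for (r in seq_len(nrow(idx)))
        counts[idx[r, 1], idx[r, 2], idx[r, 3], idx[r, 4], idx[r, 5]] <-
          counts[idx[r, 1], idx[r, 2], idx[r, 3], idx[r, 4], idx[r, 5]] + 1
    }
  }
  if (binning == "cumulative")
    counts <- aperm(apply(counts, c(1, 2, 3, 5), cumsum), c(2, 3, 4, 1, 5))
  dimnames(counts) <- dimnames(emptyContactCounts(nbins))
  new("ContactTable", counts = counts, binning = binning,
      binWidth = binWidth, maxRadius = maxRadius)
}

#' Merge contact tables by summing their counts
#' @param ... ContactTable objects with identical geometry.
#' @return A \linkS4class{ContactTable}.
#' @export
mergeContactTables <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1]]) && !is(tabs[[1]], "ContactTable"))
    tabs <- tabs[[1]]
  stopifnot(length(tabs) >= 1L)
  ref <- tabs[[1]]
  counts <- ref@counts
  for (t in tabs[-1]) {
    stopifnot(identical(dim(t@counts), dim(counts)),
              t@binning == ref@binning)
    counts <- counts + t@counts
  }
  new("ContactTable", counts = counts, binning = ref@binning,
      binWidth = ref@binWidth, maxRadius = ref@maxRadius)
}

#' Contact abundance score
#'
#' The coverage of the potential contact space: log10 of the ratio
#' between the total number of potential contact types (16 dinucleotides
#' x 20 amino acids x 48 environment classes = 15360) and the number of
#' distinct (dinucleotide, amino acid, environment) triples observed at
#' less than 30 A. A fully covered table scores 0; sparser tables score
#' higher, and adding distinct triples can only lower the score.
#'
#' @param table a \linkS4class{ContactTable}.
#' @return numeric score.
#' @export
contactAbundance <- function(table) {
  pooled <- table@counts[, , , , 1L] + table@counts[, , , , 2L]
  nd <- sum(rowSums(matrix(pooled, nrow = 20L * 16L * 48L)) > 0)
  if (nd == 0) stop("contact abundance undefined for an empty table")
  log10(contactSpaceSize() / nd)
}

#' Size of the full potential contact space
#'
#' Enumerated from the implemented class spaces: dinucleotide alphabet
#' (16) x amino-acid alphabet (20) x environment classes (48).
#' @return integer, 15360.
#' @export
contactSpaceSize <- function() {
  length(DINUCS) * length(AA1) * nrow(envClasses())
}

#' Write a ContactTable as TSV
#'
#' One row per nonzero cell: aa, dinuc, the five environment labels,
#' bin, provenance, count.
#' @param table a \linkS4class{ContactTable}.
#' @param file optional output path.
#' @return the data.frame, invisibly when written to file.
#' @export
contactTableTSV <- function(table, file = NULL) {
  idx <- which(table@counts > 0, arr.ind = TRUE)
  ec <- envClasses()
  df <- data.frame(
    aa = AA1[idx[, 1]], dinuc = DINUCS[idx[, 2]],
    ec[idx[, 3], c("hydrophobicity", "ss", "exposure", "groove", "strandSide")],
    bin = idx[, 4], provenance = c("pdb", "pbm")[idx[, 5]],
    count = table@counts[idx], stringsAsFactors = FALSE)
  rownames(df) <- NULL
  if (!is.null(file)) {
    write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}
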