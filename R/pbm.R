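#' Protein-binding-microarray experiment container
#'
#' @param kmers character vector of 8-mers over A,C,G,T.
#' @param escores E-scores in the closed range [-0.50, 0.50].
#' @param tfId TF identifier.
#' @return A \code{PbmExperiment} (list with \code{tfId} and
#'   \code{records}).
#' @export
pbmExperiment <- function(kmers, escores, tfId = "TF") {
  stopifnot(length(kmers) == length(escores))
  if (length(kmers)) {
    if (any(nchar(kmers) != 8) || any(!grepl("^[ACGT]+$", kmers)))
      stop("kmers must be 8-mers over {A,C,G,T}")
    if (any(escores < -0.50 | escores > 0.50))
      stop("E-scores must lie in [-0.50, 0.50]")
  }
  structure(list(tfId = tfId,
                 records = data.frame(kmer = as.character(kmers),
                                      escore = as.numeric(escores),
                                      stringsAsFactors = FALSE)),
            class = "PbmExperiment")
}

#' @export
print.PbmExperiment <- function(x, ...) {
  cat("PbmExperiment", x$tfId, "with", nrow(x$records), "8-mers\n")
  invisible(x)
}

#' Read a PBM 8-mer table
#'
#' Two-column flat text (8-mer, E-score), tab- or whitespace-separated;
#' a header line is tolerated, as are extra columns (Cis-BP exports
#' carry both orientations and additional statistics; the first
#' sequence-like column and the first numeric column are used).
#'
#' @param file path to the table.
#' @param tfId TF identifier.
#' @return A \code{PbmExperiment}.
#' @export
readPBM <- function(file, tfId = sub("\\..*$", "", basename(file))) {
  df <- read.table(file, header = FALSE, stringsAsFactors = FALSE,
                   fill = TRUE, comment.char = "#")
  if (!nrow(df)) return(pbmExperiment(character(0), numeric(0), tfId))
  if (!grepl("^[ACGT]{8}$", df[1, 1]))   # header line
    df <- df[-1, , drop = FALSE]
  kcol <- which(vapply(df, function(c) all(grepl("^[ACGT]{8}$", c)),
                       logical(1)))[1]
  vals <- suppressWarnings(lapply(df, as.numeric))
  ncol <- which(vapply(vals, function(v) !anyNA(v), logical(1)))[1]
  pbmExperiment(df[[kcol]], vals[[ncol]], tfId)
}

#' Classify PBM 8-mers by E-score
#'
#' E-scores above 0.45 are high-affinity ("positive") interactions,
#' E-scores below 0.37 are non-bound ("negative"), and the band in
#' between is discarded from statistical analyses. The three sets
#' partition the experiment's records.
#'
#' @param exp a \code{PbmExperiment}.
#' @param positiveAbove,negativeBelow thresholds (defaults 0.45, 0.37).
#' @return list with character vectors \code{positive},
#'   \code{negative}, \code{discarded}.
#' @export
classify8mers <- function(exp, positiveAbove = 0.45, negativeBelow = 0.37) {
  r <- exp$records
  list(positive = r$kmer[r$escore > positiveAbove],
       negative = r$kmer[r$escore < negativeBelow],
       discarded = r$kmer[r$escore >= negativeBelow &
                            r$escore <= positiveAbove])
}

#' Align an 8-mer into the template binding site via the TF's PWM
#'
#' Scores every ungapped placement of the 8-mer against the PWM (both
#' strands; the shorter of the two is slid fully inside the longer) by
#' the sum of log column probabilities, and returns the best placement
#' mapped onto template-site coordinates. Placements whose best score
#' does not exceed a floor - the median PWM log-likelihood of 10000
#' random 8-mers, computed with a fixed internal seed - are rejected
#' (\code{accepted = FALSE}).
#'
#' @param kmer an 8-mer.
#' @param pwm the TF's \linkS4class{PWMotif}; its width must equal the
#'   template site length when \code{templateSite} is given.
#' @param templateSite optional DNA sequence of the structural binding
#'   site (used only to validate the length correspondence).
#' @param floor "median" (default) or "none".
#' @param nNull sample size for the floor estimate.
#' @return list: \code{offset} (1-based position of the 8-mer's first
#'   base on the PWM/template), \code{strand} ("+"/"-"), \code{score},
#'   \code{floor}, \code{accepted}.
#' @export
align8merToSite <- function(kmer, pwm, templateSite = NULL,
                            floor = c("median", "none"), nNull = 10000) {
  floor <- match.arg(floor)
  stopifnot(nchar(kmer) == 8)
  w <- pwmWidth(pwm)
  if (!is.null(templateSite) && nchar(templateSite) != w)
    stop("PWM width and template site length differ")
  lp <- log(pwmMatrix(pwm) + 1e-6)
  scoreK <- function(k) {
    ki <- match(strsplit(k, "")[[1]], DNA_BASES)
    if (w >= 8) {
      offs <- seq_len(w - 7L)
      vapply(offs, function(o) sum(lp[cbind(ki, o:(o + 7L))]), numeric(1))
    } else {
      offs <- seq_len(8L - w + 1L)
      vapply(offs, function(o)
        sum(lp[cbind(ki[o:(o + w - 1L)], seq_len(w))]), numeric(1))
    }
  }
  best <- function(k) {
    fs <- scoreK(k); rs <- scoreK(revcomp(k))
    bf <- which.max(fs); br <- which.max(rs)
    if (fs[bf] >= rs[br]) list(offset = bf, strand = "+", score = fs[bf])
    else list(offset = br, strand = "-", score = rs[br])
  }
  b <- best(kmer)
  fl <- -Inf
  if (floor == "median") {
    fl <- withLocalSeed(20240612L, {
      ks <- vapply(seq_len(nNull), function(i)
        paste(sample(DNA_BASES, 8, replace = TRUE), collapse = ""),
        character(1))
      median(vapply(ks, function(k) max(scoreK(k)), numeric(1)))
    })
  }
  c(b, list(floor = fl, accepted = b$score > fl))
}

#' Homolog residue correspondence from a pairwise protein alignment
#'
#' Global alignment with affine gaps (BLOSUM62, gap open 10, gap extend
#' 0.5), one deterministic traceback per pair. Maps with gaps inside
#' the interface are rejected downstream by
#' \code{\link{extendContacts}}.
#'
#' @param templateSeq,targetSeq protein sequences (1-letter).
#' @param templateId,targetId identifiers.
#' @return A \code{HomologMap}: list with the position map
#'   (template position -> target position, NA at gaps), the target
#'   sequence, ids and the percent identity.
#' @export
makeHomologMap <- function(templateSeq, targetSeq,
                           templateId = "template", targetId = "target") {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(templateSeq), Biostrings::AAString(targetSeq),
    type = "global", substitutionMatrix = BLOSUM62,
    gapOpening = 10, gapExtension = 0.5)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  map <- rep(NA_integer_, nchar(templateSeq))
  ti <- 0L; si <- 0L
  for (k in seq_along(pat)) {
    if (pat[k] != "-") ti <- ti + 1L
    if (sub[k] != "-") si <- si + 1L
    if (pat[k] != "-" && sub[k] != "-") map[ti] <- si
  }
  pid <- Biostrings::pid(aln, type = "PID1")
  structure(list(templateId = templateId, targetId = targetId,
                 map = map, targetSeq = targetSeq, identity = pid),
            class = "HomologMap")
}

#' Extend template contacts with placed positive 8-mers and homologs
#'
#' For each accepted 8-mer placement (and each homolog map, or the
#' template itself when none is given), the template's contacts are
#' re-emitted with the dinucleotides of steps covered by the placed
#' 8-mer substituted according to the placement, and amino acids
#' substituted according to the homolog correspondence. Distances and
#' environments are inherited from the template. Homolog maps with a
#' gap at any interface residue are rejected with a warning and
#' contribute no records.
#'
#' @param templateContacts contact data.frame of the template structure.
#' @param placements list of placements from
#'   \code{\link{align8merToSite}} together with their kmers:
#'   each element \code{list(kmer=, placement=)}; rejected placements
#'   are skipped.
#' @param homologMaps optional list of \code{HomologMap}; NULL means
#'   the template TF itself.
#' @param siteStart template-site position corresponding to the first
#'   contacted step's first nucleotide (default 1).
#' @return contact data.frame with \code{provenance = "pbm"}.
#' @export
extendContacts <- function(templateContacts, placements,
                           homologMaps = NULL, siteStart = 1L) {
  tc <- templateContacts
  if (!nrow(tc)) return(emptyContactsDf())
  smin <- min(tc$step)
  interface <- sort(unique(tc$residue))
  aaSets <- list(stats::setNames(tc$aa[match(interface, tc$residue)],
                                 interface))
  if (!is.null(homologMaps)) {
    aaSets <- lapply(homologMaps, function(hm) {
      pos <- hm$map[interface]
      if (anyNA(pos)) {
        warning("homolog map ", hm$targetId,
                " has a gap in the interface; removed")
        return(NULL)
      }
      stats::setNames(strsplit(hm$targetSeq, "")[[1]][pos], interface)
    })
    aaSets <- aaSets[!vapply(aaSets, is.null, logical(1))]
    if (!length(aaSets)) return(emptyContactsDf())
  }
  out <- list()
  for (pl in placements) {
    p <- pl$placement
    if (!isTRUE(p$accepted)) next
    k <- if (p$strand == "+") pl$kmer else revcomp(pl$kmer)
    # site positions covered by the 8-mer
    kStart <- p$offset
    for (aset in aaSets) {
      rec <- tc
      rec$aa <- unname(aset[as.character(rec$residue)])
      # substitute dinucleotides at steps inside the placement
      sitePos <- rec$step - smin + siteStart      # first nt of the step
      inside <- sitePos >= kStart & sitePos + 1L <= kStart + 7L
      koff <- sitePos - kStart + 1L
      rec$dinuc[inside] <- substr(rep(k, sum(inside)),
                                  koff[inside], koff[inside] + 1L)
      rec$provenance <- "pbm"
      out[[length(out) + 1L]] <- rec
    }
  }
  if (!length(out)) return(emptyContactsDf())
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}
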