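#' @import methods
#' @importFrom stats median sd lm predict BIC runif rgamma cor setNames
#' @importFrom utils head read.table write.table
NULL

#' TFComplex: an annotated transcription factor-DNA complex
#'
#' Holds a parsed protein-DNA complex: protein residues with their
#' structural-environment annotations (secondary structure, solvent
#' exposure, hydrophobicity class and a Cbeta coordinate, virtual for
#' glycine), the two paired DNA strands (position-by-position, 5'->3' on
#' the leading strand) and the dinucleotide steps with their base-atom
#' centroids.
#'
#' @slot sourceId free-text identifier of the structure.
#' @slot residues data.frame, one row per protein residue: \code{chain},
#'   \code{resno}, \code{aa} (1-letter), \code{cbx,cby,cbz},
#'   \code{ss}, \code{exposure}, \code{relAcc}, \code{hydrophobicity}.
#' @slot proteinAtoms data.frame of protein heavy atoms (used by the
#'   secondary-structure and accessibility assigners).
#' @slot strands list of two data.frames (\code{leading},
#'   \code{complementary}) aligned position-by-position.
#' @slot steps data.frame, one row per dinucleotide step: \code{index},
#'   \code{dinuc} (read on the leading strand) and the centroid
#'   \code{cx,cy,cz} (unweighted mean over the nitrogen-base atoms of the
#'   two nucleotides and their complements).
#' @slot baseAtoms data.frame of nitrogen-base atoms with groove labels.
#' @slot mismatches integer positions where the strands are not
#'   complementary (flagged, not dropped).
#' @export
setClass("TFComplex", representation(
  sourceId = "character",
  residues = "data.frame",
  proteinAtoms = "data.frame",
  strands = "list",
  steps = "data.frame",
  baseAtoms = "data.frame",
  mismatches = "integer"
))

setValidity("TFComplex", function(object) {
  msg <- character(0)
  ld <- object@strands$leading
  cp <- object@strands$complementary
  if (is.null(ld) || is.null(cp) || nrow(ld) != nrow(cp))
    msg <- c(msg, "the two DNA strands must be aligned with equal length")
  if (nrow(ld) >= 2 && nrow(object@steps) != nrow(ld) - 1L)
    msg <- c(msg, "steps must have length (strand length - 1)")
  if (nrow(object@residues) &&
      !all(object@residues$aa %in% AA1))
    msg <- c(msg, "residues restricted to the 20-letter amino-acid alphabet")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TFComplex", function(object) {
  cat("TFComplex:", object@sourceId, "\n")
  cat("  ", nrow(object@residues), "protein residues;",
      nrow(object@strands$leading), "bp duplex;",
      nrow(object@steps), "dinucleotide steps\n")
  if (length(object@mismatches))
    cat("  ", length(object@mismatches), "mismatched base pair(s) at:",
        paste(object@mismatches, collapse = ","), "\n")
})

#' @rdname TFComplex-class
#' @param x a \code{TFComplex}
#' @export
proteinResidues <- function(x) x@residues

#' @rdname TFComplex-class
#' @export
dnaSteps <- function(x) x@steps

#' @rdname TFComplex-class
#' @export
dnaStrands <- function(x) x@strands

#' ContactTable: counted amino-acid/dinucleotide contacts
#'
#' Counts of contacts indexed by amino acid (20), dinucleotide (16),
#' environment class (48) and 1-Angstrom distance bin, kept separately
#' for the two provenances (contacts observed in structures, "pdb", and
#' contacts transferred from protein-binding-microarray positives,
#' "pbm"). This is the training substrate for statistical potentials.
#'
#' @slot counts 5-d array \code{[aa, dinuc, env, bin, provenance]}.
#' @slot binning "interval" (x-1 < d <= x) or "cumulative" (d <= x).
#' @slot binWidth bin width in Angstrom (1 by default).
#' @slot maxRadius largest distance retained, Angstrom.
#' @export
setClass("ContactTable", representation(
  counts = "array",
  binning = "character",
  binWidth = "numeric",
  maxRadius = "numeric"
))

setValidity("ContactTable", function(object) {
  d <- dim(object@counts)
  msg <- character(0)
  if (length(d) != 5 || d[1] != 20L || d[2] != 16L || d[3] != 48L || d[5] != 2L)
    msg <- c(msg, "counts must be a [20 x 16 x 48 x bins x 2] array")
  if (any(object@counts < 0)) msg <- c(msg, "all counts must be >= 0")
  if (!object@binning %in% c("interval", "cumulative"))
    msg <- c(msg, "binning must be 'interval' or 'cumulative'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ContactTable", function(object) {
  tot <- sum(object@counts)
  cat("ContactTable (", object@binning, " binning, ",
      dim(object@counts)[4], " bins of ", object@binWidth, " A, <",
      object@maxRadius, " A)\n", sep = "")
  cat("  counts: pdb =", sum(object@counts[, , , , "pdb"]),
      " pbm =", sum(object@counts[, , , , "pbm"]),
      " total =", tot, "\n")
  pooled <- object@counts[, , , , 1L] + object@counts[, , , , 2L]
  nd <- sum(rowSums(matrix(pooled, nrow = 20L * 16L * 48L)) > 0)
  cat("  distinct (aa, dinuc, env) triples:", nd, "of 15360\n")
})

emptyContactCounts <- function(nbins) {
  array(0, dim = c(20L, 16L, 48L, nbins, 2L),
        dimnames = list(aa = AA1, dinuc = DINUCS,
                        env = as.character(seq_len(48L)),
                        bin = as.character(seq_len(nbins)),
                        provenance = c("pdb", "pbm")))
}

#' @rdname ContactTable-class
#' @param x a \code{ContactTable}
#' @export
contactCounts <- function(x) x@counts

#' StatPotential: a knowledge-based protein-DNA scoring potential
#'
#' Log-odds scores over (amino acid, dinucleotide, environment class,
#' distance bin) derived from a \linkS4class{ContactTable}, in either
#' interval ("bins") or cumulative ("acc") form, with the per-contact
#' Z-score transform precomputed over the 20 amino-acid substitutions.
#' Lower scores are more favorable; more negative Z is better.
#'
#' @slot scores numeric array \code{[20 x 16 x 48 x bins]}.
#' @slot zscores same shape; Z over amino-acid substitutions.
#' @slot config the \code{familyConfig} used to build the potential.
#' @slot kappa pseudocount.
#' @export
setClass("StatPotential", representation(
  scores = "array",
  zscores = "array",
  config = "list",
  kappa = "numeric"
))

setMethod("show", "StatPotential", function(object) {
  cfg <- object@config
  cat("StatPotential (", cfg$family, "): ", cfg$binning,
      " binning, radius ", cfg$radius, " A, db=", cfg$db,
      ", taylor=", cfg$taylor, "\n", sep = "")
  cat("  ", dim(object@scores)[4], " distance bin(s); kappa = ",
      object@kappa, "\n", sep = "")
})

#' @rdname StatPotential-class
#' @param x a \code{StatPotential}
#' @export
potentialScores <- function(x) x@scores

#' @rdname StatPotential-class
#' @export
potentialConfig <- function(x) x@config

#' PWMotif: a position weight matrix
#'
#' A 4 x N matrix of per-position nucleotide probabilities (rows A, C,
#' G, T; every column sums to 1) with an id, a source tag and a
#' background distribution. Read and written in MEME minimal format.
#'
#' @slot mat 4 x N probability matrix, rows named A,C,G,T.
#' @slot id motif identifier.
#' @slot source "predicted" or "experimental".
#' @slot background length-4 background nucleotide frequencies.
#' @slot nsites number of sequences the matrix was built from (0 if
#'   unknown).
#' @export
setClass("PWMotif", representation(
  mat = "matrix",
  id = "character",
  source = "character",
  background = "numeric",
  nsites = "numeric"
))

setValidity("PWMotif", function(object) {
  m <- object@mat
  msg <- character(0)
  if (nrow(m) != 4L || ncol(m) < 1L)
    msg <- c(msg, "matrix must be 4 x N with N >= 1")
  if (any(m < 0)) msg <- c(msg, "probabilities must be >= 0")
  if (ncol(m) >= 1L && any(abs(colSums(m) - 1) > 1e-9))
    msg <- c(msg, "every column must sum to 1 (+/- 1e-9)")
  if (length(object@background) != 4L ||
      abs(sum(object@background) - 1) > 1e-6)
    msg <- c(msg, "background must be 4 frequencies summing to 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PWMotif", function(object) {
  cat("PWMotif ", object@id, " (", object@source, "), width ",
      ncol(object@mat), ", consensus ", consensus(object), "\n", sep = "")
})

#' Construct a PWMotif
#'
#' Columns are renormalized exactly; input columns deviating from sum 1
#' by more than \code{tol} are rejected.
#'
#' @param mat 4 x N matrix (rows A,C,G,T) of probabilities, or an N x 4
#'   matrix which is transposed.
#' @param id motif identifier.
#' @param source "predicted" or "experimental".
#' @param background background frequencies (default uniform).
#' @param nsites number of supporting sequences.
#' @param tol largest tolerated deviation of a column sum from 1.
#' @return A \linkS4class{PWMotif}.
#' @export
pwMotif <- function(mat, id = "motif", source = "predicted",
                    background = rep(0.25, 4), nsites = 0,
                    tol = 1e-3) {
  if (nrow(mat) != 4L && ncol(mat) == 4L) mat <- t(mat)
  if (nrow(mat) != 4L) stop("matrix must have 4 nucleotide rows")
  cs <- colSums(mat)
  if (any(abs(cs - 1) > tol))
    stop("normalization error: column(s) ",
         paste(which(abs(cs - 1) > tol), collapse = ","),
         " do not sum to 1")
  mat <- sweep(mat, 2, cs, "/")
  dimnames(mat) <- list(DNA_BASES, NULL)
  new("PWMotif", mat = mat, id = id, source = source,
      background = background / sum(background), nsites = nsites)
}

#' @rdname PWMotif-class
#' @param x a \code{PWMotif}
#' @export
pwmMatrix <- function(x) x@mat

#' @rdname PWMotif-class
#' @export
pwmWidth <- function(x) ncol(x@mat)

#' @rdname PWMotif-class
#' @export
pwmId <- function(x) x@id

#' Consensus sequence of a motif (ties broken alphabetically)
#' @param x a \code{PWMotif}
#' @return character consensus of length \code{pwmWidth(x)}.
#' @export
consensus <- function(x) {
  paste(DNA_BASES[apply(x@mat, 2, which.max)], collapse = "")
}

#' Reverse complement of a motif
#' @param x a \code{PWMotif}
#' @return a \code{PWMotif} on the opposite strand.
#' @export
pwmReverseComplement <- function(x) {
  m <- x@mat[4:1, rev(seq_len(ncol(x@mat))), drop = FALSE]
  rownames(m) <- DNA_BASES
  new("PWMotif", mat = m, id = x@id, source = x@source,
      background = x@background, nsites = x@nsites)
}
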