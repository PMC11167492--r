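# Internal lookup tables shared across the package.

AA1 <- c("A","C","D","E","F","G","H","I","K","L",
         "M","N","P","Q","R","S","T","V","W","Y")

AA3TO1 <- c(
  ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F",
  GLY = "G", HIS = "H", ILE = "I", LYS = "K", LEU = "L",
  MET = "M", ASN = "N", PRO = "P", GLN = "Q", ARG = "R",
  SER = "S", THR = "T", VAL = "V", TRP = "W", TYR = "Y",
  # common non-standard parents
  MSE = "M", SEC = "C", PYL = "K", HYP = "P", SEP = "S",
  TPO = "T", PTR = "Y", CSO = "C", KCX = "K", MLY = "K"
)

AA1TO3 <- c(
  A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
  G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
  M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
  S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR"
)

# fixed hydrophobicity classes (nonpolar side chains incl. G and P)
NONPOLAR_AA <- c("A","V","L","I","M","F","W","C","G","P")

DNA_BASES <- c("A","C","G","T")
DINUCS <- as.vector(outer(DNA_BASES, DNA_BASES, paste0))  # AA,CA,GA,TA,AC,...

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

NUC_RESID <- c(DA = "A", DC = "C", DG = "G", DT = "T",
               A = "A", C = "C", G = "G", T = "T")

# Sugar-phosphate atom names (PDB v3 and legacy '*' spellings)
DNA_BACKBONE_ATOMS <- c(
  "P","OP1","OP2","OP3","O1P","O2P","O3P",
  "O5'","C5'","C4'","O4'","C3'","O3'","C2'","O2'","C1'",
  "O5*","C5*","C4*","O4*","C3*","O3*","C2*","O2*","C1*"
)

# Canonical chemical partition of nitrogen-base atoms into groove sides.
# Watson-Crick edge atoms are assigned to the groove they flank in B-DNA
# (purine N1 / pyrimidine N3 face neither groove; they are kept on the
# minor side for purines and major side for pyrimidines so the partition
# is exhaustive).
GROOVE_TABLE <- list(
  A = c(N9 = "minor", C8 = "major", N7 = "major", C5 = "major",
        C6 = "major", N6 = "major", N1 = "minor", C2 = "minor",
        N3 = "minor", C4 = "minor"),
  G = c(N9 = "minor", C8 = "major", N7 = "major", C5 = "major",
        C6 = "major", O6 = "major", N1 = "minor", C2 = "minor",
        N2 = "minor", N3 = "minor", C4 = "minor"),
  C = c(N1 = "minor", C2 = "minor", O2 = "minor", N3 = "major",
        C4 = "major", N4 = "major", C5 = "major", C6 = "major"),
  T = c(N1 = "minor", C2 = "minor", O2 = "minor", N3 = "major",
        C4 = "major", O4 = "major", C5 = "major", C7 = "major",
        C5M = "major", C6 = "major")
)

# Theoretical maximum accessible surface areas (Gly-X-Gly), A^2
MAX_ASA <- c(
  A = 129, R = 274, N = 195, D = 193, C = 167, Q = 225, E = 223,
  G = 104, H = 224, I = 197, L = 201, K = 236, M = 224, F = 240,
  P = 159, S = 155, T = 172, W = 285, Y = 263, V = 174
)

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)

vdwRadius <- function(elety) {
  elem <- substr(gsub("[^A-Za-z].*", "", toupper(elety)), 1, 1)
  r <- VDW_RADII[elem]
  r[is.na(r)] <- 1.70
  unname(r)
}

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(unname(COMPLEMENT[strsplit(s, "")[[1]]])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Enumerate the contact environment class space
#'
#' A contact between an amino acid and a dinucleotide step carries five
#' categorical environment features: the residue hydrophobicity class
#' (polar/nonpolar), its secondary structure (helix/strand/coil), its
#' solvent exposure (buried/exposed), the DNA groove closest to the
#' residue (major/minor) and the strand the nearest base atom belongs to
#' (leading/complementary). Their crossing yields the 48 environment
#' classes; combined with 20 amino acids and 16 dinucleotides the
#' potential contact space has 16 x 20 x 48 = 15360 cells.
#'
#' @return A data.frame with one row per environment class (48 rows) and
#'   columns \code{env} (integer id), \code{hydrophobicity}, \code{ss},
#'   \code{exposure}, \code{groove}, \code{strandSide}.
#' @export
#' @examples
#' nrow(envClasses())  # 48
envClasses <- function() {
  grid <- expand.grid(
    hydrophobicity = c("polar", "nonpolar"),
    ss = c("helix", "strand", "coil"),
    exposure = c("buried", "exposed"),
    groove = c("major", "minor"),
    strandSide = c("leading", "complementary"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  cbind(env = seq_len(nrow(grid)), grid)
}

#' Classify a contact environment into its class id
#'
#' @param hydrophobicity "polar" or "nonpolar".
#' @param ss "helix", "strand" or "coil".
#' @param exposure "buried" or "exposed".
#' @param groove "major" or "minor".
#' @param strandSide "leading" or "complementary".
#' @return Integer class id in 1..48. Vectorized over all arguments.
#' @export
envClassId <- function(hydrophobicity, ss, exposure, groove, strandSide) {
  h <- match(hydrophobicity, c("polar", "nonpolar"))
  s <- match(ss, c("helix", "strand", "coil"))
  e <- match(exposure, c("buried", "exposed"))
  g <- match(groove, c("major", "minor"))
  d <- match(strandSide, c("leading", "complementary"))
  if (anyNA(h) || anyNA(s) || anyNA(e) || anyNA(g) || anyNA(d))
    stop("invalid environment label")
  h + 2L * (s - 1L) + 6L * (e - 1L) + 12L * (g - 1L) + 24L * (d - 1L)
}

# run a block with a locally-seeded RNG, restoring global state afterwards
withLocalSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
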