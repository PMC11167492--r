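#' Per-family parameter configuration
#'
#' The six parameters selected per TF family by the grid search: the
#' contacts database (structures only, or extended with PBM data), the
#' scope (family-specific or general), polynomial smoothing of the
#' contact space ("Taylor"), the distance binning (interval "bins" or
#' cumulative "acc"), the interface radius (15, 22 or 30 A) and the
#' redundancy (MSA) threshold. The shipped defaults for the most
#' populated families are in \code{inst/extdata/family_params.yaml} and
#' are returned by \code{\link{familyDefaults}}.
#'
#' @param family family label or "general".
#' @param db "pdb" or "pbm" (pbm = structures + PBM-extended contacts).
#' @param scope "family" or "general".
#' @param taylor logical, polynomial smoothing of sparse distance
#'   profiles.
#' @param binning "bins" (interval) or "acc" (cumulative).
#' @param radius 15, 22 or 30 Angstrom.
#' @param msaThreshold redundancy threshold in [0.7, 1].
#' @param threshold top-score selection cut-off for PWM construction.
#' @return list of class \code{familyConfig}.
#' @export
familyConfig <- function(family = "general", db = c("pdb", "pbm"),
                         scope = c("family", "general"), taylor = FALSE,
                         binning = c("bins", "acc"), radius = 30,
                         msaThreshold = 0.82, threshold = 0.95) {
  db <- match.arg(db)
  scope <- match.arg(scope)
  binning <- match.arg(binning)
  stopifnot(radius %in% c(15, 22, 30),
            msaThreshold >= 0.7, msaThreshold <= 1,
            threshold >= 0.7, threshold <= 1)
  structure(list(family = family, db = db, scope = scope,
                 taylor = isTRUE(taylor), binning = binning,
                 radius = radius, msaThreshold = msaThreshold,
                 threshold = threshold),
            class = "familyConfig")
}

#' Shipped per-family parameter defaults
#'
#' @param family optional family name; when given, that family's
#'   \code{familyConfig} is returned (falling back to the general row).
#' @return A data.frame of all rows, or a single \code{familyConfig}.
#' @export
familyDefaults <- function(family = NULL) {
  path <- system.file("extdata", "family_params.yaml",
                      package = "StructMotif", mustWork = TRUE)
  y <- yaml::read_yaml(path)
  df <- do.call(rbind, lapply(y$families, function(r)
    data.frame(family = r$family, contactsPdb = r$contacts_pdb,
               contactsPbm = r$contacts_pbm, db = r$db, scope = r$scope,
               taylor = r$taylor, binning = r$binning, radius = r$radius,
               msaThreshold = r$msa_threshold, stringsAsFactors = FALSE)))
  if (is.null(family)) return(df)
  row <- df[df$family == family, , drop = FALSE]
  if (!nrow(row)) row <- df[df$family == "GLOBAL", , drop = FALSE]
  if (!nrow(row)) stop("unknown family and no GLOBAL row")
  familyConfig(family = row$family, db = row$db, scope = row$scope,
               taylor = row$taylor, binning = row$binning,
               radius = row$radius, msaThreshold = row$msaThreshold)
}

#' Build a statistical potential from a contact table
#'
#' The score of a cell (a = amino acid, b = dinucleotide, e =
#' environment class; distance bin x) is the negative log odds of the
#' observed, pseudocounted contact frequency in that bin against the
#' product of the amino-acid marginal and the (dinucleotide,
#' environment) marginal:
#' \deqn{score = -log[ ((N_{abe,x}+\kappa)/(N_x+\kappa K)) /
#'       (P(a) P(b,e)) ]}
#' with \eqn{\kappa} the pseudocount and \eqn{K = 15360} the class-space
#' size. Lower scores are more favorable. With cumulative ("acc")
#' binning the counts at threshold x are the interval counts summed over
#' bins 1..x, and complexes are scored at the radius threshold. The
#' per-contact Z-score over the 20 amino-acid substitutions at the same
#' (b, e, x) is precomputed (\code{zscores}); a zero substitution
#' standard deviation yields Z = 0.
#'
#' @param table a \linkS4class{ContactTable} with interval counts.
#' @param config a \code{\link{familyConfig}}.
#' @param kappa pseudocount (default 0.1).
#' @return A \linkS4class{StatPotential}.
#' @export
buildPotential <- function(table, config = familyConfig(), kappa = 0.1) {
  stopifnot(is(table, "ContactTable"))
  if (table@binning != "interval")
    stop("buildPotential expects interval counts; cumulation is applied internally")
  counts <- table@counts
  cc <- switch(config$db,
               pdb = counts[, , , , "pdb"],
               pbm = counts[, , , , "pdb"] + counts[, , , , "pbm"])
  if (sum(cc) == 0) stop("empty contact table")
  if (config$taylor) cc <- taylorSmoothArray(cc)
  nbins <- min(dim(cc)[4], ceiling(config$radius / table@binWidth))
  cc <- cc[, , , seq_len(nbins), drop = FALSE]
  if (config$binning == "acc")
    cc <- aperm(apply(cc, c(1, 2, 3), cumsum), c(2, 3, 4, 1))
  K <- contactSpaceSize()
  Ntot <- sum(cc)
  Na <- apply(cc, 1, sum)
  Nbe <- apply(cc, c(2, 3), sum)
  Pa <- (Na + kappa) / (Ntot + 20 * kappa)
  Pbe <- (Nbe + kappa) / (Ntot + 16 * 48 * kappa)
  Nx <- apply(cc, 4, sum)
  num <- sweep(cc + kappa, 4, Nx + kappa * K, "/")
  ref <- outer(Pa, Pbe)                       # [aa, dinuc, env]
  sc <- -log(sweep(num, c(1, 2, 3), ref, "/"))
  dimnames(sc) <- dimnames(cc)
  zs <- zscoreArray(sc)
  new("StatPotential", scores = sc, zscores = zs,
      config = unclass(config), kappa = kappa)
}

# Z over the amino-acid axis, population sd; sd == 0 -> 0
zscoreArray <- function(sc) {
  d <- dim(sc)
  m <- matrix(sc, nrow = d[1])
  mu <- colMeans(m)
  sdv <- sqrt(colMeans(m^2) - mu^2)
  z <- sweep(m, 2, mu, "-")
  z <- sweep(z, 2, ifelse(sdv > 0, sdv, Inf), "/")
  array(z, dim = d, dimnames = dimnames(sc))
}

#' Z-score of one contact under a potential
#'
#' Compares the score of the contact's amino acid with the mean score of
#' all 20 amino-acid substitutions at the same (dinucleotide,
#' environment, bin), normalized by their (population) standard
#' deviation. More negative Z marks a more favorable contact; if the
#' substitution scores are all equal, Z = 0.
#'
#' @param potential a \linkS4class{StatPotential}.
#' @param aa amino acid (1-letter).
#' @param dinuc dinucleotide.
#' @param env environment class id.
#' @param bin distance bin.
#' @return numeric Z.
#' @export
zscoreContact <- function(potential, aa, dinuc, env, bin) {
  potential@zscores[match(aa, AA1), match(dinuc, DINUCS), env, bin]
}

# map contact distances to score-array bins for a built potential
contactBins <- function(potential, distance, binWidth = 1) {
  nbins <- dim(potential@scores)[4]
  if (potential@config$binning == "acc") rep(nbins, length(distance))
  else pmax(1L, pmin(nbins, ceiling(distance / binWidth)))
}

#' Score a set of contacts with a potential
#'
#' Deterministic sums over the interface: the raw potential score
#' (ES3DC-style, sum of per-contact scores) and its Z-transform
#' (ZES3DC-style, sum of per-contact Z-scores). Contacts beyond the
#' potential's radius are excluded; pseudocounts guarantee every
#' retained contact has a finite score.
#'
#' @param potential a \linkS4class{StatPotential}.
#' @param contacts contact data.frame.
#' @return list with \code{ES3DC} and \code{ZES3DC}.
#' @export
scoreComplex <- function(potential, contacts) {
  if (!nrow(contacts)) return(list(ES3DC = 0, ZES3DC = 0))
  keep <- contacts$distance < potential@config$radius
  cc <- contacts[keep, , drop = FALSE]
  if (!nrow(cc)) return(list(ES3DC = 0, ZES3DC = 0))
  idx <- cbind(match(cc$aa, AA1), match(cc$dinuc, DINUCS), cc$env,
               contactBins(potential, cc$distance))
  list(ES3DC = sum(potential@scores[idx]),
       ZES3DC = sum(potential@zscores[idx]))
}

#' Polynomial smoothing of sparse distance profiles
#'
#' For each (amino acid, dinucleotide, environment) profile of interval
#' counts along distance, unobserved bins lying between observed ones
#' are imputed from a low-degree polynomial (degree at most 2, chosen by
#' BIC) fitted to log counts versus bin midpoint. Observed bins are
#' never overwritten. This completes the contact space where the
#' training data leave holes.
#'
#' @param table a \linkS4class{ContactTable} with interval counts.
#' @param maxDegree largest polynomial degree considered.
#' @return A smoothed \linkS4class{ContactTable}.
#' @export
taylorSmooth <- function(table, maxDegree = 2) {
  stopifnot(is(table, "ContactTable"), table@binning == "interval")
  counts <- table@counts
  for (p in 1:2)
    counts[, , , , p] <- taylorSmoothArray(counts[, , , , p], maxDegree)
  new("ContactTable", counts = counts, binning = table@binning,
      binWidth = table@binWidth, maxRadius = table@maxRadius)
}

taylorSmoothArray <- function(cc, maxDegree = 2) {
  d <- dim(cc)
  m <- matrix(cc, nrow = prod(d[1:3]))
  use <- which(rowSums(m > 0) >= 2)
  for (r in use) {
    prof <- m[r, ]
    obs <- which(prof > 0)
    holes <- setdiff(seq(min(obs), max(obs)), obs)
    if (!length(holes)) next
    xs <- obs; ys <- log(prof[obs])
    bestFit <- NULL; bestBIC <- Inf
    for (deg in 0:min(maxDegree, length(obs) - 1)) {
      fit <- if (deg == 0) lm(ys ~ 1) else lm(ys ~ poly(xs, deg, raw = TRUE))
      b <- BIC(fit)
      if (b < bestBIC) { bestBIC <- b; bestFit <- fit }
    }
    pred <- if (length(bestFit$coefficients) == 1L)
      rep(bestFit$coefficients[1], length(holes))
    else
      predict(bestFit, newdata = data.frame(xs = holes))
    m[r, holes] <- exp(pred)
  }
  array(m, dim = d, dimnames = dimnames(cc))
}

#' Remove redundant TFs from a training set
#'
#' Each TF is fingerprinted by its set of nonzero (aa, dinucleotide,
#' environment, bin) contact cells; the fraction of identical contacts
#' between two TFs is the intersection size over the smaller
#' fingerprint. TFs are visited greedily in order of descending total
#' contact count (ties by id) and dropped when their fraction of
#' identical contacts with an already-kept TF exceeds the cutoff
#' (default 0.70 family-specific, 0.40 general). The operation is
#' idempotent.
#'
#' @param tables named list of per-TF \linkS4class{ContactTable}s.
#' @param mode "family" or "general".
#' @param cutoff override the mode default.
#' @return list with \code{kept} (ids) and \code{tables} (the filtered
#'   list).
#' @export
filterRedundancy <- function(tables, mode = c("family", "general"),
                             cutoff = NULL) {
  mode <- match.arg(mode)
  if (is.null(cutoff)) cutoff <- if (mode == "family") 0.70 else 0.40
  ids <- names(tables)
  stopifnot(!is.null(ids))
  fps <- lapply(tables, contactFingerprint)
  tot <- vapply(tables, function(t) sum(t@counts), numeric(1))
  ord <- order(-tot, ids)
  kept <- character(0)
  for (i in ord) {
    redundant <- FALSE
    for (k in kept) {
      inter <- length(intersect(fps[[i]], fps[[k]]))
      denom <- min(length(fps[[i]]), length(fps[[k]]))
      if (denom > 0 && inter / denom > cutoff) { redundant <- TRUE; break }
    }
    if (!redundant) kept <- c(kept, ids[i])
  }
  kept <- ids[ids %in% kept]      # report in input order
  list(kept = kept, tables = tables[kept])
}

# nonzero (aa, dinuc, env, bin) cells, provenances pooled
contactFingerprint <- function(table) {
  which(table@counts[, , , , 1L] + table@counts[, , , , 2L] > 0)
}

fingerprintSimilarity <- function(fa, fb) {
  if (!length(fa) || !length(fb)) return(0)
  length(intersect(fa, fb)) / min(length(fa), length(fb))
}

# pairwise fingerprint similarity between two contact tables
contactSimilarity <- function(tableA, tableB) {
  fingerprintSimilarity(contactFingerprint(tableA),
                        contactFingerprint(tableB))
}
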