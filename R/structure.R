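#' Parse a TF-DNA complex from PDB text
#'
#' Reads a protein-DNA complex in PDB format, establishes the DNA duplex
#' by maximal complementary pairing of two DNA chains (mismatched pairs
#' are flagged, not dropped), builds the dinucleotide steps with their
#' base-atom centroids, and annotates every protein residue with the
#' structural-environment features the contact classifier needs:
#' secondary structure, solvent exposure, hydrophobicity class and a
#' Cbeta coordinate (a virtual Cbeta is constructed for glycine from
#' ideal tetrahedral backbone geometry).
#'
#' The leading strand is the strand whose first paired nucleotide has
#' the lower author number; step \code{i} covers leading-strand
#' nucleotides \code{i, i+1} and their paired complements. Nonstandard
#' amino acids are mapped to their parents (MSE to M, etc.); unmappable
#' residues are dropped with a warning, as are protein chains with fewer
#' than 3 residues.
#'
#' @param pdb PDB-format text (single string or character vector of
#'   lines), or a path to a PDB file.
#' @param proteinChains optional chain ids to restrict the protein side.
#' @param dnaChains optional chain ids to restrict the DNA side.
#' @param sourceId identifier stored on the object.
#' @param annotate assign secondary structure and exposure (default
#'   TRUE).
#' @param relAccCutoff relative-accessibility cutoff passed to
#'   \code{\link{assignExposure}}.
#' @return A \linkS4class{TFComplex}.
#' @export
parseComplex <- function(pdb, proteinChains = NULL, dnaChains = NULL,
                         sourceId = "complex", annotate = TRUE,
                         relAccCutoff = 0.25) {
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    lines <- readLines(pdb)
  } else {
    lines <- unlist(strsplit(paste(pdb, collapse = "\n"), "\n"))
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  p <- bio3d::read.pdb(tmp, verbose = FALSE)
  at <- p$atom
  at <- at[at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  at$resid <- trimws(at$resid)
  at$elety <- trimws(at$elety)
  at$insert[is.na(at$insert)] <- ""
  at$rkey <- paste(at$chain, at$resno, at$insert, sep = "|")

  isNuc <- at$resid %in% names(NUC_RESID)
  isProt <- at$resid %in% names(AA3TO1)
  if (!is.null(dnaChains)) isNuc <- isNuc & at$chain %in% dnaChains
  if (!is.null(proteinChains)) isProt <- isProt & at$chain %in% proteinChains

  ## ---- DNA duplex ----
  nuc <- at[isNuc, , drop = FALSE]
  dnaChainIds <- unique(nuc$chain)
  chainSeqs <- lapply(dnaChainIds, function(ch) {
    sub <- nuc[nuc$chain == ch, , drop = FALSE]
    keys <- unique(sub$rkey)
    resno <- sub$resno[match(keys, sub$rkey)]
    keys <- keys[order(resno)]           # author numbering is 5'->3'
    base <- unname(NUC_RESID[sub$resid[match(keys, sub$rkey)]])
    resno <- sort(resno)
    list(chain = ch, keys = keys, base = base, resno = resno)
  })
  names(chainSeqs) <- dnaChainIds
  pairing <- findDuplex(chainSeqs)
  if (is.null(pairing)) stop("no DNA duplex")

  lead <- pairing$lead; comp <- pairing$comp
  L <- length(lead$base)
  mism <- which(unname(COMPLEMENT[lead$base]) != comp$base)

  strands <- list(
    leading = data.frame(chain = lead$chain, resno = lead$resno,
                         base = lead$base, stringsAsFactors = FALSE),
    complementary = data.frame(chain = comp$chain, resno = comp$resno,
                               base = comp$base, stringsAsFactors = FALSE)
  )

  ## base atoms with groove labels
  baseAtoms <- do.call(rbind, lapply(c("leading", "complementary"), function(sd) {
    rec <- if (sd == "leading") lead else comp
    do.call(rbind, lapply(seq_len(L), function(k) {
      sub <- nuc[nuc$rkey == rec$keys[k], , drop = FALSE]
      sub <- sub[!(sub$elety %in% DNA_BACKBONE_ATOMS), , drop = FALSE]
      if (!nrow(sub)) return(NULL)
      gt <- GROOVE_TABLE[[rec$base[k]]]
      data.frame(strand = sd, pos = k, atom = sub$elety,
                 groove = unname(gt[sub$elety]),
                 x = sub$x, y = sub$y, z = sub$z,
                 stringsAsFactors = FALSE)
    }))
  }))

  ## dinucleotide steps
  steps <- do.call(rbind, lapply(seq_len(L - 1L), function(k) {
    ba <- baseAtoms[baseAtoms$pos %in% c(k, k + 1L), , drop = FALSE]
    din <- paste0(lead$base[k], lead$base[k + 1L])
    if (!din %in% DINUCS) din <- NA_character_
    data.frame(index = k, dinuc = din,
               cx = mean(ba$x), cy = mean(ba$y), cz = mean(ba$z),
               stringsAsFactors = FALSE)
  }))

  ## ---- protein residues ----
  prot <- at[isProt, , drop = FALSE]
  dropped <- at[!isNuc & !isProt & !(at$resid %in% c("HOH", "WAT")), , drop = FALSE]
  if (nrow(dropped))
    warning("dropped ", length(unique(dropped$rkey)),
            " unmappable residue(s): ",
            paste(unique(dropped$resid), collapse = ","))
  keepChains <- names(which(
    tapply(prot$rkey, prot$chain, function(k) length(unique(k))) >= 3L))
  if (length(setdiff(unique(prot$chain), keepChains)))
    warning("rejected protein chain(s) with <3 residues: ",
            paste(setdiff(unique(prot$chain), keepChains), collapse = ","))
  prot <- prot[prot$chain %in% keepChains, , drop = FALSE]
  if (!nrow(prot)) stop("no protein chain with >=3 residues")

  keys <- unique(prot$rkey)
  resDf <- do.call(rbind, lapply(keys, function(k) {
    sub <- prot[prot$rkey == k, , drop = FALSE]
    aa <- unname(AA3TO1[sub$resid[1]])
    cb <- sub[sub$elety == "CB", c("x", "y", "z"), drop = FALSE]
    if (nrow(cb)) {
      cbc <- as.numeric(cb[1, ])
    } else {
      bb <- lapply(c("N", "CA", "C"), function(e)
        as.numeric(sub[match(e, sub$elety), c("x", "y", "z")]))
      if (anyNA(unlist(bb))) cbc <- c(NA_real_, NA_real_, NA_real_)
      else cbc <- virtualCB(bb[[1]], bb[[2]], bb[[3]])
    }
    data.frame(chain = sub$chain[1], resno = sub$resno[1],
               insert = sub$insert[1], aa = aa,
               cbx = cbc[1], cby = cbc[2], cbz = cbc[3],
               ss = "coil", exposure = "exposed", relAcc = NA_real_,
               hydrophobicity = if (aa %in% NONPOLAR_AA) "nonpolar" else "polar",
               stringsAsFactors = FALSE)
  }))
  if (anyNA(resDf$cbx)) {
    warning("residue(s) without Cbeta or full backbone dropped")
    resDf <- resDf[!is.na(resDf$cbx), , drop = FALSE]
  }

  obj <- new("TFComplex", sourceId = sourceId, residues = resDf,
             proteinAtoms = prot[, c("chain", "resno", "insert", "resid",
                                     "elety", "x", "y", "z")],
             strands = strands, steps = steps, baseAtoms = baseAtoms,
             mismatches = as.integer(mism))
  if (annotate) {
    obj <- assignSecondaryStructure(obj)
    obj <- assignExposure(obj, relAccCutoff = relAccCutoff)
  }
  obj
}

# pick the chain pair + sliding offset with maximal complementary
# matches; returns aligned (lead, comp) records or NULL
findDuplex <- function(chainSeqs) {
  if (length(chainSeqs) < 2L) return(NULL)
  best <- NULL
  ids <- names(chainSeqs)
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i >= j) next
    s1 <- chainSeqs[[i]]; s2 <- chainSeqs[[j]]
    n1 <- length(s1$base); n2 <- length(s2$base)
    # reverse s2 so that pairing is position-by-position
    r2 <- list(chain = s2$chain, keys = rev(s2$keys),
               base = rev(s2$base), resno = rev(s2$resno))
    for (off in seq(-(n2 - 1L), n1 - 1L)) {
      k1 <- max(1L, 1L + off):min(n1, n2 + off)
      if (length(k1) < 4L) next
      k2 <- k1 - off
      m <- sum(unname(COMPLEMENT[s1$base[k1]]) == r2$base[k2])
      if (m < 4L || m < length(k1) / 2) next
      if (is.null(best) || m > best$m) {
        best <- list(m = m,
          lead = lapply(s1, function(v) if (length(v) > 1L) v[k1] else v),
          comp = lapply(r2, function(v) if (length(v) > 1L) v[k2] else v))
      }
    }
  }
  if (is.null(best)) return(NULL)
  lead <- best$lead; comp <- best$comp
  # leading strand: lower author number of the first paired nucleotide
  if (comp$resno[1] < lead$resno[1]) {
    tmp <- lead
    lead <- lapply(comp, function(v) if (length(v) > 1L) rev(v) else v)
    comp <- lapply(tmp, function(v) if (length(v) > 1L) rev(v) else v)
  }
  list(lead = lead, comp = comp)
}

#' Assign secondary structure from backbone geometry
#'
#' A self-contained assigner with the usual three-state contract
#' (helix/strand/coil): backbone phi/psi dihedrals are computed along
#' each chain (chain breaks where the peptide bond exceeds 2.5 A),
#' residues falling in the alpha-helical region (phi in [-120,-30], psi
#' in [-80,-5]) or the extended region (phi in [-180,-45], psi >= 90 or
#' <= -150) are labelled, and labels are kept only in runs of at least 3
#' (helix) or 2 (strand) residues, mirroring the collapse of the 8
#' DSSP states onto 3 (H,G,I to helix; E,B to strand; else coil).
#' Residues with missing backbone atoms are labelled coil with a
#' warning.
#'
#' @param x a \linkS4class{TFComplex}.
#' @return \code{x} with the residue \code{ss} column filled.
#' @export
assignSecondaryStructure <- function(x) {
  res <- x@residues
  at <- x@proteinAtoms
  res$ss <- "coil"
  miss <- FALSE
  for (ch in unique(res$chain)) {
    idx <- which(res$chain == ch)
    idx <- idx[order(res$resno[idx])]
    n <- length(idx)
    getBB <- function(i, e) {
      sub <- at[at$chain == ch & at$resno == res$resno[i] &
                  at$insert == res$insert[i] & at$elety == e, , drop = FALSE]
      if (!nrow(sub)) return(c(NA_real_, NA_real_, NA_real_))
      as.numeric(sub[1, c("x", "y", "z")])
    }
    Nc <- t(vapply(idx, getBB, numeric(3), e = "N"))
    CAc <- t(vapply(idx, getBB, numeric(3), e = "CA"))
    Cc <- t(vapply(idx, getBB, numeric(3), e = "C"))
    if (anyNA(Nc) || anyNA(CAc) || anyNA(Cc)) miss <- TRUE
    raw <- rep("coil", n)
    for (i in seq_len(n)) {
      if (i == 1L || i == n) next
      if (anyNA(Nc[(i - 1):(i + 1), ]) || anyNA(CAc[i, ]) ||
          anyNA(Cc[(i - 1):i, ])) next
      # contiguity: peptide bonds on both sides
      if (vnorm(Nc[i, ] - Cc[i - 1, ]) > 2.5) next
      if (vnorm(Nc[i + 1, ] - Cc[i, ]) > 2.5) next
      phi <- dihedralAngle(Cc[i - 1, ], Nc[i, ], CAc[i, ], Cc[i, ])
      psi <- dihedralAngle(Nc[i, ], CAc[i, ], Cc[i, ], Nc[i + 1, ])
      if (phi >= -120 && phi <= -30 && psi >= -80 && psi <= -5) {
        raw[i] <- "helix"
      } else if (phi >= -180 && phi <= -45 && (psi >= 90 || psi <= -150)) {
        raw[i] <- "strand"
      }
    }
    lab <- smoothRuns(raw, minRun = c(helix = 3L, strand = 2L))
    res$ss[idx] <- lab
  }
  if (miss) warning("residue(s) with missing backbone atoms labelled coil")
  x@residues <- res
  x
}

smoothRuns <- function(raw, minRun) {
  r <- rle(raw)
  for (k in seq_along(r$values)) {
    v <- r$values[k]
    if (v %in% names(minRun) && r$lengths[k] < minRun[[v]])
      r$values[k] <- "coil"
  }
  inverse.rle(r)
}

#' Assign solvent exposure from accessible surface area
#'
#' Computes per-atom accessible surface area with a rolling-probe
#' (Shrake-Rupley) construction over all heavy atoms of the complex
#' (protein and DNA both occlude), sums it per residue, divides by the
#' residue's theoretical maximum (Gly-X-Gly) and labels the residue
#' exposed iff the relative accessibility exceeds \code{relAccCutoff}.
#'
#' @param x a \linkS4class{TFComplex}.
#' @param relAccCutoff relative-accessibility threshold (default 0.25).
#' @param probe probe radius in Angstrom.
#' @param nPoints sphere sample points per atom.
#' @return \code{x} with \code{exposure} and \code{relAcc} filled.
#' @export
assignExposure <- function(x, relAccCutoff = 0.25, probe = 1.4,
                           nPoints = 92L) {
  at <- x@proteinAtoms
  ba <- x@baseAtoms
  occl <- rbind(
    data.frame(x = at$x, y = at$y, z = at$z, elety = at$elety,
               stringsAsFactors = FALSE),
    if (nrow(ba)) data.frame(x = ba$x, y = ba$y, z = ba$z, elety = ba$atom,
                             stringsAsFactors = FALSE)
  )
  xyz <- as.matrix(occl[, c("x", "y", "z")])
  radii <- vdwRadius(occl$elety)
  asa <- shrakeRupley(xyz, radii, probe = probe, nPoints = nPoints)
  res <- x@residues
  protN <- nrow(at)
  for (i in seq_len(nrow(res))) {
    sel <- which(at$chain == res$chain[i] & at$resno == res$resno[i] &
                   at$insert == res$insert[i])
    tot <- sum(asa[sel])
    res$relAcc[i] <- tot / MAX_ASA[[res$aa[i]]]
  }
  res$exposure <- ifelse(res$relAcc > relAccCutoff, "exposed", "buried")
  x@residues <- res
  x
}

#' Per-residue / per-step annotation report
#'
#' @param x a \linkS4class{TFComplex}.
#' @param file optional path; when given the report is written as TSV.
#' @return A data.frame with one row per protein residue and one per
#'   dinucleotide step, carrying all environment labels (1-based step
#'   indices).
#' @export
annotationReport <- function(x, file = NULL) {
  res <- x@residues
  rr <- data.frame(record = "residue", chain = res$chain, index = res$resno,
                   label = res$aa, ss = res$ss, exposure = res$exposure,
                   hydrophobicity = res$hydrophobicity,
                   relAcc = round(res$relAcc, 4), stringsAsFactors = FALSE)
  st <- x@steps
  sr <- data.frame(record = "step", chain = x@strands$leading$chain[1],
                   index = st$index, label = st$dinuc, ss = NA, exposure = NA,
                   hydrophobicity = NA, relAcc = NA, stringsAsFactors = FALSE)
  out <- rbind(rr, sr)
  if (!is.null(file))
    write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
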