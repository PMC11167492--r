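# Internal geometry helpers: dihedrals, ideal-geometry atom placement,
# virtual Cbeta construction and a Shrake-Rupley accessibility engine.

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

unitv <- function(a) a / vnorm(a)

# signed dihedral p1-p2-p3-p4 in degrees
dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unitv(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# place a new atom D given A-B-C, bond length |CD|, angle B-C-D (deg)
# and torsion A-B-C-D (deg): the standard NeRF construction.
placeAtom <- function(a, b, c, bond, angle, torsion) {
  angle <- angle * pi / 180; torsion <- torsion * pi / 180
  bc <- unitv(c - b)
  n <- unitv(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- c(-bond * cos(angle),
          bond * sin(angle) * cos(torsion),
          -bond * sin(angle) * sin(torsion))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# virtual Cbeta from backbone N, CA, C with ideal tetrahedral geometry
virtualCB <- function(n, ca, c) {
  b <- ca - n; cc <- c - ca
  a <- vcross(b, cc)
  -0.58273431 * a + 0.56802827 * b - 0.54067466 * cc + ca
}

# near-uniform points on the unit sphere (golden spiral)
spherePoints <- function(n = 92L) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Shrake-Rupley accessible surface area per atom.
# xyz: m x 3 matrix; radii: per-atom van der Waals radii.
shrakeRupley <- function(xyz, radii, probe = 1.4, nPoints = 92L) {
  m <- nrow(xyz)
  pts <- spherePoints(nPoints)
  rr <- radii + probe
  asa <- numeric(m)
  if (m == 0L) return(asa)
  # neighbor search on the expanded radii
  maxr <- max(rr)
  for (i in seq_len(m)) {
    di <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(di < rr[i] + maxr & seq_len(m) != i)
    nb <- nb[di[nb] < rr[i] + rr[nb]]
    sp <- pts * rr[i]
    sp <- sweep(sp, 2, xyz[i, ], "+")
    if (length(nb)) {
      free <- rep(TRUE, nPoints)
      for (j in nb) {
        d2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
          (sp[, 3] - xyz[j, 3])^2
        free <- free & d2 > rr[j]^2
        if (!any(free)) break
      }
      nfree <- sum(free)
    } else nfree <- nPoints
    asa[i] <- 4 * pi * rr[i]^2 * nfree / nPoints
  }
  asa
}

# Build an ideal polypeptide backbone (N, CA, C, O + CB) with constant
# phi/psi, trans peptide bonds and standard bond geometry.
# Returns a data.frame of atoms: resno, elety, x, y, z.
buildIdealChain <- function(n, phi = -57, psi = -47, aa = "A",
                            origin = c(0, 0, 0)) {
  stopifnot(n >= 1)
  aa <- rep_len(aa, n)
  atoms <- list()
  # seed the first residue explicitly
  N <- origin
  CA <- origin + c(1.458, 0, 0)
  C <- CA + 1.525 * c(cos(pi - 111.2 * pi / 180), sin(pi - 111.2 * pi / 180), 0)
  for (i in seq_len(n)) {
    O <- placeAtom(N, CA, C, 1.231, 120.5, psi + 180)
    atoms[[length(atoms) + 1L]] <- data.frame(
      resno = i, elety = c("N", "CA", "C", "O"),
      x = c(N[1], CA[1], C[1], O[1]),
      y = c(N[2], CA[2], C[2], O[2]),
      z = c(N[3], CA[3], C[3], O[3]),
      stringsAsFactors = FALSE)
    if (aa[i] != "G") {
      cb <- virtualCB(N, CA, C)
      atoms[[length(atoms) + 1L]] <- data.frame(
        resno = i, elety = "CB", x = cb[1], y = cb[2], z = cb[3],
        stringsAsFactors = FALSE)
    }
    if (i < n) {
      Nn <- placeAtom(N, CA, C, 1.329, 116.2, psi)
      CAn <- placeAtom(CA, C, Nn, 1.458, 121.7, 180)   # omega = 180
      Cn <- placeAtom(C, Nn, CAn, 1.525, 111.2, phi)
      N <- Nn; CA <- CAn; C <- Cn
    }
  }
  df <- do.call(rbind, atoms)
  df$aa <- aa[df$resno]
  df
}
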