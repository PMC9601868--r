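# Synthetic benchmark structures: an antiparallel two-helix dimer with a
# small four-helix domain bound asymmetrically at its centre, carrying a
# fully designed, machine-readable contact inventory plus confidence
# annotations (pLDDT, PAE). Sidechains are reduced to CB plus one typed
# "tip" pseudo-atom placed at the designed interaction geometry; element
# typing is correct so the contact rules and SASA radii apply unchanged.

# tip atom name and element per residue type (reduced representation)
.TIP_ATOM <- list(
  LYS = c("NZ", "N"),  ARG = c("NH1", "N"), GLU = c("OE1", "O"),
  ASP = c("OD1", "O"), ASN = c("OD1", "O"), SER = c("OG", "O"),
  THR = c("OG1", "O"), LEU = c("CD1", "C"), VAL = c("CG1", "C"),
  ILE = c("CD1", "C"), MET = c("CE", "C"),  PHE = c("CZ", "C"))

# ideal alpha-helix parameters: 1.5 A rise, 100 deg twist per residue
.HELIX <- list(rise = 1.5, twist = 100 * pi / 180, rCA = 2.3, rN = 1.6,
               rC = 1.6, rO = 2.0, rCB = 3.3, rTip = 5.0,
               aN = -0.75, aC = 0.55, aO = 0.75,
               dphiN = -28 * pi / 180, dphiC = 28 * pi / 180,
               dphiO = 35 * pi / 180)

# Position on an ideal helix: axisPoint + direction*(i*rise + a) +
# r*(cos(t+dphi)*up + sin(t+dphi)*side), side = up x direction.
helixPoint <- function(i, a, r, dphi, axisPoint, direction, up, phase0) {
  side <- c(up[2] * direction[3] - up[3] * direction[2],
            up[3] * direction[1] - up[1] * direction[3],
            up[1] * direction[2] - up[2] * direction[1])
  t <- phase0 + i * .HELIX$twist + dphi
  axisPoint + direction * (i * .HELIX$rise + a) +
    r * (cos(t) * up + sin(t) * side)
}

# Backbone + CB + default radial tip atoms for one helical residue.
helixResidueAtoms <- function(i, resno, resid, chainId, plddt, axisPoint,
                              direction, up, phase0) {
  pt <- function(a, r, dphi) helixPoint(i, a, r, dphi, axisPoint,
                                        direction, up, phase0)
  rows <- list(
    c("N", "N", pt(.HELIX$aN, .HELIX$rN, .HELIX$dphiN)),
    c("CA", "C", pt(0, .HELIX$rCA, 0)),
    c("C", "C", pt(.HELIX$aC, .HELIX$rC, .HELIX$dphiC)),
    c("O", "O", pt(.HELIX$aO, .HELIX$rO, .HELIX$dphiO)))
  if (resid != "GLY")
    rows <- c(rows, list(c("CB", "C", pt(0, .HELIX$rCB, 0))))
  if (!resid %in% c("GLY", "ALA")) {
    tip <- .TIP_ATOM[[resid]]
    if (!is.null(tip))
      rows <- c(rows, list(c(tip[1], tip[2], pt(0, .HELIX$rTip, 0))))
  }
  do.call(rbind, lapply(rows, function(r)
    data.frame(chain = chainId, resno = resno, icode = "", resid = resid,
               elety = r[1], element = r[2],
               x = as.numeric(r[3]), y = as.numeric(r[4]),
               z = as.numeric(r[5]), b = plddt, occ = 1, altloc = "",
               stringsAsFactors = FALSE)))
}

#' Build an ideal alpha-helix
#'
#' Places backbone N/CA/C/O plus CB (and a radial sidechain tip pseudo-atom
#' for residues beyond Ala) on an ideal alpha-helix: 1.5 \enc{Å}{A} rise and
#' 100 degrees twist per residue, giving consecutive CA--CA distances of
#' \eqn{\approx 3.8} \enc{Å}{A} and a translationally repeating internal
#' geometry.
#'
#' @param nRes number of residues (>= 4).
#' @param chainId chain identifier.
#' @param startResno author number of the first residue.
#' @param sequence single 3-letter code recycled, or a vector of length
#'   `nRes`.
#' @param axisPoint point on the helix axis at the first residue.
#' @param direction unit axis direction.
#' @param up unit vector (perpendicular to `direction`) toward which a
#'   residue at helical phase zero points.
#' @param phase0 phase of the first residue (radians).
#' @param plddt per-residue confidence written to the B-factor column
#'   (scalar or length `nRes`).
#' @return a single-chain [StructureModel-class].
#' @examples
#' h <- buildIdealHelix(36)
#' nResidues(h)  # 36
#' @export
buildIdealHelix <- function(nRes, chainId = "A", startResno = 1,
                            sequence = "ALA", axisPoint = c(0, 0, 0),
                            direction = c(1, 0, 0), up = c(0, 0, 1),
                            phase0 = 0, plddt = 90) {
  if (nRes < 4) stop("need at least 4 residues for a helix")
  direction <- direction / sqrt(sum(direction^2))
  up <- up - sum(up * direction) * direction
  if (sum(up^2) < 1e-12) stop("'up' must not be parallel to 'direction'")
  up <- up / sqrt(sum(up^2))
  sequence <- rep_len(toupper(sequence), nRes)
  plddt <- rep_len(plddt, nRes)
  atoms <- do.call(rbind, lapply(seq_len(nRes) - 1L, function(i)
    helixResidueAtoms(i, startResno + i, sequence[i + 1], chainId,
                      plddt[i + 1], axisPoint, direction, up, phase0)))
  structureModel(atoms, modelId = paste0("helix_", chainId))
}

#' Specification of the synthetic 2:1 complex
#'
#' Parameters of the synthetic benchmark: an antiparallel coiled-coil-like
#' dimer (chains A and B, `nTurnsCoil` helical turns each, ~160
#' \enc{Å}{A} long at the default 30 turns) with 40-residue low-confidence
#' terminal linkers, and a small four-helix domain (chain C) bound
#' asymmetrically at the dimer centre through two designed hydrophobic
#' pockets (7 and 5 residues) seating one pin leucine per dimer chain,
#' plus designed salt bridges and hydrogen bonds at stated target
#' distances.
#'
#' @param nTurnsCoil helical turns per dimer chain (default 30, i.e. 108
#'   residues).
#' @param linkerLen low-confidence linker length per dimer chain (default
#'   40 residues).
#' @param linkerPlddt pLDDT assigned to linker residues (default 30).
#' @param corePlddt pLDDT assigned to all other residues (default 92).
#' @param saltBridgeDist,hBondDist,pinContactDist target distances
#'   (\enc{Å}{A}) for the designed salt bridges, hydrogen bonds and
#'   pin-tip-to-pocket carbon contacts; each must sit within its
#'   classifier cutoff. Cluster-member contacts arise from the member
#'   C-beta positions against the pocket cage (~3.1 \enc{Å}{A}).
#' @param paeIntra,paeInter,paeLinker PAE block constants (\enc{Å}{A}).
#' @param seed integer seed recorded in the ground truth (the construction
#'   itself is deterministic).
#' @return list of class `ComplexSpec`.
#' @export
complexSpec <- function(nTurnsCoil = 30, linkerLen = 40, linkerPlddt = 30,
                        corePlddt = 92, saltBridgeDist = 3.4,
                        hBondDist = 3.0, pinContactDist = 4.1,
                        paeIntra = 2, paeInter = 5, paeLinker = 25,
                        seed = 1) {
  cut <- defaultContactCutoffs()
  if (saltBridgeDist > cut$saltBridge || hBondDist > cut$hBond ||
      pinContactDist > cut$hydrophobic)
    stop("designed target distances must sit within the classifier cutoffs")
  if (linkerPlddt >= 50 || corePlddt < 90)
    stop("linkerPlddt must be < 50 and corePlddt >= 90")
  structure(list(nTurnsCoil = nTurnsCoil, linkerLen = linkerLen,
                 linkerPlddt = linkerPlddt, corePlddt = corePlddt,
                 saltBridgeDist = saltBridgeDist, hBondDist = hBondDist,
                 pinContactDist = pinContactDist,
                 paeIntra = paeIntra, paeInter = paeInter,
                 paeLinker = paeLinker, seed = seed),
            class = "ComplexSpec")
}

# points on a sphere cage around `center`: nRing atoms on a ring at
# `ringElev` (radians, negative = below centre) plus nTop atoms at
# `topElev`, all at distance `radius`.
cagePoints <- function(center, radius, nRing, ringElev, nTop, topElev,
                       phi0 = pi / 2) {
  ring <- t(vapply(seq_len(nRing) - 1L, function(k) {
    phi <- phi0 + k * 2 * pi / nRing
    center + radius * c(cos(ringElev) * cos(phi),
                        cos(ringElev) * sin(phi), sin(ringElev))
  }, numeric(3)))
  top <- if (nTop > 0)
    t(vapply(seq_len(nTop) - 1L, function(k) {
      phi <- phi0 + k * 2 * pi / max(nTop, 1)
      center + radius * c(cos(topElev) * cos(phi),
                          cos(topElev) * sin(phi), sin(topElev))
    }, numeric(3)))
  else NULL
  rbind(ring, top)
}

unitv <- function(v) v / sqrt(sum(v^2))

# generator-local contact typing (intentionally separate, simple code;
# the analysis module has its own vectorized implementation)
.truthKind <- function(ra, ea, sa, rda, rb, eb, sb, sdb, d,
                       cut = defaultContactCutoffs()) {
  sideA <- !(ea %in% .BACKBONE_ATOMS); sideB <- !(eb %in% .BACKBONE_ATOMS)
  sbA <- sideA && sa == "N" && ra %in% c("LYS", "ARG", "HIS")
  sbB <- sideB && sdb == "O" && rb %in% c("ASP", "GLU")
  sbA2 <- sideB && sdb == "N" && rb %in% c("LYS", "ARG", "HIS")
  sbB2 <- sideA && sa == "O" && ra %in% c("ASP", "GLU")
  if (d <= cut$saltBridge && ((sbA && sbB) || (sbA2 && sbB2)))
    return("salt_bridge")
  if (d <= cut$hBond && sa %in% c("N", "O") && sdb %in% c("N", "O"))
    return("hydrogen_bond")
  if (d <= cut$hydrophobic && sideA && sideB && sa == "C" && sdb == "C" &&
      ra %in% .HYDROPHOBIC_RES && rb %in% .HYDROPHOBIC_RES)
    return("hydrophobic")
  NA_character_
}

#' Build the synthetic 2:1 dimer--domain complex
#'
#' Constructs the benchmark complex described by [complexSpec()]: chains A
#' and B form an antiparallel helix pair (core residues 248--355, preceded
#' in sequence by a 40-residue low-confidence linker, residues 208--247),
#' and chain C is a small four-helix domain (residues 1--56) docked over
#' the dimer midpoint. A pin leucine on each dimer chain (A301, B302 —
#' distinct positions, making the interface asymmetric) seats inside a
#' designed pocket cage of chain-C leucines (7 and 5 residues); designed
#' salt bridges, hydrogen bonds and cluster-member contacts are placed at
#' their target distances. After construction an audit verifies that no
#' cross-partition atom pair outside the designed inventory satisfies any
#' contact rule (with a 0.1 \enc{Å}{A} margin); a violation raises an
#' "infeasible geometry" error.
#'
#' The returned ground truth enumerates every designed contact, the two
#' pocket clusters with their expected pin assignments, the pin residues,
#' the linker residues, the interface residue set and per-chain spans, the
#' buried surface area per group, and the PAE block constants. The
#' distance-based parts are computed with independent generator-local
#' code; the \eqn{\Delta}SASA-dependent parts (interface membership beyond
#' the 5 \enc{Å}{A} shell, BSA) use the package SASA engine on the
#' generated coordinates, which is itself validated against closed forms.
#'
#' @param spec a [complexSpec()].
#' @param sasaTruth compute the SASA-dependent ground-truth fields
#'   (default TRUE; disable for cheap geometry-only uses).
#' @return list with `model` ([StructureModel-class]), `pae`
#'   ([PAEMatrix-class]) and `truth` (list).
#' @export
buildComplex <- function(spec = complexSpec(), sasaTruth = TRUE) {
  stopifnot(inherits(spec, "ComplexSpec"))
  nCore <- round(spec$nTurnsCoil * 3.6)
  nLink <- spec$linkerLen
  nTot <- nCore + nLink
  coreStart <- 248L
  firstResno <- coreStart - nLink
  lastResno <- coreStart + nCore - 1L

  pinA <- 301L; pinB <- 302L
  if (pinA > lastResno || pinB > lastResno)
    stop("coil too short to host the central pin stations")

  # helix frames ------------------------------------------------------
  iPinA <- pinA - firstResno
  axisA <- c(-(iPinA) * .HELIX$rise, 0, 0)       # pin A CA at x = 0
  dirA <- c(1, 0, 0); upZ <- c(0, 0, 1)
  phaseA <- -(iPinA) * .HELIX$twist

  iPinB <- pinB - firstResno
  xPinB <- 2.25
  axisB <- c(xPinB + iPinB * .HELIX$rise, 12.0, 0)
  dirB <- c(-1, 0, 0)
  phaseB <- -(iPinB) * .HELIX$twist

  cbOf <- function(i, axisPoint, direction, phase0)
    helixPoint(i, 0, .HELIX$rCB, 0, axisPoint, direction, upZ, phase0)
  cbA <- function(resno) cbOf(resno - firstResno, axisA, dirA, phaseA)
  cbB <- function(resno) cbOf(resno - firstResno, axisB, dirB, phaseB)

  # chain C: four 14-residue helices, bottom layer hosts the stations
  cAxes <- list(C1 = c(-9.75, 3.9, 13.8), C2 = c(-9.75, 8.1, 13.8),
                C3 = c(-9.75, 3.9, 18.9), C4 = c(-9.75, 8.1, 18.9))
  cStart <- c(C1 = 1L, C2 = 15L, C3 = 29L, C4 = 43L)
  cbC <- function(resno) {
    hx <- names(cStart)[findInterval(resno, cStart)]
    i <- resno - cStart[[hx]]
    helixPoint(i, 0, .HELIX$rCB, 0, cAxes[[hx]], c(1, 0, 0), c(0, 0, -1), 0)
  }

  # designed stations ---------------------------------------------------
  # dimer side: resno -> type & role
  # cluster members are alanines: their CB sits naturally against the
  # pocket cage (~3.1 A), giving the designed member contacts without an
  # engineered tip
  stationsA <- list(
    list(resno = 294L, resid = "LYS", role = "salt", partner = 1L),
    list(resno = 298L, resid = "ALA", role = "member"),
    list(resno = pinA, resid = "LEU", role = "pin"),
    list(resno = 305L, resid = "ALA", role = "member"),
    list(resno = 309L, resid = "ARG", role = "salt", partner = 14L))
  stationsB <- list(
    list(resno = 295L, resid = "LYS", role = "salt", partner = 28L),
    list(resno = 299L, resid = "ALA", role = "member"),
    list(resno = pinB, resid = "LEU", role = "pin"),
    list(resno = 306L, resid = "ALA", role = "member"),
    # one Asn donating two hydrogen bonds to neighbouring acceptors
    list(resno = 310L, resid = "ASN", role = "hbond",
         partner = c(15L, 16L)))
  partnerType <- c(`1` = "GLU", `14` = "GLU", `28` = "ASP", `15` = "SER",
                   `16` = "THR")
  pocket1 <- c(3L, 5L, 7L, 9L, 11L, 13L, 17L)   # 7 residues, cage of pin A
  pocket2 <- c(23L, 24L, 25L, 26L, 27L)          # 5 residues, cage of pin B

  # engineered tip coordinates -----------------------------------------
  tipACenter <- cbA(pinA) + c(0, 1.55, 2.45)
  tipBCenter <- cbB(pinB) + c(0, -1.55, 2.45)
  cage1 <- cagePoints(tipACenter, spec$pinContactDist, nRing = 5,
                      ringElev = -15 * pi / 180, nTop = 2,
                      topElev = 50 * pi / 180)
  cage2 <- cagePoints(tipBCenter, spec$pinContactDist, nRing = 4,
                      ringElev = -15 * pi / 180, nTop = 1,
                      topElev = 55 * pi / 180)

  tips <- list()   # "chain\rresno" -> xyz of the engineered tip
  setTip <- function(ch, resno, xyz)
    tips[[paste(ch, resno, sep = "\r")]] <<- as.numeric(xyz)

  setTip("A", pinA, tipACenter)
  setTip("B", pinB, tipBCenter)
  for (k in seq_along(pocket1)) setTip("C", pocket1[k], cage1[k, ])
  for (k in seq_along(pocket2)) setTip("C", pocket2[k], cage2[k, ])

  placeStations <- function(stations, cb, chain) {
    for (st in stations) {
      if (st$role %in% c("pin", "member")) next
      cbS <- cb(st$resno)
      d0 <- if (st$role == "salt") 2.8 else 3.0    # tip reach from CB
      dTarget <- if (st$role == "salt") spec$saltBridgeDist else
        spec$hBondDist
      tipS <- cbS + d0 * unitv(cbC(st$partner[1]) - cbS)
      setTip(chain, st$resno, tipS)
      # a two-partner station donates to both acceptors, splayed apart
      # along the helix axis so the acceptor tips do not collide
      tilt <- if (length(st$partner) > 1)
        seq(-0.45, 0.45, length.out = length(st$partner)) else 0
      for (k in seq_along(st$partner))
        setTip("C", st$partner[k],
               tipS + dTarget * unitv(unitv(cbC(st$partner[k]) - tipS) +
                                        c(tilt[k], 0, 0)))
    }
  }
  placeStations(stationsA, cbA, "A")
  placeStations(stationsB, cbB, "B")

  # residue type assignments -------------------------------------------
  seqA <- rep("GLY", nTot); seqB <- rep("GLY", nTot)
  for (st in stationsA) seqA[st$resno - firstResno + 1] <- st$resid
  for (st in stationsB) seqB[st$resno - firstResno + 1] <- st$resid
  seqC <- rep("GLY", 56)
  seqC[c(pocket1, pocket2)] <- "LEU"
  for (p in names(partnerType)) seqC[as.integer(p)] <- partnerType[[p]]

  plddtAB <- c(rep(spec$linkerPlddt, nLink), rep(spec$corePlddt, nCore))

  mkChain <- function(chain, seqv, axisPoint, direction, phase0, up,
                      startRes, plddt) {
    n <- length(seqv)
    do.call(rbind, lapply(seq_len(n) - 1L, function(i)
      helixResidueAtoms(i, startRes + i, seqv[i + 1], chain,
                        plddt[i + 1], axisPoint, direction, up, phase0)))
  }
  atomsA <- mkChain("A", seqA, axisA, dirA, phaseA, upZ, firstResno,
                    plddtAB)
  atomsB <- mkChain("B", seqB, axisB, dirB, phaseB, upZ, firstResno,
                    plddtAB)
  atomsC <- do.call(rbind, lapply(names(cAxes), function(hx) {
    i0 <- cStart[[hx]]
    mkChain("C", seqC[i0:(i0 + 13)], cAxes[[hx]], c(1, 0, 0), 0,
            c(0, 0, -1), i0, rep(spec$corePlddt, 14))
  }))
  atoms <- rbind(atomsA, atomsB, atomsC)

  # replace default radial tips with the engineered coordinates
  for (key in names(tips)) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    tipName <- .TIP_ATOM[[if (parts[1] == "C")
      seqC[as.integer(parts[2])] else if (parts[1] == "A")
        seqA[as.integer(parts[2]) - firstResno + 1] else
          seqB[as.integer(parts[2]) - firstResno + 1]]][1]
    hit <- atoms$chain == parts[1] & atoms$resno == as.integer(parts[2]) &
      atoms$elety == tipName
    stopifnot(sum(hit) == 1)
    atoms[hit, c("x", "y", "z")] <- as.list(tips[[key]])
  }
  model <- structureModel(atoms, modelId = "synthetic_2to1_complex")

  # designed contact inventory (generator-local typing) ----------------
  designedKey <- c(
    unlist(lapply(stationsA, function(st) paste("A", st$resno, sep = "\r"))),
    unlist(lapply(stationsB, function(st) paste("B", st$resno, sep = "\r"))),
    paste("C", c(pocket1, pocket2,
                 as.integer(names(partnerType))), sep = "\r"))
  a <- model@atoms
  akey <- paste(a$chain, a$resno, sep = "\r")
  sidechain <- !(a$elety %in% .BACKBONE_ATOMS)
  desAB <- which(akey %in% designedKey & a$chain %in% c("A", "B") &
                   sidechain)
  desC <- which(akey %in% designedKey & a$chain == "C" & sidechain &
                  !(a$elety %in% "CB"))
  xyz <- as.matrix(a[, c("x", "y", "z")])
  contacts <- list()
  for (i in desAB) for (j in desC) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d > 4.5) next
    kind <- .truthKind(a$resid[i], a$elety[i], a$element[i], NA,
                       a$resid[j], a$elety[j], NA, a$element[j], d)
    if (!is.na(kind))
      contacts[[length(contacts) + 1]] <- data.frame(
        kind = kind, chainA = a$chain[i], resnoA = a$resno[i],
        icodeA = "", residA = a$resid[i], atomA = a$elety[i],
        chainB = "C", resnoB = a$resno[j], icodeB = "",
        residB = a$resid[j], atomB = a$elety[j], distance = d,
        stringsAsFactors = FALSE)
  }
  contacts <- do.call(rbind, contacts)
  contacts <- contacts[order(contacts$chainA, contacts$resnoA,
                             contacts$atomA, contacts$chainB,
                             contacts$resnoB, contacts$atomB), ]
  rownames(contacts) <- NULL

  # audit: no cross-partition pair outside the designed inventory may
  # satisfy any contact rule (0.1 A margin)
  idxAB <- which(a$chain %in% c("A", "B"))
  idxC <- which(a$chain == "C")
  cut <- defaultContactCutoffs()
  desPair <- paste(contacts$chainA, contacts$resnoA, contacts$atomA,
                   contacts$resnoB, contacts$atomB)
  for (i in idxAB) {
    di <- sqrt(colSums((t(xyz[idxC, , drop = FALSE]) - xyz[i, ])^2))
    close <- which(di <= max(unlist(cut)) + 0.1)
    for (k in close) {
      j <- idxC[k]
      pr <- paste(a$chain[i], a$resno[i], a$elety[i], a$resno[j],
                  a$elety[j])
      if (pr %in% desPair) next
      kind <- .truthKind(a$resid[i], a$elety[i], a$element[i], NA,
                         a$resid[j], a$elety[j], NA, a$element[j],
                         max(di[k] - 0.1, 0))
      if (!is.na(kind))
        stop("infeasible geometry: accidental ", kind, " between ",
             a$chain[i], a$resno[i], ":", a$elety[i], " and C",
             a$resno[j], ":", a$elety[j], " at ",
             sprintf("%.2f", di[k]), " A")
      if (di[k] < 2.4)
        stop("infeasible geometry: clash between ", a$chain[i],
             a$resno[i], ":", a$elety[i], " and C", a$resno[j], ":",
             a$elety[j])
    }
  }

  # clusters: union-find over chain-C hydrophobic contact residues
  hp <- contacts[contacts$kind == "hydrophobic", , drop = FALSE]
  cRes <- sort(unique(hp$resnoB))
  parent <- seq_along(cRes)
  findRoot <- function(k) { while (parent[k] != k) k <- parent[k]; k }
  unite <- function(p, q) {
    rp <- findRoot(p); rq <- findRoot(q)
    if (rp != rq) parent[max(rp, rq)] <<- min(rp, rq)
  }
  for (p in seq_along(cRes)) for (q in seq_len(p - 1L)) {
    sharePartner <- length(intersect(
      paste(hp$chainA, hp$resnoA)[hp$resnoB == cRes[p]],
      paste(hp$chainA, hp$resnoA)[hp$resnoB == cRes[q]])) > 0
    if (sharePartner || abs(cRes[p] - cRes[q]) <= 4) unite(p, q)
  }
  roots <- vapply(seq_along(cRes), findRoot, integer(1))
  clustersTruth <- lapply(unique(roots), function(r) {
    members <- cRes[roots == r]
    partners <- unique(hp[hp$resnoB %in% members,
                          c("chainA", "resnoA")])
    isPin <- (partners$chainA == "A" & partners$resnoA == pinA) |
      (partners$chainA == "B" & partners$resnoA == pinB)
    list(members = members,
         pinChain = partners$chainA[isPin][1],
         pinResno = partners$resnoA[isPin][1])
  })
  clustersTruth <- clustersTruth[order(vapply(clustersTruth, function(cl)
    min(cl$members), numeric(1)))]

  linkers <- data.frame(
    chain = rep(c("A", "B"), each = nLink),
    resno = rep(seq(firstResno, coreStart - 1L), 2),
    stringsAsFactors = FALSE)

  # interface residues: independent 5.0 A distance shell ...
  d2 <- function(i, J) sqrt(colSums((t(xyz[J, , drop = FALSE]) -
                                       xyz[i, ])^2))
  minDistAB <- vapply(idxAB, function(i) min(d2(i, idxC)), numeric(1))
  shellAB <- unique(data.frame(chain = a$chain[idxAB],
                               resno = a$resno[idxAB],
                               stringsAsFactors = FALSE)[
                                 minDistAB <= 5.0, ])
  minDistC <- vapply(idxC, function(i) min(d2(i, idxAB)), numeric(1))
  shellC <- unique(data.frame(chain = a$chain[idxC],
                              resno = a$resno[idxC],
                              stringsAsFactors = FALSE)[minDistC <= 5.0, ])
  interfaceTruth <- rbind(shellAB, shellC)

  bsaTruth <- NULL
  if (sasaTruth) {
    # ... plus residues losing > 0.1 A^2 SASA (package engine; validated
    # independently against closed forms)
    det <- interfaceSasa(model, selectionSpec(chainId = c("A", "B")),
                         selectionSpec(chainId = "C"))
    extra <- rbind(
      det$dRes1[det$dRes1$dsasa > 0.1, c("chain", "resno")],
      det$dRes2[det$dRes2$dsasa > 0.1, c("chain", "resno")])
    interfaceTruth <- unique(rbind(interfaceTruth, extra))
    bsaTruth <- pmax(det$bsa, 0)
  }
  interfaceTruth <- interfaceTruth[order(interfaceTruth$chain,
                                         interfaceTruth$resno), ]
  rownames(interfaceTruth) <- NULL
  spansTruth <- do.call(rbind, lapply(split(interfaceTruth,
                                            interfaceTruth$chain),
    function(df) data.frame(chain = df$chain[1], start = min(df$resno),
                            end = max(df$resno), stringsAsFactors = FALSE)))
  rownames(spansTruth) <- NULL

  # PAE matrix ----------------------------------------------------------
  rt <- residueTable(model)
  n <- nrow(rt)
  isLinker <- paste(rt$chain, rt$resno) %in% paste(linkers$chain,
                                                   linkers$resno)
  pae <- matrix(spec$paeInter, n, n)
  sameChain <- outer(rt$chain, rt$chain, "==")
  pae[sameChain] <- spec$paeIntra
  linkerAny <- outer(isLinker, isLinker, "|") & !sameChain
  pae[linkerAny] <- spec$paeLinker
  diag(pae) <- 0
  paeObj <- paeMatrix(pae, data.frame(chain = rt$chain, resno = rt$resno,
                                      stringsAsFactors = FALSE))

  truth <- list(
    contacts = contacts,
    clusters = clustersTruth,
    pins = data.frame(chain = c("A", "B"), resno = c(pinA, pinB),
                      resid = "LEU", stringsAsFactors = FALSE),
    linkers = linkers,
    interfaceResidues = interfaceTruth,
    spans = spansTruth,
    bsa = bsaTruth,
    paeIntra = spec$paeIntra, paeInter = spec$paeInter,
    paeLinker = spec$paeLinker,
    corePlddt = spec$corePlddt, linkerPlddt = spec$linkerPlddt,
    partition = list(group1 = selectionSpec(chainId = c("A", "B")),
                     group2 = selectionSpec(chainId = "C")),
    spec = spec)
  list(model = model, pae = paeObj, truth = truth)
}
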