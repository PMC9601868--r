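.BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")
.HYDROPHOBIC_RES <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP",
                      "TYR", "PRO")

resKey <- function(df) paste(df$chain, df$resno, df$icode, sep = "\r")
atomKey <- function(df) paste(df$chain, df$resno, df$icode, df$elety,
                              sep = "\r")

#' Default interface cutoffs
#'
#' Conventional distance cutoffs used throughout the interface analysis
#' (none are dictated by the underlying science of a specific complex;
#' all are exposed as arguments): salt bridge 4.0 \enc{Å}{A} (sidechain N of
#' Lys/Arg/His to sidechain carboxylate O of Asp/Glu), hydrogen bond 3.5
#' \enc{Å}{A} (N/O donor-acceptor heavy-atom pair; distance-only, since
#' predicted models lack hydrogens for angle checks), hydrophobic 4.5
#' \enc{Å}{A} (sidechain carbon pair between apolar residues).
#'
#' @return named list of cutoffs.
#' @export
defaultContactCutoffs <- function() {
  list(saltBridge = 4.0, hBond = 3.5, hydrophobic = 4.5)
}

# Shared SASA bookkeeping for a two-group partition of a complex:
# isolated-group and in-complex SASA, per-atom and per-residue deltas.
interfaceSasa <- function(complex, group1, group2, probe = 1.4,
                          nPoints = 960, radii = defaultVdwRadii()) {
  m1 <- selectAtoms(complex, group1)
  m2 <- selectAtoms(complex, group2)
  if (nrow(m1@atoms) == 0 || nrow(m2@atoms) == 0)
    stop("both partition groups must be non-empty")
  if (length(intersect(atomKey(m1@atoms), atomKey(m2@atoms))) > 0)
    stop("partition groups overlap")
  m12 <- m1
  m12@atoms <- rbind(m1@atoms, m2@atoms)
  s1 <- shrakeRupleySasa(m1, probe, nPoints, radii)
  s2 <- shrakeRupleySasa(m2, probe, nPoints, radii)
  s12 <- shrakeRupleySasa(m12, probe, nPoints, radii)
  n1 <- nrow(s1@atoms)
  cplx1 <- s12@perAtom[seq_len(n1)]
  cplx2 <- s12@perAtom[-seq_len(n1)]
  stopifnot(length(cplx2) == nrow(s2@atoms))
  dAtom1 <- s1@perAtom - cplx1
  dAtom2 <- s2@perAtom - cplx2
  resDelta <- function(atoms, d) {
    key <- resKey(atoms)
    first <- !duplicated(key)
    grp <- match(key, key[first])
    out <- data.frame(chain = atoms$chain[first],
                      resno = atoms$resno[first],
                      icode = atoms$icode[first],
                      resid = atoms$resid[first],
                      dsasa = as.numeric(rowsum(d, grp)),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  }
  list(s1 = s1, s2 = s2, s12 = s12,
       dAtom1 = dAtom1, dAtom2 = dAtom2,
       dRes1 = resDelta(s1@atoms, dAtom1),
       dRes2 = resDelta(s2@atoms, dAtom2),
       bsa = c(group1 = sum(dAtom1), group2 = sum(dAtom2)))
}

#' Buried surface area of a two-group partition
#'
#' The buried surface area (BSA) of each group is its SASA in isolation
#' minus the SASA its atoms retain within the complex, i.e. the area each
#' molecule loses on binding. By construction
#' \eqn{BSA_1 + BSA_2 = SASA_1 + SASA_2 - SASA_{12}}. Reported values are
#' clamped at zero (quadrature noise can produce tiny negatives for
#' non-interacting groups).
#'
#' @param complex a [StructureModel-class] holding both molecules.
#' @param group1,group2 [SelectionSpec-class] objects partitioning the
#'   complex (disjoint, non-empty). For a 2:1 coiled-coil dimer / domain
#'   complex the dimer's two chains together form one group.
#' @param probe,nPoints,radii passed to [shrakeRupleySasa()].
#' @return list with `bsa` (named length-2, \enc{Å²}{A^2}), the three total
#'   SASA values, and the full per-atom/per-residue `detail`.
#' @export
buriedSurfaceArea <- function(complex, group1, group2, probe = 1.4,
                              nPoints = 960, radii = defaultVdwRadii()) {
  d <- interfaceSasa(complex, group1, group2, probe, nPoints, radii)
  list(bsa = pmax(d$bsa, 0),
       sasaGroup1 = d$s1@total, sasaGroup2 = d$s2@total,
       sasaComplex = d$s12@total, detail = d)
}

# Cross-partition heavy-atom pairs within a distance cutoff.
# Returns a data.frame of candidate pairs with indices into the two heavy
# atom tables and their distance.
crossPairs <- function(a1, a2, cutoff) {
  x1 <- as.matrix(a1[, c("x", "y", "z")])
  x2 <- as.matrix(a2[, c("x", "y", "z")])
  d2 <- outer(rowSums(x1^2), rowSums(x2^2), "+") - 2 * tcrossprod(x1, x2)
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  data.frame(i = hit[, 1], j = hit[, 2],
             distance = sqrt(pmax(0, d2[hit])))
}

#' Classify cross-partition atomic contacts
#'
#' Typed contact inventory between two molecule groups. Classes, in
#' priority order (each atom pair is reported once, under its
#' highest-priority class):
#' \itemize{
#'   \item \strong{salt_bridge}: sidechain nitrogen of Lys/Arg/His against
#'     sidechain carboxylate oxygen of Asp/Glu, within 4.0 \enc{Å}{A};
#'   \item \strong{hydrogen_bond}: any N/O donor-acceptor heavy-atom pair
#'     within 3.5 \enc{Å}{A} not already counted as a salt bridge;
#'   \item \strong{hydrophobic}: sidechain carbon-carbon pair within 4.5
#'     \enc{Å}{A} where both residues are apolar (Ala, Val, Leu, Ile, Met,
#'     Phe, Trp, Tyr, Pro).
#' }
#' Cutoffs are configurable; hydrogens are excluded throughout.
#'
#' @param complex a [StructureModel-class].
#' @param group1,group2 [SelectionSpec-class] partition.
#' @param cutoffs list as from [defaultContactCutoffs()].
#' @return data.frame with columns `kind`, `chainA`, `resnoA`, `icodeA`,
#'   `residA`, `atomA`, `chainB`, `resnoB`, `icodeB`, `residB`, `atomB`,
#'   `distance`; side A is always `group1`.
#' @export
classifyContacts <- function(complex, group1, group2,
                             cutoffs = defaultContactCutoffs()) {
  hs <- selectionSpec(heavyOnly = TRUE)
  a1 <- selectAtoms(selectAtoms(complex, group1), hs)@atoms
  a2 <- selectAtoms(selectAtoms(complex, group2), hs)@atoms
  empty <- data.frame(kind = character(0), chainA = character(0),
                      resnoA = integer(0), icodeA = character(0),
                      residA = character(0), atomA = character(0),
                      chainB = character(0), resnoB = integer(0),
                      icodeB = character(0), residB = character(0),
                      atomB = character(0), distance = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(a1) == 0 || nrow(a2) == 0) return(empty)
  maxCut <- max(unlist(cutoffs))
  cp <- crossPairs(a1, a2, maxCut)
  if (nrow(cp) == 0) return(empty)

  classAtoms <- function(a) {
    side <- !(a$elety %in% .BACKBONE_ATOMS)
    list(sbN = side & a$element == "N" &
           a$resid %in% c("LYS", "ARG", "HIS"),
         sbO = side & a$element == "O" & a$resid %in% c("ASP", "GLU"),
         no = a$element %in% c("N", "O"),
         hydC = side & a$element == "C" & a$resid %in% .HYDROPHOBIC_RES)
  }
  c1 <- classAtoms(a1); c2 <- classAtoms(a2)
  i <- cp$i; j <- cp$j; d <- cp$distance
  is_sb <- d <= cutoffs$saltBridge &
    ((c1$sbN[i] & c2$sbO[j]) | (c1$sbO[i] & c2$sbN[j]))
  is_hb <- !is_sb & d <= cutoffs$hBond & c1$no[i] & c2$no[j]
  is_hp <- d <= cutoffs$hydrophobic & c1$hydC[i] & c2$hydC[j]
  kind <- rep(NA_character_, nrow(cp))
  kind[is_hp] <- "hydrophobic"
  kind[is_hb] <- "hydrogen_bond"
  kind[is_sb] <- "salt_bridge"
  sel <- !is.na(kind)
  if (!any(sel)) return(empty)
  out <- data.frame(kind = kind[sel],
                    chainA = a1$chain[i[sel]], resnoA = a1$resno[i[sel]],
                    icodeA = a1$icode[i[sel]], residA = a1$resid[i[sel]],
                    atomA = a1$elety[i[sel]],
                    chainB = a2$chain[j[sel]], resnoB = a2$resno[j[sel]],
                    icodeB = a2$icode[j[sel]], residB = a2$resid[j[sel]],
                    atomB = a2$elety[j[sel]],
                    distance = d[sel], stringsAsFactors = FALSE)
  out <- out[order(out$chainA, out$resnoA, out$atomA, out$chainB,
                   out$resnoB, out$atomB), ]
  rownames(out) <- NULL
  out
}

#' Interface residues and per-chain spans
#'
#' A residue is interfacial when it loses more than `dsasaMin`
#' \enc{Å²}{A^2} of SASA on complex formation or has any cross-partition
#' heavy-atom pair within `contactDist`. Spans are the min/max author
#' residue numbers per chain among interfacial residues.
#'
#' @param complex a [StructureModel-class].
#' @param group1,group2 [SelectionSpec-class] partition.
#' @param dsasaMin per-residue \eqn{\Delta}SASA threshold (\enc{Å²}{A^2},
#'   default 0.1).
#' @param contactDist heavy-atom distance criterion (\enc{Å}{A}, default
#'   5.0).
#' @param sasaDetail optional precomputed result of the internal SASA
#'   bookkeeping (reused by [interfaceReport()]); computed when `NULL`.
#' @return list with `residues` (data.frame `chain`, `resno`, `icode`,
#'   `resid`, `group`, `dsasa`, `minDist`) and `spans` (data.frame `chain`,
#'   `group`, `start`, `end`).
#' @export
interfaceResidues <- function(complex, group1, group2, dsasaMin = 0.1,
                              contactDist = 5.0, sasaDetail = NULL) {
  if (is.null(sasaDetail))
    sasaDetail <- interfaceSasa(complex, group1, group2)
  hs <- selectionSpec(heavyOnly = TRUE)
  a1 <- selectAtoms(selectAtoms(complex, group1), hs)@atoms
  a2 <- selectAtoms(selectAtoms(complex, group2), hs)@atoms
  cp <- crossPairs(a1, a2, contactDist)
  collect <- function(dRes, atoms, idx, grpname) {
    key <- resKey(atoms)
    touched <- unique(key[idx])
    mind <- rep(NA_real_, nrow(dRes))
    if (nrow(cp) > 0) {
      agg <- tapply(cp$distance, key[idx], min)
      mind[match(names(agg), resKey(dRes))] <- as.numeric(agg)
    }
    keep <- dRes$dsasa > dsasaMin | resKey(dRes) %in% touched
    out <- dRes[keep, , drop = FALSE]
    out$group <- rep(grpname, nrow(out))
    out$minDist <- mind[keep]
    out
  }
  r1 <- collect(sasaDetail$dRes1, a1, cp$i, "group1")
  r2 <- collect(sasaDetail$dRes2, a2, cp$j, "group2")
  res <- rbind(r1, r2)
  rownames(res) <- NULL
  spans <- do.call(rbind, lapply(split(res, res[, c("chain", "group")],
                                       drop = TRUE), function(df)
    data.frame(chain = df$chain[1], group = df$group[1],
               start = min(df$resno), end = max(df$resno),
               stringsAsFactors = FALSE)))
  if (is.null(spans))
    spans <- data.frame(chain = character(0), group = character(0),
                        start = integer(0), end = integer(0))
  spans <- spans[order(spans$group, spans$chain), , drop = FALSE]
  rownames(spans) <- NULL
  list(residues = res, spans = spans)
}

#' Hydrophobic interface clusters
#'
#' Groups one side's hydrophobic interface residues into clusters:
#' connected components of the graph whose nodes are that side's residues
#' carrying at least one cross-partition hydrophobic contact, with edges
#' between residues that share a common contact partner on the other
#' molecule or are sequence neighbours (same chain, residue numbers
#' within 4). Each cluster reports its `partnerPins` — residues of the
#' other molecule hydrophobically contacting at least half of the cluster
#' members, i.e. the residues seated in the cluster's pocket. The default
#' side is group 2: for a dimer + domain complex the pockets live on the
#' domain and the pins protrude from the dimer chains.
#'
#' @param contacts contact table from [classifyContacts()].
#' @param maxSeqGap sequence-neighbour edge threshold (default 4).
#' @param side `"group2"` (default) to cluster the group-2 residues, or
#'   `"group1"`.
#' @return list of clusters, each a list with `members` and `partnerPins`
#'   data.frames (`chain`, `resno`, `icode`, `resid`).
#' @export
hydrophobicClusters <- function(contacts, maxSeqGap = 4,
                                side = c("group2", "group1")) {
  side <- match.arg(side)
  hp <- contacts[contacts$kind == "hydrophobic", , drop = FALSE]
  if (nrow(hp) == 0) return(list())
  if (side == "group2") {
    nodeKey <- paste(hp$chainB, hp$resnoB, hp$icodeB, sep = "\r")
    partnerKey <- paste(hp$chainA, hp$resnoA, hp$icodeA, sep = "\r")
    nodeCols <- c("chainB", "resnoB", "icodeB", "residB")
    partnerCols <- c("chainA", "resnoA", "icodeA", "residA")
  } else {
    nodeKey <- paste(hp$chainA, hp$resnoA, hp$icodeA, sep = "\r")
    partnerKey <- paste(hp$chainB, hp$resnoB, hp$icodeB, sep = "\r")
    nodeCols <- c("chainA", "resnoA", "icodeA", "residA")
    partnerCols <- c("chainB", "resnoB", "icodeB", "residB")
  }
  nodes <- !duplicated(nodeKey)
  ndf <- data.frame(chain = hp[[nodeCols[1]]][nodes],
                    resno = hp[[nodeCols[2]]][nodes],
                    icode = hp[[nodeCols[3]]][nodes],
                    resid = hp[[nodeCols[4]]][nodes],
                    key = nodeKey[nodes], stringsAsFactors = FALSE)
  n <- nrow(ndf)
  adj <- matrix(FALSE, n, n)
  partnersOf <- split(partnerKey, factor(nodeKey, levels = ndf$key))
  for (p in seq_len(n)) {
    for (q in seq_len(n)) {
      if (q <= p) next
      shared <- length(intersect(partnersOf[[p]], partnersOf[[q]])) > 0
      seqnb <- ndf$chain[p] == ndf$chain[q] &&
        abs(ndf$resno[p] - ndf$resno[q]) <= maxSeqGap
      if (shared || seqnb) adj[p, q] <- adj[q, p] <- TRUE
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  lapply(sort(unique(comp)), function(ci) {
    mem <- ndf[comp == ci, c("chain", "resno", "icode", "resid"),
               drop = FALSE]
    memKey <- ndf$key[comp == ci]
    rownames(mem) <- NULL
    # partner residues contacting at least half the members
    inCluster <- nodeKey %in% memKey
    perPartner <- tapply(nodeKey[inCluster], partnerKey[inCluster],
                         function(k) length(unique(k)))
    pinKeys <- names(perPartner)[perPartner >= nrow(mem) / 2]
    pidx <- match(pinKeys, partnerKey)
    pins <- data.frame(chain = hp[[partnerCols[1]]][pidx],
                       resno = hp[[partnerCols[2]]][pidx],
                       icode = hp[[partnerCols[3]]][pidx],
                       resid = hp[[partnerCols[4]]][pidx],
                       stringsAsFactors = FALSE)
    pins <- pins[order(pins$chain, pins$resno), , drop = FALSE]
    rownames(pins) <- NULL
    list(members = mem[order(mem$chain, mem$resno), , drop = FALSE],
         partnerPins = pins)
  })
}

#' Detect pin residues
#'
#' A pin is a residue of group 1 whose sidechain inserts deeply into a
#' pocket of group 2: its sidechain buried fraction (sidechain
#' \eqn{\Delta}SASA over sidechain SASA in the isolated group) is at least
#' `burialMin` and it makes hydrophobic contacts with at least `partnerMin`
#' distinct group-2 residues. The thresholds (0.75, 4) are heuristics
#' calibrated on the synthetic benchmark complex so that a designed,
#' deeply-seated leucine qualifies and ordinary surface residues do not.
#'
#' @param complex a [StructureModel-class].
#' @param group1,group2 [SelectionSpec-class] partition.
#' @param contacts contact table from [classifyContacts()]; computed when
#'   `NULL`.
#' @param sasaDetail optional precomputed SASA bookkeeping.
#' @param burialMin minimum sidechain buried fraction (default 0.75).
#' @param partnerMin minimum distinct hydrophobic partner residues
#'   (default 4).
#' @return data.frame with one row per pin: `chain`, `resno`, `icode`,
#'   `resid`, `buriedFraction`, `nPartners`, `pocket` (comma-separated
#'   partner residue labels).
#' @export
pinResidues <- function(complex, group1, group2, contacts = NULL,
                        sasaDetail = NULL, burialMin = 0.75,
                        partnerMin = 4) {
  if (is.null(contacts))
    contacts <- classifyContacts(complex, group1, group2)
  if (is.null(sasaDetail))
    sasaDetail <- interfaceSasa(complex, group1, group2)
  empty <- data.frame(chain = character(0), resno = integer(0),
                      icode = character(0), resid = character(0),
                      buriedFraction = numeric(0), nPartners = integer(0),
                      pocket = character(0), stringsAsFactors = FALSE)
  hp <- contacts[contacts$kind == "hydrophobic", , drop = FALSE]
  if (nrow(hp) == 0) return(empty)
  candKey <- unique(paste(hp$chainA, hp$resnoA, hp$icodeA, sep = "\r"))
  atoms1 <- sasaDetail$s1@atoms
  iso <- sasaDetail$s1@perAtom
  cplx <- iso - sasaDetail$dAtom1
  akey <- resKey(atoms1)
  side <- !(atoms1$elety %in% .BACKBONE_ATOMS)
  rows <- lapply(candKey, function(k) {
    sel <- akey == k & side
    isoS <- sum(iso[sel])
    if (isoS <= 0) return(NULL)
    frac <- (isoS - sum(cplx[sel])) / isoS
    hk <- paste(hp$chainA, hp$resnoA, hp$icodeA, sep = "\r") == k
    partners <- unique(paste(hp$chainB[hk], hp$resnoB[hk], hp$icodeB[hk],
                             sep = "\r"))
    if (frac < burialMin || length(partners) < partnerMin) return(NULL)
    first <- which(akey == k)[1]
    plabels <- unique(sprintf("%s:%s%d", hp$chainB[hk], hp$residB[hk],
                              hp$resnoB[hk]))
    data.frame(chain = atoms1$chain[first], resno = atoms1$resno[first],
               icode = atoms1$icode[first], resid = atoms1$resid[first],
               buriedFraction = frac, nPartners = length(partners),
               pocket = paste(sort(plabels), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$chain, out$resno), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full interface report
#'
#' Orchestrates the complete interface characterization of a two-group
#' partition: buried surface area per group (with a per-chain breakdown),
#' interface residues and author-numbering spans, typed contacts,
#' hydrophobic clusters and pin residues. The asymmetry flag is set when
#' group 1 contains two chains whose interface spans differ — the signature
#' of a partner bound asymmetrically across a homodimer's two-fold axis.
#'
#' @param complex a [StructureModel-class].
#' @param group1,group2 [SelectionSpec-class] partition (for a dimer +
#'   domain complex, the dimer chains together form group 1).
#' @param cutoffs contact cutoffs, see [defaultContactCutoffs()].
#' @param dsasaMin,contactDist interface-residue thresholds, see
#'   [interfaceResidues()].
#' @param burialMin,partnerMin pin thresholds, see [pinResidues()].
#' @param probe,nPoints SASA parameters, see [shrakeRupleySasa()].
#' @return an [InterfaceReport-class].
#' @export
interfaceReport <- function(complex, group1, group2,
                            cutoffs = defaultContactCutoffs(),
                            dsasaMin = 0.1, contactDist = 5.0,
                            burialMin = 0.75, partnerMin = 4,
                            probe = 1.4, nPoints = 960) {
  detail <- interfaceSasa(complex, group1, group2, probe, nPoints)
  contacts <- classifyContacts(complex, group1, group2, cutoffs)
  ir <- interfaceResidues(complex, group1, group2, dsasaMin, contactDist,
                          sasaDetail = detail)
  clusters <- hydrophobicClusters(contacts)
  pins <- pinResidues(complex, group1, group2, contacts, detail,
                      burialMin, partnerMin)
  perChain <- function(atoms, d, grpname) {
    if (nrow(atoms) == 0)
      return(NULL)
    agg <- rowsum(d, atoms$chain)
    data.frame(chain = rownames(agg), group = grpname,
               bsa = pmax(0, as.numeric(agg)), stringsAsFactors = FALSE)
  }
  bsaPerChain <- rbind(perChain(detail$s1@atoms, detail$dAtom1, "group1"),
                       perChain(detail$s2@atoms, detail$dAtom2, "group2"))
  rownames(bsaPerChain) <- NULL
  g1spans <- ir$spans[ir$spans$group == "group1", , drop = FALSE]
  asym <- FALSE
  if (nrow(g1spans) >= 2) {
    rng <- unique(paste(g1spans$start, g1spans$end))
    asym <- length(rng) > 1
  }
  new("InterfaceReport",
      partition = list(group1 = group1, group2 = group2),
      bsa = pmax(detail$bsa, 0), bsaPerChain = bsaPerChain,
      interfaceResidues = ir$residues, spans = ir$spans,
      contacts = contacts, clusters = clusters, pins = pins,
      asymmetric = asym,
      options = list(cutoffs = cutoffs, dsasaMin = dsasaMin,
                     contactDist = contactDist, burialMin = burialMin,
                     partnerMin = partnerMin, probe = probe,
                     nPoints = nPoints))
}

#' Serialize an interface report
#'
#' `reportToJson()` writes the full report as JSON (numbers at 6
#' significant digits for stable diffs); `contactsToTsv()` writes the typed
#' contact table as TSV.
#'
#' @param report an [InterfaceReport-class].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
reportToJson <- function(report, path) {
  stopifnot(is(report, "InterfaceReport"))
  obj <- list(
    bsa = as.list(signif(report@bsa, 6)),
    bsaPerChain = report@bsaPerChain,
    spans = report@spans,
    asymmetric = report@asymmetric,
    interfaceResidues = report@interfaceResidues,
    contacts = report@contacts,
    clusters = lapply(report@clusters, function(cl)
      list(members = cl$members, partnerPins = cl$partnerPins)),
    pins = report@pins,
    options = report@options)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 6,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname reportToJson
#' @export
contactsToTsv <- function(report, path) {
  stopifnot(is(report, "InterfaceReport"))
  utils::write.table(report@contacts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
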