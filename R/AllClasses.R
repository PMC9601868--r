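#' @import methods
NULL

# Recognized element symbols for coordinate models handled here. Proteins
# only; nucleic-acid/ligand atoms pass through unchanged if their element is
# listed.
.KNOWN_ELEMENTS <- c("H", "D", "C", "N", "O", "S", "P", "SE", "FE", "ZN",
                     "MG", "MN", "CA", "NA", "K", "CL", "BR", "I", "F", "CU",
                     "NI", "CO")

.ATOM_COLUMNS <- c("chain", "resno", "icode", "resid", "elety", "element",
                   "x", "y", "z", "b", "occ", "altloc")

#' Atomic structure model
#'
#' An atomic coordinate model stored as a flat atom table (one row per atom),
#' the conventional representation for structural work in R. Rows keep file
#' order, so the chain \eqn{\to} residue \eqn{\to} atom hierarchy is
#' recoverable by grouping; [residueTable()] and [chainIds()] provide the
#' hierarchical views. For predicted models the B-factor column carries the
#' per-residue pLDDT confidence estimate (0--100), following the AlphaFold
#' convention.
#'
#' @slot atoms `data.frame` with columns `chain`, `resno` (author residue
#'   number), `icode` (insertion code, `""` if none), `resid` (3-letter
#'   residue name), `elety` (atom name, e.g. `"CA"`), `element`, `x`, `y`,
#'   `z` (\enc{Å}{Angstrom}), `b` (B-factor / pLDDT), `occ` (occupancy),
#'   `altloc` (`""` if none).
#' @slot modelId character scalar identifier.
#' @slot source file path the model was read from, or `"synthetic"`.
#'
#' @seealso [readStructure()], [writeStructure()], [selectAtoms()],
#'   [residueTable()]
#' @export
setClass("StructureModel",
  representation(atoms = "data.frame", modelId = "character",
                 source = "character"),
  prototype(modelId = "model", source = "synthetic"))

setValidity("StructureModel", function(object) {
  a <- object@atoms
  msgs <- character(0)
  missing_cols <- setdiff(.ATOM_COLUMNS, names(a))
  if (length(missing_cols) > 0)
    return(paste("atom table lacks columns:",
                 paste(missing_cols, collapse = ", ")))
  if (nrow(a) == 0) msgs <- c(msgs, "model has no atoms")
  if (nrow(a) > 0) {
    if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
      msgs <- c(msgs, "non-finite coordinates")
    if (any(!is.na(a$b) & a$b < 0))
      msgs <- c(msgs, "negative B-factor")
    bad <- setdiff(unique(toupper(a$element)), .KNOWN_ELEMENTS)
    if (length(bad) > 0)
      msgs <- c(msgs, paste("unrecognized element symbol(s):",
                            paste(bad, collapse = ", ")))
    key <- paste(a$chain, a$resno, a$icode, a$elety, a$altloc)
    if (anyDuplicated(key))
      msgs <- c(msgs, "duplicate atom (chain, resno, icode, name, altloc)")
  }
  if (length(msgs) == 0) TRUE else msgs
})

#' Predicted aligned error matrix
#'
#' Square matrix of predicted aligned error (PAE) values in
#' \enc{Å}{Angstrom}: entry \eqn{(i, j)} is the expected positional error of
#' residue \eqn{i} when the prediction is aligned on residue \eqn{j}. Rows
#' and columns follow model residue order; `residueIndex` maps matrix indices
#' to `(chain, resno)`.
#'
#' @slot values numeric n x n matrix, all entries >= 0.
#' @slot residueIndex `data.frame` with columns `chain`, `resno`, one row per
#'   matrix row/column, in order.
#'
#' @seealso [readPaeJson()], [paeBlock()]
#' @export
setClass("PAEMatrix",
  representation(values = "matrix", residueIndex = "data.frame"))

setValidity("PAEMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("PAE matrix must be square")
  if (any(!is.finite(v))) return("PAE matrix has non-finite entries")
  if (any(v < 0)) return("PAE matrix has negative entries")
  if (nrow(object@residueIndex) != nrow(v))
    return("residueIndex length must equal matrix dimension")
  if (!all(c("chain", "resno") %in% names(object@residueIndex)))
    return("residueIndex needs columns chain, resno")
  TRUE
})

#' Atom selection specification
#'
#' Declarative atom selection: any combination of chain identifiers, an
#' inclusive author-numbering residue range, a set of atom names, and a
#' heavy-atom-only flag. Empty fields select everything.
#'
#' @slot chainId character vector of chain ids (empty = all chains).
#' @slot resRange numeric of length 0 or 2, inclusive `[start, end]` in
#'   author numbering.
#' @slot atomNames character vector of atom names (empty = all).
#' @slot heavyOnly logical; drop hydrogens.
#'
#' @seealso [selectionSpec()], [selectAtoms()]
#' @export
setClass("SelectionSpec",
  representation(chainId = "character", resRange = "numeric",
                 atomNames = "character", heavyOnly = "logical"),
  prototype(chainId = character(0), resRange = numeric(0),
            atomNames = character(0), heavyOnly = FALSE))

setValidity("SelectionSpec", function(object) {
  if (!length(object@resRange) %in% c(0L, 2L))
    return("resRange must be empty or length 2")
  if (length(object@resRange) == 2 &&
      object@resRange[1] > object@resRange[2])
    return("resRange start must be <= end")
  if (length(object@heavyOnly) != 1) return("heavyOnly must be length 1")
  TRUE
})

#' Rigid-body transform
#'
#' Proper rotation plus translation, applied as \eqn{x \mapsto R x + t}.
#'
#' @slot rotation 3 x 3 proper orthogonal matrix (det = +1).
#' @slot translation numeric length-3 vector (\enc{Å}{Angstrom}).
#'
#' @seealso [kabschFit()], [applyTransform()]
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3, 3))) return("rotation must be 3x3")
  if (length(object@translation) != 3) return("translation must be length 3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    return("rotation is not orthogonal within 1e-8")
  if (abs(det(R) - 1) > 1e-8)
    return("rotation must be proper (det = +1)")
  TRUE
})

#' Superposition result
#'
#' @slot transform [RigidTransform-class] mapping mobile onto reference.
#' @slot rmsd root-mean-square deviation (\enc{Å}{Angstrom}) over the
#'   reported atom pairs after superposition.
#' @slot nAtoms number of atom pairs the RMSD was computed over.
#' @slot nFit number of atom pairs the transform was fitted on.
#'
#' @seealso [superposeModels()]
#' @export
setClass("SuperpositionResult",
  representation(transform = "RigidTransform", rmsd = "numeric",
                 nAtoms = "integer", nFit = "integer"))

setValidity("SuperpositionResult", function(object) {
  if (object@rmsd < 0) return("rmsd must be >= 0")
  if (object@nAtoms < 1) return("nAtoms must be >= 1")
  TRUE
})

#' Solvent-accessible surface area result
#'
#' Per-atom and per-residue solvent-accessible surface area (SASA) from the
#' deterministic Shrake--Rupley engine.
#'
#' @slot perAtom numeric vector, \enc{Å²}{A^2} per atom, aligned with
#'   `atoms` rows.
#' @slot atoms `data.frame` identifying the atoms (chain, resno, icode,
#'   resid, elety).
#' @slot perResidue `data.frame` with columns `chain`, `resno`, `icode`,
#'   `resid`, `sasa`.
#' @slot total total SASA (\enc{Å²}{A^2}).
#' @slot probeRadius probe radius used (\enc{Å}{Angstrom}).
#' @slot nPoints sphere quadrature point count.
#'
#' @seealso [shrakeRupleySasa()]
#' @export
setClass("SasaResult",
  representation(perAtom = "numeric", atoms = "data.frame",
                 perResidue = "data.frame", total = "numeric",
                 probeRadius = "numeric", nPoints = "integer"))

setValidity("SasaResult", function(object) {
  if (any(object@perAtom < 0)) return("negative per-atom SASA")
  if (abs(object@total - sum(object@perAtom)) > 1e-6)
    return("total must equal the sum of per-atom values")
  TRUE
})

#' Interface report
#'
#' Full characterization of the interface between two molecule groups of a
#' complex: buried surface area per group, interface residues and author-
#' numbering spans per chain, typed contacts, hydrophobic clusters, pin
#' residues, and an asymmetry flag (set when the per-chain spans of a
#' two-chain group differ, as for a domain bound asymmetrically across a
#' homodimer two-fold axis).
#'
#' @slot partition list of two [SelectionSpec-class] objects defining the
#'   molecule groups.
#' @slot bsa named numeric length 2: buried area (\enc{Å²}{A^2}) of each
#'   group.
#' @slot bsaPerChain `data.frame` chain-level breakdown (`chain`, `group`,
#'   `bsa`).
#' @slot interfaceResidues `data.frame`: `chain`, `resno`, `resid`, `group`.
#' @slot spans `data.frame`: `chain`, `group`, `start`, `end` (author
#'   numbering).
#' @slot contacts `data.frame` of typed contacts (see [classifyContacts()]).
#' @slot clusters list of hydrophobic clusters (see [hydrophobicClusters()]).
#' @slot pins `data.frame` of pin residues (see [pinResidues()]).
#' @slot asymmetric logical flag.
#' @slot options list of the cutoffs used.
#'
#' @seealso [interfaceReport()]
#' @export
setClass("InterfaceReport",
  representation(partition = "list", bsa = "numeric",
                 bsaPerChain = "data.frame", interfaceResidues = "data.frame",
                 spans = "data.frame", contacts = "data.frame",
                 clusters = "list", pins = "data.frame",
                 asymmetric = "logical", options = "list"))

#' SPR sensorgram
#'
#' A single surface plasmon resonance time-course: response units (RU)
#' against time for one analyte concentration, with the end of the injection
#' phase marking the start of dissociation.
#'
#' @slot times numeric, seconds, strictly increasing.
#' @slot response numeric, RU, same length as `times`.
#' @slot analyteConc analyte concentration (molar) during injection.
#' @slot tInjEnd end of injection / start of dissociation (s).
#'
#' @seealso [simulateTwoState()], [fitTwoState()]
#' @export
setClass("Sensorgram",
  representation(times = "numeric", response = "numeric",
                 analyteConc = "numeric", tInjEnd = "numeric"))

setValidity("Sensorgram", function(object) {
  if (length(object@times) != length(object@response))
    return("times and response must have equal length")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  if (object@analyteConc < 0) return("analyteConc must be >= 0")
  if (object@tInjEnd < min(object@times) ||
      object@tInjEnd > max(object@times))
    return("tInjEnd must lie within the time range")
  TRUE
})

#' Steady-state concentration series
#'
#' Equilibrium (plateau) SPR responses across an analyte concentration
#' series, the input of steady-state affinity analysis.
#'
#' @slot concs analyte concentrations (molar), all > 0, >= 2 distinct.
#' @slot req equilibrium responses (RU), same length.
#'
#' @seealso [fitEquilibrium()], [generateEquilibriumSeries()]
#' @export
setClass("EquilibriumSeries",
  representation(concs = "numeric", req = "numeric"))

setValidity("EquilibriumSeries", function(object) {
  if (length(object@concs) != length(object@req))
    return("concs and req must have equal length")
  if (any(object@concs <= 0)) return("concentrations must be > 0")
  if (length(unique(object@concs)) < 2)
    return("need at least 2 distinct concentrations")
  TRUE
})

#' Two-state kinetic parameters
#'
#' Rate constants of the two-state (conformational change) binding scheme
#' \deqn{A + B \rightleftharpoons AB \rightleftharpoons AB^*}
#' plus the saturation response: `ka1` (M\eqn{^{-1}}s\eqn{^{-1}}), `kd1`
#' (s\eqn{^{-1}}) for the binding step, `ka2`, `kd2` (both s\eqn{^{-1}}) for
#' the conformational step, and `rmax` (RU). The apparent dissociation
#' constant is \eqn{K_D = (k_{d1}/k_{a1}) \cdot k_{d2}/(k_{d2}+k_{a2})}.
#'
#' @slot ka1,kd1,ka2,kd2,rmax numeric scalars, all >= 0, `rmax` > 0.
#'
#' @seealso [kineticParams()], [kdApparent()]
#' @export
setClass("KineticParams",
  representation(ka1 = "numeric", kd1 = "numeric", ka2 = "numeric",
                 kd2 = "numeric", rmax = "numeric"))

setValidity("KineticParams", function(object) {
  v <- c(object@ka1, object@kd1, object@ka2, object@kd2, object@rmax)
  if (length(v) != 5 || any(!is.finite(v))) return("parameters must be finite scalars")
  if (any(v < 0)) return("rate constants must be >= 0")
  if (object@rmax <= 0) return("rmax must be > 0")
  TRUE
})

#' Binding fit result
#'
#' @slot params named numeric of fitted parameters (natural scale).
#' @slot kdApparent apparent dissociation constant (molar).
#' @slot rss residual sum of squares.
#' @slot se named numeric of per-parameter standard errors (natural scale;
#'   delta method from the log-parameterized fit).
#' @slot converged logical.
#' @slot nStarts number of multi-start seeds tried.
#' @slot model `"equilibrium"` or `"two_state"`.
#' @slot diagnostics character messages (e.g. identifiability warnings).
#'
#' @seealso [fitEquilibrium()], [fitTwoState()]
#' @export
setClass("FitResult",
  representation(params = "numeric", kdApparent = "numeric",
                 rss = "numeric", se = "numeric", converged = "logical",
                 nStarts = "integer", model = "character",
                 diagnostics = "character"))

setValidity("FitResult", function(object) {
  if (object@rss < 0) return("rss must be >= 0")
  if (isTRUE(object@converged) && !is.na(object@kdApparent) &&
      object@kdApparent <= 0)
    return("kdApparent must be > 0 when converged")
  TRUE
})
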