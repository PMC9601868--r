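#' Construct a structure model from an atom table
#'
#' Low-level constructor used by the readers and the synthetic generators.
#' Missing optional columns (`icode`, `altloc`, `occ`, `b`) are filled with
#' defaults; `element` is derived from the atom name when absent.
#'
#' @param atoms data.frame with at least `chain`, `resno`, `resid`, `elety`,
#'   `x`, `y`, `z`.
#' @param modelId character scalar identifier.
#' @param source provenance string (file path or `"synthetic"`).
#' @return a [StructureModel-class].
#' @export
structureModel <- function(atoms, modelId = "model", source = "synthetic") {
  stopifnot(is.data.frame(atoms))
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0)
    stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(atoms$icode)) atoms$icode <- ""
  if (is.null(atoms$altloc)) atoms$altloc <- ""
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$element))
    atoms$element <- guessElement(atoms$elety)
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  atoms$icode[is.na(atoms$icode)] <- ""
  atoms$altloc[is.na(atoms$altloc)] <- ""
  atoms <- atoms[, .ATOM_COLUMNS]
  rownames(atoms) <- NULL
  new("StructureModel", atoms = atoms, modelId = modelId, source = source)
}

#' Guess element symbols from PDB atom names
#'
#' @param elety character vector of atom names.
#' @return character vector of element symbols.
#' @keywords internal
guessElement <- function(elety) {
  nm <- toupper(gsub("[0-9' ]", "", elety))
  two <- c("SE", "FE", "ZN", "MG", "MN", "NA", "CL", "BR", "CU", "NI", "CO")
  out <- ifelse(nm %in% two, nm, substr(nm, 1, 1))
  # names like "1HB" reduce to "HB" -> hydrogen
  out[substr(nm, 1, 1) == "H"] <- "H"
  out
}

#' Read an atomic structure (PDB or mmCIF)
#'
#' Reads a coordinate file into a [StructureModel-class], preserving file
#' order. When several alternate locations are present for an atom, the one
#' with the highest occupancy is kept (ties broken by altloc character
#' order); predicted models carry no altlocs so this only affects
#' experimental references. Per-residue pLDDT is available afterwards via
#' [residueTable()] as the CA B-factor (mean atom B-factor for CA-less
#' residues), the convention used by structure predictors.
#'
#' @param path file path.
#' @param dialect `"auto"` (default; decided by file extension), `"pdb"` or
#'   `"mmcif"`.
#' @return a [StructureModel-class].
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writeLines(c(
#'   "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00 90.00           N",
#'   "ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00 90.00           C",
#'   "END"), pdb)
#' m <- readStructure(pdb)
#' nAtoms(m)
#' @export
readStructure <- function(path, dialect = c("auto", "pdb", "mmcif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  raw <- tryCatch(
    suppressWarnings(
      if (dialect == "pdb")
        bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
      else bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE)),
    error = function(e) stop("failed to parse ", dialect, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  a <- raw$atom
  if (is.null(a) || nrow(a) == 0) stop("no atoms in ", path)
  atoms <- data.frame(
    chain = ifelse(is.na(a$chain), "", as.character(a$chain)),
    resno = as.integer(a$resno),
    icode = ifelse(is.na(a$insert), "", as.character(a$insert)),
    resid = as.character(a$resid),
    elety = as.character(a$elety),
    element = toupper(ifelse(is.na(a$elesy) | a$elesy == "",
                             guessElement(a$elety),
                             as.character(a$elesy))),
    x = a$x, y = a$y, z = a$z,
    b = ifelse(is.na(a$b), 0, a$b),
    occ = ifelse(is.na(a$o), 1, a$o),
    altloc = ifelse(is.na(a$alt), "", as.character(a$alt)),
    stringsAsFactors = FALSE)
  atoms <- collapseAltlocs(atoms)
  structureModel(atoms, modelId = basename(path), source = path)
}

# Keep one altloc per atom: highest occupancy, ties by altloc character.
collapseAltlocs <- function(atoms) {
  if (all(atoms$altloc == "")) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$elety,
               sep = "\r")
  ord <- order(key, -atoms$occ, atoms$altloc)
  keep <- ord[!duplicated(key[ord])]
  out <- atoms[sort(keep), , drop = FALSE]
  out$altloc <- ""
  rownames(out) <- NULL
  out
}

#' Write a structure model as a fixed-column PDB file
#'
#' Emits standard `ATOM` records (with `TER`/`END`). Coordinates are written
#' at the 3-decimal PDB column precision; re-reading reproduces the
#' hierarchy. Values that do not fit the fixed columns (coordinates beyond
#' +/-9999.999, residue numbers above 9999) raise an error rather than
#' silently corrupting the file.
#'
#' @param model a [StructureModel-class].
#' @param path output path.
#' @param dialect only `"pdb"` is supported.
#' @return invisibly, `path`.
#' @export
writeStructure <- function(model, path, dialect = "pdb") {
  stopifnot(is(model, "StructureModel"))
  if (!identical(dialect, "pdb"))
    stop("unsupported output dialect: ", dialect)
  a <- model@atoms
  if (nrow(a) == 0) stop("refusing to write an empty model")
  if (any(abs(c(a$x, a$y, a$z)) > 9999.999))
    stop("coordinate overflows the 8.3 PDB column")
  if (any(a$resno > 9999 | a$resno < -999))
    stop("residue number does not fit the 4-character PDB column")
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, chain = a$chain,
                   insert = ifelse(a$icode == "", NA, a$icode),
                   alt = ifelse(a$altloc == "", NA, a$altloc),
                   elety = a$elety, o = a$occ, b = a$b,
                   elesy = a$element, chainter = TRUE, end = TRUE)
  invisible(path)
}

#' Construct a PAE matrix
#'
#' @param values square numeric matrix of predicted aligned errors
#'   (\enc{Å}{Angstrom}), all >= 0.
#' @param residueIndex optional data.frame with columns `chain`, `resno`
#'   mapping matrix indices to model residues; defaults to sequential
#'   numbering with an empty chain id.
#' @return a [PAEMatrix-class].
#' @export
paeMatrix <- function(values, residueIndex = NULL) {
  values <- as.matrix(values)
  if (is.null(residueIndex))
    residueIndex <- data.frame(chain = "", resno = seq_len(nrow(values)),
                               stringsAsFactors = FALSE)
  new("PAEMatrix", values = values, residueIndex = residueIndex)
}

#' Read an AlphaFold-style PAE JSON file
#'
#' Accepts the AlphaFold database layout (a one-element array of objects) as
#' well as a bare object, and looks up the conventional
#' `predicted_aligned_error` key. The matrix must be square with
#' non-negative entries.
#'
#' @param path JSON file path.
#' @param residueIndex optional residue index (see [paeMatrix()]).
#' @return a [PAEMatrix-class].
#' @export
readPaeJson <- function(path, residueIndex = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  pae <- NULL
  if (is.data.frame(obj) && "predicted_aligned_error" %in% names(obj)) {
    pae <- obj$predicted_aligned_error[[1]]
  } else if (is.list(obj)) {
    if (!is.null(obj[["predicted_aligned_error"]])) {
      pae <- obj[["predicted_aligned_error"]]
    } else if (length(obj) >= 1 && is.list(obj[[1]]) &&
               !is.null(obj[[1]][["predicted_aligned_error"]])) {
      pae <- obj[[1]][["predicted_aligned_error"]]
    }
  }
  if (is.null(pae))
    stop("no 'predicted_aligned_error' key found in ", path)
  pae <- as.matrix(pae)
  if (nrow(pae) != ncol(pae))
    stop("PAE matrix in ", path, " is not square (", nrow(pae), " x ",
         ncol(pae), ")")
  if (any(pae < 0)) stop("PAE matrix in ", path, " has negative entries")
  paeMatrix(pae, residueIndex)
}

#' Build a selection specification
#'
#' @param chainId character vector of chain ids (empty = all).
#' @param resRange inclusive author-numbering range `c(start, end)`, or
#'   `NULL`.
#' @param atomNames character vector of atom names (empty = all).
#' @param heavyOnly drop hydrogens.
#' @return a [SelectionSpec-class].
#' @examples
#' selectionSpec(chainId = "A", resRange = c(294, 321))
#' @export
selectionSpec <- function(chainId = character(0), resRange = NULL,
                          atomNames = character(0), heavyOnly = FALSE) {
  new("SelectionSpec", chainId = as.character(chainId),
      resRange = if (is.null(resRange)) numeric(0) else as.numeric(resRange),
      atomNames = as.character(atomNames), heavyOnly = heavyOnly)
}

# Logical mask of atoms matching a SelectionSpec.
selectionMask <- function(atoms, spec) {
  keep <- rep(TRUE, nrow(atoms))
  if (length(spec@chainId) > 0) keep <- keep & atoms$chain %in% spec@chainId
  if (length(spec@resRange) == 2)
    keep <- keep & atoms$resno >= spec@resRange[1] &
      atoms$resno <= spec@resRange[2]
  if (length(spec@atomNames) > 0)
    keep <- keep & atoms$elety %in% spec@atomNames
  if (isTRUE(spec@heavyOnly))
    keep <- keep & !(atoms$element %in% c("H", "D"))
  keep
}

#' Select a sub-model
#'
#' Projects a model onto the atoms matching a [SelectionSpec-class]. An
#' empty selection is allowed and returns a model with an empty atom table
#' (which most downstream operations reject).
#'
#' @param model a [StructureModel-class].
#' @param spec a [SelectionSpec-class].
#' @return a [StructureModel-class] containing only the matching atoms.
#' @export
selectAtoms <- function(model, spec) {
  stopifnot(is(model, "StructureModel"), is(spec, "SelectionSpec"))
  atoms <- model@atoms[selectionMask(model@atoms, spec), , drop = FALSE]
  rownames(atoms) <- NULL
  out <- model
  out@atoms <- atoms
  out
}

#' Pair equivalent atoms of two models
#'
#' Atoms are equivalent when they agree on `(chain, resno, icode, elety)`;
#' unmatched atoms are dropped. The pairing is symmetric: swapping the
#' arguments yields the same pairs.
#'
#' @param a,b [StructureModel-class] objects.
#' @return data.frame with columns `idxA`, `idxB` (row indices into the two
#'   atom tables) plus the identifying key columns.
#' @export
equivalentAtomMap <- function(a, b) {
  stopifnot(is(a, "StructureModel"), is(b, "StructureModel"))
  ta <- a@atoms; tb <- b@atoms
  keyA <- paste(ta$chain, ta$resno, ta$icode, ta$elety, sep = "\r")
  keyB <- paste(tb$chain, tb$resno, tb$icode, tb$elety, sep = "\r")
  ia <- which(!duplicated(keyA)); ib <- which(!duplicated(keyB))
  m <- match(keyA[ia], keyB[ib])
  sel <- !is.na(m)
  if (!any(sel))
    stop("no equivalent atoms between the two models (nothing to compare)")
  idxA <- ia[sel]; idxB <- ib[m[sel]]
  data.frame(idxA = idxA, idxB = idxB, chain = ta$chain[idxA],
             resno = ta$resno[idxA], icode = ta$icode[idxA],
             elety = ta$elety[idxA], stringsAsFactors = FALSE)
}

# 3-column coordinate matrix of (a subset of) a model's atoms.
coordMatrix <- function(model, idx = NULL) {
  a <- model@atoms
  if (!is.null(idx)) a <- a[idx, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}
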