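#' Accessors for coordinate models and results
#'
#' `atomTable()` returns the flat atom table; `chainIds()` the chain
#' identifiers in file order; `residueTable()` one row per residue (file
#' order) with the residue-level pLDDT (the CA B-factor by the predictor
#' convention, mean atom B-factor for CA-less residues); `nAtoms()` and
#' `nResidues()` the obvious counts.
#'
#' @param x a [StructureModel-class] (or for `kdApparent()`, a
#'   [FitResult-class] or [KineticParams-class]).
#' @return `atomTable()`: data.frame; `chainIds()`: character;
#'   `residueTable()`: data.frame with columns `chain`, `resno`, `icode`,
#'   `resid`, `nAtoms`, `plddt`; counts: integer.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname accessors
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' @rdname accessors
#' @export
setGeneric("residueTable", function(x) standardGeneric("residueTable"))

#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname accessors
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @rdname accessors
#' @export
setGeneric("kdApparent", function(x) standardGeneric("kdApparent"))

#' @rdname accessors
#' @export
setMethod("atomTable", "StructureModel", function(x) x@atoms)

#' @rdname accessors
#' @export
setMethod("chainIds", "StructureModel",
          function(x) unique(x@atoms$chain))

#' @rdname accessors
#' @export
setMethod("nAtoms", "StructureModel", function(x) nrow(x@atoms))

#' @rdname accessors
#' @export
setMethod("residueTable", "StructureModel", function(x) {
  a <- x@atoms
  key <- paste(a$chain, a$resno, a$icode, sep = "\r")
  first <- !duplicated(key)
  grp <- match(key, key[first])
  # split() orders integer groups numerically, i.e. by first occurrence here
  plddt <- vapply(split(seq_len(nrow(a)), grp), function(idx) {
    i_ca <- idx[a$elety[idx] == "CA"]
    if (length(i_ca) >= 1) a$b[i_ca[1]] else mean(a$b[idx])
  }, numeric(1))
  out <- data.frame(chain = a$chain[first], resno = a$resno[first],
                    icode = a$icode[first], resid = a$resid[first],
                    nAtoms = as.integer(tabulate(grp)),
                    plddt = unname(plddt),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
})

#' @rdname accessors
#' @export
setMethod("nResidues", "StructureModel", function(x) {
  a <- x@atoms
  length(unique(paste(a$chain, a$resno, a$icode, sep = "\r")))
})

setMethod("show", "StructureModel", function(object) {
  rt <- residueTable(object)
  cat("StructureModel '", object@modelId, "' (", object@source, ")\n",
      sep = "")
  cat("  ", length(chainIds(object)), " chain(s): ",
      paste(chainIds(object), collapse = ", "), "\n", sep = "")
  cat("  ", nrow(rt), " residues, ", nAtoms(object), " atoms\n", sep = "")
  if (!all(is.na(rt$plddt)))
    cat("  pLDDT (B-factor) range: ",
        sprintf("%.1f-%.1f", min(rt$plddt, na.rm = TRUE),
                max(rt$plddt, na.rm = TRUE)), "\n", sep = "")
})

setMethod("show", "PAEMatrix", function(object) {
  cat("PAEMatrix: ", nrow(object@values), " x ", ncol(object@values),
      " residues, values ", sprintf("%.2f-%.2f", min(object@values),
      max(object@values)), " Å\n", sep = "")
})

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform\n  rotation:\n")
  print(round(object@rotation, 6))
  cat("  translation: ", paste(sprintf("%.4f", object@translation),
      collapse = " "), "\n", sep = "")
})

setMethod("show", "SuperpositionResult", function(object) {
  cat(sprintf("SuperpositionResult: rmsd %.4f Å over %d atoms (fit on %d)\n",
              object@rmsd, object@nAtoms, object@nFit))
})

setMethod("show", "SasaResult", function(object) {
  cat(sprintf(
    "SasaResult: total %.2f Å² over %d atoms (probe %.2f Å, %d points)\n",
    object@total, length(object@perAtom), object@probeRadius,
    object@nPoints))
})

setMethod("show", "InterfaceReport", function(object) {
  cat("InterfaceReport\n")
  cat(sprintf("  buried surface area: group1 %.1f / group2 %.1f Å²\n",
              object@bsa[1], object@bsa[2]))
  cat("  interface residues: ", nrow(object@interfaceResidues),
      " across ", length(unique(object@interfaceResidues$chain)),
      " chain(s)\n", sep = "")
  if (nrow(object@spans) > 0) {
    sp <- object@spans
    cat("  spans: ", paste(sprintf("%s:%d-%d", sp$chain, sp$start, sp$end),
                           collapse = ", "), "\n", sep = "")
  }
  cat("  contacts: ", nrow(object@contacts), " (",
      paste(sprintf("%s %d", names(table(object@contacts$kind)),
                    as.integer(table(object@contacts$kind))),
            collapse = ", "), ")\n", sep = "")
  cat("  hydrophobic clusters: ", length(object@clusters),
      "; pins: ", nrow(object@pins), "\n", sep = "")
  cat("  asymmetric interface: ", object@asymmetric, "\n", sep = "")
})

setMethod("show", "Sensorgram", function(object) {
  cat(sprintf(
    "Sensorgram: %d points, conc %.3g M, injection ends at %.0f s, max %.2f RU\n",
    length(object@times), object@analyteConc, object@tInjEnd,
    max(object@response)))
})

setMethod("show", "EquilibriumSeries", function(object) {
  cat(sprintf("EquilibriumSeries: %d concentrations, %.3g-%.3g M\n",
              length(object@concs), min(object@concs), max(object@concs)))
})

setMethod("show", "KineticParams", function(object) {
  cat(sprintf(
    "KineticParams: ka1 %.3g /M/s, kd1 %.3g /s, ka2 %.3g /s, kd2 %.3g /s, rmax %.3g RU\n",
    object@ka1, object@kd1, object@ka2, object@kd2, object@rmax))
  cat(sprintf("  apparent Kd: %.4g M\n", kdApparent(object)))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult (%s): converged = %s, rss = %.4g, %d start(s)\n",
              object@model, object@converged, object@rss, object@nStarts))
  cat(sprintf("  apparent Kd: %.4g M\n", object@kdApparent))
  p <- object@params
  for (nm in names(p))
    cat(sprintf("  %-5s %.5g (se %.3g)\n", nm, p[[nm]],
                if (nm %in% names(object@se)) object@se[[nm]] else NA_real_))
  if (length(object@diagnostics) > 0)
    cat("  notes: ", paste(object@diagnostics, collapse = "; "), "\n",
        sep = "")
})

#' @rdname accessors
#' @export
setMethod("kdApparent", "KineticParams", function(x) {
  if (x@ka1 == 0) return(Inf)
  (x@kd1 / x@ka1) * if (x@kd2 + x@ka2 > 0) x@kd2 / (x@kd2 + x@ka2) else 1
})

#' @rdname accessors
#' @export
setMethod("kdApparent", "FitResult", function(x) x@kdApparent)
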