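#' Default van der Waals radii
#'
#' Field-standard heavy-atom radii (\enc{Å}{Angstrom}) used by the SASA
#' engine: C 1.70, N 1.55, O 1.52, S 1.80. Hydrogens (1.20) and selenium
#' (1.90) are included for completeness; geometry runs exclude hydrogens by
#' default since predicted models omit them.
#'
#' @return named numeric vector of radii.
#' @export
defaultVdwRadii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, D = 1.20, SE = 1.90,
    P = 1.80)
}

#' Deterministic golden-spiral unit sphere points
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @keywords internal
goldenSpiralPoints <- function(n) {
  k <- seq_len(n)
  z <- 1 - (2 * k - 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  phi <- (k - 1) * golden
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake--Rupley solvent-accessible surface area
#'
#' Computes per-atom SASA by sampling each atom's solvent-extended sphere
#' (van der Waals radius + probe) with a deterministic golden-spiral point
#' set and counting points not occluded by any neighbouring atom's extended
#' sphere. No randomness is involved: repeated runs are identical.
#'
#' @param model a [StructureModel-class].
#' @param probe probe radius in \enc{Å}{Angstrom} (default 1.4, water).
#' @param nPoints quadrature points per atom (default 960).
#' @param radii named vector of per-element radii; defaults to
#'   [defaultVdwRadii()]. An atom whose element has no radius raises an
#'   error.
#' @param includeHydrogens keep hydrogens in the calculation (default
#'   FALSE).
#' @return a [SasaResult-class].
#' @examples
#' m <- structureModel(data.frame(chain = "A", resno = 1, resid = "GLY",
#'                                elety = "C", x = 0, y = 0, z = 0))
#' shrakeRupleySasa(m)@total  # lone carbon: 4*pi*(1.70+1.4)^2 = 120.76
#' @export
shrakeRupleySasa <- function(model, probe = 1.4, nPoints = 960,
                             radii = defaultVdwRadii(),
                             includeHydrogens = FALSE) {
  stopifnot(is(model, "StructureModel"))
  a <- model@atoms
  if (!includeHydrogens) a <- a[!(a$element %in% c("H", "D")), ,
                                drop = FALSE]
  if (nrow(a) == 0) stop("no atoms to compute SASA over")
  el <- toupper(a$element)
  unknown <- setdiff(unique(el), names(radii))
  if (length(unknown) > 0)
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "),
         " - supply them via the 'radii' argument")
  r <- unname(radii[el])
  pts <- goldenSpiralPoints(nPoints)
  per_atom <- .sasaEngine(as.matrix(a[, c("x", "y", "z")]), r, probe, pts)
  key <- paste(a$chain, a$resno, a$icode, sep = "\r")
  first <- !duplicated(key)
  grp <- match(key, key[first])
  per_res <- data.frame(chain = a$chain[first], resno = a$resno[first],
                        icode = a$icode[first], resid = a$resid[first],
                        sasa = as.numeric(rowsum(per_atom, grp)),
                        stringsAsFactors = FALSE)
  rownames(per_res) <- NULL
  new("SasaResult", perAtom = as.numeric(per_atom),
      atoms = a[, c("chain", "resno", "icode", "resid", "elety")],
      perResidue = per_res, total = sum(per_atom),
      probeRadius = probe, nPoints = as.integer(nPoints))
}
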