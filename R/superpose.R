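#' Least-squares rigid-body fit (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the sum of squared
#' distances between paired coordinates, by singular value decomposition of
#' the cross-covariance matrix with the usual determinant sign correction so
#' that reflections are excluded.
#'
#' @param mobile,reference n x 3 coordinate matrices (paired rows), n >= 3
#'   and not all collinear.
#' @return a [RigidTransform-class] mapping `mobile` onto `reference`.
#' @export
kabschFit <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3)
    stop("coordinate sets must be equal-size n x 3 matrices")
  n <- nrow(mobile)
  if (n < 3) stop("need at least 3 paired atoms for a rigid fit")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  M <- sweep(mobile, 2, cm); Rf <- sweep(reference, 2, cr)
  H <- crossprod(M, Rf)             # sum over pairs of m_i r_i^T
  sv <- svd(H)
  # degenerate (collinear) point sets leave the rotation underdetermined
  scale0 <- max(sv$d[1], .Machine$double.eps)
  if (sv$d[2] / scale0 < 1e-10 && sum(M^2) > 0)
    stop("degenerate (collinear) coordinates: rigid fit is underdetermined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  new("RigidTransform", rotation = R,
      translation = as.numeric(cr - R %*% cm))
}

#' Apply a rigid transform to a model
#'
#' Maps every atom coordinate through \eqn{x \mapsto R x + t}. Pairwise
#' intra-model distances are preserved (proper rigid motion).
#'
#' @param model a [StructureModel-class].
#' @param transform a [RigidTransform-class].
#' @return the transformed [StructureModel-class].
#' @export
applyTransform <- function(model, transform) {
  stopifnot(is(model, "StructureModel"), is(transform, "RigidTransform"))
  xyz <- coordMatrix(model)
  new_xyz <- xyz %*% t(transform@rotation)
  new_xyz <- sweep(new_xyz, 2, transform@translation, "+")
  out <- model
  out@atoms$x <- new_xyz[, 1]
  out@atoms$y <- new_xyz[, 2]
  out@atoms$z <- new_xyz[, 3]
  out
}

#' Compose two rigid transforms
#'
#' `composeTransforms(t2, t1)` is the transform equivalent to applying `t1`
#' first, then `t2`.
#'
#' @param t2,t1 [RigidTransform-class] objects.
#' @return a [RigidTransform-class].
#' @export
composeTransforms <- function(t2, t1) {
  new("RigidTransform",
      rotation = t2@rotation %*% t1@rotation,
      translation = as.numeric(t2@rotation %*% t1@translation +
                                 t2@translation))
}

#' Superpose one model onto another and report RMSD
#'
#' Pairs equivalent atoms of the two models (same chain, author residue
#' number, insertion code and atom name; heavy atoms by default, since
#' predicted models carry no hydrogens), fits the rigid transform on the
#' `fitOn` selection and reports the RMSD over the `reportOn` selection —
#' both default to all equivalent heavy atoms, the "all equivalent atoms"
#' convention for comparing a predicted model against an experimental
#' structure. When the two models use different chain labelling (e.g. a
#' monomer model against one chain of a dimer), `chainMap` renames mobile
#' chains before matching; no automatic chain assignment is attempted.
#'
#' @param mobile,reference [StructureModel-class] objects.
#' @param fitOn,reportOn [SelectionSpec-class] objects (default: everything,
#'   heavy atoms only).
#' @param chainMap named character vector renaming mobile chains, e.g.
#'   `c(A = "B")` relabels mobile chain A as B.
#' @param heavyOnly drop hydrogens before matching (default TRUE).
#' @return a [SuperpositionResult-class].
#' @export
superposeModels <- function(mobile, reference,
                            fitOn = selectionSpec(),
                            reportOn = fitOn,
                            chainMap = NULL, heavyOnly = TRUE) {
  stopifnot(is(mobile, "StructureModel"), is(reference, "StructureModel"))
  if (!is.null(chainMap)) {
    ch <- mobile@atoms$chain
    hit <- ch %in% names(chainMap)
    mobile@atoms$chain[hit] <- unname(chainMap[ch[hit]])
  }
  if (heavyOnly) {
    hs <- selectionSpec(heavyOnly = TRUE)
    mobile <- selectAtoms(mobile, hs)
    reference <- selectAtoms(reference, hs)
  }
  pairAndCoords <- function(spec) {
    msel <- selectAtoms(mobile, spec)
    rsel <- selectAtoms(reference, spec)
    if (nrow(msel@atoms) == 0 || nrow(rsel@atoms) == 0)
      stop("selection matches no atoms in one of the models")
    map <- equivalentAtomMap(msel, rsel)
    list(mob = coordMatrix(msel, map$idxA),
         ref = coordMatrix(rsel, map$idxB), n = nrow(map))
  }
  fit <- pairAndCoords(fitOn)
  transform <- kabschFit(fit$mob, fit$ref)
  rep_ <- if (identical(fitOn, reportOn)) fit else pairAndCoords(reportOn)
  moved <- sweep(rep_$mob %*% t(transform@rotation), 2,
                 transform@translation, "+")
  rmsd <- sqrt(mean(rowSums((moved - rep_$ref)^2)))
  new("SuperpositionResult", transform = transform, rmsd = rmsd,
      nAtoms = as.integer(rep_$n), nFit = as.integer(fit$n))
}
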