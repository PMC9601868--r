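# Independent oracles used to cross-check the package implementations.
# These deliberately use different algorithms from the code under test.

# Optimal-superposition RMSD by the quaternion characteristic-polynomial
# route: the maximum eigenvalue of the 4x4 key matrix built from the
# cross-covariance gives the optimal overlap directly, without computing
# the rotation. Independent of the SVD-based Kabsch implementation.
quaternionRmsd <- function(X, Y) {
  stopifnot(nrow(X) == nrow(Y), ncol(X) == 3)
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  G <- sum(Xc^2) + sum(Yc^2)
  M <- crossprod(Xc, Yc)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lmax <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, G - 2 * lmax) / n)
}

# Analytic SASA of two equal spheres (radius r, probe p) at centre
# distance d: each solvent-extended sphere (R = r + p) loses a cap of
# height h = R - d/2 when d < 2R.
twoSphereSasaAnalytic <- function(r, probe, d) {
  R <- r + probe
  if (d >= 2 * R) return(2 * 4 * pi * R^2)
  h <- R - d / 2
  2 * (4 * pi * R^2 - 2 * pi * R * h)
}

# random rigid transform (proper rotation + translation), seeded outside
randomRigidTransform <- function() {
  A <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(A)
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  list(R = Q, t = stats::rnorm(3, sd = 5))
}

# deSolve integration of the two-state scheme, used as an independent
# check of the closed-form forward model.
odeTwoStateOracle <- function(params, conc, times, tInjEnd) {
  rhs <- function(t, y, parms) {
    C <- if (t <= tInjEnd) conc else 0
    ab <- y[1]; abs_ <- y[2]
    list(c(params@ka1 * C * (params@rmax - ab - abs_) -
             params@kd1 * ab - params@ka2 * ab + params@kd2 * abs_,
           params@ka2 * ab - params@kd2 * abs_))
  }
  out <- deSolve::lsoda(c(0, 0), times, rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
  as.numeric(out[, 2] + out[, 3])
}
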