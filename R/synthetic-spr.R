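# Synthetic SPR data from known binding parameters, emulating the
# bench protocol: 60 s injection followed by a 600 s buffer wash, analyte
# concentration series by serial dilution.

# run expr with a private, restored RNG stream
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

#' Specification of a synthetic sensorgram set
#'
#' Defaults emulate the study protocol: 60 s injection, 600 s wash,
#' sampling every 2 s, a 3-fold serial dilution from 1 \eqn{\mu}M, and
#' wild-type-like two-state kinetics (apparent \eqn{K_d \approx} 16.7 nM)
#' with 1 RU Gaussian noise on a 100 RU surface.
#'
#' @param params a [KineticParams-class].
#' @param concentrations analyte concentrations (M).
#' @param tInjEnd injection length (s).
#' @param tEnd end of the wash (s).
#' @param dt sampling interval (s).
#' @param noiseSd Gaussian noise s.d. (RU).
#' @param drift baseline drift (RU/s), 0 by default (reference-subtracted
#'   data).
#' @param nReplicates replicates per concentration.
#' @param seed integer seed; all randomness flows through it.
#' @return list of class `SprSpec`.
#' @export
sprSpec <- function(params = kineticParams(1e5, 5e-3, 4e-3, 2e-3, 100),
                    concentrations = 1e-6 / 3^(0:4), tInjEnd = 60,
                    tEnd = 660, dt = 2, noiseSd = 1, drift = 0,
                    nReplicates = 1, seed = 1) {
  stopifnot(is(params, "KineticParams"), all(concentrations > 0),
            noiseSd >= 0, nReplicates >= 1)
  structure(list(params = params, concentrations = concentrations,
                 tInjEnd = tInjEnd, tEnd = tEnd, dt = dt,
                 noiseSd = noiseSd, drift = drift,
                 nReplicates = nReplicates, seed = seed),
            class = "SprSpec")
}

#' Simulate a set of sensorgrams
#'
#' One sensorgram per concentration and replicate: the exact two-state
#' forward model plus seeded Gaussian noise and optional linear drift.
#' Identical spec and seed give identical output.
#'
#' @param spec an [sprSpec()].
#' @return list of [Sensorgram-class] objects, ordered by concentration
#'   (as given) then replicate.
#' @export
simulateSensorgramSet <- function(spec = sprSpec()) {
  stopifnot(inherits(spec, "SprSpec"))
  tGrid <- seq(0, spec$tEnd, by = spec$dt)
  withSeed(spec$seed, {
    out <- list()
    for (conc in spec$concentrations) {
      clean <- twoStateResponse(spec$params, conc, tGrid, spec$tInjEnd)
      for (rep_ in seq_len(spec$nReplicates)) {
        resp <- clean
        if (spec$noiseSd > 0)
          resp <- resp + stats::rnorm(length(tGrid), 0, spec$noiseSd)
        if (spec$drift != 0) resp <- resp + spec$drift * tGrid
        out[[length(out) + 1]] <- sensorgram(tGrid, resp, conc,
                                             spec$tInjEnd)
      }
    }
    out
  })
}

#' Generate a steady-state concentration series
#'
#' Equilibrium responses from the 1:1 steady-state model plus seeded
#' Gaussian noise.
#'
#' @param kd dissociation constant (M).
#' @param rmax saturation response (RU).
#' @param concentrations analyte concentrations (M); default 8 points
#'   log-spaced from 0.1 to 100 times `kd`.
#' @param noiseSd Gaussian noise s.d. (RU).
#' @param seed integer seed.
#' @return an [EquilibriumSeries-class].
#' @export
generateEquilibriumSeries <- function(kd = 14.6e-9, rmax = 100,
                                      concentrations = NULL,
                                      noiseSd = 0, seed = 1) {
  stopifnot(kd > 0, rmax > 0, noiseSd >= 0)
  if (is.null(concentrations))
    concentrations <- kd * 10^seq(-1, 2, length.out = 8)
  req <- equilibriumResponse(concentrations, kd, rmax)
  if (noiseSd > 0)
    req <- withSeed(seed, req + stats::rnorm(length(req), 0, noiseSd))
  equilibriumSeries(concentrations, req)
}
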