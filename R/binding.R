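#' Construct two-state kinetic parameters
#'
#' @param ka1 association rate of the binding step (M\eqn{^{-1}}s\eqn{^{-1}}).
#' @param kd1 dissociation rate of the binding step (s\eqn{^{-1}}).
#' @param ka2 forward rate of the conformational step (s\eqn{^{-1}}).
#' @param kd2 reverse rate of the conformational step (s\eqn{^{-1}}).
#' @param rmax saturation response (RU).
#' @return a [KineticParams-class].
#' @examples
#' p <- kineticParams(1e5, 5e-3, 4e-3, 2e-3, 100)
#' kdApparent(p)  # (kd1/ka1) * kd2/(kd2 + ka2)
#' @export
kineticParams <- function(ka1, kd1, ka2 = 0, kd2 = 0, rmax = 100) {
  new("KineticParams", ka1 = ka1, kd1 = kd1, ka2 = ka2, kd2 = kd2,
      rmax = rmax)
}

#' Construct a sensorgram
#'
#' @param times time points (s), strictly increasing.
#' @param response responses (RU).
#' @param analyteConc analyte concentration (M).
#' @param tInjEnd end of injection (s).
#' @return a [Sensorgram-class].
#' @export
sensorgram <- function(times, response, analyteConc, tInjEnd) {
  new("Sensorgram", times = as.numeric(times),
      response = as.numeric(response), analyteConc = analyteConc,
      tInjEnd = tInjEnd)
}

#' Construct an equilibrium series
#'
#' @param concs analyte concentrations (M), > 0.
#' @param req equilibrium responses (RU).
#' @return an [EquilibriumSeries-class].
#' @export
equilibriumSeries <- function(concs, req) {
  new("EquilibriumSeries", concs = as.numeric(concs),
      req = as.numeric(req))
}

#' Steady-state 1:1 binding response
#'
#' The Langmuir steady-state response
#' \deqn{R_{eq} = R_{max} \, C / (K_d + C),}
#' monotone increasing in the analyte concentration \eqn{C} and saturating
#' at \eqn{R_{max}}.
#'
#' @param conc analyte concentration(s), molar, >= 0.
#' @param kd equilibrium dissociation constant, molar, > 0.
#' @param rmax saturation response (RU).
#' @return response(s) in RU.
#' @examples
#' equilibriumResponse(14.6e-9, 14.6e-9, 100)  # half-saturation: 50
#' @export
equilibriumResponse <- function(conc, kd, rmax) {
  if (any(kd <= 0)) stop("kd must be > 0")
  if (any(conc < 0)) stop("concentrations must be >= 0")
  rmax * conc / (kd + conc)
}

# One constant-concentration phase of the two-state scheme
#   A + B <-> AB <-> AB*
#   d[AB]/dt  = ka1 C (Rmax - AB - AB*) - kd1 AB - ka2 AB + kd2 AB*
#   d[AB*]/dt = ka2 AB - kd2 AB*
# a linear constant-coefficient ODE, solved in closed form by 2x2
# eigen-decomposition (exact); a stiff-solver fallback covers degenerate
# eigenvalue configurations.
twoStatePhase <- function(x0, C, p, times) {
  ka1 <- p@ka1; kd1 <- p@kd1; ka2 <- p@ka2; kd2 <- p@kd2; rmax <- p@rmax
  nt <- length(times)
  if (nt == 0) return(matrix(numeric(0), 0, 2))
  M11 <- -(ka1 * C + kd1 + ka2); M12 <- kd2 - ka1 * C
  M21 <- ka2;                    M22 <- -kd2
  b1 <- ka1 * C * rmax
  tr <- M11 + M22
  dt <- M11 * M22 - M12 * M21   # = kd2*(ka1*C + kd1) + ka2*ka1*C >= 0
  if ((ka2 == 0 && kd2 == 0) || (b1 != 0 && dt <= 0)) {
    # plain 1:1 limit (exactly, or because the conformational-step rates
    # have underflowed to numerical zero); AB* frozen at its start value
    reff <- rmax - x0[2]
    k <- ka1 * C + kd1
    ss <- if (k > 0) ka1 * C * reff / k else x0[1]
    ab <- ss + (x0[1] - ss) * exp(-k * times)
    return(cbind(ab, rep(x0[2], nt)))
  }
  xss <- if (b1 == 0) c(0, 0) else c(-b1 * M22, b1 * M21) / dt
  # closed-form 2x2 matrix exponential: with s = tr/2 and
  # q^2 = tr^2/4 - det, exp(Mt) = e^{st}[cosh(qt) I + sinh(qt)/q (M - sI)];
  # both eigenvalues s +/- q are <= 0 here (tr < 0, det >= 0), so the
  # exponential terms never overflow
  s <- tr / 2
  disc4 <- s * s - dt
  v <- x0 - xss
  w <- c((M11 - s) * v[1] + M12 * v[2],
         M21 * v[1] + (M22 - s) * v[2])
  if (disc4 > 1e-24 * s * s) {
    q <- sqrt(disc4)
    e1 <- exp((s + q) * times); e2 <- exp((s - q) * times)
    ch <- (e1 + e2) / 2; sh <- (e1 - e2) / (2 * q)
  } else if (disc4 < -1e-24 * s * s) {
    q <- sqrt(-disc4)
    es <- exp(s * times)
    ch <- es * cos(q * times); sh <- es * sin(q * times) / q
  } else {
    es <- exp(s * times); ch <- es; sh <- es * times
  }
  cbind(xss[1] + ch * v[1] + sh * w[1],
        xss[2] + ch * v[2] + sh * w[2])
}

twoStatePhaseOde <- function(x0, C, p, times) {
  rhs <- function(t, y, parms) {
    ab <- y[1]; abs_ <- y[2]
    dab <- p@ka1 * C * (p@rmax - ab - abs_) - p@kd1 * ab -
      p@ka2 * ab + p@kd2 * abs_
    dabs <- p@ka2 * ab - p@kd2 * abs_
    list(c(dab, dabs))
  }
  t0 <- if (times[1] > 0) c(0, times) else times
  out <- tryCatch(
    deSolve::lsoda(y = x0, times = t0, func = rhs, parms = NULL,
                   rtol = 1e-8, atol = 1e-10),
    error = function(e)
      stop("two-state ODE integration failed (ka1=", p@ka1, ", kd1=",
           p@kd1, ", ka2=", p@ka2, ", kd2=", p@kd2, ", rmax=", p@rmax,
           ", C=", C, "): ", conditionMessage(e), call. = FALSE))
  res <- unname(as.matrix(out[, 2:3, drop = FALSE]))
  if (times[1] > 0) res <- res[-1, , drop = FALSE]
  res
}

# Response (AB + AB*) of the two-state scheme on an arbitrary time grid
# with injection up to tInjEnd and buffer wash afterwards.
twoStateResponse <- function(p, conc, times, tInjEnd) {
  phase1 <- times[times <= tInjEnd]
  phase2 <- times[times > tInjEnd]
  out <- numeric(length(times))
  x0 <- c(0, 0)
  if (length(phase1) > 0) {
    st <- twoStatePhase(x0, conc, p, phase1)
    out[seq_along(phase1)] <- st[, 1] + st[, 2]
  }
  if (length(phase2) > 0) {
    xInj <- as.numeric(twoStatePhase(x0, conc, p, tInjEnd))
    st <- twoStatePhase(xInj, 0, p, phase2 - tInjEnd)
    out[length(phase1) + seq_along(phase2)] <- st[, 1] + st[, 2]
  }
  out
}

#' Simulate a two-state SPR sensorgram
#'
#' Integrates the two-state reaction scheme
#' \deqn{A + B \rightleftharpoons AB \rightleftharpoons AB^*}
#' with the analyte held at `conc` during injection and at zero afterwards,
#' and reports the response \eqn{AB + AB^*}. The scheme is a linear
#' constant-coefficient ODE within each phase, so it is solved exactly by
#' eigen-decomposition; the response starts at zero and never exceeds
#' `rmax`. With `ka2 = kd2 = 0` the model reduces to the closed-form 1:1
#' association/dissociation curves.
#'
#' @param params a [KineticParams-class].
#' @param conc analyte concentration (M) during injection.
#' @param tGrid increasing time grid (s).
#' @param tInjEnd end of injection (s).
#' @return a [Sensorgram-class].
#' @export
simulateTwoState <- function(params, conc, tGrid, tInjEnd) {
  stopifnot(is(params, "KineticParams"))
  if (any(diff(tGrid) <= 0)) stop("tGrid must be strictly increasing")
  if (conc < 0) stop("conc must be >= 0")
  resp <- twoStateResponse(params, conc, tGrid, tInjEnd)
  sensorgram(tGrid, resp, conc, tInjEnd)
}

# Shared multi-start Levenberg-Marquardt driver on log-parameterized
# positives. Returns the best start's nls.lm fit plus bookkeeping.
multiStartLm <- function(residFun, starts, maxiter = 200) {
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = log(s), fn = residFun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("all fit starts failed")
  best
}

# Standard errors on the natural scale from a log-parameterized nls.lm fit
# (delta method). Singular information matrices yield wide (Inf) errors
# plus a diagnostic instead of an error.
lmStandardErrors <- function(fit, nObs) {
  p <- length(fit$par)
  dof <- max(nObs - p, 1)
  s2 <- fit$deviance / dof
  hess <- fit$hessian
  notes <- character(0)
  cov <- tryCatch(solve(hess) * 2 * s2, error = function(e) NULL)
  if (is.null(cov) || any(!is.finite(diag(cov))) || any(diag(cov) < 0)) {
    sv <- svd(hess)
    pos <- sv$d > max(sv$d) * 1e-10
    if (!all(pos))
      notes <- c(notes, "weakly identified parameter(s): flat residual surface")
    dinv <- ifelse(pos, 1 / sv$d, Inf)
    cov <- sv$v %*% (dinv * t(sv$u)) * 2 * s2
  }
  seLog <- sqrt(pmax(diag(cov), 0))
  natural <- exp(fit$par)
  list(se = natural * seLog, notes = notes)
}

#' Fit a steady-state affinity
#'
#' Least-squares fit of the 1:1 steady-state model
#' \eqn{R_{eq} = R_{max} C/(K_d + C)} to an equilibrium concentration
#' series, with log-parameterization (both parameters strictly positive)
#' and multiple log-spaced \eqn{K_d} starts. A series that does not bracket
#' the fitted \eqn{K_d} (all concentrations far below or far above it)
#' is flagged as non-converged with a diagnostic.
#'
#' @param series an [EquilibriumSeries-class] with at least 3 points
#'   spanning at least a factor of 10 in concentration.
#' @param nStarts number of \eqn{K_d} starting values (default 8).
#' @return a [FitResult-class] with `params["kd"]`, `params["rmax"]`.
#' @export
fitEquilibrium <- function(series, nStarts = 8) {
  stopifnot(is(series, "EquilibriumSeries"))
  concs <- series@concs; req <- series@req
  if (length(concs) < 3) stop("need at least 3 concentrations")
  if (max(concs) / min(concs) < 10)
    stop("concentration series must span at least a factor of 10")
  residFun <- function(logp) {
    kd <- exp(logp[1]); rmax <- exp(logp[2])
    r <- rmax * concs / (kd + concs) - req
    r[!is.finite(r)] <- 1e6
    r
  }
  kd0 <- exp(seq(log(min(concs) / 10), log(max(concs) * 10),
                 length.out = nStarts))
  rmax0 <- max(req) * 1.05
  if (rmax0 <= 0) rmax0 <- 1
  starts <- lapply(kd0, function(k) c(kd = k, rmax = rmax0))
  best <- multiStartLm(residFun, starts)
  kd <- exp(best$par[1]); rmax <- exp(best$par[2])
  params <- c(kd = unname(kd), rmax = unname(rmax))
  seInfo <- lmStandardErrors(best, length(concs))
  se <- seInfo$se; names(se) <- names(params)
  converged <- best$info %in% 1:3
  notes <- seInfo$notes
  if (kd > 20 * max(concs) || kd < min(concs) / 20) {
    converged <- FALSE
    notes <- c(notes,
               "concentration series does not bracket the fitted Kd")
  }
  new("FitResult", params = params, kdApparent = unname(kd),
      rss = best$deviance, se = se, converged = converged,
      nStarts = as.integer(nStarts), model = "equilibrium",
      diagnostics = notes)
}

#' Globally fit the two-state model to sensorgrams
#'
#' Trust-region least squares (Levenberg--Marquardt) over all points of all
#' sensorgrams with one shared parameter set (`ka1`, `kd1`, `ka2`, `kd2`,
#' `rmax`), log-parameterized so every parameter stays positive, started
#' from at least 8 log-spaced apparent-\eqn{K_d} seeds. The apparent
#' dissociation constant of the two-state scheme is
#' \deqn{K_D = (k_{d1}/k_{a1}) \cdot k_{d2}/(k_{d2}+k_{a2}).}
#' Non-identifiable directions (flat residual surface) are reported as wide
#' standard errors with a diagnostic, not as a failure.
#'
#' @param sensorgrams list of [Sensorgram-class] objects (a concentration
#'   series for a global fit).
#' @param nStarts number of starting points (default 8).
#' @return a [FitResult-class].
#' @export
fitTwoState <- function(sensorgrams, nStarts = 8) {
  if (is(sensorgrams, "Sensorgram")) sensorgrams <- list(sensorgrams)
  stopifnot(length(sensorgrams) >= 1,
            all(vapply(sensorgrams, is, logical(1), "Sensorgram")))
  obs <- unlist(lapply(sensorgrams, function(s) s@response))
  residFun <- function(logp) {
    p <- kineticParams(exp(logp[1]), exp(logp[2]), exp(logp[3]),
                       exp(logp[4]), exp(logp[5]))
    r <- unlist(lapply(sensorgrams, function(s)
      twoStateResponse(p, s@analyteConc, s@times, s@tInjEnd))) - obs
    r[!is.finite(r)] <- 1e6   # keep LM away from overflow regions
    r
  }
  rmax0 <- max(obs)
  if (rmax0 <= 0) rmax0 <- 1
  kdSeeds <- 10^seq(-10, -4, length.out = nStarts)
  starts <- lapply(kdSeeds, function(kd)
    c(ka1 = 1e5, kd1 = 1e5 * kd * 2, ka2 = 1e-2, kd2 = 1e-2,
      rmax = rmax0))
  best <- multiStartLm(residFun, starts)
  pars <- exp(best$par)
  names(pars) <- c("ka1", "kd1", "ka2", "kd2", "rmax")
  kp <- kineticParams(pars[["ka1"]], pars[["kd1"]], pars[["ka2"]],
                      pars[["kd2"]], pars[["rmax"]])
  seInfo <- lmStandardErrors(best, length(obs))
  se <- seInfo$se; names(se) <- names(pars)
  new("FitResult", params = pars, kdApparent = kdApparent(kp),
      rss = best$deviance, se = se, converged = best$info %in% 1:3,
      nStarts = as.integer(nStarts), model = "two_state",
      diagnostics = seInfo$notes)
}

#' Fold decrease in affinity
#'
#' Ratio of a mutant's dissociation constant to the reference (wild-type)
#' value, reported both unrounded and as the conventional integer
#' (round-half-up). Scale-invariant: only the ratio matters.
#'
#' @param kdMutant,kdReference dissociation constants (same units), > 0.
#' @return list with `fold` (integer) and `ratio` (numeric).
#' @examples
#' foldChange(2.7e-6, 14.6e-9)$fold  # 185
#' @export
foldChange <- function(kdMutant, kdReference) {
  if (kdMutant <= 0 || kdReference <= 0)
    stop("dissociation constants must be > 0")
  ratio <- kdMutant / kdReference
  list(fold = as.integer(floor(ratio + 0.5)), ratio = ratio)
}

#' Mutant fold-decrease table
#'
#' Builds the conventional mutant-panel summary: one row per variant with
#' its \eqn{K_d}, the unrounded ratio to the reference, and the integer
#' fold-decrease (round-half-up). Binding-deficient variants (no measurable
#' \eqn{K_d}, encoded as `NA`) are flagged qualitatively and get no fold
#' value. When a `printedFold` column accompanies the input (a previously
#' published rounding of the same data), rows whose recomputed integer
#' disagrees are marked `discrepant` — published folds are often computed
#' from unrounded estimates and need not match ratios of rounded
#' \eqn{K_d}s.
#'
#' @param entries data.frame with columns `name`, `kd` (molar; `NA` =
#'   binding-deficient) and optionally `printedFold`.
#' @param referenceKd reference (wild-type) \eqn{K_d}, molar.
#' @return data.frame with columns `name`, `kd`, `ratio`, `foldDecrease`,
#'   `qualitative`, and (when `printedFold` is supplied) `printedFold`,
#'   `discrepant`, `note`.
#' @export
foldChangeTable <- function(entries, referenceKd) {
  stopifnot(is.data.frame(entries),
            all(c("name", "kd") %in% names(entries)))
  if (referenceKd <= 0) stop("referenceKd must be > 0")
  if (anyDuplicated(entries$name))
    stop("duplicate entry names: ",
         paste(unique(entries$name[duplicated(entries$name)]),
               collapse = ", "))
  deficient <- is.na(entries$kd)
  ratio <- ifelse(deficient, NA_real_, entries$kd / referenceKd)
  if (any(!deficient & entries$kd <= 0))
    stop("dissociation constants must be > 0")
  fold <- ifelse(deficient, NA_integer_,
                 as.integer(floor(ratio + 0.5)))
  out <- data.frame(name = entries$name, kd = entries$kd, ratio = ratio,
                    foldDecrease = fold,
                    qualitative = ifelse(deficient, "binding_deficient",
                                         "ok"),
                    stringsAsFactors = FALSE)
  if ("printedFold" %in% names(entries)) {
    out$printedFold <- entries$printedFold
    out$discrepant <- !deficient & !is.na(entries$printedFold) &
      entries$printedFold != fold
    out$note <- ifelse(
      out$discrepant %in% TRUE,
      sprintf("published fold %s differs from ratio of rounded Kds (%s); likely computed from unrounded estimates",
              entries$printedFold, fold),
      "")
  }
  attr(out, "referenceKd") <- referenceKd
  out
}

#' Sensorgram CSV input/output
#'
#' Sensorgrams are exchanged as CSV with two metadata header comments
#' (`# analyte_conc_M:`, `# t_inject_end_s:`) followed by
#' `time_s,response_RU` columns; equilibrium series as plain
#' `conc_M,Req_RU` CSV.
#'
#' @param sg a [Sensorgram-class].
#' @param series an [EquilibriumSeries-class].
#' @param path file path.
#' @return readers return the parsed object; writers return `path`
#'   invisibly.
#' @name sprCsv
NULL

#' @rdname sprCsv
#' @export
writeSensorgramCsv <- function(sg, path) {
  stopifnot(is(sg, "Sensorgram"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# analyte_conc_M: %.10g", sg@analyteConc),
               sprintf("# t_inject_end_s: %.10g", sg@tInjEnd),
               "time_s,response_RU"), con)
  utils::write.table(data.frame(sg@times, sg@response), con, sep = ",",
                     col.names = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname sprCsv
#' @export
readSensorgramCsv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  getMeta <- function(key) {
    hit <- grep(paste0("^#\\s*", key, ":"), meta, value = TRUE)
    if (length(hit) == 0) stop("missing metadata '", key, "' in ", path)
    as.numeric(sub(paste0("^#\\s*", key, ":\\s*"), "", hit[1]))
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  sensorgram(df$time_s, df$response_RU, getMeta("analyte_conc_M"),
             getMeta("t_inject_end_s"))
}

#' @rdname sprCsv
#' @export
writeEquilibriumCsv <- function(series, path) {
  stopifnot(is(series, "EquilibriumSeries"))
  utils::write.csv(data.frame(conc_M = series@concs,
                              Req_RU = series@req),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname sprCsv
#' @export
readEquilibriumCsv <- function(path) {
  df <- utils::read.csv(path)
  equilibriumSeries(df$conc_M, df$Req_RU)
}
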