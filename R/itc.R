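## One-site ITC analysis: forward isotherm with displacement-volume
## dilution, dilution-blank subtraction, nonlinear fitting with
## multi-start initialization, and the thermodynamic decomposition.

## per-injection total concentrations (M) in the active cell under the
## displacement-volume convention used by the instrument software
itcConcentrations <- function(sched) {
  v0 <- sched@cellVolume * 1e-6          # L
  vi <- sched@injectionVolume * 1e-6     # L
  dV <- cumsum(rep(vi, sched@nInjections))
  list(
    mt = sched@cellConc * 1e-6 * (1 - dV / (2 * v0)) / (1 + dV / (2 * v0)),
    xt = sched@syringeConc * 1e-6 * (dV / v0) * (1 - dV / (2 * v0)),
    v0 = v0, vi = vi)
}

#' One-site binding isotherm: per-injection heats
#'
#' Computes the integrated heat of each injection for a single-site
#' binding model.  The cumulative heat content of the cell after
#' injection i is
#' \deqn{Q_i = \frac{n M_t \Delta H V_0}{2}\left[1 + r + K -
#'   \sqrt{(1 + r + K)^2 - 4 r}\right]}
#' with r = X_t / (n M_t) and K = K_D / (n M_t), where M_t and X_t are
#' the running total macromolecule and titrant concentrations in the
#' active volume V_0 after displacement-volume dilution (cell species
#' scaled by (1 - dV/2V0)/(1 + dV/2V0), titrant by (dV/V0)(1 - dV/2V0)).
#' The observed heat of injection i is the difference
#' \deqn{\Delta Q_i = Q_i - Q_{i-1} + \frac{v}{V_0}\,
#'   \frac{Q_i + Q_{i-1}}{2}}
#' which accounts for complex carried out of the active volume by the
#' displaced liquid.
#'
#' @param n stoichiometry (sites per macromolecule).
#' @param kd dissociation constant (M).
#' @param dh binding enthalpy (kcal/mol).
#' @param sched an \linkS4class{InjectionSchedule}.
#' @return Numeric vector of heats (ucal), one per injection.
#' @examples
#' wisemanIsotherm(1, 4.8e-6, -11.5, InjectionSchedule())
#' @export
wisemanIsotherm <- function(n, kd, dh, sched) {
  stopifnot(is(sched, "InjectionSchedule"))
  validObject(sched)
  if (kd <= 0) stop("kd must be positive")
  cc <- itcConcentrations(sched)
  r <- cc$xt / (n * cc$mt)
  K <- kd / (n * cc$mt)
  ## cumulative heat content (cal); dh kcal/mol -> cal/mol
  Q <- n * cc$mt * (dh * 1000) * cc$v0 / 2 *
       (1 + r + K - sqrt((1 + r + K)^2 - 4 * r))
  dQ <- Q - c(0, Q[-length(Q)]) +
        (cc$vi / cc$v0) * (Q + c(0, Q[-length(Q)])) / 2
  dQ * 1e6                               # cal -> ucal
}

#' Subtract dilution-control heats from an ITC experiment
#'
#' Elementwise subtraction of the blank (titrant-into-buffer) heats from
#' the measured heats of binding.  With no blank recorded, the heats are
#' returned unchanged with a warning.
#'
#' @param exp an \linkS4class{ItcExperiment}.
#' @return A new \linkS4class{ItcExperiment} with corrected heats and an
#'   empty blank.
#' @export
subtractDilution <- function(exp) {
  stopifnot(is(exp, "ItcExperiment"))
  validObject(exp)
  if (!length(exp@blankHeats)) {
    warning("no blank heats present; returning heats unchanged")
    return(exp)
  }
  ItcExperiment(exp@schedule, exp@heats - exp@blankHeats)
}

#' Fit a one-site binding model to ITC heats
#'
#' Nonlinear least squares of the measured injection heats against
#' \code{\link{wisemanIsotherm}} over (n, KD, dH), with multi-start
#' initialization: dH is seeded from the early-injection plateau, n from
#' the molar ratio at the isotherm half-height, KD from a fraction of
#' the cell concentration, and the best of several jittered restarts (by
#' residual sum of squares) is kept.  KD is fit on a log scale to keep it positive.
#'
#' The c-value (cell concentration / KD) governs how well the isotherm
#' constrains KD; fits with c outside [1, 1e5] are returned with an
#' ill-conditioning flag rather than suppressed.
#'
#' @param exp an \linkS4class{ItcExperiment}; apply
#'   \code{\link{subtractDilution}} first if a blank was recorded.
#' @param excludeFirst drop the first injection before fitting (common
#'   practice for diffusion artifacts; default FALSE).
#' @param nStarts number of jittered restarts.
#' @param seed seed for the restart jitter.
#' @return A \linkS4class{BindingFit}.
#' @examples
#' exp <- simulateItc(1, 4.8e-6, -11.5, InjectionSchedule())
#' fitOneSite(exp)
#' @export
fitOneSite <- function(exp, excludeFirst = FALSE, nStarts = 5, seed = 1L) {
  stopifnot(is(exp, "ItcExperiment"))
  validObject(exp)
  sched <- exp@schedule
  q <- exp@heats
  use <- seq_along(q)
  if (excludeFirst) use <- use[-1]
  if (length(use) < 5) stop("need at least 5 informative injections")
  if (all(abs(q[use]) < .Machine$double.eps^0.5))
    stop("no binding signal: all heats are zero")

  cc <- itcConcentrations(sched)
  molar <- cc$xt / cc$mt                 # molar ratio per injection
  ## initial guesses
  injMoles <- cc$vi * sched@syringeConc * 1e-6
  dh0 <- q[use][1] * 1e-6 / injMoles / 1000      # ucal -> kcal/mol
  half <- which.min(abs(abs(q) - abs(q[use][1]) / 2))
  n0 <- max(molar[half], 0.1)
  ## slope at inflection ~ steepness -> crude kd scale
  kd0 <- max(sched@cellConc * 1e-6 / 20, 1e-12)

  ssr <- function(p) {
    pred <- wisemanIsotherm(p[1], exp(p[2]), p[3], sched)
    sum((q[use] - pred[use])^2)
  }
  starts <- withSeed(seed, lapply(seq_len(nStarts), function(k) {
    jit <- if (k == 1) c(1, 1, 1) else exp(stats::rnorm(3, sd = 0.3))
    c(n0 * jit[1], log(kd0 * jit[2]^3), dh0 * jit[3])
  }))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st,
        fn = function(p) {
          pred <- wisemanIsotherm(p[1], exp(p[2]), p[3], sched)
          q[use] - pred[use]
        },
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("one-site fit failed to converge")

  p <- best$par
  nFit <- p[1]; kdFit <- exp(p[2]); dhFit <- p[3]
  ## parameter sd from the Jacobian (Gauss-Newton approximation)
  sds <- c(n = NA_real_, kd = NA_real_, dh = NA_real_)
  cov <- tryCatch({
    dof <- length(use) - 3
    if (dof > 0) {
      h <- best$hessian
      s2 <- best$deviance / dof
      cv <- s2 * solve(h)
      sqrt(pmax(diag(cv), 0))
    } else NULL
  }, error = function(e) NULL)
  if (!is.null(cov))
    sds <- c(n = cov[1], kd = cov[2] * kdFit, dh = cov[3])

  flags <- character()
  cval <- sched@cellConc * 1e-6 / kdFit
  if (cval > 1e5 || cval < 1)
    flags <- c(flags, sprintf(
      "c-value %.3g outside the reliably fittable range [1, 1e5]", cval))
  BindingFit(nFit, kdFit, dhFit, temperature = sched@temperature,
             sd = sds, flags = flags)
}

#' Thermodynamic decomposition of a binding constant
#'
#' dG = R T ln(KD) and -T dS = dG - dH, with
#' R = 1.987e-3 kcal mol-1 K-1.  Values are returned at full precision;
#' rounding (1 decimal) is applied only at report time.
#'
#' @param kd dissociation constant (M).
#' @param dh binding enthalpy (kcal/mol).
#' @param temperature temperature (K); default 298.15 (25 C).
#' @return Named numeric vector \code{c(dg = , tdsNeg = )} (kcal/mol).
#' @examples
#' thermodynamics(4800e-9, -11.5)  # dg ~ -7.3, -TdS ~ +4.2
#' @export
thermodynamics <- function(kd, dh, temperature = 298.15) {
  if (any(kd <= 0)) stop("kd must be positive")
  R <- nmrConstants()$gas_constant_kcal
  dg <- R * temperature * log(kd)
  c(dg = dg, tdsNeg = dg - dh)
}

#' Affinity enhancement factor between two binding modes
#'
#' Ratio of a weaker to a tighter dissociation constant; e.g. the
#' fold-increase in affinity of an inhibitor for an effector complex
#' relative to the free enzyme.
#'
#' @param kdWeak dissociation constant of the weaker interaction (M).
#' @param kdTight dissociation constant of the tighter interaction (M).
#' @return Dimensionless fold enhancement.
#' @examples
#' enhancementFactor(4800e-9, 0.6e-9)  # 8000
#' @export
enhancementFactor <- function(kdWeak, kdTight) {
  if (any(c(kdWeak, kdTight) <= 0)) stop("both constants must be positive")
  kdWeak / kdTight
}
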