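#' @import methods
NULL

## ---------------------------------------------------------------------------
## Spin parameters (model-free simulator input)
## ---------------------------------------------------------------------------

#' Lipari-Szabo spin parameters
#'
#' Container for the per-residue model-free parameters used by the
#' synthetic-data generators: the generalized order parameter S2, the
#' global rotational correlation time tau_c, the internal-motion
#' correlation time tau_e, a chemical-exchange contribution Rex that adds
#' to R2 only, and the 1H Larmor frequency of the spectrometer.
#'
#' @slot s2 order parameter S2, dimensionless in [0, 1].
#' @slot tauC global rotational correlation time (ns).
#' @slot tauE internal correlation time (ps).
#' @slot rex exchange contribution to R2 (s-1).
#' @slot fieldH1 proton Larmor frequency (MHz).
#' @export
setClass("SpinParams",
  representation(s2 = "numeric", tauC = "numeric", tauE = "numeric",
                 rex = "numeric", fieldH1 = "numeric"))

setValidity("SpinParams", function(object) {
  msg <- character()
  if (length(object@s2) != 1 || is.na(object@s2) ||
      object@s2 < 0 || object@s2 > 1)
    msg <- c(msg, "s2 must be a single value in [0, 1]")
  if (length(object@tauC) != 1 || is.na(object@tauC) || object@tauC <= 0)
    msg <- c(msg, "tauC must be a single positive value (ns)")
  if (length(object@tauE) != 1 || is.na(object@tauE) || object@tauE < 0)
    msg <- c(msg, "tauE must be non-negative (ps)")
  if (length(object@rex) != 1 || is.na(object@rex) || object@rex < 0)
    msg <- c(msg, "rex must be non-negative (s-1)")
  if (length(object@fieldH1) != 1 || is.na(object@fieldH1) ||
      object@fieldH1 <= 0)
    msg <- c(msg, "fieldH1 must be positive (MHz)")
  if (length(msg)) msg else TRUE
})

#' Construct a SpinParams object
#'
#' @param s2 order parameter S2 (dimensionless, 0-1).
#' @param tauC global rotational correlation time (ns).
#' @param tauE internal correlation time (ps); 0 disables the internal
#'   motion term.
#' @param rex exchange broadening added to R2 (s-1).
#' @param fieldH1 proton Larmor frequency (MHz).
#' @return A \linkS4class{SpinParams} object.
#' @examples
#' SpinParams(s2 = 0.87, tauC = 6.2, tauE = 50, rex = 0, fieldH1 = 800)
#' @export
SpinParams <- function(s2, tauC, tauE = 0, rex = 0, fieldH1 = 800) {
  new("SpinParams", s2 = as.numeric(s2), tauC = as.numeric(tauC),
      tauE = as.numeric(tauE), rex = as.numeric(rex),
      fieldH1 = as.numeric(fieldH1))
}

setMethod("show", "SpinParams", function(object) {
  cat("SpinParams: S2 =", object@s2, " tauC =", object@tauC, "ns",
      " tauE =", object@tauE, "ps", " Rex =", object@rex, "s-1",
      " field =", object@fieldH1, "MHz\n")
})

## ---------------------------------------------------------------------------
## Relaxation series
## ---------------------------------------------------------------------------

#' Per-residue relaxation decay series
#'
#' Peak intensities of one amide resonance recorded over a set of
#' relaxation delays, together with an intensity-noise estimate used for
#' Monte Carlo error propagation.
#'
#' @slot residueId 1-based residue number.
#' @slot residueName 3-letter residue code.
#' @slot delays relaxation delays (s).
#' @slot intensities peak intensities (arbitrary units), parallel to
#'   \code{delays}.
#' @slot noiseSd intensity noise standard deviation (same units as
#'   intensities).
#' @export
setClass("RelaxationSeries",
  representation(residueId = "integer", residueName = "character",
                 delays = "numeric", intensities = "numeric",
                 noiseSd = "numeric"))

setValidity("RelaxationSeries", function(object) {
  msg <- character()
  if (length(object@delays) != length(object@intensities))
    msg <- c(msg, "delays and intensities must have equal length")
  if (any(object@delays < 0)) msg <- c(msg, "delays must be non-negative")
  if (anyDuplicated(object@delays))
    msg <- c(msg, "delays must be distinct")
  if (length(object@noiseSd) != 1 || object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be a single non-negative value")
  if (length(msg)) msg else TRUE
})

#' Construct a RelaxationSeries
#'
#' @param residueId 1-based residue number.
#' @param delays relaxation delays (s).
#' @param intensities peak intensities, parallel to \code{delays}.
#' @param noiseSd intensity noise standard deviation.
#' @param residueName 3-letter residue code.
#' @return A \linkS4class{RelaxationSeries} object.
#' @export
RelaxationSeries <- function(residueId, delays, intensities, noiseSd = 0,
                             residueName = "XXX") {
  ord <- order(delays)
  new("RelaxationSeries", residueId = as.integer(residueId),
      residueName = as.character(residueName),
      delays = as.numeric(delays)[ord],
      intensities = as.numeric(intensities)[ord],
      noiseSd = as.numeric(noiseSd))
}

setMethod("show", "RelaxationSeries", function(object) {
  cat("RelaxationSeries: residue", object@residueId,
      paste0("(", object@residueName, "),"),
      length(object@delays), "delays,",
      "noise sd", object@noiseSd, "\n")
})

## ---------------------------------------------------------------------------
## Spectrometer configuration
## ---------------------------------------------------------------------------

#' Spectrometer configuration for R1rho analysis
#'
#' Holds the static field (as the 1H Larmor frequency), the spin-lock
#' field strength and optional per-residue 15N resonance offsets used in
#' the offset correction that converts R1rho to R2.
#'
#' @slot fieldH1 proton Larmor frequency (MHz).
#' @slot spinlock spin-lock field strength gamma_N * B1 (Hz).
#' @slot offsets named numeric vector of per-residue resonance offsets
#'   Omega_N (Hz), names are residue ids; empty means all offsets zero.
#' @export
setClass("SpectrometerConfig",
  representation(fieldH1 = "numeric", spinlock = "numeric",
                 offsets = "numeric"))

setValidity("SpectrometerConfig", function(object) {
  msg <- character()
  if (length(object@fieldH1) != 1 || object@fieldH1 <= 0)
    msg <- c(msg, "fieldH1 must be positive (MHz)")
  if (length(object@spinlock) != 1 || object@spinlock <= 0)
    msg <- c(msg, "spinlock must be positive (Hz)")
  if (length(object@offsets) && is.null(names(object@offsets)))
    msg <- c(msg, "offsets must be named by residue id")
  if (length(msg)) msg else TRUE
})

#' Construct a SpectrometerConfig
#'
#' @param fieldH1 proton Larmor frequency (MHz).
#' @param spinlock spin-lock field strength (Hz).
#' @param offsets optional named numeric vector of per-residue 15N
#'   resonance offsets (Hz); when omitted the R1rho offset correction
#'   reduces to the identity.
#' @return A \linkS4class{SpectrometerConfig} object.
#' @examples
#' SpectrometerConfig(fieldH1 = 800, spinlock = 1500)
#' @export
SpectrometerConfig <- function(fieldH1 = 800, spinlock = 1500,
                               offsets = numeric()) {
  new("SpectrometerConfig", fieldH1 = as.numeric(fieldH1),
      spinlock = as.numeric(spinlock), offsets = offsets)
}

setMethod("show", "SpectrometerConfig", function(object) {
  cat("SpectrometerConfig:", object@fieldH1, "MHz, spin-lock",
      object@spinlock, "Hz,",
      if (length(object@offsets)) paste(length(object@offsets),
                                        "per-residue offsets")
      else "zero offsets", "\n")
})

## ---------------------------------------------------------------------------
## Tumbling estimate
## ---------------------------------------------------------------------------

#' Global rotational correlation time estimate
#'
#' Result of inverting the rigid-rotor R2/R1 ratio over the trimmed set
#' of ordered-region residues.
#'
#' @slot tauC estimated rotational correlation time (ns).
#' @slot nResiduesUsed number of residues surviving the trim.
#' @slot trimmedIds residue ids excluded by the trimming rule.
#' @slot ratio the trimmed-mean R2/R1 ratio that was inverted.
#' @export
setClass("TumblingEstimate",
  representation(tauC = "numeric", nResiduesUsed = "integer",
                 trimmedIds = "integer", ratio = "numeric"))

setValidity("TumblingEstimate", function(object) {
  if (length(object@tauC) != 1 || object@tauC <= 0)
    "tauC must be a single positive value (ns)" else TRUE
})

setMethod("show", "TumblingEstimate", function(object) {
  cat("TumblingEstimate: tauC =", format(object@tauC, digits = 4),
      "ns from", object@nResiduesUsed, "residues (",
      length(object@trimmedIds), "trimmed )\n")
})

#' @describeIn TumblingEstimate-class extract the estimated correlation
#'   time (ns).
#' @param object a \code{TumblingEstimate}.
#' @export
setGeneric("tauC", function(object) standardGeneric("tauC"))

#' @rdname TumblingEstimate-class
#' @export
setMethod("tauC", "TumblingEstimate", function(object) object@tauC)

## ---------------------------------------------------------------------------
## Bond vectors & alignment tensor
## ---------------------------------------------------------------------------

#' Set of unit bond vectors in the molecular frame
#'
#' N-H (or other) internuclear unit vectors used in RDC back-calculation
#' and alignment-tensor fitting.
#'
#' @slot residueId integer residue ids, parallel to the rows of
#'   \code{vectors}.
#' @slot vectors numeric matrix (n x 3) of unit vectors.
#' @export
setClass("BondVectorSet",
  representation(residueId = "integer", vectors = "matrix"))

setValidity("BondVectorSet", function(object) {
  msg <- character()
  if (ncol(object@vectors) != 3)
    msg <- c(msg, "vectors must have 3 columns")
  if (nrow(object@vectors) != length(object@residueId))
    msg <- c(msg, "residueId must be parallel to vector rows")
  if (nrow(object@vectors)) {
    nrm <- sqrt(rowSums(object@vectors^2))
    if (any(abs(nrm - 1) > 1e-6))
      msg <- c(msg, "all bond vectors must be unit length (|v|-1 <= 1e-6)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a BondVectorSet
#'
#' @param residueId integer residue ids.
#' @param vectors n x 3 matrix of unit vectors (checked to 1e-6).
#' @return A \linkS4class{BondVectorSet}.
#' @export
BondVectorSet <- function(residueId, vectors) {
  vectors <- as.matrix(vectors)
  dimnames(vectors) <- NULL
  new("BondVectorSet", residueId = as.integer(residueId), vectors = vectors)
}

setMethod("show", "BondVectorSet", function(object) {
  cat("BondVectorSet:", nrow(object@vectors), "unit vectors\n")
})

#' @describeIn BondVectorSet-class number of vectors.
#' @param x a \code{BondVectorSet}.
#' @export
setMethod("length", "BondVectorSet", function(x) nrow(x@vectors))

#' Molecular alignment (Saupe-type) tensor in coupling units
#'
#' Traceless symmetric 3 x 3 order tensor expressed directly in coupling
#' units (Hz), so that the back-calculated dipolar coupling of a unit
#' bond vector v is the quadratic form t(v) A v.  In the principal frame
#' with eigenvalues ordered |Azz| >= |Ayy| >= |Axx| the tensor is
#' parameterized by the axial magnitude Da = Azz / 2 (Hz) and the
#' rhombicity R = (2/3) (Axx - Ayy) / Azz, with 0 <= R <= 2/3.
#'
#' @slot tensor 3 x 3 traceless symmetric matrix (Hz).
#' @slot daSd optional bootstrap standard error of Da (Hz).
#' @slot rhombicitySd optional bootstrap standard error of the rhombicity.
#' @export
setClass("AlignmentTensor",
  representation(tensor = "matrix", daSd = "numeric",
                 rhombicitySd = "numeric"))

setValidity("AlignmentTensor", function(object) {
  msg <- character()
  A <- object@tensor
  if (!all(dim(A) == c(3, 3))) msg <- c(msg, "tensor must be 3 x 3")
  else {
    if (max(abs(A - t(A))) > 1e-9)
      msg <- c(msg, "tensor must be symmetric")
    scale <- max(1, max(abs(A)))
    if (abs(sum(diag(A))) > 1e-9 * scale)
      msg <- c(msg, "tensor must be traceless (|trace| <= 1e-9)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AlignmentTensor from its axial and rhombic magnitudes
#'
#' Builds the tensor in its principal frame (eigenvalues 2 Da,
#' -Da (1 + 3 R / 2), -Da (1 - 3 R / 2)) and rotates it into the
#' molecular frame by z-y-z Euler angles.
#'
#' @param da axial magnitude Da (Hz).
#' @param rhombicity rhombicity R, dimensionless in [0, 2/3].
#' @param euler z-y-z Euler angles (degrees) rotating the principal frame
#'   into the molecular frame; default keeps the principal frame.
#' @return An \linkS4class{AlignmentTensor}.
#' @examples
#' AlignmentTensor(da = 7.3, rhombicity = 0.35)
#' @export
AlignmentTensor <- function(da, rhombicity = 0, euler = c(0, 0, 0)) {
  if (rhombicity < 0 || rhombicity > 2 / 3)
    stop("rhombicity must be in [0, 2/3]")
  pr <- diag(c(-da * (1 - 1.5 * rhombicity),
               -da * (1 + 1.5 * rhombicity),
               2 * da))
  U <- eulerRotation(euler)
  A <- U %*% pr %*% t(U)
  A <- (A + t(A)) / 2
  A <- A - diag(rep(sum(diag(A)) / 3, 3))
  new("AlignmentTensor", tensor = A, daSd = NA_real_,
      rhombicitySd = NA_real_)
}

## z-y-z Euler rotation matrix, angles in degrees
eulerRotation <- function(euler) {
  a <- euler * pi / 180
  rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0,
                             0, 0, 1), 3, 3)
  ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0,
                             sin(t), 0, cos(t)), 3, 3)
  rz(a[1]) %*% ry(a[2]) %*% rz(a[3])
}

#' @describeIn AlignmentTensor-class axial magnitude Da (Hz), half the
#'   largest-magnitude eigenvalue.
#' @param object an \code{AlignmentTensor}.
#' @export
setGeneric("Da", function(object) standardGeneric("Da"))

#' @rdname AlignmentTensor-class
#' @export
setMethod("Da", "AlignmentTensor", function(object) {
  tensorPrincipal(object@tensor)$da
})

#' @describeIn AlignmentTensor-class rhombicity R in [0, 2/3].
#' @export
setGeneric("rhombicity", function(object) standardGeneric("rhombicity"))

#' @rdname AlignmentTensor-class
#' @export
setMethod("rhombicity", "AlignmentTensor", function(object) {
  tensorPrincipal(object@tensor)$rhombicity
})

#' @describeIn AlignmentTensor-class the 3 x 3 tensor matrix (Hz).
#' @export
setGeneric("saupeMatrix", function(object) standardGeneric("saupeMatrix"))

#' @rdname AlignmentTensor-class
#' @export
setMethod("saupeMatrix", "AlignmentTensor", function(object) object@tensor)

#' @describeIn AlignmentTensor-class z-y-z Euler angles (degrees) of the
#'   principal axes in the molecular frame.
#' @export
setGeneric("eulerAngles", function(object) standardGeneric("eulerAngles"))

#' @rdname AlignmentTensor-class
#' @export
setMethod("eulerAngles", "AlignmentTensor", function(object) {
  tensorPrincipal(object@tensor)$euler
})

setMethod("show", "AlignmentTensor", function(object) {
  p <- tensorPrincipal(object@tensor)
  cat("AlignmentTensor: Da =", format(p$da, digits = 5), "Hz,",
      "rhombicity =", format(p$rhombicity, digits = 4), "\n")
  if (!is.na(object@daSd))
    cat("  bootstrap sd: Da", format(object@daSd, digits = 3), "Hz,",
        "R", format(object@rhombicitySd, digits = 3), "\n")
})

## ---------------------------------------------------------------------------
## ITC classes
## ---------------------------------------------------------------------------

#' ITC injection schedule
#'
#' Geometry and concentrations of a titration: number and volume of
#' injections, active cell volume, macromolecule (cell) and titrant
#' (syringe) concentrations, and temperature.
#'
#' @slot nInjections number of injections (>= 2).
#' @slot injectionVolume volume per injection (uL).
#' @slot cellVolume active cell volume (uL).
#' @slot cellConc macromolecule concentration in the cell (uM).
#' @slot syringeConc titrant concentration in the syringe (uM).
#' @slot temperature temperature (K).
#' @export
setClass("InjectionSchedule",
  representation(nInjections = "integer", injectionVolume = "numeric",
                 cellVolume = "numeric", cellConc = "numeric",
                 syringeConc = "numeric", temperature = "numeric"))

setValidity("InjectionSchedule", function(object) {
  msg <- character()
  if (object@nInjections < 2) msg <- c(msg, "nInjections must be >= 2")
  vals <- c(object@injectionVolume, object@cellVolume, object@cellConc,
            object@syringeConc, object@temperature)
  if (any(!is.finite(vals)) || any(vals <= 0))
    msg <- c(msg, "all schedule quantities must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct an InjectionSchedule
#'
#' Defaults correspond to a standard small-volume calorimeter run:
#' twenty 2 uL injections of 500 uM titrant into 50 uM macromolecule in
#' a 200 uL active cell at 25 C.
#'
#' @param nInjections number of injections.
#' @param injectionVolume uL per injection.
#' @param cellVolume active cell volume (uL).
#' @param cellConc macromolecule concentration (uM).
#' @param syringeConc titrant concentration (uM).
#' @param temperature temperature (K).
#' @return An \linkS4class{InjectionSchedule}.
#' @examples
#' InjectionSchedule()
#' @export
InjectionSchedule <- function(nInjections = 20, injectionVolume = 2,
                              cellVolume = 200, cellConc = 50,
                              syringeConc = 500, temperature = 298.15) {
  new("InjectionSchedule", nInjections = as.integer(nInjections),
      injectionVolume = as.numeric(injectionVolume),
      cellVolume = as.numeric(cellVolume),
      cellConc = as.numeric(cellConc),
      syringeConc = as.numeric(syringeConc),
      temperature = as.numeric(temperature))
}

setMethod("show", "InjectionSchedule", function(object) {
  cat("InjectionSchedule:", object@nInjections, "x",
      object@injectionVolume, "uL of", object@syringeConc,
      "uM titrant into", object@cellConc, "uM in", object@cellVolume,
      "uL at", object@temperature, "K\n")
})

#' ITC experiment: schedule plus integrated injection heats
#'
#' @slot schedule the \linkS4class{InjectionSchedule}.
#' @slot heats integrated heat per injection (ucal).
#' @slot blankHeats optional dilution-control heats (ucal); empty if no
#'   blank was recorded.
#' @export
setClass("ItcExperiment",
  representation(schedule = "InjectionSchedule", heats = "numeric",
                 blankHeats = "numeric"))

setValidity("ItcExperiment", function(object) {
  msg <- character()
  if (length(object@heats) != object@schedule@nInjections)
    msg <- c(msg, "length(heats) must equal schedule nInjections")
  if (length(object@blankHeats) &&
      length(object@blankHeats) != length(object@heats))
    msg <- c(msg, "blankHeats must match heats in length")
  if (length(msg)) msg else TRUE
})

#' Construct an ItcExperiment
#'
#' @param schedule an \linkS4class{InjectionSchedule}.
#' @param heats integrated heats (ucal), one per injection.
#' @param blankHeats optional dilution-control heats (ucal).
#' @return An \linkS4class{ItcExperiment}.
#' @export
ItcExperiment <- function(schedule, heats, blankHeats = numeric()) {
  new("ItcExperiment", schedule = schedule, heats = as.numeric(heats),
      blankHeats = as.numeric(blankHeats))
}

setMethod("show", "ItcExperiment", function(object) {
  cat("ItcExperiment:", length(object@heats), "injections, total heat",
      format(sum(object@heats), digits = 5), "ucal",
      if (length(object@blankHeats)) "(blank present)" else "", "\n")
})

#' @describeIn ItcExperiment-class integrated injection heats (ucal).
#' @param object an \code{ItcExperiment}.
#' @export
setGeneric("heats", function(object) standardGeneric("heats"))

#' @rdname ItcExperiment-class
#' @export
setMethod("heats", "ItcExperiment", function(object) object@heats)

#' @describeIn ItcExperiment-class the injection schedule.
#' @export
setGeneric("schedule", function(object) standardGeneric("schedule"))

#' @rdname ItcExperiment-class
#' @export
setMethod("schedule", "ItcExperiment", function(object) object@schedule)

#' One-site binding fit result
#'
#' Fitted stoichiometry, dissociation constant and binding enthalpy,
#' together with the derived free energy and entropic term.  The
#' thermodynamic identities dG = R T ln(KD) and -T dS = dG - dH are
#' enforced by the class validity (to 1e-6 kcal/mol before any report
#' rounding).
#'
#' @slot n stoichiometry (sites per macromolecule).
#' @slot kd dissociation constant (M).
#' @slot dh binding enthalpy (kcal/mol).
#' @slot dg binding free energy (kcal/mol).
#' @slot tdsNeg entropic term -T dS (kcal/mol).
#' @slot sd named numeric vector of parameter uncertainties (n, kd, dh).
#' @slot temperature temperature (K) at which dg was evaluated.
#' @slot flags character vector of fit warnings (e.g. c-value range).
#' @export
setClass("BindingFit",
  representation(n = "numeric", kd = "numeric", dh = "numeric",
                 dg = "numeric", tdsNeg = "numeric", sd = "numeric",
                 temperature = "numeric", flags = "character"))

setValidity("BindingFit", function(object) {
  msg <- character()
  if (object@kd <= 0) msg <- c(msg, "kd must be positive")
  R <- nmrConstants()$gas_constant_kcal
  if (abs(object@dg - R * object@temperature * log(object@kd)) > 1e-6)
    msg <- c(msg, "dg must equal R T ln(kd) (kcal/mol)")
  if (abs(object@tdsNeg - (object@dg - object@dh)) > 1e-6)
    msg <- c(msg, "tdsNeg must equal dg - dh")
  if (length(msg)) msg else TRUE
})

#' Construct a BindingFit
#'
#' \code{dg} and \code{tdsNeg} are derived from \code{kd}, \code{dh} and
#' the temperature via \code{\link{thermodynamics}}; they are not free
#' inputs.
#'
#' @param n stoichiometry.
#' @param kd dissociation constant (M).
#' @param dh binding enthalpy (kcal/mol).
#' @param temperature temperature (K).
#' @param sd named numeric vector of uncertainties for n, kd and dh.
#' @param flags character vector of fit warnings.
#' @return A \linkS4class{BindingFit}.
#' @export
BindingFit <- function(n, kd, dh, temperature = 298.15,
                       sd = c(n = NA_real_, kd = NA_real_, dh = NA_real_),
                       flags = character()) {
  td <- thermodynamics(kd, dh, temperature)
  new("BindingFit", n = as.numeric(n), kd = as.numeric(kd),
      dh = as.numeric(dh), dg = td[["dg"]], tdsNeg = td[["tdsNeg"]],
      sd = sd, temperature = as.numeric(temperature), flags = flags)
}

setMethod("show", "BindingFit", function(object) {
  cat("BindingFit (one-site):\n")
  cat("  n      =", format(object@n, digits = 4), "\n")
  cat("  KD     =", format(object@kd * 1e9, digits = 4), "nM\n")
  cat("  dG     =", sprintf("%.1f", object@dg), "kcal/mol\n")
  cat("  dH     =", sprintf("%.1f", object@dh), "kcal/mol\n")
  cat("  -TdS   =", sprintf("%.1f", object@tdsNeg), "kcal/mol\n")
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})

#' @describeIn BindingFit-class fitted dissociation constant (M).
#' @param object a \code{BindingFit}.
#' @export
setGeneric("kdFit", function(object) standardGeneric("kdFit"))

#' @rdname BindingFit-class
#' @export
setMethod("kdFit", "BindingFit", function(object) object@kd)

#' @describeIn BindingFit-class fitted stoichiometry.
#' @export
setGeneric("stoichiometry", function(object) standardGeneric("stoichiometry"))

#' @rdname BindingFit-class
#' @export
setMethod("stoichiometry", "BindingFit", function(object) object@n)

#' @describeIn BindingFit-class thermodynamic summary as a named vector
#'   (kd_nM, dg, dh, tds_neg), on the scale used in reporting.
#' @export
setGeneric("thermoTable", function(object) standardGeneric("thermoTable"))

#' @rdname BindingFit-class
#' @export
setMethod("thermoTable", "BindingFit", function(object) {
  c(kd_nM = object@kd * 1e9, dg = round(object@dg, 1),
    dh = round(object@dh, 1), tds_neg = round(object@tdsNeg, 1))
})

## ---------------------------------------------------------------------------
## Structure ensemble, selection, restraints
## ---------------------------------------------------------------------------

#' Multi-model structure ensemble
#'
#' Conformer ensemble with a shared atom inventory: an atom table
#' (residue id, residue name, atom name) and a coordinate array of
#' dimension (atoms x 3 x models), in Angstrom.
#'
#' @slot atoms data.frame with columns residueId, residueName, atomName.
#' @slot coords numeric array (n_atoms, 3, n_models), Angstrom.
#' @export
setClass("StructureEnsemble",
  representation(atoms = "data.frame", coords = "array"))

setValidity("StructureEnsemble", function(object) {
  msg <- character()
  d <- dim(object@coords)
  if (length(d) != 3 || d[2] != 3)
    msg <- c(msg, "coords must be an (atoms x 3 x models) array")
  else {
    if (d[1] != nrow(object@atoms))
      msg <- c(msg, "atom table must be parallel to coords rows")
    if (d[3] < 1) msg <- c(msg, "at least one model required")
  }
  need <- c("residueId", "residueName", "atomName")
  if (!all(need %in% names(object@atoms)))
    msg <- c(msg, "atoms must have columns residueId, residueName, atomName")
  if (length(msg)) msg else TRUE
})

#' Construct a StructureEnsemble
#'
#' @param atoms data.frame with columns residueId, residueName, atomName.
#' @param coords array (n_atoms, 3, n_models) of coordinates (Angstrom).
#' @return A \linkS4class{StructureEnsemble}.
#' @export
StructureEnsemble <- function(atoms, coords) {
  new("StructureEnsemble", atoms = atoms, coords = coords)
}

setMethod("show", "StructureEnsemble", function(object) {
  cat("StructureEnsemble:", dim(object@coords)[3], "models,",
      nrow(object@atoms), "atoms,",
      length(unique(object@atoms$residueId)), "residues\n")
})

#' @describeIn StructureEnsemble-class number of models.
#' @param object a \code{StructureEnsemble}.
#' @export
setGeneric("nModels", function(object) standardGeneric("nModels"))

#' @rdname StructureEnsemble-class
#' @export
setMethod("nModels", "StructureEnsemble",
          function(object) dim(object@coords)[3])

#' @describeIn StructureEnsemble-class the atom table.
#' @export
setGeneric("atomTable", function(object) standardGeneric("atomTable"))

#' @rdname StructureEnsemble-class
#' @export
setMethod("atomTable", "StructureEnsemble", function(object) object@atoms)

#' @describeIn StructureEnsemble-class coordinates of one model as an
#'   n x 3 matrix.
#' @param model 1-based model index.
#' @export
setGeneric("modelCoords",
           function(object, model = 1) standardGeneric("modelCoords"))

#' @rdname StructureEnsemble-class
#' @export
setMethod("modelCoords", "StructureEnsemble", function(object, model = 1) {
  object@coords[, , model, drop = TRUE]
})

#' Atom selection by residue range and atom names
#'
#' @slot ranges integer matrix (k x 2) of 1-based inclusive residue
#'   ranges.
#' @slot atomNames character vector of atom names; empty selects all.
#' @export
setClass("Selection",
  representation(ranges = "matrix", atomNames = "character"))

setValidity("Selection", function(object) {
  msg <- character()
  if (ncol(object@ranges) != 2) msg <- c(msg, "ranges must be k x 2")
  else if (any(object@ranges[, 2] < object@ranges[, 1]))
    msg <- c(msg, "range end must be >= start")
  if (length(msg)) msg else TRUE
})

#' Construct a Selection
#'
#' @param ranges either a k x 2 matrix of residue ranges, a numeric
#'   vector of residue ids, or a selection string such as
#'   \code{"2-13,16-19:N,CA,C"} (ranges before the colon, atom names
#'   after; atom part optional).
#' @param atomNames atom names to keep; empty keeps all atoms.
#' @return A \linkS4class{Selection}.
#' @examples
#' Selection("2-13,16-19,29-33,40-44,50-59,68-85:N,CA,C")
#' @export
Selection <- function(ranges, atomNames = character()) {
  if (is.character(ranges)) {
    parts <- strsplit(ranges, ":", fixed = TRUE)[[1]]
    if (length(parts) > 1 && !length(atomNames))
      atomNames <- strsplit(parts[2], ",", fixed = TRUE)[[1]]
    rng <- strsplit(parts[1], ",", fixed = TRUE)[[1]]
    ranges <- t(vapply(rng, function(r) {
      ab <- as.integer(strsplit(r, "-", fixed = TRUE)[[1]])
      if (anyNA(ab)) stop("malformed residue range: ", r)
      if (length(ab) == 1) c(ab, ab) else ab
    }, integer(2)))
    rownames(ranges) <- NULL
  } else if (is.null(dim(ranges))) {
    ranges <- cbind(as.integer(ranges), as.integer(ranges))
  }
  storage.mode(ranges) <- "integer"
  new("Selection", ranges = ranges, atomNames = toupper(atomNames))
}

setMethod("show", "Selection", function(object) {
  cat("Selection:",
      paste(apply(object@ranges, 1, function(r)
        if (r[1] == r[2]) r[1] else paste0(r[1], "-", r[2])),
        collapse = ","),
      if (length(object@atomNames))
        paste0(":", paste(object@atomNames, collapse = ",")) else "",
      "\n")
})

## logical index of selected atoms in an ensemble atom table
selectionIndex <- function(atoms, sel) {
  inRange <- rep(FALSE, nrow(atoms))
  for (k in seq_len(nrow(sel@ranges)))
    inRange <- inRange | (atoms$residueId >= sel@ranges[k, 1] &
                          atoms$residueId <= sel@ranges[k, 2])
  if (length(sel@atomNames))
    inRange <- inRange & toupper(atoms$atomName) %in% sel@atomNames
  inRange
}

#' Restraint-count table for a structure determination
#'
#' @slot noeCount nonredundant NOE distance restraints.
#' @slot dihedralCounts named numeric vector with elements phi, psi, chi.
#' @slot hbondCount hydrogen-bond restraints, counted as given (some
#'   conventions count 2 restraints per bond).
#' @slot rdcCount residual dipolar coupling restraints.
#' @slot nResidues number of residues in the construct.
#' @export
setClass("RestraintTable",
  representation(noeCount = "numeric", dihedralCounts = "numeric",
                 hbondCount = "numeric", rdcCount = "numeric",
                 nResidues = "numeric"))

setValidity("RestraintTable", function(object) {
  counts <- c(object@noeCount, object@dihedralCounts, object@hbondCount,
              object@rdcCount)
  if (any(counts < 0)) "all restraint counts must be >= 0" else TRUE
})

#' Construct a RestraintTable
#'
#' @param noeCount nonredundant NOE restraints.
#' @param dihedralCounts named vector c(phi=, psi=, chi=) of dihedral
#'   restraints.
#' @param hbondCount hydrogen-bond restraints.
#' @param rdcCount RDC restraints.
#' @param nResidues residues in the construct.
#' @return A \linkS4class{RestraintTable}.
#' @examples
#' tallyRestraints(RestraintTable(1504, c(phi = 71, psi = 71, chi = 19),
#'                                38, 79, 87))
#' @export
RestraintTable <- function(noeCount = 0,
                           dihedralCounts = c(phi = 0, psi = 0, chi = 0),
                           hbondCount = 0, rdcCount = 0, nResidues = 1) {
  new("RestraintTable", noeCount = as.numeric(noeCount),
      dihedralCounts = dihedralCounts, hbondCount = as.numeric(hbondCount),
      rdcCount = as.numeric(rdcCount), nResidues = as.numeric(nResidues))
}

setMethod("show", "RestraintTable", function(object) {
  t <- tallyRestraints(object)
  cat("RestraintTable:", t["total"], "restraints (",
      t["per_residue"], "per residue )\n")
})
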