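## Synthetic-data generators: every input the analysis stages consume can
## be produced here with known ground truth, so the whole pipeline is
## testable without external data.  All generators take explicit seeds and
## leave the caller's RNG state untouched.

## evaluate expr under a local RNG seed without disturbing global state
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Simulate an exponential relaxation decay
#'
#' Generates peak intensities I(t) = I0 exp(-R t) over the given delays
#' and adds i.i.d. Gaussian noise of the stated standard deviation.
#'
#' @param rate decay rate R (s-1).
#' @param i0 intensity at zero delay (arbitrary units).
#' @param delays relaxation delays (s); non-empty, non-negative.
#' @param noiseSd Gaussian noise standard deviation (intensity units).
#' @param seed integer seed; the generator is reproducible given the seed
#'   and does not touch the global RNG state.
#' @param residueId residue id recorded in the output.
#' @param residueName residue name recorded in the output.
#' @return A \linkS4class{RelaxationSeries}.
#' @examples
#' simulateDecay(1.5, 100, c(10, 50, 100, 400, 800, 1200, 1500) / 1000,
#'               noiseSd = 0)
#' @export
simulateDecay <- function(rate, i0, delays, noiseSd = 0, seed = 1L,
                          residueId = 1L, residueName = "XXX") {
  if (!length(delays) || any(delays < 0))
    stop("delays must be non-empty and non-negative")
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  ideal <- i0 * exp(-rate * delays)
  noisy <- if (noiseSd > 0)
    withSeed(seed, ideal + stats::rnorm(length(delays), sd = noiseSd))
  else ideal
  RelaxationSeries(residueId, delays, noisy, noiseSd = noiseSd,
                   residueName = residueName)
}

#' Random unit bond vectors
#'
#' Draws vectors uniformly on the unit sphere; used to emulate N-H bond
#' orientations for alignment-tensor work.
#'
#' @param n number of vectors.
#' @param seed integer seed.
#' @param residueId residue ids; defaults to 1..n.
#' @return A \linkS4class{BondVectorSet}.
#' @export
randomBondVectors <- function(n, seed = 1L, residueId = seq_len(n)) {
  v <- withSeed(seed, matrix(stats::rnorm(3 * n), ncol = 3))
  v <- v / sqrt(rowSums(v^2))
  BondVectorSet(residueId, v)
}

#' Simulate residual dipolar couplings from a known alignment tensor
#'
#' Back-calculates 1D couplings for each bond vector from the tensor and
#' adds Gaussian noise.  With zero noise an SVD refit
#' (\code{\link{svdFit}}) recovers the tensor exactly.
#'
#' @param tensor an \linkS4class{AlignmentTensor}.
#' @param vectors a \linkS4class{BondVectorSet} of unit vectors.
#' @param noiseSd Gaussian noise on the couplings (Hz).
#' @param seed integer seed.
#' @return data.frame with columns residue_id, atom1, atom2, d_obs_hz,
#'   d_err_hz (the RDC table format used throughout the package).
#' @examples
#' tens <- AlignmentTensor(da = 7.3, rhombicity = 0.35)
#' simulateRdc(tens, randomBondVectors(5, seed = 2))
#' @export
simulateRdc <- function(tensor, vectors, noiseSd = 0, seed = 1L) {
  stopifnot(is(tensor, "AlignmentTensor"), is(vectors, "BondVectorSet"))
  validObject(vectors)
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  d <- backCalculate(tensor, vectors)
  if (noiseSd > 0)
    d <- withSeed(seed, d + stats::rnorm(length(d), sd = noiseSd))
  data.frame(residue_id = vectors@residueId, atom1 = "N", atom2 = "H",
             d_obs_hz = d, d_err_hz = noiseSd)
}

#' Simulate a one-site ITC thermogram
#'
#' Produces per-injection heats from the one-site binding isotherm
#' (\code{\link{wisemanIsotherm}}) plus Gaussian noise.
#'
#' @param n stoichiometry (sites per macromolecule).
#' @param kd dissociation constant (M).
#' @param dh binding enthalpy (kcal/mol).
#' @param sched an \linkS4class{InjectionSchedule}.
#' @param noiseSd Gaussian noise per injection (ucal).
#' @param seed integer seed.
#' @return An \linkS4class{ItcExperiment}.
#' @examples
#' simulateItc(1, 4.8e-6, -11.5, InjectionSchedule())
#' @export
simulateItc <- function(n, kd, dh, sched = InjectionSchedule(),
                        noiseSd = 0, seed = 1L) {
  stopifnot(is(sched, "InjectionSchedule"))
  validObject(sched)
  if (kd <= 0) stop("kd must be positive")
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  q <- wisemanIsotherm(n, kd, dh, sched)
  if (noiseSd > 0)
    q <- withSeed(seed, q + stats::rnorm(length(q), sd = noiseSd))
  ItcExperiment(sched, q)
}

## local atom offsets (Angstrom) from the CA position; coarse backbone
## geometry, adequate for superposition and precision metrics
ensembleAtomOffsets <- function() {
  rbind(N  = c(-1.20,  0.80,  0.00),
        CA = c( 0.00,  0.00,  0.00),
        C  = c( 1.30,  0.60,  0.40),
        O  = c( 1.60,  1.75,  0.30),
        CB = c(-0.30, -0.90,  1.20))
}

#' Simulate a multi-model coordinate ensemble
#'
#' Generates an ensemble whose models share a common mean conformation (a
#' helical CA trace with N, H, CA, C, O and CB atoms per residue) and
#' differ by isotropic Gaussian displacement of each atom, with a
#' per-residue scatter profile.  Side-chain proxy atoms (CB) receive
#' \code{sidechainScale} times the backbone scatter, mimicking the usual
#' ordering of heavy-atom over backbone coordinate spread.
#'
#' @param nModels number of models (>= 2).
#' @param nResidues number of residues.
#' @param scatterProfile per-residue positional standard deviation
#'   (Angstrom); recycled to length \code{nResidues}.
#' @param seed integer seed.
#' @param sidechainScale multiplier applied to the scatter of CB atoms.
#' @return A \linkS4class{StructureEnsemble}.
#' @examples
#' simulateEnsemble(5, 20, scatterProfile = 0.3, seed = 7)
#' @export
simulateEnsemble <- function(nModels, nResidues, scatterProfile = 0.3,
                             seed = 1L, sidechainScale = 2) {
  if (nModels < 2) stop("nModels must be >= 2")
  scatter <- rep_len(scatterProfile, nResidues)
  if (any(scatter < 0)) stop("scatter values must be >= 0")

  off <- ensembleAtomOffsets()
  atomNames <- c(rownames(off), "H")
  perRes <- length(atomNames)
  i <- seq_len(nResidues)
  ca <- cbind(2.3 * cos(i * 100 * pi / 180),
              2.3 * sin(i * 100 * pi / 180), 1.5 * i)
  mean1 <- do.call(rbind, lapply(i, function(r) {
    base <- sweep(off, 2, ca[r, ], "+")
    ## amide H: 1.02 Angstrom from N along a residue-dependent direction
    phi <- r * 0.7; theta <- 1.0 + 0.5 * sin(r)
    u <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
    rbind(base, H = base["N", ] + 1.02 * u)
  }))
  atoms <- data.frame(
    residueId = rep(i, each = perRes),
    residueName = "ALA",
    atomName = rep(atomNames, nResidues),
    stringsAsFactors = FALSE)
  sdAtom <- rep(scatter, each = perRes)
  sdAtom[atoms$atomName == "CB"] <-
    sdAtom[atoms$atomName == "CB"] * sidechainScale

  coords <- withSeed(seed, {
    arr <- array(0, dim = c(nrow(atoms), 3, nModels))
    for (m in seq_len(nModels))
      arr[, , m] <- mean1 + matrix(stats::rnorm(3 * nrow(atoms)),
                                   ncol = 3) * sdAtom
    arr
  })
  StructureEnsemble(atoms, coords)
}
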