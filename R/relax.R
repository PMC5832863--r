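## Relaxation analysis: exponential rate fitting, R1rho -> R2 offset
## correction, heteronuclear NOE, global tumbling time from trimmed R2/R1
## ratios, and per-residue dynamics classification.

#' Fit a monoexponential decay to a relaxation series
#'
#' Least-squares fit of I(t) = I0 exp(-R t) to the intensities of one
#' residue.  The rate uncertainty is estimated by Monte Carlo: the
#' noise-free curve implied by the fit is resampled \code{nBoot} times
#' with Gaussian noise at the series' \code{noiseSd} and refit; the
#' standard deviation of the refitted rates is reported.
#'
#' @param series a \linkS4class{RelaxationSeries} with >= 3 points.
#' @param nBoot Monte Carlo resamples for the rate uncertainty; 0
#'   disables error estimation (rateSd = NA).
#' @param seed seed for the Monte Carlo resampling.
#' @return Named list: \code{rate} (s-1), \code{i0}, \code{rateSd} (s-1),
#'   \code{converged} (logical).
#' @examples
#' s <- simulateDecay(1.2, 100, c(10, 50, 100, 400, 800, 1200, 1500) / 1000,
#'                    noiseSd = 0)
#' fitExponential(s, nBoot = 0)
#' @export
fitExponential <- function(series, nBoot = 200, seed = 1L) {
  stopifnot(is(series, "RelaxationSeries"))
  validObject(series)
  t <- series@delays
  y <- series@intensities
  if (length(t) < 3) stop("at least 3 delay points required")
  if (all(y == 0)) stop("intensities are all zero")

  fit <- expFitCore(t, y)
  if (!fit$converged)
    return(list(rate = NA_real_, i0 = NA_real_, rateSd = NA_real_,
                converged = FALSE))

  rateSd <- NA_real_
  if (nBoot > 0 && series@noiseSd > 0) {
    ideal <- fit$i0 * exp(-fit$rate * t)
    rates <- withSeed(seed, vapply(seq_len(nBoot), function(b) {
      f <- expFitCore(t, ideal + stats::rnorm(length(t),
                                              sd = series@noiseSd))
      if (f$converged) f$rate else NA_real_
    }, numeric(1)))
    rateSd <- stats::sd(rates, na.rm = TRUE)
  } else if (nBoot > 0 && series@noiseSd == 0) {
    rateSd <- 0
  }
  list(rate = fit$rate, i0 = fit$i0, rateSd = rateSd, converged = TRUE)
}

## core two-parameter exponential fit; log-linear start, Levenberg-
## Marquardt refinement
expFitCore <- function(t, y) {
  if (stats::sd(y) == 0)
    return(list(rate = 0, i0 = y[1], converged = TRUE))
  pos <- y > 0
  start <- if (sum(pos) >= 2) {
    cf <- stats::coef(stats::lm(log(y[pos]) ~ t[pos]))
    list(i0 = exp(cf[[1]]), rate = max(-cf[[2]], 1e-6))
  } else list(i0 = max(abs(y)), rate = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ i0 * exp(-rate * t),
                      start = list(i0 = start$i0, rate = start$rate),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(list(rate = NA_real_, i0 = NA_real_,
                                converged = FALSE))
  cf <- stats::coef(fit)
  list(rate = unname(cf["rate"]), i0 = unname(cf["i0"]), converged = TRUE)
}

#' Offset-correct R1rho to R2
#'
#' Applies the resonance-offset correction
#' \deqn{R_2 = (R_{1\rho} - R_1 \sin^2\theta)/\cos^2\theta,\qquad
#'   \theta = \arctan(\Omega_N / \gamma_N B_1)}
#' where Omega_N is the 15N resonance offset and gamma_N B1 the spin-lock
#' field strength.  Uncertainties are propagated in quadrature.  At zero
#' offset the correction is the identity.
#'
#' @param r1rho rotating-frame rate R1rho (s-1); vectorized.
#' @param r1 longitudinal rate R1 (s-1).
#' @param offset resonance offset Omega_N (Hz); default 0.
#' @param spinlock spin-lock field strength (Hz); must be > 0.
#' @param r1rhoSd,r1Sd optional uncertainties (s-1).
#' @param tol minimum allowed cos^2(theta); larger offsets are rejected
#'   as uncorrectable.
#' @return Named list \code{r2}, \code{r2Sd} (NA when no uncertainties
#'   supplied).
#' @examples
#' r2FromR1rho(10, 2, offset = 1500, spinlock = 1500)  # theta = 45 deg
#' @export
r2FromR1rho <- function(r1rho, r1, offset = 0, spinlock,
                        r1rhoSd = NA_real_, r1Sd = NA_real_,
                        tol = 1e-3) {
  if (any(spinlock <= 0)) stop("spinlock must be positive")
  theta <- atan2(offset, spinlock)
  s2 <- sin(theta)^2
  c2 <- cos(theta)^2
  if (any(c2 < tol))
    stop("offset too large for the R1rho correction (cos^2 theta < ",
         tol, ")")
  r2 <- (r1rho - r1 * s2) / c2
  r2Sd <- sqrt(r1rhoSd^2 + (s2 * r1Sd)^2) / c2
  list(r2 = r2, r2Sd = r2Sd)
}

#' Heteronuclear 1H-15N NOE from saturated/reference intensities
#'
#' NOE = I_sat / I_ref; the uncertainty follows from the intensity noise
#' by quadrature.  Reference intensities within \code{flagFactor} noise
#' standard deviations of zero are flagged undefined (NA).
#'
#' @param iSat peak intensity with 1H saturation; vectorized.
#' @param iRef reference peak intensity.
#' @param noiseSd intensity noise standard deviation.
#' @param flagFactor reference intensities with |I_ref| <= flagFactor *
#'   noiseSd are reported NA.
#' @return Named list \code{noe}, \code{noeSd}, \code{undefined}
#'   (logical).
#' @examples
#' hetNoe(0.6, 0.8, noiseSd = 0.01)
#' @export
hetNoe <- function(iSat, iRef, noiseSd = 0, flagFactor = 3) {
  if (any(iRef == 0)) stop("reference intensity must be non-zero")
  undefined <- abs(iRef) <= flagFactor * noiseSd
  noe <- iSat / iRef
  noeSd <- (noiseSd / abs(iRef)) * sqrt(1 + noe^2)
  noe[undefined] <- NA_real_
  noeSd[undefined] <- NA_real_
  list(noe = noe, noeSd = noeSd, undefined = undefined)
}

## IQR-based R2 trim used by estimateTauc and classifyDynamics
r2TrimKeep <- function(r2, iqrFactor = 1.5) {
  med <- stats::median(r2, na.rm = TRUE)
  iqr <- stats::IQR(r2, na.rm = TRUE)
  !is.na(r2) & abs(r2 - med) <= iqrFactor * iqr
}

#' Estimate the global rotational correlation time from R2/R1 ratios
#'
#' Computes the trimmed mean R2/R1 ratio over ordered-region residues and
#' inverts the rigid-rotor model-free ratio (S2 = 1, tau_e = 0, Rex = 0)
#' as a monotone function of tau_c at the configured field, by numerical
#' root finding.  Trimming excludes residues with NOE below
#' \code{noeCut} (mobile) and residues whose R2 falls outside median
#' +/- 1.5 IQR (exchange-broadened or noisy), so the ratio reflects
#' overall tumbling only.
#'
#' The closed-form approximation
#' \eqn{\tau_c \approx \sqrt{6 R_2/R_1 - 7} / (2\omega_N)} is available
#' via \code{method = "closed"} as a cross-check; the numerical inversion
#' is the default because it makes forward-model round trips exact.
#'
#' @param rates data.frame with columns \code{residue_id}, \code{r1},
#'   \code{r2} and (if trimming on NOE) \code{noe}.
#' @param fieldH1 proton Larmor frequency (MHz).
#' @param noeCut residues with NOE below this are excluded (default 0.8).
#' @param iqrFactor R2 trim width in IQR units (default 1.5).
#' @param method "invert" (numerical inversion, default) or "closed"
#'   (closed-form approximation).
#' @return A \linkS4class{TumblingEstimate}.
#' @examples
#' p <- SpinParams(s2 = 1, tauC = 6.2, fieldH1 = 800)
#' r <- modelfreeRates(p)
#' rates <- data.frame(residue_id = 1:6, r1 = r$r1, r2 = r$r2, noe = r$noe)
#' estimateTauc(rates, fieldH1 = 800)
#' @export
estimateTauc <- function(rates, fieldH1 = 800, noeCut = 0.8,
                         iqrFactor = 1.5, method = c("invert", "closed")) {
  method <- match.arg(method)
  stopifnot(all(c("residue_id", "r1", "r2") %in% names(rates)))
  keep <- !is.na(rates$r1) & !is.na(rates$r2) & rates$r1 > 0
  if ("noe" %in% names(rates))
    keep <- keep & !is.na(rates$noe) & rates$noe >= noeCut
  keep[keep] <- r2TrimKeep(rates$r2[keep], iqrFactor)
  if (sum(keep) < 5)
    stop("fewer than 5 residues survive trimming; cannot estimate tauC")
  ratio <- mean(rates$r2[keep] / rates$r1[keep])

  tau <- if (method == "closed") {
    if (6 * ratio - 7 < 0)
      stop("R2/R1 ratio too small for the closed-form estimate")
    wN <- larmorFrequencies(fieldH1)$wN
    sqrt(6 * ratio - 7) / (2 * wN) * 1e9
  } else {
    lo <- 0.05; hi <- 200
    if (ratio <= rigidR2R1Ratio(lo, fieldH1) ||
        ratio >= rigidR2R1Ratio(hi, fieldH1))
      stop("R2/R1 ratio ", format(ratio, digits = 4),
           " outside the invertible range for tauC in [", lo, ", ", hi,
           "] ns")
    stats::uniroot(function(tc) rigidR2R1Ratio(tc, fieldH1) - ratio,
                   c(lo, hi), tol = 1e-12)$root
  }
  new("TumblingEstimate", tauC = tau, nResiduesUsed = sum(keep),
      trimmedIds = as.integer(rates$residue_id[!keep]), ratio = ratio)
}

#' Classify per-residue backbone dynamics from relaxation parameters
#'
#' Partitions residues into five mutually exclusive regimes:
#' \itemize{
#'   \item \code{fast}: NOE below \code{noeCut} (fast ps-ns internal
#'     motion);
#'   \item \code{exchange}: R2 above the trimmed mean by more than
#'     \code{k} trimmed standard deviations (us-ms conformational
#'     exchange);
#'   \item \code{both}: both criteria met;
#'   \item \code{broadened/missing}: no observable rates (NA), e.g.
#'     exchange-broadened beyond detection or missing amide;
#'   \item \code{rigid}: none of the above.
#' }
#' The trimmed R2 statistics use the same median +/- 1.5 IQR rule as the
#' tumbling-time estimator.
#'
#' @param rates data.frame with columns \code{residue_id}, \code{r2},
#'   \code{noe} (NA marks unobserved residues).
#' @param noeCut NOE threshold for fast motion (default 0.8).
#' @param k exchange threshold in trimmed standard deviations above the
#'   trimmed mean R2 (default 1.5).
#' @param iqrFactor trim width for the R2 statistics.
#' @return data.frame with columns \code{residue_id}, \code{label}
#'   (factor with levels rigid, fast, exchange, both, broadened/missing);
#'   exactly one label per residue.
#' @examples
#' rates <- data.frame(residue_id = 1:5, r2 = c(10, 10, 18, 10, NA),
#'                     noe = c(0.85, 0.6, 0.85, 0.82, NA))
#' classifyDynamics(rates)
#' @export
classifyDynamics <- function(rates, noeCut = 0.8, k = 1.5,
                             iqrFactor = 1.5) {
  stopifnot(all(c("residue_id", "r2", "noe") %in% names(rates)))
  obs <- !is.na(rates$r2) & !is.na(rates$noe)
  keep <- obs
  keep[obs] <- r2TrimKeep(rates$r2[obs], iqrFactor)
  mu <- mean(rates$r2[keep])
  sdv <- stats::sd(rates$r2[keep])
  if (is.na(sdv)) sdv <- 0

  fast <- obs & rates$noe < noeCut
  exch <- obs & rates$r2 > mu + k * sdv
  label <- rep("rigid", nrow(rates))
  label[fast] <- "fast"
  label[exch] <- "exchange"
  label[fast & exch] <- "both"
  label[!obs] <- "broadened/missing"
  data.frame(residue_id = rates$residue_id,
             label = factor(label, levels = c("rigid", "fast", "exchange",
                                              "both", "broadened/missing")))
}

#' Per-residue intensity ratio between two spectra
#'
#' Elementwise I_bound / I_free over matched residue ids, as used in
#' titration line-broadening analysis.  Residues present in the free
#' spectrum but missing (or zero) in the bound spectrum are reported as
#' ratio 0; residues whose free intensity is zero are flagged undefined.
#'
#' @param bound data.frame with columns \code{residue_id},
#'   \code{intensity} for the complexed state.
#' @param free data.frame with the same columns for the free state.
#' @return data.frame with columns \code{residue_id}, \code{ratio},
#'   \code{undefined}.
#' @examples
#' free <- data.frame(residue_id = 1:3, intensity = c(1, 2, 4))
#' bound <- data.frame(residue_id = 1:3, intensity = c(0.3, 0.6, 1.2))
#' intensityRatio(bound, free)
#' @export
intensityRatio <- function(bound, free) {
  stopifnot(all(c("residue_id", "intensity") %in% names(bound)),
            all(c("residue_id", "intensity") %in% names(free)))
  ib <- bound$intensity[match(free$residue_id, bound$residue_id)]
  ib[is.na(ib)] <- 0
  undef <- free$intensity == 0
  ratio <- ifelse(undef, NA_real_, ib / free$intensity)
  data.frame(residue_id = free$residue_id, ratio = ratio,
             undefined = undef)
}

#' Full relaxation analysis of R1, R1rho and NOE tables
#'
#' Convenience wrapper binding the per-residue stages together: fits R1
#' and R1rho decays, applies the offset correction to obtain R2, forms
#' the NOE, and returns one row per residue.  Residues present in any
#' input are carried through; missing data yield NA (never silently
#' dropped).
#'
#' @param r1Series list of \linkS4class{RelaxationSeries} for R1.
#' @param r1rhoSeries list of \linkS4class{RelaxationSeries} for R1rho.
#' @param noeTable data.frame with columns \code{residue_id},
#'   \code{i_sat}, \code{i_ref}, \code{noise_sd}.
#' @param cfg a \linkS4class{SpectrometerConfig}; per-residue offsets are
#'   looked up by residue id and default to 0 (with a warning) when
#'   absent.
#' @param nBoot Monte Carlo resamples for rate errors.
#' @param seed seed for the Monte Carlo resampling.
#' @return data.frame with columns residue_id, r1, r1_sd, r1rho,
#'   r1rho_sd, r2, r2_sd, noe, noe_sd.
#' @export
analyzeRelaxation <- function(r1Series, r1rhoSeries, noeTable, cfg,
                              nBoot = 200, seed = 1L) {
  stopifnot(is(cfg, "SpectrometerConfig"))
  ids <- sort(unique(c(vapply(r1Series, function(s) s@residueId,
                              integer(1)),
                       vapply(r1rhoSeries, function(s) s@residueId,
                              integer(1)),
                       as.integer(noeTable$residue_id))))
  if (!length(cfg@offsets))
    warning("no per-residue offsets supplied; ",
            "R1rho correction reduces to the identity")
  fitOne <- function(lst, id, sd_seed) {
    i <- which(vapply(lst, function(s) s@residueId, integer(1)) == id)
    if (!length(i)) return(c(NA_real_, NA_real_))
    f <- tryCatch(fitExponential(lst[[i]], nBoot = nBoot,
                                 seed = sd_seed),
                  error = function(e) list(rate = NA_real_,
                                           rateSd = NA_real_))
    c(f$rate, f$rateSd)
  }
  out <- lapply(seq_along(ids), function(j) {
    id <- ids[j]
    r1 <- fitOne(r1Series, id, seed + j)
    rr <- fitOne(r1rhoSeries, id, seed + 10000L + j)
    offs <- if (as.character(id) %in% names(cfg@offsets))
      cfg@offsets[[as.character(id)]] else 0
    r2 <- if (is.na(r1[1]) || is.na(rr[1])) list(r2 = NA_real_,
                                                 r2Sd = NA_real_)
    else r2FromR1rho(rr[1], r1[1], offset = offs,
                     spinlock = cfg@spinlock, r1rhoSd = rr[2],
                     r1Sd = r1[2])
    k <- which(noeTable$residue_id == id)
    noe <- if (!length(k)) list(noe = NA_real_, noeSd = NA_real_)
    else hetNoe(noeTable$i_sat[k[1]], noeTable$i_ref[k[1]],
                noeTable$noise_sd[k[1]])
    data.frame(residue_id = id, r1 = r1[1], r1_sd = r1[2],
               r1rho = rr[1], r1rho_sd = rr[2], r2 = r2$r2,
               r2_sd = r2$r2Sd, noe = noe$noe, noe_sd = noe$noeSd)
  })
  do.call(rbind, out)
}
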