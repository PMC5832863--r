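## Lipari-Szabo model-free forward model for backbone 15N relaxation.
## Used by the synthetic-data generators and by the rotational correlation
## time estimator (rigid limit); the package performs no per-residue
## model-free parameter fitting.

## angular frequencies (rad/s) of 1H and 15N at a given 1H MHz field
larmorFrequencies <- function(fieldH1) {
  k <- nmrConstants()
  wH <- 2 * pi * fieldH1 * 1e6
  wN <- abs(wH / k$gamma_ratio)
  list(wH = wH, wN = wN)
}

## two-timescale spectral density (s/rad); tauC, taue in seconds
spectralDensity <- function(w, s2, tauc, taue) {
  tau <- if (taue > 0) 1 / (1 / tauc + 1 / taue) else 0
  (2 / 5) * (s2 * tauc / (1 + (w * tauc)^2) +
             (1 - s2) * tau / (1 + (w * tau)^2))
}

## dipolar and CSA interaction constants at a given field
interactionConstants <- function(fieldH1) {
  k <- nmrConstants()
  w <- larmorFrequencies(fieldH1)
  d <- k$mu0_4pi * k$hbar * k$gamma_h * abs(k$gamma_n) / k$r_nh^3
  list(d2_4 = d^2 / 4, c2 = (w$wN * k$csa_n * 1e-6)^2 / 3,
       wH = w$wH, wN = w$wN)
}

#' Backbone 15N relaxation rates from model-free spin parameters
#'
#' Forward-simulates R1, R2 and the heteronuclear 1H-15N NOE of an amide
#' 15N spin from Lipari-Szabo parameters, using the two-timescale
#' spectral density
#' \deqn{J(\omega) = \frac{2}{5}\left[\frac{S^2\tau_c}{1+(\omega\tau_c)^2}
#'   + \frac{(1-S^2)\tau}{1+(\omega\tau)^2}\right],\quad
#'   \tau^{-1} = \tau_c^{-1} + \tau_e^{-1}}
#' with the standard dipolar (N-H, 1.02 Angstrom) and 15N CSA (-172 ppm)
#' interaction terms at the stated field.  The exchange term Rex adds to
#' R2 only; R1 and the NOE are unaffected by it.
#'
#' @param params a \linkS4class{SpinParams} object.
#' @return Named list with elements \code{r1} (s-1), \code{r2} (s-1) and
#'   \code{noe} (dimensionless).
#' @examples
#' modelfreeRates(SpinParams(s2 = 0.87, tauC = 6.2, tauE = 50,
#'                           fieldH1 = 800))
#' @export
modelfreeRates <- function(params) {
  stopifnot(is(params, "SpinParams"))
  validObject(params)
  k <- nmrConstants()
  ic <- interactionConstants(params@fieldH1)
  tauc <- params@tauC * 1e-9
  taue <- params@tauE * 1e-12
  J <- function(w) spectralDensity(w, params@s2, tauc, taue)
  r1 <- ic$d2_4 * (J(ic$wH - ic$wN) + 3 * J(ic$wN) +
                   6 * J(ic$wH + ic$wN)) + ic$c2 * J(ic$wN)
  r2 <- ic$d2_4 / 2 * (4 * J(0) + J(ic$wH - ic$wN) + 3 * J(ic$wN) +
                       6 * J(ic$wH) + 6 * J(ic$wH + ic$wN)) +
        ic$c2 / 6 * (4 * J(0) + 3 * J(ic$wN)) + params@rex
  noe <- 1 + ic$d2_4 * (k$gamma_h / k$gamma_n) *
             (6 * J(ic$wH + ic$wN) - J(ic$wH - ic$wN)) / r1
  list(r1 = r1, r2 = r2, noe = noe)
}

## rigid-rotor (S2 = 1, taue = 0, Rex = 0) R2/R1 ratio at tauc (ns)
rigidR2R1Ratio <- function(taucNs, fieldH1) {
  r <- modelfreeRates(SpinParams(s2 = 1, tauC = taucNs, tauE = 0, rex = 0,
                                 fieldH1 = fieldH1))
  r$r2 / r$r1
}
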