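#' Physical constants used throughout the package
#'
#' All constants live in one place so that every run can log the exact
#' values used.  The amide-specific parameters (N-H bond length, 15N CSA)
#' are the conventional values used in backbone relaxation analysis; they
#' enter only the model-free forward simulation and the rotational
#' correlation time estimator.
#'
#' @return Named list with elements:
#' \describe{
#'   \item{gamma_h}{1H gyromagnetic ratio (rad s-1 T-1).}
#'   \item{gamma_ratio}{gamma_H / gamma_N = -9.8656 (dimensionless).}
#'   \item{gamma_n}{15N gyromagnetic ratio, derived from the ratio.}
#'   \item{r_nh}{amide N-H bond length (m), 1.02 Angstrom.}
#'   \item{csa_n}{15N chemical shift anisotropy (ppm), -172.}
#'   \item{hbar}{reduced Planck constant (J s).}
#'   \item{mu0_4pi}{vacuum permeability / 4 pi (T m A-1).}
#'   \item{gas_constant_kcal}{gas constant (kcal mol-1 K-1), 1.987e-3.}
#' }
#' @examples
#' nmrConstants()$gamma_ratio
#' @export
nmrConstants <- function() {
  list(
    gamma_h           = 2.6752218744e8,
    gamma_ratio       = -9.8656,
    gamma_n           = 2.6752218744e8 / -9.8656,
    r_nh              = 1.02e-10,
    csa_n             = -172,
    hbar              = 1.054571817e-34,
    mu0_4pi           = 1e-7,
    gas_constant_kcal = 1.987e-3
  )
}
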