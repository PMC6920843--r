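#' Physical constants used by the dipolar-coupling formulas
#'
#' Returns the CODATA values of the gyromagnetic ratios of \eqn{^1}H and
#' \eqn{^{14}}N, the reduced Planck constant and \eqn{\mu_0/4\pi}.  These
#' enter the definitions of the dipolar relaxation constants
#' \eqn{C_{HH} = (3/10)\,((\mu_0/4\pi)\gamma_H^2\hbar/r_{HH}^3)^2} and
#' \eqn{C_{HN} = (2/3)\,((\mu_0/4\pi)\gamma_H\gamma_N\hbar/r_{HN}^3)^2},
#' both in squared angular frequency units (rad^2 s^-2).
#'
#' @return A list of class `physical_constants` with elements
#'   `gamma_H`, `gamma_N` (rad s^-1 T^-1), `hbar` (J s) and
#'   `mu0_over_4pi` (T m A^-1).
#' @examples
#' pc <- physical_constants()
#' pc$gamma_N / pc$gamma_H   # ~0.0723, ratio of 14N to 1H Larmor frequencies
#' @export
physical_constants <- function() {
  pc <- list(
    gamma_H = 2.6752e8,       # 1H gyromagnetic ratio, rad s^-1 T^-1
    gamma_N = 1.9338e7,       # 14N gyromagnetic ratio, rad s^-1 T^-1
    hbar = 1.0546e-34,        # J s
    mu0_over_4pi = 1e-7       # T m A^-1
  )
  stopifnot(all(unlist(pc) > 0))
  class(pc) <- "physical_constants"
  pc
}

#' Convert a frequency in MHz to angular frequency in rad/s
#'
#' All model formulas evaluate in angular frequency; all I/O uses ordinary
#' frequencies in MHz.  This is the single point where the conversion
#' \eqn{\omega = 2\pi\nu} is performed.
#'
#' @param nu_MHz frequency in MHz (vectorised)
#' @return angular frequency in rad/s
#' @export
omega_from_MHz <- function(nu_MHz) 2 * pi * nu_MHz * 1e6

#' @rdname omega_from_MHz
#' @param omega angular frequency in rad/s
#' @export
MHz_from_omega <- function(omega) omega / (2 * pi * 1e6)
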