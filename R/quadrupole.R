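#' Quadrupole coupling of a spin-1 nucleus
#'
#' Bundles the amplitude \eqn{a_Q = e^2qQ/h} (MHz) and asymmetry parameter
#' \eqn{\eta} of the electric-field-gradient (EFG) tensor at a \eqn{^{14}}N
#' nucleus.  When the quadrupole coupling dominates the \eqn{^{14}}N Zeeman
#' interaction the \eqn{^{14}}N energy levels and transition frequencies are
#' fixed by these two numbers alone; see [transition_frequencies()].
#'
#' @param a_Q quadrupole coupling amplitude in MHz, positive
#' @param eta asymmetry parameter, in `[0, 1]`
#' @return An object of class `quadrupole_coupling`.
#' @examples
#' quadrupole_coupling(3.36, 0.42)
#' @export
quadrupole_coupling <- function(a_Q, eta) {
  stopifnot(length(a_Q) == 1, length(eta) == 1)
  if (!is.finite(a_Q) || a_Q <= 0)
    stop("'a_Q' must be a positive quadrupole amplitude in MHz", call. = FALSE)
  if (!is.finite(eta) || eta < 0 || eta > 1)
    stop("asymmetry parameter 'eta' must lie in [0, 1]", call. = FALSE)
  structure(list(a_Q = a_Q, eta = eta), class = "quadrupole_coupling")
}

#' @export
print.quadrupole_coupling <- function(x, ...) {
  cat(sprintf("<quadrupole coupling>  a_Q = %.4g MHz,  eta = %.3g\n",
              x$a_Q, x$eta))
  invisible(x)
}

#' Energy levels and transition frequencies of a quadrupolar spin-1 nucleus
#'
#' For a spin-1 nucleus whose energy-level structure is dominated by the
#' quadrupole coupling the three levels are
#' \eqn{E_1 = a_Q(1-\eta)/4}, \eqn{E_2 = -a_Q/2},
#' \eqn{E_3 = a_Q(1+\eta)/4} (in frequency units of MHz), giving the
#' transition frequencies
#' \eqn{\nu_- = \tfrac34 a_Q (1-\eta/3)},
#' \eqn{\nu_+ = \tfrac34 a_Q (1+\eta/3)} and
#' \eqn{\nu_0 = \nu_+ - \nu_- = \tfrac12 \eta a_Q}.
#' These are the frequencies at which QRE maxima ("quadrupole peaks") appear
#' in a 1H relaxation dispersion profile.
#'
#' @param quad a [quadrupole_coupling()]
#' @return An object of class `quadrupole_spectrum`: list with `E1`, `E2`,
#'   `E3` (MHz), `nu_minus`, `nu_plus`, `nu_zero` (MHz).
#' @examples
#' transition_frequencies(quadrupole_coupling(3.36, 0.42))
#' @export
transition_frequencies <- function(quad) {
  stopifnot(inherits(quad, "quadrupole_coupling"))
  a <- quad$a_Q
  eta <- quad$eta
  E1 <- a * (1 - eta) / 4
  E2 <- -a / 2
  E3 <- a * (1 + eta) / 4
  structure(list(
    E1 = E1, E2 = E2, E3 = E3,
    nu_minus = 0.75 * a * (1 - eta / 3),
    nu_plus  = 0.75 * a * (1 + eta / 3),
    nu_zero  = 0.5 * eta * a
  ), class = "quadrupole_spectrum")
}

#' @export
print.quadrupole_spectrum <- function(x, ...) {
  cat(sprintf(
    "<14N quadrupole spectrum>  nu- = %.4f  nu+ = %.4f  nu0 = %.4f MHz\n",
    x$nu_minus, x$nu_plus, x$nu_zero))
  invisible(x)
}

#' Quadrupole parameters from observed peak positions
#'
#' Exact inversion of the transition-frequency formulas: given the two main
#' quadrupole-peak positions \eqn{\nu_-}, \eqn{\nu_+} (MHz),
#' \eqn{a_Q = \tfrac23(\nu_+ + \nu_-)} and
#' \eqn{\eta = 2(\nu_+ - \nu_-)/a_Q}.
#'
#' @param report a [peak_report()] or any list with `nu_minus_obs` and
#'   `nu_plus_obs` in MHz
#' @return a [quadrupole_coupling()]
#' @seealso [detect_peaks()] which produces the peak report from a profile.
#' @export
quad_params_from_peaks <- function(report) {
  nm <- report$nu_minus_obs
  np <- report$nu_plus_obs
  if (is.null(nm) || is.null(np) || !is.finite(nm) || !is.finite(np))
    stop("both nu_minus_obs and nu_plus_obs are required", call. = FALSE)
  if (np <= nm)
    stop("nu_plus_obs must exceed nu_minus_obs", call. = FALSE)
  a_Q <- (2 / 3) * (np + nm)
  eta <- 2 * (np - nm) / a_Q
  if (eta > 1 + 1e-9)
    stop(sprintf(
      "peak positions imply eta = %.3f outside [0, 1]; they are unlikely to be a nu-/nu+ pair",
      eta), call. = FALSE)
  quadrupole_coupling(a_Q, min(eta, 1))
}
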