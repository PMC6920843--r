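#' A single Lorentzian relaxation component
#'
#' One dynamical process contributing to the 1H-1H dipolar relaxation rate:
#' a dipolar relaxation constant `C` (rad^2 s^-2) and a correlation time
#' `tau` (s).
#'
#' @param C dipolar relaxation constant, rad^2 s^-2, non-negative
#' @param tau correlation time in seconds, positive
#' @return list of class `hh_component`
#' @export
hh_component <- function(C, tau) {
  stopifnot(length(C) == 1, length(tau) == 1)
  if (!is.finite(C) || C < 0)
    stop("dipolar constant 'C' must be non-negative", call. = FALSE)
  if (!is.finite(tau) || tau <= 0)
    stop("correlation time 'tau' must be positive", call. = FALSE)
  structure(list(C = C, tau = tau), class = "hh_component")
}

#' Model-free parameters of the 1H-1H relaxation rate
#'
#' The three-Lorentzian ("model-free") decomposition of the 1H-1H dipolar
#' relaxation dispersion: slow, intermediate and fast dynamical processes
#' plus a frequency-independent rate `A` accounting for dynamics faster than
#' about 1 ns.  The labels are ordered: `tau_s > tau_i > tau_f`.
#'
#' @param C_s,tau_s slow-process dipolar constant (rad^2 s^-2) and
#'   correlation time (s)
#' @param C_i,tau_i intermediate process
#' @param C_f,tau_f fast process
#' @param A frequency-independent relaxation rate, s^-1, non-negative
#' @return list of class `hh_params` with elements `slow`, `intermediate`,
#'   `fast` (each an [hh_component()]) and `A`
#' @examples
#' hh_params(7.85e7, 2.55e-6, 2.84e8, 1.43e-7, 4.21e8, 1.31e-8, A = 6.47)
#' @export
hh_params <- function(C_s, tau_s, C_i, tau_i, C_f, tau_f, A = 0) {
  if (!is.finite(A) || A < 0)
    stop("'A' must be a non-negative rate in s^-1", call. = FALSE)
  if (!(tau_s > tau_i && tau_i > tau_f))
    stop("correlation times must be ordered tau_s > tau_i > tau_f",
         call. = FALSE)
  structure(list(
    slow = hh_component(C_s, tau_s),
    intermediate = hh_component(C_i, tau_i),
    fast = hh_component(C_f, tau_f),
    A = A
  ), class = "hh_params")
}

#' Parameters of the 1H-14N quadrupole-relaxation-enhancement rate
#'
#' @param C_HN 1H-14N dipolar relaxation constant, rad^2 s^-2
#' @param tau_Q correlation time of the H-N dipole-dipole fluctuations, s
#' @param theta,phi polar and azimuthal angles (degrees) of the H-N
#'   dipole-dipole axis in the principal axis system of the EFG tensor at
#'   the 14N position
#' @param quad a [quadrupole_coupling()]
#' @return list of class `hn_params`
#' @examples
#' hn_params(1.93e8, 8.91e-7, theta = 68, phi = 33,
#'           quad = quadrupole_coupling(3.36, 0.42))
#' @export
hn_params <- function(C_HN, tau_Q, theta, phi, quad) {
  if (!is.finite(C_HN) || C_HN < 0)
    stop("'C_HN' must be non-negative", call. = FALSE)
  if (!is.finite(tau_Q) || tau_Q <= 0)
    stop("'tau_Q' must be positive", call. = FALSE)
  if (theta < 0 || theta > 180) stop("theta must lie in [0, 180] degrees", call. = FALSE)
  if (phi < 0 || phi >= 360) stop("phi must lie in [0, 360) degrees", call. = FALSE)
  stopifnot(inherits(quad, "quadrupole_coupling"))
  structure(list(C_HN = C_HN, tau_Q = tau_Q, theta = theta, phi = phi,
                 quad = quad), class = "hn_params")
}

#' @export
print.hh_params <- function(x, ...) {
  cat("<1H-1H model-free parameters>\n")
  for (nm in c("slow", "intermediate", "fast"))
    cat(sprintf("  %-12s C = %.4g rad^2 s^-2, tau = %.4g s\n",
                nm, x[[nm]]$C, x[[nm]]$tau))
  cat(sprintf("  constant     A = %.4g s^-1\n", x$A))
  invisible(x)
}

#' @export
print.hn_params <- function(x, ...) {
  cat(sprintf(
    "<1H-14N QRE parameters> C_HN = %.4g rad^2 s^-2, tau_Q = %.4g s,\n  theta = %g deg, phi = %g deg, a_Q = %.4g MHz, eta = %.3g\n",
    x$C_HN, x$tau_Q, x$theta, x$phi, x$quad$a_Q, x$quad$eta))
  invisible(x)
}
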