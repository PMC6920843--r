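#' Single-Lorentzian 1H-1H dipolar relaxation rate
#'
#' Classic homonuclear dipolar dispersion for one dynamical process:
#' \deqn{R_1^{HH}(\omega_H) = C\left[\frac{\tau}{1+\omega_H^2\tau^2}
#'   + \frac{4\tau}{1+4\omega_H^2\tau^2}\right]}
#' with `C` in rad^2 s^-2 and `tau` in s.  At zero frequency the rate is
#' \eqn{5C\tau}; it decreases monotonically with frequency.
#'
#' @param comp an [hh_component()]
#' @param omega_H 1H angular frequency in rad/s (vectorised, non-negative)
#' @return relaxation rate(s) in s^-1
#' @export
hh_component_rate <- function(comp, omega_H) {
  stopifnot(inherits(comp, "hh_component"))
  if (any(omega_H < 0)) stop("omega_H must be non-negative", call. = FALSE)
  t <- comp$tau
  w2t2 <- (omega_H * t)^2
  comp$C * (t / (1 + w2t2) + 4 * t / (1 + 4 * w2t2))
}

#' Three-component model-free 1H-1H relaxation rate
#'
#' Sum of slow, intermediate and fast Lorentzian contributions plus the
#' frequency-independent rate `A`:
#' \deqn{R_1^{HH}(\omega_H) = R_{1,s}^{HH} + R_{1,i}^{HH} + R_{1,f}^{HH} + A.}
#'
#' @param params an [hh_params()]
#' @inheritParams hh_component_rate
#' @return relaxation rate(s) in s^-1
#' @export
hh_total_rate <- function(params, omega_H) {
  stopifnot(inherits(params, "hh_params"))
  hh_component_rate(params$slow, omega_H) +
    hh_component_rate(params$intermediate, omega_H) +
    hh_component_rate(params$fast, omega_H) +
    params$A
}

#' Closed-form 1H-14N quadrupole-relaxation-enhancement rate
#'
#' The perturbation-theory expression for the 1H relaxation rate through the
#' 1H-14N dipole-dipole coupling when the 14N level structure is set by a
#' static quadrupole interaction:
#' \deqn{R_1^{HN}(\omega_H) = C_{HN}\sum_{i\in\{-,+,0\}} w_i(\Theta,\Phi)
#'  \left[\frac{\tau_Q}{1+(\omega_H-\omega_i)^2\tau_Q^2}
#'      + \frac{\tau_Q}{1+(\omega_H+\omega_i)^2\tau_Q^2}\right]}
#' with angular weights \eqn{w_- = 1/3 + \sin^2\Theta\cos^2\Phi},
#' \eqn{w_+ = 1/3 + \sin^2\Theta\sin^2\Phi},
#' \eqn{w_0 = 1/3 + \cos^2\Theta} (the weights sum to 2 for any angles) and
#' \eqn{\omega_i = 2\pi\nu_i} the 14N transition frequencies.
#'
#' The expression is valid when \eqn{\omega_Q\tau_Q \ll 1} or
#' \eqn{\omega_Q\tau_Q \gg 1} (in practice \eqn{x \le 1} or \eqn{x \ge 25}
#' with \eqn{x = 2\pi a_Q \tau_Q}); validity is *not* enforced here — use
#' [r1_hn_sle()] / [sle_validity_scan()] to judge the regime.
#'
#' @param params an [hn_params()]
#' @inheritParams hh_component_rate
#' @return relaxation rate(s) in s^-1
#' @export
hn_closed_form_rate <- function(params, omega_H) {
  stopifnot(inherits(params, "hn_params"))
  if (any(omega_H < 0)) stop("omega_H must be non-negative", call. = FALSE)
  tf <- transition_frequencies(params$quad)
  th <- params$theta * pi / 180
  ph <- params$phi * pi / 180
  w <- c(1 / 3 + sin(th)^2 * cos(ph)^2,
         1 / 3 + sin(th)^2 * sin(ph)^2,
         1 / 3 + cos(th)^2)
  om <- omega_from_MHz(c(tf$nu_minus, tf$nu_plus, tf$nu_zero))
  tq <- params$tau_Q
  out <- 0
  for (i in 1:3) {
    out <- out + w[i] * (tq / (1 + ((omega_H - om[i]) * tq)^2) +
                         tq / (1 + ((omega_H + om[i]) * tq)^2))
  }
  params$C_HN * out
}

#' Extreme-narrowing limit of the 1H-14N rate
#'
#' When \eqn{\omega_Q\tau_Q \ll 1} the quadrupole coupling averages out of
#' the 14N level structure and the closed-form rate collapses to a single
#' Lorentzian,
#' \deqn{R_1^{HN}(\omega_H) = \frac{4 C_{HN}\,\tau_Q}{1+\omega_H^2\tau_Q^2},}
#' identical to [hn_closed_form_rate()] with all three transition
#' frequencies set to zero.  No quadrupole peaks survive in this regime.
#'
#' @param C_HN dipolar relaxation constant, rad^2 s^-2
#' @param tau_Q correlation time, s
#' @inheritParams hh_component_rate
#' @return relaxation rate(s) in s^-1
#' @export
hn_extreme_narrowing_rate <- function(C_HN, tau_Q, omega_H) {
  if (any(omega_H < 0)) stop("omega_H must be non-negative", call. = FALSE)
  4 * C_HN * tau_Q / (1 + (omega_H * tau_Q)^2)
}

#' Total 1H spin-lattice relaxation rate
#'
#' Additive decomposition into the 1H-1H and 1H-14N contributions:
#' \eqn{R_1(\omega_H) = R_1^{HH}(\omega_H) + R_1^{HN}(\omega_H)}.
#'
#' @param hh an [hh_params()]
#' @param hn an [hn_params()]
#' @inheritParams hh_component_rate
#' @return relaxation rate(s) in s^-1
#' @export
total_rate <- function(hh, hn, omega_H) {
  hh_total_rate(hh, omega_H) + hn_closed_form_rate(hn, omega_H)
}
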