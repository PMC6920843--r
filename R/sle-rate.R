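#' 1H-14N relaxation rate from the stochastic Liouville equation
#'
#' Computes the 1H spin-lattice relaxation contribution of the 1H-14N
#' dipolar coupling by solving the stochastic Liouville problem for a
#' spin-1 14N nucleus with quadrupole coupling `quad` under isotropic
#' rotational diffusion, \eqn{R_1^{HN}(\omega_H) \propto
#' \mathrm{Re}\{[T_1^1]^+ [M]^{-1} [T_1^1]\}}.  Unlike the closed form
#' [hn_closed_form_rate()], the result is valid at arbitrary
#' \eqn{x = \omega_Q\tau_Q}; the closed form is trustworthy only for
#' \eqn{x \le 1} or \eqn{x \ge 25} (see [sle_validity_scan()]).
#'
#' The rate is normalized so that for \eqn{a_Q \to 0} it reduces exactly to
#' the extreme-narrowing form \eqn{4 C_{HN}\tau_Q/(1+\omega_H^2\tau_Q^2)}
#' (up to the small 14N Zeeman shifts retained by the SLE), and it is
#' strictly linear in `C_HN`.
#'
#' @param omega_H proton angular frequencies, rad/s (vectorised)
#' @param quad a [quadrupole_coupling()]
#' @param tau_Q rotational correlation time, s
#' @param C_HN 1H-14N dipolar relaxation constant, rad^2 s^-2
#' @param L_max rotational basis truncation (default 8, sufficient in the
#'   regimes of interest; convergence can be verified with
#'   `check_convergence = TRUE`)
#' @param theta,phi orientation (degrees) of the H-N axis in the EFG frame
#' @param check_convergence if `TRUE`, the rate is recomputed at
#'   `L_max + 2` for the frequency of maximum rate and an error is raised
#'   when the relative change exceeds `conv_tol`
#' @param conv_tol relative tolerance for the convergence check
#' @param constants a [physical_constants()]
#' @return relaxation rate(s) in s^-1
#' @examples
#' quad <- quadrupole_coupling(3.4, 0.4)
#' r1_hn_sle(omega_from_MHz(2.5), quad, tau_Q = 1.17e-6, C_HN = 1e8)
#' @export
r1_hn_sle <- function(omega_H, quad, tau_Q, C_HN, L_max = 8,
                      theta = 0, phi = 0, check_convergence = FALSE,
                      conv_tol = 1e-3, constants = physical_constants()) {
  rates <- .sle_profile(omega_H, quad, tau_Q, C_HN, L_max, theta, phi,
                        constants)
  if (check_convergence) {
    i <- which.max(rates)
    r2 <- .sle_profile(omega_H[i], quad, tau_Q, C_HN, L_max + 2, theta, phi,
                       constants)
    rel <- abs(r2 - rates[i]) / max(abs(r2), .Machine$double.xmin)
    if (rel > conv_tol)
      stop(sprintf(
        "SLE not converged at L_max = %d: relative change %.3g going to L_max = %d",
        L_max, rel, L_max + 2), call. = FALSE)
  }
  rates
}

.sle_profile <- function(omega_H, quad, tau_Q, C_HN, L_max, theta, phi,
                         constants) {
  parities <- if (theta == 0) 0L else c(0L, 1L)
  basis <- sle_block_basis(L_max, p = -1L, K_parities = parities)
  Mq <- .sle_quad_matrix(basis, quad)
  gamma_diag <- basis$L * (basis$L + 1) / (6 * tau_Q)
  b <- sle_t11(basis, theta, phi)
  n <- nrow(basis)
  vapply(omega_H, function(w) {
    dg <- .sle_diagonal(basis, w, tau_Q, constants)
    M <- Mq
    diag(M) <- diag(M) + dg
    y <- tryCatch(solve(M, b), error = function(e)
      stop(sprintf(
        "SLE matrix singular or ill-conditioned at omega_H = %.6g rad/s, tau_Q = %.3g s: %s",
        w, tau_Q, conditionMessage(e)), call. = FALSE))
    # spectral density Re{ b^+ [Gamma + i(L - w)]^{-1} b } = -Im{ b^+ M^{-1} b }
    -(12 / 5) * C_HN * Im(sum(Conj(b) * y))
  }, numeric(1))
}

#' Validity scan of the closed-form QRE expression against the SLE
#'
#' For each value of \eqn{x = \omega_Q\tau_Q} (with
#' \eqn{\omega_Q = 2\pi a_Q}, so \eqn{\tau_Q = x / (2\pi a_Q)}), computes
#' the 1H-14N relaxation profile with both the SLE solver and the closed
#' form, and summarises their agreement.  The expected picture: good
#' agreement for \eqn{x \le 1}, breakdown for \eqn{1 < x < 25}, recovery
#' for \eqn{x \ge 25} where the quadrupole coupling is effectively static.
#'
#' @param x_values positive products \eqn{\omega_Q\tau_Q} to scan
#' @param quad a [quadrupole_coupling()]
#' @param C_HN dipolar relaxation constant, rad^2 s^-2
#' @param nu_MHz frequency grid (MHz) over which the profiles are compared
#' @param L_max rotational basis truncation
#' @param theta,phi H-N axis orientation in the EFG frame, degrees
#' @return An object of class `sle_validity_scan`: list with `curves`
#'   (data frame: `x`, `nu_MHz`, `r1_sle`, `r1_closed`, `rel_dev`) and
#'   `summary` (data frame per x: `tau_Q`, `max_rel_dev`, `mean_rel_dev`,
#'   `peak_nu_sle`, `peak_nu_closed` — grid positions of the highest local
#'   maximum above the low-frequency plateau, `NA` when no interior peak
#'   exists).
#' @export
sle_validity_scan <- function(x_values, quad, C_HN,
                              nu_MHz = 10^seq(log10(0.01), log10(10),
                                              length.out = 60),
                              L_max = 8, theta = 0, phi = 0) {
  stopifnot(all(x_values > 0), inherits(quad, "quadrupole_coupling"))
  omega <- omega_from_MHz(nu_MHz)
  curves <- list()
  summ <- list()
  for (x in x_values) {
    tau_Q <- x / omega_from_MHz(quad$a_Q)
    r_sle <- r1_hn_sle(omega, quad, tau_Q, C_HN, L_max = L_max,
                       theta = theta, phi = phi)
    hn <- hn_params(C_HN, tau_Q, theta = theta, phi = phi, quad = quad)
    r_cf <- hn_closed_form_rate(hn, omega)
    rel <- abs(r_sle - r_cf) / r_cf
    curves[[length(curves) + 1]] <- data.frame(
      x = x, nu_MHz = nu_MHz, r1_sle = r_sle, r1_closed = r_cf,
      rel_dev = rel)
    summ[[length(summ) + 1]] <- data.frame(
      x = x, tau_Q = tau_Q,
      max_rel_dev = max(rel), mean_rel_dev = mean(rel),
      peak_nu_sle = .grid_peak(nu_MHz, r_sle),
      peak_nu_closed = .grid_peak(nu_MHz, r_cf))
  }
  structure(list(curves = do.call(rbind, curves),
                 summary = do.call(rbind, summ),
                 quad = quad, C_HN = C_HN, L_max = L_max),
            class = "sle_validity_scan")
}

# position of the largest interior local maximum, NA if the curve is
# monotone on the grid
.grid_peak <- function(nu, r) {
  n <- length(r)
  i <- which(r[2:(n - 1)] > r[1:(n - 2)] & r[2:(n - 1)] >= r[3:n]) + 1L
  if (!length(i)) return(NA_real_)
  nu[i[which.max(r[i])]]
}

#' @export
print.sle_validity_scan <- function(x, ...) {
  cat(sprintf(
    "<SLE vs closed-form validity scan>  a_Q = %.3g MHz, eta = %.3g, L_max = %d\n",
    x$quad$a_Q, x$quad$eta, x$L_max))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
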