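#' Wigner 3-j symbol for integer angular momenta
#'
#' Racah's closed form evaluated with log-factorials.  Only integer `j` are
#' needed here (rotational quantum numbers and rank-2 tensor couplings), and
#' the magnitudes stay small (j <= ~12), so double precision is ample.
#'
#' @param j1,j2,j3 integer angular momenta
#' @param m1,m2,m3 integer projections
#' @return the value of \eqn{\begin{pmatrix} j_1 & j_2 & j_3 \\ m_1 & m_2 &
#'   m_3 \end{pmatrix}}
#' @export
wigner_3j <- function(j1, j2, j3, m1, m2, m3) {
  if (m1 + m2 + m3 != 0) return(0)
  if (abs(m1) > j1 || abs(m2) > j2 || abs(m3) > j3) return(0)
  if (j3 < abs(j1 - j2) || j3 > j1 + j2) return(0)
  lf <- function(n) lgamma(n + 1)
  # triangle coefficient
  ltri <- lf(j1 + j2 - j3) + lf(j1 - j2 + j3) + lf(-j1 + j2 + j3) -
    lf(j1 + j2 + j3 + 1)
  lpre <- 0.5 * (ltri + lf(j1 + m1) + lf(j1 - m1) + lf(j2 + m2) +
                   lf(j2 - m2) + lf(j3 + m3) + lf(j3 - m3))
  tmin <- max(0, j2 - j3 - m1, j1 - j3 + m2)
  tmax <- min(j1 + j2 - j3, j1 - m1, j2 + m2)
  if (tmin > tmax) return(0)
  s <- 0
  for (t in tmin:tmax) {
    lden <- lf(t) + lf(j3 - j2 + t + m1) + lf(j3 - j1 + t - m2) +
      lf(j1 + j2 - j3 - t) + lf(j1 - m1 - t) + lf(j2 + m2 - t)
    s <- s + (-1)^t * exp(lpre - lden)
  }
  (-1)^(j1 - j2 - m3) * s
}

#' Reduced Wigner rotation matrix elements d^2_{k0}
#'
#' The k-th rank-2 spherical component acquired by a symmetric axial tensor
#' whose symmetry axis is tilted by beta: used to express the H-N dipolar
#' tensor in the EFG principal axis system.
#'
#' @param k component index, -2..2
#' @param beta tilt angle in radians
#' @return numeric value of \eqn{d^2_{k0}(\beta)}
#' @keywords internal
wigner_d2_k0 <- function(k, beta) {
  switch(as.character(k),
    "0"  = (3 * cos(beta)^2 - 1) / 2,
    "1"  = -sqrt(3 / 2) * sin(beta) * cos(beta),
    "-1" = sqrt(3 / 2) * sin(beta) * cos(beta),
    "2"  = sqrt(3 / 8) * sin(beta)^2,
    "-2" = sqrt(3 / 8) * sin(beta)^2,
    stop("k must be in -2..2"))
}
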