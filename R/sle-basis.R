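#' Liouville-space basis for the stochastic Liouville equation
#'
#' The SLE treatment of the 1H-14N relaxation contribution expands lattice
#' operators in an outer-product basis of normalized spin tensor operators
#' and Wigner rotation functions, \eqn{|\Sigma,\sigma) \otimes |L,K,M)}.
#' For a spin-1 nucleus the tensor ranks are \eqn{\Sigma \in \{1,2\}}
#' (rank 0 is the identity and does not evolve), with components
#' \eqn{\sigma = -\Sigma..\Sigma}; the rotational quantum numbers run over
#' \eqn{L = 0..L_{max}}, \eqn{K,M = -L..L}.  The basis is ordered
#' lexicographically in \eqn{(\Sigma, \sigma, L, K, M)}.
#'
#' The isotropic rotational function \eqn{L = 0} (a single state,
#' \eqn{K = M = 0}) is retained even though slow-motion treatments often
#' quote the range as starting at \eqn{L = 1}: products of rank-2 coupling
#' functions with \eqn{L = 2} basis functions have isotropic components,
#' and pure spin operators (e.g. \eqn{S_z}) live at \eqn{L = 0}.  Dropping
#' it truncates the operator algebra and visibly corrupts the slow-motion
#' (large \eqn{\omega_Q\tau_Q}) limit.
#'
#' @param L_max largest rotational rank retained; must be at least 2 to
#'   represent the rank-2 quadrupole and dipolar couplings.  `L_max = 8`
#'   is sufficient for convergence in the regimes studied here.
#' @param S spin quantum number of the quadrupolar nucleus; only `S = 1`
#'   (14N) is supported
#' @return A data frame of class `sle_basis` with integer columns `Sigma`,
#'   `sigma`, `L`, `K`, `M`, one row per basis vector.  The attribute
#'   `"n_rotational"` records the number of rotational functions
#'   \eqn{\sum_{L=1}^{L_{max}} (2L+1)^2}.
#' @examples
#' b <- sle_basis(2)
#' nrow(b)                     # 8 spin components x 34 rotational functions
#' attr(b, "n_rotational")
#' @export
sle_basis <- function(L_max, S = 1) {
  if (S != 1) stop("only S = 1 (14N) is supported", call. = FALSE)
  if (!is.numeric(L_max) || L_max < 2)
    stop("L_max must be >= 2 (rank-2 couplings cannot be represented below L = 2)",
         call. = FALSE)
  L_max <- as.integer(L_max)
  spin <- do.call(rbind, lapply(1:2, function(Sg)
    data.frame(Sigma = Sg, sigma = seq(-Sg, Sg))))
  rot <- do.call(rbind, lapply(0:L_max, function(L) {
    km <- expand.grid(M = seq(-L, L), K = seq(-L, L))
    data.frame(L = L, K = km$K, M = km$M)
  }))
  out <- merge(spin, rot, by = NULL)
  out <- out[order(out$Sigma, out$sigma, out$L, out$K, out$M), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rotational") <- sum((2 * (0:L_max) + 1)^2)
  attr(out, "L_max") <- L_max
  class(out) <- c("sle_basis", "data.frame")
  out
}

# integer key encoding one basis vector; spin_idx in 1..8, L <= 15, |K|,|M| <= 15
.sle_key <- function(spin_idx, L, K, M) {
  ((spin_idx * 16L + L) * 32L + (K + 15L)) * 32L + (M + 15L)
}

# spin component index (row of the 8-row spin table) from (Sigma, sigma)
.sle_spin_idx <- function(Sigma, sigma) {
  ifelse(Sigma == 1L, sigma + 2L, 3L + sigma + 3L)
}

#' Restriction of the SLE basis to the block coupled to the dipolar vector
#'
#' The assembled SLE matrix conserves \eqn{p = \sigma + M} (lab-frame
#' projection of the lattice operator) and the parity of \eqn{K} (the
#' quadrupole coupling connects \eqn{|K - K'| \in \{0, 2\}}).  The dipolar
#' source vector lives entirely in \eqn{p = -1}; when the H-N axis is along
#' the EFG z axis (theta = 0) it touches only even `K`.  Solving on this
#' block is exactly equivalent to solving on the full basis.
#'
#' @inheritParams sle_basis
#' @param p conserved projection (default -1, the spin-lattice block)
#' @param K_parities integer vector of K parities (0 = even, 1 = odd) to keep
#' @return an `sle_basis` data frame restricted to the block
#' @export
sle_block_basis <- function(L_max, p = -1L, K_parities = c(0L, 1L)) {
  b <- sle_basis(L_max)
  keep <- (b$sigma + b$M) == p & (abs(b$K) %% 2L) %in% K_parities
  out <- b[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rotational") <- attr(b, "n_rotational")
  attr(out, "L_max") <- L_max
  class(out) <- c("sle_basis", "data.frame")
  out
}
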