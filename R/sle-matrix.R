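# Spin-space algebra for S = 1 and assembly of the SLE matrix.
#
# The lattice seen by the proton is the 14N spin (quadrupole + Zeeman)
# coupled to isotropic rotational diffusion.  Operators are expanded in
# normalized spin tensors T^Sigma_sigma (Hilbert-Schmidt orthonormal) times
# normalized Wigner functions |L,K,M).  All spin-space matrix elements are
# computed numerically from the 3x3 operator representations; the
# rotational integrals reduce to products of two Wigner 3-j symbols.

# 3x3 spin-1 operator matrices in the basis |+1>, |0>, |-1>
.spin1_ops <- function() {
  Sz <- diag(c(1, 0, -1))
  Sp <- matrix(0, 3, 3); Sp[1, 2] <- Sp[2, 3] <- sqrt(2)
  Sm <- t(Sp)
  list(Sz = Sz, Sp = Sp, Sm = Sm, Id = diag(3))
}

# normalized spherical tensor operators for S = 1, ranks 1 and 2.
# Rows of the spin table: (1,-1),(1,0),(1,1),(2,-2),...,(2,2).
# For S = 1 the physical rank-2 tensors used in the quadrupole Hamiltonian
# coincide with the normalized ones.
.spin1_tensors <- function() {
  op <- .spin1_ops()
  T1 <- list(`-1` = op$Sm / 2, `0` = op$Sz / sqrt(2), `1` = -op$Sp / 2)
  T2 <- list(
    `-2` = op$Sm %*% op$Sm / 2,
    `-1` = (op$Sz %*% op$Sm + op$Sm %*% op$Sz) / 2,
    `0`  = (3 * op$Sz %*% op$Sz - 2 * op$Id) / sqrt(6),
    `1`  = -(op$Sz %*% op$Sp + op$Sp %*% op$Sz) / 2,
    `2`  = op$Sp %*% op$Sp / 2
  )
  tensors <- c(T1[c("-1", "0", "1")], T2[c("-2", "-1", "0", "1", "2")])
  tab <- data.frame(Sigma = c(1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L),
                    sigma = c(-1L, 0L, 1L, -2L, -1L, 0L, 1L, 2L))
  list(tensors = tensors, table = tab, T2 = T2)
}

# Q[m+3, j, i] = Tr( T_i^dagger [T^2_m, T_j] ) over the 8 spin components;
# real for the operator set above.  Computed once per session.
.spin1_commutator_table <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    st <- .spin1_tensors()
    Q <- array(0, dim = c(5, 8, 8))
    for (mi in 1:5) {
      T2m <- st$T2[[mi]]          # m = mi - 3
      for (j in 1:8) {
        comm <- T2m %*% st$tensors[[j]] - st$tensors[[j]] %*% T2m
        for (i in 1:8) {
          v <- sum(Conj(t(st$tensors[[i]])) * t(comm))  # Tr(Ti^dag comm)
          Q[mi, j, i] <- Re(v)
        }
      }
    }
    cache <<- Q
    Q
  }
})

# memoized scalar Wigner 3-j
.w3j_cached <- local({
  env <- new.env(parent = emptyenv())
  function(j1, j2, j3, m1, m2, m3) {
    key <- paste(j1, j2, j3, m1, m2, m3)
    v <- env[[key]]
    if (is.null(v)) {
      v <- wigner_3j(j1, j2, j3, m1, m2, m3)
      env[[key]] <- v
    }
    v
  }
})

#' Assemble the SLE matrix over a basis
#'
#' Builds the matrix \eqn{[M]} of the stochastic Liouville problem for a
#' spin-1 nucleus with quadrupole coupling `quad` undergoing isotropic
#' rotational diffusion with correlation time `tau_Q`, evaluated at proton
#' angular frequency `omega_H`.  Matrix elements follow the selection rules
#' \eqn{\delta_{K'K\pm\{0,2\}}}, \eqn{\delta_{M'M+m}},
#' \eqn{\sigma' = \sigma + m}, with the rank-2 EFG components
#' \eqn{F_0 \propto \sqrt6}, \eqn{F_{\pm1} = 0}, \eqn{F_{\pm2} \propto \eta}
#' and rotational integrals given by products of two 3-j symbols.  The
#' diagonal carries the 14N precession \eqn{\sigma\omega_N} (with
#' \eqn{\omega_N = \omega_H \gamma_N/\gamma_H}), the offset \eqn{-\omega_H}
#' at which the spectral density is evaluated, and the imaginary rotational
#' damping \eqn{i\,L(L+1)/(6\tau_Q)}.
#'
#' The quadrupole part is real and symmetric; the imaginary part of the
#' assembled matrix is confined to the diagonal.
#'
#' @param basis an [sle_basis()] or [sle_block_basis()]
#' @param omega_H proton angular frequency, rad/s (scalar)
#' @param quad a [quadrupole_coupling()]
#' @param tau_Q rotational correlation time, s
#' @param constants a [physical_constants()]
#' @return a complex matrix over the basis
#' @export
sle_matrix <- function(basis, omega_H, quad, tau_Q,
                       constants = physical_constants()) {
  stopifnot(inherits(basis, "sle_basis"), inherits(quad, "quadrupole_coupling"),
            tau_Q > 0, omega_H >= 0)
  Mq <- .sle_quad_matrix(basis, quad)
  diag(Mq) <- diag(Mq) + .sle_diagonal(basis, omega_H, tau_Q, constants)
  Mq
}

# real symmetric quadrupole superoperator over the basis (rad/s)
.sle_quad_matrix <- function(basis, quad) {
  n <- nrow(basis)
  Q <- .spin1_commutator_table()
  st <- .spin1_tensors()
  spin_idx <- .sle_spin_idx(basis$Sigma, basis$sigma)
  ord_keys <- .sle_key(spin_idx, basis$L, basis$K, basis$M)
  wQ <- omega_from_MHz(quad$a_Q)          # 2 pi a_Q, rad/s
  V <- c(`-2` = wQ / 4 * quad$eta, `0` = wQ / 4 * sqrt(6),
         `2` = wQ / 4 * quad$eta)
  out <- matrix(0 + 0i, n, n)
  Lb <- basis$L; Kb <- basis$K; Mb <- basis$M
  L_max <- attr(basis, "L_max")
  if (is.null(L_max)) L_max <- max(Lb)
  for (k in c(-2L, 0L, 2L)) {
    Vk <- V[[as.character(k)]]
    if (Vk == 0) next
    for (m in -2L:2L) {
      # spin pairs with nonzero commutator element for this m
      for (j_sp in 1:8) {
        qcol <- Q[m + 3L, j_sp, ]
        nz <- which(abs(qcol) > 1e-14)
        if (!length(nz)) next
        rows_j <- which(spin_idx == j_sp)
        if (!length(rows_j)) next
        K2 <- Kb[rows_j] + k
        M2 <- Mb[rows_j] - m
        for (i_sp in nz) {
          qv <- qcol[i_sp]
          for (dL in -2L:2L) {
            L2 <- Lb[rows_j] + dL
            ok <- L2 >= 0L & L2 <= L_max & abs(K2) <= L2 & abs(M2) <= L2
            if (!any(ok)) next
            jj <- rows_j[ok]
            tk <- .sle_key(i_sp, L2[ok], K2[ok], M2[ok])
            ii <- match(tk, ord_keys)
            sel <- !is.na(ii)
            if (!any(sel)) next
            jj <- jj[sel]; ii <- ii[sel]
            L1v <- Lb[jj]; L2v <- Lb[ii]
            w <- vapply(seq_along(jj), function(t) {
              .w3j_cached(L2v[t], 2L, L1v[t], -Kb[ii[t]], k, Kb[jj[t]]) *
                .w3j_cached(L2v[t], 2L, L1v[t], -Mb[ii[t]], -m, Mb[jj[t]])
            }, numeric(1))
            val <- (-1)^m * Vk * sqrt((2 * L1v + 1) * (2 * L2v + 1)) *
              (-1)^(Kb[ii] - Mb[ii]) * w * qv
            out[cbind(ii, jj)] <- out[cbind(ii, jj)] + val
          }
        }
      }
    }
  }
  out
}

# diagonal terms: sigma*omega_N - omega_H + i L(L+1)/(6 tau_Q)
.sle_diagonal <- function(basis, omega_H, tau_Q, constants) {
  omega_N <- omega_H * constants$gamma_N / constants$gamma_H
  basis$sigma * omega_N - omega_H +
    1i * basis$L * (basis$L + 1) / (6 * tau_Q)
}

#' Representation of the dipolar source vector in the SLE basis
#'
#' The proton-flip part of the 1H-14N dipolar Hamiltonian projects onto the
#' rank-1 spin tensors combined with L = 2, K = mu rotational functions,
#' where the K-components are weighted by the orientation
#' \eqn{A_\mu = d^2_{\mu 0}(\Theta) e^{-i\mu\Phi}} of the H-N axis in the
#' EFG frame.  For theta = 0 the vector has exactly three non-zero entries,
#' on \eqn{(\Sigma,\sigma;L,K,M) = (1,-1;2,0,0)}, \eqn{(1,0;2,0,-1)} and
#' \eqn{(1,1;2,0,-2)}, with squared weights in the ratio 1 : 3 : 6 (the
#' familiar heteronuclear dipolar spectral-density weights).
#'
#' @inheritParams sle_matrix
#' @param theta,phi orientation of the H-N axis in the EFG principal axis
#'   system, degrees
#' @return a complex vector over the basis
#' @export
sle_t11 <- function(basis, theta = 0, phi = 0) {
  stopifnot(inherits(basis, "sle_basis"))
  th <- theta * pi / 180
  ph <- phi * pi / 180
  spin_idx <- .sle_spin_idx(basis$Sigma, basis$sigma)
  keys <- .sle_key(spin_idx, basis$L, basis$K, basis$M)
  b <- complex(length.out = nrow(basis))
  # (spin component, M, coefficient of A_mu)
  comp <- list(list(sp = .sle_spin_idx(1L, -1L), M = 0L,  c = -1 / sqrt(6)),
               list(sp = .sle_spin_idx(1L, 0L),  M = -1L, c = 1 / sqrt(2)),
               list(sp = .sle_spin_idx(1L, 1L),  M = -2L, c = -1))
  for (mu in -2L:2L) {
    A <- wigner_d2_k0(mu, th) * exp(-1i * mu * ph)
    if (abs(A) < 1e-15) next
    for (cc in comp) {
      pos <- match(.sle_key(cc$sp, 2L, mu, cc$M), keys)
      if (!is.na(pos)) b[pos] <- b[pos] + cc$c * A
    }
  }
  b
}
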