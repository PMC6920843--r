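test_that("basis enumeration matches the truncation scheme", {
  b <- sle_basis(2)
  # 8 spin components (ranks 1 and 2 of a spin-1) per rotational function;
  # rotational functions with L >= 1 number sum_{L=1..Lmax} (2L+1)^2,
  # plus the single isotropic L = 0 function
  one_spin <- b[b$Sigma == 1 & b$sigma == 0, ]
  expect_identical(sum(one_spin$L >= 1), 9L + 25L)        # 34
  expect_identical(nrow(one_spin), 35L)
  expect_identical(nrow(b), 8L * 35L)

  b8 <- sle_basis(8)
  one_spin8 <- b8[b8$Sigma == 2 & b8$sigma == -2, ]
  expect_identical(sum(one_spin8$L >= 1), 968L)   # sum_{L=1..8} (2L+1)^2
  expect_error(sle_basis(1), "L_max")
  expect_error(sle_basis(4, S = 3 / 2), "S = 1")
})

test_that("basis index keys are unique and round-trip", {
  b <- sle_basis(4)
  keys <- nmrdfit:::.sle_key(nmrdfit:::.sle_spin_idx(b$Sigma, b$sigma),
                             b$L, b$K, b$M)
  expect_false(any(duplicated(keys)))
  expect_identical(match(keys, keys), seq_len(nrow(b)))
})

test_that("assembled matrix respects the printed selection rules", {
  b <- sle_block_basis(3, K_parities = 0L)
  M <- sle_matrix(b, omega_H = omega_from_MHz(1), quad_fig1(),
                  tau_Q = 1e-7)
  # quadrupole part: real symmetric off-diagonal; damping/precession on
  # the diagonal only
  off <- M; diag(off) <- 0
  expect_lt(max(abs(Im(off))), 1e-9 * max(abs(off)))
  expect_lt(max(abs(off - t(off))), 1e-6 * max(abs(off)))
  # rotational damping on the diagonal: strictly positive except for the
  # undamped isotropic L = 0 state
  expect_true(all(Im(diag(M))[b$L >= 1] > 0))
  expect_true(all(Im(diag(M)) >= 0))
  # |K - K'| in {0, 2} and delta(sigma', sigma + m) with |m| <= 2
  nz <- which(abs(M) > 1e-9 * max(abs(M)), arr.ind = TRUE)
  dK <- abs(b$K[nz[, 1]] - b$K[nz[, 2]])
  expect_true(all(dK %in% c(0, 2)))
  dSig <- abs(b$sigma[nz[, 1]] - b$sigma[nz[, 2]])
  expect_true(all(dSig <= 2))
  # rank parity: quadrupole couples Sigma to Sigma +- 1 only
  offnz <- nz[nz[, 1] != nz[, 2], , drop = FALSE]
  expect_true(all(abs(b$Sigma[offnz[, 1]] - b$Sigma[offnz[, 2]]) == 1))
})

test_that("eta = 0 removes all |K-K'| = 2 couplings", {
  b <- sle_block_basis(3, K_parities = 0L)
  M <- sle_matrix(b, 0, quadrupole_coupling(3.4, 0), tau_Q = 1e-7)
  nz <- which(abs(M) > 1e-9 * max(abs(M)), arr.ind = TRUE)
  expect_true(all(b$K[nz[, 1]] == b$K[nz[, 2]]))
})

test_that("T11 vector has the three canonical entries at theta = 0", {
  b <- sle_block_basis(4, K_parities = 0L)
  v <- sle_t11(b)
  nz <- which(abs(v) > 1e-14)
  expect_length(nz, 3)
  sub <- b[nz, ]
  expect_true(all(sub$Sigma == 1 & sub$L == 2 & sub$K == 0))
  expect_setequal(paste(sub$sigma, sub$M), c("-1 0", "0 -1", "1 -2"))
  # squared weights in the heteronuclear dipolar ratio 1:3:6
  w2 <- sort(abs(v[nz])^2)
  expect_equal(w2 / w2[1], c(1, 3, 6), tolerance = 1e-12)
})

test_that("a_Q -> 0 reduces the SLE to the extreme-narrowing form", {
  quad0 <- quadrupole_coupling(1e-10, 0.4)
  tau <- 2e-7; C <- 5e7
  om <- omega_from_MHz(c(0.01, 0.3, 2, 8))
  # with the 14N Zeeman precession disabled the reduction is exact
  pc <- physical_constants(); pc$gamma_N <- pc$gamma_N * 1e-8
  r <- r1_hn_sle(om, quad0, tau, C, L_max = 4, constants = pc)
  expect_equal(r, hn_extreme_narrowing_rate(C, tau, om), tolerance = 1e-6)
  # with the physical gamma_N the deviation is the Zeeman shift of the
  # sideband Lorentzians, bounded by ~(1 +- gamma_N/gamma_H)^2 - 1 at
  # large omega*tau
  r2 <- r1_hn_sle(om, quad0, tau, C, L_max = 4)
  expect_lt(max(abs(r2 - hn_extreme_narrowing_rate(C, tau, om)) /
                  hn_extreme_narrowing_rate(C, tau, om)), 0.1)
})

test_that("SLE rate is strictly linear in C_HN and real non-negative", {
  om <- omega_from_MHz(c(0.05, 0.7, 2.2, 6))
  r1 <- r1_hn_sle(om, quad_fig1(), 1e-7, 1e8, L_max = 4)
  r2 <- r1_hn_sle(om, quad_fig1(), 1e-7, 2e8, L_max = 4)
  expect_equal(r2, 2 * r1, tolerance = 1e-12)
  expect_true(all(r1 >= 0))
})

test_that("block solve equals full-basis solve", {
  # the p = sigma + M and K-parity selection rules make the T11 block
  # exactly invariant: solving on it must reproduce the full solve
  quad <- quad_fig1()
  tau <- 2e-7
  om <- omega_from_MHz(1.3)
  full <- sle_basis(3)
  Mf <- sle_matrix(full, om, quad, tau)
  bf <- sle_t11(full)
  yf <- solve(Mf, bf)
  r_full <- -(12 / 5) * 1e8 * Im(sum(Conj(bf) * yf))
  r_block <- r1_hn_sle(om, quad, tau, 1e8, L_max = 3)
  expect_equal(r_block, r_full, tolerance = 1e-10)
})

test_that("L_max truncation is converged at 8", {
  # relative change below 0.1% from L_max = 8 to 10 at the x = 1 and
  # x = 25 regimes (worst case: peak frequencies)
  quad <- quad_fig1()
  om <- omega_from_MHz(c(0.05, 0.68, 2.21, 2.89))
  for (x in c(1, 25)) {
    tau <- x / omega_from_MHz(quad$a_Q)
    r8 <- r1_hn_sle(om, quad, tau, 1e8, L_max = 8)
    r10 <- r1_hn_sle(om, quad, tau, 1e8, L_max = 10)
    expect_lt(max(abs(r10 - r8) / r10), 1e-3)
  }
  # the built-in convergence check passes quietly at L_max = 8
  expect_silent(r1_hn_sle(omega_from_MHz(2.21), quad,
                          25 / omega_from_MHz(quad$a_Q), 1e8,
                          L_max = 8, check_convergence = TRUE))
})

test_that("validity scan reproduces the good/bad/good agreement story", {
  nu <- 10^seq(log10(0.05), 1, length.out = 20)
  scan <- sle_validity_scan(c(0.2, 4, 25), quad_fig1(), 1e8,
                            nu_MHz = nu, L_max = 6)
  s <- scan$summary
  expect_equal(s$tau_Q[1], 0.2 / omega_from_MHz(3.4), tolerance = 1e-12)
  # breakdown region deviates far more than the fast-motion edge
  expect_gt(s$max_rel_dev[s$x == 4], 2 * s$max_rel_dev[s$x == 0.2])
  # recovery at x = 25: at the dominant nu0 peak the closed form is an
  # order of magnitude closer than in the breakdown region
  quad <- quad_fig1()
  om0 <- omega_from_MHz(0.68)
  dev_at <- vapply(c(4, 25), function(x) {
    tau <- x / omega_from_MHz(quad$a_Q)
    r <- r1_hn_sle(om0, quad, tau, 1e8, L_max = 6)
    cf <- hn_closed_form_rate(hn_params(1e8, tau, 0, 0, quad), om0)
    abs(r - cf) / cf
  }, numeric(1))
  expect_lt(dev_at[2], 0.02)
  expect_gt(dev_at[1], 2 * dev_at[2])
  expect_identical(nrow(scan$curves), length(nu) * 3L)
})
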