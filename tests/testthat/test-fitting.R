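test_that("noiseless recovery on all four reference parameter sets", {
  fx <- table1_fixtures()
  for (nm in names(fx)) {
    prof <- simulate_profile(fx[[nm]], generator_config())
    fit <- fit_profile(prof)
    errs <- recovery_errors(fit, fx[[nm]])
    bound <- pmax(printed_uncertainty(nm)[names(errs)], 0.05)
    expect_true(all(abs(errs) < bound),
                info = sprintf("%s: worst %s = %.4f", nm,
                               names(errs)[which.max(abs(errs))],
                               max(abs(errs))))
    # fixed quadrupole parameters from the peaks, within 1%
    expect_equal(fit$fixed$a_Q, fx[[nm]]$hn$quad$a_Q, tolerance = 0.01)
    expect_equal(fit$fixed$eta, fx[[nm]]$hn$quad$eta, tolerance = 0.02)
    expect_true(fit$converged)
  }
})

test_that("fit objective is monotone non-increasing across iterations", {
  fx <- table1_fixtures()$elastin
  prof <- simulate_profile(fx, generator_config(noise_cv = 0.02, seed = 11))
  fit <- fit_profile(prof)
  expect_true(all(diff(fit$objective_trace) <= 1e-12))
})

test_that("correlation-time labels come out ordered", {
  fx <- table1_fixtures()$BSA
  prof <- simulate_profile(fx, generator_config(noise_cv = 0.02, seed = 3))
  fit <- fit_profile(prof)
  expect_gt(fit$hh$slow$tau, fit$hh$intermediate$tau)
  expect_gt(fit$hh$intermediate$tau, fit$hh$fast$tau)
})

test_that("tau_Q stays inside its +-10% trust region", {
  fx <- table1_fixtures()$AHP
  prof <- simulate_profile(fx, generator_config(noise_cv = 0.02, seed = 5))
  fit <- suppressWarnings(fit_profile(prof))
  expect_lt(abs(fit$hn$tau_Q / fit$tau_Q_init - 1), 0.10 + 1e-9)
})

test_that("a pure-constant profile fits to A with negligible amplitudes", {
  # flat profile: only the frequency-independent term survives
  nu <- 10^seq(-2, log10(40), length.out = 40)
  prof <- relaxation_profile(nu, rep(2.36, length(nu)))
  cfg <- list(quad = quad_lysozyme(), tau_Q_init = 8.91e-7)
  fit <- suppressWarnings(fit_profile(prof, cfg))
  expect_equal(fit$hh$A, 2.36, tolerance = 1e-3)
  model0 <- decompose(fit, nu)
  expect_lt(max(model0$R1_slow + model0$R1_intermediate + model0$R1_fast +
                  model0$R1_HN), 0.01 * 2.36)
})

test_that("noisy recovery stays within 3x the printed uncertainties (median over seeds)", {
  fx <- table1_fixtures()
  for (nm in c("elastin", "lysozyme")) {
    unc <- pmax(printed_uncertainty(nm), 0.05)
    errs <- sapply(1:10, function(s) {
      prof <- simulate_profile(fx[[nm]],
                               generator_config(noise_cv = 0.02, seed = s))
      fit <- suppressWarnings(fit_profile(prof))
      abs(recovery_errors(fit, fx[[nm]]))
    })
    med <- apply(errs, 1, stats::median)
    expect_true(all(med < 3 * unc[names(med)]),
                info = sprintf("%s: worst %s = %.4f", nm,
                               names(med)[which.max(med / (3 * unc[names(med)]))],
                               max(med)))
  }
})

test_that("decomposition sums exactly to the total model", {
  fx <- table1_fixtures()$lysozyme
  prof <- simulate_profile(fx, generator_config())
  fit <- fit_profile(prof)
  nu <- 10^seq(-2, log10(40), length.out = 73)
  d <- decompose(fit, nu)
  expect_equal(d$total,
               d$R1_slow + d$R1_intermediate + d$R1_fast + d$A + d$R1_HN,
               tolerance = 1e-12)
  expect_equal(d$total, total_rate(fit$hh, fit$hn, omega_from_MHz(nu)),
               tolerance = 1e-12)
  # at 40 MHz the fast component dominates the slow one for every protein
  for (p in table1_fixtures()) {
    d40 <- decompose(p, 40)
    expect_gt(d40$R1_fast, d40$R1_slow)
  }
  # HN maxima confined to the quadrupole window
  dd <- decompose(fx, 10^seq(-2, log10(40), length.out = 400))
  imax <- which.max(dd$R1_HN)
  expect_true(dd$nu_MHz[imax] > 0.5 && dd$nu_MHz[imax] < 3.5)
})
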