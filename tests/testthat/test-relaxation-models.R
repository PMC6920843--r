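test_that("single-Lorentzian HH rate matches closed-form values and limits", {
  # zero-frequency limit 5*C*tau with the elastin fast component
  comp <- hh_component(4.21e8, 1.31e-8)
  expect_equal(hh_component_rate(comp, 0), 5 * 4.21e8 * 1.31e-8,
               tolerance = 1e-12)
  # unit evaluation of the formula
  expect_equal(hh_component_rate(hh_component(1, 1), 1), 0.5 + 0.8,
               tolerance = 1e-12)
  # vanishes at large frequency, monotone non-increasing
  om <- omega_from_MHz(10^seq(-2, 4, length.out = 80))
  r <- hh_component_rate(comp, om)
  expect_true(all(diff(r) <= 1e-12))
  expect_lt(r[length(r)], 1e-4 * r[1])
  expect_error(hh_component_rate(comp, -1), "non-negative")
})

test_that("model-free sum equals its components plus the constant", {
  fx <- table1_fixtures()$elastin
  om <- omega_from_MHz(c(0.01, 0.1, 1, 10, 40))
  expect_equal(
    hh_total_rate(fx$hh, om),
    hh_component_rate(fx$hh$slow, om) +
      hh_component_rate(fx$hh$intermediate, om) +
      hh_component_rate(fx$hh$fast, om) + fx$hh$A,
    tolerance = 1e-12)
  # high-frequency limit -> A (Table value 6.47 for elastin)
  expect_equal(hh_total_rate(fx$hh, omega_from_MHz(1e7)), 6.47,
               tolerance = 1e-4)
  # zero-frequency limit: 5 * sum(C tau) + A
  expect_equal(hh_total_rate(fx$hh, 0),
               5 * (7.85e7 * 2.55e-6 + 2.84e8 * 1.43e-7 + 4.21e8 * 1.31e-8) +
                 6.47, tolerance = 1e-12)
})

test_that("QRE angular weights always sum to two", {
  # the three weights (1/3+sin2Tcos2P, 1/3+sin2Tsin2P, 1/3+cos2T)
  set.seed(3)
  for (i in 1:100) {
    th <- runif(1, 0, 180) * pi / 180
    ph <- runif(1, 0, 360) * pi / 180
    w <- c(1 / 3 + sin(th)^2 * cos(ph)^2,
           1 / 3 + sin(th)^2 * sin(ph)^2,
           1 / 3 + cos(th)^2)
    expect_equal(sum(w), 2, tolerance = 1e-12)
  }
})

test_that("closed-form QRE rate: limits, positivity and peak positions", {
  # all transitions at zero, theta = phi = 0, omega_H = 0: rate = 4 C tau
  hn0 <- hn_params(2, 3, 0, 0, quadrupole_coupling(1e-12, 0))
  expect_equal(hn_closed_form_rate(hn0, 0), 4 * 2 * 3, tolerance = 1e-6)

  # lysozyme parameters: the two main local maxima sit at nu-/nu+
  fx <- table1_fixtures()$lysozyme
  nu <- seq(1.5, 3.5, by = 2e-4)
  r <- hn_closed_form_rate(fx$hn, omega_from_MHz(nu))
  expect_true(all(r > 0))
  n <- length(r)
  pk <- which(r[2:(n - 1)] > r[1:(n - 2)] & r[2:(n - 1)] >= r[3:n]) + 1L
  pk <- pk[order(-r[pk])][1:2]
  tf <- transition_frequencies(fx$hn$quad)
  expect_equal(sort(nu[pk]), c(tf$nu_minus, tf$nu_plus), tolerance = 5e-3)
  # peak-height asymmetry controlled by Phi = 33 deg: nu- peak higher
  expect_gt(r[which.min(abs(nu - tf$nu_minus))],
            r[which.min(abs(nu - tf$nu_plus))])
})

test_that("extreme-narrowing form is the zero-transition limit of Eq QRE", {
  set.seed(4)
  quad0 <- quadrupole_coupling(1e-14, 0)   # transitions ~ 0
  for (i in 1:100) {
    C <- 10^runif(1, 6, 9); tq <- 10^runif(1, -9, -5)
    om <- omega_from_MHz(10^runif(1, -2, 2))
    hn <- hn_params(C, tq, runif(1, 0, 180), runif(1, 0, 360), quad0)
    expect_equal(hn_closed_form_rate(hn, om),
                 hn_extreme_narrowing_rate(C, tq, om),
                 tolerance = 1e-9)
  }
  expect_equal(hn_extreme_narrowing_rate(1, 1, 0), 4)
  expect_equal(hn_extreme_narrowing_rate(1, 1, 1), 2)
})

test_that("total rate decomposes additively", {
  fx <- table1_fixtures()$elastin
  om <- omega_from_MHz(10^seq(-2, log10(40), length.out = 30))
  expect_equal(total_rate(fx$hh, fx$hn, om),
               hh_total_rate(fx$hh, om) + hn_closed_form_rate(fx$hn, om),
               tolerance = 1e-12)
  # C_HN = 0 removes the HN contribution
  hn0 <- hn_params(0, fx$hn$tau_Q, fx$hn$theta, fx$hn$phi, fx$hn$quad)
  expect_equal(total_rate(fx$hh, hn0, om), hh_total_rate(fx$hh, om))
  # at 40 MHz the rate is dominated by the fast component plus A
  om40 <- omega_from_MHz(40)
  parts <- c(slow = hh_component_rate(fx$hh$slow, om40),
             fast = hh_component_rate(fx$hh$fast, om40))
  expect_gt(parts["fast"], parts["slow"])
})

test_that("dipolar constant <-> distance conversions reproduce printed values", {
  # Table-derived H-N distances, 3 significant figures
  expect_equal(signif(hn_distance_from_constant(1.01e8), 3), 1.64)
  expect_equal(signif(hn_distance_from_constant(7.81e7), 3), 1.71)
  expect_equal(signif(hn_distance_from_constant(1.93e8), 3), 1.47)
  # inverses: the r^-6 dependence amplifies the 3-significant-figure
  # rounding of the printed distances by a factor ~6, hence the 2% band
  expect_equal(hn_constant_from_distance(1.64), 1.01e8, tolerance = 0.02)
  expect_equal(hn_constant_from_distance(1.71), 7.81e7, tolerance = 0.02)
})

test_that("constant-distance round trips and r^-6 scaling", {
  set.seed(5)
  r <- 10^runif(20, -0.3, 1)
  expect_equal(hn_distance_from_constant(hn_constant_from_distance(r)), r,
               tolerance = 1e-12)
  expect_equal(hn_constant_from_distance(r / 2) / hn_constant_from_distance(r),
               rep(64, 20), tolerance = 1e-12)
  expect_equal(hh_constant_from_distance(r / 2) / hh_constant_from_distance(r),
               rep(64, 20), tolerance = 1e-12)
  expect_error(hn_distance_from_constant(-1), "positive")
})
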