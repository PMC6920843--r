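# shared fixtures for the test suite

quad_lysozyme <- function() quadrupole_coupling(3.36, 0.42)
quad_elastin  <- function() quadrupole_coupling(3.38, 0.39)
quad_fig1     <- function() quadrupole_coupling(3.4, 0.4)

# printed relative uncertainties of the correlation times (fractions);
# dipolar constants carry 5-8% (we use the upper 8%), parameters without a
# stated uncertainty get 5%
printed_uncertainty <- function(protein) {
  tau_unc <- list(
    elastin  = c(tau_s = 0.02, tau_i = 0.05, tau_f = 0.12, tau_Q = 0.08),
    AHP      = c(tau_s = 0.08, tau_i = 0.09, tau_f = 0.11, tau_Q = 0.12),
    BSA      = c(tau_s = 0.02, tau_i = 0.03, tau_f = 0.05, tau_Q = 0.07),
    lysozyme = c(tau_s = 0.07, tau_i = 0.05, tau_f = 0.07, tau_Q = 0.08))
  c(tau_unc[[protein]],
    C_s = 0.08, C_i = 0.08, C_f = 0.08, C_HN = 0.08,
    A = 0.05, theta = 0.05, phi = 0.05)
}

# all relative recovery errors of a fit against a truth fixture
recovery_errors <- function(fit, truth) {
  c(C_s = fit$hh$slow$C / truth$hh$slow$C - 1,
    tau_s = fit$hh$slow$tau / truth$hh$slow$tau - 1,
    C_i = fit$hh$intermediate$C / truth$hh$intermediate$C - 1,
    tau_i = fit$hh$intermediate$tau / truth$hh$intermediate$tau - 1,
    C_f = fit$hh$fast$C / truth$hh$fast$C - 1,
    tau_f = fit$hh$fast$tau / truth$hh$fast$tau - 1,
    A = fit$hh$A / truth$hh$A - 1,
    C_HN = fit$hn$C_HN / truth$hn$C_HN - 1,
    tau_Q = fit$hn$tau_Q / truth$hn$tau_Q - 1,
    theta = fit$hn$theta / truth$hn$theta - 1,
    phi = fit$hn$phi / truth$hn$phi - 1)
}
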