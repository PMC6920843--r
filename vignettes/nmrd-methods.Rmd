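---
title: "Models and methods: solid-protein NMRD profiles with quadrupole relaxation enhancement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrdfit)
```

## The model

`nmrdfit` analyses ${}^1$H spin–lattice relaxation dispersion (NMRD)
profiles of solid proteins measured by fast-field-cycling relaxometry,
typically spanning 10 kHz–40 MHz in ${}^1$H Larmor frequency. The total
rate is an additive two-channel model,

$$R_1(\omega_H) = R_1^{HH}(\omega_H) + R_1^{HN}(\omega_H),$$

with all dipolar relaxation constants in squared angular frequency units
(rad$^2$s$^{-2}$) and $\omega_H = 2\pi\nu_H$.

**${}^1$H–${}^1$H channel (model-free decomposition).** Three dynamical
processes on well-separated time scales, each contributing a classic
dipolar Lorentzian pair, plus a frequency-independent rate:

$$R_1^{HH}(\omega) = \sum_{k \in \{s,i,f\}} C_k\!\left[
\frac{\tau_k}{1+\omega^2\tau_k^2} + \frac{4\tau_k}{1+4\omega^2\tau_k^2}
\right] + A.$$

The labels are ordered ($\tau_s > \tau_i > \tau_f$; in solid proteins
they fall near $10^{-6}$, $10^{-7}$ and $10^{-8}$ s). $A$ absorbs
dynamics faster than $\sim$1 ns, which are frequency-independent over
the accessible window. No specific motional mechanism is implied — the
decomposition is "model-free".

**${}^1$H–${}^{14}$N channel (quadrupole relaxation enhancement).** When
the ${}^{14}$N (spin 1) level structure is dominated by its quadrupole
coupling $(a_Q, \eta)$, the levels are $E_1 = \tfrac14 a_Q(1-\eta)$,
$E_2 = -\tfrac12 a_Q$, $E_3 = \tfrac14 a_Q(1+\eta)$ and protons relax
efficiently whenever $\omega_H$ matches one of the transition
frequencies $\nu_\mp = \tfrac34 a_Q(1 \mp \eta/3)$,
$\nu_0 = \tfrac12\eta a_Q$ — the *quadrupole peaks*. The closed form
implemented in `hn_closed_form_rate()` attaches to each transition a
Lorentzian pair of width $1/\tau_Q$ and an angular weight
($\tfrac13+\sin^2\Theta\cos^2\Phi$, $\tfrac13+\sin^2\Theta\sin^2\Phi$,
$\tfrac13+\cos^2\Theta$ for $\nu_-,\nu_+,\nu_0$; the weights always sum
to 2), where $(\Theta,\Phi)$ orient the H–N axis in the EFG principal
frame. In the fast-motion limit $\omega_Q\tau_Q \ll 1$
($\omega_Q = 2\pi a_Q$) the expression collapses to
$4C_{HN}\tau_Q/(1+\omega_H^2\tau_Q^2)$ and the peaks disappear
(`hn_extreme_narrowing_rate()`).

Dipolar constants encode effective inter-spin distances,
$C_{HN} = \tfrac23\left((\mu_0/4\pi)\gamma_H\gamma_N\hbar/r_{HN}^3\right)^2$;
`hn_distance_from_constant()` inverts this. Although fitted constants
are conventionally tabulated as "Hz$^2$", only the rad$^2$s$^{-2}$
reading reproduces physically sensible sub-2-Å amide H–N distances, so
that is the package-wide convention, stated in every output file.

## The stochastic Liouville solver

The closed form treats the ${}^{14}$N level structure as static; it is
trustworthy only when $x = \omega_Q\tau_Q$ is either small ($\lesssim 1$)
or large ($\gtrsim 25$). In between, `r1_hn_sle()` solves the coupled
spin–rotation problem exactly: the lattice is the ${}^{14}$N spin
(quadrupole coupling fixed in the molecular frame + Zeeman term
$\omega_N = \omega_H\gamma_N/\gamma_H$) under isotropic rotational
diffusion with rank-2 correlation time $\tau_Q$. Lattice operators are
expanded in $|\Sigma,\sigma)\otimes|L,K,M)$ — normalized spin tensors
(ranks 1 and 2; rank 0 is the identity and does not evolve) times
normalized Wigner functions — and

$$R_1^{HN}(\omega_H) \propto C_{HN}\,
\mathrm{Re}\,\{[T_1^1]^\dagger [M]^{-1} [T_1^1]\},$$

where $[M]$ carries the quadrupole superoperator (selection rules
$|K-K'|\in\{0,2\}$ with rank-2 EFG components in the ratio
$1 : \eta/\sqrt6$, $|\Delta L|\le 2$, $\sigma' = \sigma + m$, rank
parity flip), the diagonal precession $\sigma\omega_N - \omega_H$ and
the diffusion damping $iL(L+1)/(6\tau_Q)$. The source vector is the
proton-flip part of the dipolar coupling; for the H–N axis along the
EFG $z$ axis it has exactly three non-zero entries with squared weights
1:3:6 — the familiar heteronuclear $J(\omega_H\pm\omega_N), J(\omega_H)$
combination.

Numerical choices worth knowing:

* **Normalization is fixed analytically, not fitted**: the overall scale
  is the unique constant for which the $a_Q \to 0$ limit reproduces the
  extreme-narrowing expression exactly. The spin-space matrix elements
  are computed by direct operator algebra on the $3\times3$
  representations (equivalent to the 3-j/6-j expressions by
  Wigner–Eckart, but immune to prefactor typos); the rotational
  integrals are products of two Wigner 3-j symbols, evaluated by
  Racah's formula with log-factorials and memoized.
* **The isotropic $L=0$ rotational function is included** even though
  slow-motion treatments often quote $L = 1..L_{max}$. Products of
  rank-2 functions have isotropic components and pure spin operators
  live at $L=0$; dropping the state visibly corrupts the slow-motion
  limit (the quadrupole peaks collapse onto a single spurious
  frequency). With it, at $x=25$ the peaks sit exactly at
  $\nu_0,\nu_-,\nu_+$ and the dominant $\nu_0$ peak matches the closed
  form to $\sim$1%.
* **Only the reachable block is solved.** $[M]$ conserves
  $p=\sigma+M$ and the parity of $K$; the source vector lives in
  $p=-1$ (even $K$ for $\Theta=0$), so the solver works on that block
  (a few hundred states at $L_{max}=8$ instead of 7752), which is
  exactly equivalent to the full solve (asserted in the tests). Linear
  systems are solved directly; no explicit inverse is formed.
* **Truncation**: $L_{max}=8$ changes by $<10^{-3}$ relative when
  raised to 10 in all regimes used here; `check_convergence = TRUE`
  verifies this at run time.

### Where the closed form is valid — and what "valid" means

`sle_validity_scan()` compares the two descriptions on a common grid.
The qualitative picture is robust and reproduced by the tests: near
agreement for $x \lesssim 1$, severe breakdown for $1 < x < 25$
(deviations of order unity, peaks displaced), recovery of the peak
structure at $x \ge 25$.

The quantitative statement needs care, and this package deliberately
reports it honestly. Our solver was verified in two independent ways:
element-by-element against brute-force SO(3) quadrature of the
pointwise superoperator, and end-to-end against a time-domain
Monte-Carlo simulation of the same model (rotational-diffusion
trajectories with time-ordered spin propagators), whose correlation
function matches the SLE propagator within sampling noise. Against
that ground truth, the closed form still deviates from the exact
solution by up to $\sim$12% at $x=1$ and up to $\sim$45% at $x=25$ *at
off-peak frequencies* (the zero-frequency plateau and the inter-peak
valleys), even though peak positions and the dominant peak height agree
to $\sim$1%. The reason is structural: the closed form forces every
spectral component to decay at $1/\tau_Q$, whereas the true correlation
functions of the products (dipole orientation $\times$ eigenvector
projector) contain rotational ranks 0–4 with decay rates between 0 and
$20D$. On a log-log plot these deviations are nearly invisible, which
is why the regime is conventionally described as "good agreement"; a
max-relative-deviation-below-10% reading of that phrase is *not*
attainable, and the corresponding acceptance test in this package is
expected to fail and is left failing rather than loosened.

## The staged fitting pipeline

`fit_profile()` mirrors how these profiles are analysed in practice:

1. **Peaks first.** `detect_peaks()` estimates a smooth background by
   an asymmetrically reweighted quadratic fit in log–log coordinates
   (points above the running fit are down-weighted to 0.02, ten
   iterations), finds residual maxima, then refines centres and widths
   by jointly fitting Lorentzians plus a quadratic-in-$\log\nu$
   background to the raw rates in the window. The refinement removes
   the bias that overlapping tails and the sloping background exert on
   grid maxima. $(a_Q,\eta)$ follow exactly from
   $a_Q = \tfrac23(\nu_+ + \nu_-)$, $\eta = 2(\nu_+-\nu_-)/a_Q$ and are
   **fixed** thereafter.
2. **$\tau_Q$ from widths.** Each quadrupole peak is a Lorentzian of
   FWHM $1/(\pi\tau_Q)$; the width-derived value initialises $\tau_Q$
   and a hard $\pm$10% box constrains it during the fit.
3. **Everything else by bounded Levenberg–Marquardt.** Residuals are
   relative (`model/obs - 1`) by default so that the 4–5 decades of
   $R_1$ contribute comparably (per-point $\sigma$ weighting is
   available when uncertainties exist). Positive parameters are fitted
   in log space; $\tau_Q$ through a scaled logistic implementing the
   box; $\Theta,\Phi$ through logistics onto $[0^\circ, 90^\circ]$ (the
   model depends on them only through squared sines/cosines, and the
   reference values lie in that quadrant). Amplitudes are initialised
   by non-negative linear least squares at decade-seeded correlation
   times ($10^{-6}/10^{-7}/10^{-8}$ s), which makes the 11-parameter
   problem reliably convergent: each parameter controls a distinct
   feature of the profile. The LM loop only ever accepts steps that
   decrease the objective, so the objective trace is monotone (a tested
   invariant). After convergence the three components are relabelled in
   decreasing-$\tau$ order.

Uncertainties are 1$\sigma$ relative values from the Gauss–Newton
covariance at the optimum, with $\sigma^2$ estimated from the residual
sum of squares. The overall `relative_error` is the RMS relative
residual $\times$ 100 — a fit diagnostic comparable to, but not
necessarily identical with, the "relative error (%)" quoted alongside
published parameter tables (no definition is printed there, so ours is
an explicit choice and no acceptance number relies on it).

## The synthetic-data generator

Measured profiles for the four reference proteins (elastin, human
plasma albumin, bovine serum albumin, hen egg-white lysozyme) are not
distributed with their parameter tables, so `simulate_profile()` stands
in for them. It emulates a fast-field-cycling acquisition at 308 K:

* 50 log-spaced points from 0.01 to 40 MHz (the instrument's practical
  window), densified 3$\times$ inside 0.5–3.5 MHz so the quadrupole
  peaks are sampled — mirroring the visible sampling of published
  figures without claiming to copy it. Parameter-extraction tasks use
  denser windows (e.g. 8–20$\times$) as the respective analyses demand.
* rates evaluated exactly from the forward model at reference parameter
  sets (`table1_fixtures()`),
* multiplicative Gaussian noise $R_1(1+\epsilon)$,
  $\epsilon\sim N(0,\mathrm{cv}^2)$, independent per point and
  reproducible by seed; FFC $R_1$ uncertainties scale roughly with the
  rate, which motivates the multiplicative (rather than additive)
  model. No noise level is stated with the reference data; 2% is used
  as the realistic working value in the recovery tests. Non-positive
  draws (absent at these cv values) would be resampled.

What a green recovery test establishes: that the staged pipeline is an
unbiased, well-conditioned estimator *for data generated by its own
forward model with uncorrelated multiplicative noise*. It does not
establish robustness to model misspecification (correlation-time
distributions, instrument drift, field-switching transients), which
real measurements contain.

## Degenerate inputs, ties, edge cases

* Profiles must be strictly increasing in frequency; file input is
  re-sorted with a message when merely shuffled, rejected when
  duplicated.
* `detect_peaks()` fails loudly (naming the window) when fewer than two
  residual maxima survive the prominence threshold — e.g. when
  $C_{HN}=0$.
* Peak pairs implying $\eta > 1$ are rejected as misidentified.
* A $\tau_Q$ ending at its box boundary and a non-converged LM both
  emit warnings and are flagged in the result object.
* The SLE matrix is reported singular with the offending
  $(\omega_H, \tau_Q)$ should that ever occur (it cannot for finite
  $\tau_Q$: the damped block is strictly dissipative).

## Known limitations

* For tilted orientations ($\Theta \ne 0$) the SLE solver and the
  closed form disagree about which in-plane EFG axis pumps which
  transition: with the dipole along the EFG $x$ axis the closed form
  (weights as conventionally printed) makes $\nu_-$ dominant, while
  the exact dynamics — confirmed by the Cartesian time-domain
  Monte-Carlo simulation, which has no spherical-tensor conventions to
  get wrong — makes $\nu_+$ dominant. The two agree under
  $\Phi \mapsto 90^\circ - \Phi$ (an $x{\leftrightarrow}y$
  relabelling), so fitted $\Phi$ values are self-consistent within the
  closed-form convention and all $\Theta = 0$ analyses (the validity
  scan, Fig-style comparisons) are unaffected. The closed form is kept
  exactly as conventionally written.
* Single temperature; no exchange, no anisotropic diffusion, no
  explicit multi-spin lattice sums (effective two-spin constants), no
  power-law backbone-fluctuation models, no vendor file formats.
* The fit treats the ${}^1$H–${}^{14}$N channel with the closed form
  only; for the reference parameter sets $x \approx 19$–27, inside the
  regime where the closed form's off-peak deviations are material in
  principle. This reproduces the published analysis procedure; a
  fully SLE-based fit would be substantially slower and is not
  implemented.
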