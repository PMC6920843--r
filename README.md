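# nmrdfit

Analysis of ¹H spin–lattice relaxation dispersion (NMRD) profiles of
solid proteins measured by fast-field-cycling relaxometry.

## The problem

Lyophilized proteins relax their ¹H magnetization through two channels.
¹H–¹H dipolar couplings, modulated by dynamics on microsecond to
nanosecond time scales, produce a smooth dispersion that is well
described by a *model-free* sum of three Lorentzian contributions plus
a frequency-independent term:

    R1_HH(ω) = Σ_{k∈{s,i,f}} C_k [ τ_k/(1+ω²τ_k²) + 4τ_k/(1+4ω²τ_k²) ] + A

¹H–¹⁴N dipolar couplings add *quadrupole relaxation enhancement* (QRE):
the ¹⁴N (spin-1) level structure is fixed by its quadrupole coupling
(amplitude `a_Q = e²qQ/h`, asymmetry `η`), and whenever the ¹H Larmor
frequency matches one of the ¹⁴N transition frequencies

    ν∓ = (3/4) a_Q (1 ∓ η/3),    ν0 = ν+ − ν− = (1/2) η a_Q

the ¹H relaxation rate shows a local maximum — a *quadrupole peak*.
The closed-form QRE rate attaches to each transition a Lorentzian pair
of width 1/τ_Q with angular weights (⅓+sin²Θcos²Φ, ⅓+sin²Θsin²Φ,
⅓+cos²Θ) that encode the orientation of the H–N axis in the
electric-field-gradient frame. The dipolar constant
`C_HN = (2/3)((μ0/4π)γ_H γ_N ħ / r³)²` encodes an effective H–N
distance.

The closed form is valid only when `x = 2π a_Q τ_Q` is ≲1 or ≳25. The
package also contains a stochastic Liouville equation (SLE) solver —
spin-1 quadrupole + Zeeman dynamics coupled to isotropic rotational
diffusion in a `|Σ,σ)⊗|L,K,M)` operator basis — that is exact at any
`x` and is used to map the closed form's validity range.

For whom: NMR relaxometrists fitting FFC dispersion profiles of solids
(proteins, tissues, pharmaceuticals) who need the staged
peak-position/peak-width/least-squares pipeline, and spin-dynamics
practitioners who want an independently validated SLE reference
implementation for ¹H–¹⁴N QRE.

## Worked example

Simulate a lysozyme-like profile with 2 % multiplicative noise, then
run the staged analysis (peaks → quadrupole parameters → widths → τ_Q
→ bounded least squares):

```r
library(nmrdfit)
fx   <- table1_fixtures()                      # reference parameter sets
prof <- simulate_profile(fx$lysozyme,
                         generator_config(noise_cv = 0.02, seed = 7))

(rep <- detect_peaks(prof))
#> <peak report> nu- = 2.1698 MHz, nu+ = 2.8712 MHz
#>   FWHM (MHz): nu_minus = 0.4035, nu_plus = 0.3896

quad_params_from_peaks(rep)
#> <quadrupole coupling>  a_Q = 3.361 MHz,  eta = 0.417

(fit <- fit_profile(prof))
#> <NMRD profile fit>
#>   fixed: a_Q = 3.361 MHz, eta = 0.417
#>   C_s    = 8.863e+07  (1.6%)
#>   tau_s  = 3.706e-06  (2.7%)
#>   C_i    = 3.297e+08  (1.9%)
#>   tau_i  = 2.169e-07  (2.6%)
#>   C_f    = 4.217e+08  (1.3%)
#>   tau_f  = 1.671e-08  (3.0%)
#>   A      = 2.483  (2.2%)
#>   C_HN   = 1.936e+08  (1.5%)
#>   tau_Q  = 8.788e-07  (1.8%)
#>   Theta  = 67.52  (1.7%)
#>   Phi    = 33.43  (1.9%)
#>   relative error = 1.74%  (83 points)

signif(hn_distance_from_constant(fit$hn$C_HN), 3)
#> [1] 1.47      # effective H-N distance in Angstrom
```

Reading the output: the two quadrupole peaks at 2.17/2.87 MHz fix
`a_Q = 3.36 MHz`, `η = 0.42` (generator truth: 3.36/0.42); the peak
widths give `τ_Q ≈ 0.88 µs`; the three dipolar components recover the
µs/100 ns/10 ns dynamics; `C_HN ≈ 1.9e8 rad²s⁻²` corresponds to an
effective H–N distance of 1.47 Å — longer than the ~1 Å amide bond
because several non-bonded ¹⁴N neighbours contribute. Parenthesized
percentages are 1σ relative uncertainties from the fit covariance.

Compare the closed-form QRE expression with the SLE:

```r
scan <- sle_validity_scan(c(1, 4, 25), quadrupole_coupling(3.4, 0.4),
                          C_HN = 1e8)
scan$summary       # per-x max/mean relative deviation, peak positions
```

## Command line

```sh
Rscript -e 'nmrdfit::nmrd_main()' simulate --protein lysozyme \
    --noise-cv 0.02 --seed 7 --out prof.csv
Rscript -e 'nmrdfit::nmrd_main()' fit --in prof.csv --out fit.json
Rscript -e 'nmrdfit::nmrd_main()' report --in prof.csv --fit fit.json --out report.pdf
```

(Or use the wrapper installed at `inst/cli/nmrdfit`.) Subcommands:
`simulate`, `peaks`, `fit`, `decompose`, `sle-validate`, `report`.
Profiles are CSV with `# key: value` metadata headers; frequencies in
MHz, rates in s⁻¹, times in s, angles in degrees, dipolar constants in
rad²s⁻².

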