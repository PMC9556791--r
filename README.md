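# fibrilquant

Quantitative analysis of amyloid–membrane interaction data from solid-state
NMR, dark-field TEM and plate-reader assays.

When β-amyloid (Aβ) peptides nucleate on neuronal membranes, the earliest
events — peptide chains assembling into β-sheet oligomers, side chains
contacting lipid headgroups, lipid motions speeding up or slowing down —
are visible only through indirect, quantitative observables: relaxation
times, dipolar dephasing curves, crosspeak volumes, image intensities,
fluorescence kinetics. `fibrilquant` implements the full analysis chain
that turns those observables into physical quantities, together with a
seeded synthetic-data generator so every stage can be validated against
known ground truth without spectrometer data.

## What it computes

**Lipid dynamics from ³¹P relaxation.** T₁ inversion-recovery and T₂ echo
decays are fit to exponentials; the fast (nanosecond, headgroup
rotation/wobble) and slow (microsecond, lateral diffusion) correlation
times τ_f and τ_s follow from the two-timescale CSA relaxation model

    R1 = (2/15) ω² σ² (1 + η²/3) [ S²τ_s/(1+(ωτ_s)²) + (1−S²)τ_f/(1+(ωτ_f)²) ]
    R2 = (1/15) ω² σ² (1 + η²/3) { [ ... same ... ] + (4/3)[S²τ_s + (1−S²)τ_f] }

inverted under the fast-motion approximation (ωτ_f)² ≫ 1 (validity metric
reported; the regime of interest is (ωτ_f)² ≈ 4–10). First-order
uncertainty propagation uses the constants C1–C4 derived from ω, the CSA
σ, the asymmetry η and the order parameter S; with the study constants
(2π·242 MHz, 160 ppm, 0.57, 0.2), C1 = 8.75·10⁹ s⁻² and
C2 = 4.29·10⁻⁹ s². Peptide-induced changes Δτ_f, Δτ_s against
peptide-free controls carry quadrature-combined uncertainties.

**Internuclear distances from dipolar recoupling.** Powder-averaged
two-spin PITHIRDS-CT decay (¹³C–¹³C) and the universal isolated-pair REDOR
build-up (¹³C–³¹P, closed Bessel form
ΔS/S₀ = 1 − (√2π/4)·J₁∕₄(√2λ)·J₋₁∕₄(√2λ), λ = N·T_r·d) are simulated from
the dipolar coupling d = (μ₀/4π)·γ_aγ_b·ħ/(2πr³) and matched against
measured curves over a 4–8 Å grid.

**Interstrand contacts from isotope dilution.** Crosspeak and diagonal
volumes from 2D ¹³C–¹³C spin-diffusion spectra (1.5 × 1.5 ppm windows,
noise from 10 seeded peak-free regions) give the Reduction statistic
(V₁,d/V₀,d)/(V₁,n/V₀,n) × 100 % with its four-term propagated uncertainty.
Under independent 1:1 labeling an interstrand contact reduces to
p² = 25 %, an intrastrand one stays at ~100 %. Secondary chemical-shift
deviations ΔδCβ − ΔδCα against a bundled random-coil table flag β-strand
residues.

**Fibril mass-per-length from dark-field TEM.** Background-subtracted
intensities against the tobacco-mosaic-virus internal standard
(131 kDa/nm), and a constrained Gaussian-mixture fit (means at exact
integer multiples of a unit MPL, shared width, EM) that reads off the
filament count and rotational symmetry (~18.8 kDa/nm per two-fold layer of
Aβ₁₋₄₀).

**Assay quantification.** ThT fibrillation kinetics (logistic fit, lag =
t½ − 2/k with delta-method SE), BCA membrane-binding percentage, GdnHCl
denaturation midpoints C½, MTT cell viability, and Welch t-tests with star
annotation.

## Worked example

```r
library(fibrilquant)

params <- spin_system_params()          # 242 MHz, 160 ppm, eta 0.57, S 0.2

# synthetic sample/control decays with a programmed +0.3 ns headgroup
# restriction and a -0.5 us diffusion change, 2 % noise
set <- gen_relaxation_set(tau_f_sample = 1.8e-9, tau_s_sample = 3.5e-6,
                          tau_f_control = 1.5e-9, tau_s_control = 4e-6,
                          noise_sd = 0.02, seed = 42)
smp <- invert_simplified(fit_exponential_decay(set$sample$t1),
                         fit_exponential_decay(set$sample$t2), params)
ctl <- invert_simplified(fit_exponential_decay(set$control$t1),
                         fit_exponential_decay(set$control$t2), params)
print(smp)
#> Lipid-motion correlation times
#>   tau_f = 1.987e-09 s  (sigma = 1.02e-10 s)  [fast, headgroup]
#>   tau_s = 3.522e-06 s  (sigma = 1.18e-07 s)  [slow, lateral diffusion]
#>   (omega*tau_f)^2 = 9.13  -> within validity window
print(delta_correlation_times(smp, ctl, label = "5 h"))
#> Delta tau (sample - control) [5 h]
#>   delta tau_f = +1.911e-10 s +/- 1.33e-10 s
#>   delta tau_s = -4.436e-07 s +/- 1.55e-07 s
```

The recovered τ_f (1.99 ns) sits above the 1.8 ns truth by the documented
fast-motion approximation bias (~+13 % in this regime, shared by sample and
control, so Δτ signs are preserved: headgroup restriction +0.19 ns, faster
lateral diffusion −0.44 µs, both matching the programmed effects within
uncertainty).

```r
# distance from a noisy dephasing curve (true r = 5.0 A)
estimate_distance(gen_dephasing(5.0, "PITHIRDS_CT", noise_sd = 0.05, seed = 7))
#> PITHIRDS_CT distance estimate: r = 5.2 Angstrom (strong dephasing)

# isotope-dilution contact classification
reduction_statistic(dilution_quartet(v1_n = 40, v0_n = 400,
                                     v1_d = 2.6, v0_d = 205,
                                     delta_n = 1.2, delta_d = 1.0))
#> Crosspeak reduction: 12.7 % +/- 4.9 % -> interstrand

# mass-per-length mixture: 500 synthetic segments, two/three-filament bundles
fit <- fit_mpl_distribution(gen_mpl_sample(u = 18.8, weights = c(0, .5, .5),
                                           width = 3, n = 500, seed = 1))
#> MPL mixture at multiples of u = 18.74 kDa/nm (width 3.15)
#>   k = 2 (37.5 kDa/nm): weight 0.539  *
#>   k = 3 (56.2 kDa/nm): weight 0.461  *
infer_symmetry(fit$unit_u)              # fold 2, mismatch ~1.7 %

# ThT kinetics: lag period of an aqueous-condition trace
fit_tht_kinetics(gen_tht_trace(lag = 28.5, k = 0.5, noise_sd = 0.02, seed = 11))
#> ThT kinetics fit: lag = 28.5 h +/- 0.1 h
#>   t_half = 32.5 h, k = 0.492 1/h, A = 1.02e+03, F0 = 92.8
```

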