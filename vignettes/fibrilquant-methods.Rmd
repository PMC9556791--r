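---
title: "Models and methods behind fibrilquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fibrilquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilquant)
```

`fibrilquant` implements the quantitative analysis chain used in
solid-state NMR studies of early β-amyloid–membrane interactions. This
vignette documents the models, the parameters that matter, the numerical
choices, and — importantly — what the synthetic-data validation does and
does not establish.

## Lipid dynamics from ³¹P relaxation

### Model

Phospholipid ³¹P relaxation in a fluid bilayer is driven by chemical-shift
anisotropy modulated on two timescales: nanosecond headgroup rotation and
wobble (correlation time $\tau_f$) and microsecond lateral diffusion
around the curved vesicle surface ($\tau_s$). With Larmor angular
frequency $\omega$, CSA $\sigma$ (the ppm value used as a dimensionless
fraction, e.g. 160 ppm $\to 1.6\times10^{-4}$), tensor asymmetry $\eta$
and order parameter $S$ partitioning spectral density between the two
motions, the rates are

$$R_1 = \tfrac{2}{15}\omega^2\sigma^2(1+\tfrac{\eta^2}{3})
 \Big[\tfrac{S^2\tau_s}{1+(\omega\tau_s)^2}
 + \tfrac{(1-S^2)\tau_f}{1+(\omega\tau_f)^2}\Big],$$

$$R_2 = \tfrac{1}{15}\omega^2\sigma^2(1+\tfrac{\eta^2}{3})
 \Big\{\big[\cdot\big]
 + \tfrac{4}{3}\big[S^2\tau_s + (1-S^2)\tau_f\big]\Big\},$$

with $[\cdot]$ the same bracket as in $R_1$. `full_rate_model()`
evaluates these exactly; `gen_relaxation_set()` simulates decays from
them, so the inversion below is always exercised against the full model,
approximation error included.

### Simplified inversion

For microsecond $\tau_s$ at 242 MHz, $S^2\tau_s/(1+(\omega\tau_s)^2)
\approx S^2/(\omega^2\tau_s) \sim 10^{-15}$ s and is negligible; for
nanosecond $\tau_f$, $(\omega\tau_f)^2 \approx 4$–$10 \gg 1$, so the fast
term collapses to $(1-S^2)/(\omega^2\tau_f)$. This linearises the system:

$$\tau_f = \tfrac{2}{15}\sigma^2(1+\tfrac{\eta^2}{3})(1-S^2)\, T_1,
\qquad
\tau_s = \frac{R_2 - R_1/2}
 {\tfrac{4}{45}\omega^2\sigma^2(1+\tfrac{\eta^2}{3})\,S^2}
 - \frac{(1-S^2)\tau_f}{S^2}.$$

$\omega$ cancels from the $\tau_f$ inversion (a property test asserts
this). `invert_simplified()` reports the validity metric
$(\omega\tau_f)^2$ and flags results outside a configurable window
(default $[4, 10]$). The approximation biases $\tau_f$ upward by the
factor $(1+(\omega\tau_f)^2)/(\omega\tau_f)^2$ — +13 % at
$(\omega\tau_f)^2 = 7.5$, bounded by +25 % over the window — while
$\tau_s$ is nearly unbiased (&lt; 1 % in the same regime) because its
secular term does not involve the approximated spectral densities. Both
bounds are asserted in the tests against full-model forward simulations.
Because sample and control share the bias, the differences
$\Delta\tau_f$, $\Delta\tau_s$ preserve sign and approximate magnitude;
the seeded pipeline test requires sign recovery in ≥ 90 % of runs at 2 %
decay noise.

A negative inverted $\tau_s$ (transverse rate too small to accommodate
the $\tau_f$ terms) is physically inconsistent; it is reported, flagged
invalid, and warned about rather than suppressed.

### Uncertainty propagation and the constants C1–C4

The first-order propagation is
$\sigma_{\tau_f} = (C_1/\omega^2)\sigma_{T_1}$ and
$\sigma_{\tau_s} = [(C_2/T_2^2)^2\sigma_{T_2}^2 +
(C_3/T_1^2 - C_4)^2\sigma_{T_1}^2]^{1/2}$ with
$C_1 = \tfrac{2}{15}\omega^2\sigma^2(1+\eta^2/3)$ and
$C_2 = 45/(4\omega^2\sigma^2(1+\eta^2/3)S^2)$; for the default spin
constants these evaluate to $8.75\times10^9$ and $4.29\times10^{-9}$.
Differentiating the implemented inversion gives $C_3 = C_2/2$ and
$C_4 = (1-S^2)^2\tfrac{2}{15}\sigma^2(1+\eta^2/3)/S^2$.

Two deliberate subtleties:

* The closed-form $C_1$ omits the $(1-S^2)$ factor present in the
  $\tau_f$ inversion slope. `propagation_constants()` therefore ships two
  modes: `as_printed` (default; matches the published closed forms) and
  `self_consistent` (all four constants strictly as partial derivatives
  of `invert_simplified()`, so $C_1^{self} = (1-S^2)C_1$). A ratio test
  pins the relationship.
* Commonly quoted values for $C_3$ and $C_4$ in this analysis tradition
  ($2.20\times10^{-9}$, $9.58\times10^{-8}$) differ by 3–10 % from any
  set derivable self-consistently from the other constants; the package
  returns the derivable values and validates them against
  finite-difference derivatives of the inversion.

The analytic propagation is validated against Monte-Carlo resampling of
$(T_1, T_2)$ at 3 % relative error (agreement within 15 %).

### Fitting details

Exponential fits are deterministic: initial values from log-linear
regression, refinement by Levenberg–Marquardt. The inversion-recovery
amplitude factor $\beta$ in $I(t) = I_0(1 - \beta e^{-t/\tau_1})$ is free
by default (real data rarely achieve the ideal $\beta = 2$) with
`fix_beta = 2` available. $\sigma_\tau$ is the standard error from the
fit covariance; a Monte-Carlo test confirms it tracks the replicate
scatter of $\tau$ within 20 % at 2 % noise.

## Dipolar recoupling distances

`dipolar_coupling()` computes $d = (\mu_0/4\pi)\gamma_a\gamma_b
\hbar/(2\pi r^3)$ (about 61 Hz for a ¹³C pair at 5 Å). PITHIRDS-CT
dephasing is the powder average
$S(t)/S_0 = \langle\cos(\kappa\pi d P_2(\cos\theta) t)\rangle$, evaluated
by Gauss–Legendre quadrature over $\cos\theta$ (256 nodes by default;
a 10⁴–10⁵-sample Monte-Carlo powder average is kept in the tests as an
independent oracle). The sequence scaling constant $\kappa$ is not
derivable from curve-matching data alone, since data and fits use the
same simulator; the default $\kappa = 0.25$ was fixed once so that a
4.8 Å pair (the parallel in-register interstrand distance) loses about
half its intensity across the ~61 ms constant-time window, the
tens-of-milliseconds scale of published simulated curves. The
powder-averaged cosine is monotone in its argument up to $\approx 7.25$;
at $\kappa = 0.25$ the strongest curve in the supported window (4 Å,
61.4 ms) reaches only $\approx 5.7$, so the whole 4–8 Å family is
monotone non-increasing and strictly ordered in $r$ — the ordering that
makes "faster decay means shorter interstrand distance" a valid read.

REDOR uses the universal isolated-pair curve; the closed Bessel form
$\Delta S/S_0 = 1 - \tfrac{\sqrt2\pi}{4}J_{1/4}(\sqrt2\lambda)
J_{-1/4}(\sqrt2\lambda)$ is the fast path and agrees with brute-force
powder integration of the accumulated phase to machine precision
(asserted to $10^{-3}$).

`estimate_distance()` minimises noise-weighted RSS over a 4–8 Å grid
(0.1 Å step), breaking ties toward larger distance (the conservative
call), with classes strong/medium/little at 5.5 and 7 Å (configurable).
An overall-rising PITHIRDS curve is unphysical for an isolated pair and
is classified as little dephasing with a warning. Seeded recovery tests
require the median estimate within 0.3 Å of truth at per-point noise
0.05 for $r \in \{4.5, 5, 6, 7\}$ Å. Multi-spin effects and relaxation
damping are out of scope; an optional per-candidate exponential damping
profile (`scale_fit = TRUE`) absorbs imperfect constant-time
compensation. Low REDOR plateaus (ΔS/S₀ &lt; 0.1), which indicate a large
population distant from ³¹P, are reported as-is — converting a plateau
into a bound-population fraction requires a mixture model the data do not
constrain.

## Isotope-dilution spin-diffusion quantification

Volumes are inclusive rectangular sums over 1.5 × 1.5 ppm windows
(half-width 0.75 ppm per side); integration is exactly linear, and a
brute-force point-by-point reference reproduces it in the tests. Axes are
normalised to the descending-ppm NMR convention on input. Spectral noise
is the SD of 10 window volumes placed on a coarse tiling of whole windows
(guaranteeing disjointness) away from listed peaks; placement is seeded
and returned with the result.

The Reduction statistic
$(V_{1,d}/V_{0,d})/(V_{1,n}/V_{0,n})\times100\,\%$ is scale-invariant
within each spectrum, and its four-term first-order uncertainty is
validated against Monte-Carlo resampling (within 15 % at ≤ 10 % relative
noise). Classification thresholds are not dictated by theory beyond the
endpoints — intrastrand contacts should stay near 100 %, interstrand ones
fall to ~25 % under independent 1:1 labeling — so the defaults sit midway:
≥ 75 % intrastrand, ≤ 50 % interstrand, ambiguous between, and a call is
demoted to ambiguous when the ± uncertainty interval straddles the
opposite threshold.

One convention is worth stating explicitly. A both-ends-labeled model
gives $p^2$ for the *absolute* interstrand crosspeak intensity, but if
the diagonal reference itself scales with the labeled fraction $p$, the
diagonal-normalised ratio would reduce by $p$, i.e. to 50 % rather than
25 % at $p = 0.5$. The package implements the ~25 %-after-normalisation
expectation throughout (`dilution_expectation()` returns $100p^2$, and
`gen_spectrum2d()` scales diluted diagonals and intrastrand crosspeaks by
$p$ and interstrand crosspeaks by $p\cdot p^2$ so that measured
crosspeak/diagonal ratios reduce by exactly $p^2$). The alternative
normalisation is noted here deliberately rather than silently "fixed";
users comparing against differently normalised analyses should check
which convention their reference used.

Secondary-shift calls use
$(\delta C_\beta^{obs}-\delta C_\beta^{rc}) -
(\delta C_\alpha^{obs}-\delta C_\alpha^{rc})$ against a bundled
Wishart-style random-coil table (`inst/extdata`); positive deviations
indicate β-strand. The default call band is ±0.5 ppm around zero —
deviations inside it (including exact random-coil shifts) are
undetermined, as is glycine (no Cβ).

## Mass-per-length from dark-field TEM

Dark-field intensity is proportional to projected mass, so the physical
form of the TMV-calibrated equation is
$\mathrm{MPL} = \frac{I_{fib}-I_{B,fib}}{I_{TMV}-I_{B,TMV}}\times131$
kDa/nm. The equation is sometimes typeset with the reciprocal ratio;
both conventions are available (`physical` default, `as_printed` behind
the flag), they coincide at the 131 kDa/nm identity point, and only the
physical form is linear in fibril mass. The discrepancy is documented
rather than hidden because the identity case — the only directly
checkable value — cannot distinguish them.

`fit_mpl_distribution()` is a constrained Gaussian mixture: means pinned
to $k\cdot u$, shared width, weights and optionally $u$ by EM. The
$u$-update is the weighted least-squares solution
$u = \sum_{ik} r_{ik} k x_i / \sum_{ik} r_{ik} k^2$, which preserves the
EM monotonicity property (asserted per iteration in the tests).
Initialisation is deterministic (uniform weights, MAD-based width), so
the fit is order-invariant with no random restarts; a width floor
(0.5 kDa/nm) keeps the likelihood bounded for degenerate samples.
Components with weight &gt; 0.15 are reported as dominant.

`infer_symmetry()` reports fold $= \mathrm{round}(u\cdot\mathrm{rise}/
\mathrm{MW})$ plus the relative mismatch rather than asserting exactness:
with the standard Aβ₁₋₄₀ mass (4.33 kDa) and β-sheet rise (0.47 nm), the
canonical unit 18.8 kDa/nm sits ~2 % above $2\times4.33/0.47$, a gap that
may reflect isotope-labeled monomer mass and is left visible.

## Assay quantification

* **ThT kinetics** — logistic $F(t) = F_0 + A/(1+e^{-k(t-t_{1/2})})$;
  lag $= t_{1/2} - 2/k$, the tangent-intercept convention standard for
  ThT traces (the 10 %-amplitude alternative is available). The lag SE
  uses the delta method on the $(t_{1/2}, k)$ covariance, including the
  cross term. Whether published lag uncertainties are fit SEs or
  replicate SDs is generally ambiguous, so both routes exist: `lag_se`
  per fit, and replicate SDs by fitting each trace. Decreasing traces
  are refused; truncated-before-plateau fits are flagged lower-bound-only.
* **BCA binding** — the background-corrected supernatant over initial
  concentration is the *free* fraction; the default output is its
  complement (the bound percentage), with the supernatant ratio preserved
  under `as_printed` because that ratio sometimes appears typeset under a
  bound-percentage label. The two always sum to 100.
* **GdnHCl stability** — two-state sigmoid
  $f(c) = 1/(1+e^{(c-C_{1/2})/w})$; for degenerate step data the midpoint
  falls back to the interpolated 0.5 crossing. Lower $C_{1/2}$ ranks a
  fibril less stable.
* **Viability and significance** — the exact MTT absorbance ratio
  (&gt; 100 % reported as-is), and Welch t-tests (Student optional) with
  the star map *, **, *** at p &lt; 0.1, 0.01, 0.001.

## The synthetic-data generator

Every analysis stage has a seeded generator producing inputs in exactly
the form the stage consumes, with ground truth embedded: relaxation decay
pairs forward-simulated from the *full* rate model (defaults
$\tau_f$ 1.5–1.8 ns, $\tau_s$ 4 µs, 2 % Gaussian noise, 10 delays
spanning 0.05–3 relaxation times); dephasing curves from the simulators
plus i.i.d. noise; 2D spectra as discrete unit-volume Gaussian peaks with
dilution scaling as above; MPL draws from the constrained mixture
(default $u = 18.8$, width 3 kDa/nm, $n = 500$, matching the ~500
analyzed segments); logistic ThT traces with $t_{1/2} = \mathrm{lag} +
2/k$. The `tht_presets()` table carries the four study conditions
(aqueous 28.5 h; membrane presets 37.2–40.5 h) as generator truths for
ordering demonstrations. Noise defaults (Gaussian, SD 2 % of maximum
signal; Poisson available for TEM counts) mimic typical spectral scatter.

Generators are pure functions of their seed (asserted byte-identical) and
restore the caller's RNG state.

**What passing tests do and do not show.** The generators emulate the
*statistical* structure of each observable — exponential/logistic/sigmoid
signal shapes, Gaussian peaks, i.i.d. noise — not the physics upstream of
it: no vendor spectral processing, no baseline or phasing artifacts, no
multi-spin dipolar couplings or relaxation damping in the dephasing
curves, no per-lipid-species resolution (an overall ³¹P intensity is
assumed, as spectral resolution rarely permits more), no image
segmentation for TEM. Recovery within the stated tolerances therefore
validates the estimators against their own model class under realistic
noise, and the full-model-to-simplified-inversion tests additionally bound
one known model mismatch; they do not certify performance under artifacts
the generators deliberately omit.

## Problem sizes and runtime choices

Tests use problem sizes chosen to keep the full suite fast while leaving
the statistical assertions well-powered: 15–40 seeds for recovery studies,
3000–4000 Monte-Carlo draws for propagation checks, 10⁵–10⁶ draws where a
closed form is being confirmed, n = 500 for MPL fits. All stochastic
tests fix their seeds; tolerances are stated next to each assertion and
derive from the property being tested (machine precision for algebra,
sampling error for Monte Carlo, documented approximation bounds for the
inversion).

## Known limitations

* Distance estimation assumes isolated spin pairs; population mixtures of
  distances and multi-spin effects are out of scope.
* The PITHIRDS $\kappa$ is a module constant, not a fitted quantity;
  absolute distances from measured data inherit its calibration, though
  orderings and same-simulator recovery do not.
* The simplified relaxation inversion is biased for $\tau_f$ by
  construction (documented above); analyses needing unbiased absolute
  $\tau_f$ should fit the full model directly.
* Peak picking, resonance assignment and dihedral-angle prediction are
  not provided; the spin-diffusion module consumes peak lists or centred
  windows.
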