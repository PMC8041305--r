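---
title: "Modelling buffer-specific protein phase separation with patchyllps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling buffer-specific protein phase separation with patchyllps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchyllps)
```

## The physical picture

Globular proteins in aqueous solution behave, to a useful approximation,
like colloids with short-ranged, strongly anisotropic attractions. On
cooling, a sufficiently concentrated solution crosses a liquid–liquid
binodal and demixes into a protein-poor and a protein-rich liquid; the
temperature at which turbidity first appears on cooling is the cloud point
T_cloud. Because the attraction is short-ranged and patchy rather than
isotropic, the coexistence dome is much flatter and broader than a
mean-field (van der Waals) dome, and isotropic models fail to reproduce it.

`patchyllps` implements the minimal model with the right physics: a hard
sphere of diameter σ decorated with M equivalent attraction sites on its
surface, treated by Wertheim's first-order thermodynamic perturbation
theory (TPT1). The solvent — water, buffer and simple salt — is not modelled
explicitly; in the McMillan–Mayer spirit it acts only through the effective
site–site well depth ε. Buffer identity and salt content are therefore
carried by a single energetic parameter, which is what makes the model
practical for formulation screening: one cloud-point measurement pins the
buffer, one salt series pins the salt response, and the whole phase diagram
follows.

## The model and its state functions

Two molecules at centre distance r interact through a hard core (r < σ
forbidden) plus a square-well site–site term: sites sit at d = σ/2 from the
centre, and a site pair on different molecules gains −ε when its separation
is within ω. Multiple bonding of a single site is prohibited. All
energies are carried as ε/k_B in kelvin throughout the package; no joules
appear anywhere in the interface.

The free energy per particle is additive:

* ideal: βA_id/N = ln(ρΛ³) − 1 with Λ fixed at 1 nm. Λ shifts the chemical
  potential by a state-independent constant that cancels identically in
  every coexistence condition, so it is documented rather than
  configurable.
* hard sphere: Carnahan–Starling, βA_hs/N = η(4 − 3η)/(1 − η)², with
  η = πρσ³/6.
* association (TPT1, M equivalent sites): βA_ass/N = M(ln X − X/2 + 1/2),
  where the unbonded-site fraction X solves the mass-action law
  X + MρΔ_AB X² = 1. The solution is taken in closed form,
  X = 2/(1 + sqrt(1 + 4MρΔ_AB)) — the unique root in (0, 1], with no
  iteration and no tolerance.

The association strength is evaluated in the sticky limit: the contact
value of the hard-sphere pair correlation times the radial integral of the
orientation-averaged Mayer function of the site–site well,

Δ_AB = g_hs(σ) (e^{βε} − 1) v_b,  v_b = πω⁴(15σ + 4ω)/(30σ²).

The orientational average for sites at d = σ/2 has the closed form
f̄(r) = (e^{βε} − 1)(ω + σ − r)²(2ω + r − σ)/(6rσ²) on σ ≤ r ≤ σ + ω and
vanishes beyond σ + ω, where the sites cannot reach. The test suite checks
this form two independent ways: against brute-force Monte-Carlo averaging
of the configurational pair energy over millions of orientation pairs, and
against adaptive quadrature of the radial integral.

One deliberate, inherited inconsistency: the contact value inside Δ_AB is
Percus–Yevick, g_hs(σ) = (1 + η/2)/(1 − η)², while the hard-sphere free
energy is Carnahan–Starling. The antecedent coarse-grained protein model
was built that way, and the calibrated ε₀ values are only meaningful under
the same convention, so we keep it.

Osmotic pressure and chemical potential come from analytic differentiation
of βA/N (the closed-form X makes this exact), and they satisfy the
Gibbs–Duhem relation βμ = βA/N + βΠ/ρ identically. The second virial
coefficient is B₂ = 2πσ³/3 − (M²/2)(e^{βε} − 1)v_b, and the experimental
convention B₂₂ = B₂ N_A/M₂² (in mol·mL/g²) is one centralised unit
conversion.

Temperature enters the model only through βε (the Carnahan–Starling and
ideal parts are athermal up to constants that cancel). A direct consequence
— left in the code as a testable prediction rather than exploited as a
shortcut — is that coexistence densities depend on βε alone, so T_c and
T_cloud at fixed composition are exactly proportional to ε. The test suite
checks this invariance numerically.

## Parameters

| parameter | meaning | default | units |
|---|---|---|---|
| σ | hard-sphere diameter | 3.43 | nm |
| ω | square-well range | 0.18 | nm |
| M | equivalent surface sites | 10 | – |
| M₂ | molar mass | 14300 | g/mol |
| ε₀ | well depth, zero added salt | per buffer (1940–2250) | K |
| a | salt coefficient in ε(I) = ε₀ + a√I | per buffer (500–1090) | K·L^1/2·mol^−1/2 |

The geometry defaults are the lysozyme values (σ from the solvent-excluded
surface volume of the crystal structure; ω, M from the antecedent model
calibration); they are deliberately held fixed across buffers, since
measured hydrodynamic radii show no buffer dependence. The salt law uses
addition (+a√I) because the packaged salt coefficients are positive and
NaBr promotes phase separation: added salt screens protein charge, deepens
the net attraction and raises T_cloud.

## Numerics

**Critical point.** ∂βΠ/∂ρ = ∂²βΠ/∂ρ² = 0 is solved by an outer Brent
search in temperature on the minimum pressure slope, then polished by a
two-variable Newton iteration. The first density derivative is hand-derived
and analytic; the second comes from symbolic differentiation (`stats::D`)
of the closed-form pressure, so residuals at the returned point are at
machine level (the implementation requires < 1e−9). Solved critical points
are cached per (geometry, ε), which both avoids recomputation inside
fitting loops and guarantees bit-identical output for identical inputs.

**Coexistence.** Equal βΠ and equal βμ are solved by a damped
two-variable Newton iteration in (ln ρ_dilute, ρ_dense) — the logarithm
keeps the very dilute branch well conditioned — seeded from the spinodal
(near T_c the binodal half-width is ~√3 times the spinodal half-width),
with a common-tangent scan on βA/V over a dense density grid as a fallback
seed. Residual demands are |ΔβΠ| < 1e−13 nm⁻³ and |Δβμ| < 1e−11; every
emitted binodal point carries its residuals. The binodal is traced by
temperature continuation from T_c(1 − 10⁻³) downward with geometrically
growing steps, warm-starting each solve from the previous point.

**Cloud point.** T_cloud(γ) is the Brent/bisection root in temperature of
ρ_branch(T) = ρ(γ), with tolerance 10⁻³ K — far below the 0.1 °C/min
resolution of the measurement it models. Concentrations below the critical
one cross the dilute branch (the experimentally relevant case: 90 and
125 mg/mL sit well left of the ~231 mg/mL apex); above it, the dense
branch. The lower search bound defaults to 150 K: the model contains no
solvent-freezing physics, so this is a plain bracket bound, not a
prediction of where water freezes.

**Calibration.** `fit_eps0` inverts T_cloud(ε) by Brent iteration over
ε ∈ [500, 5000] K; the map is strictly increasing (in this model, exactly
linear), so the root is unique and found in a handful of iterations.
Per-salt-point depths are pooled over protein concentrations and regressed
on √I, inverse-variance weighted when the cloud points carry measurement
SDs; the intercept is ε₀ and the slope a, with OLS/WLS standard errors.
The regression is done in ε-space (matching how the per-point depths are
obtained); for ε₀ from a single point, the SD of the cloud point is
propagated through the numerically evaluated dT_cloud/dε. Zero-salt
extrapolation of raw T_cloud series defaults to a basis linear in salt
concentration, with a √c basis available and the choice recorded in the
output.

## Measurement reduction

The experiment-facing half of the package is deliberately plain weighted
least squares through `stats::lm`:

* DLS: D = D₀(1 + k_D γ) with γ converted to g/mL so k_D carries mL/g;
  k_D's standard error via the delta method from the OLS covariance.
* SLS: count rates are normalised by laser intensity, converted to Rayleigh
  ratios against the toluene reference (R_tol = 14.0 × 10⁻⁶ cm⁻¹), and the
  Debye plot Kc/R = 1/M_w + 2B₂₂c fitted by OLS; the optical constant is
  K = 4π²n₀²(dn/dc)²/(N_A λ₀⁴) with defaults λ₀ = 632.8 nm,
  dn/dc = 0.185 mL/g, n₀ = 1.332 (aqueous buffer; configurable). A
  non-positive Debye intercept is reported with a warning (M_w undefined)
  rather than rejected, since strongly attractive systems can produce one.
* Viscometry: η = η₀(ρt)/(ρ₀t₀) against the water reference
  (0.8900 mPa·s at 25 °C, 1.5182 at 5 °C), then the Jones–Dole fit
  η/η₀ − 1 = A√c + Bc in the linear basis {√c, c}. A can be pinned to a
  Debye–Hückel value instead of fitted.

The "semidilute window" for the k_D and Debye fits is a configurable
concentration window defaulting to all supplied points, and the window used
is recorded in the fit output.

## Synthetic data: what it does and does not emulate

Every fitting stage is exercised against generated data with known truth:
exact model curves (the TPT1 cloud-point curve with ε(I), the k_D line, the
Debye line mapped back to count rates, the Jones–Dole curve) plus additive
Gaussian noise on the measured ordinate — multiplicative for count rates,
where noise scales with intensity. Defaults mirror the measured ranges:
NaBr 0.1–0.5 M, DLS 4–70 mg/mL, Debye window 2–10 mg/mL, viscometry
0.02–0.1 M; cloud-point noise 0.2 K. Generators are seeded, restore the
caller's RNG state, and embed their truth in the object (and in `#`
metadata lines when written to CSV).

The generators emulate the *statistical* structure of the measurements,
not their physics: no DLS correlograms or inverse-Laplace step (inputs
start at D or R_h), no photon statistics, no multi-angle scattering, no
drift or systematic error, and cloud-point noise is symmetric Gaussian
although real opacification detection is one-sided. Passing the recovery
tests therefore demonstrates that the estimators are correct and unbiased
under the stated error model — not that the error model captures every
pathology of the real instruments.

Parameter-recovery scale, for orientation: with 0.2 K cloud-point noise at
six salt points, the recovered ε₀ lands within ±10 K and a within ±5% of
truth in ≥95% of seeded replicates — the same order as the uncertainties
quoted for the packaged buffer parameter sets. The test suite runs exactly
this experiment (50 replicates for each of the four packaged buffers).

## Problem sizes used by the test suite

Oracle comparisons use 4 × 10⁶ Monte-Carlo orientation pairs per radius
(enough events in the rarest bonding geometries that a ±3·SE normal band is
well calibrated), 10⁴-point coarse grids with local refinement for the
common-tangent construction, 5 × 5 × 3 (η, T, ε) grids for the
derivative-consistency checks, and 200–500 seeded replicates for the
recovery and bias studies. Binodals in examples and the pipeline default to
20–40 temperature points.

## Known limitations

* One-component effective model: buffer and salt act only through ε; no
  explicit ions, no pH dependence (all packaged parameters are pH 7.0).
* No crystallisation/solubility line and no nucleation kinetics: the cloud
  point is the equilibrium binodal crossing, and the LLPS it describes is
  metastable with respect to crystallisation for these systems.
* No amyloid or irreversible aggregation physics.
* The ε-T_cloud map being exactly linear is a property of this model
  (temperature enters only through βε); a solvent with its own temperature
  dependence would break it, and calibrations should then re-fit rather
  than rescale.
* Site geometry is fixed at d = σ/2 with all sites equivalent; no
  site-specific chemistry.
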