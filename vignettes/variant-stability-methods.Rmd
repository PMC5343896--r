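---
title: "Methods: quantifying the stability of ligand-binding-domain variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the stability of ligand-binding-domain variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pparstab)
```

This vignette is the package's own account of the models and estimators it
implements, the conventions it adopts where the underlying experimental
practice leaves choices open, and what its synthetic-data tests do and do
not establish about real instrument data.

## The measurement problem

A single amino acid substitution in an all-helical domain such as the PPARγ
ligand-binding domain can change (i) the secondary-structure content and
inter-helical packing seen by circular dichroism, (ii) the tertiary
environment of aromatic residues seen by fluorescence, (iii) thermal
stability, (iv) the thermodynamics of chemical denaturation, and (v) the
conformational dynamics seen in molecular-dynamics trajectories. The package
computes one quantitative summary per probe, with a common synthetic-data
harness so every estimator can be validated against known ground truth.

## Spectral statistics

**Mean residue ellipticity.** Raw ellipticity θ (mdeg) is normalized per
peptide bond: [Θ] = θ·M_res/(10·l·c) with path length *l* in cm,
concentration *c* in mg/mL, and a mean residue molecular mass M_res of
110 g/mol — the standard convention when the exact sequence mass is not
propagated. The conversion is linear in θ and inverse in *l* and *c*, and
the implementation refuses non-positive metadata.

**Intensity-averaged emission wavelength.** λ̄ = Σ I_i λ_i / Σ I_i is the
first moment of the emission spectrum: an integral statistic, negligibly
sensitive to point noise, that tracks both shifts and shape changes of the
band. It is a weighted mean, so weights must be non-negative:
baseline-subtracted spectra with small negative excursions are clipped to
zero with a warning, and an all-nonpositive spectrum is an error. The
integration window defaults to the full recorded range (fluorescence scans
here span 290–440 nm); it is configurable because truncation conventions
vary between laboratories.

**222/208 ratio.** The ratio of [Θ] at 222 and 208 nm reports on
inter-helical packing; values below 0.9 are conventionally read as
non-interacting helices. Off-grid wavelengths are linearly interpolated —
at 1 nm sampling, higher-order interpolation changes nothing at the
precision the ratio is quoted to.

**SVD denoising.** A titration series (wavelength × condition matrix) is
decomposed by SVD and reconstructed from its leading components. The
automatic rank rule keeps components whose singular value exceeds twice the
median singular value *and* whose left singular vector has lag-1
autocorrelation above 0.8. The rationale: true spectral components are
smooth functions of wavelength, noise components are not, and the magnitude
test alone can be fooled by structured noise. At full rank the
reconstruction is the identity (tested to 1e-9 relative), and retained
variance is non-decreasing in rank.

## Thermal melts

Melts are Θ₂₂₂(T) traces sampled every 0.5 °C from 20 to 75 °C. The melting
temperature is the temperature of the extremum of the first derivative. Raw
differencing at 0.5 °C steps is noise-dominated, so the estimator (a) smooths
the signal with a centred moving average (default window 5 points ≈ 2 °C),
(b) takes centred finite differences, and (c) smooths the absolute
derivative with the same window before locating the peak. Step (c) is what
guarantees, in seeded sweeps, that noise up to 2% of the transition
amplitude cannot move the reported Tm by more than one grid step for
transitions at least 2 °C wide. The extremum searched is the one of largest
*absolute* derivative, so the result is invariant to affine transforms of
the signal and does not assume the instrument's sign convention. Tm is
reported at grid resolution (0.5 °C); parabolic refinement of the peak is
available but off by default, matching how melting temperatures are
conventionally quoted. A trace whose derivative maximum does not stand
clearly above the background level (at least twice the median absolute
derivative) raises a no-transition error rather than returning a number.

Aggregation is flagged from the photomultiplier voltage: the first
temperature at which it *strictly* exceeds 370 V, the operating point above
which rising turbidity is the usual cause. Reversibility is judged by
comparing the post-cooling spectrum to the native one over the helical band
(205–240 nm); the deviation is measured relative to the largest native
signal in the band rather than pointwise, so near-zero crossings of the
spectrum cannot inflate the ratio. No van 't Hoff enthalpy is extracted from
melts: the thermal transitions of this system are irreversible
(aggregation follows unfolding), so equilibrium thermal thermodynamics
would not be meaningful.

The normalization used for fraction-unfolded output is min–max between the
plateau medians of the first and last 10% of points, clamped to [0, 1]; the
underlying practice is never fully specified in instrument workflows, so
this is documented as a convention.

## Equilibrium unfolding thermodynamics

The linear extrapolation model (LEM) takes the unfolding free energy linear
in denaturant, ΔG(x) = ΔG^H₂O − m·x with m > 0, so K(x) =
exp((m·x − ΔG^H₂O)/RT) and the transition midpoint is [Urea]₀.₅ = ΔG^H₂O/m.
A note on signs: the LEM is sometimes written with "+ m[Urea]" for the
*destabilization*; this package stores m positive and subtracts, which is
the parameterization under which the midpoint identity and every derived
free energy in the report tables hold. R = 1.987204 × 10⁻³ kcal mol⁻¹ K⁻¹
and T defaults to 283.15 K (unfolding equilibria here are measured at
10 °C).

**Two-state model.** Observed signal is the population-weighted average of
two linear baselines. Nine-point curves are the practical minimum; the
implementation requires 8.

**Three-state model.** A sequential N ⇌ I ⇌ U scheme in which each step has
its own m-value and midpoint: with K₁ and K₂ as above, F(x) = (F_N + K₁F_I +
K₁K₂F_U)/(1 + K₁ + K₁K₂), native and unfolded baselines linear in
denaturant, and the intermediate's signal F_I constant. A consistency
property worth stating explicitly: some renderings of this equation
duplicate the first transition's exponential inside the denominator's
second factor; the partition form used here is the one under which the
tabulated per-transition free energies equal m × D50 exactly, and
population fractions f_N + f_I + f_U = 1 at every concentration. When the
first transition is saturated the model reduces numerically to a two-state
transition between F_I and the unfolded baseline (tested to 1e-8).

**Fitting.** Levenberg–Marquardt least squares (`minpack.lm::nlsLM`) with
deterministic initialization: baselines by OLS on the first/last 15% of
points, midpoints at the largest (or two largest well-separated) peaks of
the absolute data slope, m-values starting at 2 kcal/mol/M. A steep
starting m can collapse the transition onto a single grid point and make
the initial Jacobian singular, so the two-state fitter falls back over
gentler slopes (2, 1, 0.5, 4 kcal/mol/M) before giving up. Standard errors
are asymptotic, from the Jacobian at the optimum — the "± SE of the fit"
convention. Degenerate inputs are flagged rather than silently fitted:
indistinguishable plateaus warn of ill-conditioning; a three-state fit
whose intermediate signal leaves the data range, whose transition
amplitudes vanish, or whose SEs dwarf the estimates carries `suspicious`
flags. The internal exponent is clamped at ±700 before exponentiation —
pure overflow protection, unreachable for physical parameters.

The constraint D50_IN < D50_UI is available (`enforce_order = TRUE`, via a
non-negative-gap reparameterization) but off by default: curves with an
early first transition fit fine unconstrained, and an unconstrained fit that
*wants* to cross midpoints is itself diagnostic.

**Model choice.** `model_select()` fits both models and prefers the lower
AICc (RSS-based, with the residual variance counted as a parameter), with a
Wald–Wolfowitz runs test on residual signs reported as a lack-of-fit
diagnostic. A three-state fit that wins on AICc but carries `suspicious`
flags is not preferred. With fewer than 12 points only the two-state model
is attempted. In seeded simulations the generating model is selected on
both sides.

**Validation.** Noiseless synthetic curves are refitted to 1e-6 (two-state)
and 1e-4 relative (all nine three-state parameters); a coarse grid-search
minimizer — an implementation-independent oracle — agrees with the
least-squares route to within its grid resolution; and under 2% noise the
median bias of ΔG and m over seeded replicates stays below 5%.

## Trajectory metrics

Coordinates are stored in nm; PDB files (Å, one MODEL per frame, identical
atom tables across models) are converted on read/write via bio3d.
Superposition is the Kabsch algorithm — SVD of the covariance matrix with
the reflection branch excluded — validated against a brute-force
rotation-grid oracle and against bio3d's fitting routine. RMSF is computed
about the window-average structure after iterative alignment to it.
Radius of gyration is mass-weighted, with masses inferred from atom names
unless supplied. Summary statistics (mean, sd) are computed over a
configurable frame window defaulting to everything after the first 1/12 of
the trajectory — the convention of analyzing the last 110 ns of a 120 ns
run after discarding equilibration.

Two conventions are deliberate choices rather than measurements, and every
report echoes them: helix ranges default to the LBD numbering H3 = 276–306,
H12 = 466–477, subportion 280–287 (helix boundaries are usually shown
graphically, not enumerated); and the inter-helix distance is the distance
between Cα centroids (closest-approach is available via `method =
"closest"`). Salt bridges are tracked as the per-frame minimum distance
between the carboxylate oxygens (GLU OE1/OE2, ASP OD1/OD2) and the basic
nitrogens (ARG NE/NH1/NH2, LYS NZ), with occupancy as the fraction of
window frames below a 0.40 nm cutoff — the community convention; the raw
distance trace is always returned so conclusions need not hinge on the
cutoff.

Published trajectory-derived tables for this system come from 120 ns
explicit-solvent MD runs and are not reproducible without rerunning the
simulations, which is out of scope here; this module computes metrics from
supplied trajectories, and its correctness is established against closed
forms (pair Rg = d/2, ring Rg = r, rod Rg = L/√12, RMSF → σ√3 for isotropic
jitter) and the oracles above.

## What the synthetic generators emulate — and what they don't

Each generator is a pure function of its arguments including the seed, and
embeds its ground truth for recovery tests. The fixed study conditions:
urea grids span 0–9 M in 0.25 M steps; melts span 20–75 °C at 0.5 °C;
unfolding temperature 283.15 K. The emission-band generator uses a single
Gaussian band centred near 308 nm (a tyrosine-only emitter) with σ growing
4 → 6 nm and amplitude 1 → 1.6 across the titration — chosen so the
truncation of the band at the 290–440 nm grid shifts λ̄ from the band
centre by less than 0.05 nm, letting the centre serve as a closed-form
expectation. Three-state curves default to λ̄-like baselines (308 → 317 nm
with an intermediate at 313 nm). Jitter trajectories are ideal Cα helices
(rise 0.15 nm, 100° twist, radius 0.23 nm) with isotropic per-residue
Gaussian noise, so RMSF has the closed form σ√3.

These generators reproduce the *functional forms* the estimators assume.
Real instrument data add what they do not: correlated baseline drift,
wavelength-dependent noise, non-Gaussian band shapes, slow equilibration at
high denaturant, and anharmonic, correlated atomic motions. Passing the
recovery tests therefore establishes that the estimators are correct and
unbiased under their stated models — not that the models are complete
descriptions of any instrument's output. Sampling-size choices in the test
suite (36-point titrations, 100-replicate recovery studies, 2000-frame
trajectories with 30-residue helices) were made so that Monte-Carlo error
is small against each tolerance; in the RMSF checks the helix size also
keeps the variance absorbed by superposition (6 rigid-body degrees of
freedom out of 3N) well below the 5% band.

## Known limitations

- No global multi-probe fitting (CD and fluorescence linked in one model);
  probes are fitted separately, as is standard when their transitions do
  not coincide.
- No secondary-structure deconvolution of CD spectra and no DSSP-class
  secondary-structure assignment from coordinates.
- Asymptotic SEs understate uncertainty when parameters are strongly
  correlated (e.g. m and D50 of a poorly sampled transition); the
  `suspicious` flags catch the gross cases but are not a substitute for
  replicate experiments.
- The three-state fit assumes a constant intermediate signal F_I; a
  denaturant-dependent intermediate baseline is not identifiable from
  single-probe data of this length and is deliberately not offered.
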