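---
title: "Two-site exchange dispersion, size-score PCA and void-volume analysis: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-site exchange dispersion, size-score PCA and void-volume analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringflipr)
```

# The scientific problem

Buried aromatic side chains in folded proteins undergo 180-degree ring
flips, which require transient "breathing" motions of the surrounding
protein. In the SH3 domain system this package models, a buried tyrosine
exchanges between a highly populated eclipsed conformation (chi2 near 0
degrees) and a lowly populated staggered conformation (chi2 near -40 to
-75 degrees). Three quantitative strands of evidence characterize this
process, and the package implements the computation behind each:

1. **CPMG / R1rho relaxation dispersion.** Two-site chemical exchange
   between a major state A and minor state B modulates the effective
   transverse relaxation rate R2eff as a function of the CPMG refocusing
   frequency. A global fit across spins, nuclei and static fields yields
   the exchange rate constant `k_ex`, the minor-state population
   `p_minor`, and per-spin shift differences `|ddelta|`.
2. **Sequence size-score PCA.** The conformation of the buried aromatic
   ring correlates with the heavy-atom sizes of the side chains at three
   surrounding alignment positions (493, 517, 541 in the reference
   numbering); PCA of these integer size scores separates eclipsed-like
   (group 1) from staggered-like (group 2) SH3 domains.
3. **Morph-trajectory void volume.** Interpolating between the major- and
   minor-state structures and measuring the pocket volume around the ring
   (with the tyrosine replaced by glycine) quantifies the transient void
   volume that permits fast ring flipping.

# Two-site exchange forward models

## Bloch-McConnell propagation

The transverse magnetization of the two exchanging states evolves under

$$
\frac{d}{dt}
\begin{pmatrix} M_A \\ M_B \end{pmatrix}
=
\begin{pmatrix}
-R_{2,0} - k_{AB} + i\Omega_A & k_{BA} \\
k_{AB} & -R_{2,0} - k_{BA} + i\Omega_B
\end{pmatrix}
\begin{pmatrix} M_A \\ M_B \end{pmatrix},
$$

with $k_{AB} = p_B\,k_{ex}$, $k_{BA} = p_A\,k_{ex}$ (detailed balance) and
$\Omega_B - \Omega_A = \Delta\omega$. `simulate_cpmg_profile()` propagates
the equilibrium-population start vector $(p_A, p_B)$ through the
constant-time CPMG element $(\tau - 180^\circ - 2\tau - 180^\circ - \tau)$
repeated $N/2$ times, with $N = 2 T \nu_{\mathrm{CPMG}}$ ideal refocusing
pulses modeled as complex conjugation, and reports

$$
R_{2,\mathrm{eff}}(\nu) = -\frac{1}{T}\,
\ln\frac{|M_A(T)|}{p_A} + R_{2,0}.
$$

Detection follows the major-state resonance, which is what a resolved peak
in the spectrum reports. With equal $R_{2,0}$ in both states the exchange
contribution is exactly additive, so propagation is done once with
$R_{2,0}=0$; the 2x2 complex matrix exponentials use the Cayley-Hamilton
closed form and the element propagator is powered by repeated squaring.

## Closed forms

`carver_richards_profile()` evaluates the same quantity in closed form by
analytic eigendecomposition of the 2x2 CPMG element propagator. With
`amplitude = "exact"` (the default) it retains the exact initial-condition
amplitudes and agrees with the numerical propagation to numerical roundoff
at all exchange regimes -- this is what the global fit uses as its fast
engine. With `amplitude = "dominant"` it reduces to the textbook
Carver-Richards expression (the slowest-decaying eigenvalue only), which
deviates visibly in slow exchange when the minor population is large; it
is retained because it is the form most practitioners know, and the
difference between the two is itself informative. `luz_meiboom_rex()`
provides the fast-exchange limit

$$
R_{ex}(\nu) = \frac{p_A p_B \Delta\omega^2}{k_{ex}}
\left(1 - \frac{4\nu}{k_{ex}}\tanh\frac{k_{ex}}{4\nu}\right),
$$

used as an independent cross-check and as the shape basis of the per-spin
exchange detection test.

## On-resonance R1rho

`r1rho_on_resonance()` builds the full 6x6 two-state rotating-frame
evolution matrix (x, y, z of both states; R1, R2,0, spin-lock field
omega1, and state offsets relative to the population-average shift, where
the on-resonance carrier is placed). The reported rate is the dominant
decay eigenvalue, selected by overlap of the eigenvectors with the
spin-locked start vector rather than by magnitude, because the slowest
eigenvalue of the full matrix is the longitudinal (R1-like) mode. The
asymmetric-population closed form
$R_{1\rho} = R_{2,0} + p_A p_B \Delta\omega^2 k_{ex} /
(\omega_{A,\mathrm{eff}}^2\omega_{B,\mathrm{eff}}^2/\omega_{\mathrm{eff}}^2
+ k_{ex}^2)$ is retained as a cross-check; the two routes agree to better
than 0.1% over spin-lock fields of 0.7-10 kHz at the wild-type kinetics.

## Units and conversions

Shift differences are carried in ppm and converted per nucleus and field
with `ppm_to_angular()`: $\Delta\omega = 2\pi\,\Delta\delta\,
f_{^1\mathrm{H}}\,|\gamma_X/\gamma_{^1\mathrm{H}}|$ with the gyromagnetic
ratio table shipped in the package (ratios good to 5 significant digits).
Magnitudes of `ddelta` are fitted by default; CPMG data at a single
temperature do not determine the sign robustly.

# The global dispersion fit

`global_fit()` minimizes the weighted residual sum of squares with `k_ex`
and `p_minor` shared globally, `|ddelta|` per (spin, nucleus), and
`R2,0` free per (spin, nucleus, field). The problem is solved by variable
projection: `R2,0` enters linearly and is profiled out exactly;
`|ddelta|` is profiled per group over a grid with parabolic refinement;
the remaining 2-D problem in $(\log k_{ex}, \mathrm{logit}\,2p_B)$ is
minimized by Nelder-Mead from a multi-start grid (`k_ex` in
{250, 1000, 2500, 7000, 20000} /s times `p_minor` in {0.01, 0.05, 0.15}),
followed by an adaptive zoom of the ddelta grids and a joint quasi-Newton
polish over all parameters. On noiseless synthetic data the truth is
recovered to better than 0.01% relative; the polish stage exists because
grid-profiled objectives otherwise limit the attainable precision.

Intensity-mode data are first reduced by `prepare_r2eff()`:
$R_{2,\mathrm{eff}} = -(1/T)\ln(I/I_0)$, with one pooled intensity
standard deviation per dataset from the technical-replicate pools
(`pooled_sd()`) propagated to each point by Monte Carlo
(`propagate_r2eff_errors()`). Points with zero uncertainty receive the
dataset median (degenerate-input guard). Parameter uncertainties come from
`mc_parameter_uncertainty()`: refits of noise-perturbed datasets,
warm-started at the point estimate (the warm path skips the global grid
stages, which exist only to locate the basin; it provably converges to the
same optimum on these problems). Coverage of the 1-sigma interval was
verified at 69.5% over 200 replicate experiments.

## Exchange detection

`detect_exchange()` compares a flat model against `R2,0 + phi *
shape(k_ex)` with a Luz-Meiboom shape, amplitude fitted and `k_ex`
profiled over a log-spaced grid. Because `k_ex` disappears under the null,
the chi-square improvement is a Davies-type sup statistic and the textbook
F(2, n-3) reference is miscalibrated (measured type-I rate near 0.03 at
alpha = 0.05 for 8-point profiles). The p-value is therefore computed from
the exact finite-sample null of the whitened sup statistic by parametric
simulation with a fixed internal seed -- cheap (one matrix product) and
calibrated by construction; the measured type-I rate is 0.043 at
alpha = 0.05 with power > 0.99 against a 10 /s dispersion at 0.3 /s noise.
An F-type statistic and the AIC of both models are reported alongside.

# The synthetic-data generators

Every pipeline stage has a generator that is a pure function of
(parameters, seed) and serializes its ground truth alongside the data.

**Dispersion experiments** (`make_dispersion_dataset()`) emulate the
acquired studies: 15 spins; 15N CPMG at 600/850 MHz with T = 32 ms and
CPMG frequencies 31.25-1000 Hz; amide-1H CPMG at 600/950 MHz with
T = 20 ms and 50-2000 Hz; 13C CPMG at 100-1000 Hz with T = 20 ms.
The packaged fixtures carry the published kinetics: wild type
(`k_ex` = 2600 /s, `p_minor` = 2.8%), H493A (2830 /s) and V517A (6800 /s).
The mutant minor populations are not printed; they were fixed once at 0.07
(H493A slightly stabilizes the minor state) and 0.45 (V517A nearly inverts
the populations). Shift differences are drawn uniformly within the
observed spans (4.7 ppm 15N, 1.1 ppm 1HN), with one spin pinned at each
span maximum so span recovery is testable. Base rates R2,0 are drawn
uniformly in ranges typical of an ~8 kDa domain at 15 C (7-13 /s for 15N,
14-26 /s for amide 1H). Intensities are `exp(-R2eff * T)` relative to a
noisy reference, with Gaussian noise of standard deviation `noise * I0`;
the default noise is 2% of `I0`, typical of well-behaved dispersion data.
Technical replicates are added at two random CPMG frequencies per spin and
dataset. Peak picking uses the conventional S/N >= 3 threshold: points
whose noisy intensity falls below three times the noise level are lost,
exactly as strongly exchange-broadened peaks vanish from real spectra.

Two features of real data are deliberately not emulated: peak overlap and
any spin-spin variation of the noise level. Passing recovery tests on
these data therefore demonstrates the correctness of the model and the
fitting machinery, not robustness to assignment or overlap artifacts.

A consequence worth knowing: for the V517A fixture the near-inverted
populations make `p_minor` weakly identifiable from fast-exchange CPMG
alone (the profiles constrain mainly `p_A p_B \Delta\omega^2` and the
dispersion timescale), and the strongest-shifted spins are broadened below
the peak-picking floor. The maximum-likelihood `k_ex` then scatters by
roughly +/- 10-15% between noise realizations -- not an optimizer artifact
(all starts converge to the same optimum; the noiseless fit is exact), but
a genuine identifiability limit of the experimental design, consistent
with the larger uncertainty reported for this variant in the source
analyses, which also drew on chemical-shift information.

**Sequence families** (`make_sequence_family()`) plant the two signatures
at the scored positions: group 1 draws large residues at 493 (H/Y/F/R),
small at 517 (V/A/T) and small at 541 (A/G/S); group 2 draws small at 493,
Ile/Leu at 517 and larger at 541 (L/F/Y/W/M); all sequences carry Y or F
at the anchor and Q/R/K at position 520. Other columns are uniform draws,
which makes the planted structure the only systematic signal.

**Breathing cages** (`make_breathing_cage()`) place pseudo-carbon atoms on
a Fibonacci lattice over a sphere of radius 6 Angstrom, enclosing a cavity
whose volume is analytically $(4/3)\pi(R - r_{vdW} - 1.09)^3$. The "open"
partner displaces a polar cap of atoms (chord radius 4 Angstrom) radially
outward; a single displaced atom of a dense shell opens nothing, because
its neighbors' exclusion spheres still seal the hole.

# Structure analysis choices

- **chi2 dihedral**: standard atan2 construction over CA-CB-CG-CD1, folded
  into (-90, +90] using the two-fold ring symmetry. Verified against an
  independent vector-algebra oracle and against the bio3d torsion
  convention.
- **Superposition**: Kabsch via SVD with the reflection guard, verified
  against bio3d's least-squares fit.
- **Morphing**: Kabsch superposition followed by per-atom linear Cartesian
  interpolation. The reference trajectory tool uses energy-refined
  interpolation; linear morphing differs from it most in the middle
  frames, which is why pocket-expansion values reproduced from deposited
  structures carry a wider tolerance (about +/- 15 Angstrom^3) than grid
  discretization alone would suggest.
- **Pocket volume**: cubic grid of spacing 0.5 Angstrom (default) snapped
  to the inclusion-sphere center; a point is deleted when within
  `vdW + 1.09` Angstrom of any heavy-atom center (Bondi radii; the 1.09
  Angstrom cutoff is the van der Waals radius of hydrogen and compensates
  for operating on heavy atoms only); the pocket is the 6-connected
  component containing the seed; volume = count x spacing^3. The inclusion
  region is a sphere of radius 8 Angstrom centered on the frame-0 ring
  centroid of the target residue -- exposed as configuration, since the
  reference method's region settings are not printed. The target residue
  is replaced by glycine in every frame so the complete pocket is
  measured. On the analytic cage the grid is accurate to ~3% at 0.5
  Angstrom spacing, exactly invariant under rotations about the grid
  center, and converges monotonically under grid refinement.

# Model-free analysis choices

The Lipari-Szabo spectral density
$J(\omega) = \tfrac{2}{5}\left[S^2\tau_c/(1+(\omega\tau_c)^2) +
(1-S^2)\tau'/(1+(\omega\tau')^2)\right]$, $1/\tau' = 1/\tau_c + 1/\tau_e$,
feeds the standard dipolar + CSA expressions for backbone 15N R1, R2 and
heteronuclear NOE. Constants are community defaults, documented as such:
N-H bond length 1.02 Angstrom, 15N CSA -172 ppm (field-independent),
CODATA gyromagnetic ratios. Tumbling is isotropic; the model set per
residue is {S2} and {S2, tau_e} with AIC selection; the shared tau_c is
fitted by a coarse scan plus golden-section refinement of the total
chi-square. Closed-loop recovery: S2 to better than 0.01 on noiseless
data and 0.05 at 3% noise for S2 >= 0.5.

# Chemical-shift logic

Peak geometry is computed in composite shift space with the
community-standard 0.14 weighting of 15N relative to 1H (the source
figures plot raw peaks without stating a metric, so the weighting is a
package choice). `collinearity_deviation()` reports the perpendicular
distance of the middle peak from the line through the outer two;
`fractional_position()` projects an observed peak onto the major-to-minor
axis, which under fast-exchange averaging estimates the minor-state
fraction; both routes to populations (shift projection and dispersion
fitting) are provided because the evidence in this system drew on both.

# Numerical and testing notes

- All randomness flows through explicit integer seeds; generators restore
  the caller's RNG state.
- Degenerate closed-form corners (element-propagator eigenvalue
  coalescence) fall back to numerical propagation, flagged per point.
- The slow-exchange overflow region of the dominant-eigenvalue expression
  is evaluated in log space.
- Test problem sizes are chosen to exercise the statistics at meaningful
  replicate counts while remaining routine on a laptop: the calibration
  study of the detection test uses 1000 null profiles of 8 points; the
  coverage study uses 200 replicate single-spin, two-field experiments
  with 20 Monte Carlo refits each; full-scale recovery uses the complete
  15-spin, four-dataset design.

# Known limitations

- Off-resonance R1rho, three-site exchange and pulse imperfections are out
  of scope; the CPMG propagator assumes ideal pulses and in-phase
  magnetization.
- Equal R2,0 in both exchanging states (a state-specific ΔR2 is not
  modeled; this keeps the two-site model identifiable).
- The ring-flip flatness analysis (analysis/03) shows that at the
  published rate bound of 50,000 /s a symmetric flip with a 13C shift
  difference of 2 ppm would still produce a 100-1000 Hz window amplitude
  of about 1.3 /s at 600 MHz; "flat within error" at that bound holds for
  shift differences up to about 1.7 ppm, a constraint worth keeping in
  mind when interpreting the bound.
- Linear morphing is not energy-refined; deposited-structure pocket
  expansions carry the corresponding tolerance.
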