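---
title: "Deconvoluting conformational exchange from Raman spectra"
author: "ramanmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvoluting conformational exchange from Raman spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanmix)
```

## The problem

Flexible biomolecules such as RNA nucleosides interconvert between a small
number of major conformers on picosecond-to-nanosecond timescales. A solution
Raman spectrum is therefore not the spectrum of any single structure: it is a
population-weighted average of the spectra of the exchanging conformers, with
the exchange showing up as band broadening and intensity redistribution.
Reading the spectrum the other way around — decomposing a measured spectrum
into conformer *sub-spectra* and interpreting the mixture weights as solution
populations — turns Raman spectroscopy into a probe of conformational
equilibria. `ramanmix` implements that decomposition and every support step
around it: conformer classification of trajectories, sub-spectrum synthesis
from either harmonic mode tables or polarizability time series, experimental
preprocessing, and seeded synthetic-data generators that give every stage a
known ground truth.

## Conformer coordinates

For a nucleoside the two dominant slow coordinates are the glycosidic torsion
$\chi$ (O4′–C1′–N9–C4 for purines, O4′–C1′–N1–C2 for pyrimidines) and the
ribose pseudorotation phase angle $P$. `pseudorotation()` computes $P$ and
the pucker amplitude $\tau_m$ from the five endocyclic torsions through the
generating identity

$$\nu_j = \tau_m \cos\!\big(P + 144^\circ (j-2)\big), \qquad j = 0,\dots,4,$$

inverted with the atan2 form so the map is exact: `pucker_torsions()` followed
by `pseudorotation()` round-trips to $10^{-13}$ degrees. The torsion index
convention ($\nu_2$ = C1′–C2′–C3′–C4′) is fixed so that $P \approx 18^\circ$
is *c3′-endo* (north) and $P \approx 162^\circ$ is *c2′-endo* (south).

Classification uses half-open intervals — *syn* for
$\chi \in [-90^\circ, 90^\circ)$, south for $P \in [90^\circ, 270^\circ)$ —
because a total, deterministic rule is needed at the boundaries and
open-interval conventions leave the boundary points unassigned. An optional hysteresis buffer (`label_trajectory(...,
hysteresis = 10)`) keeps the previous frame's state within a configurable
angular band of a boundary, suppressing the rate inflation caused by rapid
boundary recrossing; it is off by default so that raw classification remains the
baseline behavior. The buffer lives in the labelling step, not the kinetics step,
because only the labelling step still sees the angle series.

`populations()` counts label frequencies; `transition_kinetics()` estimates
exchange rates as counted transitions per unit occupancy time,
$k_{a\to b} = N_{a\to b} / T_a$, and mean lifetimes as mean contiguous dwell
times. Rates in the regime of interest (0.1–3.3 ns$^{-1}$ at 10 ps frames)
are recovered within a few percent from chains of $5\times10^5$ frames, which
is the length the tests use.

## Sub-spectra

Two routes produce conformer sub-spectra.

**Harmonic route.** A table of vibrational frequencies and Raman activities
(from a double-harmonic calculation) is frequency-scaled
(`scale_frequencies()`; the empirical factor is a user input; such factors are
method- and basis-set-specific), converted from activities to
intensities (`activity_to_intensity()`) using the standard excitation and
thermal-occupation correction

$$I_i \propto \frac{(\tilde\nu_0-\tilde\nu_i)^4 S_i}
{\tilde\nu_i \left[1 - e^{-c_2 \tilde\nu_i / T}\right]},$$

with $\tilde\nu_0 = 10^7/\lambda$ (532 nm and 293 K by default, matching the
measurement conditions the package targets), and broadened with
area-normalized Lorentzians of 5 cm$^{-1}$ FWHM (`lorentzian_broaden()`), the
intrinsic linewidth. Area rather than height scaling is used because for a
uniform width the two differ only by a global constant, which the final
max-normalization removes. `average_spectra()` averages the spectra of many
conformers drawn from an ensemble.

**Dynamics route.** For a polarizability time series $\alpha(t)$ (typically
0.5 fs steps over ~17.5 ps), `raman_from_polarizability()` forms the spectrum
as the Fourier transform of autocorrelation functions of the polarizability,
which captures local dynamics without polarizability derivatives. The tensor
is split (`tensor_invariant_series()`) into its isotropic mean
$\bar\alpha = \mathrm{tr}\,\alpha/3$ and traceless anisotropic part $\beta$,
and the two channels combine with the standard orientational-averaging
weights 45:7 (configurable). The ACF uses overlap-count (unbiased)
normalization — computed via FFT cross-correlation, which is numerically
identical to the direct sum but $O(n\log n)$ — so closed-form tests hold
exactly: $C(0)$ equals the series variance, and the unwindowed power spectrum
satisfies the discrete Parseval identity to floating-point precision. A Hann
lag window (default) controls leakage, zero padding (default 4×) refines the
frequency sampling, and an optional harmonic quantum-correction factor is
available but off by default since the choice is convention-dependent. A
spectrum whose peak power is below $10^{-10}$ times the total tensor variance
is reported as degenerate rather than normalized: such a channel contains
only floating-point residue.

Polarizabilities can be assembled from finite-field dipole traces
(`finite_field_polarizability()`): a forward difference against an explicit
zero-field reference at a default field strength of $5\times10^{-4}$ a.u.,
with central differences used automatically when traces under the negated
field are supplied. The raw tensor is symmetrized and the maximum asymmetry
reported. Dipoles themselves can come from Voronoi integration of gridded
electron densities (`read_cube()`, `voronoi_dipole()`): each voxel is
assigned to its nearest atom by plain Euclidean distance (the QM box is
non-periodic), ties to the lowest index.

## The mixture model

The core model writes the experimental intensity at grid point $x_i$ as a
weighted combination of rescaled, shifted sub-spectrum splines:

$$y_i^{\mathrm{conf},j}(r_j, s) = f^{\mathrm{fit},j}(r_j x_i + s),$$

with cubic splines $f^{\mathrm{fit},j}$ built from each (max-normalized)
sub-spectrum and evaluated as 0 outside the sub-spectrum's measured domain
(extrapolated cubics diverge, and the rescaling/shift can probe beyond the
measured range). The parameters — weights $w$, per-conformer rescalings $r$,
one global shift $s$ — minimize

$$L = \sum_i \Big( y_i^{\mathrm{exp}} - \sum_j w_j\, y_i^{\mathrm{conf},j} \Big)^2
  + L_{\mathrm{weight}} + L_{\mathrm{scaling}} + L_{\mathrm{shift}}$$

with the default constants $c_{\mathrm{weight}} = 10^8$,
$c_{\mathrm{rescaling}} = 10^2$, $c_{\mathrm{shift}} = 5\times10^8$,
$r_{\mathrm{eq}} = 0.05$, $s \in [0, 200]$ cm$^{-1}$. The weight penalty is
$c_{\mathrm{weight}}(\sum_j w_j - 1)^2$ by default: pinning the *linear* sum
to 1 is what makes the weights readable as relative populations. A variant
that squares the weights inside the sum is available via
`weight_penalty_variant = "literal_sum_of_squares"`. The scaling penalty,
$c_{\mathrm{rescaling}}\sum_j(|r_j - 1| - r_{\mathrm{eq}})^2$, attracts
$|r_j - 1|$ *toward* 5% rather than to zero — an unusual but deliberate form
that tolerates small frequency rescalings instead of fighting them; set
`r_eq = 0` to attract $r_j$ to exactly 1. The shift penalty is a step (flat
inside the bounds, $c_\mathrm{shift}$ outside); a logistic-smoothed variant
of width 1 cm$^{-1}$ exists for robustness.

Optimization is quasi-Newton (BFGS) from 50 random restarts — $w$ uniform on
the simplex, $r$ uniform in $1 \pm 2r_{\mathrm{eq}}$, $s$ uniform in
$[s_{\min}, s_{\max}]$ — keeping the best result, followed by a polish pass
that re-runs BFGS from the best point until no further improvement.
Multi-start is not optional here: single-digit restart counts demonstrably
terminate in aliasing minima where a few-percent rescaling plus a tens-of-
cm$^{-1}$ shift aligns the wrong peaks. The gradient is analytic (spline
derivatives included): with a penalty of scale $10^8$, finite-difference
gradients are dominated by penalty curvature error and stall the
squared-weight mode far from the optimum. The non-smooth pieces use the
subgradient $\mathrm{sign}(r_j - 1)$ and the flat step; restarts initialize
$s$ inside its bounds so the step is invisible unless a step leaves them.

Weights are unconstrained by default — no positivity is imposed — and
negative recovered weights are flagged; `nonnegative_weights = TRUE` switches
to a squared parametrization $w_j = v_j^2$. `populations_from_fit()`
normalizes the weights to percentages. `combine_fixed_weights()` implements
the complementary approach of imposing simulation-derived population weights
(renormalized over the simulated regions, which need not cover all four
conformer classes) instead of fitting them.

Residuals are computed against the unrenormalized weighted combination; the
weight penalty already pins the overall scale, and renormalizing inside the
loss would make the weights unidentifiable up to a common factor.

## Preprocessing

`subtract_background()` subtracts an identically acquired solvent spectrum
(scale 1 by default; a least-squares-optimal scale is available for
constructed tests). `asls_baseline()` is asymmetric least squares: an
iteratively reweighted Whittaker smoother with second-difference penalty
$\lambda$ and asymmetric weights ($p$ above the baseline, $1-p$ below). The
phrase "asymmetric least squares (third-order polynomial)" in the source
description is internally ambiguous — the cited method is a Whittaker
smoother, not a polynomial — so the smoother is the default and a
third-order-polynomial basis with the same asymmetric reweighting is
selectable. Defaults $p = 0.001$, $\lambda = 3\times10^4$ were chosen once
for ~1000-point spectra sampled at 1 cm$^{-1}$ with bands a few cm$^{-1}$
wide: on a cubic background they leave a residual below 1% of the background
range with no peaks present, and recover apex heights of 5 cm$^{-1}$
Lorentzians within 2%. Both parameters are exposed, and as with all AsLS
applications they should be re-tuned when the sampling or band widths differ
substantially. `truncate_window()` restricts to the 600–1600 cm$^{-1}$
analysis window, beyond which the water background makes baselines
unreliable.

## Synthetic data and what the tests show

Every input has a seeded generator with a machine-readable truth record:
`gen_subspectrum()` (analytic Lorentzian/Gaussian peak sums),
`gen_mixture_observation()` (the forward model above),
`gen_conformer_chain()` (discrete-time Markov chains with per-frame hop
probability $1 - e^{-k\,\Delta t}$, optionally with continuous torsion series
synthesized through the inverse pseudorotation relation plus wrapped-Gaussian
angular noise, default sd 8°), `gen_polarizability_trace()` (damped cosine
modes on fixed symmetric tensors), and `gen_density_cube()` (normalized
Gaussian blobs). Generators restore the caller's RNG state, so they are pure
functions of (parameters, seed). `gen_subspectrum()` normalizes the analytic
peak sum to maximum 1 *before* adding noise, so the recorded truth curve is
exactly the noise-free shape and the residual sd is exactly the requested
sigma.

Default synthetic sub-spectra use three well-separated peaks per conformer,
so weight-recovery tolerances measure the optimizer rather than
identifiability; heavily overlapping sub-spectra — the regime of real
pyrimidine spectra — remain harder, and recovery there degrades gracefully
rather than being certified by these tests. The generators emulate peak
positions, intensities, exchange statistics and noise, but not instrument
response, cosmic rays, solvent artifacts, or anharmonic/resonance effects;
passing tests therefore validate the machinery, not the physics of any
particular molecule.

Problem sizes used throughout the test-suite and the acceptance script are
the package's reference conditions: mixture fits on 600–1600 cm$^{-1}$ grids
(0.5 cm$^{-1}$ synthesis grids for end-to-end checks, 3 cm$^{-1}$ —
the experimental resolution — for unit tests), noise sd 0.01 on
max-normalized intensities, $5\times10^5$-frame chains at 10 ps, and
35,000-sample polarizability traces at 0.5 fs (17.5 ps).

## Known limitations

* Weight uncertainty is not quantified (no bootstrap is implemented); the
  restart-loss spread is reported as a diagnostic only.
* The literal scaling penalty means even a self-fit has a small non-zero
  data residual at the free optimum (the penalty prefers $|r-1| = 0.05$);
  freeze $r$ and $s$ for exact self-consistency checks.
* Rate estimation counts raw label changes; without the hysteresis option,
  boundary recrossing inflates rates when angular noise is large relative to
  the distance between conformer basins and the classification boundaries.
* The activity-to-intensity conversion fixes one standard prefactor
  convention; alternative conventions differ by mode-independent factors
  that max-normalization removes, but mode-*dependent* variants (e.g.
  $\tilde\nu_i$ exponents) are not offered.
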