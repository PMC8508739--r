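---
title: "Methods: equilibrium unfolding analysis from time-resolved tryptophan fluorescence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: equilibrium unfolding analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unfoldscope)
```

`unfoldscope` analyzes protein equilibrium unfolding monitored through
intrinsic tryptophan fluorescence, the workflow used to compare the
urea-induced denaturation of homologous multi-tryptophan proteins such as
bacterial luciferases. It covers four stages — global fitting of
time-correlated single photon counting (TCSPC) decays, decay-associated
spectra, denaturation-curve thermodynamics, and structure-based analysis of
the tryptophan microenvironment and Trp–Trp energy transfer — plus seedable
generators that produce every input synthetically. This vignette explains
the models, the choices behind them, and what the synthetic tests do and do
not demonstrate.

## 1. TCSPC decay model and global fitting

A TCSPC histogram records photon arrivals on a uniform channel grid
(default 0.027 ns/channel). The measured decay at emission wavelength
$\lambda$ is modelled as the instrument response function (IRF) $S(t)$
convolved with a multi-exponential decay law plus a constant background:

$$ I_\lambda(t) \;=\; S(t) \otimes \sum_{i=1}^{N} \alpha_{i\lambda}
   e^{-t/\tau_i} \;+\; b_\lambda . $$

`convolve_decay()` evaluates the discrete causal convolution of the decay
law, sampled at channel times, with the area-normalized (and optionally
fractional-channel shifted) IRF histogram. Because each exponential obeys a
one-step recursion on a uniform grid, the convolution is computed by an
exact recursive filter, so a model evaluation is $O(n)$ per component.
Treating IRF counts as point masses at channel centers is the conventional
discrete scheme; it reproduces a bare exponential exactly under a
delta-function IRF, and agrees with the continuous convolution integral to
well below 0.1% once the excitation pulse has decayed. On the pulse's
rising edge the discrete and continuous definitions differ by roughly
$S(t)\,\Delta t/2$ by construction — a property of the discretization, not a
numerical defect — which is why the quadrature-oracle test in the suite
compares the two beyond five IRF widths past the pulse peak.

`fit_decays()` performs the global (linked) fit: lifetimes $\tau_i$ are
shared across all traces while amplitudes $\alpha_{i\lambda}$ and
backgrounds $b_\lambda$ are free per wavelength. Numerically this uses
variable projection: for any candidate lifetime set the per-trace linear
parameters have a closed weighted least-squares solution, so the nonlinear
search (damped least squares, `minpack.lm`) runs only over the lifetimes
(and, optionally, a global IRF shift). Key choices:

* **Weights.** Neyman weights $1/\max(c_k, 1)$, the standard Poisson
  approximation in TCSPC. They keep the weighted residual variance near 1
  for well-specified data without special-casing empty channels.
* **Fit window.** From 5 channels before the IRF peak to the last channel
  with at least one count, per trace; configurable via `fit_window`.
* **Background.** One additive constant per trace, always estimated inside
  the linear solve rather than from pre-pulse channels; with the window
  above this is well conditioned whenever the tail is recorded.
* **Multi-start.** The lifetime search starts from one log-spaced heuristic
  plus `n_starts - 1` seeded log-uniform draws; the lowest global
  $\chi^2$ wins. This guards against the local minima that multi-exponential
  fits are known for while keeping the fit deterministic for a given `seed`.
* **Component count.** Three by default (protein decays typically resolve
  three components on this kind of instrument), configurable 1–4.
* **Reporting.** Lifetimes are sorted descending, so $\tau_1$ is the longest
  lived. Lifetimes below 1.5 channel widths are flagged `reliable = FALSE`:
  at 0.027 ns/channel a ~0.04 ns component shape is carried almost entirely
  by the IRF and its value should not be over-interpreted. Adjacent
  lifetime estimates within 5% of each other trigger a degeneracy warning.

Fit quality is summarized by the global $\chi^2$ and the per-channel
weighted residuals; on correctly specified synthetic data the reduced
$\chi^2$ falls in roughly $[0.8, 1.2]$ (slightly above 1 on average — the
small, well-understood bias of Neyman weighting at finite counts).

## 2. Decay-associated spectra

Given a converged global fit, the fractional contribution of component $i$
at wavelength $\lambda$ is

$$ f_{i\lambda} = \frac{\alpha_{i\lambda}\tau_i}{\sum_j
   \alpha_{j\lambda}\tau_j}, $$

and the decay-associated spectra partition the steady-state emission
spectrum: $I_{i\lambda} = f_{i\lambda}\, I_{ss}(\lambda)$
(`spectral_fractions()`, `decay_associated_spectra()`). The steady-state
spectrum is interpolated linearly onto the fitted wavelengths; requesting a
wavelength outside its range is an error rather than an extrapolation. Two
identities hold to numerical precision and are enforced by tests:
$\sum_i f_{i\lambda} = 1$ and $\sum_i I_{i\lambda} = I_{ss}(\lambda)$ at
every fitted wavelength. The scalar spectral-shift descriptor
$I_{320}/I_{360}$ (`intensity_ratio()`) is interpolated from the same
spectrum.

## 3. Denaturation curves and thermodynamics

Transition curves — any scalar optical parameter (a lifetime, the molar
ellipticity $\Theta_{222}$, $I_{320}/I_{360}$) versus denaturant molarity —
are fitted with a double-Boltzmann function
(`double_boltzmann()`, `fit_transition()`):

$$ y(u) = y_0 + A\left[\frac{p}{1+e^{(c_1-u)/k_1}} +
   \frac{1-p}{1+e^{(c_2-u)/k_2}}\right], $$

with shared baseline $y_0$, total amplitude $A$, amplitude fraction $p$,
midpoints $c_i$ ([Urea]$_{50\%}$, in M) and widths $k_i$ (M). Among the
several double-sigmoid parameterizations in circulation we chose the
shared-amplitude form because the fraction $p$ is then directly the share of
the total optical change carried by the first transition — the quantity used
to compare how sensitive different probes are to each unfolding stage. With
$p = 1$ the expression reduces exactly to a single Boltzmann, which is also
how `n_transitions = 1` is implemented.

Initialization takes midpoint guesses from the two largest steps of a
smoothed finite-difference derivative of the signal (requiring the two
candidates to be separated by at least a fifth of the urea range), widths
start at 0.3 M, and the optimizer runs with box constraints
($k_i > 0$, $p \in [0,1]$). Estimates are reported with $c_1 < c_2$
enforced by relabelling, so fits started with swapped midpoints converge to
identical ordered estimates. A constant signal, or an optimizer failure,
yields a flagged non-converged result rather than an exception; fitted
$\hat p$ outside $[0.05, 0.95]$ triggers a warning that the data may support
only one transition.

**Thermodynamics.** `thermo_from_fit()` maps each step to two-state
linear-extrapolation parameters: $m_i = RT/k_i$ and
$\Delta G_{H_2O,i} = m_i c_i$ ($R$ = 8.314 J mol⁻¹ K⁻¹, default
$T$ = 298.15 K). This is the standard correspondence between a Boltzmann
width on a denaturant axis and the m-value of a two-state transition, and
it is an interpretation: it assumes each step is an independent two-state
equilibrium and that the observed signal is a population-weighted average.
For multimeric proteins whose later transitions involve dissociation these
$\Delta G$ values should be read as apparent stabilities at the measured
protein concentration, not concentration-independent free energies.

## 4. Tryptophan microenvironment descriptors

Given PDB coordinates (parsed with `bio3d`, including multi-MODEL files,
altloc resolution by highest occupancy, and HELIX/SHEET records),
`microenv_report()` computes per tryptophan and per model the descriptor
set commonly used to rationalize per-residue fluorescence differences:

* $N_\Sigma$ — protein atoms within 7 Å of any atom of the tryptophan
  (packing density), own residue excluded;
* $N_{pol}$ — the polar (N, O; optionally S) subset of those;
* SASA — absolute and relative solvent-accessible surface area;
* $N_{C\text{-}term}$ — neighbors belonging to a designated C-terminal
  domain (default residues 236–355 of the α-subunit chain when chain roles
  are configured), a proxy for sensitivity to the first unfolding stage;
* $N_{sec}$ — the percentage of neighbors in helix/strand residues, a proxy
  for sensitivity to secondary-structure loss;
* $N_{\beta\text{-}sub}$ — neighbors from other-subunit chains within 7 Å of
  the side chain, a proxy for sensitivity to subunit dissociation;
* quencher contacts within 5.5 Å of the indole ring
  (`screen_quenchers()`), tagged by mechanism: Lys/Tyr proton donors,
  Cys sulfur, His/Gln/Asn amides and Asp/Glu carboxyls as electron
  acceptors, and backbone carbonyl carbons near the ring CE3 atom (the
  tryptophan's own carbonyl included for that mechanism, since
  own-backbone quenching is physically possible).

Hydrogens are excluded from all counts and areas by default so that crystal
structures (no hydrogens) and MD frames (with hydrogens) give comparable
numbers. SASA uses a Shrake–Rupley implementation with a deterministic
Fibonacci sphere lattice (default 960 points, probe 1.4 Å) and a fixed van
der Waals radius table (C 1.70, N 1.55, O 1.52, S 1.80 Å); no installed R
package provides SASA, so it is implemented here and validated against the
analytic isolated-sphere area (to < 1%) and a 20× denser lattice (to < 2%).
Relative SASA is the residue's in-context area divided by its area with all
other residues deleted. Note one numerical consequence of the fixed global
lattice: neighbor counts and distances are exactly invariant under
rigid-body motion, while SASA is invariant only to quadrature accuracy
(~1%) under rotation.

Secondary structure comes from the file's HELIX/SHEET records when present;
otherwise a dihedral-window fallback labels runs of ≥ 3 residues whose
φ/ψ fall in canonical helix or strand regions. The fallback is deliberately
coarse — it avoids an external assignment dependency — and can be disabled,
in which case the descriptor is reported missing.

## 5. Trp–Trp FRET geometry

`indole_geometry()` extracts the 9 indole ring atoms, the ring centroid
(geometric, or mass-weighted on request), the best-fit plane normal (SVD),
and a transition-dipole direction modelled as an in-plane unit vector at a
configurable angle from the projected CE3→NE1 long axis. The default angle
of −38° approximates the commonly assumed orientation of the
environment-sensitive ¹La transition moment of indole; because the exact
in-plane direction is a modelling convention rather than a measured
quantity, `fret_pair()` also reports the range of $\kappa^2$ and $E$ over a
±15° scan of both dipole angles. The orientation factor and transfer
efficiency follow the standard expressions

$$ \kappa^2 = (\cos\theta - 3\cos\theta_A\cos\theta_D)^2, \qquad
   E = \left[1 + \frac{2/3}{\kappa^2}\left(\frac{R}{R_0}\right)^6
   \right]^{-1}, $$

with $R_0 = 7.8$ Å for the Trp–Trp pair by default (the accepted value
given the uncertainty of the indole donor quantum yield and overlap
integral). $E$ is defined as 0 at $\kappa^2 = 0$ by continuity. Static
structures use geometric ring centers; `distance_distribution()`, which
histograms center–center distances across trajectory frames, defaults to
mass-weighted centers, matching how such distributions are conventionally
computed from MD trajectories — both conventions are overridable, and on an
idealized ring they differ by under 0.2 Å.

## 6. Synthetic data: what it emulates, and what it does not

The generators produce every input the pipeline consumes, under the
conditions the analysis assumes:

* `simulate_decays()` — 19 wavelengths (320–410 nm, 5 nm step), lifetimes
  5.1/1.9/0.1 ns, Gaussian IRF of 1.2 ns FWHM, 0.027 ns/channel, 1024
  channels, peak 10⁴ counts, Poisson counting noise. Component amplitude
  spectra are Gaussian bands with the long-lived component centered redder
  (350 vs 335/330 nm) and band heights chosen so the time-integrated
  ($\alpha_i \tau_i$) contributions split roughly 40/50/10% at the band
  centers — representative of a folded multi-tryptophan protein where the
  two long components dominate. Averaged over the full emission window the
  long component's broader, redder band raises its mean spectral fraction
  above the short-lived ones, which exercises wavelength-dependent
  fractions in the DAS step.
* `simulate_transition_curve()` — a double-Boltzmann truth with midpoints
  1.5 and 4.0 M urea, widths 0.3 M, 24 points over 0–8 M, 1%
  multiplicative Gaussian noise: a two-stage unfolding with the first
  transition below 2 M and the second near 4 M.
* `build_toy_structure()` / `simulate_trajectory()` — idealized planar
  indole rings placed at controlled separations and orientations, random
  single-atom background residues, and i.i.d. Gaussian frame jitter.

All generators are bit-reproducible per seed, and changing the seed changes
only the noise, never the expectations. What passing tests on these inputs
demonstrate: the estimators recover the parameters of their own generating
model at realistic counts and noise, the conservation identities hold, and
the geometric kernels agree with analytic and exhaustive oracles. What they
do not demonstrate: robustness to IRF drift or color shift, detector
afterpulsing and pile-up, correlated baseline error in denaturation series,
or physically realistic conformational dynamics — the jittered trajectories
have no covariance structure. Real-data conclusions still require the usual
experimental controls.

## 7. Problem sizes and numerics

The test suite and the acceptance script size their simulations to make
statistical statements while staying quick: 20 seeds for recovery medians,
10⁶ draws for the isotropic $\langle\kappa^2\rangle = 2/3$ check (standard
error ≈ 0.0009), 50 random structures for the neighbor-count oracle, 900–
1024 channels per decay. Tolerances follow the quantity's own precision:
conservation identities at 10⁻⁹, quadrature-based areas at 1–2%, recovery
checks at the dispersion observed across seeds. Optimizer tolerances are
set tight (`ftol`/`ptol` ≈ 10⁻¹²–10⁻¹⁴) so that reported estimates are
limited by data, not by early stopping; all randomness (multi-start draws,
noise) flows from explicit seeds, which is what makes the end-to-end
pipeline byte-reproducible.

## 8. Known limitations

* $\Delta G_{H_2O}$ from sigmoid widths inherits the two-state assumption;
  see §3.
* The ¹La dipole direction, and hence $\kappa^2$, carries the stated
  angular convention; use the reported sensitivity range rather than the
  point value when the orientation matters.
* The dihedral secondary-structure fallback is not a hydrogen-bond-based
  assignment and will disagree with DSSP near termini and irregular
  elements.
* mmCIF files, protonation states, and lifetime-distribution
  (maximum-entropy) decay analysis are out of scope.
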