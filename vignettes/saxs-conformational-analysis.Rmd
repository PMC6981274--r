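---
title: "Inferring domain opening from solution scattering: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring domain opening from solution scattering: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saxsens)
```

## The problem

A multi-domain protein whose crystal structure shows a closed, ligand-bound
conformation may adopt a different, more open conformation in solution when
the ligand is absent. Small-angle X-ray scattering (SAXS) is the natural
probe: it reports, orientation-averaged, the distribution of pairwise
distances inside the particle. `saxsens` implements the complete chain of
reasoning needed to turn a 1-D scattering curve plus a crystallographic
ground state into a statement about domain motion:

1. model-free invariants of each curve (Guinier radius of gyration and
   forward scattering, dimensionless Kratky curve, Porod volume);
2. inversion of the curve into the real-space pair-distance distribution
   P(r) with its maximum dimension d_max;
3. prediction of scattering from coordinates (coarse-grained Debye sum);
4. generation of stereochemically plausible candidate conformations by
   rigid-body perturbation of the ground state under distance restraints
   derived from the data themselves;
5. scoring of candidates, singly or as weighted two-state mixtures,
   against the measured curve by reduced chi-square.

The same package carries the two companion analyses this kind of study
needs: least-squares structure superposition (including a
sequence-independent correspondence search and per-domain temperature-factor
summaries, which flag the mobile domain in the crystal), and
single-exponential fitting of single-turnover nicking time courses.

## Models and conventions

### Guinier analysis

At low q, `I(q) = I(0) exp(-q^2 Rg^2 / 3)`. `guinier_fit()` performs a
weighted linear fit of ln I against q^2, choosing the window
self-consistently so that `q * Rg <= 1.3` everywhere inside it (the common
convention for globular particles; the limit is a parameter). Weights are
`(I/sigma)^2`, the delta-method weights for ln I.

The linear fit at that window width is slightly biased for genuinely
compact shapes: for a uniform sphere
`ln I = -q^2 Rg^2/3 - (qR)^4/350 + O(u^6)`, so the fitted Rg is high by
about `(q_max Rg)^2 / 140` (2% at `q Rg = 1.3`). When the quadratic term
in q^2 is statistically significant inside the converged window (|t| > 3)
and shifts Rg by more than 0.2%, the fit reports the extended (quadratic)
model's Rg and I(0) instead; this reduces the sphere bias to ~0.1% while
leaving ideal-Gaussian data untouched. The flag `curvature_corrected`
records which estimate was returned. On noisy data the quadratic term is
usually not resolvable and the conventional linear estimate stands.

### Dimensionless Kratky transform

`dimensionless_kratky()` returns `y = (q Rg)^2 I(q)/I(0)` against
`x = q Rg`. A compact globular particle peaks at the Guinier-Kratky point
`(sqrt(3), 3/e)`; an ideal random coil rises to a plateau of 2. The curve
is invariant under intensity rescaling by construction, so it isolates
shape from concentration and calibration.

### Moore indirect Fourier transform

`moore_pr()` represents the pair-distance distribution as a truncated sine
series, `p(r) = r * sum_n a_n sin(n pi r / dmax)` on `[0, dmax]`, which
enforces `p(0) = p(dmax) = 0`. Each basis term has a closed-form
reciprocal-space image, so the coefficients come from a weighted linear
least-squares fit to the measured intensities (solved by SVD; a condition
number above 1e10 raises an error suggesting fewer terms or a smaller
dmax). Conventions, stated because P(r) normalisations differ between
programs:

* `i0_real = 4 pi * integral p(r) dr`;
* `rg_real^2 = integral r^2 p dr / (2 integral p dr)`;
* the default number of terms is the Shannon number
  `ceil(q_max dmax / pi)` **plus two**, capped at 30. The bare Shannon
  count is the information-theoretic minimum, but for compact shapes it
  leaves ~2% truncation bias in the derived I(0); two extra channels
  remove it without inviting oscillatory over-fitting.

### Choosing d_max

The data do not hand over d_max; `estimate_dmax()` scans a candidate grid,
scoring each candidate by the reciprocal-space reduced chi-square plus a
negativity penalty, `integral |min(p,0)| dr / integral |p| dr`. Every
candidate gets its own Shannon+2 basis so none is handicapped by
truncation. Among candidates within 5% of the best score the smallest
dmax wins: the most parsimonious particle size that explains the data
without driving p(r) negative. Too-small candidates fail loudly (chi-square
explodes); too-large candidates buy nothing and begin to oscillate.

### Porod volume

`porod_volume()` computes `V_p = 2 pi^2 I(0) / Q` with
`Q = integral_0^q_cut q^2 I(q) dq`, filling the unmeasured `[0, q_first]`
gap with the Guinier model and integrating the measured grid by
trapezoids. The cut defaults to `8/Rg` (truncated to the measured range)
because published analyses rarely state their cut; the value used is
recorded in every report.

### Coarse-grained Debye calculator

`debye_intensity()` evaluates
`I(q) = sum_i sum_j f_i f_j sin(q r_ij)/(q r_ij)` exactly (all pairs) for
up to 5,000 beads — a ~640-residue protein at one bead per residue stays
comfortably on the exact path — and switches to a pair-distance histogram
above that. The histogram uses per-bin centroid distances and a
second-order within-bin-variance correction, keeping it within 0.5% of the
exact sum at the default 0.5 A bin width. `coarse_grain()` places one bead
per C-alpha; the default `calpha-weighted` scheme sets each form factor to
the residue's non-hydrogen electron count, `calpha-uniform` (f = 1) is
retained for analytic tests.

There is deliberately no hydration layer, excluded-volume term, or
q-dependent atomic form factor. Absolute chi-square values against real
measured curves will therefore differ systematically from calculators that
model the solvent; the package's inferences are built on chi-square
*contrasts* (closed rejected, open accepted) and on synthetic data where
the generating model is the calculator itself.

### Restraints and rigid-body sampling

`default_decomposition()` encodes the architecture of a two-CARF-domain
effector nuclease: the two CARF domains (residues 3-151 and 293-422) form
one rigid unit — their mutual arrangement builds the ligand-binding site
and is conserved — while the nuclease-like domain (168-276) and the
nuclease domain (426-638) are independent rigid bodies. Inter-domain
loops (152-167, 277-292, and the hinge loop 423-428) are unconstrained
tethers; tether residues are stripped from any rigid group that nominally
covers them, so the hinge loop belongs to no rigid body.

`build_restraints()` turns the experimental P(r) into sampling bounds: for
every pair of rigid groups with ground-state centre-of-mass separation d0,
the allowed window is `[max(0, d0 - pi/q_max), min(dmax, d0 + pi/q_max)]`.
`pi/q_max` is the nominal real-space resolution of the measurement — the
data cannot distinguish COM shifts smaller than that — and no intra-particle
distance may exceed the P(r)'s maximum dimension. The window modes
(`window:5`, `window:10`) additionally cap each mobile group's COM
displacement from its crystallographic position at 5 or 10 A, encoded as
anchor restraints; whether such caps should bound COM displacement or
all-atom RMSD is genuinely open, and COM displacement was chosen because it
matches the COM-based restraint machinery (the choice is recorded in the
restraint set's provenance).

`sample_conformations()` runs a constant-temperature Metropolis walk over
rigid-body placements: each proposal rotates every mobile group about its
COM by up to 15 degrees and translates it by up to 5 A (defaults), and is
accepted iff it satisfies every restraint window, anchor, linker tether,
and clash criterion — the target density is uniform over the allowed
region. The state is recorded every 10 accepted moves; the default request
of 2,430 conformations mirrors the scale of the original ensemble the
package emulates. Three numerical guards matter:

* **linker tethers**: the gap between the residues flanking a linker may
  not exceed `3.8 A * (linker length + 1) * stretch factor` — a fully
  extended peptide at 3.8 A per residue;
* **clashes**: inter-group C-alpha contacts closer than 3.0 A are
  rejected, but the threshold is relaxed per group pair to the ground
  state's own closest contact, so a valid ground state is never frozen by
  its own geometry;
* **determinism**: the walk is a pure function of the seed; the RNG state
  of the session is saved and restored.

If fewer than 1% of the first 10,000 proposals are accepted the sampler
stops and asks for looser parameters rather than burning time silently.

### Ensemble scoring

`chi2()` uses `chi^2 = 1/(N-1) * sum((I_exp - c I_calc)^2 / sigma^2)` with
the analytic scale `c = sum(I_e I_c/sigma^2)/sum(I_c^2/sigma^2)`; the
`N-1` accounts for the one fitted scale. A constant background term is
off by default (flag `fit_constant`), since whether published multi-state
fits subtracted a constant is usually unknowable; both modes are
available. Calculated curves are interpolated linearly in q onto the
experimental grid; a partial overlap is used with a warning.

`best_single_state()` is an argmin with lexicographic tie-breaking (pool
order cannot change the answer). `multi_state_fit()` enumerates all pairs
for k = 2 (the default, matching the minimal-ensemble idea: the smallest
number of states that explains the data) and solves each subset's
non-negative weights by NNLS (`pracma::lsqnonneg`), normalising weights
to sum to one with the overall scale refit; k > 2 grows the best pair
greedily. Nesting guarantees `chi2(k=2) <= chi2(k=1)`.

### Nicking kinetics

`normalize_lanes()` converts gel band volumes to fraction-cleaved using the
within-lane supercoiled fraction first (`SC/(SC+N+L)`), then normalising to
the zero-time lane — the within-lane ratio cancels loading and scanner-gain
differences, which is why it is the default; direct SC-band normalisation
is available behind a flag. `fit_single_exponential()` fits
`f(t) = A(1 - exp(-k t))` to replicate means by nonlinear least squares
(`nls`, with a bounded Levenberg-Marquardt fallback for degenerate cases
such as exactly noise-free data), weighting by the inverse variance of the
replicate mean when there are two or more replicates. The curve is pinned
to `f(0) = 0` because zero-time controls are quenched immediately; an
offset term is available behind a flag.

## The synthetic-data generator

`make_two_state_toy()` builds a three-domain particle (120 beads per
domain, uniform in 15 A spheres, domains packed in contact along a line)
in a closed state and an open state in which the terminal domain is
translated outward by 25 A — a hinged domain opening with known truth:
the open state has larger Rg and a d_max larger by almost exactly the
hinge translation. Consecutive domains are tethered (effective linker
length 10 residues) so the sampler's linker machinery is exercised while
still allowing the full 25 A opening.

`simulate_profile()` applies multiplicative Gaussian noise whose relative
standard deviation grows toward high q
(`noise_level * (1 + 5 q / q_max)`, 1% at q = 0 by default), as in real
detectors where the signal falls orders of magnitude; the sigma column
carries the true noise level, which is what makes the chi-square
calibration (`mean chi2 ~ 1` against the generating model) meaningful.
The q grid used in the worked analyses spans 0.008-0.12 1/A: with a 25 A
hinge, the restraint half-width `pi/q_max ~ 26 A` is just wide enough
that the true open state is inside the allowed region — the same
consistency a real experiment has, where the restraints come from the
data that the open state itself produced.

What the generator deliberately omits: interparticle interference,
buffer-subtraction artefacts, detector-specific error correlations,
hydration-shell contrast, and side-chain-level structure. Tests passing
on these toys therefore demonstrate the correctness of the estimators and
the samplers, not instrument-grade accuracy on real curves.

## Known limitations

* SAXS is orientation-averaged: conformations with very different domain
  *directions* but similar pair-distance spectra fit equally well. The
  pipeline reports the COM displacement of the best-fitting model, but
  the displacement direction is not identifiable from one curve, and the
  best-fit displacement magnitude can exceed the true one whenever a
  different geometry mimics the same P(r).
* The correspondence search in `align_domains()` is an iterative
  nearest-neighbour trim seeded by a best-matching gapless window, not a
  full distance-matrix alignment; matched counts on distantly related
  folds are comparable to, but not identical with, DALI-style results,
  and structures with exact internal translational symmetry (ideal
  infinite helices) can admit shifted self-matches.
* The Porod volume depends on the integration cut when the measured range
  is short; the cut used is always recorded.
* Problem sizes in the shipped analyses (3 x 120-bead toys, 120-point
  curves, 150-600 conformations, 20-seed recovery studies, 100-trial
  kinetics simulations) were chosen so each stage completes in seconds to
  a couple of minutes while keeping every statistical criterion
  well-resolved; all are parameters, and the full 2,430-conformation runs
  simply take proportionally longer.

## Reproducibility

`run_conformational_analysis()` executes the whole chain from one config
and returns a report embedding every numerical convention used (Guinier
limit, Moore terms, Porod cut, restraint mode and bounds, clash distance,
chi-square convention, seed, package version), so two runs can be diffed
assumption by assumption. Reports serialise to JSON with full-precision
floats; the same seed gives byte-identical numeric content.
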