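---
title: "Hydration-site thermodynamics with hydrosite: models, estimators and their validated regime"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydration-site thermodynamics with hydrosite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrosite)
```

## The model

Water molecules buried in protein cavities are strongly ordered by hydrogen
bonding. Inhomogeneous fluid solvation theory (IFST) expresses the
contribution of each such water to the hydration free energy as a per-site
energy/entropy ledger against pure bulk solvent:

$$\Delta G_{IFST} = \Delta E_{IFST} - T\,\Delta S_{IFST},$$
$$\Delta E_{IFST} = E_{sw} + E_{ww} - n\,E_{bulk}, \qquad
  \Delta S_{IFST} = S_{sw} + S_{ww} - n\,S_{bulk}.$$

$E_{sw}$ is the mean solute–water interaction energy over the frames where
the site is occupied; $E_{ww}$ (like $E_{bulk}$) is *half* the interaction
energy of the site water with all other waters, so that summing per-water
values conserves the total pair energy. The entropies are relative to the
uniform bulk reference: number density $\rho$ over positions and the full
rotation group (volume $8\pi^2$) over orientations.

Everything is computed from rigid-body poses: the oxygen position plus a
unit quaternion for the rotation from the laboratory frame to a fixed
molecular body frame (origin at the oxygen, $z$ along the H–O–H bisector,
molecule in the $xz$ plane, hydrogen 1 at $+x$). The body-frame convention
is arbitrary — any fixed choice yields identical pose–pose distances — and
the test suite checks that entropy estimates are exactly invariant under a
global rigid motion of the laboratory frame.

### Distances and the solute–water entropy

The configuration-space metric mixes ångströms and radians as raw numbers:

$$d_{trans} = \lVert r_1 - r_2 \rVert,\qquad
  d_{orient} = 2\arccos\lvert q_1 \cdot q_2 \rvert,\qquad
  d_{total} = \sqrt{d_{trans}^2 + d_{orient}^2}.$$

The absolute value in $d_{orient}$ handles the quaternion double cover; the
twofold molecular symmetry of water is deliberately *not* folded in, because
the symmetry number cancels between the sample entropy and the uniform
reference. No unit-weighting factor is introduced in $d_{total}$: the bulk
density $\rho$ carries the entire dimensional bookkeeping of the entropy
formulas.

$S_{sw}$ is estimated from each sample's distance to its $k$th nearest
neighbour among all other occupied frames ($k = 1$ in production; any $k$
is supported and cross-checked),

$$S_{sw} = R\left\{\frac 1n \sum_i
   \ln\!\Big[\frac{n\, d_{total,i}^{6}\, \pi\, \rho}{48}\Big]
   + \gamma\right\},$$

the 6-dimensional first-nearest-neighbour form with Euler's constant
$\gamma$ as the $k=1$ bias correction. The 12-dimensional analogue over
pair distances $d_{pair} = \sqrt{d_{total}^2 + d_{total}'^2}$ (constant
46080, reference $64\pi^4/\rho^2$) gives the joint entropy of a
synchronized pair of sites.

### Water–water correlation by permuted fill modes

The additional correlation between two cavity waters beyond what their
separate solute-frame distributions capture is a mutual information. It is
estimated by *decorrelating* the pair series: site-1 poses keep their frame
order while site-2 poses are reassigned by a random permutation of frames,
which preserves both marginals exactly and destroys the joint structure.
With $d_{perm}$ the nearest-neighbour pair distances of the permuted
series,

$$I_{ww} = \frac Rn \sum_i \ln\frac{d_{perm,i}^{12}}{d_{pair,i}^{12}} \ge 0
  \text{ in expectation},$$

and $S_{ww} = -\sum_{pairs}(I_{ww} + S_{vol})$ over site pairs whose
centers lie within 4.0 Å. Because both terms are 12-dimensional estimates
on the same $n$, the additive nearest-neighbour bias cancels by
construction. A note on orientation: some presentations write this
difference with the ratio inverted; the implemented sign is fixed by the
requirement that $I_{ww}$ is a Kullback–Leibler divergence (nonnegative in
expectation, zero for independent sites) and that ordered pairs contribute
*unfavourably* to the free energy through $-T S_{ww} > 0$, which is also
the sign the benchmark tables carry. The decomposition route
$I_{ww} = S^*_{sw} + S^*_{sw'} - S_{sww'}$ is shipped as a diagnostic
(`mi_decomposition_check()`) but is not the production estimator: it mixes
6- and 12-dimensional nearest-neighbour biases that do not cancel (see
*Validated regime* below).

In the per-site report, each member of a pair is assigned half of the
pair's $-(I_{ww} + S_{vol})$, mirroring the half-share convention of
$E_{ww}$, so cavity totals are conserved. $S_{vol}$ defaults to zero —
appropriate for buried sites, where the regions of joint solute–water
density are tiny — and the bulk-water value $-0.99$ cal/mol/K is shipped
as the constant `SVOL_BULK` for sensitivity analyses only.

### Energies, cycle arithmetic and blocks

Interaction energies are direct Lennard-Jones + Coulomb sums with
Lorentz–Berthelot combination, the TIP4P-2005 water model built in (LJ on
oxygen; charges on the hydrogens and on the M site, which is rebuilt
geometrically from each pose), optional CHARMM-style switching of the LJ
term between 9.0 and 11.0 Å, and optional minimum-image wrapping in an
orthorhombic box. No Ewald summation is performed: lattice-sum
electrostatics belong to the sampling engine, while the per-site ledger is
defined on plain interaction energies. This is the one deliberate
difference from typical production simulation settings and is configurable
(`scheme = "none"` or `"switched"`).

The binding free-energy cycle is pure arithmetic around user-supplied
alchemical legs: $\Delta G_{bind} = \Delta G_{exnihilation} -
\Delta G_{insertion} + \Delta G_{restrain}$, with the analytic restraint
penalty $\Delta G_{restrain} = -RT\ln[C_0 V_{harm}]$,
$V_{harm} = (2\pi RT/k_{harm})^{3/2}$. At $k_{harm} = 0.5$ kcal/mol/Å²,
300 K and $C_0 = 55$ M (0.03312 molecules/Å³) this is $+0.23$ kcal/mol.
The penalty increases with $k_{harm}$ and *decreases* with $C_0$: a higher
bulk concentration means less entropy is lost on confinement.

Error bars come from disjoint random blocks (`block_partition()`): every
quantity is recomputed per block and reported as mean ± between-block SD.
Disjointness keeps the SD a clean between-block estimate; a bootstrap mode
is available behind a flag.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `rho` | 0.03324 | molecules/Å³ | bulk TIP4P-2005 number density |
| `E_bulk` | −11.5748 | kcal/mol | bulk half water–water energy |
| `S_bulk` | −15.5097 (`"printed"`) | cal/mol/K | bulk excess entropy |
| `S_bulk` | −15.416 (`"consistent"`) | cal/mol/K | $1000(E_{bulk}-\Delta G_{ins})/T$ |
| `temperature` | 300 | K | analysis temperature |
| `dG_insertion` | −6.95 | kcal/mol | bulk insertion of a fixed water |
| `k_harm` | 0.5 | kcal/mol/Å² | restraint force constant |
| site `radius` | 1.2 | Å | capture radius for assignment |
| `pair_gate` | 4.0 | Å | site-center cutoff for $I_{ww}$ pairs |
| `n_permutations` | 8 | — | fill permutations averaged per $I_{ww}$ |
| `k` | 1 | — | neighbour order of the estimators |

Two $S_{bulk}$ conventions ship because the printed constant and the one
implied by $E_{bulk}$ and $\Delta G_{insertion}$ differ by about 0.09
cal/mol/K; benchmark-table arithmetic closes at 0.01 kcal/mol only under
the consistent convention ($T S_{bulk} = E_{bulk} - \Delta G_{insertion} =
-4.62$ kcal/mol), so table-reproduction tests use it while `"printed"`
remains the default constant. The number of fill permutations is exposed
because the construction itself does not fix it; averaging over 8 reduces
permutation noise well below the seed-to-seed scatter at the sample sizes
used here.

## The synthetic generators and what they do (not) emulate

Every estimator is validated against generators with closed-form
references (`sample_site()`, `sample_correlated_pair()`); each generated
series carries its analytic value, so round-trips are self-describing.
Orientations are always uniform on the rotation group (sampled by
normalizing 4-D Gaussians, verified against the Haar rotation-angle law
$\propto \sin^2(\theta/2)$), which makes the orientational relative
entropy exactly zero and leaves the translational closed forms exact:

* `uniform_box` (edge 1 Å): $S_{sw} = R\ln(V\rho)$;
* `gaussian_well` ($\sigma = 0.5$ Å): $S_{sw} = R[\tfrac32\ln(2\pi e\sigma^2) + \ln\rho]$ — the default spread corresponds to a crystallographic B-factor near 20 Å² via $\sigma = \sqrt{B/8\pi^2}$, typical of ordered buried waters;
* `harmonic_boltzmann` ($k_{harm} = 0.5$ kcal/mol/Å², 300 K): the Gaussian with $\sigma^2 = RT/k_{harm}$ per axis, matching the restraint construction of the free-energy cycle;
* `correlated_pair` ($\sigma = 0.5$ Å, centers 2.8 Å apart — a hydrogen-bond O–O distance): jointly Gaussian translations with per-axis correlation $r$, independent uniform orientations, $I_{ww} = -\tfrac32 R\ln(1-r^2)$.

What they do **not** emulate: the orientational ordering of real
hydrogen-bonded cavity waters (real $S_{sw}$ values near −24 cal/mol/K are
dominated by it; the generators' uniform orientations leave only the
translational part), cavity-wall confinement, the protein's electrostatic
field, or time correlation between frames (samples are i.i.d., whereas MD
snapshots at 5 ps spacing are nearly so but not exactly). Passing the
validation suite therefore demonstrates estimator correctness on known
distributions, not force-field realism.

## Validated regime and numerical behaviour of the estimators

The validation suite (unit tests plus the acceptance tests) runs the
single-site estimators at $n$ up to 16000 over 20 seeds and the
pair/mutual-information estimators at $n = 4000$–16000; these sizes match
the source data scale (blocks of 2000 from 20000 snapshots) while keeping
the whole suite within minutes on one CPU. Four findings shape how the
estimators should be used:

1. **Smooth localized distributions are the estimator's home turf.** For
   the harmonic/Gaussian wells at ångström-scale spreads the
   first-neighbour estimate recovers the closed form within the
   seed-to-seed standard error at $n = 16000$, and the error decays as a
   power law in $n$ throughout.

2. **Hard support boundaries bias the estimate upward.** For the uniform
   box, neighbour balls of boundary points protrude into empty space, so
   the estimator systematically overestimates the entropy (several tenths
   of a nat at $n = 16000$ for a 1 Å box). The error still decreases
   monotonically with $n$, but slowly; tight closed-form recovery on
   compact supports should not be expected at desk-scale $n$. Real
   hydration-site distributions are smooth and boundary-free, so this
   mode matters for synthetic validation, not production.

3. **Sub-ångström spreads expose the curvature of the rotation group.**
   The estimator replaces the true metric ball volume by the Euclidean
   $\pi^3 d^6/6$; on the rotation group the exact ball volume is
   $8\pi(\theta - \sin\theta)$, smaller by $O(\theta^2)$. When the
   translational spread is small, the neighbour balls are
   orientation-dominated and this curvature leaves a small negative bias
   (a few hundredths of a cal/mol/K at $n = 16000$ for a 0.5 Å well) that
   decays like $n^{-1/3}$ — physically negligible (≲ 0.015 kcal/mol on
   $-T\Delta S$) but resolvable against the tiny seed-scatter SE.

4. **The permuted-fill mutual information is reliable near independence
   and conservative for strong correlation.** For independent pairs the
   estimate is centred on zero (its own bias cancellation at work). For
   strongly correlated translations ($r \gtrsim 0.4$ at 0.5 Å spreads) it
   *underestimates* the Gaussian closed form at desk-scale $n$: six of
   the twelve coordinates are independent uniform orientations whose
   O(1)-radian scale dominates the neighbour balls, while the correlation
   lives at the ångström translational scale. The error shrinks with $n$
   but not on a clean power law — a known property of this estimator.
   Production $I_{ww}$ values for cavity waters are small (≈ 0.1
   cal/mol/K), squarely in the validated near-independence regime. The
   entropy-decomposition route (6D + 6D − 12D) inherits a dimensional bias
   mismatch and disagrees with the permuted-fill route on strongly
   correlated data; it is shipped as a diagnostic only.

## Numerical choices and degenerate inputs

* The $\arccos$ argument in $d_{orient}$ is clamped to $[0,1]$: the inner
  product can exceed 1 by ~1e−16.
* Quaternions are reported on the canonical hemisphere (nonnegative scalar
  part; first nonzero component positive at the boundary).
* Nearest-neighbour searches are exact brute force in compiled code
  (approximate search would bias the distance distribution); the inner
  loop prunes with $\arccos x \ge \sqrt{2(1-x)}$ so the expensive
  $\arccos$ is evaluated only for genuine candidates.
* Duplicate samples (zero nearest-neighbour distance) raise an error by
  default; an opt-in jitter of 1e−10 Å breaks ties — a silent $\pm\infty$
  is worse than an explicit contract.
* Collinear O/H/H atoms, mismatched O–H bond lengths (> 20%) and H–O–H
  angles outside (60°, 180°) are rejected at pose construction.
* Water–site assignment is greedy by increasing distance with exact ties
  broken by lexicographic site id; for well-separated sites (gaps > 2×
  radius) it coincides with exhaustive optimal matching, which the tests
  verify by enumeration.
* Frames where a site is transiently empty are dropped from that site's
  series ($n$ in the estimator is the number of occupied frames);
  occupancies below 0.99 trigger a warning because buried cavity sites
  are normally fully occupied.
* The pair gate is applied to the fixed site-center separation, not
  per-frame O–O distances: sites, not frames, define pairs here.

## Limitations

The framework assumes a fixed (rigid) solute: a mobile protein blurs the
probability densities and the entropies lose their meaning as two-particle
terms in a solute frame. Correlations are truncated at the two-particle
level — no triplet (three-site) terms — and the excluded-volume integral
$S_{vol}$ is not evaluated, only assumed zero (buried sites) or supplied
as a constant. Alchemical legs of the binding cycle are inputs, never
sampled. Trajectory input covers the plain-text snapshot dialect, PDB and
DCD (via bio3d); XTC is not supported. Concentrated-orientation synthetic
generators (which would exercise the orientational part of $S_{sw}$
against a non-trivial reference) are not provided; the orientational
machinery is instead validated through the exact invariance, double-cover
and Haar-marginal tests.
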