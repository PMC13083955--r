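---
title: "Coarse-grained groove-occupancy analysis of multidomain proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained groove-occupancy analysis of multidomain proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GrooveSim)
```

## The scientific problem

Many multidomain proteins combine folded domains with long intrinsically
disordered regions (IDRs).  A recurring question is whether particular
segments of the IDR — for example transient amphipathic helices — make
specific contacts with a folded domain, such as the hydrophobic groove of
a STI1/DP2-type helical domain.  Because these contacts are transient and
the chain is heterogeneous, the natural tool is a residue-level
coarse-grained simulation of the single chain, followed by a geometric
classification of which IDR residues sit inside the groove in each frame,
normalized against a null model in which all attractive interactions are
switched off.

GrooveSim implements that full workflow:

1. a one-bead-per-residue chain model with hydropathy-scaled short-range
   attraction, screened electrostatics, harmonic backbone bonds and an
   elastic-network model (ENM) for folded domains;
2. Langevin dynamics over independent replicas;
3. a three-test geometric groove-occupancy classifier with an
   excluded-volume baseline and fold-enrichment reporting;
4. ensemble observables used for validation against experiment (radius
   of gyration, effective concentration of tethered domains, Guinier
   fits of small-angle scattering profiles);
5. the NMR observable calculators that accompany such studies
   (chemical-shift perturbations, secondary shifts, relaxation-rate
   fits, heteronuclear NOE).

## The chain model

Each residue is a bead at its residue center; per-residue parameters
(stickiness $\lambda \in [0,1]$, size $\sigma$, charge, mass) are read
from a bundled CSV (`loadParameterTable()`), the published defaults of
the hydropathy-scale model family this simulator implements.  Every
constant is overridable.

Pair interactions:

* **Short-range (Ashbaugh–Hatch form).**  With
  $L(r) = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6]$, the energy is
  $L(r) + (1-\lambda)\epsilon$ for $r \le 2^{1/6}\sigma$ and
  $\lambda L(r)$ beyond, truncated at 2 nm.  Both branches equal
  $-\lambda\epsilon$ at $2^{1/6}\sigma$, so the potential is continuous
  for every parameter combination (a property the test suite checks for
  randomized $(\lambda, \sigma, \epsilon)$).  $\epsilon$ defaults to
  0.8368 kJ/mol.  Pair parameters combine arithmetically.
* **Electrostatics (Debye–Hückel).**  $B(\epsilon_r)\, q_i q_j
  e^{-\kappa r}/r$ with $B = 138.935/\epsilon_r$ kJ nm/mol, the
  temperature-dependent water dielectric, and $\kappa$ from the ionic
  strength; truncated at 4 nm.  Charges come from fixed valences
  (D/E $-1$, K/R $+1$) plus a Henderson–Hasselbalch fractional histidine
  charge, with optional terminal charges — this is how pH enters the
  model.
* **Bonds.**  Harmonic springs between consecutive beads
  ($r_0 = 0.38$ nm, $k = 8033$ kJ/mol/nm²).
* **Elastic network.**  Within each folded-domain restraint group, every
  pair with $|i-j| \ge 2$ closer than 0.9 nm in the reference structure
  is harmonically restrained at its reference distance
  ($k = 700$ kJ/mol/nm²).  Restrained and bonded pairs are excluded from
  non-bonded interactions.  A brute-force $O(n^2)$ enumeration is the
  test oracle for the restraint set.

Two topology variants derive from a base chain:

* `excludedVolumeVariant()` zeroes all $\lambda$ **and** all charges —
  the baseline of occupancy expected from connectivity and sterics
  alone.  We zero charges by default because the variant is meant as an
  excluded-volume null model; a `keepCharges` flag restores
  electrostatics for users who read the null model more narrowly.
* `boundComplexVariant()` merges two restraint groups in a supplied
  bound pose, adding inter-group restraints for every cross-group pair
  within the ENM cutoff in that pose (the mechanism used to hold a
  UBL–UBA-type domain pair docked).

Buried-residue stickiness rescaling at bead resolution is approximated
by a coordination-number proxy (`buriedLambdaScale`,
`buriedMinNeighbors`); because it is an approximation of a surface-area
based scheme and not the scheme itself, it defaults to off.

## Dynamics

`runLangevin()` integrates with a BAOAB-type Langevin scheme at 10 fs
timestep and drag coefficient 0.01 ps$^{-1}$, initial velocities
Maxwell–Boltzmann under the replica seed.  The default protocol
(`simulationConfig()`) is 298.15 K, pH 6.8, ionic strength 0.22 M, 70 ns
per replica with the first 3.5 ns discarded as equilibration, frames
every 0.5 ps — the save interval is the unique value reconciling those
spans with 133,000 production frames
(`productionFrameCount(70, 3.5, 0.5)`) — and 10 replicas.

Starting conformations come from the topology's reference coordinates
with the linker geometry perturbed per replica seed.  Before production,
a short *soft-core warmup* (not part of the saved trajectory) runs with
the magnitude of each non-bonded pair force capped, the cap annealed
upward geometrically, under a strong thermostat: residual steric clashes
in an assembled starting structure are squeezed out quasi-statically
instead of detonating when the full $r^{-12}$ core first acts.  Bonds
and restraints are never capped, so strained chain geometry can relax
against the softened core.  Warmup length and cap are arguments;
production dynamics are entirely unmodified.

Thermostat and integrator sanity are tested by equipartition (kinetic
temperature of a toy chain within three blocked standard errors of the
target), the Einstein relation for a free bead ($D = k_BT/m\gamma$), and
the harmonic-bond Boltzmann distribution against a quadrature oracle.

## Groove occupancy

A `GrooveDefinition` labels the groove-bearing domain's residues interior
(lining the groove) or exterior (convex back).  The package ships a
sphere-fit helper (`proposeGrooveInterior()`) that proposes interior
residues from reference coordinates, but the explicit list is always the
source of truth.  Per frame, `classifyFrame()` marks a candidate residue
occupied iff

1. it is strictly closer to the groove center (mean of interior
   positions, recomputed per frame) than the furthest interior residue
   is;
2. its minimum distance to any interior residue is strictly smaller than
   to any exterior residue;
3. its perpendicular distance to the dominant principal axis of the
   interior group is at most the interior group's own maximal
   perpendicular distance scaled by the groove's alignment threshold
   (default 1), which accounts for the groove's curvature.

The third test's wording admits several formalizations; we chose the
perpendicular-distance criterion because it has a single interpretable
knob (the threshold, recorded in the manifest) and reduces to "inside
the interior group's own envelope" at the default.  Radii are recomputed
per frame (the domains are restrained, so frame-to-frame variation is
small); ties break toward non-occupancy (strict inequalities in tests
1–2).  The classifier is validated against an independently coded
brute-force oracle on >10⁴ random configurations and is invariant under
rigid-body motion of the frame.

`occupancyProfile()` averages occupied-frame fractions over replicas
(spread = across-replica SD); `excessOccupancy()` divides an observed
profile by the excluded-volume baseline per residue, flagging undefined
(0/0) and infinite (x/0) ratios rather than applying pseudo-counts;
`regionEnrichment()` averages defined per-residue enrichments over named
spans (e.g. transient-helix regions).

## Ensemble observables

* `radiusOfGyration()` / `rgSummary()`: mass-weighted Rg per frame,
  replica means, grand mean ± SEM across replicas, pooled histogram.
  Simulation runs in nm; Rg is reported in Å at this boundary only.
* `effectiveConcentration()`: the tethered-ligand definition — the
  fraction of frames in which the center-of-mass distance between two
  residue spans falls in a spherical shell (contact distance ±
  half-width), divided by the shell volume $4\pi d^2 w$ and Avogadro's
  number, in µM with an across-replica SEM.  The contact distance
  defaults to the domain separation in the bound pose and the shell
  width to 0.2 nm; both are configuration knobs, logged in the manifest.
  Center-of-mass distance is the default definition.  An empty shell is
  reported as 0 with an explicit flag, never silently.
* `guinierFit()`: linear fit of $\ln I$ vs $q^2$ over the largest low-q
  window with $qR_g \le 1.3$, iterated to self-consistency (≤ 20 rounds,
  ties toward the smaller window); $R_g = \sqrt{-3 \times
  \mathrm{slope}}$.  Exact on noiseless synthetic profiles across
  10–100 Å; non-decaying profiles are rejected, and
  `compareToExperiment()` propagates that rejection as a flagged
  comparison.

## NMR observables

`csp()` implements $\Delta\delta = \sqrt{(\Delta\delta_H)^2 +
(\Delta\delta_N/5)^2}$ with the nitrogen weight as a parameter;
`intensityRatio()` divides intensities by sample concentration before
ratioing; `secondaryShift()` computes $\Delta\delta(C_\alpha - C_\beta)$
against user-supplied random-coil tables (the package deliberately ships
no random-coil table of record — those values are versioned externally
and are treated as data); `fitMonoexponential()` fits
$I(t) = I_0 e^{-Rt}$ by untransformed non-linear least squares (so noise
stays additive), initial guess from a two-point log slope, with the rate
SD from 500 Monte Carlo refits at the stored spectral noise;
`hetNOE()` is the saturated/reference height ratio with the standard
propagated error.  Peak disappearance is an explicit absent state
throughout, never a zero intensity.  Duplicate relaxation delays are
kept as independent observations (configurable by simply averaging the
input, but independence is the default).

## Synthetic data: what it emulates and what it does not

Every test fixture is generated in code:

* `makeToyGrooveSystem()`: a rigid hemicylindrical groove (interior on
  the concave face, exterior on the convex back) with analytically known
  classification ground truth; "outside" placements in
  `makePlantedOccupancyTrajectory()` sit at three times the
  furthest-interior radius, guaranteed to fail the first test, so
  planted occupancy probabilities are exact Bernoulli ground truth.
* `makeRelaxationSeries()` and `makeGuinierProfile()`: exact closed-form
  evaluations plus seeded Gaussian noise.
* `syntheticMultidomainSequence()` / `syntheticReferenceCoords()`: a
  deterministic 373-residue stand-in for a UBL–IDR–STI1–IDR–UBA
  architecture (domains 1–75, 147–223, 327–373; transient-helix spans
  114–134, 279–291, 303–313) with a hydrophobic groove face and polar
  back, solenoid folds for the terminal domains, a hemicylindrical
  groove fold for the central domain, linkers routed over radial stalks
  and tapered coils, and a deterministic steric relaxation pass.  A
  docked pose (terminal domains in contact) accompanies it for the
  bound-complex variant.  These are synthetic constructs: they share the
  architecture, not the sequence or structure, of any natural protein,
  so passing tests demonstrate correctness of the machinery, not
  biological accuracy of predictions for a specific protein.

All generators draw from private RNG streams (`withSeed`) and are
bit-reproducible; they never touch the caller's RNG state.

## Study pipeline and problem sizes

`runStudy()` orchestrates the three topology variants (unbound, bound,
excluded-volume), replica simulations, equilibration trimming, occupancy
and excess profiles, region enrichments, Rg summaries, and the effective
concentration of the terminal-domain pair, with optional TSV/JSON
reports and a trajectory cache keyed by variant, replica and seed
(re-runs with an identical config reuse it; outputs are byte-identical).
The excluded-volume baseline runs longer than the interacting variants
(default 10×) because baseline occupancies are small and need more
frames.

The default configuration is the full protocol above.  The package's
own acceptance analysis (`scripts/acceptance.R`) runs a desk-scale
version: 2 replicas × 2.5 ns per interacting variant, 0.5 ns discarded,
1 ps saves, excluded-volume 2× longer.  At that scale the ensemble
averages are reproducible but not converged: the tethered terminal
domains rarely visit contact range, so the effective concentration
carries a large sampling error (and can be an honest zero), and the
excluded-volume baseline can record no occupancy events at all — which
is why the desk-scale report gives per-variant pooled occupancies
rather than fold enrichments; enrichment over the baseline (with its
undefined/infinite flags) is a full-scale quantity.

## Known limitations

* Single chain only: no condensate or multi-chain simulations.
* The groove classifier is purely geometric; no energetic or
  solvent-accessibility definition of binding.
* Bead-resolution burial proxy instead of surface-area based stickiness
  rescaling (off by default).
* No scattering-curve prediction from coordinates; experimental
  comparison is at the level of Guinier Rg.
* The synthetic chain is a stand-in; quantitative results for a real
  protein require its sequence, reference structures and groove residue
  lists as inputs.
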