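# GrooveSim

Coarse-grained simulation and groove-occupancy analysis of multidomain
proteins with intrinsically disordered regions (IDRs).

Many shuttle and chaperone proteins pair folded domains — including
STI1/DP2-type helical domains with a hydrophobic client-binding groove —
with long disordered linkers that harbor transient amphipathic helices.
Whether those helices transiently occupy the groove of their own chain
is hard to see directly; the standard computational route is a
residue-level coarse-grained simulation of the single chain, a geometric
per-frame classification of groove occupancy, and normalization against
an excluded-volume null model.  GrooveSim implements that route for R
users (structural biologists and biophysicists analyzing IDR–domain
contacts), together with the ensemble observables used to validate such
simulations (radius of gyration, effective concentration of tethered
domains, Guinier fits of SAXS profiles) and the accompanying NMR
calculators (CSPs, secondary chemical shifts, relaxation fits, hetNOE).

## The model in brief

One bead per residue.  Pair energies: an Ashbaugh–Hatch short-range term

    L(r) = 4 eps [ (sigma/r)^12 - (sigma/r)^6 ]
    U(r) = L(r) + (1 - lambda) eps   for r <= 2^(1/6) sigma
         = lambda L(r)               beyond (truncated at 2 nm)

with per-residue stickiness `lambda` and size `sigma` from a bundled
parameter table; Debye–Hückel screened electrostatics
`B(eps_r) q_i q_j exp(-kappa r)/r` (truncated at 4 nm) with charges
from residue valences plus a Henderson–Hasselbalch histidine term;
harmonic backbone bonds (0.38 nm, 8033 kJ/mol/nm²); and an elastic
network (cutoff 0.9 nm, 700 kJ/mol/nm²) holding folded domains to their
reference structure.  Dynamics are BAOAB Langevin (10 fs step,
0.01 ps⁻¹ drag, 298.15 K) over independent replicas.

A frame's candidate residue is "in the groove" iff it is (1) closer to
the groove center than the furthest groove-lining residue, (2) closer
to a groove-lining residue than to any back-side residue, and (3)
within the groove group's own envelope around its dominant principal
axis.  Occupancy profiles are replica means; dividing by the
excluded-volume baseline (all stickiness and charge zeroed) gives
per-residue fold enrichments.

## Worked example

```r
library(GrooveSim)

## a rigid toy groove with known ground truth
sys <- makeToyGrooveSystem(nInterior = 10, nExterior = 8,
                           grooveRadius = 7, seed = 11)
sys
#> ToyGrooveSystem: 18 beads (radius 0.7 nm), 10 interior / 8 exterior

## plant two probes at 25% occupancy and recover it
planted <- makePlantedOccupancyTrajectory(sys, nProbes = 2,
                                          targetOccupancy = 0.25,
                                          nFrames = 5000, seed = 42)
prof <- occupancyProfile(planted$trajectory, planted$groove,
                         planted$probeResidues)
occupancyTable(prof)
#>   residue probability spread
#> 1      19       0.249      0
#> 2      20       0.259      0
```

The classifier reproduces the planted per-frame truth exactly, so the
probabilities are binomial draws around 0.25.

```r
## Guinier analysis of a noisy synthetic scattering profile
profile <- makeGuinierProfile(rg = 38, i0 = 100,
                              qGrid = seq(0.002, 0.05, 5e-4),
                              noiseSD = 0.3, seed = 7)
fit <- guinierFit(profile)
sprintf("Rg = %.2f +/- %.2f A (qRg <= %.2f)", fit$rg, fit$rgSE, fit$qRgMax)
#> "Rg = 38.01 +/- 0.05 A (qRg <= 1.29)"

## NMR relaxation: mono-exponential fit with Monte Carlo errors
s <- makeRelaxationSeries(rate = 2, amplitude = 100,
                          delays = rep(c(0.004, 0.6, 1.0), 2),
                          noiseSD = 1, seed = 3)
f <- fitMonoexponential(s, mcTrials = 500, seed = 4)
sprintf("R = %.3f +/- %.3f s^-1", f$rate, f$rateSD)
#> "R = 1.982 +/- 0.032 s^-1"
```

The fitted rate (1.982 s⁻¹) recovers the planted 2 s⁻¹ within its
Monte-Carlo uncertainty; the Guinier fit recovers the planted 38 Å.

For an end-to-end study — building unbound, bound and excluded-volume
topology variants of a multidomain chain, running replica simulations,
and computing occupancy, enrichment, Rg and effective-concentration
reports — see `?runStudy` and the methods vignette
(`vignettes/groove-occupancy-methods.Rmd`).

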