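---
title: "Methods: PPII conformational analysis of glycosylated mucin-domain peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PPII conformational analysis of glycosylated mucin-domain peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoppii)
```

## The scientific problem

Mucin domains are densely O-glycosylated, repeat-rich protein regions. In
lubricin (PRG4), the boundary lubricant of articular cartilage, the central
mucin domain is built from KEPAPTTP-type tandem repeats whose threonines
carry O-linked GalNAc--Gal disaccharides. Because prolines disrupt both
alpha helices and beta sheets, the natural structural hypothesis for such a
domain is the polyproline type II (PPII) helix: a left-handed backbone
helix near (phi, psi) = (-75, 145) degrees with 3 residues per turn and no
regular backbone hydrogen bonding. This package provides the machinery to
examine that hypothesis quantitatively for model peptides: it builds
idealised backbones from torsions, samples torsional ensembles with a
desk-scale replica-exchange Monte Carlo (REMC) sampler, converts ensembles
into Ramachandran free-energy surfaces by Boltzmann inversion, tabulates
per-residue secondary-structure populations with confidence intervals, and
checks sampling convergence with the standard two-interval
radius-of-gyration overlap diagnostic.

The reference system throughout is the two-tandem-repeat model peptide
PKEPAPTTTKEPAPTTPK (residues 393--410 of lubricin), which contains one
exact KEPAPTTP repeat and its most common variant KEPAPTTT. Thr401 — the
third threonine — is not glycosylated in vivo, so the glycosylated form
carries glycans on the other four threonines (399, 400, 407, 408). The
TTTT threonine tetrapeptide, fully glycosylated in its modified form, is
available as a second preset for probing threonine's intrinsic PPII
propensity.

## Backbone model

`build_backbone()` constructs N/CA/C coordinates from per-residue
(phi, psi) by sequential frame placement (a natural-extension algorithm),
using standard covalent geometry: N--CA 1.458 A, CA--C 1.525 A, C--N
1.329 A, bond angles N-CA-C 111.2, CA-C-N 116.2, C-N-CA 121.7 degrees, and
trans peptide bonds (omega = 180). All values are configurable through
`backbone_geometry()`; exact coordinates of any particular external
structure-building tool are not recoverable and not needed, since every
analysis downstream depends on torsions only. The construction is exact:
recomputing dihedrals from the built coordinates reproduces the inputs to
well below 1e-6 degrees (a tested invariant). Terminal residues lack one
of phi/psi; these are stored as `NA` and excluded from analytics, never
imputed. Side chains and glycans are never built in 3D — glycosylation
enters as an annotation on the peptide and as an energy modifier in the
sampler.

`helix_parameters()` treats the residue-to-residue rigid transform of a
uniform chain as a screw motion (Kabsch superposition of consecutive
N/CA/C triads, then axis-angle decomposition with the axis oriented along
the helix advance). The canonical checks come out as the field expects:

```{r helix}
helix_parameters(build_backbone(12, -75, 145))   # PPII
helix_parameters(build_backbone(12, -57, -47))   # alpha helix
```

## The torsional potential and the REMC sampler

The sampler needs a smooth stand-in for a molecular force field that (i)
has its global minimum in the PPII basin, (ii) offers competing basins in
the other Ramachandran regions, and (iii) lets glycosylation act on a
residue's local preferences. We use a per-residue basin mixture,

$$U(\phi,\psi) = -\epsilon\,\log \sum_k w_k\,
  e^{\kappa(\cos(\phi-\phi_{0k})-1)}\,e^{\kappa(\cos(\psi-\psi_{0k})-1)},$$

a log-sum of von Mises-type bells centred at PPII (-75, 145), alpha_R
(-60, -45), beta (-135, 135) and alpha_L (60, 45) — each centre safely
inside its classification region so that basin occupancy is unambiguous.
Defaults: kappa = 8 (about 20 degrees of angular spread), depth scale
epsilon = 1 kcal/mol, and weights 1 / 0.22 / 0.35 / 0.10, which place the
competing basins roughly 1--2.4 kcal/mol above PPII — the ordering and
magnitude expected for a proline-rich repeat at room temperature.
Residues are energetically independent (no coupling model is available
for these repeats, so none is imposed). Glycosylation multiplies the
alpha_R weight of glycosylated residues by 0.05 and transfers the removed
weight to PPII, encoding the steric destabilisation of the compact
alpha_R conformation by the bulky GalNAc--Gal glycan. These are model
choices, not fitted quantities: the package makes no claim of
thermodynamic equivalence to atomistic simulation, and the analytics are
deliberately agnostic about where ensembles come from.

`run_remd()` samples this potential with replica-exchange Metropolis
Monte Carlo. The temperature ladder is geometric
(`make_ladder()`; T_i = T_min r^(i-1)), mirroring the usual REMD practice
of 64 replicas from 300 to 455.95 K for the model peptide and 32 replicas
to 452.32 K for the tetrapeptide; the desk-scale default uses 8 replicas
over the same 300--455.95 K range, which keeps neighbour exchange
acceptance high (about 0.8) at a fraction of the cost. One sweep proposes
every phi and psi once with a uniform step of +/- 60 degrees; each
proposal is accepted with probability min(1, exp(-dU/kT)), with
k_B = 0.0019872041 kcal/(mol K) so all energies are in kcal/mol. Every 10
sweeps, neighbouring replicas attempt configuration swaps (odd/even pair
alternation) under the standard parallel-tempering criterion
min(1, exp[(1/kT_i - 1/kT_j)(E_i - E_j)]). Swaps permute configurations
across temperature slots and never create or destroy them — a tested
invariant — and recorded series are per temperature.

Numerical choices worth stating:

* **Proposal step 60 degrees.** At kappa = 8 a basin is ~20 degrees wide;
  30-degree proposals almost never hop basins directly and the package's
  own two-interval overlap diagnostic flags such runs as unconverged at
  2e5 sweeps. At 60 degrees single-residue sampling reproduces the exact
  grid Boltzmann distribution with total-variation distance ~0.03 at 1e5
  sweeps (a tested bound of 0.05), and full-scale runs converge
  reproducibly.
* **Burn-in 0.5.** Analysis discards the first half of each recorded
  trajectory, mirroring the convention of analysing only the converged
  last half of a production run.
* **Determinism.** One integer seed drives the single-threaded sampler
  through R's RNG; identical seeds give bitwise-identical trajectories,
  and a single-replica run is bitwise identical to a plain Metropolis
  loop.
* **Initialisation.** All replicas start at (-75, 145). Burn-in plus
  exchange with hot replicas removes any practical initialisation bias at
  the tested scales.

## Ensemble analytics

`ramachandran_histogram()` bins all defined (phi, psi) pooled over frames
and residues on a 72 x 72 grid (5-degree bins; the resolution is a free
choice and configurable). `free_energy_surface()` applies Boltzmann
inversion, dG = -k_B T log(P / P_max), so the surface is zero at the
global minimum; empty bins are masked as undefined rather than set to
zero or infinity, which keeps surfaces plottable and temperature scaling
exactly linear bin-wise (a tested equivariance). Per-residue tables come
from `region_populations()` with the literature region bounds:
alpha_R (-160 < phi < -20, -120 < psi < 50), beta (-180 < phi < -90,
50 < psi < 240), PPII (-90 < phi < 20, 50 < psi < 240), alpha_L
(30 < phi < 100, 0 < psi < 80), coil elsewhere. Two conventions are
applied exactly as printed: bounds are strict, so exact boundary values
classify as coil (a zero-measure choice), and psi bounds above 180 are
handled by lifting psi by 360 degrees when psi < upper - 360, so
psi = -150 tests as 210 and the beta/PPII regions wrap across the
periodic seam. Disjointness and totality of the classification are
verified by brute force on a 1-degree grid.

Confidence intervals (`population_ci()`) use a moving-block bootstrap
over frames — blocks of length ceiling(n^(1/3)) preserve the short-range
autocorrelation that Monte Carlo and molecular dynamics trajectories
always carry — with percentile intervals at 95%. The glyco/nonglyco
comparison (`compare_populations()`) separates statistical from practical
significance: the p-value comes from a null-calibrated block bootstrap
(both pseudo-ensembles resampled from the pooled frames), which stays at
or below its nominal level even for very short series, where interval
inversion is anticonservative for proportions; practical significance
additionally requires the occupancy difference to exceed 0.05. Both must
hold for a flag. This two-part criterion is this package's concrete
reading of a "practically and statistically significant" population
difference at alpha = 0.05; it is a substitute for, not a reconstruction
of, any particular published test.

## Convergence diagnostics

`radius_of_gyration()` implements the mass-weighted root-mean-square
distance from the centre of mass; for idealised N/CA/C backbones equal
masses are the default (per-atom masses are supported when full
coordinates are supplied). `rg_convergence()` runs the standard protocol:
per-frame backbone Rg, split of the analysis window into two equal
contiguous halves (for an odd frame count the first half is the smaller),
50-bin histograms on shared edges spanning the pooled range, and the
overlap coefficient sum(min(p, q)). The overlap statistic itself is a
definition adopted here — the diagnostic is conventionally described just
as "overlap" — and the pass threshold is 90%, applied inclusively.
Identical distributions give exactly 1; at the package's default scale
(8 replicas, 2e5 sweeps, 1e4 post-burn-in frames) converged runs sit
around 93%, and under-mixed runs fall visibly below 90.

## The synthetic-ensemble generator

Analytics need test data with known truth. `sample_ensemble()` draws, per
residue, a sticky Markov chain over the five basins (stationary
distribution equal to the basin weights; stay-probability rho, default
0.9, so the autocorrelation that justifies the block bootstrap is
actually present), then places angles around the basin centre with von
Mises concentration kappa (default 8; Best--Fisher sampler); coil draws
uniformly on the torus. Default weights 0.55 / 0.15 / 0.20 / 0.03 / 0.07
(PPII / alpha_R / beta / alpha_L / coil) describe a PPII-dominant residue
with realistic minority populations. `paired_glyco_ensembles()` applies
the glycosylation effect — alpha_R weight times 0.02, mass moved to
PPII — at the glycosylated threonines and, by default, also at a
nonglycosylated threonine directly adjacent to a glycosylated one
(mirroring the cooperativity seen for the repeat-variant threonine), with
a shared seed for paired testing.

One quantitative subtlety is documented rather than hidden: at kappa = 8
the PPII bell centred at phi = -75 puts about 23% of its mass beyond the
phi = -90 region boundary, i.e. into the beta region. Basin weights and
region populations are therefore *not* interchangeable at moderate
concentration. All recovery tests compare empirical region fractions
against the generator's true push-forward (the basin-to-region confusion
matrix computed by quadrature); direct weight recovery is exercised at
high concentration (kappa = 128), where leakage is genuinely negligible.

## What the tests do and do not show

The synthetic generator and the toy potential emulate basin occupancies,
angular spread, temporal autocorrelation and a localised glycosylation
effect. They do not emulate atomistic energetics, solvent, glycan
geometry, sequence-dependent coupling between neighbouring residues, or
long-range electrostatics. Passing tests therefore demonstrate that the
*analysis machinery* is correct and calibrated — classification exact,
inversion exact, intervals with nominal coverage, comparison with
controlled error rates, convergence diagnostics that respond to real
mixing failures — not that any particular real peptide is PPII-dominant.
The package's scientific statements about lubricin-like repeats
(PPII-ranked populations, PPII free-energy minimum, alpha_R suppression
at glycosylated threonines) hold for the model potential by construction
and are validated end-to-end at desk scale: 8 replicas times 2e5 sweeps
(about 10 seconds of compute), 1e4-frame analyses, 200-replication
calibration studies. These sizes were chosen as the smallest at which the
stochastic checks have comfortable margins.

## Known limitations

* Torsion-only state space: no Cartesian clash model, so the sampler
  cannot capture excluded-volume effects beyond what the basin weights
  encode.
* The glycosylation modifier acts on one basin weight; real glycans also
  perturb psi distributions within basins and couple neighbouring
  residues.
* No reweighting across temperatures: only the 300 K replica is
  analysed, as is conventional.
* No hydrogen-bond-based secondary-structure assignment; classification
  is purely dihedral, by design, since PPII has no hydrogen-bonding
  signature.
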