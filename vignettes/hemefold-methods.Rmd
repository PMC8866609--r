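---
title: "The hemefold model: a coarse-grained protein coupled to an atomistic heme"
author: "hemefold authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The hemefold model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Heme proteins bind an iron-protoporphyrin cofactor either noncovalently
(heme b) or additionally through two thioester bonds from a CXXC cysteine
motif (heme c).  hemefold couples a three-bead-per-residue coarse-grained
protein (Calpha, Cbeta, carbonyl O; glycine has no Cbeta) to an
atomistically represented heme through knowledge-based interaction
potentials, so that folding and cofactor binding can be explored together.

All lengths are nm, energies kJ/mol, angles radians, temperatures K.
Residue charges follow the minimal coarse-grained convention: Asp/Glu $-1$,
Lys/Arg $+1$, everything else (including His) 0, located on the Cbeta.

The protein-heme coupling has six terms for heme b, plus one for heme c:

* **Fe coordination** ($V_{\mathrm{Fe\text{-}cc}}$): for each inner,
  non-glycine residue $i$,
  $\lambda_i\, e^{s\,(r_i - r_0)^2}\prod_{j=1}^{4}
  \tfrac12\!\left[1 + \tanh 2(\sin\theta_{ij} - \sin\theta_0)\right]$,
  where $r_i$ is the Cbeta--Fe distance and $\theta_{ij}$ the
  Cbeta--Fe--N(pyrrole) angle.  The literal printed form of the radial
  factor has a positive exponent and diverges with separation; since the
  term is described as *restraining* the distance, the bounded Gaussian
  ($s = -1$, an attractive well with $\lambda < 0$) is the default, with
  the `fe_cc.exponent_sign` switch exposing the literal form.  Only
  residue types that actually coordinate iron carry a nonzero strength
  (His $-300$, Met $-200$ by default).
* **Screened electrostatics**: Debye-Hueckel,
  $\lambda_{\mathrm{elec}}\sum q_i q_j\, e^{-\kappa r_{ij}}/r_{ij}$ between
  residue unit charges (on Cbeta) and the heme partial charges.  The
  default prefactor folds in the Coulomb constant and a relative
  dielectric of 80; the screening length is 1 nm.
* **Backbone hydrogen bond**: virtual N--H sites are reconstructed as
  affine combinations of (Calpha$_{i-1}$, Calpha$_i$, O$_{i-1}$) using the
  standard three-bead coefficients (normalized so they sum exactly to 1,
  which makes the sites strictly equivariant under rigid-body motion).  A
  Gaussian well on the H...O(carboxylate) distance is gated by
  $\tfrac12[\tanh(4(\theta-\theta_0) - 6) + 1]$ on the N-H...O angle; the
  $-6$ offset means the gate opens about 1.5 rad above $\theta_0$, i.e. for
  near-linear hydrogen bonds.
* **Sidechain hydrogen bond**: per-residue-type Gaussian wells between the
  Cbeta and the carboxylate oxygens.
* **Carboxylate burial**: $\lambda_{\mathrm{burial}}\sum
  (1 - \tanh 8(r_{ij} - r_0))/(4N)$, a penalty (positive $\lambda$) for
  burying the hydrophilic propionates away from solvent.
* **Excluded volume**: one-sided quadratic wall between every protein bead
  and every heme atom.  The default cutoff (0.25 nm) sits below the
  thioester bond length so covalently attached cysteines are not
  penalized.
* **Thioester (heme c)**: per attachment cysteine,
  $\lambda_{CS}\, e^{-4\Delta^2}(1 - \tanh 3\Delta)(1 + \tanh 32\Delta)$
  with $\Delta = r - r_0$ on the Cbeta--vinyl-carbon distance.  The factor
  $(1+\tanh 32\Delta)$ peaks at about $1.63$ just outside $r_0$, so the
  well bottom is at $\Delta \approx +0.06$ nm with depth $1.63\lambda_{CS}$.
  The sum is restricted to one specific bond per cysteine (matched to its
  nearest vinyl): under the unrestricted double sum over all
  cysteine-vinyl pairs, both cysteines can chelate both vinyls
  simultaneously, which collapses the attachment geometry — a failure mode
  that sterics forbid in the real system but that a bead model cannot
  exclude on its own.

The heme itself carries harmonic bonds and angles, periodic dihedrals and
LJ + screened-Coulomb nonbonded interactions (1-2/1-3 excluded, 1-4 scaled
AMBER-style).  The topology is generated from the reference geometry by
element-specific bond-distance detection, with equilibrium values taken
from that geometry, so the bonded energy of the reference structure is
exactly zero.  Two numerical choices matter here: angles with equilibria
beyond 2.6 rad are omitted (the harmonic angle gradient direction is
undefined at collinearity; the dihedrals hold planarity instead), and the
LJ potential continues linearly below $0.8\sigma$.  Without the soft core,
rare thermal core breaches at the coarse-grained timestep inject enormous
$r^{-12}$ impulses that can tear the cofactor apart; the cap bounds the
force while leaving the physically sampled region untouched.  Internal
electrostatics use the same dielectric-scaled screened Coulomb as the
protein-heme term: with quantum-derived partial charges and no explicit
solvent, vacuum Coulomb between a propionate oxygen and the iron would
overwhelm the geometry.

## The protein stand-in

The transferable protein forcefield whose place this package's stand-in
takes is a large, separately parameterized model; hemefold instead ships a
structure-based single-memory potential in the tradition of Go models:
Gaussian wells on all Calpha--Calpha and Cbeta--Cbeta pair distances at
their native values (sequence separation $\ge 3$, width
$0.1\,|j-i|^{0.15}$ nm), harmonic chain-connectivity bonds, a chirality
restraint on the signed volume spanned by consecutive Calphas and the
Cbeta, native-valued virtual-bond angle and dihedral terms, and
Calpha--Calpha excluded volume.  The angle/dihedral/self-avoidance terms
are standard in structure-based models and are what give the unfolded
chain realistic local stiffness; without them a coil can wrap its
coordinating residues onto the cofactor at negligible cost.  The tertiary
well depths (`epsilon_ca` 0.3, `epsilon_cb` 0.15 kJ/mol) were calibrated
once so the 30-residue toy protein is marginally stable near 300 K — the
regime in which apo/holo comparisons are informative — and are not
revisited per experiment.

## Metrics

$Q_w$ is the Gaussian-weighted fraction of native Calpha--Calpha distances
over pairs with $|j - i| > 2$, normalized by $(N-2)(N-3)/2$, with the
sequence-separation-dependent well width $\sigma_{ij} = |j-i|^{0.15}$ in
Angstrom.  The width's unit is part of the metric's definition: read in nm
the wells would be an order of magnitude too forgiving and a random coil
already scores above 0.5, while in Angstrom the customary scale (unfolded
$\approx 0.1$--$0.2$, folded above $0.6$) is reproduced.  $Q_c$ counts
reproduced native heme contacts: a residue is in contact when any heme
atom lies within 0.65 nm of its Cbeta, and predicted contacts count only
if they also exist in the reference, so $Q_c \in [0, 1]$.  Residue-level
counting is the default (robust to heme atom-naming differences); atom-pair
counting is available via `mode = "atom"`.  RMSD uses Kabsch superposition
and reports per-residue deviations for structure coloring.

## Dynamics

BAOAB-discretized Langevin dynamics with a 5 fs timestep and a friction of
0.5/ps by default.  Masses are uniformly repartitioned to 10 amu:
equilibrium (configurational) statistics are independent of the mass
assignment, and light uniform beads let the free cofactor diffuse far
enough to encounter the protein within desk-scale runs.  At zero friction
and temperature the integrator reduces to velocity Verlet and conserves
energy; the thermostat reproduces equipartition on a harmonic oscillator
to within statistical error (both are asserted in the test suite).

The annealing protocol ramps the temperature linearly (800 K down to
200 K by default) from an extended, self-avoiding random-coil start with
the heme placed more than 3 nm from the protein centroid.  A flat-bottom
spherical container (radius 2.5 nm, 50 kJ/mol/nm$^2$, centered on the
initial centroid) keeps the dilute two-molecule system together: an
unconfined 3D random walk is transient, and without the container most
desk-scale runs would simply lose the cofactor.  The container acts on
both molecules and on every comparison arm identically.  Desk-scale runs
use 40,000 steps; the API supports arbitrarily long schedules.

Umbrella sampling biases $Q_w$ with $\tfrac12 k (Q_w - q_0)^2$ (the bias
force is chain-ruled exactly through every Calpha pair and verified
against finite differences).  Windows are laddered — each starts from the
previous window's final coordinates — with default centers 0.9 down to 0.1
in steps of 0.05 and $k = 500$ kJ/mol, chosen so neighboring histograms
overlap well (an overlap below 10% shared mass triggers a warning).  WHAM
recombines the windows by the standard self-consistent iteration
(convergence threshold $10^{-8}$ on the window shifts), after discarding
the first 20-30% of each window as equilibration.

## The synthetic toy system

`makeMiniGlobin()` builds a 30-residue helical hairpin sandwiching an
idealized planar 24-atom heme: helix A above the ring carries the axial
His (residue 11) with its Cbeta exactly at the Fe-coordination equilibrium
distance on the ring normal; helix B below the ring carries the distal Met
(residue 25), the bis-axial His/Met coordination of cytochromes; the
N-terminal tail carries the CXXC motif (residues 2 and 5) with the
cysteine Cbetas exactly at the thioester equilibrium distance from the
vinyl carbons (heme c).  The pocket is constructed *at the equilibrium
distances of the loaded parameter set*, so energy-minimum tests stay valid
if parameters change.  The extended state is a seeded self-avoiding random
coil with the heme at 3.2 nm.  `relaxSystem()` quenches the idealized
construction onto the actual minimum of the loaded forcefield (50 K down
to 10 K); umbrella protocols use this relaxed structure as the reference
so that the coupled system fluctuates around a self-consistent "crystal".

What the toy does *not* emulate: real globin topology, sequence-dependent
foldability, solvent, the transferable many-body protein energetics, and
the extensive (~10^2-contact) pockets of real heme proteins.  Passing
tests on the toy therefore demonstrate the mechanics and the qualitative
binding physics of the model, not predictive accuracy on real structures.

## What the acceptance suite shows — and one honest negative

The acceptance tests verify: exact metric identities; equality of every
energy term with independently coded naive double-loop oracles (relative
error $< 10^{-10}$); force/finite-difference consistency ($< 10^{-4}$,
including virtual-site chain rules and the umbrella bias); thermostat
statistics; WHAM recovery of an analytically known double well within
0.2 kT; and the binding-funnel property — over 10 annealing seeds per arm,
the median final $Q_c$ with the Fe-coordination (and, for heme c,
thioester) terms enabled clearly exceeds the median with those terms
zeroed (typical medians 0.5--0.7 versus 0--0.3).  This operationalizes the
claim that the specific coordinate-covalent and thioester bonds, not
diffuse stickiness, drive the cofactor into its native pocket.

One property does **not** reproduce at toy scale: the deepening of the
folded-state free-energy basin by heme attachment (the apo/holo $Q_w$
profile comparison).  The coupling's energetic preference for the folded
toy (~16 kT, measured window by window) is carried almost entirely by
stiff, bond-like few-body terms, and stiff-well energy differences are
nearly exactly entropy-compensated, so the $Q_w$-resolved free energy of
the 30-mer is insensitive to the coupling; the corresponding acceptance
test is implemented faithfully and fails.  In the source physics the
effect rides on an extensive soft pocket across a 100+-residue protein and
on the full transferable protein Hamiltonian, both outside this package's
scope.

## Reproducibility and problem sizes

Every stochastic routine takes an explicit seed and is bitwise
reproducible.  The shipped problem sizes — a 30-residue toy, 40,000-step
anneals, 17 umbrella windows of 25,000 steps, $10^6$-step thermostat
checks, 20,000-sample Metropolis windows for WHAM — were chosen so the
full test suite and the acceptance script each complete in minutes on a
single core while leaving the statistical assertions well-resolved.
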