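# hemefold

Heme proteins fold around their cofactor: the iron-protoporphyrin group
binds noncovalently (heme b) or additionally through two thioester bonds
from a CXXC cysteine motif (heme c), and the pocket it occupies is shaped
by the fold itself.  `hemefold` is an R package for exploring this coupled
folding-and-binding problem with a hybrid energy model: a coarse-grained
protein (three beads per residue — Cα, Cβ, carbonyl O) interacting with an
atomistically represented heme through knowledge-based potentials.

The protein-heme Hamiltonian is

```
H(heme b) = V_Fe-cc + V_elec + V_hb-backbone + V_hb-sidechain + V_burial + V_excl
H(heme c) = H(heme b) + V_thioester
```

where `V_Fe-cc` restrains an axial ligand's Cβ above the Fe through a
radial well gated by the four Cβ–Fe–N(pyrrole) angles, `V_elec` is
Debye–Hückel screened electrostatics against the heme partial charges,
the hydrogen-bond terms couple backbone N–H groups and polar sidechains to
the heme carboxylates, `V_burial` penalizes burying the hydrophilic
propionates, `V_excl` is excluded volume, and `V_thioester` is a narrow
bond-like well between each attachment cysteine Cβ and its vinyl carbon.
The heme carries its own bonds/angles/dihedrals/nonbonded forcefield; the
protein is driven by a structure-based single-memory (Gō-style) stand-in.

On top of the energy model the package provides:

* **Metrics** — `qw()` (Gaussian-weighted fraction of native Cα–Cα
  distances), `qc()` (fraction of reproduced native heme contacts under a
  0.65 nm cutoff), `rmsdCA()` (Kabsch superposition with per-residue
  deviations).
* **Sampling** — BAOAB Langevin dynamics, simulated-annealing structure
  prediction (`runAnnealing()`), Q_w-biased umbrella sampling
  (`umbrellaRun()`).
* **Landscapes** — 2D free-energy surfaces over any pair of recorded
  observables (`fes2D()`), WHAM recombination (`wham()`), basin/barrier
  analysis (`basinReport()`).
* **Self-contained toys** — an idealized planar heme and a designable
  30-residue mini-globin with an exactly constructed pocket
  (`makeIdealHeme()`, `makeMiniGlobin()`), so everything is testable with
  no external structure downloads.
* **I/O** — PDB read/write (`readSystemPDB()`, `writeSystemPDB()`), YAML
  parameter files with a strict loader (`loadParameters()`), and a
  command-line entry point (`hemefoldMain()`; thin wrapper at
  `inst/cli/hemefold.R`) with subcommands `energy`, `qscore`, `anneal`,
  `umbrella`, `fes`, `make-toy`.

## Worked example

Build the heme c toy, score its native state, and run a desk-scale
annealing prediction from an extended coil with the heme 3.2 nm away:

```r
library(hemefold)

toy <- makeMiniGlobin("c", seed = 1)
totalEnergy(toy$native, native = toy$native)
#> EnergyBreakdown (kJ/mol):
#>   fe_cc                -51.8767
#>   elec                   2.2847
#>   hb_backbone           -0.7010
#>   hb_sidechain          -8.7988
#>   burial                 1.9151
#>   excl                   0.0000
#>   thioester           -300.0000
#>   heme_internal          1.3269
#>   protein_standin     -162.6000
#>   total               -518.4498

qw(toy$extended, toy$native)   # 0.0494935  (unfolded coil)
qc(toy$native, toy$native)     # 1

cfg <- simulationConfig(nSteps = 40000, seed = 1, tStart = 800, tEnd = 200,
                        friction = 0.5, recordEvery = 8000)
traj <- runAnnealing(toy$extended, toy$native, config = cfg,
                     confine = list(radius = 2.5, k = 50))
round(observables(traj)[, c("qw", "qc", "fe_cc", "thioester")], 3)
#>      qw  qc   fe_cc thioester
#> 1 0.049 0.0  -0.004     0.000
#> 2 0.373 0.3  -1.597  -482.336
#> 3 0.516 0.3 -20.857  -463.939
#> 4 0.630 0.7 -24.389  -486.118
#> 5 0.650 0.3  -8.471  -393.227
#> 6 0.819 0.7 -42.153  -477.899
```

The protein folds (Q_w 0.05 → 0.82) while the heme finds and covalently
attaches to its pocket: the thioester engages early (~−480 kJ/mol, acting
as a folding nucleus) and the Fe coordination tightens as the pocket
assembles, ending with 70% of the native heme contacts reproduced.
Zeroing the Fe-coordination and thioester terms
(`zeroCoupling(defaultParameters(), c("fe_cc", "thioester"))`) and
re-running the same seeds collapses the final Q_c toward zero — the
binding funnel is carried by the specific bonds, not by diffuse
stickiness.

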