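# Default hemefold parameter set.
# Units: lengths nm, energies kJ/mol, angles radians, charges e, temperature K.
# Every key is required; the loader refuses to run with missing keys.
schema_version: 1

# Coordinate-covalent Fe--residue restraint.
# lambda is per residue type (three-letter codes); types not listed use
# "default".  Negative lambda = attractive well.  r0 is the equilibrium
# Cbeta--Fe distance, theta0 the equilibrium Cbeta-Fe-N(pyrrole) angle.
# exponent_sign -1 gives the bounded Gaussian radial well; +1 reproduces the
# unbounded literal form (see vignette).
fe_cc:
  lambda:
    HIS: -300.0
    MET: -200.0
    default: 0.0
  r0: 0.45
  theta0: 1.2
  exponent_sign: -1

# Debye-Hueckel screened electrostatics between residue Cbeta charges and the
# heme partial charges.  lambda folds in the Coulomb constant and relative
# dielectric (138.935 / 80).
elec:
  lambda: 1.7367
  k_screening: 1.0
  l_screening: 1.0

# Backbone N-H ... carboxylate-O hydrogen bond.
hb_backbone:
  lambda: -10.0
  r0: 0.20
  theta0: 1.4

# Sidechain Cbeta ... carboxylate-O hydrogen bond, per residue type.
hb_sidechain:
  lambda:
    SER: -1.5
    THR: -1.5
    TYR: -1.5
    ASN: -1.5
    GLN: -1.5
    LYS: -1.0
    ARG: -1.0
    HIS: -1.0
    TRP: -1.0
    default: 0.0
  r0:
    SER: 0.40
    THR: 0.40
    TYR: 0.55
    ASN: 0.45
    GLN: 0.50
    LYS: 0.60
    ARG: 0.60
    HIS: 0.45
    TRP: 0.50
    default: 0.45

# Carboxylate burial penalty (positive lambda penalizes burying the
# hydrophilic carboxylates away from water).
burial:
  lambda: 20.0
  r0: 0.60

# Excluded volume between every protein bead and every heme atom.  The
# cutoff sits below the thioester bond length so covalently attached
# cysteines are not penalized.
excl:
  lambda: 2000.0
  r0: 0.25

# Thioester attachment of heme c vinyl carbons to the CXXC cysteine Cbetas.
thioester:
  lambda_cs: -150.0
  r0: 0.28

# Contact cutoff for the Q_c metric.
qc_cutoff: 0.65

# Ideal-geometry virtual-site coefficients: N_i and H_i are linear
# combinations of (Calpha_{i-1}, Calpha_i, O_{i-1}); C'_i of
# (Calpha_i, Calpha_{i+1}, O_i).  Coefficients sum to 1 (affine).
backbone_geometry:
  n_coeff: [0.48318, 0.70328, -0.18643]
  h_coeff: [0.84100, 0.89296, -0.73389]
  c_coeff: [0.44365, 0.23520, 0.32115]

# Structure-based single-memory stand-in for the transferable protein
# forcefield: Gaussian wells on Calpha-Calpha and Cbeta-Cbeta pair distances
# at their native values (sequence separation >= min_separation), harmonic
# chain-connectivity bonds and a chirality term.
# Well width sigma_ij = width_scale * |j-i|^0.15 (nm).
standin:
  epsilon_ca: 0.3
  epsilon_cb: 0.15
  width_scale: 0.1
  min_separation: 3
  k_bond: 4000.0
  k_chirality: 10000.0
  k_angle: 30.0
  k_dihedral: 4.0
  excl_lambda: 500.0
  excl_r0: 0.35

# Internal heme forcefield (harmonic bonds/angles, periodic dihedrals,
# LJ + screened Coulomb nonbonded with 1-2/1-3 exclusion and AMBER-style
# 1-4 scaling).  Equilibrium geometry is taken from the reference structure.
heme:
  formal_charge:
    b: -2.0
    c: -2.0
  k_bond: 4000.0
  k_angle: 50.0
  k_dihedral: 10.0
  scale14_lj: 0.5
  scale14_coul: 0.8333
  lj:
    "C":  {sigma: 0.340, epsilon: 0.360}
    "N":  {sigma: 0.325, epsilon: 0.710}
    "O":  {sigma: 0.296, epsilon: 0.880}
    "FE": {sigma: 0.260, epsilon: 0.050}
  charges:
    FE:   0.80
    "NA": -0.30
    "NB": -0.30
    "NC": -0.30
    "ND": -0.30
    C1A:  0.05
    C2A:  0.05
    C1B:  0.05
    C2B:  0.05
    C1C:  0.05
    C2C:  0.05
    C1D:  0.05
    C2D:  0.05
    CHA: -0.10
    CHB: -0.10
    CHC: -0.10
    CGA:  0.55
    CGD:  0.55
    O1A: -0.70
    O2A: -0.70
    O1D: -0.70
    O2D: -0.70
    CAB:  0.00
    CAC:  0.00
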