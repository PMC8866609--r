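#' Coarse-grained protein representation
#'
#' Three beads per residue: Calpha, Cbeta (absent for glycine) and the
#' carbonyl O, with one-letter sequence and unit residue charges on Cbeta.
#' Coordinates are in nm.  Residues are implicitly numbered 1..N in row
#' order.
#'
#' @slot sequence character vector of one-letter codes, length N.
#' @slot ca,cb,o N x 3 coordinate matrices (nm); cb rows are NA for glycine.
#' @slot charge numeric vector of unit charges in \{-1, 0, +1\}.
#' @export
setClass("CoarseProtein",
  representation(sequence = "character", ca = "matrix", cb = "matrix",
                 o = "matrix", charge = "numeric"))

setValidity("CoarseProtein", function(object) {
  n <- length(object@sequence)
  msg <- character()
  if (n < 1) msg <- c(msg, "empty protein")
  for (sl in c("ca", "cb", "o")) {
    m <- slot(object, sl)
    if (!is.numeric(m) || nrow(m) != n || ncol(m) != 3)
      msg <- c(msg, sprintf("slot '%s' must be an N x 3 numeric matrix", sl))
  }
  if (length(object@charge) != n) msg <- c(msg, "charge length != N")
  if (!all(object@charge %in% c(-1, 0, 1)))
    msg <- c(msg, "residue charges must be -1, 0 or +1")
  gly <- object@sequence == "G"
  if (any(!is.na(object@cb[gly, , drop = FALSE])))
    msg <- c(msg, "glycine must have no Cbeta coordinate")
  if (any(is.na(object@cb[!gly, , drop = FALSE])))
    msg <- c(msg, "non-glycine residue missing Cbeta")
  if (any(is.na(object@ca)) || any(is.na(object@o)))
    msg <- c(msg, "Calpha/O coordinates must be complete")
  if (length(msg)) msg else TRUE
})

#' All-atom heme cofactor
#'
#' Atom names, elements, coordinates (nm), partial charges, role tags
#' (FE, N_PYRROLE, O_CARBOXYL, C_VINYL, OTHER), heme type ("b" or "c") and
#' the internal bonded/nonbonded topology used by the cofactor forcefield.
#'
#' @slot name,element,role character vectors, one entry per atom.
#' @slot xyz n x 3 coordinate matrix (nm).
#' @slot charge per-atom partial charges (e), summing to formalCharge.
#' @slot type "b" or "c".
#' @slot bonds data.frame(i, j, k, r0); angles data.frame(i, j, k, kf, theta0);
#'   dihedrals data.frame(i, j, k, l, kf, n, delta); nonbonded
#'   data.frame(i, j, sigma, epsilon, ljscale, qscale).
#' @slot formalCharge declared total charge (e).
#' @export
setClass("Heme",
  representation(name = "character", element = "character", xyz = "matrix",
                 charge = "numeric", role = "character", type = "character",
                 bonds = "data.frame", angles = "data.frame",
                 dihedrals = "data.frame", nonbonded = "data.frame",
                 formalCharge = "numeric"))

setValidity("Heme", function(object) {
  n <- length(object@name)
  msg <- character()
  if (nrow(object@xyz) != n || ncol(object@xyz) != 3)
    msg <- c(msg, "xyz must be n x 3")
  if (length(object@charge) != n || length(object@role) != n ||
      length(object@element) != n)
    msg <- c(msg, "per-atom slots must have equal length")
  if (!object@type %in% c("b", "c")) msg <- c(msg, "type must be 'b' or 'c'")
  counts <- table(factor(object@role,
    levels = c("FE", "N_PYRROLE", "O_CARBOXYL", "C_VINYL", "OTHER")))
  if (counts[["FE"]] != 1) msg <- c(msg, "need exactly 1 FE atom")
  if (counts[["N_PYRROLE"]] != 4) msg <- c(msg, "need exactly 4 pyrrole N atoms")
  if (counts[["O_CARBOXYL"]] != 4) msg <- c(msg, "need exactly 4 carboxyl O atoms")
  if (counts[["C_VINYL"]] != 2) msg <- c(msg, "need exactly 2 vinyl C atoms")
  if (abs(sum(object@charge) - object@formalCharge) > 1e-6)
    msg <- c(msg, sprintf("partial charges sum to %.6f, declared %.6f",
                          sum(object@charge), object@formalCharge))
  for (tab in c("bonds", "angles", "dihedrals", "nonbonded")) {
    df <- slot(object, tab)
    idx <- unlist(df[intersect(c("i", "j", "k", "l"), names(df))],
                  use.names = FALSE)
    if (length(idx) && (any(idx < 1) || any(idx > n)))
      msg <- c(msg, sprintf("%s topology references invalid atom index", tab))
  }
  if (length(msg)) msg else TRUE
})

setClassUnion("HemeOrNULL", c("Heme", "NULL"))
setClassUnion("listOrNULL", c("list", "NULL"))

#' Coupled protein + heme system
#'
#' @slot protein a [CoarseProtein].
#' @slot heme a [Heme] or NULL for apo systems.
#' @slot cysAttach for heme c, the residue indices of the two attachment
#'   cysteines (C-X-X-C spacing); integer(0) otherwise.
#' @slot distalRestraint NULL, or list(face = +1/-1) masking residues on the
#'   occupied heme face out of the Fe coordination term.
#' @export
setClass("SystemState",
  representation(protein = "CoarseProtein", heme = "HemeOrNULL",
                 cysAttach = "integer", distalRestraint = "listOrNULL"))

setValidity("SystemState", function(object) {
  msg <- character()
  if (!is.null(object@heme) && object@heme@type == "c") {
    ca <- object@cysAttach
    if (length(ca) != 2)
      msg <- c(msg, "heme c system must identify exactly 2 attachment cysteines")
    else {
      if (diff(sort(ca)) != 3)
        msg <- c(msg, "attachment cysteines must be separated by two residues (CXXC)")
      if (!all(object@protein@sequence[ca] == "C"))
        msg <- c(msg, "attachment residues must be cysteines")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Forcefield parameter set
#'
#' Validated container for every coupling constant, equilibrium distance and
#' angle of the hybrid model, loaded from YAML.  Missing keys are a load
#' error, never a silent default.
#' @slot values nested named list mirroring the YAML schema.
#' @export
setClass("ParameterSet", representation(values = "list"))

.required_keys <- list(
  fe_cc = c("lambda", "r0", "theta0", "exponent_sign"),
  elec = c("lambda", "k_screening", "l_screening"),
  hb_backbone = c("lambda", "r0", "theta0"),
  hb_sidechain = c("lambda", "r0"),
  burial = c("lambda", "r0"),
  excl = c("lambda", "r0"),
  thioester = c("lambda_cs", "r0"),
  qc_cutoff = character(),
  backbone_geometry = c("n_coeff", "h_coeff", "c_coeff"),
  standin = c("epsilon_ca", "epsilon_cb", "width_scale", "min_separation",
              "k_bond", "k_chirality", "k_angle", "k_dihedral",
              "excl_lambda", "excl_r0"),
  heme = c("formal_charge", "k_bond", "k_angle", "k_dihedral",
           "scale14_lj", "scale14_coul", "lj", "charges"))

setValidity("ParameterSet", function(object) {
  v <- object@values
  msg <- character()
  for (top in names(.required_keys)) {
    if (is.null(v[[top]])) { msg <- c(msg, paste("missing key:", top)); next }
    for (sub in .required_keys[[top]])
      if (is.null(v[[top]][[sub]]))
        msg <- c(msg, sprintf("missing key: %s.%s", top, sub))
  }
  for (sect in c("fe_cc", "hb_backbone", "burial", "excl", "thioester")) {
    r0 <- v[[sect]][["r0"]]
    if (!is.null(r0) && r0 <= 0) msg <- c(msg, paste(sect, "r0 must be > 0"))
  }
  if (!is.null(v$qc_cutoff) && v$qc_cutoff <= 0)
    msg <- c(msg, "qc_cutoff must be > 0")
  if (!is.null(v$hb_sidechain$lambda) && is.null(v$hb_sidechain$lambda$default))
    msg <- c(msg, "missing key: hb_sidechain.lambda.default")
  if (length(msg)) msg else TRUE
})

#' Per-term energy breakdown
#'
#' @slot terms named numeric vector (kJ/mol) of the component energies.
#' @export
setClass("EnergyBreakdown", representation(terms = "numeric"))

BREAKDOWN_TERMS <- c("fe_cc", "elec", "hb_backbone", "hb_sidechain", "burial",
                     "excl", "thioester", "heme_internal", "protein_standin")

setValidity("EnergyBreakdown", function(object) {
  if (!all(BREAKDOWN_TERMS %in% names(object@terms)))
    return("missing breakdown components")
  TRUE
})

#' Langevin simulation configuration
#'
#' @slot timestep integration step (ps); friction collision rate (1/ps);
#'   tStart,tEnd temperature schedule endpoints (K); nSteps step count;
#'   seed RNG seed; recordEvery frame recording stride.
#' @export
setClass("SimulationConfig",
  representation(timestep = "numeric", friction = "numeric",
                 tStart = "numeric", tEnd = "numeric", nSteps = "numeric",
                 seed = "numeric", recordEvery = "numeric"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nSteps < 0) msg <- c(msg, "nSteps must be >= 0")
  if (object@tStart < object@tEnd)
    msg <- c(msg, "annealing requires tStart >= tEnd")
  if (object@timestep <= 0) msg <- c(msg, "timestep must be > 0")
  if (object@recordEvery < 1) msg <- c(msg, "recordEvery must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Recorded trajectory
#'
#' @slot step,temperature per-frame integers/K; coords list of particle
#'   coordinate matrices; observables data.frame with qw, qc and the energy
#'   breakdown per frame.
#' @export
setClass("Trajectory",
  representation(step = "numeric", temperature = "numeric", coords = "list",
                 observables = "data.frame", layout = "list"))

setValidity("Trajectory", function(object) {
  if (is.unsorted(object@step)) return("frames must be ordered by step")
  if (length(object@coords) != length(object@step)) return("coords/step mismatch")
  TRUE
})

#' Umbrella-sampling window
#'
#' @slot q0 target Q_w; kBias spring constant (kJ/mol); temperature (K);
#'   samples data.frame(step, qw) of recorded reaction-coordinate values.
#' @export
setClass("UmbrellaWindow",
  representation(q0 = "numeric", kBias = "numeric", temperature = "numeric",
                 samples = "data.frame"))

setValidity("UmbrellaWindow", function(object) {
  if (object@kBias < 0) return("kBias must be >= 0")
  TRUE
})

#' Binned 2D free-energy surface
#'
#' F is in units of kT at the stated temperature, shifted so the minimum over
#' populated bins is 0; empty bins are NA.
#' @export
setClass("FreeEnergySurface",
  representation(xname = "character", yname = "character",
                 xedges = "numeric", yedges = "numeric",
                 f = "matrix", counts = "matrix", temperature = "numeric"))

setValidity("FreeEnergySurface", function(object) {
  ok <- is.finite(object@f)
  if (any(ok) && abs(min(object@f[ok]) - 0) > 1e-9)
    return("populated free-energy minimum must be 0")
  if (any(object@counts[!ok] != 0))
    return("empty bins must have zero counts")
  TRUE
})

## ---- accessors & show methods ------------------------------------------

#' Number of residues
#' @param x a CoarseProtein or SystemState
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @rdname nResidues
#' @export
setMethod("nResidues", "CoarseProtein", function(x) length(x@sequence))

#' @rdname nResidues
#' @export
setMethod("nResidues", "SystemState", function(x) nResidues(x@protein))

#' Calpha coordinates (N x 3, nm)
#' @param x a CoarseProtein
#' @export
caCoords <- function(x) x@ca

#' Cbeta coordinates (N x 3, nm; NA rows for glycine)
#' @param x a CoarseProtein
#' @export
cbCoords <- function(x) x@cb

#' Carbonyl O coordinates (N x 3, nm)
#' @param x a CoarseProtein
#' @export
oCoords <- function(x) x@o

#' Protein sequence (one-letter codes)
#' @param x a CoarseProtein or SystemState
#' @export
proteinSequence <- function(x) {
  if (is(x, "SystemState")) x@protein@sequence else x@sequence
}

#' Heme type ("b" or "c")
#' @param x a Heme
#' @export
hemeType <- function(x) x@type

#' Heme atom coordinates (n x 3, nm)
#' @param x a Heme
#' @export
hemeCoords <- function(x) x@xyz

#' Heme atom role tags
#' @param x a Heme
#' @export
hemeRoles <- function(x) x@role

#' Component energies of an EnergyBreakdown
#' @param x an EnergyBreakdown
#' @export
energyTerms <- function(x) x@terms

#' Total energy (sum of components, kJ/mol)
#' @param x an EnergyBreakdown
#' @export
totalOf <- function(x) sum(x@terms)

#' Per-frame observables of a trajectory
#' @param x a Trajectory
#' @export
observables <- function(x) x@observables

setMethod("show", "CoarseProtein", function(object) {
  cat(sprintf("CoarseProtein: %d residues\n", nResidues(object)))
  cat(" sequence:", paste(object@sequence, collapse = ""), "\n")
  cat(sprintf(" charges: %+d net (%d charged residues)\n",
              as.integer(sum(object@charge)), sum(object@charge != 0)))
})

setMethod("show", "Heme", function(object) {
  cat(sprintf("Heme %s: %d atoms (1 Fe, 4 pyrrole N, 4 carboxyl O, 2 vinyl C)\n",
              object@type, length(object@name)))
  cat(sprintf(" formal charge %+.1f e; %d bonds, %d angles, %d dihedrals, %d nonbonded pairs\n",
              object@formalCharge, nrow(object@bonds), nrow(object@angles),
              nrow(object@dihedrals), nrow(object@nonbonded)))
})

setMethod("show", "SystemState", function(object) {
  cat(sprintf("SystemState: %d-residue protein, heme %s\n",
              nResidues(object),
              if (is.null(object@heme)) "absent" else object@heme@type))
  if (length(object@cysAttach))
    cat(" attachment cysteines:", paste(object@cysAttach, collapse = ", "), "\n")
})

setMethod("show", "EnergyBreakdown", function(object) {
  cat("EnergyBreakdown (kJ/mol):\n")
  for (nm in names(object@terms))
    cat(sprintf("  %-16s %12.4f\n", nm, object@terms[[nm]]))
  cat(sprintf("  %-16s %12.4f\n", "total", totalOf(object)))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d frames, steps %s..%s, T %.0f..%.0f K\n",
              length(object@step), min(object@step), max(object@step),
              object@temperature[1], tail(object@temperature, 1)))
})

setMethod("show", "FreeEnergySurface", function(object) {
  cat(sprintf("FreeEnergySurface %s x %s: %d x %d bins at %.0f K (%d populated)\n",
              object@xname, object@yname, nrow(object@f), ncol(object@f),
              object@temperature, sum(is.finite(object@f))))
})

setMethod("show", "UmbrellaWindow", function(object) {
  cat(sprintf("UmbrellaWindow q0 = %.3f, k = %.0f kJ/mol, %d samples at %.0f K\n",
              object@q0, object@kBias, nrow(object@samples), object@temperature))
})
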