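# Energy terms of the hybrid Hamiltonian and their assembly into a total
# energy / force evaluation over one global particle coordinate matrix.
#
# Particle layout (rows of P): Calpha (1..N), Cbeta (non-glycine residues in
# order), O (1..N), then heme atoms.

packLayout <- function(state) {
  p <- state@protein
  n <- nResidues(p)
  gly <- p@sequence == "G"
  idx_ca <- seq_len(n)
  idx_cb <- rep(NA_integer_, n)
  idx_cb[!gly] <- n + seq_len(sum(!gly))
  idx_o <- n + sum(!gly) + seq_len(n)
  nprot <- 2 * n + sum(!gly)
  nh <- if (is.null(state@heme)) 0L else length(state@heme@name)
  idx_heme <- if (nh) nprot + seq_len(nh) else integer()
  # uniform mass repartitioning: equilibrium (configurational) statistics
  # are mass-independent, and light uniform beads give the cofactor a
  # realistic chance to diffuse at desk-scale run lengths
  masses <- rep(10, nprot + nh)
  list(n = n, gly = gly, idx_ca = idx_ca, idx_cb = idx_cb, idx_o = idx_o,
       idx_heme = idx_heme, nprot = nprot, ntot = nprot + nh,
       masses = masses)
}

packCoords <- function(state, layout = packLayout(state)) {
  p <- state@protein
  P <- matrix(0, layout$ntot, 3)
  P[layout$idx_ca, ] <- p@ca
  P[layout$idx_cb[!layout$gly], ] <- p@cb[!layout$gly, , drop = FALSE]
  P[layout$idx_o, ] <- p@o
  if (length(layout$idx_heme)) P[layout$idx_heme, ] <- state@heme@xyz
  P
}

unpackCoords <- function(P, layout, template) {
  p <- template@protein
  p@ca <- P[layout$idx_ca, , drop = FALSE]
  cb <- matrix(NA_real_, layout$n, 3)
  cb[!layout$gly, ] <- P[layout$idx_cb[!layout$gly], , drop = FALSE]
  p@cb <- cb
  p@o <- P[layout$idx_o, , drop = FALSE]
  out <- template
  out@protein <- p
  if (length(layout$idx_heme)) {
    h <- template@heme
    h@xyz <- P[layout$idx_heme, , drop = FALSE]
    out@heme <- h
  }
  out
}

.affine <- function(v) { v <- as.numeric(v); v / sum(v) }

.pairGrid <- function(a, b) {
  list(i = rep(a, each = length(b)), j = rep(b, times = length(a)))
}

# Precompute every index table needed by the energy/force evaluation and
# package them for the single-pass C++ evaluator.  `native` is required
# only when the protein stand-in term is wanted.
ffContext <- function(state, native = NULL, params = defaultParameters()) {
  p <- state@protein
  layout <- packLayout(state)
  n <- layout$n
  seqs <- p@sequence
  heme <- state@heme
  ctx <- list(layout = layout, params = params, hemePresent = !is.null(heme),
              hemeType = if (is.null(heme)) NA_character_ else heme@type)
  tab <- list()

  inner <- seq_len(n)[-c(1, n)]                     # i = 2..N-1
  if (n < 3) inner <- integer()

  if (!is.null(heme)) {
    ife <- layout$idx_heme[which(heme@role == "FE")]
    in4 <- layout$idx_heme[which(heme@role == "N_PYRROLE")]
    iox <- layout$idx_heme[which(heme@role == "O_CARBOXYL")]
    ivin <- layout$idx_heme[which(heme@role == "C_VINYL")]
    face <- if (is.null(state@distalRestraint)) 0
            else as.numeric(state@distalRestraint$face)

    # Fe coordinate-covalent: inner non-glycine residues
    el <- inner[!layout$gly[inner]]
    if (length(el))
      tab$fe_cc <- list(
        icb = as.integer(layout$idx_cb[el]),
        lam = residueParam(pget(params, "fe_cc", "lambda"), seqs[el]),
        ife = as.integer(ife), in4 = as.integer(in4),
        r0 = pget(params, "fe_cc", "r0"),
        th0 = pget(params, "fe_cc", "theta0"),
        sign = as.numeric(pget(params, "fe_cc", "exponent_sign")),
        face = face)

    # screened electrostatics: charged Cbetas x charged heme atoms
    ic <- which(p@charge != 0 & !layout$gly)
    jh <- which(heme@charge != 0)
    kappa <- pget(params, "elec", "k_screening") /
             pget(params, "elec", "l_screening")
    lam_e <- pget(params, "elec", "lambda")
    if (length(ic) && length(jh)) {
      g <- .pairGrid(ic, jh)
      tab$elec <- list(
        ia = as.integer(layout$idx_cb[g$i]),
        ib = as.integer(layout$idx_heme[g$j]),
        qq = lam_e * p@charge[g$i] * heme@charge[g$j],
        kappa = kappa)
    }

    # backbone H-bond donors (virtual N-H of residues 2..N-1)
    if (length(inner))
      tab$hb_bb <- list(
        ica_prev = as.integer(layout$idx_ca[inner - 1]),
        ica = as.integer(layout$idx_ca[inner]),
        io_prev = as.integer(layout$idx_o[inner - 1]),
        iox = as.integer(iox),
        cn = .affine(pget(params, "backbone_geometry", "n_coeff")),
        ch = .affine(pget(params, "backbone_geometry", "h_coeff")),
        lambda = pget(params, "hb_backbone", "lambda"),
        r0 = pget(params, "hb_backbone", "r0"),
        th0 = pget(params, "hb_backbone", "theta0"))

    # sidechain H-bond: inner non-glycine residues x carboxyl O
    lam_sc <- residueParam(pget(params, "hb_sidechain", "lambda"), seqs[el])
    r0_sc <- residueParam(pget(params, "hb_sidechain", "r0"), seqs[el])
    keep <- which(lam_sc != 0)
    if (length(keep)) {
      g <- .pairGrid(keep, seq_along(iox))
      tab$hb_sc <- list(
        ia = as.integer(layout$idx_cb[el[g$i]]), ib = as.integer(iox[g$j]),
        lam = lam_sc[g$i], r0 = r0_sc[g$i])
    }

    # burial: every Cbeta x carboxyl O, prefactor lambda/(4N)
    nb <- which(!layout$gly)
    if (length(nb)) {
      g <- .pairGrid(nb, seq_along(iox))
      tab$burial <- list(
        ia = as.integer(layout$idx_cb[g$i]), ib = as.integer(iox[g$j]),
        pref = pget(params, "burial", "lambda") / (4 * n),
        r0 = pget(params, "burial", "r0"))
    }

    # excluded volume: every protein bead x every heme atom
    prot_rows <- c(layout$idx_ca, layout$idx_cb[!layout$gly], layout$idx_o)
    g <- .pairGrid(prot_rows, layout$idx_heme)
    tab$excl <- list(ia = as.integer(g$i), ib = as.integer(g$j),
                     lambda = pget(params, "excl", "lambda"),
                     r0 = pget(params, "excl", "r0"))

    # thioester (heme c only): one bond per attachment cysteine, matched to
    # its nearest vinyl carbon so each vinyl carries a single specific bond
    if (heme@type == "c" && length(state@cysAttach) == 2) {
      cbx <- p@cb[state@cysAttach, , drop = FALSE]
      vx <- heme@xyz[heme@role == "C_VINYL", , drop = FALSE]
      d <- function(i, j) sqrt(sum((cbx[i, ] - vx[j, ])^2))
      pairing <- if (d(1, 1) + d(2, 2) <= d(1, 2) + d(2, 1)) c(1L, 2L)
                 else c(2L, 1L)
      tab$thio <- list(ia = as.integer(layout$idx_cb[state@cysAttach]),
                       ib = as.integer(ivin[pairing]),
                       lambda = pget(params, "thioester", "lambda_cs"),
                       r0 = pget(params, "thioester", "r0"))
    }

    # internal heme forcefield, indices shifted into the global layout
    off <- layout$idx_heme[1] - 1L
    b <- heme@bonds; a <- heme@angles; d <- heme@dihedrals; nbp <- heme@nonbonded
    qnb <- lam_e * nbp$qscale * heme@charge[nbp$i] * heme@charge[nbp$j]
    sel <- qnb != 0
    tab$heme_int <- list(
      bonds = list(ia = as.integer(b$i + off), ib = as.integer(b$j + off),
                   k = b$kf, r0 = b$r0),
      angles = list(ia = as.integer(a$i + off), ib = as.integer(a$j + off),
                    ic = as.integer(a$k + off), k = a$kf, th0 = a$theta0),
      dihedrals = list(ia = as.integer(d$i + off), ib = as.integer(d$j + off),
                       ic = as.integer(d$k + off), id = as.integer(d$l + off),
                       k = d$kf, n = as.numeric(d$n), delta = d$delta),
      lj = list(ia = as.integer(nbp$i + off), ib = as.integer(nbp$j + off),
                sig = nbp$sigma, eps = nbp$epsilon, scale = nbp$ljscale),
      coul = list(ia = as.integer((nbp$i + off)[sel]),
                  ib = as.integer((nbp$j + off)[sel]),
                  qq = qnb[sel], kappa = kappa))
  }

  if (!is.null(native)) tab$standin <- standinTables(p, native, params, layout)
  ctx$tab <- tab
  ctx
}

# Structure-based single-memory stand-in tables (native = reference protein)
standinTables <- function(p, native, params, layout) {
  np <- if (is(native, "SystemState")) native@protein else native
  n <- layout$n
  if (nResidues(np) != n) stop("native/protein length mismatch")
  sep_min <- pget(params, "standin", "min_separation")
  eps_ca <- pget(params, "standin", "epsilon_ca")
  eps_cb <- pget(params, "standin", "epsilon_cb")
  w <- pget(params, "standin", "width_scale")
  kb <- pget(params, "standin", "k_bond")
  kc <- pget(params, "standin", "k_chirality")

  pr <- function(idx_rows, coords, eps) {
    keep <- which(!is.na(idx_rows))
    cmb <- if (length(keep) >= 2) t(combn(keep, 2)) else matrix(0L, 0, 2)
    if (nrow(cmb)) cmb <- cmb[cmb[, 2] - cmb[, 1] >= sep_min, , drop = FALSE]
    if (!nrow(cmb)) return(list(ia = integer(), ib = integer(),
                                eps = numeric(), r0 = numeric(),
                                sigma = numeric()))
    r0 <- sqrt(rowSums((coords[cmb[, 1], , drop = FALSE] -
                        coords[cmb[, 2], , drop = FALSE])^2))
    list(ia = idx_rows[cmb[, 1]], ib = idx_rows[cmb[, 2]],
         eps = rep(eps, nrow(cmb)), r0 = r0,
         sigma = w * (cmb[, 2] - cmb[, 1])^0.15)
  }
  wells_ca <- pr(layout$idx_ca, np@ca, eps_ca)
  cb_rows <- layout$idx_cb
  wells_cb <- pr(cb_rows, np@cb, eps_cb)
  wells <- list(ia = as.integer(c(wells_ca$ia, wells_cb$ia)),
                ib = as.integer(c(wells_ca$ib, wells_cb$ib)),
                eps = c(wells_ca$eps, wells_cb$eps),
                r0 = c(wells_ca$r0, wells_cb$r0),
                sigma = c(wells_ca$sigma, wells_cb$sigma))

  # chain-connectivity bonds at native geometry
  bi <- integer(); bj <- integer(); br <- numeric()
  add_bond <- function(i, j, r) { bi <<- c(bi, i); bj <<- c(bj, j); br <<- c(br, r) }
  dnat <- function(a, b) sqrt(sum((a - b)^2))
  for (i in seq_len(n - 1))
    add_bond(layout$idx_ca[i], layout$idx_ca[i + 1], dnat(np@ca[i, ], np@ca[i + 1, ]))
  for (i in which(!layout$gly))
    add_bond(layout$idx_ca[i], layout$idx_cb[i], dnat(np@ca[i, ], np@cb[i, ]))
  for (i in seq_len(n)) {
    add_bond(layout$idx_ca[i], layout$idx_o[i], dnat(np@ca[i, ], np@o[i, ]))
    if (i < n)
      add_bond(layout$idx_o[i], layout$idx_ca[i + 1], dnat(np@o[i, ], np@ca[i + 1, ]))
  }
  bonds <- list(ia = as.integer(bi), ib = as.integer(bj),
                k = rep(kb, length(bi)), r0 = br)

  # chirality: signed volume around each inner non-glycine residue
  ci <- which(!layout$gly)
  ci <- ci[ci > 1 & ci < n]
  d0 <- vapply(ci, function(i) {
    v1 <- np@ca[i, ] - np@ca[i - 1, ]
    v2 <- np@ca[i + 1, ] - np@ca[i, ]
    w3 <- np@cb[i, ] - np@ca[i, ]
    sum((c(v1[2] * v2[3] - v1[3] * v2[2],
           v1[3] * v2[1] - v1[1] * v2[3],
           v1[1] * v2[2] - v1[2] * v2[1])) * w3)
  }, numeric(1))
  chir <- list(ia = as.integer(layout$idx_ca[ci - 1]),
               ib = as.integer(layout$idx_ca[ci]),
               ic = as.integer(layout$idx_ca[ci + 1]),
               id = as.integer(layout$idx_cb[ci]),
               k = rep(kc, length(ci)), d0 = d0)

  # native backbone geometry (standard structure-based-model terms): Calpha
  # virtual-bond angles and dihedrals at their native values give the chain
  # realistic stiffness, so an unfolded coil cannot wrap the cofactor
  # without paying for non-native local structure
  ka <- pget(params, "standin", "k_angle")
  kd <- pget(params, "standin", "k_dihedral")
  ang_i <- if (n >= 3) 2:(n - 1) else integer()
  th0 <- vapply(ang_i, function(i) {
    u <- np@ca[i - 1, ] - np@ca[i, ]; v <- np@ca[i + 1, ] - np@ca[i, ]
    acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
  }, numeric(1))
  angles <- list(ia = as.integer(layout$idx_ca[ang_i - 1]),
                 ib = as.integer(layout$idx_ca[ang_i]),
                 ic = as.integer(layout$idx_ca[ang_i + 1]),
                 k = rep(ka, length(ang_i)), th0 = th0)
  dih_i <- if (n >= 4) seq_len(n - 3) else integer()
  phi0 <- vapply(dih_i, function(i)
    .dihedral_angle(np@ca[i, ], np@ca[i + 1, ], np@ca[i + 2, ], np@ca[i + 3, ]),
    numeric(1))
  ok <- !is.na(phi0)
  dih_i <- dih_i[ok]; phi0 <- phi0[ok]
  # k (1 + cos(phi - phi0 - pi)) = k (1 - cos(phi - phi0))
  dihedrals <- list(ia = as.integer(layout$idx_ca[dih_i]),
                    ib = as.integer(layout$idx_ca[dih_i + 1]),
                    ic = as.integer(layout$idx_ca[dih_i + 2]),
                    id = as.integer(layout$idx_ca[dih_i + 3]),
                    k = rep(kd, length(dih_i)), n = rep(1, length(dih_i)),
                    delta = phi0 - pi)

  # chain self-avoidance between Calphas (sequence separation >= 3)
  cmb <- if (n >= 2) t(combn(seq_len(n), 2)) else matrix(0L, 0, 2)
  cmb <- cmb[cmb[, 2] - cmb[, 1] >= 3, , drop = FALSE]
  sexcl <- list(ia = as.integer(layout$idx_ca[cmb[, 1]]),
                ib = as.integer(layout$idx_ca[cmb[, 2]]),
                lambda = pget(params, "standin", "excl_lambda"),
                r0 = pget(params, "standin", "excl_r0"))

  list(wells = wells, bonds = bonds, chir = chir, angles = angles,
       dihedrals = dihedrals, excl = sexcl)
}

# Q_w pair tables against a reference protein
qwTables <- function(ref, layout = NULL) {
  rp <- if (is(ref, "SystemState")) ref@protein else ref
  n <- nResidues(rp)
  if (n < 4) stop("Q_w needs at least 4 residues")
  cmb <- t(combn(seq_len(n), 2))
  cmb <- cmb[cmb[, 2] - cmb[, 1] > 2, , drop = FALSE]
  rn <- sqrt(rowSums((rp@ca[cmb[, 1], , drop = FALSE] -
                      rp@ca[cmb[, 2], , drop = FALSE])^2))
  rows_a <- cmb[, 1]; rows_b <- cmb[, 2]
  if (!is.null(layout)) { rows_a <- layout$idx_ca[rows_a]; rows_b <- layout$idx_ca[rows_b] }
  # sequence-separation-dependent well width |j-i|^0.15 Angstrom, expressed
  # in the package's nm length unit
  list(ia = rows_a, ib = rows_b, rn = rn,
       sigma = 0.1 * (cmb[, 2] - cmb[, 1])^0.15,
       pref = 2 / ((n - 2) * (n - 3)))
}

# Full energy/gradient evaluation on the packed coordinates (single C++
# pass over the precomputed tables).
.energyGrad <- function(P, ctx, grad = TRUE) {
  res <- cpp_total(P, ctx$tab)
  terms <- res$terms
  list(terms = terms[BREAKDOWN_TERMS], restraint = terms[["restraint"]],
       grad = if (grad) res$grad else NULL)
}

# internal helper states skip the SystemState validity check so single
# coupling terms can be evaluated without a full heme-c attachment spec
.miniState <- function(protein, heme, cys = integer(), distal = NULL) {
  st <- new("SystemState", protein = protein, heme = NULL,
            cysAttach = as.integer(cys), distalRestraint = distal)
  slot(st, "heme", check = FALSE) <- heme
  st
}

.termEnergy <- function(protein, heme, params, which, cys = integer(),
                        distal = NULL) {
  st <- .miniState(protein, heme, cys, distal)
  ctx <- ffContext(st, native = NULL, params = params)
  P <- packCoords(st, ctx$layout)
  .energyGrad(P, ctx, grad = FALSE)$terms[[which]]
}

#' Coordinate-covalent Fe-residue energy
#'
#' Sum over inner, non-glycine residues of a radial well on the Cbeta-Fe
#' distance gated by the four Cbeta-Fe-N(pyrrole) angles, restraining an
#' axial ligand directly above the heme plane.  Residues on a blocked distal
#' face (see `distal`) contribute zero.
#'
#' @param protein a [CoarseProtein-class]
#' @param heme a [Heme-class]
#' @param params a [ParameterSet-class]
#' @param distal optional list(face = +1/-1) masking one heme face
#' @return energy in kJ/mol
#' @export
vFeCC <- function(protein, heme, params = defaultParameters(), distal = NULL) {
  .termEnergy(protein, heme, params, "fe_cc", distal = distal)
}

#' Screened (Debye-Hueckel) electrostatic energy between residue charges and
#' heme partial charges
#' @inheritParams vFeCC
#' @export
vElec <- function(protein, heme, params = defaultParameters()) {
  .termEnergy(protein, heme, params, "elec")
}

#' Backbone N-H to heme-carboxylate hydrogen-bond energy
#' @inheritParams vFeCC
#' @export
vHBBackbone <- function(protein, heme, params = defaultParameters()) {
  .termEnergy(protein, heme, params, "hb_backbone")
}

#' Sidechain to heme-carboxylate hydrogen-bond energy
#' @inheritParams vFeCC
#' @export
vHBSidechain <- function(protein, heme, params = defaultParameters()) {
  .termEnergy(protein, heme, params, "hb_sidechain")
}

#' Carboxylate burial penalty
#' @inheritParams vFeCC
#' @export
vBurial <- function(protein, heme, params = defaultParameters()) {
  .termEnergy(protein, heme, params, "burial")
}

#' Excluded-volume energy between all protein beads and all heme atoms
#' @inheritParams vFeCC
#' @export
vExcl <- function(protein, heme, params = defaultParameters()) {
  .termEnergy(protein, heme, params, "excl")
}

#' Thioester covalent-bond energy (heme c only)
#'
#' @inheritParams vFeCC
#' @param cys residue indices of the two attachment cysteines (CXXC spacing)
#' @export
vThioester <- function(protein, heme, cys, params = defaultParameters()) {
  if (heme@type != "c")
    stop("thioester term is undefined for heme b")
  .termEnergy(protein, heme, params, "thioester", cys = cys)
}

#' Internal heme energy (bonds, angles, dihedrals, LJ + screened Coulomb)
#' @param heme a [Heme-class]
#' @param params a [ParameterSet-class]
#' @export
hemeInternalEnergy <- function(heme, params = defaultParameters()) {
  # evaluate with a 1-residue placeholder protein far away so only the
  # internal term is nonzero; coupling terms need >= 3 residues anyway
  dummy <- new("CoarseProtein", sequence = "G",
               ca = matrix(c(1e3, 0, 0), 1), cb = matrix(NA_real_, 1, 3),
               o = matrix(c(1e3, 0.3, 0), 1), charge = 0)
  .termEnergy(dummy, heme, params, "heme_internal")
}

#' Structure-based single-memory protein energy
#'
#' Gaussian wells on Calpha-Calpha and Cbeta-Cbeta pair distances centered
#' on their native values (sequence separation >= 3), harmonic
#' chain-connectivity bonds and a chirality restraint.  Stands in for a
#' transferable protein forcefield so the coupled system has a funneled
#' protein landscape.
#'
#' @param protein current conformation, a [CoarseProtein-class]
#' @param native reference conformation (same sequence)
#' @param params a [ParameterSet-class]
#' @export
proteinStandinEnergy <- function(protein, native, params = defaultParameters()) {
  st <- .miniState(protein, NULL)
  ctx <- ffContext(st, native = native, params = params)
  P <- packCoords(st, ctx$layout)
  .energyGrad(P, ctx, grad = FALSE)$terms[["protein_standin"]]
}

#' Total energy of the coupled system
#'
#' Assembles every applicable term (the thioester term only for heme c) into
#' an [EnergyBreakdown-class] whose total is the exact sum of components.
#'
#' @param state a [SystemState-class]
#' @param native reference [SystemState-class] or [CoarseProtein-class] for
#'   the protein stand-in term (NULL to omit it)
#' @param params a [ParameterSet-class]
#' @export
totalEnergy <- function(state, native = NULL, params = defaultParameters()) {
  ctx <- ffContext(state, native = native, params = params)
  P <- packCoords(state, ctx$layout)
  new("EnergyBreakdown", terms = .energyGrad(P, ctx, grad = FALSE)$terms)
}

#' Forces on all particles
#'
#' Negative gradient of the total energy with respect to every mobile
#' coordinate; forces on the reconstructed (virtual) backbone sites are
#' chain-ruled onto their parent beads.
#'
#' @inheritParams totalEnergy
#' @return list with N x 3 force matrices `ca`, `cb` (NA rows for glycine),
#'   `o` and, if present, `heme` (kJ/mol/nm)
#' @export
systemForces <- function(state, native = NULL, params = defaultParameters()) {
  ctx <- ffContext(state, native = native, params = params)
  P <- packCoords(state, ctx$layout)
  res <- .energyGrad(P, ctx, grad = TRUE)
  Fm <- -res$grad
  lay <- ctx$layout
  cb <- matrix(NA_real_, lay$n, 3)
  cb[!lay$gly, ] <- Fm[lay$idx_cb[!lay$gly], , drop = FALSE]
  out <- list(ca = Fm[lay$idx_ca, , drop = FALSE], cb = cb,
              o = Fm[lay$idx_o, , drop = FALSE])
  if (length(lay$idx_heme)) out$heme <- Fm[lay$idx_heme, , drop = FALSE]
  out
}
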