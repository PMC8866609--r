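# Heme construction: role tagging by PDB v3 atom-name convention, internal
# topology generated from the reference geometry, and charge assignment from
# the parameter file.

# default PDB v3 HEM/HEC role map
.default_role_map <- list(
  FE = "FE",
  N_PYRROLE = c("NA", "NB", "NC", "ND"),
  O_CARBOXYL = c("O1A", "O2A", "O1D", "O2D"),
  C_VINYL = c("CAB", "CAC"))

#' Tag heme atoms with their functional role
#'
#' Maps atom names to roles (FE, N_PYRROLE, O_CARBOXYL, C_VINYL, OTHER)
#' using the PDB v3 HEM/HEC naming convention by default.
#'
#' @param names character vector of atom names
#' @param role_map optional override list with entries FE, N_PYRROLE,
#'   O_CARBOXYL, C_VINYL (each a character vector of atom names)
#' @export
tagHemeRoles <- function(names, role_map = NULL) {
  rm <- .default_role_map
  if (!is.null(role_map)) rm[names(role_map)] <- role_map
  role <- rep("OTHER", length(names))
  for (r in names(rm)) role[names %in% rm[[r]]] <- r
  role
}

elementFromName <- function(name) {
  ifelse(name == "FE", "FE", substr(gsub("[0-9]", "", name), 1, 1))
}

# assign partial charges from the parameter table by atom name; atoms absent
# from the table share the residual so the total matches the declared formal
# charge (keeps the invariant for nonstandard atom sets)
hemeCharges <- function(names, params, type) {
  tbl <- pget(params, "heme", "charges")
  q <- vapply(names, function(nm) {
    v <- tbl[[nm]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  formal <- as.numeric(pget(params, "heme", "formal_charge")[[type]])
  miss <- is.na(q)
  if (any(miss)) {
    q[miss] <- (formal - sum(q[!miss])) / sum(miss)
  } else if (abs(sum(q) - formal) > 1e-6) {
    # tabulated subset of a larger atom set: spread the residual evenly
    q <- q + (formal - sum(q)) / length(q)
  }
  unname(q)
}

# covalent bond detection cutoffs (nm) by element pair
.bond_cutoff <- function(e1, e2) {
  pair <- paste(sort(c(e1, e2)), collapse = "-")
  switch(pair,
    "FE-N" = 0.23,
    "C-N" = 0.18,
    "C-C" = 0.27,
    "C-O" = 0.17,
    0)
}

#' Build internal heme topology from a reference geometry
#'
#' Detects covalent bonds by element-specific distance cutoffs, then derives
#' angles (every bonded pair around a central atom), one periodic dihedral
#' per central bond, and the nonbonded pair list with 1-2/1-3 exclusions and
#' 1-4 scaling.  Equilibrium values are taken from the reference geometry so
#' the bonded energy of the reference structure is exactly zero.
#'
#' @param name,element character vectors per atom
#' @param xyz n x 3 coordinates (nm)
#' @param params a [ParameterSet-class]
#' @return list(bonds, angles, dihedrals, nonbonded) data.frames
#' @export
hemeTopologyFromGeometry <- function(name, element, xyz, params) {
  n <- length(name)
  kb <- pget(params, "heme", "k_bond")
  ka <- pget(params, "heme", "k_angle")
  kd <- pget(params, "heme", "k_dihedral")
  ljtbl <- pget(params, "heme", "lj")
  s14lj <- pget(params, "heme", "scale14_lj")
  s14q <- pget(params, "heme", "scale14_coul")

  dmat <- as.matrix(dist(xyz))
  bi <- integer(); bj <- integer()
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    cut <- .bond_cutoff(element[i], element[j])
    if (cut > 0 && dmat[i, j] < cut) { bi <- c(bi, i); bj <- c(bj, j) }
  }
  bonds <- data.frame(i = bi, j = bj, kf = rep(kb, length(bi)),
                      r0 = dmat[cbind(bi, bj)])

  adj <- lapply(seq_len(n), function(i) sort(c(bj[bi == i], bi[bj == i])))

  ai <- integer(); aj <- integer(); ak <- integer(); th0 <- numeric()
  for (b in seq_len(n)) {
    nb <- adj[[b]]
    if (length(nb) < 2) next
    for (p in seq_len(length(nb) - 1)) for (q in seq(p + 1, length(nb))) {
      a <- nb[p]; cc <- nb[q]
      u <- xyz[a, ] - xyz[b, ]; v <- xyz[cc, ] - xyz[b, ]
      cth <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
      th <- acos(max(-1, min(1, cth)))
      # near-linear angles are left to the dihedral terms: the harmonic
      # angle gradient has a 1/sin(theta) singularity at theta = pi
      if (th > 2.6) next
      ai <- c(ai, a); aj <- c(aj, b); ak <- c(ak, cc)
      th0 <- c(th0, th)
    }
  }
  angles <- data.frame(i = ai, j = aj, k = ak, kf = rep(ka, length(ai)),
                       theta0 = th0)

  # one dihedral per central bond with flanking neighbors, n = 2,
  # delta chosen so the reference geometry sits at a minimum
  di <- integer(); dj <- integer(); dk <- integer(); dl <- integer()
  del <- numeric()
  for (t in seq_len(nrow(bonds))) {
    b <- bonds$i[t]; cc <- bonds$j[t]
    a <- setdiff(adj[[b]], cc); d <- setdiff(adj[[cc]], b)
    if (!length(a) || !length(d)) next
    a <- a[1]; d <- d[1]
    if (a == d) next
    phi <- .dihedral_angle(xyz[a, ], xyz[b, ], xyz[cc, ], xyz[d, ])
    if (is.na(phi)) next
    di <- c(di, a); dj <- c(dj, b); dk <- c(dk, cc); dl <- c(dl, d)
    del <- c(del, 2 * phi - pi)
  }
  dihedrals <- data.frame(i = di, j = dj, k = dk, l = dl,
                          kf = rep(kd, length(di)), n = rep(2, length(di)),
                          delta = del)

  # bonded-path distances for exclusions (BFS up to 3 bonds)
  sep <- matrix(Inf, n, n)
  diag(sep) <- 0
  for (i in seq_len(n)) {
    frontier <- i
    for (d in 1:3) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[sep[i, nxt] > d]
      if (!length(nxt)) break
      sep[i, nxt] <- pmin(sep[i, nxt], d)
      frontier <- nxt
    }
  }
  ni <- integer(); nj <- integer(); sg <- numeric(); ep <- numeric()
  ls <- numeric(); qs <- numeric()
  ljel <- function(e) {
    v <- ljtbl[[e]]
    if (is.null(v)) stop("no LJ parameters for element ", e)
    v
  }
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (sep[i, j] <= 2) next
    li <- ljel(element[i]); lj <- ljel(element[j])
    ni <- c(ni, i); nj <- c(nj, j)
    sg <- c(sg, (li$sigma + lj$sigma) / 2)
    ep <- c(ep, sqrt(li$epsilon * lj$epsilon))
    if (sep[i, j] == 3) { ls <- c(ls, s14lj); qs <- c(qs, s14q) }
    else { ls <- c(ls, 1); qs <- c(qs, 1) }
  }
  nonbonded <- data.frame(i = ni, j = nj, sigma = sg, epsilon = ep,
                          ljscale = ls, qscale = qs)

  list(bonds = bonds, angles = angles, dihedrals = dihedrals,
       nonbonded = nonbonded)
}

.dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-18 || sum(n2^2) < 1e-18) return(NA_real_)
  m <- c(n1[2] * n2[3] - n1[3] * n2[2],
         n1[3] * n2[1] - n1[1] * n2[3],
         n1[1] * n2[2] - n1[2] * n2[1])
  atan2(sum(m * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
}

#' Construct a Heme object
#'
#' Tags roles, assigns charges from the parameter file and builds the
#' internal topology from the supplied geometry.
#'
#' @param name,xyz atom names and n x 3 coordinates (nm)
#' @param type "b" or "c"
#' @param params a [ParameterSet-class]
#' @param role_map optional role-map override (see [tagHemeRoles])
#' @export
newHeme <- function(name, xyz, type, params = defaultParameters(),
                    role_map = NULL) {
  role <- tagHemeRoles(name, role_map)
  if (sum(role == "FE") != 1 || sum(role == "N_PYRROLE") != 4)
    stop("heme topology error: need 1 FE and 4 pyrrole N atoms (found ",
         sum(role == "FE"), " FE, ", sum(role == "N_PYRROLE"), " N)")
  element <- elementFromName(name)
  topo <- hemeTopologyFromGeometry(name, element, xyz, params)
  charge <- hemeCharges(name, params, type)
  formal <- as.numeric(pget(params, "heme", "formal_charge")[[type]])
  h <- new("Heme", name = name, element = element, xyz = xyz,
           charge = charge, role = role, type = type,
           bonds = topo$bonds, angles = topo$angles,
           dihedrals = topo$dihedrals, nonbonded = topo$nonbonded,
           formalCharge = formal)
  validObject(h)
  h
}

hemeMasses <- function(heme) {
  m <- c(C = 12.011, N = 14.007, O = 15.999, FE = 55.845, H = 1.008,
         S = 32.06)
  out <- m[heme@element]
  out[is.na(out)] <- 12.011
  unname(out)
}
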