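# Self-contained toy systems: an idealized planar heme and a designable
# helical-hairpin mini-globin with a defined native pocket, so every other
# module is testable without external structure downloads.

# idealized heme layout: (name, radius nm, angle deg); Fe at the origin,
# everything in the z = 0 plane
.ideal_heme_layout <- data.frame(
  name = c("FE",
           "NA", "NB", "NC", "ND",
           "C1A", "C2A", "C1B", "C2B", "C1C", "C2C", "C1D", "C2D",
           "CHA", "CHB", "CHC",
           "CGA", "O1A", "O2A",
           "CGD", "O1D", "O2D",
           "CAB", "CAC"),
  r = c(0,
        0.20, 0.20, 0.20, 0.20,
        0.31, 0.31, 0.31, 0.31, 0.31, 0.31, 0.31, 0.31,
        0.34, 0.34, 0.34,
        0.47, 0.575, 0.575,
        0.47, 0.575, 0.575,
        0.45, 0.45),
  ang = c(0,
          45, 135, 225, 315,
          25, 65, 115, 155, 205, 245, 295, 335,
          0, 90, 180,
          25, 13, 37,
          335, 323, 347,
          150, 210),
  stringsAsFactors = FALSE)

#' Build an idealized planar heme
#'
#' A 24-atom porphyrin skeleton: Fe at the origin, four pyrrole N at 0.20 nm
#' in a square, eight pyrrole and three meso carbons closing the ring, two
#' propionate arms each ending in two carboxylate O, and two vinyl carbons
#' (thioester attachment points for heme c).  All atoms are coplanar and the
#' Fe coincides with the pyrrole-N centroid by construction.  Partial
#' charges come from the parameter file and sum to the declared formal
#' charge; the internal topology is generated from this geometry, so the
#' bonded energy of the ideal structure is exactly zero.
#'
#' @param type "b" or "c"
#' @param params a [ParameterSet-class]
#' @return a [Heme-class]
#' @export
makeIdealHeme <- function(type = "b", params = defaultParameters()) {
  lay <- .ideal_heme_layout
  th <- lay$ang * pi / 180
  xyz <- cbind(lay$r * cos(th), lay$r * sin(th), 0)
  newHeme(lay$name, xyz, type, params)
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) c(0, 0, 1) else v / n
}

# circular-arc bridge between two anchors with nseg equal segments of
# length ~target, bulging toward `bulge`; returns the nseg-1 interior points
.bridge <- function(p0, p1, nseg, bulge, target = 0.37) {
  cvec <- p1 - p0
  cl <- sqrt(sum(cvec^2))
  if (cl / nseg > target + 0.05)
    stop("bridge anchors too far apart (", signif(cl, 3), " nm over ",
         nseg, " segments)")
  e1 <- cvec / cl
  e2 <- .unit(bulge - sum(bulge * e1) * e1)
  seglen <- function(h) {
    R <- cl^2 / (8 * h) + h / 2
    th_tot <- 2 * asin(min(cl / (2 * R), 1))
    2 * R * sin(th_tot / (2 * nseg))
  }
  if (cl / nseg >= target - 0.02) {
    h <- 1e-4
  } else if (seglen(cl / 2 * 0.999) <= target) {
    h <- cl / 2 * 0.999              # semicircle: longest minor-arc spacing
  } else {
    h <- uniroot(function(h) seglen(h) - target, c(1e-5, cl / 2 * 0.999))$root
  }
  R <- cl^2 / (8 * h) + h / 2
  m <- (p0 + p1) / 2
  phi0 <- atan2(R - h, -cl / 2)
  phi1 <- atan2(R - h, cl / 2)
  phis <- seq(phi0, phi1, length.out = nseg + 1)[2:nseg]
  t(vapply(phis, function(ph)
    m + (R - h) * (-e2) + R * (cos(ph) * e1 + sin(ph) * e2), numeric(3)))
}

.autoSequence <- function(n, hemeType) {
  if (n < 28 || n > 36) stop("toy size must be between 28 and 36 residues")
  att <- if (hemeType == "c") "C" else "S"
  # helix B carries the distal methionine at position 25 (His/Met bis-axial
  # coordination, as in cytochromes)
  helB <- rep(c("L", "K", "A", "L", "M", "E", "L", "A", "K", "L", "S", "E",
                "A", "L", "K"), length.out = n - 21)
  c("A", att, "E", "K", att, "A",
    "L", "E", "A", "L", "H", "K", "L", "A", "E", "L",
    "G", "D", "G", "A",
    helB, "A")
}

#' Build the toy mini-globin with its heme pocket
#'
#' Constructs a compact helical-hairpin protein docked on an idealized heme:
#' the axial histidine's Cbeta sits exactly at the Fe coordination
#' equilibrium distance on the ring normal, several residues form native
#' pocket contacts under the Q_c cutoff, and (for heme c) the two vinyl
#' carbons sit at the thioester equilibrium distance from the CXXC cysteine
#' Cbetas.  The pocket is built at the equilibrium distances of the loaded
#' parameter set, so energy-minimum tests stay valid if parameters change.
#' Also returns an extended state: the same sequence as a self-avoiding
#' random coil with the heme placed >= 3 nm from the protein centroid.
#'
#' @param hemeType "b" or "c"
#' @param n number of residues (28..36)
#' @param seed RNG seed for the extended-coil construction
#' @param params a [ParameterSet-class]
#' @param sequence optional explicit one-letter sequence (length n; must
#'   keep H at position 11 and, for heme c, C at positions 2 and 5)
#' @return list(native, extended), both [SystemState-class]
#' @export
makeMiniGlobin <- function(hemeType = c("b", "c"), n = 30, seed = 1,
                           params = defaultParameters(), sequence = NULL) {
  hemeType <- match.arg(hemeType)
  seqv <- if (is.null(sequence)) .autoSequence(n, hemeType)
          else strsplit(sequence, "")[[1]]
  if (length(seqv) != n) stop("sequence length != n")
  if (seqv[11] != "H") stop("pocket spec requires His at position 11")
  if (seqv[25] != "M") stop("pocket spec requires Met at position 25")
  if (hemeType == "c" && !(seqv[2] == "C" && seqv[5] == "C"))
    stop("heme c pocket spec requires cysteines at positions 2 and 5 (CXXC)")

  heme <- makeIdealHeme(hemeType, params)
  r0 <- pget(params, "fe_cc", "r0")
  rth <- pget(params, "thioester", "r0")
  helixR <- 0.23; rise <- 0.15; twist <- 100 * pi / 180
  z0 <- r0 + 0.153 + helixR

  ca <- matrix(NA_real_, n, 3)
  cbdir <- matrix(NA_real_, n, 3)    # explicit Cbeta directions where fixed

  # helix A (residues 8..16), axial His at 11 pointing straight down at Fe
  for (i in 8:16) {
    ph <- (i - 11) * twist
    ca[i, ] <- c((i - 11) * rise, helixR * sin(ph), z0 - helixR * cos(ph))
    cbdir[i, ] <- c(0, sin(ph), -cos(ph))
  }
  # helix B (residues 21..n-1) below the heme plane, running back in -x,
  # with the distal Met (residue 25) pointing its Cbeta up at the Fe
  for (i in 21:(n - 1)) {
    ph <- (i - 25) * twist
    ca[i, ] <- c((25 - i) * rise, helixR * sin(ph), -z0 + helixR * cos(ph))
    cbdir[i, ] <- c(0, sin(ph), cos(ph))
  }

  # cysteine (or serine stand-in) anchors over the heme rim near the vinyls
  vin <- heme@xyz[heme@role == "C_VINYL", , drop = FALSE]
  anchor <- function(v) {
    out <- .unit(c(v[1], v[2], 0))
    dirv <- .unit(out * cos(50 * pi / 180) + c(0, 0, sin(50 * pi / 180)))
    cb <- v + rth * dirv
    caup <- cb + 0.153 * .unit(0.3 * out + c(0, 0, 1))
    list(cb = cb, ca = caup)
  }
  a2 <- anchor(vin[1, ]); a5 <- anchor(vin[2, ])
  ca[2, ] <- a2$ca; ca[5, ] <- a5$ca

  away <- function(p) .unit(c(p[1], p[2], 0))
  ca[3:4, ] <- .bridge(ca[2, ], ca[5, ], 3, away((ca[2, ] + ca[5, ]) / 2))
  ca[6:7, ] <- .bridge(ca[5, ], ca[8, ], 3, away(ca[5, ]) + c(0, 0, 0.5))
  ca[1, ] <- ca[2, ] + 0.38 * .unit(ca[2, ] - ca[3, ])
  # turn 17..20 wraps around the propionate rim (+x side) from helix A down
  # to helix B, on an arc in the x-z plane clearing the heme edge
  p16 <- ca[16, ]; p21 <- ca[21, ]
  a0 <- atan2(p16[3], p16[1]); r0p <- sqrt(p16[1]^2 + p16[3]^2)
  a1 <- atan2(p21[3], p21[1]); r1p <- sqrt(p21[1]^2 + p21[3]^2)
  for (k in 1:4) {
    t <- k / 5
    rr <- (1 - t) * r0p + t * r1p + 0.05 * sin(pi * t)   # slight bulge past the rim
    aa <- (1 - t) * a0 + t * a1
    ca[16 + k, ] <- c(rr * cos(aa), (1 - t) * p16[2] + t * p21[2],
                      rr * sin(aa))
  }
  ca[n, ] <- ca[n - 1, ] + 0.38 * .unit(ca[n - 1, ] - ca[n - 2, ])

  # Cbeta placement: fixed direction on helices, curvature rule elsewhere
  cb <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    if (seqv[i] == "G") next
    d <- if (i %in% c(8:16, 21:(n - 1))) cbdir[i, ]
    else if (i == 1) .unit(pracma_cross(ca[2, ] - ca[1, ], c(0, 0, 1)))
    else if (i == n) .unit(pracma_cross(ca[n, ] - ca[n - 1, ], c(0, 0, 1)))
    else .unit(2 * ca[i, ] - ca[i - 1, ] - ca[i + 1, ])
    cb[i, ] <- ca[i, ] + 0.153 * d
  }
  cb[2, ] <- a2$cb
  cb[5, ] <- a5$cb

  # carbonyl O from the local frame (screw-covariant on the helices, so
  # reconstructed backbone sites repeat exactly along a helix)
  o <- matrix(NA_real_, n, 3)
  for (i in seq_len(n - 1)) {
    u <- .unit(ca[i + 1, ] - ca[i, ])
    d <- if (!any(is.na(cb[i, ]))) .unit(cb[i, ] - ca[i, ]) else c(0, 0, 1)
    w <- pracma_cross(u, d)
    if (sqrt(sum(w^2)) < 1e-6) w <- pracma_cross(u, c(1, 0, 0))
    o[i, ] <- (ca[i, ] + ca[i + 1, ]) / 2 + 0.1 * .unit(w)
  }
  o[n, ] <- ca[n, ] + 0.24 * .unit(ca[n, ] - ca[n - 1, ])

  protein <- new("CoarseProtein", sequence = seqv, ca = ca, cb = cb, o = o,
                 charge = residueCharge(seqv))
  validObject(protein)
  cys <- if (hemeType == "c") c(2L, 5L) else integer()
  native <- new("SystemState", protein = protein, heme = heme,
                cysAttach = cys, distalRestraint = NULL)
  validObject(native)
  .validatePocket(native, params)

  extended <- makeExtendedState(native, seed = seed, params = params)
  list(native = native, extended = extended)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.validatePocket <- function(native, params) {
  p <- native@protein; h <- native@heme
  rex <- pget(params, "excl", "r0")
  beads <- rbind(p@ca, p@cb[p@sequence != "G", , drop = FALSE], p@o)
  d <- sqrt(outer(rowSums(beads^2), rowSums(h@xyz^2), "+") -
            2 * beads %*% t(h@xyz))
  allow <- rex * 0.999
  if (min(d) < allow)
    stop("unsatisfiable pocket spec: protein bead within excluded-volume ",
         "distance of heme (", signif(min(d), 3), " nm)")
  ncont <- length(.contacts(native, pget(params, "qc_cutoff"), "residue"))
  if (ncont < 4)
    stop("unsatisfiable pocket spec: only ", ncont, " native heme contacts")
  # chain geometry sanity
  bl <- sqrt(rowSums(diff(p@ca)^2))
  if (any(bl < 0.25) || any(bl > 0.45))
    stop("unsatisfiable pocket spec: Calpha spacing out of range (",
         signif(min(bl), 3), "..", signif(max(bl), 3), ")")
  invisible(TRUE)
}

#' Extended (unfolded) starting state
#'
#' Same sequence as `native`, rebuilt as a self-avoiding random coil with
#' the heme (if present) placed `hemeDistance` nm from the protein centroid
#' in a random orientation.  Deterministic under `seed`.
#'
#' @param native a [SystemState-class]
#' @param seed RNG seed
#' @param params a [ParameterSet-class]
#' @param hemeDistance heme placement distance from the coil centroid (nm)
#' @export
makeExtendedState <- function(native, seed = 1, params = defaultParameters(),
                              hemeDistance = 3.2) {
  set.seed(seed)
  seqv <- native@protein@sequence
  n <- length(seqv)
  step <- 0.38
  ca <- matrix(NA_real_, n, 3)
  ca[1, ] <- 0
  dir <- .unit(rnorm(3))
  ca[2, ] <- ca[1, ] + step * dir
  for (i in 3:n) {
    for (try in 1:200) {
      # bend by < 90 degrees from the previous direction
      prop <- .unit(dir + .unit(rnorm(3)) * 0.9)
      cand <- ca[i - 1, ] + step * prop
      dmin <- min(sqrt(rowSums(sweep(ca[1:(i - 2), , drop = FALSE], 2,
                                     cand)^2)))
      if (dmin > 0.36) { ca[i, ] <- cand; dir <- prop; break }
    }
    if (any(is.na(ca[i, ]))) stop("self-avoiding walk failed at residue ", i)
  }
  cb <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    if (seqv[i] == "G") next
    d <- if (i == 1) .unit(pracma_cross(ca[2, ] - ca[1, ], c(0, 0, 1)))
    else if (i == n) .unit(pracma_cross(ca[n, ] - ca[n - 1, ], c(0, 0, 1)))
    else .unit(2 * ca[i, ] - ca[i - 1, ] - ca[i + 1, ])
    cb[i, ] <- ca[i, ] + 0.153 * d
  }
  o <- matrix(NA_real_, n, 3)
  for (i in seq_len(n - 1)) {
    u <- .unit(ca[i + 1, ] - ca[i, ])
    d <- if (!any(is.na(cb[i, ]))) .unit(cb[i, ] - ca[i, ]) else c(0, 0, 1)
    w <- pracma_cross(u, d)
    if (sqrt(sum(w^2)) < 1e-6) w <- pracma_cross(u, c(1, 0, 0))
    o[i, ] <- (ca[i, ] + ca[i + 1, ]) / 2 + 0.1 * .unit(w)
  }
  o[n, ] <- ca[n, ] + 0.24 * .unit(ca[n, ] - ca[n - 1, ])
  protein <- new("CoarseProtein", sequence = seqv, ca = ca, cb = cb, o = o,
                 charge = residueCharge(seqv))
  ext <- native
  ext@protein <- protein
  if (!is.null(native@heme)) {
    h <- native@heme
    centroid <- colMeans(ca)
    place <- centroid + hemeDistance * .unit(rnorm(3))
    # random orientation
    A <- matrix(rnorm(9), 3)
    qr_ <- qr(A)
    R <- qr.Q(qr_)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    xyz <- sweep(h@xyz %*% t(R), 2, place, "+")
    h@xyz <- xyz
    ext@heme <- h
  }
  validObject(ext)
  ext
}

#' Metropolis sampler on a 1D double well (WHAM test harness)
#'
#' Samples U(q) = a (q^2 - b)^2 with Gaussian proposals, optionally under a
#' harmonic umbrella bias 0.5 k (q - q0)^2.  The analytic potential is known
#' exactly, so WHAM output can be checked quantitatively.
#'
#' @param seed RNG seed
#' @param a barrier scale (kJ/mol); wells at q = +/- sqrt(b)
#' @param b well position squared
#' @param temperature K
#' @param step proposal standard deviation
#' @return list with `potential(q)`, `sample(n, q_init, bias)` (bias = NULL
#'   or list(k, q0); returns list(q, acceptance)), and the parameters
#' @export
makeDoubleWellSampler <- function(seed = 1, a = 20, b = 1, temperature = 300,
                                  step = 0.4) {
  beta <- 1 / (KB * temperature)
  U <- function(q) a * (q^2 - b)^2
  sample_fn <- function(n, q_init = sqrt(b), bias = NULL) {
    Ub <- if (is.null(bias)) U
          else function(q) U(q) + 0.5 * bias$k * (q - bias$q0)^2
    q <- numeric(n)
    cur <- q_init
    ecur <- Ub(cur)
    acc <- 0
    prop <- rnorm(n, sd = step)
    u <- runif(n)
    for (k in seq_len(n)) {
      cand <- cur + prop[k]
      ec <- Ub(cand)
      if (u[k] < exp(-beta * (ec - ecur))) {
        cur <- cand; ecur <- ec; acc <- acc + 1
      }
      q[k] <- cur
    }
    list(q = q, acceptance = acc / n)
  }
  list(potential = U, sample = sample_fn, a = a, b = b,
       temperature = temperature, seed = seed, step = step)
}

#' Umbrella windows drawn from the double-well sampler
#'
#' @param sampler from [makeDoubleWellSampler]
#' @param q0s window centers; kBias spring constant (kJ/mol)
#' @param kBias spring constant
#' @param nsamp samples per window
#' @return list of [UmbrellaWindow-class] (coordinate stored as `qw`)
#' @export
sampleDoubleWellWindows <- function(sampler, q0s, kBias = 100, nsamp = 5000) {
  set.seed(sampler$seed)
  lapply(q0s, function(q0) {
    out <- sampler$sample(nsamp, q_init = q0, bias = list(k = kBias, q0 = q0))
    new("UmbrellaWindow", q0 = q0, kBias = kBias,
        temperature = sampler$temperature,
        samples = data.frame(step = seq_len(nsamp), qw = out$q))
  })
}
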