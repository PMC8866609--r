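# Independent naive double-loop oracles for every energy term, written
# directly from the functional forms with no shared code with the package
# implementation, plus small fixture helpers.

KB_T <- 0.008314462618

pg <- function(params, ...) {
  v <- params@values
  for (k in c(...)) v <- v[[k]]
  v
}

res_param <- function(tbl, aa1) {
  three <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")[aa1]
  vapply(three, function(k) {
    v <- tbl[[k]]
    if (is.null(v)) tbl[["default"]] else v
  }, numeric(1))
}

o_dist <- function(a, b) sqrt(sum((a - b)^2))

o_fe_cc <- function(protein, heme, params) {
  n <- length(protein@sequence)
  lam <- res_param(pg(params, "fe_cc", "lambda"), protein@sequence)
  r0 <- pg(params, "fe_cc", "r0"); th0 <- pg(params, "fe_cc", "theta0")
  sgn <- pg(params, "fe_cc", "exponent_sign")
  fe <- heme@xyz[heme@role == "FE", ]
  npyr <- heme@xyz[heme@role == "N_PYRROLE", , drop = FALSE]
  E <- 0
  for (i in seq_len(n)) {
    if (i == 1 || i == n) next
    if (protein@sequence[i] == "G") next
    cb <- protein@cb[i, ]
    r <- o_dist(cb, fe)
    gates <- 1
    for (j in 1:4) {
      u <- cb - fe; v <- npyr[j, ] - fe
      cth <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
      th <- acos(max(-1, min(1, cth)))
      gates <- gates * (1 + tanh(2 * (sin(th) - sin(th0)))) / 2
    }
    E <- E + lam[i] * exp(sgn * (r - r0)^2) * gates
  }
  E
}

o_elec <- function(protein, heme, params) {
  lam <- pg(params, "elec", "lambda")
  kap <- pg(params, "elec", "k_screening") / pg(params, "elec", "l_screening")
  E <- 0
  for (i in seq_along(protein@sequence)) {
    if (protein@sequence[i] == "G" || protein@charge[i] == 0) next
    for (j in seq_along(heme@charge)) {
      if (heme@charge[j] == 0) next
      r <- o_dist(protein@cb[i, ], heme@xyz[j, ])
      E <- E + lam * protein@charge[i] * heme@charge[j] / r * exp(-kap * r)
    }
  }
  E
}

# virtual backbone sites from the affine coefficients in the parameter file
o_virtual_sites <- function(protein, params) {
  cn <- as.numeric(pg(params, "backbone_geometry", "n_coeff")); cn <- cn / sum(cn)
  ch <- as.numeric(pg(params, "backbone_geometry", "h_coeff")); ch <- ch / sum(ch)
  n <- length(protein@sequence)
  N <- H <- matrix(NA_real_, n, 3)
  for (i in 2:n) {
    N[i, ] <- cn[1] * protein@ca[i - 1, ] + cn[2] * protein@ca[i, ] +
      cn[3] * protein@o[i - 1, ]
    H[i, ] <- ch[1] * protein@ca[i - 1, ] + ch[2] * protein@ca[i, ] +
      ch[3] * protein@o[i - 1, ]
  }
  list(N = N, H = H)
}

o_hb_backbone <- function(protein, heme, params) {
  lam <- pg(params, "hb_backbone", "lambda")
  r0 <- pg(params, "hb_backbone", "r0"); th0 <- pg(params, "hb_backbone", "theta0")
  vs <- o_virtual_sites(protein, params)
  ox <- heme@xyz[heme@role == "O_CARBOXYL", , drop = FALSE]
  n <- length(protein@sequence)
  E <- 0
  for (i in seq_len(n)) {
    if (i == 1 || i == n) next
    H <- vs$H[i, ]; N <- vs$N[i, ]
    for (j in seq_len(nrow(ox))) {
      O <- ox[j, ]
      r <- o_dist(H, O)
      u <- N - H; v <- O - H
      cth <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
      th <- acos(max(-1, min(1, cth)))
      E <- E + lam * exp(-4 * (r - r0)^2) *
        (tanh(4 * (th - th0) - 6) + 1) / 2
    }
  }
  E
}

o_hb_sidechain <- function(protein, heme, params) {
  lam <- res_param(pg(params, "hb_sidechain", "lambda"), protein@sequence)
  r0 <- res_param(pg(params, "hb_sidechain", "r0"), protein@sequence)
  ox <- heme@xyz[heme@role == "O_CARBOXYL", , drop = FALSE]
  n <- length(protein@sequence)
  E <- 0
  for (i in seq_len(n)) {
    if (i == 1 || i == n || protein@sequence[i] == "G") next
    for (j in seq_len(nrow(ox))) {
      r <- o_dist(protein@cb[i, ], ox[j, ])
      E <- E + lam[i] * exp(-4 * (r - r0[i])^2)
    }
  }
  E
}

o_burial <- function(protein, heme, params) {
  lam <- pg(params, "burial", "lambda"); r0 <- pg(params, "burial", "r0")
  ox <- heme@xyz[heme@role == "O_CARBOXYL", , drop = FALSE]
  n <- length(protein@sequence)
  E <- 0
  for (i in seq_len(n)) {
    if (protein@sequence[i] == "G") next
    for (j in seq_len(nrow(ox))) {
      r <- o_dist(protein@cb[i, ], ox[j, ])
      E <- E + lam * (1 - tanh(8 * (r - r0))) / (4 * n)
    }
  }
  E
}

o_excl <- function(protein, heme, params) {
  lam <- pg(params, "excl", "lambda"); r0 <- pg(params, "excl", "r0")
  gly <- protein@sequence == "G"
  beads <- rbind(protein@ca, protein@cb[!gly, , drop = FALSE], protein@o)
  E <- 0
  for (i in seq_len(nrow(beads))) for (j in seq_along(heme@name)) {
    r <- o_dist(beads[i, ], heme@xyz[j, ])
    if (r < r0) E <- E + lam * (r - r0)^2
  }
  E
}

# one specific bond per attachment cysteine (nearest-vinyl pairing)
o_thioester <- function(protein, heme, cys, params) {
  lam <- pg(params, "thioester", "lambda_cs")
  r0 <- pg(params, "thioester", "r0")
  vin <- heme@xyz[heme@role == "C_VINYL", , drop = FALSE]
  cb <- protein@cb[cys, , drop = FALSE]
  d11 <- o_dist(cb[1, ], vin[1, ]) + o_dist(cb[2, ], vin[2, ])
  d12 <- o_dist(cb[1, ], vin[2, ]) + o_dist(cb[2, ], vin[1, ])
  pairs <- if (d11 <= d12) list(c(1, 1), c(2, 2)) else list(c(1, 2), c(2, 1))
  E <- 0
  for (pr in pairs) {
    dr <- o_dist(cb[pr[1], ], vin[pr[2], ]) - r0
    E <- E + lam * exp(-4 * dr^2) * (1 - tanh(3 * dr)) * (1 + tanh(32 * dr))
  }
  E
}

o_dihedral_phi <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cx <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cx(b1, b2); n2 <- cx(b2, b3)
  atan2(sum(cx(n1, n2) * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
}

o_heme_bonded <- function(heme) {
  E <- 0
  b <- heme@bonds
  for (t in seq_len(nrow(b)))
    E <- E + b$kf[t] * (o_dist(heme@xyz[b$i[t], ], heme@xyz[b$j[t], ]) - b$r0[t])^2
  a <- heme@angles
  for (t in seq_len(nrow(a))) {
    u <- heme@xyz[a$i[t], ] - heme@xyz[a$j[t], ]
    v <- heme@xyz[a$k[t], ] - heme@xyz[a$j[t], ]
    cth <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
    E <- E + a$kf[t] * (acos(max(-1, min(1, cth))) - a$theta0[t])^2
  }
  d <- heme@dihedrals
  for (t in seq_len(nrow(d))) {
    phi <- o_dihedral_phi(heme@xyz[d$i[t], ], heme@xyz[d$j[t], ],
                          heme@xyz[d$k[t], ], heme@xyz[d$l[t], ])
    E <- E + d$kf[t] * (1 + cos(d$n[t] * phi - d$delta[t]))
  }
  E
}

o_heme_internal <- function(heme, params) {
  E <- o_heme_bonded(heme)
  lam <- pg(params, "elec", "lambda")
  kap <- pg(params, "elec", "k_screening") / pg(params, "elec", "l_screening")
  nb <- heme@nonbonded
  for (t in seq_len(nrow(nb))) {
    r <- o_dist(heme@xyz[nb$i[t], ], heme@xyz[nb$j[t], ])
    sig <- nb$sigma[t]; eps <- nb$epsilon[t]
    rc <- 0.8 * sig
    re <- max(r, rc)
    sr6 <- (sig / re)^6
    e_lj <- 4 * eps * (sr6^2 - sr6)
    if (r < rc) {
      slope <- 4 * eps * (-12 * sr6^2 + 6 * sr6) / re
      e_lj <- e_lj + slope * (r - rc)
    }
    E <- E + nb$ljscale[t] * e_lj
    qq <- lam * nb$qscale[t] * heme@charge[nb$i[t]] * heme@charge[nb$j[t]]
    if (qq != 0) E <- E + qq / r * exp(-kap * r)
  }
  E
}

o_qw <- function(pred, ref) {
  n <- length(pred@sequence)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j - i <= 2) next
    r <- o_dist(pred@ca[i, ], pred@ca[j, ])
    rn <- o_dist(ref@ca[i, ], ref@ca[j, ])
    sig <- 0.1 * (j - i)^0.15
    tot <- tot + exp(-(r - rn)^2 / (2 * sig^2))
  }
  2 / ((n - 2) * (n - 3)) * tot
}

## ---- fixture helpers ----------------------------------------------------

# randomly perturbed copy of a system (protein beads and heme atoms)
perturb_state <- function(state, sd = 0.03, seed = 1) {
  set.seed(seed)
  p <- state@protein
  n <- length(p@sequence)
  p@ca <- p@ca + matrix(rnorm(3 * n, sd = sd), n)
  gly <- p@sequence == "G"
  p@cb[!gly, ] <- p@cb[!gly, , drop = FALSE] +
    matrix(rnorm(3 * sum(!gly), sd = sd), sum(!gly))
  p@o <- p@o + matrix(rnorm(3 * n, sd = sd), n)
  out <- state
  out@protein <- p
  if (!is.null(state@heme)) {
    h <- state@heme
    h@xyz <- h@xyz + matrix(rnorm(length(h@xyz), sd = sd), nrow(h@xyz))
    methods::slot(out, "heme", check = FALSE) <- h
  }
  out
}

rigid_motion <- function(state, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(9), 3)
  R <- qr.Q(qr(A))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  tr <- rnorm(3, sd = 2)
  mv <- function(m) {
    out <- m
    ok <- stats::complete.cases(m)
    out[ok, ] <- sweep(m[ok, , drop = FALSE] %*% R, 2, tr, "+")
    out
  }
  p <- state@protein
  p@ca <- mv(p@ca); p@cb <- mv(p@cb); p@o <- mv(p@o)
  out <- state
  out@protein <- p
  if (!is.null(state@heme)) {
    h <- state@heme
    h@xyz <- mv(h@xyz)
    methods::slot(out, "heme", check = FALSE) <- h
  }
  out
}

# a protein of n residues along a line, far from the origin unless shifted
line_protein <- function(seqs, origin = c(0, 0, 0), dir = c(1, 0, 0),
                         spacing = 0.38) {
  n <- length(seqs)
  ca <- t(vapply(seq_len(n) - 1, function(k) origin + k * spacing * dir,
                 numeric(3)))
  perp <- if (abs(dir[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  cb <- ca + matrix(rep(0.153 * perp, n), n, byrow = TRUE)
  cb[seqs == "G", ] <- NA
  o <- ca + matrix(rep(c(0, 0.2, 0), n), n, byrow = TRUE)
  new("CoarseProtein", sequence = seqs, ca = ca, cb = cb, o = o,
      charge = ifelse(seqs %in% c("D", "E"), -1,
                      ifelse(seqs %in% c("K", "R"), 1, 0)))
}

mini_state <- function(protein, heme, cys = integer()) {
  st <- new("SystemState", protein = protein, heme = NULL,
            cysAttach = as.integer(cys), distalRestraint = NULL)
  methods::slot(st, "heme", check = FALSE) <- heme
  st
}
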