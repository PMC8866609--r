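# Closed-form single-pair checks of every coupling term, plus structural
# properties (term assembly, rigid-motion invariance, stand-in minimum).

# fake heme with role-complete naming but freely placed atoms; `charges`
# overrides the default table so pair charges are known exactly
fake_heme <- function(positions, params = defaultParameters(),
                      charges = NULL, type = "b") {
  names <- c("FE", "NA", "NB", "NC", "ND", "O1A", "O2A", "O1D", "O2D",
             "CAB", "CAC")
  far <- matrix(rep(c(30, 30, 30), length(names)), ncol = 3, byrow = TRUE) +
    outer(seq_along(names), c(1, 0, 0))
  xyz <- far
  for (nm in names(positions)) xyz[match(nm, names), ] <- positions[[nm]]
  if (!is.null(charges)) {
    full <- as.list(setNames(rep(0, length(names)), names))
    full[names(charges)] <- charges
    params <- setParam(params, "heme.charges", full)
    params <- setParam(params, "heme.formal_charge",
                       list(b = sum(unlist(full)), c = sum(unlist(full))))
  }
  list(heme = newHeme(names, xyz, type, params), params = params)
}

test_that("Fe coordination term hits the analytic gate value", {
  p <- defaultParameters()
  r0 <- hemefold:::pget(p, "fe_cc", "r0")
  th0 <- hemefold:::pget(p, "fe_cc", "theta0")
  # pyrrole N on a cone at angle th0 from the Cbeta direction (+z)
  npos <- lapply(c(0, 90, 180, 270) * pi / 180, function(ph)
    0.2 * c(sin(th0) * cos(ph), sin(th0) * sin(ph), cos(th0)))
  fh <- fake_heme(list(FE = c(0, 0, 0), "NA" = npos[[1]], NB = npos[[2]],
                       NC = npos[[3]], ND = npos[[4]]), p)
  prot <- line_protein(c("A", "H", "A"), origin = c(-0.38, 0.5, 0.5))
  prot@cb[2, ] <- c(0, 0, r0)
  lamH <- hemefold:::pget(p, "fe_cc", "lambda")$HIS
  expect_equal(vFeCC(prot, fh$heme, fh$params), lamH / 16, tolerance = 1e-12)
  # glycines and termini are excluded: an all-glycine/terminal chain gives 0
  protG <- line_protein(c("H", "G", "H"), origin = c(0, 0, 0.5))
  expect_identical(vFeCC(protG, fh$heme, fh$params), 0)
})

test_that("screened electrostatics matches the single-pair closed form", {
  p <- defaultParameters()
  lam <- hemefold:::pget(p, "elec", "lambda")
  ks <- hemefold:::pget(p, "elec", "k_screening")
  ls <- hemefold:::pget(p, "elec", "l_screening")
  fh <- fake_heme(list(FE = c(0, 0, 0)), p,
                  charges = list(FE = 0.8, "NA" = -0.7, NB = -0.7,
                                 NC = -0.7, ND = -0.7))
  prot <- line_protein(c("A", "K", "A"), origin = c(-0.38, 2, 0))
  r <- ls / ks
  prot@cb[2, ] <- c(r, 0, 0)
  expect_equal(vElec(prot, fh$heme, fh$params),
               lam * 0.8 * (ks / ls) * exp(-1), tolerance = 1e-9)
  # bilinear in the charges: negating every charge leaves the energy fixed
  e1 <- vElec(prot, fh$heme, fh$params)
  prot2 <- prot
  prot2@charge <- -prot@charge
  fh2 <- fake_heme(list(FE = c(0, 0, 0)), p,
                   charges = list(FE = -0.8, "NA" = 0.7, NB = 0.7,
                                  NC = 0.7, ND = 0.7))
  expect_equal(vElec(prot2, fh2$heme, fh2$params), e1, tolerance = 1e-12)
  # all residue charges zero -> 0
  prot3 <- line_protein(c("A", "S", "A"), origin = c(-0.38, 2, 0))
  expect_identical(vElec(prot3, fh$heme, fh$params), 0)
})

test_that("backbone hydrogen bond reproduces the half-gate closed form", {
  p <- defaultParameters()
  lam <- hemefold:::pget(p, "hb_backbone", "lambda")
  r0 <- hemefold:::pget(p, "hb_backbone", "r0")
  th0 <- hemefold:::pget(p, "hb_backbone", "theta0")
  prot <- line_protein(c("A", "A", "A"))
  vs <- reconstructBackbone(prot, p)
  H <- vs$h[2, ]; N <- vs$n[2, ]
  e1 <- hemefold:::.unit(N - H)
  e2 <- hemefold:::.unit(c(-e1[2], e1[1], 0) -
                           sum(c(-e1[2], e1[1], 0) * e1) * e1)
  tht <- th0 + 1.5
  O <- H + r0 * (cos(tht) * e1 + sin(tht) * e2)
  fh <- fake_heme(list(O1A = O), p, charges = list(FE = 0))
  expect_equal(vHBBackbone(prot, fh$heme, fh$params), lam / 2,
               tolerance = 1e-9)
  # Gaussian decay: a distant heme contributes nothing measurable
  fh_far <- fake_heme(list(), p, charges = list(FE = 0))
  expect_lt(abs(vHBBackbone(prot, fh_far$heme, fh_far$params)),
            abs(lam) * 1e-12)
})

test_that("sidechain hydrogen bond and burial single-pair values", {
  p <- defaultParameters()
  prot <- line_protein(c("A", "S", "A"), origin = c(5, 5, 5))
  lamS <- hemefold:::pget(p, "hb_sidechain", "lambda")$SER
  r0S <- hemefold:::pget(p, "hb_sidechain", "r0")$SER
  O <- prot@cb[2, ] + c(r0S, 0, 0)
  fh <- fake_heme(list(O1A = O), p, charges = list(FE = 0))
  expect_equal(vHBSidechain(prot, fh$heme, fh$params), lamS, tolerance = 1e-9)
  # a residue type with zero strength contributes exactly nothing
  protL <- line_protein(c("A", "L", "A"), origin = c(5, 5, 5))
  protL@cb[2, ] <- prot@cb[2, ]
  expect_identical(vHBSidechain(protL, fh$heme, fh$params), 0)

  lamB <- hemefold:::pget(p, "burial", "lambda")
  r0B <- hemefold:::pget(p, "burial", "r0")
  # residues far apart so only one Cbeta sits inside the soft burial switch
  protB <- line_protein(c("A", "A", "A"), origin = c(5, 5, 5), spacing = 3)
  OB <- protB@cb[2, ] + c(r0B, 0, 0)
  fhB <- fake_heme(list(O1A = OB), p, charges = list(FE = 0))
  expect_equal(vBurial(protB, fhB$heme, fhB$params), lamB / (4 * 3),
               tolerance = 1e-6)
})

test_that("excluded volume is a one-sided quadratic wall", {
  p <- defaultParameters()
  r0 <- hemefold:::pget(p, "excl", "r0")
  lam <- hemefold:::pget(p, "excl", "lambda")
  prot <- line_protein("A", origin = c(r0 - 0.05, 0, 0))
  prot@cb[1, ] <- prot@ca[1, ] + c(0, 0, 0.3)
  prot@o[1, ] <- prot@ca[1, ] + c(0, 0.3, 0)
  fh <- fake_heme(list(FE = c(0, 0, 0)), p, charges = list(FE = 0))
  expect_equal(vExcl(prot, fh$heme, fh$params), lam * 0.05^2,
               tolerance = 1e-9)
  # every pair beyond the cutoff -> exactly zero
  prot2 <- line_protein(c("A", "A"), origin = c(2, 0, 0))
  expect_identical(vExcl(prot2, fh$heme, fh$params), 0)
})

test_that("thioester bond value, decay, and heme b refusal", {
  p <- defaultParameters()
  lam <- hemefold:::pget(p, "thioester", "lambda_cs")
  r0 <- hemefold:::pget(p, "thioester", "r0")
  prot <- line_protein(c("A", "C", "A", "A", "C", "A"), origin = c(4, 4, 4))
  cab <- prot@cb[2, ] + c(r0, 0, 0)
  cac <- prot@cb[5, ] + c(2 + r0, 0, 0)      # second bond 2 nm out of range
  fh <- fake_heme(list(CAB = cab, CAC = cac), p, charges = list(FE = 0),
                  type = "c")
  expect_equal(vThioester(prot, fh$heme, c(2L, 5L), fh$params), lam,
               tolerance = abs(lam) * 1e-6)
  fhb <- fake_heme(list(CAB = cab, CAC = cac), p, charges = list(FE = 0),
                   type = "b")
  expect_error(vThioester(prot, fhb$heme, c(2L, 5L), fhb$params),
               "undefined for heme b")
})

test_that("heme internal bonded energy vanishes at the reference geometry", {
  p <- defaultParameters()
  h <- makeIdealHeme("b", p)
  expect_equal(o_heme_bonded(h), 0, tolerance = 1e-18)
  # the full internal energy then equals the nonbonded residual alone
  expect_equal(hemeInternalEnergy(h, p), o_heme_internal(h, p),
               tolerance = 1e-10)
})

test_that("breakdown assembles the applicable terms and sums exactly", {
  p <- defaultParameters()
  toyb <- makeMiniGlobin("b", seed = 1, params = p)
  bb <- totalEnergy(toyb$native, toyb$native, p)
  expect_identical(energyTerms(bb)[["thioester"]], 0)
  toyc <- makeMiniGlobin("c", seed = 1, params = p)
  bc <- totalEnergy(toyc$native, toyc$native, p)
  expect_lt(energyTerms(bc)[["thioester"]], -10)
  expect_equal(totalOf(bc), sum(energyTerms(bc)), tolerance = 1e-12)
  # per-term public functions agree with the breakdown components
  expect_equal(vFeCC(toyc$native@protein, toyc$native@heme, p),
               energyTerms(bc)[["fe_cc"]], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(vThioester(toyc$native@protein, toyc$native@heme, c(2L, 5L), p),
               energyTerms(bc)[["thioester"]], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("every term is invariant under rigid-body motion", {
  p <- defaultParameters()
  toy <- makeMiniGlobin("c", seed = 1, params = p)
  st <- perturb_state(toy$native, sd = 0.02, seed = 9)
  e0 <- energyTerms(totalEnergy(st, toy$native, p))
  for (s in 1:3) {
    moved_state <- rigid_motion(st, seed = s)
    moved_native <- rigid_motion(toy$native, seed = s)
    e1 <- energyTerms(totalEnergy(moved_state, moved_native, p))
    expect_equal(e1, e0, tolerance = 1e-8)
  }
})

test_that("the stand-in potential has its global minimum at the native fold", {
  p <- defaultParameters()
  toy <- makeMiniGlobin("b", seed = 1, params = p)
  native <- toy$native@protein
  e0 <- proteinStandinEnergy(native, native, p)
  set.seed(31)
  worse <- vapply(1:1000, function(k) {
    sd <- runif(1, 0.01, 0.3)
    st <- perturb_state(toy$native, sd = sd, seed = 1000 + k)
    proteinStandinEnergy(st@protein, native, p)
  }, numeric(1))
  expect_true(all(worse >= e0 - 1e-9))

  # far from the native, the memory wells contribute essentially nothing
  wells <- function(prot) {
    n <- length(prot@sequence)
    eps_ca <- hemefold:::pget(p, "standin", "epsilon_ca")
    eps_cb <- hemefold:::pget(p, "standin", "epsilon_cb")
    w <- hemefold:::pget(p, "standin", "width_scale")
    tot <- 0
    for (i in 1:(n - 3)) for (j in (i + 3):n) {
      sig <- w * (j - i)^0.15
      tot <- tot - eps_ca * exp(-(o_dist(prot@ca[i, ], prot@ca[j, ]) -
                                  o_dist(native@ca[i, ], native@ca[j, ]))^2 /
                                  (2 * sig^2))
      if (!any(is.na(prot@cb[i, ])) && !any(is.na(prot@cb[j, ])))
        tot <- tot - eps_cb * exp(-(o_dist(prot@cb[i, ], prot@cb[j, ]) -
                                    o_dist(native@cb[i, ], native@cb[j, ]))^2 /
                                    (2 * sig^2))
    }
    tot
  }
  expect_lt(abs(wells(toy$extended@protein)), 0.08 * abs(wells(native)))
})

test_that("a blocked distal face masks its residues out of the Fe term", {
  p <- defaultParameters()
  toy <- makeMiniGlobin("b", seed = 1, params = p)
  prot <- toy$native@protein
  heme <- toy$native@heme
  lamH <- hemefold:::pget(p, "fe_cc", "lambda")$HIS
  lamM <- hemefold:::pget(p, "fe_cc", "lambda")$MET
  th0 <- hemefold:::pget(p, "fe_cc", "theta0")
  gate <- ((1 + tanh(2 * (1 - sin(th0)))) / 2)^4
  # the axial His sits above the ring (+ face), the distal Met below
  e_up <- vFeCC(prot, heme, p, distal = list(face = +1))
  e_dn <- vFeCC(prot, heme, p, distal = list(face = -1))
  expect_equal(sort(c(e_up, e_dn)), sort(c(lamH, lamM)) * gate,
               tolerance = 1e-6)
  expect_equal(e_up + e_dn, vFeCC(prot, heme, p), tolerance = 1e-6)
})

test_that("forces balance: the net force on an isolated system is zero", {
  p <- defaultParameters()
  toy <- makeMiniGlobin("c", seed = 1, params = p)
  st <- perturb_state(toy$native, sd = 0.03, seed = 4)
  f <- systemForces(st, toy$native, p)
  gly <- proteinSequence(st) == "G"
  net <- colSums(f$ca) + colSums(f$cb[!gly, , drop = FALSE]) +
    colSums(f$o) + colSums(f$heme)
  expect_lt(max(abs(net)), 1e-7)
})
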