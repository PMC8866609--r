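test_that("Q_w identities and closed-form single-pair value", {
  toy <- makeMiniGlobin("c", seed = 1)
  expect_equal(qw(toy$native, toy$native), 1, tolerance = 1e-12)
  # symmetric in pred/ref
  expect_equal(qw(toy$extended, toy$native), qw(toy$native, toy$extended),
               tolerance = 1e-12)

  # N = 4: the only included pair is (1,4); displace it by exactly sigma_14
  ref <- line_protein(c("A", "A", "A", "A"))
  pred <- ref
  sig14 <- 0.1 * 3^0.15
  pred@ca[4, ] <- pred@ca[4, ] + c(sig14, 0, 0)
  expect_equal(qw(pred, ref), exp(-1 / 2), tolerance = 1e-12)

  # blowing the structure up by x100 destroys all native distances
  ref20 <- line_protein(rep("A", 20))
  set.seed(2)
  ref20@ca <- ref20@ca + matrix(rnorm(60, sd = 0.05), 20)
  big <- ref20
  big@ca <- big@ca * 100
  expect_lt(qw(big, ref20), 0.01)

  expect_error(qw(line_protein(c("A", "A", "A")), ref), "mismatch|4 residues")
})

test_that("Q_c counts reproduced native contacts at residue granularity", {
  toy <- makeMiniGlobin("c", seed = 1)
  expect_equal(qc(toy$native, toy$native), 1, tolerance = 1e-12)
  # heme displaced far from the pocket: no contact survives
  far <- toy$native
  h <- far@heme
  h@xyz <- sweep(h@xyz, 2, c(5, 0, 0), "+")
  methods::slot(far, "heme", check = FALSE) <- h
  expect_equal(qc(far, toy$native), 0)
  # reference without contacts is undefined
  expect_error(qc(toy$native, far), "no heme contacts")
  # not symmetric: normalization is by native contacts
  part <- toy$extended
  expect_false(isTRUE(all.equal(qc(part, toy$native),
                                tryCatch(qc(toy$native, part),
                                         error = function(e) NA_real_))))
})

test_that("constructed pocket with half its contacts scores one half", {
  p <- defaultParameters()
  h <- makeIdealHeme("b", p)
  # 8 residues; 6 Cbetas within the cutoff of heme atoms, 2 far away
  seqs <- rep("A", 8)
  ca <- matrix(0, 8, 3)
  cb <- matrix(0, 8, 3)
  ang <- seq(0, 2 * pi, length.out = 7)[1:6]
  for (i in 1:6) {
    cb[i, ] <- c(0.35 * cos(ang[i]), 0.35 * sin(ang[i]), 0.45)
    ca[i, ] <- cb[i, ] + c(0, 0, 0.153)
  }
  for (i in 7:8) {
    cb[i, ] <- c(3 + i, 0, 0)
    ca[i, ] <- cb[i, ] + c(0, 0, 0.153)
  }
  o <- ca + matrix(rep(c(0, 0.2, 0), 8), 8, byrow = TRUE)
  prot <- new("CoarseProtein", sequence = seqs, ca = ca, cb = cb, o = o,
              charge = rep(0, 8))
  ref <- mini_state(prot, h)
  pred <- prot
  pred@cb[4:6, ] <- pred@cb[4:6, ] + 5     # break 3 of the 6 contacts
  pred_state <- mini_state(pred, h)
  expect_equal(qc(pred_state, ref), 0.5)
  # atom-granularity mode also available and bounded
  expect_gte(qc(pred_state, ref, mode = "atom"), 0)
  expect_lte(qc(pred_state, ref, mode = "atom"), 1)
})

test_that("Q_c decays monotonically as the heme leaves the pocket", {
  toy <- makeMiniGlobin("b", seed = 1)
  vals <- vapply(seq(0, 2.5, by = 0.25), function(d) {
    st <- toy$native
    h <- st@heme
    h@xyz <- sweep(h@xyz, 2, c(0, 0, -d), "+")
    methods::slot(st, "heme", check = FALSE) <- h
    qc(st, toy$native)
  }, numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
  expect_equal(vals[1], 1)
  expect_equal(tail(vals, 1), 0)
})

test_that("Kabsch RMSD: identities, rigid invariance, optimality", {
  toy <- makeMiniGlobin("b", seed = 1)
  p <- toy$native@protein
  expect_equal(rmsdCA(p, p)$rmsd, 0, tolerance = 1e-12)

  moved <- rigid_motion(toy$native, seed = 5)@protein
  r <- rmsdCA(moved, p)
  expect_lt(r$rmsd, 1e-10)
  expect_equal(length(r$per_residue), nResidues(p))

  pert <- perturb_state(toy$native, sd = 0.1, seed = 6)@protein
  expect_lte(rmsdCA(pert, p)$rmsd, rmsdCA(pert, p, align = FALSE)$rmsd + 1e-12)

  # brute-force oracle on a 3-point toy: no sampled rotation beats Kabsch
  X <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1.2, 0.3), 3, byrow = TRUE)
  Y <- matrix(c(0.1, 0, 0, 0.9, 0.2, 0, -0.1, 1.1, 0.5), 3, byrow = TRUE)
  toP <- function(m) new("CoarseProtein", sequence = rep("A", 3), ca = m,
                         cb = m + 0.1, o = m + 0.2, charge = rep(0, 3))
  best <- rmsdCA(toP(X), toP(Y))$rmsd
  set.seed(8)
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  sampled <- vapply(1:20000, function(k) {
    A <- matrix(rnorm(9), 3)
    R <- qr.Q(qr(A)); if (det(R) < 0) R[, 1] <- -R[, 1]
    sqrt(mean(rowSums((Xc %*% R - Yc)^2)))
  }, numeric(1))
  expect_lte(best, min(sampled) + 1e-9)
  expect_lt(best, min(sampled) + 0.02)   # the oracle gets close to it
})
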