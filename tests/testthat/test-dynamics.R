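test_that("same seed gives bitwise-identical trajectories", {
  toy <- makeMiniGlobin("b", seed = 1)
  cfg <- simulationConfig(nSteps = 400, seed = 17, tStart = 500, tEnd = 300,
                          friction = 0.5, recordEvery = 100)
  t1 <- runAnnealing(toy$extended, toy$native, config = cfg)
  t2 <- runAnnealing(toy$extended, toy$native, config = cfg)
  expect_identical(t1@coords, t2@coords)
  expect_identical(observables(t1)$qw, observables(t2)$qw)
  t3 <- runAnnealing(toy$extended, toy$native,
                     config = simulationConfig(nSteps = 400, seed = 18,
                                               tStart = 500, tEnd = 300,
                                               friction = 0.5,
                                               recordEvery = 100))
  expect_false(identical(t1@coords[[length(t1@coords)]],
                         t3@coords[[length(t3@coords)]]))
})

test_that("a zero-length schedule returns the initial state unchanged", {
  toy <- makeMiniGlobin("b", seed = 1)
  cfg <- simulationConfig(nSteps = 0, seed = 1, tStart = 300)
  traj <- runAnnealing(toy$extended, toy$native, config = cfg)
  fin <- finalState(traj)
  expect_equal(caCoords(fin@protein), caCoords(toy$extended@protein),
               tolerance = 1e-15)
  expect_equal(hemeCoords(fin@heme), hemeCoords(toy$extended@heme),
               tolerance = 1e-15)
})

test_that("frictionless zero-temperature limit conserves energy", {
  # harmonic dimer, E = k (r - r0)^2
  k <- 200; r0 <- 0.5; m <- c(10, 10); dt <- 0.002
  x <- matrix(c(0, 0, 0, 0.6, 0, 0), 2, byrow = TRUE)
  v <- matrix(c(0.05, 0, 0, -0.05, 0, 0), 2, byrow = TRUE)
  forceFn <- function(x) {
    d <- x[1, ] - x[2, ]
    r <- sqrt(sum(d^2))
    f1 <- -2 * k * (r - r0) * d / r
    rbind(f1, -f1)
  }
  etot <- function(x, v) {
    r <- sqrt(sum((x[1, ] - x[2, ])^2))
    k * (r - r0)^2 + 0.5 * sum(m * rowSums(v^2))
  }
  e0 <- etot(x, v)
  f <- forceFn(x)
  for (i in 1:10000) {
    st <- langevinStep(x, v, f, forceFn, m, dt, friction = 0, temperature = 0)
    x <- st$x; v <- st$v; f <- st$f
  }
  expect_lt(abs(etot(x, v) - e0) / abs(e0), 1e-4)
})

test_that("free particle with friction decays at the exact Langevin rate", {
  m <- 5; dt <- 0.01; g <- 2
  x <- 0; v <- 1; f <- 0
  for (i in 1:500) {
    st <- langevinStep(x, v, f, function(x) 0, m, dt, friction = g,
                       temperature = 0)
    x <- st$x; v <- st$v; f <- st$f
  }
  expect_equal(v, exp(-g * dt * 500), tolerance = 1e-10)
})

test_that("a stiff umbrella pins Q_w at the window center", {
  toy <- makeMiniGlobin("b", seed = 1)
  p <- defaultParameters()
  ref <- relaxSystem(toy$native, toy$native, p, tStart = 50, tEnd = 5)
  cfg <- simulationConfig(nSteps = 6000, seed = 3, tStart = 300,
                          friction = 0.5, recordEvery = 10)
  q0 <- 0.7
  wins <- umbrellaRun(ref, ref, p, q0s = q0, kBias = 5000, config = cfg)
  qs <- wins[[1]]@samples$qw
  qs <- qs[seq_len(length(qs)) > length(qs) / 3]
  expect_lt(abs(mean(qs) - q0), 0.02)
})

test_that("zero bias reduces umbrella sampling to unbiased dynamics", {
  toy <- makeMiniGlobin("b", seed = 1)
  p <- defaultParameters()
  cfg <- simulationConfig(nSteps = 4000, seed = 5, tStart = 400,
                          friction = 0.5, recordEvery = 200)
  w0 <- umbrellaRun(toy$native, toy$native, p, q0s = 0.5, kBias = 0,
                    config = cfg)
  traj <- runAnnealing(toy$native, toy$native, p,
                       simulationConfig(nSteps = 4000, seed = 6, tStart = 400,
                                        tEnd = 400, friction = 0.5,
                                        recordEvery = 200), confine = NULL)
  ks <- suppressWarnings(stats::ks.test(w0[[1]]@samples$qw,
                                        observables(traj)$qw))
  expect_gt(ks$p.value, 0.001)
})

test_that("the Q_w bias gradient matches finite differences", {
  toy <- makeMiniGlobin("b", seed = 1)
  pp <- perturb_state(toy$native, sd = 0.05, seed = 2)@protein
  ref <- toy$native@protein
  b <- qwBias(pp, ref, q0 = 0.5, kBias = 500)
  h <- 1e-6
  set.seed(3)
  for (i in sample(nResidues(pp), 6)) for (d in 1:3) {
    pa <- pp; pa@ca[i, d] <- pa@ca[i, d] + h
    pm <- pp; pm@ca[i, d] <- pm@ca[i, d] - h
    fd <- (qwBias(pa, ref, 0.5, 500)$energy -
           qwBias(pm, ref, 0.5, 500)$energy) / (2 * h)
    expect_equal(b$grad[i, d], fd, tolerance = 1e-4)
  }
})

test_that("recorded observables are recomputable from the stored coordinates", {
  toy <- makeMiniGlobin("c", seed = 1)
  cfg <- simulationConfig(nSteps = 600, seed = 9, tStart = 400, tEnd = 300,
                          friction = 0.5, recordEvery = 200)
  traj <- runAnnealing(toy$extended, toy$native, config = cfg)
  lay <- traj@layout$layout
  for (k in seq_along(traj@coords)) {
    st <- hemefold:::unpackCoords(traj@coords[[k]], lay, toy$extended)
    expect_equal(qw(st, toy$native), observables(traj)$qw[k],
                 tolerance = 1e-10)
    expect_equal(qc(st, toy$native), observables(traj)$qc[k],
                 tolerance = 1e-10)
  }
})

test_that("non-overlapping umbrella windows trigger a diagnostic warning", {
  mk <- function(q0, center, spread) {
    new("UmbrellaWindow", q0 = q0, kBias = 500, temperature = 300,
        samples = data.frame(step = 1:200,
                             qw = rnorm(200, center, spread)))
  }
  set.seed(1)
  expect_warning(hemefold:::.checkWindowOverlap(list(mk(0.2, 0.2, 0.01),
                                                     mk(0.8, 0.8, 0.01))),
                 "overlap")
  expect_silent(hemefold:::.checkWindowOverlap(list(mk(0.45, 0.45, 0.05),
                                                    mk(0.55, 0.55, 0.05))))
})
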