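# Langevin (BAOAB) dynamics, simulated annealing and Q_w-biased umbrella
# sampling on the coupled protein-heme system.

#' Create a simulation configuration
#'
#' @param nSteps number of integration steps
#' @param seed RNG seed (same seed gives an identical trajectory)
#' @param timestep integration step in ps
#' @param friction Langevin collision rate in 1/ps
#' @param tStart,tEnd temperature schedule endpoints in K (equal for
#'   constant-temperature runs; tStart >= tEnd)
#' @param recordEvery frame recording stride in steps
#' @export
simulationConfig <- function(nSteps, seed = 1, timestep = 0.005, friction = 1,
                             tStart = 300, tEnd = tStart, recordEvery = 100) {
  cfg <- new("SimulationConfig", timestep = timestep, friction = friction,
             tStart = tStart, tEnd = tEnd, nSteps = nSteps, seed = seed,
             recordEvery = recordEvery)
  validObject(cfg)
  cfg
}

#' One BAOAB Langevin step
#'
#' Deterministic given the RNG state.  `x`, `v` and `f` are matrices (or
#' vectors) of positions (nm), velocities (nm/ps) and forces (kJ/mol/nm);
#' `mass` is per row (amu).  At temperature 0 with zero friction this
#' reduces to velocity Verlet.
#'
#' @param x,v,f current positions, velocities, forces
#' @param forceFn function(x) returning the force at x
#' @param mass per-particle masses
#' @param dt timestep (ps); friction in 1/ps; temperature in K
#' @param friction,temperature Langevin parameters
#' @return list(x, v, f) after the step
#' @export
langevinStep <- function(x, v, f, forceFn, mass, dt, friction, temperature) {
  hm <- 0.5 * dt / mass
  v <- v + hm * f
  x <- x + 0.5 * dt * v
  if (friction > 0) {
    c1 <- exp(-friction * dt)
    c2 <- sqrt((1 - c1^2) * KB * temperature / mass)
    noise <- if (is.matrix(x)) matrix(rnorm(length(x)), nrow(x)) else rnorm(length(x))
    v <- c1 * v + c2 * noise
  } else if (temperature > 0) {
    # frictionless limit still needs no thermal kicks; nothing to do
  }
  x <- x + 0.5 * dt * v
  f <- forceFn(x)
  v <- v + hm * f
  list(x = x, v = v, f = f)
}

# shared inner loop; biasFn(P) returns list(energy, grad) or NULL
.runLangevin <- function(P, ctx, config, template, qwTab, biasFn = NULL,
                         record = TRUE) {
  lay <- ctx$layout
  mass <- lay$masses
  n <- nrow(P)
  dt <- config@timestep
  gamma <- config@friction
  nSteps <- config@nSteps
  recEvery <- config@recordEvery
  temps <- if (nSteps > 1)
    config@tStart + (config@tEnd - config@tStart) * (seq_len(nSteps) - 1) / (nSteps - 1)
  else rep(config@tStart, max(nSteps, 1))

  forceFn <- function(P) {
    eg <- .energyGrad(P, ctx)
    g <- eg$grad
    q <- NA_real_
    if (!is.null(biasFn)) {
      b <- biasFn(P)
      g <- g + b$grad
      q <- b$q
    }
    list(f = -g, terms = eg$terms, q = q)
  }

  frames_step <- integer(); frames_T <- numeric()
  frames_coords <- list(); frames_obs <- list()
  qcRef <- attr(qwTab, "qcRef")

  recordFrame <- function(step, Tcur, P, terms) {
    if (any(!is.finite(P)))
      stop("numerical blow-up: non-finite coordinates at step ", step)
    qwv <- if (!is.null(qwTab))
      cpp_qw(P, qwTab$ia, qwTab$ib, qwTab$rn, qwTab$sigma, qwTab$pref)$q
    else NA_real_
    qcv <- NA_real_
    if (!is.null(qcRef) && ctx$hemePresent) {
      st <- unpackCoords(P, lay, template)
      qcv <- tryCatch(qc(st, qcRef), error = function(e) NA_real_)
    }
    frames_step[[length(frames_step) + 1]] <<- step
    frames_T[[length(frames_T) + 1]] <<- Tcur
    frames_coords[[length(frames_coords) + 1]] <<- P
    frames_obs[[length(frames_obs) + 1]] <<- c(qw = qwv, qc = qcv, terms)
  }

  set.seed(config@seed)
  # Maxwell-Boltzmann start at the initial temperature
  v <- matrix(rnorm(3 * n), n, 3) * sqrt(KB * temps[1] / mass)
  fr <- forceFn(P)
  if (record) recordFrame(0L, temps[1], P, fr$terms)

  hm <- 0.5 * dt / mass
  for (k in seq_len(nSteps)) {
    Tk <- temps[k]
    v <- v + hm * fr$f
    P <- P + 0.5 * dt * v
    if (gamma > 0) {
      c1 <- exp(-gamma * dt)
      c2 <- sqrt((1 - c1^2) * KB * Tk / mass)
      v <- c1 * v + c2 * matrix(rnorm(3 * n), n, 3)
    }
    P <- P + 0.5 * dt * v
    fr <- forceFn(P)
    v <- v + hm * fr$f
    if (record && (k %% recEvery == 0 || k == nSteps))
      recordFrame(k, Tk, P, fr$terms)
  }
  obs <- if (length(frames_obs))
    as.data.frame(do.call(rbind, frames_obs)) else data.frame()
  list(P = P, v = v,
       traj = new("Trajectory", step = as.numeric(frames_step),
                  temperature = frames_T, coords = frames_coords,
                  observables = obs,
                  layout = list(layout = lay, template = template)))
}

#' Simulated-annealing structure prediction run
#'
#' Langevin dynamics on the coupled system while the temperature is ramped
#' linearly from `tStart` down to `tEnd`, starting (per protocol) from an
#' extended/disordered protein with the heme placed away from it.  The
#' final frame is the prediction; the best-Q_w frame is also of interest
#' (see [bestFrame]).
#'
#' @param state starting [SystemState-class]
#' @param native reference [SystemState-class] (defines the stand-in
#'   potential, Q_w and Q_c)
#' @param params a [ParameterSet-class]
#' @param config a [SimulationConfig-class]
#' @param confine flat-bottom spherical container keeping the dilute system
#'   together at desk scale: list(radius, k) in nm and kJ/mol/nm^2, centered
#'   on the initial system centroid; NULL disables it
#' @return a [Trajectory-class]
#' @export
runAnnealing <- function(state, native, params = defaultParameters(), config,
                         confine = list(radius = 3.5, k = 50)) {
  ctx <- ffContext(state, native = native, params = params)
  P <- packCoords(state, ctx$layout)
  tab <- qwTables(native, ctx$layout)
  attr(tab, "qcRef") <- if (!is.null(native@heme)) native else NULL
  if (!is.null(confine))
    ctx$tab$confine <- list(center = colMeans(P), radius = confine$radius,
                            k = confine$k)
  .runLangevin(P, ctx, config, state, tab)$traj
}

#' Quench a system to a nearby energy minimum
#'
#' Short low-temperature annealing (150 K down to 10 K by default) that
#' relaxes a constructed pose onto the actual minimum of the loaded
#' forcefield.  Used to turn the idealized toy construction into the
#' reference ("crystal") structure against which Q_w and the single-memory
#' stand-in are defined, so the coupled system fluctuates around a
#' self-consistent reference.
#'
#' @param state a [SystemState-class] to relax
#' @param native reference for the stand-in term (defaults to `state`)
#' @param params a [ParameterSet-class]
#' @param nSteps,tStart,tEnd,seed quench schedule
#' @return the relaxed [SystemState-class]
#' @export
relaxSystem <- function(state, native = state, params = defaultParameters(),
                        nSteps = 10000, tStart = 150, tEnd = 10, seed = 1) {
  cfg <- simulationConfig(nSteps = nSteps, seed = seed, tStart = tStart,
                          tEnd = tEnd, friction = 1, recordEvery = nSteps)
  finalState(runAnnealing(state, native, params, cfg, confine = NULL))
}

#' Final state of a trajectory
#' @param traj a [Trajectory-class]
#' @export
finalState <- function(traj) {
  unpackCoords(traj@coords[[length(traj@coords)]],
               traj@layout$layout, traj@layout$template)
}

#' Index and state of the best-Q_w frame
#' @param traj a [Trajectory-class]
#' @export
bestFrame <- function(traj) {
  i <- which.max(traj@observables$qw)
  list(index = i, qw = traj@observables$qw[i],
       state = unpackCoords(traj@coords[[i]], traj@layout$layout,
                            traj@layout$template))
}

#' Q_w-biased umbrella sampling
#'
#' Runs one constant-temperature Langevin window per target `q0` with the
#' harmonic bias 0.5 k (Q_w - q0)^2 (bias forces chain-ruled through the
#' Q_w definition over all Calpha pairs).  Windows are laddered: each
#' window starts from the previous window's final coordinates.  Neighboring
#' windows whose Q_w histograms share < 10% mass trigger a warning.
#'
#' @param state starting [SystemState-class]
#' @param native reference [SystemState-class]
#' @param params a [ParameterSet-class]
#' @param q0s vector of window centers along Q_w
#' @param kBias bias spring constant (kJ/mol)
#' @param config a [SimulationConfig-class]; tStart is the window temperature
#' @return list of [UmbrellaWindow-class]
#' @export
umbrellaRun <- function(state, native, params = defaultParameters(),
                        q0s = seq(0.1, 0.9, by = 0.05), kBias = 500, config) {
  ctx <- ffContext(state, native = native, params = params)
  P <- packCoords(state, ctx$layout)
  tab <- qwTables(native, ctx$layout)
  temp <- config@tStart
  windows <- vector("list", length(q0s))
  for (w in seq_along(q0s)) {
    q0 <- q0s[w]
    biasFn <- function(P) {
      res <- cpp_qw(P, tab$ia, tab$ib, tab$rn, tab$sigma, tab$pref)
      list(q = res$q, grad = kBias * (res$q - q0) * res$grad,
           energy = 0.5 * kBias * (res$q - q0)^2)
    }
    cfg_w <- simulationConfig(nSteps = config@nSteps,
                              seed = config@seed + w,
                              timestep = config@timestep,
                              friction = config@friction,
                              tStart = temp, tEnd = temp,
                              recordEvery = config@recordEvery)
    out <- .runLangevin(P, ctx, cfg_w, state, tab, biasFn = biasFn)
    P <- out$P
    qs <- out$traj@observables$qw
    windows[[w]] <- new("UmbrellaWindow", q0 = q0, kBias = kBias,
                        temperature = temp,
                        samples = data.frame(step = out$traj@step, qw = qs))
  }
  .checkWindowOverlap(windows)
  windows
}

.checkWindowOverlap <- function(windows, min_share = 0.1) {
  if (length(windows) < 2) return(invisible(TRUE))
  edges <- seq(0, 1.2, by = 0.02)
  hists <- lapply(windows, function(w) {
    h <- hist(pmin(pmax(w@samples$qw, 0), 1.19), breaks = edges, plot = FALSE)
    h$counts / max(sum(h$counts), 1)
  })
  for (k in seq_len(length(windows) - 1)) {
    share <- sum(pmin(hists[[k]], hists[[k + 1]]))
    if (share < min_share)
      warning(sprintf("umbrella windows %d (q0=%.2f) and %d (q0=%.2f) overlap by only %.1f%% of histogram mass",
                      k, windows[[k]]@q0, k + 1, windows[[k + 1]]@q0,
                      100 * share))
  }
  invisible(TRUE)
}

#' Q_w bias energy and force tables (exposed for testing)
#'
#' Returns the bias energy 0.5 k (Q_w - q0)^2 and its gradient with respect
#' to all Calpha coordinates of `protein`.
#' @param protein current conformation
#' @param ref reference conformation
#' @param q0 window center; kBias spring constant (kJ/mol)
#' @param kBias spring constant
#' @export
qwBias <- function(protein, ref, q0, kBias) {
  pp <- if (is(protein, "SystemState")) protein@protein else protein
  tab <- qwTables(ref)
  res <- cpp_qw(pp@ca, tab$ia, tab$ib, tab$rn, tab$sigma, tab$pref)
  list(q = res$q, energy = 0.5 * kBias * (res$q - q0)^2,
       grad = kBias * (res$q - q0) * res$grad)
}
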