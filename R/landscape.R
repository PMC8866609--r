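# Free-energy surfaces: unbiased 2D histogram projections and WHAM
# recombination of umbrella windows.

#' 2D free-energy surface from a trajectory
#'
#' Histograms two recorded observables and reports F = -ln P in units of
#' k_B T, shifted so the minimum over populated bins is zero.  Empty bins
#' are NA, never a finite free energy.
#'
#' @param traj a [Trajectory-class]
#' @param x,y observable names: "qw", "qc" or any energy-breakdown component
#' @param bins number of bins per axis (edges padded 5% beyond the observed
#'   range)
#' @param discard fraction of initial frames dropped as equilibration
#' @param temperature temperature label for the surface (K)
#' @export
fes2D <- function(traj, x = "qw", y = "qc", bins = 40, discard = 0.2,
                  temperature = 300) {
  obs <- traj@observables
  for (nm in c(x, y))
    if (!nm %in% names(obs))
      stop("unknown observable '", nm, "'; valid names: ",
           paste(names(obs), collapse = ", "))
  keep <- seq_len(nrow(obs)) > floor(discard * nrow(obs))
  xs <- obs[[x]][keep]; ys <- obs[[y]][keep]
  ok <- is.finite(xs) & is.finite(ys)
  xs <- xs[ok]; ys <- ys[ok]
  if (!length(xs)) stop("no finite samples for ", x, "/", y)
  pad <- function(v) {
    r <- range(v)
    w <- max(diff(r), 1e-9)
    seq(r[1] - 0.05 * w, r[2] + 0.05 * w, length.out = bins + 1)
  }
  xe <- pad(xs); ye <- pad(ys)
  ix <- pmin(pmax(findInterval(xs, xe, rightmost.closed = TRUE), 1), bins)
  iy <- pmin(pmax(findInterval(ys, ye, rightmost.closed = TRUE), 1), bins)
  counts <- matrix(0, bins, bins)
  for (k in seq_along(ix)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1
  f <- -log(counts / sum(counts))
  f[!is.finite(f)] <- NA
  f <- f - min(f, na.rm = TRUE)
  new("FreeEnergySurface", xname = x, yname = y, xedges = xe, yedges = ye,
      f = f, counts = counts, temperature = temperature)
}

#' WHAM recombination of umbrella windows
#'
#' Standard self-consistent weighted-histogram analysis over the biased Q_w
#' histograms.  Iterates the window free-energy shifts until they change by
#' less than `tol` and returns the unbiased profile in k_B T, shifted to a
#' zero minimum (gauge fixed).
#'
#' @param windows list of [UmbrellaWindow-class]
#' @param bins number of bins across the sampled coordinate range
#' @param discard fraction of each window's initial samples dropped
#' @param tol convergence threshold on the shifts
#' @param maxit iteration cap (warns with diagnostics if not converged,
#'   e.g. for non-overlapping windows)
#' @return data.frame(q, f, counts) with attribute "converged"
#' @export
wham <- function(windows, bins = 60, discard = 0.2, tol = 1e-8,
                 maxit = 10000) {
  temp <- windows[[1]]@temperature
  beta <- 1 / (KB * temp)
  qs <- lapply(windows, function(w) {
    v <- w@samples$qw
    v[seq_len(length(v)) > floor(discard * length(v))]
  })
  allq <- unlist(qs)
  edges <- seq(min(allq), max(allq), length.out = bins + 1)
  centers <- (edges[-1] + edges[-(bins + 1)]) / 2
  H <- vapply(qs, function(v) {
    ix <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1), bins)
    tabulate(ix, bins)
  }, numeric(bins))                      # bins x K
  Nk <- colSums(H)
  # bias factors c_{bk} = exp(-beta * W_k(q_b))
  W <- vapply(windows, function(w) 0.5 * w@kBias * (centers - w@q0)^2,
              numeric(bins))
  C <- exp(-beta * W)
  f <- rep(0, length(windows))           # dimensionless shifts exp-form
  ntot <- rowSums(H)
  conv <- FALSE
  for (it in seq_len(maxit)) {
    denom <- C %*% (Nk * exp(f))         # bins x 1
    p <- ntot / pmax(as.numeric(denom), 1e-300)
    p[ntot == 0] <- 0
    fnew <- -log(pmax(as.numeric(t(C) %*% p), 1e-300))
    fnew <- fnew - fnew[1]
    if (max(abs(fnew - f)) < tol) { f <- fnew; conv <- TRUE; break }
    f <- fnew
  }
  if (!conv)
    warning("WHAM did not converge in ", maxit,
            " iterations (max shift change ", signif(max(abs(fnew - f)), 3),
            "); check window overlap")
  denom <- C %*% (Nk * exp(f))
  p <- ntot / pmax(as.numeric(denom), 1e-300)
  p[ntot == 0] <- NA
  fq <- -log(p)
  fq <- fq - min(fq, na.rm = TRUE)
  out <- data.frame(q = centers, f = fq, counts = ntot)
  attr(out, "converged") <- conv
  out
}

#' Locate basins and barriers on a 1D free-energy profile
#'
#' Identifies the local minima (basins) of the profile.  For each basin the
#' barrier is the height of the saddle (the highest point of the profile
#' between this basin and its nearest neighboring basin, taking the lower
#' of the two sides when both exist) and the depth is that saddle height
#' minus the basin free energy.  A single-well profile has one basin with
#' no barrier (NA).  Small-amplitude noise can be suppressed with
#' `min_prominence`.
#'
#' @param profile data.frame(q, f) as returned by [wham] (NA bins ignored)
#' @param min_prominence merge minima whose separating saddle rises less
#'   than this above the shallower minimum (k_B T units)
#' @return data.frame(location, f, depth, barrier), ordered by location
#' @export
basinReport <- function(profile, min_prominence = 0.5) {
  ok <- is.finite(profile$f)
  q <- profile$q[ok]; f <- profile$f[ok]
  n <- length(f)
  if (n < 3) return(data.frame(location = numeric(), f = numeric(),
                               depth = numeric(), barrier = numeric()))
  is_min <- c(f[1] < f[2],
              f[2:(n - 1)] <= f[1:(n - 2)] & f[2:(n - 1)] <= f[3:n] &
                (f[2:(n - 1)] < f[1:(n - 2)] | f[2:(n - 1)] < f[3:n]),
              f[n] < f[n - 1])
  mins <- which(is_min)
  if (length(mins) > 1) mins <- mins[c(TRUE, diff(mins) > 1)]
  # merge shallow (noise) basins into their deeper neighbor
  repeat {
    if (length(mins) < 2) break
    saddles <- vapply(seq_len(length(mins) - 1), function(k)
      max(f[mins[k]:mins[k + 1]]), numeric(1))
    prom <- vapply(seq_len(length(mins) - 1), function(k)
      saddles[k] - max(f[mins[k]], f[mins[k + 1]]), numeric(1))
    w <- which.min(prom)
    if (prom[w] >= min_prominence) break
    drop <- if (f[mins[w]] >= f[mins[w + 1]]) w else w + 1
    mins <- mins[-drop]
  }
  if (length(mins) == 1) {
    return(data.frame(location = q[mins], f = f[mins], depth = NA_real_,
                      barrier = NA_real_))
  }
  saddles <- vapply(seq_len(length(mins) - 1), function(k)
    max(f[mins[k]:mins[k + 1]]), numeric(1))
  res <- lapply(seq_along(mins), function(k) {
    s <- c(if (k > 1) saddles[k - 1], if (k < length(mins)) saddles[k])
    barrier <- min(s)
    data.frame(location = q[mins[k]], f = f[mins[k]],
               depth = barrier - f[mins[k]], barrier = barrier)
  })
  do.call(rbind, res)
}

#' Export a free-energy surface as a long-format grid
#'
#' @param surface a [FreeEnergySurface-class]
#' @return data.frame(x_center, y_center, F_kT, count)
#' @export
fesGrid <- function(surface) {
  xc <- (surface@xedges[-1] + head(surface@xedges, -1)) / 2
  yc <- (surface@yedges[-1] + head(surface@yedges, -1)) / 2
  data.frame(x_center = rep(xc, times = length(yc)),
             y_center = rep(yc, each = length(xc)),
             F_kT = as.numeric(surface@f),
             count = as.numeric(surface@counts))
}
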