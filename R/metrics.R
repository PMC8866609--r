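# Structural similarity metrics: Q_w, Q_c, Kabsch RMSD.

#' Q_w structural similarity
#'
#' Gaussian-weighted fraction of native Calpha-Calpha distances over residue
#' pairs with sequence separation > 2:
#' \deqn{Q_w = \frac{2}{(N-2)(N-3)} \sum_{j-i>2}
#'   \exp\left(-\frac{(r_{ij}-r_{ij}^N)^2}{2\sigma_{ij}^2}\right),\quad
#'   \sigma_{ij} = |j-i|^{0.15}}
#' Identical structures give exactly 1.
#'
#' @param pred,ref [CoarseProtein-class] or [SystemState-class] objects with
#'   identical residue numbering, N >= 4
#' @return value in (0, 1]
#' @export
qw <- function(pred, ref) {
  pp <- if (is(pred, "SystemState")) pred@protein else pred
  rp <- if (is(ref, "SystemState")) ref@protein else ref
  n <- nResidues(pp)
  if (n != nResidues(rp)) stop("pred/ref length mismatch")
  if (n < 4) stop("Q_w requires at least 4 residues")
  tab <- qwTables(rp)
  r <- sqrt(rowSums((pp@ca[tab$ia, , drop = FALSE] -
                     pp@ca[tab$ib, , drop = FALSE])^2))
  tab$pref * sum(exp(-(r - tab$rn)^2 / (2 * tab$sigma^2)))
}

# residue-level heme contacts: residues whose Cbeta is within `cutoff` of
# any heme atom (atom mode: individual (residue, heme-atom) pairs)
.contacts <- function(state, cutoff, mode) {
  p <- state@protein
  h <- state@heme
  if (is.null(h)) stop("state has no heme")
  nb <- which(p@sequence != "G")
  if (!length(nb)) return(character())
  d <- sqrt(outer(rowSums(p@cb[nb, , drop = FALSE]^2), rowSums(h@xyz^2), "+") -
            2 * p@cb[nb, , drop = FALSE] %*% t(h@xyz))
  hit <- which(d < cutoff, arr.ind = TRUE)
  if (mode == "residue") unique(as.character(nb[hit[, 1]]))
  else paste(nb[hit[, 1]], hit[, 2], sep = "-")
}

#' Q_c heme-pocket accuracy
#'
#' Fraction of native heme-protein contacts reproduced in a predicted
#' structure.  A native contact is a heme atom within `cutoff` of a residue
#' Cbeta in the reference; the predicted count includes only contacts that
#' also exist in the reference, so the value is normalized to [0, 1].
#' Contacts are counted at residue granularity by default ("residue" mode);
#' "atom" mode counts individual heme-atom/Cbeta pairs.
#'
#' @param pred,ref [SystemState-class] objects containing a heme
#' @param cutoff contact distance in nm
#' @param mode "residue" or "atom"
#' @export
qc <- function(pred, ref, cutoff = 0.65, mode = c("residue", "atom")) {
  mode <- match.arg(mode)
  native <- .contacts(ref, cutoff, mode)
  if (!length(native))
    stop("reference structure has no heme contacts under cutoff ", cutoff)
  found <- .contacts(pred, cutoff, mode)
  length(intersect(found, native)) / length(native)
}

# Kabsch optimal rotation R minimizing |X R - Y| (X, Y centered m x 3)
.kabsch <- function(X, Y) {
  s <- svd(t(X) %*% Y)
  d <- sign(det(s$u) * det(s$v))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Calpha RMSD with optional Kabsch superposition
#'
#' @param pred,ref [CoarseProtein-class] or [SystemState-class] objects
#' @param align superpose `pred` onto `ref` (optimal rigid-body fit) first
#' @return list with `rmsd` (nm) and `per_residue` deviations (nm) for
#'   structure coloring
#' @export
rmsdCA <- function(pred, ref, align = TRUE) {
  pp <- if (is(pred, "SystemState")) pred@protein else pred
  rp <- if (is(ref, "SystemState")) ref@protein else ref
  if (nResidues(pp) != nResidues(rp)) stop("pred/ref length mismatch")
  X <- pp@ca; Y <- rp@ca
  if (align) {
    xc <- colMeans(X); yc <- colMeans(Y)
    Xc <- sweep(X, 2, xc); Yc <- sweep(Y, 2, yc)
    R <- .kabsch(Xc, Yc)
    X <- Xc %*% R
    Y <- Yc
  }
  dev <- sqrt(rowSums((X - Y)^2))
  list(rmsd = sqrt(mean(dev^2)), per_residue = dev)
}
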