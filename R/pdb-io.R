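# PDB reading/writing and coarse-graining.  Internally everything is nm;
# PDB I/O converts Angstrom <-> nm.

#' Coarse-grain parsed residue atoms into a three-bead protein
#'
#' Takes one row per atom with columns `resno`, `resid` (three-letter code),
#' `elety` (atom name) and `x`, `y`, `z` in nm, and keeps the Calpha, Cbeta
#' and carbonyl O of every residue.  Glycine carries no Cbeta.  Unit residue
#' charges (ASP/GLU -1, LYS/ARG +1, all others 0) are placed on the Cbeta.
#'
#' @param atoms data.frame as described above
#' @return a [CoarseProtein-class]
#' @export
coarseGrain <- function(atoms) {
  resnos <- unique(atoms$resno)
  n <- length(resnos)
  if (n < 1) stop("no residues to coarse-grain")
  seq1 <- character(n)
  ca <- cb <- o <- matrix(NA_real_, n, 3)
  for (k in seq_len(n)) {
    rows <- atoms[atoms$resno == resnos[k], , drop = FALSE]
    res3 <- rows$resid[1]
    aa <- AA1[res3]
    if (is.na(aa)) stop("unknown residue type '", res3, "' at residue ", resnos[k])
    seq1[k] <- aa
    pick <- function(nm) {
      r <- rows[rows$elety == nm, , drop = FALSE]
      if (!nrow(r)) return(NULL)
      as.numeric(r[1, c("x", "y", "z")])
    }
    pca <- pick("CA"); po <- pick("O")
    if (is.null(pca)) stop("residue ", resnos[k], " (", res3, ") is missing CA")
    if (is.null(po)) stop("residue ", resnos[k], " (", res3, ") is missing O")
    ca[k, ] <- pca; o[k, ] <- po
    if (aa != "G") {
      pcb <- pick("CB")
      if (is.null(pcb)) stop("residue ", resnos[k], " (", res3, ") is missing CB")
      cb[k, ] <- pcb
    }
  }
  p <- new("CoarseProtein", sequence = seq1, ca = ca, cb = cb, o = o,
           charge = residueCharge(seq1))
  validObject(p)
  p
}

#' Reconstruct ideal-geometry backbone N, H and C' positions
#'
#' The coarse-grained model keeps only Calpha, Cbeta and O explicitly; the
#' remaining backbone sites are fixed affine combinations of neighboring
#' bead coordinates (coefficients sum to 1, so the sites are equivariant
#' under rigid-body motion).  N_i and H_i are built from
#' (Calpha_{i-1}, Calpha_i, O_{i-1}) for i = 2..N; C'_i from
#' (Calpha_i, Calpha_{i+1}, O_i) for i = 1..N-1.  Undefined rows are NA.
#'
#' @param protein a [CoarseProtein-class]
#' @param params a [ParameterSet-class] holding the coefficients
#' @return list with N x 3 matrices `n`, `h`, `c`
#' @export
reconstructBackbone <- function(protein, params = defaultParameters()) {
  n <- nResidues(protein)
  if (n < 2) stop("backbone reconstruction needs at least 2 residues")
  # normalized to an exactly affine combination so the sites are strictly
  # equivariant under rigid-body motion
  cn <- as.numeric(pget(params, "backbone_geometry", "n_coeff")); cn <- cn / sum(cn)
  ch <- as.numeric(pget(params, "backbone_geometry", "h_coeff")); ch <- ch / sum(ch)
  cc <- as.numeric(pget(params, "backbone_geometry", "c_coeff")); cc <- cc / sum(cc)
  ca <- protein@ca; o <- protein@o
  N <- H <- C <- matrix(NA_real_, n, 3)
  i <- 2:n
  N[i, ] <- cn[1] * ca[i - 1, , drop = FALSE] + cn[2] * ca[i, , drop = FALSE] +
            cn[3] * o[i - 1, , drop = FALSE]
  H[i, ] <- ch[1] * ca[i - 1, , drop = FALSE] + ch[2] * ca[i, , drop = FALSE] +
            ch[3] * o[i - 1, , drop = FALSE]
  j <- 1:(n - 1)
  C[j, ] <- cc[1] * ca[j, , drop = FALSE] + cc[2] * ca[j + 1, , drop = FALSE] +
            cc[3] * o[j, , drop = FALSE]
  list(n = N, h = H, c = C)
}

#' Read a heme-protein system from a PDB file
#'
#' Parses the file (via bio3d), coarse-grains the first protein chain and
#' builds the all-atom heme representation if a heme heterogroup is present.
#' Coordinates are converted to nm.  For heme c (residue name HEC) the two
#' attachment cysteines are auto-detected as the CXXC pair whose Cbetas are
#' nearest the vinyl carbons, unless given explicitly.
#'
#' @param path PDB file path
#' @param heme_resnames residue names treated as heme groups
#' @param params a [ParameterSet-class]
#' @param role_map optional heme atom-name role override
#' @param cys_attach optional explicit attachment cysteine indices (length 2)
#' @return a [SystemState-class] (heme absent if none found)
#' @export
readSystemPDB <- function(path, heme_resnames = c("HEM", "HEC"),
                          params = defaultParameters(), role_map = NULL,
                          cys_attach = NULL) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("PDB parse error in '", path, "': ",
                                           conditionMessage(e)))
  at <- pdb$atom
  # first alternate location only
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]

  prot <- at[at$type == "ATOM" & at$resid %in% names(AA1), , drop = FALSE]
  if (!nrow(prot)) stop("no protein chain found in ", path)
  prot <- prot[prot$chain == prot$chain[1], , drop = FALSE]
  atoms <- data.frame(resno = prot$resno, resid = prot$resid,
                      elety = prot$elety,
                      x = prot$x / 10, y = prot$y / 10, z = prot$z / 10)
  protein <- coarseGrain(atoms)

  hm <- at[at$resid %in% heme_resnames, , drop = FALSE]
  heme <- NULL
  cysAttach <- integer()
  if (nrow(hm)) {
    hm <- hm[hm$resno == hm$resno[1], , drop = FALSE]
    type <- if (hm$resid[1] == "HEC") "c" else "b"
    xyz <- cbind(hm$x, hm$y, hm$z) / 10
    heme <- newHeme(hm$elety, xyz, type, params, role_map)
    if (type == "c") {
      cysAttach <- if (is.null(cys_attach))
        detectAttachmentCys(protein, heme) else as.integer(cys_attach)
    }
  }
  st <- new("SystemState", protein = protein, heme = heme,
            cysAttach = cysAttach, distalRestraint = NULL)
  validObject(st)
  st
}

#' Auto-detect heme c attachment cysteines
#'
#' Finds the C-X-X-C pair whose Cbetas lie nearest the heme vinyl carbons.
#' @param protein a [CoarseProtein-class]
#' @param heme a [Heme-class] of type "c"
#' @export
detectAttachmentCys <- function(protein, heme) {
  s <- protein@sequence
  n <- length(s)
  starts <- which(s == "C")
  starts <- starts[starts + 3 <= n & s[starts + 3] == "C"]
  if (!length(starts)) stop("heme c system has no CXXC motif")
  vin <- heme@xyz[heme@role == "C_VINYL", , drop = FALSE]
  score <- vapply(starts, function(i) {
    cb1 <- protein@cb[i, ]; cb2 <- protein@cb[i + 3, ]
    if (any(is.na(cb1)) || any(is.na(cb2))) return(Inf)
    min(sqrt(colSums((t(vin) - cb1)^2))) + min(sqrt(colSums((t(vin) - cb2)^2)))
  }, numeric(1))
  i <- starts[which.min(score)]
  c(i, i + 3L)
}

#' Write a system to a PDB file
#'
#' Protein beads as ATOM records (CA, CB, O), heme atoms as HETATM, in
#' Angstrom (nm are converted).
#'
#' @param state a [SystemState-class]
#' @param path output file path
#' @export
writeSystemPDB <- function(state, path) {
  p <- state@protein
  n <- nResidues(p)
  if (n < 1) stop("refusing to write an empty protein")
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0
  fmtName <- function(nm) if (nchar(nm) >= 4) substr(nm, 1, 4) else sprintf(" %-3s", nm)
  emit <- function(type, nm, res3, chain, resno, xyz, elem) {
    serial <<- serial + 1
    writeLines(sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                       type, serial, fmtName(nm), res3, chain, resno,
                       xyz[1] * 10, xyz[2] * 10, xyz[3] * 10, 1, 0, elem), con)
  }
  for (i in seq_len(n)) {
    res3 <- AA3[p@sequence[i]]
    emit("ATOM", "CA", res3, "A", i, p@ca[i, ], "C")
    if (p@sequence[i] != "G") emit("ATOM", "CB", res3, "A", i, p@cb[i, ], "C")
    emit("ATOM", "O", res3, "A", i, p@o[i, ], "O")
  }
  if (!is.null(state@heme)) {
    h <- state@heme
    res3 <- if (h@type == "c") "HEC" else "HEM"
    for (k in seq_along(h@name))
      emit("HETATM", h@name[k], res3, "A", n + 1, h@xyz[k, ], h@element[k])
  }
  writeLines("END", con)
  invisible(path)
}
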