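test_that("PDB write/read round trip preserves structure and topology tags", {
  for (type in c("b", "c")) {
    toy <- makeMiniGlobin(type, seed = 1)
    path <- tempfile(fileext = ".pdb")
    writeSystemPDB(toy$native, path)
    back <- readSystemPDB(path)
    expect_equal(nResidues(back), nResidues(toy$native))
    expect_equal(proteinSequence(back), proteinSequence(toy$native))
    expect_lt(max(abs(caCoords(back@protein) - caCoords(toy$native@protein))),
              1e-4)
    gly <- proteinSequence(back) == "G"
    expect_lt(max(abs(cbCoords(back@protein)[!gly, ] -
                      cbCoords(toy$native@protein)[!gly, ])), 1e-4)
    h <- back@heme
    expect_equal(hemeType(h), type)
    expect_equal(sum(hemeRoles(h) == "FE"), 1)
    expect_equal(sum(hemeRoles(h) == "N_PYRROLE"), 4)
    expect_equal(sum(hemeRoles(h) == "O_CARBOXYL"), 4)
    expect_equal(sum(hemeRoles(h) == "C_VINYL"), 2)
    expect_lt(max(abs(hemeCoords(h) - hemeCoords(toy$native@heme))), 1e-4)
    if (type == "c") expect_equal(back@cysAttach, c(2L, 5L))
    # second round trip is idempotent to format precision
    path2 <- tempfile(fileext = ".pdb")
    writeSystemPDB(back, path2)
    again <- readSystemPDB(path2)
    expect_lt(max(abs(caCoords(again@protein) - caCoords(back@protein))), 1e-9)
  }
})

test_that("protein-only file gives a heme-free state; broken heme errors", {
  toy <- makeMiniGlobin("b", seed = 1)
  apo <- new("SystemState", protein = toy$native@protein, heme = NULL,
             cysAttach = integer(), distalRestraint = NULL)
  path <- tempfile(fileext = ".pdb")
  writeSystemPDB(apo, path)
  back <- readSystemPDB(path)
  expect_null(back@heme)

  # strip the FE record: must raise a topology error naming the problem
  writeSystemPDB(toy$native, path)
  lines <- readLines(path)
  writeLines(lines[!grepl("^HETATM.* FE ", lines)], path)
  expect_error(readSystemPDB(path), "FE")
})

test_that("coarse graining applies the charge rule and glycine handling", {
  atoms <- do.call(rbind, lapply(seq_along(c("ALA", "GLY", "ASP", "LYS")),
    function(i) {
      res <- c("ALA", "GLY", "ASP", "LYS")[i]
      base <- data.frame(resno = i, resid = res,
                         elety = c("CA", "O", "CB"),
                         x = i * 0.4 + c(0, 0.1, 0.05), y = c(0, 0.2, 0.15),
                         z = 0)
      if (res == "GLY") base[base$elety != "CB", ] else base
    }))
  p <- coarseGrain(atoms)
  expect_equal(p@charge, c(0, 0, -1, 1))
  expect_true(all(is.na(p@cb[2, ])))
  expect_false(any(is.na(p@cb[c(1, 3, 4), ])))
  # bead coordinates equal the corresponding atom records
  expect_equal(unname(p@ca[3, 1]), 3 * 0.4)

  bad <- atoms[atoms$elety != "CA" | atoms$resno != 3, ]
  expect_error(coarseGrain(bad), "residue 3")
})

test_that("reconstructed backbone sites are rigid-motion equivariant", {
  toy <- makeMiniGlobin("b", seed = 2)
  p <- toy$native@protein
  sites <- reconstructBackbone(p)
  for (s in 1:3) {
    set.seed(s)
    A <- matrix(rnorm(9), 3)
    R <- qr.Q(qr(A)); if (det(R) < 0) R[, 1] <- -R[, 1]
    tr <- rnorm(3, sd = 3)
    p2 <- p
    p2@ca <- sweep(p@ca %*% R, 2, tr, "+")
    gly <- p@sequence == "G"
    p2@cb[!gly, ] <- sweep(p@cb[!gly, , drop = FALSE] %*% R, 2, tr, "+")
    p2@o <- sweep(p@o %*% R, 2, tr, "+")
    s2 <- reconstructBackbone(p2)
    for (nm in c("n", "h", "c")) {
      ok <- stats::complete.cases(sites[[nm]])
      expect_lt(max(abs(s2[[nm]][ok, ] -
                        sweep(sites[[nm]][ok, , drop = FALSE] %*% R, 2, tr, "+"))),
                1e-10)
    }
  }
})

test_that("N-H bond length is constant along an ideal helix", {
  toy <- makeMiniGlobin("b", seed = 1)
  sites <- reconstructBackbone(toy$native@protein)
  # helix A interior: residues whose N/H derive from screw-symmetric beads
  idx <- 10:16
  nh <- sqrt(rowSums((sites$n[idx, ] - sites$h[idx, ])^2))
  expect_lt(diff(range(nh)), 1e-9)
})

test_that("degenerate proteins are rejected", {
  expect_error(new("CoarseProtein", sequence = character(0),
                   ca = matrix(0, 0, 3), cb = matrix(0, 0, 3),
                   o = matrix(0, 0, 3), charge = numeric(0)))
  toy <- makeMiniGlobin("b", seed = 1)
  one <- new("CoarseProtein", sequence = "A", ca = matrix(0, 1, 3),
             cb = matrix(c(0.15, 0, 0), 1), o = matrix(c(0, 0.2, 0), 1),
             charge = 0)
  expect_error(reconstructBackbone(one), "at least 2")
})
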