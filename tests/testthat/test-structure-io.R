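test_that("a single PDB ATOM record parses to its stated coordinates", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(paste0("ATOM      1  CA  ALA A   1       1.000   2.000",
                      "   3.000  1.00  0.00           C"),
               "END"), p)
  st <- readStructure(p)
  expect_equal(nAtoms(st$topology), 1L)
  expect_equal(as.numeric(st$coords), c(1, 2, 3))
  a <- atoms(st$topology)
  expect_equal(a$name, "CA")
  expect_equal(a$resno, 1L)
  expect_equal(a$chain, "A")
})

test_that("GRO coordinates in nm convert to Angstrom (exactly x10)", {
  p <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("one atom", "    1",
               "    1ALA     CA    1   0.100   0.200   0.300",
               "  10.00000  10.00000  10.00000"), p)
  st <- readStructure(p)
  expect_equal(as.numeric(st$coords), c(1, 2, 3))
})

test_that("malformed GRO atom lines are reported with their line number", {
  p <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("bad", "    1", "    1ALA     CA    1   xxx   0.2   0.3",
               "  10 10 10"), p)
  expect_error(readStructure(p), "line 3")
})

test_that("synthetic hexamer structure round-trips through PDB and GRO", {
  spec <- syntheticChannelSpec(nFrames = 1, noiseSigma = 0.3, seed = 11)
  tr <- generateTrajectory(spec)
  co <- frameCoords(tr, 1)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(topology(tr), co, pdb)
  back <- readStructure(pdb)
  expect_equal(nAtoms(back$topology), nAtoms(tr))
  expect_lt(max(abs(back$coords - co)), 1e-3)   # PDB: 3 decimals
  expect_identical(atoms(back$topology)$resno, atoms(tr)$resno)
  expect_identical(atoms(back$topology)$chain, atoms(tr)$chain)

  gro <- withr::local_tempfile(fileext = ".gro")
  writeStructure(topology(tr), co, gro)
  bg <- suppressMessages(readStructure(gro))
  expect_lt(max(abs(bg$coords - co)), 1e-2)     # GRO: 3 decimals in nm
})

test_that("multi-model PDB trajectories round-trip in file order", {
  spec <- syntheticChannelSpec(nFrames = 4, noiseSigma = 0.3, seed = 3)
  tr <- generateTrajectory(spec)
  p <- withr::local_tempfile(fileext = ".pdb")
  writeTrajectory(tr, p)
  back <- readTrajectory(p, topology(tr))
  expect_equal(nFrames(back), 4L)
  expect_lt(max(abs(back@xyz - tr@xyz)), 1e-3)
})

test_that("identical models give zero pairwise frame differences", {
  topo <- dummyTopology(2)
  co <- rbind(c(0, 0, 0), c(1, 1, 1))
  tr <- channelTrajectory(topo, array(rep(co, 3), dim = c(2, 3, 3)))
  p <- withr::local_tempfile(fileext = ".pdb")
  writeTrajectory(tr, p)
  back <- readTrajectory(p, topo)
  expect_equal(nFrames(back), 3L)
  expect_equal(max(abs(back@xyz[, , 1] - back@xyz[, , 3])), 0)
})

test_that("atom-count mismatches and unsupported formats raise errors", {
  topo5 <- dummyTopology(5)
  co <- matrix(rnorm(15), 5, 3)
  p <- withr::local_tempfile(fileext = ".pdb")
  writeTrajectory(channelTrajectory(topo5, co), p)
  expect_error(readTrajectory(p, dummyTopology(6)), "atom-count mismatch")
  expect_error(readTrajectory(p, topo5, format = "xtc"), "xtc")
  expect_error(readStructure(p, format = "mol2"), "unsupported")
})

test_that("selection resolution matches an exhaustive scan and is stable", {
  spec <- syntheticChannelSpec(nFrames = 1, seed = 5)
  topo <- syntheticTopology(spec)
  a <- atoms(topo)

  got <- resolveSelection(topo, "name CA and resid 210")
  expect_identical(got, which(a$name == "CA" & a$resno == 210L))
  expect_length(got, 6L)
  expect_identical(got, sort(got))

  expect_identical(resolveSelection(topo, "resid 1000"), integer(0))

  ox <- resolveSelection(topo, "element O and resname TIP3")
  expect_identical(ox, which(a$element == "O" & a$resname == "TIP3"))

  rng <- resolveSelection(topo, "name CA and resid 169:173 and chain B")
  expect_identical(rng, which(a$name == "CA" & a$resno >= 169 &
                                a$resno <= 173 & a$chain == "B"))
  expect_length(rng, 5L)

  cmb <- resolveSelection(topo, "(resid 163 or resid 178) and not name CB")
  expect_identical(cmb, which(a$resno %in% c(163L, 178L) & a$name != "CB"))

  # repeat resolution is identical
  expect_identical(resolveSelection(topo, "name CA and resid 210"), got)
})

test_that("invalid selection expressions raise parse errors", {
  topo <- dummyTopology(3)
  expect_error(resolveSelection(topo, "bogus CA"), "parse error")
  expect_error(resolveSelection(topo, "name"), "needs a value")
  expect_error(resolveSelection(topo, "(name C"), "missing ')'")
  expect_error(resolveSelection(topo, ""), "empty")
})

test_that("vdW assignment covers heavy atoms, flags hydrogens, and fails loudly", {
  topo <- channelTopology(name = c("CA", "HA", "OH2", "NZ"),
                          resname = c("ALA", "ALA", "TIP3", "LYS"),
                          resno = c(1, 1, 2, 3), chain = "A",
                          element = c("C", "H", "O", "N"))
  out <- assignVdwRadii(topo)
  a <- atoms(out)
  expect_equal(a$vdw[1], 1.70)           # Bondi carbon
  expect_true(a$hydrogen[2])             # excluded from profiling
  expect_true(is.na(a$vdw[2]))
  expect_equal(a$vdw[3], 1.52)
  expect_equal(a$vdw[4], 1.55)

  weird <- channelTopology(name = "XX", resname = "UNK", resno = 1,
                           chain = "A", element = "Xx")
  expect_error(assignVdwRadii(weird), "XX")
})
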