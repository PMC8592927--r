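test_that("a dense ring gives the analytic clearance R - r", {
  topo <- dummyTopology(36)
  co <- ringCoords(36, 5.0, 0)
  prof <- radiusProfile(co, topo, zAxis(), zRange = c(0, 0),
                        escapeLimit = 4)
  expect_equal(profileTable(prof)$radius, 3.30, tolerance = 0.01)
  expect_equal(profileTable(prof)$cx, 0, tolerance = 0.01)
})

test_that("stacked rings produce profile minima at their clearances", {
  co <- rbind(ringCoords(36, 1.5 + 1.7, 0), ringCoords(36, 2.5 + 1.7, 3))
  topo <- dummyTopology(72)
  prof <- radiusProfile(co, topo, zAxis(), zRange = c(-1, 4), zStep = 0.5,
                        escapeLimit = 4)
  p <- profileTable(prof)
  expect_equal(p$radius[p$z == 0], 1.5, tolerance = 0.02)
  expect_equal(p$radius[p$z == 3], 2.5, tolerance = 0.02)
  expect_true(all(p$radius >= 1.5 - 0.02))
})

test_that("profiler agrees with an exhaustive 0.02 A grid on random configs", {
  for (seed in 1:10) {
    cfg <- randomConfig(sample(10:50, 1), seed = seed)
    ax <- zAxis()
    zs <- c(-1, 0.5)
    prof <- radiusProfile(cfg$coords, cfg$topology, ax,
                          zRange = c(zs[1], zs[2]), zStep = diff(zs),
                          escapeLimit = 4)
    p <- profileTable(prof)
    for (k in seq_along(zs)) {
      oracle <- gridSliceRadius(cfg$coords, cfg$topology, ax, zs[k],
                                gridStep = 0.02, escapeLimit = 4)
      expect_lt(abs(max(p$radius[k], 0) - max(oracle, 0)), 0.05)
    }
  }
})

test_that("profile radius never increases when an atom's vdW radius grows", {
  cfg <- randomConfig(30, seed = 77)
  ax <- zAxis()
  base <- profileTable(radiusProfile(cfg$coords, cfg$topology, ax,
                                     zRange = c(-2, 2), zStep = 1,
                                     escapeLimit = 4))$radius
  topo2 <- cfg$topology
  a <- atoms(topo2)
  a$vdw[5] <- a$vdw[5] + 0.6
  topo2@atoms <- a
  grown <- profileTable(radiusProfile(cfg$coords, topo2, ax,
                                      zRange = c(-2, 2), zStep = 1,
                                      escapeLimit = 4))$radius
  expect_true(all(grown <= base + 1e-9))
})

test_that("fully blocked slices are flagged with radius zero", {
  topo <- dummyTopology(1, vdw = 2.0)
  co <- matrix(c(0, 0, 0), 1, 3)
  prof <- radiusProfile(co, topo, zAxis(), zRange = c(0, 0),
                        escapeLimit = 1)
  p <- profileTable(prof)
  expect_true(p$blocked)
  expect_equal(p$radius, 0)
})

test_that("pore axis equals the TM1 C-alpha centroid and is equivariant", {
  spec <- quietSpec(1, seed = 8)
  tr <- generateTrajectory(spec)
  co <- frameCoords(tr, 1)
  topo <- topology(tr)
  ann <- channelAnnotation()
  ax <- poreAxis(co, topo, ann)
  expect_lt(max(abs(ax@center[1:2])), 1e-9)   # C6 symmetry

  sel <- resolveSelection(topo, "name CA and resid 144:180")
  expect_equal(ax@center, unname(colMeans(co[sel, ])))  # brute force

  shifted <- sweep(co, 2, c(-10, 0, 0))
  ax2 <- poreAxis(shifted, topo, ann)
  expect_equal(ax2@center - ax@center, c(10, 0, 0))

  empty <- channelAnnotation(tm1Range = c(9000L, 9001L))
  expect_error(poreAxis(co, topo, empty), "no TM1")
})

test_that("gate radius is the windowed minimum around the gate ring", {
  co <- rbind(ringCoords(36, 1.5 + 1.7, 0), ringCoords(36, 3.0 + 1.7, 2))
  topo <- dummyTopology(72)
  prof <- radiusProfile(co, topo, zAxis(), zRange = c(-3, 5), zStep = 0.5,
                        escapeLimit = 4)
  expect_equal(gateRadius(prof, gateZ = 1, window = 3), 1.5,
               tolerance = 0.02)
  expect_error(gateRadius(prof, gateZ = 50), "outside profile range")
})

test_that("ring radius is the mean radial distance over chains", {
  topo <- channelTopology(name = rep("CA", 6), resname = rep("LYS", 6),
                          resno = rep(270L, 6), chain = LETTERS[1:6],
                          element = rep("C", 6))
  expect_equal(ringRadius(ringCoords(6, 12.30, 5), topo, zAxis(), 270),
               12.30)
  alt <- ringCoords(6, 1, 5)
  alt[, 1:2] <- alt[, 1:2] * rep(c(10, 14), 3)
  expect_equal(ringRadius(alt, topo, zAxis(), 270), 12.0)

  # brute force on a noisy ring
  set.seed(3)
  noisy <- ringCoords(6, 12.3, 5) + matrix(rnorm(18, sd = 0.3), 6, 3)
  expect_equal(ringRadius(noisy, topo, zAxis(), 270),
               mean(sqrt(noisy[, 1]^2 + noisy[, 2]^2)))

  five <- channelTopology(name = rep("CA", 5), resname = rep("LYS", 5),
                          resno = rep(270L, 5), chain = LETTERS[1:5],
                          element = rep("C", 5))
  six <- channelTopology(name = c(rep("CA", 5), "CB"),
                         resname = rep("LYS", 6), resno = rep(270L, 6),
                         chain = LETTERS[1:6], element = rep("C", 6))
  expect_error(ringRadius(ringCoords(6, 12, 0), six, zAxis(), 270), "F")
})

test_that("average structure is invariant to rigid motions of a constant frame", {
  spec <- quietSpec(1, seed = 14)
  tr <- generateTrajectory(spec)
  co <- frameCoords(tr, 1)
  xyz <- array(NA_real_, dim = c(nrow(co), 3, 4))
  xyz[, , 1] <- co
  for (f in 2:4) xyz[, , f] <- applyRigid(co, randomRigid(f))
  moved <- channelTrajectory(topology(tr), xyz)
  avg <- averageStructure(moved)
  expect_lt(max(abs(avg - co)), 1e-6)
})

test_that("average structure is the per-atom mean of pre-aligned frames", {
  topo <- channelTopology(name = c("CA", "CA", "CA", "O"),
                          resname = "ALA", resno = 1:4, chain = "A",
                          element = c("C", "C", "C", "O"))
  f1 <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(1, 1, 0))
  f2 <- f1
  f2[4, 3] <- 2                      # only the non-CA atom moves
  tr <- channelTrajectory(topo, array(c(f1, f2), dim = c(4, 3, 2)))
  avg <- averageStructure(tr)
  expect_equal(avg[4, 3], 1)
  expect_equal(avg[1:3, ], f1[1:3, ])
  expect_error(averageStructure(tr, window = 5:6), "window outside")
})

test_that("RMSD is zero for self and rigid copies, closed-form otherwise", {
  spec <- quietSpec(1, seed = 15)
  tr1 <- generateTrajectory(spec)
  co <- frameCoords(tr1, 1)
  xyz <- array(c(co, applyRigid(co, randomRigid(99))), dim = c(nrow(co), 3, 2))
  tr <- channelTrajectory(topology(tr1), xyz)
  r <- rmsdSeries(tr)
  expect_equal(r[1], 0)
  expect_lt(r[2], 1e-9)              # nm, Kabsch invariance

  # uniform +1 A displacement of the selected atoms, no superposition
  xyz2 <- array(c(co, co + rep(c(1, 0, 0), each = nrow(co))),
                dim = c(nrow(co), 3, 2))
  tr2 <- channelTrajectory(topology(tr1), xyz2)
  expect_equal(rmsdSeries(tr2, fit = FALSE)[2], 0.1)   # 1 A = 0.1 nm
  expect_lt(rmsdSeries(tr2, fit = TRUE)[2], 1e-9)      # pure translation
  expect_error(rmsdSeries(tr2, reference = co[1:5, ]), "size")
})

test_that("contact distance equals the exhaustive heavy-atom minimum", {
  topo <- channelTopology(name = c("CA", "CA"), resname = c("LEU", "ALA"),
                          resno = c(210L, 166L), chain = "A",
                          element = c("C", "C"))
  co <- rbind(c(0, 0, 0), c(4, 0, 0))
  expect_equal(unname(contactMinDistance(co, topo, 210, 166)["A"]), 4.0)

  spec <- quietSpec(1, seed = 16)
  tr <- generateTrajectory(spec)
  co2 <- frameCoords(tr, 1)
  a <- atoms(tr)
  d <- contactMinDistance(co2, topology(tr), 210, 166)
  ia <- which(a$resno == 210 & a$chain == "A")
  ib <- which(a$resno == 166 & a$chain == "A")
  brute <- min(as.matrix(dist(rbind(co2[ia, ], co2[ib, ])))[
    seq_along(ia), length(ia) + seq_along(ib)])
  expect_equal(unname(d["A"]), brute)

  expect_error(contactMinDistance(co2, topology(tr), 210, 163,
                                  chains = "W"), "chain W")
})
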