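test_that("cylinder counting matches an exhaustive scan, boundaries inclusive", {
  topo <- dummyTopology(200, chain = "W")
  set.seed(41)
  co <- cbind(runif(200, -8, 8), runif(200, -8, 8), runif(200, -10, 10))
  idx <- seq_len(200)
  ax <- zAxis()
  got <- countInCylinder(co, idx, ax, -5, 5, 4)
  brute <- sum(co[, 3] >= -5 & co[, 3] <= 5 &
                 sqrt(co[, 1]^2 + co[, 2]^2) <= 4)
  expect_identical(got, as.integer(brute))

  # boundary atoms count
  bco <- rbind(c(4, 0, 0), c(0, 0, 5), c(0, 0, -5), c(4.0001, 0, 0),
               c(0, 0, 5.0001))
  expect_equal(countInCylinder(bco, 1:5, ax, -5, 5, 4), 3)
  expect_equal(countInCylinder(bco, integer(0), ax, -5, 5, 4), 0L)
  expect_error(countInCylinder(bco, 1:5, ax, 5, -5, 4), "zLo")
})

test_that("counts are monotone in radius and z window", {
  set.seed(42)
  co <- cbind(rnorm(100, sd = 4), rnorm(100, sd = 4), rnorm(100, sd = 6))
  ax <- zAxis()
  c1 <- countInCylinder(co, 1:100, ax, -3, 3, 3)
  c2 <- countInCylinder(co, 1:100, ax, -3, 3, 5)
  c3 <- countInCylinder(co, 1:100, ax, -6, 6, 3)
  expect_gte(c2, c1)
  expect_gte(c3, c1)
})

test_that("counting is invariant under a joint rigid motion", {
  spec <- syntheticChannelSpec(nFrames = 2, noiseSigma = 0.2, seed = 43)
  tr <- generateTrajectory(spec)
  ann <- channelAnnotation()
  base <- occupancySeries(tr, ann, "water")$series$count
  xyz <- tr@xyz
  for (f in 1:2) xyz[, , f] <- rotateAboutZ(xyz[, , f], 123,
                                            shift = c(4, -6, 9))
  moved <- channelTrajectory(topology(tr), xyz)
  expect_identical(occupancySeries(moved, ann, "water")$series$count, base)
})

test_that("programmed occupancy distributions are recovered", {
  spec <- syntheticChannelSpec(nFrames = 1000, seed = 44,
                               waterModel = list(type = "poisson",
                                                 mean = 16))
  tr <- generateTrajectory(spec)
  ann <- channelAnnotation()
  occ <- occupancySeries(tr, ann, "water")
  expect_identical(occ$series$count,
                   as.integer(tr@metadata$groundTruth$waterCounts))
  se <- sqrt(16 / 1000)
  expect_lt(abs(mean(occ$series$count) - 16), 3 * se)

  ions <- occupancySeries(tr, ann, "na")
  expect_identical(ions$histogram$count, 7L)
  expect_identical(ions$histogram$prob, 1)
})

test_that("a bimodal hydration program yields a bimodal count histogram", {
  spec <- syntheticChannelSpec(nFrames = 1500, seed = 45,
                               waterModel = list(type = "mixture",
                                                 means = c(12, 21),
                                                 weights = c(0.5, 0.5)))
  tr <- generateTrajectory(spec)
  occ <- occupancySeries(tr, channelAnnotation(), "water")
  h <- occ$histogram
  p <- function(k) { i <- which(h$count == k); if (length(i)) h$prob[i] else 0 }
  peak1 <- max(vapply(10:14, p, numeric(1)))
  peak2 <- max(vapply(19:23, p, numeric(1)))
  valley <- min(vapply(15:18, p, numeric(1)))
  expect_gt(peak1, valley)
  expect_gt(peak2, valley)
})

test_that("ring z is the mean over chains and matches brute force", {
  topo <- channelTopology(name = rep("CA", 6), resname = "PHE",
                          resno = rep(171L, 6), chain = LETTERS[1:6],
                          element = "C")
  co <- ringCoords(6, 6, 10)
  expect_equal(ringZ(co, topo, 171), 10)
  co[, 3] <- c(9, 9, 10, 10, 11, 11)
  expect_equal(ringZ(co, topo, 171), 10)
  set.seed(46)
  co[, 3] <- rnorm(6, 10)
  expect_equal(ringZ(co, topo, 171), mean(co[, 3]))
  expect_error(ringZ(co, topo, 999), "not found")
})

test_that("density grids conserve mass and localise fixed particles", {
  topo <- channelTopology(name = "SOD", resname = "SOD", resno = 1L,
                          chain = "X", element = "Na")
  co <- matrix(c(2.2, 3.1, 4.7), 1, 3)
  xyz <- array(rep(co, 5), dim = c(1, 3, 5))
  tr <- channelTrajectory(topo, xyz)
  g <- densityGrid(tr, "resname SOD", origin = c(0, 0, 0),
                   lengths = c(10, 10, 10), spacing = 1)
  expect_equal(sum(g@values), 1)                    # conservation
  expect_equal(g@values[3, 4, 5], 1)                # voxel [2,3]x[3,4]x[4,5]
  expect_equal(sum(g@values > 0), 1L)

  # half the frames in voxel A, half in voxel B
  xyz2 <- xyz
  xyz2[, , 4:5] <- rep(c(8.5, 8.5, 8.5), 1)
  xyz2[, , 3] <- c(8.5, 8.5, 8.5)
  tr2 <- channelTrajectory(topo, xyz2)
  g2 <- densityGrid(tr2, "resname SOD", c(0, 0, 0), c(10, 10, 10), 1)
  expect_equal(g2@values[3, 4, 5], 0.4)
  expect_equal(g2@values[9, 9, 9], 0.6)
  expect_equal(sum(g2@values), 1, tolerance = 1e-12)
})

test_that("a random walk accumulates exactly its brute-force voxel histogram", {
  topo <- channelTopology(name = "SOD", resname = "SOD", resno = 1L,
                          chain = "X", element = "Na")
  set.seed(47)
  nf <- 200
  pos <- matrix(runif(3 * nf, 0, 10), ncol = 3)
  xyz <- array(t(pos)[rep(1:3, each = 1), ], dim = c(1, 3, nf))
  for (f in seq_len(nf)) xyz[1, , f] <- pos[f, ]
  tr <- channelTrajectory(topo, xyz)
  g <- densityGrid(tr, "resname SOD", c(0, 0, 0), c(10, 10, 10), 2)
  vi <- floor(pos / 2) + 1
  brute <- array(0, dim = c(5, 5, 5))
  for (f in seq_len(nf))
    brute[vi[f, 1], vi[f, 2], vi[f, 3]] <-
      brute[vi[f, 1], vi[f, 2], vi[f, 3]] + 1
  expect_equal(g@values, brute / nf)
  expect_equal(sum(g@values), mean(rep(1, nf)), tolerance = 1e-9)
})

test_that("OpenDX export writes a parseable grid with conserved values", {
  spec <- syntheticChannelSpec(nFrames = 3, seed = 48)
  tr <- generateTrajectory(spec)
  g <- densityGrid(tr, speciesSelection("na"), c(-12, -12, -12),
                   c(24, 24, 30), spacing = 2)
  p <- withr::local_tempfile(fileext = ".dx")
  writeOpenDX(g, p)
  lines <- readLines(p)
  expect_match(lines[2], "gridpositions counts 12 12 15")
  items <- as.numeric(unlist(strsplit(trimws(
    lines[(which(grepl("data follows", lines)) + 1):
            (grep("attribute", lines) - 1)]), "\\s+")))
  expect_equal(length(items), prod(dim(g@values)))
  expect_equal(sum(items), sum(g@values), tolerance = 1e-9)
})
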