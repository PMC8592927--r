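# minimal one-subunit fixture: CA of residue 210 on the x axis, CG placed
# explicitly; pore centre at the origin
rot210Fixture <- function(cg) {
  topo <- channelTopology(name = c("CA", "CG"), resname = "LEU",
                          resno = c(210L, 210L), chain = "A",
                          element = c("C", "C"))
  co <- rbind(c(5, 0, 0), cg)
  list(topology = topo, coords = co)
}

test_that("rotation angle is 0 when the side chain points at the pore", {
  f <- rot210Fixture(c(2.5, 0, 0.5))   # CG on the CA->centre direction
  expect_equal(f210RotationAngle(f$coords, f$topology, zAxis(), "A"), 0)
})

test_that("a perpendicular side chain on the clockwise side reads +90", {
  # viewed from +z, clockwise rotation of the inward vector (-1,0) by 90
  # degrees points along +y
  f <- rot210Fixture(c(5, 2.5, 0.5))
  expect_equal(f210RotationAngle(f$coords, f$topology, zAxis(), "A"), 90)
  g <- rot210Fixture(c(5, -2.5, 0.5))
  expect_equal(f210RotationAngle(g$coords, g$topology, zAxis(), "A"), -90)
})

test_that("degenerate projections are flagged undefined, not silently zero", {
  f <- rot210Fixture(c(5, 0, 2.5))     # CG straight above CA
  expect_true(is.na(f210RotationAngle(f$coords, f$topology, zAxis(), "A")))
})

test_that("orientation angle is 0 when the apex lies on the centre ray", {
  spec <- quietSpec(1, f171Schedule = 0, seed = 2)
  tr <- generateTrajectory(spec)
  co <- frameCoords(tr, 1)
  ax <- poreAxis(co, topology(tr), channelAnnotation())
  expect_equal(f171OrientationAngle(co, topology(tr), ax, "A"), 0,
               tolerance = 1e-9)
})

test_that("both statistics are invariant under rotation about the axis and translation", {
  spec <- syntheticChannelSpec(nFrames = 1, noiseSigma = 0.3, seed = 19)
  tr <- generateTrajectory(spec)
  co <- frameCoords(tr, 1)
  topo <- topology(tr)
  ann <- channelAnnotation()
  ax <- poreAxis(co, topo, ann)
  a210 <- f210RotationAngle(co, topo, ax, "C")
  a171 <- f171OrientationAngle(co, topo, ax, "C")
  for (seed in 1:5) {
    set.seed(seed)
    moved <- rotateAboutZ(co, runif(1, 0, 360), shift = rnorm(3, sd = 8))
    axm <- poreAxis(moved, topo, ann)
    expect_equal(f210RotationAngle(moved, topo, axm, "C"), a210,
                 tolerance = 1e-9)
    expect_equal(f171OrientationAngle(moved, topo, axm, "C"), a171,
                 tolerance = 1e-9)
  }
})

test_that("rotating the side chain about the CA vertical shifts the angle by delta", {
  base <- rot210Fixture(c(5 - 2.5 * cos(pi / 6), 2.5 * sin(pi / 6), 0.5))
  a0 <- f210RotationAngle(base$coords, base$topology, zAxis(), "A")
  for (delta in c(-40, 15, 60)) {
    cg_rel <- base$coords[2, 1:2] - c(5, 0)
    th <- -delta * pi / 180            # clockwise-positive convention
    rot <- c(cos(th) * cg_rel[1] - sin(th) * cg_rel[2],
             sin(th) * cg_rel[1] + cos(th) * cg_rel[2])
    f <- rot210Fixture(c(5 + rot[1], rot[2], 0.5))
    a1 <- f210RotationAngle(f$coords, f$topology, zAxis(), "A")
    expect_equal(a1 - a0, delta, tolerance = 1e-9)
  }
})

test_that("angle series recovers programmed values through the full stack", {
  spec <- quietSpec(3, f210Schedule = c(5, 50, -20),
                    f171Schedule = c(40, 55, 10), seed = 22)
  tr <- generateTrajectory(spec)
  ann <- channelAnnotation()
  s210 <- computeAngleSeries(tr, ann, "F210")
  s171 <- computeAngleSeries(tr, ann, "F171")
  expect_equal(nrow(s210), 18L)        # 3 frames x 6 subunits
  expect_equal(s210$angle[s210$frame == 2], rep(50, 6), tolerance = 1e-6)
  expect_equal(s210$angle[s210$frame == 3], rep(-20, 6), tolerance = 1e-6)
  expect_equal(s171$angle[s171$frame == 2], rep(55, 6), tolerance = 1e-6)
})

test_that("noisy frames recover programmed angles within 3 standard errors", {
  n <- 1000
  spec <- syntheticChannelSpec(n, noiseSigma = 0.2, f210Schedule = 50,
                               f171Schedule = 40, seed = 23)
  tr <- generateTrajectory(spec)
  ann <- channelAnnotation()
  for (m in c("F210", "F171")) {
    s <- computeAngleSeries(tr, ann, m)
    mu <- if (m == "F210") 50 else 40
    se <- sd(s$angle) / sqrt(nrow(s))
    expect_lt(abs(mean(s$angle) - mu), 3 * se)
  }
})

test_that("histogram probabilities are normalised and binned as documented", {
  h <- angleHistogram(rep(12, 40), binWidth = 5)
  expect_equal(sum(h$prob), 1, tolerance = 1e-12)
  expect_equal(h$prob[h$mids == 12.5], 1)   # [10, 15) bin

  set.seed(5)
  u <- runif(20000, 0, 50)
  hu <- angleHistogram(u, binWidth = 5, range = c(0, 50))
  expect_length(hu$prob, 10L)
  expect_true(all(abs(hu$prob - 0.1) < 0.02))

  withNA <- c(rep(12, 9), NA)
  hn <- angleHistogram(withNA)
  expect_equal(hn$nDropped, 1L)
  expect_error(angleHistogram(c(NA_real_, NA_real_)), "no defined angles")
})

test_that("Boltzmann inversion reproduces the two-state closed form", {
  kB <- 0.008314462618
  h <- list(mids = c(2.5, 7.5), prob = c(0.5, 0.5))
  f <- boltzmannFreeEnergy(h, 310)
  expect_equal(diff(f$deltaF_kJ_mol), 0)

  h2 <- list(mids = c(2.5, 7.5), prob = c(0.731, 0.269))
  f2 <- boltzmannFreeEnergy(h2, 310)
  expect_equal(f2$deltaF_kJ_mol[1], 0)
  expect_equal(f2$deltaF_kJ_mol[2], kB * 310 * log(0.731 / 0.269),
               tolerance = 1e-12)
  # population ratios are recovered exactly
  expect_equal(exp(-diff(f2$deltaF_kJ_mol) / (kB * 310)),
               0.269 / 0.731, tolerance = 1e-12)

  h3 <- list(mids = c(1, 2, 3), prob = c(0, 1, 0))
  f3 <- boltzmannFreeEnergy(h3)
  expect_equal(f3$deltaF_kJ_mol, c(NA, 0, NA))

  expect_error(boltzmannFreeEnergy(list(mids = 1, prob = 0)), "all-zero")
  expect_error(boltzmannFreeEnergy(h, temperature = -1), "temperature")
})
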