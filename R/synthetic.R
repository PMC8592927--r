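## Synthetic hexameric-channel trajectories with exact programmable ground
## truth. The generator places idealised C6-symmetric atom rings so that
## every downstream statistic of a noise-free frame equals its programmed
## value:
##   - the gate ring's C-alpha atoms sit at radius (clearance + vdW), so
##     the analytic pore radius at that z IS the scheduled clearance;
##   - C-gamma of residue 210 is placed 2.5 A from C-alpha in the XY plane
##     at the scheduled signed angle from the C-alpha -> pore-centre
##     direction (clockwise positive), with a small fixed +z offset;
##   - the C-alpha atoms of residues 169-173 form a helical arc whose XY
##     geometric centre b and the C-alpha of 171 (point c) realise the
##     orientation angle exactly: the four flanking atoms compensate the
##     displacement of c so that b stays on the symmetric ring whatever
##     the angle;
##   - water oxygens are placed uniformly inside the water cylinder (with
##     a 0.75 A safety margin so coordinate noise does not move them
##     across the counting boundary), ions in their binding regions, and
##     unused pool atoms are parked far outside every analysis region
##     (topologies must have a constant atom count across frames).
## Isotropic Gaussian coordinate noise is added last.

# fixed construction geometry (Angstrom)
.HELIX <- list(Rb = 6.5, z = 5, rc = 2.5, rise = 1.5)
.R210 <- list(R = 15, z = 0, cgDist = 2.5, cgZOff = 0.5)
.PARK <- c(45, 45, 60)          # parking corner for unused pool atoms
.MARGIN <- 0.75                 # placement margin inside counting regions
.VDW_C <- 1.70                  # Bondi carbon, gate clearance offset

#' Default ring layout of the synthetic channel
#'
#' One C-alpha ring per annotated residue: selectivity filter (178) above
#' the hydrophobic rings (174, 167), the gate (163) and basic rings
#' (159, 155) below, flanked by the cylinder-bounding rings (184/182 top,
#' 148 bottom), the contact residue 166, the TM2 mutation site 210 and
#' the TM3 ring 270 (default radius 12.30 A). Radii are C-alpha distances
#' from the axis; the pore clearance at a ring is radius - vdW(C). The
#' gate ring's radius column is a placeholder: its atoms follow the
#' per-frame gate schedule.
#'
#' @param ring270Radius radius of the residue-270 ring (default 12.30).
#' @return data.frame(resno, resname, z, radius).
#' @export
defaultRings <- function(ring270Radius = 12.30) {
  data.frame(
    resno   = c(148L, 155L, 159L, 163L, 166L, 167L, 174L, 178L, 182L,
                184L, 210L, 270L),
    resname = c("TRP", "ARG", "LYS", "LYS", "ALA", "LEU", "VAL", "GLU",
                "ASP", "ASP", "LEU", "LYS"),
    z       = c(-10, -7, -4, -1, 0, 2, 8, 12, 15, 18, .R210$z, 5),
    radius  = c(9.0, 6.0, 5.7, 3.2, 8.0, 5.2, 4.7, 4.7, 7.0, 8.0,
                .R210$R, ring270Radius),
    stringsAsFactors = FALSE)
}

.expand_schedule <- function(x, nFrames, nSubunits, what) {
  if (is.matrix(x)) {
    if (nrow(x) != nFrames || ncol(x) != nSubunits)
      stop(what, " schedule must be nFrames x nSubunits")
    return(x)
  }
  if (length(x) == 1L) x <- rep(x, nFrames)
  if (length(x) != nFrames)
    stop(what, " schedule length (", length(x),
         ") must equal nFrames (", nFrames, ")")
  matrix(rep(x, nSubunits), nrow = nFrames, ncol = nSubunits)
}

.water_pool_size <- function(waterModel) {
  if (!is.null(waterModel$maxCount)) return(as.integer(waterModel$maxCount))
  m <- switch(waterModel$type,
              poisson = waterModel$mean,
              mixture = max(waterModel$means),
              fixed   = max(waterModel$counts),
              stop("unknown water model type: ", waterModel$type))
  as.integer(ceiling(m + 6 * sqrt(max(m, 1)) + 10))
}

.ion_pool_size <- function(ion) {
  if (!is.null(ion$maxCount)) return(as.integer(ion$maxCount))
  m <- if (identical(ion$type, "poisson")) ion$mean else ion$count
  as.integer(ceiling(m + 6 * sqrt(max(m, 1)) + 5))
}

#' Construct a SyntheticChannelSpec
#'
#' Defaults describe a wild-type-like closed channel: gate clearance
#' 1.5 A, rotation angle 5 degrees, orientation angle 40 degrees, pore
#' water counts Poisson with mean 16, a constant 7 sodium and 16 chloride
#' ions in their binding regions, and 0.2 A coordinate noise.
#'
#' @param nFrames number of frames (schedule length).
#' @param nSubunits >= 3, default 6.
#' @param gateSchedule scalar or per-frame gate clearance, Angstrom.
#' @param f210Schedule scalar, per-frame vector, or nFrames x nSubunits
#'   matrix of target rotation angles (degrees, clockwise positive).
#' @param f171Schedule same shapes; target orientation angles (degrees,
#'   counter-clockwise positive).
#' @param waterModel list: \code{type = "poisson"} with \code{mean};
#'   \code{type = "mixture"} with \code{means}, \code{weights};
#'   \code{type = "fixed"} with \code{counts} (scalar or per frame).
#'   Optional \code{maxCount} fixes the water pool size.
#' @param ionModel list with \code{na} and \code{cl}, each
#'   \code{list(type = "fixed", count = )} or
#'   \code{list(type = "poisson", mean = )}.
#' @param noiseSigma isotropic Gaussian coordinate noise, Angstrom.
#' @param box box lengths, Angstrom.
#' @param seed integer RNG seed.
#' @param rings ring layout (default \code{\link{defaultRings}()}).
#' @param resname210 residue name at the mutation site ("LEU" wild-type,
#'   "PHE" mutant).
#' @return a \linkS4class{SyntheticChannelSpec}.
#' @export
syntheticChannelSpec <- function(nFrames, nSubunits = 6L,
                                 gateSchedule = 1.5,
                                 f210Schedule = 5,
                                 f171Schedule = 40,
                                 waterModel = list(type = "poisson",
                                                   mean = 16),
                                 ionModel = list(
                                   na = list(type = "fixed", count = 7),
                                   cl = list(type = "fixed", count = 16)),
                                 noiseSigma = 0.2,
                                 box = c(80, 80, 80),
                                 seed = 42L,
                                 rings = defaultRings(),
                                 resname210 = "LEU") {
  nFrames <- as.integer(nFrames)
  nSubunits <- as.integer(nSubunits)
  if (length(gateSchedule) == 1L) gateSchedule <- rep(gateSchedule, nFrames)
  if (length(gateSchedule) != nFrames)
    stop("gate schedule length (", length(gateSchedule),
         ") must equal nFrames (", nFrames, ")")
  if (identical(waterModel$type, "fixed") &&
      length(waterModel$counts) == 1L)
    waterModel$counts <- rep(waterModel$counts, nFrames)
  rings$resname[rings$resno == 210L] <- resname210
  spec <- new("SyntheticChannelSpec",
              nSubunits = nSubunits, nFrames = nFrames, rings = rings,
              gateSchedule = as.numeric(gateSchedule),
              f210Schedule = .expand_schedule(f210Schedule, nFrames,
                                              nSubunits, "f210"),
              f171Schedule = .expand_schedule(f171Schedule, nFrames,
                                              nSubunits, "f171"),
              waterModel = waterModel, ionModel = ionModel,
              noiseSigma = noiseSigma, box = as.numeric(box),
              seed = as.integer(seed))
  spec
}

# residue names of the orientation-window helix
.HELIX_RESNAMES <- c("ALA", "ALA", "PHE", "ALA", "ALA")

#' Topology of a synthetic channel (frame-independent)
#'
#' Protein atoms chain by chain (A, B, ...), then the water-oxygen pool
#' (chain W, TIP3/OH2), the sodium pool (chain X, SOD) and the chloride
#' pool (chain Y, CLA). vdW radii are pre-assigned from the Bondi set.
#'
#' @param spec a \linkS4class{SyntheticChannelSpec}.
#' @return a \linkS4class{ChannelTopology}.
#' @export
syntheticTopology <- function(spec) {
  rg <- spec@rings[order(spec@rings$z), ]
  name <- character(); resname <- character(); resno <- integer()
  chain <- character(); element <- character()
  add <- function(nm, rn, no, ch, el) {
    name <<- c(name, nm); resname <<- c(resname, rn)
    resno <<- c(resno, no); chain <<- c(chain, ch); element <<- c(element, el)
  }
  for (s in seq_len(spec@nSubunits)) {
    ch <- LETTERS[s]
    ord <- order(rg$resno)
    for (k in ord) {
      add("CA", rg$resname[k], rg$resno[k], ch, "C")
      if (rg$resno[k] == 166L) add("CB", rg$resname[k], 166L, ch, "C")
      if (rg$resno[k] == 210L) add("CG", rg$resname[k], 210L, ch, "C")
    }
    for (j in 1:5)
      add("CA", .HELIX_RESNAMES[j], 168L + j, ch, "C")
  }
  nW <- .water_pool_size(spec@waterModel)
  for (i in seq_len(nW)) add("OH2", "TIP3", i, "W", "O")
  nNa <- .ion_pool_size(spec@ionModel$na)
  for (i in seq_len(nNa)) add("SOD", "SOD", i, "X", "Na")
  nCl <- .ion_pool_size(spec@ionModel$cl)
  for (i in seq_len(nCl)) add("CLA", "CLA", i, "Y", "Cl")
  topo <- channelTopology(name = name, resname = resname, resno = resno,
                          chain = chain, element = element)
  assignVdwRadii(topo)
}

# 2D rotation, counter-clockwise by deg degrees
.rot2 <- function(v, deg) {
  th <- deg * pi / 180
  c(cos(th) * v[1] - sin(th) * v[2], sin(th) * v[1] + cos(th) * v[2])
}

.draw_count <- function(model, frameIndex) {
  switch(model$type,
         poisson = stats::rpois(1, model$mean),
         mixture = {
           comp <- sample.int(length(model$means), 1, prob = model$weights)
           stats::rpois(1, model$means[comp])
         },
         fixed = {
           k <- if (!is.null(model$counts)) model$counts[frameIndex]
                else model$count
           if (length(k) != 1L || is.na(k))
             stop("fixed count model: no count for frame ", frameIndex)
           as.integer(k)
         },
         stop("unknown count model type: ", model$type))
}

# uniform placement in an axial cylinder shell [zlo, zhi], r <= rmax
.place_in_cylinder <- function(n, zlo, zhi, rmax) {
  if (n == 0) return(matrix(numeric(0), ncol = 3))
  r <- rmax * sqrt(stats::runif(n))
  phi <- stats::runif(n, 0, 2 * pi)
  cbind(r * cos(phi), r * sin(phi), stats::runif(n, zlo, zhi))
}

#' Build one synthetic frame
#'
#' Deterministic given (spec, frameIndex): the frame RNG is seeded from
#' the spec seed and the frame index, so frames can be rebuilt in
#' isolation and a whole trajectory is reproducible.
#'
#' @param spec a \linkS4class{SyntheticChannelSpec}.
#' @param frameIndex 1-based frame number within the schedules.
#' @param topology the matching \code{\link{syntheticTopology}} (rebuilt
#'   if omitted; pass it when generating many frames).
#' @return list: \code{coords} (nAtoms x 3, Angstrom) and \code{truth}
#'   (list with the realised water/ion counts and programmed values).
#' @export
buildFrame <- function(spec, frameIndex, topology = NULL) {
  if (frameIndex < 1 || frameIndex > spec@nFrames)
    stop("frameIndex ", frameIndex, " outside schedule length ",
         spec@nFrames)
  if (is.null(topology)) topology <- syntheticTopology(spec)
  a <- topology@atoms
  co <- matrix(NA_real_, nrow = nrow(a), ncol = 3)
  n <- spec@nSubunits
  rg <- spec@rings
  gate <- spec@gateSchedule[frameIndex]
  for (s in seq_len(n)) {
    ch <- LETTERS[s]
    phi <- 2 * pi * (s - 1) / n
    uhat <- c(-cos(phi), -sin(phi))       # inward, toward the axis
    for (k in seq_len(nrow(rg))) {
      rn <- rg$resno[k]
      R <- if (rn == 163L) gate + .VDW_C else rg$radius[k]
      i <- which(a$chain == ch & a$resno == rn & a$name == "CA")
      co[i, ] <- c(R * cos(phi), R * sin(phi), rg$z[k])
      if (rn == 166L) {
        j <- which(a$chain == ch & a$resno == 166L & a$name == "CB")
        co[j, ] <- c((R + 1.5) * cos(phi), (R + 1.5) * sin(phi), rg$z[k])
      }
      if (rn == 210L) {
        j <- which(a$chain == ch & a$resno == 210L & a$name == "CG")
        ca <- co[i, 1:2]
        # clockwise-positive schedule: rotate u by -theta (CCW frame)
        v <- .rot2(uhat, -spec@f210Schedule[frameIndex, s]) * .R210$cgDist
        co[j, ] <- c(ca + v, rg$z[k] + .R210$cgZOff)
      }
    }
    # orientation-window helix: b = XY centre of the five C-alphas,
    # c (residue 171) at the scheduled CCW angle from the b->axis ray
    b <- .HELIX$Rb * c(cos(phi), sin(phi))
    cvec <- .rot2(uhat, spec@f171Schedule[frameIndex, s]) * .HELIX$rc
    cxy <- b + cvec
    that <- c(-sin(phi), cos(phi))        # tangential spread direction
    base <- -cvec / 4
    offs <- list(`169` = base + 1.2 * that, `170` = base + 0.6 * that,
                 `172` = base - 0.6 * that, `173` = base - 1.2 * that)
    zrel <- c(`169` = -2, `170` = -1, `171` = 0, `172` = 1, `173` = 2)
    for (rn in 169:173) {
      i <- which(a$chain == ch & a$resno == rn & a$name == "CA")
      xy <- if (rn == 171L) cxy else b + offs[[as.character(rn)]]
      co[i, ] <- c(xy, .HELIX$z + zrel[[as.character(rn)]] * .HELIX$rise)
    }
  }

  seed_f <- (spec@seed + 77003 * frameIndex) %% 2147483646L + 1L
  set.seed(seed_f)

  # water: uniform in the counting cylinder (residues 171 -> 178 rings,
  # radius from the annotation default 5 A) with a safety margin
  zW <- c(.HELIX$z, rg$z[rg$resno == 178L])
  iW <- which(a$chain == "W")
  kW <- min(.draw_count(spec@waterModel, frameIndex), length(iW))
  posW <- .place_in_cylinder(kW, zW[1] + .MARGIN, zW[2] - .MARGIN,
                             5 - .MARGIN)
  co[iW, ] <- matrix(rep(.PARK, each = length(iW)), ncol = 3) +
    cbind(seq_along(iW), 0, 0)
  if (kW > 0) co[iW[seq_len(kW)], ] <- posW

  iNa <- which(a$chain == "X")
  kNa <- min(.draw_count(spec@ionModel$na, frameIndex), length(iNa))
  posNa <- .place_in_cylinder(kNa, 10.5, 12.75, 2.5)   # near the SF rings
  co[iNa, ] <- matrix(rep(.PARK + c(0, 5, 0), each = length(iNa)),
                      ncol = 3) + cbind(seq_along(iNa), 0, 0)
  if (kNa > 0) co[iNa[seq_len(kNa)], ] <- posNa

  iCl <- which(a$chain == "Y")
  kCl <- min(.draw_count(spec@ionModel$cl, frameIndex), length(iCl))
  posCl <- .place_in_cylinder(kCl, -7.5, -2, 3.5)      # basic region
  co[iCl, ] <- matrix(rep(.PARK + c(0, 10, 0), each = length(iCl)),
                      ncol = 3) + cbind(seq_along(iCl), 0, 0)
  if (kCl > 0) co[iCl[seq_len(kCl)], ] <- posCl

  if (spec@noiseSigma > 0)
    co <- co + matrix(stats::rnorm(length(co), sd = spec@noiseSigma),
                      ncol = 3)

  list(coords = co,
       truth = list(gate = gate,
                    f210 = spec@f210Schedule[frameIndex, ],
                    f171 = spec@f171Schedule[frameIndex, ],
                    nWater = kW, nNa = kNa, nCl = kCl))
}

#' Generate a synthetic channel trajectory
#'
#' Builds all frames of the spec. Identical (spec, seed) yield identical
#' coordinates. When \code{outDir} is given, writes the topology as PDB,
#' the trajectory as a multi-model PDB and a JSON ground-truth sidecar
#' (schedules, seed, realised per-frame counts).
#'
#' @param spec a \linkS4class{SyntheticChannelSpec}.
#' @param nFrames optional; must equal the spec's schedule length if
#'   given (guards against mismatched specs).
#' @param outDir optional output directory.
#' @param prefix file name prefix (default "synthetic").
#' @return a \linkS4class{ChannelTrajectory}; the ground truth is in
#'   \code{metadata(trajectory)$groundTruth} and, when written, in
#'   \code{<prefix>_truth.json}.
#' @export
generateTrajectory <- function(spec, nFrames = NULL, outDir = NULL,
                               prefix = "synthetic") {
  if (!is.null(nFrames) && nFrames != spec@nFrames)
    stop("nFrames (", nFrames, ") differs from the spec schedule length (",
         spec@nFrames, ")")
  topo <- syntheticTopology(spec)
  nf <- spec@nFrames
  xyz <- array(NA_real_, dim = c(nAtoms(topo), 3, nf))
  truths <- vector("list", nf)
  for (f in seq_len(nf)) {
    b <- buildFrame(spec, f, topology = topo)
    xyz[, , f] <- b$coords
    truths[[f]] <- b$truth
  }
  gt <- list(seed = spec@seed,
             gateSchedule = spec@gateSchedule,
             f210Schedule = spec@f210Schedule,
             f171Schedule = spec@f171Schedule,
             waterCounts = vapply(truths, `[[`, numeric(1), "nWater"),
             naCounts = vapply(truths, `[[`, numeric(1), "nNa"),
             clCounts = vapply(truths, `[[`, numeric(1), "nCl"))
  traj <- channelTrajectory(topo, xyz, box = spec@box,
                            metadata = list(groundTruth = gt))
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    writeStructure(topo, xyz[, , 1], file.path(outDir,
                                               paste0(prefix, "_top.pdb")),
                   box = spec@box)
    writeTrajectory(traj, file.path(outDir, paste0(prefix, "_traj.pdb")))
    jsonlite::write_json(
      gt, file.path(outDir, paste0(prefix, "_truth.json")),
      auto_unbox = TRUE, digits = NA)
  }
  traj
}

#' Sample angles from a two-state wrapped-Gaussian mixture
#'
#' Emulates a bimodal side-chain rotation-angle distribution: with
#' probability \code{1 - pState2} the angle is drawn around \code{mu1},
#' otherwise around \code{mu2}; samples are wrapped to (-180, 180].
#'
#' @param pState2 probability of the second state, in [0, 1].
#' @param mu1,mu2 state means, degrees.
#' @param sigma common standard deviation, degrees (> 0).
#' @param n sample size.
#' @param seed RNG seed.
#' @return numeric vector of n angles in (-180, 180].
#' @export
twoStateAngleSampler <- function(pState2, mu1, mu2, sigma, n, seed) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (pState2 < 0 || pState2 > 1) stop("pState2 must be in [0, 1]")
  set.seed(as.integer(seed))
  comp <- stats::runif(n) < pState2
  x <- ifelse(comp, stats::rnorm(n, mu2, sigma), stats::rnorm(n, mu1, sigma))
  ((x + 180) %% 360) - 180 + ifelse(((x + 180) %% 360) == 0, 360, 0)
}

#' Paired wild-type-like and mutant-like synthetic specs
#'
#' Encodes the qualitative contrasts of the study as generator programs:
#' the wild-type-like channel has a bimodal rotation angle (peaks near 5
#' and 50 degrees, equal weights), a mostly closed gate (closed fraction
#' 10123/15000), unimodal orientation angles near 40 degrees, Poisson(16)
#' pore waters and 7 Na+/16 Cl-; the mutant-like channel is unimodal near
#' 50 degrees, mostly dilated (closed fraction 5175/15000), carries
#' orientation angles shifted +20 degrees in dilated frames, bimodal
#' hydration (Poisson mixture, means 12 and 21, mean about 18),
#' 9 Na+/15 Cl- and a dilated TM3 ring (13.33 A vs 12.30 A). Closed
#' frames come first; state schedules are deterministic so
#' classification counts are exact.
#'
#' @param nFrames frames per variant (default 200).
#' @param seed base RNG seed.
#' @param noiseSigma coordinate noise, Angstrom (default 0.2).
#' @return list with elements \code{wild} and \code{mutant}
#'   (\linkS4class{SyntheticChannelSpec}) plus \code{closedFrames} counts.
#' @export
exampleVariantSpecs <- function(nFrames = 200, seed = 1L,
                                noiseSigma = 0.2) {
  nFrames <- as.integer(nFrames)
  nClosedW <- as.integer(round(nFrames * 10123 / 15000))
  nClosedM <- as.integer(round(nFrames * 5175 / 15000))
  gateW <- c(rep(1.5, nClosedW), rep(2.5, nFrames - nClosedW))
  gateM <- c(rep(1.5, nClosedM), rep(2.5, nFrames - nClosedM))
  set.seed(as.integer(seed))
  f210W <- matrix(twoStateAngleSampler(0.5, 5, 50, 5, nFrames * 6,
                                       seed = seed + 101L),
                  nrow = nFrames)
  f210M <- matrix(stats::rnorm(nFrames * 6, 50, 5), nrow = nFrames)
  f171W <- matrix(stats::rnorm(nFrames * 6, 40, 3), nrow = nFrames)
  f171M <- matrix(stats::rnorm(nFrames * 6, 40, 3), nrow = nFrames)
  f171M[seq_len(nFrames) > nClosedM, ] <-
    f171M[seq_len(nFrames) > nClosedM, ] + 20   # dilated frames shifted
  wild <- syntheticChannelSpec(
    nFrames, gateSchedule = gateW, f210Schedule = f210W,
    f171Schedule = f171W,
    waterModel = list(type = "poisson", mean = 16),
    ionModel = list(na = list(type = "fixed", count = 7),
                    cl = list(type = "fixed", count = 16)),
    noiseSigma = noiseSigma, seed = seed + 1L, resname210 = "LEU")
  mutant <- syntheticChannelSpec(
    nFrames, gateSchedule = gateM, f210Schedule = f210M,
    f171Schedule = f171M,
    waterModel = list(type = "mixture", means = c(12, 21),
                      weights = c(1 / 3, 2 / 3)),
    ionModel = list(na = list(type = "fixed", count = 9),
                    cl = list(type = "fixed", count = 15)),
    noiseSigma = noiseSigma, seed = seed + 2L,
    rings = defaultRings(ring270Radius = 13.33), resname210 = "PHE")
  list(wild = wild, mutant = mutant,
       closedFrames = c(wild = nClosedW, mutant = nClosedM))
}
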