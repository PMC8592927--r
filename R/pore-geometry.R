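## Pore geometry: axis, HOLE-style radius profiles, gate and ring radii,
## average structures, RMSD series and contact distances.
##
## The radius at height z is the largest probe-sphere radius whose surface
## clears every heavy-atom vdW sphere:
##   radius(z) = max_{p in disk} min_i ( ||p - x_i|| - vdw_i )
## with p constrained to an in-plane disk of radius escapeLimit around the
## axis so the probe cannot leak out of lateral gaps. The maximiser is
## found by deterministic multi-start Nelder-Mead refinement (previous
## slice centre + axis + 8 perimeter starts), not by simulated annealing.

#' Pore axis of a frame
#'
#' The centre is the unweighted mean of the C-alpha positions of the TM1
#' residue range over all subunits; the direction is +z by convention
#' (frames are assumed pre-aligned with the channel axis along z). An
#' optional principal-axis mode estimates the direction as the dominant
#' eigenvector of the selected C-alpha covariance and emits a message.
#'
#' @param coords nAtoms x 3 matrix (one frame), Angstrom.
#' @param topology a \linkS4class{ChannelTopology}.
#' @param annotation a \linkS4class{ChannelAnnotation}.
#' @param mode "z" (default) or "principal".
#' @return a \linkS4class{PoreAxis}.
#' @export
poreAxis <- function(coords, topology, annotation, mode = c("z", "principal")) {
  mode <- match.arg(mode)
  sel <- resolveSelection(topology, sprintf("name CA and resid %d:%d",
                                            annotation@tm1Range[1],
                                            annotation@tm1Range[2]))
  if (!length(sel)) stop("pore axis: no TM1 C-alpha atoms in range ",
                         annotation@tm1Range[1], "-", annotation@tm1Range[2])
  ctr <- colMeans(coords[sel, , drop = FALSE])
  dir <- c(0, 0, 1)
  if (mode == "principal") {
    x <- sweep(coords[sel, , drop = FALSE], 2, ctr)
    ev <- eigen(crossprod(x), symmetric = TRUE)$vectors[, 1]
    if (ev[3] < 0) ev <- -ev
    dir <- ev / sqrt(sum(ev^2))
    message("pore axis: principal-axis mode, direction (",
            paste(signif(dir, 4), collapse = ", "), ")")
  }
  new("PoreAxis", center = unname(ctr), direction = dir)
}

# heavy-atom coordinate/vdw matrix for profiling
.heavy_atoms <- function(coords, topology) {
  a <- topology@atoms
  keep <- !a$hydrogen
  if (any(is.na(a$vdw[keep])))
    stop("vdW radii not assigned; call assignVdwRadii() first")
  list(xyz = coords[keep, , drop = FALSE], vdw = a$vdw[keep])
}

# clearance of a probe at (px, py, z): min over atoms of dist - vdw
.clearance <- function(px, py, z, xyz, vdw) {
  min(sqrt((xyz[, 1] - px)^2 + (xyz[, 2] - py)^2 + (xyz[, 3] - z)^2) - vdw)
}

# maximise clearance in the slice at z; returns list(radius, cx, cy)
.max_clearance_slice <- function(z, axis_xy, xyz, vdw, escapeLimit,
                                 prev_center = NULL) {
  # safe pruning: radius <= clearance(axis) + escapeLimit, so atoms whose
  # minimal possible clearance over the disk exceeds that bound can never
  # be the binding constraint
  cl_axis <- .clearance(axis_xy[1], axis_xy[2], z, xyz, vdw)
  bound <- cl_axis + escapeLimit
  dxy <- sqrt((xyz[, 1] - axis_xy[1])^2 + (xyz[, 2] - axis_xy[2])^2)
  lo <- sqrt(pmax(0, dxy - escapeLimit)^2 + (xyz[, 3] - z)^2) - vdw
  keep <- lo <= bound + 1e-9
  x <- xyz[keep, , drop = FALSE]
  v <- vdw[keep]

  # probe positions outside the allowed disk are projected onto its
  # boundary, so the objective stays continuous and maxima on the
  # boundary are reachable by the simplex search
  proj <- function(p) {
    d <- sqrt((p[1] - axis_xy[1])^2 + (p[2] - axis_xy[2])^2)
    if (d <= escapeLimit) p
    else axis_xy + (p - axis_xy) * (escapeLimit / d)
  }
  obj <- function(p) {
    pp <- proj(p)
    -.clearance(pp[1], pp[2], z, x, v)
  }
  starts <- rbind(axis_xy,
                  if (!is.null(prev_center)) prev_center)
  ang <- seq(0, 2 * pi, length.out = 9)[-9]
  starts <- rbind(starts, cbind(axis_xy[1] + 0.5 * escapeLimit * cos(ang),
                                axis_xy[2] + 0.5 * escapeLimit * sin(ang)))
  # coarse deterministic pre-scan: clearance landscapes are min-of-cones
  # with basins wider than ~1 A, so seeding the local refinement from the
  # best coarse cells makes the multi-start search reliably global
  gstep <- min(0.5, escapeLimit / 8)
  gg <- seq(-escapeLimit, escapeLimit, by = gstep)
  gx <- rep(axis_xy[1] + gg, times = length(gg))
  gy <- rep(axis_xy[2] + gg, each = length(gg))
  # clip coarse points to the disk (keeps boundary cells in play)
  gr <- pmax(1, sqrt((gx - axis_xy[1])^2 + (gy - axis_xy[2])^2) /
               escapeLimit)
  gx <- axis_xy[1] + (gx - axis_xy[1]) / gr
  gy <- axis_xy[2] + (gy - axis_xy[2]) / gr
  gcl <- rep(Inf, length(gx))
  for (i in seq_len(nrow(x)))
    gcl <- pmin(gcl, sqrt((gx - x[i, 1])^2 + (gy - x[i, 2])^2 +
                            (z - x[i, 3])^2) - v[i])
  top <- order(gcl, decreasing = TRUE)[seq_len(min(3, length(gcl)))]
  starts <- rbind(starts, cbind(gx[top], gy[top]))
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    s <- as.numeric(starts[k, ])
    v0 <- obj(s)
    o <- stats::optim(s, obj, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-12))
    # monotone improvement: never worse than the start itself
    cand <- if (o$value <= v0) list(p = proj(o$par), val = o$value)
            else list(p = s, val = v0)
    if (is.null(best) || cand$val < best$val - 1e-12) best <- cand
    else if (!is.null(prev_center) && abs(cand$val - best$val) <= 1e-12) {
      # tie-break: probe centre closest to the previous slice centre
      if (sum((cand$p - prev_center)^2) < sum((best$p - prev_center)^2))
        best <- cand
    }
  }
  list(radius = -best$val, cx = best$p[1], cy = best$p[2])
}

#' HOLE-style pore radius profile
#'
#' For each z on a uniform grid, finds the largest probe sphere centred in
#' that plane (within \code{escapeLimit} of the axis) whose surface clears
#' all heavy-atom vdW spheres; distances are full 3D distances, so atoms
#' above and below the slice constrain it too. Slices where no positive
#' clearance exists are flagged \code{blocked} with radius 0.
#'
#' @param coords nAtoms x 3 matrix (one frame), Angstrom.
#' @param topology a \linkS4class{ChannelTopology} with vdW radii assigned.
#' @param axis a \linkS4class{PoreAxis}.
#' @param zRange length-2 numeric; default spans the heavy-atom z range.
#' @param zStep slice spacing, Angstrom (default 0.5).
#' @param escapeLimit maximal in-plane probe distance from the axis
#'   (default 12 Angstrom).
#' @return a \linkS4class{RadiusProfile}.
#' @export
radiusProfile <- function(coords, topology, axis, zRange = NULL,
                          zStep = 0.5, escapeLimit = 12) {
  h <- .heavy_atoms(coords, topology)
  if (!nrow(h$xyz)) stop("radius profile: empty heavy-atom set")
  if (is.null(zRange)) zRange <- range(h$xyz[, 3])
  zs <- seq(zRange[1], zRange[2], by = zStep)
  axy <- axis@center[1:2]
  out <- data.frame(z = zs, radius = NA_real_, cx = NA_real_, cy = NA_real_,
                    blocked = FALSE)
  prev <- NULL
  for (i in seq_along(zs)) {
    r <- .max_clearance_slice(zs[i], axy, h$xyz, h$vdw, escapeLimit, prev)
    if (r$radius < 0) {
      out$radius[i] <- 0
      out$blocked[i] <- TRUE
      prev <- NULL
    } else {
      out$radius[i] <- r$radius
      prev <- c(r$cx, r$cy)
    }
    out$cx[i] <- r$cx
    out$cy[i] <- r$cy
  }
  new("RadiusProfile", profile = out, zStep = zStep,
      escapeLimit = escapeLimit)
}

#' Exhaustive grid reference for the pore radius of one slice
#'
#' Brute-force maximisation of the probe clearance over a uniform XY grid
#' inside the escape disk. Slow but assumption-free; used as the
#' independent oracle for \code{\link{radiusProfile}}.
#'
#' @param coords,topology,axis as in \code{\link{radiusProfile}}.
#' @param z slice height, Angstrom.
#' @param gridStep grid spacing (default 0.02 Angstrom).
#' @param escapeLimit disk radius, Angstrom.
#' @return largest clearance found on the grid (Angstrom; may be negative
#'   if the slice is blocked).
#' @export
gridSliceRadius <- function(coords, topology, axis, z, gridStep = 0.02,
                            escapeLimit = 12) {
  h <- .heavy_atoms(coords, topology)
  axy <- axis@center[1:2]
  g <- seq(-escapeLimit, escapeLimit, by = gridStep)
  px <- rep(axy[1] + g, times = length(g))
  py <- rep(axy[2] + g, each = length(g))
  inside <- (px - axy[1])^2 + (py - axy[2])^2 <= escapeLimit^2
  px <- px[inside]; py <- py[inside]
  cl <- rep(Inf, length(px))
  for (i in seq_len(nrow(h$xyz)))
    cl <- pmin(cl, sqrt((px - h$xyz[i, 1])^2 + (py - h$xyz[i, 2])^2 +
                          (z - h$xyz[i, 3])^2) - h$vdw[i])
  max(cl)
}

#' Gate radius from a profile
#'
#' Minimum profile radius within a z window around the gate ring. The
#' window (default +/- 3 Angstrom) absorbs the variable z offset of the
#' constricting side chains from their C-alpha plane.
#'
#' @param profile a \linkS4class{RadiusProfile}.
#' @param gateZ z of the gate ring (mean C-alpha z of the gate residues).
#' @param window half-width of the z window, Angstrom.
#' @return gate radius, Angstrom.
#' @export
gateRadius <- function(profile, gateZ, window = 3) {
  p <- profile@profile
  if (gateZ < min(p$z) - 1e-9 || gateZ > max(p$z) + 1e-9)
    stop("gate z = ", gateZ, " outside profile range [",
         min(p$z), ", ", max(p$z), "]")
  sel <- abs(p$z - gateZ) <= window + 1e-9
  min(p$radius[sel])
}

#' Mean z of a residue's atoms over all chains
#'
#' @param coords nAtoms x 3 matrix, Angstrom.
#' @param topology a \linkS4class{ChannelTopology}.
#' @param resno residue number.
#' @param atomName atom defining the ring (default "CA").
#' @return mean z, Angstrom.
#' @export
ringZ <- function(coords, topology, resno, atomName = "CA") {
  sel <- resolveSelection(topology, sprintf("name %s and resid %d",
                                            atomName, resno))
  if (!length(sel))
    stop("ringZ: atom ", atomName, " of residue ", resno, " not found")
  mean(coords[sel, 3])
}

#' Per-frame gate radius series
#'
#' Runs the pore profiler only on the slices inside the gate window of
#' each frame (the pore axis and the gate ring z are recomputed per
#' frame) and returns the windowed minimum radius.
#'
#' @param trajectory a \linkS4class{ChannelTrajectory} with vdW-assigned
#'   topology.
#' @param annotation a \linkS4class{ChannelAnnotation}.
#' @param window half-width of the gate z window, Angstrom (default 3).
#' @param zStep slice spacing (default 0.5).
#' @param escapeLimit probe disk radius (default 5: the gate constriction
#'   search is confined to the pore lumen so the probe cannot wander into
#'   inter-helix gaps outside the basic region).
#' @param heavySelection optional selection limiting the profiled atom set
#'   (default: all heavy atoms).
#' @return numeric vector of gate radii (Angstrom), one per frame.
#' @export
gateRadiusSeries <- function(trajectory, annotation, window = 3,
                             zStep = 0.5, escapeLimit = 5,
                             heavySelection = NULL) {
  topo <- trajectory@topology
  keep <- NULL
  if (!is.null(heavySelection)) {
    keep <- resolveSelection(topo, heavySelection)
    topo <- new("ChannelTopology", atoms = topo@atoms[keep, , drop = FALSE])
  }
  nf <- nFrames(trajectory)
  out <- numeric(nf)
  for (f in seq_len(nf)) {
    co <- if (is.null(heavySelection)) frameCoords(trajectory, f)
          else frameCoords(trajectory, f)[keep, , drop = FALSE]
    ax <- poreAxis(co, topo, annotation)
    gz <- ringZ(co, topo, annotation@gateResidue)
    prof <- radiusProfile(co, topo, ax, zRange = c(gz - window, gz + window),
                          zStep = zStep, escapeLimit = escapeLimit)
    out[f] <- gateRadius(prof, gz, window = window)
  }
  out
}

#' Radial ring radius of a residue's atoms
#'
#' Mean over chains of the in-plane (XY) distance of the named atom from
#' the pore axis.
#'
#' @param coords nAtoms x 3 matrix, Angstrom.
#' @param topology a \linkS4class{ChannelTopology}.
#' @param axis a \linkS4class{PoreAxis}.
#' @param resno residue number (e.g. the K270 ring).
#' @param atomName defining atom, default "CA" (side-chain atoms such as
#'   "NZ" are accepted; results should be labelled with the atom used).
#' @return mean radial distance, Angstrom.
#' @export
ringRadius <- function(coords, topology, axis, resno, atomName = "CA") {
  a <- topology@atoms
  chains <- sort(unique(a$chain[a$resno == resno]))
  if (!length(chains)) stop("ringRadius: residue ", resno, " not found")
  sel <- resolveSelection(topology, sprintf("name %s and resid %d",
                                            atomName, resno))
  have <- a$chain[sel]
  miss <- setdiff(chains, have)
  if (length(miss))
    stop("ringRadius: atom ", atomName, " of residue ", resno,
         " missing on chains: ", paste(miss, collapse = ", "))
  d <- sqrt((coords[sel, 1] - axis@center[1])^2 +
              (coords[sel, 2] - axis@center[2])^2)
  mean(d)
}

# bio3d-style flat xyz (x1,y1,z1,x2,...) per frame
.flat_xyz <- function(trajectory) {
  nf <- nFrames(trajectory)
  n <- nAtoms(trajectory)
  m <- matrix(NA_real_, nrow = nf, ncol = 3L * n)
  for (f in seq_len(nf)) m[f, ] <- as.numeric(t(trajectory@xyz[, , f]))
  m
}

#' Average structure over a frame window
#'
#' Each window frame is superposed onto the first window frame by
#' least-squares (Kabsch) rigid fitting on the alignment selection, then
#' coordinates are averaged per atom.
#'
#' @param trajectory a \linkS4class{ChannelTrajectory}.
#' @param window integer vector of frame indices (default: all frames).
#' @param alignmentSelection selection for the fit (default "name CA").
#' @return nAtoms x 3 matrix of averaged coordinates, Angstrom.
#' @export
averageStructure <- function(trajectory, window = NULL,
                             alignmentSelection = "name CA") {
  nf <- nFrames(trajectory)
  if (is.null(window)) window <- seq_len(nf)
  if (!length(window) || any(window < 1 | window > nf))
    stop("average structure: window outside trajectory (1..", nf, ")")
  sel <- resolveSelection(trajectory@topology, alignmentSelection)
  if (!length(sel)) stop("average structure: empty alignment selection")
  inds <- bio3d::atom2xyz(sel)
  m <- .flat_xyz(trajectory)[window, , drop = FALSE]
  fitted <- bio3d::fit.xyz(fixed = m[1, ], mobile = m,
                           fixed.inds = inds, mobile.inds = inds)
  if (is.null(dim(fitted))) fitted <- matrix(fitted, nrow = 1)
  avg <- colMeans(fitted)
  matrix(avg, ncol = 3, byrow = TRUE)
}

#' C-alpha RMSD series
#'
#' Optimal-superposition (Kabsch) RMSD of each frame against a reference,
#' reported in nanometres (coordinates are Angstrom internally; RMSD is
#' conventionally plotted in nm).
#'
#' @param trajectory a \linkS4class{ChannelTrajectory}.
#' @param reference nAtoms x 3 matrix; default the first frame.
#' @param selection atom selection (default "name CA").
#' @param fit superpose before computing (default TRUE).
#' @return numeric vector, one RMSD in nm per frame.
#' @export
rmsdSeries <- function(trajectory, reference = NULL, selection = "name CA",
                       fit = TRUE) {
  sel <- resolveSelection(trajectory@topology, selection)
  if (!length(sel)) stop("rmsd: empty selection")
  if (is.null(reference)) reference <- frameCoords(trajectory, 1)
  if (nrow(reference) != nAtoms(trajectory))
    stop("rmsd: reference size differs from trajectory atom count")
  inds <- bio3d::atom2xyz(sel)
  m <- .flat_xyz(trajectory)
  ref <- as.numeric(t(reference))
  r <- bio3d::rmsd(a = ref, b = m, a.inds = inds, b.inds = inds, fit = fit)
  as.numeric(r) / 10  # Angstrom -> nm
}

#' Minimum heavy-atom contact distance between two residues
#'
#' Per subunit: the minimum over all heavy-atom pairs between residue A
#' and residue B of the same chain (e.g. the mutation-site/A166
#' hydrophobic contact).
#'
#' @param coords nAtoms x 3 matrix, Angstrom.
#' @param topology a \linkS4class{ChannelTopology}.
#' @param residueA,residueB residue numbers.
#' @param chains chains to evaluate (default: all chains carrying
#'   residue A).
#' @return named numeric vector of distances (Angstrom), one per chain.
#' @export
contactMinDistance <- function(coords, topology, residueA, residueB,
                               chains = NULL) {
  a <- topology@atoms
  if (is.null(chains)) chains <- sort(unique(a$chain[a$resno == residueA]))
  if (!length(chains)) stop("contact: residue ", residueA, " not found")
  out <- setNames(numeric(length(chains)), chains)
  for (ch in chains) {
    ia <- which(a$resno == residueA & a$chain == ch & !a$hydrogen)
    ib <- which(a$resno == residueB & a$chain == ch & !a$hydrogen)
    if (!length(ia) || !length(ib))
      stop("contact: residue pair ", residueA, "/", residueB,
           " does not resolve on chain ", ch)
    d <- sqrt(outer(coords[ia, 1], coords[ib, 1], "-")^2 +
                outer(coords[ia, 2], coords[ib, 2], "-")^2 +
                outer(coords[ia, 3], coords[ib, 3], "-")^2)
    out[ch] <- min(d)
  }
  out
}

#' Export a radius profile as CSV (and optionally SPH-like text)
#'
#' @param profile a \linkS4class{RadiusProfile}.
#' @param path CSV output path.
#' @param sphPath optional path for a minimal SPH-like visualisation file
#'   (x y z radius per slice).
#' @return \code{path}, invisibly.
#' @export
writeProfileCsv <- function(profile, path, sphPath = NULL) {
  p <- profile@profile
  utils::write.csv(p[, c("z", "radius", "cx", "cy")], path,
                   row.names = FALSE)
  if (!is.null(sphPath)) {
    writeLines(c("! SPH-like pore profile (x y z radius)",
                 sprintf("%10.4f %10.4f %10.4f %10.4f",
                         p$cx, p$cy, p$z, p$radius)), sphPath)
  }
  invisible(path)
}
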