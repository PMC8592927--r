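## Water and ion occupancy in residue-bounded axial cylinders, plus 3D
## density grids for isosurface export.
##
## Species conventions: pore water = oxygen atoms of water residues
## (TIP3/SOL/WAT/HOH dialects); Na+ matched as SOD/NA, Cl- as CLA/CL.

.SPECIES_SELECTIONS <- c(
  water = "element O and resname TIP3 TIP3P SOL WAT HOH",
  na    = "resname SOD NA and name SOD NA",
  cl    = "resname CLA CL and name CLA CL")

#' Default selection expression for a species
#' @param species "water", "na" or "cl".
#' @return selection string.
#' @export
speciesSelection <- function(species = c("water", "na", "cl")) {
  unname(.SPECIES_SELECTIONS[match.arg(species)])
}

#' Count atoms inside an axial cylinder
#'
#' Boundary convention is inclusive on both the radius and the z bounds
#' (counts are integers; tests compare them exactly).
#'
#' @param coords nAtoms x 3 matrix, Angstrom.
#' @param indices atom indices of the species (from
#'   \code{\link{resolveSelection}}).
#' @param axis a \linkS4class{PoreAxis}.
#' @param zLo,zHi axial bounds, Angstrom (zLo < zHi).
#' @param radius cylinder radius, Angstrom.
#' @return integer count.
#' @export
countInCylinder <- function(coords, indices, axis, zLo, zHi, radius) {
  if (zLo >= zHi) stop("cylinder: zLo must be < zHi")
  if (radius <= 0) stop("cylinder: radius must be > 0")
  if (!length(indices)) return(0L)
  x <- coords[indices, , drop = FALSE]
  inz <- x[, 3] >= zLo & x[, 3] <= zHi
  r2 <- (x[, 1] - axis@center[1])^2 + (x[, 2] - axis@center[2])^2
  sum(inz & r2 <= radius^2 + 1e-12)
}

#' Per-frame occupancy series in a residue-bounded cylinder
#'
#' The cylinder is recomputed every frame: its z bounds are the mean
#' C-alpha z of the two bounding residue rings, its axis the per-frame
#' pore axis. Defaults follow the annotation: water counted between
#' residues 171 and 178 in a 5 Angstrom cylinder, ions between residues
#' 148 and 184 in a 10 Angstrom cylinder.
#'
#' @param trajectory a \linkS4class{ChannelTrajectory}.
#' @param annotation a \linkS4class{ChannelAnnotation}.
#' @param species "water", "na" or "cl".
#' @param window frame indices to analyse (default: all frames).
#' @param selection override the species selection expression.
#' @return list: \code{series} data.frame(frame, time_ps, count),
#'   \code{histogram} data.frame(count, prob) over integer counts,
#'   \code{species}, \code{radius}, \code{bounds} (residue pair).
#' @export
occupancySeries <- function(trajectory, annotation,
                            species = c("water", "na", "cl"),
                            window = NULL, selection = NULL) {
  species <- match.arg(species)
  topo <- trajectory@topology
  nf <- nFrames(trajectory)
  if (is.null(window)) window <- seq_len(nf)
  if (!length(window) || any(window < 1 | window > nf))
    stop("occupancy: empty or out-of-range window")
  if (is.null(selection)) selection <- speciesSelection(species)
  idx <- resolveSelection(topo, selection)
  if (species == "water") {
    bounds <- annotation@waterBounds
    radius <- annotation@waterCylinderRadius
  } else {
    bounds <- annotation@ionBounds
    radius <- annotation@ionCylinderRadius
  }
  counts <- integer(length(window))
  for (k in seq_along(window)) {
    f <- window[k]
    co <- frameCoords(trajectory, f)
    ax <- poreAxis(co, topo, annotation)
    z1 <- ringZ(co, topo, bounds[1])
    z2 <- ringZ(co, topo, bounds[2])
    counts[k] <- countInCylinder(co, idx, ax, min(z1, z2), max(z1, z2),
                                 radius)
  }
  tab <- table(counts)
  hist <- data.frame(count = as.integer(names(tab)),
                     prob = as.numeric(tab) / length(counts))
  list(series = data.frame(frame = window,
                           time_ps = trajectory@time[window],
                           count = counts),
       histogram = hist, species = species, radius = radius,
       bounds = bounds)
}

#' Time-averaged 3D density grid
#'
#' Accumulates selected atoms into voxels of a regular grid and divides by
#' the number of frames, giving a mean count per voxel per frame; the sum
#' over voxels equals the mean in-box count per frame (conservation).
#' With \code{normalization = "per_A3"} values are additionally divided by
#' the voxel volume.
#'
#' @param trajectory a \linkS4class{ChannelTrajectory}.
#' @param selection species selection expression.
#' @param origin grid corner, numeric(3), Angstrom.
#' @param lengths grid extent along x, y, z, numeric(3), Angstrom.
#' @param spacing voxel edge, Angstrom (default 1).
#' @param window frame indices (default all).
#' @param normalization "count_per_frame" (default) or "per_A3".
#' @param species tag stored in the grid (default the selection string).
#' @return a \linkS4class{DensityGrid}.
#' @export
densityGrid <- function(trajectory, selection, origin, lengths, spacing = 1,
                        window = NULL, normalization = "count_per_frame",
                        species = selection) {
  if (spacing <= 0) stop("density grid: spacing must be > 0")
  nf <- nFrames(trajectory)
  if (is.null(window)) window <- seq_len(nf)
  if (!length(window)) stop("density grid: zero frames")
  idx <- resolveSelection(trajectory@topology, selection)
  dims <- pmax(1L, as.integer(ceiling(lengths / spacing)))
  vals <- array(0, dim = dims)
  for (f in window) {
    co <- matrix(trajectory@xyz[idx, , f], ncol = 3)
    vi <- floor(sweep(co, 2, origin) / spacing) + 1L
    keep <- vi[, 1] >= 1 & vi[, 1] <= dims[1] &
            vi[, 2] >= 1 & vi[, 2] <= dims[2] &
            vi[, 3] >= 1 & vi[, 3] <= dims[3]
    vi <- vi[keep, , drop = FALSE]
    if (nrow(vi)) {
      lin <- vi[, 1] + dims[1] * (vi[, 2] - 1L) +
        dims[1] * dims[2] * (vi[, 3] - 1L)
      t_ <- tabulate(lin, nbins = prod(dims))
      vals <- vals + array(t_, dim = dims)
    }
  }
  vals <- vals / length(window)
  if (normalization == "per_A3") vals <- vals / spacing^3
  else if (normalization != "count_per_frame")
    stop("unknown normalization: ", normalization)
  new("DensityGrid", origin = as.numeric(origin), spacing = spacing,
      values = vals, species = species, nFrames = length(window),
      normalization = normalization)
}

#' Write a density grid in OpenDX format
#'
#' Plain-text OpenDX scalar grid (as written by APBS and read by VMD/
#' PyMOL): data follow with z varying fastest. The normalisation mode is
#' recorded in a comment because isosurface values depend on it.
#'
#' @param grid a \linkS4class{DensityGrid}.
#' @param path output path (.dx).
#' @return the path, invisibly.
#' @export
writeOpenDX <- function(grid, path) {
  d <- dim(grid@values)
  # z varies fastest, x slowest
  seqv <- as.vector(aperm(grid@values, c(3, 2, 1)))
  pad <- c(seqv, rep(NA_real_, (3 - length(seqv) %% 3) %% 3))
  m <- matrix(pad, ncol = 3, byrow = TRUE)
  datalines <- apply(m, 1, function(r)
    paste(sprintf("%.9e", r[!is.na(r)]), collapse = " "))
  lines <- c(
    sprintf("# poreGating density grid: %s; units: %s", grid@species,
            grid@normalization),
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f", grid@origin[1], grid@origin[2],
            grid@origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", grid@spacing),
    sprintf("delta 0.000000 %.6f 0.000000", grid@spacing),
    sprintf("delta 0.000000 0.000000 %.6f", grid@spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d)),
    datalines,
    'attribute "dep" string "positions"',
    'object "density" class field')
  writeLines(lines, path)
  invisible(path)
}
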