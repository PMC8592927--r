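#' @import methods
NULL

.TOPOLOGY_COLS <- c("eleno", "name", "element", "resname", "resno", "chain",
                    "vdw", "hydrogen")

#' ChannelTopology: static atom metadata
#'
#' Holds one row per atom: serial number (\code{eleno}, 1-based in keeping
#' with R convention), atom name, element, residue name, author residue
#' number, chain identifier (one per subunit), an assigned van der Waals
#' radius in Angstrom (\code{NA} until \code{\link{assignVdwRadii}} is
#' called) and a hydrogen flag used to exclude hydrogens from pore
#' profiling.
#'
#' @slot atoms data.frame with columns \code{eleno}, \code{name},
#'   \code{element}, \code{resname}, \code{resno}, \code{chain},
#'   \code{vdw}, \code{hydrogen}.
#' @export
setClass("ChannelTopology", representation(atoms = "data.frame"))

setValidity("ChannelTopology", function(object) {
  a <- object@atoms
  msg <- character()
  if (!all(.TOPOLOGY_COLS %in% names(a)))
    msg <- c(msg, paste("atoms must have columns:",
                        paste(.TOPOLOGY_COLS, collapse = ", ")))
  else {
    if (anyDuplicated(a$eleno)) msg <- c(msg, "eleno must be unique")
    if (any(!is.na(a$vdw) & a$vdw <= 0))
      msg <- c(msg, "assigned vdw radii must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' ChannelTrajectory: time-ordered coordinate sets over a fixed topology
#'
#' Coordinates are stored in Angstrom as an \code{nAtoms x 3 x nFrames}
#' array; the box is orthorhombic (3 lengths per frame, Angstrom) and the
#' frame times are picoseconds, non-decreasing.
#'
#' @slot topology a \linkS4class{ChannelTopology}.
#' @slot xyz numeric array, \code{dim = c(nAtoms, 3, nFrames)}.
#' @slot time numeric, frame times in ps.
#' @slot box 3 x nFrames matrix of box lengths in Angstrom.
#' @slot metadata list; free-form provenance (e.g. synthetic ground truth).
#' @export
setClass("ChannelTrajectory",
         representation(topology = "ChannelTopology", xyz = "array",
                        time = "numeric", box = "matrix",
                        metadata = "list"))

setValidity("ChannelTrajectory", function(object) {
  d <- dim(object@xyz)
  msg <- character()
  if (length(d) != 3L || d[2] != 3L)
    msg <- c(msg, "xyz must be an nAtoms x 3 x nFrames array")
  else {
    if (d[1] != nrow(object@topology@atoms))
      msg <- c(msg, "atom count of xyz differs from topology")
    if (length(object@time) != d[3])
      msg <- c(msg, "time must have one entry per frame")
    if (!all(is.finite(object@xyz)))
      msg <- c(msg, "all coordinates must be finite")
    if (is.unsorted(object@time))
      msg <- c(msg, "frame times must be non-decreasing")
    if (ncol(object@box) != d[3] || nrow(object@box) != 3L)
      msg <- c(msg, "box must be a 3 x nFrames matrix")
  }
  if (length(msg)) msg else TRUE
})

#' ChannelAnnotation: functional role to residue-number map
#'
#' Central configuration read by every analysis: which author residue
#' numbers play which functional role in the hexamer, plus the convention
#' that the extracellular side is +z. Defaults follow the Drosophila Orai
#' numbering (selectivity filter E178, K163 gate, hydrophobic ring
#' L167/F171/V174, mutation site 210, K270 ring, water cylinder bounded by
#' residues 171 and 178, ion cylinder bounded by 148 and 184, contact pair
#' 210/166, orientation window 169-173).
#'
#' @slot tm1Range integer(2); residue interval whose C-alpha atoms define
#'   the pore centre.
#' @slot sfResidue integer; selectivity-filter residue.
#' @slot gateResidue integer; gate (narrowest constriction) residue.
#' @slot hydrophobicResidues integer; hydrophobic-gate residues.
#' @slot basicResidues integer; basic-region residues.
#' @slot mutationSite integer; rotating side-chain residue on TM2.
#' @slot ringResidue integer; TM3 ring residue for ring-radius reporting.
#' @slot waterBounds integer(2); residues bounding the water cylinder.
#' @slot ionBounds integer(2); residues bounding the ion cylinder.
#' @slot waterCylinderRadius numeric; Angstrom.
#' @slot ionCylinderRadius numeric; Angstrom.
#' @slot contactPair integer(2); residue pair for contact distances.
#' @slot orientationWindow integer(2); residue window for the orientation
#'   angle (geometric centre of its C-alpha atoms is the angle vertex).
#' @slot extracellularDirection numeric; +1 means extracellular = +z.
#' @export
setClass("ChannelAnnotation",
         representation(tm1Range = "integer", sfResidue = "integer",
                        gateResidue = "integer",
                        hydrophobicResidues = "integer",
                        basicResidues = "integer", mutationSite = "integer",
                        ringResidue = "integer", waterBounds = "integer",
                        ionBounds = "integer",
                        waterCylinderRadius = "numeric",
                        ionCylinderRadius = "numeric",
                        contactPair = "integer",
                        orientationWindow = "integer",
                        extracellularDirection = "numeric"))

setValidity("ChannelAnnotation", function(object) {
  msg <- character()
  if (length(object@tm1Range) != 2L || object@tm1Range[1] > object@tm1Range[2])
    msg <- c(msg, "tm1Range must be an increasing integer pair")
  for (s in c("waterBounds", "ionBounds", "contactPair", "orientationWindow"))
    if (length(slot(object, s)) != 2L)
      msg <- c(msg, paste(s, "must have length 2"))
  if (!object@extracellularDirection %in% c(-1, 1))
    msg <- c(msg, "extracellularDirection must be +1 or -1")
  if (length(msg)) msg else TRUE
})

#' PoreAxis: pore centre and direction
#'
#' @slot center numeric(3), Angstrom.
#' @slot direction unit numeric(3); by convention +z.
#' @export
setClass("PoreAxis", representation(center = "numeric",
                                    direction = "numeric"))

setValidity("PoreAxis", function(object) {
  if (length(object@center) != 3L || length(object@direction) != 3L)
    return("center and direction must have length 3")
  if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-9)
    return("direction must be a unit vector")
  TRUE
})

#' RadiusProfile: per-slice pore radius along the axis
#'
#' One row per z slice: slice height (Angstrom), the largest probe-sphere
#' radius whose surface clears all heavy-atom vdW spheres, the in-plane
#' probe centre that achieves it, and a \code{blocked} flag for slices
#' where no probe of positive radius fits.
#'
#' @slot profile data.frame with columns \code{z}, \code{radius},
#'   \code{cx}, \code{cy}, \code{blocked}.
#' @slot zStep numeric; grid spacing, Angstrom.
#' @slot escapeLimit numeric; maximal probe distance from the axis.
#' @export
setClass("RadiusProfile", representation(profile = "data.frame",
                                         zStep = "numeric",
                                         escapeLimit = "numeric"))

setValidity("RadiusProfile", function(object) {
  p <- object@profile
  need <- c("z", "radius", "cx", "cy", "blocked")
  if (!all(need %in% names(p)))
    return(paste("profile must have columns:", paste(need, collapse = ", ")))
  if (nrow(p) > 1 && any(diff(p$z) <= 0))
    return("z must be strictly increasing")
  if (any(p$radius < 0 & !p$blocked))
    return("negative radius on a non-blocked slice")
  TRUE
})

#' SyntheticChannelSpec: full parameterisation of the fixture generator
#'
#' Describes an idealised C\eqn{_n}-symmetric hexamer: one atom ring per
#' annotated residue at a programmed radius and height, a per-frame gate
#' clearance schedule, per-frame/per-subunit target angles for the
#' mutation-site rotation and the orientation statistic, a pore-water
#' count model, ion count models, coordinate noise and a seed. All
#' downstream statistics of a noise-free generated trajectory equal their
#' programmed values exactly, which is what makes the generator usable as
#' ground truth.
#'
#' @slot nSubunits integer >= 3 (default 6).
#' @slot nFrames integer; schedule length.
#' @slot rings data.frame: \code{resno}, \code{resname}, \code{z},
#'   \code{radius} (C-alpha ring radius, Angstrom).
#' @slot gateSchedule numeric(nFrames); programmed pore clearance at the
#'   gate ring, Angstrom.
#' @slot f210Schedule nFrames x nSubunits matrix; target rotation angle
#'   (degrees, clockwise-positive viewed from extracellular).
#' @slot f171Schedule nFrames x nSubunits matrix; target orientation angle
#'   (degrees, counter-clockwise positive).
#' @slot waterModel list; \code{type} in \code{"poisson"}, \code{"mixture"},
#'   \code{"fixed"} plus parameters and \code{maxCount} (pool size).
#' @slot ionModel list with \code{na} and \code{cl} sub-lists
#'   (\code{type}, \code{mean} or \code{count}, \code{maxCount}).
#' @slot noiseSigma numeric; isotropic Gaussian coordinate noise, Angstrom.
#' @slot box numeric(3); Angstrom.
#' @slot seed integer.
#' @export
setClass("SyntheticChannelSpec",
         representation(nSubunits = "integer", nFrames = "integer",
                        rings = "data.frame", gateSchedule = "numeric",
                        f210Schedule = "matrix", f171Schedule = "matrix",
                        waterModel = "list", ionModel = "list",
                        noiseSigma = "numeric", box = "numeric",
                        seed = "integer"))

setValidity("SyntheticChannelSpec", function(object) {
  msg <- character()
  if (object@nSubunits < 3L) msg <- c(msg, "nSubunits must be >= 3")
  nf <- object@nFrames
  if (length(object@gateSchedule) != nf)
    msg <- c(msg, "gateSchedule length must equal nFrames")
  if (nrow(object@f210Schedule) != nf || ncol(object@f210Schedule) != object@nSubunits)
    msg <- c(msg, "f210Schedule must be nFrames x nSubunits")
  if (nrow(object@f171Schedule) != nf || ncol(object@f171Schedule) != object@nSubunits)
    msg <- c(msg, "f171Schedule must be nFrames x nSubunits")
  need <- c("resno", "resname", "z", "radius")
  if (!all(need %in% names(object@rings)))
    msg <- c(msg, "rings must have columns resno, resname, z, radius")
  else {
    if (anyDuplicated(object@rings$resno))
      msg <- c(msg, "one ring per residue number")
    if (any(object@rings$radius <= max(.BONDI_DEFAULT)))
      msg <- c(msg, "ring radii must exceed the largest vdW radius")
  }
  if (any(object@gateSchedule <= 0))
    msg <- c(msg, "gate clearances must be positive")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (length(msg)) msg else TRUE
})

#' DensityGrid: time-averaged 3D occupancy on a regular grid
#'
#' Voxel values are mean counts per voxel per frame (optionally divided by
#' voxel volume when \code{normalization == "per_A3"}); the sum over
#' voxels equals the mean in-box count per frame (conservation), before
#' volume normalisation.
#'
#' @slot origin numeric(3); grid corner, Angstrom.
#' @slot spacing numeric; voxel edge, Angstrom.
#' @slot values 3D numeric array.
#' @slot species character tag.
#' @slot nFrames integer; frames averaged.
#' @slot normalization \code{"count_per_frame"} or \code{"per_A3"}.
#' @export
setClass("DensityGrid",
         representation(origin = "numeric", spacing = "numeric",
                        values = "array", species = "character",
                        nFrames = "integer", normalization = "character"))

setValidity("DensityGrid", function(object) {
  if (length(dim(object@values)) != 3L)
    return("values must be a 3D array")
  if (object@spacing <= 0) return("spacing must be > 0")
  TRUE
})
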