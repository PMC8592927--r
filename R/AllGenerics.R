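#' Number of atoms
#' @param x a ChannelTopology or ChannelTrajectory
#' @return integer
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Number of frames
#' @param x a ChannelTrajectory
#' @return integer
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Atom table accessor
#' @param x a ChannelTopology or ChannelTrajectory
#' @return data.frame of atom records
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' Topology accessor
#' @param x a ChannelTrajectory
#' @return ChannelTopology
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' Coordinates of one frame
#' @param x a ChannelTrajectory
#' @param i frame index (1-based)
#' @return nAtoms x 3 matrix, Angstrom
#' @export
setGeneric("frameCoords", function(x, i) standardGeneric("frameCoords"))

#' Frame times (ps)
#' @param x a ChannelTrajectory
#' @return numeric vector
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' Profile table accessor
#' @param x a RadiusProfile
#' @return data.frame (z, radius, cx, cy, blocked)
#' @export
setGeneric("profileTable", function(x) standardGeneric("profileTable"))

#' @rdname nAtoms
setMethod("nAtoms", "ChannelTopology", function(x) nrow(x@atoms))
#' @rdname nAtoms
setMethod("nAtoms", "ChannelTrajectory", function(x) dim(x@xyz)[1])
#' @rdname nFrames
setMethod("nFrames", "ChannelTrajectory", function(x) dim(x@xyz)[3])
#' @rdname atoms
setMethod("atoms", "ChannelTopology", function(x) x@atoms)
#' @rdname atoms
setMethod("atoms", "ChannelTrajectory", function(x) x@topology@atoms)
#' @rdname topology
setMethod("topology", "ChannelTrajectory", function(x) x@topology)
#' @rdname frameCoords
setMethod("frameCoords", "ChannelTrajectory", function(x, i) {
  stopifnot(i >= 1, i <= dim(x@xyz)[3])
  x@xyz[, , i, drop = TRUE]
})
#' @rdname frameTimes
setMethod("frameTimes", "ChannelTrajectory", function(x) x@time)
#' @rdname profileTable
setMethod("profileTable", "RadiusProfile", function(x) x@profile)

setMethod("show", "ChannelTopology", function(object) {
  a <- object@atoms
  cat("ChannelTopology:", nrow(a), "atoms,",
      length(unique(a$chain)), "chains,",
      sum(!is.na(a$vdw)), "with vdW radii assigned\n")
})

setMethod("show", "ChannelTrajectory", function(object) {
  cat("ChannelTrajectory:", dim(object@xyz)[1], "atoms x",
      dim(object@xyz)[3], "frames; t =",
      object@time[1], "..", object@time[length(object@time)], "ps\n")
})

setMethod("show", "ChannelAnnotation", function(object) {
  cat("ChannelAnnotation: SF", object@sfResidue,
      "| gate", object@gateResidue,
      "| hydrophobic", paste(object@hydrophobicResidues, collapse = "/"),
      "| mutation site", object@mutationSite,
      "| ring", object@ringResidue, "\n")
  cat("  water cylinder:", paste(object@waterBounds, collapse = "->"),
      "r =", object@waterCylinderRadius, "A; ion cylinder:",
      paste(object@ionBounds, collapse = "->"),
      "r =", object@ionCylinderRadius, "A\n")
})

setMethod("show", "RadiusProfile", function(object) {
  p <- object@profile
  cat("RadiusProfile:", nrow(p), "slices, z in [",
      min(p$z), ",", max(p$z), "] A, min radius",
      round(min(p$radius), 3), "A\n")
})

setMethod("show", "SyntheticChannelSpec", function(object) {
  cat("SyntheticChannelSpec:", object@nSubunits, "subunits,",
      object@nFrames, "frames,", nrow(object@rings), "rings, noise sigma",
      object@noiseSigma, "A, seed", object@seed, "\n")
})

setMethod("show", "DensityGrid", function(object) {
  cat("DensityGrid (", object@species, "): ",
      paste(dim(object@values), collapse = " x "),
      " voxels, spacing ", object@spacing, " A, ",
      object@nFrames, " frames, total mass ",
      signif(sum(object@values), 6), "\n", sep = "")
})
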