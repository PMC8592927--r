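#' Construct a ChannelAnnotation
#'
#' Defaults follow the Drosophila Orai numbering: pore centre from TM1
#' C-alpha atoms (residues 144-180), selectivity filter E178, K163 gate,
#' hydrophobic ring L167/F171/V174, basic ring R155/K159/K163, mutation
#' site 210 on TM2, K270 ring on TM3, water cylinder bounded by residues
#' 171 and 178 with a 5 Angstrom radius, ion cylinder bounded by 148 and
#' 184 with a 10 Angstrom radius, contact pair 210/166, orientation-angle
#' window 169-173, extracellular side at +z.
#'
#' @param tm1Range integer(2).
#' @param sfResidue,gateResidue,mutationSite,ringResidue integers.
#' @param hydrophobicResidues,basicResidues integer vectors.
#' @param waterBounds,ionBounds,contactPair,orientationWindow integer(2).
#' @param waterCylinderRadius,ionCylinderRadius numeric, Angstrom.
#' @param extracellularDirection +1 (extracellular = +z) or -1.
#' @return a \linkS4class{ChannelAnnotation}.
#' @export
channelAnnotation <- function(tm1Range = c(144L, 180L),
                              sfResidue = 178L,
                              gateResidue = 163L,
                              hydrophobicResidues = c(167L, 171L, 174L),
                              basicResidues = c(155L, 159L, 163L),
                              mutationSite = 210L,
                              ringResidue = 270L,
                              waterBounds = c(171L, 178L),
                              ionBounds = c(148L, 184L),
                              waterCylinderRadius = 5,
                              ionCylinderRadius = 10,
                              contactPair = c(210L, 166L),
                              orientationWindow = c(169L, 173L),
                              extracellularDirection = 1) {
  new("ChannelAnnotation",
      tm1Range = as.integer(tm1Range), sfResidue = as.integer(sfResidue),
      gateResidue = as.integer(gateResidue),
      hydrophobicResidues = as.integer(hydrophobicResidues),
      basicResidues = as.integer(basicResidues),
      mutationSite = as.integer(mutationSite),
      ringResidue = as.integer(ringResidue),
      waterBounds = as.integer(waterBounds),
      ionBounds = as.integer(ionBounds),
      waterCylinderRadius = waterCylinderRadius,
      ionCylinderRadius = ionCylinderRadius,
      contactPair = as.integer(contactPair),
      orientationWindow = as.integer(orientationWindow),
      extracellularDirection = extracellularDirection)
}
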