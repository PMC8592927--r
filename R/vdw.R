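## van der Waals radii. Default set: Bondi (1964) radii in Angstrom,
## shipped as a YAML config so a CHARMM-derived table can be swapped in.

.BONDI_DEFAULT <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
                    P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98,
                    Na = 2.27, K = 2.75, Mg = 1.73, Zn = 1.39)

#' Load a vdW radius table
#'
#' @param path YAML file mapping element symbol to radius in Angstrom;
#'   default is the packaged Bondi set.
#' @return named numeric vector (element -> Angstrom).
#' @export
loadVdwTable <- function(path = system.file("extdata", "vdw_bondi.yaml",
                                            package = "poreGating")) {
  tab <- yaml::read_yaml(path)
  unlist(tab)
}

#' Assign vdW radii to all non-hydrogen atoms
#'
#' Radii are looked up by element symbol, with a fallback on the leading
#' letter of the atom name for atoms whose element field is blank.
#' Hydrogens (element H, or atom names starting with H/1H/2H/3H) keep the
#' \code{hydrogen} exclusion flag and need no radius: pore profiling is
#' done with all hydrogen atoms removed.
#'
#' @param topology a \linkS4class{ChannelTopology}.
#' @param table named numeric vector element -> radius (Angstrom);
#'   defaults to the Bondi set.
#' @return the topology with \code{vdw} filled for every heavy atom.
#' @export
assignVdwRadii <- function(topology, table = .BONDI_DEFAULT) {
  a <- topology@atoms
  key <- trimws(a$element)
  # case-normalise: "NA"/"na" -> "Na", "CL" -> "Cl"
  key <- paste0(toupper(substr(key, 1, 1)), tolower(substring(key, 2)))
  r <- unname(table[key])
  miss <- is.na(r) & !a$hydrogen
  if (any(miss)) {
    # fallback: first letter of the atom name
    fb <- toupper(substr(sub("^[0-9]+", "", trimws(a$name[miss])), 1, 1))
    r[miss] <- unname(table[fb])
    still <- is.na(r) & !a$hydrogen
    if (any(still)) {
      bad <- unique(paste0(a$name[still], " (element '", a$element[still],
                           "')"))
      stop("no vdW radius for: ", paste(bad, collapse = ", "))
    }
  }
  a$vdw <- ifelse(a$hydrogen, NA_real_, r)
  topology@atoms <- a
  validObject(topology)
  topology
}
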