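## Structure and trajectory I/O. PDB/DCD parsing is delegated to bio3d;
## GRO (fixed-column, nm) and multi-model PDB writing are implemented here.

.infer_element <- function(name) {
  nm <- toupper(trimws(name))
  # strip leading digits ("1HB" style hydrogens)
  nm <- sub("^[0-9]+", "", nm)
  two <- substr(nm, 1, 2)
  vapply(seq_along(nm), function(i) {
    t2 <- two[i]
    if (t2 %in% c("CL", "NA", "BR", "MG", "ZN", "FE", "CA") &&
        nchar(nm[i]) == nchar(t2)) {
      # bare ion names only; "CA"/"CG" as protein atom names stay carbon
      if (t2 %in% c("CL", "NA", "BR", "MG", "ZN", "FE")) return(
        paste0(substr(t2, 1, 1), tolower(substr(t2, 2, 2))))
    }
    substr(nm[i], 1, 1)
  }, character(1))
}

.is_hydrogen <- function(name, element) {
  toupper(element) == "H" | grepl("^(H|1H|2H|3H)", trimws(name))
}

#' Construct a ChannelTopology from atom vectors
#'
#' @param name atom names (e.g. "CA", "CG", "OH2").
#' @param resname residue names.
#' @param resno author residue numbers.
#' @param chain chain identifiers (subunits).
#' @param element element symbols; inferred from atom names when missing.
#' @param vdw van der Waals radii in Angstrom (\code{NA} = unassigned).
#' @return a \linkS4class{ChannelTopology}.
#' @export
channelTopology <- function(name, resname, resno, chain,
                            element = NULL, vdw = NA_real_) {
  n <- length(name)
  if (is.null(element)) element <- .infer_element(name)
  atoms <- data.frame(eleno = seq_len(n), name = as.character(name),
                      element = as.character(element),
                      resname = as.character(resname),
                      resno = as.integer(resno),
                      chain = as.character(chain),
                      vdw = rep_len(as.numeric(vdw), n),
                      hydrogen = .is_hydrogen(name, element),
                      stringsAsFactors = FALSE)
  new("ChannelTopology", atoms = atoms)
}

#' Construct a ChannelTrajectory
#'
#' @param topology a \linkS4class{ChannelTopology}.
#' @param xyz nAtoms x 3 x nFrames array (Angstrom), or an nAtoms x 3
#'   matrix for a single frame.
#' @param time frame times in ps; defaults to 0, 1, 2, ...
#' @param box 3 x nFrames matrix of box lengths (Angstrom), or a length-3
#'   vector recycled over frames.
#' @param metadata free-form provenance list.
#' @return a \linkS4class{ChannelTrajectory}.
#' @export
channelTrajectory <- function(topology, xyz, time = NULL, box = NULL,
                              metadata = list()) {
  if (length(dim(xyz)) == 2L) xyz <- array(xyz, dim = c(dim(xyz), 1L))
  nf <- dim(xyz)[3]
  if (is.null(time)) time <- as.numeric(seq_len(nf) - 1L)
  if (is.null(box)) box <- c(100, 100, 100)
  if (is.null(dim(box))) box <- matrix(box, nrow = 3, ncol = nf)
  new("ChannelTrajectory", topology = topology, xyz = xyz,
      time = as.numeric(time), box = box, metadata = metadata)
}

.detect_format <- function(path, format) {
  if (!identical(format, "auto")) return(tolower(format))
  switch(tolower(tools::file_ext(path)),
         pdb = "pdb", ent = "pdb", gro = "gro", dcd = "dcd", xtc = "xtc",
         stop("cannot infer format from extension of '", path,
              "'; pass format= explicitly"))
}

#' Read a structure file (PDB or GRO)
#'
#' Every ATOM/HETATM record (PDB) or atom line (GRO) becomes one atom
#' record. GRO coordinates (nm) are converted to Angstrom (x10). Chain
#' identifiers are preserved verbatim; GRO files carry no chains, so
#' subunits are inferred from residue-number periodicity (each drop in
#' the running residue number starts a new chain) and a message is
#' emitted.
#'
#' @param path file path.
#' @param format "pdb", "gro" or "auto" (from extension).
#' @return list with elements \code{topology}
#'   (\linkS4class{ChannelTopology}) and \code{coords} (nAtoms x 3 matrix,
#'   Angstrom).
#' @export
readStructure <- function(path, format = "auto") {
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- .detect_format(path, format)
  switch(fmt,
         pdb = .read_pdb_structure(path),
         gro = .read_gro(path),
         stop("unsupported structure format: ", fmt))
}

.read_pdb_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  a <- pdb$atom
  element <- a$elesy
  bad <- is.na(element) | trimws(element) == ""
  if (any(bad)) element[bad] <- .infer_element(a$elety[bad])
  chain <- a$chain
  chain[is.na(chain)] <- ""
  topo <- channelTopology(name = a$elety, resname = a$resid,
                          resno = a$resno, chain = chain,
                          element = trimws(element))
  list(topology = topo, coords = cbind(a$x, a$y, a$z))
}

.read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("malformed GRO file: fewer than 3 lines")
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop("malformed GRO line 2: expected atom count")
  if (length(lines) < n + 3)
    stop("truncated GRO file: expected ", n, " atom lines")
  al <- lines[3:(2 + n)]
  num <- function(s, from, to) {
    v <- suppressWarnings(as.numeric(substr(s, from, to)))
    v
  }
  resno <- suppressWarnings(as.integer(substr(al, 1, 5)))
  resname <- trimws(substr(al, 6, 10))
  name <- trimws(substr(al, 11, 15))
  x <- num(al, 21, 28); y <- num(al, 29, 36); z <- num(al, 37, 44)
  bad <- which(is.na(resno) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad))
    stop("malformed GRO atom line ", bad[1] + 2L, ": '", al[bad[1]], "'")
  # infer subunits: a drop in running residue number starts a new chain
  brk <- c(TRUE, diff(resno) < 0)
  chain <- LETTERS[cumsum(brk)]
  if (length(unique(chain)) > 1)
    message("GRO has no chain IDs; inferred ", length(unique(chain)),
            " subunits from residue-number periodicity")
  topo <- channelTopology(name = name, resname = resname, resno = resno,
                          chain = chain)
  list(topology = topo, coords = cbind(x, y, z) * 10)  # nm -> Angstrom
}

.pdb_atom_line <- function(i, name, resname, chain, resno, xyz, element) {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else substr(name, 1, 4)
  sprintf("ATOM  %5d %4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          i %% 100000, nm, substr(resname, 1, 4),
          substr(paste0(chain, " "), 1, 1), resno %% 10000,
          xyz[1], xyz[2], xyz[3], 1, 0, substr(element, 1, 2))
}

.write_pdb_models <- function(topology, xyz, path, box = NULL) {
  a <- topology@atoms
  nf <- dim(xyz)[3]
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(box))
    writeLines(sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      box[1], box[2], box[3], 90, 90, 90), con)
  for (f in seq_len(nf)) {
    if (nf > 1) writeLines(sprintf("MODEL     %4d", f), con)
    lines <- vapply(seq_len(nrow(a)), function(i)
      .pdb_atom_line(i, a$name[i], a$resname[i], a$chain[i], a$resno[i],
                     xyz[i, , f], a$element[i]), character(1))
    writeLines(lines, con)
    if (nf > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a structure file (PDB or GRO)
#'
#' @param topology a \linkS4class{ChannelTopology}.
#' @param coords nAtoms x 3 matrix, Angstrom.
#' @param path output path.
#' @param format "pdb", "gro" or "auto".
#' @param box optional length-3 box (Angstrom).
#' @return the path, invisibly.
#' @export
writeStructure <- function(topology, coords, path, format = "auto",
                           box = NULL) {
  fmt <- .detect_format(path, format)
  if (fmt == "pdb") {
    .write_pdb_models(topology, array(coords, dim = c(dim(coords), 1L)),
                      path, box = box)
  } else if (fmt == "gro") {
    a <- topology@atoms
    b <- if (is.null(box)) c(100, 100, 100) else box
    lines <- c("written by poreGating", sprintf("%5d", nrow(a)),
               vapply(seq_len(nrow(a)), function(i)
                 sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                         a$resno[i] %% 100000, substr(a$resname[i], 1, 5),
                         substr(a$name[i], 1, 5), a$eleno[i] %% 100000,
                         coords[i, 1] / 10, coords[i, 2] / 10,
                         coords[i, 3] / 10), character(1)),
               sprintf("%10.5f%10.5f%10.5f", b[1] / 10, b[2] / 10, b[3] / 10))
    writeLines(lines, path)
  } else stop("unsupported structure format: ", fmt)
  invisible(path)
}

#' Read a trajectory (DCD or multi-model PDB)
#'
#' Frames are returned in file order with coordinates in Angstrom. The
#' atom count in the file must equal the topology size. XTC is not
#' readable by any installed backend and raises an explicit error.
#'
#' @param path trajectory file.
#' @param topology the matching \linkS4class{ChannelTopology}.
#' @param format "dcd", "pdb" (multi-model) or "auto".
#' @param dt time between frames in ps (DCD and PDB carry no reliable
#'   time stamps; default 1).
#' @return a \linkS4class{ChannelTrajectory}.
#' @export
readTrajectory <- function(path, topology, format = "auto", dt = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- .detect_format(path, format)
  n <- nAtoms(topology)
  if (fmt == "xtc")
    stop("unsupported trajectory format: xtc (use DCD or multi-model PDB)")
  if (fmt == "dcd") {
    m <- bio3d::read.dcd(path, verbose = FALSE)  # nframes x 3N
    if (ncol(m) != 3L * n)
      stop("atom-count mismatch: file has ", ncol(m) / 3,
           " atoms, topology has ", n)
    nf <- nrow(m)
    xyz <- array(NA_real_, dim = c(n, 3, nf))
    for (f in seq_len(nf)) xyz[, , f] <- matrix(m[f, ], ncol = 3, byrow = TRUE)
  } else if (fmt == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    m <- pdb$xyz
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    if (ncol(m) != 3L * n)
      stop("atom-count mismatch: file has ", ncol(m) / 3,
           " atoms, topology has ", n)
    nf <- nrow(m)
    xyz <- array(NA_real_, dim = c(n, 3, nf))
    for (f in seq_len(nf)) xyz[, , f] <- matrix(m[f, ], ncol = 3, byrow = TRUE)
  } else stop("unsupported trajectory format: ", fmt)
  channelTrajectory(topology, xyz, time = dt * (seq_len(dim(xyz)[3]) - 1L))
}

#' Write a trajectory as a multi-model PDB
#'
#' @param trajectory a \linkS4class{ChannelTrajectory}.
#' @param path output path (.pdb).
#' @return the path, invisibly.
#' @export
writeTrajectory <- function(trajectory, path) {
  .write_pdb_models(trajectory@topology, trajectory@xyz, path,
                    box = trajectory@box[, 1])
}
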