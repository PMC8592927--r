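## Side-chain rotation statistics.
##
## F210 rotation angle (per subunit): project the C-alpha of residue 210
## and the pore centre onto the XY plane; u points from C-alpha to the
## pore centre, v from C-alpha to C-gamma. The statistic is the signed
## angle from u to v with clockwise (viewed from the extracellular +z
## side) positive, so "side chain points at the pore" reads 0 and a
## clockwise rotation of ~50 degrees reads +50.
##
## F171 orientation angle (per subunit): on the XY plane, a = projected
## pore centre, b = projected geometric centre of the C-alpha atoms of the
## orientation window (residues 169-173 of that subunit), c = projected
## C-alpha of residue 171. The statistic is the signed angle at vertex b
## from b->a to b->c, counter-clockwise positive viewed from +z.

.KB_KJ_MOL_K <- 0.008314462618  # Boltzmann constant, kJ/mol/K

# signed angle from u to v (2D), counter-clockwise positive, degrees
.signed_angle_ccw <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-6 || nv < 1e-6) return(NA_real_)  # flagged-undefined
  atan2(u[1] * v[2] - u[2] * v[1], sum(u * v)) * 180 / pi
}

#' Rotation angle of the mutation-site side chain (residue 210)
#'
#' @param coords nAtoms x 3 matrix (one frame), Angstrom.
#' @param topology a \linkS4class{ChannelTopology}.
#' @param axis a \linkS4class{PoreAxis} (per-frame pore centre).
#' @param chain subunit chain identifier.
#' @param resno rotating residue (default 210).
#' @return signed angle in degrees, clockwise-from-extracellular positive,
#'   in (-180, 180]; \code{NA} when a projection is degenerate
#'   (< 1e-6 Angstrom).
#' @export
f210RotationAngle <- function(coords, topology, axis, chain, resno = 210L) {
  a <- topology@atoms
  ica <- which(a$resno == resno & a$chain == chain & toupper(a$name) == "CA")
  icg <- which(a$resno == resno & a$chain == chain & toupper(a$name) == "CG")
  if (length(ica) != 1L || length(icg) != 1L)
    stop("residue ", resno, " chain ", chain,
         ": need exactly one CA and one CG")
  ca <- coords[ica, 1:2]
  u <- axis@center[1:2] - ca          # C-alpha -> pore centre
  v <- coords[icg, 1:2] - ca          # C-alpha -> C-gamma
  ccw <- .signed_angle_ccw(u, v)
  -ccw                                 # clockwise positive (viewed from +z)
}

#' Orientation angle of the hydrophobic-gate residue (171)
#'
#' @param coords nAtoms x 3 matrix (one frame), Angstrom.
#' @param topology a \linkS4class{ChannelTopology}.
#' @param axis a \linkS4class{PoreAxis}.
#' @param chain subunit chain identifier.
#' @param window residue window whose C-alpha centre is the vertex
#'   (default 169:173).
#' @param resno apex residue (default 171).
#' @return signed angle in degrees, counter-clockwise positive viewed from
#'   +z; \code{NA} when a projection is degenerate.
#' @export
f171OrientationAngle <- function(coords, topology, axis, chain,
                                 window = c(169L, 173L), resno = 171L) {
  a <- topology@atoms
  iw <- which(a$resno >= window[1] & a$resno <= window[2] &
                a$chain == chain & toupper(a$name) == "CA")
  ic <- which(a$resno == resno & a$chain == chain & toupper(a$name) == "CA")
  if (length(iw) < 2L || length(ic) != 1L)
    stop("orientation window ", window[1], "-", window[2], " chain ", chain,
         ": unresolved C-alpha atoms")
  b <- colMeans(coords[iw, 1:2, drop = FALSE])
  u <- axis@center[1:2] - b            # b -> a (projected pore centre)
  v <- coords[ic, 1:2] - b             # b -> c (projected C-alpha 171)
  .signed_angle_ccw(u, v)              # counter-clockwise positive
}

#' Per-frame, per-subunit angle series
#'
#' Computes one of the two angle statistics for every frame and subunit.
#' The pore centre is recomputed per frame by default. The returned data
#' frame carries the signed angle (\code{signed}); the reported
#' \code{angle} equals the signed value for the F210 metric and its
#' absolute value for the F171 metric (orientation angles are plotted as
#' positive by convention).
#'
#' @param trajectory a \linkS4class{ChannelTrajectory}.
#' @param annotation a \linkS4class{ChannelAnnotation}.
#' @param metric "F210" or "F171".
#' @param chains subunits to evaluate (default: all carrying the residue).
#' @param perFrameCenter recompute the pore axis every frame (default
#'   TRUE); FALSE reuses the first frame's axis.
#' @return data.frame(frame, time_ps, chain, metric, angle, signed), one
#'   row per (frame, subunit); undefined angles are \code{NA}.
#' @export
computeAngleSeries <- function(trajectory, annotation,
                               metric = c("F210", "F171"), chains = NULL,
                               perFrameCenter = TRUE) {
  metric <- match.arg(metric)
  topo <- trajectory@topology
  resno <- if (metric == "F210") annotation@mutationSite else 171L
  if (is.null(chains))
    chains <- sort(unique(topo@atoms$chain[topo@atoms$resno == resno]))
  nf <- nFrames(trajectory)
  ax0 <- poreAxis(frameCoords(trajectory, 1), topo, annotation)
  rows <- vector("list", nf)
  for (f in seq_len(nf)) {
    co <- frameCoords(trajectory, f)
    ax <- if (perFrameCenter) poreAxis(co, topo, annotation) else ax0
    ang <- vapply(chains, function(ch) {
      if (metric == "F210")
        f210RotationAngle(co, topo, ax, ch, resno = annotation@mutationSite)
      else
        f171OrientationAngle(co, topo, ax, ch,
                             window = annotation@orientationWindow)
    }, numeric(1))
    rows[[f]] <- data.frame(frame = f, time_ps = trajectory@time[f],
                            chain = chains, metric = metric, signed = ang,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$angle <- if (metric == "F171") abs(out$signed) else out$signed
  attr(out, "convention") <- if (metric == "F210")
    "clockwise-from-extracellular positive; 0 = side chain points at pore"
  else
    "counter-clockwise positive viewed from extracellular; reported as |angle|"
  out[, c("frame", "time_ps", "chain", "metric", "angle", "signed")]
}

#' Normalised angle histogram
#'
#' Flagged-undefined (NA) angles are dropped and their count reported;
#' probabilities are counts over total retained and sum to one.
#'
#' @param angles numeric vector, degrees (NA allowed).
#' @param binWidth bin width in degrees (default 5).
#' @param range optional length-2 numeric; bins cover it exactly. Default:
#'   bin edges are multiples of \code{binWidth} spanning the data.
#' @return list of class \code{"angleHistogram"}: \code{breaks},
#'   \code{mids}, \code{counts}, \code{prob}, \code{binWidth},
#'   \code{nDropped}.
#' @export
angleHistogram <- function(angles, binWidth = 5, range = NULL) {
  nDropped <- sum(is.na(angles))
  x <- angles[!is.na(angles)]
  if (!length(x)) stop("angle histogram: no defined angles after filtering")
  if (is.null(range))
    range <- c(floor(min(x) / binWidth), ceiling(max(x) / binWidth)) * binWidth
  if (range[2] <= range[1]) range[2] <- range[1] + binWidth
  breaks <- seq(range[1], range[2], by = binWidth)
  if (breaks[length(breaks)] < range[2])
    breaks <- c(breaks, breaks[length(breaks)] + binWidth)
  # bins are [lo, hi): shift the top edge so max(x) falls in the last bin
  idx <- findInterval(x, breaks, rightmost.closed = FALSE)
  idx[idx == length(breaks)] <- length(breaks) - 1L
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  structure(list(breaks = breaks,
                 mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 counts = counts, prob = counts / sum(counts),
                 binWidth = binWidth, nDropped = nDropped),
            class = "angleHistogram")
}

#' Boltzmann inversion of an angle histogram
#'
#' Converts bin probabilities into a relative free-energy profile,
#' \eqn{\Delta F = -k_B T \ln p}, shifted so the minimum is zero.
#' Zero-probability bins are undefined (NA), not zero.
#'
#' @param histogram an \code{"angleHistogram"} (or any list with
#'   \code{mids} and \code{prob}).
#' @param temperature Kelvin (default 310, physiological).
#' @return data.frame(center_deg, deltaF_kJ_mol) with attribute
#'   \code{temperature}.
#' @export
boltzmannFreeEnergy <- function(histogram, temperature = 310) {
  if (temperature <= 0) stop("temperature must be > 0")
  p <- histogram$prob
  if (all(p == 0)) stop("free energy: all-zero histogram")
  f <- ifelse(p > 0, -.KB_KJ_MOL_K * temperature * log(p), NA_real_)
  f <- f - min(f, na.rm = TRUE)
  out <- data.frame(center_deg = histogram$mids, deltaF_kJ_mol = f)
  attr(out, "temperature") <- temperature
  out
}
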