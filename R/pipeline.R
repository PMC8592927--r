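## Gating-state classification and the end-to-end analysis pipeline.

#' Classify frames into closed/dilated gate states
#'
#' A frame whose gate radius is strictly below the threshold is closed;
#' radii greater than or equal to the threshold (including exactly at it)
#' are dilated. Non-finite radii yield NA labels and are reported.
#'
#' @param gateRadii numeric vector of per-frame gate radii, Angstrom.
#' @param threshold Angstrom (default 2.0).
#' @return character vector of "closed"/"dilated" labels (NA for
#'   non-finite radii) with attribute \code{threshold}.
#' @export
classifyFrames <- function(gateRadii, threshold = 2.0) {
  bad <- !is.finite(gateRadii)
  if (any(bad))
    message(sum(bad), " frame(s) with non-finite gate radius excluded")
  lab <- ifelse(bad, NA_character_,
                ifelse(gateRadii < threshold, "closed", "dilated"))
  attr(lab, "threshold") <- threshold
  lab
}

#' Build the four state datasets from two variants
#'
#' Partitions all labelled frames of two variants into
#' \code{<variant>-closed} / \code{<variant>-dilated} sets. The four sets
#' partition the analysed frames: per variant, closed + dilated equals
#' the variant total (NA-labelled frames are excluded and counted
#' separately).
#'
#' @param labels named list of two label vectors (from
#'   \code{\link{classifyFrames}}), e.g.
#'   \code{list(wild = ..., mutant = ...)}.
#' @return list with \code{sizes} (named integer vector),
#'   \code{members} (named list of frame-index vectors) and
#'   \code{excluded} (NA counts per variant).
#' @export
buildStateDatasets <- function(labels) {
  if (length(labels) != 2L || is.null(names(labels)) ||
      anyDuplicated(names(labels)))
    stop("exactly two distinctly named variants are required")
  members <- list()
  excluded <- integer(0)
  for (v in names(labels)) {
    lv <- labels[[v]]
    members[[paste0(v, "-closed")]] <- which(!is.na(lv) & lv == "closed")
    members[[paste0(v, "-dilated")]] <- which(!is.na(lv) & lv == "dilated")
    excluded[v] <- sum(is.na(lv))
  }
  sizes <- vapply(members, length, integer(1))
  for (v in names(labels))
    stopifnot(sizes[paste0(v, "-closed")] + sizes[paste0(v, "-dilated")] +
                excluded[v] == length(labels[[v]]))
  list(sizes = sizes, members = members, excluded = excluded)
}

#' State-conditioned angle histograms
#'
#' One normalised histogram per state dataset, built from the rows of the
#' angle series whose frames belong to that dataset. Empty datasets are
#' omitted with a warning rather than an error.
#'
#' @param angleSeries named list of angle series data.frames (one per
#'   variant, from \code{\link{computeAngleSeries}}).
#' @param datasets result of \code{\link{buildStateDatasets}} on the same
#'   variants.
#' @param binWidth degrees (default 5).
#' @param range optional common histogram range.
#' @return named list of \code{angleHistogram} objects with attribute
#'   \code{nFrames} per dataset.
#' @export
stateConditionedAngles <- function(angleSeries, datasets, binWidth = 5,
                                   range = NULL) {
  out <- list()
  for (ds in names(datasets$members)) {
    v <- sub("-(closed|dilated)$", "", ds)
    if (is.null(angleSeries[[v]]))
      stop("no angle series for variant '", v, "'")
    frames <- datasets$members[[ds]]
    if (!length(frames)) {
      warning("dataset '", ds, "' is empty; histogram omitted")
      next
    }
    s <- angleSeries[[v]]
    h <- angleHistogram(s$angle[s$frame %in% frames], binWidth = binWidth,
                        range = range)
    attr(h, "nFrames") <- length(frames)
    out[[ds]] <- h
  }
  out
}

.protein_heavy_selection <-
  "not resname TIP3 TIP3P SOL WAT HOH SOD NA CLA CL"

.load_variant_trajectory <- function(vspec) {
  if (!is.null(vspec$trajectory)) {
    stopifnot(is(vspec$trajectory, "ChannelTrajectory"))
    return(vspec$trajectory)
  }
  st <- readStructure(vspec$topology)
  topo <- assignVdwRadii(st$topology)
  parts <- lapply(vspec$trajectories, readTrajectory, topology = topo)
  xyz <- array(unlist(lapply(parts, function(p) p@xyz)),
               dim = c(nAtoms(topo), 3, sum(vapply(parts, nFrames,
                                                   integer(1)))))
  channelTrajectory(topo, xyz)
}

.validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$variants) || length(config$variants) != 2L)
    stop("config: exactly two variants are required")
  if (is.null(names(config$variants)) ||
      anyDuplicated(names(config$variants)))
    stop("config: variants must have two distinct names")
  for (v in names(config$variants)) {
    vs <- config$variants[[v]]
    if (is.null(vs$trajectory)) {
      if (is.null(vs$topology) || !file.exists(vs$topology))
        stop("config: variant '", v, "': topology path missing or not found")
      if (!length(vs$trajectories) ||
          !all(file.exists(unlist(vs$trajectories))))
        stop("config: variant '", v,
             "': trajectory path missing or not found")
    }
  }
  defaults <- list(windowFraction = 0.4, angleWindowFraction = 1.0,
                   gateThreshold = 2.0, binWidth = 5, zStep = 0.5,
                   escapeLimit = 12, gateEscapeLimit = 5, gateWindow = 3,
                   ringAtom = "CA",
                   temperature = 310, gridSpacing = 1.0, seed = 1L,
                   writePlots = FALSE, outDir = NULL)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  config
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full gating analysis pipeline
#'
#' Orchestrates, for two variants: per-trajectory C-alpha RMSD series; an
#' average structure and its pore radius profile over the equilibrated
#' window (default: last 40\% of frames); per-frame gate radii,
#' closed/dilated labels and the four state datasets; rotation and
#' orientation angle series with overall and state-conditioned histograms
#' and Boltzmann free-energy profiles; water/Na+/Cl- occupancy series and
#' histograms over the window; ion density grids (OpenDX); the ring-radius
#' series of the annotated TM3 ring; and the mutation-site contact
#' distances. All derived conventions (sign, boundary, windows, atoms)
#' are echoed into the summary for provenance. Deterministic given inputs
#' and config.
#'
#' @param config a list, or path to a YAML file, with entries:
#'   \code{variants} (named list of two; each either
#'   \code{trajectory = <ChannelTrajectory>} or \code{topology} +
#'   \code{trajectories} paths), and optional \code{windowFraction},
#'   \code{angleWindowFraction}, \code{gateThreshold}, \code{binWidth},
#'   \code{zStep}, \code{escapeLimit}, \code{gateWindow}, \code{ringAtom},
#'   \code{temperature}, \code{gridSpacing}, \code{outDir},
#'   \code{writePlots}.
#' @param annotation a \linkS4class{ChannelAnnotation} (default
#'   \code{channelAnnotation()}).
#' @return (invisibly) a list: \code{summary} (also written as JSON when
#'   \code{outDir} is set), \code{datasets}, \code{labels},
#'   \code{angles}, \code{histograms}, \code{occupancy},
#'   \code{profiles}, \code{rmsd}.
#' @export
runPipeline <- function(config, annotation = channelAnnotation()) {
  config <- .stage("config validation", .validate_config(config))
  outDir <- config$outDir
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)

  variants <- names(config$variants)
  trajs <- .stage("input loading", lapply(config$variants,
                                          .load_variant_trajectory))
  names(trajs) <- variants

  res <- list()
  labels <- list()
  angles210 <- list()
  angles171 <- list()
  for (v in variants) {
    tr <- trajs[[v]]
    nf <- nFrames(tr)
    wStart <- max(1L, nf - as.integer(ceiling(config$windowFraction * nf)) + 1L)
    window <- wStart:nf
    aStart <- max(1L, nf - as.integer(ceiling(config$angleWindowFraction * nf)) + 1L)
    angleWindow <- aStart:nf

    rmsd <- .stage(paste0(v, ": rmsd"), rmsdSeries(tr))

    avg <- .stage(paste0(v, ": average structure"),
                  averageStructure(tr, window = window))
    protSel <- resolveSelection(tr@topology, .protein_heavy_selection)
    protTopo <- new("ChannelTopology",
                    atoms = tr@topology@atoms[protSel, , drop = FALSE])
    avgProt <- avg[protSel, , drop = FALSE]
    ax <- poreAxis(avgProt, protTopo, annotation)
    zlo <- ringZ(avgProt, protTopo, annotation@ionBounds[1]) - 5
    zhi <- ringZ(avgProt, protTopo, annotation@ionBounds[2]) + 5
    prof <- .stage(paste0(v, ": radius profile"),
                   radiusProfile(avgProt, protTopo, ax,
                                 zRange = c(zlo, zhi), zStep = config$zStep,
                                 escapeLimit = config$escapeLimit))

    gates <- .stage(paste0(v, ": gate radii"),
                    gateRadiusSeries(tr, annotation,
                                     window = config$gateWindow,
                                     zStep = config$zStep,
                                     escapeLimit = config$gateEscapeLimit,
                                     heavySelection =
                                       .protein_heavy_selection))
    labels[[v]] <- classifyFrames(gates, config$gateThreshold)

    sub <- function(df, w) df[df$frame %in% w, , drop = FALSE]
    a210 <- .stage(paste0(v, ": rotation angles"),
                   sub(computeAngleSeries(tr, annotation, "F210"),
                       angleWindow))
    a171 <- .stage(paste0(v, ": orientation angles"),
                   sub(computeAngleSeries(tr, annotation, "F171"),
                       angleWindow))
    angles210[[v]] <- a210
    angles171[[v]] <- a171

    occ <- .stage(paste0(v, ": occupancy"), list(
      water = occupancySeries(tr, annotation, "water", window = window),
      na = occupancySeries(tr, annotation, "na", window = window),
      cl = occupancySeries(tr, annotation, "cl", window = window)))

    grids <- .stage(paste0(v, ": density grids"), {
      co1 <- frameCoords(tr, 1)
      gz <- c(ringZ(co1, tr@topology, annotation@ionBounds[1]) - 2,
              ringZ(co1, tr@topology, annotation@ionBounds[2]) + 2)
      org <- c(ax@center[1] - 12, ax@center[2] - 12, gz[1])
      len <- c(24, 24, gz[2] - gz[1])
      list(na = densityGrid(tr, speciesSelection("na"), org, len,
                            spacing = config$gridSpacing, window = window,
                            species = "Na+"),
           cl = densityGrid(tr, speciesSelection("cl"), org, len,
                            spacing = config$gridSpacing, window = window,
                            species = "Cl-"))
    })

    ring <- .stage(paste0(v, ": ring radius"), vapply(window, function(f) {
      co <- frameCoords(tr, f)
      axf <- poreAxis(co, tr@topology, annotation)
      ringRadius(co, tr@topology, axf, annotation@ringResidue,
                 atomName = config$ringAtom)
    }, numeric(1)))

    contact <- .stage(paste0(v, ": contact distances"),
                      vapply(window, function(f)
                        mean(contactMinDistance(frameCoords(tr, f),
                                                tr@topology,
                                                annotation@contactPair[1],
                                                annotation@contactPair[2])),
                        numeric(1)))

    res[[v]] <- list(rmsd = rmsd, profile = prof, gateRadii = gates,
                     occupancy = occ, grids = grids, ringRadii = ring,
                     contact = contact, window = window)
  }

  datasets <- .stage("state datasets", buildStateDatasets(labels))
  hist171 <- .stage("state-conditioned angles",
                    stateConditionedAngles(angles171, datasets,
                                           binWidth = config$binWidth))
  hist210 <- .stage("state-conditioned angles (rotation)",
                    stateConditionedAngles(angles210, datasets,
                                           binWidth = config$binWidth))

  overall <- list()
  for (v in variants) {
    h210 <- angleHistogram(angles210[[v]]$angle, binWidth = config$binWidth)
    h171 <- angleHistogram(angles171[[v]]$angle, binWidth = config$binWidth)
    overall[[v]] <- list(
      F210 = h210, F171 = h171,
      F210_freeEnergy = boltzmannFreeEnergy(h210, config$temperature),
      F171_freeEnergy = boltzmannFreeEnergy(h171, config$temperature))
  }

  modal <- function(h) h$mids[which.max(h$prob)]
  summary <- list(
    conventions = list(
      gateBoundary = "radius < threshold: closed; radius >= threshold: dilated (equality dilated)",
      rotationSign = "F210 clockwise-from-extracellular positive; 0 = side chain points at pore",
      orientationSign = "F171 counter-clockwise positive; reported as |angle|",
      lengths = "Angstrom internally; RMSD reported in nm",
      windows = sprintf("profile/occupancy window: last %.0f%% of frames; angle window: last %.0f%%",
                        100 * config$windowFraction,
                        100 * config$angleWindowFraction),
      ringAtom = config$ringAtom,
      gateWindowA = config$gateWindow),
    gateThreshold = config$gateThreshold,
    stateCounts = as.list(datasets$sizes),
    excludedFrames = as.list(datasets$excluded),
    variants = lapply(variants, function(v) {
      occ <- res[[v]]$occupancy
      list(name = v, nFrames = nFrames(trajs[[v]]),
           rmsdFinal_nm = mean(utils::tail(res[[v]]$rmsd,
                                           max(1, length(res[[v]]$rmsd) %/% 5))),
           minPoreRadius_A = min(res[[v]]$profile@profile$radius),
           gateRadiusMean_A = mean(res[[v]]$gateRadii),
           waterMean = mean(occ$water$series$count),
           naModal = occ$na$histogram$count[which.max(occ$na$histogram$prob)],
           clModal = occ$cl$histogram$count[which.max(occ$cl$histogram$prob)],
           ringRadiusMean_A = mean(res[[v]]$ringRadii),
           contactMean_A = mean(res[[v]]$contact),
           F210_modal_deg = modal(overall[[v]]$F210),
           F171_modal_deg = modal(overall[[v]]$F171))
    }))
  names(summary$variants) <- variants

  if (!is.null(outDir)) {
    .stage("report output", {
      for (v in variants) {
        utils::write.csv(data.frame(time_ps = trajs[[v]]@time,
                                    rmsd_nm = res[[v]]$rmsd),
                         file.path(outDir, paste0(v, "_rmsd.csv")),
                         row.names = FALSE)
        writeProfileCsv(res[[v]]$profile,
                        file.path(outDir, paste0(v, "_profile.csv")),
                        sphPath = file.path(outDir, paste0(v, "_profile.sph")))
        utils::write.csv(data.frame(frame = seq_along(res[[v]]$gateRadii),
                                    gate_radius_A = res[[v]]$gateRadii,
                                    label = labels[[v]]),
                         file.path(outDir, paste0(v, "_gate.csv")),
                         row.names = FALSE)
        utils::write.csv(angles210[[v]],
                         file.path(outDir, paste0(v, "_angles_F210.csv")),
                         row.names = FALSE)
        utils::write.csv(angles171[[v]],
                         file.path(outDir, paste0(v, "_angles_F171.csv")),
                         row.names = FALSE)
        for (sp in c("water", "na", "cl")) {
          occ <- res[[v]]$occupancy[[sp]]
          utils::write.csv(occ$series,
                           file.path(outDir,
                                     paste0(v, "_occupancy_", sp, ".csv")),
                           row.names = FALSE)
          utils::write.csv(occ$histogram,
                           file.path(outDir,
                                     paste0(v, "_occupancy_", sp,
                                            "_hist.csv")),
                           row.names = FALSE)
        }
        writeOpenDX(res[[v]]$grids$na,
                    file.path(outDir, paste0(v, "_density_na.dx")))
        writeOpenDX(res[[v]]$grids$cl,
                    file.path(outDir, paste0(v, "_density_cl.dx")))
      }
      jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      if (isTRUE(config$writePlots)) .write_plots(res, overall, outDir)
    })
  }

  invisible(list(summary = summary, datasets = datasets, labels = labels,
                 angles = list(F210 = angles210, F171 = angles171),
                 histograms = list(overall = overall, F171_state = hist171,
                                   F210_state = hist210),
                 occupancy = lapply(res, `[[`, "occupancy"),
                 profiles = lapply(res, `[[`, "profile"),
                 rmsd = lapply(res, `[[`, "rmsd")))
}

.write_plots <- function(res, overall, outDir) {
  for (v in names(res)) {
    grDevices::png(file.path(outDir, paste0(v, "_profile.png")),
                   width = 600, height = 480)
    p <- res[[v]]$profile@profile
    graphics::plot(p$radius, p$z, type = "l", xlab = "pore radius (A)",
                   ylab = "z (A)", main = paste(v, "pore profile"))
    grDevices::dev.off()
    grDevices::png(file.path(outDir, paste0(v, "_angles.png")),
                   width = 600, height = 480)
    h <- overall[[v]]$F210
    graphics::plot(h$mids, h$prob, type = "h", xlab = "angle (deg)",
                   ylab = "probability", main = paste(v, "rotation angle"))
    grDevices::dev.off()
  }
}
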