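#' Read and validate a run configuration YAML
#'
#' A run configuration has exactly one of \code{input} (paths to pose
#' HDF5 files) or \code{simulate} (SessionConfig fields, optionally a
#' \code{cohort} block with \code{n_per_group}, \code{days},
#' \code{group_effects}), plus optional \code{arena}, \code{anchors}
#' (\code{head}, \code{body}), \code{ethogram} (\code{k}, \code{seed},
#' \code{method}, embedding fields), \code{stats} (\code{alpha},
#' \code{control}, \code{posthoc}) and \code{out} blocks.
#'
#' @param path YAML file path.
#' @return validated configuration list with an \code{arena}
#'   [ArenaGeometry-class] attached.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  hasInput <- !is.null(cfg$input)
  hasSim <- !is.null(cfg$simulate)
  if (hasInput == hasSim) {
    stop("config must contain exactly one of 'input' or 'simulate'")
  }
  a <- cfg$arena
  cfg$arena <- ArenaGeometry(
    xMinPx = a$x_min_px %||% 0, xMaxPx = a$x_max_px %||% 1219.2,
    yMinPx = a$y_min_px %||% 0, yMaxPx = a$y_max_px %||% 203.2,
    lengthCm = a$length_cm %||% 60.96, widthCm = a$width_cm %||% 10.16,
    nZones = a$n_zones %||% 4L, portZone = a$port_zone %||% 4L)
  cfg$ethogram <- utils::modifyList(
    list(k = 4L, seed = 42L, method = "pca"), cfg$ethogram %||% list())
  cfg$stats <- utils::modifyList(
    list(alpha = 0.05, posthoc = "tukey"), cfg$stats %||% list())
  cfg
}

#' Analyze one session end to end
#'
#' Scores occupancy, computes kinematics and a heat map, runs the
#' ethogram stage, and writes the report bundle: \code{occupancy.csv}
#' (per-second zone), \code{occupancy_summary.csv}, \code{kinematics.csv}
#' (distance per zone), \code{node_speed.csv}, \code{heatmap.csv},
#' \code{labels.csv}, \code{embedding.csv} and \code{ethogram.json}, plus
#' a \code{run.log}. With \code{figures = TRUE} each figure gains a PNG
#' twin of its CSV.
#'
#' @param track a [PoseTrack-class] or path to a pose HDF5 file.
#' @param geometry an [ArenaGeometry-class].
#' @param outDir output directory (created).
#' @param occupancyAnchor,distanceNode anchor overrides; defaults head /
#'   metathorax.
#' @param k,seed ethogram clustering settings.
#' @param embedParams [EmbeddingParams-class] for the 2-D embedding.
#' @param maxGapFrames gap-fill threshold applied before analysis
#'   (default 3 frames).
#' @param figures also render PNG figures (default FALSE).
#' @return invisibly, a list with the occupancy, kinematics, heat map and
#'   ethogram objects.
#' @export
analyzeSession <- function(track, geometry = ArenaGeometry(), outDir,
                           occupancyAnchor = NULL, distanceNode = NULL,
                           k = 4L, seed = 42L,
                           embedParams = EmbeddingParams(),
                           maxGapFrames = 3L, figures = FALSE) {
  if (is.character(track)) track <- readPoseH5(track)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(outDir, "run.log")
  logLine <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    message(msg)
    cat(msg, "\n", file = logFile, append = TRUE)
  }
  logLine("session ", videoID(track), ": ", nFrames(track), " frames at ",
    framesPerSecond(track), " fps")
  track <- fillMissing(track, maxGapFrames)
  sk <- skeleton(track)
  occAnchor <- occupancyAnchor %||% anchorHead(sk)
  distNode <- distanceNode %||% anchorBody(sk)

  occ <- scoreOccupancy(track, geometry, anchor = occAnchor)
  kin <- computeKinematics(track, geometry, distanceNode = distNode)
  hm <- occupancyHeatmap(track, geometry, node = distNode)
  eth <- runEthogram(track, geometry, k = k, seed = seed,
    params = embedParams)

  utils::write.csv(data.frame(second = seq_along(perSecond(occ)) - 1L,
    zone = perSecond(occ)), file.path(outDir, "occupancy.csv"),
    row.names = FALSE, na = "")
  utils::write.csv(data.frame(zone = names(secondsPerZone(occ)),
    seconds = unname(secondsPerZone(occ))),
    file.path(outDir, "occupancy_summary.csv"), row.names = FALSE)
  utils::write.csv(data.frame(zone = names(distancePerZone(kin)),
    distance_cm = unname(distancePerZone(kin))),
    file.path(outDir, "kinematics.csv"), row.names = FALSE)
  utils::write.csv(data.frame(node = names(kin@meanSpeedPerNode),
    mean_speed_cm_s = unname(kin@meanSpeedPerNode)),
    file.path(outDir, "node_speed.csv"), row.names = FALSE)
  utils::write.table(hm, file.path(outDir, "heatmap.csv"), sep = ",",
    row.names = FALSE, col.names = FALSE)
  lbl <- data.frame(frame = eth@frames, label = frameLabels(eth))
  if (length(semanticMap(eth))) {
    lbl$behavior <- unname(semanticMap(eth)[as.character(lbl$label)])
  }
  utils::write.csv(lbl, file.path(outDir, "labels.csv"), row.names = FALSE)
  emb <- embeddingCoords(eth)
  if (nrow(emb)) {
    utils::write.csv(data.frame(frame = eth@frames, emb),
      file.path(outDir, "embedding.csv"), row.names = FALSE)
  }
  jsonlite::write_json(list(
    video_id = videoID(track), k = eth@k, seed = eth@seed,
    semantic_map = as.list(semanticMap(eth)),
    time_per_behavior_s = as.list(timePerBehavior(eth)),
    seconds_per_zone = as.list(secondsPerZone(occ)),
    total_distance_cm = totalDistanceCm(kin),
    mean_speed_cm_s = kin@meanSpeedOverall,
    tie = eth@tie,
    bouts = bouts(eth)),
    file.path(outDir, "ethogram.json"), auto_unbox = TRUE, digits = NA)
  if (figures) renderSessionFigures(track, geometry, occ, kin, hm, eth, outDir)
  logLine("bundle written to ", outDir)
  invisible(list(occupancy = occ, kinematics = kin, heatmap = hm,
    ethogram = eth))
}

renderSessionFigures <- function(track, geometry, occ, kin, hm, eth, outDir) {
  j <- match(anchorBody(skeleton(track)), nodeNames(track))
  xy <- data.frame(x = track@coords[, j, 1], y = track@coords[, j, 2])
  xy$zone <- factor(assignZone(xy$x, geometry))
  sp <- c(NA, rowMeans(nodeSpeed(kin), na.rm = TRUE))
  xy$speed <- sp
  gg <- ggplot2::ggplot(xy[!is.na(xy$x), ],
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$zone)) +
    ggplot2::geom_path(linewidth = 0.3) + ggplot2::scale_y_reverse() +
    ggplot2::labs(title = "Body-anchor track by quadrant", x = "x (px)",
      y = "y (px)")
  ggplot2::ggsave(file.path(outDir, "track_zones.png"), gg,
    width = 8, height = 3, dpi = 120)
  gg <- ggplot2::ggplot(xy[!is.na(xy$x) & !is.na(xy$speed), ],
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$speed)) +
    ggplot2::geom_path(linewidth = 0.3) + ggplot2::scale_y_reverse() +
    ggplot2::scale_colour_viridis_c(name = "cm/s") +
    ggplot2::labs(title = "Velocity-coloured track", x = "x (px)", y = "y (px)")
  ggplot2::ggsave(file.path(outDir, "velocity_track.png"), gg,
    width = 8, height = 3, dpi = 120)
  hdf <- data.frame(count = as.vector(hm),
    yb = rep(seq_len(nrow(hm)), ncol(hm)),
    xb = rep(seq_len(ncol(hm)), each = nrow(hm)))
  gg <- ggplot2::ggplot(hdf, ggplot2::aes(x = .data$xb, y = .data$yb,
      fill = .data$count)) +
    ggplot2::geom_tile() + ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::labs(title = "Occupancy heat map", x = "x bin", y = "y bin")
  ggplot2::ggsave(file.path(outDir, "heatmap.png"), gg,
    width = 8, height = 2.5, dpi = 120)
  emb <- embeddingCoords(eth)
  if (nrow(emb)) {
    ed <- data.frame(emb, label = factor(frameLabels(eth)))
    if (length(semanticMap(eth))) {
      ed$label <- factor(unname(semanticMap(eth)[as.character(frameLabels(eth))]))
    }
    gg <- ggplot2::ggplot(ed, ggplot2::aes(x = .data$dim1, y = .data$dim2,
        colour = .data$label)) +
      ggplot2::geom_point(size = 0.4, alpha = 0.6) +
      ggplot2::labs(title = "Behavior cluster embedding")
    ggplot2::ggsave(file.path(outDir, "embedding.png"), gg,
      width = 5, height = 4, dpi = 120)
  }
  tb <- data.frame(behavior = names(timePerBehavior(eth)),
    seconds = unname(timePerBehavior(eth)))
  gg <- ggplot2::ggplot(tb, ggplot2::aes(x = "session", y = .data$seconds,
      fill = .data$behavior)) +
    ggplot2::geom_col() +
    ggplot2::labs(title = "Time per behavior", x = NULL, y = "seconds")
  ggplot2::ggsave(file.path(outDir, "behavior_bars.png"), gg,
    width = 3, height = 4, dpi = 120)
  invisible(NULL)
}

#' Analyze a cohort and run the gated group comparisons
#'
#' Aggregates per-session occupancy, distance and speed to per-animal
#' means (across days), then emits assumption-gated comparison reports
#' for: time per quadrant between groups (one family per quadrant), time
#' per quadrant within each group (one family per group), distance per
#' quadrant between groups, and overall node speed between groups. When
#' ethograms are requested, time per behavior is compared within each
#' group. Each family is BH-adjusted on its own, matching per-panel
#' reporting.
#'
#' @param datasets list of [SyntheticDataset-class] (with manifest
#'   attribute, as from [generateCohort()]) or the path of a cohort
#'   manifest CSV written by [writeCohort()].
#' @param geometry an [ArenaGeometry-class].
#' @param outDir optional output directory for
#'   \code{session_metrics.csv}, \code{comparisons.csv} and
#'   \code{comparisons.json}.
#' @param groups optional expected group labels; a manifest group outside
#'   this set is an error naming the label.
#' @param alpha gate level (default 0.05).
#' @param posthoc,control parametric post hoc settings, see
#'   [gatedCompare()].
#' @param doEthogram also run the ethogram stage per session (default
#'   FALSE; clustering every session is the slow part).
#' @param handScores optional hand-scored (session x zone) seconds matrix;
#'   adds an [agreement()] report against the machine scores.
#' @param k,seed ethogram settings when \code{doEthogram} is TRUE.
#' @return invisibly, a list with \code{metrics} (per-session data.frame),
#'   \code{comparisons} (named list of [ComparisonReport-class]),
#'   \code{pairwise} (tidy data.frame over all families) and optionally
#'   \code{agreement}.
#' @export
analyzeCohort <- function(datasets, geometry = ArenaGeometry(),
                          outDir = NULL, groups = NULL, alpha = 0.05,
                          posthoc = "tukey", control = NULL,
                          doEthogram = FALSE, handScores = NULL,
                          k = 4L, seed = 42L) {
  if (is.character(datasets)) datasets <- readCohortManifest(datasets)
  man <- attr(datasets, "manifest")
  if (is.null(man)) stop("datasets must carry a cohort manifest")
  if (!is.null(groups)) {
    bad <- setdiff(unique(man$group), groups)
    if (length(bad)) stop("unknown group label in manifest: ",
      paste(bad, collapse = ", "))
  }
  if (length(unique(man$group)) < 2L) {
    stop("cohort comparisons need at least 2 groups")
  }
  nz <- geometry@nZones
  rows <- vector("list", length(datasets))
  occList <- vector("list", length(datasets))
  for (i in seq_along(datasets)) {
    tr <- poseTrack(datasets[[i]])
    occ <- scoreOccupancy(tr, geometry)
    kin <- computeKinematics(tr, geometry)
    r <- data.frame(id = man$id[i], group = man$group[i],
      animal = man$animal[i], day = man$day[i])
    spz <- secondsPerZone(occ); dpz <- distancePerZone(kin)
    for (z in seq_len(nz)) {
      r[[paste0("time_Q", z)]] <- spz[z]
      r[[paste0("dist_Q", z)]] <- dpz[z]
    }
    r$mean_speed <- kin@meanSpeedOverall
    if (doEthogram) {
      eth <- runEthogram(tr, geometry, k = k, seed = seed, embed = FALSE)
      tpb <- timePerBehavior(eth)
      for (b in names(tpb)) r[[paste0("beh_", b)]] <- tpb[b]
    }
    rows[[i]] <- r
    occList[[i]] <- occ
  }
  metrics <- do.call(rbind, rows)
  names(occList) <- man$id

  perAnimal <- stats::aggregate(
    metrics[, setdiff(names(metrics), c("id", "group", "animal", "day"))],
    by = list(group = metrics$group, animal = metrics$animal), FUN = mean)

  comparisons <- list()
  addCmp <- function(name, df) {
    comparisons[[name]] <<- tryCatch(
      gatedCompare(df, alpha = alpha, posthoc = posthoc, control = control),
      error = function(e) e)
  }
  for (z in seq_len(nz)) {
    addCmp(sprintf("time_Q%d_between_groups", z),
      data.frame(group = perAnimal$group, value = perAnimal[[paste0("time_Q", z)]]))
    addCmp(sprintf("dist_Q%d_between_groups", z),
      data.frame(group = perAnimal$group, value = perAnimal[[paste0("dist_Q", z)]]))
  }
  for (g in unique(perAnimal$group)) {
    sub <- perAnimal[perAnimal$group == g, ]
    long <- data.frame(
      group = rep(paste0("Q", seq_len(nz)), each = nrow(sub)),
      value = unlist(sub[paste0("time_Q", seq_len(nz))], use.names = FALSE))
    addCmp(sprintf("time_within_%s", g), long)
    if (doEthogram) {
      bcols <- grep("^beh_", names(sub), value = TRUE)
      if (length(bcols) >= 2) {
        addCmp(sprintf("behavior_within_%s", g), data.frame(
          group = rep(sub("^beh_", "", bcols), each = nrow(sub)),
          value = unlist(sub[bcols], use.names = FALSE)))
      }
    }
  }
  addCmp("speed_between_groups",
    data.frame(group = perAnimal$group, value = perAnimal$mean_speed))

  tidy <- do.call(rbind, lapply(names(comparisons), function(nm) {
    cr <- comparisons[[nm]]
    if (inherits(cr, "error")) return(NULL)
    cbind(family = nm, branch = cr@branch,
      omnibus_p = cr@omnibus$p.value, cr@pairwise)
  }))

  agr <- NULL
  if (!is.null(handScores)) {
    mach <- occupancyTable(occList)[rownames(handScores), , drop = FALSE]
    colnames(mach) <- colnames(handScores)
    agr <- agreement(handScores, mach,
      durationS = durationS(occList[[1]]))
  }

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(metrics, file.path(outDir, "session_metrics.csv"),
      row.names = FALSE)
    if (!is.null(tidy)) {
      utils::write.csv(tidy, file.path(outDir, "comparisons.csv"),
        row.names = FALSE)
      jsonlite::write_json(tidy, file.path(outDir, "comparisons.json"),
        auto_unbox = TRUE, digits = NA)
    }
    if (!is.null(agr)) {
      utils::write.csv(agr@cells, file.path(outDir, "agreement.csv"),
        row.names = FALSE)
    }
  }
  invisible(list(metrics = metrics, perAnimal = perAnimal,
    comparisons = comparisons, pairwise = tidy, agreement = agr))
}

readCohortManifest <- function(path) {
  man <- utils::read.csv(path)
  req <- c("id", "group", "animal", "day", "track_path", "truth_path")
  if (!all(req %in% names(man))) {
    stop("manifest must have columns: ", paste(req, collapse = ", "))
  }
  base <- dirname(path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, basename(p)))
  out <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    tr <- readPoseH5(resolve(man$track_path[i]))
    truth <- jsonlite::read_json(resolve(man$truth_path[i]),
      simplifyVector = TRUE)
    out[[i]] <- new("SyntheticDataset", track = tr,
      truthOccupancy = as.integer(truth$truth_occupancy),
      truthStates = as.character(truth$truth_states),
      group = truth$group, config = SessionConfig())
  }
  attr(out, "manifest") <- man[, c("id", "group", "animal", "day", "seed")]
  out
}
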