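setMethod("show", "SkeletonDef", function(object) {
  cat("SkeletonDef with", length(object@nodeNames), "nodes\n")
  cat("  head anchor:", object@anchorHead,
    "| body anchor:", object@anchorBody, "\n")
  cat("  sides:", sum(object@limbSides == "left"), "left,",
    sum(object@limbSides == "right"), "right,",
    sum(object@limbSides == "midline"), "midline\n")
})

setMethod("show", "PoseTrack", function(object) {
  d <- dim(object@coords)
  miss <- mean(is.na(object@coords[, , 1]))
  cat("PoseTrack '", object@videoID, "': ", d[1], " frames x ", d[2],
    " nodes @ ", object@fps, " fps (",
    sprintf("%.1f%%", 100 * miss), " missing)\n", sep = "")
})

setMethod("show", "ArenaGeometry", function(object) {
  cat("ArenaGeometry: ", object@lengthCm, " x ", object@widthCm, " cm, ",
    object@nZones, " zones, port in zone ", object@portZone, "\n", sep = "")
  cat("  calibration:", sprintf("%.2f px/cm", pixelsPerCm(object)), "\n")
})

setMethod("show", "ZoneOccupancySeries", function(object) {
  cat("ZoneOccupancySeries over", object@durationS, "s\n")
  print(object@secondsPerZone)
  nm <- sum(is.na(object@perSecond))
  if (nm) cat("  unscorable seconds:", nm, "\n")
})

setMethod("show", "KinematicsResult", function(object) {
  cat("KinematicsResult (distance node: ", object@distanceNode, ")\n",
    sep = "")
  cat("  total distance:", sprintf("%.1f cm", object@totalDistanceCm),
    "| mean speed:", sprintf("%.2f cm/s", object@meanSpeedOverall), "\n")
  print(round(object@distancePerZone, 1))
})

setMethod("show", "FeatureMatrix", function(object) {
  cat("FeatureMatrix:", nrow(object@mat), "frames x", ncol(object@mat),
    "features (z-scored)\n")
})

setMethod("show", "EthogramResult", function(object) {
  cat("EthogramResult: k =", object@k, "over", length(object@labels),
    "frames,", nrow(object@bouts), "bouts\n")
  if (length(object@semanticMap)) {
    print(round(object@timePerBehavior, 1))
    if (object@tie) cat("  note: semantic tie broken by cluster id\n")
  }
})

setMethod("show", "SyntheticDataset", function(object) {
  cat("SyntheticDataset (group ", object@group, ")\n", sep = "")
  show(object@track)
  cat("  truth states:", paste(names(table(object@truthStates)),
    table(object@truthStates), collapse = ", "), "\n")
})

setMethod("show", "ComparisonReport", function(object) {
  cat("ComparisonReport:", object@branch, "branch (",
    object@omnibus$method, ")\n")
  cat("  omnibus p =", format.pval(object@omnibus$p.value, digits = 3), "\n")
  print(object@pairwise)
})

setMethod("show", "AgreementReport", function(object) {
  cat("AgreementReport over", nrow(object@cells), "cells\n")
  cat("  mean |error|:", sprintf("%.2f%%", object@meanAbsErrorPct),
    "of", object@durationS, "s | paired t p =",
    format.pval(object@pairedT$p.value, digits = 3), "\n")
})
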