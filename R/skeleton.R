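#' Default 27-node cockroach skeleton
#'
#' The node set used for pose tracking of \emph{Gromphadorhina portentosa}:
#' head, antenna base/midpoint/tip, palp base/tip, prothorax, metathorax,
#' abdomen, anus, and fore/mid/hind leg joint and tip, with bilateral parts
#' split into left and right nodes (27 nodes total). The head is the
#' occupancy anchor; the metathorax is the body anchor for distance and
#' velocity.
#'
#' @return a [SkeletonDef-class] with 27 nodes.
#' @examples
#' sk <- cockroachSkeleton()
#' length(nodeNames(sk))  # 27
#' @export
cockroachSkeleton <- function() {
  midline <- c("head", "prothorax", "metathorax", "abdomen", "anus")
  sided <- c("antenna_base", "antenna_mid", "antenna_tip",
             "palp_base", "palp_tip",
             "fore_leg_joint", "fore_leg_tip",
             "mid_leg_joint", "mid_leg_tip",
             "hind_leg_joint", "hind_leg_tip")
  nodes <- c("head",
             paste0("l_", sided[1:5]), paste0("r_", sided[1:5]),
             "prothorax", "metathorax", "abdomen", "anus",
             paste0("l_", sided[6:11]), paste0("r_", sided[6:11]))
  sides <- ifelse(nodes %in% midline, "midline",
    ifelse(startsWith(nodes, "l_"), "left", "right"))
  names(sides) <- nodes
  new("SkeletonDef", nodeNames = nodes, anchorHead = "head",
    anchorBody = "metathorax", limbSides = sides)
}

#' Leg nodes of a skeleton, by side
#'
#' Nodes whose name marks them as legs and whose side matches. Used by the
#' semantic labeling heuristic and the limb oscillation of the simulator.
#'
#' @param skeleton a [SkeletonDef-class].
#' @param side \code{"left"} or \code{"right"}.
#' @return character vector of node names.
#' @export
legNodes <- function(skeleton, side = c("left", "right")) {
  side <- match.arg(side)
  nn <- skeleton@nodeNames
  nn[grepl("leg", nn) & skeleton@limbSides[nn] == side]
}

# Body-template offsets (cm) of each node relative to the metathorax,
# body axis along +x (toward the head). Rough adult G. portentosa scale:
# ~6 cm body, antennae projecting forward, legs splayed +-1.2 cm laterally.
skeletonTemplate <- function(skeleton) {
  base <- list(
    head = c(2.6, 0), prothorax = c(1.6, 0), metathorax = c(0, 0),
    abdomen = c(-1.6, 0), anus = c(-3.0, 0),
    antenna_base = c(3.0, 0.3), antenna_mid = c(4.2, 0.9),
    antenna_tip = c(5.4, 1.6),
    palp_base = c(2.9, 0.15), palp_tip = c(3.3, 0.35),
    fore_leg_joint = c(1.8, 0.8), fore_leg_tip = c(2.3, 1.3),
    mid_leg_joint = c(0.4, 0.9), mid_leg_tip = c(0.4, 1.5),
    hind_leg_joint = c(-1.2, 0.9), hind_leg_tip = c(-1.8, 1.6)
  )
  nn <- skeleton@nodeNames
  off <- matrix(0, length(nn), 2, dimnames = list(nn, c("x", "y")))
  for (i in seq_along(nn)) {
    name <- nn[i]
    stem <- sub("^[lr]_", "", name)
    side <- skeleton@limbSides[[name]]
    o <- base[[stem]]
    if (is.null(o)) o <- c(0, 0)  # unknown nodes sit on the centroid
    if (side == "right") o[2] <- -o[2]
    off[i, ] <- o
  }
  off
}
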