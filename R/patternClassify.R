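# Classification of a final activator field into root-type patterns.

#' Binarize an activator field
#'
#' Cells are labelled HIGH when `u` exceeds the midrange
#' `(min(u) + max(u)) / 2`. When the range of `u` is below 5% of the
#' homogeneous equilibrium `u0` the field is declared homogeneous. The
#' midrange threshold makes the labels invariant under affine rescaling
#' of `u`.
#'
#' @param state an [RDState-class]
#' @param network the matching [CellNetwork-class]
#' @param params an [RDParams-class] (supplies `u0` for the homogeneity guard)
#' @return logical vector (`TRUE` = HIGH) with attribute `homogeneous`
#' @export
binarizeActivator <- function(state, network, params) {
  u <- state@u
  if (length(u) != nCells(network)) stop("state not aligned to network")
  if (length(u) == 0) stop("empty state")
  u0 <- equilibriumState(params)$u0
  rng <- max(u) - min(u)
  if (rng < 0.05 * u0) {
    return(structure(rep(FALSE, length(u)), homogeneous = TRUE))
  }
  thr <- (min(u) + max(u)) / 2
  structure(u > thr, homogeneous = FALSE)
}

#' Connected minority-phase regions
#'
#' The minority phase is whichever label (HIGH or LOW) occupies less than
#' half of the total cell area; an exact 50/50 split is broken toward HIGH.
#' Regions are connected components of the minority cells over the
#' wall-sharing adjacency graph. Polarity is `"spotted"` when the minority
#' phase is HIGH, `"reverse_spotted"` when LOW.
#'
#' @param network a [CellNetwork-class]
#' @param labels logical HIGH labels as from [binarizeActivator()]
#' @return list with `polarity`, `minority` (logical per-cell membership) and
#'   `components` (list of integer cell-id vectors, one per region)
#' @export
activatorRegions <- function(network, labels) {
  if (length(labels) != nCells(network)) stop("labels not aligned to network")
  areas <- cellAreas(network)
  highArea <- sum(areas[labels])
  minorityHigh <- highArea <= sum(areas) / 2   # ties broken to HIGH minority
  minority <- if (minorityHigh) labels else !labels
  polarity <- if (minorityHigh) "spotted" else "reverse_spotted"
  ids <- which(minority)
  if (length(ids) == 0)
    return(list(polarity = polarity, minority = minority, components = list()))
  w <- network@walls
  inner <- !is.na(w$c2)
  keep <- inner & w$c1 %in% ids & w$c2 %in% ids
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(w$c1[keep]), to = as.character(w$c2[keep])),
    directed = FALSE,
    vertices = data.frame(name = as.character(ids)))
  comp <- igraph::components(g)
  members <- split(as.integer(igraph::V(g)$name), comp$membership)
  names(members) <- NULL
  list(polarity = polarity, minority = minority,
       components = lapply(members, sort))
}

# Perimeter of a set of cells: total length of walls with exactly one side
# in the set (boundary walls of member cells included).
.regionPerimeter <- function(network, members) {
  w <- network@walls
  inA <- w$c1 %in% members
  inB <- !is.na(w$c2) & w$c2 %in% members
  sel <- xor(inA, inB) | (inA & is.na(w$c2))
  if (!any(sel)) return(0)
  dx <- network@pos[w$v2[sel], 1] - network@pos[w$v1[sel], 1]
  dy <- network@pos[w$v2[sel], 2] - network@pos[w$v1[sel], 2]
  sum(sqrt(dx^2 + dy^2))
}

# Angular extent of member-cell centroids around the network centroid:
# 2*pi minus the largest circular gap between successive angles.
.angularExtent <- function(network, members) {
  cen <- cellCentroids(network)
  areas <- cellAreas(network)
  netC <- colSums(cen * areas) / sum(areas)
  ang <- sort(atan2(cen[members, 2] - netC[2], cen[members, 1] - netC[1]))
  if (length(ang) == 1) return(0)
  gaps <- diff(c(ang, ang[1] + 2 * pi))
  2 * pi - max(gaps)
}

#' Classify an activator pattern into a root-type label
#'
#' Computes per-region metrics (area fraction, perimeter, circularity
#' `4*pi*A/P^2`, centroid, angular extent around the network centroid) for
#' the minority-phase regions and derives the label: `"1"`..`"4"` when 1-4
#' regions are all compact (circularity >= `circularityMin`), `"C"` when a
#' single elongated region (circularity < `circularityMin`) spans at least
#' `arcExtentMin` radians, otherwise `"other"`. A homogeneous field has 0
#' regions and label `"other"`.
#'
#' @param network a [CellNetwork-class]
#' @param state the matching [RDState-class]
#' @param params an [RDParams-class]
#' @param circularityMin compactness threshold (default 0.4)
#' @param arcExtentMin angular-extent threshold for the C label, radians
#'   (default `2*pi/3`, i.e. 120 degrees)
#' @return a [PatternSummary-class]
#' @export
classifyPattern <- function(network, state, params,
                            circularityMin = 0.4, arcExtentMin = 2 * pi / 3) {
  labels <- binarizeActivator(state, network, params)
  emptyMetrics <- data.frame(area = numeric(), areaFraction = numeric(),
                             perimeter = numeric(), circularity = numeric(),
                             centroidX = numeric(), centroidY = numeric(),
                             angularExtent = numeric())
  if (attr(labels, "homogeneous")) {
    return(new("PatternSummary", polarity = NA_character_, nRegions = 0L,
               rootLabel = "other", regionMetrics = emptyMetrics,
               homogeneous = TRUE))
  }
  reg <- activatorRegions(network, as.logical(labels))
  comps <- reg$components
  if (length(comps) == 0) {
    return(new("PatternSummary", polarity = reg$polarity, nRegions = 0L,
               rootLabel = "other", regionMetrics = emptyMetrics,
               homogeneous = FALSE))
  }
  areas <- cellAreas(network)
  cen <- cellCentroids(network)
  total <- sum(areas)
  metrics <- do.call(rbind, lapply(comps, function(members) {
    A <- sum(areas[members])
    P <- .regionPerimeter(network, members)
    data.frame(area = A, areaFraction = A / total, perimeter = P,
               circularity = 4 * pi * A / P^2,
               centroidX = sum(cen[members, 1] * areas[members]) / A,
               centroidY = sum(cen[members, 2] * areas[members]) / A,
               angularExtent = .angularExtent(network, members))
  }))
  k <- length(comps)
  label <- "other"
  if (k >= 1 && k <= 4 && all(metrics$circularity >= circularityMin)) {
    label <- as.character(k)
  } else if (k == 1 && metrics$circularity[1] < circularityMin &&
             metrics$angularExtent[1] >= arcExtentMin) {
    label <- "C"
  }
  new("PatternSummary", polarity = reg$polarity, nRegions = as.integer(k),
      rootLabel = label, regionMetrics = metrics, homogeneous = FALSE)
}

setMethod("show", "PatternSummary", function(object) {
  if (object@homogeneous) {
    cat("PatternSummary: homogeneous field (0 regions, label other)\n")
  } else {
    cat(sprintf("PatternSummary: %s, %d region(s), root label %s\n",
                object@polarity, object@nRegions, object@rootLabel))
    if (nrow(object@regionMetrics))
      print(round(object@regionMetrics[, c("areaFraction", "circularity",
                                           "angularExtent")], 3))
  }
})
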