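# JSON round-trip and SVG snapshots of cell networks.

#' Write a network to JSON
#'
#' Schema: `{vertices: [{id,x,y}], walls: [{id,v1,v2,cells:[..]}],
#' cells: [{id,walls:[..]}]}` with cells listing their ordered wall cycle.
#' Round-trip stable with [readNetworkJSON()].
#'
#' @param network a [CellNetwork-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeNetworkJSON <- function(network, path) {
  w <- network@walls
  wallId <- function(a, b) which(w$v1 == pmin(a, b) & w$v2 == pmax(a, b))
  cells <- lapply(seq_along(network@cells), function(i) {
    cyc <- network@cells[[i]]
    nxt <- c(cyc[-1], cyc[1])
    list(id = i, walls = vapply(seq_along(cyc),
                                function(k) wallId(cyc[k], nxt[k]), integer(1)))
  })
  doc <- list(
    vertices = lapply(seq_len(nVertices(network)), function(i)
      list(id = i, x = network@pos[i, 1], y = network@pos[i, 2])),
    walls = lapply(seq_len(nrow(w)), function(j)
      list(id = j, v1 = w$v1[j], v2 = w$v2[j],
           cells = as.integer(c(w$c1[j], w$c2[j])[!is.na(c(w$c1[j], w$c2[j]))]))),
    cells = cells)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a network written by [writeNetworkJSON()]
#'
#' Vertex cycles are reconstructed by chaining each cell's wall cycle.
#'
#' @param path JSON file
#' @return a [CellNetwork-class]
#' @export
readNetworkJSON <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  vt <- doc$vertices[order(doc$vertices$id), ]
  pos <- cbind(vt$x, vt$y)
  wt <- doc$walls[order(doc$walls$id), ]
  cellsRaw <- doc$cells[order(doc$cells$id), ]
  cells <- lapply(cellsRaw$walls, function(wids) {
    wids <- as.integer(wids)
    ends <- cbind(wt$v1[wids], wt$v2[wids])
    n <- length(wids)
    cyc <- integer(n)
    # start so that the first vertex is shared with the last wall
    cyc[1] <- if (ends[1, 1] %in% ends[n, ]) ends[1, 1] else ends[1, 2]
    for (k in seq_len(n - 1)) {
      cur <- ends[k, ]
      cyc[k + 1] <- cur[cur != cyc[k]][1]
    }
    cyc
  })
  .newNetwork(pos, cells)
}

#' Write an SVG snapshot of a network
#'
#' Cells are filled by a scalar per-cell field (e.g. activator
#' concentration), dark blue at the maximum, white at the minimum.
#'
#' @param network a [CellNetwork-class]
#' @param path output file
#' @param values optional numeric per-cell field; constant grey if `NULL`
#' @param width canvas width in pixels
#' @return `path`, invisibly
#' @export
writeNetworkSVG <- function(network, path, values = NULL, width = 600) {
  pos <- network@pos
  rng <- apply(pos, 2, range)
  span <- max(rng[2, ] - rng[1, ])
  sc <- (width * 0.9) / span
  tx <- function(x) (x - rng[1, 1]) * sc + width * 0.05
  ty <- function(y) width - ((y - rng[1, 2]) * sc + width * 0.05)
  if (is.null(values)) {
    fills <- rep("#cccccc", nCells(network))
  } else {
    z <- (values - min(values)) / max(max(values) - min(values), 1e-12)
    fills <- grDevices::rgb(1 - z, 1 - z, 1, maxColorValue = 1)
  }
  lines <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
    width, width))
  for (i in seq_along(network@cells)) {
    cyc <- network@cells[[i]]
    ptstr <- paste(sprintf("%.2f,%.2f", tx(pos[cyc, 1]), ty(pos[cyc, 2])),
                   collapse = " ")
    lines <- c(lines, sprintf(
      '<polygon points="%s" fill="%s" stroke="black" stroke-width="0.6"/>',
      ptstr, fills[i]))
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, path)
  invisible(path)
}
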