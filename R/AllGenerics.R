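#' @name RootRD-generics
#' @title Generics for cell-network and pattern objects
#' @param object,network an object (typically a [CellNetwork-class])
#' @param ... passed to methods
NULL

#' Number of cells in a network
#' @param object a [CellNetwork-class]
#' @return integer count
#' @export
setGeneric("nCells", function(object) standardGeneric("nCells"))

#' Number of vertices in a network
#' @param object a [CellNetwork-class]
#' @return integer count
#' @export
setGeneric("nVertices", function(object) standardGeneric("nVertices"))

#' Number of walls in a network
#' @param object a [CellNetwork-class]
#' @return integer count
#' @export
setGeneric("nWalls", function(object) standardGeneric("nWalls"))

#' Area of one cell
#' @param network a [CellNetwork-class]
#' @param cellId integer cell id
#' @return positive shoelace area of the cell polygon
#' @export
setGeneric("cellArea", function(network, cellId) standardGeneric("cellArea"))

#' Id of the largest cell (ties broken by smallest id)
#' @param network a [CellNetwork-class]
#' @return integer cell id
#' @export
setGeneric("largestCell", function(network) standardGeneric("largestCell"))

#' Cells sharing at least one wall with the given cell
#' @param network a [CellNetwork-class]
#' @param cellId integer cell id
#' @return sorted integer vector of neighbouring cell ids
#' @export
setGeneric("cellNeighbors", function(network, cellId) standardGeneric("cellNeighbors"))

#' Is a cell on the network boundary?
#'
#' A cell is marginal when at least one of its walls has no cell on the
#' other side. Marginal cells receive the extra activator decay `alphaM`.
#'
#' @param network a [CellNetwork-class]
#' @param cellId integer cell id
#' @return logical
#' @export
setGeneric("isMarginal", function(network, cellId) standardGeneric("isMarginal"))
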