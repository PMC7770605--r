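#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' RegionOntology: an atlas region tree with volumes and flags
#'
#' Holds the hierarchical region ontology of a reference atlas (for example
#' the Allen CCFv3-2017 mouse hierarchy or the Waxholm Space rat hierarchy)
#' as a node table. Edges are implied by \code{parent_id}; the single node
#' with a missing parent is the root. Leaves are the only identifiers that
#' may occur in atlas label images. \code{volume_mm3} is the bilateral
#' region volume taken from the 3D reference atlas and is the denominator
#' of all density estimates.
#'
#' @slot nodes data.frame with columns \code{id}, \code{acronym},
#'   \code{name}, \code{parent_id} (NA for the root), \code{r}, \code{g},
#'   \code{b}, \code{volume_mm3}, \code{oversaturated}.
#' @seealso [loadOntology()], [leafIds()], [resolveGrouping()]
#' @export
setClass("RegionOntology", representation(nodes = "data.frame"))

setValidity("RegionOntology", function(object) {
  nd <- object@nodes
  req <- c("id", "acronym", "name", "parent_id", "r", "g", "b",
           "volume_mm3", "oversaturated")
  miss <- setdiff(req, names(nd))
  if (length(miss) > 0)
    return(sprintf("missing ontology columns: %s", paste(miss, collapse = ", ")))
  if (anyDuplicated(nd$id))
    return(sprintf("duplicate region id(s): %s",
                   paste(unique(nd$id[duplicated(nd$id)]), collapse = ", ")))
  if (any(nd$volume_mm3 < 0, na.rm = TRUE))
    return(sprintf("negative volume for id(s): %s",
                   paste(nd$id[!is.na(nd$volume_mm3) & nd$volume_mm3 < 0],
                         collapse = ", ")))
  roots <- nd$id[is.na(nd$parent_id)]
  if (length(roots) != 1)
    return(sprintf("ontology must have exactly one root, found %d (%s)",
                   length(roots), paste(roots, collapse = ", ")))
  bad <- setdiff(nd$parent_id[!is.na(nd$parent_id)], nd$id)
  if (length(bad) > 0)
    return(sprintf("parent id(s) not present in table: %s",
                   paste(bad, collapse = ", ")))
  cyc <- .findCycle(nd$id, nd$parent_id)
  if (!is.null(cyc))
    return(sprintf("cycle in parent links involving id(s): %s",
                   paste(sort(cyc), collapse = ", ")))
  cols <- paste(nd$r, nd$g, nd$b)
  if (anyDuplicated(cols))
    return(sprintf("non-unique color for id(s): %s",
                   paste(nd$id[cols %in% cols[duplicated(cols)]], collapse = ", ")))
  if (any(nd$r < 0 | nd$r > 255 | nd$g < 0 | nd$g > 255 | nd$b < 0 | nd$b > 255))
    return("color channels must be within 0-255")
  TRUE
})

# follow parent chains; return ids on a cycle, or NULL if the graph is a tree
.findCycle <- function(ids, parents) {
  parent <- stats::setNames(parents, ids)
  state <- stats::setNames(integer(length(ids)), ids)  # 0 new, 1 active, 2 done
  for (start in as.character(ids)) {
    if (state[start] != 0L) next
    chain <- character(0)
    node <- start
    while (!is.na(node) && state[node] == 0L) {
      state[node] <- 1L
      chain <- c(chain, node)
      node <- as.character(parent[node])
      if (!is.na(node) && !node %in% names(state)) node <- NA
    }
    if (!is.na(node) && state[node] == 1L) {
      i <- match(node, chain)
      return(as(chain[i:length(chain)], class(ids)))
    }
    state[chain] <- 2L
  }
  NULL
}

#' AtlasSection: one registered atlas label map
#'
#' A single 2D section of the registered atlas: an integer label image whose
#' pixel values are leaf region ids of a bound [RegionOntology] (0 means
#' outside the atlas), plus the physical metadata needed for quantification.
#' Pixels are square; the matrix is indexed \code{[row, col]} with origin at
#' the top-left, 1-based as usual in R.
#'
#' @slot labels integer matrix of region ids (0 = outside atlas).
#' @slot sectionIndex integer position of the section in the series.
#' @slot pixelSize pixel edge length in micrometers.
#' @slot thickness section thickness T in micrometers.
#' @slot axisCoord dorsoventral (bregma-like) coordinate in mm, used to
#'   order sections for gradient profiling; decreases dorsal to ventral.
#' @slot hemisphere optional integer matrix of the same shape
#'   (0 = none, 1 = left, 2 = right), or NULL.
#' @export
setClass("AtlasSection", representation(
  labels = "matrix",
  sectionIndex = "integer",
  pixelSize = "numeric",
  thickness = "numeric",
  axisCoord = "numeric",
  hemisphere = "matrixOrNULL"
))

setValidity("AtlasSection", function(object) {
  if (!is.numeric(object@labels)) return("labels must be numeric/integer")
  if (any(object@labels < 0)) return("labels must be non-negative")
  if (length(object@pixelSize) != 1 || object@pixelSize <= 0)
    return("pixelSize must be a positive scalar (micrometers)")
  if (length(object@thickness) != 1 || object@thickness <= 0)
    return("thickness must be a positive scalar (micrometers)")
  if (!is.null(object@hemisphere)) {
    if (!identical(dim(object@hemisphere), dim(object@labels)))
      return("hemisphere mask must have the same shape as labels")
    if (!all(object@hemisphere %in% c(0, 1, 2)))
      return("hemisphere values must be 0 (none), 1 (left) or 2 (right)")
  }
  TRUE
})

#' QuantParams: stereological quantification parameters
#'
#' The three parameters of Abercrombie-corrected, interval-extrapolated
#' quantification: section thickness T, mean cell diameter D (both in
#' micrometers) and the section sampling interval k (every k-th section is
#' analyzed; totals are multiplied by k). Final totals use half-up rounding.
#'
#' @slot thickness section thickness T in micrometers, > 0.
#' @slot diameter mean cell diameter D in micrometers, >= 0.
#' @slot interval integer sampling interval k >= 1.
#' @seealso [quantParams()], [abercrombie()], [estimateRegions()]
#' @export
setClass("QuantParams", representation(
  thickness = "numeric", diameter = "numeric", interval = "integer"
))

setValidity("QuantParams", function(object) {
  if (length(object@thickness) != 1 || object@thickness <= 0)
    return("thickness T must be a positive scalar")
  if (length(object@diameter) != 1 || object@diameter < 0)
    return("diameter D must be a non-negative scalar")
  if (!.isCount(object@interval))
    return("interval k must be an integer >= 1")
  TRUE
})

#' @param thickness section thickness T in micrometers (> 0).
#' @param diameter mean cell diameter D in micrometers (>= 0).
#' @param interval section sampling interval k (integer >= 1).
#' @return a validated \code{QuantParams} object.
#' @rdname QuantParams-class
#' @examples
#' quantParams(thickness = 40, diameter = 15, interval = 6)
#' @export
quantParams <- function(thickness, diameter, interval = 1L) {
  new("QuantParams", thickness = as.numeric(thickness),
      diameter = as.numeric(diameter), interval = as.integer(interval))
}

#' DetectedObjects: connected components of a segmentation mask
#'
#' The result of connected-component extraction on one binary segmentation
#' mask: a per-object table plus the object label map (pixel value = object
#' id, 0 = background) that downstream steps use to resolve region
#' assignment and exclusion references.
#'
#' @slot table data.frame with one row per object: \code{object_id}
#'   (row-major scan order), \code{pixel_count}, \code{row}, \code{col}
#'   (centroid), \code{region_id} (0 until assigned), \code{hemisphere}
#'   ("left"/"right"/"none"), \code{excluded}.
#' @slot labelmap integer matrix mapping pixels to object ids.
#' @seealso [extractObjects()], [assignRegions()], [applyExclusions()]
#' @export
setClass("DetectedObjects", representation(
  table = "data.frame", labelmap = "matrix"
))

#' GroundTruth: planted-object registry of a synthetic dataset
#'
#' Exact record of every object planted by the synthetic generator, enabling
#' count-recovery tests with no tolerance. \code{row}/\code{col} is a pixel
#' guaranteed to lie inside the object (disc center, or the seed pixel of an
#' artifact blob), so exclusion registries built from it always resolve.
#'
#' @slot registry data.frame with columns \code{section_index},
#'   \code{region_id}, \code{object_id}, \code{row}, \code{col},
#'   \code{radius} (NA for artifacts), \code{is_artifact}.
#' @seealso [plantCells()], [injectArtifacts()], [truthCounts()]
#' @export
setClass("GroundTruth", representation(registry = "data.frame"))

setValidity("GroundTruth", function(object) {
  req <- c("section_index", "region_id", "object_id", "row", "col",
           "radius", "is_artifact")
  miss <- setdiff(req, names(object@registry))
  if (length(miss) > 0)
    return(sprintf("missing registry columns: %s", paste(miss, collapse = ", ")))
  TRUE
})

#' SlabSimResult: output of the sphere-in-slab sectioning simulator
#'
#' Records a simulated sectioning experiment: cells of diameter D with
#' centers uniform along the depth axis of a tissue block, cut into slabs of
#' thickness T, each cell producing a countable profile in every slab its
#' extent intersects (this split-cell overcounting is exactly what the
#' Abercrombie factor T/(T+D) corrects). Only every k-th slab is reported as
#' sampled.
#'
#' @slot trueCellCount the true number of cells N placed in the block.
#' @slot profileCounts integer profile counts in the sampled slabs, in
#'   depth order.
#' @slot sampledSlabs 0-based indices of the sampled slabs.
#' @slot thickness,diameter micrometers.
#' @slot interval integer sampling interval k.
#' @slot tissueDepth block depth in micrometers.
#' @slot seed RNG seed used.
#' @seealso [simulateSectioning()]
#' @export
setClass("SlabSimResult", representation(
  trueCellCount = "integer", profileCounts = "integer",
  sampledSlabs = "integer", thickness = "numeric", diameter = "numeric",
  interval = "integer", tissueDepth = "numeric", seed = "integer"
))

setValidity("SlabSimResult", function(object) {
  if (any(object@profileCounts < 0)) return("profile counts must be >= 0")
  expected <- floor(object@tissueDepth / (object@interval * object@thickness))
  if (length(object@profileCounts) != expected)
    return(sprintf("expected %d sampled slabs, got %d",
                   expected, length(object@profileCounts)))
  TRUE
})
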