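#' @rdname RegionOntology-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("regionNodes", function(x) standardGeneric("regionNodes"))

#' @rdname RegionOntology-class
#' @export
setGeneric("leafIds", function(x) standardGeneric("leafIds"))

#' @rdname AtlasSection-class
#' @export
setGeneric("sectionLabels", function(x) standardGeneric("sectionLabels"))

#' @rdname DetectedObjects-class
#' @export
setGeneric("objectTable", function(x) standardGeneric("objectTable"))

#' @rdname DetectedObjects-class
#' @export
setGeneric("labelMap", function(x) standardGeneric("labelMap"))

#' @rdname GroundTruth-class
#' @export
setGeneric("truthRegistry", function(x) standardGeneric("truthRegistry"))

#' Per-(section, region) planted counts from a ground-truth registry
#'
#' Tallies the non-artifact registry entries (optionally the artifacts
#' instead) per section and region. By construction this equals the planted
#' profile count, so it serves as the exact oracle for count recovery.
#'
#' @param x a [GroundTruth-class] object.
#' @param artifacts if TRUE, tally the artifact entries instead.
#' @return data.frame with columns \code{section_index}, \code{region_id},
#'   \code{n}.
#' @export
setGeneric("truthCounts", function(x, artifacts = FALSE)
  standardGeneric("truthCounts"))

#' @rdname SlabSimResult-class
#' @export
setGeneric("profileCounts", function(x) standardGeneric("profileCounts"))

#' @rdname SlabSimResult-class
#' @export
setGeneric("trueCellCount", function(x) standardGeneric("trueCellCount"))

setMethod("regionNodes", "RegionOntology", function(x) x@nodes)

setMethod("leafIds", "RegionOntology", function(x) {
  nd <- x@nodes
  sort(nd$id[!nd$id %in% nd$parent_id[!is.na(nd$parent_id)]])
})

setMethod("sectionLabels", "AtlasSection", function(x) x@labels)

setMethod("objectTable", "DetectedObjects", function(x) x@table)

setMethod("labelMap", "DetectedObjects", function(x) x@labelmap)

setMethod("truthRegistry", "GroundTruth", function(x) x@registry)

setMethod("truthCounts", "GroundTruth", function(x, artifacts = FALSE) {
  reg <- x@registry[x@registry$is_artifact == artifacts, , drop = FALSE]
  if (nrow(reg) == 0)
    return(data.frame(section_index = integer(0), region_id = integer(0),
                      n = integer(0)))
  agg <- stats::aggregate(list(n = reg$object_id),
                          by = list(section_index = reg$section_index,
                                    region_id = reg$region_id),
                          FUN = length)
  agg[order(agg$section_index, agg$region_id), , drop = FALSE]
})

setMethod("profileCounts", "SlabSimResult", function(x) x@profileCounts)

setMethod("trueCellCount", "SlabSimResult", function(x) x@trueCellCount)

setMethod("show", "RegionOntology", function(object) {
  nd <- object@nodes
  cat(sprintf("RegionOntology: %d nodes, %d leaves, root '%s'\n",
              nrow(nd), length(leafIds(object)),
              nd$acronym[is.na(nd$parent_id)]))
  cat(sprintf("  total leaf volume: %.3f mm^3; oversaturated nodes: %d\n",
              sum(nd$volume_mm3[nd$id %in% leafIds(object)]),
              sum(nd$oversaturated)))
})

setMethod("show", "AtlasSection", function(object) {
  cat(sprintf(
    "AtlasSection %d: %d x %d px @ %.1f um, T = %.1f um, axis %.3f mm%s\n",
    object@sectionIndex, nrow(object@labels), ncol(object@labels),
    object@pixelSize, object@thickness, object@axisCoord,
    if (is.null(object@hemisphere)) "" else ", with hemisphere mask"))
  ids <- sort(unique(as.vector(object@labels)))
  cat(sprintf("  region ids present: %s\n", paste(ids, collapse = " ")))
})

setMethod("show", "QuantParams", function(object) {
  cat(sprintf("QuantParams: T = %g um, D = %g um, k = %d (M = T/(T+D) = %.4f)\n",
              object@thickness, object@diameter, object@interval,
              object@thickness / (object@thickness + object@diameter)))
})

setMethod("show", "DetectedObjects", function(object) {
  tab <- object@table
  cat(sprintf("DetectedObjects: %d objects (%d excluded, %d unassigned)\n",
              nrow(tab), sum(tab$excluded), sum(tab$region_id == 0)))
})

setMethod("show", "GroundTruth", function(object) {
  reg <- object@registry
  cat(sprintf("GroundTruth: %d planted cells + %d artifacts over %d sections\n",
              sum(!reg$is_artifact), sum(reg$is_artifact),
              length(unique(reg$section_index))))
})

setMethod("show", "SlabSimResult", function(object) {
  cat(sprintf(
    "SlabSimResult: N = %d cells, T = %g, D = %g, k = %d; %d sampled slabs, %d profiles\n",
    object@trueCellCount, object@thickness, object@diameter,
    object@interval, length(object@profileCounts),
    sum(object@profileCounts)))
})
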