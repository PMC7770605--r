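#' Load a region ontology from a TSV table
#'
#' Reads the region-ontology table (one row per region) and validates it as
#' a single rooted tree. Expected tab-separated columns:
#' \code{id}, \code{acronym}, \code{name}, \code{parent_id} (empty for the
#' root), \code{r}, \code{g}, \code{b}, \code{volume_mm3},
#' \code{oversaturated} (0/1). Structural violations (duplicate ids, cycles,
#' multiple roots, negative volumes) raise errors naming the offending ids.
#'
#' @param path path to the ontology TSV.
#' @return a validated [RegionOntology-class].
#' @examples
#' tsv <- system.file("extdata", "ontology_demo.tsv", package = "atlasquant")
#' ont <- loadOntology(tsv)
#' leafIds(ont)
#' @export
loadOntology <- function(path) {
  if (!file.exists(path)) stop("ontology file not found: ", path)
  nd <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("id", "acronym", "name", "parent_id", "r", "g", "b",
           "volume_mm3", "oversaturated")
  miss <- setdiff(req, names(nd))
  if (length(miss) > 0)
    stop("ontology file lacks column(s): ", paste(miss, collapse = ", "))
  nd <- nd[req]
  nd$id <- as.integer(nd$id)
  nd$parent_id <- suppressWarnings(as.integer(nd$parent_id))
  nd$oversaturated <- as.logical(as.integer(nd$oversaturated))
  new("RegionOntology", nodes = nd)
}

#' Write a region ontology to a TSV table
#'
#' @param ontology a [RegionOntology-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeOntology <- function(ontology, path) {
  nd <- regionNodes(ontology)
  nd$oversaturated <- as.integer(nd$oversaturated)
  utils::write.table(nd, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a custom-grouping table
#'
#' A grouping assigns atlas leaves to custom (super-)regions for reporting,
#' the way atlas leaves are pooled into e.g. "neocortex" or "striatum and
#' pallidum" rows. Tab-separated columns: \code{leaf_id},
#' \code{group_acronym}.
#'
#' @param path path to the grouping TSV.
#' @return data.frame with columns \code{leaf_id}, \code{group_acronym}.
#' @export
readGrouping <- function(path) {
  if (!file.exists(path)) stop("grouping file not found: ", path)
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("leaf_id", "group_acronym") %in% names(g)))
    stop("grouping file needs columns leaf_id and group_acronym")
  g$leaf_id <- as.integer(g$leaf_id)
  g
}

#' Resolve a custom grouping into a total leaf-to-group mapping
#'
#' Validates the grouping against the ontology (every mapped id must be a
#' leaf and belong to exactly one group) and extends it to a total mapping
#' over all leaves; leaves not mentioned by the grouping map to
#' \code{"UNGROUPED"}.
#'
#' @param ontology a [RegionOntology-class].
#' @param grouping data.frame with columns \code{leaf_id},
#'   \code{group_acronym}, or NULL for the identity grouping (each leaf its
#'   own group, named by its acronym).
#' @return named character vector: names are leaf ids, values group
#'   acronyms.
#' @export
resolveGrouping <- function(ontology, grouping = NULL) {
  leaves <- leafIds(ontology)
  nd <- regionNodes(ontology)
  if (is.null(grouping)) {
    out <- nd$acronym[match(leaves, nd$id)]
    return(stats::setNames(out, leaves))
  }
  if (!all(c("leaf_id", "group_acronym") %in% names(grouping)))
    stop("grouping needs columns leaf_id and group_acronym")
  unknown <- setdiff(grouping$leaf_id, nd$id)
  if (length(unknown) > 0)
    stop("grouping references unknown id(s): ", paste(unknown, collapse = ", "))
  nonleaf <- setdiff(intersect(grouping$leaf_id, nd$id), leaves)
  if (length(nonleaf) > 0)
    stop("grouping maps non-leaf id(s): ", paste(nonleaf, collapse = ", "))
  dup <- unique(grouping$leaf_id[duplicated(grouping$leaf_id)])
  if (length(dup) > 0) {
    amb <- dup[vapply(dup, function(i)
      length(unique(grouping$group_acronym[grouping$leaf_id == i])) > 1,
      logical(1))]
    if (length(amb) > 0)
      stop("partition violation: leaf id(s) mapped to more than one group: ",
           paste(amb, collapse = ", "))
  }
  out <- stats::setNames(rep("UNGROUPED", length(leaves)), leaves)
  idx <- match(grouping$leaf_id, leaves)
  out[idx] <- grouping$group_acronym
  out
}

#' Read a cross-atlas region mapping table
#'
#' Maps comparable target regions onto source region-id lists in two
#' atlases (e.g. mouse CCFv3-2017 ids and rat WHSv2 ids for the same named
#' hippocampal region). Tab-separated columns: \code{target_acronym},
#' \code{atlasA_ids}, \code{atlasB_ids}; the id lists are comma-separated.
#' Within each atlas the id lists must be non-empty and disjoint across
#' rows.
#'
#' @param path path to the mapping TSV.
#' @return data.frame with columns \code{target_acronym} and list columns
#'   \code{ids_a}, \code{ids_b}.
#' @export
readCrossAtlasMapping <- function(path) {
  if (!file.exists(path)) stop("mapping file not found: ", path)
  m <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!all(c("target_acronym", "atlasA_ids", "atlasB_ids") %in% names(m)))
    stop("mapping file needs columns target_acronym, atlasA_ids, atlasB_ids")
  parse <- function(x) lapply(strsplit(x, ","), function(v) as.integer(trimws(v)))
  out <- data.frame(target_acronym = m$target_acronym,
                    stringsAsFactors = FALSE)
  out$ids_a <- parse(m$atlasA_ids)
  out$ids_b <- parse(m$atlasB_ids)
  for (side in c("ids_a", "ids_b")) {
    lens <- lengths(out[[side]])
    if (any(lens == 0) || any(vapply(out[[side]], anyNA, logical(1))))
      stop("empty or unparseable id list in column ", side)
    all_ids <- unlist(out[[side]])
    if (anyDuplicated(all_ids))
      stop("id(s) mapped to multiple targets in ", side, ": ",
           paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  }
  out
}

#' Effective oversaturation flags of all leaves
#'
#' A leaf is considered oversaturated (counts not reportable) if it or any
#' of its ancestors carries the flag; saturation of a parent region
#' suppresses all of its members.
#'
#' @param ontology a [RegionOntology-class].
#' @return named logical vector over leaf ids.
#' @export
leafOversaturation <- function(ontology) {
  nd <- regionNodes(ontology)
  parent <- stats::setNames(nd$parent_id, nd$id)
  flag <- stats::setNames(nd$oversaturated, nd$id)
  leaves <- leafIds(ontology)
  eff <- vapply(as.character(leaves), function(id) {
    while (!is.na(id)) {
      if (isTRUE(flag[[id]])) return(TRUE)
      id <- as.character(parent[[id]])
      if (is.na(id) || !nzchar(id)) break
    }
    FALSE
  }, logical(1))
  stats::setNames(eff, leaves)
}
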