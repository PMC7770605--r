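## Connected-component extraction of labeled objects, majority-overlap
## region assignment (each object counted in exactly one region), and the
## manual exclusion step.

#' Extract connected objects from a binary segmentation mask
#'
#' Labels maximal connected foreground components under 4- or 8-pixel
#' connectivity, discards components smaller than \code{minSize} pixels,
#' and numbers the surviving objects by their first-encountered pixel in a
#' row-major (top-left origin) scan so that object ids are reproducible.
#' Components are found as connected components of the pixel-adjacency
#' graph.
#'
#' @param mask integer/logical 0-1 matrix; anything non-binary is an error.
#' @param connectivity 4 or 8 (default 8, merging diagonal pixel chains).
#' @param minSize minimum pixel count an object must have (default 4,
#'   suppressing single-pixel noise).
#' @return a [DetectedObjects-class]; \code{region_id} is 0 until
#'   [assignRegions()] is applied.
#' @examples
#' m <- matrix(0L, 5, 5); m[1:2, 1:2] <- 1L; m[4, 4] <- 1L
#' objectTable(extractObjects(m, minSize = 1))
#' @export
extractObjects <- function(mask, connectivity = 8, minSize = 4) {
  m <- .checkBinaryMask(mask)
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  h <- nrow(m); w <- ncol(m)
  fg <- which(m == 1L)
  labelmap <- matrix(0L, h, w)
  empty <- data.frame(object_id = integer(0), pixel_count = integer(0),
                      row = numeric(0), col = numeric(0),
                      region_id = integer(0), hemisphere = character(0),
                      excluded = logical(0), stringsAsFactors = FALSE)
  if (length(fg) == 0)
    return(new("DetectedObjects", table = empty, labelmap = labelmap))

  rows <- ((fg - 1) %% h) + 1
  cols <- ((fg - 1) %/% h) + 1
  offsets <- list(c(1, 0), c(0, 1))                    # down, right
  if (connectivity == 8)
    offsets <- c(offsets, list(c(1, 1), c(-1, 1)))     # both diagonals
  from <- integer(0); to <- integer(0)
  inmask <- matrix(FALSE, h, w); inmask[fg] <- TRUE
  for (off in offsets) {
    nr <- rows + off[1]; nc <- cols + off[2]
    ok <- nr >= 1 & nr <= h & nc >= 1 & nc <= w
    lin <- (nc[ok] - 1) * h + nr[ok]
    hit <- inmask[lin]
    from <- c(from, fg[ok][hit]); to <- c(to, lin[hit])
  }
  vid <- match(fg, fg)  # 1..n in linear-index order
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(from) > 0)
    g <- igraph::add_edges(g, rbind(match(from, fg), match(to, fg)))
  comp <- igraph::components(g)$membership

  # order components by first pixel in row-major scan, then filter by size
  rowmajor <- (rows - 1) * w + cols
  firsts <- tapply(rowmajor, comp, min)
  sizes <- tabulate(comp)
  keep <- which(sizes >= minSize)
  keep <- keep[order(firsts[as.character(keep)])]
  if (length(keep) == 0)
    return(new("DetectedObjects", table = empty, labelmap = labelmap))
  newid <- integer(max(comp)); newid[keep] <- seq_along(keep)
  objid <- newid[comp]
  sel <- objid > 0
  labelmap[fg[sel]] <- objid[sel]
  tab <- data.frame(
    object_id = seq_along(keep),
    pixel_count = as.integer(sizes[keep]),
    row = as.numeric(tapply(rows[sel], objid[sel], mean)),
    col = as.numeric(tapply(cols[sel], objid[sel], mean)),
    region_id = 0L,
    hemisphere = "none",
    excluded = FALSE,
    stringsAsFactors = FALSE)
  new("DetectedObjects", table = tab, labelmap = labelmap)
}

#' Assign each object to exactly one atlas region
#'
#' Every object is attributed to the region whose atlas label covers the
#' largest number of its pixels (the object is counted in one region only;
#' no splitting across regions). Label 0 (outside the atlas) wins only when
#' no nonzero label overlaps the object, in which case the object is
#' "unassigned" and reported separately. Ties go to the lowest region id so
#' results are reproducible. If the section carries a hemisphere mask the
#' hemisphere is determined the same way.
#'
#' @param objects a [DetectedObjects-class].
#' @param section the pixel-aligned [AtlasSection-class].
#' @return the objects with \code{region_id} (and \code{hemisphere})
#'   filled in.
#' @export
assignRegions <- function(objects, section) {
  stopifnot(is(objects, "DetectedObjects"), is(section, "AtlasSection"))
  lm <- objects@labelmap
  if (!identical(dim(lm), dim(section@labels)))
    stop("mask and atlas section have different shapes")
  tab <- objects@table
  if (nrow(tab) == 0) return(objects)
  pix <- which(lm > 0)
  tab$region_id <- .majorityLabel(lm[pix], section@labels[pix], nrow(tab))
  if (!is.null(section@hemisphere)) {
    hcode <- .majorityLabel(lm[pix], section@hemisphere[pix], nrow(tab))
    tab$hemisphere <- c("none", "left", "right")[hcode + 1]
  }
  new("DetectedObjects", table = tab, labelmap = lm)
}

# majority nonzero label per object; ties -> lowest label; 0 only if no
# nonzero label overlaps
.majorityLabel <- function(obj, lab, nObj) {
  cnt <- stats::aggregate(list(n = obj),
                          by = list(obj = obj, lab = lab), FUN = length)
  out <- integer(nObj)
  nz <- cnt[cnt$lab != 0, , drop = FALSE]
  if (nrow(nz) > 0) {
    nz <- nz[order(nz$obj, -nz$n, nz$lab), , drop = FALSE]
    first <- nz[!duplicated(nz$obj), , drop = FALSE]
    out[first$obj] <- as.integer(first$lab)
  }
  out
}

#' Apply the manual exclusion step to extracted objects
#'
#' Emulates the post-processing step in which erroneously segmented objects
#' (clutter that is not a cell) are manually flagged and removed from all
#' downstream counting. Excluded objects stay in the table with
#' \code{excluded = TRUE}. The registry can be either a data.frame of
#' reference points with columns \code{row}, \code{col} (a reference
#' resolves to the object whose pixels contain that point) or a logical
#' matrix (an object is excluded when the mask covers its centroid pixel).
#' Unresolvable references produce a warning and are reported in the
#' \code{"unresolved"} attribute, not an error.
#'
#' @param objects a [DetectedObjects-class].
#' @param registry data.frame with \code{row}, \code{col}, or a logical
#'   matrix the shape of the mask.
#' @return the objects with exclusion flags set; attribute
#'   \code{unresolved} holds the number of references that matched nothing.
#' @export
applyExclusions <- function(objects, registry) {
  stopifnot(is(objects, "DetectedObjects"))
  tab <- objects@table
  lm <- objects@labelmap
  unresolved <- 0L
  if (is.matrix(registry)) {
    if (!identical(dim(registry), dim(lm)))
      stop("exclusion mask shape differs from the object label map")
    cent <- cbind(pmin(pmax(round(tab$row), 1), nrow(lm)),
                  pmin(pmax(round(tab$col), 1), ncol(lm)))
    hit <- as.logical(registry[cent])
    tab$excluded <- tab$excluded | hit
  } else {
    if (!all(c("row", "col") %in% names(registry)))
      stop("exclusion registry needs columns row and col")
    for (i in seq_len(nrow(registry))) {
      r <- round(registry$row[i]); c <- round(registry$col[i])
      oid <- if (r >= 1 && r <= nrow(lm) && c >= 1 && c <= ncol(lm))
        lm[r, c] else 0L
      if (oid > 0) tab$excluded[tab$object_id == oid] <- TRUE
      else unresolved <- unresolved + 1L
    }
    if (unresolved > 0)
      warning(sprintf("%d exclusion reference(s) did not resolve to any object",
                      unresolved))
  }
  out <- new("DetectedObjects", table = tab, labelmap = lm)
  attr(out, "unresolved") <- unresolved
  out
}
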