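## Synthetic atlas sections, planted cell masks with exact ground truth,
## clutter artifacts, and a 1D sphere-in-slab sectioning simulator. These
## generators define the study conditions for all recovery tests: every
## planted object is recorded exactly, so counting tests run at zero
## tolerance.

#' Generate a series of synthetic atlas sections plus their ontology
#'
#' Builds \code{nSections} label maps that partition the tissue pixels among
#' \code{nLeaves} leaf regions, either as equal vertical bands or as a
#' Voronoi tessellation of random seed points (re-drawn per section). The
#' accompanying ontology has one root and \code{nLeaves} leaves; each leaf
#' volume is the volume its pixels represent across the generated series
#' (pixel area x thickness, summed over sections), so totals and densities
#' computed from the series are mutually consistent. The dorsoventral
#' coordinate decreases by \code{axisStep} per section, i.e. sections are
#' ordered dorsal to ventral.
#'
#' @param nSections number of sections (>= 1).
#' @param shape c(rows, cols), at least 8 x 8.
#' @param nLeaves number of leaf regions (>= 1).
#' @param geometry "bands" (vertical bands, identical across sections) or
#'   "voronoi" (per-section random tessellation).
#' @param pixelSize pixel edge in micrometers.
#' @param thickness section thickness in micrometers.
#' @param axisStart dorsoventral coordinate of the first (most dorsal)
#'   section, mm.
#' @param axisStep decrement of the coordinate per section, mm.
#' @param margin width of a zero (outside-atlas) border in pixels.
#' @param seed RNG seed.
#' @return list with elements \code{sections} (list of
#'   [AtlasSection-class]) and \code{ontology} ([RegionOntology-class];
#'   leaf ids 2..nLeaves+1, root id 1).
#' @export
generateAtlasSeries <- function(nSections, shape, nLeaves,
                                geometry = c("bands", "voronoi"),
                                pixelSize = 10, thickness = 40,
                                axisStart = 0, axisStep = 0.1,
                                margin = 0, seed = 1) {
  geometry <- match.arg(geometry)
  stopifnot(nLeaves >= 1, length(shape) == 2, all(shape >= 8), nSections >= 1)
  set.seed(seed)
  h <- shape[1]; w <- shape[2]
  leaf_ids <- seq_len(nLeaves) + 1L
  inner_rows <- (margin + 1):(h - margin)
  inner_cols <- (margin + 1):(w - margin)

  makeLabels <- function() {
    lab <- matrix(0L, h, w)
    iw <- length(inner_cols)
    if (geometry == "bands") {
      bw <- iw %/% nLeaves
      breaks <- c(rep(bw, nLeaves - 1), iw - bw * (nLeaves - 1))
      band <- rep(seq_len(nLeaves), breaks)
      lab[inner_rows, inner_cols] <- matrix(leaf_ids[band],
                                            nrow = length(inner_rows),
                                            ncol = iw, byrow = TRUE)
    } else {
      sr <- stats::runif(nLeaves, min(inner_rows), max(inner_rows))
      sc <- stats::runif(nLeaves, min(inner_cols), max(inner_cols))
      rr <- matrix(inner_rows, length(inner_rows), iw)
      cc <- matrix(inner_cols, length(inner_rows), iw, byrow = TRUE)
      d2 <- vapply(seq_len(nLeaves),
                   function(i) as.vector((rr - sr[i])^2 + (cc - sc[i])^2),
                   numeric(length(inner_rows) * iw))
      nearest <- max.col(-d2, ties.method = "first")
      lab[inner_rows, inner_cols] <- leaf_ids[nearest]
    }
    lab
  }

  sections <- vector("list", nSections)
  areas <- stats::setNames(numeric(nLeaves), leaf_ids)
  for (i in seq_len(nSections)) {
    lab <- makeLabels()
    sections[[i]] <- new("AtlasSection", labels = lab,
                         sectionIndex = i,
                         pixelSize = as.numeric(pixelSize),
                         thickness = as.numeric(thickness),
                         axisCoord = axisStart - (i - 1) * axisStep,
                         hemisphere = NULL)
    tab <- table(lab[lab > 0])
    areas[names(tab)] <- areas[names(tab)] + as.integer(tab)
  }

  px_mm2 <- (pixelSize / 1000)^2
  t_mm <- thickness / 1000
  leaf_vol <- areas * px_mm2 * t_mm
  nd <- data.frame(
    id = c(1L, leaf_ids),
    acronym = c("ROOT", sprintf("R%d", seq_len(nLeaves))),
    name = c("whole tissue", sprintf("synthetic region %d", seq_len(nLeaves))),
    parent_id = c(NA_integer_, rep(1L, nLeaves)),
    r = c(0L, leaf_ids), g = c(0L, (leaf_ids * 40L) %% 256L),
    b = c(0L, (leaf_ids * 90L) %% 256L),
    volume_mm3 = c(sum(leaf_vol), unname(leaf_vol)),
    oversaturated = FALSE,
    stringsAsFactors = FALSE
  )
  list(sections = sections, ontology = new("RegionOntology", nodes = nd))
}

# distance of each foreground pixel of `m` to the nearest background pixel,
# with outside-image treated as background (via padding)
.distToBackground <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(0, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  d <- EBImage::imageData(EBImage::distmap(pad))
  d[2:(h + 1), 2:(w + 1)]
}

#' Plant circular cell profiles into segmentation masks
#'
#' For every section and every region named by the density (or fixed-count)
#' specification, draws a profile count and places that many filled discs
#' entirely inside the region's pixels, at least \code{minGap} pixels from
#' the region boundary and from every other disc. Placement is therefore
#' unambiguous: each disc belongs to exactly one region and connected
#' components never merge, so the recorded registry is an exact counting
#' oracle. Counts are Poisson draws with mean density x region area (in
#' mm^2) under \code{densitySpec}, or exact per-section counts under
#' \code{countSpec}.
#'
#' @param sections list of [AtlasSection-class] (e.g. from
#'   [generateAtlasSeries()]).
#' @param densitySpec named numeric vector, region id -> mean profiles per
#'   mm^2 of section area (Poisson mode). Ignored if \code{countSpec} given.
#' @param countSpec named integer vector, region id -> exact profile count
#'   per section (fixed-count mode, Poisson disabled).
#' @param radiusRange integer range of disc radii in pixels.
#' @param minGap minimum clearance in pixels between a disc and the region
#'   boundary / other objects (default 2).
#' @param seed RNG seed.
#' @param maxTries placement attempts per disc before declaring the packing
#'   infeasible.
#' @return list with \code{masks} (list of integer 0/1 matrices, parallel
#'   to \code{sections}) and \code{truth} ([GroundTruth-class]).
#' @export
plantCells <- function(sections, densitySpec = NULL, countSpec = NULL,
                       radiusRange = c(2, 4), minGap = 2, seed = 1,
                       maxTries = 200) {
  if (is.null(densitySpec) && is.null(countSpec))
    stop("one of densitySpec or countSpec is required")
  set.seed(seed)
  spec_ids <- as.integer(names(if (is.null(countSpec)) densitySpec else countSpec))
  rmin <- min(radiusRange); rmax <- max(radiusRange)
  stopifnot(rmin >= 1)

  masks <- vector("list", length(sections))
  reg <- list()
  for (si in seq_along(sections)) {
    sec <- sections[[si]]
    lab <- sec@labels
    mask <- matrix(0L, nrow(lab), ncol(lab))
    px_mm2 <- (sec@pixelSize / 1000)^2
    placed_r <- numeric(0); placed_c <- numeric(0); placed_rad <- numeric(0)
    oid <- 0L
    for (rid in sort(spec_ids)) {
      rmask <- lab == rid
      area_px <- sum(rmask)
      if (area_px == 0) next
      if (is.null(countSpec)) {
        mu <- densitySpec[[as.character(rid)]] * area_px * px_mm2
        n <- stats::rpois(1, mu)
      } else {
        n <- countSpec[[as.character(rid)]]
      }
      if (n == 0) next
      if (n * pi * rmax^2 > 0.4 * area_px)
        stop(sprintf("region %d: %d discs of radius <= %d cannot occupy <= 40%% of %d px",
                     rid, n, rmax, area_px))
      dist <- .distToBackground(rmask * 1)
      for (j in seq_len(n)) {
        ok <- FALSE
        for (try in seq_len(maxTries)) {
          rad <- if (rmin == rmax) rmin else sample(rmin:rmax, 1)
          cand <- which(dist > rad + minGap)
          if (length(cand) == 0) next
          pick <- cand[sample.int(length(cand), 1)]
          r0 <- ((pick - 1) %% nrow(lab)) + 1
          c0 <- ((pick - 1) %/% nrow(lab)) + 1
          if (length(placed_r) > 0) {
            dd <- sqrt((placed_r - r0)^2 + (placed_c - c0)^2)
            if (any(dd < placed_rad + rad + minGap)) next
          }
          ok <- TRUE
          break
        }
        if (!ok)
          stop(sprintf("region %d, section %d: could not place disc %d of %d after %d tries",
                       rid, sec@sectionIndex, j, n, maxTries))
        rr <- max(1, r0 - rad):min(nrow(lab), r0 + rad)
        cc <- max(1, c0 - rad):min(ncol(lab), c0 + rad)
        sub <- outer((rr - r0)^2, (cc - c0)^2, "+") <= rad^2
        mask[rr, cc][sub] <- 1L
        placed_r <- c(placed_r, r0); placed_c <- c(placed_c, c0)
        placed_rad <- c(placed_rad, rad)
        oid <- oid + 1L
        reg[[length(reg) + 1L]] <- data.frame(
          section_index = sec@sectionIndex, region_id = rid,
          object_id = oid, row = as.integer(r0), col = as.integer(c0),
          radius = as.numeric(rad), is_artifact = FALSE)
      }
    }
    masks[[si]] <- mask
  }
  registry <- if (length(reg) > 0) do.call(rbind, reg) else
    data.frame(section_index = integer(0), region_id = integer(0),
               object_id = integer(0), row = integer(0), col = integer(0),
               radius = numeric(0), is_artifact = logical(0))
  list(masks = masks, truth = new("GroundTruth", registry = registry))
}

#' Inject non-cell clutter blobs into a segmentation mask
#'
#' Adds \code{nArtifacts} irregular foreground blobs (grown by a random
#' 4-connected walk) that emulate erroneously segmented material such as
#' clustered neuropil. Blobs keep at least \code{minGap} pixels of
#' clearance from all existing foreground and from each other, so planted
#' discs are never touched, and are appended to the ground-truth registry
#' with \code{is_artifact = TRUE}; the recorded \code{row}/\code{col} is
#' the blob's seed pixel (guaranteed interior), usable as an exclusion
#' reference.
#'
#' @param mask integer 0/1 matrix to modify.
#' @param truth the [GroundTruth-class] to extend.
#' @param sectionIndex section the mask belongs to.
#' @param nArtifacts number of blobs to add (>= 0).
#' @param sizeRange integer range of blob pixel counts.
#' @param minGap clearance in pixels (default 2).
#' @param section optional [AtlasSection-class]; if given, each artifact
#'   records the atlas label under its seed pixel, else region_id 0.
#' @param seed RNG seed.
#' @param maxTries placement attempts per blob.
#' @return list with updated \code{mask} and \code{truth}.
#' @export
injectArtifacts <- function(mask, truth, sectionIndex, nArtifacts,
                            sizeRange = c(5, 15), minGap = 2,
                            section = NULL, seed = 1, maxTries = 200) {
  stopifnot(nArtifacts >= 0)
  if (nArtifacts == 0) return(list(mask = mask, truth = truth))
  set.seed(seed)
  h <- nrow(mask); w <- ncol(mask)
  dist <- if (any(mask > 0)) .distToBackground(1 - mask) else
    matrix(Inf, h, w)
  allowed <- dist > minGap  # background pixels clear of existing foreground
  allowed[mask > 0] <- FALSE
  reg <- truth@registry
  base_oid <- if (any(reg$section_index == sectionIndex))
    max(reg$object_id[reg$section_index == sectionIndex]) else 0L

  blockNeighborhood <- function(rows, cols, radius) {
    for (i in seq_along(rows)) {
      rr <- max(1, rows[i] - radius):min(h, rows[i] + radius)
      cc <- max(1, cols[i] - radius):min(w, cols[i] + radius)
      allowed[rr, cc] <<- FALSE
    }
  }

  for (a in seq_len(nArtifacts)) {
    target <- if (min(sizeRange) == max(sizeRange)) min(sizeRange) else
      sample(min(sizeRange):max(sizeRange), 1)
    done <- FALSE
    for (try in seq_len(maxTries)) {
      open <- which(allowed)
      if (length(open) == 0) break
      seedpix <- open[sample.int(length(open), 1)]
      sr <- ((seedpix - 1) %% h) + 1; sc <- ((seedpix - 1) %/% h) + 1
      blob_r <- sr; blob_c <- sc
      while (length(blob_r) < target) {
        nb_r <- c(blob_r - 1, blob_r + 1, blob_r, blob_r)
        nb_c <- c(blob_c, blob_c, blob_c - 1, blob_c + 1)
        keep <- nb_r >= 1 & nb_r <= h & nb_c >= 1 & nb_c <= w
        nb_r <- nb_r[keep]; nb_c <- nb_c[keep]
        lin <- (nb_c - 1) * h + nb_r
        lin <- unique(lin[allowed[lin] & !lin %in% ((blob_c - 1) * h + blob_r)])
        if (length(lin) == 0) break
        pick <- lin[sample.int(length(lin), 1)]
        blob_r <- c(blob_r, ((pick - 1) %% h) + 1)
        blob_c <- c(blob_c, ((pick - 1) %/% h) + 1)
      }
      if (length(blob_r) >= target) {
        mask[(blob_c - 1) * h + blob_r] <- 1L
        blockNeighborhood(blob_r, blob_c, minGap)
        rid <- if (!is.null(section)) section@labels[sr, sc] else 0L
        reg <- rbind(reg, data.frame(
          section_index = sectionIndex, region_id = as.integer(rid),
          object_id = as.integer(base_oid + a), row = as.integer(sr),
          col = as.integer(sc), radius = NA_real_, is_artifact = TRUE))
        done <- TRUE
        break
      }
    }
    if (!done)
      stop(sprintf("could not place artifact %d of %d (mask too crowded)",
                   a, nArtifacts))
  }
  list(mask = mask, truth = new("GroundTruth", registry = reg))
}

#' Simulate sectioning of a cell population into slabs
#'
#' Places \code{trueCellCount} cells of diameter D with centers uniform on
#' the depth axis of a tissue block and cuts the block into consecutive
#' slabs of thickness T. A cell produces one countable profile in every
#' slab its extent (center - D/2, center + D/2) intersects, so a cell is
#' counted once per slab it touches -- the split-cell overcounting whose
#' expectation, (T+D)/T profiles per cell, Abercrombie's factor T/(T+D)
#' inverts. With D = 0 a cell belongs to exactly one slab (centers falling
#' on a slab boundary go to the lower slab). Only every k-th slab is
#' reported as sampled.
#'
#' @param trueCellCount true number of cells N.
#' @param thickness slab thickness T in micrometers (> 0).
#' @param diameter cell diameter D in micrometers (>= 0).
#' @param interval sampling interval k (integer >= 1).
#' @param tissueDepth block depth in micrometers (>= k * T).
#' @param seed RNG seed.
#' @param centers optional explicit center depths in micrometers,
#'   overriding the uniform draw (then \code{trueCellCount} must equal
#'   \code{length(centers)}).
#' @return a [SlabSimResult-class].
#' @examples
#' sim <- simulateSectioning(1000, thickness = 40, diameter = 15,
#'                           interval = 1, tissueDepth = 40000, seed = 1)
#' sum(profileCounts(sim)) / trueCellCount(sim)  # close to (40+15)/40
#' @export
simulateSectioning <- function(trueCellCount, thickness, diameter,
                               interval = 1L, tissueDepth, seed = 1,
                               centers = NULL) {
  if (thickness <= 0) stop("thickness T must be > 0")
  if (diameter < 0) stop("diameter D must be >= 0")
  if (!.isCount(interval)) stop("interval k must be an integer >= 1")
  if (tissueDepth < interval * thickness)
    stop("tissueDepth must be at least k * T")
  set.seed(seed)
  N <- as.integer(trueCellCount)
  if (is.null(centers)) {
    centers <- stats::runif(N, 0, tissueDepth)
  } else if (length(centers) != N) {
    stop("length(centers) must equal trueCellCount")
  }
  nSlabs <- floor(tissueDepth / thickness)
  if (diameter == 0) {
    idx <- ceiling(centers / thickness) - 1   # boundary ties to lower slab
    idx[idx < 0] <- 0
    lo <- hi <- pmin(idx, nSlabs - 1)
  } else {
    lo <- pmax(0, floor((centers - diameter / 2) / thickness))
    hi <- pmin(nSlabs - 1, ceiling((centers + diameter / 2) / thickness) - 1)
  }
  widths <- hi - lo + 1
  slab <- sequence(widths) - 1 + rep(lo, widths)
  counts <- tabulate(slab + 1, nbins = nSlabs)
  m <- floor(tissueDepth / (interval * thickness))
  sampled <- as.integer(interval * (seq_len(m) - 1))
  new("SlabSimResult", trueCellCount = N,
      profileCounts = as.integer(counts[sampled + 1]),
      sampledSlabs = sampled, thickness = as.numeric(thickness),
      diameter = as.numeric(diameter), interval = as.integer(interval),
      tissueDepth = as.numeric(tissueDepth), seed = as.integer(seed))
}

#' Write / read a ground-truth registry as TSV
#'
#' Columns: \code{section}, \code{region_id}, \code{object_id}, \code{row},
#' \code{col}, \code{radius}, \code{is_artifact} (0/1).
#'
#' @param truth a [GroundTruth-class].
#' @param path file path.
#' @return \code{writeGroundTruth}: invisibly, the path;
#'   \code{readGroundTruth}: a [GroundTruth-class].
#' @export
writeGroundTruth <- function(truth, path) {
  reg <- truth@registry
  out <- data.frame(section = reg$section_index, region_id = reg$region_id,
                    object_id = reg$object_id, row = reg$row, col = reg$col,
                    radius = reg$radius,
                    is_artifact = as.integer(reg$is_artifact))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  new("GroundTruth", registry = data.frame(
    section_index = as.integer(d$section), region_id = as.integer(d$region_id),
    object_id = as.integer(d$object_id), row = as.integer(d$row),
    col = as.integer(d$col), radius = as.numeric(d$radius),
    is_artifact = as.logical(d$is_artifact)))
}

#' Write a complete synthetic dataset to a directory
#'
#' Writes atlas sections (\code{sec_NNN.flat} + \code{sec_NNN.hdr.json}),
#' masks (\code{sec_NNN.png}, 8-bit 0/255), \code{ontology.tsv} and
#' \code{ground_truth.tsv}, i.e. everything [runPipeline()] needs as input.
#'
#' @param dir output directory (created if missing).
#' @param sections list of [AtlasSection-class].
#' @param masks parallel list of 0/1 matrices.
#' @param ontology a [RegionOntology-class].
#' @param truth a [GroundTruth-class].
#' @return invisibly, \code{dir}.
#' @export
writeSyntheticDataset <- function(dir, sections, masks, ontology, truth) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(sections)) {
    stem <- file.path(dir, sprintf("sec_%03d", sections[[i]]@sectionIndex))
    writeAtlasSection(sections[[i]], stem)
    writeMask(masks[[i]], paste0(stem, ".png"))
  }
  writeOntology(ontology, file.path(dir, "ontology.tsv"))
  writeGroundTruth(truth, file.path(dir, "ground_truth.tsv"))
  invisible(dir)
}
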