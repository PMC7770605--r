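# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: plain loops, explicit queues, first-principles formulas.

# BFS flood fill: returns a list of components, each a sorted vector of
# linear (column-major) pixel indices
bfsComponents <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  offs <- if (connectivity == 4)
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  comps <- list()
  for (c0 in seq_len(w)) for (r0 in seq_len(h)) {
    if (mask[r0, c0] == 0 || seen[r0, c0]) next
    queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    pix <- integer(0)
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      pix <- c(pix, (p[2] - 1) * h + p[1])
      for (o in offs) {
        rr <- p[1] + o[1]; cc <- p[2] + o[2]
        if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
            mask[rr, cc] != 0 && !seen[rr, cc]) {
          seen[rr, cc] <- TRUE
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
    comps[[length(comps) + 1]] <- as.integer(sort(pix))
  }
  comps
}

# canonical pixel-set representation of an object label map, for comparing
# two labelings regardless of label numbering
labelmapAsSets <- function(lm) {
  idx <- which(lm > 0)
  sets <- split(idx, lm[idx])
  sets <- lapply(sets, sort)
  sets[order(vapply(sets, min, numeric(1)))]
}

# per-value pixel tally by explicit double loop
bruteTally <- function(labels) {
  counts <- list()
  for (c0 in seq_len(ncol(labels))) for (r0 in seq_len(nrow(labels))) {
    key <- as.character(labels[r0, c0])
    counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
  }
  counts
}

# per-slab profile counts by interval-overlap enumeration
bruteSlabCounts <- function(centers, diameter, thickness, nSlabs) {
  counts <- integer(nSlabs)
  for (i in seq_len(nSlabs)) {
    lo <- (i - 1) * thickness; hi <- i * thickness
    for (c0 in centers) {
      if (diameter == 0) {
        slab <- ceiling(c0 / thickness) - 1
        if (slab < 0) slab <- 0
        if (slab == i - 1) counts[i] <- counts[i] + 1L
      } else if (lo < c0 + diameter / 2 && hi > c0 - diameter / 2) {
        counts[i] <- counts[i] + 1L
      }
    }
  }
  counts
}

# Spearman's rho from first principles: mid-ranks, then Pearson on ranks
bruteSpearman <- function(x, y) {
  midrank <- function(v) {
    vapply(v, function(vi) 1 + sum(v < vi) + (sum(v == vi) - 1) / 2,
           numeric(1))
  }
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# path to the bundled demo ontology
demoOntologyPath <- function() {
  system.file("extdata", "ontology_demo.tsv", package = "atlasquant")
}

# small planted series used by several tests: returns sections, ontology,
# masks, truth
makePlantedSeries <- function(nSections = 5, nLeaves = 3, shape = c(60, 90),
                              densities = NULL, countSpec = NULL,
                              seed = 1, radiusRange = c(2, 3)) {
  g <- generateAtlasSeries(nSections, shape, nLeaves, "bands",
                           pixelSize = 10, thickness = 40, seed = seed)
  if (is.null(densities) && is.null(countSpec)) {
    countSpec <- stats::setNames(rep(5L, nLeaves), seq_len(nLeaves) + 1)
  }
  pc <- plantCells(g$sections, densitySpec = densities,
                   countSpec = countSpec, radiusRange = radiusRange,
                   seed = seed + 1)
  list(sections = g$sections, ontology = g$ontology,
       masks = pc$masks, truth = pc$truth)
}

# builds a small on-disk synthetic dataset and a config for runPipeline
makePipelineFixture <- function(root, seed = 31, nArtifacts = 3) {
  g <- generateAtlasSeries(3, c(60, 80), 3, "bands", seed = seed)
  pc <- plantCells(g$sections, countSpec = c("2" = 5L, "3" = 4L, "4" = 3L),
                   seed = seed + 1)
  masks <- pc$masks; truth <- pc$truth
  if (nArtifacts > 0) {
    for (i in seq_along(masks)) {
      inj <- injectArtifacts(masks[[i]], truth, i, nArtifacts,
                             sizeRange = c(5, 9), seed = seed + 10 + i,
                             section = g$sections[[i]])
      masks[[i]] <- inj$mask; truth <- inj$truth
    }
  }
  dataDir <- file.path(root, "data")
  writeSyntheticDataset(dataDir, g$sections, masks, g$ontology, truth)
  reg <- truthRegistry(truth)
  art <- reg[reg$is_artifact, c("section_index", "row", "col")]
  names(art)[1] <- "section"
  exclPath <- file.path(root, "exclusions.tsv")
  utils::write.table(art, exclPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  outDir <- file.path(root, "out")
  config <- list(
    ontology = file.path(dataDir, "ontology.tsv"),
    atlas_dir = dataDir, mask_dir = dataDir, output_dir = outDir,
    exclusions = exclPath,
    quant = list(thickness_um = 40, diameter_um = 15, interval = 6,
                 scope = "unilateral"),
    extraction = list(connectivity = 8, min_size = 4))
  list(config = config, truth = truth, outDir = outDir)
}

# full extraction chain over a series; returns list of DetectedObjects
extractSeries <- function(masks, sections, connectivity = 8, minSize = 4) {
  lapply(seq_along(sections), function(i)
    assignRegions(extractObjects(masks[[i]], connectivity, minSize),
                  sections[[i]]))
}
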