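## Downstream comparative statistics: validity percent differences,
## inter-rater reliability ranges, cell-type fractions, cross-species
## density comparison, and dorsoventral gradient profiling.

#' Percent difference of a test count against a reference count
#'
#' 100 * (test - ref) / ref, with the reference (e.g. manual) count as
#' denominator; the sign is preserved (negative means the test count is
#' lower). The rounded value uses half-up rounding for report display.
#'
#' @param count_ref reference count (> 0).
#' @param count_test test count (>= 0).
#' @return list with \code{pct} (real) and \code{rounded} (integer).
#' @examples
#' percentDifference(2175, 2379)  # 9.38 -> 9
#' percentDifference(98, 96)      # -2.04 -> -2
#' @export
percentDifference <- function(count_ref, count_test) {
  if (any(count_ref <= 0))
    stop("percent difference is undefined for a non-positive reference count")
  pct <- 100 * (count_test - count_ref) / count_ref
  list(pct = pct, rounded = as.integer(roundHalfUp(pct)))
}

#' Validity comparison table: automated vs reference counts per group
#'
#' One row per reporting group comparing a reference (manual) count with a
#' test (automated) count, plus an \code{"ALL"} row over the summed counts.
#'
#' @param manual named numeric vector of reference counts per group.
#' @param automated named numeric vector of test counts over the same
#'   groups.
#' @return data.frame with columns \code{label}, \code{count_ref},
#'   \code{count_test}, \code{pct_diff}, \code{pct_diff_rounded}.
#' @export
validityTable <- function(manual, automated) {
  if (!setequal(names(manual), names(automated)))
    stop("manual and automated tables cover different groups")
  automated <- automated[names(manual)]
  labels <- c(names(manual), "ALL")
  ref <- c(unname(manual), sum(manual))
  test <- c(unname(automated), sum(automated))
  pd <- percentDifference(ref, test)
  data.frame(label = labels, count_ref = ref, count_test = test,
             pct_diff = pd$pct, pct_diff_rounded = pd$rounded,
             stringsAsFactors = FALSE)
}

#' Inter-rater reliability of counts derived from independent segmentations
#'
#' Given count tables produced by two or more raters over the same groups,
#' computes the absolute percent difference of every non-reference rater
#' against the reference, per group, and summarizes the spread at three
#' granularities: overall (min, max) across raters and groups, per rater,
#' and per group.
#'
#' @param tables list (>= 2) of named numeric vectors with identical names.
#' @param reference index of the reference table (default 1).
#' @return list with \code{perGroup} (data.frame rater/group/abs_pct_diff),
#'   \code{range} (overall c(min, max)), \code{perRater} and
#'   \code{perGroupRange} data.frames of per-stratum ranges.
#' @export
raterReliability <- function(tables, reference = 1) {
  if (length(tables) < 2) stop("at least two rater tables are required")
  nms <- names(tables[[1]])
  for (t in tables)
    if (!setequal(names(t), nms)) stop("rater tables cover different groups")
  ref <- tables[[reference]][nms]
  raters <- setdiff(seq_along(tables), reference)
  rows <- do.call(rbind, lapply(raters, function(i) {
    d <- abs(100 * (tables[[i]][nms] - ref) / ref)
    data.frame(rater = i, group = nms, abs_pct_diff = unname(d),
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  perRater <- do.call(rbind, lapply(split(rows, rows$rater), function(d)
    data.frame(rater = d$rater[1], min = min(d$abs_pct_diff),
               max = max(d$abs_pct_diff))))
  perGroup <- do.call(rbind, lapply(split(rows, rows$group), function(d)
    data.frame(group = d$group[1], min = min(d$abs_pct_diff),
               max = max(d$abs_pct_diff))))
  rownames(perRater) <- rownames(perGroup) <- NULL
  list(perGroup = rows,
       range = c(min = min(rows$abs_pct_diff), max = max(rows$abs_pct_diff)),
       perRater = perRater, perGroupRange = perGroup)
}

#' Fraction of one cell type among two
#'
#' a / (a + b), the share of cell type A among the two counted types in a
#' region (the quantity behind per-region pie charts).
#'
#' @param a,b non-negative totals of the two cell types; a + b must be > 0.
#' @return fraction in [0, 1].
#' @export
cellTypeFraction <- function(a, b) {
  if (any(a < 0) || any(b < 0)) stop("counts must be non-negative")
  if (any(a + b == 0))
    stop("fraction is undefined when both counts are zero")
  a / (a + b)
}

#' Cross-species (cross-atlas) density comparison
#'
#' Re-expresses two sets of region estimates (one per atlas) at the level
#' of mapped target regions and compares densities. Target densities are
#' recomputed volume-correctly as summed totals over summed volumes of the
#' mapped source regions, never as averaged densities. The headline
#' statistic is the percent by which atlas A's density is lower than atlas
#' B's, 100 * (1 - dA / dB); negative values mean A is denser.
#'
#' @param estimatesA,estimatesB data.frames from [estimateRegions()] with
#'   leaf-id regions (columns \code{region}, \code{total_estimate},
#'   \code{volume_mm3}).
#' @param mapping data.frame from [readCrossAtlasMapping()].
#' @return data.frame with columns \code{target_acronym},
#'   \code{density_a}, \code{density_b}, \code{pct_lower_a_vs_b},
#'   \code{ratio}, \code{status}; rows with missing source regions carry a
#'   reason code instead of numbers.
#' @export
crossSpeciesTable <- function(estimatesA, estimatesB, mapping) {
  pool <- function(est, ids) {
    idx <- match(as.character(ids), est$region)
    if (anyNA(idx)) return(NULL)
    list(total = sum(est$total_estimate[idx]),
         vol = sum(est$volume_mm3[idx]))
  }
  rows <- lapply(seq_len(nrow(mapping)), function(i) {
    a <- pool(estimatesA, mapping$ids_a[[i]])
    b <- pool(estimatesB, mapping$ids_b[[i]])
    if (is.null(a) || is.null(b))
      return(data.frame(target_acronym = mapping$target_acronym[i],
                        density_a = NA_real_, density_b = NA_real_,
                        pct_lower_a_vs_b = NA_real_, ratio = NA_real_,
                        status = "missing source region",
                        stringsAsFactors = FALSE))
    da <- a$total / a$vol; db <- b$total / b$vol
    data.frame(target_acronym = mapping$target_acronym[i],
               density_a = da, density_b = db,
               pct_lower_a_vs_b = 100 * (1 - da / db),
               ratio = da / db, status = "ok", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' GradientProfile: dorsoventral density trend of one region
#'
#' @slot label region/group label.
#' @slot table data.frame of (axis_coord_mm, density_per_mm3), ordered
#'   dorsal to ventral.
#' @slot rho Spearman rank correlation between dorsoventral order and
#'   density (NA when there are too few sections).
#' @slot classification "decreasing", "increasing", "none" or
#'   "insufficient data".
#' @seealso [gradientProfile()]
#' @export
setClass("GradientProfile", representation(
  label = "character", table = "data.frame", rho = "numeric",
  classification = "character"))

setMethod("show", "GradientProfile", function(object) {
  cat(sprintf("GradientProfile '%s': %d sections, rho = %s -> %s\n",
              object@label, nrow(object@table),
              ifelse(is.na(object@rho), "NA", sprintf("%.3f", object@rho)),
              object@classification))
})

#' Dorsoventral density gradient of one region
#'
#' Computes a per-section density for one region (profiles per mm^3 of the
#' region's sectioned tissue: count / (area_px * pixel_size^2 * T)), orders
#' sections dorsal to ventral by decreasing axis coordinate, and tests for
#' a monotone trend with Spearman's rank correlation between dorsoventral
#' order and density. The trend is classified "decreasing" when
#' rho <= -rhoThreshold, "increasing" when rho >= rhoThreshold, else
#' "none"; being rank-based, the classification is invariant to monotone
#' transforms of the densities. Sections with zero region area are ignored;
#' fewer than \code{minSections} usable sections yield
#' \code{"insufficient data"} rather than an error. Exactly constant
#' densities give rho = 0.
#'
#' @param sectionCounts data.frame with columns \code{axis_coord_mm},
#'   \code{n_profiles}, \code{region_area_px} (one row per section for one
#'   region, e.g. filtered from [countProfiles()] joined with section
#'   coordinates).
#' @param pixelSize pixel edge in micrometers.
#' @param thickness section thickness in micrometers.
#' @param label region label for the result.
#' @param minSections minimum usable sections (default 4).
#' @param rhoThreshold classification threshold on |rho| (default 0.5).
#' @return a [GradientProfile-class].
#' @export
gradientProfile <- function(sectionCounts, pixelSize, thickness,
                            label = "region", minSections = 4,
                            rhoThreshold = 0.5) {
  d <- sectionCounts[sectionCounts$region_area_px > 0, , drop = FALSE]
  d <- d[order(-d$axis_coord_mm), , drop = FALSE]  # dorsal first
  vol_mm3 <- d$region_area_px * (pixelSize / 1000)^2 * (thickness / 1000)
  dens <- d$n_profiles / vol_mm3
  tab <- data.frame(axis_coord_mm = d$axis_coord_mm,
                    density_per_mm3 = dens)
  if (nrow(d) < minSections)
    return(new("GradientProfile", label = label, table = tab,
               rho = NA_real_, classification = "insufficient data"))
  rho <- if (stats::sd(dens) == 0) 0 else
    suppressWarnings(stats::cor(seq_len(nrow(d)), dens, method = "spearman"))
  cls <- if (rho <= -rhoThreshold) "decreasing"
         else if (rho >= rhoThreshold) "increasing" else "none"
  new("GradientProfile", label = label, table = tab, rho = rho,
      classification = cls)
}
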