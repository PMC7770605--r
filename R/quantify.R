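## From per-section profile counts to Abercrombie-corrected, interval-
## extrapolated whole-region totals and atlas-volume densities.

#' Abercrombie's profile-count correction
#'
#' Converts a profile count n observed in sections of thickness T into an
#' estimated cell number N = n * T / (T + D), where D is the mean cell
#' diameter. Sectioning splits cells so that a cell of extent D is seen in
#' (T + D) / T sections on average; the factor inverts that overcounting.
#'
#' @param n profile count(s), >= 0.
#' @param thickness section thickness T in micrometers (> 0).
#' @param diameter mean cell diameter D in micrometers (>= 0).
#' @return corrected (real-valued) count(s).
#' @examples
#' abercrombie(3400, thickness = 40, diameter = 15)  # 2472.727
#' abercrombie(1000, 40, 0)                          # D = 0: identity
#' @export
abercrombie <- function(n, thickness, diameter) {
  if (any(thickness <= 0)) stop("thickness T must be > 0")
  if (any(diameter < 0)) stop("diameter D must be >= 0")
  if (any(n < 0)) stop("profile count n must be >= 0")
  n * thickness / (thickness + diameter)
}

#' Tally non-excluded objects per section and reporting group
#'
#' Counts assigned, non-excluded objects per section for every reporting
#' group of the resolved grouping (plus an \code{"UNASSIGNED"} row for
#' objects overlapping only pixels outside the atlas), and records the
#' group's pixel area in each section. Conservation holds by construction:
#' summed group counts plus unassigned equal the number of non-excluded
#' objects.
#'
#' @param objectsList list of [DetectedObjects-class], parallel to
#'   \code{sections}.
#' @param sections list of [AtlasSection-class].
#' @param grouping named character vector leaf id -> group acronym, as
#'   returned by [resolveGrouping()]; NULL counts per leaf id.
#' @return data.frame with columns \code{section_index}, \code{region},
#'   \code{n_profiles}, \code{region_area_px}, one row per
#'   (section, group), groups with zero objects included.
#' @export
countProfiles <- function(objectsList, sections, grouping = NULL) {
  stopifnot(length(objectsList) == length(sections))
  groups <- if (is.null(grouping)) NULL else sort(unique(grouping))
  rows <- list()
  for (i in seq_along(sections)) {
    sec <- sections[[i]]
    tab <- objectTable(objectsList[[i]])
    tab <- tab[!tab$excluded, , drop = FALSE]
    areas <- regionAreas(sec)
    toGroup <- function(ids) {
      ids <- as.character(ids)
      out <- rep("UNASSIGNED", length(ids))
      if (is.null(grouping)) {
        nz <- ids != "0"
        out[nz] <- ids[nz]
      } else {
        known <- ids %in% names(grouping)
        out[known] <- grouping[ids[known]]
      }
      out
    }
    gAll <- if (is.null(grouping))
      sort(unique(c(as.character(areas$region_id[areas$region_id != 0]),
                    toGroup(tab$region_id)))) else
      sort(unique(c(groups, toGroup(tab$region_id))))
    cnt <- table(factor(toGroup(tab$region_id), levels = gAll))
    areaByGroup <- tapply(areas$pixels,
                          factor(toGroup(areas$region_id), levels = gAll),
                          sum)
    areaByGroup[is.na(areaByGroup)] <- 0
    rows[[i]] <- data.frame(
      section_index = sec@sectionIndex,
      region = gAll,
      n_profiles = as.integer(cnt),
      region_area_px = as.integer(areaByGroup),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Whole-region totals and densities from per-section profile counts
#'
#' For each reporting group: sums raw profile counts across the sampled
#' sections, applies Abercrombie's correction N = n * T / (T + D), then
#' extrapolates to the whole series by multiplying by the sampling interval
#' k, rounding half-up to an integer total. Density is total / volume using
#' the bilateral reference-atlas volume (halved under unilateral scope),
#' never section-derived areas. Groups containing an oversaturated region
#' are emitted with counts suppressed (see [excludeFlagged()]); groups
#' without a volume get a total but no density, with a reason code.
#'
#' @param counts data.frame from [countProfiles()] (columns
#'   \code{section_index}, \code{region}, \code{n_profiles}).
#' @param params a [QuantParams-class].
#' @param ontology optional [RegionOntology-class] supplying volumes and
#'   oversaturation flags.
#' @param grouping named character vector leaf id -> group acronym used to
#'   pool leaf volumes; NULL when \code{counts} is per leaf id.
#' @param scope "unilateral" or "bilateral"; the recorded volume is the
#'   bilateral atlas volume divided by 2 under unilateral scope.
#' @param suppressOversaturated apply [excludeFlagged()] before returning
#'   (default TRUE).
#' @return data.frame with columns \code{region}, \code{n_raw},
#'   \code{n_corrected}, \code{total_estimate}, \code{volume_mm3},
#'   \code{density_per_mm3}, \code{scope}, \code{status}.
#' @examples
#' cnt <- data.frame(section_index = 1, region = "MEC", n_profiles = 3400)
#' p <- quantParams(thickness = 40, diameter = 15, interval = 6)
#' estimateRegions(cnt, p)$total_estimate  # 14836
#' @export
estimateRegions <- function(counts, params, ontology = NULL,
                            grouping = NULL,
                            scope = c("unilateral", "bilateral"),
                            suppressOversaturated = TRUE) {
  scope <- match.arg(scope)
  stopifnot(is(params, "QuantParams"))
  validObject(params)
  n_raw <- tapply(counts$n_profiles, counts$region, sum)
  regions <- names(n_raw)
  n_corr <- abercrombie(as.numeric(n_raw), params@thickness, params@diameter)
  total <- as.integer(roundHalfUp(params@interval * n_corr))

  vol <- rep(NA_real_, length(regions))
  if (!is.null(ontology)) {
    nd <- regionNodes(ontology)
    leaves <- leafIds(ontology)
    leafVol <- stats::setNames(nd$volume_mm3[match(leaves, nd$id)], leaves)
    map <- if (is.null(grouping))
      stats::setNames(as.character(leaves), leaves) else grouping
    for (j in seq_along(regions)) {
      members <- names(map)[map == regions[j]]
      if (length(members) > 0) vol[j] <- sum(leafVol[members])
    }
    if (scope == "unilateral") vol <- vol / 2
  }
  dens <- ifelse(!is.na(vol) & vol > 0, total / vol, NA_real_)
  status <- ifelse(is.na(vol) | vol <= 0, "no volume (density omitted)", "ok")
  status[regions == "UNASSIGNED"] <- "unassigned (outside atlas)"
  out <- data.frame(region = regions, n_raw = as.integer(n_raw),
                    n_corrected = n_corr, total_estimate = total,
                    volume_mm3 = vol, density_per_mm3 = dens,
                    scope = scope, status = status,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (suppressOversaturated && !is.null(ontology))
    out <- excludeFlagged(out, ontology, grouping)
  out
}

#' Merge two unilateral estimates into a bilateral one
#'
#' Raw, corrected and total counts add; the density is recomputed from the
#' full bilateral atlas volume (the sum of the two recorded unilateral
#' half-volumes).
#'
#' @param left,right data.frames from [estimateRegions()] with scope
#'   "unilateral" and identical region sets.
#' @return a bilateral estimate data.frame.
#' @export
bilateralMerge <- function(left, right) {
  if (!all(left$scope == "unilateral") || !all(right$scope == "unilateral"))
    stop("bilateralMerge requires two unilateral estimate sets")
  if (!setequal(left$region, right$region))
    stop("estimate sets cover different regions")
  right <- right[match(left$region, right$region), , drop = FALSE]
  vol <- left$volume_mm3 + right$volume_mm3
  total <- left$total_estimate + right$total_estimate
  data.frame(region = left$region,
             n_raw = left$n_raw + right$n_raw,
             n_corrected = left$n_corrected + right$n_corrected,
             total_estimate = total,
             volume_mm3 = vol,
             density_per_mm3 = ifelse(!is.na(vol) & vol > 0, total / vol,
                                      NA_real_),
             scope = "bilateral",
             status = ifelse(left$status == "ok" & right$status == "ok",
                             "ok", paste(left$status)),
             stringsAsFactors = FALSE)
}

#' Suppress estimates for oversaturated regions
#'
#' Regions whose staining saturates the image cannot be counted validly;
#' their rows remain in the report but all numbers are blanked and the
#' status reads \code{"not reported (oversaturated)"}. The flag propagates
#' down the ontology (a flagged parent suppresses all member leaves) and a
#' group is suppressed when any of its member leaves is affected.
#'
#' @param estimates data.frame from [estimateRegions()].
#' @param ontology a [RegionOntology-class].
#' @param grouping named character vector leaf id -> group acronym, or NULL
#'   when estimates are per leaf id.
#' @return the estimates with suppressed rows.
#' @export
excludeFlagged <- function(estimates, ontology, grouping = NULL) {
  eff <- leafOversaturation(ontology)
  flaggedLeaves <- names(eff)[eff]
  if (length(flaggedLeaves) == 0) return(estimates)
  flaggedGroups <- if (is.null(grouping)) flaggedLeaves else
    unique(grouping[flaggedLeaves])
  hit <- estimates$region %in% flaggedGroups
  estimates$n_raw[hit] <- NA_integer_
  estimates$n_corrected[hit] <- NA_real_
  estimates$total_estimate[hit] <- NA_integer_
  estimates$density_per_mm3[hit] <- NA_real_
  estimates$status[hit] <- "not reported (oversaturated)"
  estimates
}
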