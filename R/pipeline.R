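## Configuration-driven end-to-end runs: extract -> count -> quantify,
## report writing, and a run manifest for reproducibility auditing.

#' Write a tabular report as TSV
#'
#' UTF-8, LF line endings, header row, fixed column order. Integer columns
#' are written plain; real-valued density/percentage/corrected-count
#' columns with two decimals (half-up); NA as empty fields.
#'
#' @param rows data.frame to write.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeReport <- function(rows, path) {
  out <- rows
  twoDec <- grepl("density|pct|n_corrected|ratio|rho|volume", names(out))
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && twoDec[j])
      out[[j]] <- ifelse(is.na(out[[j]]), "",
                         sprintf("%.2f", roundHalfUp(out[[j]], 2)))
    else if (is.numeric(out[[j]]))
      out[[j]] <- ifelse(is.na(out[[j]]), "", format(out[[j]], trim = TRUE,
                                                     scientific = FALSE))
  }
  con <- file(path, "wb")  # binary connection forces LF on every platform
  on.exit(close(con))
  writeLines(c(paste(names(out), collapse = "\t"),
               if (nrow(out) > 0)
                 do.call(paste, c(unname(as.list(out)), sep = "\t"))),
             con, sep = "\n")
  invisible(path)
}

#' Read back a TSV report
#'
#' @param path report path.
#' @return data.frame.
#' @export
readReport <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# validate a pipeline configuration (paths exist, parameters in domain)
.validateConfig <- function(config) {
  req <- c("atlas_dir", "mask_dir", "output_dir", "ontology")
  for (f in req)
    if (is.null(config[[f]])) stop("config field missing: ", f)
  for (f in c("ontology", "atlas_dir", "mask_dir"))
    if (!file.exists(config[[f]]))
      stop("config path does not exist: ", f, " = ", config[[f]])
  if (!is.null(config$grouping) && !file.exists(config$grouping))
    stop("config path does not exist: grouping = ", config$grouping)
  if (!is.null(config$exclusions) && !file.exists(config$exclusions))
    stop("config path does not exist: exclusions = ", config$exclusions)
  q <- config$quant
  if (is.null(q$thickness_um) || is.null(q$diameter_um))
    stop("config$quant needs thickness_um and diameter_um")
  invisible(TRUE)
}

#' Run the full quantification pipeline from a configuration
#'
#' Executes extract -> assign -> exclude -> count -> quantify on a
#' directory of atlas sections (\code{sec_*.flat} + \code{.hdr.json}) and
#' pixel-aligned masks (\code{sec_*.png}), writing \code{objects.tsv},
#' \code{counts.tsv}, \code{region_report.tsv} and \code{manifest.json} to
#' the output directory. The run is deterministic: identical inputs give
#' byte-identical reports. A conservation audit (summed region counts +
#' unassigned + excluded = total extracted objects) is asserted every run
#' and recorded in the manifest.
#'
#' Config (YAML file or list): \code{ontology}, \code{grouping} (optional),
#' \code{exclusions} (optional TSV with columns section, row, col),
#' \code{atlas_dir}, \code{mask_dir}, \code{output_dir};
#' \code{quant: thickness_um, diameter_um, interval, scope};
#' \code{extraction: connectivity, min_size}.
#'
#' @param config path to a YAML config file, or an equivalent named list.
#' @return invisibly, a list with the estimates, counts, objects and the
#'   manifest.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  .validateConfig(config)
  ex <- config$extraction
  connectivity <- if (is.null(ex$connectivity)) 8 else ex$connectivity
  minSize <- if (is.null(ex$min_size)) 4 else ex$min_size
  q <- config$quant
  params <- quantParams(q$thickness_um, q$diameter_um,
                        if (is.null(q$interval)) 1L else q$interval)
  scope <- if (is.null(q$scope)) "unilateral" else q$scope

  ontology <- loadOntology(config$ontology)
  groupingTab <- if (is.null(config$grouping)) NULL else
    readGrouping(config$grouping)
  grouping <- resolveGrouping(ontology, groupingTab)

  flats <- sort(list.files(config$atlas_dir, pattern = "\\.flat$",
                           full.names = TRUE))
  if (length(flats) == 0) stop("no .flat atlas sections in ", config$atlas_dir)
  excl <- if (is.null(config$exclusions)) NULL else
    utils::read.delim(config$exclusions, stringsAsFactors = FALSE)

  sections <- list(); objectsList <- list(); objRows <- list()
  warnings <- character(0)
  nExcluded <- 0L
  for (i in seq_along(flats)) {
    stem <- sub("\\.flat$", "", flats[i])
    sec <- readAtlasSection(flats[i])
    maskPath <- file.path(config$mask_dir, paste0(basename(stem), ".png"))
    if (!file.exists(maskPath)) stop("mask not found for section: ", maskPath)
    mask <- readMask(maskPath)
    obj <- extractObjects(mask, connectivity = connectivity, minSize = minSize)
    obj <- assignRegions(obj, sec)
    if (!is.null(excl)) {
      pts <- excl[excl$section == sec@sectionIndex, c("row", "col"),
                  drop = FALSE]
      if (nrow(pts) > 0) {
        obj <- withCallingHandlers(
          applyExclusions(obj, pts),
          warning = function(w) {
            warnings <<- c(warnings, conditionMessage(w))
            invokeRestart("muffleWarning")
          })
      }
    }
    tab <- objectTable(obj)
    nExcluded <- nExcluded + sum(tab$excluded)
    if (nrow(tab) > 0)
      objRows[[length(objRows) + 1L]] <-
        cbind(section = sec@sectionIndex, tab)
    sections[[i]] <- sec
    objectsList[[i]] <- obj
  }

  counts <- countProfiles(objectsList, sections, grouping)
  estimates <- estimateRegions(counts, params, ontology, grouping,
                               scope = scope)

  nExtracted <- sum(vapply(objectsList,
                           function(o) nrow(objectTable(o)), integer(1)))
  nCounted <- sum(counts$n_profiles)
  if (nCounted + nExcluded != nExtracted)
    stop(sprintf("conservation audit failed: %d counted + %d excluded != %d extracted",
                 nCounted, nExcluded, nExtracted))

  outDir <- config$output_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  objects <- if (length(objRows) > 0) do.call(rbind, objRows) else
    data.frame(section = integer(0), object_id = integer(0),
               pixel_count = integer(0), row = numeric(0), col = numeric(0),
               region_id = integer(0), hemisphere = character(0),
               excluded = logical(0))
  writeReport(objects, file.path(outDir, "objects.tsv"))
  writeReport(counts, file.path(outDir, "counts.tsv"))
  writeReport(estimates, file.path(outDir, "region_report.tsv"))

  manifest <- list(
    tool = "atlasquant",
    version = as.character(utils::packageVersion("atlasquant")),
    config = config,
    input_checksums = list(
      ontology = .fileChecksum(config$ontology),
      grouping = .fileChecksum(config$grouping),
      exclusions = .fileChecksum(config$exclusions),
      atlas_sections = stats::setNames(
        lapply(flats, .fileChecksum), basename(flats))),
    stages = list(sections = length(flats),
                  objects_extracted = nExtracted,
                  objects_excluded = nExcluded,
                  objects_counted = nCounted,
                  count_rows = nrow(counts),
                  estimate_rows = nrow(estimates)),
    conservation = list(counted = nCounted, excluded = nExcluded,
                        extracted = nExtracted, holds = TRUE),
    warnings = warnings)
  # atomic write: manifest appears only once complete
  tmp <- file.path(outDir, ".manifest.json.tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  file.rename(tmp, file.path(outDir, "manifest.json"))

  invisible(list(estimates = estimates, counts = counts, objects = objects,
                 manifest = manifest))
}
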