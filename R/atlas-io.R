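## Atlas label-map I/O: raw little-endian 32-bit "flat" image + JSON header.
## The flat file is row-major with origin top-left; the header carries the
## physical metadata. Round-trips are bit-identical.

.HDR_FIELDS <- c("width", "height", "pixel_size_um", "thickness_um",
                 "section_index", "axis_coord_mm")

#' Write an atlas section to flat + header files
#'
#' Writes \code{<stem>.flat}, the label image as unsigned 32-bit
#' little-endian integers in row-major order (origin top-left), and
#' \code{<stem>.hdr.json} with fields \code{width}, \code{height},
#' \code{pixel_size_um}, \code{thickness_um}, \code{section_index},
#' \code{axis_coord_mm}.
#'
#' @param section an [AtlasSection-class].
#' @param stem output path stem (no extension).
#' @return invisibly, the two paths written.
#' @seealso [readAtlasSection()]
#' @export
writeAtlasSection <- function(section, stem) {
  stopifnot(is(section, "AtlasSection"))
  lab <- section@labels
  flat <- paste0(stem, ".flat")
  hdr <- paste0(stem, ".hdr.json")
  con <- file(flat, "wb")
  on.exit(close(con))
  # t() serializes the column-major R matrix in row-major pixel order
  writeBin(as.integer(t(lab)), con, size = 4L, endian = "little")
  meta <- list(width = ncol(lab), height = nrow(lab),
               pixel_size_um = section@pixelSize,
               thickness_um = section@thickness,
               section_index = section@sectionIndex,
               axis_coord_mm = section@axisCoord)
  jsonlite::write_json(meta, hdr, auto_unbox = TRUE, digits = NA)
  invisible(c(flat = flat, header = hdr))
}

#' Read an atlas section from flat + header files
#'
#' @param flatPath path to the \code{.flat} label image.
#' @param headerPath path to the JSON header; by default derived from
#'   \code{flatPath} by replacing \code{.flat} with \code{.hdr.json}.
#' @return an [AtlasSection-class].
#' @export
readAtlasSection <- function(flatPath,
                             headerPath = sub("\\.flat$", ".hdr.json", flatPath)) {
  if (!file.exists(flatPath)) stop("flat file not found: ", flatPath)
  if (!file.exists(headerPath)) stop("header file not found: ", headerPath)
  meta <- jsonlite::read_json(headerPath, simplifyVector = TRUE)
  unknown <- setdiff(names(meta), .HDR_FIELDS)
  if (length(unknown) > 0)
    stop("unknown header field(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(.HDR_FIELDS, names(meta))
  if (length(missing) > 0)
    stop("missing header field(s): ", paste(missing, collapse = ", "))
  w <- as.integer(meta$width); h <- as.integer(meta$height)
  expected <- as.numeric(w) * h * 4
  actual <- file.size(flatPath)
  if (actual != expected)
    stop(sprintf("flat file size mismatch: %d bytes, expected %d (%d x %d x 4)",
                 actual, as.integer(expected), w, h))
  con <- file(flatPath, "rb")
  on.exit(close(con))
  vals <- readBin(con, what = "integer", n = w * h, size = 4L,
                  endian = "little")
  labels <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  new("AtlasSection", labels = labels,
      sectionIndex = as.integer(meta$section_index),
      pixelSize = as.numeric(meta$pixel_size_um),
      thickness = as.numeric(meta$thickness_um),
      axisCoord = as.numeric(meta$axis_coord_mm),
      hemisphere = NULL)
}

#' Per-region pixel areas of a section
#'
#' Tallies how many pixels each region id covers in the label map,
#' including id 0 (outside the atlas). The counts always sum to
#' width x height.
#'
#' @param section an [AtlasSection-class].
#' @return data.frame with columns \code{region_id}, \code{pixels}, sorted
#'   by id.
#' @export
regionAreas <- function(section) {
  stopifnot(is(section, "AtlasSection"))
  tab <- table(as.vector(section@labels))
  data.frame(region_id = as.integer(names(tab)),
             pixels = as.integer(tab))
}

#' Read a binary segmentation mask from an 8-bit PNG
#'
#' Masks are stored as 8-bit grayscale PNGs with foreground 255 and
#' background 0. Any other pixel value is an error: quantification requires
#' a truly binary mask.
#'
#' @param path path to the PNG.
#' @return integer 0/1 matrix.
#' @export
readMask <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  v <- round(img * 255)
  if (!all(v %in% c(0, 255)))
    stop("mask is not binary (expected only 0 and 255 pixel values): ", path)
  matrix(as.integer(v == 255), nrow = nrow(img))
}

#' Write a binary segmentation mask as an 8-bit PNG
#'
#' @param mask integer/logical 0-1 matrix.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeMask <- function(mask, path) {
  m <- .checkBinaryMask(mask)
  png::writePNG(m * 1.0, path)
  invisible(path)
}

# validate + coerce a binary mask to an integer 0/1 matrix
.checkBinaryMask <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  if (is.logical(mask)) return(matrix(as.integer(mask), nrow = nrow(mask)))
  if (!all(mask %in% c(0, 1)))
    stop("mask is not binary (values other than 0/1 present)")
  matrix(as.integer(mask), nrow = nrow(mask))
}
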