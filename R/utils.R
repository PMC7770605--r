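#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for all user-facing integers and
#' displayed decimals. Base \code{round()} rounds half to even, which would
#' turn e.g. 0.5 into 0; whole-region totals are defined with half-up
#' rounding instead so that results are stable across platforms.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return numeric vector rounded half away from zero.
#' @examples
#' roundHalfUp(2.5)   # 3
#' roundHalfUp(-2.5)  # -3
#' roundHalfUp(1.005, 2)
#' @export
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# scalar positive integer check used by parameter validation
.isCount <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

# md5 of a file, NA-safe; used by the run manifest
.fileChecksum <- function(path) {
  if (is.null(path) || !file.exists(path)) return(NA_character_)
  unname(tools::md5sum(path))
}
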