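#' Parse a length given as "number + unit" into micrometers
#'
#' The unit system is anchored to micrometers. Recognised suffixes are
#' `nm`, `um`, `mm`, `cm` and `px`; whitespace between number and suffix is
#' optional (`"100um"`, `"3 mm"`). Pixel lengths require a pixel scale,
#' usually derived from the platform's center-to-center distance.
#'
#' @param text Character vector of lengths (e.g. `"3 mm"`, `"100um"`) or a
#'   numeric vector, which is taken to be in micrometers already.
#' @param px_per_um Pixels per micrometer; only needed when `text` uses the
#'   `px` suffix.
#' @return Numeric vector of lengths in micrometers.
#' @examples
#' parse_length("1.5 mm")   # 1500
#' parse_length("100um")    # 100
#' parse_length("200px", px_per_um = 2) # 100
#' @export
parse_length <- function(text, px_per_um = NULL) {
  if (is.numeric(text)) {
    return(as.numeric(text))
  }
  stopifnot(is.character(text))
  vapply(text, function(tx) {
    m <- regmatches(tx, regexec("^\\s*([0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?)\\s*(nm|um|mm|cm|px)\\s*$", tx))[[1]]
    if (length(m) == 0) {
      stop("cannot parse length '", tx, "': expected <number><nm|um|mm|cm|px>", call. = FALSE)
    }
    val <- as.numeric(m[2])
    unit <- m[4]
    switch(unit,
      nm = val / 1000,
      um = val,
      mm = val * 1000,
      cm = val * 10000,
      px = {
        if (is.null(px_per_um) || !is.numeric(px_per_um) || px_per_um <= 0) {
          stop("pixel length '", tx, "' needs a positive px_per_um scale", call. = FALSE)
        }
        val / px_per_um
      }
    )
  }, numeric(1), USE.NAMES = FALSE)
}

#' Pixel-to-micrometer scale
#'
#' A minimal unit-scale record: how many pixels correspond to one
#' micrometer, plus where the value came from. When raw coordinates are in
#' pixels, the scale is usually estimated by equating the observed mean
#' nearest-neighbour spacing with the platform's known center-to-center
#' distance.
#'
#' @param px_per_um Positive scalar.
#' @param derivation `"given"` or `"estimated_from_ccd"`.
#' @return An object of class `sgs_unit_scale`.
#' @export
unit_scale <- function(px_per_um, derivation = c("given", "estimated_from_ccd")) {
  derivation <- match.arg(derivation)
  stopifnot(is.numeric(px_per_um), length(px_per_um) == 1, is.finite(px_per_um), px_per_um > 0)
  structure(list(px_per_um = px_per_um, derivation = derivation), class = "sgs_unit_scale")
}

#' @export
print.sgs_unit_scale <- function(x, ...) {
  cat(sprintf("<unit scale> %.6g px/um (%s)\n", x$px_per_um, x$derivation))
  invisible(x)
}
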