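#' Create a spatial trajectory
#'
#' A directed segment from `origin` to `end` with a screening `width`. The
#' screening frame is the closed rectangle spanned by the segment and
#' `width/2` on either side; by convention the width defaults to the
#' trajectory length, so the frame is a square.
#'
#' @param id Trajectory identifier.
#' @param origin,end Numeric length-2 points (x, y) in um.
#' @param width Screening width (um or length string); default = trajectory
#'   length.
#' @return An object of class `sgs_trajectory`.
#' @examples
#' tr <- spatial_trajectory("t1", c(0, 0), c(1000, 0), width = "500um")
#' @export
spatial_trajectory <- function(id, origin, end, width = NULL) {
  origin <- as.numeric(origin); end <- as.numeric(end)
  stopifnot(length(origin) == 2, length(end) == 2, all(is.finite(c(origin, end))))
  len <- sqrt(sum((end - origin)^2))
  if (len <= 0) stop("zero-length trajectory", call. = FALSE)
  width <- if (is.null(width)) len else parse_length(width)
  if (width <= 0) stop("trajectory width must be positive", call. = FALSE)
  structure(
    list(id = as.character(id), origin = origin, end = end, width = width),
    class = "sgs_trajectory"
  )
}

#' @export
print.sgs_trajectory <- function(x, ...) {
  cat(sprintf("<sgs_trajectory> '%s': (%.4g, %.4g) -> (%.4g, %.4g), length %.4g um, width %.4g um\n",
              x$id, x$origin[1], x$origin[2], x$end[1], x$end[2],
              trajectory_length(x), x$width))
  invisible(x)
}

#' Trajectory length in um
#' @param traj An [spatial_trajectory()].
#' @export
trajectory_length <- function(traj) {
  sqrt(sum((traj$end - traj$origin)^2))
}

#' Read or write a trajectory as JSON
#'
#' Format: `{"id": ..., "origin": [x, y], "end": [x, y], "width": w}`,
#' coordinates in micrometers.
#'
#' @param path JSON file path.
#' @return [spatial_trajectory()] for `read_trajectory()`.
#' @export
read_trajectory <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  spatial_trajectory(j$id, j$origin, j$end, width = j$width)
}

#' @rdname read_trajectory
#' @param traj Trajectory to serialize.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "sgs_trajectory"))
  jsonlite::write_json(
    list(id = traj$id, origin = traj$origin, end = traj$end, width = traj$width),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
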