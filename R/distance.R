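#' Distance field along a spatial trajectory
#'
#' Projects every data point onto the trajectory axis. With trajectory
#' vector `T = end - origin` and point offset `C = point - origin`, the
#' scalar projection `s = (C . T) / |T|` is the distance along the
#' trajectory; the perpendicular offset is recorded as well. A point is in
#' scope iff `0 <= s <= |T|` and its absolute offset is at most `width / 2`
#' (the closed trajectory frame).
#'
#' @param traj An [spatial_trajectory()].
#' @param ds An [sgs_dataset()] (or a coordinate tibble with `id`, `x`, `y`).
#' @return A tibble of class `sgs_field` with columns `id`, `distance` (um),
#'   `offset` (signed um), `in_scope`; attributes `type = "trajectory"`,
#'   `ref`, `max_distance`.
#' @examples
#' tr <- spatial_trajectory("t", c(0, 0), c(10, 0), width = 4)
#' co <- tibble::tibble(id = "a", x = 3, y = 1)
#' trajectory_distance(tr, co)  # distance 3, offset 1, in scope
#' @export
trajectory_distance <- function(traj, ds) {
  stopifnot(inherits(traj, "sgs_trajectory"))
  coords <- dataset_coords(ds)
  Tv <- traj$end - traj$origin
  len <- sqrt(sum(Tv^2))
  cx <- coords$x - traj$origin[1]
  cy <- coords$y - traj$origin[2]
  s <- (cx * Tv[1] + cy * Tv[2]) / len
  off <- (Tv[1] * cy - Tv[2] * cx) / len  # signed offset, positive left of the course
  in_scope <- s >= 0 & s <= len & abs(off) <= traj$width / 2
  out <- tibble::tibble(id = coords$id, distance = s, offset = off, in_scope = in_scope)
  structure(out, class = c("sgs_field", class(out)),
            type = "trajectory", ref = traj, max_distance = len)
}

#' Distance field around spatial annotations
#'
#' For each data point: distance 0 if the point lies inside any
#' annotation's area (outer ring minus holes); otherwise the minimum
#' Euclidean distance to any annotation's outline (outer and hole rings).
#' With several annotations the pointwise minimum is taken, so gradients
#' describe proximity to the nearest reference area. A point is in scope
#' iff its distance does not exceed `max_distance`.
#'
#' @param anns A single [spatial_annotation()] or a list of them.
#' @param ds An [sgs_dataset()] (or a coordinate tibble).
#' @param max_distance Screening distance (um or length string), or
#'   `"dte"` to cap at the farthest extent of the point cloud from the
#'   outline (distance-to-edge interpretation).
#' @param dist_mode `"edge"` (point-to-segment minimum, default) or
#'   `"vertex"` (distance to the nearest polygon vertex only).
#' @return A tibble of class `sgs_field` with columns `id`, `distance`,
#'   `inside`, `in_scope`; attributes `type = "annotation"`, `ref`,
#'   `max_distance`.
#' @export
annotation_distance <- function(anns, ds, max_distance, dist_mode = c("edge", "vertex")) {
  dist_mode <- match.arg(dist_mode)
  if (inherits(anns, "sgs_annotation")) anns <- list(anns)
  stopifnot(length(anns) >= 1, all(vapply(anns, inherits, logical(1), "sgs_annotation")))
  coords <- dataset_coords(ds)
  x <- coords$x; y <- coords$y
  inside <- rep(FALSE, length(x))
  dist <- rep(Inf, length(x))
  for (a in anns) {
    inside_a <- points_in_polygon(x, y, a$outer, a$holes)
    rings <- c(list(a$outer), a$holes)
    d_a <- if (dist_mode == "edge") {
      dist_to_segments(x, y, do.call(rbind, lapply(rings, ring_segments)))
    } else {
      dist_to_vertices(x, y, do.call(rbind, rings))
    }
    if (!any(inside_a) && all(d_a > 0)) {
      hull_d <- min(d_a)
      if (hull_d > 0 && !any(inside_a)) {
        # annotation may sit entirely outside the data: warn, keep going
        bb_x <- range(x); bb_y <- range(y)
        out_bb <- all(a$outer[, 1] < bb_x[1]) || all(a$outer[, 1] > bb_x[2]) ||
          all(a$outer[, 2] < bb_y[1]) || all(a$outer[, 2] > bb_y[2])
        if (out_bb) warning("annotation '", a$id, "' lies outside the coordinate hull", call. = FALSE)
      }
    }
    inside <- inside | inside_a
    dist <- pmin(dist, d_a)
  }
  dist[inside] <- 0
  if (identical(max_distance, "dte")) {
    hx <- grDevices::chull(x, y)
    max_distance <- max(dist[hx], 1e-9)
  } else {
    max_distance <- parse_length(max_distance)
  }
  stopifnot(max_distance > 0)
  in_scope <- dist <= max_distance
  out <- tibble::tibble(id = coords$id, distance = dist, inside = inside, in_scope = in_scope)
  structure(out, class = c("sgs_field", class(out)),
            type = "annotation", ref = anns, max_distance = max_distance)
}

dataset_coords <- function(ds) {
  if (inherits(ds, "sgs_dataset")) return(ds$coords)
  coords <- tibble::as_tibble(ds)
  stopifnot(all(c("id", "x", "y") %in% names(coords)))
  coords
}

# points usable for gradient fitting: in scope and (by default) outside the
# annotation interior -- the gradient describes the environment.
field_fit_index <- function(field, include_inside = FALSE) {
  idx <- field$in_scope
  if (!include_inside && "inside" %in% names(field)) idx <- idx & !field$inside
  which(idx)
}
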