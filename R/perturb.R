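#' Perturb a spatial annotation and quantify the deviation
#'
#' Emulates human variability in outlining a reference area. Three modes:
#' `"jitter"` deforms the outline with a smooth random radial field (a few
#' random harmonics around the centroid, relative amplitude `magnitude`);
#' `"rotate"` rotates the outline about its centroid by `magnitude`
#' degrees; `"shift"` translates it by `magnitude` micrometers in a random
#' direction. The deviation score is overlap-based:
#' `100 * (1 - area(intersection) / area(union))` between the original and
#' perturbed areas, i.e. 0% for an identical outline and 100% for disjoint
#' ones.
#'
#' @param ann An [spatial_annotation()].
#' @param mode `"jitter"`, `"rotate"` or `"shift"`.
#' @param magnitude Mode-dependent: relative amplitude (jitter), degrees
#'   (rotate), or micrometers (shift).
#' @param seed RNG seed for the random components.
#' @param max_retries Retries when a jitter draw self-intersects.
#' @return List with `annotation` (the perturbed copy, holes dropped — the
#'   outline is what is perturbed) and `deviation_pct`.
#' @export
perturb_annotation <- function(ann, mode = c("jitter", "rotate", "shift"),
                               magnitude, seed = 1, max_retries = 20) {
  stopifnot(inherits(ann, "sgs_annotation"), is.numeric(magnitude), magnitude >= 0)
  mode <- match.arg(mode)
  set.seed(seed)
  ctr <- polygon_centroid(ann$outer)
  new_outer <- NULL
  if (mode == "rotate") {
    th <- magnitude * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    new_outer <- sweep(sweep(ann$outer, 2, ctr) %*% R, 2, ctr, `+`)
  } else if (mode == "shift") {
    dir <- stats::runif(1, 0, 2 * pi)
    new_outer <- sweep(ann$outer, 2, magnitude * c(cos(dir), sin(dir)), `+`)
  } else {
    for (try in seq_len(max_retries)) {
      rel <- sweep(ann$outer, 2, ctr)
      theta <- atan2(rel[, 2], rel[, 1])
      f <- rep(0, nrow(rel))
      for (k in 1:3) {
        f <- f + stats::rnorm(1) * cos(k * theta) + stats::rnorm(1) * sin(k * theta)
      }
      if (max(abs(f)) > 0) f <- f / max(abs(f))
      cand <- sweep(rel * (1 + magnitude * f), 2, ctr, `+`)
      if (magnitude == 0 || polygon_is_simple(cand)) {
        new_outer <- cand
        break
      }
    }
    if (is.null(new_outer)) {
      stop("jitter produced self-intersecting outlines in every retry", call. = FALSE)
    }
  }
  colnames(new_outer) <- c("x", "y")
  pert <- spatial_annotation(paste0(ann$id, "_", mode), new_outer,
                             tags = ann$tags, source = "programmatic")
  iou <- polygon_iou(ann$outer, ann$holes, pert$outer, pert$holes)
  list(annotation = pert, deviation_pct = 100 * (1 - iou))
}

#' Perturb a spatial trajectory and quantify the deviation
#'
#' `"endpoints"`: displaces start and end by independent Gaussian offsets
#' (sd `magnitude` um); the deviation is the absolute change in trajectory
#' length (um). `"angle"`: displaces the endpoint perpendicular to the
#' course so the trajectory tilts by `magnitude` degrees about its origin
#' (length preserved); deviation in degrees. `"width"`: sets the screening
#' width to `magnitude`; deviation is the new width.
#'
#' @param traj An [spatial_trajectory()].
#' @param mode `"endpoints"`, `"angle"` or `"width"`.
#' @param magnitude See above.
#' @param seed RNG seed (endpoints mode only).
#' @return List with `trajectory` and `deviation` (um, degrees, or um of
#'   width, by mode).
#' @export
perturb_trajectory <- function(traj, mode = c("endpoints", "angle", "width"),
                               magnitude, seed = 1) {
  stopifnot(inherits(traj, "sgs_trajectory"), is.numeric(magnitude))
  mode <- match.arg(mode)
  if (mode == "endpoints") {
    set.seed(seed)
    new <- spatial_trajectory(traj$id,
                              traj$origin + stats::rnorm(2, 0, magnitude),
                              traj$end + stats::rnorm(2, 0, magnitude),
                              width = traj$width)
    dev <- abs(trajectory_length(new) - trajectory_length(traj))
  } else if (mode == "angle") {
    th <- magnitude * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    new_end <- traj$origin + as.numeric(R %*% (traj$end - traj$origin))
    new <- spatial_trajectory(traj$id, traj$origin, new_end, width = traj$width)
    dev <- magnitude
  } else {
    stopifnot(magnitude > 0)
    new <- spatial_trajectory(traj$id, traj$origin, traj$end, width = magnitude)
    dev <- magnitude
  }
  list(trajectory = new, deviation = dev)
}
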