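#' Gradient screening configuration
#'
#' Bundles the geometric screening parameters: total screened distance,
#' resolution (bin width, which also drives the LOESS span), LOESS degree
#' and the correction-factor mode. The LOESS span is
#' `alpha = resolution / (distance * CF)` where `CF` is the fraction of the
#' data points a geometrically complete screening region would contain that
#' actually exist.
#'
#' @param distance Total screened distance (um or length string, e.g.
#'   `"3mm"`).
#' @param resolution Bin width (um or length string); should not exceed the
#'   dataset's center-to-center distance.
#' @param loess_degree Local polynomial degree, 1 or 2 (default 2).
#' @param cf_mode `"annulus"` (annotations), `"rectangle"` (trajectories) or
#'   `"off"` (CF fixed at 1). The driver functions pick the matching mode
#'   automatically; `"off"` disables the correction.
#' @return An object of class `sgs_config`.
#' @examples
#' gradient_config("3mm", "100um")
#' @export
gradient_config <- function(distance, resolution, loess_degree = 2,
                            cf_mode = c("auto", "annulus", "rectangle", "off")) {
  cf_mode <- match.arg(cf_mode)
  distance <- parse_length(distance)
  resolution <- parse_length(resolution)
  stopifnot(distance > 0, resolution > 0, loess_degree %in% 1:2)
  if (resolution > distance) stop("resolution must not exceed distance", call. = FALSE)
  structure(
    list(distance = distance, resolution = resolution,
         loess_degree = as.integer(loess_degree), cf_mode = cf_mode),
    class = "sgs_config"
  )
}

#' @export
print.sgs_config <- function(x, ...) {
  cat(sprintf("<sgs_config> distance %.4g um, resolution %.4g um, degree %d, cf %s\n",
              x$distance, x$resolution, x$loess_degree, x$cf_mode))
  invisible(x)
}

# area of one point's share of an ideal hexagonally packed lattice
hex_area_per_point <- function(ccd) sqrt(3) / 2 * ccd^2

#' Coverage correction factor
#'
#' The fraction of the data points required for a geometrically complete
#' screening region that actually exist. For a trajectory the complete
#' region is the screening rectangle (length x width); for annotations it
#' is the band of width `distance` around the annotation outline (outside
#' the annotation area), whose area is measured by deterministic grid
#' rasterisation so arbitrary polygons and unions of several annotations
#' are handled. The expected count is region area divided by the area per
#' point of an ideal hexagonal lattice, `sqrt(3)/2 * ccd^2`.
#'
#' @param field An `sgs_field` from [annotation_distance()] or
#'   [trajectory_distance()].
#' @param ds The [sgs_dataset()] the field was computed on (supplies the
#'   ccd).
#' @param cfg An [gradient_config()].
#' @return Scalar CF in (0, 1].
#' @export
correction_factor <- function(field, ds, cfg) {
  stopifnot(inherits(field, "sgs_field"), inherits(cfg, "sgs_config"))
  if (cfg$cf_mode == "off") return(1)
  ccd <- if (inherits(ds, "sgs_dataset")) ds$ccd else attr(ds, "ccd")
  stopifnot(is.numeric(ccd), ccd > 0)
  type <- attr(field, "type")
  if (type == "trajectory") {
    traj <- attr(field, "ref")
    len <- min(trajectory_length(traj), cfg$distance)
    region_area <- len * traj$width
  } else {
    region_area <- annulus_area(attr(field, "ref"), cfg$distance, cell = ccd / 2)
  }
  expected <- region_area / hex_area_per_point(ccd)
  if (expected <= 0) stop("expected point count is zero for this screening region", call. = FALSE)
  observed <- length(field_fit_index(field))
  min(1, observed / expected)
}

# area of the band within `distance` of the annotation outline(s), outside
# the annotation area(s); grid-rasterised
annulus_area <- function(anns, distance, cell) {
  if (inherits(anns, "sgs_annotation")) anns <- list(anns)
  verts <- do.call(rbind, lapply(anns, function(a) do.call(rbind, c(list(a$outer), a$holes))))
  xr <- range(verts[, 1]) + c(-distance, distance)
  yr <- range(verts[, 2]) + c(-distance, distance)
  gx <- seq(xr[1] + cell / 2, xr[2], by = cell)
  gy <- seq(yr[1] + cell / 2, yr[2], by = cell)
  g <- expand.grid(x = gx, y = gy)
  inside <- rep(FALSE, nrow(g))
  d <- rep(Inf, nrow(g))
  for (a in anns) {
    inside <- inside | points_in_polygon(g$x, g$y, a$outer, a$holes)
    segs <- do.call(rbind, lapply(c(list(a$outer), a$holes), ring_segments))
    d <- pmin(d, dist_to_segments(g$x, g$y, segs))
  }
  sum(!inside & d <= distance) * cell^2
}

#' LOESS span from resolution, distance and coverage
#'
#' `alpha = resolution / (distance * CF)`, clamped to at most 1 and to a
#' lower bound that keeps at least 4 points in every local window (sparse
#' data would otherwise break the local fit). A warning is emitted when the
#' clamp binds.
#'
#' @param cfg An [gradient_config()].
#' @param cf Correction factor in (0, 1].
#' @param n_points Number of points entering the fit (used for the lower
#'   clamp; omit to skip it).
#' @return The span actually used.
#' @examples
#' loess_alpha(gradient_config("2mm", "100um"), cf = 1)   # 0.05
#' loess_alpha(gradient_config("2mm", "100um"), cf = 0.5) # 0.10
#' @export
loess_alpha <- function(cfg, cf, n_points = NULL) {
  stopifnot(cf > 0, cf <= 1)
  alpha <- cfg$resolution / (cfg$distance * cf)
  alpha_min <- if (is.null(n_points)) 0 else min(1, 4 / n_points)
  out <- min(1, max(alpha, alpha_min))
  if (out != alpha) {
    warning(sprintf("LOESS span clamped from %.4g to %.4g", alpha, out), call. = FALSE)
  }
  out
}

#' Infer a standardized expression gradient
#'
#' Fits a LOESS curve of expression on distance over the in-scope points,
#' partitions `[0, distance]` into bins of width `resolution`, predicts the
#' fitted curve at the mean observed distance of each non-empty bin, and
#' range-standardizes the predictions to `[0, 1]`. A constant curve maps to
#' all 0.5. E.g. screening 3 mm at 0.1 mm resolution yields 30 expression
#' estimates with bin centers near 0.05 mm ... 2.95 mm on fully covered
#' data.
#'
#' @param values Per-point numeric vector aligned with the field rows (or
#'   named by point id).
#' @param field An `sgs_field`.
#' @param cfg An [gradient_config()].
#' @param cf Correction factor; default 1 (use [correction_factor()] to
#'   supply the coverage-corrected value).
#' @param include_inside Include points inside the annotation as a
#'   distance-0 contribution (default FALSE: the gradient describes the
#'   environment).
#' @param variable Variable name carried into metadata and error messages.
#' @return A tibble of class `sgs_gradient` with columns `bin`, `center`
#'   (um) and `estimate` (in `[0, 1]`); attributes `variable`, `alpha`,
#'   `cf`, `n_bins`, `n_points`.
#' @export
infer_gradient <- function(values, field, cfg, cf = 1, include_inside = FALSE,
                           variable = "variable") {
  stopifnot(inherits(field, "sgs_field"), inherits(cfg, "sgs_config"))
  if (!is.null(names(values))) values <- values[field$id]
  stopifnot(length(values) == nrow(field))
  idx <- field_fit_index(field, include_inside = include_inside)
  d <- field$distance[idx]
  v <- values[idx]
  ok <- is.finite(d) & is.finite(v)
  d <- d[ok]; v <- v[ok]
  breaks <- seq(0, cfg$distance, by = cfg$resolution)
  if (breaks[length(breaks)] < cfg$distance) breaks <- c(breaks, cfg$distance)
  bin <- findInterval(d, breaks, rightmost.closed = TRUE, left.open = FALSE)
  bin[d == 0] <- 1L
  n_occupied <- length(unique(bin))
  if (length(d) < 10 || n_occupied < 2) {
    stop(insufficient_coverage(variable))
  }
  alpha <- suppressWarnings(loess_alpha(cfg, cf, n_points = length(d)))
  # regular lattices project many points onto identical distances; loess
  # warns about the resulting ties (pseudoinverse fallback) but the fit is
  # well-defined, so those numerical warnings are muffled
  quiet_ties <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      if (grepl("condition number|singularit|pseudoinverse|neighborhood radius",
                conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  }
  fit <- quiet_ties(
    stats::loess(v ~ d, span = alpha, degree = cfg$loess_degree,
                 family = "gaussian",
                 control = stats::loess.control(surface = "interpolate",
                                                statistics = "none"))
  )
  centers <- tapply(d, bin, mean)
  ord <- order(as.numeric(centers))
  centers <- as.numeric(centers)[ord]
  est <- unname(quiet_ties(stats::predict(fit, newdata = data.frame(d = centers))))
  keep <- is.finite(est)
  centers <- centers[keep]; est <- est[keep]
  if (length(est) < 2) stop(insufficient_coverage(variable))
  rng <- max(est) - min(est)
  # a relative tolerance absorbs the numerical wiggle a LOESS fit leaves on
  # exactly constant input
  est_std <- if (rng <= 1e-8 * (1 + max(abs(est)))) {
    rep(0.5, length(est))
  } else {
    (est - min(est)) / rng
  }
  out <- tibble::tibble(bin = seq_along(centers), center = centers, estimate = est_std)
  structure(out, class = c("sgs_gradient", class(out)),
            variable = variable, alpha = alpha, cf = cf,
            n_bins = length(centers), n_points = length(d))
}

insufficient_coverage <- function(variable) {
  structure(
    class = c("sgs_insufficient_coverage", "error", "condition"),
    list(message = paste0("insufficient coverage for variable '", variable,
                          "': need >= 10 in-scope points spanning >= 2 bins"),
         call = NULL)
  )
}
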