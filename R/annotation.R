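#' Create a spatial annotation
#'
#' A named polygon delimiting a reference area (e.g. a necrotic zone or a
#' wound), optionally with interior holes. Distances in screening are
#' measured from the annotation's outline; points inside the area (outer
#' ring minus holes) get distance zero.
#'
#' @param id Unique annotation identifier.
#' @param outer Matrix or data frame of vertices (columns x, y, in um); the
#'   ring is implicitly closed, do not repeat the first vertex.
#' @param holes List of vertex matrices strictly inside `outer`.
#' @param tags Character vector of free-text tags.
#' @param source One of `"image"`, `"group"`, `"numeric"`, `"programmatic"`.
#' @return An object of class `sgs_annotation`.
#' @examples
#' sq <- spatial_annotation("roi", cbind(c(0, 100, 100, 0), c(0, 0, 100, 100)))
#' @export
spatial_annotation <- function(id, outer, holes = list(), tags = character(),
                               source = c("programmatic", "image", "group", "numeric")) {
  source <- match.arg(source)
  outer <- ring_matrix(outer)
  if (nrow(outer) < 3) stop("annotation outline needs at least 3 vertices", call. = FALSE)
  if (!polygon_is_simple(outer)) stop("annotation outline is self-intersecting", call. = FALSE)
  if (polygon_area(outer) <= 0) stop("annotation outline has zero area", call. = FALSE)
  holes <- lapply(holes, ring_matrix)
  for (h in holes) {
    if (!all(points_in_polygon(h[, 1], h[, 2], outer))) {
      stop("hole vertices must lie strictly inside the annotation outline", call. = FALSE)
    }
    if (!polygon_is_simple(h)) stop("hole ring is self-intersecting", call. = FALSE)
  }
  if (length(holes) > 1) {
    for (i in seq_along(holes)) {
      for (j in seq_along(holes)) {
        if (i < j && any(points_in_polygon(holes[[j]][, 1], holes[[j]][, 2], holes[[i]]))) {
          stop("holes must be pairwise disjoint", call. = FALSE)
        }
      }
    }
  }
  structure(
    list(id = as.character(id), outer = outer, holes = holes,
         tags = as.character(tags), source = source),
    class = "sgs_annotation"
  )
}

ring_matrix <- function(v) {
  m <- as.matrix(as.data.frame(v))
  if (ncol(m) < 2) stop("polygon vertices need x and y columns", call. = FALSE)
  m <- m[, 1:2, drop = FALSE]
  storage.mode(m) <- "double"
  colnames(m) <- c("x", "y")
  # drop a repeated closing vertex if present
  if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  m
}

#' @export
print.sgs_annotation <- function(x, ...) {
  cat(sprintf("<sgs_annotation> '%s' (%s): %d vertices, %d hole(s), area %.4g um^2\n",
              x$id, x$source, nrow(x$outer), length(x$holes), annotation_area(x)))
  invisible(x)
}

#' Area of an annotation (outer ring minus holes), in um^2
#' @param ann An [spatial_annotation()].
#' @export
annotation_area <- function(ann) {
  polygon_area(ann$outer) - sum(vapply(ann$holes, polygon_area, numeric(1)))
}

#' Add an interior hole to an annotation
#'
#' The resulting annotation's area excludes the hole: points inside the hole
#' are no longer inside the annotation and acquire a positive distance to
#' the hole's ring.
#'
#' @param ann Target [spatial_annotation()].
#' @param hole An annotation (its outer ring is used) or a vertex matrix.
#' @return A new `sgs_annotation`.
#' @export
add_hole <- function(ann, hole) {
  stopifnot(inherits(ann, "sgs_annotation"))
  ring <- if (inherits(hole, "sgs_annotation")) hole$outer else ring_matrix(hole)
  if (!all(points_in_polygon(ring[, 1], ring[, 2], ann$outer))) {
    stop("hole is not contained in the annotation outline", call. = FALSE)
  }
  spatial_annotation(ann$id, ann$outer, holes = c(ann$holes, list(ring)),
                     tags = ann$tags, source = ann$source)
}

#' Build an annotation from a point grouping
#'
#' Selects the points carrying `group` in `labels`, removes spatial
#' outliers by density-based clustering (points not reachable from a dense
#' core at radius `eps` are dropped), and outlines the retained points with
#' a concave hull. The returned polygon contains every retained point.
#'
#' @param ds An [sgs_dataset()].
#' @param labels Per-point grouping, either a vector aligned with
#'   `ds$coords` or a name of a row of `ds$expr`.
#' @param group The group label to outline.
#' @param eps Density radius in um; default 1.25 x ccd.
#' @param min_pts Minimum neighbourhood size for a core point.
#' @param concavity Hull concavity; larger values give smoother, more convex
#'   outlines.
#' @param id Annotation id; defaults to the group label.
#' @return An `sgs_annotation` with `source = "group"`.
#' @export
create_group_annotation <- function(ds, labels, group, eps = NULL, min_pts = 3,
                                    concavity = 2, id = group) {
  stopifnot(inherits(ds, "sgs_dataset"))
  if (is.null(eps)) eps <- 1.25 * ds$ccd
  sel <- which(as.character(labels) == group)
  if (length(sel) < min_pts) {
    stop("group '", group, "' has fewer than min_pts = ", min_pts, " members", call. = FALSE)
  }
  outline_points(ds$coords$x[sel], ds$coords$y[sel], eps, min_pts, concavity,
                 id = id, source = "group")
}

#' Build an annotation from a numeric variable
#'
#' Points are selected either by a manual threshold (value >= threshold) or
#' by 2-means clustering on the value vector (the higher-center cluster is
#' kept), then outlined the same way as group annotations: density-based
#' outlier removal followed by a concave hull.
#'
#' @param ds An [sgs_dataset()].
#' @param variable Row name of `ds$expr`.
#' @param method `"kmeans"` or `"threshold"`.
#' @param threshold Required when `method = "threshold"`.
#' @inheritParams create_group_annotation
#' @return An `sgs_annotation` with `source = "numeric"`.
#' @export
create_numeric_annotation <- function(ds, variable, method = c("kmeans", "threshold"),
                                      threshold = NULL, eps = NULL, min_pts = 3,
                                      concavity = 2, id = variable) {
  stopifnot(inherits(ds, "sgs_dataset"))
  method <- match.arg(method)
  if (!variable %in% rownames(ds$expr)) {
    stop("variable '", variable, "' not found", call. = FALSE)
  }
  v <- ds$expr[variable, ]
  if (is.null(eps)) eps <- 1.25 * ds$ccd
  if (method == "threshold") {
    if (is.null(threshold)) stop("threshold method needs a threshold", call. = FALSE)
    sel <- which(v >= threshold)
  } else {
    if (stats::sd(v) == 0) stop("constant variable: k-means binning is degenerate", call. = FALSE)
    km <- stats::kmeans(v, centers = 2, nstart = 5)
    hi <- which.max(km$centers)
    sel <- which(km$cluster == hi)
  }
  if (!length(sel)) stop("empty selection for numeric annotation", call. = FALSE)
  outline_points(ds$coords$x[sel], ds$coords$y[sel], eps, min_pts, concavity,
                 id = id, source = "numeric")
}

outline_points <- function(x, y, eps, min_pts, concavity, id, source) {
  labels <- dbscan_labels(x, y, eps = eps, min_pts = min_pts)
  if (all(labels == 0)) stop("no spatial core: all points flagged as noise", call. = FALSE)
  main <- as.integer(names(which.max(table(labels[labels > 0]))))
  keep <- labels == main
  k0 <- max(3, round(3 * concavity))
  hull <- concave_hull(x[keep], y[keep], k = k0)
  spatial_annotation(id, hull, source = source)
}

# --- GeoJSON I/O ------------------------------------------------------------

#' Read annotations from a GeoJSON file
#'
#' Expects a FeatureCollection of Polygon features (first ring outer,
#' subsequent rings holes), coordinates in micrometers, with `id`, `tags`
#' and `source` in the feature properties.
#'
#' @param path GeoJSON file path.
#' @return List of [spatial_annotation()] objects.
#' @export
read_annotations <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  lapply(feats, function(f) {
    geom <- f$geometry
    if (!identical(geom$type, "Polygon")) stop("only Polygon features supported", call. = FALSE)
    rings <- lapply(geom$coordinates, function(r) {
      do.call(rbind, lapply(r, function(p) c(p[[1]], p[[2]])))
    })
    props <- f$properties
    spatial_annotation(
      id = props$id %||% "annotation",
      outer = rings[[1]],
      holes = rings[-1],
      tags = unlist(props$tags) %||% character(),
      source = props$source %||% "programmatic"
    )
  })
}

#' Write annotations to a GeoJSON file
#' @param anns A single annotation or a list of them.
#' @param path Output path.
#' @export
write_annotations <- function(anns, path) {
  if (inherits(anns, "sgs_annotation")) anns <- list(anns)
  feats <- lapply(anns, function(a) {
    rings <- c(list(a$outer), a$holes)
    coords <- lapply(rings, function(r) {
      r <- close_ring(r)
      lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
    })
    list(
      type = "Feature",
      properties = list(id = a$id, tags = as.list(a$tags), source = a$source),
      geometry = list(type = "Polygon", coordinates = coords)
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
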