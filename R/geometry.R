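# Low-level planar geometry used by annotations, distance fields and the
# perturbation machinery. Polygons are n x 2 matrices of vertices (not
# repeating the first vertex); rings are implicitly closed.

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  abs(sum(x * y2 - x2 * y)) / 2
}

polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x), mean(y)))
  c(sum((x + x2) * cr) / (6 * a), sum((y + y2) * cr) / (6 * a))
}

# segment-segment proper/improper intersection test (excluding shared endpoints
# of adjacent edges is handled by the caller)
segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  (d1 == 0 && on_seg(p3, p4, p1)) || (d2 == 0 && on_seg(p3, p4, p2)) ||
    (d3 == 0 && on_seg(p1, p2, p3)) || (d4 == 0 && on_seg(p1, p2, p4))
}

polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  idx <- cbind(seq_len(n), c(seq_len(n)[-1], 1))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # skip adjacent edges (shared vertex)
      if (j == i + 1 || (i == 1 && j == n)) next
      if (segments_intersect(poly[idx[i, 1], ], poly[idx[i, 2], ],
                             poly[idx[j, 1], ], poly[idx[j, 2], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# ring as closed loop for mgcv::in.out
close_ring <- function(poly) rbind(poly, poly[1, , drop = FALSE])

# points-in-polygon with optional holes (even-odd rule)
points_in_polygon <- function(x, y, outer, holes = list()) {
  bnd <- close_ring(outer)
  for (h in holes) bnd <- rbind(bnd, c(NA, NA), close_ring(h))
  mgcv::in.out(bnd, cbind(x, y))
}

# minimum distance from each point to a set of segments.
# segs: matrix with columns x1, y1, x2, y2. Vectorized over points, looped
# over segments in blocks to bound memory.
dist_to_segments <- function(x, y, segs) {
  n <- length(x)
  best <- rep(Inf, n)
  for (k in seq_len(nrow(segs))) {
    ax <- segs[k, 1]; ay <- segs[k, 2]; bx <- segs[k, 3]; by <- segs[k, 4]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx * dx + dy * dy
    if (len2 == 0) {
      d <- sqrt((x - ax)^2 + (y - ay)^2)
    } else {
      t <- ((x - ax) * dx + (y - ay) * dy) / len2
      t <- pmin(1, pmax(0, t))
      px <- ax + t * dx; py <- ay + t * dy
      d <- sqrt((x - px)^2 + (y - py)^2)
    }
    best <- pmin(best, d)
  }
  best
}

dist_to_vertices <- function(x, y, verts) {
  best <- rep(Inf, length(x))
  for (k in seq_len(nrow(verts))) {
    best <- pmin(best, sqrt((x - verts[k, 1])^2 + (y - verts[k, 2])^2))
  }
  best
}

ring_segments <- function(poly) {
  p2 <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE])
  cbind(poly[, 1], poly[, 2], p2[, 1], p2[, 2])
}

# --- density-based clustering (DBSCAN, direct O(n^2) implementation) -------
# Returns integer cluster labels, 0 = noise. Border points join the first
# core cluster that reaches them, as in the reference algorithm.
dbscan_labels <- function(x, y, eps, min_pts) {
  n <- length(x)
  d <- as.matrix(stats::dist(cbind(x, y)))
  neighbors <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  is_core <- vapply(neighbors, length, integer(1)) >= min_pts
  labels <- integer(n)  # 0 = unvisited/noise
  cluster <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !is_core[i]) next
    cluster <- cluster + 1L
    queue <- i
    labels[i] <- cluster
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (is_core[j]) {
        for (k in neighbors[[j]]) {
          if (labels[k] == 0L) {
            labels[k] <- cluster
            queue <- c(queue, k)
          }
        }
      }
    }
  }
  labels
}

# --- concave hull (Moreira & Santos k-nearest-neighbour algorithm) ---------
# Walks the boundary choosing, among the k nearest unused points, the one
# with the largest right-hand turn that does not intersect the hull built so
# far. k escalates (eventually reaching n, i.e. the convex hull) until a
# simple polygon containing all points is produced.
concave_hull <- function(x, y, k = 8) {
  pts <- unique(cbind(x, y))
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 distinct points for a hull", call. = FALSE)
  if (n == 3) return(pts)
  k <- max(3, min(k, n - 1))
  while (k < n) {
    hull <- try(concave_hull_k(pts, k), silent = TRUE)
    if (!inherits(hull, "try-error") && !is.null(hull) &&
        all(points_in_or_on(pts[, 1], pts[, 2], hull, tol = 1e-9))) {
      return(hull)
    }
    k <- min(n, k + max(1, k %/% 2))
  }
  pts[rev(grDevices::chull(pts[, 1], pts[, 2])), , drop = FALSE]
}

points_in_or_on <- function(x, y, poly, tol = 1e-9) {
  inside <- points_in_polygon(x, y, poly)
  on_edge <- dist_to_segments(x, y, ring_segments(poly)) <= tol
  inside | on_edge
}

concave_hull_k <- function(pts, k) {
  n <- nrow(pts)
  used <- rep(FALSE, n)
  start <- which.min(pts[, 2])  # lowest point
  hull_idx <- start
  used[start] <- TRUE
  cur <- start
  prev_angle <- 0  # direction we came from, radians
  for (step in seq_len(10 * n)) {
    if (step > 4) used[start] <- FALSE  # allow closing the ring
    cand <- which(!used)
    if (!length(cand)) return(NULL)
    dd <- sqrt((pts[cand, 1] - pts[cur, 1])^2 + (pts[cand, 2] - pts[cur, 2])^2)
    near <- cand[order(dd)[seq_len(min(k, length(cand)))]]
    ang <- atan2(pts[near, 2] - pts[cur, 2], pts[near, 1] - pts[cur, 1])
    turn <- (prev_angle - ang) %% (2 * pi)  # rightmost turn first
    near <- near[order(turn, decreasing = TRUE)]
    nxt <- NA_integer_
    for (cd in near) {
      seg_new <- c(pts[cur, ], pts[cd, ])
      crosses <- FALSE
      m <- length(hull_idx)
      if (m >= 2) {
        for (e in seq_len(m - 1)) {
          # skip edge sharing current vertex
          if (e == m - 1) next
          if (hull_idx[e] == cd || hull_idx[e + 1] == cd) next
          if (segments_intersect(pts[hull_idx[e], ], pts[hull_idx[e + 1], ],
                                 pts[cur, ], pts[cd, ])) {
            crosses <- TRUE
            break
          }
        }
      }
      if (!crosses) { nxt <- cd; break }
    }
    if (is.na(nxt)) return(NULL)
    if (nxt == start) {
      hull <- pts[hull_idx, , drop = FALSE]
      if (nrow(hull) >= 3 && polygon_is_simple(hull)) return(hull)
      return(NULL)
    }
    prev_angle <- atan2(pts[cur, 2] - pts[nxt, 2], pts[cur, 1] - pts[nxt, 1])
    hull_idx <- c(hull_idx, nxt)
    used[nxt] <- TRUE
    cur <- nxt
  }
  NULL
}

# --- grid-rasterised polygon overlap ---------------------------------------
# Fraction-of-grid estimates of intersection-over-union between two polygon
# areas (each possibly with holes). Deterministic: same grid for both.
polygon_iou <- function(outer1, holes1, outer2, holes2, n_cells = 360) {
  all_x <- c(outer1[, 1], outer2[, 1], unlist(lapply(c(holes1, holes2), function(h) h[, 1])))
  all_y <- c(outer1[, 2], outer2[, 2], unlist(lapply(c(holes1, holes2), function(h) h[, 2])))
  xr <- range(all_x); yr <- range(all_y)
  step <- max(diff(xr), diff(yr)) / n_cells
  if (step <= 0) return(1)
  gx <- seq(xr[1] + step / 2, xr[2], by = step)
  gy <- seq(yr[1] + step / 2, yr[2], by = step)
  g <- expand.grid(x = gx, y = gy)
  in1 <- points_in_polygon(g$x, g$y, outer1, holes1)
  in2 <- points_in_polygon(g$x, g$y, outer2, holes2)
  un <- sum(in1 | in2)
  if (un == 0) return(1)
  sum(in1 & in2) / un
}
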