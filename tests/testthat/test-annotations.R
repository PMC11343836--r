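test_that("distance to a unit-square annotation matches the axis distance", {
  sq <- unit_square_ann()
  co <- tibble::tibble(id = c("right", "center", "diag"),
                       x = c(2, 0.5, 2), y = c(0.5, 0.5, 2))
  f <- annotation_distance(sq, co, max_distance = 3)
  expect_equal(f$distance[1], 1)                 # 1 right of the edge
  expect_equal(f$distance[2], 0)                 # centroid: inside
  expect_true(f$inside[2])
  expect_equal(f$distance[3], sqrt(2), tolerance = 1e-12)  # corner distance
  expect_true(all(f$in_scope))
  f2 <- annotation_distance(sq, co, max_distance = 1.2)
  expect_false(f2$in_scope[3])
})

test_that("multiple annotations screen the pointwise minimum distance", {
  a1 <- unit_square_ann("a1")
  a2 <- unit_square_ann("a2", at = c(5, 0))
  co <- tibble::tibble(id = c("p1", "p2"), x = c(2, 3.8), y = c(0.5, 0.5))
  f <- suppressWarnings(annotation_distance(list(a1, a2), co, max_distance = 10))
  expect_equal(f$distance[1], 1)    # nearer a1
  expect_equal(f$distance[2], 1.2)  # nearer a2 (distance to x = 5)
})

test_that("edge distance equals the per-edge closed form on convex polygons", {
  set.seed(7)
  poly <- circle_poly(c(0, 0), 10, n = 12)
  ann <- spatial_annotation("c", poly)
  co <- tibble::tibble(id = paste0("p", 1:40),
                       x = runif(40, -25, 25), y = runif(40, -25, 25))
  f <- annotation_distance(ann, co, max_distance = 100)
  # oracle: minimize the analytic point-to-segment distance over every edge
  oracle <- sapply(seq_len(nrow(co)), function(i) {
    p <- c(co$x[i], co$y[i])
    n <- nrow(poly)
    min(sapply(seq_len(n), function(k) {
      a <- poly[k, ]; b <- poly[if (k == n) 1 else k + 1, ]
      ab <- b - a
      t <- max(0, min(1, sum((p - a) * ab) / sum(ab^2)))
      sqrt(sum((p - a - t * ab)^2))
    }))
  })
  inside <- f$inside
  expect_equal(f$distance[!inside], oracle[!inside], tolerance = 1e-9)
  expect_true(all(f$distance[inside] == 0))
})

test_that("annotation distances are equivariant under rigid motion", {
  set.seed(11)
  poly <- circle_poly(c(300, 200), 80, n = 20)
  co <- tibble::tibble(id = paste0("p", 1:60),
                       x = runif(60, 0, 600), y = runif(60, 0, 600))
  f0 <- annotation_distance(spatial_annotation("a", poly), co, max_distance = 1e4)
  th <- 2.1; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  shift <- c(-37, 1200)
  poly2 <- sweep(poly %*% R, 2, shift, `+`)
  rot <- as.matrix(co[, c("x", "y")]) %*% R
  co2 <- tibble::tibble(id = co$id, x = rot[, 1] + shift[1], y = rot[, 2] + shift[2])
  f2 <- annotation_distance(spatial_annotation("a", poly2), co2, max_distance = 1e4)
  expect_equal(f2$distance, f0$distance, tolerance = 1e-6)
  expect_equal(f2$inside, f0$inside)
})

test_that("vertex distance mode is an upper bound on edge distance", {
  poly <- circle_poly(c(0, 0), 10, n = 8)
  ann <- spatial_annotation("c", poly)
  co <- tibble::tibble(id = "p", x = 12, y = 0)
  fe <- suppressWarnings(annotation_distance(ann, co, max_distance = 100, dist_mode = "edge"))
  fv <- suppressWarnings(annotation_distance(ann, co, max_distance = 100, dist_mode = "vertex"))
  expect_gte(fv$distance, fe$distance)
  expect_equal(fv$distance, 2)  # (12,0) to vertex (10,0)
})

test_that("holes carve the annotation area", {
  outer <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  hole <- cbind(c(4, 6, 6, 4), c(4, 4, 6, 6))
  ann <- add_hole(spatial_annotation("sq", outer), hole)
  co <- tibble::tibble(id = c("hole_center", "annulus"), x = c(5, 2), y = c(5, 2))
  f <- annotation_distance(ann, co, max_distance = 50)
  expect_false(f$inside[1])
  expect_equal(f$distance[1], 1)  # to the hole ring
  expect_true(f$inside[2])
  expect_equal(f$distance[2], 0)
})

test_that("a hole outside the outline is rejected", {
  ann <- unit_square_ann()
  expect_error(add_hole(ann, cbind(c(0.5, 3, 3), c(0.5, 0.5, 3))), "not contained")
})

test_that("annotation invariants are enforced", {
  expect_error(spatial_annotation("bad", cbind(c(0, 1), c(0, 1))), "3 vertices")
  bowtie <- cbind(c(0, 1, 1, 0), c(0, 1, 0, 1))
  expect_error(spatial_annotation("bad", bowtie), "self-intersecting")
})

test_that("an annotation outside the point cloud warns but does not abort", {
  ann <- unit_square_ann(at = c(100, 100))
  co <- tibble::tibble(id = c("a", "b"), x = c(0, 1), y = c(0, 1))
  expect_warning(annotation_distance(ann, co, max_distance = 1000), "outside")
})

test_that("annotations round-trip through GeoJSON with holes and tags", {
  outer <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  hole <- cbind(c(4, 6, 6, 4), c(4, 4, 6, 6))
  ann <- spatial_annotation("necrotic", outer, holes = list(hole),
                            tags = c("necrosis", "core"), source = "image")
  p <- withr::local_tempfile(fileext = ".geojson")
  write_annotations(ann, p)
  back <- read_annotations(p)[[1]]
  expect_equal(back$id, "necrotic")
  expect_equal(back$outer, ann$outer, ignore_attr = TRUE)
  expect_equal(back$holes[[1]], hole, ignore_attr = TRUE)
  expect_equal(back$tags, c("necrosis", "core"))
  expect_equal(back$source, "image")
})

test_that("group annotations drop stragglers and contain every retained point", {
  set.seed(3)
  th <- runif(50, 0, 2 * pi); r <- sqrt(runif(50)) * 150  # tight disc: one density core
  core <- tibble::tibble(x = 1000 + r * cos(th), y = 1000 + r * sin(th))
  straggler <- tibble::tibble(x = 1000 + 10 * 100, y = 1000)  # 10 x ccd away
  other <- tibble::tibble(x = runif(60, 2500, 4000), y = runif(60, 2500, 4000))
  coords <- dplyr::bind_rows(core, straggler, other)
  coords <- tibble::tibble(id = paste0("p", seq_len(nrow(coords))),
                           x = coords$x, y = coords$y)
  labels <- c(rep("roi", 51), rep("bg", 60))
  expr <- matrix(0, 1, nrow(coords), dimnames = list("g", coords$id))
  ds <- sgs_dataset(coords, expr, ccd = 100)
  ann <- create_group_annotation(ds, labels, "roi")
  inside <- sgscreen:::points_in_or_on(core$x, core$y, ann$outer, tol = 1e-6)
  expect_true(all(inside))                     # all 50 core points contained
  expect_false(sgscreen:::points_in_or_on(straggler$x, straggler$y, ann$outer, tol = 1e-6))
  expect_equal(ann$source, "group")
})

test_that("group annotation contracts are enforced", {
  co <- make_lattice("1mm", "1mm")
  expr <- matrix(0, 1, nrow(co), dimnames = list("g", co$id))
  ds <- sgs_dataset(co, expr, ccd = 100)
  labels <- rep("a", nrow(co)); labels[1:2] <- "tiny"
  expect_error(create_group_annotation(ds, labels, "tiny", min_pts = 3), "fewer than")
  # all members isolated from each other -> no core
  labels2 <- rep("a", nrow(co))
  far <- order(co$x + co$y)[c(1, nrow(co))]
  labels2[far] <- "spread"
  expect_error(create_group_annotation(ds, labels2, "spread", eps = 10, min_pts = 2),
               "no spatial core")
})

test_that("numeric annotations recover a step-function disc", {
  co <- make_lattice("3mm", "3mm")
  inside_disc <- sqrt((co$x - 1500)^2 + (co$y - 1500)^2) <= 500
  expr <- matrix(as.numeric(inside_disc), 1, nrow(co), dimnames = list("marker", co$id))
  ds <- sgs_dataset(co, expr, ccd = 100)
  for (method in c("threshold", "kmeans")) {
    ann <- create_numeric_annotation(ds, "marker", method = method, threshold = 0.5)
    hit <- sgscreen:::points_in_or_on(co$x[inside_disc], co$y[inside_disc],
                                      ann$outer, tol = 1e-6)
    expect_true(all(hit))
    # the outline stays close to the disc: no point farther than ~1 ccd out
    out_pts <- sgscreen:::points_in_polygon(co$x[!inside_disc], co$y[!inside_disc], ann$outer)
    d_out <- sqrt((co$x[!inside_disc][out_pts] - 1500)^2 + (co$y[!inside_disc][out_pts] - 1500)^2)
    if (length(d_out)) expect_lt(max(d_out), 500 + 150)
  }
})

test_that("numeric annotation removes bright outliers before outlining", {
  co <- make_lattice("3mm", "3mm")
  inside_disc <- sqrt((co$x - 1000)^2 + (co$y - 1000)^2) <= 400
  v <- as.numeric(inside_disc)
  corner <- order(-(co$x + co$y))[1:2]  # two distant bright spots
  v[corner] <- 1
  expr <- matrix(v, 1, nrow(co), dimnames = list("marker", co$id))
  ds <- sgs_dataset(co, expr, ccd = 100)
  ann <- create_numeric_annotation(ds, "marker", method = "threshold", threshold = 0.5)
  expect_false(any(sgscreen:::points_in_polygon(co$x[corner], co$y[corner], ann$outer)))
})

test_that("degenerate numeric annotations are fatal", {
  co <- make_lattice("1mm", "1mm")
  expr <- matrix(1, 1, nrow(co), dimnames = list("const", co$id))
  ds <- sgs_dataset(co, expr, ccd = 100)
  expect_error(create_numeric_annotation(ds, "const", method = "kmeans"), "constant")
  expect_error(create_numeric_annotation(ds, "const", method = "threshold", threshold = 5),
               "empty selection")
})
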