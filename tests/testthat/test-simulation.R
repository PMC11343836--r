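test_that("hex lattices have the expected density and spacing", {
  co <- make_lattice("1mm", "1mm", ccd = 100)
  # ideal hex density: area / (sqrt(3)/2 ccd^2) ~ 115 points, plus boundary
  expect_gt(nrow(co), 0.85 * 115)
  expect_lt(nrow(co), 1.25 * 115)
  expect_equal(estimate_ccd(co), 100, tolerance = 1e-9)
})

test_that("masking removes about the masked share of points", {
  full <- make_lattice("2mm", "2mm")
  half_mask <- cbind(c(-1, 2001, 2001, -1), c(-1, -1, 1000, 1000))
  half <- make_lattice("2mm", "2mm", mask = half_mask)
  expect_equal(nrow(half) / nrow(full), 0.5, tolerance = 0.1)
})

test_that("patterns paint identical values within a distance bin", {
  sc <- small_scene()
  v <- simulate_pattern(sc$field, list(values = c(1, 0)), binwidth = 750)
  d <- pmin(sc$field$distance, attr(sc$field, "max_distance"))
  bin <- findInterval(d, c(0, 750, 1500), rightmost.closed = TRUE)
  bin[d == 0] <- 1
  expect_true(all(tapply(v, bin, function(z) length(unique(z)) == 1)))
  # two bins, pattern [1, 0]: inner high, outer low
  expect_equal(unname(unique(v[bin == 1])), 1)
  expect_equal(unname(unique(v[bin == 2])), 0)
  vc <- simulate_pattern(sc$field, list(values = c(0.4, 0.4)), binwidth = 750)
  expect_true(all(vc == vc[1]))  # constant pattern -> constant values
})

test_that("the simulator and screener are adjoint on noiseless patterns", {
  sc <- small_scene()
  cf <- correction_factor(sc$field, sc$ds, sc$cfg)
  for (tm in simulation_templates()) {
    v <- simulate_pattern(sc$field, tm, sc$cfg$resolution)
    g <- infer_gradient(v, sc$field, sc$cfg, cf = cf)
    f <- fit_models(g, default_models(attr(g, "n_bins")))
    expect_lt(f$rmse[f$model == tm$name], 0.05)
  }
})

test_that("zero noise is the identity and 100% ED noise erases the pattern", {
  sc <- small_scene()
  tm <- simulation_templates()
  v1 <- simulate_pattern(sc$field, tm$desc_linear, 100)
  v2 <- simulate_pattern(sc$field, tm$asc_linear, 100)
  for (ty in c("ED", "EP", "FP", "Combined")) {
    expect_identical(apply_noise(v1, ty, 0, seed = 3, coords = sc$coords), v1)
  }
  # at 100% ED the output is independent of the underlying pattern
  n1 <- apply_noise(v1, "ED", 100, seed = 5, coords = sc$coords)
  n2 <- apply_noise(v2, "ED", 100, seed = 5, coords = sc$coords)
  expect_equal(unname(n1), unname(n2), tolerance = 1e-12)
  expect_error(apply_noise(v1, "ED", 150), "0, 100")
})

test_that("EP noise replaces exactly the prescribed number of points", {
  # non-degenerate value range so replacement draws differ almost surely
  v <- stats::setNames(seq(0, 1, length.out = 200), paste0("p", 1:200))
  out <- apply_noise(v, "EP", 50, seed = 8)
  expect_equal(sum(out != v), 100)
  out2 <- apply_noise(v, "EP", 1, seed = 8)
  expect_equal(sum(out2 != v), 2)  # ceiling(0.01 * 200)
})

test_that("FP noise forms spatial niches of the prescribed size", {
  co <- make_lattice("3mm", "3mm")
  v <- stats::setNames(seq(0, 1, length.out = nrow(co)), co$id)
  out <- apply_noise(v, "FP", 30, seed = 4, coords = co, fp_niche_radius = 300)
  changed <- which(out != v)
  expect_equal(length(changed), ceiling(0.3 * nrow(co)))
  # changed points cluster: their mean nearest-neighbour distance stays at
  # the lattice constant, far below that of a random scatter of equal size
  nn <- sgscreen:::nn_distances(co$x[changed], co$y[changed])
  expect_lt(mean(nn), 150)
})

test_that("noise is reproducible per seed and varies across iterations", {
  sc <- small_scene()
  v <- simulate_pattern(sc$field, simulation_templates()$desc_linear, 100)
  a <- apply_noise(v, "ED", 40, seed = 77, coords = sc$coords)
  b <- apply_noise(v, "ED", 40, seed = 77, coords = sc$coords)
  expect_identical(a, b)
  c2 <- apply_noise(v, "ED", 40, seed = 78, coords = sc$coords)
  expect_false(identical(a, c2))
})

test_that("simulation names round-trip through the naming syntax", {
  nm <- sim_name("desc_linear", "ED", 42, 7)
  expect_equal(nm, "SE.desc_linear.ED.42.7")
  p <- parse_sim_name(nm)
  expect_equal(p$pattern, "desc_linear")
  expect_equal(p$noise_type, "ED")
  expect_equal(p$noise_pct, 42)
  expect_equal(p$iteration, 7L)
  expect_false(p$ground_truth_random)
  expect_true(parse_sim_name(sim_name("x", "FP", 100, 1))$ground_truth_random)
  expect_error(parse_sim_name("not.a.name"), "not a simulation name")
})

test_that("benchmark grids enumerate the full cartesian product", {
  tm <- simulation_templates()
  full <- benchmark_combinations(tm, c("ED", "EP", "FP", "Combined"),
                                 seq(0, 100, by = 2), 50)
  expect_equal(nrow(full), 61200)
  small <- benchmark_combinations(names(tm)[1:2], c("ED", "Combined"),
                                  seq(0, 100, by = 10), 3)
  expect_equal(nrow(small), 132)
  expect_equal(sum(full$ground_truth_random), 6 * 4 * 50)
})

test_that("a small benchmark run returns one TV per simulation", {
  sc <- small_scene()
  b <- run_benchmark_grid(sc$ds, sc$field, sc$cfg,
                          patterns = simulation_templates()[c(1, 5)],
                          noise_types = "ED", pct_grid = c(0, 100),
                          iterations = 1, seed = 5, n_sim = 50)
  expect_equal(nrow(b), 4)
  expect_true(all(is.finite(b$tot_var)))
  expect_true(all(b$p_value >= 0 & b$p_value <= 1))
  expect_true(all(b$fdr >= b$p_value - 1e-12))
  # noiseless patterns are smoother than pure noise
  expect_true(all(b$tot_var[b$noise_pct == 0] < b$tot_var[b$noise_pct == 100]))
})

test_that("TV increases with the noise level within each stratum", {
  sc <- small_scene()
  b <- run_benchmark_grid(sc$ds, sc$field, sc$cfg,
                          patterns = simulation_templates()["desc_linear"],
                          noise_types = c("ED", "EP"),
                          pct_grid = seq(0, 100, by = 5), iterations = 5,
                          seed = 13, n_sim = 0)
  rho <- b |>
    dplyr::group_by(noise_type) |>
    dplyr::summarise(rho = stats::cor(noise_pct, tot_var, method = "spearman"))
  expect_true(all(rho$rho > 0.5))
})

test_that("reliability R^2 is high when noise levels separate cleanly", {
  sc <- small_scene()
  r2 <- estimate_r2(sc$ds, sc$field, sc$cfg, noise_types = "ED",
                    patterns = simulation_templates()["desc_linear"],
                    pct_grid = c(0, 100), iterations = 5, seed = 2)
  expect_gt(r2$r2, 0.9)
  expect_warning(
    r2c <- estimate_r2(sc$ds, sc$field, sc$cfg, noise_types = "ED",
                       patterns = simulation_templates()["desc_linear"],
                       pct_grid = 50, iterations = 3, seed = 2),
    "undefined")
  expect_true(is.na(r2c$r2))
})
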