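# end-to-end behaviour of the SAS and STS drivers on simulated data

simulated_dataset <- function(sc, seed = 1) {
  tm <- simulation_templates()
  base_desc <- simulate_pattern(sc$field, tm$desc_linear, 100)
  base_peak <- simulate_pattern(sc$field, tm$peak_50_broad, 100)
  expr <- rbind(
    desc_clean = base_desc,
    peak_clean = base_peak,
    noisy = apply_noise(base_desc, "ED", 100, seed = seed + 1),
    zero_heavy = {
      v <- rep(0, nrow(sc$coords)); v[1:10] <- 90; v
    }
  )
  colnames(expr) <- sc$coords$id
  sgs_dataset(sc$coords, expr, ccd = 100)
}

test_that("annotation screening separates clean patterns from noise", {
  sc <- small_scene()
  ds <- simulated_dataset(sc)
  res <- spatial_annotation_screening(ds, sc$ann, sc$cfg, n_sim = 300, seed = 42)
  df <- tidy(res)
  clean <- df[df$variable %in% c("desc_clean", "peak_clean"), ]
  expect_true(all(clean$fdr == 0))
  expect_equal(clean$best_class[clean$variable == "desc_clean"], "descending")
  expect_equal(clean$best_class[clean$variable == "peak_clean"], "peaking")
  expect_true(all(clean$significant))
  noisy <- df[df$variable == "noisy", ]
  expect_gt(noisy$fdr, 0.05)
  zi <- df[df$variable == "zero_heavy", ]
  expect_true(zi$zero_inflated)
  expect_true(is.na(zi$fdr))
  # glance reports the run-level facts
  gl <- glance(res)
  expect_equal(gl$n_variables, 4)
  expect_equal(gl$n_zero_inflated, 1)
  expect_equal(gl$n_sim, 300)
})

test_that("screening with identical seed is fully reproducible", {
  sc <- small_scene()
  ds <- simulated_dataset(sc)
  r1 <- spatial_annotation_screening(ds, sc$ann, sc$cfg, n_sim = 100, seed = 9)
  r2 <- spatial_annotation_screening(ds, sc$ann, sc$cfg, n_sim = 100, seed = 9)
  expect_identical(r1$results, r2$results)
})

test_that("per-variable failures never abort the batch", {
  sc <- small_scene()
  ds <- simulated_dataset(sc)
  res <- spatial_annotation_screening(ds, sc$ann, sc$cfg, n_sim = 100, seed = 3,
                                      rm_zero_infl = TRUE)
  expect_equal(nrow(res$results), nrow(ds$expr))
})

test_that("trajectory screening mirrors ascending/descending under reversal", {
  co <- make_lattice("5mm", "3mm")
  tr <- spatial_trajectory("fwd", c(500, 1500), c(4500, 1500), width = 2000)
  cfg <- gradient_config("4mm", "100um")
  field <- trajectory_distance(tr, co)
  # left-to-right decreasing expression
  vals <- 1000 - 0.2 * co$x + 0.00001 * co$y
  expr <- matrix(vals, 1, nrow(co), dimnames = list("lr", co$id))
  ds <- sgs_dataset(co, expr, ccd = 100)
  res_f <- spatial_trajectory_screening(ds, tr, cfg, n_sim = 200, seed = 21)
  expect_equal(tidy(res_f)$best_class, "descending")
  expect_lt(tidy(res_f)$fdr, 0.05)
  tr_rev <- spatial_trajectory("rev", c(4500, 1500), c(500, 1500), width = 2000)
  res_r <- spatial_trajectory_screening(ds, tr_rev, cfg, n_sim = 200, seed = 21)
  expect_equal(tidy(res_r)$best_class, "ascending")
})

test_that("shrinking the trajectory width drops flagged points from the fit", {
  co <- make_lattice("5mm", "3mm")
  tr_wide <- spatial_trajectory("w", c(500, 1500), c(4500, 1500), width = 2500)
  tr_narrow <- spatial_trajectory("n", c(500, 1500), c(4500, 1500), width = 600)
  f_wide <- trajectory_distance(tr_wide, co)
  f_narrow <- trajectory_distance(tr_narrow, co)
  expect_gt(sum(f_wide$in_scope), sum(f_narrow$in_scope))
  expect_true(all(abs(f_narrow$offset[f_narrow$in_scope]) <= 300))
})

test_that("results serialize to an ordered TSV", {
  sc <- small_scene()
  ds <- simulated_dataset(sc)
  res <- spatial_annotation_screening(ds, sc$ann, sc$cfg, n_sim = 100, seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results(res, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(back), 4)
  expect_true(all(c("variable", "tot_var", "p_value", "fdr", "best_model",
                    "best_mae", "best_rmse") %in% names(back)))
  expect_true(any(startsWith(names(back), "mae.")))
  expect_true(any(startsWith(names(back), "rmse.")))
  ranked <- back$fdr[!is.na(back$fdr)]
  expect_true(all(diff(ranked) >= 0))
  # ties in fdr resolve lexicographically by variable name
  tied <- back$variable[which(back$fdr == 0)]
  expect_equal(tied, sort(tied))
  # empty result: header-only file
  empty <- res$results[0, ]
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_results(empty, path2)
  expect_equal(nrow(readr::read_tsv(path2, show_col_types = FALSE)), 0)
})

test_that("sensitivity to perturbed annotations reports FPR and FNR", {
  # screening distance chosen so the shifted screening region is fully
  # disjoint from the pattern zone: 2 * (300 + 900) < 2600 shift
  sc <- small_scene(distance = "900um")
  perturbed <- list(
    perturb_annotation(sc$ann, "jitter", 0, seed = 1),       # identity
    perturb_annotation(sc$ann, "shift", 2600, seed = 2)      # disjoint
  )
  # low-noise (not exactly noiseless) positives: a noiseless localized
  # pattern is constant far from its annotation, which a disjoint reference
  # reads as a perfectly smooth gradient
  sens <- suppressWarnings(
    sensitivity_experiment(sc$ds, sc$ann, perturbed, sc$cfg,
                           patterns = simulation_templates()[c(1, 2)],
                           positive_pcts = c(5, 10), n_negatives = 20,
                           n_sim = 150, seed = 6))
  expect_equal(nrow(sens), 2)
  expect_equal(sens$deviation[1], 0)
  expect_equal(sens$deviation[2], 100)
  # identity perturbation reproduces the original classification
  expect_equal(sens$fnr[1], 0)
  expect_lte(sens$fpr[1], 0.05)
  # noise variables stay insignificant even against a disjoint annotation
  expect_lte(sens$fpr[2], 0.05)
  expect_gt(sens$fnr[2], 0.5)  # localized patterns are missed without overlap
})
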