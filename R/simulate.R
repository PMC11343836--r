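#' Generate a Visium-like hexagonal lattice
#'
#' Hex-packed points with center-to-center distance `ccd` (100 um on the
#' Visium platform) filling a `width` x `height` box, optionally minus a
#' mask polygon (to emulate tissue edges or missing capture area). All
#' interior points have nearest-neighbour distance exactly `ccd`.
#'
#' @param width,height Box dimensions (um or length strings); at least
#'   3 x ccd.
#' @param ccd Center-to-center distance (default 100 um).
#' @param mask Optional polygon (vertex matrix or [spatial_annotation()]);
#'   points inside it are removed.
#' @return Tibble with columns `id`, `x`, `y` and attribute `ccd`.
#' @examples
#' nrow(make_lattice("1mm", "1mm"))  # ~115 points
#' @export
make_lattice <- function(width, height, ccd = 100, mask = NULL) {
  width <- parse_length(width); height <- parse_length(height); ccd <- parse_length(ccd)
  stopifnot(width >= 3 * ccd, height >= 3 * ccd)
  dy <- ccd * sqrt(3) / 2
  ys <- seq(0, height, by = dy)
  pts <- purrr::map_dfr(seq_along(ys), function(j) {
    offset <- if (j %% 2 == 0) ccd / 2 else 0
    xs <- seq(offset, width, by = ccd)
    tibble::tibble(x = xs, y = ys[j])
  })
  if (!is.null(mask)) {
    ring <- if (inherits(mask, "sgs_annotation")) mask$outer else ring_matrix(mask)
    pts <- pts[!points_in_polygon(pts$x, pts$y, ring), ]
  }
  out <- tibble::tibble(id = sprintf("p%05d", seq_len(nrow(pts))), x = pts$x, y = pts$y)
  attr(out, "ccd") <- ccd
  out
}

#' Assemble a dataset from a lattice and an expression matrix
#'
#' Convenience wrapper: builds an [sgs_dataset()] from [make_lattice()]
#' coordinates, defaulting the ccd to the lattice constant.
#'
#' @param coords Lattice tibble from [make_lattice()].
#' @param expr Variables x points matrix (columns named by point id). When
#'   omitted, a zero-row matrix placeholder is used.
#' @param platform Platform tag.
#' @return An `sgs_dataset`.
#' @export
lattice_dataset <- function(coords, expr = NULL, platform = "synthetic_hex") {
  if (is.null(expr)) {
    expr <- matrix(numeric(0), nrow = 0, ncol = nrow(coords),
                   dimnames = list(character(), coords$id))
  }
  sgs_dataset(coords, expr, ccd = attr(coords, "ccd") %||% "auto", platform = platform)
}

#' Paint a pattern onto a distance field
#'
#' The first simulation step: data points are binned by their distance to
#' the reference feature (bin width `binwidth`), bins are ordered by mean
#' distance, and every member of bin `k` receives the pattern's `k`-th
#' value — identical expression for all members of a bin, before any noise.
#' Distances beyond the screening distance are clamped into the last bin so
#' every point carries a value.
#'
#' @param field An `sgs_field`.
#' @param pattern A pattern model (from [default_models()]) or a numeric
#'   template; resampled to the number of occupied bins.
#' @param binwidth Bin width (um or length string).
#' @return Named numeric vector of per-point values (names = point ids).
#' @export
simulate_pattern <- function(field, pattern, binwidth) {
  stopifnot(inherits(field, "sgs_field"))
  binwidth <- parse_length(binwidth)
  values <- if (is.list(pattern)) pattern$values else as.numeric(pattern)
  maxd <- attr(field, "max_distance")
  d <- pmin(pmax(field$distance, 0), maxd)
  breaks <- seq(0, maxd, by = binwidth)
  if (breaks[length(breaks)] < maxd) breaks <- c(breaks, maxd)
  bin <- findInterval(d, breaks, rightmost.closed = TRUE, left.open = FALSE)
  bin[d == 0] <- 1L
  occupied <- sort(unique(bin))
  v <- if (length(occupied) == 1) {
    rep(mean(values), length(occupied))
  } else {
    resample_model(values, length(occupied))
  }
  out <- v[match(bin, occupied)]
  names(out) <- field$id
  out
}

#' Inject controlled noise into simulated expression
#'
#' Four mechanisms, all drawing noise uniformly over the observed value
#' range. `ED` (equally distributed): each point's value becomes
#' `(1 - r) * pattern + r * noise` with `r = noise_pct / 100`. `EP`
#' (equally punctuated): a uniformly random `ceiling(r * N)`-subset of
#' points is replaced by noise. `FP` (focally punctuated): the same count,
#' but points are selected by growing discs of radius `fp_niche_radius`
#' around random seed points until the quota is met — spatial niches of
#' randomness. `Combined`: the total budget `r` is split equally across the
#' three mechanisms.
#'
#' @param values Named per-point vector (as from [simulate_pattern()]).
#' @param noise_type `"ED"`, `"EP"`, `"FP"` or `"Combined"`.
#' @param noise_pct Noise percentage in `[0, 100]`.
#' @param seed RNG seed.
#' @param coords Coordinate tibble (needed for `FP`/`Combined`).
#' @param fp_niche_radius Disc radius for focal noise (default 300 um =
#'   3 x Visium ccd).
#' @return Noised vector, same names and length.
#' @export
apply_noise <- function(values, noise_type = c("ED", "EP", "FP", "Combined"),
                        noise_pct, seed = 1, coords = NULL, fp_niche_radius = 300) {
  noise_type <- match.arg(noise_type)
  if (!is.numeric(noise_pct) || noise_pct < 0 || noise_pct > 100) {
    stop("noise_pct must be in [0, 100]", call. = FALSE)
  }
  set.seed(seed)
  noised <- noise_step(values, noise_type, noise_pct / 100, coords, fp_niche_radius)
  names(noised) <- names(values)
  noised
}

noise_step <- function(values, noise_type, r, coords, fp_niche_radius) {
  n <- length(values)
  rng <- range(values)
  draw <- function(k) stats::runif(k, rng[1], rng[2])
  if (r == 0) return(values)
  switch(noise_type,
    ED = (1 - r) * values + r * draw(n),
    EP = {
      k <- ceiling(r * n)
      sel <- sample.int(n, k)
      values[sel] <- draw(k)
      values
    },
    FP = {
      k <- ceiling(r * n)
      sel <- fp_select(coords, k, fp_niche_radius)
      values[sel] <- draw(length(sel))
      values
    },
    Combined = {
      v <- noise_step(values, "ED", r / 3, coords, fp_niche_radius)
      v <- noise_step(v, "EP", r / 3, coords, fp_niche_radius)
      noise_step(v, "FP", r / 3, coords, fp_niche_radius)
    }
  )
}

# grow discs around random seed points until `quota` points are selected
fp_select <- function(coords, quota, radius) {
  if (is.null(coords)) stop("FP noise needs point coordinates", call. = FALSE)
  n <- nrow(coords)
  quota <- min(quota, n)
  selected <- logical(n)
  while (sum(selected) < quota) {
    free <- which(!selected)
    ctr <- free[sample.int(length(free), 1)]
    d <- sqrt((coords$x - coords$x[ctr])^2 + (coords$y - coords$y[ctr])^2)
    cand <- free[d[free] <= radius]
    cand <- cand[order(d[cand])]
    room <- quota - sum(selected)
    selected[cand[seq_len(min(room, length(cand)))]] <- TRUE
  }
  which(selected)
}

#' Compose and parse simulation names
#'
#' Simulated variables are named `SE.<pattern>.<noise type>.<noise
#' percentage>.<iteration>`; the name round-trips to its fields.
#' `ground_truth_random` is true iff the noise percentage is 100.
#'
#' @param pattern,noise_type,noise_pct,iteration Name components.
#' @return `sim_name()`: a character scalar. `parse_sim_name()`: a tibble
#'   with columns `pattern`, `noise_type`, `noise_pct`, `iteration`,
#'   `ground_truth_random`.
#' @export
sim_name <- function(pattern, noise_type, noise_pct, iteration) {
  sprintf("SE.%s.%s.%s.%s", pattern, noise_type, format(noise_pct), iteration)
}

#' @rdname sim_name
#' @param name Character vector of simulation names.
#' @export
parse_sim_name <- function(name) {
  parts <- strsplit(name, ".", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 5 | vapply(parts, `[[`, character(1), 1) != "SE"
  if (any(bad)) stop("not a simulation name: ", name[bad][1], call. = FALSE)
  tibble::tibble(
    name = name,
    pattern = vapply(parts, `[[`, character(1), 2),
    noise_type = vapply(parts, `[[`, character(1), 3),
    noise_pct = as.numeric(vapply(parts, `[[`, character(1), 4)),
    iteration = as.integer(vapply(parts, `[[`, character(1), 5)),
    ground_truth_random = as.numeric(vapply(parts, `[[`, character(1), 4)) == 100
  )
}

#' Default simulation templates
#'
#' The six canonical pattern templates used by the benchmarking grid: two
#' descending, two ascending, two peaking, drawn from [default_models()].
#'
#' @return Named list of 6 pattern models.
#' @export
simulation_templates <- function() {
  default_models(100)[c("desc_linear", "desc_sigmoid",
                        "asc_linear", "asc_sigmoid",
                        "peak_50_sharp", "peak_50_broad")]
}

#' Enumerate a benchmark grid
#'
#' Expands patterns x noise types x noise levels x iterations into the
#' simulation roster; e.g. the full 6 x 4 x 51 x 50 grid enumerates 61,200
#' simulations.
#'
#' @param patterns Character vector of template names (or list of models).
#' @param noise_types Subset of `c("ED", "EP", "FP", "Combined")`.
#' @param pct_grid Noise percentages, e.g. `seq(0, 100, by = 2)`.
#' @param iterations Iterations per combination.
#' @return Tibble with one row per simulation, named by [sim_name()].
#' @export
benchmark_combinations <- function(patterns, noise_types, pct_grid, iterations) {
  pnames <- if (is.list(patterns)) names(patterns) else as.character(patterns)
  g <- tidyr::expand_grid(pattern = pnames, noise_type = noise_types,
                          noise_pct = pct_grid, iteration = seq_len(iterations))
  g$name <- sim_name(g$pattern, g$noise_type, g$noise_pct, g$iteration)
  g$ground_truth_random <- g$noise_pct == 100
  g
}

#' Run the simulation benchmark grid
#'
#' Simulates every (pattern, noise type, noise level, iteration)
#' combination on the given geometry and screens each simulated variable
#' with the identical gradient/TV pipeline. With `n_sim > 0` a shared
#' permutation null is built and p-values/FDR are reported as well.
#'
#' @param ds An [sgs_dataset()] (coordinates and ccd are used).
#' @param field An `sgs_field` for the reference feature.
#' @param cfg An [gradient_config()].
#' @param patterns Named list of pattern models (default
#'   [simulation_templates()]).
#' @param noise_types Noise mechanisms to cross.
#' @param pct_grid Noise percentages.
#' @param iterations Iterations per combination (the full published grid
#'   used 50).
#' @param seed Master seed; per-simulation seeds derive from it.
#' @param n_sim Null simulations for p-values; 0 skips p-values (TV only).
#' @param fp_niche_radius Focal-noise radius (default 3 x ccd).
#' @return Tidy tibble: one row per simulation with `tot_var` (and
#'   `p_value`, `fdr` when `n_sim > 0`).
#' @export
run_benchmark_grid <- function(ds, field, cfg, patterns = simulation_templates(),
                               noise_types = c("ED", "EP", "FP", "Combined"),
                               pct_grid = seq(0, 100, by = 2), iterations = 50,
                               seed = 1, n_sim = 0, fp_niche_radius = NULL) {
  stopifnot(inherits(field, "sgs_field"), inherits(cfg, "sgs_config"))
  coords <- dataset_coords(ds)
  ccd <- if (inherits(ds, "sgs_dataset")) ds$ccd else attr(ds, "ccd")
  if (is.null(fp_niche_radius)) fp_niche_radius <- 3 * ccd
  grid <- benchmark_combinations(patterns, noise_types, pct_grid, iterations)
  cf <- correction_factor(field, ds, cfg)
  base_values <- lapply(patterns, simulate_pattern, field = field,
                        binwidth = cfg$resolution)
  tv <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    v <- apply_noise(base_values[[grid$pattern[i]]], grid$noise_type[i],
                     grid$noise_pct[i],
                     seed = derive_seed(seed, grid$name[i]),
                     coords = coords, fp_niche_radius = fp_niche_radius)
    g <- infer_gradient(v, field, cfg, cf = cf, variable = grid$name[i])
    tv[i] <- total_variation(g)
  }
  grid$tot_var <- tv
  if (n_sim > 0) {
    null <- null_distribution(field, cfg, n_sim = n_sim,
                              seed = derive_seed(seed, "null"), cf = cf)
    grid$p_value <- vapply(tv, p_value, numeric(1), null = null)
    grid$fdr <- adjust_fdr(grid$p_value)
  }
  grid
}

# reliability of the TV statistic on this exact geometry: per-stratum OLS
# R^2 of TV against noise percentage
reliability_r2 <- function(ds, field, cfg, noise_types = "Combined",
                           patterns = simulation_templates(),
                           pct_grid = seq(0, 100, by = 4), iterations = 10,
                           seed = 1) {
  bench <- run_benchmark_grid(ds, field, cfg, patterns = patterns,
                              noise_types = noise_types, pct_grid = pct_grid,
                              iterations = iterations, seed = seed, n_sim = 0)
  out <- bench |>
    dplyr::group_by(.data$pattern, .data$noise_type) |>
    dplyr::summarise(r2 = {
      if (stats::var(.data$noise_pct) == 0) {
        warning("noise percentage held constant: R^2 undefined", call. = FALSE)
        NA_real_
      } else {
        summary(stats::lm(tot_var ~ noise_pct,
                          data = data.frame(tot_var = .data$tot_var,
                                            noise_pct = .data$noise_pct)))$r.squared
      }
    }, .groups = "drop")
  mean_by_type <- out |>
    dplyr::group_by(.data$noise_type) |>
    dplyr::summarise(mean_r2 = mean(.data$r2, na.rm = TRUE), .groups = "drop")
  attr(out, "mean_by_type") <- mean_by_type
  out
}

#' Estimate the reliability (R squared) of the screening setup
#'
#' Re-runs the pattern-plus-noise simulation on the user's exact geometry
#' and configuration and regresses the total-variation statistic on the
#' ground-truth noise percentage, per pattern template and noise type. The
#' resulting R squared measures how well TV tracks randomness under this
#' setup; it grows with resolution and data completeness. The attribute
#' `mean_by_type` carries the across-pattern mean per noise type.
#'
#' @inheritParams run_benchmark_grid
#' @return Tibble with columns `pattern`, `noise_type`, `r2`; attribute
#'   `mean_by_type`.
#' @export
estimate_r2 <- function(ds, field, cfg, noise_types = "Combined",
                        patterns = simulation_templates(),
                        pct_grid = seq(0, 100, by = 4), iterations = 10,
                        seed = 1) {
  reliability_r2(ds, field, cfg, noise_types = noise_types, patterns = patterns,
                 pct_grid = pct_grid, iterations = iterations, seed = seed)
}

#' Sensitivity of screening to perturbed reference features
#'
#' Builds ground-truth variable sets against the original reference
#' feature — positives are low-noise simulated patterns whose FDR is
#' exactly 0 under the original screening; negatives are pure-noise
#' (100% ED) variables — then re-screens both sets against each perturbed
#' feature. The false positive rate is the share of negatives declared
#' non-random (fdr < threshold); the false negative rate is the share of
#' positives declared random (fdr >= threshold).
#'
#' @param ds An [sgs_dataset()].
#' @param original An [spatial_annotation()] (or list) or
#'   [spatial_trajectory()].
#' @param perturbed List of perturbed references: either bare
#'   annotation/trajectory objects or the lists returned by
#'   [perturb_annotation()] / [perturb_trajectory()] (their deviation is
#'   carried into the output).
#' @param cfg An [gradient_config()].
#' @param patterns Templates for the positive set (default
#'   [simulation_templates()]); `NULL` skips positives (FNR reported NA).
#' @param positive_pcts ED noise levels for the positive candidates.
#' @param n_negatives Number of pure-noise variables.
#' @param n_sim Null simulations per screening.
#' @param seed Master seed.
#' @param fdr_threshold Significance threshold (default 0.05).
#' @return Tibble: one row per perturbed reference with `ref_id`,
#'   `deviation`, `fpr`, `fnr`, `n_positives`, `n_negatives`.
#' @export
sensitivity_experiment <- function(ds, original, perturbed, cfg,
                                   patterns = simulation_templates(),
                                   positive_pcts = c(0, 10, 20),
                                   n_negatives = 100, n_sim = 1000, seed = 1,
                                   fdr_threshold = 0.05) {
  field0 <- ref_field(original, ds, cfg)
  cf0 <- correction_factor(field0, ds, cfg)
  coords <- dataset_coords(ds)
  vars <- list()
  if (!is.null(patterns) && length(positive_pcts)) {
    for (pn in names(patterns)) {
      base <- simulate_pattern(field0, patterns[[pn]], cfg$resolution)
      for (pct in positive_pcts) {
        nm <- sim_name(pn, "ED", pct, 1)
        vars[[nm]] <- apply_noise(base, "ED", pct, seed = derive_seed(seed, nm),
                                  coords = coords)
      }
    }
  }
  # base vector for the negative set; its value range spans [0, 1] so that
  # 100% ED noise is a genuine uniform draw
  flat <- if (length(patterns)) {
    simulate_pattern(field0, patterns[[1]], cfg$resolution)
  } else {
    stats::setNames(seq(0, 1, length.out = nrow(coords)), coords$id)
  }
  for (i in seq_len(n_negatives)) {
    nm <- sim_name("flat", "ED", 100, i)
    vars[[nm]] <- apply_noise(flat, "ED", 100, seed = derive_seed(seed, nm),
                              coords = coords)
  }
  expr <- do.call(rbind, vars)
  colnames(expr) <- coords$id
  sim_ds <- sgs_dataset(coords, expr,
                        ccd = if (inherits(ds, "sgs_dataset")) ds$ccd else attr(ds, "ccd"))
  screen_ref <- function(ref, tag) {
    field <- ref_field(ref, sim_ds, cfg)
    screen_field(sim_ds, field, cfg, n_sim = n_sim,
                 seed = derive_seed(seed, "screen", tag),
                 rm_zero_infl = FALSE, fdr_threshold = fdr_threshold)
  }
  res0 <- screen_ref(original, "original")
  info <- parse_sim_name(res0$results$variable)
  positives <- res0$results$variable[!info$ground_truth_random & res0$results$fdr == 0]
  negatives <- res0$results$variable[info$ground_truth_random]
  purrr::imap_dfr(perturbed, function(p, i) {
    dev <- NA_real_
    ref <- p
    if (is.list(p) && !inherits(p, c("sgs_annotation", "sgs_trajectory"))) {
      ref <- p$annotation %||% p$trajectory
      dev <- p$deviation_pct %||% p$deviation %||% NA_real_
    }
    res <- screen_ref(ref, paste0("perturbed", i))
    rr <- res$results
    # a variable that cannot be screened against the perturbed feature is a
    # miss, not a discovery
    fdr_neg <- rr$fdr[rr$variable %in% negatives]
    fpr <- mean(!is.na(fdr_neg) & fdr_neg < fdr_threshold)
    fnr <- if (length(positives)) {
      fdr_pos <- rr$fdr[rr$variable %in% positives]
      mean(is.na(fdr_pos) | fdr_pos >= fdr_threshold)
    } else NA_real_
    tibble::tibble(ref_id = ref_ids(if (inherits(ref, "sgs_annotation")) list(ref) else ref)[1],
                   deviation = dev, fpr = fpr, fnr = fnr,
                   n_positives = length(positives), n_negatives = length(negatives))
  })
}

ref_field <- function(ref, ds, cfg) {
  if (inherits(ref, "sgs_trajectory")) {
    trajectory_distance(ref, ds)
  } else {
    annotation_distance(ref, ds, max_distance = cfg$distance)
  }
}
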