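#' Total variation of a gradient
#'
#' `TV = sum over i of |y[i+1] - y[i]|` on the standardized expression
#' estimates. Smooth gradients have low TV; random gradients wiggle and
#' accumulate high TV.
#'
#' @param g An `sgs_gradient` or a numeric vector of estimates (>= 2).
#' @return Scalar total variation.
#' @examples
#' total_variation(c(0, 1, 0, 1))  # 3
#' total_variation(c(1, 0.5, 0))   # 1
#' @export
total_variation <- function(g) {
  est <- if (inherits(g, "sgs_gradient")) g$estimate else as.numeric(g)
  if (length(est) < 2) stop("total variation needs at least 2 estimates", call. = FALSE)
  sum(abs(diff(est)))
}

#' Permutation null distribution of total variation
#'
#' Repeatedly assigns i.i.d. uniform(0, 1) expression values to the
#' in-scope points, infers a gradient through the identical pipeline, and
#' records its total variation. TV scores outside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` are trimmed so outliers do not distort
#' the null. The null depends only on the geometry and configuration, not
#' on any variable, so one null serves a whole screening run.
#'
#' @param field An `sgs_field`.
#' @param cfg An [gradient_config()].
#' @param n_sim Number of random gradients (default 10000).
#' @param seed RNG seed (required for reproducibility).
#' @param cf Correction factor used for the gradient pipeline.
#' @param include_inside Passed to [infer_gradient()].
#' @return Object of class `sgs_null`: list with `tvs` (kept TV scores),
#'   `n_raw`, `n_kept`, `seed`.
#' @export
null_distribution <- function(field, cfg, n_sim = 10000, seed = 1, cf = 1,
                              include_inside = FALSE) {
  stopifnot(n_sim >= 1)
  idx <- field_fit_index(field, include_inside = include_inside)
  n_pts <- length(idx)
  values <- rep(NA_real_, nrow(field))
  tvs <- numeric(n_sim)
  set.seed(seed)
  for (i in seq_len(n_sim)) {
    values[idx] <- stats::runif(n_pts)
    g <- infer_gradient(values, field, cfg, cf = cf,
                        include_inside = include_inside, variable = "null")
    tvs[i] <- total_variation(g)
  }
  q <- stats::quantile(tvs, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  keep <- tvs >= q[1] - 1.5 * iqr & tvs <= q[2] + 1.5 * iqr
  structure(
    list(tvs = tvs[keep], n_raw = n_sim, n_kept = sum(keep), seed = seed),
    class = "sgs_null"
  )
}

#' @export
print.sgs_null <- function(x, ...) {
  cat(sprintf("<sgs_null> %d/%d TV scores kept after IQR trim (seed %d)\n",
              x$n_kept, x$n_raw, x$seed))
  invisible(x)
}

#' Permutation p-value for an observed total variation
#'
#' The fraction of null TV scores less than or equal to the observed TV:
#' low TV (a smooth, non-random gradient) gives a small p-value. Ties count
#' against significance (the indicator uses `<=`). An optional pseudocount
#' `(1 + sum) / (1 + n)` avoids exact zeros.
#'
#' @param otv Observed total variation.
#' @param null An `sgs_null`.
#' @param pseudocount Use the add-one estimator (default FALSE, matching
#'   the plain ratio).
#' @return p-value in `[0, 1]`.
#' @export
p_value <- function(otv, null, pseudocount = FALSE) {
  stopifnot(inherits(null, "sgs_null"), null$n_kept > 0)
  s <- sum(null$tvs <= otv)
  if (pseudocount) (1 + s) / (1 + null$n_kept) else s / null$n_kept
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (`stats::p.adjust(method = "BH")`), reported
#' in the `fdr` column of screening results.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Adjusted values, capped at 1.
#' @export
adjust_fdr <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  stats::p.adjust(pvalues, method = "BH")
}

#' Detect zero-inflated variables
#'
#' Removes values outside 1.5 x IQR beyond the quartiles; if every retained
#' value is exactly zero (all non-zero observations were outliers), the
#' variable is deemed zero-inflated and should be excluded from screening.
#'
#' @param values Per-point numeric vector.
#' @return Logical scalar.
#' @examples
#' is_zero_inflated(c(rep(0, 97), 50, 60, 70))  # TRUE
#' is_zero_inflated(runif(100))                 # FALSE
#' @export
is_zero_inflated <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) return(FALSE)
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  kept <- values[values >= q[1] - 1.5 * iqr & values <= q[2] + 1.5 * iqr]
  length(kept) > 0 && all(kept == 0)
}

# shared screening engine behind the annotation and trajectory drivers
screen_field <- function(ds, field, cfg, variables = NULL, n_sim = 10000,
                         seed = 1, estimate_r2 = FALSE, rm_zero_infl = TRUE,
                         models = NULL, include_inside = FALSE,
                         fdr_threshold = 0.05, rmse_threshold = 0.25) {
  stopifnot(inherits(ds, "sgs_dataset"), inherits(field, "sgs_field"))
  if (is.null(variables)) variables <- rownames(ds$expr)
  missing_vars <- setdiff(variables, rownames(ds$expr))
  if (length(missing_vars)) {
    stop("variables not in the dataset: ", paste(utils::head(missing_vars, 5), collapse = ", "),
         call. = FALSE)
  }
  cf <- correction_factor(field, ds, cfg)
  null <- null_distribution(field, cfg, n_sim = n_sim, seed = derive_seed(seed, "null"),
                            cf = cf, include_inside = include_inside)
  per_var <- purrr::map(variables, function(v) {
    vals <- ds$expr[v, ]
    if (rm_zero_infl && is_zero_inflated(vals)) {
      return(list(variable = v, zero_inflated = TRUE, insufficient_coverage = FALSE))
    }
    g <- tryCatch(
      infer_gradient(vals, field, cfg, cf = cf, include_inside = include_inside, variable = v),
      sgs_insufficient_coverage = function(e) NULL
    )
    if (is.null(g)) {
      return(list(variable = v, zero_inflated = FALSE, insufficient_coverage = TRUE))
    }
    list(variable = v, zero_inflated = FALSE, insufficient_coverage = FALSE,
         gradient = g, tot_var = total_variation(g))
  })
  tested <- purrr::keep(per_var, ~ !is.null(.x$gradient))
  n_bins <- if (length(tested)) attr(tested[[1]]$gradient, "n_bins") else NA_integer_
  if (is.null(models)) {
    models <- if (!is.na(n_bins)) default_models(n_bins) else list()
  } else if (!is.na(n_bins)) {
    models <- lapply(models, function(m) {
      m$values <- resample_model(m$values, n_bins)
      m
    })
  }
  pvals <- vapply(tested, function(r) p_value(r$tot_var, null), numeric(1))
  fdrs <- adjust_fdr(pvals)
  fit_rows <- purrr::imap(tested, function(r, i) {
    fits <- fit_models(r$gradient, models)
    best <- fits[1, ]
    wide_mae <- stats::setNames(as.list(fits$mae), paste0("mae.", fits$model))
    wide_rmse <- stats::setNames(as.list(fits$rmse), paste0("rmse.", fits$model))
    tibble::tibble(
      variable = r$variable, tot_var = r$tot_var,
      p_value = pvals[i], fdr = fdrs[i],
      best_model = best$model, best_class = best$class,
      best_mae = best$mae, best_rmse = best$rmse,
      significant = fdrs[i] < fdr_threshold & best$rmse < rmse_threshold,
      zero_inflated = FALSE, insufficient_coverage = FALSE,
      !!!wide_mae, !!!wide_rmse
    )
  })
  skipped <- purrr::keep(per_var, ~ is.null(.x$gradient))
  skip_rows <- purrr::map(skipped, function(r) {
    tibble::tibble(
      variable = r$variable, tot_var = NA_real_, p_value = NA_real_, fdr = NA_real_,
      best_model = NA_character_, best_class = NA_character_,
      best_mae = NA_real_, best_rmse = NA_real_, significant = FALSE,
      zero_inflated = r$zero_inflated, insufficient_coverage = r$insufficient_coverage
    )
  })
  results <- dplyr::bind_rows(c(fit_rows, skip_rows))
  results <- dplyr::arrange(results, dplyr::desc(!is.na(.data$fdr)), .data$fdr, .data$variable)
  r2 <- NULL
  if (estimate_r2) {
    r2 <- reliability_r2(ds, field, cfg, seed = derive_seed(seed, "r2"))
  }
  structure(
    list(results = results, null = null, config = cfg, cf = cf,
         field_type = attr(field, "type"),
         ref_ids = ref_ids(attr(field, "ref")),
         n_sim = n_sim, seed = seed,
         fdr_threshold = fdr_threshold, rmse_threshold = rmse_threshold,
         gradients = stats::setNames(lapply(tested, `[[`, "gradient"),
                                     vapply(tested, `[[`, character(1), "variable")),
         r2 = r2),
    class = "sgs_result"
  )
}

ref_ids <- function(ref) {
  if (inherits(ref, "sgs_trajectory")) return(ref$id)
  vapply(ref, `[[`, character(1), "id")
}

#' Spatial annotation screening (SAS)
#'
#' The full screening pipeline against one or more annotated areas:
#' zero-inflation filter, distance-binned LOESS gradient per variable,
#' total variation, permutation p-value against a shared geometric null,
#' Benjamini-Hochberg FDR across the tested variables, and pattern-model
#' classification (best model = lowest RMSE; a hit is significant when
#' `fdr < 0.05` and the best RMSE < 0.25 by default).
#'
#' @param ds An [sgs_dataset()].
#' @param anns One annotation or a list of annotations (pointwise-minimum
#'   distance is screened).
#' @param cfg An [gradient_config()]; its `distance` is the screening
#'   radius.
#' @param variables Variables (rows of `ds$expr`) to screen; default all.
#'   Supply an external spatially-variable-gene list here to pre-filter.
#' @param n_sim Null simulations (default 10000).
#' @param seed Single integer seed; all internal streams derive from it
#'   deterministically.
#' @param estimate_r2 Also run the reliability simulation on this exact
#'   geometry and store per-noise-type R squared values.
#' @param rm_zero_infl Filter zero-inflated variables first (default TRUE).
#' @param models Pattern model list; default [default_models()] resampled
#'   to the gradient length.
#' @param include_inside Include annotation-interior points at distance 0.
#' @param fdr_threshold,rmse_threshold Significance defaults 0.05 / 0.25.
#' @return An `sgs_result`; see [tidy.sgs_result()] and [write_results()].
#' @export
spatial_annotation_screening <- function(ds, anns, cfg, variables = NULL,
                                         n_sim = 10000, seed = 1,
                                         estimate_r2 = FALSE, rm_zero_infl = TRUE,
                                         models = NULL, include_inside = FALSE,
                                         fdr_threshold = 0.05, rmse_threshold = 0.25) {
  field <- annotation_distance(anns, ds, max_distance = cfg$distance)
  if (cfg$resolution > ds$ccd * (1 + 1e-9)) {
    warning("resolution exceeds the center-to-center distance; results may be unreliable",
            call. = FALSE)
  }
  screen_field(ds, field, cfg, variables = variables, n_sim = n_sim, seed = seed,
               estimate_r2 = estimate_r2, rm_zero_infl = rm_zero_infl,
               models = models, include_inside = include_inside,
               fdr_threshold = fdr_threshold, rmse_threshold = rmse_threshold)
}

#' Spatial trajectory screening (STS)
#'
#' Identical statistical contract to [spatial_annotation_screening()], with
#' the distance axis given by orthogonal projection onto a directed
#' trajectory; only points inside the trajectory frame (projection within
#' the segment, offset within half the width) are screened.
#'
#' @inheritParams spatial_annotation_screening
#' @param traj An [spatial_trajectory()].
#' @return An `sgs_result`.
#' @export
spatial_trajectory_screening <- function(ds, traj, cfg = NULL, variables = NULL,
                                         n_sim = 10000, seed = 1,
                                         estimate_r2 = FALSE, rm_zero_infl = TRUE,
                                         models = NULL,
                                         fdr_threshold = 0.05, rmse_threshold = 0.25) {
  if (is.null(cfg)) {
    cfg <- gradient_config(trajectory_length(traj), min(ds$ccd, trajectory_length(traj)))
  }
  field <- trajectory_distance(traj, ds)
  if (cfg$resolution > ds$ccd * (1 + 1e-9)) {
    warning("resolution exceeds the center-to-center distance; results may be unreliable",
            call. = FALSE)
  }
  screen_field(ds, field, cfg, variables = variables, n_sim = n_sim, seed = seed,
               estimate_r2 = estimate_r2, rm_zero_infl = rm_zero_infl,
               models = models, include_inside = FALSE,
               fdr_threshold = fdr_threshold, rmse_threshold = rmse_threshold)
}

#' @export
print.sgs_result <- function(x, ...) {
  n <- nrow(x$results)
  sig <- sum(x$results$significant, na.rm = TRUE)
  cat(sprintf("<sgs_result> %s screening of %d variable(s): %d significant (fdr < %g, rmse < %g)\n",
              x$field_type, n, sig, x$fdr_threshold, x$rmse_threshold))
  invisible(x)
}

#' Write screening results to TSV
#'
#' One row per variable: `variable`, `tot_var`, `p_value`, `fdr`,
#' `best_model`, `best_mae`, `best_rmse`, flags, and one `mae.<model>` /
#' `rmse.<model>` column per fitted model. Rows are ordered by `fdr`, ties
#' broken lexicographically by variable name.
#'
#' @param result An `sgs_result` (or its `results` tibble).
#' @param path Output TSV path.
#' @return Invisibly, the tibble written.
#' @export
write_results <- function(result, path) {
  df <- if (inherits(result, "sgs_result")) result$results else tibble::as_tibble(result)
  df <- dplyr::arrange(df, dplyr::desc(!is.na(.data$fdr)), .data$fdr, .data$variable)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(df)
}

# deterministic seed derivation: one user seed, independent named streams,
# always below 2^31
derive_seed <- function(seed, ...) {
  tags <- paste(c(...), collapse = "/")
  h <- sum(utf8ToInt(tags) * seq_along(utf8ToInt(tags)) * 2654435761) %% 1e9
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}
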