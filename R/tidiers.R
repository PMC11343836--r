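#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a screening result
#'
#' One row per variable with the core screening columns (`variable`,
#' `tot_var`, `p_value`, `fdr`, best model fit and flags). Per-model
#' `mae.*` / `rmse.*` columns are included with `all_fits = TRUE`.
#'
#' @param x An `sgs_result`.
#' @param all_fits Keep the per-model fit columns (default FALSE).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy sgs_result
#' @export
tidy.sgs_result <- function(x, all_fits = FALSE, ...) {
  df <- x$results
  if (!all_fits) {
    df <- dplyr::select(df, -dplyr::starts_with("mae."), -dplyr::starts_with("rmse."))
  }
  df
}

#' One-row summary of a screening result
#'
#' @param x An `sgs_result`.
#' @param ... Unused.
#' @return A tibble with run-level facts: variable counts, significance
#'   tally, null size, correction factor and thresholds.
#' @method glance sgs_result
#' @export
glance.sgs_result <- function(x, ...) {
  tibble::tibble(
    n_variables = nrow(x$results),
    n_tested = sum(!is.na(x$results$fdr)),
    n_significant = sum(x$results$significant, na.rm = TRUE),
    n_zero_inflated = sum(x$results$zero_inflated, na.rm = TRUE),
    field_type = x$field_type,
    cf = x$cf,
    distance = x$config$distance,
    resolution = x$config$resolution,
    n_sim = x$n_sim,
    null_kept = x$null$n_kept,
    fdr_threshold = x$fdr_threshold,
    rmse_threshold = x$rmse_threshold,
    seed = x$seed
  )
}

#' Tidy a gradient
#'
#' @param x An `sgs_gradient`.
#' @param ... Unused.
#' @return Tibble with `variable`, `bin`, `center`, `estimate`.
#' @method tidy sgs_gradient
#' @export
tidy.sgs_gradient <- function(x, ...) {
  tibble::tibble(variable = attr(x, "variable"), bin = x$bin,
                 center = x$center, estimate = x$estimate)
}

#' Plot an inferred gradient
#'
#' Standardized expression estimates against the distance to the reference
#' feature, as a polygonal curve.
#'
#' @param object An `sgs_gradient`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sgs_gradient
#' @export
autoplot.sgs_gradient <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$center / 1000, y = .data$estimate)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "distance (mm)", y = "standardized expression",
                  title = attr(object, "variable")) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a screening result
#'
#' The permutation null distribution of total variation with the observed
#' per-variable TV values overlaid; significant variables are highlighted.
#'
#' @param object An `sgs_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sgs_result
#' @export
autoplot.sgs_result <- function(object, ...) {
  null_df <- tibble::tibble(tv = object$null$tvs)
  obs <- dplyr::filter(object$results, !is.na(.data$tot_var))
  ggplot2::ggplot(null_df, ggplot2::aes(x = .data$tv)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey80", color = "grey60") +
    ggplot2::geom_vline(data = obs,
                        ggplot2::aes(xintercept = .data$tot_var,
                                     color = .data$significant),
                        alpha = 0.7) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey30"),
                                name = "significant") +
    ggplot2::labs(x = "total variation", y = "null count",
                  title = sprintf("%s screening: observed TV vs permutation null",
                                  object$field_type)) +
    ggplot2::theme_minimal()
}

#' Plot gradients of the top screening hits
#'
#' Line panel of the inferred gradients for the `n` most significant
#' variables (lowest FDR, then lowest RMSE).
#'
#' @param result An `sgs_result`.
#' @param n Number of variables to show.
#' @return A ggplot.
#' @export
plot_top_gradients <- function(result, n = 6) {
  stopifnot(inherits(result, "sgs_result"))
  top <- result$results |>
    dplyr::filter(!is.na(.data$fdr)) |>
    dplyr::arrange(.data$fdr, .data$best_rmse) |>
    utils::head(n)
  df <- purrr::map_dfr(top$variable, ~ tidy(result$gradients[[.x]]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$center / 1000, y = .data$estimate)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::facet_wrap(~variable) +
    ggplot2::labs(x = "distance (mm)", y = "standardized expression") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
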