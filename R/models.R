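#' Canonical pattern model library
#'
#' Predefined gradient shapes against which inferred gradients are scored.
#' Three classes: descending (association: high near the reference area,
#' decaying with distance), ascending (recovery: the mirror image) and
#' peaking (layered: a transient bump at some distance). Each model is a
#' 100-point canonical template in `[0, 1]`, resampled to the requested
#' length by linear interpolation and re-standardized.
#'
#' Members: descending `linear`, `early` (fast initial drop), `late`
#' (drop near the far end), `sigmoid`; ascending mirrors of each; peaking
#' bumps centered at 25/50/75% of the distance, one `sharp` and one
#' `broad` variant each.
#'
#' @param n_bins Length to resample the templates to (>= 2).
#' @param classes Optional subset of `c("descending", "ascending",
#'   "peaking")`.
#' @return Named list of pattern models; each is a list with `name`,
#'   `class` and `values` (length `n_bins`, min 0, max 1).
#' @examples
#' m <- default_models(3)
#' m$desc_linear$values  # 1, 0.5, 0
#' @export
default_models <- function(n_bins = 100,
                           classes = c("descending", "ascending", "peaking")) {
  stopifnot(n_bins >= 2)
  classes <- match.arg(classes, several.ok = TRUE)
  t <- seq(0, 1, length.out = 100)
  desc <- list(
    desc_linear  = 1 - t,
    desc_early   = (exp(-4 * t) - exp(-4)) / (1 - exp(-4)),
    desc_late    = 1 - (exp(4 * t) - 1) / (exp(4) - 1),
    desc_sigmoid = stats::plogis(-10 * (t - 0.5))
  )
  asc <- lapply(desc, rev)
  names(asc) <- sub("^desc", "asc", names(desc))
  peak <- list()
  for (ctr in c(0.25, 0.5, 0.75)) {
    for (wd in c(sharp = 0.06, broad = 0.18)) {
      nm <- sprintf("peak_%d_%s", round(ctr * 100),
                    if (wd < 0.1) "sharp" else "broad")
      peak[[nm]] <- exp(-(t - ctr)^2 / (2 * wd^2))
    }
  }
  all <- list(descending = desc, ascending = asc, peaking = peak)
  out <- list()
  for (cl in classes) {
    for (nm in names(all[[cl]])) {
      out[[nm]] <- list(name = nm, class = cl,
                        values = resample_model(standardize01(all[[cl]][[nm]]), n_bins))
    }
  }
  out
}

standardize01 <- function(v) {
  r <- max(v) - min(v)
  if (r <= 0) return(rep(0.5, length(v)))
  (v - min(v)) / r
}

#' Resample a model template to a new length by linear interpolation
#' @param values Numeric template.
#' @param n_bins Target length.
#' @return Length-`n_bins` vector, re-standardized to min 0 / max 1.
#' @export
resample_model <- function(values, n_bins) {
  stopifnot(n_bins >= 2, length(values) >= 2)
  out <- stats::approx(seq(0, 1, length.out = length(values)), values,
                       xout = seq(0, 1, length.out = n_bins))$y
  standardize01(out)
}

#' Score a gradient against pattern models
#'
#' Computes, for each model, the mean absolute error
#' `MAE = mean(|G_i - M_i|)` and the root mean squared error
#' `RMSE = sqrt(mean((G_i - M_i)^2))` between the gradient estimates `G`
#' and the model values `M`.
#'
#' @param g An `sgs_gradient` (or a bare numeric vector of estimates).
#' @param models A list from [default_models()], already resampled to the
#'   gradient's length.
#' @return Tibble with columns `model`, `class`, `mae`, `rmse`, sorted by
#'   `rmse`.
#' @export
fit_models <- function(g, models) {
  est <- if (inherits(g, "sgs_gradient")) g$estimate else as.numeric(g)
  rows <- purrr::map(models, function(m) {
    if (length(m$values) != length(est)) {
      stop("model '", m$name, "' has length ", length(m$values),
           " but the gradient has ", length(est),
           " bins; resample the models first", call. = FALSE)
    }
    r <- est - m$values
    tibble::tibble(model = m$name, class = m$class,
                   mae = mean(abs(r)), rmse = sqrt(mean(r^2)))
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$rmse)
}
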