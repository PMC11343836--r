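#' Assemble a spatial dataset
#'
#' The substrate of all screening: point coordinates in micrometers, a
#' variables-by-points expression matrix (assumed normalized), and the
#' center-to-center distance (CCD) that anchors the unit system (100 um on
#' the Visium platform).
#'
#' @param coords Data frame with columns `id`, `x`, `y`. Coordinates are
#'   Cartesian (y increasing upward), in micrometers.
#' @param expr Numeric matrix, variables x points; column names must match
#'   `coords$id` (order may differ; columns are reordered to match).
#' @param ccd Center-to-center distance in micrometers, a length string
#'   (`"100um"`), or `"auto"` to estimate it as the robust mean
#'   nearest-neighbour distance (1.5 x IQR trim).
#' @param platform Free-text platform tag.
#' @return An object of class `sgs_dataset` with elements `coords` (tibble),
#'   `expr` (matrix), `ccd` (um), `platform`.
#' @examples
#' coords <- expand.grid(x = c(0, 100), y = c(0, 100))
#' coords <- tibble::tibble(id = paste0("p", 1:4), x = coords$x, y = coords$y)
#' expr <- matrix(rnorm(8), 2, 4, dimnames = list(c("g1", "g2"), coords$id))
#' ds <- sgs_dataset(coords, expr, ccd = "auto")
#' ds$ccd  # 100
#' @export
sgs_dataset <- function(coords, expr, ccd = "auto", platform = "generic") {
  coords <- tibble::as_tibble(coords)
  req <- c("id", "x", "y")
  if (!all(req %in% names(coords))) {
    stop("coords must have columns id, x, y", call. = FALSE)
  }
  coords$id <- as.character(coords$id)
  if (!is.numeric(coords$x) || !is.numeric(coords$y)) {
    stop("coordinates must be numeric", call. = FALSE)
  }
  if (anyNA(coords$x) || anyNA(coords$y) || any(!is.finite(coords$x)) || any(!is.finite(coords$y))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  if (anyDuplicated(coords$id)) {
    stop("duplicated point ids: ", paste(unique(coords$id[duplicated(coords$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(coords[, c("x", "y")])) {
    stop("duplicated (x, y) coordinate pairs", call. = FALSE)
  }
  expr <- as.matrix(expr)
  storage.mode(expr) <- "double"
  if (is.null(colnames(expr))) {
    stop("expression matrix needs point ids as column names", call. = FALSE)
  }
  orphan_expr <- setdiff(colnames(expr), coords$id)
  orphan_coord <- setdiff(coords$id, colnames(expr))
  if (length(orphan_expr) || length(orphan_coord)) {
    stop("ID mismatch between coordinates and expression matrix.\n",
         "  in expr only: ", paste(utils::head(orphan_expr, 10), collapse = ", "),
         if (length(orphan_expr) > 10) " ..." else "", "\n",
         "  in coords only: ", paste(utils::head(orphan_coord, 10), collapse = ", "),
         if (length(orphan_coord) > 10) " ..." else "",
         call. = FALSE)
  }
  expr <- expr[, coords$id, drop = FALSE]
  if (identical(ccd, "auto")) {
    ccd <- estimate_ccd(coords)
  } else {
    ccd <- parse_length(ccd)
  }
  stopifnot(is.numeric(ccd), length(ccd) == 1, ccd > 0)
  structure(
    list(coords = coords, expr = expr, ccd = as.numeric(ccd), platform = platform),
    class = "sgs_dataset"
  )
}

#' @export
print.sgs_dataset <- function(x, ...) {
  cat(sprintf("<sgs_dataset> %d points, %d variables, ccd %.4g um (%s)\n",
              nrow(x$coords), nrow(x$expr), x$ccd, x$platform))
  invisible(x)
}

#' Estimate the center-to-center distance from coordinates
#'
#' Mean of per-point nearest-neighbour distances after trimming values
#' outside 1.5 x IQR beyond the quartiles, so irregular or partially masked
#' layouts do not inflate the estimate.
#'
#' @param coords Data frame with `x`, `y` in micrometers.
#' @return Scalar CCD in micrometers.
#' @export
estimate_ccd <- function(coords) {
  nn <- nn_distances(coords$x, coords$y)
  q <- stats::quantile(nn, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  keep <- nn >= q[1] - 1.5 * iqr & nn <= q[2] + 1.5 * iqr
  mean(nn[keep])
}

# Nearest-neighbour distances via cell binning; O(n) in practice, no kd-tree
# dependency. Widening search handles sparse neighbourhoods.
nn_distances <- function(x, y) {
  n <- length(x)
  if (n < 2) stop("need at least 2 points", call. = FALSE)
  if (n <= 200) {
    d <- as.matrix(stats::dist(cbind(x, y)))
    diag(d) <- Inf
    return(apply(d, 1, min))
  }
  span <- max(diff(range(x)), diff(range(y)), .Machine$double.eps)
  cell <- span / max(1, floor(sqrt(n)))
  cx <- floor((x - min(x)) / cell)
  cy <- floor((y - min(y)) / cell)
  key <- paste(cx, cy)
  idx_by_cell <- split(seq_len(n), key)
  out <- numeric(n)
  for (i in seq_len(n)) {
    r <- 1
    best <- Inf
    repeat {
      cand <- integer(0)
      for (dx in -r:r) for (dy in -r:r) {
        k <- paste(cx[i] + dx, cy[i] + dy)
        j <- idx_by_cell[[k]]
        if (!is.null(j)) cand <- c(cand, j)
      }
      cand <- setdiff(cand, i)
      if (length(cand)) {
        best <- min(sqrt((x[cand] - x[i])^2 + (y[cand] - y[i])^2))
        # a neighbour in ring r guarantees correctness once r*cell >= best
        if (best <= r * cell) break
      }
      r <- r + 1
      if (r > 1000) break
    }
    out[i] <- best
  }
  out
}

#' Read a spatial dataset from files
#'
#' Coordinates come as CSV/TSV with header `id,x,y[,unit]`; expression as a
#' dense CSV/TSV (variables x points, first column variable names) or a
#' MatrixMarket `.mtx` triplet with `<path>.rownames` / `<path>.colnames`
#' sidecar text files (one name per line).
#'
#' @param coords_path Path to the coordinate table.
#' @param expr_path Path to the expression matrix.
#' @param ccd Center-to-center distance (length string or um) or `"auto"`.
#' @param px_per_um Optional pixel scale when the coordinate unit is `px`.
#' @return An [sgs_dataset()].
#' @export
read_dataset <- function(coords_path, expr_path, ccd = "auto", px_per_um = NULL) {
  coords <- readr::read_delim(coords_path, delim = sniff_delim(coords_path),
                              show_col_types = FALSE, progress = FALSE)
  if (!all(c("id", "x", "y") %in% names(coords))) {
    stop("coordinate file must have columns id, x, y", call. = FALSE)
  }
  if (!is.numeric(coords$x) || !is.numeric(coords$y)) {
    stop("non-numeric coordinates in ", coords_path, call. = FALSE)
  }
  if ("unit" %in% names(coords)) {
    u <- unique(coords$unit)
    if (length(u) != 1) stop("mixed coordinate units", call. = FALSE)
    fac <- parse_length(paste0("1", u), px_per_um = px_per_um)
    coords$x <- coords$x * fac
    coords$y <- coords$y * fac
    coords$unit <- NULL
  }
  expr <- read_expr_matrix(expr_path)
  sgs_dataset(coords, expr, ccd = ccd)
}

read_expr_matrix <- function(path) {
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(paste0(path, ".rownames"))
    cn <- readLines(paste0(path, ".colnames"))
    stopifnot(nrow(m) == length(rn), ncol(m) == length(cn))
    dimnames(m) <- list(rn, cn)
    return(m)
  }
  df <- readr::read_delim(path, delim = sniff_delim(path),
                          show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

sniff_delim <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\t", first)) "\t" else ","
}

#' Write a spatial dataset to files
#'
#' Inverse of [read_dataset()]: coordinates as CSV (`id,x,y`, um) and the
#' expression matrix as dense TSV with variable names in the first column.
#'
#' @param ds An [sgs_dataset()].
#' @param coords_path,expr_path Output paths.
#' @return Invisibly, `ds`.
#' @export
write_dataset <- function(ds, coords_path, expr_path) {
  stopifnot(inherits(ds, "sgs_dataset"))
  readr::write_csv(ds$coords, coords_path, progress = FALSE)
  df <- tibble::as_tibble(ds$expr, rownames = "variable")
  readr::write_tsv(df, expr_path, progress = FALSE)
  invisible(ds)
}
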