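#' Analysis grid for histograms and free-energy maps
#'
#' A regular grid over reaction-coordinate space with half-open bins
#' `[lo, hi)` identified by their centers. The default spacing of 0.1 Å
#' per axis is the resolution at which umbrella-sampling histograms are
#' accumulated and PMFs reported.
#'
#' @param lower,upper Numeric vectors (Å), one entry per axis.
#' @param spacing Bin width (Å), scalar or per axis; `(upper - lower) /
#'   spacing` must be an integer (to within 1e-9).
#' @return An object of class `analysis_grid` with per-axis bin counts
#'   and centers.
#' @export
analysis_grid <- function(lower, upper, spacing = 0.1) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  stopifnot(length(lower) == length(upper), all(upper > lower),
            length(lower) %in% 1:2)
  spacing <- rep_len(as.numeric(spacing), length(lower))
  stopifnot(all(spacing > 0))
  nb <- (upper - lower) / spacing
  if (any(abs(nb - round(nb)) > 1e-9))
    stop("(upper - lower) must be an integer multiple of spacing")
  nb <- as.integer(round(nb))
  centers <- lapply(seq_along(nb), function(d)
    lower[d] + (seq_len(nb[d]) - 0.5) * spacing[d])
  structure(list(lower = lower, upper = upper, spacing = spacing,
                 nbins = nb, dimension = length(nb), centers = centers),
            class = "analysis_grid")
}

#' @export
print.analysis_grid <- function(x, ...) {
  cat(sprintf("Analysis grid (%dD): %s, spacing %s A, %s bins\n",
              x$dimension,
              paste(sprintf("[%.3g, %.3g)", x$lower, x$upper), collapse = " x "),
              paste(signif(x$spacing, 4), collapse = "/"),
              paste(x$nbins, collapse = " x ")))
  invisible(x)
}

.same_grid <- function(a, b) {
  isTRUE(all.equal(a$lower, b$lower)) && isTRUE(all.equal(a$upper, b$upper)) &&
    isTRUE(all.equal(a$spacing, b$spacing))
}

# Per-axis bin index with the half-open convention: a sample exactly on a
# bin edge belongs to the upper bin. Returns NA outside the grid.
.axis_bin <- function(z, lo, spacing, nbins) {
  u <- (z - lo) / spacing
  snap <- abs(u - round(u)) < 1e-9
  u[snap] <- round(u[snap])
  idx <- floor(u) + 1
  idx[idx < 1 | idx > nbins] <- NA_integer_
  as.integer(idx)
}

#' Map coordinates to linear bin indices
#'
#' @param grid An [analysis_grid()].
#' @param z Coordinate vector or matrix (rows = points).
#' @return Integer vector of linear (column-major) bin indices; `NA` for
#'   points outside the grid.
#' @export
bin_index <- function(grid, z) {
  stopifnot(inherits(grid, "analysis_grid"))
  if (is.null(dim(z))) {
    z <- if (grid$dimension == 1) matrix(z, ncol = 1)
         else matrix(z, ncol = grid$dimension, byrow = FALSE,
                     nrow = length(z) / grid$dimension)
  }
  z <- as.matrix(z)
  stopifnot(ncol(z) == grid$dimension)
  idx <- .axis_bin(z[, 1], grid$lower[1], grid$spacing[1], grid$nbins[1])
  if (grid$dimension == 2) {
    i2 <- .axis_bin(z[, 2], grid$lower[2], grid$spacing[2], grid$nbins[2])
    idx <- idx + (i2 - 1L) * grid$nbins[1]
    idx[is.na(i2)] <- NA_integer_
  }
  idx
}

# All bin centers as a matrix (rows follow linear/column-major bin order).
.bin_centers <- function(grid) {
  if (grid$dimension == 1) matrix(grid$centers[[1]], ncol = 1)
  else as.matrix(expand.grid(grid$centers[[1]], grid$centers[[2]],
                             KEEP.OUT.ATTRS = FALSE))
}
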