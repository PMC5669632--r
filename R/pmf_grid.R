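#' Gridded potential of mean force
#'
#' A free-energy value per grid bin, referenced so that the minimum over
#' sampled (defined) bins is exactly zero. Bins never visited by any
#' window carry `NA`, an explicit "undefined" marker, and are excluded
#' from every downstream statistic.
#'
#' @param grid An [analysis_grid()].
#' @param f Numeric vector of free energies (kcal/mol), one per bin in
#'   linear bin order; `NA` marks unsampled bins.
#' @param temperature Temperature (K) at which the map was produced.
#' @return An object of class `pmf_grid`.
#' @export
pmf_grid <- function(grid, f, temperature) {
  stopifnot(inherits(grid, "analysis_grid"),
            length(f) == prod(grid$nbins))
  if (all(is.na(f))) stop("PMF has no defined bins")
  f <- f - min(f, na.rm = TRUE)
  structure(list(grid = grid, f = as.numeric(f), mask = !is.na(f),
                 temperature = temperature),
            class = "pmf_grid")
}

#' @export
print.pmf_grid <- function(x, ...) {
  cat(sprintf("PMF on %s grid: %d/%d bins defined, range 0 to %.3g kcal/mol (T = %.5g K)\n",
              paste(x$grid$nbins, collapse = " x "),
              sum(x$mask), length(x$f), max(x$f, na.rm = TRUE),
              x$temperature))
  invisible(x)
}

#' @export
as.data.frame.pmf_grid <- function(x, row.names = NULL, optional = FALSE, ...) {
  ctr <- .bin_centers(x$grid)
  df <- as.data.frame(ctr)
  names(df) <- paste0("z", seq_len(ncol(ctr)))
  df$f <- x$f
  df
}

#' @export
plot.pmf_grid <- function(x, max_f = NULL, ...) {
  g <- x$grid
  if (g$dimension == 1) {
    plot(g$centers[[1]], x$f, type = "l", xlab = "z (A)",
         ylab = "F (kcal/mol)", ...)
  } else {
    fm <- matrix(x$f, nrow = g$nbins[1])
    if (!is.null(max_f)) fm[fm > max_f] <- NA
    image(g$centers[[1]], g$centers[[2]], fm, xlab = "z1 (A)",
          ylab = "z2 (A)", col = hcl.colors(64, "viridis"), ...)
    contour(g$centers[[1]], g$centers[[2]], fm, add = TRUE,
            col = "grey30", lwd = 0.5)
  }
  invisible(x)
}

#' Exact Boltzmann reference PMF of an analytic landscape
#'
#' Evaluates the landscape at every bin center and subtracts the minimum.
#' For these reaction-coordinate-space landscapes no marginalization is
#' involved, so this is the exact free-energy surface any unbiasing
#' scheme should recover, independent of temperature; it serves as the
#' oracle in the WHAM and adaptive-sampling tests.
#'
#' @param landscape An [analytic_landscape()].
#' @param grid An [analysis_grid()] inside the landscape domain.
#' @param temperature Temperature (K), recorded in the result.
#' @return A [pmf_grid()] with every bin defined and minimum exactly 0.
#' @export
boltzmann_pmf <- function(landscape, grid, temperature = 323.25) {
  stopifnot(inherits(landscape, "analytic_landscape"),
            inherits(grid, "analysis_grid"),
            grid$dimension == landscape$dimension)
  u <- potential(landscape, .bin_centers(grid))
  pmf_grid(grid, u - min(u), temperature)
}

#' Write or read a PMF as whitespace-delimited text
#'
#' One row per bin: bin-center coordinate(s), then the free energy, with
#' `nan` marking undefined bins. Grid geometry and temperature are stored
#' on `#` header lines so the file round-trips.
#'
#' @param pmf A [pmf_grid()].
#' @param path File path.
#' @return `read_pmf()` returns a [pmf_grid()].
#' @export
write_pmf <- function(pmf, path) {
  stopifnot(inherits(pmf, "pmf_grid"))
  g <- pmf$grid
  hdr <- c(sprintf("# lower %s", paste(g$lower, collapse = " ")),
           sprintf("# upper %s", paste(g$upper, collapse = " ")),
           sprintf("# spacing %s", paste(g$spacing, collapse = " ")),
           sprintf("# temperature %.10g", pmf$temperature))
  body <- cbind(.bin_centers(g), pmf$f)
  lines <- apply(body, 1, function(r) paste(sprintf("%.10g", r), collapse = " "))
  lines <- gsub("NA", "nan", lines, fixed = TRUE)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' @rdname write_pmf
#' @export
read_pmf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key) {
    ln <- grep(paste0("^# ", key, " "), hdr, value = TRUE)[1]
    as.numeric(strsplit(sub(paste0("^# ", key, " "), "", ln), " +")[[1]])
  }
  g <- analysis_grid(getv("lower"), getv("upper"), getv("spacing"))
  body <- lines[!grepl("^#", lines)]
  vals <- t(vapply(strsplit(trimws(body), "[ \t]+"), function(x)
    suppressWarnings(as.numeric(x)), numeric(g$dimension + 1)))
  f <- vals[, g$dimension + 1]
  pmf_grid(g, f, getv("temperature"))
}
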