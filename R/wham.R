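#' Histogram a biased trajectory onto an analysis grid
#'
#' Samples recorded during the first `discard` ps are treated as
#' equilibration and dropped (the time-honored 100 ps of a 600 ps
#' umbrella window); each retained sample increments exactly one
#' half-open bin. Samples falling outside the grid are counted in an
#' overflow tally and excluded.
#'
#' @param traj An [rc_trajectory()].
#' @param grid An [analysis_grid()] of the same dimension.
#' @param discard Equilibration time to drop (ps, default 100); a sample
#'   at time t is retained when t > discard.
#' @return An object of class `window_data` with the bias, per-bin counts
#'   `counts`, retained sample count `n`, overflow count, and the
#'   retained samples themselves (needed for adaptive seeding and
#'   interval slicing).
#' @export
bin_samples <- function(traj, grid, discard = 100) {
  stopifnot(inherits(traj, "rc_trajectory"), inherits(grid, "analysis_grid"),
            ncol(traj$coords) == grid$dimension)
  keep <- traj$times > discard
  if (!any(keep))
    stop("empty window: all samples fall inside the equilibration discard")
  z <- traj$coords[keep, , drop = FALSE]
  idx <- bin_index(grid, z)
  counts <- tabulate(idx[!is.na(idx)], nbins = prod(grid$nbins))
  structure(list(bias = traj$bias, grid = grid,
                 counts = counts, n = sum(counts),
                 overflow = sum(is.na(idx)),
                 samples = z, times = traj$times[keep],
                 discard = discard),
            class = "window_data")
}

#' @export
print.window_data <- function(x, ...) {
  cat(sprintf("Umbrella window at %s (k = %s): %d retained samples in %d bins (%d overflow)\n",
              paste(signif(x$bias$center, 4), collapse = "/"),
              paste(signif(x$bias$k, 4), collapse = "/"),
              x$n, sum(x$counts > 0), x$overflow))
  invisible(x)
}

# window x bin bias-energy matrix, evaluated at bin centers
.bias_matrix <- function(windows, centers) {
  t(vapply(windows, function(w) .bias_energy(w$bias, centers),
           numeric(nrow(centers))))
}

# Connected components of the window-overlap graph (windows are linked
# when they have counts in a common bin). WHAM cannot tie together groups
# that share no histogram support.
.window_components <- function(counts_mat) {
  nw <- nrow(counts_mat)
  comp <- seq_len(nw)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (b in which(colSums(counts_mat > 0) > 1)) {
    ws <- which(counts_mat[, b] > 0)
    r <- find(ws[1])
    for (j in ws[-1]) comp[find(j)] <- r
  }
  roots <- vapply(seq_len(nw), find, integer(1))
  split(seq_len(nw), match(roots, unique(roots)))
}

#' Unbias umbrella windows into a PMF by self-consistent WHAM
#'
#' Iterates the weighted-histogram equations
#' \deqn{P(b) \propto \frac{\sum_i n_i(b)}{\sum_i N_i \exp[(f_i - w_i(b))/kT]},
#'       \qquad f_i = -kT \ln \sum_b P(b) e^{-w_i(b)/kT}}
#' to self-consistency, with the bias \eqn{w_i} evaluated at bin centers
#' and the first window's offset anchored at zero. The returned PMF is
#' \eqn{-kT \ln P(b)} re-referenced so its minimum over sampled bins is
#' exactly zero; unsampled bins stay undefined. Exponentials are handled
#' in a factored form with re-anchored offsets so that windows far apart
#' underflow harmlessly to zero weight instead of overflowing.
#'
#' @param windows List of [bin_samples()] results sharing one grid.
#' @param grid The common [analysis_grid()].
#' @param temperature Temperature (K).
#' @param tolerance Convergence threshold on `max |delta f_i|`
#'   (kcal/mol); default 1e-7, far below thermal noise.
#' @param max_iterations Iteration cap; exceeding it returns an
#'   unconverged result rather than an error.
#' @param f_init Optional initial free-energy offsets (kcal/mol), e.g.
#'   the previous round's offsets during adaptive sampling.
#' @return An object of class `wham_fit`: `pmf` ([pmf_grid()]),
#'   per-window offsets `offsets` (kcal/mol, first anchored at 0),
#'   `iterations`, `converged`, `residual`, and the window list.
#' @export
wham_solve <- function(windows, grid, temperature = 323.25,
                       tolerance = 1e-7, max_iterations = 1e5,
                       f_init = NULL) {
  stopifnot(length(windows) >= 1,
            all(vapply(windows, inherits, logical(1), "window_data")))
  for (w in windows)
    if (!.same_grid(w$grid, grid)) stop("windows disagree on the grid")
  C <- t(vapply(windows, `[[`, numeric(prod(grid$nbins)), "counts"))
  ct <- colSums(C)
  if (!any(ct > 0)) stop("no bin has any counts")
  comps <- .window_components(C)
  if (length(comps) > 1)
    stop("disconnected sampling: window groups {",
         paste(vapply(comps, paste, character(1), collapse = ","),
               collapse = "} {"), "} share no histogram bins")
  sampled <- which(ct > 0)
  centers <- .bin_centers(grid)[sampled, , drop = FALSE]
  kt <- kT(temperature)
  W <- .bias_matrix(windows, centers)        # I x Bs, w_i(b) >= 0
  EA <- exp(-W / kt)                         # underflow to 0 is harmless
  N <- vapply(windows, `[[`, numeric(1), "n")
  ctb <- ct[sampled]
  g <- if (is.null(f_init)) numeric(length(windows)) else {
    stopifnot(length(f_init) == length(windows))
    (f_init - f_init[1]) / kt
  }
  iter <- 0L
  resid <- Inf
  repeat {
    iter <- iter + 1L
    denom <- crossprod(EA, N * exp(g))[, 1]  # sum_i N_i e^{g_i} e^{-w/kT}
    p <- ctb / denom
    p <- p / sum(p)
    gnew <- -log((EA %*% p)[, 1])
    gnew <- gnew - gnew[1]
    resid <- kt * max(abs(gnew - g))
    g <- gnew
    if (resid < tolerance || iter >= max_iterations) break
  }
  fbins <- rep(NA_real_, prod(grid$nbins))
  fbins[sampled] <- -kt * log(p)
  structure(list(pmf = pmf_grid(grid, fbins, temperature),
                 offsets = g * kt, iterations = iter,
                 converged = resid < tolerance, residual = resid,
                 tolerance = tolerance, windows = windows,
                 temperature = temperature),
            class = "wham_fit")
}

#' @export
print.wham_fit <- function(x, ...) {
  cat(sprintf("WHAM solution: %d windows, %s after %d iterations (residual %.3g kcal/mol)\n",
              length(x$windows),
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$residual))
  print(x$pmf)
  invisible(x)
}

#' @export
plot.wham_fit <- function(x, ...) plot(x$pmf, ...)

#' @export
coef.wham_fit <- function(object, ...) object$offsets

#' Write a WHAM solution: PMF text plus a JSON sidecar
#'
#' The PMF goes to `path` in the [write_pmf()] format; window offsets,
#' iteration count and residual go to `<path>.json`.
#'
#' @param fit A [wham_solve()] result.
#' @param path Output path for the PMF text file.
#' @export
write_wham <- function(fit, path) {
  stopifnot(inherits(fit, "wham_fit"))
  write_pmf(fit$pmf, path)
  jsonlite::write_json(
    list(offsets = fit$offsets, iterations = fit$iterations,
         converged = fit$converged, residual = fit$residual,
         temperature = fit$temperature),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load umbrella windows listed in a metadata CSV
#'
#' The metadata file has columns `path`, then one or two `center*` and
#' `k*` columns (mirroring community WHAM-tool conventions); each path
#' points to a trajectory in the [write_trajectory()] text format. The
#' bias stored in the file header is overridden by the metadata columns
#' when both are present.
#'
#' @param meta_csv Path to the metadata CSV.
#' @param grid An [analysis_grid()].
#' @param discard Equilibration discard (ps).
#' @return List of `window_data`.
#' @export
read_windows <- function(meta_csv, grid, discard = 100) {
  meta <- read.csv(meta_csv, stringsAsFactors = FALSE)
  stopifnot("path" %in% names(meta))
  ccols <- grep("^center", names(meta), value = TRUE)
  kcols <- grep("^k", names(meta), value = TRUE)
  base <- dirname(meta_csv)
  lapply(seq_len(nrow(meta)), function(i) {
    p <- meta$path[i]
    if (!file.exists(p)) p <- file.path(base, meta$path[i])
    traj <- read_trajectory(p)
    if (length(ccols))
      traj$bias <- bias_spec(unlist(meta[i, ccols]),
                             if (length(kcols)) unlist(meta[i, kcols]) else 20)
    bin_samples(traj, grid, discard)
  })
}
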