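#' Configuration of the self-learning adaptive umbrella-sampling loop
#'
#' Starting from a single seed window, the loop repeatedly (i) simulates
#' the newly proposed windows, (ii) re-solves WHAM over all windows, and
#' (iii) proposes new windows on the neighboring lattice nodes whose
#' estimated free energy lies below the creation limit — so the window
#' set grows along the valleys of low free energy and stops at the
#' surrounding barriers and walls.
#'
#' @param spacing Window lattice spacing (Å, default 0.5); must be an
#'   integer multiple of `grid_spacing`.
#' @param creation_limit Upper free-energy limit for creating new windows
#'   (kcal/mol, default 12).
#' @param window_duration Sampling time per window (ps, default 600;
#'   scale down together with the sampler's `sampling_interval` for
#'   desk-scale runs).
#' @param equilibration Equilibration discard per window (ps, default 100).
#' @param force_constant Umbrella force constant (kcal/mol/Å^2, default 20).
#' @param topology Lattice neighborhood in 2D: 8 (default; follows
#'   diagonal valleys without staircase artifacts) or 4.
#' @param max_rounds Cap on the number of growth rounds.
#' @param temperature Temperature (K).
#' @param frontier How the free energy of a candidate node is estimated
#'   from the current PMF: `"interpolate"` (bilinear at the candidate
#'   center, the default) or `"nearest"` (the candidate's own bin).
#'   Where any of the needed bins is undefined, both fall back to the
#'   minimum defined free energy among the candidate's sampled
#'   neighboring bins (centers within 1.5 grid spacings); candidates
#'   with no sampled bin nearby are not proposed (sampling has not
#'   reached them yet).
#' @param grid_spacing Analysis-grid spacing (Å, default 0.1).
#' @param wham_tolerance,wham_max_iterations Passed to [wham_solve()].
#' @return An object of class `adaptive_config`.
#' @export
adaptive_config <- function(spacing = 0.5, creation_limit = 12,
                            window_duration = 600, equilibration = 100,
                            force_constant = 20, topology = 8,
                            max_rounds = 100, temperature = 323.25,
                            frontier = c("interpolate", "nearest"),
                            grid_spacing = 0.1, wham_tolerance = 1e-7,
                            wham_max_iterations = 1e5) {
  frontier <- match.arg(frontier)
  stopifnot(spacing > 0, creation_limit > 0, topology %in% c(4, 8),
            window_duration > equilibration, force_constant >= 0)
  ratio <- spacing / grid_spacing
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("lattice spacing must be an integer multiple of the grid spacing")
  structure(list(spacing = spacing, creation_limit = creation_limit,
                 window_duration = window_duration,
                 equilibration = equilibration,
                 force_constant = force_constant, topology = topology,
                 max_rounds = max_rounds, temperature = temperature,
                 frontier = frontier, grid_spacing = grid_spacing,
                 wham_tolerance = wham_tolerance,
                 wham_max_iterations = wham_max_iterations),
            class = "adaptive_config")
}

.lattice_neighbor_offsets <- function(dim, spacing, topology) {
  if (dim == 1) return(matrix(c(-spacing, spacing), ncol = 1))
  off <- expand.grid(dx = c(-spacing, 0, spacing),
                     dy = c(-spacing, 0, spacing))
  off <- off[!(off$dx == 0 & off$dy == 0), ]
  if (topology == 4) off <- off[off$dx == 0 | off$dy == 0, ]
  as.matrix(off)
}

.center_key <- function(m) apply(round(m, 9), 1, paste, collapse = "|")

# Free-energy estimate at an off-grid point from a (partially defined)
# PMF: multilinear interpolation over the surrounding bin centers; where
# any of those bins is undefined, the minimum defined value among the
# point's sampled neighboring bins (centers within 1.5 grid spacings);
# +Inf when none of them is defined -- sampling never reached the
# candidate, so it has no estimate yet.
.frontier_estimate <- function(pmf, pt, mode = "interpolate") {
  g <- pmf$grid
  fm <- array(pmf$f, dim = g$nbins)
  # bracketing bin centers per axis (clamped at the grid border)
  lo_i <- hi_i <- integer(g$dimension)
  frac <- numeric(g$dimension)
  for (d in seq_len(g$dimension)) {
    u <- (pt[d] - g$lower[d]) / g$spacing[d] - 0.5
    lo_i[d] <- max(1L, min(g$nbins[d] - 1L, as.integer(floor(u)) + 1L))
    hi_i[d] <- lo_i[d] + 1L
    frac[d] <- min(1, max(0, u - (lo_i[d] - 1L)))
  }
  corners <- as.matrix(expand.grid(lapply(seq_len(g$dimension), function(d)
    c(lo_i[d], hi_i[d]))))
  vals <- apply(corners, 1, function(ix)
    if (g$dimension == 1) fm[ix[1]] else fm[ix[1], ix[2]])
  # bins whose center lies within 1.5 grid spacings of the point
  fallback <- function() {
    rngs <- lapply(seq_len(g$dimension), function(d) {
      u <- (pt[d] - g$lower[d]) / g$spacing[d]
      max(1L, as.integer(ceiling(u - 1 - 1e-9))):
        min(g$nbins[d], as.integer(floor(u + 2 + 1e-9)))
    })
    v <- if (g$dimension == 1) fm[rngs[[1]]] else fm[rngs[[1]], rngs[[2]]]
    if (all(is.na(v))) Inf else min(v, na.rm = TRUE)
  }
  if (mode == "nearest") {
    nearest_idx <- vapply(seq_len(g$dimension), function(d) {
      i <- as.integer(floor((pt[d] - g$lower[d]) / g$spacing[d])) + 1L
      min(max(i, 1L), g$nbins[d])
    }, integer(1))
    v <- if (g$dimension == 1) fm[nearest_idx[1]]
         else fm[nearest_idx[1], nearest_idx[2]]
    return(if (is.na(v)) fallback() else v)
  }
  if (anyNA(vals)) return(fallback())
  if (g$dimension == 1)
    vals[1] * (1 - frac[1]) + vals[2] * frac[1]
  else {
    f00 <- vals[1]; f10 <- vals[2]; f01 <- vals[3]; f11 <- vals[4]
    (f00 * (1 - frac[1]) + f10 * frac[1]) * (1 - frac[2]) +
      (f01 * (1 - frac[1]) + f11 * frac[1]) * frac[2]
  }
}

#' Propose new umbrella windows on the lattice frontier
#'
#' Candidates are the lattice neighbors (per the configured topology) of
#' the completed window centers that have not been simulated yet and
#' whose estimated free energy is below the creation limit. The returned
#' centers are in lexicographic order, so proposal is deterministic.
#'
#' @param current A [wham_solve()] result for the completed windows, or
#'   `NULL` before the first round.
#' @param completed Matrix of completed window centers (possibly 0 rows).
#' @param config An [adaptive_config()].
#' @param bounds List with `lower`/`upper` domain bounds (Å).
#' @param seed_center Seed window center; returned as the sole proposal
#'   when nothing has been completed yet.
#' @return Matrix of proposed centers (0 rows when the frontier is
#'   exhausted).
#' @export
propose_new_windows <- function(current, completed, config, bounds,
                                seed_center = NULL) {
  dim <- length(bounds$lower)
  if (is.null(completed) || nrow(completed) == 0) {
    stopifnot(!is.null(seed_center))
    return(matrix(as.numeric(seed_center), nrow = 1))
  }
  off <- .lattice_neighbor_offsets(dim, config$spacing, config$topology)
  cand <- do.call(rbind, lapply(seq_len(nrow(completed)), function(i)
    sweep(off, 2, completed[i, ], "+")))
  cand <- cand[!duplicated(.center_key(cand)), , drop = FALSE]
  cand <- cand[!(.center_key(cand) %in% .center_key(completed)), ,
               drop = FALSE]
  inside <- rep(TRUE, nrow(cand))
  for (d in seq_len(dim))
    inside <- inside & cand[, d] >= bounds$lower[d] - 1e-9 &
      cand[, d] <= bounds$upper[d] + 1e-9
  cand <- cand[inside, , drop = FALSE]
  if (nrow(cand) == 0 || is.null(current)) return(cand[0, , drop = FALSE])
  est <- apply(cand, 1, function(p)
    .frontier_estimate(current$pmf, p, config$frontier))
  cand <- cand[est < config$creation_limit, , drop = FALSE]
  ord <- do.call(order, lapply(seq_len(dim), function(d) cand[, d]))
  cand[ord, , drop = FALSE]
}

#' Starting coordinate for a new window
#'
#' The new window inherits its starting configuration from its completed
#' neighbors: the retained sample, over all neighboring windows, closest
#' in Euclidean distance to the new center (ties broken by lowest window
#' index, then earliest sample).
#'
#' @param new_center Numeric center of the window to be created (Å).
#' @param neighbor_windows List of `window_data` for the completed
#'   neighboring windows (at least one).
#' @return Coordinate vector (Å).
#' @export
seed_position_for <- function(new_center, neighbor_windows) {
  if (length(neighbor_windows) == 0)
    stop("a new window needs at least one completed neighbor")
  best <- NULL
  bestd <- Inf
  for (w in neighbor_windows) {
    d2 <- colSums((t(w$samples) - new_center)^2)
    j <- which.min(d2)          # earliest sample on ties
    if (d2[j] < bestd) {        # strict: lowest window index on ties
      bestd <- d2[j]
      best <- w$samples[j, ]
    }
  }
  as.numeric(best)
}

#' Run the self-learning adaptive umbrella-sampling loop
#'
#' @param landscape An [analytic_landscape()].
#' @param seed_center Center of the seed window (Å); the lattice is
#'   anchored here.
#' @param config An [adaptive_config()].
#' @param brownian A [brownian_params()].
#' @param master_seed Integer; every per-window RNG seed is drawn
#'   deterministically from it, so the whole run transcript is
#'   reproducible.
#' @return An object of class `adaptive_run`: `rounds` (per round: new
#'   centers, their seeds, the WHAM solution after the round), `centers`
#'   (all window centers in creation order), `windows`, `final` (last
#'   WHAM solution), `grid`, `config`.
#' @export
run_adaptive <- function(landscape, seed_center, config, brownian,
                         master_seed = 1L) {
  stopifnot(inherits(landscape, "analytic_landscape"),
            inherits(config, "adaptive_config"),
            inherits(brownian, "brownian_params"))
  seed_center <- as.numeric(seed_center)
  stopifnot(length(seed_center) == landscape$dimension)
  .check_domain(landscape, matrix(seed_center, nrow = 1))
  grid <- analysis_grid(landscape$lower, landscape$upper,
                        config$grid_spacing)
  bounds <- list(lower = landscape$lower, upper = landscape$upper)
  # deterministic per-window seed pool, sized by the lattice
  n_nodes <- prod(floor((landscape$upper - landscape$lower) /
                          config$spacing) + 1)
  set.seed(master_seed)
  seed_pool <- sample.int(.Machine$integer.max, n_nodes, replace = FALSE)
  n_used <- 0L

  windows <- list()
  centers <- matrix(numeric(0), ncol = landscape$dimension)
  rounds <- list()
  solution <- NULL
  off <- .lattice_neighbor_offsets(landscape$dimension, config$spacing,
                                   config$topology)
  for (round_i in seq_len(config$max_rounds)) {
    proposals <- propose_new_windows(solution, centers, config, bounds,
                                     seed_center)
    if (nrow(proposals) == 0) break
    new_seeds <- integer(nrow(proposals))
    for (i in seq_len(nrow(proposals))) {
      ctr <- proposals[i, ]
      nbr_keys <- .center_key(sweep(off, 2, ctr, "+"))
      nbrs <- windows[.center_key(centers) %in% nbr_keys]
      start <- if (length(nbrs)) seed_position_for(ctr, nbrs) else ctr
      n_used <- n_used + 1L
      new_seeds[i] <- seed_pool[n_used]
      traj <- simulate_rc(landscape,
                          bias_spec(ctr, config$force_constant),
                          brownian, config$window_duration,
                          new_seeds[i], start = start)
      windows[[length(windows) + 1]] <-
        bin_samples(traj, grid, config$equilibration)
      centers <- rbind(centers, ctr)
    }
    f_init <- if (is.null(solution)) NULL
              else c(solution$offsets, rep(0, nrow(proposals)))
    solution <- tryCatch(
      wham_solve(windows, grid, config$temperature,
                 tolerance = config$wham_tolerance,
                 max_iterations = config$wham_max_iterations,
                 f_init = f_init),
      error = function(e)
        stop(sprintf("adaptive run aborted in round %d: %s", round_i,
                     conditionMessage(e)), call. = FALSE))
    rounds[[round_i]] <- list(new_centers = proposals, seeds = new_seeds,
                              wham = solution)
  }
  rownames(centers) <- NULL
  structure(list(rounds = rounds, centers = centers, windows = windows,
                 final = solution, grid = grid, config = config,
                 landscape = landscape, brownian = brownian,
                 master_seed = master_seed),
            class = "adaptive_run")
}

#' @export
print.adaptive_run <- function(x, ...) {
  cat(sprintf("Adaptive umbrella-sampling run: %d windows in %d rounds (lattice %.3g A, limit %.3g kcal/mol)\n",
              nrow(x$centers), length(x$rounds), x$config$spacing,
              x$config$creation_limit))
  if (!is.null(x$final)) print(x$final)
  invisible(x)
}

#' @export
plot.adaptive_run <- function(x, ...) {
  plot(x$final$pmf, ...)
  if (x$grid$dimension == 2)
    points(x$centers[, 1], x$centers[, 2], pch = 3, col = "white")
  invisible(x)
}
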