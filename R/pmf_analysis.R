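#' Combine independent umbrella-sampling runs into one PMF
#'
#' Pools the windows of two or more independent runs (e.g. automated
#' runs initiated in different ion-occupancy states) and performs a
#' single joint WHAM solve — the histogram analogue of combining forward
#' and backward perturbation runs: the combined map is NOT an average of
#' per-run PMFs, it is the maximum-likelihood solution of the pooled
#' sampling.
#'
#' @param window_sets List of two or more window lists (each as passed
#'   to [wham_solve()]).
#' @param grid The common [analysis_grid()].
#' @param temperature Temperature (K).
#' @param run_ids Optional character identifiers for provenance.
#' @param ... Passed to [wham_solve()].
#' @return A `wham_fit` whose `provenance` field lists the contributing
#'   runs and their window counts.
#' @export
combine_runs <- function(window_sets, grid, temperature = 323.25,
                         run_ids = NULL, ...) {
  stopifnot(is.list(window_sets), length(window_sets) >= 2)
  if (is.null(run_ids)) run_ids <- paste0("run", seq_along(window_sets))
  pooled <- do.call(c, window_sets)
  fit <- wham_solve(pooled, grid, temperature, ...)
  fit$provenance <- data.frame(
    run = run_ids,
    n_windows = vapply(window_sets, length, integer(1)))
  fit
}

#' Interval-based statistical error of a PMF
#'
#' The post-equilibration sampling of every window is subdivided into
#' consecutive disjoint slices (100 ps by default); each slice is
#' re-unbiased by a full WHAM solve. Every interval PMF is then given a
#' free-energy offset by a least-squares fit to the final PMF over the
#' grid points with final free energy below `mask_f` (closed form:
#' the offset is the mean of `final - interval` over the mask), and the
#' per-bin standard deviation over the last `n_last` offset interval
#' PMFs is reported. For the standard 600 ps windows with 100 ps
#' equilibration this yields exactly five 100 ps intervals.
#'
#' @param windows List of `window_data` (with retained samples).
#' @param final The final [pmf_grid()] from the full sampling.
#' @param slice_length Slice length (ps, default 100).
#' @param n_last Number of trailing intervals forming the ensemble
#'   (default 5).
#' @param mask_f Free-energy cutoff of the least-squares mask (kcal/mol,
#'   default 6).
#' @param temperature Temperature (K).
#' @param ... Passed to [wham_solve()].
#' @return An object of class `error_map`: per-bin standard deviation
#'   `sd` (kcal/mol; `NA` where any interval is unsampled), `n_intervals`,
#'   `slice_length`, the fit `mask`, the `offsets` applied, and the
#'   aligned interval PMFs.
#' @export
interval_error <- function(windows, final, slice_length = 100, n_last = 5,
                           mask_f = 6, temperature = 323.25, ...) {
  stopifnot(inherits(final, "pmf_grid"), length(windows) >= 1)
  grid <- windows[[1]]$grid
  discard <- windows[[1]]$discard
  t_end <- min(vapply(windows, function(w) max(w$times), numeric(1)))
  n_slices <- floor((t_end - discard) / slice_length)
  if (n_slices < n_last)
    stop(sprintf("only %d full slices of %g ps available, need %d",
                 n_slices, slice_length, n_last))
  use <- seq(n_slices - n_last + 1, n_slices)
  mask <- final$mask & final$f < mask_f
  f_final <- final$f
  aligned <- matrix(NA_real_, nrow = length(f_final), ncol = n_last)
  offsets <- numeric(n_last)
  for (j in seq_along(use)) {
    k <- use[j]
    t0 <- discard + (k - 1) * slice_length
    t1 <- discard + k * slice_length
    sliced <- lapply(windows, function(w) {
      sel <- w$times > t0 & w$times <= t1
      if (!any(sel))
        stop(sprintf("interval %d (%g-%g ps) leaves a window empty",
                     k, t0, t1))
      w$counts <- tabulate(bin_index(grid, w$samples[sel, , drop = FALSE]),
                           nbins = prod(grid$nbins))
      w$n <- sum(w$counts)
      w$samples <- w$samples[sel, , drop = FALSE]
      w$times <- w$times[sel]
      w
    })
    fit <- wham_solve(sliced, grid, temperature, ...)
    f_int <- fit$pmf$f
    if (any(mask & is.na(f_int)))
      stop(sprintf("interval %d (%g-%g ps) leaves %d mask bins unsampled",
                   k, t0, t1, sum(mask & is.na(f_int))))
    offsets[j] <- mean(f_final[mask] - f_int[mask])
    aligned[, j] <- f_int + offsets[j]
  }
  defined_all <- rowSums(!is.na(aligned)) == n_last
  sdv <- rep(NA_real_, length(f_final))
  sdv[defined_all] <- apply(aligned[defined_all, , drop = FALSE], 1, sd)
  structure(list(sd = sdv, n_intervals = n_last,
                 slice_length = slice_length, mask = mask,
                 offsets = offsets, aligned = aligned, grid = grid),
            class = "error_map")
}

#' @export
print.error_map <- function(x, ...) {
  cat(sprintf("Interval error map: %d intervals of %g ps; mean sd %.3g kcal/mol over %d mask bins\n",
              x$n_intervals, x$slice_length,
              mean(x$sd[x$mask], na.rm = TRUE), sum(x$mask)))
  invisible(x)
}

.neighbor_shifts <- function(dim) {
  if (dim == 1) matrix(c(-1L, 1L), ncol = 1)
  else {
    s <- as.matrix(expand.grid(di = -1:1, dj = -1:1))
    s[!(s[, 1] == 0 & s[, 2] == 0), , drop = FALSE]
  }
}

#' Locate occupancy-state minima on a PMF
#'
#' States are the defined bins that are strict minima over their full
#' neighborhood (8-connected in 2D) with free energy below `max_f`;
#' minima closer together than `merge_radius` are merged into the lower
#' one. On an ion-occupancy map these are the metastable filter
#' configurations (e.g. S0-S2-S4 or S1-S3-Cav).
#'
#' @param pmf A [pmf_grid()].
#' @param max_f Report only minima with F below this (kcal/mol,
#'   default 6).
#' @param merge_radius Merge radius (Å, default 0: no merging).
#' @param labels Optional character labels assigned in order of
#'   increasing free energy.
#' @return Data frame with columns `label`, the bin-center coordinates
#'   (`z1`[, `z2`]) and `f`, sorted by increasing free energy.
#' @export
find_states <- function(pmf, max_f = 6, merge_radius = 0, labels = NULL) {
  stopifnot(inherits(pmf, "pmf_grid"))
  g <- pmf$grid
  nb <- g$nbins
  fm <- array(pmf$f, dim = nb)
  shifts <- .neighbor_shifts(g$dimension)
  idx <- which(!is.na(pmf$f) & pmf$f < max_f)
  is_min <- logical(length(idx))
  for (ii in seq_along(idx)) {
    b <- idx[ii]
    ij <- if (g$dimension == 1) b else
      c((b - 1L) %% nb[1] + 1L, (b - 1L) %/% nb[1] + 1L)
    ok <- TRUE
    for (s in seq_len(nrow(shifts))) {
      q <- ij + shifts[s, ]
      if (any(q < 1L | q > nb)) next
      v <- if (g$dimension == 1) fm[q] else fm[q[1], q[2]]
      if (!is.na(v) && v <= pmf$f[b]) { ok <- FALSE; break }
    }
    is_min[ii] <- ok
  }
  mins <- idx[is_min]
  if (!length(mins)) {
    out <- data.frame(label = character(0), z1 = numeric(0), f = numeric(0))
    if (g$dimension == 2) out$z2 <- numeric(0)
    return(out)
  }
  ctr <- .bin_centers(g)[mins, , drop = FALSE]
  f <- pmf$f[mins]
  ord <- order(f)
  ctr <- ctr[ord, , drop = FALSE]; f <- f[ord]; mins <- mins[ord]
  keep <- logical(length(f))
  for (i in seq_along(f)) {
    if (merge_radius > 0 && any(keep)) {
      d <- sqrt(rowSums((ctr[keep, , drop = FALSE] -
                           matrix(ctr[i, ], sum(keep), g$dimension,
                                  byrow = TRUE))^2))
      if (any(d < merge_radius)) next
    }
    keep[i] <- TRUE
  }
  ctr <- ctr[keep, , drop = FALSE]; f <- f[keep]; mins <- mins[keep]
  if (is.null(labels)) labels <- sprintf("min%d", seq_along(f))
  out <- data.frame(label = labels[seq_along(f)], z1 = ctr[, 1], f = f,
                    bin = mins, stringsAsFactors = FALSE)
  if (g$dimension == 2) out <- data.frame(label = out$label, z1 = ctr[, 1],
                                          z2 = ctr[, 2], f = f, bin = mins,
                                          stringsAsFactors = FALSE)
  out
}

#' Minimax (widest) path and barrier between two states
#'
#' Finds the grid path between two states that minimizes the maximum
#' free energy encountered (modified Dijkstra over the defined bins,
#' 8-connected in 2D) — the way a saddle height is read off a
#' free-energy map. The barrier is `max F on the path - F(A)`.
#'
#' @param pmf A [pmf_grid()].
#' @param from,to State coordinates (Å): numeric vectors, or single rows
#'   of a [find_states()] data frame.
#' @return List of class `path_result`: `path` (matrix of bin-center
#'   coordinates from A to B), `barrier` (kcal/mol), `saddle`
#'   (coordinates of the highest bin on the path), `f_path` (free energy
#'   along the path).
#' @export
minimax_path <- function(pmf, from, to) {
  stopifnot(inherits(pmf, "pmf_grid"))
  g <- pmf$grid
  tocoord <- function(s) {
    if (is.data.frame(s))
      unlist(s[1, intersect(c("z1", "z2"), names(s))])
    else as.numeric(s)
  }
  a <- bin_index(g, matrix(tocoord(from), nrow = 1))
  b <- bin_index(g, matrix(tocoord(to), nrow = 1))
  if (is.na(a) || is.na(b) || is.na(pmf$f[a]) || is.na(pmf$f[b]))
    stop("both states must lie on defined bins")
  if (a == b)
    return(structure(list(path = .bin_centers(g)[integer(0), , drop = FALSE],
                          barrier = 0, saddle = NULL, f_path = numeric(0)),
                     class = "path_result"))
  nb <- g$nbins
  defined <- which(!is.na(pmf$f))
  sub <- match(seq_len(prod(nb)), defined)   # full -> subset index
  f <- pmf$f[defined]
  nv <- length(defined)
  score <- rep(Inf, nv)
  prev <- rep(NA_integer_, nv)
  done <- logical(nv)
  s0 <- sub[a]
  score[s0] <- f[s0]
  shifts <- .neighbor_shifts(g$dimension)
  ij_all <- if (g$dimension == 1) matrix(defined, ncol = 1) else
    cbind((defined - 1L) %% nb[1] + 1L, (defined - 1L) %/% nb[1] + 1L)
  repeat {
    masked <- ifelse(done, Inf, score)
    u <- which.min(masked)
    if (!is.finite(masked[u])) break
    if (u == sub[b]) break
    done[u] <- TRUE
    ij <- ij_all[u, ]
    for (s in seq_len(nrow(shifts))) {
      q <- ij + shifts[s, ]
      if (any(q < 1L | q > nb)) next
      lin <- if (g$dimension == 1) q[1] else q[1] + (q[2] - 1L) * nb[1]
      v <- sub[lin]
      if (is.na(v) || done[v]) next
      cand <- max(score[u], f[v])
      if (cand < score[v]) { score[v] <- cand; prev[v] <- u }
    }
  }
  if (!is.finite(score[sub[b]]))
    stop("states are not connected through defined bins")
  path_sub <- sub[b]
  while (!is.na(prev[path_sub[1]]))
    path_sub <- c(prev[path_sub[1]], path_sub)
  bins <- defined[path_sub]
  fp <- pmf$f[bins]
  imax <- which.max(fp)
  structure(list(path = .bin_centers(g)[bins, , drop = FALSE],
                 barrier = max(fp) - pmf$f[a],
                 saddle = .bin_centers(g)[bins[imax], ],
                 f_path = fp),
            class = "path_result")
}

#' @export
print.path_result <- function(x, ...) {
  cat(sprintf("Minimax path: %d bins, barrier %.4g kcal/mol%s\n",
              nrow(x$path), x$barrier,
              if (is.null(x$saddle)) "" else
                sprintf(" (saddle at %s A)",
                        paste(signif(x$saddle, 4), collapse = "/"))))
  invisible(x)
}

#' Assign ions to filter sites and count permeation events
#'
#' Each frame maps each ion's pore-axis position to the unique interval
#' of a strictly decreasing boundary list (extracellular side high,
#' intracellular low). With the canonical 7 boundaries the sites are
#' extracellular, S0-S4, Cav (cavity) and intracellular. A permeation
#' event is an ion crossing from below the lowest boundary (the
#' Cav/intracellular cutoff) to above the highest (the
#' extracellular/S0 cutoff), with hysteresis: both thresholds must be
#' fully crossed, in order, so mere oscillation across one internal
#' boundary never counts.
#'
#' @param ion_z Matrix of pore-axis positions (Å), one row per frame, one
#'   column per tracked ion (a vector is taken as a single ion).
#' @param boundaries Strictly decreasing z cutoffs (Å).
#' @param sites Optional site names, length `length(boundaries) + 1`.
#' @param bound_sites Site names counted as "bound to the filter"
#'   (default S0-S4 when present).
#' @return An object of class `occupancy_series`: `sites` (character
#'   matrix frame x ion), `bound_count` (ions bound per frame),
#'   `cumulative_events` (non-decreasing), `events` (total count).
#' @export
classify_occupancy <- function(ion_z, boundaries, sites = NULL,
                               bound_sites = NULL) {
  if (is.null(dim(ion_z))) ion_z <- matrix(ion_z, ncol = 1)
  ion_z <- as.matrix(ion_z)
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) < 1 || any(diff(boundaries) >= 0))
    stop("boundaries must be strictly decreasing along z")
  k <- length(boundaries)
  if (is.null(sites)) {
    sites <- if (k == 7)
      c("extracellular", "S0", "S1", "S2", "S3", "S4", "Cav",
        "intracellular")
    else c("extracellular", paste0("site", seq_len(k - 1)),
           "intracellular")
  }
  stopifnot(length(sites) == k + 1)
  if (is.null(bound_sites))
    bound_sites <- intersect(c("S0", "S1", "S2", "S3", "S4"), sites)
  nf <- nrow(ion_z); ni <- ncol(ion_z)
  site_idx <- matrix(0L, nf, ni)
  for (j in seq_len(ni))
    site_idx[, j] <- 1L + rowSums(outer(ion_z[, j], boundaries, "<="))
  site_lab <- matrix(sites[site_idx], nf, ni)
  bound <- matrix(site_lab %in% bound_sites, nf, ni)
  bound_count <- rowSums(bound)
  # hysteresis counter per ion
  upper <- boundaries[1]; lowest <- boundaries[k]
  cum <- numeric(nf)
  total <- 0L
  per_frame_events <- integer(nf)
  for (j in seq_len(ni)) {
    armed <- FALSE
    for (t in seq_len(nf)) {
      z <- ion_z[t, j]
      if (!armed && z <= lowest) armed <- TRUE
      else if (armed && z > upper) {
        armed <- FALSE
        per_frame_events[t] <- per_frame_events[t] + 1L
      }
    }
  }
  cum <- cumsum(per_frame_events)
  total <- sum(per_frame_events)
  structure(list(sites = site_lab, bound_count = bound_count,
                 cumulative_events = cum, events = total,
                 boundaries = boundaries, site_names = sites),
            class = "occupancy_series")
}

#' @export
print.occupancy_series <- function(x, ...) {
  cat(sprintf("Occupancy series: %d frames, %d ions; %d permeation events; max bound ions %d\n",
              nrow(x$sites), ncol(x$sites), x$events, max(x$bound_count)))
  invisible(x)
}

#' Toy three-ion permeation cycle
#'
#' Constructs an idealized coordinate series in which ions step through
#' the knock-on cycle S1-S3-Cav -> S0-S2-S4 -> release: each release
#' puts one ion above the extracellular cutoff while a fresh ion enters
#' the cavity from the intracellular side (modeled by wrapping the
#' released ion around). The constructed number of releases is the
#' ground-truth permeation count for testing the event counter, and at
#' most three ions are ever bound to the filter.
#'
#' @param n_releases Number of completed permeation events to construct
#'   (ground truth for the counter).
#' @return List with `ion_z` (frame x 3 matrix, Å), the matching
#'   `boundaries` (Å), and `n_events` (= `n_releases`).
#' @export
toy_permeation_cycle <- function(n_releases = 3) {
  boundaries <- c(6, 4.5, 3, 1.5, 0, -1.5, -3)
  # stations: intracellular, Cav, S4, S3, S2, S1, S0, extracellular
  stations <- c(-4, -2.25, -0.75, 0.75, 2.25, 3.75, 5.25, 7)
  # ions advance one station per frame, staggered two stations apart,
  # wrapping from the extracellular side back below the cavity; starting
  # at (S1, S3, Cav), ion j first reaches the top unarmed, dips below,
  # and from then on releases once per 8-frame revolution.  The n-th
  # completed event lands at 0-based frame 8*ceil(n/3) + 2*(1 + (n-1)%%3).
  stopifnot(n_releases >= 1)
  k <- ceiling(n_releases / 3)
  t_last <- 8 * k + 2 * (1 + (n_releases - 1) %% 3)
  nf <- t_last + 1
  s0 <- c(6, 4, 2)
  ion_z <- vapply(1:3, function(j)
    stations[((s0[j] - 1 + seq_len(nf) - 1) %% 8) + 1], numeric(nf))
  list(ion_z = ion_z, boundaries = boundaries, n_events = n_releases)
}
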