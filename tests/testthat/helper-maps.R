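# Shared fixtures: engineered 2D maps and lattice oracles for the
# adaptive-sampling tests.
#
# The three maps keep every sub-limit lattice node at F <= 11 kcal/mol
# and every excluded node at F >= 16, with the 12 kcal/mol contour at
# least 0.25 A from every excluded node, so the window set grown by the
# self-learning loop can be compared bin-for-bin with a flood fill of
# the analytic surface.

open_pair_map <- function() {
  analytic_landscape("permeation_map",
                     bounds = list(lower = c(0, 0), upper = c(6, 4)),
                     wells = rbind(c(1.5, 2), c(4.5, 2)), barriers = 2.5,
                     k_transverse = 40, k_wall = 32)
}

closed_pair_map <- function() {
  analytic_landscape("permeation_map",
                     bounds = list(lower = c(0, 0), upper = c(6, 4)),
                     wells = rbind(c(1.5, 2), c(4.5, 2)), barriers = 22,
                     k_transverse = 40, k_wall = 32)
}

triple_chain_map <- function() {
  analytic_landscape("permeation_map",
                     bounds = list(lower = c(0, 0), upper = c(6, 4)),
                     wells = rbind(c(1.5, 2), c(3, 2), c(4.5, 2)),
                     barriers = c(4, 5),
                     k_transverse = 40, k_wall = 32)
}

# all lattice nodes (spacing 0.5 A) anchored at `seed`, inside the domain
lattice_nodes <- function(ls, seed, spacing = 0.5) {
  ax <- lapply(seq_len(ls$dimension), function(d) {
    lo <- seed[d] - spacing * floor((seed[d] - ls$lower[d]) / spacing)
    seq(lo, ls$upper[d], by = spacing)
  })
  if (ls$dimension == 1) matrix(ax[[1]], ncol = 1)
  else as.matrix(expand.grid(ax[[1]], ax[[2]]))
}

node_key <- function(m) apply(round(m, 6), 1, paste, collapse = "|")

# independent oracle: nodes below `limit` reachable from the seed node
# through sub-limit 8-connected lattice steps on the analytic surface
flood_fill_oracle <- function(ls, seed, spacing = 0.5, limit = 12) {
  nodes <- lattice_nodes(ls, seed, spacing)
  f <- potential(ls, nodes)
  f <- f - min(f)
  ok <- f < limit
  key <- node_key(nodes)
  reach <- logical(nrow(nodes))
  start <- which(key == node_key(matrix(seed, nrow = 1)))
  stopifnot(length(start) == 1, ok[start])
  reach[start] <- TRUE
  frontier <- start
  off <- as.matrix(expand.grid(c(-spacing, 0, spacing),
                               c(-spacing, 0, spacing)))
  off <- off[rowSums(off != 0) > 0, , drop = FALSE]
  if (ncol(nodes) == 1) off <- matrix(c(-spacing, spacing), ncol = 1)
  while (length(frontier)) {
    nxt <- integer(0)
    for (i in frontier) {
      j <- match(node_key(sweep(off, 2, nodes[i, ], "+")), key)
      j <- j[!is.na(j)]
      j <- j[ok[j] & !reach[j]]
      reach[j] <- TRUE
      nxt <- c(nxt, j)
    }
    frontier <- nxt
  }
  nodes[reach, , drop = FALSE]
}

# umbrella windows on a 1D landscape plus the matching analysis grid
# (window span widened by half the window spacing)
make_1d_windows <- function(ls, centers, duration = 600, discard = 100,
                            k = 20, seed0 = 100,
                            params = brownian_params()) {
  half <- diff(centers[1:2]) / 2
  lo <- floor((min(centers) - half) / 0.1) * 0.1
  hi <- ceiling((max(centers) + half) / 0.1) * 0.1
  grid <- analysis_grid(lo, hi, 0.1)
  wins <- lapply(seq_along(centers), function(i) {
    tr <- simulate_rc(ls, bias_spec(centers[i], k), params, duration,
                      seed = seed0 + i)
    bin_samples(tr, grid, discard)
  })
  list(windows = wins, grid = grid)
}

rms_vs_oracle <- function(fit, ls, grid, max_f = 6) {
  orac <- boltzmann_pmf(ls, grid)
  sel <- fit$pmf$mask & orac$f < max_f
  sqrt(mean((fit$pmf$f[sel] - orac$f[sel])^2))
}
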