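test_that("combining a split run reproduces the unsplit PMF bit-for-bit", {
  dw <- analytic_landscape("double_well", half_separation = 1, barrier = 3,
                           bounds = list(lower = -2, upper = 2))
  mk <- make_1d_windows(dw, seq(-1.5, 1.5, 0.5), duration = 60, discard = 10)
  whole <- wham_solve(mk$windows, mk$grid, 323.25)
  halves <- combine_runs(list(mk$windows[1:3], mk$windows[4:7]), mk$grid,
                         323.25)
  expect_identical(halves$pmf$f, whole$pmf$f)
  # passing the same run twice = duplication invariance (identical up to
  # floating-point summation order over the doubled window list)
  dup <- combine_runs(list(mk$windows, mk$windows), mk$grid, 323.25)
  expect_equal(dup$pmf$f, whole$pmf$f, tolerance = 1e-12)
  expect_equal(halves$provenance$n_windows, c(3L, 4L))
})

test_that("pooled disconnected runs raise an error", {
  g <- analysis_grid(0, 1, 0.1)
  mkw <- function(z, c0) {
    tr <- structure(list(times = seq_along(z), coords = matrix(z, ncol = 1),
                         bias = bias_spec(c0, 20), seed = 0L),
                    class = "rc_trajectory")
    bin_samples(tr, g, 0)
  }
  set.seed(2)
  r1 <- list(mkw(runif(50, 0, 0.2), 0.1))
  r2 <- list(mkw(runif(50, 0.8, 1), 0.9))
  expect_error(combine_runs(list(r1, r2), g, 300), "disconnected")
})

test_that("interval error is zero for degenerate identical intervals", {
  g <- analysis_grid(0, 1, 0.1)
  pattern <- rep(seq(0.05, 0.95, 0.1), 10)          # 100 samples per slice
  z <- rep(pattern, 6)
  tr <- structure(list(times = seq_along(z), coords = matrix(z, ncol = 1),
                       bias = bias_spec(0, 0), seed = 0L),
                  class = "rc_trajectory")
  w <- bin_samples(tr, g, discard = 100)
  final <- wham_solve(list(w), g, 300)$pmf
  em <- interval_error(list(w), final, slice_length = 100, n_last = 5,
                       temperature = 300)
  expect_equal(em$n_intervals, 5)
  expect_true(all(em$sd[!is.na(em$sd)] == 0))
  expect_true(all(em$offsets == 0))
})

test_that("600 ps windows with 100 ps equilibration give exactly 5 intervals", {
  h <- analytic_landscape("harmonic", k = 2, center = 0,
                          bounds = list(lower = -2, upper = 2))
  mk <- make_1d_windows(h, c(-0.5, 0, 0.5), duration = 600, discard = 100)
  final <- wham_solve(mk$windows, mk$grid, 323.25)
  em <- interval_error(mk$windows, final$pmf, slice_length = 100, n_last = 5)
  expect_equal(em$n_intervals, 5)
  expect_error(interval_error(mk$windows, final$pmf, slice_length = 100,
                              n_last = 6), "only 5")
  expect_true(all(em$sd[em$mask] >= 0))
  expect_gt(mean(em$sd[em$mask]), 0)
})

test_that("the least-squares offset matches a brute-force 1D scan", {
  h <- analytic_landscape("harmonic", k = 2, center = 0,
                          bounds = list(lower = -2, upper = 2))
  mk <- make_1d_windows(h, c(-0.5, 0, 0.5), duration = 600, discard = 100)
  final <- wham_solve(mk$windows, mk$grid, 323.25)
  em <- interval_error(mk$windows, final$pmf, slice_length = 100, n_last = 5)
  mask <- em$mask
  for (j in seq_len(em$n_intervals)) {
    f_int_raw <- em$aligned[, j] - em$offsets[j]
    sse <- function(c0) sum((f_int_raw[mask] + c0 - final$pmf$f[mask])^2)
    cs <- seq(em$offsets[j] - 1, em$offsets[j] + 1, by = 1e-4)
    brute <- cs[which.min(vapply(cs, sse, numeric(1)))]
    expect_lt(abs(brute - em$offsets[j]), 1e-3)
  }
})

test_that("interval offsets are translation invariant", {
  h <- analytic_landscape("harmonic", k = 2, center = 0,
                          bounds = list(lower = -2, upper = 2))
  mk <- make_1d_windows(h, c(-0.5, 0, 0.5), duration = 600, discard = 100)
  final <- wham_solve(mk$windows, mk$grid, 323.25)
  em <- interval_error(mk$windows, final$pmf, 100, 5)
  # adding a constant to every interval PMF is absorbed by the offsets:
  # the aligned ensemble, and hence the error map, cannot change
  shifted <- em$aligned - em$offsets[col(em$aligned)] + 3.7
  c_new <- vapply(seq_len(ncol(shifted)), function(j)
    mean(final$pmf$f[em$mask] - shifted[em$mask, j]), numeric(1))
  expect_equal(c_new, em$offsets - 3.7, tolerance = 1e-9)
  realigned <- shifted + c_new[col(shifted)]
  expect_equal(realigned, em$aligned, tolerance = 1e-9)
})

test_that("interval error shrinks roughly as one over sqrt(slice length)", {
  h <- analytic_landscape("harmonic", k = 1.2, center = 0,
                          bounds = list(lower = -2, upper = 2))
  mk <- make_1d_windows(h, seq(-1, 1, 0.5), duration = 1050, discard = 50)
  final <- wham_solve(mk$windows, mk$grid, 323.25)
  em_short <- interval_error(mk$windows, final$pmf, 50, 5)
  em_long <- interval_error(mk$windows, final$pmf, 200, 5)
  ratio <- mean(em_short$sd[em_short$mask], na.rm = TRUE) /
    mean(em_long$sd[em_long$mask], na.rm = TRUE)
  expect_gt(ratio, 2 / 2)      # expected ratio 2 within a factor of 2
  expect_lt(ratio, 2 * 2)
})

test_that("states are strict local minima sorted by free energy", {
  h <- analytic_landscape("harmonic", k = 2, center = 0.2,
                          bounds = list(lower = -2, upper = 2))
  p <- boltzmann_pmf(h, analysis_grid(-2, 2, 0.1))
  st <- find_states(p)
  expect_equal(nrow(st), 1L)
  expect_equal(st$f, 0)
  expect_lt(abs(st$z1 - 0.2), 0.1)

  chain <- triple_chain_map()
  pc <- boltzmann_pmf(chain, analysis_grid(c(0, 0), c(6, 4), 0.1))
  st3 <- find_states(pc, max_f = 6)
  expect_equal(nrow(st3), 3L)
  expect_true(all(abs(sort(st3$z1) - c(1.5, 3, 4.5)) <= 0.1))
  expect_true(all(abs(st3$z2 - 2) <= 0.1))
  expect_true(!is.unsorted(st3$f))
  # max_f between two well depths keeps only the deeper state
  asym <- analytic_landscape("permeation_map",
                             bounds = list(lower = c(0, 0), upper = c(6, 4)),
                             wells = rbind(c(1.5, 2), c(4.5, 2)),
                             barriers = 5, depths = c(0, 2),
                             k_transverse = 40, k_wall = 32)
  pa <- boltzmann_pmf(asym, analysis_grid(c(0, 0), c(6, 4), 0.1))
  expect_equal(nrow(find_states(pa, max_f = 6)), 2L)
  st1 <- find_states(pa, max_f = 1)
  expect_equal(nrow(st1), 1L)
  expect_lt(abs(st1$z1 - 1.5), 0.1)
  # merging: minima closer than the radius collapse to the lower one
  stm <- find_states(pc, max_f = 6, merge_radius = 4)
  expect_equal(nrow(stm), 1L)
})

test_that("minimax barriers agree with a threshold-connectivity oracle", {
  # oracle: the barrier between a and b is the smallest threshold t such
  # that a and b are connected through bins with F <= t (computed by
  # exhaustive flood fill over all candidate thresholds)
  oracle_barrier <- function(fm, a, b) {
    vals <- sort(unique(as.vector(fm)))
    for (t in vals) {
      ok <- fm <= t
      reach <- matrix(FALSE, nrow(fm), ncol(fm))
      reach[a[1], a[2]] <- ok[a[1], a[2]]
      repeat {
        grown <- reach
        for (i in which(reach)) {
          r <- (i - 1) %% nrow(fm) + 1
          cc <- (i - 1) %/% nrow(fm) + 1
          for (dr in -1:1) for (dc in -1:1) {
            rr <- r + dr; cc2 <- cc + dc
            if (rr >= 1 && rr <= nrow(fm) && cc2 >= 1 && cc2 <= ncol(fm) &&
                ok[rr, cc2]) grown[rr, cc2] <- TRUE
          }
        }
        if (identical(grown, reach)) break
        reach <- grown
      }
      if (reach[b[1], b[2]]) return(t - fm[a[1], a[2]])
    }
    Inf
  }
  set.seed(33)
  g <- analysis_grid(c(0, 0), c(0.5, 0.5), 0.1)    # 5x5
  for (rep in 1:5) {
    fm <- matrix(round(runif(25, 0, 8), 2), 5, 5)
    fm[1, 1] <- 0
    pmf <- pmf_grid(g, as.vector(fm), 300)
    fm0 <- matrix(pmf$f, 5, 5)                     # re-referenced
    a <- c(1, 1); b <- c(5, 5)
    pr <- minimax_path(pmf, c(g$centers[[1]][a[1]], g$centers[[2]][a[2]]),
                       c(g$centers[[1]][b[1]], g$centers[[2]][b[2]]))
    expect_equal(pr$barrier, oracle_barrier(fm0, a, b))
    # consecutive path bins are 8-connected
    if (nrow(pr$path) > 1)
      expect_true(all(apply(abs(diff(pr$path)), 1, max) <= 0.1 + 1e-9))
  }
})

test_that("minimax path handles identical endpoints and designed barriers", {
  dw <- analytic_landscape("double_well", half_separation = 1.5, barrier = 6,
                           bounds = list(lower = -3, upper = 3))
  pmf <- boltzmann_pmf(dw, analysis_grid(-3, 3, 0.1))
  st <- find_states(pmf, max_f = 3)
  same <- minimax_path(pmf, st[1, ], st[1, ])
  expect_equal(same$barrier, 0)
  expect_equal(nrow(same$path), 0L)
  pr <- minimax_path(pmf, st[1, ], st[2, ])
  expect_lt(abs(pr$barrier - 6), 0.05)             # half-bin discretization
  expect_lt(abs(pr$saddle), 0.1)
})

test_that("minimax barrier is shift invariant and monotone in bin values", {
  set.seed(9)
  g <- analysis_grid(c(0, 0), c(0.8, 0.8), 0.1)
  base <- runif(64, 0, 5)
  pmf1 <- pmf_grid(g, base, 300)
  a <- c(0.05, 0.05); b <- c(0.75, 0.75)
  b1 <- minimax_path(pmf1, a, b)$barrier
  # adding a constant: pmf_grid re-references, barrier unchanged
  pmf2 <- pmf_grid(g, base + 2.5, 300)
  expect_equal(minimax_path(pmf2, a, b)$barrier, b1)
  # raising any one bin never lowers the barrier
  for (i in c(10, 30, 55)) {
    raised <- base
    raised[i] <- raised[i] + 3
    expect_gte(minimax_path(pmf_grid(g, raised, 300), a, b)$barrier,
               b1 - 1e-9)
  }
})

test_that("disconnected defined regions make the path fail loudly", {
  g <- analysis_grid(0, 1, 0.1)
  f <- c(0, 0.5, NA, NA, 1, 1.2, NA, NA, 0.3, 0.8)
  pmf <- pmf_grid(g, f, 300)
  expect_error(minimax_path(pmf, 0.05, 0.95), "not connected")
})

test_that("occupancy classification follows the boundary intervals", {
  b <- c(6, 4.5, 3, 1.5, 0, -1.5, -3)
  occ <- classify_occupancy(c(7, 5, 3.7, 2, 1, -1, -2, -3.5), b)
  expect_equal(as.vector(occ$sites),
               c("extracellular", "S0", "S1", "S2", "S3", "S4", "Cav",
                 "intracellular"))
  expect_equal(occ$bound_count, c(0, 1, 1, 1, 1, 1, 0, 0))
  expect_error(classify_occupancy(1, c(3, 3.5)), "strictly decreasing")
})

test_that("permeation counting uses full-crossing hysteresis", {
  b <- c(6, 4.5, 3, 1.5, 0, -1.5, -3)
  # a single ion ramping monotonically across the filter: one event
  ramp <- seq(-4, 7, by = 0.5)
  expect_equal(classify_occupancy(ramp, b)$events, 1L)
  # oscillation across one internal boundary only: zero events
  osc <- rep(c(1.4, 1.6), 50)
  expect_equal(classify_occupancy(osc, b)$events, 0L)
  # partial excursions never count, full cycles count once each
  updown <- c(-4, 0, 5, 0, -4, 0, 7, 0)
  expect_equal(classify_occupancy(updown, b)$events, 1L)
})

test_that("constructed three-ion knock-on cycles count exactly", {
  for (n in c(1, 3, 7)) {
    cyc <- toy_permeation_cycle(n)
    occ <- classify_occupancy(cyc$ion_z, cyc$boundaries)
    expect_equal(occ$events, n)
    expect_equal(max(occ$bound_count), 3)
    expect_true(all(diff(occ$cumulative_events) >= 0))
  }
})
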