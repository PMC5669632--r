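#' Brownian-dynamics sampler parameters
#'
#' Parameters of the overdamped Langevin (Brownian dynamics) integrator
#' that stands in for the molecular-dynamics engine. Only the stationary
#' Boltzmann distribution matters for free-energy recovery, so an
#' inertialess Euler-Maruyama scheme is used.
#'
#' @param temperature Temperature in K (default 323.25, the simulation
#'   temperature of the channel systems being emulated).
#' @param diffusion Diffusion coefficient (Å^2/ps); the default 0.5 is of
#'   the order of a K+ ion in water.
#' @param timestep Integration timestep (ps).
#' @param sampling_interval Time between recorded samples (ps); must be a
#'   multiple of `timestep`.
#' @return An object of class `brownian_params`.
#' @export
brownian_params <- function(temperature = 323.25, diffusion = 0.5,
                            timestep = 0.002, sampling_interval = 0.01) {
  stopifnot(temperature > 0, diffusion > 0, timestep > 0,
            sampling_interval >= timestep)
  stride <- sampling_interval / timestep
  if (abs(stride - round(stride)) > 1e-9)
    stop("sampling_interval must be an integer multiple of timestep")
  structure(list(temperature = temperature, diffusion = diffusion,
                 timestep = timestep, sampling_interval = sampling_interval,
                 stride = as.integer(round(stride))),
            class = "brownian_params")
}

#' Harmonic umbrella bias
#'
#' @param center Bias center (Å), length = landscape dimension.
#' @param k Force constant per axis (kcal/mol/Å^2), default 20 — the
#'   standard umbrella force constant for 0.5 Å window spacing.
#' @return An object of class `bias_spec`. The bias energy at its own
#'   center is exactly zero.
#' @export
bias_spec <- function(center, k = 20) {
  center <- as.numeric(center)
  k <- rep_len(as.numeric(k), length(center))
  stopifnot(all(k >= 0))
  structure(list(center = center, k = k), class = "bias_spec")
}

.bias_energy <- function(bias, z) {
  z <- as.matrix(z)
  e <- 0
  for (d in seq_along(bias$center))
    e <- e + 0.5 * bias$k[d] * (z[, d] - bias$center[d])^2
  e
}

#' Sample a biased trajectory on an analytic landscape
#'
#' Propagates overdamped Euler-Maruyama dynamics
#' \eqn{z \leftarrow z - (D/kT)\,\nabla(U+w)\,dt + \sqrt{2 D dt}\,\xi}
#' under the umbrella bias `w`, with reflecting boundaries at the domain
#' edges, and records the reaction coordinates every
#' `sampling_interval`. Runs are bit-reproducible for a fixed seed.
#'
#' @param landscape An [analytic_landscape()].
#' @param bias A [bias_spec()] (use `k = 0` for unbiased sampling).
#' @param params A [brownian_params()].
#' @param duration Trajectory length (ps), at least 10 sampling intervals.
#' @param seed Integer RNG seed.
#' @param start Optional starting coordinate (Å); defaults to the bias
#'   center.
#' @return An object of class `rc_trajectory` with fields `times` (ps),
#'   `coords` (matrix, one row per sample), `bias`, `seed`.
#' @export
simulate_rc <- function(landscape, bias, params, duration, seed,
                        start = NULL) {
  stopifnot(inherits(landscape, "analytic_landscape"),
            inherits(bias, "bias_spec"),
            inherits(params, "brownian_params"))
  if (duration < 10 * params$sampling_interval)
    stop("duration must be at least 10 sampling intervals")
  stopifnot(length(bias$center) == landscape$dimension)
  if (is.null(start)) start <- bias$center
  start <- as.numeric(start)
  stopifnot(length(start) == landscape$dimension)
  .check_domain(landscape, matrix(start, nrow = 1))
  .check_stability(landscape, bias, params)
  nsamples <- floor(duration / params$sampling_interval)
  set.seed(seed)
  coords <- bd_simulate_cpp(landscape, bias$center, bias$k,
                            params$diffusion, kT(params$temperature),
                            params$timestep, params$stride,
                            as.integer(nsamples), start,
                            landscape$lower, landscape$upper)
  structure(list(times = seq_len(nsamples) * params$sampling_interval,
                 coords = coords, bias = bias, seed = seed,
                 params = params),
            class = "rc_trajectory")
}

# The explicit Euler drift step must stay well below the domain scale or
# the discretized dynamics diverge near steep walls.
.check_stability <- function(landscape, bias, params, npts = 41) {
  axes <- lapply(seq_len(landscape$dimension), function(d)
    seq(landscape$lower[d], landscape$upper[d], length.out = npts))
  pts <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  g <- landscape_gradient(landscape, pts)
  for (d in seq_len(landscape$dimension))
    g[, d] <- g[, d] + bias$k[d] * (pts[, d] - bias$center[d])
  drift <- params$diffusion / kT(params$temperature) * params$timestep *
    sqrt(rowSums(g^2))
  if (max(drift) > 0.5)
    stop(sprintf(paste0("timestep too large: |drift*dt| reaches %.3g A on ",
                        "the domain; reduce timestep"), max(drift)))
  invisible(TRUE)
}

#' @export
print.rc_trajectory <- function(x, ...) {
  cat(sprintf("Biased trajectory: %d samples over %.4g ps (%dD), bias center %s, k %s, seed %d\n",
              length(x$times), max(x$times), ncol(x$coords),
              paste(signif(x$bias$center, 4), collapse = "/"),
              paste(signif(x$bias$k, 4), collapse = "/"), x$seed))
  invisible(x)
}

#' Write or read a trajectory as whitespace-delimited text
#'
#' Column 1 is time (ps), the remaining columns are the reaction
#' coordinates (Å). Header lines prefixed `#` carry the bias center,
#' force constant and seed so window metadata survives the round trip.
#'
#' @param traj An [rc_trajectory()].
#' @param path File path.
#' @return `read_trajectory()` returns an `rc_trajectory` (without
#'   integrator parameters, which are not stored in the file).
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "rc_trajectory"))
  hdr <- c(sprintf("# bias_center %s", paste(traj$bias$center, collapse = " ")),
           sprintf("# force_constant %s", paste(traj$bias$k, collapse = " ")),
           sprintf("# seed %d", traj$seed))
  tab <- cbind(traj$times, traj$coords)
  writeLines(c(hdr, apply(tab, 1, function(r)
    paste(sprintf("%.10g", r), collapse = " "))), path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key) {
    ln <- grep(paste0("^# ", key, " "), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    as.numeric(strsplit(sub(paste0("^# ", key, " "), "", ln[1]), " +")[[1]])
  }
  body <- lines[!grepl("^#", lines)]
  vals <- t(vapply(strsplit(trimws(body), "[ \t]+"), as.numeric,
                   numeric(length(strsplit(trimws(body[1]), "[ \t]+")[[1]]))))
  ctr <- getv("bias_center")
  kk <- getv("force_constant")
  sd <- getv("seed")
  structure(list(times = vals[, 1],
                 coords = vals[, -1, drop = FALSE],
                 bias = bias_spec(ctr, if (is.null(kk)) 0 else kk),
                 seed = if (is.null(sd)) NA_integer_ else as.integer(sd),
                 params = NULL),
            class = "rc_trajectory")
}

#' Reduced reaction coordinates from three pore-axis ion positions
#'
#' For three ions ordered from the extracellular (first) to the
#' intracellular (third) side, the 2D reaction coordinates are the
#' pore-axis position of the center of mass of the two outermost ions
#' (`z12`) and of the innermost ion (`z3`), both relative to the center
#' of mass of the selectivity filter.
#'
#' @param ion_z Numeric vector of 3 positions (Å), or a matrix with one
#'   row per frame and 3 columns.
#' @param filter_com_z Pore-axis position of the selectivity-filter
#'   center of mass (Å; scalar or one value per frame).
#' @return A matrix (or vector for a single frame) with columns `z12`,
#'   `z3` (Å).
#' @export
reaction_coords <- function(ion_z, filter_com_z) {
  one <- is.null(dim(ion_z))
  m <- if (one) matrix(ion_z, nrow = 1) else as.matrix(ion_z)
  if (ncol(m) != 3)
    stop("exactly three pore-axis ion positions are required per frame")
  out <- cbind(z12 = (m[, 1] + m[, 2]) / 2 - filter_com_z,
               z3 = m[, 3] - filter_com_z)
  if (one) out[1, ] else out
}
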