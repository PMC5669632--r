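#' Analytic free-energy landscapes
#'
#' Differentiable model free-energy surfaces on a 1D or 2D
#' reaction-coordinate domain, used as the ground truth that the biased
#' Brownian sampler explores and that the WHAM machinery must recover.
#' Four families are available:
#'
#' * `flat`: zero everywhere (useful for sampler calibration).
#' * `harmonic`: \eqn{U(z) = \sum_d k_d (z_d - c_d)^2 / 2}.
#' * `double_well` (1D): quartic
#'   \eqn{U(z) = h\,((z-c)^2 - a^2)^2 / a^4} with minima at \eqn{c \pm a}
#'   (depth 0) and a barrier of exactly `barrier` kcal/mol at \eqn{c}.
#' * `permeation_map` (2D): a chain of wells joined by a smooth valley,
#'   mimicking the topology of ion-occupancy free-energy maps of a
#'   potassium-channel selectivity filter. The longitudinal profile
#'   interpolates the well depths with cubic smoothsteps plus a symmetric
#'   C1 bump per segment whose amplitude is solved numerically so that the
#'   minimax barrier between adjacent wells equals the requested height
#'   (relative to the lower of the two wells) to better than 1e-6
#'   kcal/mol. Transverse confinement is harmonic about the valley center
#'   line, and harmonic walls rise beyond the terminal wells.
#'
#' @param family One of `"flat"`, `"harmonic"`, `"double_well"`,
#'   `"permeation_map"`.
#' @param bounds List with numeric vectors `lower` and `upper` (Å), one
#'   entry per axis; the closed simulation domain (reflecting boundaries).
#' @param k Harmonic force constant(s), kcal/mol/Å^2 (recycled per axis).
#' @param center Harmonic or double-well center (Å).
#' @param half_separation Double well: half distance between the two
#'   minima (Å).
#' @param barrier Double well: barrier height (kcal/mol).
#' @param wells Permeation map: n x 2 matrix of well centers (Å), x
#'   strictly increasing.
#' @param barriers Permeation map: n-1 barrier heights between adjacent
#'   wells (kcal/mol, measured from the lower adjacent well).
#' @param depths Permeation map: free energy of each well (kcal/mol,
#'   default all 0).
#' @param k_transverse Permeation map: harmonic stiffness across the
#'   valley (kcal/mol/Å^2).
#' @param k_wall Permeation map: stiffness of the confining walls beyond
#'   the terminal wells (kcal/mol/Å^2).
#'
#' @return An object of class `analytic_landscape`.
#' @examples
#' ls1 <- analytic_landscape("harmonic", k = 2, center = 0,
#'                           bounds = list(lower = -5, upper = 5))
#' potential(ls1, 1)   # k/2 * z^2 = 1 kcal/mol
#' @export
analytic_landscape <- function(family = c("flat", "harmonic", "double_well",
                                          "permeation_map"),
                               bounds,
                               k = NULL, center = NULL,
                               half_separation = NULL, barrier = NULL,
                               wells = NULL, barriers = NULL, depths = NULL,
                               k_transverse = 20, k_wall = 32) {
  family <- match.arg(family)
  stopifnot(is.list(bounds), all(c("lower", "upper") %in% names(bounds)))
  lower <- as.numeric(bounds$lower)
  upper <- as.numeric(bounds$upper)
  stopifnot(length(lower) == length(upper), all(upper > lower),
            length(lower) %in% 1:2)
  dim <- length(lower)

  ls <- list(family = family, dimension = dim, lower = lower, upper = upper,
             family_code = match(family, c("flat", "harmonic", "double_well",
                                           "permeation_map")) - 1L)
  if (family == "harmonic") {
    stopifnot(!is.null(k), !is.null(center))
    ls$k <- rep_len(as.numeric(k), dim)
    ls$center <- rep_len(as.numeric(center), dim)
    stopifnot(all(ls$k >= 0))
  } else if (family == "double_well") {
    stopifnot(dim == 1, !is.null(half_separation), !is.null(barrier),
              half_separation > 0, barrier > 0)
    ls$center <- if (is.null(center)) 0 else as.numeric(center)
    ls$half_separation <- as.numeric(half_separation)
    ls$barrier <- as.numeric(barrier)
  } else if (family == "permeation_map") {
    stopifnot(dim == 2, !is.null(wells), !is.null(barriers))
    wells <- as.matrix(wells)
    n <- nrow(wells)
    stopifnot(ncol(wells) == 2, n >= 1,
              n == 1 || all(diff(wells[, 1]) > 0))
    if (is.null(depths)) depths <- rep(0, n)
    stopifnot(length(depths) == n,
              n == 1 || length(barriers) == n - 1)
    barriers <- as.numeric(barriers)
    if (n > 1) {
      dlo <- pmin(depths[-n], depths[-1])
      dhi <- pmax(depths[-n], depths[-1])
      if (any(barriers <= dhi - dlo))
        stop("each barrier must exceed the depth difference of its wells")
    }
    ls$well_x <- wells[, 1]
    ls$well_y <- wells[, 2]
    ls$depths <- as.numeric(depths)
    ls$k_transverse <- as.numeric(k_transverse)
    ls$k_wall <- as.numeric(k_wall)
    ls$barriers <- barriers
    ls$amplitudes <- if (n > 1) {
      vapply(seq_len(n - 1), function(i) {
        .solve_segment_amplitude(depths[i], depths[i + 1], barriers[i])
      }, numeric(1))
    } else numeric(0)
  }
  class(ls) <- "analytic_landscape"
  ls
}

# Solve the bump amplitude A so that
#   max_u [ d1 + (d2-d1) s(u) + A phi(u) ] - min(d1,d2) = b.
# The maximum is monotone increasing in A, so bisection via uniroot.
.solve_segment_amplitude <- function(d1, d2, b) {
  target <- min(d1, d2) + b
  seg_max <- function(A) {
    f <- function(u) d1 + (d2 - d1) * .sstep(u) + A * .bump(u)
    optimize(f, c(1e-9, 1 - 1e-9), maximum = TRUE, tol = 1e-12)$objective
  }
  if (abs(d1 - d2) < 1e-12) return(b)  # exact: max = d + A at u = 1/2
  uniroot(function(A) seg_max(A) - target, lower = 0, upper = 2 * b + abs(d2 - d1),
          tol = 1e-11)$root
}

.sstep <- function(t) t^2 * (3 - 2 * t)
.bump <- function(u) ifelse(u <= 0.5, .sstep(2 * u), .sstep(2 - 2 * u))

.as_coord_matrix <- function(ls, z) {
  if (is.null(dim(z))) {
    if (ls$dimension == 1) z <- matrix(as.numeric(z), ncol = 1)
    else {
      stopifnot(length(z) == ls$dimension)
      z <- matrix(as.numeric(z), ncol = ls$dimension)
    }
  }
  z <- as.matrix(z)
  stopifnot(ncol(z) == ls$dimension)
  z
}

.check_domain <- function(ls, z) {
  for (d in seq_len(ls$dimension)) {
    bad <- z[, d] < ls$lower[d] - 1e-12 | z[, d] > ls$upper[d] + 1e-12
    if (any(bad))
      stop(sprintf("coordinate outside domain on axis %d: %.6g", d,
                   z[which(bad)[1], d]))
  }
  invisible(TRUE)
}

#' Evaluate a landscape potential
#'
#' @param landscape An [analytic_landscape()].
#' @param z Coordinate vector (one point) or matrix with one row per point
#'   and one column per axis (Å).
#' @return Energy in kcal/mol, one value per point.
#' @export
potential <- function(landscape, z) {
  stopifnot(inherits(landscape, "analytic_landscape"))
  z <- .as_coord_matrix(landscape, z)
  .check_domain(landscape, z)
  ls_potential_cpp(landscape, z)
}

#' Analytic gradient of a landscape potential
#'
#' @inheritParams potential
#' @return Matrix of gradients (kcal/mol/Å), one row per point.
#' @export
landscape_gradient <- function(landscape, z) {
  stopifnot(inherits(landscape, "analytic_landscape"))
  z <- .as_coord_matrix(landscape, z)
  .check_domain(landscape, z)
  ls_gradient_cpp(landscape, z)
}

#' @export
print.analytic_landscape <- function(x, ...) {
  cat(sprintf("Analytic landscape: %s (%dD)\n", x$family, x$dimension))
  cat(sprintf("  domain: %s\n",
              paste(sprintf("[%.3g, %.3g]", x$lower, x$upper),
                    collapse = " x ")))
  if (x$family == "harmonic")
    cat(sprintf("  k = %s kcal/mol/A^2, center = %s A\n",
                paste(signif(x$k, 4), collapse = ", "),
                paste(signif(x$center, 4), collapse = ", ")))
  if (x$family == "double_well")
    cat(sprintf("  wells at %.3g +/- %.3g A, barrier %.3g kcal/mol\n",
                x$center, x$half_separation, x$barrier))
  if (x$family == "permeation_map")
    cat(sprintf("  %d wells, barriers %s kcal/mol, k_t = %.3g, k_wall = %.3g\n",
                length(x$well_x), paste(signif(x$barriers, 4), collapse = "/"),
                x$k_transverse, x$k_wall))
  invisible(x)
}

#' Toy selectivity-filter permeation maps
#'
#' Ready-made 2D landscapes with three wells along a diagonal valley,
#' mirroring the topology of the ion-occupancy maps of a K+ channel
#' selectivity filter (e.g. S1-S3-Cav -> S0-S2-S4 -> release). The
#' `"open"` preset uses low inter-well barriers of 2.5 kcal/mol, the kind
#' conducive to ion diffusion; the `"closed"` preset uses 8 kcal/mol
#' barriers (> 6 kcal/mol), the kind that traps ions in deep wells.
#'
#' @param mode `"open"` or `"closed"`.
#' @param barrier Optional barrier override (kcal/mol, one value recycled).
#' @return An [analytic_landscape()] of family `permeation_map`.
#' @export
toy_permeation_map <- function(mode = c("open", "closed"), barrier = NULL) {
  mode <- match.arg(mode)
  if (is.null(barrier)) barrier <- if (mode == "open") 2.5 else 8
  wells <- rbind(c(1.5, 1.5), c(3.0, 3.0), c(4.5, 4.5))
  analytic_landscape("permeation_map",
                     bounds = list(lower = c(0, 0), upper = c(6, 6)),
                     wells = wells, barriers = rep_len(barrier, 2),
                     k_transverse = 20, k_wall = 32)
}

#' Read or write a landscape definition file
#'
#' Landscapes are stored as YAML with keys `family`, `params` and
#' `bounds`, so runs can be reproduced from a plain-text config.
#'
#' @param landscape An [analytic_landscape()].
#' @param path File path.
#' @return `read_landscape()` returns an [analytic_landscape()];
#'   `write_landscape()` returns `path` invisibly.
#' @export
write_landscape <- function(landscape, path) {
  stopifnot(inherits(landscape, "analytic_landscape"))
  params <- switch(landscape$family,
    flat = list(),
    harmonic = list(k = landscape$k, center = landscape$center),
    double_well = list(center = landscape$center,
                       half_separation = landscape$half_separation,
                       barrier = landscape$barrier),
    permeation_map = list(
      wells = lapply(seq_along(landscape$well_x),
                     function(i) c(landscape$well_x[i], landscape$well_y[i])),
      barriers = landscape$barriers, depths = landscape$depths,
      k_transverse = landscape$k_transverse, k_wall = landscape$k_wall))
  yaml::write_yaml(list(family = landscape$family, params = params,
                        bounds = list(lower = landscape$lower,
                                      upper = landscape$upper)), path)
  invisible(path)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopifnot(!is.null(cfg$family), !is.null(cfg$bounds))
  p <- cfg$params
  if (cfg$family == "permeation_map")
    p$wells <- do.call(rbind, p$wells)
  do.call(analytic_landscape,
          c(list(family = cfg$family,
                 bounds = list(lower = unlist(cfg$bounds$lower),
                               upper = unlist(cfg$bounds$upper))), p))
}
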