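#' Hill model of proton-dependent open probability
#'
#' Empirical dose-response description of channel activation by
#' protons,
#' \deqn{P_o(\mathrm{pH}) = \frac{P_{o,max}}{1 + 10^{(\mathrm{pH} -
#'   \mathrm{pH}_{1/2})\, n_H}},}
#' equivalently \eqn{P_{o,max} / (1 + (EC_{50}/[H^+])^{n_H})} with
#' \eqn{EC_{50} = 10^{-\mathrm{pH}_{1/2}}}. Open probability is maximal
#' at low pH (high proton concentration) and satisfies
#' \eqn{P_o(\mathrm{pH}_{1/2}) = P_{o,max}/2} exactly.
#'
#' @param pomax Maximal open probability, in (0, 1].
#' @param ph_half pH of half-activation.
#' @param nh Hill coefficient (> 0; apparent cooperativity).
#' @return An object of class `hill_params`.
#' @export
hill_params <- function(pomax = 1, ph_half = 5.3, nh = 4) {
  stopifnot(pomax > 0, pomax <= 1, nh > 0)
  structure(list(pomax = pomax, ph_half = ph_half, nh = nh),
            class = "hill_params")
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf("Hill gating: Pomax = %.4g, pH1/2 = %.4g, nH = %.4g\n",
              x$pomax, x$ph_half, x$nh))
  invisible(x)
}

#' Evaluate the Hill open-probability curve
#'
#' @param params A [hill_params()].
#' @param pH pH value(s).
#' @return Open probability, same length as `pH`.
#' @export
hill_po <- function(params, pH) {
  stopifnot(inherits(params, "hill_params"))
  .hill_po(pH, params$pomax, params$ph_half, params$nh)
}

.hill_po <- function(pH, pomax, ph_half, nh) {
  # pomax * 1/(1 + 10^((pH - ph_half) nh)), overflow-safe via plogis
  pomax * plogis(-(pH - ph_half) * nh * log(10))
}

#' Two-sensor MWC model of pH gating
#'
#' Concerted allosteric (Monod-Wyman-Changeux) model of a homotetrameric
#' channel with two proton sensors per subunit (in KcsA: H25 and E118).
#' The channel is open with probability
#' \deqn{P_o = \frac{L_o A_o B_o}{L_o A_o B_o + A_c B_c}, \qquad
#'   A_x = (1 + 10^{pK_{a1,x} - \mathrm{pH}})^4,\;
#'   B_x = (1 + 10^{pK_{a2,x} - \mathrm{pH}})^4,}
#' where \eqn{L_o} is the intrinsic open/closed equilibrium of the fully
#' deprotonated channel and the pKa values are the sensors' acid
#' dissociation constants in the open and closed conformations. A sensor
#' can be marked absent (as for the "-" entries of a mutant lacking it),
#' in which case its factor is identically 1. The subunit exponent is
#' fixed at 4 (homotetramer).
#'
#' @param lo Intrinsic gating equilibrium Lo (> 0).
#' @param pka1_closed,pka1_open Sensor-1 pKa in the closed/open state
#'   (`NA` for an absent sensor 1).
#' @param pka2_closed,pka2_open Sensor-2 pKa (`NA` for an absent
#'   sensor 2).
#' @return An object of class `mwc_params`.
#' @export
mwc_params <- function(lo, pka1_closed = NA, pka1_open = NA,
                       pka2_closed = NA, pka2_open = NA) {
  stopifnot(lo > 0)
  s1 <- !is.na(pka1_closed) || !is.na(pka1_open)
  s2 <- !is.na(pka2_closed) || !is.na(pka2_open)
  if (s1) stopifnot(!is.na(pka1_closed), !is.na(pka1_open))
  if (s2) stopifnot(!is.na(pka2_closed), !is.na(pka2_open))
  structure(list(lo = lo,
                 pka1_closed = pka1_closed, pka1_open = pka1_open,
                 pka2_closed = pka2_closed, pka2_open = pka2_open,
                 sensor1 = s1, sensor2 = s2),
            class = "mwc_params")
}

#' @export
print.mwc_params <- function(x, ...) {
  fmt <- function(on, c, o) if (on) sprintf("pKa %.4g (closed) / %.4g (open)",
                                            c, o) else "absent"
  cat(sprintf("MWC gating (tetramer, two proton sensors):\n  Lo = %.4g\n  sensor 1: %s\n  sensor 2: %s\n",
              x$lo, fmt(x$sensor1, x$pka1_closed, x$pka1_open),
              fmt(x$sensor2, x$pka2_closed, x$pka2_open)))
  invisible(x)
}

# log(1 + 10^t) in natural log, safe for any t
.log1p10 <- function(t) ifelse(t > 30, t * log(10), log1p(10^t))

#' Evaluate the MWC open-probability curve
#'
#' Computed in the log domain, so extreme Lo values (down to 1e-15 and
#' beyond) and pH far from the pKa values neither overflow nor lose the
#' tail.
#'
#' @param params An [mwc_params()].
#' @param pH pH value(s).
#' @return Open probability, same length as `pH`.
#' @export
mwc_po <- function(params, pH) {
  stopifnot(inherits(params, "mwc_params"))
  .mwc_po(pH, params$lo,
          if (params$sensor1) params$pka1_closed else NA,
          if (params$sensor1) params$pka1_open else NA,
          if (params$sensor2) params$pka2_closed else NA,
          if (params$sensor2) params$pka2_open else NA)
}

.mwc_po <- function(pH, lo, p1c, p1o, p2c, p2o) {
  lopen <- log(lo)
  if (!is.na(p1o)) lopen <- lopen + 4 * .log1p10(p1o - pH)
  if (!is.na(p2o)) lopen <- lopen + 4 * .log1p10(p2o - pH)
  lclosed <- 0
  if (!is.na(p1c)) lclosed <- lclosed + 4 * .log1p10(p1c - pH)
  if (!is.na(p2c)) lclosed <- lclosed + 4 * .log1p10(p2c - pH)
  plogis(lopen - lclosed)
}

#' Published KcsA gating-model parameters
#'
#' The summary table of Hill and two-sensor MWC fits for the
#' inactivation-removed (E71A background) KcsA constructs: the control
#' channel, the outer-helix mutant L40A (fit with the sensor-1 pKa made
#' state-independent), and the pH-sensor mutants H25R (sensor 1 absent)
#' and E118A (sensor 2 absent). These parameter sets are the inputs for
#' regenerating the model dose-response curves.
#'
#' @param mutant One of `"control"`, `"L40A"`, `"H25R"`, `"E118A"`, or
#'   `NULL` to get the whole table.
#' @return For a single mutant, an [mwc_params()]; otherwise a data
#'   frame of all rows (including the published Hill-fit summaries
#'   `ph_half` and `nh`).
#' @export
kcsa_gating_params <- function(mutant = NULL) {
  tab <- data.frame(
    mutant = c("control", "L40A", "H25R", "E118A"),
    ph_half = c(5.3, 5.2, 5.3, 5.5),
    nh = c(4.4, 1.9, 1.9, 4.5),
    pka1_closed = c(4.8, 7.6, NA, 4.8),
    pka1_open = c(7.6, 7.6, NA, 7.6),
    pka2_closed = c(5.0, 5.0, 5.0, NA),
    pka2_open = c(6.2, 6.2, 6.2, NA),
    lo = c(2.5e-12, 6.2e-4, 7e-4, 1.1e-8),
    stringsAsFactors = FALSE)
  if (is.null(mutant)) return(tab)
  r <- tab[tab$mutant == match.arg(mutant, tab$mutant), ]
  mwc_params(lo = r$lo,
             pka1_closed = r$pka1_closed, pka1_open = r$pka1_open,
             pka2_closed = r$pka2_closed, pka2_open = r$pka2_open)
}

#' Synthetic open-probability datasets around an MWC curve
#'
#' Emulates a bilayer dose-response experiment: at each pH, `replicates`
#' independent bilayer measurements are drawn as the MWC curve value
#' plus normal noise clipped to [0, 1], and the per-pH mean, standard
#' error of the mean, and replicate count are tabulated.
#'
#' @param params An [mwc_params()] (the ground-truth gating model).
#' @param pH pH values (each in `[0, 14]`).
#' @param replicates Bilayers per pH (default 5).
#' @param noise_sd Replicate noise standard deviation on Po (default
#'   0.05, the bilayer-to-bilayer scatter scale).
#' @param seed Integer RNG seed.
#' @return An object of class `po_dataset`: a data frame `data` with
#'   columns `pH`, `po` (mean), `sem`, `n`, plus the raw `replicates`
#'   matrix and the generating parameters.
#' @export
generate_po_dataset <- function(params, pH, replicates = 5,
                                noise_sd = 0.05, seed = 1L) {
  stopifnot(inherits(params, "mwc_params"), all(pH >= 0 & pH <= 14),
            replicates >= 1, noise_sd >= 0)
  set.seed(seed)
  truth <- mwc_po(params, pH)
  reps <- vapply(seq_along(pH), function(i)
    pmin(1, pmax(0, truth[i] + rnorm(replicates, 0, noise_sd))),
    numeric(replicates))
  reps <- matrix(reps, nrow = replicates)
  po <- colMeans(reps)
  sem <- apply(reps, 2, sd) / sqrt(replicates)
  structure(list(data = data.frame(pH = pH, po = po, sem = sem,
                                   n = replicates),
                 replicates = reps, truth = truth, params = params,
                 noise_sd = noise_sd, seed = seed),
            class = "po_dataset")
}

#' @export
print.po_dataset <- function(x, ...) {
  cat(sprintf("Po(pH) dataset: %d pH points, %d replicates each, noise sd %.3g\n",
              nrow(x$data), x$data$n[1], x$noise_sd))
  print(x$data, row.names = FALSE)
  invisible(x)
}

.as_po_df <- function(data) {
  if (inherits(data, "po_dataset")) data <- data$data
  data <- as.data.frame(data)
  stopifnot(all(c("pH", "po") %in% names(data)),
            all(data$po >= 0 & data$po <= 1), !anyDuplicated(data$pH))
  data
}

#' Write or read a Po(pH) dataset as CSV
#'
#' Columns `pH`, `po`, `sem`, `n`.
#'
#' @param data A [generate_po_dataset()] result or a compatible data
#'   frame.
#' @param path File path.
#' @return `read_po_csv()` returns a data frame.
#' @export
write_po_csv <- function(data, path) {
  write.csv(.as_po_df(data), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_po_csv
#' @export
read_po_csv <- function(path) .as_po_df(read.csv(path))
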