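# Nonlinear least-squares machinery shared by the Hill and MWC fits.
# Levenberg-Marquardt with box bounds via minpack.lm; asymptotic standard
# errors from a finite-difference Jacobian at the optimum, reported only
# for free parameters (constrained/fixed parameters get none, as in the
# original analysis).

.num_jacobian <- function(fn, par, eps = 1e-6) {
  r0 <- fn(par)
  J <- matrix(0, length(r0), length(par))
  for (j in seq_along(par)) {
    h <- eps * max(1, abs(par[j]))
    pp <- par; pp[j] <- pp[j] + h
    J[, j] <- (fn(pp) - r0) / h
  }
  J
}

.lm_fit <- function(resid_fn, par, lower, upper) {
  fit <- minpack.lm::nls.lm(par = par, fn = resid_fn,
                            lower = lower, upper = upper,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-12, ptol = 1e-12))
  est <- fit$par
  rr <- resid_fn(est)
  ssr <- sum(rr^2)
  n <- length(rr); p <- length(est)
  se <- rep(NA_real_, p)
  note <- NULL
  if (n > p) {
    J <- .num_jacobian(resid_fn, est)
    JtJ <- crossprod(J)
    cv <- try(solve(JtJ) * ssr / (n - p), silent = TRUE)
    if (inherits(cv, "try-error") || any(!is.finite(diag(as.matrix(cv))))) {
      note <- "rank-deficient fit: standard errors unavailable"
    } else se <- sqrt(pmax(0, diag(cv)))
  }
  at_bound <- (is.finite(lower) & abs(est - lower) < 1e-6) |
    (is.finite(upper) & abs(est - upper) < 1e-6)
  # info 1-3: x/f convergence; 4: gradient orthogonal to machine precision
  list(par = est, se = se, ssr = ssr,
       converged = fit$info %in% 1:4, info = fit$info,
       at_bound = at_bound, note = note)
}

.new_gating_fit <- function(model, params, se, fixed, active_bounds, ssr,
                            converged, data, note = NULL) {
  structure(list(model = model, params = params, se = se, fixed = fixed,
                 active_bounds = active_bounds, ssr = ssr,
                 converged = converged, data = data, note = note),
            class = "gating_fit")
}

#' Fit the Hill equation to an open-probability dataset
#'
#' Unweighted nonlinear least squares of the Hill dose-response curve to
#' the per-pH Po means (standard errors are carried in the data but not
#' used as weights unless requested), with Pomax, pH1/2 and nH free by
#' default. Any subset can be fixed at its initial value.
#'
#' @param data A [generate_po_dataset()] result, or a data frame with
#'   columns `pH` and `po` (optionally `sem`, `n`).
#' @param init A [hill_params()] starting point; `NULL` derives one from
#'   the data (Pomax from the plateau, pH1/2 by interpolation, nH from
#'   the logit slope).
#' @param fixed Character vector naming parameters to hold at their
#'   initial values (subset of `"pomax"`, `"ph_half"`, `"nh"`).
#' @param weighted If `TRUE`, residuals are divided by the reported sem.
#' @return An object of class `gating_fit`; see [coef.gating_fit()],
#'   [predict.gating_fit()], [summary.gating_fit()]. Non-convergence is
#'   flagged, never thrown; degenerate (flat) data yields a
#'   rank-deficiency note.
#' @export
fit_hill <- function(data, init = NULL, fixed = character(),
                     weighted = FALSE) {
  df <- .as_po_df(data)
  stopifnot(all(fixed %in% c("pomax", "ph_half", "nh")))
  if (is.null(init)) init <- .hill_init(df)
  full <- c(pomax = init$pomax, ph_half = init$ph_half, nh = init$nh)
  free <- setdiff(names(full), fixed)
  if (length(free) > nrow(df))
    stop("more free parameters than informative pH points")
  w <- if (weighted) {
    stopifnot("sem" %in% names(df), all(df$sem > 0))
    1 / df$sem
  } else rep(1, nrow(df))
  lower <- c(pomax = 1e-8, ph_half = -10, nh = 1e-8)[free]
  upper <- c(pomax = 1, ph_half = 24, nh = 100)[free]
  resid_fn <- function(p) {
    full[free] <- p
    w * (.hill_po(df$pH, full["pomax"], full["ph_half"], full["nh"]) -
           df$po)
  }
  res <- .lm_fit(resid_fn, full[free], lower, upper)
  full[free] <- res$par
  se <- setNames(rep(NA_real_, 3), names(full))
  se[free] <- res$se
  note <- res$note
  if (length(unique(df$po)) == 1)
    note <- c(note, "degenerate data: all Po values identical")
  .new_gating_fit("hill", as.list(full), as.list(se), fixed,
                  free[res$at_bound], res$ssr, res$converged, df, note)
}

.hill_init <- function(df) {
  pomax <- min(1, max(df$po))
  po <- df$po[order(df$pH)]
  pH <- sort(df$pH)
  half <- pomax / 2
  i <- which(diff(sign(po - half)) != 0)
  ph50 <- if (length(i)) {
    i <- i[1]
    pH[i] + (half - po[i]) * (pH[i + 1] - pH[i]) / (po[i + 1] - po[i])
  } else median(pH)
  frac <- pmin(1 - 1e-6, pmax(1e-6, po / max(pomax, 1e-6)))
  lg <- log(frac / (1 - frac))
  use <- frac > 0.05 & frac < 0.95
  nh <- if (sum(use) >= 2)
    max(0.3, -coef(lm(lg[use] ~ pH[use]))[2] / log(10)) else 2
  hill_params(pomax = max(1e-3, pomax), ph_half = ph50, nh = nh)
}

#' Fit the two-sensor MWC gating model
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) of the MWC
#' open-probability curve to per-pH Po means. Lo is fitted on a log10
#' scale (its standard error is mapped back by the delta method). The
#' physical ordering pKa_closed <= pKa_open is enforced as a box bound
#' on each free pKa_closed whenever the matching pKa_open is fixed, so
#' the constrained workflow used for mutants whose sensor loses
#' state-dependence works out of the box: a first stage with Lo and
#' pKa1_closed free detects the bound becoming active, and a second
#' stage pins pKa1_closed to pKa1_open and refits Lo alone (see
#' [fit_mwc_two_stage()]).
#'
#' @param data As in [fit_hill()].
#' @param init An [mwc_params()] starting point; absent sensors stay
#'   absent.
#' @param fixed Character vector naming parameters to hold at their
#'   initial values (subset of `"lo"`, `"pka1_closed"`, `"pka1_open"`,
#'   `"pka2_closed"`, `"pka2_open"`). Default: every pKa fixed, `lo`
#'   free.
#' @param bounds Optional named list overriding the default box bounds
#'   (each entry `c(lower, upper)`; use name `"lo"` on the natural
#'   scale).
#' @param weighted If `TRUE`, residuals are divided by the reported sem.
#' @return A `gating_fit` (model `"mwc"`) whose `active_bounds` reports
#'   parameters that ended on a constraint; such parameters carry no
#'   standard error.
#' @export
fit_mwc <- function(data, init, fixed = NULL, bounds = NULL,
                    weighted = FALSE) {
  df <- .as_po_df(data)
  stopifnot(inherits(init, "mwc_params"))
  pnames <- c("lo",
              if (init$sensor1) c("pka1_closed", "pka1_open"),
              if (init$sensor2) c("pka2_closed", "pka2_open"))
  if (is.null(fixed)) fixed <- setdiff(pnames, "lo")
  stopifnot(all(fixed %in% pnames))
  free <- setdiff(pnames, fixed)
  if (length(free) > nrow(df))
    stop("more free parameters than informative pH points")
  vals <- c(lo = init$lo, pka1_closed = init$pka1_closed,
            pka1_open = init$pka1_open, pka2_closed = init$pka2_closed,
            pka2_open = init$pka2_open)
  # internal scale: log10(lo)
  par0 <- vals[free]
  if ("lo" %in% free) par0["lo"] <- log10(vals["lo"])
  lower <- setNames(rep(0, length(free)), free)
  upper <- setNames(rep(14, length(free)), free)
  if ("lo" %in% free) { lower["lo"] <- -20; upper["lo"] <- 6 }
  for (s in 1:2) {
    pc <- sprintf("pka%d_closed", s); po <- sprintf("pka%d_open", s)
    if (pc %in% free && po %in% fixed && pc %in% pnames)
      upper[pc] <- vals[po]
  }
  if (!is.null(bounds))
    for (nm in names(bounds)) {
      if (!nm %in% free) next
      b <- bounds[[nm]]
      if (nm == "lo") b <- log10(b)
      lower[nm] <- b[1]; upper[nm] <- b[2]
    }
  w <- if (weighted) 1 / df$sem else rep(1, nrow(df))
  resid_fn <- function(p) {
    v <- vals
    v[free] <- p
    if ("lo" %in% free) v["lo"] <- 10^p["lo"]
    w * (.mwc_po(df$pH, v["lo"],
                 if (init$sensor1) v["pka1_closed"] else NA,
                 if (init$sensor1) v["pka1_open"] else NA,
                 if (init$sensor2) v["pka2_closed"] else NA,
                 if (init$sensor2) v["pka2_open"] else NA) - df$po)
  }
  res <- .lm_fit(resid_fn, par0, lower, upper)
  est <- vals
  est[free] <- res$par
  se <- setNames(rep(NA_real_, length(vals)), names(vals))
  se[free] <- res$se
  if ("lo" %in% free) {
    est["lo"] <- 10^res$par["lo"]
    se["lo"] <- est["lo"] * log(10) * se["lo"]   # delta method
  }
  active <- free[res$at_bound]
  se[active] <- NA_real_   # no error when a constraint is active
  params <- mwc_params(lo = unname(est["lo"]),
                       pka1_closed = unname(est["pka1_closed"]),
                       pka1_open = unname(est["pka1_open"]),
                       pka2_closed = unname(est["pka2_closed"]),
                       pka2_open = unname(est["pka2_open"]))
  .new_gating_fit("mwc", params, as.list(se), fixed, active, res$ssr,
                  res$converged, df, res$note)
}

#' Two-stage constrained MWC fit
#'
#' Reproduces the constrained workflow used when a mutation appears to
#' abolish a sensor's state-dependence: stage 1 frees Lo and
#' pKa1_closed (bounded above by the fixed pKa1_open); if pKa1_closed
#' climbs to that bound, stage 2 pins it there and refits with Lo as
#' the single free parameter.
#'
#' @inheritParams fit_mwc
#' @return A `gating_fit` with an extra `stages` field recording both
#'   stage results.
#' @export
fit_mwc_two_stage <- function(data, init, weighted = FALSE) {
  stopifnot(init$sensor1)
  s1 <- fit_mwc(data, init, fixed = setdiff(
    c("pka1_closed", "pka1_open",
      if (init$sensor2) c("pka2_closed", "pka2_open")), "pka1_closed"),
    weighted = weighted)
  if (!"pka1_closed" %in% s1$active_bounds) {
    s1$stages <- list(stage1 = s1)
    return(s1)
  }
  init2 <- init
  init2$pka1_closed <- init$pka1_open
  init2$lo <- s1$params$lo
  s2 <- fit_mwc(data, init2, fixed = setdiff(
    c("pka1_closed", "pka1_open",
      if (init$sensor2) c("pka2_closed", "pka2_open")), character(0)),
    weighted = weighted)
  s2$stages <- list(stage1 = s1, stage2 = s2)
  s2
}

#' Hill summary of an MWC curve
#'
#' Evaluates the MWC open-probability model on a pH grid and fits the
#' Hill equation (Pomax free) to the noiseless curve — the standard way
#' to express a mechanistic gating model as an apparent pH1/2 and Hill
#' coefficient for comparison across constructs. The default grid,
#' pH 4.0-6.5 in steps of 0.05, spans the experimental range plus the
#' upper shoulder. Several deterministic starting points are tried and
#' the lowest-SSR fit returned.
#'
#' @param params An [mwc_params()].
#' @param pH_grid Evaluation grid; the Po curve must cross 0.5 inside
#'   it.
#' @return A `gating_fit` (model `"hill"`).
#' @export
hill_summary_of_mwc <- function(params, pH_grid = seq(4, 6.5, by = 0.05)) {
  stopifnot(inherits(params, "mwc_params"))
  po <- mwc_po(params, pH_grid)
  if (!(any(po > 0.5) && any(po < 0.5)))
    stop("the MWC curve does not cross Po = 0.5 inside the pH grid")
  df <- data.frame(pH = pH_grid, po = po)
  init0 <- .hill_init(df)
  best <- NULL
  for (nh0 in unique(c(init0$nh, 1, 2, 4, 6))) {
    ini <- init0; ini$nh <- nh0
    f <- tryCatch(fit_hill(df, init = ini), error = function(e) NULL)
    if (is.null(f)) next
    if (is.null(best) || f$ssr < best$ssr) best <- f
  }
  if (is.null(best)) stop("Hill summary fit failed")
  best
}

#' @export
print.gating_fit <- function(x, ...) {
  cat(sprintf("%s fit: SSR = %.4g over %d pH points%s\n",
              if (x$model == "hill") "Hill" else "MWC",
              x$ssr, nrow(x$data),
              if (x$converged) "" else " (NOT converged)"))
  print(summary(x)$coefficients)
  if (length(x$active_bounds))
    cat("active bound constraints:", paste(x$active_bounds, collapse = ", "),
        "\n")
  if (!is.null(x$note)) cat("note:", paste(x$note, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.gating_fit <- function(object, ...) {
  p <- object$params
  if (object$model == "hill") unlist(p)
  else c(lo = p$lo, pka1_closed = p$pka1_closed, pka1_open = p$pka1_open,
         pka2_closed = p$pka2_closed, pka2_open = p$pka2_open)
}

#' Summarize a gating fit
#'
#' @param object A `gating_fit`.
#' @param ... Unused.
#' @return A list with a coefficient table (estimate, standard error,
#'   and a flag column: `fixed`, `bound`, or `free`), the SSR and the
#'   convergence flag. Standard errors appear only for free,
#'   unconstrained parameters.
#' @export
summary.gating_fit <- function(object, ...) {
  est <- coef(object)
  est <- est[!is.na(est)]
  se <- unlist(object$se)[names(est)]
  status <- ifelse(names(est) %in% object$fixed, "fixed",
                   ifelse(names(est) %in% object$active_bounds, "bound",
                          "free"))
  out <- list(coefficients = data.frame(estimate = est, se = se,
                                        status = status),
              ssr = object$ssr, converged = object$converged,
              model = object$model)
  class(out) <- "summary.gating_fit"
  out
}

#' @export
print.summary.gating_fit <- function(x, ...) {
  print(x$coefficients)
  cat(sprintf("SSR %.4g, %s\n", x$ssr,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Predicted open probability from a gating fit
#'
#' @param object A `gating_fit`.
#' @param pH pH values (defaults to the fitted data's).
#' @param ... Unused.
#' @export
predict.gating_fit <- function(object, pH = NULL, ...) {
  if (is.null(pH)) pH <- object$data$pH
  p <- object$params
  if (object$model == "hill")
    .hill_po(pH, p$pomax, p$ph_half, p$nh)
  else mwc_po(p, pH)
}

#' @export
residuals.gating_fit <- function(object, ...) {
  object$data$po - predict(object)
}

#' @export
plot.gating_fit <- function(x, ...) {
  df <- x$data
  plot(df$pH, df$po, xlab = "pH", ylab = "Po", ylim = c(0, 1), ...)
  ph <- seq(min(df$pH), max(df$pH), length.out = 200)
  lines(ph, predict(x, ph), col = "steelblue")
  invisible(x)
}

#' Export a gating fit as JSON
#'
#' Parameters, standard errors (only for free parameters), the fixed
#' list, active bounds and SSR, in a layout mirroring the published
#' summary tables.
#'
#' @param fit A `gating_fit`.
#' @param path File path.
#' @export
write_gating_fit <- function(fit, path) {
  stopifnot(inherits(fit, "gating_fit"))
  p <- fit$params
  if (fit$model == "mwc")
    p <- list(lo = p$lo, pka1_closed = p$pka1_closed,
              pka1_open = p$pka1_open, pka2_closed = p$pka2_closed,
              pka2_open = p$pka2_open)
  jsonlite::write_json(list(model = fit$model, params = p,
                            se = fit$se, fixed = fit$fixed,
                            active_bounds = fit$active_bounds,
                            ssr = fit$ssr, converged = fit$converged),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
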