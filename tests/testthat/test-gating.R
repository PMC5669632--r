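test_that("the Hill curve hits its defining points and limits", {
  p <- hill_params(pomax = 1, ph_half = 5.3, nh = 4.4)
  expect_equal(hill_po(p, 5.3), 0.5)
  p2 <- hill_params(pomax = 0.8, ph_half = 5.0, nh = 2)
  expect_equal(hill_po(p2, 5.0), 0.4)                 # Pomax/2 exactly
  expect_equal(hill_po(p2, -50), 0.8, tolerance = 1e-12)
  expect_equal(hill_po(p2, 50), 0)
  ph <- seq(0, 14, 0.1)
  expect_true(all(diff(hill_po(p, ph)) <= 0))          # non-increasing
})

test_that("the MWC curve matches its closed-form limits and oracle value", {
  ctrl <- kcsa_gating_params("control")
  # high pH: Po -> Lo/(1+Lo); low pH the factors saturate at
  # 10^(4*sum(pKa_open - pKa_closed)), so Po -> 1/(1 + 10^(-4*sum)/Lo)
  expect_equal(mwc_po(ctrl, 14), ctrl$lo / (1 + ctrl$lo), tolerance = 1e-6)
  sat <- 1 / (1 + 10^(-4 * ((7.6 - 4.8) + (6.2 - 5.0))) / ctrl$lo)
  expect_equal(mwc_po(ctrl, -5), sat, tolerance = 1e-9)
  expect_gt(sat, 0.9999)
  # state-independent pKa values cancel: flat curve at Lo/(1+Lo)
  flat <- mwc_params(lo = 0.3, pka1_closed = 5, pka1_open = 5,
                     pka2_closed = 6, pka2_open = 6)
  expect_equal(mwc_po(flat, c(2, 5, 8, 12)), rep(0.3 / 1.3, 4),
               tolerance = 1e-12)
  # control parameters at pH 5.3 (independent high-precision evaluation)
  expect_equal(mwc_po(ctrl, 5.3), 0.6291, tolerance = 1e-4)
})

test_that("MWC sensors are exchangeable and the log-domain form is exact", {
  a <- mwc_params(lo = 1e-9, pka1_closed = 4.8, pka1_open = 7.6,
                  pka2_closed = 5.0, pka2_open = 6.2)
  b <- mwc_params(lo = 1e-9, pka1_closed = 5.0, pka1_open = 6.2,
                  pka2_closed = 4.8, pka2_open = 7.6)
  ph <- seq(0, 14, 0.05)
  expect_equal(mwc_po(a, ph), mwc_po(b, ph), tolerance = 1e-14)
  # direct power-form evaluation as the cross-check oracle
  direct <- function(p, pH) {
    A_o <- (1 + 10^(p$pka1_open - pH))^4
    A_c <- (1 + 10^(p$pka1_closed - pH))^4
    B_o <- (1 + 10^(p$pka2_open - pH))^4
    B_c <- (1 + 10^(p$pka2_closed - pH))^4
    p$lo * A_o * B_o / (p$lo * A_o * B_o + A_c * B_c)
  }
  set.seed(41)
  for (lo in c(1e-15, 1e-8, 1e-3, 1, 1e3)) {
    pk <- sort(runif(4, 2, 12))
    p <- mwc_params(lo = lo, pka1_closed = pk[1], pka1_open = pk[3],
                    pka2_closed = pk[2], pka2_open = pk[4])
    d <- direct(p, ph)
    expect_equal(mwc_po(p, ph), d, tolerance = 1e-12)
  }
})

test_that("MWC curves with ordered pKa values decrease monotonically in pH", {
  set.seed(17)
  ph <- seq(0, 14, 0.02)
  for (i in 1:25) {
    pk1 <- sort(runif(2, 2, 12)); pk2 <- sort(runif(2, 2, 12))
    p <- mwc_params(lo = 10^runif(1, -14, 2),
                    pka1_closed = pk1[1], pka1_open = pk1[2],
                    pka2_closed = pk2[1], pka2_open = pk2[2])
    expect_true(all(diff(mwc_po(p, ph)) <= 1e-12))
  }
  # one-sensor variants keep the limits (low-pH saturation closed form)
  one <- mwc_params(lo = 7e-4, pka2_closed = 5.0, pka2_open = 6.2)
  expect_equal(mwc_po(one, 14), 7e-4 / (1 + 7e-4), tolerance = 1e-6)
  expect_equal(mwc_po(one, -10), 1 / (1 + 10^(-4 * 1.2) / 7e-4),
               tolerance = 1e-9)
})

test_that("synthetic Po datasets reproduce the generating curve", {
  ctrl <- kcsa_gating_params("control")
  ph <- seq(4.6, 6, 0.2)
  # zero noise: means equal the curve exactly
  d0 <- generate_po_dataset(ctrl, ph, replicates = 5, noise_sd = 0, seed = 1)
  expect_equal(d0$data$po, mwc_po(ctrl, ph), tolerance = 1e-12)
  expect_true(all(d0$data$sem == 0))
  # law of large numbers at mid-range Po (away from the clipping bounds)
  mid <- 5.3
  big <- generate_po_dataset(ctrl, mid, replicates = 1e4, noise_sd = 0.05,
                             seed = 2)
  expect_lt(abs(big$data$po - mwc_po(ctrl, mid)), 3 * big$data$sem)
  expect_lt(big$data$sem, 0.001)
  # Lo -> infinity: open at every pH
  always <- mwc_params(lo = 1e6, pka1_closed = 4.8, pka1_open = 7.6)
  dl <- generate_po_dataset(always, ph, replicates = 3, noise_sd = 0,
                            seed = 3)
  expect_true(all(dl$data$po > 0.999))
  # seeded: same seed, same replicates
  expect_identical(generate_po_dataset(ctrl, ph, seed = 9)$replicates,
                   generate_po_dataset(ctrl, ph, seed = 9)$replicates)
  expect_error(generate_po_dataset(ctrl, c(4, 15)), "pH")
})

test_that("Po CSV files round-trip", {
  d <- generate_po_dataset(kcsa_gating_params("L40A"), seq(4, 6, 0.5),
                           seed = 4)
  p <- file.path(withr::local_tempdir(), "po.csv")
  write_po_csv(d, p)
  d2 <- read_po_csv(p)
  expect_equal(d2$po, d$data$po, tolerance = 1e-12)
  expect_equal(d2$n, d$data$n)
})

test_that("Hill fits recover noiseless truth and summarize MWC rows", {
  truth <- hill_params(pomax = 0.9, ph_half = 5.4, nh = 3.2)
  ph <- seq(4, 6.5, 0.1)
  df <- data.frame(pH = ph, po = hill_po(truth, ph))
  fit <- fit_hill(df)
  expect_true(fit$converged)
  expect_lt(fit$ssr, 1e-10)
  expect_equal(coef(fit)[["ph_half"]], 5.4, tolerance = 1e-4)
  expect_equal(coef(fit)[["nh"]], 3.2, tolerance = 1e-3)
  # fixing parameters keeps them at their initial values, without errors
  fitf <- fit_hill(df, init = hill_params(pomax = 0.9, ph_half = 5, nh = 2),
                   fixed = "pomax")
  expect_equal(fitf$params$pomax, 0.9)
  expect_true(is.na(fitf$se$pomax))
  # degenerate flat data is flagged, not thrown
  flat <- data.frame(pH = ph, po = rep(0.4, length(ph)))
  ffit <- fit_hill(flat)
  expect_true(any(grepl("degenerate", ffit$note)))
})

test_that("the Hill summary of the L40A parameters matches the mutant", {
  fit <- fit_hill(data.frame(pH = seq(4, 6.5, 0.05),
                             po = mwc_po(kcsa_gating_params("L40A"),
                                         seq(4, 6.5, 0.05))))
  expect_lt(abs(coef(fit)[["ph_half"]] - 5.2), 0.1)
  expect_lt(abs(coef(fit)[["nh"]] - 2), 0.3)
})

test_that("Hill fit standard errors give nominal 3-SE coverage", {
  # truth away from the Pomax <= 1 boundary so the Wald intervals apply
  truth <- hill_params(pomax = 0.9, ph_half = 5.3, nh = 3)
  ph <- seq(4.2, 6.4, 0.2)
  hits <- c(pomax = 0L, ph_half = 0L, nh = 0L)
  nseeds <- 200
  for (s in seq_len(nseeds)) {
    set.seed(s)
    po <- pmin(1, pmax(0, hill_po(truth, ph) +
                            rnorm(length(ph), 0, 0.05 / sqrt(5))))
    fit <- fit_hill(data.frame(pH = ph, po = po))
    ok <- abs(coef(fit) - unlist(truth)) < 3 * unlist(fit$se)
    hits <- hits + as.integer(ok)
  }
  expect_true(all(hits / nseeds >= 0.95))
})

test_that("MWC fits recover Lo to four significant figures when alone", {
  truth <- kcsa_gating_params("L40A")       # Lo = 6.2e-4
  ph <- seq(4, 6.5, 0.05)
  df <- data.frame(pH = ph, po = mwc_po(truth, ph))
  init <- truth; init$lo <- 1e-5
  fit <- fit_mwc(df, init)                  # default: only lo free
  expect_true(fit$converged)
  expect_equal(fit$params$lo, 6.2e-4, tolerance = 1e-4)
  expect_true(all(c("pka1_closed", "pka1_open") %in% fit$fixed))
})

test_that("state-independent data drives pKa1_closed to its bound", {
  # data generated with pKa1_closed = pKa1_open: stage 1 must hit the
  # constraint, stage 2 pins it and refits Lo alone
  truth <- kcsa_gating_params("L40A")       # pKa1 7.6/7.6
  ph <- seq(4, 6.5, 0.05)
  df <- data.frame(pH = ph, po = mwc_po(truth, ph))
  init <- mwc_params(lo = 1e-8, pka1_closed = 4.8, pka1_open = 7.6,
                     pka2_closed = 5.0, pka2_open = 6.2)
  fit <- fit_mwc_two_stage(df, init)
  expect_true("pka1_closed" %in% fit$stages$stage1$active_bounds)
  expect_true(is.na(fit$stages$stage1$se$pka1_closed))
  expect_equal(fit$params$pka1_closed, 7.6)
  expect_equal(fit$params$lo, 6.2e-4, tolerance = 1e-3)
  expect_true("stage2" %in% names(fit$stages))
})

test_that("a one-sensor model recovers the H25R intrinsic gating", {
  truth <- kcsa_gating_params("H25R")       # sensor 1 absent, Lo = 7e-4
  ph <- seq(4, 6.5, 0.25)
  d <- generate_po_dataset(truth, ph, replicates = 5, noise_sd = 0.05,
                           seed = 12)
  init <- truth; init$lo <- 1e-5
  fit <- fit_mwc(d, init)
  expect_false(fit$params$lo == init$lo)
  expect_lt(abs(fit$params$lo - 7e-4), 3 * fit$se$lo)
})

test_that("the Hill summary workflow errors without a half-activation", {
  flat <- mwc_params(lo = 0.5, pka1_closed = 5, pka1_open = 5)
  expect_error(hill_summary_of_mwc(flat), "cross")
})

test_that("Hill summaries of the published rows reproduce frozen values", {
  # regression against an independent direct-evaluation + nls oracle
  expected <- list(control = c(5.3419, 5.3376),
                   L40A = c(5.2623, 2.2495),
                   H25R = c(5.2851, 2.2633),
                   E118A = c(5.5400, 3.3513))
  for (m in names(expected)) {
    fit <- hill_summary_of_mwc(kcsa_gating_params(m))
    expect_equal(unname(coef(fit)[c("ph_half", "nh")]), expected[[m]],
                 tolerance = 1e-3)
  }
})

test_that("gating fits export their constrained layout as JSON", {
  df <- data.frame(pH = seq(4, 6.5, 0.1),
                   po = mwc_po(kcsa_gating_params("control"),
                               seq(4, 6.5, 0.1)))
  init <- kcsa_gating_params("control"); init$lo <- 1e-10
  fit <- fit_mwc(df, init)
  p <- file.path(withr::local_tempdir(), "fit.json")
  write_gating_fit(fit, p)
  j <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(j$model, "mwc")
  expect_equal(j$params$lo, fit$params$lo, tolerance = 1e-9)
  expect_setequal(j$fixed, fit$fixed)
})
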