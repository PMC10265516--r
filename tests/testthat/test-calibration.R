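# Fitters (Michaelis-Menten, MWC, joint ODE), the BCECF pH conversion, and
# the shipped calibrated defaults.

test_that("fit_mm recovers noiseless parameters exactly and noisy ones within 10%", {
  C <- c(0.5, 1, 2, 5, 10, 20, 50, 100)
  v <- 10 * C / (5 + C)
  f <- fit_mm(C, v)
  expect_true(f$converged)
  expect_equal(unname(f$estimates["Vmax"]), 10, tolerance = 1e-8)
  expect_equal(unname(f$estimates["Km"]), 5, tolerance = 1e-8)
  expect_equal(f$r2, 1, tolerance = 1e-12)

  # median recovery over a handful of seeded noise draws (3% of Vmax)
  errs <- vapply(1:5, function(s) {
    set.seed(s)
    vn <- v + stats::rnorm(8, 0, 0.03 * 10)
    abs(fit_mm(C, vn)$estimates[["Km"]] - 5) / 5
  }, numeric(1))
  expect_lt(stats::median(errs), 0.10)
  expect_error(fit_mm(c(1, 1, 2), c(1, 1, 2)), "3 distinct")
})

test_that("fit_mwc recovers the printed activation constants from its own curve", {
  m <- mwc_constants()
  pH <- seq(5.6, 7.6, by = 0.2)
  rate <- m$Vmax * mwc_activation(10^-pH, m)
  f <- fit_mwc(pH, rate)
  expect_true(f$converged)
  expect_equal(unname(f$estimates["K_h"]), m$K_h, tolerance = 1e-6)
  expect_equal(unname(f$estimates["K_l"]), m$K_l, tolerance = 1e-6)
  expect_equal(unname(f$estimates["L0"]), m$L0, tolerance = 1e-6)
  expect_equal(unname(f$estimates["Vmax"]), m$Vmax, tolerance = 1e-6)
  expect_lt(f$estimates[["K_h"]], f$estimates[["K_l"]])

  # midpoint of the fitted curve sits at the derived half-activation pH
  mid <- mwc_midpoint_ph(as.list(f$estimates[c("K_h", "K_l", "L0")]))
  expect_equal(mid, mwc_midpoint_ph(m), tolerance = 1e-4)
  expect_error(fit_mwc(c(6, 6.5), c(1, 2)), "6 pH points")
})

test_that("bcecf_ph implements the ratiometric calibration formula", {
  expect_equal(bcecf_ph(1.5, 1, 2, pKa = 6.98, F_ratio = 1), 6.98)
  # frozen hand evaluation
  expect_equal(bcecf_ph(1.75, 1, 2, pKa = 6.98, F_ratio = 0.9),
               7.409409129247696, tolerance = 1e-12)
  R <- seq(1.05, 1.95, by = 0.1)
  expect_true(all(diff(bcecf_ph(R, 1, 2)) > 0))
  expect_error(bcecf_ph(2.0, 1, 2), "strictly between")
  expect_error(bcecf_ph(0.9, 1, 2), "strictly between")
})

test_that("joint_fit recovers parameters from the model's own noiseless output", {
  cell <- default_cell(); mem <- default_mem()
  truth <- default_exch()
  times <- c(5, 10, 20, 30, 60)
  tr <- simulate_uptake(cell, mem, truth, times = c(0, times))
  kin <- data.frame(t_s = times, Li_cell_mM = tr$Li_cell_mM[-1])
  del <- data.frame(t_s = times, delta7Li_permil = tr$delta7Li_permil[-1])
  start <- truth
  f <- joint_fit(kin, del, cell, mem, start,
                 init = c(gamma_on = 1.02, n_scale = 1.3 * truth$n_scale))
  expect_true(f$converged)
  expect_equal(unname(f$estimates["gamma_on"]), truth$gamma_on,
               tolerance = 1e-4)
  expect_equal(unname(f$estimates["n_scale"]), truth$n_scale,
               tolerance = 1e-3)
  expect_gt(f$r2, 1 - 1e-6)
})

test_that("joint_fit recovers the translocation KIE from one noisy replicate", {
  cell <- default_cell(); mem <- default_mem()
  truth <- default_exch()
  noisy <- generate_kinetics(cell, mem, truth, times = c(5, 10, 20, 30, 60),
                             noise = noise_spec(n_replicates = 2, seed = 5))
  f <- joint_fit(noisy[, c("t_s", "Li_cell_mM")],
                 noisy[, c("t_s", "delta7Li_permil")],
                 cell, mem, truth,
                 init = c(alpha_kie = 0.98, n_scale = truth$n_scale))
  expect_lt(abs(f$estimates[["alpha_kie"]] - truth$alpha_kie) /
              truth$alpha_kie, 0.15)
})

test_that("the shipped defaults reproduce the calibration anchors", {
  cell <- default_cell(); mem <- default_mem(); exch <- default_exch()
  anchors <- default_anchors()

  # channel-only fractionation anchor
  tr <- simulate_uptake(cell, mem, NULL, times = c(0, 60))
  expect_equal(tr$delta7Li_permil[2] - cell$delta_out, -4.4, tolerance = 0.1)

  # plateau mean
  tr <- simulate_uptake(cell, mem, exch, times = c(0, 5, 10, 20, 30))
  expect_equal(mean(tr$delta7Li_permil[-1]), 1.2, tolerance = 0.5)

  # dose-response anchors
  dr <- dose_response(cell, mem, exch, conc = c(0.3, 60, 120))
  expect_equal(dr$delta7Li_permil[1], 5.4, tolerance = 0.5)
  expect_equal(dr$delta7Li_permil[2], 1.4, tolerance = 0.5)
  expect_equal(dr$delta7Li_permil[3], 1.4, tolerance = 0.5)

  # apparent Km
  drk <- dose_response(cell, mem, exch, conc = c(1, 3, 10, 30, 60, 120))
  km <- fit_mm(drk$Li_out_mM, drk$Li_cell_mM)$estimates[["Km"]]
  expect_equal(km, 9.94, tolerance = 0.5)
})

test_that("calibrated bundles serialise to JSON and back bit-exactly", {
  b <- structure(list(cell = default_cell(), mem = default_mem(),
                      exch = default_exch(), anchors = default_anchors(),
                      excluded = character(0),
                      residuals = c(km = 0.12)),
                 class = "li_bundle")
  path <- withr::local_tempfile(fileext = ".json")
  bundle_to_json(b, path)
  b2 <- bundle_from_json(path)
  expect_identical(b2$exch$gamma_on, b$exch$gamma_on)
  expect_identical(b2$exch$n_scale, b$exch$n_scale)
  expect_identical(b2$mem$rho_ch, b$mem$rho_ch)
  expect_equal(b2$cell$V_cell_um3, b$cell$V_cell_um3)
  tr1 <- simulate_uptake(b$cell, b$mem, b$exch, times = c(0, 10))
  tr2 <- simulate_uptake(b2$cell, b2$mem, b2$exch, times = c(0, 10))
  expect_identical(tr1$delta7Li_permil, tr2$delta7Li_permil)
})
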