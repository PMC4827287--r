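# Cyclic compression analysis: thickness detection, cycle segmentation,
# exponential fit and tangent moduli.

test_that("thickness is read at the tare crossing of a linear-spring contact", {
  # spring k = 0.004 N/um reaches the 0.02 N tare exactly 5 um past contact
  tr <- spring_trace(start_gap = 1250, contact_gap = 1200, k = 0.004,
                     speed = 50, rate = 10)
  # 5 um/sample: gap 1195 falls exactly on a sample -> no interpolation
  expect_equal(detect_thickness(tr, tare_N = 0.02), 1195)
  # 4 um/sample: crossing between samples -> linear interpolation, same gap
  tr2 <- spring_trace(rate = 12.5)
  expect_equal(detect_thickness(tr2, tare_N = 0.02), 1195)
})

test_that("thickness detection is invariant to uniform time rescaling", {
  tr <- spring_trace(rate = 12.5)
  slow <- cyclic_trace(tr$data$time_s * 3, tr$data$force_N,
                       tr$data$displacement_um, start_gap_um = tr$start_gap_um)
  expect_identical(detect_thickness(tr), detect_thickness(slow))
})

test_that("degenerate contact records raise the documented errors", {
  n <- 100
  flat <- cyclic_trace(seq(0, 9.9, 0.1), rep(0, n), seq(0, 495, 5),
                       start_gap_um = 1250)
  expect_error(detect_thickness(flat), "no contact detected")
  pre <- cyclic_trace(seq(0, 9.9, 0.1), rep(0.5, n), seq(0, 495, 5),
                      start_gap_um = 1250)
  expect_error(detect_thickness(pre), "pre-loaded specimen")
  nogap <- cyclic_trace(1:10, rep(0, 10), 1:10)
  expect_error(detect_thickness(nogap), "start_gap_um")
})

test_that("cycle extraction keeps the requested loading limbs", {
  tr <- gen_mech_trace(noise_sd = 0)
  cv <- extract_cycles(tr, diameter_mm = 5)
  expect_identical(attr(cv, "cycles_used"), 7:10)
  expect_equal(max(cv$strain), 0.20, tolerance = 1e-10)
  expect_gte(min(cv$strain), -1e-12)
  # keep_last = n_cycles returns every cycle
  all10 <- extract_cycles(tr, 5, keep_last = 10L)
  expect_identical(attr(all10, "cycles_used"), 1:10)
})

test_that("cycle extraction conserves loading samples without duplication", {
  tr <- gen_mech_trace(noise_sd = 0)
  all10 <- extract_cycles(tr, 5, keep_last = 10L)
  idx <- attr(all10, "index")
  expect_false(any(duplicated(idx)))
  # each loading limb spans exactly half a cycle of samples (+1 endpoints):
  # 10 limbs over 10 s at 100 Hz -> 10 * 51 samples
  expect_length(idx, 10L * (50L + 1L))
  # limbs are monotone non-decreasing in displacement
  d <- tr$data$displacement_um[idx]
  limb <- rep(seq_len(10L), each = 51L)
  expect_true(all(tapply(d, limb, function(z) all(diff(z) >= 0))))
})

test_that("truncated or aperiodic records fail cycle segmentation", {
  tr <- gen_mech_trace(noise_sd = 0, n_cycles = 6L)
  expect_error(extract_cycles(tr, 5, n_cycles = 10L), "incomplete test")
  ramp <- cyclic_trace(seq(0, 20, 0.01), c(rep(0, 500), seq(0, 2, length.out = 1501)),
                       c(seq(0, 250, length.out = 500), seq(250, 500, length.out = 1501)),
                       start_gap_um = 1430)
  expect_error(extract_cycles(ramp, 5, thickness_um = 1180), "incomplete test")
})

test_that("noiseless synthetic curves return the generating exponential law", {
  for (par in list(c(0.01, 20), c(0.005, 28), c(0.04, 12))) {
    tr <- gen_mech_trace(A_MPa = par[1], B = par[2], noise_sd = 0)
    cv <- extract_cycles(tr, 5)
    fit <- fit_exponential(cv)
    expect_equal(fit$A, par[1], tolerance = 1e-6)
    expect_equal(fit$B, par[2], tolerance = 1e-6)
    expect_lt(fit$rss, 1e-12)
  }
})

test_that("fit recovers parameters within 5% under 1% stress noise", {
  set.seed(11)
  eps <- rep(seq(0, 0.2, length.out = 120), 4)
  for (r in 1:5) {
    sig <- 0.01 * (exp(20 * eps) - 1)
    sig <- sig + rnorm(length(sig), 0, 0.01 * max(sig))
    cv <- structure(data.frame(strain = eps, stress = sig),
                    class = c("stress_strain_curve", "data.frame"))
    fit <- fit_exponential(cv)
    expect_lt(abs(fit$A - 0.01) / 0.01, 0.05)
    expect_lt(abs(fit$B - 20) / 20, 0.05)
  }
})

test_that("degenerate stress data fail the fit with a diagnostic", {
  cv <- structure(data.frame(strain = seq(0, 0.2, 0.01),
                             stress = rep(0, 21)),
                  class = c("stress_strain_curve", "data.frame"))
  expect_error(fit_exponential(cv), "fit failed")
})

test_that("tangent moduli are the analytic derivative of the fitted law", {
  fit <- structure(list(A = 0.01, B = 20, fit_range = c(0, 0.2),
                        rss = 0, n_points = 100L), class = "exp_fit")
  m <- tangent_moduli(fit, c(0, 0.10, 0.18))
  expect_equal(m$modulus_MPa[1], 0.01 * 20)        # A*B exactly at origin
  expect_equal(m$modulus_MPa[2], 0.2 * exp(2), tolerance = 1e-9)
  expect_equal(m$modulus_MPa[3], 0.2 * exp(3.6), tolerance = 1e-9)
})

test_that("tangent moduli increase strictly with strain whenever B > 0", {
  set.seed(21)
  for (r in 1:20) {
    fit <- structure(list(A = runif(1, 1e-4, 0.1), B = runif(1, 1, 60),
                          fit_range = c(0, 0.2), rss = 0, n_points = 50L),
                     class = "exp_fit")
    m <- tangent_moduli(fit, seq(0, 0.25, 0.01))
    expect_true(all(diff(m$modulus_MPa) > 0))
    expect_true(all(m$modulus_MPa > 0))
  }
})

test_that("fit-to-tangent round trip matches analytic moduli to 1e-6", {
  strains <- c(0.10, 0.12, 0.15, 0.18)
  for (par in list(c(0.02, 15), c(0.008, 25))) {
    tr <- gen_mech_trace(A_MPa = par[1], B = par[2], noise_sd = 0)
    fit <- fit_exponential(extract_cycles(tr, 5))
    m <- tangent_moduli(fit, strains)$modulus_MPa
    truth <- par[1] * par[2] * exp(par[2] * strains)
    expect_equal(m, truth, tolerance = 1e-6)
  }
})

test_that("thickness window selection enumerates inclusively", {
  th <- c(1100, 1110, 1200, 1250, 1260)
  sel <- select_by_thickness(th, 1110, 1250)
  expect_identical(sel$selected, 2:4)
  expect_equal(sel$discard_fraction, 0.4)
  all_in <- select_by_thickness(c(1150, 1200), 1110, 1250)
  expect_equal(all_in$discard_fraction, 0)
  expect_error(select_by_thickness(numeric(0)), "no thicknesses")
  # default window is the protocol's 1110-1250 um
  expect_identical(select_by_thickness(th)$selected, 2:4)
})
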