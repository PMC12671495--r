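make_rect_trace <- function(F0 = 1, Fm = 5, levels) {
  # dark baseline with a pulse at 15 s, then 60-s light steps with a pulse
  # of known (Fs, Fm') near the end of each
  tg <- seq(0, 30 + 60 * nrow(levels), by = 0.5)
  val <- rep(F0, length(tg))
  segs <- data.frame(start = 30 + 60 * (seq_len(nrow(levels)) - 1L),
                     end = 30 + 60 * seq_len(nrow(levels)),
                     intensity = levels$I)
  pulses <- c(15, segs$end - 5)
  for (i in seq_len(nrow(levels))) {
    w <- tg >= segs$start[i] & tg < segs$end[i]
    val[w] <- levels$Fs[i]
  }
  for (k in seq_along(pulses)) {
    w <- tg >= pulses[k] & tg <= pulses[k] + 0.8
    val[w] <- if (k == 1L) Fm else levels$Fmp[k - 1L]
  }
  list(trace = fluor_trace(tg, val, kind = "pam"),
       protocol = pulse_protocol(segs, pulses, pulse_duration = 0.8))
}

test_that("constructed rectangular pulse levels are recovered exactly", {
  lv <- data.frame(I = c(100, 500, 1000), Fs = c(2.0, 1.5, 1.2),
                   Fmp = c(4.0, 3.0, 2.5))
  x <- make_rect_trace(F0 = 1, Fm = 5, lv)
  qs <- extract_pulse_levels(x$trace, x$protocol)
  expect_equal(qs$F0, 1)
  expect_equal(qs$Fm, 5)
  expect_equal(qs$FvFm, 0.8)
  expect_equal(qs$pulses$Fs[-1L], lv$Fs)
  expect_equal(qs$pulses$Fm_prime[-1L], lv$Fmp)
})

test_that("pulse-level extraction tolerates +/-50 ms timing jitter", {
  ds <- generate_dataset("WT", "npq_protocol")
  qs0 <- extract_pulse_levels(ds$trace, ds$protocol)
  set.seed(7)
  jit <- ds$protocol
  jit$pulses <- jit$pulses + stats::runif(length(jit$pulses), -0.05, 0.05)
  qs1 <- extract_pulse_levels(ds$trace, jit)
  expect_lt(max(abs(qs1$pulses$Fm_prime - qs0$pulses$Fm_prime) /
                  qs0$pulses$Fm_prime), 0.01)
  ok <- !is.na(qs0$pulses$Fs)
  expect_lt(max(abs(qs1$pulses$Fs[ok] - qs0$pulses$Fs[ok]) /
                  qs0$pulses$Fs[ok]), 0.01)
})

test_that("NPQ follows the Stern-Volmer definition", {
  qs <- quench_series(F0 = 0.5, Fm = 2,
                      pulses = data.frame(t = c(10, 20), Fs = c(0.6, 0.6),
                                          Fm_prime = c(1.0, 2.0)))
  npq <- npq_timecourse(qs)
  expect_equal(npq$NPQ, c(1, 0))  # (2-1)/1 = 1; Fm' = Fm => 0
})

test_that("yield partition matches hand arithmetic and sums to one", {
  qs <- quench_series(F0 = 0.1, Fm = 1,
                      pulses = data.frame(t = 1, Fs = 0.3, Fm_prime = 0.5))
  y <- partition_yields(qs)
  expect_equal(y$Phi_II, 0.4)
  expect_equal(y$Phi_NPQ, 0.3)
  expect_equal(y$Phi_NO, 0.3)
  expect_equal(y$Phi_II + y$Phi_NPQ + y$Phi_NO, 1)
})

test_that("a dark-adapted pulse gives Phi_II = Fv/Fm and Phi_NPQ = 0", {
  qs <- quench_series(F0 = 1, Fm = 5,
                      pulses = data.frame(t = 1, Fs = 1, Fm_prime = 5))
  y <- partition_yields(qs)
  expect_equal(y$Phi_II, 0.8)
  expect_equal(y$Phi_NPQ, 0)
  expect_equal(y$qL, 1)
})

test_that("yield conservation holds at machine precision for every preset", {
  for (g in preset_names()) {
    ds <- generate_dataset(g, "pam_session")
    y <- partition_yields(extract_pulse_levels(ds$trace, ds$protocol))
    expect_lt(max(abs(y$Phi_II + y$Phi_NPQ + y$Phi_NO - 1)), 1e-14)
    expect_true(all(y$Phi_NO >= 0 & y$Phi_NPQ >= -1e-14))
  }
})

test_that("lake-model partition also sums to one", {
  ds <- generate_dataset("WT", "pam_session")
  y <- partition_yields(extract_pulse_levels(ds$trace, ds$protocol),
                        lake = TRUE)
  expect_lt(max(abs(y$Phi_II + y$Phi_NPQ + y$Phi_NO - 1)), 1e-14)
})

test_that("qE/qI decomposition: flat-zero NPQ gives (0, 0)", {
  proto <- pulse_protocol(data.frame(start = 0, end = 480, intensity = 1000),
                          pulses = seq(30, 960, 30),
                          dark = data.frame(start = 480, end = 960))
  npq <- data.frame(t = seq(30, 960, 30), NPQ = 0)
  dec <- decompose_qe_qi(npq, proto)
  expect_equal(dec$qE, 0)
  expect_equal(dec$qI, 0)
  expect_error(decompose_qe_qi(npq, pulse_protocol(
    data.frame(start = 0, end = 480, intensity = 1000), pulses = 30)),
    "no dark window")
})

test_that("exponential unmixing agrees with the endpoint split on preset data", {
  ds <- generate_dataset("WT", "npq_protocol")
  npq <- npq_timecourse(extract_pulse_levels(ds$trace, ds$protocol))
  d1 <- decompose_qe_qi(npq, ds$protocol)
  d2 <- decompose_qe_qi(npq, ds$protocol, method = "exponential")
  expect_equal(d2$qE, d1$qE, tolerance = 0.02)
  expect_gt(d2$tau, 0)
})

test_that("the PsbS-null preset yields qE of zero", {
  ds <- generate_dataset("npq4", "npq_protocol")
  dec <- decompose_qe_qi(npq_timecourse(extract_pulse_levels(ds$trace, ds$protocol)),
                         ds$protocol)
  expect_lt(dec$qE, 0.01)
})

test_that("NPQ integral: constant level, additivity, window checks", {
  npq <- data.frame(t = seq(0, 600, 10), NPQ = 1)
  expect_equal(npq_integral(npq, c(0, 480)), 480)
  ramp <- data.frame(t = seq(0, 600, 10), NPQ = seq(0, 600, 10) / 100)
  expect_equal(npq_integral(ramp, c(0, 480)),
               npq_integral(ramp, c(0, 123)) + npq_integral(ramp, c(123, 480)))
  expect_error(npq_integral(ramp, c(0, 1000)), "exceeds")
  # baseline subtraction flag
  flat <- data.frame(t = seq(0, 480, 10), NPQ = 0.5)
  expect_equal(npq_integral(flat, c(0, 480), subtract_baseline = TRUE), 0)
})

test_that("logistic NPQ-vs-LHC fit recovers noiseless parameters", {
  truth <- list(y0 = 150, a = 900, x0 = 0.014, b = 0.003)
  pts <- generate_lhc_npq_points(n = 16, coef = truth)
  expect_equal(range(pts$lhc), c(0.004, 0.028))
  fit <- fit_sigmoid_lhc_npq(pts)
  expect_rel_equal(fit$coef[["a"]], truth$a, 1e-6)
  expect_rel_equal(fit$coef[["x0"]], truth$x0, 1e-6)
  expect_gt(fit$r_squared, 0.9999)
  # monotone increasing prediction with a > 0
  xs <- seq(0.004, 0.028, length.out = 50)
  expect_true(all(diff(fit$predict(xs)) > 0))
})
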