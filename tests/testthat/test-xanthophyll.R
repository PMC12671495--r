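test_that("de-epoxidation index endpoints and hand value", {
  expect_equal(deepoxidation_index(1, 0, 0), 0)
  expect_equal(deepoxidation_index(0, 0, 1), 1)
  expect_equal(deepoxidation_index(0.7, 0.2, 0.1), 0.2)
  expect_equal(deepoxidation_index(0.7, 0.2, 0.1, formula = "z_only"), 0.1)
  expect_error(deepoxidation_index(0, 0, 0), "zero")
  # unnormalized amounts give the same index
  expect_equal(deepoxidation_index(7, 2, 1), 0.2)
})

light_dark_protocol <- function() {
  pulse_protocol(data.frame(start = 0, end = 480, intensity = 1000),
                 pulses = numeric(0),
                 dark = data.frame(start = 480, end = 960))
}

test_that("zero rates give a constant profile; pool always conserved", {
  proto <- light_dark_protocol()
  sim0 <- simulate_vaz(deepox_kinetics(0, 0, 0), proto, seq(0, 960, 60))
  expect_true(all(sim0$data$V == 1 & sim0$data$A == 0 & sim0$data$Z == 0))
  sim <- simulate_vaz(deepox_kinetics(0.002, 0.001, 0.0017), proto,
                      seq(0, 960, 30))
  expect_lt(max(abs(sim$data$V + sim$data$A + sim$data$Z - 1)), 1e-12)
})

test_that("DI rises monotonically under continuous light without epoxidation", {
  proto <- pulse_protocol(data.frame(start = 0, end = 960, intensity = 1000),
                          pulses = numeric(0))
  sim <- simulate_vaz(deepox_kinetics(0.003, 0.0015, 0), proto, seq(0, 960, 30))
  di <- deepoxidation_index(sim$data$V, sim$data$A, sim$data$Z)
  expect_true(all(diff(di) > 0))
})

test_that("dark reversal lowers DI after the light phase", {
  ds <- generate_dataset("WT", "vaz_course")
  d <- ds$profile$data
  di <- deepoxidation_index(d$V, d$A, d$Z)
  i480 <- which(d$time == 480)
  expect_lt(di[length(di)], di[i480])
})

test_that("noiseless rate recovery is exact; noisy recovery is unbiased", {
  proto <- light_dark_protocol()
  truth <- deepox_kinetics(0.0025, 0.0012, 0.0017)
  tgrid <- seq(0, 960, 60)
  prof <- simulate_vaz(truth, proto, tgrid)
  fit <- fit_vaz(prof, proto)
  expect_rel_equal(fit$kinetics$k_vd, truth$k_vd, 1e-3)
  expect_rel_equal(fit$kinetics$k_az, truth$k_az, 1e-3)
  expect_rel_equal(fit$kinetics$k_ep, truth$k_ep, 1e-3)

  # 5% multiplicative noise, many seeds: median bias < 10%
  kvd_hat <- vapply(1:50, function(s) {
    d <- prof$data
    noisy <- with_seed_for_tests(s, as.matrix(d[c("V", "A", "Z")]) *
                                   (1 + stats::rnorm(3 * nrow(d), 0, 0.05)))
    np <- pigment_profile(d$time, pmax(noisy[, 1], 0), pmax(noisy[, 2], 0),
                          pmax(noisy[, 3], 0))
    fit_vaz(np, proto)$kinetics$k_vd
  }, numeric(1))
  expect_lt(abs(stats::median(kvd_hat) - truth$k_vd) / truth$k_vd, 0.10)
})

test_that("the low-antenna genotype de-epoxidizes faster than wild type", {
  proto <- light_dark_protocol()
  f_wt <- fit_vaz(generate_dataset("WT", "vaz_course")$profile, proto)
  f_kb <- fit_vaz(generate_dataset("koLhcb", "vaz_course")$profile, proto)
  expect_gt(f_kb$kinetics$k_vd, f_wt$kinetics$k_vd)
})

test_that("all-dark data are rejected as under-determined", {
  proto <- pulse_protocol(data.frame(start = 0, end = 1, intensity = 1000),
                          pulses = numeric(0),
                          dark = data.frame(start = 1, end = 960))
  prof <- pigment_profile(seq(100, 900, 100), rep(0.5, 9), rep(0.3, 9),
                          rep(0.2, 9))
  expect_error(fit_vaz(prof, proto), "under-determined")
})

test_that("preset VAZ-pool metadata is carried on generated profiles", {
  expect_equal(generate_dataset("WT", "vaz_course")$profile$meta$vaz_per_100chl, 5.2)
  expect_equal(generate_dataset("koLHCII", "vaz_course")$profile$meta$vaz_per_100chl, 7.6)
  expect_equal(generate_dataset("koLhcb", "vaz_course")$profile$meta$vaz_per_100chl, 9.4)
})
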