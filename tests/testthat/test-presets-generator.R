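test_that("presets carry the published genotype values", {
  wt <- make_preset("WT")
  expect_equal(wt$J, 2.05)
  expect_equal(wt$FvFm, 0.82)
  expect_equal(wt$sigma_rel, 1)
  ko <- make_preset("koLHCII")
  expect_equal(ko$sigma_rel, 0.55)
  expect_equal(ko$qE, 0.8)
  expect_equal(make_preset("npq4")$qE, 0)
  err <- tryCatch(make_preset("nonesuch"), error = conditionMessage)
  expect_match(err, "unknown genotype")
  expect_match(err, "WT.*koLHCII", )  # error lists the available presets
})

test_that("every numeric preset field carries a provenance annotation", {
  for (g in preset_names()) {
    p <- make_preset(g)
    prov <- preset_provenance(p)
    fields <- names(p)[vapply(p, is.numeric, logical(1))]
    missing <- setdiff(fields, names(prov))
    expect_length(missing, 0L)
    expect_true(all(nzchar(prov)))
  }
})

test_that("derived preset parameters are consistent with their constraints", {
  # the koLhcb sustained component is solved so its end-of-light NPQ is
  # 22% of the wild type's
  wt <- make_preset("WT"); kb <- make_preset("koLhcb")
  npq_end <- function(p)
    p$qE * (1 - exp(-480 / p$tau_fast)) + p$qI * (1 - exp(-480 / p$tau_slow))
  expect_equal(npq_end(kb) / npq_end(wt), 0.22, tolerance = 1e-10)
  # the xanthophyll forward rate reproduces the end-of-light DI target
  proto <- pulse_protocol(data.frame(start = 0, end = 480, intensity = 1000),
                          numeric(0))
  sim <- simulate_vaz(deepox_kinetics(kb$k_vd, kb$k_az, 0), proto, c(0, 240, 480))
  expect_equal(deepoxidation_index(sim$data$V[3L], sim$data$A[3L],
                                   sim$data$Z[3L]), kb$di_end,
               tolerance = 1e-9)
  # photoinhibition endpoint identity for the wild type
  expect_equal(wt$pi_plateau + (wt$pi_y_init - wt$pi_plateau) *
                 exp(-wt$pi_k * 6), wt$pi_endpoint_frac * wt$pi_y_init,
               tolerance = 1e-12)
})

test_that("generation is deterministic given a seed and exact at zero noise", {
  a <- generate_dataset("WT", "dcmu_induction", seed = 3, noise = 0.02)
  b <- generate_dataset("WT", "dcmu_induction", seed = 3, noise = 0.02)
  c <- generate_dataset("WT", "dcmu_induction", seed = 4, noise = 0.02)
  expect_identical(a$trace$value, b$trace$value)
  expect_false(identical(a$trace$value, c$trace$value))
  clean <- generate_dataset("WT", "dcmu_induction", seed = 3, noise = 0)
  p <- make_preset("WT")
  model <- simulate_dcmu_induction(
    connectivity_params(p$J, p$k_ph, p$F0, p$Fv), clean$trace$time)
  expect_identical(clean$trace$value, model$value)
})

test_that("add_noise is seeded, unbiased, clipped and leaves RNG state alone", {
  tr <- fluor_trace(seq(0, 99, 1), rep(2, 100), kind = "pam")
  expect_identical(add_noise(tr, 0, 1)$value, tr$value)
  expect_error(add_noise(tr, -0.1), ">= 0")
  set.seed(123); before <- stats::runif(1)
  set.seed(123)
  n1 <- add_noise(tr, 0.05, seed = 9)
  expect_identical(stats::runif(1), before)  # global RNG untouched
  expect_identical(n1$value, add_noise(tr, 0.05, seed = 9)$value)
  # CLT: mean over 1000 replicates of a constant trace within 3 se
  means <- vapply(1:1000, function(s) mean(add_noise(tr, 0.1, s)$value),
                  numeric(1))
  se <- 0.1 * 2 / sqrt(100 * 1000)
  expect_lt(abs(mean(means) - 2), 3 * se)
  # heavy noise never yields negative fluorescence
  expect_true(all(add_noise(tr, 2, seed = 11)$value >= 0))
})

test_that("analysis fitters do not reach into the generator", {
  for (fn in list(fit_dcmu_induction, extract_pulse_levels, fit_vaz,
                  fit_decay_half_time, fit_saturation)) {
    src <- paste(deparse(body(fn)), collapse = "\n")
    expect_false(grepl("generate_dataset|make_preset|npq_trajectory", src))
  }
})

test_that("write_dataset lays out trace, protocol and provenance files", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset("koLHCII", "npq_protocol", seed = 2, noise = 0.01)
  files <- write_dataset(ds, dir, seed = 2, noise = 0.01)
  expect_true(all(file.exists(files)))
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"))
  expect_equal(prov$preset, "koLHCII")
  back <- read_trace(file.path(dir, "trace.csv"), kind = "pam")
  expect_equal(back$value, ds$trace$value, tolerance = 1e-12)
})
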