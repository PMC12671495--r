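# Synthetic-trace generator ---------------------------------------------
#
# Emulates the measurement kinds the analysis chain consumes, from genotype
# presets. Everything is deterministic given (preset, what, seed, noise);
# noise = 0 yields the exact model curve.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Add multiplicative Gaussian noise to a trace
#'
#' Fluorescence noise scales with the signal, so noise is multiplicative:
#' `value * (1 + sd * N(0,1))`, clipped at zero. Seeded and reproducible;
#' the global random-number state is left untouched.
#'
#' @param trace A [fluor_trace()].
#' @param sd Relative standard deviation (`>= 0`); 0 returns the trace
#'   unchanged.
#' @param seed Integer seed.
#' @return A noisy [fluor_trace()].
#' @export
add_noise <- function(trace, sd, seed = 1L) {
  stopifnot(inherits(trace, "fluor_trace"))
  if (sd < 0) stop("noise sd must be >= 0")
  if (sd == 0) return(trace)
  noisy <- with_seed(seed, trace$value * (1 + stats::rnorm(length(trace$value), 0, sd)))
  trace$value <- pmax(noisy, 0)
  trace
}

# NPQ trajectory over a light/dark protocol: the fast (energy-quenching)
# and sustained components each relax first-order toward their light- or
# dark-phase targets (fast: qE in light, 0 in dark with tau_relax;
# sustained: qI in light with tau_slow, frozen in dark).
npq_trajectory <- function(preset, segments, t) {
  qe <- numeric(length(t))
  qi <- numeric(length(t))
  qe0 <- 0; qi0 <- 0
  for (i in seq_len(nrow(segments))) {
    a <- segments$start[i]; b <- segments$end[i]
    light <- segments$intensity[i] > 0
    idx <- which(t >= a - 1e-9 & t <= b + 1e-9)
    dt <- t[idx] - a
    if (light) {
      qe[idx] <- preset$qE + (qe0 - preset$qE) * exp(-dt / preset$tau_fast)
      qi[idx] <- preset$qI + (qi0 - preset$qI) * exp(-dt / preset$tau_slow)
    } else {
      qe[idx] <- qe0 * exp(-dt / preset$tau_relax)
      qi[idx] <- qi0
    }
    w <- b - a
    if (light) {
      qe0 <- preset$qE + (qe0 - preset$qE) * exp(-w / preset$tau_fast)
      qi0 <- preset$qI + (qi0 - preset$qI) * exp(-w / preset$tau_slow)
    } else {
      qe0 <- qe0 * exp(-w / preset$tau_relax)
    }
  }
  qe + qi
}

# steady-state yield model for the light-response staircase: Phi_NO rises
# from its dark value (1 - Fv/Fm) to the genotype plateau, Phi_NPQ rises
# hyperbolically, capped so that Phi_II stays positive
staircase_yields <- function(preset, I) {
  phi_no <- preset$phi_no_plateau -
    (preset$phi_no_plateau - (1 - preset$FvFm)) * exp(-I / 60)
  phi_npq <- pmin(preset$phi_npq_max * I / (I + 150),
                  1 - phi_no - 0.02)
  list(phi_no = phi_no, phi_npq = pmax(phi_npq, 0))
}

#' Generate a synthetic dataset for one genotype
#'
#' Produces the input for one analysis, from a genotype preset:
#' \describe{
#'   \item{dcmu_induction}{DCMU fluorescence-induction trace, 0-2 s at 1 ms.}
#'   \item{pq_rise}{Untreated induction rise limited by the finite PQ pool,
#'     0-10 s at 5 ms.}
#'   \item{pam_session}{Light-response staircase (8 intensities, 25-1000
#'     umol photons m-2 s-1) with a dark-adapted pulse and one saturating
#'     pulse at the end of each step; used for Fv/Fm and yield partition.}
#'   \item{npq_protocol}{Two 8-min illumination periods at 1000 umol with
#'     8-min dark-relaxation windows, pulses every 30 s; used for NPQ
#'     kinetics and qE/qI decomposition.}
#'   \item{vaz_course}{Xanthophyll mole fractions over 8 min light + 8 min
#'     dark, sampled every 30 s.}
#'   \item{fvfm_course}{Fv/Fm photoinhibition decay over 6 h (time in
#'     hours), sampled every 0.25 h.}
#'   \item{ecs_curve}{Electrochromic-shift amplitudes at 8 irradiances
#'     from 25 to 1000 umol photons m-2 s-1.}
#' }
#'
#' @param preset A [make_preset()] result (or genotype name).
#' @param what Dataset kind (see Details).
#' @param seed Integer seed for the noise realization.
#' @param noise Relative noise standard deviation (0 = exact model curve).
#' @return A list with elements among `trace`, `protocol`, `profile`,
#'   `points`, plus `preset_name`.
#' @export
generate_dataset <- function(preset,
                             what = c("dcmu_induction", "pq_rise",
                                      "pam_session", "npq_protocol",
                                      "vaz_course", "fvfm_course",
                                      "ecs_curve"),
                             seed = 1L, noise = 0) {
  what <- match.arg(what)
  if (is.character(preset)) preset <- make_preset(preset)
  stopifnot(inherits(preset, "genotype_preset"))
  if (noise < 0) stop("noise must be >= 0")
  meta <- list(genotype = preset$name)
  out <- switch(
    what,
    dcmu_induction = {
      pars <- connectivity_params(preset$J, preset$k_ph, preset$F0,
                                  preset$Fv, preset$sigma_rel)
      tr <- simulate_dcmu_induction(pars, seq(0, 2, by = 1e-3),
                                    meta = c(meta, list(actinic = 7)))
      list(trace = tr)
    },
    pq_rise = {
      pars <- connectivity_params(preset$J, preset$k_ph, preset$F0,
                                  preset$Fv, preset$sigma_rel)
      pq <- pq_pool_params(preset$n_pq, preset$k_ox)
      tr <- simulate_pq_pool_rise(pars, pq, seq(0, 10, by = 5e-3),
                                  meta = c(meta, list(actinic = 7)))
      list(trace = tr)
    },
    pam_session = gen_pam_session(preset, meta),
    npq_protocol = gen_npq_protocol(preset, meta),
    vaz_course = {
      kin <- deepox_kinetics(preset$k_vd, preset$k_az, preset$k_ep)
      proto <- pulse_protocol(
        actinic = data.frame(start = 0, end = 480, intensity = 1000),
        pulses = numeric(0),
        dark = data.frame(start = 480, end = 960))
      prof <- simulate_vaz(kin, proto, seq(0, 960, by = 30),
                           meta = c(meta,
                                    list(vaz_per_100chl = preset$vaz_per_100chl)))
      list(profile = prof, protocol = proto)
    },
    fvfm_course = {
      tr <- simulate_fvfm_decay(preset$pi_y_init, preset$pi_plateau,
                                preset$pi_k, seq(0, 6, by = 0.25),
                                meta = c(meta, list(time_unit = "h",
                                                    actinic = 550,
                                                    temperature = "4C")))
      list(trace = tr)
    },
    ecs_curve = {
      I <- c(25, 50, 100, 200, 400, 600, 800, 1000)
      amp <- preset$pmf_amp_rel * I / (I + preset$pmf_I_half)
      list(points = data.frame(I = I, amplitude = amp))
    })
  if (noise > 0) {
    if (!is.null(out$trace)) out$trace <- add_noise(out$trace, noise, seed)
    if (!is.null(out$points))
      out$points$amplitude <- with_seed(seed, pmax(
        out$points$amplitude * (1 + stats::rnorm(nrow(out$points), 0, noise)), 0))
    if (!is.null(out$profile)) {
      d <- out$profile$data
      noisy <- with_seed(seed, as.matrix(d[c("V", "A", "Z")]) *
                           (1 + stats::rnorm(3 * nrow(d), 0, noise)))
      noisy <- pmax(noisy, 0)
      out$profile <- pigment_profile(d$time, noisy[, 1L], noisy[, 2L],
                                     noisy[, 3L], meta = out$profile$meta)
    }
  }
  out$preset_name <- preset$name
  out
}

# Fig-4-style session: dark-adapted pulse, then two light periods with
# interleaved dark-relaxation windows, pulses every 30 s
gen_npq_protocol <- function(preset, meta) {
  light <- 480; dark <- 480; lead <- 30
  segs <- data.frame(
    start = c(lead, lead + light + dark),
    end = c(lead + light, lead + 2 * light + dark),
    intensity = c(1000, 1000))
  darkw <- data.frame(
    start = c(lead + light, lead + 2 * light + dark),
    end = c(lead + light + dark, lead + 2 * (light + dark)))
  pulses <- c(15, unlist(lapply(seq_len(nrow(segs)), function(i)
    seq(segs$start[i] + 30, segs$end[i] + dark, by = 30))))
  pulses <- sort(pulses)
  proto <- pulse_protocol(segs, pulses, dark = darkw, pulse_duration = 0.8)

  tgrid <- seq(0, lead + 2 * (light + dark), by = 0.5)
  # NPQ(t) over the protocol phases (dark lead has NPQ = 0)
  phases <- rbind(
    data.frame(start = 0, end = segs$start[1L], intensity = 0),
    data.frame(start = segs$start[1L], end = segs$end[1L], intensity = 1000),
    data.frame(start = segs$end[1L], end = segs$start[2L], intensity = 0),
    data.frame(start = segs$start[2L], end = segs$end[2L], intensity = 1000),
    data.frame(start = segs$end[2L], end = tgrid[length(tgrid)], intensity = 0))
  npq <- npq_trajectory(preset, phases, tgrid)
  Fm <- preset$F0 + preset$Fv
  fmp <- Fm / (1 + npq)
  in_light <- vapply(tgrid, function(t)
    any(t >= segs$start & t < segs$end), logical(1))
  fs <- ifelse(in_light, (1 - preset$phi_ii_light) * fmp,
               pmin(preset$F0, fmp))
  value <- fs
  # overlay the saturating pulses: during a pulse the signal sits at the
  # maximal level frozen at pulse onset (Fm dark-adapted, Fm' otherwise) --
  # quenching does not relax within a sub-second pulse
  for (tp in proto$pulses) {
    w <- tgrid >= tp & tgrid <= tp + proto$pulse_duration
    npq_tp <- npq[which(w)[1L]]
    value[w] <- if (tp < segs$start[1L] && npq_tp < 1e-12) Fm
                else Fm / (1 + npq_tp)
  }
  tr <- fluor_trace(tgrid, value, kind = "pam",
                    meta = c(meta, list(actinic = 1000)))
  list(trace = tr, protocol = proto)
}

# light-response staircase for yield partitioning
gen_pam_session <- function(preset, meta) {
  I_steps <- c(25, 50, 100, 200, 400, 600, 800, 1000)
  step <- 60; lead <- 30
  segs <- data.frame(start = lead + (seq_along(I_steps) - 1L) * step,
                     end = lead + seq_along(I_steps) * step,
                     intensity = I_steps)
  pulses <- c(15, segs$end - 5)
  proto <- pulse_protocol(segs, pulses, pulse_duration = 0.8)
  tgrid <- seq(0, lead + length(I_steps) * step + 10, by = 0.5)

  Fm <- preset$F0 + preset$Fv
  value <- rep(preset$F0, length(tgrid))
  fs_of <- fmp_of <- rep(NA_real_, length(I_steps))
  yl <- staircase_yields(preset, I_steps)
  fs_of <- yl$phi_no * Fm
  fmp_of <- fs_of / (yl$phi_no + yl$phi_npq)
  for (i in seq_along(I_steps)) {
    w <- tgrid >= segs$start[i] & tgrid < segs$end[i]
    value[w] <- fs_of[i]
  }
  for (k in seq_along(pulses)) {
    tp <- pulses[k]
    w <- tgrid >= tp & tgrid <= tp + proto$pulse_duration
    value[w] <- if (k == 1L) Fm else fmp_of[k - 1L]
  }
  tr <- fluor_trace(tgrid, value, kind = "pam", meta = meta)
  list(trace = tr, protocol = proto)
}

#' Generate a synthetic antenna-content versus NPQ-integral panel
#'
#' Emulates a population of lines spanning a range of light-harvesting
#' complex contents whose NPQ definite integrals follow a logistic
#' dose-response; used to exercise [fit_sigmoid_lhc_npq()].
#'
#' @param n Number of lines (default 16).
#' @param lhc_range Range of LHC contents (nmol LHC per ug Chl).
#' @param coef Named list/vector with true `y0`, `a`, `x0`, `b`.
#' @param seed,noise Noise realization (relative sd on the integrals).
#' @return Data frame with columns `lhc`, `integral`.
#' @export
generate_lhc_npq_points <- function(n = 16,
                                    lhc_range = c(0.004, 0.028),
                                    coef = list(y0 = 150, a = 900,
                                                x0 = 0.014, b = 0.003),
                                    seed = 1L, noise = 0) {
  x <- seq(lhc_range[1L], lhc_range[2L], length.out = n)
  y <- coef$y0 + coef$a / (1 + exp(-(x - coef$x0) / coef$b))
  if (noise > 0)
    y <- with_seed(seed, pmax(y * (1 + stats::rnorm(n, 0, noise)), 0))
  data.frame(lhc = x, integral = y)
}

#' Write a generated dataset to a directory
#'
#' Writes the trace/profile, protocol and a provenance JSON (preset name,
#' seed, noise, field provenance) under `dir`.
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @param seed,noise Recorded in the provenance file.
#' @return Invisibly, the vector of files written.
#' @export
write_dataset <- function(dataset, dir, seed = NA, noise = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  if (!is.null(dataset$trace)) {
    f <- file.path(dir, "trace.csv")
    write_trace(dataset$trace, f); files <- c(files, f)
  }
  if (!is.null(dataset$profile)) {
    f <- file.path(dir, "pigments.csv")
    write_pigments(dataset$profile, f); files <- c(files, f)
  }
  if (!is.null(dataset$protocol)) {
    f <- file.path(dir, "protocol.json")
    write_protocol(dataset$protocol, f); files <- c(files, f)
  }
  if (!is.null(dataset$points)) {
    f <- file.path(dir, "points.csv")
    utils::write.csv(dataset$points, f, row.names = FALSE); files <- c(files, f)
  }
  prov <- list(preset = dataset$preset_name, seed = seed, noise = noise,
               provenance = as.list(preset_provenance(make_preset(dataset$preset_name))))
  f <- file.path(dir, "provenance.json")
  jsonlite::write_json(prov, f, auto_unbox = TRUE, digits = NA)
  invisible(c(files, f))
}
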