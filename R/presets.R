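# Genotype presets ------------------------------------------------------
#
# Each preset bundles the published phenotype of one PSII antenna genotype
# (connectivity, antenna size, quenching amplitudes, xanthophyll and
# photoinhibition kinetics, pmf saturation) together with per-field
# provenance: "measured" fields carry the literature value verbatim,
# "derived" fields are computed from measured ones at preset-build time,
# "assumed" fields are plausible placeholders the source does not pin down.

# Reference closure rate: the wild-type functional antenna size is
# 1/t_2/3 = 5.76e-3 ms^-1, i.e. t_2/3 = 173.6 ms; with J_WT = 2.05 the
# implicit closed form gives k_ph = kt(V = 2/3, J) / t_2/3.
.wt_inv_t23_ms <- 5.76e-3   # ms^-1, measured (WT)
.wt_J <- 2.05               # measured (WT)

.preset_rows <- list(
  WT = list(
    J = c(2.05, "measured"),
    FvFm = c(0.82, "measured"),
    F0_rel = c(1.0, "measured"),
    inv_t23_table = c(5.76e-3, "measured"),       # ms^-1
    sigma_rel = c(1.0, "measured (reference genotype)"),
    n_pq_ratio = c(1.0, "measured (reference genotype)"),
    qE = c(2.2, "measured"),
    qI = c(0.5, "assumed"),
    tau_fast = c(30, "assumed"), tau_slow = c(180, "assumed"),
    tau_relax = c(60, "assumed"),
    npq_max_rel = c(1.0, "measured (reference genotype)"),
    phi_no_plateau = c(0.28, "measured"),
    phi_npq_max = c(0.6, "measured"),
    di_end = c(0.3, "measured"),
    vaz_per_100chl = c(5.2, "measured"),
    pi_t_half = c(NA, "derived (from 6-h endpoint)"),
    pi_endpoint_frac = c(0.8, "measured"),
    pi_plateau = c(0, "assumed"),
    pmf_amp_rel = c(1.0, "measured (reference genotype)"),
    pmf_I_half = c(100, "measured"),
    psbs_rel = c(1.0, "measured (reference genotype)"),
    chl_ab = c(3.51, "measured")),
  npq4 = list(
    J = c(2.05, "assumed (antenna-intact, WT-like)"),
    FvFm = c(0.82, "assumed (WT-like)"),
    F0_rel = c(1.0, "assumed (WT-like)"),
    inv_t23_table = c(5.76e-3, "assumed (WT-like)"),
    sigma_rel = c(1.0, "assumed (WT-like)"),
    n_pq_ratio = c(1.0, "assumed"),
    qE = c(0.0, "measured (PsbS null: no energy quenching)"),
    qI = c(0.6, "assumed (slowest dark recovery)"),
    tau_fast = c(30, "assumed"), tau_slow = c(240, "assumed"),
    tau_relax = c(60, "assumed"),
    npq_max_rel = c(NA, "derived"),
    phi_no_plateau = c(0.35, "assumed"),
    phi_npq_max = c(0.15, "assumed"),
    di_end = c(0.3, "assumed (xanthophyll cycle intact)"),
    vaz_per_100chl = c(5.2, "assumed (WT-like)"),
    pi_t_half = c(1.7, "assumed"),
    pi_endpoint_frac = c(NA, "derived"),
    pi_plateau = c(0.1, "assumed"),
    pmf_amp_rel = c(1.0, "assumed"),
    pmf_I_half = c(100, "measured (common to all genotypes)"),
    psbs_rel = c(0.0, "measured (knockout)"),
    chl_ab = c(3.40, "measured")),
  NoM = list(
    J = c(0.79, "measured"),
    FvFm = c(0.61, "measured"),
    F0_rel = c(3.23, "measured"),
    inv_t23_table = c(10.70e-3, "measured"),
    sigma_rel = c(1.9, "measured"),
    n_pq_ratio = c(6.0, "measured (PQ per RC ~6x WT)"),
    qE = c(1.5, "assumed (residual, slowly activated)"),
    qI = c(0.5, "assumed"),
    tau_fast = c(90, "assumed (slow activation)"),
    tau_slow = c(180, "assumed"), tau_relax = c(60, "assumed"),
    npq_max_rel = c(NA, "derived"),
    phi_no_plateau = c(0.3, "assumed"),
    phi_npq_max = c(0.6, "measured"),
    di_end = c(0.3, "assumed"),
    vaz_per_100chl = c(5.2, "assumed (WT-like)"),
    pi_t_half = c(1.4, "measured"),
    pi_endpoint_frac = c(NA, "derived"),
    pi_plateau = c(0.1, "assumed"),
    pmf_amp_rel = c(0.9, "assumed"),
    pmf_I_half = c(100, "measured (common to all genotypes)"),
    psbs_rel = c(1.0, "assumed"),
    chl_ab = c(3.28, "measured")),
  koLHCII = list(
    J = c(1.76, "measured"),
    FvFm = c(0.76, "measured"),
    F0_rel = c(2.13, "measured"),
    inv_t23_table = c(2.47e-3, "measured"),
    sigma_rel = c(0.55, "measured"),
    n_pq_ratio = c(1.0, "measured (PQ/RC equal to WT)"),
    qE = c(0.8, "measured"),
    qI = c(0.5, "assumed (no substantial increase)"),
    tau_fast = c(30, "assumed"), tau_slow = c(180, "assumed"),
    tau_relax = c(60, "assumed"),
    npq_max_rel = c(NA, "derived"),
    phi_no_plateau = c(0.6, "measured"),
    phi_npq_max = c(0.42, "measured (0.4-0.45)"),
    di_end = c(0.3, "measured (similar to WT)"),
    vaz_per_100chl = c(7.6, "measured"),
    pi_t_half = c(1.9, "measured"),
    pi_endpoint_frac = c(NA, "derived"),
    pi_plateau = c(0.1, "assumed"),
    pmf_amp_rel = c(0.80, "measured (-20%)"),
    pmf_I_half = c(100, "measured (common to all genotypes)"),
    psbs_rel = c(0.5, "measured (-50%)"),
    chl_ab = c(5.23, "measured")),
  koLhcb = list(
    J = c(0.60, "measured"),
    FvFm = c(0.54, "measured"),
    F0_rel = c(5.46, "measured"),
    inv_t23_table = c(1.74e-3, "measured"),
    sigma_rel = c(0.25, "measured"),
    n_pq_ratio = c(1.0, "assumed"),
    qE = c(0.45, "assumed (split of the 22%-of-WT amplitude)"),
    qI = c(NA, "derived (from npq_max_rel constraint)"),
    tau_fast = c(120, "assumed (much slower rise)"),
    tau_slow = c(180, "assumed"), tau_relax = c(60, "assumed"),
    npq_max_rel = c(0.22, "measured (22% of WT)"),
    phi_no_plateau = c(0.8, "measured"),
    phi_npq_max = c(0.2, "measured"),
    di_end = c(0.5, "measured"),
    vaz_per_100chl = c(9.4, "measured"),
    pi_t_half = c(1.0, "assumed"),
    pi_endpoint_frac = c(NA, "derived"),
    pi_plateau = c(0.1, "assumed"),
    pmf_amp_rel = c(0.65, "measured (-35%)"),
    pmf_I_half = c(100, "measured (common to all genotypes)"),
    psbs_rel = c(0.83, "measured (-14 to -20%)"),
    chl_ab = c(6.14, "measured")),
  lowLHCII = list(
    J = c(1.76, "assumed (koLHCII-like PSII/LHC stoichiometry)"),
    FvFm = c(0.76, "assumed (koLHCII-like)"),
    F0_rel = c(2.13, "assumed (koLHCII-like)"),
    inv_t23_table = c(2.47e-3, "assumed (koLHCII-like)"),
    sigma_rel = c(0.55, "assumed (koLHCII-like)"),
    n_pq_ratio = c(1.0, "assumed"),
    qE = c(1.0, "assumed (NPQ above koLHCII)"),
    qI = c(0.5, "assumed"),
    tau_fast = c(30, "assumed"), tau_slow = c(180, "assumed"),
    tau_relax = c(60, "assumed"),
    npq_max_rel = c(NA, "derived"),
    phi_no_plateau = c(0.5, "assumed"),
    phi_npq_max = c(0.45, "assumed"),
    di_end = c(0.3, "assumed"),
    vaz_per_100chl = c(7.6, "assumed (koLHCII-like)"),
    pi_t_half = c(1.1, "measured"),
    pi_endpoint_frac = c(NA, "derived"),
    pi_plateau = c(0.1, "assumed"),
    pmf_amp_rel = c(0.8, "assumed (koLHCII-like)"),
    pmf_I_half = c(100, "measured (common to all genotypes)"),
    psbs_rel = c(1.0, "assumed"),
    chl_ab = c(5.2, "assumed")))

# physical constants of the synthetic models (shared across genotypes)
.preset_shared <- list(
  n_pq_base = c(14.0, "assumed (~7 PQ per PSII x 2 electron equivalents, WT)"),
  k_ox = c(300, "assumed (ms-scale QA- reoxidation by oxidized PQ)"),
  vaz_k_ratio = c(0.5, "assumed (k_az / k_vd)"),
  vaz_k_ep = c(1 / 600, "assumed (dark epoxidation, tau = 10 min)"),
  phi_ii_light = c(0.3, "assumed (steady-state PSII yield at 1000 umol)"),
  pi_span_h = c(6, "measured (6-h photoinhibitory treatment)"),
  di_light_s = c(480, "measured (8-min light phase)"))

#' Available genotype presets
#' @return Character vector of preset names.
#' @export
preset_names <- function() names(.preset_rows)

#' Build the parameter bundle for one genotype
#'
#' Returns the shipped preset for a genotype: measured phenotype values
#' plus derived model parameters (closure rate `k_ph`, variable
#' fluorescence `Fv`, xanthophyll rates solved so that the simulated
#' end-of-light de-epoxidation index equals the measured endpoint,
#' photoinhibition decay rate from the half-time or 6-h endpoint, and -- for
#' genotypes whose NPQ is specified relative to the wild type -- the
#' sustained-quenching amplitude solved from that constraint). The
#' `provenance` element names the source status of every numeric field.
#'
#' @param genotype One of `preset_names()`.
#' @return Object of class `genotype_preset`.
#' @examples
#' p <- make_preset("WT")
#' p$J        # 2.05
#' p$FvFm     # 0.82
#' @export
make_preset <- function(genotype) {
  if (!genotype %in% names(.preset_rows))
    stop("unknown genotype '", genotype, "'; available: ",
         paste(names(.preset_rows), collapse = ", "))
  row <- .preset_rows[[genotype]]
  val <- lapply(row, function(x) as.numeric(x[[1L]]))
  prov <- vapply(row, function(x) x[[2L]], character(1))
  for (k in names(.preset_shared)) {
    val[[k]] <- as.numeric(.preset_shared[[k]][[1L]])
    prov[[k]] <- .preset_shared[[k]][[2L]]
  }

  # closure rate anchored to the WT antenna size and scaled by the relative
  # optical cross-section (same irradiance for all genotypes)
  t23_wt <- 1e-3 / .wt_inv_t23_ms                   # s
  k_wt <- kt_at_V(2 / 3, .wt_J) / t23_wt            # s^-1
  val$k_ph <- k_wt * val$sigma_rel
  prov[["k_ph"]] <- "derived (WT antenna size x sigma_rel)"

  # fluorescence levels: F0 from the normalized minimal-fluorescence
  # column, Fv from Fv/Fm
  val$F0 <- val$F0_rel
  prov[["F0"]] <- "derived (equals F0_rel)"
  val$Fv <- val$F0 * val$FvFm / (1 - val$FvFm)
  prov[["Fv"]] <- "derived (from F0 and Fv/Fm)"

  # PQ pool per RC
  val$n_pq <- val$n_pq_base * val$n_pq_ratio
  prov[["n_pq"]] <- "derived (n_pq_base x n_pq_ratio)"

  # NPQ amplitudes: when the preset pins the maximal NPQ relative to WT,
  # solve the sustained component from that constraint
  npq_at <- function(qE, qI, tf, ts, t) {
    qE * (1 - exp(-t / tf)) + qI * (1 - exp(-t / ts))
  }
  wt <- .preset_rows$WT
  wt_npq_end <- npq_at(as.numeric(wt$qE[[1L]]), as.numeric(wt$qI[[1L]]),
                       as.numeric(wt$tau_fast[[1L]]),
                       as.numeric(wt$tau_slow[[1L]]), 480)
  if (is.na(val$qI) && !is.na(val$npq_max_rel)) {
    target <- val$npq_max_rel * wt_npq_end
    val$qI <- (target - val$qE * (1 - exp(-480 / val$tau_fast))) /
      (1 - exp(-480 / val$tau_slow))
    if (val$qI < 0) stop("inconsistent NPQ constraint for ", genotype)
    prov[["qI"]] <- "derived (npq_max_rel constraint)"
  }
  if (is.na(val$npq_max_rel)) {
    val$npq_max_rel <- npq_at(val$qE, val$qI, val$tau_fast, val$tau_slow,
                              480) / wt_npq_end
    prov[["npq_max_rel"]] <- "derived (from amplitudes)"
  }

  # xanthophyll rates: forward rate solved so the simulated DI at the end
  # of the light phase matches the measured endpoint (A -> Z rate tied to
  # the V -> A rate by vaz_k_ratio)
  val$k_vd <- solve_kvd(val$di_end, val$vaz_k_ratio, val$di_light_s)
  prov[["k_vd"]] <- "derived (matches end-of-light DI)"
  val$k_az <- val$vaz_k_ratio * val$k_vd
  prov[["k_az"]] <- "derived (vaz_k_ratio x k_vd)"
  val$k_ep <- val$vaz_k_ep
  prov[["k_ep"]] <- prov[["vaz_k_ep"]]

  # photoinhibition: decay rate from the half-time where measured,
  # otherwise from the 6-h endpoint fraction
  val$pi_y_init <- val$FvFm
  prov[["pi_y_init"]] <- "derived (equals dark-adapted Fv/Fm)"
  if (is.na(val$pi_t_half)) {
    # endpoint fraction f of the initial value after T hours, plateau y_p:
    # y_p + (y0 - y_p) exp(-kT) = f y0
    y0 <- val$pi_y_init; yp <- val$pi_plateau; f <- val$pi_endpoint_frac
    k <- -log((f * y0 - yp) / (y0 - yp)) / val$pi_span_h
    val$pi_k <- k
    prov[["pi_k"]] <- "derived (from 6-h endpoint)"
    val$pi_t_half <- log(2) / k
    prov[["pi_t_half"]] <- "derived (ln2 / pi_k)"
  } else {
    val$pi_k <- log(2) / val$pi_t_half
    prov[["pi_k"]] <- "derived (ln2 / t_half)"
    y0 <- val$pi_y_init; yp <- val$pi_plateau
    val$pi_endpoint_frac <- (yp + (y0 - yp) * exp(-val$pi_k * val$pi_span_h)) / y0
    prov[["pi_endpoint_frac"]] <- "derived (model endpoint)"
  }

  structure(c(list(name = genotype), val, list(provenance = prov)),
            class = "genotype_preset")
}

# solve the forward de-epoxidation rate so that the all-forward chain
# starting from pure violaxanthin reaches the target DI at time t_end
solve_kvd <- function(di_target, ratio, t_end) {
  di_at <- function(k1) {
    kin <- deepox_kinetics(k1, ratio * k1, 0)
    Q <- vaz_generator(kin, light = TRUE)
    s <- as.numeric(as.matrix(Matrix::expm(Q * t_end)) %*% c(1, 0, 0))
    deepoxidation_index(s[1L], s[2L], s[3L])
  }
  stats::uniroot(function(k) di_at(k) - di_target,
                 interval = c(1e-7, 1), tol = 1e-12)$root
}

#' @export
print.genotype_preset <- function(x, ...) {
  cat(sprintf("<genotype_preset> %s: J=%.3g, Fv/Fm=%.3g, sigma_rel=%.3g, qE=%.3g, DI_end=%.3g, t_1/2(PI)=%.3g h\n",
              x$name, x$J, x$FvFm, x$sigma_rel, x$qE, x$di_end, x$pi_t_half))
  invisible(x)
}

#' Preset field provenance
#'
#' @param preset A [make_preset()] result.
#' @return Named character vector mapping each numeric field to its source
#'   status (measured / derived / assumed).
#' @export
preset_provenance <- function(preset) {
  stopifnot(inherits(preset, "genotype_preset"))
  preset$provenance
}
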