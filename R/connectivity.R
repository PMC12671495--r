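#' Connected-units fluorescence-induction model
#'
#' In the Joliot connected-units picture, excitation can hop between PSII
#' units, so variable fluorescence is a hyperbolic (sigmoidal in time)
#' function of the fraction of closed reaction centers C rather than a
#' linear one. With inter-unit transfer probability `p = J/(1+J)`:
#'
#'   V(C) = (1 - p) C / (1 - p C)
#'
#' and closure under continuous illumination with DCMU (no reoxidation of
#' the reduced quinone acceptor) obeys
#'
#'   dC/dt = k_ph (1 - C) / (1 - p C),  C(0) = 0
#'
#' whose implicit solution is `k_ph t = -(1-p) log(1-C) + p C`. `J = 0`
#' recovers the unconnected ("puddle") exponential limit `V = 1 - exp(-k t)`.
#'
#' @param C Fraction of closed PSII reaction centers, in `[0, 1]`.
#' @param J Connectivity parameter, `>= 0`. The transfer probability
#'   parameterization `p` is available via [p_from_J()]/[J_from_p()].
#' @return `vf_from_closed`: relative variable fluorescence V in `[0, 1]`.
#' @seealso [simulate_dcmu_induction()], [fit_dcmu_induction()]
#' @examples
#' vf_from_closed(0.5, J = 1)   # 1/3
#' closed_from_vf(vf_from_closed(0.3, 2), 2)  # 0.3
#' @export
vf_from_closed <- function(C, J) {
  check_CJ(C, J)
  p <- J / (1 + J)
  (1 - p) * C / (1 - p * C)
}

#' @rdname vf_from_closed
#' @param V Relative variable fluorescence in `[0, 1]`.
#' @return `closed_from_vf`: the closed fraction C, inverse of
#'   `vf_from_closed` at the same J.
#' @export
closed_from_vf <- function(V, J) {
  check_CJ(V, J)
  p <- J / (1 + J)
  V / (1 - p + p * V)
}

check_CJ <- function(C, J) {
  if (any(!is.finite(C)) || any(C < 0) || any(C > 1))
    stop("closed fraction / V must lie in [0, 1]")
  if (any(!is.finite(J)) || any(J < 0))
    stop("connectivity J must be >= 0")
  invisible(NULL)
}

#' Convert between connectivity J and transfer probability p
#' @param J Connectivity (`>= 0`).
#' @param p Inter-unit transfer probability in `[0, 1)`.
#' @return The other parameterization of the same hyperbola.
#' @export
p_from_J <- function(J) {
  if (any(J < 0)) stop("J must be >= 0")
  J / (1 + J)
}

#' @rdname p_from_J
#' @export
J_from_p <- function(p) {
  if (any(p < 0 | p >= 1)) stop("p must lie in [0, 1)")
  p / (1 - p)
}

#' Parameter bundle for the connected-units induction model
#'
#' @param J Connectivity (dimensionless, `>= 0`).
#' @param k_ph Photochemical closure rate at C = 0 (s^-1); proportional to
#'   optical cross-section times irradiance.
#' @param F0 Minimal fluorescence (relative units, `>= 0`).
#' @param Fv Variable fluorescence (relative units, `> 0`).
#' @param sigma_rel Optical cross-section relative to a reference genotype.
#' @return Object of class `connectivity_params`.
#' @export
connectivity_params <- function(J, k_ph, F0 = 0, Fv = 1, sigma_rel = 1) {
  if (J < 0) stop("J must be >= 0")
  if (k_ph <= 0) stop("k_ph must be > 0")
  if (Fv <= 0) stop("Fv must be > 0")
  if (F0 < 0) stop("F0 must be >= 0")
  structure(list(J = J, p = p_from_J(J), k_ph = k_ph, F0 = F0, Fv = Fv,
                 sigma_rel = sigma_rel),
            class = "connectivity_params")
}

#' @export
print.connectivity_params <- function(x, ...) {
  cat(sprintf("<connectivity_params> J=%.4g (p=%.4g), k_ph=%.4g s-1, F0=%.4g, Fv=%.4g\n",
              x$J, x$p, x$k_ph, x$F0, x$Fv))
  invisible(x)
}

# Solve the implicit closure equation k t = -(1-p) log(1-C) + p C for C,
# vectorized over t by bisection. g(C) is strictly increasing on [0, 1), so
# 90 halvings pin C to ~1e-27 — far below the 1e-12 round-trip tolerance.
closure_fraction <- function(t, k_ph, J) {
  p <- p_from_J(J)
  tau <- k_ph * t
  lo <- rep(0, length(tau))
  hi <- rep(1 - 1e-16, length(tau))
  for (i in 1:90) {
    mid <- (lo + hi) / 2
    g <- -(1 - p) * log1p(-mid) + p * mid
    below <- g < tau
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  out <- (lo + hi) / 2
  out[t <= 0] <- 0
  out
}

#' Simulate a DCMU fluorescence-induction trace
#'
#' Generates `F(t) = F0 + Fv * V(C(t))` on the given time grid, with `C(t)`
#' obtained from the implicit closed form of the closure kinetics by guarded
#' bisection (monotone, cannot fail for valid inputs).
#'
#' @param params A [connectivity_params()].
#' @param t_grid Increasing time grid starting at 0 (seconds).
#' @param meta Extra metadata stored on the trace.
#' @return A [fluor_trace()] of kind `"induction"` with `dcmu = TRUE`.
#' @export
simulate_dcmu_induction <- function(params, t_grid, meta = list()) {
  stopifnot(inherits(params, "connectivity_params"))
  if (t_grid[1L] < 0 || any(diff(t_grid) <= 0))
    stop("t_grid must be increasing and start at >= 0")
  C <- closure_fraction(t_grid, params$k_ph, params$J)
  F <- params$F0 + params$Fv * vf_from_closed(C, params$J)
  fluor_trace(t_grid, F, kind = "induction",
              meta = utils::modifyList(list(dcmu = TRUE), as.list(meta)))
}

#' Fit the connected-units model to a DCMU induction trace
#'
#' Least-squares estimation of `(J, k_ph, F0, Fv)` by Levenberg-Marquardt,
#' initialized from a coarse grid over J with `k_ph` matched to the observed
#' two-thirds rise time. Also reports the two-thirds time of the fitted
#' curve and its reciprocal (the functional antenna size).
#'
#' @param trace A [fluor_trace()] spanning the F0 plateau through the Fm
#'   plateau.
#' @param init Optional [connectivity_params()] used as starting values
#'   instead of the automatic initialization.
#' @return Object of class `induction_fit`: list with `params`
#'   ([connectivity_params()]), `rss`, `se` (per-parameter standard errors
#'   where available), `t23`, `inv_t23`, `fitted` (trace of fitted values),
#'   `convergence`.
#' @export
fit_dcmu_induction <- function(trace, init = NULL) {
  stopifnot(inherits(trace, "fluor_trace"))
  t <- trace$time
  y <- trace$value
  F0_0 <- min(y)
  Fm_0 <- max(y)
  Fv_0 <- Fm_0 - F0_0
  if (Fv_0 <= 0) stop("fit failure: trace has no variable fluorescence")
  # observed two-thirds time for rate initialization
  t23_obs <- two_thirds_time_num(t, (y - F0_0) / Fv_0)

  model <- function(J, k_ph, F0, Fv)
    F0 + Fv * vf_from_closed(closure_fraction(t, k_ph, J), J)

  if (is.null(init)) {
    # coarse grid over J; k from matching the observed t_2/3
    Js <- c(0, 0.25, 0.5, 1, 1.5, 2, 3, 5, 8)
    best <- NULL
    for (J in Js) {
      k <- kt_at_V(2 / 3, J) / t23_obs
      rss <- sum((y - model(J, k, F0_0, Fv_0))^2)
      if (is.null(best) || rss < best$rss)
        best <- list(J = J, k = k, rss = rss)
    }
    start <- list(J = max(best$J, 1e-3), k_ph = best$k, F0 = F0_0, Fv = Fv_0)
  } else {
    start <- list(J = max(init$J, 1e-3), k_ph = init$k_ph,
                  F0 = init$F0, Fv = init$Fv)
  }

  df <- data.frame(t = t, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ F0 + Fv * vf_from_closed(closure_fraction(t, k_ph, J), J),
      data = df, start = start,
      lower = c(J = 0, k_ph = 1e-8, F0 = 0, Fv = 1e-8),
      upper = c(J = 10, k_ph = Inf, F0 = Inf, Fv = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) stop("fit failure: ", conditionMessage(e)))

  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4))
  pars <- connectivity_params(cf[["J"]], cf[["k_ph"]], cf[["F0"]], cf[["Fv"]])
  # fitted-curve two-thirds time (closed form at the estimates)
  t23 <- kt_at_V(2 / 3, pars$J) / pars$k_ph
  Fm_hat <- pars$F0 + pars$Fv
  if (max(y) < pars$F0 + 0.95 * pars$Fv)
    warning("truncated induction: trace does not reach 95% of fitted Fm")
  structure(list(params = pars, rss = sum(stats::resid(fit)^2), se = se,
                 t23 = t23, inv_t23 = 1 / t23,
                 Fm = Fm_hat,
                 fitted = fluor_trace(t, stats::fitted(fit), kind = "induction",
                                      meta = trace$meta),
                 convergence = fit$convInfo$isConv %||% TRUE),
            class = "induction_fit")
}

#' @export
print.induction_fit <- function(x, ...) {
  cat(sprintf(
    "<induction_fit> J=%.4g, k_ph=%.4g s-1, F0=%.4g, Fv=%.4g | t_2/3=%.4g s (1/t_2/3=%.4g s-1), RSS=%.3g\n",
    x$params$J, x$params$k_ph, x$params$F0, x$params$Fv, x$t23, x$inv_t23, x$rss))
  invisible(x)
}

# k_ph * t at which V reaches level v, from the implicit closed form
kt_at_V <- function(v, J) {
  C <- closed_from_vf(v, J)
  p <- p_from_J(J)
  -(1 - p) * log1p(-C) + p * C
}

# earliest linear-interpolated crossing of `level` by a normalized signal
two_thirds_time_num <- function(t, v, level = 2 / 3) {
  above <- v >= level
  if (!any(above)) stop("level ", signif(level, 3), " never reached")
  i <- which(above)[1L]
  if (i == 1L) return(t[1L])
  t[i - 1L] + (level - v[i - 1L]) / (v[i] - v[i - 1L]) * (t[i] - t[i - 1L])
}

#' Two-thirds rise time and functional antenna size
#'
#' Normalizes the trace to `(F - F0)/(Fm - F0)` with `F0 = min`, `Fm = max`,
#' and returns the earliest time at which the normalized rise crosses 2/3
#' (linear interpolation between bracketing samples) together with its
#' reciprocal, the conventional functional-antenna-size measure.
#'
#' @param trace A [fluor_trace()] covering the full rise.
#' @return List with `t23` (s) and `inv_t23` (s^-1).
#' @export
two_thirds_antenna_size <- function(trace) {
  stopifnot(inherits(trace, "fluor_trace"))
  v <- (trace$value - min(trace$value)) /
    (max(trace$value) - min(trace$value))
  # Fm must be identifiable: the rise has to flatten within the record
  # (compare the medians of the last two 10%-of-span windows; noise-robust)
  span <- diff(range(trace$time))
  w1 <- v[trace$time >= trace$time[1L] + 0.8 * span &
            trace$time < trace$time[1L] + 0.9 * span]
  w2 <- v[trace$time >= trace$time[1L] + 0.9 * span]
  if (stats::median(w2) - stats::median(w1) > 0.02)
    stop("2/3 level never reached reliably: no Fm plateau within the record")
  t23 <- two_thirds_time_num(trace$time, v)
  list(t23 = t23, inv_t23 = 1 / t23)
}

#' Relative optical cross-section by equal-complementary-area rescaling
#'
#' Both traces are normalized to variable fluorescence,
#' `V = (F - F0)/(Fm - F0)`. For the connected-units model the area above
#' the normalized curve, `integral of (1 - V) dt`, equals `1/k_ph` exactly
#' and independently of J, so the time-scale factor that equalizes the
#' complementary areas of test and reference is the ratio of their closure
#' rates — i.e. the optical cross-section of the test genotype relative to
#' the reference (same irradiance). A factor < 1 means a smaller antenna.
#'
#' Normalization levels (F0, Fv) are taken from a connected-units fit of
#' each trace rather than from the observed extremes, and the complementary
#' area beyond the recorded span is completed with the fitted model's
#' analytic tail; this removes the downward bias that truncated records
#' (slow genotypes not fully saturated within the sweep) would otherwise
#' introduce.
#'
#' @param trace Test-genotype DCMU induction trace.
#' @param reference Reference (e.g. wild-type) DCMU induction trace.
#' @param shape_threshold Relative RMS discrepancy between the rescaled test
#'   curve and the reference above which a shape mismatch (differing J) is
#'   flagged.
#' @return List with `factor` (relative cross-section), `t06_ratio`
#'   (diagnostic time-scale ratio at the V = 0.6 crossing),
#'   `shape_discrepancy` (RMS difference of the rescaled curves),
#'   `shape_flag`, and the two double-normalized traces (`test_scaled`,
#'   `reference_norm`) with time axes such that the areas match.
#' @export
cross_section_rescale <- function(trace, reference, shape_threshold = 0.02) {
  stopifnot(inherits(trace, "fluor_trace"), inherits(reference, "fluor_trace"))
  norm_v <- function(tr) {
    fit <- fit_dcmu_induction(tr)
    v <- pmin(pmax((tr$value - fit$params$F0) / fit$params$Fv, 0), 1)
    # analytic completion of the complementary area beyond the record:
    # integral from t_end to Inf of (1 - V) dt = (1 - C_end) / k_ph
    t_end <- tr$time[length(tr$time)]
    C_end <- closure_fraction(t_end, fit$params$k_ph, fit$params$J)
    list(t = tr$time, v = v,
         area = pracma::trapz(tr$time, 1 - v) + (1 - C_end) / fit$params$k_ph)
  }
  a <- norm_v(trace)
  b <- norm_v(reference)
  area_test <- a$area
  area_ref <- b$area
  factor <- area_ref / area_test
  t06_ratio <- two_thirds_time_num(b$t, b$v, 0.6) /
    two_thirds_time_num(a$t, a$v, 0.6)
  # shape check: compare rescaled test V(t) with reference V(t) on the
  # reference grid
  v_interp <- stats::approx(a$t * factor, a$v, xout = b$t, rule = 2)$y
  shape <- sqrt(mean((v_interp - b$v)^2))
  structure(list(
    factor = factor,
    t06_ratio = t06_ratio,
    shape_discrepancy = shape,
    shape_flag = shape > shape_threshold,
    test_scaled = fluor_trace(a$t * factor, a$v, kind = "induction",
                              meta = trace$meta, strict = FALSE),
    reference_norm = fluor_trace(b$t, b$v, kind = "induction",
                                 meta = reference$meta, strict = FALSE)),
    class = "cross_section_rescale")
}

#' @export
print.cross_section_rescale <- function(x, ...) {
  cat(sprintf("<cross_section_rescale> factor=%.4g (V=0.6 diagnostic %.4g)%s\n",
              x$factor, x$t06_ratio,
              if (x$shape_flag) sprintf(", shape mismatch (RMS %.3g)",
                                        x$shape_discrepancy) else ""))
  invisible(x)
}

#' Plastoquinone-pool parameters for untreated induction rises
#'
#' @param n_pq Oxidized plastoquinone (electron-equivalent) capacity per
#'   active PSII reaction center (`> 0`).
#' @param k_ox Rate constant of reduced-acceptor reoxidation by the oxidized
#'   pool (s^-1, `>= 0`).
#' @return Object of class `pq_pool_params`.
#' @export
pq_pool_params <- function(n_pq, k_ox) {
  if (n_pq <= 0) stop("n_pq must be > 0")
  if (k_ox < 0) stop("k_ox must be >= 0")
  structure(list(n_pq = n_pq, k_ox = k_ox), class = "pq_pool_params")
}

#' Simulate an untreated (no-DCMU) fluorescence rise
#'
#' Minimal two-pool kinetics: closed-center fraction C is driven by
#' photochemistry as in the DCMU model but reopened by electron transfer to
#' a finite oxidized plastoquinone pool q (fraction of its capacity `n_pq`):
#'
#'   dC/dt = k_ph (1-C)/(1 - p C) - k_ox C q
#'   dq/dt = -k_ox C q / n_pq
#'
#' Fluorescence rises to Fm as the pool fills. With `k_ox = 0` or
#' `n_pq -> 0` the DCMU curve is recovered.
#'
#' @param params A [connectivity_params()].
#' @param pq A [pq_pool_params()].
#' @param t_grid Increasing time grid (seconds) starting at 0.
#' @param meta Extra trace metadata.
#' @return A [fluor_trace()] of kind `"induction"` with `dcmu = FALSE`.
#' @export
simulate_pq_pool_rise <- function(params, pq, t_grid, meta = list()) {
  stopifnot(inherits(params, "connectivity_params"),
            inherits(pq, "pq_pool_params"))
  p <- params$p
  rhs <- function(t, state, parms) {
    C <- min(max(state[1L], 0), 1)
    q <- min(max(state[2L], 0), 1)
    flux <- pq$k_ox * C * q
    dC <- params$k_ph * (1 - C) / (1 - p * C) - flux
    dq <- -flux / pq$n_pq
    list(c(dC, dq))
  }
  sol <- deSolve::lsoda(c(C = 0, q = 1), times = t_grid, func = rhs,
                        parms = NULL, rtol = 1e-10, atol = 1e-12)
  C <- pmin(pmax(sol[, "C"], 0), 1)
  if (any(!is.finite(C))) stop("non-finite integration in PQ-pool model")
  F <- params$F0 + params$Fv * vf_from_closed(C, params$J)
  fluor_trace(t_grid, F, kind = "induction",
              meta = utils::modifyList(list(dcmu = FALSE), as.list(meta)))
}

#' Fluorescence-rise slowdown and PQ-pool-per-RC ratio
#'
#' Measures how much slower the test genotype's untreated fluorescence rise
#' is than the reference's (ratio of times at which the normalized variable
#' fluorescence crosses `level`), and combines it with a known relative
#' optical cross-section: since the rise rate of the untreated curve is set
#' by cross-section while its duration is set by the plastoquinone pool, the
#' product `sigma_ratio * slowdown` estimates the fold-difference in PQ pool
#' size per active reaction center. A nominal value following the
#' round-half-to-even convention on the slowdown is reported alongside the
#' raw product.
#'
#' @param trace,reference Untreated (no-DCMU) rise traces, test and
#'   reference genotype.
#' @param sigma_ratio Relative optical cross-section (test / reference).
#' @param level Normalized fluorescence level used for timing (default 0.6).
#' @return List with `slowdown`, `pq_per_rc_ratio` (raw product),
#'   `pq_per_rc_nominal` (product using the rounded slowdown, itself rounded
#'   to the nearest integer).
#' @export
slowdown_and_pq_ratio <- function(trace, reference, sigma_ratio, level = 0.6) {
  stopifnot(sigma_ratio > 0)
  tt <- function(tr) {
    v <- (tr$value - min(tr$value)) / (max(tr$value) - min(tr$value))
    two_thirds_time_num(tr$time, v, level)
  }
  slowdown <- tt(trace) / tt(reference)
  raw <- sigma_ratio * slowdown
  nominal <- round(sigma_ratio * round(slowdown))
  list(slowdown = slowdown, pq_per_rc_ratio = raw,
       pq_per_rc_nominal = nominal)
}
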