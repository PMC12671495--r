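#' Extract per-pulse fluorescence levels from a PAM trace
#'
#' Standard saturating-pulse bookkeeping: the dark-adapted minimal level F0
#' is the median of the pre-actinic baseline (pulse windows excluded), the
#' dark-adapted maximal level Fm is the maximum within the first pulse
#' window, and for each pulse Fm' is the maximum within the pulse window and
#' Fs the median of the second preceding the pulse. Windows are derived from
#' the protocol's pulse times and pulse duration, which makes the extraction
#' robust to moderate timing jitter.
#'
#' @param trace A [fluor_trace()] of kind `"pam"`.
#' @param protocol A [pulse_protocol()] listing the pulses; a dark-adapted
#'   segment (with at least one pulse) must precede the first actinic
#'   segment.
#' @return Object of class `quench_series`: list with `F0`, `Fm`, `FvFm`,
#'   and data frame `pulses` (`t`, `Fs`, `Fm_prime`).
#' @export
extract_pulse_levels <- function(trace, protocol) {
  stopifnot(inherits(trace, "fluor_trace"), inherits(protocol, "pulse_protocol"))
  t <- trace$time
  y <- trace$value
  dur <- protocol$pulse_duration
  pulses <- protocol$pulses
  if (!length(pulses)) stop("protocol lists no pulses")
  in_pulse <- function(tp) t >= tp - 0.1 & t <= tp + dur + 0.1
  act_start <- if (nrow(protocol$actinic)) min(protocol$actinic$start) else Inf

  # baseline: before the actinic light, outside any pulse window
  base_idx <- t < act_start
  for (tp in pulses) base_idx <- base_idx & !in_pulse(tp)
  if (!any(base_idx)) stop("no dark-adapted baseline samples before actinic light")
  F0 <- stats::median(y[base_idx])

  w1 <- in_pulse(pulses[1L])
  if (!any(w1)) stop("first pulse window contains no samples")
  Fm <- max(y[w1])

  recs <- lapply(pulses, function(tp) {
    w <- in_pulse(tp)
    if (!any(w)) stop(sprintf("pulse window at t=%g s contains no samples", tp))
    pre <- t >= tp - 1.1 & t < tp - 0.1
    Fs <- if (any(pre)) stats::median(y[pre]) else NA_real_
    data.frame(t = tp, Fs = Fs, Fm_prime = max(y[w]))
  })
  pulses_df <- do.call(rbind, recs)
  bad <- pulses_df$Fm_prime > Fm * 1.001
  if (any(bad)) {
    if (max(pulses_df$Fm_prime) <= Fm * 1.02)
      warning("Fm' slightly exceeds Fm at some pulses (<=2%): attributed to noise")
    else
      warning("Fm' exceeds Fm by more than 2% at some pulses")
  }
  quench_series(F0, Fm, pulses_df)
}

#' Construct a quench series directly from levels
#'
#' @param F0,Fm Dark-adapted minimal and maximal fluorescence (`Fm > F0 >= 0`).
#' @param pulses Data frame with columns `t`, `Fs`, `Fm_prime` and optionally
#'   `F0_prime`.
#' @return Object of class `quench_series`.
#' @export
quench_series <- function(F0, Fm, pulses) {
  pulses <- as.data.frame(pulses)
  stopifnot(all(c("t", "Fs", "Fm_prime") %in% names(pulses)))
  if (!(Fm > F0 && F0 >= 0)) stop("need Fm > F0 >= 0")
  ok <- !is.na(pulses$Fs)
  if (any(pulses$Fm_prime[ok] < pulses$Fs[ok]))
    warning("Fm' < Fs at some pulses: check pulse windows")
  structure(list(F0 = F0, Fm = Fm, FvFm = (Fm - F0) / Fm, pulses = pulses),
            class = "quench_series")
}

#' @export
print.quench_series <- function(x, ...) {
  cat(sprintf("<quench_series> F0=%.4g, Fm=%.4g (Fv/Fm=%.3f), %d pulses\n",
              x$F0, x$Fm, x$FvFm, nrow(x$pulses)))
  invisible(x)
}

#' NPQ time course from a quench series
#'
#' Stern-Volmer non-photochemical quenching, `NPQ = (Fm - Fm')/Fm'` per
#' pulse.
#'
#' @param series A [quench_series()].
#' @return Data frame with columns `t`, `NPQ`.
#' @export
npq_timecourse <- function(series) {
  stopifnot(inherits(series, "quench_series"))
  fmp <- series$pulses$Fm_prime
  if (any(fmp <= 0)) stop("Fm' must be > 0")
  data.frame(t = series$pulses$t, NPQ = (series$Fm - fmp) / fmp)
}

#' Quantum-yield partition and fraction of open centers
#'
#' Complementary partition of absorbed excitation at each pulse:
#' `Phi_II = (Fm' - Fs)/Fm'` (photochemistry),
#' `Phi_NPQ = Fs/Fm' - Fs/Fm` (regulated dissipation),
#' `Phi_NO = Fs/Fm` (unregulated losses); the three sum to 1 identically.
#' `qL = ((Fm' - Fs)/(Fm' - F0')) * (F0'/Fs)` estimates the fraction of
#' open centers in a lake model; when F0' was not measured it is estimated
#' as `F0 / (Fv/Fm + F0/Fm')`.
#'
#' With `lake = TRUE` the fuller lake-model partition is used instead:
#' `Phi_NO = 1 / (NPQ + 1 + qL (Fm/F0 - 1))` and
#' `Phi_NPQ = 1 - Phi_II - Phi_NO`, which also sums to 1 by construction.
#'
#' @param series A [quench_series()].
#' @param lake Use the lake-model partition (see Details). Default `FALSE`.
#' @return Data frame with columns `t`, `Phi_II`, `Phi_NPQ`, `Phi_NO`, `qL`.
#' @export
partition_yields <- function(series, lake = FALSE) {
  stopifnot(inherits(series, "quench_series"))
  p <- series$pulses
  Fm <- series$Fm
  F0 <- series$F0
  FvFm <- series$FvFm
  f0p <- if ("F0_prime" %in% names(p) && !all(is.na(p$F0_prime))) p$F0_prime
         else F0 / (FvFm + F0 / p$Fm_prime)
  if (any(abs(p$Fm_prime - f0p) < .Machine$double.eps * 10))
    stop("degenerate Fm' = F0'")
  phi_ii <- (p$Fm_prime - p$Fs) / p$Fm_prime
  qL <- ((p$Fm_prime - p$Fs) / (p$Fm_prime - f0p)) * (f0p / p$Fs)
  if (lake) {
    npq <- (Fm - p$Fm_prime) / p$Fm_prime
    phi_no <- 1 / (npq + 1 + qL * (Fm / F0 - 1))
    phi_npq <- 1 - phi_ii - phi_no
  } else {
    phi_no <- p$Fs / Fm
    phi_npq <- p$Fs / p$Fm_prime - phi_no
  }
  data.frame(t = p$t, Phi_II = phi_ii, Phi_NPQ = phi_npq, Phi_NO = phi_no,
             qL = qL)
}

#' Decompose NPQ into rapidly relaxing (qE) and sustained (qI) components
#'
#' Operational split at the end of the recorded dark-relaxation window:
#' `npq_max` is the NPQ at the last pulse of the light period preceding the
#' dark window, `qI` is the NPQ at the final pulse inside the dark window,
#' and `qE = npq_max - qI`. An exponential-unmixing variant
#' (`method = "exponential"`) instead fits `qI + qE * exp(-t/tau)` to the
#' dark-phase NPQ points.
#'
#' @param npq Data frame `(t, NPQ)` as returned by [npq_timecourse()].
#' @param protocol A [pulse_protocol()] whose first dark window defines the
#'   relaxation phase.
#' @param method `"endpoint"` (default) or `"exponential"`.
#' @return Object of class `quench_decomposition`: list with `qE`, `qI`,
#'   `npq_max` (and `tau` for the exponential method).
#' @export
decompose_qe_qi <- function(npq, protocol, method = c("endpoint", "exponential")) {
  method <- match.arg(method)
  stopifnot(inherits(protocol, "pulse_protocol"))
  if (!nrow(protocol$dark)) stop("protocol has no dark window")
  d <- protocol$dark[1L, ]
  before <- npq$t <= d$start + 1e-9
  if (!any(before)) stop("no pulses before the dark window")
  npq_max <- npq$NPQ[which(before)[sum(before)]]
  in_dark <- npq$t > d$start & npq$t <= d$end + 1e-9
  if (!any(in_dark)) stop("no pulses inside the dark window")
  if (method == "endpoint") {
    qI <- npq$NPQ[which(in_dark)[sum(in_dark)]]
    tau <- NA_real_
  } else {
    dt <- npq$t[in_dark] - d$start
    dn <- npq$NPQ[in_dark]
    fit <- minpack.lm::nlsLM(dn ~ qI + qE * exp(-dt / tau),
                             start = list(qI = min(dn),
                                          qE = max(npq_max - min(dn), 1e-3),
                                          tau = max(diff(range(dt)) / 3, 1)),
                             lower = c(0, 0, 1e-6))
    qI <- stats::coef(fit)[["qI"]]
    tau <- stats::coef(fit)[["tau"]]
  }
  qE <- max(npq_max - qI, 0)
  structure(list(qE = qE, qI = qI, npq_max = npq_max, tau = tau,
                 method = method),
            class = "quench_decomposition")
}

#' @export
print.quench_decomposition <- function(x, ...) {
  cat(sprintf("<quench_decomposition> qE=%.3f, qI=%.3f (NPQ max=%.3f, %s)\n",
              x$qE, x$qI, x$npq_max, x$method))
  invisible(x)
}

#' Definite integral of an NPQ time course
#'
#' Trapezoidal integral of NPQ over a time window (conventionally the first
#' 8 minutes of illumination). No baseline subtraction is applied unless
#' `subtract_baseline = TRUE`, in which case the first NPQ value inside the
#' window is subtracted.
#'
#' @param npq Data frame `(t, NPQ)`.
#' @param window Numeric length-2 vector `(t0, t1)` in seconds; must lie
#'   within the sampled span.
#' @param subtract_baseline Subtract the initial NPQ value first.
#' @return The integral (dimensionless x seconds).
#' @export
npq_integral <- function(npq, window = c(0, 480), subtract_baseline = FALSE) {
  stopifnot(length(window) == 2L, window[2L] > window[1L])
  if (window[1L] < min(npq$t) - 1e-9 || window[2L] > max(npq$t) + 1e-9)
    stop("integration window exceeds the sampled span")
  # interpolate to the window edges so subwindow additivity holds exactly
  tt <- sort(unique(c(window, npq$t[npq$t > window[1L] & npq$t < window[2L]])))
  vv <- stats::approx(npq$t, npq$NPQ, xout = tt)$y
  if (subtract_baseline) vv <- vv - vv[1L]
  pracma::trapz(tt, vv)
}

#' Four-parameter logistic fit of NPQ integral versus antenna content
#'
#' Fits `y = y0 + a / (1 + exp(-(x - x0)/b))` with `a > 0` (monotone
#' increasing) to points of light-harvesting-complex content (x) against
#' NPQ definite integral (y).
#'
#' @param points Data frame with columns `lhc` (e.g. nmol LHC per ug Chl)
#'   and `integral`.
#' @return List with `coef` (named y0, a, x0, b), `r_squared`, `fitted`,
#'   and `predict(x)` closure.
#' @export
fit_sigmoid_lhc_npq <- function(points) {
  points <- as.data.frame(points)
  stopifnot(all(c("lhc", "integral") %in% names(points)), nrow(points) >= 5L)
  x <- points$lhc
  y <- points$integral
  rng <- diff(range(y))
  start <- list(y0 = min(y), a = max(rng, 1e-6),
                x0 = stats::median(x), b = diff(range(x)) / 6)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ y0 + a / (1 + exp(-(x - x0) / b)),
                      start = start,
                      lower = c(y0 = -Inf, a = 0, x0 = -Inf, b = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) stop("sigmoid fit did not converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  yhat <- stats::fitted(fit)
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(coef = cf, r_squared = r2,
       fitted = data.frame(lhc = x, integral = y, fitted = yhat),
       predict = function(xnew)
         cf[["y0"]] + cf[["a"]] / (1 + exp(-(xnew - cf[["x0"]]) / cf[["b"]])))
}
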