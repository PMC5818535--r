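#' Finke-Watzky two-step aggregation model
#'
#' Product concentration under the two-step nucleation/autocatalytic-growth
#' mechanism:
#' \deqn{B(t) = A_0 - \frac{k_1/k_2 + A_0}{1 + \frac{k_1}{k_2 A_0}
#'   e^{(k_1 + k_2 A_0) t}}}
#' B(0) = 0 holds as an algebraic identity and B(t) rises monotonically to
#' the initial reactant amplitude A0.
#'
#' @param t time in hours (vectorized).
#' @param A0 initial reactant amplitude, signal units (> 0).
#' @param k1 nucleation rate constant, per hour (> 0).
#' @param k2 elongation rate constant, per hour per signal unit (> 0).
#' @return product signal, same units as `A0`.
#' @export
fw_model <- function(t, A0, k1, k2) {
  stopifnot(A0 > 0, k1 > 0, k2 > 0)
  A0 - (k1 / k2 + A0) / (1 + (k1 / (k2 * A0)) * exp((k1 + k2 * A0) * t))
}

# Baseline of a ThT curve. The Finke-Watzky product curve starts rising
# immediately (there is no true plateau unless k1 << k2*A0), and the tangent
# lag is referenced to the signal level at t = 0, so the level is taken from
# the earliest points only: the first 2% of the curve, never past the point
# where the (median-smoothed) signal crosses 20% of its range. The noise SD
# comes from the same segment.
tht_baseline <- function(y, cross_frac = 0.2, min_pts = 3, early_frac = 0.02) {
  ys <- if (length(y) >= 7) stats::runmed(y, 5) else y
  lo <- min(ys) + cross_frac * (max(ys) - min(ys))
  i_cross <- which(ys > lo)[1]
  n_pre <- if (is.na(i_cross)) length(y) else i_cross - 1
  n0 <- max(min_pts, min(ceiling(early_frac * length(y)), n_pre))
  seg <- y[seq_len(n0)]
  list(level = stats::median(seg), noise_sd = stats::sd(seg), n_pre = n0)
}

# Closed-form lag of the FW logistic by the inflection-tangent construction:
# tangent at the inflection point extended to the pre-transition baseline (0).
fw_lag_closed_form <- function(A0, k1, k2) {
  K <- k1 / k2 + A0
  lam <- k1 + k2 * A0
  t_star <- log(k2 * A0 / k1) / lam
  slope <- K * lam / 4
  t_star - (A0 - K / 2) / slope
}

#' Fit the Finke-Watzky model to a ThT curve
#'
#' Bounded Levenberg-Marquardt least squares of [fw_model()] on the
#' baseline-subtracted fluorescence. The baseline is the median of the
#' pre-transition segment (points before the smoothed signal crosses 20% of
#' its range). Requires a net signal increase.
#'
#' @param curve data frame `time_h, fluorescence` (single well or a
#'   per-condition average), strictly ascending times, >= 10 points.
#' @param A0 optional fixed reactant amplitude; `NULL` (default) fits it.
#' @return list of class `fw_fit` with `A0`, `k1`, `k2`, `se` (named),
#'   `baseline`, `rss`, `fitted`.
#' @export
fit_fw <- function(curve, A0 = NULL) {
  t <- curve$time_h
  y <- curve$fluorescence
  if (length(t) < 10) stop("need at least 10 time points")
  if (is.unsorted(t, strictly = TRUE)) stop("times must be strictly ascending")
  base <- tht_baseline(y)
  n_tail <- max(3, ceiling(0.1 * length(t)))
  if (mean(utils::tail(y, n_tail)) <= mean(utils::head(y, n_tail))) {
    stop("no transition: curve shows no net increase")
  }
  amp <- max(y) - base$level
  fixed_A0 <- !is.null(A0)
  # kinetic parameters are fitted on the log scale (k1 can sit many orders of
  # magnitude below k2*A0 in nucleation-limited curves); the baseline is an
  # additive offset fitted alongside (subtracting a pre-estimate would bias
  # A0 on clean data). The lag-based nucleation guess comes from the
  # inflection-tangent relation rather than a fixed ratio.
  slopes <- diff(y) / diff(t)
  lam0 <- max(4 * max(slopes) / amp, 1e-3)
  lag0 <- max(t[which.max(slopes)] - 2 / lam0, t[2])
  k1_0 <- max(lam0 * exp(-lam0 * (lag0 + 2 / lam0)), 1e-300)
  start <- if (fixed_A0) {
    c(b = base$level, log_k1 = log(k1_0), log_k2 = log(lam0 / A0))
  } else {
    c(b = base$level, log_A0 = log(amp), log_k1 = log(k1_0),
      log_k2 = log(lam0 / amp))
  }
  resid_fun <- function(par) {
    p <- as.list(par)
    a <- if (fixed_A0) A0 else exp(p$log_A0)
    p$b + fw_model(t, a, exp(p$log_k1), exp(p$log_k2)) - y
  }
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 1000, maxfev = 5000))
  if (fit$info < 1 || fit$info > 4) {
    stop("Finke-Watzky fit did not converge: ", fit$message)
  }
  par <- fit$par
  dof <- length(t) - length(par)
  sig2 <- fit$deviance / max(dof, 1)
  vcov <- tryCatch(sig2 * solve(fit$hessian / 2), error = function(e) NULL)
  se_log <- if (is.null(vcov)) rep(NA_real_, length(par)) else sqrt(pmax(diag(vcov), 0))
  names(se_log) <- names(par)
  a_hat <- if (fixed_A0) A0 else exp(par[["log_A0"]])
  k1_hat <- exp(par[["log_k1"]])
  k2_hat <- exp(par[["log_k2"]])
  # delta-method SEs on the natural scale
  se <- c(k1 = unname(k1_hat * se_log[["log_k1"]]),
          k2 = unname(k2_hat * se_log[["log_k2"]]),
          A0 = if (fixed_A0) 0 else unname(a_hat * se_log[["log_A0"]]),
          b = unname(se_log[["b"]]))
  structure(list(A0 = a_hat, k1 = k1_hat, k2 = k2_hat, se = se,
                 baseline = par[["b"]], rss = fit$deviance,
                 fitted = par[["b"]] + fw_model(t, a_hat, k1_hat, k2_hat)),
            class = "fw_fit")
}

#' @method print fw_fit
#' @export
print.fw_fit <- function(x, ...) {
  cat(sprintf("Finke-Watzky fit: A0 = %.4g, k1 = %.4g /h, k2 = %.4g /(h*unit), RSS = %.3g\n",
              x$A0, x$k1, x$k2, x$rss))
  invisible(x)
}

#' Lag time by the tangent method
#'
#' Baseline = median of the pre-transition segment (points before the
#' smoothed signal crosses 20% of its range). A straight line is fitted to
#' the elongation phase (points between `window[1]` and `window[2]` of the
#' baseline-subtracted amplitude) and extended back to the baseline level;
#' the intersection time is the lag. Requires a detectable transition
#' (amplitude > 5 x baseline noise SD). A negative intersection is clamped to
#' 0 with a warning.
#'
#' @param curve data frame `time_h, fluorescence`.
#' @param window amplitude fractions delimiting the elongation phase
#'   (default `c(0.2, 0.8)`).
#' @return list of class `lag_time` with `lag` (h), `slope`, `intercept`
#'   (elongation line in original fluorescence units), `baseline`.
#' @export
lag_time_tangent <- function(curve, window = c(0.2, 0.8)) {
  t <- curve$time_h
  y <- curve$fluorescence
  base <- tht_baseline(y)
  baseline <- base$level
  noise_sd <- base$noise_sd
  amp <- max(y) - baseline
  if (amp <= 5 * noise_sd) stop("no detectable transition above baseline noise")
  lo <- baseline + window[1] * amp
  hi <- baseline + window[2] * amp
  # restrict to the rising phase up to the first maximum
  i_max <- which.max(y)
  sel <- which(y >= lo & y <= hi & seq_along(y) <= i_max)
  if (length(sel) < 2) {
    # degenerate sharp transition: place the lag at the jump
    i_jump <- which(y > hi)[1]
    lag <- t[max(i_jump - 1, 1)]
    return(structure(list(lag = lag, slope = Inf, intercept = NA_real_,
                          baseline = baseline), class = "lag_time"))
  }
  # the elongation line is the tangent at the steepest part of the
  # transition: local least-squares slopes over a short sliding window, take
  # the steepest one (a single secant over the whole 20-80% window
  # systematically underestimates the slope and overestimates the lag)
  # window scales with the sampled transition so that sharp transitions are
  # not averaged over; floor of 3 points, cap of 11
  w <- max(3, min(11, 2 * (length(sel) %/% 6) + 1))
  half <- w %/% 2
  best <- NULL
  for (i in sel) {
    idx <- max(1, i - half):min(length(y), i + half)
    if (length(idx) < 3) next
    b_i <- stats::cov(t[idx], y[idx]) / stats::var(t[idx])
    if (is.null(best) || b_i > best$b) {
      best <- list(b = b_i, a = mean(y[idx]) - b_i * mean(t[idx]))
    }
  }
  if (is.null(best) || !is.finite(best$b) || best$b <= 0) {
    stop("could not fit an elongation line")
  }
  a <- best$a
  b <- best$b
  lag <- (baseline - a) / b
  if (lag < 0) {
    warning("negative lag clamped to 0")
    lag <- 0
  }
  structure(list(lag = lag, slope = b, intercept = a, baseline = baseline),
            class = "lag_time")
}

#' @method print lag_time
#' @export
print.lag_time <- function(x, ...) {
  cat(sprintf("Tangent lag time %.2f h (baseline %.3g, elongation slope %.3g)\n",
              x$lag, x$baseline, x$slope))
  invisible(x)
}

#' Fold change between two rates
#'
#' @param value_a numerator.
#' @param value_b denominator (> 0).
#' @return `value_a / value_b`.
#' @export
fold_change <- function(value_a, value_b) {
  if (any(value_b == 0)) stop("zero denominator in fold change")
  value_a / value_b
}

#' Monomer concentration from an SEC calibration line
#'
#' Ordinary least-squares line through the calibration points maps a peak
#' area to a concentration. Areas outside the calibration range are still
#' mapped but flagged as extrapolated.
#'
#' @param peak_area observed peak area(s).
#' @param calibration data frame `area, conc_uM` with >= 2 distinct areas.
#' @return data frame `peak_area, conc_uM, extrapolated`.
#' @export
sec_monomer <- function(peak_area, calibration) {
  stopifnot(nrow(calibration) >= 2)
  if (length(unique(calibration$area)) < 2) {
    stop("calibration areas must be distinct")
  }
  fit <- stats::lm(conc_uM ~ area, data = calibration)
  conc <- stats::predict(fit, data.frame(area = peak_area))
  data.frame(peak_area = peak_area, conc_uM = unname(conc),
             extrapolated = peak_area < min(calibration$area) |
                            peak_area > max(calibration$area))
}

#' Average replicate ThT wells per condition
#'
#' Means the fluorescence across wells on the shared time grid, per
#' condition. Lag times are extracted from these averaged curves.
#'
#' @param tht long-format data frame `time_h, well, condition, fluorescence`.
#' @return named list: condition -> data frame `time_h, fluorescence`.
#' @export
average_tht_curves <- function(tht) {
  lapply(split(tht, tht$condition), function(d) {
    agg <- stats::aggregate(fluorescence ~ time_h, data = d, FUN = mean)
    agg[order(agg$time_h), ]
  })
}
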