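# Two-state chemical denaturation with linear baselines, ligand-linkage
# extrapolation of the folding free energy to zero cofactor, and
# apparent melting temperatures from dye-based thermal melts.

#' Construct a denaturation curve
#'
#' Fluorescence versus denaturant (GuHCl) at a fixed cofactor (NADPH)
#' concentration.  At least 10 points with increasing denaturant are
#' required so that both baselines can be resolved.
#'
#' @param D Molar GuHCl, non-negative, increasing.
#' @param F_signal Fluorescence (AU), same length.
#' @param ligand_conc Molar NADPH present during the titration.
#' @param temperature Kelvin.
#' @return Object of class `denaturation_curve`.
#' @export
denaturation_curve <- function(D, F_signal, ligand_conc = 0,
                               temperature = 296.15) {
  stopifnot(is.numeric(D), is.numeric(F_signal),
            length(D) == length(F_signal))
  if (length(D) < 10L) stop("need at least 10 points")
  if (any(!is.finite(D)) || any(!is.finite(F_signal)))
    stop("non-finite values in denaturation curve")
  if (any(D < 0)) stop("'D' must be >= 0")
  if (any(diff(D) <= 0)) stop("'D' must be increasing")
  if (ligand_conc < 0) stop("'ligand_conc' must be >= 0")
  structure(list(D = D, F_signal = F_signal, ligand_conc = ligand_conc,
                 temperature = temperature),
            class = "denaturation_curve")
}

#' Two-state denaturation model with linear baselines
#'
#' `F(D) = [F_U0 + a D + (F_N0 + b D) K] / (1 + K)` with
#' `K = exp(-(delta_g0 + m D)/(R T))`.  Under the folding free-energy
#' convention used throughout (`delta_g0` negative for a stable
#' protein, `m > 0`), the exponential weights the native baseline: at low
#' denaturant the native signal dominates and at high denaturant the
#' unfolded baseline is recovered.  The midpoint is `D_half = -delta_g0/m`.
#'
#' @param D Molar GuHCl (vectorized).
#' @param delta_g0 Folding free energy at zero denaturant, kcal mol^-1.
#' @param m Denaturant dependence of the free energy,
#'   kcal mol^-1 M^-1 (> 0).
#' @param F_N0,b Native-baseline intercept (AU) and slope (AU M^-1).
#' @param F_U0,a Unfolded-baseline intercept (AU) and slope (AU M^-1).
#' @param consts A [physical_constants()].
#' @return Fluorescence (AU).
#' @export
two_state_denaturation_model <- function(D, delta_g0, m, F_N0, b, F_U0, a,
                                         consts = physical_constants()) {
  stopifnot(all(is.finite(c(delta_g0, m, F_N0, b, F_U0, a))))
  RT <- consts$R * consts$T
  # native population; plogis keeps the limits numerically stable
  fN <- plogis(-(delta_g0 + m * D) / RT)
  (F_N0 + b * D) * fN + (F_U0 + a * D) * (1 - fN)
}

#' Fit a denaturation curve to the two-state model
#'
#' Least-squares fit of the six parameters (delta_g0, m, and two linear
#' baselines).  Starting values are data driven: baselines from the
#' first and last quarters, the midpoint from the half-signal crossing.
#' A curve whose transition midpoint sits too close to either end of the
#' denaturant range (less than ~2RT/m from the edge) cannot pin down a
#' baseline; such fits carry `baseline_resolved = FALSE` and the free
#' energy should not be trusted.
#'
#' @param curve A [denaturation_curve()].
#' @param consts A [physical_constants()]; defaults to the curve's
#'   temperature.
#' @param sigma Optional known noise SD (AU) for the reduced chi-square.
#' @return Object of class `denaturation_fit` with `delta_g0`, `m`,
#'   `F_N0`, `b`, `F_U0`, `a`, `se`, `residuals`, `reduced_chi2`,
#'   `d_half`, `baseline_resolved`, `ligand_conc`, `temperature`.
#' @export
fit_denaturation <- function(curve, consts = NULL, sigma = NULL) {
  stopifnot(inherits(curve, "denaturation_curve"))
  if (is.null(consts)) consts <- physical_constants(curve$temperature)
  D <- curve$D; y <- curve$F_signal
  n <- length(D)
  RT <- consts$R * consts$T

  q <- max(3L, floor(n / 4))
  lo <- seq_len(q); hi <- seq.int(n - q + 1L, n)
  bl_n <- stats::lm.fit(cbind(1, D[lo]), y[lo])$coefficients
  bl_u <- stats::lm.fit(cbind(1, D[hi]), y[hi])$coefficients
  midval <- (bl_n[1L] + bl_n[2L] * D + bl_u[1L] + bl_u[2L] * D) / 2
  D_mid0 <- D[which.min(abs(y - midval))]
  if (D_mid0 <= min(D)) D_mid0 <- stats::median(D)
  # transition width guess: distance between 25% and 75% crossings
  frac <- (y - (bl_n[1L] + bl_n[2L] * D)) /
    ((bl_u[1L] + bl_u[2L] * D) - (bl_n[1L] + bl_n[2L] * D))
  width <- diff(range(D[frac > 0.25 & frac < 0.75], na.rm = TRUE))
  if (!is.finite(width) || width <= 0) width <- diff(range(D)) / 5
  m0 <- max(2.2 * RT / (width / 2), 0.1)
  dg0 <- -m0 * D_mid0

  dat <- data.frame(D = D, y = y)
  fit <- tryCatch(
    suppressWarnings(nls(y ~ two_state_denaturation_model(D, dg, m, FN0, b, FU0, a, consts),
        data = dat,
        start = list(dg = dg0, m = m0, FN0 = unname(bl_n[1L]),
                     b = unname(bl_n[2L]), FU0 = unname(bl_u[1L]),
                     a = unname(bl_u[2L])),
        algorithm = "port",
        lower = c(dg = -Inf, m = 1e-6, FN0 = -Inf, b = -Inf,
                  FU0 = -Inf, a = -Inf),
        control = list(maxiter = 500, warnOnly = TRUE))),
    error = function(e) e)
  if (inherits(fit, "error"))
    stop("denaturation fit did not converge: ", conditionMessage(fit))
  # port's "false convergence" usually still sits at the optimum; accept
  # the solution but record the diagnostic instead of failing silently
  convergence_note <- if (isTRUE(fit$convInfo$isConv)) ""
                      else fit$convInfo$stopMessage
  cf <- coef(fit)
  se <- tryCatch(coef(summary(fit))[, 2L],
                 error = function(e) setNames(rep(NA_real_, 6L), names(cf)))
  res <- unname(stats::residuals(fit))
  dof <- n - 6L
  rchi2 <- if (is.null(sigma)) sum(res^2) / dof
           else sum(res^2) / sigma^2 / dof
  d_half <- -cf[["dg"]] / cf[["m"]]
  margin <- 2 * RT / cf[["m"]]
  baseline_resolved <- d_half - margin > min(D) && d_half + margin < max(D)
  if (!baseline_resolved)
    warning("transition midpoint too close to the denaturant range edge; ",
            "baseline unresolved and delta_g0 unreliable", call. = FALSE)
  structure(list(delta_g0 = unname(cf[["dg"]]), m = unname(cf[["m"]]),
                 F_N0 = unname(cf[["FN0"]]), b = unname(cf[["b"]]),
                 F_U0 = unname(cf[["FU0"]]), a = unname(cf[["a"]]),
                 se = setNames(unname(se[c("dg", "m", "FN0", "b", "FU0",
                                           "a")]),
                               c("delta_g0", "m", "F_N0", "b", "F_U0",
                                 "a")),
                 residuals = res, reduced_chi2 = rchi2, d_half = d_half,
                 baseline_resolved = baseline_resolved,
                 convergence_note = convergence_note,
                 ligand_conc = curve$ligand_conc,
                 temperature = consts$T),
            class = "denaturation_fit")
}

#' @export
print.denaturation_fit <- function(x, ...) {
  cat("Two-state denaturation fit (folding convention)\n")
  cat(sprintf("  delta_g0 = %.3f +/- %.3f kcal/mol at [NADPH] = %g M\n",
              x$delta_g0, x$se[["delta_g0"]], x$ligand_conc))
  cat(sprintf("  m        = %.3f +/- %.3f kcal/mol/M; midpoint %.2f M\n",
              x$m, x$se[["m"]], x$d_half))
  if (!x$baseline_resolved) cat("  warning: baseline unresolved\n")
  invisible(x)
}

#' Extrapolate folding free energies to zero ligand
#'
#' Given per-titration free energies measured at different cofactor
#' concentrations, fits the one-parameter linkage model
#' `delta_g(S) = delta_g0 - R T log(1 + S/Km)` by (weighted) least
#' squares; the solution is the closed-form weighted mean of
#' `delta_g_i + R T log(1 + S_i/Km)`.
#'
#' @param fits Either a list of [fit_denaturation()] results or a
#'   data.frame with columns `ligand_conc`, `delta_g0` and optionally
#'   `se`.
#' @param Km Ligand Michaelis constant, molar (default 13e-6 for NADPH).
#' @param consts A [physical_constants()].
#' @return A [stability_result()] with `source = "extrapolation"`.
#' @export
extrapolate_ligand_series <- function(fits, Km = 13e-6,
                                      consts = physical_constants()) {
  if (Km <= 0) stop("'Km' must be > 0")
  if (is.list(fits) && !is.data.frame(fits) &&
      all(vapply(fits, inherits, TRUE, "denaturation_fit"))) {
    temps <- vapply(fits, `[[`, 0, "temperature")
    if (diff(range(temps)) > 0.5)
      stop("inconsistent temperatures across denaturation fits")
    fits <- data.frame(
      ligand_conc = vapply(fits, `[[`, 0, "ligand_conc"),
      delta_g0 = vapply(fits, `[[`, 0, "delta_g0"),
      se = vapply(fits, function(f) f$se[["delta_g0"]], 0))
  }
  stopifnot(is.data.frame(fits),
            all(c("ligand_conc", "delta_g0") %in% names(fits)))
  RT <- consts$R * consts$T
  x <- fits$delta_g0 + RT * log1p(fits$ligand_conc / Km)
  if (!is.null(fits$se) && all(is.finite(fits$se)) && all(fits$se > 0)) {
    w <- 1 / fits$se^2
    dg0 <- sum(w * x) / sum(w)
    se <- sqrt(1 / sum(w))
  } else {
    dg0 <- mean(x)
    se <- if (length(x) > 1L) sd(x) / sqrt(length(x)) else NA_real_
  }
  stability_result(dg0, consts$T, source = "extrapolation",
                   uncertainty = se)
}

#' Construct a thermal melt curve
#'
#' Dye (SYPRO) fluorescence versus temperature, scanned on a roughly
#' uniform grid (the assay uses 0.5 degree C steps).
#'
#' @param T_C Temperatures in degrees Celsius, increasing.
#' @param F_signal Dye fluorescence (AU), same length.
#' @param label Sample label.
#' @return Object of class `melt_curve`.
#' @export
melt_curve <- function(T_C, F_signal, label = "") {
  stopifnot(is.numeric(T_C), is.numeric(F_signal),
            length(T_C) == length(F_signal))
  if (length(T_C) < 11L) stop("need at least 11 points")
  if (any(!is.finite(T_C)) || any(!is.finite(F_signal)))
    stop("non-finite values in melt curve")
  st <- diff(T_C)
  if (any(st <= 0)) stop("'T_C' must be increasing")
  if (max(st) > 1.5 * stats::median(st))
    stop("temperature grid must be roughly uniform")
  structure(list(T_C = T_C, F_signal = F_signal, label = label),
            class = "melt_curve")
}

# Savitzky-Golay convolution weights for a local polynomial of given
# degree over an odd window; row 1 smooths, row 2 differentiates
# (per unit step).
.sg_weights <- function(window, degree = 2L) {
  h <- (window - 1L) %/% 2L
  X <- outer(seq(-h, h), 0:degree, `^`)
  solve(crossprod(X), t(X))
}

#' Apparent melting temperature from a dye melt
#'
#' Smooths the fluorescence with a local-quadratic (Savitzky-Golay)
#' filter, differentiates the smoothed signal, and returns the
#' temperature of the interior extremum of largest absolute derivative.
#' Whether the transition appears as a maximum or a minimum of dF/dT
#' depends on dye orientation, so the magnitude is used.  Comparable
#' secondary peaks (>= 80% of the largest) are reported and flagged.
#'
#' @param curve A [melt_curve()].
#' @param smooth_window Odd integer >= 5 (default 11 points, i.e. 5.5
#'   degrees C at 0.5 degree steps).
#' @return Object of class `tm_result`: `tm` (deg C),
#'   `derivative_peak_height` (signed AU/deg C), `smooth_window`,
#'   `all_peaks` (data.frame), `ambiguous`.
#' @export
melting_temperature <- function(curve, smooth_window = 11L) {
  stopifnot(inherits(curve, "melt_curve"))
  smooth_window <- as.integer(smooth_window)
  if (smooth_window < 5L || smooth_window %% 2L == 0L)
    stop("'smooth_window' must be odd and >= 5")
  n <- length(curve$T_C)
  if (n < smooth_window + 4L) stop("melt curve shorter than filter window")
  h <- (smooth_window - 1L) %/% 2L
  W <- .sg_weights(smooth_window, 2L)
  step <- stats::median(diff(curve$T_C))
  interior <- seq.int(h + 1L, n - h)
  emb <- vapply(interior, function(i)
    curve$F_signal[(i - h):(i + h)], numeric(smooth_window))
  deriv <- as.numeric(W[2L, ] %*% emb) / step
  mag <- abs(deriv)
  # interior local maxima of |dF/dT|
  k <- length(mag)
  is_peak <- c(FALSE, mag[2:(k - 1)] > mag[1:(k - 2)] &
                 mag[2:(k - 1)] >= mag[3:k], FALSE)
  if (!any(is_peak) || diff(range(mag)) < 0.05 * max(mag))
    stop("no interior derivative extremum: no transition captured")
  peaks <- which(is_peak)
  best <- peaks[which.max(mag[peaks])]
  if (mag[best] < max(mag[c(1L, k)]))
    stop("largest derivative lies on the scan boundary: no transition captured")
  keep <- peaks[mag[peaks] >= 0.8 * mag[best]]
  all_peaks <- data.frame(tm = curve$T_C[interior][keep],
                          derivative = deriv[keep])
  # sub-grid refinement: parabola through the peak and its neighbours
  tm_best <- curve$T_C[interior][best]
  if (best > 1L && best < k) {
    den <- mag[best - 1L] - 2 * mag[best] + mag[best + 1L]
    if (den < 0)
      tm_best <- tm_best + 0.5 * step *
        (mag[best - 1L] - mag[best + 1L]) / den
  }
  structure(list(tm = tm_best,
                 derivative_peak_height = deriv[best],
                 smooth_window = smooth_window,
                 all_peaks = all_peaks,
                 ambiguous = length(keep) > 1L),
            class = "tm_result")
}

#' @export
print.tm_result <- function(x, ...) {
  cat(sprintf("Apparent Tm = %.2f C (derivative peak %.3g AU/C, window %d)\n",
              x$tm, x$derivative_peak_height, x$smooth_window))
  if (x$ambiguous) {
    cat("  multiple comparable transitions:\n")
    print(x$all_peaks)
  }
  invisible(x)
}
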