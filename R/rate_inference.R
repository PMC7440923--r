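# Inference of folding and unfolding rate constants from the substrate
# dependence of the lag rate constant:
#   lambda(S) = k1 + k_minus1 / (Ka S + 1)
# The model is linear in (k1, k_minus1) once Ka is fixed, so the fit is
# a one-dimensional search over log(Ka) with a closed-form weighted
# least-squares solve inside -- fast, deterministic and free of
# starting-value trouble.  Chi-square surfaces and confidence intervals
# are profile based.

#' Construct a lambda-versus-substrate series
#'
#' @param S Molar substrate (DHF) concentrations (>= 0).
#' @param lam Observed lag rate constants, s^-1 (> 0).
#' @param lam_err Optional standard errors of `lam` (s^-1, > 0); used as
#'   1/sigma^2 weights by the fitters.
#' @param temperature Kelvin.
#' @return Object of class `lambda_series`.  Duplicate `S` values are
#'   allowed and are pooled (mean, pooled sigma) by [fit_lambda_curve()].
#' @export
lambda_series <- function(S, lam, lam_err = NULL, temperature = 296.15) {
  stopifnot(is.numeric(S), is.numeric(lam), length(S) == length(lam))
  if (any(!is.finite(S)) || any(!is.finite(lam)))
    stop("non-finite values in lambda series")
  if (any(S < 0)) stop("'S' must be >= 0")
  if (any(lam <= 0)) stop("'lam' must be > 0")
  if (!is.null(lam_err)) {
    stopifnot(length(lam_err) == length(lam))
    if (any(!is.finite(lam_err)) || any(lam_err <= 0))
      stop("'lam_err' must be positive and finite")
  }
  structure(list(S = S, lam = lam, lam_err = lam_err,
                 temperature = temperature),
            class = "lambda_series")
}

# Pool duplicate substrate concentrations: mean lambda, pooled sigma
# (errors combined as standard errors of the mean when supplied).
.pool_duplicates <- function(series) {
  if (!anyDuplicated(series$S)) return(series)
  sp <- split(seq_along(series$S), series$S)
  S <- as.numeric(names(sp))
  lam <- unname(vapply(sp, function(i) mean(series$lam[i]), 0))
  lam_err <- if (is.null(series$lam_err)) NULL else
    unname(vapply(sp, function(i)
      sqrt(sum(series$lam_err[i]^2)) / length(i), 0))
  lambda_series(S, lam, lam_err, series$temperature)
}

# Closed-form weighted LS for (k1, k_minus1) >= 0 at fixed Ka.
# Returns list(k1, k_minus1, chi2).
.lambda_wls <- function(Ka, S, y, w) {
  g <- 1 / (Ka * S + 1)
  sw <- sum(w); swg <- sum(w * g); swg2 <- sum(w * g^2)
  swy <- sum(w * y); swyg <- sum(w * y * g)
  det <- sw * swg2 - swg^2
  cand <- list()
  if (det > 0) {
    k1 <- (swy * swg2 - swyg * swg) / det
    km1 <- (sw * swyg - swg * swy) / det
    if (k1 >= 0 && km1 >= 0) cand <- c(cand, list(c(k1, km1)))
  }
  cand <- c(cand,
            list(c(max(0, swy / sw), 0),            # k_minus1 on boundary
                 c(0, max(0, swyg / swg2))))        # k1 on boundary
  chi2 <- vapply(cand, function(p)
    sum(w * (y - p[1L] - p[2L] * g)^2), 0)
  best <- cand[[which.min(chi2)]]
  list(k1 = best[1L], k_minus1 = best[2L], chi2 = min(chi2))
}

# Default log(Ka) search bounds from the substrate design.
.ka_bounds <- function(S) {
  Spos <- S[S > 0]
  if (!length(Spos)) stop("at least one positive substrate concentration needed")
  c(log(1e-3 / max(Spos)), log(1e4 / min(Spos)))
}

#' Fit the substrate dependence of the lag rate constant
#'
#' Weighted least-squares fit of `lambda(S) = k1 + k_minus1/(Ka S + 1)`
#' with all parameters constrained non-negative.  When `lam_err` is
#' present in the series, weights are 1/sigma^2 and the chi-square is on
#' an absolute scale; otherwise the fit is unweighted and the error
#' scale is estimated from the residuals.
#'
#' @param series A [lambda_series()] (>= 4 distinct concentrations).
#' @param fix_Ka Fix the association constant at this value (M^-1)
#'   instead of fitting it (e.g. from an independently measured Km).
#' @return Object of class `lambda_fit`: `rates` ([scheme_rates()]),
#'   `se` (named k1, k_minus1, Ka), `chi2`, `reduced_chi2`, `n_par`,
#'   `identifiable` (named logicals), `series` (pooled), `weighted`.
#' @export
fit_lambda_curve <- function(series, fix_Ka = NULL) {
  stopifnot(inherits(series, "lambda_series"))
  series <- .pool_duplicates(series)
  S <- series$S; y <- series$lam
  if (length(unique(S)) < 4L)
    stop("need at least 4 distinct substrate concentrations")
  weighted <- !is.null(series$lam_err)
  w <- if (weighted) 1 / series$lam_err^2 else rep(1, length(S))

  if (is.null(fix_Ka)) {
    bounds <- .ka_bounds(S)
    obj <- function(lk) .lambda_wls(exp(lk), S, y, w)$chi2
    opt <- optimize(obj, bounds, tol = 1e-10)
    # guard against boundary/flat objectives
    Ka <- exp(opt$minimum)
    ka_at_bound <- min(opt$minimum - bounds[1L],
                       bounds[2L] - opt$minimum) < 1e-3
  } else {
    stopifnot(fix_Ka > 0)
    Ka <- fix_Ka
    ka_at_bound <- FALSE
  }
  sol <- .lambda_wls(Ka, S, y, w)
  k1 <- sol$k1; km1 <- sol$k_minus1; chi2 <- sol$chi2
  n <- length(S); n_par <- if (is.null(fix_Ka)) 3L else 2L
  dof <- n - n_par
  if (dof <= 0L) stop("not enough points for the number of parameters")
  s2 <- if (weighted) 1 else chi2 / dof

  # analytic Jacobian at the optimum: d(lambda)/d(k1, k_minus1, Ka)
  g <- 1 / (Ka * S + 1)
  J <- cbind(k1 = rep(1, n), k_minus1 = g,
             Ka = -km1 * S / (Ka * S + 1)^2)
  if (!is.null(fix_Ka)) J <- J[, 1:2, drop = FALSE]
  JWJ <- crossprod(J, w * J)
  # scale to unit diagonal before inverting; parameter magnitudes span
  # ~8 orders (k1 ~ 1e-4 s^-1, Ka ~ 1e3 M^-1)
  cov <- tryCatch({
    d0 <- 1 / sqrt(diag(JWJ))
    Dm <- diag(d0, nrow = length(d0))
    (Dm %*% solve(Dm %*% JWJ %*% Dm) %*% Dm) * s2
  }, error = function(e) NULL)
  se <- c(k1 = NA_real_, k_minus1 = NA_real_, Ka = NA_real_)
  if (!is.null(cov)) {
    d <- sqrt(pmax(diag(cov), 0))
    se[colnames(J)] <- d
  }
  identifiable <- c(
    k1 = TRUE,
    k_minus1 = is.finite(se[["k_minus1"]]) &&
      km1 >= 2 * se[["k_minus1"]],
    Ka = !ka_at_bound && is.finite(se[["Ka"]]) && se[["Ka"]] <= 10 * Ka)
  if (!identifiable[["k_minus1"]]) identifiable[["Ka"]] <- FALSE
  structure(list(rates = scheme_rates(k1 = k1, k_minus1 = km1, Ka = Ka),
                 se = se, chi2 = chi2, reduced_chi2 = chi2 / dof,
                 n = n, n_par = n_par, dof = dof, s2 = s2,
                 weighted = weighted, fixed_Ka = !is.null(fix_Ka),
                 identifiable = identifiable, series = series),
            class = "lambda_fit")
}

#' @export
print.lambda_fit <- function(x, ...) {
  cat("Fit of lambda(S) = k1 + k_minus1/(Ka S + 1)\n")
  cat(sprintf("  k1       = %.4g +/- %.2g s^-1\n", x$rates$k1,
              x$se[["k1"]]))
  cat(sprintf("  k_minus1 = %.4g +/- %.2g s^-1\n", x$rates$k_minus1,
              x$se[["k_minus1"]]))
  cat(sprintf("  Ka       = %.4g +/- %.2g M^-1%s\n", x$rates$Ka,
              x$se[["Ka"]], if (x$fixed_Ka) " (fixed)" else ""))
  cat(sprintf("  reduced chi2 = %.4g on %d dof%s\n", x$reduced_chi2,
              x$dof, if (x$weighted) " (weighted)" else ""))
  bad <- names(x$identifiable)[!x$identifiable]
  if (length(bad))
    cat("  flagged unidentifiable:", paste(bad, collapse = ", "), "\n")
  invisible(x)
}

# Profile chi2 with one rate constant fixed; the other rate constant is
# closed form and Ka is profiled numerically.
.profile_chi2 <- function(series, param, value, weighted) {
  S <- series$S; y <- series$lam
  w <- if (weighted) 1 / series$lam_err^2 else rep(1, length(S))
  bounds <- .ka_bounds(S)
  inner <- function(lk) {
    g <- 1 / (exp(lk) * S + 1)
    if (param == "k1") {
      km1 <- max(0, sum(w * (y - value) * g) / sum(w * g^2))
      sum(w * (y - value - km1 * g)^2)
    } else {
      k1 <- max(0, sum(w * (y - value * g)) / sum(w))
      sum(w * (y - k1 - value * g)^2)
    }
  }
  optimize(inner, bounds, tol = 1e-8)$objective
}

#' Profile confidence intervals for k1 and k_minus1
#'
#' For each rate constant, the profile chi-square (re-optimizing the
#' other two parameters) is scanned away from the point estimate and the
#' crossing of `chi2_min + delta * s2` is located by root finding
#' (`delta = 1` gives 1-sigma intervals for one parameter; `s2` is 1 for
#' weighted fits and the residual variance estimate otherwise).
#'
#' @param fit A [fit_lambda_curve()] result.
#' @param delta Chi-square increment (default 1).
#' @return Matrix with rows `k1`, `k_minus1` and columns `lower`,
#'   `upper`.  A lower limit of 0 or an infinite upper limit means the
#'   profile never crossed the threshold inside the search range.
#' @export
confint_lambda <- function(fit, delta = 1) {
  stopifnot(inherits(fit, "lambda_fit"))
  series <- fit$series
  target <- fit$chi2 + delta * fit$s2
  est <- c(k1 = fit$rates$k1, k_minus1 = fit$rates$k_minus1)
  out <- matrix(NA_real_, 2L, 2L,
                dimnames = list(c("k1", "k_minus1"), c("lower", "upper")))
  for (p in rownames(out)) {
    e <- est[[p]]
    f <- function(v) .profile_chi2(series, p, v, fit$weighted) - target
    scale0 <- max(e, max(series$lam) * 1e-3)
    # upper limit
    hi <- e + scale0
    for (i in 1:60) {
      if (f(hi) > 0) break
      hi <- e + (hi - e) * 1.7
    }
    out[p, "upper"] <- if (f(hi) > 0)
      uniroot(f, c(e, hi), tol = scale0 * 1e-8)$root else Inf
    # lower limit (bounded below by 0)
    if (e <= 0 || f(0) <= 0) {
      out[p, "lower"] <- 0
    } else {
      lo <- e * 0.5
      found <- FALSE
      for (i in 1:60) {
        if (f(lo) > 0) { found <- TRUE; break }
        lo <- lo * 0.5
        if (lo < e * 1e-12) break
      }
      out[p, "lower"] <- if (found)
        uniroot(f, c(lo, e), tol = scale0 * 1e-8)$root else 0
    }
  }
  out
}

#' Reduced chi-square surface over (k1, k_minus1)
#'
#' On a log-spaced grid around the fitted rate constants (spanning at
#' least +/- `span` standard errors per axis, with the fitted values
#' inserted as grid nodes), the association constant is re-optimized at
#' every node (profile chi-square) and the reduced chi-square
#' `chi2 / (n - p)` is reported.
#'
#' @param series A [lambda_series()] (pooled automatically).
#' @param fit The corresponding [fit_lambda_curve()] result.
#' @param grid_spec List with `n` (nodes per axis, default 101) and
#'   `span` (standard errors per side, default 3, minimum 3).
#' @return Object of class `chi2_surface`: `k1`, `k_minus1` (axes),
#'   `reduced_chi2` (matrix, k1 by k_minus1), `minimum` (value and
#'   indices), `fit`.
#' @export
chi2_surface <- function(series, fit, grid_spec = list(n = 101L, span = 3)) {
  stopifnot(inherits(series, "lambda_series"), inherits(fit, "lambda_fit"))
  series <- .pool_duplicates(series)
  n_grid <- if (is.null(grid_spec$n)) 101L else as.integer(grid_spec$n)
  span <- if (is.null(grid_spec$span)) 3 else grid_spec$span
  if (span < 3) stop("grid must span at least +/- 3 standard errors")
  at_boundary <- FALSE
  axis_for <- function(est, se) {
    if (!is.finite(se) || se <= 0) se <- max(est / 2, 1e-12)
    if (est <= 0) {
      # estimate pinned at the non-negativity boundary: scan upward only
      at_boundary <<- TRUE
      return(exp(seq(log(se / 1e3), log(span * se), length.out = n_grid)))
    }
    lo <- max(est - span * se, est / 50)
    hi <- est + span * se
    if (lo <= 0 || est <= lo || est >= hi)
      stop("grid does not contain the fitted minimum in its interior")
    sort(unique(c(est, exp(seq(log(lo), log(hi), length.out = n_grid)))))
  }
  k1_axis <- axis_for(fit$rates$k1, fit$se[["k1"]])
  km1_axis <- axis_for(fit$rates$k_minus1, fit$se[["k_minus1"]])
  S <- series$S; y <- series$lam
  weighted <- fit$weighted
  w <- if (weighted) 1 / series$lam_err^2 else rep(1, length(S))
  bounds <- .ka_bounds(S)
  Ka_fit <- fit$rates$Ka
  prof <- function(k1, km1) {
    g_of <- function(lk) {
      g <- 1 / (exp(lk) * S + 1)
      sum(w * (y - k1 - km1 * g)^2)
    }
    min(optimize(g_of, bounds, tol = 1e-6)$objective,
        g_of(log(Ka_fit)))
  }
  m <- matrix(NA_real_, length(k1_axis), length(km1_axis))
  for (i in seq_along(k1_axis))
    for (j in seq_along(km1_axis))
      m[i, j] <- prof(k1_axis[i], km1_axis[j])
  m <- m / fit$dof
  imin <- which(m == min(m), arr.ind = TRUE)[1L, ]
  # the discrete minimum must sit at (or within one cell of) the fit
  if (!at_boundary) {
    i_fit <- which.min(abs(k1_axis - fit$rates$k1))
    j_fit <- which.min(abs(km1_axis - fit$rates$k_minus1))
    if (max(abs(imin[1L] - i_fit), abs(imin[2L] - j_fit)) > 1L)
      stop("chi-square surface minimum does not coincide with the fit")
  }
  structure(list(k1 = k1_axis, k_minus1 = km1_axis, reduced_chi2 = m,
                 minimum = list(value = min(m), i = imin[1L], j = imin[2L]),
                 at_boundary = at_boundary, fit = fit),
            class = "chi2_surface")
}

#' Classify the kinetic mechanism from the lambda trend
#'
#' A weighted linear trend of lambda on substrate concentration:
#' a significantly decreasing trend (two-sided p < `alpha`) is the
#' signature of conformational selection (ligand binds the folded state
#' only); a significantly increasing trend indicates induced fit or
#' substrate penetration (indistinguishable in this assay); otherwise
#' the series is indeterminate.
#'
#' @param series A [lambda_series()] with >= 4 points.
#' @param alpha Two-sided significance level (default 0.05).
#' @return List with `mechanism` (one of `"conformational_selection"`,
#'   `"induced_fit_or_penetration"`, `"indeterminate"`), `slope`,
#'   `p_value`.
#' @export
classify_mechanism <- function(series, alpha = 0.05) {
  stopifnot(inherits(series, "lambda_series"))
  if (length(series$S) < 4L) stop("need at least 4 points")
  w <- if (is.null(series$lam_err)) rep(1, length(series$S))
       else 1 / series$lam_err^2
  fit <- lm(lam ~ S, data = data.frame(S = series$S, lam = series$lam),
            weights = w)
  cf <- coef(summary(fit))
  slope <- cf["S", "Estimate"]; p <- cf["S", "Pr(>|t|)"]
  mech <- if (p < alpha && slope < 0) "conformational_selection"
          else if (p < alpha && slope > 0) "induced_fit_or_penetration"
          else "indeterminate"
  list(mechanism = mech, slope = slope, p_value = p)
}
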