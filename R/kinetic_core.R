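# Closed-form models and thermodynamic identities of the
# folding-binding scheme EU <-> EF <-> ES.  Everything here is a pure
# function of its arguments; downstream fitting modules call these.

#' Physical constants used throughout the package
#'
#' The gas constant is fixed at 1.987e-3 kcal mol^-1 K^-1.  The default
#' temperature is 296.15 K (23 degrees C), the temperature at which the
#' enzymatic and equilibrium assays are performed.
#'
#' @param temperature Absolute temperature in kelvin (> 0).
#' @return An object of class `physical_constants` with elements `R`
#'   (kcal mol^-1 K^-1) and `T` (kelvin).
#' @export
physical_constants <- function(temperature = 296.15) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.finite(temperature), temperature > 0)
  structure(list(R = 1.987e-3, T = temperature),
            class = "physical_constants")
}

#' Rate constants of the folding-binding-catalysis scheme
#'
#' Bundles the rate constants of the scheme EU <-> EF <-> ES (+ turnover):
#' `k1` (folding, s^-1), `k_minus1` (unfolding, s^-1), `k2` (substrate
#' association, M^-1 s^-1), `k_minus2` (substrate dissociation, s^-1),
#' `Ka = k2 / k_minus2` (association constant, M^-1) and `kcat`
#' (catalytic turnover, s^-1; used by the simulator only).
#'
#' Either `Ka` or the pair (`k2`, `k_minus2`) may be given; when all
#' three are supplied they must be mutually consistent to a relative
#' tolerance of 1e-9.
#'
#' @param k1,k_minus1 Folding and unfolding rate constants (s^-1, >= 0).
#' @param k2,k_minus2 Substrate association (M^-1 s^-1) and dissociation
#'   (s^-1) rate constants, or `NULL`.
#' @param Ka Substrate association constant (M^-1), or `NULL` to derive
#'   it from `k2 / k_minus2`.
#' @param kcat Catalytic turnover number (s^-1); simulator only.
#' @return An object of class `scheme_rates`.
#' @examples
#' scheme_rates(k1 = 1.4e-4, k_minus1 = 7.3e-3, Ka = 3571)
#' @export
scheme_rates <- function(k1, k_minus1, k2 = NULL, k_minus2 = NULL,
                         Ka = NULL, kcat = 0) {
  chk <- function(x, nm, strict = FALSE) {
    if (is.null(x)) return(invisible(NULL))
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("'%s' must be a single finite number", nm))
    if (x < 0) stop(sprintf("'%s' must be >= 0 (rate constant)", nm))
    invisible(NULL)
  }
  chk(k1, "k1"); chk(k_minus1, "k_minus1"); chk(k2, "k2")
  chk(k_minus2, "k_minus2"); chk(Ka, "Ka"); chk(kcat, "kcat")
  if (!is.null(k2) && !is.null(k_minus2)) {
    if (k_minus2 <= 0) stop("'k_minus2' must be > 0 when binding is modeled")
    Ka_derived <- k2 / k_minus2
    if (!is.null(Ka)) {
      if (abs(Ka - Ka_derived) > 1e-9 * max(abs(Ka), abs(Ka_derived)))
        stop("'Ka' inconsistent with k2 / k_minus2 (relative tolerance 1e-9)")
    }
    Ka <- Ka_derived
  }
  if (!is.null(Ka) && Ka <= 0)
    stop("'Ka' must be > 0 when binding is modeled")
  structure(list(k1 = k1, k_minus1 = k_minus1, k2 = k2,
                 k_minus2 = k_minus2, Ka = Ka, kcat = kcat),
            class = "scheme_rates")
}

#' @export
print.scheme_rates <- function(x, ...) {
  cat("Folding-binding scheme rate constants\n")
  cat(sprintf("  k1      (folding)     : %g s^-1\n", x$k1))
  cat(sprintf("  k_minus1 (unfolding)  : %g s^-1\n", x$k_minus1))
  if (!is.null(x$Ka))
    cat(sprintf("  Ka      (association) : %g M^-1\n", x$Ka))
  if (!is.null(x$k2))
    cat(sprintf("  k2 = %g M^-1 s^-1, k_minus2 = %g s^-1\n",
                x$k2, x$k_minus2))
  if (isTRUE(x$kcat > 0))
    cat(sprintf("  kcat    (turnover)    : %g s^-1\n", x$kcat))
  invisible(x)
}

#' A folding free energy with provenance
#'
#' Sign convention: `delta_g` is the free energy of folding, so a
#' positive value means the unfolded state is favored.  This is the only
#' reading under which a destabilized caged enzyme (+2.4 kcal/mol) and a
#' stable bulk enzyme (-3.45 kcal/mol) are mutually consistent; see the
#' methods vignette.
#'
#' @param delta_g Folding free energy, kcal mol^-1.
#' @param temperature Kelvin.
#' @param source One of `"rates"`, `"denaturation"`, `"extrapolation"`.
#' @param uncertainty Standard uncertainty, kcal mol^-1 (`NA` if unknown).
#' @return An object of class `stability_result`.
#' @export
stability_result <- function(delta_g, temperature,
                             source = c("rates", "denaturation",
                                        "extrapolation"),
                             uncertainty = NA_real_) {
  source <- match.arg(source)
  stopifnot(is.numeric(delta_g), length(delta_g) == 1L, is.finite(delta_g),
            is.numeric(temperature), temperature > 0)
  structure(list(delta_g = delta_g, temperature = temperature,
                 source = source, uncertainty = uncertainty,
                 convention = "folding (positive = unfolded favored)"),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("Folding free energy: %.3f", x$delta_g))
  if (is.finite(x$uncertainty)) cat(sprintf(" +/- %.3f", x$uncertainty))
  cat(sprintf(" kcal/mol at %.2f K [%s]\n", x$temperature, x$source))
  cat(sprintf("  convention: %s\n", x$convention))
  invisible(x)
}

#' Lag-phase progress-curve model
#'
#' Product signal as a function of time for an activity assay with a
#' first-order lag: `P(t) = V t + A (exp(-lambda t) - 1)`.  `V` is the
#' steady-state slope, `A` the lag amplitude and `lambda` the lag rate
#' constant; the curve passes through the origin and approaches the
#' asymptote `V t - A`.
#'
#' @param t Time(s), seconds (>= 0, vectorized).
#' @param V Steady-state velocity, signal s^-1.
#' @param A Lag amplitude, signal units.
#' @param lam Lag rate constant, s^-1 (>= 0).
#' @return Signal values, same length as `t`.
#' @examples
#' lag_progress_model(1000, V = 2e-4, A = 0.05, lam = 4e-3)  # 0.15092
#' @export
lag_progress_model <- function(t, V, A, lam) {
  stopifnot(is.numeric(t), is.numeric(V), is.numeric(A), is.numeric(lam))
  if (any(t < 0)) stop("'t' must be >= 0")
  if (any(lam < 0)) stop("'lam' must be >= 0")
  V * t + A * (exp(-lam * t) - 1)
}

#' Observed lag rate constant as a function of substrate concentration
#'
#' Under conformational selection with binding fast relative to folding,
#' the relaxation rate of the lag phase is
#' `lambda(S) = k1 + k_minus1 / (Ka S + 1)`: it decreases from
#' `k1 + k_minus1` at zero substrate to `k1` at saturation.  An increase
#' of lambda with substrate would instead indicate induced fit or
#' substrate penetration.
#'
#' @param S Free substrate concentration(s), molar (>= 0, vectorized).
#' @param rates A [scheme_rates()] with `k1`, `k_minus1` and `Ka` set.
#' @return lambda in s^-1, same length as `S`.
#' @export
lambda_of_substrate <- function(S, rates) {
  stopifnot(inherits(rates, "scheme_rates"))
  if (is.null(rates$Ka)) stop("'rates$Ka' must be defined")
  if (any(S < 0)) stop("'S' must be >= 0")
  rates$k1 + rates$k_minus1 / (rates$Ka * S + 1)
}

#' Folding free energy from folding and unfolding rate constants
#'
#' `delta_g = R T log(k_minus1 / k1)` (kcal mol^-1, folding convention:
#' positive when unfolding is faster than folding).  Uncertainty is
#' propagated from the rate-constant standard errors either to first
#' order (delta method) or by Monte Carlo over log-normal rate draws.
#'
#' @param rates A [scheme_rates()] with `k1 > 0`, `k_minus1 > 0`.
#' @param consts A [physical_constants()].
#' @param k1_se,k_minus1_se Optional standard errors of the rates (s^-1).
#' @param method `"delta"` (first-order propagation, default) or
#'   `"mc"` (Monte Carlo).
#' @param n_mc,seed Monte Carlo sample size and seed (method `"mc"`).
#' @return A [stability_result()] with `source = "rates"`.
#' @examples
#' r <- scheme_rates(k1 = 1.4e-4, k_minus1 = 7.3e-3)
#' delta_g_from_rates(r)  # about 2.33 kcal/mol
#' @export
delta_g_from_rates <- function(rates, consts = physical_constants(),
                               k1_se = NULL, k_minus1_se = NULL,
                               method = c("delta", "mc"),
                               n_mc = 10000L, seed = NULL) {
  stopifnot(inherits(rates, "scheme_rates"),
            inherits(consts, "physical_constants"))
  method <- match.arg(method)
  if (rates$k1 <= 0 || rates$k_minus1 <= 0)
    stop("'k1' and 'k_minus1' must both be > 0")
  RT <- consts$R * consts$T
  dg <- RT * log(rates$k_minus1 / rates$k1)
  unc <- NA_real_
  if (!is.null(k1_se) || !is.null(k_minus1_se)) {
    s1 <- if (is.null(k1_se)) 0 else k1_se
    s2 <- if (is.null(k_minus1_se)) 0 else k_minus1_se
    if (method == "delta") {
      unc <- RT * sqrt((s1 / rates$k1)^2 + (s2 / rates$k_minus1)^2)
    } else {
      if (!is.null(seed)) set.seed(seed)
      # log-normal draws keep rates positive; moments matched on log scale
      draw <- function(mu, se) {
        cv2 <- (se / mu)^2
        sdlog <- sqrt(log1p(cv2))
        stats::rlnorm(n_mc, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
      }
      dgs <- RT * log(draw(rates$k_minus1, s2) / draw(rates$k1, s1))
      unc <- stats::sd(dgs)
    }
  }
  stability_result(dg, consts$T, source = "rates", uncertainty = unc)
}

#' Ligand-linkage shift of the folding free energy
#'
#' Saturating ligand stabilizes the folded state (Wyman linkage):
#' `delta_g(S) = delta_g0 - R T log(1 + S / Km)`.
#'
#' @param delta_g0 Folding free energy without ligand, kcal mol^-1.
#' @param S Ligand (cofactor) concentration, molar (>= 0, vectorized).
#' @param Km Michaelis constant of the ligand, molar (> 0).
#' @param consts A [physical_constants()].
#' @return Shifted free energy, kcal mol^-1.
#' @export
delta_g_ligand_shift <- function(delta_g0, S, Km,
                                 consts = physical_constants()) {
  stopifnot(is.numeric(delta_g0), is.numeric(S), is.numeric(Km),
            inherits(consts, "physical_constants"))
  if (Km <= 0) stop("'Km' must be > 0")
  if (any(S < 0)) stop("'S' must be >= 0")
  delta_g0 - consts$R * consts$T * log1p(S / Km)
}

#' Destabilization of the caged protein relative to bulk solution
#'
#' The difference `delta_g_cage - delta_g_bulk` (kcal mol^-1, folding
#' convention), with uncertainties combined in quadrature.  Both inputs
#' must refer to the same temperature within 0.5 K unless
#' `allow_temperature_mismatch = TRUE`.
#'
#' @param delta_g_cage,delta_g_bulk [stability_result()] objects.
#' @param allow_temperature_mismatch Override the temperature check.
#' @return A list with `ddg` (kcal mol^-1), `uncertainty` and the two
#'   inputs, of class `destabilization_result`.
#' @export
destabilization <- function(delta_g_cage, delta_g_bulk,
                            allow_temperature_mismatch = FALSE) {
  stopifnot(inherits(delta_g_cage, "stability_result"),
            inherits(delta_g_bulk, "stability_result"))
  dT <- abs(delta_g_cage$temperature - delta_g_bulk$temperature)
  if (dT > 0.5 && !allow_temperature_mismatch)
    stop(sprintf(
      "temperature mismatch (%.2f K vs %.2f K); set allow_temperature_mismatch = TRUE to override",
      delta_g_cage$temperature, delta_g_bulk$temperature))
  u <- sqrt(sum(c(delta_g_cage$uncertainty, delta_g_bulk$uncertainty)^2,
                na.rm = !all(is.na(c(delta_g_cage$uncertainty,
                                     delta_g_bulk$uncertainty)))))
  if (is.na(delta_g_cage$uncertainty) && is.na(delta_g_bulk$uncertainty))
    u <- NA_real_
  structure(list(ddg = delta_g_cage$delta_g - delta_g_bulk$delta_g,
                 uncertainty = u, cage = delta_g_cage, bulk = delta_g_bulk),
            class = "destabilization_result")
}

#' @export
print.destabilization_result <- function(x, ...) {
  cat(sprintf("Cage-vs-bulk destabilization: %.2f", x$ddg))
  if (is.finite(x$uncertainty)) cat(sprintf(" +/- %.2f", x$uncertainty))
  cat(" kcal/mol (folding convention)\n")
  invisible(x)
}
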