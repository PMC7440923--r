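# Generators for every input the pipeline consumes, with known ground
# truth, stated noise models and seeds.  Defaults mirror the assay
# conditions: 23 C, ~40 nM enzyme, 350 uM NADPH, 10-500 uM DHF.

#' Simulate the folding-binding-catalysis scheme by ODE integration
#'
#' Integrates
#' `dE_U/dt = -k1 E_U + k_minus1 E_F`,
#' `dE_F/dt = k1 E_U - k_minus1 E_F - k2 E_F S + k_minus2 ES + kcat ES`,
#' `dES/dt = k2 E_F S - k_minus2 ES - kcat ES`,
#' with substrate and cofactor depleted stoichiometrically and product
#' formed at `kcat ES` (catalysis regenerates the folded enzyme, so
#' total enzyme is conserved).  The enzyme starts at its folding
#' equilibrium with no substrate bound, as for a pre-equilibrated caged
#' enzyme at the moment substrates are added.  Cofactor consumption is
#' converted to an A340 trace through the optics configuration
#' (`A340(t) = A0 - delta_eps * path * (N0 - N(t))`, falling as NADPH is
#' consumed).
#'
#' @param rates A [scheme_rates()]; `k2` and `k_minus2` must be set.
#' @param E0 Total enzyme, molar (default 40e-9).
#' @param S0 Initial substrate (DHF), molar.
#' @param N0 Initial cofactor (NADPH), molar (default 350e-6).
#' @param t_grid Output times, seconds (first element is time zero).
#' @param optics An [optics_config()]; `A0 = NULL` uses
#'   `delta_eps * path * N0 + 0.05`.
#' @param noise_sd Gaussian noise SD added to the absorbance (AU; 0 for
#'   noiseless).
#' @param seed Seed used when `noise_sd > 0`.
#' @param clamp_substrate Hold free substrate constant
#'   (pseudo-first-order mode, used by analytic oracles).
#' @param rtol,atol Integrator tolerances (relative; absolute, molar).
#'   The absolute tolerance must sit well below the smallest species
#'   concentration (enzyme states are ~1e-11 M here), hence the 1e-18
#'   default.
#' @return List with `curve` (a [progress_curve()]), `states`
#'   (data.frame of the hidden trajectory, including `time_s`), and
#'   `truth` (parameters, seed, noise).
#' @export
simulate_scheme_ode <- function(rates, E0 = 40e-9, S0, N0 = 350e-6,
                                t_grid, optics = optics_config(),
                                noise_sd = 0, seed = NULL,
                                clamp_substrate = FALSE,
                                rtol = 1e-8, atol = 1e-18) {
  stopifnot(inherits(rates, "scheme_rates"),
            inherits(optics, "optics_config"))
  if (is.null(rates$k2) || is.null(rates$k_minus2))
    stop("'rates' must define k2 and k_minus2 for simulation")
  stopifnot(E0 >= 0, S0 >= 0, N0 >= 0, noise_sd >= 0)
  if (t_grid[1L] != 0) stop("'t_grid' must start at 0")
  ksum <- rates$k1 + rates$k_minus1
  EU0 <- if (ksum > 0) E0 * rates$k_minus1 / ksum else E0
  EF0 <- E0 - EU0
  y0 <- c(EU0, EF0, 0, S0, N0, 0)
  traj <- .scheme_ode_cpp(y0, t_grid, rates$k1, rates$k_minus1,
                          rates$k2, rates$k_minus2, rates$kcat,
                          clamp_substrate, rtol, atol, 5e7)
  states <- as.data.frame(traj)
  states$time_s <- t_grid
  eps_l <- optics$delta_eps * optics$path_cm
  A0 <- if (is.null(optics$A0)) eps_l * N0 + 0.05 else optics$A0
  a340 <- A0 - eps_l * (N0 - states$N)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    a340 <- a340 + rnorm(length(a340), 0, noise_sd)
  }
  curve <- progress_curve(t_grid, a340, substrate_conc = S0,
                          cofactor_conc = N0, enzyme_conc = E0,
                          label = sprintf("simulated S0=%g M", S0))
  list(curve = curve, states = states,
       truth = list(rates = rates, E0 = E0, S0 = S0, N0 = N0,
                    optics = optics, A0 = A0, noise_sd = noise_sd,
                    seed = seed, clamp_substrate = clamp_substrate,
                    lambda_expected = lambda_of_substrate(S0, rates)))
}

#' Simulate a lambda-versus-substrate series
#'
#' Direct sampling of `lambda(S) = k1 + k_minus1/(Ka S + 1)` with
#' multiplicative Gaussian noise of fractional standard deviation
#' `noise_frac`.
#'
#' @param rates A [scheme_rates()] with `Ka` defined.
#' @param S_list Distinct molar substrate concentrations.
#' @param noise_frac Fractional Gaussian noise (0 for noiseless).
#' @param seed Seed used when `noise_frac > 0`.
#' @return A [lambda_series()] with `lam_err` set to the true per-point
#'   sigma when noise is added; ground truth in `attr(, "truth")`.
#' @export
simulate_lambda_series <- function(rates, S_list, noise_frac = 0,
                                   seed = NULL) {
  stopifnot(inherits(rates, "scheme_rates"), noise_frac >= 0)
  if (anyDuplicated(S_list)) stop("'S_list' must be distinct")
  lam_true <- lambda_of_substrate(S_list, rates)
  lam <- lam_true
  lam_err <- NULL
  if (noise_frac > 0) {
    if (!is.null(seed)) set.seed(seed)
    sigma <- noise_frac * lam_true
    lam <- pmax(lam_true + rnorm(length(lam_true), 0, sigma),
                lam_true * 1e-3)
    lam_err <- sigma
  }
  out <- lambda_series(S_list, lam, lam_err)
  attr(out, "truth") <- list(rates = rates, noise_frac = noise_frac,
                             seed = seed, lam_true = lam_true)
  out
}

#' Simulate a chemical denaturation curve
#'
#' Two-state curve with linear baselines; the free energy at the stated
#' cofactor concentration follows the linkage relation
#' `delta_g = delta_g0 - RT log(1 + S/Km)`.  Gaussian noise with SD
#' equal to `noise_frac` times the noiseless signal range.
#'
#' @param delta_g0 Folding free energy at zero ligand, kcal/mol.
#' @param m m-value, kcal/mol/M (> 0).
#' @param D_grid Molar denaturant grid (increasing, >= 10 points).
#' @param ligand_conc Molar cofactor present (default 0).
#' @param Km Cofactor Michaelis constant, molar (default 13e-6).
#' @param baselines List with `F_N0`, `b`, `F_U0`, `a`.
#' @param noise_frac Fractional noise (of the signal range).
#' @param seed Seed used when `noise_frac > 0`.
#' @param consts A [physical_constants()].
#' @return A [denaturation_curve()]; ground truth in `attr(, "truth")`.
#' @export
simulate_denaturation_curve <- function(delta_g0, m, D_grid,
                                        ligand_conc = 0, Km = 13e-6,
                                        baselines = list(F_N0 = 100,
                                                         b = -2,
                                                         F_U0 = 40,
                                                         a = 1),
                                        noise_frac = 0, seed = NULL,
                                        consts = physical_constants()) {
  stopifnot(m > 0, noise_frac >= 0)
  dg <- delta_g_ligand_shift(delta_g0, ligand_conc, Km, consts)
  f <- two_state_denaturation_model(D_grid, dg, m, baselines$F_N0,
                                    baselines$b, baselines$F_U0,
                                    baselines$a, consts)
  sigma <- noise_frac * diff(range(f))
  if (noise_frac > 0) {
    if (!is.null(seed)) set.seed(seed)
    f <- f + rnorm(length(f), 0, sigma)
  }
  out <- denaturation_curve(D_grid, f, ligand_conc = ligand_conc,
                            temperature = consts$T)
  attr(out, "truth") <- list(delta_g0 = delta_g0,
                             delta_g_at_ligand = dg, m = m, Km = Km,
                             baselines = baselines, sigma = sigma,
                             noise_frac = noise_frac, seed = seed)
  out
}

#' Simulate a dye-based thermal melt
#'
#' Two-state apparent-equilibrium sigmoid with linear baselines:
#' the dye signal rises from the folded to the unfolded baseline with
#' midpoint `tm` and width `width` (the 10-90% transition spans about
#' 4.4 widths).  No claim is made of reproducing SYPRO photophysics.
#' Gaussian noise with SD `noise_frac` times the signal range.
#'
#' @param tm Midpoint temperature, deg C.
#' @param width Transition width parameter, deg C (> 0, default 2).
#' @param T_range Scan range, deg C (default c(4, 94)).
#' @param step Scan increment, deg C (default 0.5).
#' @param F_low,F_high Baseline intercepts (AU).
#' @param slope_low,slope_high Baseline slopes (AU per deg C).
#' @param noise_frac Fractional noise (of the signal range).
#' @param seed Seed used when `noise_frac > 0`.
#' @return A [melt_curve()]; ground truth in `attr(, "truth")`.
#' @export
simulate_melt_curve <- function(tm, width = 2, T_range = c(4, 94),
                                step = 0.5, F_low = 10, F_high = 100,
                                slope_low = 0.05, slope_high = -0.2,
                                noise_frac = 0, seed = NULL) {
  stopifnot(width > 0, step > 0, noise_frac >= 0)
  Tg <- seq(T_range[1L], T_range[2L], by = step)
  if (tm <= min(Tg) || tm >= max(Tg))
    stop("'tm' must lie inside the scanned range")
  frac <- plogis((Tg - tm) / width)
  f <- (F_low + slope_low * (Tg - T_range[1L])) * (1 - frac) +
    (F_high + slope_high * (Tg - tm)) * frac
  sigma <- noise_frac * diff(range(f))
  if (noise_frac > 0) {
    if (!is.null(seed)) set.seed(seed)
    f <- f + rnorm(length(f), 0, sigma)
  }
  out <- melt_curve(Tg, f, label = sprintf("simulated Tm=%g C", tm))
  attr(out, "truth") <- list(tm = tm, width = width, sigma = sigma,
                             noise_frac = noise_frac, seed = seed)
  out
}

#' Simulate polarized fluorescence decays
#'
#' Builds parallel and perpendicular intensity decays from a total
#' intensity `exp(-t/lifetime)` and anisotropy
#' `r(t) = r0 exp(-t/theta)`:
#' `I_par = I (1 + 2 r)/3`, `I_perp = I (1 - r)/(3 G)` (the measured
#' perpendicular channel is scaled by the sensitivity factor), binned
#' over a repetition window of `window` ns.  Expected counts are scaled
#' so the two channels sum to `total_counts`; Poisson noise is applied
#' per bin unless `noise = "none"`, in which case the continuous
#' expectations are returned.
#'
#' @param r0 Initial anisotropy (-0.2..0.4, default 0.35).
#' @param theta Rotational correlation time, ns.
#' @param lifetime Fluorescence lifetime, ns (default 2.8, eGFP-like).
#' @param total_counts Total detected photons (default 1e6).
#' @param G Polarization sensitivity factor (default 1).
#' @param window Repetition window, ns (default 50, i.e. 20 MHz).
#' @param n_bins Number of time bins (default 1000).
#' @param background_frac Constant background per channel as a fraction
#'   of that channel's mean expected counts (default 0).
#' @param noise `"poisson"` (default) or `"none"`.
#' @param seed Seed used for Poisson sampling.
#' @return An [anisotropy_decay()]; ground truth in `attr(, "truth")`.
#' @export
simulate_anisotropy <- function(r0 = 0.35, theta, lifetime = 2.8,
                                total_counts = 1e6, G = 1, window = 50,
                                n_bins = 1000L, background_frac = 0,
                                noise = c("poisson", "none"),
                                seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(r0 >= -0.2, r0 <= 0.4, theta > 0, lifetime > 0,
            total_counts > 0, G > 0, window > 0, background_frac >= 0)
  t <- (seq_len(n_bins) - 0.5) * window / n_bins
  I <- exp(-t / lifetime)
  r <- r0 * exp(-t / theta)
  par_shape <- I * (1 + 2 * r) / 3
  perp_shape <- I * (1 - r) / (3 * G)
  scale <- total_counts / sum(par_shape + perp_shape)
  mu_par <- par_shape * scale + background_frac * mean(par_shape * scale)
  mu_perp <- perp_shape * scale +
    background_frac * mean(perp_shape * scale)
  if (noise == "poisson") {
    if (!is.null(seed)) set.seed(seed)
    I_par <- rpois(n_bins, mu_par)
    I_perp <- rpois(n_bins, mu_perp)
  } else {
    I_par <- mu_par
    I_perp <- mu_perp
  }
  out <- anisotropy_decay(t, I_par, I_perp, G = G,
                          background_par = background_frac *
                            mean(par_shape * scale),
                          background_perp = background_frac *
                            mean(perp_shape * scale))
  attr(out, "truth") <- list(r0 = r0, theta = theta,
                             lifetime = lifetime,
                             total_counts = total_counts, G = G,
                             window = window, noise = noise,
                             seed = seed)
  out
}
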