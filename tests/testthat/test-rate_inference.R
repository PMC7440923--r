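test_that("lambda_series validates and pools duplicates", {
  expect_error(lambda_series(c(-1e-6, 1e-6), c(1, 1)), ">= 0")
  expect_error(lambda_series(c(1e-6, 2e-6), c(0, 1)), "> 0")
  ser <- lambda_series(c(1e-5, 1e-5, 2e-5, 3e-5, 4e-5),
                       c(1.0, 1.2, 0.9, 0.8, 0.7) * 1e-3,
                       rep(1e-4, 5))
  pooled <- cagefold:::.pool_duplicates(ser)
  expect_equal(length(pooled$S), 4L)
  expect_equal(pooled$lam[pooled$S == 1e-5], 1.1e-3)
  expect_equal(pooled$lam_err[pooled$S == 1e-5],
               sqrt(2 * 1e-8) / 2)
})

test_that("noiseless lambda(S) fits recover the rates exactly", {
  ser <- simulate_lambda_series(ref_rates(), s_grid8)
  fit <- fit_lambda_curve(ser)
  expect_equal(fit$rates$k1, 1.4e-4, tolerance = 1e-6)
  expect_equal(fit$rates$k_minus1, 7.3e-3, tolerance = 1e-6)
  expect_equal(fit$rates$Ka, 3571, tolerance = 1e-6)
  expect_lt(fit$reduced_chi2, 1e-12)
  expect_true(all(fit$identifiable))
})

test_that("a flat lambda series flags k_minus1 and Ka unidentifiable", {
  set.seed(3)
  lam <- 1.4e-4 * (1 + rnorm(8, 0, 0.02))
  ser <- lambda_series(s_grid8, lam, rep(1.4e-4 * 0.02, 8))
  fit <- fit_lambda_curve(ser)
  expect_false(fit$identifiable[["Ka"]])
  expect_false(fit$identifiable[["k_minus1"]])
  expect_lt(fit$rates$k_minus1, 0.1 * max(ser$lam))
})

test_that("fits are equivariant under rescaling substrate units", {
  set.seed(6)
  ser <- simulate_lambda_series(ref_rates(), s_grid8, noise_frac = 0.05,
                                seed = 99)
  f1 <- fit_lambda_curve(ser)
  ser2 <- lambda_series(ser$S * 1000, ser$lam, ser$lam_err)
  f2 <- fit_lambda_curve(ser2)
  expect_equal(f2$rates$k1, f1$rates$k1, tolerance = 1e-5)
  expect_equal(f2$rates$k_minus1, f1$rates$k_minus1, tolerance = 1e-5)
  expect_equal(f2$rates$Ka, f1$rates$Ka / 1000, tolerance = 1e-4)
  expect_equal(lambda_of_substrate(ser2$S, f2$rates),
               lambda_of_substrate(ser$S, f1$rates), tolerance = 1e-6)
})

test_that("chi2 surface is consistent with the fit and brute-force profiles", {
  ser <- simulate_lambda_series(ref_rates(), s_grid8, noise_frac = 0.05,
                                seed = 17)
  fit <- fit_lambda_curve(ser)
  surf <- chi2_surface(ser, fit, grid_spec = list(n = 15L, span = 3))
  # global minimum equals the fit's reduced chi2
  expect_equal(surf$minimum$value, fit$reduced_chi2, tolerance = 1e-6)
  # profile is non-decreasing moving away from the minimum along axes
  i0 <- surf$minimum$i; j0 <- surf$minimum$j
  row <- surf$reduced_chi2[, j0]; col <- surf$reduced_chi2[i0, ]
  slack <- 1e-9 * max(row)
  expect_true(all(diff(row[i0:length(row)]) >= -slack))
  expect_true(all(diff(rev(row[1:i0])) >= -slack))
  expect_true(all(diff(col[j0:length(col)]) >= -slack))
  expect_true(all(diff(rev(col[1:j0])) >= -slack))
  # brute-force oracle at a few nodes: dense grid search over Ka
  w <- 1 / ser$lam_err^2
  for (idx in list(c(3L, 5L), c(10L, 12L), c(8L, 2L))) {
    k1 <- surf$k1[idx[1L]]; km1 <- surf$k_minus1[idx[2L]]
    lka <- seq(log(1e-3 / max(ser$S)), log(1e4 / min(ser$S)),
               length.out = 4000)
    brute <- min(vapply(lka, function(l) {
      g <- 1 / (exp(l) * ser$S + 1)
      sum(w * (ser$lam - k1 - km1 * g)^2)
    }, 0)) / fit$dof
    # brute grid is the coarser of the two; agree to its resolution
    expect_equal(surf$reduced_chi2[idx[1L], idx[2L]], brute,
                 tolerance = 1e-3)
  }
  # grid that excludes the minimum errors out
  expect_error(chi2_surface(ser, fit, grid_spec = list(n = 5L, span = 2)),
               "at least")
})

test_that("profile intervals behave sensibly (coverage, containment)", {
  # k_minus1 is well identified: delta-chi2 = 1 intervals should show
  # ~68% coverage.  k1 sits against the non-negativity boundary in this
  # design (see the methods vignette): truncation makes its intervals
  # conservative, so only a lower bound on coverage is asserted.
  set.seed(12)
  res <- t(replicate(120, {
    ser <- simulate_lambda_series(ref_rates(), s_grid8,
                                  noise_frac = 0.05,
                                  seed = sample.int(1e7, 1))
    fit <- fit_lambda_curve(ser)
    ci <- confint_lambda(fit)
    c(ci["k1", 1L] <= 1.4e-4 && 1.4e-4 <= ci["k1", 2L],
      ci["k_minus1", 1L] <= 7.3e-3 && 7.3e-3 <= ci["k_minus1", 2L],
      ci["k1", 1L] <= fit$rates$k1 && fit$rates$k1 <= ci["k1", 2L],
      ci["k_minus1", 1L] <= fit$rates$k_minus1 &&
        fit$rates$k_minus1 <= ci["k_minus1", 2L])
  }))
  expect_gte(mean(res[, 2L]), 0.56)
  expect_lte(mean(res[, 2L]), 0.80)
  expect_gte(mean(res[, 1L]), 0.60)
  # intervals always contain the point estimates
  expect_true(all(res[, 3L]))
  expect_true(all(res[, 4L]))
})

test_that("mechanism classification separates the three regimes", {
  # decreasing lambda(S): conformational selection (reference rates)
  ser <- simulate_lambda_series(ref_rates(), s_grid8, noise_frac = 0.05,
                                seed = 2)
  expect_identical(classify_mechanism(ser)$mechanism,
                   "conformational_selection")
  # increasing saturating curve: induced fit / penetration
  lam_up <- 2e-3 + 5e-3 * s_grid8 / (s_grid8 + 1e-4)
  ser_up <- lambda_series(s_grid8, lam_up * (1 + 0.02 * sin(1:8)))
  expect_identical(classify_mechanism(ser_up)$mechanism,
                   "induced_fit_or_penetration")
  # flat null: mostly indeterminate
  set.seed(9)
  frac <- mean(replicate(60, {
    ser0 <- lambda_series(s_grid8, 4e-3 * (1 + rnorm(8, 0, 0.05)),
                          rep(2e-4, 8))
    classify_mechanism(ser0)$mechanism == "indeterminate"
  }))
  expect_gte(frac, 0.85)
})

test_that("two-stage pipeline recovers the simulator's rates (noiseless)", {
  # deep fast-binding, pseudo-first-order, slow-turnover regime: the
  # conditions under which the closed-form lambda(S) is exact enough for
  # k1 (a 2% perturbation on lambda) to survive the chain
  rates <- fast_rates(km2 = 5000, kcat = 0.01)
  lam_hat <- vapply(s_grid8, function(S0) {
    lam <- lambda_of_substrate(S0, rates)
    sim <- simulate_scheme_ode(rates, S0 = S0,
                               t_grid = seq(0, 5 / lam,
                                            length.out = 600),
                               clamp_substrate = TRUE)
    fit_progress_curve(sim$curve)$lam
  }, 0)
  fit <- fit_lambda_curve(lambda_series(s_grid8, lam_hat))
  expect_equal(fit$rates$k1, rates$k1, tolerance = 0.10)
  expect_equal(fit$rates$k_minus1, rates$k_minus1, tolerance = 0.10)
  # delta G from the fitted rates lies inside the profile-interval box
  ci <- confint_lambda(fit)
  consts <- physical_constants()
  dg <- delta_g_from_rates(fit$rates, consts)$delta_g
  RT <- consts$R * consts$T
  expect_gte(dg, RT * log(ci["k_minus1", 1L] / max(ci["k1", 2L], 1e-12)))
  expect_lte(dg, RT * log(ci["k_minus1", 2L] / max(ci["k1", 1L], 1e-12)))
})
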