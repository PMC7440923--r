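test_that("progress_curve enforces its invariants", {
  expect_error(progress_curve(1:5, 1:5), "at least 10")
  expect_error(progress_curve(c(1:9, 9), rnorm(10)),
               "strictly increasing")
  expect_error(progress_curve(1:10, c(rnorm(9), NA)), "non-finite")
})

test_that("fit window stops before substrate depletion (ODE oracle)", {
  # high-turnover regime so the cofactor is consumed appreciably
  rates <- scheme_rates(k1 = 1.4e-4, k_minus1 = 7.3e-3,
                        k2 = 3571 * 2000, k_minus2 = 2000, kcat = 20)
  S0 <- 20e-6
  sim <- simulate_scheme_ode(rates, S0 = S0, N0 = 350e-6,
                             t_grid = seq(0, 10000, length.out = 400))
  # oracle from the hidden trajectory: consumption crossing 10% of the
  # limiting-substrate stoichiometric signal change
  optics <- optics_config()
  consumed <- (350e-6 - sim$states$N) * optics$delta_eps * optics$path_cm
  oracle_last <- which(consumed > 0.10 * S0 * optics$delta_eps *
                         optics$path_cm)[1L] - 1L
  expect_false(is.na(oracle_last))  # depletion does occur
  win <- select_fit_window(sim$curve, 0.10, optics)
  expect_lte(abs(win[2L] - oracle_last), 1L)
  # a curve with no depletion keeps the full range
  sim0 <- simulate_scheme_ode(fast_rates(kcat = 0), S0 = S0,
                              t_grid = seq(0, 1000, length.out = 50))
  expect_equal(select_fit_window(sim0$curve), c(1L, 50L))
})

test_that("noiseless lag-model curves are recovered exactly", {
  tt <- seq(0, 1500, length.out = 120)
  y <- lag_progress_model(tt, 2e-4, 0.05, 4e-3)
  f <- fit_progress_curve(progress_curve(tt, y))
  expect_equal(f$V, 2e-4, tolerance = 1e-6)
  expect_equal(f$A, 0.05, tolerance = 1e-6)
  expect_equal(f$lam, 4e-3, tolerance = 1e-6)
  expect_true(f$lag_detected)
  # orientation: the same curve as a falling A340 trace
  f2 <- fit_progress_curve(progress_curve(tt, 1.1 - y))
  expect_equal(f2$lam, 4e-3, tolerance = 1e-6)
  expect_equal(f2$orientation, -1)
})

test_that("lag detection separates lagged from lag-free curves", {
  # the 2-standard-error rule has a ~5% two-sided false-positive rate by
  # construction; assert the rates, not a single draw
  set.seed(31)
  tt <- seq(0, 1500, length.out = 100)
  fp <- mean(replicate(60, {
    y <- 2e-4 * tt + rnorm(100, 0, 2e-4)
    fit_progress_curve(progress_curve(tt, y))$lag_detected
  }))
  tp <- mean(replicate(30, {
    y <- lag_progress_model(tt, 2e-4, 0.05, 4e-3) + rnorm(100, 0, 2e-4)
    fit_progress_curve(progress_curve(tt, y))$lag_detected
  }))
  expect_lte(fp, 0.15)
  expect_gte(tp, 0.95)
})

test_that("fitting is invariant to a constant signal baseline", {
  set.seed(5)
  tt <- seq(0, 1500, length.out = 90)
  y <- lag_progress_model(tt, 2e-4, 0.05, 4e-3) + rnorm(90, 0, 3e-4)
  f1 <- fit_progress_curve(progress_curve(tt, y))
  f2 <- fit_progress_curve(progress_curve(tt, y + 0.735))
  # identical up to the float rounding of the added constant
  expect_equal(f1$V, f2$V, tolerance = 1e-6)
  expect_equal(f1$A, f2$A, tolerance = 1e-6)
  expect_equal(f1$lam, f2$lam, tolerance = 1e-6)
})

test_that("fitted V on a pure-linear curve equals the OLS slope", {
  tt <- seq(0, 1000, length.out = 40)
  y <- 3e-4 * tt
  # "essentially perfect fit" summary warning is expected on exact data
  f <- suppressWarnings(fit_progress_curve(progress_curve(tt, y)))
  ols <- unname(coef(lm(y ~ tt))[2L])
  expect_lt(abs(f$V - ols), 1e-10 * abs(ols))
})

test_that("reduced chi2 is calibrated on correctly specified data", {
  set.seed(2)
  tt <- seq(0, 1500, length.out = 80)
  rc <- replicate(200, {
    y <- lag_progress_model(tt, 2e-4, 0.05, 4e-3) + rnorm(80, 0, 5e-4)
    fit_progress_curve(progress_curve(tt, y), sigma = 5e-4)$reduced_chi2
  })
  expect_gte(mean(rc > 0.7 & rc < 1.3), 0.9)
})

test_that("runs test flags pathological residuals and passes honest ones", {
  expect_false(residual_randomness(rep(c(1, -1), 15))$passed)
  expect_false(residual_randomness(rep(1, 25))$passed)
  expect_error(residual_randomness(rnorm(10)), "at least 20")
  set.seed(4)
  tt <- seq(0, 1500, length.out = 80)
  ok <- replicate(100, {
    y <- lag_progress_model(tt, 2e-4, 0.05, 4e-3) + rnorm(80, 0, 5e-4)
    residual_randomness(fit_progress_curve(progress_curve(tt, y)))$passed
  })
  expect_gte(mean(ok), 0.9)
})

test_that("Michaelis-Menten fits recover known kinetics", {
  S <- c(5, 15, 33, 100, 300) * 1e-6
  for (truth in list(c(Vmax = 1, Km = 33e-6),
                     c(Vmax = 2.5e-4, Km = 0.28e-3))) {
    V <- truth[["Vmax"]] * S / (truth[["Km"]] + S)
    mm <- fit_michaelis_menten(S, V)
    expect_equal(mm$Vmax, truth[["Vmax"]], tolerance = 1e-6)
    expect_equal(mm$Km, truth[["Km"]], tolerance = 1e-6)
  }
  expect_error(fit_michaelis_menten(S[1:3], rep(1, 3)), "4 distinct")
})

test_that("degenerate Michaelis-Menten designs are flagged", {
  S <- c(5, 15, 33, 100, 300) * 1e-6
  expect_warning(mm <- fit_michaelis_menten(S, rep(1, 5)), "degenerate")
  expect_false(mm$identifiable)
  # narrow concentration range flagged
  Sn <- c(30, 35, 40, 45) * 1e-6
  expect_warning(fit_michaelis_menten(Sn, 1 * Sn / (33e-6 + Sn)),
                 "5-fold")
})
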