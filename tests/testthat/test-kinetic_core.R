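test_that("scheme_rates validates inputs and the Ka identity", {
  r <- scheme_rates(k1 = 1.4e-4, k_minus1 = 7.3e-3, k2 = 3571 * 500,
                    k_minus2 = 500)
  expect_equal(r$Ka, 3571, tolerance = 1e-12)
  expect_error(scheme_rates(k1 = -1, k_minus1 = 1), ">= 0")
  expect_error(scheme_rates(k1 = 1, k_minus1 = 1, k2 = 10, k_minus2 = 1,
                            Ka = 11), "inconsistent")
  # consistent triple accepted
  expect_silent(scheme_rates(k1 = 1, k_minus1 = 1, k2 = 10,
                             k_minus2 = 2, Ka = 5))
})

test_that("lag progress model matches direct evaluation and its limits", {
  expect_identical(lag_progress_model(0, 2e-4, 0.05, 4e-3), 0)
  expect_equal(lag_progress_model(c(0, 0), 1, 2, 3), c(0, 0))
  # direct evaluation oracle
  expect_equal(lag_progress_model(1000, 2e-4, 0.05, 4e-3),
               2e-4 * 1000 + 0.05 * (exp(-4) - 1), tolerance = 1e-12)
  # linear asymptote with intercept -A once lam * t >> 1
  t_big <- 1e5
  expect_equal(lag_progress_model(t_big, 2e-4, 0.05, 4e-3),
               2e-4 * t_big - 0.05, tolerance = 1e-12)
  expect_error(lag_progress_model(-1, 1, 1, 1), "must be >= 0")
  expect_error(lag_progress_model(1, 1, 1, -1), "must be >= 0")
})

test_that("lambda(S) closed form: limits, oracle value, monotonicity", {
  r <- ref_rates()
  expect_equal(lambda_of_substrate(0, r), r$k1 + r$k_minus1)
  expect_equal(lambda_of_substrate(1e6, r), r$k1, tolerance = 1e-6)
  # direct evaluation oracle at the reference conditions
  expect_equal(lambda_of_substrate(250e-6, r),
               1.4e-4 + 7.3e-3 / (3571 * 250e-6 + 1), tolerance = 1e-12)
  expect_equal(lambda_of_substrate(250e-6, r), 3.997e-3,
               tolerance = 1e-3)
  # strictly decreasing over a grid
  lam <- lambda_of_substrate(seq(0, 1e-3, length.out = 200), r)
  expect_true(all(diff(lam) < 0))
  expect_error(lambda_of_substrate(-1e-6, r), ">= 0")
})

test_that("delta G from rates: reference value, symmetry, round trip", {
  consts <- physical_constants()
  dg <- delta_g_from_rates(ref_rates(), consts)
  # printed reference: 2.4 +/- 0.2 kcal/mol
  expect_gt(dg$delta_g, 2.2)
  expect_lt(dg$delta_g, 2.6)
  expect_equal(dg$delta_g, consts$R * consts$T * log(7.3e-3 / 1.4e-4),
               tolerance = 1e-12)
  # equal rates -> exactly zero
  expect_identical(delta_g_from_rates(
    scheme_rates(k1 = 5e-3, k_minus1 = 5e-3), consts)$delta_g, 0)
  # antisymmetry under swapping the rates
  sw <- delta_g_from_rates(scheme_rates(k1 = 7.3e-3, k_minus1 = 1.4e-4),
                           consts)
  expect_equal(sw$delta_g, -dg$delta_g, tolerance = 1e-12)
  # round trip: rates built from a target free energy recover it
  for (dg0 in c(-3.45, -1, 0.5, 2.4)) {
    k1 <- 1e-3
    km1 <- k1 * exp(dg0 / (consts$R * consts$T))
    rt <- delta_g_from_rates(scheme_rates(k1 = k1, k_minus1 = km1),
                             consts)
    expect_equal(rt$delta_g, dg0, tolerance = 1e-9)
  }
  expect_error(delta_g_from_rates(scheme_rates(k1 = 0, k_minus1 = 1)),
               "> 0")
})

test_that("delta-method and Monte-Carlo uncertainties agree", {
  dg_d <- delta_g_from_rates(ref_rates(), k1_se = 0.4e-4,
                             k_minus1_se = 0.8e-3)
  dg_m <- delta_g_from_rates(ref_rates(), k1_se = 0.4e-4,
                             k_minus1_se = 0.8e-3, method = "mc",
                             seed = 7, n_mc = 20000L)
  expect_equal(dg_d$uncertainty, 0.2, tolerance = 0.15)
  expect_equal(dg_m$uncertainty, dg_d$uncertainty, tolerance = 0.15)
})

test_that("ligand-linkage shift: limits, half-saturation, identity", {
  consts <- physical_constants()
  RT <- consts$R * consts$T
  expect_identical(delta_g_ligand_shift(-3.45, 0, 13e-6), -3.45)
  # S = Km shifts by exactly -RT log 2
  expect_equal(delta_g_ligand_shift(0, 13e-6, 13e-6), -RT * log(2),
               tolerance = 1e-12)
  expect_equal(-RT * log(2), -0.408, tolerance = 1e-3)
  # direct evaluation oracle
  expect_equal(delta_g_ligand_shift(-3.45, 500e-6, 13e-6),
               -3.45 - RT * log(1 + 500 / 13), tolerance = 1e-12)
  expect_equal(delta_g_ligand_shift(-3.45, 500e-6, 13e-6), -5.61,
               tolerance = 1e-3)
  # exact linkage identity: shift + RT log(1 + S/Km) constant in S
  S <- c(0, 1e-6, 13e-6, 1e-4, 1e-3)
  v <- delta_g_ligand_shift(-3.45, S, 13e-6) + RT * log1p(S / 13e-6)
  expect_equal(v, rep(-3.45, length(S)), tolerance = 1e-12)
  expect_error(delta_g_ligand_shift(0, 1e-6, 0), "> 0")
})

test_that("destabilization combines stabilities and their errors", {
  cage <- stability_result(2.4, 296.15, "rates", 0.2)
  bulk <- stability_result(-3.45, 296.15, "extrapolation", 0.09)
  d <- destabilization(cage, bulk)
  expect_equal(d$ddg, 5.85, tolerance = 1e-12)
  expect_equal(d$uncertainty, sqrt(0.2^2 + 0.09^2), tolerance = 1e-12)
  expect_gt(d$ddg, 5)  # "more than five kcal/mol"
  # composition with the rate-derived cage value
  cage2 <- delta_g_from_rates(ref_rates())
  expect_equal(destabilization(cage2, bulk)$ddg, 5.78, tolerance = 1e-2)
  expect_equal(destabilization(cage, cage)$ddg, 0)
  warm <- stability_result(-3.45, 298.15, "extrapolation")
  expect_error(destabilization(cage, warm), "temperature mismatch")
  expect_silent(destabilization(cage, warm,
                                allow_temperature_mismatch = TRUE))
})

test_that("closed forms agree with a second arithmetic path to 1e-12", {
  r <- ref_rates()
  consts <- physical_constants()
  S <- c(1e-6, 5e-5, 2.5e-4, 1e-3)
  # lambda via Ka and via (k2, k_minus2) written differently
  alt <- r$k1 + r$k_minus1 * (1 / (1 + exp(log(3571) + log(S))))
  expect_equal(lambda_of_substrate(S, r), alt, tolerance = 1e-12)
  # delta G via log ratio vs difference of logs
  expect_equal(delta_g_from_rates(r, consts)$delta_g,
               consts$R * consts$T * (log(r$k_minus1) - log(r$k1)),
               tolerance = 1e-12)
})
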