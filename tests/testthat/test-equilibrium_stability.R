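consts23 <- physical_constants()

test_that("two-state model limits, midpoint symmetry and oracle value", {
  D <- seq(0, 4, by = 0.25)
  # deeply stable protein: pure native baseline
  expect_equal(two_state_denaturation_model(D, -50, 2, 100, -2, 40, 1,
                                            consts23),
               100 - 2 * D, tolerance = 1e-10)
  # deeply unstable: pure unfolded baseline
  expect_equal(two_state_denaturation_model(D, 50, 2, 100, -2, 40, 1,
                                            consts23),
               40 + 1 * D, tolerance = 1e-10)
  # at the midpoint the signal is the exact mean of the baselines
  dg <- -3.45; m <- 2; Dh <- -dg / m
  expect_equal(two_state_denaturation_model(Dh, dg, m, 100, -2, 40, 1,
                                            consts23),
               ((100 - 2 * Dh) + (40 + 1 * Dh)) / 2, tolerance = 1e-12)
  # direct evaluation oracle at D = 1.725 M
  expect_equal(two_state_denaturation_model(1.725, -3.45, 2, 100, -2,
                                            40, 1, consts23),
               (41.725 + 96.55) / 2, tolerance = 1e-6)
})

test_that("noiseless denaturation curves are recovered exactly", {
  cv <- simulate_denaturation_curve(-3.45, 2,
                                    seq(0, 4, length.out = 25))
  fit <- fit_denaturation(cv)
  expect_equal(fit$delta_g0, -3.45, tolerance = 1e-6)
  expect_equal(fit$m, 2, tolerance = 1e-6)
  expect_equal(fit$F_N0, 100, tolerance = 1e-6)
  expect_equal(fit$b, -2, tolerance = 1e-5)
  expect_equal(fit$F_U0, 40, tolerance = 1e-5)
  expect_equal(fit$a, 1, tolerance = 1e-5)
  # algebraic midpoint identity
  expect_equal(fit$d_half * fit$m + fit$delta_g0, 0, tolerance = 1e-9)
  expect_true(fit$baseline_resolved)
})

test_that("truncated curves without an unfolded baseline are flagged", {
  cv <- simulate_denaturation_curve(-3.45, 2,
                                    seq(0, 2.0, length.out = 15))
  w <- capture_warnings(fit <- fit_denaturation(cv))
  expect_true(any(grepl("unresolved", w)))
  expect_false(fit$baseline_resolved)
})

test_that("fit is invariant under affine rescaling of the fluorescence", {
  cv <- simulate_denaturation_curve(-3.45, 2, seq(0, 4, length.out = 25),
                                    noise_frac = 0.01, seed = 21)
  f1 <- suppressWarnings(fit_denaturation(cv))
  cv2 <- denaturation_curve(cv$D, 3.2 * cv$F_signal + 17,
                            cv$ligand_conc, cv$temperature)
  f2 <- suppressWarnings(fit_denaturation(cv2))
  expect_equal(f2$delta_g0, f1$delta_g0, tolerance = 1e-4)
  expect_equal(f2$m, f1$m, tolerance = 1e-4)
  expect_equal(f2$F_N0, 3.2 * f1$F_N0 + 17, tolerance = 1e-3)
})

test_that("noisy recovery is consistent with the information bound", {
  # At 25 points over 0-4 M with noise = 1% of the signal range, the
  # Fisher bound for delta_g0 is ~0.2 kcal/mol (see methods vignette);
  # the fit should be unbiased and not much worse than that bound.
  set.seed(14)
  errs <- replicate(60, {
    cv <- simulate_denaturation_curve(
      -4.94, 2, seq(0, 4, length.out = 25), noise_frac = 0.01,
      seed = sample.int(1e7, 1))
    suppressWarnings(fit_denaturation(cv))$delta_g0 - (-4.94)
  })
  expect_lt(abs(mean(errs)), 0.10)
  expect_lt(sd(errs), 0.35)
  expect_gt(sd(errs), 0.08)
})

test_that("ligand-linkage identity holds across cofactor levels", {
  RT <- consts23$R * consts23$T
  fits <- lapply(c(50e-6, 400e-6), function(s)
    fit_denaturation(simulate_denaturation_curve(
      -3.45, 2, seq(0, 5, length.out = 31), ligand_conc = s)))
  expect_equal(fits[[1L]]$delta_g0 - fits[[2L]]$delta_g0,
               -RT * log((1 + 50 / 13) / (1 + 400 / 13)),
               tolerance = 1e-5)
})

test_that("extrapolation to zero ligand recovers the reference value", {
  fits <- lapply(c(50e-6, 150e-6, 400e-6), function(s)
    fit_denaturation(simulate_denaturation_curve(
      -3.45, 2, seq(0, 5, length.out = 31), ligand_conc = s)))
  ex <- extrapolate_ligand_series(fits)
  expect_equal(ex$delta_g, -3.45, tolerance = 1e-6)
  expect_identical(ex$source, "extrapolation")
  # all measurements at zero ligand: weighted mean
  df <- data.frame(ligand_conc = c(0, 0, 0),
                   delta_g0 = c(-3.3, -3.5, -3.4),
                   se = c(0.1, 0.1, 0.2))
  ex0 <- extrapolate_ligand_series(df)
  expect_equal(ex0$delta_g,
               weighted.mean(df$delta_g0, 1 / df$se^2), tolerance = 1e-12)
  # single point: algebraic inversion with the input error
  df1 <- data.frame(ligand_conc = 150e-6, delta_g0 = -4.94, se = 0.12)
  ex1 <- extrapolate_ligand_series(df1)
  RT <- consts23$R * consts23$T
  expect_equal(ex1$delta_g, -4.94 + RT * log(1 + 150 / 13),
               tolerance = 1e-12)
  expect_equal(ex1$uncertainty, 0.12)
})

test_that("melt curves: midpoint recovery, refinement, error modes", {
  # symmetric sigmoid with flat baselines: derivative extremum at the
  # exact midpoint
  cv <- simulate_melt_curve(50.25, width = 3, slope_low = 0,
                            slope_high = 0)
  tm <- melting_temperature(cv)
  expect_equal(tm$tm, 50.25, tolerance = 0.05)
  expect_false(tm$ambiguous)
  # strictly linear signal: no transition
  lin <- melt_curve(seq(4, 94, by = 0.5),
                    10 + 0.3 * seq(4, 94, by = 0.5))
  expect_error(melting_temperature(lin), "no transition")
  # two comparable transitions are reported and flagged
  Tg <- seq(4, 94, by = 0.5)
  f2 <- 100 * plogis((Tg - 30) / 2) + 95 * plogis((Tg - 70) / 2)
  tm2 <- melting_temperature(melt_curve(Tg, f2))
  expect_true(tm2$ambiguous)
  expect_equal(nrow(tm2$all_peaks), 2L)
  expect_equal(sort(tm2$all_peaks$tm), c(30, 70), tolerance = 0.03)
  # melt grid validation
  expect_error(melt_curve(c(1, 2, 4, 8, 16, 32, 40, 50, 60, 70, 80),
                          rnorm(11)), "uniform")
})
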