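# Shared fixtures: the reference rate constants of the caged enzyme
# (k1 = 1.4e-4 s^-1, k_minus1 = 7.3e-3 s^-1, Ka = 3571 M^-1) and small
# analytic oracles used against the ODE simulator.

ref_rates <- function() scheme_rates(k1 = 1.4e-4, k_minus1 = 7.3e-3,
                                     Ka = 3571)

# simulation regimes: binding fast relative to folding, catalysis slow
# relative to dissociation (the regime in which the closed-form lambda
# holds)
fast_rates <- function(km2 = 500, kcat = 0.1)
  scheme_rates(k1 = 1.4e-4, k_minus1 = 7.3e-3, k2 = 3571 * km2,
               k_minus2 = km2, kcat = kcat)

s_grid8 <- exp(seq(log(10e-6), log(500e-6), length.out = 8))

# Analytic solution of the clamped (pseudo-first-order) linear
# three-state system via eigendecomposition -- an independent oracle for
# the ODE integrator.
relax_analytic <- function(rates, S, E0, times) {
  k1 <- rates$k1; km1 <- rates$k_minus1
  k2 <- rates$k2; km2 <- rates$k_minus2; kcat <- rates$kcat
  M <- matrix(c(-k1, km1, 0,
                k1, -(km1 + k2 * S), km2 + kcat,
                0, k2 * S, -(km2 + kcat)), 3, 3, byrow = TRUE)
  ev <- eigen(M)
  y0 <- c(E0 * km1 / (k1 + km1), E0 * k1 / (k1 + km1), 0)
  co <- solve(ev$vectors, y0)
  t(sapply(times, function(t)
    Re(ev$vectors %*% (co * exp(ev$values * t)))))
}
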