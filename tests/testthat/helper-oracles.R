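# Independent oracles and shared fixtures for the test suite.
# Everything here is deliberately naive (interval halving, finite
# differences, direct grid counting) so it cannot share a defect with
# the package's own code paths.

# closed-form stable equilibria of the canonical symmetric model
# (gamma = 3, delta = 1, h = 2): A and P are (3 +- sqrt(5))/2
phi_hi <- (3 + sqrt(5)) / 2
phi_lo <- (3 - sqrt(5)) / 2

# plain interval-halving root finder, independent of the package's solver
oracle_bisect <- function(f, lo, hi, iter = 120L) {
  flo <- f(lo)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (sign(f(mid)) == sign(flo)) { lo <- mid; flo <- f(mid) } else hi <- mid
  }
  (lo + hi) / 2
}

# saddle of the canonical model: A solves A^3 + A - 3 = 0
saddle_A <- oracle_bisect(function(x) x^3 + x - 3, 0, 3)

# unique equilibrium of the subcritical symmetric model (gamma = 1):
# x (1 + x^2) = 1
subcrit_A <- oracle_bisect(function(x) x * (1 + x^2) - 1, 0, 1)

canonical   <- reference_models()$canonical_bistable
subcritical <- reference_models()$subcritical_monostable
pitchfork   <- reference_models()$pitchfork_threshold
hill1       <- reference_models()$hill1_monostable

# count equilibria by sign changes of the composed residual on a dense
# reference grid (the brute-force oracle for the root finder)
oracle_equilibrium_count <- function(model, n_grid = 1e5) {
  a_max <- invariant_box(model)[["A_max"]]
  grid <- seq(0, 1.05 * a_max, length.out = n_grid)
  Fv <- composed_residual(model, grid)
  sum(sign(Fv[-length(Fv)]) * sign(Fv[-1]) < 0) + sum(Fv == 0)
}

# positive root of the h = 1 fixed-point quadratic
# delta_A a^2 + (delta_A delta_P + gamma_P - gamma_A) a - gamma_A delta_P = 0
oracle_hill1_root <- function(model) {
  eA <- effective_arm_A(model)
  gA <- eA$gamma; dA <- eA$delta
  gP <- model$arm_P$gamma; dP <- model$arm_P$delta
  b <- dA * dP + gP - gA
  (-b + sqrt(b^2 + 4 * dA * gA * dP)) / (2 * dA)
}

# small deterministic pool of random models for property tests
sampled_models <- function(n, seed = 20260928) {
  sample_models(fixture_spec(seed = seed, n_models = n),
                require_both_regimes = FALSE)$models
}
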