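test_that("integrate_loop reaches the closed-form attractor", {
  tr <- integrate_loop(canonical, c(2.5, 0.5), t_end = 50)
  fs <- attr(tr, "final_state")
  expect_equal(unname(fs), c(phi_hi, phi_lo), tolerance = 1e-4)
  expect_true(all(diff(tr$t) > 0))
  expect_true(all(tr$A >= 0 & tr$P >= 0))
})

test_that("zero stimulus decouples the loop to its single-ODE limits", {
  m0 <- set_stimulus(canonical, 0)  # gain mode: A production off
  tr <- integrate_loop(m0, c(1, 1), t_end = 60)
  fs <- attr(tr, "final_state")
  expect_equal(fs[["A"]], 0, tolerance = 1e-6)
  expect_equal(fs[["P"]], hill_max(m0$arm_P), tolerance = 1e-6)  # g_P(0)
})

test_that("an equilibrium initial condition stays put", {
  tr <- integrate_loop(canonical, c(phi_hi, phi_lo), t_end = 10, atol = 1e-10)
  fs <- attr(tr, "final_state")
  expect_equal(unname(fs), c(phi_hi, phi_lo), tolerance = 1e-8)
})

test_that("run_to_steady_state finds the basin-appropriate attractor", {
  res <- run_to_steady_state(canonical, c(0.1, 3))
  expect_true(res$converged)
  expect_equal(unname(res$state), c(phi_lo, phi_hi), tolerance = 1e-6)
  res2 <- run_to_steady_state(canonical, c(3, 0.1))
  expect_equal(unname(res2$state), c(phi_hi, phi_lo), tolerance = 1e-6)
})

test_that("a monostable model converges to its unique state from anywhere", {
  set.seed(31)
  for (i in 1:5) {
    init <- runif(2, 0, 1)
    res <- run_to_steady_state(subcritical, init)
    expect_true(res$converged)
    expect_equal(unname(res$state), c(subcrit_A, subcrit_A), tolerance = 1e-6)
  }
})

test_that("insufficient time reports non-convergence", {
  res <- run_to_steady_state(canonical, c(2.5, 0.5), max_time = 1e-6)
  expect_false(res$converged)
})

test_that("halving tolerances barely moves converged final states", {
  set.seed(32)
  for (m in sampled_models(5)) {
    box <- invariant_box(m)
    init <- c(runif(1, 0, box[["A_max"]]), runif(1, 0, box[["P_max"]]))
    a <- run_to_steady_state(m, init, rtol = 1e-8, atol = 1e-10)$state
    b <- run_to_steady_state(m, init, rtol = 5e-9, atol = 5e-11)$state
    expect_lt(sqrt(sum((a - b)^2)), 10 * 1e-8 + 1e-6)
  }
})

test_that("converged terminal states are equilibria known to the root finder", {
  set.seed(33)
  for (m in sampled_models(8)) {
    box <- invariant_box(m)
    init <- c(runif(1, 0, box[["A_max"]]), runif(1, 0, box[["P_max"]]))
    res <- run_to_steady_state(m, init)
    if (!res$converged) next
    expect_lt(sqrt(sum(vector_field(m, res$state)^2)), 1e-9 * (1 + 1e-6))
    eq <- find_equilibria(m)
    d <- sqrt((eq$A - res$state[["A"]])^2 + (eq$P - res$state[["P"]])^2)
    expect_lt(min(d), 1e-6)
  }
})

test_that("trajectory CSV export round-trips at full precision", {
  tr <- integrate_loop(canonical, c(2.5, 0.5), t_end = 5, n_out = 21)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  back <- utils::read.csv(path)
  expect_identical(names(back), c("t", "A", "P"))
  expect_equal(back$A, tr$A, tolerance = 1e-15)
  expect_equal(back$P, tr$P, tolerance = 1e-15)
})
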