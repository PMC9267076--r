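test_that("composed_residual has the documented sign structure", {
  # closed-form root of the canonical model
  expect_lt(abs(composed_residual(canonical, phi_hi)), 1e-12)
  set.seed(41)
  for (m in sampled_models(10)) {
    expect_gt(composed_residual(m, 0), 0)
    expect_lt(composed_residual(m, 2 * invariant_box(m)[["A_max"]]), 0)
  }
})

test_that("find_equilibria recovers the canonical model's three equilibria", {
  eq <- find_equilibria(canonical)
  expect_equal(nrow(eq), 3L)
  expect_identical(eq$stability, c("stable", "saddle", "stable"))
  expect_equal(eq$A, c(phi_lo, saddle_A, phi_hi), tolerance = 1e-8)
  expect_equal(eq$P, c(phi_hi, saddle_A, phi_lo), tolerance = 1e-8)
  # stable eigenvalues -1 +- 2/3; saddle eigenvalues -1 +- |g'(x*)|
  expect_equal(sort(Re(eq$eig1[c(1, 3)])), c(-1/3, -1/3), tolerance = 1e-6)
  expect_equal(sort(Re(eq$eig2[c(1, 3)])), c(-5/3, -5/3), tolerance = 1e-6)
  gs <- 2 * saddle_A^2 / (1 + saddle_A^2)  # |g'| at the symmetric saddle
  expect_equal(Re(eq$eig1[2]), -1 + gs, tolerance = 1e-6)
  expect_equal(Re(eq$eig2[2]), -1 - gs, tolerance = 1e-6)
})

test_that("the subcritical model has a single stable symmetric equilibrium", {
  eq <- find_equilibria(subcritical)
  expect_equal(nrow(eq), 1L)
  expect_identical(eq$stability, "stable")
  expect_equal(eq$A, subcrit_A, tolerance = 1e-8)
  expect_equal(eq$P, subcrit_A, tolerance = 1e-8)
})

test_that("Hill coefficient 1 forces a unique equilibrium (quadratic oracle)", {
  set.seed(42)
  for (i in 1:20) {
    m <- loop_model(hill_arm(runif(1, 0.5, 10), runif(1, 0.5, 2), 1),
                    hill_arm(runif(1, 0.5, 10), runif(1, 0.5, 2), 1),
                    tau_A = runif(1, 0.5, 2), tau_P = runif(1, 0.5, 2))
    eq <- find_equilibria(m)
    expect_equal(nrow(eq), 1L)
    expect_equal(eq$A, oracle_hill1_root(m), tolerance = 1e-8)
  }
})

test_that("classify_stability covers the planar cases", {
  expect_identical(classify_stability(c(-1/3, -5/3)), "stable")
  expect_identical(classify_stability(c(0.19105, -2.19105)), "saddle")
  expect_identical(classify_stability(c(0.5, 1.2)), "unstable")
  expect_identical(classify_stability(c(0, -2)), "marginal")
  expect_identical(classify_stability(complex(real = c(-0.5, -0.5),
                                              imaginary = c(1, -1))), "stable")
})

test_that("root counts agree with the dense-grid sign-change oracle", {
  models <- sampled_models(40, seed = 43)
  for (m in models) {
    expect_equal(nrow(find_equilibria(m)), oracle_equilibrium_count(m))
  }
})

test_that("equilibrium parity holds: stable count = saddle count + 1", {
  for (m in sampled_models(25, seed = 44)) {
    eq <- find_equilibria(m)
    expect_true(nrow(eq) %in% c(1L, 3L))
    expect_equal(sum(eq$stability == "stable"),
                 sum(eq$stability == "saddle") + 1L)
  }
})

test_that("the symmetric pitchfork threshold sits at gamma = 2", {
  count_at <- function(gamma) {
    arm <- hill_arm(gamma, 1, 2)
    nrow(find_equilibria(loop_model(arm, arm), grid_n = 5000))
  }
  lo <- 1.5; hi <- 2.5
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (count_at(mid) == 1L) lo <- mid else hi <- mid
  }
  expect_equal((lo + hi) / 2, 2, tolerance = 1e-3)
})

test_that("stable points attract small perturbations; saddles repel", {
  eq <- find_equilibria(canonical)
  for (i in seq_len(nrow(eq))) {
    start <- c(eq$A[i] + 1e-3, max(eq$P[i] - 1e-3, 0))  # off the separatrix diagonal
    res <- run_to_steady_state(canonical, start)
    d <- sqrt((res$state[["A"]] - eq$A[i])^2 + (res$state[["P"]] - eq$P[i])^2)
    if (eq$stability[i] == "stable") expect_lt(d, 1e-6) else expect_gt(d, 0.1)
  }
})

test_that("equilibria CSV export has the documented schema", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_equilibria_csv(find_equilibria(canonical), path)
  back <- utils::read.csv(path)
  expect_identical(names(back),
                   c("A", "P", "eig1_re", "eig1_im", "eig2_re", "eig2_im",
                     "stability"))
  expect_equal(back$A, c(phi_lo, saddle_A, phi_hi), tolerance = 1e-8)
})
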