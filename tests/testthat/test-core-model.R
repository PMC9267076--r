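test_that("loop_model validates and applies the stimulus coupling", {
  arm <- hill_arm(3, 1, 2)
  expect_error(loop_model(arm, arm, tau_A = 0), "tau_A")
  expect_error(loop_model(arm, arm, stimulus = -1), "stimulus")
  m_gain <- loop_model(arm, arm, stimulus_mode = "gain", stimulus = 2)
  expect_equal(effective_arm_A(m_gain)$gamma, 6)
  expect_equal(effective_arm_A(m_gain)$delta, 1)
  m_thr <- loop_model(arm, arm, stimulus_mode = "threshold", stimulus = 2)
  expect_equal(effective_arm_A(m_thr)$gamma, 3)
  expect_equal(effective_arm_A(m_thr)$delta, 0.5)
  # threshold mode at s = 0 uses the documented floor instead of dividing by 0
  m_thr0 <- set_stimulus(m_thr, 0)
  expect_true(is.finite(effective_arm_A(m_thr0)$delta))
})

test_that("vector_field vanishes at the closed-form fixed point", {
  # (A, P) = ((3+sqrt(5))/2, (3-sqrt(5))/2): 1 + P^2 = 3P so g(P) = 1/P = A
  expect_equal(unname(vector_field(canonical, c(phi_hi, phi_lo))), c(0, 0),
               tolerance = 1e-12)
  # A-nullcline: any state (g_A(P), P) has dA/dt = 0
  set.seed(21)
  for (m in sampled_models(10)) {
    P <- runif(1, 0, invariant_box(m)[["P_max"]])
    eA <- effective_arm_A(m)
    A <- eA$gamma / (eA$delta^eA$h + P^eA$h)
    expect_equal(vector_field(m, c(A, P))[["dA"]], 0, tolerance = 1e-14)
  }
  # zero gain kills production: dA/dt = -A / tau_A
  m0 <- set_stimulus(canonical, 0)
  expect_equal(vector_field(m0, c(1.7, 0.4))[["dA"]], -1.7)
})

test_that("jacobian matches finite differences and the monotone sign structure", {
  # pitchfork-threshold model at its symmetric point: marginal linearization
  J <- jacobian(pitchfork, c(1, 1))
  expect_equal(unname(J), matrix(c(-1, -1, -1, -1), 2), tolerance = 1e-12)
  expect_equal(sort(eigen(J)$values), c(-2, 0), tolerance = 1e-12)
  set.seed(22)
  for (m in sampled_models(10)) {
    box <- invariant_box(m)
    st <- c(runif(1, 0.01, box[["A_max"]]), runif(1, 0.01, box[["P_max"]]))
    J <- jacobian(m, st)
    expect_true(all(diag(J) < 0))
    expect_true(all(J[row(J) != col(J)] < 0))
    eps <- 1e-6
    fd <- matrix(NA_real_, 2, 2)
    for (k in 1:2) {
      dp <- dm <- st
      dp[k] <- dp[k] + eps; dm[k] <- dm[k] - eps
      fd[, k] <- (vector_field(m, dp) - vector_field(m, dm)) / (2 * eps)
    }
    expect_equal(unname(J), fd, tolerance = 1e-6)
  }
})

test_that("the invariant box is forward invariant under the flow", {
  set.seed(23)
  for (m in sampled_models(5)) {
    box <- invariant_box(m)
    inits <- rbind(c(0, 0), box,
                   cbind(runif(3, 0, box[["A_max"]]), runif(3, 0, box[["P_max"]])))
    for (r in seq_len(nrow(inits))) {
      tr <- integrate_loop(m, inits[r, ], t_end = 20, n_out = 101)
      expect_true(all(tr$A >= 0 & tr$A <= box[["A_max"]] * (1 + 1e-8)))
      expect_true(all(tr$P >= 0 & tr$P <= box[["P_max"]] * (1 + 1e-8)))
    }
  }
})

test_that("model JSON configs round-trip and reject unknown keys", {
  m <- loop_model(hill_arm(2.5, 0.8, 1.7), hill_arm(4, 1.2, 3),
                  tau_A = 0.6, tau_P = 1.4,
                  stimulus_mode = "threshold", stimulus = 0.9)
  path <- withr::local_tempfile(fileext = ".json")
  write_loop_model(m, path)
  m2 <- read_loop_model(path)
  expect_equal(m2, m)
  cfg <- jsonlite::fromJSON(path)
  cfg$extra_knob <- 1
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, path2, auto_unbox = TRUE)
  expect_error(read_loop_model(path2), "unknown model config key")
  cfg$extra_knob <- NULL
  cfg$tau_A <- NULL
  jsonlite::write_json(cfg, path2, auto_unbox = TRUE)
  expect_error(read_loop_model(path2), "missing model config key")
})
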